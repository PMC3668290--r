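#' Draw noise-SNP minor allele frequencies
#'
#' Noise SNPs receive MAFs drawn i.i.d. from the uniform distribution on
#' (0.05, 0.5) (configurable range).
#'
#' @param k number of frequencies to draw.
#' @param range lower/upper bounds of the uniform distribution.
#' @return numeric vector of length `k`.
#' @examples
#' set.seed(1); drawNoiseMafs(5)
#' @export
drawNoiseMafs <- function(k, range = c(0.05, 0.5)) {
  stopifnot(k >= 0, length(range) == 2L, range[1] < range[2])
  runif(k, range[1], range[2])
}

#' Simulate genotypes under Hardy-Weinberg and linkage equilibrium
#'
#' Each SNP's minor-allele count is Binomial(2, maf) per individual (HWE);
#' SNPs are mutually independent (linkage equilibrium).
#'
#' @param n number of individuals.
#' @param mafs minor allele frequency per SNP, each in (0, 0.5].
#' @param snpIds optional column names.
#' @return n x length(mafs) integer matrix with entries in {0, 1, 2}.
#' @examples
#' set.seed(1)
#' G <- simulateGenotypes(100, c(0.5, 0.1))
#' colMeans(G) / 2  # close to the MAFs
#' @export
simulateGenotypes <- function(n, mafs, snpIds = NULL) {
  stopifnot(n >= 1)
  if (any(mafs <= 0 | mafs > 0.5))
    stop("minor allele frequencies must lie in (0, 0.5]")
  m <- length(mafs)
  G <- matrix(rbinom(n * m, 2L, rep(mafs, each = n)), nrow = n, ncol = m)
  storage.mode(G) <- "integer"
  colnames(G) <- if (is.null(snpIds)) paste0("SNP", seq_len(m)) else snpIds
  G
}

#' Checkerboard (M170) high-trait indicator
#'
#' Under the two-locus checkerboard epistasis model an individual has an
#' elevated trait iff it is heterozygous at exactly one of the two causal
#' loci and homozygous at the other: cells (0,1), (2,1), (1,0), (1,2) of the
#' 3x3 genotype grid. The double heterozygote (1,1) and all double
#' homozygotes are unaffected. With both MAFs at 0.5 the model has no
#' marginal effects (pure epistasis).
#'
#' @param g1,g2 genotype codes (minor-allele counts in {0,1,2}), vectorized.
#' @return logical vector.
#' @examples
#' m170HighIndicator(c(1, 1, 0), c(0, 1, 2))
#' @export
m170HighIndicator <- function(g1, g2) {
  if (any(!(g1 %in% 0:2)) || any(!(g2 %in% 0:2)))
    stop("genotype codes must be 0, 1 or 2")
  xor(g1 == 1L, g2 == 1L)
}

#' Draw a residual-distribution scenario
#'
#' Builds the per-cell residual distributions of one replicate:
#' \describe{
#'   \item{normal}{heteroscedastic: 9 cell variances i.i.d. U(1, 10);
#'     homoscedastic: all cells share the mean of one such draw of 9.}
#'   \item{chi_square}{homoscedastic: central chi-square, df = 2, in every
#'     cell (variance 4); heteroscedastic: per-cell df ~ U(2, 10) with
#'     non-centrality ncp = 10 - df, so every cell mean is 10 and the cell
#'     variance 2 df + 4 ncp ranges over (20, 36).}
#'   \item{t_dist}{homoscedastic: Student t, df = 3, in every cell
#'     (variance 3); heteroscedastic: per-cell target variances v ~
#'     U(3, 10), imposed by scaling t(3) draws by sqrt(v / 3). The
#'     alternative reading of a U(3, 10) heterogeneity specification —
#'     per-cell degrees of freedom df ~ U(3, 10), hence variances
#'     df / (df - 2) — is available as `tHeteroMode = "df"`.}
#' }
#'
#' @param scenario family tag.
#' @param homoscedastic logical.
#' @param tHeteroMode heteroscedastic t parameterization: `"variance"`
#'   (default) or `"df"`.
#' @return A [ScenarioSpec-class] with `effectSize = 0`; see
#'   [calibrateEffect()].
#' @examples
#' set.seed(1)
#' makeScenario("chi_square", homoscedastic = FALSE)
#' @export
makeScenario <- function(scenario = c("normal", "chi_square", "t_dist"),
                         homoscedastic = TRUE,
                         tHeteroMode = c("variance", "df")) {
  scenario <- match.arg(scenario)
  tHeteroMode <- match.arg(tHeteroMode)
  maxNcp <- 10
  if (scenario == "normal") {
    v <- runif(9, 1, 10)
    if (homoscedastic) v <- rep(mean(v), 9)
    df <- rep(1, 9)  # unused for the normal family
    ncp <- rep(0, 9)
  } else if (scenario == "chi_square") {
    if (homoscedastic) {
      df <- rep(2, 9)
      ncp <- rep(0, 9)
    } else {
      df <- runif(9, 2, 10)
      ncp <- maxNcp - df
    }
    v <- 2 * df + 4 * ncp
  } else {
    ncp <- rep(0, 9)
    if (homoscedastic) {
      df <- rep(3, 9)
      v <- rep(3, 9)
    } else if (tHeteroMode == "variance") {
      df <- rep(3, 9)
      v <- runif(9, 3, 10)
    } else {
      df <- runif(9, 3, 10)
      v <- df / (df - 2)
    }
  }
  new("ScenarioSpec", family = scenario, homoscedastic = homoscedastic,
      cellVariance = v, cellDf = df, cellNcp = ncp, maxNcp = maxNcp,
      effectSize = 0)
}

#' Probability of the checkerboard high cell under HWE
#'
#' Enumerates the nine two-locus HWE cell probabilities and sums those with
#' exactly one heterozygous locus. Equals 0.5 when both MAFs are 0.5.
#'
#' @param maf1,maf2 causal minor allele frequencies.
#' @return scalar probability.
#' @examples
#' highCellProbability(0.5, 0.5)
#' @export
highCellProbability <- function(maf1, maf2 = maf1) {
  p1 <- c((1 - maf1)^2, 2 * maf1 * (1 - maf1), maf1^2)
  p2 <- c((1 - maf2)^2, 2 * maf2 * (1 - maf2), maf2^2)
  grid <- outer(0:2, 0:2, function(a, b) m170HighIndicator(a, b))
  sum(outer(p1, p2)[grid])
}

#' Calibrate the additive high-cell effect for a target variance fraction
#'
#' The epistatic signal is an additive mean shift beta on the checkerboard
#' high cells. With high-cell probability p and expected residual variance
#' s2, total variance is beta^2 p (1 - p) + s2, so the shift achieving an
#' epistatic fraction g2 is
#' `beta = sqrt(g2 / (1 - g2) * s2 / (p * (1 - p)))`.
#'
#' @param g2 target epistatic variance fraction in `[0, 1)`.
#' @param pHigh probability of the high-indicator cells.
#' @param residualVariance expected residual variance (the mean of the nine
#'   per-cell variances of the scenario).
#' @return the mean shift beta.
#' @examples
#' calibrateEffect(0.05, 0.5, 5.5)
#' @export
calibrateEffect <- function(g2, pHigh, residualVariance) {
  if (g2 < 0 || g2 >= 1) stop("g2 must lie in [0, 1)")
  stopifnot(pHigh > 0, pHigh < 1, residualVariance > 0)
  if (g2 == 0) return(0)
  sqrt(g2 / (1 - g2) * residualVariance / (pHigh * (1 - pHigh)))
}

#' Expected residual variance of a scenario
#'
#' The unweighted mean of the nine per-cell residual variances — the same
#' quantity the homoscedastic normal construction equalizes across cells.
#'
#' @param spec a [ScenarioSpec-class].
#' @return scalar variance.
#' @export
scenarioResidualVariance <- function(spec) {
  stopifnot(is(spec, "ScenarioSpec"))
  mean(spec@cellVariance)
}

#' Set the calibrated high-cell effect on a scenario
#'
#' @param spec a [ScenarioSpec-class].
#' @param value nonnegative mean shift.
#' @return the updated spec.
#' @export
`effectSize<-` <- function(spec, value) {
  spec@effectSize <- value
  validObject(spec)
  spec
}

#' Simulate a quantitative trait from the two-locus model
#'
#' For each individual the residual is drawn from the distribution of its
#' causal-pair genotype cell (columns 1 and 2 of `G`), and the calibrated
#' shift `effectSize(spec)` is added when the individual falls in a
#' checkerboard high cell.
#'
#' @param G genotype matrix whose first two columns are the causal pair.
#' @param spec a [ScenarioSpec-class].
#' @return numeric trait vector of length `nrow(G)`.
#' @examples
#' set.seed(1)
#' G <- simulateGenotypes(200, c(0.5, 0.5))
#' sp <- makeScenario("normal")
#' y <- simulateTrait(G, sp)
#' @export
simulateTrait <- function(G, spec) {
  stopifnot(is(spec, "ScenarioSpec"), ncol(G) >= 2L)
  n <- nrow(G)
  cell <- 3L * G[, 1L] + G[, 2L] + 1L  # 1..9, row-major in locus 1
  v <- spec@cellVariance[cell]
  y <- switch(spec@family,
    normal = rnorm(n, 0, sqrt(v)),
    chi_square = {
      df <- spec@cellDf[cell]
      ncp <- spec@cellNcp[cell]
      if (all(ncp == 0)) rchisq(n, df) else rchisq(n, df, ncp)
    },
    t_dist = {
      df <- spec@cellDf[cell]
      # scale a t(df) draw (variance df/(df-2)) to the cell's target variance
      rt(n, df) * sqrt(v * (df - 2) / df)
    }
  )
  high <- m170HighIndicator(G[, 1L], G[, 2L])
  y + spec@effectSize * high
}

#' Simulate one replicate dataset of a setting
#'
#' Derives a deterministic sub-stream from (master seed, setting, replicate
#' index), redraws noise MAFs and the residual scenario, calibrates the
#' high-cell shift to the configured g2, and simulates genotypes and trait.
#' The causal pair occupies columns 1 and 2.
#'
#' @param cfg a [SimulationConfig-class].
#' @param replicate replicate index (1-based).
#' @return list with elements `genotypes` (n x m integer matrix), `trait`
#'   (numeric n-vector), `scenario` (the [ScenarioSpec-class] used, with its
#'   calibrated effect) and `seed` (the derived sub-stream seed).
#' @examples
#' cfg <- simulationConfig(g2 = 0.1, nNoiseSnps = 8L, seed = 7L)
#' rep1 <- simulateReplicate(cfg, 1)
#' dim(rep1$genotypes)
#' @export
simulateReplicate <- function(cfg, replicate = 1L) {
  stopifnot(is(cfg, "SimulationConfig"), replicate >= 1)
  seed <- mixSeed(cfg@seed, settingId(cfg), replicate)
  withr::with_seed(seed, {
    mafs <- c(cfg@causalMaf, cfg@causalMaf,
              drawNoiseMafs(cfg@nNoiseSnps, cfg@noiseMafRange))
    G <- simulateGenotypes(cfg@nIndividuals, mafs)
    spec <- makeScenario(cfg@scenario, cfg@homoscedastic)
    if (cfg@g2 > 0) {
      pHigh <- highCellProbability(cfg@causalMaf)
      effectSize(spec) <- calibrateEffect(cfg@g2, pHigh,
                                          scenarioResidualVariance(spec))
    }
    y <- simulateTrait(G, spec)
    list(genotypes = G, trait = y, scenario = spec, seed = seed)
  })
}
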