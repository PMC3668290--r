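#' Run one replicate of the robustness study
#'
#' Simulates one dataset from the setting, applies the trait
#' transformation, runs the MB-MDR scan, and reports which kinds of pairs
#' reached significance. The permutation seed is derived from the same
#' (master seed, setting, replicate) stream as the data, offset so data and
#' permutations are independent.
#'
#' @param simCfg a [SimulationConfig-class].
#' @param acfg an [AnalysisConfig-class].
#' @param transform transformation tag, see [traitTransform()].
#' @param replicate replicate index.
#' @return list with logicals `causalSignificant` (the pair in columns 1-2),
#'   `anyNoncausalSignificant`, `anySignificant`, and integer
#'   `nNoncausalSignificant`.
#' @export
runReplicate <- function(simCfg, acfg, transform = "raw", replicate = 1L) {
  d <- simulateReplicate(simCfg, replicate)
  y <- traitTransform(d$trait, transform)
  acfg@seed <- mixSeed(acfg@seed, d$seed, 777L)
  res <- runMbmdr(d$genotypes, y, acfg)
  p <- pairResults(res)
  causal <- p$significant[1L]  # causal pair is the first lexicographic pair
  nonc <- sum(p$significant[-1L])
  list(causalSignificant = causal,
       anyNoncausalSignificant = nonc > 0L,
       anySignificant = causal || nonc > 0L,
       nNoncausalSignificant = nonc)
}

#' Estimate FWER, power and false-positive rates over replicates
#'
#' Runs `R` replicates of one study cell. Under the null (g2 = 0) the
#' familywise error rate is the fraction of replicates with any significant
#' pair. Under an effect (g2 > 0) the power is the fraction in which the
#' causal pair is significant, and the false-positive rate the fraction
#' with at least one significant non-causal pair (`fpMode = "familywise"`)
#' or the mean count of significant non-causal pairs
#' (`fpMode = "mean_count"`).
#'
#' @param simCfg a [SimulationConfig-class]; `simCfg@nReplicates` is
#'   overridden by `R`.
#' @param acfg an [AnalysisConfig-class].
#' @param transform transformation tag.
#' @param R number of replicates.
#' @param fpMode false-positive summary for g2 > 0 settings.
#' @return data.frame of study cells: one `fwer` row when g2 = 0, else
#'   `power` and `fp` rows; columns include the Monte-Carlo standard error
#'   `mcSE = sqrt(est (1 - est) / R)`.
#' @examples
#' \donttest{
#' cfg <- simulationConfig(nNoiseSnps = 8L, seed = 5L)
#' estimateRates(cfg, analysisConfig(nPermutations = 99L), R = 5)
#' }
#' @export
estimateRates <- function(simCfg, acfg, transform = "raw", R = 100L,
                          fpMode = c("familywise", "mean_count")) {
  fpMode <- match.arg(fpMode)
  stopifnot(R >= 1)
  hits <- vapply(seq_len(R), function(r) {
    out <- runReplicate(simCfg, acfg, transform, r)
    c(out$causalSignificant, out$anyNoncausalSignificant,
      out$anySignificant, out$nNoncausalSignificant)
  }, numeric(4))
  cellRow <- function(metric, est) {
    data.frame(scenario = simCfg@scenario,
               homoscedastic = simCfg@homoscedastic,
               g2 = simCfg@g2, test = acfg@testKind,
               transform = transform, metric = metric,
               estimate = est,
               mcSE = sqrt(max(est, 0) * max(1 - est, 0) / R),
               nReplicates = R, stringsAsFactors = FALSE)
  }
  if (simCfg@g2 == 0) {
    cellRow("fwer", mean(hits[3, ]))
  } else {
    fp <- if (fpMode == "familywise") mean(hits[2, ]) else mean(hits[4, ])
    rbind(cellRow("power", mean(hits[1, ])), cellRow("fp", fp))
  }
}

#' Bradley's liberal robustness criterion
#'
#' An empirical rejection rate is considered under control at level `alpha`
#' when it lies in the closed interval `[0.5 alpha, 1.5 alpha]`.
#'
#' @param rate empirical rate.
#' @param alpha nominal level.
#' @return logical (vectorized over `rate`).
#' @examples
#' bradleyCheck(c(0.04, 0.08, 0.025), 0.05)
#' @export
bradleyCheck <- function(rate, alpha = 0.05) {
  stopifnot(alpha > 0, alpha < 1)
  rate >= 0.5 * alpha & rate <= 1.5 * alpha
}

# display name of a test x transform arm, e.g. Rank_ST, WT
armName <- function(test, transform) {
  tst <- c(student = "ST", welch = "WT")[[test]]
  pre <- c(raw = "", log = "Log_", stz = "Stz_", rank = "Rank_",
           rtn = "Rtn_")[[transform]]
  paste0(pre, tst)
}

#' Lay study cells out as the report tables
#'
#' Pivots a long data.frame of study cells (as produced by
#' [estimateRates()], row-bound over settings and arms) into the familiar
#' wide layout: one row per g2 x distribution x variance status, one column
#' per test-transform arm (ST, WT, Rank_ST, ...), values the estimated
#' rates. A parallel wide table of Monte-Carlo standard errors is attached
#' as attribute `"mcSE"`.
#'
#' @param cells long data.frame of study cells.
#' @param metric which metric to tabulate (`"fwer"`, `"power"` or `"fp"`).
#' @return wide data.frame.
#' @export
renderTables <- function(cells, metric = c("fwer", "power", "fp")) {
  metric <- match.arg(metric)
  cells <- cells[cells$metric == metric, , drop = FALSE]
  if (!nrow(cells)) stop("no study cells for metric ", metric)
  cells$arm <- mapply(armName, cells$test, cells$transform)
  cells$rowKey <- paste(cells$g2, cells$scenario,
                        ifelse(cells$homoscedastic, "Equal", "Unequal"))
  rows <- unique(cells[, c("rowKey", "g2", "scenario", "homoscedastic")])
  arms <- unique(cells$arm)
  wide <- data.frame(
    g2 = rows$g2, distribution = rows$scenario,
    variances = ifelse(rows$homoscedastic, "Equal", "Unequal"),
    stringsAsFactors = FALSE)
  se <- wide
  for (a in arms) {
    est <- rep(NA_real_, nrow(rows))
    ms <- rep(NA_real_, nrow(rows))
    sub <- cells[cells$arm == a, , drop = FALSE]
    pos <- match(sub$rowKey, rows$rowKey)
    est[pos] <- sub$estimate
    ms[pos] <- sub$mcSE
    wide[[a]] <- est
    se[[a]] <- ms
  }
  attr(wide, "mcSE") <- se
  wide
}

#' Run the simulation-study grid
#'
#' Orchestrates [estimateRates()] over a grid of settings and analysis
#' arms, writing one TSV per study cell into `outDir` (cells whose file
#' already exists are skipped, so an interrupted study resumes), plus the
#' aggregated long table and a JSON metadata sidecar.
#'
#' @param scenarios residual families to cover.
#' @param homoscedastic variance statuses to cover.
#' @param g2s epistatic variance fractions to cover.
#' @param tests association tests to cover.
#' @param transforms transformation tags to cover.
#' @param preset `"desk"` (R = 100, B = 199) for reduced-scale runs or
#'   `"paper"` (R = 1000, B = 999) for the full-scale grid; `R`, `B`
#'   override the preset when given.
#' @param R,B replicate and permutation counts.
#' @param nIndividuals,nNoiseSnps cohort and panel size.
#' @param seed master seed.
#' @param outDir output directory, or `NULL` to skip writing.
#' @return long data.frame of all study cells.
#' @export
runStudy <- function(scenarios = c("normal", "chi_square", "t_dist"),
                     homoscedastic = c(TRUE, FALSE),
                     g2s = c(0, 0.05, 0.1),
                     tests = c("student", "welch"),
                     transforms = c("raw", "log", "stz", "rank", "rtn"),
                     preset = c("desk", "paper"),
                     R = NULL, B = NULL,
                     nIndividuals = 500L, nNoiseSnps = 98L,
                     seed = 1L, outDir = NULL) {
  preset <- match.arg(preset)
  if (is.null(R)) R <- if (preset == "desk") 100L else 1000L
  if (is.null(B)) B <- if (preset == "desk") 199L else 999L
  if (!is.null(outDir) && !dir.exists(outDir))
    dir.create(outDir, recursive = TRUE)
  grid <- expand.grid(scenario = scenarios, homo = homoscedastic,
                      g2 = g2s, test = tests, transform = transforms,
                      stringsAsFactors = FALSE)
  out <- vector("list", nrow(grid))
  for (k in seq_len(nrow(grid))) {
    g <- grid[k, ]
    tag <- paste(g$scenario, ifelse(g$homo, "eq", "uneq"),
                 paste0("g", g$g2 * 100), g$test, g$transform, sep = "_")
    cellPath <- if (is.null(outDir)) NULL
                else file.path(outDir, paste0("cell_", tag, ".tsv"))
    if (!is.null(cellPath) && file.exists(cellPath)) {
      out[[k]] <- read.delim(cellPath, stringsAsFactors = FALSE)
      next
    }
    simCfg <- simulationConfig(nIndividuals = nIndividuals,
                               nNoiseSnps = nNoiseSnps, g2 = g$g2,
                               scenario = g$scenario,
                               homoscedastic = g$homo,
                               nReplicates = R, seed = seed)
    acfg <- analysisConfig(testKind = g$test, nPermutations = B,
                           seed = seed)
    cell <- estimateRates(simCfg, acfg, g$transform, R)
    out[[k]] <- cell
    if (!is.null(cellPath))
      write.table(cell, cellPath, sep = "\t", quote = FALSE,
                  row.names = FALSE)
  }
  cells <- do.call(rbind, out)
  if (!is.null(outDir)) {
    writeResults(cells, file.path(outDir, "study_cells.tsv"),
                 seed = seed,
                 meta = list(R = R, B = B, n = nIndividuals,
                             m = nNoiseSnps + 2L))
  }
  cells
}
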