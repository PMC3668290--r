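#' Partition individuals over the nine two-locus genotype cells
#'
#' @param G genotype matrix (0/1/2 entries).
#' @param i,j distinct column indices of the SNP pair.
#' @return list with `members` (list of 9 index vectors, cell order
#'   row-major in the genotype of SNP `i`) and `counts` (3x3 integer
#'   matrix, rows = genotype of SNP `i`).
#' @examples
#' set.seed(1)
#' G <- simulateGenotypes(100, c(0.5, 0.5))
#' partitionPair(G, 1, 2)$counts
#' @export
partitionPair <- function(G, i, j) {
  stopifnot(i != j, i >= 1, j >= 1, i <= ncol(G), j <= ncol(G))
  cell <- 3L * G[, i] + G[, j] + 1L
  members <- split(seq_len(nrow(G)), factor(cell, levels = 1:9))
  counts <- matrix(lengths(members), 3L, 3L, byrow = TRUE)
  storage.mode(counts) <- "integer"
  list(members = members, counts = counts)
}

#' Label the genotype cells of one SNP pair H, L or O
#'
#' Dimensionality-reduction step: each cell holding at least `minCell`
#' individuals (with at least `minCell` in its complement) is tested against
#' the pooled remaining individuals with the configured two-group test. A
#' cell is "H" when the test is significant at `alphaLabel` with the cell
#' mean above the rest, "L" when below; anything else — including cells
#' failing the size rule — is "O".
#'
#' @param cells output of [partitionPair()].
#' @param y trait vector.
#' @param cfg an [AnalysisConfig-class].
#' @return A [LabelGrid-class].
#' @examples
#' set.seed(1)
#' G <- simulateGenotypes(500, c(0.5, 0.5))
#' sp <- makeScenario("normal"); effectSize(sp) <- 2
#' y <- simulateTrait(G, sp)
#' labelCells(partitionPair(G, 1, 2), y, analysisConfig())
#' @export
labelCells <- function(cells, y, cfg) {
  stopifnot(is(cfg, "AnalysisConfig"))
  n <- length(y)
  testFun <- if (cfg@testKind == "student") studentT else welchT
  labels <- matrix("O", 3L, 3L)
  for (c in 1:9) {
    idx <- cells$members[[c]]
    nc <- length(idx)
    if (nc < cfg@minCell || n - nc < cfg@minCell) next
    res <- testFun(y[idx], y[-idx])
    if (res$valid && res$pValue <= cfg@alphaLabel) {
      lab <- if (res$statistic > 0) "H" else if (res$statistic < 0) "L"
             else "O"
      labels[(c - 1) %/% 3 + 1, (c - 1) %% 3 + 1] <- lab
    }
  }
  new("LabelGrid", labels = labels, cellCounts = cells$counts)
}

#' MB-MDR step-2 statistic for one labeled pair
#'
#' The per-pair epistasis evidence: the larger of the squared test
#' statistics for pooled H cells versus everyone else and pooled L cells
#' versus everyone else. A branch with no labeled cells, or whose pooling
#' violates the minimum-size rule on either side, contributes 0.
#'
#' @param grid a [LabelGrid-class].
#' @param cells output of [partitionPair()] the grid was built from.
#' @param y trait vector.
#' @param cfg an [AnalysisConfig-class].
#' @return nonnegative F value.
#' @export
step2Statistic <- function(grid, cells, y, cfg) {
  stopifnot(is(grid, "LabelGrid"), is(cfg, "AnalysisConfig"))
  n <- length(y)
  testFun <- if (cfg@testKind == "student") studentT else welchT
  lab <- as.vector(t(grid@labels))  # cell order 3*g1 + g2
  branch <- function(which) {
    idx <- unlist(cells$members[lab == which], use.names = FALSE)
    k <- length(idx)
    if (k < cfg@minCell || n - k < cfg@minCell) return(0)
    res <- testFun(y[idx], y[-idx])
    if (res$valid) res$fValue else 0
  }
  max(branch("H"), branch("L"))
}

# Run the compiled scan kernel. Y columns are analyzed independently; the
# first column is conventionally the observed trait.
scanKernel <- function(G, Y, cfg, exportCell = -1L) {
  storage.mode(G) <- "integer"
  if (is.null(dim(Y))) Y <- matrix(Y, ncol = 1L)
  .mbmdrScanKernel(G, Y,
                   if (cfg@testKind == "student") 0L else 1L,
                   cfg@minCell, cfg@alphaLabel, as.integer(exportCell))
}

#' Step-2 statistics for every SNP pair
#'
#' Runs the labeling and step-2 stages over all `m (m - 1) / 2` unordered
#' SNP pairs in lexicographic order (see [pairIndices()]).
#'
#' @param G genotype matrix.
#' @param y trait vector.
#' @param cfg an [AnalysisConfig-class].
#' @return numeric vector of step-2 F values, one per pair.
#' @export
analyzeAllPairs <- function(G, y, cfg) {
  stopifnot(ncol(G) >= 2L, nrow(G) == length(y), is(cfg, "AnalysisConfig"))
  as.vector(scanKernel(G, y, cfg)$stats)
}

# trait permutation matrix: n x B, column b = y[perm_b]
permuteTraits <- function(y, B, seed) {
  n <- length(y)
  withr::with_seed(seed, {
    out <- matrix(0, n, B)
    for (b in seq_len(B)) out[, b] <- y[sample.int(n)]
    out
  })
}

# Westfall-Young step-down maxT from observed statistics and a B x P matrix
# of permutation statistics. +1 convention in numerator and denominator;
# ties in the observed ranking are broken by the stable lexicographic pair
# order; permutation comparisons use >=.
maxtStepDown <- function(observed, permStats) {
  P <- length(observed)
  B <- nrow(permStats)
  ord <- order(-observed)            # stable: ties keep pair order
  M <- permStats[, ord, drop = FALSE]
  if (P > 1) {
    for (k in (P - 1):1) M[, k] <- pmax(M[, k], M[, k + 1]) # successive maxima
  }
  exceed <- colSums(M >= rep(observed[ord], each = B))
  padj <- cummax((1 + exceed) / (B + 1))   # enforce step-down monotonicity
  out <- numeric(P)
  out[ord] <- padj
  out
}

#' Step-down maxT adjusted p-values
#'
#' For each of B permutations the trait vector is re-shuffled across
#' individuals (genotypes fixed) and the full per-pair analysis — cell
#' labeling and the step-2 maximum — is redone, which is what keeps the
#' permutation null honest. Adjusted p-values follow the Westfall-Young
#' step-down construction with successive maxima and the +1 convention, so
#' they lie in `[1/(B+1), 1]` and are nondecreasing along decreasing
#' observed statistics.
#'
#' @param G genotype matrix.
#' @param y trait vector.
#' @param observed statistics from [analyzeAllPairs()] on `(G, y)`.
#' @param cfg an [AnalysisConfig-class]; `cfg@seed` drives the permutation
#'   stream.
#' @return numeric vector of adjusted p-values aligned with `observed`.
#' @export
maxtAdjust <- function(G, y, observed, cfg) {
  stopifnot(length(observed) == ncol(G) * (ncol(G) - 1) / 2)
  B <- cfg@nPermutations
  Y <- permuteTraits(y, B, cfg@seed)
  permStats <- scanKernel(G, Y, cfg)$stats
  maxtStepDown(observed, permStats)
}

#' Run a full MB-MDR scan
#'
#' Computes every pair's step-2 statistic, the step-down maxT adjusted
#' p-values from `cfg@nPermutations` trait permutations, and the
#' significance calls at `cfg@alphaOverall`.
#'
#' @param G genotype matrix (individuals x SNPs, minor-allele counts).
#' @param y quantitative trait vector, already transformed if desired.
#' @param cfg an [AnalysisConfig-class].
#' @return An [MbmdrResult-class].
#' @examples
#' cfg <- simulationConfig(g2 = 0.1, nNoiseSnps = 8L, seed = 3L)
#' d <- simulateReplicate(cfg, 1)
#' res <- runMbmdr(d$genotypes, d$trait,
#'                 analysisConfig(nPermutations = 99L, seed = 3L))
#' significantPairs(res)
#' @export
runMbmdr <- function(G, y, cfg = analysisConfig()) {
  stopifnot(nrow(G) == length(y), all(is.finite(y)))
  B <- cfg@nPermutations
  Y <- cbind(y, permuteTraits(y, B, cfg@seed))
  stats <- scanKernel(G, Y, cfg)$stats
  observed <- stats[1L, ]
  padj <- maxtStepDown(observed, stats[-1L, , drop = FALSE])
  idx <- pairIndices(ncol(G))
  snps <- colnames(G)
  if (is.null(snps)) snps <- paste0("SNP", seq_len(ncol(G)))
  pairs <- data.frame(
    snpI = snps[idx$i], snpJ = snps[idx$j],
    step2F = observed, adjustedP = padj,
    significant = padj <= cfg@alphaOverall,
    stringsAsFactors = FALSE)
  new("MbmdrResult", pairs = pairs, config = cfg,
      nIndividuals = nrow(G))
}

#' Pooled permutation null statistics for qq diagnostics
#'
#' Re-runs the permutation analysis and pools, over all SNP pairs and all
#' `cfg@nPermutations` permutations, either the step-2 statistics or the
#' cell-versus-rest F values of one fixed genotype cell. Under complete-data
#' permutation these cell-versus-rest statistics should track F(1, n - 2);
#' the step-2 statistic, being a maximum of two tests, is stochastically
#' larger.
#'
#' @param G genotype matrix.
#' @param y trait vector.
#' @param cfg an [AnalysisConfig-class].
#' @param which `"step2"` or `"cell"`.
#' @param cell length-2 integer genotype codes (e.g. `c(0, 0)`) selecting
#'   the fixed cell when `which = "cell"`.
#' @return numeric vector of pooled F values; cell comparisons undefined
#'   under the minimum-size rule are dropped.
#' @export
exportNullStatistics <- function(G, y, cfg, which = c("step2", "cell"),
                                 cell = c(0L, 0L)) {
  which <- match.arg(which)
  B <- cfg@nPermutations
  Y <- permuteTraits(y, B, cfg@seed)
  if (which == "step2") {
    as.vector(scanKernel(G, Y, cfg)$stats)
  } else {
    stopifnot(length(cell) == 2L, all(cell %in% 0:2))
    out <- scanKernel(G, Y, cfg, exportCell = 3L * cell[1] + cell[2])
    v <- as.vector(out$cellF)
    v[!is.na(v)]
  }
}
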