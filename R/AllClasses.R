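#' Simulation configuration for the two-locus epistasis model
#'
#' Describes one simulation setting: cohort size, SNP panel, the epistatic
#' variance fraction g2, the residual-distribution scenario and its
#' homo-/heteroscedasticity, and the master seed. Defaults are the study
#' conditions: 500 unrelated individuals, 2 causal SNPs at minor allele
#' frequency 0.5 plus 98 noise SNPs with MAFs uniform on (0.05, 0.5), all in
#' Hardy-Weinberg and linkage equilibrium.
#'
#' @slot nIndividuals cohort size per replicate.
#' @slot nNoiseSnps number of non-causal SNPs.
#' @slot causalMaf minor allele frequency of the two causal SNPs; the
#'   checkerboard model is pure-epistatic (no marginal effects) at 0.5.
#' @slot noiseMafRange lower/upper bound of the uniform MAF distribution for
#'   noise SNPs.
#' @slot g2 fraction of total trait variance attributable to the epistatic
#'   component, in `[0, 1)`.
#' @slot scenario residual family: `"normal"`, `"chi_square"` or `"t_dist"`.
#' @slot homoscedastic logical; equal residual variance across the nine
#'   two-locus genotype cells.
#' @slot nReplicates number of replicate datasets the setting comprises.
#' @slot seed master seed; per-replicate streams are derived from it.
#'
#' @seealso [simulationConfig()], [simulateReplicate()]
#' @export
setClass("SimulationConfig",
  representation(
    nIndividuals = "integer",
    nNoiseSnps = "integer",
    causalMaf = "numeric",
    noiseMafRange = "numeric",
    g2 = "numeric",
    scenario = "character",
    homoscedastic = "logical",
    nReplicates = "integer",
    seed = "integer"
  )
)

setValidity("SimulationConfig", function(object) {
  msg <- character()
  if (object@nIndividuals < 1L) msg <- c(msg, "nIndividuals must be >= 1")
  if (object@nNoiseSnps < 0L) msg <- c(msg, "nNoiseSnps must be >= 0")
  if (object@causalMaf <= 0 || object@causalMaf > 0.5)
    msg <- c(msg, "causalMaf must lie in (0, 0.5]")
  if (length(object@noiseMafRange) != 2L ||
      object@noiseMafRange[1] >= object@noiseMafRange[2] ||
      object@noiseMafRange[1] <= 0 || object@noiseMafRange[2] > 0.5)
    msg <- c(msg, "noiseMafRange must be an ordered pair within (0, 0.5]")
  if (object@g2 < 0 || object@g2 >= 1)
    msg <- c(msg, "g2 must lie in [0, 1)")
  if (!object@scenario %in% c("normal", "chi_square", "t_dist"))
    msg <- c(msg, "scenario must be normal, chi_square or t_dist")
  if (object@nReplicates < 1L) msg <- c(msg, "nReplicates must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Residual-distribution scenario for the nine two-locus genotype cells
#'
#' Holds, per multilocus genotype cell of the causal pair, the residual
#' distribution parameters of one simulation scenario, plus the calibrated
#' additive effect placed on the checkerboard high cells.
#'
#' @slot family `"normal"`, `"chi_square"` or `"t_dist"`.
#' @slot homoscedastic logical.
#' @slot cellVariance residual variance of each of the 9 cells (row-major in
#'   the first-locus genotype).
#' @slot cellDf per-cell degrees of freedom (chi-square and t families).
#' @slot cellNcp per-cell non-centrality (chi-square heteroscedastic case;
#'   zeros otherwise).
#' @slot maxNcp the preset ceiling on df + ncp (10), which pins every cell
#'   mean in the heteroscedastic chi-square case.
#' @slot effectSize additive mean shift applied to the high-indicator cells.
#'
#' @seealso [makeScenario()], [calibrateEffect()], [simulateTrait()]
#' @export
setClass("ScenarioSpec",
  representation(
    family = "character",
    homoscedastic = "logical",
    cellVariance = "numeric",
    cellDf = "numeric",
    cellNcp = "numeric",
    maxNcp = "numeric",
    effectSize = "numeric"
  )
)

setValidity("ScenarioSpec", function(object) {
  msg <- character()
  if (!object@family %in% c("normal", "chi_square", "t_dist"))
    msg <- c(msg, "family must be normal, chi_square or t_dist")
  if (length(object@cellVariance) != 9L || any(object@cellVariance < 0))
    msg <- c(msg, "cellVariance must be 9 nonnegative values")
  if (length(object@cellDf) != 9L || any(object@cellDf <= 0))
    msg <- c(msg, "cellDf must be 9 positive values")
  if (length(object@cellNcp) != 9L || any(object@cellNcp < 0))
    msg <- c(msg, "cellNcp must be 9 nonnegative values")
  if (object@family == "chi_square" && !object@homoscedastic &&
      any(abs(object@cellNcp - (object@maxNcp - object@cellDf)) > 1e-8))
    msg <- c(msg, "heteroscedastic chi-square requires ncp = maxNcp - df")
  if (object@effectSize < 0) msg <- c(msg, "effectSize must be >= 0")
  if (length(msg)) msg else TRUE
})

#' MB-MDR analysis configuration
#'
#' @slot testKind internal two-group association test: `"student"`
#'   (pooled-variance) or `"welch"`.
#' @slot alphaLabel two-sided significance level used to label a genotype
#'   cell H or L in the dimensionality-reduction step.
#' @slot minCell minimum number of individuals required on *each* side of
#'   every two-group comparison; smaller cells fall through to "O".
#' @slot nPermutations number of trait permutations B for the step-down
#'   maxT correction.
#' @slot alphaOverall familywise significance level applied to maxT-adjusted
#'   p-values.
#' @slot seed seed for the permutation stream.
#'
#' @seealso [analysisConfig()], [runMbmdr()]
#' @export
setClass("AnalysisConfig",
  representation(
    testKind = "character",
    alphaLabel = "numeric",
    minCell = "integer",
    nPermutations = "integer",
    alphaOverall = "numeric",
    seed = "integer"
  )
)

setValidity("AnalysisConfig", function(object) {
  msg <- character()
  if (!object@testKind %in% c("student", "welch"))
    msg <- c(msg, "testKind must be student or welch")
  if (object@alphaLabel <= 0 || object@alphaLabel >= 1)
    msg <- c(msg, "alphaLabel must lie in (0, 1)")
  if (object@minCell < 2L) msg <- c(msg, "minCell must be >= 2")
  if (object@nPermutations < 1L) msg <- c(msg, "nPermutations must be >= 1")
  if (object@alphaOverall <= 0 || object@alphaOverall >= 1)
    msg <- c(msg, "alphaOverall must lie in (0, 1)")
  if (length(msg)) msg else TRUE
})

#' H/L/O label grid for one SNP pair
#'
#' The dimensionality-reduction step's output for a single pair: each of the
#' nine two-locus genotype cells carries a label — "H" (trait-increasing),
#' "L" (trait-decreasing) or "O" (no evidence, including cells failing the
#' minimum-size rule) — together with the cell occupancies.
#'
#' @slot labels 3x3 character matrix over {"H","L","O"}; rows index the
#'   first locus genotype (0,1,2), columns the second.
#' @slot cellCounts 3x3 integer matrix of cell occupancies; sums to n.
#'
#' @seealso [labelCells()], [step2Statistic()]
#' @export
setClass("LabelGrid",
  representation(labels = "matrix", cellCounts = "matrix")
)

setValidity("LabelGrid", function(object) {
  msg <- character()
  if (!all(dim(object@labels) == c(3L, 3L)) ||
      !all(object@labels %in% c("H", "L", "O")))
    msg <- c(msg, "labels must be a 3x3 matrix over {H, L, O}")
  if (!all(dim(object@cellCounts) == c(3L, 3L)) ||
      any(object@cellCounts < 0))
    msg <- c(msg, "cellCounts must be a 3x3 nonnegative matrix")
  if (length(msg)) msg else TRUE
})

#' Result of an MB-MDR scan
#'
#' One row per unordered SNP pair (lexicographic order), carrying the step-2
#' max-F statistic and its step-down maxT-adjusted p-value.
#'
#' @slot pairs data.frame with columns `snpI`, `snpJ`, `step2F`,
#'   `adjustedP`, `significant`.
#' @slot config the [AnalysisConfig-class] used.
#' @slot nIndividuals cohort size analyzed.
#'
#' @seealso [runMbmdr()], [pairResults()], [significantPairs()]
#' @export
setClass("MbmdrResult",
  representation(
    pairs = "data.frame",
    config = "AnalysisConfig",
    nIndividuals = "integer"
  )
)

setValidity("MbmdrResult", function(object) {
  need <- c("snpI", "snpJ", "step2F", "adjustedP", "significant")
  if (!all(need %in% names(object@pairs)))
    return(paste("pairs must have columns", paste(need, collapse = ", ")))
  p <- object@pairs
  lo <- 1 / (object@config@nPermutations + 1)
  if (nrow(p) && (any(p$adjustedP < lo - 1e-12) || any(p$adjustedP > 1 + 1e-12)))
    return("adjustedP must lie in [1/(B+1), 1]")
  TRUE
})
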