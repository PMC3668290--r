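#' Create a simulation configuration
#'
#' Defaults are the study conditions of the robustness study: n = 500
#' individuals, 98 noise SNPs with MAF ~ U(0.05, 0.5), causal MAFs 0.5
#' (pure epistasis), 1000 replicates.
#'
#' @param nIndividuals cohort size per replicate.
#' @param nNoiseSnps number of non-causal SNPs.
#' @param causalMaf minor allele frequency of the causal pair.
#' @param noiseMafRange range of the uniform noise-MAF distribution.
#' @param g2 epistatic variance fraction in `[0, 1)`.
#' @param scenario `"normal"`, `"chi_square"` or `"t_dist"`.
#' @param homoscedastic equal per-cell residual variances?
#' @param nReplicates replicate datasets per setting.
#' @param seed master seed.
#' @return A [SimulationConfig-class] object.
#' @examples
#' simulationConfig(g2 = 0.05, scenario = "chi_square")
#' @export
simulationConfig <- function(nIndividuals = 500L, nNoiseSnps = 98L,
                             causalMaf = 0.5, noiseMafRange = c(0.05, 0.5),
                             g2 = 0, scenario = "normal",
                             homoscedastic = TRUE, nReplicates = 1000L,
                             seed = 1L) {
  new("SimulationConfig",
      nIndividuals = as.integer(nIndividuals),
      nNoiseSnps = as.integer(nNoiseSnps),
      causalMaf = causalMaf,
      noiseMafRange = as.numeric(noiseMafRange),
      g2 = g2,
      scenario = match.arg(scenario, c("normal", "chi_square", "t_dist")),
      homoscedastic = homoscedastic,
      nReplicates = as.integer(nReplicates),
      seed = as.integer(seed))
}

#' Create an MB-MDR analysis configuration
#'
#' Defaults follow the method's conventions: labeling at two-sided 0.1,
#' minimum 10 individuals on each side of any comparison, 999 permutations,
#' overall familywise level 0.05.
#'
#' @param testKind `"student"` (pooled-variance t) or `"welch"`.
#' @param alphaLabel two-sided cell-labeling level.
#' @param minCell minimum group size on each side of a comparison.
#' @param nPermutations permutation count B for maxT.
#' @param alphaOverall familywise significance level.
#' @param seed permutation-stream seed.
#' @return An [AnalysisConfig-class] object.
#' @examples
#' analysisConfig(testKind = "welch", nPermutations = 199)
#' @export
analysisConfig <- function(testKind = "student", alphaLabel = 0.1,
                           minCell = 10L, nPermutations = 999L,
                           alphaOverall = 0.05, seed = 1L) {
  new("AnalysisConfig",
      testKind = match.arg(testKind, c("student", "welch")),
      alphaLabel = alphaLabel,
      minCell = as.integer(minCell),
      nPermutations = as.integer(nPermutations),
      alphaOverall = alphaOverall,
      seed = as.integer(seed))
}

#' Access MB-MDR per-pair results
#'
#' @param x an [MbmdrResult-class].
#' @return `pairResults`: the full data.frame (one row per unordered SNP
#'   pair); `significantPairs`: the subset with maxT-adjusted p-value at or
#'   below the configured familywise level; `analysisConfigOf`: the
#'   [AnalysisConfig-class] the scan used.
#' @export
setGeneric("pairResults", function(x) standardGeneric("pairResults"))

#' @rdname pairResults
#' @export
setMethod("pairResults", "MbmdrResult", function(x) x@pairs)

#' @rdname pairResults
#' @export
setGeneric("significantPairs", function(x) standardGeneric("significantPairs"))

#' @rdname pairResults
#' @export
setMethod("significantPairs", "MbmdrResult", function(x) {
  x@pairs[x@pairs$significant, , drop = FALSE]
})

#' @rdname pairResults
#' @export
setGeneric("analysisConfigOf", function(x) standardGeneric("analysisConfigOf"))

#' @rdname pairResults
#' @export
setMethod("analysisConfigOf", "MbmdrResult", function(x) x@config)

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig:",
      object@nIndividuals, "individuals,",
      object@nNoiseSnps + 2L, "SNPs (2 causal @ MAF",
      paste0(object@causalMaf, ")"), "\n")
  cat("  scenario:", object@scenario,
      if (object@homoscedastic) "(equal variances)" else "(unequal variances)",
      " g2 =", object@g2, "\n")
  cat("  replicates:", object@nReplicates, " seed:", object@seed, "\n")
})

setMethod("show", "ScenarioSpec", function(object) {
  cat("ScenarioSpec:", object@family,
      if (object@homoscedastic) "homoscedastic" else "heteroscedastic", "\n")
  cat("  cell variances:", paste(signif(object@cellVariance, 3),
                                 collapse = " "), "\n")
  cat("  effect size (high cells):", signif(object@effectSize, 4), "\n")
})

setMethod("show", "AnalysisConfig", function(object) {
  cat("AnalysisConfig:", object@testKind, "t-test;",
      "labeling alpha =", object@alphaLabel, "\n")
  cat("  min cell =", object@minCell,
      " permutations =", object@nPermutations,
      " overall alpha =", object@alphaOverall, "\n")
})

setMethod("show", "LabelGrid", function(object) {
  cat("LabelGrid (rows: locus 1 genotype 0/1/2; cols: locus 2):\n")
  lab <- object@labels
  for (r in 1:3) {
    cat(" ", paste(sprintf("%s(%d)", lab[r, ], object@cellCounts[r, ]),
                   collapse = "  "), "\n")
  }
})

setMethod("show", "MbmdrResult", function(object) {
  p <- object@pairs
  cat("MbmdrResult:", nrow(p), "SNP pairs,",
      object@nIndividuals, "individuals;",
      object@config@testKind, "test,",
      object@config@nPermutations, "permutations\n")
  cat("  significant pairs (adjusted p <=",
      paste0(object@config@alphaOverall, "):"), sum(p$significant), "\n")
  if (nrow(p)) {
    top <- p[order(-p$step2F), , drop = FALSE][seq_len(min(5L, nrow(p))), ]
    rownames(top) <- NULL
    print(top)
  }
})
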