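#' Two-group association tests used inside MB-MDR
#'
#' `studentT()` is the classical pooled-variance two-sample t-test
#' (df = nA + nB - 2); `welchT()` the unequal-variance t-test with
#' Welch-Satterthwaite degrees of freedom. Both report the squared
#' statistic as `fValue` — the two-group ANOVA F — which is MB-MDR's
#' evidence scale. A degenerate comparison (zero variance) yields
#' `valid = FALSE` with `fValue = 0` and `pValue = 1` rather than an error,
#' so degenerate multilocus cells never abort a scan.
#'
#' @param a,b numeric value groups, each of length >= 2.
#' @return list of class `"qmbmdrTest"` with elements `statistic` (signed
#'   t, positive when `mean(a) > mean(b)`), `fValue` (t^2), `df`, `pValue`
#'   (two-sided) and `valid`.
#' @examples
#' studentT(c(1, 2, 3, 4), c(2, 4, 6, 8))
#' welchT(rnorm(10, sd = 2), rnorm(100))
#' @export
studentT <- function(a, b) {
  checkGroups(a, b)
  nA <- length(a); nB <- length(b)
  df <- nA + nB - 2
  sp2 <- ((nA - 1) * var(a) + (nB - 1) * var(b)) / df
  if (sp2 <= 0) return(invalidTest(df))
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / nA + 1 / nB))
  finishTest(t, df)
}

#' @rdname studentT
#' @export
welchT <- function(a, b) {
  checkGroups(a, b)
  nA <- length(a); nB <- length(b)
  va <- var(a) / nA; vb <- var(b) / nB
  se2 <- va + vb
  if (se2 <= 0) return(invalidTest(nA + nB - 2))
  df <- se2^2 / (va^2 / (nA - 1) + vb^2 / (nB - 1))
  t <- (mean(a) - mean(b)) / sqrt(se2)
  finishTest(t, df)
}

checkGroups <- function(a, b) {
  if (length(a) < 2 || length(b) < 2)
    stop("insufficient data: each group needs at least 2 observations")
  stopifnot(all(is.finite(a)), all(is.finite(b)))
}

invalidTest <- function(df) {
  structure(list(statistic = 0, fValue = 0, df = df, pValue = 1,
                 valid = FALSE),
            class = "qmbmdrTest")
}

finishTest <- function(t, df) {
  structure(list(statistic = t, fValue = t * t, df = df,
                 pValue = 2 * pt(-abs(t), df), valid = TRUE),
            class = "qmbmdrTest")
}

#' @export
print.qmbmdrTest <- function(x, ...) {
  cat(sprintf("two-group t: t = %.4f (F = %.4f), df = %.2f, p = %.4g%s\n",
              x$statistic, x$fValue, x$df, x$pValue,
              if (x$valid) "" else " [degenerate]"))
  invisible(x)
}
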