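#' Pre-analysis trait transformations
#'
#' The transformations applied to a trait before MB-MDR screening:
#' \describe{
#'   \item{raw}{identity.}
#'   \item{log}{natural logarithm; traits with non-positive values are first
#'     shifted by `-min(x) + 1` so the arm is defined for any input. The
#'     shift is monotone, so rank-based results downstream are unaffected.}
#'   \item{stz}{standardization by the overall mean and overall sample
#'     standard deviation (n - 1 denominator). Affine, so every two-group t
#'     statistic — and hence every MB-MDR result — is unchanged.}
#'   \item{rank}{pooled average-tie ranks 1..n.}
#'   \item{rtn}{rank transformation to normality: the normal quantile of the
#'     percentile rank, `qnorm((r - 0.5) / n)` by default.}
#' }
#'
#' @param x numeric trait vector.
#' @param tag transformation name.
#' @return transformed numeric vector of the same length.
#' @examples
#' y <- rchisq(20, 2)
#' traitTransform(y, "rtn")
#' @seealso [transformLog()], [transformStandardize()], [transformRank()],
#'   [transformRankToNormal()]
#' @export
traitTransform <- function(x, tag = c("raw", "log", "stz", "rank", "rtn")) {
  tag <- match.arg(tag)
  switch(tag,
    raw = x,
    log = transformLog(x),
    stz = transformStandardize(x),
    rank = transformRank(x),
    rtn = transformRankToNormal(x))
}

#' Logarithm transformation with shift for non-positive traits
#'
#' @param x numeric vector.
#' @return `log(x)` when all values are positive, otherwise
#'   `log(x - min(x) + 1)`.
#' @examples
#' transformLog(c(1, exp(1), exp(2)))
#' transformLog(c(-1, 0, 3))  # shifted: log(1), log(2), log(5)
#' @export
transformLog <- function(x) {
  stopifnot(length(x) >= 1, all(is.finite(x)))
  if (any(x <= 0)) x <- x - min(x) + 1
  log(x)
}

#' Standardization transformation
#'
#' Centers by the overall mean and scales by the overall sample standard
#' deviation.
#'
#' @param x numeric vector with positive sample variance.
#' @return vector with mean 0 and sample variance 1.
#' @examples
#' transformStandardize(c(1, 2, 3))
#' @export
transformStandardize <- function(x) {
  stopifnot(length(x) >= 2, all(is.finite(x)))
  s <- sd(x)
  if (s == 0) stop("cannot standardize a constant trait")
  (x - mean(x)) / s
}

#' Pooled rank transformation
#'
#' Ranks all trait measurements jointly in increasing order; ties receive
#' the average of their rank positions.
#'
#' @param x numeric vector.
#' @return rank vector (values in 1..n, averaged over ties).
#' @examples
#' transformRank(c(5, 5, 1))  # 2.5 2.5 1
#' @export
transformRank <- function(x) {
  stopifnot(length(x) >= 1, all(is.finite(x)))
  rank(x, ties.method = "average")
}

#' Rank transformation to normality
#'
#' Maps each observation to the standard normal quantile of its percentile
#' rank. The default plotting position `(r - 0.5) / n` is symmetric and
#' never reaches 0 or 1, so the output has no infinities; `"vdw"` selects
#' the van der Waerden position r/(n+1).
#'
#' @param x numeric vector.
#' @param position plotting-position convention.
#' @return numeric vector, approximately standard normal for untied input.
#' @examples
#' transformRankToNormal(c(3, 1, 2))
#' @export
transformRankToNormal <- function(x, position = c("midrank", "vdw")) {
  position <- match.arg(position)
  r <- transformRank(x)
  n <- length(x)
  p <- switch(position, midrank = (r - 0.5) / n, vdw = r / (n + 1))
  qnorm(p)
}
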