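# Deterministic derivation of sub-stream seeds from a master seed plus
# integer context (setting id, replicate index, stage salt). Keeps every
# intermediate below 2^53 so the arithmetic is exact in doubles; result is a
# valid 32-bit seed.
mixSeed <- function(...) {
  v <- as.numeric(c(...))
  h <- 2166136261
  for (x in v) {
    h <- (h * 69069 + x + 1) %% 2147483647
  }
  as.integer(h)
}

# Integer code of a simulation setting, used to decorrelate replicate
# streams across settings sharing a master seed.
settingId <- function(cfg) {
  scen <- match(cfg@scenario, c("normal", "chi_square", "t_dist"))
  mixSeed(scen, as.integer(cfg@homoscedastic), round(cfg@g2 * 1000))
}

#' Enumerate SNP pairs in scan order
#'
#' MB-MDR scans all unordered SNP pairs lexicographically: (1,2), (1,3),
#' ..., (m-1, m). Row k of the returned data.frame is pair k of every
#' per-pair result vector.
#'
#' @param m number of SNPs.
#' @return data.frame with integer columns `i` and `j` (i < j) and
#'   `m * (m - 1) / 2` rows.
#' @examples
#' pairIndices(4)
#' @export
pairIndices <- function(m) {
  m <- as.integer(m)
  stopifnot(m >= 2L)
  i <- rep.int(seq_len(m - 1L), times = (m - 1L):1L)
  j <- sequence((m - 1L):1L) + i
  data.frame(i = i, j = j)
}
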