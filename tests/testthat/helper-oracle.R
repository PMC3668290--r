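# Naive, loop-based re-implementation of the MB-MDR scan and the step-down
# maxT correction, sharing no code with the package internals. Labeling and
# pooled tests go through stats::t.test; step-down maxima are recomputed by
# direct maximization for every rank. Only usable at toy sizes.

naiveTestP <- function(a, b, kind) {
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    return(list(p = 1, t = 0, f = 0, valid = FALSE))
  }
  ht <- stats::t.test(a, b, var.equal = (kind == "student"))
  t <- unname(ht$statistic)
  list(p = ht$p.value, t = t, f = t^2, valid = TRUE)
}

naivePairStat <- function(g1, g2, y, kind, minCell, alphaLabel) {
  n <- length(y)
  lab <- rep("O", 9)
  for (c in 0:8) {
    idx <- which(3 * g1 + g2 == c)
    if (length(idx) < minCell || n - length(idx) < minCell) next
    res <- naiveTestP(y[idx], y[-idx], kind)
    if (res$valid && res$p <= alphaLabel) {
      if (res$t > 0) lab[c + 1] <- "H"
      if (res$t < 0) lab[c + 1] <- "L"
    }
  }
  stat <- 0
  for (which in c("H", "L")) {
    idx <- which((3 * g1 + g2 + 1) %in% which(lab == which))
    if (length(idx) >= minCell && n - length(idx) >= minCell) {
      res <- naiveTestP(y[idx], y[-idx], kind)
      if (res$valid) stat <- max(stat, res$f)
    }
  }
  stat
}

naiveScan <- function(G, y, kind, minCell, alphaLabel) {
  m <- ncol(G)
  stats <- numeric(0)
  for (i in seq_len(m - 1)) {
    for (j in (i + 1):m) {
      stats <- c(stats,
                 naivePairStat(G[, i], G[, j], y, kind, minCell, alphaLabel))
    }
  }
  stats
}

# Step-down maxT by direct maximization: for the hypothesis ranked r
# (decreasing observed order), the permutation reference is the max of the
# permuted statistics over all hypotheses ranked r or lower.
naiveStepDown <- function(observed, permStats) {
  P <- length(observed)
  B <- nrow(permStats)
  ord <- order(-observed)
  padj <- numeric(P)
  prev <- 0
  for (r in seq_len(P)) {
    tail <- ord[r:P]
    count <- 0
    for (b in seq_len(B)) {
      if (max(permStats[b, tail]) >= observed[ord[r]]) count <- count + 1
    }
    p <- (1 + count) / (B + 1)
    prev <- max(prev, p)
    padj[ord[r]] <- prev
  }
  padj
}

# Replicates the package's permutation stream so oracle and implementation
# correct the same statistics with the same shuffles.
samePermutations <- function(y, B, seed) {
  withr::with_seed(seed, {
    out <- matrix(0, length(y), B)
    for (b in seq_len(B)) out[, b] <- y[sample.int(length(y))]
    out
  })
}
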