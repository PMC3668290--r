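makeToyData <- function(n = 200, m = 4, seed = 1, maf = 0.5, beta = 0) {
  withr::with_seed(seed, {
    G <- simulateGenotypes(n, rep(maf, m))
    y <- rnorm(n) + beta * m170HighIndicator(G[, 1], G[, 2])
    list(G = G, y = y)
  })
}

test_that("pair partition covers every individual exactly once", {
  d <- makeToyData(n = 500)
  cells <- partitionPair(d$G, 1, 2)
  expect_equal(sum(cells$counts), 500)
  expect_equal(sort(unname(unlist(cells$members))), 1:500)
  # HWE at MAF 0.5: double-heterozygote cell near 500/4
  expect_equal(cells$counts[2, 2], 125, tolerance = 0.25)
  # degenerate: single occupied cell
  G0 <- matrix(0L, 30, 2)
  expect_equal(partitionPair(G0, 1, 2)$counts[1, 1], 30L)
  expect_error(partitionPair(d$G, 2, 2))
})

test_that("cell labeling obeys the minimum-size rule and test direction", {
  cfg <- analysisConfig()
  # a cell with 9 individuals stays O no matter how extreme the trait
  G <- matrix(0L, 100, 2)
  G[1:9, 1] <- 1L
  y <- c(rep(100, 9), rnorm(91))
  grid <- labelCells(partitionPair(G, 1, 2), y, cfg)
  expect_equal(grid@labels[2, 1], "O")
  # constant trait: all O
  gridC <- labelCells(partitionPair(makeToyData()$G, 1, 2),
                      rep(1, 200), cfg)
  expect_true(all(gridC@labels == "O"))
  # 50 individuals shifted +10 pooled sd: H; shifted down: L
  G2 <- matrix(0L, 500, 2)
  G2[1:50, 1] <- 2L
  set.seed(7)
  y2 <- rnorm(500); y2[1:50] <- y2[1:50] + 10
  grid2 <- labelCells(partitionPair(G2, 1, 2), y2, cfg)
  expect_equal(grid2@labels[3, 1], "H")
  grid3 <- labelCells(partitionPair(G2, 1, 2), -y2, cfg)
  expect_equal(grid3@labels[3, 1], "L")
})

test_that("step-2 statistic is the max of the two pooled branch tests", {
  cfg <- analysisConfig()
  d <- makeToyData(n = 500, seed = 3, beta = 1)
  cells <- partitionPair(d$G, 1, 2)
  grid <- labelCells(cells, d$y, cfg)
  stat <- step2Statistic(grid, cells, d$y, cfg)
  lab <- as.vector(t(grid@labels))
  branchF <- function(which) {
    idx <- unlist(cells$members[lab == which])
    if (length(idx) < 10 || 500 - length(idx) < 10) return(0)
    studentT(d$y[idx], d$y[-idx])$fValue
  }
  expect_equal(stat, max(branchF("H"), branchF("L")))
  expect_gt(stat, 0)
  # all-O grid scores zero
  gridO <- labelCells(cells, rep(0, 500), cfg)
  expect_equal(step2Statistic(gridO, cells, rep(0, 500), cfg), 0)
})

test_that("compiled scan equals the R reference path pair by pair", {
  for (test in c("student", "welch")) {
    cfg <- analysisConfig(testKind = test)
    d <- makeToyData(n = 150, m = 6, seed = 11, beta = 0.8)
    obs <- analyzeAllPairs(d$G, d$y, cfg)
    pi <- pairIndices(6)
    ref <- vapply(seq_len(nrow(pi)), function(k) {
      cells <- partitionPair(d$G, pi$i[k], pi$j[k])
      step2Statistic(labelCells(cells, d$y, cfg), cells, d$y, cfg)
    }, numeric(1))
    expect_equal(obs, ref, tolerance = 1e-12)
  }
})

test_that("scan is invariant to identically reordering individuals", {
  cfg <- analysisConfig()
  d <- makeToyData(n = 120, m = 5, seed = 5, beta = 1)
  obs <- analyzeAllPairs(d$G, d$y, cfg)
  set.seed(8)
  perm <- sample.int(120)
  expect_equal(analyzeAllPairs(d$G[perm, ], d$y[perm], cfg), obs)
  expect_length(analyzeAllPairs(d$G[, 1:2], d$y, cfg), 1L)
  expect_length(obs, 10L)
})

test_that("naive loop oracle reproduces statistics and adjusted p exactly", {
  for (test in c("student", "welch")) {
    cfg <- analysisConfig(testKind = test, nPermutations = 199L,
                          minCell = 10L, seed = 21L)
    d <- makeToyData(n = 60, m = 4, seed = 13, beta = 1.5)
    obs <- analyzeAllPairs(d$G, d$y, cfg)
    expect_equal(obs, naiveScan(d$G, d$y, test, 10L, 0.1),
                 tolerance = 1e-12)
    padj <- maxtAdjust(d$G, d$y, obs, cfg)
    Y <- samePermutations(d$y, 199L, 21L)
    permStats <- t(apply(Y, 2, function(yp)
      naiveScan(d$G, yp, test, 10L, 0.1)))
    expect_equal(padj, naiveStepDown(obs, permStats), tolerance = 1e-12)
    # top-ranked pair: step-down equals single-step maxT over full maxima
    top <- which.max(obs)
    singleStep <- (1 + sum(apply(permStats, 1, max) >= obs[top])) / 200
    expect_equal(padj[top], singleStep)
  }
})

test_that("adjusted p-values respect the permutation floor and monotonicity", {
  cfg <- analysisConfig(nPermutations = 99L, seed = 4L)
  d <- makeToyData(n = 300, m = 5, seed = 17, beta = 3)
  res <- runMbmdr(d$G, d$y, cfg)
  p <- pairResults(res)
  expect_true(all(p$adjustedP >= 1 / 100 & p$adjustedP <= 1))
  ord <- order(-p$step2F)
  expect_true(all(diff(p$adjustedP[ord]) >= 0))
  # dominant observed statistic attains the floor
  expect_equal(min(p$adjustedP), 1 / 100)
})

test_that("full scan is deterministic and affine/rank invariant", {
  cfg <- analysisConfig(nPermutations = 49L, seed = 6L)
  d <- makeToyData(n = 200, m = 5, seed = 19, beta = 1)
  r1 <- runMbmdr(d$G, d$y, cfg)
  r2 <- runMbmdr(d$G, d$y, cfg)
  expect_identical(pairResults(r1), pairResults(r2))
  # affine transform of the trait changes nothing
  r3 <- runMbmdr(d$G, 2.5 * d$y + 3, cfg)
  expect_equal(pairResults(r3), pairResults(r1))
  # rank pipeline ignores strictly increasing pre-transforms
  r4 <- runMbmdr(d$G, transformRank(d$y), cfg)
  r5 <- runMbmdr(d$G, transformRank(exp(d$y)), cfg)
  expect_equal(pairResults(r5), pairResults(r4))
  # constant trait: all statistics zero, nothing significant
  rc <- runMbmdr(d$G, rep(1, 200), cfg)
  expect_true(all(pairResults(rc)$step2F == 0))
  expect_equal(nrow(significantPairs(rc)), 0L)
})

test_that("a strong planted signal puts the causal pair on top", {
  hits <- 0L
  for (s in 1:10) {
    cfg <- simulationConfig(nIndividuals = 500L, nNoiseSnps = 8L,
                            g2 = 0.1, seed = s)
    d <- simulateReplicate(cfg, 1)
    obs <- analyzeAllPairs(d$genotypes, d$trait, analysisConfig())
    if (which.max(obs) == 1L) hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})

test_that("null statistics export pools the requested F values", {
  cfg <- analysisConfig(nPermutations = 20L, seed = 12L)
  d <- makeToyData(n = 400, m = 4, seed = 23)
  s2 <- exportNullStatistics(d$G, d$y, cfg, "step2")
  expect_length(s2, 20L * 6L)
  expect_true(all(s2 >= 0))
  c00 <- exportNullStatistics(d$G, d$y, cfg, "cell", cell = c(0L, 0L))
  expect_true(all(is.finite(c00)))
  expect_lte(length(c00), 20L * 6L)
  # the corner cell (2,2) is sparsest: some comparisons get dropped
  c22 <- exportNullStatistics(d$G, d$y, cfg, "cell", cell = c(2L, 2L))
  expect_true(length(c22) <= length(c00))
})
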