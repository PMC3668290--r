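test_that("noise MAF draws are uniform on the configured range", {
  expect_length(drawNoiseMafs(0), 0)
  set.seed(1)
  m <- drawNoiseMafs(98)
  expect_length(m, 98)
  expect_true(all(m > 0.05 & m < 0.5))
  big <- drawNoiseMafs(1e5)
  expect_equal(mean(big), 0.275, tolerance = 0.005)  # analytic mean of U(.05,.5)
})

test_that("genotypes follow Hardy-Weinberg and linkage equilibrium", {
  set.seed(2)
  n <- 1e5
  G <- simulateGenotypes(n, c(0.5, 0.1))
  freq1 <- tabulate(G[, 1] + 1L, 3) / n
  expect_equal(freq1, c(0.25, 0.5, 0.25), tolerance = 0.02)
  # chi-square goodness of fit against HWE expectations, both SNPs
  for (k in 1:2) {
    p <- c(0.5, 0.1)[k]
    expected <- c((1 - p)^2, 2 * p * (1 - p), p^2)
    gof <- chisq.test(tabulate(G[, k] + 1L, 3), p = expected)
    expect_gt(gof$p.value, 0.001)
  }
  expect_equal(mean(G[, 2] == 1L), 0.18, tolerance = 0.01)  # 2pq at p=0.1
  expect_lt(abs(cor(G[, 1], G[, 2])), 0.02)
  expect_error(simulateGenotypes(10, 0.7), "0, 0.5")
})

test_that("checkerboard high indicator requires exactly one heterozygous locus", {
  expect_true(m170HighIndicator(1, 0))
  expect_true(m170HighIndicator(1, 2))
  expect_true(m170HighIndicator(0, 1))
  expect_false(m170HighIndicator(1, 1))
  expect_false(m170HighIndicator(0, 2))
  expect_false(m170HighIndicator(0, 0))
  expect_error(m170HighIndicator(3, 0), "0, 1 or 2")
  expect_equal(highCellProbability(0.5), 0.5)  # enumeration over HWE cells
})

test_that("scenario construction matches the three residual families", {
  set.seed(3)
  # normal, heteroscedastic: 9 variances U(1,10); homoscedastic: their mean
  sp <- makeScenario("normal", homoscedastic = FALSE)
  expect_true(all(sp@cellVariance > 1 & sp@cellVariance < 10))
  sph <- makeScenario("normal", homoscedastic = TRUE)
  expect_length(unique(sph@cellVariance), 1L)
  expect_true(sph@cellVariance[1] > 1 && sph@cellVariance[1] < 10)
  # chi-square homoscedastic: central, df 2 => mean 2, variance 4
  sp2 <- makeScenario("chi_square", homoscedastic = TRUE)
  expect_equal(sp2@cellDf, rep(2, 9))
  expect_equal(sp2@cellVariance, rep(4, 9))
  # chi-square heteroscedastic: ncp = 10 - df, mean 10, variance in (20,36)
  sp2h <- makeScenario("chi_square", homoscedastic = FALSE)
  expect_equal(sp2h@cellNcp, 10 - sp2h@cellDf)
  expect_equal(sp2h@cellDf + sp2h@cellNcp, rep(10, 9))
  expect_true(all(sp2h@cellVariance > 20 & sp2h@cellVariance < 36))
  # t family: df 3; heteroscedastic target variances U(3,10)
  sp3 <- makeScenario("t_dist", homoscedastic = TRUE)
  expect_equal(sp3@cellVariance, rep(3, 9))
  sp3h <- makeScenario("t_dist", homoscedastic = FALSE)
  expect_true(all(sp3h@cellVariance > 3 & sp3h@cellVariance < 10))
  expect_equal(sp3h@cellDf, rep(3, 9))
  # alternative df parameterization of t heteroscedasticity
  sp3d <- makeScenario("t_dist", homoscedastic = FALSE, tHeteroMode = "df")
  expect_true(all(sp3d@cellDf > 3 & sp3d@cellDf < 10))
  expect_equal(sp3d@cellVariance, sp3d@cellDf / (sp3d@cellDf - 2))
})

test_that("effect calibration hits the target variance fraction", {
  expect_equal(calibrateEffect(0, 0.5, 5), 0)
  beta <- calibrateEffect(0.05, 0.5, 5.5)
  expect_equal(beta, sqrt(0.05 / 0.95 * 5.5 / 0.25), tolerance = 1e-12)
  expect_equal(beta, 1.0761, tolerance = 1e-4)
  expect_error(calibrateEffect(1, 0.5, 5), "g2")
  # simulation check: realized variance fraction matches the target
  set.seed(4)
  n <- 1e6
  high <- runif(n) < 0.5
  y <- beta * high + rnorm(n, sd = sqrt(5.5))
  realized <- var(beta * high) / var(y)
  expect_equal(realized, 0.05, tolerance = 0.003)
})

test_that("simulated traits have the scenario's cell structure", {
  set.seed(5)
  G <- simulateGenotypes(2e4, c(0.5, 0.5))
  cell <- 3 * G[, 1] + G[, 2]
  # null, homoscedastic normal: all cell means equal
  spn <- makeScenario("normal", homoscedastic = TRUE)
  y <- simulateTrait(G, spn)
  means <- tapply(y, cell, mean)
  expect_true(all(abs(means) < 4 * sqrt(spn@cellVariance[1] / min(table(cell)))))
  # heteroscedastic chi-square: constant mean 10 despite unequal variances
  sp2h <- makeScenario("chi_square", homoscedastic = FALSE)
  y2 <- simulateTrait(G, sp2h)
  expect_equal(as.numeric(tapply(y2, cell, mean)), rep(10, 9),
               tolerance = 0.04)
  cellVar <- as.numeric(tapply(y2, cell, var))
  expect_equal(cellVar,
               as.numeric(sp2h@cellVariance[sort(unique(cell)) + 1]),
               tolerance = 0.15)
})

test_that("large-sample replicate recovers beta and g2 by regression", {
  for (scen in c("normal", "chi_square", "t_dist")) {
    cfg <- simulationConfig(nIndividuals = 2e5, nNoiseSnps = 0L, g2 = 0.1,
                            scenario = scen, homoscedastic = TRUE,
                            seed = 6L)
    d <- simulateReplicate(cfg, 1)
    high <- m170HighIndicator(d$genotypes[, 1], d$genotypes[, 2])
    fit <- coef(lm(d$trait ~ high))
    expect_equal(unname(fit[2]), d$scenario@effectSize, tolerance = 0.05)
    genVar <- var(d$scenario@effectSize * high)
    expect_equal(genVar / var(d$trait), 0.1, tolerance = 0.05)
  }
})

test_that("replicate generation is reproducible and setting-decorrelated", {
  cfg <- simulationConfig(nNoiseSnps = 5L, g2 = 0.05, seed = 9L)
  a <- simulateReplicate(cfg, 3)
  b <- simulateReplicate(cfg, 3)
  expect_identical(a$genotypes, b$genotypes)
  expect_identical(a$trait, b$trait)
  c <- simulateReplicate(cfg, 4)
  expect_false(identical(a$trait, c$trait))
  cfg2 <- simulationConfig(nNoiseSnps = 5L, g2 = 0.05, seed = 9L,
                           scenario = "chi_square")
  d <- simulateReplicate(cfg2, 3)
  expect_false(identical(a$genotypes, d$genotypes))
})
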