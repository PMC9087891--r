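test_that("label initialization prefers the small-phi tower", {
  mp <- basicMappings()
  tab <- data.frame(phi_X = c(0.35, 0.65, 0.5), phi_Y = c(0.10, 0.90, 0.5),
                    theta_X = rep(0.01, 3), theta_Y = rep(0.02, 3))
  ev <- detectBdiEvents(basicBdiModel())[[1]]
  expect_identical(initLabels(tab, ev), c(0L, 1L, 1L))
  expect_identical(initLabels(tab, mp), c(0L, 1L, 1L))
  expect_error(initLabels(tab[, 1:2], ev), "lacks column")
})

test_that("tower distance is Euclidean, optionally variance-normalized", {
  x <- c(1, 0, 0, 0)
  expect_equal(towerDistance(x, x), 0)
  expect_equal(towerDistance(x, rep(0, 4)), 1)
  ## unit weights reduce the normalized distance to the Euclidean one
  y <- c(0.3, 0.8, 0.01, 0.02)
  expect_equal(towerDistance(x, y, weights = rep(1, 4)),
               towerDistance(x, y))
  expect_error(towerDistance(x, y[1:3]), "same length")
  expect_error(towerDistance(x, y, weights = c(1, 1, 0, 1)), "positive")
})

test_that("CoG relabeling collapses well-separated twin towers", {
  mp <- basicMappings()
  sim <- simulateLabelSwitchingSamples(separatedSpec(), mp, seed = 101)
  for (normalized in c(FALSE, TRUE)) {
    res <- cogRelabel(sim$samples, mp, normalized = normalized)
    expect_gte(relabelAccuracy(res@labels, sim$labels), 0.99)
    ## processed phi_X marginal is unimodal around one tower center
    expect_false(msciTowers:::.bimodalPhi(res@samples$phi_X))
    ## processed rows are exact mapping images of the input rows
    flipped <- which(res@labels == 1L)
    i <- flipped[1]
    expect_equal(unlist(res@samples[i, ]),
                 applyMapping(unlist(sim$samples[i, ]), mp[[2]]))
    same <- which(res@labels == 0L)[1]
    expect_identical(res@samples[same, ], sim$samples[same, ])
  }
  ## a table already in one tower is a fixed point
  one <- sim$samples[sim$labels == 0L & sim$samples$phi_X +
                       sim$samples$phi_Y < 1, ]
  res <- cogRelabel(one, mp)
  expect_true(all(res@labels == 0L))
  expect_identical(res@samples, one)
})

test_that("the CoG0 objective is nonincreasing on random tables", {
  mp <- basicMappings()
  set.seed(202)
  for (i in 1:100) {
    tab <- randomEventTable(n = sample(20:200, 1))
    res <- cogRelabel(tab, mp)
    expect_true(all(diff(res@objective) <= 1e-8))
  }
})

test_that("beta ML fitting recovers parameters via sufficient statistics", {
  set.seed(1)
  x <- rbeta(1e5, 2, 5)
  fit <- fitBetaML(x)
  expect_lt(max(abs(fit - c(2, 5)) / c(2, 5)), 0.05)
  ## symmetric sample about 0.5 gives p ~ q
  y <- c(x[1:5000], 1 - x[1:5000])
  fy <- fitBetaML(y)
  expect_lt(abs(fy[1] - fy[2]) / fy[1], 0.02)
  ## boundary values are clamped, fit stays finite
  fz <- fitBetaML(c(0, runif(100), 1))
  expect_true(all(is.finite(fz)))
  expect_error(fitBetaML(rep(0.4, 10)), "distinct")
})

test_that("gamma ML fitting matches theory and a direct 2-D oracle", {
  set.seed(2)
  x <- rgamma(1e5, shape = 3, rate = 200)
  fit <- fitGammaML(x)
  expect_lt(max(abs(fit - c(3, 200)) / c(3, 200)), 0.05)
  ## first-order condition: fitted mean equals the sample mean
  expect_equal(unname(fit["a"] / fit["b"]), mean(x), tolerance = 1e-8)
  ## two-point sample: finite, agrees with a grid+optim oracle
  f2 <- fitGammaML(c(1, 2))
  expect_true(all(is.finite(f2)))
  oracle <- optim(c(5, 3), function(p) {
    if (any(p <= 0)) return(1e10)
    -sum(dgamma(c(1, 2), shape = p[1], rate = p[2], log = TRUE))
  })
  expect_equal(unname(f2), oracle$par, tolerance = 1e-3)
  expect_error(fitGammaML(c(-1, 2)), "positive")
  expect_error(fitGammaML(rep(2, 5)), "distinct")
})

test_that("ML fits agree with an independent fitting library", {
  skip_if_not_installed("fitdistrplus")
  set.seed(3)
  x <- rbeta(20000, 3.2, 1.7)
  ref <- fitdistrplus::fitdist(x, "beta")$estimate
  expect_equal(unname(fitBetaML(x)), unname(ref), tolerance = 1e-3)
  y <- rgamma(20000, shape = 4, rate = 300)
  refg <- fitdistrplus::fitdist(y, "gamma")$estimate
  expect_equal(unname(fitGammaML(y)), unname(refg), tolerance = 1e-3)
})

test_that("the beta-gamma log likelihood matches a density-sum oracle", {
  mp <- basicMappings()
  set.seed(4)
  tab <- randomEventTable(100)
  z <- initLabels(tab, mp)
  fit <- fitTowerDensities(tab, z, mp)
  ll <- betaGammaLoglik(tab, z, fit, mp)

  ## oracle: transform rows, sum stats:: log densities
  M <- as.matrix(tab)
  oracle <- 0
  for (i in seq_len(nrow(M))) {
    r <- if (z[i] == 1L) applyMapping(M[i, ], mp[[2]]) else M[i, ]
    oracle <- oracle +
      dbeta(r["phi_X"], fit$phi_X$par[1], fit$phi_X$par[2], log = TRUE) +
      dbeta(r["phi_Y"], fit$phi_Y$par[1], fit$phi_Y$par[2], log = TRUE) +
      dgamma(r["theta_X"], fit$theta_X$par[1], rate = fit$theta_X$par[2],
             log = TRUE) +
      dgamma(r["theta_Y"], fit$theta_Y$par[1], rate = fit$theta_Y$par[2],
             log = TRUE)
  }
  expect_equal(ll, unname(oracle), tolerance = 1e-10)

  ## doubling the table doubles the log likelihood
  tab2 <- rbind(tab, tab)
  expect_equal(betaGammaLoglik(tab2, c(z, z), fit, mp), 2 * ll,
               tolerance = 1e-12)
})

test_that("beta-gamma relabeling is monotone and accurate", {
  mp <- basicMappings()
  ## nondecreasing log likelihood on random tables
  set.seed(5)
  for (i in 1:100) {
    tab <- randomEventTable(n = sample(20:150, 1))
    res <- betaGammaRelabel(tab, mp)
    expect_true(all(diff(res@objective) >= -1e-6))
  }

  ## symmetric twin towers: processed phi_X mean lands on a tower center,
  ## not on the symmetric-mixture value 1/2
  sim <- simulateLabelSwitchingSamples(separatedSpec(n = 20000L), mp,
                                       seed = 77)
  expect_equal(mean(sim$samples$phi_X), 0.5, tolerance = 0.05)
  res <- betaGammaRelabel(sim$samples, mp)
  expect_gte(relabelAccuracy(res@labels, sim$labels), 0.99)
  m1 <- mean(res@samples$phi_X)
  expect_true(abs(m1 - 0.7) < 0.02 || abs(m1 - 0.3) < 0.02)
  expect_false(msciTowers:::.bimodalPhi(res@samples$phi_X))

  ## four-tower double-BDI sample
  zz <- doubleMappings()
  sim4 <- simulateLabelSwitchingSamples(separatedDoubleSpec(), zz, seed = 78)
  res4 <- betaGammaRelabel(sim4$samples, zz)
  expect_gte(relabelAccuracy(res4@labels, sim4$labels), 0.99)
})

test_that("with normal densities the beta-gamma algorithm reduces to CoG", {
  mp <- basicMappings()
  sim <- simulateLabelSwitchingSamples(
    towerSpec(phi = list(phi_X = c(6, 4), phi_Y = c(3, 7)),
              theta = list(theta_X = c(8, 1600), theta_Y = c(8, 400)),
              stay = 0.99, n = 5000L), mp, seed = 9)
  cog0 <- cogRelabel(sim$samples, mp, normalized = FALSE)
  bgPooled <- betaGammaRelabel(sim$samples, mp, family = "normal-pooled")
  expect_identical(bgPooled@labels, cog0@labels)
  cogn <- cogRelabel(sim$samples, mp, normalized = TRUE)
  bgNorm <- betaGammaRelabel(sim$samples, mp, family = "normal")
  expect_gte(mean(bgNorm@labels == cogn@labels), 0.999)
})

test_that("all algorithms agree and are idempotent on the standard fixture", {
  mp <- basicMappings()
  sim <- simulateLabelSwitchingSamples(separatedSpec(), mp, seed = 13)
  res <- list(
    cog0 = cogRelabel(sim$samples, mp, normalized = FALSE),
    cogn = cogRelabel(sim$samples, mp, normalized = TRUE),
    bg = betaGammaRelabel(sim$samples, mp))
  for (a in 1:2) for (b in (a + 1):3)
    expect_gte(relabelAccuracy(res[[a]]@labels, res[[b]]@labels), 0.999)
  ## idempotence: rerunning on processed output moves nothing
  for (r in res) {
    again <- switch(r@algorithm,
      cog0 = cogRelabel(r@samples, mp),
      cogn = cogRelabel(r@samples, mp, normalized = TRUE),
      betagamma = betaGammaRelabel(r@samples, mp))
    expect_true(all(again@labels == 0L))
    expect_equal(again@samples, r@samples)
  }
})

test_that("relabelAll sweeps sister events in time order", {
  mp <- basicMappings()
  ## five-species, three sister events -> three passes
  m5 <- fiveSistersModel()
  cols <- unlist(lapply(detectBdiEvents(m5), function(e) e@params))
  set.seed(21)
  tab <- as.data.frame(matrix(runif(50 * length(cols)), 50,
                              dimnames = list(NULL, cols)))
  tab[grep("^theta_", cols)] <- abs(tab[grep("^theta_", cols)]) + 0.01
  sweep5 <- relabelAll(tab, m5, algorithm = "cog0")
  expect_length(sweep5@passes, 3L)
  expect_identical(names(sweep5@passes), c("X1-Y1", "X2-Y2", "X3-Y3"))

  ## mixed model: two passes, nonsister event reported
  mmix <- fiveMixedModel()
  sweepMix <- relabelAll(tab, mmix, algorithm = "cog0")
  expect_length(sweepMix@passes, 2L)
  expect_identical(sweepMix@nonsister, "X1-Y1")

  ## stacked double-BDI: one four-transform pass
  md <- doubleBdiModel()
  zz <- doubleMappings()
  sim <- simulateLabelSwitchingSamples(separatedDoubleSpec(n = 2000L), zz,
                                       seed = 31)
  sweepD <- relabelAll(sim$samples, md, algorithm = "betagamma")
  expect_length(sweepD@passes, 1L)
  expect_length(sweepD@passes[[1]]@mappings, 4L)
  expect_gte(relabelAccuracy(sweepD@passes[[1]]@labels, sim$labels), 0.99)

  ## model with no sister events: table unchanged
  m0 <- parseModel(noFlowModelText)
  sweep0 <- relabelAll(tab, m0, algorithm = "cog0")
  expect_identical(sweep0@table, tab)
  expect_length(sweep0@passes, 0L)
})

test_that("label accuracy is permutation-invariant with a 1/2 random floor", {
  z <- sample(0:1, 1000, replace = TRUE)
  expect_equal(relabelAccuracy(z, z), 1)
  expect_equal(relabelAccuracy(z, 1L - z), 1)
  expect_error(relabelAccuracy(z, z[-1]), "equal length")
  set.seed(55)
  a <- sample(0:1, 1e4, replace = TRUE)
  b <- sample(0:1, 1e4, replace = TRUE)
  expect_lt(abs(relabelAccuracy(a, b) - 0.5), 0.02)
})
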