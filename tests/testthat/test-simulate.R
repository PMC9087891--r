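test_that("the label-switching generator honours its spec", {
  mp <- basicMappings()

  ## stay probability 1: the chain never leaves its starting tower
  spec1 <- towerSpec(n = 500L, stay = 1)
  sim1 <- simulateLabelSwitchingSamples(spec1, mp, seed = 2)
  expect_length(unique(sim1$labels), 1L)

  ## equal-weight symmetric twin towers: unprocessed means near 1/2,
  ## within-tower means at the reference beta means 0.7 and 0.2
  spec <- towerSpec(n = 50000L, stay = 0.99)
  sim <- simulateLabelSwitchingSamples(spec, mp, seed = 5)
  expect_equal(mean(sim$samples$phi_X), 0.5, tolerance = 0.05)
  expect_equal(mean(sim$samples$phi_Y), 0.5, tolerance = 0.05)
  ref <- sim$labels == 0L
  expect_equal(mean(sim$samples$phi_X[ref]), 0.7, tolerance = 0.01)
  expect_equal(mean(sim$samples$phi_Y[ref]), 0.2, tolerance = 0.01)

  ## marginals within the reference tower follow the specified laws
  ks <- suppressWarnings(
    ks.test(sim$samples$phi_X[ref], pbeta, 7, 3))
  expect_gt(ks$p.value, 0.01)
  ksg <- suppressWarnings(
    ks.test(sim$samples$theta_X[ref], pgamma, 4, 800))
  expect_gt(ksg$p.value, 0.01)

  ## mirrored tower carries the mapped laws
  mir <- !ref
  ksm <- suppressWarnings(
    ks.test(1 - sim$samples$phi_X[mir], pbeta, 7, 3))
  expect_gt(ksm$p.value, 0.01)

  ## reproducible under the same seed
  sim2 <- simulateLabelSwitchingSamples(spec, mp, seed = 5)
  expect_identical(sim2, sim)
})

test_that("coalescent expectations hold for simple configurations", {
  ## single population, two sequences: mean coalescent time theta/2
  m1 <- parseModel(c("tree ((A,B)R;)", "tau R=50",
                     "theta A=0.01 B=0.01 R=0.01"))
  ## with tauR huge, the two lineages effectively share one population of
  ## theta 0.01 only after the root; instead sample two sequences from A
  tr <- simulateGeneTrees(m1, c(A = 2), nloci = 4000, seed = 17)
  ct <- coalescentTimes(tr)
  expect_equal(mean(ct), 0.01 / 2, tolerance = 0.05)

  ## basic BDI shape with phi = 0: no coalescence before the root, so the
  ## mean time is tauR + thetaR/2
  m0 <- parseModel(c(
    "tree ((A,B)R;)", "bdi X=A@0.00125 Y=B@0.00125", "tau R=0.01",
    "theta A=0.01 B=0.01 R=0.01 X=0.005 Y=0.02", "phi X=0 Y=0"))
  tr0 <- simulateGeneTrees(m0, c(A = 1, B = 1), nloci = 4000, seed = 18)
  ct0 <- coalescentTimes(tr0)
  expect_true(all(ct0 >= 0.01))
  expect_equal(mean(ct0), 0.01 + 0.01 / 2, tolerance = 0.05)

  ## gene trees are valid, reparseable Newick with n-1 internal nodes
  m <- basicBdiModel()
  trs <- simulateGeneTrees(m, c(A = 3, B = 2), nloci = 5, seed = 19)
  for (tr in trs) {
    expect_equal(tr$Nnode, 4L)
    back <- ape::read.tree(text = ape::write.tree(tr))
    expect_setequal(back$tip.label, c(paste0("A_", 1:3), paste0("B_", 1:2)))
    expect_true(ape::is.ultrametric(back, tol = 1e-8))
    ## path choices recorded at the hybridization nodes passed
    p <- attr(tr, "paths")
    expect_true(all(p$node %in% c("X", "Y")))
    expect_true(all(p$path %in% c("horizontal", "vertical")))
  }

  ## per-locus streams: extending nloci does not perturb earlier loci
  a <- simulateGeneTrees(m, c(A = 1, B = 1), nloci = 5, seed = 23)
  b <- simulateGeneTrees(m, c(A = 1, B = 1), nloci = 10, seed = 23)
  expect_equal(coalescentTimes(a), coalescentTimes(b)[1:5])
})

test_that("the analytic pairwise density is a proper mirror-invariant law", {
  m <- basicBdiModel()
  ev <- detectBdiEvents(m)[[1]]

  ## proper density: integrates to one
  expect_equal(stats::integrate(function(x) pairwiseCoalDensity(m, x),
                                0, Inf, rel.tol = 1e-10)$value, 1,
               tolerance = 1e-8)
  ## zero before the introgression time
  expect_true(all(pairwiseCoalDensity(m, seq(0, ev@tau * 0.999,
                                             length.out = 50)) == 0))

  ## mirror invariance on a fine grid
  mirror <- function(model) {
    nd <- modelNodes(model)
    i <- match(c("X", "Y"), nd$name)
    nd$phi[i] <- 1 - nd$phi[i]
    nd$theta[i] <- nd$theta[rev(i)]
    methods::new("MSciModel", nodes = nd)
  }
  grid <- seq(0, 0.06, length.out = 1000)
  d0 <- pairwiseCoalDensity(m, grid)
  d1 <- pairwiseCoalDensity(mirror(m), grid)
  expect_lt(max(abs(d1 - d0) / pmax(d0, 1e-12)), 1e-10)

  ## negative control: complementing phis without swapping thetas changes
  ## the law (theta_X != theta_Y here)
  noswap <- function(model) {
    nd <- modelNodes(model)
    i <- match(c("X", "Y"), nd$name)
    nd$phi[i] <- 1 - nd$phi[i]
    methods::new("MSciModel", nodes = nd)
  }
  d2 <- pairwiseCoalDensity(noswap(m), grid)
  expect_gt(max(abs(d2 - d0)), 1)

  expect_error(pairwiseCoalDensity(fiveSistersModel(), 0.01), "shape")
})

test_that("simulated coalescent times match the analytic density", {
  ## histogram of simulated times against the analytic law (chi-square on
  ## deciles), a cross-validation of simulator and oracle against each other
  m <- basicBdiModel()
  tr <- simulateGeneTrees(m, c(A = 1, B = 1), nloci = 20000, seed = 29)
  ct <- coalescentTimes(tr)
  qs <- quantile(ct, probs = seq(0.1, 0.9, 0.1))
  cdf <- function(t) vapply(t, function(ti)
    stats::integrate(function(x) pairwiseCoalDensity(m, x), 0, ti,
                     rel.tol = 1e-9)$value, 0)
  expected <- diff(c(0, cdf(qs), 1))
  observed <- diff(c(0, seq(0.1, 0.9, 0.1), 1))
  chi <- sum((observed - expected)^2 / expected) * length(ct)
  expect_lt(chi, qchisq(0.999, df = 9))
})
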