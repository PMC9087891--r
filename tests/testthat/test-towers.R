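test_that("the single-event mirror complements phis and swaps thetas", {
  mp <- basicMappings()[[2]]
  row <- c(phi_X = 0.35, phi_Y = 0.1, theta_X = 0.004, theta_Y = 0.02,
           tau_R = 0.01, tau_X = 0.00125, theta_A = 0.01, theta_B = 0.01,
           theta_R = 0.01)
  out <- applyMapping(row, mp)
  expect_equal(unname(out[c("phi_X", "phi_Y", "theta_X", "theta_Y")]),
               c(1 - 0.35, 1 - 0.1, 0.02, 0.004))
  ## only the four event parameters change
  others <- c("tau_R", "tau_X", "theta_A", "theta_B", "theta_R")
  expect_identical(out[others], row[others])
  ## involution: symbolically the self-composition is the exact identity
  ## (empty transform), numerically sequential application is 1-ulp exact
  expect_length(composeMappings(mp, mp)@target, 0L)
  expect_equal(applyMapping(out, mp), row, tolerance = 1e-15)
  ## theta entries move without arithmetic: bit-exact under two applications
  expect_identical(applyMapping(out, mp)[c("theta_X", "theta_Y")],
                   row[c("theta_X", "theta_Y")])
  ## fixed point at phi = 1/2, equal thetas
  fx <- c(phi_X = 0.5, phi_Y = 0.5, theta_X = 0.01, theta_Y = 0.01)
  expect_equal(applyMapping(fx, mp), fx)
  ## identity mapping leaves everything alone
  expect_identical(applyMapping(row, identityMapping()), row)
  expect_error(applyMapping(c(phi_X = 0.2), mp), "missing parameter")
})

test_that("double-BDI transforms match the four-tower table and form a
           Klein four-group", {
  zz <- doubleMappings()
  v <- c(phi_X = 0.1, phi_Y = 0.2, theta_X = 0.005, theta_Y = 0.02,
         phi_Z = 0.2, phi_W = 0.3, theta_Z = 0.004, theta_W = 0.03)
  ## z = 2 (tower 3): complement lower phis, swap lower thetas, swap upper
  ## phis and thetas
  out <- applyMapping(v, zz[[3]])
  expect_equal(unname(out),
               c(0.9, 0.8, 0.02, 0.005, 0.3, 0.2, 0.03, 0.004))
  ## z = 0 is the identity
  expect_identical(applyMapping(v, zz[[1]]), v)

  ## brute-force composition table on random vectors: closed, self-inverse
  set.seed(42)
  for (rep in 1:3) {
    w <- randomParamVector()
    comp <- matrix(NA_integer_, 4, 4)
    for (i in 1:4) for (j in 1:4) {
      im <- applyMapping(applyMapping(w, zz[[i]]), zz[[j]])
      hit <- which(vapply(zz, function(z)
        isTRUE(all.equal(applyMapping(w, z), im)), TRUE))
      expect_length(hit, 1L)
      comp[i, j] <- hit
    }
    expect_equal(diag(comp), rep(1L, 4))               # self-inverse
    expect_true(all(apply(comp, 1, sort) == 1:4))      # latin square
  }

  ## composeMappings agrees with sequential application
  z13 <- composeMappings(zz[[2]], zz[[3]])
  w <- randomParamVector()
  expect_equal(applyMapping(w, z13),
               applyMapping(applyMapping(w, zz[[2]]), zz[[3]]))

  ## events not stacked -> error
  ev5 <- detectBdiEvents(fiveSistersModel())
  expect_error(doubleBdiMappings(ev5[[2]], ev5[[1]]), "younger")
})

test_that("tower enumeration yields 2^n models x 2^m towers", {
  ts <- enumerateTowers(basicBdiModel())
  expect_equal(c(variantCount(ts), towersPerVariant(ts)), c(1L, 2L))

  ts <- enumerateTowers(fiveSistersModel())
  expect_equal(c(variantCount(ts), towersPerVariant(ts)), c(1L, 8L))

  ts <- enumerateTowers(fiveMixedModel())
  expect_equal(c(variantCount(ts), towersPerVariant(ts)), c(2L, 4L))

  ts <- enumerateTowers(threeNonsisterModel())
  expect_equal(c(variantCount(ts), towersPerVariant(ts)), c(4L, 1L))

  ## stacked double-BDI contributes the four-tower unit, not 2 x 2 mirrors
  ts <- enumerateTowers(doubleBdiModel())
  expect_equal(c(variantCount(ts), towersPerVariant(ts)), c(1L, 4L))
  v <- randomParamVector()
  zz <- doubleMappings()
  for (k in 1:4)
    expect_equal(applyMapping(v, towerMappings(ts)[[k]]),
                 applyMapping(v, zz[[k]]))

  ## plain species tree: one variant, one (identity) tower
  ts <- enumerateTowers(parseModel(noFlowModelText))
  expect_equal(c(variantCount(ts), towersPerVariant(ts)), c(1L, 1L))
})

test_that("enumerated tower count matches a brute-force event toggler", {
  ## independently toggle each sister event's mirror and count distinct
  ## images of a random parameter vector
  for (model in list(fiveSistersModel(), fiveMixedModel())) {
    events <- detectBdiEvents(model)
    sis <- Filter(function(e) e@sister, events)
    m <- length(sis)
    n <- length(events) - m
    set.seed(7)
    v <- modelParams(model)
    v[grep("^phi_", names(v))] <- runif(sum(grepl("^phi_", names(v))))
    images <- list()
    for (code in seq_len(2^m) - 1L) {
      w <- v
      for (b in seq_len(m))
        if (bitwAnd(bitwShiftR(code, b - 1L), 1L) == 1L)
          w <- applyMapping(w, singleBdiMapping(sis[[b]]))
      images[[code + 1L]] <- w
    }
    expect_equal(length(unique(lapply(images, unname))), 2L^m)
    ts <- enumerateTowers(model)
    expect_equal(towersPerVariant(ts), 2L^m)
    expect_equal(variantCount(ts), 2L^n)
    ## every enumerated within-model mapping reproduces one toggled image
    for (mp in towerMappings(ts)) {
      im <- applyMapping(v, mp)
      expect_true(any(vapply(images, function(x)
        isTRUE(all.equal(x, im)), TRUE)))
    }
  }
})

test_that("mappings preserve theta totals and never touch taus", {
  for (model in list(basicBdiModel(), doubleBdiModel(), fiveSistersModel())) {
    ts <- enumerateTowers(model)
    set.seed(11)
    v <- modelParams(model)
    v[grep("^phi_", names(v))] <- runif(sum(grepl("^phi_", names(v))))
    thetas <- grep("^theta_", names(v))
    taus <- grep("^tau_", names(v))
    for (mp in towerMappings(ts)) {
      w <- applyMapping(v, mp)
      expect_equal(sum(w[thetas]), sum(v[thetas]))
      expect_identical(w[taus], v[taus])
    }
  }
})
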