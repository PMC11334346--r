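# gamma and carbon weights of the tracked pools, for conservation audits
.gam <- c(CO = 2, CO2 = 0, H2 = 2, TCE = 9, cDCE = 10, VC = 11,
          ethene = 12, acetate = 8, CH4 = 8, HCl = 1)
.carb <- c(CO = 1, CO2 = 1, H2 = 0, TCE = 2, cDCE = 2, VC = 2,
           ethene = 2, acetate = 2, CH4 = 1, HCl = 0)

test_that("the same seed gives bit-identical results", {
  a <- simulateBottle(fastSimConfig(seed = 99))
  b <- simulateBottle(fastSimConfig(seed = 99))
  expect_identical(speciesAmounts(truth(a)), speciesAmounts(truth(b)))
  expect_identical(speciesAmounts(noisy(a)), speciesAmounts(noisy(b)))
  expect_identical(fluxes(a), fluxes(b))
  c <- simulateBottle(fastSimConfig(seed = 100))
  expect_false(identical(speciesAmounts(noisy(a)), speciesAmounts(noisy(c))))
})

test_that("the simulator does not disturb the caller's RNG stream", {
  set.seed(1234)
  before <- runif(3)
  set.seed(1234)
  invisible(simulateBottle(fastSimConfig()))
  after <- runif(3)
  expect_identical(before, after)
})

test_that("total carbon and gamma-electrons are conserved at every timestep", {
  cfg <- fastSimConfig(noise_sd = 0, k_me = 0.05)
  res <- simulateBottle(cfg)
  tr <- speciesAmounts(truth(res))
  tm <- timepoints(truth(res))
  doseU <- gasVolumeToUmol(c(2, 2), digits = NULL)
  dosedByT <- vapply(tm, function(t)
    sum(doseU[c(0, 3) <= t + 1e-9]), numeric(1))
  etot <- drop(tr %*% .gam[colnames(tr)])
  ctot <- drop(tr %*% .carb[colnames(tr)])
  expect_equal(etot, cfg@tce0 * 9 + dosedByT * 2, tolerance = 1e-10)
  expect_equal(ctot, cfg@tce0 * 2 + cfg@co2_0 + dosedByT, tolerance = 1e-10)
})

test_that("a noise-free default bottle dechlorinates completely and closes", {
  res <- simulateBottle(simConfig(noise_sd = 0))
  tr <- speciesAmounts(truth(res))
  fin <- tr[nrow(tr), ]
  expect_equal(fin[["ethene"]], 35.8, tolerance = 0.001)
  cl <- chloroetheneClosure(truth(res))
  expect_lt(cl$max_deviation, 1e-9)
  # electron recovery over true fluxes closes at 100 % with residuals and
  # CO2 counted (every simulated reaction conserves gamma-electrons)
  bal <- finalBalance(res)
  expect_equal(
    electronRecovery(bal, includeCO2 = TRUE, includeResiduals = TRUE,
                     digits = NULL),
    100, tolerance = 0.5 / 100)
  expect_equal(
    carbonRecovery(bal, includeCO2 = TRUE, includeResiduals = TRUE,
                   digits = NULL),
    100, tolerance = 0.5 / 100)
})

test_that("the recovery-table balance exposes the CO2 carbon shortfall", {
  res <- simulateBottle(simConfig(noise_sd = 0))
  bal <- makeTable2Like(res)
  crec <- carbonRecovery(bal, digits = NULL)
  expect_lt(crec, 100)
  # the shortfall is exactly the carbon parked in CO2 and residual pools
  expect_equal(carbonRecovery(bal, includeCO2 = TRUE,
                              includeResiduals = TRUE, digits = NULL),
               100, tolerance = 1e-6)
  expect_setequal(names(products(bal)), c("ethene", "acetic_acid"))
  expect_true(all(c("CO2", "HCl") %in% names(residualAmounts(bal))))
})

test_that("methanogenesis adds methane to the product side when switched on", {
  bal <- makeTable2Like(fastSimConfig(noise_sd = 0, k_me = 0.05))
  expect_true("methane" %in% names(products(bal)))
  expect_gt(products(bal)[["methane"]], 0)
})

test_that("a zero-rate bottle forms nothing and the report refuses it", {
  cfg <- fastSimConfig(noise_sd = 0, k_co = 0, k_ac = 0,
                       k_dechlor = c(TCE = 0, cDCE = 0, VC = 0))
  bal <- makeTable2Like(cfg)
  expect_length(products(bal), 0)
  expect_error(balanceReport(bal), "at least one")
})

test_that("dechlorination intermediates appear and peak sequentially", {
  res <- simulateBottle(simConfig(noise_sd = 0))
  tr <- speciesAmounts(truth(res))
  tm <- timepoints(truth(res))
  expect_lt(tm[which.max(tr[, "cDCE"])], tm[which.max(tr[, "VC"])])
  expect_true(all(diff(tr[, "ethene"]) > -1e-12))   # ethene only accumulates
  expect_true(all(diff(tr[, "TCE"]) < 1e-12))       # TCE only declines
})

test_that("H2 accumulates above 10x its dechlorination-phase baseline only after VC dominates", {
  res <- simulateBottle(simConfig(noise_sd = 0))
  tr <- speciesAmounts(truth(res))
  tm <- timepoints(truth(res))
  h2 <- tr[, "H2"]
  vcDominant <- tr[, "VC"] > tr[, "TCE"] + tr[, "cDCE"]
  tVC <- tm[which(vcDominant)[1]]
  baseline <- stats::median(h2[tm > 0.5 & tm < tVC])
  crossings <- tm[h2 > 10 * baseline]
  expect_gt(length(crossings), 0)          # accumulation does happen
  expect_true(all(crossings > tVC))        # ... but only in the VC stage
  # and the peak H2 is an order of magnitude above the early baseline
  expect_gt(max(h2) / baseline, 10)
})

test_that("measurement noise scales as configured", {
  cfg <- simConfig(noise_sd = 0.1, t_end = 30, seed = 4L)
  res <- simulateBottle(cfg)
  tt <- speciesAmounts(truth(res))
  nn <- speciesAmounts(noisy(res))
  sel <- tt > 1   # relative noise is ill-defined near zero (truncation)
  expect_gt(sum(sel), 1000)
  relErr <- ((nn - tt) / tt)[sel]
  expect_equal(stats::sd(relErr), 0.1, tolerance = 0.3)
  # truth itself is untouched by noise settings
  res0 <- simulateBottle(simConfig(noise_sd = 0, t_end = 30, seed = 4L))
  expect_identical(speciesAmounts(truth(res0)), tt)
})

test_that("invalid configurations are rejected up front", {
  expect_error(simConfig(dt = 0), "> 0")
  expect_error(simConfig(k_co = -1), ">= 0")
  expect_error(simConfig(k_dechlor = c(TCE = 1, cDCE = 1)), "VC")
})
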