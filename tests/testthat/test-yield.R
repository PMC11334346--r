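test_that("gas volumes convert to micromoles at 24.5 L/mol", {
  expect_equal(gasVolumeToUmol(35), 1428.6)
  expect_equal(gasVolumeToUmol(14), 571.4)
  expect_equal(gasVolumeToUmol(5), 204.1)
  expect_equal(gasVolumeToUmol(0), 0)
  expect_error(gasVolumeToUmol(-1), ">= 0")
  expect_error(gasVolumeToUmol(1, molar_volume = 0), "> 0")
})

test_that("the CO to H2 step is one-to-one", {
  expect_equal(maxH2FromCO(1428.6), 1428.6)
  expect_equal(maxH2FromCO(204.1), 204.1)
  expect_equal(maxH2FromCO(0), 0)
})

test_that("dechlorination H2 demand is one H2 per chlorine removed", {
  expect_equal(h2DemandDechlorination(33.3), 99.9)
  expect_equal(h2DemandDechlorination(0), 0)
  expect_equal(h2DemandDechlorination(10, steps = 1), 10)
  expect_equal(h2DemandDechlorination(10, steps = 2), 20)
  expect_error(h2DemandDechlorination(1, steps = 4), "steps")
})

test_that("residual H2 routes to acetate at 4 H2 per acetate", {
  expect_equal(roundHalfUp(acetateFromResidualH2(1428.6, 100.0), 1), 332.2)
  expect_equal(acetateFromResidualH2(400, 0), 100)
  expect_equal(acetateFromResidualH2(50, 50), 0)
  expect_error(acetateFromResidualH2(10, 11), "exceeds")
})

test_that("concentration conversion reproduces the printed 4.2 mM", {
  expect_equal(umolToMM(332.1, 80), 4.2)
  expect_equal(umolToMM(80, 80), 1.0)
  expect_equal(umolToMM(0, 80), 0.0)
  expect_error(umolToMM(10, 0), "> 0")
})

test_that("the full chain reproduces the published accounting", {
  # as-printed chain: the 100.0 µmol demand is fed forward explicitly
  yc <- yieldChain(co_ml = 35, tce_umol = 33.3, h2_demand_umol = 100.0)
  expect_equal(roundHalfUp(yc$co_umol, 1), 1428.6)
  expect_equal(roundHalfUp(yc$h2_max_umol, 1), 1428.6)
  expect_equal(roundHalfUp(yc$acetate_umol, 1), 332.1)
  expect_equal(roundHalfUp(yc$acetate_mM, 1), 4.2)
  # exact chain: demand computed from the TCE amount (3 per mol)
  yce <- yieldChain(co_ml = 35, tce_umol = 33.3)
  expect_equal(yce$h2_dechlor_umol, 99.9)
  expect_equal(roundHalfUp(yce$acetate_umol, 1), 332.2)
})

test_that("the chain conserves electrons exactly when run without losses", {
  # CO electrons in = electrons of the H2 spent on dechlorination +
  # electrons captured in acetate (gamma: CO 2, H2 2, acetate 8)
  set.seed(13)
  for (i in 1:20) {
    co_ml <- runif(1, 1, 50)
    tce <- runif(1, 0, gasVolumeToUmol(co_ml, digits = NULL) / 3)
    yc <- yieldChain(co_ml, tce)
    expect_equal(yc$co_umol * 2,
                 yc$h2_dechlor_umol * 2 + yc$acetate_umol * 8)
  }
})

test_that("predicted acetate is monotone in the CO dose", {
  doses <- seq(5, 50, by = 5)
  ac <- vapply(doses, function(v) yieldChain(v, tce_umol = 5)$acetate_umol,
               numeric(1))
  expect_true(all(diff(ac) > 0))
})
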