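test_that("published recovery percentages reproduce from the row inventories", {
  for (row in table2Rows()) {
    expect_equal(carbonRecovery(row$balance), row$carbon_pct)
    expect_equal(electronRecovery(row$balance), row$electron_pct)
  }
})

test_that("balance reports expose the underlying in/out totals", {
  rep1 <- balanceReport(table2Rows()$row1$balance)
  # 571.4*1 + 38.2*2 carbon in; 3.2 + 28.7*2 + 170.1*2 carbon out
  expect_equal(rep1$carbon_in, 647.8)
  expect_equal(rep1$carbon_out, 400.8)
  # gamma-weighted: 571.4*2 + 38.2*9 in; 3.2*8 + 28.7*12 + 170.1*8 out
  expect_equal(rep1$electrons_in, 1486.6)
  expect_equal(rep1$electrons_out, 1730.8)
  expect_equal(rep1$carbon_recovery_pct,
               roundHalfUp(100 * 400.8 / 647.8, 1))
})

test_that("degenerate bottles behave sensibly", {
  b <- bottleBalance("empty products", substrates = c(CO = 10),
                     products = numeric())
  expect_equal(carbonRecovery(b), 0)
  expect_error(balanceReport(b), "at least one substrate and one product")
  b2 <- bottleBalance("no carbon", substrates = c(H2 = 10),
                      products = c(methane = 1))
  expect_error(carbonRecovery(b2), "substrate carbon")
  expect_error(bottleBalance("x", c(CO = -1), c(methane = 1)))
  expect_error(bottleBalance("x", c(CO = 1), c(CO = 1)))  # disjoint maps
})

test_that("electron recovery of an identity bottle is 100 % for any amount", {
  set.seed(3)
  for (x in runif(10, 0.01, 2000)) {
    b <- bottleBalance("identity", substrates = c(H2 = x),
                       products = c(H2copy = x),
                       registry = {
                         reg <- compoundRegistry()
                         reg@compounds$H2copy <- compound("H2copy", "H2",
                                                          phase = "gas", dfG = 0)
                         reg
                       })
    expect_equal(electronRecovery(b), 100.0)
  }
})

test_that("recoveries are invariant under uniform rescaling of all amounts", {
  row <- table2Rows()$row1$balance
  set.seed(5)
  for (s in c(0.01, 0.5, 3, 100)) {
    scaled <- bottleBalance(row@treatment, substrates(row) * s,
                            products(row) * s)
    expect_equal(carbonRecovery(scaled, digits = NULL),
                 carbonRecovery(row, digits = NULL))
    expect_equal(electronRecovery(scaled, digits = NULL),
                 electronRecovery(row, digits = NULL))
  }
})

test_that("CO2 is excluded by default and counted on request", {
  b <- bottleBalance("with co2", substrates = c(CO = 100),
                     products = c(CO2 = 60, acetate = 10))
  # default: CO2 invisible on both sides
  expect_equal(carbonRecovery(b, digits = NULL), 100 * 20 / 100)
  # included: the mineralised carbon returns to the product side
  expect_equal(carbonRecovery(b, includeCO2 = TRUE, digits = NULL),
               100 * 80 / 100)
  # electron recovery is unaffected (gamma of CO2 is 0)
  expect_equal(electronRecovery(b, digits = NULL),
               electronRecovery(b, includeCO2 = TRUE, digits = NULL))
})

test_that("residuals enter the product side only when requested", {
  b <- bottleBalance("resid", substrates = c(CO = 100),
                     products = c(acetate = 20),
                     residuals = c(CO = 20))
  expect_equal(carbonRecovery(b, digits = NULL), 40)
  expect_equal(carbonRecovery(b, includeResiduals = TRUE, digits = NULL), 60)
})
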