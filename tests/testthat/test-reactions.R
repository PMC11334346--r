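test_that("reaction strings parse into signed stoichiometric maps", {
  wgs <- parseReaction("wgs: CO(g) + H2O(l) -> CO2(g) + H2(g)")
  expect_length(stoich(wgs), 4)
  expect_equal(unname(abs(stoich(wgs))), rep(1, 4))
  expect_equal(stoich(wgs)[["CO"]], -1)
  expect_equal(stoich(wgs)[["H2"]], 1)

  de <- parseReaction("dechlor: C2HCl3 + 3 H2(g) -> C2H4(g) + 3 HCl")
  expect_equal(stoich(de)[c("TCE", "H2", "ethene", "HCl")],
               c(TCE = -1, H2 = -3, ethene = 1, HCl = 3))
})

test_that("malformed reaction strings are rejected", {
  expect_error(parseReaction("x: -> H2(g)"), "no reactant")
  expect_error(parseReaction("x: CO(g) + H2O(l) = CO2(g)"), "arrow")
  expect_error(parseReaction("x: CO(g) -> unobtainium(g)"), "unknown")
})

test_that("balance audits pass for every ledger reaction and catch imbalance", {
  rx <- referenceReactions()
  for (nm in names(rx)) {
    aud <- auditBalance(rx[[nm]])
    expect_true(aud$balanced, info = nm)
    expect_equal(max(abs(aud$elements)), 0, info = nm)
    expect_equal(aud$electrons, 0, info = nm)
  }
  # hand check of the dechlorination electron sum: 9 + 3*2 in, 12 + 3*1 out
  expect_equal(9 + 3 * 2, 12 + 3 * 1)

  bad <- parseReaction("bad: CO(g) -> CO2(g)")
  aud <- auditBalance(bad)
  expect_false(aud$balanced)
  expect_equal(aud$elements[["O"]], 1)
})

test_that("Gibbs energies recompute from the shipped CRC constants", {
  rx <- referenceReactions()
  expect_equal(deltaGStandard(rx$wgs), -20.1, tolerance = 0.2 / 20.1)
  expect_equal(deltaGStandard(rx$methanogenesis_h2), -130.3,
               tolerance = 0.5 / 130.3)
  # the whole recomputable ledger agrees with its stored constants
  for (nm in c("wgs", "acetogenesis_h2", "acetogenesis_co",
               "methanogenesis_ac", "methanogenesis_h2",
               "methanogenesis_co")) {
    expect_equal(round(deltaGStandard(rx[[nm]]), 1), deltaG(rx[[nm]]),
                 info = nm)
  }
  # TCE carries no formation energy: recomputation must refuse, not guess
  expect_error(deltaGStandard(rx$dechlorination), "TCE")
})

test_that("Hess combination reproduces the composite ledger rows", {
  rx <- referenceReactions()
  eq4 <- combineReactions(list(list(4, rx$wgs), list(1, rx$acetogenesis_h2)))
  expect_equal(sort(names(stoich(eq4))), sort(names(stoich(rx$acetogenesis_co))))
  expect_equal(stoich(eq4)[names(stoich(rx$acetogenesis_co))],
               stoich(rx$acetogenesis_co))
  expect_equal(deltaG(eq4), -155.7, tolerance = 0.05 / 155.7)

  eq5 <- combineReactions(list(list(1, rx$methanogenesis_h2),
                               list(-1, rx$acetogenesis_h2)))
  expect_equal(stoich(eq5)[names(stoich(rx$methanogenesis_ac))],
               stoich(rx$methanogenesis_ac))
  expect_equal(deltaG(eq5), -55.0, tolerance = 0.05 / 55)

  eq7 <- combineReactions(list(list(4, rx$wgs), list(1, rx$methanogenesis_h2)))
  expect_equal(stoich(eq7)[names(stoich(rx$methanogenesis_co))],
               stoich(rx$methanogenesis_co))
  expect_equal(deltaG(eq7), -210.7, tolerance = 0.05 / 210.7)
})

test_that("reaction combination is linear and refuses the null reaction", {
  rx <- referenceReactions()
  set.seed(11)
  for (i in 1:10) {
    a <- sample(c(-3, -2, -1, 1, 2, 3), 1)
    b <- sample(c(-2, -1, 1, 2), 1)
    step1 <- combineReactions(list(list(a, rx$wgs)))
    nested <- combineReactions(list(list(b, step1)))
    direct <- combineReactions(list(list(a * b, rx$wgs)))
    expect_equal(stoich(nested)[names(stoich(direct))], stoich(direct))
    expect_equal(deltaG(nested), deltaG(direct))
  }
  expect_error(
    combineReactions(list(list(1, rx$wgs), list(-1, rx$wgs))),
    "null reaction")
})

test_that("combining reactions without energies yields NA energy", {
  reg <- compoundRegistry()
  r <- parseReaction("r: CO(g) + H2O(l) -> CO2(g) + H2(g)", reg)  # dG not set
  comb <- combineReactions(list(list(2, r)))
  expect_true(is.na(deltaG(comb)))
})
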