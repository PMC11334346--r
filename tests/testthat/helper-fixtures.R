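# Hand-tabulated degrees of reduction (C=4, H=1, O=-2, Cl=0) for every
# species of the reaction ledger.
gammaFixture <- c(
  CO = 2, CO2 = 0, H2 = 2, H2O = 0, CH4 = 8, C2H4 = 12, C2H4O2 = 8,
  C2HCl3 = 9, C2H2Cl2 = 10, C2H3Cl = 11, HCl = 1
)

# Published per-bottle inventories (µmol/bottle) for the two CO-dose
# treatments, with their printed recovery percentages.
table2Rows <- function(registry = compoundRegistry()) {
  list(
    row1 = list(
      balance = bottleBalance(
        "2 mL/dose CO",
        substrates = c(CO = 571.4, TCE = 38.2),
        products = c(methane = 3.2, ethene = 28.7, acetate = 170.1),
        registry = registry),
      carbon_pct = 61.9, electron_pct = 116.4),
    row2 = list(
      balance = bottleBalance(
        "5 mL/dose CO",
        substrates = c(CO = 1428.6, TCE = 35.8),
        products = c(methane = 11.0, ethene = 25.5, acetate = 349.6),
        registry = registry),
      carbon_pct = 50.7, electron_pct = 100.4)
  )
}

# Random plausible formulas over the C/H/O/Cl/N alphabet for property tests.
randomFormula <- function() {
  els <- sample(c("C", "H", "O", "Cl", "N"), sample(1:4, 1))
  setNames(sample(1:9, length(els), replace = TRUE), els)
}

# A small, fast simulator configuration used where the full default run is
# not needed.
fastSimConfig <- function(...) {
  simConfig(doses = doseSchedule(c(0, 3), 2), tce0 = 10, t_end = 10,
            dt = 0.01, ...)
}
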