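Package: COdechlor
Title: Stoichiometric and Thermodynamic Accounting for CO-Fueled Reductive Dechlorination
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the bioenergetic bookkeeping of anaerobic microcosms in
    which carbon monoxide fuels syntrophic trichloroethene (TCE)
    dechlorination to ethene. Provides a molecular-formula and
    degree-of-reduction (effective electron number) calculus, a reaction
    ledger with elemental and electron balancing audits, standard Gibbs
    energies of reaction from formation energies and their Hess-law
    combination, per-bottle carbon- and electron-recovery statistics, the
    CO to hydrogen to dechlorination to acetate theoretical yield chain,
    time-course bookkeeping (chloroethene molar closure, cumulative gas
    dosing, growth fold change), and a seeded kinetic simulator of CO-fed
    bottle experiments for testing the accounting without laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils
Suggests: testthat (>= 3.0.0), knitr, rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
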