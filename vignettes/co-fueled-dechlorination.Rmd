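---
title: "Accounting for CO-fueled syntrophic dechlorination: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Accounting for CO-fueled syntrophic dechlorination: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(COdechlor)
```

# The system and the questions the package answers

Carbon monoxide is both a potent inhibitor of many anaerobes and, for
hydrogenogenic carboxydotrophs, a growth substrate: the biological
water-gas shift CO + H₂O → CO₂ + H₂ turns each CO into one H₂.  In
TCE-contaminated anaerobic communities that H₂ can drive organohalide
respiration by *Dehalococcoides* — the sequential hydrogenolysis
TCE → cDCE → VC → ethene, one H₂ (two electrons) per chlorine removed —
while acetogens convert surplus H₂ and CO₂ to acetate via the
Wood–Ljungdahl pathway.  The claim that CO alone can fuel such a
community rests on bookkeeping: do the electrons and carbon of the dosed
CO account for the dechlorination, methane and acetate observed, and is
every step exergonic?  This package implements that bookkeeping as
reusable, tested functions.

# Degree-of-reduction calculus

The electron balance uses the classical degree-of-reduction convention:
each element carries a fixed number of available electrons per atom —
C = +4, H = +1, O = −2 — and a species' degree of reduction γ is the sum
over its atoms.  Chlorine is assigned 0.  That value is not arbitrary: in
a recovery statistic over CO/TCE inventories, the per-atom chlorine
number is identifiable from the published percentages, and 0 is the
unique simple value that reproduces both treatment rows to the printed
decimal (the test suite carries this derivation).  Physically it reflects
that hydrogenolysis replaces C–Cl by C–H while the chlorine leaves as
chloride at the same oxidation state, so a chlorine substituent neither
donates nor accepts balance electrons.  With this scheme γ(TCE) = 9,
γ(cDCE) = 10, γ(VC) = 11, γ(ethene) = 12: each step adds exactly the two
electrons of one H₂ (γ = 2), minus the one electron parked in HCl
(γ = 1), which is why the reaction ledger's electron audits close.

Nitrogen also defaults to 0; that is an extension beyond the C/H/O/Cl
set the balances actually need, and `electronScheme()` lets callers
override any element.

# Recovery statistics

`carbonRecovery()` and `electronRecovery()` compute
100·Σ(products µmol·w)/Σ(substrates µmol·w) with w the carbon count or γ.
Two conventions matter:

* **CO₂ is excluded by default** from the carbon balance (it is the
  mineralised end product, not a recovered one); `includeCO2 = TRUE`
  restores it, which is how the simulator's conservation checks close at
  100 %.  Electron recovery is indifferent to CO₂ since γ(CO₂) = 0.
* **Residual (unconsumed) amounts are excluded by default** and can be
  added to the product side with `includeResiduals = TRUE`.

Percentages are rounded half away from zero to one decimal at
presentation (`roundHalfUp()`); base R's round-half-even would disagree
with published tables at .5 cases.  Full-precision values are always
available via `digits = NULL` or the totals in `balanceReport()`.

# The thermodynamic ledger

`referenceReactions()` ships the seven-reaction redox ledger of the
system.  ΔrG′° is computed as Σ ν·ΔfG′° at 298.15 K with gases at 1 atm
and solutes at 1 M; no pH-dependent Legendre transform is applied because
the ledger writes its species as neutral molecules (CH₃COOH, HCl), so the
plain formation-energy sum is the stated convention.  The shipped
constants are CRC Handbook (84th ed.) values carried at one decimal:
CO −137.2, CO₂ −394.4, H₂O(l) −237.1, CH₄ −50.5, C₂H₄ +68.4, CH₃COOH
−389.9 kJ/mol, H₂ 0.  A deliberate documentation point: **acetic acid is
treated as a liquid** (−389.9 kJ/mol); with that choice all six
CO/H₂/acetate/methane reactions recompute to the ledger decimals exactly,
and the three composite rows are exact Hess combinations of the three
elementary ones.  The TCE-dechlorination energy (−150.5 kJ/mol) is a
ledger constant only: no consistent ΔfG′° for the chloroethenes
reproduces it, so `deltaGStandard()` refuses to recompute it rather than
guess, and the chloroethenes ship without formation energies.

Coefficients are stored as doubles, with combinations cancelling species
below 10⁻⁹; for the small integer and quarter-integer coefficients of
this chemistry that is exact in IEEE arithmetic, and the Hess closures
hold to < 10⁻¹² kJ/mol.  An exact-rational representation was considered
and rejected as machinery without a payoff at these coefficient sizes.

# The yield chain

`yieldChain()` composes the stepwise theoretical maxima: CO volume to
µmol at a molar volume of 24.5 L/mol (ideal gas at ~25 °C and 1 atm,
rounded to the convention under which 14 mL = 571.4 µmol and
35 mL = 1428.6 µmol); H₂ 1:1 from CO; 3 H₂ per TCE for full
dechlorination; residual H₂ to acetate at 4:1; µmol to mM over the
medium volume.  All intermediates are carried at full precision and
rounded only for display — feeding rounded intermediates forward would
create half-way rounding ambiguities one decimal in.  Because a demand of
100.0 µmol (for 33.3 µmol TCE, itself plausibly a rounded 100/3) is the
kind of printed intermediate users may want to reproduce exactly,
`h2_demand_umol` lets the caller override the computed 99.9; both chains
are first-class.  The chain conserves electrons identically:
2·CO = 2·H₂(dechlorination) + 8·acetate.

# The synthetic bottle generator

`simulateBottle()` exists so the accounting layer can be exercised on
data with known truth.  It integrates, with a fixed explicit step, the
interaction network of a CO-fed dechlorinating bottle:

* CO oxidation (water-gas shift): rate `k_co`·[CO], first order — CO
  dosed as impulses at the schedule times.
* Acetogenesis: H₂ consumed at `k_ac`·[H₂] with 4 H₂ + 2 CO₂ per acetate.
* Dechlorination step *i*: rate `k_i`·[Sᵢ]·H₂/(K_H + H₂), gated to zero
  below a per-step H₂ threshold.
* Acetoclastic methanogenesis (optional): `k_me`·[acetate].

Each reaction is applied as a whole extent with exact stoichiometry;
per-pool flux limiting scales a reaction down when it would overdraw any
pool it consumes within the step.  Total carbon and total γ-electrons
over the tracked pools (including CO₂ and the HCl by-product) are
therefore conserved to round-off at every step, for any step size — the
package's conservation tests exploit this.  Noise is applied only at the
measurement layer, as relative Gaussian noise truncated at zero, under a
private RNG stream derived from the config seed (bit-identical reruns,
caller's RNG untouched).

## Default study conditions and parameter choices

The default `simConfig()` emulates the 5 mL/dose condition: 35.8 µmol
TCE in an 80 mL bicarbonate-buffered bottle, seven 5-mL CO doses
(1428.6 µmol) at days 0–60, simulated to day 120 with dt = 0.01 d.
The network topology and the per-step H₂ thresholds are empirically
grounded (thresholds 0.06, 0.1 and 1.0 nmol/bottle, i.e. mid-range of
reported 0.6–0.9 nM, 0.1–2.5 nM and 2–24 nM dissolved H₂ at 80 mL); the
rate *forms* are the simplest ones producing sequential intermediates
and stage-resolved H₂, and the rate *constants* are invented defaults
fixed by steady-state reasoning:

* `k_co = 0.05`/d: CO carries over between doses, so the H₂ supply rises
  over the run (~6 µmol H₂/d early, ~20 µmol/d late).
* `k_TCE = k_cDCE = 3`/d, `K_H = 100` nmol/bottle: during the TCE/cDCE
  phase dechlorination is the dominant H₂ sink and holds H₂ near
  90 nmol/bottle.
* `k_VC = 0.12`/d: the VC step is slow; once VC dominates, H₂ climbs
  more than ten-fold (peak ≈ 1.2 µmol/bottle) before acetogenesis
  (`k_ac = 20`/d) caps it — reproducing the qualitative observation that
  H₂ accumulates only during the VC-to-ethene transition.
* `k_me = 0`: the enrichment makes only traces of methane; switch it on
  to see the acetate → CH₄ + CO₂ route.

With linear (first-order in H₂) acetogenesis as specified, a steady-state
argument shows no constant-supply parameterisation can combine
multi-week TCE/cDCE phases with a >10× H₂ stage contrast — the early H₂
ceiling is always ≈ supply/`k_ac` once dechlorination is a minor sink.
The defaults therefore realise the stage contrast in a compressed
timeline (TCE/cDCE resolved within days, VC over ~10 weeks).  What
passing tests show, accordingly, is that the *accounting* is right on
data with the assumed structure: conservation, closure, recovery, noise
scaling, stage ordering.  They do not show that the kinetics match real
bottles — real data add gas/liquid partitioning, growing (and dying)
populations, CO toxicity to the dechlorinators, multi-bottle variance,
and sampling far sparser than the integrator grid.  No kinetic parameter
fitting is claimed or attempted.

## Numerical conventions and degenerate inputs

* Explicit fixed-step integration (dt = 0.01 d default) was chosen over
  an adaptive stiff solver because exact per-step conservation auditing
  and bit-reproducibility outweigh stiffness concerns at these rates
  (`k`·dt ≤ 0.2 for every default rate).
* Flux limiting floors every pool at zero; a reaction is scaled, never
  its stoichiometry broken.
* A zero-rate configuration yields an empty product side, which
  `balanceReport()` rejects rather than reporting 0/0.
* Dose times coinciding with a step boundary are applied once, in the
  step ending at that time; doses at t ≤ 0 are in the initial state.

# Problem sizes

The shipped tests and the reproduction script run entirely on desk-scale
inputs: inventories of ≤ 5 species, a 7-reaction ledger, and simulations
of a single bottle over 120 days at 12 001 steps (under a second each).
Property-style tests use 10–50 randomised cases under fixed seeds.

# Known limitations

* Gas/liquid partitioning of CO and H₂ is ignored (single well-mixed
  pool per species); thresholds given in nmol/bottle are compared to the
  total pool.
* No temperature dependence, ionic strength, activity or
  reaction-quotient corrections in the ledger; standard-state values
  only.
* The chlorine balance is not closed (HCl is tracked in the simulator
  but chloride speciation is not modelled).
* Cell counts are carried as data (`foldChange()`), not simulated.
* Statistical uncertainty of measured inventories is not propagated.
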