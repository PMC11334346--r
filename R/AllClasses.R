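#' @import methods
NULL

# Recognised element symbols (IUPAC periodic table, Z = 1..103). Used to
# reject typos such as "Xx" in formulas rather than silently storing them.
.PERIODIC_SYMBOLS <- c(
  "H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne", "Na", "Mg", "Al",
  "Si", "P", "S", "Cl", "Ar", "K", "Ca", "Sc", "Ti", "V", "Cr", "Mn", "Fe",
  "Co", "Ni", "Cu", "Zn", "Ga", "Ge", "As", "Se", "Br", "Kr", "Rb", "Sr",
  "Y", "Zr", "Nb", "Mo", "Tc", "Ru", "Rh", "Pd", "Ag", "Cd", "In", "Sn",
  "Sb", "Te", "I", "Xe", "Cs", "Ba", "La", "Ce", "Pr", "Nd", "Pm", "Sm",
  "Eu", "Gd", "Tb", "Dy", "Ho", "Er", "Tm", "Yb", "Lu", "Hf", "Ta", "W",
  "Re", "Os", "Ir", "Pt", "Au", "Hg", "Tl", "Pb", "Bi", "Po", "At", "Rn",
  "Fr", "Ra", "Ac", "Th", "Pa", "U", "Np", "Pu", "Am", "Cm", "Bk", "Cf",
  "Es", "Fm", "Md", "No", "Lr"
)

.PHASES <- c("gas", "liquid", "aqueous")

#' Compound: a named chemical species
#'
#' A chemical species with its atomic composition, phase, optional standard
#' Gibbs energy of formation, and formal charge.  Compounds are the carriers
#' of the degree-of-reduction (effective electron number) calculus and of the
#' formation energies used to compute reaction Gibbs energies.
#'
#' @slot name character(1), the species name used in reactions and balances.
#' @slot formula named numeric vector of non-negative integer atom counts,
#'   names are element symbols (e.g. `c(C = 2, H = 1, Cl = 3)`).
#' @slot phase one of `"gas"`, `"liquid"`, `"aqueous"`.
#' @slot dfG standard Gibbs energy of formation, kJ/mol, `NA_real_` if
#'   unknown.  Elemental reference species (e.g. H2) must carry 0.
#' @slot charge integer formal charge; all built-in species are neutral.
#'
#' @seealso [compound()], [compoundRegistry()], [degreeOfReduction()]
#' @export
setClass("Compound",
  representation(
    name = "character",
    formula = "numeric",
    phase = "character",
    dfG = "numeric",
    charge = "integer"
  ),
  prototype(dfG = NA_real_, charge = 0L)
)

setValidity("Compound", function(object) {
  msg <- character()
  if (length(object@name) != 1L || !nzchar(object@name))
    msg <- c(msg, "'name' must be a single non-empty string")
  f <- object@formula
  if (length(f) == 0L) {
    msg <- c(msg, "'formula' must contain at least one element")
  } else {
    if (is.null(names(f)) || any(!nzchar(names(f))))
      msg <- c(msg, "'formula' must be a named vector of atom counts")
    bad <- setdiff(names(f), .PERIODIC_SYMBOLS)
    if (length(bad))
      msg <- c(msg, paste0("unknown element symbol(s): ",
                           paste(bad, collapse = ", ")))
    if (any(f < 1 | f != round(f)))
      msg <- c(msg, "atom counts must be integers >= 1")
    if (anyDuplicated(names(f)))
      msg <- c(msg, "duplicate element symbols in formula")
  }
  if (length(object@phase) != 1L || !object@phase %in% .PHASES)
    msg <- c(msg, paste0("'phase' must be one of: ",
                         paste(.PHASES, collapse = ", ")))
  if (length(object@dfG) != 1L)
    msg <- c(msg, "'dfG' must be a single value (possibly NA)")
  # Elemental reference species have dfG identically 0 by definition.
  if (!is.na(object@dfG) && length(f) == 1L && object@dfG != 0 &&
      names(f)[1L] %in% c("H", "O", "N", "Cl") )
    msg <- c(msg, "formation energy of an elemental reference species must be 0")
  if (length(msg)) msg else TRUE
})

#' CompoundRegistry: a lookup table of compounds
#'
#' Maps species names (and condensed-formula aliases such as `"CH3COOH"`)
#' to [Compound-class] objects.  Reactions and bottle balances resolve their
#' species against a registry.
#'
#' @slot compounds named list of [Compound-class] objects.
#' @slot aliases named character vector mapping alternative spellings to
#'   canonical compound names.
#'
#' @seealso [compoundRegistry()]
#' @export
setClass("CompoundRegistry",
  representation(compounds = "list", aliases = "character")
)

setValidity("CompoundRegistry", function(object) {
  msg <- character()
  cl <- object@compounds
  if (length(cl)) {
    if (!all(vapply(cl, is, logical(1), "Compound")))
      msg <- c(msg, "all entries must be Compound objects")
    if (is.null(names(cl)) || anyDuplicated(names(cl)))
      msg <- c(msg, "compounds must be uniquely named")
  }
  if (length(object@aliases)) {
    unresolved <- setdiff(object@aliases, names(cl))
    if (length(unresolved))
      msg <- c(msg, paste0("aliases point to unknown compounds: ",
                           paste(unresolved, collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
})

#' Reaction: a signed stoichiometric map over compounds
#'
#' Coefficients are negative for consumed species and positive for formed
#' species.  A reaction optionally carries a standard Gibbs energy change
#' (kJ per mole of reaction as written).
#'
#' @slot name character(1) reaction label.
#' @slot stoich named numeric vector of nonzero signed coefficients; names
#'   are compound names resolvable in `compounds`.
#' @slot compounds named list of the [Compound-class] objects involved,
#'   so a `Reaction` is self-contained for balancing audits.
#' @slot dG standard Gibbs energy change of reaction, kJ/mol, or `NA_real_`.
#'
#' @seealso [parseReaction()], [auditBalance()], [combineReactions()]
#' @export
setClass("Reaction",
  representation(
    name = "character",
    stoich = "numeric",
    compounds = "list",
    dG = "numeric"
  ),
  prototype(dG = NA_real_)
)

setValidity("Reaction", function(object) {
  msg <- character()
  s <- object@stoich
  if (length(s) < 2L || is.null(names(s)))
    msg <- c(msg, "'stoich' must be a named vector with >= 2 species")
  if (any(s == 0) || any(!is.finite(s)))
    msg <- c(msg, "stoichiometric coefficients must be nonzero and finite")
  if (length(s) && !any(s < 0))
    msg <- c(msg, "reaction has no reactant (no negative coefficient)")
  if (length(s) && !any(s > 0))
    msg <- c(msg, "reaction has no product (no positive coefficient)")
  missing <- setdiff(names(s), names(object@compounds))
  if (length(missing))
    msg <- c(msg, paste0("species without Compound entries: ",
                         paste(missing, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' BottleBalance: per-bottle substrate/product inventory
#'
#' Amounts (µmol per bottle) of substrates consumed and products formed in
#' one microcosm bottle (or treatment mean), the input to carbon- and
#' electron-recovery statistics.
#'
#' @slot treatment character(1) label, e.g. `"5 mL/dose CO"`.
#' @slot substrates named numeric, µmol consumed per bottle (names are
#'   compound names).
#' @slot products named numeric, µmol formed per bottle.
#' @slot residuals named numeric, µmol remaining unconsumed (optional;
#'   excluded from recoveries unless requested).
#' @slot registry the [CompoundRegistry-class] used to resolve species.
#'
#' @seealso [carbonRecovery()], [electronRecovery()], [balanceReport()]
#' @export
setClass("BottleBalance",
  representation(
    treatment = "character",
    substrates = "numeric",
    products = "numeric",
    residuals = "numeric",
    registry = "CompoundRegistry"
  ),
  prototype(residuals = numeric())
)

setValidity("BottleBalance", function(object) {
  msg <- character()
  for (slotnm in c("substrates", "products", "residuals")) {
    v <- slot(object, slotnm)
    if (length(v)) {
      if (is.null(names(v)) || any(!nzchar(names(v))))
        msg <- c(msg, paste0("'", slotnm, "' must be named by species"))
      if (any(v < 0))
        msg <- c(msg, paste0("'", slotnm, "' amounts must be >= 0"))
    }
  }
  both <- intersect(names(object@substrates), names(object@products))
  if (length(both))
    msg <- c(msg, paste0("species in both substrates and products: ",
                         paste(both, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' DoseSchedule: timed gas additions
#'
#' An ordered series of gas doses (mL at the working temperature/pressure)
#' applied to a bottle at given times.
#'
#' @slot time_d numeric, days since inoculation, non-decreasing, >= 0.
#' @slot volume_ml numeric, dose volumes in mL, >= 0.
#' @slot molar_volume L/mol used to convert volumes to µmol (default 24.5,
#'   ideal gas at ~25 degC and 1 atm as rounded in the source accounting).
#'
#' @seealso [doseSchedule()], [cumulativeDose()]
#' @export
setClass("DoseSchedule",
  representation(time_d = "numeric", volume_ml = "numeric",
                 molar_volume = "numeric"),
  prototype(molar_volume = 24.5)
)

setValidity("DoseSchedule", function(object) {
  msg <- character()
  if (length(object@time_d) != length(object@volume_ml))
    msg <- c(msg, "'time_d' and 'volume_ml' must have equal length")
  if (any(object@time_d < 0)) msg <- c(msg, "dose times must be >= 0")
  if (is.unsorted(object@time_d)) msg <- c(msg, "dose times must be non-decreasing")
  if (any(object@volume_ml < 0)) msg <- c(msg, "dose volumes must be >= 0")
  if (length(object@molar_volume) != 1L || object@molar_volume <= 0)
    msg <- c(msg, "'molar_volume' must be a single positive value")
  if (length(msg)) msg else TRUE
})

#' TimeCourse: species trajectories for one bottle
#'
#' Per-timepoint amounts of the tracked species (µmol/bottle; H2 may be
#' carried in nmol/bottle and acetate in mM by the caller -- the `units`
#' slot records the convention per species).
#'
#' @slot time numeric vector of days.
#' @slot amounts numeric matrix, one row per timepoint, one named column per
#'   species.
#' @slot units named character vector, unit label per species column.
#' @slot cells optional numeric vector of cell counts (cells/mL), length 0
#'   or length(time).
#'
#' @seealso [timeCourse()], [chloroetheneClosure()]
#' @export
setClass("TimeCourse",
  representation(time = "numeric", amounts = "matrix",
                 units = "character", cells = "numeric"),
  prototype(cells = numeric())
)

setValidity("TimeCourse", function(object) {
  msg <- character()
  if (nrow(object@amounts) != length(object@time))
    msg <- c(msg, "'amounts' must have one row per timepoint")
  if (is.null(colnames(object@amounts)))
    msg <- c(msg, "'amounts' columns must be named by species")
  if (any(object@amounts < 0, na.rm = TRUE))
    msg <- c(msg, "amounts must be >= 0")
  if (is.unsorted(object@time))
    msg <- c(msg, "'time' must be non-decreasing")
  if (length(object@cells) &&
      length(object@cells) != length(object@time))
    msg <- c(msg, "'cells' must be empty or one value per timepoint")
  if (length(msg)) msg else TRUE
})

#' SimConfig: parameters of the synthetic bottle generator
#'
#' Rate constants, Monod/threshold parameters, dosing, noise, and seed for
#' [simulateBottle()].  Defaults emulate a bicarbonate-buffered 80 mL bottle
#' amended with 5 mL CO per dose (seven doses, 35 mL total) and ~35 µmol TCE.
#'
#' @slot doses a [DoseSchedule-class] of CO additions.
#' @slot tce0 initial TCE, µmol/bottle.
#' @slot co2_0 initial dissolved CO2 pool available to acetogens, µmol.
#' @slot liquid_ml liquid volume, mL.
#' @slot k_co CO oxidation (biological water-gas shift) first-order rate, /day.
#' @slot k_ac acetogenesis rate constant, /day (first-order in H2).
#' @slot k_me acetoclastic methanogenesis rate constant, /day (default 0).
#' @slot k_dechlor named numeric, per-step dechlorination rate constants
#'   `c(TCE=, cDCE=, VC=)`, /day (first-order in the chloroethene, Monod in H2).
#' @slot K_H named numeric, H2 half-saturation per step, nmol/bottle.
#' @slot h2_threshold named numeric, H2 cutoff per step, nmol/bottle; the
#'   step stops below its threshold.
#' @slot noise_sd relative Gaussian measurement noise (0 = noise-free).
#' @slot seed integer RNG seed; same seed gives bit-identical output.
#' @slot dt integration step, days.
#' @slot t_end simulation horizon, days.
#'
#' @seealso [simConfig()], [simulateBottle()]
#' @export
setClass("SimConfig",
  representation(
    doses = "DoseSchedule", tce0 = "numeric", co2_0 = "numeric",
    liquid_ml = "numeric", k_co = "numeric", k_ac = "numeric",
    k_me = "numeric", k_dechlor = "numeric", K_H = "numeric",
    h2_threshold = "numeric", noise_sd = "numeric", seed = "integer",
    dt = "numeric", t_end = "numeric"
  )
)

setValidity("SimConfig", function(object) {
  msg <- character()
  pos <- c(dt = object@dt, t_end = object@t_end, liquid_ml = object@liquid_ml)
  if (any(pos <= 0))
    msg <- c(msg, "'dt', 't_end' and 'liquid_ml' must be > 0")
  nonneg <- c(object@tce0, object@co2_0, object@k_co, object@k_ac,
              object@k_me, object@k_dechlor, object@K_H, object@h2_threshold,
              object@noise_sd)
  if (any(nonneg < 0))
    msg <- c(msg, "rates, pools, thresholds and noise_sd must be >= 0")
  steps <- c("TCE", "cDCE", "VC")
  for (slotnm in c("k_dechlor", "K_H", "h2_threshold"))
    if (!all(steps %in% names(slot(object, slotnm))))
      msg <- c(msg, paste0("'", slotnm, "' must be named TCE, cDCE, VC"))
  if (length(object@seed) != 1L || is.na(object@seed))
    msg <- c(msg, "'seed' must be a single integer")
  if (length(msg)) msg else TRUE
})

#' SimResult: output of the synthetic bottle generator
#'
#' @slot truth noise-free [TimeCourse-class] (µmol/bottle for every pool,
#'   including CO, CO2, H2 and HCl).
#' @slot noisy measured [TimeCourse-class]: truth plus truncated Gaussian
#'   relative noise on every species.
#' @slot fluxes named numeric, cumulative extent (µmol of reaction turnover)
#'   of each simulated reaction.
#' @slot balance the final [BottleBalance-class] assembled from true fluxes.
#' @slot config the [SimConfig-class] that produced the result.
#'
#' @seealso [simulateBottle()], [makeTable2Like()]
#' @export
setClass("SimResult",
  representation(truth = "TimeCourse", noisy = "TimeCourse",
                 fluxes = "numeric", balance = "BottleBalance",
                 config = "SimConfig")
)
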