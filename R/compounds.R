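#' Parse a Hill-style molecular formula
#'
#' Parses a formula written as a sequence of element symbols each followed by
#' an optional integer count (e.g. `"C2HCl3"`).  Condensed structural
#' formulas are not interpreted atom-group by atom-group; common condensed
#' spellings (e.g. `"CH3COOH"`) are supported through the registry alias
#' table instead (see [compoundRegistry()]).
#'
#' @param text a single formula string.
#' @return named numeric vector of atom counts (an element-count map).
#' @examples
#' parseFormula("C2HCl3")   # trichloroethene: C 2, H 1, Cl 3
#' parseFormula("H2O")
#' @export
parseFormula <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text) || !nzchar(text))
    stop("formula must be a single non-empty string", call. = FALSE)
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", text, perl = TRUE)[[1]]
  tokens <- regmatches(text, list(m))[[1]]
  if (sum(attr(m, "match.length")) != nchar(text) || !length(tokens))
    stop("cannot parse formula '", text, "'", call. = FALSE)
  syms <- sub("[0-9]*$", "", tokens)
  cnts <- as.numeric(ifelse(grepl("[0-9]+$", tokens),
                            sub("^[A-Za-z]+", "", tokens), "1"))
  bad <- setdiff(syms, .PERIODIC_SYMBOLS)
  if (length(bad))
    stop("unknown element symbol(s) in '", text, "': ",
         paste(unique(bad), collapse = ", "), call. = FALSE)
  counts <- tapply(cnts, factor(syms, levels = unique(syms)), sum)
  out <- as.numeric(counts)
  names(out) <- names(counts)
  out
}

#' Write an element-count map back to a Hill-ordered formula string
#'
#' Carbon first, then hydrogen, then remaining elements alphabetically
#' (plain alphabetical when no carbon is present).  `parseFormula()` of the
#' result round-trips to the same counts.
#'
#' @param counts named numeric vector of atom counts.
#' @return a single formula string.
#' @export
writeFormula <- function(counts) {
  stopifnot(is.numeric(counts), !is.null(names(counts)))
  els <- names(counts)
  ord <- if ("C" %in% els) {
    c("C", if ("H" %in% els) "H", sort(setdiff(els, c("C", "H"))))
  } else sort(els)
  paste0(ord, ifelse(counts[ord] == 1, "", counts[ord]), collapse = "")
}

#' Effective electron numbers per element
#'
#' The degree-of-reduction convention assigns each element a signed number
#' of available electrons per atom: C = +4, H = +1, O = -2.  Chlorine in
#' organochlorines is assigned 0 (consistent with the recovery statistics
#' this package reproduces: a chlorine substituent neither donates nor
#' accepts electrons in the balance); nitrogen defaults to 0 as well, an
#' extension beyond the C/H/O/Cl set that callers may override.
#'
#' @param ... named overrides or additions, e.g. `Cl = -1`.
#' @return named numeric vector mapping element symbols to electrons/atom;
#'   always contains C, H and O.
#' @examples
#' electronScheme()           # C=4, H=1, O=-2, Cl=0, N=0
#' electronScheme(N = -3)
#' @export
electronScheme <- function(...) {
  scheme <- c(C = 4, H = 1, O = -2, Cl = 0, N = 0)
  dots <- c(...)
  if (length(dots)) {
    if (is.null(names(dots)) || any(!nzchar(names(dots))))
      stop("overrides must be named by element symbol", call. = FALSE)
    bad <- setdiff(names(dots), .PERIODIC_SYMBOLS)
    if (length(bad))
      stop("unknown element symbol(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    scheme[names(dots)] <- dots
  }
  if (!all(c("C", "H", "O") %in% names(scheme)))
    stop("scheme must define C, H and O", call. = FALSE)
  scheme
}

#' Degree of reduction of a formula
#'
#' The degree of reduction (gamma) of a species is the sum over its atoms of
#' the per-element effective electron numbers: `sum(count[e] * scheme[e])`.
#' With the default scheme, CH4 gives 8, ethene (C2H4) 12, acetic acid
#' (C2H4O2) 8, CO 2, CO2 0, H2 2, and TCE (C2HCl3) 9.
#'
#' @param x a [Compound-class], a named element-count vector, or a formula
#'   string (parsed with [parseFormula()]).
#' @param scheme a named electron-number vector, see [electronScheme()].
#' @return electrons per mole (signed numeric scalar).
#' @examples
#' degreeOfReduction("CH4")              # 8
#' degreeOfReduction("C2HCl3")           # 9 (Cl counted as 0)
#' @export
degreeOfReduction <- function(x, scheme = electronScheme()) {
  counts <- .asCounts(x)
  missing <- setdiff(names(counts), names(scheme))
  if (length(missing))
    stop("element(s) missing from electron scheme: ",
         paste(missing, collapse = ", "), call. = FALSE)
  sum(counts * scheme[names(counts)])
}

#' Carbon atoms in a formula
#'
#' @inheritParams degreeOfReduction
#' @return integer count of C atoms (0 if absent).
#' @examples
#' carbonCount("CH3COOH")  # 2 (via the registry alias)
#' carbonCount("H2")       # 0
#' @export
carbonCount <- function(x) {
  counts <- .asCounts(x)
  if ("C" %in% names(counts)) as.integer(counts[["C"]]) else 0L
}

# Coerce compound / string / count-vector inputs to an element-count map.
# Strings try the default registry (so condensed aliases like "CH3COOH"
# work) before falling back to the Hill parser.
.asCounts <- function(x) {
  if (is(x, "Compound")) return(x@formula)
  if (is.character(x)) {
    reg <- compoundRegistry()
    if (x %in% names(reg@compounds) || x %in% names(reg@aliases))
      return(getCompound(reg, x)@formula)
    return(parseFormula(x))
  }
  if (is.numeric(x) && !is.null(names(x))) return(x)
  stop("cannot interpret formula input of class ", class(x)[1L], call. = FALSE)
}

#' Construct a Compound
#'
#' @param name species name.
#' @param formula a Hill formula string or a named count vector.
#' @param phase `"gas"`, `"liquid"` or `"aqueous"`.
#' @param dfG standard Gibbs energy of formation, kJ/mol (`NA` if unknown).
#' @param charge integer formal charge (default 0; the shipped species are
#'   all written as neutral molecules).
#' @return a [Compound-class] object.
#' @export
compound <- function(name, formula, phase = c("aqueous", "gas", "liquid"),
                     dfG = NA_real_, charge = 0L) {
  phase <- match.arg(phase)
  counts <- if (is.character(formula)) parseFormula(formula) else formula
  new("Compound", name = name, formula = counts, phase = phase,
      dfG = as.numeric(dfG), charge = as.integer(charge))
}

#' The built-in compound registry
#'
#' Ships the species of the CO-fed dechlorinating system: CO, CO2, H2, H2O,
#' CH4, ethene, acetic acid, TCE, cDCE, VC and HCl, with phases as used in
#' the thermodynamic ledger (H2, CO, CO2 and ethene gaseous; water and
#' acetic acid liquid; chloroethenes aqueous) and standard Gibbs formation
#' energies from the CRC Handbook of Chemistry and Physics, 84th edition
#' (298.15 K; values carried at the one-decimal precision of that source).
#' Acetic acid carries the liquid-phase value (-389.9 kJ/mol).  TCE, cDCE
#' and VC ship without formation energies: the dechlorination reaction's
#' Gibbs energy is a ledger constant, not recomputed (see
#' [referenceReactions()]).
#'
#' @param constants optional data.frame overriding the shipped constants
#'   table; must have columns `name`, `formula`, `phase`, `dfG_kJ_per_mol`
#'   (see [formationEnergies()]).
#' @return a [CompoundRegistry-class].
#' @examples
#' reg <- compoundRegistry()
#' getCompound(reg, "acetate")   # alias for acetic acid
#' @export
compoundRegistry <- function(constants = formationEnergies()) {
  stopifnot(all(c("name", "formula", "phase", "dfG_kJ_per_mol") %in%
                names(constants)))
  comps <- lapply(seq_len(nrow(constants)), function(i) {
    compound(constants$name[i], constants$formula[i],
             phase = constants$phase[i],
             dfG = constants$dfG_kJ_per_mol[i])
  })
  names(comps) <- constants$name
  aliases <- c(
    CH3COOH = "acetic_acid", acetate = "acetic_acid",
    C2H4O2 = "acetic_acid", C2H4 = "ethene", ethylene = "ethene",
    C2HCl3 = "TCE", trichloroethene = "TCE",
    C2H2Cl2 = "cDCE", dichloroethene = "cDCE",
    C2H3Cl = "VC", vinyl_chloride = "VC",
    CH4 = "methane", H2O = "water"
  )
  aliases <- aliases[aliases %in% names(comps)]
  new("CompoundRegistry", compounds = comps, aliases = aliases)
}

#' Shipped formation-energy constants
#'
#' Standard Gibbs energies of formation (kJ/mol, 298.15 K) from the CRC
#' Handbook of Chemistry and Physics, 84th edition, for the species of the
#' CO/H2/acetate/methane/chloroethene system.  Chloroethenes carry `NA`:
#' their reaction energetics enter through ledger constants only.  The table
#' is also shipped as `inst/extdata/formation_energies.csv`.
#'
#' @param file optional path to a CSV with columns `name`, `formula`,
#'   `phase`, `dfG_kJ_per_mol` (extra columns ignored).
#' @return data.frame with those columns.
#' @export
formationEnergies <- function(file = NULL) {
  if (!is.null(file)) {
    tab <- utils::read.csv(file, stringsAsFactors = FALSE)
    need <- c("name", "formula", "phase", "dfG_kJ_per_mol")
    if (!all(need %in% names(tab)))
      stop("constants table must have columns: ",
           paste(need, collapse = ", "), call. = FALSE)
    return(tab)
  }
  data.frame(
    name = c("CO", "CO2", "H2", "water", "methane", "ethene",
             "acetic_acid", "TCE", "cDCE", "VC", "HCl"),
    formula = c("CO", "CO2", "H2", "H2O", "CH4", "C2H4",
                "C2H4O2", "C2HCl3", "C2H2Cl2", "C2H3Cl", "HCl"),
    phase = c("gas", "gas", "gas", "liquid", "gas", "gas",
              "liquid", "aqueous", "aqueous", "aqueous", "aqueous"),
    dfG_kJ_per_mol = c(-137.2, -394.4, 0, -237.1, -50.5, 68.4,
                       -389.9, NA, NA, NA, NA),
    source = c(rep("CRC Handbook 84th ed.", 7), rep("", 4)),
    stringsAsFactors = FALSE
  )
}
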