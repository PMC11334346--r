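# Coefficients smaller than this are treated as exact cancellation when
# combining reactions; keeps Hess bookkeeping clean in double precision.
.COEF_TOL <- 1e-9

#' Parse a reaction string
#'
#' Grammar: `"name: c1 SP(phase) + ... -> c2 SP(phase) + ..."`.
#' Coefficients default to 1; the `(phase)` annotation is optional and
#' purely decorative (phases come from the registry).  Species are resolved
#' against a [CompoundRegistry-class], so aliases like `CH3COOH` work.
#'
#' @param text a single reaction string.
#' @param registry compound registry for species resolution.
#' @return a [Reaction-class] with negative coefficients for reactants and
#'   positive for products.
#' @examples
#' parseReaction("wgs: CO(g) + H2O(l) -> CO2(g) + H2(g)")
#' @export
parseReaction <- function(text, registry = compoundRegistry()) {
  stopifnot(is.character(text), length(text) == 1L)
  txt <- trimws(text)
  name <- ""
  if (grepl("^[^:]+:", txt)) {
    name <- trimws(sub(":.*$", "", txt))
    txt <- trimws(sub("^[^:]+:", "", txt))
  }
  if (!grepl("->|→", txt))
    stop("reaction '", name, "': missing arrow ('->')", call. = FALSE)
  sides <- strsplit(txt, "->|→")[[1]]
  if (length(sides) != 2L)
    stop("reaction must have exactly one arrow", call. = FALSE)

  parseSide <- function(side, sign) {
    side <- trimws(side)
    if (!nzchar(side))
      stop("reaction '", name, "': ",
           if (sign < 0) "no reactant" else "no product", call. = FALSE)
    terms <- trimws(strsplit(side, "+", fixed = TRUE)[[1]])
    out <- numeric(0)
    for (term in terms) {
      if (!nzchar(term))
        stop("empty term in reaction '", name, "'", call. = FALSE)
      m <- regexec("^([0-9]*\\.?[0-9]*(?:/[0-9]+)?)\\s*([A-Za-z][A-Za-z0-9_]*)\\s*(?:\\(([a-z]+)\\))?$",
                   term)
      parts <- regmatches(term, m)[[1]]
      if (!length(parts))
        stop("cannot parse term '", term, "' in reaction '", name, "'",
             call. = FALSE)
      coefTxt <- parts[2]
      coef <- if (!nzchar(coefTxt)) 1
        else if (grepl("/", coefTxt)) {
          nd <- as.numeric(strsplit(coefTxt, "/", fixed = TRUE)[[1]])
          nd[1] / nd[2]
        } else as.numeric(coefTxt)
      sp <- parts[3]
      cmp <- getCompound(registry, sp)  # errors on unresolvable species
      nm <- compoundName(cmp)
      prev <- if (nm %in% names(out)) out[[nm]] else 0
      out[nm] <- prev + sign * coef
    }
    out
  }

  lhs <- parseSide(sides[1], -1)
  rhs <- parseSide(sides[2], +1)
  st <- lhs
  for (sp in names(rhs)) st[sp] <- (if (sp %in% names(st)) st[sp] else 0) + rhs[sp]
  st <- st[abs(st) > .COEF_TOL]
  comps <- lapply(names(st), getCompound, x = registry)
  names(comps) <- names(st)
  new("Reaction", name = name, stoich = st, compounds = comps, dG = NA_real_)
}

#' Construct a Reaction from a coefficient map
#'
#' @param name reaction label.
#' @param stoich named numeric vector of signed coefficients (negative =
#'   consumed), names resolvable in `registry`.
#' @param dG optional standard Gibbs energy of reaction, kJ/mol.
#' @param registry compound registry.
#' @return a [Reaction-class].
#' @export
reaction <- function(name, stoich, dG = NA_real_,
                     registry = compoundRegistry()) {
  comps <- lapply(names(stoich), getCompound, x = registry)
  names(comps) <- vapply(comps, compoundName, character(1))
  names(stoich) <- names(comps)
  new("Reaction", name = name, stoich = stoich, compounds = comps,
      dG = as.numeric(dG))
}

#' Audit elemental, charge and electron balance of a reaction
#'
#' Sums `coefficient * atom count` per element over all species (products
#' minus reactants), plus the net charge and the net degree-of-reduction
#' (gamma-weighted) electron delta.  A balanced redox reaction has every
#' delta exactly 0; electron conservation under the C=4/H=1/O=-2/Cl=0
#' scheme is implied by elemental balance but is reported separately so an
#' unbalanced scheme override is caught.
#'
#' @param r a [Reaction-class].
#' @param scheme electron-number scheme, see [electronScheme()].
#' @return a list of class `"BalanceAudit"` with components `elements`
#'   (named numeric net atom deltas), `charge`, `electrons`, and `balanced`
#'   (TRUE when all deltas are 0 to 1e-9).
#' @examples
#' r <- parseReaction("wgs: CO(g) + H2O(l) -> CO2(g) + H2(g)")
#' auditBalance(r)$balanced
#' @export
auditBalance <- function(r, scheme = electronScheme()) {
  stopifnot(is(r, "Reaction"))
  els <- sort(unique(unlist(lapply(r@compounds, function(cmp)
    names(cmp@formula)))))
  delta <- setNames(numeric(length(els)), els)
  charge <- 0
  electrons <- 0
  for (sp in names(r@stoich)) {
    cmp <- r@compounds[[sp]]
    cf <- r@stoich[[sp]]
    delta[names(cmp@formula)] <- delta[names(cmp@formula)] + cf * cmp@formula
    charge <- charge + cf * cmp@charge
    electrons <- electrons + cf * degreeOfReduction(cmp, scheme)
  }
  structure(
    list(reaction = r@name, elements = delta, charge = charge,
         electrons = electrons,
         balanced = all(abs(c(delta, charge, electrons)) <= .COEF_TOL)),
    class = "BalanceAudit"
  )
}

#' @export
print.BalanceAudit <- function(x, ...) {
  cat("Balance audit", if (nzchar(x$reaction)) paste0("'", x$reaction, "'"),
      if (x$balanced) "- balanced\n" else "- NOT balanced\n")
  nz <- x$elements[abs(x$elements) > .COEF_TOL]
  if (length(nz)) {
    cat("  element deltas:",
        paste(sprintf("%s %+g", names(nz), nz), collapse = ", "), "\n")
  }
  if (abs(x$charge) > .COEF_TOL) cat("  charge delta:", x$charge, "\n")
  if (abs(x$electrons) > .COEF_TOL)
    cat("  electron delta:", x$electrons, "\n")
  invisible(x)
}

#' Standard Gibbs energy of reaction from formation energies
#'
#' Computes `sum(coefficient * dfG'(species))` at 298.15 K with gases at
#' 1 atm and solutes at 1 M.  No pH-dependent (Legendre) transformation is
#' applied: the ledger's species are written as neutral molecules
#' (CH3COOH, HCl), so the formation-energy sum is the stated convention.
#'
#' @param r a [Reaction-class].
#' @param registry registry supplying formation energies (the reaction's
#'   own compounds are used if they carry energies; the registry is the
#'   fallback source).
#' @return kJ per mole of reaction as written (full precision; display
#'   rounds to one decimal).
#' @examples
#' wgs <- parseReaction("wgs: CO(g) + H2O(l) -> CO2(g) + H2(g)")
#' deltaGStandard(wgs)   # -20.1 kJ/mol
#' @export
deltaGStandard <- function(r, registry = compoundRegistry()) {
  stopifnot(is(r, "Reaction"))
  total <- 0
  for (sp in names(r@stoich)) {
    cmp <- r@compounds[[sp]]
    g <- cmp@dfG
    if (is.na(g)) g <- tryCatch(getCompound(registry, sp)@dfG,
                                error = function(e) NA_real_)
    if (is.na(g))
      stop("no formation energy for compound '", sp, "'", call. = FALSE)
    total <- total + r@stoich[[sp]] * g
  }
  total
}

#' Linear (Hess-law) combination of reactions
#'
#' Forms `sum(multiplier_i * reaction_i)`: coefficients add linearly,
#' species cancelling to zero are dropped, and the Gibbs energy of the
#' combination is the same linear combination of the inputs' energies when
#' every input carries one (otherwise `NA`).
#'
#' @param terms list of `list(multiplier, Reaction)` pairs (or a named list
#'   with elements `m` and `r`).
#' @param name label for the combined reaction.
#' @return a [Reaction-class].
#' @examples
#' rx <- referenceReactions()
#' # 4 x (water-gas shift) + (hydrogenotrophic acetogenesis)
#' # = acetogenesis from CO
#' combineReactions(list(list(4, rx$wgs), list(1, rx$acetogenesis_h2)))
#' @export
combineReactions <- function(terms, name = "combined") {
  stopifnot(is.list(terms), length(terms) >= 1L)
  st <- numeric(0)
  comps <- list()
  dG <- 0
  haveG <- TRUE
  for (term in terms) {
    m <- term[[1]]
    r <- term[[2]]
    stopifnot(is.numeric(m), length(m) == 1L, is(r, "Reaction"))
    if (m == 0) stop("multipliers must be nonzero", call. = FALSE)
    for (sp in names(r@stoich)) {
      st[sp] <- (if (sp %in% names(st)) st[[sp]] else 0) + m * r@stoich[[sp]]
      comps[[sp]] <- r@compounds[[sp]]
    }
    if (is.na(r@dG)) haveG <- FALSE else dG <- dG + m * r@dG
  }
  st <- st[abs(st) > .COEF_TOL]
  if (!length(st))
    stop("null reaction: all species cancel", call. = FALSE)
  new("Reaction", name = name, stoich = st, compounds = comps[names(st)],
      dG = if (haveG) dG else NA_real_)
}

#' Human-readable equation for a reaction
#'
#' @param r a [Reaction-class].
#' @return a single string, e.g. `"CO + H2O -> CO2 + H2"`.
#' @export
reactionEquation <- function(r) {
  stopifnot(is(r, "Reaction"))
  fmt <- function(sp) {
    cf <- abs(r@stoich[[sp]])
    paste0(if (abs(cf - 1) > .COEF_TOL) paste0(format(cf), " "), sp)
  }
  lhs <- names(r@stoich)[r@stoich < 0]
  rhs <- names(r@stoich)[r@stoich > 0]
  paste(paste(vapply(lhs, fmt, character(1)), collapse = " + "),
        "->",
        paste(vapply(rhs, fmt, character(1)), collapse = " + "))
}

#' The built-in reaction ledger
#'
#' The seven redox reactions of the CO-fed dechlorinating system with their
#' standard Gibbs energy changes (kJ/mol, 298.15 K, 1 atm gases, 1 M
#' solutes):
#'
#' 1. `dechlorination`: C2HCl3 + 3 H2 -> C2H4 + 3 HCl, -150.5 (ledger
#'    constant: the chloroethene formation energies are not shipped)
#' 2. `wgs`: CO + H2O -> CO2 + H2, -20.1 (biological water-gas shift)
#' 3. `acetogenesis_h2`: 2 CO2 + 4 H2 -> 2 H2O + CH3COOH, -75.3
#' 4. `acetogenesis_co`: 4 CO + 2 H2O -> 2 CO2 + CH3COOH, -155.7
#'    (the Wood-Ljungdahl route with CO as carbon and energy source)
#' 5. `methanogenesis_ac`: CH3COOH -> CO2 + CH4, -55.0
#' 6. `methanogenesis_h2`: CO2 + 4 H2 -> 2 H2O + CH4, -130.3
#' 7. `methanogenesis_co`: 4 CO + 2 H2O -> 3 CO2 + CH4, -210.7
#'
#' Reactions 2-7 are recomputable from the shipped CRC formation energies;
#' reaction 1 carries its ledger value only.  Rows 4, 5 and 7 are Hess
#' combinations of rows 2, 3 and 6 (e.g. 4 x wgs + acetogenesis_h2 =
#' acetogenesis_co).
#'
#' @param registry compound registry used to resolve species.
#' @return named list of seven [Reaction-class] objects, each with its
#'   ledger `deltaG` attached.
#' @export
referenceReactions <- function(registry = compoundRegistry()) {
  def <- list(
    dechlorination    = c("TCE(aq) + 3 H2(g) -> ethene(g) + 3 HCl", -150.5),
    wgs               = c("CO(g) + water(l) -> CO2(g) + H2(g)", -20.1),
    acetogenesis_h2   = c("2 CO2(g) + 4 H2(g) -> 2 water(l) + CH3COOH", -75.3),
    acetogenesis_co   = c("4 CO(g) + 2 water(l) -> 2 CO2(g) + CH3COOH", -155.7),
    methanogenesis_ac = c("CH3COOH -> CO2(g) + CH4(g)", -55.0),
    methanogenesis_h2 = c("CO2(g) + 4 H2(g) -> 2 water(l) + CH4(g)", -130.3),
    methanogenesis_co = c("4 CO(g) + 2 water(l) -> 3 CO2(g) + CH4(g)", -210.7)
  )
  out <- lapply(names(def), function(nm) {
    r <- parseReaction(paste0(nm, ": ", def[[nm]][1]), registry)
    r@dG <- as.numeric(def[[nm]][2])
    r
  })
  names(out) <- names(def)
  out
}
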