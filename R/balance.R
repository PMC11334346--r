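#' Construct a per-bottle substrate/product inventory
#'
#' @param treatment label for the bottle or treatment.
#' @param substrates named numeric, µmol of each substrate consumed.
#' @param products named numeric, µmol of each product formed.
#' @param residuals named numeric, µmol remaining unconsumed (optional).
#' @param registry compound registry resolving the species names.
#' @return a [BottleBalance-class].
#' @examples
#' b <- bottleBalance("2 mL/dose CO",
#'                    substrates = c(CO = 571.4, TCE = 38.2),
#'                    products = c(methane = 3.2, ethene = 28.7,
#'                                 acetate = 170.1))
#' carbonRecovery(b)   # 61.9
#' @export
bottleBalance <- function(treatment, substrates, products,
                          residuals = numeric(),
                          registry = compoundRegistry()) {
  canon <- function(v) {
    if (!length(v)) return(v)
    names(v) <- vapply(names(v), function(nm)
      compoundName(getCompound(registry, nm)), character(1))
    v
  }
  new("BottleBalance", treatment = treatment, substrates = canon(substrates),
      products = canon(products), residuals = canon(residuals),
      registry = registry)
}

# Weighted sum of amounts: weight(species) from `fun`, optionally dropping
# CO2 (the convention of the recovery statistics) and adding residuals.
.weightedTotal <- function(amounts, registry, fun, excludeCO2 = TRUE) {
  if (!length(amounts)) return(0)
  total <- 0
  for (sp in names(amounts)) {
    cmp <- getCompound(registry, sp)
    if (excludeCO2 && identical(writeFormula(cmp@formula), "CO2")) next
    total <- total + amounts[[sp]] * fun(cmp)
  }
  total
}

#' Carbon recovery of a bottle balance
#'
#' The percentage of substrate carbon recovered in the measured products:
#' `100 * sum(products umol * C atoms) / sum(substrates umol * C atoms)`.
#' CO2 is excluded from both sides by default, the convention of the
#' recovery statistics this reproduces (the resulting shortfall is the
#' mineralised CO2 share); residuals are excluded unless requested.
#'
#' @param b a [BottleBalance-class].
#' @param includeCO2 count CO2 on both sides (default FALSE).
#' @param includeResiduals add residual amounts to the product side
#'   (default FALSE).
#' @param digits decimals for the returned percentage (half-up rounding;
#'   `NULL` for full precision).
#' @return percentage (numeric scalar).
#' @export
carbonRecovery <- function(b, includeCO2 = FALSE, includeResiduals = FALSE,
                           digits = 1) {
  stopifnot(is(b, "BottleBalance"))
  w <- function(cmp) carbonCount(cmp)
  cin <- .weightedTotal(b@substrates, b@registry, w, !includeCO2)
  cout <- .weightedTotal(b@products, b@registry, w, !includeCO2)
  if (includeResiduals)
    cout <- cout + .weightedTotal(b@residuals, b@registry, w, !includeCO2)
  if (cin <= 0)
    stop("no substrate carbon: cannot compute carbon recovery", call. = FALSE)
  pct <- 100 * cout / cin
  if (is.null(digits)) pct else roundHalfUp(pct, digits)
}

#' Electron recovery of a bottle balance
#'
#' The percentage of substrate degree-of-reduction electrons recovered in
#' the products: `100 * sum(products umol * gamma) / sum(substrates umol *
#' gamma)` with gamma from [degreeOfReduction()] (C=4, H=1, O=-2, Cl=0 by
#' default, so TCE contributes 9 electrons/mol on the substrate side).
#' Species with gamma = 0 (CO2, H2O) drop out of the statistic naturally.
#'
#' @inheritParams carbonRecovery
#' @param scheme electron-number scheme, see [electronScheme()].
#' @return percentage (numeric scalar).
#' @export
electronRecovery <- function(b, scheme = electronScheme(),
                             includeCO2 = FALSE, includeResiduals = FALSE,
                             digits = 1) {
  stopifnot(is(b, "BottleBalance"))
  w <- function(cmp) degreeOfReduction(cmp, scheme)
  ein <- .weightedTotal(b@substrates, b@registry, w, !includeCO2)
  eout <- .weightedTotal(b@products, b@registry, w, !includeCO2)
  if (includeResiduals)
    eout <- eout + .weightedTotal(b@residuals, b@registry, w, !includeCO2)
  if (ein <= 0)
    stop("no substrate electrons: cannot compute electron recovery",
         call. = FALSE)
  pct <- 100 * eout / ein
  if (is.null(digits)) pct else roundHalfUp(pct, digits)
}

#' Full recovery report for a bottle
#'
#' Bundles carbon and electron recoveries with the underlying in/out totals
#' (µmol carbon and µmol gamma-electrons).
#'
#' @inheritParams electronRecovery
#' @return a list of class `"RecoveryResult"`: `treatment`,
#'   `carbon_recovery_pct`, `electron_recovery_pct`, `carbon_in`,
#'   `carbon_out`, `electrons_in`, `electrons_out` (totals at full
#'   precision, percentages rounded half-up to one decimal).
#' @export
balanceReport <- function(b, scheme = electronScheme(),
                          includeCO2 = FALSE, includeResiduals = FALSE) {
  stopifnot(is(b, "BottleBalance"))
  if (!length(b@substrates) || !length(b@products))
    stop("bottle balance needs at least one substrate and one product",
         call. = FALSE)
  wc <- function(cmp) carbonCount(cmp)
  we <- function(cmp) degreeOfReduction(cmp, scheme)
  resid <- if (includeResiduals) b@residuals else numeric()
  cin <- .weightedTotal(b@substrates, b@registry, wc, !includeCO2)
  cout <- .weightedTotal(b@products, b@registry, wc, !includeCO2) +
    .weightedTotal(resid, b@registry, wc, !includeCO2)
  ein <- .weightedTotal(b@substrates, b@registry, we, !includeCO2)
  eout <- .weightedTotal(b@products, b@registry, we, !includeCO2) +
    .weightedTotal(resid, b@registry, we, !includeCO2)
  if (cin <= 0 || ein <= 0)
    stop("substrate totals are zero: cannot compute recoveries",
         call. = FALSE)
  structure(
    list(treatment = b@treatment,
         carbon_recovery_pct = roundHalfUp(100 * cout / cin, 1),
         electron_recovery_pct = roundHalfUp(100 * eout / ein, 1),
         carbon_in = cin, carbon_out = cout,
         electrons_in = ein, electrons_out = eout),
    class = "RecoveryResult"
  )
}

#' @export
print.RecoveryResult <- function(x, ...) {
  cat("Recovery report:", x$treatment, "\n")
  cat(sprintf("  carbon:   %.1f %%  (%.1f / %.1f µmol C)\n",
              x$carbon_recovery_pct, x$carbon_out, x$carbon_in))
  cat(sprintf("  electron: %.1f %%  (%.1f / %.1f µmol e-)\n",
              x$electron_recovery_pct, x$electrons_out, x$electrons_in))
  invisible(x)
}

#' Round half away from zero
#'
#' Presentation rounding used throughout the reports (base `round()` uses
#' round-half-even, which disagrees with the printed tables at .5 cases).
#'
#' @param x numeric.
#' @param digits decimal places.
#' @return rounded numeric.
#' @export
roundHalfUp <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
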