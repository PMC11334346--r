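#' Convert a gas volume to micromoles
#'
#' Ideal-gas conversion at the bottle's working conditions.  The default
#' molar volume of 24.5 L/mol corresponds to ~25 degC and 1 atm rounded to
#' the convention under which 14 mL of CO is 571.4 µmol and 35 mL is
#' 1428.6 µmol.
#'
#' @param volume_ml gas volume in mL (scalar or vector).
#' @param molar_volume L/mol (default 24.5).
#' @param digits decimals for presentation (`NULL` for full precision,
#'   which downstream chain computations use).
#' @return µmol.
#' @examples
#' gasVolumeToUmol(35)   # 1428.6
#' gasVolumeToUmol(5)    # 204.1
#' @export
gasVolumeToUmol <- function(volume_ml, molar_volume = 24.5, digits = 1) {
  if (any(volume_ml < 0)) stop("gas volume must be >= 0", call. = FALSE)
  if (molar_volume <= 0) stop("molar volume must be > 0", call. = FALSE)
  umol <- 1000 * volume_ml / molar_volume
  if (is.null(digits)) umol else roundHalfUp(umol, digits)
}

#' Maximal H2 from CO oxidation
#'
#' The biological water-gas shift (CO + H2O -> CO2 + H2) yields one H2 per
#' CO, so the theoretical maximum equals the CO amount.
#'
#' @param co_umol µmol CO.
#' @return µmol H2.
#' @examples
#' maxH2FromCO(1428.6)   # 1428.6
#' @export
maxH2FromCO <- function(co_umol) {
  if (any(co_umol < 0)) stop("CO amount must be >= 0", call. = FALSE)
  co_umol
}

#' H2 demand of reductive dechlorination
#'
#' Hydrogenolysis consumes one H2 per chlorine removed, so complete
#' TCE -> ethene dechlorination needs 3 H2 per TCE.  The `steps` argument
#' gives the partial chain: 1 step is TCE -> cDCE, 2 is TCE -> VC, 3 (the
#' default) is TCE -> ethene.
#'
#' @param tce_umol µmol TCE to dechlorinate.
#' @param steps number of hydrogenolysis steps (1-3).
#' @return µmol H2 required.
#' @examples
#' h2DemandDechlorination(33.3)            # 99.9 (prints as 100.0 rounded up)
#' h2DemandDechlorination(10, steps = 1)   # 10: TCE -> cDCE only
#' @export
h2DemandDechlorination <- function(tce_umol, steps = 3) {
  if (any(tce_umol < 0)) stop("TCE amount must be >= 0", call. = FALSE)
  if (!steps %in% 1:3) stop("'steps' must be 1, 2 or 3", call. = FALSE)
  tce_umol * steps
}

#' Acetate from residual H2
#'
#' H2 left over after dechlorination, if routed entirely into
#' hydrogenotrophic acetogenesis (2 CO2 + 4 H2 -> CH3COOH + 2 H2O), yields
#' one acetate per four H2.
#'
#' @param h2_max_umol µmol H2 available.
#' @param h2_consumed_umol µmol H2 already spent (e.g. on dechlorination).
#' @return µmol acetate (full precision).
#' @examples
#' acetateFromResidualH2(1428.6, 100)   # 332.15
#' @export
acetateFromResidualH2 <- function(h2_max_umol, h2_consumed_umol) {
  if (any(h2_consumed_umol > h2_max_umol))
    stop("H2 consumed exceeds the available H2", call. = FALSE)
  (h2_max_umol - h2_consumed_umol) / 4
}

#' Micromoles to millimolar concentration
#'
#' @param umol amount, µmol.
#' @param liquid_ml liquid volume, mL.
#' @param digits decimals (half-up; `NULL` for full precision).
#' @return mM.
#' @examples
#' umolToMM(332.1, 80)   # 4.2
#' @export
umolToMM <- function(umol, liquid_ml, digits = 1) {
  if (liquid_ml <= 0) stop("liquid volume must be > 0", call. = FALSE)
  conc <- umol / liquid_ml
  if (is.null(digits)) conc else roundHalfUp(conc, digits)
}

#' The CO -> H2 -> dechlorination -> acetate yield chain
#'
#' Runs the stepwise theoretical-yield accounting for a CO-fed bottle: the
#' dosed CO volume is converted to µmol, oxidised 1:1 to H2, the
#' dechlorination demand (3 H2 per TCE) is subtracted, and the residual H2
#' is routed to acetate (4 H2 per acetate), finally expressed as a medium
#' concentration.  All intermediates are carried at full precision; only
#' the printed report rounds (half-up, one decimal).  `h2_demand_umol`
#' optionally overrides the computed demand so an as-printed intermediate
#' (e.g. 100.0 µmol for 33.3 µmol TCE) can be fed forward.
#'
#' @param co_ml CO dosed, mL of gas.
#' @param tce_umol TCE dechlorinated, µmol.
#' @param liquid_ml medium volume, mL (default 80).
#' @param molar_volume L/mol for the gas conversion (default 24.5).
#' @param h2_demand_umol optional externally supplied dechlorination H2
#'   demand, µmol; default `tce_umol * 3`.
#' @return list of class `"YieldChainResult"`: `co_umol`, `h2_max_umol`,
#'   `h2_dechlor_umol`, `h2_residual_umol`, `acetate_umol`, `acetate_mM`
#'   (full precision).
#' @examples
#' yieldChain(co_ml = 35, tce_umol = 33.3, h2_demand_umol = 100)
#' @export
yieldChain <- function(co_ml, tce_umol, liquid_ml = 80,
                       molar_volume = 24.5, h2_demand_umol = NULL) {
  co <- gasVolumeToUmol(co_ml, molar_volume, digits = NULL)
  h2max <- maxH2FromCO(co)
  demand <- if (is.null(h2_demand_umol)) h2DemandDechlorination(tce_umol)
            else h2_demand_umol
  ac <- acetateFromResidualH2(h2max, demand)
  structure(
    list(co_umol = co, h2_max_umol = h2max, h2_dechlor_umol = demand,
         h2_residual_umol = h2max - demand, acetate_umol = ac,
         acetate_mM = umolToMM(ac, liquid_ml, digits = NULL)),
    class = "YieldChainResult"
  )
}

#' @export
print.YieldChainResult <- function(x, ...) {
  cat("Theoretical yield chain\n")
  cat(sprintf("  CO dosed:             %8.1f µmol\n", roundHalfUp(x$co_umol, 1)))
  cat(sprintf("  maximal H2 (1:1):     %8.1f µmol\n", roundHalfUp(x$h2_max_umol, 1)))
  cat(sprintf("  dechlorination H2:    %8.1f µmol\n", roundHalfUp(x$h2_dechlor_umol, 1)))
  cat(sprintf("  residual H2:          %8.1f µmol\n", roundHalfUp(x$h2_residual_umol, 1)))
  cat(sprintf("  acetate (1 per 4 H2): %8.1f µmol\n", roundHalfUp(x$acetate_umol, 1)))
  cat(sprintf("  acetate concentration:%8.1f mM\n", roundHalfUp(x$acetate_mM, 1)))
  invisible(x)
}
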