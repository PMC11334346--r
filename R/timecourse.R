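#' Construct a TimeCourse
#'
#' @param time numeric vector of days.
#' @param amounts matrix or data.frame of species amounts (one column per
#'   species, µmol/bottle unless `units` says otherwise).
#' @param units optional named character of unit labels per species
#'   (default `"umol"` for every column).
#' @param cells optional cells/mL vector.
#' @return a [TimeCourse-class].
#' @export
timeCourse <- function(time, amounts, units = NULL, cells = numeric()) {
  m <- as.matrix(amounts)
  if (is.null(units)) units <- setNames(rep("umol", ncol(m)), colnames(m))
  new("TimeCourse", time = as.numeric(time), amounts = m,
      units = units, cells = as.numeric(cells))
}

#' Construct a dose schedule
#'
#' @param time_d dose times, days (non-decreasing).
#' @param volume_ml dose volumes, mL (recycled if scalar).
#' @param molar_volume L/mol for volume-to-µmol conversion (default 24.5).
#' @return a [DoseSchedule-class].
#' @examples
#' doseSchedule(seq(0, 60, by = 10), 5)   # seven 5-mL doses, 35 mL total
#' @export
doseSchedule <- function(time_d, volume_ml, molar_volume = 24.5) {
  if (length(volume_ml) == 1L) volume_ml <- rep(volume_ml, length(time_d))
  new("DoseSchedule", time_d = as.numeric(time_d),
      volume_ml = as.numeric(volume_ml),
      molar_volume = as.numeric(molar_volume))
}

#' Chloroethene molar closure of a time course
#'
#' Sequential hydrogenolysis preserves the two-carbon ethene skeleton, so
#' TCE + cDCE + VC + ethene should stay constant at the initial TCE amount
#' throughout a dechlorination time course.  Reports the per-timepoint
#' total and the maximum relative deviation from the initial total.
#'
#' @param tc a [TimeCourse-class] containing columns `TCE`, `cDCE`, `VC`
#'   and `ethene` (µmol/bottle).
#' @return list with `total` (µmol per timepoint) and `max_deviation`
#'   (max |total - total0| / total0).
#' @export
chloroetheneClosure <- function(tc) {
  stopifnot(is(tc, "TimeCourse"))
  need <- c("TCE", "cDCE", "VC", "ethene")
  if (length(tc@time) == 0L)
    stop("empty time course", call. = FALSE)
  missing <- setdiff(need, colnames(tc@amounts))
  if (length(missing))
    stop("time course lacks species: ", paste(missing, collapse = ", "),
         call. = FALSE)
  total <- rowSums(tc@amounts[, need, drop = FALSE])
  t0 <- total[1L]
  if (t0 <= 0)
    stop("initial chloroethene total is zero", call. = FALSE)
  list(total = unname(total),
       max_deviation = max(abs(total - t0)) / t0)
}

#' Cumulative gas dose up to a time
#'
#' @param ds a [DoseSchedule-class].
#' @param until cutoff in days (default `Inf`: whole schedule); doses at
#'   exactly `until` are included.
#' @return list with `ml` and `umol` totals of doses with time <= `until`.
#' @examples
#' cumulativeDose(doseSchedule(seq(0, 144, by = 12), 2))   # 13 doses, 26 mL
#' @export
cumulativeDose <- function(ds, until = Inf) {
  stopifnot(is(ds, "DoseSchedule"))
  sel <- ds@time_d <= until
  ml <- sum(ds@volume_ml[sel])
  list(ml = ml, umol = gasVolumeToUmol(ml, ds@molar_volume, digits = NULL))
}

#' Growth fold change
#'
#' @param initial initial cell density, cells/mL (> 0).
#' @param final final cell density, cells/mL.
#' @param digits decimals (half-up; `NULL` for full precision).
#' @return final/initial ratio.
#' @examples
#' foldChange(3.6e5, 1.5e8)   # 416.7
#' @export
foldChange <- function(initial, final, digits = 1) {
  if (any(initial <= 0)) stop("initial count must be > 0", call. = FALSE)
  fc <- final / initial
  if (is.null(digits)) fc else roundHalfUp(fc, digits)
}
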