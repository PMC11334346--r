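#' Accessors for COdechlor classes
#'
#' Small accessor generics so user code never reaches into slots.
#'
#' @param object an object of the documented class.
#' @param x an object of the documented class.
#' @param name a species or compound name.
#' @return The slot contents documented for each method.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("compoundName", function(object) standardGeneric("compoundName"))
#' @rdname accessors
#' @export
setGeneric("elementCounts", function(object) standardGeneric("elementCounts"))
#' @rdname accessors
#' @export
setGeneric("phase", function(object) standardGeneric("phase"))
#' @rdname accessors
#' @export
setGeneric("formationEnergy", function(object) standardGeneric("formationEnergy"))
#' @rdname accessors
#' @export
setGeneric("stoich", function(object) standardGeneric("stoich"))
#' @rdname accessors
#' @export
setGeneric("deltaG", function(object) standardGeneric("deltaG"))
#' @rdname accessors
#' @export
setGeneric("getCompound", function(x, name) standardGeneric("getCompound"))
#' @rdname accessors
#' @export
setGeneric("compoundNames", function(x) standardGeneric("compoundNames"))
#' @rdname accessors
#' @export
setGeneric("substrates", function(object) standardGeneric("substrates"))
#' @rdname accessors
#' @export
setGeneric("products", function(object) standardGeneric("products"))
#' @rdname accessors
#' @export
setGeneric("residualAmounts", function(object) standardGeneric("residualAmounts"))
#' @rdname accessors
#' @export
setGeneric("speciesAmounts", function(object) standardGeneric("speciesAmounts"))
#' @rdname accessors
#' @export
setGeneric("timepoints", function(object) standardGeneric("timepoints"))
#' @rdname accessors
#' @export
setGeneric("truth", function(object) standardGeneric("truth"))
#' @rdname accessors
#' @export
setGeneric("noisy", function(object) standardGeneric("noisy"))
#' @rdname accessors
#' @export
setGeneric("fluxes", function(object) standardGeneric("fluxes"))
#' @rdname accessors
#' @export
setGeneric("finalBalance", function(object) standardGeneric("finalBalance"))

setMethod("compoundName", "Compound", function(object) object@name)
setMethod("elementCounts", "Compound", function(object) object@formula)
setMethod("phase", "Compound", function(object) object@phase)
setMethod("formationEnergy", "Compound", function(object) object@dfG)

setMethod("stoich", "Reaction", function(object) object@stoich)
setMethod("deltaG", "Reaction", function(object) object@dG)

setMethod("compoundNames", "CompoundRegistry", function(x) names(x@compounds))
setMethod("getCompound", "CompoundRegistry", function(x, name) {
  stopifnot(is.character(name), length(name) == 1L)
  key <- if (name %in% names(x@compounds)) name else unname(x@aliases[name])
  if (is.na(key) || is.null(key) || !key %in% names(x@compounds))
    stop("unknown compound: '", name, "'", call. = FALSE)
  x@compounds[[key]]
})

setMethod("substrates", "BottleBalance", function(object) object@substrates)
setMethod("products", "BottleBalance", function(object) object@products)
setMethod("residualAmounts", "BottleBalance", function(object) object@residuals)

setMethod("timepoints", "TimeCourse", function(object) object@time)
setMethod("speciesAmounts", "TimeCourse", function(object) object@amounts)

setMethod("truth", "SimResult", function(object) object@truth)
setMethod("noisy", "SimResult", function(object) object@noisy)
setMethod("fluxes", "SimResult", function(object) object@fluxes)
setMethod("finalBalance", "SimResult", function(object) object@balance)

setMethod("show", "Compound", function(object) {
  cat("Compound:", object@name, "\n")
  cat("  formula:", writeFormula(object@formula),
      " phase:", object@phase, "\n")
  if (!is.na(object@dfG))
    cat("  dfG':", format(object@dfG), "kJ/mol\n")
  invisible(NULL)
})

setMethod("show", "CompoundRegistry", function(object) {
  cat("CompoundRegistry with", length(object@compounds), "compounds\n")
  cat(" ", paste(names(object@compounds), collapse = ", "), "\n")
  if (length(object@aliases))
    cat("  aliases:", paste(names(object@aliases), collapse = ", "), "\n")
  invisible(NULL)
})

setMethod("show", "Reaction", function(object) {
  cat("Reaction:", object@name, "\n  ", reactionEquation(object), "\n")
  if (!is.na(object@dG))
    cat("  deltaG'° =", format(round(object@dG, 1), nsmall = 1), "kJ/mol\n")
  invisible(NULL)
})

setMethod("show", "BottleBalance", function(object) {
  cat("BottleBalance:", object@treatment, "\n")
  fmt <- function(v) paste(sprintf("%s %.1f", names(v), v), collapse = ", ")
  cat("  substrates (µmol):", fmt(object@substrates), "\n")
  cat("  products   (µmol):", fmt(object@products), "\n")
  if (length(object@residuals))
    cat("  residuals  (µmol):", fmt(object@residuals), "\n")
  invisible(NULL)
})

setMethod("show", "DoseSchedule", function(object) {
  cat("DoseSchedule:", length(object@time_d), "doses,",
      sum(object@volume_ml), "mL total",
      sprintf("(%.1f µmol at %.1f L/mol)\n",
              1000 * sum(object@volume_ml) / object@molar_volume,
              object@molar_volume))
  invisible(NULL)
})

setMethod("show", "TimeCourse", function(object) {
  cat("TimeCourse:", length(object@time), "timepoints over",
      if (length(object@time)) max(object@time) else 0, "days;",
      ncol(object@amounts), "species\n")
  cat("  species:", paste(colnames(object@amounts), collapse = ", "), "\n")
  invisible(NULL)
})

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig: TCE0 =", object@tce0, "µmol;",
      length(object@doses@time_d), "CO doses (",
      sum(object@doses@volume_ml), "mL );",
      "noise_sd =", object@noise_sd, "; seed =", object@seed, "\n")
  invisible(NULL)
})

setMethod("show", "SimResult", function(object) {
  cat("SimResult (seed", object@config@seed, ")\n")
  show(object@truth)
  cat("  cumulative reaction extents (µmol):\n")
  print(round(object@fluxes, 2))
  invisible(NULL)
})
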