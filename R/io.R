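#' Read per-bottle balances from a measurement CSV
#'
#' Expected columns: `treatment`, `role` (one of `substrate`, `product`,
#' `residual`), `species`, `umol`.  One [BottleBalance-class] is built per
#' treatment.  Malformed rows are reported with their line numbers.
#'
#' @param file path to the CSV.
#' @param registry compound registry resolving species names.
#' @return named list of [BottleBalance-class] objects, one per treatment
#'   in file order.
#' @export
readBottleBalances <- function(file, registry = compoundRegistry()) {
  tab <- utils::read.csv(file, stringsAsFactors = FALSE)
  if (nrow(tab) == 0L) stop("no records in '", file, "'", call. = FALSE)
  need <- c("treatment", "role", "species", "umol")
  if (!all(need %in% names(tab)))
    stop("measurement CSV must have columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  errs <- character()
  for (i in seq_len(nrow(tab))) {
    line <- i + 1L  # header is line 1
    if (!tab$role[i] %in% c("substrate", "product", "residual"))
      errs <- c(errs, sprintf("line %d: bad role '%s'", line, tab$role[i]))
    ok <- tryCatch({ getCompound(registry, tab$species[i]); TRUE },
                   error = function(e) FALSE)
    if (!ok)
      errs <- c(errs, sprintf("line %d: unknown species '%s'", line,
                              tab$species[i]))
    if (is.na(suppressWarnings(as.numeric(tab$umol[i]))) ||
        as.numeric(tab$umol[i]) < 0)
      errs <- c(errs, sprintf("line %d: bad amount '%s'", line, tab$umol[i]))
  }
  if (length(errs))
    stop("invalid measurement rows:\n  ", paste(errs, collapse = "\n  "),
         call. = FALSE)
  tab$umol <- as.numeric(tab$umol)
  out <- lapply(unique(tab$treatment), function(tr) {
    sub <- tab[tab$treatment == tr, ]
    pick <- function(role) {
      r <- sub[sub$role == role, ]
      setNames(r$umol, r$species)
    }
    bottleBalance(tr, substrates = pick("substrate"),
                  products = pick("product"),
                  residuals = pick("residual"), registry = registry)
  })
  names(out) <- unique(tab$treatment)
  out
}

#' Read reactions from a plain-text reaction file
#'
#' One reaction per line in the grammar of [parseReaction()]; blank lines
#' and `#` comments are skipped.
#'
#' @param file path to the reaction file.
#' @param registry compound registry.
#' @return named list of [Reaction-class] objects.
#' @export
readReactions <- function(file, registry = compoundRegistry()) {
  lines <- readLines(file, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) stop("no reactions in '", file, "'", call. = FALSE)
  out <- lapply(lines, parseReaction, registry = registry)
  names(out) <- vapply(out, function(r) r@name, character(1))
  out
}

#' Read a dose schedule CSV
#'
#' Expected columns: `time_d`, `volume_ml`.
#'
#' @param file path to the CSV.
#' @param molar_volume L/mol (default 24.5).
#' @return a [DoseSchedule-class].
#' @export
readDoseSchedule <- function(file, molar_volume = 24.5) {
  tab <- utils::read.csv(file, stringsAsFactors = FALSE)
  if (!all(c("time_d", "volume_ml") %in% names(tab)))
    stop("dose CSV must have columns time_d, volume_ml", call. = FALSE)
  tab <- tab[order(tab$time_d), ]
  doseSchedule(tab$time_d, tab$volume_ml, molar_volume)
}

#' Write a time course to long-format CSV
#'
#' Columns `bottle_id`, `time_d`, `species`, `amount`, `unit`.
#'
#' @param tc a [TimeCourse-class].
#' @param file output path.
#' @param bottle_id identifier written into the first column.
#' @return the file path, invisibly.
#' @export
writeTimeCourse <- function(tc, file, bottle_id = "bottle1") {
  stopifnot(is(tc, "TimeCourse"))
  long <- data.frame(
    bottle_id = bottle_id,
    time_d = rep(tc@time, times = ncol(tc@amounts)),
    species = rep(colnames(tc@amounts), each = length(tc@time)),
    amount = as.vector(tc@amounts),
    unit = rep(unname(tc@units[colnames(tc@amounts)]),
               each = length(tc@time))
  )
  utils::write.csv(long, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Read a long-format time-course CSV
#'
#' @param file path written by [writeTimeCourse()] (columns `bottle_id`,
#'   `time_d`, `species`, `amount`, `unit`).
#' @param bottle_id which bottle to extract (default: the first).
#' @return a [TimeCourse-class].
#' @export
readTimeCourse <- function(file, bottle_id = NULL) {
  tab <- utils::read.csv(file, stringsAsFactors = FALSE)
  need <- c("bottle_id", "time_d", "species", "amount", "unit")
  if (!all(need %in% names(tab)))
    stop("time-course CSV must have columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  if (is.null(bottle_id)) bottle_id <- tab$bottle_id[1L]
  tab <- tab[tab$bottle_id == bottle_id, ]
  species <- unique(tab$species)
  times <- sort(unique(tab$time_d))
  m <- matrix(NA_real_, nrow = length(times), ncol = length(species),
              dimnames = list(NULL, species))
  for (sp in species) {
    sub <- tab[tab$species == sp, ]
    m[match(sub$time_d, times), sp] <- sub$amount
  }
  units <- tapply(tab$unit, tab$species, function(u) u[1L])
  timeCourse(times, m, units = setNames(as.character(units), names(units)))
}

#' Hess-law consistency checks on the reaction ledger
#'
#' Verifies that the three composite rows of the built-in ledger are the
#' stated linear combinations of the elementary rows:
#' `acetogenesis_co = 4 wgs + acetogenesis_h2`,
#' `methanogenesis_ac = methanogenesis_h2 - acetogenesis_h2`, and
#' `methanogenesis_co = 4 wgs + methanogenesis_h2` -- both in
#' stoichiometry and in Gibbs energy.
#'
#' @param reactions the ledger, as from [referenceReactions()].
#' @param tol_kJ tolerance on the Gibbs-energy comparison (default 0.05).
#' @return data.frame with one row per check: `target`, `combination`,
#'   `dG_target`, `dG_combined`, `stoich_match`, `dG_match`.
#' @export
hessChecks <- function(reactions = referenceReactions(), tol_kJ = 0.05) {
  combos <- list(
    acetogenesis_co = list(c(4, 1), c("wgs", "acetogenesis_h2")),
    methanogenesis_ac = list(c(1, -1),
                             c("methanogenesis_h2", "acetogenesis_h2")),
    methanogenesis_co = list(c(4, 1), c("wgs", "methanogenesis_h2"))
  )
  rows <- lapply(names(combos), function(target) {
    mult <- combos[[target]][[1]]
    parts <- combos[[target]][[2]]
    comb <- combineReactions(Map(function(m, nm) list(m, reactions[[nm]]),
                                 mult, parts), name = target)
    tgt <- reactions[[target]]
    sameSpecies <- setequal(names(comb@stoich), names(tgt@stoich))
    stoichOK <- sameSpecies &&
      all(abs(comb@stoich[names(tgt@stoich)] - tgt@stoich) < 1e-9)
    data.frame(
      target = target,
      combination = paste(sprintf("%+g %s", mult, parts), collapse = " "),
      dG_target = tgt@dG, dG_combined = comb@dG,
      stoich_match = stoichOK,
      dG_match = abs(comb@dG - tgt@dG) <= tol_kJ,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Run the recovery-report pipeline over a measurement CSV
#'
#' Reads per-bottle inventories, computes carbon and electron recoveries
#' per treatment, and (optionally) writes a TSV report in the layout of
#' the published recovery table plus the underlying in/out totals.
#'
#' @param input path to the measurement CSV (see [readBottleBalances()]).
#' @param output optional path for the TSV report.
#' @param includeCO2,includeResiduals see [balanceReport()].
#' @param registry compound registry.
#' @return data.frame of the report, invisibly when `output` is given.
#' @export
runBalance <- function(input, output = NULL, includeCO2 = FALSE,
                       includeResiduals = FALSE,
                       registry = compoundRegistry()) {
  bottles <- readBottleBalances(input, registry)
  rows <- lapply(bottles, function(b) {
    rep <- balanceReport(b, includeCO2 = includeCO2,
                         includeResiduals = includeResiduals)
    data.frame(
      treatment = rep$treatment,
      carbon_recovery_pct = rep$carbon_recovery_pct,
      electron_recovery_pct = rep$electron_recovery_pct,
      carbon_in_umol = rep$carbon_in, carbon_out_umol = rep$carbon_out,
      electrons_in_umol = rep$electrons_in,
      electrons_out_umol = rep$electrons_out,
      stringsAsFactors = FALSE
    )
  })
  report <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (!is.null(output)) {
    utils::write.table(report, output, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    return(invisible(report))
  }
  report
}

#' Run the reaction-ledger pipeline
#'
#' Audits every reaction for elemental/charge/electron balance, attaches
#' the ledger Gibbs energy and, where the constants allow, the value
#' recomputed from formation energies, and runs the Hess-consistency
#' checks.  Optionally writes the ledger as TSV.
#'
#' @param reactions a reaction list (default [referenceReactions()]) or a
#'   path to a reaction text file (see [readReactions()]).
#' @param output optional path for the TSV report.
#' @param registry compound registry (also the formation-energy source).
#' @return list with `ledger` (data.frame: name, equation, deltaG ledger
#'   and recomputed, balanced flag) and `hess` (data.frame from
#'   [hessChecks()]; only when the standard ledger names are present).
#' @export
runLedger <- function(reactions = referenceReactions(), output = NULL,
                      registry = compoundRegistry()) {
  if (is.character(reactions)) reactions <- readReactions(reactions, registry)
  rows <- vector("list", length(reactions))
  for (i in seq_along(reactions)) {
    r <- reactions[[i]]
    aud <- auditBalance(r)
    recomputed <- tryCatch(deltaGStandard(r, registry),
                           error = function(e) NA_real_)
    # reactions loaded from a plain equation file carry no energy; back
    # them with the recomputed value so the Hess checks can run
    if (is.na(r@dG) && !is.na(recomputed)) {
      r@dG <- round(recomputed, 1)
      reactions[[i]] <- r
    }
    rows[[i]] <- data.frame(
      name = r@name, equation = reactionEquation(r),
      dG_ledger_kJ = r@dG, dG_recomputed_kJ = round(recomputed, 1),
      balanced = aud$balanced, stringsAsFactors = FALSE
    )
  }
  ledger <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  std <- c("wgs", "acetogenesis_h2", "acetogenesis_co", "methanogenesis_ac",
           "methanogenesis_h2", "methanogenesis_co")
  hess <- if (all(std %in% names(reactions))) hessChecks(reactions) else NULL
  if (!is.null(output))
    utils::write.table(ledger, output, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  list(ledger = ledger, hess = hess)
}
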