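## CSV serialisation of simulation outputs and the reproducibility manifest.

## small FNV-1a hash over the deparsed configuration, for the manifest
.config_hash <- function(config) {
  txt <- paste(deparse(unclass(config)[.config_fields]), collapse = "")
  bytes <- utf8ToInt(txt)
  h <- 2166136261
  for (b in bytes) h <- (bitwXor(as.integer(h %% 2^31), b) * 16777619) %% 2^31
  sprintf("%08x", as.integer(h))
}

#' Run manifest
#'
#' A small record sufficient to reproduce every output file of a run
#' bit-for-bit: package version, comparison case, simulation count,
#' correlation levels, master seed, and a hash plus full copy of the
#' configuration.
#'
#' @param object a `"psi_sim"` object.
#' @return A named list; serialise with [write_manifest()].
#' @export
run_manifest <- function(object) {
  stopifnot(inherits(object, "psi_sim"))
  list(package = "psisim",
       version = as.character(utils::packageVersion("psisim")),
       case = object$case, n_sims = object$n_sims, rho = object$rho,
       seed = object$seed,
       config_hash = .config_hash(object$config),
       config = unclass(object$config)[.config_fields],
       created = format(Sys.time(), tz = "UTC", usetz = TRUE))
}

#' @rdname run_manifest
#' @param path output path for the JSON manifest.
#' @export
write_manifest <- function(object, path) {
  jsonlite::write_json(run_manifest(object), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Export the headline summary table
#'
#' Writes the per-correlation summary in the published layout: one row per
#' (output measure, correlation level), columns for the PSI-absent and
#' PSI-active scenarios. Measures: average total cost (currency millions),
#' average total benefit (thousands), average number of interventions
#' funded, expected ICER per funding cycle (vs doing nothing, thousands of
#' currency per benefit unit), and the expected NHB of the active scenario
#' (active column only).
#'
#' @param object a `"psi_sim"` or `"summary.psi_sim"` object.
#' @param path output CSV path.
#' @return The path, invisibly.
#' @export
export_summary <- function(object, path) {
  s <- if (inherits(object, "psi_sim")) summary(object) else object
  stopifnot(inherits(s, "summary.psi_sim"))
  cfg <- s$config
  tab <- s$table
  measure <- c(
    sprintf("Average total cost (%s M)", cfg$currency),
    sprintf("Average total %s (thousands)", cfg$benefit_unit),
    "Average number of interventions funded",
    "Expected ICER per funding cycle",
    sprintf("Expected NHB (thousand %ss per funding cycle)", cfg$benefit_unit))
  rows <- do.call(rbind, lapply(seq_len(5L), function(m) {
    data.frame(measure = measure[m], correlation = tab$rho,
               absent = switch(m, tab$cf_cost, tab$cf_benefit, tab$cf_count,
                               tab$cf_icer, NA_real_),
               active = switch(m, tab$act_cost, tab$act_benefit,
                               tab$act_count, tab$act_icer, tab$nhb))
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Export per-simulation records
#'
#' One row per (correlation level, simulation): both scenarios' totals,
#' the cost and benefit increments, NHB, ICER and sign quadrant -- the data
#' behind the cost-effectiveness-plane scatter plots.
#'
#' @param object a `"psi_sim"` object.
#' @param path output CSV path.
#' @return The path, invisibly.
#' @export
export_records <- function(object, path) {
  stopifnot(inherits(object, "psi_sim"))
  utils::write.csv(object$records, path, row.names = FALSE)
  invisible(path)
}

#' Export quadrant classification tables
#'
#' Per correlation level, the percentage of simulations in each sign
#' quadrant of (cost increment, benefit increment), with row, column and
#' grand totals (grand total 100).
#'
#' @param object a `"psi_sim"` or `"summary.psi_sim"` object.
#' @param path output CSV path.
#' @return The path, invisibly.
#' @export
export_quadrants <- function(object, path) {
  s <- if (inherits(object, "psi_sim")) summary(object) else object
  stopifnot(inherits(s, "summary.psi_sim"))
  rows <- do.call(rbind, lapply(names(s$quadrants), function(r) {
    q <- s$quadrants[[r]]
    data.frame(correlation = as.numeric(r),
               cost_increment = c(">=0", "<0", "Totals"),
               benefit_down = c(q[, "<0"], sum(q[, "<0"])),
               benefit_up = c(q[, ">=0"], sum(q[, ">=0"])),
               totals = c(rowSums(q), sum(q)))
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Write all outputs of a run
#'
#' Writes `summary.csv`, `records.csv`, `quadrants.csv` and
#' `manifest.json` into a directory.
#'
#' @param object a `"psi_sim"` object.
#' @param dir output directory (created if needed).
#' @return The directory, invisibly.
#' @export
export_run <- function(object, dir) {
  stopifnot(inherits(object, "psi_sim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  export_summary(object, file.path(dir, "summary.csv"))
  export_records(object, file.path(dir, "records.csv"))
  export_quadrants(object, file.path(dir, "quadrants.csv"))
  write_manifest(object, file.path(dir, "manifest.json"))
  invisible(dir)
}
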