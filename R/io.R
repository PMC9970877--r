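# Plain-text interchange: long-format trace CSV, events CSV, activity
# pattern CSV + hyperparameter JSON.

#' Read and write the long-format trace and events tables
#'
#' Traces: `cell_id`, `time_min`, channel columns, `R_major_um`,
#' `r_minor_um`, `bud_R_major_um`, `bud_r_minor_um`. Events: `cell_id`,
#' `event` (ME/START/BUD/KARYO), `time_min`, optional `source`
#' (auto/manual).
#'
#' @param path CSV file path.
#' @param x data.frame to write.
#' @return data.frame (readers) or invisible path (writers).
#' @export
read_traces <- function(path) utils::read.csv(path)

#' @rdname read_traces
#' @export
write_traces <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' @rdname read_traces
#' @export
read_events <- function(path) {
  ev <- utils::read.csv(path)
  stopifnot(all(c("cell_id", "event", "time_min") %in% names(ev)))
  ev
}

#' @rdname read_traces
#' @export
write_events <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' Write an activity pattern as CSV plus hyperparameter JSON
#'
#' @param pattern a `cycleflux_activity` from [fit_phase_gp()].
#' @param csv_path,json_path output paths (either may be `NULL`).
#' @return invisible list of paths.
#' @export
write_activity_pattern <- function(pattern, csv_path = NULL,
                                   json_path = NULL) {
  if (!is.null(csv_path))
    utils::write.csv(data.frame(phase = pattern$phase,
                                mean = pattern$mean, sd = pattern$sd),
                     csv_path, row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(list(
      hyperparameters = as.list(pattern$hyperparameters),
      log_marginal_likelihood = pattern$log_marginal_likelihood,
      n = pattern$n), json_path, auto_unbox = TRUE, digits = NA)
  invisible(list(csv = csv_path, json = json_path))
}
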