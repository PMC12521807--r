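# File readers and writers for the formats the pipeline consumes/emits.

#' Read / write individual patient data CSV
#'
#' Columns `time,event` (header required), one row per subject.
#'
#' @param path CSV path.
#' @param records IPD `data.frame(time, event)`.
#' @return `read_ipd`: the validated records; `write_ipd`: `path`,
#'   invisibly.
#' @export
read_ipd <- function(path) {
  df <- read.csv(path)
  if (!all(c("time", "event") %in% names(df))) {
    stop("IPD CSV must have columns 'time' and 'event'")
  }
  ipd_records(df$time, df$event)
}

#' @rdname read_ipd
#' @export
write_ipd <- function(records, path) {
  write.csv(records[, c("time", "event")], path, row.names = FALSE)
  invisible(path)
}

#' Read a digitised-curve CSV
#'
#' Columns `time,survival`; cohort size is supplied separately (it is not
#' part of the digitised coordinates).
#'
#' @param path CSV path.
#' @param total_n Cohort size behind the curve.
#' @return A [digitized_curve()].
#' @export
read_digitized <- function(path, total_n) {
  df <- read.csv(path)
  if (!all(c("time", "survival") %in% names(df))) {
    stop("digitised-curve CSV must have columns 'time' and 'survival'")
  }
  digitized_curve(df$time, df$survival, total_n)
}

#' Write a digitised curve to CSV
#'
#' @param curve A [digitized_curve()].
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_digitized <- function(curve, path) {
  write.csv(curve$points, path, row.names = FALSE)
  invisible(path)
}

#' Write a model-selection report
#'
#' @param model A [select_model()] winner (carries the ranking attribute).
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_selection_report <- function(model, path) {
  ranking <- attr(model, "ranking")
  if (is.null(ranking)) stop("model carries no ranking table (use select_model())")
  write.csv(ranking, path, row.names = FALSE)
  invisible(path)
}
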