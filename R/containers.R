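#' Parcellated BOLD time series
#'
#' One subject's region-by-time matrix of BOLD signal with its repetition time.
#' Rows are parcellation regions in canonical order; columns are volumes.
#'
#' @param data Numeric matrix, regions x timepoints.
#' @param tr_seconds Repetition time in seconds.
#' @param region_ids Ordered region identifiers; defaults to existing rownames
#'   or `R001..Rnnn`.
#' @param subject_id Optional subject identifier.
#' @return A `parcel_ts` object.
#' @examples
#' ts <- parcel_ts(matrix(rnorm(20), 4, 5), tr_seconds = 3)
#' dim(ts$data)
#' @export
parcel_ts <- function(data, tr_seconds, region_ids = NULL, subject_id = NA_character_) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (nrow(data) < 2L)
    abort_ignitr("a parcellated series needs at least 2 regions",
                 "ignitr_validation_error")
  if (any(!is.finite(data)))
    abort_ignitr("time series contains non-finite values",
                 "ignitr_validation_error")
  if (!(is.numeric(tr_seconds) && length(tr_seconds) == 1L && tr_seconds > 0))
    abort_ignitr("tr_seconds must be a positive scalar",
                 "ignitr_validation_error")
  if (is.null(region_ids)) {
    region_ids <- rownames(data)
    if (is.null(region_ids))
      region_ids <- sprintf("R%03d", seq_len(nrow(data)))
  }
  if (length(region_ids) != nrow(data))
    abort_ignitr("region_ids must match the number of rows",
                 "ignitr_validation_error")
  rownames(data) <- region_ids
  structure(list(data = data, tr_seconds = as.numeric(tr_seconds),
                 region_ids = as.character(region_ids),
                 subject_id = as.character(subject_id)),
            class = "parcel_ts")
}

#' @export
print.parcel_ts <- function(x, ...) {
  cat(sprintf("Parcellated BOLD series: %d regions x %d volumes, TR = %g s",
              nrow(x$data), ncol(x$data), x$tr_seconds))
  if (!is.na(x$subject_id)) cat(sprintf(" [%s]", x$subject_id))
  cat("\n")
  invisible(x)
}

#' Binary event raster
#'
#' Region-by-time binary matrix of threshold-crossing (driving) events,
#' together with the threshold that produced it.
#'
#' @param events Binary (0/1 or logical) matrix, regions x timepoints.
#' @param theta Threshold in z-score units.
#' @param tr_seconds Repetition time in seconds.
#' @param region_ids Ordered region identifiers.
#' @return An `event_raster` object.
#' @export
event_raster <- function(events, theta, tr_seconds = NA_real_, region_ids = NULL) {
  events <- as.matrix(events)
  if (is.logical(events)) storage.mode(events) <- "integer"
  if (anyNA(events) || any(events != 0L & events != 1L))
    abort_ignitr("event raster entries must be 0/1", "ignitr_validation_error")
  storage.mode(events) <- "integer"
  if (is.null(region_ids)) {
    region_ids <- rownames(events)
    if (is.null(region_ids))
      region_ids <- sprintf("R%03d", seq_len(nrow(events)))
  }
  rownames(events) <- region_ids
  structure(list(events = events, theta = as.numeric(theta),
                 tr_seconds = as.numeric(tr_seconds),
                 region_ids = as.character(region_ids)),
            class = "event_raster")
}

#' @export
print.event_raster <- function(x, ...) {
  cat(sprintf("Event raster: %d regions x %d TRs, theta = %g z, %d events\n",
              nrow(x$events), ncol(x$events), x$theta, sum(x$events)))
  invisible(x)
}
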