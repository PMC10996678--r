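# Tabular interchange. All tables are TSV with a one-line header; region order
# is the canonical alignment key. Numeric cells are written with 17 significant
# digits so a write/read round trip is bitwise lossless.

fmt_num <- function(x) sprintf("%.17g", x)

#' Read a parcellated time-series table
#'
#' TSV with header `region_id  t1 ... tN`; one row per region, columns are
#' volumes. The repetition time is not stored in the table and must be
#' supplied.
#'
#' @param path File path.
#' @param tr_seconds Repetition time in seconds.
#' @param subject_id Optional subject identifier.
#' @return A [parcel_ts()] with region identifiers in input order.
#' @export
read_timeseries <- function(path, tr_seconds, subject_id = NA_character_) {
  widths <- utils::count.fields(path, sep = "\t", quote = "")
  if (length(unique(widths)) > 1L)
    abort_ignitr(sprintf("%s: ragged rows (field counts %s)", path,
                         paste(unique(widths), collapse = "/")),
                 "ignitr_format_error")
  raw <- utils::read.delim(path, colClasses = "character",
                           check.names = FALSE)
  if (!"region_id" %in% names(raw))
    abort_ignitr(sprintf("%s: missing region_id column", path),
                 "ignitr_format_error")
  ids <- raw$region_id
  cells <- as.matrix(raw[, setdiff(names(raw), "region_id"), drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(cells), nrow(cells), ncol(cells)))
  bad <- which(is.na(num) | cells == "NA", arr.ind = TRUE)
  if (nrow(bad))
    abort_ignitr(sprintf(
      "%s: non-numeric or missing cell at row %s (region %s), column %s",
      path, bad[1, 1], ids[bad[1, 1]], colnames(cells)[bad[1, 2]]),
      "ignitr_data_error")
  parcel_ts(num, tr_seconds, region_ids = ids, subject_id = subject_id)
}

#' Write a parcellated time-series table
#'
#' @param series A [parcel_ts()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(series, path) {
  stopifnot(inherits(series, "parcel_ts"))
  m <- series$data
  header <- c("region_id", sprintf("t%d", seq_len(ncol(m))))
  lines <- vapply(seq_len(nrow(m)), function(i)
    paste(c(series$region_ids[i], fmt_num(m[i, ])), collapse = "\t"),
    character(1))
  writeLines(c(paste(header, collapse = "\t"), lines), path)
  invisible(path)
}

#' Read a regional burden table
#'
#' TSV with columns `region_id`, `abeta`, `tau` (and optionally
#' `metastability` for synthetic tables). When `region_ids` is given the rows
#' are aligned to that parcellation order; missing regions raise an alignment
#' error naming them.
#'
#' @param path File path.
#' @param region_ids Optional canonical region order to align against.
#' @return Data frame with positive SUVR columns in parcellation order.
#' @export
read_burden_table <- function(path, region_ids = NULL) {
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  need <- c("region_id", "abeta", "tau")
  if (!all(need %in% names(tab)))
    abort_ignitr(sprintf("%s: required columns %s", path,
                         paste(need, collapse = ", ")),
                 "ignitr_format_error")
  if (!is.null(region_ids)) {
    missing <- setdiff(region_ids, tab$region_id)
    if (length(missing))
      abort_ignitr(sprintf("%s: regions absent from burden table: %s", path,
                           paste(missing, collapse = ", ")),
                   "ignitr_alignment_error")
    tab <- tab[match(region_ids, tab$region_id), , drop = FALSE]
    rownames(tab) <- NULL
  }
  if (any(tab$abeta <= 0) || any(tab$tau <= 0))
    abort_ignitr(sprintf("%s: SUVR values must be positive", path),
                 "ignitr_data_error")
  tab
}

#' Write a regional burden table
#' @param table Data frame with `region_id`, `abeta`, `tau` (and optional
#'   further numeric columns).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_burden_table <- function(table, path) {
  numcols <- setdiff(names(table), "region_id")
  lines <- vapply(seq_len(nrow(table)), function(i)
    paste(c(table$region_id[i],
            vapply(numcols, function(cn) fmt_num(table[[cn]][i]), character(1))),
          collapse = "\t"), character(1))
  writeLines(c(paste(c("region_id", numcols), collapse = "\t"), lines), path)
  invisible(path)
}

#' Read a centroid table
#'
#' TSV with columns `region_id`, `x`, `y`, `z` in millimetres.
#' @param path File path.
#' @return Data frame.
#' @export
read_centroids <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("region_id", "x", "y", "z")
  if (!all(need %in% names(tab)))
    abort_ignitr(sprintf("%s: required columns %s", path,
                         paste(need, collapse = ", ")), "ignitr_format_error")
  tab
}

#' Read an RSN label table
#'
#' TSV with columns `region_id`, `rsn`.
#' @param path File path.
#' @return Named character vector of labels.
#' @export
read_rsn_labels <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!all(c("region_id", "rsn") %in% names(tab)))
    abort_ignitr(sprintf("%s: required columns region_id, rsn", path),
                 "ignitr_format_error")
  stats::setNames(as.character(tab$rsn), tab$region_id)
}

#' Write an ignition profile
#' @param profile An `ignition_profile`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  utils::write.table(as.data.frame(profile), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
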