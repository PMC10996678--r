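#' Analysis configuration
#'
#' Bundles every tunable parameter of the ignition pipeline in one validated
#' object. Defaults follow the study design this package models: a point-process
#' threshold of 1 z-unit, a 4-TR propagation window, 10,000 label permutations
#' at alpha = 0.05 with FDR control at q = 0.05, 10 mRMR-selected features,
#' k-nearest-neighbour tuning over k = 2..5, and a 0.01-0.09 Hz band-pass.
#'
#' @param threshold_theta Event-detection threshold, in z-score units. A
#'   region emits a driving event when its z-scored BOLD signal crosses this
#'   value from below.
#' @param window_trs Width of the propagation window in TRs, inclusive of the
#'   triggering TR.
#' @param n_permutations Number of Monte-Carlo label permutations per group
#'   comparison.
#' @param alpha Two-sided significance level.
#' @param fdr_q Benjamini-Hochberg false-discovery-rate level.
#' @param n_features Number of features retained by mRMR selection.
#' @param k_range Inclusive integer range of neighbour counts tuned by the
#'   classifier's inner loop.
#' @param seed Master seed; every stochastic stage derives its own substream
#'   from it.
#' @param band_low_hz,band_high_hz Band-pass edges in Hz. Must satisfy
#'   0 < low < high < Nyquist for the series' TR.
#' @return A `study_config` object (a validated named list).
#' @examples
#' cfg <- study_config(seed = 1)
#' cfg$window_trs
#' @export
study_config <- function(threshold_theta = 1.0,
                         window_trs = 4L,
                         n_permutations = 10000L,
                         alpha = 0.05,
                         fdr_q = 0.05,
                         n_features = 10L,
                         k_range = 2:5,
                         seed = 1L,
                         band_low_hz = 0.01,
                         band_high_hz = 0.09) {
  cfg <- list(
    threshold_theta = as.numeric(threshold_theta),
    window_trs = as.integer(window_trs),
    n_permutations = as.integer(n_permutations),
    alpha = as.numeric(alpha),
    fdr_q = as.numeric(fdr_q),
    n_features = as.integer(n_features),
    k_range = as.integer(k_range),
    seed = as.integer(seed),
    band_low_hz = as.numeric(band_low_hz),
    band_high_hz = as.numeric(band_high_hz)
  )
  if (cfg$window_trs < 1L)
    abort_ignitr("window_trs must be >= 1", "ignitr_parameter_error")
  if (cfg$n_permutations < 1L)
    abort_ignitr("n_permutations must be >= 1", "ignitr_parameter_error")
  if (!(cfg$alpha > 0 && cfg$alpha < 1) || !(cfg$fdr_q > 0 && cfg$fdr_q < 1))
    abort_ignitr("alpha and fdr_q must lie in (0, 1)", "ignitr_parameter_error")
  if (length(cfg$k_range) < 1L || min(cfg$k_range) < 1L)
    abort_ignitr("k_range must be non-empty with minimum >= 1",
                 "ignitr_parameter_error")
  if (cfg$n_features < 1L)
    abort_ignitr("n_features must be >= 1", "ignitr_parameter_error")
  if (!(cfg$band_low_hz > 0 && cfg$band_low_hz < cfg$band_high_hz))
    abort_ignitr("band edges must satisfy 0 < low < high",
                 "ignitr_parameter_error")
  structure(cfg, class = "study_config")
}

#' @export
print.study_config <- function(x, ...) {
  cat("Ignition analysis configuration\n")
  cat(sprintf("  theta = %g z, window = %d TRs, band = %g-%g Hz\n",
              x$threshold_theta, x$window_trs, x$band_low_hz, x$band_high_hz))
  cat(sprintf("  %d permutations, alpha = %g, FDR q = %g\n",
              x$n_permutations, x$alpha, x$fdr_q))
  cat(sprintf("  classifier: %d mRMR features, k in {%s}\n",
              x$n_features, paste(x$k_range, collapse = ",")))
  cat(sprintf("  seed = %d\n", x$seed))
  invisible(x)
}

#' Cohort manifest
#'
#' Describes the subjects of a study: a unique id, a diagnosis drawn from the
#' closed set HC / MCI / AD, and the on-disk locations of each subject's
#' time-series and burden tables.
#'
#' @param subject_id Character vector of unique subject identifiers.
#' @param diagnosis Character vector, one of `"HC"`, `"MCI"`, `"AD"` per
#'   subject.
#' @param ts_path,burden_path Optional file paths per subject (may be `NA` when
#'   data are passed in memory).
#' @return A `cohort_manifest` data frame.
#' @export
cohort_manifest <- function(subject_id, diagnosis,
                            ts_path = NA_character_,
                            burden_path = NA_character_) {
  subject_id <- as.character(subject_id)
  diagnosis <- as.character(diagnosis)
  if (anyDuplicated(subject_id))
    abort_ignitr("subject ids must be unique", "ignitr_validation_error")
  bad <- setdiff(unique(diagnosis), c("HC", "MCI", "AD"))
  if (length(bad))
    abort_ignitr(paste0("unknown diagnosis label(s): ",
                        paste(bad, collapse = ", ")),
                 "ignitr_validation_error")
  if (length(diagnosis) != length(subject_id))
    abort_ignitr("diagnosis must match subject_id in length",
                 "ignitr_validation_error")
  out <- data.frame(subject_id = subject_id,
                    diagnosis = diagnosis,
                    ts_path = rep_len(as.character(ts_path),
                                      length(subject_id)),
                    burden_path = rep_len(as.character(burden_path),
                                          length(subject_id)),
                    stringsAsFactors = FALSE)
  class(out) <- c("cohort_manifest", "data.frame")
  out
}
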