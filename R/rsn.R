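#' Canonical resting-state network labels
#'
#' The seven cortical systems plus the subcortical marker used throughout the
#' package.
#' @export
RSN_LEVELS <- c("VIS", "SM", "DAT", "SAL", "LIM", "CNT", "DMN", "SUBCORT")

#' Transfer RSN labels by nearest centroid
#'
#' Assigns each target region the resting-state-network label of its
#' Euclidean-nearest source node, with ties resolved towards the lowest source
#' index. Regions named in `subcortical_ids` are labelled `"SUBCORT"` instead
#' and are excluded from RSN-level comparisons downstream.
#'
#' @param target_centroids Data frame with columns `region_id`, `x`, `y`, `z`
#'   (mm) for the analysis parcellation.
#' @param source_centroids Data frame of the same shape for the labelled
#'   source atlas.
#' @param source_labels Character vector of RSN labels, one per source row
#'   (or a data frame with columns `region_id`, `rsn`).
#' @param subcortical_ids Target region ids to label `"SUBCORT"`.
#' @return Named character vector: an RSN label per target region, in target
#'   order.
#' @export
assign_rsn <- function(target_centroids, source_centroids, source_labels,
                       subcortical_ids = character(0)) {
  if (is.data.frame(source_labels)) {
    source_labels <- source_labels$rsn[
      match(source_centroids$region_id, source_labels$region_id)]
  }
  if (nrow(source_centroids) < 1L)
    abort_ignitr("empty source atlas", "ignitr_parameter_error")
  if (length(source_labels) != nrow(source_centroids))
    abort_ignitr("one label per source node required", "ignitr_alignment_error")
  tc <- as.matrix(target_centroids[, c("x", "y", "z")])
  sc <- as.matrix(source_centroids[, c("x", "y", "z")])
  if (any(!is.finite(tc)) || any(!is.finite(sc)))
    abort_ignitr("centroid coordinates must be finite",
                 "ignitr_validation_error")
  # squared Euclidean distances target x source; which.min takes the first
  # (lowest-index) minimum, giving the deterministic tie-break
  d2 <- outer(rowSums(tc^2), rowSums(sc^2), "+") - 2 * tcrossprod(tc, sc)
  labels <- as.character(source_labels)[apply(d2, 1L, which.min)]
  names(labels) <- target_centroids$region_id
  labels[names(labels) %in% subcortical_ids] <- "SUBCORT"
  labels
}
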