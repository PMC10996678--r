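#' Monte-Carlo permutation test for a difference of means
#'
#' Shuffles group labels `n_perm` times and compares the absolute difference
#' of means under shuffling to the observed one. The two-sided p-value uses
#' the add-one correction `p = (1 + #{|d_perm| >= |d_obs|}) / (n_perm + 1)`,
#' so it is never exactly zero.
#'
#' @param a,b Numeric vectors (both non-empty).
#' @param n_perm Number of label permutations.
#' @param seed Optional seed for the permutation stream.
#' @return The p-value, with the observed difference attached as attribute
#'   `"observed"`.
#' @examples
#' permutation_test(rnorm(10, 1), rnorm(10), n_perm = 500, seed = 1)
#' @export
permutation_test <- function(a, b, n_perm = 10000L, seed = NULL) {
  if (!length(a) || !length(b))
    abort_ignitr("both samples must be non-empty", "ignitr_parameter_error")
  if (n_perm < 1L)
    abort_ignitr("n_perm must be >= 1", "ignitr_parameter_error")
  pooled <- c(a, b)
  n <- length(pooled)
  na <- length(a)
  obs <- mean(a) - mean(b)
  tol <- 1e-12 * max(1, abs(obs))
  total <- sum(pooled)
  exceed <- with_seed(seed, {
    hits <- 0L
    for (i in seq_len(n_perm)) {
      sa <- sum(pooled[sample.int(n, na)])
      d <- sa / na - (total - sa) / (n - na)
      if (abs(d) >= abs(obs) - tol) hits <- hits + 1L
    }
    hits
  })
  p <- (1 + exceed) / (n_perm + 1)
  attr(p, "observed") <- obs
  p
}

#' Benjamini-Hochberg FDR control
#'
#' Step-up FDR adjustment (via [stats::p.adjust()]) plus the rejection mask at
#' level `q`.
#'
#' @param pvals Numeric vector of p-values in `[0, 1]`.
#' @param q FDR level.
#' @return List with `adjusted` (BH-adjusted p-values, monotone in the raw
#'   ones) and `rejected` (logical mask).
#' @export
bh_fdr <- function(pvals, q = 0.05) {
  if (any(!is.finite(pvals)) || any(pvals < 0 | pvals > 1))
    abort_ignitr("p-values must lie in [0, 1]", "ignitr_contract_error")
  adjusted <- stats::p.adjust(pvals, method = "BH")
  list(adjusted = adjusted, rejected = adjusted <= q)
}

#' Cohen's d with pooled standard deviation
#'
#' `(mean(a) - mean(b)) / s_p` with the Bessel-corrected pooled standard
#' deviation `s_p = sqrt(((n_a - 1) s_a^2 + (n_b - 1) s_b^2) / (n_a + n_b - 2))`.
#'
#' @param a,b Numeric vectors, each of length >= 2.
#' @return Effect size (positive when `a` has the larger mean).
#' @export
cohen_d <- function(a, b) {
  na <- length(a); nb <- length(b)
  if (na < 2L || nb < 2L)
    abort_ignitr("each sample needs >= 2 values", "ignitr_parameter_error")
  cohen_d_from_stats(mean(a), stats::sd(a), na, mean(b), stats::sd(b), nb)
}

#' Cohen's d from summary statistics
#'
#' Same pooled-sd convention as [cohen_d()], computed from printed
#' mean / sd / n summaries.
#'
#' @param mean_a,sd_a,n_a Summary statistics of the first group.
#' @param mean_b,sd_b,n_b Summary statistics of the second group.
#' @return Effect size.
#' @examples
#' cohen_d_from_stats(0.094, 0.0044, 17, 0.070, 0.0037, 10)
#' @export
cohen_d_from_stats <- function(mean_a, sd_a, n_a, mean_b, sd_b, n_b) {
  pooled <- sqrt(((n_a - 1) * sd_a^2 + (n_b - 1) * sd_b^2) / (n_a + n_b - 2))
  if (pooled == 0)
    abort_ignitr("zero pooled standard deviation", "ignitr_degenerate_error")
  (mean_a - mean_b) / pooled
}

#' Minimum detectable effect size
#'
#' Normal-approximation two-sample formula
#' `d = (z_{1 - alpha/2} + z_{power}) * sqrt(1/n_a + 1/n_b)`, with an optional
#' Wilcoxon-Mann-Whitney asymptotic-relative-efficiency adjustment
#' (division by `sqrt(0.955)`).
#'
#' @param n_a,n_b Group sizes (each >= 2).
#' @param alpha Two-sided significance level.
#' @param power Target power.
#' @param wilcoxon Apply the ARE adjustment for a rank test.
#' @return The smallest detectable Cohen's d.
#' @examples
#' min_detectable_d(17, 10)        # ~ 1.12
#' @export
min_detectable_d <- function(n_a, n_b, alpha = 0.05, power = 0.8,
                             wilcoxon = FALSE) {
  stopifnot(n_a >= 2, n_b >= 2)
  d <- (stats::qnorm(1 - alpha / 2) + stats::qnorm(power)) *
    sqrt(1 / n_a + 1 / n_b)
  if (wilcoxon) d <- d / sqrt(0.955)
  d
}

#' Cohort hierarchy of node-metastability
#'
#' Averages node-metastability across subjects per region and sorts
#' descending: the cohort's processing hierarchy. The identifiers of the 10
#' highest-ranking regions are attached as attribute `"top10"`.
#'
#' @param profiles List of `ignition_profile` objects sharing one region set.
#' @return A `cohort_hierarchy` data frame (`region_id`, `metastability`),
#'   values non-increasing.
#' @export
build_hierarchy <- function(profiles) {
  if (!length(profiles))
    abort_ignitr("need at least one profile", "ignitr_parameter_error")
  ids <- profiles[[1]]$region_id
  for (p in profiles) {
    if (!identical(sort(p$region_id), sort(ids)))
      abort_ignitr("profiles do not share one region set",
                   "ignitr_alignment_error")
  }
  meta <- vapply(profiles, function(p)
    p$node_metastability[match(ids, p$region_id)], numeric(length(ids)))
  meta <- if (is.matrix(meta)) rowMeans(meta, na.rm = TRUE) else meta
  ord <- order(meta, decreasing = TRUE)
  out <- data.frame(region_id = ids[ord], metastability = meta[ord],
                    stringsAsFactors = FALSE)
  class(out) <- c("cohort_hierarchy", "data.frame")
  attr(out, "top10") <- out$region_id[seq_len(min(10L, nrow(out)))]
  out
}

#' Hierarchy disruption factor
#'
#' l2 distance between two cohort hierarchies, compared rank-aligned (sorted
#' value against sorted value): `sqrt(sum((a_r - b_r)^2))` over ranks `r`.
#'
#' @param a,b `cohort_hierarchy` objects (or sorted numeric vectors) of equal
#'   length.
#' @return Non-negative disruption factor.
#' @examples
#' hdf(rep(0.094, 379), rep(0.070, 379))   # uniform gap: 0.024 * sqrt(379)
#' @export
hdf <- function(a, b) {
  va <- if (is.data.frame(a)) a$metastability else as.numeric(a)
  vb <- if (is.data.frame(b)) b$metastability else as.numeric(b)
  if (length(va) != length(vb))
    abort_ignitr("hierarchies must have equal length", "ignitr_contract_error")
  sqrt(sum((va - vb)^2))
}

#' Pairwise cohort comparisons
#'
#' Runs the permutation test, BH-FDR correction across all comparisons, and
#' Cohen's d for every pair of groups on a per-subject statistic (for example
#' whole-brain mean node-metastability, or a single RSN's mean).
#'
#' @param values Named list of numeric vectors, one per group.
#' @param n_perm Permutations per test.
#' @param q FDR level.
#' @param seed Optional seed.
#' @return A `group_comparison` data frame with columns `group_a`, `group_b`,
#'   `observed`, `p`, `p_adj`, `rejected`, `cohen_d`.
#' @export
compare_groups <- function(values, n_perm = 10000L, q = 0.05, seed = NULL) {
  groups <- names(values)
  stopifnot(length(groups) >= 2L)
  pairs <- utils::combn(groups, 2L, simplify = FALSE)
  rows <- lapply(seq_along(pairs), function(i) {
    g <- pairs[[i]]
    p <- permutation_test(values[[g[1]]], values[[g[2]]], n_perm,
                          seed = if (is.null(seed)) NULL
                                 else stage_seed(seed, paste(g, collapse = "-")))
    data.frame(group_a = g[1], group_b = g[2],
               observed = attr(p, "observed"), p = as.numeric(p),
               cohen_d = cohen_d(values[[g[1]]], values[[g[2]]]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  fdr <- bh_fdr(out$p, q)
  out$p_adj <- fdr$adjusted
  out$rejected <- fdr$rejected
  out <- out[, c("group_a", "group_b", "observed", "p", "p_adj",
                 "rejected", "cohen_d")]
  class(out) <- c("group_comparison", "data.frame")
  out
}

#' Per-subject RSN summaries of node-metastability
#'
#' Averages each subject's regional node-metastability within every RSN,
#' excluding `SUBCORT`.
#'
#' @param profiles Named list of `ignition_profile` objects.
#' @param rsn Named character vector of RSN labels per region id.
#' @return Data frame `subject_id` x RSN columns of mean metastability.
#' @export
rsn_metastability <- function(profiles, rsn) {
  networks <- setdiff(intersect(RSN_LEVELS, unique(rsn)), "SUBCORT")
  rows <- lapply(names(profiles), function(sid) {
    p <- profiles[[sid]]
    labels <- rsn[p$region_id]
    vals <- vapply(networks, function(net)
      mean(p$node_metastability[labels == net], na.rm = TRUE), numeric(1))
    as.data.frame(c(list(subject_id = sid), as.list(vals)),
                  stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
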