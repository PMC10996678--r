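#' Assemble the long modelling table
#'
#' Joins per-subject ignition profiles, burden tables and RSN labels into one
#' row per subject x region. Rows whose metastability is missing (fewer than
#' two driving events) are dropped with a message stating the count.
#'
#' @param profiles Named list of `ignition_profile` objects (or, for synthetic
#'   burden tables that carry their own `metastability` column, `NULL`).
#' @param burdens Named list of burden data frames (`region_id`, `abeta`,
#'   `tau`, optionally `metastability`), same names as `profiles`.
#' @param rsn Named character vector of RSN labels per region id (optional).
#' @return A `long_table` data frame with columns `subject_id`, `region_id`,
#'   `rsn`, `metastability`, `abeta`, `tau`, sorted by subject then region.
#' @export
build_long_table <- function(profiles, burdens, rsn = NULL) {
  subjects <- names(burdens)
  if (is.null(subjects))
    abort_ignitr("burden list must be named by subject", "ignitr_alignment_error")
  rows <- lapply(subjects, function(sid) {
    b <- burdens[[sid]]
    if (anyDuplicated(b$region_id))
      abort_ignitr(sprintf("duplicated region ids for subject %s", sid),
                   "ignitr_alignment_error")
    meta <- if (!is.null(profiles)) {
      p <- profiles[[sid]]
      if (is.null(p))
        abort_ignitr(sprintf("no profile for subject %s", sid),
                     "ignitr_alignment_error")
      p$node_metastability[match(b$region_id, p$region_id)]
    } else {
      b$metastability
    }
    data.frame(subject_id = sid, region_id = b$region_id,
               rsn = if (is.null(rsn)) NA_character_
                     else unname(rsn[b$region_id]),
               metastability = meta, abeta = b$abeta, tau = b$tau,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  dropped <- sum(is.na(out$metastability))
  if (dropped > 0) {
    message(sprintf("dropping %d row(s) with missing metastability", dropped))
    out <- out[!is.na(out$metastability), , drop = FALSE]
  }
  out <- out[order(out$subject_id, out$region_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("long_table", "data.frame")
  out
}

lme_result <- function(fit, formula_used, fallback = FALSE) {
  ct <- as.data.frame(stats::coef(summary(fit)))
  names(ct) <- c("estimate", "std_error", "df", "t_value", "p_value")
  ct$term <- rownames(ct)
  rownames(ct) <- NULL
  vc <- as.data.frame(lme4::VarCorr(fit))
  structure(list(fixed = ct[, c("term", "estimate", "std_error", "df",
                                "t_value", "p_value")],
                 varcor = vc,
                 loglik = as.numeric(stats::logLik(fit)),
                 formula = formula_used,
                 fallback = fallback,
                 fit = fit),
            class = "iif_lme")
}

#' @export
print.iif_lme <- function(x, digits = 4, ...) {
  cat("Linear mixed-effects model:", x$formula, "\n")
  if (x$fallback)
    cat("  (full random-effects structure failed; random-intercept fallback)\n")
  print(format(x$fixed, digits = digits), row.names = FALSE)
  cat(sprintf("log-likelihood (REML): %.2f\n", x$loglik))
  invisible(x)
}

#' @export
coef.iif_lme <- function(object, ...) {
  stats::setNames(object$fixed$estimate, object$fixed$term)
}

fit_converged <- function(fit) {
  msgs <- fit@optinfo$conv$lme4$messages
  is.null(msgs) && !lme4::isSingular(fit, tol = 1e-5)
}

#' Whole-brain burden model
#'
#' Fits `metastability ~ abeta * tau + (1 | subject_id)` by restricted maximum
#' likelihood, with Satterthwaite degrees of freedom for the fixed-effect
#' p-values (lmerTest).
#'
#' @param table A [build_long_table()] result.
#' @return An `iif_lme` object: fixed-effect table (estimate, std. error, df,
#'   t, p), variance components, REML log-likelihood and the underlying fit.
#' @export
fit_wholebrain_lme <- function(table) {
  if (length(unique(table$subject_id)) < 3L)
    abort_ignitr("need at least 3 subjects", "ignitr_parameter_error")
  fml <- metastability ~ abeta * tau + (1 | subject_id)
  fit <- lmerTest::lmer(fml, data = table, REML = TRUE)
  lme_result(fit, "metastability ~ abeta * tau + (1 | subject_id)")
}

#' RSN-resolved burden model
#'
#' Fits the three-way fixed-effect interaction of amyloid-beta, tau and RSN,
#' with a subject random intercept plus random RSN offsets nested within
#' subject: `metastability ~ abeta * tau * rsn + (1 | subject_id) +
#' (1 | subject_id:rsn)`. `SUBCORT` rows are excluded. If the nested
#' random-effects structure fails to converge (or is singular), the model
#' falls back to the random-intercept-only form and flags the downgrade.
#'
#' @param table A [build_long_table()] result with an `rsn` column.
#' @param reference_rsn RSN used as the factor reference level.
#' @return An `iif_lme` object; `$fallback` records a downgrade.
#' @export
fit_rsn_lme <- function(table, reference_rsn = NULL) {
  tab <- table[!is.na(table$rsn) & table$rsn != "SUBCORT", , drop = FALSE]
  if (length(unique(tab$rsn)) == 1L)   # degenerate nesting: one network only
    return(fit_wholebrain_lme(tab))
  counts <- table(unique(tab[, c("subject_id", "rsn")])$rsn)
  if (any(counts < 2L))
    abort_ignitr("every RSN must be present in >= 2 subjects",
                 "ignitr_parameter_error")
  tab$rsn <- factor(tab$rsn)
  if (!is.null(reference_rsn))
    tab$rsn <- stats::relevel(tab$rsn, ref = reference_rsn)
  full <- metastability ~ abeta * tau * rsn + (1 | subject_id) +
    (1 | subject_id:rsn)
  # convergence complaints here are expected at small n; the fallback handles
  # them, so keep the attempt quiet and inspect the optimizer info instead
  fit <- tryCatch(
    suppressWarnings(suppressMessages(lmerTest::lmer(full, data = tab,
                                                     REML = TRUE))),
    error = function(e) NULL)
  if (!is.null(fit) && fit_converged(fit))
    return(lme_result(fit,
      "metastability ~ abeta * tau * rsn + (1 | subject_id) + (1 | subject_id:rsn)"))
  fallback <- metastability ~ abeta * tau * rsn + (1 | subject_id)
  fit2 <- lmerTest::lmer(fallback, data = tab, REML = TRUE)
  lme_result(fit2, "metastability ~ abeta * tau * rsn + (1 | subject_id)",
             fallback = TRUE)
}

#' Per-RSN burden contrast
#'
#' The slope of `term` within a given RSN under treatment coding is the main
#' effect plus the corresponding interaction; this evaluates that contrast
#' with a Satterthwaite t-test.
#'
#' @param model An `iif_lme` from [fit_rsn_lme()].
#' @param rsn RSN label of interest.
#' @param term `"tau"`, `"abeta"` or `"abeta:tau"`.
#' @return One-row data frame: `estimate`, `std_error`, `df`, `t_value`,
#'   `p_value`.
#' @export
rsn_contrast <- function(model, rsn, term = "tau") {
  stopifnot(inherits(model, "iif_lme"))
  terms_all <- model$fixed$term
  L <- numeric(length(terms_all))
  main <- if (term == "abeta:tau") "abeta:tau" else term
  L[terms_all == main] <- 1
  inter <- c(paste0(main, ":rsn", rsn),
             if (term == "abeta:tau") paste0("abeta:tau:rsn", rsn))
  hit <- terms_all %in% inter
  L[hit] <- 1
  if (sum(L) == 1 && !any(terms_all %in% inter) && rsn != levels(
        model$fit@frame$rsn)[1])
    abort_ignitr(sprintf("no interaction term found for RSN %s", rsn),
                 "ignitr_contract_error")
  ct <- lmerTest::contest1D(model$fit, L, confint = TRUE)
  data.frame(estimate = ct$Estimate, std_error = ct$`Std. Error`,
             df = ct$df, t_value = ct$`t value`, p_value = ct$`Pr(>|t|)`,
             lower = ct$lower, upper = ct$upper)
}
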