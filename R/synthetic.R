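#' Synthetic cohort specification
#'
#' Parameters of the clique-event generator. Global ignition events occur at
#' Bernoulli-thinned TRs with rate `event_rate`; a refractory gap of
#' `refractory_trs` TRs after each accepted event keeps propagation windows
#' from straddling two events, so each integration record is identified with
#' exactly one generating event. For each event a recruitment fraction
#' `f ~ Beta(recruit_alpha, recruit_beta)` is drawn and shrunk towards its
#' mean by `severity` (`f' = mu + (1 - severity) * (f - mu)`); every region is
#' then active at that TR independently with probability `f'`, with one
#' uniformly chosen nominal driver always active.
#'
#' Shrinking reduces the variance of the recruited fraction — exactly the
#' quantity node-metastability measures — without changing its mean, so
#' increasing `severity` lowers metastability while leaving mean ignition
#' almost untouched.
#'
#' @param n_regions Number of regions (default 379, the cortical + subcortical
#'   parcellation size this package models).
#' @param n_timepoints Number of TRs (default 197, one resting-state scan).
#' @param tr_seconds Repetition time in seconds (default 3).
#' @param event_rate Global ignition events per TR.
#' @param recruit_alpha,recruit_beta Beta shape parameters of the recruitment
#'   fraction.
#' @param noise_sd Gaussian noise amplitude added by [raster_to_bold()], in
#'   arbitrary BOLD units.
#' @param severity Scalar in `[0, 1]` scaling recruitment variability downward.
#' @param refractory_trs Minimum gap (TRs) between consecutive global events.
#' @param seed Integer seed for this subject's raster.
#' @return A `synthetic_spec` object.
#' @export
synthetic_spec <- function(n_regions = 379L, n_timepoints = 197L,
                           tr_seconds = 3, event_rate = 0.15,
                           recruit_alpha = 2, recruit_beta = 2,
                           noise_sd = 0.1, severity = 0,
                           refractory_trs = 3L, seed = 1L) {
  spec <- list(n_regions = as.integer(n_regions),
               n_timepoints = as.integer(n_timepoints),
               tr_seconds = as.numeric(tr_seconds),
               event_rate = as.numeric(event_rate),
               recruit_alpha = as.numeric(recruit_alpha),
               recruit_beta = as.numeric(recruit_beta),
               noise_sd = as.numeric(noise_sd),
               severity = as.numeric(severity),
               refractory_trs = as.integer(refractory_trs),
               seed = as.integer(seed))
  if (spec$recruit_alpha <= 0 || spec$recruit_beta <= 0)
    abort_ignitr("recruit_alpha and recruit_beta must be > 0",
                 "ignitr_parameter_error")
  if (spec$severity < 0 || spec$severity > 1)
    abort_ignitr("severity must lie in [0, 1]", "ignitr_parameter_error")
  if (spec$event_rate <= 0 || spec$event_rate >= 1)
    abort_ignitr("event_rate must lie in (0, 1) events per TR",
                 "ignitr_parameter_error")
  if (spec$event_rate * spec$n_timepoints < 10)
    abort_ignitr("expected fewer than 10 events; lengthen the scan or raise event_rate",
                 "ignitr_parameter_error")
  structure(spec, class = "synthetic_spec")
}

#' Generate a clique event raster with known ground truth
#'
#' Draws global ignition events and per-event recruitment as described in
#' [synthetic_spec()]. Because all recruited regions co-activate at a single
#' TR and windows never contain two events, the integration of every driving
#' event equals the recruited fraction — giving the generator an analytic
#' node-metastability target ([clique_meta_sd()]).
#'
#' @param spec A [synthetic_spec()].
#' @return A list with elements `raster` (an [event_raster()]) and `truth`
#'   (event times, post-shrinkage recruitment fractions, nominal drivers and
#'   realized recruited counts).
#' @export
generate_event_raster <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed, {
    n <- spec$n_regions
    tt <- spec$n_timepoints
    cand <- which(stats::runif(tt) < spec$event_rate)
    times <- integer(0)
    last <- -Inf
    for (t in cand) {                       # enforce the refractory gap
      if (t - last > spec$refractory_trs) {
        times <- c(times, t)
        last <- t
      }
    }
    ne <- length(times)
    mu <- spec$recruit_alpha / (spec$recruit_alpha + spec$recruit_beta)
    f <- stats::rbeta(ne, spec$recruit_alpha, spec$recruit_beta)
    f <- mu + (1 - spec$severity) * (f - mu)
    drivers <- sample.int(n, ne, replace = TRUE)
    ev <- matrix(0L, n, tt)
    if (ne) {
      recruit <- matrix(stats::runif(ne * n), n, ne) < rep(f, each = n)
      recruit[cbind(drivers, seq_len(ne))] <- TRUE
      ev[, times] <- recruit * 1L
    }
    raster <- event_raster(ev, theta = NA_real_, tr_seconds = spec$tr_seconds)
    truth <- list(event_times = times,
                  recruit_fraction = f,
                  drivers = drivers,
                  recruit_count = if (ne) colSums(ev[, times, drop = FALSE])
                                  else integer(0),
                  severity = spec$severity)
    list(raster = raster, truth = truth)
  })
}

#' Canonical two-gamma haemodynamic kernel
#'
#' Difference of two gamma densities with modes at `peak_s` and
#' `undershoot_s` (unit rate), sampled on the TR grid and scaled to unit peak.
#'
#' @param tr_seconds Sampling interval in seconds.
#' @param duration_s Kernel support in seconds.
#' @param peak_s Mode of the positive lobe (default 6 s).
#' @param undershoot_s Mode of the undershoot (default 16 s).
#' @param undershoot_ratio Relative undershoot amplitude (default 1/6).
#' @return Numeric vector of kernel samples starting at lag 0.
#' @export
hrf_kernel <- function(tr_seconds, duration_s = 32, peak_s = 6,
                       undershoot_s = 16, undershoot_ratio = 1 / 6) {
  t <- seq(0, duration_s, by = tr_seconds)
  h <- stats::dgamma(t, shape = peak_s + 1, rate = 1) -
    undershoot_ratio * stats::dgamma(t, shape = undershoot_s + 1, rate = 1)
  h / max(h)
}

#' Convolve an event raster into a BOLD-like series
#'
#' Each region's binary event train is convolved with the canonical two-gamma
#' haemodynamic kernel sampled at the TR, and Gaussian noise of amplitude
#' `spec$noise_sd` is added. The output can be pushed through the full
#' analysis chain including thresholded event detection.
#'
#' @param raster An [event_raster()] (typically from [generate_event_raster()]).
#' @param spec The [synthetic_spec()] that produced it.
#' @return A [parcel_ts()].
#' @export
raster_to_bold <- function(raster, spec) {
  stopifnot(inherits(raster, "event_raster"), inherits(spec, "synthetic_spec"))
  kernel <- hrf_kernel(spec$tr_seconds)
  ev <- raster$events
  tt <- ncol(ev)
  bold <- t(apply(ev, 1L, function(row) {
    stats::convolve(row, rev(kernel), type = "open")[seq_len(tt)]
  }))
  with_seed(spec$seed + 1L, {
    if (spec$noise_sd > 0)
      bold <- bold + matrix(stats::rnorm(length(bold), sd = spec$noise_sd),
                            nrow(bold), tt)
  })
  parcel_ts(bold, spec$tr_seconds, raster$region_ids)
}

#' Closed-form node-metastability of the clique generator
#'
#' Analytic cohort-mean node-metastability implied by a [synthetic_spec()]'s
#' recruitment model, in the limit of many events. A region's integration
#' records exist only at events where it was recruited, which size-biases the
#' recruitment fraction (weight proportional to `f`); with `f*` the
#' size-biased, severity-shrunk fraction, the integration of one record is
#' `(1 + Binomial(n - 1, f*)) / n` and
#' `Var(I) = ((n-1)^2 Var(f*) + (n-1) E[f*(1-f*)]) / n^2`.
#'
#' @param recruit_alpha,recruit_beta Beta shape parameters.
#' @param n_regions Number of regions.
#' @param severity Shrinkage in `[0, 1]`.
#' @return The analytic standard deviation of per-record integration.
#' @examples
#' clique_meta_sd(2, 2, 100)   # ~ 0.203
#' @export
clique_meta_sd <- function(recruit_alpha, recruit_beta, n_regions,
                           severity = 0) {
  a <- recruit_alpha; b <- recruit_beta; n <- n_regions
  lam <- 1 - severity
  mu <- a / (a + b)
  vf <- a * b / ((a + b)^2 * (a + b + 1))
  skew <- 2 * (b - a) * sqrt(a + b + 1) / ((a + b + 2) * sqrt(a * b))
  m3 <- skew * vf^1.5
  # raw moments of the shrunk fraction g = mu + lam * (f - mu)
  Eg <- mu
  Eg2 <- mu^2 + lam^2 * vf
  Eg3 <- mu^3 + 3 * mu * lam^2 * vf + lam^3 * m3
  # size-biased moments (weight g / E[g])
  Es1 <- Eg2 / mu
  Es2 <- Eg3 / mu
  var_star <- Es2 - Es1^2
  varI <- ((n - 1)^2 * var_star + (n - 1) * (Es1 - Es2)) / n^2
  sqrt(varI)
}

#' Severity that yields a target cohort metastability
#'
#' Inverts [clique_meta_sd()] numerically.
#'
#' @param target Desired cohort-mean node-metastability.
#' @param recruit_alpha,recruit_beta Beta shape parameters.
#' @param n_regions Number of regions.
#' @return Severity in `[0, 1]`.
#' @export
severity_for_target <- function(target, recruit_alpha = 2, recruit_beta = 2,
                                n_regions = 379L) {
  upper <- clique_meta_sd(recruit_alpha, recruit_beta, n_regions, 0)
  # full shrinkage leaves the binomial recruitment noise floor
  lower <- clique_meta_sd(recruit_alpha, recruit_beta, n_regions, 1)
  if (target > upper || target < lower)
    abort_ignitr(sprintf(
      "target %g outside attainable range [%g, %g] at %d regions",
      target, lower, upper, n_regions), "ignitr_parameter_error")
  stats::uniroot(function(s)
    clique_meta_sd(recruit_alpha, recruit_beta, n_regions, s) - target,
    c(0, 1), tol = 1e-10)$root
}

#' Simulate a three-stage cohort
#'
#' Generates one raster (or BOLD series) per subject with group sizes and
#' severity settings that reproduce the disease-continuum ordering of
#' cohort-mean node-metastability HC > MCI > AD. Default targets are the
#' printed group means 0.094 / 0.087 / 0.070, inverted through
#' [severity_for_target()].
#'
#' @param n_per_group Named integer vector of subjects per diagnosis
#'   (default `c(HC = 17, MCI = 9, AD = 10)`).
#' @param targets Named cohort-mean metastability targets per diagnosis.
#' @param spec Template [synthetic_spec()]; its `severity` and `seed` fields
#'   are overridden per subject.
#' @param mode `"raster"` returns clique rasters (analytic path);
#'   `"bold"` convolves each raster through [raster_to_bold()].
#' @param seed Master seed; per-subject seeds are derived from it.
#' @return A list with `manifest` (a [cohort_manifest()]), `subjects` (list of
#'   rasters or `parcel_ts`), `truths` and `severities`.
#' @export
simulate_cohort <- function(n_per_group = c(HC = 17L, MCI = 9L, AD = 10L),
                            targets = c(HC = 0.094, MCI = 0.087, AD = 0.070),
                            spec = synthetic_spec(),
                            mode = c("raster", "bold"),
                            seed = 1L) {
  mode <- match.arg(mode)
  groups <- names(n_per_group)
  stopifnot(!is.null(groups), all(groups %in% names(targets)))
  severities <- vapply(groups, function(g)
    severity_for_target(targets[[g]], spec$recruit_alpha, spec$recruit_beta,
                        spec$n_regions), numeric(1))
  subject_id <- character(0)
  diagnosis <- character(0)
  subjects <- list()
  truths <- list()
  idx <- 0L
  for (g in groups) {
    for (j in seq_len(n_per_group[[g]])) {
      idx <- idx + 1L
      sid <- sprintf("%s%02d", g, j)
      sspec <- spec
      sspec$severity <- severities[[g]]
      sspec$seed <- stage_seed(seed, paste0("subject/", sid))
      gen <- generate_event_raster(sspec)
      subjects[[sid]] <- if (mode == "bold") raster_to_bold(gen$raster, sspec)
                         else gen$raster
      truths[[sid]] <- gen$truth
      subject_id <- c(subject_id, sid)
      diagnosis <- c(diagnosis, g)
    }
  }
  list(manifest = cohort_manifest(subject_id, diagnosis),
       subjects = subjects, truths = truths, severities = severities)
}

#' Generate burden tables with known mixed-effects structure
#'
#' Draws per-region amyloid-beta and tau SUVR values from log-normal
#' distributions whose group means rise along the disease continuum, then
#' regenerates node-level metastability targets from the linear mixed-effects
#' model `meta = intercept + b_abeta * ABeta + b_tau * Tau +
#' b_interaction * ABeta * Tau [+ network-specific tau slope] + subject random
#' intercept + residual`, recording every coefficient as ground truth.
#'
#' @param diagnoses Character vector of per-subject diagnoses (HC/MCI/AD).
#' @param region_ids Region identifiers of the parcellation.
#' @param rsn Optional named RSN label per region (used by `tau_rsn`).
#' @param coefs Named list of true fixed effects: `intercept`, `abeta`, `tau`,
#'   `abeta_tau`, and optionally `tau_rsn`, a named vector of *additional* tau
#'   slope per RSN label.
#' @param ranef_sd True subject random-intercept standard deviation.
#' @param resid_sd True residual standard deviation.
#' @param suvr_mean Named list with per-diagnosis mean SUVR for `abeta` and
#'   `tau` (defaults follow the modelled study's group means).
#' @param suvr_sdlog Log-scale standard deviation of regional SUVR.
#' @param seed Integer seed.
#' @return A list: `tables` (per subject, data frame `region_id`, `abeta`,
#'   `tau`, `metastability`) and `truth` (all generating parameters plus the
#'   realized random intercepts).
#' @export
generate_burden_tables <- function(diagnoses, region_ids, rsn = NULL,
                                   coefs = list(intercept = 0.094,
                                                abeta = -0.002,
                                                tau = -0.001,
                                                abeta_tau = 0),
                                   ranef_sd = 0.005, resid_sd = 0.01,
                                   suvr_mean = list(
                                     abeta = c(HC = 1.31, MCI = 1.52, AD = 2.01),
                                     tau = c(HC = 1.53, MCI = 1.80, AD = 2.46)),
                                   suvr_sdlog = 0.15,
                                   seed = 1L) {
  n_sub <- length(diagnoses)
  n_reg <- length(region_ids)
  if (!is.null(rsn) && length(rsn) != n_reg)
    abort_ignitr("rsn labels must match region_ids", "ignitr_alignment_error")
  with_seed(seed, {
    u <- stats::rnorm(n_sub, sd = ranef_sd)   # subject random intercepts
    tables <- vector("list", n_sub)
    for (s in seq_len(n_sub)) {
      dg <- diagnoses[s]
      ab <- stats::rlnorm(n_reg,
                          log(suvr_mean$abeta[[dg]]) - suvr_sdlog^2 / 2,
                          suvr_sdlog)
      ta <- stats::rlnorm(n_reg,
                          log(suvr_mean$tau[[dg]]) - suvr_sdlog^2 / 2,
                          suvr_sdlog)
      meta <- coefs$intercept + coefs$abeta * ab + coefs$tau * ta +
        coefs$abeta_tau * ab * ta + u[s] +
        stats::rnorm(n_reg, sd = resid_sd)
      if (!is.null(coefs$tau_rsn) && !is.null(rsn)) {
        extra <- coefs$tau_rsn[rsn]
        extra[is.na(extra)] <- 0
        meta <- meta + extra * ta
      }
      tables[[s]] <- data.frame(region_id = region_ids, abeta = ab, tau = ta,
                                metastability = meta,
                                stringsAsFactors = FALSE)
    }
    names(tables) <- names(diagnoses) %||% sprintf("S%03d", seq_len(n_sub))
    list(tables = tables,
         truth = list(coefs = coefs, ranef = u, ranef_sd = ranef_sd,
                      resid_sd = resid_sd, suvr_sdlog = suvr_sdlog))
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
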