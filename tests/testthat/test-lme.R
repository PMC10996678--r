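make_cohort_tables <- function(n_regions = 60, coefs = NULL, resid_sd = 0.01,
                               ranef_sd = 0.005, seed = 1, rsn = NULL) {
  regions <- if (is.null(rsn)) sprintf("R%03d", seq_len(n_regions))
             else names(rsn)
  diag <- setNames(rep(c("HC", "MCI", "AD"), c(17, 9, 10)),
                   sprintf("S%02d", 1:36))
  args <- list(diagnoses = diag, region_ids = regions, rsn = rsn,
               ranef_sd = ranef_sd, resid_sd = resid_sd, seed = seed)
  if (!is.null(coefs)) args$coefs <- coefs
  do.call(generate_burden_tables, args)
}

test_that("long-table assembly joins, drops and sorts deterministically", {
  prof <- data.frame(region_id = c("R1", "R2", "R3"),
                     ignition = c(0.5, 0.6, 0.4),
                     node_metastability = c(0.09, NA, 0.07),
                     n_events = c(10L, 1L, 8L))
  class(prof) <- c("ignition_profile", "data.frame")
  burden <- data.frame(region_id = c("R1", "R2", "R3"),
                       abeta = c(1.2, 1.4, 1.3), tau = c(1.5, 1.6, 1.7))
  profs <- list(A = prof, B = prof)
  burds <- list(A = burden, B = burden)
  expect_message(tab <- build_long_table(profs, burds), "dropping 2")
  expect_identical(nrow(tab), 4L)                 # 2 subjects x 3 regions - 2
  expect_identical(tab$subject_id, c("A", "A", "B", "B"))
  # shuffled burden rows give the identical sorted table
  burds2 <- list(A = burden[c(3, 1, 2), ], B = burden[c(2, 3, 1), ])
  expect_equal(suppressMessages(build_long_table(profs, burds2)), tab)
})

test_that("with zero random-effect variance the fit collapses to least squares", {
  gb <- make_cohort_tables(n_regions = 30, ranef_sd = 0, seed = 3)
  tab <- build_long_table(NULL, gb$tables)
  fit <- suppressMessages(fit_wholebrain_lme(tab))
  ols <- lm(metastability ~ abeta * tau, data = tab)
  expect_equal(unname(coef(fit)), unname(coef(ols)), tolerance = 1e-4)
})

test_that("the whole-brain model recovers its generating coefficient", {
  gb <- make_cohort_tables(n_regions = 120, seed = 4)
  fit <- fit_wholebrain_lme(build_long_table(NULL, gb$tables))
  row <- fit$fixed[fit$fixed$term == "abeta", ]
  ci <- row$estimate + c(-1, 1) * qt(0.975, row$df) * row$std_error
  expect_lt(ci[1], -0.002)
  expect_gt(ci[2], -0.002)
  expect_true(all(fit$fixed$std_error > 0))
})

test_that("t-statistics are invariant to predictor rescaling", {
  gb <- make_cohort_tables(n_regions = 40, seed = 5)
  tab <- build_long_table(NULL, gb$tables)
  fit_raw <- fit_wholebrain_lme(tab)
  tab2 <- tab
  tab2$abeta <- tab$abeta / sd(tab$abeta)
  tab2$tau <- tab$tau / sd(tab$tau)
  fit_scaled <- fit_wholebrain_lme(tab2)
  expect_equal(fit_scaled$fixed$t_value, fit_raw$fixed$t_value,
               tolerance = 1e-5)
})

test_that("adding the interaction never lowers the ML likelihood", {
  gb <- make_cohort_tables(n_regions = 40, seed = 6)
  tab <- build_long_table(NULL, gb$tables)
  ml_add <- lme4::lmer(metastability ~ abeta + tau + (1 | subject_id),
                       data = tab, REML = FALSE)
  ml_int <- lme4::lmer(metastability ~ abeta * tau + (1 | subject_id),
                       data = tab, REML = FALSE)
  expect_gte(as.numeric(logLik(ml_int)), as.numeric(logLik(ml_add)))
})

test_that("estimates are invariant to subject relabelling", {
  gb <- make_cohort_tables(n_regions = 30, seed = 7)
  tab <- build_long_table(NULL, gb$tables)
  tab2 <- tab
  tab2$subject_id <- chartr("S", "Z", tab$subject_id)
  f1 <- fit_wholebrain_lme(tab)
  f2 <- fit_wholebrain_lme(tab2)
  expect_equal(coef(f1), coef(f2), tolerance = 1e-8)
})

seven_rsn_labels <- function(per_net = 10) {
  nets <- setdiff(RSN_LEVELS, "SUBCORT")
  setNames(rep(nets, each = per_net),
           sprintf("R%03d", seq_len(per_net * length(nets))))
}

test_that("the RSN model detects a planted network-specific tau effect", {
  rsn <- seven_rsn_labels(10)
  gb <- make_cohort_tables(coefs = list(intercept = 0.094, abeta = -0.002,
                                        tau = 0, abeta_tau = 0,
                                        tau_rsn = c(DAT = -0.02)),
                           seed = 8, rsn = rsn)
  tab <- build_long_table(NULL, gb$tables, rsn)
  fit <- fit_rsn_lme(tab)
  dat <- rsn_contrast(fit, "DAT", "tau")
  expect_lt(dat$p_value, 0.05)
  expect_lt(dat$estimate, 0)
  # network without a planted effect stays quiet
  lim <- rsn_contrast(fit, "LIM", "tau")
  expect_gt(lim$p_value, 0.05)
})

test_that("permuting RSN labels destroys the planted contrast", {
  rsn <- seven_rsn_labels(10)
  gb <- make_cohort_tables(coefs = list(intercept = 0.094, abeta = 0,
                                        tau = 0, abeta_tau = 0,
                                        tau_rsn = c(DAT = -0.02)),
                           seed = 9, rsn = rsn)
  # permuted labels: the DAT signal is spread evenly across networks
  perm <- withr::with_seed(10, setNames(sample(unname(rsn)), names(rsn)))
  tab <- build_long_table(NULL, gb$tables, perm)
  fit <- fit_rsn_lme(tab)
  ps <- vapply(setdiff(RSN_LEVELS, "SUBCORT"), function(net)
    rsn_contrast(fit, net, "tau")$p_value, numeric(1))
  # no single network should soak up the whole effect any more
  expect_gte(min(ps), 1e-4)
})

test_that("a single-network table collapses to the whole-brain model", {
  rsn <- setNames(rep("DMN", 25), sprintf("R%03d", 1:25))
  gb <- make_cohort_tables(seed = 11, rsn = rsn)
  tab <- build_long_table(NULL, gb$tables, rsn)
  collapsed <- fit_rsn_lme(tab)
  wholebrain <- fit_wholebrain_lme(tab)
  expect_equal(coef(collapsed), coef(wholebrain))
})

test_that("fixed-effect p-values are roughly uniform on null data", {
  ps <- vapply(1:20, function(r) {
    gb <- make_cohort_tables(n_regions = 25,
                             coefs = list(intercept = 0.09, abeta = 0,
                                          tau = 0, abeta_tau = 0),
                             seed = 200 + r)
    fit <- fit_wholebrain_lme(build_long_table(NULL, gb$tables))
    fit$fixed$p_value[fit$fixed$term == "abeta"]
  }, numeric(1))
  expect_gt(mean(ps > 0.05), 0.7)       # ~95% expected; allow wide slack
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})
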