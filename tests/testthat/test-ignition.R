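test_that("band-pass preserves in-band tones and suppresses out-of-band ones", {
  tr <- 3
  tt <- 197
  tvec <- (0:(tt - 1)) * tr
  amp_ratio <- function(freq) {
    x <- rbind(sin(2 * pi * freq * tvec), cos(2 * pi * freq * tvec))
    filt <- bandpass(parcel_ts(x, tr), 0.01, 0.09)
    ctr <- 40:(tt - 40)                      # avoid filtfilt edge transients
    sqrt(mean(filt$data[1, ctr]^2) / mean(x[1, ctr]^2))
  }
  expect_equal(amp_ratio(0.05), 1, tolerance = 0.05)
  expect_lt(amp_ratio(0.15), 1 / 5)
  zero <- bandpass(parcel_ts(matrix(0, 2, 60), tr), 0.01, 0.09)
  expect_true(all(abs(zero$data) < 1e-10))
  expect_error(bandpass(toy_series(), 0.05, 0.4),
               class = "ignitr_parameter_error")
})

test_that("z-scoring is idempotent and affine-invariant", {
  ts <- toy_series(n = 5, tt = 80)
  z <- zscore(ts)
  expect_equal(unname(rowMeans(z$data)), rep(0, 5), tolerance = 1e-12)
  expect_equal(unname(apply(z$data, 1, sd)), rep(1, 5), tolerance = 1e-12)
  expect_equal(zscore(z)$data, z$data, tolerance = 1e-12)
  affine <- parcel_ts(2.5 * ts$data + 7, ts$tr_seconds)
  expect_equal(zscore(affine)$data, z$data, tolerance = 1e-10)
  const <- parcel_ts(rbind(ts$data[1, ], rep(1, 80)), 3,
                     region_ids = c("ok", "flat"))
  err <- expect_error(zscore(const), class = "ignitr_degenerate_error")
  expect_match(conditionMessage(err), "flat")
})

test_that("event detection marks exactly the upward threshold crossings", {
  z <- parcel_ts(rbind(c(-1, 2, 2, -1, 3), rep(-2, 5)), 3)
  ev <- detect_events(z, theta = 1)
  expect_identical(unname(ev$events[1, ]), c(0L, 1L, 0L, 0L, 1L))
  expect_identical(sum(ev$events[2, ]), 0L)

  long <- withr::with_seed(11, rnorm(3000))
  ev2 <- detect_events(parcel_ts(rbind(long, long), 3), 1)
  expect_identical(which(ev2$events[1, ] == 1L), oracle_upcrossings(long, 1))
})

test_that("co-activation matrices are cliques on the window-active set", {
  ev <- matrix(0L, 5, 8)
  ev[1, 3] <- 1L                          # lone driver
  r <- event_raster(ev, theta = 1)
  expect_true(all(coactivation_matrix(r, 1, 3, 4) == 0))

  ev2 <- matrix(0L, 5, 8)
  ev2[1, 2] <- ev2[2, 3] <- ev2[3, 5] <- 1L
  adj <- coactivation_matrix(event_raster(ev2, 1), 1, 2, 4)
  expect_equal(sort(unname(which(rowSums(adj) > 0))), 1:3)
  expect_true(all(adj[1:3, 1:3][upper.tri(diag(3))] == 1))
  expect_true(all(adj[4:5, ] == 0))

  # algebraic oracle: adjacency = outer product of activity minus diagonal
  withr::with_seed(7, {
    for (rep in 1:20) {
      evr <- matrix(rbinom(6 * 12, 1, 0.2), 6, 12)
      raster <- event_raster(evr, 1)
      t0 <- sample(1:9, 1)
      drv <- sample(1:6, 1)
      v <- as.integer(rowSums(evr[, t0:(t0 + 3)]) > 0)
      v[drv] <- 1L
      expected <- outer(v, v)
      diag(expected) <- 0L
      expect_equal(unname(coactivation_matrix(raster, drv, t0, 4)), expected)
    }
  })
})

test_that("integration equals the largest-component fraction", {
  expect_equal(integration(matrix(0, 5, 5)), 1 / 5)
  complete <- matrix(1, 5, 5) - diag(5)
  expect_equal(integration(complete), 1)
  adj <- matrix(0, 6, 6)
  edges <- rbind(c(1, 2), c(2, 3), c(4, 5))
  adj[edges] <- 1
  adj <- adj + t(adj)
  expect_equal(integration(adj), 0.5)
  expect_error(integration(matrix(0, 3, 2)), class = "ignitr_contract_error")
  asym <- matrix(0, 3, 3); asym[1, 2] <- 1
  expect_error(integration(asym), class = "ignitr_contract_error")
})

test_that("integration matches independent union-find and igraph oracles", {
  skip_if_not_installed("igraph")
  withr::with_seed(99, {
    for (rep in 1:60) {
      n <- sample(3:20, 1)
      adj <- random_adjacency(n)
      mine <- integration(adj)
      expect_equal(mine, oracle_integration_unionfind(adj))
      g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
      expect_equal(mine, max(igraph::components(g)$csize) / n)
    }
  })
})

test_that("ignition profile reproduces hand-computed statistics", {
  # region 1 fires at t = 1, 5, 9 with active sets of sizes 1, 2, 3 (of 5)
  ev <- matrix(0L, 5, 14)
  ev[1, c(1, 5, 9)] <- 1L
  ev[2, 6] <- 1L
  ev[2, 10] <- 1L
  ev[3, 11] <- 1L
  prof <- ignition_profile(event_raster(ev, 1), window_trs = 4)
  i1 <- c(1, 2, 3) / 5
  expect_equal(prof$ignition[1], mean(i1))
  expect_equal(prof$node_metastability[1], sqrt(sum((i1 - mean(i1))^2) / 3))
  expect_equal(prof$n_events[1], 3L)
  # single-event region: ignition defined, metastability missing
  expect_equal(prof$n_events[3], 1L)
  expect_true(is.na(prof$node_metastability[3]))
  # eventless region
  expect_true(is.na(prof$ignition[4]))

  # constant-integration region has zero metastability
  ev2 <- matrix(0L, 4, 20)
  ev2[1, c(1, 6, 11)] <- 1L
  ev2[2, c(1, 6, 11)] <- 1L
  prof2 <- ignition_profile(event_raster(ev2, 1), 4)
  expect_equal(prof2$ignition[1], 0.5)
  expect_equal(prof2$node_metastability[1], 0)

  # sample-sd convention is switchable
  prof_s <- ignition_profile(event_raster(ev, 1), 4, sd = "sample")
  expect_equal(prof_s$node_metastability[1], sd(i1))
})

test_that("events too close to the scan end are dropped, not truncated", {
  ev <- matrix(0L, 3, 10)
  ev[1, c(3, 9)] <- 1L                      # t = 9 window would overrun
  prof <- ignition_profile(event_raster(ev, 1), 4)
  expect_equal(prof$n_events[1], 1L)
})

test_that("profiles are label-equivariant and deterministic", {
  gen <- generate_event_raster(synthetic_spec(n_regions = 12,
                                              n_timepoints = 600,
                                              event_rate = 0.1, seed = 5))
  prof <- ignition_profile(gen$raster, 4)
  expect_identical(prof, ignition_profile(gen$raster, 4))
  perm <- sample(12)
  shuffled <- event_raster(gen$raster$events[perm, ], 1,
                           region_ids = gen$raster$region_ids[perm])
  prof_perm <- ignition_profile(shuffled, 4)
  reordered <- prof_perm[match(prof$region_id, prof_perm$region_id), ]
  expect_equal(reordered$ignition, prof$ignition)
  expect_equal(reordered$node_metastability, prof$node_metastability)
})

test_that("clique equivalence holds exhaustively up to 8 regions", {
  for (n in 2:8) {
    for (code in 0:(2^n - 1)) {
      v <- as.integer(intToBits(code)[1:n])
      active <- which(v == 1L)
      drivers <- if (length(active)) active else 1L
      ev <- matrix(0L, n, 5)
      ev[active, 2] <- 1L
      raster <- event_raster(ev, 1)
      for (drv in drivers) {
        frac <- integration(coactivation_matrix(raster, drv, 2, 4))
        expect_equal(frac, max(sum(v), 1L) / n)
      }
    }
  }
})
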