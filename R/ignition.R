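#' Zero-phase band-pass filter
#'
#' Band-passes each region's signal with a second-order Butterworth filter
#' applied forwards and backwards (`signal::filtfilt`), so the output is
#' zero-phase. The per-region mean is removed before filtering.
#'
#' @param series A [parcel_ts()].
#' @param low_hz,high_hz Pass-band edges in Hz; must satisfy
#'   `0 < low_hz < high_hz < 1 / (2 * tr_seconds)`.
#' @return A filtered `parcel_ts` of the same shape.
#' @examples
#' ts <- parcel_ts(matrix(rnorm(400), 2, 200), tr_seconds = 3)
#' filt <- bandpass(ts, 0.01, 0.09)
#' @export
bandpass <- function(series, low_hz = 0.01, high_hz = 0.09) {
  stopifnot(inherits(series, "parcel_ts"))
  nyquist <- 1 / (2 * series$tr_seconds)
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < nyquist))
    abort_ignitr(sprintf(
      "band [%g, %g] Hz infeasible for TR = %g s (Nyquist %g Hz)",
      low_hz, high_hz, series$tr_seconds, nyquist), "ignitr_parameter_error")
  bf <- signal::butter(2, c(low_hz, high_hz) / nyquist, type = "pass")
  x <- series$data - rowMeans(series$data)
  filtered <- t(apply(x, 1L, function(row) signal::filtfilt(bf, row)))
  parcel_ts(filtered, series$tr_seconds, series$region_ids, series$subject_id)
}

#' Per-region z-scoring
#'
#' Standardizes each region's signal to temporal mean 0 and standard deviation
#' 1, the form required by the point-process event detector.
#'
#' @param series A [parcel_ts()].
#' @return A z-scored `parcel_ts`.
#' @export
zscore <- function(series) {
  stopifnot(inherits(series, "parcel_ts"))
  mu <- rowMeans(series$data)
  sdv <- apply(series$data, 1L, stats::sd)
  degenerate <- which(sdv == 0 | !is.finite(sdv))
  if (length(degenerate))
    abort_ignitr(paste0("constant signal in region(s): ",
                        paste(series$region_ids[degenerate], collapse = ", ")),
                 "ignitr_degenerate_error")
  parcel_ts((series$data - mu) / sdv, series$tr_seconds,
            series$region_ids, series$subject_id)
}

#' Point-process event detection
#'
#' Marks a driving event wherever a region's z-scored signal crosses the
#' threshold from below: `events[i, t] = 1` iff `z[i, t] > theta` and
#' `z[i, t - 1] <= theta`. The first volume can never host an event.
#'
#' @param z A z-scored [parcel_ts()].
#' @param theta Threshold in z-score units.
#' @return An [event_raster()].
#' @examples
#' z <- parcel_ts(rbind(c(-1, 2, 2, -1, 3), c(0, 0, 0, 0, 0)), tr_seconds = 3)
#' detect_events(z, theta = 1)$events[1, ]
#' @export
detect_events <- function(z, theta = 1.0) {
  stopifnot(inherits(z, "parcel_ts"))
  x <- z$data
  tt <- ncol(x)
  if (tt < 2L)
    abort_ignitr("need at least 2 timepoints", "ignitr_validation_error")
  ev <- matrix(0L, nrow(x), tt)
  ev[, 2:tt] <- (x[, 2:tt, drop = FALSE] > theta) &
    (x[, 1:(tt - 1), drop = FALSE] <= theta)
  event_raster(ev, theta, z$tr_seconds, z$region_ids)
}

#' Windowed co-activation matrix for one driving event
#'
#' For a driving event of `driver` at TR `t`, regions showing at least one
#' event inside the window `[t, t + window_trs - 1]` (the driver always
#' included) form the simultaneously active set `A`; the returned binary
#' adjacency links every ordered pair of distinct members of `A`. The result
#' is by construction a clique on `A` plus isolated nodes.
#'
#' @param raster An [event_raster()].
#' @param driver Region id or row index of the triggering region.
#' @param t TR index (1-based) of the driving event.
#' @param window_trs Window width in TRs, inclusive of `t`.
#' @return Symmetric binary adjacency matrix with zero diagonal.
#' @export
coactivation_matrix <- function(raster, driver, t, window_trs = 4L) {
  stopifnot(inherits(raster, "event_raster"))
  ev <- raster$events
  n <- nrow(ev)
  if (is.character(driver)) driver <- match(driver, raster$region_ids)
  if (is.na(driver) || driver < 1L || driver > n)
    abort_ignitr("unknown driver region", "ignitr_validation_error")
  if (t + window_trs - 1L > ncol(ev))
    abort_ignitr("window exceeds the scan; event should be skipped upstream",
                 "ignitr_validation_error")
  active <- rowSums(ev[, t:(t + window_trs - 1L), drop = FALSE]) > 0
  active[driver] <- TRUE
  adj <- outer(active, active) * 1L
  diag(adj) <- 0L
  dimnames(adj) <- list(raster$region_ids, raster$region_ids)
  adj
}

#' Integration of a co-activation graph
#'
#' Size of the largest connected component of a binary undirected graph,
#' expressed as a fraction of nodes. Isolated nodes count as components of
#' size one, so the value lies in `[1/n, 1]`.
#'
#' @param adjacency Square symmetric binary matrix.
#' @return Fraction in `[1/n, 1]`.
#' @examples
#' adj <- matrix(0, 5, 5)
#' integration(adj)              # all singletons -> 1/5
#' @export
integration <- function(adjacency) {
  adjacency <- as.matrix(adjacency)
  n <- nrow(adjacency)
  if (n != ncol(adjacency))
    abort_ignitr("adjacency must be square", "ignitr_contract_error")
  if (!isTRUE(all.equal(adjacency, t(adjacency))))
    abort_ignitr("adjacency must be symmetric", "ignitr_contract_error")
  comp <- integer(n)          # component label per node, 0 = unvisited
  label <- 0L
  adj_list <- apply(adjacency != 0, 1L, which, simplify = FALSE)
  for (start in seq_len(n)) {
    if (comp[start]) next
    label <- label + 1L
    frontier <- start
    comp[start] <- label
    while (length(frontier)) {       # breadth-first search
      nb <- unique(unlist(adj_list[frontier], use.names = FALSE))
      nb <- nb[comp[nb] == 0L]
      comp[nb] <- label
      frontier <- nb
    }
  }
  max(tabulate(comp)) / n
}

#' Ignition profile: per-region ignition and node-metastability
#'
#' Iterates the framework over every driving event in the raster: each event
#' (driver i, TR t) with a complete `[t, t + window_trs - 1]` window yields one
#' integration record, the active fraction of the window's co-activation
#' graph. Per region, ignition is the mean and node-metastability the standard
#' deviation of that region's records. Events whose window would overrun the
#' scan are dropped. Regions with fewer than two usable events get `NA`
#' metastability.
#'
#' Because the co-activation graph is a clique on the active set plus isolated
#' nodes, its largest-component fraction equals the active fraction; the
#' implementation uses that identity (verified exhaustively in the test suite)
#' rather than materializing one adjacency matrix per event.
#'
#' @param raster An [event_raster()].
#' @param window_trs Window width in TRs (default 4).
#' @param sd Standard-deviation convention for metastability:
#'   `"population"` (n denominator, default) or `"sample"` (n - 1).
#' @param keep_records Return the per-event integration records as well.
#' @return An `ignition_profile`: data frame with columns `region_id`,
#'   `ignition`, `node_metastability`, `n_events`; when `keep_records = TRUE`,
#'   the records data frame (`driver_region`, `event_time`, `integration`) is
#'   attached as attribute `"records"`.
#' @export
ignition_profile <- function(raster, window_trs = 4L,
                             sd = c("population", "sample"),
                             keep_records = FALSE) {
  stopifnot(inherits(raster, "event_raster"))
  sd <- match.arg(sd)
  ev <- raster$events
  n <- nrow(ev)
  tt <- ncol(ev)
  if (tt < window_trs + 1L)
    abort_ignitr("scan shorter than one propagation window",
                 "ignitr_validation_error")
  t_max <- tt - window_trs + 1L          # last TR with a complete window
  # occupancy[i, t]: region i has >= 1 event in [t, t + window_trs - 1]
  occupancy <- ev[, 1:t_max, drop = FALSE]
  if (window_trs > 1L) {
    for (lag in 1:(window_trs - 1L))
      occupancy <- occupancy | ev[, (1L + lag):(t_max + lag), drop = FALSE]
  }
  active_count <- colSums(occupancy)
  # one record per event (driver i, time t): integration = active fraction
  idx <- which(ev[, 1:t_max, drop = FALSE] == 1L)
  rows <- ((idx - 1L) %% n) + 1L
  cols <- ((idx - 1L) %/% n) + 1L
  ord <- order(rows, cols)
  rows <- rows[ord]; cols <- cols[ord]
  integ <- active_count[cols] / n        # driver is in its own window
  n_events <- tabulate(rows, n)
  ignition <- node_meta <- rep(NA_real_, n)
  fired <- n_events > 0L
  if (any(fired)) {
    s1 <- rowsum(integ, rows)[, 1]       # sums per firing region, sorted
    s2 <- rowsum(integ^2, rows)[, 1]
    m <- n_events[fired]
    mu <- s1 / m
    ignition[fired] <- mu
    varr <- pmax(0, s2 / m - mu^2)       # population variance
    if (sd == "sample") varr <- varr * m / pmax(m - 1L, 1L)
    node_meta[fired] <- sqrt(varr)
    node_meta[n_events < 2L] <- NA_real_
  }
  out <- data.frame(region_id = raster$region_ids,
                    ignition = ignition,
                    node_metastability = node_meta,
                    n_events = n_events,
                    stringsAsFactors = FALSE)
  class(out) <- c("ignition_profile", "data.frame")
  attr(out, "window_trs") <- as.integer(window_trs)
  attr(out, "theta") <- raster$theta
  attr(out, "sd") <- sd
  if (keep_records) {
    attr(out, "records") <- data.frame(
      driver_region = raster$region_ids[rows],
      event_time = cols,
      integration = integ,
      stringsAsFactors = FALSE)
  }
  out
}

#' @export
print.ignition_profile <- function(x, ...) {
  cat(sprintf(
    "Ignition profile: %d regions, %d events, window %d TRs, theta %g z\n",
    nrow(x), sum(x$n_events), attr(x, "window_trs"), attr(x, "theta")))
  ok <- !is.na(x$node_metastability)
  if (any(ok))
    cat(sprintf("  mean ignition %.4f, mean node-metastability %.4f (%d regions)\n",
                mean(x$ignition, na.rm = TRUE),
                mean(x$node_metastability[ok]), sum(ok)))
  invisible(x)
}

#' @export
summary.ignition_profile <- function(object, ...) {
  ok <- !is.na(object$node_metastability)
  out <- list(
    n_regions = nrow(object),
    n_events = sum(object$n_events),
    mean_ignition = mean(object$ignition, na.rm = TRUE),
    mean_metastability = mean(object$node_metastability[ok]),
    n_regions_with_metastability = sum(ok))
  class(out) <- "summary.ignition_profile"
  out
}

#' @export
print.summary.ignition_profile <- function(x, ...) {
  cat(sprintf("%d regions (%d with metastability), %d driving events\n",
              x$n_regions, x$n_regions_with_metastability, x$n_events))
  cat(sprintf("mean ignition = %.4f, mean node-metastability = %.4f\n",
              x$mean_ignition, x$mean_metastability))
  invisible(x)
}

#' @export
plot.ignition_profile <- function(x, ...) {
  meta <- sort(x$node_metastability[!is.na(x$node_metastability)],
               decreasing = TRUE)
  graphics::plot(seq_along(meta), meta, type = "h",
                 xlab = "region rank", ylab = "node-metastability",
                 main = "Node-metastability hierarchy", ...)
  invisible(x)
}

#' Full single-subject ignition analysis
#'
#' Convenience wrapper chaining [bandpass()], [zscore()], [detect_events()] and
#' [ignition_profile()] with the settings of a [study_config()].
#'
#' @param series A [parcel_ts()].
#' @param config A [study_config()].
#' @param filter Apply the band-pass stage (disable for pre-filtered or
#'   event-level synthetic input).
#' @return An `ignition_profile`.
#' @export
analyze_subject <- function(series, config = study_config(), filter = TRUE) {
  if (filter)
    series <- bandpass(series, config$band_low_hz, config$band_high_hz)
  raster <- detect_events(zscore(series), config$threshold_theta)
  ignition_profile(raster, config$window_trs)
}
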