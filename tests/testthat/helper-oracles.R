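# Independent oracles, deliberately implemented with different algorithms
# than the package routines they check.

# Union-find largest connected component fraction.
oracle_integration_unionfind <- function(adj) {
  n <- nrow(adj)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j && adj[i, j] != 0) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[rj] <- ri
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  max(table(roots)) / n
}

# Hand-rolled Benjamini-Hochberg step-up: rejection mask and adjusted p.
oracle_bh <- function(p, q) {
  m <- length(p)
  ord <- order(p)
  thresh <- q * seq_len(m) / m
  passed <- which(p[ord] <= thresh)
  k <- if (length(passed)) max(passed) else 0L
  rejected <- logical(m)
  if (k > 0) rejected[ord[seq_len(k)]] <- TRUE
  adj <- rev(cummin(rev(p[ord] * m / seq_len(m))))
  adj <- pmin(adj, 1)
  adjusted <- numeric(m)
  adjusted[ord] <- adj
  list(adjusted = adjusted, rejected = rejected)
}

# All-pairs rank statistic AUC for binary labels (positive class given).
oracle_auc <- function(labels, scores, positive) {
  pos <- scores[labels == positive]
  neg <- scores[labels != positive]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# Direct upcrossing scan, plain loop.
oracle_upcrossings <- function(z, theta) {
  out <- integer(0)
  for (t in 2:length(z)) {
    if (z[t] > theta && z[t - 1] <= theta) out <- c(out, t)
  }
  out
}

# Exhaustive pairwise-distance nearest-neighbour labels.
oracle_nearest_label <- function(target_xyz, source_xyz, labels) {
  apply(target_xyz, 1L, function(p) {
    d <- sqrt(rowSums(sweep(source_xyz, 2L, p)^2))
    labels[which.min(d)]
  })
}

# Random symmetric binary adjacency matrix.
random_adjacency <- function(n, p = 0.15) {
  adj <- matrix(0L, n, n)
  upper <- which(upper.tri(adj))
  adj[upper] <- as.integer(stats::runif(length(upper)) < p)
  adj[lower.tri(adj)] <- t(adj)[lower.tri(adj)]
  adj
}

# Small deterministic parcel series fixture.
toy_series <- function(n = 4, tt = 120, tr = 3, seed = 42) {
  withr::with_seed(seed, parcel_ts(matrix(rnorm(n * tt), n, tt), tr))
}

# Classification fixture: `n_signal` informative columns (class-shifted) among
# noise, mirroring burden maps where pathology elevates many regions at once.
make_classification_data <- function(n_a = 17, n_b = 10, n_noise = 68,
                                     n_signal = 12, gap = 1.5, sd_sig = 0.5,
                                     seed = 1) {
  withr::with_seed(seed, {
    n <- n_a + n_b
    labels <- rep(c("HC", "AD"), c(n_a, n_b))
    x <- matrix(rnorm(n * (n_noise + n_signal)), n, n_noise + n_signal)
    colnames(x) <- c(sprintf("sig%02d", seq_len(n_signal)),
                     sprintf("noise%02d", seq_len(n_noise)))
    rownames(x) <- sprintf("S%02d", seq_len(n))
    shift <- ifelse(labels == "AD", gap, 0)
    for (j in seq_len(n_signal)) x[, j] <- shift + rnorm(n, sd = sd_sig)
    list(x = x, labels = labels,
         signal_features = colnames(x)[seq_len(n_signal)])
  })
}
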