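# Disease-stage classification: mRMR feature selection, kNN with nested
# leave-one-out cross-validation, ROC/accuracy reporting, permutation-based
# feature attribution.

# Quantile discretization into nbins equal-frequency bins (ties collapse bins).
discretize_feature <- function(x, nbins = 4L) {
  qs <- unique(stats::quantile(x, probs = seq(0, 1, length.out = nbins + 1),
                               type = 7))
  if (length(qs) < 2L) return(rep(1L, length(x)))
  as.integer(cut(x, qs, include.lowest = TRUE))
}

# Plug-in mutual information (nats) between two discrete vectors.
mutual_information <- function(x, y) {
  tab <- table(x, y)
  p <- tab / sum(tab)
  px <- rowSums(p); py <- colSums(p)
  nz <- p > 0
  sum(p[nz] * log(p[nz] / outer(px, py)[nz]))
}

#' Minimum-redundancy maximum-relevance feature selection
#'
#' Greedy forward selection: the first feature maximizes mutual information
#' with the class label (relevance); each subsequent pick maximizes relevance
#' minus the mean mutual information with the already selected features
#' (redundancy) — the difference (MID) scheme. Features are discretized into
#' equal-frequency quartile bins before estimating mutual information.
#' Constant features are excluded with a warning. Deterministic given input
#' order; score ties resolve to the lower column index.
#'
#' @param x Numeric matrix, subjects x features (column names required).
#' @param labels Class labels (factor or character).
#' @param m Number of features to select.
#' @param nbins Discretization bins per feature.
#' @return Character vector of selected feature names, in selection order.
#' @export
mrmr_select <- function(x, labels, m, nbins = 4L) {
  x <- as.matrix(x)
  if (is.null(colnames(x)))
    abort_ignitr("feature matrix needs column names", "ignitr_contract_error")
  if (length(unique(labels)) < 2L)
    abort_ignitr("need >= 2 classes", "ignitr_parameter_error")
  if (m > ncol(x))
    abort_ignitr("m exceeds the number of features", "ignitr_parameter_error")
  constant <- apply(x, 2L, function(col) length(unique(col)) == 1L)
  if (any(constant)) {
    warning(sprintf("excluding %d constant feature(s)", sum(constant)))
    x <- x[, !constant, drop = FALSE]
    m <- min(m, ncol(x))
  }
  disc <- apply(x, 2L, discretize_feature, nbins = nbins)
  y <- as.integer(factor(labels))
  nf <- ncol(x)
  relevance <- vapply(seq_len(nf), function(j)
    mutual_information(disc[, j], y), numeric(1))
  selected <- integer(0)
  redundancy_sum <- numeric(nf)
  for (step in seq_len(m)) {
    score <- if (!length(selected)) relevance
             else relevance - redundancy_sum / length(selected)
    score[selected] <- -Inf
    pick <- which.max(score)
    selected <- c(selected, pick)
    if (step < m) {
      upd <- setdiff(seq_len(nf), selected)
      redundancy_sum[upd] <- redundancy_sum[upd] + vapply(upd, function(j)
        mutual_information(disc[, j], disc[, pick]), numeric(1))
    }
  }
  colnames(x)[selected]
}

#' k-nearest-neighbour class scores
#'
#' Euclidean kNN on features standardized by the *training* mean and standard
#' deviation. The score per class is the neighbour vote fraction; the
#' predicted label is the highest-scoring class, ties broken towards the
#' smaller (first-sorted) class label.
#'
#' @param train Numeric matrix of training subjects x features.
#' @param train_labels Training class labels.
#' @param test Numeric matrix of test subjects x features (same columns).
#' @param k Number of neighbours (`1 <= k <= nrow(train)`).
#' @return List with `scores` (test x class vote-fraction matrix, classes in
#'   sorted order) and `predicted` (character vector).
#' @export
knn_predict <- function(train, train_labels, test, k) {
  train <- as.matrix(train); test <- as.matrix(test)
  if (k < 1L) abort_ignitr("k must be >= 1", "ignitr_parameter_error")
  if (k > nrow(train))
    abort_ignitr("k exceeds the training-set size", "ignitr_parameter_error")
  mu <- colMeans(train)
  sdv <- apply(train, 2L, stats::sd)
  sdv[sdv == 0] <- 1
  tr <- sweep(sweep(train, 2L, mu), 2L, sdv, "/")
  te <- sweep(sweep(test, 2L, mu), 2L, sdv, "/")
  classes <- sort(unique(as.character(train_labels)))
  lab <- as.character(train_labels)
  scores <- matrix(0, nrow(te), length(classes),
                   dimnames = list(rownames(te), classes))
  for (i in seq_len(nrow(te))) {
    d <- sqrt(colSums((t(tr) - te[i, ])^2))
    nb <- order(d)[seq_len(k)]           # stable order: index breaks ties
    votes <- table(factor(lab[nb], levels = classes))
    scores[i, ] <- as.numeric(votes) / k
  }
  predicted <- classes[apply(scores, 1L, which.max)]  # first max = smaller label
  list(scores = scores, predicted = predicted)
}

# Stratified 75/25 index split; returns training indices.
stratified_split <- function(labels, train_frac = 0.75) {
  idx <- unlist(lapply(split(seq_along(labels), labels), function(ix) {
    ntr <- max(1L, round(train_frac * length(ix)))
    if (ntr >= length(ix)) ntr <- length(ix) - 1L
    sample(ix, ntr)
  }), use.names = FALSE)
  sort(idx)
}

auc_score <- function(labels, scores, positive) {
  resp <- factor(as.integer(labels == positive), levels = c(0, 1))
  if (length(unique(resp)) < 2L || stats::sd(scores) == 0) {
    # degenerate: no discrimination measurable; fall back to rank formula
    return(0.5)
  }
  as.numeric(pROC::auc(resp, scores, direction = "<", quiet = TRUE,
                       levels = c("0", "1")))
}

#' Nested leave-one-out cross-validated kNN classification
#'
#' Outer loop: leave-one-subject-out. Per outer fold, mRMR feature selection
#' and k tuning run on the training subjects only (no leakage into the
#' held-out subject). Inner loop: `inner_reps` repeated stratified 75/25
#' splits of the training set choose k from `config$k_range` by mean
#' validation accuracy (ties towards the smaller k). The best model is refit
#' on the full training fold and scored on the held-out subject; test accuracy
#' and AUC are computed from the pooled outer-fold scores, train metrics from
#' the refit models' own training folds (averaged).
#'
#' @param x Numeric matrix, subjects x features, with row and column names.
#' @param labels Class labels (two classes).
#' @param config A [study_config()]; uses `n_features`, `k_range`, `seed`.
#' @param inner_reps Repeated stratified splits per inner loop.
#' @return A `classification_report`: accuracy/AUC (test and train, %), best
#'   k per fold and its mode, selected features per fold with selection
#'   frequencies, pooled test scores.
#' @export
nested_cv <- function(x, labels, config = study_config(), inner_reps = 20L) {
  x <- as.matrix(x)
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) != 2L)
    abort_ignitr("nested_cv handles binary problems", "ignitr_parameter_error")
  if (any(table(labels) < 2L))
    abort_ignitr("each class needs >= 2 subjects for stratification",
                 "ignitr_stratification_error")
  n <- nrow(x)
  positive <- classes[2]                  # larger label scores as positive
  test_scores <- numeric(n)
  test_pred <- character(n)
  best_ks <- integer(n)
  sel_features <- vector("list", n)
  train_acc <- train_auc <- numeric(n)
  for (fold in seq_len(n)) {
    tr_idx <- setdiff(seq_len(n), fold)
    xtr <- x[tr_idx, , drop = FALSE]
    ytr <- labels[tr_idx]
    feats <- with_seed(stage_seed(config$seed, sprintf("mrmr/%d", fold)),
                       mrmr_select(xtr, ytr, config$n_features))
    sel_features[[fold]] <- feats
    # inner loop: tune k on repeated stratified splits of the training fold
    ks <- config$k_range
    acc <- matrix(NA_real_, inner_reps, length(ks))
    with_seed(stage_seed(config$seed, sprintf("inner/%d", fold)), {
      for (r in seq_len(inner_reps)) {
        tr2 <- stratified_split(ytr)
        va2 <- setdiff(seq_along(ytr), tr2)
        for (j in seq_along(ks)) {
          if (ks[j] > length(tr2)) next
          pr <- knn_predict(xtr[tr2, feats, drop = FALSE], ytr[tr2],
                            xtr[va2, feats, drop = FALSE], ks[j])
          acc[r, j] <- mean(pr$predicted == ytr[va2])
        }
      }
    })
    mean_acc <- colMeans(acc, na.rm = TRUE)
    best_k <- ks[which.max(mean_acc)]     # first max = smaller k
    best_ks[fold] <- best_k
    pr_test <- knn_predict(xtr[, feats, drop = FALSE], ytr,
                           x[fold, feats, drop = FALSE], best_k)
    test_scores[fold] <- pr_test$scores[1, positive]
    test_pred[fold] <- pr_test$predicted
    pr_train <- knn_predict(xtr[, feats, drop = FALSE], ytr,
                            xtr[, feats, drop = FALSE], best_k)
    train_acc[fold] <- mean(pr_train$predicted == ytr)
    train_auc[fold] <- auc_score(ytr, pr_train$scores[, positive], positive)
  }
  freq <- sort(table(unlist(sel_features)), decreasing = TRUE)
  report <- list(
    classes = classes,
    positive = positive,
    test_accuracy = 100 * mean(test_pred == labels),
    test_auc = 100 * auc_score(labels, test_scores, positive),
    train_accuracy = 100 * mean(train_acc),
    train_auc = 100 * mean(train_auc),
    best_k = as.integer(names(sort(table(best_ks), decreasing = TRUE))[1]),
    best_k_per_fold = best_ks,
    n_features = config$n_features,
    selected_features = sel_features,
    feature_frequency = freq,
    test_scores = stats::setNames(test_scores, rownames(x)),
    test_predicted = test_pred,
    labels = labels)
  class(report) <- "classification_report"
  report
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("kNN classification %s vs %s (LOOCV, %d features)\n",
              x$classes[1], x$classes[2], x$n_features))
  cat(sprintf("  test  accuracy %5.1f%%   AUC %5.1f%%\n",
              x$test_accuracy, x$test_auc))
  cat(sprintf("  train accuracy %5.1f%%   AUC %5.1f%%\n",
              x$train_accuracy, x$train_auc))
  cat(sprintf("  best k (mode over folds): %d\n", x$best_k))
  cat("  most frequently selected features:",
      paste(utils::head(names(x$feature_frequency), 5), collapse = ", "), "\n")
  invisible(x)
}

#' Permutation feature attribution
#'
#' Model-agnostic importance for a fitted kNN configuration: each selected
#' feature's values are permuted `n_rep` times and the mean drop in
#' leave-one-out accuracy relative to the intact data is reported. The method
#' is recorded in the result (`"permutation_importance"`).
#'
#' @param x Feature matrix (subjects x features).
#' @param labels Class labels.
#' @param features Selected feature names (the model's inputs).
#' @param k Neighbour count of the fitted model.
#' @param n_rep Permutations per feature.
#' @param seed Seed for the permutation stream.
#' @return Data frame `feature`, `importance` (accuracy drop), sorted
#'   descending, with attribute `"method"`.
#' @export
feature_attribution <- function(x, labels, features, k, n_rep = 25L,
                                seed = 1L) {
  x <- as.matrix(x)[, features, drop = FALSE]
  labels <- as.character(labels)
  n <- nrow(x)
  loo_acc <- function(mat) {
    hits <- vapply(seq_len(n), function(i) {
      pr <- knn_predict(mat[-i, , drop = FALSE], labels[-i],
                        mat[i, , drop = FALSE], min(k, n - 1L))
      pr$predicted == labels[i]
    }, logical(1))
    mean(hits)
  }
  base <- loo_acc(x)
  imp <- with_seed(seed, {
    vapply(seq_along(features), function(j) {
      drops <- vapply(seq_len(n_rep), function(r) {
        xp <- x
        xp[, j] <- x[sample.int(n), j]
        base - loo_acc(xp)
      }, numeric(1))
      mean(drops)
    }, numeric(1))
  })
  out <- data.frame(feature = features, importance = imp,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$importance), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "method") <- "permutation_importance"
  out
}

#' Assemble the classification feature table
#'
#' Concatenates, per subject, the four regional measures — ignition,
#' node-metastability, amyloid-beta SUVR and tau SUVR — into one feature
#' vector with names `<region>_<measure>` (4 x n_regions features).
#'
#' @param profiles Named list of `ignition_profile` objects.
#' @param burdens Named list of burden data frames aligned to the same
#'   regions.
#' @param region_ids Regions to include (default: all in the first profile).
#' @return Numeric matrix, subjects x features, rownames = subject ids.
#' @export
build_feature_table <- function(profiles, burdens,
                                region_ids = NULL) {
  subjects <- names(profiles)
  if (is.null(region_ids)) region_ids <- profiles[[1]]$region_id
  rows <- lapply(subjects, function(sid) {
    p <- profiles[[sid]]
    b <- burdens[[sid]]
    pi <- match(region_ids, p$region_id)
    bi <- match(region_ids, b$region_id)
    c(stats::setNames(p$ignition[pi], paste0(region_ids, "_ignition")),
      stats::setNames(p$node_metastability[pi],
                      paste0(region_ids, "_metastability")),
      stats::setNames(b$abeta[bi], paste0(region_ids, "_abeta")),
      stats::setNames(b$tau[bi], paste0(region_ids, "_tau")))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- subjects
  if (anyNA(out))
    abort_ignitr("feature table contains missing values; drop sparse regions first",
                 "ignitr_validation_error")
  out
}
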