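# Hyperparameter selection and the repeated-splits evaluation protocol.

# Stratified fold assignment: within each class, shuffled indices are
# dealt round-robin so every fold's prevalence matches the sample's within
# one observation. Returns an integer vector of fold ids.
stratified_folds <- function(labels, k, seed = NULL) {
  with_seed(seed, {
    fold <- integer(length(labels))
    for (cls in unique(labels)) {
      idx <- sample(which(labels == cls))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
    fold
  })
}

# Evaluate one trained model on held-out data: the metric panel used
# throughout the comparison protocol. AUC is computed on the raw decision
# scores (ranking is scale-free and clipping would only collapse scores
# into ties); the calibration metrics use the probability read-out.
panel_metrics <- function(model, data, hl_g = 10) {
  proba <- predict_proba(model, data$features)
  preds <- scored_predictions(proba, data$labels)
  auc <- tryCatch(
    auc_mann_whitney(predict_raw(model, data$features), data$labels),
    error = function(e) NA_real_)
  thr <- tryCatch(threshold_metrics(preds),
                  error = function(e) list(sensitivity = NA_real_,
                                           specificity = NA_real_,
                                           f_score = NA_real_))
  hl <- tryCatch(
    suppressWarnings(hosmer_lemeshow(preds, scheme = "C",
                                     g = min(hl_g, data$n))),
    error = function(e) list(statistic = NA_real_, p_value = NA_real_)
  )
  c(auc = auc, f_score = thr$f_score, sensitivity = thr$sensitivity,
    specificity = thr$specificity, brier = brier_score(preds),
    hlc_stat = hl$statistic, hlc_p = hl$p_value)
}

train_spec <- function(data, spec, config) {
  train(data,
        model_kind = spec$model_kind,
        c_hinge = spec$c_hinge %||% 1,
        c_squared = spec$c_squared %||% 1,
        config = config)
}

#' Stratified k-fold cross-validation over a penalty grid
#'
#' For every grid point, trains on k-1 folds and evaluates the metric
#' panel on the held-out fold; the selected point optimizes the mean of
#' `criterion` across folds (`"brier"` minimized; `"auc"` and `"hlc_p"`
#' maximized), with ties broken toward smaller `c_squared`, then smaller
#' `c_hinge`. Folds are stratified by label; if a fold still ends up
#' single-class (tiny or very unbalanced data) the folds are redrawn up to
#' 10 times before erroring.
#'
#' @param data A [labeled_dataset()].
#' @param model_kind Passed to [train()].
#' @param grid Data frame with columns `c_hinge` and `c_squared` (for an
#'   SVM, `c_squared` is forced to 0), or `NULL` for the default 7-point
#'   log-spaced grid over 1e-3..1e3 in each penalty.
#' @param k Number of folds, default 10.
#' @param criterion `"brier"` (default), `"auc"` or `"hlc_p"`.
#' @param seed Seed for the fold assignment.
#' @param config A [train_config()].
#' @return An object of class `cv_result`: a list with `grid`,
#'   `per_point` (mean and sd of each panel metric per grid point),
#'   `best` (row of `grid`), `criterion`, `seed`.
#' @export
kfold_cv <- function(data, model_kind = "docsvm", grid = NULL, k = 10,
                     criterion = c("brier", "auc", "hlc_p"), seed = NULL,
                     config = train_config()) {
  data <- as_labeled_dataset(data)
  criterion <- match.arg(criterion)
  k <- as.integer(k)
  if (k < 2L || data$n < k) {
    stop("need 2 <= k <= N folds", call. = FALSE)
  }
  if (is.null(grid)) {
    pts <- 10^seq(-3, 3, length.out = 7)
    grid <- if (model_kind == "svm") {
      data.frame(c_hinge = pts, c_squared = 0)
    } else {
      expand.grid(c_hinge = pts, c_squared = pts)
    }
  }
  grid <- as.data.frame(grid)
  if (nrow(grid) == 0L) stop("grid must be non-empty", call. = FALSE)
  if (model_kind == "svm") grid$c_squared <- 0

  fold <- NULL
  for (attempt in seq_len(10L)) {
    cand <- stratified_folds(data$labels,
                             k, seed = if (is.null(seed)) NULL
                                       else seed + attempt - 1L)
    ok <- all(vapply(seq_len(k), function(f) {
      length(unique(data$labels[cand != f])) == 2L
    }, logical(1)))
    if (ok) {
      fold <- cand
      break
    }
  }
  if (is.null(fold)) {
    stop("could not build folds with both classes in every training set",
         call. = FALSE)
  }

  metric_names <- c("auc", "f_score", "sensitivity", "specificity",
                    "brier", "hlc_stat", "hlc_p")
  per_point <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    fold_metrics <- vapply(seq_len(k), function(f) {
      tr <- dataset_subset(data, fold != f)
      te <- dataset_subset(data, fold == f)
      model <- train_spec(tr, list(model_kind = model_kind,
                                   c_hinge = grid$c_hinge[i],
                                   c_squared = grid$c_squared[i]),
                          config)
      panel_metrics(model, te)
    }, numeric(length(metric_names)))
    per_point[[i]] <- data.frame(
      metric = metric_names,
      mean = rowMeans(fold_metrics, na.rm = TRUE),
      sd = apply(fold_metrics, 1L, stats::sd, na.rm = TRUE)
    )
  }
  crit_mean <- vapply(per_point, function(p) {
    p$mean[p$metric == criterion]
  }, numeric(1))
  score <- if (criterion == "brier") crit_mean else -crit_mean
  ord <- order(score, grid$c_squared, grid$c_hinge)
  best_i <- ord[1L]
  structure(
    list(grid = grid, per_point = per_point, best = grid[best_i, ],
         best_index = best_i, criterion = criterion, seed = seed),
    class = "cv_result"
  )
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("Cross-validation over %d grid points, criterion '%s'\n",
              nrow(x$grid), x$criterion))
  cat("  best: c_hinge =", x$best$c_hinge,
      ", c_squared =", x$best$c_squared, "\n")
  invisible(x)
}

#' Plan for repeated random train/test splits
#'
#' The comparison protocol trains each candidate model on a fresh random
#' (optionally label-stratified) split and evaluates the full metric panel
#' on the held-out part, repeated `n_splits` times (30 in the reference
#' protocol).
#'
#' @param n_splits Number of random splits, default 30.
#' @param train_size,test_size Observations per split;
#'   `train_size + test_size` must not exceed the dataset size.
#' @param stratified Stratify the split by label, default TRUE.
#' @param seed Seed; split `i` is reproducible from `(seed, i)`.
#' @return A list of class `split_plan`.
#' @export
split_plan <- function(n_splits = 30, train_size, test_size,
                       stratified = TRUE, seed = NULL) {
  stopifnot(n_splits >= 1, train_size >= 2, test_size >= 1)
  structure(list(n_splits = as.integer(n_splits),
                 train_size = as.integer(train_size),
                 test_size = as.integer(test_size),
                 stratified = stratified, seed = seed),
            class = "split_plan")
}

# Draw one train/test split of the requested sizes. Stratification
# allocates both sets proportionally to class prevalence (largest
# remainder), keeping test prevalence within one observation of the
# sample's.
draw_split <- function(labels, plan, index) {
  seed <- if (is.null(plan$seed)) NULL else plan$seed + index
  with_seed(seed, {
    n <- length(labels)
    if (plan$train_size + plan$test_size > n) {
      stop("split plan larger than the dataset", call. = FALSE)
    }
    if (!plan$stratified) {
      idx <- sample(n, plan$train_size + plan$test_size)
      return(list(train = idx[seq_len(plan$train_size)],
                  test = idx[-seq_len(plan$train_size)]))
    }
    pos <- which(labels == 1L)
    neg <- which(labels == 0L)
    prev <- length(pos) / n
    tr_pos <- min(max(round(plan$train_size * prev), 1L),
                  length(pos) - 1L)
    tr_neg <- plan$train_size - tr_pos
    if (tr_neg > length(neg)) {
      stop("split plan incompatible with class counts", call. = FALSE)
    }
    te_pos <- min(max(round(plan$test_size * prev), 1L),
                  length(pos) - tr_pos)
    te_neg <- plan$test_size - te_pos
    if (te_neg > length(neg) - tr_neg) {
      te_neg <- length(neg) - tr_neg
      te_pos <- plan$test_size - te_neg
      if (te_pos > length(pos) - tr_pos) {
        stop("split plan incompatible with class counts", call. = FALSE)
      }
    }
    pos <- sample(pos)
    neg <- sample(neg)
    list(
      train = c(pos[seq_len(tr_pos)], neg[seq_len(tr_neg)]),
      test = c(pos[tr_pos + seq_len(te_pos)], neg[tr_neg + seq_len(te_neg)])
    )
  })
}

#' Evaluate model specifications over repeated random splits
#'
#' For each split of `plan` and each entry of `model_specs`, trains on the
#' split's training part and computes the held-out metric panel: AUC,
#' F-score, sensitivity, specificity, Brier score, and the HL-C statistic
#' and p-value. A split on which a model cannot be trained (e.g. a
#' degenerate single-class draw) is recorded as a row of `NA`s with the
#' failure reason, and the run continues.
#'
#' @param data A [labeled_dataset()].
#' @param plan A [split_plan()].
#' @param model_specs Named list of specs, each a list with `model_kind`
#'   and optionally `c_hinge`, `c_squared`.
#' @param config A [train_config()].
#' @return A data frame with one row per (split, model), columns `split`,
#'   `model`, the panel metrics, and `note`.
#' @export
repeated_splits_eval <- function(data, plan, model_specs,
                                 config = train_config()) {
  data <- as_labeled_dataset(data)
  if (is.null(names(model_specs)) || any(names(model_specs) == "")) {
    names(model_specs) <- paste0("model_", seq_along(model_specs))
  }
  na_row <- function(i, name, reason) {
    data.frame(split = i, model = name, auc = NA_real_,
               f_score = NA_real_, sensitivity = NA_real_,
               specificity = NA_real_, brier = NA_real_,
               hlc_stat = NA_real_, hlc_p = NA_real_,
               note = reason, stringsAsFactors = FALSE)
  }
  rows <- list()
  for (i in seq_len(plan$n_splits)) {
    split <- tryCatch(draw_split(data$labels, plan, i),
                      error = function(e) conditionMessage(e))
    if (is.character(split)) {
      for (name in names(model_specs)) {
        rows[[length(rows) + 1L]] <- na_row(i, name, split)
      }
      next
    }
    tr <- dataset_subset(data, split$train)
    te <- dataset_subset(data, split$test)
    for (name in names(model_specs)) {
      row <- tryCatch({
        model <- suppressWarnings(train_spec(tr, model_specs[[name]],
                                             config))
        m <- suppressWarnings(panel_metrics(model, te))
        data.frame(split = i, model = name, t(m), note = "",
                   stringsAsFactors = FALSE)
      }, error = function(e) na_row(i, name, conditionMessage(e)))
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' One-tailed paired t-test
#'
#' Tests whether `mean(a) > mean(b)` from paired observations, as used to
#' compare per-split metric columns between models. Degenerate difference
#' vectors follow explicit conventions: all-zero differences give
#' `t = 0, p = 0.5` with a warning; constant non-zero differences give
#' `p = 0` or `1` by sign.
#'
#' @param a,b Paired numeric vectors of equal length (at least 2).
#' @return A list with `t`, `df` and the one-tailed `p`.
#' @export
paired_ttest_one_tailed <- function(a, b) {
  if (length(a) != length(b) || length(a) < 2L) {
    stop("a and b must be paired vectors of length >= 2", call. = FALSE)
  }
  d <- a - b
  n <- length(d)
  if (stats::sd(d) == 0) {
    if (all(d == 0)) {
      warning("all paired differences are zero", call. = FALSE)
      return(list(t = 0, df = n - 1L, p = 0.5))
    }
    return(list(t = sign(mean(d)) * Inf, df = n - 1L,
                p = if (mean(d) > 0) 0 else 1))
  }
  t_stat <- mean(d) / (stats::sd(d) / sqrt(n))
  list(t = t_stat, df = n - 1L,
       p = stats::pt(t_stat, df = n - 1L, lower.tail = FALSE))
}

#' Rank features by two-sample t statistics
#'
#' Orders features by the absolute Welch t statistic between classes and
#' returns the indices of the strongest `top_k` (15 in the reference
#' protocol, which keeps the top 15 genes of a microarray by t-test).
#' Zero-variance features are handled with a variance floor of 1e-12;
#' ties break by feature index.
#'
#' @param data A [labeled_dataset()].
#' @param top_k Number of features to keep, default 15.
#' @return Integer vector of feature indices, strongest first.
#' @export
ttest_feature_rank <- function(data, top_k = 15) {
  data <- as_labeled_dataset(data)
  check_both_classes(data$labels, "ttest_feature_rank")
  if (data$d < top_k) {
    stop("top_k exceeds the number of features", call. = FALSE)
  }
  pos <- data$features[data$labels == 1L, , drop = FALSE]
  neg <- data$features[data$labels == 0L, , drop = FALSE]
  v_pos <- pmax(apply(pos, 2L, stats::var), 1e-12)
  v_neg <- pmax(apply(neg, 2L, stats::var), 1e-12)
  t_stat <- (colMeans(pos) - colMeans(neg)) /
    sqrt(v_pos / nrow(pos) + v_neg / nrow(neg))
  ord <- order(-abs(t_stat), seq_along(t_stat))
  ord[seq_len(top_k)]
}
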