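# Independent brute-force oracles used to check the fast implementations.

# AUC by explicit pair enumeration, ties counted one half.
auc_brute <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  mean(outer(pos, neg, ">") + 0.5 * outer(pos, neg, "=="))
}

# ROC by exhaustive threshold enumeration (predict positive at >= t).
roc_brute <- function(scores, labels) {
  thresholds <- c(Inf, sort(unique(scores), decreasing = TRUE))
  fpr <- sapply(thresholds, function(t) {
    mean(scores[labels == 0] >= t)
  })
  tpr <- sapply(thresholds, function(t) {
    mean(scores[labels == 1] >= t)
  })
  list(fpr = fpr, tpr = tpr)
}

# Random scored predictions with both classes and grouped (tied) scores.
random_grouped_preds <- function(n = 30, n_levels = 8) {
  repeat {
    labels <- rbinom(n, 1, runif(1, 0.2, 0.8))
    if (length(unique(labels)) == 2) break
  }
  # score levels on an exact binary grid so float grouping is exact
  levels <- sample(seq(0, 64, by = 1), n_levels) / 64
  scores <- sample(levels, n, replace = TRUE)
  scored_predictions(scores, labels)
}

# Grouped instance whose between-group ranking is concordant: realized
# group event fractions non-decreasing in the group score (the sorted
# score values are assigned to groups in order of realized fraction).
concordant_grouped_preds <- function(max_groups = 5) {
  k <- sample(2:max_groups, 1)
  s <- sort(sample(1:63, k)) / 64
  n_g <- sample(2:8, k, replace = TRUE)
  o_g <- rbinom(k, n_g, runif(k))
  ord <- order(o_g / n_g)
  n_g <- n_g[ord]
  o_g <- o_g[ord]
  labels <- unlist(mapply(function(n, o) c(rep(1, o), rep(0, n - o)),
                          n_g, o_g, SIMPLIFY = FALSE))
  scores <- rep(s, n_g)
  if (length(unique(labels)) < 2) return(NULL)
  scored_predictions(scores, labels)
}

make_gaussian_dataset <- function(n = 200, d = 3, delta = 2, seed = 1) {
  sim <- gen_gaussian_classes(n, d, delta, seed = seed)
  labeled_dataset(sim$features, sim$labels)
}

quiet_train <- function(...) suppressWarnings(train(...))
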