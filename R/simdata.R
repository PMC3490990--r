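# Seeded synthetic generators for the calibration/discrimination
# phenomena, plus the tradeoff sweep experiment.

new_simulated_sample <- function(features = NULL, scores = NULL, labels,
                                 truth) {
  structure(
    list(features = features, scores = scores,
         labels = check_binary_labels(labels), truth = truth),
    class = "simulated_sample"
  )
}

#' @export
print.simulated_sample <- function(x, ...) {
  cat("Simulated sample:", length(x$labels), "observations;",
      sum(x$labels), "positive\n")
  if (!is.null(x$truth$generator)) {
    cat("  generator:", x$truth$generator, "\n")
  }
  invisible(x)
}

#' Perfectly calibrated scores from complementary triangular densities
#'
#' Draws labels from `Bernoulli(prior)` and scores from the unique
#' complementary pair of triangular beta densities on `[0, 1]`: positives
#' from the increasing density `2s` (Beta(2,1)), negatives from the
#' decreasing density `2(1 - s)` (Beta(1,2)), realized as the max and min
#' of a uniform pair. With `prior = 0.5` the posterior equals the score,
#' `P(y = 1 | s) = s`, so the model is perfectly calibrated in
#' expectation, yet its AUC is capped at `P(S+ > S-) = 5/6` (0.83): the
#' Diamond bound on a perfectly, non-trivially calibrated model.
#'
#' @param n Number of observations.
#' @param prior Probability of the positive class, default 0.5 (the value
#'   at which perfect calibration holds).
#' @param seed Optional RNG seed.
#' @return A `simulated_sample` with `scores`, `labels`, and `truth`
#'   recording the generator, `prior`, and the analytic `auc = 5/6`.
#' @export
gen_triangular_beta <- function(n, prior = 0.5, seed = NULL) {
  stopifnot(n >= 1, prior > 0, prior < 1)
  with_seed(seed, {
    labels <- stats::rbinom(n, 1L, prior)
    u1 <- stats::runif(n)
    u2 <- stats::runif(n)
    scores <- ifelse(labels == 1L, pmax(u1, u2), pmin(u1, u2))
    new_simulated_sample(
      scores = scores, labels = labels,
      truth = list(generator = "triangular_beta", prior = prior,
                   auc = triangular_beta_auc(), seed = seed)
    )
  })
}

#' Analytic AUC of the complementary triangular pair
#'
#' Computes `P(S+ > S-)` for independent `S+ ~ 2s` and `S- ~ 2(1 - t)` on
#' `[0, 1]` by integrating `f+(s) P(S- < s)` over the unit interval; the
#' value is 5/6, which prints as 0.83 at two decimals.
#'
#' @return The concordance probability (a number close to 5/6 up to
#'   quadrature error).
#' @export
triangular_beta_auc <- function() {
  # P(S- < s) = 1 - (1 - s)^2
  stats::integrate(function(s) 2 * s * (1 - (1 - s)^2), 0, 1,
                   rel.tol = 1e-12)$value
}

#' Shrink probability scores by a constant factor
#'
#' Dividing every score by `factor` (10 in the motivating example) leaves
#' every rank-based quantity, hence the ROC curve and the AUC, unchanged,
#' while destroying calibration: the returned scores systematically
#' understate the event rate.
#'
#' @param scores Probability scores in `[0, 1]`.
#' @param factor Shrinkage factor, at least 1; default 10.
#' @return `scores / factor`.
#' @export
shrink_scores <- function(scores, factor = 10) {
  scores <- check_probability_scores(scores)
  if (factor < 1) {
    stop("factor must be at least 1", call. = FALSE)
  }
  scores / factor
}

#' Class-conditional Gaussian features
#'
#' Spherical unit-variance Gaussian features in d dimensions, with the
#' positive class shifted by `delta` along the first axis. The true
#' posterior is logistic in the first coordinate,
#' `P(y=1|x) = plogis(delta x1 - delta^2/2 + logit(prior))`, so the
#' Bayes-calibrated score is known in closed form and recorded in `truth`
#' (as `bayes_scores`), along with the analytic AUC of the Bayes score,
#' `pnorm(delta / sqrt(2))`.
#'
#' @param n Number of observations (at least 2).
#' @param d Number of features (at least 1).
#' @param delta Mean separation along the first axis, non-negative.
#' @param prior Probability of the positive class, default 0.5.
#' @param seed Optional RNG seed.
#' @return A `simulated_sample` with `features`, `labels`, and a `truth`
#'   record.
#' @export
gen_gaussian_classes <- function(n, d, delta, prior = 0.5, seed = NULL) {
  stopifnot(n >= 2, d >= 1, delta >= 0, prior > 0, prior < 1)
  with_seed(seed, {
    labels <- stats::rbinom(n, 1L, prior)
    x <- matrix(stats::rnorm(n * d), nrow = n, ncol = d)
    x[, 1L] <- x[, 1L] + delta * labels
    bayes <- stats::plogis(delta * x[, 1L] - delta^2 / 2 +
                             stats::qlogis(prior))
    new_simulated_sample(
      features = x, labels = labels,
      truth = list(generator = "gaussian_classes", prior = prior,
                   delta = delta, analytic_auc = stats::pnorm(delta / sqrt(2)),
                   bayes_scores = bayes, seed = seed)
    )
  })
}

#' Grouped scores: perfectly calibrated, imperfectly discriminative
#'
#' Each group g emits identical scores equal to its `group_probs[g]` and
#' labels drawn `Bernoulli(group_probs[g])`: calibrated by construction,
#' but any group with probability strictly between 0 and 1 is mixed and
#' forces tied (hence half-discordant) positive-negative pairs. Features
#' are the one-hot group indicators (identical rows within a group), which
#' is the fixture for the calibration-pull property of the joint learner:
#' with a dominant squared-loss penalty its per-group prediction converges
#' to the group's positive fraction.
#'
#' @param group_sizes Integer vector of group sizes.
#' @param group_probs Per-group event probabilities in `[0, 1]`.
#' @param seed Optional RNG seed.
#' @return A `simulated_sample` with `features` (one-hot), `scores`,
#'   `labels`, and a `truth` record including the analytic refinement
#'   `sum(n_g p_g (1 - p_g)) / N`.
#' @export
gen_grouped_bins <- function(group_sizes, group_probs, seed = NULL) {
  stopifnot(length(group_sizes) == length(group_probs),
            all(group_sizes >= 1),
            all(group_probs >= 0 & group_probs <= 1))
  with_seed(seed, {
    g <- length(group_sizes)
    group_id <- rep(seq_len(g), group_sizes)
    scores <- group_probs[group_id]
    labels <- stats::rbinom(length(group_id), 1L, scores)
    features <- matrix(0, nrow = length(group_id), ncol = g,
                       dimnames = list(NULL, paste0("group", seq_len(g))))
    features[cbind(seq_along(group_id), group_id)] <- 1
    new_simulated_sample(
      features = features, scores = scores, labels = labels,
      truth = list(generator = "grouped_bins", group_sizes = group_sizes,
                   group_probs = group_probs, group_id = group_id,
                   analytic_ref = sum(group_sizes * group_probs *
                                        (1 - group_probs)) /
                     sum(group_sizes),
                   seed = seed)
    )
  })
}

#' Scores with a target AUC from the binormal model
#'
#' Generates label-conditional scores whose population AUC equals
#' `target_auc`, using equal-variance Gaussians on the probit scale
#' (separation `sqrt(2) * qnorm(target_auc)`) mapped through `pnorm` onto
#' `[0, 1]`. A stand-in for "models sampled at AUCs close to a given
#' value"; no calibration guarantee is implied.
#'
#' @param n Number of observations.
#' @param target_auc Desired population AUC in `(0, 1)`.
#' @param prior Probability of the positive class, default 0.5.
#' @param seed Optional RNG seed.
#' @return A `simulated_sample` with `scores`, `labels`, `truth`.
#' @export
gen_target_auc <- function(n, target_auc, prior = 0.5, seed = NULL) {
  stopifnot(n >= 1, target_auc > 0, target_auc < 1, prior > 0, prior < 1)
  with_seed(seed, {
    labels <- stats::rbinom(n, 1L, prior)
    mu <- sqrt(2) * stats::qnorm(target_auc)
    scores <- stats::pnorm(stats::rnorm(n) + mu * labels - mu / 2)
    new_simulated_sample(
      scores = scores, labels = labels,
      truth = list(generator = "target_auc", target_auc = target_auc,
                   prior = prior, seed = seed)
    )
  })
}

#' Sweep the squared-loss penalty and chart the tradeoff
#'
#' Splits `base_data` into a training and a held-out half, trains a
#' DOC-SVM at each value of `c2_grid` with `c1` fixed, and records the
#' held-out AUC, HL-C statistic and p-value, and Brier score per point.
#' On data where a linear score can be made either well-ranked or
#' well-calibrated but not maximally both, the HL-C p-value across the
#' sweep rises and then falls: an interior calibration optimum, the
#' qualitative tradeoff phenomenon.
#'
#' @param base_data A `simulated_sample` with features (e.g. from
#'   [gen_gaussian_classes()]).
#' @param c2_grid Values of the squared-loss penalty to sweep.
#' @param c1 Fixed hinge penalty, default 1.
#' @param config A [train_config()].
#' @param holdout Fraction of observations held out for evaluation,
#'   default 0.5.
#' @param seed Seed for the train/holdout split.
#' @return A data frame sorted by `c2` with columns `c2`, `auc`,
#'   `hlc_stat`, `hlc_p`, `brier`, `note` (non-empty when a grid point
#'   failed and was skipped).
#' @export
tradeoff_sweep <- function(base_data, c2_grid, c1 = 1,
                           config = train_config(), holdout = 0.5,
                           seed = NULL) {
  if (is.null(base_data$features)) {
    stop("base_data must carry features", call. = FALSE)
  }
  if (length(c2_grid) == 0L) stop("c2_grid must be non-empty", call. = FALSE)
  data <- labeled_dataset(base_data$features, base_data$labels)
  n_test <- max(1L, round(data$n * holdout))
  plan <- split_plan(n_splits = 1L, train_size = data$n - n_test,
                     test_size = n_test, stratified = TRUE, seed = seed)
  split <- draw_split(data$labels, plan, 1L)
  tr <- dataset_subset(data, split$train)
  te <- dataset_subset(data, split$test)
  c2_grid <- sort(c2_grid)
  rows <- lapply(c2_grid, function(c2) {
    tryCatch({
      model <- suppressWarnings(
        train(tr, "docsvm", c_hinge = c1, c_squared = c2, config = config)
      )
      m <- suppressWarnings(panel_metrics(model, te))
      data.frame(c2 = c2, auc = m[["auc"]], hlc_stat = m[["hlc_stat"]],
                 hlc_p = m[["hlc_p"]], brier = m[["brier"]], note = "",
                 stringsAsFactors = FALSE)
    }, error = function(e) {
      data.frame(c2 = c2, auc = NA_real_, hlc_stat = NA_real_,
                 hlc_p = NA_real_, brier = NA_real_,
                 note = conditionMessage(e), stringsAsFactors = FALSE)
    })
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
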