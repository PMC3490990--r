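cv_config <- train_config(max_iters = 250)

test_that("cross-validation is deterministic and respects the grid", {
  ds <- make_gaussian_dataset(n = 80, d = 2, delta = 2, seed = 61)
  grid1 <- data.frame(c_hinge = 1, c_squared = 0.5)
  one <- suppressWarnings(kfold_cv(ds, "docsvm", grid1, k = 4, seed = 61,
                                   config = cv_config))
  expect_equal(one$best, grid1)

  grid <- data.frame(c_hinge = c(0.1, 1), c_squared = c(0.1, 1))
  a <- suppressWarnings(kfold_cv(ds, "docsvm", grid, k = 4, seed = 62,
                                 config = cv_config))
  b <- suppressWarnings(kfold_cv(ds, "docsvm", grid, k = 4, seed = 62,
                                 config = cv_config))
  expect_identical(a$best, b$best)
  expect_identical(a$per_point, b$per_point)
  expect_true(all(vapply(a$per_point, nrow, 1L) == 7))
})

test_that("stratified folds partition the data and retain both classes", {
  set.seed(63)
  labels <- rbinom(57, 1, 0.3)
  labels[1:2] <- c(0, 1)
  fold <- docsvm:::stratified_folds(labels, k = 5, seed = 63)
  expect_equal(sort(unique(fold)), 1:5)
  expect_equal(length(fold), 57)
  # every index in exactly one fold, prevalence balanced within 1
  for (f in 1:5) {
    expect_true(all(table(labels[fold == f]) >= 1))
  }
  pos_per_fold <- tapply(labels, fold, sum)
  expect_lte(diff(range(pos_per_fold)), 1)
})

test_that("brier-guided selection enforces more calibration than auc-guided", {
  # single miscalibrated-but-well-ranked feature: every positive weight
  # ranks identically, so the auc criterion ties and prefers small C2,
  # while the brier criterion needs the squared loss to rescale the score
  grid <- data.frame(c_hinge = 1, c_squared = c(1e-3, 1, 100))
  picks <- sapply(1:3, function(i) {
    tb <- gen_triangular_beta(200, seed = 400 + i)
    ds <- labeled_dataset(matrix(shrink_scores(tb$scores, 10), ncol = 1),
                          tb$labels)
    cb <- suppressWarnings(kfold_cv(ds, "docsvm", grid, k = 5,
                                    criterion = "brier", seed = 400 + i,
                                    config = cv_config))
    ca <- suppressWarnings(kfold_cv(ds, "docsvm", grid, k = 5,
                                    criterion = "auc", seed = 400 + i,
                                    config = cv_config))
    c(cb$best$c_squared, ca$best$c_squared)
  })
  expect_true(all(picks[1, ] > picks[2, ]))
})

test_that("repeated splits evaluate every model on every split", {
  ds <- make_gaussian_dataset(n = 200, d = 3, delta = 2, seed = 64)
  plan <- split_plan(n_splits = 3, train_size = 100, test_size = 60,
                     seed = 64)
  specs <- list(doc = list(model_kind = "docsvm", c_hinge = 1,
                           c_squared = 1),
                doc_again = list(model_kind = "docsvm", c_hinge = 1,
                                 c_squared = 1))
  tab <- repeated_splits_eval(ds, plan, specs, config = cv_config)
  expect_equal(nrow(tab), 6)
  expect_equal(sort(unique(tab$model)), c("doc", "doc_again"))
  # identical specs give identical metric columns
  expect_equal(tab[tab$model == "doc", c("auc", "brier")],
               tab[tab$model == "doc_again", c("auc", "brier")],
               ignore_attr = TRUE)
})

test_that("stratified splits preserve prevalence within one observation", {
  ds <- make_gaussian_dataset(n = 150, d = 2, delta = 1, seed = 65)
  plan <- split_plan(n_splits = 10, train_size = 80, test_size = 50,
                     stratified = TRUE, seed = 65)
  prev <- mean(ds$labels)
  for (i in 1:10) {
    sp <- docsvm:::draw_split(ds$labels, plan, i)
    expect_equal(length(intersect(sp$train, sp$test)), 0)
    te_pos <- sum(ds$labels[sp$test])
    expect_lte(abs(te_pos - prev * 50), 1)
  }
})

test_that("30 random splits recover the generator's analytic AUC", {
  sim <- gen_gaussian_classes(600, 4, 2, seed = 7)
  ds <- labeled_dataset(sim$features, sim$labels)
  plan <- split_plan(n_splits = 30, train_size = 300, test_size = 200,
                     seed = 7)
  tab <- suppressWarnings(repeated_splits_eval(
    ds, plan, list(doc = list(model_kind = "docsvm", c_hinge = 1,
                              c_squared = 1)),
    config = train_config(max_iters = 400)))
  expect_equal(nrow(tab), 30)
  expect_lt(abs(mean(tab$auc) - sim$truth$analytic_auc),
            2 * sd(tab$auc))
})

test_that("the one-tailed paired t-test follows its conventions", {
  a <- c(1, 2, 3, 4)
  expect_warning(same <- paired_ttest_one_tailed(a, a), "zero")
  expect_equal(same$t, 0)
  expect_equal(same$p, 0.5)

  shifted <- paired_ttest_one_tailed(rep(1, 30) + 5, rep(1, 30))
  expect_equal(shifted$p, 0)
  expect_equal(paired_ttest_one_tailed(rep(0, 5), rep(2, 5))$p, 1)

  set.seed(66)
  for (i in 1:20) {
    x <- rnorm(25)
    y <- rnorm(25, 0.3)
    ours <- paired_ttest_one_tailed(x, y)
    ref <- t.test(x, y, paired = TRUE, alternative = "greater")
    expect_equal(ours$t, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(ours$p, ref$p.value, tolerance = 1e-10)
  }
})

test_that("t-test feature ranking finds the informative feature", {
  set.seed(67)
  n <- 120
  y <- rep(c(0, 1), n / 2)
  x <- matrix(rnorm(n * 10), ncol = 10)
  x[, 4] <- x[, 4] + 2 * y  # effect size two standard deviations
  ds <- labeled_dataset(x, y)
  expect_equal(ttest_feature_rank(ds, top_k = 1), 4)
  expect_setequal(ttest_feature_rank(ds, top_k = 10), 1:10)
  expect_error(ttest_feature_rank(ds, top_k = 11), "top_k")

  # label permutation destroys any systematic winner
  winners <- replicate(30, ttest_feature_rank(
    labeled_dataset(x, sample(y)), top_k = 1))
  expect_gt(length(unique(winners)), 3)

  # zero-variance feature handled by the variance floor
  x[, 2] <- 1
  expect_no_error(ttest_feature_rank(labeled_dataset(x, y), top_k = 10))
})
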