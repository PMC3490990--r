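test_that("generators are reproducible from their seed", {
  expect_identical(gen_triangular_beta(50, seed = 1),
                   gen_triangular_beta(50, seed = 1))
  expect_identical(gen_gaussian_classes(30, 3, 1.5, seed = 2),
                   gen_gaussian_classes(30, 3, 1.5, seed = 2))
  expect_identical(gen_grouped_bins(c(10, 20), c(0.2, 0.8), seed = 3),
                   gen_grouped_bins(c(10, 20), c(0.2, 0.8), seed = 3))
  expect_identical(gen_target_auc(40, 0.8, seed = 4),
                   gen_target_auc(40, 0.8, seed = 4))
  # and they restore the caller's RNG stream
  set.seed(99)
  before <- runif(1)
  set.seed(99)
  invisible(gen_triangular_beta(10, seed = 5))
  expect_identical(runif(1), before)
})

test_that("triangular-beta concordance approaches the 5/6 Diamond cap", {
  expect_equal(triangular_beta_auc(), 5 / 6, tolerance = 1e-9)
  s <- gen_triangular_beta(2e5, seed = 71)
  expect_equal(auc_mann_whitney(s$scores, s$labels), 5 / 6,
               tolerance = 0.01)
  # calibrated samples never rise far above the cap
  aucs <- sapply(1:100, function(i) {
    s <- gen_triangular_beta(1e4, seed = 600 + i)
    auc_mann_whitney(s$scores, s$labels)
  })
  expect_lt(max(aucs), 0.86)
})

test_that("triangular-beta samples are calibrated: diagonal reliability and quiet HL", {
  s3 <- gen_triangular_beta(1e3, seed = 11)
  s4 <- gen_triangular_beta(1e4, seed = 11)
  dev <- function(s) {
    b <- reliability_bins(scored_predictions(s$scores, s$labels))$bins
    max(abs(b$mean_pred - b$obs_frac))
  }
  expect_lt(dev(s4), dev(s3))
  expect_lt(dev(s4), 0.06)

  # calibrated null: HL-C fails to reject at 0.1 in most samples
  fit_ok <- sapply(1:60, function(i) {
    s <- gen_triangular_beta(5000, seed = 500 + i)
    hosmer_lemeshow(scored_predictions(s$scores, s$labels),
                    scheme = "C", g = 10)$p_value > 0.1
  })
  expect_gte(mean(fit_ok), 0.75)
})

test_that("score shrinkage keeps ranks but destroys calibration", {
  s <- gen_triangular_beta(800, seed = 72)
  shrunk <- shrink_scores(s$scores, 10)
  expect_identical(shrink_scores(s$scores, 1), s$scores)
  expect_error(shrink_scores(s$scores, 0.5), "at least 1")

  expect_equal(auc_mann_whitney(shrunk, s$labels),
               auc_mann_whitney(s$scores, s$labels))
  r1 <- roc_curve(s$scores, s$labels)
  r2 <- roc_curve(shrunk, s$labels)
  expect_equal(r1$fpr, r2$fpr)
  expect_equal(r1$tpr, r2$tpr)

  expect_gt(brier_score(shrunk, s$labels),
            brier_score(s$scores, s$labels))
  hl1 <- hosmer_lemeshow(scored_predictions(s$scores, s$labels),
                         scheme = "C")
  hl2 <- hosmer_lemeshow(scored_predictions(shrunk, s$labels),
                         scheme = "C")
  expect_gt(hl2$statistic, hl1$statistic)
})

test_that("gaussian classes match their closed-form Bayes AUC", {
  flat <- gen_gaussian_classes(4000, 3, delta = 0, seed = 73)
  # no separation: any fixed scorer is a coin toss
  expect_equal(auc_mann_whitney(flat$features[, 1], flat$labels), 0.5,
               tolerance = 0.03)
  expect_equal(flat$truth$analytic_auc, 0.5)

  sim <- gen_gaussian_classes(1e4, 2, delta = 1.5, seed = 74)
  expect_equal(sim$truth$analytic_auc, pnorm(1.5 / sqrt(2)))
  emp <- auc_mann_whitney(sim$truth$bayes_scores, sim$labels)
  expect_lt(abs(emp - sim$truth$analytic_auc), 0.015)  # ~3 MC sd

  # strong separation: trained model reaches near-perfect test AUC
  tr <- gen_gaussian_classes(400, 3, delta = 6, seed = 75)
  te <- gen_gaussian_classes(400, 3, delta = 6, seed = 76)
  fit <- quiet_train(labeled_dataset(tr$features, tr$labels), "docsvm",
                     c_hinge = 1, c_squared = 1,
                     config = train_config(max_iters = 500))
  expect_gt(auc_mann_whitney(predict_raw(fit, te$features), te$labels),
            0.99)
})

test_that("grouped bins are calibrated with closed-form refinement", {
  single <- gen_grouped_bins(1000, 0.5, seed = 77)
  expect_equal(auc_mann_whitney(single$scores, single$labels), 0.5)

  g <- gen_grouped_bins(c(500, 500), c(0.1, 0.9), seed = 78)
  d <- brier_decomposition(g$scores, g$labels)
  expect_equal(g$truth$analytic_ref, 0.09)
  expect_lt(d$cal, 0.01)
  expect_equal(d$ref, 0.09, tolerance = 0.015)

  pure <- gen_grouped_bins(c(50, 50), c(0, 1), seed = 79)
  expect_equal(auc_mann_whitney(pure$scores, pure$labels), 1)
  expect_equal(brier_decomposition(pure$scores, pure$labels)$ref, 0)
})

test_that("target-AUC generator hits its requested concordance", {
  for (target in c(0.6, 0.8, 0.95)) {
    s <- gen_target_auc(2e4, target, seed = 80)
    expect_equal(auc_mann_whitney(s$scores, s$labels), target,
                 tolerance = 0.02)
    expect_true(all(s$scores >= 0 & s$scores <= 1))
  }
})

test_that("the squared-penalty sweep exposes the tradeoff shape", {
  sim <- gen_gaussian_classes(600, 4, 3, seed = 201)
  tab <- tradeoff_sweep(sim, 10^seq(-3, 2, length.out = 8), c1 = 1,
                        config = train_config(max_iters = 800),
                        seed = 201)
  expect_equal(nrow(tab), 8)
  expect_true(!is.unsorted(tab$c2))
  expect_true(all(tab$note == ""))
  # calibration improves with the squared penalty: HL statistic trends down
  expect_lt(cor(tab$c2, tab$hlc_stat, method = "spearman"), 0)
  # and the HL-C p-value peaks strictly inside the sweep
  k <- which.max(tab$hlc_p)
  expect_gt(k, 1)
  expect_lt(k, nrow(tab))

  one <- tradeoff_sweep(sim, 1, c1 = 1,
                        config = train_config(max_iters = 200), seed = 201)
  expect_equal(nrow(one), 1)
})
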