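test_that("hinge loss evaluates margins as defined", {
  # 1-D identity models make the raw score equal the feature
  m <- linear_model(weights = 1, bias = 0, c_hinge = 1, c_squared = 1)
  ds <- labeled_dataset(matrix(c(2, 0, -0.5), ncol = 1), c(1, 0, 1))
  expect_equal(hinge_loss_vector(m, ds), c(0, 1, 1.5))
})

test_that("the joint objective matches hand computation and reductions", {
  ds <- labeled_dataset(matrix(c(1, -1), ncol = 1), c(1, 0))
  zero <- linear_model(0, 0, c_hinge = 1, c_squared = 1)
  # 0 + 2 hinge losses of 1 + squared losses (0-1)^2 + (0-0)^2 = 3
  expect_equal(docsvm_objective(zero, ds), 3)

  w <- linear_model(c(0.4, -0.2), 0.1, c_hinge = 2, c_squared = 0)
  ds2 <- make_gaussian_dataset(n = 20, d = 2, seed = 51)
  svm_obj <- 0.5 * sum(w$weights^2) +
    2 * sum(hinge_loss_vector(w, ds2))
  expect_equal(docsvm_objective(w, ds2), svm_obj)

  reg_only <- linear_model(c(3, 4), 1, c_hinge = 0, c_squared = 0)
  expect_equal(docsvm_objective(reg_only, ds2), 12.5)

  expect_error(linear_model(1, 0, c_hinge = -1), "non-negative")
})

test_that("the objective is convex along parameter segments", {
  set.seed(52)
  ds <- make_gaussian_dataset(n = 40, d = 3, seed = 52)
  for (i in 1:25) {
    a <- linear_model(rnorm(3), rnorm(1), c_hinge = 0.7, c_squared = 0.3)
    b <- linear_model(rnorm(3), rnorm(1), c_hinge = 0.7, c_squared = 0.3)
    lam <- runif(1)
    mid <- linear_model(lam * a$weights + (1 - lam) * b$weights,
                        lam * a$bias + (1 - lam) * b$bias,
                        c_hinge = 0.7, c_squared = 0.3)
    expect_lte(docsvm_objective(mid, ds),
               lam * docsvm_objective(a, ds) +
                 (1 - lam) * docsvm_objective(b, ds) + 1e-10)
  }
})

test_that("raw predictions are the affine map of the features", {
  m <- linear_model(c(0, 0), 0.3)
  x <- matrix(rnorm(10), ncol = 2)
  expect_equal(predict_raw(m, x), rep(0.3, 5))

  m2 <- linear_model(c(2, 0), 0)
  expect_equal(predict_raw(m2, matrix(c(1, 0), ncol = 2)), 2)

  set.seed(53)
  for (i in 1:20) {
    w <- rnorm(4)
    b <- rnorm(1)
    x <- matrix(rnorm(24), ncol = 4)
    m3 <- linear_model(w, b)
    oracle <- apply(x, 1, function(r) sum(r * w) + b)
    expect_equal(predict_raw(m3, x), oracle, tolerance = 1e-12)
  }
  expect_error(predict_raw(m2, matrix(1, ncol = 3, nrow = 1)),
               "dimension")
})

test_that("probability read-outs follow the model kind", {
  doc <- linear_model(1, 0, model_kind = "docsvm")
  expect_equal(predict_proba(doc, matrix(1.7)), 1)   # clipped from 1.7
  expect_equal(predict_proba(doc, matrix(-0.2)), 0)  # clipped from -0.2
  expect_equal(predict_proba(doc, matrix(0.4)), 0.4)

  lr <- linear_model(1, 0, model_kind = "logreg", c_hinge = 0)
  expect_equal(predict_proba(lr, matrix(0)), 0.5)

  svm <- linear_model(1, 0, model_kind = "svm", c_squared = 0)
  expect_error(predict_proba(svm, matrix(0.5)), "calibrate first")
})

test_that("training solves separable data and never increases the best objective", {
  ds <- make_gaussian_dataset(n = 120, d = 2, delta = 8, seed = 54)
  fit <- quiet_train(ds, "docsvm", c_hinge = 1, c_squared = 1,
                     config = train_config(max_iters = 600))
  expect_equal(
    auc_mann_whitney(predict_raw(fit, ds$features), ds$labels), 1)
  expect_true(all(is.finite(fit$trace)))
  expect_lte(min(fit$trace), fit$trace[1])
  # returned parameters achieve the best traced objective
  expect_equal(docsvm_objective(fit, ds), min(fit$trace),
               tolerance = 1e-10)

  expect_error(train(labeled_dataset(matrix(1:4, ncol = 1),
                                     c(1, 1, 1, 1)), "docsvm"),
               "both classes")
})

test_that("DOC-SVM with zero squared penalty reproduces the SVM trajectory", {
  ds <- make_gaussian_dataset(n = 100, d = 3, delta = 2, seed = 55)
  cfg <- train_config(max_iters = 300)
  doc <- quiet_train(ds, "docsvm", c_hinge = 1, c_squared = 0, cfg)
  svm <- quiet_train(ds, "svm", c_hinge = 1, c_squared = 0, cfg,
                     platt = FALSE)
  expect_identical(doc$trace, svm$trace)
  expect_identical(doc$weights, svm$weights)
  expect_identical(doc$bias, svm$bias)
})

test_that("a dominant squared penalty calibrates grouped predictions", {
  g <- gen_grouped_bins(c(700, 700, 600), c(0.2, 0.5, 0.8), seed = 56)
  ds <- labeled_dataset(g$features, g$labels)
  fit <- quiet_train(ds, "docsvm", c_hinge = 1, c_squared = 100)
  p <- predict_proba(fit, g$features)
  rho <- tapply(g$labels, g$truth$group_id, mean)
  pred <- tapply(p, g$truth$group_id, mean)
  expect_lt(max(abs(rho - pred)), 0.02)
})

test_that("Platt scaling fits a monotone sigmoid with smoothed targets", {
  set.seed(57)
  y <- rep(c(1, 0), each = 30)
  a <- abs(rnorm(30)) + 0.5
  f <- c(a, -a)  # exactly antisymmetric, balanced classes
  ps <- platt_fit(f, y)
  expect_lt(ps$A, 0)          # higher score, higher probability
  expect_lt(abs(ps$B), 1e-4)  # symmetric likelihood centres the sigmoid

  prob <- 1 / (1 + exp(ps$A * f + ps$B))
  expect_equal(auc_mann_whitney(prob, y), auc_mann_whitney(f, y))

  expect_warning(cs <- platt_fit(rep(0.7, 20), rep(c(1, 0), 10)),
                 "constant")
  expect_equal(cs$A, 0)
  p_const <- 1 / (1 + exp(cs$B))
  expect_equal(p_const, mean(c(rep(11 / 12, 10), rep(1 / 12, 10))))
})

test_that("logistic training matches the analytic and reference fits", {
  # intercept-only data: fitted probability is the prevalence
  ds0 <- labeled_dataset(matrix(0, nrow = 10, ncol = 1),
                         c(rep(1, 3), rep(0, 7)))
  lr0 <- logreg_train(ds0, l2 = 0)
  expect_equal(predict_proba(lr0, ds0$features), rep(0.3, 10),
               tolerance = 1e-6)

  ds <- make_gaussian_dataset(n = 150, d = 3, delta = 1.5, seed = 58)
  lr <- logreg_train(ds, l2 = 0,
                     config = train_config(max_iters = 1000,
                                           standardize = FALSE))
  ref <- glm(ds$labels ~ ds$features, family = binomial)
  expect_lt(max(abs(predict_proba(lr, ds$features) - fitted(ref))), 1e-4)
  expect_gt(length(lr$trace), 0)

  # heavy regularization collapses probabilities to the prevalence
  lr_inf <- logreg_train(ds, l2 = 1e4,
                         config = train_config(max_iters = 2000,
                                               tol = 1e-12))
  expect_equal(predict_proba(lr_inf, ds$features),
               rep(mean(ds$labels), ds$n), tolerance = 1e-2)
})

test_that("svm training attaches Platt parameters for probabilities", {
  ds <- make_gaussian_dataset(n = 100, d = 2, delta = 2, seed = 59)
  svm <- quiet_train(ds, "svm", c_hinge = 1,
                     config = train_config(max_iters = 300))
  expect_false(is.null(svm$platt))
  p <- predict_proba(svm, ds$features)
  expect_true(all(p >= 0 & p <= 1))
  expect_equal(auc_mann_whitney(p, ds$labels),
               auc_mann_whitney(predict_raw(svm, ds$features), ds$labels))
})
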