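#' Linear model container
#'
#' Holds the weight vector, bias and hyperparameters of a trained (or
#' hand-specified) linear classifier, together with the optimization trace
#' and optional Platt sigmoid parameters. Three kinds are supported:
#' `"docsvm"` (joint hinge + squared loss; probabilities by clipping the
#' raw score to `[0, 1]`), `"svm"` (hinge only, `c_squared` forced to 0;
#' probabilities require Platt scaling) and `"logreg"` (logistic loss;
#' probabilities via the logistic link).
#'
#' @param weights Numeric weight vector, length d.
#' @param bias Intercept.
#' @param model_kind One of `"docsvm"`, `"svm"`, `"logreg"`.
#' @param c_hinge Hinge-loss penalty \eqn{C_1 \ge 0}.
#' @param c_squared Squared-loss penalty \eqn{C_2 \ge 0}.
#' @param trace Per-iteration objective values (may be empty for a
#'   hand-built model).
#' @param platt Optional `c(A, B)` Platt sigmoid parameters.
#' @param center,scale Optional feature standardization parameters applied
#'   before the dot product (stored by [train()] when
#'   `standardize = TRUE`).
#' @param converged Logical: did training meet its tolerance?
#' @param warning_flag Logical: was a degraded-mode fallback used?
#' @return An object of class `linear_model`.
#' @export
linear_model <- function(weights, bias, model_kind = "docsvm",
                         c_hinge = 1, c_squared = 1, trace = numeric(),
                         platt = NULL, center = NULL, scale = NULL,
                         converged = NA, warning_flag = FALSE) {
  weights <- as.numeric(weights)
  if (anyNA(weights) || any(!is.finite(weights)) || !is.finite(bias)) {
    stop("weights and bias must be finite", call. = FALSE)
  }
  model_kind <- match.arg(model_kind, c("docsvm", "svm", "logreg"))
  if (c_hinge < 0 || c_squared < 0) {
    stop("penalty parameters must be non-negative", call. = FALSE)
  }
  if (model_kind == "svm" && c_squared != 0) {
    stop("an svm model must have c_squared = 0", call. = FALSE)
  }
  structure(
    list(weights = weights, bias = as.numeric(bias),
         model_kind = model_kind, c_hinge = c_hinge,
         c_squared = c_squared, trace = as.numeric(trace), platt = platt,
         center = center, scale = scale, converged = converged,
         warning_flag = warning_flag),
    class = "linear_model"
  )
}

#' @export
print.linear_model <- function(x, ...) {
  cat(sprintf("%s linear model: %d features, C1 = %g, C2 = %g\n",
              x$model_kind, length(x$weights), x$c_hinge, x$c_squared))
  if (length(x$trace)) {
    cat(sprintf("  trained %d iterations, final objective %.6g%s\n",
                length(x$trace), x$trace[length(x$trace)],
                if (isTRUE(x$converged)) " (converged)" else ""))
  }
  if (!is.null(x$platt)) {
    cat(sprintf("  Platt sigmoid: A = %.4f, B = %.4f\n",
                x$platt[1], x$platt[2]))
  }
  invisible(x)
}

#' Training configuration
#'
#' Settings of the deterministic full-batch subgradient descent used by
#' [train()]. The step size at iteration t is
#' `eta0 / (L * (1 + decay * t))` where `L` is a gradient-scale constant
#' computed from the data and penalties (see the methods vignette), so
#' that the same nominal `eta0` is usable across penalty magnitudes.
#'
#' @param max_iters Maximum iterations, default 2000.
#' @param eta0 Initial nominal step size, default 0.1.
#' @param decay Step decay rate, default 0.01.
#' @param tol Stopping tolerance on the relative objective change,
#'   default 1e-8.
#' @param standardize Z-score features before training (parameters stored
#'   in the model for test-time reuse), default TRUE.
#' @param seed Optional RNG seed recorded for provenance; training itself
#'   is deterministic (zero initialization, full batches).
#' @return A list of class `train_config`.
#' @export
train_config <- function(max_iters = 2000, eta0 = 0.1, decay = 0.01,
                         tol = 1e-8, standardize = TRUE, seed = NULL) {
  stopifnot(max_iters >= 1, eta0 > 0, decay >= 0, tol >= 0)
  structure(list(max_iters = as.integer(max_iters), eta0 = eta0,
                 decay = decay, tol = tol, standardize = standardize,
                 seed = seed),
            class = "train_config")
}

# Apply a model's stored standardization to a raw feature matrix.
model_view <- function(model, features) {
  features <- as.matrix(features)
  storage.mode(features) <- "double"
  if (ncol(features) != length(model$weights)) {
    stop("feature dimension does not match the model", call. = FALSE)
  }
  if (!is.null(model$center)) {
    features <- sweep(features, 2L, model$center, "-")
    features <- sweep(features, 2L, model$scale, "/")
  }
  features
}

#' Raw decision scores of a linear model
#'
#' Computes `w . x + b` per row, after applying any standardization stored
#' in the model.
#'
#' @param model A [linear_model()].
#' @param features Feature matrix with the model's dimensionality.
#' @return Numeric vector of raw scores.
#' @export
predict_raw <- function(model, features) {
  x <- model_view(model, features)
  as.vector(x %*% model$weights) + model$bias
}

#' Predicted probabilities of a linear model
#'
#' The probability read-out depends on the model kind: DOC-SVM scores are
#' already on the probability scale up to clipping, so they are clipped to
#' `[0, 1]`; logistic models use the logistic link; SVM scores carry no
#' probability scale and must be Platt-scaled first ([platt_fit()]).
#' `method` overrides the model's default read-out.
#'
#' @inheritParams predict_raw
#' @param method `NULL` (model default), `"clip"`, `"logistic"`, or
#'   `"platt"`.
#' @return Numeric vector of probabilities in `[0, 1]`.
#' @export
predict_proba <- function(model, features, method = NULL) {
  raw <- predict_raw(model, features)
  method <- method %||% switch(model$model_kind,
                               docsvm = "clip",
                               svm = "platt",
                               logreg = "logistic")
  switch(method,
    clip = pmin(pmax(raw, 0), 1),
    logistic = stats::plogis(raw),
    platt = {
      if (is.null(model$platt)) {
        stop("calibrate first: no Platt parameters in this model",
             call. = FALSE)
      }
      1 / (1 + exp(model$platt[1] * raw + model$platt[2]))
    },
    stop("unknown probability method: ", method, call. = FALSE)
  )
}

#' Per-example hinge loss
#'
#' `max(0, 1 - y (w . x + b))` with labels recoded to -1/+1. This is the
#' classification-error surrogate the SVM minimizes.
#'
#' @param model A [linear_model()].
#' @param data A [labeled_dataset()].
#' @return Numeric vector of hinge losses, one per observation.
#' @export
hinge_loss_vector <- function(model, data) {
  data <- as_labeled_dataset(data)
  raw <- predict_raw(model, data$features)
  y_pm <- 2 * data$labels - 1
  pmax(0, 1 - y_pm * raw)
}

#' Joint hinge + squared loss objective
#'
#' The DOC-SVM training objective
#' \deqn{\tfrac12\|w\|^2 + C_1 \sum_i \max(0, 1 - \tilde y_i (w x_i + b))
#'       + C_2 \sum_i (w x_i + b - y_i)^2,}
#' with hinge labels \eqn{\tilde y_i \in \{-1,+1\}} and squared-loss
#' targets \eqn{y_i \in \{0,1\}} so that the squared term pulls raw scores
#' onto the probability scale. With \eqn{C_2 = 0} this is the plain
#' soft-margin SVM objective.
#'
#' @inheritParams hinge_loss_vector
#' @return The objective value (a non-negative scalar).
#' @export
docsvm_objective <- function(model, data) {
  data <- as_labeled_dataset(data)
  raw <- predict_raw(model, data$features)
  y_pm <- 2 * data$labels - 1
  0.5 * sum(model$weights^2) +
    model$c_hinge * sum(pmax(0, 1 - y_pm * raw)) +
    model$c_squared * sum((raw - data$labels)^2)
}

# Largest eigenvalue of t(Xb) %*% Xb for the bias-augmented design, used
# to scale steps; exact eigen is cheap at the dimensionalities in scope.
design_lmax <- function(xb) {
  max(eigen(crossprod(xb), symmetric = TRUE, only.values = TRUE)$values)
}

# Core subgradient-descent loop shared by docsvm and svm training.
subgradient_fit <- function(x, labels, c_hinge, c_squared, config) {
  n <- nrow(x)
  d <- ncol(x)
  y01 <- labels
  y_pm <- 2 * labels - 1
  lmax <- design_lmax(cbind(x, 1))
  # gradient-scale constant: curvature of the smooth part plus a bound on
  # the hinge subgradient norm, so nominal eta0 is penalty-invariant
  lscale <- 1 + 2 * c_squared * lmax + c_hinge * sqrt(n * lmax)
  w <- numeric(d)
  b <- 0
  objective <- function(w, b) {
    raw <- as.vector(x %*% w) + b
    0.5 * sum(w^2) + c_hinge * sum(pmax(0, 1 - y_pm * raw)) +
      c_squared * sum((raw - y01)^2)
  }
  trace <- numeric(config$max_iters + 1L)
  trace[1L] <- objective(w, b)
  best <- list(w = w, b = b, obj = trace[1L])
  converged <- FALSE
  iters <- 0L
  for (t in seq_len(config$max_iters)) {
    raw <- as.vector(x %*% w) + b
    active <- (y_pm * raw) < 1          # hinge subgradient support
    resid <- raw - y01
    gw <- w - c_hinge * as.vector(crossprod(x, y_pm * active)) +
      2 * c_squared * as.vector(crossprod(x, resid))
    gb <- -c_hinge * sum(y_pm * active) + 2 * c_squared * sum(resid)
    eta <- config$eta0 / (lscale * (1 + config$decay * (t - 1)))
    w <- w - eta * gw
    b <- b - eta * gb
    obj <- objective(w, b)
    trace[t + 1L] <- obj
    iters <- t
    if (obj < best$obj) {
      best <- list(w = w, b = b, obj = obj)
    }
    if (abs(obj - trace[t]) <= config$tol * max(1, abs(trace[t]))) {
      converged <- TRUE
      break
    }
  }
  list(weights = best$w, bias = best$b, trace = trace[seq_len(iters + 1L)],
       converged = converged)
}

#' Train a linear classifier
#'
#' Fits the joint hinge + squared loss objective of [docsvm_objective()]
#' by deterministic full-batch subgradient descent (zero initialization,
#' best iterate returned). `model_kind = "svm"` is the same optimizer with
#' `c_squared` forced to 0, followed by Platt scaling of the training
#' scores (unless `platt = FALSE`) so that [predict_proba()] works;
#' `model_kind = "logreg"` delegates to [logreg_train()] with
#' `l2 = c_squared`.
#'
#' Non-convergence within `config$max_iters` returns the best iterate with
#' a warning, never an error.
#'
#' @param data A [labeled_dataset()] with both classes present.
#' @param model_kind `"docsvm"`, `"svm"` or `"logreg"`.
#' @param c_hinge Hinge penalty \eqn{C_1} (ignored by `"logreg"`).
#' @param c_squared Squared-loss penalty \eqn{C_2}; L2 penalty for
#'   `"logreg"`.
#' @param config A [train_config()].
#' @param platt Fit Platt parameters on the training scores for
#'   `model_kind = "svm"`, default TRUE.
#' @return A trained [linear_model()].
#' @examples
#' sim <- gen_gaussian_classes(n = 80, d = 2, delta = 4, seed = 1)
#' fit <- train(labeled_dataset(sim$features, sim$labels),
#'              model_kind = "docsvm", c_hinge = 1, c_squared = 1,
#'              config = train_config(max_iters = 200))
#' auc_mann_whitney(predict_proba(fit, sim$features), sim$labels)
#' @export
train <- function(data, model_kind = c("docsvm", "svm", "logreg"),
                  c_hinge = 1, c_squared = 1, config = train_config(),
                  platt = TRUE) {
  data <- as_labeled_dataset(data)
  model_kind <- match.arg(model_kind)
  check_both_classes(data$labels, "training")
  if (c_hinge < 0 || c_squared < 0) {
    stop("penalty parameters must be non-negative", call. = FALSE)
  }
  if (model_kind == "logreg") {
    return(logreg_train(data, l2 = c_squared, config = config))
  }
  if (model_kind == "svm") {
    c_squared <- 0
  }
  std <- standardize_features(data$features, config$standardize)
  fit <- subgradient_fit(std$x, data$labels, c_hinge, c_squared, config)
  if (!fit$converged) {
    warning("training did not meet tolerance within max_iters; ",
            "returning best iterate", call. = FALSE)
  }
  model <- linear_model(
    weights = fit$weights, bias = fit$bias, model_kind = model_kind,
    c_hinge = c_hinge, c_squared = c_squared, trace = fit$trace,
    center = std$center, scale = std$scale, converged = fit$converged,
    warning_flag = !fit$converged
  )
  if (model_kind == "svm" && isTRUE(platt)) {
    ps <- platt_fit(predict_raw(model, data$features), data$labels)
    model$platt <- c(ps$A, ps$B)
    model$warning_flag <- model$warning_flag || ps$warning_flag
  }
  model
}

standardize_features <- function(x, standardize) {
  if (!standardize) {
    return(list(x = x, center = NULL, scale = NULL))
  }
  center <- unname(colMeans(x))
  scale <- unname(apply(x, 2L, stats::sd))
  scale[scale < 1e-12] <- 1  # constant columns pass through untouched
  xs <- sweep(sweep(x, 2L, center, "-"), 2L, scale, "/")
  list(x = xs, center = center, scale = scale)
}

#' Platt scaling of raw classifier scores
#'
#' Fits the sigmoid `p = 1 / (1 + exp(A f + B))` to raw scores `f` by
#' maximum likelihood against Platt's smoothed targets
#' `t+ = (N+ + 1) / (N+ + 2)` and `t- = 1 / (N- + 2)`, which regularize
#' the fit on small samples. `A` is negative when scores are positively
#' associated with the positive class. Constant scores cannot identify
#' `A`; then `A = 0` and `B` reproduces the smoothed prevalence, with
#' `warning_flag = TRUE`.
#'
#' @param raw_scores Real-valued classifier outputs.
#' @param labels Binary 0/1 outcomes.
#' @return A list with `A`, `B` and `warning_flag`.
#' @export
platt_fit <- function(raw_scores, labels) {
  labels <- check_binary_labels(labels)
  if (length(raw_scores) != length(labels)) {
    stop("raw_scores and labels must have the same length", call. = FALSE)
  }
  check_both_classes(labels, "platt_fit")
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  target <- ifelse(labels == 1L, (n_pos + 1) / (n_pos + 2),
                   1 / (n_neg + 2))
  if (stats::sd(raw_scores) < 1e-12) {
    warning("constant scores: Platt slope set to 0", call. = FALSE)
    p_star <- mean(target)
    return(list(A = 0, B = log(1 / p_star - 1), warning_flag = TRUE))
  }
  f <- raw_scores
  nll <- function(par) {
    q <- par[1] * f + par[2]
    # -sum(t log p + (1-t) log(1-p)) with p = 1/(1+e^q), stable form
    sum(log1p(exp(-abs(q))) + pmax(q, 0) - (1 - target) * q)
  }
  grad <- function(par) {
    q <- par[1] * f + par[2]
    p <- 1 / (1 + exp(q))
    d <- target - p            # dNLL/dq = t - p
    c(sum(d * f), sum(d))
  }
  start <- c(0, log((n_neg + 1) / (n_pos + 1)))
  opt <- stats::optim(start, nll, grad, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12))
  list(A = opt$par[1], B = opt$par[2], warning_flag = FALSE)
}

#' Train an L2-regularized logistic regression by gradient-based descent
#'
#' Minimizes the penalized negative log-likelihood
#' `-sum(y log p + (1-y) log(1-p)) + l2/2 ||w||^2` (bias unregularized)
#' with BFGS and an analytic gradient; the objective evaluations are
#' recorded as the model trace. Deterministic given the data and
#' configuration. With `l2 = 0` on separable data the optimum is at
#' infinity; the fit stops at `max_iters` with large finite weights and a
#' warning.
#'
#' @param data A [labeled_dataset()].
#' @param l2 L2 penalty on the weights, default 0.
#' @param config A [train_config()] (`max_iters`, `standardize` and `tol`
#'   are honoured; the step schedule is BFGS's own).
#' @return A trained [linear_model()] of kind `"logreg"`.
#' @export
logreg_train <- function(data, l2 = 0, config = train_config()) {
  data <- as_labeled_dataset(data)
  check_both_classes(data$labels, "training")
  if (l2 < 0) stop("l2 must be non-negative", call. = FALSE)
  std <- standardize_features(data$features, config$standardize)
  x <- std$x
  y <- data$labels
  d <- ncol(x)
  trace_env <- new.env()
  trace_env$values <- numeric()
  nll <- function(par) {
    raw <- as.vector(x %*% par[seq_len(d)]) + par[d + 1L]
    # stable -loglik: log(1+e^raw) - y*raw
    val <- sum(log1p(exp(-abs(raw))) + pmax(raw, 0) - y * raw) +
      l2 / 2 * sum(par[seq_len(d)]^2)
    trace_env$values <- c(trace_env$values, val)
    val
  }
  grad <- function(par) {
    raw <- as.vector(x %*% par[seq_len(d)]) + par[d + 1L]
    p <- stats::plogis(raw)
    c(as.vector(crossprod(x, p - y)) + l2 * par[seq_len(d)], sum(p - y))
  }
  opt <- stats::optim(rep(0, d + 1L), nll, grad, method = "BFGS",
                      control = list(maxit = config$max_iters,
                                     reltol = config$tol))
  converged <- opt$convergence == 0L
  if (!converged) {
    warning("logistic fit stopped at max_iters without meeting tolerance",
            call. = FALSE)
  }
  linear_model(
    weights = opt$par[seq_len(d)], bias = opt$par[d + 1L],
    model_kind = "logreg", c_hinge = 0, c_squared = l2,
    trace = trace_env$values, center = std$center, scale = std$scale,
    converged = converged, warning_flag = !converged
  )
}
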