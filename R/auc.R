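#' Area under the ROC curve by concordant-pair counting
#'
#' The AUC (equivalently, the c-index) is the fraction of
#' positive-negative observation pairs in which the positive observation
#' receives the higher score, with tied pairs counted as one half. It is
#' computed from midranks, which is algebraically identical to explicit
#' pair counting but O(N log N).
#'
#' @param preds A [scored_predictions()] object, or a numeric score vector.
#' @param labels Binary 0/1 outcomes, required when `preds` is a plain
#'   vector.
#' @return The AUC, a number in `[0, 1]`.
#' @seealso [roc_curve()], [auc_trapezoidal()] for the geometric route that
#'   yields the identical value.
#' @examples
#' auc_mann_whitney(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))  # 1
#' auc_mann_whitney(c(0.3, 0.7), c(1, 0))                  # 0
#' @export
auc_mann_whitney <- function(preds, labels = NULL) {
  preds <- as_scored_predictions(preds, labels)
  if (preds$n_pos == 0L || preds$n_neg == 0L) {
    stop("AUC undefined: both classes must be present", call. = FALSE)
  }
  r <- rank(preds$scores, ties.method = "average")
  n_pos <- as.numeric(preds$n_pos)
  (sum(r[preds$labels == 1L]) - n_pos * (n_pos + 1) / 2) /
    (n_pos * preds$n_neg)
}

#' Empirical ROC curve
#'
#' One operating point per distinct score threshold (observations scoring
#' at or above the threshold are called positive), plus the (0,0) origin.
#' Tied scores collapse into a single step, so ties appear as a diagonal
#' segment whose trapezoid reproduces the half-credit convention of
#' [auc_mann_whitney()].
#'
#' @inheritParams auc_mann_whitney
#' @return An object of class `roc_curve` with elements `thresholds`
#'   (descending distinct scores preceded by an `Inf` sentinel for the
#'   (0,0) point), `fpr` and `tpr`.
#' @export
roc_curve <- function(preds, labels = NULL) {
  preds <- as_scored_predictions(preds, labels)
  if (preds$n_pos == 0L || preds$n_neg == 0L) {
    stop("ROC undefined: both classes must be present", call. = FALSE)
  }
  ord <- order(preds$scores, decreasing = TRUE)
  s <- preds$scores[ord]
  y <- preds$labels[ord]
  # cumulative counts at each distinct threshold (last index of each run)
  last <- cumsum(rle(s)$lengths)
  tp <- cumsum(y)[last]
  fp <- cumsum(1L - y)[last]
  structure(
    list(
      thresholds = c(Inf, s[last]),
      fpr = c(0, fp / preds$n_neg),
      tpr = c(0, tp / preds$n_pos)
    ),
    class = "roc_curve"
  )
}

#' @export
print.roc_curve <- function(x, ...) {
  cat("ROC curve with", length(x$fpr), "points; trapezoidal AUC =",
      format(auc_trapezoidal(x)), "\n")
  invisible(x)
}

#' Area under an ROC curve by the trapezoidal rule
#'
#' Sums the trapezoid areas between consecutive ROC points. On the curve
#' produced by [roc_curve()] this equals [auc_mann_whitney()] on the same
#' data to machine precision: the diagonal tie segments carry exactly the
#' half credit the pair-counting form assigns.
#'
#' @param curve A `roc_curve` object.
#' @return The AUC, a number in `[0, 1]`.
#' @export
auc_trapezoidal <- function(curve) {
  if (!inherits(curve, "roc_curve")) {
    stop("curve must be a roc_curve object", call. = FALSE)
  }
  k <- length(curve$fpr)
  sum(diff(curve$fpr) * (curve$tpr[-1] + curve$tpr[-k]) / 2)
}

#' Confusion-matrix metrics at a fixed decision threshold
#'
#' Observations scoring at or above `threshold` are called positive.
#' The F-score is the harmonic mean of precision and sensitivity; when it
#' is undefined because there are neither predicted nor actual positives
#' it is reported as 0 with `warning_flag = TRUE`. Sensitivity requires
#' actual positives and specificity actual negatives; each is `NA` when
#' its class is absent.
#'
#' @inheritParams auc_mann_whitney
#' @param threshold Decision threshold, default 0.5.
#' @return A list with `sensitivity`, `specificity`, `precision`,
#'   `f_score`, the confusion counts `tp`, `fp`, `tn`, `fn`, and
#'   `warning_flag`.
#' @export
threshold_metrics <- function(preds, labels = NULL, threshold = 0.5) {
  preds <- as_scored_predictions(preds, labels)
  pred_pos <- preds$scores >= threshold
  y <- preds$labels == 1L
  tp <- sum(pred_pos & y)
  fp <- sum(pred_pos & !y)
  fn <- sum(!pred_pos & y)
  tn <- sum(!pred_pos & !y)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  warn <- FALSE
  if (tp + fp + fn == 0) {
    # no predicted positives and no actual positives: F undefined
    f <- 0
    warn <- TRUE
    warning("F-score undefined (no predicted or actual positives); ",
            "reporting 0", call. = FALSE)
  } else {
    f <- 2 * tp / (2 * tp + fp + fn)
  }
  prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  list(sensitivity = sens, specificity = spec, precision = prec,
       f_score = f, tp = tp, fp = fp, tn = tn, fn = fn,
       warning_flag = warn)
}

# Placement values behind the DeLong variance: for each positive, the
# fraction of negatives it beats (ties half), and vice versa.
delong_placements <- function(scores, labels) {
  pos <- scores[labels == 1L]
  neg <- scores[labels == 0L]
  v10 <- vapply(pos, function(x) mean((x > neg) + 0.5 * (x == neg)),
                numeric(1))
  v01 <- vapply(neg, function(x) mean((pos > x) + 0.5 * (pos == x)),
                numeric(1))
  list(v10 = v10, v01 = v01, theta = mean(v10))
}

#' z-test for the difference of two correlated AUCs
#'
#' Compares the AUCs of two score vectors evaluated on the same
#' observations (hence correlated), using the DeLong placement-value
#' covariance estimate. This is the paired-AUC comparison reviewed by
#' Lasko and colleagues for probabilistic classifier evaluation.
#'
#' @param preds_a,preds_b [scored_predictions()] objects sharing the same
#'   label vector.
#' @return A list with `z`, the two-sided `p_value`, and the two AUCs
#'   `auc_a`, `auc_b`. Identical placements give `z = 0`, `p = 1`.
#' @export
compare_auc_z <- function(preds_a, preds_b) {
  preds_a <- as_scored_predictions(preds_a)
  preds_b <- as_scored_predictions(preds_b)
  if (preds_a$n != preds_b$n || !all(preds_a$labels == preds_b$labels)) {
    stop("both prediction sets must share the same labels", call. = FALSE)
  }
  check_both_classes(preds_a$labels, "compare_auc_z")
  pa <- delong_placements(preds_a$scores, preds_a$labels)
  pb <- delong_placements(preds_b$scores, preds_b$labels)
  m <- preds_a$n_pos
  n <- preds_a$n_neg
  var_diff <- stats::var(pa$v10 - pb$v10) / m +
    stats::var(pa$v01 - pb$v01) / n
  delta <- pa$theta - pb$theta
  z <- if (var_diff <= 0) {
    if (abs(delta) > 0) sign(delta) * Inf else 0
  } else {
    delta / sqrt(var_diff)
  }
  list(z = z, p_value = 2 * stats::pnorm(-abs(z)),
       auc_a = pa$theta, auc_b = pb$theta)
}
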