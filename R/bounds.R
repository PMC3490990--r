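#' Refinement-based lower bound on the AUC
#'
#' The refinement term REF of the Brier decomposition measures the
#' impurity of the score groups, and impure groups are the only source of
#' discordant or tied positive-negative pairs when the groups themselves
#' are ranked concordantly (higher score, higher event rate). Scaling REF
#' by the pair-counting normalization gives a lower bound on the AUC:
#' \deqn{AUC \ge 1 - \frac{N^2}{2 N_+ N_-}\, REF.}
#' Minimizing refinement therefore pushes the AUC up, which is what lets a
#' squared-loss (Brier) objective serve discrimination as well as
#' calibration. The bound is tight for the all-0.5 balanced case and holds
#' whenever the between-group ranking is concordant; the constant is a
#' re-derivation (the published statement is not machine-readable in the
#' source text) and is exercised property-style in the test suite.
#'
#' @inheritParams auc_mann_whitney
#' @return The lower bound on the AUC (may be negative for very impure
#'   samples, in which case it is vacuous).
#' @export
refinement_auc_bound <- function(preds, labels = NULL) {
  preds <- as_scored_predictions(preds, labels)
  if (preds$n_pos == 0L || preds$n_neg == 0L) {
    stop("bound undefined: both classes must be present", call. = FALSE)
  }
  dec <- brier_decomposition(preds)
  1 - as.numeric(preds$n)^2 /
    (2 * as.numeric(preds$n_pos) * preds$n_neg) * dec$ref
}

#' Hinge-loss upper bound on the rank loss
#'
#' The rank loss (one minus the AUC) of a real-valued scorer is bounded by
#' its mean hinge loss scaled by the class-prior normalization:
#' \deqn{1 - AUC \le \frac{\bar{L}_{hinge}}{\pi (1 - \pi)},}
#' where \eqn{\pi} is the fraction of positives and the hinge loss of an
#' observation with label \eqn{\tilde y \in \{-1,+1\}} and raw score
#' \eqn{f} is \eqn{\max(0, 1 - \tilde y f)}. The bound is loose but
#' explains why minimizing the hinge loss drives the AUC toward 1. As with
#' [refinement_auc_bound()], the constant is a re-derivation of a
#' statement that is not machine-readable in the source text, and is
#' verified property-style against brute-force pair counting in the tests.
#'
#' @param raw_scores Real-valued decision scores (any scale).
#' @param labels Binary 0/1 outcomes.
#' @return The upper bound on `1 - AUC` (not truncated at 1).
#' @export
hinge_rank_bound <- function(raw_scores, labels) {
  labels <- check_binary_labels(labels)
  if (length(raw_scores) != length(labels)) {
    stop("raw_scores and labels must have the same length", call. = FALSE)
  }
  check_both_classes(labels, "hinge_rank_bound")
  y_pm <- 2 * labels - 1
  mean_hinge <- mean(pmax(0, 1 - y_pm * raw_scores))
  pi_pos <- mean(labels)
  mean_hinge / (pi_pos * (1 - pi_pos))
}
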