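#' Brier score
#'
#' Mean squared difference between predicted probabilities and the 0/1
#' outcomes. Scores must already be on the probability scale; out-of-range
#' scores raise an error rather than being clipped.
#'
#' @inheritParams auc_mann_whitney
#' @return The Brier score, a number in `[0, 1]`.
#' @export
brier_score <- function(preds, labels = NULL) {
  preds <- as_scored_predictions(preds, labels)
  s <- check_probability_scores(preds$scores)
  mean((s - preds$labels)^2)
}

#' Two-component Brier score decomposition
#'
#' Groups observations by their exact predicted score value and splits the
#' Brier score into dis-calibration (CAL) and refinement (REF):
#' \deqn{CAL = \frac{1}{N}\sum_s n_s (s - \rho_s)^2, \qquad
#'       REF = \frac{1}{N}\sum_s n_s \rho_s (1 - \rho_s),}
#' where \eqn{n_s} is the number of observations receiving score \eqn{s}
#' and \eqn{\rho_s} the fraction of positives among them. CAL measures the
#' gap between stated scores and observed event rates; REF measures how
#' impure (far from 0/1) the score groups are and is the discrimination-
#' related component, never exceeding 0.25.
#'
#' Scores are rounded to 12 decimals before grouping so that values that
#' are equal up to floating-point noise land in the same group; with
#' continuous scores every group is a singleton and REF is 0, which is
#' still a valid decomposition.
#'
#' @inheritParams auc_mann_whitney
#' @return An object of class `brier_decomposition`: a list with `brier`,
#'   `cal`, `ref`, and `groups`, a data frame of distinct score values with
#'   columns `score`, `n`, `rho` (positive fraction).
#' @export
brier_decomposition <- function(preds, labels = NULL) {
  preds <- as_scored_predictions(preds, labels)
  s <- round(check_probability_scores(preds$scores), 12)
  n_total <- preds$n
  grp <- factor(s, levels = sort(unique(s)))
  n_s <- as.vector(table(grp))
  rho_s <- as.vector(tapply(preds$labels, grp, mean))
  score_s <- sort(unique(s))
  cal <- sum(n_s * (score_s - rho_s)^2) / n_total
  ref <- sum(n_s * rho_s * (1 - rho_s)) / n_total
  structure(
    list(
      brier = cal + ref,
      cal = cal,
      ref = ref,
      groups = data.frame(score = score_s, n = n_s, rho = rho_s)
    ),
    class = "brier_decomposition"
  )
}

#' @export
print.brier_decomposition <- function(x, ...) {
  cat("Brier score decomposition over", nrow(x$groups), "score groups\n")
  cat(sprintf("  brier = %.6f = CAL %.6f + REF %.6f\n",
              x$brier, x$cal, x$ref))
  invisible(x)
}
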