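#' Paired predicted scores and binary outcomes
#'
#' The universal input of the calibration and discrimination metrics: one
#' predicted score per observation together with its observed 0/1 outcome.
#' Ranking-only metrics ([auc_mann_whitney()], [roc_curve()]) accept scores
#' on any real scale; calibration metrics ([brier_score()],
#' [brier_decomposition()], [hosmer_lemeshow()], [reliability_bins()])
#' require scores on the probability scale and refuse, rather than clip,
#' out-of-range values.
#'
#' @param scores Numeric vector of predictions, one per observation.
#' @param labels Binary outcomes coded 0 (negative) / 1 (positive), same
#'   length as `scores`.
#' @return An object of class `scored_predictions`: a list with elements
#'   `scores`, `labels`, and the derived counts `n`, `n_pos`, `n_neg`.
#' @examples
#' sp <- scored_predictions(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
#' auc_mann_whitney(sp)
#' @export
scored_predictions <- function(scores, labels) {
  if (!is.numeric(scores) || anyNA(scores) || any(!is.finite(scores))) {
    stop("scores must be finite numeric values", call. = FALSE)
  }
  labels <- check_binary_labels(labels)
  if (length(scores) != length(labels)) {
    stop("scores and labels must have the same length", call. = FALSE)
  }
  structure(
    list(
      scores = as.numeric(scores),
      labels = labels,
      n = length(labels),
      n_pos = sum(labels == 1L),
      n_neg = sum(labels == 0L)
    ),
    class = "scored_predictions"
  )
}

# Coerce (scores, labels) pairs or pass through an existing object.
as_scored_predictions <- function(x, labels = NULL) {
  if (inherits(x, "scored_predictions")) {
    return(x)
  }
  scored_predictions(x, labels)
}

#' @export
print.scored_predictions <- function(x, ...) {
  cat("Scored predictions:", x$n, "observations (",
      x$n_pos, "positive /", x$n_neg, "negative )\n")
  cat("  score range: [", format(min(x$scores)), ",",
      format(max(x$scores)), "]\n")
  invisible(x)
}

#' Read scored predictions from a delimited text file
#'
#' Expects a header and two columns, `score` and `label`; lines starting
#' with `#` are ignored.
#'
#' @param path Path to a delimited text file.
#' @param delimiter Field separator, tab by default.
#' @return A [scored_predictions()] object.
#' @export
read_predictions <- function(path, delimiter = "\t") {
  tab <- utils::read.table(path, header = TRUE, sep = delimiter,
                           comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("score", "label") %in% names(tab))) {
    stop("prediction file must have 'score' and 'label' columns",
         call. = FALSE)
  }
  scored_predictions(tab$score, map_labels(tab$label))
}

#' Write scored predictions to a delimited text file
#'
#' @param preds A [scored_predictions()] object.
#' @param path Output path.
#' @param delimiter Field separator, tab by default.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(preds, path, delimiter = "\t") {
  preds <- as_scored_predictions(preds)
  utils::write.table(
    data.frame(score = preds$scores, label = preds$labels),
    path, sep = delimiter, quote = FALSE, row.names = FALSE
  )
  invisible(path)
}
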