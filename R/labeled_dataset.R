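#' Labeled feature dataset
#'
#' Container for a numeric feature matrix plus binary outcomes, the input
#' of the training routines. Missing values are refused.
#'
#' @param features Numeric matrix (or data frame) of N observations by d
#'   features.
#' @param labels Binary 0/1 outcomes, length N.
#' @param feature_names Optional character vector of column names.
#' @return An object of class `labeled_dataset` with elements `features`
#'   (matrix), `labels`, `feature_names`, `n`, `d`.
#' @export
labeled_dataset <- function(features, labels, feature_names = NULL) {
  features <- as.matrix(features)
  storage.mode(features) <- "double"
  if (anyNA(features) || any(!is.finite(features))) {
    stop("features must be finite with no missing values", call. = FALSE)
  }
  labels <- check_binary_labels(labels)
  if (nrow(features) != length(labels)) {
    stop("features and labels disagree on the number of observations",
         call. = FALSE)
  }
  if (nrow(features) < 2L) {
    stop("a dataset needs at least 2 observations", call. = FALSE)
  }
  if (!is.null(feature_names)) {
    stopifnot(length(feature_names) == ncol(features))
    colnames(features) <- feature_names
  } else if (is.null(colnames(features))) {
    colnames(features) <- paste0("x", seq_len(ncol(features)))
  }
  structure(
    list(features = features, labels = labels,
         feature_names = colnames(features),
         n = nrow(features), d = ncol(features)),
    class = "labeled_dataset"
  )
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat("Labeled dataset:", x$n, "observations x", x$d, "features;",
      sum(x$labels), "positive\n")
  invisible(x)
}

as_labeled_dataset <- function(x) {
  if (inherits(x, "labeled_dataset")) return(x)
  if (is.list(x) && !is.null(x$features) && !is.null(x$labels)) {
    return(labeled_dataset(x$features, x$labels))
  }
  stop("cannot interpret input as a labeled dataset", call. = FALSE)
}

# Subset a dataset by row indices.
dataset_subset <- function(data, idx) {
  labeled_dataset(data$features[idx, , drop = FALSE], data$labels[idx],
                  data$feature_names)
}
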