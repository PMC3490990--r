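# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG seed, restoring the caller's RNG
# state afterwards. seed = NULL uses (and advances) the current stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

check_binary_labels <- function(labels, what = "labels") {
  if (length(labels) < 1L) {
    stop(what, " must have length >= 1", call. = FALSE)
  }
  if (anyNA(labels) || !all(labels %in% c(0, 1))) {
    stop(what, " must be coded 0/1 with no missing values", call. = FALSE)
  }
  as.integer(labels)
}

check_both_classes <- function(labels, what = "input") {
  if (length(unique(labels)) < 2L) {
    stop(what, " requires both classes to be present", call. = FALSE)
  }
  invisible(labels)
}

check_probability_scores <- function(scores, what = "scores") {
  if (anyNA(scores) || !is.numeric(scores)) {
    stop(what, " must be numeric with no missing values", call. = FALSE)
  }
  if (any(scores < 0 | scores > 1)) {
    stop(what, " must lie within [0, 1] for calibration metrics",
         call. = FALSE)
  }
  as.numeric(scores)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
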