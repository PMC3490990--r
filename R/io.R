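# Delimited-text datasets, JSON model serialization, and metric reports.

# Map a raw label column to 0/1: accepts {0,1}, {-1,+1}, or exactly two
# string levels (mapped by sorted order; first level -> 0).
map_labels <- function(raw) {
  if (is.numeric(raw)) {
    u <- sort(unique(raw))
    if (all(u %in% c(0, 1))) return(as.integer(raw))
    if (all(u %in% c(-1, 1))) return(as.integer(raw == 1))
    stop("numeric labels must be coded {0,1} or {-1,+1}", call. = FALSE)
  }
  raw <- as.character(raw)
  lev <- sort(unique(raw))
  if (length(lev) > 2L) {
    stop("label column has more than two levels", call. = FALSE)
  }
  message("mapping labels: '", lev[1], "' -> 0",
          if (length(lev) == 2L) paste0(", '", lev[2], "' -> 1"))
  as.integer(raw == lev[length(lev)])
}

#' Read a labeled dataset from delimited text
#'
#' Expects a header row, numeric feature columns and one label column
#' (`{0,1}`, `{-1,+1}`, or two string levels mapped by sorted order).
#' Lines starting with `#` are ignored. Malformed numeric cells and
#' missing values are reported with their row and column. A single-class
#' file loads with a warning (training will refuse it).
#'
#' @param path Path to the file.
#' @param delimiter Field separator, tab by default (`","` for CSV).
#' @param label_column Name of the label column, default `"label"`.
#' @return A [labeled_dataset()].
#' @export
read_dataset <- function(path, delimiter = "\t", label_column = "label") {
  tab <- utils::read.table(path, header = TRUE, sep = delimiter,
                           comment.char = "#", stringsAsFactors = FALSE,
                           check.names = FALSE)
  if (!label_column %in% names(tab)) {
    stop("no '", label_column, "' column in ", path, call. = FALSE)
  }
  labels <- map_labels(tab[[label_column]])
  feat <- tab[names(tab) != label_column]
  for (col in names(feat)) {
    v <- feat[[col]]
    if (!is.numeric(v)) {
      parsed <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(parsed) & !is.na(v))
      if (length(bad)) {
        stop("malformed numeric cell at row ", bad[1], ", column '", col,
             "'", call. = FALSE)
      }
      feat[[col]] <- parsed
    }
    if (anyNA(feat[[col]])) {
      stop("missing value at row ", which(is.na(feat[[col]]))[1],
           ", column '", col, "'", call. = FALSE)
    }
  }
  if (length(unique(labels)) < 2L) {
    warning("dataset contains a single class; training will refuse it",
            call. = FALSE)
    # bypass the two-class constructor check while keeping validation
    ds <- labeled_dataset(as.matrix(feat), rep(0:1, length.out = nrow(feat)))
    ds$labels <- labels
    return(ds)
  }
  labeled_dataset(as.matrix(feat), labels)
}

#' Write a labeled dataset (or simulated sample) to delimited text
#'
#' Feature columns followed by a `label` column. A `simulated_sample`
#' without features is written as its score/label pairs (a predictions
#' file); when `truth_sidecar` is set, the sample's generating parameters
#' are stored alongside as JSON for recovery tests.
#'
#' @param data A [labeled_dataset()] or `simulated_sample`.
#' @param path Output path.
#' @param delimiter Field separator, tab by default.
#' @param truth_sidecar Optional path for the JSON truth record (only
#'   meaningful for simulated samples).
#' @return `path`, invisibly.
#' @export
write_dataset <- function(data, path, delimiter = "\t",
                          truth_sidecar = NULL) {
  if (inherits(data, "simulated_sample")) {
    if (!is.null(truth_sidecar)) {
      truth <- data$truth
      truth$bayes_scores <- NULL  # bulky; re-derivable from parameters
      jsonlite::write_json(truth, truth_sidecar, auto_unbox = TRUE,
                           digits = NA, null = "null")
    }
    if (is.null(data$features)) {
      return(write_predictions(
        scored_predictions(data$scores, data$labels), path, delimiter))
    }
    data <- labeled_dataset(data$features, data$labels)
  }
  df <- as.data.frame(data$features)
  df$label <- data$labels
  utils::write.table(df, path, sep = delimiter, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Serialize a linear model to JSON
#'
#' Writes every field needed to reconstruct the model (kind, weights,
#' bias, penalties, standardization parameters, Platt parameters) at full
#' float precision, plus a summary of the training trace. The round trip
#' through [read_model()] is lossless.
#'
#' @param model A [linear_model()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  payload <- list(
    model_kind = model$model_kind,
    weights = model$weights,
    bias = model$bias,
    c_hinge = model$c_hinge,
    c_squared = model$c_squared,
    center = model$center,
    scale = model$scale,
    platt = model$platt,
    converged = model$converged,
    warning_flag = model$warning_flag,
    trace_summary = list(
      iterations = length(model$trace),
      initial = if (length(model$trace)) model$trace[1] else NULL,
      final = if (length(model$trace)) {
        model$trace[length(model$trace)]
      } else {
        NULL
      }
    )
  )
  # 17 significant digits: the smallest figure count that round-trips
  # IEEE doubles exactly
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17),
                       null = "null")
  invisible(path)
}

#' Read a linear model from JSON
#'
#' @param path Path written by [write_model()].
#' @return A [linear_model()].
#' @export
read_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  linear_model(
    weights = p$weights, bias = p$bias, model_kind = p$model_kind,
    c_hinge = p$c_hinge, c_squared = p$c_squared,
    platt = if (is.null(p$platt)) NULL else as.numeric(p$platt),
    center = if (is.null(p$center)) NULL else as.numeric(p$center),
    scale = if (is.null(p$scale)) NULL else as.numeric(p$scale),
    converged = p$converged %||% NA,
    warning_flag = isTRUE(p$warning_flag)
  )
}

#' Full metric report for a set of scored predictions
#'
#' Computes the whole measurement panel at once, nested as
#' `discrimination` (AUC, threshold metrics), `calibration` (Brier score
#' and its decomposition, HL-H and HL-C tests, reliability bins) and
#' `bounds` (refinement lower bound on the AUC; with raw scores supplied,
#' the hinge upper bound on the rank loss).
#'
#' @inheritParams auc_mann_whitney
#' @param raw_scores Optional raw (pre-probability) decision scores for
#'   the hinge bound.
#' @param hl_g Bins for the Hosmer-Lemeshow tests, default 10.
#' @param n_bins Reliability-diagram bins, default 10.
#' @return A nested list of class `metric_report`.
#' @export
evaluate_predictions <- function(preds, labels = NULL, raw_scores = NULL,
                                 hl_g = 10, n_bins = 10) {
  preds <- as_scored_predictions(preds, labels)
  dec <- brier_decomposition(preds)
  thr <- threshold_metrics(preds)
  hl_h <- tryCatch(
    suppressWarnings(hosmer_lemeshow(preds, scheme = "H", g = hl_g)),
    error = function(e) list(statistic = NA_real_, p_value = NA_real_))
  hl_c <- tryCatch(
    suppressWarnings(hosmer_lemeshow(preds, scheme = "C",
                                     g = min(hl_g, preds$n))),
    error = function(e) list(statistic = NA_real_, p_value = NA_real_))
  rel <- reliability_bins(preds, n_bins = n_bins)
  bounds <- list(refinement_auc_lower = refinement_auc_bound(preds))
  if (!is.null(raw_scores)) {
    bounds$hinge_rank_upper <- hinge_rank_bound(raw_scores, preds$labels)
  }
  structure(
    list(
      discrimination = list(
        auc = auc_mann_whitney(preds),
        sensitivity = thr$sensitivity,
        specificity = thr$specificity,
        f_score = thr$f_score
      ),
      calibration = list(
        brier = brier_score(preds),
        cal = dec$cal,
        ref = dec$ref,
        hl_h_stat = hl_h$statistic, hl_h_p = hl_h$p_value,
        hl_c_stat = hl_c$statistic, hl_c_p = hl_c$p_value
      ),
      bounds = bounds,
      reliability = rel$bins
    ),
    class = "metric_report"
  )
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("AUC %.4f | Brier %.4f (CAL %.4f + REF %.4f) | HL-C p %s\n",
              x$discrimination$auc, x$calibration$brier,
              x$calibration$cal, x$calibration$ref,
              if (is.na(x$calibration$hl_c_p)) "NA"
              else sprintf("%.4f", x$calibration$hl_c_p)))
  invisible(x)
}

# Flatten the scalar entries of a metric report into name/value pairs.
flatten_report <- function(report) {
  scalars <- c(
    lapply(report$discrimination, identity),
    lapply(report$calibration, identity),
    lapply(report$bounds, identity)
  )
  names(scalars) <- c(
    paste0("discrimination.", names(report$discrimination)),
    paste0("calibration.", names(report$calibration)),
    paste0("bounds.", names(report$bounds))
  )
  data.frame(metric = names(scalars),
             value = vapply(scalars, as.numeric, numeric(1)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Write a metric report as JSON or TSV
#'
#' The JSON form keeps the nesting of [evaluate_predictions()] and carries
#' the reliability-bin table; the TSV form is the flat metric/value table
#' (identical numbers). The reliability table alone can be written with
#' [write_reliability_tsv()].
#'
#' @param report A `metric_report`.
#' @param path Output path.
#' @param format `"json"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, format = c("json", "tsv")) {
  format <- match.arg(format)
  if (format == "json") {
    jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                         digits = NA, dataframe = "rows", null = "null")
  } else {
    utils::write.table(flatten_report(report), path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Write a reliability-bin table as TSV
#'
#' Columns `bin_lo`, `bin_hi`, `n`, `mean_pred`, `obs_frac`, one row per
#' non-empty bin.
#'
#' @param rel A `reliability_bins` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_reliability_tsv <- function(rel, path) {
  utils::write.table(rel$bins, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
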