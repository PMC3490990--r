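#' Hosmer-Lemeshow goodness-of-fit test
#'
#' Chi-square test of agreement between predicted probabilities and
#' observed event counts over risk bins. Two binning schemes are
#' supported: `"H"` bins by equal-width probability intervals
#' (`[0-0.1), [0.1-0.2), ..., [0.9-1]` when `g = 10`) and `"C"` bins by
#' equal counts of the sorted scores (deciles of risk when `g = 10`).
#' With \eqn{O_g} the observed positives, \eqn{n_g} the bin size and
#' \eqn{E_g} the sum of predicted scores in bin \eqn{g}, the statistic is
#' \deqn{\sum_g \frac{(O_g - E_g)^2}{E_g (1 - E_g / n_g)},}
#' referred to a chi-square distribution with (retained bins − 2) degrees
#' of freedom. Large statistics (small p-values) indicate poor calibration;
#' at `g = 10` the 0.1-level critical value is 13.36 (see
#' [hl_critical_value()]).
#'
#' Degenerate bins (where \eqn{E_g = 0} or \eqn{E_g = n_g} would zero the
#' denominator) contribute 0 and are retained if their numerator is also
#' 0; otherwise they are merged with their neighbour toward the centre of
#' the bin sequence, which preserves all counts while avoiding division by
#' zero. Empty bins are dropped. The degrees of freedom count the bins
#' that remain after this; when fewer than 3 remain the statistic is still
#' reported but the p-value is `NA` with a warning.
#'
#' For scheme `"C"`, observations are stably sorted by score (and, within
#' tied scores, by label, making the statistic invariant to the input
#' order) and cut into `g` consecutive blocks of near-equal size.
#'
#' @inheritParams auc_mann_whitney
#' @param scheme `"C"` (equal-count bins, the default reported in model
#'   comparisons) or `"H"` (equal-width bins).
#' @param g Number of bins, default 10; must be at least 2 (at least 3 for
#'   a testable number of degrees of freedom).
#' @return An object of class `hl_test`: a list with `statistic`,
#'   `scheme`, `g` (retained bins), `df`, `p_value`, and `bins`, a data
#'   frame with columns `observed` (\eqn{O_g}), `n` (\eqn{n_g}) and
#'   `expected` (\eqn{E_g}).
#' @export
hosmer_lemeshow <- function(preds, labels = NULL, scheme = c("C", "H"),
                            g = 10) {
  preds <- as_scored_predictions(preds, labels)
  scheme <- match.arg(scheme)
  s <- check_probability_scores(preds$scores)
  y <- preds$labels
  g <- as.integer(g)
  if (g < 2L) {
    stop("g must be at least 2", call. = FALSE)
  }
  if (scheme == "C") {
    if (preds$n < g) {
      stop("scheme C requires at least g observations", call. = FALSE)
    }
    ord <- order(s, y)  # stable; label as tie-break for order invariance
    bin <- ceiling(seq_len(preds$n) * g / preds$n)
    s <- s[ord]
    y <- y[ord]
  } else {
    bin <- pmin(floor(s * g) + 1L, g)  # last bin closed at 1
  }
  obs <- as.vector(tapply(y, factor(bin, levels = seq_len(g)), sum))
  n_g <- as.vector(tapply(y, factor(bin, levels = seq_len(g)), length))
  exp_g <- as.vector(tapply(s, factor(bin, levels = seq_len(g)), sum))
  keep <- !is.na(n_g) & n_g > 0          # drop empty bins
  tab <- data.frame(observed = obs[keep], n = n_g[keep],
                    expected = exp_g[keep])
  tab <- merge_degenerate_bins(tab)
  if (nrow(tab) == 0L) {
    stop("HL undefined: all bins degenerate", call. = FALSE)
  }
  denom <- tab$expected * (1 - tab$expected / tab$n)
  contrib <- ifelse(denom > 0, (tab$observed - tab$expected)^2 / denom, 0)
  g_used <- nrow(tab)
  df <- g_used - 2L
  if (df < 1L) {
    warning("fewer than 3 retained bins: p-value undefined (df < 1)",
            call. = FALSE)
    p <- NA_real_
  } else {
    p <- stats::pchisq(sum(contrib), df = df, lower.tail = FALSE)
  }
  structure(
    list(statistic = sum(contrib), scheme = scheme, g = g_used, df = df,
         p_value = p, bins = tab),
    class = "hl_test"
  )
}

# Merge bins whose denominator E(1 - E/n) is zero while the numerator
# (O - E)^2 is not, folding each offender into its neighbour toward the
# centre of the bin sequence. Zero-numerator degenerate bins are valid
# (contribution 0) and kept.
merge_degenerate_bins <- function(tab) {
  repeat {
    denom <- tab$expected * (1 - tab$expected / tab$n)
    bad <- which(denom <= 0 & (tab$observed - tab$expected)^2 > 0)
    if (length(bad) == 0L || nrow(tab) == 1L) {
      if (length(bad) > 0L) return(tab[0L, ])  # single unusable bin
      return(tab)
    }
    i <- bad[1L]
    centre <- (nrow(tab) + 1) / 2
    j <- if (i < centre) i + 1L else i - 1L
    tab[j, ] <- tab[i, ] + tab[j, ]
    tab <- tab[-i, , drop = FALSE]
    rownames(tab) <- NULL
  }
}

#' @export
print.hl_test <- function(x, ...) {
  cat(sprintf(
    "Hosmer-Lemeshow %s test: statistic %.4f on %d bins (df %d), p = %s\n",
    x$scheme, x$statistic, x$g, x$df,
    if (is.na(x$p_value)) "NA" else format.pval(x$p_value)))
  invisible(x)
}

#' Critical value of the Hosmer-Lemeshow statistic
#'
#' Upper-tail chi-square quantile with `g - 2` degrees of freedom: the
#' threshold above which the fit is rejected at level `alpha`. At the
#' conventional `g = 10`, `alpha = 0.1`, the value is 13.36.
#'
#' @param alpha Significance level, default 0.1.
#' @param g Number of bins, default 10.
#' @return The critical value of the statistic.
#' @export
hl_critical_value <- function(alpha = 0.1, g = 10) {
  if (g < 3) stop("g must be at least 3", call. = FALSE)
  stats::qchisq(1 - alpha, df = g - 2)
}

#' Reliability diagram bins
#'
#' Divides the probability scale into `n_bins` equal-width bins
#' (half-open, the last closed at 1) and tabulates, per non-empty bin, the
#' mean predicted score against the observed fraction of positives. A
#' well-calibrated model yields points near the diagonal.
#'
#' @inheritParams auc_mann_whitney
#' @param n_bins Number of bins over `[0, 1]`, default 10.
#' @return An object of class `reliability_bins`: a list with `edges`
#'   (length `n_bins + 1`), `counts` (per-bin sizes including zeros), and
#'   `bins`, a data frame of the non-empty bins with columns `bin_lo`,
#'   `bin_hi`, `n`, `mean_pred`, `obs_frac`.
#' @export
reliability_bins <- function(preds, labels = NULL, n_bins = 10) {
  preds <- as_scored_predictions(preds, labels)
  s <- check_probability_scores(preds$scores)
  n_bins <- as.integer(n_bins)
  if (n_bins < 1L) stop("n_bins must be positive", call. = FALSE)
  edges <- seq(0, 1, length.out = n_bins + 1L)
  bin <- pmin(floor(s * n_bins) + 1L, n_bins)
  f <- factor(bin, levels = seq_len(n_bins))
  counts <- as.vector(table(f))
  nonempty <- which(counts > 0L)
  structure(
    list(
      edges = edges,
      counts = counts,
      bins = data.frame(
        bin_lo = edges[nonempty],
        bin_hi = edges[nonempty + 1L],
        n = counts[nonempty],
        mean_pred = as.vector(tapply(s, f, mean))[nonempty],
        obs_frac = as.vector(tapply(preds$labels, f, mean))[nonempty]
      )
    ),
    class = "reliability_bins"
  )
}

#' @export
print.reliability_bins <- function(x, ...) {
  cat("Reliability diagram with", length(x$counts), "bins (",
      nrow(x$bins), "non-empty )\n")
  print(x$bins, row.names = FALSE)
  invisible(x)
}
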