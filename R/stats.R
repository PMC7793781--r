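#' Fisher-Snedecor F-test for equality of variances
#'
#' `F = s_x^2 / s_y^2` with a two-sided p-value
#' `2 * min(P(F <= f), P(F >= f))` from the `F(n_x - 1, n_y - 1)`
#' distribution.
#'
#' @param x,y numeric samples (n >= 2, nonzero variance).
#' @return list with `f_stat` and `p`.
#' @export
f_test_equal_var <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) stop("need at least 2 values per sample")
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("zero variance; F-test undefined")
  ft <- stats::var.test(x, y)
  list(f_stat = unname(ft$statistic), p = ft$p.value)
}

#' Two-sample t-test with pooled or Satterthwaite degrees of freedom
#'
#' `equal_var = TRUE` gives the pooled-variance statistic with
#' `df = n_x + n_y - 2`; `FALSE` gives the Welch statistic with the
#' Satterthwaite approximate degrees of freedom. Per-group 95% confidence
#' intervals are `mean +/- t_{0.975, n-1} * s / sqrt(n)`.
#'
#' @param x,y numeric samples.
#' @param equal_var pooled (`TRUE`) or Satterthwaite (`FALSE`).
#' @return list with `t`, `df`, `p`, `ci_x`, `ci_y` (each CI `c(lo, hi)`).
#' @export
two_sample_t <- function(x, y, equal_var = TRUE) {
  if (length(x) < 2 || length(y) < 2) stop("need at least 2 values per sample")
  tt <- stats::t.test(x, y, var.equal = equal_var)
  ci <- function(v) {
    n <- length(v); se <- stats::sd(v) / sqrt(n)
    mean(v) + c(-1, 1) * stats::qt(0.975, n - 1) * se
  }
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
       ci_x = ci(x), ci_y = ci(y))
}

#' Stage contrast across a long-format feature table
#'
#' For every `metric x location x band_or_freq` cell, gates on the
#' Fisher-Snedecor F-test at `alpha` to choose between the pooled and the
#' Satterthwaite two-sample t-test of Preparation against Generation session
#' means, and emits the full comparison row (group means, per-group 95% CIs,
#' F gate, test used, t, df, p, significance at `alpha`). Cells with fewer
#' than two sessions in either stage are emitted with `skipped = TRUE`.
#'
#' @param feature_table data frame with columns `session_id`, `stage`,
#'   `metric`, `location`, `band_or_freq`, `value`.
#' @param alpha significance level (default 0.05).
#' @param fdr apply Benjamini-Hochberg correction across rows (off by
#'   default; the uncorrected per-cell decision is the reference behavior).
#' @return data frame of stage-comparison rows.
#' @export
compare_stages <- function(feature_table, alpha = 0.05, fdr = FALSE) {
  ft <- as.data.frame(feature_table)
  need <- c("session_id", "stage", "metric", "location", "band_or_freq", "value")
  stopifnot(all(need %in% names(ft)))
  cells <- unique(ft[c("metric", "location", "band_or_freq")])
  cells <- cells[order(cells$metric, cells$location, cells$band_or_freq), ]
  rows <- vector("list", nrow(cells))
  for (r in seq_len(nrow(cells))) {
    sel <- ft$metric == cells$metric[r] & ft$location == cells$location[r] &
      ft$band_or_freq == cells$band_or_freq[r]
    x <- ft$value[sel & ft$stage == "Preparation"]
    y <- ft$value[sel & ft$stage == "Generation"]
    x <- x[is.finite(x)]; y <- y[is.finite(y)]
    base <- data.frame(metric = cells$metric[r], location = cells$location[r],
                       band_or_freq = cells$band_or_freq[r],
                       n_prep = length(x), n_gen = length(y))
    if (length(x) < 2 || length(y) < 2 ||
        stats::var(x) == 0 || stats::var(y) == 0) {
      rows[[r]] <- cbind(base, mean_prep = mean(x), ci_lo_prep = NA, ci_hi_prep = NA,
                         mean_gen = mean(y), ci_lo_gen = NA, ci_hi_gen = NA,
                         f_stat = NA, f_p = NA, test_used = NA, t_stat = NA,
                         df = NA, p = NA_real_, significant = NA, skipped = TRUE)
      next
    }
    f <- f_test_equal_var(x, y)
    equal_var <- f$p >= alpha
    t <- two_sample_t(x, y, equal_var = equal_var)
    rows[[r]] <- cbind(base,
                       mean_prep = mean(x), ci_lo_prep = t$ci_x[1], ci_hi_prep = t$ci_x[2],
                       mean_gen = mean(y), ci_lo_gen = t$ci_y[1], ci_hi_gen = t$ci_y[2],
                       f_stat = f$f_stat, f_p = f$p,
                       test_used = if (equal_var) "pooled" else "satterthwaite",
                       t_stat = t$t, df = t$df, p = t$p,
                       significant = t$p < alpha, skipped = FALSE)
  }
  out <- do.call(rbind, rows)
  if (fdr) {
    out$p_adj <- stats::p.adjust(out$p, method = "BH")
    out$significant <- !is.na(out$p_adj) & out$p_adj < alpha
  }
  rownames(out) <- NULL
  out
}

#' Contiguous significant PSD frequency ranges
#'
#' Summarizes runs of adjacent significant PSD bins per channel as
#' `channel, range_lo_hz, range_hi_hz` rows.
#'
#' @param comparison output of [compare_stages()].
#' @export
psd_significant_ranges <- function(comparison) {
  psd <- comparison[comparison$metric == "psd" & !comparison$skipped, ]
  out <- list()
  for (ch in unique(psd$location)) {
    sub <- psd[psd$location == ch, ]
    sub <- sub[order(as.numeric(sub$band_or_freq)), ]
    sig <- sub$significant %in% TRUE
    if (!any(sig)) next
    runs <- rle(sig)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    for (k in which(runs$values)) {
      out[[length(out) + 1L]] <- data.frame(
        channel = ch,
        range_lo_hz = as.numeric(sub$band_or_freq[starts[k]]),
        range_hi_hz = as.numeric(sub$band_or_freq[ends[k]]))
    }
  }
  if (!length(out))
    return(data.frame(channel = character(), range_lo_hz = numeric(),
                      range_hi_hz = numeric()))
  do.call(rbind, out)
}

#' Participant retention report
#'
#' Given per-session usability (from the preprocessing reports), counts how
#' many participants contribute at least one usable session and expresses
#' the yield as a percentage of those enrolled.
#'
#' @param reports data frame with columns `participant_id` and `usable`
#'   (e.g. row-bound `report`s from [preprocess_session()]).
#' @param n_enrolled total participants enrolled (defaults to the number of
#'   distinct participants in `reports`).
#' @return list with `n_enrolled`, `n_retained`, `yield_pct`.
#' @export
participant_yield <- function(reports, n_enrolled = NULL) {
  by_p <- tapply(reports$usable, reports$participant_id, any)
  if (is.null(n_enrolled)) n_enrolled <- length(by_p)
  n_ret <- sum(by_p)
  list(n_enrolled = n_enrolled, n_retained = n_ret,
       yield_pct = 100 * n_ret / n_enrolled)
}
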