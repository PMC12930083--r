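# Scan-to-scan agreement statistics: Bland-Altman bias and limits of
# agreement, Pearson correlation, paired t-test, and the association of
# paired differences with the inter-scan interval.  Test statistics are
# computed in closed form (the p-values use the t distribution directly),
# which keeps them independently checkable against reference
# implementations.

#' Bland-Altman agreement of paired measurements
#'
#' Differences are `values2 - values1` throughout the package. Pairs with
#' a missing value in either scan are dropped pairwise and counted.
#'
#' @param values1,values2 paired numeric vectors.
#' @return List: `bias` (mean difference), `sd` (sample SD, n-1
#'   denominator), `loa_low`/`loa_high` (bias -/+ 1.96 SD), `n_used`,
#'   `n_dropped`.
#' @examples
#' bland_altman(c(1, 2, 3), c(2, 4, 6))
#' @export
bland_altman <- function(values1, values2) {
  stopifnot(length(values1) == length(values2))
  ok <- is.finite(values1) & is.finite(values2)
  d <- values2[ok] - values1[ok]
  if (length(d) < 3) stop("bland_altman needs at least 3 usable pairs")
  bias <- mean(d)
  s <- stats::sd(d)
  list(
    bias = bias, sd = s,
    loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s,
    n_used = length(d), n_dropped = sum(!ok)
  )
}

# Two-sided Pearson correlation p-value via the t transform.
#' @noRd
pearson_test <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3 || stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(r = NA_real_, p = NA_real_, n = n))
  }
  r <- stats::cor(x, y)
  if (abs(r) >= 1) return(list(r = r, p = 0, n = n))
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(tstat), df = n - 2), n = n)
}

# Two-sided paired t-test p-value.  Zero-variance differences are handled
# explicitly: identical scans (all d = 0) give t = 0, p = 1; a constant
# non-zero difference gives p = 0.
#' @noRd
paired_t_test <- function(d) {
  d <- d[is.finite(d)]
  n <- length(d)
  if (n < 3) return(list(t = NA_real_, p = NA_real_, n = n))
  s <- stats::sd(d)
  if (s == 0) {
    if (mean(d) == 0) return(list(t = 0, p = 1, n = n))
    return(list(t = Inf * sign(mean(d)), p = 0, n = n))
  }
  tstat <- mean(d) / (s / sqrt(n))
  list(t = tstat, p = 2 * stats::pt(-abs(tstat), df = n - 1), n = n)
}

#' Agreement hypothesis tests for one metric
#'
#' Pearson correlation between the two scans (with two-sided p), paired
#' t-test on the differences, and the interval association: correlation of
#' the signed differences with the inter-scan interval (Pearson by
#' default, Spearman optionally). A zero-variance correlate yields `NA`
#' for the affected statistic rather than an error. The two-sided 0.05
#' significance convention applies throughout.
#'
#' @param values1,values2 paired numeric vectors.
#' @param intervals_h inter-scan intervals in hours, aligned to the pairs.
#' @param interval_assoc `"pearson"` or `"spearman"`.
#' @return List: `r`, `r_p`, `t`, `t_p`, `interval_r`, `interval_p`,
#'   `n_used`.
#' @export
agreement_tests <- function(values1, values2, intervals_h = NULL,
                            interval_assoc = c("pearson", "spearman")) {
  interval_assoc <- match.arg(interval_assoc)
  stopifnot(length(values1) == length(values2))
  ok <- is.finite(values1) & is.finite(values2)
  pe <- pearson_test(values1, values2)
  tt <- paired_t_test(values2[ok] - values1[ok])

  interval_r <- interval_p <- NA_real_
  if (!is.null(intervals_h)) {
    stopifnot(length(intervals_h) == length(values1))
    d <- values2 - values1
    if (interval_assoc == "pearson") {
      it <- pearson_test(d, intervals_h)
      interval_r <- it$r
      interval_p <- it$p
    } else {
      ok2 <- is.finite(d) & is.finite(intervals_h)
      if (sum(ok2) >= 3 && stats::sd(d[ok2]) > 0 && stats::sd(intervals_h[ok2]) > 0) {
        ct <- suppressWarnings(stats::cor.test(d[ok2], intervals_h[ok2],
          method = "spearman"))
        interval_r <- unname(ct$estimate)
        interval_p <- ct$p.value
      }
    }
  }
  list(
    r = pe$r, r_p = pe$p,
    t = tt$t, t_p = tt$p,
    interval_r = interval_r, interval_p = interval_p,
    n_used = sum(ok)
  )
}

#' Aggregate pair results into a cohort agreement report
#'
#' Takes a per-pair metric table (one row per scan pair), excludes pairs
#' whose scenario is a disruptive cerebrovascular event, and computes
#' Bland-Altman and test statistics for every metric. Pairs with an
#' undefined value for a given metric are dropped from that metric only,
#' so `n_used` can differ between metrics.
#'
#' @param pair_table data frame with columns `pair_id`, `scenario`,
#'   `interval_h` and `<metric>_1` / `<metric>_2` for each metric in
#'   `metrics`.
#' @param metrics metric base names (default: the six study metrics).
#' @param disruptive scenario names excluded from agreement statistics.
#' @param interval_assoc passed to [agreement_tests()].
#' @return List of class `agreement_report`: `table` (one row per metric:
#'   bias, sd, limits of agreement, Pearson r/p, paired-t p, interval
#'   r/p, n), `excluded` (pair id + scenario), `n_pairs`,
#'   `n_excluded`, `status`.
#' @export
cohort_report <- function(pair_table,
                          metrics = c("core_ml", "hypoperfusion_ml", "aspects",
                            "median_tmax_hypo_s", "rel_cbf_core_pct",
                            "rel_hu_core_pct"),
                          disruptive = DISRUPTIVE_SCENARIOS,
                          interval_assoc = c("pearson", "spearman")) {
  interval_assoc <- match.arg(interval_assoc)
  stopifnot(is.data.frame(pair_table))
  excl_rows <- pair_table$scenario %in% disruptive
  excluded <- pair_table[excl_rows, c("pair_id", "scenario"), drop = FALSE]
  keep <- pair_table[!excl_rows, , drop = FALSE]

  if (nrow(keep) < 3) {
    return(structure(list(
      table = NULL, excluded = excluded,
      n_pairs = nrow(pair_table), n_excluded = sum(excl_rows),
      status = "no usable pairs"
    ), class = "agreement_report"))
  }

  rows <- lapply(metrics, function(m) {
    v1 <- keep[[paste0(m, "_1")]]
    v2 <- keep[[paste0(m, "_2")]]
    ok <- is.finite(v1) & is.finite(v2)
    if (sum(ok) < 3) {
      return(data.frame(metric = m, n_used = sum(ok), bias = NA, sd = NA,
        loa_low = NA, loa_high = NA, r = NA, r_p = NA, t_p = NA,
        interval_r = NA, interval_p = NA))
    }
    ba <- bland_altman(v1, v2)
    at <- agreement_tests(v1, v2, keep$interval_h, interval_assoc)
    data.frame(metric = m, n_used = ba$n_used, bias = ba$bias, sd = ba$sd,
      loa_low = ba$loa_low, loa_high = ba$loa_high,
      r = at$r, r_p = at$r_p, t_p = at$t_p,
      interval_r = at$interval_r, interval_p = at$interval_p)
  })

  structure(list(
    table = do.call(rbind, rows),
    excluded = excluded,
    n_pairs = nrow(pair_table),
    n_excluded = sum(excl_rows),
    status = "ok"
  ), class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("<agreement_report> %d pairs (%d excluded as disruptive), status: %s\n",
    x$n_pairs, x$n_excluded, x$status))
  if (!is.null(x$table)) {
    print(format(x$table, digits = 3), row.names = FALSE)
  }
  invisible(x)
}

#' Bland-Altman plot for one metric
#'
#' Paired differences (scan 2 minus scan 1) against pair means, with the
#' bias as a solid line and the 95 % limits of agreement as dotted lines.
#'
#' @param values1,values2 paired numeric vectors.
#' @param main,xlab,ylab plot annotation.
#' @return The [bland_altman()] summary, invisibly.
#' @export
plot_bland_altman <- function(values1, values2, main = "Bland-Altman",
                              xlab = "mean of pair", ylab = "difference (scan2 - scan1)") {
  ba <- bland_altman(values1, values2)
  ok <- is.finite(values1) & is.finite(values2)
  m <- (values1[ok] + values2[ok]) / 2
  d <- values2[ok] - values1[ok]
  graphics::plot(m, d, pch = 19, main = main, xlab = xlab, ylab = ylab,
    ylim = range(c(d, ba$loa_low, ba$loa_high)))
  graphics::abline(h = ba$bias, lty = 1)
  graphics::abline(h = c(ba$loa_low, ba$loa_high), lty = 3)
  invisible(ba)
}
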