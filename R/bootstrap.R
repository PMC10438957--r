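#' Bootstrap confidence intervals for collocation statistics
#'
#' Non-parametric bootstrap of any subset of the six statistics: in each
#' replicate, 75% (by default) of the raw intervals of each set are drawn
#' independently and without replacement, the sets are re-merged and the
#' statistics recomputed; 20 replicates by default. Two 95% intervals are
#' reported per metric: the normal approximation (replicate mean ± 1.96 SD,
#' clamped to the metric's theoretical range) — the default, since the
#' percentile interval is unstable at 20 replicates — and the raw 2.5/97.5
#' percentile interval. `-Inf` PMI replicates (an empty resampled
#' intersection) are excluded from the interval with their count recorded;
#' if more than half the replicates are `-Inf` the PMI interval is `NA`.
#'
#' @inheritParams summarize_overlap
#' @param metrics Metrics to bootstrap; any of `"c"`, `"j"`, `"sd"`, `"ss"`,
#'   `"pmi"`, `"npmi"` (default all six).
#' @param fraction Resampled proportion of each set's raw intervals,
#'   in (0, 1]; default 0.75.
#' @param n_reps Number of bootstrap replicates (>= 2); default 20.
#' @param seed Integer seed; the whole run is reproducible given the seed.
#' @param conf Confidence level, default 0.95.
#' @return A `coloc_boot` object; `tidy()` gives one row per metric with
#'   `estimate`, `ci_low`, `ci_high` (normal approximation),
#'   `ci_low_pct`, `ci_high_pct` (percentile) and `n_dropped`; `glance()`
#'   gives the run parameters; `$replicates` is the n_reps × metrics matrix.
#' @examples
#' g <- sim_genome(c(chr1 = 10000))
#' ab <- sim_pair(g, n_a = 40, n_b = 40, shared_fraction = 0.5,
#'                lengths = list(dist = "fixed", len = 50), seed = 1)
#' tidy(coloc_bootstrap(ab$a, ab$b, g, seed = 7))
#' @export
coloc_bootstrap <- function(a, b, genome, metrics = metric_names,
                            fraction = 0.75, n_reps = 20, seed = NULL,
                            conf = 0.95) {
  check_intervals(a)
  check_intervals(b)
  metrics <- match.arg(metrics, metric_names, several.ok = TRUE)
  if (nrow(a) == 0 || nrow(b) == 0) {
    abort("bootstrap needs two non-empty interval sets")
  }
  if (n_reps < 2) abort("`n_reps` must be at least 2")
  if (fraction <= 0 || fraction > 1) abort("`fraction` must be in (0, 1]")

  full <- summarize_overlap(a, b, genome)
  point <- map_dbl(metrics, ~ metric_fun(.x)(full))
  names(point) <- metrics
  if (anyNA(point)) {
    abort(paste0("metric ", metrics[which(is.na(point))[1]],
                 " is undefined (NA) on the full data; nothing to bootstrap"))
  }

  one_rep <- function() {
    o <- summarize_overlap(subsample_intervals(a, fraction),
                           subsample_intervals(b, fraction), genome)
    map_dbl(metrics, ~ metric_fun(.x)(o))
  }
  run <- function() {
    out <- vapply(seq_len(n_reps), function(i) one_rep(),
                  numeric(length(metrics)))
    if (is.null(dim(out))) matrix(out, ncol = 1) else t(out)
  }
  reps <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  colnames(reps) <- metrics

  z <- qnorm(1 - (1 - conf) / 2)
  rows <- purrr::map(metrics, function(m) {
    r <- reps[, m]
    dropped <- sum(!is.finite(r))
    r_ok <- r[is.finite(r)]
    rng <- metric_range(m)
    if (dropped > n_reps / 2 || length(r_ok) < 2) {
      lo <- hi <- lo_p <- hi_p <- NA_real_
    } else {
      s <- sd(r_ok)
      lo <- max(mean(r_ok) - z * s, rng[1])
      hi <- min(mean(r_ok) + z * s, rng[2])
      qs <- quantile(r_ok, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                     names = FALSE, type = 7)
      lo_p <- qs[1]
      hi_p <- qs[2]
    }
    tibble(metric = m, estimate = point[[m]], ci_low = lo, ci_high = hi,
           ci_low_pct = lo_p, ci_high_pct = hi_p, n_dropped = dropped)
  })

  structure(
    list(
      summary = dplyr::bind_rows(rows),
      replicates = reps,
      fraction = fraction, n_reps = n_reps, seed = seed, conf = conf
    ),
    class = "coloc_boot"
  )
}

#' @export
tidy.coloc_boot <- function(x, ...) x$summary

#' @export
glance.coloc_boot <- function(x, ...) {
  tibble(n_reps = x$n_reps, fraction = x$fraction, conf = x$conf,
         seed = x$seed %||% NA_integer_,
         n_metrics = nrow(x$summary))
}

#' @export
print.coloc_boot <- function(x, ...) {
  cat("Bootstrap of collocation statistics (", x$n_reps, " replicates, ",
      format(100 * x$fraction), "% of raw intervals without replacement)\n",
      sep = "")
  print(x$summary)
  invisible(x)
}

#' @describeIn coloc_bootstrap Point estimates with normal-approximation
#'   interval bars, one facet row.
#' @param object A `coloc_boot` object.
#' @param ... Unused.
#' @export
autoplot.coloc_boot <- function(object, ...) {
  d <- object$summary
  d$metric <- factor(d$metric, levels = metric_names)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$metric, y = .data$estimate)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ci_low,
                                          ymax = .data$ci_high)) +
    ggplot2::labs(x = NULL, y = "score",
                  title = sprintf("Collocation statistics with %g%% bootstrap CI",
                                  100 * object$conf)) +
    ggplot2::theme_minimal()
}
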