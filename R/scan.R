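# One-query-vs-many-database scan: six metrics per target, per-metric
# Z-standardization over the scan table, a combined Z ranking statistic,
# and the 3-SD outlier rule that nominates putative cofactors.

#' Combine per-metric Z-scores into one ranking statistic
#'
#' `Z = sum(Z_i) / sqrt(k)` over the k non-missing per-metric Z-scores
#' (`method = "sqrt_k"`, the default, following the Z-combination used by
#' gene-set variation analysis), or `sum(Z_i) / k` (`method = "mean"`).
#' Both are monotone transforms of the plain sum, so rankings and outlier
#' calls are identical under either; only the scale differs. Returns `NA`
#' when every input is missing.
#'
#' @param z Numeric vector of per-metric Z-scores (or a matrix with one row
#'   per target and one column per metric).
#' @param method `"sqrt_k"` or `"mean"`.
#' @return A single combined score (or one per matrix row).
#' @export
combine_z <- function(z, method = c("sqrt_k", "mean")) {
  method <- match.arg(method)
  if (is.matrix(z) || is.data.frame(z)) {
    return(apply(as.matrix(z), 1, combine_z, method = method))
  }
  z <- z[!is.na(z)]
  k <- length(z)
  if (k == 0) return(NA_real_)
  sum(z) / if (method == "sqrt_k") sqrt(k) else k
}

#' Flag combined-Z outliers by the 3-SD rule
#'
#' Marks a target as an outlier (a putative cofactor / master regulator)
#' when its combined Z-score lies more than `n_sd` sample standard
#' deviations from the mean combined Z of the scan.
#'
#' @param records Data frame with a `combined_z` column (e.g. a scan table).
#' @param n_sd Distance threshold in standard deviations; default 3.
#' @return `records` with a logical `outlier` column added or replaced.
#' @export
flag_outliers <- function(records, n_sd = 3) {
  if (!is.data.frame(records) || !"combined_z" %in% names(records)) {
    abort("`records` must be a data frame with a combined_z column")
  }
  cz <- records$combined_z
  mu <- mean(cz, na.rm = TRUE)
  s <- sd(cz, na.rm = TRUE)
  records$outlier <- if (is.na(s) || s == 0) {
    rep(FALSE, length(cz))
  } else {
    !is.na(cz) & abs(cz - mu) > n_sd * s
  }
  records
}

#' Scan a query interval set against a database of interval sets
#'
#' Computes the six collocation statistics between the query and every
#' database entry, standardizes each metric to a Z-score over the scan
#' table (`Z_i = (x − mean) / sd`, sample SD), combines the per-metric
#' Z-scores with [combine_z()], ranks targets by the combined score
#' (descending, ties broken by target name) and flags 3-SD outliers.
#' `-Inf` PMI values (targets sharing no bases with the query) cannot be
#' standardized and are treated as missing for the PMI column; the combined
#' score then renormalizes over the remaining metrics. A metric with zero
#' variance across targets gets Z = 0 everywhere, with a warning.
#'
#' @param query Interval tibble (the query peak set).
#' @param database Named list of interval tibbles, or a path accepted by
#'   [read_bed_database()] (a directory of BED files or a two-column
#'   manifest TSV of label and path).
#' @param genome Genome tibble.
#' @param exclude Optional label(s) removed from the database before
#'   standardization — typically the query itself when it is also a
#'   database entry.
#' @param method Combined-Z denominator passed to [combine_z()].
#' @param n_sd Outlier threshold passed to [flag_outliers()].
#' @return A `coloc_scan` tibble, one row per target, sorted by
#'   `combined_z` descending: `target`, `card_a`, `card_b`, `card_ab`,
#'   `c`, `j`, `sd`, `ss`, `pmi`, `npmi`, `z_c` ... `z_npmi`, `combined_z`,
#'   `rank`, `outlier`.
#' @examples
#' g <- sim_genome(c(chr1 = 100000))
#' q <- sim_intervals(g, n = 60, lengths = list(dist = "fixed", len = 100), seed = 1)
#' db <- list(
#'   hit  = sim_pair(g, n_a = 60, n_b = 40, shared_fraction = 0.8, seed = 2)$b,
#'   bg1  = sim_intervals(g, 50, seed = 3),
#'   bg2  = sim_intervals(g, 50, seed = 4),
#'   bg3  = sim_intervals(g, 50, seed = 5)
#' )
#' coloc_scan(q, db, g)
#' @export
coloc_scan <- function(query, database, genome, exclude = NULL,
                       method = c("sqrt_k", "mean"), n_sd = 3) {
  method <- match.arg(method)
  check_intervals(query)
  if (is.character(database)) database <- read_bed_database(database)
  if (!is.list(database) || is.data.frame(database)) {
    abort("`database` must be a named list of interval tibbles or a path")
  }
  if (is.null(names(database)) || any(names(database) == "")) {
    abort("every database entry needs a name")
  }
  database <- database[!names(database) %in% exclude]
  if (length(database) < 3) {
    abort("scan needs at least 3 database targets (after exclusions)")
  }

  rows <- imap(database, function(tgt, nm) {
    o <- summarize_overlap(query, tgt, genome)
    dplyr::bind_cols(tibble(target = nm), o, metric_columns(o))
  })
  tab <- bind_rows(rows)

  zcols <- paste0("z_", metric_names)
  for (m in metric_names) {
    x <- tab[[m]]
    x[!is.finite(x)] <- NA  # -Inf PMI: not standardizable
    mu <- mean(x, na.rm = TRUE)
    s <- sd(x, na.rm = TRUE)
    z <- if (is.na(s) || s == 0) {
      if (sum(!is.na(x)) > 0) {
        warn(paste0("metric '", m, "' has zero variance across targets; ",
                    "its Z-scores are set to 0"))
      }
      ifelse(is.na(x), NA_real_, 0)
    } else {
      (x - mu) / s
    }
    tab[[paste0("z_", m)]] <- z
  }
  tab$combined_z <- combine_z(tab[zcols], method = method)
  tab <- flag_outliers(tab, n_sd = n_sd)
  tab <- arrange(tab, desc(.data$combined_z), .data$target)
  tab$rank <- seq_len(nrow(tab))
  tab <- dplyr::relocate(tab, "outlier", .after = "rank")
  class(tab) <- c("coloc_scan", class(tab))
  attr(tab, "method") <- method
  attr(tab, "n_sd") <- n_sd
  tab
}

#' Load a database of BED files
#'
#' @param path Either a directory containing `*.bed` / `*.bed.gz` files
#'   (labels are the base names) or a two-column TSV manifest of
#'   label and BED path (relative paths resolved against the manifest's
#'   directory).
#' @return Named list of interval tibbles.
#' @export
read_bed_database <- function(path) {
  if (dir.exists(path)) {
    files <- list.files(path, pattern = "\\.bed(\\.gz)?$", full.names = TRUE)
    if (length(files) == 0) abort(paste0("no BED files found in ", path))
    labels <- sub("\\.bed(\\.gz)?$", "", basename(files))
  } else if (file.exists(path)) {
    man <- readr::read_tsv(path, col_names = c("label", "path"),
                           col_types = "cc", comment = "#")
    labels <- man$label
    files <- ifelse(grepl("^/", man$path), man$path,
                    file.path(dirname(path), man$path))
  } else {
    abort(paste0("database path not found: ", path))
  }
  stats::setNames(purrr::map2(files, labels, read_bed), labels)
}

#' @describeIn coloc_scan Bar plot of combined Z-scores with outliers
#'   highlighted.
#' @param object A `coloc_scan` tibble.
#' @param top Show only the `top` highest-ranked targets (default 20).
#' @param ... Unused.
#' @export
autoplot.coloc_scan <- function(object, top = 20, ...) {
  d <- as_tibble(head(object, top))
  d$target <- stats::reorder(d$target, d$combined_z)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$target, y = .data$combined_z,
                                  fill = .data$outlier)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey55", `TRUE` = "firebrick"),
                               name = "> 3 SD") +
    ggplot2::labs(x = NULL, y = "combined Z-score") +
    ggplot2::theme_minimal()
}
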