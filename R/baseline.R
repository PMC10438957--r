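# The conventional threshold-and-count baseline: label each query peak
# overlapped/non-overlapped at a cutoff and report the overlapped
# proportion. Implemented for comparison with the threshold-free
# statistics; its peak-count bias is what they are designed to avoid.

parse_threshold <- function(threshold) {
  if (is.numeric(threshold)) {
    pct <- threshold
  } else if (identical(tolower(threshold), "1nt")) {
    return(list(label = "1nt", pct = NA_real_))
  } else {
    pct <- suppressWarnings(as.numeric(sub("%$", "", threshold)))
  }
  if (is.na(pct) || pct <= 0 || pct > 100) {
    abort(paste0("invalid threshold '", threshold,
                 "': use \"1nt\" or a percentage in (0, 100]"))
  }
  list(label = paste0(pct, "%"), pct = pct)
}

# Total overlap (bases) of each raw query peak with the merged target.
per_peak_overlap <- function(query, target) {
  lv <- sort(union(unique(query$chrom), unique(target$chrom)))
  qr <- as_granges(query, lv)
  tr <- IRanges::reduce(as_granges(target, lv))
  ov <- rep(0, nrow(query))
  hits <- IRanges::findOverlaps(qr, tr)
  if (length(hits) > 0) {
    w <- BiocGenerics::width(IRanges::pintersect(
      qr[S4Vectors::queryHits(hits)], tr[S4Vectors::subjectHits(hits)]))
    agg <- tapply(w, S4Vectors::queryHits(hits), sum)
    ov[as.integer(names(agg))] <- as.numeric(agg)
  }
  ov
}

#' Threshold-and-count overlap between a query and one target
#'
#' Labels each raw query peak overlapped (1) or non-overlapped (0) at a
#' cutoff, and reports the overlapped proportion as the collocation
#' measure. A peak's overlap is its total shared bases with the merged
#' target, summed across target fragments. The cutoff is either `"1nt"`
#' (any positive overlap, the most relaxed) or a percentage of each query
#' peak's own length (`100` — full coverage — being the most stringent).
#'
#' @param query Non-empty interval tibble; peaks are counted as given, not
#'   merged.
#' @param target Interval tibble (merged internally).
#' @param threshold `"1nt"`, or a percentage in (0, 100] given as a number
#'   or a string like `"30%"`.
#' @return One-row tibble: `threshold`, `n_query_peaks`, `n_overlapped`,
#'   `proportion`.
#' @examples
#' q <- tibble::tibble(chrom = "chr1", start = 0, end = 100)
#' t <- tibble::tibble(chrom = "chr1", start = 90, end = 500)
#' threshold_and_count(q, t, "1nt")
#' threshold_and_count(q, t, 50)
#' @export
threshold_and_count <- function(query, target, threshold = "1nt") {
  check_intervals(query)
  check_intervals(target)
  if (nrow(query) == 0) abort("`query` must contain at least one peak")
  th <- parse_threshold(threshold)
  ov <- per_peak_overlap(query, target)
  cut <- if (identical(th$label, "1nt")) {
    rep(1, nrow(query))
  } else {
    th$pct / 100 * (query$end - query$start)
  }
  hit <- ov >= cut
  tibble(
    threshold = th$label,
    n_query_peaks = nrow(query),
    n_overlapped = sum(hit),
    proportion = sum(hit) / nrow(query)
  )
}

#' Rank targets by overlapped proportion
#'
#' Descending by `proportion`, ties broken by target name (stable,
#' reproducible). When a `threshold` column is present, ranking is done
#' within each threshold.
#'
#' @param results Data frame with columns `target` and `proportion`
#'   (optionally `threshold`).
#' @return The input with a 1-based `rank` column, sorted.
#' @export
rank_by_proportion <- function(results) {
  if (!is.data.frame(results) ||
      !all(c("target", "proportion") %in% names(results))) {
    abort("`results` must have columns target and proportion")
  }
  if ("threshold" %in% names(results)) {
    results <- results |>
      group_by(.data$threshold) |>
      arrange(desc(.data$proportion), .data$target, .by_group = TRUE) |>
      mutate(rank = row_number()) |>
      ungroup()
  } else {
    results <- results |>
      arrange(desc(.data$proportion), .data$target) |>
      mutate(rank = row_number())
  }
  results
}

#' Threshold-and-count baseline over a database
#'
#' Runs [threshold_and_count()] for every database target at each
#' threshold and ranks targets within each threshold.
#'
#' @inheritParams coloc_scan
#' @param thresholds Vector of thresholds; default the conventional ladder
#'   `"1nt"`, 10, 30, 50, 80, 100 (percent of query-peak length).
#' @return Tibble with one row per target × threshold: `threshold`,
#'   `target`, `n_query_peaks`, `n_overlapped`, `proportion`, `rank`.
#' @export
baseline_scan <- function(query, database, exclude = NULL,
                          thresholds = c("1nt", 10, 30, 50, 80, 100)) {
  check_intervals(query)
  if (is.character(database)) database <- read_bed_database(database)
  database <- database[!names(database) %in% exclude]
  if (length(database) == 0) abort("empty database")
  out <- purrr::map(thresholds, function(th) {
    bind_rows(imap(database, function(tgt, nm) {
      dplyr::bind_cols(tibble(target = nm),
                       threshold_and_count(query, tgt, th))
    }))
  })
  out <- bind_rows(out)
  out <- dplyr::relocate(out, "threshold")
  out$threshold <- factor(out$threshold, levels = unique(out$threshold))
  rank_by_proportion(out)
}
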