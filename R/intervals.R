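# Interval-set algebra in base-pair units. Tibbles (chrom/start/end,
# 0-based half-open) are the user-facing representation; GenomicRanges does
# the set operations internally (1-based closed), converted at the boundary.

check_intervals <- function(x, arg = deparse(substitute(x))) {
  if (!is.data.frame(x) || !all(c("chrom", "start", "end") %in% names(x))) {
    abort(paste0("`", arg, "` must be a data frame with columns chrom, start, end"))
  }
  if (nrow(x) > 0 && any(x$end <= x$start | x$start < 0)) {
    abort(paste0("`", arg, "` contains invalid intervals (need 0 <= start < end)"))
  }
  invisible(x)
}

check_genome <- function(genome, arg = deparse(substitute(genome))) {
  if (!is.data.frame(genome) || !all(c("chrom", "size") %in% names(genome))) {
    abort(paste0("`", arg, "` must be a data frame with columns chrom, size"))
  }
  if (any(genome$size <= 0) || anyDuplicated(genome$chrom)) {
    abort(paste0("`", arg, "` must have unique chromosomes with positive sizes"))
  }
  invisible(genome)
}

# tibble (0-based half-open) -> GRanges (1-based closed)
as_granges <- function(x, chroms = NULL) {
  lv <- chroms %||% sort(unique(x$chrom))
  GenomicRanges::GRanges(
    seqnames = factor(x$chrom, levels = lv),
    ranges = IRanges::IRanges(start = x$start + 1, end = x$end)
  )
}

as_interval_tbl <- function(gr) {
  tibble(
    chrom = as.character(GenomeInfoDb::seqnames(gr)),
    start = as.numeric(BiocGenerics::start(gr)) - 1,
    end = as.numeric(BiocGenerics::end(gr))
  )
}

# Validate interval chromosomes/bounds against the genome; clip or error.
conform_to_genome <- function(x, genome, clip = FALSE,
                              arg = deparse(substitute(x))) {
  check_intervals(x, arg)
  check_genome(genome)
  if (nrow(x) == 0) return(x)
  unknown <- setdiff(unique(x$chrom), genome$chrom)
  if (length(unknown) > 0) {
    abort(paste0("chromosome ", unknown[1], " in `", arg,
                 "` is not in the genome"))
  }
  lim <- genome$size[match(x$chrom, genome$chrom)]
  over <- x$end > lim
  if (any(over)) {
    if (!clip) {
      i <- which(over)[1]
      abort(paste0("interval ", x$chrom[i], ":", x$start[i], "-", x$end[i],
                   " in `", arg, "` extends past the chromosome end (",
                   lim[i], " bp); use clip = TRUE to truncate"))
    }
    warn(paste0("clipped ", sum(over), " interval(s) in `", arg,
                "` to chromosome bounds"))
    x$end <- pmin(x$end, lim)
    x <- x[x$end > x$start, , drop = FALSE]
  }
  x
}

#' Merge an interval set to canonical form
#'
#' Sorts by (chrom, start) and fuses overlapping and abutting intervals so
#' every covered base appears exactly once ("non-redundant" coverage). All
#' base-count statistics in this package are computed on merged sets, so
#' duplicated or overlapping input peaks never inflate a cardinality.
#' Idempotent and coverage-preserving.
#'
#' @param x Interval tibble.
#' @return A canonical interval tibble covering the same bases.
#' @examples
#' merge_intervals(tibble::tibble(chrom = "chr1", start = c(10, 15), end = c(20, 30)))
#' @export
merge_intervals <- function(x) {
  check_intervals(x)
  if (nrow(x) == 0) {
    return(tibble(chrom = character(), start = numeric(), end = numeric()))
  }
  as_interval_tbl(IRanges::reduce(as_granges(x)))
}

#' Cardinality of an interval set
#'
#' Total number of distinct bases covered (each base counted once; the set
#' is merged internally if needed).
#'
#' @param x Interval tibble.
#' @return Number of covered bases.
#' @export
interval_cardinality <- function(x) {
  check_intervals(x)
  if (nrow(x) == 0) return(0)
  # double, not integer: cardinality products exceed 32-bit range
  sum(as.numeric(BiocGenerics::width(IRanges::reduce(as_granges(x)))))
}

#' Base-level intersection of two interval sets
#'
#' @param a,b Interval tibbles.
#' @return Canonical interval tibble of the bases covered by both.
#' @export
intersect_intervals <- function(a, b) {
  check_intervals(a)
  check_intervals(b)
  if (nrow(a) == 0 || nrow(b) == 0) {
    return(tibble(chrom = character(), start = numeric(), end = numeric()))
  }
  lv <- sort(union(unique(a$chrom), unique(b$chrom)))
  as_interval_tbl(BiocGenerics::intersect(as_granges(a, lv), as_granges(b, lv)))
}

#' Base-count summary of the overlap between two interval sets
#'
#' Computes the quadruple from which every collocation statistic derives:
#' the merged cardinalities |A| and |B|, the intersection |A ∩ B|, the union
#' |A ∪ B| = |A| + |B| − |A ∩ B|, and the background genome size G. Every
#' input interval participates, whether or not it overlaps the other set.
#'
#' @param a,b Interval tibbles.
#' @param genome Genome tibble; every chromosome used by `a` or `b` must be
#'   present (exact string match), otherwise an error names the offender.
#' @param clip If `TRUE`, intervals running past a chromosome end are
#'   truncated with a warning instead of raising an error.
#' @return One-row tibble with columns `card_a`, `card_b`, `card_ab`,
#'   `card_union`, `genome_size` (all in bases).
#' @examples
#' g <- sim_genome(c(chr1 = 1000))
#' a <- tibble::tibble(chrom = "chr1", start = 0, end = 200)
#' b <- tibble::tibble(chrom = "chr1", start = 190, end = 240)
#' summarize_overlap(a, b, g)
#' @export
summarize_overlap <- function(a, b, genome, clip = FALSE) {
  a <- conform_to_genome(a, genome, clip = clip, arg = "a")
  b <- conform_to_genome(b, genome, clip = clip, arg = "b")
  card_a <- interval_cardinality(a)
  card_b <- interval_cardinality(b)
  card_ab <- interval_cardinality(intersect_intervals(a, b))
  tibble(
    card_a = card_a,
    card_b = card_b,
    card_ab = card_ab,
    card_union = card_a + card_b - card_ab,
    genome_size = genome_size(genome)
  )
}

#' Subsample raw intervals without replacement
#'
#' Draws `max(1, floor(fraction * n))` of the raw (pre-merge) intervals
#' uniformly without replacement; the unit resampled by the bootstrap.
#'
#' @param x Non-empty interval tibble.
#' @param fraction Proportion in (0, 1].
#' @param seed Optional integer; when given, the draw is reproducible and
#'   the caller's RNG state is untouched.
#' @return Interval tibble with the sampled rows (input order preserved).
#' @export
subsample_intervals <- function(x, fraction, seed = NULL) {
  check_intervals(x)
  n <- nrow(x)
  if (n == 0) abort("cannot subsample an empty interval set")
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 1) {
    abort("`fraction` must be in (0, 1]")
  }
  k <- max(1L, floor(fraction * n))
  draw <- function() sort(sample.int(n, k))
  idx <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  x[idx, , drop = FALSE]
}
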