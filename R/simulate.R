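# Synthetic fixture generators: BED-style interval sets with controlled
# count, length distribution and shared-base structure, so the statistics
# can be exercised and validated without any external download. The
# generators report their own bookkeeping (realized cardinalities by
# construction), which the measurement code can then be checked against.

#' Build a genome tibble from a named vector of chromosome sizes
#'
#' @param sizes Named numeric vector, e.g. `c(chr1 = 1e6)`. The default toy
#'   genome is a single 1 Mb chromosome: large enough for stable coverage
#'   fractions, small enough for per-base validation.
#' @return Genome tibble with columns `chrom`, `size`.
#' @export
sim_genome <- function(sizes = c(chr1 = 1e6)) {
  if (is.null(names(sizes)) || any(names(sizes) == "")) {
    abort("`sizes` must be a named vector")
  }
  g <- tibble(chrom = names(sizes), size = as.numeric(sizes))
  check_genome(g)
  g
}

sample_lengths <- function(n, lengths) {
  if (n == 0) return(numeric(0))
  dist <- lengths$dist %||% "uniform"
  out <- switch(dist,
    fixed = rep(lengths$len, n),
    uniform = sample(seq(lengths$min, lengths$max), n, replace = TRUE),
    geometric = stats::rgeom(n, prob = 1 / lengths$mean) + 1,
    abort(paste0("unknown length distribution '", dist, "'"))
  )
  as.numeric(out)
}

# Uniform non-overlapping placement of intervals with the given lengths on
# one chromosome, keeping >= 1 bp between neighbours so the merged set has
# exactly one block per requested interval.
place_on_chrom <- function(chrom, size, lens) {
  k <- length(lens)
  if (k == 0) {
    return(tibble(chrom = character(), start = numeric(), end = numeric()))
  }
  free <- size - sum(lens) - (k - 1)
  if (free < 0) {
    abort(paste0("infeasible packing: ", k, " intervals totalling ",
                 sum(lens), " bp do not fit on ", chrom, " (", size, " bp)"))
  }
  slack <- sort(sample.int(free + 1, k, replace = TRUE) - 1)
  starts <- slack + cumsum(c(0, head(lens, -1) + 1))
  tibble(chrom = chrom, start = starts, end = starts + lens)
}

#' Generate a random non-overlapping interval set
#'
#' Places `n` intervals uniformly on the genome (chromosome chosen with
#' probability proportional to its size) with no two intervals overlapping
#' or abutting, so the set is already canonical and its cardinality is the
#' sum of the drawn lengths.
#'
#' @param genome Genome tibble.
#' @param n Number of intervals.
#' @param lengths Length distribution: `list(dist = "fixed", len = )`,
#'   `list(dist = "uniform", min = , max = )` (the default, 100–300 bp,
#'   a typical ChIP-seq peak width range) or
#'   `list(dist = "geometric", mean = )`.
#' @param seed Optional integer seed (reproducible, caller's RNG untouched).
#' @return Interval tibble sorted by (chrom, start).
#' @export
sim_intervals <- function(genome, n,
                          lengths = list(dist = "uniform", min = 100, max = 300),
                          seed = NULL) {
  check_genome(genome)
  run <- function() {
    lens <- sample_lengths(n, lengths)
    chrom <- sample(genome$chrom, n, replace = TRUE,
                    prob = genome$size / sum(genome$size))
    parts <- purrr::map(genome$chrom, function(cm) {
      place_on_chrom(cm, genome$size[genome$chrom == cm], lens[chrom == cm])
    })
    arrange(bind_rows(parts), .data$chrom, .data$start)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

# Place intervals of the given lengths inside free gaps, keeping >= 1 bp
# from every gap edge (so nothing placed here touches existing coverage or
# earlier placements). gaps: tibble(chrom, start, end), 0-based half-open.
place_in_gaps <- function(gaps, lens) {
  gs <- gaps$start
  ge <- gaps$end
  gc <- gaps$chrom
  out_chrom <- character(length(lens))
  out_start <- numeric(length(lens))
  for (i in seq_along(lens)) {
    l <- lens[i]
    room <- ge - gs - l - 1  # number of valid start positions - 1
    ok <- which(room >= 1)
    if (length(ok) == 0) {
      abort("infeasible packing: no free gap large enough")
    }
    gi <- if (length(ok) == 1) ok else sample(ok, 1, prob = room[ok])
    s <- gs[gi] + sample.int(room[gi], 1)
    out_chrom[i] <- gc[gi]
    out_start[i] <- s
    # split the used gap
    gs <- c(gs, s + l)
    ge <- c(ge, ge[gi])
    gc <- c(gc, gc[gi])
    ge[gi] <- s
  }
  tibble(chrom = out_chrom, start = out_start, end = out_start + lens)
}

genome_complement <- function(x, genome) {
  whole <- tibble(chrom = genome$chrom, start = 0, end = genome$size)
  if (nrow(x) == 0) return(whole)
  lv <- genome$chrom
  as_interval_tbl(GenomicRanges::setdiff(as_granges(whole, lv),
                                         as_granges(x, lv)))
}

#' Generate a pair of interval sets with a planted shared-base fraction
#'
#' Set A is placed as in [sim_intervals()]. A target fraction of A's bases
#' is then re-used verbatim as intervals of B (whole A intervals in random
#' order, plus one trimmed prefix to land on the exact base budget); B's
#' remaining intervals are placed in the space not covered by A, so the
#' realized shared fraction equals the plant up to the one-interval
#' rounding. Everything is deterministic for a fixed seed.
#'
#' @inheritParams sim_intervals
#' @param n_a,n_b Interval counts for A and B.
#' @param shared_fraction Target fraction of A's bases also covered by B,
#'   in \[0, 1\].
#' @return List with `a`, `b` (interval tibbles), `genome`, and `realized`,
#'   a one-row tibble of the generator's own bookkeeping: `card_a`,
#'   `card_b`, `card_ab`, `shared_fraction` (= card_ab / card_a).
#' @examples
#' g <- sim_genome(c(chr1 = 100000))
#' ab <- sim_pair(g, n_a = 50, n_b = 50, shared_fraction = 0.5, seed = 1)
#' ab$realized
#' @export
sim_pair <- function(genome, n_a = 500, n_b = 500,
                     lengths = list(dist = "uniform", min = 100, max = 300),
                     shared_fraction = 0.5, seed = NULL) {
  check_genome(genome)
  if (shared_fraction < 0 || shared_fraction > 1) {
    abort("`shared_fraction` must be in [0, 1]")
  }
  if (n_a < 1) abort("`n_a` must be at least 1")
  run <- function() {
    a <- sim_intervals(genome, n_a, lengths)
    card_a <- sum(a$end - a$start)
    budget <- round(shared_fraction * card_a)
    ord <- sample.int(nrow(a))
    shared <- tibble(chrom = character(), start = numeric(), end = numeric())
    got <- 0
    for (i in ord) {
      if (got >= budget) break
      len <- a$end[i] - a$start[i]
      take <- min(len, budget - got)
      shared <- bind_rows(shared, tibble(chrom = a$chrom[i],
                                         start = a$start[i],
                                         end = a$start[i] + take))
      got <- got + take
    }
    n_rest <- max(0, n_b - nrow(shared))
    rest <- place_in_gaps(genome_complement(a, genome),
                          sample_lengths(n_rest, lengths))
    b <- arrange(bind_rows(shared, rest), .data$chrom, .data$start)
    list(
      a = a, b = b, genome = genome,
      realized = tibble(
        card_a = card_a,
        card_b = got + sum(rest$end - rest$start),
        card_ab = got,
        shared_fraction = got / card_a
      )
    )
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Construct an exactly independent pair of interval sets
#'
#' Builds A covering `card_a` bases and B covering `card_b` bases whose
#' shared coverage is exactly the product-of-marginals expectation
#' `card_a * card_b / G`, so PMI = 0 and NPMI = 0 by construction. Requires
#' `card_a * card_b` to be divisible by the genome size G (otherwise the
#' expected intersection is not a whole number of bases and the error
#' suggests the nearest feasible `card_b`). The layout is a deterministic
#' block construction, rotated around the genome by a seed-dependent offset.
#'
#' @inheritParams sim_intervals
#' @param card_a,card_b Cardinalities of A and B in bases (0 < card <= G).
#' @return List with interval tibbles `a` and `b`.
#' @examples
#' g <- sim_genome(c(chr1 = 1000))
#' ab <- sim_independent_pair(g, card_a = 500, card_b = 200)
#' pmi(summarize_overlap(ab$a, ab$b, g))
#' @export
sim_independent_pair <- function(genome, card_a, card_b, seed = NULL) {
  check_genome(genome)
  g <- genome_size(genome)
  if (card_a <= 0 || card_b <= 0 || card_a > g || card_b > g) {
    abort("cardinalities must be in (0, G]")
  }
  if ((card_a * card_b) %% g != 0) {
    step <- g / gcd2(card_a, g)
    near <- max(step, round(card_b / step) * step)
    abort(paste0(
      "card_a * card_b must be divisible by the genome size (", g,
      ") for an exact independence construction; with card_a = ", card_a,
      ", the nearest feasible card_b is ", near
    ))
  }
  card_ab <- card_a * card_b / g
  offset <- if (is.null(seed)) 0 else withr::with_seed(seed, sample.int(g, 1) - 1)
  # linear [0, G) layout: A = [0, card_a); B = [0, card_ab) u
  # [card_a, card_a + card_b - card_ab); rotate by offset, map to chroms
  a_lin <- matrix(c(0, card_a), ncol = 2)
  b_lin <- rbind(
    if (card_ab > 0) c(0, card_ab),
    if (card_b > card_ab) c(card_a, card_a + card_b - card_ab)
  )
  list(
    a = linear_to_intervals(a_lin, genome, offset),
    b = linear_to_intervals(b_lin, genome, offset)
  )
}

gcd2 <- function(a, b) if (b == 0) a else gcd2(b, a %% b)

# Map linear [start, end) intervals on the concatenated genome coordinate
# (rotated by offset, wrapping) onto per-chromosome intervals.
linear_to_intervals <- function(m, genome, offset = 0) {
  g <- sum(genome$size)
  cum <- cumsum(c(0, genome$size))
  pieces <- list()
  for (r in seq_len(nrow(m))) {
    s <- (m[r, 1] + offset) %% g
    len <- m[r, 2] - m[r, 1]
    while (len > 0) {
      take <- min(len, g - s)
      pieces <- c(pieces, list(c(s, s + take)))
      s <- 0
      len <- len - take
    }
  }
  out <- purrr::map(pieces, function(p) {
    res <- list()
    for (ci in seq_len(nrow(genome))) {
      lo <- max(p[1], cum[ci])
      hi <- min(p[2], cum[ci + 1])
      if (hi > lo) {
        res <- c(res, list(tibble(chrom = genome$chrom[ci],
                                  start = lo - cum[ci], end = hi - cum[ci])))
      }
    }
    bind_rows(res)
  })
  merge_intervals(bind_rows(out))
}

#' Generate a database that exposes the peak-count bias of
#' threshold-and-count ranking
#'
#' Emits one truly collocated target — a small number of the query's own
#' peaks, copied verbatim, so its bases are fully shared with the query —
#' plus `n_targets − 1` independently placed targets whose peak counts span
#' two orders of magnitude (log-spaced between `count_range[1]` and
#' `count_range[2]`). A large independent target overlaps many query peaks
#' by chance alone, so the 1-nt threshold-and-count baseline ranks it above
#' the collocated target, while the threshold-free statistics (and the
#' combined Z-score) do not — the classic failure mode of counting binary
#' overlaps when database entries differ greatly in peak number.
#'
#' @inheritParams sim_intervals
#' @param query Interval tibble; the collocated target copies a subset of
#'   its merged peaks.
#' @param n_targets Total number of database entries (>= 1); default 20.
#' @param n_collocated_peaks Number of query peaks copied into the
#'   collocated target (default 100, capped at the number of query peaks).
#' @param count_range Peak-count span of the independent targets; default
#'   `c(50, 5000)`.
#' @param peak_length Fixed peak length of the independent targets (bases).
#' @return List with `database` (named list of interval tibbles; the
#'   planted target is named `"collocated"`) and `info` (tibble of target,
#'   n_peaks, type).
#' @export
sim_biased_database <- function(genome, query, n_targets = 20,
                                n_collocated_peaks = 100,
                                count_range = c(50, 5000),
                                peak_length = 100, seed = NULL) {
  check_genome(genome)
  check_intervals(query)
  if (n_targets < 1) abort("`n_targets` must be at least 1")
  run <- function() {
    q <- merge_intervals(query)
    k <- min(n_collocated_peaks, nrow(q))
    coll <- arrange(q[sort(sample.int(nrow(q), k)), ],
                    .data$chrom, .data$start)
    db <- list(collocated = coll)
    n_ind <- n_targets - 1
    if (n_ind > 0) {
      counts <- round(exp(seq(log(count_range[1]), log(count_range[2]),
                              length.out = n_ind)))
      nms <- sprintf("random_%02d", seq_len(n_ind))
      for (i in seq_len(n_ind)) {
        db[[nms[i]]] <- sim_intervals(
          genome, counts[i], lengths = list(dist = "fixed", len = peak_length))
      }
      info <- tibble(
        target = c("collocated", nms),
        n_peaks = c(nrow(coll), counts),
        type = c("collocated", rep("independent", n_ind))
      )
    } else {
      info <- tibble(target = "collocated", n_peaks = nrow(coll),
                     type = "collocated")
    }
    list(database = db, info = info)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}
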