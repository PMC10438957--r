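# Independent per-base boolean-array oracle for small genomes, plus plain
# arithmetic versions of the six statistics. Deliberately brute-force and
# independent of the package's interval code paths.

oracle_cover <- function(x, genome) {
  cov <- lapply(stats::setNames(genome$size, genome$chrom), function(s) {
    rep(FALSE, s)
  })
  for (i in seq_len(nrow(x))) {
    ch <- x$chrom[i]
    cov[[ch]][(x$start[i] + 1):x$end[i]] <- TRUE
  }
  cov
}

oracle_summary <- function(a, b, genome) {
  ca <- oracle_cover(a, genome)
  cb <- oracle_cover(b, genome)
  card_a <- sum(vapply(ca, sum, numeric(1)))
  card_b <- sum(vapply(cb, sum, numeric(1)))
  card_ab <- sum(mapply(function(u, v) sum(u & v), ca, cb))
  list(card_a = card_a, card_b = card_b, card_ab = card_ab,
       card_union = card_a + card_b - card_ab, genome_size = sum(genome$size))
}

# the six statistics written out directly from the base counts
oracle_metrics <- function(card_a, card_b, card_ab, g) {
  p_a <- card_a / g
  p_b <- card_b / g
  p_ab <- card_ab / g
  list(
    c = if (card_a == 0 || card_b == 0) 0 else card_ab / sqrt(card_a * card_b),
    j = if (card_a == 0 || card_b == 0) 0 else card_ab / (card_a + card_b - card_ab),
    sd = if (card_a == 0 || card_b == 0) 0 else 2 * card_ab / (card_a + card_b),
    ss = if (card_a == 0 || card_b == 0) 0 else card_ab / min(card_a, card_b),
    pmi = if (card_a == 0 || card_b == 0) NA_real_
          else if (card_ab == 0) -Inf else log(p_ab / (p_a * p_b)),
    npmi = if (card_a == 0 || card_b == 0) NA_real_
           else if (card_ab == 0) -1
           else if (p_ab == 1) 1
           else log(p_a * p_b) / log(p_ab) - 1
  )
}

# random interval set that MAY contain overlapping/duplicated intervals
rand_iset <- function(genome, n, max_len = 50) {
  if (n == 0) {
    return(tibble::tibble(chrom = character(), start = numeric(),
                          end = numeric()))
  }
  chrom <- sample(genome$chrom, n, replace = TRUE)
  size <- genome$size[match(chrom, genome$chrom)]
  len <- pmin(sample.int(max_len, n, replace = TRUE), size)
  start <- floor(runif(n) * (size - len + 1))
  tibble::tibble(chrom = chrom, start = start, end = start + len)
}

# random overlap summaries with valid structure (for formula-level checks)
rand_summaries <- function(n) {
  g <- sample(100:100000, n, replace = TRUE)
  card_a <- sample.int(99, n, replace = TRUE) / 100 * g
  card_b <- sample.int(99, n, replace = TRUE) / 100 * g
  card_a <- pmax(1, floor(card_a))
  card_b <- pmax(1, floor(card_b))
  card_ab <- floor(runif(n) * (pmin(card_a, card_b) + 1))
  tibble::tibble(card_a = card_a, card_b = card_b, card_ab = card_ab,
                 card_union = card_a + card_b - card_ab, genome_size = g)
}

# absolute-tolerance comparison; NA and infinities must match exactly
expect_metric_equal <- function(actual, expected, tol = 1e-12) {
  if (is.na(expected) || is.infinite(expected)) {
    testthat::expect_identical(actual, expected)
  } else {
    testthat::expect_lt(abs(actual - expected), tol)
  }
}
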