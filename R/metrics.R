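# The six collocation statistics. Each takes a summary data frame with
# columns card_a, card_b, card_ab, genome_size (as produced by
# summarize_overlap()) and is vectorized over its rows.

check_summary <- function(o, need_genome = FALSE) {
  need <- c("card_a", "card_b", "card_ab", if (need_genome) "genome_size")
  if (!is.data.frame(o) || !all(need %in% names(o))) {
    abort(paste0("expected an overlap summary data frame with columns ",
                 paste(need, collapse = ", ")))
  }
  invisible(o)
}

#' Collocation coefficient
#'
#' Intersection size over the geometric mean of the two cardinalities:
#' `C = |A ∩ B| / sqrt(|A| |B|)`, bounded in \[0, 1\]. The geometric-mean
#' denominator makes C less sensitive than Jaccard or Sørensen–Dice to a
#' large size imbalance between the two sets. Defined as 0 when either set
#' is empty.
#'
#' @param o Overlap summary data frame (see [summarize_overlap()]);
#'   vectorized over rows.
#' @return Numeric vector of scores.
#' @export
collocation_coefficient <- function(o) {
  check_summary(o)
  ifelse(o$card_a == 0 | o$card_b == 0, 0,
         o$card_ab / sqrt(o$card_a * o$card_b))
}

#' Jaccard coefficient
#'
#' `J = |A ∩ B| / |A ∪ B|`, bounded in \[0, 1\]; 0 when either set is empty.
#' Unlike the BEDTools flavor, the denominator counts every input interval,
#' overlapping or not.
#'
#' @inheritParams collocation_coefficient
#' @return Numeric vector of scores.
#' @export
jaccard <- function(o) {
  check_summary(o)
  un <- o$card_a + o$card_b - o$card_ab
  ifelse(o$card_a == 0 | o$card_b == 0, 0, o$card_ab / un)
}

#' Sørensen–Dice coefficient
#'
#' Intersection over the arithmetic mean: `SD = 2|A ∩ B| / (|A| + |B|)`,
#' bounded in \[0, 1\]; 0 when either set is empty. Interconvertible with
#' Jaccard: `J = SD / (2 − SD)` and `SD = 2J / (1 + J)`.
#'
#' @inheritParams collocation_coefficient
#' @return Numeric vector of scores.
#' @export
sorensen_dice <- function(o) {
  check_summary(o)
  ifelse(o$card_a == 0 | o$card_b == 0, 0,
         2 * o$card_ab / (o$card_a + o$card_b))
}

#' Szymkiewicz–Simpson (overlap) coefficient
#'
#' Intersection over the smaller cardinality:
#' `SS = |A ∩ B| / min(|A|, |B|)`, bounded in \[0, 1\]; reaches 1 whenever
#' one set is contained in the other. Defined as 0 when either set is empty.
#'
#' @inheritParams collocation_coefficient
#' @return Numeric vector of scores.
#' @export
szymkiewicz_simpson <- function(o) {
  check_summary(o)
  ifelse(o$card_a == 0 | o$card_b == 0, 0,
         o$card_ab / pmin(o$card_a, o$card_b))
}

#' Pointwise mutual information of base coverage
#'
#' With coverage probabilities `p(A) = |A|/G`, `p(B) = |B|/G` and
#' `p(A ∩ B) = |A ∩ B|/G`, `PMI = ln( p(A ∩ B) / (p(A) p(B)) )` (natural
#' logarithm). PMI = 0 means the observed shared coverage equals the
#' product-of-marginals expectation (independence); positive / negative PMI
#' means more / less overlap than expected. Empty intersection gives `-Inf`;
#' an empty input set gives `NA` (the expression is meaningless when a
#' marginal probability is 0). Upper bound: `min(-ln p(A), -ln p(B))`.
#'
#' @inheritParams collocation_coefficient
#' @return Numeric vector of scores in natural-log units.
#' @export
pmi <- function(o) {
  check_summary(o, need_genome = TRUE)
  g <- o$genome_size
  out <- ifelse(o$card_ab == 0, -Inf,
                log(o$card_ab * g / (o$card_a * o$card_b)))
  out[o$card_a == 0 | o$card_b == 0] <- NA_real_
  out
}

#' Normalized pointwise mutual information
#'
#' `NPMI = PMI / (−ln p(A ∩ B)) = ln(p(A) p(B)) / ln(p(A ∩ B)) − 1`,
#' rescaling PMI to \[−1, 1\]: −1 for no shared bases, 0 for independence,
#' 1 for identical sets. The degenerate case p(A ∩ B) = 1 (both sets cover
#' the whole genome, so A = B) returns 1; an empty input set gives `NA`.
#'
#' @inheritParams collocation_coefficient
#' @return Numeric vector of unitless scores.
#' @export
npmi <- function(o) {
  check_summary(o, need_genome = TRUE)
  g <- o$genome_size
  p_ab <- o$card_ab / g
  denom <- log(p_ab)  # -Inf for empty intersection, 0 when p_ab = 1
  out <- ifelse(o$card_ab == 0, -1,
                ifelse(p_ab == 1, 1,
                       log((o$card_a / g) * (o$card_b / g)) / denom - 1))
  out[o$card_a == 0 | o$card_b == 0] <- NA_real_
  out
}

metric_names <- c("c", "j", "sd", "ss", "pmi", "npmi")

metric_fun <- function(metric) {
  switch(metric,
    c = collocation_coefficient,
    j = jaccard,
    sd = sorensen_dice,
    ss = szymkiewicz_simpson,
    pmi = pmi,
    npmi = npmi,
    abort(paste0("unknown metric '", metric, "'; choose from ",
                 paste(metric_names, collapse = ", ")))
  )
}

metric_range <- function(metric) {
  switch(metric,
    c = , j = , sd = , ss = c(0, 1),
    npmi = c(-1, 1),
    pmi = c(-Inf, Inf)
  )
}

# All six metrics as columns appended to a summary data frame.
metric_columns <- function(o) {
  check_summary(o, need_genome = TRUE)
  tibble(
    c = collocation_coefficient(o),
    j = jaccard(o),
    sd = sorensen_dice(o),
    ss = szymkiewicz_simpson(o),
    pmi = pmi(o),
    npmi = npmi(o)
  )
}

#' Pairwise collocation statistics for two interval sets
#'
#' The main pairwise entry point: merges both sets, assembles the base-count
#' summary against the genome background, and computes all six collocation
#' statistics.
#'
#' @inheritParams summarize_overlap
#' @param name_a,name_b Labels for the report (default to the sets'
#'   `"coloc_name"` attributes, falling back to `"A"` / `"B"`).
#' @return One-row tibble with columns `name_a`, `name_b`, `card_a`,
#'   `card_b`, `card_ab`, `card_union`, `genome_size`, `c`, `j`, `sd`, `ss`,
#'   `pmi`, `npmi`.
#' @examples
#' g <- sim_genome(c(chr1 = 1000))
#' a <- tibble::tibble(chrom = "chr1", start = 0, end = 200)
#' b <- tibble::tibble(chrom = "chr1", start = 150, end = 200)
#' coloc_stats(a, b, g)
#' @export
coloc_stats <- function(a, b, genome, name_a = NULL, name_b = NULL,
                        clip = FALSE) {
  o <- summarize_overlap(a, b, genome, clip = clip)
  dplyr::bind_cols(
    tibble(
      name_a = name_a %||% attr(a, "coloc_name") %||% "A",
      name_b = name_b %||% attr(b, "coloc_name") %||% "B"
    ),
    o,
    metric_columns(o)
  )
}
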