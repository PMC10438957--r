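test_that("sim_intervals places canonical, in-bounds, reproducible sets", {
  g <- sim_genome(c(chr1 = 20000, chr2 = 10000))
  x <- sim_intervals(g, 50, lengths = list(dist = "fixed", len = 100), seed = 3)
  expect_equal(nrow(x), 50)
  expect_identical(as.data.frame(merge_intervals(x)), as.data.frame(x))
  expect_equal(interval_cardinality(x), 50 * 100)
  lim <- g$size[match(x$chrom, g$chrom)]
  expect_true(all(x$start >= 0 & x$end <= lim))
  expect_identical(sim_intervals(g, 50, lengths = list(dist = "fixed", len = 100), seed = 3), x)
  expect_error(sim_intervals(sim_genome(c(chr1 = 100)), 5,
                             lengths = list(dist = "fixed", len = 50)),
               "infeasible")
})

test_that("sim_pair plants the requested shared fraction", {
  g <- sim_genome(c(chr1 = 200000))
  ab <- sim_pair(g, n_a = 100, n_b = 100, shared_fraction = 0.5, seed = 9)
  expect_lt(abs(ab$realized$shared_fraction - 0.5), 0.05)
  ab2 <- sim_pair(g, n_a = 100, n_b = 100, shared_fraction = 0.5, seed = 9)
  expect_identical(ab, ab2)
})

test_that("generator bookkeeping matches measurement on the emitted files", {
  g <- sim_genome(c(chr1 = 200000))
  ab <- sim_pair(g, n_a = 80, n_b = 120, shared_fraction = 0.3, seed = 13)
  dir <- withr::local_tempdir()
  write_bed(ab$a, file.path(dir, "A.bed"))
  write_bed(ab$b, file.path(dir, "B.bed"))
  o <- summarize_overlap(read_bed(file.path(dir, "A.bed")),
                         read_bed(file.path(dir, "B.bed")), g)
  expect_equal(o$card_a, ab$realized$card_a)
  expect_equal(o$card_b, ab$realized$card_b)
  expect_equal(o$card_ab, ab$realized$card_ab)
})

test_that("shared-fraction extremes give the boundary metric values", {
  g <- sim_genome(c(chr1 = 100000))
  dis <- sim_pair(g, n_a = 50, n_b = 50, shared_fraction = 0, seed = 4)
  s0 <- coloc_stats(dis$a, dis$b, g)
  expect_equal(unlist(s0[, c("c", "j", "sd", "ss")]),
               c(c = 0, j = 0, sd = 0, ss = 0))
  expect_equal(s0$npmi, -1)
  full <- sim_pair(g, n_a = 50, n_b = 50, shared_fraction = 1, seed = 4)
  s1 <- coloc_stats(full$a, full$b, g)
  expect_equal(unlist(s1[, c("c", "j", "sd", "ss", "npmi")]),
               c(c = 1, j = 1, sd = 1, ss = 1, npmi = 1))
})

test_that("realized collocation increases with the planted fraction", {
  g <- sim_genome(c(chr1 = 100000))
  grid <- c(0, 0.25, 0.5, 0.75, 1)
  vals <- purrr::map(grid, function(f) {
    ab <- sim_pair(g, n_a = 60, n_b = 60, shared_fraction = f, seed = 17)
    coloc_stats(ab$a, ab$b, g)
  })
  for (m in c("c", "j", "sd", "ss", "npmi")) {
    expect_true(all(diff(purrr::map_dbl(vals, m)) > 0))
  }
})

test_that("the independence construction gives PMI of exactly zero", {
  g <- sim_genome(c(chr1 = 1000))
  ab <- sim_independent_pair(g, card_a = 500, card_b = 200, seed = 2)
  o <- summarize_overlap(ab$a, ab$b, g)
  expect_equal(o$card_ab, 100)
  expect_lt(abs(pmi(o)), 1e-12)
  expect_lt(abs(npmi(o)), 1e-12)
  # a grid of valid specs, including multi-chromosome genomes
  g2 <- sim_genome(c(chr1 = 600, chr2 = 400))
  for (spec in list(c(100, 10), c(500, 500), c(250, 800), c(1000, 123))) {
    ab <- sim_independent_pair(g2, spec[1], spec[2], seed = spec[1])
    o <- summarize_overlap(ab$a, ab$b, g2)
    expect_equal(o$card_a, spec[1])
    expect_equal(o$card_b, spec[2])
    expect_lt(abs(pmi(o)), 1e-12)
  }
  # whole-genome A: conditioning on G makes any B independent
  abw <- sim_independent_pair(g, card_a = 1000, card_b = 137)
  ow <- summarize_overlap(abw$a, abw$b, g)
  expect_equal(ow$card_ab, 137)
  expect_lt(abs(pmi(ow)), 1e-12)
})

test_that("infeasible independence specs fail with a helpful suggestion", {
  g <- sim_genome(c(chr1 = 1000))
  expect_error(sim_independent_pair(g, 3, 7), "divisible.*feasible")
  expect_error(sim_independent_pair(g, 0, 10), "in \\(0, G\\]")
})

test_that("the biased database separates counting bias from collocation", {
  g <- sim_genome()
  q <- sim_intervals(g, 500, lengths = list(dist = "fixed", len = 100), seed = 10)
  db <- sim_biased_database(g, q, seed = 20)
  expect_equal(length(db$database), 20)
  expect_equal(db$info$type[1], "collocated")
  counts <- db$info$n_peaks[db$info$type == "independent"]
  expect_gte(max(counts) / min(counts), 100)  # spans two orders of magnitude
  # byte-identical regeneration under the same seed
  db2 <- sim_biased_database(g, q, seed = 20)
  expect_identical(db, db2)
  # the collocated target's bases all come from the query
  o <- summarize_overlap(q, db$database$collocated, g)
  expect_equal(o$card_ab, o$card_b)
  # degenerate size-1 database
  expect_equal(names(sim_biased_database(g, q, n_targets = 1, seed = 1)$database),
               "collocated")
})
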