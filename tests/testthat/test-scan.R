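tbl <- function(chrom, start, end) tibble::tibble(chrom = chrom, start = start, end = end)

# small hand-checkable scan fixture: query on chr1, three targets with
# strictly decreasing shared bases
scan_fixture <- function() {
  g <- sim_genome(c(chr1 = 10000))
  query <- tbl("chr1", c(0, 2000, 4000), c(1000, 3000, 5000))  # 3 kb
  db <- list(
    t1 = tbl("chr1", 0, 900),         # 900 shared of 900
    t2 = tbl("chr1", c(500, 8000), c(1000, 8400)),  # 500 shared of 900
    t3 = tbl("chr1", c(900, 6000), c(1000, 6800))   # 100 shared of 900
  )
  list(g = g, query = query, db = db)
}

test_that("combine_z follows the sqrt-k normalization and drops NAs", {
  expect_equal(combine_z(rep(0, 6)), 0)
  expect_equal(combine_z(rep(1, 6)), 6 / sqrt(6))
  expect_equal(combine_z(rep(1, 6), method = "mean"), 1)
  expect_equal(combine_z(c(1, 2, NA)), 3 / sqrt(2))
  expect_true(is.na(combine_z(c(NA_real_, NA_real_))))
  expect_gt(combine_z(rep(2, 6)), combine_z(rep(1, 6)))
  m <- rbind(rep(1, 6), rep(0, 6))
  expect_equal(combine_z(m), c(sqrt(6), 0))
})

test_that("scan standardizes, ranks and keeps the best-shared target first", {
  fx <- scan_fixture()
  sc <- coloc_scan(fx$query, fx$db, fx$g)
  expect_s3_class(sc, "coloc_scan")
  expect_equal(sc$target, c("t1", "t2", "t3"))
  expect_equal(sc$rank, 1:3)
  # every metric column is strictly decreasing down the table, so t1's
  # per-metric Z-scores are the largest; spot-check against by-hand Z
  x <- sc$j
  expect_equal(sc$z_j, (x - mean(x)) / sd(x))
  for (zc in paste0("z_", c("c", "j", "sd", "ss", "pmi", "npmi"))) {
    expect_lt(abs(mean(sc[[zc]])), 1e-9)
    expect_lt(abs(sd(sc[[zc]]) - 1), 1e-9)
  }
  expect_equal(sc$combined_z,
               combine_z(as.matrix(tibble::as_tibble(sc)[paste0("z_", c("c", "j", "sd", "ss", "pmi", "npmi"))])))
})

test_that("scan ranking is invariant to the combined-Z denominator", {
  fx <- scan_fixture()
  s1 <- coloc_scan(fx$query, fx$db, fx$g, method = "sqrt_k")
  s2 <- coloc_scan(fx$query, fx$db, fx$g, method = "mean")
  expect_equal(s1$target, s2$target)
  expect_equal(s1$rank, s2$rank)
  expect_equal(s1$outlier, s2$outlier)
  expect_equal(s1$combined_z, s2$combined_z * sqrt(6))
})

test_that("exclude removes the self-match before standardization", {
  fx <- scan_fixture()
  db <- c(fx$db, list(QUERY = fx$query))
  sc <- coloc_scan(fx$query, db, fx$g, exclude = "QUERY")
  expect_false("QUERY" %in% sc$target)
  expect_equal(nrow(sc), 3)
  expect_error(coloc_scan(fx$query, fx$db[1:2], fx$g), "at least 3")
})

test_that("identical targets give zero variance, Z = 0 and no outliers", {
  fx <- scan_fixture()
  db <- list(a = fx$db$t1, b = fx$db$t1, c = fx$db$t1)
  w <- capture_warnings(sc <- coloc_scan(fx$query, db, fx$g))
  expect_true(any(grepl("zero variance", w)))
  expect_true(all(sc$combined_z == 0))
  expect_false(any(sc$outlier))
  # rank ties broken by name, stably
  expect_equal(sc$target, c("a", "b", "c"))
})

test_that("-Inf PMI targets are standardized as missing, not propagated", {
  fx <- scan_fixture()
  db <- c(fx$db, list(far = tbl("chr1", 9000, 9500)))  # no shared bases
  sc <- coloc_scan(fx$query, db, fx$g)
  far <- sc[sc$target == "far", ]
  expect_equal(far$pmi, -Inf)
  expect_true(is.na(far$z_pmi))
  expect_false(is.na(far$combined_z))
  expect_true(all(is.finite(sc$combined_z)))
})

test_that("the 3-SD rule flags exactly the planted extreme", {
  # 100 records at 0 plus one at 10 sample-SDs above their mean
  base <- tibble::tibble(combined_z = c(rep(0, 100), 5))
  fl <- flag_outliers(base)
  expect_equal(sum(fl$outlier), 1)
  expect_true(fl$outlier[101])
  expect_false(any(flag_outliers(tibble::tibble(combined_z = rep(1, 5)))$outlier))
  # two symmetric extremes inflate the SD enough that neither is flagged
  sym <- tibble::tibble(combined_z = c(-4, 0, 0, 0, 4))
  expect_false(any(flag_outliers(sym)$outlier))
  # brute-force check of the rule on the planted table
  cz <- base$combined_z
  expect_identical(fl$outlier, abs(cz - mean(cz)) > 3 * sd(cz))
})

test_that("a planted collocated target attains rank 1 in a random database", {
  g <- sim_genome(c(chr1 = 500000))
  ab <- sim_pair(g, n_a = 150, n_b = 100, shared_fraction = 0.5,
                 lengths = list(dist = "fixed", len = 100), seed = 71)
  db <- list(planted = ab$b)
  for (i in 1:8) {
    db[[paste0("bg", i)]] <- sim_intervals(
      g, 100, lengths = list(dist = "fixed", len = 100), seed = 71 + i)
  }
  sc <- coloc_scan(ab$a, db, g)
  expect_equal(sc$target[1], "planted")
})

test_that("scan accepts an on-disk database directory", {
  fx <- scan_fixture()
  dir <- withr::local_tempdir()
  for (nm in names(fx$db)) write_bed(fx$db[[nm]], file.path(dir, paste0(nm, ".bed")))
  sc <- coloc_scan(fx$query, dir, fx$g)
  expect_equal(sort(sc$target), c("t1", "t2", "t3"))
  man <- file.path(dir, "manifest.tsv")
  writeLines(paste(names(fx$db), paste0(names(fx$db), ".bed"), sep = "\t"), man)
  db2 <- read_bed_database(man)
  expect_equal(names(db2), c("t1", "t2", "t3"))
  expect_equal(as.data.frame(db2$t2), as.data.frame(fx$db$t2),
               ignore_attr = TRUE)
})
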