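test_that("interval constructor enforces the invariants", {
  x <- genomic_intervals(c("chr2", "chr1"), c(5L, 10L), c(9L, 20L))
  expect_equal(x$chrom, c("chr1", "chr2"))        # sorted
  expect_equal(interval_width(x), c(10L, 4L))
  expect_error(genomic_intervals("chr1", -1L, 5L), "start")
  expect_error(genomic_intervals("chr1", 5L, 5L), "end")
  expect_error(genomic_intervals("chr1", c(0L, 0L), c(10L, 10L)),
               "duplicate")
  expect_silent(genomic_intervals("chr1", c(0L, 0L), c(10L, 10L),
                                  unique = FALSE))
})

test_that("reciprocal overlap filter applies 'at least' on both sides", {
  a <- ivl(0L, 1000L)
  expect_equal(nrow(reciprocal_overlap_filter(a, ivl(0L, 1000L))), 1L)
  # exactly 50% of both partners passes; one bp less fails
  expect_equal(nrow(reciprocal_overlap_filter(a, ivl(500L, 1500L), 0.5)), 1L)
  expect_equal(nrow(reciprocal_overlap_filter(a, ivl(501L, 1501L), 0.5)), 0L)
  # one pair must pass both fractions; no summing across b-peaks
  b2 <- ivl(c(0L, 600L), c(400L, 1000L))
  expect_equal(nrow(reciprocal_overlap_filter(a, b2, 0.5)), 0L)
  expect_equal(nrow(reciprocal_overlap_filter(a[0], ivl(0L, 10L))), 0L)
  expect_error(reciprocal_overlap_filter(a, a, 0), "min_fraction")
  expect_error(reciprocal_overlap_filter(a, a, 1.5), "min_fraction")
})

test_that("reciprocal filter is a subset of a and idempotent", {
  set.seed(31)
  for (rep in 1:25) {
    a <- genomic_intervals("chr1", st <- sort(sample(0:5000, 30)) * 10L,
                           st * 10L + sample(50:500, 30, TRUE),
                           unique = FALSE)
    a <- unique(a, by = c("chrom", "start", "end"))
    st2 <- sort(sample(0:5000, 30)) * 10L
    b <- genomic_intervals("chr1", st2, st2 + sample(50:500, 30, TRUE),
                           unique = FALSE)
    b <- unique(b, by = c("chrom", "start", "end"))
    f <- reciprocal_overlap_filter(a, b, 0.5)
    expect_true(all(paste(f$start, f$end) %in% paste(a$start, a$end)))
    f2 <- reciprocal_overlap_filter(f, b, 0.5)
    expect_equal(f2, f)
  }
})

test_that("top_n_by_signal keeps the n highest with coordinate tie-break", {
  p3 <- ivl(c(0L, 100L, 200L), c(50L, 150L, 250L), signal = c(1, 2, 3))
  expect_equal(nrow(top_n_by_signal(p3, 20000L)), 3L)
  set.seed(1)
  big <- genomic_intervals("chr1", s <- (1:25000) * 100L, s + 50L,
                           signal = sample(25000))
  kept <- top_n_by_signal(big, 20000L)
  expect_equal(nrow(kept), 20000L)
  expect_setequal(kept$signal, 5001:25000)
  ties <- ivl((1:5) * 100L, (1:5) * 100L + 10L,
              signal = c(9, 9, 9, 1, 1))
  got <- top_n_by_signal(ties, 2L)
  expect_equal(got$start, c(100L, 200L))   # coordinate-smallest of the 9s
  nosig <- ivl(0L, 10L)
  expect_error(top_n_by_signal(nosig, 1L), "chr1:0-10")
})

test_that("merge_within is a transitive closure on the gap relation", {
  expect_equal(nrow(merge_within(ivl(0L, 100L), 10L)), 1L)
  m <- merge_within(ivl(c(0L, 200L), c(100L, 300L)), 100L)
  expect_equal(m[, .(start, end)], data.table(start = 0L, end = 300L))
  expect_equal(m$n_constituents, 2L)
  expect_equal(nrow(merge_within(ivl(c(0L, 201L), c(100L, 300L)), 100L)), 2L)
  # properties over random inputs
  set.seed(17)
  for (rep in 1:25) {
    n <- sample(2:60, 1)
    st <- sort(sample(0:10000, n))
    x <- genomic_intervals("chr1", st, st + sample(10:400, n, TRUE),
                           unique = FALSE)
    gap <- sample(0:300, 1)
    m <- merge_within(x, gap)
    if (nrow(m) > 1) expect_true(all(diff(m$start) - head(m$end, -1) +
                                       head(m$start, -1) > gap))
    cov_in <- sum(interval_width(
      merge_within(x, 0L)))  # union coverage of input
    expect_gte(sum(interval_width(m)), cov_in)
    expect_equal(sum(m$n_constituents), nrow(x))
  }
})

test_that("quantify_rpm counts >=1 bp overlaps scaled per million", {
  region <- ivl(1000L, 2000L)
  expect_equal(quantify_rpm(region, frags(integer())), 0)
  expect_equal(quantify_rpm(region, frags(seq(1000L, 1900L, 100L))), 10)
  # 1 bp overlap counts: fragment [901,1001) touches [1000,2000)
  expect_equal(quantify_rpm(region, frags(901L)), 1)
  # and [900,1000) does not
  expect_equal(quantify_rpm(region, frags(900L)), 0)
  expect_error(fragment_set(ivl(0L, 10L), 0), "library_size")
})

test_that("quantify_rpm is additive over disjoint fragment subsets", {
  set.seed(23)
  region <- ivl(0L, 5000L)
  st <- sample(0:6000, 200)
  all_f <- frags(st)
  f1 <- frags(st[1:80])
  f2 <- frags(st[81:200])
  expect_equal(quantify_rpm(region, all_f),
               quantify_rpm(region, f1) + quantify_rpm(region, f2))
})

test_that("BED and manifest round-trips preserve intervals", {
  dir <- withr::local_tempdir()
  x <- genomic_intervals(c("chr1", "chr2"), c(10L, 5L), c(90L, 55L),
                         name = c("a", "b"), signal = c(1.5, 2))
  p <- file.path(dir, "x.bed")
  write_bed(x, p)
  y <- read_bed(p)
  expect_equal(y[, .(chrom, start, end, name, signal)],
               x[, .(chrom, start, end, name, signal)])
  writeLines("sample_label\tpath\tlibrary_size\ns1\tx.bed\t1000",
             file.path(dir, "mani.tsv"))
  m <- read_manifest(file.path(dir, "mani.tsv"))
  fs <- load_fragments(m, "s1")
  expect_s3_class(fs, "fragment_set")
  expect_equal(fs$library_size, 1000)
  expect_error(load_fragments(m, "nope"), "not found")
})
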