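test_that("chain parsing verifies block arithmetic and round-trips", {
  txt <- chain_text(data.table(size = c(100L, 100L), dt = c(50L, 0L),
                               dq = c(0L, 0L)))
  ch <- parse_chain(text = txt)[[1]]
  expect_equal(ch$t_end - ch$t_start, 250L)
  expect_equal(ch$q_end - ch$q_start, 200L)
  # writer round-trip
  dir <- withr::local_tempdir()
  write_chain(list(ch), f <- file.path(dir, "t.chain"))
  ch2 <- parse_chain(f)[[1]]
  expect_equal(ch2, ch)
  # violated target arithmetic -> error naming the chain
  bad <- txt
  bad[1] <- sub(" 0 250 ", " 0 260 ", bad[1])
  expect_error(parse_chain(text = bad), "target block arithmetic")
  expect_error(parse_chain(text = c("chain 1 chr1", "10", "")), "header")
})

test_that("liftover through an identity chain is the identity", {
  chains <- identity_chain(100000L)
  set.seed(53)
  for (rep in 1:40) {
    st <- sample(0:90000, 1)
    iv <- ivl(st, st + sample(10:5000, 1))
    r <- liftover(iv, chains)
    expect_equal(r$status, "mapped")
    expect_equal(r$match_fraction, 1)
    expect_equal(r$mapped_interval[, .(chrom, start, end)],
                 iv[, .(chrom, start, end)])
  }
})

test_that("minimum-match filtering uses mappable bases over width", {
  # one 150 bp block inside a 1000 bp interval -> fraction 0.15 < 0.2
  chains <- parse_chain(text = chain_text(
    data.table(size = c(100L, 150L, 100L), dt = c(300L, 1350L, 0L),
               dq = c(300L, 1350L, 0L)), t_size = 5000L, q_size = 5000L))
  r <- liftover(ivl(400L, 1400L), chains, min_match = 0.2)
  expect_equal(r$status, "unmapped_low_match")
  expect_equal(r$match_fraction, 0.15)
  r2 <- liftover(ivl(400L, 1400L), chains, min_match = 0.15)
  expect_equal(r2$status, "mapped")
  expect_equal(r2$mapped_interval$start, 400L)
  expect_equal(r2$mapped_interval$end, 550L)
  expect_equal(liftover(ivl(900000L, 900100L, chrom = "chr9"),
                        chains)$status, "unmapped_no_chain")
  expect_error(liftover(ivl(0L, 10L), chains, min_match = 0), "min_match")
})

test_that("minus-strand chains reflect coordinates as qSize - pos", {
  # block maps target [100,200) to alignment coords [100,200) on '-' of a
  # 10,000 bp query: expected interval [10000-200, 10000-100)
  chains <- parse_chain(text = chain_text(
    data.table(size = 100L), t_size = 1000L, t_start = 100L,
    q_size = 10000L, q_strand = "-", q_start = 100L))
  r <- liftover(ivl(100L, 200L), chains)
  expect_equal(r$status, "mapped")
  expect_equal(r$mapped_interval$start, 9800L)
  expect_equal(r$mapped_interval$end, 9900L)
  # partial: target [150,200) -> alignment [150,200) -> [9800, 9850)
  rp <- liftover(ivl(150L, 200L), chains)
  expect_equal(rp$mapped_interval$start, 9800L)
  expect_equal(rp$mapped_interval$end, 9850L)
})

test_that("round-trip through the inverse chain contains the original", {
  # forward: gapped chain; inverse swaps target/query and dt/dq
  fwd_blocks <- data.table(size = c(500L, 800L, 300L),
                           dt = c(200L, 100L, 0L), dq = c(50L, 400L, 0L))
  inv_blocks <- data.table(size = fwd_blocks$size, dt = fwd_blocks$dq,
                           dq = fwd_blocks$dt)
  fwd <- parse_chain(text = chain_text(fwd_blocks, t_size = 5000L,
                                       q_size = 5000L))
  inv <- parse_chain(text = chain_text(inv_blocks, t_size = 5000L,
                                       q_size = 5000L))
  # target block spans implied by fwd_blocks (t_start = 0)
  t0 <- cumsum(c(0L, head(fwd_blocks$size + fwd_blocks$dt, -1)))
  t1 <- t0 + fwd_blocks$size
  set.seed(59)
  n_checked <- 0L
  for (rep in 1:25) {
    st <- sample(0:1500, 1)
    iv <- ivl(st, st + sample(20:400, 1))
    f <- liftover(iv, fwd, min_match = 0.05)
    if (f$status != "mapped") next
    b <- liftover(f$mapped_interval, inv, min_match = 0.05)
    expect_equal(b$status, "mapped")
    # the back-mapped span contains every originally block-mapped base
    ov_lo <- pmax(t0, iv$start); ov_hi <- pmin(t1, iv$end)
    hit <- ov_hi > ov_lo
    expect_lte(b$mapped_interval$start, min(ov_lo[hit]))
    expect_gte(b$mapped_interval$end, max(ov_hi[hit]))
    n_checked <- n_checked + 1L
  }
  expect_gt(n_checked, 5L)
})

test_that("match fraction never increases as target gaps widen", {
  fractions <- sapply(c(0L, 100L, 300L, 600L, 1200L), function(gap) {
    chains <- parse_chain(text = chain_text(
      data.table(size = c(400L, 400L), dt = c(gap, 0L), dq = c(gap, 0L)),
      t_size = 10000L, q_size = 10000L))
    liftover(ivl(0L, 800L + gap), chains, min_match = 0.01)$match_fraction
  })
  expect_true(all(diff(fractions) <= 0))
})

test_that("two passing chains with disjoint query spans are ambiguous", {
  c1 <- chain_text(data.table(size = 1000L), t_size = 10000L,
                   t_start = 0L, q_size = 50000L, q_start = 0L, id = "1")
  c2 <- chain_text(data.table(size = 1000L), t_size = 10000L,
                   t_start = 0L, q_size = 50000L, q_start = 30000L,
                   id = "2", score = 900)
  chains <- parse_chain(text = c(c1, c2))
  r <- liftover(ivl(100L, 600L), chains)
  expect_equal(r$status, "ambiguous_multiple_chains")
})

test_that("liftover agrees with rtracklayer on a gapped chain", {
  skip_if_not_installed("rtracklayer")
  blocks <- data.table(size = c(500L, 700L), dt = c(250L, 0L),
                       dq = c(900L, 0L))
  txt <- chain_text(blocks, t_size = 5000L, q_size = 9000L, q_name = "chrQ")
  dir <- withr::local_tempdir()
  writeLines(txt, f <- file.path(dir, "t.chain"))
  ch <- rtracklayer::import.chain(f)
  gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 1300))  # 1-based
  hits <- unlist(rtracklayer::liftOver(gr, ch))
  want_span <- c(min(GenomicRanges::start(hits)) - 1L,
                 max(GenomicRanges::end(hits)))
  ours <- liftover(ivl(100L, 1300L), parse_chain(f), min_match = 0.2)
  expect_equal(ours$mapped_interval$start, want_span[1])
  expect_equal(ours$mapped_interval$end, want_span[2])
})

test_that("functional conservation requires links in both other species", {
  pig <- ivl(c(1000L, 5000L, 9000L), c(2000L, 6000L, 10000L),
             name = c("e1", "e2", "e3"))
  human <- ivl(c(1500L, 5500L), c(2500L, 6500L))
  mouse <- ivl(1200L, 2200L)
  fc <- classify_functionally_conserved(pig, human, mouse)
  expect_equal(fc$elements[order(name), conserved], c(TRUE, FALSE, FALSE))
  expect_equal(fc$n_conserved, 1L)
  expect_equal(fc$fraction, 1 / 3)
  # unmapped elements enlarge the denominator
  fc2 <- classify_functionally_conserved(pig, human, mouse, n_unmapped = 2L)
  expect_equal(fc2$n_total, 5L)
  expect_equal(fc2$fraction, 0.2)
  # frame mismatch heuristic
  alt <- ivl(0L, 10L, chrom = "scaffold_7")
  expect_error(classify_functionally_conserved(pig, alt, mouse),
               "frame mismatch")
})

test_that("track readers and score aggregation honor missing data", {
  dir <- withr::local_tempdir()
  writeLines(c("fixedStep chrom=chr1 start=101 step=1", "0.8", "0.8",
               "0.8", "fixedStep chrom=chr1 start=201 step=1", "1.0",
               "0.0"),
             w <- file.path(dir, "t.wig"))
  tr <- read_track(w)
  expect_s3_class(tr, "conservation_track")
  expect_equal(tr$start[1], 100L)                 # 1-based converted
  full <- mean_conservation_score(ivl(100L, 103L), tr)
  expect_equal(full$mean_score, 0.8)
  expect_equal(full$coverage, 1)
  half <- mean_conservation_score(ivl(200L, 202L), tr)
  expect_equal(half$mean_score, 0.5)
  nodata <- mean_conservation_score(ivl(5000L, 6000L), tr)
  expect_true(is.na(nodata$mean_score))
  expect_equal(nodata$coverage, 0)
  # bedGraph path, run-length spans
  writeLines("chr1\t0\t100\t0.25", b <- file.path(dir, "t.bg"))
  tb <- read_track(b)
  got <- mean_conservation_score(ivl(50L, 150L), tb)
  expect_equal(got$mean_score, 0.25)
  expect_equal(got$coverage, 0.5)
  expect_error(conservation_track(data.table(chrom = "chr1", start = 0L,
                                             end = 10L, score = 1.2)),
               "scores")
})
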