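test_that("the generator is deterministic under a fixed seed", {
  dir <- withr::local_tempdir()
  generate_panel(small_config(7L), file.path(dir, "a"))
  generate_panel(small_config(7L), file.path(dir, "b"))
  fa <- list.files(file.path(dir, "a"), recursive = TRUE)
  fb <- list.files(file.path(dir, "b"), recursive = TRUE)
  expect_equal(fa, fb)
  for (f in fa) {
    expect_equal(unname(tools::md5sum(file.path(dir, "a", f))),
                 unname(tools::md5sum(file.path(dir, "b", f))),
                 label = f)
  }
  # a different seed changes placements
  generate_panel(small_config(8L), file.path(dir, "c"))
  ta <- fread(file.path(dir, "a", "truth.tsv"))
  tc <- fread(file.path(dir, "c", "truth.tsv"))
  expect_false(identical(ta$start, tc$start))
})

test_that("emitted peak counts match the configured panel structure", {
  dir <- withr::local_tempdir()
  cfg <- small_config(13L, n_background_peaks = 200L)
  pan <- generate_panel(cfg, dir)
  k27 <- read_bed(file.path(dir, "focal", "tisA.k27.peaks.bed"))
  # 5 clusters x 4 peaks + 200 background = 220 peaks
  expect_equal(nrow(k27), 220L)
  expect_equal(pan$truth[tissue == "tisA" & class == "se", .N], 5L)
  k4 <- read_bed(file.path(dir, "focal", "tisA.k4.peaks.bed"))
  expect_equal(nrow(k4), 105L)
  # planted BDs are >= 3x wider than any background H3K4me3 peak
  w <- interval_width(k4)
  bd_w <- pan$truth[tissue == "tisA" & class == "bd", end - start]
  expect_gte(min(bd_w), 3 * max(w[!w %in% bd_w]))
})

test_that("planted net rpm re-quantified from fragment files is exact", {
  dir <- withr::local_tempdir()
  cfg <- small_config(21L)
  pan <- generate_panel(cfg, dir)
  man <- read_manifest(file.path(dir, "focal", "manifest.tsv"))
  chip <- load_fragments(man, "tisA_k27_chip")
  ctl <- load_fragments(man, "tisA_k27_control")
  se <- pan$truth[tissue == "tisA" & class == "se"]
  net <- quantify_rpm(se[, .(chrom, start, end)], chip) -
    quantify_rpm(se[, .(chrom, start, end)], ctl)
  target <- se$chip_count - cfg$peaks_per_cluster * cfg$control_per_peak
  expect_true(all(abs(net - target) <= 1))
  # planted cluster net exceeds the strongest background region 10-fold
  te <- pan$truth[tissue == "tisA" & class == "te"]
  te_net <- quantify_rpm(te[, .(chrom, start, end)], chip) -
    quantify_rpm(te[, .(chrom, start, end)], ctl)
  expect_gte(min(net) / max(te_net), 10)
})

test_that("emitted chains are valid and planted orthologs lift cleanly", {
  dir <- withr::local_tempdir()
  pan <- generate_panel(small_config(29L), dir)
  fchains <- parse_chain(file.path(dir, "focal_to_reference.chain"))
  tchains <- parse_chain(file.path(dir, "third_to_reference.chain"))
  expect_length(fchains, 2L)
  expect_equal(sum(vapply(fchains, function(c) c$q_strand == "-",
                          logical(1))), 1L)   # one strand-flipped chain
  cons <- unique(pan$truth[conserved == TRUE & class %in% c("se", "bd"),
                           .(chrom, start, end, name = site_id)])
  lifted <- liftover_table(cons, fchains)
  expect_true(all(lifted$status == "mapped"))
  expect_true(all(lifted$match_fraction >= 0.95))
  # reference counterparts overlap the lifted focal elements
  ref <- rbind(read_bed(file.path(dir, "reference", "tisA.se.bed")),
               read_bed(file.path(dir, "reference", "tisA.bd.bed")))
  hit <- merge(lifted[name %in% ref$name,
                      .(name, lifted_start, lifted_end)],
               ref[, .(name, start, end)], by = "name")
  expect_true(all(hit$lifted_start < hit$end &
                    hit$start < hit$lifted_end))
  # third-species counterparts lift onto the same reference loci
  thr <- rbind(read_bed(file.path(dir, "third", "tisA.se.bed")),
               read_bed(file.path(dir, "third", "tisA.bd.bed")))
  thr_l <- liftover_table(thr, tchains)
  expect_true(all(thr_l$status == "mapped"))
})

test_that("fully private panels yield fraction_specific 1 end to end", {
  dir <- withr::local_tempdir()
  cfg <- small_config(37L,
                      fraction_private = list(se = 1, te = 1, bd = 1, nd = 1),
                      fraction_conserved = list(se = 0, te = 0,
                                                bd = 0, nd = 0))
  pan <- generate_panel(cfg, dir)
  sizes <- read_chrom_sizes(file.path(dir, "focal.sizes"))
  panel <- lapply(split(pan$truth[class == "te"], by = "tissue"),
                  function(x) unify_width(x[, .(chrom, start, end)],
                                          2000L, sizes))
  res <- classify_specific(panel, 2000L)
  expect_equal(res$per_tissue$fraction_specific, rep(1, 2))
})

test_that("infeasible geometry and bad fractions are config errors", {
  expect_error(generate_panel(small_config(1L, n_background_peaks = 5000L),
                              withr::local_tempdir()),
               "infeasible geometry")
  expect_error(small_config(1L, intra_cluster_gap = 20000L), "12.5 kb")
  expect_error(
    generate_panel(small_config(1L, fraction_private = list(
      se = 0.5, te = 0.4, bd = 0.2, nd = 0.1)), withr::local_tempdir()),
    "integer")
})
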