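#' Simulation configuration for the synthetic panel generator
#'
#' The generator emulates the statistical structure the pipeline assumes:
#' clustered high-signal H3K27ac peaks (planted super-enhancer clusters)
#' among isolated background peaks, a long right tail of H3K4me3 widths
#' (planted broad domains), tissue-shared versus tissue-private element
#' placement, three toy genomes linked by alignment chains with
#' three-way-orthologous positions, and elevated expression of genes
#' nearest planted elements. All placement happens on a fixed site grid
#' inside chain-aligned blocks, with inter-site pitch large enough that
#' distinct sites never stitch (gap > 12.5 kb) nor merge at the widest
#' specificity distance (8 kb).
#'
#' @param seed integer seed; every random draw derives from it.
#' @param tissues tissue labels (>= 2).
#' @param n_background_peaks isolated background H3K27ac peaks (typical
#'   enhancers) per tissue.
#' @param n_se_clusters planted SE clusters per tissue.
#' @param peaks_per_cluster constituent peaks per planted cluster.
#' @param cluster_peak_width constituent peak width (bp).
#' @param intra_cluster_gap gap between cluster peaks (bp, < 12500).
#' @param background_width_range min/max background H3K27ac peak width.
#' @param n_k4_peaks background (narrow) H3K4me3 peaks per tissue.
#' @param k4_width_range min/max background H3K4me3 peak width.
#' @param n_planted_bd planted broad domains per tissue.
#' @param bd_width_multiplier planted BD width as a multiple of the
#'   maximum background H3K4me3 width.
#' @param fraction_private per-class fraction (se, te, bd, nd) of each
#'   tissue's elements placed at tissue-private sites; the rest sit at
#'   sites shared by every tissue. Counts must come out integer.
#' @param fraction_conserved per-class fraction of each tissue's elements
#'   given orthologous counterparts in both other species (drawn from the
#'   shared sites, so the flag is consistent across tissues).
#' @param se_effect planted cluster net rpm as a multiple of the maximum
#'   background chip count.
#' @param background_chip_range min/max chip fragments per background peak.
#' @param control_per_peak control fragments per peak.
#' @param fragment_length emitted fragment length (bp).
#' @param chip_library,control_library manifest library sizes; the default
#'   1e6 makes rpm equal the fragment count.
#' @param expression list: `meanlog`, `sdlog` of baseline log-normal
#'   counts, `boost` multiplier for genes nearest planted SEs/BDs,
#'   `library_size` for RPKM.
#' @param gene_length annotated gene length (bp).
#' @param conservation_scores list: `conserved_mean`, `background_mean`,
#'   `sd`, and `direction` ("conserved_higher" or "conserved_lower").
#' @param noise add Poisson resampling to fragment counts (default FALSE:
#'   exact counts, crisp expectations).
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       tissues = c("adipose", "brain", "liver",
                                   "lung", "muscle", "spleen"),
                       n_background_peaks = 100L,
                       n_se_clusters = 5L,
                       peaks_per_cluster = 4L,
                       cluster_peak_width = 1000L,
                       intra_cluster_gap = 2000L,
                       background_width_range = c(600L, 1400L),
                       n_k4_peaks = 100L,
                       k4_width_range = c(300L, 1000L),
                       n_planted_bd = 5L,
                       bd_width_multiplier = 3,
                       fraction_private = list(se = 0.6, te = 0.4,
                                               bd = 0.2, nd = 0.1),
                       fraction_conserved = list(se = 0.4, te = 0.1,
                                                 bd = 0.4, nd = 0.1),
                       se_effect = 10,
                       background_chip_range = c(5L, 20L),
                       control_per_peak = 2L,
                       fragment_length = 100L,
                       chip_library = 1e6,
                       control_library = 1e6,
                       expression = list(meanlog = log(200), sdlog = 0.5,
                                         boost = 8, library_size = 1e7),
                       gene_length = 2000L,
                       conservation_scores = list(conserved_mean = 0.8,
                                                  background_mean = 0.3,
                                                  sd = 0.05,
                                                  direction = "conserved_higher"),
                       noise = FALSE) {
  cfg <- as.list(environment())
  if (length(tissues) < 2L) stop("need >= 2 tissues")
  if (intra_cluster_gap > 12500L) stop("intra_cluster_gap must be < 12.5 kb")
  for (f in c(fraction_private, fraction_conserved)) {
    if (f < 0 || f > 1) stop("fractions must be in [0, 1]")
  }
  if (!conservation_scores$direction %in%
      c("conserved_higher", "conserved_lower")) {
    stop("direction must be conserved_higher or conserved_lower")
  }
  cluster_span <- peaks_per_cluster * cluster_peak_width +
    (peaks_per_cluster - 1L) * intra_cluster_gap
  if (cluster_span > 12000L) {
    stop("cluster span ", cluster_span, " bp exceeds the 12 kb site slot")
  }
  # fixed toy-genome geometry (three species, two chromosomes each)
  cfg$geometry <- list(
    block_size = 200000L,
    focal = list(name = "focal", chroms = c(chr1 = 5000000L, chr2 = 5000000L),
                 n_blocks = 24L, dt = 5000L, dq = 9000L),
    reference = list(name = "reference",
                     chroms = c(chr1 = 5200000L, chr2 = 5200000L)),
    third = list(name = "third", chroms = c(chr1 = 5400000L, chr2 = 5400000L),
                 n_blocks = 26L, dt = 7000L, dq = 0L),
    site_pitch = 25000L, sites_per_block = 8L, lane_offset = 12500L,
    site_margin = 5000L)
  class(cfg) <- "sim_config"
  cfg
}

# site grid: positions fully inside focal alignment blocks, one lane per
# mark; returns data.table(chrom, pos, block)
.site_grid <- function(geom, lane = c("k27", "k4")) {
  lane <- match.arg(lane)
  off <- geom$site_margin + if (lane == "k4") geom$lane_offset else 0L
  bs <- geom$block_size
  pitch_t <- bs + geom$focal$dt
  grid <- CJ(chrom = names(geom$focal$chroms),
             block = 0:(geom$focal$n_blocks - 1L),
             slot = 0:(geom$sites_per_block - 1L))
  grid[, pos := block * pitch_t + off + slot * geom$site_pitch]
  setorder(grid, chrom, pos)
  grid[]
}

# map a focal position to reference coordinates (alignment arithmetic on
# the constructed chains; positions must lie inside aligned blocks)
.focal_to_ref <- function(chrom, pos, geom) {
  g <- geom$focal
  bs <- geom$block_size
  k <- pos %/% (bs + g$dt)
  o <- pos - k * (bs + g$dt)
  stopifnot(all(o < bs))
  a <- k * (bs + g$dq) + o
  a  # alignment coords; chr2 chain is minus-strand, reflect at interval level
}

.focal_ivl_to_ref <- function(chrom, start, end, geom) {
  a_s <- .focal_to_ref(chrom, start, geom)
  a_e <- .focal_to_ref(chrom, end - 1L, geom) + 1L
  q_size <- geom$reference$chroms[[chrom]]
  if (chrom == "chr2") {  # minus-strand chain: reflect
    list(start = q_size - a_e, end = q_size - a_s)
  } else {
    list(start = a_s, end = a_e)
  }
}

# inverse-map a reference interval into third-species coordinates through
# the third->reference chain (dq = 0: contiguous query). If the interval
# straddles a query-block boundary, the larger single-block piece is used
# so the planted element lifts cleanly within one block.
.ref_ivl_to_third <- function(chrom, start, end, geom) {
  g <- geom$third
  bs <- geom$block_size
  k_s <- start %/% bs
  k_e <- (end - 1L) %/% bs
  if (k_s != k_e) {
    cutpt <- k_e * bs
    if (cutpt - start >= end - cutpt) end <- cutpt else start <- cutpt
    k_s <- start %/% bs
  }
  t0 <- k_s * (bs + g$dt) + (start - k_s * bs)
  list(start = t0, end = t0 + (end - start))
}

# build the constructed chain objects for one genome pair
.make_chains <- function(geom, which = c("focal", "third")) {
  which <- match.arg(which)
  g <- geom[[which]]
  bs <- geom$block_size
  n <- g$n_blocks
  lapply(seq_along(names(g$chroms)), function(i) {
    ch_name <- names(g$chroms)[i]
    q_strand <- if (which == "focal" && ch_name == "chr2") "-" else "+"
    blocks <- data.table(size = rep(bs, n),
                         dt = c(rep(g$dt, n - 1L), 0L),
                         dq = c(rep(g$dq, n - 1L), 0L))
    ch <- list(score = 1000 - (i - 1L) * 100,
               t_name = ch_name, t_size = g$chroms[[ch_name]],
               t_strand = "+", t_start = 0L,
               t_end = as.integer(n * bs + (n - 1L) * g$dt),
               q_name = ch_name,
               q_size = geom$reference$chroms[[ch_name]],
               q_strand = q_strand, q_start = 0L,
               q_end = as.integer(n * bs + (n - 1L) * g$dq),
               id = paste0(which, "_", ch_name))
    ch$blocks <- blocks
    class(ch) <- "chain"
    ch
  })
}

# deterministic evenly-spread fragment starts within a peak
.spread_fragments <- function(start, end, count, frag_len) {
  if (count <= 0L) return(integer())
  span <- max(end - start - frag_len, 1L)
  start + (span * (seq_len(count) - 1L)) %/% max(count, 1L)
}

#' Generate a complete synthetic input panel with planted truth
#'
#' Writes, under `out_dir`: per-tissue H3K27ac and H3K4me3 peak BEDs with
#' matching ChIP/control fragment BEDs and a library-size manifest for the
#' focal species; a gene annotation TSV and per-tissue count TSVs;
#' chromosome-size files for all three toy species; alignment chains
#' focal-to-reference and third-to-reference; per-tissue SE and BD element
#' BEDs for the reference and third species (the orthologous counterparts
#' of conserved focal sites); a conservation-score bedGraph in focal
#' coordinates; a pipeline `run.yaml`; and `truth.tsv` with the planted
#' labels. All randomness derives from `config$seed`, so identical
#' configurations produce byte-identical output trees.
#'
#' @param config a [sim_config()].
#' @param out_dir output directory (created).
#' @return invisible list with `dir`, `truth` (a `data.table`), `files`
#'   (named paths) and `config`.
#' @export
generate_panel <- function(config, out_dir) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  geom <- config$geometry
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (d in c("focal", "reference", "third", "counts")) {
    dir.create(file.path(out_dir, d), showWarnings = FALSE)
  }
  tissues <- config$tissues
  nt <- length(tissues)

  int_count <- function(f, n, what) {
    k <- f * n
    if (abs(k - round(k)) > 1e-9) {
      stop("fraction_", what, " does not give an integer count for n = ", n)
    }
    as.integer(round(k))
  }
  alloc <- list(
    se = list(n = config$n_se_clusters,
              private = int_count(config$fraction_private$se,
                                  config$n_se_clusters, "private$se")),
    te = list(n = config$n_background_peaks,
              private = int_count(config$fraction_private$te,
                                  config$n_background_peaks, "private$te")),
    bd = list(n = config$n_planted_bd,
              private = int_count(config$fraction_private$bd,
                                  config$n_planted_bd, "private$bd")),
    nd = list(n = config$n_k4_peaks,
              private = int_count(config$fraction_private$nd,
                                  config$n_k4_peaks, "private$nd")))
  for (cls in names(alloc)) {
    a <- alloc[[cls]]
    a$shared <- a$n - a$private
    a$conserved <- int_count(config$fraction_conserved[[cls]], a$n,
                             paste0("conserved$", cls))
    if (a$conserved > a$shared) {
      stop("class ", cls, ": conserved count ", a$conserved,
           " exceeds shared count ", a$shared,
           " (conserved sites are drawn from the shared pool)")
    }
    alloc[[cls]] <- a
  }

  # --- allocate sites per lane ----------------------------------------
  take_sites <- function(grid, classes) {
    need <- sum(vapply(classes, function(a) a$shared + a$private * nt,
                       numeric(1)))
    if (need > nrow(grid)) {
      stop("infeasible geometry: need ", need, " sites, grid has ",
           nrow(grid))
    }
    idx <- sample.int(nrow(grid))  # shuffle, then deal sequentially
    out <- list(); p <- 1L
    for (nm in names(classes)) {
      a <- classes[[nm]]
      sh <- grid[idx[seq_len(a$shared) + p - 1L]]; p <- p + a$shared
      pr <- lapply(seq_len(nt), function(i) {
        s <- grid[idx[seq_len(a$private) + p - 1L + (i - 1L) * a$private]]
        s
      })
      p <- p + a$private * nt
      out[[nm]] <- list(shared = sh, private = pr)
    }
    out
  }
  k27_sites <- take_sites(.site_grid(geom, "k27"), alloc[c("se", "te")])
  k4_sites <- take_sites(.site_grid(geom, "k4"), alloc[c("bd", "nd")])

  # --- element geometry per site --------------------------------------
  rng <- function(r, n) if (r[1] == r[2]) rep(r[1], n) else
    sample(seq(r[1], r[2]), n, replace = TRUE)
  build_sites <- function(sites, cls) {
    all_sites <- rbindlist(c(
      list(copy(sites$shared)[, tissue := "__shared__"]),
      lapply(seq_len(nt), function(i)
        copy(sites$private[[i]])[, tissue := tissues[i]])))
    n <- nrow(all_sites)
    a <- alloc[[cls]]
    all_sites[, class := cls]
    all_sites[, site_id := sprintf("%s_%03d", cls, .I)]
    all_sites[, private := tissue != "__shared__"]
    # conserved flag lives on the first `conserved` shared sites
    all_sites[, conserved := FALSE]
    if (a$conserved > 0L) all_sites[seq_len(a$conserved), conserved := TRUE]
    if (cls == "te") {
      all_sites[, width := rng(config$background_width_range, n)]
    } else if (cls == "nd") {
      all_sites[, width := rng(config$k4_width_range, n)]
    } else if (cls == "bd") {
      all_sites[, width := as.integer(round(config$bd_width_multiplier *
                                              config$k4_width_range[2]))]
    } else {
      all_sites[, width := config$peaks_per_cluster * config$cluster_peak_width +
                  (config$peaks_per_cluster - 1L) * config$intra_cluster_gap]
    }
    all_sites[, `:=`(start = pos, end = pos + width)]
    all_sites[]
  }
  sites <- rbindlist(lapply(c("se", "te"), function(cl)
    build_sites(k27_sites[[cl]], cl)), fill = TRUE)
  sites <- rbind(sites, rbindlist(lapply(c("bd", "nd"), function(cl)
    build_sites(k4_sites[[cl]], cl)), fill = TRUE))

  # per-site chip fragment counts (reused across tissues for shared sites)
  sites[class == "te",
        chip_count := rng(config$background_chip_range, .N)]
  sites[class == "nd", chip_count := 10L]
  sites[class == "bd", chip_count := as.integer(round(0.02 * width))]
  # planted clusters: distinct net targets, multiples of peaks_per_cluster
  base_net <- config$se_effect * config$background_chip_range[2]
  sites[class == "se",
        chip_count := {
          tgt <- base_net * (1 + 0.06 * (seq_len(.N) - 1L))
          as.integer(config$peaks_per_cluster *
                       ceiling(tgt / config$peaks_per_cluster))
        }]
  sites[, control_count := config$control_per_peak]

  # conservation scores per k27/k4 SE+BD site (focal frame)
  cs <- config$conservation_scores
  hi_cons <- cs$direction == "conserved_higher"
  sites[class %in% c("se", "bd"),
        cons_score := pmin(pmax(stats::rnorm(
          .N,
          mean = fifelse(conserved,
                         if (hi_cons) cs$conserved_mean else cs$background_mean,
                         if (hi_cons) cs$background_mean else cs$conserved_mean),
          sd = cs$sd), 0), 1)]

  # genes: one per site, TSS just downstream of the element midpoint
  sites[, gene_id := sprintf("g_%s", site_id)]
  genes <- sites[, .(gene_id, chrom,
                     strand = "+",
                     start = (start + end) %/% 2L + 200L)]
  genes[, `:=`(end = start + config$gene_length,
               length = config$gene_length)]
  setorder(genes, chrom, start)

  # --- per-tissue membership ------------------------------------------
  membership <- rbindlist(lapply(tissues, function(tis) {
    m <- sites[tissue == "__shared__" | tissue == tis]
    m[, tissue := tis]
    m
  }))

  # --- emit focal files ------------------------------------------------
  fl <- config$fragment_length
  emit_counts <- function(n) if (config$noise) stats::rpois(length(n), n) else n
  manifest <- list()
  files <- list()
  for (tis in tissues) {
    mt <- membership[tissue == tis]
    for (lane in c("k27", "k4")) {
      cls_in <- if (lane == "k27") c("se", "te") else c("bd", "nd")
      ml <- mt[class %in% cls_in]
      # peaks: clusters expand to constituent peaks
      peaks <- rbindlist(lapply(seq_len(nrow(ml)), function(i) {
        r <- ml[i]
        if (r$class == "se") {
          ppc <- config$peaks_per_cluster
          w <- config$cluster_peak_width
          g <- config$intra_cluster_gap
          st <- r$start + (seq_len(ppc) - 1L) * (w + g)
          per <- rep(r$chip_count %/% ppc, ppc)
          per[1] <- per[1] + r$chip_count %% ppc
          data.table(chrom = r$chrom, start = st, end = st + w,
                     name = sprintf("%s_p%d", r$site_id, seq_len(ppc)),
                     chip = per, control = r$control_count)
        } else {
          data.table(chrom = r$chrom, start = r$start, end = r$end,
                     name = r$site_id, chip = r$chip_count,
                     control = r$control_count)
        }
      }))
      setorder(peaks, chrom, start, end)
      peaks[, chip := emit_counts(chip)]
      frag <- function(counts) {
        rbindlist(lapply(seq_len(nrow(peaks)), function(i) {
          st <- .spread_fragments(peaks$start[i], peaks$end[i], counts[i], fl)
          if (!length(st)) return(NULL)
          data.table(chrom = peaks$chrom[i], start = st, end = st + fl)
        }))
      }
      pb <- file.path(out_dir, "focal", sprintf("%s.%s.peaks.bed", tis, lane))
      cb <- file.path(out_dir, "focal", sprintf("%s.%s.chip.bed", tis, lane))
      xb <- file.path(out_dir, "focal", sprintf("%s.%s.control.bed", tis, lane))
      write_bed(peaks[, .(chrom, start, end, name, signal = chip,
                          strand = ".")], pb)
      fwrite(frag(peaks$chip)[order(chrom, start)], cb, sep = "\t",
             col.names = FALSE)
      fwrite(frag(peaks$control)[order(chrom, start)], xb, sep = "\t",
             col.names = FALSE)
      manifest[[length(manifest) + 1L]] <- data.table(
        sample_label = sprintf("%s_%s_%s", tis, lane, c("chip", "control")),
        path = basename(c(cb, xb)),
        library_size = c(config$chip_library, config$control_library))
    }
    # expression counts
    mt[, baseline := pmax(1, round(stats::rlnorm(
      .N, config$expression$meanlog, config$expression$sdlog)))]
    mt[, count := fifelse(class %in% c("se", "bd"),
                          baseline * config$expression$boost, baseline)]
    cf <- file.path(out_dir, "counts", sprintf("%s.counts.tsv", tis))
    fwrite(mt[order(gene_id), .(gene_id, count)], cf, sep = "\t")
  }
  manifest <- rbindlist(manifest)
  fwrite(manifest, file.path(out_dir, "focal", "manifest.tsv"), sep = "\t")

  # --- reference/third counterparts -----------------------------------
  cons_sites <- sites[conserved == TRUE & class %in% c("se", "bd")]
  counterparts <- data.table(site_id = character(), class = character(),
                             chrom = character(), ref_start = integer(),
                             ref_end = integer(), third_start = integer(),
                             third_end = integer())
  if (nrow(cons_sites)) counterparts <- rbindlist(lapply(seq_len(nrow(cons_sites)), function(i) {
    r <- cons_sites[i]
    rr <- .focal_ivl_to_ref(r$chrom, r$start, r$end, geom)
    tt <- .ref_ivl_to_third(r$chrom, rr$start, rr$end, geom)
    data.table(site_id = r$site_id, class = r$class, chrom = r$chrom,
               ref_start = rr$start, ref_end = rr$end,
               third_start = tt$start, third_end = tt$end)
  }))
  for (tis in tissues) {
    for (cl in c("se", "bd")) {
      ids <- membership[tissue == tis & class == cl & conserved == TRUE,
                        site_id]
      cp <- counterparts[site_id %in% ids]
      write_bed(genomic_intervals(cp[, .(chrom, start = ref_start,
                                         end = ref_end, name = site_id)]),
                file.path(out_dir, "reference",
                          sprintf("%s.%s.bed", tis, cl)))
      write_bed(genomic_intervals(cp[, .(chrom, start = third_start,
                                         end = third_end, name = site_id)]),
                file.path(out_dir, "third",
                          sprintf("%s.%s.bed", tis, cl)))
    }
  }

  # --- chains, sizes, genes, scores, truth -----------------------------
  write_chain(.make_chains(geom, "focal"),
              file.path(out_dir, "focal_to_reference.chain"))
  write_chain(.make_chains(geom, "third"),
              file.path(out_dir, "third_to_reference.chain"))
  for (sp in c("focal", "reference", "third")) {
    fwrite(data.table(chrom = names(geom[[sp]]$chroms),
                      size = as.integer(geom[[sp]]$chroms)),
           file.path(out_dir, paste0(sp, ".sizes")), sep = "\t",
           col.names = FALSE)
  }
  fwrite(genes[, .(gene_id, chrom, strand, start, end, length)],
         file.path(out_dir, "genes.tsv"), sep = "\t")
  scores <- sites[class %in% c("se", "bd"),
                  .(chrom, start, end, score = round(cons_score, 4))]
  setorder(scores, chrom, start)
  fwrite(scores, file.path(out_dir, "scores.bedgraph"), sep = "\t",
         col.names = FALSE)

  truth <- membership[, .(tissue, class, site_id, chrom, start, end,
                          private, conserved, gene_id,
                          chip_count, control_count)]
  setorder(truth, tissue, class, chrom, start)
  fwrite(truth, file.path(out_dir, "truth.tsv"), sep = "\t")

  run_cfg <- list(
    out_dir = "results",
    tissues = as.list(tissues),
    focal_dir = "focal", counts_dir = "counts",
    genes = "genes.tsv",
    chrom_sizes = "focal.sizes",
    chain_focal_to_reference = "focal_to_reference.chain",
    chain_third_to_reference = "third_to_reference.chain",
    reference_dir = "reference", third_dir = "third",
    scores = "scores.bedgraph",
    parameters = list(max_gap = 12500L, bd_fraction = 0.05,
                      unify_widths = c(2000L, 4000L, 8000L),
                      merge_distances = c(2000L, 4000L, 8000L),
                      min_match = 0.2,
                      expression_library_size = config$expression$library_size))
  yaml::write_yaml(run_cfg, file.path(out_dir, "run.yaml"))

  invisible(list(dir = out_dir, truth = truth,
                 files = list(manifest = file.path(out_dir, "focal",
                                                   "manifest.tsv"),
                              truth = file.path(out_dir, "truth.tsv"),
                              run_config = file.path(out_dir, "run.yaml")),
                 config = config))
}
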