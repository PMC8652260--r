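#' Read a pipeline run configuration
#'
#' YAML with the file layout written by [generate_panel()] (or assembled
#' by hand): `tissues`, `focal_dir` (peaks + fragments + `manifest.tsv`),
#' `counts_dir`, `genes`, `chrom_sizes`, the two chain files,
#' `reference_dir`/`third_dir` element BEDs, `scores`, `out_dir`, and a
#' `parameters` block (`max_gap`, `bd_fraction`, `unify_widths`,
#' `merge_distances`, `min_match`, `expression_library_size`). Relative
#' paths resolve against the YAML's directory.
#'
#' @param path YAML path.
#' @return a `run_config` list with absolute paths.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  absolutize <- function(p) {
    if (grepl("^/", p)) p else file.path(base, p)
  }
  for (f in c("focal_dir", "counts_dir", "genes", "chrom_sizes",
              "chain_focal_to_reference", "chain_third_to_reference",
              "reference_dir", "third_dir", "scores", "out_dir")) {
    if (!is.null(cfg[[f]])) cfg[[f]] <- absolutize(cfg[[f]])
  }
  cfg$tissues <- unlist(cfg$tissues)
  class(cfg) <- "run_config"
  cfg
}

.stage <- function(log, fmt, ...) {
  msg <- sprintf(fmt, ...)
  message(msg)
  c(log, msg)
}

#' Run the full comparative regulatory-element pipeline
#'
#' For every tissue of the focal species: calls super-enhancers (SEs) and
#' typical enhancers (TEs) from the H3K27ac peaks and fragments, broad
#' (BD) and narrow (ND) H3K4me3 domains, associates every element with
#' the nearest-TSS gene and its RPKM, classifies cross-tissue specificity
#' for each class at every unified width / merge distance, and classifies
#' three-species functional conservation of SEs and BDs with
#' conservation-score comparison. Writes `elements.tsv`,
#' `specificity.tsv`, `conservation.tsv`, intermediate element BEDs and a
#' run log under the configured output directory.
#'
#' @param config a `run_config` from [read_run_config()].
#' @return invisible list of the three summary tables plus `calls`
#'   (per-tissue element tables) and the log.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  p <- config$parameters
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  log <- character()
  manifest <- read_manifest(file.path(config$focal_dir, "manifest.tsv"))
  genes <- read_genes(config$genes)
  chrom_sizes <- read_chrom_sizes(config$chrom_sizes)
  focal_chains <- parse_chain(config$chain_focal_to_reference)
  third_chains <- parse_chain(config$chain_third_to_reference)
  track <- read_track(config$scores)

  calls <- list()   # per tissue: list of class -> element table
  element_rows <- list()
  conservation_rows <- list()
  for (tis in config$tissues) {
    bedp <- function(lane) file.path(config$focal_dir,
                                     sprintf("%s.%s.peaks.bed", tis, lane))
    k27 <- read_bed(bedp("k27"))
    k4 <- read_bed(bedp("k4"))
    frg <- function(lane, role) load_fragments(
      manifest, sprintf("%s_%s_%s", tis, lane, role))
    se_res <- call_superenhancers(k27, frg("k27", "chip"),
                                  frg("k27", "control"),
                                  max_gap = p$max_gap)
    bd_res <- call_broad_domains(k4, fraction = p$bd_fraction)
    k4_chip <- frg("k4", "chip"); k4_ctl <- frg("k4", "control")
    log <- .stage(log, "[%s] %d stitched regions -> %d SE / %d TE; %d peaks -> %d BD / %d ND",
                  tis, nrow(se_res$ranked), nrow(se_res$superenhancers),
                  nrow(se_res$typical), nrow(k4), nrow(bd_res$broad),
                  nrow(bd_res$narrow))
    cls <- list(se = se_res$superenhancers[, .(chrom, start, end)],
                te = se_res$typical[, .(chrom, start, end)],
                bd = copy(bd_res$broad), nd = copy(bd_res$narrow))
    # per-element value: net signal for SE/TE, intensity for BD/ND
    cls$se[, value := se_res$superenhancers$net_signal]
    cls$te[, value := se_res$typical$net_signal]
    cls$bd[, value := peak_intensity(bd_res$broad, k4_chip, k4_ctl)]
    cls$nd[, value := peak_intensity(bd_res$narrow, k4_chip, k4_ctl)]

    # expression of associated genes
    counts <- read_counts(file.path(config$counts_dir,
                                    sprintf("%s.counts.tsv", tis)))
    expr <- compute_rpkm(counts, genes, p$expression_library_size)
    for (cl in names(cls)) {
      el <- cls[[cl]]
      asg <- assign_nearest_tss(el, genes)
      el[, gene_id := asg$gene_id]
      el[, rpkm := expr$rpkm[match(gene_id, expr$gene_id)]]
      n_un <- sum(is.na(el$gene_id) | is.na(el$rpkm))
      if (n_un) log <- .stage(log, "[%s/%s] %d element(s) without expression",
                              tis, cl, n_un)
      write_bed(el[, .(chrom, start, end)],
                file.path(out, sprintf("%s.%s.bed", tis, cl)))
      cls[[cl]] <- el
    }
    calls[[tis]] <- cls
    mk_row <- function(cl) {
      el <- cls[[cl]]
      data.table(tissue = tis, class = cl, n = nrow(el),
                 median_width = stats::median(el$end - el$start),
                 median_value = stats::median(el$value),
                 median_rpkm = stats::median(el$rpkm, na.rm = TRUE))
    }
    rows <- rbindlist(lapply(names(cls), mk_row))
    test_p <- function(a, b, col) {
      va <- cls[[a]][[col]]; vb <- cls[[b]][[col]]
      va <- va[!is.na(va)]; vb <- vb[!is.na(vb)]
      if (!length(va) || !length(vb)) return(NA_real_)
      rank_sum_compare(va, vb)$p_value
    }
    rows[, p_value_vs_typical := c(test_p("se", "te", "value"), NA,
                                   test_p("bd", "nd", "value"), NA)]
    rows[, p_rpkm_vs_typical := c(test_p("se", "te", "rpkm"), NA,
                                  test_p("bd", "nd", "rpkm"), NA)]
    element_rows[[tis]] <- rows

    # conservation: SE and BD elements lifted to the reference frame
    for (cl in c("se", "bd")) {
      el <- cls[[cl]]
      lifted <- liftover_table(el, focal_chains, min_match = p$min_match)
      ok <- lifted[status == "mapped"]
      ref_el <- read_bed(file.path(config$reference_dir,
                                   sprintf("%s.%s.bed", tis, cl)))
      thr_el <- read_bed(file.path(config$third_dir,
                                   sprintf("%s.%s.bed", tis, cl)))
      thr_lift <- liftover_table(thr_el, third_chains,
                                 min_match = p$min_match)
      thr_ok <- thr_lift[status == "mapped",
                         .(chrom = lifted_chrom, start = lifted_start,
                           end = lifted_end)]
      fc <- classify_functionally_conserved(
        ok[, .(chrom = lifted_chrom, start = lifted_start,
               end = lifted_end, name = paste0(chrom, ":", start))],
        ref_el, thr_ok, merge_distance = 0L,
        n_unmapped = nrow(lifted) - nrow(ok))
      # score comparison in the focal frame
      el[, conserved := FALSE]
      el[match(fc$elements$name[fc$elements$conserved],
               paste0(chrom, ":", start)), conserved := TRUE]
      sc <- mean_conservation_score(el, track)
      el[, mean_score := sc$mean_score]
      grp_c <- el$mean_score[el$conserved & !is.na(el$mean_score)]
      grp_u <- el$mean_score[!el$conserved & !is.na(el$mean_score)]
      p_sc <- if (length(grp_c) && length(grp_u)) {
        rank_sum_compare(grp_c, grp_u)$p_value
      } else NA_real_
      conservation_rows[[paste(tis, cl)]] <- data.table(
        tissue = tis, class = cl, n_conserved = fc$n_conserved,
        n_total = fc$n_total, fraction = fc$fraction,
        n_unmapped = nrow(lifted) - nrow(ok),
        median_score_conserved = stats::median(grp_c),
        median_score_unconserved = stats::median(grp_u),
        p_score = p_sc)
      log <- .stage(log, "[%s/%s] %d/%d functionally conserved",
                    tis, cl, fc$n_conserved, fc$n_total)
    }
  }
  elements <- rbindlist(element_rows)

  # specificity across tissues, per class, width x distance
  spec_rows <- list()
  for (cl in c("se", "te", "bd", "nd")) {
    for (i in seq_along(p$unify_widths)) {
      w <- p$unify_widths[i]; d <- p$merge_distances[i]
      panel <- lapply(calls, function(x)
        unify_width(x[[cl]][, .(chrom, start, end)], width = w,
                    chrom_sizes = chrom_sizes))
      res <- classify_specific(panel, merge_distance = d)
      spec_rows[[paste(cl, w, d)]] <- cbind(
        data.table(class = cl, unify_width = w, merge_distance = d),
        res$per_tissue)
    }
  }
  specificity <- rbindlist(spec_rows)
  # paired SE-vs-TE / BD-vs-ND tests per parameterization
  pair_p <- function(c1, c2, w, d) {
    f1 <- specificity[class == c1 & unify_width == w & merge_distance == d]
    f2 <- specificity[class == c2 & unify_width == w & merge_distance == d]
    setorder(f1, tissue); setorder(f2, tissue)
    paired_fraction_test(f1$fraction_specific, f2$fraction_specific)
  }
  spec_tests <- rbindlist(lapply(seq_along(p$unify_widths), function(i) {
    w <- p$unify_widths[i]; d <- p$merge_distances[i]
    data.table(comparison = c("se_vs_te", "bd_vs_nd"),
               unify_width = w, merge_distance = d,
               p_value = c(pair_p("se", "te", w, d),
                           pair_p("bd", "nd", w, d)))
  }))
  conservation <- rbindlist(conservation_rows)

  fwrite(elements, file.path(out, "elements.tsv"), sep = "\t")
  fwrite(specificity, file.path(out, "specificity.tsv"), sep = "\t")
  fwrite(spec_tests, file.path(out, "specificity_tests.tsv"), sep = "\t")
  fwrite(conservation, file.path(out, "conservation.tsv"), sep = "\t")
  writeLines(log, file.path(out, "run.log"))
  invisible(list(elements = elements, specificity = specificity,
                 specificity_tests = spec_tests,
                 conservation = conservation, calls = calls, log = log))
}
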