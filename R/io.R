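#' Read a BED-like peak file
#'
#' Accepts BED3/BED6 and narrowPeak (tab-separated, no header). For BED5/6
#' the score column is taken as the peak signal; for narrowPeak (>= 7
#' columns) the signalValue column overrides it. Coordinates are kept in
#' the file's native 0-based half-open convention.
#'
#' @param path file path.
#' @param unique reject duplicate (chrom,start,end) rows (default TRUE;
#'   set FALSE for fragment BEDs).
#' @return a sorted interval table.
#' @export
read_bed <- function(path, unique = TRUE) {
  dt <- fread(path, header = FALSE, sep = "\t", fill = TRUE)
  if (!ncol(dt)) stop("empty BED file: ", path)
  nc <- ncol(dt)
  out <- data.table(chrom = as.character(dt[[1]]),
                    start = as.integer(dt[[2]]),
                    end = as.integer(dt[[3]]))
  out[, name := if (nc >= 4) as.character(dt[[4]]) else NA_character_]
  out[, signal := if (nc >= 5) suppressWarnings(as.numeric(dt[[5]])) else NA_real_]
  out[, strand := if (nc >= 6) as.character(dt[[6]]) else "."]
  if (nc >= 7) out[, signal := suppressWarnings(as.numeric(dt[[7]]))]
  out[is.na(strand) | !strand %in% c("+", "-", "."), strand := "."]
  genomic_intervals(out, unique = unique)
}

#' Write an interval table as BED
#'
#' Writes BED6 when any name/signal/strand information is present,
#' BED3 otherwise. Missing names become `.`, missing signals 0.
#'
#' @param x interval table.
#' @param path output path.
#' @export
write_bed <- function(x, path) {
  x <- genomic_intervals(x, unique = FALSE)
  if (nrow(x) && (any(!is.na(x$name)) || any(!is.na(x$signal)) ||
                  any(x$strand != "."))) {
    out <- x[, .(chrom, start, end,
                 name = fifelse(is.na(name), ".", name),
                 score = fifelse(is.na(signal), 0, signal),
                 strand)]
  } else {
    out <- x[, .(chrom, start, end)]
  }
  fwrite(out, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a sample manifest
#'
#' Tab-separated sidecar with columns `sample_label`, `path`,
#' `library_size` (header required). Relative paths are resolved against
#' the manifest's directory.
#'
#' @param path manifest path.
#' @return `data.table` with resolved paths.
#' @export
read_manifest <- function(path) {
  m <- fread(path, sep = "\t", header = TRUE)
  need <- c("sample_label", "path", "library_size")
  if (!all(need %in% names(m))) {
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  }
  m[, path := fifelse(grepl("^/", path), path,
                      file.path(dirname(..path), path))]
  if (any(m$library_size <= 0)) stop("library_size must be positive")
  m[]
}

#' Load a fragment set named in a manifest
#'
#' @param manifest a table from [read_manifest()].
#' @param sample_label the sample to load.
#' @return a [fragment_set()].
#' @export
load_fragments <- function(manifest, sample_label) {
  wanted <- sample_label
  row <- manifest[manifest$sample_label == wanted]
  if (nrow(row) != 1L) stop("sample not found in manifest: ", sample_label)
  fragment_set(read_bed(row$path, unique = FALSE), row$library_size)
}

#' Read gene models
#'
#' Two formats: a 6-column TSV `gene_id, chrom, strand, start, end, length`
#' (header optional; coordinates 0-based half-open; `length` is the span
#' used for RPKM) or a GTF whose `gene` records are used (1-based closed
#' coordinates converted at this boundary; length = gene span).
#' The TSS is `start` for `+` genes and `end - 1` for `-` genes.
#'
#' @param path file path; format chosen by extension (`.gtf`/`.gff` vs TSV).
#' @return `data.table` with `gene_id, chrom, strand, start, end, length, tss`.
#' @export
read_genes <- function(path) {
  if (grepl("\\.(gtf|gff|gff3)$", path, ignore.case = TRUE)) {
    g <- fread(path, header = FALSE, sep = "\t",
               col.names = c("chrom", "source", "feature", "start", "end",
                             "score", "strand", "frame", "attr"))
    g <- g[feature == "gene"]
    if (!nrow(g)) stop("no gene records in ", path)
    g[, gene_id := sub('.*gene_id[ =]+"?([^";]+)"?.*', "\\1", attr)]
    genes <- g[, .(gene_id, chrom = as.character(chrom), strand,
                   start = as.integer(start) - 1L, end = as.integer(end))]
    genes[, length := end - start]
  } else {
    genes <- fread(path, sep = "\t", header = "auto")
    if (!"gene_id" %in% names(genes)) {
      if (ncol(genes) != 6) stop("gene TSV must have 6 columns")
      setnames(genes, c("gene_id", "chrom", "strand", "start", "end",
                        "length"))
    }
    genes <- genes[, .(gene_id = as.character(gene_id),
                       chrom = as.character(chrom), strand,
                       start = as.integer(start), end = as.integer(end),
                       length = as.integer(length))]
  }
  if (!all(genes$strand %in% c("+", "-"))) stop("gene strand must be + or -")
  if (any(genes$length <= 0)) {
    stop("non-positive length for gene ",
         genes$gene_id[genes$length <= 0][1])
  }
  genes[, tss := fifelse(strand == "+", start, end - 1L)]
  setorder(genes, chrom, start, end)
  genes[]
}

#' Read gene counts
#'
#' Two-column TSV `gene_id, count` (header optional).
#'
#' @param path file path.
#' @return `data.table` with `gene_id`, `count`.
#' @export
read_counts <- function(path) {
  ct <- fread(path, sep = "\t", header = "auto")
  if (ncol(ct) < 2) stop("counts TSV must have 2 columns")
  if (!all(c("gene_id", "count") %in% names(ct))) {
    setnames(ct, 1:2, c("gene_id", "count"))
  }
  ct <- ct[, .(gene_id = as.character(gene_id), count = as.numeric(count))]
  if (any(ct$count < 0)) stop("negative counts")
  ct[]
}

#' Read chromosome sizes
#'
#' Two-column TSV `chrom, size`.
#' @param path file path.
#' @return named integer vector of sizes.
#' @export
read_chrom_sizes <- function(path) {
  cs <- fread(path, sep = "\t", header = FALSE)
  stats::setNames(as.integer(cs[[2]]), as.character(cs[[1]]))
}
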