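#' @import data.table
#' @importFrom stats median pnorm rnorm rlnorm rpois setNames
NULL

# Internal column order for interval tables.
.ivl_cols <- c("chrom", "start", "end", "strand", "name", "signal")

#' Construct a validated genomic-interval table
#'
#' The package's currency is a `data.table` of half-open genomic intervals:
#' `chrom` (character), `start` (0-based inclusive), `end` (exclusive),
#' `strand` (one of `+`, `-`, `.`), optional `name` and non-negative
#' `signal`. Rows are sorted by (chrom, start, end) and duplicates of the
#' (chrom, start, end) triple are rejected for peak sets.
#'
#' @param chrom character vector of chromosome names, or a data.frame with
#'   at least `chrom`, `start`, `end` columns.
#' @param start,end integer coordinates, 0-based half-open; `end > start`.
#' @param strand strand characters, recycled; default `"."`.
#' @param name optional identifiers (recycled).
#' @param signal optional non-negative signal values (recycled).
#' @param unique logical; reject duplicated (chrom, start, end) triples
#'   (the peak-set invariant). Fragment collections may set `FALSE`.
#' @return a sorted `data.table` with columns
#'   `chrom, start, end, strand, name, signal`.
#' @export
genomic_intervals <- function(chrom, start = NULL, end = NULL,
                              strand = ".", name = NA_character_,
                              signal = NA_real_, unique = TRUE) {
  if (is.data.frame(chrom)) {
    df <- as.data.table(chrom)
    if (!all(c("chrom", "start", "end") %in% names(df))) {
      stop("interval table needs chrom/start/end columns")
    }
    if (!"strand" %in% names(df)) df[, strand := "."]
    if (!"name" %in% names(df)) df[, name := NA_character_]
    if (!"signal" %in% names(df)) df[, signal := NA_real_]
    dt <- df[, .ivl_cols, with = FALSE]
  } else {
    dt <- data.table(chrom = as.character(chrom),
                     start = as.integer(start), end = as.integer(end),
                     strand = as.character(strand),
                     name = as.character(name),
                     signal = as.numeric(signal))
  }
  dt[, `:=`(chrom = as.character(chrom), start = as.integer(start),
            end = as.integer(end))]
  if (nrow(dt)) {
    if (anyNA(dt$start) || anyNA(dt$end)) stop("NA coordinates")
    if (any(dt$start < 0L)) stop("start must be >= 0")
    if (any(dt$end <= dt$start)) stop("end must be > start")
    if (!all(dt$strand %in% c("+", "-", "."))) stop("strand must be +, - or .")
    if (any(!is.na(dt$signal) & dt$signal < 0)) stop("signal must be >= 0")
  }
  setorder(dt, chrom, start, end)
  if (unique && anyDuplicated(dt, by = c("chrom", "start", "end"))) {
    stop("duplicate (chrom, start, end) triples in peak set")
  }
  dt[]
}

#' Interval widths
#' @param x an interval table.
#' @return integer vector `end - start`.
#' @export
interval_width <- function(x) x$end - x$start

#' Construct a fragment set
#'
#' A fragment set couples aligned-fragment intervals with the originating
#' sample's library size (total mapped reads), the denominator of rpm.
#' The fragments may be a subsample of the library.
#'
#' @param fragments interval table (duplicates allowed).
#' @param library_size positive integer, total mapped reads.
#' @return object of class `fragment_set`.
#' @export
fragment_set <- function(fragments, library_size) {
  library_size <- as.numeric(library_size)
  if (length(library_size) != 1L || is.na(library_size) || library_size <= 0) {
    stop("library_size must be a single positive number")
  }
  fragments <- genomic_intervals(fragments, unique = FALSE)
  structure(list(fragments = fragments, library_size = library_size),
            class = "fragment_set")
}

#' @export
print.fragment_set <- function(x, ...) {
  cat(sprintf("<fragment_set> %d fragments, library_size %.0f\n",
              nrow(x$fragments), x$library_size))
  invisible(x)
}

# closed-coordinate view for foverlaps(): [start, end) -> [start, end-1]
.closed <- function(dt) {
  out <- dt[, .(chrom, start, end = end - 1L)]
  setkey(out, chrom, start, end)
  out
}

#' Filter replicate peaks by reciprocal overlap
#'
#' Keeps the peaks of `a` for which some single peak of `b` overlaps at
#' least `min_fraction` of the a-peak's width while the same intersection
#' also covers at least `min_fraction` of that b-peak's width. The
#' comparison is `>=` (a boundary overlap passes). Overlaps are never
#' summed across multiple b-peaks: one pair must pass both fractions.
#'
#' @param a,b interval tables on the same genome.
#' @param min_fraction required fraction in (0, 1]; default 0.5.
#' @return the qualifying subset of `a`, coordinate-sorted.
#' @export
reciprocal_overlap_filter <- function(a, b, min_fraction = 0.5) {
  if (!is.numeric(min_fraction) || length(min_fraction) != 1L ||
      min_fraction <= 0 || min_fraction > 1) {
    stop("min_fraction must be in (0, 1]")
  }
  a <- genomic_intervals(a)
  b <- genomic_intervals(b)
  if (!nrow(a) || !nrow(b)) return(a[0])
  qa <- a[, .(chrom, start, end = end - 1L, ia = .I)]
  qb <- .closed(b)[, ib := .I]
  setkey(qb, chrom, start, end)
  hits <- foverlaps(qa, qb, type = "any", nomatch = NULL)
  if (!nrow(hits)) return(a[0])
  # recover half-open spans of both partners for each hit
  hits[, `:=`(a_start = a$start[ia], a_end = a$end[ia],
              b_start = b$start[ib], b_end = b$end[ib])]
  hits[, ov := pmin(a_end, b_end) - pmax(a_start, b_start)]
  hits[, ok := ov >= min_fraction * (a_end - a_start) &
               ov >= min_fraction * (b_end - b_start)]
  keep <- sort(unique(hits$ia[hits$ok]))
  a[keep]
}

#' Keep the n highest-signal peaks
#'
#' Fallback for samples without replicates: retain the `n` peaks with
#' highest signal, re-sorted by coordinate. Ties at rank `n` are broken by
#' (chrom, start) ascending so exactly `n` records are returned.
#'
#' @param peaks interval table; every row must carry a signal.
#' @param n number of peaks to keep (default 20000).
#' @return interval table with `min(n, nrow(peaks))` rows.
#' @export
top_n_by_signal <- function(peaks, n = 20000L) {
  peaks <- genomic_intervals(peaks)
  if (any(is.na(peaks$signal))) {
    bad <- peaks[is.na(signal)][1]
    stop(sprintf("peak %s:%d-%d lacks a signal value",
                 bad$chrom, bad$start, bad$end))
  }
  if (nrow(peaks) <= n) return(peaks)
  ord <- order(-peaks$signal, peaks$chrom, peaks$start, peaks$end)
  out <- peaks[ord[seq_len(n)]]
  setorder(out, chrom, start, end)
  out[]
}

#' Merge intervals separated by at most a gap
#'
#' Transitive closure: adjacent intervals join one merged region iff the
#' gap `next.start - prev.end` is at most `max_gap`; `max_gap = 0` merges
#' touching or overlapping intervals only. Each merged region spans
#' min(start)..max(end) of its constituents.
#'
#' @param x interval table (sorted internally).
#' @param max_gap non-negative gap in bp.
#' @return `data.table` with `chrom, start, end, n_constituents` and a
#'   list-column `constituents` of row indices into the sorted input.
#' @export
merge_within <- function(x, max_gap = 0L) {
  if (max_gap < 0) stop("max_gap must be >= 0")
  x <- genomic_intervals(x, unique = FALSE)
  if (!nrow(x)) {
    return(data.table(chrom = character(), start = integer(),
                      end = integer(), n_constituents = integer(),
                      constituents = list()))
  }
  # running maximum end within chrom defines the chain
  x[, run_end := cummax(end), by = chrom]
  x[, new_grp := start - shift(run_end, fill = first(start)) > max_gap,
    by = chrom]
  x[, grp := cumsum(new_grp) , by = chrom]
  out <- x[, .(start = min(start), end = max(end),
               n_constituents = .N, constituents = list(.I)),
           by = .(chrom, grp)][, grp := NULL]
  x[, c("run_end", "new_grp", "grp") := NULL]
  setorder(out, chrom, start, end)
  out[]
}

#' Quantify region signal in reads per million (rpm)
#'
#' Counts fragments overlapping each region by at least 1 bp and scales by
#' the fragment set's library size: `count * 1e6 / library_size`. Feature-
#' count semantics, not per-base pileup.
#'
#' @param regions interval table of one or more regions.
#' @param reads a [fragment_set()].
#' @return numeric vector of rpm values, one per region row (input order).
#' @export
quantify_rpm <- function(regions, reads) {
  stopifnot(inherits(reads, "fragment_set"))
  regions <- as.data.table(regions)[, .(chrom = as.character(chrom),
                                        start = as.integer(start),
                                        end = as.integer(end))]
  if (!nrow(regions)) return(numeric())
  if (any(regions$end <= regions$start)) stop("end must be > start")
  frags <- reads$fragments
  counts <- integer(nrow(regions))
  if (nrow(frags)) {
    q <- regions[, .(chrom, start, end = end - 1L, iq = .I)]
    s <- .closed(frags)
    hits <- foverlaps(q, s, type = "any", nomatch = NULL)
    if (nrow(hits)) {
      tab <- hits[, .N, by = iq]
      counts[tab$iq] <- tab$N
    }
  }
  counts * 1e6 / reads$library_size
}
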