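#' Stitch enhancer peaks into candidate regions
#'
#' Enhancer peaks whose end-to-start gap is at most `max_gap` (default
#' 12.5 kb, inclusive) are merged transitively into stitched regions, the
#' candidate units of super-enhancer calling.
#'
#' @param peaks non-empty interval table of enhancer peaks.
#' @param max_gap stitching gap in bp (default 12500).
#' @return `data.table` of stitched regions with `n_constituents` and the
#'   `constituents` list-column (row indices into the sorted input).
#' @export
stitch_enhancers <- function(peaks, max_gap = 12500L) {
  peaks <- genomic_intervals(peaks)
  if (!nrow(peaks)) stop("no peaks to stitch")
  merge_within(peaks, max_gap = max_gap)
}

#' Score stitched regions by background-normalized signal
#'
#' Fills `chip_rpm` and `input_rpm` for every region via [quantify_rpm()]
#' and computes `net_signal = max(chip_rpm - input_rpm, 0)`. The control
#' rpm is subtracted directly (both are already library-size normalized).
#'
#' @param regions stitched-region table (or any interval table).
#' @param chip,control [fragment_set()] objects for ChIP and input.
#' @return the regions sorted ascending by `net_signal` (ties by
#'   coordinate), with `chip_rpm`, `input_rpm`, `net_signal` columns.
#' @export
score_regions <- function(regions, chip, control) {
  regions <- as.data.table(regions)
  regions[, chip_rpm := quantify_rpm(.SD, chip), .SDcols = c("chrom", "start", "end")]
  regions[, input_rpm := quantify_rpm(.SD, control), .SDcols = c("chrom", "start", "end")]
  regions[, net_signal := pmax(chip_rpm - input_rpm, 0)]
  setorder(regions, net_signal, chrom, start, end)
  regions[]
}

#' Hockey-stick tangent cutoff on a ranked signal curve
#'
#' Signals are clamped at 0 and sorted ascending as `s_1..s_N`. The
#' reference slope is `m = (s_N - s_1) / N` — slope 1 once both axes are
#' rescaled to a common span. For each candidate rank `x` the number of
#' points lying on or below the line of slope `m` through `(x, s_x)` is
#' counted; the tangent rank minimizes that count (the line touching the
#' convex elbow of the curve from below; ties resolved to the largest
#' rank for determinism), and the cutoff is the signal at the tangent
#' rank. Elements strictly above the cutoff become super-enhancers.
#'
#' A point `j` is on or below the line iff `s_j - m*j <= s_x - m*x`, so
#' the count at `x` is the rank of the residual `t_x = s_x - m*x` —
#' computed in one ranking pass rather than per-candidate; the tangent is
#' the largest rank attaining the minimal residual.
#'
#' @param signals non-negative numeric vector, length >= 2.
#' @return list with `cutoff_value` and `tangent_index` (1-based rank on
#'   the ascending curve).
#' @export
hockey_stick_cutoff <- function(signals) {
  if (length(signals) < 2L) stop("need at least 2 signal values")
  s <- sort(pmax(as.numeric(signals), 0))
  n <- length(s)
  m <- (s[n] - s[1]) / n
  t <- s - m * seq_len(n)
  # on-or-below count at x = #{j : t_j <= t_x} = rank of t_x
  counts <- frank(t, ties.method = "max")
  best <- max(which(counts == min(counts)))
  list(cutoff_value = s[best], tangent_index = best)
}

#' Call super-enhancers
#'
#' The four-step procedure: stitch enhancer peaks within `max_gap`, score
#' stitched regions by background-normalized ChIP rpm, rank ascending,
#' and split at the hockey-stick tangent cutoff. Regions with
#' `net_signal` strictly above the cutoff are super-enhancers (SEs); the
#' rest are typical enhancers (TEs). A region exactly at the cutoff is a TE.
#'
#' @param peaks enhancer peak table (e.g. H3K27ac peaks).
#' @param chip,control [fragment_set()] objects.
#' @param max_gap stitching gap in bp (default 12500).
#' @return object of class `se_call`: list with `ranked` (ascending by
#'   `net_signal`, with `is_se` flag), `cutoff_value`, `cutoff_index`,
#'   `superenhancers`, `typical`.
#' @export
call_superenhancers <- function(peaks, chip, control, max_gap = 12500L) {
  stitched <- stitch_enhancers(peaks, max_gap = max_gap)
  if (nrow(stitched) < 2L) {
    stop("need at least 2 stitched regions to place a cutoff")
  }
  ranked <- score_regions(stitched, chip, control)
  cut <- hockey_stick_cutoff(ranked$net_signal)
  ranked[, rank := .I]
  ranked[, is_se := net_signal > cut$cutoff_value]
  res <- list(ranked = ranked,
              cutoff_value = cut$cutoff_value,
              cutoff_index = cut$tangent_index,
              superenhancers = ranked[is_se == TRUE],
              typical = ranked[is_se == FALSE])
  class(res) <- "se_call"
  res
}

#' @export
print.se_call <- function(x, ...) {
  cat(sprintf("<se_call> %d stitched regions: %d SE / %d TE (cutoff %.4g at rank %d)\n",
              nrow(x$ranked), nrow(x$superenhancers), nrow(x$typical),
              x$cutoff_value, x$cutoff_index))
  invisible(x)
}
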