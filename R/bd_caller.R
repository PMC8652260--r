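#' Call broad H3K4me3 domains
#'
#' Broad domains (BDs) are the top `fraction` broadest peaks of a sample:
#' peaks are ranked by width descending and the top `k = ceiling(fraction
#' * N)` are taken, so any non-empty input yields at least one BD. Ties at
#' the boundary width are resolved by (chrom, start) ascending so exactly
#' `k` peaks are BDs. The remainder are narrow domains (NDs).
#'
#' @param peaks non-empty interval table of H3K4me3 peaks.
#' @param fraction width quantile in (0, 1); default 0.05.
#' @return object of class `bd_call`: list with `broad`, `narrow`
#'   (coordinate-sorted interval tables), `width_threshold` (smallest BD
#'   width) and `fraction`.
#' @export
call_broad_domains <- function(peaks, fraction = 0.05) {
  peaks <- genomic_intervals(peaks)
  if (!nrow(peaks)) stop("no peaks")
  if (!is.numeric(fraction) || fraction <= 0 || fraction >= 1) {
    stop("fraction must be in (0, 1)")
  }
  n <- nrow(peaks)
  k <- ceiling(fraction * n)
  w <- interval_width(peaks)
  ord <- order(-w, peaks$chrom, peaks$start, peaks$end)
  broad_idx <- sort(ord[seq_len(k)])
  res <- list(broad = peaks[broad_idx],
              narrow = peaks[setdiff(seq_len(n), broad_idx)],
              width_threshold = min(w[broad_idx]),
              fraction = fraction)
  class(res) <- "bd_call"
  res
}

#' @export
print.bd_call <- function(x, ...) {
  cat(sprintf("<bd_call> %d BD / %d ND (width threshold %d bp, top %.1f%%)\n",
              nrow(x$broad), nrow(x$narrow), x$width_threshold,
              100 * x$fraction))
  invisible(x)
}

#' Per-bp input-normalized peak intensity
#'
#' Tags per base pair: `max(chip_rpm - input_rpm, 0) / width`. The input
#' (control) rpm over the same interval is subtracted before dividing by
#' peak breadth, keeping the subtraction convention used for enhancer
#' scoring.
#'
#' @param peaks interval table (positive widths).
#' @param chip,control [fragment_set()] objects.
#' @return numeric vector of intensities (rpm per bp), one per peak in
#'   input order.
#' @export
peak_intensity <- function(peaks, chip, control) {
  peaks <- as.data.table(peaks)[, .(chrom, start, end)]
  w <- interval_width(peaks)
  if (any(w <= 0)) stop("zero-width peak")
  chip_rpm <- quantify_rpm(peaks, chip)
  input_rpm <- quantify_rpm(peaks, control)
  pmax(chip_rpm - input_rpm, 0) / w
}
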