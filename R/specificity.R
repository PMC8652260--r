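#' Unify elements to a common width
#'
#' Each element is replaced by a window of `width` bp centred on its
#' midpoint `floor((start+end)/2)`, i.e. `[mid - width/2, mid + width/2)`,
#' truncated at chromosome bounds (truncated elements still participate;
#' their count is attached as an attribute and logged).
#'
#' @param elements interval table.
#' @param width target width in bp (default 2000).
#' @param chrom_sizes named vector of chromosome sizes.
#' @return interval table of unified windows, attribute `n_truncated`.
#' @export
unify_width <- function(elements, width = 2000L, chrom_sizes) {
  if (width <= 0) stop("width must be positive")
  elements <- genomic_intervals(elements, unique = FALSE)
  unknown <- setdiff(unique(elements$chrom), names(chrom_sizes))
  if (length(unknown)) stop("unknown chromosome: ", unknown[1])
  half <- width %/% 2L
  out <- elements[, .(chrom, strand, name, signal,
                      mid = (start + end) %/% 2L)]
  out[, `:=`(start = mid - half, end = mid - half + as.integer(width))]
  out[, size := chrom_sizes[chrom]]
  n_trunc <- out[, sum(start < 0L | end > size)]
  out[, `:=`(start = pmax(start, 0L), end = pmin(end, size))]
  if (n_trunc) message(n_trunc, " element(s) truncated at chromosome bounds")
  out <- genomic_intervals(out[, .(chrom, start, end, strand, name, signal)],
                           unique = FALSE)
  setattr(out, "n_truncated", n_trunc)
  out
}

#' Classify elements as tissue-specific or shared
#'
#' All tissues' elements of one class are pooled and grouped by
#' single-linkage: two elements link iff they lie on the same chromosome
#' with midpoints at most `merge_distance` apart; linkage is transitive.
#' An element is tissue-specific iff its group contains elements from
#' exactly one tissue.
#'
#' @param panel named list (tissue label -> interval table) of
#'   width-unified elements; at least 2 tissues.
#' @param merge_distance midpoint-distance linkage threshold in bp.
#' @return object of class `specificity_result`: list with `per_tissue`
#'   (`tissue, n_total, n_specific, fraction_specific`), `elements`
#'   (pooled table with `tissue`, `group`, `specific`), and
#'   `merge_distance`.
#' @export
classify_specific <- function(panel, merge_distance) {
  if (length(panel) < 2L) stop("specificity needs >= 2 tissues")
  if (is.null(names(panel)) || any(!nzchar(names(panel)))) {
    stop("panel must be a named list of tissue element sets")
  }
  pooled <- rbindlist(lapply(names(panel), function(tis) {
    dt <- genomic_intervals(panel[[tis]], unique = FALSE)
    dt[, tissue := tis]
    dt
  }))
  pooled[, mid := (start + end) %/% 2L]
  setorder(pooled, chrom, mid, tissue, start)
  # single-linkage on a line: maximal runs of consecutive midpoint gaps <= d
  pooled[, new_grp := c(TRUE, diff(mid) > merge_distance), by = chrom]
  pooled[, group := paste0(chrom, "_", cumsum(new_grp)), by = chrom]
  pooled[, specific := uniqueN(tissue) == 1L, by = group]
  pooled[, new_grp := NULL]
  per_tissue <- pooled[, .(n_total = .N, n_specific = sum(specific),
                           fraction_specific = mean(specific)),
                       by = tissue]
  setorder(per_tissue, tissue)
  res <- list(per_tissue = per_tissue, elements = pooled[],
              merge_distance = merge_distance)
  class(res) <- "specificity_result"
  res
}

#' @export
print.specificity_result <- function(x, ...) {
  cat(sprintf("<specificity_result> d=%d bp\n", as.integer(x$merge_distance)))
  print(x$per_tissue)
  invisible(x)
}

# exact two-sided signed-rank p over all 2^n sign assignments
.signedrank_exact <- function(d) {
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  e_v <- sum(r) / 2
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.vector(signs %*% r)
  eps <- 1e-9
  mean(abs(v_all - e_v) >= abs(v_obs - e_v) - eps)
}

#' Paired Wilcoxon signed-rank test on per-tissue fractions
#'
#' Two-sided signed-rank test on paired per-tissue values (one pair per
#' tissue). Zero differences are dropped (standard convention); if all
#' differences are zero the p-value is 1. The null distribution is exact
#' (full 2^n sign enumeration) for up to 15 non-zero pairs, and the
#' normal approximation with tie correction beyond.
#'
#' @param fractions_class1,fractions_class2 equal-length numeric vectors.
#' @return two-sided p-value.
#' @export
paired_fraction_test <- function(fractions_class1, fractions_class2) {
  x <- as.numeric(fractions_class1); y <- as.numeric(fractions_class2)
  if (length(x) != length(y)) stop("paired vectors must have equal length")
  if (length(x) < 2L) stop("need at least 2 pairs")
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) return(1)
  if (n <= 15L) return(.signedrank_exact(d))
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  e_v <- n * (n + 1) / 4
  ties <- table(r)
  var_v <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  z <- (v - e_v) / sqrt(var_v)
  min(1, 2 * stats::pnorm(-abs(z)))
}
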