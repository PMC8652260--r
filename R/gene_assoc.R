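#' Assign elements to the gene with the closest TSS
#'
#' Distance is measured from the element midpoint `floor((start+end)/2)`
#' to each gene's transcription start site on the same chromosome; strand
#' only determines where the TSS sits. Ties go to the lexicographically
#' smallest `gene_id`. Elements on chromosomes with no annotated gene are
#' left unassigned (`NA`), not an error.
#'
#' @param elements interval table.
#' @param genes gene table from [read_genes()] (needs `gene_id`, `chrom`,
#'   `tss`).
#' @return `data.table` with one row per element: `chrom, start, end,
#'   gene_id, distance` (`NA` when unassigned).
#' @export
assign_nearest_tss <- function(elements, genes) {
  elements <- as.data.table(elements)
  if (!nrow(genes)) stop("empty gene annotation")
  g <- as.data.table(genes)[, .(gene_id, chrom, tss)]
  setorder(g, chrom, tss, gene_id)
  out <- elements[, .(chrom = as.character(chrom),
                      start = as.integer(start), end = as.integer(end))]
  out[, mid := (start + end) %/% 2L]
  out[, `:=`(gene_id = NA_character_, distance = NA_integer_)]
  for (ch in unique(out$chrom)) {
    gc <- g[chrom == ch]
    if (!nrow(gc)) next
    idx <- which(out$chrom == ch)
    mids <- out$mid[idx]
    # nearest TSS by binary search over the sorted TSS vector; candidates
    # are the flanking TSSs, ties resolved by gene_id then examined over
    # the full tie set at equal distance
    pos <- findInterval(mids, gc$tss)
    lo <- pmax(pos, 1L)
    hi <- pmin(pos + 1L, nrow(gc))
    d_lo <- abs(mids - gc$tss[lo])
    d_hi <- abs(mids - gc$tss[hi])
    best_d <- pmin(d_lo, d_hi)
    pick <- character(length(mids))
    for (j in seq_along(mids)) {
      cand <- gc[abs(tss - mids[j]) == best_d[j]]
      pick[j] <- min(cand$gene_id)
    }
    out[idx, `:=`(gene_id = pick, distance = best_d)]
  }
  out[, mid := NULL]
  out[]
}

#' Compute RPKM from gene counts
#'
#' Reads per kilobase of gene length per million mapped reads:
#' `rpkm = count * 1e9 / (library_size * length)`.
#'
#' @param counts `data.table`/data.frame with `gene_id`, `count`.
#' @param genes gene table carrying `gene_id` and `length` (bp).
#' @param library_size positive total mapped reads.
#' @return `data.table` with `gene_id, count, length, rpkm`.
#' @export
compute_rpkm <- function(counts, genes, library_size) {
  if (!is.numeric(library_size) || library_size <= 0) {
    stop("library_size must be positive")
  }
  ct <- as.data.table(counts)[, .(gene_id = as.character(gene_id),
                                  count = as.numeric(count))]
  g <- as.data.table(genes)[, .(gene_id = as.character(gene_id), length)]
  tab <- merge(ct, g, by = "gene_id", all.x = TRUE, sort = TRUE)
  if (anyNA(tab$length)) {
    stop("no annotated length for gene ", tab$gene_id[is.na(tab$length)][1])
  }
  if (any(tab$length <= 0)) {
    stop("non-positive length for gene ", tab$gene_id[tab$length <= 0][1])
  }
  tab[, rpkm := count * 1e9 / (library_size * length)]
  tab[]
}

# exact two-sided rank-sum p over all C(n+m, n) splits of the midranks;
# p = P(|W - E[W]| >= |w_obs - E[W]|) under the permutation null
.ranksum_exact <- function(a, b) {
  n <- length(a); m <- length(b)
  r <- rank(c(a, b))          # midranks handle ties exactly
  w_obs <- sum(r[seq_len(n)])
  e_w <- n * mean(r) # = n * (n + m + 1) / 2 without ties
  splits <- utils::combn(n + m, n)
  w_all <- colSums(matrix(r[splits], nrow = n))
  eps <- 1e-9
  p <- mean(abs(w_all - e_w) >= abs(w_obs - e_w) - eps)
  list(statistic = w_obs, p_value = p)
}

#' Wilcoxon rank-sum comparison of two groups
#'
#' Two-sided Mann-Whitney/Wilcoxon rank-sum test. When both groups have at
#' most 8 observations the p-value is an exact enumeration over all rank
#' splits (midranks, so tied data remain exact); otherwise the normal
#' approximation with tie correction is used (no continuity correction).
#' The statistic is the rank sum of the first group.
#'
#' @param group_a,group_b non-empty numeric vectors.
#' @return list with `statistic` (rank sum of `group_a`) and `p_value`.
#' @export
rank_sum_compare <- function(group_a, group_b) {
  a <- as.numeric(group_a); b <- as.numeric(group_b)
  if (!length(a) || !length(b)) stop("both groups must be non-empty")
  n <- length(a); m <- length(b)
  if (n <= 8 && m <= 8) return(.ranksum_exact(a, b))
  r <- rank(c(a, b))
  w <- sum(r[seq_len(n)])
  e_w <- n * (n + m + 1) / 2
  ties <- table(r)
  tie_term <- sum(ties^3 - ties) / ((n + m) * (n + m - 1))
  v_w <- n * m / 12 * (n + m + 1 - tie_term)
  if (v_w <= 0) return(list(statistic = w, p_value = 1))
  z <- (w - e_w) / sqrt(v_w)
  list(statistic = w, p_value = 2 * stats::pnorm(-abs(z)))
}
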