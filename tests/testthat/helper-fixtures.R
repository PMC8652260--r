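library(data.table)

# shorthand interval table on one chromosome
ivl <- function(start, end, chrom = "chr1", ...) {
  genomic_intervals(chrom, start, end, ...)
}

# fragment set from fragment start positions (fixed length)
frags <- function(starts, len = 100L, chrom = "chr1", lib = 1e6) {
  if (!length(starts)) {
    return(fragment_set(genomic_intervals(character(), integer(), integer(),
                                          unique = FALSE), lib))
  }
  fragment_set(genomic_intervals(chrom, starts, starts + len, unique = FALSE),
               lib)
}

# UCSC chain text from a block table; header coords derived from blocks
chain_text <- function(blocks, t_name = "chr1", t_size = 10000L,
                       t_start = 0L, q_name = "chr1", q_size = 10000L,
                       q_strand = "+", q_start = 0L, score = 1000,
                       id = "1") {
  b <- as.data.table(blocks)
  n <- nrow(b)
  if (!"dt" %in% names(b)) b[, dt := 0L]
  if (!"dq" %in% names(b)) b[, dq := 0L]
  t_end <- t_start + sum(b$size) + sum(b$dt[-n])
  q_end <- q_start + sum(b$size) + sum(b$dq[-n])
  hdr <- sprintf("chain %s %s %d + %d %d %s %d %s %d %d %s",
                 format(score, scientific = FALSE), t_name, t_size,
                 t_start, t_end, q_name, q_size, q_strand, q_start,
                 q_end, id)
  body <- if (n > 1) sprintf("%d %d %d", b$size[-n], b$dt[-n], b$dq[-n])
          else character()
  c(hdr, body, as.character(b$size[n]), "")
}

# whole-chromosome identity chain
identity_chain <- function(size = 10000L, chrom = "chr1") {
  parse_chain(text = chain_text(data.table(size = size), t_size = size,
                                q_size = size))
}

# independent brute-force oracle for the hockey-stick tangent: for every
# candidate rank, count points on or below the slope-m line through it
brute_cutoff <- function(signals) {
  s <- sort(pmax(as.numeric(signals), 0))
  n <- length(s)
  m <- (s[n] - s[1]) / n
  counts <- integer(n)
  for (x in seq_len(n)) {
    counts[x] <- sum(s <= s[x] + m * (seq_len(n) - x))
  }
  best <- max(which(counts == min(counts)))
  list(cutoff_value = s[best], tangent_index = best)
}

# small generator configuration for fast replicate tests (2 tissues).
# n_k4_peaks stays at 100 so the 5 planted broad domains remain <= 5% of
# the 105 H3K4me3 peaks (the recovery premise).
small_config <- function(seed, ...) {
  defaults <- list(seed = seed, tissues = c("tisA", "tisB"),
                   n_background_peaks = 50L, n_k4_peaks = 100L,
                   fraction_private = list(se = 0.6, te = 0.4,
                                           bd = 0.2, nd = 0.1),
                   fraction_conserved = list(se = 0.4, te = 0.1,
                                             bd = 0.4, nd = 0.1))
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}
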