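#' Parse a UCSC chain file
#'
#' Reads pairwise-alignment chains: a header line
#' `chain score tName tSize tStrand tStart tEnd qName qSize qStrand qStart
#' qEnd id` followed by alignment blocks `size dt dq` with a final
#' size-only line. Both block-arithmetic invariants are verified per
#' chain: the sizes plus target gaps must span `tEnd - tStart` and the
#' sizes plus query gaps must span `qEnd - qStart`.
#'
#' @param path chain file path, or a character vector of lines via
#'   `text =`.
#' @param text optional character vector of chain-format lines.
#' @return list of `chain` objects: fields `score`, `t_name`, `t_size`,
#'   `t_strand`, `t_start`, `t_end`, `q_name`, `q_size`, `q_strand`,
#'   `q_start`, `q_end`, `id`, and `blocks` (`data.table` of
#'   `size, dt, dq`; gaps are 0 on the final block).
#' @export
parse_chain <- function(path = NULL, text = NULL) {
  lines <- if (is.null(text)) readLines(path) else text
  lines <- trimws(lines)
  chains <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(lines[i])) { i <- i + 1L; next }
    f <- strsplit(lines[i], "[ \t]+")[[1]]
    if (f[1] != "chain" || length(f) < 13L) {
      stop("malformed chain header at line ", i, ": ", lines[i])
    }
    ch <- list(score = as.numeric(f[2]),
               t_name = f[3], t_size = as.integer(f[4]), t_strand = f[5],
               t_start = as.integer(f[6]), t_end = as.integer(f[7]),
               q_name = f[8], q_size = as.integer(f[9]), q_strand = f[10],
               q_start = as.integer(f[11]), q_end = as.integer(f[12]),
               id = f[13])
    if (ch$t_strand != "+") stop("chain ", ch$id, ": target strand must be +")
    i <- i + 1L
    sizes <- integer(); dts <- integer(); dqs <- integer()
    repeat {
      if (i > length(lines) || !nzchar(lines[i])) {
        stop("chain ", ch$id, ": truncated block list at line ", i)
      }
      bf <- suppressWarnings(as.integer(strsplit(lines[i], "[ \t]+")[[1]]))
      if (anyNA(bf)) stop("chain ", ch$id, ": malformed block at line ", i)
      if (length(bf) == 1L) {
        sizes <- c(sizes, bf[1]); dts <- c(dts, 0L); dqs <- c(dqs, 0L)
        i <- i + 1L
        break
      } else if (length(bf) == 3L) {
        sizes <- c(sizes, bf[1]); dts <- c(dts, bf[2]); dqs <- c(dqs, bf[3])
        i <- i + 1L
      } else {
        stop("chain ", ch$id, ": malformed block at line ", i)
      }
    }
    if (any(sizes <= 0L)) stop("chain ", ch$id, ": block sizes must be > 0")
    if (any(dts < 0L) || any(dqs < 0L)) {
      stop("chain ", ch$id, ": gaps must be >= 0")
    }
    if (sum(sizes) + sum(dts) != ch$t_end - ch$t_start) {
      stop("chain ", ch$id, ": target block arithmetic violated (",
           sum(sizes) + sum(dts), " != ", ch$t_end - ch$t_start, ")")
    }
    if (sum(sizes) + sum(dqs) != ch$q_end - ch$q_start) {
      stop("chain ", ch$id, ": query block arithmetic violated (",
           sum(sizes) + sum(dqs), " != ", ch$q_end - ch$q_start, ")")
    }
    ch$blocks <- data.table(size = sizes, dt = dts, dq = dqs)
    class(ch) <- "chain"
    chains[[length(chains) + 1L]] <- ch
  }
  chains
}

#' Write chains in UCSC chain format
#'
#' @param chains list of `chain` objects (as from [parse_chain()]).
#' @param path output path.
#' @export
write_chain <- function(chains, path) {
  if (inherits(chains, "chain")) chains <- list(chains)
  out <- unlist(lapply(chains, function(ch) {
    hdr <- sprintf("chain %s %s %d %s %d %d %s %d %s %d %d %s",
                   format(ch$score, scientific = FALSE), ch$t_name,
                   ch$t_size, ch$t_strand, ch$t_start, ch$t_end,
                   ch$q_name, ch$q_size, ch$q_strand, ch$q_start,
                   ch$q_end, ch$id)
    b <- ch$blocks
    n <- nrow(b)
    body <- if (n > 1L) {
      sprintf("%d\t%d\t%d", b$size[-n], b$dt[-n], b$dq[-n])
    } else character()
    c(hdr, body, as.character(b$size[n]), "")
  }))
  writeLines(out, path)
  invisible(path)
}

# cumulative block coordinates on target and query (alignment frame)
.chain_block_coords <- function(ch) {
  b <- ch$blocks
  tb <- ch$t_start + c(0L, cumsum(b$size + b$dt))[seq_len(nrow(b))]
  qb <- ch$q_start + c(0L, cumsum(b$size + b$dq))[seq_len(nrow(b))]
  data.table(t0 = tb, t1 = tb + b$size, q0 = qb, q1 = qb + b$size)
}

# lift one interval through one chain; NULL if no aligned base
.lift_through_chain <- function(start, end, ch) {
  bc <- .chain_block_coords(ch)
  ov0 <- pmax(bc$t0, start)
  ov1 <- pmin(bc$t1, end)
  hit <- ov1 > ov0
  if (!any(hit)) return(NULL)
  mappable <- sum(ov1[hit] - ov0[hit])
  q_lo <- bc$q0[hit] + (ov0[hit] - bc$t0[hit])
  q_hi <- bc$q0[hit] + (ov1[hit] - bc$t0[hit])
  qs <- min(q_lo); qe <- max(q_hi)
  if (ch$q_strand == "-") {
    tmp <- ch$q_size - qe
    qe <- ch$q_size - qs
    qs <- tmp
  }
  list(chrom = ch$q_name, start = qs, end = qe, mappable = mappable)
}

#' Lift an interval to another genome through alignment chains
#'
#' Candidate chains are those whose target span overlaps the interval,
#' tried in descending chain score. Within a chain the mappable bases are
#' those falling inside aligned blocks; `match_fraction` is mappable bases
#' over interval width. If the fraction reaches `min_match` the mapped
#' interval spans min..max of the block-mapped query coordinates
#' (reflected as `pos' = q_size - pos` for minus-strand chains). An
#' interval passing `min_match` on two chains whose query spans do not
#' overlap is rejected as ambiguous rather than duplicated.
#'
#' @param interval a single-row interval table, or a list/row with
#'   `chrom`, `start`, `end`.
#' @param chains list of `chain` objects (same genome pair).
#' @param min_match minimum alignable fraction in (0, 1]; default 0.2.
#' @return list with `status` (one of `mapped`, `unmapped_no_chain`,
#'   `unmapped_low_match`, `ambiguous_multiple_chains`), `mapped_interval`
#'   (single-row interval table or `NULL`) and `match_fraction`.
#' @export
liftover <- function(interval, chains, min_match = 0.2) {
  if (!is.numeric(min_match) || min_match <= 0 || min_match > 1) {
    stop("min_match must be in (0, 1]")
  }
  iv <- as.list(as.data.table(as.list(interval))[1])
  chrom <- as.character(iv$chrom)
  start <- as.integer(iv$start); end <- as.integer(iv$end)
  width <- end - start
  cand <- Filter(function(ch) ch$t_name == chrom &&
                   ch$t_start < end && start < ch$t_end, chains)
  if (!length(cand)) {
    return(list(status = "unmapped_no_chain", mapped_interval = NULL,
                match_fraction = 0))
  }
  cand <- cand[order(-vapply(cand, `[[`, numeric(1), "score"))]
  lifts <- lapply(cand, function(ch) .lift_through_chain(start, end, ch))
  fracs <- vapply(lifts, function(l) if (is.null(l)) 0 else l$mappable / width,
                  numeric(1))
  pass <- which(fracs >= min_match)
  if (!length(pass)) {
    return(list(status = "unmapped_low_match", mapped_interval = NULL,
                match_fraction = max(fracs)))
  }
  if (length(pass) > 1L) {
    for (a in seq_along(pass)[-length(pass)]) {
      for (b in seq((a + 1), length(pass))) {
        la <- lifts[[pass[a]]]; lb <- lifts[[pass[b]]]
        disjoint <- la$chrom != lb$chrom ||
          la$end <= lb$start || lb$end <= la$start
        if (disjoint) {
          return(list(status = "ambiguous_multiple_chains",
                      mapped_interval = NULL,
                      match_fraction = max(fracs)))
        }
      }
    }
  }
  best <- pass[1]  # highest score among passing chains
  l <- lifts[[best]]
  mapped <- genomic_intervals(chrom = l$chrom, start = l$start, end = l$end)
  list(status = "mapped", mapped_interval = mapped,
       match_fraction = fracs[best])
}

#' Lift a whole element table
#'
#' Applies [liftover()] row-wise and returns one row per input element
#' with the lift status and mapped coordinates (`NA` when unmapped).
#'
#' @param elements interval table.
#' @param chains list of `chain` objects.
#' @param min_match minimum alignable fraction (default 0.2).
#' @return `data.table` with input coordinates, `status`,
#'   `match_fraction`, and `lifted_chrom/lifted_start/lifted_end`.
#' @export
liftover_table <- function(elements, chains, min_match = 0.2) {
  elements <- genomic_intervals(elements, unique = FALSE)
  res <- lapply(seq_len(nrow(elements)), function(i) {
    r <- liftover(elements[i], chains, min_match = min_match)
    data.table(status = r$status, match_fraction = r$match_fraction,
               lifted_chrom = if (is.null(r$mapped_interval)) NA_character_
                              else r$mapped_interval$chrom,
               lifted_start = if (is.null(r$mapped_interval)) NA_integer_
                              else r$mapped_interval$start,
               lifted_end = if (is.null(r$mapped_interval)) NA_integer_
                            else r$mapped_interval$end)
  })
  cbind(elements[, .(chrom, start, end, name)], rbindlist(res))
}

# link elements of a to elements of b: overlap >= 1 bp when d = 0,
# midpoint distance <= d otherwise; returns logical per a row
.links_any <- function(a, b, merge_distance) {
  if (!nrow(a)) return(logical())
  if (!nrow(b)) return(rep(FALSE, nrow(a)))
  if (merge_distance == 0) {
    qa <- a[, .(chrom, start, end = end - 1L, ia = .I)]
    sb <- .closed(b)
    hits <- foverlaps(qa, sb, type = "any", nomatch = NULL)
    out <- rep(FALSE, nrow(a))
    out[unique(hits$ia)] <- TRUE
    out
  } else {
    qa <- a[, .(chrom, mid = (start + end) %/% 2L, ia = .I)]
    qa[, `:=`(start = mid - as.integer(merge_distance),
              end = mid + as.integer(merge_distance))]
    setkey(qa, chrom, start, end)
    sb <- b[, .(chrom, mid = (start + end) %/% 2L)]
    sb[, `:=`(start = mid, end = mid)]
    setkey(sb, chrom, start, end)
    hits <- foverlaps(qa, sb, type = "any", nomatch = NULL)
    out <- rep(FALSE, nrow(a))
    out[unique(hits$ia)] <- TRUE
    out
  }
}

#' Classify functionally conserved elements across three species
#'
#' A focal-species element (already lifted into the reference frame) is
#' functionally conserved iff it links to at least one reference-species
#' element AND at least one third-species element (also lifted). Linking
#' is same-chromosome interval overlap (>= 1 bp) when `merge_distance` is
#' 0, or midpoint distance <= `merge_distance` otherwise. Elements that
#' failed liftover upstream are by definition not conserved but still
#' count toward `n_total` via `n_unmapped`.
#'
#' @param focal_lifted focal-species elements in the reference frame.
#' @param reference reference-species elements (native frame).
#' @param third_lifted third-species elements lifted to the reference.
#' @param merge_distance linkage distance in bp (default 0 = overlap).
#' @param n_unmapped focal elements dropped by liftover (added to
#'   `n_total`).
#' @return list with `elements` (focal table plus `conserved` flag),
#'   `n_conserved`, `n_total`, `fraction`.
#' @export
classify_functionally_conserved <- function(focal_lifted, reference,
                                            third_lifted,
                                            merge_distance = 0L,
                                            n_unmapped = 0L) {
  a <- genomic_intervals(focal_lifted, unique = FALSE)
  b <- genomic_intervals(reference, unique = FALSE)
  c_ <- genomic_intervals(third_lifted, unique = FALSE)
  if (nrow(a) && nrow(b) &&
      !length(intersect(unique(a$chrom), unique(b$chrom)))) {
    stop("no shared chromosome names: coordinate-frame mismatch?")
  }
  conserved <- .links_any(a, b, merge_distance) &
               .links_any(a, c_, merge_distance)
  a[, conserved := conserved]
  n_total <- nrow(a) + as.integer(n_unmapped)
  list(elements = a[], n_conserved = sum(conserved), n_total = n_total,
       fraction = if (n_total) sum(conserved) / n_total else NA_real_)
}

#' Read a per-base conservation score track
#'
#' Accepts fixedStep WIG (`fixedStep chrom=... start=... step=...
#' [span=...]`; 1-based starts converted here) or bedGraph (4 columns,
#' already 0-based half-open). Scores must lie in \[0, 1\]; bases without
#' data are simply absent from the track and are distinguishable from
#' score 0.
#'
#' @param path track file path.
#' @return a `conservation_track`: `data.table` of scored runs
#'   `chrom, start, end, score`.
#' @export
read_track <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("^(fixedStep|track)", first)) {
    lines <- readLines(path)
    runs <- list()
    chrom <- NULL; pos <- NA_integer_; step <- 1L; span <- 1L
    for (ln in lines) {
      if (grepl("^track", ln)) next
      if (grepl("^fixedStep", ln)) {
        get <- function(key, default = NA) {
          m <- regmatches(ln, regexec(paste0(key, "=([^ \t]+)"), ln))[[1]]
          if (length(m) < 2) default else m[2]
        }
        chrom <- get("chrom")
        pos <- as.integer(get("start")) - 1L  # WIG is 1-based
        step <- as.integer(get("step", "1"))
        span <- as.integer(get("span", "1"))
        if (is.na(chrom) || is.na(pos)) stop("malformed fixedStep header")
        next
      }
      if (!nzchar(ln)) next
      if (is.null(chrom)) stop("WIG data before fixedStep header")
      runs[[length(runs) + 1L]] <-
        data.table(chrom = chrom, start = pos, end = pos + span,
                   score = as.numeric(ln))
      pos <- pos + step
    }
    track <- rbindlist(runs)
  } else {
    bg <- fread(path, header = FALSE, sep = "\t")
    if (ncol(bg) < 4) stop("bedGraph needs 4 columns")
    track <- data.table(chrom = as.character(bg[[1]]),
                        start = as.integer(bg[[2]]),
                        end = as.integer(bg[[3]]),
                        score = as.numeric(bg[[4]]))
  }
  conservation_track(track)
}

#' Construct a conservation track from scored runs
#'
#' @param runs data.frame with `chrom, start, end, score`; scores in
#'   \[0, 1\].
#' @return validated `conservation_track` (a keyed `data.table`).
#' @export
conservation_track <- function(runs) {
  tr <- as.data.table(runs)[, .(chrom = as.character(chrom),
                                start = as.integer(start),
                                end = as.integer(end),
                                score = as.numeric(score))]
  if (any(tr$score < 0 | tr$score > 1)) stop("scores must be in [0, 1]")
  if (any(tr$end <= tr$start)) stop("empty track run")
  setorder(tr, chrom, start, end)
  setattr(tr, "class", c("conservation_track", class(tr)))
  tr
}

#' Mean conservation score over an element
#'
#' Arithmetic mean of per-base scores over the bases WITH data inside
#' each interval, plus the fraction of the interval covered by data. An
#' interval with no scored base gets mean `NA` (distinct from 0).
#'
#' @param elements interval table (one or more rows).
#' @param track a [conservation_track()].
#' @return `data.table` with `chrom, start, end, mean_score, coverage`,
#'   one row per element in input order.
#' @export
mean_conservation_score <- function(elements, track) {
  elements <- as.data.table(elements)
  out <- elements[, .(chrom = as.character(chrom),
                      start = as.integer(start), end = as.integer(end))]
  if (nrow(out) && any(out$end <= out$start)) stop("end must be > start")
  out[, `:=`(mean_score = NA_real_, coverage = 0)]
  if (!nrow(elements) || !nrow(track)) return(out[])
  q <- out[, .(chrom, qs = start, qe = end - 1L, iq = .I)]
  s <- track[, .(chrom, start, end = end - 1L, score)]
  setkey(s, chrom, start, end)
  hits <- foverlaps(q, s, by.x = c("chrom", "qs", "qe"),
                    type = "any", nomatch = NULL)
  if (!nrow(hits)) return(out[])
  # half-open overlap widths (closed coords were end - 1)
  hits[, ov := pmin(qe + 1L, end + 1L) - pmax(qs, start)]
  agg <- hits[, .(covered = sum(ov), total = sum(ov * score)), by = iq]
  out[agg$iq, `:=`(mean_score = agg$total / agg$covered,
                   coverage = agg$covered / (end - start))]
  out[]
}
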