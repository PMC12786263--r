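# Long-read annotation of CNV/unit sequences: seed-and-extend local hits,
# greedy non-redundant hit acceptance, tandem-array and co-localization
# annotation, flank-anchored locus reconstruction and premature-stop
# screening.

#' Find local alignments of query sequences on a long read
#'
#' Seed-and-extend local alignment specialised for low-divergence data:
#' exact `seed_len`-mer seed matches between query and read (both strands)
#' define diagonals, and each diagonal is scored ungapped (+1 match, -2
#' mismatch) with the maximal-scoring segment taken as the hit. Hits shorter
#' than `min_len` or below `min_identity` are removed; hits on distinct
#' diagonals (adjacent or gap-separated copies) are reported separately.
#'
#' @param read read sequence (character scalar).
#' @param queries named character vector of query sequences (CNVs, repeat
#'   unit, flanks).
#' @param min_len minimum hit length in bp (default 200).
#' @param min_identity minimum identity fraction (default 0.80).
#' @param seed_len exact seed length (default 15, <= 26).
#' @return data.frame of hits: `query_id`, `read_start`, `read_end`
#'   (0-based half-open on the read), `length`, `identity`, `orientation`.
#' @export
find_hits <- function(read, queries, min_len = 200L, min_identity = 0.80,
                      seed_len = 15L) {
  if (!length(queries)) stop("queries must be nonempty")
  if (is.null(names(queries))) names(queries) <- paste0("q", seq_along(queries))
  empty <- data.frame(query_id = character(0), read_start = numeric(0),
                      read_end = numeric(0), length = numeric(0),
                      identity = numeric(0), orientation = character(0))
  nr <- nchar(read)
  if (nr == 0L) return(empty)
  if (nr < seed_len) return(empty)
  read_codes <- encode_windows(read, seed_len)
  rdt <- data.table::data.table(code = read_codes, rpos = seq_along(read_codes))
  rdt <- rdt[!is.na(code)]
  data.table::setkey(rdt, code)
  read_raw <- charToRaw(read)
  hits <- list()
  for (qi in seq_along(queries)) {
    for (ori in c("+", "-")) {
      q <- if (ori == "+") queries[[qi]] else revcomp(queries[[qi]])
      nq <- nchar(q)
      if (nq < seed_len) next
      qcodes <- encode_windows(q, seed_len)
      qdt <- data.table::data.table(code = qcodes, qpos = seq_along(qcodes))
      qdt <- qdt[!is.na(code)]
      mm <- rdt[qdt, on = "code", allow.cartesian = TRUE, nomatch = NULL]
      if (nrow(mm) == 0L) next
      diags <- unique(mm$rpos - mm$qpos)            # read_start - query_start
      q_raw <- charToRaw(q)
      for (d in diags) {
        r_lo <- max(1L, d + 1L)                     # 1-based on read
        r_hi <- min(nr, d + nq)
        if (r_hi - r_lo + 1L < min_len) next
        eq <- read_raw[r_lo:r_hi] == q_raw[(r_lo - d):(r_hi - d)]
        step <- ifelse(eq, 1, -2)
        s <- cumsum(step)
        prevmin <- cummin(c(0, s[-length(s)]))
        gain <- s - prevmin
        j <- which.max(gain)
        i <- which(c(0, s[-length(s)]) == prevmin[j])
        i <- max(i[i <= j])                         # tightest segment [i, j]
        len <- j - i + 1L
        if (len < min_len) next
        ident <- mean(eq[i:j])
        if (ident < min_identity) next
        hits[[length(hits) + 1L]] <- data.frame(
          query_id = names(queries)[qi],
          read_start = r_lo + i - 2L,               # 0-based
          read_end = r_lo + j - 1L,
          length = len, identity = ident, orientation = ori)
      }
    }
  }
  if (!length(hits)) return(empty)
  out <- do.call(rbind, hits)
  # a hit can be rediscovered from overlapping diagonals on near-identical
  # tandem neighbours; keep one record per (query, interval, orientation)
  out <- unique(out)
  out[order(out$read_start, out$read_end, out$query_id), , drop = FALSE]
}

#' Greedy non-redundant acceptance of overlapping hits
#'
#' Reproduces the redundancy filter used for nested local-alignment hits:
#' hits on one read are sorted by decreasing alignment length (ties broken
#' by read start, then query id) and accepted iteratively; a hit is
#' discarded when at least 80% of its length overlaps the union of already
#' accepted hits. Adjacent or gap-separated hits remain distinct.
#'
#' @param hits data.frame from [find_hits()] (one read).
#' @param max_overlap overlap fraction above which a hit is discarded
#'   (default 0.8).
#' @return the accepted subset of `hits`, in acceptance order.
#' @export
dedupe_hits <- function(hits, max_overlap = 0.8) {
  if (nrow(hits) == 0L) return(hits)
  ord <- order(-hits$length, hits$read_start, hits$query_id)
  h <- hits[ord, , drop = FALSE]
  acc_start <- numeric(0); acc_end <- numeric(0)
  keep <- logical(nrow(h))
  for (i in seq_len(nrow(h))) {
    ov <- 0
    if (length(acc_start)) {
      ov_each <- pmax(0, pmin(acc_end, h$read_end[i]) - pmax(acc_start, h$read_start[i]))
      # accepted intervals are kept disjoint, so overlaps add up exactly
      ov <- sum(ov_each)
    }
    if (ov >= max_overlap * h$length[i]) next
    keep[i] <- TRUE
    # merge into the disjoint accepted union
    s <- h$read_start[i]; e <- h$read_end[i]
    if (length(acc_start)) {
      touch <- acc_end >= s & acc_start <= e
      if (any(touch)) {
        s <- min(s, acc_start[touch]); e <- max(e, acc_end[touch])
        acc_start <- acc_start[!touch]; acc_end <- acc_end[!touch]
      }
    }
    acc_start <- c(acc_start, s); acc_end <- c(acc_end, e)
  }
  h[keep, , drop = FALSE]
}

#' Annotate tandem arrays and query co-occurrence on long reads
#'
#' Merges consecutive same-orientation hits of the repeat unit whose
#' inter-hit gap is at most `0.2 * unit_length` into tandem arrays
#' (head-to-tail organisation), and counts, for every query pair, the number
#' of reads on which both queries have accepted hits (co-localization).
#'
#' @param hits data.frame of accepted hits across reads; must carry a
#'   `read_id` column in addition to the [find_hits()] columns.
#' @param unit_length repeat unit length in bp.
#' @param unit_id query id of the repeat unit (default `"unit"`).
#' @return list with `arrays` (data.frame `read_id`, `unit_count`, `span`,
#'   `start`, `end`, `head_to_tail`, `orientation`) and `cooccurrence`
#'   (symmetric integer matrix over query ids; diagonal = reads containing
#'   the query).
#' @export
annotate_arrays <- function(hits, unit_length, unit_id = "unit") {
  queries <- sort(unique(hits$query_id))
  co <- matrix(0L, length(queries), length(queries),
               dimnames = list(queries, queries))
  arrays <- list()
  for (rid in unique(hits$read_id)) {
    h <- hits[hits$read_id == rid, , drop = FALSE]
    present <- unique(h$query_id)
    co[present, present] <- co[present, present] + 1L
    u <- h[h$query_id == unit_id, , drop = FALSE]
    if (nrow(u) == 0L) next
    u <- u[order(u$read_start), , drop = FALSE]
    gap_ok <- c(FALSE,
                u$read_start[-1L] - u$read_end[-nrow(u)] <= 0.2 * unit_length &
                  u$orientation[-1L] == u$orientation[-nrow(u)])
    grp <- cumsum(!gap_ok)
    for (g in unique(grp)) {
      seg <- u[grp == g, , drop = FALSE]
      arrays[[length(arrays) + 1L]] <- data.frame(
        read_id = rid, unit_count = nrow(seg),
        span = max(seg$read_end) - min(seg$read_start),
        start = min(seg$read_start), end = max(seg$read_end),
        head_to_tail = nrow(seg) == 1L ||
          all(seg$orientation == seg$orientation[1L]),
        orientation = seg$orientation[1L])
    }
  }
  arrays <- if (length(arrays)) do.call(rbind, arrays) else
    data.frame(read_id = character(0), unit_count = integer(0),
               span = numeric(0), start = numeric(0), end = numeric(0),
               head_to_tail = logical(0), orientation = character(0))
  list(arrays = arrays, cooccurrence = co)
}

#' Reconstruct a flank-anchored locus from long reads
#'
#' Identifies reads containing both locus flanks in consistent orientation,
#' counts repeat units between the flanks on each such read (the
#' units-per-read histogram), and builds a consensus of the locus from
#' single-unit reads by anchor-offset column majority vote — exact on
#' error-free reads. If an exon interval is supplied the consensus reads are
#' screened for premature stop codons.
#'
#' @param reads a long-read `read_set` or data.frame with `id`, `seq`.
#' @param flank_left,flank_right,unit locus component sequences.
#' @param min_len,min_identity,seed_len passed to [find_hits()].
#' @param exon2 optional 0-based half-open interval of the coding exon
#'   relative to the left flank start; enables stop screening.
#' @return a `locus_model`: list with `consensus`, `histogram` (named
#'   integer vector: units-per-read), `n_anchored`, `segments` (oriented
#'   locus sequences, one per anchored read), `stop_fraction` (or `NA`).
#' @export
reconstruct_locus <- function(reads, flank_left, flank_right, unit,
                              min_len = 200L, min_identity = 0.80,
                              seed_len = 15L, exon2 = NULL) {
  r <- if (inherits(reads, "read_set")) reads$reads else as.data.frame(reads)
  queries <- c(flankL = flank_left, flankR = flank_right, unit = unit)
  segments <- character(0)
  unit_counts <- integer(0)
  for (i in seq_len(nrow(r))) {
    h <- find_hits(r$seq[i], queries, min_len = min_len,
                   min_identity = min_identity, seed_len = seed_len)
    if (nrow(h) == 0L) next
    h <- dedupe_hits(h)
    fl <- h[h$query_id == "flankL", , drop = FALSE]
    fr <- h[h$query_id == "flankR", , drop = FALSE]
    if (nrow(fl) == 0L || nrow(fr) == 0L) next
    # consistent orientation: both flanks same strand, left before right on
    # '+', right before left on '-' (use the closest consistent pair)
    found <- FALSE
    for (a in seq_len(nrow(fl))) {
      for (b in seq_len(nrow(fr))) {
        if (fl$orientation[a] != fr$orientation[b]) next
        ok <- if (fl$orientation[a] == "+") fl$read_end[a] <= fr$read_start[b]
              else fr$read_end[b] <= fl$read_start[a]
        if (!ok) next
        if (fl$orientation[a] == "+") {
          s <- fl$read_start[a]; e <- fr$read_end[b]
        } else {
          s <- fr$read_start[b]; e <- fl$read_end[a]
        }
        un <- h[h$query_id == "unit" & h$read_start >= s & h$read_end <= e &
                  h$orientation == fl$orientation[a], , drop = FALSE]
        seg <- substr(r$seq[i], s + 1L, e)
        if (fl$orientation[a] == "-") seg <- revcomp(seg)
        segments <- c(segments, seg)
        unit_counts <- c(unit_counts, nrow(un))
        found <- TRUE
        break
      }
      if (found) break
    }
  }
  n_anchored <- length(segments)
  if (n_anchored == 0L) {
    warning("no flank-anchored reads found; empty locus model")
    return(structure(list(consensus = NA_character_,
                          histogram = integer(0), n_anchored = 0L,
                          segments = character(0), stop_fraction = NA_real_),
                     class = "locus_model"))
  }
  histogram <- table(unit_counts)
  single <- segments[unit_counts == 1L]
  consensus <- if (length(single)) .column_majority(single) else NA_character_
  stop_fraction <- NA_real_
  if (!is.null(exon2)) {
    sc <- screen_stop_codons(segments, exon2[1], exon2[2])
    stop_fraction <- sc$stop_fraction
  }
  structure(list(consensus = consensus,
                 histogram = stats::setNames(as.integer(histogram), names(histogram)),
                 n_anchored = n_anchored,
                 segments = segments,
                 stop_fraction = stop_fraction),
            class = "locus_model")
}

# per-column majority vote over left-anchored sequences; consensus length is
# the most common segment length
.column_majority <- function(seqs) {
  if (length(seqs) == 1L) return(seqs)
  lens <- nchar(seqs)
  L <- as.integer(names(sort(table(lens), decreasing = TRUE))[1L])
  ints <- lapply(seqs, function(s) as.integer(charToRaw(s)))
  cons <- integer(L)
  for (j in seq_len(L)) {
    col <- unlist(lapply(ints, function(x) if (length(x) >= j) x[j] else NULL))
    tb <- sort(table(col), decreasing = TRUE)
    cons[j] <- as.integer(names(tb)[1L])
  }
  rawToChar(as.raw(cons))
}

#' @export
print.locus_model <- function(x, ...) {
  cat("locus_model:", x$n_anchored, "flank-anchored read(s)\n")
  if (length(x$histogram)) {
    cat("  units-per-read histogram:",
        paste(sprintf("%s:%d", names(x$histogram), x$histogram), collapse = " "), "\n")
  }
  if (!is.na(x$stop_fraction)) {
    cat(sprintf("  premature-stop fraction: %.3f\n", x$stop_fraction))
  }
  invisible(x)
}

#' Screen sequences for premature stop codons in an annotated exon
#'
#' Walks codons across the annotated exon of each sequence; a sequence is
#' flagged iff an in-frame TAA/TAG/TGA occurs before the exon's end. Codons
#' are read from `exon_start + frame` in steps of 3; a trailing partial
#' codon is ignored. Out-of-frame stop triplets are not flagged.
#'
#' @param seqs character vector (copies, reads or locus segments sharing the
#'   exon coordinate system).
#' @param exon_start,exon_end 0-based half-open exon interval on each
#'   sequence.
#' @param frame reading-frame offset within the exon (0, 1 or 2).
#' @return list with `flags` (logical per sequence) and `stop_fraction`.
#' @export
screen_stop_codons <- function(seqs, exon_start, exon_end, frame = 0L) {
  if (exon_end - exon_start < 3L) stop("exon shorter than 3 bp")
  stopifnot(frame %in% 0:2)
  starts1 <- seq.int(exon_start + frame + 1L, exon_end - 2L, by = 3L)
  flags <- vapply(seqs, function(s) {
    cods <- substring(s, starts1, starts1 + 2L)
    any(cods %in% c("TAA", "TAG", "TGA"))
  }, logical(1), USE.NAMES = FALSE)
  list(flags = flags, stop_fraction = mean(flags))
}

#' Run find/dedupe across many reads
#'
#' Applies [find_hits()] and [dedupe_hits()] to each read and binds the
#' accepted hits with a `read_id` column, ready for [annotate_arrays()].
#'
#' @param reads long-read `read_set` or data.frame (`id`, `seq`).
#' @param queries named character vector.
#' @param ... passed to [find_hits()].
#' @return data.frame of accepted hits.
#' @export
find_hits_reads <- function(reads, queries, ...) {
  r <- if (inherits(reads, "read_set")) reads$reads else as.data.frame(reads)
  out <- lapply(seq_len(nrow(r)), function(i) {
    h <- dedupe_hits(find_hits(r$seq[i], queries, ...))
    if (nrow(h)) cbind(read_id = r$id[i], h) else NULL
  })
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) {
    return(data.frame(read_id = character(0), query_id = character(0),
                      read_start = numeric(0), read_end = numeric(0),
                      length = numeric(0), identity = numeric(0),
                      orientation = character(0)))
  }
  do.call(rbind, out)
}
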