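# Exact-match short-read mapping, depth tracks and read-depth CNV calling.
#
# The mapper is deliberately minimal: on error-free synthetic reads, "mapping"
# reduces to exact substring occurrence on either strand, which is what a
# default seed-and-extend aligner converges to on identical sequence. Reads
# with several placements (collapsed repeats) take one placement uniformly at
# random, so depth over the collapsed copy accumulates all repeat-derived
# reads.

#' Build a reusable seed index over a reference sequence
#'
#' Indexes every `seed_k`-mer start position of the reference. Building the
#' index once and passing it to repeated [map_reads()] calls (e.g. across
#' simulation replicates on the same reference) avoids re-indexing.
#'
#' @param reference reference sequence (character scalar).
#' @param seed_k seed length in bp (<= 26).
#' @return a `ref_index` object.
#' @export
ref_index <- function(reference, seed_k = 21L) {
  stopifnot(is.character(reference), length(reference) == 1L,
            seed_k >= 1L, seed_k <= 31L)
  structure(list(seq = reference, len = nchar(reference),
                 seed_k = as.integer(seed_k),
                 ptr = cpp_ref_index(reference, as.integer(seed_k))),
            class = "ref_index")
}

#' Map reads to a reference by exact substring occurrence
#'
#' A read is mapped iff it occurs as an exact substring of the reference or
#' of its reverse complement. Candidate placements are located via the
#' read's leading `seed_k`-mer (a necessary condition for a full exact
#' match, so no true placement is missed) and verified by full-string
#' comparison. When a read has several valid placements, one is chosen
#' uniformly at random.
#'
#' @param reads a `read_set` from the simulators, or a data.frame with at
#'   least a `seq` column (optional `id`, `pair_id`, `mate`).
#' @param reference a `ref_index` or a character scalar (indexed on the fly).
#' @param seed_k seed length used when `reference` is a plain sequence.
#' @param seed optional integer seed for the placement tie-break; `NULL`
#'   uses (and advances) the session RNG.
#' @return data.frame of alignment records: `id`, `pair_id`, `mate`,
#'   `start`, `end` (0-based half-open on the reference), `strand`,
#'   `mapped`, `seq`. Unmapped reads keep `NA` coordinates.
#' @export
map_reads <- function(reads, reference, seed_k = 21L, seed = NULL) {
  idx <- if (inherits(reference, "ref_index")) reference else ref_index(reference, seed_k)
  if (!is.null(seed)) return(with_seed(seed, .map_reads_impl(reads, idx)))
  .map_reads_impl(reads, idx)
}

.map_reads_impl <- function(reads, idx) {
  blob <- NULL
  if (inherits(reads, "read_set")) {
    r <- reads$reads
    blob <- reads$blob
  } else {
    r <- as.data.frame(reads)
  }
  n <- nrow(r)
  if (n == 0L) {
    return(data.frame(pair_id = integer(0), mate = integer(0),
                      start = numeric(0), end = numeric(0),
                      strand = character(0), mapped = logical(0)))
  }
  if (!"pair_id" %in% names(r)) r$pair_id <- seq_len(n)
  if (!"mate" %in% names(r)) r$mate <- NA_integer_
  if (!is.null(blob) && is.null(r$seq)) {
    L <- r$len
    if (any(L > idx$len)) stop("read length exceeds reference length")
    if (any(L < idx$seed_k)) stop("seed_k exceeds read length")
    hit <- cpp_map_blob(idx$ptr, blob, as.integer(r$offset), as.integer(r$len))
  } else {
    L <- nchar(r$seq)
    if (any(L > idx$len)) stop("read length exceeds reference length")
    if (any(L < idx$seed_k)) stop("seed_k exceeds read length")
    hit <- cpp_map_reads(idx$ptr, r$seq)
  }
  mapped <- hit$start >= 0L
  start <- as.numeric(hit$start)
  start[!mapped] <- NA_real_
  out <- data.frame(pair_id = r$pair_id, mate = r$mate,
                    start = start, end = start + L,
                    strand = c("+", "-")[hit$strand + 1L],
                    mapped = mapped)
  if (!is.null(r$id)) out$id <- r$id
  if (!is.null(r$seq)) {
    out$seq <- r$seq
  } else {
    out$offset <- r$offset
    out$len <- r$len
    attr(out, "seq_blob") <- blob
  }
  out
}

#' Per-position depth track and baseline from alignments
#'
#' Accumulates per-position coverage over the whole reference from mapped
#' records and estimates the diploid baseline as the median per-position
#' depth outside `mask` (masking candidate CNV intervals keeps the baseline
#' robust; the median is used rather than the mean for the same reason —
#' the mean is available via `baseline_stat = "mean"`).
#'
#' @param alignments data.frame from [map_reads()].
#' @param reference_len reference length in bp.
#' @param mask optional data.frame (`start`, `end`; 0-based half-open) of
#'   intervals to exclude from the baseline.
#' @param baseline_stat `"median"` (default) or `"mean"`.
#' @return list with `track` (class `depth_track`: integer `depth`,
#'   `reference_len`) and `baseline` (numeric).
#' @export
build_depth_track <- function(alignments, reference_len, mask = NULL,
                              baseline_stat = c("median", "mean")) {
  baseline_stat <- match.arg(baseline_stat)
  reference_len <- as.integer(reference_len)
  a <- alignments[alignments$mapped, , drop = FALSE]
  delta <- numeric(reference_len + 1L)
  if (nrow(a)) {
    s <- as.integer(a$start) + 1L       # 1-based
    e <- as.integer(a$end) + 1L         # one past the end, 1-based
    ts <- tabulate(s, nbins = reference_len + 1L)
    te <- tabulate(e, nbins = reference_len + 1L)
    delta <- ts - te
  }
  depth <- as.integer(cumsum(delta)[seq_len(reference_len)])
  keep <- rep(TRUE, reference_len)
  if (!is.null(mask) && nrow(mask)) {
    for (i in seq_len(nrow(mask))) {
      check_interval(mask$start[i], mask$end[i], reference_len, "mask interval")
      keep[(mask$start[i] + 1L):mask$end[i]] <- FALSE
    }
  }
  if (!any(keep)) stop("no baseline region: reference fully masked")
  baseline <- if (baseline_stat == "median") stats::median(depth[keep])
              else mean(depth[keep])
  list(track = structure(list(depth = depth, reference_len = reference_len),
                         class = "depth_track"),
       baseline = baseline)
}

# mean depth per fixed-size window; last (partial) window kept
.window_means <- function(depth, window) {
  n <- length(depth)
  cs <- c(0, cumsum(as.numeric(depth)))
  starts <- seq(1L, n, by = window)
  ends <- pmin(starts + window - 1L, n)
  (cs[ends + 1L] - cs[starts]) / (ends - starts + 1L)
}

#' Call CNV intervals from a heterozygote/homozygote depth contrast
#'
#' Scans fixed-size windows and flags those where the baseline-normalised
#' heterozygote depth exceeds the normalised homozygote depth by at least
#' `min_ratio`, or where the homozygote itself is amplified at least
#' `min_ratio`-fold over its baseline (wild-type amplifications such as a
#' collapsed repeat present in both genotypes). Flagged windows are merged
#' across gaps up to `merge_gap`.
#'
#' @param track_het,track_hom `depth_track`s over the same reference.
#' @param baseline_het,baseline_hom baselines from [build_depth_track()].
#' @param min_ratio detection ratio floor (default 1.5 = one extra copy per
#'   homolog).
#' @param window window size in bp.
#' @param merge_gap maximum gap (bp) bridged when merging flagged windows.
#' @return data.frame of calls (`start`, `end`; 0-based half-open bp).
#' @export
call_cnv_intervals <- function(track_het, track_hom,
                               baseline_het, baseline_hom,
                               min_ratio = 1.5, window = 1000L,
                               merge_gap = 1000L) {
  stopifnot(inherits(track_het, "depth_track"), inherits(track_hom, "depth_track"))
  if (track_het$reference_len != track_hom$reference_len) {
    stop("depth tracks cover different reference lengths")
  }
  if (baseline_het <= 0 || baseline_hom <= 0) stop("zero baseline")
  wh <- .window_means(track_het$depth, window) / baseline_het
  wo <- .window_means(track_hom$depth, window) / baseline_hom
  ratio <- ifelse(wo > 0, wh / wo, ifelse(wh > 0, Inf, 1))
  flag <- ratio >= min_ratio | wo >= min_ratio
  if (!any(flag)) return(data.frame(start = numeric(0), end = numeric(0)))
  n <- length(flag)
  gap_w <- floor(merge_gap / window)
  idx <- which(flag)
  brk <- c(TRUE, diff(idx) > gap_w + 1L)
  grp <- cumsum(brk)
  starts <- tapply(idx, grp, min)
  ends <- tapply(idx, grp, max)
  data.frame(start = (starts - 1) * window,
             end = pmin(ends * window, track_het$reference_len),
             row.names = NULL)
}

#' Quantify copy numbers and extra DNA over CNV intervals
#'
#' For each interval, the total copy number in a sample is
#' `2 * mean_depth / baseline` (two copies at baseline depth). The wild-type
#' per-homolog copy number is half the homozygote total; the rearranged
#' homolog carries the heterozygote total minus the wild-type homolog
#' (clipped at 0 with a warning if negative). The extra DNA contributed by
#' an interval is its length times the copies exceeding the normal diploid
#' state, and the cumulative extra DNA is the sum over calls (reported as
#' an attribute `cumulative_extra_dna`).
#'
#' @param calls data.frame (`start`, `end`) of intervals, e.g. from
#'   [call_cnv_intervals()].
#' @param track_het,track_hom `depth_track`s.
#' @param baseline_het,baseline_hom baselines.
#' @return data.frame with one row per call: `start`, `end`, `length`,
#'   `mean_depth_het`, `mean_depth_hom`, `total_copies_het`,
#'   `total_copies_hom`, `per_homolog_wild`, `per_homolog_rearranged`,
#'   `extra_dna_het`, `extra_dna_hom`.
#' @export
quantify_cnvs <- function(calls, track_het, track_hom,
                          baseline_het, baseline_hom) {
  if (baseline_het <= 0 || baseline_hom <= 0) stop("zero baseline")
  n <- nrow(calls)
  res <- data.frame(start = calls$start, end = calls$end,
                    length = calls$end - calls$start)
  mdep <- function(track, s, e) {
    vapply(seq_along(s), function(i) {
      check_interval(s[i], e[i], track$reference_len, "CNV call")
      mean(track$depth[(s[i] + 1L):e[i]])
    }, numeric(1))
  }
  res$mean_depth_het <- if (n) mdep(track_het, calls$start, calls$end) else numeric(0)
  res$mean_depth_hom <- if (n) mdep(track_hom, calls$start, calls$end) else numeric(0)
  res$total_copies_het <- 2 * res$mean_depth_het / baseline_het
  res$total_copies_hom <- 2 * res$mean_depth_hom / baseline_hom
  res$per_homolog_wild <- res$total_copies_hom / 2
  phr <- res$total_copies_het - res$per_homolog_wild
  if (any(phr < 0)) {
    warning("negative per-homolog estimate clipped to 0")
    phr <- pmax(phr, 0)
  }
  res$per_homolog_rearranged <- phr
  res$extra_dna_het <- res$length * pmax(0, res$total_copies_het - 2)
  res$extra_dna_hom <- res$length * pmax(0, res$total_copies_hom - 2)
  attr(res, "cumulative_extra_dna") <-
    c(het = sum(res$extra_dna_het), hom = sum(res$extra_dna_hom))
  res
}

#' Depth-contrast CNV pipeline (map, track, two-pass baseline, call, quantify)
#'
#' Convenience orchestrator: maps heterozygote and homozygote read sets,
#' builds depth tracks, estimates baselines with one masking pass (a first
#' unmasked pass yields candidate calls, which are then masked out before
#' the final baseline is taken), calls CNV intervals and quantifies them.
#'
#' @param reads_het,reads_hom `read_set`s (short reads).
#' @param reference `ref_index` or character scalar.
#' @param min_ratio,window,merge_gap passed to [call_cnv_intervals()].
#' @param map_seed seed for placement tie-breaking.
#' @return list with `alignments_het`, `alignments_hom`, `tracks`,
#'   `baselines`, `calls`, `cnvs`.
#' @export
run_depth_cnv <- function(reads_het, reads_hom, reference,
                          min_ratio = 1.5, window = 1000L, merge_gap = 1000L,
                          map_seed = 1L) {
  idx <- if (inherits(reference, "ref_index")) reference else ref_index(reference)
  ah <- map_reads(reads_het, idx, seed = map_seed)
  ao <- map_reads(reads_hom, idx, seed = map_seed + 1L)
  pass1_het <- build_depth_track(ah, idx$len)
  pass1_hom <- build_depth_track(ao, idx$len)
  calls0 <- call_cnv_intervals(pass1_het$track, pass1_hom$track,
                               pass1_het$baseline, pass1_hom$baseline,
                               min_ratio, window, merge_gap)
  dh <- build_depth_track(ah, idx$len, mask = calls0)
  do_ <- build_depth_track(ao, idx$len, mask = calls0)
  calls <- call_cnv_intervals(dh$track, do_$track, dh$baseline, do_$baseline,
                              min_ratio, window, merge_gap)
  cnvs <- quantify_cnvs(calls, dh$track, do_$track, dh$baseline, do_$baseline)
  list(alignments_het = ah, alignments_hom = ao,
       tracks = list(het = dh$track, hom = do_$track),
       baselines = c(het = dh$baseline, hom = do_$baseline),
       calls = calls, cnvs = cnvs)
}

#' Write CNV calls as BED-like TSV
#'
#' 0-based half-open coordinates, one row per call with copy-number columns.
#'
#' @param cnvs data.frame from [quantify_cnvs()].
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_cnv_bed <- function(cnvs, path) {
  df <- data.frame(chrom = "ref", chromStart = cnvs$start, chromEnd = cnvs$end,
                   name = sprintf("CNV%d", seq_len(nrow(cnvs))),
                   total_copies_het = cnvs$total_copies_het,
                   total_copies_hom = cnvs$total_copies_hom,
                   extra_dna_het = cnvs$extra_dna_het)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
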