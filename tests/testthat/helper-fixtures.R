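# Shared fixture builders: small deterministic configurations used across
# test files. Everything is generated in code; no data files.

# minimal chromosome with one multicopy locus carrying the tandem unit
locus_fixture <- function(chrom_len = 2e5, insert_at = 1e5,
                          unit_length = 630L,
                          counts_wt = 1L, counts_re = 7L,
                          flank = 1200L, stop_fraction = 0,
                          seed = 101L, ...) {
  cfg <- sim_config(chrom_len,
                    locus = locus_spec(insert_at = insert_at,
                                       flank_left_len = flank,
                                       flank_right_len = flank,
                                       unit_length = unit_length,
                                       unit_counts_wildtype = counts_wt,
                                       unit_counts_rearranged = counts_re,
                                       stop_fraction = stop_fraction, ...),
                    seed = seed)
  build_haplotypes(cfg)
}

# spanning long reads covering every locus copy of one haplotype
spanning_reads <- function(sim, haplotype = "rearranged", pad = 150L,
                           seed = 5L) {
  lt <- sim$truth$locus
  counts <- if (haplotype == "wildtype") lt$unit_counts_wildtype
            else lt$unit_counts_rearranged
  feat <- sim$hap$features[[haplotype]]
  lf <- feat[feat$label == "locus", , drop = FALSE]
  lens <- lt$flank_left_len + counts * lt$unit_length + lt$flank_right_len
  ends <- lf$start + cumsum(lens)
  simulate_long_reads(sim$hap, "S/M", coverage = 0,
                      spanning = data.frame(hap = haplotype,
                                            start = ends - lens, end = ends,
                                            pad = pad),
                      seed = seed)
}

locus_flanks <- function(sim) {
  lt <- sim$truth$locus
  ref <- sim$hap$reference
  list(left = substr(ref, lt$insert_at - lt$flank_left_len + 1L, lt$insert_at),
       right = substr(ref, lt$insert_at + 1L, lt$insert_at + lt$flank_right_len))
}

# independent brute-force implementation of the greedy hit-acceptance rule,
# used as an oracle for dedupe_hits(): per-position overlap bookkeeping on a
# coverage vector instead of interval arithmetic
brute_force_dedupe <- function(hits, max_overlap = 0.8) {
  if (nrow(hits) == 0L) return(hits)
  ord <- order(-hits$length, hits$read_start, hits$query_id)
  h <- hits[ord, , drop = FALSE]
  span <- max(h$read_end) + 1L
  covered <- rep(FALSE, span)
  keep <- logical(nrow(h))
  for (i in seq_len(nrow(h))) {
    pos <- (h$read_start[i] + 1L):h$read_end[i]
    if (sum(covered[pos]) >= max_overlap * h$length[i]) next
    keep[i] <- TRUE
    covered[pos] <- TRUE
  }
  h[keep, , drop = FALSE]
}

# random hit set on one read for the dedupe oracle comparison
random_hits <- function(n, read_len = 5000L) {
  start <- sample.int(read_len - 300L, n, replace = TRUE)
  len <- sample(20:800, n, replace = TRUE)
  end <- pmin(start + len, read_len)
  data.frame(query_id = sample(c("q1", "q2", "q3"), n, replace = TRUE),
             read_start = start, read_end = end, length = end - start,
             identity = 1, orientation = "+")
}
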