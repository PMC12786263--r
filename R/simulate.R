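# Synthetic-data generator: diploid haplotype pairs carrying a paracentric
# inversion, amplified copy-number blocks and a multicopy locus with a nested
# tandem repeat unit, plus short/long read simulators and fixture I/O.
#
# The generator is first-class, tested code: every downstream module is
# validated against the truth tables it emits.

#' Describe one copy-number block for the simulator
#'
#' A block is a tandem array of a unit sequence present in different copy
#' numbers on the wild-type and rearranged haplotypes. A *collapsed* block
#' takes its unit from an interval of the background chromosome and is
#' represented exactly once in the mapping reference (the classic collapsed
#' repeat, causing elevated read depth). A *novel* block uses a randomly
#' drawn unit inserted at a given position and is absent from the reference.
#'
#' @param id block identifier (e.g. `"CNV7"`).
#' @param copies_wildtype,copies_rearranged integer tandem copy number per
#'   haplotype (>= 0; 0 means the block is deleted on that haplotype).
#' @param ref_start,ref_end 0-based half-open interval on the background
#'   chromosome supplying the unit (collapsed blocks only).
#' @param novel_at insertion position on the background chromosome (novel
#'   blocks only).
#' @param unit_length unit length in bp (novel blocks only; collapsed blocks
#'   take `ref_end - ref_start`).
#' @param tandem logical; only head-to-tail tandem organisation is supported.
#' @return a `cnv_block` list.
#' @export
cnv_block <- function(id, copies_wildtype, copies_rearranged,
                      ref_start = NULL, ref_end = NULL,
                      novel_at = NULL, unit_length = NULL,
                      tandem = TRUE) {
  novel <- !is.null(novel_at)
  if (novel) {
    stopifnot(!is.null(unit_length), unit_length >= 1)
  } else {
    stopifnot(!is.null(ref_start), !is.null(ref_end))
  }
  if (!isTRUE(tandem)) {
    stop("only tandem (head-to-tail) block organisation is supported")
  }
  stopifnot(copies_wildtype >= 0, copies_rearranged >= 0)
  structure(list(id = as.character(id),
                 novel = novel,
                 ref_start = ref_start, ref_end = ref_end,
                 novel_at = novel_at,
                 unit_length = if (novel) as.integer(unit_length)
                               else as.integer(ref_end - ref_start),
                 copies_wildtype = as.integer(copies_wildtype),
                 copies_rearranged = as.integer(copies_rearranged),
                 tandem = TRUE),
            class = "cnv_block")
}

#' Describe the multicopy locus carrying a nested tandem repeat unit
#'
#' The locus models a gene-bearing segment that is itself multicopy and whose
#' copies each contain a variable-length head-to-tail array of a short unit.
#' Each locus copy is `flank_left + unit x k + flank_right`, where the flanks
#' are the background sequence adjacent to the insertion point (so they are
#' present, once, in the mapping reference, while the unit array is not).
#' A coding exon ("exon 2") lies in the left flank and can carry a planted
#' premature stop codon; a second exon ("exon 3") is embedded in the unit.
#'
#' @param insert_at 0-based insertion position on the background chromosome.
#' @param flank_left_len,flank_right_len flank lengths in bp.
#' @param unit_length repeat unit length in bp (default 630).
#' @param unit_counts_wildtype,unit_counts_rearranged integer vector of
#'   units per locus copy; its length is the locus copy number on that
#'   haplotype.
#' @param exon2 0-based half-open interval of exon 2 *within the left
#'   flank*; its reading frame starts at `exon2[1]`.
#' @param exon3 0-based half-open interval of exon 3 *within the unit*.
#' @param stop_fraction fraction (0..1) of rearranged-haplotype locus copies
#'   carrying a planted in-frame TAA in exon 2. The planted count is
#'   `round(stop_fraction * copies)`, chosen at seeded random positions, so
#'   a fraction of 0.40 over 100 copies plants exactly 40 stops.
#' @param divergent_first_unit logical; if `TRUE`, the first unit of every
#'   array is diverged by ~2% substitutions placed outside exon 3.
#' @return a `locus_spec` list.
#' @export
locus_spec <- function(insert_at, flank_left_len = 2000L, flank_right_len = 2000L,
                       unit_length = 630L,
                       unit_counts_wildtype = 20L,
                       unit_counts_rearranged = 400L,
                       exon2 = c(300L, 600L),
                       exon3 = c(200L, 424L),
                       stop_fraction = 0,
                       divergent_first_unit = FALSE) {
  stopifnot(stop_fraction >= 0, stop_fraction <= 1,
            all(unit_counts_wildtype >= 0), all(unit_counts_rearranged >= 0))
  check_interval(exon2[1], exon2[2], flank_left_len, "exon2 (within left flank)")
  check_interval(exon3[1], exon3[2], unit_length, "exon3 (within unit)")
  structure(list(insert_at = as.integer(insert_at),
                 flank_left_len = as.integer(flank_left_len),
                 flank_right_len = as.integer(flank_right_len),
                 unit_length = as.integer(unit_length),
                 unit_counts_wildtype = as.integer(unit_counts_wildtype),
                 unit_counts_rearranged = as.integer(unit_counts_rearranged),
                 exon2 = as.integer(exon2), exon3 = as.integer(exon3),
                 stop_fraction = stop_fraction,
                 divergent_first_unit = isTRUE(divergent_first_unit)),
            class = "locus_spec")
}

#' Simulation configuration
#'
#' Collects everything the haplotype builder needs: chromosome length, an
#' optional paracentric inversion, copy-number blocks, an optional multicopy
#' locus, and the master seed. The same configuration and seed always yield
#' byte-identical outputs.
#'
#' @param chromosome_length background chromosome length in bp.
#' @param inversion `c(start, end)` 0-based half-open, or `NULL`. The
#'   inversion is applied to the rearranged haplotype only and must not
#'   overlap any block or the locus.
#' @param cnv_blocks list of [cnv_block()] objects.
#' @param locus a [locus_spec()] or `NULL`.
#' @param seed integer master seed.
#' @return a `sim_config` list.
#' @export
sim_config <- function(chromosome_length, inversion = NULL,
                       cnv_blocks = list(), locus = NULL, seed = 1L) {
  stopifnot(chromosome_length >= 1)
  if (!is.null(inversion)) {
    check_interval(inversion[1], inversion[2], chromosome_length, "inversion")
  }
  if (length(cnv_blocks) && inherits(cnv_blocks, "cnv_block")) {
    cnv_blocks <- list(cnv_blocks)
  }
  structure(list(chromosome_length = as.numeric(chromosome_length),
                 inversion = if (is.null(inversion)) NULL else as.numeric(inversion),
                 cnv_blocks = cnv_blocks, locus = locus,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# footprint of each planted element on the background chromosome, used for
# overlap validation and right-to-left editing
.config_footprints <- function(config) {
  fp <- list()
  for (b in config$cnv_blocks) {
    fp[[length(fp) + 1L]] <- list(id = b$id, type = "block",
                                  start = if (b$novel) b$novel_at else b$ref_start,
                                  end = if (b$novel) b$novel_at else b$ref_end,
                                  block = b)
  }
  if (!is.null(config$locus)) {
    ls <- config$locus
    fp[[length(fp) + 1L]] <- list(id = "locus", type = "locus",
                                  start = ls$insert_at - ls$flank_left_len,
                                  end = ls$insert_at + ls$flank_right_len,
                                  locus = ls)
  }
  fp
}

.validate_config <- function(config) {
  L <- config$chromosome_length
  fp <- .config_footprints(config)
  iv <- lapply(fp, function(f) {
    check_interval(f$start, f$end, L, paste0("planted element '", f$id, "'"),
                   allow_empty = TRUE)
    c(f$start, f$end)
  })
  if (length(iv) > 1L) {
    m <- do.call(rbind, iv)
    o <- order(m[, 1L])
    m <- m[o, , drop = FALSE]
    if (any(m[-1L, 1L] < m[-nrow(m), 2L])) {
      stop("planted intervals overlap: configuration error", call. = FALSE)
    }
  }
  if (!is.null(config$inversion) && length(iv)) {
    for (j in seq_along(iv)) {
      if (config$inversion[1] < iv[[j]][2] && iv[[j]][1] < config$inversion[2]) {
        stop("inversion overlaps planted element '", fp[[j]]$id,
             "': configuration error", call. = FALSE)
      }
    }
  }
  invisible(TRUE)
}

# remove in-frame stop codons from a coding stretch by recoding the first
# base of each offending codon (T -> C keeps composition near-uniform)
.sanitize_stops <- function(seq, start0, end0) {
  n <- (end0 - start0) %/% 3L
  if (n < 1L) return(seq)
  for (i in seq_len(n)) {
    a <- start0 + (i - 1L) * 3L + 1L   # 1-based codon start
    cod <- substr(seq, a, a + 2L)
    if (cod %in% c("TAA", "TAG", "TGA")) {
      substr(seq, a, a) <- "C"
    }
  }
  seq
}

#' Build a wild-type/rearranged haplotype pair plus mapping reference
#'
#' Constructs three sequences from a [sim_config()]: the wild-type haplotype,
#' the rearranged haplotype (inversion applied, blocks/locus at their
#' rearranged copy numbers) and the mapping reference, in which collapsed
#' blocks appear exactly once and novel blocks (and the locus unit array)
#' are absent. A truth table records every planted quantity.
#'
#' @param config a [sim_config()].
#' @return list with components `hap` (class `hap_pair`: `wildtype`,
#'   `rearranged`, `reference`, `features`) and `truth` (class
#'   `truth_table`: `blocks` data.frame, `locus` list or `NULL`,
#'   `inversion`, `unit_sequences`).
#' @export
build_haplotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  .validate_config(config)
  with_seed(config$seed, .build_haplotypes_impl(config))
}

.build_haplotypes_impl <- function(config) {
  L <- as.integer(config$chromosome_length)
  bg <- random_dna(L)
  units <- list()
  locus_truth <- NULL

  # pre-draw locus pieces so exon regions can be sanitised once
  if (!is.null(config$locus)) {
    ls <- config$locus
    unit <- random_dna(ls$unit_length)
    # keep exon 3 (inside unit) free of in-frame stops
    unit <- .sanitize_stops(unit, ls$exon3[1], ls$exon3[2])
    # keep exon 2 (inside left flank, i.e. background) free of stops
    fl_start <- ls$insert_at - ls$flank_left_len        # 0-based
    e2 <- fl_start + ls$exon2                            # exon2 on background
    bg <- .sanitize_stops(bg, e2[1], e2[2])
    units[["locus_unit"]] <- unit
    divergent_unit <- NULL
    if (ls$divergent_first_unit) {
      divergent_unit <- .diverge_outside(unit, ls$exon3, rate = 0.02)
    }
    n_wt <- length(ls$unit_counts_wildtype)
    n_re <- length(ls$unit_counts_rearranged)
    # exact-count stop planting on each haplotype's locus copies
    plant <- function(n) {
      k <- round(ls$stop_fraction * n)
      flags <- rep(FALSE, n)
      if (k > 0) flags[sample.int(n, k)] <- TRUE
      flags
    }
    locus_truth <- list(insert_at = ls$insert_at,
                        flank_left_len = ls$flank_left_len,
                        flank_right_len = ls$flank_right_len,
                        unit = unit,
                        unit_length = ls$unit_length,
                        divergent_unit = divergent_unit,
                        unit_counts_wildtype = ls$unit_counts_wildtype,
                        unit_counts_rearranged = ls$unit_counts_rearranged,
                        exon2 = ls$exon2, exon3 = ls$exon3,
                        stop_fraction = ls$stop_fraction,
                        stop_flags_wildtype = plant(n_wt),
                        stop_flags_rearranged = plant(n_re))
  }
  for (b in config$cnv_blocks) {
    units[[b$id]] <- if (b$novel) random_dna(b$unit_length)
                     else substr(bg, b$ref_start + 1L, b$ref_end)
  }

  # assemble one haplotype by editing background right-to-left
  assemble <- function(which_hap) {
    fp <- .config_footprints(config)
    if (length(fp) == 0L) return(list(seq = bg, feat = NULL))
    ord <- order(vapply(fp, `[[`, numeric(1), "start"), decreasing = TRUE)
    seqv <- bg
    feats <- list()
    for (f in fp[ord]) {
      if (f$type == "block") {
        b <- f$block
        copies <- if (which_hap == "wildtype") b$copies_wildtype else b$copies_rearranged
        ins <- strrep(units[[b$id]], copies)
        seqv <- paste0(substr(seqv, 1L, f$start),
                       ins,
                       substr(seqv, f$end + 1L, nchar(seqv)))
        feats[[length(feats) + 1L]] <- data.frame(
          id = b$id, start = f$start, end = f$start + nchar(ins),
          label = "cnv_block", copies = copies)
      } else {
        ls <- f$locus
        counts <- if (which_hap == "wildtype") ls$unit_counts_wildtype
                  else ls$unit_counts_rearranged
        stops <- if (which_hap == "wildtype") locus_truth$stop_flags_wildtype
                 else locus_truth$stop_flags_rearranged
        flankL <- substr(bg, f$start + 1L, ls$insert_at)
        flankR <- substr(bg, ls$insert_at + 1L, f$end)
        copies <- vapply(seq_along(counts), function(i) {
          fl <- flankL
          if (stops[i]) {
            # replace the second in-frame codon of exon 2 with TAA
            a <- ls$exon2[1] + 3L + 1L
            substr(fl, a, a + 2L) <- "TAA"
          }
          k <- counts[i]
          arr <- if (k == 0L) "" else if (!is.null(locus_truth$divergent_unit) && k >= 1L) {
            paste0(locus_truth$divergent_unit, strrep(locus_truth$unit, k - 1L))
          } else strrep(locus_truth$unit, k)
          paste0(fl, arr, flankR)
        }, character(1))
        ins <- paste0(copies, collapse = "")
        seqv <- paste0(substr(seqv, 1L, f$start),
                       ins,
                       substr(seqv, f$end + 1L, nchar(seqv)))
        feats[[length(feats) + 1L]] <- data.frame(
          id = "locus", start = f$start, end = f$start + nchar(ins),
          label = "locus", copies = length(counts))
      }
    }
    list(seq = seqv, feat = do.call(rbind, feats))
  }

  wt <- assemble("wildtype")
  re <- assemble("rearranged")

  # mapping reference: collapsed blocks once (the background already holds
  # one copy), novel blocks and the locus unit array absent -> reference is
  # the untouched background
  reference <- bg

  rearranged <- re$seq
  if (!is.null(config$inversion)) {
    # inversion coordinates are given on the background; translate to the
    # rearranged haplotype by the length offsets of elements to its left
    inv <- config$inversion
    shift <- 0
    for (f in .config_footprints(config)) {
      if (f$end <= inv[1]) {
        planted_len <- if (f$type == "block") {
          f$block$unit_length * f$block$copies_rearranged
        } else {
          ls <- f$locus
          sum(ls$unit_counts_rearranged) * ls$unit_length +
            length(ls$unit_counts_rearranged) * (ls$flank_left_len + ls$flank_right_len)
        }
        shift <- shift + planted_len - (f$end - f$start)
      }
    }
    a <- inv[1] + shift
    b <- inv[2] + shift
    seg <- substr(rearranged, a + 1L, b)
    rearranged <- paste0(substr(rearranged, 1L, a),
                         revcomp(seg),
                         substr(rearranged, b + 1L, nchar(rearranged)))
  }

  blocks_df <- if (length(config$cnv_blocks)) {
    do.call(rbind, lapply(config$cnv_blocks, function(b) {
      data.frame(id = b$id, novel = b$novel,
                 ref_start = if (b$novel) NA_real_ else b$ref_start,
                 ref_end = if (b$novel) NA_real_ else b$ref_end,
                 unit_length = b$unit_length,
                 copies_wildtype = b$copies_wildtype,
                 copies_rearranged = b$copies_rearranged)
    }))
  } else {
    data.frame(id = character(0), novel = logical(0),
               ref_start = numeric(0), ref_end = numeric(0),
               unit_length = integer(0),
               copies_wildtype = integer(0), copies_rearranged = integer(0))
  }

  hap <- structure(list(wildtype = wt$seq,
                        rearranged = rearranged,
                        reference = reference,
                        features = list(wildtype = wt$feat, rearranged = re$feat)),
                   class = "hap_pair")
  truth <- structure(list(blocks = blocks_df,
                          locus = locus_truth,
                          inversion = config$inversion,
                          unit_sequences = units,
                          config = config),
                     class = "truth_table")
  list(hap = hap, truth = truth)
}

# substitute bases at rate `rate`, never inside [protect[1], protect[2])
.diverge_outside <- function(unit, protect, rate = 0.02) {
  n <- nchar(unit)
  pos <- setdiff(seq_len(n), (protect[1] + 1L):protect[2])
  hit <- pos[stats::runif(length(pos)) < rate]
  if (!length(hit)) hit <- pos[1L]  # guarantee at least one difference
  ch <- strsplit(unit, "", fixed = TRUE)[[1L]]
  alt <- c(A = "G", C = "T", G = "A", T = "C")
  ch[hit] <- alt[ch[hit]]
  paste0(ch, collapse = "")
}

#' Extract individual locus copy sequences from a haplotype pair
#'
#' Returns one sequence per locus copy (flank + unit array + flank) for the
#' requested haplotype, together with the planted stop flags — the ground
#' truth consumed by [screen_stop_codons()] recovery tests.
#'
#' @param sim result of [build_haplotypes()].
#' @param haplotype `"wildtype"` or `"rearranged"`.
#' @return list with `copies` (character vector) and `stop_flags` (logical).
#' @export
locus_copies <- function(sim, haplotype = c("rearranged", "wildtype")) {
  haplotype <- match.arg(haplotype)
  lt <- sim$truth$locus
  if (is.null(lt)) stop("configuration has no locus")
  counts <- if (haplotype == "wildtype") lt$unit_counts_wildtype
            else lt$unit_counts_rearranged
  feat <- sim$hap$features[[haplotype]]
  lf <- feat[feat$label == "locus", , drop = FALSE]
  seqv <- sim$hap[[haplotype]]
  lens <- lt$flank_left_len + counts * lt$unit_length + lt$flank_right_len
  ends <- lf$start + cumsum(lens)
  starts <- ends - lens
  copies <- substring(seqv, starts + 1L, ends)
  flags <- if (haplotype == "wildtype") lt$stop_flags_wildtype
           else lt$stop_flags_rearranged
  list(copies = copies, stop_flags = flags, unit_counts = counts)
}

.hap_for_genotype <- function(hap, genotype) {
  switch(genotype,
         "S/S" = c(hap$wildtype, hap$wildtype),
         "S/M" = c(hap$wildtype, hap$rearranged),
         stop("genotype must be 'S/S' or 'S/M'"))
}

#' Simulate paired short reads (whole-genome or proximity-ligation mode)
#'
#' Error-free 150 bp-style paired reads. In WGS mode, mate 2 is the reverse
#' complement of the opposite fragment end at a fixed insert size. In
#' ligation mode, mate 2 starts at a distance `d` from mate 1 drawn from a
#' truncated power law `P(d) ~ d^-decay_exponent`, emulating proximity-
#' ligation contact decay. Heterozygotes contribute a deterministic
#' length-proportional share of pairs from each haplotype (both homologs are
#' present once per cell), which makes depth expectations exact.
#'
#' @param hap a `hap_pair` from [build_haplotypes()].
#' @param genotype `"S/S"` (homozygote) or `"S/M"` (heterozygote).
#' @param coverage fold coverage (>= 0). The pair count is
#'   `floor(coverage * genome_len / (2 * read_len))` with `genome_len` the
#'   mean haplotype length.
#' @param read_len read length in bp.
#' @param mode `"WGS"` or `"ligation"`.
#' @param insert_size WGS fragment length (bp).
#' @param decay_exponent ligation-mode decay exponent (distance law
#'   `P(d) ~ d^-decay_exponent`, truncated to the chromosome).
#' @param min_dist minimum ligation distance (bp).
#' @param error_rate optional uniform substitution rate (default 0,
#'   error-free).
#' @param seed integer seed.
#' @return a `read_set`: list with `mode`, `read_len` and `reads`
#'   data.frame (`pair_id`, `mate`, `id`, `seq`, `hap`, `src_start`).
#' @export
simulate_short_reads <- function(hap, genotype = c("S/S", "S/M"),
                                 coverage, read_len = 150L,
                                 mode = c("WGS", "ligation"),
                                 insert_size = 450L,
                                 decay_exponent = 1,
                                 min_dist = 1000L,
                                 error_rate = 0,
                                 seed = 1L) {
  genotype <- match.arg(genotype)
  mode <- match.arg(mode)
  stopifnot(coverage >= 0)
  haps <- .hap_for_genotype(hap, genotype)
  hlen <- nchar(haps)
  if (any(read_len > hlen)) stop("read_len exceeds haplotype length")
  genome_len <- mean(hlen)
  n_pairs <- floor(coverage * genome_len / (2 * read_len))
  empty <- data.frame(pair_id = integer(0), mate = integer(0),
                      hap = character(0), src_start = numeric(0),
                      offset = numeric(0), len = integer(0))
  if (n_pairs == 0) {
    return(structure(list(mode = mode, read_len = as.integer(read_len),
                          genotype = genotype, blob = "", reads = empty),
                     class = "read_set"))
  }
  hap_names <- if (genotype == "S/S") c("wildtype", "wildtype")
               else c("wildtype", "rearranged")
  # deterministic length-proportional split between the two haplotypes: both
  # homologs are present once per cell, so per-bp depth must be equal even
  # when the rearranged haplotype is much longer
  n1 <- round(n_pairs * hlen[1] / sum(hlen))
  hap_idx <- rep(1:2, c(n1, n_pairs - n1))

  with_seed(seed, {
    if (mode == "WGS") {
      frag <- max(insert_size, 2L * read_len)
      maxstart <- hlen[hap_idx] - frag
      p1 <- floor(stats::runif(n_pairs) * (maxstart + 1))
      s2 <- p1 + frag - read_len
    } else {
      dmax <- hlen[hap_idx] - read_len - min_dist
      u <- stats::runif(n_pairs)
      d <- if (abs(decay_exponent - 1) < 1e-12) {
        min_dist * exp(u * log(dmax / min_dist))
      } else {
        a <- 1 - decay_exponent
        (min_dist^a + u * (dmax^a - min_dist^a))^(1 / a)
      }
      d <- floor(d)
      p1 <- floor(stats::runif(n_pairs) * (hlen[hap_idx] - read_len - d + 1))
      s2 <- p1 + d
    }
    rl <- as.integer(read_len)
    lens <- rep.int(rl, n_pairs)
    # reads live in one concatenated blob (mate-1 block, then mate-2 block):
    # slicing happens in compiled code, keeping millions of reads cheap
    blob1 <- cpp_extract_concat(haps[1L], haps[2L], hap_idx,
                                as.integer(p1), lens, FALSE)
    blob2 <- cpp_extract_concat(haps[1L], haps[2L], hap_idx,
                                as.integer(s2), lens, TRUE)
    blob <- paste0(blob1, blob2)
    if (error_rate > 0) blob <- .mutate_blob(blob, error_rate)
    reads <- data.frame(
      pair_id = rep(seq_len(n_pairs), 2L),
      mate = rep(1:2, each = n_pairs),
      hap = rep(hap_names[hap_idx], 2L),
      src_start = c(p1, s2),
      offset = (seq_len(2L * n_pairs) - 1) * as.numeric(rl),
      len = rl)
    structure(list(mode = mode, read_len = rl,
                   genotype = genotype, blob = blob, reads = reads),
              class = "read_set")
  })
}

# uniform substitutions over a concatenated read blob
.mutate_blob <- function(blob, rate) {
  raw <- charToRaw(blob)
  hit <- which(stats::runif(length(raw)) < rate)
  if (length(hit)) {
    alt <- chartr("ACGT", "GTAC", rawToChar(raw[hit]))
    raw[hit] <- charToRaw(alt)
  }
  rawToChar(raw)
}

#' Read sequences of a read set as a character vector
#'
#' Materialises individual read strings from a `read_set` (short-read sets
#' store their sequences in one concatenated blob for speed).
#'
#' @param x a `read_set`.
#' @param i optional row indices into `x$reads`.
#' @return character vector of read sequences.
#' @export
read_seqs <- function(x, i = NULL) {
  stopifnot(inherits(x, "read_set"))
  r <- x$reads
  if (!is.null(i)) r <- r[i, , drop = FALSE]
  if (!is.null(r$seq)) return(r$seq)
  if (nrow(r) == 0L) return(character(0))
  substring(x$blob, r$offset + 1L, r$offset + r$len)
}

#' Read identifiers of a read set
#'
#' @param x a `read_set`.
#' @return character vector (`p<pair>/<mate>` for paired sets).
#' @export
read_ids <- function(x) {
  r <- x$reads
  if (!is.null(r$id)) return(r$id)
  paste0("p", r$pair_id, "/", r$mate)
}

#' Simulate long reads
#'
#' Error-free long reads with exponential-tailed lengths
#' (`min_len + Exp(mean_len - min_len)`), drawn until the base total reaches
#' `coverage * genome_len` (the last read is trimmed so the total stays
#' within 2% of the target). Optionally, guaranteed spanning reads covering
#' given truth intervals (e.g. whole locus copies) are appended, mirroring
#' the deliberate selection of reads that span both flanks of a tandem
#' array.
#'
#' @param hap a `hap_pair`.
#' @param genotype `"S/S"` or `"S/M"`.
#' @param coverage fold coverage (>= 0).
#' @param mean_len,min_len length law parameters (bp), `mean_len >= min_len > 0`.
#' @param spanning optional data.frame (`hap`, `start`, `end`, optional
#'   `pad`) of intervals each of which must be covered by one read.
#' @param seed integer seed.
#' @return a `read_set` with `reads` data.frame (`id`, `seq`, `hap`,
#'   `src_start`, `src_end`).
#' @export
simulate_long_reads <- function(hap, genotype = c("S/M", "S/S"),
                                coverage, mean_len = 15000L, min_len = 1000L,
                                spanning = NULL, seed = 1L) {
  genotype <- match.arg(genotype)
  stopifnot(mean_len >= min_len, min_len > 0, coverage >= 0)
  haps <- .hap_for_genotype(hap, genotype)
  hap_names <- if (genotype == "S/S") c("wildtype", "wildtype")
               else c("wildtype", "rearranged")
  hlen <- nchar(haps)
  target <- coverage * mean(hlen)
  with_seed(seed, {
    lens <- integer(0); srcs <- integer(0)
    if (target > 0) {
      n_guess <- max(16L, ceiling(1.3 * target / mean_len))
      repeat {
        lens <- c(lens, pmin(floor(min_len + stats::rexp(n_guess, 1 / (mean_len - min_len + 1))),
                             min(hlen)))
        if (sum(lens) >= target) break
      }
      cum <- cumsum(as.numeric(lens))
      nkeep <- which(cum >= target)[1L]
      lens <- lens[seq_len(nkeep)]
      over <- sum(lens) - target
      lens[nkeep] <- max(min_len, lens[nkeep] - floor(over))
      srcs <- sample.int(2L, length(lens), replace = TRUE)
    }
    starts <- if (length(lens)) floor(stats::runif(length(lens)) * (hlen[srcs] - lens + 1)) else integer(0)
    seqs <- if (length(lens)) substring(haps[srcs], starts + 1L, starts + lens) else character(0)
    reads <- data.frame(id = if (length(lens)) paste0("L", seq_along(lens)) else character(0),
                        seq = seqs,
                        hap = if (length(lens)) hap_names[srcs] else character(0),
                        src_start = as.numeric(starts),
                        src_end = as.numeric(starts + lens))
    if (!is.null(spanning) && nrow(spanning)) {
      pad <- if ("pad" %in% names(spanning)) spanning$pad else rep(500L, nrow(spanning))
      hi <- match(spanning$hap, hap_names)
      if (anyNA(hi)) stop("spanning$hap must name a haplotype present in this genotype")
      s <- pmax(0, spanning$start - pad)
      e <- pmin(hlen[hi], spanning$end + pad)
      reads <- rbind(reads, data.frame(
        id = paste0("SPAN", seq_len(nrow(spanning))),
        seq = substring(haps[hi], s + 1L, e),
        hap = spanning$hap, src_start = s, src_end = e))
    }
    structure(list(mode = "long", read_len = NA_integer_,
                   genotype = genotype, reads = reads),
              class = "read_set")
  })
}

#' Write simulation fixtures to disk
#'
#' Emits 2-line FASTA for the haplotypes and reference, 4-line FASTQ
#' (constant quality `I`) for reads, and JSON for the truth table and a
#' config echo. Output bytes are deterministic given the seed.
#'
#' @param sim result of [build_haplotypes()].
#' @param reads a `read_set` (or `NULL`).
#' @param outdir output directory (created if needed).
#' @return invisibly, a named character vector of paths written.
#' @export
write_fixtures <- function(sim, reads = NULL, outdir) {
  if (!dir.exists(outdir)) {
    ok <- dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(outdir)) stop("cannot create output directory: ", outdir)
  }
  paths <- c()
  wf <- function(lines, fname) {
    p <- file.path(outdir, fname)
    con <- file(p, open = "wb")  # binary mode => byte-deterministic newlines
    on.exit(close(con))
    writeLines(lines, con, sep = "\n")
    p
  }
  hap <- sim$hap
  paths["haplotypes"] <- wf(c(">wildtype", hap$wildtype,
                              ">rearranged", hap$rearranged), "haplotypes.fa")
  paths["reference"] <- wf(c(">reference", hap$reference), "reference.fa")
  if (!is.null(reads)) {
    seqs <- read_seqs(reads)
    if (length(seqs)) {
      qual <- strrep("I", nchar(seqs))
      lines <- as.vector(rbind(paste0("@", read_ids(reads)), seqs, "+", qual))
    } else lines <- character(0)
    paths["reads"] <- wf(lines, "reads.fastq")
  }
  truth <- sim$truth
  tr <- list(blocks = truth$blocks,
             inversion = truth$inversion,
             locus = if (is.null(truth$locus)) NULL else
               truth$locus[c("insert_at", "flank_left_len", "flank_right_len",
                             "unit", "unit_length", "unit_counts_wildtype",
                             "unit_counts_rearranged", "exon2", "exon3",
                             "stop_fraction", "stop_flags_wildtype",
                             "stop_flags_rearranged")])
  pj <- file.path(outdir, "truth.json")
  jsonlite::write_json(tr, pj, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  paths["truth"] <- pj
  cfgj <- file.path(outdir, "config.json")
  cfg <- sim$truth$config
  jsonlite::write_json(list(chromosome_length = cfg$chromosome_length,
                            inversion = cfg$inversion,
                            seed = cfg$seed,
                            n_blocks = length(cfg$cnv_blocks),
                            has_locus = !is.null(cfg$locus)),
                       cfgj, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  paths["config"] <- cfgj
  invisible(paths)
}

#' Read fixtures back from disk
#'
#' Round-trip companion to [write_fixtures()].
#'
#' @param outdir directory written by [write_fixtures()].
#' @return list with `haplotypes` (named character), `reference`
#'   (character), `reads` (data.frame `id`, `seq`; `NULL` if absent) and
#'   `truth` (parsed JSON).
#' @export
read_fixtures <- function(outdir) {
  fa <- Biostrings::readDNAStringSet(file.path(outdir, "haplotypes.fa"))
  ref <- Biostrings::readDNAStringSet(file.path(outdir, "reference.fa"))
  fq_path <- file.path(outdir, "reads.fastq")
  reads <- NULL
  if (file.exists(fq_path) && file.size(fq_path) > 0) {
    fq <- Biostrings::readDNAStringSet(fq_path, format = "fastq")
    reads <- data.frame(id = names(fq), seq = as.character(fq))
  } else if (file.exists(fq_path)) {
    reads <- data.frame(id = character(0), seq = character(0))
  }
  truth <- jsonlite::read_json(file.path(outdir, "truth.json"),
                               simplifyVector = TRUE)
  list(haplotypes = stats::setNames(as.character(fa), names(fa)),
       reference = as.character(ref)[[1L]],
       reads = reads, truth = truth)
}

#' @export
print.hap_pair <- function(x, ...) {
  w <- format(c(nchar(x$wildtype), nchar(x$rearranged), nchar(x$reference)),
              big.mark = ",", width = 12)
  cat("Haplotype pair:\n",
      "  wildtype   ", w[1], " bp\n",
      "  rearranged ", w[2], " bp\n",
      "  reference  ", w[3], " bp\n", sep = "")
  invisible(x)
}

#' @export
print.truth_table <- function(x, ...) {
  cat("Truth table:", nrow(x$blocks), "CNV block(s);",
      if (is.null(x$locus)) "no locus;" else
        sprintf("locus with %d/%d copies;",
                length(x$locus$unit_counts_wildtype),
                length(x$locus$unit_counts_rearranged)),
      if (is.null(x$inversion)) "no inversion\n" else
        sprintf("inversion [%s, %s)\n",
                format(x$inversion[1], scientific = FALSE, big.mark = ","),
                format(x$inversion[2], scientific = FALSE, big.mark = ",")))
  invisible(x)
}
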