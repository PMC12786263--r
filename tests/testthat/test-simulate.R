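# Haplotype construction, read simulation and fixture round-trips.

test_that("a configuration with no planted elements is the identity", {
  sim <- build_haplotypes(sim_config(5000, seed = 1))
  expect_identical(sim$hap$wildtype, sim$hap$rearranged)
  expect_identical(sim$hap$wildtype, sim$hap$reference)
  expect_equal(nrow(sim$truth$blocks), 0L)
})

test_that("planted inversion breakpoints echo the configuration exactly", {
  cfg <- sim_config(7e6, inversion = c(350000, 5687300), seed = 2)
  sim <- build_haplotypes(cfg)
  expect_equal(sim$truth$inversion, c(350000, 5687300))
  # length-neutral; inverted segment is the reverse complement
  expect_equal(nchar(sim$hap$rearranged), nchar(sim$hap$wildtype))
  seg_wt <- substr(sim$hap$wildtype, 350001, 5687300)
  seg_re <- substr(sim$hap$rearranged, 350001, 5687300)
  expect_identical(seg_re, revcomp(seg_wt))
  # outside the inversion the haplotypes agree
  expect_identical(substr(sim$hap$wildtype, 1, 350000),
                   substr(sim$hap$rearranged, 1, 350000))
})

test_that("length bookkeeping: one 630 bp block at 20 vs 400 copies adds 239,400 bp", {
  cfg <- sim_config(1e5,
                    cnv_blocks = list(cnv_block("CNV8", 20, 400,
                                                novel_at = 5e4,
                                                unit_length = 630)),
                    seed = 3)
  sim <- build_haplotypes(cfg)
  expect_equal(nchar(sim$hap$rearranged) - nchar(sim$hap$wildtype),
               630 * (400 - 20))
  # novel block absent from the reference
  expect_false(grepl(sim$truth$unit_sequences$CNV8, sim$hap$reference, fixed = TRUE))
  expect_true(grepl(sim$truth$unit_sequences$CNV8, sim$hap$wildtype, fixed = TRUE))
})

test_that("collapsed blocks appear exactly once in the reference", {
  cfg <- sim_config(5e4,
                    cnv_blocks = list(cnv_block("CNV7", 3, 20,
                                                ref_start = 2e4, ref_end = 25e3)),
                    seed = 4)
  sim <- build_haplotypes(cfg)
  unit <- sim$truth$unit_sequences$CNV7
  n_occ <- length(gregexpr(unit, sim$hap$reference, fixed = TRUE)[[1L]])
  expect_equal(n_occ, 1L)
  expect_equal(nchar(sim$hap$wildtype) - nchar(sim$hap$reference), 2 * 5000)
})

test_that("length bookkeeping holds for random block configurations", {
  for (s in 1:8) {
    set.seed(s)
    n_blocks <- sample(1:3, 1)
    starts <- sort(sample(seq(5e3, 4e4, by = 5e3), n_blocks))
    blocks <- lapply(seq_len(n_blocks), function(i) {
      cnv_block(paste0("B", i),
                copies_wildtype = sample(0:5, 1),
                copies_rearranged = sample(0:50, 1),
                ref_start = starts[i], ref_end = starts[i] + sample(500:2000, 1))
    })
    cfg <- sim_config(5e4, cnv_blocks = blocks, seed = s)
    sim <- build_haplotypes(cfg)
    expected <- sum(vapply(blocks, function(b) {
      b$unit_length * (b$copies_rearranged - b$copies_wildtype)
    }, numeric(1)))
    expect_equal(nchar(sim$hap$rearranged) - nchar(sim$hap$wildtype), expected)
  }
})

test_that("overlapping planted intervals and block-overlapping inversions error", {
  b1 <- cnv_block("a", 1, 2, ref_start = 1000, ref_end = 3000)
  b2 <- cnv_block("b", 1, 2, ref_start = 2500, ref_end = 4000)
  expect_error(build_haplotypes(sim_config(1e4, cnv_blocks = list(b1, b2))),
               "overlap")
  expect_error(
    build_haplotypes(sim_config(1e4, inversion = c(500, 2000),
                                cnv_blocks = list(b1))),
    "inversion overlaps")
})

test_that("pair counts are exact and coverage 0 gives an empty read set", {
  sim <- build_haplotypes(sim_config(1e6, seed = 5))
  rs <- simulate_short_reads(sim$hap, "S/S", coverage = 30, read_len = 150,
                             seed = 6)
  expect_equal(nrow(rs$reads), 2 * 100000)   # floor(30e6 / 300) pairs
  empty <- simulate_short_reads(sim$hap, "S/S", coverage = 0, seed = 6)
  expect_equal(nrow(empty$reads), 0L)
  expect_error(simulate_short_reads(sim$hap, "S/S", coverage = 1,
                                    read_len = 2e6, seed = 1),
               "read_len")
})

test_that("identical seed gives byte-identical FASTQ; reads are haplotype substrings", {
  sim <- build_haplotypes(sim_config(3e4, seed = 7))
  rs1 <- simulate_short_reads(sim$hap, "S/M", coverage = 3, seed = 8)
  rs2 <- simulate_short_reads(sim$hap, "S/M", coverage = 3, seed = 8)
  d1 <- tempfile(); d2 <- tempfile()
  write_fixtures(sim, rs1, d1)
  write_fixtures(sim, rs2, d2)
  expect_identical(readBin(file.path(d1, "reads.fastq"), "raw", 1e6),
                   readBin(file.path(d2, "reads.fastq"), "raw", 1e6))
  # error-free contract: mate 1 forward, mate 2 reverse complement
  r <- rs1$reads
  seqs <- read_seqs(rs1)
  for (i in sample(nrow(r), 20)) {
    hap <- sim$hap[[r$hap[i]]]
    src <- substr(hap, r$src_start[i] + 1, r$src_start[i] + r$len[i])
    expect_identical(if (r$mate[i] == 1) seqs[i] else revcomp(seqs[i]), src)
  }
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("ligation-mode distances follow the configured power law", {
  sim <- build_haplotypes(sim_config(5e6, seed = 9))
  rs <- simulate_short_reads(sim$hap, "S/S", coverage = 12, mode = "ligation",
                             decay_exponent = 1, seed = 10)
  r <- rs$reads
  d <- abs(r$src_start[r$mate == 2] - r$src_start[r$mate == 1])
  expect_gte(length(d), 1e5)
  # log-log histogram slope of P(d) ~ d^-1
  br <- 10^seq(log10(1000), log10(4e6), length.out = 25)
  h <- hist(d[d >= 1000 & d <= 4e6], breaks = br, plot = FALSE)
  keep <- h$counts > 0
  fit <- stats::lm(log10(h$density[keep]) ~ log10(h$mids[keep]))
  expect_lt(abs(unname(stats::coef(fit)[2]) + 1), 0.1)
})

test_that("long reads hit the coverage target and are exact substrings", {
  sim <- build_haplotypes(sim_config(2e5, seed = 11))
  lr <- simulate_long_reads(sim$hap, "S/S", coverage = 5, mean_len = 8000,
                            min_len = 500, seed = 12)
  total <- sum(nchar(lr$reads$seq))
  expect_lt(abs(total - 5 * 2e5) / (5 * 2e5), 0.02)
  for (i in sample(nrow(lr$reads), 10)) {
    r <- lr$reads[i, ]
    expect_identical(r$seq,
                     substr(sim$hap[[r$hap]], r$src_start + 1, r$src_end))
  }
  expect_equal(nrow(simulate_long_reads(sim$hap, "S/S", coverage = 0,
                                        seed = 1)$reads), 0L)
})

test_that("guaranteed spanning reads cover the requested intervals", {
  sim <- locus_fixture(counts_re = c(1L, 35L), seed = 13)
  lr <- spanning_reads(sim)
  lt <- sim$truth$locus
  # the long copy spans flankL + 35 units + flankR
  expect_true(any(nchar(lr$reads$seq) >=
                    lt$flank_left_len + 35 * 630 + lt$flank_right_len))
  for (i in seq_len(nrow(lr$reads))) {
    r <- lr$reads[i, ]
    expect_identical(r$seq,
                     substr(sim$hap[[r$hap]], r$src_start + 1, r$src_end))
  }
})

test_that("fixtures round-trip through FASTA/FASTQ/JSON", {
  sim <- locus_fixture(counts_re = c(2L, 3L), stop_fraction = 0.5, seed = 14)
  rs <- simulate_short_reads(sim$hap, "S/M", coverage = 1, seed = 15)
  d <- tempfile()
  write_fixtures(sim, rs, d)
  back <- read_fixtures(d)
  expect_identical(back$haplotypes[["wildtype"]], sim$hap$wildtype)
  expect_identical(back$haplotypes[["rearranged"]], sim$hap$rearranged)
  expect_identical(back$reference, sim$hap$reference)
  expect_identical(back$reads$seq, read_seqs(rs))
  expect_equal(back$truth$locus$unit, sim$truth$locus$unit)
  expect_equal(back$truth$locus$unit_counts_rearranged,
               sim$truth$locus$unit_counts_rearranged)
  expect_equal(back$truth$locus$stop_flags_rearranged,
               sim$truth$locus$stop_flags_rearranged)
  # empty read set still yields a valid (empty) FASTQ
  d2 <- tempfile()
  write_fixtures(sim, simulate_short_reads(sim$hap, "S/S", 0, seed = 1), d2)
  expect_true(file.exists(file.path(d2, "reads.fastq")))
  expect_equal(file.size(file.path(d2, "reads.fastq")), 0)
  unlink(c(d, d2), recursive = TRUE)
})

test_that("stop planting is exact-count and confined to exon 2", {
  sim <- locus_fixture(counts_re = rep(1L, 10), stop_fraction = 0.4, seed = 16)
  lc <- locus_copies(sim, "rearranged")
  expect_equal(sum(lc$stop_flags), 4L)
  lt <- sim$truth$locus
  sc <- screen_stop_codons(lc$copies, lt$exon2[1], lt$exon2[2])
  expect_identical(sc$flags, lc$stop_flags)
})
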