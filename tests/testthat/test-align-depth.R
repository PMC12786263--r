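# Exact-substring mapping, depth tracks, CNV calling and quantification.

test_that("unique reads map to their source position; foreign reads do not map", {
  set.seed(1)
  ref <- invamp:::random_dna(20000)
  reads <- data.frame(seq = c(substr(ref, 1001, 1150),          # forward
                              revcomp(substr(ref, 5001, 5150)), # reverse
                              invamp:::random_dna(150)))        # foreign
  aln <- map_reads(reads, ref, seed = 1)
  expect_equal(aln$start[1], 1000)
  expect_equal(aln$end[1], 1150)
  expect_equal(aln$strand[1], "+")
  expect_equal(aln$start[2], 5000)
  expect_equal(aln$strand[2], "-")
  expect_false(aln$mapped[3])
  expect_true(is.na(aln$start[3]))
})

test_that("reads from a collapsed repeat map inside the single reference copy", {
  cfg <- sim_config(4e4,
                    cnv_blocks = list(cnv_block("rep", 10, 10,
                                                ref_start = 15000, ref_end = 16000)),
                    seed = 2)
  sim <- build_haplotypes(cfg)
  # read from the 5th copy on the wild-type haplotype
  read5 <- substr(sim$hap$wildtype, 15000 + 4 * 1000 + 101, 15000 + 4 * 1000 + 250)
  aln <- map_reads(data.frame(seq = read5), sim$hap$reference, seed = 3)
  expect_true(aln$mapped[1])
  # brute-force oracle: all exact placements on either strand
  hits_f <- gregexpr(read5, sim$hap$reference, fixed = TRUE)[[1L]]
  hits_r <- gregexpr(revcomp(read5), sim$hap$reference, fixed = TRUE)[[1L]]
  valid <- c(hits_f[hits_f > 0] - 1, hits_r[hits_r > 0] - 1)
  expect_true(aln$start[1] %in% valid)
  expect_gte(aln$start[1], 15000)
  expect_lte(aln$end[1], 16000)
})

test_that("multi-placement choice is uniform-ish and depth conserves mapped bases", {
  cfg <- sim_config(6e4,
                    cnv_blocks = list(cnv_block("rep", 6, 6,
                                                ref_start = 2e4, ref_end = 22e3)),
                    seed = 4)
  sim <- build_haplotypes(cfg)
  rs <- simulate_short_reads(sim$hap, "S/S", coverage = 10, seed = 5)
  aln <- map_reads(rs, sim$hap$reference, seed = 6)
  dt <- build_depth_track(aln, nchar(sim$hap$reference))
  expect_equal(sum(as.numeric(dt$track$depth)),
               sum(aln$len[aln$mapped]))
  expect_true(all(dt$track$depth >= 0))
  # collapsed block depth approximates baseline * copies (6 per homolog)
  blk <- mean(dt$track$depth[20500:21500])
  expect_lt(abs(blk / dt$baseline - 6), 1)
})

test_that("single mapped read yields unit depth and zero median baseline", {
  set.seed(7)
  ref <- invamp:::random_dna(10000)
  aln <- map_reads(data.frame(seq = substr(ref, 2001, 2150)), ref, seed = 1)
  dt <- build_depth_track(aln, 10000)
  expect_equal(sum(dt$track$depth), 150)
  expect_equal(sum(dt$track$depth == 1), 150)
  expect_equal(dt$baseline, 0)
  expect_error(build_depth_track(aln, 10000,
                                 mask = data.frame(start = 0, end = 10000)),
               "no baseline")
})

test_that("baseline tracks simulated coverage and masking removes block influence", {
  cfg <- sim_config(2e5,
                    cnv_blocks = list(cnv_block("big", 1, 50,
                                                ref_start = 9e4, ref_end = 1e5)),
                    seed = 8)
  sim <- build_haplotypes(cfg)
  rs <- simulate_short_reads(sim$hap, "S/M", coverage = 30, seed = 9)
  aln <- map_reads(rs, sim$hap$reference, seed = 10)
  unmasked <- build_depth_track(aln, 2e5)
  expect_lt(abs(unmasked$baseline - 30) / 30, 0.05)
  masked <- build_depth_track(aln, 2e5,
                              mask = data.frame(start = 9e4, end = 1e5))
  expect_lt(abs(masked$baseline - unmasked$baseline) / unmasked$baseline, 0.02)
})

test_that("identical tracks give no CNV calls; zero baseline errors", {
  depth <- as.integer(rep(30, 5e4))
  tr <- structure(list(depth = depth, reference_len = 5e4), class = "depth_track")
  expect_equal(nrow(call_cnv_intervals(tr, tr, 30, 30)), 0L)
  expect_error(call_cnv_intervals(tr, tr, 0, 30), "zero baseline")
})

test_that("a planted 20-vs-2 block is called with >=90% reciprocal overlap", {
  cfg <- sim_config(2e5,
                    cnv_blocks = list(cnv_block("blk", 1, 9,
                                                ref_start = 8e4, ref_end = 9e4)),
                    seed = 11)
  sim <- build_haplotypes(cfg)
  rs_het <- simulate_short_reads(sim$hap, "S/M", coverage = 30, seed = 12)
  rs_hom <- simulate_short_reads(sim$hap, "S/S", coverage = 30, seed = 13)
  out <- run_depth_cnv(rs_het, rs_hom, sim$hap$reference, map_seed = 14)
  expect_equal(nrow(out$calls), 1L)
  ov <- min(out$calls$end[1], 9e4) - max(out$calls$start[1], 8e4)
  expect_gte(ov, 0.9 * 1e4)
  expect_gte(ov, 0.9 * (out$calls$end[1] - out$calls$start[1]))
  # total copies het = 1 + 9 = 10
  expect_lt(abs(out$cnvs$total_copies_het[1] - 10) / 10, 0.1)
})

test_that("merge_gap separates or merges adjacent flagged windows", {
  n <- 6e4
  base <- as.integer(rep(30, n))
  mk <- function(where) {
    d <- base
    for (iv in where) d[(iv[1] + 1):iv[2]] <- 90L
    structure(list(depth = d, reference_len = n), class = "depth_track")
  }
  hom <- structure(list(depth = base, reference_len = n), class = "depth_track")
  far <- mk(list(c(10000, 15000), c(20000, 25000)))   # 5 kb gap > merge_gap
  near <- mk(list(c(10000, 15000), c(15800, 20000)))  # 800 bp gap <= merge_gap
  calls_far <- call_cnv_intervals(far, hom, 30, 30, window = 1000, merge_gap = 1000)
  calls_near <- call_cnv_intervals(near, hom, 30, 30, window = 1000, merge_gap = 1000)
  expect_equal(nrow(calls_far), 2L)
  expect_equal(nrow(calls_near), 1L)
})

test_that("copy-number arithmetic matches the depth ratios exactly", {
  n <- 2e4
  hom_d <- as.integer(rep(10, n)); hom_d[5001:15000] <- 200L  # 20x baseline
  het_d <- as.integer(rep(10, n)); het_d[5001:15000] <- 300L
  hom <- structure(list(depth = hom_d, reference_len = n), class = "depth_track")
  het <- structure(list(depth = het_d, reference_len = n), class = "depth_track")
  q <- quantify_cnvs(data.frame(start = 5000, end = 15000), het, hom, 10, 10)
  expect_equal(q$total_copies_hom, 40)       # 2 * 200 / 10
  expect_equal(q$per_homolog_wild, 20)
  expect_equal(q$total_copies_het, 60)
  expect_equal(q$per_homolog_rearranged, 40)
  expect_equal(q$extra_dna_hom, 10000 * 38)
  expect_equal(q$extra_dna_het, 10000 * 58)
  # depth == baseline -> two copies, no extra DNA
  q2 <- suppressWarnings(
    quantify_cnvs(data.frame(start = 100, end = 2100), het, hom, 10, 10))
  expect_equal(q2$total_copies_het, 2)
  expect_equal(q2$extra_dna_het, 0)
  # 10 kb call at 6 total copies -> 40 kb extra DNA
  het_d2 <- as.integer(rep(10, n)); het_d2[5001:15000] <- 30L
  het2 <- structure(list(depth = het_d2, reference_len = n), class = "depth_track")
  q3 <- suppressWarnings(
    quantify_cnvs(data.frame(start = 5000, end = 15000), het2, hom, 10, 10))
  expect_equal(q3$extra_dna_het, 40000)
})

test_that("negative per-homolog estimates are clipped with a warning", {
  n <- 1e4
  hom_d <- as.integer(rep(10, n)); hom_d[2001:4000] <- 40L
  het_d <- as.integer(rep(10, n))
  hom <- structure(list(depth = hom_d, reference_len = n), class = "depth_track")
  het <- structure(list(depth = het_d, reference_len = n), class = "depth_track")
  expect_warning(
    q <- quantify_cnvs(data.frame(start = 2000, end = 4000), het, hom, 10, 10),
    "clipped")
  expect_equal(q$per_homolog_rearranged, 0)
})
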