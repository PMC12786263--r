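# Long-read hit finding, greedy dedupe, tandem arrays, locus reconstruction
# and premature-stop screening.

test_that("find_hits reports exact unit copies and filters short fragments", {
  set.seed(41)
  unit <- invamp:::random_dna(630)
  bg1 <- invamp:::random_dna(2000)
  bg2 <- invamp:::random_dna(2000)
  read <- paste0(bg1, unit, bg2)
  h <- find_hits(read, c(unit = unit))
  expect_equal(nrow(h), 1L)
  expect_equal(h$identity, 1.0)
  expect_equal(h$length, 630)
  expect_equal(h$read_start, 2000)
  expect_equal(h$read_end, 2630)
  expect_equal(h$orientation, "+")
  # reverse-strand copy found with '-' orientation
  h2 <- find_hits(paste0(bg1, revcomp(unit), bg2), c(unit = unit))
  expect_equal(h2$orientation, "-")
  expect_equal(h2$identity, 1.0)
  # a 150 bp fragment falls below the 200 bp filter
  h3 <- find_hits(paste0(bg1, substr(unit, 1, 150), bg2), c(unit = unit))
  expect_equal(nrow(h3), 0L)
  # read with no query content and empty read
  expect_equal(nrow(find_hits(bg1, c(unit = unit))), 0L)
  expect_equal(nrow(find_hits("", c(unit = unit))), 0L)
  expect_error(find_hits(read, character(0)), "nonempty")
})

test_that("hits tolerate substitutions down to the identity floor", {
  set.seed(42)
  unit <- invamp:::random_dna(630)
  mut <- unit
  pos <- seq(10, 620, by = 12)                      # ~8% substitutions
  for (p in pos) substr(mut, p, p) <- chartr("ACGT", "GTAC", substr(mut, p, p))
  read <- paste0(invamp:::random_dna(1000), mut, invamp:::random_dna(1000))
  h <- find_hits(read, c(unit = unit))
  expect_equal(nrow(h), 1L)
  expect_gte(h$identity, 0.80)
  expect_lt(h$identity, 1.0)
  expect_gte(h$length, 500)
})

test_that("greedy dedupe: nested hits drop, disjoint hits stay", {
  hits <- data.frame(query_id = c("a", "a"),
                     read_start = c(0, 100), read_end = c(1000, 400),
                     length = c(1000, 300), identity = 1,
                     orientation = "+")
  expect_equal(nrow(dedupe_hits(hits)), 1L)
  disj <- data.frame(query_id = c("a", "b"),
                     read_start = c(0, 2000), read_end = c(1000, 2500),
                     length = c(1000, 500), identity = 1, orientation = "+")
  expect_equal(nrow(dedupe_hits(disj)), 2L)
})

test_that("dedupe matches an independent brute-force oracle on random hit sets", {
  set.seed(43)
  for (i in 1:1000) {
    hits <- random_hits(sample.int(10, 1))
    a <- dedupe_hits(hits)
    b <- brute_force_dedupe(hits)
    expect_identical(a[order(a$read_start, a$read_end, a$query_id), ],
                     b[order(b$read_start, b$read_end, b$query_id), ])
  }
})

test_that("accepted hits never overlap the prior acceptance union by >= 80%", {
  set.seed(44)
  for (i in 1:50) {
    acc <- dedupe_hits(random_hits(10))
    acc <- acc[order(-acc$length, acc$read_start), ]
    span <- max(acc$read_end) + 1L
    covered <- rep(FALSE, span)
    for (j in seq_len(nrow(acc))) {
      pos <- (acc$read_start[j] + 1L):acc$read_end[j]
      expect_lt(sum(covered[pos]), 0.8 * acc$length[j])
      covered[pos] <- TRUE
    }
  }
})

test_that("tandem arrays merge consecutive unit hits and count exactly", {
  set.seed(45)
  unit <- invamp:::random_dna(630)
  read <- paste0(invamp:::random_dna(800), strrep(unit, 7),
                 invamp:::random_dna(800))
  h <- find_hits_reads(data.frame(id = "r1", seq = read), c(unit = unit))
  ann <- annotate_arrays(h, 630)
  expect_equal(nrow(ann$arrays), 1L)
  expect_equal(ann$arrays$unit_count, 7L)
  expect_equal(ann$arrays$span, 7 * 630)
  expect_true(ann$arrays$head_to_tail)
  # no unit content -> no arrays
  empty <- annotate_arrays(
    data.frame(read_id = "r", query_id = "other", read_start = 0,
               read_end = 300, length = 300, identity = 1, orientation = "+"),
    630)
  expect_equal(nrow(empty$arrays), 0L)
})

test_that("co-occurrence matrix reflects planted block clustering", {
  set.seed(46)
  q <- list(CNV1 = invamp:::random_dna(400), CNV2 = invamp:::random_dna(400),
            CNV3 = invamp:::random_dna(400), CNV4 = invamp:::random_dna(400),
            CNV7 = invamp:::random_dna(400))
  gap <- function() invamp:::random_dna(300)
  # cluster A: CNV1-3 contiguous; cluster B: CNV4 + CNV7
  readsA <- vapply(1:4, function(i) paste0(gap(), q$CNV1, gap(), q$CNV2,
                                           gap(), q$CNV3, gap()), character(1))
  readsB <- vapply(1:3, function(i) paste0(gap(), q$CNV4, gap(), q$CNV7,
                                           gap()), character(1))
  reads <- data.frame(id = paste0("r", 1:7), seq = c(readsA, readsB))
  h <- find_hits_reads(reads, unlist(q))
  ann <- annotate_arrays(h, 400, unit_id = "none")
  co <- ann$cooccurrence
  expect_equal(co["CNV1", "CNV2"], 4L)
  expect_equal(co["CNV2", "CNV3"], 4L)
  expect_equal(co["CNV4", "CNV7"], 3L)
  expect_equal(co["CNV1", "CNV4"], 0L)
  expect_equal(co["CNV3", "CNV7"], 0L)
})

test_that("strand symmetry: reverse-complementing a read mirrors coordinates", {
  set.seed(47)
  unit <- invamp:::random_dna(630)
  read <- paste0(invamp:::random_dna(500), strrep(unit, 5),
                 invamp:::random_dna(500))
  h_f <- dedupe_hits(find_hits(read, c(unit = unit)))
  h_r <- dedupe_hits(find_hits(revcomp(read), c(unit = unit)))
  expect_equal(nrow(h_f), nrow(h_r))
  L <- nchar(read)
  expect_equal(sort(L - h_f$read_end), sort(h_r$read_start))
  a_f <- annotate_arrays(cbind(read_id = "r", h_f), 630)
  a_r <- annotate_arrays(cbind(read_id = "r", h_r), 630)
  expect_equal(a_f$arrays$unit_count, a_r$arrays$unit_count)
})

test_that("flank-anchored histogram is exact, including a 35-unit read", {
  counts <- c(1L, 1L, 1L, 1L, 7L, 7L, 7L, 35L)
  sim <- locus_fixture(chrom_len = 3e5, insert_at = 15e4, flank = 1500L,
                       counts_wt = 1L, counts_re = counts,
                       stop_fraction = 0.5, seed = 48)
  lr <- spanning_reads(sim)
  fl <- locus_flanks(sim)
  lm <- reconstruct_locus(lr$reads, fl$left, fl$right, sim$truth$locus$unit,
                          exon2 = sim$truth$locus$exon2)
  expect_equal(lm$histogram, c("1" = 4L, "7" = 3L, "35" = 1L))
  # histogram conservation: counts sum to the number of anchored reads
  expect_equal(sum(lm$histogram), lm$n_anchored)
  expect_equal(lm$n_anchored, length(counts))
  # planted stop flags recovered from the anchored segments
  lc <- locus_copies(sim, "rearranged")
  expect_equal(lm$stop_fraction, mean(lc$stop_flags))
  # no spanning reads -> empty model with warning
  expect_warning(
    empty <- reconstruct_locus(data.frame(id = "x",
                                          seq = invamp:::random_dna(5000)),
                               fl$left, fl$right, sim$truth$locus$unit),
    "no flank-anchored")
  expect_equal(empty$n_anchored, 0L)
})

test_that("error-free single-unit consensus is byte-identical to the planted locus", {
  sim <- locus_fixture(chrom_len = 2e5, insert_at = 1e5, flank = 1200L,
                       counts_wt = 1L, counts_re = c(1L, 1L, 6L), seed = 49)
  lr <- spanning_reads(sim)
  fl <- locus_flanks(sim)
  lm <- reconstruct_locus(lr$reads, fl$left, fl$right, sim$truth$locus$unit)
  lc <- locus_copies(sim, "rearranged")
  expect_identical(lm$consensus, lc$copies[1])
})

test_that("stop screening walks codons in frame", {
  base <- strrep("GCT", 40)                                   # 120 bp, no stops
  seqs <- c(base,
            paste0(substr(base, 1, 30), "TAA", substr(base, 34, 120)),  # in frame
            paste0(substr(base, 1, 31), "TAA", substr(base, 35, 120)))  # out of frame
  sc <- screen_stop_codons(seqs, 0, 120)
  expect_identical(sc$flags, c(FALSE, TRUE, FALSE))
  expect_equal(sc$stop_fraction, 1 / 3)
  # 40 planted among 100 -> 0.40 exactly
  many <- c(rep(seqs[2], 40), rep(base, 60))
  expect_equal(screen_stop_codons(many, 0, 120)$stop_fraction, 0.40)
  # frame offset moves the codon grid
  expect_identical(screen_stop_codons(seqs[3], 0, 120, frame = 1)$flags, TRUE)
  expect_error(screen_stop_codons(base, 0, 2), "shorter")
})

test_that("divergent first unit stays alignable and outside exon 3", {
  sim <- locus_fixture(chrom_len = 2e5, insert_at = 1e5, flank = 1200L,
                       counts_wt = 1L, counts_re = 5L,
                       divergent_first_unit = TRUE, seed = 50)
  lt <- sim$truth$locus
  expect_false(identical(lt$divergent_unit, lt$unit))
  # differences confined outside exon 3
  e3 <- (lt$exon3[1] + 1):lt$exon3[2]
  expect_identical(substring(lt$divergent_unit, e3, e3),
                   substring(lt$unit, e3, e3))
  lr <- spanning_reads(sim)
  fl <- locus_flanks(sim)
  lm <- reconstruct_locus(lr$reads, fl$left, fl$right, lt$unit)
  expect_equal(unname(lm$histogram), 1L)
  expect_equal(names(lm$histogram), "5")
})
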