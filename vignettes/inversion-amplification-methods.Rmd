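---
title: "Methods: simulating and detecting inversion-amplification rearrangements"
author: "invamp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and detecting inversion-amplification rearrangements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(invamp)
```

# The problem

Some of the largest structural variants known in vertebrate genomes combine
a multi-megabase paracentric inversion on one chromosome arm with massive
copy-number expansion on the other. A bird heterozygous for such a variant
carries one standard haplotype and one rearranged haplotype whose short arm
has gained tens of megabases of sequence, much of it tandem copies of a
short (~630 bp) repeat unit nested inside an amplified, gene-bearing locus
that is entirely missing from the mapping reference. `invamp` packages the
computational side of characterising such a variant — read-depth
copy-number quantification, differential k-mer discovery of the
unassembled repeat, long-read tandem-array annotation and locus
reconstruction, contact-map inversion breakpoint detection, and the
population statistics used to describe the polymorphism — together with a
simulator that generates diploid genotypes with all of these features
planted and recorded in a truth table.

Every analysis function is therefore testable end to end: the simulator
defines exactly what is in the genome, the analysis recovers it, and the
test suite compares the two.

# The simulator

`sim_config()` describes a background chromosome (uniform i.i.d. ACGT,
drawn once from the master seed) and up to three kinds of planted
structure:

* **Inversion** — a 0-based half-open interval on the background; applied
  as a reverse complement to the rearranged haplotype only. It is
  length-neutral and must not overlap any other planted element
  (configurations that violate this error out).
* **CNV blocks** (`cnv_block()`) — head-to-tail tandem arrays of a unit,
  with separate copy numbers for the wild-type and rearranged haplotypes.
  *Collapsed* blocks take their unit from a reference interval, so the
  mapping reference keeps exactly one copy and mapped depth over it grows
  with copy number — the classic collapsed-repeat signature. *Novel*
  blocks use a freshly drawn unit inserted at a position and are absent
  from the reference altogether.
* **The multicopy locus** (`locus_spec()`) — each locus copy is
  `flank_left + unit × k + flank_right`, with per-copy unit counts given
  as a vector per haplotype. The flanks are background sequence (present,
  once, in the reference), the unit array is not. A coding exon ("exon
  2") lies in the left flank and may carry a planted TAA premature stop;
  a second exon ("exon 3") is embedded in the unit. Background sequence
  under both exons is sanitised so that no spurious in-frame stop exists
  before planting.

Reads are simulated error-free by default (an optional uniform
substitution rate exists for robustness experiments). Paired short reads
come in two modes. **WGS** mode draws a fragment of fixed insert size
uniformly from a haplotype; mate 1 is the forward end, mate 2 the
reverse-complemented other end. **Ligation** mode emulates proximity
ligation: mate 2 lies at a distance `d` from mate 1 with
`P(d) ∝ d^-decay_exponent`, truncated to the chromosome. The decay
exponent defaults to 1, the canonical contact-decay slope; nothing in the
analysed literature pins the value, so it is a package choice, verified by
a property test that recovers the slope from 10^5 sampled distances to
within ±0.1. Long reads have exponential-tailed lengths
(`min_len + Exp(mean_len − min_len)`), and a `spanning` option emits
guaranteed reads covering given truth intervals — the in-silico analogue
of selecting reads that span both flanks of a tandem array.

Two deliberate bookkeeping choices make depth expectations exact rather
than merely asymptotic. First, heterozygotes receive a deterministic
*length-proportional* split of read pairs between haplotypes: both
homologs are present once per cell, so per-bp depth must be equal even
when the rearranged haplotype is 50% longer. (A 50/50 split by read count
— the superficially obvious choice — halves the longer haplotype's
per-bp depth and biases copy-number estimates by tens of percent.)
Second, premature stops are planted at an exact count,
`round(stop_fraction × n_copies)`, at seeded random copies, so a planted
fraction of 0.40 over 100 copies is exactly 40/100 and screening tests
can assert equality rather than approximation.

What the generator does **not** emulate: sequencing error profiles, GC
and mappability bias, indels and chimeric reads, restriction-site-aware
ligation fragmentation, or background SNP heterozygosity. Passing tests
therefore demonstrate the correctness of the algorithms under their
stated models, not robustness to every artefact of real data; on real
libraries the mapping step would be a production aligner and the
alignment-based modules consume its output in the same interval form.

# Read mapping and depth-based copy number

`map_reads()` is a minimal exact-substring mapper: a read is mapped iff
it occurs exactly in the reference or its reverse complement. Candidates
are located through the read's leading k-mer (default `seed_k = 21`)
in a hashed index of all reference k-mer positions (`ref_index()`,
reusable across replicates) and verified by full comparison — the leading
k-mer of a true occurrence necessarily matches, so no placement is
missed. A read with several placements (a collapsed repeat) takes one
uniformly at random under the caller's seed, mirroring how a default
short-read aligner distributes multi-mappers; depth over the collapsed
reference copy then accumulates every repeat-derived read. The hot loops
(indexing, mapping, read extraction, canonical k-mer counting) are
compiled C++; short-read sets store their sequences in a single
concatenated blob sliced natively, which keeps multi-million-read
simulations cheap in R.

`build_depth_track()` accumulates per-position coverage and estimates the
diploid **baseline** as the *median* depth outside a mask. The median is
deliberately robust to residual amplified intervals (the mean is
available via `baseline_stat = "mean"`). `run_depth_cnv()` applies the
mask iteratively: a first pass with no mask yields candidate calls, which
are masked before the final baseline — two passes suffice on synthetic
data because the candidate set is already essentially correct after one.

`call_cnv_intervals()` scans fixed windows (default 1 kb) and flags those
where baseline-normalised heterozygote depth exceeds the homozygote's by
`min_ratio` (default 1.5 — exactly the ratio produced by one extra copy
per homolog, hence the detection floor), or where the homozygote itself
is amplified ≥ `min_ratio`-fold (wild-type amplifications present in both
genotypes). Flagged windows merge across gaps up to `merge_gap` (default
1 kb). `quantify_cnvs()` converts interval depth into copy number as
`total_copies = 2 × mean_depth / baseline`; the wild-type homolog carries
half the homozygote total, the rearranged homolog the heterozygote total
minus that (clipped at zero with a warning). Extra DNA per interval is
`length × max(0, total_copies − 2)`, and the cumulative sum over calls
estimates the total sequence gain. Because both totals are reported, the
perennial ambiguity between "copies per diploid genome" and "copies per
homolog" is resolved by printing both.

Edge effects bound the accuracy: reads straddling a copy junction are not
exact reference substrings and go unmapped, depressing mean block depth
by roughly `read_len / block_len`. For blocks ≥ 5 kb at 150 bp reads this
is ≤ 3%, well inside the 10% recovery tolerance the tests assert over
randomised blocks of 2–50 copies at 30× coverage.

# Differential k-mer discovery of the unassembled unit

The discovery pipeline (`discover_repeat_unit()`) follows four steps.

1. **Half-mapped pairs** (`extract_half_mapped()`): pairs with exactly
   one mapped mate enrich for sequence adjacent to, or inside, loci
   missing from the assembly. Ligation-mode pairs are essential here:
   their long-range mates reach arbitrarily deep into a long novel array,
   whereas WGS insert-size pairs only ever sample its first few hundred
   bases.
2. **Canonical k-mer counting** (`count_kmers()`): every k-mer is
   recorded as the lexicographic minimum of itself and its reverse
   complement, making counts strand-independent (a property test
   reverse-complements all input reads and asserts an identical table).
3. **Enrichment selection** (`select_enriched_kmers()`): a k-mer is
   selected when its depth-normalised heterozygote abundance exceeds the
   pseudocounted homozygote abundance `min_ratio`-fold (default 4) and
   its raw count reaches `min_count` (default 5). Normalisation is by
   total sequenced bases, so doubling one sample's depth changes
   nothing. The ratio rule is deterministic by design — no hypothesis
   test — because on error-free data the unit k-mers separate from
   background by an order of magnitude. The defaults interact with the
   planted scenario: with ~20 wild-type and ~400 rearranged-haplotype
   copies the expected ratio is ≈ 20, so the floor of 4 leaves a wide
   margin, while flank-junction k-mers (present equally in both
   genotypes) sit near ratio 1 and are excluded.
4. **De Bruijn reconstruction** (`reconstruct_unit()`): the selected
   k-mers (both orientations) form a de Bruijn graph on their
   (k−1)-mers. A tandem repeat closes into a single simple cycle whose
   edge count *is* the unit length; a linear contig gives a simple path;
   a branching graph raises an error naming the branch nodes, and
   disconnected components each yield a unit. Units are collapsed to
   their minimal string period (so `k` larger than the unit still
   returns the unit, not a multiple) and circular units are reported in
   **canonical rotation** — the lexicographic minimum over all rotations
   of both strands — which gives every rotation/strand presentation of
   the same tandem unit a single comparable name (`units_equivalent()`).

The default `k = 31` differs from the long k one would use on noisy real
data; error-free synthetic reads need no extra specificity, and the
k-scan test confirms that k ∈ {21, 31, 41, 80} reconstruct the identical
unit after period collapse. De Bruijn chaining here replaces a manual
multiple-alignment consensus; on error-free data the two are equivalent,
and the graph formulation is exactly testable.

# Long-read annotation and locus reconstruction

`find_hits()` is a seed-and-extend local aligner specialised to
low-divergence data: exact 15-mer seeds define read/query diagonals and
each diagonal is scored ungapped (+1 match, −2 mismatch) with the
maximal-scoring segment taken as the hit (Kadane's rule on the
match/mismatch profile). Hits shorter than 200 bp or under 80% identity
are discarded. Extension is deliberately ungapped: the simulator plants
substitutions only (the divergent-first-unit option), so a banded gapped
extension would add complexity without changing any result the package
can produce; with indel-bearing data the gap penalty of a full aligner
would be needed.

`dedupe_hits()` implements greedy non-redundant acceptance: hits sorted
by decreasing length (ties by read start, then query id) are accepted
unless ≥ 80% of a hit's length overlaps the union of already accepted
hits — adjacent or gap-separated hits stay distinct. The test suite runs
this against an independent brute-force implementation (per-position
coverage bookkeeping) on 1,000 random hit sets.

`annotate_arrays()` merges consecutive same-orientation unit hits with
inter-hit gaps ≤ 0.2 × unit length into head-to-tail tandem arrays
(exact unit counts on error-free reads) and tabulates a query
co-occurrence matrix over reads — the evidence used to conclude that
some amplified segments travel together while others form separate
clusters.

`reconstruct_locus()` selects flank-anchored reads (both flanks present
in consistent orientation), counts unit hits between the flanks into the
units-per-read histogram, and builds a consensus from single-unit reads
by anchor-offset column majority vote — exact on error-free reads, and a
stand-in for the multiple-alignment consensus one would build from noisy
reads. When copies legitimately differ (planted stop variants), the
consensus is a column-wise majority and need not equal any single copy.
`screen_stop_codons()` walks codons across the annotated exon from a
given frame offset and flags a sequence iff an in-frame TAA/TAG/TGA
occurs before the exon end; out-of-frame stop triplets are ignored.

# Contact maps and the butterfly score

`build_contact_map()` bins both-mapped ligation pairs into a symmetric
matrix (`M + t(M)`, so the total equals twice the pair count) and
`normalize_by_decay()` divides each cell by the mean contact at its bin
distance — the standard observed/expected transform, invariant to
global scaling.

A heterozygous inversion with breakpoints `x1 < x2` creates excess
contacts between sequence just outside `x1` and just inside `x2`, and
between just inside `x1` and just outside `x2` — the butterfly pattern.
`detect_inversion()` scores every candidate bin pair `(b1, b2)` with
`b2 − b1 ≥ 10` bins by the **minimum** of the heterozygote's two 5-bin
wing means (row `b1` at columns just below `b2`; column `b2` at rows
just above `b1`) minus the same statistic on the homozygote map. Using
the minimum rather than the average of the wings is a deliberate
discriminator: a genuine inversion heats *both* wings at the same bin
pair, while a random fluctuation rarely elevates two disjoint 5-cell
strips simultaneously, so the null maximum drops sharply while the true
signal is untouched. The wing width of 5 bins and minimum span of 10
bins target the large-inversion regime; at 100 kb bins the smallest
detectable inversion is 1 Mb.

The call threshold is permutation-calibrated on the homozygote map.
Each of 50 permutation rounds draws *two* independent shuffles of the
homozygote O/E entries within each bin-distance stratum (preserving
distance decay, destroying breakpoint structure), scores one against
the other, and records the full-grid maximum — replicating the
distribution of the maximal score between two structure-free maps at
the observed noise level, which is exactly the situation of comparing
two homozygotes. The threshold is the 99th percentile of those maxima
times a 1.2 safety margin. Calibrating on the grid maximum (not on
single-pair scores) controls the family-wise false-call rate over the
~1,500 candidate pairs, and the margin absorbs the sampling variability
of a 50-round quantile. In design evaluation runs (7 Mb chromosome,
10^5 pairs, 100 kb bins) planted breakpoints were recovered within one
bin in every replicate, with true scores 1.0–1.5 against thresholds of
0.75–0.9, while homozygote-vs-homozygote comparisons peaked at 0.6 and
produced no calls. Reported breakpoints follow the junction
geometry of the maximising pair — the hot wing row holds sequence just
left of the proximal junction (so its right bin edge is reported) and
the hot wing column sequence just right of the distal junction (its
left bin edge) — with a tolerance of one bin; sub-bin precision is out
of scope, so a 100 kb bin size means ±100 kb.

# Population and cytogenetic statistics

`cytotype_frequencies()` estimates the heterozygote frequency over `N`
individuals and the rearranged-chromosome frequency over `2N`
chromosomes, each with the sampling standard error
`sqrt(p (1 − p) / N)` — the plug-in binomial form, with `N` the
denominator that matches the estimate.

`hwe_test()` computes the Pearson chi-square of observed genotype counts
against `N·(p̂², 2p̂q̂, q̂²)` on **1 degree of freedom** (three classes
minus one estimated allele frequency), without continuity correction;
monomorphic samples return χ² = 0, p = 1 by convention. Label-swap
invariance (M ↔ S) is asserted as a property. `contingency_chisq()`
wraps the standard Pearson 2×2 test with optional Yates correction
(default off) and rejects degenerate margins.

`mlh1_recombination_map()` turns crossover-marking MLH1 focus positions
along synaptonemal complexes into a recombination map: positions are
rescaled to the mean SC length, binned into `round(mean_length /
target_bin)` equal intervals (1 µm target by default) anchored at one
terminus, and expressed as proportions per bin, overall and stratified
by foci-per-bivalent class. The mean rescaled centromere position is
reported for marking on the axis; both the absolute-µm map and the
centromere position are returned because axis conventions differ between
studies.

`mann_whitney_u()` uses midranks for ties and switches between exact
enumeration of all `choose(n1+n2, n1)` group assignments (valid under
ties; used for `n1 + n2 ≤ 12`) and a normal approximation with
tie-corrected variance and continuity correction. The two modes agree
within |Δp| ≤ 0.05 at n = 6 per group, and the exact mode matches
`stats::wilcox.test(exact = TRUE)` on tie-free data — the package keeps
its own implementation because the exact-under-ties case is not covered
by the standard routine.

# Numerical and design notes

* Coordinates are 0-based half-open everywhere internally (BED
  convention); printed reports are 1-based only where flagged.
* All randomness is seeded through a save/restore wrapper, so simulators
  never perturb the session RNG and equal seeds give byte-identical
  outputs (including FASTQ bytes on disk).
* Uniform base composition makes accidental k-mer collisions at k ≥ 21
  vanishingly rare (~n²·4^-k), which the discovery and mapping modules
  rely on; the one deliberate repeat structure is the planted unit
  itself.
* Ties in the greedy hit acceptance are broken by read start and then
  query id, making acceptance order — and therefore output — fully
  deterministic.
* Degenerate inputs fail loudly: fully masked baselines, zero baselines,
  unpaired alignment records, branching de Bruijn graphs, empty
  candidate grids, zero contingency margins and out-of-range foci all
  raise errors naming the offending object.

## Problem sizes used in the test and acceptance runs

The shipped tests run the discovery pipeline on a 5 Mb chromosome at 30×
(20 read-set replicates), copy-number recovery on 20 chromosomes of
400 kb with five blocks each (100 blocks), and breakpoint detection on a
7 Mb chromosome with 10^5 ligation pairs per genotype (20 replicates).
These sizes are the package's chosen compromise between statistical
resolution and a test suite that completes in minutes; all of them scale
linearly if larger experiments are wanted.

## Known limitations

* The exact-substring mapper is not an aligner: a single substitution
  unmaps a read. That is the correct semantics for the error-free
  simulator and keeps the mapped/unmapped dichotomy sharp for the
  half-mapped-pair logic, but real data requires an external aligner.
* Contact-map breakpoints are bin-resolution only; no sub-bin
  refinement is attempted.
* The locus consensus assumes anchor-aligned, indel-free segments.
* `reconstruct_unit()` refuses branching graphs rather than resolving
  them; resolving repeat families with shared subsequences is the domain
  of a real assembler.
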