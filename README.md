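# invamp

Simulation and detection of complex **inv**ersion–**amp**lification
chromosome rearrangements.

Some of the most striking structural variants in vertebrate genomes pair a
multi-megabase paracentric inversion on one chromosome arm with massive
copy-number amplification on the other — including a multicopy, gene-bearing
locus that carries a nested ~630 bp tandem repeat and is missing from the
mapping reference entirely. `invamp` is an R toolkit for geneticists who
want to characterise such variants from short-read, long-read and
proximity-ligation data, and to validate every step of that analysis on
synthetic genomes with known ground truth.

The package provides six building blocks:

* **Simulator** — diploid haplotype pairs with a planted inversion,
  collapsed/novel CNV blocks and a multicopy locus (`sim_config()`,
  `build_haplotypes()`, `simulate_short_reads()`, `simulate_long_reads()`,
  `write_fixtures()`), all recorded in a truth table; identical seeds give
  byte-identical output.
* **Read depth** — exact-match mapping, depth tracks, CNV interval calls
  from a heterozygote/homozygote contrast, and copy-number / extra-DNA
  quantification: `total_copies = 2 × mean_depth / baseline`,
  `extra_dna = length × max(0, total_copies − 2)` (`map_reads()`,
  `run_depth_cnv()`, `quantify_cnvs()`).
* **Differential k-mers** — half-mapped-pair extraction, canonical k-mer
  counting, heterozygote-enrichment selection and de Bruijn reconstruction
  of the unassembled repeat unit (`discover_repeat_unit()`,
  `reconstruct_unit()`). A tandem unit appears as a single cycle whose
  length *is* the unit length, reported in canonical rotation.
* **Long reads** — seed-and-extend hits, greedy non-redundant acceptance
  (a hit is dropped when ≥ 80% of it overlaps accepted hits), head-to-tail
  tandem array counting, co-occurrence matrices, flank-anchored locus
  reconstruction and premature-stop screening (`find_hits()`,
  `dedupe_hits()`, `annotate_arrays()`, `reconstruct_locus()`,
  `screen_stop_codons()`).
* **Contact maps** — binned ligation maps, observed/expected
  normalisation, and butterfly-score grid search for heterozygous
  inversion breakpoints with a permutation-calibrated threshold
  (`build_contact_map()`, `detect_inversion()`).
* **Population statistics** — cytotype frequencies with sampling errors
  `sqrt(p(1−p)/N)`, Hardy–Weinberg and 2×2 chi-square tests, MLH1
  crossover recombination maps, and a Mann–Whitney U test with exact
  small-sample enumeration (`cytotype_frequencies()`, `hwe_test()`,
  `mlh1_recombination_map()`, `mann_whitney_u()`).

See the methods vignette
(`vignettes/inversion-amplification-methods.Rmd`) for the models,
parameter choices and limitations.

## Worked example

Plant a 630 bp unit at 20 (wild-type) vs 400 (rearranged) copies per
homolog on a 5 Mb chromosome, simulate 30× proximity-ligation pairs for a
heterozygote and a homozygote, and rediscover the unit without ever
showing it to the pipeline:

```r
library(invamp)

cfg <- sim_config(5e6,
  locus = locus_spec(insert_at = 25e5, flank_left_len = 2000,
                     flank_right_len = 2000, unit_length = 630,
                     unit_counts_wildtype = 20,
                     unit_counts_rearranged = 400),
  seed = 11)
sim <- build_haplotypes(cfg)
print(sim$hap)
#> Haplotype pair:
#>   wildtype      5,012,600 bp
#>   rearranged    5,252,000 bp
#>   reference     5,000,000 bp

het <- simulate_short_reads(sim$hap, "S/M", coverage = 30,
                            mode = "ligation", seed = 101)
hom <- simulate_short_reads(sim$hap, "S/S", coverage = 30,
                            mode = "ligation", seed = 102)
res <- discover_repeat_unit(het, hom, sim$hap$reference, k = 31)
print(res$unit)
#> consensus_unit: 630 bp, circular (tandem unit)
units_equivalent(res$unit, sim$truth$locus$unit)
#> [1] TRUE
```

The read sets contain about half a million pairs each; 630 canonical
k-mers pass the enrichment filter and chain into a single 630-node cycle —
the planted unit, recovered as a rotation/strand-equivalent circular
sequence. The wild-type haplotype is 12,600 bp longer than the reference
(the 20 × 630 bp unit array, which the reference lacks) and the
rearranged haplotype carries 380 extra units (239,400 bp more).

Population summaries use the same functions a field study would report:

```r
cytotype_table(list(genotype_counts(0, 4, 13, "females"),
                    genotype_counts(0, 4, 22, "males"),
                    genotype_counts(0, 8, 35, "pooled")))
#>     group n_MM n_SM n_SS  N het_p het_se allele_p allele_se hwe_chi2 hwe_p
#> 1 females    0    4   13 17 0.235 0.1029   0.1176    0.0553    0.302 0.582
#> 2   males    0    4   22 26 0.154 0.0708   0.0769    0.0370    0.181 0.671
#> 3  pooled    0    8   35 43 0.186 0.0593   0.0930    0.0313    0.452 0.501
```

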