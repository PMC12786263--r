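Package: invamp
Title: Simulation and Detection of Complex Inversion-Amplification
    Chromosome Rearrangements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to simulate and analyse complex structural variants that
    combine a large paracentric inversion with massive copy-number
    amplification, as found on avian macrochromosomes. Provides a
    deterministic diploid haplotype simulator with planted inversions,
    copy-number blocks and a multicopy locus carrying a nested tandem
    repeat unit; an exact-match short-read mapper with read-depth
    copy-number quantification; a differential k-mer pipeline that
    reconstructs unassembled repeat units from half-mapped read pairs;
    long-read tandem-array annotation, flank-anchored locus reconstruction
    and premature-stop-codon screening; binned proximity-ligation contact
    maps with butterfly-score inversion breakpoint detection; and
    population statistics for cytotype frequencies, Hardy-Weinberg tests
    and crossover (MLH1 focus) recombination maps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    Rcpp,
    data.table,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
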