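# Differential k-mer discovery of unassembled amplified sequence: half-mapped
# pair extraction, canonical k-mer counting, between-genotype enrichment
# selection and de Bruijn path/cycle reconstruction of the repeat unit.

#' Extract the unmapped mates of half-mapped read pairs
#'
#' A half-mapped pair has exactly one mate aligned to the reference — the
#' signature of sequence adjacent to loci missing from the assembly. Pairs
#' with both mates mapped or both unmapped are excluded.
#'
#' @param alignments paired alignment records from [map_reads()] (columns
#'   `pair_id`, `mate`, `mapped`, `seq`; every pair must have exactly two
#'   records).
#' @return character vector: sequences of the unmapped mates.
#' @export
extract_half_mapped <- function(alignments) {
  if (anyNA(alignments$pair_id)) stop("unpaired records: pair_id is missing")
  dt <- data.table::data.table(pair_id = alignments$pair_id,
                               mapped = alignments$mapped,
                               row = seq_len(nrow(alignments)))
  cnt <- dt[, .(n = .N, n_mapped = sum(mapped)), by = "pair_id"]
  if (any(cnt$n != 2L)) stop("unpaired records: every pair needs exactly 2 mates")
  half <- cnt$pair_id[cnt$n_mapped == 1L]
  rows <- dt[pair_id %in% half & !mapped, row]
  if (!is.null(alignments$seq)) return(alignments$seq[rows])
  blob <- attr(alignments, "seq_blob")
  if (is.null(blob)) stop("alignments carry neither sequences nor a sequence blob")
  substring(blob, alignments$offset[rows] + 1L,
            alignments$offset[rows] + alignments$len[rows])
}

#' Count canonical k-mers
#'
#' Counts every k-long substring of the input sequences under canonical
#' representation (the lexicographic minimum of a k-mer and its reverse
#' complement), making counts strand-independent. k-mers containing
#' non-ACGT characters are skipped; sequences shorter than k contribute
#' nothing.
#'
#' @param seqs character vector of sequences.
#' @param k k-mer length (>= 3).
#' @return a `kmer_table`: list with `k`, `counts` (data.frame `kmer`,
#'   `count`) and `total_bases` (normalisation denominator, the summed
#'   input length).
#' @export
count_kmers <- function(seqs, k) {
  stopifnot(k >= 3L)
  total_bases <- sum(nchar(seqs))
  res <- cpp_count_canonical(seqs, as.integer(k))
  counts <- data.frame(kmer = res$kmer, count = res$count)
  counts <- counts[order(counts$kmer, method = "radix"), , drop = FALSE]
  rownames(counts) <- NULL
  structure(list(k = as.integer(k), counts = counts,
                 total_bases = total_bases),
            class = "kmer_table")
}

#' @export
print.kmer_table <- function(x, ...) {
  cat("kmer_table: k =", x$k, "|", nrow(x$counts), "distinct canonical k-mers |",
      format(x$total_bases, big.mark = ","), "bases counted\n")
  invisible(x)
}

#' Select k-mers enriched in the heterozygote
#'
#' Flags canonical k-mers whose sequencing-depth-normalised abundance in the
#' heterozygote exceeds the (pseudocounted) homozygote abundance at least
#' `min_ratio`-fold:
#' `(count_het / total_bases_het) / ((count_hom + 1) / total_bases_hom) >= min_ratio`,
#' with an absolute floor `count_het >= min_count`. Normalising by total
#' sequenced bases makes the selection invariant to sequencing depth.
#'
#' @param table_het,table_hom `kmer_table`s with the same `k`.
#' @param min_ratio enrichment ratio floor (default 4).
#' @param min_count minimum heterozygote count (default 5).
#' @return character vector of enriched canonical k-mers.
#' @export
select_enriched_kmers <- function(table_het, table_hom,
                                  min_ratio = 4, min_count = 5L) {
  if (table_het$k != table_hom$k) stop("k mismatch between k-mer tables")
  het <- data.table::as.data.table(table_het$counts)
  hom <- data.table::as.data.table(table_hom$counts)
  m <- merge(het, hom, by = "kmer", all.x = TRUE, suffixes = c("_het", "_hom"))
  m[is.na(count_hom), count_hom := 0L]
  ratio <- (m$count_het / table_het$total_bases) /
           ((m$count_hom + 1) / table_hom$total_bases)
  m$kmer[ratio >= min_ratio & m$count_het >= min_count]
}

#' Reconstruct a repeat unit from enriched k-mers by de Bruijn chaining
#'
#' Builds the de Bruijn graph whose edges are the selected k-mers (both
#' orientations of each canonical k-mer) and whose nodes are their
#' (k-1)-prefixes/suffixes, then walks it. A single simple cycle yields a
#' circular unit whose length equals the number of k-mers in the cycle — the
#' signature of a tandem repeat; a single simple path yields a linear
#' contig. Units are collapsed to their minimal string period and circular
#' units are reported in canonical rotation. A branching graph (a node with
#' in- or out-degree above 1 on both strands) raises an error naming the
#' branch points; disconnected components each yield one unit.
#'
#' @param kmers character vector of k-mers (canonical or not).
#' @param k k-mer length (all k-mers must have `nchar == k`).
#' @return a `consensus_unit` (list with `sequence`, `circular`,
#'   `canonical`, `unit_length`) when the graph has one component, or a
#'   list of `consensus_unit`s (one per component).
#' @export
reconstruct_unit <- function(kmers, k) {
  if (!length(kmers)) stop("empty k-mer set")
  stopifnot(all(nchar(kmers) == k))
  kmers <- unique(kmers)
  # orient edges consistently: keep one strand per k-mer, but the graph may
  # mix strands; walk on the strand graph containing both orientations and
  # dedupe mirrored components afterwards
  edges <- unique(c(kmers, revcomp(kmers)))
  pre <- substr(edges, 1L, k - 1L)
  suf <- substr(edges, 2L, k)
  nodes <- unique(c(pre, suf))
  out_deg <- table(factor(pre, levels = nodes))
  in_deg <- table(factor(suf, levels = nodes))
  branch <- nodes[out_deg > 1L | in_deg > 1L]
  if (length(branch)) {
    stop("branching de Bruijn graph; no unique path/cycle. Branch nodes: ",
         paste(utils::head(branch, 5L), collapse = ", "),
         if (length(branch) > 5L) sprintf(" (+%d more)", length(branch) - 5L) else "")
  }
  nxt <- stats::setNames(match(suf, nodes), NULL)      # by edge
  edge_from <- match(pre, nodes)
  edge_of_node <- rep(NA_integer_, length(nodes))      # outgoing edge per node
  edge_of_node[edge_from] <- seq_along(edges)
  has_in <- nodes %in% suf
  visited <- rep(FALSE, length(edges))
  units <- list()
  seen_canon <- character(0)

  walk_from <- function(start_node) {
    seq_edges <- integer(0)
    node <- start_node
    repeat {
      e <- edge_of_node[node]
      if (is.na(e) || visited[e]) break
      visited[e] <<- TRUE
      seq_edges <- c(seq_edges, e)
      node <- nxt[e]
    }
    seq_edges
  }

  emit <- function(seq_edges, circular) {
    if (circular) {
      s <- paste0(substr(edges[seq_edges], 1L, 1L), collapse = "")
      p <- minimal_period_circular(s)
      s <- substr(s, 1L, p)
      canon <- canonical_rotation(s)
      if (canon %in% seen_canon) return(invisible())
      seen_canon <<- c(seen_canon, canon)
      units[[length(units) + 1L]] <<- structure(
        list(sequence = canon, circular = TRUE, canonical = canon,
             unit_length = nchar(canon)), class = "consensus_unit")
    } else {
      s <- paste0(edges[seq_edges[1L]],
                  paste0(substr(edges[seq_edges[-1L]], k, k), collapse = ""))
      p <- minimal_period_linear(s)
      s2 <- substr(s, 1L, p)
      canon <- sort(c(s2, revcomp(s2)), method = "radix")[1L]
      if (canon %in% seen_canon) return(invisible())
      seen_canon <<- c(seen_canon, canon)
      units[[length(units) + 1L]] <<- structure(
        list(sequence = s2, circular = FALSE, canonical = canon,
             unit_length = nchar(s2)), class = "consensus_unit")
    }
  }

  # paths first (start at nodes without incoming edge)
  for (ni in which(!has_in)) {
    se <- walk_from(ni)
    if (length(se)) emit(se, circular = FALSE)
  }
  # remaining edges belong to simple cycles
  for (e in seq_along(edges)) {
    if (visited[e]) next
    se <- walk_from(edge_from[e])
    if (length(se)) emit(se, circular = TRUE)
  }
  if (length(units) == 1L) units[[1L]] else units
}

#' @export
print.consensus_unit <- function(x, ...) {
  cat(sprintf("consensus_unit: %d bp, %s\n", x$unit_length,
              if (x$circular) "circular (tandem unit)" else "linear"))
  invisible(x)
}

#' Test rotation/strand equivalence of two repeat units
#'
#' Two tandem-repeat units are equivalent when one is a rotation of the
#' other or of its reverse complement.
#'
#' @param a,b unit sequences (character scalars or `consensus_unit`s).
#' @return logical.
#' @export
units_equivalent <- function(a, b) {
  sa <- if (inherits(a, "consensus_unit")) a$sequence else a
  sb <- if (inherits(b, "consensus_unit")) b$sequence else b
  nchar(sa) == nchar(sb) && canonical_rotation(sa) == canonical_rotation(sb)
}

#' End-to-end discovery of an unassembled amplified repeat unit
#'
#' Runs the full differential k-mer pipeline: map both genotypes' read sets
#' to the reference, extract the unmapped mates of half-mapped pairs, count
#' canonical k-mers, select heterozygote-enriched k-mers and reconstruct the
#' unit by de Bruijn chaining.
#'
#' @param reads_het,reads_hom paired `read_set`s.
#' @param reference `ref_index` or character scalar.
#' @param k k-mer length (default 31; error-free data needs no long k).
#' @param min_ratio,min_count passed to [select_enriched_kmers()].
#' @param map_seed seed for mapping tie-breaks.
#' @return list with `unit` (a `consensus_unit`, list of them, or `NULL` if
#'   no k-mer was enriched), `enriched` (character), `n_half_mapped_het`,
#'   `n_half_mapped_hom`.
#' @export
discover_repeat_unit <- function(reads_het, reads_hom, reference, k = 31L,
                                 min_ratio = 4, min_count = 5L,
                                 map_seed = 1L) {
  idx <- if (inherits(reference, "ref_index")) reference else ref_index(reference)
  ah <- map_reads(reads_het, idx, seed = map_seed)
  ao <- map_reads(reads_hom, idx, seed = map_seed + 1L)
  hm_het <- extract_half_mapped(ah)
  hm_hom <- extract_half_mapped(ao)
  th <- count_kmers(hm_het, k)
  # normalise by the full sequencing effort of each sample
  th$total_bases <- .total_bases(reads_het)
  to <- count_kmers(hm_hom, k)
  to$total_bases <- .total_bases(reads_hom)
  enriched <- select_enriched_kmers(th, to, min_ratio, min_count)
  unit <- if (length(enriched)) reconstruct_unit(enriched, k) else NULL
  list(unit = unit, enriched = enriched,
       n_half_mapped_het = length(hm_het), n_half_mapped_hom = length(hm_hom))
}

.total_bases <- function(reads) {
  if (inherits(reads, "read_set")) {
    if (!is.null(reads$blob) && is.null(reads$reads$seq)) return(nchar(reads$blob))
    return(sum(nchar(reads$reads$seq)))
  }
  sum(nchar(reads$seq))
}

#' Write a k-mer table as TSV
#'
#' @param table a `kmer_table`.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_kmer_table <- function(table, path) {
  utils::write.table(table$counts, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
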