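# Population and cytogenetic statistics: cytotype frequencies with sampling
# variance, Hardy-Weinberg and contingency chi-square tests, crossover (MLH1
# focus) recombination maps and a Mann-Whitney U test with exact small-sample
# enumeration.

#' Genotype counts for a chromosomal cytotype
#'
#' @param n_MM,n_SM,n_SS nonnegative integer counts of rearranged
#'   homozygotes, heterozygotes and standard homozygotes.
#' @param group optional group label (e.g. `"females"`).
#' @return a `genotype_counts` list with `N` total.
#' @export
genotype_counts <- function(n_MM, n_SM, n_SS, group = "pooled") {
  stopifnot(n_MM >= 0, n_SM >= 0, n_SS >= 0)
  N <- n_MM + n_SM + n_SS
  if (N < 1) stop("empty sample: N = 0")
  structure(list(n_MM = as.integer(n_MM), n_SM = as.integer(n_SM),
                 n_SS = as.integer(n_SS), N = as.integer(N),
                 group = group),
            class = "genotype_counts")
}

#' Cytotype and allele frequencies with sampling standard errors
#'
#' The heterozygote frequency is `n_SM / N` over `N` individuals; the
#' rearranged-chromosome (allele) frequency is `(2 n_MM + n_SM) / (2N)` over
#' `2N` chromosomes. The sampling variance of a frequency estimate `p` is
#' `p (1 - p) / N`, with `N` the number of individuals for genotype
#' frequencies and the number of chromosomes for allele frequencies.
#'
#' @param counts a [genotype_counts()].
#' @return list with `het` and `allele_M`, each a `frequency_estimate`
#'   (`p`, `se`, `denominator`).
#' @export
cytotype_frequencies <- function(counts) {
  stopifnot(inherits(counts, "genotype_counts"))
  fe <- function(p, N) {
    structure(list(p = p, se = sqrt(p * (1 - p) / N), denominator = N),
              class = "frequency_estimate")
  }
  list(het = fe(counts$n_SM / counts$N, counts$N),
       allele_M = fe((2 * counts$n_MM + counts$n_SM) / (2 * counts$N),
                     2 * counts$N))
}

#' @export
print.frequency_estimate <- function(x, ...) {
  cat(sprintf("%.2f +/- %.2f (N = %d)\n", x$p, x$se, x$denominator))
  invisible(x)
}

#' Hardy-Weinberg equilibrium chi-square test
#'
#' Pearson chi-square of observed genotype counts against Hardy-Weinberg
#' expectations `N * (p^2, 2pq, q^2)` at the estimated allele frequency,
#' without continuity correction, on 1 degree of freedom (three genotype
#' classes minus one estimated allele frequency). A monomorphic sample
#' returns `chi2 = 0`, `p = 1` by convention.
#'
#' @param counts a [genotype_counts()].
#' @return an `hwe_result` list (`chi2`, `df = 1`, `p_value`, `p_hat`).
#' @export
hwe_test <- function(counts) {
  stopifnot(inherits(counts, "genotype_counts"))
  N <- counts$N
  p_hat <- (2 * counts$n_MM + counts$n_SM) / (2 * N)
  if (p_hat %in% c(0, 1)) {
    return(structure(list(chi2 = 0, df = 1L, p_value = 1, p_hat = p_hat),
                     class = "hwe_result"))
  }
  expected <- N * c(p_hat^2, 2 * p_hat * (1 - p_hat), (1 - p_hat)^2)
  observed <- c(counts$n_MM, counts$n_SM, counts$n_SS)
  chi2 <- sum((observed - expected)^2 / expected)
  structure(list(chi2 = chi2, df = 1L,
                 p_value = stats::pchisq(chi2, df = 1L, lower.tail = FALSE),
                 p_hat = p_hat),
            class = "hwe_result")
}

#' @export
print.hwe_result <- function(x, ...) {
  cat(sprintf("HWE chi-square = %.3f (df = 1), p = %.3f (allele freq %.3f)\n",
              x$chi2, x$p_value, x$p_hat))
  invisible(x)
}

#' Pearson chi-square test for a 2x2 contingency table
#'
#' @param table 2x2 numeric matrix of counts; all row and column margins
#'   must be positive.
#' @param correction apply Yates continuity correction (default `FALSE`).
#' @return list with `chi2`, `df = 1`, `p_value`.
#' @export
contingency_chisq <- function(table, correction = FALSE) {
  table <- as.matrix(table)
  stopifnot(all(dim(table) == c(2L, 2L)))
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("zero margin in contingency table")
  }
  ct <- suppressWarnings(stats::chisq.test(table, correct = correction))
  list(chi2 = unname(ct$statistic), df = 1L, p_value = unname(ct$p.value))
}

#' Crossover (MLH1 focus) recombination map from chromosome spreads
#'
#' Positions of crossover-marking MLH1 foci along the synaptonemal complex
#' (SC) are rescaled to the mean SC length, binned into
#' `round(mean_length / target_bin)` equal intervals anchored at one
#' terminus, and expressed as the proportion of foci per bin — overall and
#' stratified by the number of foci on the bivalent. The mean centromere
#' position (rescaled) is reported for marking on the axis.
#'
#' @param spreads data.frame with one row per focus: `spread_id`,
#'   `sc_length` (micrometres), `centromere` (micrometres from the anchored
#'   terminus) and `focus_pos` (micrometres).
#' @param target_bin target bin width in micrometres (default 1).
#' @return a `recombination_map`: list with `bin_edges`, `proportions`
#'   (sums to 1), `by_class` (matrix, one row per foci-per-bivalent class,
#'   each row sums to 1), `n_foci`, `mean_sc_length`, `centromere`.
#' @export
mlh1_recombination_map <- function(spreads, target_bin = 1) {
  stopifnot(nrow(spreads) >= 1)
  bad <- spreads$focus_pos < 0 | spreads$focus_pos > spreads$sc_length
  if (any(bad)) {
    stop("focus outside [0, sc_length] in spread(s): ",
         paste(unique(spreads$spread_id[bad]), collapse = ", "))
  }
  per_spread <- unique(spreads[, c("spread_id", "sc_length", "centromere")])
  mean_len <- mean(per_spread$sc_length)
  n_bins <- max(1L, round(mean_len / target_bin))
  edges <- seq(0, mean_len, length.out = n_bins + 1L)
  scaled <- spreads$focus_pos * mean_len / spreads$sc_length
  bin <- pmin(findInterval(scaled, edges, rightmost.closed = TRUE), n_bins)
  bin <- pmax(bin, 1L)
  counts <- tabulate(bin, nbins = n_bins)
  foci_per <- table(spreads$spread_id)
  cls <- as.integer(foci_per[as.character(spreads$spread_id)])
  classes <- sort(unique(cls))
  by_class <- t(vapply(classes, function(cl) {
    b <- tabulate(bin[cls == cl], nbins = n_bins)
    b / sum(b)
  }, numeric(n_bins)))
  rownames(by_class) <- paste0("foci_", classes)
  cent <- mean(per_spread$centromere * mean_len / per_spread$sc_length)
  structure(list(bin_edges = edges,
                 proportions = counts / sum(counts),
                 by_class = by_class,
                 n_foci = sum(counts),
                 mean_sc_length = mean_len,
                 centromere = cent),
            class = "recombination_map")
}

#' Mann-Whitney U test with midrank ties and exact small-sample enumeration
#'
#' Computes the rank-sum U statistic with midranks for ties. For
#' `n1 + n2 <= 12` the null distribution is obtained by exact enumeration of
#' all group assignments of the pooled observations (valid under ties);
#' otherwise a normal approximation with tie-corrected variance and
#' continuity correction is used.
#'
#' @param x,y numeric samples (nonempty).
#' @param alternative `"two.sided"`, `"less"` or `"greater"` (of `x`
#'   relative to `y`).
#' @param exact force (`TRUE`) or suppress (`FALSE`) exact enumeration;
#'   `NULL` (default) switches on `n1 + n2 <= 12`.
#' @return list with `U` (statistic for sample `x`), `p_value`, `method`.
#' @export
mann_whitney_u <- function(x, y, alternative = c("two.sided", "less", "greater"),
                           exact = NULL) {
  alternative <- match.arg(alternative)
  if (!length(x) || !length(y)) stop("empty sample")
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (exact %||% (n1 + n2 <= 12L)) {
    if (n1 + n2 > 20L) stop("exact enumeration is limited to n1 + n2 <= 20")
    combos <- utils::combn(n1 + n2, n1)
    Udist <- colSums(matrix(r[combos], nrow = n1)) - n1 * (n1 + 1) / 2
    p <- switch(alternative,
                two.sided = min(1, mean(Udist <= min(U, n1 * n2 - U)) +
                                   mean(Udist >= max(U, n1 * n2 - U))),
                less = mean(Udist <= U),
                greater = mean(Udist >= U))
    return(list(U = U, p_value = p, method = "exact enumeration"))
  }
  N <- n1 + n2
  ties <- table(pooled)
  tie_term <- sum(ties^3 - ties) / (N * (N - 1))
  sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term)
  mu <- n1 * n2 / 2
  dev <- U - mu
  cc <- switch(alternative,                 # continuity correction
               two.sided = sign(dev) * 0.5, less = -0.5, greater = 0.5)
  z <- (dev - cc) / sqrt(sigma2)
  p <- switch(alternative,
              two.sided = 2 * stats::pnorm(-abs(z)),
              less = stats::pnorm(z),
              greater = stats::pnorm(z, lower.tail = FALSE))
  list(U = U, p_value = min(1, p), method = "normal approximation")
}

#' Reproduce a cytotype frequency table from grouped genotype counts
#'
#' Convenience wrapper producing, for each group, the heterozygote and
#' allele frequencies with standard errors plus the Hardy-Weinberg test —
#' the standard population summary for a chromosomal polymorphism.
#'
#' @param counts_list list of [genotype_counts()].
#' @return data.frame with one row per group: `group`, `n_MM`, `n_SM`,
#'   `n_SS`, `N`, `het_p`, `het_se`, `allele_p`, `allele_se`, `hwe_chi2`,
#'   `hwe_p`.
#' @export
cytotype_table <- function(counts_list) {
  do.call(rbind, lapply(counts_list, function(gc) {
    fr <- cytotype_frequencies(gc)
    hw <- hwe_test(gc)
    data.frame(group = gc$group, n_MM = gc$n_MM, n_SM = gc$n_SM,
               n_SS = gc$n_SS, N = gc$N,
               het_p = fr$het$p, het_se = fr$het$se,
               allele_p = fr$allele_M$p, allele_se = fr$allele_M$se,
               hwe_chi2 = hw$chi2, hwe_p = hw$p_value)
  }))
}
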