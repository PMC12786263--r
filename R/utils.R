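# Low-level sequence utilities shared across modules.
#
# Sequences are plain upper-case ACGT character scalars/vectors; intervals are
# 0-based half-open everywhere internally (BED convention). Human-readable
# report helpers convert to 1-based inclusive.

# byte -> 2-bit base code lookup (A=0, C=1, G=2, T=3; everything else NA)
.dna_lut <- local({
  lut <- rep(NA_real_, 256L)
  lut[utf8ToInt("A") + 1L] <- 0
  lut[utf8ToInt("C") + 1L] <- 1
  lut[utf8ToInt("G") + 1L] <- 2
  lut[utf8ToInt("T") + 1L] <- 3
  lut
})

#' Run code with a private, restorable RNG state
#'
#' Evaluates `expr` under `set.seed(seed)` and restores the caller's RNG
#' state afterwards, so seeded simulators do not perturb the session RNG.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Reverse complement of DNA strings
#'
#' Vectorised reverse complement (A/T and C/G swapped, any other character
#' kept); fast enough for millions of reads per call.
#'
#' @param x character vector of ACGT sequences.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  cpp_revcomp(x)
}

#' Random uniform i.i.d. DNA sequence
#'
#' @param n length in bp.
#' @return single character string of length `n`.
#' @keywords internal
random_dna <- function(n) {
  if (n == 0L) return("")
  rawToChar(as.raw(c(65L, 67L, 71L, 84L)[sample.int(4L, n, replace = TRUE)]))
}

# 2-bit rolling codes for every k-window of a single sequence.
# Returns numeric vector of length nchar(s) - k + 1 (NA where non-ACGT).
# Exact for k <= 26 (4^26 < 2^53).
encode_windows <- function(s, k) {
  stopifnot(k >= 1L, k <= 26L)
  v <- .dna_lut[as.integer(charToRaw(s)) + 1L]
  n <- length(v)
  if (n < k) return(numeric(0))
  # filter with weights 4^(0:(k-1)) gives, at position i, the code of the
  # window ENDING at i with the leftmost base most significant
  y <- stats::filter(v, 4^(0:(k - 1)), method = "convolution", sides = 1)
  as.numeric(y[k:n])
}

# Minimal period of a linear string: smallest p such that s is a prefix of
# an infinite repetition of s[1..p] and p divides nchar(s); otherwise nchar(s).
minimal_period_linear <- function(s) {
  n <- nchar(s)
  for (p in seq_len(n - 1L)) {
    if (n %% p != 0L) next
    if (identical(s, strrep(substr(s, 1L, p), n %/% p))) return(p)
  }
  n
}

# Minimal rotational period of a circular string (smallest divisor p of n
# with rotate(s, p) == s).
minimal_period_circular <- function(s) {
  n <- nchar(s)
  ss <- paste0(s, s)
  for (p in seq_len(n - 1L)) {
    if (n %% p != 0L) next
    if (identical(s, substr(ss, p + 1L, p + n))) return(p)
  }
  n
}

# All rotations of a string, as a character vector.
all_rotations <- function(s) {
  n <- nchar(s)
  ss <- paste0(s, s)
  substring(ss, seq_len(n), seq_len(n) + n - 1L)
}

#' Canonical rotation of a (possibly circular) repeat unit
#'
#' The lexicographically smallest string among all rotations of the unit and
#' all rotations of its reverse complement. Two tandem-repeat units that are
#' rotations and/or reverse complements of one another share the same
#' canonical rotation, which makes unit identity testable.
#'
#' @param s repeat unit sequence (character scalar).
#' @return character scalar, the canonical rotation.
#' @export
canonical_rotation <- function(s) {
  cand <- c(all_rotations(s), all_rotations(revcomp(s)))
  sort(cand, method = "radix")[1L]
}

# interval sanity check: 0-based half-open within [0, len]
check_interval <- function(start, end, len, what = "interval",
                           allow_empty = FALSE) {
  ok_order <- if (allow_empty) start <= end else start < end
  if (!(start >= 0 && ok_order && end <= len)) {
    stop(sprintf("%s [%s, %s) out of bounds for length %s",
                 what, format(start, scientific = FALSE),
                 format(end, scientific = FALSE),
                 format(len, scientific = FALSE)), call. = FALSE)
  }
  invisible(TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
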