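# IUPAC nucleotide algebra.
#
# Every sequence in the package is a plain character string over the IUPAC
# alphabet, stored uppercase with U normalized to T (DNA oligo context).
# Degenerate codes are represented internally as 4-bit masks (A=1, C=2, G=4,
# T=8); two codes "match" iff their base sets intersect, which is how a
# degenerate primer behaves during annealing.

IUPAC_CODES <- c(
  A = 1L, C = 2L, G = 4L, T = 8L,
  R = 5L,  # A/G
  Y = 10L, # C/T
  S = 6L,  # C/G
  W = 9L,  # A/T
  K = 12L, # G/T
  M = 3L,  # A/C
  B = 14L, # C/G/T
  D = 13L, # A/G/T
  H = 11L, # A/C/T
  V = 7L,  # A/C/G
  N = 15L
)

# complement by swapping A<->T, C<->G within each code's base set
IUPAC_COMP_FROM <- "ACGTRYSWKMBDHVN"
IUPAC_COMP_TO   <- "TGCAYRSWMKVHDBN"

# 256-slot lookup: byte value of an (uppercased) character -> bitmask, NA if invalid
.mask256 <- local({
  m <- rep(NA_integer_, 256L)
  m[utf8ToInt(paste(names(IUPAC_CODES), collapse = "")) + 1L] <- unname(IUPAC_CODES)
  m
})

#' Normalize and validate an IUPAC nucleotide string
#'
#' Uppercases the input, converts U to T, and rejects any character outside
#' the 15-letter IUPAC nucleotide alphabet.
#'
#' @param s character string (possibly empty).
#' @param what label used in error messages.
#' @return the normalized string.
#' @export
normalize_seq <- function(s, what = "sequence") {
  if (length(s) != 1L || !is.character(s) || is.na(s))
    stop(what, " must be a single character string")
  s <- chartr("u", "t", s)
  s <- toupper(s)
  s <- chartr("U", "T", s)
  if (nchar(s) == 0L) return(s)
  masks <- .mask256[as.integer(charToRaw(s)) + 1L]
  if (anyNA(masks)) {
    bad <- substr(s, which(is.na(masks))[1L], which(is.na(masks))[1L])
    stop("invalid IUPAC nucleotide code '", bad, "' in ", what)
  }
  s
}

# string -> integer bitmask vector (input assumed normalized)
seq_masks <- function(s) {
  if (nchar(s) == 0L) return(integer(0))
  .mask256[as.integer(charToRaw(s)) + 1L]
}

#' Do two IUPAC codes match?
#'
#' Two codes match iff the base sets they denote intersect, e.g. \code{R}
#' (A/G) matches \code{A} but not \code{C}; \code{N} matches everything.
#' Vectorized over both arguments; the relation is symmetric.
#'
#' @param a,b single IUPAC codes (character vectors of single letters).
#' @return logical vector.
#' @export
#' @examples
#' iupac_match("A", "R")  # TRUE
#' iupac_match("C", "R")  # FALSE
iupac_match <- function(a, b) {
  ma <- .code_masks(a)
  mb <- .code_masks(b)
  bitwAnd(ma, mb) > 0L
}

.code_masks <- function(x) {
  x <- toupper(as.character(x))
  x <- chartr("U", "T", x)
  if (any(nchar(x) != 1L))
    stop("expected single IUPAC codes, got multi-character string")
  m <- .mask256[as.integer(vapply(x, function(ch) as.integer(charToRaw(ch)), integer(1))) + 1L]
  if (anyNA(m)) stop("invalid IUPAC nucleotide code '", x[which(is.na(m))[1L]], "'")
  m
}

#' Reverse complement of an IUPAC string
#'
#' Degenerate codes map to the complement of their base set
#' (R<->Y, K<->M, B<->V, D<->H; S, W and N are self-complementary).
#'
#' @param s IUPAC nucleotide string.
#' @return the reverse complement, uppercase.
#' @export
#' @examples
#' revcomp("ACGT")                  # "ACGT"
#' revcomp("CCTTCYGCAGGTTCACCTAC") # "GTAGGTGAACCTGCRGAAGG"
revcomp <- function(s) {
  s <- normalize_seq(s)
  if (nchar(s) == 0L) return(s)
  comp <- chartr(IUPAC_COMP_FROM, IUPAC_COMP_TO, s)
  intToUtf8(rev(utf8ToInt(comp)))
}

#' Count mismatching positions between two equal-length IUPAC strings
#'
#' A position mismatches iff the two codes' base sets do not intersect
#' (so N never mismatches, R vs A does not mismatch, R vs C does).
#'
#' @param a,b IUPAC strings of equal length.
#' @return integer mismatch count in \code{[0, nchar(a)]}.
#' @export
mismatch_count <- function(a, b) {
  a <- normalize_seq(a, "first sequence")
  b <- normalize_seq(b, "second sequence")
  if (nchar(a) != nchar(b))
    stop("mismatch_count requires equal-length sequences (", nchar(a), " vs ", nchar(b), ")")
  sum(bitwAnd(seq_masks(a), seq_masks(b)) == 0L)
}

#' Degenerate expansion cardinality
#'
#' Number of concrete ACGT sequences a degenerate IUPAC string denotes:
#' the product of per-position base-set sizes.
#'
#' @param s IUPAC string.
#' @return numeric count (1 for the empty string).
#' @export
degeneracy <- function(s) {
  s <- normalize_seq(s)
  if (nchar(s) == 0L) return(1)
  bits <- vapply(seq_masks(s), function(m) sum(bitwAnd(m, c(1L, 2L, 4L, 8L)) > 0L), integer(1))
  prod(bits)
}

#' Expand a degenerate IUPAC string into its concrete sequences
#'
#' @param s IUPAC string; expansion must not exceed \code{max_expand}.
#' @param max_expand guard against combinatorial blow-up.
#' @return character vector of concrete ACGT sequences, lexicographic order.
#' @export
expand_iupac <- function(s, max_expand = 4096) {
  s <- normalize_seq(s)
  if (degeneracy(s) > max_expand)
    stop("degenerate expansion exceeds max_expand = ", max_expand)
  if (nchar(s) == 0L) return("")
  sets <- lapply(seq_masks(s), function(m) {
    c("A", "C", "G", "T")[bitwAnd(m, c(1L, 2L, 4L, 8L)) > 0L]
  })
  out <- Reduce(function(acc, set) {
    as.vector(t(outer(acc, set, paste0)))
  }, sets, accumulate = FALSE, init = "")
  sort(out)
}

#' GC fraction of an IUPAC string
#'
#' Each position contributes the G+C share of its code's base set
#' (S = 1, R = 0.5, N = 0.5, A = 0, ...), so degenerate strings get the
#' expectation over their expansion.
#'
#' @param s IUPAC string, non-empty.
#' @return fraction in \code{[0, 1]}.
#' @export
gc_fraction <- function(s) {
  s <- normalize_seq(s)
  if (nchar(s) == 0L) stop("gc_fraction of empty sequence")
  masks <- seq_masks(s)
  gc_bits <- vapply(masks, function(m) sum(bitwAnd(m, c(2L, 4L)) > 0L), integer(1))
  all_bits <- vapply(masks, function(m) sum(bitwAnd(m, c(1L, 2L, 4L, 8L)) > 0L), integer(1))
  mean(gc_bits / all_bits)
}

# Mismatch counts of `query` slid along `subject` at every plus-strand offset.
# Returns integer vector of length nchar(subject) - nchar(query) + 1 (0-based
# offset i-1 for element i); length 0 if the subject is shorter than the query.
slide_mismatches <- function(query, subject) {
  q <- seq_masks(query)
  s <- seq_masks(subject)
  nq <- length(q)
  ns <- length(s)
  if (nq == 0L) stop("empty query")
  noff <- ns - nq + 1L
  if (noff < 1L) return(integer(0))
  mm <- integer(noff)
  for (j in seq_len(nq)) {
    mm <- mm + (bitwAnd(q[j], s[j:(j + noff - 1L)]) == 0L)
  }
  mm
}
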