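# Design rules: the selection thresholds applied to blocking-primer candidates.

#' Blocking-primer design rules
#'
#' The thresholds a candidate window must satisfy: a minimum length of 20 nt
#' inside the hypervariable amplicon interior, no overlap with either
#' amplification-primer footprint, uniqueness on the host reference, and at
#' least three mismatching nucleotides against every off-target sequence so
#' the blocker cannot anneal to non-host templates. \code{max_len} bounds the
#' enumeration (a cap typical of synthesized blocking oligos);
#' \code{max_primer_site_mismatches} is the annealing tolerance used when
#' locating the amplification primers, 0 under degeneracy-aware matching
#' because the primers' IUPAC codes already encode the intended wobble.
#'
#' @param min_len minimum candidate length, nt.
#' @param max_len maximum candidate length, nt.
#' @param min_offtarget_mismatches minimum mismatch count required against
#'   every off-target sequence.
#' @param require_host_unique must the candidate occur exactly once on the
#'   host reference?
#' @param footprint_overlap_allowed may a candidate overlap an
#'   amplification-primer footprint? (Kept configurable; the default
#'   enforces strict non-overlap.)
#' @param max_primer_site_mismatches mismatch tolerance for amplification
#'   primer binding-site search in in-silico PCR.
#' @return an object of class \code{design_rules}.
#' @export
design_rules <- function(min_len = 20L,
                         max_len = 30L,
                         min_offtarget_mismatches = 3L,
                         require_host_unique = TRUE,
                         footprint_overlap_allowed = FALSE,
                         max_primer_site_mismatches = 0L) {
  min_len <- as.integer(min_len)
  max_len <- as.integer(max_len)
  min_offtarget_mismatches <- as.integer(min_offtarget_mismatches)
  max_primer_site_mismatches <- as.integer(max_primer_site_mismatches)
  if (is.na(min_len) || min_len < 1L) stop("min_len must be >= 1")
  if (is.na(max_len) || max_len < min_len) stop("max_len must be >= min_len")
  if (is.na(min_offtarget_mismatches) || min_offtarget_mismatches < 0L)
    stop("min_offtarget_mismatches must be >= 0")
  if (is.na(max_primer_site_mismatches) || max_primer_site_mismatches < 0L)
    stop("max_primer_site_mismatches must be >= 0")
  structure(list(min_len = min_len,
                 max_len = max_len,
                 min_offtarget_mismatches = min_offtarget_mismatches,
                 require_host_unique = isTRUE(require_host_unique),
                 footprint_overlap_allowed = isTRUE(footprint_overlap_allowed),
                 max_primer_site_mismatches = max_primer_site_mismatches),
            class = "design_rules")
}

#' @export
print.design_rules <- function(x, ...) {
  cat("Blocking-primer design rules\n")
  cat(sprintf("  candidate length:          %d-%d nt\n", x$min_len, x$max_len))
  cat(sprintf("  min off-target mismatches: %d\n", x$min_offtarget_mismatches))
  cat(sprintf("  require host-unique:       %s\n", x$require_host_unique))
  cat(sprintf("  footprint overlap allowed: %s\n", x$footprint_overlap_allowed))
  cat(sprintf("  primer-site mismatches:    <= %d (degeneracy-aware)\n",
              x$max_primer_site_mismatches))
  invisible(x)
}
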