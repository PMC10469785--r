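# In-silico PCR: primer binding-site search and amplicon extraction.
#
# Coordinates are 0-based half-open on the template plus strand everywhere
# in this package; `end - start` always equals the length of the slice.

.template_id <- function(template, default = "template") {
  id <- names(template)
  if (is.null(id) || !nzchar(id[1])) default else id[1]
}

#' Locate primer binding sites on a template
#'
#' Exhaustive degeneracy-aware scan of every offset on both strands. The
#' adapter tail, if the oligo declares one, is excluded: only the
#' gene-specific portion binds. A site on the minus strand means the primer
#' anneals to the plus strand as drawn, i.e. the reverse complement of the
#' gene-specific sequence occurs at the reported plus-strand interval.
#'
#' @param template length-1 named character vector (name = template id).
#' @param primer a \code{\link{primer_oligo}} or plain sequence string.
#' @param max_mismatches maximum mismatches for a reported site.
#' @return data.frame with columns template_id, start, end (0-based
#'   half-open, plus strand), strand ("+"/"-"), mismatches, primer_name,
#'   sorted by ascending start then strand.
#' @export
find_binding_sites <- function(template, primer, max_mismatches = 0L) {
  primer <- as_primer_oligo(primer, role = "amplification_forward")
  tid <- .template_id(template)
  tseq <- normalize_seq(unname(template[1]), "template")
  if (nchar(tseq) == 0L) stop("template is empty")
  gs <- primer$gene_specific
  hits <- list()
  for (strand in c("+", "-")) {
    q <- if (strand == "+") gs else revcomp(gs)
    mm <- slide_mismatches(q, tseq)
    keep <- which(mm <= max_mismatches)
    if (length(keep)) {
      hits[[strand]] <- data.frame(
        template_id = tid,
        start = keep - 1L,
        end = keep - 1L + nchar(gs),
        strand = strand,
        mismatches = mm[keep],
        primer_name = primer$name,
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(hits)) do.call(rbind, unname(hits)) else
    data.frame(template_id = character(0), start = integer(0), end = integer(0),
               strand = character(0), mismatches = integer(0),
               primer_name = character(0), stringsAsFactors = FALSE)
  out <- out[order(out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# classed conditions so the simulator can distinguish failure modes
.no_amplicon <- function(msg) {
  stop(structure(class = c("bp_no_amplicon", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}
.ambiguous_amplicon <- function(msg) {
  stop(structure(class = c("bp_ambiguous_amplicon", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

#' Extract the amplicon implied by a primer pair
#'
#' Finds the forward primer on the plus strand and the reverse primer on the
#' minus strand, requires a unique productive pairing (forward footprint
#' upstream of, and not overlapping, the reverse footprint), and returns the
#' amplicon together with its interior -- the region strictly between the
#' two footprints, which for an 18S V9 assay is the hypervariable stretch
#' eligible for blocking-primer placement.
#'
#' @param template length-1 named character vector.
#' @param fwd forward amplification \code{\link{primer_oligo}}.
#' @param rev reverse amplification \code{\link{primer_oligo}}.
#' @param rules a \code{\link{design_rules}} object (supplies
#'   \code{max_primer_site_mismatches}).
#' @return an object of class \code{amplicon_map}: template_id,
#'   amplicon_start/end, interior_start/end (all 0-based half-open, plus
#'   strand) and the two footprint rows.
#' @export
extract_amplicon <- function(template, fwd, rev, rules = design_rules()) {
  fwd <- as_primer_oligo(fwd, role = "amplification_forward")
  rev <- as_primer_oligo(rev, role = "amplification_reverse")
  if (fwd$role != "amplification_forward")
    stop("fwd must have role amplification_forward")
  if (rev$role != "amplification_reverse")
    stop("rev must have role amplification_reverse")
  mm <- rules$max_primer_site_mismatches
  fsites <- find_binding_sites(template, fwd, mm)
  fsites <- fsites[fsites$strand == "+", , drop = FALSE]
  rsites <- find_binding_sites(template, rev, mm)
  rsites <- rsites[rsites$strand == "-", , drop = FALSE]
  tid <- .template_id(template)
  if (nrow(fsites) == 0L)
    .no_amplicon(sprintf("no amplicon on '%s': no plus-strand binding site for forward primer '%s'",
                         tid, fwd$name))
  if (nrow(rsites) == 0L)
    .no_amplicon(sprintf("no amplicon on '%s': no minus-strand binding site for reverse primer '%s'",
                         tid, rev$name))
  pairs <- expand.grid(fi = seq_len(nrow(fsites)), ri = seq_len(nrow(rsites)))
  productive <- pairs[fsites$end[pairs$fi] <= rsites$start[pairs$ri], , drop = FALSE]
  if (nrow(productive) == 0L)
    .no_amplicon(sprintf("no amplicon on '%s': no productive orientation of '%s'/'%s'",
                         tid, fwd$name, rev$name))
  if (nrow(productive) > 1L) {
    desc <- apply(productive, 1, function(p) {
      sprintf("[%d,%d)+[%d,%d)", fsites$start[p[1]], fsites$end[p[1]],
              rsites$start[p[2]], rsites$end[p[2]])
    })
    .ambiguous_amplicon(sprintf("ambiguous amplicon on '%s': %d productive pairings: %s",
                                tid, nrow(productive), paste(desc, collapse = ", ")))
  }
  f <- fsites[productive$fi[1], ]
  r <- rsites[productive$ri[1], ]
  structure(list(template_id = tid,
                 amplicon_start = f$start,
                 amplicon_end = r$end,
                 interior_start = f$end,
                 interior_end = r$start,
                 fwd_footprint = f,
                 rev_footprint = r),
            class = "amplicon_map")
}

#' @export
print.amplicon_map <- function(x, ...) {
  cat(sprintf("Amplicon on '%s': [%d,%d) (%d nt)\n", x$template_id,
              x$amplicon_start, x$amplicon_end, x$amplicon_end - x$amplicon_start))
  cat(sprintf("  forward footprint %s: [%d,%d) %d mismatch(es)\n",
              x$fwd_footprint$primer_name, x$fwd_footprint$start,
              x$fwd_footprint$end, x$fwd_footprint$mismatches))
  cat(sprintf("  reverse footprint %s: [%d,%d) %d mismatch(es)\n",
              x$rev_footprint$primer_name, x$rev_footprint$start,
              x$rev_footprint$end, x$rev_footprint$mismatches))
  cat(sprintf("  interior (blocker-eligible): [%d,%d) (%d nt)\n",
              x$interior_start, x$interior_end, x$interior_end - x$interior_start))
  invisible(x)
}

#' Write an amplicon map as TSV
#'
#' @param map an \code{amplicon_map}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_amplicon_tsv <- function(map, path) {
  df <- data.frame(template_id = map$template_id,
                   amplicon_start = map$amplicon_start,
                   amplicon_end = map$amplicon_end,
                   interior_start = map$interior_start,
                   interior_end = map$interior_end,
                   fwd_mismatches = map$fwd_footprint$mismatches,
                   rev_mismatches = map$rev_footprint$mismatches,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
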