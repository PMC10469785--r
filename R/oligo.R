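# Primer oligos and the packaged oligo table.

#' Construct a primer oligo
#'
#' A primer oligo is the 5'->3' gene-specific sequence plus an optional 5'
#' adapter tail (a sequencing-platform prefix that never takes part in
#' template binding) and an optional 3' terminator. Blocking oligos carry a
#' C3 spacer -- a three-carbon 3' modification that lets the oligo anneal but
#' prevents the polymerase from extending it, which is what arrests
#' elongation across the host template. Amplification oligos must be
#' extensible, so they carry no terminator.
#'
#' @param name oligo name.
#' @param gene_specific 5'->3' gene-specific (template-binding) sequence;
#'   IUPAC degeneracy allowed.
#' @param role one of \code{"amplification_forward"},
#'   \code{"amplification_reverse"}, \code{"blocking"}.
#' @param adapter_tail optional 5' adapter prefix (excluded from binding-site
#'   search), or \code{NULL}.
#' @param terminator \code{"none"} or \code{"C3_spacer"}; defaults to
#'   \code{"C3_spacer"} for blocking oligos and \code{"none"} otherwise.
#' @return an object of class \code{primer_oligo}.
#' @export
primer_oligo <- function(name, gene_specific, role,
                         adapter_tail = NULL,
                         terminator = if (role == "blocking") "C3_spacer" else "none") {
  role <- match.arg(role, c("amplification_forward", "amplification_reverse", "blocking"))
  terminator <- match.arg(terminator, c("none", "C3_spacer"))
  if (role == "blocking" && terminator != "C3_spacer")
    stop("blocking oligos must carry a C3_spacer terminator")
  if (role != "blocking" && terminator != "none")
    stop("amplification oligos must not carry a 3' terminator")
  gene_specific <- normalize_seq(gene_specific, paste0("gene-specific sequence of '", name, "'"))
  if (nchar(gene_specific) < 1L) stop("gene_specific must be non-empty")
  if (!is.null(adapter_tail) && nzchar(adapter_tail))
    adapter_tail <- normalize_seq(adapter_tail, paste0("adapter tail of '", name, "'"))
  else
    adapter_tail <- NULL
  structure(list(name = as.character(name),
                 gene_specific = gene_specific,
                 adapter_tail = adapter_tail,
                 role = role,
                 terminator = terminator),
            class = "primer_oligo")
}

#' @method format primer_oligo
#' @export
format.primer_oligo <- function(x, ...) {
  tail <- if (is.null(x$adapter_tail)) "" else x$adapter_tail
  spc <- if (x$terminator == "C3_spacer") "[SpcC3]" else ""
  sprintf("%s (%s): 5'-%s%s%s-3'", x$name, x$role, tail, x$gene_specific, spc)
}

#' @export
print.primer_oligo <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

as_primer_oligo <- function(x, role = "blocking", name = NULL) {
  if (inherits(x, "primer_oligo")) return(x)
  seq <- sub("\\[SpcC3\\]$", "", as.character(x))
  primer_oligo(name %||% "oligo", seq, role = role)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Packaged oligo table
#'
#' The amplification primers for the 16S V3-V4 (341F/785R) and 18S V9
#' (1389F/1015R) regions, and the two black soldier fly
#' (\emph{Hermetia illucens}) V9 blocking primers BP-F_Hi_V9 and BP-R_Hi_V9,
#' with their shared Illumina adapter tail annotated. All carry their
#' published sequences; the blocking primers are 3'-modified with a C3
#' spacer.
#'
#' @return data.frame with columns name, role, adapter_tail, gene_specific,
#'   terminator.
#' @export
bp_oligo_table <- function() {
  path <- system.file("extdata", "oligos.tsv", package = "bpdesign", mustWork = TRUE)
  utils::read.delim(path, sep = "\t", comment.char = "#",
                    colClasses = "character")
}

#' Look up a packaged oligo by name
#'
#' @param name oligo name as listed by \code{\link{bp_oligo_table}}
#'   (e.g. "1389F", "BP-F_Hi_V9").
#' @return a \code{\link{primer_oligo}}.
#' @export
bp_oligo <- function(name) {
  tab <- bp_oligo_table()
  i <- match(name, tab$name)
  if (is.na(i)) stop("unknown packaged oligo '", name, "'; see bp_oligo_table()")
  primer_oligo(tab$name[i], tab$gene_specific[i], role = tab$role[i],
               adapter_tail = if (nzchar(tab$adapter_tail[i])) tab$adapter_tail[i] else NULL,
               terminator = tab$terminator[i])
}
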