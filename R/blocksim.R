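# In-silico efficacy evaluation of a blocking-primer set on a mock community.
#
# Binding model: a blocker anneals wherever it matches a template with at
# most `t_block` mismatches (degeneracy-aware, ungapped, either strand).
# Annealing arrests elongation only when the hit lies strictly inside the
# amplicon interior -- a hit overlapping a primer footprint is reported but
# does not block, because elongation-arrest blockers act between the two
# amplification primers, not at their binding sites. Outcomes are binary
# per template: no PCR-efficiency or cycle-level modelling.

#' Predict the amplification outcome of one template
#'
#' A template amplifies iff the primer pair yields a unique amplicon and no
#' blocker attains \code{<= t_block} mismatches anywhere strictly inside the
#' amplicon interior (either strand); otherwise it is blocked. Templates
#' without a (unique) amplicon are \code{no_amplicon}; an ambiguous amplicon
#' is reported with its own reason so community summaries can count it
#' separately.
#'
#' @param template length-1 named character vector.
#' @param fwd,rev amplification \code{\link{primer_oligo}}s.
#' @param blockers list of blocking \code{\link{primer_oligo}}s (may be
#'   empty).
#' @param t_block mismatch threshold at or below which a blocker is
#'   considered bound; defaults to one less than the design rules'
#'   off-target minimum so design and simulation are mutually consistent.
#' @param rules a \code{\link{design_rules}} object.
#' @return object of class \code{template_outcome}: template_id,
#'   has_amplicon, outcome ("amplified"/"blocked"/"no_amplicon"), reason,
#'   ambiguous flag, and the data.frame of blocking hits (blocker, offset,
#'   strand, mismatches, in_interior, blocks).
#' @export
predict_outcome <- function(template, fwd, rev, blockers,
                            t_block = design_rules()$min_offtarget_mismatches - 1L,
                            rules = design_rules()) {
  if (t_block < 0L) stop("t_block must be >= 0")
  blockers <- lapply(blockers, as_primer_oligo, role = "blocking")
  for (b in blockers)
    if (b$role != "blocking") stop("all blockers must have role 'blocking'")
  tid <- .template_id(template)
  hits0 <- data.frame(blocker = character(0), offset = integer(0),
                      strand = character(0), mismatches = integer(0),
                      in_interior = logical(0), blocks = logical(0),
                      stringsAsFactors = FALSE)

  amp <- tryCatch(extract_amplicon(template, fwd, rev, rules),
                  bp_no_amplicon = function(e) e,
                  bp_ambiguous_amplicon = function(e) e)
  if (inherits(amp, "condition")) {
    return(structure(list(template_id = tid, has_amplicon = FALSE,
                          outcome = "no_amplicon",
                          reason = conditionMessage(amp),
                          ambiguous = inherits(amp, "bp_ambiguous_amplicon"),
                          hits = hits0, amplicon = NULL),
                     class = "template_outcome"))
  }

  tseq <- normalize_seq(unname(template[1]), "template")
  rows <- list()
  for (b in blockers) {
    len <- nchar(b$gene_specific)
    for (strand in c("+", "-")) {
      q <- if (strand == "+") b$gene_specific else revcomp(b$gene_specific)
      mm <- slide_mismatches(q, tseq)
      keep <- which(mm <= t_block)
      for (i in keep) {
        s0 <- i - 1L
        inside <- s0 >= amp$interior_start && (s0 + len) <= amp$interior_end
        rows[[length(rows) + 1L]] <- data.frame(
          blocker = b$name, offset = s0, strand = strand,
          mismatches = mm[i], in_interior = inside, blocks = inside,
          stringsAsFactors = FALSE)
      }
    }
  }
  hits <- if (length(rows)) do.call(rbind, rows) else hits0
  blocked <- any(hits$blocks)
  structure(list(template_id = tid, has_amplicon = TRUE,
                 outcome = if (blocked) "blocked" else "amplified",
                 reason = if (blocked)
                   sprintf("blocker hit with <= %d mismatch(es) inside interior", t_block)
                 else "no blocker bound inside interior",
                 ambiguous = FALSE, hits = hits, amplicon = amp),
            class = "template_outcome")
}

#' @export
print.template_outcome <- function(x, ...) {
  cat(sprintf("'%s': %s (%s)\n", x$template_id, x$outcome, x$reason))
  if (nrow(x$hits)) {
    cat(sprintf("  %d blocker hit(s), %d inside interior\n",
                nrow(x$hits), sum(x$hits$in_interior)))
  }
  invisible(x)
}

#' Simulate blocking on a mock community
#'
#' Applies \code{\link{predict_outcome}} to every template and aggregates:
#' host suppression is the fraction of designated host templates predicted
#' blocked among those that would otherwise amplify; collateral blocking is
#' the same fraction over non-host templates (off-target templates
#' erroneously arrested).
#'
#' @param community named character vector of template sequences.
#' @param host_ids character vector of ids designating host templates
#'   (must be a subset of the community ids).
#' @param fwd,rev amplification \code{\link{primer_oligo}}s.
#' @param blockers list of blocking \code{\link{primer_oligo}}s.
#' @param t_block blocker binding mismatch threshold.
#' @param rules a \code{\link{design_rules}} object.
#' @return object of class \code{block_report}: \code{per_template}
#'   data.frame, \code{host_suppression}, \code{collateral_blocking},
#'   \code{counts} per outcome class (plus ambiguous).
#' @export
simulate_community <- function(community, host_ids, fwd, rev, blockers,
                               t_block = design_rules()$min_offtarget_mismatches - 1L,
                               rules = design_rules()) {
  if (length(community) == 0L) stop("community is empty")
  ids <- names(community)
  if (is.null(ids) || any(!nzchar(ids))) stop("every community template needs an id")
  if (!all(host_ids %in% ids))
    stop("host ids not present in community: ",
         paste(setdiff(host_ids, ids), collapse = ", "))

  rows <- vector("list", length(community))
  for (i in seq_along(community)) {
    oc <- predict_outcome(community[i], fwd, rev, blockers, t_block, rules)
    best <- if (nrow(oc$hits)) oc$hits[which.min(oc$hits$mismatches), ] else NULL
    rows[[i]] <- data.frame(
      template_id = ids[i],
      is_host = ids[i] %in% host_ids,
      has_amplicon = oc$has_amplicon,
      outcome = oc$outcome,
      ambiguous = oc$ambiguous,
      best_blocker = if (is.null(best)) NA_character_ else best$blocker,
      best_offset = if (is.null(best)) NA_integer_ else best$offset,
      best_strand = if (is.null(best)) NA_character_ else best$strand,
      best_mismatches = if (is.null(best)) NA_integer_ else best$mismatches,
      reason = oc$reason,
      stringsAsFactors = FALSE)
  }
  per <- do.call(rbind, rows)

  frac_blocked <- function(subset) {
    amp <- subset[subset$has_amplicon, , drop = FALSE]
    if (nrow(amp) == 0L) return(NA_real_)
    sum(amp$outcome == "blocked") / nrow(amp)
  }
  counts <- c(amplified = sum(per$outcome == "amplified"),
              blocked = sum(per$outcome == "blocked"),
              no_amplicon = sum(per$outcome == "no_amplicon"),
              ambiguous = sum(per$ambiguous))
  structure(list(per_template = per,
                 host_suppression = frac_blocked(per[per$is_host, , drop = FALSE]),
                 collateral_blocking = frac_blocked(per[!per$is_host, , drop = FALSE]),
                 counts = counts,
                 n = nrow(per),
                 t_block = as.integer(t_block)),
            class = "block_report")
}

#' @export
print.block_report <- function(x, ...) {
  cat(sprintf("Mock-community blocking report (%d templates, t_block = %d)\n",
              x$n, x$t_block))
  cat(sprintf("  amplified %d | blocked %d | no amplicon %d (ambiguous %d)\n",
              x$counts[["amplified"]], x$counts[["blocked"]],
              x$counts[["no_amplicon"]], x$counts[["ambiguous"]]))
  cat(sprintf("  host suppression:    %s\n", .fmt_frac(x$host_suppression)))
  cat(sprintf("  collateral blocking: %s\n", .fmt_frac(x$collateral_blocking)))
  invisible(x)
}

.fmt_frac <- function(f) if (is.na(f)) "NA (no amplifiable templates)" else sprintf("%.3f", f)

#' Write a block report as TSV + JSON
#'
#' @param report a \code{block_report}.
#' @param tsv_path per-template TSV path (NULL to skip).
#' @param json_path machine-readable summary JSON path (NULL to skip).
#' @return the report, invisibly.
#' @export
write_block_report <- function(report, tsv_path = NULL, json_path = NULL) {
  if (!is.null(tsv_path)) {
    con <- file(tsv_path, open = "wb")
    writeLines(paste(names(report$per_template), collapse = "\t"), con, sep = "\n")
    if (nrow(report$per_template))
      writeLines(do.call(paste, c(lapply(report$per_template, as.character), sep = "\t")),
                 con, sep = "\n")
    close(con)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(n_templates = report$n,
           t_block = report$t_block,
           counts = as.list(report$counts),
           host_suppression = report$host_suppression,
           collateral_blocking = report$collateral_blocking),
      json_path, auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
  }
  invisible(report)
}
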