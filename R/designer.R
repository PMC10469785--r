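# Blocking-primer candidate enumeration, screening, ranking and validation.
#
# Selection rules: candidates are windows of at least `min_len` nt lying
# entirely inside the amplicon interior (never overlapping a primer
# footprint), unique on the host reference, and at least
# `min_offtarget_mismatches` mismatches away from every off-target sequence
# under an ungapped degeneracy-aware sliding comparison on both strands.

#' Enumerate candidate blocking-primer windows
#'
#' Every window of length \code{min_len..max_len} fully inside the amplicon
#' interior, in both orientations (the strand records which strand the
#' synthesized oligo would have; elongation arrest can target either the
#' forward- or reverse-extension pass). No window overlaps an
#' amplification-primer footprint by even one nucleotide, by construction.
#'
#' @param amplicon an \code{amplicon_map} extracted from \code{host}.
#' @param host length-1 named character vector, the host reference.
#' @param rules a \code{\link{design_rules}} object.
#' @return data.frame of candidate windows (host_id, start, end, strand,
#'   seq, gc_fraction); zero rows (with a warning) if the interior is
#'   shorter than \code{min_len}.
#' @export
enumerate_candidates <- function(amplicon, host, rules = design_rules()) {
  hseq <- normalize_seq(unname(host[1]), "host")
  hid <- .template_id(host, "host")
  is_len <- amplicon$interior_end - amplicon$interior_start
  empty <- data.frame(host_id = character(0), start = integer(0), end = integer(0),
                      strand = character(0), seq = character(0),
                      gc_fraction = numeric(0), stringsAsFactors = FALSE)
  if (is_len < rules$min_len) {
    warning(sprintf("amplicon interior (%d nt) shorter than min_len (%d): no candidate windows",
                    is_len, rules$min_len))
    return(empty)
  }
  lens <- rules$min_len:min(rules$max_len, is_len)
  rows <- list()
  for (L in lens) {
    starts <- amplicon$interior_start:(amplicon$interior_end - L)
    rows[[length(rows) + 1L]] <- data.frame(start = starts, end = starts + L)
  }
  win <- do.call(rbind, rows)
  win <- win[order(win$start, win$end), , drop = FALSE]
  plus_seq <- substring(hseq, win$start + 1L, win$end)
  out <- rbind(
    data.frame(host_id = hid, start = win$start, end = win$end, strand = "+",
               seq = plus_seq, stringsAsFactors = FALSE),
    data.frame(host_id = hid, start = win$start, end = win$end, strand = "-",
               seq = vapply(plus_seq, revcomp, character(1), USE.NAMES = FALSE),
               stringsAsFactors = FALSE))
  out <- out[order(out$start, out$end, out$strand), , drop = FALSE]
  out$gc_fraction <- vapply(out$seq, gc_fraction, numeric(1), USE.NAMES = FALSE)
  rownames(out) <- NULL
  out
}

#' Count occurrences of a candidate on the host
#'
#' Degeneracy-aware exact (0-mismatch) occurrences of the oligo sequence on
#' either strand of the full host, counted as distinct plus-strand
#' intervals (a palindromic oligo matching both strands of one locus counts
#' once).
#'
#' @param seq candidate oligo sequence (5'->3').
#' @param host length-1 named character vector.
#' @return integer copy count (>= 1 whenever the candidate was cut from the
#'   host).
#' @export
host_uniqueness <- function(seq, host) {
  seq <- normalize_seq(seq, "candidate")
  if (nchar(seq) == 0L) stop("candidate sequence is empty")
  hseq <- normalize_seq(unname(host[1]), "host")
  offs <- integer(0)
  for (q in unique(c(seq, revcomp(seq)))) {
    mm <- slide_mismatches(q, hseq)
    offs <- c(offs, which(mm == 0L) - 1L)
  }
  length(unique(offs))
}

# Best ungapped semi-global match of query against subject on one strand:
# the query is slid along the subject; if the subject is shorter, the
# subject is slid along the query instead (full-overlap diagonals of the
# shorter length) and uncovered query positions count as mismatches.
# Returns list(mismatches, offset) where offset is the 0-based plus-strand
# position of the query start on the subject (negative if the subject is
# shorter and the query overhangs its 5' end).
.best_offset_match <- function(query, subject) {
  nq <- nchar(query)
  ns <- nchar(subject)
  if (ns >= nq) {
    mm <- slide_mismatches(query, subject)
    i <- which.min(mm)
    list(mismatches = mm[i], offset = i - 1L)
  } else {
    mm <- slide_mismatches(subject, query) + (nq - ns)
    i <- which.min(mm)
    list(mismatches = mm[i], offset = -(i - 1L))
  }
}

#' Screen a candidate against an off-target library
#'
#' For each off-target, the minimum mismatch count over every ungapped
#' offset on both strands (semi-global: the candidate slides along the
#' off-target; off-targets shorter than the candidate are compared over all
#' full-overlap diagonals with uncovered candidate positions counted as
#' mismatches). The candidate passes when the aggregate minimum is at least
#' \code{rules$min_offtarget_mismatches}. An empty library yields an
#' explicit "unscreened" result, never a silent pass.
#'
#' @param seq candidate oligo sequence (5'->3').
#' @param offtargets named character vector of off-target sequences.
#' @param rules a \code{\link{design_rules}} object.
#' @return object of class \code{screen_result}: \code{per_target}
#'   data.frame (offtarget_id, mismatches, offset, strand),
#'   \code{min_mismatches} (NA if unscreened), \code{unscreened},
#'   \code{pass} (NA if unscreened).
#' @export
specificity_screen <- function(seq, offtargets, rules = design_rules()) {
  seq <- normalize_seq(seq, "candidate")
  if (nchar(seq) == 0L) stop("candidate sequence is empty")
  if (length(offtargets) == 0L) {
    return(structure(list(
      per_target = data.frame(offtarget_id = character(0), mismatches = integer(0),
                              offset = integer(0), strand = character(0),
                              stringsAsFactors = FALSE),
      min_mismatches = NA_integer_, unscreened = TRUE, pass = NA),
      class = "screen_result"))
  }
  ids <- names(offtargets) %||% paste0("offtarget_", seq_along(offtargets))
  rc <- revcomp(seq)
  rows <- vector("list", length(offtargets))
  for (i in seq_along(offtargets)) {
    subj <- normalize_seq(unname(offtargets[i]), paste0("off-target '", ids[i], "'"))
    best_p <- .best_offset_match(seq, subj)
    best_m <- .best_offset_match(rc, subj)
    if (best_p$mismatches <= best_m$mismatches) {
      rows[[i]] <- data.frame(offtarget_id = ids[i], mismatches = best_p$mismatches,
                              offset = best_p$offset, strand = "+",
                              stringsAsFactors = FALSE)
    } else {
      rows[[i]] <- data.frame(offtarget_id = ids[i], mismatches = best_m$mismatches,
                              offset = best_m$offset, strand = "-",
                              stringsAsFactors = FALSE)
    }
  }
  per <- do.call(rbind, rows)
  agg <- min(per$mismatches)
  structure(list(per_target = per,
                 min_mismatches = as.integer(agg),
                 unscreened = FALSE,
                 pass = agg >= rules$min_offtarget_mismatches),
            class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  if (x$unscreened) {
    cat("Specificity screen: UNSCREENED (empty off-target library)\n")
  } else {
    cat(sprintf("Specificity screen: min %d mismatch(es) over %d off-target(s) -> %s\n",
                x$min_mismatches, nrow(x$per_target),
                if (isTRUE(x$pass)) "pass" else "FAIL"))
  }
  invisible(x)
}

#' Rank screened candidates
#'
#' Stable sort by descending minimum off-target mismatches, then GC fraction
#' closest to 0.5, then shorter length, then 5'-most start. The ranking keys
#' are a tool convention (advisory, flagged in report headers): the design
#' rules define acceptability, not an ordering.
#'
#' @param candidates data.frame with columns min_offtarget_mismatches,
#'   gc_fraction, start, end (as produced by the design pipeline).
#' @return the same data.frame, reordered; unscreened (NA) candidates sort
#'   last.
#' @export
rank_candidates <- function(candidates) {
  if (nrow(candidates) == 0L) return(candidates)
  key1 <- ifelse(is.na(candidates$min_offtarget_mismatches),
                 -Inf, candidates$min_offtarget_mismatches)
  o <- order(-key1,
             abs(candidates$gc_fraction - 0.5),
             candidates$end - candidates$start,
             candidates$start,
             method = "radix")
  out <- candidates[o, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Convert top-ranked accepted candidates into blocking oligos
#'
#' @param ranked ranked candidate data.frame (must carry a \code{status}
#'   column).
#' @param k number of blocking primers wanted; if fewer candidates are
#'   accepted, all accepted are returned with a warning.
#' @return list of blocking \code{\link{primer_oligo}}s (C3-spacer
#'   terminated), named \code{<host id>:<start>-<end>:<strand>}.
#' @export
emit_blocking_primers <- function(ranked, k = 1L) {
  if (k < 1L) stop("k must be >= 1")
  acc <- ranked[ranked$status == "accepted", , drop = FALSE]
  if (nrow(acc) < k)
    warning(sprintf("only %d accepted candidate(s) available (requested %d)",
                    nrow(acc), k))
  acc <- utils::head(acc, k)
  lapply(seq_len(nrow(acc)), function(i) {
    primer_oligo(sprintf("%s:%d-%d:%s", acc$host_id[i], acc$start[i],
                         acc$end[i], acc$strand[i]),
                 acc$seq[i], role = "blocking", terminator = "C3_spacer")
  })
}

.RULE_IDS <- c(length = "length", host_locus = "host_locus",
               in_interior = "in_interior", footprint = "footprint_overlap",
               unique = "host_unique", offtarget = "offtarget_mismatches")

#' Validate a blocking primer against the design rules
#'
#' Checks an externally supplied blocking oligo (for example a published
#' one) rule by rule: length, mapping to the host (0-mismatch
#' degeneracy-aware, either strand), containment in the amplicon interior,
#' footprint non-overlap, host copy count, and off-target mismatch minimum
#' (reported "unscreened" when no library is given). A oligo that does not
#' map to the host yields a report with a "no host locus" failure, not an
#' error.
#'
#' @param oligo blocking \code{\link{primer_oligo}} or plain sequence
#'   (trailing "[SpcC3]" accepted and stripped).
#' @param amplicon \code{amplicon_map} on the host.
#' @param host length-1 named character vector.
#' @param offtargets named character vector (possibly empty/NULL).
#' @param rules a \code{\link{design_rules}} object.
#' @return object of class \code{bp_validation}: \code{checks} data.frame
#'   (rule, value, threshold, pass), \code{verdict} (TRUE/FALSE),
#'   \code{unscreened}, plus the mapped locus if any.
#' @export
validate_blocking_primer <- function(oligo, amplicon, host, offtargets = NULL,
                                     rules = design_rules()) {
  oligo <- as_primer_oligo(oligo, role = "blocking")
  if (oligo$role != "blocking") stop("oligo must have role 'blocking'")
  gs <- oligo$gene_specific
  hseq <- normalize_seq(unname(host[1]), "host")
  len <- nchar(gs)

  loci <- list()
  for (strand in c("+", "-")) {
    q <- if (strand == "+") gs else revcomp(gs)
    mm <- slide_mismatches(q, hseq)
    for (s0 in which(mm == 0L) - 1L)
      loci[[length(loci) + 1L]] <- list(start = s0, end = s0 + len, strand = strand)
  }
  # distinct plus-strand intervals (palindrome double-hit collapses)
  if (length(loci)) {
    key <- vapply(loci, function(l) paste0(l$start, ":", l$end), character(1))
    loci <- loci[!duplicated(key)]
  }
  n_loci <- length(loci)

  in_interior <- vapply(loci, function(l)
    l$start >= amplicon$interior_start && l$end <= amplicon$interior_end, logical(1))
  primary <- if (n_loci == 0L) NULL else if (any(in_interior))
    loci[[which(in_interior)[1L]]] else loci[[1L]]

  overlaps <- function(l, fp) l$start < fp$end && fp$start < l$end
  fp_overlap <- if (is.null(primary)) NA else
    overlaps(primary, amplicon$fwd_footprint) || overlaps(primary, amplicon$rev_footprint)

  screen <- if (is.null(offtargets) || length(offtargets) == 0L)
    specificity_screen(gs, character(0), rules) else
    specificity_screen(gs, offtargets, rules)

  checks <- data.frame(
    rule = c("length", "host_locus", "in_interior", "footprint_overlap",
             "host_unique", "offtarget_mismatches"),
    value = c(as.character(len),
              if (n_loci == 0L) "no host locus" else as.character(n_loci),
              if (is.null(primary)) NA_character_ else as.character(any(in_interior)),
              if (is.null(primary)) NA_character_ else as.character(!fp_overlap),
              as.character(n_loci),
              if (screen$unscreened) "unscreened" else as.character(screen$min_mismatches)),
    threshold = c(sprintf(">= %d", rules$min_len), ">= 1", "TRUE",
                  if (rules$footprint_overlap_allowed) "(not enforced)" else "no overlap",
                  if (rules$require_host_unique) "== 1" else "(not enforced)",
                  sprintf(">= %d", rules$min_offtarget_mismatches)),
    pass = c(len >= rules$min_len,
             n_loci >= 1L,
             if (n_loci == 0L) NA else any(in_interior),
             if (n_loci == 0L) NA else (rules$footprint_overlap_allowed || !fp_overlap),
             if (n_loci == 0L) NA else (!rules$require_host_unique || n_loci == 1L),
             if (screen$unscreened) NA else screen$pass),
    stringsAsFactors = FALSE)

  evaluated <- checks$pass[!is.na(checks$pass)]
  verdict <- n_loci >= 1L && all(evaluated)
  structure(list(oligo = oligo, checks = checks, verdict = verdict,
                 unscreened = screen$unscreened, screen = screen,
                 locus = primary, n_loci = n_loci),
            class = "bp_validation")
}

#' @export
print.bp_validation <- function(x, ...) {
  cat(sprintf("Validation of %s\n", format(x$oligo)))
  for (i in seq_len(nrow(x$checks))) {
    st <- if (is.na(x$checks$pass[i])) "  --  " else
      if (x$checks$pass[i]) " pass " else " FAIL "
    cat(sprintf("  [%s] %-22s %-14s (%s)\n", st, x$checks$rule[i],
                x$checks$value[i], x$checks$threshold[i]))
  }
  cat(sprintf("  verdict: %s%s\n",
              if (x$verdict) "PASS" else "FAIL",
              if (x$unscreened) " (specificity unscreened)" else ""))
  invisible(x)
}

#' Design blocking primers for a host reference
#'
#' The full pipeline: extract the amplicon with the amplification primer
#' pair, enumerate every candidate window inside the hypervariable interior,
#' compute GC content and host copy count, screen each candidate against the
#' off-target library, apply the design rules, rank the survivors and emit
#' the top \code{k} as C3-spacer blocking oligos.
#'
#' @param host length-1 named character vector, the host reference.
#' @param fwd,rev amplification \code{\link{primer_oligo}}s (or packaged
#'   names resolved via \code{\link{bp_oligo}}).
#' @param offtargets named character vector of off-target sequences; an
#'   empty library leaves every candidate rejected as unscreened.
#' @param rules a \code{\link{design_rules}} object.
#' @param k number of blocking primers to emit.
#' @return object of class \code{bp_design}: the amplicon map, the ranked
#'   candidate table (with status and reject_reasons), the emitted blocking
#'   primers and the rules used.
#' @export
design_blocking_primers <- function(host, fwd, rev, offtargets,
                                    rules = design_rules(), k = 2L) {
  if (is.character(fwd) && length(fwd) == 1L && !grepl("[^A-Za-z0-9_-]", fwd) &&
      fwd %in% bp_oligo_table()$name) fwd <- bp_oligo(fwd)
  if (is.character(rev) && length(rev) == 1L && !grepl("[^A-Za-z0-9_-]", rev) &&
      rev %in% bp_oligo_table()$name) rev <- bp_oligo(rev)
  amplicon <- extract_amplicon(host, fwd, rev, rules)
  cand <- enumerate_candidates(amplicon, host, rules)
  if (nrow(cand) == 0L) {
    cand$host_copy_count <- integer(0)
    cand$min_offtarget_mismatches <- integer(0)
    cand$status <- character(0)
    cand$reject_reasons <- character(0)
    return(structure(list(host_id = .template_id(host, "host"),
                          amplicon = amplicon, candidates = cand,
                          primers = list(), rules = rules, k = k,
                          offtarget_ids = names(offtargets) %||% character(0),
                          unscreened = length(offtargets) == 0L),
                     class = "bp_design"))
  }
  cand$host_copy_count <- vapply(cand$seq, host_uniqueness, integer(1),
                                 host = host, USE.NAMES = FALSE)
  unscreened <- is.null(offtargets) || length(offtargets) == 0L
  cand$min_offtarget_mismatches <- if (unscreened) NA_integer_ else
    vapply(cand$seq, function(s)
      specificity_screen(s, offtargets, rules)$min_mismatches, integer(1),
      USE.NAMES = FALSE)

  reasons <- vector("list", nrow(cand))
  for (i in seq_len(nrow(cand))) {
    r <- character(0)
    if (rules$require_host_unique && cand$host_copy_count[i] != 1L)
      r <- c(r, "host_not_unique")
    if (unscreened)
      r <- c(r, "unscreened_specificity")
    else if (cand$min_offtarget_mismatches[i] < rules$min_offtarget_mismatches)
      r <- c(r, sprintf("offtarget_mismatches<%d", rules$min_offtarget_mismatches))
    reasons[[i]] <- r
  }
  cand$status <- ifelse(lengths(reasons) == 0L, "accepted", "rejected")
  cand$reject_reasons <- vapply(reasons, paste, character(1), collapse = ";")
  cand <- rank_candidates(cand)
  cand$rank <- NA_integer_
  acc_idx <- which(cand$status == "accepted")
  cand$rank[acc_idx] <- seq_along(acc_idx)

  primers <- if (length(acc_idx)) {
    withCallingHandlers(
      emit_blocking_primers(cand, min(k, length(acc_idx))),
      warning = function(w) invokeRestart("muffleWarning"))
  } else list()
  if (length(acc_idx) < k)
    warning(sprintf("only %d accepted candidate(s) available (requested %d)",
                    length(acc_idx), k))

  structure(list(host_id = .template_id(host, "host"), amplicon = amplicon,
                 candidates = cand, primers = primers, rules = rules, k = k,
                 offtarget_ids = names(offtargets) %||% character(0),
                 unscreened = unscreened),
            class = "bp_design")
}

#' @export
print.bp_design <- function(x, ...) {
  cat(sprintf("Blocking-primer design on '%s'\n", x$host_id))
  cat(sprintf("  amplicon [%d,%d), interior [%d,%d)\n",
              x$amplicon$amplicon_start, x$amplicon$amplicon_end,
              x$amplicon$interior_start, x$amplicon$interior_end))
  n_acc <- sum(x$candidates$status == "accepted")
  cat(sprintf("  %d candidate window(s), %d accepted, %d off-target(s)%s\n",
              nrow(x$candidates), n_acc, length(x$offtarget_ids),
              if (x$unscreened) " [UNSCREENED]" else ""))
  if (length(x$primers)) {
    cat("  emitted blocking primers:\n")
    for (p in x$primers) cat("    ", format(p), "\n", sep = "")
  }
  invisible(x)
}

#' @method summary bp_design
#' @export
summary.bp_design <- function(object, ...) {
  cand <- object$candidates
  out <- list(host_id = object$host_id,
              n_candidates = nrow(cand),
              n_accepted = sum(cand$status == "accepted"),
              n_rejected = sum(cand$status == "rejected"),
              interior_length = object$amplicon$interior_end - object$amplicon$interior_start,
              min_offtarget_mismatches_accepted =
                if (any(cand$status == "accepted"))
                  min(cand$min_offtarget_mismatches[cand$status == "accepted"])
                else NA_integer_,
              rules = object$rules)
  class(out) <- "summary.bp_design"
  out
}

#' @export
print.summary.bp_design <- function(x, ...) {
  cat(sprintf("Design summary for '%s': %d windows enumerated in a %d nt interior;\n",
              x$host_id, x$n_candidates, x$interior_length))
  cat(sprintf("  accepted %d, rejected %d; accepted off-target minimum: %s\n",
              x$n_accepted, x$n_rejected,
              ifelse(is.na(x$min_offtarget_mismatches_accepted), "NA",
                     x$min_offtarget_mismatches_accepted)))
  invisible(x)
}

.CANDIDATE_COLS <- c("host_id", "start", "end", "strand", "seq", "gc_fraction",
                     "host_copy_count", "min_offtarget_mismatches", "status",
                     "reject_reasons", "rank")

#' Write the candidate table as TSV
#'
#' Deterministic byte output for fixed input: stable column order, fixed
#' numeric formatting, a header noting that the ranking keys are a tool
#' convention.
#'
#' @param design a \code{bp_design}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_candidates_tsv <- function(design, path) {
  cand <- design$candidates
  for (col in .CANDIDATE_COLS) if (!col %in% names(cand)) cand[[col]] <- NA
  cand <- cand[, .CANDIDATE_COLS, drop = FALSE]
  cand$gc_fraction <- sprintf("%.4f", cand$gc_fraction)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(
    "# bpdesign candidate blocking-primer windows",
    "# ranking keys (tool convention, advisory): desc min_offtarget_mismatches, |gc-0.5|, length, start",
    paste(.CANDIDATE_COLS, collapse = "\t")), con, sep = "\n")
  if (nrow(cand))
    writeLines(do.call(paste, c(lapply(cand, as.character), sep = "\t")), con, sep = "\n")
  invisible(path)
}

#' Write emitted blocking primers as FASTA
#'
#' Description lines carry the "[SpcC3]" suffix marking the 3' C3 spacer.
#'
#' @param design a \code{bp_design} (or a list of blocking
#'   \code{primer_oligo}s).
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_primers_fasta <- function(design, path) {
  primers <- if (inherits(design, "bp_design")) design$primers else design
  if (length(primers) == 0L) stop("no blocking primers to write")
  seqs <- vapply(primers, function(p) p$gene_specific, character(1))
  names(seqs) <- vapply(primers, function(p) paste0(p$name, " [SpcC3]"), character(1))
  write_fasta(seqs, path)
}

#' Write a validation report as TSV
#'
#' @param validation a \code{bp_validation}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_validation_tsv <- function(validation, path) {
  df <- validation$checks
  df$pass <- ifelse(is.na(df$pass), "unscreened", ifelse(df$pass, "pass", "fail"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(sprintf("# bpdesign validation report for %s", validation$oligo$name),
               paste(names(df), collapse = "\t")), con, sep = "\n")
  writeLines(do.call(paste, c(lapply(df, as.character), sep = "\t")), con, sep = "\n")
  writeLines(sprintf("# verdict\t%s", if (validation$verdict) "PASS" else "FAIL"),
             con, sep = "\n")
  invisible(path)
}
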