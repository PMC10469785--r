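# Brute-force oracles, kept deliberately naive and independent of the
# package's sliding-window implementation: double loops over offsets and
# strands, scoring each window with mismatch_count on substrings.

# all binding sites of a primer on a template, by exhaustive substring scan
oracle_find_sites <- function(template_seq, gene_specific, max_mismatches) {
  n <- nchar(template_seq)
  rows <- list()
  for (strand in c("+", "-")) {
    q <- if (strand == "+") gene_specific else revcomp(gene_specific)
    m <- nchar(q)
    if (m > n) next
    for (s0 in 0:(n - m)) {
      w <- substr(template_seq, s0 + 1, s0 + m)
      mm <- mismatch_count(w, q)
      if (mm <= max_mismatches)
        rows[[length(rows) + 1L]] <- data.frame(start = s0, end = s0 + m,
                                                strand = strand, mismatches = mm,
                                                stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(start = integer(0), end = integer(0),
                      strand = character(0), mismatches = integer(0),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out[order(out$start, out$strand), , drop = FALSE]
}

# best ungapped semi-global mismatch count of query vs subject, both strands;
# short subjects are slid along the query with uncovered positions counted
oracle_best_mismatches <- function(query, subject) {
  best <- Inf
  nq <- nchar(query)
  ns <- nchar(subject)
  for (q in c(query, revcomp(query))) {
    if (ns >= nq) {
      for (s0 in 0:(ns - nq)) {
        mm <- mismatch_count(q, substr(subject, s0 + 1, s0 + nq))
        best <- min(best, mm)
      }
    } else {
      for (q0 in 0:(nq - ns)) {
        mm <- mismatch_count(substr(q, q0 + 1, q0 + ns), subject) + (nq - ns)
        best <- min(best, mm)
      }
    }
  }
  as.integer(best)
}

random_acgt <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                 collapse = "")

random_iupac <- function(n, p_degenerate = 0.15) {
  codes <- c("A", "C", "G", "T")
  degen <- c("R", "Y", "S", "W", "K", "M", "B", "D", "H", "V", "N")
  paste(ifelse(stats::runif(n) < p_degenerate,
               sample(degen, n, replace = TRUE),
               sample(codes, n, replace = TRUE)),
        collapse = "")
}

# poly-A background never matches the packaged primer sites, so constructed
# templates have exactly the sites we embed
polyA <- function(n) strrep("A", n)

# one shared seed-42 study bundle, built once per test run
.bundle_cache <- new.env(parent = emptyenv())
fixture_bundle_42 <- function() {
  if (!is.null(.bundle_cache$b)) return(.bundle_cache$b)
  spec <- fixture_spec(seed = 42)
  host <- make_host(spec)
  offt <- make_offtargets(host, spec)
  comm <- make_community(host, offt, spec)
  design <- suppressWarnings(design_blocking_primers(
    host, bp_oligo("1389F"), bp_oligo("1015R"), offt, design_rules(), k = 2))
  .bundle_cache$b <- list(spec = spec, host = host, offtargets = offt,
                          community = comm$community, host_ids = comm$host_ids,
                          design = design,
                          amplicon = design$amplicon)
  .bundle_cache$b
}
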