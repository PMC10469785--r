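# Deterministic synthetic fixtures: a host-like marker region with embedded
# primer binding sites, off-target variants at controlled mismatch
# distances, and mixed mock communities. Everything is driven by a single
# explicit seed so identical specs reproduce byte-identical FASTA files.

# run code under a seed without disturbing the caller's RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

.rand_bases <- function(n, gc = 0.5) {
  if (n == 0L) return("")
  paste(sample(c("A", "T", "G", "C"), n, replace = TRUE,
               prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
        collapse = "")
}

#' Fixture generation parameters
#'
#' Describes a synthetic study: a host marker region of
#' \code{host_length} nt whose amplicon interior (the hypervariable
#' stretch between the packaged 1389F/1015R binding sites) is
#' \code{interior_length} nt; \code{offtarget_count} off-target sequences
#' sharing the host's amplicon scaffold but with interiors at exact
#' mismatch distances \code{offtarget_distances}; and a mock community of
#' \code{community_size} templates with a \code{community_host_fraction}
#' expected host share. One explicit \code{seed} drives every draw.
#'
#' @param seed integer seed (< 2^31).
#' @param host_length total host reference length, nt.
#' @param interior_length amplicon interior length, nt.
#' @param offtarget_count number of off-target sequences.
#' @param offtarget_distances integer vector (recycled/truncated to
#'   \code{offtarget_count}) of exact interior mismatch distances.
#' @param community_size number of mock-community templates.
#' @param community_host_fraction expected fraction of host templates.
#' @param background_gc GC fraction of the random background.
#' @return object of class \code{fixture_spec}.
#' @export
fixture_spec <- function(seed = 42L,
                         host_length = 500L,
                         interior_length = 120L,
                         offtarget_count = 6L,
                         offtarget_distances = 3:8,
                         community_size = 20L,
                         community_host_fraction = 0.5,
                         background_gc = 0.5) {
  seed <- as.integer(seed)
  if (is.na(seed)) stop("seed must be an integer")
  if (host_length < 1L || interior_length < 1L)
    stop("host_length and interior_length must be positive")
  if (offtarget_count < 0L) stop("offtarget_count must be >= 0")
  offtarget_distances <- as.integer(rep_len(offtarget_distances,
                                            max(offtarget_count, 1L)))[seq_len(offtarget_count)]
  if (any(offtarget_distances < 0L)) stop("off-target distances must be >= 0")
  if (any(offtarget_distances > interior_length))
    stop("off-target distance exceeds interior length (unattainable)")
  if (community_host_fraction < 0 || community_host_fraction > 1)
    stop("community_host_fraction must be in [0,1]")
  if (background_gc < 0 || background_gc > 1)
    stop("background_gc must be in [0,1]")
  structure(list(seed = seed,
                 host_length = as.integer(host_length),
                 interior_length = as.integer(interior_length),
                 offtarget_count = as.integer(offtarget_count),
                 offtarget_distances = offtarget_distances,
                 community_size = as.integer(community_size),
                 community_host_fraction = community_host_fraction,
                 background_gc = background_gc),
            class = "fixture_spec")
}

# concrete (ACGT) resolution of the packaged amplification sites: the one
# degenerate position of 1015R (Y) is fixed to C so the synthetic host is a
# single concrete sequence every run.
.fixture_sites <- function() {
  fwd <- bp_oligo("1389F")$gene_specific
  rev_gs <- bp_oligo("1015R")$gene_specific
  rev_concrete <- chartr("Y", "C", rev_gs)
  list(fwd_site = fwd, rev_site_plus = revcomp(rev_concrete))
}

#' Generate the synthetic host reference
#'
#' Structure: random background + 1389F binding site + random interior +
#' reverse-complemented 1015R binding site + random background. The
#' generator redraws (bounded retries) until each primer binds exactly once
#' in the productive orientation, so \code{\link{extract_amplicon}} on the
#' output recovers the construction coordinates exactly. The layout is
#' recorded in attributes \code{interior_start}/\code{interior_end}.
#'
#' @param spec a \code{\link{fixture_spec}}.
#' @return length-1 named character vector (id "host") with coordinate
#'   attributes.
#' @export
make_host <- function(spec) {
  sites <- .fixture_sites()
  n_fwd <- nchar(sites$fwd_site)
  n_rev <- nchar(sites$rev_site_plus)
  bg_total <- spec$host_length - n_fwd - n_rev - spec$interior_length
  if (bg_total < 2L)
    stop("host_length too small for sites + interior (need >= ",
         n_fwd + n_rev + spec$interior_length + 2L, ")")
  bg_left_n <- bg_total %/% 2L
  bg_right_n <- bg_total - bg_left_n
  fwd_oligo <- bp_oligo("1389F")
  rev_oligo <- bp_oligo("1015R")

  with_seed(spec$seed, {
    for (attempt in 1:50) {
      hseq <- paste0(.rand_bases(bg_left_n, spec$background_gc),
                     sites$fwd_site,
                     .rand_bases(spec$interior_length, spec$background_gc),
                     sites$rev_site_plus,
                     .rand_bases(bg_right_n, spec$background_gc))
      host <- stats::setNames(hseq, "host")
      f <- find_binding_sites(host, fwd_oligo, 0L)
      r <- find_binding_sites(host, rev_oligo, 0L)
      ok <- sum(f$strand == "+") == 1L && sum(r$strand == "-") == 1L &&
        nrow(f) == 1L && nrow(r) == 1L
      if (ok) {
        attr(host, "interior_start") <- bg_left_n + n_fwd
        attr(host, "interior_end") <- bg_left_n + n_fwd + spec$interior_length
        return(host)
      }
    }
    stop("could not generate a host with unique primer sites in 50 attempts")
  })
}

#' Generate off-target sequences at exact mismatch distances
#'
#' Off-target i shares the host's amplicon scaffold (background and primer
#' sites) but its interior differs from the host interior at exactly
#' \code{spec$offtarget_distances[i]} seeded positions. The mutated
#' positions are drawn within one focal stretch of the interior, shared by
#' all off-targets: this emulates relatives whose divergence from the host
#' concentrates in a short diagnostic stretch of the hypervariable region
#' -- the situation in which a species-specific blocking site exists at all.
#' Each off-target is re-verified with the specificity screen (no closer
#' spurious match anywhere on either strand): the full host interior used
#' as a query, and the focal stretch used as a query, must both score
#' exactly the requested distance, else the mutation positions are redrawn.
#'
#' @param host output of \code{\link{make_host}}.
#' @param spec the same \code{\link{fixture_spec}}.
#' @return named character vector of off-target sequences
#'   (\code{offtarget_<i>_d<distance>}), with the focal stretch recorded in
#'   attributes \code{focal_start}/\code{focal_end} (host plus-strand,
#'   0-based half-open).
#' @export
make_offtargets <- function(host, spec) {
  if (spec$offtarget_count == 0L) return(stats::setNames(character(0), character(0)))
  i0 <- attr(host, "interior_start")
  i1 <- attr(host, "interior_end")
  if (is.null(i0) || is.null(i1)) {
    amp <- extract_amplicon(host, bp_oligo("1389F"), bp_oligo("1015R"))
    i0 <- amp$interior_start
    i1 <- amp$interior_end
  }
  hseq <- unname(host[1])
  interior <- substring(hseq, i0 + 1L, i1)
  prefix <- substring(hseq, 1L, i0)
  suffix <- substring(hseq, i1 + 1L, nchar(hseq))
  n_int <- nchar(interior)

  # focal stretch: one blocker-sized window centred in the interior
  w <- min(n_int, max(20L, max(spec$offtarget_distances)))
  if (any(spec$offtarget_distances > w))
    stop("off-target distance exceeds the focal stretch width (unattainable)")
  fs <- (n_int - w) %/% 2L  # 0-based within interior
  focal <- substring(interior, fs + 1L, fs + w)

  with_seed(spec$seed + 1L, {
    out <- character(spec$offtarget_count)
    ids <- character(spec$offtarget_count)
    for (i in seq_len(spec$offtarget_count)) {
      d <- spec$offtarget_distances[i]
      done <- FALSE
      for (attempt in 1:50) {
        mut <- unlist(strsplit(interior, ""))
        if (d > 0L) {
          pos <- fs + sample.int(w, d)
          for (p in pos) mut[p] <- sample(setdiff(c("A", "C", "G", "T"), mut[p]), 1L)
        }
        cand_seq <- paste0(prefix, paste(mut, collapse = ""), suffix)
        ot <- stats::setNames(cand_seq, "x")
        sc_int <- specificity_screen(interior, ot, design_rules())
        sc_foc <- specificity_screen(focal, ot, design_rules())
        if (sc_int$min_mismatches == d && sc_foc$min_mismatches == d) {
          out[i] <- cand_seq
          ids[i] <- sprintf("offtarget_%02d_d%d", i, d)
          done <- TRUE
          break
        }
      }
      if (!done)
        stop("could not realize off-target at exact distance ",
             d, " in 50 attempts")
    }
    out <- stats::setNames(out, ids)
    attr(out, "focal_start") <- i0 + fs
    attr(out, "focal_end") <- i0 + fs + w
    out
  })
}

#' Assemble a mock community
#'
#' A seeded multinomial draw of template copies over the host and the
#' off-targets: the host cell has probability
#' \code{community_host_fraction}, the rest is split evenly. Copies get
#' unique ids (\code{<source id>_c<copy>}); the host-id list designates
#' every host copy.
#'
#' @param host output of \code{\link{make_host}}.
#' @param offtargets output of \code{\link{make_offtargets}}.
#' @param spec the same \code{\link{fixture_spec}}.
#' @return list with \code{community} (named character vector) and
#'   \code{host_ids} (character vector).
#' @export
make_community <- function(host, offtargets, spec) {
  if (spec$community_size < 1L) stop("community_size must be >= 1")
  sources <- c(host, offtargets)
  k <- length(sources)
  probs <- if (k == 1L) 1 else
    c(spec$community_host_fraction,
      rep((1 - spec$community_host_fraction) / (k - 1L), k - 1L))
  with_seed(spec$seed + 2L, {
    counts <- as.vector(stats::rmultinom(1L, spec$community_size, probs))
    seqs <- character(0)
    ids <- character(0)
    for (j in seq_len(k)) {
      if (counts[j] == 0L) next
      src_id <- names(sources)[j]
      copy_ids <- sprintf("%s_c%d", src_id, seq_len(counts[j]))
      seqs <- c(seqs, rep(unname(sources[j]), counts[j]))
      ids <- c(ids, copy_ids)
    }
    community <- stats::setNames(seqs, ids)
    list(community = community,
         host_ids = ids[startsWith(ids, paste0(names(host)[1], "_c"))])
  })
}

#' Write a complete fixture bundle to a directory
#'
#' Writes host.fasta, offtargets.fasta, community.fasta, host_ids.txt and
#' spec.yaml (an echo of the parameters including the seed). Identical
#' specs produce byte-identical files.
#'
#' @param spec a \code{\link{fixture_spec}}.
#' @param dir output directory (created if missing).
#' @return named list of paths, invisibly.
#' @export
write_fixture_bundle <- function(spec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  host <- make_host(spec)
  offt <- make_offtargets(host, spec)
  comm <- make_community(host, offt, spec)
  paths <- list(host = file.path(dir, "host.fasta"),
                offtargets = file.path(dir, "offtargets.fasta"),
                community = file.path(dir, "community.fasta"),
                host_ids = file.path(dir, "host_ids.txt"),
                spec = file.path(dir, "spec.yaml"))
  write_fasta(host, paths$host)
  if (length(offt)) write_fasta(offt, paths$offtargets)
  write_fasta(comm$community, paths$community)
  writeLines(comm$host_ids, paths$host_ids)
  yaml::write_yaml(unclass(spec), paths$spec)
  invisible(paths)
}
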