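# Candidate enumeration, screening, ranking, emission and validation.

fwd <- bp_oligo("1389F")
rev_p <- bp_oligo("1015R")
rev_concrete <- chartr("Y", "C", rev_p$gene_specific)

# host with a fully specified interior, poly-A background
make_test_host <- function(interior, left = 20, right = 20) {
  c(host = paste0(polyA(left), fwd$gene_specific, interior,
                  revcomp(rev_concrete), polyA(right)))
}

test_that("enumeration counts windows combinatorially and respects boundaries", {
  set.seed(23)
  interior <- random_acgt(25)
  host <- make_test_host(interior)
  amp <- extract_amplicon(host, fwd, rev_p)
  rules <- design_rules(min_len = 20, max_len = 25)
  cand <- enumerate_candidates(amp, host, rules)
  # sum over L = 20..25 of (25 - L + 1) = 21 windows per orientation
  expect_equal(sum(cand$strand == "+"), 21L)
  expect_equal(sum(cand$strand == "-"), 21L)
  expect_true(all(cand$start >= amp$interior_start))
  expect_true(all(cand$end <= amp$interior_end))
  # a window ending exactly at interior_end is legal and present
  expect_true(any(cand$end == amp$interior_end))
  expect_false(any(cand$end > amp$interior_end))
  # lengths bounded by the rules
  lens <- cand$end - cand$start
  expect_true(all(lens >= 20 & lens <= 25))
  # minus-strand windows carry the reverse complement of the plus slice
  i <- which(cand$strand == "-")[1]
  plus_slice <- substr(unname(host), cand$start[i] + 1, cand$end[i])
  expect_identical(cand$seq[i], revcomp(plus_slice))
})

test_that("an interior shorter than min_len enumerates nothing, with a warning", {
  set.seed(29)
  host <- make_test_host(random_acgt(19))
  amp <- extract_amplicon(host, fwd, rev_p)
  expect_warning(cand <- enumerate_candidates(amp, host, design_rules()),
                 "shorter than min_len")
  expect_equal(nrow(cand), 0L)
})

test_that("raising min_len never enlarges the enumerated set", {
  set.seed(31)
  host <- make_test_host(random_acgt(40))
  amp <- extract_amplicon(host, fwd, rev_p)
  n_prev <- Inf
  for (ml in c(20, 24, 28, 32)) {
    n <- nrow(enumerate_candidates(amp, host, design_rules(min_len = ml, max_len = 35)))
    expect_lte(n, n_prev)
    n_prev <- n
  }
})

test_that("host copy count sees tandem duplications and both strands", {
  set.seed(37)
  unit <- random_acgt(30)
  host1 <- c(h = paste0(polyA(10), unit, polyA(10)))
  expect_equal(host_uniqueness(unit, host1), 1L)
  host2 <- c(h = paste0(polyA(10), unit, unit, polyA(10)))
  expect_equal(host_uniqueness(unit, host2), 2L)
  # a reverse-complement occurrence counts as a copy
  host3 <- c(h = paste0(polyA(10), unit, polyA(5), revcomp(unit), polyA(10)))
  expect_equal(host_uniqueness(unit, host3), 2L)
  # palindromic candidate on one locus counts once (intervals, not strand hits)
  pal <- "ACGTACGTACGTACGTACGT"
  expect_identical(pal, revcomp(pal))
  hostp <- c(h = paste0(polyA(10), pal, polyA(10)))
  expect_equal(host_uniqueness(pal, hostp), 1L)
})

test_that("specificity screen scores constructed off-targets exactly", {
  set.seed(41)
  cand <- random_acgt(24)
  # identical off-target -> 0 mismatches, fails the rules
  sc <- specificity_screen(cand, c(same = cand))
  expect_equal(sc$min_mismatches, 0L)
  expect_false(sc$pass)
  # off-target with the candidate locus mutated at exactly 3 positions,
  # flanked by high-distance scramble
  mutated <- strsplit(cand, "")[[1]]
  for (p in c(4, 12, 20))
    mutated[p] <- setdiff(c("A", "C", "G", "T"), mutated[p])[1]
  offt <- paste0(strrep("TG", 30), paste(mutated, collapse = ""), strrep("CA", 30))
  sc3 <- specificity_screen(cand, c(ot = offt))
  expect_equal(sc3$min_mismatches, 3L)
  expect_true(sc3$pass)
  expect_equal(sc3$min_mismatches, oracle_best_mismatches(cand, offt))
})

test_that("an empty off-target library is an explicit unscreened result", {
  sc <- specificity_screen("ACGTACGTACGTACGTACGT", character(0))
  expect_true(sc$unscreened)
  expect_true(is.na(sc$min_mismatches))
  expect_true(is.na(sc$pass))
})

test_that("off-targets shorter than the candidate cannot pass as trivial decoys", {
  cand <- strrep("ACGT", 6)                # 24 nt
  decoy <- substr(cand, 1, 10)             # exact 10 nt substring
  sc <- specificity_screen(cand, c(d = decoy))
  # 14 uncovered candidate positions count as mismatches
  expect_equal(sc$min_mismatches, 14L)
  expect_equal(sc$min_mismatches, oracle_best_mismatches(cand, decoy))
})

test_that("screen equals the brute-force oracle on random pairs", {
  set.seed(43)
  for (i in 1:30) {
    cand <- random_acgt(sample(15:60, 1))
    offt <- random_acgt(sample(8:500, 1))
    sc <- specificity_screen(cand, c(x = offt))
    expect_equal(sc$min_mismatches, oracle_best_mismatches(cand, offt))
  }
})

test_that("ranking applies its keys in order and is stable", {
  cand <- data.frame(
    host_id = "h", start = c(10L, 30L, 20L, 20L),
    end = c(34L, 50L, 40L, 44L), strand = "+",
    seq = "x", gc_fraction = c(0.50, 0.30, 0.45, 0.50),
    min_offtarget_mismatches = c(3L, 5L, 5L, 3L),
    status = "accepted", stringsAsFactors = FALSE)
  ranked <- rank_candidates(cand)
  # hand-applied keys: mm desc -> {30,20} before {10,20}; within mm=5 the
  # gc closest to 0.5 wins (0.45 beats 0.30); within mm=3 both gc=0.5, the
  # shorter window (24 nt at start 10) beats the 24... lengths 24 vs 24 ->
  # 5'-most start wins
  expect_equal(ranked$start, c(20L, 30L, 10L, 20L))
  expect_equal(ranked$end, c(40L, 50L, 34L, 44L))
  # ties on every key preserve input order
  tie <- cand[c(1, 1), ]
  tie$seq <- c("first", "second")
  expect_identical(rank_candidates(tie)$seq, c("first", "second"))
})

test_that("emission converts top-k accepted candidates into C3-spacer oligos", {
  cand <- data.frame(
    host_id = "h", start = 10L + 0:4, end = 34L + 0:4, strand = "+",
    seq = vapply(1:5, function(i) random_acgt(24), character(1)),
    gc_fraction = 0.5, min_offtarget_mismatches = 5L,
    status = c("accepted", "accepted", "rejected", "accepted", "accepted"),
    stringsAsFactors = FALSE)
  out <- emit_blocking_primers(cand, k = 2)
  expect_length(out, 2L)
  for (p in out) {
    expect_s3_class(p, "primer_oligo")
    expect_identical(p$role, "blocking")
    expect_identical(p$terminator, "C3_spacer")
    expect_match(format(p), "\\[SpcC3\\]")
  }
  expect_identical(out[[1]]$name, "h:10-34:+")
  one <- cand[cand$start == 10L, ]
  expect_warning(out1 <- emit_blocking_primers(one, k = 2), "only 1 accepted")
  expect_length(out1, 1L)
})

test_that("validation checks the published blocking primers' length rule", {
  b <- fixture_bundle_42()
  for (nm in c("BP-F_Hi_V9", "BP-R_Hi_V9")) {
    val <- validate_blocking_primer(bp_oligo(nm), b$amplicon, b$host, b$offtargets)
    len_row <- val$checks[val$checks$rule == "length", ]
    expect_true(len_row$pass)
  }
  # printed gene-specific lengths: 23 and 22 nt
  expect_equal(nchar(bp_oligo("BP-F_Hi_V9")$gene_specific), 23L)
  expect_equal(nchar(bp_oligo("BP-R_Hi_V9")$gene_specific), 22L)
})

test_that("validation flags footprint overlap and unmapped oligos", {
  b <- fixture_bundle_42()
  host_seq <- unname(b$host)
  amp <- b$amplicon
  # a window overlapping the forward footprint by exactly 1 nt
  s0 <- amp$fwd_footprint$end - 1L
  overlap_oligo <- primer_oligo("overlap", substr(host_seq, s0 + 1, s0 + 22),
                                "blocking")
  val <- validate_blocking_primer(overlap_oligo, amp, b$host)
  expect_false(val$checks$pass[val$checks$rule == "footprint_overlap"])
  expect_false(val$verdict)
  # an oligo absent from the host: report, not exception
  stranger <- primer_oligo("stranger", strrep("GT", 11), "blocking")
  val2 <- validate_blocking_primer(stranger, amp, b$host)
  expect_identical(val2$checks$value[val2$checks$rule == "host_locus"],
                   "no host locus")
  expect_false(val2$verdict)
})

test_that("accepted candidates re-validate clean (closure property)", {
  b <- fixture_bundle_42()
  acc <- b$design$candidates[b$design$candidates$status == "accepted", ]
  set.seed(47)
  pick <- acc[sample.int(nrow(acc), min(10, nrow(acc))), ]
  for (i in seq_len(nrow(pick))) {
    oligo <- primer_oligo(sprintf("c%d", i), pick$seq[i], "blocking")
    val <- validate_blocking_primer(oligo, b$amplicon, b$host, b$offtargets,
                                    b$design$rules)
    expect_true(val$verdict)
    expect_true(all(val$checks$pass[!is.na(val$checks$pass)]))
  }
})

test_that("raising the off-target threshold never enlarges the accepted set", {
  b <- fixture_bundle_42()
  n_prev <- Inf
  for (t in c(3, 4, 6, 9)) {
    d <- suppressWarnings(design_blocking_primers(
      b$host, bp_oligo("1389F"), bp_oligo("1015R"), b$offtargets,
      design_rules(min_offtarget_mismatches = t), k = 1))
    n_acc <- sum(d$candidates$status == "accepted")
    expect_lte(n_acc, n_prev)
    n_prev <- n_acc
  }
})

test_that("candidate TSV reports are byte-identical across repeated writes", {
  b <- fixture_bundle_42()
  p1 <- withr::local_tempfile(fileext = ".tsv")
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_candidates_tsv(b$design, p1)
  write_candidates_tsv(b$design, p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
  # header flags the ranking as a tool convention
  expect_match(readLines(p1, n = 2)[2], "tool convention")
})
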