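# Per-template outcome prediction and mock-community aggregation.

fwd <- bp_oligo("1389F")
rev_p <- bp_oligo("1015R")
rev_concrete <- chartr("Y", "C", rev_p$gene_specific)

tpl_with_interior <- function(interior, id = "t") {
  stats::setNames(paste0(polyA(15), fwd$gene_specific, interior,
                         revcomp(rev_concrete), polyA(15)), id)
}

test_that("a perfect interior blocker hit arrests the template", {
  set.seed(53)
  interior <- random_acgt(60)
  tpl <- tpl_with_interior(interior)
  blocker <- primer_oligo("b1", substr(interior, 11, 32), "blocking")
  oc <- predict_outcome(tpl, fwd, rev_p, list(blocker), t_block = 2)
  expect_identical(oc$outcome, "blocked")
  expect_true(oc$has_amplicon)
  expect_true(any(oc$hits$in_interior & oc$hits$mismatches == 0))
})

test_that("a distant blocker leaves the template amplified", {
  set.seed(59)
  interior <- random_acgt(60)
  tpl <- tpl_with_interior(interior)
  # mutate a blocker-sized window at 5 positions
  w <- strsplit(substr(interior, 11, 32), "")[[1]]
  for (p in c(2, 7, 12, 17, 21)) w[p] <- setdiff(c("A","C","G","T"), w[p])[1]
  far <- primer_oligo("b5", paste(w, collapse = ""), "blocking")
  sc <- specificity_screen(far$gene_specific, stats::setNames(unname(tpl), "t"))
  expect_gte(sc$min_mismatches, 3L)  # construction sanity
  oc <- predict_outcome(tpl, fwd, rev_p, list(far), t_block = 2)
  expect_identical(oc$outcome, "amplified")
})

test_that("templates without a primer site are no_amplicon regardless of blockers", {
  set.seed(61)
  interior <- random_acgt(60)
  no_rev <- stats::setNames(paste0(polyA(15), fwd$gene_specific, interior, polyA(15)), "t")
  blocker <- primer_oligo("b", substr(interior, 1, 22), "blocking")
  oc <- predict_outcome(no_rev, fwd, rev_p, list(blocker), t_block = 2)
  expect_identical(oc$outcome, "no_amplicon")
  expect_false(oc$has_amplicon)
  expect_false(oc$ambiguous)
})

test_that("a blocker hit overlapping a footprint reports but does not block", {
  set.seed(67)
  interior <- random_acgt(60)
  tpl <- tpl_with_interior(interior)
  # oligo spanning the last 10 nt of the fwd footprint and 12 nt of interior
  host_seq <- unname(tpl)
  amp <- extract_amplicon(tpl, fwd, rev_p)
  s0 <- amp$fwd_footprint$end - 10L
  straddle <- primer_oligo("straddle", substr(host_seq, s0 + 1, s0 + 22), "blocking")
  oc <- predict_outcome(tpl, fwd, rev_p, list(straddle), t_block = 2)
  expect_identical(oc$outcome, "amplified")
  expect_true(nrow(oc$hits) >= 1L)
  expect_false(any(oc$hits$blocks))
})

test_that("an ambiguous amplicon is an explicit, separately counted outcome", {
  set.seed(71)
  interior <- random_acgt(40)
  amb <- stats::setNames(
    paste0(polyA(10), fwd$gene_specific, interior, revcomp(rev_concrete),
           polyA(10), revcomp(rev_concrete), polyA(10)), "amb")
  oc <- predict_outcome(amb, fwd, rev_p, list(), t_block = 2)
  expect_identical(oc$outcome, "no_amplicon")
  expect_true(oc$ambiguous)
  rep <- simulate_community(amb, character(0), fwd, rev_p, list(), t_block = 2)
  expect_equal(rep$counts[["ambiguous"]], 1L)
})

test_that("community fractions follow the constructed composition", {
  set.seed(73)
  interior <- random_acgt(60)
  blocker <- primer_oligo("b", substr(interior, 11, 34), "blocking")
  hosts <- stats::setNames(
    rep(unname(tpl_with_interior(interior)), 10), paste0("host_", 1:10))
  # off-targets: random interiors, far beyond t_block of the blocker
  offs <- character(10)
  for (i in 1:10) {
    repeat {
      cand_int <- random_acgt(60)
      if (oracle_best_mismatches(blocker$gene_specific,
                                 paste0(fwd$gene_specific, cand_int,
                                        revcomp(rev_concrete))) > 2) break
    }
    offs[i] <- unname(tpl_with_interior(cand_int))
  }
  names(offs) <- paste0("off_", 1:10)
  comm <- c(hosts, offs)
  rep <- simulate_community(comm, names(hosts), fwd, rev_p, list(blocker),
                            t_block = 2)
  expect_equal(rep$host_suppression, 1.0)
  expect_equal(rep$collateral_blocking, 0.0)
  expect_equal(sum(rep$counts[c("amplified", "blocked", "no_amplicon")]), 20L)

  # empty blocker list: nothing suppressed
  rep0 <- simulate_community(comm, names(hosts), fwd, rev_p, list(), t_block = 2)
  expect_equal(rep0$host_suppression, 0.0)

  # plant 3 of 10 off-targets within t_block of the blocker
  comm2 <- comm
  for (i in 1:3) {
    w <- strsplit(blocker$gene_specific, "")[[1]]
    w[5 + i] <- setdiff(c("A","C","G","T"), w[5 + i])[1]  # 1 mismatch
    near_int <- paste0(substr(interior, 1, 10), paste(w, collapse = ""),
                       substr(interior, 35, 60))
    comm2[[paste0("off_", i)]] <- unname(tpl_with_interior(near_int))
  }
  rep3 <- simulate_community(comm2, names(hosts), fwd, rev_p, list(blocker),
                             t_block = 2)
  expect_equal(rep3$collateral_blocking, 0.3)
})

test_that("raising t_block never decreases either blocking fraction", {
  b <- fixture_bundle_42()
  blockers <- b$design$primers
  prev_h <- -Inf; prev_c <- -Inf
  for (t in 0:4) {
    rep <- simulate_community(b$community, b$host_ids, bp_oligo("1389F"),
                              bp_oligo("1015R"), blockers, t_block = t)
    expect_gte(rep$host_suppression, prev_h)
    expect_gte(rep$collateral_blocking, prev_c)
    prev_h <- rep$host_suppression
    prev_c <- rep$collateral_blocking
  }
})

test_that("summary fractions equal fractions recomputed from per-template rows", {
  b <- fixture_bundle_42()
  rep <- simulate_community(b$community, b$host_ids, bp_oligo("1389F"),
                            bp_oligo("1015R"), b$design$primers, t_block = 2)
  per <- rep$per_template
  recompute <- function(sub) sum(sub$outcome == "blocked") /
    sum(sub$has_amplicon)
  expect_equal(rep$host_suppression, recompute(per[per$is_host, ]))
  expect_equal(rep$collateral_blocking, recompute(per[!per$is_host, ]))
  expect_equal(sum(rep$counts[c("amplified", "blocked", "no_amplicon")]), rep$n)
})

test_that("report files round-trip the summary numbers", {
  b <- fixture_bundle_42()
  rep <- simulate_community(b$community, b$host_ids, bp_oligo("1389F"),
                            bp_oligo("1015R"), b$design$primers, t_block = 2)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  js <- withr::local_tempfile(fileext = ".json")
  write_block_report(rep, tsv_path = tsv, json_path = js)
  per <- read.delim(tsv)
  expect_equal(nrow(per), rep$n)
  j <- jsonlite::read_json(js)
  expect_equal(j$host_suppression, rep$host_suppression)
  expect_equal(j$collateral_blocking, rep$collateral_blocking)
})

test_that("an empty community is an error", {
  expect_error(simulate_community(character(0), character(0), fwd, rev_p,
                                  list(), 2), "empty")
})
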