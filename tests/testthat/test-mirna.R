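test_that("base-pair maximisation folds known structures", {
  f <- fold_hairpin("GGGAAACCC")
  expect_identical(f$n_pairs, 3L)
  expect_identical(f$structure, "(((...)))")
  expect_identical(fold_hairpin("AAAAAA")$n_pairs, 0L)
  expect_error(fold_hairpin("ACGX"), "non-nucleotide")
  # pair table is an involution and brackets are balanced
  p <- f$pairs
  expect_true(all(p[p[!is.na(p)]] == which(!is.na(p))))
})

test_that("fold equals exhaustive structure enumeration for short sequences", {
  set.seed(77)
  for (k in 1:200) {
    s <- paste(sample(c("A", "C", "G", "T"), sample(5:15, 1), TRUE),
               collapse = "")
    expect_identical(fold_hairpin(s)$n_pairs, bf_max_pairs(s),
                     info = s)
  }
})

test_that("single-hairpin test distinguishes stems, junk, and split hairpins", {
  arm <- "GCGCGAGCUCGGUACGGUCC"                       # 20 nt
  hp <- paste0(arm, "AACAAACA", as.character(
    Biostrings::reverseComplement(Biostrings::RNAString(arm))))
  expect_true(has_single_hairpin(fold_hairpin(hp), min_stem = 15))
  set.seed(5)
  junk <- paste(sample(c("A", "C"), 60, TRUE), collapse = "")
  expect_false(has_single_hairpin(fold_hairpin(junk), min_stem = 15))
  # two separate hairpins with matures in different stems
  two <- paste0(hp, "AAAA", hp)
  m1 <- c(1L, 20L); m2 <- c(nchar(hp) + 4L + 29L, 20L)
  expect_false(has_single_hairpin(fold_hairpin(two), 15, m1, m2))
})

test_that("mature location is strict exact matching", {
  prec <- "AACCGGTTACGTACGTACGTAA"
  expect_identical(locate_mature(prec, substr(prec, 10, 20)), 10L)
  expect_true(is.na(locate_mature(prec, "ACGTACGTACGA")))  # one mismatch
  expect_identical(locate_mature(prec, "ACGTACGTACGA", max_mismatch = 1), 9L)
  expect_error(locate_mature(prec, ""), "empty")
  multi <- locate_mature("ACGACGACG", "ACG")
  expect_identical(as.integer(multi), 1L)
  expect_true(attr(multi, "multiple"))
})

test_that("duplex geometry reports arms, mismatches and bulges", {
  hp <- perfect_hairpin_fixture()
  fold <- fold_hairpin(hp$precursor)
  ds <- duplex_stats(fold, c(hp$off5, 21L), c(hp$off3, 21L))
  expect_true(ds$opposite_arms)
  expect_identical(ds$mismatched_positions, 0L)
  expect_identical(ds$max_asymmetric_bulge, 0L)
  # matures both on the 5' arm: not opposite
  ds2 <- duplex_stats(fold, c(1L, 8L), c(11L, 8L))
  expect_false(ds2$opposite_arms)
  expect_error(duplex_stats(fold, c(1L, 10L), c(5L, 10L)), "overlap")
})

test_that("redundancy collapses exact and reverse-complement duplicates", {
  cands <- data.frame(
    id = c("a", "b", "c", "d"),
    precursor = c("ACGTACGTGGCC", "ACGTACGTGGCC",
                  as.character(Biostrings::reverseComplement(
                    Biostrings::DNAString("ACGTACGTGGCC"))), "TTTTCCCCAAAA"),
    source = c("s1", "s2", "s2", "s1"), stringsAsFactors = FALSE)
  dd <- deduplicate_mirnas(cands, source_priority = c("s1", "s2"))
  expect_identical(dd$unique$id, c("a", "d"))
  expect_identical(dd$redundancy$redundant_id, c("b", "c"))
  expect_identical(dd$redundancy$reverse_complement, c(FALSE, TRUE))
  allu <- deduplicate_mirnas(cands[c(1, 4), ])
  expect_identical(nrow(allu$redundancy), 0L)
})

test_that("curation buckets boundary fixtures onto the intended rules", {
  sim <- simulate_ncrna(sim_config(seed = 3, n_extra_snorna = 0L,
                                   n_extra_trna = 0L, n_extra_snrna = 0L,
                                   n_extra_mirna = 0L, n_extra_lnc = 0L))
  mc <- sim$mirna_candidates
  expr <- data.frame(key = c(mc$mature5p, mc$mature3p), lib1 = 3L, lib2 = 3L,
                     stringsAsFactors = FALSE)
  expr <- expr[!is.na(expr$key), ]
  expr$lib1[expr$key %in% mc$mature5p[mc$id == "mir_noreads"] |
              expr$key %in% mc$mature3p[mc$id == "mir_noreads"]] <- 0L
  expr$lib2[expr$lib1 == 0L] <- 0L
  cfg <- mirna_config(source_priority = c("this_study", "prior_study"))
  cur <- curate_mirnas(mc, expr, cfg)
  rep <- cur$report
  get <- function(id) rep$failed_rules[rep$id == id]
  expect_identical(get("mir_301nt"), "R2")
  expect_identical(nchar(mc$precursor[mc$id == "mir_301nt"]), 301L)
  expect_identical(get("mir_single"), "R4")
  expect_identical(get("mir_23nt"), "R6")
  expect_identical(get("mir_noreads"), "R7")
  expect_identical(get("mir_dup1"), "R1")
  expect_identical(get("mir_pass1"), "")
  expect_setequal(strsplit(get("mir_nohairpin"), ",")[[1]], c("R3", "R8"))
  # summary buckets partition the candidate set
  expect_identical(sum(cur$summary$n), nrow(mc))
})

test_that("curation verdicts are monotone under threshold relaxation", {
  sim <- simulate_ncrna(sim_config(seed = 13, n_extra_snorna = 0L,
                                   n_extra_trna = 0L, n_extra_snrna = 0L,
                                   n_extra_lnc = 0L))
  mc <- sim$mirna_candidates
  strict <- curate_mirnas(mc, NULL, mirna_config(require_expression = FALSE))
  relaxed <- curate_mirnas(mc, NULL, mirna_config(
    require_expression = FALSE, max_precursor_len = 400L,
    mature_len = c(20L, 24L), min_stem = 10L, max_mismatch = 8L,
    max_bulge = 5L))
  passed <- strict$report$id[strict$report$verdict == "pass"]
  expect_true(all(relaxed$report$verdict[relaxed$report$id %in% passed] ==
                    "pass"))
})

test_that("allowlist rescues candidates failing only mature-count/expression", {
  sim <- simulate_ncrna(sim_config(seed = 4, n_extra_snorna = 0L,
                                   n_extra_trna = 0L, n_extra_snrna = 0L,
                                   n_extra_mirna = 0L, n_extra_lnc = 0L))
  mc <- sim$mirna_candidates[sim$mirna_candidates$id == "mir_single", ]
  cfg <- mirna_config(require_expression = FALSE, allowlist = "mir_single")
  cur <- curate_mirnas(mc, NULL, cfg)
  expect_identical(cur$report$verdict, "pass")
  expect_true(cur$report$rescued)
  # not rescued when another rule also fails
  cfg2 <- mirna_config(require_expression = FALSE, allowlist = "mir_single",
                       mature_len = c(24L, 25L))
  expect_identical(curate_mirnas(mc, NULL, cfg2)$report$verdict, "fail")
})

test_that("expectation scoring follows the penalty scheme", {
  m <- "TGGAGAAGCAGGGCACGTGCA"
  rc <- function(x) as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(x)))
  perfect <- rc(m)
  expect_identical(expectation_score(m, perfect), 0)
  # G:U at mature position 19 (a G, outside the 2-13 seed): 0.5
  sv <- strsplit(perfect, "")[[1]]
  mpos <- function(i) nchar(m) - i + 1L
  expect_identical(substr(m, 19, 19), "G")
  gu <- sv
  gu[mpos(19)] <- "T"
  expect_identical(expectation_score(m, paste(gu, collapse = "")), 0.5)
  # mismatch at mature position 5 doubles to 2.0: not high-confidence
  mm <- sv; mm[mpos(5)] <- substr(m, 5, 5)
  expect_identical(expectation_score(m, paste(mm, collapse = "")), 2)
  # property: perfect reverse complements always score zero
  set.seed(55)
  for (k in 1:25) {
    mat <- paste(sample(c("A", "C", "G", "T"), 21, TRUE), collapse = "")
    expect_identical(expectation_score(mat, rc(mat)), 0)
  }
})

test_that("target scanning keeps sub-cutoff antisense sites", {
  m <- "TGGAGAAGCAGGGCACGTGCA"
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(m)))
  set.seed(8)
  tx <- c(hit = paste0(paste(sample(c("A", "C", "G", "T"), 50, TRUE),
                             collapse = ""), rc,
                       paste(sample(c("A", "C", "G", "T"), 50, TRUE),
                             collapse = "")),
          miss = paste(sample(c("A", "C", "G", "T"), 120, TRUE),
                       collapse = ""))
  hits <- scan_targets(m, tx, cutoff = 2)
  expect_true(all(hits$transcript_id == "hit"))
  best <- hits[which.min(hits$expectation), ]
  expect_identical(best$start, 51L)
  expect_identical(best$expectation, 0)
  expect_true(best$high_confidence)
  expect_true(all(hits$expectation <= 2))
})
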