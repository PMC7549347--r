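mk_hits <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    d <- data.frame(query_id = r$q, seq_id = r$chr %||% "c1",
                    start = r$s, end = r$e,
                    strand = r$strand %||% "+",
                    length = r$e - r$s + 1L,
                    percent_identity = r$id %||% 95,
                    query_coverage = r$cov %||% 95,
                    e_value = r$ev %||% 1e-10,
                    bit_score = r$bit %||% 100,
                    source = r$src %||% "similarity",
                    class_label = r$cls %||% "snoRNA",
                    family_label = "fam", stringsAsFactors = FALSE)
    d
  }))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("similarity filter applies strict >90 bounds and >=60 nt", {
  h <- mk_hits(list(q = "a", s = 1, e = 80, cov = 95, id = 95),
               list(q = "b", s = 100, e = 180, cov = 90, id = 95),
               list(q = "c", s = 200, e = 280, cov = 95, id = 90),
               list(q = "d", s = 300, e = 358, cov = 95, id = 95),
               list(q = "e", s = 400, e = 459, cov = 95, id = 95),
               list(q = "f", s = 500, e = 580, cov = NA, id = 95))
  expect_message(kept <- filter_similarity_hits(h), "unknown query coverage")
  expect_identical(kept$query_id, c("a", "e"))   # 59 nt out, 60 nt in
})

test_that("structural filter keeps >=60 nt hits of the five small classes", {
  h <- mk_hits(list(q = "a", s = 1, e = 60, cls = "snoRNA"),
               list(q = "b", s = 100, e = 219, cls = "lncRNA"),
               list(q = "c", s = 300, e = 358, cls = "tRNA"))
  kept <- filter_structural_hits(h)
  expect_identical(kept$query_id, "a")
  expect_identical(nrow(filter_structural_hits(h[0, ])), 0L)
})

test_that("overlap resolution follows the coverage/identity/e-value/bitscore cascade", {
  h <- mk_hits(list(q = "hi", s = 100, e = 200, cov = 95),
               list(q = "lo", s = 150, e = 250, cov = 92))
  r <- resolve_overlaps(h)
  expect_identical(r$query_id, "hi")
  log <- attr(r, "decision_log")
  expect_identical(log$deciding_criterion, "query_coverage")
  h2 <- mk_hits(list(q = "p", s = 100, e = 200, ev = 1e-20),
                list(q = "q", s = 150, e = 250, ev = 1e-5))
  expect_identical(resolve_overlaps(h2)$query_id, "p")
  expect_identical(attr(resolve_overlaps(h2), "decision_log")$deciding_criterion,
                   "e_value")
  # cross-strand overlaps coexist in stranded mode
  h3 <- mk_hits(list(q = "f", s = 100, e = 200, strand = "+"),
                list(q = "r", s = 120, e = 220, strand = "-"))
  expect_identical(nrow(resolve_overlaps(h3)), 2L)
  expect_identical(nrow(resolve_overlaps(h3, stranded = FALSE)), 1L)
})

test_that("resolution is idempotent, order-independent, and matches the tournament oracle", {
  set.seed(101)
  cascade <- tiebreak_cascade()
  for (k in 1:500) {
    h <- random_hits(sample(2:8, 1))
    r <- resolve_overlaps(h, cascade)
    # oracle equivalence
    o <- bf_resolve(h, cascade)
    expect_identical(r$query_id, o$query_id)
    # idempotence
    r2 <- resolve_overlaps(r, cascade)
    expect_identical(r2$query_id, r$query_id)
    # order independence
    sh <- h[sample.int(nrow(h)), , drop = FALSE]
    expect_identical(resolve_overlaps(sh, cascade)$query_id, r$query_id)
  }
})

test_that("merged loci subsume same-class provenance and report class conflicts", {
  sim <- mk_hits(list(q = "s1", s = 100, e = 200, bit = 120))
  str <- mk_hits(list(q = "s2", s = 100, e = 200, bit = 80, src = "structural"))
  spec <- mk_hits(list(q = "t1", s = 500, e = 580, bit = 60,
                       src = "specialist", cls = "tRNA"))
  m <- merge_sources(sim, str, spec)
  expect_identical(nrow(m), 2L)
  expect_identical(m$provenance[m$query_id == "s1"], "similarity,structural")
  expect_identical(m$provenance[m$query_id == "t1"], "specialist")
  # higher score wins on a same-class overlap
  a <- mk_hits(list(q = "hiscore", s = 100, e = 200, bit = 60))
  b <- mk_hits(list(q = "loscore", s = 120, e = 220, bit = 40,
                    src = "structural"))
  expect_identical(merge_sources(a, b)$query_id, "hiscore")
  # class conflict lands in the conflicts sidecar
  x <- mk_hits(list(q = "sno", s = 100, e = 200, bit = 90))
  y <- mk_hits(list(q = "srn", s = 150, e = 250, bit = 50, cls = "snRNA",
                    src = "structural"))
  mm <- merge_sources(x, y)
  conf <- attr(mm, "conflicts")
  expect_identical(conf$conflicting_id, "srn")
  expect_identical(mm$query_id, "sno")
})
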