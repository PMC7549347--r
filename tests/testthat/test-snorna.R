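test_that("C/D box detection requires both boxes in their terminal windows", {
  # C box ATGATGA at position 2, D box CTGA ending one base from the 3' end
  s <- paste0("G", "ATGATGA", strrep("GC", 30), "CTGA", "G")
  b <- find_cd_boxes(s)
  expect_identical(b$kind, "CD")
  expect_identical(b$c_box_pos, 2L)
  expect_identical(b$d_box_pos, nchar(s) - 4L)
  # C box outside the 10-nt window
  s2 <- paste0(strrep("GC", 12), "ATGATGA", strrep("GC", 20), "CTGAG")
  expect_null(find_cd_boxes(s2))
  # no D box at all
  s3 <- paste0("GATGATGA", strrep("GC", 30))
  expect_null(find_cd_boxes(s3))
})

test_that("H/ACA detection requires a hinge H box and terminal ACA", {
  L <- 120L
  mid <- paste0(strrep("G", 59), "AGAGGA", strrep("G", L - 59 - 6 - 3), "ACA")
  b <- find_haca_boxes(mid)
  expect_identical(b$kind, "HACA")
  expect_identical(b$h_box_pos, 60L)
  expect_identical(b$aca_pos, L - 2L)
  # ACA present only near the 5' end fails
  s2 <- paste0("GG", "ACA", strrep("G", 54), "AGAGGA", strrep("G", 55))
  expect_null(find_haca_boxes(s2))
  # H box outside the hinge fails
  s3 <- paste0("AGAGGA", strrep("G", L - 9), "ACA")
  expect_null(find_haca_boxes(s3))
})

test_that("box finders agree with brute-force window-restricted scans", {
  set.seed(21)
  for (k in 1:100) {
    s <- paste(sample(c("A", "C", "G", "T"), sample(60:150, 1), TRUE),
               collapse = "")
    L <- nchar(s)
    cd <- find_cd_boxes(s)
    c_hits <- bf_iupac_match("RTGATGA", s)
    d_hits <- bf_iupac_match("CTGA", s)
    c_ok <- c_hits[c_hits <= 10]
    expect_identical(!is.null(cd),
                     length(c_ok) > 0 &&
                       any(d_hits + 3 >= L - 9 & d_hits > min(c_ok) + 6))
    haca <- find_haca_boxes(s)
    aca <- bf_iupac_match("ACA", s)
    aca <- aca[aca >= L - 5 & aca + 2 <= L]
    h <- bf_iupac_match("ANANNA", s)
    h <- h[h >= ceiling(0.35 * L) & h <= floor(0.75 * L)]
    expect_identical(!is.null(haca),
                     length(aca) > 0 && any(h + 5 < max(aca)))
  }
})

test_that("snoRNA validation assigns classes and high-confidence status", {
  sim <- simulate_ncrna(sim_config(seed = 9, n_extra_snorna = 3L,
                                   n_extra_trna = 0L, n_extra_snrna = 0L,
                                   n_extra_mirna = 0L, n_extra_lnc = 0L))
  sno <- sim$truth[sim$truth$nc_class == "snoRNA", ]
  for (i in seq_len(nrow(sno))) {
    v <- validate_snorna(sno$sequence[i], sno$family[i])
    expect_identical(v$high_confidence, sno$sno_high_conf[i])
    if (sno$sno_high_conf[i]) expect_identical(v$sno_class, sno$sno_class[i])
  }
  # out-of-bounds sizes are rejected outright
  expect_true(validate_snorna(strrep("A", 59))$rejected)
  expect_true(validate_snorna(strrep("A", 301))$rejected)
})

test_that("cluster detection chains gaps strictly below 500 nt", {
  loci <- locus_table(c("a", "b"), "chr1", c(1000L, 1400L), c(1100L, 1500L),
                      "+")
  cl <- detect_clusters(loci)        # gap 299
  expect_identical(nrow(cl), 1L)
  expect_identical(cl$n_members, 2L)
  # gap exactly 500 does not cluster
  loci2 <- locus_table(c("a", "b"), "chr1", c(1000L, 1601L), c(1100L, 1700L),
                       "+")
  expect_identical(nrow(detect_clusters(loci2)), 0L)
  # gap 499 does
  loci3 <- locus_table(c("a", "b"), "chr1", c(1000L, 1600L), c(1100L, 1700L),
                       "+")
  expect_identical(nrow(detect_clusters(loci3)), 1L)
  # chaining of three members across two sub-threshold gaps
  loci4 <- locus_table(c("a", "b", "c"), "chr1",
                       c(1000L, 1301L, 1602L), c(1200L, 1501L, 1802L), "+")
  cl4 <- detect_clusters(loci4)
  expect_identical(cl4$n_members, 3L)
  expect_identical(cl4$members, "a,b,c")
})

test_that("cluster membership is order-invariant and conserves loci", {
  set.seed(33)
  start <- cumsum(sample(c(100:300, 600:900), 20, TRUE)) + 1000L
  loci <- locus_table(sprintf("s%02d", 1:20), "chr1", start, start + 99L, "+")
  cl <- detect_clusters(loci)
  sh <- loci[sample.int(nrow(loci)), ]
  expect_identical(detect_clusters(sh), cl)
  expect_lte(sum(cl$n_members), nrow(loci))
  members <- unlist(strsplit(cl$members, ","))
  expect_identical(anyDuplicated(members), 0L)
})
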