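rc_chr <- function(x) as.character(Biostrings::reverseComplement(
  Biostrings::DNAString(x)))

test_that("length filter keeps transcripts of at least 200 nt", {
  set.seed(2)
  tx <- c(a = paste(sample(c("A", "C", "G", "T"), 200, TRUE), collapse = ""),
          b = paste(sample(c("A", "C", "G", "T"), 199, TRUE), collapse = ""))
  expect_identical(names(length_filter(tx)), "a")
  expect_length(length_filter(character(0)), 0L)
})

test_that("redundancy clustering is longest-first and deterministic", {
  set.seed(14)
  base <- paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = "")
  tx <- c(long = base, copy = base,
          part = substr(base, 1, 240),                    # 100% of shorter
          other = paste(sample(c("A", "C", "G", "T"), 260, TRUE),
                        collapse = ""))
  cl <- redundancy_cluster(tx)
  # equal lengths tie-break by name: "copy" precedes "long"
  expect_setequal(names(cl$representatives), c("copy", "other"))
  expect_identical(
    cl$clusters$representative[cl$clusters$member == "part"], "copy")
  # a ~75% identical pair stays apart
  v <- strsplit(base, "")[[1]]
  flip <- seq(1, 300, by = 4)
  v[flip] <- chartr("ACGT", "GTAC", v[flip])
  tx2 <- c(a = base, b = paste(v, collapse = ""))
  expect_length(redundancy_cluster(tx2)$representatives, 2L)
  # shuffled input gives the same representative set
  sh <- tx[sample(names(tx))]
  expect_setequal(names(redundancy_cluster(sh)$representatives),
                  names(cl$representatives))
})

test_that("coding filter removes ORF-bearing transcripts and honours plugin labels", {
  set.seed(6)
  codons <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE != "*"]
  coding <- paste0("ATG", paste(sample(codons, 150, TRUE), collapse = ""),
                   "TAA")
  stopish <- paste(rep("TAA", 100), collapse = "")
  tx <- c(orf = coding, stops = stopish)
  kept <- coding_filter(tx, "orf_heuristic")
  expect_identical(names(kept), "stops")
  # plugin labels take precedence; missing ids treated as coding
  labs <- data.frame(id = c("orf", "stops"),
                     label = c("noncoding", "noncoding"),
                     stringsAsFactors = FALSE)
  expect_setequal(names(coding_filter(tx, "plugin", labels = labs)),
                  c("orf", "stops"))
  expect_identical(names(coding_filter(tx, "plugin", labels = labs,
                                       protein_hits = "orf")), "stops")
  labs2 <- labs[1, ]
  expect_message(kept2 <- coding_filter(tx, "plugin", labels = labs2),
                 "missing")
  expect_identical(names(kept2), "orf")
})

test_that("genome anchoring applies inclusive 95% bounds and the cascade", {
  tx <- c(t1 = strrep("A", 250), t2 = strrep("C", 250), t3 = strrep("G", 250))
  hits <- data.frame(
    query_id = c("t1", "t2", "t3", "t3"),
    seq_id = "chr1", start = c(1000L, 2000L, 3000L, 3100L),
    end = c(1249L, 2249L, 3249L, 3349L),
    strand = "+", length = 250L,
    percent_identity = c(95, 95, 99, 99),
    query_coverage = c(95, 94, 98, 96),
    e_value = 1e-50, bit_score = 400, source = "similarity",
    class_label = NA_character_, family_label = NA_character_,
    stringsAsFactors = FALSE)
  loci <- anchor_to_genome(tx, hits)
  expect_setequal(loci$id, c("t1", "t3"))             # 94% coverage out
  expect_identical(loci$start[loci$id == "t3"], 3000L) # best hit by cascade
})

test_that("candidates overlapping known ncRNAs are excluded strictly", {
  cand <- locus_table(c("c1", "c2"), "chr1", c(100L, 400L), c(300L, 600L), "+")
  nc <- locus_table("t", "chr1", 290L, 360L, "-", nc_class = "tRNA")
  kept <- exclude_ncrna_overlap(cand, nc)
  expect_identical(kept$id, "c2")                      # strand-agnostic
  nc2 <- locus_table("t", "chr1", 301L, 360L, "+", nc_class = "tRNA")
  expect_identical(exclude_ncrna_overlap(cand, nc2)$id, c("c1", "c2"))
  expect_warning(out <- exclude_ncrna_overlap(cand, nc[0, ]), "unchanged")
  expect_identical(out$id, cand$id)
})

test_that("positional classification follows the sense>antisense>gene>none precedence", {
  genes <- data.frame(id = "g1", seq_id = "chr1", start = 1000L, end = 1900L,
                      strand = "+", stringsAsFactors = FALSE)
  exons <- data.frame(gene_id = "g1", seq_id = "chr1",
                      start = c(1000L, 1600L), end = c(1299L, 1900L),
                      strand = "+", stringsAsFactors = FALSE)
  cand <- locus_table(c("se", "as", "int", "no"), "chr1",
                      c(1100L, 1700L, 1350L, 5000L),
                      c(1400L, 1950L, 1550L, 5300L),
                      c("+", "-", "-", "+"))
  out <- classify_position(cand, genes, exons)
  expect_identical(out$lnc_class, c("sense", "antisense", "gene_overlap",
                                    "no_overlap"))
  # a gene without exon features is all non-exonic gene region
  expect_message(out2 <- classify_position(cand, genes, NULL), "without exon")
  expect_identical(out2$lnc_class[1], "gene_overlap")
})

test_that("the staged pipeline classifies planted candidates perfectly", {
  sim <- simulate_ncrna(sim_config(seed = 2, n_extra_snorna = 0L,
                                   n_extra_trna = 5L, n_extra_snrna = 0L,
                                   n_extra_mirna = 0L, n_extra_lnc = 2L))
  truth <- sim$truth
  lh <- sim$lnc_hits
  hits <- data.frame(query_id = lh$id, seq_id = lh$seq_id, start = lh$start,
                     end = lh$end, strand = lh$strand,
                     length = lh$end - lh$start + 1L,
                     percent_identity = 99, query_coverage = 100,
                     e_value = 1e-50, bit_score = 300, source = "similarity",
                     class_label = NA_character_,
                     family_label = NA_character_, stringsAsFactors = FALSE)
  tr <- truth[truth$nc_class == "tRNA" & truth$expected_kept, ]
  nc <- locus_table(tr$id, tr$seq_id, tr$start, tr$end, tr$strand,
                    nc_class = "tRNA")
  out <- lncrna_pipeline(sim$transcripts, hits, nc, sim$genes, sim$exons)
  lt <- truth[truth$nc_class == "lncRNA" & truth$expected_kept, ]
  expect_setequal(out$id, lt$id)
  expect_identical(out$lnc_class[match(lt$id, out$id)], lt$lnc_class)
  # the four classes partition the classified set
  expect_identical(sum(table(out$lnc_class)), nrow(out))
  counts <- attr(out, "stage_counts")
  expect_true(all(diff(counts[-1]) <= 0))
})
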