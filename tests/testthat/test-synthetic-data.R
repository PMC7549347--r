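small_cfg <- function(seed = 1) {
  sim_config(seed = seed, n_extra_snorna = 2L, n_extra_trna = 2L,
             n_extra_snrna = 2L, n_extra_mirna = 1L, n_extra_lnc = 1L)
}

test_that("simulation is byte-deterministic under a fixed seed", {
  s1 <- simulate_ncrna(small_cfg())
  s2 <- simulate_ncrna(small_cfg())
  expect_identical(s1$genome, s2$genome)
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$transcripts, s2$transcripts)
  s3 <- simulate_ncrna(small_cfg(seed = 2))
  expect_false(identical(s1$genome, s3$genome))
})

test_that("planted loci respect their intended boundary constructions", {
  sim <- simulate_ncrna(small_cfg())
  truth <- sim$truth
  # genome slice reproduces the oriented planted sequence
  for (i in sample(nrow(truth), 10)) {
    r <- truth[i, ]
    s <- substr(sim$genome[[r$seq_id]], r$start, r$end)
    if (r$strand == "-")
      s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    expect_identical(s, r$sequence)
  }
  # cluster gap fixtures: members of A and B chain, the 500-gap pair does not
  sno <- truth[truth$nc_class == "snoRNA" & truth$seq_id == "chr2", ]
  sno <- sno[order(sno$start), ]
  expect_identical(sno$cluster_id[sno$id %in% c("cd1", "cd2", "cd3")],
                   rep("A", 3))
  gaps <- sno$start[-1] - sno$end[-nrow(sno)] - 1L
  in_b <- which(sno$id %in% c("cd4", "cd5"))
  expect_identical(gaps[in_b[1]], 499L)
  cd6_next <- which(sno$id == "cd6")
  expect_identical(gaps[cd6_next], 500L)
  # tRNA length boundaries are planted exactly
  lens <- truth$end - truth$start + 1L
  expect_setequal(lens[truth$id %in% c("trna_met70", "trna_gly95",
                                       "trna_ala69", "trna_ser96")],
                  c(70L, 95L, 69L, 96L))
  expect_identical(lens[truth$id == "mir_301nt"], 301L)
})

test_that("hit tables carry one above-threshold hit per locus plus sub-threshold decoys", {
  sim <- simulate_ncrna(small_cfg())
  paths <- emit_hit_tables(sim, withr::local_tempdir())
  h <- read_hits(paths$blast6, "blast6")
  is_decoy <- grepl("\\|d[0-9]$", h$query_id)
  expect_identical(sum(is_decoy), 3L)
  expect_true(all(h$query_coverage[!is_decoy] > 90 &
                    h$percent_identity[!is_decoy] > 90))
  kept <- filter_similarity_hits(h)
  expect_true(!any(grepl("\\|d[0-9]$", kept$query_id)))
  # competition fixture: after resolution the higher-coverage hit wins
  u1 <- sim$truth[sim$truth$id == "u1", ]
  over_u1 <- h[h$seq_id == u1$seq_id & h$start <= u1$end & h$end >= u1$start, ]
  expect_identical(nrow(over_u1), 2L)
  res <- resolve_overlaps(filter_similarity_hits(over_u1))
  expect_match(res$query_id, "_win$")
  expect_identical(res$query_coverage, sim$competitions$winner_cov)
})

test_that("simulated reads reproduce intended per-library counts exactly", {
  sim <- simulate_ncrna(small_cfg())
  reads <- simulate_reads(sim)
  truth <- sim$truth
  # miRNA reads sit on mature spans; the tRNA-overlapping lncRNA candidate
  # legitimately shares the tRNA's reads (per-locus independent counting)
  keep <- truth$nc_class != "miRNA" & truth$id != "lnc_over_trna"
  loci <- locus_table(truth$id[keep], truth$seq_id[keep], truth$start[keep],
                      truth$end[keep], truth$strand[keep])
  ev <- count_reads(loci, reads)
  for (lib in c("lib1", "lib2", "lib3"))
    expect_identical(ev[[lib]], truth[[lib]][keep])
  # no reads leak onto loci from the unplaced-scaffold background
  expect_true(all(unlist(lapply(reads, function(r)
    r$seq_id[grepl("^bg", r$id)])) == "chr0"))
})

test_that("an overfull genome is rejected", {
  expect_error(simulate_ncrna(sim_config(seed = 1, chrom_length = 3000L)),
               "genome too small")
})
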