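## Seeded generator of a toy genome with planted ncRNA loci of all six
## classes, emulated similarity/structural/specialist hit tables and
## small-RNA read libraries. Every planted locus carries its intended
## downstream outcome in a truth table, so the whole pipeline can be tested
## closed-loop without any external data. Background reads and decoy hits
## live on an unplaced scaffold ("chr0"), mirroring the pseudomolecule
## bookkeeping of real draft assemblies.

#' Simulation configuration
#'
#' Defaults define the study conditions emulated by the generator: two
#' assembled chromosomes plus an unplaced scaffold, three small-RNA
#' libraries from three independent studies, planted boundary fixtures for
#' every filter (snoRNA cluster gaps 100/499/500 around the strict <500
#' rule; tRNA lengths 69/70/95/96; a 301-nt miRNA precursor; 199/200-nt
#' lncRNA transcripts; read totals of 10 and 11 around the >10 high-support
#' rule) and configurable numbers of additional unremarkable pass loci.
#'
#' @param seed integer seed fixing every random draw.
#' @param chrom_length length of each assembled chromosome (nt).
#' @param n_extra_snorna,n_extra_trna,n_extra_snrna,n_extra_mirna,n_extra_lnc
#'   additional isolated pass loci per class.
#' @param n_background_reads background reads per library placed on the
#'   unplaced scaffold.
#' @param libraries named character vector library -> study.
#' @return config list.
#' @export
sim_config <- function(seed = 1, chrom_length = 50000L,
                       n_extra_snorna = 20L, n_extra_trna = 15L,
                       n_extra_snrna = 8L, n_extra_mirna = 5L,
                       n_extra_lnc = 5L, n_background_reads = 30L,
                       libraries = c(lib1 = "studyA", lib2 = "studyB",
                                     lib3 = "studyC"),
                       source_priority = c("this_study", "prior_study")) {
  if (any(c(n_extra_snorna, n_extra_trna, n_extra_snrna, n_extra_mirna,
            n_extra_lnc, n_background_reads) < 0L))
    stop("counts must be >= 0")
  list(seed = as.integer(seed), chrom_length = as.integer(chrom_length),
       n_extra_snorna = n_extra_snorna, n_extra_trna = n_extra_trna,
       n_extra_snrna = n_extra_snrna, n_extra_mirna = n_extra_mirna,
       n_extra_lnc = n_extra_lnc, n_background_reads = n_background_reads,
       libraries = libraries, source_priority = source_priority)
}

rand_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# genome under construction: per-chromosome character vectors + cursors
.new_builder <- function(chroms, length_each) {
  env <- new.env(parent = emptyenv())
  env$letters <- lapply(chroms, function(ch)
    sample(c("A", "C", "G", "T"), length_each, replace = TRUE))
  names(env$letters) <- chroms
  env$cursor <- stats::setNames(rep(0L, length(chroms)), chroms)
  env
}

# advance the cursor and return the reserved interval (background kept)
.reserve <- function(b, chrom, len, gap = 600L) {
  start <- b$cursor[[chrom]] + gap + 1L
  end <- start + len - 1L
  if (end > length(b$letters[[chrom]]))
    stop("genome too small for requested loci on ", chrom)
  b$cursor[[chrom]] <- end
  c(start = start, end = end)
}

# write a sequence (5'->3' on `strand`) into a reserved slot
.plant <- function(b, chrom, seq, strand = "+", gap = 600L) {
  iv <- .reserve(b, chrom, nchar(seq), gap)
  s <- if (strand == "-") reverse_complement(seq) else seq
  b$letters[[chrom]][iv["start"]:iv["end"]] <- strsplit(s, "")[[1]]
  iv
}

.segment <- function(b, chrom, start, end, strand = "+") {
  s <- paste(b$letters[[chrom]][start:end], collapse = "")
  if (strand == "-") reverse_complement(s) else s
}

# rewrite a region with fresh background until its transcript has no long ORF
.ensure_noncoding <- function(b, chrom, start, end, strand = "+",
                              max_orf = 100L) {
  for (try in 1:50) {
    tx <- .segment(b, chrom, start, end, strand)
    if (longest_orf_codons(tx) < max_orf) return(tx)
    b$letters[[chrom]][start:end] <-
      sample(c("A", "C", "G", "T"), end - start + 1L, replace = TRUE)
  }
  stop("could not generate a noncoding background segment")
}

# -- planted sequence constructors (rejection-sampled so that accidental
#    motifs in the random background never flip the intended verdict) -------

.make_cd_snorna <- function(len = 90L) {
  for (try in 1:100) {
    s <- rand_dna(len)
    s <- paste0(substr(s, 1, 2), "ATGATGA", substr(s, 10, len - 6), "CTGA",
                substr(s, len - 1, len))
    v <- validate_snorna(s)
    if (identical(v$sno_class, "CD") && v$high_confidence) return(s)
  }
  stop("CD snoRNA construction failed")
}

.make_haca_snorna <- function(len = 120L) {
  h <- floor(0.5 * len)
  for (try in 1:100) {
    s <- rand_dna(len)
    s <- paste0(substr(s, 1, h - 1), "AGACTA", substr(s, h + 6, len - 3), "ACA")
    v <- validate_snorna(s, family_label = "HACA")
    if (identical(v$sno_class, "HACA") && v$high_confidence) return(s)
  }
  stop("H/ACA snoRNA construction failed")
}

.make_sno_decoy <- function(len = 100L) {
  # broken boxes: neither motif set may be present anywhere in-window
  for (try in 1:200) {
    s <- rand_dna(len)
    if (is.null(find_cd_boxes(s)) && is.null(find_haca_boxes(s))) return(s)
  }
  stop("snoRNA decoy construction failed")
}

# perfect-stem precursor (paired flanking extensions + mature duplex + loop,
# ~70-90 nt like real plant pre-miRNAs); verified against the rule engine
.make_mirna_hairpin <- function(mature_len = 21L, loop_len = 8L,
                                ext_len = 10L) {
  for (try in 1:100) {
    e5 <- rand_dna(ext_len)
    m5 <- rand_dna(mature_len)
    loop <- paste(sample(c("A", "C"), loop_len, replace = TRUE), collapse = "")
    m3 <- reverse_complement(m5)
    prec <- paste0(e5, m5, loop, m3, reverse_complement(e5))
    off5 <- ext_len + 1L
    off3 <- ext_len + mature_len + loop_len + 1L
    if (!identical(locate_mature(prec, m5), off5)) next
    if (!identical(locate_mature(prec, m3), off3)) next
    fold <- fold_hairpin(prec)
    if (!has_single_hairpin(fold, 15L, c(off5, mature_len),
                            c(off3, mature_len))) next
    ds <- duplex_stats(fold, c(off5, mature_len), c(off3, mature_len))
    if (ds$opposite_arms && ds$mismatched_positions <= 5 &&
        ds$max_asymmetric_bulge <= 3)
      return(list(precursor = prec, mature5p = m5, mature3p = m3,
                  off5 = off5, off3 = off3))
  }
  stop("miRNA hairpin construction failed")
}

# 301-nt precursor around a valid hairpin; every rule except R2 must hold
.make_301_candidate <- function(mature_len = 21L, total = 301L) {
  for (try in 1:100) {
    base <- .make_mirna_hairpin(mature_len)
    pad <- total - nchar(base$precursor)
    left <- pad %/% 2L; right <- pad - left
    prec <- paste0(rand_dna(left), base$precursor, rand_dna(right))
    off5 <- locate_mature(prec, base$mature5p)
    off3 <- locate_mature(prec, base$mature3p)
    if (is.na(off5) || is.na(off3) || off5 >= off3 ||
        !is.null(attr(off5, "multiple")) || !is.null(attr(off3, "multiple")))
      next
    off5 <- as.integer(off5); off3 <- as.integer(off3)
    fold <- fold_hairpin(prec)
    m1 <- c(off5, mature_len); m2 <- c(off3, mature_len)
    if (!has_single_hairpin(fold, 15L, m1, m2)) next
    ds <- duplex_stats(fold, m1, m2)
    if (ds$opposite_arms && ds$mismatched_positions <= 5 &&
        ds$max_asymmetric_bulge <= 3)
      return(list(precursor = prec, mature5p = base$mature5p,
                  mature3p = base$mature3p))
  }
  stop("301-nt candidate construction failed")
}

.make_no_hairpin_candidate <- function(mature_len = 21L) {
  # both matures located, no qualifying hairpin: intended failures {R3, R8}
  for (try in 1:200) {
    m5 <- rand_dna(mature_len); m3 <- rand_dna(mature_len)
    prec <- paste0(m5, rand_dna(30L), m3)
    fold <- fold_hairpin(prec)
    if (has_single_hairpin(fold, 15L, c(1L, mature_len),
                           c(mature_len + 31L, mature_len))) next
    ds <- duplex_stats(fold, c(1L, mature_len), c(mature_len + 31L, mature_len))
    if (!ds$opposite_arms) return(list(precursor = prec, mature5p = m5,
                                       mature3p = m3))
  }
  stop("no-hairpin candidate construction failed")
}

.truth_row <- function(id, nc_class, chrom, iv, strand, family, sequence,
                       sources, expected_kept, counts = c(0L, 0L, 0L),
                       sno_class = NA_character_, sno_high_conf = NA,
                       cluster_id = NA_character_,
                       mirna_rules_failed = NA_character_,
                       lnc_class = NA_character_) {
  data.frame(id = id, nc_class = nc_class, seq_id = chrom,
             start = unname(iv["start"]), end = unname(iv["end"]),
             strand = strand, family = family, sequence = sequence,
             sources = sources, expected_kept = expected_kept,
             lib1 = counts[1], lib2 = counts[2], lib3 = counts[3],
             sno_class = sno_class, sno_high_conf = sno_high_conf,
             cluster_id = cluster_id,
             mirna_rules_failed = mirna_rules_failed,
             lnc_class = lnc_class, stringsAsFactors = FALSE)
}

#' Simulate a toy genome with planted ncRNA loci and ground truth
#'
#' Generates two assembled chromosomes plus an unplaced scaffold, plants
#' loci of all six ncRNA classes (including engineered boundary failures for
#' every filter), builds gene models for lncRNA classification, candidate
#' transcripts, miRNA candidate records, and a truth table holding every
#' intended downstream verdict. The same seed yields byte-identical output.
#'
#' @param config from [sim_config()].
#' @return list with `genome` (named character vector, incl. `chr0`),
#'   `truth` (data.frame), `genes`, `exons`, `transcripts`,
#'   `mirna_candidates`, `decoy_hits`, `competitions`, `config`.
#' @export
simulate_ncrna <- function(config = sim_config()) {
  set.seed(config$seed)
  b <- .new_builder(c("chr1", "chr2"), config$chrom_length)
  rows <- list()
  add <- function(r) rows[[length(rows) + 1L]] <<- r

  ## ---- snoRNAs on chr2: clusters with gaps 100/499/500, strands, decoys --
  exp_counts <- function() c(4L, 4L, 4L)         # expressed + high support
  cd_seq <- replicate(6, .make_cd_snorna(), simplify = TRUE)
  # cluster A: three members, gaps 100/100
  gaps_a <- c(600L, 100L, 100L)
  for (k in 1:3) {
    iv <- .plant(b, "chr2", cd_seq[k], "+", gap = gaps_a[k])
    add(.truth_row(paste0("cd", k), "snoRNA", "chr2", iv, "+", "R71",
                   cd_seq[k], "similarity,structural", TRUE, exp_counts(),
                   sno_class = "CD", sno_high_conf = TRUE, cluster_id = "A"))
  }
  # cluster B: two members, gap 499 (strictly < 500)
  for (k in 4:5) {
    iv <- .plant(b, "chr2", cd_seq[k], "+", gap = if (k == 4) 800L else 499L)
    add(.truth_row(paste0("cd", k), "snoRNA", "chr2", iv, "+", "R12",
                   cd_seq[k], "similarity,structural", TRUE, exp_counts(),
                   sno_class = "CD", sno_high_conf = TRUE, cluster_id = "B"))
  }
  # gap exactly 500: NOT a cluster
  iv <- .plant(b, "chr2", cd_seq[6], "+", gap = 800L)
  add(.truth_row("cd6", "snoRNA", "chr2", iv, "+", "R38", cd_seq[6],
                 "similarity,structural", TRUE, c(50L, 0L, 0L),
                 sno_class = "CD", sno_high_conf = TRUE))
  haca_seq <- replicate(3, .make_haca_snorna(), simplify = TRUE)
  iv <- .plant(b, "chr2", haca_seq[1], "+", gap = 500L)
  add(.truth_row("haca1", "snoRNA", "chr2", iv, "+", "R74-HACA", haca_seq[1],
                 "similarity,structural", TRUE, c(1L, 1L, 0L),
                 sno_class = "HACA", sno_high_conf = TRUE))
  iv <- .plant(b, "chr2", haca_seq[2], "-", gap = 800L)
  add(.truth_row("haca2", "snoRNA", "chr2", iv, "-", "R10-HACA", haca_seq[2],
                 "similarity,structural", TRUE, exp_counts(),
                 sno_class = "HACA", sno_high_conf = TRUE))
  iv <- .plant(b, "chr2", haca_seq[3], "+", gap = 800L)
  add(.truth_row("haca3", "snoRNA", "chr2", iv, "+", "R21-HACA", haca_seq[3],
                 "similarity,structural", TRUE, exp_counts(),
                 sno_class = "HACA", sno_high_conf = TRUE))
  # evidence-only decoys: boxes broken, still snoRNA loci, not high confidence
  for (k in 1:2) {
    s <- .make_sno_decoy()
    iv <- .plant(b, "chr2", s, "+", gap = 800L)
    add(.truth_row(paste0("snodecoy", k), "snoRNA", "chr2", iv, "+", "Rx",
                   s, "similarity", TRUE, exp_counts(),
                   sno_class = NA_character_, sno_high_conf = FALSE))
  }

  ## ---- tRNAs on chr2: 69/70/95/96 boundaries, SeC, isoacceptors ----------
  trna_spec <- list(
    list(id = "trna_met70", len = 70L, iso = "Met", ac = "CAT", keep = TRUE),
    list(id = "trna_leu72", len = 72L, iso = "Leu", ac = "CAA", keep = TRUE),
    list(id = "trna_leu75", len = 75L, iso = "Leu", ac = "CAA", keep = TRUE),
    list(id = "trna_leu80", len = 80L, iso = "Leu", ac = "TAA", keep = TRUE),
    list(id = "trna_his74", len = 74L, iso = "His", ac = "GTG", keep = TRUE),
    list(id = "trna_gly95", len = 95L, iso = "Gly", ac = "GCC", keep = TRUE),
    list(id = "trna_ala69", len = 69L, iso = "Ala", ac = "AGC", keep = FALSE),
    list(id = "trna_ser96", len = 96L, iso = "Ser", ac = "AGA", keep = FALSE),
    list(id = "trna_sec85", len = 85L, iso = "SeC", ac = "TCA", keep = TRUE))
  for (t in trna_spec) {
    s <- rand_dna(t$len)
    iv <- .plant(b, "chr2", s, "+", gap = 800L)
    add(.truth_row(t$id, "tRNA", "chr2", iv, "+",
                   paste0("tRNA-", t$iso, "-", t$ac), s, "specialist",
                   t$keep, if (t$keep) exp_counts() else c(0L, 0L, 0L)))
  }

  ## ---- rRNAs on chr2 ------------------------------------------------------
  rrna_spec <- list(
    list(id = "r5s_1", len = 120L, fam = "5S_rRNA"),
    list(id = "r5s_2", len = 119L, fam = "5S_rRNA"),
    list(id = "r58s", len = 155L, fam = "5_8S_rRNA"),
    list(id = "rssu", len = 302L, fam = "SSU_rRNA_eukarya"),
    list(id = "rindet", len = 150L, fam = "rRNA_x"))
  for (t in rrna_spec) {
    s <- rand_dna(t$len)
    iv <- .plant(b, "chr2", s, "+", gap = 800L)
    cnt <- if (t$id == "rindet") c(0L, 0L, 0L) else exp_counts()
    add(.truth_row(t$id, "rRNA", "chr2", iv, "+", t$fam, s,
                   "similarity,structural", TRUE, cnt))
  }

  ## ---- snRNAs on chr1: 60-220 bounds, read-total boundaries, competitor --
  snrna_spec <- list(
    list(id = "u1", len = 160L, fam = "U1", strand = "+", keep = TRUE,
         counts = c(5L, 5L, 0L)),                    # total 10: not high support
    list(id = "u2", len = 90L, fam = "U2", strand = "-", keep = TRUE,
         counts = c(6L, 5L, 0L)),                    # total 11: high support
    list(id = "u6", len = 199L, fam = "U6", strand = "+", keep = TRUE,
         counts = c(4L, 4L, 4L)),
    list(id = "u6atac", len = 140L, fam = "U6atac", strand = "+", keep = TRUE,
         counts = c(4L, 4L, 4L)),
    list(id = "u6_long", len = 230L, fam = "U6", strand = "+", keep = FALSE,
         counts = c(0L, 0L, 0L)))
  for (t in snrna_spec) {
    s <- rand_dna(t$len)
    iv <- .plant(b, "chr1", s, t$strand, gap = 800L)
    add(.truth_row(t$id, "snRNA", "chr1", iv, t$strand, t$fam, s,
                   "similarity", t$keep, t$counts))
  }

  ## ---- miRNA candidates on chr1 ------------------------------------------
  mir <- list(); mrow <- function(x) mir[[length(mir) + 1L]] <<- x
  plant_mir <- function(id, hp, fam, rules_failed, counts5, counts3,
                        source = "this_study") {
    iv <- .plant(b, "chr1", hp$precursor, "+", gap = 800L)
    add(.truth_row(id, "miRNA", "chr1", iv, "+", fam, hp$precursor,
                   "similarity", TRUE, counts5 + counts3,
                   mirna_rules_failed = rules_failed))
    mrow(data.frame(id = id, precursor = hp$precursor,
                    mature5p = hp$mature5p, mature3p = hp$mature3p,
                    source = source, family = fam, seq_id = "chr1",
                    start = unname(iv["start"]), end = unname(iv["end"]),
                    strand = "+",
                    m5_lib1 = counts5[1], m5_lib2 = counts5[2],
                    m5_lib3 = counts5[3], m3_lib1 = counts3[1],
                    m3_lib2 = counts3[2], m3_lib3 = counts3[3],
                    stringsAsFactors = FALSE))
  }
  r <- c(3L, 3L, 0L)                                  # per-mature read support
  pass1 <- .make_mirna_hairpin(21L); pass2 <- .make_mirna_hairpin(22L)
  pass3 <- .make_mirna_hairpin(21L)
  plant_mir("mir_pass1", pass1, "miR-171", "", r, r)
  plant_mir("mir_pass2", pass2, "miR-399", "", r, r)
  plant_mir("mir_pass3", pass3, "miR-156", "", r, r)
  # R2: pad a valid hairpin to exactly 301 nt (rejection-verified so that
  # only the length rule fails)
  hp301 <- .make_301_candidate()
  plant_mir("mir_301nt", hp301, "miR-827", "R2", r, r)
  # R4: single mature
  single <- .make_mirna_hairpin(21L)
  single$mature3p <- NA_character_
  plant_mir("mir_single", single, "miR-398", "R4", r, c(0L, 0L, 0L))
  # R3+R8: matures located but no hairpin
  nohp <- .make_no_hairpin_candidate()
  plant_mir("mir_nohairpin", nohp, "miR-160", "R3,R8", r, r)
  # R6: 23-nt matures
  hp23 <- .make_mirna_hairpin(23L)
  plant_mir("mir_23nt", hp23, "miR-479", "R6", r, r)
  # R7: no expression
  hp_noexpr <- .make_mirna_hairpin(21L)
  plant_mir("mir_noreads", hp_noexpr, "miR-1446", "R7",
            c(0L, 0L, 0L), c(0L, 0L, 0L))
  # R1: redundant duplicate of pass1 from a prior study (no genomic anchor)
  mrow(data.frame(id = "mir_dup1", precursor = pass1$precursor,
                  mature5p = pass1$mature5p, mature3p = pass1$mature3p,
                  source = "prior_study", family = "miR-171",
                  seq_id = NA_character_, start = NA_integer_,
                  end = NA_integer_, strand = NA_character_,
                  m5_lib1 = 0L, m5_lib2 = 0L, m5_lib3 = 0L,
                  m3_lib1 = 0L, m3_lib2 = 0L, m3_lib3 = 0L,
                  stringsAsFactors = FALSE))

  ## ---- extra unremarkable pass loci --------------------------------------
  extra_chrom <- function(i) if (i %% 2L == 0L) "chr1" else "chr2"
  if (config$n_extra_snorna > 0L) for (k in seq_len(config$n_extra_snorna)) {
    s <- .make_cd_snorna(80L + 2L * (k %% 10L))
    ch <- extra_chrom(k)
    iv <- .plant(b, ch, s, "+", gap = 800L)
    add(.truth_row(sprintf("xsno%02d", k), "snoRNA", ch, iv, "+",
                   sprintf("R%d", 40 + k), s, "similarity,structural", TRUE,
                   exp_counts(), sno_class = "CD", sno_high_conf = TRUE))
  }
  iso_pool <- list(c("Leu", "CAG"), c("Ala", "AGC"), c("Gly", "GCC"),
                   c("Ser", "GCT"), c("Val", "AAC"), c("Thr", "AGT"))
  if (config$n_extra_trna > 0L) for (k in seq_len(config$n_extra_trna)) {
    pick <- iso_pool[[1L + (k %% length(iso_pool))]]
    len <- 71L + (k %% 20L)
    s <- rand_dna(len)
    ch <- extra_chrom(k)
    iv <- .plant(b, ch, s, "+", gap = 800L)
    add(.truth_row(sprintf("xtrna%02d", k), "tRNA", ch, iv, "+",
                   paste0("tRNA-", pick[1], "-", pick[2]), s, "specialist",
                   TRUE, exp_counts()))
  }
  ufams <- c("U1", "U2", "U4", "U5", "U6", "U11", "U12")
  if (config$n_extra_snrna > 0L) for (k in seq_len(config$n_extra_snrna)) {
    len <- 90L + 10L * (k %% 10L)
    s <- rand_dna(len)
    ch <- extra_chrom(k)
    iv <- .plant(b, ch, s, "+", gap = 800L)
    add(.truth_row(sprintf("xsnrna%02d", k), "snRNA", ch, iv, "+",
                   ufams[1L + (k %% length(ufams))], s, "similarity", TRUE,
                   exp_counts()))
  }
  if (config$n_extra_mirna > 0L) for (k in seq_len(config$n_extra_mirna)) {
    hp <- .make_mirna_hairpin(21L + (k %% 2L))
    plant_mir(sprintf("xmir%02d", k), hp, sprintf("miR-%d", 300 + k), "", r, r)
  }

  ## ---- gene models and lncRNA candidates on chr1 --------------------------
  gene_len <- 900L
  g_iv <- .reserve(b, "chr1", gene_len, gap = 800L)
  g1s <- unname(g_iv["start"]); g1e <- unname(g_iv["end"])
  genes <- data.frame(id = "gene1", seq_id = "chr1", start = g1s, end = g1e,
                      strand = "+", stringsAsFactors = FALSE)
  exons <- data.frame(gene_id = c("gene1", "gene1"), seq_id = "chr1",
                      start = c(g1s, g1s + 600L),
                      end = c(g1s + 299L, g1e), strand = "+",
                      stringsAsFactors = FALSE)
  tx <- character(0)
  lnc_hit_rows <- list()
  lnc_hit <- function(id, chrom, start, end, strand) {
    lnc_hit_rows[[length(lnc_hit_rows) + 1L]] <<-
      data.frame(id = id, seq_id = chrom, start = start, end = end,
                 strand = strand, stringsAsFactors = FALSE)
  }
  add_lnc <- function(id, chrom, start, end, strand, lnc_class, counts,
                      kept = TRUE, rewrite = TRUE) {
    seq <- if (rewrite) .ensure_noncoding(b, chrom, start, end, strand) else
      .segment(b, chrom, start, end, strand)
    tx[id] <<- seq
    lnc_hit(id, chrom, start, end, strand)
    add(.truth_row(id, "lncRNA", chrom, c(start = start, end = end), strand,
                   "", seq, "similarity", kept, counts,
                   lnc_class = if (kept) lnc_class else NA_character_))
  }
  add_lnc("lnc_sense", "chr1", g1s - 50L, g1s + 249L, "+", "sense",
          exp_counts())
  add_lnc("lnc_antisense", "chr1", g1s + 650L, g1e + 49L, "-", "antisense",
          exp_counts())
  add_lnc("lnc_intronic", "chr1", g1s + 320L, g1s + 559L, "+", "gene_overlap",
          exp_counts())
  iv <- .reserve(b, "chr1", 350L, gap = 800L)
  add_lnc("lnc_intergenic1", "chr1", unname(iv["start"]), unname(iv["end"]),
          "+", "no_overlap", exp_counts())
  iv <- .reserve(b, "chr1", 260L, gap = 800L)
  add_lnc("lnc_intergenic2", "chr1", unname(iv["start"]), unname(iv["end"]),
          "+", "no_overlap", c(1L, 0L, 1L))
  # candidate overlapping a planted tRNA locus: excluded at the ncRNA stage
  t72 <- rows[[which(vapply(rows, function(x) x$id, "") == "trna_leu72")]]
  add_lnc("lnc_over_trna", "chr2", t72$start - 150L, t72$end + 150L, "+",
          NA_character_, c(0L, 0L, 0L), kept = FALSE, rewrite = FALSE)
  if (config$n_extra_lnc > 0L) for (k in seq_len(config$n_extra_lnc)) {
    iv <- .reserve(b, extra_chrom(k), 220L + 30L * k, gap = 800L)
    add_lnc(sprintf("xlnc%02d", k), extra_chrom(k), unname(iv["start"]),
            unname(iv["end"]), "+", "no_overlap", exp_counts())
  }
  # transcripts removed before anchoring: too short, coding, redundant copy
  tx["lnc_tooshort"] <- rand_dna(199L)
  codons <- names(standard_code())[standard_code() != "*"]
  tx["lnc_coding"] <- paste0(rand_dna(50L), "ATG",
                             paste(sample(codons, 150L, replace = TRUE),
                                   collapse = ""), "TAA", rand_dna(30L))
  # truncated exact copy: clusters with (and under) the longer original
  tx["lnc_dup"] <- substr(tx[["lnc_intergenic1"]], 1L,
                          floor(0.8 * nchar(tx[["lnc_intergenic1"]])))

  ## ---- assemble -----------------------------------------------------------
  genome <- vapply(b$letters, paste, "", collapse = "")
  genome["chr0"] <- rand_dna(5000L)
  truth <- do.call(rbind, rows)
  rownames(truth) <- NULL
  truth$expressed <- .expected_expressed(truth, config$libraries)
  truth$high_support <- (truth$lib1 + truth$lib2 + truth$lib3) > 10L
  mirna_candidates <- do.call(rbind, mir)
  rownames(mirna_candidates) <- NULL
  # overlap-resolution competition fixture (extra losing hit over u1)
  competitions <- data.frame(locus_id = "u1", winner_cov = 97, loser_cov = 93,
                             stringsAsFactors = FALSE)
  list(genome = genome, truth = truth, genes = genes, exons = exons,
       transcripts = tx, mirna_candidates = mirna_candidates,
       lnc_hits = do.call(rbind, lnc_hit_rows), competitions = competitions,
       config = config)
}

.expected_expressed <- function(truth, libraries) {
  studies <- unique(libraries)
  counts <- as.matrix(truth[, c("lib1", "lib2", "lib3")])
  per_study <- sapply(studies, function(st)
    rowSums(counts[, which(libraries == st), drop = FALSE]) > 0L)
  if (is.null(dim(per_study))) per_study <- matrix(per_study, nrow = 1L)
  rowSums(per_study) >= 2L
}

#' Emit emulated search-tool hit tables for a simulation
#'
#' Writes one above-threshold hit per planted locus into the dialect its
#' evidence source uses (blast6 for similarity, Infernal tblout for
#' structural, tRNAscan tabular for specialist), an extra losing competitor
#' hit over the competition locus (lower coverage, same family), and decoy
#' blast6 hits below the filter thresholds (identity 85, coverage 88,
#' length < 60). lncRNA anchoring hits go to a separate blast6 table with
#' coverage/identity at or above 95.
#'
#' @param sim result of [simulate_ncrna()].
#' @param dir output directory.
#' @return named list of file paths (`blast6`, `infernal`, `trnascan`,
#'   `lnc_blast6`).
#' @export
emit_hit_tables <- function(sim, dir) {
  set.seed(sim$config$seed + 1L)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  truth <- sim$truth
  b6 <- character(0); inf <- character(0); trn <- character(0)
  blast_row <- function(qid, row, pid, cov, evalue, bits, shift = 0L) {
    len <- row$end - row$start + 1L
    s1 <- row$start + shift; s2 <- row$end + shift
    if (row$strand == "-") { tmp <- s1; s1 <- s2; s2 <- tmp }
    paste(qid, row$seq_id, sprintf("%.2f", pid), len, 0, 0, 1, len, s1, s2,
          sprintf("%.1e", evalue), sprintf("%.1f", bits),
          sprintf("%.1f", cov), sep = "\t")
  }
  infernal_row <- function(qid, row, bits, evalue) {
    paste(row$seq_id, "-", qid, "-", "cm", 1, row$end - row$start + 1L,
          if (row$strand == "-") row$end else row$start,
          if (row$strand == "-") row$start else row$end,
          row$strand, "no", 1, 0.5, 0.0, sprintf("%.1f", bits),
          sprintf("%.1e", evalue), "!", "-")
  }
  ntr <- 0L
  comp <- sim$competitions
  for (i in seq_len(nrow(truth))) {
    row <- truth[i, ]
    if (row$nc_class == "lncRNA") next
    qid <- paste(row$nc_class, row$family, paste0("q_", row$id), sep = "|")
    srcs <- strsplit(row$sources, ",")[[1]]
    pid <- stats::runif(1, 94, 99.5)
    cov <- stats::runif(1, 95, 100)
    bits <- stats::runif(1, 100, 200)
    ev <- 10^stats::runif(1, -40, -20)
    if ("similarity" %in% srcs && !(row$id %in% comp$locus_id))
      b6 <- c(b6, blast_row(qid, row, pid, cov, ev, bits))
    if ("structural" %in% srcs)
      inf <- c(inf, infernal_row(qid, row, bits - 50, ev * 10))
    if ("specialist" %in% srcs) {
      ntr <- ntr + 1L
      parts <- strsplit(row$family, "-")[[1]]
      begin <- if (row$strand == "-") row$end else row$start
      endc <- if (row$strand == "-") row$start else row$end
      trn <- c(trn, paste(row$seq_id, ntr, begin, endc, parts[2], parts[3],
                          0, 0, sprintf("%.1f", stats::runif(1, 50, 90)),
                          sep = "\t"))
    }
  }
  # competing hit pair over the competition locus: same family, the higher
  # coverage wins
  for (i in seq_len(nrow(comp))) {
    row <- truth[truth$id == comp$locus_id[i], ]
    qid <- paste(row$nc_class, row$family, paste0("q_", row$id, "_win"), sep = "|")
    b6 <- c(b6, blast_row(qid, row, 96, comp$winner_cov[i], 1e-30, 150))
    qid_l <- paste(row$nc_class, row$family, paste0("q_", row$id, "_lose"), sep = "|")
    b6 <- c(b6, blast_row(qid_l, row, 96, comp$loser_cov[i], 1e-30, 150,
                          shift = 10L))
  }
  # decoys, below thresholds, on the unplaced scaffold
  decoy <- data.frame(seq_id = "chr0", start = c(100L, 600L, 1100L),
                      end = c(100L + 79L, 600L + 79L, 1100L + 49L),
                      strand = "+", stringsAsFactors = FALSE)
  b6 <- c(b6,
          blast_row("snoRNA|Rdecoy|d1", decoy[1, ], 85, 98, 1e-10, 80),
          blast_row("snoRNA|Rdecoy|d2", decoy[2, ], 97, 88, 1e-10, 80),
          blast_row("snRNA|U1|d3", decoy[3, ], 97, 98, 1e-10, 80))
  # lncRNA anchoring hits
  lh <- sim$lnc_hits
  lb6 <- vapply(seq_len(nrow(lh)), function(i)
    blast_row(lh$id[i], lh[i, ], 99, 100, 1e-50, 300), "")
  paths <- list(blast6 = file.path(dir, "similarity_hits.blast6.tsv"),
                infernal = file.path(dir, "structural_hits.tblout"),
                trnascan = file.path(dir, "trnascan_hits.tsv"),
                lnc_blast6 = file.path(dir, "lncrna_anchor_hits.blast6.tsv"))
  writeLines(b6, paths$blast6)
  writeLines(c("# emulated cmsearch tblout", inf,
               "# [ok]"), paths$infernal)
  writeLines(c("Sequence\t\tBounds\t", "Name\ttRNA #\tBegin\tEnd\tType\tCodon\tBegin\tEnd\tScore",
               "--------\t------\t-----\t---\t----\t-----\t-----\t---\t-----",
               trn), paths$trnascan)
  writeLines(lb6, paths$lnc_blast6)
  paths
}

#' Simulate small-RNA read libraries
#'
#' Places, for every planted locus, exactly the intended number of reads per
#' library (18-25 nt, within the locus, on its strand; for miRNA loci the
#' reads sit on the mature spans), plus background reads on the unplaced
#' scaffold. Same seed, same reads.
#'
#' @param sim result of [simulate_ncrna()].
#' @param dir optional directory; when given, one BED6 file per library is
#'   written.
#' @return named list (per library) of read tables.
#' @export
simulate_reads <- function(sim, dir = NULL) {
  set.seed(sim$config$seed + 2L)
  libs <- names(sim$config$libraries)
  out <- stats::setNames(vector("list", length(libs)), libs)
  for (l in libs) out[[l]] <- list()
  emit <- function(lib, chrom, start, end, strand, n, tag) {
    if (n <= 0L) return()
    span <- end - start + 1L
    len <- pmin(span, sample(18:25, n, replace = TRUE))
    s <- start + vapply(span - len, function(m) sample.int(m + 1L, 1L) - 1L, 1L)
    out[[lib]][[length(out[[lib]]) + 1L]] <<- data.frame(
      seq_id = chrom, start = s, end = s + len - 1L, strand = strand,
      id = paste0(tag, "_", lib, "_", seq_len(n)), stringsAsFactors = FALSE)
  }
  truth <- sim$truth
  mir_ids <- sim$mirna_candidates$id
  for (i in seq_len(nrow(truth))) {
    row <- truth[i, ]
    if (row$nc_class == "miRNA") next          # placed on mature spans below
    for (k in seq_along(libs))
      emit(libs[k], row$seq_id, row$start, row$end, row$strand,
           row[[paste0("lib", k)]], row$id)
  }
  mc <- sim$mirna_candidates
  for (i in seq_len(nrow(mc))) {
    if (is.na(mc$start[i])) next
    off5 <- locate_mature(mc$precursor[i], mc$mature5p[i])
    len5 <- nchar(mc$mature5p[i])
    for (k in seq_along(libs))
      emit(libs[k], mc$seq_id[i], mc$start[i] + off5 - 1L,
           mc$start[i] + off5 + len5 - 2L, mc$strand[i],
           mc[[paste0("m5_lib", k)]][i], paste0(mc$id[i], "_m5"))
    if (!is.na(mc$mature3p[i])) {
      off3 <- locate_mature(mc$precursor[i], mc$mature3p[i])
      len3 <- nchar(mc$mature3p[i])
      for (k in seq_along(libs))
        emit(libs[k], mc$seq_id[i], mc$start[i] + off3 - 1L,
             mc$start[i] + off3 + len3 - 2L, mc$strand[i],
             mc[[paste0("m3_lib", k)]][i], paste0(mc$id[i], "_m3"))
    }
  }
  nb <- sim$config$n_background_reads
  if (nb > 0L) for (l in libs)
    emit(l, "chr0", 1L, 4000L, "+", nb, "bg")
  for (l in libs) {
    out[[l]] <- if (length(out[[l]])) do.call(rbind, out[[l]]) else
      data.frame(seq_id = character(0), start = integer(0), end = integer(0),
                 strand = character(0), id = character(0),
                 stringsAsFactors = FALSE)
    rownames(out[[l]]) <- NULL
  }
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (l in libs) {
      r <- out[[l]]
      loci <- locus_table(r$id, r$seq_id, r$start, r$end, r$strand)
      write_bed(loci, file.path(dir, paste0(l, ".reads.bed")))
    }
  }
  out
}
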