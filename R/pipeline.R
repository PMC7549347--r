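## End-to-end orchestration: evidence merging -> class filters -> snoRNA
## validation/clustering -> miRNA curation -> lncRNA pipeline -> expression
## flagging -> summary report. All stage outputs are written as
## GFF3/BED/TSV, deterministically (stable sort orders, no timestamps), so a
## rerun with the same seed and config is byte-identical.

#' Pipeline configuration
#'
#' Collects every threshold of the curation pipeline with its default:
#' similarity filter coverage/identity strictly over 90% and length >= 60 nt;
#' snRNA length 60-220 nt; tRNA length 70-95 nt; snoRNA box windows (C and D
#' 10 nt terminal, ACA 6 nt, hinge 35-75%) and cluster gap < 500 nt; miRNA
#' precursor <= 300 nt with 21-22 nt matures; lncRNA length >= 200 nt,
#' redundancy identity 0.80, anchoring coverage/identity >= 95%; expression
#' evidence from >= 2 independent studies, high support > 10 total reads;
#' target expectation cutoff 2; bootstrap replicates 5000.
#'
#' @param ... overrides of any listed element.
#' @return validated config list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    min_cov = 90, min_id = 90, min_len = 60,
    snrna_len = c(60L, 220L), trna_len = c(70L, 95L),
    sno_c_window = 10L, sno_d_window = 10L, sno_aca_window = 6L,
    sno_hinge = c(0.35, 0.75), cluster_gap = 500L,
    mirna = mirna_config(),
    lnc_min_len = 200L, lnc_identity = 0.80, lnc_min_cov = 95,
    lnc_min_id = 95,
    min_studies = 2L, hc_reads = 10L,
    target_cutoff = 2.0, bootstrap_replicates = 5000L,
    stranded = TRUE,
    chromosomes = c("chr1", "chr2"))
  user <- list(...)
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg[names(user)] <- user
  for (key in c("snrna_len", "trna_len")) {
    if (length(cfg[[key]]) != 2L || cfg[[key]][1] > cfg[[key]][2])
      stop("invalid bounds for ", key)
  }
  if (cfg$lnc_identity <= 0 || cfg$lnc_identity > 1)
    stop("lnc_identity must be in (0, 1]")
  cfg
}

#' Run the curation pipeline on a simulation
#'
#' Emits the simulation's hit tables and read libraries to disk, reads them
#' back through the format readers, and runs every stage: similarity and
#' structural filtering, per-source overlap resolution, cross-source
#' merging, snRNA/tRNA/rRNA selection, snoRNA box validation and
#' clustering, miRNA curation (with expression support recomputed from the
#' simulated reads over the mature spans), the lncRNA pipeline, expression
#' flagging of every kept locus, and the summary report.
#'
#' @param sim result of [simulate_ncrna()].
#' @param config [pipeline_config()].
#' @param out_dir artifacts directory (default: a temporary directory).
#' @return list with per-stage outputs (`merged`, `loci` by class,
#'   `clusters`, `mirna` report, `lncrna`, `evidence`, `report`,
#'   `out_dir`).
#' @export
run_pipeline <- function(sim, config = pipeline_config(), out_dir = NULL) {
  if (is.null(out_dir)) out_dir <- tempfile("ncrna_run_")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- emit_hit_tables(sim, file.path(out_dir, "hits"))
  reads <- simulate_reads(sim, file.path(out_dir, "reads"))

  ## evidence merging
  sim_hits <- read_hits(paths$blast6, "blast6")
  str_hits <- read_hits(paths$infernal, "infernal_tblout")
  spec_hits <- read_hits(paths$trnascan, "trnascan_tab")
  f_sim <- filter_similarity_hits(sim_hits, config$min_cov, config$min_id,
                                  config$min_len)
  f_str <- filter_structural_hits(str_hits, config$min_len)
  r_sim <- resolve_overlaps(f_sim, tiebreak_cascade(), config$stranded)
  r_str <- resolve_overlaps(f_str, structural_cascade(), config$stranded)
  r_spec <- resolve_overlaps(spec_hits, merge_cascade(), config$stranded)
  merged <- merge_sources(r_sim, r_str, r_spec, merge_cascade(),
                          config$stranded)
  loci <- hits_to_loci(merged, sim$genome)

  ## class-specific stages
  by_class <- function(cl) loci[!is.na(loci$nc_class) & loci$nc_class == cl, ,
                                drop = FALSE]
  snrna <- select_snrna(by_class("snRNA"), config$snrna_len[1],
                        config$snrna_len[2])
  trna <- select_trna(by_class("tRNA"), config$trna_len[1],
                      config$trna_len[2])
  isoacceptors <- isoacceptor_table(trna)
  rrna <- select_rrna(by_class("rRNA"))
  snorna <- validate_snorna_loci(by_class("snoRNA"),
                                 min_len = config$min_len,
                                 c_window = config$sno_c_window,
                                 d_window = config$sno_d_window,
                                 aca_window = config$sno_aca_window,
                                 hinge = config$sno_hinge)
  clusters <- detect_clusters(snorna, config$cluster_gap)
  mirna_loci <- by_class("miRNA")

  ## miRNA curation with read support over the mature spans
  mc <- sim$mirna_candidates
  mature_rows <- list()
  for (i in seq_len(nrow(mc))) {
    if (is.na(mc$start[i])) next
    for (arm in c("mature5p", "mature3p")) {
      mat <- mc[[arm]][i]
      if (is.na(mat) || !nzchar(mat)) next
      off <- locate_mature(mc$precursor[i], mat)
      if (is.na(off)) next
      mature_rows[[length(mature_rows) + 1L]] <- data.frame(
        key = normalize_seq(mat), seq_id = mc$seq_id[i],
        start = mc$start[i] + off - 1L,
        end = mc$start[i] + off + nchar(mat) - 2L,
        strand = mc$strand[i], stringsAsFactors = FALSE)
    }
  }
  mirna_expression <- NULL
  if (length(mature_rows)) {
    mt <- do.call(rbind, mature_rows)
    mt_loci <- locus_table(paste0("m", seq_len(nrow(mt))), mt$seq_id,
                           mt$start, mt$end, mt$strand)
    ev <- count_reads(mt_loci, reads, config$stranded)
    mirna_expression <- data.frame(key = mt$key, stringsAsFactors = FALSE)
    for (lib in names(reads)) mirna_expression[[lib]] <- ev[[lib]]
  }
  mir_cfg <- config$mirna
  if (is.null(mir_cfg$source_priority))
    mir_cfg$source_priority <- sim$config$source_priority
  curation <- curate_mirnas(mc, mirna_expression, mir_cfg)

  ## lncRNA pipeline
  lnc_hits <- read_hits(paths$lnc_blast6, "blast6")
  small_core <- rbind(snrna[, names(empty_locus_table())],
                      trna[, names(empty_locus_table())],
                      rrna[, names(empty_locus_table())],
                      snorna[, names(empty_locus_table())],
                      mirna_loci[, names(empty_locus_table())])
  lncrna <- lncrna_pipeline(sim$transcripts, lnc_hits, small_core,
                            sim$genes, sim$exons,
                            min_len = config$lnc_min_len,
                            identity = config$lnc_identity,
                            min_cov = config$lnc_min_cov,
                            min_id = config$lnc_min_id)

  ## expression evidence over every kept locus
  all_loci <- rbind(small_core, lncrna[, names(empty_locus_table())])
  evidence <- count_reads(all_loci, reads, config$stranded)
  evidence <- flag_expression(evidence, sim$config$libraries,
                              config$min_studies, config$hc_reads)
  flag_at <- match(all_loci$id, evidence$id)
  all_loci$expressed <- evidence$expressed[flag_at]
  all_loci$high_support <- evidence$high_support[flag_at]

  report <- ncrna_report(all_loci, evidence, isoacceptors, clusters,
                         curation$summary, lncrna, config$chromosomes)

  ## artifacts
  write_gff3(all_loci, file.path(out_dir, "ncrna_loci.gff3"))
  write_bed(all_loci, file.path(out_dir, "ncrna_loci.bed"))
  export_count_matrix(evidence, file.path(out_dir, "counts.tsv"),
                      names(reads))
  utils::write.table(clusters, file.path(out_dir, "snorna_clusters.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(curation$report,
                     file.path(out_dir, "mirna_curation.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(isoacceptors$table,
                     file.path(out_dir, "trna_isoacceptors.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(format_report(report), file.path(out_dir, "report.txt"))

  list(merged = merged, loci = list(snRNA = snrna, tRNA = trna, rRNA = rrna,
                                    snoRNA = snorna, miRNA = mirna_loci,
                                    lncRNA = lncrna),
       all_loci = all_loci, isoacceptors = isoacceptors, clusters = clusters,
       mirna = curation, lncrna = lncrna, evidence = evidence,
       report = report, out_dir = out_dir)
}

#' Summary report of a pipeline run
#'
#' Tallies per-class locus counts (assembled chromosomes and unplaced
#' scaffolds reported separately), the per-chromosome distribution, the mean
#' length of the small ncRNAs (snRNA, snoRNA, tRNA, rRNA and miRNA
#' precursor loci), the isoacceptor table, snoRNA clusters, miRNA curation
#' buckets, lncRNA positional class counts and expression tallies.
#'
#' @param all_loci combined locus table with class and expression flags.
#' @param evidence flagged output of [flag_expression()].
#' @param isoacceptors output of [isoacceptor_table()].
#' @param clusters output of [detect_clusters()].
#' @param mirna_summary curation summary buckets.
#' @param lncrna classified lncRNA table.
#' @param chromosomes assembled chromosome names; loci elsewhere are counted
#'   separately.
#' @return report list.
#' @export
ncrna_report <- function(all_loci, evidence, isoacceptors, clusters,
                         mirna_summary, lncrna,
                         chromosomes = c("chr1", "chr2")) {
  assembled <- all_loci$seq_id %in% chromosomes
  per_class <- table(factor(all_loci$nc_class[assembled], levels = NC_CLASSES))
  per_chrom <- table(all_loci$seq_id)
  small <- assembled & all_loci$nc_class %in% c("snRNA", "snoRNA", "tRNA",
                                                "rRNA", "miRNA")
  lnc_classes <- if (nrow(lncrna) && !is.null(lncrna$lnc_class))
    table(factor(lncrna$lnc_class, levels = LNC_CLASSES)) else
      table(factor(character(0), levels = LNC_CLASSES))
  list(per_class = per_class,
       total = sum(per_class),
       unplaced = sum(!assembled),
       per_chromosome = per_chrom,
       mean_small_ncrna_length =
         mean(all_loci$end[small] - all_loci$start[small] + 1L),
       isoacceptors = isoacceptors,
       n_clusters = nrow(clusters),
       n_clustered_genes = sum(clusters$n_members),
       mirna_summary = mirna_summary,
       lnc_classes = lnc_classes,
       n_expressed = sum(evidence$expressed),
       n_high_support = sum(evidence$high_support))
}

#' @rdname ncrna_report
#' @param report report list.
#' @export
format_report <- function(report) {
  c("ncRNA curation summary",
    "----------------------",
    sprintf("%-8s %6d", names(report$per_class), as.integer(report$per_class)),
    sprintf("total    %6d", report$total),
    sprintf("unplaced %6d", report$unplaced),
    "",
    sprintf("mean small-ncRNA length: %.1f nt", report$mean_small_ncrna_length),
    sprintf("distinct tRNA anticodons: %d",
            report$isoacceptors$n_distinct_anticodons),
    sprintf("snoRNA clusters: %d (%d genes)", report$n_clusters,
            report$n_clustered_genes),
    "",
    "lncRNA classes:",
    sprintf("  %-12s %6d", names(report$lnc_classes),
            as.integer(report$lnc_classes)),
    "",
    "miRNA curation buckets:",
    sprintf("  %-10s %6d", report$mirna_summary[[1]],
            report$mirna_summary$n),
    "",
    sprintf("expressed loci: %d", report$n_expressed),
    sprintf("high-support loci: %d", report$n_high_support))
}
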