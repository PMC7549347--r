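## Per-locus small-RNA read support across libraries, expressed /
## high-support flagging, and count-matrix export for external differential
## expression tools.

.loci_granges <- function(loci) {
  GenomicRanges::GRanges(loci$seq_id,
                         IRanges::IRanges(loci$start, loci$end),
                         strand = loci$strand)
}

#' Count reads per locus and library
#'
#' Counts, for every locus and every library, the reads overlapping the
#' locus by at least 1 bp on the same strand (strand-agnostic with
#' `stranded = FALSE`). A read overlapping several loci counts once for each
#' of them. Overlap counting goes through GenomicRanges.
#'
#' @param loci locus table.
#' @param reads named list (one element per library) of read tables with
#'   columns `seq_id`, `start`, `end`, `strand` (e.g. from [read_bed()]).
#' @param stranded strand-aware counting (default TRUE).
#' @return data.frame `id` + one count column per library, plus
#'   `total_reads` and `n_libraries_with_reads`.
#' @export
count_reads <- function(loci, reads, stranded = TRUE) {
  if (is.null(names(reads)) || any(!nzchar(names(reads))))
    stop("reads must be a named list of libraries")
  out <- data.frame(id = loci$id, stringsAsFactors = FALSE)
  lgr <- .loci_granges(loci)
  for (lib in names(reads)) {
    r <- reads[[lib]]
    if (is.null(r) || !nrow(r)) {
      warning("library '", lib, "' has zero reads")
      out[[lib]] <- rep(0L, nrow(loci))
      next
    }
    rgr <- .loci_granges(r)
    out[[lib]] <- GenomicRanges::countOverlaps(lgr, rgr,
                                               ignore.strand = !stranded)
  }
  counts <- as.matrix(out[, names(reads), drop = FALSE])
  out$total_reads <- as.integer(rowSums(counts))
  out$n_libraries_with_reads <- as.integer(rowSums(counts > 0L))
  out
}

#' Flag expressed and high-support loci
#'
#' A locus is `expressed` when reads from at least `min_studies` distinct
#' independent studies support it (>= 1 read in any library of the study),
#' and `high_support` when its total read count across all libraries is
#' strictly greater than `hc_reads`. The two flags are independent; the
#' composite `expressed_or_high_support` is also reported.
#'
#' @param evidence output of [count_reads()].
#' @param studies named character vector mapping library name -> study name;
#'   every count column must be assigned.
#' @param min_studies minimum number of distinct supporting studies.
#' @param hc_reads strict lower bound on total reads for high support.
#' @return `evidence` with columns `n_studies_with_reads`, `expressed`,
#'   `high_support`, `expressed_or_high_support`.
#' @export
flag_expression <- function(evidence, studies, min_studies = 2, hc_reads = 10) {
  libs <- setdiff(names(evidence),
                  c("id", "total_reads", "n_libraries_with_reads",
                    "n_studies_with_reads", "expressed", "high_support",
                    "expressed_or_high_support"))
  if (!all(libs %in% names(studies)))
    stop("unassigned libraries: ",
         paste(setdiff(libs, names(studies)), collapse = ", "))
  counts <- as.matrix(evidence[, libs, drop = FALSE])
  by_study <- sapply(unique(studies[libs]), function(st)
    rowSums(counts[, libs[studies[libs] == st], drop = FALSE]) > 0L)
  if (is.null(dim(by_study))) by_study <- matrix(by_study, nrow = 1L)
  evidence$n_studies_with_reads <- as.integer(rowSums(by_study))
  evidence$expressed <- evidence$n_studies_with_reads >= min_studies
  evidence$high_support <- evidence$total_reads > hc_reads
  evidence$expressed_or_high_support <- evidence$expressed | evidence$high_support
  evidence
}

#' Export a count matrix for external DE tools
#'
#' Writes a loci x libraries TSV of integer counts (header: `id` + library
#' names), suitable as input to count-based differential expression tools.
#'
#' @param evidence output of [count_reads()].
#' @param path output TSV.
#' @param libraries library columns to export (default: all count columns).
#' @return the exported data.frame, invisibly.
#' @export
export_count_matrix <- function(evidence, path, libraries = NULL) {
  if (is.null(libraries))
    libraries <- setdiff(names(evidence),
                         c("id", "total_reads", "n_libraries_with_reads",
                           "n_studies_with_reads", "expressed", "high_support",
                           "expressed_or_high_support"))
  tab <- evidence[, c("id", libraries), drop = FALSE]
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(tab)
}

#' Build a contrast (group) file for DE analysis
#'
#' @param counts count data.frame as written by [export_count_matrix()].
#' @param groups named character vector library -> group label (e.g. control
#'   vs one drought cycle); unknown libraries are an error.
#' @param path optional output TSV.
#' @return data.frame (library, group).
#' @export
build_contrast <- function(counts, groups, path = NULL) {
  libs <- setdiff(names(counts), "id")
  unknown <- setdiff(names(groups), libs)
  if (length(unknown))
    stop("unknown library in groups: ", paste(unknown, collapse = ", "))
  if (!all(libs %in% names(groups)))
    stop("libraries without group: ",
         paste(setdiff(libs, names(groups)), collapse = ", "))
  out <- data.frame(library = libs, group = unname(groups[libs]),
                    stringsAsFactors = FALSE)
  if (!is.null(path))
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  out
}
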