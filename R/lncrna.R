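## lncRNA identification and positional classification: length filter,
## redundancy clustering, coding-potential filter (pluggable external labels
## or a self-contained ORF heuristic), genome anchoring, exclusion of loci
## overlapping other ncRNAs, and the four-way positional classification
## against gene models.

LNC_CLASSES <- c("sense", "antisense", "gene_overlap", "no_overlap")

#' Length filter for lncRNA candidate transcripts
#'
#' Long non-coding RNAs are at least 200 nt; the bound is inclusive.
#'
#' @param transcripts named character vector.
#' @param min_len inclusive minimum length (nt).
#' @return filtered named character vector.
#' @export
length_filter <- function(transcripts, min_len = 200) {
  transcripts[nchar(transcripts) >= min_len]
}

# ungapped identity between two sequences: best k-mer-anchored diagonal,
# matches / length of the shorter sequence
.pair_identity <- function(a, b, k = 11L) {
  if (nchar(a) < nchar(b)) { tmp <- a; a <- b; b <- tmp }   # a is longer
  la <- nchar(a); lb <- nchar(b)
  if (lb < k) return(if (a == b) 1 else 0)
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  kmers_b <- substring(b, 1:(lb - k + 1L), k:lb)
  kmers_a <- substring(a, 1:(la - k + 1L), k:la)
  pos_a <- split(seq_along(kmers_a), kmers_a)
  diagonals <- unique(unlist(lapply(seq_along(kmers_b), function(j) {
    ia <- pos_a[[kmers_b[j]]]
    if (is.null(ia)) integer(0) else ia - j
  }), use.names = FALSE))
  if (!length(diagonals)) return(0)
  best <- 0
  for (d in sort(diagonals)) {
    # b position j aligns a position j + d
    js <- seq(max(1L, 1L - d), min(lb, la - d))
    matches <- sum(bv[js] == av[js + d])
    best <- max(best, matches / lb)
  }
  best
}

#' Greedy redundancy clustering of transcripts
#'
#' Deterministic longest-first clustering standing in for CD-HIT-EST: in
#' decreasing length order (ties broken by name), a transcript joins the
#' first existing representative with which its best ungapped
#' k-mer-anchored alignment reaches the identity cutoff (matches over the
#' shorter length); otherwise it becomes a new representative.
#'
#' @param transcripts named character vector.
#' @param identity identity cutoff in `[0, 1]` (default 0.80).
#' @param k anchor k-mer size.
#' @return list with `representatives` (named character vector) and
#'   `clusters` (data.frame member, representative).
#' @export
redundancy_cluster <- function(transcripts, identity = 0.80, k = 11L) {
  transcripts <- normalize_seq(transcripts)
  ord <- order(-nchar(transcripts), names(transcripts))
  reps <- character(0)
  member <- character(0); representative <- character(0)
  for (i in ord) {
    nm <- names(transcripts)[i]
    assigned <- NA_character_
    for (r in reps) {
      if (.pair_identity(transcripts[[r]], transcripts[[i]], k) >= identity) {
        assigned <- r; break
      }
    }
    if (is.na(assigned)) {
      reps <- c(reps, nm)
      assigned <- nm
    }
    member <- c(member, nm); representative <- c(representative, assigned)
  }
  list(representatives = transcripts[reps],
       clusters = data.frame(member = member, representative = representative,
                             stringsAsFactors = FALSE))
}

# longest ORF (in codons, ATG..stop, stop excluded) over all six frames
longest_orf_codons <- function(sequence) {
  sequence <- normalize_seq(sequence)
  best <- 0L
  for (s in c(sequence, reverse_complement(sequence))) {
    v <- strsplit(s, "")[[1]]
    for (frame in 0:2) {
      idx <- seq(frame + 1L, length(v) - (length(v) - frame) %% 3L)
      if (length(idx) < 3L) next
      codons <- paste0(v[idx[c(TRUE, FALSE, FALSE)]],
                       v[idx[c(FALSE, TRUE, FALSE)]],
                       v[idx[c(FALSE, FALSE, TRUE)]])
      aa <- standard_code()[codons]
      aa[is.na(aa)] <- "X"
      open <- NA_integer_
      for (ci in seq_along(codons)) {
        if (is.na(open) && codons[ci] == "ATG") open <- ci
        if (!is.na(open) && aa[ci] == "*") {
          best <- max(best, ci - open)
          open <- NA_integer_
        }
      }
      if (!is.na(open)) best <- max(best, length(codons) - open + 1L)
    }
  }
  best
}

#' Coding-potential filter
#'
#' In `plugin` mode, consumes an external coding/noncoding label table (CPC2
#' style) and an optional protein-database hit id list: transcripts labelled
#' noncoding *and* absent from the protein-hit list are kept; ids missing
#' from the table are treated as coding (conservative) with a message. In
#' `orf_heuristic` mode (a self-contained stand-in for an external coding
#' potential classifier), transcripts whose longest ORF across all six
#' frames is shorter than `max_orf_codons` codons are kept.
#'
#' @param transcripts named character vector.
#' @param mode `"plugin"` or `"orf_heuristic"`.
#' @param labels data.frame (id, label) with labels `"coding"`/`"noncoding"`.
#' @param protein_hits character vector of transcript ids with protein hits.
#' @param max_orf_codons ORF-length threshold (codons) in heuristic mode.
#' @return the noncoding subset of `transcripts`.
#' @export
coding_filter <- function(transcripts, mode = c("orf_heuristic", "plugin"),
                          labels = NULL, protein_hits = character(0),
                          max_orf_codons = 100L) {
  mode <- match.arg(mode)
  if (mode == "plugin") {
    if (is.null(labels)) stop("plugin mode requires a label table")
    lab <- labels$label[match(names(transcripts), labels$id)]
    missing <- is.na(lab)
    if (any(missing))
      message(sum(missing), " transcript(s) missing from the label table ",
              "treated as coding")
    keep <- !missing & tolower(lab) == "noncoding" &
      !names(transcripts) %in% protein_hits
  } else {
    keep <- vapply(transcripts, longest_orf_codons, 1L) < max_orf_codons
  }
  transcripts[keep]
}

#' Anchor candidate transcripts to the genome
#'
#' Keeps transcripts whose best genome hit has query coverage and identity
#' of at least 95% (inclusive bounds), then resolves overlapping anchored
#' loci with the tie-break cascade.
#'
#' @param transcripts named character vector (the candidates).
#' @param hits hit table mapping transcript `query_id`s to the genome.
#' @param min_cov,min_id inclusive bounds (%).
#' @param cascade cascade used for redundancy resolution.
#' @return locus table of anchored lncRNA candidates.
#' @export
anchor_to_genome <- function(transcripts, hits, min_cov = 95, min_id = 95,
                             cascade = tiebreak_cascade()) {
  hits <- hits[hits$query_id %in% names(transcripts), , drop = FALSE]
  ok <- !is.na(hits$query_coverage) & hits$query_coverage >= min_cov &
    !is.na(hits$percent_identity) & hits$percent_identity >= min_id
  hits <- hits[ok, , drop = FALSE]
  if (!nrow(hits)) return(empty_locus_table())
  # best hit per transcript, then cross-transcript overlap resolution
  best <- do.call(rbind, lapply(split(hits, hits$query_id), function(h)
    h[.cascade_order(h, cascade)[1], , drop = FALSE]))
  resolved <- resolve_overlaps(best, cascade)
  loci <- locus_table(id = resolved$query_id, seq_id = resolved$seq_id,
                      start = resolved$start, end = resolved$end,
                      strand = resolved$strand, nc_class = "lncRNA",
                      provenance = "similarity")
  order_loci(loci)
}

#' Exclude candidates overlapping known ncRNA loci
#'
#' Removes candidates sharing at least 1 bp (strand-agnostic) with any
#' snRNA/snoRNA/tRNA/rRNA/miRNA locus.
#'
#' @param candidates locus table of lncRNA candidates.
#' @param ncrna_loci locus table of other ncRNA classes.
#' @return filtered candidate table.
#' @export
exclude_ncrna_overlap <- function(candidates, ncrna_loci) {
  if (is.null(ncrna_loci) || !nrow(ncrna_loci)) {
    warning("no ncRNA loci supplied; candidates returned unchanged")
    return(candidates)
  }
  if (!nrow(candidates)) return(candidates)
  keep <- vapply(seq_len(nrow(candidates)), function(i)
    !any(overlap_widths(candidates[i, ], ncrna_loci, stranded = FALSE) > 0L),
    NA)
  candidates[keep, , drop = FALSE]
}

#' Positionally classify lncRNA candidates against gene models
#'
#' Precedence sense > antisense > gene_overlap > no_overlap: a candidate
#' overlapping an exon on the same strand is `sense`; overlapping an exon on
#' the opposite strand, `antisense`; overlapping a gene span but no exon
#' (e.g. fully intronic, either strand), `gene_overlap`; otherwise
#' `no_overlap` (intergenic). A gene without exon sub-features contributes
#' its whole span as non-exonic gene region.
#'
#' @param candidates locus table.
#' @param genes data.frame (id, seq_id, start, end, strand) of gene spans.
#' @param exons data.frame (gene_id, seq_id, start, end, strand) of exons.
#' @return the candidate table with an `lnc_class` column.
#' @export
classify_position <- function(candidates, genes, exons = NULL) {
  if (!nrow(candidates)) { candidates$lnc_class <- character(0); return(candidates) }
  if (is.null(exons))
    exons <- data.frame(gene_id = character(0), seq_id = character(0),
                        start = integer(0), end = integer(0),
                        strand = character(0), stringsAsFactors = FALSE)
  no_exon <- !genes$id %in% exons$gene_id
  if (any(no_exon))
    message(sum(no_exon), " gene(s) without exon sub-features treated as ",
            "non-exonic gene regions")
  cls <- character(nrow(candidates))
  for (i in seq_len(nrow(candidates))) {
    cand <- candidates[i, ]
    ex_ov <- overlap_widths(cand, exons, stranded = FALSE) > 0L
    if (any(ex_ov & exons$strand == cand$strand)) {
      cls[i] <- "sense"
    } else if (any(ex_ov)) {
      cls[i] <- "antisense"
    } else if (any(overlap_widths(cand, genes, stranded = FALSE) > 0L)) {
      cls[i] <- "gene_overlap"
    } else {
      cls[i] <- "no_overlap"
    }
  }
  candidates$lnc_class <- cls
  candidates
}

#' Run the full lncRNA identification pipeline
#'
#' Stage order: length filter, redundancy clustering, coding filter, genome
#' anchoring, exclusion of known-ncRNA overlaps, positional classification.
#' Each stage's output is a subset of its input.
#'
#' @param transcripts named character vector of candidate transcripts.
#' @param genome_hits hit table anchoring transcripts to the genome.
#' @param ncrna_loci locus table of the other five classes.
#' @param genes,exons gene models (see [classify_position()]).
#' @param min_len,identity,min_cov,min_id stage thresholds.
#' @param coding_mode,labels,protein_hits see [coding_filter()].
#' @return classified lncRNA locus table with a `stage_counts` attribute.
#' @export
lncrna_pipeline <- function(transcripts, genome_hits, ncrna_loci, genes,
                            exons = NULL, min_len = 200, identity = 0.80,
                            min_cov = 95, min_id = 95,
                            coding_mode = "orf_heuristic", labels = NULL,
                            protein_hits = character(0)) {
  n0 <- length(transcripts)
  tx <- length_filter(transcripts, min_len)
  n1 <- length(tx)
  tx <- redundancy_cluster(tx, identity)$representatives
  n2 <- length(tx)
  tx <- coding_filter(tx, coding_mode, labels, protein_hits)
  n3 <- length(tx)
  loci <- anchor_to_genome(tx, genome_hits, min_cov, min_id)
  n4 <- nrow(loci)
  loci <- if (nrow(loci)) exclude_ncrna_overlap(loci, ncrna_loci) else loci
  n5 <- nrow(loci)
  loci <- classify_position(loci, genes, exons)
  attr(loci, "stage_counts") <- c(input = n0, length = n1, redundancy = n2,
                                  coding = n3, anchored = n4, excluded = n5)
  loci
}
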