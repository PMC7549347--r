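## snoRNA box-motif validation (C/D vs H/ACA) and genomic cluster calling.
##
## High-confidence C/D box snoRNAs carry an RUGAUGA-like C box near the
## 5' end and a CUGA D box near the 3' end; H/ACA snoRNAs carry an ANANNA
## H box in the hinge region and an ACA box at the 3' terminus. "Near" the
## termini is quantified as 10-nt terminal windows, the hinge as the central
## 35-75% of the sequence, and the ACA window as the last 6 nt -- all
## configurable, since canonical snoRNA descriptions place the boxes in
## these regions without exact offsets.

#' Locate C and D boxes in a candidate snoRNA sequence
#'
#' The C box is the leftmost RTGATGA match starting within the first
#' `c_window` nt; the D box is the rightmost CTGA match *ending* within the
#' last `d_window` nt. Both are required, and the C box must precede the
#' D box.
#'
#' @param sequence candidate sequence (T-normalized on entry).
#' @param c_window,d_window terminal window sizes (nt).
#' @return list `(kind = "CD", c_box_pos, d_box_pos, c_box, d_box)` or `NULL`.
#' @export
find_cd_boxes <- function(sequence, c_window = 10, d_window = 10) {
  sequence <- normalize_seq(sequence)
  L <- nchar(sequence)
  if (L < 11L) return(NULL)
  c_hits <- iupac_match("RTGATGA", sequence)
  c_hits <- c_hits[c_hits <= c_window]
  if (!length(c_hits)) return(NULL)
  c_pos <- min(c_hits)
  d_hits <- iupac_match("CTGA", sequence)
  d_hits <- d_hits[d_hits + 3L >= L - d_window + 1L & d_hits > c_pos + 6L]
  if (!length(d_hits)) return(NULL)
  d_pos <- max(d_hits)
  list(kind = "CD", c_box_pos = c_pos, d_box_pos = d_pos,
       c_box = substr(sequence, c_pos, c_pos + 6L),
       d_box = substr(sequence, d_pos, d_pos + 3L))
}

#' Locate H and ACA boxes in a candidate snoRNA sequence
#'
#' The ACA box is an ACA trinucleotide starting within the last `aca_window`
#' nt; the H box is an ANANNA match starting within the hinge region
#' `[hinge[1]*L, hinge[2]*L]`. Both are required, with the H box preceding
#' the ACA box.
#'
#' @param sequence candidate sequence.
#' @param aca_window 3'-terminal window (nt) for the ACA box.
#' @param hinge numeric length-2 vector: hinge region as fractions of the
#'   sequence length.
#' @return list `(kind = "HACA", h_box_pos, aca_pos, h_box)` or `NULL`.
#' @export
find_haca_boxes <- function(sequence, aca_window = 6, hinge = c(0.35, 0.75)) {
  sequence <- normalize_seq(sequence)
  L <- nchar(sequence)
  if (L < 12L) return(NULL)
  aca_hits <- iupac_match("ACA", sequence)
  aca_hits <- aca_hits[aca_hits >= L - aca_window + 1L & aca_hits + 2L <= L]
  if (!length(aca_hits)) return(NULL)
  aca_pos <- max(aca_hits)
  h_lo <- max(1L, ceiling(hinge[1] * L))
  h_hi <- floor(hinge[2] * L)
  h_hits <- iupac_match("ANANNA", sequence)
  h_hits <- h_hits[h_hits >= h_lo & h_hits <= h_hi & h_hits + 5L < aca_pos]
  if (!length(h_hits)) return(NULL)
  list(kind = "HACA", h_box_pos = min(h_hits), aca_pos = aca_pos,
       h_box = substr(sequence, min(h_hits), min(h_hits) + 5L))
}

#' Validate a snoRNA candidate by box motifs
#'
#' A candidate within the size bounds is assigned class CD when C/D boxes
#' are found and HACA when H/ACA boxes are found; when both motif sets are
#' present the evidence family label decides (a label containing "HACA"
#' or a known H/ACA family prefix picks HACA), defaulting to CD. Motif
#' success confers `high_confidence = TRUE`; candidates failing both motif
#' searches keep their evidence-only status (`high_confidence = FALSE`,
#' class `NA`).
#'
#' @param sequence candidate sequence.
#' @param family_label evidence family label (used only to break CD/HACA
#'   double matches).
#' @param min_len,max_len size bounds (nt).
#' @param c_window,d_window,aca_window,hinge motif window parameters, see
#'   [find_cd_boxes()] and [find_haca_boxes()].
#' @return list `(sno_class, high_confidence, boxes, rejected)`; `rejected`
#'   is TRUE when the size bounds fail.
#' @export
validate_snorna <- function(sequence, family_label = "", min_len = 60,
                            max_len = 300, c_window = 10, d_window = 10,
                            aca_window = 6, hinge = c(0.35, 0.75)) {
  L <- nchar(sequence)
  if (L < min_len || L > max_len)
    return(list(sno_class = NA_character_, high_confidence = FALSE,
                boxes = NULL, rejected = TRUE))
  cd <- find_cd_boxes(sequence, c_window, d_window)
  haca <- find_haca_boxes(sequence, aca_window, hinge)
  if (!is.null(cd) && !is.null(haca)) {
    pick_haca <- grepl("haca|h/aca|snor[0-9]*h", tolower(family_label))
    boxes <- if (pick_haca) haca else cd
  } else boxes <- if (!is.null(cd)) cd else haca
  if (is.null(boxes))
    return(list(sno_class = NA_character_, high_confidence = FALSE,
                boxes = NULL, rejected = FALSE))
  list(sno_class = boxes$kind, high_confidence = TRUE, boxes = boxes,
       rejected = FALSE)
}

#' Validate a table of snoRNA loci
#'
#' @param loci locus table with sequences.
#' @param ... passed to [validate_snorna()].
#' @return the locus table with `sno_class` and `high_confidence` columns.
#' @export
validate_snorna_loci <- function(loci, ...) {
  if (!nrow(loci)) {
    loci$sno_class <- character(0); loci$high_confidence <- logical(0)
    return(loci)
  }
  res <- lapply(seq_len(nrow(loci)), function(i)
    validate_snorna(loci$sequence[i], loci$family[i], ...))
  loci$sno_class <- vapply(res, function(r) r$sno_class, "")
  loci$high_confidence <- vapply(res, function(r) r$high_confidence, NA)
  loci$nc_class <- "snoRNA"
  loci
}

#' Detect snoRNA gene clusters
#'
#' Single-linkage chaining per chromosome: successive loci (sorted by start,
#' strand-agnostic, since plant snoRNA clusters are polycistronic) whose gap
#' `next.start - prev.end - 1` is strictly below `max_gap` nt are chained;
#' chains with at least two members are clusters.
#'
#' @param snorna_loci locus table.
#' @param max_gap strict upper bound on the inter-locus gap (nt).
#' @return data.frame (cluster_id, seq_id, start, end, n_members, members).
#' @export
detect_clusters <- function(snorna_loci, max_gap = 500) {
  empty <- data.frame(cluster_id = character(0), seq_id = character(0),
                      start = integer(0), end = integer(0),
                      n_members = integer(0), members = character(0),
                      stringsAsFactors = FALSE)
  if (nrow(snorna_loci) < 2L) return(empty)
  out <- list()
  for (chrom in sort(unique(snorna_loci$seq_id))) {
    part <- snorna_loci[snorna_loci$seq_id == chrom, , drop = FALSE]
    part <- part[order(part$start, part$end, part$id), , drop = FALSE]
    if (nrow(part) < 2L) next
    gap <- part$start[-1] - part$end[-nrow(part)] - 1L
    brk <- c(0L, cumsum(gap >= max_gap))
    for (g in split(seq_len(nrow(part)), brk)) {
      if (length(g) < 2L) next
      out[[length(out) + 1L]] <- data.frame(
        cluster_id = NA_character_, seq_id = chrom,
        start = min(part$start[g]), end = max(part$end[g]),
        n_members = length(g),
        members = paste(part$id[g], collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(empty)
  clusters <- do.call(rbind, out)
  clusters <- clusters[order(clusters$seq_id, clusters$start), , drop = FALSE]
  clusters$cluster_id <- sprintf("snocl%03d", seq_len(nrow(clusters)))
  rownames(clusters) <- NULL
  clusters
}
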