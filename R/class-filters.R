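## snRNA, tRNA and rRNA class-specific selection and labelling.

#' The nine spliceosomal U snRNA families
#'
#' The family universe accepted by [select_snrna()]. U4atac is part of the
#' vocabulary even though it is rarely found in plants: the filter defines
#' the family universe, not any one species' result.
#' @export
U_SNRNA_FAMILIES <- c("U1", "U2", "U4", "U4atac", "U5", "U6", "U6atac",
                      "U11", "U12")

#' Select spliceosomal U snRNA loci
#'
#' Keeps loci whose family is one of the nine spliceosomal U snRNA families
#' and whose length is within 60-220 nt (inclusive bounds).
#'
#' @param loci merged locus table with family labels.
#' @param min_len,max_len inclusive length bounds (nt).
#' @return filtered locus table with `nc_class = "snRNA"`.
#' @export
select_snrna <- function(loci, min_len = 60, max_len = 220) {
  if (!nrow(loci)) return(loci)
  fam <- .u_family(loci$family)
  len <- loci$end - loci$start + 1L
  out <- loci[!is.na(fam) & len >= min_len & len <= max_len, , drop = FALSE]
  if (nrow(out)) {
    out$nc_class <- "snRNA"
    out$family <- .u_family(out$family)
  }
  out
}

# canonical U family from a family label like "U6", "U6atac", "U4_atac", "U2 snRNA"
.u_family <- function(family) {
  x <- gsub("[ _-]", "", tolower(family))
  canon <- tolower(gsub("[ _-]", "", U_SNRNA_FAMILIES))
  # longest-first so "u4atac" is not swallowed by "u4"
  ord <- order(-nchar(canon))
  out <- rep(NA_character_, length(x))
  for (i in ord) {
    m <- is.na(out) & startsWith(x, canon[i]) &
      (nchar(x) == nchar(canon[i]) |
         !substr(x, nchar(canon[i]) + 1L, nchar(canon[i]) + 4L) %in% c("atac"))
    out[m] <- U_SNRNA_FAMILIES[i]
  }
  out
}

#' Select tRNA loci and annotate isotype/anticodon
#'
#' Keeps loci of length 70-95 nt (inclusive; the exclusion rule drops
#' sequences smaller than 70 nt or with more than 95 nt). Selenocysteine
#' (SeC) predictions are kept but flagged as putative false positives, since
#' tRNA scanners are known to call spurious tRNA-SeC in plants (higher
#' plants lack the selenocysteine insertion machinery). An anticodon whose
#' reverse complement does not translate to the claimed isotype under the
#' standard code is flagged (`anticodon_consistent = FALSE`), not dropped.
#'
#' @param loci merged locus table whose tRNA family labels have the form
#'   `tRNA-<isotype>-<anticodon>`.
#' @param min_len,max_len inclusive length bounds (nt).
#' @return locus table with extra columns `isotype`, `anticodon`, `is_sec`,
#'   `is_putative_false_positive`, `anticodon_consistent`.
#' @export
select_trna <- function(loci, min_len = 70, max_len = 95) {
  if (!nrow(loci)) {
    loci$isotype <- character(0); loci$anticodon <- character(0)
    loci$is_sec <- logical(0); loci$is_putative_false_positive <- logical(0)
    loci$anticodon_consistent <- logical(0)
    return(loci)
  }
  len <- loci$end - loci$start + 1L
  out <- loci[len >= min_len & len <= max_len, , drop = FALSE]
  parts <- strsplit(out$family, "-", fixed = TRUE)
  out$isotype <- vapply(parts, function(p) if (length(p) >= 2) p[2] else NA_character_, "")
  out$anticodon <- vapply(parts, function(p) if (length(p) >= 3) normalize_seq(p[3]) else NA_character_, "")
  out$nc_class <- "tRNA"
  out$is_sec <- out$isotype %in% c("SeC", "Sec", "SeC(e)", "SeC(p)")
  out$is_putative_false_positive <- out$is_sec
  code <- standard_code()
  out$anticodon_consistent <- vapply(seq_len(nrow(out)), function(i) {
    iso <- out$isotype[i]; ac <- out$anticodon[i]
    if (is.na(iso) || is.na(ac) || nchar(ac) != 3L) return(NA)
    if (out$is_sec[i]) return(TRUE)           # SeC uses the UCA/stop anticodon
    codon <- reverse_complement(ac)
    aa <- tryCatch(.aa_one_letter(iso), error = function(e) NA_character_)
    if (is.na(aa)) return(NA)
    identical(unname(code[[codon]]), aa)
  }, NA)
  out
}

#' Isoacceptor accounting for annotated tRNA loci
#'
#' Tabulates, per isotype, the distinct anticodons observed and the number
#' of loci per anticodon. In the standard genetic code at most 61 distinct
#' anticodons (one per sense codon) are possible.
#'
#' @param trna_loci output of [select_trna()].
#' @return list with `table` (data.frame isotype, anticodon, n_loci),
#'   `isoacceptors_per_isotype` (named integer vector) and
#'   `n_distinct_anticodons`.
#' @export
isoacceptor_table <- function(trna_loci) {
  if (!nrow(trna_loci))
    return(list(table = data.frame(isotype = character(0),
                                   anticodon = character(0),
                                   n_loci = integer(0),
                                   stringsAsFactors = FALSE),
                isoacceptors_per_isotype = integer(0),
                n_distinct_anticodons = 0L))
  tab <- as.data.frame(table(isotype = trna_loci$isotype,
                             anticodon = trna_loci$anticodon),
                       stringsAsFactors = FALSE)
  tab <- tab[tab$Freq > 0L, , drop = FALSE]
  tab <- tab[order(tab$isotype, tab$anticodon), , drop = FALSE]
  names(tab)[3] <- "n_loci"
  rownames(tab) <- NULL
  per_iso <- vapply(split(tab$anticodon, tab$isotype),
                    function(x) length(unique(x)), 1L)
  list(table = tab, isoacceptors_per_isotype = per_iso,
       n_distinct_anticodons = length(unique(tab$anticodon)))
}

#' Label rRNA loci by ribosomal unit
#'
#' Assigns each locus one of `5S`, `5.8S`, `LSU-fragment`, `SSU-fragment` or
#' `indeterminate` from its family label, then collapses redundant same-unit
#' overlapping loci with the merge cascade (higher score, lower e-value).
#'
#' @param loci merged rRNA locus table.
#' @param collapse whether to collapse overlapping same-unit loci.
#' @return locus table with an `rrna_unit` column.
#' @export
select_rrna <- function(loci, collapse = TRUE) {
  if (!nrow(loci)) { loci$rrna_unit <- character(0); return(loci) }
  loci$rrna_unit <- rrna_unit_label(loci$family)
  loci$nc_class <- "rRNA"
  if (collapse && nrow(loci) > 1L) {
    kept <- lapply(split(loci, loci$rrna_unit), function(part) {
      if (nrow(part) == 1L) return(part)
      h <- part
      h$query_id <- part$id
      h$e_value <- if (!is.null(part$e_value)) part$e_value else NA_real_
      h$bit_score <- if (!is.null(part$bit_score)) part$bit_score else NA_real_
      res <- resolve_overlaps(h, merge_cascade())
      part[match(res$query_id, part$id), , drop = FALSE]
    })
    loci <- do.call(rbind, kept)
    loci <- loci[order(loci$seq_id, loci$start, loci$end, loci$id), , drop = FALSE]
    rownames(loci) <- NULL
  }
  loci
}

#' @rdname select_rrna
#' @param family character vector of rRNA family labels.
#' @export
rrna_unit_label <- function(family) {
  x <- tolower(family)
  out <- rep("indeterminate", length(x))
  out[grepl("5[._ ]?8s", x)] <- "5.8S"
  out[out == "indeterminate" & grepl("(^|[^.0-9])5s", x)] <- "5S"
  out[grepl("lsu|28s|25s|23s", x)] <- "LSU-fragment"
  out[grepl("ssu|18s|16s", x)] <- "SSU-fragment"
  out
}
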