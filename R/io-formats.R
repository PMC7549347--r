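## Readers and writers for the standard formats the pipeline touches.
## FASTA goes through Biostrings, GFF3 through rtracklayer; the tool-specific
## tabular dialects (BLAST outfmt6, Infernal tblout, tRNAscan-SE) and BED6
## are parsed here directly.

#' Read a FASTA file
#'
#' Sequences are normalized to the uppercase T alphabet on ingestion (U and T
#' are treated as equivalent throughout the pipeline).
#'
#' @param path FASTA file.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  seqs <- normalize_seq(as.character(set))
  ids <- sub("\\s.*$", "", names(set))
  if (any(nchar(seqs) == 0L))
    stop("empty sequence record(s): ",
         paste(ids[nchar(seqs) == 0L], collapse = ", "))
  if (anyDuplicated(ids)) {
    warning("duplicate FASTA ids disambiguated with numeric suffixes")
    ids <- make.unique(ids, sep = ".")
  }
  names(seqs) <- ids
  seqs
}

#' Write a FASTA file
#'
#' @param records named character vector of sequences.
#' @param path output file.
#' @param width line-wrap width.
#' @export
write_fasta <- function(records, path, width = 70L) {
  if (is.null(names(records)) || any(names(records) == ""))
    stop("records must be named")
  set <- Biostrings::BStringSet(normalize_seq(records))
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

## -- evidence hit tables -----------------------------------------------------

empty_hit_table <- function() {
  data.frame(query_id = character(0), seq_id = character(0),
             start = integer(0), end = integer(0), strand = character(0),
             length = integer(0), percent_identity = numeric(0),
             query_coverage = numeric(0), e_value = numeric(0),
             bit_score = numeric(0), source = character(0),
             class_label = character(0), family_label = character(0),
             stringsAsFactors = FALSE)
}

# Query ids of the form "class|family|name" carry their own metadata; an
# explicit query_meta table (query_id, class_label, family_label,
# query_length) overrides it.
.query_lookup <- function(query_id, query_meta, field) {
  if (!is.null(query_meta) && field %in% names(query_meta)) {
    i <- match(query_id, query_meta$query_id)
    v <- query_meta[[field]][i]
    if (!all(is.na(v))) return(v)
  }
  parts <- strsplit(query_id, "|", fixed = TRUE)
  pick <- c(class_label = 1L, family_label = 2L)[[field]]
  vapply(parts, function(p) if (length(p) >= 3L) p[[pick]] else NA_character_, "")
}

#' Read a similarity/structural/specialist search hit table
#'
#' Supported dialects:
#' \describe{
#'   \item{`blast6`}{BLAST `-outfmt 6` with the 12 standard columns
#'     (qseqid sseqid pident length mismatch gapopen qstart qend sstart send
#'     evalue bitscore), plus an optional 13th `qcovs` column. Minus-strand
#'     hits (`sstart > send`) are normalized to `start < end` with
#'     `strand = "-"`. Query coverage is taken from `qcovs` when present,
#'     recomputed as `100 * (|qend-qstart|+1) / query_length` when query
#'     lengths are supplied, and left `NA` otherwise (such hits later fail
#'     the coverage filter closed).}
#'   \item{`infernal_tblout`}{`cmsearch --tblout` style whitespace-separated
#'     table; `#` comment lines are skipped. The per-model GA-cutoff
#'     filtering (`--cut_ga`) is assumed done upstream.}
#'   \item{`trnascan_tab`}{tRNAscan-SE tabular output with isotype and
#'     anticodon columns; `family_label` becomes `"tRNA-<isotype>-<anticodon>"`.}
#' }
#'
#' @param path file in the named dialect.
#' @param dialect one of `"blast6"`, `"infernal_tblout"`, `"trnascan_tab"`.
#' @param query_meta optional data.frame with columns `query_id` and any of
#'   `class_label`, `family_label`, `query_length`.
#' @param source evidence source tag recorded on each hit; defaults to
#'   `"similarity"` for blast6, `"structural"` for infernal_tblout and
#'   `"specialist"` for trnascan_tab.
#' @return hit table data.frame (one row per hit) with 1-based inclusive
#'   genome intervals.
#' @export
read_hits <- function(path, dialect = c("blast6", "infernal_tblout", "trnascan_tab"),
                      query_meta = NULL, source = NULL) {
  dialect <- match.arg(dialect)
  if (is.null(source))
    source <- c(blast6 = "similarity", infernal_tblout = "structural",
                trnascan_tab = "specialist")[[dialect]]
  switch(dialect,
         blast6 = .read_blast6(path, query_meta, source),
         infernal_tblout = .read_infernal(path, query_meta, source),
         trnascan_tab = .read_trnascan(path, source))
}

.read_lines_nonempty <- function(path) {
  ln <- readLines(path)
  which_keep <- which(nzchar(trimws(ln)))
  list(text = ln[which_keep], lineno = which_keep)
}

.read_blast6 <- function(path, query_meta, source) {
  ln <- .read_lines_nonempty(path)
  if (!length(ln$text)) return(empty_hit_table())
  fields <- strsplit(ln$text, "\t", fixed = TRUE)
  ncol <- lengths(fields)
  bad <- which(!(ncol %in% c(12L, 13L)))
  if (length(bad))
    stop("malformed blast6 row at line ", ln$lineno[bad[1]],
         " (", ncol[bad[1]], " columns)")
  # rows may mix 12 and 13 columns; pad the missing qcovs with NA
  m <- t(vapply(fields, function(f) c(f, rep(NA_character_, 13L - length(f))),
                character(13)))
  num <- function(j) suppressWarnings(as.numeric(m[, j]))
  qstart <- num(7); qend <- num(8); sstart <- num(9); send <- num(10)
  if (anyNA(c(qstart, qend, sstart, send, num(3), num(11), num(12))))
    stop("non-numeric field in blast6 table: ", path)
  strand <- ifelse(sstart > send, "-", "+")
  start <- as.integer(pmin(sstart, send))
  end <- as.integer(pmax(sstart, send))
  qid <- m[, 1]
  qcov <- num(13)
  if (anyNA(qcov)) {
    qlen <- .query_meta_length(qid, query_meta)
    recompute <- is.na(qcov) & !is.na(qlen)
    qcov[recompute] <- 100 * (abs(qend - qstart) + 1)[recompute] / qlen[recompute]
  }
  data.frame(query_id = qid, seq_id = m[, 2], start = start, end = end,
             strand = strand, length = end - start + 1L,
             percent_identity = num(3), query_coverage = qcov,
             e_value = num(11), bit_score = num(12), source = source,
             class_label = .query_lookup(qid, query_meta, "class_label"),
             family_label = .query_lookup(qid, query_meta, "family_label"),
             stringsAsFactors = FALSE)
}

.query_meta_length <- function(query_id, query_meta) {
  if (is.null(query_meta) || !"query_length" %in% names(query_meta))
    return(rep(NA_real_, length(query_id)))
  as.numeric(query_meta$query_length[match(query_id, query_meta$query_id)])
}

.read_infernal <- function(path, query_meta, source) {
  ln <- .read_lines_nonempty(path)
  keep <- !startsWith(trimws(ln$text), "#")
  text <- ln$text[keep]; lineno <- ln$lineno[keep]
  if (!length(text)) return(empty_hit_table())
  fields <- strsplit(trimws(text), "[[:space:]]+")
  bad <- which(lengths(fields) < 17L)
  if (length(bad))
    stop("malformed infernal tblout row at line ", lineno[bad[1]])
  m <- do.call(rbind, lapply(fields, `[`, 1:17))
  num <- function(j) suppressWarnings(as.numeric(m[, j]))
  sfrom <- num(8); sto <- num(9)
  if (anyNA(c(sfrom, sto, num(15), num(16))))
    stop("non-numeric field in infernal tblout: ", path)
  strand <- m[, 10]
  if (!all(strand %in% c("+", "-")))
    stop("invalid strand column in infernal tblout: ", path)
  start <- as.integer(pmin(sfrom, sto)); end <- as.integer(pmax(sfrom, sto))
  qid <- m[, 3]
  data.frame(query_id = qid, seq_id = m[, 1], start = start, end = end,
             strand = strand, length = end - start + 1L,
             percent_identity = NA_real_, query_coverage = NA_real_,
             e_value = num(16), bit_score = num(15), source = source,
             class_label = .query_lookup(qid, query_meta, "class_label"),
             family_label = .query_lookup(qid, query_meta, "family_label"),
             stringsAsFactors = FALSE)
}

.read_trnascan <- function(path, source) {
  ln <- .read_lines_nonempty(path)
  keep <- !grepl("^(Sequence|Name|--)", ln$text) & !startsWith(ln$text, "#")
  text <- ln$text[keep]; lineno <- ln$lineno[keep]
  if (!length(text)) return(empty_hit_table())
  fields <- strsplit(text, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 9L)
  if (length(bad))
    stop("malformed tRNAscan row at line ", lineno[bad[1]])
  m <- do.call(rbind, lapply(fields, `[`, 1:9))
  num <- function(j) suppressWarnings(as.numeric(m[, j]))
  begin <- num(3); endc <- num(4); score <- num(9)
  if (anyNA(c(begin, endc, score)))
    stop("non-numeric field in tRNAscan table: ", path)
  strand <- ifelse(begin > endc, "-", "+")
  start <- as.integer(pmin(begin, endc)); end <- as.integer(pmax(begin, endc))
  isotype <- trimws(m[, 5]); anticodon <- normalize_seq(trimws(m[, 6]))
  data.frame(query_id = paste0("tRNA|", isotype, "|", trimws(m[, 2])),
             seq_id = trimws(m[, 1]), start = start, end = end, strand = strand,
             length = end - start + 1L, percent_identity = NA_real_,
             query_coverage = NA_real_, e_value = NA_real_, bit_score = score,
             source = source, class_label = "tRNA",
             family_label = paste0("tRNA-", isotype, "-", anticodon),
             stringsAsFactors = FALSE)
}

## -- GFF3 --------------------------------------------------------------------

#' Read loci from a GFF3 file
#'
#' Only the `ID`, `Name`, `family` and `class` attribute keys are
#' interpreted; the feature `type` column carries the ncRNA class when it is
#' one of the six classes.
#'
#' @param path GFF3 file (1-based inclusive coordinates).
#' @return locus table data.frame.
#' @export
read_gff3 <- function(path) {
  ln <- readLines(path)
  rows <- which(nzchar(ln) & !startsWith(ln, "#"))
  if (length(rows)) {
    f <- strsplit(ln[rows], "\t", fixed = TRUE)
    bad <- which(lengths(f) != 9L)
    if (length(bad))
      stop("malformed GFF3 row at line ", rows[bad[1]])
    st <- suppressWarnings(as.integer(vapply(f, `[`, "", 4)))
    en <- suppressWarnings(as.integer(vapply(f, `[`, "", 5)))
    bad <- which(is.na(st) | is.na(en) | st < 1L | en < st)
    if (length(bad))
      stop("out-of-range coordinates in GFF3 row at line ", rows[bad[1]])
  }
  gr <- rtracklayer::import(path, format = "gff3")
  mc <- S4Vectors::mcols(gr)
  get <- function(key, default = NA_character_) {
    if (key %in% names(mc)) as.character(mc[[key]]) else
      rep(default, length(gr))
  }
  type <- get("type")
  id <- get("ID")
  id[is.na(id)] <- paste0("locus", seq_along(gr))[is.na(id)]
  loci <- locus_table(
    id = id,
    seq_id = as.character(GenomicRanges::seqnames(gr)),
    start = BiocGenerics::start(gr), end = BiocGenerics::end(gr),
    strand = ifelse(as.character(BiocGenerics::strand(gr)) == "-", "-", "+"),
    nc_class = ifelse(type %in% NC_CLASSES, type, NA_character_),
    family = ifelse(is.na(get("family")), "", get("family")),
    provenance = ifelse(is.na(get("provenance")), "", get("provenance")))
  cls <- get("class")
  if (!all(is.na(cls))) loci$sno_class <- cls
  order_loci(loci)
}

#' Write loci to a GFF3 file
#'
#' The feature type column is the locus `nc_class`; `ID`, `Name`, `family`,
#' `provenance` and (when present) the snoRNA `class` column are written as
#' attributes. Rows are emitted in a stable (seq_id, start, end, id) order so
#' identical input always yields byte-identical output.
#'
#' @param loci locus table.
#' @param path output file.
#' @param source source column value.
#' @export
write_gff3 <- function(loci, path, source = "ncRNAcurator") {
  if (!nrow(loci)) {
    writeLines("##gff-version 3", path)
    return(invisible(path))
  }
  loci <- order_loci(loci)
  type <- ifelse(is.na(loci$nc_class), "ncRNA", loci$nc_class)
  attrs <- paste0("ID=", loci$id, ";Name=", loci$id)
  fam <- !is.na(loci$family) & nzchar(loci$family)
  attrs[fam] <- paste0(attrs[fam], ";family=", loci$family[fam])
  if (!is.null(loci$sno_class)) {
    sc <- !is.na(loci$sno_class) & nzchar(loci$sno_class)
    attrs[sc] <- paste0(attrs[sc], ";class=", loci$sno_class[sc])
  }
  prov <- !is.na(loci$provenance) & nzchar(loci$provenance)
  attrs[prov] <- paste0(attrs[prov], ";provenance=",
                        gsub(",", "%2C", loci$provenance[prov]))
  rows <- paste(loci$seq_id, source, type, loci$start, loci$end, ".",
                loci$strand, ".", attrs, sep = "\t")
  writeLines(c("##gff-version 3", rows), path)
  invisible(path)
}

## -- BED6 --------------------------------------------------------------------

#' Read a 6-column BED file as loci
#'
#' BED is 0-based half-open; coordinates are converted to the package's
#' 1-based inclusive convention on read.
#'
#' @param path BED file (>= 6 columns).
#' @return locus table data.frame.
#' @export
read_bed <- function(path) {
  ln <- readLines(path)
  rows <- which(nzchar(ln) & !grepl("^(#|track|browser)", ln))
  if (!length(rows)) return(empty_locus_table())
  f <- strsplit(ln[rows], "\t", fixed = TRUE)
  bad <- which(lengths(f) < 6L)
  if (length(bad))
    stop("BED row with fewer than 6 columns at line ", rows[bad[1]])
  m <- do.call(rbind, lapply(f, `[`, 1:6))
  st0 <- suppressWarnings(as.integer(m[, 2]))
  en0 <- suppressWarnings(as.integer(m[, 3]))
  bad <- which(is.na(st0) | is.na(en0) | st0 < 0L | en0 <= st0)
  if (length(bad))
    stop("out-of-range BED coordinates at line ", rows[bad[1]])
  order_loci(locus_table(id = m[, 4], seq_id = m[, 1],
                         start = st0 + 1L, end = en0, strand = m[, 6]))
}

#' Write loci as 6-column BED
#'
#' Converts from 1-based inclusive to BED's 0-based half-open convention;
#' the unused score column is written as `"."`.
#'
#' @param loci locus table.
#' @param path output file.
#' @export
write_bed <- function(loci, path) {
  if (!nrow(loci)) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  loci <- order_loci(loci)
  rows <- paste(loci$seq_id, loci$start - 1L, loci$end, loci$id, ".",
                loci$strand, sep = "\t")
  writeLines(rows, path)
  invisible(path)
}

## -- count tables ------------------------------------------------------------

#' Read a per-locus, per-library count table
#'
#' @param path TSV with a locus id column followed by one integer column per
#'   library.
#' @param libraries optional expected library names; a header mismatch is an
#'   error.
#' @return data.frame with column `id` plus one non-negative integer column
#'   per library; missing cells become 0 with a warning.
#' @export
read_counts <- function(path, libraries = NULL) {
  first <- readLines(path, n = 1L)
  if (!length(first) || !nzchar(first)) {
    warning("empty count table: ", path)
    return(data.frame(id = character(0), stringsAsFactors = FALSE))
  }
  tab <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                           stringsAsFactors = FALSE)
  names(tab)[1] <- "id"
  if (!is.null(libraries) && !identical(names(tab)[-1], as.character(libraries)))
    stop("count table libraries (", paste(names(tab)[-1], collapse = ", "),
         ") do not match the configured libraries")
  for (j in seq_along(tab)[-1]) {
    v <- suppressWarnings(as.numeric(tab[[j]]))
    if (anyNA(v)) {
      warning("missing counts in column '", names(tab)[j], "' set to 0")
      v[is.na(v)] <- 0
    }
    if (any(v < 0)) stop("negative count in column '", names(tab)[j], "'")
    if (any(v != round(v))) stop("non-integer count in column '", names(tab)[j], "'")
    tab[[j]] <- as.integer(v)
  }
  tab
}
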