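#' Normalize a nucleotide sequence to the DNA (T) alphabet
#'
#' All sequences entering the pipeline are normalized once, on ingestion:
#' uppercased and with U replaced by T, so that RNA- and DNA-alphabet inputs
#' compare equal everywhere downstream.
#'
#' @param x character vector of nucleotide sequences.
#' @return character vector of the same length, uppercase T-alphabet.
#' @export
normalize_seq <- function(x) {
  chartr("u", "T", chartr("U", "T", toupper(x)))
}

#' Construct a genomic interval
#'
#' Coordinates are 1-based and inclusive at both ends (GFF3 convention);
#' BED I/O converts to and from 0-based half-open at the file boundary.
#'
#' @param seq_id chromosome or contig name.
#' @param start,end 1-based inclusive positions, `start <= end`, `start >= 1`.
#' @param strand `"+"` or `"-"`.
#' @return a one-row data.frame with columns `seq_id`, `start`, `end`, `strand`.
#' @export
genomic_interval <- function(seq_id, start, end, strand = "+") {
  start <- as.integer(start); end <- as.integer(end)
  if (any(is.na(start)) || any(is.na(end)) || any(start < 1L))
    stop("interval start must be an integer >= 1")
  if (any(end < start))
    stop("interval end must be >= start")
  if (!all(strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  data.frame(seq_id = as.character(seq_id), start = start, end = end,
             strand = strand, stringsAsFactors = FALSE)
}

#' Overlap length between two genomic intervals
#'
#' @param a,b intervals as returned by [genomic_interval()] (one row each).
#' @param stranded if `TRUE` (default) intervals on different strands do not
#'   overlap; overlap resolution and read counting are strand-aware by default.
#' @return non-negative integer number of shared base pairs; 0 when the
#'   `seq_id`s differ, the strands differ (stranded mode), or the ranges are
#'   disjoint.
#' @examples
#' a <- genomic_interval("chr1", 100, 200, "+")
#' b <- genomic_interval("chr1", 150, 250, "+")
#' interval_overlap(a, b)  # 51
#' @export
interval_overlap <- function(a, b, stranded = TRUE) {
  if (a$seq_id != b$seq_id) return(0L)
  if (stranded && a$strand != b$strand) return(0L)
  max(0L, min(a$end, b$end) - max(a$start, b$start) + 1L)
}

# Vectorised overlap widths of one interval row against many rows.
overlap_widths <- function(row, tab, stranded = TRUE) {
  w <- pmin(row$end, tab$end) - pmax(row$start, tab$start) + 1L
  w[tab$seq_id != row$seq_id] <- 0L
  if (stranded) w[tab$strand != row$strand] <- 0L
  pmax(w, 0L)
}

#' Find IUPAC pattern matches in a sequence window
#'
#' Matches an IUPAC-coded nucleotide pattern (R = A/G, N = any, ... ) against
#' a sequence, treating U and T as equivalent. Matching is delegated to
#' [Biostrings::matchPattern()] with ambiguity codes enabled in the pattern.
#'
#' @param pattern IUPAC pattern string (e.g. `"RTGATGA"`).
#' @param sequence nucleotide string.
#' @param window integer vector `c(from, to)` restricting match *start and
#'   end* to lie within `sequence[from..to]`; default is the whole sequence.
#' @return integer vector of 1-based match start positions (relative to the
#'   full sequence), possibly empty.
#' @export
iupac_match <- function(pattern, sequence, window = NULL) {
  pattern <- normalize_seq(pattern)
  sequence <- normalize_seq(sequence)
  bad <- setdiff(strsplit(pattern, "")[[1]], names(Biostrings::IUPAC_CODE_MAP))
  if (length(bad))
    stop("unknown IUPAC symbol(s) in pattern: ", paste(bad, collapse = ", "))
  if (is.null(window)) window <- c(1L, nchar(sequence))
  from <- max(1L, as.integer(window[1]))
  to <- min(nchar(sequence), as.integer(window[2]))
  if (to - from + 1L < nchar(pattern)) return(integer(0))
  sub <- substr(sequence, from, to)
  m <- Biostrings::matchPattern(pattern, Biostrings::DNAString(sub),
                                fixed = c(pattern = FALSE, subject = TRUE))
  as.integer(BiocGenerics::start(m)) + from - 1L
}

## -- genetic code accounting -------------------------------------------------

# Standard genetic code as a named vector codon -> one-letter AA ("*" = stop),
# from Biostrings; codons use the T alphabet.
standard_code <- function() Biostrings::GENETIC_CODE

.aa_one_letter <- function(amino_acid) {
  aa3 <- Biostrings::AMINO_ACID_CODE         # one-letter -> three-letter
  amino_acid <- as.character(amino_acid)
  if (nchar(amino_acid) == 1L) {
    if (!amino_acid %in% names(aa3))
      stop("unknown amino acid: ", amino_acid)
    return(amino_acid)
  }
  hit <- names(aa3)[tolower(aa3) == tolower(amino_acid)]
  if (length(hit) != 1L) stop("unknown amino acid: ", amino_acid)
  hit
}

#' Count sense (non-stop) codons in a genetic code
#'
#' The standard code has 61 sense codons, i.e. 61 possible tRNA
#' anticodons/isoacceptors, and 3 stop codons.
#'
#' @param code named character vector codon -> amino acid (`"*"` for stop);
#'   defaults to the standard code.
#' @return integer count of non-stop codons.
#' @export
sense_codon_count <- function(code = standard_code()) {
  if (length(code) != 64L) stop("genetic code must have exactly 64 codons")
  sum(code != "*")
}

#' Codons translating to a given amino acid
#'
#' @param code genetic code as in [sense_codon_count()].
#' @param amino_acid one-letter (`"L"`) or three-letter (`"Leu"`) code.
#' @return character vector of codons (T alphabet).
#' @examples
#' length(codons_for(amino_acid = "Leu"))  # 6
#' @export
codons_for <- function(code = standard_code(), amino_acid) {
  aa <- .aa_one_letter(amino_acid)
  sort(names(code)[code == aa])
}

## -- loci --------------------------------------------------------------------

# The shared locus container is a data.frame with (at least) columns
# id, seq_id, start, end, strand, nc_class, family, sequence, provenance,
# expressed, high_support.  provenance is a comma-joined subset of
# {similarity, structural, specialist}.

NC_CLASSES <- c("snRNA", "snoRNA", "tRNA", "rRNA", "miRNA", "lncRNA")

#' Build a locus table
#'
#' @param id stable locus identifiers.
#' @param seq_id,start,end,strand coordinates (1-based inclusive).
#' @param nc_class one of snRNA, snoRNA, tRNA, rRNA, miRNA, lncRNA (or `NA`
#'   before class assignment).
#' @param family family label (e.g. `"U1"`, `"R71"`, `"tRNA-Leu-CAA"`) or `""`.
#' @param sequence locus nucleotide sequence or `NA`; when present its length
#'   must equal `end - start + 1`.
#' @param provenance comma-joined evidence sources.
#' @return data.frame of loci.
#' @export
locus_table <- function(id, seq_id, start, end, strand, nc_class = NA_character_,
                        family = "", sequence = NA_character_,
                        provenance = "") {
  start <- as.integer(start); end <- as.integer(end)
  if (any(start < 1L) || any(end < start))
    stop("invalid locus coordinates")
  if (!all(strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  if (!all(is.na(nc_class) | nc_class %in% NC_CLASSES))
    stop("unknown ncRNA class")
  n <- length(id)
  for (nm in c("seq_id", "strand", "nc_class", "family", "sequence",
               "provenance")) {
    v <- get(nm)
    if (length(v) == 1L && n != 1L) assign(nm, rep(v, n))
  }
  sequence <- ifelse(is.na(sequence), NA_character_, normalize_seq(sequence))
  ok <- is.na(sequence) | nchar(sequence) == (end - start + 1L)
  if (!all(ok))
    stop("sequence length disagrees with coordinates for: ",
         paste(id[!ok], collapse = ", "))
  data.frame(id = as.character(id), seq_id = as.character(seq_id),
             start = start, end = end, strand = strand,
             nc_class = nc_class, family = as.character(family),
             sequence = sequence, provenance = as.character(provenance),
             expressed = rep(NA, n), high_support = rep(NA, n),
             stringsAsFactors = FALSE)
}

empty_locus_table <- function() {
  locus_table(character(0), character(0), integer(0), integer(0), character(0))
}

# deterministic canonical order used by all writers
order_loci <- function(loci) {
  loci[order(loci$seq_id, loci$start, loci$end, loci$id), , drop = FALSE]
}

reverse_complement <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(normalize_seq(x))))
}
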