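## Filtering of similarity/structural hits and resolution of overlapping
## candidates into non-redundant loci via an ordered tie-break cascade.

#' Tie-break cascade constructor
#'
#' An ordered list of (criterion, direction) pairs used to pick one hit among
#' overlapping candidates. The default is the similarity-search cascade:
#' highest query coverage, then highest identity, then lowest e-value, then
#' highest bit score. Covariance-model and specialist merges use score/e-value
#' cascades (see [structural_cascade()] and [merge_cascade()]).
#'
#' @param criteria character vector of numeric hit-table columns.
#' @param directions `"max"` or `"min"` per criterion.
#' @return data.frame with columns `criterion`, `direction`.
#' @export
tiebreak_cascade <- function(criteria = c("query_coverage", "percent_identity",
                                          "e_value", "bit_score"),
                             directions = c("max", "max", "min", "max")) {
  if (!length(criteria) || length(criteria) != length(directions))
    stop("criteria and directions must be non-empty and of equal length")
  if (!all(directions %in% c("max", "min")))
    stop("directions must be 'max' or 'min'")
  data.frame(criterion = criteria, direction = directions,
             stringsAsFactors = FALSE)
}

#' @rdname tiebreak_cascade
#' @export
structural_cascade <- function() {
  tiebreak_cascade(c("e_value", "bit_score"), c("min", "max"))
}

#' @rdname tiebreak_cascade
#' @export
merge_cascade <- function() {
  tiebreak_cascade(c("bit_score", "e_value"), c("max", "min"))
}

#' Filter similarity-search hits
#'
#' Keeps hits with query coverage and percent identity strictly over the
#' thresholds (both default 90) and hit length of at least `min_len`
#' (default 60 nt). Hits with missing coverage fail the coverage filter
#' closed; their count is reported in a message.
#'
#' @param hits hit table.
#' @param min_cov,min_id strict lower bounds on query coverage / identity (%).
#' @param min_len inclusive lower bound on hit length (nt).
#' @param classes optional class labels to retain (default: the five small
#'   ncRNA classes searched by homology).
#' @return filtered hit table.
#' @export
filter_similarity_hits <- function(hits, min_cov = 90, min_id = 90,
                                   min_len = 60,
                                   classes = c("tRNA", "rRNA", "miRNA",
                                               "snRNA", "snoRNA")) {
  if (!nrow(hits)) return(hits)
  na_cov <- is.na(hits$query_coverage)
  if (any(na_cov))
    message(sum(na_cov), " hit(s) with unknown query coverage excluded")
  keep <- !na_cov & hits$query_coverage > min_cov &
    !is.na(hits$percent_identity) & hits$percent_identity > min_id &
    hits$length >= min_len
  if (!is.null(classes))
    keep <- keep & (is.na(hits$class_label) | hits$class_label %in% classes)
  hits[keep, , drop = FALSE]
}

#' Filter covariance-model (structural) hits
#'
#' Keeps hits of length >= `min_len` whose claimed class is one of the five
#' small ncRNA classes retrieved at this stage.
#'
#' @param hits hit table.
#' @param min_len inclusive lower bound on hit length (nt).
#' @param classes retained class labels.
#' @return filtered hit table.
#' @export
filter_structural_hits <- function(hits, min_len = 60,
                                   classes = c("tRNA", "rRNA", "miRNA",
                                               "snRNA", "snoRNA")) {
  if (!nrow(hits)) return(hits)
  keep <- hits$length >= min_len & hits$class_label %in% classes
  hits[keep, , drop = FALSE]
}

# Order hit rows best-first under the cascade, with a final deterministic
# lexicographic (seq_id, start, end, query_id) tie-break.
.cascade_order <- function(hits, cascade) {
  keys <- lapply(seq_len(nrow(cascade)), function(i) {
    v <- hits[[cascade$criterion[i]]]
    if (is.null(v)) stop("unknown cascade criterion: ", cascade$criterion[i])
    v <- as.numeric(v)
    # missing values always lose
    worst <- if (cascade$direction[i] == "max") -Inf else Inf
    v[is.na(v)] <- worst
    if (cascade$direction[i] == "max") -v else v
  })
  do.call(order, c(keys, list(hits$seq_id, hits$start, hits$end, hits$query_id)))
}

# First cascade criterion on which `a` (row) beats `b` (row), or NA on full tie.
.deciding_criterion <- function(a, b, cascade) {
  for (i in seq_len(nrow(cascade))) {
    crit <- cascade$criterion[i]
    va <- as.numeric(a[[crit]]); vb <- as.numeric(b[[crit]])
    worst <- if (cascade$direction[i] == "max") -Inf else Inf
    if (is.na(va)) va <- worst
    if (is.na(vb)) vb <- worst
    if (va != vb) return(crit)
  }
  NA_character_
}

#' Resolve overlapping hits into non-overlapping loci
#'
#' Repeated tournament: the best remaining hit under the cascade is kept and
#' every hit overlapping it (>= 1 shared bp on the same seq_id, and same
#' strand in stranded mode) is removed; this repeats until no hits remain.
#' Full ties fall back to lexicographic (seq_id, start, end, query_id) order,
#' so the result is deterministic and independent of input order.
#'
#' @param hits filtered hit table.
#' @param cascade tie-break cascade (default [tiebreak_cascade()]).
#' @param stranded whether overlap requires matching strands (default TRUE).
#' @return kept hit table, with a `decision_log` attribute: data.frame
#'   (kept_id, removed_id, deciding_criterion) naming, for every removed hit,
#'   the kept hit that beat it and the first non-tied cascade criterion.
#' @export
resolve_overlaps <- function(hits, cascade = tiebreak_cascade(),
                             stranded = TRUE) {
  if (!nrow(hits)) {
    attr(hits, "decision_log") <- data.frame(kept_id = character(0),
                                             removed_id = character(0),
                                             deciding_criterion = character(0),
                                             stringsAsFactors = FALSE)
    return(hits)
  }
  hits <- hits[.cascade_order(hits, cascade), , drop = FALSE]
  n <- nrow(hits)
  alive <- rep(TRUE, n)
  kept <- logical(n)
  log_kept <- character(0); log_removed <- character(0); log_crit <- character(0)
  for (i in seq_len(n)) {
    if (!alive[i]) next
    kept[i] <- TRUE
    later <- which(alive & !kept)
    if (length(later)) {
      ov <- overlap_widths(hits[i, ], hits[later, , drop = FALSE], stranded)
      losers <- later[ov > 0L]
      for (j in losers) {
        alive[j] <- FALSE
        crit <- .deciding_criterion(hits[i, ], hits[j, ], cascade)
        log_kept <- c(log_kept, hits$query_id[i])
        log_removed <- c(log_removed, hits$query_id[j])
        log_crit <- c(log_crit, if (is.na(crit)) "order" else crit)
      }
    }
  }
  out <- hits[kept, , drop = FALSE]
  out <- out[order(out$seq_id, out$start, out$end, out$query_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "decision_log") <- data.frame(kept_id = log_kept,
                                          removed_id = log_removed,
                                          deciding_criterion = log_crit,
                                          stringsAsFactors = FALSE)
  out
}

#' Merge per-source locus candidates into one non-redundant set
#'
#' Each input set (similarity, structural, specialist) must already be
#' internally non-overlapping. Overlaps across sources are resolved by the
#' cascade (default: higher score, then lower e-value); the kept locus
#' records the union of sources of every same-class hit it subsumes
#' (overlap >= 1 bp). Overlaps between different claimed classes are resolved
#' by the same cascade but reported in a `conflicts` attribute.
#'
#' @param similarity_hits,structural_hits,specialist_hits per-source hit
#'   tables (any may be empty or NULL).
#' @param cascade tie-break cascade; default [merge_cascade()].
#' @param stranded strand-aware overlap (default TRUE).
#' @return merged hit table with a `provenance` column (comma-joined source
#'   tags), plus `decision_log` and `conflicts` attributes.
#' @export
merge_sources <- function(similarity_hits = NULL, structural_hits = NULL,
                          specialist_hits = NULL, cascade = merge_cascade(),
                          stranded = TRUE) {
  parts <- Filter(function(x) !is.null(x) && nrow(x) > 0,
                  list(similarity_hits, structural_hits, specialist_hits))
  if (!length(parts)) {
    out <- empty_hit_table(); out$provenance <- character(0)
    attr(out, "conflicts") <- data.frame()
    return(out)
  }
  all_hits <- do.call(rbind, parts)
  resolved <- resolve_overlaps(all_hits, cascade, stranded)
  # provenance: all sources whose (same-class, overlapping) hit the winner subsumes
  prov <- character(nrow(resolved))
  conflicts <- list()
  for (i in seq_len(nrow(resolved))) {
    ov <- overlap_widths(resolved[i, ], all_hits, stranded)
    touching <- all_hits[ov > 0L, , drop = FALSE]
    same <- touching$class_label == resolved$class_label[i]
    same[is.na(same)] <- FALSE
    self <- touching$query_id == resolved$query_id[i] &
      touching$start == resolved$start[i] & touching$end == resolved$end[i]
    prov[i] <- paste(sort(unique(touching$source[same | self])), collapse = ",")
    if (any(!same & !self))
      conflicts[[length(conflicts) + 1L]] <- data.frame(
        kept_id = resolved$query_id[i],
        kept_class = resolved$class_label[i],
        conflicting_id = touching$query_id[!same & !self],
        conflicting_class = touching$class_label[!same & !self],
        stringsAsFactors = FALSE)
  }
  resolved$provenance <- prov
  attr(resolved, "conflicts") <-
    if (length(conflicts)) do.call(rbind, conflicts) else
      data.frame(kept_id = character(0), kept_class = character(0),
                 conflicting_id = character(0),
                 conflicting_class = character(0), stringsAsFactors = FALSE)
  resolved
}

#' Convert a (resolved) hit table to a locus table
#'
#' @param hits hit table, optionally with a `provenance` column.
#' @param genome optional named character vector of chromosome sequences used
#'   to fill in locus sequences.
#' @param prefix id prefix.
#' @return locus table.
#' @export
hits_to_loci <- function(hits, genome = NULL, prefix = "ncl") {
  if (!nrow(hits)) return(empty_locus_table())
  seqs <- rep(NA_character_, nrow(hits))
  if (!is.null(genome)) {
    seqs <- vapply(seq_len(nrow(hits)), function(i) {
      s <- substr(genome[[hits$seq_id[i]]], hits$start[i], hits$end[i])
      if (hits$strand[i] == "-") reverse_complement(s) else s
    }, "")
  }
  loci <- locus_table(
    id = sprintf("%s%04d", prefix, seq_len(nrow(hits))),
    seq_id = hits$seq_id, start = hits$start, end = hits$end,
    strand = hits$strand,
    nc_class = ifelse(hits$class_label %in% NC_CLASSES, hits$class_label,
                      NA_character_),
    family = ifelse(is.na(hits$family_label), "", hits$family_label),
    sequence = seqs,
    provenance = if (!is.null(hits$provenance)) hits$provenance else hits$source)
  loci$query_id <- hits$query_id
  loci$bit_score <- hits$bit_score
  loci
}
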