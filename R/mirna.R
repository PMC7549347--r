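## miRNA precursor curation: base-pair-maximisation folding, single-hairpin
## test, mature location, miRNA/miR* duplex geometry, redundancy detection,
## the rule engine (R1-R8) and psRNATarget-style target expectation scoring.

.PAIRABLE <- matrix(FALSE, 4, 4, dimnames = list(c("A", "C", "G", "T"),
                                                 c("A", "C", "G", "T")))
.PAIRABLE["A", "T"] <- .PAIRABLE["T", "A"] <- TRUE
.PAIRABLE["G", "C"] <- .PAIRABLE["C", "G"] <- TRUE
.PAIRABLE["G", "T"] <- .PAIRABLE["T", "G"] <- TRUE

#' Fold a sequence by base-pair maximisation
#'
#' Computes the pseudoknot-free secondary structure with the maximum number
#' of base pairs (allowed pairs AU, GC, GU; minimum hairpin loop 3 nt) by
#' dynamic programming. Traceback is deterministic: at each subproblem,
#' pairing the 5' base is preferred over leaving it unpaired, and among
#' equally scoring partners the 5'-most is taken.
#'
#' @param sequence nucleotide string (<= 1000 nt).
#' @param min_loop minimum hairpin loop length (nt).
#' @return list with `structure` (dot-bracket string), `pairs` (integer
#'   vector, partner position or `NA`), `n_pairs`.
#' @export
fold_hairpin <- function(sequence, min_loop = 3L) {
  sequence <- normalize_seq(sequence)
  n <- nchar(sequence)
  if (n > 1000L) stop("sequence longer than 1000 nt")
  b <- strsplit(sequence, "")[[1]]
  if (!all(b %in% c("A", "C", "G", "T")))
    stop("non-nucleotide symbol in sequence")
  pairs <- rep(NA_integer_, n)
  if (n < min_loop + 2L)
    return(list(structure = strrep(".", n), pairs = pairs, n_pairs = 0L))
  canp <- .PAIRABLE[b, b, drop = FALSE]      # n x n pairability
  # dp[i, j] = max pairs in b[i..j]; the (n+1)-sized matrix leaves all
  # empty/short subranges at 0 so dp[i+1, k-1] and dp[k+1, j] index safely
  dp <- matrix(0L, n + 1L, n + 1L)
  for (i in seq(n - min_loop - 1L, 1L)) {
    for (j in seq(i + min_loop + 1L, n)) {
      best <- dp[i + 1L, j]                  # i unpaired
      ks <- seq(i + min_loop + 1L, j)
      ks <- ks[canp[i, ks]]
      if (length(ks)) {
        inner <- dp[cbind(i + 1L, ks - 1L)]
        outer <- dp[cbind(ks + 1L, j)]
        best <- max(best, max(inner + 1L + outer))
      }
      dp[i, j] <- best
    }
  }
  # deterministic traceback
  stack <- list(c(1L, n))
  while (length(stack)) {
    ij <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
    i <- ij[1]; j <- ij[2]
    while (i <= j) {
      if (j - i < min_loop + 1L || dp[i, j] == 0L) break
      ks <- seq(i + min_loop + 1L, j)
      ks <- ks[canp[i, ks]]
      paired_k <- NA_integer_
      for (k in ks) {
        inner <- if (k - 1L >= i + 1L) dp[i + 1L, k - 1L] else 0L
        outer <- if (k + 1L <= j) dp[k + 1L, j] else 0L
        if (inner + 1L + outer == dp[i, j]) { paired_k <- k; break }
      }
      if (!is.na(paired_k)) {
        pairs[i] <- paired_k; pairs[paired_k] <- i
        if (paired_k + 1L <= j) stack[[length(stack) + 1L]] <- c(paired_k + 1L, j)
        j <- paired_k - 1L
        i <- i + 1L
      } else {
        i <- i + 1L
      }
    }
  }
  structure_chr <- rep(".", n)
  structure_chr[!is.na(pairs) & seq_len(n) < pairs] <- "("
  structure_chr[!is.na(pairs) & seq_len(n) > pairs] <- ")"
  list(structure = paste(structure_chr, collapse = ""), pairs = pairs,
       n_pairs = sum(!is.na(pairs)) %/% 2L)
}

# terminal (hairpin) loops of a pair table: pairs (i, j) with no paired
# position strictly between them
.terminal_loops <- function(pairs) {
  n <- length(pairs)
  ij <- which(!is.na(pairs) & seq_len(n) < pairs)
  keep <- vapply(ij, function(i) {
    j <- pairs[i]
    inner <- seq(i + 1L, j - 1L)
    !any(!is.na(pairs[inner]))
  }, NA)
  cbind(i = ij[keep], j = pairs[ij[keep]])
}

# number of stem pairs enclosing a terminal loop (i, j), counting only pairs
# that do not also enclose another terminal loop (stops at multiloop junctions)
.stem_size <- function(pairs, loop, loops) {
  n <- length(pairs)
  enclosing <- which(!is.na(pairs) & seq_len(n) <= loop["i"] &
                       pairs >= loop["j"] & seq_len(n) < pairs)
  if (nrow(loops) > 1L) {
    others <- loops[!(loops[, "i"] == loop["i"] & loops[, "j"] == loop["j"]), ,
                    drop = FALSE]
    ok <- vapply(enclosing, function(a) {
      bpos <- pairs[a]
      !any(others[, "i"] >= a & others[, "j"] <= bpos)
    }, NA)
    enclosing <- enclosing[ok]
  }
  length(enclosing)
}

#' Test for a single qualifying hairpin
#'
#' TRUE when the folded structure contains at least one stem-loop whose stem
#' holds `min_stem` or more base pairs. When both mature spans are supplied
#' the test additionally requires the stem-loop to be the single terminal
#' loop lying between the matures (one loop on the path covering both
#' matures), i.e. the two matures sit on opposite arms of one hairpin.
#'
#' @param fold result of [fold_hairpin()].
#' @param min_stem minimum stem size in base pairs.
#' @param m1,m2 optional integer `c(start, length)` spans of the 5' and 3'
#'   matures within the precursor (m1 upstream of m2).
#' @return logical.
#' @export
has_single_hairpin <- function(fold, min_stem = 15L, m1 = NULL, m2 = NULL) {
  loops <- .terminal_loops(fold$pairs)
  if (!nrow(loops)) return(FALSE)
  if (is.null(m1) || is.null(m2)) {
    stems <- vapply(seq_len(nrow(loops)), function(r)
      .stem_size(fold$pairs, loops[r, ], loops), 1L)
    return(any(stems >= min_stem))
  }
  e1 <- m1[1] + m1[2] - 1L; s2 <- m2[1]
  if (e1 >= s2) stop("mature spans must be ordered and non-overlapping")
  between <- loops[loops[, "i"] >= e1 & loops[, "j"] <= s2, , drop = FALSE]
  if (nrow(between) != 1L) return(FALSE)
  .stem_size(fold$pairs, between[1, ], loops) >= min_stem
}

#' Locate a mature sequence within its precursor
#'
#' Exact substring match (strict mode; with `max_mismatch = 1` a single
#' mismatch is tolerated). Multiple match positions return the leftmost with
#' a `multiple` attribute.
#'
#' @param precursor,mature nucleotide strings.
#' @param max_mismatch 0 (default, strict) or 1.
#' @return 1-based offset, or `NA` when the mature is divergent from the
#'   precursor.
#' @export
locate_mature <- function(precursor, mature, max_mismatch = 0L) {
  precursor <- normalize_seq(precursor); mature <- normalize_seq(mature)
  if (!nchar(mature)) stop("empty mature sequence")
  if (max_mismatch == 0L) {
    hits <- gregexpr(mature, precursor, fixed = TRUE)[[1]]
    hits <- hits[hits > 0L]
  } else {
    m <- Biostrings::matchPattern(mature, Biostrings::DNAString(precursor),
                                  max.mismatch = as.integer(max_mismatch))
    hits <- as.integer(BiocGenerics::start(m))
  }
  if (!length(hits)) return(NA_integer_)
  out <- hits[1]
  if (length(hits) > 1L) attr(out, "multiple") <- TRUE
  out
}

#' miRNA/miR* duplex geometry from a folded precursor
#'
#' Given the fold and both mature spans, reports whether the matures occupy
#' opposite arms (>= 50% of the 5' mature's positions pair into the 3'
#' mature's span), the number of mismatched positions (positions of either
#' mature unpaired or paired outside the partner span) and the largest
#' asymmetric bulge (difference in unpaired positions between the two
#' strands within an internal loop of the duplex).
#'
#' @param fold result of [fold_hairpin()] on the precursor.
#' @param m1,m2 integer `c(start, length)` spans; must not overlap.
#' @return list `(opposite_arms, mismatched_positions, max_asymmetric_bulge)`.
#' @export
duplex_stats <- function(fold, m1, m2) {
  p1 <- seq(m1[1], m1[1] + m1[2] - 1L)
  p2 <- seq(m2[1], m2[1] + m2[2] - 1L)
  if (length(intersect(p1, p2))) stop("mature spans overlap")
  partner <- fold$pairs
  into2 <- !is.na(partner[p1]) & partner[p1] %in% p2
  into1 <- !is.na(partner[p2]) & partner[p2] %in% p1
  opposite <- mean(into2) >= 0.5
  mism <- sum(!into2) + sum(!into1)
  bulge <- 0L
  anchors <- p1[into2]
  if (length(anchors) >= 2L) {
    for (k in seq_len(length(anchors) - 1L)) {
      a <- anchors[k]; b <- anchors[k + 1L]
      un1 <- b - a - 1L
      un2 <- abs(partner[a] - partner[b]) - 1L
      bulge <- max(bulge, abs(un1 - un2))
    }
  }
  list(opposite_arms = opposite, mismatched_positions = as.integer(mism),
       max_asymmetric_bulge = as.integer(bulge))
}

#' Collapse redundant miRNA precursor candidates
#'
#' Candidates whose T-normalized precursor sequences are identical, or
#' identical up to reverse complement, are collapsed. The representative is
#' the first candidate by source priority, then by id.
#'
#' @param candidates data.frame with columns `id`, `precursor`, optional
#'   `source`.
#' @param source_priority character vector ordering `source` values
#'   (earlier = preferred); unlisted sources come last.
#' @return list with `unique` (representative rows), `redundancy` (data.frame
#'   redundant_id, representative_id, reverse_complement).
#' @export
deduplicate_mirnas <- function(candidates, source_priority = NULL) {
  if (!nrow(candidates))
    return(list(unique = candidates,
                redundancy = data.frame(redundant_id = character(0),
                                        representative_id = character(0),
                                        reverse_complement = logical(0),
                                        stringsAsFactors = FALSE)))
  norm <- normalize_seq(candidates$precursor)
  rc <- reverse_complement(norm)
  key <- pmin(norm, rc)
  src <- if (!is.null(candidates$source)) candidates$source else
    rep("", nrow(candidates))
  prio <- if (is.null(source_priority)) rep(1L, nrow(candidates)) else {
    p <- match(src, source_priority)
    p[is.na(p)] <- length(source_priority) + 1L
    p
  }
  ord <- order(prio, candidates$id)
  red <- list()
  keep <- logical(nrow(candidates))
  rep_idx <- integer(0); names(rep_idx) <- character(0)
  for (i in ord) {
    k <- key[i]
    if (is.na(rep_idx[k])) {
      rep_idx[k] <- i
      keep[i] <- TRUE
    } else {
      r <- rep_idx[k]
      red[[length(red) + 1L]] <- data.frame(
        redundant_id = candidates$id[i],
        representative_id = candidates$id[r],
        reverse_complement = norm[i] != norm[r],
        stringsAsFactors = FALSE)
    }
  }
  list(unique = candidates[keep, , drop = FALSE],
       redundancy = if (length(red)) do.call(rbind, red) else
         data.frame(redundant_id = character(0),
                    representative_id = character(0),
                    reverse_complement = logical(0), stringsAsFactors = FALSE))
}

#' Default miRNA curation configuration
#'
#' Thresholds of the curation rule engine: precursor length cap 300 nt,
#' mature length window [21, 22] nt (a relaxed [20, 24] window can be
#' configured), minimum hairpin stem 15 bp, duplex geometry at most 5
#' mismatched positions and a 3-nt asymmetric bulge, and expression support
#' requiring each mature to have at least one read in at least one library.
#'
#' @param ... overrides.
#' @return named list of thresholds.
#' @export
mirna_config <- function(...) {
  cfg <- list(max_precursor_len = 300L, mature_len = c(21L, 22L),
              min_stem = 15L, max_mismatch = 5L, max_bulge = 3L,
              require_expression = TRUE, min_read = 1L,
              allowlist = character(0),
              source_priority = NULL)
  user <- list(...)
  cfg[names(user)] <- user
  cfg
}

.mature_support <- function(cand_id, mature, expression, min_read) {
  if (is.null(expression) || !nrow(expression)) return(FALSE)
  counts <- as.matrix(expression[, -1, drop = FALSE])
  key <- as.character(expression[[1]])
  row <- which(key == mature | key == cand_id)
  length(row) > 0L && any(counts[row, , drop = FALSE] >= min_read)
}

#' Curate miRNA precursor candidates
#'
#' Applies the rule engine to each candidate:
#' \describe{
#'   \item{R1}{not redundant (exact or reverse-complement duplicate of an
#'     earlier candidate);}
#'   \item{R2}{precursor length <= 300 nt (strictly longer fails);}
#'   \item{R3}{a single qualifying hairpin covers both matures;}
#'   \item{R4}{two mature sequences present;}
#'   \item{R5}{both matures exactly located in the precursor;}
#'   \item{R6}{mature lengths within the configured window (default 21-22 nt);}
#'   \item{R7}{expression support for both matures (>= 1 read in >= 1
#'     library);}
#'   \item{R8}{matures on opposite arms with at most 5 mismatched positions
#'     and a 3-nt asymmetric bulge.}
#' }
#' A candidate failing only R4 and/or R7 can be force-included through the
#' config allowlist (experimentally validated loci).
#'
#' @param candidates data.frame with columns `id`, `precursor`, `mature5p`,
#'   `mature3p` (either may be `NA`), optional `source`.
#' @param expression optional data.frame keyed (first column) by candidate id
#'   or mature sequence, remaining columns per-library read counts.
#' @param config list from [mirna_config()].
#' @return list with `report` (per-candidate rule results and verdicts) and
#'   `summary` (bucketed counts: redundant, pass, one bucket per
#'   single-failed rule, multi_fail; buckets partition the input).
#' @export
curate_mirnas <- function(candidates, expression = NULL,
                          config = mirna_config()) {
  n <- nrow(candidates)
  rules <- paste0("R", 1:8)
  rep_mat <- matrix(NA, n, 8, dimnames = list(candidates$id, rules))
  dedup <- deduplicate_mirnas(candidates, config$source_priority)
  redundant <- candidates$id %in% dedup$redundancy$redundant_id
  rep_mat[, "R1"] <- !redundant
  rescued <- logical(n)
  for (i in seq_len(n)) {
    prec <- normalize_seq(candidates$precursor[i])
    m5 <- candidates$mature5p[i]; m3 <- candidates$mature3p[i]
    have5 <- !is.na(m5) && nzchar(m5); have3 <- !is.na(m3) && nzchar(m3)
    rep_mat[i, "R2"] <- nchar(prec) <= config$max_precursor_len
    rep_mat[i, "R4"] <- have5 && have3
    lens <- nchar(normalize_seq(c(if (have5) m5, if (have3) m3)))
    rep_mat[i, "R6"] <- if (length(lens))
      all(lens >= config$mature_len[1] & lens <= config$mature_len[2]) else NA
    if (config$require_expression) {
      sup5 <- !have5 || .mature_support(candidates$id[i], normalize_seq(m5),
                                        expression, config$min_read)
      sup3 <- !have3 || .mature_support(candidates$id[i], normalize_seq(m3),
                                        expression, config$min_read)
      rep_mat[i, "R7"] <- (have5 || have3) && sup5 && sup3
    } else rep_mat[i, "R7"] <- TRUE
    off5 <- if (have5) locate_mature(prec, m5) else NA_integer_
    off3 <- if (have3) locate_mature(prec, m3) else NA_integer_
    rep_mat[i, "R5"] <- if (have5 && have3) !is.na(off5) && !is.na(off3) else NA
    foldable <- nchar(prec) <= 1000L
    if (foldable) {
      fold <- fold_hairpin(prec)
      if (have5 && have3 && !is.na(off5) && !is.na(off3)) {
        len5 <- nchar(normalize_seq(m5)); len3 <- nchar(normalize_seq(m3))
        if (off5 > off3) { tmp <- off5; off5 <- off3; off3 <- tmp
                           tmp <- len5; len5 <- len3; len3 <- tmp }
        spans_ok <- off5 + len5 - 1L < off3
        rep_mat[i, "R3"] <- spans_ok &&
          has_single_hairpin(fold, config$min_stem, c(off5, len5), c(off3, len3))
        rep_mat[i, "R8"] <- if (spans_ok) {
          ds <- duplex_stats(fold, c(off5, len5), c(off3, len3))
          ds$opposite_arms && ds$mismatched_positions <= config$max_mismatch &&
            ds$max_asymmetric_bulge <= config$max_bulge
        } else FALSE
      } else {
        rep_mat[i, "R3"] <- has_single_hairpin(fold, config$min_stem)
        rep_mat[i, "R8"] <- NA
      }
    }
    failed <- rules[!is.na(rep_mat[i, ]) & !rep_mat[i, ]]
    if (length(failed) && all(failed %in% c("R4", "R7")) &&
        candidates$id[i] %in% config$allowlist)
      rescued[i] <- TRUE
  }
  failed_list <- apply(rep_mat, 1, function(r) rules[!is.na(r) & !r],
                       simplify = FALSE)
  n_failed <- lengths(failed_list)
  verdict <- n_failed == 0L | rescued
  report <- data.frame(id = candidates$id, stringsAsFactors = FALSE)
  for (r in rules) report[[tolower(r)]] <- rep_mat[, r]
  report$n_failed <- as.integer(n_failed)
  report$first_failed <- vapply(failed_list, function(f)
    if (length(f)) f[1] else NA_character_, "")
  report$failed_rules <- vapply(failed_list, paste, "", collapse = ",")
  report$rescued <- rescued
  report$verdict <- ifelse(verdict, "pass", "fail")
  # summary buckets: redundant first, then single-rule, then multi-fail
  bucket <- character(n)
  bucket[redundant] <- "redundant"
  rest <- !redundant
  nf_rest <- vapply(failed_list, function(f) length(setdiff(f, "R1")), 1L)
  bucket[rest & verdict] <- "pass"
  single <- rest & !verdict & nf_rest == 1L
  bucket[single] <- vapply(failed_list[single], function(f)
    setdiff(f, "R1")[1], "")
  bucket[rest & !verdict & nf_rest > 1L] <- "multi_fail"
  counts <- table(factor(bucket, levels = c("pass", rules[-1], "multi_fail",
                                            "redundant")))
  list(report = report, summary = as.data.frame(counts,
                                                responseName = "n",
                                                stringsAsFactors = FALSE))
}

## -- target expectation scoring ----------------------------------------------

.site_penalties <- function(mx, sx, seed = c(2L, 13L)) {
  # mx: mature base, sx: aligned site base (site read 3'->5' against mature)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  pen <- ifelse(sx == comp[mx], 0,
                ifelse((mx == "G" & sx == "T") | (mx == "T" & sx == "G"),
                       0.5, 1))
  pen[!sx %in% c("A", "C", "G", "T")] <- 1  # ambiguous site base = mismatch
  pen
}

.seed_mult <- function(i, seed = c(2L, 13L)) ifelse(i >= seed[1] & i <= seed[2], 2, 1)

#' Expectation score of a miRNA/target-site duplex
#'
#' Additive penalty over the duplex read 5' to 3' along the mature: each
#' mismatch costs 1, each G:U pair 0.5, each opened gap 2 and each extended
#' gap position 0.5; penalties at mature positions 2-13 (the seed region)
#' are doubled. Scored by a penalty-minimising affine-gap alignment of the
#' mature against the reversed site (the mature binds the site antisense),
#' which reduces to position-wise scoring for equal-length gap-free duplexes.
#' A perfect reverse-complement site scores 0.
#'
#' @param mature mature miRNA sequence (5'->3').
#' @param site target site on the transcript (5'->3').
#' @param seed seed position range on the mature (inclusive).
#' @param gap_open,gap_extend gap penalties.
#' @return numeric expectation (>= 0).
#' @export
expectation_score <- function(mature, site, seed = c(2L, 13L),
                              gap_open = 2, gap_extend = 0.5) {
  mc <- strsplit(normalize_seq(mature), "")[[1]]
  sc <- rev(strsplit(normalize_seq(site), "")[[1]])  # align site 3'->5'
  m <- length(mc); n <- length(sc)
  if (!m || !n) stop("empty mature or site")
  mult <- .seed_mult(seq_len(m), seed)
  INF <- 1e9
  M <- matrix(INF, m + 1L, n + 1L); Ix <- M; Iy <- M
  M[1, 1] <- 0
  # Ix: gap in site (mature base unpaired); Iy: gap in mature (site bulge)
  for (i in 0:m) for (j in 0:n) {
    if (i == 0 && j == 0) next
    ii <- i + 1L; jj <- j + 1L
    w <- if (i >= 1) mult[i] else 1
    if (i >= 1) {
      open <- M[ii - 1L, jj] + w * gap_open
      ext <- Ix[ii - 1L, jj] + w * gap_extend
      Ix[ii, jj] <- min(open, ext)
    }
    if (j >= 1) {
      w2 <- if (i >= 1) mult[i] else 1
      open <- M[ii, jj - 1L] + w2 * gap_open
      ext <- Iy[ii, jj - 1L] + w2 * gap_extend
      Iy[ii, jj] <- min(open, ext)
    }
    if (i >= 1 && j >= 1) {
      pen <- .site_penalties(mc[i], sc[j]) * mult[i]
      M[ii, jj] <- min(M[ii - 1L, jj - 1L], Ix[ii - 1L, jj - 1L],
                       Iy[ii - 1L, jj - 1L]) + pen
    }
  }
  min(M[m + 1L, n + 1L], Ix[m + 1L, n + 1L], Iy[m + 1L, n + 1L])
}

#' Scan transcripts for miRNA target sites
#'
#' Slides an ungapped window of the mature's length over each transcript
#' (antisense orientation only: the site is the transcript segment whose
#' reverse complement pairs the mature), scores each window with the
#' expectation scheme, and keeps non-overlapping best hits with expectation
#' not above `cutoff`. Hits with expectation strictly below 2 are flagged
#' high-confidence.
#'
#' @param mature mature miRNA sequence.
#' @param transcripts named character vector of transcript sequences.
#' @param cutoff maximum reported expectation.
#' @param mature_id id recorded in the output.
#' @param seed seed position range.
#' @return data.frame (mature_id, transcript_id, start, end, expectation,
#'   high_confidence).
#' @export
scan_targets <- function(mature, transcripts, cutoff = 2.0,
                         mature_id = "mature", seed = c(2L, 13L)) {
  mc <- strsplit(normalize_seq(mature), "")[[1]]
  m <- length(mc)
  mult <- .seed_mult(seq_len(m), seed)
  out <- list()
  for (tid in names(transcripts)) {
    tc <- strsplit(normalize_seq(transcripts[[tid]]), "")[[1]]
    L <- length(tc)
    if (L < m) next
    for (w in seq_len(L - m + 1L)) {
      sx <- tc[w + m - seq_len(m)]          # site base aligned to mature i
      score <- sum(.site_penalties(mc, sx) * mult)
      if (score <= cutoff)
        out[[length(out) + 1L]] <- data.frame(
          mature_id = mature_id, transcript_id = tid,
          start = w, end = w + m - 1L, expectation = score,
          high_confidence = score < 2, stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(mature_id = character(0), transcript_id = character(0),
                      start = integer(0), end = integer(0),
                      expectation = numeric(0), high_confidence = logical(0),
                      stringsAsFactors = FALSE))
  hits <- do.call(rbind, out)
  hits[order(hits$transcript_id, hits$start), , drop = FALSE]
}
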