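# Independent brute-force oracles used by the property and acceptance tests.
# These deliberately share no code with the implementation.

# overlap as explicit position-set intersection
bf_overlap <- function(a, b, stranded = TRUE) {
  if (a$seq_id != b$seq_id) return(0L)
  if (stranded && a$strand != b$strand) return(0L)
  length(intersect(seq(a$start, a$end), seq(b$start, b$end)))
}

# IUPAC matching by per-position sliding scan against expanded symbol sets
bf_iupac_sets <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"), B = c("C", "G", "T"),
  D = c("A", "G", "T"), H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T"))

bf_iupac_match <- function(pattern, sequence) {
  pattern <- chartr("U", "T", toupper(pattern))
  sequence <- chartr("U", "T", toupper(sequence))
  p <- strsplit(pattern, "")[[1]]
  s <- strsplit(sequence, "")[[1]]
  n <- length(s); m <- length(p)
  if (n < m) return(integer(0))
  hits <- integer(0)
  for (i in seq_len(n - m + 1L)) {
    ok <- TRUE
    for (j in seq_len(m))
      if (!(s[i + j - 1L] %in% bf_iupac_sets[[p[j]]])) { ok <- FALSE; break }
    if (ok) hits <- c(hits, i)
  }
  hits
}

# exhaustive enumeration of all pseudoknot-free structures (AU/GC/GU pairs,
# min loop 3); returns the maximum number of pairs
bf_can_pair <- function(x, y) {
  paste0(x, y) %in% c("AT", "TA", "GC", "CG", "GT", "TG")
}

bf_max_pairs <- function(sequence, min_loop = 3L) {
  s <- strsplit(chartr("U", "T", toupper(sequence)), "")[[1]]
  enumerate <- function(i, j) {
    if (j - i < min_loop + 1L) return(0L)
    best <- enumerate(i + 1L, j)              # i unpaired
    for (k in seq(i + min_loop + 1L, j)) {
      if (bf_can_pair(s[i], s[k]))
        best <- max(best, 1L + enumerate(i + 1L, k - 1L) +
                      (if (k < j) enumerate(k + 1L, j) else 0L))
    }
    best
  }
  if (length(s) < min_loop + 2L) return(0L)
  enumerate(1L, length(s))
}

# exhaustive tournament for overlap resolution: repeatedly pick the hit that
# beats every other remaining hit pairwise under the cascade, drop its
# overlappers, recurse
bf_beats <- function(a, b, cascade) {
  for (r in seq_len(nrow(cascade))) {
    crit <- cascade$criterion[r]; dir <- cascade$direction[r]
    va <- a[[crit]]; vb <- b[[crit]]
    worst <- if (dir == "max") -Inf else Inf
    if (is.na(va)) va <- worst
    if (is.na(vb)) vb <- worst
    if (va != vb) return(if (dir == "max") va > vb else va < vb)
  }
  # deterministic lexicographic fallback
  ka <- paste(a$seq_id, sprintf("%012d", a$start), sprintf("%012d", a$end),
              a$query_id)
  kb <- paste(b$seq_id, sprintf("%012d", b$start), sprintf("%012d", b$end),
              b$query_id)
  ka < kb
}

bf_resolve <- function(hits, cascade, stranded = TRUE) {
  kept <- hits[0, ]
  while (nrow(hits)) {
    best <- 1L
    for (i in seq_len(nrow(hits)))
      if (i != best && bf_beats(hits[i, ], hits[best, ], cascade)) best <- i
    kept <- rbind(kept, hits[best, ])
    drop <- vapply(seq_len(nrow(hits)), function(i)
      i == best || bf_overlap(hits[best, ], hits[i, ], stranded) > 0L, NA)
    hits <- hits[!drop, , drop = FALSE]
  }
  kept[order(kept$seq_id, kept$start, kept$end, kept$query_id), , drop = FALSE]
}

# random hit tables with forced overlap structure for the resolve oracle
random_hits <- function(n, seq_ids = c("c1", "c2"), span = 60L) {
  start <- sample.int(span, n, replace = TRUE)
  len <- sample(5:30, n, replace = TRUE)
  data.frame(query_id = paste0("q", seq_len(n)),
             seq_id = sample(seq_ids, n, replace = TRUE),
             start = start, end = start + len,
             strand = sample(c("+", "-"), n, replace = TRUE, prob = c(.8, .2)),
             length = len + 1L,
             percent_identity = round(stats::runif(n, 90, 100), 1),
             query_coverage = sample(c(91, 93, 95, 97), n, replace = TRUE),
             e_value = 10^sample(-20:-5, n, replace = TRUE),
             bit_score = sample(c(50, 60, 70), n, replace = TRUE),
             source = "similarity", class_label = "snoRNA",
             family_label = "R1", stringsAsFactors = FALSE)
}

# random additive (tree-metric) distance matrix and its generating topology
random_additive <- function(n_taxa) {
  tr <- ape::rtree(n_taxa, br = function(k) stats::runif(k, 0.05, 1))
  tr$tip.label <- paste0("t", seq_len(n_taxa))
  d <- ape::cophenetic.phylo(tr)
  d <- d[order(rownames(d)), order(colnames(d))]
  list(tree = ape::unroot(tr), d = d)
}

# deterministic perfect-stem hairpin: 10 nt paired extension, 21 nt mature
# duplex, 8 nt unpairable loop
perfect_hairpin_fixture <- function() {
  rc <- function(x) as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(x)))
  e5 <- "GCGAACGTCC"
  m5 <- "TGGAGAAGCAGGGCACGTGCA"
  loop <- "AACAAACA"
  list(precursor = paste0(e5, m5, loop, rc(m5), rc(e5)),
       mature5p = m5, mature3p = rc(m5), off5 = 11L, off3 = 40L)
}

same_topology <- function(t1, t2) {
  ape::dist.topo(ape::unroot(t1), ape::unroot(t2), method = "PH85") == 0
}
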