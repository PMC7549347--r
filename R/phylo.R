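## p-distance matrix, neighbor-joining tree and bootstrap support for miRNA
## precursor family analysis. The NJ construction and the bootstrap
## bookkeeping use ape; the p-distance is computed here so that both
## pairwise- and complete-deletion gap policies are available.

#' p-distance matrix from aligned sequences
#'
#' `d(a, b)` is the proportion of differing sites among compared sites.
#' Under `pairwise_delete` (default) sites with a gap (`-`) in either member
#' of the pair are excluded pair by pair; under `complete_delete` any column
#' containing a gap in any sequence is excluded for all pairs.
#'
#' @param sequences named character vector of equal-length aligned sequences.
#' @param gap_policy `"pairwise_delete"` or `"complete_delete"`.
#' @return symmetric `dist`-convertible matrix with zero diagonal, entries in
#'   `[0, 1]`, taxon labels as dimnames.
#' @export
p_distance <- function(sequences,
                       gap_policy = c("pairwise_delete", "complete_delete")) {
  gap_policy <- match.arg(gap_policy)
  if (length(unique(nchar(sequences))) != 1L)
    stop("sequences must be aligned (equal length)")
  n <- length(sequences)
  if (n < 2L) stop("need at least two sequences")
  m <- do.call(rbind, strsplit(toupper(sequences), ""))
  rownames(m) <- names(sequences)
  gap <- m == "-" | m == "."
  if (gap_policy == "complete_delete") {
    keep <- colSums(gap) == 0L
    m <- m[, keep, drop = FALSE]
    gap <- gap[, keep, drop = FALSE]
  }
  d <- matrix(0, n, n, dimnames = list(names(sequences), names(sequences)))
  for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
    comp <- !gap[i, ] & !gap[j, ]
    if (!any(comp))
      stop("no comparable sites between ", names(sequences)[i], " and ",
           names(sequences)[j])
    d[i, j] <- d[j, i] <- sum(m[i, comp] != m[j, comp]) / sum(comp)
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Classical NJ (Q-criterion minimisation with the standard branch-length
#' formulas), via ape. Negative branch lengths are reported as computed
#' unless `clamp = TRUE` sets them to zero.
#'
#' @param d symmetric distance matrix (or `dist`) over >= 3 taxa.
#' @param clamp clamp negative branch lengths to zero.
#' @return an unrooted `ape::phylo` tree.
#' @export
nj_tree <- function(d, clamp = FALSE) {
  d <- as.matrix(d)
  if (nrow(d) < 3L) stop("neighbor-joining needs at least 3 taxa")
  tr <- ape::nj(stats::as.dist(d))
  if (clamp) tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' Bootstrap support for an NJ tree
#'
#' Resamples alignment columns with replacement, rebuilds the NJ tree per
#' replicate, and reports for every internal edge of the original tree the
#' percentage of replicates containing that bipartition (via
#' `ape::boot.phylo` with `rooted = FALSE`). Supports are stored as node
#' labels, so `ape::write.tree` emits them in Newick form.
#'
#' @param sequences named character vector of aligned sequences.
#' @param replicates number of bootstrap replicates (the conventional
#'   full-scale setting is 5000).
#' @param seed RNG seed; identical seeds give identical supports.
#' @param gap_policy passed to [p_distance()].
#' @return the original NJ `phylo` tree; when `replicates > 0`, with a
#'   `node.label` vector of supports in `[0, 100]` (`NA` for the root) and a
#'   `bootstrap` attribute.
#' @export
bootstrap_tree <- function(sequences, replicates = 5000, seed = 1,
                           gap_policy = "pairwise_delete") {
  tr <- nj_tree(p_distance(sequences, gap_policy))
  if (replicates <= 0) return(tr)
  x <- do.call(rbind, strsplit(toupper(sequences), ""))
  rownames(x) <- names(sequences)
  build <- function(mat) {
    seqs <- apply(mat, 1, paste, collapse = "")
    nj_tree(p_distance(seqs, gap_policy))
  }
  set.seed(seed)
  counts <- ape::boot.phylo(tr, x, build, B = replicates, rooted = FALSE,
                            quiet = TRUE)
  support <- round(100 * counts / replicates)
  support[1] <- NA            # root "split" is not an internal edge
  tr$node.label <- support
  attr(tr, "bootstrap") <- support
  tr
}
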