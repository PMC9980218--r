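#' Read an aligned protein FASTA
#' @param path aligned FASTA (gaps as `-`)
#' @return character matrix, one row per sequence, one column per alignment
#'   position
#' @export
read_protein_alignment <- function(path) {
  ss <- Biostrings::readAAStringSet(path)
  if (length(unique(Biostrings::width(ss))) != 1)
    stopf("alignment rows have unequal lengths")
  m <- do.call(rbind, strsplit(toupper(as.character(ss)), ""))
  rownames(m) <- names(ss)
  m
}

.aln_matrix <- function(aln) {
  if (is.matrix(aln)) return(aln)
  if (is(aln, "AAStringSet")) {
    m <- do.call(rbind, strsplit(toupper(as.character(aln)), ""))
    rownames(m) <- names(aln)
    return(m)
  }
  stopf("alignment must be a character matrix or AAStringSet")
}

#' Pairwise p-distances of an alignment
#'
#' The p-distance is the proportion of compared sites at which two aligned
#' sequences differ — amino acid differences per site, uncorrected. Under
#' `gap_mode = "pairwise"` (default) a column is compared for a pair only if
#' neither member has a gap there; `"complete"` first drops every column
#' containing any gap.
#'
#' @param aln character matrix or `AAStringSet` of aligned sequences
#' @param gap_mode `"pairwise"` or `"complete"` deletion
#' @return symmetric numeric matrix with zero diagonal, entries in `[0, 1]`
#' @examples
#' m <- rbind(a = strsplit("ACDE", "")[[1]], b = strsplit("ACDQ", "")[[1]])
#' p_distance(m)["a", "b"]  # 0.25
#' @export
p_distance <- function(aln, gap_mode = c("pairwise", "complete")) {
  gap_mode <- match.arg(gap_mode)
  m <- .aln_matrix(aln)
  if (nrow(m) < 2) stopf("need >= 2 sequences")
  gap <- m == "-" | m == "." | m == "?"
  if (gap_mode == "complete") {
    keep <- colSums(gap) == 0
    m <- m[, keep, drop = FALSE]
    gap <- gap[, keep, drop = FALSE]
    if (ncol(m) == 0) stopf("no gap-free columns under complete deletion")
  }
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- !gap[i, ] & !gap[j, ]
      if (!any(ok))
        stopf("no comparable columns between '%s' and '%s'",
              rownames(m)[i], rownames(m)[j])
      d[i, j] <- d[j, i] <- mean(m[i, ok] != m[j, ok])
    }
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou–Nei agglomeration (standard Q-criterion) on a symmetric distance
#' matrix, returning an unrooted tree. Negative branch lengths, which NJ can
#' produce on non-additive matrices, are clamped to zero with a warning.
#'
#' @param d symmetric numeric matrix with zero diagonal, >= 3 taxa
#' @return an unrooted [ape::phylo] tree
#' @export
neighbor_joining <- function(d) {
  if (!is.matrix(d) || nrow(d) != ncol(d)) stopf("d must be a square matrix")
  if (nrow(d) < 3) stopf("need >= 3 taxa")
  if (any(abs(d - t(d)) > 1e-12) || any(diag(d) != 0))
    stopf("d must be symmetric with a zero diagonal")
  tree <- ape::nj(d)
  if (any(tree$edge.length < 0)) {
    warning("negative NJ branch length(s) clamped to 0")
    tree$edge.length[tree$edge.length < 0] <- 0
  }
  tree
}

#' Bootstrap support for the NJ tree of an alignment
#'
#' Resamples alignment columns with replacement `n_reps` times, rebuilds the
#' p-distance NJ tree from each replicate, and reports for each internal
#' edge of the full-data tree the fraction of replicate trees containing the
#' same bipartition. Supports are attached as node labels, so
#' [ape::write.tree()] emits them at internal nodes. Deterministic under
#' `seed`.
#'
#' @param aln character matrix or `AAStringSet`
#' @param n_reps bootstrap replicates (default 1000)
#' @param seed RNG seed
#' @param gap_mode passed to [p_distance()]
#' @return list: `tree` (full-data NJ tree with `node.label` = support
#'   fractions), `support` (numeric vector per internal node), `n_reps`
#' @export
bootstrap_support <- function(aln, n_reps = 1000, seed = 42, gap_mode = "pairwise") {
  if (n_reps < 1) stopf("n_reps must be >= 1")
  m <- .aln_matrix(aln)
  tree <- neighbor_joining(p_distance(m, gap_mode))
  set.seed(seed)
  boots <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
    boots[[r]] <- suppressWarnings(
      neighbor_joining(p_distance(m[, cols, drop = FALSE], gap_mode)))
  }
  counts <- ape::prop.clades(tree, boots, rooted = FALSE)
  support <- counts / n_reps
  support[is.na(support)] <- NA_real_
  tree$node.label <- ifelse(is.na(support), "", format(round(support, 3)))
  list(tree = tree, support = support, n_reps = n_reps)
}
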