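#' Ward hierarchical clustering of a gene distance matrix
#'
#' Agglomerates individuals with Ward's minimum-dispersion criterion applied
#' directly to the supplied dissimilarities (the classical Lance-Williams
#' update on the distances as given, not squared — the transform in
#' [similarity_to_distance()] is not Euclidean, so no embedding is assumed).
#' The result is deterministic for identical input. Height inversions are
#' possible with non-Euclidean input; cuts are made by number of clusters,
#' never by height, so they do not affect partitions.
#'
#' @param dist A [similarity_to_distance()] result, any symmetric matrix
#'   with zero diagonal, or a [stats::dist] object.
#' @param method Agglomeration convention passed to [stats::hclust()];
#'   default `"ward.D"` (distances used as-is).
#' @return An [stats::hclust] tree with a `gene` attribute.
#' @export
ward_tree <- function(dist, method = "ward.D") {
  if (inherits(dist, "dist")) {
    d <- dist
    gene <- NA_character_
  } else {
    M <- unclass(dist)
    if (!isSymmetric(unname(M))) abort("distance matrix must be symmetric")
    d <- as.dist(M)
    gene <- attr(dist, "gene", exact = TRUE) %||% NA_character_
  }
  if (attr(d, "Size") < 2) abort("need at least 2 individuals")
  tree <- hclust(d, method = method)
  attr(tree, "gene") <- gene
  tree
}

#' Cut a cluster tree into k groups
#'
#' @param tree An [stats::hclust] tree from [ward_tree()].
#' @param k Number of partition elements, `1 <= k <= n`.
#' @return Integer vector of element labels `1..k`, named by individual id,
#'   with attribute `sizes` (element sizes). Every element is nonempty, and
#'   cuts from the same tree are nested: the cut at k is refined by the cut
#'   at k + 1.
#' @export
cut_tree <- function(tree, k) {
  n <- length(tree$order)
  if (length(k) != 1 || k < 1 || k > n) {
    abort(sprintf("k must lie in [1, %d]", n))
  }
  labels <- cutree(tree, k = k)
  structure(as.integer(labels), names = names(labels),
            sizes = tabulate(labels, nbins = k))
}

#' Cut one tree at several partition sizes
#'
#' The screen considers partition sizes 5 to 10 by default; all cuts come
#' from the same Ward tree, so they are nested.
#'
#' @param dist A [similarity_to_distance()] result (or symmetric matrix).
#' @param ks Integer vector of partition sizes, default `5:10`.
#' @return Named list of label vectors (one [cut_tree()] result per k).
#' @export
partition_sweep <- function(dist, ks = 5:10) {
  if (!length(ks)) abort("ks must be nonempty")
  tree <- ward_tree(dist)
  setNames(lapply(ks, function(k) cut_tree(tree, k)), as.character(ks))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
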