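#' Hierarchical clustering of samples (Euclidean distance, Ward linkage)
#'
#' Agglomerative clustering of the rows of the fused matrix with the Ward
#' criterion: each merge minimises the increase in total within-cluster
#' variance. The implementation uses the Lance-Williams recurrence on
#' squared Euclidean distances with merge heights reported on the
#' Euclidean scale (`hclust` method `"ward.D2"`), the textbook Ward
#' variant; the `linkage` argument is configurable for comparison.
#'
#' @param x Numeric samples x variables matrix or fused matrix.
#' @param distance Distance measure (passed to [stats::dist()]).
#' @param linkage `"ward"` (Ward.D2 semantics) or any [stats::hclust()]
#'   method name.
#' @return An [stats::hclust()] object; leaf labels are sample IDs.
#' @export
hierarchical_cluster <- function(x, distance = "euclidean",
                                 linkage = "ward") {
  x <- as_num_matrix(x)
  if (nrow(x) < 2L)
    stop("clustering needs at least 2 samples", call. = FALSE)
  method <- if (identical(linkage, "ward")) "ward.D2" else linkage
  hclust(dist(x, method = distance), method = method)
}

#' Leaf sets of the first cluster break
#'
#' Splits a dendrogram at its root: the two subtrees of the final merge,
#' i.e. the two groups obtained by cutting the tree into two clusters.
#'
#' @param d An [stats::hclust()] object.
#' @return A list of two character vectors of leaf labels (or indices if
#'   the tree is unlabelled).
#' @export
cut_first_split <- function(d) {
  stopifnot(inherits(d, "hclust"))
  grp <- cutree(d, k = 2)
  labs <- if (is.null(d$labels)) as.character(seq_along(grp)) else d$labels
  split(labs, grp)
}

#' Serialise a dendrogram as a Newick string
#'
#' Ultrametric convention: a leaf sits at depth `h_root / 2`, and the
#' branch from a node merged at height `h` to its child merged at height
#' `h_c` has length `(h - h_c) / 2` (leaves have `h_c = 0`). Two leaves
#' A, B joined at height h therefore give `"(A:h/2,B:h/2);"`.
#'
#' @param d An [stats::hclust()] object.
#' @return A single Newick string (terminated by `";"`).
#' @export
dendrogram_to_newick <- function(d) {
  stopifnot(inherits(d, "hclust"))
  labs <- if (is.null(d$labels))
    as.character(seq_len(length(d$order))) else d$labels
  node <- function(i) {
    # i < 0: leaf -i; i > 0: internal node from merge row i
    if (i < 0) list(txt = labs[-i], h = 0)
    else {
      l <- node(d$merge[i, 1])
      r <- node(d$merge[i, 2])
      h <- d$height[i]
      list(txt = sprintf("(%s:%s,%s:%s)", l$txt, fmt_num((h - l$h) / 2),
                         r$txt, fmt_num((h - r$h) / 2)),
           h = h)
    }
  }
  paste0(node(nrow(d$merge))$txt, ";")
}
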