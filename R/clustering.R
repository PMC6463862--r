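# Hierarchical clustering of per-gene polymorphism profiles: Manhattan
# distances, ward.D linkage, k-group cuts. The distance / linkage /
# cut machinery is R's canonical stats::dist / hclust / cutree; this module
# adds the input validation, NA-row policy and deterministic wrappers the
# pipeline relies on.

#' Manhattan distances between statistic profiles
#'
#' Rows are genes, columns are features (e.g. Tajima's D for the upstream,
#' CDS and downstream regions). Rows containing undefined values (`NA`,
#' e.g. D for a region with no segregating sites) are dropped with a
#' warning rather than imputed.
#'
#' @param m Numeric matrix with unique row names; at least two complete
#'   rows.
#' @return A `dist` object (`d(i,j) = sum_k |m_ik - m_jk|`).
#' @export
manhattan_distances <- function(m) {
  m <- as.matrix(m)
  if (is.null(rownames(m))) rownames(m) <- paste0("row", seq_len(nrow(m)))
  if (anyDuplicated(rownames(m))) stop("manhattan_distances: duplicate row labels")
  bad <- rowSums(is.na(m)) > 0L
  if (any(bad)) {
    warning("manhattan_distances: dropping ", sum(bad),
            " row(s) with undefined values: ",
            paste(rownames(m)[bad], collapse = ", "))
    m <- m[!bad, , drop = FALSE]
  }
  if (nrow(m) < 2L) stop("manhattan_distances: need at least two complete rows")
  dist(m, method = "manhattan")
}

#' Agglomerative clustering with ward.D linkage
#'
#' Applies the ward.D Lance-Williams update to the given (unsquared)
#' distances — the `hclust(method = "ward.D")` convention. Merges are
#' deterministic for a given input ordering.
#'
#' @param d A `dist` object or symmetric distance matrix.
#' @return An `hclust` dendrogram.
#' @export
hierarchical_ward <- function(d) {
  if (is.matrix(d)) {
    if (!isSymmetric(unname(d), tol = 1e-12)) {
      stop("hierarchical_ward: distance matrix not symmetric")
    }
    d <- as.dist(d)
  }
  if (!inherits(d, "dist")) stop("hierarchical_ward: need a dist or matrix")
  hclust(d, method = "ward.D")
}

#' Cut a dendrogram into k groups
#'
#' @param dendrogram An `hclust` object.
#' @param k Number of groups, `1 <= k <= n`.
#' @return Named integer vector of cluster memberships.
#' @export
cut_tree <- function(dendrogram, k) {
  n <- length(dendrogram$order)
  if (k < 1L || k > n) stop("cut_tree: k out of range [1, ", n, "]")
  cutree(dendrogram, k = k)
}

#' Cluster genes by their polymorphism profiles
#'
#' Convenience pipeline: optional row z-scaling, Manhattan distances,
#' ward.D linkage, cut into `k` groups (default 3, the number of
#' evolutionary-constraint classes the D profiles separate into).
#'
#' @param m Statistic matrix (genes x features), e.g. Tajima's D for
#'   up/CDS/down regions.
#' @param k Number of clusters.
#' @param scale_rows Z-scale each row before clustering (default FALSE:
#'   raw values).
#' @return List with `dendrogram` (`hclust`), `clusters` (named integer
#'   vector) and `dropped` (row labels removed for undefined values).
#' @export
cluster_statistic_matrix <- function(m, k = 3L, scale_rows = FALSE) {
  m <- as.matrix(m)
  all_rows <- rownames(m) %||% paste0("row", seq_len(nrow(m)))
  rownames(m) <- all_rows
  if (scale_rows) m <- t(scale(t(m)))
  d <- withCallingHandlers(
    manhattan_distances(m),
    warning = function(w) invokeRestart("muffleWarning"))
  kept <- attr(d, "Labels")
  dropped <- setdiff(all_rows, kept)
  if (length(dropped)) {
    warning("cluster_statistic_matrix: dropped row(s) with undefined values: ",
            paste(dropped, collapse = ", "))
  }
  hc <- hierarchical_ward(d)
  list(dendrogram = hc, clusters = cut_tree(hc, k), dropped = dropped)
}
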