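#' Alpha diversity per sample
#'
#' Observed richness (taxa with at least one read) and Shannon diversity
#' in nats, computed on proportions within each sample. Warns when row
#' sums are unequal, since unrarefied tables confound depth with
#' diversity.
#'
#' @param table samples-x-taxa count matrix.
#' @return data.frame with columns `sample_id`, `richness`, `shannon`.
#' @export
alpha_diversity <- function(table) {
  validate_count_table(table)
  if (length(unique(rowSums(table))) > 1L)
    warnf("alpha_diversity: unequal sample depths; consider rarefying first")
  data.frame(
    sample_id = rownames(table),
    richness = as.integer(rowSums(table > 0)),
    shannon = as.numeric(vegan::diversity(table, index = "shannon")),
    stringsAsFactors = FALSE
  )
}

#' Aitchison distance
#'
#' Euclidean distance between CLR-transformed samples.
#'
#' @param clr_matrix output of [clr_transform()].
#' @return a [stats::dist] object labelled by sample id.
#' @export
aitchison_distance <- function(clr_matrix) {
  if (!is.matrix(clr_matrix) || is.null(rownames(clr_matrix)))
    stopf("clr_matrix must be a matrix with sample rownames")
  dist(clr_matrix)
}

#' Weighted UniFrac distance
#'
#' For each pair of samples, the branch-length-weighted difference in
#' the fraction of each community's abundance descending through every
#' branch of the shared tree: `raw = sum_b len_b * |p_A(b) - p_B(b)|`.
#' The normalized form divides by `sum_b len_b * (p_A(b) + p_B(b))` and
#' lies in [0, 1].
#'
#' @param table samples-x-taxa count matrix; taxa must all be tree tips.
#' @param tree rooted [ape::phylo] with branch lengths.
#' @param normalized return the normalized form (default) or the raw
#'   branch-length-weighted sum.
#' @return a [stats::dist] object.
#' @export
weighted_unifrac <- function(table, tree, normalized = TRUE) {
  validate_count_table(table)
  validate_tree(tree)
  if (!all(colnames(table) %in% tree$tip.label))
    stopf("alignment error: taxa absent from tree: %s",
          paste(setdiff(colnames(table), tree$tip.label), collapse = ", "))
  tree <- ape::keep.tip(tree, colnames(table))
  P <- relative_abundance(table)[, tree$tip.label, drop = FALSE]

  n_tip <- length(tree$tip.label)
  n_node <- tree$Nnode
  # abundance flowing through each node, accumulated tips-up (postorder)
  A <- matrix(0, nrow(P), n_tip + n_node, dimnames = list(rownames(P), NULL))
  A[, seq_len(n_tip)] <- P
  eo <- ape::reorder.phylo(tree, "postorder")
  for (e in seq_len(nrow(eo$edge)))
    A[, eo$edge[e, 1L]] <- A[, eo$edge[e, 1L]] + A[, eo$edge[e, 2L]]
  # per-edge abundance = abundance of the child node of that edge
  E <- A[, tree$edge[, 2L], drop = FALSE]
  len <- tree$edge.length

  raw <- dist(sweep(E, 2L, len, `*`), method = "manhattan")
  if (!normalized) return(raw)
  through <- as.numeric(E %*% len)  # sum_b len_b * p_X(b) per sample
  denom <- as.dist(outer(through, through, `+`))
  out <- raw / denom
  out[denom == 0] <- 0
  out
}

#' Principal coordinates analysis
#'
#' Classical metric scaling of a distance matrix: double-centred Gower
#' matrix eigendecomposition. Coordinates are returned for axes with
#' positive eigenvalues; negative eigenvalues are retained in the
#' eigenvalue vector and reported, not corrected.
#'
#' @param dm a [stats::dist] or symmetric matrix.
#' @return list with `vectors` (samples x axes), `eigenvalues` (all, in
#'   decreasing order), and `proportion_explained` (relative to the sum
#'   of positive eigenvalues).
#' @export
pcoa_ordination <- function(dm) {
  d <- as_square_distance(dm)
  n <- nrow(d)
  a <- -0.5 * d^2
  rm <- rowMeans(a)
  G <- a - outer(rm, rm, `+`) + mean(a)
  G <- (G + t(G)) / 2
  eig <- eigen(G, symmetric = TRUE)
  pos <- which(eig$values > 1e-12 * max(abs(eig$values), 1))
  vec <- eig$vectors[, pos, drop = FALSE] %*%
    diag(sqrt(eig$values[pos]), length(pos))
  dimnames(vec) <- list(rownames(d), paste0("Axis.", seq_along(pos)))
  list(vectors = vec,
       eigenvalues = eig$values,
       proportion_explained = eig$values[pos] / sum(eig$values[pos]))
}

#' Hierarchical clustering of samples
#'
#' Agglomerative clustering of a sample distance matrix; UPGMA (average
#' linkage) by default, matching common practice for community
#' dissimilarities.
#'
#' @param dm a [stats::dist] or symmetric matrix.
#' @param linkage linkage criterion passed to [stats::hclust()].
#' @return an [stats::hclust] object.
#' @export
hierarchical_cluster <- function(dm, linkage = "average") {
  hclust(as.dist(as_square_distance(dm)), method = linkage)
}
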