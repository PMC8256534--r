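# Independent brute-force oracles, deliberately written as naive loops
# over first-principles definitions so they share no code path with the
# implementation they check.

# Patristic distance by root-path summation: distance(a, b) =
# depth(a) + depth(b) - 2 * depth(mrca), with depths and ancestor paths
# walked directly on the edge table.
oracle_patristic <- function(tree) {
  n <- length(tree$tip.label)
  parent_of <- integer(n + tree$Nnode)
  edge_len_to <- numeric(n + tree$Nnode)
  for (e in seq_len(nrow(tree$edge))) {
    parent_of[tree$edge[e, 2]] <- tree$edge[e, 1]
    edge_len_to[tree$edge[e, 2]] <- tree$edge.length[e]
  }
  root <- setdiff(tree$edge[, 1], tree$edge[, 2])[1]
  path_to_root <- function(node) {
    path <- node
    while (node != root) {
      node <- parent_of[node]
      path <- c(path, node)
    }
    path
  }
  depth_of <- function(node) {
    d <- 0
    while (node != root) {
      d <- d + edge_len_to[node]
      node <- parent_of[node]
    }
    d
  }
  D <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  for (a in seq_len(n)) for (b in seq_len(n)) {
    if (a == b) next
    mrca <- intersect(path_to_root(a), path_to_root(b))[1]
    D[a, b] <- depth_of(a) + depth_of(b) - 2 * depth_of(mrca)
  }
  D
}

oracle_mntd <- function(comm, D, weighted = TRUE) {
  present <- which(comm > 0)
  nn <- numeric(length(present))
  for (i in seq_along(present)) {
    best <- Inf
    for (j in present) {
      if (j == present[i]) next
      if (D[present[i], j] < best) best <- D[present[i], j]
    }
    nn[i] <- best
  }
  if (weighted) sum(comm[present] / sum(comm[present]) * nn) else mean(nn)
}

oracle_beta_mntd <- function(ca, cb, D, weighted = TRUE) {
  pa <- which(ca > 0); pb <- which(cb > 0)
  da <- sapply(pa, function(i) min(D[i, pb]))
  db <- sapply(pb, function(j) min(D[j, pa]))
  if (weighted) {
    0.5 * (sum(ca[pa] / sum(ca[pa]) * da) + sum(cb[pb] / sum(cb[pb]) * db))
  } else {
    0.5 * (mean(da) + mean(db))
  }
}

# Weighted UniFrac by per-branch walk: for every edge collect its
# descendant tips recursively, then sum len * |pA - pB|.
oracle_wunifrac <- function(xa, xb, tree, normalized = TRUE) {
  pa <- xa / sum(xa); pb <- xb / sum(xb)
  tips_under <- function(node) {
    if (node <= length(tree$tip.label)) return(node)
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    unlist(lapply(kids, tips_under))
  }
  num <- 0; den <- 0
  for (e in seq_len(nrow(tree$edge))) {
    tips <- tree$tip.label[tips_under(tree$edge[e, 2])]
    fa <- sum(pa[tips]); fb <- sum(pb[tips])
    num <- num + tree$edge.length[e] * abs(fa - fb)
    den <- den + tree$edge.length[e] * (fa + fb)
  }
  if (normalized) num / den else num
}

oracle_moran <- function(z, W) {
  n <- length(z)
  zc <- z - mean(z)
  num <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) num <- num + W[i, j] * zc[i] * zc[j]
  unname((n / sum(W)) * num / sum(zc^2))
}

# Random community fixtures used across tests.
random_table <- function(n_samples, n_taxa, seed, depth = 500) {
  set.seed(seed)
  p <- rlnorm(n_taxa, 0, 1.5)
  x <- t(sapply(seq_len(n_samples),
                function(i) rmultinom(1, depth, sample(p))[, 1]))
  dimnames(x) <- list(paste0("s", seq_len(n_samples)),
                      paste0("t", seq_len(n_taxa)))
  x
}

random_tip_tree <- function(n_tips, seed) {
  set.seed(seed)
  tr <- ape::rtree(n_tips)
  tr$tip.label <- paste0("t", seq_len(n_tips))
  tr
}
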