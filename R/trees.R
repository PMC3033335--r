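# UPGMA feature trees and feature-tree/reference-tree discordance.
#
# Discordance between two trees is the root mean squared deviation between
# their nodal matrices (per leaf pair, the number of internal nodes on the
# connecting path); significance comes from a label-permutation null with
# a normal-tail approximation.

#' UPGMA tree from a distance matrix
#'
#' Standard average-linkage agglomeration: the closest pair of clusters is
#' merged at height d/2 and inter-cluster distances are updated as
#' size-weighted arithmetic means. Ties at the minimal distance are broken
#' towards the lexicographically smallest pair of cluster representative
#' labels, making the result fully deterministic. Negative entries (the
#' motif divergence can dip below zero) are clipped at 0 with a warning.
#'
#' @param D symmetric labelled distance matrix (or `dist`).
#' @return an ultrametric `ape::phylo` tree.
#' @export
upgma <- function(D) {
  if (inherits(D, "dist")) D <- as.matrix(D)
  n <- nrow(D)
  if (n < 2L) stop("need at least 2 taxa")
  labels <- rownames(D) %||% paste0("t", seq_len(n))
  if (any(D < 0)) {
    warning("negative distances clipped at 0 for UPGMA")
    D[D < 0] <- 0
  }
  d <- D
  diag(d) <- Inf
  size <- rep(1L, n)
  height <- rep(0, n)
  repr <- labels                 # representative label per active cluster
  active <- rep(TRUE, n)
  merge_node <- seq_len(n)       # phylo node id of each active cluster
  # phylo bookkeeping: tips 1..n, internal nodes n+1 .. 2n-1 (root last is
  # not required by ape, but parents must exceed n)
  edge <- matrix(0L, 2L * (n - 1L), 2L)
  elen <- numeric(2L * (n - 1L))
  next_node <- n + 1L
  erow <- 0L
  for (step in seq_len(n - 1L)) {
    idx <- which(active)
    sub <- d[idx, idx, drop = FALSE]
    mn <- min(sub)
    hit <- which(sub == mn, arr.ind = TRUE)
    hit <- hit[hit[, 1] < hit[, 2], , drop = FALSE]
    # lexicographic tie-break on sorted representative label pairs
    keys <- apply(hit, 1L, function(h) {
      pr <- sort(c(repr[idx[h[1]]], repr[idx[h[2]]]))
      paste(pr, collapse = "\r")
    })
    h <- hit[order(keys)[1L], ]
    i <- idx[h[1L]]; j <- idx[h[2L]]
    hgt <- mn / 2
    edge[erow + 1L, ] <- c(next_node, merge_node[i])
    elen[erow + 1L] <- hgt - height[i]
    edge[erow + 2L, ] <- c(next_node, merge_node[j])
    elen[erow + 2L] <- hgt - height[j]
    erow <- erow + 2L
    # update distances into cluster i
    others <- setdiff(idx, c(i, j))
    if (length(others)) {
      newd <- (size[i] * d[i, others] + size[j] * d[j, others]) /
        (size[i] + size[j])
      d[i, others] <- newd; d[others, i] <- newd
    }
    size[i] <- size[i] + size[j]
    height[i] <- hgt
    repr[i] <- min(repr[i], repr[j])
    merge_node[i] <- next_node
    active[j] <- FALSE
    next_node <- next_node + 1L
  }
  # renumber internal nodes to ape convention (root = n+1, preorder)
  children <- split(seq_len(nrow(edge)), edge[, 1])
  root_old <- setdiff(edge[, 1], edge[, 2])[1]
  newid <- integer(2L * n - 1L)
  newid[seq_len(n)] <- seq_len(n)
  counter <- n
  row_order <- integer(0)
  stack <- root_old
  while (length(stack)) {
    nd <- stack[length(stack)]
    stack <- stack[-length(stack)]
    counter <- counter + 1L
    newid[nd] <- counter
    rows <- children[[as.character(nd)]]
    row_order <- c(row_order, rows)
    kids <- edge[rows, 2]
    stack <- c(stack, rev(kids[kids > n]))
  }
  edge2 <- cbind(newid[edge[row_order, 1]], newid[edge[row_order, 2]])
  storage.mode(edge2) <- "integer"
  tree <- list(edge = edge2, edge.length = elen[row_order],
               tip.label = labels, Nnode = n - 1L)
  class(tree) <- "phylo"
  tree
}

#' Nodal matrix of a tree
#'
#' Entry (a, b) is the number of internal nodes on the path between leaves
#' a and b (1 for a cherry). Multifurcating nodes count once.
#'
#' @param tree an `ape::phylo` tree.
#' @return symmetric integer matrix with leaf labels, zero diagonal.
#' @export
nodal_matrix <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  n <- length(tree$tip.label)
  if (n < 2L) stop("need at least 2 leaves")
  parent <- integer(n + tree$Nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  root <- setdiff(tree$edge[, 1], tree$edge[, 2])[1]
  anc <- vector("list", n)
  for (tip in seq_len(n)) {
    path <- integer(0)
    nd <- parent[tip]
    while (nd != 0L) { path <- c(path, nd); nd <- parent[nd] }
    anc[[tip]] <- path
  }
  M <- matrix(0L, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  for (a in seq_len(n - 1L)) for (b in (a + 1L):n) {
    pa <- anc[[a]]; pb <- anc[[b]]
    mr <- pa[match(TRUE, pa %in% pb)]
    cnt <- match(mr, pa) + match(mr, pb) - 1L
    M[a, b] <- cnt; M[b, a] <- cnt
  }
  M
}

# RMSD between nodal matrices over the shared leaf set (unordered pairs)
#' @noRd
.nodal_rmsd <- function(M1, M2) {
  sh <- intersect(rownames(M1), rownames(M2))
  A <- M1[sh, sh]; B <- M2[sh, sh]
  sqrt(mean((A[upper.tri(A)] - B[upper.tri(B)])^2))
}

#' Discordance between a feature tree and reference trees
#'
#' The observed statistic is the mean nodal-distance RMSD between the
#' feature tree and each reference tree (computed on the shared leaf set).
#' The null distribution is obtained by randomly permuting the feature
#' tree's leaf labels on its fixed topology `n_perm` times; a lower-tail
#' normal probability of the observed statistic is reported, together with
#' an exact permutation p-value (rank among permutations), since a small
#' permutation count cannot itself support extreme tail probabilities.
#'
#' @param feature_tree `ape::phylo`.
#' @param reference_trees a `phylo`, a list of them, or a `multiPhylo`.
#' @param n_perm number of label permutations (default 100).
#' @param seed optional RNG seed for the permutations.
#' @return object of class `discordance_report`: list with `rmsd`,
#'   `null_mean`, `null_sd`, `p_value` (normal tail), `p_exact`,
#'   `n_permutations`.
#' @export
tree_discordance <- function(feature_tree, reference_trees, n_perm = 100L,
                             seed = NULL) {
  if (inherits(reference_trees, "phylo"))
    reference_trees <- list(reference_trees)
  if (n_perm < 1L) stop("'n_perm' must be at least 1")
  if (!is.null(seed)) set.seed(seed)
  shared <- Reduce(intersect, c(list(feature_tree$tip.label),
                                lapply(reference_trees, `[[`, "tip.label")))
  if (length(shared) < 3L) stop("fewer than 3 shared leaves")
  if (length(shared) < length(feature_tree$tip.label))
    warning("leaf sets differ; using the ", length(shared),
            " shared leaves")
  Mf <- nodal_matrix(feature_tree)[shared, shared]
  Mr <- lapply(reference_trees,
               function(t) nodal_matrix(t)[shared, shared])
  stat <- function(M) mean(vapply(Mr, function(R) .nodal_rmsd(M, R),
                                  numeric(1)))
  obs <- stat(Mf)
  null <- vapply(seq_len(n_perm), function(b) {
    perm <- sample(shared)
    Mp <- Mf
    dimnames(Mp) <- list(perm, perm)
    stat(Mp[shared, shared])
  }, numeric(1))
  mu <- mean(null); sdv <- stats::sd(null)
  p <- stats::pnorm(obs, mean = mu, sd = max(sdv, 1e-12))
  p <- min(max(p, .Machine$double.xmin), 1 - 1e-16)
  structure(list(rmsd = obs, null_mean = mu, null_sd = sdv, p_value = p,
                 p_exact = (1 + sum(null <= obs)) / (n_perm + 1),
                 n_permutations = n_perm),
            class = "discordance_report")
}

#' @export
print.discordance_report <- function(x, ...) {
  cat(sprintf("nodal RMSD %.3f vs null %.3f +/- %.3f (normal p = %.3g, exact p = %.3g, %d permutations)\n",
              x$rmsd, x$null_mean, x$null_sd, x$p_value, x$p_exact,
              x$n_permutations))
  invisible(x)
}
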