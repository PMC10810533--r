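# Small helpers over ape "phylo" trees shared by the Dollo, reconciliation
# and selection modules. Node numbering follows ape: tips 1..n, root n+1.

tree_children <- function(tree) {
  n_node <- ape::Ntip(tree) + tree$Nnode
  ch <- vector("list", n_node)
  for (i in seq_len(nrow(tree$edge))) {
    p <- tree$edge[i, 1]
    ch[[p]] <- c(ch[[p]], tree$edge[i, 2])
  }
  ch
}

tree_root <- function(tree) ape::Ntip(tree) + 1L

# logical matrix [node, tip]: tip descends from node (a node descends from itself)
node_leafsets <- function(tree) {
  ntip <- ape::Ntip(tree)
  n_node <- ntip + tree$Nnode
  m <- matrix(FALSE, n_node, ntip)
  m[cbind(seq_len(ntip), seq_len(ntip))] <- TRUE
  edges <- tree$edge[order(node_depths(tree)[tree$edge[, 2]], decreasing = TRUE), , drop = FALSE]
  for (i in seq_len(nrow(edges))) {
    m[edges[i, 1], ] <- m[edges[i, 1], ] | m[edges[i, 2], ]
  }
  m
}

# depth in edges from the root (root = 0)
node_depths <- function(tree) {
  n_node <- ape::Ntip(tree) + tree$Nnode
  d <- rep(NA_integer_, n_node)
  d[tree_root(tree)] <- 0L
  edges <- tree$edge
  repeat {
    todo <- is.na(d[edges[, 2]]) & !is.na(d[edges[, 1]])
    if (!any(todo)) break
    d[edges[todo, 2]] <- d[edges[todo, 1]] + 1L
  }
  d
}

# human-readable id per node: tip label, node label, or n<number>
node_ids <- function(tree) {
  ntip <- ape::Ntip(tree)
  ids <- c(tree$tip.label, rep(NA_character_, tree$Nnode))
  inner <- ntip + seq_len(tree$Nnode)
  if (!is.null(tree$node.label) && length(tree$node.label) == tree$Nnode &&
      !anyNA(tree$node.label) && all(nzchar(tree$node.label))) {
    ids[inner] <- tree$node.label
  } else {
    ids[inner] <- paste0("n", inner)
  }
  ids
}

# MRCA of a set of tips given the leafset matrix (deepest node covering all)
mrca_from_leafsets <- function(leafsets, depths, tip_idx) {
  if (length(tip_idx) == 1L) return(tip_idx)
  cover <- which(rowSums(leafsets[, tip_idx, drop = FALSE]) == length(tip_idx))
  cover[which.max(depths[cover])]
}

is_ancestor_matrix <- function(tree) {
  # anc[a, b]: a is ancestor-or-equal of b
  ls <- node_leafsets(tree)
  n <- nrow(ls)
  anc <- matrix(FALSE, n, n)
  for (a in seq_len(n)) {
    for (b in seq_len(n)) {
      anc[a, b] <- all(ls[b, ] <= ls[a, ])
    }
  }
  diag(anc) <- TRUE
  anc
}
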