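#' LCA reconciliation of a gene tree against a rooted species tree
#'
#' Maps every gene-tree node to the lowest common ancestor (LCA) of its
#' descendants' species. An internal gene-tree node is a duplication when
#' its mapping coincides with the mapping of at least one child, otherwise a
#' speciation; this mapping minimises the number of duplications over all
#' valid reconciliations. Input gene-tree topologies are taken as given (no
#' topology search). Losses are counted internally with the standard
#' depth-difference formula but excluded from default reports, because
#' transcriptome-dominated datasets grossly overestimate absence.
#'
#' @param gene_tree rooted `phylo`; if unrooted, rooted by midpoint
#'   (`root_method = "midpoint"`, the default for unrooted input) or by
#'   `outgroup`.
#' @param species_tree rooted `phylo`.
#' @param leaf_species optional named character vector mapping gene-tree tip
#'   labels to species-tree tip labels. By default a tip label is used
#'   directly if it is a species label, else the part before the last `"@"`
#'   (the simulator emits `taxon@copy` labels).
#' @param root_method one of `"asis"`, `"midpoint"`, `"outgroup"`.
#' @param outgroup tip label(s) for `root_method = "outgroup"`.
#' @return list of class `reconciliation`: `map` (data.frame `gene_node`,
#'   `species_node`, `species_id`, `event` in leaf/speciation/duplication),
#'   `n_duplications`, `n_speciations`, `n_losses`, `branch_events`
#'   (per species branch: duplications, speciations).
#' @export
reconcile_gene_tree <- function(gene_tree, species_tree, leaf_species = NULL,
                                root_method = c("asis", "midpoint", "outgroup"),
                                outgroup = NULL) {
  root_method <- match.arg(root_method)
  if (!ape::is.rooted(gene_tree) && root_method == "asis") root_method <- "midpoint"
  if (root_method == "midpoint" && !ape::is.rooted(gene_tree)) {
    gene_tree <- midpoint_root(gene_tree)
  } else if (root_method == "outgroup") {
    gene_tree <- ape::root(gene_tree, outgroup = outgroup, resolve.root = TRUE)
  }

  sp_labels <- species_tree$tip.label
  map_leaf <- function(lab) {
    if (!is.null(leaf_species) && lab %in% names(leaf_species)) return(leaf_species[[lab]])
    if (lab %in% sp_labels) return(lab)
    stripped <- sub("@[^@]*$", "", lab)
    if (stripped %in% sp_labels) return(stripped)
    stop("gene-tree leaf '", lab, "' cannot be mapped to a species")
  }
  leaf_sp <- vapply(gene_tree$tip.label, map_leaf, character(1))

  s_ls <- node_leafsets(species_tree)
  s_depth <- node_depths(species_tree)
  s_ids <- node_ids(species_tree)
  s_root <- tree_root(species_tree)
  lca2 <- function(a, b) {
    need <- s_ls[a, ] | s_ls[b, ]
    cover <- which(apply(s_ls, 1, function(r) all(r >= need)))
    cover[which.max(s_depth[cover])]
  }

  g_ntip <- ape::Ntip(gene_tree)
  g_nnode <- g_ntip + gene_tree$Nnode
  children <- tree_children(gene_tree)
  M <- rep(NA_integer_, g_nnode)
  M[seq_len(g_ntip)] <- match(leaf_sp, sp_labels)
  event <- rep(NA_character_, g_nnode)
  event[seq_len(g_ntip)] <- "leaf"

  ord <- order(node_depths(gene_tree), decreasing = TRUE)
  for (v in ord) {
    ch <- children[[v]]
    if (is.null(ch)) next
    m <- M[ch[1]]
    for (c2 in ch[-1]) m <- lca2(m, M[c2])
    M[v] <- m
    event[v] <- if (any(M[ch] == m)) "duplication" else "speciation"
  }

  # losses: depth(M(child)) - depth(M(v)) - 1 per child at speciations,
  # depth difference alone at duplications
  losses <- 0L
  for (v in which(event %in% c("speciation", "duplication"))) {
    for (c in children[[v]]) {
      d <- s_depth[M[c]] - s_depth[M[v]]
      losses <- losses + d - as.integer(event[v] == "speciation")
    }
  }

  map <- data.frame(gene_node = seq_len(g_nnode), species_node = M,
                    species_id = s_ids[M], event = event,
                    stringsAsFactors = FALSE)
  s_nodes <- seq_len(ape::Ntip(species_tree) + species_tree$Nnode)
  branch_events <- data.frame(
    branch = ifelse(s_nodes == s_root, "root", s_ids[s_nodes]),
    node = s_nodes,
    duplications = tabulate(M[event == "duplication"], nbins = length(s_nodes)),
    speciations = tabulate(M[event == "speciation"], nbins = length(s_nodes)),
    stringsAsFactors = FALSE)
  structure(list(map = map,
                 n_duplications = sum(event == "duplication", na.rm = TRUE),
                 n_speciations = sum(event == "speciation", na.rm = TRUE),
                 n_losses = losses,
                 branch_events = branch_events),
            class = "reconciliation")
}

#' @export
print.reconciliation <- function(x, ...) {
  cat("LCA reconciliation:", x$n_duplications, "duplications,",
      x$n_speciations, "speciations,", x$n_losses, "losses (not reported)\n")
  invisible(x)
}

midpoint_root <- function(tree) {
  phangorn::midpoint(tree)
}

#' Write a Newick tree with comment-style per-branch event annotations
#'
#' Attaches `[&gains=..,duplications=..,speciations=..]` comments to each
#' branch (keyed by child node id) so annotated trees can be viewed in tree
#' viewers that understand NHX-style comments.
#'
#' @param tree rooted `phylo` whose node ids match `events$branch`.
#' @param events data.frame with `branch` (child node id) and one or more
#'   numeric columns (e.g. `gains`, `duplications`, `speciations`).
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_annotated_tree <- function(tree, events, path) {
  ids <- node_ids(tree)
  num_cols <- setdiff(names(events), c("branch", "node"))
  ann <- vapply(seq_len(ape::Ntip(tree) + tree$Nnode), function(n) {
    row <- events[events$branch == ids[n], , drop = FALSE]
    if (nrow(row) == 0) return("")
    paste0("[&", paste(sprintf("%s=%g", num_cols,
                               as.numeric(row[1, num_cols])),
                       collapse = ","), "]")
  }, character(1))
  children <- tree_children(tree)
  lens <- rep(NA_real_, length(ids))
  lens[tree$edge[, 2]] <- tree$edge.length
  nwk <- function(n) {
    lab <- if (n <= ape::Ntip(tree)) tree$tip.label[n] else ""
    body <- if (is.null(children[[n]])) lab else {
      paste0("(", paste(vapply(children[[n]], nwk, character(1)),
                        collapse = ","), ")", lab)
    }
    if (is.na(lens[n])) body
    else sprintf("%s:%g%s", body, lens[n], ann[n])
  }
  writeLines(paste0(nwk(tree_root(tree)), ";"), path)
  invisible(path)
}
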