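#' Dollo-parsimony dating of gene-family births
#'
#' Under Dollo parsimony a gene family is gained exactly once and may be
#' lost any number of times, which suits presence/absence data dominated by
#' transcriptomes where absences are unreliable. The birth node of a family
#' is then the MRCA of the taxa possessing it; the gain is assigned to the
#' branch subtending that node (gains at the root are reported on a
#' synthetic root branch).
#'
#' @param pm a [presence_matrix()] or a binary matrix (families x taxa).
#' @param tree rooted species tree (`phylo`); tip labels must cover the
#'   matrix's taxa.
#' @return list: `births` (data.frame `family_id`, `birth_node` (ape node
#'   number), `birth_id`, `n_present`), `branch_gains` (data.frame
#'   `branch` = child-node id, `node`, `gains`), with root gains under
#'   branch id `"root"`. Families with zero presence are skipped with a
#'   warning.
#' @export
dollo_gain_map <- function(pm, tree) {
  mat <- if (inherits(pm, "presence_matrix")) pm$presence else pm
  missing_taxa <- setdiff(colnames(mat), tree$tip.label)
  if (length(missing_taxa)) {
    stop("taxa absent from species tree: ", paste(missing_taxa, collapse = ", "))
  }
  ls <- node_leafsets(tree)
  depths <- node_depths(tree)
  ids <- node_ids(tree)
  root <- tree_root(tree)

  empty <- rowSums(mat) == 0
  if (any(empty)) {
    warning("skipping ", sum(empty), " famil",
            ifelse(sum(empty) == 1, "y", "ies"), " with zero presence")
  }
  fams <- rownames(mat)[!empty]
  births <- do.call(rbind, lapply(fams, function(f) {
    tips <- match(colnames(mat)[mat[f, ] > 0], tree$tip.label)
    bn <- mrca_from_leafsets(ls, depths, tips)
    data.frame(family_id = f, birth_node = bn, birth_id = ids[bn],
               n_present = length(tips), stringsAsFactors = FALSE)
  }))
  if (is.null(births)) {
    births <- data.frame(family_id = character(), birth_node = integer(),
                         birth_id = character(), n_present = integer())
  }

  nodes <- c(seq_len(ape::Ntip(tree) + tree$Nnode))
  gains <- tabulate(births$birth_node, nbins = length(nodes))
  branch_gains <- data.frame(
    branch = ifelse(nodes == root, "root", ids[nodes]),
    node = nodes, gains = gains, stringsAsFactors = FALSE)
  list(births = births, branch_gains = branch_gains)
}

#' Minimal number of losses explaining a presence pattern under Dollo
#'
#' Given the birth node, the minimal loss count is the number of maximal
#' subtrees below the birth node containing no present taxon: each such
#' subtree is explained by one loss on its stem branch. Computed as a
#' diagnostic; losses are excluded from default reports because
#' transcriptome sampling inflates apparent absence.
#'
#' @param presence named binary vector over tip labels (or subset; missing
#'   tips count as absent).
#' @param tree rooted species tree (`phylo`).
#' @param birth_node ape node number; must be ancestral to (or equal to)
#'   every present tip.
#' @return integer loss count.
#' @export
dollo_loss_count <- function(presence, tree, birth_node) {
  ntip <- ape::Ntip(tree)
  pres <- rep(FALSE, ntip)
  names(pres) <- tree$tip.label
  pres[intersect(names(presence)[presence > 0], tree$tip.label)] <- TRUE
  ls <- node_leafsets(tree)
  if (!all(ls[birth_node, ] >= pres)) {
    stop("birth_node is not ancestral to every present tip")
  }
  # nodes below (or equal to) the birth node
  below <- which(apply(ls, 1, function(r) all(r <= ls[birth_node, ])))
  alive <- rowSums(ls[, pres, drop = FALSE]) > 0   # subtree holds a present tip
  losses <- 0L
  for (i in seq_len(nrow(tree$edge))) {
    p <- tree$edge[i, 1]; ch <- tree$edge[i, 2]
    if (!(ch %in% below) || ch == birth_node) next
    if (!alive[ch] && (alive[p] || p == birth_node)) losses <- losses + 1L
  }
  losses
}
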