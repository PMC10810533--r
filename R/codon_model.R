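# Codon-model machinery shared by the selection tests and the simulator.
#
# The substitution process is an MG94/GTR-style Markov model on the sense
# codons of the active genetic code: only single-nucleotide codon changes
# have nonzero rate, each weighted by a GTR exchangeability for the
# nucleotide pair, the equilibrium frequency of the target codon, and omega
# for nonsynonymous changes. Branch-site variation in omega is modelled as
# a random effect: every branch x site draws omega independently from the
# discrete distribution attached to the branch's group, so the per-branch
# transition matrix is the weighted mixture over categories.

.codon_structure_cache <- new.env(parent = emptyenv())

# Transition structure of a genetic code: sense codons and the list of
# single-nucleotide changes with their GTR pair index and synonymy.
codon_model_structure <- function(code) {
  code <- genetic_code(code)
  key <- code$id
  if (!is.null(.codon_structure_cache[[key]])) return(.codon_structure_cache[[key]])
  sense <- code$sense_codons
  S <- length(sense)
  nt <- c("A", "C", "G", "T")
  pair_names <- c("AC", "AG", "AT", "CG", "CT", "GT")
  splits <- strsplit(sense, "")
  tr <- list(i = integer(), j = integer(), pair = integer(), nonsyn = integer())
  for (i in seq_len(S)) {
    ci <- splits[[i]]
    for (pos in 1:3) {
      for (b in nt) {
        if (b == ci[pos]) next
        cj <- ci; cj[pos] <- b
        codj <- paste(cj, collapse = "")
        j <- match(codj, sense)
        if (is.na(j)) next   # change into a stop codon: rate 0
        pr <- match(paste(sort(c(ci[pos], b)), collapse = ""), pair_names)
        tr$i <- c(tr$i, i); tr$j <- c(tr$j, j); tr$pair <- c(tr$pair, pr)
        tr$nonsyn <- c(tr$nonsyn, as.integer(code$map[sense[i]] != code$map[codj]))
      }
    }
  }
  out <- list(code = code, sense = sense, S = S,
              tr_i = tr$i - 1L, tr_j = tr$j - 1L, tr_pair = tr$pair - 1L,
              tr_nonsyn = tr$nonsyn)
  .codon_structure_cache[[key]] <- out
  out
}

#' Build a codon alignment object from aligned CDS strings
#'
#' @param seqs named character vector of equal-length, in-frame aligned
#'   nucleotide sequences (no internal stops; `---` or ambiguous codons
#'   become missing states).
#' @param code a [genetic_code()] or id.
#' @return object of class `codon_alignment`: integer matrix `states`
#'   (nsites x ntaxa, 1-based sense-codon index, `NA` = missing), `code`.
#' @export
codon_alignment <- function(seqs, code = 1) {
  code <- genetic_code(code)
  if (is.null(names(seqs)) || any(!nzchar(names(seqs)))) stop("sequences must be named")
  w <- unique(nchar(seqs))
  if (length(w) != 1L) stop("aligned sequences must have equal length")
  if (w %% 3L != 0L) stop("alignment length not divisible by 3")
  nsites <- w %/% 3L
  states <- matrix(NA_integer_, nsites, length(seqs),
                   dimnames = list(NULL, names(seqs)))
  for (t in seq_along(seqs)) {
    s <- toupper(seqs[[t]])
    cods <- substring(s, 3L * seq_len(nsites) - 2L, 3L * seq_len(nsites))
    if (any(cods %in% code$stop_codons)) {
      stop("internal stop codon in sequence '", names(seqs)[t], "'")
    }
    states[, t] <- match(cods, code$sense_codons)   # NA for gaps/ambiguity
  }
  structure(list(states = states, code = code, n_sites = nsites), class = "codon_alignment")
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat("codon_alignment:", ncol(x$states), "sequences x", x$n_sites,
      "codons (code", x$code$id, ")\n")
  invisible(x)
}

#' F3x4 equilibrium codon frequencies from an alignment
#'
#' Positional nucleotide frequencies (3 x 4, with a small pseudocount) are
#' multiplied across codon positions, stop codons excluded and the result
#' renormalised over the sense codons of the code.
#'
#' @param aln a [codon_alignment()].
#' @return numeric vector over sense codons summing to 1.
#' @export
f3x4_frequencies <- function(aln) {
  stopifnot(inherits(aln, "codon_alignment"))
  code <- aln$code
  sense <- code$sense_codons
  obs <- sense[aln$states[!is.na(aln$states)]]
  nt <- c("A", "C", "G", "T")
  posfreq <- matrix(1 / 4, 3, 4, dimnames = list(NULL, nt))
  if (length(obs)) {
    for (p in 1:3) {
      cnt <- table(factor(substr(obs, p, p), levels = nt)) + 0.5
      posfreq[p, ] <- as.numeric(cnt / sum(cnt))
    }
  }
  pi <- vapply(sense, function(cod) {
    b <- strsplit(cod, "")[[1]]
    posfreq[1, b[1]] * posfreq[2, b[2]] * posfreq[3, b[3]]
  }, numeric(1))
  pi / sum(pi)
}

# effective omega distribution after applying the RELAX intensity exponent
apply_k <- function(dist, k) {
  om <- pmin(dist$omega^k, 1e4)
  list(omega = om, weight = dist$weight)
}

# Resolve per-edge distribution ids for the likelihood core.
# groups: named list label -> list(omega, weight); edge_labels: character per
# tree edge row. Returns list(dists, edge_dist).
resolve_edge_dists <- function(groups, edge_labels) {
  labs <- unique(edge_labels)
  missing <- setdiff(labs, names(groups))
  if (length(missing)) stop("no omega distribution for group(s): ",
                            paste(missing, collapse = ", "))
  dists <- groups[labs]
  list(dists = unname(dists), edge_dist = match(edge_labels, labs))
}

# edges ordered so every child is complete before its parent edge is used
postorder_edges <- function(tree) {
  order(node_depths(tree)[tree$edge[, 2]], decreasing = TRUE)
}

#' Codon-model log-likelihood by pruning
#'
#' Computes the phylogenetic log-likelihood of a codon alignment under the
#' branch-site random-effects model: each branch carries the discrete omega
#' distribution of its group (already transformed by any intensity
#' parameter), and per-branch transition matrices are category mixtures.
#' Branch lengths are read from the tree and interpreted as expected
#' substitutions per codon at neutrality.
#'
#' @param aln a [codon_alignment()].
#' @param tree rooted `phylo` with branch lengths; tip labels must match
#'   alignment names.
#' @param pi equilibrium frequencies over sense codons.
#' @param rho GTR nucleotide exchangeabilities (AC, AG, AT, CG, CT, GT);
#'   the last is conventionally fixed to 1.
#' @param groups named list: label -> `list(omega =, weight =)`.
#' @param edge_labels character vector over `tree$edge` rows naming each
#'   branch's group; defaults to a single shared group when `groups` has
#'   length 1.
#' @return numeric log-likelihood with attribute `site_loglik`.
#' @export
codon_likelihood <- function(aln, tree, pi, rho, groups, edge_labels = NULL) {
  stopifnot(inherits(aln, "codon_alignment"))
  st <- codon_model_structure(aln$code)
  if (length(pi) != st$S) stop("pi must have one entry per sense codon (", st$S, ")")
  mismatch <- setdiff(tree$tip.label, colnames(aln$states))
  if (length(mismatch)) stop("alignment missing sequences for: ",
                             paste(mismatch, collapse = ", "))
  if (is.null(edge_labels)) {
    if (length(groups) != 1L) stop("edge_labels required with multiple groups")
    edge_labels <- rep(names(groups), nrow(tree$edge))
  }
  if (length(edge_labels) != nrow(tree$edge)) stop("edge_labels/edge mismatch")
  for (g in groups) {
    if (any(g$omega < 0)) stop("omega category values must be >= 0")
    if (abs(sum(g$weight) - 1) > 1e-8 || any(g$weight < 0)) {
      stop("omega category weights must be nonnegative and sum to 1")
    }
  }
  ord <- postorder_edges(tree)
  rd <- resolve_edge_dists(groups, edge_labels)
  tips <- t(aln$states[, tree$tip.label, drop = FALSE])   # ntips x nsites
  tips[is.na(tips)] <- 0L
  tips <- tips - 1L                                        # 0-based; NA -> -1
  res <- cpp_codon_loglik(tips, tree$edge[ord, , drop = FALSE],
                          ape::Ntip(tree) + tree$Nnode,
                          tree$edge.length[ord], rd$edge_dist[ord], rd$dists,
                          pi, rho, st$tr_i, st$tr_j, st$tr_pair, st$tr_nonsyn)
  structure(res$loglik, site_loglik = res$site_loglik)
}

# Transition matrix for one omega and branch length (used by the simulator
# and by oracle tests).
codon_pmatrix <- function(code, pi, rho, omega, t) {
  st <- codon_model_structure(code)
  cpp_pmatrix(pi, rho, st$tr_i, st$tr_j, st$tr_pair, st$tr_nonsyn, omega, t)
}

#' Simulate a codon alignment along a labelled tree
#'
#' Sites evolve independently; each branch x site pair draws an omega
#' category from the branch group's distribution (after applying any
#' intensity exponent upstream). The root sequence is drawn from `pi`.
#' Stop codons cannot be generated: the state space is the sense codons.
#'
#' @param tree rooted `phylo` with branch lengths.
#' @param pi,rho,groups,edge_labels as in [codon_likelihood()].
#' @param n_codons number of codon sites.
#' @param seed integer seed (local to this call).
#' @param code a [genetic_code()] or id.
#' @return named character vector of CDS strings (tips of the tree).
#' @export
simulate_codon_alignment <- function(tree, pi, rho, groups, edge_labels,
                                     n_codons, seed = 1, code = 1) {
  code <- genetic_code(code)
  st <- codon_model_structure(code)
  if (any(tree$edge.length < 0)) stop("negative branch length")
  if (n_codons < 1) stop("n_codons must be >= 1")
  withr::with_seed(seed, {
    n_nodes <- ape::Ntip(tree) + tree$Nnode
    states <- matrix(NA_integer_, n_nodes, n_codons)
    root <- tree_root(tree)
    states[root, ] <- sample.int(st$S, n_codons, replace = TRUE, prob = pi)
    ord <- order(node_depths(tree)[tree$edge[, 2]])   # preorder: shallow first
    pcache <- new.env(parent = emptyenv())
    for (e in ord) {
      p <- tree$edge[e, 1]; c <- tree$edge[e, 2]
      g <- groups[[edge_labels[e]]]
      if (any(g$omega < 0)) stop("omega category values must be >= 0")
      t_e <- tree$edge.length[e]
      ncat <- length(g$omega)
      Ps <- lapply(seq_len(ncat), function(k) {
        key <- sprintf("%.12g_%.12g", g$omega[k], t_e)
        if (is.null(pcache[[key]])) {
          pcache[[key]] <- cpp_pmatrix(pi, rho, st$tr_i, st$tr_j, st$tr_pair,
                                       st$tr_nonsyn, g$omega[k], t_e)
        }
        pcache[[key]]
      })
      cat_draw <- sample.int(ncat, n_codons, replace = TRUE, prob = g$weight)
      cur <- states[p, ]
      nxt <- integer(n_codons)
      for (s in seq_len(n_codons)) {
        nxt[s] <- sample.int(st$S, 1L, prob = Ps[[cat_draw[s]]][cur[s], ])
      }
      states[c, ] <- nxt
    }
    tips <- seq_len(ape::Ntip(tree))
    out <- vapply(tips, function(i) {
      paste(st$sense[states[i, ]], collapse = "")
    }, character(1))
    names(out) <- tree$tip.label
    out
  })
}

#' Estimate branch lengths and a shared omega by maximum likelihood
#'
#' First-stage fit used before the group-level selection tests: a single
#' shared 1-category omega distribution, branch lengths free on the log
#' scale. Intended for modest trees; the selection tests then hold these
#' lengths fixed.
#'
#' @param aln a [codon_alignment()].
#' @param tree rooted `phylo`; `edge.length` used as the starting point
#'   (missing lengths start at 0.1).
#' @param pi,rho as in [codon_likelihood()].
#' @param maxit optimizer iteration budget.
#' @return list: `tree` (lengths replaced by estimates), `omega`, `loglik`.
#' @export
estimate_branch_lengths <- function(aln, tree, pi = NULL, rho = rep(1, 6),
                                    maxit = 200) {
  if (is.null(pi)) pi <- f3x4_frequencies(aln)
  bl0 <- tree$edge.length
  if (is.null(bl0)) bl0 <- rep(0.1, nrow(tree$edge))
  bl0 <- pmax(bl0, 1e-4)
  obj <- function(par) {
    tr <- tree
    tr$edge.length <- exp(par[-1])
    g <- list(all = list(omega = exp(par[1]), weight = 1))
    -codon_likelihood(aln, tr, pi, rho, g)
  }
  fit <- stats::optim(c(log(0.3), log(bl0)), obj, method = "L-BFGS-B",
                      lower = c(log(1e-4), rep(log(1e-6), length(bl0))),
                      upper = c(log(50), rep(log(20), length(bl0))),
                      control = list(maxit = maxit))
  tree$edge.length <- exp(fit$par[-1])
  list(tree = tree, omega = exp(fit$par[1]), loglik = -fit$value)
}
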