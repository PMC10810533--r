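# Independent brute-force oracles and small fixture builders. These are
# deliberately naive re-derivations of each operation's definition; they
# share no code path with the package implementations they check.

random_transcript <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# ---- exhaustive ORF scanner ---------------------------------------------
# enumerate every (frame, ATG, next-stop) triple and pick the maximum with
# the documented tie-breaks
brute_force_orf <- function(transcript, code, min_aa, complete_only = TRUE) {
  code <- genetic_code(code)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(transcript)))
  n <- nchar(transcript)
  best <- NULL
  frame_defs <- list(c("+1", 0, FALSE), c("+2", 1, FALSE), c("+3", 2, FALSE),
                     c("-1", 0, TRUE), c("-2", 1, TRUE), c("-3", 2, TRUE))
  for (fr in seq_along(frame_defs)) {
    off <- as.integer(frame_defs[[fr]][2])
    seqi <- if (as.logical(frame_defs[[fr]][3])) rc else transcript
    ncod <- (n - off) %/% 3
    if (ncod < 1) next
    starts <- off + 1 + 3 * (seq_len(ncod) - 1)
    cods <- substring(seqi, starts, starts + 2)
    stops <- which(cods %in% code$stop_codons)
    atgs <- which(cods == "ATG")
    for (a in atgs) {
      nxt <- stops[stops > a]
      if (!length(nxt)) {
        if (complete_only) next
        end_c <- ncod; has_stop <- FALSE
      } else {
        end_c <- nxt[1] - 1; has_stop <- TRUE
      }
      # valid only if no stop between a and end (guaranteed by construction)
      # and, per the "first ATG after a stop" rule, no earlier ATG in the
      # same stop-delimited segment
      seg_start <- if (any(stops < a)) max(stops[stops < a]) + 1 else 1
      if (any(atgs >= seg_start & atgs < a)) next
      len <- end_c - a + 1
      if (len < min_aa) next
      cand <- list(len = len, frame = fr, start_nt = starts[a])
      if (is.null(best) ||
          cand$len > best$len ||
          (cand$len == best$len && cand$frame < best$frame) ||
          (cand$len == best$len && cand$frame == best$frame &&
           cand$start_nt < best$start_nt)) {
        cand$cds <- substr(seqi, starts[a], starts[end_c] + 2)
        best <- cand
      }
    }
  }
  best
}

# ---- Dollo: exhaustive single-gain / multi-loss minimisation -------------
# losses by exhaustive subset search over loss-branch roots; leaf sets are
# held as bitmasks and subset unions built by dynamic programming so trees
# up to 8 leaves enumerate in milliseconds
dollo_oracle_subsets <- function(tree, presence) {
  ls <- lsgfevo:::node_leafsets(tree)
  ntip <- ape::Ntip(tree)
  pres <- rep(FALSE, ntip); names(pres) <- tree$tip.label
  pres[names(presence)[presence > 0]] <- TRUE
  leafmask <- apply(ls, 1, function(r) sum(2^(which(r) - 1)))
  pres_mask <- sum(2^(which(pres) - 1))
  valid_births <- which(apply(ls, 1, function(r) all(r >= pres)))
  best <- NULL
  for (b in valid_births) {
    below <- setdiff(which(bitwAnd(leafmask, leafmask[b]) == leafmask), b)
    absent_mask <- bitwAnd(leafmask[b], bitwNot(pres_mask))
    if (absent_mask == 0) {
      sc <- list(birth = b, losses = 0L)
    } else {
      m <- length(below)
      union_mask <- integer(2^m); popcnt <- integer(2^m)
      min_l <- Inf
      for (mask in seq_len(2^m - 1)) {
        low <- bitwAnd(mask, -mask)           # lowest set bit
        i <- as.integer(log2(low)) + 1L
        rest <- mask - low
        union_mask[mask + 1] <- bitwOr(union_mask[rest + 1], leafmask[below[i]])
        popcnt[mask + 1] <- popcnt[rest + 1] + 1L
        if (union_mask[mask + 1] == absent_mask && popcnt[mask + 1] < min_l) {
          min_l <- popcnt[mask + 1]
        }
      }
      sc <- list(birth = b, losses = as.integer(min_l))
    }
    if (is.null(best) || sc$losses < best$losses) best <- sc
  }
  best
}

# ---- reconciliation: brute-force duplication minimiser -------------------
reconcile_dup_oracle <- function(gene_tree, species_tree) {
  s_ls <- lsgfevo:::node_leafsets(species_tree)
  s_n <- nrow(s_ls)
  anc <- matrix(FALSE, s_n, s_n)   # anc[a,b]: a ancestor-or-equal of b
  for (a in seq_len(s_n)) for (b in seq_len(s_n)) {
    anc[a, b] <- all(s_ls[b, ] <= s_ls[a, ])
  }
  children_s <- lsgfevo:::tree_children(species_tree)
  g_ntip <- ape::Ntip(gene_tree)
  g_children <- lsgfevo:::tree_children(gene_tree)
  leafsp <- match(sub("@[^@]*$", "", gene_tree$tip.label), species_tree$tip.label)
  internal <- (g_ntip + 1):(g_ntip + gene_tree$Nnode)
  # depth-sorted so children assignments exist when a parent is scored
  count_dups <- function(M) {
    dups <- 0L
    for (v in internal) {
      ch <- g_children[[v]]
      mv <- M[v]; mc <- M[ch]
      if (!all(anc[mv, mc])) return(NA_integer_)
      if (any(mc == mv)) { dups <- dups + 1L; next }
      # speciation requires the children to fall into distinct child
      # subtrees of M(v); otherwise the node must be a duplication
      subs <- vapply(mc, function(m) {
        which(vapply(children_s[[mv]], function(cs) anc[cs, m], logical(1)))[1]
      }, integer(1))
      if (anyNA(subs) || length(unique(subs)) < length(subs)) dups <- dups + 1L
    }
    dups
  }
  M <- integer(g_ntip + gene_tree$Nnode)
  M[seq_len(g_ntip)] <- leafsp
  grids <- rep(list(seq_len(s_n)), length(internal))
  best <- Inf
  rec <- function(i) {
    if (i > length(internal)) {
      d <- count_dups(M)
      if (!is.na(d) && d < best) best <<- d
      return(invisible())
    }
    for (m in seq_len(s_n)) {
      M[internal[i]] <<- m
      rec(i + 1)
    }
  }
  rec(1)
  as.integer(best)
}

# ---- likelihood: ancestral-state x category-tuple summation --------------
# full enumeration for a 3-taxon rooted tree ((A,B),C) with branch order
# (inner->A, inner->B, root->inner, root->C)
loglik_oracle_3taxon <- function(states, pi, Pk, w) {
  S <- length(pi); ncat <- length(w)
  total <- 0
  sapply(seq_len(nrow(states)), function(s) {
    a <- states[s, 1]; b <- states[s, 2]; cc <- states[s, 3]
    tot <- 0
    for (k1 in seq_len(ncat)) for (k2 in seq_len(ncat))
      for (k3 in seq_len(ncat)) for (k4 in seq_len(ncat)) {
        m <- 0
        for (r in seq_len(S)) for (x in seq_len(S)) {
          m <- m + pi[r] * Pk[[k3]][[3]][r, x] * Pk[[k1]][[1]][x, a] *
            Pk[[k2]][[2]][x, b] * Pk[[k4]][[4]][r, cc]
        }
        tot <- tot + w[k1] * w[k2] * w[k3] * w[k4] * m
      }
    log(tot)
  })
}

# generic fixed-category-tuple summation: enumerate the omega category of
# every branch, compute each tuple's likelihood with plain per-branch
# conditional sums, and mix. Independent of the mixture-collapse shortcut.
loglik_oracle_tuples <- function(aln, tree, pi, rho, dist, code) {
  ncat <- length(dist$omega)
  ne <- nrow(tree$edge)
  Pk <- lapply(seq_len(ncat), function(k) {
    lapply(seq_len(ne), function(e) {
      lsgfevo:::codon_pmatrix(code, pi, rho, dist$omega[k], tree$edge.length[e])
    })
  })
  states <- aln$states[, tree$tip.label, drop = FALSE]
  ntip <- ape::Ntip(tree)
  children <- lsgfevo:::tree_children(tree)
  edge_of_child <- integer(ntip + tree$Nnode)
  edge_of_child[tree$edge[, 2]] <- seq_len(ne)
  tuples <- as.matrix(expand.grid(rep(list(seq_len(ncat)), ne)))
  site_lik <- matrix(0, nrow(states), 1)
  for (ti in seq_len(nrow(tuples))) {
    tu <- tuples[ti, ]
    wt <- prod(dist$weight[tu])
    cond <- function(node, s) {
      if (node <= ntip) {
        v <- numeric(length(pi)); v[states[s, node]] <- 1
        return(v)
      }
      out <- rep(1, length(pi))
      for (ch in children[[node]]) {
        e <- edge_of_child[ch]
        out <- out * as.numeric(Pk[[tu[e]]][[e]] %*% cond(ch, s))
      }
      out
    }
    for (s in seq_len(nrow(states))) {
      site_lik[s] <- site_lik[s] + wt * sum(pi * cond(ntip + 1, s))
    }
  }
  sum(log(site_lik))
}

# random rooted tree with taxon labels and positive branch lengths
random_rooted_tree <- function(ntips, labels = NULL) {
  tr <- ape::rtree(ntips, rooted = TRUE)
  if (!is.null(labels)) tr$tip.label <- labels
  tr$edge.length <- pmax(tr$edge.length, 0.02)
  tr
}

# small taxon table builder
toy_taxa <- function(taxa, genus = NULL, category = NULL, is_ciliate = TRUE) {
  data.frame(taxon = taxa,
             genus = if (is.null(genus)) paste0("g", seq_along(taxa)) else genus,
             class = paste0("cl", seq_along(taxa)),
             category = if (is.null(category)) rep("EF", length(taxa)) else category,
             is_ciliate = is_ciliate,
             stringsAsFactors = FALSE)
}

# total branch length from the root to each node (in tree length units)
node_depth_lengths <- function(tree) {
  n <- ape::Ntip(tree) + tree$Nnode
  d <- rep(0, n)
  ord <- order(lsgfevo:::node_depths(tree)[tree$edge[, 2]])
  for (e in ord) d[tree$edge[e, 2]] <- d[tree$edge[e, 1]] + tree$edge.length[e]
  d
}
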