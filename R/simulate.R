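# Synthetic-data generator: species trees with genome-architecture
# categories, gene-family birth/loss/duplication histories, codon alignments
# evolved under group-specific selection regimes, and transcriptome-like
# FASTA inputs with recorded ground truth for every downstream stage.

#' Simulation configuration
#'
#' Bundles every tunable of the generator. Defaults emulate a ciliate-like
#' study: strongly GC-skewed third codon positions (target GC3s 0.70)
#' against low-GC contaminants (0.25), the ciliate genetic code (table 6),
#' allelic variants at >= 97% identity, and gene families evolving under a
#' purifying-dominated 3-category omega distribution with group-specific
#' intensity exponents K. Event rates are per unit branch length.
#'
#' @param loss_rate,duplication_rate Poisson rates of family loss and
#'   duplication below the birth node.
#' @param omega_ref reference omega distribution: `list(omega =, weight =)`.
#' @param K named intensity exponents per category (missing entries = 1).
#' @param pi equilibrium codon frequencies; default GC3s-skewed to
#'   `gc3s_ciliate` under `code`.
#' @param rho GTR nucleotide exchangeabilities (AC, AG, AT, CG, CT, GT).
#' @param contaminant_fraction fraction of emitted ORF records that are
#'   contaminant.
#' @param allelic_variant_rate alleles emitted per genuine ORF (deterministic
#'   apportionment: `round(rate * n_genuine)` records).
#' @param gc3s_ciliate,gc3s_contaminant target GC3s of host and contaminant
#'   ORFs.
#' @param code genetic code for simulation (default 6, the ciliate code).
#' @param root_branch_length length of the synthetic branch above the root
#'   used when sampling birth positions (default: mean edge length, set when
#'   a tree is available).
#' @param seed integer master seed.
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(loss_rate = 0.3, duplication_rate = 0.3,
                              omega_ref = list(omega = c(0.05, 0.4, 1.1),
                                               weight = c(0.6, 0.3, 0.1)),
                              K = c(EF = 1, NEF = 1, HE = 1, KA = 1),
                              pi = NULL, rho = rep(1, 6),
                              contaminant_fraction = 0.1,
                              allelic_variant_rate = 0.1,
                              gc3s_ciliate = 0.70, gc3s_contaminant = 0.25,
                              code = 6, root_branch_length = NULL,
                              seed = 1) {
  stopifnot(loss_rate >= 0, duplication_rate >= 0,
            contaminant_fraction >= 0, contaminant_fraction < 1,
            allelic_variant_rate >= 0)
  if (abs(sum(omega_ref$weight) - 1) > 1e-9) stop("omega weights must sum to 1")
  if (any(omega_ref$omega < 0)) stop("omega values must be >= 0")
  code <- genetic_code(code)
  if (is.null(pi)) pi <- gc3_skewed_pi(code, gc3s_ciliate)
  if (abs(sum(pi) - 1) > 1e-9 || length(pi) != length(code$sense_codons)) {
    stop("pi must sum to 1 over the sense codons of the code")
  }
  structure(list(loss_rate = loss_rate, duplication_rate = duplication_rate,
                 omega_ref = omega_ref, K = K, pi = pi, rho = rho,
                 contaminant_fraction = contaminant_fraction,
                 allelic_variant_rate = allelic_variant_rate,
                 gc3s_ciliate = gc3s_ciliate,
                 gc3s_contaminant = gc3s_contaminant,
                 code = code, root_branch_length = root_branch_length,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

# codon frequencies with uniform first/second positions and the third
# position skewed to a target G+C fraction; stops excluded and renormalised
gc3_skewed_pi <- function(code, gc3) {
  code <- genetic_code(code)
  third <- substr(code$sense_codons, 3L, 3L)
  w <- ifelse(third %in% c("G", "C"), gc3 / 2, (1 - gc3) / 2)
  w / sum(w)
}

#' Simulate a species tree with genome-architecture categories
#'
#' Builds a rooted binary tree whose leaves carry one of the four
#' architecture categories. By default categories are assigned clade-wise -
#' each category forms a monophyletic clade arranged on the backbone
#' `((KA, HE), (NEF, EF))`, mirroring ciliate taxonomy where Karyorelictea
#' and Heterotrichea branch off before the split of non-extensive and
#' extensive fragmenters. Leaf counts per category follow the exact
#' largest-remainder apportionment of `category_scheme`. A flag allows
#' random leaf-wise assignment for stress tests.
#'
#' @param n_taxa number of leaves (>= 2).
#' @param category_scheme named proportions over categories, summing to 1.
#' @param seed integer seed.
#' @param cladewise assign categories clade-wise (default) or randomly.
#' @param mean_branch_length expected branch length in substitutions/site.
#' @return object of class `species_tree_sim`: `tree` (`phylo`, node labels
#'   `n<k>`), `categories` (named by taxon), `taxa` (metadata data.frame),
#'   `seed`.
#' @export
simulate_species_tree <- function(n_taxa,
                                  category_scheme = c(EF = 0.4, NEF = 0.35,
                                                      HE = 0.15, KA = 0.1),
                                  seed = 1, cladewise = TRUE,
                                  mean_branch_length = 0.2) {
  if (n_taxa < 2) stop("n_taxa must be >= 2")
  if (abs(sum(category_scheme) - 1) > 1e-9) stop("category proportions must sum to 1")
  counts <- apportion(category_scheme, n_taxa)
  withr::with_seed(as.integer(seed), {
    cats_present <- names(counts)[counts > 0]
    tip_names <- unlist(lapply(cats_present, function(cc) {
      sprintf("%s%02d", cc, seq_len(counts[cc]))
    }))
    categories <- unlist(lapply(cats_present, function(cc) {
      rep(cc, counts[cc])
    }))
    names(categories) <- tip_names
    if (!cladewise) {
      categories[] <- sample(categories)
    }

    rand_len <- function() stats::rexp(1, 1 / mean_branch_length) + 0.01
    join <- function(a, b) {
      sprintf("(%s:%.6f,%s:%.6f)", a, rand_len(), b, rand_len())
    }
    subtree <- function(tips) {
      nodes <- tips
      while (length(nodes) > 1) {
        i <- sample.int(length(nodes), 2)
        nodes <- c(nodes[-i], join(nodes[i[1]], nodes[i[2]]))
      }
      nodes
    }
    if (cladewise) {
      clades <- lapply(cats_present, function(cc) subtree(tip_names[categories == cc]))
      names(clades) <- cats_present
      # backbone ((KA,HE),(NEF,EF)); absent categories drop out
      pair <- function(labs) {
        labs <- labs[!vapply(labs, is.null, logical(1))]
        if (length(labs) == 0) return(NULL)
        if (length(labs) == 1) return(labs[[1]])
        join(labs[[1]], labs[[2]])
      }
      left <- pair(clades[intersect(c("KA", "HE"), names(clades))])
      right <- pair(clades[intersect(c("NEF", "EF"), names(clades))])
      nwk <- pair(list(left, right))
    } else {
      nwk <- subtree(tip_names)
    }
    tree <- ape::read.tree(text = paste0(nwk, ";"))
    tree$node.label <- paste0("n", ape::Ntip(tree) + seq_len(tree$Nnode))

    taxa <- data.frame(
      taxon = tree$tip.label,
      genus = paste0("g_", sub("\\d+$", "", tree$tip.label),
                     (as.integer(sub("^\\D+", "", tree$tip.label)) + 1L) %/% 2L),
      class = paste0("cl_", sub("\\d+$", "", tree$tip.label),
                     ifelse(as.integer(sub("^\\D+", "", tree$tip.label)) %% 2L == 0L, "A", "B")),
      category = unname(categories[tree$tip.label]),
      data_type = ifelse(seq_along(tree$tip.label) %% 4L == 0L, "genome", "transcriptome"),
      is_ciliate = TRUE,
      stringsAsFactors = FALSE)
    structure(list(tree = tree, categories = categories, taxa = taxa,
                   seed = as.integer(seed)),
              class = "species_tree_sim")
  })
}

# exact largest-remainder apportionment of n among named proportions
apportion <- function(props, n) {
  raw <- props * n
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(-(raw - base), seq_along(raw))[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  stats::setNames(as.integer(base), names(props))
}

#' @export
print.species_tree_sim <- function(x, ...) {
  cat("species_tree_sim:", ape::Ntip(x$tree), "taxa,",
      paste(sprintf("%s=%d", names(table(x$categories)),
                    as.integer(table(x$categories))), collapse = " "), "\n")
  invisible(x)
}

#' Simulate gene-family histories along a species tree
#'
#' Each family is born at one node (sampled over branches proportionally to
#' branch length; a synthetic root branch makes root births possible) and
#' then experiences Poisson losses and duplications along the branches below
#' the birth node. A loss terminates a gene copy's lineage; a duplication
#' spawns an independent second copy. Families losing every copy are
#' returned flagged (`surviving = FALSE`), not dropped.
#'
#' @param sim a [simulate_species_tree()] result.
#' @param cfg a [simulation_config()].
#' @param n_families number of families.
#' @return list of `family_history` objects: `family_id`, `birth_node`
#'   (ape number), `birth_id`, `loss_branches` (edge child ids), `n_losses`,
#'   `duplication_events` (data.frame child id, count), `surviving_leaves`,
#'   `n_copies` (named), `gene_tree` (`phylo`, `NULL` if < 2 copies
#'   survive), `surviving`.
#' @export
simulate_family_histories <- function(sim, cfg, n_families) {
  tree <- sim$tree
  edge_len <- tree$edge.length
  rootlen <- if (is.null(cfg$root_branch_length)) mean(edge_len) else cfg$root_branch_length
  children <- tree_children(tree)
  ids <- node_ids(tree)
  root <- tree_root(tree)
  edge_of_child <- integer(ape::Ntip(tree) + tree$Nnode)
  edge_of_child[tree$edge[, 2]] <- seq_len(nrow(tree$edge))

  lapply(seq_len(n_families), function(f) {
    withr::with_seed(cfg$seed + 97L * f, {
      sim_one_family(sprintf("FAM%04d", f), tree, children, ids, root,
                     edge_of_child, edge_len, rootlen, cfg)
    })
  })
}

sim_one_family <- function(family_id, tree, children, ids, root,
                           edge_of_child, edge_len, rootlen, cfg) {
  ntip <- ape::Ntip(tree)
  # birth node: child of a length-weighted branch; the synthetic root branch
  # maps to the root node itself
  w <- c(edge_len, rootlen)
  pick <- sample.int(length(w), 1, prob = w)
  birth_node <- if (pick > length(edge_len)) root else tree$edge[pick, 2]

  losses <- integer(0)
  dups <- integer(0)
  copy_counter <- new.env(parent = emptyenv())

  leaf_node <- function(node) {
    tx <- tree$tip.label[node]
    k <- (copy_counter[[tx]] <- (if (is.null(copy_counter[[tx]])) 0L else copy_counter[[tx]]) + 1L)
    list(leaf = paste0(tx, "@", k), length = 0)
  }
  # a gene copy arriving at a species node (having just consumed its branch)
  arrive <- function(node) {
    if (node <= ntip) return(leaf_node(node))
    ch <- children[[node]]
    subs <- lapply(ch, function(c2) descend(edge_of_child[c2]))
    subs <- subs[!vapply(subs, is.null, logical(1))]
    if (length(subs) == 0) return(NULL)
    if (length(subs) == 1) {
      subs[[1]]$length <- subs[[1]]$length   # lengths already include the edge
      return(subs[[1]])
    }
    list(children = subs, length = 0)
  }
  # a gene copy entering edge e at distance `pos` from its top
  descend <- function(e, pos = 0) {
    len <- edge_len[e]
    t_rem <- len - pos
    t_loss <- if (cfg$loss_rate > 0) stats::rexp(1, cfg$loss_rate) else Inf
    t_dup <- if (cfg$duplication_rate > 0) stats::rexp(1, cfg$duplication_rate) else Inf
    if (t_loss < t_rem && t_loss <= t_dup) {
      losses <<- c(losses, e)
      return(NULL)
    }
    if (t_dup < t_rem && t_dup < t_loss) {
      dups <<- c(dups, e)
      a <- descend(e, pos + t_dup)
      b <- descend(e, pos + t_dup)
      surv <- Filter(Negate(is.null), list(a, b))
      if (length(surv) == 0) return(NULL)
      if (length(surv) == 1) {
        surv[[1]]$length <- surv[[1]]$length + t_dup
        return(surv[[1]])
      }
      return(list(children = surv, length = t_dup))
    }
    sub <- arrive(tree$edge[e, 2])
    if (is.null(sub)) return(NULL)
    sub$length <- sub$length + t_rem
    sub
  }

  groot <- arrive(birth_node)
  leaves <- gene_leaves(groot)
  gene_tree <- if (length(leaves) >= 2) {
    ape::read.tree(text = paste0(to_newick(groot), ";"))
  } else NULL
  taxa_of <- sub("@[^@]*$", "", leaves)
  dup_tab <- if (length(dups)) {
    tb <- table(ids[tree$edge[dups, 2]])
    data.frame(branch = names(tb), count = as.integer(tb), stringsAsFactors = FALSE)
  } else data.frame(branch = character(), count = integer())
  structure(list(family_id = family_id, birth_node = birth_node,
                 birth_id = ids[birth_node],
                 loss_branches = ids[tree$edge[losses, 2]],
                 n_losses = length(losses),
                 duplication_events = dup_tab,
                 n_duplications = length(dups),
                 surviving_leaves = unique(taxa_of),
                 n_copies = if (length(leaves)) table(taxa_of) else table(character()),
                 copy_labels = leaves,
                 gene_tree = gene_tree,
                 surviving = length(leaves) > 0),
            class = "family_history")
}

gene_leaves <- function(node) {
  if (is.null(node)) return(character())
  if (!is.null(node$leaf)) return(node$leaf)
  unlist(lapply(node$children, gene_leaves))
}

to_newick <- function(node) {
  if (!is.null(node$leaf)) return(sprintf("%s:%.6f", node$leaf, node$length))
  inner <- paste(vapply(node$children, to_newick, character(1)), collapse = ",")
  sprintf("(%s):%.6f", inner, node$length)
}

#' @export
print.family_history <- function(x, ...) {
  cat(sprintf("family_history %s: birth %s, %d losses, %d duplications, %d taxa surviving\n",
              x$family_id, x$birth_id, x$n_losses, x$n_duplications,
              length(x$surviving_leaves)))
  invisible(x)
}

#' Simulate a codon alignment for one family history
#'
#' Branches of the family's gene tree are labelled by architecture category
#' (terminal branches by taxon; internal branches only when all descendants
#' agree), the reference omega distribution is raised to each group's
#' intensity exponent `K`, and sites evolve independently with branch-site
#' omega draws. Unclassified branches evolve under the reference
#' distribution.
#'
#' @param history a `family_history` with a gene tree of >= 2 copies.
#' @param sim the [simulate_species_tree()] result (for categories).
#' @param cfg a [simulation_config()].
#' @param n_codons number of codon sites (>= 1).
#' @param seed integer seed.
#' @return list: `alignment` (named CDS strings), `gene_tree`, `partition`
#'   (a [label_branches()] result), `groups` (effective distributions).
#' @export
simulate_family_alignment <- function(history, sim, cfg, n_codons, seed = 1) {
  if (is.null(history$gene_tree)) stop("family has fewer than 2 surviving copies")
  if (n_codons < 1) stop("n_codons must be >= 1")
  part <- label_branches(history$gene_tree, sim$categories)
  labs <- unique(part$edge_labels)
  groups <- lapply(labs, function(g) {
    k <- if (g %in% names(cfg$K)) cfg$K[[g]] else 1
    apply_k(cfg$omega_ref, k)
  })
  names(groups) <- labs
  alignment <- simulate_codon_alignment(history$gene_tree, cfg$pi, cfg$rho,
                                        groups, part$edge_labels, n_codons,
                                        seed = seed, code = cfg$code)
  list(alignment = alignment, gene_tree = history$gene_tree,
       partition = part, groups = groups)
}

#' Reference GC3s values emulating widely conserved gene families
#'
#' The composition screen compares candidate ORFs against GC3s values of a
#' conserved-gene reference set pooled across taxa. Cross-taxon pooling
#' makes the reference wider than any single taxon's composition, which is
#' emulated by a clamped normal with a larger spread than the within-taxon
#' sampling noise of individual ORFs.
#'
#' @param n number of reference families.
#' @param mean,sd location and spread of the reference GC3s.
#' @param seed integer seed.
#' @return numeric vector in (0, 1).
#' @export
simulate_reference_gc3s <- function(n = 200, mean = 0.70, sd = 0.08, seed = 1) {
  withr::with_seed(as.integer(seed), {
    pmin(pmax(stats::rnorm(n, mean, sd), 0.02), 0.98)
  })
}

#' Emit transcriptome-like FASTA files with ground truth
#'
#' For each taxon, genuine ORFs (one per surviving gene copy) are embedded
#' in UTR-like random flanks behind an ATG start and in front of a stop
#' codon of the active code. Allelic variants (identity >= 0.97 to their
#' source) and contaminant ORFs drawn at the contaminant GC3s target are
#' injected at the configured rates; a truth table records every record's
#' class.
#'
#' @param family_alignments named list `family_id -> result of`
#'   [simulate_family_alignment()] (or any list with `alignment` of
#'   `taxon@copy` sequences).
#' @param sim the [simulate_species_tree()] result.
#' @param cfg a [simulation_config()].
#' @param out_dir optional directory for per-taxon FASTA plus
#'   `truth_table.tsv`.
#' @param histories optional named list of family histories (adds
#'   `birth_node` to the truth table).
#' @return list: `transcripts` (named list taxon -> named character of
#'   transcripts), `truth` (data.frame `record_id`, `taxon`, `family_id`,
#'   `class`, `source_record`, `birth_node`), `files` (paths, if written).
#' @export
emit_transcriptomes <- function(family_alignments, sim, cfg, out_dir = NULL,
                                histories = NULL) {
  code <- cfg$code
  stopv <- code$stop_codons[1]
  withr::with_seed(cfg$seed + 7919L, {
    per_taxon <- lapply(sim$taxa$taxon, function(tx) list(seqs = character(), truth = NULL))
    names(per_taxon) <- sim$taxa$taxon
    truth <- list()
    for (fid in names(family_alignments)) {
      aln <- family_alignments[[fid]]$alignment
      bn <- if (!is.null(histories) && fid %in% names(histories))
        histories[[fid]]$birth_id else NA_character_
      for (nm in names(aln)) {
        tx <- sub("@[^@]*$", "", nm)
        rid <- paste0(tx, "|", fid, "|", sub("^.*@", "c", nm))
        cds <- gsub("-", "", aln[[nm]])
        per_taxon[[tx]]$seqs[rid] <- wrap_transcript(cds, stopv)
        truth[[length(truth) + 1L]] <- data.frame(
          record_id = rid, taxon = tx, family_id = fid, class = "genuine",
          source_record = NA_character_, birth_node = bn,
          stringsAsFactors = FALSE)
      }
    }
    truth <- do.call(rbind, c(truth, list(NULL)))
    if (is.null(truth)) {
      truth <- data.frame(record_id = character(), taxon = character(),
                          family_id = character(), class = character(),
                          source_record = character(), birth_node = character())
    }

    # allelic variants: deterministic apportionment per taxon
    for (tx in names(per_taxon)) {
      n_gen <- length(per_taxon[[tx]]$seqs)
      n_all <- round(cfg$allelic_variant_rate * n_gen)
      if (n_all < 1) next
      src_rows <- truth[truth$taxon == tx & truth$class == "genuine", ]
      src <- src_rows$record_id[seq_len(min(n_all, nrow(src_rows)))]
      for (i in seq_along(src)) {
        cds <- extract_cds(per_taxon[[tx]]$seqs[[src[i]]], code)
        var <- mutate_allele(cds, code, max_div = 0.03)
        rid <- paste0(src[i], "|allele")
        per_taxon[[tx]]$seqs[rid] <- wrap_transcript(var, stopv)
        truth <- rbind(truth, data.frame(
          record_id = rid, taxon = tx,
          family_id = truth$family_id[truth$record_id == src[i]][1],
          class = "allele", source_record = src[i],
          birth_node = NA_character_, stringsAsFactors = FALSE))
      }
    }

    # contaminants at the configured fraction of total emitted records
    for (tx in names(per_taxon)) {
      n_now <- length(per_taxon[[tx]]$seqs)
      f <- cfg$contaminant_fraction
      n_con <- round(f * n_now / (1 - f))
      for (i in seq_len(n_con)) {
        len_aa <- sample(200:350, 1)
        cds <- random_cds(len_aa, code, cfg$gc3s_contaminant)
        rid <- paste0(tx, "|contam", i)
        per_taxon[[tx]]$seqs[rid] <- wrap_transcript(cds, stopv)
        truth <- rbind(truth, data.frame(
          record_id = rid, taxon = tx, family_id = NA_character_,
          class = "contaminant", source_record = NA_character_,
          birth_node = NA_character_, stringsAsFactors = FALSE))
      }
    }

    files <- character(0)
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      for (tx in names(per_taxon)) {
        if (!length(per_taxon[[tx]]$seqs)) next
        path <- file.path(out_dir, paste0(tx, ".fasta"))
        write_fasta(per_taxon[[tx]]$seqs, path)
        files <- c(files, path)
      }
      tpath <- file.path(out_dir, "truth_table.tsv")
      utils::write.table(truth, tpath, sep = "\t", quote = FALSE, row.names = FALSE)
      files <- c(files, tpath)
    }
    list(transcripts = lapply(per_taxon, `[[`, "seqs"), truth = truth,
         files = files)
  })
}

# embed a CDS in UTR-like flanks; the CDS is prefixed with ATG and suffixed
# with a stop codon so the ORF caller can recover it exactly
wrap_transcript <- function(cds, stop_codon) {
  f5 <- paste(sample(c("A", "C", "G", "T"), sample(20:60, 1), replace = TRUE), collapse = "")
  f3 <- paste(sample(c("A", "C", "G", "T"), sample(20:60, 1), replace = TRUE), collapse = "")
  paste0(f5, "ATG", cds, stop_codon, f3)
}

extract_cds <- function(transcript, code) {
  orf <- call_orfs(transcript, code, min_aa = 10)
  if (nrow(orf) == 0) stop("internal: failed to recover embedded ORF")
  substr(orf$nt, 4L, nchar(orf$nt))    # drop the prefixed ATG
}

# random point mutations below max_div divergence; codons that would become
# stops are left untouched
mutate_allele <- function(cds, code, max_div = 0.03) {
  n <- nchar(cds)
  n_mut <- max(1L, min(round(0.015 * n), floor(max_div * n)))
  pos <- sample.int(n, n_mut)
  s <- strsplit(cds, "")[[1]]
  for (p in pos) {
    old <- s[p]
    new <- sample(setdiff(c("A", "C", "G", "T"), old), 1)
    cod_i <- (p - 1L) %/% 3L
    cod <- s[cod_i * 3L + 1:3]
    cod[(p - 1L) %% 3L + 1L] <- new
    if (paste(cod, collapse = "") %in% code$stop_codons) next
    s[p] <- new
  }
  paste(s, collapse = "")
}

# random CDS with third positions skewed to a GC3s target
random_cds <- function(len_aa, code, gc3) {
  pi <- gc3_skewed_pi(code, gc3)
  paste(sample(code$sense_codons, len_aa, replace = TRUE, prob = pi),
        collapse = "")
}

write_fasta <- function(seqs, path) {
  ok <- tryCatch({
    con <- file(path, "w")
    on.exit(close(con))
    for (nm in names(seqs)) {
      writeLines(c(paste0(">", nm), seqs[[nm]]), con)
    }
    TRUE
  }, error = function(e) {
    stop("failed to write FASTA '", path, "': ", conditionMessage(e))
  })
  invisible(path)
}

read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}
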