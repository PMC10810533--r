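test_that("species-tree simulation validates arguments and apportions exactly", {
  expect_error(simulate_species_tree(1), "n_taxa")
  expect_error(simulate_species_tree(10, c(EF = 0.6, NEF = 0.5)), "sum to 1")
  # forced two-taxon cherry
  s2 <- simulate_species_tree(2, c(EF = 0.5, NEF = 0.5), seed = 1)
  expect_equal(ape::Ntip(s2$tree), 2)
  expect_setequal(unname(s2$categories), c("EF", "NEF"))
  # exact largest-remainder apportionment
  s40 <- simulate_species_tree(40, c(EF = 0.5, NEF = 0.25, HE = 0.125, KA = 0.125),
                               seed = 7)
  expect_equal(as.integer(table(s40$categories)[c("EF", "NEF", "HE", "KA")]),
               c(20, 10, 5, 5))
})

test_that("species-tree simulation is seed-deterministic and clade-wise monophyletic", {
  a <- simulate_species_tree(20, seed = 7)
  b <- simulate_species_tree(20, seed = 7)
  expect_identical(ape::write.tree(a$tree), ape::write.tree(b$tree))
  expect_true(all(a$tree$edge.length > 0))
  for (cc in unique(a$categories)) {
    tips <- names(a$categories)[a$categories == cc]
    if (length(tips) < 2) next
    expect_true(ape::is.monophyletic(a$tree, tips))
  }
  # random assignment flag breaks monophyly structure but keeps counts
  r <- simulate_species_tree(20, seed = 7, cladewise = FALSE)
  expect_equal(sort(table(r$categories)), sort(table(a$categories)))
})

test_that("family histories honour the no-loss/no-duplication limits", {
  sim <- simulate_species_tree(8, c(EF = 0.5, NEF = 0.5), seed = 3)
  cfg <- simulation_config(loss_rate = 0, duplication_rate = 0, seed = 5)
  ls <- lsgfevo:::node_leafsets(sim$tree)
  hs <- simulate_family_histories(sim, cfg, 20)
  for (h in hs) {
    below <- sim$tree$tip.label[ls[h$birth_node, ]]
    expect_setequal(h$surviving_leaves, below)
    expect_equal(h$n_losses, 0)
    if (length(below) >= 3) {
      # gene tree restricted to surviving leaves equals the species subtree
      st <- ape::keep.tip(sim$tree, below)
      gt <- h$gene_tree
      gt$tip.label <- sub("@.*$", "", gt$tip.label)
      expect_equal(ape::dist.topo(ape::unroot(st), ape::unroot(gt)), 0,
                   ignore_attr = TRUE)
    }
  }
})

test_that("loss counts agree with the branch-length expectation", {
  sim <- simulate_species_tree(10, c(EF = 0.5, NEF = 0.5), seed = 13)
  lam <- 0.5
  cfg <- simulation_config(loss_rate = lam, duplication_rate = 0, seed = 29)
  hs <- simulate_family_histories(sim, cfg, 800)
  # closed form, per birth node b: sum over edges below b of
  # P(lineage alive at edge top) * P(loss on the edge), where survival to
  # the top decays with the path length from b
  depth_len <- node_depth_lengths(sim$tree)
  ls <- lsgfevo:::node_leafsets(sim$tree)
  expected_for_birth <- function(b) {
    below <- which(apply(ls, 1, function(r) all(r <= ls[b, ])))
    e_idx <- which(sim$tree$edge[, 2] %in% setdiff(below, b))
    tot <- 0
    for (e in e_idx) {
      top <- sim$tree$edge[e, 1]
      d <- depth_len[top] - depth_len[b]
      tot <- tot + exp(-lam * d) * (1 - exp(-lam * sim$tree$edge.length[e]))
    }
    tot
  }
  obs <- vapply(hs, `[[`, numeric(1), "n_losses")
  exp_mean <- mean(vapply(hs, function(h) expected_for_birth(h$birth_node),
                          numeric(1)))
  se <- stats::sd(obs) / sqrt(length(obs))
  expect_lt(abs(mean(obs) - exp_mean), 3 * se + 1e-12)
})

test_that("emitted transcriptomes carry a faithful truth table", {
  sim <- simulate_species_tree(6, c(EF = 0.5, NEF = 0.5), seed = 2)
  cfg0 <- simulation_config(contaminant_fraction = 0, allelic_variant_rate = 0,
                            loss_rate = 0.2, duplication_rate = 0.2, seed = 11)
  hs <- simulate_family_histories(sim, cfg0, 10)
  names(hs) <- vapply(hs, `[[`, character(1), "family_id")
  alns <- list()
  for (h in hs) {
    if (is.null(h$gene_tree)) next
    alns[[h$family_id]] <- simulate_family_alignment(h, sim, cfg0, 120,
                                                     seed = 3 + length(alns))
  }
  em <- emit_transcriptomes(alns, sim, cfg0, histories = hs)
  # with both injection rates zero, only genuine records exist
  expect_setequal(unique(em$truth$class), "genuine")
  # conservation: every surviving copy maps to exactly one truth row
  copies <- unlist(lapply(names(alns), function(f) {
    paste0(sub("@[^@]*$", "", names(alns[[f]]$alignment)), "|", f)
  }))
  keys <- paste0(em$truth$taxon, "|", em$truth$family_id)
  expect_equal(sort(keys), sort(copies))
  expect_equal(anyDuplicated(em$truth$record_id), 0)
})

test_that("allele apportionment is deterministic and contaminants skew low GC3s", {
  sim <- simulate_species_tree(4, c(EF = 0.5, NEF = 0.5), seed = 6)
  cfg <- simulation_config(contaminant_fraction = 0.2,
                           allelic_variant_rate = 0.2,
                           loss_rate = 0, duplication_rate = 0, seed = 8)
  hs <- simulate_family_histories(sim, cfg, 12)
  names(hs) <- vapply(hs, `[[`, character(1), "family_id")
  alns <- list()
  for (h in hs) {
    if (is.null(h$gene_tree)) next
    alns[[h$family_id]] <- simulate_family_alignment(h, sim, cfg, 210,
                                                     seed = 5 + length(alns))
  }
  em <- emit_transcriptomes(alns, sim, cfg, histories = hs)
  tt <- em$truth
  for (tx in unique(tt$taxon)) {
    n_gen <- sum(tt$taxon == tx & tt$class == "genuine")
    expect_equal(sum(tt$taxon == tx & tt$class == "allele"),
                 round(0.2 * n_gen))
  }
  # recompute composition with the composition module: contaminants sit at
  # a visibly lower GC3s than genuine ciliate ORFs
  orfs <- do.call(rbind, lapply(names(em$transcripts), function(tx) {
    seqs <- em$transcripts[[tx]]
    do.call(rbind, lapply(names(seqs), function(nm) {
      o <- call_orfs(seqs[[nm]], cfg$code, min_aa = 100,
                     transcript_id = nm, taxon = tx)
      o$record_id <- nm
      o
    }))
  }))
  comp <- composition_table(orfs, cfg$code)
  comp$class <- tt$class[match(comp$record_id, tt$record_id)]
  m <- tapply(comp$gc3s, comp$class, mean)
  expect_lt(m[["contaminant"]], m[["genuine"]])
  # alleles stay within the dedupe identity contract
  al <- tt[tt$class == "allele", ]
  for (i in seq_len(nrow(al))) {
    a <- orfs$nt[orfs$record_id == al$record_id[i]]
    b <- orfs$nt[orfs$record_id == al$source_record[i]]
    expect_gte(lsgfevo:::nt_identity(a, b), 0.97)
  }
})
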