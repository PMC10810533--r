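test_that("refinement applies the length band before the membership checks", {
  taxa <- toy_taxa(c("t1", "t2"), genus = c("g1", "g2"))
  # worked two-step case: mean 160, band [80, 240], the 400-aa member drops,
  # 4 members remain below the minimum of 5
  members <- data.frame(record_id = sprintf("r%d", 1:5),
                        taxon = c("t1", "t1", "t2", "t2", "t1"),
                        length = c(100, 100, 100, 100, 400))
  r <- refine_family(members, taxa)
  expect_false(r$kept)
  expect_identical(r$reason, "min_members")
  expect_identical(r$dropped_by_band, "r5")

  # six equal-length ciliate proteins from two genera pass
  members2 <- data.frame(record_id = sprintf("r%d", 1:6),
                         taxon = rep(c("t1", "t2"), 3), length = 120)
  expect_true(refine_family(members2, taxa)$kept)
})

test_that("low ciliate proportion is the reported rejection reason", {
  taxa <- toy_taxa(c("c1", "c2", "x1"), genus = c("g1", "g2", "gx"),
                   is_ciliate = c(TRUE, TRUE, FALSE))
  members <- data.frame(record_id = sprintf("r%d", 1:10),
                        taxon = c(rep(c("c1", "c2"), 4), "x1", "x1"),
                        length = 150)
  r <- refine_family(members, taxa)   # 80% ciliate
  expect_false(r$kept)
  expect_identical(r$reason, "ciliate_proportion")
})

test_that("refinement is order-invariant and monotone in its thresholds", {
  withr::with_seed(21, {
    taxa <- toy_taxa(sprintf("t%d", 1:6), genus = rep(c("g1", "g2", "g3"), 2))
    for (i in 1:25) {
      n <- sample(3:12, 1)
      members <- data.frame(record_id = sprintf("r%d", seq_len(n)),
                            taxon = sample(taxa$taxon, n, replace = TRUE),
                            length = sample(50:400, n, replace = TRUE))
      r1 <- refine_family(members, taxa)
      r2 <- refine_family(members[sample(n), ], taxa)
      expect_equal(r1$kept, r2$kept)
      expect_setequal(r1$members$record_id, r2$members$record_id)
      # tightening a membership threshold never turns a rejected family
      # into a kept one
      if (!r1$kept) {
        expect_false(refine_family(members, taxa, min_members = 6)$kept)
        expect_false(refine_family(members, taxa, min_genera = 3)$kept)
        expect_false(refine_family(members, taxa, min_ciliate_prop = 0.99)$kept &&
                       !refine_family(members, taxa, min_ciliate_prop = 0.95)$kept)
      }
    }
  })
})

test_that("single-linkage clustering joins chains and separates the rest", {
  # A ~ B and B ~ C but A !~ C must still collapse into one family
  a <- strrep("MKLVNPQRSTWYAEDGHIKL", 10)
  b <- paste0(substr(a, 1, 120), strrep("WWWWQQQQPPPP", 10))
  c_ <- paste0(strrep("WWWWQQQQPPPP", 10), strrep("CCDDEEFFGGHH", 10))
  d <- strrep("AAAAAAAAAACCCCCCCCCC", 12)
  orfs <- data.frame(record_id = c("A", "B", "C", "D"),
                     protein = c(a, b, c_, d))
  fam <- cluster_orfs(orfs, threshold = 0.3)
  expect_equal(fam$family_id[1], fam$family_id[2])
  expect_equal(fam$family_id[2], fam$family_id[3])
  expect_false(fam$family_id[4] == fam$family_id[1])
})

test_that("clustering recovers simulated families without losses", {
  sim <- simulate_species_tree(6, c(EF = 0.5, NEF = 0.5), seed = 31)
  cfg <- simulation_config(loss_rate = 0, duplication_rate = 0, seed = 31)
  hs <- simulate_family_histories(sim, cfg, 14)
  orfs <- list()
  for (h in hs) {
    if (is.null(h$gene_tree)) next
    fa <- simulate_family_alignment(h, sim, cfg, 150, seed = 7)
    for (nm in names(fa$alignment)) {
      orfs[[length(orfs) + 1]] <- data.frame(
        record_id = paste(h$family_id, nm, sep = "|"),
        protein = translate_cds(fa$alignment[[nm]], cfg$code))
    }
  }
  orfs <- do.call(rbind, orfs)
  fam <- cluster_orfs(orfs, threshold = 0.3)
  truth <- sub("\\|.*$", "", orfs$record_id)
  # recovered components must equal the true memberships
  tab <- table(fam$family_id, truth)
  expect_true(all(rowSums(tab > 0) == 1))
  expect_equal(length(unique(fam$family_id)), length(unique(truth)))
})

test_that("presence matrix and sharing summaries are consistent", {
  taxa <- toy_taxa(c("a", "b", "c", "d"),
                   category = c("EF", "NEF", "HE", "KA"))
  membership <- data.frame(
    family_id = c("f1", "f1", "f1", "f1", "f2", "f2", "f3"),
    record_id = sprintf("r%d", 1:7),
    taxon = c("a", "b", "c", "d", "a", "b", "c"),
    length = 100)
  pm <- presence_matrix(membership, taxa)
  sh <- sharing_summary(pm)
  expect_equal(sh$family_sets$categories[sh$family_sets$family_id == "f1"],
               "EF+HE+KA+NEF")
  expect_equal(sum(sh$upset$n_families), 3)   # partition over families
  expect_equal(sh$category_summary$n_families[sh$category_summary$category == "HE"], 2)
  expect_equal(sh$taxon_summary$n_families[sh$taxon_summary$taxon == "a"], 2)
})
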