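pi61 <- rep(1 / 61, 61)
rho0 <- c(1.2, 2.0, 0.8, 1.1, 2.5, 1.0)

test_that("transition matrices are proper stochastic matrices with pi stationary", {
  P <- lsgfevo:::codon_pmatrix(1, pi61, rho0, 0.5, 0.3)
  expect_equal(rowSums(P), rep(1, 61), tolerance = 1e-10)
  expect_true(all(P >= 0))
  expect_equal(as.numeric(pi61 %*% P), pi61, tolerance = 1e-12)
  # zero time: identity
  P0 <- lsgfevo:::codon_pmatrix(1, pi61, rho0, 0.5, 0)
  expect_equal(P0, diag(61), tolerance = 1e-12)
})

test_that("pruning likelihood matches full ancestral/category enumeration", {
  tr <- ape::read.tree(text = "((A:0.2,B:0.3):0.1,C:0.4);")
  groups <- list(g = list(omega = c(0.1, 0.7, 2.0), weight = c(0.5, 0.3, 0.2)))
  seqs <- simulate_codon_alignment(tr, pi61, rho0, groups, rep("g", 4), 6,
                                   seed = 2, code = 1)
  aln <- codon_alignment(seqs, 1)
  ll <- codon_likelihood(aln, tr, pi61, rho0, groups)
  # oracle branch order: inner->A (0.2), inner->B (0.3), root->inner (0.1),
  # root->C (0.4)
  Pk <- lapply(1:3, function(k) {
    lapply(c(0.2, 0.3, 0.1, 0.4), function(t) {
      lsgfevo:::codon_pmatrix(1, pi61, rho0, groups$g$omega[k], t)
    })
  })
  osum <- sum(loglik_oracle_3taxon(aln$states[, c("A", "B", "C")], pi61, Pk,
                                   groups$g$weight))
  expect_equal(as.numeric(ll), osum, tolerance = 1e-10)
})

test_that("likelihood matches fixed-category-tuple summation on 4 taxa", {
  tr <- ape::read.tree(text = "(((A:0.15,B:0.2):0.1,C:0.25):0.05,D:0.3);")
  dist <- list(omega = c(0.2, 1.5), weight = c(0.7, 0.3))
  seqs <- simulate_codon_alignment(tr, pi61, rho0, list(g = dist),
                                   rep("g", nrow(tr$edge)), 5, seed = 9, code = 1)
  aln <- codon_alignment(seqs, 1)
  ll <- codon_likelihood(aln, tr, pi61, rho0, list(g = dist))
  oll <- loglik_oracle_tuples(aln, tr, pi61, rho0, dist, 1)
  expect_equal(as.numeric(ll), oll, tolerance = 1e-8)
})

test_that("zero-length trees reduce to the stationary distribution", {
  tr <- ape::read.tree(text = "((A:0,B:0):0,C:0);")
  s <- paste(sample(genetic_code(1)$sense_codons, 20, replace = TRUE), collapse = "")
  aln <- codon_alignment(setNames(rep(s, 3), c("A", "B", "C")), 1)
  groups <- list(g = list(omega = c(0.5, 1, 2), weight = c(1, 1, 1) / 3))
  ll <- codon_likelihood(aln, tr, pi61, rho0, groups)
  expect_equal(as.numeric(ll), sum(log(pi61[aln$states[, 1]])), tolerance = 1e-9)
})

test_that("likelihood is invariant to reordering alignment columns", {
  tr <- ape::read.tree(text = "((A:0.2,B:0.3):0.1,C:0.4);")
  groups <- list(g = list(omega = c(0.1, 1, 3), weight = c(0.6, 0.3, 0.1)))
  seqs <- simulate_codon_alignment(tr, pi61, rho0, groups, rep("g", 4), 30,
                                   seed = 4, code = 1)
  aln <- codon_alignment(seqs, 1)
  ll1 <- codon_likelihood(aln, tr, pi61, rho0, groups)
  perm <- withr::with_seed(1, sample(30))
  aln2 <- aln; aln2$states <- aln$states[perm, ]
  ll2 <- codon_likelihood(aln2, tr, pi61, rho0, groups)
  expect_equal(as.numeric(ll1), as.numeric(ll2), tolerance = 1e-10)
})

test_that("alignment/tree name mismatches are reported", {
  tr <- ape::read.tree(text = "((A:0.2,B:0.3):0.1,Z:0.4);")
  seqs <- setNames(rep("ATGATG", 3), c("A", "B", "C"))
  aln <- codon_alignment(seqs, 1)
  groups <- list(g = list(omega = 1, weight = 1))
  expect_error(codon_likelihood(aln, tr, pi61, rho0, groups), "Z")
})

test_that("simulation is seed-deterministic and never emits stops", {
  tr <- ape::read.tree(text = "((A:0.3,B:0.4):0.2,(C:0.5,D:0.1):0.3);")
  cfg <- simulation_config(seed = 1)
  groups <- list(g = cfg$omega_ref)
  s1 <- simulate_codon_alignment(tr, cfg$pi, cfg$rho, groups, rep("g", 6),
                                 50, seed = 77, code = 6)
  s2 <- simulate_codon_alignment(tr, cfg$pi, cfg$rho, groups, rep("g", 6),
                                 50, seed = 77, code = 6)
  expect_identical(s1, s2)
  stops <- genetic_code(6)$stop_codons
  for (s in s1) {
    cods <- substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
    expect_length(intersect(cods, stops), 0)
  }
  # all-zero branch lengths: sequences identical to the root draw
  tr0 <- tr; tr0$edge.length[] <- 0
  s0 <- simulate_codon_alignment(tr0, cfg$pi, cfg$rho, groups, rep("g", 6),
                                 40, seed = 5, code = 6)
  expect_length(unique(unname(s0)), 1)
})

test_that("neutral simulation reproduces the codon-graph N/S ratio", {
  # with a single omega = 1 category and uniform pi, the expected
  # nonsynonymous/synonymous substitution ratio equals the ratio of
  # nonsynonymous to synonymous single-nucleotide neighbour pairs
  st <- lsgfevo:::codon_model_structure(genetic_code(1))
  expected <- sum(st$tr_nonsyn == 1) / sum(st$tr_nonsyn == 0)
  tr <- ape::read.tree(text = "(A:0.04,B:0.04);")
  groups <- list(g = list(omega = 1, weight = 1))
  rho1 <- rep(1, 6)
  seqs <- simulate_codon_alignment(tr, pi61, rho1, groups, c("g", "g"),
                                   60000, seed = 303, code = 1)
  sense <- genetic_code(1)$sense_codons
  a <- substring(seqs[["A"]], seq(1, nchar(seqs[["A"]]), 3), seq(3, nchar(seqs[["A"]]), 3))
  b <- substring(seqs[["B"]], seq(1, nchar(seqs[["B"]]), 3), seq(3, nchar(seqs[["B"]]), 3))
  diff <- which(a != b)
  # single-nucleotide differences only (multiple hits are rare at this
  # divergence and excluded)
  nd <- mapply(function(x, y) sum(strsplit(x, "")[[1]] != strsplit(y, "")[[1]]),
               a[diff], b[diff])
  one <- diff[nd == 1]
  aa <- genetic_code(1)$map
  nonsyn <- sum(aa[a[one]] != aa[b[one]])
  syn <- length(one) - nonsyn
  expect_gt(syn, 100)
  expect_lt(abs(nonsyn / syn - expected) / expected, 0.05)
})

test_that("F3x4 frequencies are positive and normalised", {
  cfg <- simulation_config(seed = 2)
  tr <- ape::read.tree(text = "(A:0.2,B:0.2);")
  seqs <- simulate_codon_alignment(tr, cfg$pi, cfg$rho,
                                   list(g = cfg$omega_ref), c("g", "g"),
                                   100, seed = 8, code = 6)
  aln <- codon_alignment(seqs, 6)
  pi <- f3x4_frequencies(aln)
  expect_equal(sum(pi), 1, tolerance = 1e-12)
  expect_true(all(pi > 0))
  expect_length(pi, length(genetic_code(6)$sense_codons))
  # the GC3s skew of the generator shows up in the fitted frequencies
  third <- substr(genetic_code(6)$sense_codons, 3, 3)
  expect_gt(sum(pi[third %in% c("G", "C")]), 0.55)
})
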