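test_that("branch labelling follows the all-descendants rule", {
  cats <- c(a = "EF", b = "EF", c = "NEF", d = "NEF")
  tr <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1);")
  part <- label_branches(tr, cats)
  # cherry stems inherit their leaves' shared category
  ab <- part$table$label[part$table$child == "n6" | part$table$child == "n7"]
  expect_setequal(unique(part$edge_labels), c("EF", "NEF"))
  expect_equal(sum(part$edge_labels == "unclassified"), 0)

  # a mixed clade stays unclassified
  cats2 <- c(a = "EF", b = "NEF", c = "HE", d = "HE")
  part2 <- label_branches(tr, cats2)
  expect_equal(sum(part2$edge_labels == "unclassified"), 1)  # the a,b stem
  expect_equal(sum(part2$edge_labels == "HE"), 3)

  # single-category tree: nothing unclassified
  part3 <- label_branches(tr, c(a = "KA", b = "KA", c = "KA", d = "KA"))
  expect_true(all(part3$edge_labels == "KA"))

  expect_error(label_branches(tr, c(a = "EF", b = "EF", c = "NEF")), "d")
})

test_that("reference group selection follows the EF > NEF > HE > KA rule", {
  tr <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1);")
  pick <- function(c1, c2) {
    part <- label_branches(tr, setNames(c(c1, c1, c2, c2), letters[1:4]))
    choose_reference_group(part)
  }
  expect_equal(pick("EF", "HE")$reference, "EF")
  expect_equal(pick("NEF", "KA")$reference, "NEF")
  expect_equal(pick("HE", "KA")$reference, "HE")
  # one group only: untestable, flagged rather than an error
  part1 <- label_branches(tr, setNames(rep("EF", 4), letters[1:4]))
  res <- choose_reference_group(part1)
  expect_false(res$testable)
  expect_true(is.na(res$reference))
})

test_that("BH adjustment matches the step-up definition", {
  expect_equal(adjust_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjust_fdr(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(adjust_fdr(0.37), 0.37)
  withr::with_seed(2, {
    p <- runif(50)
    q <- adjust_fdr(p)
    expect_true(all(q >= p))                         # q >= p elementwise
    expect_true(all(diff(q[order(p)]) >= -1e-12))    # monotone in p rank
  })
  expect_error(adjust_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("EDS binning uses the floor rule", {
  res <- data.frame(group = c("EF", "EF", "NEF"),
                    n_branches = c(3, 7, 12),
                    q = c(0.05, 0.5, 0.01))
  bins <- bin_eds_rates(res, increment = 5)
  expect_equal(bins$bin[bins$group == "EF"], c(0, 1))
  expect_equal(bins$bin[bins$group == "NEF"], 2)
  expect_equal(bins$rate[bins$group == "EF" & bins$bin == 0], 1)
  expect_equal(nrow(bin_eds_rates(res[0, ])), 0)
  expect_error(bin_eds_rates(res, increment = 0), "increment")
})

test_that("the intensity exponent shifts omega in the documented direction", {
  d <- list(omega = c(0.1, 0.8, 2.0), weight = c(0.5, 0.4, 0.1))
  relax <- lsgfevo:::apply_k(d, 0.4)
  intens <- lsgfevo:::apply_k(d, 2.5)
  # omega < 1 rises toward 1 under relaxation, falls under intensification
  expect_gt(relax$omega[1], d$omega[1])
  expect_lt(intens$omega[1], d$omega[1])
  # omega > 1 falls toward 1 under relaxation, rises under intensification
  expect_lt(relax$omega[3], d$omega[3])
  expect_gt(intens$omega[3], d$omega[3])
  expect_identical(lsgfevo:::apply_k(d, 1)$omega, pmin(d$omega, 1e4))
})

# shared small fixture for the model-fit contracts
sim8 <- simulate_species_tree(8, c(EF = 0.5, HE = 0.5), seed = 19)
part8 <- label_branches(sim8$tree, sim8$categories)
cfg8 <- simulation_config(seed = 19)
groups8 <- list(EF = cfg8$omega_ref, HE = cfg8$omega_ref)
seqs8 <- simulate_codon_alignment(sim8$tree, cfg8$pi, cfg8$rho, groups8,
                                  part8$edge_labels, 150, seed = 21, code = 6)
aln8 <- codon_alignment(seqs8, 6)
ctl_fast <- list(maxit_short = 40, maxit_final = 150, n_starts = 2)

test_that("RELAX fit honours nesting and model consistency", {
  rx <- fit_relax_groups(aln8, sim8$tree, part8, control = ctl_fast)
  expect_true(rx$testable)
  expect_equal(rx$reference, "EF")
  expect_gte(rx$lrt, 0)
  expect_equal(rx$df, 1)
  expect_true(rx$p_value >= 0 && rx$p_value <= 1)
  # setting K = 1 in the alternative reproduces the null likelihood
  pi <- f3x4_frequencies(aln8)
  gl <- list(EF = rx$reference_dist, HE = lsgfevo:::apply_k(rx$reference_dist, 1))
  ll_k1 <- codon_likelihood(aln8, sim8$tree, pi, rep(1, 6), gl, part8$edge_labels)
  # the alternative at K = 1 can only be as good as the null optimum
  expect_lte(as.numeric(ll_k1), rx$loglik_null + 1e-6)
  # descriptive fit-check exists and has finite criteria
  expect_true(is.finite(rx$fit_check$aicc_relax))
  expect_true(is.finite(rx$fit_check$aicc_descriptive))
})

test_that("BUSTED-style screen honours nesting and boundary p-values", {
  bs <- fit_busted_s(aln8, sim8$tree, part8, "HE", control = ctl_fast)
  expect_lte(bs$loglik_constrained, bs$loglik_unconstrained + 1e-6)
  expect_gte(bs$lrt, 0)
  expect_true(bs$p_value >= 0 && bs$p_value <= 1)
  # with an effectively zero LRT the boundary mixture gives p about 1
  if (bs$lrt <= 1e-9) expect_equal(bs$p_value, 1)
  expect_error(fit_busted_s(aln8, sim8$tree, part8, "KA"), "no labelled")
})

test_that("untestable partitions yield flagged RELAX results", {
  cats1 <- setNames(rep("EF", 8), sim8$tree$tip.label)
  part1 <- label_branches(sim8$tree, cats1)
  rx <- fit_relax_groups(aln8, sim8$tree, part1)
  expect_false(rx$testable)
})
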