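test_that("ENc hits Wright's analytic limits", {
  # maximal bias: one codon per amino acid, each used 5 times -> ENc = 20
  one_per_aa <- c("ATG", "TGG", "TTT", "TAT", "TGT", "CAT", "CAA", "AAT",
                  "AAA", "GAT", "GAA", "ATT", "GTT", "CCT", "ACT", "GCT",
                  "GGT", "TTA", "TCT", "CGT")
  s <- paste(rep(one_per_aa, each = 5), collapse = "")
  expect_equal(composition_stats(s, 1)$enc, 20)
  # uniform usage: every sense codon 10 times -> clamped at 61 and within 0.5
  sense <- genetic_code(1)$sense_codons
  su <- paste(rep(sense, each = 10), collapse = "")
  expect_lt(abs(composition_stats(su, 1)$enc - 61), 0.5)
  # convergence from below the clamp: biased usage approaches the maximum
  # as bias vanishes
  biased <- paste(c(rep("GGT", 30), rep("GGC", 10), rep("TTT", 20),
                    rep("TTC", 10), rep("ATG", 5)), collapse = "")
  expect_lt(composition_stats(biased, 1)$enc, 61)
})

test_that("ENc respects the genetic code's degeneracy classes", {
  # glutamine-only codon usage: 4-fold under table 6, 2-fold under table 1
  s <- paste(rep(c("CAA", "CAG", "TAA", "TAG"), each = 6), collapse = "")
  st6 <- composition_stats(s, 6)
  expect_true(is.finite(st6$enc))
  expect_error(composition_stats(s, 1), "stop")   # TAA/TAG are stops there
  # theoretical maximum under table 6 is its sense-codon count
  sense6 <- genetic_code(6)$sense_codons
  su6 <- paste(rep(sense6, each = 10), collapse = "")
  expect_lte(composition_stats(su6, 6)$enc, length(sense6))
})

test_that("GC3s counts third positions of four-fold boxes only", {
  # all four-fold codons end G/C
  expect_equal(composition_stats(strrep("GGCGCC", 20), 1)$gc3s, 1.0)
  # two-fold families contribute nothing to GC3s
  s <- paste(c(rep("TTC", 10), rep("GGA", 10)), collapse = "")  # Phe (2-fold), Gly (4-fold, A)
  expect_equal(composition_stats(s, 1)$gc3s, 0.0)
})

test_that("ENc is stable under duplication of codon counts", {
  withr::with_seed(5, {
    sense <- genetic_code(1)$sense_codons
    s <- paste(sample(sense, 150, replace = TRUE, prob = runif(61)), collapse = "")
    e1 <- composition_stats(s, 1)$enc
    e2 <- composition_stats(strrep(s, 2), 1)$enc
    e4 <- composition_stats(strrep(s, 4), 1)$enc
    einf <- composition_stats(strrep(s, 64), 1)$enc   # large-n limit proxy
    # doubling counts moves the estimator monotonically toward its
    # large-n value (the p_i terms are exactly scale-invariant; only the
    # small-sample bias correction shrinks)
    expect_lte(abs(e4 - einf), abs(e2 - einf) + 1e-9)
    expect_lte(abs(e2 - einf), abs(e1 - einf) + 1e-9)
  })
})

test_that("composition_stats validates its input", {
  expect_error(composition_stats("ATGA", 1), "divisible")
  expect_error(composition_stats("ATGTAAGGG", 1), "stop")
})

test_that("percentile band uses interpolated bounds and closed intervals", {
  ref <- seq(0.1, 1.0, by = 0.1)
  band <- percentile_band(ref, 10, 90)
  expect_equal(band$lower, unname(quantile(ref, 0.1)))
  expect_equal(band$upper, unname(quantile(ref, 0.9)))
  cand <- data.frame(record_id = c("in", "low_edge", "high_edge", "out"),
                     taxon = "t", n_codons = 100,
                     gc3s = c(0.5, band$lower, band$upper, 0.05),
                     enc = 45)
  flt <- composition_band_filter(cand, band)
  expect_setequal(flt$kept$record_id, c("in", "low_edge", "high_edge"))
  expect_equal(flt$discarded$reason, "gc3s_below")
  expect_error(percentile_band(numeric(0)), "nonempty")
})

test_that("band filtering is idempotent", {
  withr::with_seed(8, {
    cand <- data.frame(record_id = sprintf("r%d", 1:50), taxon = "t",
                       n_codons = 100, gc3s = runif(50), enc = 45)
    band <- percentile_band(runif(30, 0.3, 0.9))
    f1 <- composition_band_filter(cand, band)
    f2 <- composition_band_filter(f1$kept, band)
    expect_identical(f2$kept$record_id, f1$kept$record_id)
    expect_equal(nrow(f2$discarded), 0)
  })
})
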