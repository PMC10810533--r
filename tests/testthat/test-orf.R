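test_that("largest complete ORF is recovered with correct coordinates", {
  tx <- paste0("ATG", strrep("AAA", 200), "TGA")
  orf <- call_orfs(tx, code = 6, min_aa = 100)
  expect_equal(nrow(orf), 1)
  expect_identical(orf$protein, paste0("M", strrep("K", 200)))
  expect_equal(orf$start, 0)
  expect_equal(orf$end, 603)                # stop codon excluded
  expect_equal(nchar(orf$nt), 3 * nchar(orf$protein))
})

test_that("stop-codon reassignment changes ORF boundaries between codes", {
  tx <- paste0("CC", "ATG", strrep("AAA", 120), "TAA", strrep("GGA", 120), "TGACC")
  o1 <- call_orfs(tx, code = 1, min_aa = 50)
  o6 <- call_orfs(tx, code = 6, min_aa = 50)
  expect_equal(nchar(o1$protein), 121)      # terminates at TAA
  expect_equal(nchar(o6$protein), 242)      # TAA read through as Gln
  expect_true(grepl("Q", o6$protein))
})

test_that("min_aa filtering, empty and invalid input behave as specified", {
  tx <- paste0("ATG", strrep("AAA", 30), "TGA")
  expect_equal(nrow(call_orfs(tx, 1, min_aa = 200)), 0)
  expect_equal(nrow(call_orfs("", 1)), 0)
  expect_error(call_orfs("ATGZZZ", 1), "position 4")
})

test_that("ORF calls match the exhaustive scanner on random sequences", {
  withr::with_seed(42, {
    for (rep in 1:10) {
      tx <- random_transcript(sample(1500:3000, 1))
      for (code in c(1, 6, 10)) {
        got <- call_orfs(tx, code, min_aa = 30)
        want <- brute_force_orf(tx, code, min_aa = 30)
        if (is.null(want)) {
          expect_equal(nrow(got), 0)
        } else {
          expect_equal(nchar(got$protein), want$len)
          expect_identical(got$nt, want$cds)
        }
      }
    }
  })
})

test_that("ORF call is invariant under flanks appended after the stop", {
  withr::with_seed(7, {
    tx <- paste0("GG", "ATG", strrep("GAA", 150), "TAATGA")
    o1 <- call_orfs(tx, 1, min_aa = 50)
    o2 <- call_orfs(paste0(tx, random_transcript(100)), 1, min_aa = 50)
    expect_identical(o1$nt, o2$nt)
    expect_identical(o1$frame, o2$frame)
  })
})

test_that("allelic dedupe clusters identical and near-identical sequences", {
  withr::with_seed(3, {
    base <- random_transcript(600)
    orfs <- data.frame(record_id = c("a", "b"), nt = c(base, base))
    dd <- dedupe_allelic_variants(orfs)
    expect_equal(nrow(dd$representatives), 1)
    expect_equal(nrow(dd$clusters), 2)
    # ~90% identity: below the 0.97 threshold
    s <- strsplit(base, "")[[1]]
    pos <- sample(600, 60)
    for (p in pos) s[p] <- setdiff(c("A", "C", "G", "T"), s[p])[1]
    orfs2 <- data.frame(record_id = c("a", "b"), nt = c(base, paste(s, collapse = "")))
    dd2 <- dedupe_allelic_variants(orfs2)
    expect_equal(nrow(dd2$representatives), 2)
  })
})

test_that("dedupe output is a partition with longest-first representatives", {
  withr::with_seed(11, {
    seqs <- replicate(12, random_transcript(sample(300:500, 1)))
    # add 4 alleles of the first four sequences (2% divergence)
    alleles <- vapply(seqs[1:4], function(x) {
      s <- strsplit(x, "")[[1]]
      pos <- sample(length(s), ceiling(0.02 * length(s)))
      for (p in pos) s[p] <- setdiff(c("A", "C", "G", "T"), s[p])[1]
      paste(s, collapse = "")
    }, character(1))
    orfs <- data.frame(record_id = sprintf("r%02d", 1:16), nt = c(seqs, alleles))
    dd <- dedupe_allelic_variants(orfs)
    expect_setequal(dd$clusters$member_id, orfs$record_id)   # partition
    expect_equal(anyDuplicated(dd$clusters$member_id), 0)
    expect_equal(nrow(dd$representatives), 12)
    lens <- setNames(nchar(orfs$nt), orfs$record_id)
    for (i in seq_len(nrow(dd$clusters))) {
      expect_gte(lens[dd$clusters$representative_id[i]], lens[dd$clusters$member_id[i]])
    }
  })
})

test_that("invalid identity threshold is rejected", {
  expect_error(dedupe_allelic_variants(data.frame(record_id = "a", nt = "ACGT"),
                                       identity = 1.5), "identity")
})
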