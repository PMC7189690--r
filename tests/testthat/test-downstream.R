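test_that("consequence classification follows the LoF/Dmis/splice rules", {
  r <- classify_consequence("stopgain")
  expect_equal(as.character(r$class), "LoF")
  expect_true(r$damaging)

  r <- classify_consequence("missense", revel = 0.6)
  expect_equal(as.character(r$class), "Dmis")
  expect_true(r$damaging)

  r <- classify_consequence("missense", revel = 0.5)   # not strictly above
  expect_equal(as.character(r$class), "Bmis")
  expect_false(r$damaging)

  r <- classify_consequence("synonymous", splice_delta = 0.3)
  expect_equal(as.character(r$class), "synonymous")
  expect_false(r$damaging)

  r <- classify_consequence("synonymous", splice_delta = 0.7)
  expect_equal(as.character(r$class), "splice_damaging")
  expect_true(r$damaging)

  r <- classify_consequence("missense", revel = 0.2, splice_delta = 0.8)
  expect_equal(as.character(r$class), "splice_damaging")
})

test_that("classification is total and the damaging flag is its complement", {
  eff <- c("stopgain", "stoploss", "frameshift", "canonical_splice",
           "missense", "missense", "synonymous", "synonymous")
  r <- classify_consequence(eff,
                            revel = c(NA, NA, NA, NA, 0.9, 0.1, NA, NA),
                            splice_delta = c(NA, NA, NA, NA, NA, NA, 0.9, NA))
  expect_false(any(is.na(r$class)))
  expect_equal(r$damaging,
               r$class %in% c("LoF", "Dmis", "splice_damaging"))
  # missing scores are conservative and flagged
  m <- classify_consequence("missense")
  expect_false(m$damaging)
  expect_true(m$score_missing)
  expect_error(classify_consequence("intergenic"), "unknown effect")
  expect_error(classify_consequence("missense", revel = 1.4), "0, 1")
})

test_that("CpG substitutions are recognized on both strands", {
  sp <- mutation_spectrum(c("C", "G", "C"), c("T", "A", "A"),
                          c("ACG", "CGT", "ACT"))
  expect_equal(sp$cpg_count, 2L)       # ACG direct; CGT via G>A collapse
  expect_equal(sp$total, 3L)
  expect_equal(sum(sp$counts), sp$total)
})

test_that("the reference CpG tally reproduces the printed percentage", {
  n_cpg <- 979L
  n_tot <- 2662L
  sp <- mutation_spectrum(rep("C", n_tot), rep("T", n_tot),
                          rep(c("ACG", "ACT"), c(n_cpg, n_tot - n_cpg)))
  expect_equal(sp$cpg_count, n_cpg)
  expect_equal(sp$total, n_tot)
  expect_equal(sp$cpg_fraction, n_cpg / n_tot)
  expect_equal(round(100 * sp$cpg_fraction), 37)
})

test_that("records with inconsistent context are flagged, counts conserved", {
  sp <- mutation_spectrum(c("C", "C", "A"), c("T", "G", "C"),
                          c("ACG", "ATT", "CAC"))
  expect_equal(sp$bad_context, 2L)     # middle base T disagrees with ref C
  expect_equal(sp$total, 2L)
  expect_equal(sum(sp$counts), sp$total)
})

test_that("identical VAF groups give a rank-sum p of 1", {
  r <- vaf_group_comparison(c(0.1, 0.2, 0.3), c(0.1, 0.2, 0.3))
  expect_equal(r$p.value, 1)
})

test_that("small-sample p-values equal exhaustive permutation enumeration", {
  x <- c(0.3, 0.31, 0.32)
  y <- c(0.05, 0.06, 0.07)
  r <- vaf_group_comparison(x, y)
  expect_equal(r$p.value, ranksum_perm_oracle(x, y))
  expect_equal(r$p.value, 0.1)   # 2 of the 20 splits are as extreme

  # with ties, and unbalanced groups
  cases <- list(
    list(x = c(0.1, 0.2, 0.2, 0.35), y = c(0.2, 0.3, 0.4)),
    list(x = c(0.05, 0.05), y = c(0.05, 0.1, 0.1, 0.3)),
    list(x = c(0.12, 0.2, 0.28, 0.31, 0.44), y = c(0.1, 0.15, 0.2, 0.33, 0.5))
  )
  for (cs in cases) {
    expect_equal(vaf_group_comparison(cs$x, cs$y)$p.value,
                 ranksum_perm_oracle(cs$x, cs$y))
  }
  expect_error(vaf_group_comparison(numeric(0), 1), "non-empty")
})

test_that("a paper-scale VAF shift is detected in most replicates", {
  set.seed(500)
  hits <- replicate(200, {
    a <- rbeta(40, 2, 11.3) + 0.08
    b <- rbeta(40, 2, 11.3)
    vaf_group_comparison(a, b)$p.value < 0.05
  })
  expect_gte(mean(hits), 0.9)
})

test_that("amplicon VAF classification uses the post-zygotic window", {
  expect_equal(as.character(classify_validation(0.13)), "mosaic_confirmed")
  expect_equal(as.character(classify_validation(0.48)), "germline")
  expect_equal(as.character(classify_validation(0.0005)), "no_variant")
  # boundary semantics: 0.01 and 0.45 are outside the confirmed interval
  expect_equal(as.character(classify_validation(c(0.01, 0.45))),
               c("no_variant", "germline"))
  expect_equal(as.character(classify_validation(0.011)), "mosaic_confirmed")
})
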