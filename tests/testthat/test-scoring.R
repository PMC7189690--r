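test_that("the likelihood ratio is exactly 1 when the site VAF equals p0", {
  expect_equal(mosaic_lr(49, 100, p0 = 0.49, rho = 0), 1)
  expect_equal(mosaic_lr(49, 100, p0 = 0.49, rho = 0.02), 1)
})

test_that("the likelihood ratio matches a direct pmf-ratio oracle", {
  lr <- mosaic_lr(6, 60, p0 = 0.49, rho = 0.01)
  oracle <- bb_pmf_oracle(6, 60, 6 / 60, 0.01) /
    bb_pmf_oracle(6, 60, 0.49, 0.01)
  expect_equal(lr, oracle, tolerance = 1e-7)
  expect_gt(lr, 100)
})

test_that("evidence grows as the count drops below the germline mean", {
  expect_gt(mosaic_lr(25, 60, 0.49, 0.01), mosaic_lr(29, 60, 0.49, 0.01))
  lrs <- mosaic_lr(1:floor(60 * 0.49), 60, 0.49, 0.01)
  expect_true(all(diff(lrs) < 0))
})

test_that("the zero-count mosaic mean is clamped, not degenerate", {
  expect_true(is.finite(mosaic_lr(0, 60, 0.49, 0.01, log = TRUE)))
  expect_true(is.finite(mosaic_lr(60, 60, 0.49, 0.01, log = TRUE)))
})

test_that("posterior odds combine the likelihood ratio with the prior", {
  expect_equal(posterior_odds(1, 0.5), 1)
  expect_equal(posterior_odds(2, 0.1215), 2 * 0.1215 / 0.8785)
  expect_equal(posterior_odds(2, 0.1215, prior_form = "probability"),
               2 * 0.1215)
  # inverting the odds formula recovers the likelihood ratio needed at the
  # calling threshold
  lr_needed <- 10 * (1 - 0.1215) / 0.1215
  expect_equal(posterior_odds(lr_needed, 0.1215), 10)
})

test_that("the per-call FDR bound is 1 / (1 + cutoff)", {
  expect_equal(odds_fdr_bound(10), 1 / 11)
  expect_equal(round(100 * odds_fdr_bound(10), 1), 9.1)
})

test_that("two-sided germline p-values are valid probabilities", {
  p <- mosaic_pvalue(c(0, 6, 29, 30, 60), 60, p0 = 0.49, rho = 0.02)
  expect_true(all(p > 0 & p <= 1))
  # the mode of the null has a p-value near 1, deep tails near 0
  expect_gt(p[3], 0.8)
  expect_lt(p[2], 1e-4)
})

test_that("calls are labelled by posterior odds and sorted by evidence", {
  sites <- data.frame(n_alt = c(6, 14, 20, 25, 29),
                      depth = rep(60, 5))
  calls <- call_mosaics(sites, pi = 0.1215, p0 = 0.49, rho = 0.01)
  expect_true(all(diff(calls$post_odds) <= 0))
  expect_equal(calls$label[calls$post_odds > 10][1], "mosaic")
  expect_true(all(calls$label[calls$post_odds <= 1] == "germline"))
  expect_true(all(calls$label[calls$post_odds > 1 &
                                calls$post_odds <= 10] == "ambiguous"))
  expect_true(all(calls$fdr_bound > 0 & calls$fdr_bound <= 1))
  expect_equal(calls$fdr_bound, 1 / (1 + calls$post_odds))
})

test_that("threshold rule: odds 25 is mosaic, odds 4.7 is ambiguous", {
  cfg <- mosaic_config(odds_cutoff = 10)
  lab <- function(odds) {
    ifelse(odds > cfg$odds_cutoff, "mosaic",
           ifelse(odds > 1, "ambiguous", "germline"))
  }
  expect_equal(lab(25), "mosaic")
  expect_equal(lab(4.7), "ambiguous")
  expect_equal(lab(0.3), "germline")
})

test_that("the probability prior form rescales odds by exactly 1 - pi", {
  sites <- data.frame(n_alt = c(5, 9, 14, 22, 30), depth = rep(60, 5))
  a <- call_mosaics(sites, 0.12, 0.5, 0.02)
  b <- call_mosaics(sites, 0.12, 0.5, 0.02,
                    config = mosaic_config(prior_form = "probability"))
  expect_equal(b$post_odds / a$post_odds, rep(1 - 0.12, 5))
})
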