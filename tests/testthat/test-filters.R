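base_site <- function(...) {
  s <- data.frame(
    sample_id = "trio0001", chrom = "1", pos = 1000L, ref = "C", alt = "T",
    proband_depth = 60L, proband_alt = 12L,
    father_depth = 30L, father_alt = 0L,
    mother_depth = 30L, mother_alt = 0L,
    ref_fwd = 24L, ref_rev = 24L, alt_fwd = 6L, alt_rev = 6L,
    stringsAsFactors = FALSE
  )
  args <- list(...)
  for (nm in names(args)) s[[nm]] <- args[[nm]]
  s
}

failed <- function(v, name) grepl(name, v$failed_filters, fixed = TRUE)

test_that("the de novo candidate rule enforces proband and parent support", {
  suppressWarnings({
    v <- mosaic_prefilter(base_site())
    expect_true(v$passed)
    v <- mosaic_prefilter(base_site(proband_alt = 5L, alt_fwd = 3L,
                                    alt_rev = 2L))
    expect_true(failed(v, "min_proband_alt"))
    v <- mosaic_prefilter(base_site(proband_alt = 6L, alt_fwd = 3L,
                                    alt_rev = 3L, father_depth = 12L,
                                    mother_depth = 15L))
    expect_true(v$passed)
    v <- mosaic_prefilter(base_site(father_alt = 1L))
    expect_true(failed(v, "parent_alt"))
    v <- mosaic_prefilter(base_site(mother_depth = 9L))
    expect_true(failed(v, "parent_depth"))
    v <- mosaic_prefilter(base_site(father_depth = NA))
    expect_true(failed(v, "missing_parent"))
  })
})

test_that("rarity, depth cap and missing population AF behave as specified", {
  suppressWarnings({
    v <- mosaic_prefilter(base_site(pop_af = 5e-4))
    expect_true(failed(v, "rarity"))
    v <- mosaic_prefilter(base_site(pop_af = 5e-5))
    expect_true(v$passed)
    deep <- base_site(proband_depth = 501L, proband_alt = 250L,
                      ref_fwd = 126L, ref_rev = 125L, alt_fwd = 125L,
                      alt_rev = 125L)
    v <- mosaic_prefilter(deep)
    expect_true(failed(v, "max_depth"))
    v <- mosaic_prefilter(base_site())   # pop_af absent: treated as 0
    expect_true(v$passed)
    expect_true(v$pop_af_missing)
  })
})

test_that("BED exclusion regions use the 1-based variant convention", {
  bed <- tempfile(fileext = ".bed")
  writeLines("1\t99\t200\tsegdup", bed)   # 0-based half-open: bases 100..200
  gr <- read_exclusion_bed(bed)
  expect_equal(GenomicRanges::start(gr), 100L)
  expect_equal(GenomicRanges::end(gr), 200L)
  suppressWarnings({
    v_in <- mosaic_prefilter(base_site(pos = 100L), regions = gr)
    v_edge <- mosaic_prefilter(base_site(pos = 200L), regions = gr)
    v_out <- mosaic_prefilter(base_site(pos = 99L), regions = gr)
  })
  expect_true(failed(v_in, "region_exclusion"))
  expect_true(failed(v_edge, "region_exclusion"))
  expect_true(v_out$passed)
  suppressWarnings(
    expect_error(read_exclusion_bed(tempfile()), "malformed|cannot")
  )
})

test_that("PV4 bias cutoffs fail biased sites and skip missing ones", {
  suppressWarnings({
    v <- mosaic_prefilter(base_site(pv4_baseq = 5e-4, pv4_mapq = 0.5,
                                    pv4_taildist = 0.5))
    expect_true(failed(v, "pv4_bias"))
    v <- mosaic_prefilter(base_site(pv4_baseq = 0.5, pv4_mapq = 1e-5,
                                    pv4_taildist = 0.5))
    expect_true(v$passed)   # 1e-5 >= the 1e-6 mapQ cutoff
    v <- mosaic_prefilter(base_site(pv4_mapq = 1e-7, pv4_baseq = 0.5,
                                    pv4_taildist = 0.5))
    expect_true(failed(v, "pv4_bias"))
    v <- mosaic_prefilter(base_site())
    expect_true(v$passed)
    expect_true(v$pv4_missing)
  })
})

test_that("strand bias fails one-strand support and Fisher-extreme tables", {
  suppressWarnings({
    v <- mosaic_prefilter(base_site(alt_fwd = 10L, alt_rev = 0L,
                                    proband_alt = 10L))
    expect_true(failed(v, "strand_zero"))
    v <- mosaic_prefilter(base_site(ref_fwd = 26L, ref_rev = 26L,
                                    alt_fwd = 8L, alt_rev = 8L,
                                    proband_alt = 16L, proband_depth = 68L))
    expect_true(v$passed)
    skew <- base_site(ref_fwd = 80L, ref_rev = 20L, alt_fwd = 2L,
                      alt_rev = 18L, proband_alt = 20L,
                      proband_depth = 120L)
    v <- mosaic_prefilter(skew)
  })
  expect_equal(v$strand_p, fisher_p_oracle(80, 20, 2, 18), tolerance = 1e-9)
  expect_equal(v$strand_or, (80 * 18) / (20 * 2))
  expect_true(failed(v, "strand_fisher"))
  expect_error(strand_bias_test(-1, 5, 3, 3), "non-negative")
})

test_that("cohort-level recurrence, outlier and cluster rules fire", {
  # 100 samples, one unique site each; the variant at 5:777 recurs in 2
  # samples (2% > 1%); trio0002 carries 9 further sites (outlier); trio0003
  # has a 9 bp pair (cluster) and trio0004 an 11 bp pair (no cluster)
  rows <- list()
  for (i in 1:100) {
    rows[[length(rows) + 1]] <- base_site(
      sample_id = sprintf("trio%04d", i), chrom = "2",
      pos = 10000L + 1000L * i)
  }
  rows[[length(rows) + 1]] <- base_site(sample_id = "trio0001", chrom = "5",
                                        pos = 777L)
  rows[[length(rows) + 1]] <- base_site(sample_id = "trio0002", chrom = "5",
                                        pos = 777L)
  for (j in 1:9) {
    rows[[length(rows) + 1]] <- base_site(sample_id = "trio0002", chrom = "7",
                                          pos = 5000L + 100L * j)
  }
  rows[[length(rows) + 1]] <- base_site(sample_id = "trio0003", chrom = "9",
                                        pos = 1000L)
  rows[[length(rows) + 1]] <- base_site(sample_id = "trio0003", chrom = "9",
                                        pos = 1009L)
  rows[[length(rows) + 1]] <- base_site(sample_id = "trio0004", chrom = "9",
                                        pos = 2000L)
  rows[[length(rows) + 1]] <- base_site(sample_id = "trio0004", chrom = "9",
                                        pos = 2011L)
  sites <- do.call(rbind, rows)
  v <- mosaic_prefilter(sites)

  rec <- sites$chrom == "5" & sites$pos == 777L
  expect_true(all(failed(v, "cohort_recurrence")[rec]))
  expect_false(any(failed(v, "cohort_recurrence")[!rec]))

  out2 <- sites$sample_id == "trio0002"
  expect_true(all(failed(v, "outlier_sample")[out2]))    # 11 sites > 8
  expect_false(any(failed(v, "outlier_sample")[!out2]))

  cl3 <- sites$sample_id == "trio0003" & sites$chrom == "9"
  cl4 <- sites$sample_id == "trio0004" & sites$chrom == "9"
  expect_true(all(failed(v, "snv_cluster")[cl3]))
  expect_false(any(failed(v, "snv_cluster")[cl4]))
})

test_that("exactly 8 candidate dnSNVs does not trip the outlier rule", {
  rows <- lapply(1:8, function(j) {
    base_site(sample_id = "trioA", chrom = "3", pos = 1000L * j)
  })
  rows <- c(rows, list(base_site(sample_id = "trioB", chrom = "4",
                                 pos = 5000L)))
  v <- mosaic_prefilter(do.call(rbind, rows))
  expect_false(any(failed(v, "outlier_sample")))
})

test_that("the minimum-N_alt threshold matches a tail-sum oracle and is
           monotone in depth", {
  cfg <- filter_config()
  thr60 <- min_nalt_fdr_threshold(60, cfg)
  target <- cfg$nalt_fdr_budget * cfg$expected_candidates
  exp_false <- function(m, n) {
    cfg$callable_sites * sum(dbinom(m:n, n, cfg$error_rate / 3))
  }
  # the unfloored threshold satisfies the budget, its predecessor does not
  m_raw <- 1
  while (exp_false(m_raw, 60) > target) m_raw <- m_raw + 1
  expect_equal(thr60, max(m_raw, cfg$min_proband_alt))
  expect_lte(exp_false(thr60, 60), target)

  # vanishing error rate leaves only the de novo candidate floor
  tiny <- filter_config(error_rate = 1e-12)
  expect_equal(min_nalt_fdr_threshold(c(40, 60, 200), tiny),
               rep(tiny$min_proband_alt, 3))

  thr <- min_nalt_fdr_threshold(c(20, 60, 120, 200, 350, 500), cfg)
  expect_true(all(diff(thr) >= 0))
  expect_gte(min_nalt_fdr_threshold(200, cfg),
             min_nalt_fdr_threshold(60, cfg))
})

test_that("the cascade is idempotent and calibrated on synthetic cohorts", {
  co <- simulate_cohort(sim_config(n_trios = 1200, sites_per_trio = 2,
                                   seed = 12))
  v <- mosaic_prefilter(co$sites)
  clean <- co$truth$truth_label != "artifact"
  expect_gte(mean(v$passed[clean]), 0.99)
  expect_gte(mean(!v$passed[!clean]), 0.95)

  surviving <- co$sites[v$passed, , drop = FALSE]
  v2 <- mosaic_prefilter(surviving)
  expect_true(all(v2$passed))

  # every failure is recorded, not only the first
  multi <- base_site(proband_alt = 4L, alt_fwd = 4L, alt_rev = 0L,
                     father_alt = 2L)
  suppressWarnings(vm <- mosaic_prefilter(multi))
  expect_true(all(failed(vm, "min_proband_alt") & failed(vm, "parent_alt") &
                    failed(vm, "strand_zero")))
  aud <- write_filter_audit(vm)
  expect_gte(nrow(aud), 3)
  expect_true(all(c("min_proband_alt", "parent_alt") %in% aud$filter))
})
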