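test_that("germline-like fractions are essentially undetectable", {
  expect_lt(detection_power(60, 0.5), 0.01)
  expect_lt(detection_power(200, 0.5), 0.01)
  expect_lt(detection_power(500, 0.5), 0.01)
})

test_that("power rises with depth and with a laxer cutoff", {
  pg <- power_curve(c(40, 60, 80, 160, 300, 500), c(0.05, 0.1, 0.2))
  expect_true(all(pg$power >= 0 & pg$power <= 1))
  for (j in seq_along(pg$vafs)) {
    expect_true(all(diff(pg$power[, j]) >= -1e-12))
  }
  lax <- power_curve(c(40, 60, 80, 160, 300, 500), c(0.05, 0.1, 0.2),
                     odds_cutoff = 2)
  expect_true(all(lax$power - pg$power >= -1e-12))
})

test_that("analytic power equals the Monte Carlo detection rate", {
  pi0 <- 0.1215; p00 <- 0.49; r0 <- 0.02
  set.seed(99)
  for (vv in c(0.1, 0.2)) {
    pred <- detection_power(60, vv, pi = pi0, p0 = p00, rho = r0)
    k <- rbetabinom(100000, 60, vv, r0)
    odds <- posterior_odds(mosaic_lr(k, 60, p00, r0), pi0)
    emp <- mean(odds > 10 & k >= min_nalt_fdr_threshold(60))
    se <- sqrt(emp * (1 - emp) / 100000)
    expect_lt(abs(pred - emp), 3 * se)
  }
})

test_that("an empirical depth distribution averages the per-depth power", {
  depths <- c(40, 40, 80)
  avg <- detection_power(depths, 0.1)
  byhand <- (2 * detection_power(40, 0.1) + detection_power(80, 0.1)) / 3
  expect_equal(avg, byhand)
})

test_that("the inverse-power adjustment divides bin counts by bin power", {
  v <- c(0.12, 0.13, 0.22)
  af <- adjust_true_frequency(v, depth = 60, cohort_size = 100)
  p1 <- detection_power(60, 0.125)
  p3 <- detection_power(60, 0.225)
  expect_equal(af$adjusted_count, 2 / p1 + 1 / p3)
  expect_equal(af$observed_count, 3L)
  expect_gte(af$adjusted_count, af$observed_count)
  expect_equal(af$per_individual, af$adjusted_count / 100)
  # adjustment scales linearly in counts and inversely in cohort size
  af2 <- adjust_true_frequency(rep(v, 2), depth = 60, cohort_size = 200)
  expect_equal(af2$adjusted_count, 2 * af$adjusted_count)
  expect_equal(af2$per_individual, af$per_individual)
})

test_that("vanishing bin power aborts instead of exploding", {
  expect_error(
    adjust_true_frequency(0.47, depth = 60, cohort_size = 100,
                          vaf_ceiling = 0.5),
    "power below")
})

test_that("per-individual arithmetic reproduces the container contract", {
  af <- adjusted_frequency(184, 361, 2530)
  expect_equal(af$per_individual, 361 / 2530)
  expect_error(adjusted_frequency(10, 5, 100), "cannot be below")
})

test_that("the adjusted count tracks simulated truth within 2 SE", {
  for (s in c(1, 2)) {
    co <- simulate_cohort(sim_config(n_trios = 3000, sites_per_trio = 1.2,
                                     pi_true = 0.12, rho_true = 0.02,
                                     artifact_rate = 0,
                                     min_candidate_alt = 0, seed = s))
    mf <- trio_model_frame(co$sites)
    keep <- mf$n_alt >= min_nalt_fdr_threshold(mf$depth)
    sc <- call_mosaics(mf[keep, ], pi = 0.12, p0 = 0.5, rho = 0.02)
    lab <- truth_labels_for(sc, co$truth)
    v <- sc$vaf[sc$label == "mosaic" & lab == "mosaic" &
                  sc$vaf > 0.1 & sc$vaf < 0.4]
    truth_n <- sum(co$truth$truth_label == "mosaic" &
                     co$truth$true_vaf > 0.1 & co$truth$true_vaf < 0.4)
    breaks <- seq(0.1, 0.4, 0.05)
    pw <- vapply(breaks[-length(breaks)] + 0.025, function(m) {
      detection_power(mf$depth, m, pi = 0.12, p0 = 0.5, rho = 0.02)
    }, numeric(1))
    cnt <- as.numeric(table(cut(v, breaks, right = FALSE)))
    adjusted <- sum(cnt / pw)
    se <- sqrt(sum(cnt / pw^2))   # counting-process (Poisson) bootstrap SE
    expect_lt(abs(adjusted - truth_n), 2 * se)
  }
})
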