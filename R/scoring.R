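#' Model configuration for mosaic scoring
#'
#' Collects the tunable parameters of the mosaic/germline scoring model.
#'
#' @param odds_cutoff posterior-odds threshold above which a site is called
#'   mosaic (default 10, giving a per-call false discovery bound of
#'   `1 / (1 + 10)` = 9.1%).
#' @param depth_bin_max maximum depth used when binning sites for the
#'   overdispersion fit (default 500).
#' @param em_tol convergence tolerance on the prior mosaic fraction
#'   (default 1e-6).
#' @param em_max_iter EM iteration cap (default 1000).
#' @param p0_mode `"re-estimated"` (default) updates the germline mean VAF
#'   inside the EM by a conditional-maximization step; `"fixed"` keeps it at
#'   its initial value (the observed mean VAF of near-heterozygous sites).
#' @param prior_form `"odds"` multiplies the likelihood ratio by the prior
#'   odds `pi / (1 - pi)` (proper Bayes); `"probability"` multiplies by `pi`
#'   itself, for exact reproduction of the legacy formulation. The two differ
#'   by the factor `1 - pi`.
#' @return A list of class `"mosaic_config"`.
#' @examples
#' mosaic_config(odds_cutoff = 5)
#' @export
mosaic_config <- function(odds_cutoff = 10, depth_bin_max = 500L,
                          em_tol = 1e-6, em_max_iter = 1000L,
                          p0_mode = c("re-estimated", "fixed"),
                          prior_form = c("odds", "probability")) {
  stopifnot(odds_cutoff > 0, em_tol > 0, em_max_iter >= 1, depth_bin_max >= 1)
  structure(
    list(odds_cutoff = odds_cutoff,
         depth_bin_max = as.integer(depth_bin_max),
         em_tol = em_tol,
         em_max_iter = as.integer(em_max_iter),
         p0_mode = match.arg(p0_mode),
         prior_form = match.arg(prior_form)),
    class = "mosaic_config"
  )
}

#' @export
print.mosaic_config <- function(x, ...) {
  cat("Mosaic scoring configuration\n")
  for (nm in names(x)) cat(sprintf("  %-12s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

#' Per-site likelihood ratio of the mosaic versus germline model
#'
#' Compares M1 (mosaic: beta-binomial with the site's own VAF `n_alt / depth`
#' as mean) against M0 (germline heterozygote: beta-binomial with the cohort
#' germline mean VAF `p0`), both with the same overdispersion `rho`. When
#' `n_alt = 0` (or `n_alt = depth`) the M1 mean degenerates and is clamped to
#' `1 / (2 * depth)` (resp. `1 - 1 / (2 * depth)`).
#'
#' Computation is in log space; `mosaic_lr()` returns the ratio on the
#' natural scale (which may overflow to `Inf` for extreme sites — use
#' `log = TRUE` for downstream arithmetic).
#'
#' @param n_alt alternate-allele read counts.
#' @param depth total site depths.
#' @param p0 germline mean VAF, in (0, 1).
#' @param rho beta-binomial overdispersion.
#' @param log if `TRUE` return the log likelihood ratio.
#' @return Numeric vector of likelihood ratios (>= 0).
#' @examples
#' mosaic_lr(49, 100, p0 = 0.49, rho = 0)   # exactly 1: the models coincide
#' mosaic_lr(6, 60, p0 = 0.49, rho = 0.01)  # strong mosaic evidence
#' @export
mosaic_lr <- function(n_alt, depth, p0, rho = 0, log = FALSE) {
  stopifnot(all(p0 > 0 & p0 < 1), all(n_alt >= 0), all(n_alt <= depth))
  p1 <- n_alt / depth
  p1 <- pmin(pmax(p1, 1 / (2 * depth)), 1 - 1 / (2 * depth))
  llr <- dbetabinom(n_alt, depth, p1, rho, log = TRUE) -
    dbetabinom(n_alt, depth, p0, rho, log = TRUE)
  if (log) llr else exp(llr)
}

#' Posterior odds that a site is mosaic
#'
#' Multiplies the likelihood ratio by the prior odds of mosaicism. With
#' `prior_form = "odds"` the multiplier is `pi / (1 - pi)`; with
#' `"probability"` it is `pi` itself (legacy formulation). At a cutoff `C`
#' on the posterior odds, the per-call false discovery bound is
#' `1 / (1 + C)`.
#'
#' @param lr likelihood ratio(s), >= 0 (`mosaic_lr()`).
#' @param pi prior mosaic fraction in (0, 1).
#' @param prior_form `"odds"` (default) or `"probability"`.
#' @return Numeric vector of posterior odds.
#' @examples
#' posterior_odds(1, 0.5)              # 1: uninformative likelihood, even prior
#' odds_fdr_bound(10)                  # 0.0909... = 9.1%
#' @export
posterior_odds <- function(lr, pi, prior_form = c("odds", "probability")) {
  stopifnot(all(lr >= 0), pi > 0, pi < 1)
  prior_form <- match.arg(prior_form)
  mult <- if (prior_form == "odds") pi / (1 - pi) else pi
  lr * mult
}

#' @rdname posterior_odds
#' @param cutoff posterior-odds cutoff `C`.
#' @export
odds_fdr_bound <- function(cutoff) {
  stopifnot(all(cutoff > 0))
  1 / (1 + cutoff)
}

#' Two-sided tail probability under the germline model
#'
#' The lower tail `P(X <= n_alt)` under M0 (beta-binomial at the germline
#' mean VAF) is doubled against the opposing tail and capped at 1:
#' `p = min(1, 2 * min(P(X <= k), P(X >= k)))`.
#'
#' @inheritParams mosaic_lr
#' @return Two-sided p-values in (0, 1].
#' @export
mosaic_pvalue <- function(n_alt, depth, p0, rho = 0) {
  m <- max(length(n_alt), length(depth))
  n_alt <- rep_len(n_alt, m)
  depth <- rep_len(depth, m)
  lo <- pbetabinom(n_alt, depth, p0, rho)
  hi <- 1 - pbetabinom(n_alt - 1, depth, p0, rho)
  pmin(1, 2 * pmin(lo, hi))
}

#' Score candidate sites and call mosaics
#'
#' Applies the fitted model to every site: likelihood ratio, posterior odds,
#' two-sided germline-model p-value, per-call false discovery bound
#' `1 / (1 + odds)`, and a three-way label — `mosaic` when the posterior odds
#' exceed `odds_cutoff`, `ambiguous` when they lie in `(1, odds_cutoff]`,
#' `germline` otherwise. Rows are returned sorted by descending posterior
#' odds.
#'
#' @param sites data frame with columns `n_alt` and `depth` (any other
#'   columns are carried through).
#' @param pi prior mosaic fraction.
#' @param p0 germline mean VAF.
#' @param rho beta-binomial overdispersion.
#' @param config a [mosaic_config()].
#' @return The input data frame with added columns `vaf`, `log_lr`, `lr`,
#'   `post_odds`, `p_value`, `fdr_bound`, `label`.
#' @examples
#' sites <- data.frame(n_alt = c(6, 20, 29), depth = c(60, 60, 60))
#' call_mosaics(sites, pi = 0.1215, p0 = 0.49, rho = 0.01)
#' @export
call_mosaics <- function(sites, pi, p0, rho, config = mosaic_config()) {
  stopifnot(is.data.frame(sites), all(c("n_alt", "depth") %in% names(sites)))
  out <- sites
  out$vaf <- out$n_alt / out$depth
  out$log_lr <- mosaic_lr(out$n_alt, out$depth, p0, rho, log = TRUE)
  out$lr <- exp(out$log_lr)
  log_prior <- if (config$prior_form == "odds") log(pi) - log1p(-pi) else log(pi)
  log_odds <- out$log_lr + log_prior
  out$post_odds <- exp(log_odds)
  out$p_value <- mosaic_pvalue(out$n_alt, out$depth, p0, rho)
  # bound computed from log odds so that Inf odds give a bound of 0, not NaN
  out$fdr_bound <- 1 / (1 + out$post_odds)
  out$fdr_bound[is.infinite(out$post_odds)] <- 0
  out$label <- ifelse(out$post_odds > config$odds_cutoff, "mosaic",
                      ifelse(out$post_odds > 1, "ambiguous", "germline"))
  out[order(-out$post_odds), , drop = FALSE]
}
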