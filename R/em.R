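#' Estimate the prior mosaic fraction by expectation-maximization
#'
#' Fits a two-component mixture to the alternate-read counts of apparent
#' de novo SNVs. The germline component is beta-binomial with mean VAF `p0`
#' and read-level overdispersion `rho`. The mosaic component is beta-binomial
#' with its own mean `mosaic_mean` and overdispersion `mosaic_rho`; this is
#' exactly the marginal distribution of reads at a site whose true mosaic
#' fraction is itself Beta-distributed across sites (a Beta VAF law with
#' concentration `nu` corresponds to `mosaic_rho = 1 / (nu + 1)`).
#'
#' The E-step computes the per-site posterior probability of mosaic origin;
#' the M-step sets the prior fraction `pi` to the mean posterior (closed
#' form) and updates `mosaic_mean`, `mosaic_rho` (and `p0`, when
#' `p0_mode = "re-estimated"`) by bounded 1-D maximization of the weighted
#' likelihood (a conditional-maximization scheme, so the observed-data
#' log-likelihood is non-decreasing at every iteration). Iteration stops when
#' the change in `pi` drops below `config$em_tol`.
#'
#' @param n_alt,depth integer vectors of alternate-allele counts and total
#'   depths.
#' @param rho read-level beta-binomial overdispersion, usually from
#'   [fit_overdispersion()].
#' @param p0 initial (or fixed) germline mean VAF; by default the mean VAF of
#'   sites with VAF > 0.4.
#' @param pi_init initial prior mosaic fraction (default 0.1).
#' @param mosaic_mean_init,mosaic_rho_init initial mosaic-component mean and
#'   overdispersion.
#' @param config a [mosaic_config()]; supplies `em_tol`, `em_max_iter` and
#'   `p0_mode`.
#' @return An object of class `"mosaic_mixture"`: list with elements `pi`,
#'   `p0`, `mosaic_mean`, `mosaic_rho`, `rho`, `posteriors`, `n_iter`,
#'   `loglik_trace`, `loglik`, `converged`.
#' @examples
#' set.seed(7)
#' depth <- rep(60, 500)
#' lab <- stats::runif(500) < 0.12
#' vaf <- ifelse(lab, stats::rbeta(500, 2, 11.3), 0.5)
#' k <- stats::rbinom(500, depth, vaf)
#' estimate_mosaic_prior(k, depth, rho = 0.01)$pi
#' @export
estimate_mosaic_prior <- function(n_alt, depth, rho, p0 = NULL,
                                  pi_init = 0.1,
                                  mosaic_mean_init = 0.15,
                                  mosaic_rho_init = 0.07,
                                  config = mosaic_config()) {
  stopifnot(length(n_alt) == length(depth), all(n_alt >= 0),
            all(n_alt <= depth), rho >= 0, rho < 1)
  n <- length(n_alt)
  if (n < 50L) {
    warning("fewer than 50 sites: the prior mosaic fraction estimate ",
            "is unstable", call. = FALSE)
  }
  vaf <- n_alt / depth
  if (is.null(p0)) {
    # initial germline mean: average VAF inside a symmetric window around
    # 1/2 (a one-sided cut would truncate the lower germline tail and bias
    # the mean upward)
    hi <- abs(vaf - 0.5) < 0.1
    p0 <- if (any(hi)) mean(vaf[hi]) else stats::median(vaf)
  }
  p0 <- min(max(p0, 1e-3), 1 - 1e-3)

  if (stats::var(vaf) == 0) {
    warning("all sites have identical VAF; returning boundary estimates",
            call. = FALSE)
  }

  pi_hat <- pi_init
  p1 <- mosaic_mean_init
  rho1 <- max(mosaic_rho_init, rho + 1e-4)

  l0 <- dbetabinom(n_alt, depth, p0, rho, log = TRUE)
  l1 <- dbetabinom(n_alt, depth, p1, rho1, log = TRUE)

  obs_ll <- function(l0, l1, pi_hat) {
    sum(log(pi_hat * exp(l1 - pmax(l0, l1)) +
              (1 - pi_hat) * exp(l0 - pmax(l0, l1))) + pmax(l0, l1))
  }

  trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    # E-step: posterior probability of mosaic origin
    lw1 <- log(pi_hat) + l1
    lw0 <- log1p(-pi_hat) + l0
    mx <- pmax(lw0, lw1)
    post <- exp(lw1 - mx) / (exp(lw0 - mx) + exp(lw1 - mx))

    # CM-steps
    pi_new <- mean(post)
    pi_new <- min(max(pi_new, 1e-8), 1 - 1e-8)

    w <- post
    # the mosaic mean is constrained below 0.45 (the post-zygotic VAF range):
    # without the cap a pure-germline input lets the mosaic component collapse
    # onto the germline one, leaving pi unidentifiable
    f1 <- function(p) -sum(w * dbetabinom(n_alt, depth, p, rho1, log = TRUE))
    p1 <- stats::optimize(f1, c(1e-4, 0.45))$minimum
    g1 <- function(r) -sum(w * dbetabinom(n_alt, depth, p1, r, log = TRUE))
    rho1 <- stats::optimize(g1, c(max(rho, 1e-6), 0.6))$minimum
    l1 <- dbetabinom(n_alt, depth, p1, rho1, log = TRUE)

    if (config$p0_mode == "re-estimated") {
      w0 <- 1 - post
      f0 <- function(p) -sum(w0 * dbetabinom(n_alt, depth, p, rho, log = TRUE))
      p0 <- stats::optimize(f0, c(0.25, 0.75))$minimum
      l0 <- dbetabinom(n_alt, depth, p0, rho, log = TRUE)
    }

    trace <- c(trace, obs_ll(l0, l1, pi_new))
    delta <- abs(pi_new - pi_hat)
    pi_hat <- pi_new
    if (delta < config$em_tol) {
      converged <- TRUE
      break
    }
    if (iter >= config$em_max_iter) break
  }
  if (!converged) {
    warning("EM reached the iteration cap (", config$em_max_iter,
            ") without |delta pi| < ", config$em_tol,
            "; returning the best estimate", call. = FALSE)
  }

  # final E-step so that the returned posteriors match the returned pi
  lw1 <- log(pi_hat) + l1
  lw0 <- log1p(-pi_hat) + l0
  mx <- pmax(lw0, lw1)
  post <- exp(lw1 - mx) / (exp(lw0 - mx) + exp(lw1 - mx))

  structure(
    list(pi = pi_hat, p0 = p0, mosaic_mean = p1, mosaic_rho = rho1,
         rho = rho, posteriors = post, n_iter = iter,
         loglik_trace = trace, loglik = trace[length(trace)],
         converged = converged),
    class = "mosaic_mixture"
  )
}

#' @export
print.mosaic_mixture <- function(x, ...) {
  cat("Beta-binomial germline/mosaic mixture (EM)\n")
  cat(sprintf("  prior mosaic fraction pi: %.4f\n", x$pi))
  cat(sprintf("  germline mean VAF p0:     %.4f\n", x$p0))
  cat(sprintf("  mosaic mean VAF:          %.4f (component rho %.4f)\n",
              x$mosaic_mean, x$mosaic_rho))
  cat(sprintf("  %d iterations, %sconverged; log-likelihood %.2f\n",
              x$n_iter, if (x$converged) "" else "NOT ", x$loglik))
  invisible(x)
}
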