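#' The beta-binomial distribution
#'
#' Density, distribution function and random generation for the beta-binomial
#' distribution parameterized by its mean success fraction `prob` and the
#' intraclass correlation `rho`. The underlying Beta shape parameters are
#' `alpha = prob * (1 - rho) / rho` and `beta = (1 - prob) * (1 - rho) / rho`,
#' so that `rho = 0` is the exact binomial limit and the variance of a draw on
#' `size` trials is `size * prob * (1 - prob) * (1 + (size - 1) * rho)`.
#'
#' All density evaluation is carried out in log space (via `lchoose()` and
#' `lbeta()`), so depths of several thousand reads are handled without
#' underflow.
#'
#' @param x,q vector of counts (number of alternate-allele reads).
#' @param n number of random draws.
#' @param size total number of trials (site read depth); must be >= 1.
#' @param prob mean success fraction, strictly inside (0, 1).
#' @param rho overdispersion (intraclass correlation) in [0, 1); `rho = 0`
#'   gives the exact binomial.
#' @param log,log.p logical; if `TRUE`, probabilities are returned on the log
#'   scale.
#' @param lower.tail logical; if `TRUE` (default), probabilities are
#'   `P(X <= q)`, otherwise `P(X > q)`.
#'
#' @return `dbetabinom` gives the probability mass, `pbetabinom` the
#'   cumulative probability and `rbetabinom` random counts.
#'
#' @examples
#' dbetabinom(5, 10, 0.5, rho = 0)        # binomial limit: choose(10,5)/2^10
#' sum(dbetabinom(0:20, 20, 0.3, 0.1))    # sums to 1
#' pbetabinom(8, 60, 0.49, 0.01)          # lower tail at a trio site
#' @export
dbetabinom <- function(x, size, prob, rho = 0, log = FALSE) {
  check_bb_params(size, prob, rho)
  if (length(x) == 0L) return(numeric(0))
  m <- max(length(x), length(size), length(prob), length(rho))
  x <- rep_len(as.numeric(x), m)
  size <- rep_len(as.numeric(size), m)
  prob <- rep_len(as.numeric(prob), m)
  rho <- rep_len(as.numeric(rho), m)

  lp <- numeric(m)
  bad <- x < 0 | x > size | x != round(x)
  bin <- rho == 0
  if (any(bin)) {
    k <- ifelse(bad[bin], 0, x[bin])     # placeholder; masked below
    lp[bin] <- stats::dbinom(k, size[bin], prob[bin], log = TRUE)
  }
  if (any(!bin)) {
    nu <- (1 - rho[!bin]) / rho[!bin]
    a <- prob[!bin] * nu
    b <- (1 - prob[!bin]) * nu
    k <- ifelse(bad[!bin], 0, x[!bin])   # placeholder; masked below
    n <- size[!bin]
    lp[!bin] <- lchoose(n, k) + lbeta(k + a, n - k + b) - lbeta(a, b)
  }
  lp[bad] <- -Inf
  if (log) lp else exp(lp)
}

#' @rdname dbetabinom
#' @export
pbetabinom <- function(q, size, prob, rho = 0, lower.tail = TRUE,
                       log.p = FALSE) {
  check_bb_params(size, prob, rho)
  m <- max(length(q), length(size), length(prob), length(rho))
  q <- rep_len(floor(as.numeric(q)), m)
  size <- rep_len(as.numeric(size), m)
  prob <- rep_len(as.numeric(prob), m)
  rho <- rep_len(as.numeric(rho), m)
  p <- vapply(seq_len(m), function(i) {
    if (q[i] < 0) return(0)
    hi <- min(q[i], size[i])
    sum(dbetabinom(0:hi, size[i], prob[i], rho[i]))
  }, numeric(1))
  p <- pmin(p, 1)
  if (!lower.tail) p <- 1 - p
  if (log.p) log(p) else p
}

#' @rdname dbetabinom
#' @export
rbetabinom <- function(n, size, prob, rho = 0) {
  check_bb_params(size, prob, rho)
  size <- rep_len(size, n)
  prob <- rep_len(prob, n)
  rho <- rep_len(rho, n)
  out <- integer(n)
  bin <- rho == 0
  if (any(bin)) {
    out[bin] <- stats::rbinom(sum(bin), size[bin], prob[bin])
  }
  if (any(!bin)) {
    nu <- (1 - rho[!bin]) / rho[!bin]
    p_i <- stats::rbeta(sum(!bin), prob[!bin] * nu, (1 - prob[!bin]) * nu)
    out[!bin] <- stats::rbinom(sum(!bin), size[!bin], p_i)
  }
  out
}

#' Convert between overdispersion parameterizations
#'
#' The intraclass correlation `rho` relates to the Beta concentration
#' `nu = alpha + beta` by `rho = 1 / (nu + 1)`. `rho_to_shape()` returns the
#' Beta shape pair for a given mean; `concentration_to_rho()` accepts a
#' concentration-style overdispersion input.
#'
#' @param prob mean success fraction in (0, 1).
#' @param rho intraclass correlation in (0, 1).
#' @param nu Beta concentration `alpha + beta`, > 0.
#' @return `rho_to_shape()` a list with `alpha` and `beta`;
#'   `concentration_to_rho()` the equivalent `rho`.
#' @examples
#' rho_to_shape(0.15, 1 / (13.3 + 1))  # Beta(2, 11.3)
#' concentration_to_rho(13.3)
#' @export
rho_to_shape <- function(prob, rho) {
  stopifnot(prob > 0, prob < 1, rho > 0, rho < 1)
  nu <- (1 - rho) / rho
  list(alpha = prob * nu, beta = (1 - prob) * nu)
}

#' @rdname rho_to_shape
#' @export
concentration_to_rho <- function(nu) {
  stopifnot(nu > 0)
  1 / (nu + 1)
}

check_bb_params <- function(size, prob, rho) {
  if (any(size < 1)) stop("'size' (read depth) must be >= 1", call. = FALSE)
  if (any(prob <= 0 | prob >= 1)) {
    stop("'prob' must lie strictly inside (0, 1)", call. = FALSE)
  }
  if (any(rho < 0 | rho >= 1)) {
    stop("'rho' must lie in [0, 1)", call. = FALSE)
  }
  invisible(TRUE)
}

# log(sum(exp(x))) without overflow; used for mixture log-likelihoods
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}
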