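# Independent oracles, deliberately implemented along different routes than
# the package code they check.

# beta-binomial pmf by numerical integration of the binomial kernel against
# the Beta mixing density (the package uses lchoose/lbeta in log space)
bb_pmf_oracle <- function(k, n, p, rho) {
  nu <- (1 - rho) / rho
  a <- p * nu
  b <- (1 - p) * nu
  stats::integrate(function(t) {
    choose(n, k) * t^k * (1 - t)^(n - k) * stats::dbeta(t, a, b)
  }, 0, 1, rel.tol = 1e-10)$value
}

# two-sided Fisher exact p by exhaustive hypergeometric enumeration over the
# support of the upper-left cell
fisher_p_oracle <- function(ref_fwd, ref_rev, alt_fwd, alt_rev) {
  m <- ref_fwd + ref_rev
  n2 <- alt_fwd + alt_rev
  kk <- ref_fwd + alt_fwd
  supp <- max(0, kk - n2):min(kk, m)
  probs <- stats::dhyper(supp, m, n2, kk)
  p_obs <- stats::dhyper(ref_fwd, m, n2, kk)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# exact two-sided rank-sum permutation p, with U computed by pair counting
# rather than via ranks
ranksum_perm_oracle <- function(x, y) {
  vals <- c(x, y)
  n1 <- length(x)
  n <- length(vals)
  u_of <- function(idx) {
    xs <- vals[idx]
    ys <- vals[-idx]
    sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
  }
  u_obs <- u_of(seq_len(n1))
  mu <- n1 * (n - n1) / 2
  us <- apply(utils::combn(n, n1), 2, u_of)
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-12)
}

# join scored calls back to generator truth labels
truth_labels_for <- function(calls, truth) {
  key <- paste(calls$sample_id, calls$chrom, calls$pos)
  truth$truth_label[match(key, paste(truth$sample_id, truth$chrom, truth$pos))]
}
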