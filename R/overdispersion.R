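#' Estimate read-count overdispersion from depth-binned maximum likelihood
#'
#' Apparent de novo sites are dominated by germline heterozygotes, whose
#' alternate-read counts at a fixed depth should be binomial around the mean
#' VAF; extra-binomial spread is captured by the intraclass correlation `rho`.
#' Sites are binned by exact read depth over `depth_range`; within each bin
#' the bin mean VAF is taken as fixed and `rho` is estimated by bounded 1-D
#' maximum likelihood; the global estimate is the site-count-weighted mean of
#' the per-bin estimates.
#'
#' @param n_alt integer vector of alternate-allele read counts.
#' @param depth integer vector of total site depths (same length).
#' @param depth_range inclusive depth range used for binning; sites outside
#'   are ignored. Default `c(1, 500)`.
#' @param min_bin_count bins with fewer sites than this are skipped
#'   (default 2; a single observation carries no information about spread).
#' @param rho_max upper bound of the search interval.
#' @param tol convergence tolerance of the 1-D optimizer.
#' @return An object of class `"overdispersion_fit"`: a list with
#'   `rho_global` (weighted-average intraclass correlation), `per_bin`
#'   (data frame of depth, site count, per-bin MLE) and `depth_range`.
#' @examples
#' set.seed(1)
#' depth <- sample(40:100, 2000, replace = TRUE)
#' k <- rbetabinom(2000, depth, 0.5, rho = 0.05)
#' fit_overdispersion(k, depth)
#' @export
fit_overdispersion <- function(n_alt, depth, depth_range = c(1L, 500L),
                               min_bin_count = 2L, rho_max = 0.5,
                               tol = 1e-8) {
  stopifnot(length(n_alt) == length(depth))
  keep <- depth >= depth_range[1] & depth <= depth_range[2]
  n_alt <- n_alt[keep]
  depth <- depth[keep]
  if (length(n_alt) == 0L) {
    stop("no sites fall inside 'depth_range' [", depth_range[1], ", ",
         depth_range[2], "]; widen the range or check depth units",
         call. = FALSE)
  }

  bins <- split(seq_along(depth), depth)
  rows <- lapply(bins, function(idx) {
    if (length(idx) < min_bin_count) return(NULL)
    n <- depth[idx][1]
    k <- n_alt[idx]
    p_bin <- mean(k) / n
    # degenerate bins (all reads ref or all alt) carry no usable VAF signal
    if (p_bin <= 0 || p_bin >= 1) return(NULL)
    nll <- function(r) -sum(dbetabinom(k, n, p_bin, r, log = TRUE))
    # compare the interior optimum against the rho = 0 boundary explicitly:
    # underdispersed bins pin the MLE at the binomial limit
    opt <- stats::optimize(nll, c(1e-9, rho_max), tol = tol)
    rho_hat <- if (opt$objective < nll(0)) opt$minimum else 0
    data.frame(depth = n, n_sites = length(idx), rho = rho_hat)
  })
  per_bin <- do.call(rbind, rows)
  if (is.null(per_bin) || nrow(per_bin) == 0L) {
    stop("no usable depth bins: every bin has fewer than ", min_bin_count,
         " sites or a degenerate mean VAF; lower 'min_bin_count' or supply ",
         "more sites", call. = FALSE)
  }
  rownames(per_bin) <- NULL
  structure(
    list(rho_global = sum(per_bin$rho * per_bin$n_sites) / sum(per_bin$n_sites),
         per_bin = per_bin,
         depth_range = as.integer(depth_range),
         n_sites_used = sum(per_bin$n_sites)),
    class = "overdispersion_fit"
  )
}

#' @export
print.overdispersion_fit <- function(x, ...) {
  cat("Depth-binned overdispersion fit\n")
  cat(sprintf("  global rho (site-count-weighted): %.5f\n", x$rho_global))
  cat(sprintf("  %d sites in %d depth bins over [%d, %d]\n",
              x$n_sites_used, nrow(x$per_bin),
              x$depth_range[1], x$depth_range[2]))
  invisible(x)
}
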