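#' Fit the mosaic/germline beta-binomial mixture to candidate de novo sites
#'
#' The main entry point of the package. Given a table of candidate de novo
#' SNVs with alternate-read counts and total depths, `mosaic_fit()`
#'
#' 1. estimates the read-level beta-binomial overdispersion `rho` by
#'    depth-binned maximum likelihood ([fit_overdispersion()]), unless a
#'    value is supplied;
#' 2. estimates the prior mosaic fraction `pi`, the germline mean VAF `p0`
#'    and the mosaic VAF component by expectation-maximization
#'    ([estimate_mosaic_prior()]);
#' 3. scores every site with a likelihood ratio, posterior odds, two-sided
#'    germline-model p-value and per-call false discovery bound, and labels
#'    it `mosaic` / `ambiguous` / `germline` ([call_mosaics()]).
#'
#' @param data data frame with integer columns `n_alt` and `depth` (a column
#'   `n` is accepted as an alias for `depth`); further columns (coordinates,
#'   sample ids, annotations) are carried through to the calls table.
#' @param rho optional known overdispersion; if `NULL` (default) it is
#'   estimated from the data.
#' @param p0 optional fixed germline mean VAF; default: estimated (see
#'   [estimate_mosaic_prior()]).
#' @param rho_vaf_min the overdispersion fit is restricted to sites with
#'   VAF above this value (default 0.3): `rho` describes the spread of the
#'   *germline heterozygous* component, and the low-VAF range is enriched
#'   for mosaics, whose presence in a depth bin would masquerade as
#'   overdispersion. Set to 0 to use every site.
#' @param config a [mosaic_config()].
#' @return An object of class `"mosaic_fit"` with components
#'   \describe{
#'     \item{estimates}{named list: `pi`, `p0`, `rho`, `mosaic_mean`,
#'       `mosaic_rho`.}
#'     \item{calls}{data frame of scored sites, sorted by descending
#'       posterior odds (see [call_mosaics()]).}
#'     \item{mixture}{the `"mosaic_mixture"` EM object (posteriors,
#'       log-likelihood trace, convergence).}
#'     \item{overdispersion}{the `"overdispersion_fit"` object, or `NULL`
#'       when `rho` was supplied.}
#'     \item{config, data, call}{inputs, for reproducibility.}
#'   }
#' @examples
#' cohort <- simulate_cohort(sim_config(n_trios = 150, seed = 1))
#' fit <- mosaic_fit(trio_model_frame(cohort$sites))
#' fit
#' coef(fit)
#' head(summary(fit)$label_counts)
#' @seealso [predict.mosaic_fit()], [simulate.mosaic_fit()],
#'   [run_mosaic_pipeline()]
#' @export
mosaic_fit <- function(data, rho = NULL, p0 = NULL, rho_vaf_min = 0.3,
                       config = mosaic_config()) {
  stopifnot(is.data.frame(data))
  if (!"depth" %in% names(data) && "n" %in% names(data)) {
    data$depth <- data$n
  }
  if (!all(c("n_alt", "depth") %in% names(data))) {
    stop("'data' must contain columns 'n_alt' and 'depth' (or 'n')",
         call. = FALSE)
  }
  if (any(data$depth < 1) || any(data$n_alt < 0) ||
      any(data$n_alt > data$depth)) {
    stop("invalid counts: need 0 <= n_alt <= depth and depth >= 1",
         call. = FALSE)
  }

  od <- NULL
  if (is.null(rho)) {
    germ <- data$n_alt / data$depth > rho_vaf_min
    if (sum(germ) < 50L) germ <- rep(TRUE, nrow(data))
    od <- fit_overdispersion(data$n_alt[germ], data$depth[germ],
                             depth_range = c(1L, config$depth_bin_max))
    rho <- od$rho_global
  }

  mix <- estimate_mosaic_prior(data$n_alt, data$depth, rho = rho, p0 = p0,
                               config = config)
  calls <- call_mosaics(data, pi = mix$pi, p0 = mix$p0, rho = rho,
                        config = config)

  structure(
    list(estimates = list(pi = mix$pi, p0 = mix$p0, rho = rho,
                          mosaic_mean = mix$mosaic_mean,
                          mosaic_rho = mix$mosaic_rho),
         calls = calls,
         mixture = mix,
         overdispersion = od,
         config = config,
         data = data,
         call = match.call()),
    class = "mosaic_fit"
  )
}

#' @export
print.mosaic_fit <- function(x, ...) {
  est <- x$estimates
  n <- nrow(x$calls)
  nm <- sum(x$calls$label == "mosaic")
  cat("Mosaic detection fit (beta-binomial EM)\n")
  cat(sprintf("  %d candidate de novo SNVs; %d called mosaic at posterior odds > %g (FDR bound %.1f%%)\n",
              n, nm, x$config$odds_cutoff,
              100 * odds_fdr_bound(x$config$odds_cutoff)))
  cat(sprintf("  pi = %.4f, p0 = %.4f, rho = %.5f, mosaic mean VAF = %.4f\n",
              est$pi, est$p0, est$rho, est$mosaic_mean))
  invisible(x)
}

#' @export
summary.mosaic_fit <- function(object, ...) {
  lbl <- factor(object$calls$label,
                levels = c("mosaic", "ambiguous", "germline"))
  out <- list(
    estimates = object$estimates,
    label_counts = table(lbl),
    odds_cutoff = object$config$odds_cutoff,
    fdr_bound = odds_fdr_bound(object$config$odds_cutoff),
    expected_mosaics = sum(object$mixture$posteriors),
    n_iter = object$mixture$n_iter,
    converged = object$mixture$converged,
    n_sites = nrow(object$calls)
  )
  class(out) <- "summary.mosaic_fit"
  out
}

#' @export
print.summary.mosaic_fit <- function(x, ...) {
  cat("Mosaic detection fit summary\n")
  cat(sprintf("  sites: %d  (mosaic %d | ambiguous %d | germline %d)\n",
              x$n_sites, x$label_counts["mosaic"],
              x$label_counts["ambiguous"], x$label_counts["germline"]))
  cat(sprintf("  posterior-odds cutoff %g => per-call FDR bound %.1f%%\n",
              x$odds_cutoff, 100 * x$fdr_bound))
  cat(sprintf("  expected mosaic count (sum of posteriors): %.1f\n",
              x$expected_mosaics))
  e <- x$estimates
  cat(sprintf("  pi = %.4f, p0 = %.4f, rho = %.5f, mosaic mean VAF = %.4f (rho1 %.4f)\n",
              e$pi, e$p0, e$rho, e$mosaic_mean, e$mosaic_rho))
  cat(sprintf("  EM: %d iterations, %sconverged\n", x$n_iter,
              if (x$converged) "" else "NOT "))
  invisible(x)
}

#' @export
coef.mosaic_fit <- function(object, ...) {
  unlist(object$estimates)
}

#' @export
logLik.mosaic_fit <- function(object, ...) {
  val <- object$mixture$loglik
  df <- 3L + (object$config$p0_mode == "re-estimated")
  structure(val, df = df, nobs = nrow(object$calls), class = "logLik")
}

#' Score new candidate sites with a fitted mosaic model
#'
#' @param object a [mosaic_fit()] object.
#' @param newdata data frame with `n_alt` and `depth` (or `n`); if omitted,
#'   the training calls table is returned.
#' @param ... unused.
#' @return A scored calls data frame (see [call_mosaics()]).
#' @export
predict.mosaic_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$calls)
  if (!"depth" %in% names(newdata) && "n" %in% names(newdata)) {
    newdata$depth <- newdata$n
  }
  est <- object$estimates
  call_mosaics(newdata, pi = est$pi, p0 = est$p0, rho = est$rho,
               config = object$config)
}

#' Pearson residuals under the germline model
#'
#' `(n_alt - depth * p0) / sqrt(depth * p0 * (1 - p0) * (1 + (depth - 1) * rho))`.
#' Mosaic sites appear as large negative residuals.
#'
#' @param object a [mosaic_fit()] object.
#' @param ... unused.
#' @export
residuals.mosaic_fit <- function(object, ...) {
  est <- object$estimates
  d <- object$data
  mu <- d$depth * est$p0
  v <- d$depth * est$p0 * (1 - est$p0) * (1 + (d$depth - 1) * est$rho)
  (d$n_alt - mu) / sqrt(v)
}

#' Simulate read counts from a fitted mosaic mixture
#'
#' Draws new cohorts at the observed site depths: each site is mosaic with
#' probability `pi` and its alternate-read count is beta-binomial from the
#' corresponding fitted component.
#'
#' @param object a [mosaic_fit()] object.
#' @param nsim number of simulated cohorts.
#' @param seed optional integer seed.
#' @param ... unused.
#' @return A list of `nsim` data frames with columns `n_alt`, `depth`,
#'   `truth` (`"mosaic"`/`"germline"`).
#' @export
simulate.mosaic_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  est <- object$estimates
  depth <- object$data$depth
  lapply(seq_len(nsim), function(i) {
    mos <- stats::runif(length(depth)) < est$pi
    k <- integer(length(depth))
    if (any(mos)) {
      k[mos] <- rbetabinom(sum(mos), depth[mos], est$mosaic_mean,
                           est$mosaic_rho)
    }
    if (any(!mos)) {
      k[!mos] <- rbetabinom(sum(!mos), depth[!mos], est$p0, est$rho)
    }
    data.frame(n_alt = k, depth = depth,
               truth = ifelse(mos, "mosaic", "germline"))
  })
}

#' Depth versus VAF diagnostic plot
#'
#' Scatter of site VAF against read depth, coloured by call label, with the
#' germline mean VAF and its 95% beta-binomial band.
#'
#' @param x a [mosaic_fit()] object.
#' @param ... passed to [graphics::plot()].
#' @export
plot.mosaic_fit <- function(x, ...) {
  cl <- x$calls
  est <- x$estimates
  col <- c(mosaic = "firebrick", ambiguous = "darkorange",
           germline = "grey30")[cl$label]
  graphics::plot(cl$depth, cl$vaf, col = col, pch = 16, cex = 0.6,
                 xlab = "read depth", ylab = "VAF", ylim = c(0, 1), ...)
  dd <- sort(unique(round(seq(min(cl$depth), max(cl$depth), length.out = 60))))
  lo <- vapply(dd, function(n) {
    q <- which(cumsum(dbetabinom(0:n, n, est$p0, est$rho)) >= 0.025)[1] - 1
    q / n
  }, numeric(1))
  hi <- vapply(dd, function(n) {
    q <- which(cumsum(dbetabinom(0:n, n, est$p0, est$rho)) >= 0.975)[1] - 1
    q / n
  }, numeric(1))
  graphics::abline(h = est$p0, col = "steelblue", lwd = 2)
  graphics::lines(dd, lo, col = "firebrick", lty = 2)
  graphics::lines(dd, hi, col = "firebrick", lty = 2)
  graphics::legend("topright", bty = "n", pch = 16,
                   col = c("firebrick", "darkorange", "grey30"),
                   legend = c("mosaic", "ambiguous", "germline"))
  invisible(x)
}
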