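#' Mosaic detection power at a given depth and variant allele fraction
#'
#' The probability that a true mosaic with allele fraction `vaf`, sequenced
#' at depth `depth`, is called: its alternate-read count is beta-binomial
#' (`rho`, set `rho = 0` for pure binomial sampling), and a count `m` is a
#' call when it clears the minimum alternate-read threshold
#' ([min_nalt_fdr_threshold()]) and its posterior odds
#' ([posterior_odds()] of [mosaic_lr()]) exceed `odds_cutoff`.
#'
#' `depth` may be a vector of per-sample depths, in which case the power is
#' averaged over it (optionally weighted).
#'
#' @param depth average read depth (scalar), or an empirical depth
#'   distribution (vector).
#' @param vaf true mosaic allele fraction in (0, 1).
#' @param pi prior mosaic fraction (default 0.1215, the EM estimate over the
#'   reference trio cohort).
#' @param p0 germline mean VAF (default 0.49).
#' @param rho beta-binomial overdispersion (default 0.02).
#' @param odds_cutoff posterior-odds calling threshold (default 10).
#' @param prior_form see [posterior_odds()].
#' @param filter_cfg a [filter_config()] supplying the minimum-N_alt rule.
#' @param use_min_nalt set `FALSE` to drop the minimum-read gate.
#' @param weights optional weights for a vector `depth`.
#' @return Detection power in [0, 1].
#' @examples
#' detection_power(60, 0.1)
#' detection_power(500, 0.05)   # deep coverage recovers low-fraction mosaics
#' @export
detection_power <- function(depth, vaf, pi = 0.1215, p0 = 0.49, rho = 0.02,
                            odds_cutoff = 10,
                            prior_form = c("odds", "probability"),
                            filter_cfg = filter_config(),
                            use_min_nalt = TRUE, weights = NULL) {
  stopifnot(all(depth >= 1), vaf > 0, vaf < 1)
  prior_form <- match.arg(prior_form)
  one <- function(n) {
    n <- as.integer(n)
    m <- 0:n
    log_odds <- mosaic_lr(m, n, p0 = p0, rho = rho, log = TRUE) +
      (if (prior_form == "odds") log(pi) - log1p(-pi) else log(pi))
    keep <- log_odds > log(odds_cutoff)
    if (use_min_nalt) {
      keep <- keep & m >= min_nalt_fdr_threshold(n, filter_cfg)
    }
    sum(dbetabinom(m[keep], n, vaf, rho))
  }
  if (length(depth) == 1L) return(one(depth))
  if (is.null(weights)) weights <- rep(1, length(depth))
  # collapse an empirical depth distribution to unique depths
  w <- tapply(weights, as.integer(depth), sum)
  d <- as.integer(names(w))
  sum(w * vapply(d, one, numeric(1))) / sum(w)
}

#' Detection-power grid over depth and VAF
#'
#' Evaluates [detection_power()] over a depth x VAF grid, e.g. to reproduce
#' depth-calibration curves or to compare alternative posterior-odds
#' cutoffs.
#'
#' @param depths vector of average depths.
#' @param vafs vector of true mosaic allele fractions.
#' @param ... passed on to [detection_power()].
#' @return An object of class `"power_grid"`: list with `depths`, `vafs`,
#'   the power `matrix` (depths x vafs) and the model settings.
#' @examples
#' pg <- power_curve(c(40, 80, 160), c(0.05, 0.1, 0.2))
#' pg$power
#' @export
power_curve <- function(depths, vafs, ...) {
  stopifnot(length(depths) > 0, length(vafs) > 0)
  pw <- outer(depths, vafs,
              Vectorize(function(d, v) detection_power(d, v, ...)))
  dimnames(pw) <- list(paste0(depths, "x"), paste0("vaf", vafs))
  structure(list(depths = depths, vafs = vafs, power = pw,
                 model = list(...)),
            class = "power_grid")
}

#' @export
print.power_grid <- function(x, ...) {
  cat("Mosaic detection power grid (rows: depth, cols: true VAF)\n")
  print(round(x$power, 3))
  invisible(x)
}

#' @export
plot.power_grid <- function(x, ...) {
  graphics::matplot(x$depths, x$power, type = "l", lty = 1, lwd = 2,
                    xlab = "average depth", ylab = "detection power",
                    ylim = c(0, 1), ...)
  graphics::legend("bottomright", bty = "n", lty = 1, lwd = 2,
                   col = seq_along(x$vafs),
                   legend = paste("VAF", x$vafs))
  invisible(x)
}

#' Inverse-power adjustment of an observed mosaic count
#'
#' Observed mosaic calls undercount the true burden because detection power
#' is below 1, especially at low allele fraction. Calls with VAF above
#' `vaf_floor` are binned (width `bin_width`, bins closed on the left) and
#' each bin count is divided by the detection power at the bin midpoint; the
#' adjusted total divided by the cohort size gives the estimated true
#' frequency of mosaicism per individual.
#'
#' @param vaf variant allele fractions of the observed mosaic calls.
#' @param depth average sequencing depth (scalar or empirical vector),
#'   passed to [detection_power()].
#' @param cohort_size number of individuals screened.
#' @param vaf_floor lower VAF bound for inclusion (default 0.1; strictly
#'   greater).
#' @param vaf_ceiling upper bound of the binning range (default 0.5).
#' @param bin_width VAF bin width (default 0.05).
#' @param power_floor bins whose power falls below this abort with an error
#'   (default 0.05), since dividing by vanishing power explodes the
#'   estimate; raise `vaf_floor` instead.
#' @param ... model settings for [detection_power()].
#' @return An [adjusted_frequency()] object.
#' @examples
#' adjust_true_frequency(c(0.12, 0.18, 0.22, 0.31), depth = 60,
#'                       cohort_size = 100)
#' @export
adjust_true_frequency <- function(vaf, depth = 60, cohort_size,
                                  vaf_floor = 0.1, vaf_ceiling = 0.5,
                                  bin_width = 0.05, power_floor = 0.05,
                                  ...) {
  stopifnot(cohort_size >= 1, vaf_floor >= 0, bin_width > 0)
  vaf <- vaf[vaf > vaf_floor]
  breaks <- seq(vaf_floor, vaf_ceiling + bin_width, by = bin_width)
  observed <- length(vaf)
  if (observed == 0L) {
    return(adjusted_frequency(0, 0, cohort_size, vaf_floor))
  }
  bin <- findInterval(vaf, breaks, rightmost.closed = FALSE)
  counts <- table(bin)
  mids <- breaks[as.integer(names(counts))] + bin_width / 2
  pw <- vapply(pmin(mids, 0.49), function(v) {
    detection_power(depth, v, ...)
  }, numeric(1))
  if (any(pw < power_floor)) {
    stop("detection power below ", power_floor, " in an included VAF bin; ",
         "raise 'vaf_floor' to avoid an exploding adjustment", call. = FALSE)
  }
  adjusted <- sum(as.numeric(counts) / pw)
  adjusted_frequency(observed, adjusted, cohort_size, vaf_floor)
}

#' Adjusted mosaic frequency per individual
#'
#' Container for an inverse-power-adjusted mosaic count: the observed call
#' count, the power-adjusted count (always >= observed), the cohort size and
#' the resulting per-individual rate.
#'
#' @param observed_count observed number of mosaic calls.
#' @param adjusted_count power-adjusted count, >= `observed_count`.
#' @param cohort_size number of individuals screened.
#' @param vaf_floor lower VAF bound used for inclusion.
#' @return A list of class `"adjusted_frequency"` with the inputs plus
#'   `per_individual = adjusted_count / cohort_size`.
#' @examples
#' adjusted_frequency(184, 361, 2530)   # 0.14 mosaics per individual
#' @export
adjusted_frequency <- function(observed_count, adjusted_count, cohort_size,
                               vaf_floor = 0.1) {
  stopifnot(cohort_size >= 1, observed_count >= 0)
  if (adjusted_count < observed_count) {
    stop("'adjusted_count' cannot be below 'observed_count'", call. = FALSE)
  }
  structure(
    list(observed_count = observed_count,
         adjusted_count = adjusted_count,
         cohort_size = cohort_size,
         per_individual = adjusted_count / cohort_size,
         vaf_floor = vaf_floor),
    class = "adjusted_frequency"
  )
}

#' @export
print.adjusted_frequency <- function(x, ...) {
  cat("Inverse-power adjusted mosaic frequency\n")
  cat(sprintf("  observed calls (VAF > %.2f): %d\n", x$vaf_floor,
              as.integer(round(x$observed_count))))
  cat(sprintf("  power-adjusted count:        %.1f\n", x$adjusted_count))
  cat(sprintf("  cohort size:                 %d\n", x$cohort_size))
  cat(sprintf("  per individual:              %.2f\n", x$per_individual))
  invisible(x)
}
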