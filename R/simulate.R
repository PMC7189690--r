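#' Configuration of the synthetic trio-cohort simulator
#'
#' The generator emulates the statistical structure of a trio exome de novo
#' candidate stream: germline heterozygous de novo sites with mean VAF 0.5,
#' a mosaic subpopulation whose true allele fractions follow a Beta law with
#' mean about 0.15, beta-binomial read sampling, a negative-binomial depth
#' distribution (mean 60 for blood-style cohorts; use 160 for deep
#' tissue-style cohorts), fair-coin strand splitting, clean parents, and two
#' kinds of technical artifacts (strand-skewed sites and error-only sites).
#'
#' By default sites are emitted as *ascertained candidates*: draws are
#' rejected until the proband has at least `min_candidate_alt` alternate
#' reads and both parents at least `min_parent_depth` reads, mirroring the
#' candidate-definition step that precedes model fitting (the prior mosaic
#' fraction is defined over that candidate set). Labels are assigned before
#' the rejection loop, so the mosaic fraction among emitted sites equals
#' `pi_true` exactly. Set `min_candidate_alt = 0` for the unascertained
#' stream (useful when detection power itself is under study).
#'
#' @param n_trios number of trios.
#' @param sites_per_trio mean number of candidate sites per trio (Poisson).
#' @param pi_true fraction of non-artifact sites that are mosaic.
#' @param mosaic_vaf_shape1,mosaic_vaf_shape2 Beta law of true mosaic VAFs
#'   (default Beta(2, 11.3), mean about 0.15).
#' @param germline_vaf true allele fraction of germline heterozygotes (0.5).
#' @param depth_mean,depth_size negative-binomial read-depth law (mean 60,
#'   size 10); depths are floored at 1. `depth_size = Inf` gives constant
#'   depth `depth_mean`.
#' @param rho_true read-level beta-binomial overdispersion (0.02).
#' @param artifact_rate fraction of emitted sites that are artifacts (0.05).
#' @param strand_skew_prob given an artifact, probability it is a
#'   strand-skewed site (all alternate reads on one strand) rather than an
#'   error-only site (0.5).
#' @param error_site_rate per-read alternate rate at error-only sites
#'   (0.005).
#' @param parent_contamination fraction of non-artifact sites whose parents
#'   carry 1-2 stray alternate reads (default 0; used to exercise the
#'   parent-alt filter).
#' @param min_candidate_alt candidate ascertainment floor on proband
#'   alternate reads (default 6; 0 disables ascertainment).
#' @param min_parent_depth parent depth floor used during ascertainment
#'   (10).
#' @param seed mandatory integer seed.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(n_trios = 200L, sites_per_trio = 1.5,
                       pi_true = 0.12,
                       mosaic_vaf_shape1 = 2, mosaic_vaf_shape2 = 11.3,
                       germline_vaf = 0.5,
                       depth_mean = 60, depth_size = 10,
                       rho_true = 0.02,
                       artifact_rate = 0.05, strand_skew_prob = 0.5,
                       error_site_rate = 0.005,
                       parent_contamination = 0,
                       min_candidate_alt = 6L, min_parent_depth = 10L,
                       seed = 1L) {
  stopifnot(n_trios >= 1, sites_per_trio > 0,
            pi_true >= 0, pi_true <= 1,
            germline_vaf > 0, germline_vaf < 1,
            depth_mean >= 1, depth_size > 0,
            rho_true >= 0, rho_true < 1,
            artifact_rate >= 0, artifact_rate < 1,
            error_site_rate > 0,
            parent_contamination >= 0, parent_contamination <= 1)
  if (is.null(seed) || is.na(seed)) stop("'seed' is mandatory", call. = FALSE)
  structure(as.list(environment()), class = "sim_config")
}

draw_depth <- function(n, cfg) {
  if (is.infinite(cfg$depth_size)) {
    return(rep(as.integer(round(cfg$depth_mean)), n))
  }
  pmax(1L, stats::rnbinom(n, mu = cfg$depth_mean, size = cfg$depth_size))
}

#' Simulate a trio cohort with truth labels
#'
#' Deterministic under `cfg$seed` (the caller's RNG state is saved and
#' restored). Every site records proband, father and mother depths and
#' alternate-read counts, strand-split proband counts, genomic coordinates
#' (random positions on chromosomes 1-22) and alleles; the companion truth
#' table records the generating label (`germline`, `mosaic` or `artifact`)
#' and the true allele fraction.
#'
#' @param cfg a [sim_config()].
#' @return List with data frames `sites` and `truth` (row-aligned).
#' @examples
#' cohort <- simulate_cohort(sim_config(n_trios = 50, seed = 3))
#' table(cohort$truth$truth_label)
#' @export
simulate_cohort <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!is.null(get0(".Random.seed", envir = globalenv()))) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(cfg$seed)

  n_per_trio <- pmax(1L, stats::rpois(cfg$n_trios, cfg$sites_per_trio))
  sample_id <- rep(sprintf("trio%04d", seq_len(cfg$n_trios)), n_per_trio)
  n <- length(sample_id)

  is_artifact <- stats::runif(n) < cfg$artifact_rate
  art_skew <- is_artifact & (stats::runif(n) < cfg$strand_skew_prob)
  art_err <- is_artifact & !art_skew
  is_mosaic <- !is_artifact & (stats::runif(n) < cfg$pi_true)

  label <- ifelse(is_artifact, "artifact",
                  ifelse(is_mosaic, "mosaic", "germline"))

  true_vaf <- numeric(n)
  depth <- integer(n)
  n_alt <- integer(n)
  father_depth <- integer(n)
  mother_depth <- integer(n)

  # rejection loop: redraw (vaf, depth, alt, parent depths) until the site
  # qualifies as a candidate; labels stay fixed, so the emitted mosaic
  # fraction is exactly pi_true. Error-only artifacts are never conditioned
  # (their whole point is to sit below the support threshold).
  pending <- seq_len(n)
  while (length(pending)) {
    m <- length(pending)
    idx <- pending
    v <- numeric(m)
    mos_i <- label[idx] == "mosaic"
    ger_i <- label[idx] == "germline"
    art_i <- label[idx] == "artifact"
    v[mos_i] <- stats::rbeta(sum(mos_i), cfg$mosaic_vaf_shape1,
                             cfg$mosaic_vaf_shape2)
    v[mos_i] <- pmin(v[mos_i], 0.499)
    v[ger_i] <- cfg$germline_vaf
    v[art_i] <- 0
    d <- draw_depth(m, cfg)
    k <- integer(m)
    real <- !art_i
    if (any(real)) {
      k[real] <- rbetabinom(sum(real), d[real], pmax(v[real], 1e-6),
                            cfg$rho_true)
    }
    if (any(art_i)) {
      skew_i <- art_skew[idx][art_i]
      ke <- stats::rbinom(sum(art_i), d[art_i], cfg$error_site_rate)
      # strand-skew artifacts look like credible candidates (moderate VAF)
      # but all their alternate reads sit on one strand
      ks <- rbetabinom(sum(art_i), d[art_i], 0.15, cfg$rho_true)
      k[art_i] <- ifelse(skew_i, pmax(ks, 1L), pmin(ke, d[art_i]))
    }
    fd <- draw_depth(m, cfg)
    md <- draw_depth(m, cfg)

    true_vaf[idx] <- v
    depth[idx] <- d
    n_alt[idx] <- k
    father_depth[idx] <- fd
    mother_depth[idx] <- md

    if (cfg$min_candidate_alt > 0L) {
      need_alt <- label[idx] != "artifact" | art_skew[idx]
      ok <- (!need_alt | k >= pmin(cfg$min_candidate_alt, d)) &
        fd >= cfg$min_parent_depth & md >= cfg$min_parent_depth
    } else {
      ok <- rep(TRUE, m)
    }
    pending <- idx[!ok]
  }

  # strand split: each read lands on the forward strand with probability
  # 1/2, except strand-skewed artifacts which put every alternate read on
  # a single strand
  alt_fwd <- stats::rbinom(n, n_alt, 0.5)
  one_strand_fwd <- stats::runif(n) < 0.5
  alt_fwd[art_skew] <- ifelse(one_strand_fwd[art_skew], n_alt[art_skew], 0L)
  alt_rev <- n_alt - alt_fwd
  n_ref <- depth - n_alt
  ref_fwd <- stats::rbinom(n, n_ref, 0.5)
  ref_rev <- n_ref - ref_fwd

  father_alt <- integer(n)
  mother_alt <- integer(n)
  if (cfg$parent_contamination > 0) {
    contam <- !is_artifact & (stats::runif(n) < cfg$parent_contamination)
    pick_father <- stats::runif(n) < 0.5
    father_alt[contam & pick_father] <-
      1L + stats::rbinom(sum(contam & pick_father), 1, 0.5)
    mother_alt[contam & !pick_father] <-
      1L + stats::rbinom(sum(contam & !pick_father), 1, 0.5)
  }

  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
  chrom <- as.character(sample(1:22, n, replace = TRUE))
  pos <- sample.int(2e8, n, replace = TRUE)

  sites <- data.frame(
    sample_id = sample_id, chrom = chrom, pos = pos, ref = ref, alt = alt,
    proband_depth = depth, proband_alt = n_alt,
    father_depth = father_depth, father_alt = father_alt,
    mother_depth = mother_depth, mother_alt = mother_alt,
    ref_fwd = ref_fwd, ref_rev = ref_rev,
    alt_fwd = alt_fwd, alt_rev = alt_rev,
    stringsAsFactors = FALSE
  )
  truth <- data.frame(
    sample_id = sample_id, chrom = chrom, pos = pos,
    truth_label = label, true_vaf = true_vaf,
    stringsAsFactors = FALSE
  )
  list(sites = sites, truth = truth, config = cfg)
}

#' Extract the model frame from a trio site table
#'
#' Maps the proband columns of a simulated or imported trio table onto the
#' `n_alt` / `depth` columns expected by [mosaic_fit()], keeping identifying
#' columns.
#'
#' @param sites a trio site data frame (e.g. `simulate_cohort()$sites` or
#'   [read_trio_vcf()] output).
#' @return Data frame with `sample_id`, `chrom`, `pos`, `ref`, `alt`,
#'   `n_alt`, `depth`, `vaf`.
#' @export
trio_model_frame <- function(sites) {
  stopifnot(all(c("proband_alt", "proband_depth") %in% names(sites)))
  out <- data.frame(
    n_alt = sites$proband_alt,
    depth = sites$proband_depth
  )
  for (col in c("sample_id", "chrom", "pos", "ref", "alt")) {
    if (col %in% names(sites)) out[[col]] <- sites[[col]]
  }
  out$vaf <- out$n_alt / out$depth
  out
}
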