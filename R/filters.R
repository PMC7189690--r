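#' Configuration of the candidate-filter cascade
#'
#' Defaults follow the published trio de novo pre-processing rules: a
#' candidate needs at least 6 alternate reads in the proband and clean,
#' well-covered parents; sites must be rare (population AF <= 1e-4), outside
#' problematic regions, at depth <= 500; alignment-bias p-values (PV4) and a
#' two-sided Fisher strand test remove technical artifacts; cohort-level
#' rules remove recurrent sites (> 1% of samples), sites from outlier samples
#' (> 8 candidate dnSNVs) and clustered SNVs (within 10 bp); and a
#' sequencing-error model sets a depth-dependent minimum alternate-read
#' count.
#'
#' @param min_proband_alt minimum alternate reads in the proband (6).
#' @param min_parent_depth minimum read depth in each parent (10).
#' @param max_parent_alt maximum alternate reads in each parent (0).
#' @param max_pop_af maximum population allele frequency (1e-4).
#' @param max_depth maximum site read depth (500).
#' @param pv4_baseq_min,pv4_taildist_min fail when the baseQ / tail-distance
#'   bias p-value is below 1e-3.
#' @param pv4_mapq_min fail when the mapQ bias p-value is below 1e-6.
#' @param strand_p_cutoff,strand_or_low,strand_or_high Fisher strand test:
#'   fail when p < 1e-3 and the odds ratio is outside [0.33, 3].
#' @param cohort_freq_max maximum fraction of samples sharing a variant
#'   (0.01).
#' @param outlier_dnsnv_cutoff samples with more than this many candidate
#'   dnSNVs are dropped (8; strictly-greater semantics).
#' @param cluster_window_bp SNVs from one sample within this many bp of each
#'   other (inclusive) all fail (10).
#' @param error_rate per-base sequencing error rate `epsilon` for the
#'   minimum-N_alt model (0.005); a specific erroneous base arises at rate
#'   `epsilon / 3`.
#' @param nalt_fdr_budget tolerated expected number of error-driven false
#'   candidates, as a fraction of `expected_candidates` (0.05).
#' @param callable_sites number of callable exome positions screened (3e7).
#' @param expected_candidates expected size of the candidate set (3000).
#' @return A list of class `"filter_config"`.
#' @export
filter_config <- function(min_proband_alt = 6L, min_parent_depth = 10L,
                          max_parent_alt = 0L, max_pop_af = 1e-4,
                          max_depth = 500L,
                          pv4_baseq_min = 1e-3, pv4_taildist_min = 1e-3,
                          pv4_mapq_min = 1e-6,
                          strand_p_cutoff = 1e-3, strand_or_low = 1 / 3,
                          strand_or_high = 3,
                          cohort_freq_max = 0.01, outlier_dnsnv_cutoff = 8L,
                          cluster_window_bp = 10L,
                          error_rate = 0.005, nalt_fdr_budget = 0.05,
                          callable_sites = 3e7, expected_candidates = 3000) {
  stopifnot(min_proband_alt >= 0, min_parent_depth >= 0, max_pop_af > 0,
            max_depth > 0, strand_or_low < 1, strand_or_high > 1,
            error_rate > 0, nalt_fdr_budget > 0, callable_sites > 0,
            expected_candidates > 0)
  structure(as.list(environment()), class = "filter_config")
}

#' @export
print.filter_config <- function(x, ...) {
  cat("Candidate-filter configuration\n")
  for (nm in names(x)) cat(sprintf("  %-22s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

#' Depth-dependent minimum alternate-read threshold from a sequencing-error
#' model
#'
#' Sequencing errors alone produce a specific alternate base at rate
#' `epsilon / 3` per read, so across `callable_sites` screened positions of
#' depth `n` the expected number of error-driven sites with at least `m`
#' alternate reads is `callable_sites * P(X >= m)`, `X ~ Binomial(n,
#' epsilon / 3)`. The threshold is the smallest `m` keeping that expectation
#' at or below `nalt_fdr_budget * expected_candidates` false candidates,
#' floored at `min_proband_alt` (the de novo candidate rule itself), and is
#' non-decreasing in depth.
#'
#' @param depth vector of site read depths.
#' @param config a [filter_config()].
#' @return Integer vector of minimum required alternate-read counts.
#' @examples
#' min_nalt_fdr_threshold(c(60, 200, 500))
#' @export
min_nalt_fdr_threshold <- function(depth, config = filter_config()) {
  if (config$error_rate <= 0) stop("'error_rate' must be > 0", call. = FALSE)
  p_err <- config$error_rate / 3
  target <- config$nalt_fdr_budget * config$expected_candidates /
    config$callable_sites
  vapply(depth, function(n) {
    m <- 1L
    # P(X >= m) = pbinom(m - 1, n, p, lower.tail = FALSE)
    while (stats::pbinom(m - 1L, n, p_err, lower.tail = FALSE) > target &&
           m <= n + 1L) {
      m <- m + 1L
    }
    max(m, as.integer(config$min_proband_alt))
  }, integer(1))
}

#' Fisher strand-bias test for one site
#'
#' Two-sided Fisher exact p-value on the 2x2 table
#' `[[ref_fwd, ref_rev], [alt_fwd, alt_rev]]` together with the sample
#' (cross-product) odds ratio `ref_fwd * alt_rev / (ref_rev * alt_fwd)`.
#' When a zero cell makes the sample OR undefined, a Haldane correction of
#' 0.5 is added to every cell (only relevant when the zero-alt-strand rule
#' has not already fired).
#'
#' @param ref_fwd,ref_rev,alt_fwd,alt_rev strand-split read counts.
#' @return List with `p` and `or`.
#' @export
strand_bias_test <- function(ref_fwd, ref_rev, alt_fwd, alt_rev) {
  counts <- c(ref_fwd, ref_rev, alt_fwd, alt_rev)
  if (any(counts < 0)) stop("strand counts must be non-negative", call. = FALSE)
  tab <- matrix(counts, nrow = 2, byrow = TRUE)
  p <- stats::fisher.test(tab)$p.value
  if (any(tab == 0)) tab <- tab + 0.5
  or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  list(p = p, or = or)
}

#' Apply the candidate-filter cascade to a trio site table
#'
#' Runs, in order: the de novo candidate rule (proband alternate-read
#' support, parental depth and absence), rarity/region/depth exclusion, the
#' PV4 technical-bias cutoffs, the Fisher strand-bias rule, cohort-level
#' recurrence / outlier-sample / SNV-cluster rules, and the FDR-based
#' minimum-N_alt threshold. Every failed filter is recorded, not just the
#' first, so verdicts double as an audit trail.
#'
#' Sites missing optional evidence are not punished for the gap: absent
#' population AF is treated as 0 (flag `pop_af_missing`), absent PV4 values
#' skip that filter (flag `pv4_missing`), absent strand counts skip the
#' strand rule (flag `strand_missing`). Missing parent columns fail the de
#' novo rule with `missing_parent`.
#'
#' @param sites data frame; recognised columns: `sample_id`, `chrom`, `pos`,
#'   `proband_alt`, `proband_depth`, `father_depth`, `father_alt`,
#'   `mother_depth`, `mother_alt`, `ref_fwd`, `ref_rev`, `alt_fwd`,
#'   `alt_rev`, `pv4_baseq`, `pv4_mapq`, `pv4_taildist`, `pop_af`.
#' @param config a [filter_config()].
#' @param regions optional exclusion regions: a `GRanges` or a named list of
#'   `GRanges` (e.g. from [read_exclusion_bed()]); any overlap fails the
#'   site.
#' @return A data frame of class `"filter_verdicts"`: one row per site with
#'   logical `passed`, a comma-separated `failed_filters` string, per-flag
#'   columns, and Fisher `strand_p` / `strand_or` details.
#' @examples
#' cohort <- simulate_cohort(sim_config(n_trios = 40, seed = 2))
#' v <- mosaic_prefilter(cohort$sites)
#' table(v$passed)
#' @export
mosaic_prefilter <- function(sites, config = filter_config(), regions = NULL) {
  stopifnot(is.data.frame(sites))
  n <- nrow(sites)
  get <- function(col) if (col %in% names(sites)) sites[[col]] else rep(NA, n)
  fails <- vector("list", n)
  add_fail <- function(which, name) {
    idx <- which(which)
    for (i in idx) fails[[i]] <<- c(fails[[i]], name)
    invisible(NULL)
  }

  proband_alt <- get("proband_alt")
  proband_depth <- get("proband_depth")
  if (all(is.na(proband_alt)) && "n_alt" %in% names(sites)) {
    proband_alt <- sites$n_alt
  }
  if (all(is.na(proband_depth)) && "depth" %in% names(sites)) {
    proband_depth <- sites$depth
  }
  if (any(is.na(proband_alt)) || any(is.na(proband_depth))) {
    stop("every site needs proband alternate-read and depth counts",
         call. = FALSE)
  }

  # -- de novo candidate rule ------------------------------------------------
  fa <- get("father_alt"); fd <- get("father_depth")
  ma <- get("mother_alt"); md <- get("mother_depth")
  parent_missing <- is.na(fa) | is.na(fd) | is.na(ma) | is.na(md)
  add_fail(parent_missing, "missing_parent")
  add_fail(proband_alt < config$min_proband_alt, "min_proband_alt")
  ok <- !parent_missing
  add_fail(ok & (fd < config$min_parent_depth | md < config$min_parent_depth),
           "parent_depth")
  add_fail(ok & (fa > config$max_parent_alt | ma > config$max_parent_alt),
           "parent_alt")

  # -- rarity, regions, depth ------------------------------------------------
  pop_af <- get("pop_af")
  pop_af_missing <- is.na(pop_af)
  pop_af[pop_af_missing] <- 0
  add_fail(pop_af > config$max_pop_af, "rarity")
  add_fail(proband_depth > config$max_depth, "max_depth")
  region_hit <- rep(FALSE, n)
  if (!is.null(regions)) {
    if (!("chrom" %in% names(sites) && "pos" %in% names(sites))) {
      stop("region filtering needs 'chrom' and 'pos' columns", call. = FALSE)
    }
    if (!is.list(regions)) regions <- list(exclusion = regions)
    site_gr <- GenomicRanges::GRanges(
      as.character(sites$chrom),
      IRanges::IRanges(start = sites$pos, width = 1L)
    )
    for (rg in regions) {
      region_hit <- region_hit |
        IRanges::overlapsAny(site_gr, rg, ignore.strand = TRUE)
    }
    add_fail(region_hit, "region_exclusion")
  }

  # -- PV4 technical bias ----------------------------------------------------
  bq <- get("pv4_baseq"); mq <- get("pv4_mapq"); td <- get("pv4_taildist")
  pv4_missing <- is.na(bq) & is.na(mq) & is.na(td)
  pv4_fail <- !pv4_missing &
    ((!is.na(bq) & bq < config$pv4_baseq_min) |
       (!is.na(td) & td < config$pv4_taildist_min) |
       (!is.na(mq) & mq < config$pv4_mapq_min))
  add_fail(pv4_fail, "pv4_bias")

  # -- strand bias -----------------------------------------------------------
  rf <- get("ref_fwd"); rr <- get("ref_rev")
  af <- get("alt_fwd"); ar <- get("alt_rev")
  strand_missing <- is.na(rf) | is.na(rr) | is.na(af) | is.na(ar)
  strand_p <- rep(NA_real_, n)
  strand_or <- rep(NA_real_, n)
  zero_strand <- !strand_missing & (af == 0 | ar == 0)
  add_fail(zero_strand, "strand_zero")
  test_idx <- which(!strand_missing & !zero_strand)
  for (i in test_idx) {
    ft <- strand_bias_test(rf[i], rr[i], af[i], ar[i])
    strand_p[i] <- ft$p
    strand_or[i] <- ft$or
  }
  add_fail(!is.na(strand_p) & strand_p < config$strand_p_cutoff &
             (strand_or < config$strand_or_low |
                strand_or > config$strand_or_high),
           "strand_fisher")

  # -- cohort-level rules ----------------------------------------------------
  if ("sample_id" %in% names(sites)) {
    sample_id <- as.character(sites$sample_id)
    n_samples <- length(unique(sample_id))
    if (n_samples > 1L &&
        all(c("chrom", "pos") %in% names(sites))) {
      key <- paste(sites$chrom, sites$pos, get("ref"), get("alt"), sep = ":")
      carriers <- tapply(sample_id, key, function(s) length(unique(s)))
      add_fail(carriers[key] / n_samples > config$cohort_freq_max,
               "cohort_recurrence")
    } else if (n_samples == 1L) {
      warning("single-sample input: cohort recurrence filter skipped",
              call. = FALSE)
    }
    counts <- table(sample_id)
    add_fail(counts[sample_id] > config$outlier_dnsnv_cutoff,
             "outlier_sample")
    if (all(c("chrom", "pos") %in% names(sites))) {
      clustered <- rep(FALSE, n)
      for (grp in split(seq_len(n), paste(sample_id, sites$chrom))) {
        if (length(grp) < 2L) next
        pos <- sites$pos[grp]
        d <- abs(outer(pos, pos, "-"))
        diag(d) <- NA
        clustered[grp] <- apply(d <= config$cluster_window_bp, 1, any,
                                na.rm = TRUE)
      }
      add_fail(clustered, "snv_cluster")
    }
  }

  # -- error-model minimum N_alt --------------------------------------------
  min_nalt <- min_nalt_fdr_threshold(proband_depth, config)
  add_fail(proband_alt < min_nalt, "min_nalt_fdr")

  failed <- vapply(fails, function(f) paste(unique(f), collapse = ","),
                   character(1))
  out <- data.frame(
    passed = failed == "",
    failed_filters = failed,
    pop_af_missing = pop_af_missing,
    pv4_missing = pv4_missing,
    strand_missing = strand_missing,
    strand_p = strand_p,
    strand_or = strand_or,
    min_nalt_required = min_nalt,
    stringsAsFactors = FALSE
  )
  for (col in c("sample_id", "chrom", "pos", "ref", "alt")) {
    if (col %in% names(sites)) out[[col]] <- sites[[col]]
  }
  class(out) <- c("filter_verdicts", "data.frame")
  out
}

#' Export verdicts as a long-format audit table
#'
#' One row per site x failed filter; sites passing everything are omitted.
#'
#' @param verdicts output of [mosaic_prefilter()].
#' @param path optional TSV path; if given the table is also written.
#' @return The audit data frame, invisibly when `path` is given.
#' @export
write_filter_audit <- function(verdicts, path = NULL) {
  idx <- which(!verdicts$passed)
  rows <- lapply(idx, function(i) {
    fl <- strsplit(verdicts$failed_filters[i], ",", fixed = TRUE)[[1]]
    data.frame(site = i,
               sample_id = if ("sample_id" %in% names(verdicts))
                 verdicts$sample_id[i] else NA,
               chrom = if ("chrom" %in% names(verdicts))
                 verdicts$chrom[i] else NA,
               pos = if ("pos" %in% names(verdicts)) verdicts$pos[i] else NA,
               filter = fl, stringsAsFactors = FALSE)
  })
  audit <- if (length(rows)) do.call(rbind, rows) else
    data.frame(site = integer(0), sample_id = character(0),
               chrom = character(0), pos = integer(0), filter = character(0))
  if (!is.null(path)) {
    utils::write.table(audit, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(audit))
  }
  audit
}

#' Read a BED exclusion track
#'
#' BED input is 0-based half-open; the returned `GRanges` uses the 1-based
#' inclusive convention of the variant tables. This is the only place in the
#' package where that conversion happens (it is performed by
#' `rtracklayer::import`).
#'
#' @param path path to a BED file.
#' @return A `GRanges` of exclusion intervals.
#' @export
read_exclusion_bed <- function(path) {
  gr <- tryCatch(
    rtracklayer::import(path, format = "bed"),
    error = function(e) stop("malformed BED file '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  gr
}
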