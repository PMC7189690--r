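#' Write one trio's candidate sites as a multi-sample VCF
#'
#' Emits a plain-text VCFv4.2 file with three genotype columns (proband,
#' father, mother), `GT:AD:DP` format fields, and the proband's strand-split
#' counts (`DP4`) and technical-bias p-values (`PV4`) in INFO when present.
#' Positions are 1-based; only biallelic SNVs are ever emitted. The file
#' round-trips losslessly through [read_trio_vcf()].
#'
#' @param sites trio site data frame (one sample id; see
#'   [simulate_cohort()]).
#' @param path output path.
#' @param sample_names character vector of length 3: proband, father,
#'   mother column names.
#' @return `path`, invisibly.
#' @export
write_trio_vcf <- function(sites, path,
                           sample_names = c("PROBAND", "FATHER", "MOTHER")) {
  stopifnot(is.data.frame(sites), nrow(sites) > 0,
            length(sample_names) == 3)
  need <- c("chrom", "pos", "ref", "alt", "proband_depth", "proband_alt",
            "father_depth", "father_alt", "mother_depth", "mother_alt")
  if (!all(need %in% names(sites))) {
    stop("missing columns: ", paste(setdiff(need, names(sites)),
                                    collapse = ", "), call. = FALSE)
  }
  if (any(nchar(sites$ref) != 1L | nchar(sites$alt) != 1L)) {
    stop("only single-nucleotide alleles can be written", call. = FALSE)
  }
  ord <- order(sites$chrom, sites$pos)
  sites <- sites[ord, , drop = FALSE]

  has_dp4 <- all(c("ref_fwd", "ref_rev", "alt_fwd", "alt_rev") %in%
                   names(sites))
  has_pv4 <- all(c("pv4_strand", "pv4_baseq", "pv4_mapq", "pv4_taildist")
                 %in% names(sites))
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=bbmosaic",
    paste0("##contig=<ID=", unique(sites$chrom), ">"),
    "##INFO=<ID=DP4,Number=4,Type=Integer,Description=\"Proband ref-forward, ref-reverse, alt-forward and alt-reverse read counts\">",
    "##INFO=<ID=PV4,Number=4,Type=Float,Description=\"P-values for strand bias, baseQ bias, mapQ bias and tail distance bias\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths for the ref and alt alleles\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample_names), collapse = "\t")
  )
  info <- rep(".", nrow(sites))
  if (has_dp4) {
    info <- sprintf("DP4=%d,%d,%d,%d", sites$ref_fwd, sites$ref_rev,
                    sites$alt_fwd, sites$alt_rev)
  }
  if (has_pv4) {
    pv4 <- sprintf("PV4=%g,%g,%g,%g", sites$pv4_strand, sites$pv4_baseq,
                   sites$pv4_mapq, sites$pv4_taildist)
    info <- ifelse(info == ".", pv4, paste(info, pv4, sep = ";"))
  }
  gt <- function(geno, depth, alt) {
    sprintf("%s:%d,%d:%d", geno, depth - alt, alt, depth)
  }
  body <- paste(
    sites$chrom, sites$pos, ".", sites$ref, sites$alt, ".", "PASS", info,
    "GT:AD:DP",
    gt("0/1", sites$proband_depth, sites$proband_alt),
    gt("0/0", sites$father_depth, sites$father_alt),
    gt("0/0", sites$mother_depth, sites$mother_alt),
    sep = "\t"
  )
  ok <- tryCatch({
    writeLines(c(header, body), path)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) {
    stop("failed to write VCF to '", path, "': ", conditionMessage(ok),
         call. = FALSE)
  }
  invisible(path)
}

#' Read a proband/father/mother trio VCF into a site table
#'
#' Parses a multi-sample VCF (via `vcfR`) into one row per biallelic SNV.
#' Indel records are skipped with a counted warning; multi-allelic SNV
#' records are decomposed into one row per alternate allele, with per-allele
#' alternate depths taken from the `AD` field. Per-sample depth comes from
#' `DP`, falling back to the sum of `AD`. Proband strand counts (`DP4`) and
#' bias p-values (`PV4`) are recovered from INFO when present.
#'
#' @param path VCF path.
#' @param sample_roles named character vector mapping roles to VCF sample
#'   columns, with names `proband`, `father`, `mother`.
#' @return A trio site data frame (same layout as `simulate_cohort()$sites`,
#'   minus `sample_id`), with attribute `n_skipped_indels`.
#' @export
read_trio_vcf <- function(path,
                          sample_roles = c(proband = "PROBAND",
                                           father = "FATHER",
                                           mother = "MOTHER")) {
  stopifnot(all(c("proband", "father", "mother") %in% names(sample_roles)))
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  samples <- colnames(v@gt)[-1]
  missing <- setdiff(unname(sample_roles), samples)
  if (length(missing)) {
    stop("VCF '", path, "' lacks sample column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  ad <- vcfR::extract.gt(v, element = "AD")
  dp <- suppressWarnings(vcfR::extract.gt(v, element = "DP", as.numeric = TRUE))
  if (all(is.na(ad))) {
    stop("VCF '", path, "' has no AD format field", call. = FALSE)
  }

  alt_list <- strsplit(fix$ALT, ",", fixed = TRUE)
  is_snv <- vapply(seq_along(alt_list), function(i) {
    nchar(fix$REF[i]) == 1L &&
      all(nchar(alt_list[[i]]) == 1L) &&
      all(alt_list[[i]] %in% c("A", "C", "G", "T"))
  }, logical(1))
  n_skipped <- sum(!is_snv)
  if (n_skipped > 0) {
    warning(n_skipped, " non-SNV (indel or symbolic) record(s) skipped",
            call. = FALSE)
  }

  parse_ad <- function(s) {
    if (is.na(s)) return(NA_integer_)
    as.integer(strsplit(s, ",", fixed = TRUE)[[1]])
  }
  rows <- list()
  for (i in which(is_snv)) {
    alts <- alt_list[[i]]
    ads <- lapply(sample_roles, function(sm) parse_ad(ad[i, sm]))
    if (any(vapply(ads, function(a) all(is.na(a)), logical(1)))) {
      stop("record ", fix$CHROM[i], ":", fix$POS[i],
           " lacks AD for a trio sample", call. = FALSE)
    }
    depth_of <- function(role, ad_vec) {
      d <- dp[i, sample_roles[[role]]]
      if (is.na(d)) d <- sum(ad_vec)
      as.integer(d)
    }
    for (a in seq_along(alts)) {
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = fix$CHROM[i], pos = as.integer(fix$POS[i]),
        ref = fix$REF[i], alt = alts[a],
        proband_depth = depth_of("proband", ads$proband),
        proband_alt = ads$proband[a + 1L],
        father_depth = depth_of("father", ads$father),
        father_alt = ads$father[a + 1L],
        mother_depth = depth_of("mother", ads$mother),
        mother_alt = ads$mother[a + 1L],
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)

  info_field <- function(key, n_expected) {
    raw <- vcfR::extract.info(v, element = key)
    t(vapply(raw, function(s) {
      if (is.na(s)) return(rep(NA_real_, n_expected))
      as.numeric(strsplit(s, ",", fixed = TRUE)[[1]])
    }, numeric(n_expected), USE.NAMES = FALSE))
  }
  snv_rows <- rep(which(is_snv), lengths(alt_list)[is_snv])
  dp4 <- info_field("DP4", 4)
  if (!all(is.na(dp4))) {
    out$ref_fwd <- as.integer(dp4[snv_rows, 1])
    out$ref_rev <- as.integer(dp4[snv_rows, 2])
    out$alt_fwd <- as.integer(dp4[snv_rows, 3])
    out$alt_rev <- as.integer(dp4[snv_rows, 4])
  }
  pv4 <- info_field("PV4", 4)
  if (!all(is.na(pv4))) {
    out$pv4_strand <- pv4[snv_rows, 1]
    out$pv4_baseq <- pv4[snv_rows, 2]
    out$pv4_mapq <- pv4[snv_rows, 3]
    out$pv4_taildist <- pv4[snv_rows, 4]
  }
  attr(out, "n_skipped_indels") <- n_skipped
  out
}

#' Read or write a tab-delimited candidate site table
#'
#' The candidate table uses 1-based positions and the column names of
#' `simulate_cohort()$sites`; extra annotation columns pass through
#' untouched.
#'
#' @param path TSV path.
#' @param sites data frame to write.
#' @return `read_candidate_table()` the data frame;
#'   `write_candidate_table()` the path, invisibly.
#' @export
read_candidate_table <- function(path) {
  out <- utils::read.delim(path, stringsAsFactors = FALSE)
  # chromosome names are labels, never numbers ("1" vs "X")
  if ("chrom" %in% names(out)) out$chrom <- as.character(out$chrom)
  out
}

#' @rdname read_candidate_table
#' @export
write_candidate_table <- function(sites, path) {
  utils::write.table(sites, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write the fitted-model JSON sidecar
#'
#' Records the fitted parameters, convergence information, configuration and
#' a schema version, so that a scored table can always be traced back to its
#' model.
#'
#' @param fit a [mosaic_fit()] object.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(fit, path) {
  stopifnot(inherits(fit, "mosaic_fit"))
  payload <- list(
    schema_version = "1.0",
    estimates = fit$estimates,
    em = list(n_iter = fit$mixture$n_iter,
              converged = fit$mixture$converged,
              loglik = fit$mixture$loglik),
    config = unclass(fit$config),
    n_sites = nrow(fit$calls),
    n_mosaic = sum(fit$calls$label == "mosaic")
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
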