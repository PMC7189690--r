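#' Classify variant consequence from supplied effect and pathogenicity scores
#'
#' Deterministic classification of each variant into `LoF` (stopgain,
#' stoploss, frameshift, canonical splice site), `Dmis` (missense with
#' REVEL above `revel_threshold`), `splice_damaging` (missense or synonymous
#' otherwise benign but with a splice delta score above `splice_threshold`),
#' `Bmis` or `synonymous`. A variant is `damaging` when it is LoF, Dmis or
#' splice-damaging. Missing scores default conservatively to non-damaging.
#'
#' @param effect_class character vector with values among `stopgain`,
#'   `stoploss`, `frameshift`, `canonical_splice`, `missense`, `synonymous`.
#' @param revel optional REVEL scores in [0, 1] (`NA` = missing).
#' @param splice_delta optional splice delta scores in [0, 1].
#' @param revel_threshold missense scores strictly above this are deleterious
#'   (default 0.5).
#' @param splice_threshold delta scores strictly above this are
#'   splice-damaging (default 0.5).
#' @return Data frame with `class` (factor) and logical `damaging`,
#'   `score_missing`.
#' @examples
#' classify_consequence(c("stopgain", "missense", "synonymous"),
#'                      revel = c(NA, 0.6, NA),
#'                      splice_delta = c(NA, NA, 0.3))
#' @export
classify_consequence <- function(effect_class, revel = NA_real_,
                                 splice_delta = NA_real_,
                                 revel_threshold = 0.5,
                                 splice_threshold = 0.5) {
  lof_classes <- c("stopgain", "stoploss", "frameshift", "canonical_splice")
  known <- c(lof_classes, "missense", "synonymous")
  if (!all(effect_class %in% known)) {
    bad <- setdiff(unique(effect_class), known)
    stop("unknown effect class(es): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  n <- length(effect_class)
  revel <- rep_len(revel, n)
  splice_delta <- rep_len(splice_delta, n)
  if (any(revel < 0 | revel > 1, na.rm = TRUE) ||
      any(splice_delta < 0 | splice_delta > 1, na.rm = TRUE)) {
    stop("scores must lie in [0, 1]", call. = FALSE)
  }

  cls <- character(n)
  lof <- effect_class %in% lof_classes
  cls[lof] <- "LoF"
  mis <- effect_class == "missense"
  dmis <- mis & !is.na(revel) & revel > revel_threshold
  cls[dmis] <- "Dmis"
  spl <- !lof & !dmis & !is.na(splice_delta) & splice_delta > splice_threshold
  cls[spl] <- "splice_damaging"
  rest <- cls == ""
  cls[rest & mis] <- "Bmis"
  cls[rest & effect_class == "synonymous"] <- "synonymous"
  data.frame(
    class = factor(cls, levels = c("LoF", "Dmis", "splice_damaging",
                                   "Bmis", "synonymous")),
    damaging = cls %in% c("LoF", "Dmis", "splice_damaging"),
    score_missing = (mis & is.na(revel)) |
      (effect_class %in% c("missense", "synonymous") & is.na(splice_delta))
  )
}

DNA_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

revcomp <- function(x) {
  vapply(strsplit(x, ""), function(b) {
    paste(rev(unname(DNA_COMPLEMENT[b])), collapse = "")
  }, character(1))
}

#' Dinucleotide mutation spectrum with CpG tally
#'
#' Tallies substitutions by the dinucleotide formed by the mutated base and
#' its 3' neighbour, after strand collapsing: substitutions reported on the
#' purine strand for C/T references are kept, those from G or A references
#' are reverse-complemented so that, e.g., a G>A with a preceding C is
#' counted as C>T in a CpG context. A variant counts as CpG when the
#' (collapsed) reference base is C followed by G.
#'
#' @param ref,alt single-character reference and alternate bases.
#' @param context trinucleotide context strings (reference base in the
#'   middle, e.g. `"ACG"`); records whose middle base disagrees with `ref`
#'   are flagged and excluded from the tallies.
#' @return An object of class `"spectrum_tally"`: list with `counts` (table
#'   keyed by collapsed dinucleotide x substitution), `cpg_count`, `total`,
#'   `cpg_fraction`, and `bad_context` (indices of inconsistent records).
#' @examples
#' mutation_spectrum(c("C", "G"), c("T", "A"), c("ACG", "CGT"))
#' @export
mutation_spectrum <- function(ref, alt, context) {
  n <- length(ref)
  stopifnot(length(alt) == n, length(context) == n)
  ref <- toupper(ref); alt <- toupper(alt); context <- toupper(context)
  ok <- nchar(context) == 3L & substr(context, 2, 2) == ref &
    ref %in% names(DNA_COMPLEMENT) & alt %in% names(DNA_COMPLEMENT) &
    ref != alt
  bad <- which(!ok)

  ref_k <- ref[ok]; alt_k <- alt[ok]; ctx <- context[ok]
  flip <- ref_k %in% c("G", "A")
  if (any(flip)) {
    ctx[flip] <- revcomp(ctx[flip])
    ref_k[flip] <- unname(DNA_COMPLEMENT[ref_k[flip]])
    alt_k[flip] <- unname(DNA_COMPLEMENT[alt_k[flip]])
  }
  dinuc <- paste0(ref_k, substr(ctx, 3, 3))
  subst <- paste0(ref_k, ">", alt_k)
  counts <- table(dinucleotide = dinuc, substitution = subst)
  cpg <- sum(dinuc == "CG")
  total <- length(dinuc)
  structure(
    list(counts = counts,
         cpg_count = cpg,
         total = total,
         cpg_fraction = if (total > 0) cpg / total else NA_real_,
         bad_context = bad),
    class = "spectrum_tally"
  )
}

#' @export
print.spectrum_tally <- function(x, ...) {
  cat("Dinucleotide mutation spectrum\n")
  cat(sprintf("  %d variants with valid context; %d CpG (%.1f%%)\n",
              x$total, x$cpg_count, 100 * x$cpg_fraction))
  if (length(x$bad_context)) {
    cat(sprintf("  %d records with context inconsistent with the reference allele\n",
                length(x$bad_context)))
  }
  print(x$counts)
  invisible(x)
}

#' Rank-sum comparison of two VAF distributions
#'
#' Mann-Whitney U comparison of, e.g., likely damaging versus likely benign
#' mosaic allele fractions. For small samples (combined n at most
#' `exact_limit`) the two-sided p-value is computed by exhaustive
#' enumeration of all group assignments (exact even under ties:
#' `P(|U - n1*n2/2| >= |u_obs - n1*n2/2|)`); larger samples use the
#' tie-corrected normal approximation of [stats::wilcox.test()].
#'
#' @param x,y numeric vectors (both non-empty), e.g. VAFs of the damaging
#'   and benign groups.
#' @param exact_limit exhaustive enumeration is used when
#'   `length(x) + length(y) <= exact_limit` (default 12).
#' @return List with `statistic` (the Mann-Whitney U of `x`), `p.value`,
#'   and `method`.
#' @examples
#' vaf_group_comparison(c(0.3, 0.31, 0.32), c(0.05, 0.06, 0.07))
#' @export
vaf_group_comparison <- function(x, y, exact_limit = 12L) {
  if (length(x) == 0L || length(y) == 0L) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  if (n <= exact_limit) {
    combos <- utils::combn(n, n1)
    us <- apply(combos, 2, function(idx) {
      sum(r[idx]) - n1 * (n1 + 1) / 2
    })
    p <- mean(abs(us - mu) >= abs(u_obs - mu) - 1e-12)
    method <- "exact permutation"
  } else {
    p <- stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value
    method <- "normal approximation with tie correction"
  }
  list(statistic = u_obs, p.value = p, method = method)
}

#' Classify an amplicon-resequencing VAF
#'
#' A deep-resequencing allele fraction at or below `lower` indicates no
#' variant; a fraction strictly between `lower` and `upper` confirms
#' post-zygotic (mosaic) origin; a fraction at or above `upper` indicates a
#' germline heterozygote.
#'
#' @param vaf amplicon VAF values in [0, 1].
#' @param lower no-variant bound (default 0.01).
#' @param upper germline bound (default 0.45).
#' @return Factor with levels `no_variant`, `mosaic_confirmed`, `germline`.
#' @examples
#' classify_validation(c(0.0005, 0.13, 0.48))
#' @export
classify_validation <- function(vaf, lower = 0.01, upper = 0.45) {
  stopifnot(all(vaf >= 0 & vaf <= 1), lower < upper)
  out <- ifelse(vaf <= lower, "no_variant",
                ifelse(vaf < upper, "mosaic_confirmed", "germline"))
  factor(out, levels = c("no_variant", "mosaic_confirmed", "germline"))
}
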