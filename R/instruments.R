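#' Select genome-wide significant candidate instruments
#'
#' Retains exposure records with `pvalue <= p_threshold` (the conventional
#' genome-wide significance level by default), sorted by ascending p-value
#' with deterministic ties broken by (chrom, pos).
#'
#' @param ds A [summary_dataset] for the exposure.
#' @param p_threshold Significance threshold (default `5e-8`).
#' @return Data frame of candidate records (possibly empty).
#' @export
select_by_pvalue <- function(ds, p_threshold = 5e-8) {
  stopifnot(inherits(ds, "summary_dataset"))
  rec <- ds$records
  hit <- rec[rec$pvalue <= p_threshold, , drop = FALSE]
  hit <- hit[order(hit$pvalue, hit$chrom, hit$pos), , drop = FALSE]
  rownames(hit) <- NULL
  hit
}

# normalize the ld argument into a pairwise r-squared lookup:
#   NULL                    -> all pairs r2 = 0
#   function(id_a, id_b)->r -> squared internally
#   data.frame(variant_a, variant_b, r2) -> symmetric table lookup, absent
#                                           pairs r2 = 0
as_ld_r2 <- function(ld) {
  if (is.null(ld)) return(function(a, b) 0)
  if (is.function(ld)) return(function(a, b) ld(a, b)^2)
  if (is.data.frame(ld)) {
    stopifnot(all(c("variant_a", "variant_b", "r2") %in% names(ld)))
    key <- c(paste(ld$variant_a, ld$variant_b), paste(ld$variant_b, ld$variant_a))
    val <- stats::setNames(c(ld$r2, ld$r2), key)
    return(function(a, b) {
      r2 <- val[paste(a, b)]
      if (is.na(r2)) 0 else unname(r2)
    })
  }
  stop("ld must be NULL, a function(id_a, id_b) -> r, or a pairwise r2 data frame")
}

#' Greedy LD clumping with a genomic-window rule
#'
#' Standard greedy clumping: repeatedly take the remaining record with the
#' lowest p-value as an index SNP and discard every remaining record that
#' is either within `window_kb` kilobases of it on the same chromosome or
#' correlated with it at `r^2 >` `r2_threshold`. Retained index SNPs are
#' returned in selection order (ascending p).
#'
#' @param candidates Data frame of candidate records, as returned by
#'   [select_by_pvalue()].
#' @param ld LD source: `NULL` (no LD information, distance rule only), a
#'   function `(id_a, id_b) -> r` over `"chrom:pos"` ids (e.g.
#'   [ld_from_study()]), or a data frame with columns `variant_a`,
#'   `variant_b`, `r2`; absent pairs count as `r2 = 0`.
#' @param r2_threshold Maximum allowed squared correlation between retained
#'   SNPs (default `0.001`).
#' @param window_kb Exclusion window around each index SNP in kilobases
#'   (default `100`).
#' @return Data frame of retained index records.
#' @export
clump <- function(candidates, ld = NULL, r2_threshold = 0.001,
                  window_kb = 100) {
  if (r2_threshold < 0 || window_kb < 0)
    stop("r2_threshold and window_kb must be non-negative")
  if (nrow(candidates) == 0) return(candidates)
  r2 <- as_ld_r2(ld)
  pool <- candidates[order(candidates$pvalue, candidates$chrom,
                           candidates$pos), , drop = FALSE]
  ids <- variant_id(pool)
  keep <- integer(0)
  alive <- seq_len(nrow(pool))
  while (length(alive) > 0) {
    idx <- alive[1]
    keep <- c(keep, idx)
    rest <- alive[-1]
    if (length(rest) == 0) break
    near <- pool$chrom[rest] == pool$chrom[idx] &
      abs(pool$pos[rest] - pool$pos[idx]) <= window_kb * 1000
    linked <- vapply(rest, function(j) r2(ids[idx], ids[j]) > r2_threshold,
                     logical(1))
    alive <- rest[!(near | linked)]
  }
  out <- pool[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Drop instruments associated with the outcome
#'
#' Removes any instrument whose matching outcome record (by chrom and
#' position) has `pvalue <= p_exclude`, enforcing that instruments are not
#' themselves outcome hits. Instruments absent from the outcome dataset
#' are retained here (they drop later, at harmonization, with an explicit
#' reason).
#'
#' @param snps Data frame of exposure-side instrument records.
#' @param outcome_ds The outcome [summary_dataset].
#' @param p_exclude Outcome-association exclusion threshold
#'   (default `5e-5`).
#' @return Filtered data frame.
#' @export
exclude_outcome_associated <- function(snps, outcome_ds, p_exclude = 5e-5) {
  stopifnot(inherits(outcome_ds, "summary_dataset"))
  if (nrow(snps) == 0) return(snps)
  m <- match(variant_id(snps), variant_id(outcome_ds$records))
  out_p <- outcome_ds$records$pvalue[m]
  drop <- !is.na(out_p) & out_p <= p_exclude
  out <- snps[!drop, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Cross-trait pleiotropy screen
#'
#' Removes any instrument that is genome-wide significant
#' (`pvalue <= p_significant`) in at least `max_traits` of the other
#' exposure datasets — a variant driving many traits at once is a likely
#' pleiotropic hub and a poor instrument for any one of them. With no
#' other exposures supplied the screen is the identity.
#'
#' @param snps Data frame of instrument records.
#' @param other_exposures List of [summary_dataset] objects for the other
#'   exposures in the scan.
#' @param max_traits Removal threshold: significant in `>= max_traits`
#'   other traits (default `5`).
#' @param p_significant Per-trait significance level (default `5e-8`).
#' @return Filtered data frame.
#' @export
cross_trait_pleiotropy_filter <- function(snps, other_exposures = list(),
                                          max_traits = 5,
                                          p_significant = 5e-8) {
  if (nrow(snps) == 0 || length(other_exposures) == 0) return(snps)
  ids <- variant_id(snps)
  sig <- vapply(other_exposures, function(ds) {
    m <- match(ids, variant_id(ds$records))
    p <- ds$records$pvalue[m]
    !is.na(p) & p <= p_significant
  }, logical(length(ids)))
  hits <- rowSums(matrix(sig, nrow = length(ids)))
  out <- snps[hits < max_traits, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-variant exposure variance explained
#'
#' Approximates the variance in a standardized exposure explained by one
#' variant: `2 eaf (1 - eaf) beta^2` when the effect-allele frequency is
#' known, else the z-statistic fallback `z^2 / (z^2 + n - 2)` with
#' `z = beta / se`.
#'
#' @param rec Data frame of association records (vectorized over rows).
#' @return Numeric vector of r-squared values in `[0, 1)`.
#' @export
snp_r2 <- function(rec) {
  z2 <- (rec$beta / rec$se)^2
  need_fallback <- is.na(rec$eaf)
  if (any(need_fallback & (is.na(rec$n) | rec$n < 3)))
    stop("r-squared undefined: eaf missing and n < 3")
  ifelse(need_fallback, z2 / (z2 + rec$n - 2),
         2 * rec$eaf * (1 - rec$eaf) * rec$beta^2)
}

#' Instrument-strength F-statistic
#'
#' `F = R^2 (n - 1 - k) / ((1 - R^2) k)`, where `R^2` is the total variance
#' in the exposure explained by the `k` instruments and `n` the exposure
#' GWAS sample size. Values above 20 are conventionally taken to indicate
#' strong instruments.
#'
#' @param r2_total Summed instrument r-squared, in `[0, 1)`.
#' @param n Exposure sample size; must exceed `k + 1`.
#' @param k Number of instruments (>= 1).
#' @return The F-value.
#' @export
f_statistic <- function(r2_total, n, k) {
  if (r2_total < 0 || r2_total >= 1) stop("r2_total must be in [0, 1)")
  if (k < 1) stop("k must be at least 1")
  if (n <= k + 1) stop("n must exceed k + 1")
  r2_total * (n - 1 - k) / ((1 - r2_total) * k)
}

#' Run the full instrument-selection funnel for one exposure
#'
#' Applies, in order: genome-wide significance selection, greedy LD
#' clumping, the outcome-association exclusion, and the cross-trait
#' pleiotropy screen; then computes total instrument r-squared and the
#' F-statistic. Per-SNP provenance records which stage removed each
#' candidate.
#'
#' @param exposure Exposure [summary_dataset].
#' @param outcome Outcome [summary_dataset], or `NULL` to skip the
#'   outcome-association exclusion.
#' @param other_exposures List of other exposure datasets for the
#'   pleiotropy screen (default none).
#' @param ld LD source for [clump()].
#' @param p_threshold,clump_r2,clump_window_kb,p_outcome_exclude,pleiotropy_max_traits
#'   Stage thresholds; defaults `5e-8`, `0.001`, `100`, `5e-5`, `5`.
#' @param f_flag F-value below which the set is flagged as weak
#'   (default `20`); reported, never used to drop instruments.
#' @return An object of class `instrument_set`: list with `snps` (retained
#'   records), `provenance` (variant, stage of removal or `"kept"`),
#'   `r2_total`, `f_stat`, `k`, `n`, `weak_flag` and the counts after each
#'   stage (`n_candidates`, `n_clumped`, `n_after_outcome_filter`,
#'   `n_final`).
#' @export
select_instruments <- function(exposure, outcome = NULL,
                               other_exposures = list(), ld = NULL,
                               p_threshold = 5e-8, clump_r2 = 0.001,
                               clump_window_kb = 100,
                               p_outcome_exclude = 5e-5,
                               pleiotropy_max_traits = 5, f_flag = 20) {
  cand <- select_by_pvalue(exposure, p_threshold)
  clumped <- clump(cand, ld, clump_r2, clump_window_kb)
  after_out <- if (is.null(outcome)) clumped else
    exclude_outcome_associated(clumped, outcome, p_outcome_exclude)
  final <- cross_trait_pleiotropy_filter(after_out, other_exposures,
                                         pleiotropy_max_traits)

  stage <- rep("clump", nrow(cand))
  stage[variant_id(cand) %in% variant_id(clumped)] <- "outcome_exclusion"
  stage[variant_id(cand) %in% variant_id(after_out)] <- "pleiotropy_filter"
  stage[variant_id(cand) %in% variant_id(final)] <- "kept"
  provenance <- data.frame(variant = variant_id(cand), stage = stage)

  k <- nrow(final)
  if (k > 0) {
    r2_total <- min(sum(snp_r2(final)), 1 - 1e-12)
    n <- round(stats::median(final$n, na.rm = TRUE))
    f <- if (is.finite(n) && n > k + 1) f_statistic(r2_total, n, k) else NA_real_
  } else {
    r2_total <- 0; n <- NA_integer_; f <- NA_real_
  }
  structure(list(exposure_trait = exposure$trait_name, snps = final,
                 provenance = provenance, r2_total = r2_total,
                 f_stat = f, k = k, n = n,
                 weak_flag = is.na(f) || f <= f_flag,
                 n_candidates = nrow(cand), n_clumped = nrow(clumped),
                 n_after_outcome_filter = nrow(after_out), n_final = k),
            class = "instrument_set")
}

#' @export
print.instrument_set <- function(x, ...) {
  cat(sprintf("Instrument set for %s: %d candidates -> %d clumped -> %d -> %d kept\n",
              x$exposure_trait, x$n_candidates, x$n_clumped,
              x$n_after_outcome_filter, x$k))
  if (x$k > 0)
    cat(sprintf("  total R^2 = %.4g, F = %.2f%s\n", x$r2_total, x$f_stat,
                if (isTRUE(x$weak_flag)) " (weak: F <= 20)" else ""))
  invisible(x)
}
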