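.complement <- c(A = "T", C = "G", G = "C", T = "A")

is_palindromic <- function(ea, oa) {
  (ea == "A" & oa == "T") | (ea == "T" & oa == "A") |
    (ea == "C" & oa == "G") | (ea == "G" & oa == "C")
}

#' Harmonize one exposure/outcome record pair to a common effect allele
#'
#' Aligns the outcome record to the exposure's effect allele. Identical
#' allele pairs are kept as-is; swapped pairs (outcome effect allele equals
#' the exposure's other allele) have the outcome beta sign-flipped; pairs
#' matching only after complementing both outcome alleles are treated as
#' strand flips (with the sign flip when also swapped). Palindromic
#' variants (A/T or C/G) carry no strand information in their labels, so
#' orientation is inferred from effect-allele frequency: both frequencies
#' must lie outside `0.5 +/- palindrome_eaf_window`; same side of 0.5
#' means same orientation, opposite sides mean the outcome beta is
#' sign-flipped. Ambiguous palindromes, frequency-free palindromes, indels
#' and incompatible allele pairs are dropped with an explicit reason.
#'
#' @param exp_rec,out_rec One-row data frames (or lists) of association
#'   records at the same (chrom, pos).
#' @param palindrome_eaf_window Half-width of the frequency ambiguity zone
#'   around 0.5 (default `0.08`, i.e. eaf in 0.42--0.58 is ambiguous).
#' @param palindromes `"infer"` (default) to use the frequency rule, or
#'   `"drop"` to drop every palindromic variant.
#' @return One-row data frame: the variant in exposure orientation,
#'   `beta_exp`, `se_exp`, `eaf_exp`, `beta_out`, `se_out`, `eaf_out`,
#'   `action` (one of `kept_as_is`, `sign_flipped`, `strand_flipped`,
#'   `dropped`) and `drop_reason` (`NA` unless dropped).
#' @export
harmonize_pair <- function(exp_rec, out_rec, palindrome_eaf_window = 0.08,
                           palindromes = c("infer", "drop")) {
  palindromes <- match.arg(palindromes)
  exp_rec <- as.list(exp_rec); out_rec <- as.list(out_rec)
  if (exp_rec$chrom != out_rec$chrom || exp_rec$pos != out_rec$pos)
    stop("records are at different genomic positions")

  res <- data.frame(chrom = exp_rec$chrom, pos = exp_rec$pos,
                    effect_allele = exp_rec$effect_allele,
                    other_allele = exp_rec$other_allele,
                    beta_exp = exp_rec$beta, se_exp = exp_rec$se,
                    eaf_exp = exp_rec$eaf,
                    beta_out = out_rec$beta, se_out = out_rec$se,
                    eaf_out = out_rec$eaf,
                    action = NA_character_, drop_reason = NA_character_)
  drop <- function(why) { res$action <- "dropped"; res$drop_reason <- why; res }

  nt <- c("A", "C", "G", "T")
  ea_x <- exp_rec$effect_allele; oa_x <- exp_rec$other_allele
  ea_y <- out_rec$effect_allele; oa_y <- out_rec$other_allele
  if (!all(c(ea_x, oa_x, ea_y, oa_y) %in% nt)) return(drop("non_snp"))

  if (is_palindromic(ea_x, oa_x)) {
    if (palindromes == "drop") return(drop("palindromic_dropped"))
    # labels are strand-ambiguous: outcome alleles must still be the same
    # pair (possibly written in either order)
    if (!setequal(c(ea_y, oa_y), c(ea_x, oa_x)))
      return(drop("allele_mismatch"))
    fx <- exp_rec$eaf
    # frequency and beta of the exposure's effect allele under the
    # same-strand reading of the outcome labels
    lab_same <- identical(ea_y, ea_x)
    fy_same <- if (is.na(out_rec$eaf)) NA_real_ else
      if (lab_same) out_rec$eaf else 1 - out_rec$eaf
    b_same <- if (lab_same) out_rec$beta else -out_rec$beta
    w <- palindrome_eaf_window
    if (is.na(fx) || is.na(fy_same) ||
        abs(fx - 0.5) <= w || abs(fy_same - 0.5) <= w)
      return(drop("palindromic_ambiguous"))
    if ((fx - 0.5) * (fy_same - 0.5) > 0) {
      res$beta_out <- b_same
      res$eaf_out <- fy_same
      res$action <- if (lab_same) "kept_as_is" else "sign_flipped"
    } else {
      # frequencies disagree: the outcome is on the opposite strand, which
      # for a palindrome swaps the alleles
      res$beta_out <- -b_same
      res$eaf_out <- 1 - fy_same
      res$action <- "strand_flipped"
    }
    return(res)
  }

  same <- identical(ea_y, ea_x) && identical(oa_y, oa_x)
  swapped <- identical(ea_y, oa_x) && identical(oa_y, ea_x)
  cea <- unname(.complement[ea_y]); coa <- unname(.complement[oa_y])
  c_same <- identical(cea, ea_x) && identical(coa, oa_x)
  c_swapped <- identical(cea, oa_x) && identical(coa, ea_x)

  if (same) {
    res$action <- "kept_as_is"
  } else if (swapped) {
    res$action <- "sign_flipped"
    res$beta_out <- -res$beta_out
    if (!is.na(res$eaf_out)) res$eaf_out <- 1 - res$eaf_out
  } else if (c_same) {
    res$action <- "strand_flipped"
  } else if (c_swapped) {
    res$action <- "strand_flipped"
    res$beta_out <- -res$beta_out
    if (!is.na(res$eaf_out)) res$eaf_out <- 1 - res$eaf_out
  } else {
    return(drop("allele_mismatch"))
  }
  res
}

#' Harmonize a set of instruments against an outcome dataset
#'
#' Matches each instrument to the outcome dataset by (chrom, pos) and
#' applies [harmonize_pair()]. Instruments absent from the outcome are
#' dropped with reason `missing_in_outcome`. Every input instrument
#' appears exactly once in the result, either kept (with an action) or
#' dropped (with a reason).
#'
#' @param instruments Data frame of exposure-side instrument records.
#' @param outcome_ds Outcome [summary_dataset].
#' @param palindrome_eaf_window,palindromes Passed to [harmonize_pair()].
#' @return Data frame of class `harmonized_pairs`, one row per instrument.
#' @export
harmonize_set <- function(instruments, outcome_ds,
                          palindrome_eaf_window = 0.08,
                          palindromes = c("infer", "drop")) {
  stopifnot(inherits(outcome_ds, "summary_dataset"))
  palindromes <- match.arg(palindromes)
  if (nrow(instruments) == 0) {
    out <- data.frame(chrom = character(), pos = integer(),
                      effect_allele = character(), other_allele = character(),
                      beta_exp = numeric(), se_exp = numeric(),
                      eaf_exp = numeric(), beta_out = numeric(),
                      se_out = numeric(), eaf_out = numeric(),
                      action = character(), drop_reason = character())
    class(out) <- c("harmonized_pairs", "data.frame")
    return(out)
  }
  m <- match(variant_id(instruments), variant_id(outcome_ds$records))
  rows <- lapply(seq_len(nrow(instruments)), function(i) {
    exp_rec <- instruments[i, , drop = FALSE]
    if (is.na(m[i])) {
      data.frame(chrom = exp_rec$chrom, pos = exp_rec$pos,
                 effect_allele = exp_rec$effect_allele,
                 other_allele = exp_rec$other_allele,
                 beta_exp = exp_rec$beta, se_exp = exp_rec$se,
                 eaf_exp = exp_rec$eaf, beta_out = NA_real_,
                 se_out = NA_real_, eaf_out = NA_real_,
                 action = "dropped", drop_reason = "missing_in_outcome")
    } else {
      harmonize_pair(exp_rec, outcome_ds$records[m[i], , drop = FALSE],
                     palindrome_eaf_window, palindromes)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("harmonized_pairs", "data.frame")
  out
}

#' Kept rows of a harmonized set
#' @param pairs A `harmonized_pairs` data frame.
#' @export
kept_pairs <- function(pairs) {
  pairs[pairs$action != "dropped", , drop = FALSE]
}

#' Write the harmonization audit trail
#'
#' @param pairs A `harmonized_pairs` data frame.
#' @param path Output TSV path (variant, action, drop_reason).
#' @export
write_harmonization_audit <- function(pairs, path) {
  audit <- data.frame(variant = variant_id(pairs), action = pairs$action,
                      drop_reason = pairs$drop_reason)
  utils::write.table(audit, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}
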