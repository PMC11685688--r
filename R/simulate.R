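#' Configuration for the summary-level GWAS simulator
#'
#' Defines a paired exposure/outcome two-sample design with known truth.
#' Variants come in loci; each locus has one index variant whose true
#' exposure effect is drawn from Normal(0, `gamma_sd`^2) (with probability
#' `prop_causal_snps`, else 0), and the remaining variants in the locus tag
#' it with exchangeable correlation `ld_rho`, so their marginal exposure
#' effects are `ld_rho` times the index effect. The true outcome effect of
#' variant j is `causal_beta * gamma_j + alpha_j`, where `alpha_j` is a
#' direct (pleiotropic) effect drawn from Normal(0, `pleiotropy_sd`^2) for
#' a fraction `pleiotropy_prop` of variants and 0 otherwise.
#'
#' Defaults encode the reference experiment used throughout the package's
#' calibration checks: 50 single-variant loci, both GWAS of size 100,000,
#' a causal effect of 0.2 on the log-odds scale, per-variant exposure
#' effects with SD 0.05, and no pleiotropy.
#'
#' @param n_loci Number of independent loci.
#' @param snps_per_locus Variants per locus.
#' @param ld_rho Within-locus exchangeable correlation, in `[0, 1)`.
#' @param maf_range Range (low, high) of the uniform minor-allele-frequency
#'   draw, within (0, 0.5].
#' @param n_exposure,n_outcome GWAS sample sizes (>= 100).
#' @param causal_beta True causal effect of exposure on outcome.
#' @param prop_causal_snps Fraction of loci whose index variant affects the
#'   exposure.
#' @param gamma_sd SD of true index-variant exposure effects.
#' @param pleiotropy_prop Fraction of variants with a direct outcome effect.
#' @param pleiotropy_sd SD of direct outcome effects.
#' @param seed Integer seed; the whole study is a pure function of the
#'   configuration.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_loci = 50, snps_per_locus = 1, ld_rho = 0,
                       maf_range = c(0.1, 0.5),
                       n_exposure = 100000, n_outcome = 100000,
                       causal_beta = 0.2, prop_causal_snps = 1,
                       gamma_sd = 0.05,
                       pleiotropy_prop = 0, pleiotropy_sd = 0,
                       seed = 1) {
  cfg <- list(n_loci = as.integer(n_loci),
              snps_per_locus = as.integer(snps_per_locus),
              ld_rho = ld_rho, maf_range = maf_range,
              n_exposure = as.integer(n_exposure),
              n_outcome = as.integer(n_outcome),
              causal_beta = causal_beta,
              prop_causal_snps = prop_causal_snps, gamma_sd = gamma_sd,
              pleiotropy_prop = pleiotropy_prop,
              pleiotropy_sd = pleiotropy_sd, seed = as.integer(seed))
  with(cfg, {
    if (n_loci < 1 || snps_per_locus < 1)
      stop("n_loci and snps_per_locus must be positive")
    if (ld_rho < 0 || ld_rho >= 1) stop("ld_rho must be in [0, 1)")
    if (length(maf_range) != 2 || maf_range[1] <= 0 ||
        maf_range[2] > 0.5 || maf_range[1] > maf_range[2])
      stop("maf_range must be (low, high) within (0, 0.5]")
    if (n_exposure < 100 || n_outcome < 100)
      stop("sample sizes must be at least 100")
    if (prop_causal_snps < 0 || prop_causal_snps > 1 ||
        pleiotropy_prop < 0 || pleiotropy_prop > 1)
      stop("proportions must be in [0, 1]")
    if (prop_causal_snps > 0 && gamma_sd <= 0)
      stop("gamma_sd must be positive when any locus is causal")
  })
  structure(cfg, class = "sim_config")
}

# run expr with a private RNG stream; the caller's .Random.seed is untouched
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has_old) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

# deterministic per-locus substream seed, kept inside 32-bit range
locus_seed <- function(seed, locus) {
  as.integer((as.numeric(seed) * 48271 + locus * 1000003) %% 2147483647)
}

# non-palindromic allele pairs only: harmonization of simulated data is
# then unambiguous, and palindrome handling is exercised by scrambling
# orientations explicitly
.allele_pairs <- cbind(ea = c("A", "A", "C", "C", "G", "G", "T", "T"),
                       oa = c("C", "G", "A", "T", "A", "T", "C", "G"))

#' Simulate a paired exposure/outcome GWAS summary study
#'
#' Generates summary statistics directly at the summary level: the
#' observed beta for each variant and trait is drawn as
#' Normal(truth, se^2) with se = 1/sqrt(2 n maf (1 - maf)), the standard
#' error of a per-allele effect on a standardized trait, and the two-sided
#' p-value follows from the normal z. See [sim_config()] for the
#' generative model of the true effects.
#'
#' The same configuration (including its seed) always yields an identical
#' study; per-locus substreams make the draw for locus `l` independent of
#' `n_loci`.
#'
#' @param config A [sim_config()].
#' @return An object of class `simulated_study`: list with `exposure` and
#'   `outcome` (two [summary_dataset] objects over the same variants),
#'   `ld` (per-locus correlation matrices), `truth` (data frame with the
#'   true `gamma` (marginal exposure effect), `alpha` (direct outcome
#'   effect), `Gamma` (total outcome effect), `maf`, locus and index-SNP
#'   bookkeeping) and `config`.
#' @export
simulate_study <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  m <- config$snps_per_locus
  per_locus <- function(l) {
    with_seed(locus_seed(config$seed, l), {
      chrom <- as.character((l - 1L) %% 22L + 1L)
      base <- 1e6 + ((l - 1L) %/% 22L) * 5e6
      pos <- as.integer(base + (seq_len(m) - 1L) * 1000L)
      pair <- .allele_pairs[sample.int(nrow(.allele_pairs), m, replace = TRUE), ,
                            drop = FALSE]
      maf <- stats::runif(m, config$maf_range[1], config$maf_range[2])
      causal <- stats::runif(1) < config$prop_causal_snps
      g_index <- if (causal) stats::rnorm(1, 0, config$gamma_sd) else 0
      gamma <- g_index * c(1, rep(config$ld_rho, m - 1L))
      pleio <- stats::runif(m) < config$pleiotropy_prop
      alpha <- ifelse(pleio, stats::rnorm(m, 0, config$pleiotropy_sd), 0)
      Gamma <- config$causal_beta * gamma + alpha
      se_x <- 1 / sqrt(2 * config$n_exposure * maf * (1 - maf))
      se_y <- 1 / sqrt(2 * config$n_outcome * maf * (1 - maf))
      bx <- stats::rnorm(m, gamma, se_x)
      by <- stats::rnorm(m, Gamma, se_y)
      data.frame(locus = l, chrom = chrom, pos = pos,
                 effect_allele = pair[, "ea"], other_allele = pair[, "oa"],
                 maf = maf, is_index = seq_len(m) == 1L,
                 gamma = gamma, alpha = alpha, Gamma = Gamma,
                 beta_x = bx, se_x = se_x, beta_y = by, se_y = se_y)
    })
  }
  tab <- do.call(rbind, lapply(seq_len(config$n_loci), per_locus))

  mk <- function(beta, se, n, trait) {
    p <- 2 * stats::pnorm(-abs(beta / se))
    summary_dataset(
      data.frame(chrom = tab$chrom, pos = tab$pos,
                 effect_allele = tab$effect_allele,
                 other_allele = tab$other_allele,
                 eaf = tab$maf, beta = beta, se = se, pvalue = p, n = n),
      trait_name = trait, trait_type = "binary", population = "synthetic")
  }
  exposure <- mk(tab$beta_x, tab$se_x, config$n_exposure, "simulated_exposure")
  outcome <- mk(tab$beta_y, tab$se_y, config$n_outcome, "simulated_outcome")

  ld <- lapply(seq_len(config$n_loci), function(l) {
    r <- matrix(config$ld_rho, m, m)
    diag(r) <- 1
    rownames(r) <- colnames(r) <-
      variant_id(tab[tab$locus == l, , drop = FALSE])
    r
  })
  truth <- tab[c("locus", "chrom", "pos", "effect_allele", "other_allele",
                 "maf", "is_index", "gamma", "alpha", "Gamma")]
  truth$variant <- variant_id(truth)
  structure(list(exposure = exposure, outcome = outcome, ld = ld,
                 truth = truth, config = config),
            class = "simulated_study")
}

#' @export
print.simulated_study <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(paste0("Simulated two-sample study: %d loci x %d SNPs, ",
                     "causal beta = %g, LD rho = %g\n"),
              cfg$n_loci, cfg$snps_per_locus, cfg$causal_beta, cfg$ld_rho))
  invisible(x)
}

#' Within-locus LD matrix of a simulated study
#'
#' @param study A `simulated_study`.
#' @param locus_index Locus number in `1..n_loci`.
#' @return Symmetric correlation matrix with unit diagonal; off-diagonals
#'   equal the configured `ld_rho` (exchangeable model).
#' @export
ld_matrix_for_locus <- function(study, locus_index) {
  stopifnot(inherits(study, "simulated_study"))
  if (length(locus_index) != 1 || locus_index < 1 ||
      locus_index > length(study$ld))
    stop("locus_index out of range")
  study$ld[[locus_index]]
}

#' Pairwise LD lookup function for a simulated study
#'
#' @param study A `simulated_study`.
#' @return A function `(id_a, id_b) -> r` over `"chrom:pos"` variant ids:
#'   1 for identical variants, the configured `ld_rho` within a locus,
#'   0 across loci. Suitable as the `ld` argument of [clump()].
#' @export
ld_from_study <- function(study) {
  stopifnot(inherits(study, "simulated_study"))
  locus_of <- stats::setNames(study$truth$locus, study$truth$variant)
  rho <- study$config$ld_rho
  function(id_a, id_b) {
    if (identical(id_a, id_b)) return(1)
    la <- locus_of[id_a]; lb <- locus_of[id_b]
    if (is.na(la) || is.na(lb) || la != lb) 0 else rho
  }
}

#' Write a simulated study to plain-text files
#'
#' Emits `exposure.tsv` and `outcome.tsv` in the summary-table dialect of
#' [write_summary_table()], `truth.tsv` (variant, locus, is_index, maf,
#' gamma_true, alpha_true, Gamma_true), and one `ld_locus<i>.txt` square
#' matrix per locus.
#'
#' @param study A `simulated_study`.
#' @param dir Output directory (created if needed).
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "simulated_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_summary_table(study$exposure, file.path(dir, "exposure.tsv"))
  write_summary_table(study$outcome, file.path(dir, "outcome.tsv"))
  tr <- study$truth
  out <- data.frame(variant = tr$variant, locus = tr$locus,
                    is_index = tr$is_index, maf = sprintf("%.17g", tr$maf),
                    gamma_true = sprintf("%.17g", tr$gamma),
                    alpha_true = sprintf("%.17g", tr$alpha),
                    Gamma_true = sprintf("%.17g", tr$Gamma))
  utils::write.table(out, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  for (l in seq_along(study$ld)) {
    utils::write.table(study$ld[[l]],
                       file.path(dir, sprintf("ld_locus%d.txt", l)),
                       sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(dir)
}
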