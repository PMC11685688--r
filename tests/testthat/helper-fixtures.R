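# shared fixtures: small record tables, random datasets for round-trip
# properties, and the calibration estimate used by the simulation checks

make_records <- function(n = 3, chrom = "1", pos = NULL, ea = "A", oa = "G",
                         beta = 0.1, se = 0.01, pvalue = 1e-10, eaf = 0.3,
                         nsamp = 50000) {
  data.frame(chrom = chrom, pos = pos %||% seq(1e6, by = 1e5, length.out = n),
             effect_allele = ea, other_allele = oa, eaf = eaf, beta = beta,
             se = se, pvalue = pvalue, n = nsamp)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

make_dataset <- function(records, name = "trait") {
  summary_dataset(records, trait_name = name)
}

random_dataset <- function(seed, n = 20) {
  set.seed(seed)
  nt <- c("A", "C", "G", "T")
  ea <- sample(nt, n, replace = TRUE)
  oa <- vapply(ea, function(a) sample(setdiff(nt, a), 1), "")
  rec <- data.frame(
    chrom = as.character(sample(1:22, n, replace = TRUE)),
    pos = sample(1e6:2e8, n),
    effect_allele = ea, other_allele = oa,
    eaf = ifelse(stats::runif(n) < 0.8, stats::runif(n, 0.01, 0.99), NA),
    beta = stats::rnorm(n, 0, 0.2),
    se = stats::runif(n, 0.001, 0.1),
    pvalue = stats::runif(n),
    n = sample(1000:500000, n))
  make_dataset(rec, name = paste0("random", seed))
}

# selection + harmonization + IVW on a simulated study; the estimation
# path used by the parameter-recovery / coverage / null checks
calibration_estimate <- function(seed, causal_beta = 0.2) {
  st <- simulate_study(sim_config(causal_beta = causal_beta, seed = seed))
  cand <- select_by_pvalue(st$exposure)
  pairs <- harmonize_set(cand, st$outcome)
  fit <- mr_fit(pairs)
  c(beta = fit$beta, ci_low = log(fit$ci_low), ci_high = log(fit$ci_high),
    pvalue = fit$pvalue, k = fit$k)
}

# brute-force validity check for clumped output: every retained pair must
# be separated (different chrom or > window) and uncorrelated (r2 <= thr)
clump_is_valid <- function(retained, r2_fun, r2_threshold, window_kb) {
  if (nrow(retained) < 2) return(TRUE)
  ids <- sprintf("%s:%d", retained$chrom, as.integer(retained$pos))
  for (i in seq_len(nrow(retained) - 1)) {
    for (j in (i + 1):nrow(retained)) {
      same_chr <- retained$chrom[i] == retained$chrom[j]
      near <- same_chr &&
        abs(retained$pos[i] - retained$pos[j]) <= window_kb * 1000
      linked <- r2_fun(ids[i], ids[j])^2 > r2_threshold
      if (near || linked) return(FALSE)
    }
  }
  TRUE
}
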