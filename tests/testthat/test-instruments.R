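test_that("p-value selection keeps exactly the sub-threshold records, sorted", {
  ds <- make_dataset(make_records(2, pos = c(1e6, 2e6),
                                  pvalue = c(1e-7, 1e-9)))
  hit <- select_by_pvalue(ds)
  expect_equal(nrow(hit), 1)
  expect_equal(hit$pvalue, 1e-9)
  expect_equal(nrow(select_by_pvalue(make_dataset(make_records(3, pvalue = 1)))), 0)
  # brute-force oracle on a large random dataset
  ds <- random_dataset(21, n = 1000)
  thr <- 0.3
  got <- select_by_pvalue(ds, thr)
  want <- ds$records[ds$records$pvalue <= thr, ]
  want <- want[order(want$pvalue, want$chrom, want$pos), ]
  expect_equal(got, want, ignore_attr = TRUE)
})

test_that("greedy clumping follows the window and r2 rules", {
  one <- make_records(1, pos = 1e6)
  expect_equal(nrow(clump(one)), 1)

  # window rule: middle SNP inside 100 kb of the top SNP is removed
  three <- make_records(3, pos = c(1e6, 1.05e6, 2e6),
                        pvalue = c(1e-12, 1e-10, 1e-9))
  got <- clump(three)
  expect_equal(got$pos, c(1e6, 2e6))

  # r2 rule: 500 kb apart but r2 = 0.5 > 0.001 removes the weaker SNP
  two <- make_records(2, pos = c(1e6, 1.5e6), pvalue = c(1e-12, 1e-9))
  ld <- data.frame(variant_a = "1:1000000", variant_b = "1:1500000", r2 = 0.5)
  got <- clump(two, ld = ld)
  expect_equal(got$pos, 1e6)
  # same pair with no LD entry: both survive (absent pairs are r2 = 0)
  expect_equal(nrow(clump(two)), 2)

  expect_error(clump(two, r2_threshold = -1), "non-negative")
})

test_that("clumped output is pairwise independent on random instances and deterministic", {
  set.seed(42)
  for (rep in 1:30) {
    n <- sample(2:8, 1)
    cand <- make_records(n, chrom = as.character(sample(1:2, n, replace = TRUE)),
                         pos = sample(seq(1e6, 1.6e6, by = 2.5e4), n),
                         pvalue = stats::runif(n, 1e-12, 1e-8))
    r <- matrix(stats::runif(n * n), n, n); r <- (r + t(r)) / 2; diag(r) <- 1
    ids <- sprintf("%s:%d", cand$chrom, as.integer(cand$pos))
    dimnames(r) <- list(ids, ids)
    ld_fun <- function(a, b) if (cand$chrom[match(a, ids)] ==
                                 cand$chrom[match(b, ids)]) r[a, b] else 0
    got <- clump(cand, ld = ld_fun)
    expect_true(clump_is_valid(got, ld_fun, 0.001, 100))
    # every removed candidate conflicts with a retained, lower-p SNP
    removed <- cand[!paste(cand$chrom, cand$pos) %in%
                      paste(got$chrom, got$pos), , drop = FALSE]
    for (i in seq_len(nrow(removed))) {
      better <- got[got$pvalue <= removed$pvalue[i], , drop = FALSE]
      conflicts <- vapply(seq_len(nrow(better)), function(j) {
        same <- better$chrom[j] == removed$chrom[i]
        (same && abs(better$pos[j] - removed$pos[i]) <= 1e5) ||
          ld_fun(sprintf("%s:%d", better$chrom[j], as.integer(better$pos[j])),
                 sprintf("%s:%d", removed$chrom[i],
                         as.integer(removed$pos[i])))^2 > 0.001
      }, logical(1))
      expect_true(any(conflicts))
    }
    expect_identical(clump(cand, ld = ld_fun), got)
  }
})

test_that("outcome-association exclusion matches a brute-force filter and commutes with selection", {
  set.seed(8)
  snps <- make_records(10, pos = seq(1e6, by = 2e6, length.out = 10),
                       pvalue = stats::runif(10, 1e-12, 1e-9))
  out_rec <- snps
  out_rec$pvalue <- c(1e-6, 0.5, stats::runif(8))
  out_ds <- make_dataset(out_rec, "outcome")
  got <- exclude_outcome_associated(snps, out_ds)
  oracle <- snps[out_rec$pvalue > 5e-5, ]
  expect_equal(got, oracle, ignore_attr = TRUE)
  expect_false(1e6 %in% got$pos)      # outcome p = 1e-6 removed
  expect_true(3e6 %in% got$pos)       # outcome p = 0.5 retained
  # SNPs absent from the outcome are retained at this stage
  small_out <- make_dataset(out_rec[3:10, ], "outcome")
  expect_equal(nrow(exclude_outcome_associated(snps[1:2, ], small_out)), 2)

  # order-insensitivity with p-value selection
  exp_ds <- make_dataset(snps, "exposure")
  a <- exclude_outcome_associated(select_by_pvalue(exp_ds), out_ds)
  b <- select_by_pvalue(make_dataset(
    exclude_outcome_associated(exp_ds$records, out_ds), "exposure"))
  expect_equal(a, b, ignore_attr = TRUE)
})

test_that("the cross-trait pleiotropy screen removes hub variants at the threshold", {
  snps <- make_records(2, pos = c(1e6, 5e6))
  other <- lapply(1:9, function(i) {
    rec <- snps
    # first SNP significant in traits 1..5, second in traits 1..4
    rec$pvalue <- c(if (i <= 5) 1e-9 else 0.5, if (i <= 4) 1e-9 else 0.5)
    make_dataset(rec, paste0("other", i))
  })
  expect_identical(cross_trait_pleiotropy_filter(snps, list()), snps)
  got <- cross_trait_pleiotropy_filter(snps, other, max_traits = 5)
  expect_equal(got$pos, 5e6)  # 5/9 removed, 4/9 retained
})

test_that("per-variant r2 and the F statistic match hand arithmetic", {
  expect_equal(snp_r2(data.frame(eaf = 0.5, beta = 0.1, se = 0.01, n = 1e4)),
               0.005)
  expect_equal(snp_r2(data.frame(eaf = NA, beta = 0.1, se = 0.01, n = 10000)),
               100 / 10098)
  expect_equal(snp_r2(data.frame(eaf = 0.3, beta = 0, se = 0.01, n = 1e4)), 0)
  expect_error(snp_r2(data.frame(eaf = NA, beta = 1, se = 1, n = 2)),
               "undefined")

  expect_equal(f_statistic(0, 1000, 5), 0)
  expect_equal(f_statistic(0.02, 10000, 10), 0.02 * 9989 / (0.98 * 10))
  expect_equal(f_statistic(0.5, 103, 1), 101)
  expect_error(f_statistic(1, 100, 1), "r2_total")
  expect_error(f_statistic(0.1, 3, 2), "n must exceed")
})

test_that("F is increasing in r2 and decreasing in k", {
  r2 <- seq(0.01, 0.5, by = 0.01)
  f <- vapply(r2, f_statistic, 0, n = 10000, k = 10)
  expect_true(all(diff(f) > 0))
  k <- 1:50
  f <- vapply(k, function(kk) f_statistic(0.1, 10000, kk), 0)
  expect_true(all(diff(f) < 0))
})

test_that("the selection funnel is monotone and its provenance complete", {
  st <- simulate_study(sim_config(n_loci = 40, snps_per_locus = 3,
                                  ld_rho = 0.4, seed = 17))
  iv <- select_instruments(st$exposure, st$outcome, ld = ld_from_study(st))
  expect_true(iv$n_candidates >= iv$n_clumped)
  expect_true(iv$n_clumped >= iv$n_after_outcome_filter)
  expect_true(iv$n_after_outcome_filter >= iv$k)
  expect_equal(nrow(iv$provenance), iv$n_candidates)
  expect_equal(sum(iv$provenance$stage == "kept"), iv$k)
  # stored F is recomputable from (r2_total, n, k)
  expect_equal(iv$f_stat, f_statistic(iv$r2_total, iv$n, iv$k))
})
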