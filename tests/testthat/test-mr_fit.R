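pair_df <- function(b_exp, se_exp, b_out, se_out) {
  data.frame(beta_exp = b_exp, se_exp = se_exp, beta_out = b_out,
             se_out = se_out)
}

test_that("the Wald ratio and its delta-method standard error are exact", {
  f <- wald_ratio(pair_df(0.1, 0.01, 0.02, 0.005))
  expect_equal(f$beta, 0.2)
  expect_equal(f$se, 0.05)
  expect_equal(f$k, 1)
  expect_equal(f$method, "wald_ratio")

  f <- wald_ratio(pair_df(-0.1, 0.01, 0.02, 0.005))
  expect_equal(f$beta, -0.2)
  expect_equal(f$se, 0.05)

  f <- wald_ratio(pair_df(0.1, 0.01, 0, 0.005))
  expect_equal(f$beta, 0)
  expect_equal(f$or, 1)

  expect_error(wald_ratio(pair_df(0, 0.01, 0.1, 0.005)), "degenerate")
})

test_that("fixed-effects IVW matches the hand-computed weighted mean and Q", {
  # ratios (0.2, 0.4) with se (0.05, 0.1): weights 400, 100
  pairs <- pair_df(c(1, 1), 0.01, c(0.2, 0.4), c(0.05, 0.1))
  f <- ivw_fixed(pairs)
  expect_equal(f$beta, 0.24)
  expect_equal(f$se, sqrt(1 / 500))
  expect_equal(f$q_stat, 400 * (0.2 - 0.24)^2 + 100 * (0.4 - 0.24)^2)
  expect_equal(f$q_stat, 3.2)
  expect_equal(f$q_df, 1)

  # identical ratios: pooled equals the common value, zero heterogeneity
  same <- pair_df(c(0.1, 0.2, 0.5), 0.01, c(0.03, 0.06, 0.15), 0.01)
  f <- ivw_fixed(same)
  expect_equal(f$beta, 0.3)
  expect_equal(f$q_stat, 0)

  expect_error(ivw_fixed(pair_df(1, 0.01, 0.2, 0.05)), "at least 2")
})

test_that("multiplicative random effects scale the SE by sqrt(Q/df), floored at 1", {
  pairs <- pair_df(c(1, 1), 0.01, c(0.2, 0.4), c(0.05, 0.1))
  f <- ivw_random(pairs)
  expect_equal(f$beta, 0.24)
  expect_equal(f$scale_factor, sqrt(3.2))
  expect_equal(f$se, sqrt(1 / 500) * sqrt(3.2))

  # homogeneous ratios: Q < df, scale floored, identical to fixed
  same <- pair_df(c(0.1, 0.2), 0.01, c(0.02, 0.04), 0.01)
  ff <- ivw_fixed(same); fr <- ivw_random(same)
  expect_equal(fr$scale_factor, 1)
  expect_equal(fr$se, ff$se)

  # property: random-effects SE never narrower than fixed
  set.seed(4)
  for (i in 1:20) {
    k <- sample(2:15, 1)
    p <- pair_df(stats::rnorm(k, 0.1, 0.02), 0.01,
                 stats::rnorm(k, 0.02, 0.02), stats::runif(k, 0.005, 0.02))
    expect_gte(ivw_random(p)$se, ivw_fixed(p)$se)
  }
})

test_that("IVW equals weighted least squares through the origin (independent oracle)", {
  set.seed(10)
  for (i in 1:25) {
    k <- sample(2:30, 1)
    p <- pair_df(stats::rnorm(k, 0.1, 0.03), 0.01,
                 stats::rnorm(k, 0.02, 0.02), stats::runif(k, 0.002, 0.02))
    f <- ivw_fixed(p)
    b <- p$beta_out / p$beta_exp
    w <- (abs(p$beta_exp) / p$se_out)^2
    wls <- stats::lm(b ~ 1, weights = w)
    expect_equal(f$beta, unname(coef(wls)[1]), tolerance = 1e-12)
    expect_equal(f$se, sqrt(1 / sum(w)), tolerance = 1e-12)
    # Cochran's Q is the weighted residual sum of squares of that fit
    expect_equal(f$q_stat, sum(w * residuals(wls)^2), tolerance = 1e-10)
  }
})

test_that("IVW is invariant to instrument order and global allele reorientation", {
  set.seed(12)
  k <- 10
  p <- pair_df(stats::rnorm(k, 0.1, 0.03), 0.01,
               stats::rnorm(k, 0.02, 0.02), stats::runif(k, 0.002, 0.02))
  f <- ivw_fixed(p)
  expect_equal(ivw_fixed(p[sample(k), ])$beta, f$beta)
  flipped <- pair_df(-p$beta_exp, p$se_exp, -p$beta_out, p$se_out)
  expect_equal(ivw_fixed(flipped)$beta, f$beta)
  expect_equal(ivw_fixed(flipped)$se, f$se)
  # duplicated single pair pools to that pair's Wald ratio
  dup <- p[c(1, 1), ]
  expect_equal(ivw_fixed(dup)$beta, wald_ratio(p[1, ])$beta)
})

test_that("Cochran's Q has chi-square mean under homogeneity", {
  set.seed(77)
  qn <- replicate(400, {
    k <- 6
    s <- stats::runif(k, 0.01, 0.05)
    b <- stats::rnorm(k, 0.2, s)     # homogeneous true ratio 0.2
    p <- pair_df(rep(1, k), 0.001, b, s)
    f <- ivw_fixed(p)
    f$q_stat / f$q_df
  })
  expect_lt(abs(mean(qn) - 1), 0.1)  # E[Q/(k-1)] = 1
})

test_that("the instrument-count rule selects the estimator", {
  expect_equal(select_model(1), "wald_ratio")
  expect_equal(select_model(2), "ivw_fixed")
  expect_equal(select_model(3), "ivw_random")
  expect_equal(select_model(5), "ivw_random")
  expect_equal(select_model(3, fixed_max_k = 3), "ivw_fixed")
  expect_error(select_model(0), "at least one")

  expect_equal(mr_fit(pair_df(0.1, 0.01, 0.02, 0.005))$method, "wald_ratio")
  p2 <- pair_df(c(1, 1), 0.01, c(0.2, 0.4), c(0.05, 0.1))
  expect_equal(mr_fit(p2)$method, "ivw_fixed")
  p3 <- pair_df(c(1, 1, 1), 0.01, c(0.2, 0.4, 0.3), 0.05)
  expect_equal(mr_fit(p3)$method, "ivw_random")
})

test_that("odds-ratio reporting matches the normal theory identities", {
  r <- to_odds_ratio(0, 0.1)
  expect_equal(r$or, 1)
  expect_equal(r$pvalue, 1)
  expect_equal(r$ci_low * r$ci_high, 1)  # symmetric around 1 on log scale

  r <- to_odds_ratio(log(2), 0.1)
  expect_equal(r$or, 2)
  expect_equal(r$ci_low, exp(log(2) - stats::qnorm(0.975) * 0.1))
  expect_equal(round(r$ci_low, 3), 1.644)
  expect_equal(round(r$ci_high, 3), 2.433)

  r <- to_odds_ratio(stats::qnorm(0.975) * 0.3, 0.3)
  expect_equal(r$pvalue, 0.05)

  expect_error(to_odds_ratio(0.1, 0), "positive")
})

test_that("mr_fit objects support the standard modelling generics", {
  p <- pair_df(c(0.1, 0.08, 0.12), 0.01, c(0.021, 0.015, 0.026),
               c(0.005, 0.006, 0.005))
  f <- mr_fit(p)
  expect_s3_class(f, "mr_fit")
  expect_named(coef(f), "causal_beta")
  expect_equal(unname(sqrt(vcov(f)[1, 1])), f$se)
  ci <- confint(f)
  expect_equal(unname(ci[1, ]), f$beta + c(-1, 1) * stats::qnorm(0.975) * f$se)
  expect_length(residuals(f), 3)
  expect_output(print(f), "Two-sample MR estimate")
  expect_output(print(summary(f)), "Cochran's Q")
  pdf(NULL); on.exit(dev.off())
  expect_invisible(plot(f))
})
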