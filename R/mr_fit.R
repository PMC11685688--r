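#' Choose the causal-effect estimator from the instrument count
#'
#' One instrument admits only the Wald ratio; two instruments are combined
#' by fixed-effects IVW; with three or more, heterogeneity between
#' ratios becomes estimable and the multiplicative random-effects IVW is
#' used.
#'
#' @param k Number of harmonized instruments (>= 1).
#' @param fixed_max_k Largest `k` for which the fixed-effects model is
#'   used (default 2); `k` above it selects random effects.
#' @return `"wald_ratio"`, `"ivw_fixed"` or `"ivw_random"`.
#' @export
select_model <- function(k, fixed_max_k = 2) {
  if (k < 1) stop("at least one instrument is required")
  if (k == 1) "wald_ratio"
  else if (k <= fixed_max_k) "ivw_fixed"
  else "ivw_random"
}

#' Odds ratio, confidence interval and p-value from a log-scale estimate
#'
#' @param beta Log-scale effect estimate.
#' @param se Standard error (> 0).
#' @param alpha Two-sided significance level (default 0.05 for a 95% CI).
#' @return Data frame with `or`, `ci_low`, `ci_high`, `pvalue` (vectorized
#'   over `beta` and `se`).
#' @export
to_odds_ratio <- function(beta, se, alpha = 0.05) {
  if (any(se <= 0)) stop("se must be positive")
  z <- stats::qnorm(1 - alpha / 2)
  data.frame(or = exp(beta),
             ci_low = exp(beta - z * se),
             ci_high = exp(beta + z * se),
             pvalue = 2 * stats::pnorm(-abs(beta / se)))
}

# per-instrument Wald ratios and first-order delta-method weights;
# exposure-side uncertainty is ignored (two-sample convention)
ratio_table <- function(pairs) {
  pairs <- kept_pairs_or_df(pairs)
  if (any(pairs$beta_exp == 0)) stop("degenerate instrument: beta_exp = 0")
  b <- pairs$beta_out / pairs$beta_exp
  s <- pairs$se_out / abs(pairs$beta_exp)
  data.frame(b = b, s = s, w = 1 / s^2)
}

kept_pairs_or_df <- function(pairs) {
  if (inherits(pairs, "harmonized_pairs")) pairs <- kept_pairs(pairs)
  stopifnot(all(c("beta_exp", "se_exp", "beta_out", "se_out") %in% names(pairs)))
  pairs
}

#' Cochran's Q heterogeneity statistic of the per-instrument ratios
#'
#' `Q = sum_j w_j (b_j - beta_hat)^2` with inverse-variance weights, on
#' `k - 1` degrees of freedom; the p-value is the upper chi-square tail.
#'
#' @param pairs Harmonized pairs (or a data frame with `beta_exp`,
#'   `se_exp`, `beta_out`, `se_out`), at least two.
#' @param beta_hat Pooled estimate the deviations are measured from.
#' @return List with `q_stat`, `q_df`, `q_pvalue`.
#' @export
cochran_q <- function(pairs, beta_hat) {
  rt <- ratio_table(pairs)
  if (nrow(rt) < 2) stop("Cochran's Q requires at least 2 instruments")
  q <- sum(rt$w * (rt$b - beta_hat)^2)
  df <- nrow(rt) - 1L
  list(q_stat = q, q_df = df,
       q_pvalue = stats::pchisq(q, df, lower.tail = FALSE))
}

new_mr_fit <- function(method, beta, se, k, rt, alpha, scale_factor = 1,
                       q = NULL) {
  rep_ <- to_odds_ratio(beta, se, alpha)
  structure(list(method = method, beta = beta, se = se,
                 or = rep_$or, ci_low = rep_$ci_low, ci_high = rep_$ci_high,
                 pvalue = rep_$pvalue, k = k,
                 q_stat = if (is.null(q)) NA_real_ else q$q_stat,
                 q_df = if (is.null(q)) NA_integer_ else q$q_df,
                 q_pvalue = if (is.null(q)) NA_real_ else q$q_pvalue,
                 scale_factor = scale_factor, alpha = alpha, ratios = rt),
            class = "mr_fit")
}

#' Wald-ratio causal estimate from a single instrument
#'
#' `beta = beta_out / beta_exp` with first-order standard error
#' `se_out / |beta_exp|`.
#'
#' @param pair One kept harmonized pair.
#' @param alpha Significance level for the reported CI.
#' @return An [mr_fit] object with `method = "wald_ratio"`, `k = 1`.
#' @export
wald_ratio <- function(pair, alpha = 0.05) {
  rt <- ratio_table(pair)
  if (nrow(rt) != 1) stop("wald_ratio takes exactly one instrument")
  new_mr_fit("wald_ratio", rt$b, rt$s, 1L, rt, alpha)
}

#' Fixed-effects inverse-variance weighted estimate
#'
#' Inverse-variance weighted mean of the per-instrument Wald ratios:
#' `beta = sum(w b) / sum(w)`, `se = sqrt(1 / sum(w))`, `w = 1/s^2`.
#'
#' @param pairs Two or more kept harmonized pairs.
#' @param alpha Significance level for the reported CI.
#' @return An [mr_fit] object with `method = "ivw_fixed"`.
#' @export
ivw_fixed <- function(pairs, alpha = 0.05) {
  rt <- ratio_table(pairs)
  if (nrow(rt) < 2) stop("IVW requires at least 2 instruments")
  beta <- sum(rt$w * rt$b) / sum(rt$w)
  se <- sqrt(1 / sum(rt$w))
  q <- cochran_q(pairs, beta)
  new_mr_fit("ivw_fixed", beta, se, nrow(rt), rt, alpha, 1, q)
}

#' Multiplicative random-effects inverse-variance weighted estimate
#'
#' Point estimate identical to [ivw_fixed()]; the standard error is
#' inflated by `sqrt(Q / (k - 1))` when Cochran's Q exceeds its
#' expectation, and never deflated (scale floor at 1), so the
#' random-effects interval is at least as wide as the fixed-effects one.
#'
#' @param pairs Two or more kept harmonized pairs.
#' @param alpha Significance level for the reported CI.
#' @return An [mr_fit] object with `method = "ivw_random"`.
#' @export
ivw_random <- function(pairs, alpha = 0.05) {
  fit <- ivw_fixed(pairs, alpha)
  scale <- sqrt(max(1, fit$q_stat / fit$q_df))
  out <- new_mr_fit("ivw_random", fit$beta, fit$se * scale, fit$k,
                    fit$ratios, alpha, scale,
                    list(q_stat = fit$q_stat, q_df = fit$q_df,
                         q_pvalue = fit$q_pvalue))
  out
}

#' Fit a two-sample Mendelian randomization model
#'
#' The central fitting function: takes harmonized exposure/outcome pairs
#' and estimates the causal effect of the exposure on the outcome.
#' `method = "auto"` (the default) follows the instrument-count rule of
#' [select_model()]: Wald ratio for one instrument, fixed-effects IVW for
#' two, multiplicative random-effects IVW for three or more.
#'
#' @param pairs A `harmonized_pairs` data frame (dropped rows are
#'   ignored), or any data frame with columns `beta_exp`, `se_exp`,
#'   `beta_out`, `se_out`.
#' @param method `"auto"`, `"wald_ratio"`, `"ivw_fixed"` or
#'   `"ivw_random"`.
#' @param alpha Two-sided significance level (default 0.05).
#' @param fixed_max_k Boundary of the instrument-count rule (see
#'   [select_model()]).
#' @return An object of class `mr_fit`: log-scale `beta` and `se`, the
#'   odds ratio `or` with `ci_low`/`ci_high`, two-sided normal `pvalue`,
#'   instrument count `k`, Cochran's `q_stat`/`q_df`/`q_pvalue` (for
#'   `k >= 2`), the multiplicative `scale_factor`, and the per-instrument
#'   ratio table.
#' @seealso [summary.mr_fit()], [plot.mr_fit()], [run_scan()]
#' @examples
#' pairs <- data.frame(beta_exp = c(0.10, 0.08, 0.12),
#'                     se_exp = 0.01,
#'                     beta_out = c(0.021, 0.015, 0.026),
#'                     se_out = c(0.005, 0.006, 0.005))
#' fit <- mr_fit(pairs)
#' summary(fit)
#' @export
mr_fit <- function(pairs, method = c("auto", "wald_ratio", "ivw_fixed",
                                     "ivw_random"),
                   alpha = 0.05, fixed_max_k = 2) {
  method <- match.arg(method)
  kept <- kept_pairs_or_df(pairs)
  k <- nrow(kept)
  if (k < 1) stop("no instruments to fit")
  if (method == "auto") method <- select_model(k, fixed_max_k)
  switch(method,
         wald_ratio = wald_ratio(kept, alpha),
         ivw_fixed = ivw_fixed(kept, alpha),
         ivw_random = ivw_random(kept, alpha))
}

#' @export
print.mr_fit <- function(x, digits = 3, ...) {
  cat(sprintf("Two-sample MR estimate (%s, k = %d instruments)\n",
              x$method, x$k))
  cat(sprintf("  OR = %.*f  %d%% CI [%.*f, %.*f]  p = %.3g\n",
              digits, x$or, round(100 * (1 - x$alpha)),
              digits, x$ci_low, digits, x$ci_high, x$pvalue))
  invisible(x)
}

#' Summarize a fitted MR model
#'
#' @param object An `mr_fit`.
#' @param ... Unused.
#' @return The object, classed for printing with the log-scale estimate,
#'   OR-scale report, and heterogeneity diagnostics.
#' @export
summary.mr_fit <- function(object, ...) {
  structure(object, class = c("summary.mr_fit", "mr_fit"))
}

#' @export
print.summary.mr_fit <- function(x, digits = 3, ...) {
  print.mr_fit(x, digits = digits)
  cat(sprintf("  log-scale beta = %.4g (se %.4g)\n", x$beta, x$se))
  if (x$k >= 2) {
    cat(sprintf("  Cochran's Q = %.3f on %d df (p = %.3g); RE scale = %.3f\n",
                x$q_stat, x$q_df, x$q_pvalue, x$scale_factor))
  }
  cat(sprintf("  per-instrument Wald ratios: median %.4g, range [%.4g, %.4g]\n",
              stats::median(x$ratios$b), min(x$ratios$b), max(x$ratios$b)))
  invisible(x)
}

#' @export
coef.mr_fit <- function(object, ...) {
  stats::setNames(object$beta, "causal_beta")
}

#' @export
vcov.mr_fit <- function(object, ...) {
  matrix(object$se^2, 1, 1, dimnames = list("causal_beta", "causal_beta"))
}

#' @export
confint.mr_fit <- function(object, parm = "causal_beta", level = 0.95, ...) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  m <- matrix(object$beta + c(-1, 1) * z * object$se, 1, 2,
              dimnames = list("causal_beta",
                              sprintf("%g %%", c((1 - level) / 2,
                                                 1 - (1 - level) / 2) * 100)))
  m
}

#' @export
residuals.mr_fit <- function(object, ...) {
  # standardized deviation of each instrument's ratio from the pooled fit
  (object$ratios$b - object$beta) / object$ratios$s
}

#' Forest-style plot of per-instrument ratios and the pooled estimate
#'
#' @param x An `mr_fit`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.mr_fit <- function(x, ...) {
  rt <- x$ratios
  k <- nrow(rt)
  z <- stats::qnorm(1 - x$alpha / 2)
  lo <- rt$b - z * rt$s; hi <- rt$b + z * rt$s
  ylim <- c(0, k + 1)
  xlim <- range(lo, hi, x$beta - z * x$se, x$beta + z * x$se, 0)
  graphics::plot(NA, xlim = xlim, ylim = ylim, yaxt = "n",
                 xlab = "causal effect (log scale)", ylab = "",
                 main = sprintf("%s (k = %d)", x$method, x$k), ...)
  graphics::abline(v = 0, col = "grey70", lty = 2)
  graphics::segments(lo, k:1, hi, k:1)
  graphics::points(rt$b, k:1, pch = 15)
  graphics::segments(x$beta - z * x$se, 0.25, x$beta + z * x$se, 0.25,
                     lwd = 2, col = "firebrick")
  graphics::points(x$beta, 0.25, pch = 18, cex = 1.5, col = "firebrick")
  graphics::axis(2, at = c(k:1, 0.25),
                 labels = c(paste0("IV", seq_len(k)), "pooled"), las = 1)
  invisible(x)
}
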