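---
title: "Methods: two-sample Mendelian randomization with mrscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-sample Mendelian randomization with mrscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrscan)
```

## The model

Mendelian randomization treats genetic variants as instrumental variables
for the causal effect of an exposure on an outcome. In the two-sample
setting, the per-variant association of instrument $j$ with the exposure
($\hat\gamma_j$, standard error $\sigma_{Xj}$) and with the outcome
($\hat\Gamma_j$, standard error $\sigma_{Yj}$) come from different GWAS
cohorts, and only summary statistics are needed. Under the three
instrumental-variable assumptions — the variant is associated with the
exposure, is independent of confounders of the exposure-outcome
relationship, and affects the outcome only through the exposure — each
instrument gives a Wald ratio estimate of the causal effect
$\beta$:

$$\hat\beta_j = \frac{\hat\Gamma_j}{\hat\gamma_j}, \qquad
  s_j = \frac{\sigma_{Yj}}{|\hat\gamma_j|},$$

where $s_j$ is the first-order delta-method standard error, ignoring
exposure-side sampling error — the standard two-sample convention, accurate
when instruments are strong. The inverse-variance weighted (IVW) estimator
pools the ratios with weights $w_j = 1/s_j^2$:

$$\hat\beta_{IVW} = \frac{\sum_j w_j \hat\beta_j}{\sum_j w_j}, \qquad
  \mathrm{se}_{fixed} = \Big(\sum_j w_j\Big)^{-1/2}.$$

Heterogeneity between ratios is measured by Cochran's
$Q = \sum_j w_j (\hat\beta_j - \hat\beta_{IVW})^2$ on $k-1$ degrees of
freedom. The multiplicative random-effects variant keeps the same point
estimate and inflates the standard error by $\sqrt{\max(1, Q/(k-1))}$ —
never deflating it below the fixed-effects value, so random-effects
intervals are always at least as wide. For binary outcomes, effects are on
the log-odds scale and are reported as odds ratios with
$\exp(\hat\beta \pm z_{0.975}\,\mathrm{se})$ confidence bounds
($z_{0.975} = 1.959964$) and a two-sided normal p-value.

`mr_fit()` chooses the estimator from the instrument count: the Wald ratio
for a single instrument, fixed-effects IVW for two, and multiplicative
random-effects IVW for three or more (`fixed_max_k` moves the boundary;
the published descriptions of such count rules are sometimes ambiguous at
exactly three instruments, and we resolve the overlap in favour of random
effects, which is the conservative choice there).

## Instrument selection

`select_instruments()` runs the selection funnel in a fixed order, with
every threshold exposed:

1. **Relevance** (`p_threshold = 5e-8`): keep variants genome-wide
   significant for the exposure. Comparisons are inclusive (`<=`); ties
   are broken by genomic coordinate so selection is deterministic.
2. **LD clumping** (`clump_r2 = 0.001`, `clump_window_kb = 100`): greedy
   index selection by ascending p-value; each index removes remaining
   variants on the same chromosome within 100 kb *or* with squared
   correlation above 0.001 to it. The distance and correlation rules are
   joined by either-removes, the standard clumping semantics. LD comes
   from the caller (a lookup function or a pairwise r² table); absent
   pairs count as uncorrelated, and no reference panel is bundled, so
   clumps can differ from those produced against any particular panel.
3. **Outcome-association exclusion** (`p_outcome_exclude = 5e-5`): drop
   instruments that are themselves associated with the outcome. Variants
   missing from the outcome dataset are *not* dropped here — they drop at
   harmonization with reason `missing_in_outcome`, keeping each removal
   attributable to exactly one stage.
4. **Cross-trait pleiotropy screen** (`pleiotropy_max_traits = 5`): drop
   variants genome-wide significant in five or more of the scan's other
   exposures. A variant driving many traits at once is a plausible
   pleiotropic hub. The screen is the identity when no other exposures are
   supplied and can be disabled; we read the "five or more" rule as a
   cross-trait count because the alternative reading (a cap on instrument
   number) would contradict the many-instrument estimates the method is
   designed to produce.

Instrument strength is summarized by
$F = R^2(n-1-k)/\big((1-R^2)k\big)$, with $R^2$ the summed per-variant
variance explained: $2\,\mathrm{eaf}(1-\mathrm{eaf})\hat\gamma^2$ under a
standardized exposure when the allele frequency is known, else the
$z^2/(z^2+n-2)$ fallback. $F \le 20$ sets a `weak_flag` on the instrument
set; it never removes instruments, since weak-instrument exclusion is a
reporting convention, not part of the estimator.

## Harmonization

`harmonize_set()` aligns each instrument's outcome record to the
exposure's effect allele: identical allele pairs are kept; swapped labels
flip the sign of the outcome beta; pairs matching only after
complementing both outcome alleles are strand flips. Palindromic variants
(A/T, C/G) carry no strand information in their labels, so orientation is
inferred from allele frequency: both frequencies must fall outside
$0.5 \pm 0.08$ (the `palindrome_eaf_window`), same-side frequencies mean
same orientation, opposite sides mean an effective allele swap. Ambiguous
palindromes, frequency-free palindromes, indels and incompatible pairs
are dropped with explicit reasons; `palindromes = "drop"` switches to the
stricter always-drop policy. Every instrument is conserved: it is either
kept with an action or dropped with a reason, and the audit can be
exported as a TSV.

## The synthetic-data generator

`simulate_study()` generates paired exposure/outcome summary statistics
directly at the summary level rather than via individual-level genotypes:
for each variant the observed beta is drawn as
$\mathrm{Normal}(\text{truth}, se^2)$ with
$se = 1/\sqrt{2\,n\,\mathrm{maf}(1-\mathrm{maf})}$, the standard error of
a per-allele effect on a standardized trait. This is sufficient for
two-sample MR — the estimators see only summary statistics — and orders of
magnitude faster than genotype simulation. Binary traits are approximated
on the log-odds scale with the same normal machinery.

Truth is built per locus: the index variant's exposure effect is
$\gamma \sim \mathrm{Normal}(0, \texttt{gamma\_sd}^2)$ (with probability
`prop_causal_snps`, else 0); the other variants in the locus tag it with
exchangeable correlation `ld_rho`, so their marginal effects are
$\rho\gamma$ — the same $\rho$ feeds the per-locus LD matrices, which
keeps the clumping tests analytically transparent (an AR(1) profile would
be more realistic but harder to reason about). The true outcome effect is
$\Gamma_j = \beta\,\gamma_j + \alpha_j$, with direct effects
$\alpha_j \sim \mathrm{Normal}(0, \texttt{pleiotropy\_sd}^2)$ for a
`pleiotropy_prop` fraction of variants. Variant allele pairs are drawn
from the non-palindromic pairs only, so harmonization of unscrambled
simulated data is unambiguous; palindrome handling is exercised by
scrambling orientations explicitly. Generation is a pure function of the
configuration: one substream per locus, derived deterministically from
the seed, makes locus $l$ reproducible regardless of `n_loci`.

The defaults are the reference design used by all calibration checks: 50
single-variant loci, exposure and outcome GWAS of $n = 100{,}000$ each,
causal effect 0.2, `gamma_sd = 0.05`, minor-allele frequencies uniform on
(0.1, 0.5), no pleiotropy. With these values roughly 30 of 50 variants
reach genome-wide significance, and median instrument F is in the
hundreds, so the design probes the estimator under strong instruments —
the regime the delta-method weights assume.

What the generator does **not** emulate: realistic human LD maps,
case-control ascertainment, sample overlap between the two GWAS,
population stratification, or winner's-curse-free replication betas.
Passing calibration here shows the estimator and pipeline are correct
under the stated generative model, not that real-data results are
unbiased under violations of it.

## Calibration experiments and their design

`scripts/acceptance.R` (and the corresponding tests) re-runs three
Monte-Carlo experiments on the reference design: parameter recovery
(mean IVW estimate over 200 replicates within 0.02 of the true 0.2),
95% CI coverage (within 93–97% over 500 replicates), and null
calibration (3–7% of replicates with $p < 0.05$ at a true effect of
zero, over 500 replicates). Replicate counts are chosen so Monte-Carlo
error is comfortably inside those bands while the whole suite runs in
about a minute.

These experiments apply significance selection, harmonization and IVW —
but deliberately *not* the outcome-association exclusion screen.
Conditioning instrument selection on the outcome's own p-values removes
instruments preferentially when the causal effect is large, biasing the
estimate toward the null; a calibration of the estimator must not bake
that selection effect in. The screen remains part of `run_scan()`, where
it serves its intended purpose of guarding against instruments with
direct outcome associations in real scans.

## Numerical and degenerate-input choices

- Zero p-values on file are clamped to the smallest positive double and
  noted, rather than rejected — printed tables often truncate.
- Duplicate variant rows keep the lowest p-value.
- A zero exposure beta makes the Wald ratio undefined and is an error;
  in practice selection at $5 \times 10^{-8}$ makes it unreachable.
- `summary_dataset` round-trips exactly through its TSV writer (17
  significant digits), so file-based and in-memory pipelines agree
  bit-for-bit.
- Scans degrade gracefully: a pair with no surviving instruments yields a
  `no_instruments` row, an unreadable dataset fails only its own pairs,
  and only a fully failed scan is an error.
- Multiple testing across a scan defaults to nominal $p < 0.05$;
  Benjamini–Hochberg q-values are available but off by default, and the
  `qvalue` column is labelled explicitly.

## Known limitations

Sensitivity estimators (MR-Egger, weighted median/mode, leave-one-out,
Steiger filtering) are out of scope by design, as are proxy-SNP lookup
for instruments missing in the outcome, LD computation from reference
genotypes, genome-build liftover, and remote retrieval of GWAS summary
data. The pipeline evaluates the causal effect as a single log-linear
parameter; it cannot distinguish direct from mediated effects.
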