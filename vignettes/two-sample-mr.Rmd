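---
title: "Two-sample MR with a small instrument set: model, calibration, and verification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-sample MR with a small instrument set}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ivwmr)
```

## The model

Mendelian randomization treats genetic variants as instrumental variables
for a biomarker: because alleles are randomized at conception, a variant
that changes the biomarker but has no other path to the outcome yields an
estimate of the biomarker's causal effect that is immune to classical
confounding and reverse causation. In the two-sample setting the
variant–exposure effects $\hat\beta_{Xj}$ and variant–outcome effects
$\hat\beta_{Yj}$ come from non-overlapping studies, and each instrument
gives a Wald ratio $\hat\theta_j = \hat\beta_{Yj}/\hat\beta_{Xj}$, pooled
by inverse-variance-weighted fixed effects. Three assumptions carry the
interpretation: relevance (strong variant–exposure association), no
variant–confounder association, and no pleiotropy (no variant–outcome path
bypassing the exposure). The package's `instruments` functions quantify the
first (F-statistics, variance explained) and screen the second
(Bonferroni-corrected confounder associations, pairwise LD); the third is
addressed by design (sensitivity subsets), not by statistics.

The packaged analysis asks whether genetically lowered 25-hydroxyvitamin D
(25OHD, natural-log scale) affects asthma, childhood asthma, atopic
dermatitis or total serum IgE. Its four instruments sit in the core genes
of vitamin D physiology — cutaneous synthesis (*DHCR7*), hepatic
25-hydroxylation (*CYP2R1*), transport (*GC*) and catabolism (*CYP24A1*) —
which is itself an argument against pleiotropy.

```{r}
tabs <- vitd_study_tables()
fit <- mr_ivw(tabs$exposure, tabs$asthma)
fit
```

## Parameters that matter

* **`sigma` (default 0.47)** — the SD of natural-log 25OHD, used to
  re-express the pooled per-unit estimate per one SD *decrease* of
  exposure. This scalar is not published anywhere in the source tables; it
  was calibrated once so that the pooled asthma odds ratio reproduces the
  published 1.03, and the same value then reproduces the other seven
  published cells that are robust to input rounding. It is recorded in
  every provenance output and is the one constant a user porting this
  analysis to another exposure must replace.
* **`wald_method` (default `"first_order"`)** — the first-order delta SE
  ignores uncertainty in $\hat\beta_{Xj}$, standard when the exposure GWAS
  is well powered; `"second_order"` propagates it. The exposure SEs shipped
  with the package are themselves back-derived from the published
  F-statistics ($se = |\beta|/\sqrt F$), because the source cohort printed
  F but not SE; they only matter under the second-order option.
* **`subset`** — named sensitivity subsets (`exclude_DHCR7` for ancestry
  association, `exclude_CYP2R1`/`exclude_CYP2R1_CYP24A1` for suspected
  pleiotropy via eosinophil and immunopeptide pathways, and the
  `synthesis_only`/`metabolism_only` pathway split).
* **Bonferroni boundary** — the confounder screen declares significance at
  $p \le 0.05/m$ inclusively: a p-value exactly at the threshold counts as
  significant.
* **Power** — `mr_power()` uses the non-centrality $n R^2 b^2$ with $b$ the
  effect per SD of exposure. A `case_control_scaled` variant multiplying by
  $K(1-K)$ is provided because binary-outcome power tools differ in this
  factor and the convention behind the published power statements could not
  be uniquely reconstructed; the plain variant is the default and
  reproduces the published anchors (power 0.83 for the IgE design against
  the stated 86%; minimal detectable asthma OR 1.13 against the stated
  1.12). The instrument-set $R^2$ defaults to 0.0036, the sum of the
  published per-variant variance-explained values.

## Numerical choices

Confidence bounds use the full-precision normal quantile (1.959964…), not
1.96. Odds ratios are converted to log-odds on input and all pooling is
additive; machine outputs are never rounded (rounding to two decimals
happens only in printed reports). The I² confidence interval uses the
Q-profile method — the generalized Q statistic profiled over the
between-instrument variance against $\chi^2_{k-1}$ quantiles, mapped to the
I² scale through the typical within-instrument variance — chosen because it
is well defined at the very small $k$ this package targets; `Q = 0` yields
`I² = 0` with a `[0, upper]` interval rather than `NaN`. The logistic
intercept in the simulator is solved by bisection to $10^{-8}$ on the
cohort-averaged event probability. Harmonization resolves strand flips via
allele complements but refuses palindromic variants whose allele
frequencies both lie in (0.42, 0.58); the packaged tables are stored in one
consistent, non-palindromic orientation (the source prints only the effect
allele, so the other allele is a documented assumption), which means
harmonization is exercised but never sign-flips the shipped data.

Reconstruction from a printed table has a known limit: the inputs are
rounded to two decimals, and I² is violently sensitive to that rounding at
$k = 4$. The published per-outcome I² values (0–15%) are **not**
recoverable from the printed inputs (the asthma cell reconstructs to ≈19%);
the pooled estimates, by contrast, move by well under 0.02. Tests therefore
pin the estimates and assert I² only through its defining formula.

## What the simulator emulates

`simulate_cohort()` generates the assumed causal diagram: independent
biallelic genotypes (Binomial(2, eaf); independence is justified by the
instruments' pairwise $r^2 \le 0.01$), a standard-normal latent confounder
acting on exposure (γ) and outcome (δ), exposure = genetic score + γC +
N(0, 0.47²), and a logistic or Gaussian outcome driven by the standardized
exposure (θ per SD), the confounder, and optional direct variant effects
(pleiotropy π). Defaults are the published study conditions: the four
allele frequencies (0.62, 0.27, 0.30, 0.19), per-allele effects (−0.052,
−0.056, −0.047, −0.027 log-units), residual SD 0.47, and a 17% binary
prevalence (the asthma case fraction). `summarize_gwas()` then emulates the
two-sample design by computing per-variant regressions in disjoint halves.

It does not emulate: linkage disequilibrium, ancestry structure, canalizing
developmental compensation, measurement error in the exposure assay, or
heterogeneous phenotype definitions across consortia. Passing tests
therefore show that the estimator chain is correct under its own
assumptions — unbiasedness for θ, nominal size and coverage, bias of the
naive observational contrast under confounding, correction by
leave-one-out under single-variant pleiotropy — not that those assumptions
hold in any particular application.

## Verification experiment sizes

The test suite fixes its seeds and uses: 2,000 replicates at n = 20,000 for
type-I error and coverage of the null model (the logistic-outcome arm of
the estimator is slightly conservative in finite samples — the identical
pipeline with a Gaussian outcome is exactly calibrated — so this check
sits near the lower edge of its tolerance band and is sensitive to the
Monte Carlo draw); 200 replicates at n = 100,000
per θ ∈ {0.1, 0.2, 0.3} for recovery; and 6,000 replicates at n = 6,000 per
grid point for the power cross-check. The power comparison runs in a
strong-instrument regime (per-allele effects scaled ×3, instrument
F ≫ 10): with weak instruments the cohort-level Monte Carlo power falls
measurably below the analytic formula, a real regression-dilution effect
of estimating $\hat\beta_{Xj}$ with noise that the formula — like standard
MR power calculators — assumes away. That gap is a property of the
formula's assumptions, not an implementation defect, and is why the
cross-check is performed where the assumptions hold.

## Known limitations

Fixed-effects IVW only: no random-effects pooling, MR-Egger, weighted
median or modal estimators, so directional pleiotropy is handled solely by
subset exclusion. LD r² values are user-supplied, not computed from
genotypes. A null MR result bounds the effect of lifelong *total* 25OHD
differences; it says nothing about the active metabolite
1,25-dihydroxyvitamin D, about cell-level vitamin D action, or about
populations beyond the one the summary statistics describe.
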