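---
title: "Weighted regression for MethyLight PMR data: model, weights, and simulation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weighted regression for MethyLight PMR data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pmrwls)
```

## The measurement problem

MethyLight quantifies locus-specific DNA methylation as the percent of
methylated reference (PMR): the methylated-allele fraction of a tumour
aliquot divided by that of a fully methylated (M.SssI-treated) reference and
multiplied by 100,

$$\mathrm{PMR} = 100 \cdot \frac{B/G}{B^r/G^r},$$

where $B$ and $B^r$ count methylated target alleles and $G$, $G^r$ count DNA
fragments in the tumour and reference reactions.  Archival specimens supply
wildly different amounts of amplifiable DNA, and the PMR of a low-input
specimen is the ratio of two very small counts.  The result is
heteroscedasticity indexed by input DNA quantity: PMR values of 0 from
methylated tumours (false-negative detection) and values far above 100, both
produced purely by sampling.

`pmrwls` implements (i) a generative model of this measurement process,
(ii) empirical variance estimation as a function of a DNA-quantity
surrogate, (iii) inverse-variance weighted least squares (WLS) tests for
two-group differential methylation, and (iv) a replicate engine for power
and type-I-error studies.

## The sampling model

A specimen is characterised by $h$ haploid genome equivalents and a true
methylated proportion $p$.  Each genome contributes $f$ measurable fragments
($f = 10^4$ by default, the ALU-based scaling), so the aliquot holds
$G = \mathrm{round}(h f)$ fragments and the methylated-target count is

$$B \sim \mathrm{Binomial}(G,\; p/f).$$

The reference reaction contains 5,500 genome equivalents by default and is
fully converted, $B^r \sim \mathrm{Binomial}(G^r, 1/f)$ with
$G^r = \mathrm{round}(5500 f)$, drawn independently per specimen (one
reference aliquot per reaction).  Conversion efficiency below 1 models an
incompletely methylated reference; it multiplies PMR by the reciprocal of
the efficiency and is off by default.

Consequences the package tests for:

* **Unbiasedness.** $E[\mathrm{PMR}] = 100\,p$ at any $h$; low input adds
  variance, not bias.
* **Zero inflation.** $\Pr(\mathrm{PMR}=0) = (1-p/f)^{\mathrm{round}(hf)}$
  exactly.  The genome-level closed form $(1-p)^h$ is the conventional
  approximation; the two agree within 0.01 for $p \lesssim 0.05$ at any $h$,
  but the gap grows with $p$ (at $p = 0.2$, $h = 10$ it is 0.028), so
  `prob_zero_detection()` exposes both (`method = "genome"` and
  `method = "fragment"`).
* **Variance structure.** $\mathrm{Var}(\mathrm{PMR} \mid p, h) \approx
  10^4 p / h$: decreasing in DNA quantity, increasing in the methylated
  proportion.

Numerical choices: $h$ is continuous (fractional genome equivalents are
physically meaningful for fragmented DNA) and the fragment count is rounded,
$G = \mathrm{round}(hf)$, introducing error below $10^{-4}$ genomes.  An
aliquot that rounds to zero fragments reads PMR 0 in the simulator, while
`compute_pmr()` treats $G = 0$ as an error for user-supplied counts.  A
reference draw of $B^r = 0$ (probability $\approx e^{-5500}$ at defaults)
would leave the ratio undefined and is redrawn a bounded number of times.

## Population scenarios

Two-group studies draw each tumour's true proportion from a group-level
distribution: with probability $\pi$ the tumour is methylation-positive and
$p \sim \mathrm{Beta}$ parameterised by mean and variance
(`beta_from_moments()`, e.g. mean 0.2 and variance 0.01 give Beta(3, 12));
otherwise $p = 0$.  The built-in registry (`scenario_registry()`) holds nine
alternatives — mean pairs 0.20/0.27 and 0.40/0.47 (difference 0.07) crossed
with variance patterns 0.01/0.01, 0.04/0.04 and 0.01/0.04, plus
Bernoulli-Beta mixtures with $\pi$ = 0.5 vs 0.7 (overall-mean difference
0.13) — and six nulls: the four pure Betas crossing means {0.2, 0.4} with
variances {0.01, 0.04}, and two mixtures at $\pi = 0.67$.  These are the
study conditions under which all shipped power and error rates are computed.
The mixture positivity is taken as 0.67 exactly as stated, not 2/3.

DNA quantities follow $\log_{10} Q = 2.74 - L$ with
$\ln L \sim N(0, 0.75^2)$: $Q$ is capped at $10^{2.74} \approx 550$
genomes, 23.0% of specimens carry fewer than 10 genomes and 9.0% fewer than
one (`quantity_cdf()` gives the analytic CDF).  The same draw serves as the
analysis surrogate, so simulation-mode thresholds cut on true genome counts;
with real data the surrogate is a measured quantity such as an ALU C(t)
value, whose orientation (more cycles = less DNA) must be declared.

Because the text this model is drawn from reuses one symbol for two
quantities, the package names the lognormal deviate $L$ and the genome count
$Q$ (= $h$) explicitly.  Group sizes are fixed by count (first $n_1$
tumours are group 1) so every replicate has exact group sizes; unequal
designs split 200 tumours as 67/133 (nearest integer for the smaller
group).

## Empirical weights

Both weighting schemes estimate $\mathrm{Var}(\mathrm{PMR})$ as a function
of the surrogate, pooling the two comparison groups — the premise is that
measurement noise depends on DNA quantity only, not on the grouping
variable.  Observations are ranked by increasing effective DNA quantity
(orientation-corrected, stable ties by input order).

* **Quantile bins** (`quantile_variances()`, WLS-Q): $k$ contiguous,
  nearly equal bins (default $k = 5$; 40 observations per quintile at
  $n = 200$); each observation receives its bin's sample variance
  ($n-1$ denominator).  Remainders are distributed one per bin from the
  lowest-quantity bin upward.
* **Sliding windows** (`window_variances()`, WLS-W): a centred window of
  $w$ ranked observations (default 41: the observation plus the 20 ranked
  just above and the 20 just below).  The 20 lowest-ranked observations
  share the variance of the bottom-most 41, symmetrically at the top.
  Window sizes must be odd so windows can be centred; "window of 40" in
  common usage maps to $w = 41$.

Weights are reciprocal variances, with variances floored at
$\max(\varepsilon, 10^{-8} \times \text{largest estimate})$ so that an
all-identical bin (for example all-zero PMRs at very low input) cannot
produce infinite leverage; a fully degenerate dataset collapses to equal
weights, i.e. ordinary least squares.  The threshold filter
(`threshold_weights()`) is the same idea with weights 0/1 at a minimum DNA
quantity, and `uniform_weights()` recovers OLS.

## Tests and their calibration

`fit_group_comparison()` regresses the outcome (PMR or $\ln(\mathrm{PMR}+1)$)
on a binary group indicator by weighted least squares, treating the
empirical weights as known — their estimation uncertainty is deliberately
ignored, which is the conventional practice this method family assumes.
With one binary predictor the fit has a closed form (difference in weighted
group means; weighted residual variance on $n_\mathrm{eff}-2$ degrees of
freedom, $n_\mathrm{eff}$ the positively weighted count), which the test
suite pins to `lm(..., weights = )` and to the pooled two-sample t-test at
$10^{-10}$ tolerance.  P-values are two-sided; OLS uses classical
homoscedastic standard errors.  When a method analyses the log scale, its
weights are estimated from the log-scale outcome.

Design notes on calibration, measured at the shipped study conditions
(10,000 null replicates, $n = 200$):

* the log, threshold and WLS tests hold the 5% level within Monte-Carlo
  error on all six null scenarios;
* OLS on raw PMR runs *conservative* (observed rates 0.040-0.045 on five of
  six nulls).  This is structural: under the lognormal quantity model
  $E[1/h]$ diverges, so rare low-input specimens produce enormous PMR
  outliers that inflate the sample variance more than the mean difference,
  deflating the t statistic.  It is one more reason not to analyse raw PMR
  unweighted;
* small windows at small samples did not inflate the type-I error in this
  implementation (FPR 0.049 at $n=100$, $w=21$, 4,000 replicates) — the
  variance floor and self-inclusive windows appear to protect against the
  inflation sometimes reported for window sizes near 20.
  `window_size_sensitivity()` lets users probe their own configuration.

## The replicate engine and reproducibility

`run_study()` simulates `replicates` datasets under a scenario and records
each method's rejection at level $\alpha$; `power_table()` / `fpr_table()`
assemble scenario-by-method grids.  One master seed generates a vector of
per-replicate seeds up front, so results are reproducible, independent of
execution order, and every source of randomness flows through the
configured seed (the command-line interface exposes it as `--seed`).
Replicates where a method fails (for example a threshold emptying one
group under a low-positivity mixture) are excluded from that method's
denominator and counted, with a warning above 1%.

Shipped problem sizes were chosen to keep a full run on one core
comfortable: 1,000 replicates for power (Monte-Carlo SE about 1.5 points),
10,000 for null rates (SE about 0.2 points), and the packaged checks use
1,000-replicate versions of both.  At these conditions the qualitative
results are stable across seeds: both WLS tests beat raw-PMR OLS in every
alternative scenario; WLS-Q and WLS-W agree within Monte-Carlo error;
threshold filtering is intermediate; and for zero-mode, right-skewed
populations the most powerful variant is WLS on $\ln(\mathrm{PMR}+1)$.

## What the generator does and does not emulate

The simulator reproduces the sampling chain from genome equivalents to
fragment counts to the PMR ratio, with population-level variation in the
methylated proportion and a realistic archival-DNA quantity distribution.
It does not model tumour/normal cell mixture, PCR amplification-efficiency
kinetics, C(t) measurement chemistry, surrogate measurement error, or
centre-stratified quantity distributions in multi-centre studies.  Passing
tests therefore demonstrate correctness of the measurement-error model and
the weighting machinery under these idealised conditions — not that any
particular real cohort's error structure is fully captured.  In particular,
absolute power levels depend strongly on the low-input tail of the quantity
distribution and on any additional assay noise, which real studies will
have and the idealised chain does not; relative method orderings are the
robust output.

## Known limitations

* Weights are treated as known; no correction is made for their estimation
  uncertainty (small windows at small $n$ make variances noisy — hence the
  41-observation default).
* Only two-group comparisons with a single binary predictor are supported;
  covariate adjustment and two-degree-of-freedom mixture tests are out of
  scope.
* Dichotomised methylated/unmethylated analyses are not offered: under
  low-input false negatives the positivity fraction is biased and a
  principled weighting for that case is an open problem.
* The quantile split uses contiguous ranked blocks, so heavy surrogate ties
  spanning a bin boundary resolve by stable input order.
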