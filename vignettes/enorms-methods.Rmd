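---
title: "The e-norms method: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The e-norms method: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(enorms)
```

## The problem and the model

Reference intervals are traditionally estimated from screened healthy
cohorts. Indirect methods instead start from a routinely collected, *mixed*
dataset in which an unknown fraction of subjects carries pathology. The
e-norms (extrapolated norms) method rests on a single empirical regularity:
values from healthy subjects occupy a narrow min-to-max band, while
pathological values spread over a much wider one. On the sorted-value versus
rank curve this shows up as geometry — a flat central **plateau** of small
first-order differences flanked by steep tails — and the plateau values are
taken as the healthy subset.

Formally, write the order statistics $x_{(1)} \le \dots \le x_{(n)}$ and
differences $d_i = x_{(i+1)} - x_{(i)}$. Where the local density of the data
is $f$, consecutive order statistics are spaced roughly $1/(n f)$ apart, so
small differences mark high-density regions. The implicit model is a
contaminated mixture: a dominant, relatively tight "healthy" component plus
a wider pathological component whose density is everywhere much lower than
the healthy peak. The method assumes (i) the healthy component is unimodal,
(ii) pathology inflates spread enough to thin the tails visibly, and
(iii) the healthy component contributes the single densest region of the
data. When pathology is frequent *and* sits close to the healthy mode, the
two components can merge into one dense region and the plateau then covers
both — see *Limitations*.

## Automatic plateau detection

The original procedure identifies the inflection points A and B by eye.
`detect_plateau()` operationalizes that judgement with three parameters
(`plateau_params()`):

* **`window` = 9** (rank units, odd). Differences are smoothed with a
  centered moving median, edge-truncated. A median — not a mean — because a
  single large gap inside an otherwise dense region (one outlying duplicate
  deleted, one transcription glitch) would drag a mean upward and split the
  plateau; a moving median absorbs isolated spikes up to
  `(window - 1) / 2` wide.
* **`k` = 6** (dimensionless). The plateau threshold is
  $\tau = k \cdot \mathrm{median}(d)$. A *relative* threshold makes the rule
  scale-equivariant: rescaling the data rescales $\tau$ identically, so the
  detected ranks are unchanged (this affine equivariance is tested). For a
  Gaussian sample the spacing at quantile $u$ is
  $\approx 1/(n f(F^{-1}(u)))$, and the median spacing corresponds to
  $|z| \approx 0.67$; requiring spacing $\le 6$ times the median then admits
  densities down to $e^{-z^2/2} \ge 0.80/6$ of the admitted median density,
  i.e. $|z| \lesssim 2.0$. The default therefore recovers approximately the
  central 95% (mean ± 2 SD) of a Gaussian sample, which is what the test
  suite asserts on N(20, 1.5) samples of 1,000 (recovered limits near 17 and
  23).
* **`min_run` = `max(10, ceiling(0.05 n))`** (points). A plateau shorter
  than this is rejected ("no plateau detected") rather than reported: a
  handful of near-equal values anywhere in the data should not masquerade as
  a healthy range.

The plateau is the **longest** contiguous run of smoothed differences at or
below $\tau$. A run over difference indices $i..j$ maps to value indices
$A = i$, $B = j + 1$, both inclusive — a difference sits *between* the two
values it separates, so both endpoints belong. Exactly one plateau is
returned; multi-modal decomposition is out of scope by design.

Numerical conventions and tie-breaks:

* Equal-length qualifying runs: the run with the smaller sum of member
  (smoothed) differences wins; if still tied, the leftmost. This makes the
  output deterministic.
* Zero differences (exact ties in the data) always pass the threshold, since
  $\tau \ge 0$. Heavily discretized data — e.g. BMI rounded to 0.1 — is
  therefore biased toward plateau membership. This is documented behaviour,
  not corrected, because any correction would need a model of the rounding.
* Sorting is stable (radix), so tied values keep their input order and
  permutation invariance holds exactly.
* Degenerate inputs: `n < 20` is a hard error for detection;
  `20 ≤ n < 100` proceeds with a warning that estimates are unstable.
  Constant series are a single all-zero-difference plateau.

## The normative range and its diagnostics

`normative_range()` reports plateau count, mean, sample SD (n − 1
denominator), and min/max. The **min–max of the plateau is the headline
healthy range**; mean ± 2 SD of the plateau is emitted as a secondary
summary (`lower_2sd`, `upper_2sd`). The min–max reading is the natural one
for a method whose premise is that the healthy band *is* a min-to-max span;
the two summaries coincide only for an exactly Gaussian plateau, and both
are reported so users can compare.

`distribution_diagnostics()` computes moment-based (population) skewness
$m_3/m_2^{3/2}$ and **excess** kurtosis $m_4/m_2^2 - 3$ (zero for a
Gaussian), the Kolmogorov–Smirnov $d$ against a Gaussian with the sample's
mean and SD, and a Lilliefors $p$ for that composite hypothesis. Because the
Gaussian parameters are estimated from the sample, the standard KS null is
wrong; rather than interpolate published Lilliefors tables, the $p$-value is
obtained by Monte-Carlo (default 10,000 replicates, default seed 20210222,
both recorded in the output, $p = (\#\{D^* \ge D\} + 1)/(B + 1)$).
Diagnostics are computed on the **plateau subset** by default — the derived
healthy values are the object of interest — with `diagnostics = "full"` for
the whole series and `"none"` to skip them. The `"none"` option exists
because the Monte-Carlo replicate loop dominates runtime in simulation
sweeps that only need plateau limits; the package's own property tests and
the stratified pipeline use it for exactly that reason.

## The cohort simulator

Real mixed clinical datasets are rarely deposited, so validation runs on
synthetic cohorts with the structure the method assumes.
`simulate_mixed_cohort()` draws each (sex × age-bin) stratum from a
two-component mixture: `round(n (1 − c))` healthy values from
$N(\mu_h, \sigma_h)$ and the remainder from
$N(\mu_h + s\,\sigma_h,\; g\,\sigma_h)$, with ages uniform integers within
the bin and one deterministic RNG substream per stratum. Defaults:
contamination $c = 0.57$ (mirroring a referral population in which 57% of
subjects carried the condition under investigation), shift $s = +4$ SD,
scale $g = 2$.

`default_bmi_spec()` fixes eight strata — two sexes × age bins 17–49,
50–69, 70–79, 80–98 — with per-stratum counts matching a large published
referral cohort (11,723 males, 22,661 females, 34,384 records), healthy SD
2.2 kg/m² and healthy means (M: 26.5, 27.5, 27.0, 25.5; F: 25.0, 26.0,
26.5, 24.5 kg/m²). No per-stratum healthy means are published for that
cohort, so these are free parameters chosen once to encode the reported
qualitative structure — men above women in every bin, a male peak at 50–69,
a female peak at 70–79, and a marked drop in the oldest bin — and the test
suite asserts only that qualitative pattern, never the cohort's exact
numeric ranges, which depend on undeposited clinical data.

What the generator does **not** emulate: within-bin age trends (ages are
uniform), measurement discretization and digit preference, non-Gaussian
healthy components, multiple pathologies with different shifts, and any
correlation between age and pathology prevalence. Passing tests on this
generator therefore show that the detector recovers a known healthy
component under idealized mixture contamination — not that any particular
real-world range is correct.

## Stratified comparisons

`run_stratified_enorms()` applies the pipeline per stratum (skipping, with
a reason, strata below the detection minimum) and compares male and female
plateau values within each age bin. Comparing strata of unequal size with a
*paired* t-test is procedurally ambiguous, so two modes are offered:
Welch's unequal-variance test on the plateau values directly (default;
well-defined on the actual data) and a paired mode that first reduces both
series to a common grid of `min(n_a, n_b)` quantiles — approximating a
matched comparison of distributional summaries. A paired comparison with
zero-variance differences is reported as degenerate (statistic 0 and
$p = 1$ when the mean difference is also zero, signed infinity and $p = 0$
otherwise) rather than erroring mid-pipeline.

Bin edges are inclusive on both sides; ages outside all bins are excluded
and counted (mirroring ingestion rules such as excluding subjects under
17). No multiple-testing correction is applied; raw $p$-values are
reported.

## Problem sizes and runtime choices

The test suite exercises the canonical 1,000-point Gaussian validation over
20 seeds, contamination robustness at n = 2,000 over 20 seeds, the full
34,384-record eight-stratum cohort over 20 seeds (with diagnostics
disabled), and brute-force oracle comparisons on series of 30–200 points.
These sizes keep the whole suite under a minute on a single CPU while
leaving the seed-averaged quantities stable to well within the asserted
tolerances. Monte-Carlo Lilliefors replicates are reduced (200–2,000) in
tests; the package default stays at 10,000.

## Known limitations

* **Component overlap.** With heavy contamination *and* a modest shift the
  mixture's density valley never drops below the threshold and the plateau
  merges both components: at contamination 0.4, shift +4 SD, scale ×2 the
  plateau mean overshoots the healthy mean by > 1 SD on average. Recovery
  within 0.5 healthy SD holds comfortably at contamination ≤ 0.3 with
  shift ≥ 4 SD, or ≤ 0.4 with shift ≥ 6 SD, which is what the property
  tests assert. Users with high expected pathology prevalence close to the
  healthy mode should treat the derived range with caution.
* **Discretization bias.** Rounded data inflates plateau membership (ties
  always qualify); the derived range can widen by up to the rounding grain.
* **One plateau only.** Genuinely multi-modal healthy populations (e.g.
  mixed ethnic groups with distinct healthy ranges) violate the single
  dense-region assumption and are not decomposed.
* **Selection effects.** The method characterizes the densest subpopulation
  of the *referral* cohort; survivor bias and referral bias (e.g. in the
  oldest age bins) propagate into the derived range and are not modelled.
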