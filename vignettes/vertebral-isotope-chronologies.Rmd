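---
title: "Vertebral isotope chronologies: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Vertebral isotope chronologies: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vertiso)
```

## The measurement and the data model

Shark vertebral centra accrete yearly growth bands that are metabolically
inert once deposited, so micro-drilling collagen band by band from the birth
ring outward yields a lifetime record of $\delta^{13}$C and $\delta^{15}$N.
`vertiso` represents such data as a *band table*: one row per band sample,
with the individual's metadata (sex, total length, age, maturity) repeated on
each row. Band index is 1-based (band 1 = the first annulus after the birth
ring); an optional band-0 row holds a birth-ring measurement. We equate band
index $i$ with the animal's age-$i$ year, which is the convention that lets
per-band samples be binned into age classes.

Delta values follow the standard definition
$\delta = (R_{sample}/R_{standard} - 1) \times 10^3$ with vPDB for carbon and
atmospheric N$_2$ for nitrogen; the reference ratios are arguments of
`delta_standard()`, defaulting to the conventional calibration constants
(0.0112372 and 0.0036765), since datasets usually arrive with deltas already
computed and the raw-ratio path is exercised only when `r13C12C`/`r15N14N`
columns are present.

Collagen quality control uses the mass C/N ratio: demineralization is deemed
effective at C/N $\le 3.5$, and the threshold is *inclusive* because that is
how the criterion is stated in the literature this package follows. Samples
without a C/N value cannot be judged and are rejected with reason
`"missing"` rather than silently kept.

The sampling plan operation (`band_sampling_plan()`) encodes the drilling
scheme "every annulus through the eighth, every second band after" — outer
bands are too narrow to drill individually. It is used by the synthetic
generator to lay out realistic chronologies; we deliberately do *not* use it
to impute the design of any real dataset, because actual drilling deviates
from the nominal plan (unreadable or edge-damaged bands), and applying the
nominal plan to a specimen table will generally over-count sections.

## The scaled trophic-position model

Additive trophic-position models assume a constant diet–tissue
$\delta^{15}$N discrimination. Experimental feeding data instead show
discrimination *narrowing* as prey $\delta^{15}$N rises, which motivates the
scaled model used here:

$$TP = \frac{\log_{10}(\delta^{15}N_{lim} - \delta^{15}N_{base}) -
\log_{10}(\delta^{15}N_{lim} - \delta^{15}N_{TP})}{k} + TP_{base}$$

Defaults (`tp_params()`): a tropical-Pacific zooplankton baseline
$\delta^{15}N_{base} = 5.3$‰ at $TP_{base} = 2$, saturating value
$\delta^{15}N_{lim} = 21.93$‰ and rate $k = 0.14$ from a meta-analysis of
controlled feeding studies. Two numerical points deserve emphasis:

* **The logarithm is base 10.** The source formula writes "log" without a
  base. Base 10 reproduces the published worked values at one-decimal
  precision — $TP(12.3) = 3.69 \to 3.7$, $TP(8.9) = 2.76 \to 2.8$,
  $TP(14.8) = 4.63 \to 4.6$, $TP(14.2) = 4.38 \to 4.4$ — while a natural log
  would give $TP(12.3) = 5.7$. The test suite pins this down.
* **Group TP statistics are means of per-sample TPs**, not the TP of the
  mean $\delta^{15}$N. The map is convex, so the two differ (e.g.
  $TP(11.5) = 3.45$ but the mean of per-sample TPs for the same group is
  higher); the per-sample convention is what grouped summary tables report.
  A corollary of strict monotonicity is that a group's min/max TP equals
  the TP of its min/max $\delta^{15}$N.

The model's domain ends at the saturating value:
$\delta^{15}N \ge \delta^{15}N_{lim}$ is a domain error, not an `NaN`.
`d15n_for_tp()` provides the exact inverse; round-tripping through it is a
tested invariant (tolerance $10^{-9}$).

## Enrichment chronologies

The birth-band-relative enrichment of element $Y$ at band $n$ is

$$\mathrm{Enrichment}_Y(n) = \frac{\delta_n - \delta_{birth}}{\delta_n}$$

implemented exactly as printed, with no absolute values and no reordering.
For carbon this has a counter-intuitive consequence the user should know:
with negative $\delta^{13}$C values, a rise *toward zero* (less negative,
i.e. $^{13}$C enrichment in the usual sense) yields a *negative* value of
this statistic, because the denominator is negative. Whether the original
formulation intended magnitudes is not decidable from the source text, so we
keep the printed form and surface the sign behaviour in documentation and
tests rather than silently "fixing" it. The reference band is band 0 when a
birth-ring row exists, otherwise the first sampled band; its enrichment is
exactly 0, and the series is invariant to re-labelling band indices.
Cohort-level chronologies (`cohort_enrichment()`) align individuals by band
and report mean ± SE across the individuals possessing that band.

## Bayesian isotopic niche

A group's isotopic niche is modelled as a bivariate normal on
($\delta^{13}$C, $\delta^{15}$N). Its *standard ellipse area*
$SEA = \pi\sqrt{\det S}$ (unbiased sample covariance $S$) measures niche
width; $SEAc = SEA\,(n-1)/(n-2)$ corrects small-sample bias. The Bayesian
version (`fit_niche()`) samples the conjugate posterior under the
noninformative (Jeffreys-style) prior:

$$\Sigma \sim \mathrm{IW}(n - 1,\; (n-1)S), \qquad
\mu \mid \Sigma \sim N(\bar{x},\, \Sigma/n)$$

each draw contributing $SEA_B = \pi\sqrt{\det\Sigma}$. We chose the
noninformative conjugate prior over a vague inverse-Wishart with a small
fixed scale because it is analytically transparent (the posterior is exact,
no MCMC) and its frequentist calibration is testable: the suite verifies
that the central 95% interval of $SEA_B$ covers the true
$\pi\sqrt{\det\Sigma}$ in at least 90% of 100 replicates at $n = 50$, and
that the posterior median lands within 5% of truth at $n = 2000$. The
point summary of $SEA_B$ is the posterior **median** — the mode is
binning-dependent and the mean is skew-inflated for small $n$.

The $p$-probability *niche region* of a fitted group is the ellipse
$\{z : (z-\mu)^\top\Sigma^{-1}(z-\mu) \le \chi^2_2(p)\}$ with area
$\chi^2_2(p)\,\pi\sqrt{\det\Sigma}$; $p = 0.95$ throughout by default.

Overlap is reported **both ways**, because the two published overlap columns
this mirrors are not formally defined in their source:

1. *Directional posterior probability* (the probabilistic-niche-region
   semantics): for each of 1000 paired posterior draws, the Monte-Carlo
   probability that a point from group A's normal falls in group B's 95%
   region, and symmetrically. Self-overlap of any group at level $p$ equals
   $p$ within Monte-Carlo error — a tested calibration property.
2. *Geometric intersection* of the two point-estimate 95% ellipses, in ‰²
   and as a percentage of each group's ellipse area. The intersection area
   is estimated by uniform sampling inside the smaller ellipse (whose area
   is known in closed form), which gives an unbiased estimate with a
   binomial standard error and is exact in the containment and disjoint
   limits.

Groups with $n < 3$ have no defined covariance and are skipped from niche
tables with a warning.

## The comparison battery

All group comparisons pass through a normality gate: Shapiro–Wilk within
every group at $\alpha = 0.05$; the parametric branch (one-way ANOVA with
Tukey HSD; paired $t$) runs only if *every* group passes, otherwise the
non-parametric branch (two-sample Kolmogorov–Smirnov for two groups,
Kruskal–Wallis with Dunn's post-hoc for more; Wilcoxon signed-rank for
paired designs). Kruskal–Wallis precedes Dunn's test because Dunn's mean-rank
statistics presuppose the shared ranking of the omnibus; p-values are
Bonferroni-adjusted by default (both choices configurable). Dunn's test is
implemented in-package (rank z statistics with the standard tie correction)
and validated against hand-enumerable rank configurations. Paired sex
comparisons "at each growth stage" pair male and female per-age-class means
ordered by age class — the only pairing consistent with eight classes per
sex. All tests are two-sided; every report carries a `decision_path` string
recording which branch fired, so the gate's routing is auditable. A response
with zero variance short-circuits to the degenerate no-difference result
(slope 0 / statistic 0, $p = 1$) instead of erroring inside base tests.

## What the synthetic generator emulates — and what it does not

`simulate_chronologies()` reproduces the statistical structure the pipeline
assumes, with defaults set once to the study conditions this package is
built around: 25 individuals (14 male, 11 female), ages uniform on 4–16
(or an explicit age/sex list for parity with a real specimen table), bands
from the nominal sampling plan, and per band
$$\delta(b) = \text{trend}(b) + \text{sex offset} + \text{individual
effect} + \text{maternal term}(b) + \text{noise}.$$
The $\delta^{13}$C trend rises 0.15‰/yr from −15.0‰; $\delta^{15}$N is flat
at 12.0‰; males sit +0.4‰ / +0.8‰ above females; individual random
intercepts have SD 0.5‰; analytical noise is 0.13‰ / 0.06‰; C/N is drawn in
(2.7, 3.5) with 5% of samples failing the 3.5 cutoff. The maternal isotopic
signature is modelled as an additive offset at band 1 decaying linearly to
zero by band 5 — the source material only asserts erasure "at 5–6 years",
so the linear form is a modelling choice; its magnitudes (−0.5‰
$\delta^{13}$C, +0.3‰ $\delta^{15}$N) were likewise fixed once to mimic
early-band $^{13}$C depletion.

Features of real vertebral data the generator does **not** emulate: within-
individual serial autocorrelation beyond the random intercept (bands are
conditionally independent), baseline isoscape drift (latitude/upwelling
effects), age-reading error, missing or unreadable bands, and
maturity-linked diet shifts. Passing tests therefore demonstrate that the
*estimators* recover known structure under the assumed model — not that the
model captures every feature of field data.

Parameter-recovery tests disable the maternal term when recovering the
configured $\delta^{13}$C slope, because the decaying maternal offset is a
deliberate confounder of the early-band trend; the sex offsets are recovered
under the full default structure (the maternal term is common to both sexes
and cancels in the contrast), with a 0.15‰ tolerance ≈ 2 design-based SEs of
a between-individual contrast at 100 + 100 individuals with 0.5‰ individual
SD. Note that sample-level SEs in grouped summary tables understate the
sampling variability of such contrasts, because samples are clustered within
individuals — which is why the recovery tolerance is design-based rather
than taken from the table.

## Problem sizes and numerical settings

Defaults: 10000 posterior draws per niche fit; 1000 paired draws × 10000
Monte-Carlo points per overlap direction; intersection areas from 10^5
uniform points. The test suite scales these down (hundreds to a few
thousand draws; calibration over 100 replicates of $n = 50$; consistency at
$n = 2000$) — sizes chosen so the whole suite runs in well under a minute
while leaving Monte-Carlo error far below the tested tolerances. All
stochastic operations take explicit seeds and restore the caller's RNG
state, so pipelines are reproducible end to end; `run_full_pipeline()`
writes every output with an MD5 checksum into a JSON run report, and
identical seed + config give an identical bundle.

## Known limitations

* The enrichment statistic's sign behaviour for negative deltas (above) is
  faithful to its printed definition but awkward to interpret for carbon.
* Singleton groups report SE 0 by convention (with a warning) so summary
  tables stay total; treat those SEs as "not estimable", not as precision.
* The niche model is bivariate normal; strongly skewed or multimodal
  isotope clouds will be summarized poorly by any ellipse-based metric.
* Trophic-position estimates inherit the calibration constants; they are
  relative to the chosen baseline, not absolute diet reconstructions.
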