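# vertiso

Retrospective stable-isotope analysis of vertebral growth bands.

Shark vertebral centra lay down yearly growth bands that stay metabolically
inert after deposition, so micro-drilling collagen band by band — from the
birth ring out to the edge — recovers a lifetime δ¹³C/δ¹⁵N chronology from a
single animal. Ecologists use such chronologies to ask how diet, trophic
position and habitat use change through ontogeny and differ between the
sexes of large pelagic predators. `vertiso` is an R package for that
workflow: it takes per-band isotope tables and produces quality-controlled,
age-binned chronologies and the standard downstream analyses.

## What it computes

* **δ notation and QC** — δ = (R_sample/R_standard − 1)×10³ from raw
  ¹³C/¹²C and ¹⁵N/¹⁴N ratios (vPDB / AIR standards), and the collagen
  demineralization filter C/N ≤ 3.5 (inclusive).
* **Chronology structure** — the band sampling plan (every annulus through
  the 8th, every second after), age classes (yearly classes 1–7, then
  "adult"), and grouped mean ± SE / range summary tables by sex × age class.
* **Scaled trophic position** — the saturating δ¹⁵N model
  TP = [log₁₀(δ¹⁵N_lim − δ¹⁵N_base) − log₁₀(δ¹⁵N_lim − δ¹⁵N)] / k + TP_base,
  default calibration δ¹⁵N_base = 5.3‰ (TP 2 zooplankton baseline),
  δ¹⁵N_lim = 21.93‰, k = 0.14. Group TP statistics are means of per-sample
  TPs.
* **Enrichment chronologies** — birth-band-relative series
  (δ_n − δ_birth)/δ_n per individual and aligned cohort mean ± SE by band.
* **Bayesian isotopic niche** — standard ellipse areas (SEA, SEAc) and the
  posterior SEA_B under the conjugate noninformative prior
  (Σ ~ IW(n−1, (n−1)S); μ|Σ ~ N(x̄, Σ/n)); 95% probabilistic niche regions;
  directional niche overlap from paired posterior draws; and geometric
  ellipse-intersection areas with Monte-Carlo SEs.
* **Comparison battery** — Shapiro–Wilk-gated ANOVA/Tukey vs
  KS/Kruskal–Wallis/Dunn, paired t vs Wilcoxon, and isotope-vs-age OLS
  regressions, each report carrying its decision path.
* **Synthetic chronologies** — a seeded generator emulating the sampling
  design (trends, sex offsets, individual effects, maternal signature,
  analytical noise, C/N failures) so every stage is testable without field
  data.

## Worked example

```r
library(vertiso)

x  <- simulate_chronologies(synthetic_config(seed = 7))   # 25 sharks
qc <- cn_qc_filter(x)          # C/N <= 3.5; 5 of 212 samples rejected

round(trophic_position(c(12.3, 8.9)), 2)
#> [1] 3.69 2.76

gs <- group_summary(qc$retained)
gs[gs$age_class == "overall",
   c("sex", "n", "mean_d13C", "mean_d15N", "mean_TP", "se_TP")]
#>         sex   n mean_d13C mean_d15N mean_TP  se_TP
#> 25     male 115     -14.0      12.9    3.89 0.0138
#> 26   female  92     -14.4      12.2    3.68 0.0166
#> 27 combined 207     -14.2      12.6    3.80 0.0130

m  <- qc$retained[qc$retained$sex == "male", ]
f  <- qc$retained[qc$retained$sex == "female", ]
fm <- fit_niche(m$d13C, m$d15N, seed = 1, group_label = "male")
ff <- fit_niche(f$d13C, f$d15N, seed = 2, group_label = "female")
fm
#> Bayesian bivariate-normal niche: male (n = 115, 10000 posterior draws)
#>   SEA (ML): 1.131   SEAc: 1.141   SEA_B median: 1.145

overlap_mc(fm, ff, seed = 3)
#> niche overlap at p = 0.95
#>   P(male in region of female) = 0.739 (MC SE 0.0021)
#>   P(female in region of male) = 0.685 (MC SE 0.0021)
#>   ellipse intersection 4.301 per-mil^2 (63.5% of male, 54.6% of female)
```

Reading the numbers: the two trophic positions are the model evaluated at a
male-mean-like δ¹⁵N (12.3‰ → TP ≈ 3.7) and at a low extreme (8.9‰ → TP ≈
2.8). The summary rows give per-sex sample counts and mean ± SE of each
isotope and of per-sample TP across the whole simulated chronology set. The
niche print shows the maximum-likelihood standard ellipse area, its
small-sample correction, and the Bayesian posterior median (all ‰²); the
overlap report gives, per direction, the posterior probability that one
sex's isotope values fall inside the other's 95% niche region, plus the
geometric intersection of the two 95% ellipses.

`run_full_pipeline(run_config(input, output_dir, seed = 1))` runs the whole
chain (validate → QC → TP/enrichment → summary tables → niche → tests) and
writes CSV tables, ellipse polylines and a JSON run report with per-file
checksums. `inst/scripts/vertiso.R` wraps the same functions as a small
command-line tool, and `inst/scripts/reproduce_tables.R` reproduces the
full summary/niche table workflow from any user-supplied band-table CSV
(for example, the archived field data of the study population, once mapped
to the documented columns).

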