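---
title: "Process-based limits and control charts for patient-specific QA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Process-based limits and control charts for patient-specific QA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psqa)
```

## The problem

Patient-specific QA (PSQA) verifies, before treatment, that an IMRT/VMAT
plan delivers the dose it promises. Each verification yields a gamma
passing rate per criterion (e.g. 3%/3 mm) and an absolute dose
difference. Judging these against a universal fixed threshold ignores
that every facility, machine and disease site is its own statistical
process; the process-based alternative derives thresholds from each
stratum's own history. `psqa` implements that derivation, the
control-charting that monitors the process over time, and the alerting
that reacts to it — over a flat, validated table of QA records.

## Model and assumptions

For a stratum with process mean $\bar{x}$, sample SD $\sigma$ (computed
with the $n-1$ denominator, the process-capability convention) and target
$T$:

$$\Delta_A = \beta\sqrt{\sigma^2 + (\bar{x}-T)^2}, \qquad
\mathrm{AL} = 100 - \Delta_A/2 .$$

$\Delta_A$ is the width between the upper and lower intervention
thresholds; the squared-offset term charges systematic deviation from the
target at the same rate as random spread. The assumptions are mild but
real: the stratum is homogeneous (one process, not a mixture), its
history is representative, and $n$ is large enough that $\bar{x}$ and
$\sigma$ are stable. Passing rates are treated **one-sided** — only low
values are actionable, so AL is a lower threshold — while dose
differences are two-sided about $T = 0$ with limits $\pm\Delta_A/2$.

The tolerance limit has no closed form in the source methodology as used
here; we define it from the individuals control chart of the
chronologically ordered series:

$$\mathrm{TL} = \overline{x} - 2.660\,\overline{mR}, \qquad
\overline{mR} = \frac{1}{n-1}\sum_{i=2}^{n}|x_i - x_{i-1}| .$$

This is the chart's lower control limit (2.660 = $3/d_2$ for moving
ranges of span 2) and matches the TG-218 practice of deriving TL from
process-behaviour statistics. Two consequences are deliberate:
TL is **order-sensitive** (permuting the history changes
$\overline{mR}$), and TL may fall **below** AL when short-term
variability is small relative to systematic offset — such strata are
flagged `TL_below_AL`, not rejected, since the same pattern occurs in
real facility data.

One printed formula in the source material gives the chart centerline as
$\tfrac{1}{2}\sum x$, which cannot be a center for general $n$; it is
implemented as the arithmetic mean $\tfrac{1}{n}\sum x$, the standard
individuals-chart centerline.

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `beta` | 6 | – | width constant in $\Delta_A$; 6 is the TG-218 process-capability choice |
| `k` | 1.5 | IQR | Tukey fence multiplier for outlier flagging |
| `min_n` | 20 | records | below this a stratum's limits are flagged `provisional` but still reported |
| `dose_window` | [−10, 10] | % | plausibility range for dose differences at validation |
| `baseline_n` | all points | records | phase-I window of `spc_chart()`; set it to judge later points against early limits |
| 2.660 | fixed | – | individuals-chart constant, $3/d_2$ for $n=2$ subgroups |

## The synthetic cohort and what a green test establishes

Clinical PSQA databases carry patient identifiers and are not public, so
the package is validated against `generate_cohort()`. The default preset
(`showa2016_strata()`) states a fixed world:

* 4 facilities × 5 disease sites, 835 records split 147 (CNS), 256
  (HeadNeck), 89 (Chest), 258 (Pelvis), 85 (Other); facility shares
  0.35/0.25/0.20/0.20 per site, apportioned by largest remainder.
* Gaussian per-stratum channels, clipped to [0, 100] for gamma. Site
  baselines (3%/3 mm): CNS 99.80 ± 0.30, HeadNeck 99.35 ± 1.00, Chest
  99.60 ± 0.60, Pelvis 98.90 ± 1.84, Other 99.40 ± 1.20 — chosen so the
  analytic AL $= 100 - 3\sqrt{\sigma^2+(\mu-100)^2}$ lands near published
  per-site limits (98.9, 96.4, 97.8, 93.6). Facility effects multiply the
  mean's gap to 100 by $a$ and the SD by $b$: UniversityHospital (1, 1),
  KotoToyosu (0.545, 0.30), NorthernYokohama (0.118, 0.055), Fujigaoka
  (2.273, 1.53), reproducing the published ordering of Pelvis facility
  limits (93.6 / 97.6 / 99.5 / 88.7) from tightest (NorthernYokohama) to
  widest (Fujigaoka). The 2%/2 mm baselines (98.5 ± 2, 93.5 ± 7, 96 ± 4,
  92.5 ± 10, 94 ± 8) pool to ≈ 94.3 ± 7.7; dose difference is
  0.46 ± 0.98 everywhere. Per-stratum values are a calibration consistent
  with published aggregates, **not** measured data.
* A single RNG stream consumed in stratum order: identical
  `(strata, seed)` ⇒ byte-identical cohorts, and the manifest regenerates
  the cohort exactly.

Clipping matters. A Gaussian at 99.4 ± 1.3 puts ≈ 32 % of its mass above
100; clipping that tail lowers the realized pooled mean to ≈ 99.2 and
shrinks the SD, so realized moments sit slightly below the spec'd ones.
The manifest reports per-stratum clip rates so this bias can be bounded
(a test checks the rates against the normal upper-tail mass). Where a
test needs the untruncated Gaussian as its reference process — parameter
recovery of the analytic AL, SPC false-alarm rates — it draws with
`clip = FALSE`; that is a statement about the estimator, not about
clinical data.

The generator does **not** model device physics, plan-complexity effects,
correlation between gamma criteria, heavy left tails from genuine
failures, or autocorrelated drift in routine operation. A green test
therefore establishes that the estimators and detectors are correct on
their stated model, not that the preset is a faithful simulation of any
particular clinic.

Anomaly injection is additive with recorded ground truth: point outliers
at listed indices, step shifts from an onset, linear ramps reaching their
magnitude at the series end; gamma channels are re-clipped afterwards.
Recovery tests require injected point outliers beyond $4\sigma$ to be
flagged by both the IQR fences and chart rule 1, and a $3\sigma$
downward step to produce its first low-side rule-1 flag at or after the
onset — low-side, because passing rates are one-sided and an upper-tail
excursion is not actionable.

## Numerical conventions

* **Quartiles** use linear interpolation between order statistics
  (`stats::quantile()` type 7); at small $n$ other conventions move the
  fences noticeably, so the choice is part of the contract and the tests'
  oracle recomputes it from scratch.
* **Breach comparisons are strict**: a value exactly equal to AL, TL or a
  fence does not alert. Limits are bounds on acceptable results, so the
  boundary passes.
* **Chronological ordering** is by `qa_date`, ties broken by input row
  order; this pins down $\overline{mR}$ and hence TL.
* The chart band identity $\mathrm{UCL}-\mathrm{LCL} =
  2\times2.660\times\overline{mR}$ holds by construction and is tested to
  machine precision ($10^{-12}$ relative), the honest meaning of "exact"
  in floating point.
* UCLs above 100 % are reported unclamped; clamping is a display option
  of `autoplot()`.
* A stratum with fewer than 2 usable values has no defined SD or moving
  range and is omitted from limit tables with a warning; the pipeline
  counts records thereby excluded from alerting in
  `provenance$n_unalerted`.

## Open design choices, resolved

* **Grouping for per-site limits**: whether published per-site limits
  pooled facilities or not is unstated; both groupings are supported
  (`group_by = "site"`, `"facility"`, or both) and the pipeline computes
  site-pooled and facility × site tables.
* **IQR grouping unit**: outliers are assessed within the configured
  stratum (default facility × site), the unit in which processes are
  homogeneous; pooling across facilities would let a wide facility mask
  a tight one's outliers.
* **Severity policy**: out-of-range numerics, missing mandatory fields,
  unparseable QA dates and unmapped sites reject a row; unknown
  facility/machine/device labels only warn, since vocabulary drift is
  common across institutions and the rows remain analysable.
* **Site synonym table**: the five canonical categories are fixed; the
  shipped synonym map (e.g. `prostate → Pelvis`) is a documented,
  overridable default, and an unmapped label is returned as `"Unmapped"`,
  never guessed.
* **Run rules** beyond limit breaches (8 same-side, 6 monotone) are
  implemented but off by default; routine QA alerting here assumes
  limit-breach-only, matching the most conservative reading of the
  source workflow.
* A duplicated "Neck" row in the published per-site list is treated as a
  printing duplication of Head & Neck, not a sixth category.

## Limitations

The package consumes precomputed gamma passing rates; it does not compute
gamma indices from dose grids, read DICOM-RT, or interface with an
oncology information system. Limits assume a stable, homogeneous stratum
history — mixed histories (machine replacement mid-series) should be
split before analysis. The 2%/2 mm channel has no published limit values
to compare against, so its pipeline output is validated only against the
package's own oracles.
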