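---
title: "From a miRNA lifespan screen to ranked target genes: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From a miRNA lifespan screen to ranked target genes: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(miRTargetRank)
```

## The model

The pipeline assumes a two-stage genetic screen. In the first stage, each
of ~44 miRNAs is conditionally overexpressed in adult glia and the
resulting cohort's survival is compared with a control cohort by the
log-rank (Mantel–Cox) test of Kaplan–Meier curves. In the second stage,
candidate target genes are knocked down by RNAi and scored the same way.
Between the two sits an in-silico step that converts miRNA phenotypes into
per-gene rankings through four target prediction databases.

The quantitative backbone is a chain of three elementary quantities:

* **Signed χ².** The 1-df log-rank χ² measures how strongly a line's
  survival differs from control, but not in which direction. A line that
  significantly *extends* lifespan contradicts the premise that the
  perturbed gene products are needed in adult glia, so its χ² enters every
  average with a negative sign. Non-significant lines (p ≥ α) keep the
  positive sign whatever their median trend: this is the only rule
  consistent with the published averages we reproduce, and it avoids
  letting noise flip signs.
* **Average strength Av(χ²).** Lines for the same miRNA (or RNAi lines for
  the same gene) are averaged arithmetically. With a single line the value
  is halved — an average with an assumed neutral second line — so that
  unreplicated evidence is discounted rather than trusted at face value.
* **Weighted, summed, normalised scores.** Within each database, every
  prediction score is multiplied by the predicting miRNA's Av(χ²) and the
  products are summed per gene. Each database's column is rescaled so its
  top gene is 100 and weighted by the fraction of screened miRNAs the
  database knows about; the pooled ranking is the per-gene sum of these
  normalised values. Validation multiplies the same per-gene scores by the
  RNAi-derived Av(χ²)IR; summing over tested genes gives each database's
  predicting power, with opposite-direction outcomes subtracting.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `alpha` | 0.05 | significance level for calling a direction; fixes the shorten/extend/none partition |
| `n_screened` | 44 | denominator of the database coverage weight |
| `collapse` | `"sum"` | transcript-to-gene score aggregation (see below) |
| site points | 10/6/4, 8/4/2 | TargetScan conserved vs poorly conserved 8mer / 7mer-m8 / 7mer-1A |
| `baseline_hazard` | log(2)/31 per day | simulator's control death rate (31-day median) |
| `n_flies_per_group` | 60 | simulator cohort size, as in the study protocol |

## Design choices in genuinely open places

* **Transcript collapsing.** When a database lists several transcripts of
  one gene, their scores are **summed** by default, consistent with the
  algorithm's later step of summing all values for the same gene; `rule =
  "max"` is available for sensitivity analysis. Nothing in our target
  tables distinguishes the two (they are already gene-level), so the choice
  is documented rather than consequential here.
* **Negative Σ values.** Family strengths can be negative, so a gene's Σ
  can be negative. We normalise by the positive maximum, which preserves
  the within-database order; the alternative (clamping at zero) would
  discard the false-positive penalty that the validation stage relies on.
* **Ties.** Pooled ranking ties are broken lexicographically by gene id,
  purely for deterministic output.
* **Equal medians.** A significant log-rank difference with exactly equal
  medians admits no direction call and raises an error instead of guessing;
  no such case occurs in the bundled tables.
* **Mixed RNAi outcomes.** A gene with significant lines in both
  directions is assigned the partial category of the dominant direction
  (largest |signed χ²|), with a warning. In the bundled data only
  endoB-like rows trigger this, and the dominant direction always agrees
  with the sign of the average.
* **Display rounding.** Exported tables round half away from zero to four
  decimals. One bundled published row (Ero1L) sits exactly on a .5
  boundary and was evidently rounded down at source; comparisons against
  published columns are therefore made at half a unit in the fourth
  decimal, i.e. at printed precision.
* **p-value floors.** Values below 1e-4 are displayed `<0.0001`; on
  re-ingest such entries are parsed as half the bound. Only significance at
  α and display depend on p, so the convention is inert downstream.

## What the simulator emulates — and what it does not

`simulate_screen()` draws per-fly death times from an exponential (Weibull
shape 1; other shapes available) distribution with a per-genotype hazard
ratio, censors at the 90-day study end, and records deaths at whole days,
mimicking the periodic counting of a transfer protocol. Screened miRNAs get
log-uniform hazard ratios in 1.5–6; planted essential genes are targeted by
3–5 of the stronger miRNAs and receive the 99th-percentile background
score in every database that covers the miRNA, while background scores are
log-normal(1, 1). Databases cover 31/44, 28/44, 43/44 and 40/44 of the
miRNAs and include genes independently at rate `overlap_target^(1/4)`, so
the expected four-way overlap matches the configured 5.6%. microRNA.org
raw scores are emitted negative and TargetScan predictions as site lists,
so the database-specific ingest transforms are exercised end to end.

The simulator does **not** emulate seed-sequence biology, realistic score
distributions, correlated database errors, or age-dependent hazards.
Passing the planted-gene recovery tests therefore shows that the ranking
arithmetic concentrates planted signal as designed — not that any real
database has comparable signal-to-noise.

## Numerical and size choices

Determinism comes from one global seed fanned out into fixed per-stage
streams, so stages can be regenerated independently. Identical survival
samples short-circuit the log-rank statistic to χ² = 0 (its
observed-minus-expected form is 0/0 there). Test problem sizes — 2000-gene
universes with 20 planted genes for recovery checks, 1000 replicate null
pairs of 60 flies for the type-I error check — are large enough for the
assertions' tolerances while keeping the whole suite in the order of a
couple of minutes on one core.

## Known limitations

* Predicting efficiency needs the database-wide predicted-target count as
  an explicit denominator; it is not recoverable from per-gene validation
  tables alone.
* Family strengths use the plain mean of measured members; members whose
  strengths were never measured are dropped with a warning, so a family
  value can rest on partial information.
* The log-rank direction call compares medians only; crossing survival
  curves with equal medians are rejected rather than adjudicated.
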