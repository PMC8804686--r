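---
title: "Autoantibody microarray analysis of immune-related adverse events"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Autoantibody microarray analysis of immune-related adverse events}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iraeab)
```

## The problem

Immune checkpoint inhibitors (ICIs) unleash anti-tumor T-cell responses but
also cause immune-related adverse events (irAEs) — autoimmune-like
toxicities that can affect the liver, gut, skin, joints, heart, muscle,
exocrine glands, thyroid and other endocrine organs. Because several irAEs
resemble classical autoimmune diseases, circulating autoantibodies are a
natural candidate biomarker: do patients with particular autoantibody
profiles *before* treatment go on to develop particular toxicities, and do
antibody levels *move* as toxicity develops?

`iraeab` implements the complete analysis pipeline for a study design that
asks exactly these questions: a cohort of melanoma patients on combination
ICI therapy, profiled on a 120-autoantigen fluorescence microarray (IgG and
IgM reactivities) at baseline and again six weeks after the first dose,
alongside conventional serology (ANA by immunofluorescence, rheumatoid
factor and anti-CCP by ELISA), total immunoglobulin levels, prospectively
adjudicated adverse events, and survival follow-up. Patient-level data from
such trials are typically not deposited, so the package pairs every
analysis stage with a seeded synthetic-cohort generator that emulates the
study design; all statistical properties are validated by parameter
recovery on synthetic cohorts, and worked examples use the cohort's
published marginal counts.

## From spots to antibody scores

Each array spot yields a net fluorescence intensity (NFI) and a
signal-to-noise ratio (SNR). The per-spot readout is the antibody score

$$\mathrm{ABS} = \log_2(\mathrm{NFI} \times \mathrm{SNR} + 1),$$

which is zero when either quantity is zero and monotone in both
(`compute_abs()`). Spots with SNR ≥ 3 are considered true signal; an
antigen is dropped from the panel when SNR < 3 in **more than** 90% of all
samples of an isotype, pooling baseline and week-6 draws
(`filter_antigens()`). The boundary is strict: an antigen low in exactly
90% of samples is retained. We apply the filter per isotype with both
timepoints pooled because the sample set it refers to covers both draws.
Negative NFI values — possible after upstream background subtraction — are
clamped to zero with a warning rather than rejected, which keeps the log
defined while flagging data quality. Masked (SNR < 3) cells of retained
antigens are flagged but still enter downstream statistics: the filter
operates on antigens, not on individual cells, matching the order of
operations of the assay protocol.

### Control-based normalization

Slides drift in overall brightness and offset. Each slide carries internal
positive-control spots; `normalize_rlm()` regresses every sample's
control-spot scores on the across-sample median control profile with a
robust linear model (Huber M-estimation, tuning constant 1.345, ≤ 50
iterations, tolerance 1e-8, intercept included) and pushes the sample's
antigen scores through the inverse of the fitted affine map. On noiseless
affine distortions this recovers the truth to numerical precision; on noisy
data it strictly reduces between-sample control variance. Samples with
degenerate controls (zero variance, failed fit, near-zero slope) fall back
to median-ratio scaling and are flagged in the normalization report. The
exact robust-regression formulation used by any given core facility is not
standardized; this affine control-profile regression is one defensible
choice and is isolated behind a single function so it can be swapped.

## Differential abundance

Patient groups are defined from adverse events attributed *definitely or
probably* to the ICI — weaker attributions never enter any analysis. Three
grouping families are supported (`grouping_spec()`): organ-specific (event
of that organ vs all others), timing (first qualifying event < 6 vs ≥ 6
weeks, no-event patients excluded; the `<6 / ≥6` convention follows the
characteristics-table partition), and severity (maximum CTCAE grade 3–5
"severe" vs 1–2, no-event patients excluded).

Per antigen, groups are compared with a two-sided Mann-Whitney U test —
exact when the pooled size is ≤ 20 without ties, otherwise the
tie-corrected normal approximation — and the fold change is the difference
of group means on the ABS scale, which is already log2, with positive
values meaning higher scores in the event group. P values are adjusted by
Benjamini–Hochberg within one (isotype, timepoint, grouping) family. Two
significance notions coexist deliberately: the *adjusted* p < 0.05 defines
the differentially expressed antigen sets passed to clustering, while the
volcano table (`volcano_table()`) draws its conventional dotted line and
corner counts at *raw* p = 0.05, as volcano plots conventionally do.

## Patient clustering

`cluster_patients()` performs hierarchical clustering of patients on their
baseline scores restricted to the differentially expressed antigen set:
Euclidean distance, complete linkage (the `hclust` default and the most
literal reading of the protocol; average and Ward linkage are available for
sensitivity runs), tree cut at k = 4. Clusters are labelled `high`,
`moderate`, `slightly_low`, `low` by descending mean score. The DE set
defaults to the union of adjusted-significant antigens over the nine
organ-specific baseline comparisons (`de_antigen_union()`); when no antigen
reaches adjusted significance — the expected outcome on a null cohort —
the function can fall back to the smallest-raw-p antigens so that the
clustering stage still has a substrate, and the manifest records the set
size. `cluster_enrichment()` then tests each (cluster, organ) pair with a
two-sided Fisher's exact test on the in-cluster vs out-of-cluster event
table; "more/less common than expected" is the odds-ratio direction,
highlighted at p < 0.05.

## Longitudinal fold changes

For patients with both draws, `fold_changes()` computes cellwise
`ABS(week6) − ABS(baseline)`. Patients missing the week-6 draw are excluded
and listed. The association between change magnitude and toxicity burden
(`fc_vs_irae_count()`) uses each patient's *mean absolute* fold change over
the antigen set as the primary summary — direction-agnostic, because both
rises and falls represent humoral movement — with the signed mean reported
alongside, and tests it against the number of *distinct organ categories*
with qualifying events by Spearman correlation plus Kruskal–Wallis across
count strata. `supervised_order()` produces the display ordering of the
event-annotated heatmap: event patients first, by descending organ count
and then descending mean |FC|; no-event patients last, kept in input order
(the magnitude key is applied to event patients only, so the no-event block
is a stable tail rather than being re-ranked).

## Serostatus, seroconversion and time-to-event

`classify_serostatus()` applies strict thresholds — RF > 14 IU/mL,
anti-CCP > 20 U/mL, ANA as the binary immunofluorescence report (no titer
modeling) — and a patient is seropositive at a timepoint if any of the
three is positive. Missing week-6 draws leave week-6 status unknown and out
of week-6 denominators. `seroconversion_accounting()` counts gains and
losses between draws and *asserts* the bookkeeping identities
`week6 = baseline(paired) + gained − lost` and `any = baseline + gained`
on every cohort, erroring on violation.

Time-to-event endpoints (`build_time_to_event()`): time to first
qualifying irAE and to first severe (grade 3–5) irAE in weeks, with
event-free patients censored at their last follow-up (default median 25
months, supplied per patient in the clinical table since the censoring rule
must be explicit in the data contract); progression-free and overall
survival in months, restricted to stage IV patients. Estimation is the
Kaplan–Meier product-limit estimator with the median defined as the
earliest time the curve reaches 0.5 or below, and group contrasts use the
standard 1-df log-rank test, stratified by baseline seropositivity.
Categorical group comparisons use Fisher's exact test, switching to the
chi-squared test when every expected cell count is at least 5 (the
conventional rule, since the protocol lists both tests without one).

## Total immunoglobulins

`assign_quartiles()` cuts total IgG/IgM at type-7 sample quantiles; tied
values land in the same quartile and an all-tied input collapses to Q1 with
a flag. `quartile_associations()` runs Fisher tests of quartile membership
against categorical traits, Wilcoxon for sex against the Ig level, and
log-rank highest-vs-lowest quartile for PFS/OS.
`ig_normalized_sensitivity()` is the robustness check that the microarray
findings are not driven by overall antibody production: it divides each
patient's linear-scale signal by that patient's relative total Ig of the
matching isotype, re-scores, reruns the comparison, and reports sign
concordance and the Spearman correlation of fold changes between runs.
Sign concordance is the sensitive summary here — a patient-constant Ig
rescaling shifts one group's fold changes almost uniformly, which flips
signs long before it disturbs ranks.

## The synthetic cohort generator

`generate_cohort()` draws a complete study: the defaults are the study
conditions (60 patients, 120 antigens × IgG/IgM × two timepoints, eight
control spots, 15% of patients missing the week-6 draw completely at
random, nine organ categories with per-organ event rates and lognormal
onset distributions whose medians follow the early/late pattern of ICI
toxicity — dermatologic and myocarditis ≈ 2.4 weeks, hepatic ≈ 5.3,
colitis ≈ 6.3, arthritis ≈ 11.5, non-thyroid endocrinopathy ≈ 11.7 —
CTCAE grades and attribution levels mostly definite/probable, baseline
serology positivity near 28%, and exponential PFS/OS censored at
follow-up).

Distributional choices the assay literature does not pin down are
conventions, not claims about the real instrument: baseline scores are
normal on the log2 ABS scale with antigen-specific means, a shared
per-patient offset and spot noise (so NFI is lognormal-like and
heavy-tailed); SNR is lognormal with a deterministic "quiet" tail of the
panel (last 10% of antigens) that mostly sits below 3 and exercises the
filter; per-slide affine distortions (slope sd 0.05, offset sd 0.15 on the
log2 scale) are applied to antigen and control spots alike, which is what
normalization must remove; NFI is recovered as `(2^ABS − 1)/SNR` so that
re-scoring the emitted table reproduces the planted scores exactly.

Planted effects (`planted_effect()`) shift chosen antigens for a chosen
group additively on the ABS scale before back-transformation. Baseline
shifts are carried into the week-6 draw so that planting a baseline group
difference does not fabricate fold changes. The coupling between
fold-change magnitude and toxicity burden is a separate knob:
`fc_sd_per_event` (default 0.1 ABS per distinct-organ event) inflates the
week-6 drift standard deviation, so patients with more distinct events
show larger absolute fold changes — the reactive-humoral-response pattern
— without moving any group mean, which keeps week-6 group comparisons
approximately null. One global seed fans out to fixed per-component
substreams, so the events table, signals, serology, immunoglobulins and
survival can each be regenerated independently and a cohort is reproduced
byte-for-byte from its seed.

What the generator does *not* emulate — and hence what passing tests do not
demonstrate about real data: antigen–antigen correlation blocks beyond the
shared patient offset, spatial slide artifacts, informative (non-random)
missingness of the week-6 draw, dependence between baseline autoantibody
levels and subsequent events (absent unless planted), organ-specific
autoantibody signatures, and assay floor/saturation effects.

## Numerical choices and degenerate inputs

* Half-up rounding (`proportion()`) for every printed percentage, because
  that is how such tables are conventionally rounded; R's own `round()`
  is half-to-even and disagrees on exact halves.
* Identical groups: Mann-Whitney returns p = 1 and fold change 0 rather
  than NaN; the log-rank result is flagged undefined when neither group has
  events; Spearman/Kruskal are flagged when counts or magnitudes are
  constant.
* Cluster labels break mean-score ties by cluster index; `hclust` itself is
  deterministic for a fixed input order.
* Quartile ties cannot be split (tied patients share a quartile); sizes
  differ by at most one for distinct levels.
* Empty strata and degenerate groupings produce flagged rows or empty
  results with warnings, never silent omissions.

## Problem sizes used in validation

The test suite validates the statistical properties at these sizes: false
discovery rate on 500 null cohorts of 40 patients × 120 antigens (BH at
0.05, empirical FDR within the binomial confidence band of 0.05); power and
bias on 200 cohorts with ten antigens shifted by +1.5 ABS at 30 vs 30
patients (median recovered fold change within ±0.1, > 80% of planted
antigens recovered after adjustment); exact recovery (adjusted Rand index
1) of four intensity groups separated by ≥ 5 within-group SDs across 100
replicates; Kaplan–Meier medians within 2% of ln 2/λ at n = 10⁴ and
log-rank null rejection at 5% ± 1.5% over 1,000 replicates; seroconversion
identities fuzzed over 100 cohorts. `scripts/acceptance.R` re-reports the
headline quantities at reduced replicate counts (100 null cohorts, 25
recovery cohorts, 400 log-rank replicates), which its output records next
to each value.

## Known limitations

* The robust-normalization formulation is one reading of
  "robust linear model with internal positive controls"; facilities differ.
* With 120 antigens and cohort-scale group sizes, organ-specific
  comparisons are underpowered for subtle effects; the package reports
  adjusted and raw significance separately rather than pretending
  otherwise.
* The four-cluster cut is fixed by design, not chosen by a stability
  criterion; alternative k and linkage are parameters, not defaults.
* PFS/OS analyses ignore competing risks; events and deaths are treated by
  standard right-censoring only.
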