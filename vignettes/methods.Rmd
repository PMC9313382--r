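---
title: "Tracking myeloma clonal evolution from paired panel sequencing: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking myeloma clonal evolution from paired panel sequencing: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mmclonetrack)
```

## The problem

Multiple myeloma relapses through clonal evolution: subclones of plasma
cells gain, lose and re-weight somatic variants under the selective
pressure of therapy. Given targeted-panel sequencing of two bone-marrow
samples per patient — a first sample and a later progression ("paired")
sample — this package reconstructs what changed between them: which
variants were acquired, lost, expanded, declined or stayed stable; which
evolution pattern each patient followed; how the prognostic copy-number
lesions evolved; how the patient's risk stage (ISS / R-ISS) shifted when
recomputed at progression; and whether the recomputed stage stratifies
progression-free and overall survival.

Because real longitudinal cohorts of this kind are rarely deposited, the
package ships a first-class synthetic-cohort simulator with ground-truth
labels, so every stage is exercised and scored without any external data.

## The variant inclusion cascade

Variants from tumor-only calling are noisy; the pipeline admits a variant
(per patient, per variant key `chrom:pos:ref:alt`) only if it passes four
stages, in order:

1. **Population allele frequency** — every non-missing AF across the three
   population databases (1000 Genomes, gnomAD, ESP) must be strictly below
   1%. A variant absent from all three passes: absence from population
   databases is evidence of rarity, and tumor-only designs cannot subtract
   germline directly.
2. **Read support** — VAF at least 10% with at least 5 alternate reads,
   simultaneously, in at least one of the two paired samples. Both bounds
   are inclusive, and support in either sample suffices (a variant may be
   absent from one sample precisely because it was acquired or lost).
3. **Predictor consensus** — a pathogenic verdict from at least 2 of six
   predictors (CRAVAT, CHASM, CScape, FATHMM Cancer, DEOGEN2, PrimateAI).
   For genes recurrently mutated in myeloma, one pathogenic verdict from a
   cancer-specific predictor (CRAVAT, CHASM, FATHMM Cancer, CScape)
   suffices. Missing verdicts count as non-pathogenic — the conservative
   reading where a predictor's coverage is silent.
4. **ACMG-class rejection** — variants classified benign or likely benign
   are rejected unless whitelisted; the default whitelist carries the
   single KMT2C c.1173C>A entry. A *missing* class is retained: rejection
   requires affirmative benign evidence.

The cascade is evaluated on the designated (first, paired) pair only;
additional samples of a patient never rescue a variant. Each stage's
retained/rejected counts are recorded in a report whose counts must
balance stage over stage — a property the tests enforce.

## Trajectory classification

Presence at a timepoint requires at least 3 alternate reads **and** VAF at
least 2%. Cohort reports of this kind state presence/absence without a numeric
floor; a floor is necessary in practice because at ~267x depth a handful
of noise reads would otherwise convert stable variants into spurious
acquisition/loss calls, and with it spurious "branching" patients. Both
thresholds are configurable (`trajectory_config()`).

A variant present only at the paired sample is **acquired**; only at the
first, **lost**. For variants present at both timepoints, **expanded** /
**declined** requires *both*:

* a two-sided two-proportion test on the (alt reads, depth) pairs
  rejecting at `change_alpha = 0.05` (implemented with `prop.test`,
  no continuity correction), and
* an absolute VAF difference of at least `change_delta_min = 0.10`.

The effect-size guard matters: at depth of several hundred, a pure
significance rule calls trivial 2–3 point VAF shifts, which no reader of a
fish-plot would label expansion. Everything else is **stable**.

Clonality is a VAF proxy: a present variant is **clonal** at VAF ≥ 0.40
(inclusive), else subclonal; a subclonal-to-clonal move between the
samples is flagged as a clonal transition. No purity or copy-number
correction is applied by default — no per-variant cancer-cell-fraction
model is assumed — but the threshold is a single configurable
number and a purity-aware adjustment can be layered on the same field.

Patient-level patterns follow from the acquired/lost counts alone:
**branching** (≥1 acquired and ≥1 lost), **acquisition** (≥1 acquired,
none lost), **loss** (≥1 lost, none acquired), **stable** (neither). These
four classes partition evaluable patients, and swapping the two samples
maps acquisition to loss (and expanded to declined) while fixing branching
and stable — a symmetry the property tests check.

**Parallel evolution** is emitted when two or more distinct variants of
one gene are present in the same sample of a patient. The phenomenon could
equally be defined to require that both variants be *acquired*;
co-presence is the default and an acquired-only mode is a config flag
(`parallel_acquired_only`).

## Copy-number events

Segments arrive as (chrom, start, end, log2) in BED-convention
coordinates; the package consumes them and never re-segments. For each of
the seven monitored windows (1p12, 1p22.1, 1p32.3, 1q21, 17p13.1, 13q14,
14q32) the region value is the length-weighted mean log2 of intersecting
segment portions, reported only when segments cover at least half the
window (`min_region_overlap = 0.5` — a sliver of coverage should not call
a chromosome-arm event).

Thresholds are `log2 <= -0.25` for losses and `log2 >= +0.20` for gains,
near the conventional defaults of segment-based CNV callers; no standard
cutoffs exist for panel data, so these are explicit, configurable
assumptions, as are the GRCh38 cytoband-scale window
coordinates shipped in `inst/extdata/cnv_regions.tsv`. "del17p /
17 monosomy" is represented by the 17p13.1 window alone. The composite
**del1p** is the OR of its three sub-regions; with a missing sub-region the
composite is true if any sub-region fired and missing otherwise.

Between the paired samples each region is classified stable-present /
stable-absent / acquired / lost; a patient's CNV profile is *stable* iff
no region changed, with missing regions excluded from the judgment but
counted. Note that with only five composite regions monitored, the
synthetic cohorts show more stable CNV profiles (roughly a third of
patients) than a genome-wide view would; a finer-grained profile is out of
scope here.

A **biallelic event** is a variant with VAF ≥ 0.80 in at least one sample
whose locus is not amplified there (locus log2 < +0.30; a locus without
segment coverage counts as not amplified). "Amplified" could reasonably mean
any gain or only high-level amplification; the default threshold sits above the gain cutoff and is configurable. **Double / triple
hits** count distinct high-risk lesions among del17p, gain1q21, del1p,
t(4;14) and t(14;16) (the translocations come only from FISH flags —
panel sequencing cannot call them); a TP53 double hit is del17p
co-occurring with a retained TP53 mutation.

## Staging and survival

ISS: stage I iff β2-microglobulin < 3.5 mg/L and albumin ≥ 3.5 g/dL;
stage III iff β2M ≥ 5.5 mg/L; else II. R-ISS: I iff ISS I with no
high-risk cytogenetics (del17p, t(4;14), t(14;16)) and normal LDH; III iff
ISS III with high-risk cytogenetics or high LDH; else II. Missing LDH or
cytogenetics yield "not reported" *unless the stage is decidable
regardless* (ISS II is always R-ISS II; ISS I with a known high-risk
lesion is R-ISS II whatever the LDH). Patients not reported at a timepoint
are excluded from that timepoint's staging analyses. Both functions are
verified against an independent lookup-table oracle over an exhaustive
grid.

Survival uses the survival package throughout: Kaplan-Meier with
Greenwood variance and log-transformed intervals, the group median defined
as the first time the estimate drops to 0.5 or below, the log-rank test,
and a single-covariate Cox model with the **Efron** tie convention
(the less biased of the common conventions at clinical tie density) with a Wald 95% CI on the log
hazard ratio. No multiple-testing correction is applied: all tests are
single-factor, two-sided comparisons at the 0.05 level.

The loss-vs-acquisition response association dichotomizes the inter-sample
response at ≥ VGPR and computes the two-sided Fisher exact p by direct
hypergeometric enumeration (`fisher_exact_p()`), cross-checked in the
tests against `stats::fisher.test` to 1e-12 over every 2x2 table with
n ≤ 40.

## The synthetic cohort generator

`simulate_cohort()` draws, per patient: an evolution pattern
(probabilities 8/11/7/4 over 30 — the observed cohort mix), variant counts
(1 + Poisson acquired/lost counts as the pattern requires; 1 + Poisson(3)
shared variants), and true CCF trajectories. Observed VAF expectation
follows the diploid-heterozygous model `purity * CCF / 2` with purity
uniform on [0.82, 0.98]; read counts are binomial at negative-binomial
depth (mean 267, size 12 — overdispersed to stress the presence-call
boundaries). Key calibration choices, made once on power grounds:

* **CCF changes** for expanded/declined variants are uniform on
  [0.25, 0.55], and stable variants keep *exactly* equal CCFs, so
  trajectory recovery is a well-posed question (the smallest change,
  0.25 CCF ≈ 0.10–0.12 VAF, sits at the effect-size threshold — the
  hardest detectable case).
* **Acquired/lost variants** carry CCF in [0.35, 0.90] at their present
  timepoint: far enough above the read-support filter that a true
  acquisition is rarely filtered away, which would silently flip a
  patient's pattern.
* **Decoys for every filter stage**: common-SNP contaminants (population
  AF ≥ 1%, germline-like VAF 0.5), low-support artifacts (true VAF below
  5%), non-consensus passengers (at most one pathogenic verdict), and
  benign/likely-benign rejects, plus exactly one whitelisted KMT2C
  c.1173C>A benign variant per cohort. Predictor verdicts are drawn with
  sensitivity 0.85 and a 5% missing rate.
* **CNV**: per-region event probabilities at the first sample and
  conditional acquisition probabilities are set from the published
  per-region detected/acquired counts; losses occur at 7%. Segments tile
  each monitored chromosome (window plus flanks) with Gaussian log2 noise
  (sd 0.10) around shifts of -0.5 (loss) / +0.4 (gain) — about 2.5 noise
  sd from the calling thresholds, so single-region miscalls are rare but
  not impossible.
* **Clinical and survival**: albumin lognormal around 3.8 g/dL, β2M
  lognormal around 4.0 (first) / 4.5 (paired) mg/L, LDH high with
  probability 0.25/0.35, small missingness rates producing "not reported"
  stages. The true R-ISS at the paired sample assigns the survival group;
  PFS and OS-from-paired-sample are exponential with medians 11 vs 3 and
  21 vs 9 months (lower-risk vs R-ISS III) under ~20% uniform censoring,
  whose bound is solved exactly from the exponential rate. OS from the
  first sample is the paired-sample OS plus the inter-sample gap (uniform
  2–12 months), which enforces the ordering invariant between the two OS
  clocks by construction rather than calibrating a third independent
  median. Response probabilities favor ≥ VGPR under the loss pattern and
  cap acquisition-pattern patients at PR-or-worse, reproducing the
  direction of the published association.
* **Biallelic fixtures** are injected by an explicit high-VAF (0.85)
  override of one stable variant in ~20% of patients; VAF is *not*
  copy-number-coupled in the generative model — a documented
  simplification that keeps trajectory truth and biallelic truth
  independent.

Randomness is governed by one master seed; per-patient substream seeds are
drawn once from the master stream, so patient *i*'s data depend only on
(seed, *i*) and enlarging the cohort appends patients without reshuffling
existing ones.

What the generator does **not** emulate: mutational signatures, phylogenetic
subclone structure (variants evolve independently), spatial heterogeneity,
copy-number-coupled VAFs, and inter-gene correlation of mutations. Passing
recovery tests therefore demonstrate that the pipeline's decision rules
invert the generator's noise model at the stated depths and effect sizes —
not that they would resolve, say, subclonal copy-number interplay in real
tumors.

## Problem sizes and numerical choices

The bundled analysis scripts simulate 30-patient cohorts (the study-scale
condition); recovery properties are tested on 200-patient cohorts at a
fixed seed, where patient-pattern recovery ≥ 95% and CNV event recovery
≥ 98% are required. Survival recovery uses 2000 subjects per arm: the Cox
estimate must cover a true hazard ratio of 6.5 within its own 95% CI and
the KM median must land within 10% of a true 11-month median. Two-group
comparisons with zero events in a group report an undefined hazard ratio
rather than a fitted one. Fisher enumeration uses the conventional
relative tolerance (1 + 1e-7) when comparing table probabilities, matching
the reference implementation. Boundary semantics follow the printed rules
exactly: "< 1%" strict, "≥ 10%", "≥ 5 reads", "≥ 0.40", "≥ 0.80"
inclusive.

## Known limitations

* Tumor-only design: the filter approximates somatic status; true
  germline variants at VAF ≈ 0.5 that are rare in population databases
  can survive it.
* Variant-level (not clone-level) tracking: no subclone deconvolution or
  phylogeny; "branching" is defined combinatorially from per-variant
  calls.
* The five-region CNV profile understates genome-wide CNV instability;
  stable-profile fractions are accordingly higher than a genome-wide
  analysis would report.
* Multi-allelic VCF records are split into independent records — an
  assumption; such sites are rare in coding panels but not impossible.
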