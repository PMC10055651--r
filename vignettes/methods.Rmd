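---
title: "Models and methods behind imprintscope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind imprintscope}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(imprintscope)
```

# The biological model

Bilateral Wilms tumor (BWT) requires a predisposing event present in both
kidneys. Two classes of initiating events dominate:

* **Pre-zygotic (germline) variants** in Wilms tumor or pediatric cancer
  predisposition genes. Germline *WT1* variants are typically followed in
  each tumor by an *independent* somatic copy-neutral LOH event on 11p
  that establishes paternal uniparental disomy across both the 11p15.5
  imprinted cluster and the *WT1*/11p13 locus, and then by private
  activating *CTNNB1* variants.
* **Post-zygotic, pre-lateralization epigenetic events**: somatic mosaic
  hypermethylation of the H19/ICR1 imprinting control region (loss of
  imprinting, LOI). Because the alteration arises before the left/right
  mesodermal kidney primordia separate at gastrulation, it is shared by
  both tumors, detectable at high cell fractions in adjacent
  histologically normal kidney (clonal nephrogenesis) and at low cell
  fractions in blood leukocytes, which are also mesoderm-derived.

Every analysis in the package operationalizes one consequence of this
timing model: shared 11p15.5 status in tumor pairs, essentially disjoint
somatic variant sets, independent cnLOH breakpoints, low-level blood
hypermethylation in LOI patients, and a positive age-drift of blood ICR1
methylation in mosaic carriers (clonal expansion over time) against a
slightly negative drift in controls.

# Imprinting classification

Region-mean β values are unweighted means over all non-missing probes
whose manifest coordinate falls inside the window, bounds inclusive
(`region_mean_beta()`). The windows default to H19/ICR1
chr11:2,019,974–2,024,738 and KCNQ1OT1/ICR2 chr11:2,721,228–2,722,228
(GRCh38). We use *all* in-window manifest probes rather than a curated
probe list; with EPIC-scale manifests the windows contain on the order of
ten probes and the unweighted mean is the obvious estimator.

The rule table (`classify_imprinting()`) uses strict inequalities on both
sides of the 0.7 (ICR1) and 0.3 (ICR2) thresholds. That leaves three
boundary/edge situations undefined by the thresholds themselves, and we
deliberately map all of them to `indeterminate` rather than silently
picking a side: exact threshold equality, missing region means (including
fewer than `min_probes` usable probes, default 3), and the unnamed
quadrant (ICR1 < 0.7 with ICR2 < 0.3, a pattern the mixture model does not
produce). Segmentation-based cnLOH evidence overrides the methylation call
to LOH; the `loh_source` field records whether LOH was established by
methylation, segmentation or both.

# Mosaic-fraction estimation

A tissue is modelled as a two-population mixture: a fraction $f$ of
altered cells and $1-f$ normal cells. At (ICR1, ICR2) the population
expectations are fixed by imprinting biology — one methylated allele per
ICR in normal cells, so ROI contributes $(0.5, 0.5)$; LOI gains ICR1
methylation, $(1.0, 0.5)$; LOH (paternal UPD) duplicates the
ICR1-methylated, ICR2-unmethylated paternal allele, $(1.0, 0.0)$. Hence

$$\bar\beta_{ICR1} = b_1 + (1 - b_1) f, \qquad
  \bar\beta_{ICR2} = b_2 (1 - f) \;\text{(LOH only)},$$

with baselines $b_1 = b_2 = 0.5$. `estimate_mosaic_fraction()` inverts
these: the ICR1 inversion for LOI (and for ROI samples, where the estimate
is a noise floor), and the average of the ICR1- and ICR2-derived estimates
for LOH, each clamped to $[0,1]$. Array β values are attenuated toward 0.5
in practice, so the baselines can be recalibrated to the observed
control-blood means; the theoretical 0.5 is the default because the
synthetic data are not attenuated.

# cnLOH calling

Copy-neutral LOH manifests as B-allele fractions split away from 0.5 with
a log2 copy ratio near 0. `call_cnloh_11p()` is a deliberately simple
change-point caller, not a reimplementation of a production CNV caller:
recursive binary segmentation on the folded BAF $|BAF - 0.5|$, minimum
segment 10 SNPs, adjacent segments merged when their means differ by
less than 0.05. A segment is LOH-like when its mean folded BAF is ≥ 0.15
while $|\log_2 R| < 0.1$; deviation ≥ 0.35 (near-pure, folded BAF of a
clonal event is 0.5 × cell fraction ≈ 0.35–0.5) is `cnloh`, below that
`partial_cnloh`. Tracks with fewer than 20 informative SNPs return a
no-call with a reason. These thresholds reproduce the qualitative
full/partial LOH distinction the downstream rules need; they are not tuned
to any particular sequencing platform.

The *WT1*/11p13 window used by `loci_overlap()`
(chr11:32,387,775–32,435,539) is a shipped default covering the *WT1* gene
body; override it if your annotation differs.

# Paired-tumor concordance

Variants are compared by exact (chrom, pos, ref, alt) identity — calls
are assumed harmonized upstream, and no position-window fuzzing is
applied. Copy-number similarity rasterizes each track's log2 ratio onto
1000-kb genome bins and takes the Pearson correlation over bins where at
least one profile is non-neutral ($|\log_2 R| \ge 0.1$): correlation over
an all-neutral genome is undefined and including neutral bins would
inflate similarity. When the retained bins are constant in one profile
(a single uniform event), Pearson is undefined and the cosine similarity
is used instead, which yields the natural ±1 for identical/mirrored
single-segment tracks. 1q gain is graded by the unioned covered fraction
of the 1q arm (GRCh38 chr1:123,400,001–248,956,422): `whole_arm` at ≥ 0.95
coverage — the distinction between whole-arm and partial gain is
qualitative, and 0.95 tolerates segment-boundary jitter.

The clonality flag fires when the shared noncoding fraction
$n_{shared}/\min(n_L, n_R)$ reaches 0.25 **and** CNV similarity is ≥ 0.8
or unavailable. In characterized BWT pair data the one clonal outlier has
shared fraction ≈ 0.62 while independent bilateral pairs stay ≤ ≈ 0.11,
so 0.25 sits in a wide separation margin; both thresholds are arguments.

# Germline triage

The decision tree applies rules in a fixed precedence: panel membership →
indel/nonsense auto-include → ClinVar pathogenic/likely-pathogenic
include → ClinVar benign/likely-benign exclude → in-silico/VAF step for
VUS, no-assertion and unreported variants. The source rules carry no
explicit precedence; we made the ClinVar benign exclusion pre-emptive over
in-silico scores because a curated benign assertion is categorical while
predictions are not. "Deleterious by PROVEAN" is mapped to the tool's
published default cutoff −2.5, and "significant VAF increase in tumor" to
a one-sided Fisher exact test ($p < 0.05$) on the ref/alt × tissue depth
table; both are configurable. Splice variants have no indel/nonsense
shortcut and traverse the in-silico step like missense variants — an
assumption, since the source rules do not address them. The shipped
default panel is the 21 Wilms-tumor predisposition genes
(`default_wt_panel()`); the full several-hundred-gene cancer panel is
user-supplied.

# Cohort statistics

* **Association**: Pearson chi-square without continuity correction on the
  tumor-status × germline-carrier table.
* **Blood comparison**: two-sided Mann-Whitney per status-group pair. The
  test is unnamed in the source analyses; we default to the nonparametric
  choice because the low-level mosaic β shifts are small and skewed, and a
  t-test is available by trivially swapping the call. Units are patients,
  with the patient-level consensus status defined as: any LOI tumor → LOI,
  else any LOH → LOH, else ROI (an altered status outranks ROI for a
  discordant pair, since the question is whether the patient carries the
  mosaic alteration anywhere).
* **Age model**: OLS of blood ICR1 β on age in controls, 95% prediction
  intervals with the standard leverage term; group comparison reports the
  group's own slope, whether its sign differs from the control slope, and
  the fraction of group points above the upper prediction bound.
* **Clustering**: probes ranked by M-value variance after excluding
  chrX/chrY (sex bias), ties broken lexicographically for determinism; the
  default view count is 10,000 probes. Views are average-linkage
  hierarchical clustering on Euclidean M distance, a two-dimensional
  principal-component embedding, and a Spearman sample-correlation matrix.
  The embedding is PCA rather than a stochastic neighbor method: it is
  deterministic by construction, and separation claims are only ever made
  on clearly separable synthetic data, which PCA resolves. Tumor samples
  below 80% purity are excluded (purity dilutes tumor-intrinsic
  methylation toward the stromal background); non-tumor samples are never
  purity-filtered.

# The synthetic cohort generator

`sim_config()` fixes the study conditions; the defaults are chosen once,
on biological grounds:

| parameter | default | rationale |
|---|---|---|
| mode_probs | wt1 0.15 / other germline 0.20 / mosaic LOI 0.40 / mosaic LOH 0.05 / none 0.20 | germline carriers ≈ 41% of patients and LOI the single most common predisposition, with mosaic LOH rare |
| f_blood | mean 0.08, sd 0.03 | blood mosaicism is low-level: blood must stay below the 0.7 frank-LOI threshold |
| f_kidney | mean 0.50, sd 0.15 | adjacent kidney carries intermediate-to-high mosaic fractions (clonal nephrogenesis), sometimes crossing frank thresholds |
| f_tumor | mean 0.90, sd 0.05 | tumors arise from the altered clone; fraction ≈ purity |
| beta_precision | 100 | per-probe β SD ≈ 0.05 near β = 0.5, the visible scatter scale of array data |
| lambda_noncoding | 90 | per-tumor noncoding loads in whole-genome-sequenced pairs run tens to a few hundred |
| lambda_shared | 1.5 | shared noncoding counts in independent bilateral pairs are 0–6 |
| drift slopes | case +0.001, control −0.0005 β/year; sd 0.01 | low-level positive drift in mosaic carriers vs slight negative drift in controls, resolvable at cohort size |

Per-probe β values are Beta-distributed with the mixture mean and
concentration `beta_precision`; background (non-ICR) probes get per-probe
baselines with tissue-specific offsets drawn once per cohort so tissues
separate in clustering. The blood-vs-kidney mosaic-fraction ratio is not
quantified anywhere we know of; the defaults above are stated assumptions
for sensitivity testing, not estimates.

Determinism: one master seed; per-patient substreams are derived from the
patient index, so patient $i$'s data are invariant to cohort size, and
`simulate_cohort()` is byte-identical under a repeated seed.

What the generator does **not** emulate — and what passing tests therefore
do not show about real data: array attenuation of β toward 0.5 and
probe-specific biases, batch/chip effects, cell-type composition of blood,
realistic genome-wide mutational signatures and variant clustering,
intra-tumor heterogeneity, and histology or treatment response. Parameter
recovery at precision 100 demonstrates correctness of the estimators under
the stated model, not calibrated performance on EPIC arrays.

# Numerical choices and problem sizes

M values are computed as $\log_2(\beta/(1-\beta))$ with β clamped to
$[10^{-6}, 1-10^{-6}]$, keeping boundary values finite while preserving
monotonicity; the intensity-based M definition is unavailable downstream
of normalization and the logit identity is the standard equivalent.
Coordinates are 1-based and inclusive throughout, including the
"BED-like" regions TSV (documented in `read_regions()`). Variant identity
is (chrom, pos, ref, alt); multi-allelic records are decomposed on read.

The shipped test and acceptance workloads use desk-scale sizes chosen to
make the stochastic properties sharp: a 200-patient cohort for
mosaic-fraction/mode recovery, 100 mosaic pairs for status agreement, 200
simulated control cohorts for prediction-interval coverage, 100 runs for
drift-sign recovery, a 201 × 201 β grid for the classifier rule-table
equivalence and the ~1,500-case annotation cross-product for the triage
tree.

# Known limitations

Cohort-scale headline fractions of a real BWT population (status
prevalences, pair-concordance rates, adjacent-kidney frank-threshold
rates) can only be reproduced from the deposited patient data (GEO
GSE226234 and companions), not from synthetic cohorts; the package's
verifiable claims are the rule-table equivalences, the transcribed
pair-summary fixture and the parameter-recovery/coverage properties. The
cnLOH caller is a change-point stand-in, not a production CNV pipeline.
The triage tree consumes user-supplied annotation tables and performs no
live database queries, by design, for reproducibility.
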