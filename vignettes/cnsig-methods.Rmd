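---
title: "Deriving copy-number-driven prognostic signatures with cnsig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving copy-number-driven prognostic signatures with cnsig}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnsig)
library(dplyr)
```

## The problem

Invasive lobular carcinoma (ILC) is the most common special-type breast
cancer. It usually presents as an estrogen-receptor-positive, grade 2
tumor whose clinical course is hard to prognosticate with standard tools
such as the Nottingham Prognostic Index (NPI), and the widely used
commercial expression signatures were developed mostly in ductal (IC-NST)
cohorts. `cnsig` implements an integrative strategy for deriving a
tumor-type-specific prognostic metagene from multi-cohort profiles: use
recurrent DNA copy-number change to nominate genes whose expression is
dosage-driven, keep the subset whose expression stratifies
breast-cancer-specific survival (BCSS), and compress them into a single
signed score with a cross-validated High/Low cutoff.

The real cohorts this kind of study draws on (SNP-array and expression
profiles with BCSS follow-up) are controlled-access, so the package
ships a synthetic multi-cohort generator with planted ground truth.
Every stage of the pipeline is exercised and validated on data whose
correct answer is known by construction.

## Pipeline stages and their models

### 1. Gene-level copy number

Copy-number substrates arrive as per-sample segments in one of three
dialects: absolute integer copies, discrete state calls, or CBS-style
log2 ratios. `call_states()` maps each to the five canonical states.
For absolute copies: 0 HOMD, 1 HETD, 2 NEUT, 3–5 GAIN, and 6 or more
AMP (published integer thresholds leave 5–6 ambiguous; with integer
copies "more than 5" and "at least 6" coincide, which is the reading we
use). For log ratios: gain above +0.3, loss below −0.3, with
amplification/homozygous-deletion cutoffs configurable (default ±1.0)
because in practice those are delegated to sample-specific segmentation
output that this package does not recompute.

`assign_gene_cn()` lifts segments to genes with the maximal-severity
rule: severity is NEUT 0, GAIN +1, AMP +2, HETD −1, HOMD −2; a gene
split by several segments takes the state (and that segment's
log-ratio) with the largest absolute severity. A gene fully inside one
segment is the degenerate one-segment case of the same rule, which also
covers genes that merely brush a single segment. Severity ties at |2|
(AMP against HOMD) are broken by the larger overlap, then in favor of
AMP — an arbitrary but deterministic choice, needed for reproducibility.
Coordinates are 0-based half-open in memory; SEG files are read and
written 1-based inclusive. Strand is ignored: copy number is
strand-agnostic.

### 2. Dosage-driven expression (integration)

Per cohort and per gene we compute two statistics:

* Spearman rank correlation ρ between log2 expression and the gene-level
  copy-number log-ratio (missing when fewer than 4 pairs or a constant
  vector — cohorts whose copy number is discrete-only contribute no ρ);
* a one-way equal-variance ANOVA of expression across the discrete
  states (a gene needs at least two states with two samples each),
  Benjamini–Hochberg adjusted within the cohort.

Cohorts are then combined per gene:

* the ρ's by a **DerSimonian–Laird random-effects model** on the Fisher
  z scale with within-study variance 1/(n−3), the moment estimate of
  between-study variance truncated at zero, and the pooled z
  back-transformed to a correlation (`dl_meta_correlation()`);
* the ANOVA p's by **Stouffer's weighted Z**,
  Z = Σ nᵢ zᵢ / √(Σ nᵢ²) with zᵢ = Φ⁻¹(1 − pᵢ)
  (`stouffer_meta()`). The one-sided conversion is appropriate because
  an ANOVA p is already one-sided in F. By default the BH-adjusted
  per-cohort p's are combined — mirroring a workflow that adjusts per
  dataset before meta-analysis — though combining adjusted p-values is
  statistically unconventional, so `use_adjusted = FALSE` switches to
  raw p's and both modes are tested.

`select_candidates()` retains genes with pooled correlation strictly
above 0.6 — on the correlation scale, not the z scale, since a
back-transformed pooled effect is what a correlation cutoff naturally
refers to — or combined p strictly below 10⁻⁵. Genes are meta-analyzed
over whichever cohorts have the statistic, requiring at least two.

### 3. Survival machinery

Kaplan–Meier curves, log-rank tests (k groups, df = k−1) and Cox
proportional-hazards fits are delegated to the `survival` package, with
Efron tie handling (the mainstream default; a `ties` argument exposes
Breslow). The tests include hand-computed product-limit and
observed-versus-expected fixtures and an independently coded
Newton–Raphson Efron partial-likelihood maximizer as oracles.

Sparse multivariate selection uses **component-wise likelihood-based
boosting** (`coxboost_select()`), written in-package: at each step every
candidate gene receives a ridge-penalized one-step Newton update
β ← β + U/(I + λ) of the partial-likelihood score U and information I
against the current linear predictor as offset; only the gene with the
largest penalized gain U²/(I + λ) is updated. The penalty defaults to
9 × (number of events), the convention for this boosting family, and the
number of steps is chosen by event-stratified 10-fold cross-validation
maximizing the Verweij–van Houwelingen validation partial
log-likelihood, scanning up to 200 candidate steps with early stopping
after 20 consecutive non-improving steps. The boosting updates use the
Breslow likelihood internally; simulated event times are continuous, so
ties are absent and Breslow and Efron coincide there.

### 4. Signature construction

`filter_prognostic()` screens each candidate gene univariately: samples
are split into expression tertiles (default; quartiles available — both
conventions appear in practice and the choice is recorded in the model's
provenance), and a gene passes when (i) the per-bin survival curves
spread monotonically, (ii) all probes for the gene pass with the same
direction, and (iii) the k-group log-rank p is below 0.01. "Monotone
spread" is made computable as a strictly monotone ordering of per-bin
restricted mean survival up to the longest follow-up; a visual
impression of curve ordering needs some such proxy, and restricted mean
survival is the standard scalar summary of a curve. The direction is +1
when the highest-expression bin has the worse restricted mean.

The deployable gene set is the **union** of the filter survivors and the
boosting selections (an intersection flag exists for sensitivity
analysis); each gene carries a coefficient of +1 or −1 — the filter
direction where available, otherwise the sign of the boosting
coefficient. The per-sample score on the signature submatrix, first
rescaled per sample so its minimum is 0 and maximum 100 (the rescaling
is applied to the signature genes, which is the submatrix the score
consumes), is

score = (Σ expression of +1 genes)/N − (Σ expression of −1 genes)/N,

i.e. each arm's mean weighted by its share of the N signature genes.
If up to 10% of signature genes are absent from a matrix the score
renormalizes and warns; beyond that it refuses.

`cv_train_classify()` trains the High/Low cutoff: five outcome-
stratified folds; on each training 4/5 the cutoff maximizing
sensitivity + specificity for the deceased label (event flag, optionally
restricted to a follow-up horizon such as 10 years) is found by an
exhaustive scan over midpoints of sorted unique scores, ties broken
toward the smaller cutoff; the held-out fold is classified, so every
sample is labeled exactly once. The deployable cutoff is the median of
the five fold cutoffs — within-CV classification never defines one
cutoff, and the median is the robust summary of the five.

### 5. Evaluation

`evaluate_strata()` reports per-class counts, KM medians, the log-rank
p, a Cox model of class adjusted for clinical covariates (grade, size,
nodal stage — the covariate list is an argument since multivariate
covariate sets vary by study), and the ROC AUC of the continuous score
against the deceased label. `chi_square_enrichment()` is the Pearson
chi-square (no continuity correction) of an annotation against the
strata. `npi()` computes 0.2 × size(cm) + grade + nodal stage with
good (< 3.4) / moderate / poor (> 5.4) bands.
`cluster_expression()` reproduces the expression-clustering recipe:
median-center each gene and divide by its MAD (zero-MAD genes dropped),
1 − Spearman correlation between samples, 1 − Pearson correlation
between genes, average-linkage agglomeration (linkage is configurable;
average is a neutral default).

## The synthetic study and what it does (not) show

`sim_config()` defaults define the study conditions: three cohorts of
30, 125 and 146 tumors whose copy number arrives as absolute copies,
discrete states, and log ratios respectively — the three encoding
dialects a real multi-cohort integration has to reconcile; a toy genome
of 3 chromosomes × 100 Mb carrying 2,000 10-kb genes; recurrent
whole-arm gains and losses plus focal amplifications (6–8 copies,
~10–12% of samples) and a rare focal homozygous deletion, echoing the
recurrent 1q/16p gains, 8p/16q losses and 8p12/11q13 amplifications of
the lobular genome; 40 planted dosage-driven genes inside altered
regions; and a 30-gene prognostic program with hazard ratio 2.5 per
risk SD, censoring targeted at 60%, baseline hazard 0.01/month
(median ≈ 5.8 years for a baseline tumor — a plausible BCSS scale).

Dosage is modeled as integer copies whose deviation from diploid is
scaled by a per-sample purity factor ~ N(1, 0.3): neutral segments stay
exactly diploid while aberrations attenuate or amplify per sample, and
this continuous dosage drives both the measured log-ratio (plus
segment-level noise, SD 0.05) and planted-gene expression (slope 1
log2-unit per copy, residual SD 0.2). Under these settings the planted
within-cohort Spearman ρ averages ≈ 0.78 for gain-arm genes — the
ceiling rank correlation permits given the tied diploid majority — and
≈ 0.7 across all planted genes. Expression baselines are N(8, 1) on the
log2 scale. With `probes_per_gene = 2`, probes share the signal with
independent noise, exercising the multi-probe consistency filter.

The latent risk recorded in the ground truth is the standardized,
sign-corrected mean expression of the planted prognostic genes — by
construction exactly the quantity a signed metagene estimates — and
survival is exponential with hazard `baseline × HR^risk`. Censoring is
uniform on [0, T_max] with T_max solved numerically so the expected
censored fraction matches the target; naive fixed-horizon censoring
would concentrate follow-up early and bias KM tails. Grade and nodal
stage are drawn with mild positive dependence on risk; size is
log-normal.

A fixed study seed reproduces every output bit-identically (R's default
Mersenne–Twister; each cohort × stage derives its own stream from the
study seed, so stages can be re-run in isolation).

What passing on these data does **not** show: the generator has no
allele-specific copy number, no microarray-specific noise spectra or
batch structure, no correlated gene–gene expression beyond the planted
programs, and its censoring is independent of risk. Recovery of planted
structure here validates the machinery, not clinical performance on
real cohorts.

## Numerical choices and degenerate inputs

* Spearman ρ of ±1 is clipped to ±(1 − 10⁻¹²) before the Fisher
  transform; p-values of exactly 0 entering Stouffer are clipped to the
  smallest positive double (with a message) and p = 1 just below 1 so
  all z's stay finite.
* A gene with a constant expression or dosage vector yields a missing
  statistic, never a fabricated p of 1 or 0; single-state genes are
  missing from the ANOVA.
* `rescale_0_100()` refuses a sample whose signature genes are
  constant, naming the sample.
* The boosting CV curve is recorded from 0 steps, so "no model" is a
  legitimate CV optimum.
* Cutoff scans place candidates at midpoints plus one sentinel below
  and above all scores, so "everything High" and "everything Low" are
  scanned too.
* Problem sizes in the test-suite simulations (e.g. 2,000 genes × 3
  cohorts × 20 seeds for selection recovery; 20 end-to-end replicates
  at 300 genes with cohorts sized 125/146, the study's
  discovery/held-out scale) were chosen as the smallest
  scales at which the planted effects are comfortably identifiable, and
  they run on a single CPU in minutes.

## Known limitations

* No GISTIC-style recurrence scoring, purity correction, or
  allele-specific copy number; the pipeline consumes segments as given.
* Stepwise multivariate comparison against external signatures (PAM50
  ROR, OncotypeDx, GGI, MammaPrint, EarlyR) requires those signatures'
  definitions and real cohorts, and is out of scope; only the generic
  signed-score machinery is provided.
* The boosting penalty and step budget follow conventions rather than a
  published value; both are exposed as arguments.
* Combining BH-adjusted p-values in Stouffer's method (the default, to
  mirror the documented workflow) is conservative; the raw-p mode is
  the statistically conventional alternative.
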