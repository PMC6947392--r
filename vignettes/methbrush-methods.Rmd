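---
title: "methbrush: models, simulator, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{methbrush: models, simulator, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`methbrush` is a reference implementation of a prognostic workflow for
patients treated for oral squamous cell carcinoma: brush the regenerated
mucosa, bisulfite-sequence a 13-gene promoter amplicon panel, summarize
243 CpG methylation ratios into a linear-discriminant score with a fixed
positivity cut-off, and relate score positivity to relapse-free
survival. This vignette documents the statistical model behind each
stage, the parameters that matter, what the synthetic-data generator
does and does not emulate, and the numerical decisions taken where the
design was genuinely open.

## 1. The measurement model

Bisulfite treatment converts unmethylated cytosine to uracil (read as
T) while 5-methylcytosine stays C. On a single amplicon read, the base
observed at a CpG's cytosine is therefore a Bernoulli draw: C with
probability $m$ (the methylation level of that CpG in the sampled cell
population) and T otherwise, degraded by two nuisance processes:

* **conversion efficiency** $e \le 1$ — an unmethylated C escapes
  conversion with probability $1 - e$ and reads as a spurious C. At
  $m = 0$ the expected C fraction is exactly $1 - e$ (a tested
  invariant). The simulator default is $e = 0.995$, a typical kit-level
  figure for fresh samples.
* **sequencing error** — uniform per-base substitution, default
  $10^{-3}$ (≈ Q30 chemistry).

The caller estimates $\hat m = \#C / (\#C + \#T)$ per CpG from assigned
reads; bases other than C/T at the CpG (sequencing errors) are excluded
from both numerator and denominator, so $\hat m \cdot (\#C + \#T)$
always reproduces an integer C count.

## 2. Read assignment

Amplicons are short, locus-specific PCR products, so assignment is
ungapped: the read is C→T collapsed and slid over every C→T-converted
amplicon; the minimal-mismatch placement wins. Three choices matter:

* **CpG masking.** Declared CpG positions are excluded from the
  mismatch count. A methylated read differs from the converted
  reference at exactly its methylated CpGs; counting those as
  mismatches would bias assignment against hypermethylated (tumor-like)
  molecules.
* **Orientation.** The reverse complement is tried as well (re-oriented
  to the top strand before collapsing); an orientation or
  cross-amplicon tie at the best score leaves the read unassigned
  rather than guessed.
* **Rejection.** Reads whose best mismatch rate exceeds
  `max_mismatch_rate` (default 0.1) are unassigned. On simulated
  truth-tagged reads the suite asserts 100% accuracy at zero error and
  > 99% at 1% substitution error.

Indels are out of model (no gapped alignment): a declared limitation,
acceptable for fixed-locus amplicons.

## 3. Quality control

"> Q30" is interpreted as *mean* read Phred strictly greater than 30: a
read at uniform Q30 is discarded. Per-base trimming is not attempted;
the mean-read rule is deterministic and matches common FASTQ QC
summaries. The simulator can emit a degraded 3' tail (`degraded_tail`)
to exercise the filter.

The coverage floor `min_coverage = 50` gates ratio reporting. No
coverage floor is inherent to the assay; 50 was chosen once so that the
binomial standard error of a ratio never exceeds
$\sqrt{0.25/50} \approx 0.071$. Raising the floor can only turn ratios
missing, never change a reported value (tested monotonicity).

## 4. The CpG score

Training proceeds in three steps on a labelled (tumor vs healthy)
methylation matrix:

1. **Ranking.** Per-CpG AUC by the rank statistic
   $\mathrm{AUC} = U / (n_1 n_0)$ with average ranks for ties —
   verified against exhaustive pair counting. CpGs with any missing
   training value are dropped. The top `k` (default 20) enter the
   model; the source assay reports only "the best CpGs" without a
   count, so `k` is an explicit configuration parameter.
2. **Discriminant.** $w = S_{\text{pooled}}^{-1}(\mu_1 - \mu_0)$, with
   constant $b = -w^\top(\mu_0 + \mu_1)/2$ so the score is zero at the
   midpoint between class means. When $S$ is singular or
   ill-conditioned (243 CpGs can exceed the sample count) a ridge
   $\lambda I$, $\lambda = 10^{-6}$, is added; `ridge = NULL` turns the
   fallback into a hard error. Identical class means yield an
   all-zero, explicitly flagged model. Two classes only: the published
   assay is described as multiclass, but only two outcome classes are
   exercised here; the model file format carries free-text provenance
   for extensions.
3. **Threshold.** Youden's $J$ maximized over midpoints of adjacent
   sorted unique scores, ties broken toward higher sensitivity, then
   the lower threshold. Positivity is strict: $S > \tau$; a score
   exactly at $\tau$ is negative. The published cut-off
   $\tau = 1.0615547$ ships as `oscc_score_threshold` and is used
   verbatim in `threshold_mode = "fixed"`; a threshold present in a
   model JSON always wins over the default (logged). A freshly trained
   discriminant has its own scale, so the pipeline default is
   `"refit"`.

Missing ratios at scoring time are imputed from the training means
stored in the model file; a sample missing more than half of the model
CpGs is flagged unevaluable instead of being scored. Cohort summary
percentages are truncated (not rounded) to one decimal — the convention
the clinical summaries follow (16/49 → 32.6%).

## 5. Survival machinery

* **Kaplan–Meier**: product-limit $S(t) = \prod_{t_i \le t} (1 -
  d_i/n_i)$; at tied times deaths precede censorings. With no censoring
  it equals the empirical survival function exactly (tested).
* **Log-rank**: two-group $\chi^2 = (\sum (O_1 - E_1))^2 / V$ with the
  hypergeometric variance; its type-I error is checked by simulation
  (1000 null replicates, rejection rate within a binomial CI of 5%).
* **Cox**: Newton–Raphson with step-halving on the Efron-tie partial
  likelihood (monthly follow-up makes ties certain; Efron is the
  least-biased standard choice), convergence at relative log-likelihood
  change $< 10^{-9}$ or 50 iterations, covariates centred for
  stability. Inference is Wald — $\exp(\beta \pm 1.96\,se)$ — matching
  the CI shape clinical reports print. Monotone likelihood (complete
  separation) is detected as $|\beta| > 15$ and reported
  non-estimable rather than as a huge finite hazard ratio.
* **Schoenfeld**: the proportionality check is a score test for adding
  $x \cdot g(t)$ interactions at $\gamma = 0$ with the identity
  transform $g(t) = t$ centred over event times; the statistic
  agrees with `survival::cox.zph(transform = "identity")` on shared
  fixtures and holds its nominal size in simulation.
* **Stepwise selection**: univariate likelihood-ratio screen at
  $p < 0.25$, then forward entry (best $p < 0.05$) interleaved with
  backward elimination ($p > 0.05$), factors entering and leaving as
  blocks with block df, full trace logged, cycle detection. The
  family-wise inflation inherent to stepwise selection is documented,
  not corrected — the procedure reproduces the clinical analysis, it
  does not improve on it.
* **Contingency tables**: Pearson chi-square without Yates correction
  and without a Fisher fallback; expected counts are returned so
  small-cell warnings are the caller's decision. The source tables'
  p-values mix unstated test choices and are not reproduction targets.

## 6. The simulator's stated world

The generator's defaults are the cohort the analysis targets, fixed
once and not tuned to test outcomes:

* 13 amplicons / 243 CpGs, 300 bp each; gene labels *ZAP70 … GP1BB*.
  Sequences are random with the declared CpGs as their *entire* CG
  content, so a string scan is an exact oracle for the coordinates.
* 49 patients; P(score-positive) = 16/49; relapse hazard ratio 15.02
  for positives; censoring uniform on (0, 72] months; baseline hazard
  0.001 events/month, chosen once so the cumulative event fraction is
  ≈ 15% (≈ 7/49). Covariate prevalences follow the published cohort
  table (e.g. 7/49 perineural invasion, 3/49 vascular invasion).
* Class-conditional per-CpG methylation is Beta-distributed: tumor
  informative CpGs Beta(8, 2), healthy Beta(1, 12), background
  Beta(1, 9), an intermediate "regenerative" class Beta(3, 6). The
  source study publishes no per-CpG distributions, so these are
  simulator knobs — realistic shapes for hypermethylated promoter
  panels — not claims about the study's data.
* Only the bisulfite top strand is simulated; CpG states are
  independent across positions and reads (the score uses marginal
  ratios only); no paired ends, indels, PCR duplicates, or non-CpG
  methylation.

Consequently, a green test establishes that the pipeline recovers the
parameters of *this* world (binomial ratio recovery, hazard-ratio
recovery including the HR ≈ 15 regime, test sizes at their nominal 5%)
— not that it reproduces the patient-level results of any particular
study, whose per-patient data are unpublished.

## 7. Reproducibility

Every generator takes an explicit seed and is bit-reproducible; the
pipeline commands write a manifest with parameters and md5 checksums,
and a rerun with the same config is byte-identical. Sub-seeds for
per-sample simulation are derived deterministically from the master
seed and the sample label, and stay below $2^{31}$.

## 8. Known limitations

* Ungapped assignment cannot place reads from indel-bearing templates.
* The LDA assumes shared within-class covariance; heavy class-specific
  correlation structure would favour regularized or quadratic
  alternatives.
* Stepwise selection inherits all the well-known instability of the
  procedure it reproduces.
* The score scale of a refit model is not commensurate with the
  published threshold 1.0615547; fixed-threshold mode is only
  meaningful with the published (unreleased) coefficients or a model
  file built on the same scale.
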