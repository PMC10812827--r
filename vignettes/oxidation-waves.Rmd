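---
title: "Methods: open-search PTM post-processing and oxidation-wave analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: open-search PTM post-processing and oxidation-wave analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem oxwave addresses

Reperfusion after myocardial ischemia triggers bursts of protein oxidation
whose timing carries mechanistic information: an early wave of irreversible
mono-oxidation on Lys/Phe/Asn/Asp immediately after reflow, and a later
wave — hours into reperfusion, coincident with leukocyte infiltration —
combining reversible cysteine oxidation with irreversible mono-, di- and
tri-oxidation of Cys and Trp. Detecting these waves from isobaric (TMT)
time-course proteomics requires three pieces of machinery that `oxwave`
implements as one tested pipeline:

1. **Open-search post-processing.** An open database search matches
   modified peptides to their unmodified sequences with a characteristic
   precursor delta mass (ΔM). The raw PSM table is noisy: it carries a
   systematic mass-calibration error, decoy matches, chemical artifacts,
   and ΔM values that are combinations of modifications. `oxwave`
   recalibrates masses, models the ΔM histogram into peaks, estimates
   target-decoy FDR at three scopes, annotates peaks against a curated
   modification list, and applies a strict curation filter.
2. **Differential-alkylation redox readout.** Free Cys thiols are blocked
   with iodoacetamide during extraction (carbamidomethyl, +57.021464 Da);
   reversibly oxidized Cys are later reduced and alkylated with MMTS
   (methylthio, +45.987721 Da). The tag mass observed in ΔM therefore
   encodes each Cys site's original redox state.
3. **Hierarchical standardized quantification.** Reporter-ion ratios are
   integrated spectrum → peptide → protein → grand mean with weights equal
   to inverse total variance at each level, yielding standardized values:
   Zp (peptide vs its protein), Zq (protein vs grand mean) and Zc
   (functional category). Zp of a modified peptidoform isolates the
   modification's abundance change from its parent protein's.

## The statistical model

For one sample (one reporter channel against its plex reference), each
spectrum contributes $x_s = \log_2(I_s / I_{ref})$. Writing $\sigma^2_S$,
$\sigma^2_P$, $\sigma^2_Q$ for the spectrum, peptide and protein level
variances (log2² units), the integration at each level is a weighted mean

$$x_{parent} = \frac{\sum_i w_i x_i}{\sum_i w_i}, \qquad
  w_i = \frac{1}{\sigma^2_{level} + 1/\pi_i},$$

where $\pi_i$ is the precision the child brings from below (a peptide with
$n$ spectra has $\pi = n/\sigma^2_S$; a protein's precision is the sum of
its peptide weights). Each child's standardized deviation is
$z_i = (x_i - x_{parent})\sqrt{w_i}$; Zp and Zq are these $z$ at the
peptide→protein and protein→grand integrations.

**Level-variance estimation.** $\sigma^2$ at each level is the value at
which the sample variance of the $z_i$ (parent means re-fitted at each
candidate) equals 1 — the property that makes Zp and Zq comparable across
peptides and proteins. The variance of $z$ is computed after winsorizing
at the 1st/99th percentiles and divided by the expected winsorized
variance of a standard normal (≈ 0.964), so the estimator is robust to
outliers yet consistent under normality; without that consistency factor
the level variances are inflated by ~4% and the null variance of Zq drifts
above 1. The equation is solved by bisection ($var(z)$ is monotone
decreasing in $\sigma^2$), floored at 0.

**Two passes.** Level variances and protein values are estimated from
*unmodified* peptides only. Modified peptidoforms are quantified in a
second pass against those frozen protein values and variances, so adding
them cannot move any protein's Zq (bit-for-bit; the package tests assert
`identical()`). Modified peptidoforms whose protein has no unmodified
anchor are excluded and reported.

**Categories.** For a category $c$ with $n$ quantified members,
$Z_c = \sum_{i \in c} Z_{q,i} / \sqrt{n}$, which is N(0,1) when members
are independent standard normal; two-sided normal p-values are BH-adjusted
*within each sample* (i.e., per time point — adjusting across time points
as well would conflate the per-time-point questions the category analysis
asks). Size bounds default to [5, 500]: below 5 the normal approximation
and the biology are both fragile; above 500 a category is too generic to
interpret.

## Open-search post-processing choices

- **Recalibration** estimates a single constant-ppm offset — the minimal
  model for instrument drift — as the median ppm error of a high-quality
  subset: score ≥ 0.15 and ΔM within 20 ppm of the nearest multiple of
  1.003355 Da (the ¹³C isotope spacing). The isotope grid keeps unmodified
  and isotope-error PSMs in the calibration subset while excluding
  genuinely modified populations (oxidation at ~16 Da, alkylation tags at
  ~57/46 Da), which would otherwise bias the offset; a plain integer-Da
  grid would admit the oxidation population at ~5 ppm apparent error.
  Decoys never calibrate. With fewer than 30 qualifying PSMs the step is
  skipped with a warning. The median makes the estimate idempotent and
  robust to residual contamination.
- **Histogram and peaks.** ΔM values are binned into half-open 1 mDa bins
  anchored at multiples of the width. A peak apex is a bin (or the first
  bin of an equal-count plateau over contiguous bins) whose count reaches
  `min_count` and where the slope changes sign; the peak extends outward
  while counts decrease monotonically, and apices are claimed in
  decreasing-count order so extents are disjoint. `min_count` defaults to
  5× the median occupied-bin count, which scales with the uniform noise
  floor of an open search. The reported apex is the count-weighted centre
  of the extent: a plain apex-bin centre can quantize up to 1.5 bins away
  from the true ΔM, while the centroid's error is ~σ/√n.
- **FDR.** Within each scope (global; local = half-open 1-Da bins
  [n − 0.5, n + 0.5), i.e., centred on integers; per peak), PSMs are
  ranked by descending score, FDR at rank k is decoys/targets among the
  top k, monotonized into q-values. Identification uses global q ≤ 0.01.
- **Annotation** matches peak apices to the nearest entry of a curated
  modification list within 10 mDa, ties broken by distance (rounded at
  0.1 µDa so exact ties exist) then name. Artifact and known-combination
  entries are data flags in the list, not code.
- **Truncation check** explains a ΔM as loss or gain of up to 3 terminal
  residues (configurable); deeper losses are indistinguishable from
  unrelated peptides.
- **Curation** keeps a peptidoform iff its peak is annotated with a
  non-zero-mass, non-artifact, non-combination modification, the site
  residue is allowed for that modification, and the form is detected in at
  least 4 biological replicates of at least one group (a form is detected
  in a sample when its plex holds a PSM with positive intensity in that
  sample's channel).

## Redox classification

Each Cys-containing PSM is classified from its ΔM: carbamidomethyl →
reduced; methylthio → reversibly oxidized; neither within 10 mDa →
indeterminate. The tag masses are inputs (the shipped defaults implement
the IAM/MMTS chemistry), so other alkylator pairs are expressible. The two
tags are 11.03 Da apart, so the 10 mDa default tolerance leaves no overlap;
peptides with several Cys in mixed states cannot be resolved from a single
precursor ΔM and come out indeterminate unless site-resolved masses are
provided.

## The synthetic-data generator

The generator (`sim_config()`, `generate_ground_truth()`,
`simulate_psm_table()`) emulates the study design the pipeline assumes:
baseline plus 7 reperfusion time points, n = 4 biological replicates per
group, one 10-plex per replicate with channel 1 a pooled-baseline
reference, channel 2 the baseline sample, channels 3–9 the time points and
channel 10 a pooled QC sample. Injected structure, with defaults:

- **Wave 1** (25% of modified peptides ÷ 2): mono-oxidation on K/F/N/D,
  effect template peaking at t1 with 2.5 Zp units.
- **Wave 2**: mono-/di-/tri-oxidation on C/W, peaking at t5 (the 6 h
  analogue) with 2.5 Zp units. Wave templates are specified in Zp units
  and converted to log2 effects through the expected peptide-level
  standard error of the noise model,
  `sigma_log2 * sqrt(2) / sqrt(spectra_per_peptide)` (≈ 0.15 log2 at the
  defaults), so recovered Zp lands on the template scale.
- **Reversible Cys oxidation** (15% of peptides): baseline oxidized
  fraction 0.15, time course rising with a template peaking at t5; the
  oxidized form carries the methylthio ΔM, the reduced form the
  carbamidomethyl ΔM, with intensities split by the oxidized fraction so
  the two forms are anticorrelated at constant total abundance.
- **Protein abundance effects by category**: an "immune" category rising
  from t3 to +1 log2 at t7 and a "mitochondrial" category falling at the
  last time points, mirroring the leukocyte-infiltration and mitochondrial
  signatures such experiments show.
- **Noise**: lognormal reporter noise (`sigma_log2` = 0.15 per channel),
  per-protein-per-sample biological noise (0.05 log2), Gaussian ppm mass
  error (1 ppm) plus a systematic +8 ppm calibration offset, uniform-ΔM
  decoys (15% of true targets, pseudo-reversed sequences) and an equal
  number of incorrect target matches with the decoy score distribution
  (Gaussian, 1.4 score units below targets) — these "false targets" give
  target-decoy FDR estimates something true to be compared against.
- **Artifacts**: isotope-error populations at ±1.003355·k Da and one
  known modification-combination mass, flagged in the shipped list so the
  curation filter has something to discard.

A 1 ppm random mass error is what recalibrated high-resolution precursor
data typically shows, and it is the regime in which removing a systematic
offset leaves sub-ppm residuals; 1.5 ppm or more would leave the median
per-PSM error above 1 ppm no matter how good the recalibration.

What the generator does **not** emulate: fragment spectra (position
assignment is taken from the search output), chromatographic or batch
drift beyond the plex structure, isotope-impurity cross-talk between
reporter channels, missing channels, shared peptides between proteins, or
alkylation side reactions. Tests passing on this generator therefore show
the statistical machinery is correct under its assumed noise model — not
that the pipeline is robust to every pathology of real data.

## Determinism and the pipeline

`run_pipeline()` executes 12 stages (simulate/load, calibrate, histogram,
peaks, FDR, annotate, curate, redox, quant, categories, waves, enrichment)
from one config; each stage's row counts go into a JSON manifest. One run
seed fans out to per-stage seeds as `(seed*101 + i*7919) mod (2^31 − 1)`.
Identical config and seed reproduce every output table bit-identically
(doubles are serialized with `%.17g`, which round-trips exactly).
Ground-truth sidecar columns (`truth_*`) ride along the simulated PSM
table so recovery can be scored; analysis stages never read them.

## Time-course analysis choices

- Replicate-averaged matrices record per-cell replicate counts; rows with
  an entirely missing time point are dropped.
- HCA uses 1 − Pearson r distance (range [0, 2]) with **average linkage**
  — the distance is prescribed by the workflow, the linkage is not;
  average linkage is the conventional choice for correlation distances and
  is exposed as a parameter. Cluster count defaults to k = 2, mirroring
  the two main oxidation-wave clusters; constant rows are dropped since
  their correlation is undefined.
- Wave-cluster extraction supports the two published profile filters:
  maximum Zp > 0 in at least one time point, and the stricter
  replicate-averaged Zp > 0.5 in at least one time point.
- PCA is column-centred, unscaled (`stats::prcomp`); component signs
  follow the largest-magnitude-loading-positive convention.
- Enrichment uses PSM counts (not peptide counts), hypergeometric upper
  tail including the observed count, and only reports (PTM, residue) pairs
  with more than 50 population PSMs.
- Group tests: Mann–Whitney and Kruskal–Wallis with tie correction; exact
  p by complete enumeration of group assignments for small samples
  (Mann–Whitney up to 10 per group; Kruskal–Wallis up to total n = 8),
  normal/χ² approximations above. With all values identical the H
  statistic is defined as 0 and p = 1.

## Problem sizes used by the tests and acceptance script

The test suite and `scripts/acceptance.R` exercise the pipeline at sizes
chosen to make the asserted statistics meaningful on one CPU in minutes:
FDR control on 20 simulations of ≥ 20,000 PSMs; null calibration on 500
proteins (≥ 16,000 Zq values pooled over samples); category power on
≥ 20-protein categories over 10 seeds; wave recovery on 20 full pipeline
runs of 100 proteins × 6 peptides; uniform-noise peak specificity on
20,000 ΔM values over [−250, 250] Da (the open-search precursor window
scale). The oracle checks (hypergeometric, rank tests, truncation) use
exhaustive enumeration at the sizes where enumeration is feasible.

## Known limitations

- The recalibration model is a single constant-ppm offset; a
  mass-dependent drift would need a spline model the pipeline does not
  implement.
- Local-FDR bins centred on integers are a convention; ΔM populations
  lying exactly at half-integers would straddle two bins.
- The SBT category value falls back to sum/√n of member Zq; a full
  category-level variance estimation (the same fixed point one tier up)
  is only as good as the member count, and the sum/√n form is what the
  package's calibration tests guarantee.
- Multi-Cys peptides in mixed redox states are reported indeterminate.
- Protein inference is taken from the PSM table's protein assignment;
  shared peptides are not re-apportioned.

```{r, eval = FALSE}
# a complete run, for reference
library(oxwave)
res <- run_pipeline(list(
  seed = 1,
  simulation = list(n_proteins = 100, peptides_per_protein = 6,
                    frac_modified = 0.3)
), out_dir = "oxwave_demo")
res$wave_clusters
```
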