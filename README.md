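# oxwave

Open-search PTM post-processing and redox oxidation-wave analysis for
isobaric (TMT) time-course proteomics.

## The scientific problem

Restoring blood flow to ischemic tissue (reperfusion) sets off protein
oxidation whose *timing* matters: an early burst of irreversible
mono-oxidation on Lys/Phe/Asn/Asp right after reflow, and a later wave —
hours into reperfusion, when neutrophils infiltrate the lesion — combining
reversible Cys oxidation with irreversible mono-/di-/tri-oxidation of Cys
and Trp. Resolving these "oxidation waves" from an open-search proteomics
time course requires careful post-processing of the raw peptide-spectrum
matches (PSMs), a chemistry-aware readout of Cys redox state, and a
quantification model that separates a modified peptide's behaviour from
its parent protein's. `oxwave` implements that pipeline for anyone running
unbiased PTM discovery on multiplexed time-course experiments, together
with a ground-truth simulator that makes every stage testable.

## What the package computes

**Delta-mass (ΔM) post-processing.** An open search matches modified
peptides to their unmodified sequence with a characteristic precursor mass
difference. `oxwave` sequentially: recalibrates masses by a constant ppm
offset estimated from high-quality PSMs (score ≥ 0.15, ΔM within 20 ppm of
the nearest isotope-spacing hypothesis); bins ΔM into a 1 mDa histogram;
detects peaks by the frequency and slope of each bin; assigns PSMs to
peaks; computes target-decoy FDR at global, local (1-Da bins) and per-peak
scope (q ≤ 0.01 for identification); annotates peaks against a curated
Unimod-style list; checks for peptide-truncation explanations and correct
site localization; and curates modified peptides — annotated, non-artifact,
non-combination, site-consistent, detected in ≥ 4 biological replicates.

**Differential-alkylation redox calls.** Free Cys thiols are blocked with
iodoacetamide (carbamidomethyl, +57.021464 Da); reversibly oxidized Cys
are later reduced and alkylated with MMTS (methylthio, +45.987721 Da), so
the tag mass in ΔM encodes each Cys peptide's original redox state.

**Standardized quantification (Zp / Zq / Zc).** Reporter log2 ratios are
integrated spectrum → peptide → protein → grand mean with inverse-variance
weights `w = 1/(σ²_level + 1/precision)`; each level variance is set so the
standardized deviations `z = (x − x_parent)·√w` have unit variance. `Zq`
standardizes proteins against the grand mean, `Zp` peptides against their
proteins, and `Zc = ΣZq/√n` functional categories (BH-adjusted per time
point). Level variances and protein values come from unmodified peptides
only; modified peptidoforms are quantified in a second pass against those
frozen values, so they can never move a protein's Zq.

**Wave analysis.** Replicate-averaged Zp time courses of curated modified
peptides are clustered with 1 − Pearson r distance (average linkage,
k = 2); wave clusters are extracted under the published profile filters
(max Zp > 0, or averaged Zp > 0.5); PTM enrichment per cluster uses the
hypergeometric upper tail on PSM counts (> 50 PSMs reported);
Kruskal–Wallis / Mann–Whitney compare groups, with exact permutation
p-values at small n.

## Worked example

```r
library(oxwave)
res <- run_pipeline(list(
  seed = 1,
  simulation = list(n_proteins = 100, peptides_per_protein = 6,
                    frac_modified = 0.3)
), out_dir = "oxwave_demo")

nrow(res$curated)                     # 176 curated modified peptidoforms
res$peaks[order(-psm_count)][1:3, .(apex_deltam, psm_count, mod_name)]
#>      apex_deltam psm_count        mod_name
#> 1: -6.051224e-06      3553      Unmodified
#> 2:  5.702145e+01      1248 Carbamidomethyl
#> 3:  1.599497e+01       944       Oxidation

res$wave_clusters[["1"]]$mean_series  # early wave, peaks at t1
#>  2.63 1.75 0.88 0.31 0.05 -0.02 0.10
res$wave_clusters[["2"]]$mean_series  # late wave, peaks at t5
#> -0.03 0.13 0.47 1.34 2.68 2.38 1.69

head(res$enrichment[p < 0.01], 5)[, .(cluster, ptm, residue, p)]
#>    cluster          ptm residue            p
#> 1:       1    Oxidation       F 5.772151e-69
#> 2:       1    Oxidation       K 5.340687e-50
#> 3:       1    Oxidation       N 2.873657e-49
#> 4:       1    Oxidation       D 1.891011e-47
#> 5:       2 Trioxidation       W 6.629813e-42

which.max(colMeans(res$redox_timecourse$values))  # reversible Cys wave: t5
res$tests                                          # Kruskal-Wallis across times
#>              test                        what statistic             p
#> 1: kruskal_wallis reversible_cys_oxidation_zp  837.2117 1.727155e-176
```

Reading the output: the ΔM histogram resolves the unmodified population,
the two alkylation tags and the oxidation series; the curated modified
peptides split into an early cluster (mean Zp peaking at the first
reperfusion time point, enriched for mono-oxidized K/F/N/D) and a late
cluster (peaking mid-course, enriched for multi-oxidized C/W); the
reversibly oxidized Cys peptides peak at the same late time point, and the
Kruskal–Wallis test confirms their Zp distribution changes across time.
The simulated categories ("immune" rising late, "mitochondrial" falling at
the end) come out significant at BH q < 0.05 in the late samples.

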