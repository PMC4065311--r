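# immunosig

Immunosignature analysis of random-sequence peptide microarrays: selecting
diagnostic and predictive autoantibody signatures of murine lupus and its
CNS behavioral manifestations, and mapping them to candidate protein
antigens.

## The problem

Serum from lupus-prone MRL/lpr mice carries autoantibodies long before (and
throughout) overt disease. Hybridized to an array of 10,000 random 20-mer
peptides (each ending in an invariant `GSC` attachment linker), those
antibodies raise the binding intensity of reproducible peptide subsets.
This package implements the complete analysis that turns per-slide GenePix
(.gpr) intensities into such signatures, for users analyzing their own
arrays or studying the method's statistical behavior:

- **Preprocessing** — per-slide median normalization, log10 transform,
  log-scale averaging of technical replicates, and array QC
  (slide-to-slide CV, replicate Pearson, minimum detectable fold-change).
- **Signature selection** — per-peptide binding ratios
  r_p = mean(case_p) / mean(control_p) on the normalized linear scale,
  kept when r_p > mean + k·SD of a reference distribution
  (k ∈ {0.25, 1.5, 2.5}), with an optional strict subgroup prefilter
  (high floaters > low floaters in the forced swim test) and cross-study
  intersection. Companion per-peptide Welch t-tests with Benjamini–Hochberg
  FDR at 5%.
- **Classification** — leave-one-out cross-validation of a linear SVM on
  the signature peptides, in `asis` (features fixed in advance) and
  `nested` (selection refit per fold) modes.
- **Target mapping** — gapless local alignment of linker-trimmed signature
  peptides against a proteome (BLOSUM62 by default); each peptide's best
  placement deposits its score along the protein, proteins are ranked by
  the maximum of the summed positional profile, and one-sided empirical
  p-values come from re-scoring random same-size peptide draws,
  p = (1 + #{null ≥ observed}) / (n_perm + 1).
- **Synthetic cohorts** — a calibrated generator (log-normal noise
  decomposed so that within-group slide CV = 14%, MDFC(95%) = 1.3-fold and
  replicate Pearson > 0.8) with spiked diagnostic / behavior / predictive
  peptide sets, so the whole pipeline is testable without array data.

The methods vignette (`vignettes/immunosignature-workflow.Rmd`) documents
the models, the threshold-reference ambiguity, the noise calibration, and
the design decisions.

## Worked example

A two-study synthetic cohort at desk scale — 2,000 peptides carrying the
full-scale arrays' spiked fraction (12 diagnostic, 8 behavior, 4 predictive
per 2,000 ≈ 58/39/18 per 10,000), calibrated noise:

```r
library(immunosig)
cfg <- demo_config(n_peptides = 2000, noise = "default", seed = 1,
                   effects = list(n_diagnostic = 12, n_behavior = 8,
                                  n_predictive = 4, fold_min = 2.5))
res <- run_pipeline(cfg, out_dir = tempfile())
print(res$qc)
for (s in c("diagnostic", "behavior", "predictive")) print(res$sets[[s]])
print(res$cv$diagnostic)
```

```
<qc_report> slide CV 12.8% | min replicate Pearson 0.978 | MDFC(95%) 1.30-fold
<peptide_set> 'diagnostic': 12 peptides
<peptide_set> 'behavior': 10 peptides
<peptide_set> 'predictive': 91 peptides
<cv_result> 0/13 misclassified (error rate 0.0%)
```

The QC report shows the generator reproducing the arrays' published noise
statistics. The intersected diagnostic signature contains exactly the 12
spiked diagnostic peptides (each member carries its two studies' binding
ratios); the behavior set holds the 8 behavior spikes plus two diagnostic
peptides that passed the coin-flip high>low prefilter — a property of the
selection rule itself. The permissive k = 0.25 predictive screen admits
many null peptides under exchangeable noise (91 selected for 4 spiked),
which is why it is a screen and not a verdict; see the vignette. LOOCV of
the diagnostic contrast classifies all 13 mice correctly.

```r
head(res$sets$diagnostic$members, 3)
#> # A tibble: 3 × 4
#>   peptide_id sequence             ratio_study1 ratio_study2
#> 1 pep00267   TYIPFPMDLEMLNHDPWGSC         2.44         2.86
#> 2 pep00340   YGKHKFADHYRVFMDEDGSC         8.25         9.26
#> 3 pep00405   VFQWRHEPVQEAKFPQEGSC         2.38         2.65
```

The numbered scripts under `analysis/` run the same workflow at full scale
(10,000 peptides): `01_simulate_cohorts.R` (cohort + QC),
`02_select_signatures.R` (selection + recovery report),
`03_crossvalidate.R` (asis vs nested LOOCV and a permuted-label control),
`04_map_targets.R` (target mapping against a synthetic proteome with a
planted antigen), `05_null_calibration.R` (negative controls). Each writes
its tables under `results/`.

Three published reference signatures ship with the package
(`load_reference_signature()`): the 58-peptide diagnostic-lupus, 39-peptide
diagnostic-behavior and 18-peptide predictive-lupus sets, with per-study
binding ratios and cross-membership flags
(see `inst/extdata/signatures/NOTES.md`).

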