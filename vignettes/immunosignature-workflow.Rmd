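---
title: "Immunosignature analysis: models, calibration and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Immunosignature analysis: models, calibration and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem and the method

Immunosignaturing profiles the serum antibody repertoire by hybridizing
diluted serum to a microarray of random-sequence peptides (here: 10,000
20-mers whose last three residues are an invariant `GSC` attachment linker).
Disease-associated autoantibodies raise the binding intensity of subsets of
peptides, and those subsets — *signatures* — can be mined for diagnosis, for
presymptomatic prediction, and for hints at the natural protein antigens.

The workflow implemented by **immunosig** covers the murine lupus setting:
MRL/lpr mice (lupus-prone, symptomatic after ~2 months), MRL/mp (genetic
control, late-onset disease) and C3H/HeJ (non-autoimmune control), with an
additional CNS phenotype — high vs low immobility ("floaters") in the forced
swim test — splitting the MRL/lpr group. Two independent cohorts ("studies")
are analyzed identically and their signatures intersected, because a
signature worth keeping should reappear.

The pipeline stages are:

1. **Array I/O** — single-channel GenePix Results (GPR) files, one per
   slide, keyed to a peptide library by peptide id.
2. **Preprocessing** — each slide is divided by its own median (making
   slides comparable), log10-transformed, and technical replicates are
   averaged on the log scale (a geometric mean on the linear scale).
3. **Selection** — per peptide, the *binding ratio* mean(case)/mean(control)
   on the normalized linear scale; a peptide is kept when its ratio strictly
   exceeds a cutoff `mean + k*SD` of a reference distribution. Behavioral
   contrasts add a prefilter: the high-floater group mean must strictly
   exceed the low-floater mean. Signatures from the two studies are
   intersected by peptide id.
4. **Differential binding** — per-peptide two-sample t-tests (Welch) on the
   log10 scale with Benjamini–Hochberg correction at 5% FDR, as the
   conventional companion analysis.
5. **Classification** — leave-one-out cross-validation of a linear SVM
   (cost 1) restricted to the signature peptides.
6. **Target mapping** — each signature peptide (linker trimmed) is aligned
   gaplessly to every protein of a proteome under BLOSUM62; the best
   placement deposits its score on the positions it covers; proteins are
   ranked by the maximum of the summed positional profile; significance
   comes from re-scoring random peptide sets of the same size.

## The threshold rule and its reference distribution

The selection statistic is the `mean + k*SD` cutoff with `k` = 0.25
(presymptomatic MRL/mp, a deliberately permissive screen), 1.5 (the standard
diagnostic setting) or 2.5 (the most conservative, behavior prediction).
The reference distribution the mean and SD are taken from is genuinely
ambiguous in the source material, so `compute_threshold()` implements three
readings:

- `control_intensity_distribution` (the package default): mean + k·SD of the
  control group's per-peptide mean intensities across peptides. This is the
  most literal reading, but it compares a *ratio* against an
  *intensity*-scale cutoff, and its value depends strongly on the spread of
  per-peptide baseline affinities.
- `ratio_distribution` (used by the demo pipeline): mean + k·SD of the
  binding-ratio vector itself. This is the dimensionally coherent reading —
  ratio against ratio-scale cutoff — and the only one under which a spiked
  synthetic cohort is recovered exactly; the published Study-1 ratio minimum
  (≈2.32) is also consistent with it.
- `per_peptide_control`: a per-peptide cutoff `(mu_p + k*sigma_p)/mu_p` from
  that peptide's own control-slide statistics.

Exceedance is strict (`>`), matching the "greater than" phrasing; at an
SD-0 reference nothing is selected.

## The synthetic cohort generator

Deposited arrays are not shipped with the package, so every stage is
exercised on synthetic cohorts with the published noise structure. On the
log10 scale an intensity is

```
log10 I = baseline(peptide) + log10 fold(peptide, group)
        + mouse(peptide, serum) + brightness(slide) + noise(peptide, slide)
```

- **Baseline**: per-peptide log10 mean ~ N(3, 0.4) — a 1000-unit typical
  intensity with ~2.5-fold spread between peptides, the affinity
  heterogeneity that makes ratio statistics nontrivial. Drawn once per
  library and shared across groups.
- **Fold effects**: log-normal with median 2.5, truncated below at 1.
  Diagnostic peptides are elevated in all 4-month MRL/lpr; behavior peptides
  (by default a subset of the diagnostic set — CNS-subgroup autoantibodies
  are also lupus autoantibodies) additionally in high floaters; predictive
  peptides in the presymptomatic groups (4-month MRL/mp, 1.5-month MRL/lpr)
  with the effect halved on the log scale, reflecting the lower
  presymptomatic autoantibody concentrations. Effects in 1.5-month future
  high floaters are attenuated the same way. Default set sizes 58/39/18
  match the cross-study signature sizes the workflow reproduces.
- **Noise**: all components log-normal. The three dispersions are calibrated
  in closed form to the three published array statistics, *before* any test
  was run:
  - replicate noise `sigma_rep` solves
    `1.96 * sqrt(2) * sigma_rep = ln(1.3)`, so the 95th percentile of
    between-replicate fold changes (the minimum detectable fold-change,
    MDFC) is 1.3;
  - mouse-level biological noise `sigma_mouse` solves
    `sigma_mouse^2 + sigma_rep^2 = ln(1 + 0.14^2)`, so the total
    within-group slide-to-slide coefficient of variation is 14%. A single
    noise scale cannot produce a 14% CV *and* a 1.3-fold MDFC (14%
    replicate noise alone implies MDFC ≈ 1.47), which is why the model
    needs this two-component decomposition;
  - a per-slide brightness factor (log10 SD 0.1) that median normalization
    must remove.

  With these defaults the generated cohorts show a slide CV near 13%
  (slightly under 14% because group-level SDs are estimated from few mice),
  replicate Pearson ≈ 0.98, and MDFC(95%) = 1.30, as
  `analysis/01_simulate_cohorts.R` verifies.
- **Design**: Study 1 has five 4-month MRL/lpr (3 high / 2 low floaters)
  and four mice in each control strain (the source material gives an
  internally inconsistent 3–6 per group, so the floater split was taken as
  authoritative); Study 2 has nine MRL/lpr (6 high / 3 low by their
  *4-month* forced-swim outcome, so presymptomatic samples carry their
  future label) and ten MRL/mp, each sampled at 1.5 and 4 months. Study 2
  reuses Study 1's 4-month C3H/HeJ mice as the ratio denominator, as the
  original analysis did. Triplicate technical slides throughout. Generation
  is a pure function of (library, design, effects, noise, seed).

### What the generator does and does not emulate

It reproduces the published noise magnitudes, the replication structure, the
group layout and spiked group effects. It does **not** model epitope-driven
cross-reactivity between peptides, heavy-tailed peptide-level ratio
dispersion of real sera, or pooling of sera. Consequences worth knowing:

- Passing recovery tests show the *procedure* is implemented correctly, not
  that real arrays would yield the same set sizes. In particular the
  permissive `k = 0.25` screen admits ~35–40% of null peptides under pure
  exchangeable noise (the published 143/10,000 count at that cutoff reflects
  real-data ratio dispersion that pure noise understates), and because both
  studies share the same control denominator, false exceedances are
  correlated between studies and intersection removes fewer of them than
  independence would suggest. `analysis/02_select_signatures.R` reports this
  honestly for the predictive contrast.
- Diagnostic-only peptides pass the behavioral high > low prefilter with
  probability ~1/2 under noise, so a few leak into the behavior signature —
  a property of the selection rule itself, visible in the published tables'
  heavy overlap.

## Numerical and procedural choices

- Scale transitions are one-way (`raw -> median_normalized -> log10`) and
  enforced; transforms return new objects. Nonpositive intensities abort
  normalization with a pointer to flooring rather than being silently
  floored.
- Ratios are computed on the median-normalized *linear* scale from per-mouse
  geometric means (replicates averaged on the log scale); t-tests and the
  SVM operate on the log10 scale. Group means weight each mouse equally even
  under unbalanced replication.
- QC statistics: slide CV is the mean per-peptide CV across slides of the
  same biological group; replicate Pearson is the per-serum minimum pairwise
  correlation; MDFC is the 95th percentile of pairwise max/min between-
  replicate fold changes. All are invariant to peptide and slide order.
- Alignment ties break toward the smallest protein offset; each peptide
  deposits only its single best placement per protein. The `GSC` linker is
  trimmed before alignment by default (chemistry, not epitope);
  `linker = ""` disables trimming. The protein summary is the maximum of
  the positional profile; `summary = "sum"` gives the simpler
  sum-of-best-scores reading.
- Permutation p-values use the add-one estimator
  `(1 + #{null >= observed}) / (n_perm + 1)`, so p > 0 always; draws are
  without replacement from the whole library and deterministic per seed.
  P-values of different proteins under one test set share the null draws
  and are therefore dependent — calibration checks pool across independent
  test draws.
- LOOCV offers `asis` mode (features fixed in advance, replicating the
  original procedure and inheriting its selection bias — the reported <3%
  error bound is of this kind) and `nested` mode (selection refit inside
  each training fold, unbiased). Fold standardization is always computed on
  the training fold only.
- BH significance is `q <= alpha` (inclusive), the standard step-up
  convention; `stats::p.adjust` is the implementation and a hand-rolled
  step-up serves as the independent oracle in the tests.

## Problem sizes used by the tests

The test-suite and acceptance script run at desk scale, chosen so each
property is measured with adequate power: oracle equivalence on 1,000
random peptide/protein pairs up to length 50; recovery on two-study cohorts
of 2,000 peptides with the spiked *fraction* of the full-scale arrays
(12/8/4 per 2,000 ≈ 58/39/18 per 10,000) and spiked folds ≥ 2.5 over 20
seeds; null FDR over 150 simulated 1,000-peptide cohorts; p-value
uniformity from 10 independent 20-peptide draws against a 100-protein
synthetic proteome at 200 permutations; QC on the full-scale 10,000-peptide
default cohort; chance-level classification over 50 label permutations of
40 mice. The analysis scripts under `analysis/` run the full-scale
(10,000-peptide) workflow.

## Known limitations

- The three threshold references can disagree substantially; conclusions
  drawn at `k = 0.25` are screen-grade under any of them.
- The `asis` LOOCV error is optimistically biased whenever features were
  selected on the full data; use `nested` for an honest estimate.
- Published candidate-target lists depend on the specific proteome release
  used originally, which is not versioned; the mapping stage is therefore
  validated on synthetic proteomes with planted targets
  (`analysis/04_map_targets.R`) rather than against those lists.
- ELISA S-values (`s_value()`, odd-well minus even-well OD, positive above
  0.1) are included as the workflow's companion assay statistic; the wet
  protocol surrounding them is out of scope.
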