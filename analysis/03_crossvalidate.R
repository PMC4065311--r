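#!/usr/bin/env Rscript
# Leave-one-out cross-validation of the diagnostic contrast with a linear
# SVM, in both modes: `asis` (features fixed in advance, as the original
# procedure did - optimistically biased) and `nested` (threshold selection
# refit inside every training fold - unbiased), plus a label-permutation
# control that must classify at chance.

library(immunosig)
dir.create("results", showWarnings = FALSE)

cfg <- demo_config(n_peptides = 10000, noise = "default", seed = 1)
cfg$qc <- FALSE
res <- run_pipeline(cfg)
avg <- res$matrix
feats <- res$sets$diagnostic

cols <- sample_filter(avg$samples, list(study = 2, strain = "MRL/lpr",
                                        age_months = 4)) |
  sample_filter(avg$samples, list(study = 1, strain = "C3H/HeJ"))
sub <- intensity_matrix(avg$values[, cols, drop = FALSE], avg$peptides,
                        avg$samples[cols, , drop = FALSE], avg$scale)
labels <- ifelse(sub$samples$strain == "MRL/lpr", "case", "control")

cv_asis <- loocv(sub, labels, feats, mode = "asis")
cat(sprintf("asis LOOCV (features fixed in advance): %d/%d errors (%.1f%%)\n",
            cv_asis$n_errors, cv_asis$n_samples, 100 * cv_asis$error_rate))

# nested: re-select by ratio threshold within each training fold
selector <- function(train_m, train_labels) {
  mn <- pow10_transform(train_m)
  ct <- contrast_spec(list(strain = "MRL/lpr"), list(strain = "C3H/HeJ"))
  r <- binding_ratio(mn, ct)
  rule <- compute_threshold(mn, ct, r, threshold_rule(1.5, "ratio_distribution"))
  ids <- select_signature(r, rule, mn$peptides)$members$peptide_id
  if (length(ids) == 0) mn$peptides$peptide_id[order(-r)[1:5]] else ids
}
cv_nested <- loocv(sub, labels, features = NULL, mode = "nested",
                   selector = selector)
cat(sprintf("nested LOOCV (selection inside folds): %d/%d errors (%.1f%%)\n",
            cv_nested$n_errors, cv_nested$n_samples,
            100 * cv_nested$error_rate))

set.seed(2)
cv_perm <- loocv(sub, sample(labels), feats)
cat(sprintf("label-permuted control: %d/%d errors (%.1f%%; chance is 50%%)\n",
            cv_perm$n_errors, cv_perm$n_samples, 100 * cv_perm$error_rate))

write_cv_result(cv_asis, "results/03_cv_asis.tsv")
write_cv_result(cv_nested, "results/03_cv_nested.tsv")
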