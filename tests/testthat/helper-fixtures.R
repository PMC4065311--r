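# shared builders and independent oracles for the test suite

tiny_library <- function(n = 4, seqs = NULL) {
  if (is.null(seqs)) {
    seqs <- vapply(seq_len(n), function(i) {
      paste0(paste(rep(LETTERS[c(1, 4, 5, 7)][(i %% 4) + 1], 17),
                   collapse = ""), "GSC")
    }, character(1))
  }
  peptide_library(tibble::tibble(
    peptide_id = paste0("p", seq_along(seqs)),
    sequence = seqs,
    block = 1L, row = seq_along(seqs), column = 1L))
}

# matrix with hand-set values and minimal metadata; cols named mouse/replicate
manual_matrix <- function(values, mice, replicates = NULL, strain = "MRL/lpr",
                          age = 4, study = 1L, phenotype = NA_character_,
                          scale = "raw", library = NULL) {
  values <- as.matrix(values)
  n_col <- ncol(values)
  if (is.null(replicates)) replicates <- rep(1L, n_col)
  if (length(strain) == 1) strain <- rep(strain, n_col)
  if (length(age) == 1) age <- rep(age, n_col)
  if (length(phenotype) == 1) phenotype <- rep(phenotype, n_col)
  if (length(study) == 1) study <- rep(study, n_col)
  if (is.null(library)) {
    library <- peptide_library(tibble::tibble(
      peptide_id = paste0("p", seq_len(nrow(values))),
      sequence = paste0(strrep("A", 17), "GSC"),
      block = 1L, row = seq_len(nrow(values)), column = 1L))
  }
  samples <- tibble::tibble(
    sample_id = paste0(mice, "_r", replicates, "_s", study, "_a", age),
    mouse_id = mice, strain = strain, age_months = age,
    phenotype = phenotype, replicate = as.integer(replicates),
    study = as.integer(study))
  intensity_matrix(values, library, samples, scale = scale)
}

random_aa_string <- function(len, alphabet = setdiff(immunosig:::AA20, "C")) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# --- independent oracles ----------------------------------------------------

# Benjamini-Hochberg step-up, written from the definition
bh_stepup_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- p[ord] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[ord] <- pmin(q_sorted, 1)
  q
}

# exhaustive-offset gapless alignment, pure R
brute_align_oracle <- function(pep, prot, smat) {
  pc <- strsplit(pep, "")[[1]]
  qc <- strsplit(prot, "")[[1]]
  n_off <- length(qc) - length(pc) + 1
  scores <- vapply(seq_len(n_off), function(o) {
    sum(smat[cbind(pc, qc[o + seq_along(pc) - 1])])
  }, numeric(1))
  best <- which.max(scores)
  list(offset = best - 1L, score = scores[best])
}

# positional-profile proteome scoring, written independently of the package
brute_profile_oracle <- function(pep_seqs, prot, smat, linker = "GSC") {
  profile <- numeric(nchar(prot))
  for (pep in pep_seqs) {
    pep <- trim_linker(pep, linker)
    al <- brute_align_oracle(pep, prot, smat)
    span <- al$offset + seq_len(nchar(pep))
    profile[span] <- profile[span] + al$score
  }
  profile
}

make_toy_proteome <- function(n = 10, len_range = c(60, 120), seed = 1) {
  withr::with_seed(seed, {
    tibble::tibble(
      protein_id = sprintf("prot%03d", seq_len(n)),
      description = "",
      sequence = vapply(seq_len(n), function(i) {
        random_aa_string(sample(seq(len_range[1], len_range[2]), 1),
                         alphabet = immunosig:::AA20)
      }, character(1)),
      has_ambiguous = FALSE)
  })
}

# log10-scale matrix of two Gaussian classes over `n_feat` peptides
two_class_matrix <- function(n_mice, n_feat = 10, sep = 0, sd = 0.1,
                             seed = 1) {
  withr::with_seed(seed, {
    half <- n_mice / 2
    shift <- matrix(rep(c(0, sep), times = c(half, n_mice - half) * n_feat),
                    nrow = n_feat)
    vals <- matrix(rnorm(n_feat * n_mice, 0, sd), nrow = n_feat) + shift
  })
  m <- manual_matrix(vals, mice = paste0("m", seq_len(n_mice)),
                     scale = "log10")
  list(m = m, labels = rep(c("ctrl", "case"), times = c(half, n_mice - half)))
}

# recovery-style config: library scaled down with the spike fraction of the
# modeled arrays (58/39/18 per 10000) and spiked folds >= 2.5
recovery_config <- function(seed, n_peptides = 2000, noise = "default") {
  demo_config(n_peptides = n_peptides, noise = noise, seed = seed,
              effects = list(n_diagnostic = 12, n_behavior = 8,
                             n_predictive = 4, fold_min = 2.5))
}
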