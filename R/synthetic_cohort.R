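#' Generate a random-sequence peptide library
#'
#' Sequences consist of a variable region drawn uniformly from the 19-letter
#' alphabet excluding cysteine (cysteine is reserved for the attachment
#' linker), followed by the invariant C-terminal linker (default `"GSC"`).
#' Array coordinates are laid out on a 1-based GenePix-style grid.
#'
#' @param n Number of peptides (default 10000, the array format modeled here).
#' @param length Total peptide length including linker (default 20).
#' @param linker C-terminal linker appended to every sequence.
#' @param alphabet Residues for the variable region.
#' @param seed Integer seed; the library is a pure function of the arguments.
#' @return A [peptide_library()].
#' @export
generate_library <- function(n = 10000, length = 20, linker = "GSC",
                             alphabet = setdiff(AA20, "C"), seed = 1) {
  if (n < 1) abort("n must be >= 1")
  if (length(alphabet) == 0) abort("variable-region alphabet is empty")
  var_len <- length - nchar(linker)
  if (var_len <= 0) abort("peptide length must exceed the linker length")
  withr::with_seed(seed, {
    letters_mat <- matrix(sample(alphabet, n * var_len, replace = TRUE),
                          nrow = n)
    seqs <- paste0(apply(letters_mat, 1, paste, collapse = ""), linker)
  })
  per_block <- 400L  # 20 x 20 spots per block
  idx <- seq_len(n) - 1L
  peptide_library(tibble(
    peptide_id = sprintf("pep%05d", seq_len(n)),
    sequence = seqs,
    block = idx %/% per_block + 1L,
    row = (idx %% per_block) %/% 20L + 1L,
    column = idx %% 20L + 1L
  ), linker = linker)
}

#' Cohort design: groups of mice and technical replication
#'
#' @param groups Tibble with columns `study`, `strain`, `age_months`,
#'   `phenotype` (`"high_floater"`, `"low_floater"` or `NA`) and `n_mice`.
#'   For MRL/lpr mice the phenotype column is the forced-swim outcome at 4
#'   months, so presymptomatic 1.5-month samples carry their *future*
#'   phenotype label; groups of the same study/strain/phenotype at different
#'   ages refer to the same mice.
#' @param replicates_per_mouse Technical replicates (slides) per serum sample.
#' @return List of class `cohort_design`.
#' @export
cohort_design <- function(groups, replicates_per_mouse = 3) {
  groups <- as_tibble(groups)
  required <- c("study", "strain", "age_months", "phenotype", "n_mice")
  missing <- setdiff(required, names(groups))
  if (length(missing) > 0) {
    abort(paste0("design lacks column(s): ", paste(missing, collapse = ", ")))
  }
  if (any(groups$n_mice < 1)) abort("every group needs n_mice >= 1")
  if (replicates_per_mouse < 1) abort("replicates_per_mouse must be >= 1")
  structure(list(groups = groups, replicates_per_mouse = replicates_per_mouse),
            class = "cohort_design")
}

#' Default two-study cohort design
#'
#' Study 1: 4-month MRL/lpr (3 high / 2 low floaters), MRL/mp and C3H/HeJ
#' controls. Study 2: 9 MRL/lpr (6 high / 3 low floaters by their 4-month
#' forced-swim outcome) and 10 MRL/mp, each sampled at 1.5 and 4 months.
#' Triplicate technical replicates throughout.
#'
#' @param studies Which studies to include (subset of `c(1, 2)`).
#' @inheritParams cohort_design
#' @export
default_design <- function(studies = c(1, 2), replicates_per_mouse = 3) {
  g1 <- tibble(study = 1L,
               strain = c("MRL/lpr", "MRL/lpr", "MRL/mp", "C3H/HeJ"),
               age_months = 4,
               phenotype = c("high_floater", "low_floater", NA, NA),
               n_mice = c(3L, 2L, 4L, 4L))
  g2 <- tibble(study = 2L,
               strain = rep(c("MRL/lpr", "MRL/lpr", "MRL/mp"), times = 2),
               age_months = rep(c(1.5, 4), each = 3),
               phenotype = rep(c("high_floater", "low_floater", NA), times = 2),
               n_mice = rep(c(6L, 3L, 10L), times = 2))
  groups <- dplyr::bind_rows(list(`1` = g1, `2` = g2)[as.character(studies)])
  cohort_design(groups, replicates_per_mouse)
}

#' Spike-in effect model
#'
#' Draws the per-peptide baseline (log10 mean intensity) and three spiked
#' peptide sets: `diagnostic` peptides elevated in all 4-month MRL/lpr mice,
#' `behavior` peptides additionally elevated in high floaters (by default a
#' subset of the diagnostic set: CNS-subgroup autoantibodies are also lupus
#' autoantibodies), and `predictive` peptides elevated, with an attenuated
#' effect, in presymptomatic lupus-prone groups (4-month MRL/mp and 1.5-month
#' MRL/lpr). Behavior effects in 1.5-month future high floaters are likewise
#' attenuated. Fold effects are log-normal with the given median, truncated
#' below at `fold_min` (and never below 1).
#'
#' @param library [peptide_library()] the spikes are drawn from.
#' @param n_diagnostic,n_behavior,n_predictive Spiked set sizes (defaults
#'   58/39/18, the cross-study signature sizes the workflow reproduces).
#' @param fold_median Median fold effect (default 2.5).
#' @param fold_sdlog10 SD of log10 fold effects.
#' @param fold_min Lower truncation for fold effects.
#' @param attenuation Presymptomatic effects are `fold^attenuation`
#'   (default 0.5: half the effect on the log scale).
#' @param behavior_within_diagnostic Draw the behavior set from the
#'   diagnostic set (default TRUE).
#' @param baseline_mean,baseline_sd Per-peptide log10 baseline distribution.
#' @param seed Integer seed; assignments are reproducible from it.
#' @return List of class `effect_model`.
#' @export
effect_model <- function(library, n_diagnostic = 58, n_behavior = 39,
                         n_predictive = 18, fold_median = 2.5,
                         fold_sdlog10 = 0.1, fold_min = 1, attenuation = 0.5,
                         behavior_within_diagnostic = TRUE,
                         baseline_mean = 3, baseline_sd = 0.4, seed = 1) {
  n <- nrow(library)
  if (n_diagnostic + n_behavior + n_predictive > 0 &&
      max(n_diagnostic, n_behavior, n_predictive) > n) {
    abort("spiked set sizes exceed the library size")
  }
  if (behavior_within_diagnostic && n_behavior > n_diagnostic) {
    abort("behavior set cannot exceed the diagnostic set it is drawn from")
  }
  draw_fold <- function(k) {
    pmax(10^rnorm(k, log10(fold_median), fold_sdlog10), max(fold_min, 1))
  }
  withr::with_seed(seed, {
    baseline <- rnorm(n, baseline_mean, baseline_sd)
    diag_ids <- sample(library$peptide_id, n_diagnostic)
    behav_pool <- if (behavior_within_diagnostic) diag_ids else library$peptide_id
    behav_ids <- sample(behav_pool, n_behavior)
    pred_ids <- sample(library$peptide_id, n_predictive)
    diagnostic <- tibble(peptide_id = diag_ids, fold = draw_fold(n_diagnostic))
    behavior <- tibble(peptide_id = behav_ids, fold = draw_fold(n_behavior))
    predictive <- tibble(peptide_id = pred_ids,
                         fold = draw_fold(n_predictive)^attenuation)
  })
  structure(list(baseline = tibble(peptide_id = library$peptide_id,
                                   log10_mean = baseline),
                 diagnostic = diagnostic, behavior = behavior,
                 predictive = predictive, attenuation = attenuation,
                 seed = seed),
            class = "effect_model")
}

#' Ground-truth table of spiked peptides
#'
#' @param effects An [effect_model()].
#' @return Tibble `(peptide_id, role, fold)`, one row per spiked
#'   (peptide, role); empty when nothing is spiked.
#' @export
spike_truth <- function(effects) {
  parts <- lapply(c("diagnostic", "behavior", "predictive"), function(role) {
    tab <- effects[[role]]
    if (nrow(tab) == 0) return(NULL)
    tibble(peptide_id = tab$peptide_id, role = role, fold = tab$fold)
  })
  out <- dplyr::bind_rows(parts)
  if (nrow(out) == 0) tibble(peptide_id = character(), role = character(),
                             fold = numeric()) else out
}

#' Multiplicative noise model
#'
#' All noise is log-normal on linear intensities. The model has three
#' dispersion components, calibrated so the generated cohorts reproduce the
#' arrays' published quality statistics:
#' \itemize{
#'   \item `replicate_log_sd` - per (peptide, slide) technical noise, in
#'     log10 units. The default solves
#'     `1.96 * sqrt(2) * sigma_ln = ln(mdfc_95)` so the 95th percentile of
#'     between-replicate fold changes is `mdfc_95` (default 1.3).
#'   \item `mouse_log_sd` - per (peptide, mouse) biological variation, in
#'     log10 units. The default takes the total within-group slide-to-slide
#'     coefficient of variation to `slide_cv` (default 14%):
#'     `sigma_mouse_ln = sqrt(ln(1 + slide_cv^2) - sigma_rep_ln^2)`.
#'   \item `scale_log_sd` - per-slide global brightness factor, removed by
#'     median normalization.
#' }
#'
#' @param slide_cv Target within-group slide-to-slide CV (fraction).
#' @param mdfc_95 Target minimum detectable fold-change at the 95th
#'   percentile, used to calibrate the default `replicate_log_sd`.
#' @param replicate_log_sd,mouse_log_sd,scale_log_sd Log10 SDs; `NULL`
#'   requests the calibrated default.
#' @param seed Integer seed for cohort generation.
#' @return List of class `noise_model`.
#' @export
noise_model <- function(slide_cv = 0.14, mdfc_95 = 1.3,
                        replicate_log_sd = NULL, mouse_log_sd = NULL,
                        scale_log_sd = 0.1, seed = 1) {
  if (is.null(replicate_log_sd)) {
    replicate_log_sd <- log(mdfc_95) / (qnorm(0.975) * sqrt(2)) / log(10)
  }
  if (is.null(mouse_log_sd)) {
    rep_ln <- replicate_log_sd * log(10)
    total_ln_var <- log(1 + slide_cv^2)
    if (total_ln_var < rep_ln^2) {
      abort("slide_cv too small for the given replicate_log_sd")
    }
    mouse_log_sd <- sqrt(total_ln_var - rep_ln^2) / log(10)
  }
  if (any(c(replicate_log_sd, mouse_log_sd, scale_log_sd) < 0)) {
    abort("dispersion parameters must be >= 0")
  }
  structure(list(slide_cv = slide_cv, mdfc_95 = mdfc_95,
                 replicate_log_sd = replicate_log_sd,
                 mouse_log_sd = mouse_log_sd, scale_log_sd = scale_log_sd,
                 seed = seed),
            class = "noise_model")
}

#' Zero-noise model (degenerate, for exact-recovery checks)
#' @param seed Integer seed (unused by the degenerate model but recorded).
#' @export
noise_free <- function(seed = 1) {
  noise_model(replicate_log_sd = 0, mouse_log_sd = 0, scale_log_sd = 0,
              seed = seed)
}

#' Generate a synthetic intensity cohort
#'
#' One column (slide) per (mouse, replicate). On the log10 scale each value
#' is `baseline + group fold effect + mouse effect + slide brightness +
#' replicate noise`; the returned matrix is linear (`scale = "raw"`).
#' Generation is a pure function of `(library, design, effects, noise)`.
#'
#' @param library [peptide_library()].
#' @param design [cohort_design()].
#' @param effects [effect_model()]; spiked ids must be in the library.
#' @param noise [noise_model()].
#' @return Raw-scale [intensity_matrix()].
#' @export
generate_cohort <- function(library, design, effects, noise) {
  unknown <- setdiff(spike_truth(effects)$peptide_id, library$peptide_id)
  if (length(unknown) > 0) {
    abort(sprintf("effect model spikes unknown peptide id(s): %s",
                  paste(head(unknown, 3), collapse = ", ")))
  }
  if (!identical(effects$baseline$peptide_id, library$peptide_id)) {
    abort("effect model was built for a different peptide library")
  }
  strain_code <- c("MRL/lpr" = "lpr", "MRL/mp" = "mp", "C3H/HeJ" = "c3h")
  g <- design$groups
  samples <- dplyr::bind_rows(lapply(seq_len(nrow(g)), function(i) {
    ph <- g$phenotype[i]
    ph_code <- if (is.na(ph)) "na" else sub("_floater", "", ph)
    mice <- sprintf("s%d_%s_%s_m%02d", g$study[i], strain_code[[g$strain[i]]],
                    ph_code, seq_len(g$n_mice[i]))
    tibble(mouse_id = rep(mice, each = design$replicates_per_mouse),
           strain = g$strain[i], age_months = g$age_months[i],
           phenotype = ph, replicate = rep(seq_len(design$replicates_per_mouse),
                                           times = g$n_mice[i]),
           study = g$study[i])
  }))
  samples$sample_id <- sprintf("%s_a%s_r%d", samples$mouse_id,
                               sub("\\.", "p", samples$age_months),
                               samples$replicate)
  n_pep <- nrow(library)
  n_col <- nrow(samples)
  row_of <- setNames(seq_len(n_pep), library$peptide_id)

  # log10 fold-effect matrix per (peptide, column)
  log_fold <- matrix(0, n_pep, n_col)
  add_effect <- function(tab, cols, atten = 1) {
    if (nrow(tab) == 0 || !any(cols)) return()
    log_fold[row_of[tab$peptide_id], cols] <<-
      log_fold[row_of[tab$peptide_id], cols] + atten * log10(tab$fold)
  }
  is_lpr <- samples$strain == "MRL/lpr"
  is_high <- !is.na(samples$phenotype) & samples$phenotype == "high_floater"
  add_effect(effects$diagnostic, is_lpr & samples$age_months == 4)
  add_effect(effects$behavior, is_lpr & is_high & samples$age_months == 4)
  add_effect(effects$behavior, is_lpr & is_high & samples$age_months < 4,
             atten = effects$attenuation)
  add_effect(effects$predictive,
             (samples$strain == "MRL/mp" & samples$age_months == 4) |
               (is_lpr & samples$age_months < 4))

  # serum unit = one mouse at one age; replicates share its biological draw
  unit <- paste(samples$mouse_id, samples$age_months)
  unit_ids <- unique(unit)
  withr::with_seed(noise$seed, {
    mouse_eff <- matrix(rnorm(n_pep * length(unit_ids), 0, noise$mouse_log_sd),
                        n_pep, length(unit_ids))
    slide_scale <- rnorm(n_col, 0, noise$scale_log_sd)
    rep_noise <- matrix(rnorm(n_pep * n_col, 0, noise$replicate_log_sd),
                        n_pep, n_col)
  })
  log_vals <- effects$baseline$log10_mean + log_fold +
    mouse_eff[, match(unit, unit_ids), drop = FALSE] +
    rep(slide_scale, each = n_pep) + rep_noise
  intensity_matrix(10^log_vals, library, samples, scale = "raw")
}

#' Write / read a cohort as per-slide GPR files plus metadata
#'
#' `write_cohort_gpr()` emits one GPR file per sample column, a
#' `samples.tsv` metadata table and a `library.tsv` peptide table into `dir`;
#' `read_cohort_gpr()` reassembles the identical cohort from such a
#' directory, in metadata order.
#'
#' @param m Raw-scale [intensity_matrix()].
#' @param dir Directory (created if needed).
#' @return The directory (write) or an [intensity_matrix()] (read).
#' @export
write_cohort_gpr <- function(m, dir) {
  stop_if_not_scale(m, "raw", "write_cohort_gpr")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_peptide_library(m$peptides, file.path(dir, "library.tsv"))
  write.table(as.data.frame(m$samples), file.path(dir, "samples.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  for (j in seq_len(ncol(m$values))) {
    write_gpr(m, file.path(dir, paste0(m$samples$sample_id[j], ".gpr")),
              sample = j)
  }
  invisible(dir)
}

#' @rdname write_cohort_gpr
#' @export
read_cohort_gpr <- function(dir) {
  library <- read_peptide_library(file.path(dir, "library.tsv"))
  samples <- as_tibble(read.delim(file.path(dir, "samples.tsv"),
                                  stringsAsFactors = FALSE))
  samples$phenotype <- as.character(samples$phenotype)
  cols <- lapply(seq_len(nrow(samples)), function(j) {
    read_gpr(file.path(dir, paste0(samples$sample_id[j], ".gpr")), library,
             sample = as.list(samples[j, ]))$values
  })
  intensity_matrix(do.call(cbind, cols), library, samples, scale = "raw")
}
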