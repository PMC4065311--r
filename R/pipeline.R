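#' Run the full two-study immunosignaturing pipeline
#'
#' Orchestrates every stage from one declarative config: cohort input
#' (synthetic generation or a directory of GPR files), median normalization
#' and log10 transform, replicate averaging, QC, per-contrast signature
#' selection, cross-study intersections, LOOCV classification and optional
#' proteome target mapping. Deterministic given the config (all seeds live
#' in it); every output table carries the config hash and the log records
#' each stage's input/output cardinalities.
#'
#' @param config Nested list, or path to a YAML file with the same
#'   structure. See [demo_config()] for the schema.
#' @param out_dir Run directory for artifacts (created if needed); `NULL`
#'   writes nothing.
#' @return List of class `pipeline_result`: `sets` (named [peptide_set()]s),
#'   `qc`, `cv` (named `cv_result`s), `mapping` (named target tables),
#'   `matrix` (log10 replicate-averaged), `truth` (spike table, synthetic
#'   runs only), `config_hash`, `log`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$seed)) abort("config must set a seed")
  config_hash <- rlang::hash(config)
  log_lines <- character()
  note <- function(...) {
    log_lines <<- c(log_lines, sprintf(...))
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)))
    })
  }
  if (!is.null(out_dir)) {
    dir.create(file.path(out_dir, "signatures"), recursive = TRUE,
               showWarnings = FALSE)
  }
  emit <- function(writer, obj, ...) {
    if (is.null(out_dir)) return(invisible(NULL))
    path <- file.path(out_dir, ...)
    writeLines(sprintf("# config_hash: %s", config_hash), path)
    tmp <- tempfile()
    writer(obj, tmp)
    cat(readLines(tmp), file = path, sep = "\n", append = TRUE)
    unlink(tmp)
  }

  # ---- cohort ----
  truth <- NULL
  raw <- stage("cohort", {
    if (!is.null(config$cohort$gpr_dir)) {
      read_cohort_gpr(config$cohort$gpr_dir)
    } else {
      syn <- config$cohort$synthetic %||%
        abort("config needs cohort$synthetic or cohort$gpr_dir")
      library <- if (!is.null(config$library$path)) {
        read_peptide_library(config$library$path)
      } else {
        generate_library(n = config$library$n %||% 10000,
                         length = config$library$length %||% 20,
                         linker = config$library$linker %||% "GSC",
                         seed = config$seed)
      }
      design <- default_design(studies = syn$studies %||% c(1, 2),
                               replicates_per_mouse =
                                 syn$replicates_per_mouse %||% 3)
      effects <- do.call(effect_model,
                         c(list(library = library, seed = config$seed + 1L),
                           syn$effects))
      noise <- if (isTRUE(syn$noise$zero)) {
        noise_free(seed = config$seed + 2L)
      } else {
        do.call(noise_model, c(list(seed = config$seed + 2L), syn$noise))
      }
      truth <- spike_truth(effects)
      generate_cohort(library, design, effects, noise)
    }
  })
  note("cohort: %d peptides x %d slides", nrow(raw$values), ncol(raw$values))

  # ---- normalize / transform / average ----
  mn <- stage("normalize", median_normalize(raw))
  lg <- stage("log10", log10_transform(mn))
  avg <- stage("average_replicates", average_technical_replicates(lg))
  mn_avg <- pow10_transform(avg)  # per-mouse geometric means, linear scale
  note("replicate averaging: %d slides -> %d serum samples",
       ncol(lg$values), ncol(avg$values))

  # ---- qc ----
  qc <- NULL
  if (!isFALSE(config$qc)) {
    qc <- stage("qc", qc_report(mn))
    note("qc: slide CV %.3f, min replicate Pearson %.3f, MDFC %.3f",
         qc$slide_cv, qc$replicate_pearson_min, qc$mdfc_95)
    emit(write_qc_report, qc, "qc.tsv")
  }

  # ---- signature selection ----
  sets <- list()
  for (name in names(config$contrasts)) {
    cc <- config$contrasts[[name]]
    set <- stage(paste0("select:", name), {
      ct <- contrast_spec(cc$case, cc$control, cc$prefilter)
      ratios <- binding_ratio(mn_avg, ct)
      mask <- if (!is.null(cc$prefilter)) {
        prefilter_greater(mn_avg, cc$prefilter$greater, cc$prefilter$lesser)
      }
      rule <- compute_threshold(mn_avg, ct, ratios,
                                threshold_rule(cc$k %||% 1.5,
                                               cc$reference %||%
                                                 "control_intensity_distribution"))
      select_signature(ratios, rule, mn_avg$peptides, mask, name = name,
                       study = cc$study %||% NA)
    })
    sets[[name]] <- set
    note("select %s: %d peptides (k = %s)", name, length(set), cc$k %||% 1.5)
  }

  # ---- intersections ----
  for (spec in config$intersections) {
    set <- stage(paste0("intersect:", spec$name), {
      for (parent in c(spec$a, spec$b)) {
        if (is.null(sets[[parent]])) {
          abort(sprintf("set '%s' is not defined before use", parent))
        }
      }
      intersect_signatures(sets[[spec$a]], sets[[spec$b]], name = spec$name)
    })
    sets[[spec$name]] <- set
    note("intersect %s = %s & %s: %d peptides", spec$name, spec$a, spec$b,
         length(set))
  }
  for (name in names(sets)) {
    if (length(sets[[name]]) > 0) {
      emit(write_signature_table, sets[[name]], "signatures",
           paste0(name, ".tsv"))
    } else {
      note("signature %s is empty; no table written", name)
    }
  }

  # ---- classification ----
  cv <- list()
  for (spec in config$classification) {
    res <- stage(paste0("crossval:", spec$name), {
      feats <- sets[[spec$features]] %||%
        abort(sprintf("feature set '%s' is not defined", spec$features))
      cols <- sample_filter(avg$samples, spec$case) |
        sample_filter(avg$samples, spec$control)
      sub <- intensity_matrix(avg$values[, cols, drop = FALSE], avg$peptides,
                              avg$samples[cols, , drop = FALSE], avg$scale)
      labels <- ifelse(sample_filter(sub$samples, spec$case), "case",
                       "control")
      loocv(sub, labels, feats, mode = spec$mode %||% "asis",
            cost = spec$cost %||% 1, seed = config$seed + 3L)
    })
    cv[[spec$name]] <- res
    note("crossval %s: %d/%d errors (%.1f%%)", spec$name, res$n_errors,
         res$n_samples, 100 * res$error_rate)
    emit(write_cv_result, res, paste0("cv_", spec$name, ".tsv"))
  }

  # ---- target mapping ----
  mapping <- list()
  if (!is.null(config$mapping$proteome)) {
    proteome <- stage("mapping", read_proteome(config$mapping$proteome))
    smat <- substitution_matrix(config$mapping$matrix %||% "BLOSUM62")
    for (set_name in config$mapping$sets) {
      tab <- stage(paste0("map-targets:", set_name), {
        empirical_pvalues(sets[[set_name]] %||%
                            abort(sprintf("set '%s' is not defined", set_name)),
                          raw$peptides, proteome, smat,
                          n_perm = config$mapping$n_perm %||% 200,
                          seed = config$seed + 4L)
      })
      mapping[[set_name]] <- tab
      note("map-targets %s: top hit %s (p = %.4f)", set_name,
           tab$protein_id[1], tab$p_value[1])
      emit(function(obj, path) {
        write.table(as.data.frame(obj), path, sep = "\t", quote = FALSE,
                    row.names = FALSE)
      }, tab, paste0("targets_", set_name, ".tsv"))
    }
  }

  if (!is.null(out_dir)) {
    writeLines(c(sprintf("# config_hash: %s", config_hash), log_lines),
               file.path(out_dir, "pipeline.log"))
  }
  structure(list(sets = sets, qc = qc, cv = cv, mapping = mapping,
                 matrix = avg, truth = truth, config_hash = config_hash,
                 log = log_lines),
            class = "pipeline_result")
}

#' Demo configuration: the two-study synthetic workflow
#'
#' A complete config for a synthetic two-study cohort mirroring the real
#' analysis: diagnostic contrasts (4-month MRL/lpr vs 4-month C3H/HeJ from
#' study 1, at k = 1.5), behavior contrasts (high floaters with the
#' high > low prefilter, k = 1.5), predictive contrasts (4-month MRL/mp at
#' k = 0.25 and 1.5-month MRL/lpr at k = 1.5) and the behavior-predictive
#' contrast (1.5-month future high floaters, k = 2.5); cross-study
#' intersections of the first three pairs; and LOOCV of the diagnostic
#' contrast on the intersected diagnostic set. Threshold cutoffs use the
#' `ratio_distribution` reference (see the methods vignette for why).
#'
#' @param n_peptides Library size for the demo (default 2000; the modeled
#'   arrays carry 10000).
#' @param noise `"default"` (calibrated noise) or `"none"` (zero noise, for
#'   exact recovery checks).
#' @param effects Named list of overrides for [effect_model()] parameters.
#' @param seed Master seed; all stage seeds derive from it.
#' @return Config list accepted by [run_pipeline()].
#' @export
demo_config <- function(n_peptides = 2000, noise = c("default", "none"),
                        effects = list(), seed = 1) {
  noise <- match.arg(noise)
  c3h <- list(study = 1, strain = "C3H/HeJ", age_months = 4)
  lpr4 <- function(s) list(study = s, strain = "MRL/lpr", age_months = 4)
  high4 <- function(s) c(lpr4(s), list(phenotype = "high_floater"))
  low4 <- function(s) c(lpr4(s), list(phenotype = "low_floater"))
  lpr15 <- list(study = 2, strain = "MRL/lpr", age_months = 1.5)
  high15 <- c(lpr15, list(phenotype = "high_floater"))
  low15 <- c(lpr15, list(phenotype = "low_floater"))
  ref <- "ratio_distribution"
  list(
    seed = seed,
    library = list(n = n_peptides, length = 20, linker = "GSC"),
    cohort = list(synthetic = list(
      studies = c(1, 2), replicates_per_mouse = 3,
      effects = effects,
      noise = if (noise == "none") list(zero = TRUE) else list()
    )),
    qc = TRUE,
    contrasts = list(
      diagnostic_s1 = list(case = lpr4(1), control = c3h, k = 1.5,
                           reference = ref, study = 1),
      diagnostic_s2 = list(case = lpr4(2), control = c3h, k = 1.5,
                           reference = ref, study = 2),
      behavior_s1 = list(case = high4(1), control = c3h, k = 1.5,
                         reference = ref, study = 1,
                         prefilter = list(greater = high4(1),
                                          lesser = low4(1))),
      behavior_s2 = list(case = high4(2), control = c3h, k = 1.5,
                         reference = ref, study = 2,
                         prefilter = list(greater = high4(2),
                                          lesser = low4(2))),
      predictive_s1 = list(case = list(study = 1, strain = "MRL/mp",
                                       age_months = 4),
                           control = c3h, k = 0.25, reference = ref,
                           study = 1),
      predictive_s2 = list(case = lpr15, control = c3h, k = 1.5,
                           reference = ref, study = 2),
      predictive_behavior = list(case = high15, control = c3h, k = 2.5,
                                 reference = ref, study = 2,
                                 prefilter = list(greater = high15,
                                                  lesser = low15))
    ),
    intersections = list(
      list(a = "diagnostic_s1", b = "diagnostic_s2", name = "diagnostic"),
      list(a = "behavior_s1", b = "behavior_s2", name = "behavior"),
      list(a = "predictive_s1", b = "predictive_s2", name = "predictive")
    ),
    classification = list(
      list(name = "diagnostic", case = lpr4(2), control = c3h,
           features = "diagnostic", mode = "asis")
    ),
    mapping = list(proteome = NULL)
  )
}
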