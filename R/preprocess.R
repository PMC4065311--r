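#' Median-normalize slides
#'
#' Divides every slide (column) by its own median so each column's median is
#' exactly 1. Removes global brightness differences between slides;
#' idempotent.
#'
#' @param m Raw or already median-normalized [intensity_matrix()] with
#'   strictly positive values.
#' @return An `intensity_matrix` with `scale = "median_normalized"`.
#' @export
median_normalize <- function(m) {
  stop_if_not_scale(m, c("raw", "median_normalized"), "median_normalize")
  if (any(m$values <= 0)) {
    abort(paste0("median_normalize needs strictly positive intensities; ",
                 "floor nonpositive values before normalizing"))
  }
  med <- apply(m$values, 2, median)
  intensity_matrix(sweep(m$values, 2, med, "/"), m$peptides, m$samples,
                   scale = "median_normalized")
}

#' Log10-transform a median-normalized matrix
#'
#' @param m Median-normalized [intensity_matrix()] with positive values.
#' @return An `intensity_matrix` with `scale = "log10"` (column medians 0).
#' @export
log10_transform <- function(m) {
  stop_if_not_scale(m, "median_normalized", "log10_transform")
  if (any(m$values <= 0)) abort("log10_transform needs positive values")
  intensity_matrix(log10(m$values), m$peptides, m$samples, scale = "log10")
}

#' Invert the log10 transform
#'
#' @param m Log10-scale [intensity_matrix()].
#' @return An `intensity_matrix` back on the median-normalized linear scale.
#' @export
pow10_transform <- function(m) {
  stop_if_not_scale(m, "log10", "pow10_transform")
  intensity_matrix(10^m$values, m$peptides, m$samples,
                   scale = "median_normalized")
}

# serum unit: one mouse at one age in one study (replicates belong to it)
replicate_unit <- function(samples) {
  paste(samples$study, samples$mouse_id, samples$age_months, sep = "|")
}

#' Average technical replicates
#'
#' Collapses replicate slides of the same serum sample (mouse at a given age)
#' to one column by the arithmetic mean on the current scale. Averaging on
#' the log10 scale (the workflow default) corresponds to geometric averaging
#' of linear intensities.
#'
#' @param m An [intensity_matrix()].
#' @return An `intensity_matrix` with one column per serum sample
#'   (`replicate = 1`).
#' @export
average_technical_replicates <- function(m) {
  unit <- replicate_unit(m$samples)
  units <- unique(unit)
  first <- match(units, unit)
  for (u in units) {
    reps <- m$samples$replicate[unit == u]
    if (anyDuplicated(reps)) {
      abort(sprintf("duplicated replicate numbers for serum sample '%s'", u))
    }
  }
  vals <- vapply(units, function(u) {
    rowMeans(m$values[, unit == u, drop = FALSE])
  }, numeric(nrow(m$values)))
  samples <- m$samples[first, , drop = FALSE]
  samples$replicate <- 1L
  samples$sample_id <- sub("_r[0-9]+$", "", samples$sample_id)
  intensity_matrix(vals, m$peptides, samples, scale = m$scale)
}

#' Array quality-control report
#'
#' Three statistics summarizing array reproducibility, all computed on the
#' median-normalized linear scale (the matrix is normalized first if raw):
#' \itemize{
#'   \item `replicate_pearson` - per serum sample, the minimum pairwise
#'     Pearson correlation across its technical-replicate slides.
#'   \item `slide_cv` - mean over peptides and biological groups
#'     (study/strain/age/phenotype) of the per-peptide coefficient of
#'     variation across the group's slides.
#'   \item `mdfc_95` - minimum detectable fold-change: the 95th percentile of
#'     between-replicate fold changes (max/min over every replicate pair,
#'     pooled over peptides and serum samples).
#' }
#'
#' @param m Raw or median-normalized [intensity_matrix()] with >= 2 slides.
#' @return List of class `qc_report` with fields `replicate_pearson` (named
#'   vector), `replicate_pearson_min`, `slide_cv` and `mdfc_95`.
#' @export
qc_report <- function(m) {
  stop_if_not_scale(m, c("raw", "median_normalized"), "qc_report")
  if (ncol(m$values) < 2) abort("qc_report needs at least two slides")
  if (m$scale == "raw") m <- median_normalize(m)
  unit <- replicate_unit(m$samples)
  rep_units <- names(which(table(unit) >= 2))
  if (length(rep_units) == 0) {
    abort("qc_report needs at least one serum sample with >= 2 replicates")
  }

  pearson <- vapply(rep_units, function(u) {
    min(cor(m$values[, unit == u, drop = FALSE]))
  }, numeric(1))

  group <- paste(m$samples$study, m$samples$strain, m$samples$age_months,
                 m$samples$phenotype, sep = "|")
  cv_groups <- names(which(table(group) >= 2))
  if (length(cv_groups) == 0) cv_groups <- character(0)
  slide_cv <- mean(vapply(cv_groups, function(g) {
    v <- m$values[, group == g, drop = FALSE]
    mu <- rowMeans(v)
    mean(apply(v, 1, sd) / mu)
  }, numeric(1)))

  fold <- unlist(lapply(rep_units, function(u) {
    v <- m$values[, unit == u, drop = FALSE]
    pairs <- utils::combn(ncol(v), 2)
    unlist(lapply(seq_len(ncol(pairs)), function(k) {
      a <- v[, pairs[1, k]]
      b <- v[, pairs[2, k]]
      pmax(a, b) / pmin(a, b)
    }))
  }), use.names = FALSE)
  mdfc_95 <- unname(quantile(fold, 0.95))

  structure(list(replicate_pearson = pearson,
                 replicate_pearson_min = min(pearson),
                 slide_cv = slide_cv, mdfc_95 = mdfc_95),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf(paste0("<qc_report> slide CV %.1f%% | min replicate Pearson ",
                     "%.3f | MDFC(95%%) %.2f-fold\n"),
              100 * x$slide_cv, x$replicate_pearson_min, x$mdfc_95))
  invisible(x)
}

#' Serialize a QC report as TSV
#' @param qc A [qc_report()].
#' @param path Output path.
#' @export
write_qc_report <- function(qc, path) {
  df <- data.frame(metric = c("slide_cv", "replicate_pearson_min", "mdfc_95"),
                   value = c(qc$slide_cv, qc$replicate_pearson_min, qc$mdfc_95))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
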