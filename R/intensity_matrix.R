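#' Peptide-by-sample intensity matrix
#'
#' The central container of the workflow: a peptides x samples grid of array
#' intensities together with the peptide library it is indexed by, per-sample
#' metadata, and the current scale of the values. Scale transitions are
#' one-way: `raw` -> `median_normalized` -> `log10`.
#'
#' @param values Numeric matrix, peptides in rows, samples in columns.
#' @param peptides Peptide library (see [peptide_library()]); row order of
#'   `values` must follow `peptides$peptide_id`.
#' @param samples Tibble of per-sample metadata with at least columns
#'   `sample_id`, `mouse_id`, `strain`, `age_months`, `phenotype`,
#'   `replicate`, `study`; one row per column of `values`.
#' @param scale One of `"raw"`, `"median_normalized"`, `"log10"`.
#'
#' @return An object of class `intensity_matrix`: a list with elements
#'   `values`, `peptides`, `samples`, `scale`.
#' @export
intensity_matrix <- function(values, peptides, samples,
                             scale = c("raw", "median_normalized", "log10")) {
  scale <- match.arg(scale)
  values <- as.matrix(values)
  samples <- as_tibble(samples)
  if (!is.numeric(values)) {
    abort("intensity values must be numeric")
  }
  if (nrow(values) != nrow(peptides)) {
    abort(sprintf("matrix has %d rows but the peptide library has %d entries",
                  nrow(values), nrow(peptides)))
  }
  if (ncol(values) != nrow(samples)) {
    abort(sprintf("matrix has %d columns but %d sample records were given",
                  ncol(values), nrow(samples)))
  }
  required <- c("sample_id", "mouse_id", "strain", "age_months",
                "phenotype", "replicate", "study")
  missing <- setdiff(required, names(samples))
  if (length(missing) > 0) {
    abort(paste0("sample metadata lacks column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(samples$sample_id)) {
    abort("sample_id values must be unique")
  }
  key <- paste(samples$mouse_id, samples$replicate, samples$study,
               samples$age_months)
  if (anyDuplicated(key)) {
    abort("(mouse_id, replicate) must be unique within a study and age")
  }
  bad_pheno <- !is.na(samples$phenotype) & samples$strain != "MRL/lpr"
  if (any(bad_pheno)) {
    abort("floater phenotype is only defined for MRL/lpr samples")
  }
  if (scale != "log10" && any(values < 0)) {
    abort("raw and median-normalized intensities must be non-negative")
  }
  rownames(values) <- peptides$peptide_id
  colnames(values) <- samples$sample_id
  structure(list(values = values, peptides = peptides, samples = samples,
                 scale = scale),
            class = "intensity_matrix")
}

#' @export
print.intensity_matrix <- function(x, ...) {
  cat(sprintf("<intensity_matrix> %d peptides x %d samples [%s]\n",
              nrow(x$values), ncol(x$values), x$scale))
  grp <- table(paste(x$samples$strain, x$samples$age_months, sep = "/"))
  cat("  slides per strain/age:",
      paste(names(grp), grp, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.intensity_matrix <- function(x) dim(x$values)

#' Select sample columns by metadata
#'
#' A sample filter is a named list of metadata conditions, e.g.
#' `list(strain = "MRL/lpr", age_months = 4, phenotype = "high_floater")`.
#' Each condition is matched with `%in%` against the corresponding metadata
#' column; `NA` in the filter matches `NA` in the column. All conditions must
#' hold.
#'
#' @param samples Sample metadata tibble.
#' @param filter Named list of conditions; `NULL` selects everything.
#' @return Logical vector over rows of `samples`.
#' @export
sample_filter <- function(samples, filter) {
  keep <- rep(TRUE, nrow(samples))
  if (is.null(filter)) return(keep)
  if (length(filter) > 0 && is.null(names(filter))) {
    abort("sample filters must be named lists of metadata conditions")
  }
  for (field in names(filter)) {
    if (!field %in% names(samples)) {
      abort(sprintf("unknown sample metadata field '%s' in filter", field))
    }
    wanted <- filter[[field]]
    col <- samples[[field]]
    hit <- col %in% wanted[!is.na(wanted)]
    if (anyNA(wanted)) hit <- hit | is.na(col)
    keep <- keep & hit
  }
  keep
}

#' Subset an intensity matrix to samples matching a filter
#'
#' @inheritParams sample_filter
#' @param m An [intensity_matrix()].
#' @return An `intensity_matrix` with the matching columns.
#' @export
subset_samples <- function(m, filter) {
  keep <- sample_filter(m$samples, filter)
  if (!any(keep)) abort("sample filter matched no columns")
  intensity_matrix(m$values[, keep, drop = FALSE], m$peptides,
                   m$samples[keep, , drop = FALSE], m$scale)
}

stop_if_not_scale <- function(m, scale, what) {
  if (!inherits(m, "intensity_matrix")) {
    abort(sprintf("%s expects an intensity_matrix", what))
  }
  if (!m$scale %in% scale) {
    abort(sprintf("%s expects scale %s, got '%s'", what,
                  paste(sQuote(scale), collapse = " or "), m$scale))
  }
  invisible(m)
}
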