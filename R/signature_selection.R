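#' Contrast specification
#'
#' Declares a case-vs-control comparison by sample metadata filters (see
#' [sample_filter()]), with an optional "A greater than B" prefilter between
#' two subgroups of the case stratum (e.g. high floaters vs low floaters).
#'
#' @param case,control Sample filters for the numerator and denominator
#'   groups; they must match disjoint sets of slides.
#' @param prefilter Optional list `list(greater = <filter>, lesser =
#'   <filter>)`; only peptides whose mean intensity in `greater` strictly
#'   exceeds that in `lesser` are eligible for selection.
#' @return List of class `contrast_spec`.
#' @export
contrast_spec <- function(case, control, prefilter = NULL) {
  if (!is.null(prefilter) &&
      !all(c("greater", "lesser") %in% names(prefilter))) {
    abort("prefilter must be list(greater = ..., lesser = ...)")
  }
  structure(list(case = case, control = control, prefilter = prefilter),
            class = "contrast_spec")
}

contrast_columns <- function(m, contrast) {
  case <- sample_filter(m$samples, contrast$case)
  control <- sample_filter(m$samples, contrast$control)
  if (!any(case) || !any(control)) {
    abort("contrast case and control groups must both be non-empty")
  }
  if (any(case & control)) {
    abort("contrast case and control groups overlap")
  }
  list(case = case, control = control)
}

# per-peptide group mean: average replicates within each serum sample first,
# then average across mice, so unbalanced replication cannot weight a mouse
group_mean <- function(m, cols) {
  v <- m$values[, cols, drop = FALSE]
  unit <- replicate_unit(m$samples[cols, , drop = FALSE])
  units <- unique(unit)
  per_unit <- vapply(units, function(u) rowMeans(v[, unit == u, drop = FALSE]),
                     numeric(nrow(v)))
  rowMeans(matrix(per_unit, nrow = nrow(v)))
}

#' Per-peptide binding ratios
#'
#' The ratio of mean case-group intensity to mean control-group intensity on
#' the median-normalized linear scale, computed per peptide. Technical
#' replicates are averaged within each mouse before group means are taken.
#'
#' @param m Median-normalized [intensity_matrix()].
#' @param contrast A [contrast_spec()].
#' @return Named numeric vector of ratios, one per library peptide.
#' @export
binding_ratio <- function(m, contrast) {
  stop_if_not_scale(m, "median_normalized", "binding_ratio")
  cols <- contrast_columns(m, contrast)
  ctrl <- group_mean(m, cols$control)
  if (any(ctrl == 0)) abort("zero control mean intensity")
  setNames(group_mean(m, cols$case) / ctrl, m$peptides$peptide_id)
}

#' Mean + k*SD threshold rule
#'
#' The selection statistic: a peptide is kept when its binding ratio strictly
#' exceeds a cutoff k standard deviations above a reference mean. Three
#' reference distributions are supported:
#' \itemize{
#'   \item `control_intensity_distribution` - mean + k*SD of the control
#'     group's per-peptide mean intensities, taken across peptides (one
#'     scalar cutoff on the normalized-intensity scale).
#'   \item `ratio_distribution` - mean + k*SD of the binding-ratio vector
#'     itself (one scalar cutoff on the ratio scale).
#'   \item `per_peptide_control` - per-peptide cutoff
#'     `(mu_p + k*sigma_p) / mu_p` from that peptide's control-slide mean and
#'     SD.
#' }
#'
#' @param k Number of SDs above the mean (the workflow uses 0.25, 1.5, 2.5).
#' @param reference Reference distribution (see above).
#' @return List of class `threshold_rule` with `tau = NULL` until
#'   [compute_threshold()] is applied.
#' @export
threshold_rule <- function(k = 1.5,
                           reference = c("control_intensity_distribution",
                                         "ratio_distribution",
                                         "per_peptide_control")) {
  if (k < 0) abort("k must be >= 0")
  structure(list(k = k, reference = match.arg(reference), tau = NULL),
            class = "threshold_rule")
}

#' Compute the cutoff for a threshold rule
#'
#' @param m Median-normalized [intensity_matrix()].
#' @param contrast The [contrast_spec()] the ratios came from.
#' @param ratios Binding-ratio vector from [binding_ratio()].
#' @param rule A [threshold_rule()].
#' @return The rule with `tau` filled in (scalar, or per-peptide vector for
#'   the `per_peptide_control` reference).
#' @export
compute_threshold <- function(m, contrast, ratios, rule) {
  stop_if_not_scale(m, "median_normalized", "compute_threshold")
  if (nrow(m$values) < 2) abort("SD undefined with a single peptide")
  cols <- contrast_columns(m, contrast)
  rule$tau <- switch(
    rule$reference,
    control_intensity_distribution = {
      ctrl <- group_mean(m, cols$control)
      mean(ctrl) + rule$k * sd(ctrl)
    },
    ratio_distribution = mean(ratios) + rule$k * sd(ratios),
    per_peptide_control = {
      v <- m$values[, cols$control, drop = FALSE]
      if (ncol(v) < 2) abort("per_peptide_control needs >= 2 control slides")
      mu <- rowMeans(v)
      sigma <- apply(v, 1, sd)
      setNames((mu + rule$k * sigma) / mu, m$peptides$peptide_id)
    })
  if (any(!is.finite(rule$tau))) abort("computed cutoff is not finite")
  rule
}

#' Prefilter mask: group A strictly greater than group B
#'
#' @param m Median-normalized [intensity_matrix()].
#' @param groupA,groupB Disjoint, non-empty sample filters.
#' @return Logical vector per peptide: `mean_A > mean_B` (strict).
#' @export
prefilter_greater <- function(m, groupA, groupB) {
  a <- sample_filter(m$samples, groupA)
  b <- sample_filter(m$samples, groupB)
  if (!any(a) || !any(b)) abort("prefilter groups must be non-empty")
  if (any(a & b)) abort("prefilter groups overlap")
  setNames(group_mean(m, a) > group_mean(m, b), m$peptides$peptide_id)
}

#' Select a signature by threshold exceedance
#'
#' Members are the peptides passing the (optional) prefilter mask whose
#' binding ratio strictly exceeds the cutoff. An empty result is valid.
#'
#' @param ratios Binding-ratio vector aligned to the library.
#' @param rule A [threshold_rule()] with `tau` computed.
#' @param library The [peptide_library()] (provides sequences).
#' @param prefilter_mask Optional logical vector aligned to the library.
#' @param name Signature name.
#' @param study Optional study label stored in provenance.
#' @return A [peptide_set()] whose members carry their ratios.
#' @export
select_signature <- function(ratios, rule, library, prefilter_mask = NULL,
                             name = "signature", study = NA) {
  if (is.null(rule$tau)) abort("rule has no cutoff; run compute_threshold()")
  if (length(ratios) != nrow(library)) {
    abort("ratio vector and library lengths differ")
  }
  keep <- ratios > rule$tau
  if (!is.null(prefilter_mask)) {
    if (length(prefilter_mask) != length(ratios)) {
      abort("prefilter mask and ratio vector lengths differ")
    }
    keep <- keep & prefilter_mask
  }
  peptide_set(name,
              tibble(peptide_id = library$peptide_id[keep],
                     sequence = library$sequence[keep],
                     ratio = unname(ratios[keep])),
              provenance = list(rule = rule, study = study))
}

#' Intersect two signatures
#'
#' Members present in both sets (by peptide id), carrying both parents'
#' ratios as `ratio_study1` / `ratio_study2` (in argument order).
#'
#' @param a,b [peptide_set()]s keyed on the same library.
#' @param name Name for the intersection (default records both parents).
#' @return A [peptide_set()].
#' @export
intersect_signatures <- function(a, b, name = NULL) {
  shared <- intersect(a$members$peptide_id, b$members$peptide_id)
  ia <- match(shared, a$members$peptide_id)
  ib <- match(shared, b$members$peptide_id)
  if (any(a$members$sequence[ia] != b$members$sequence[ib])) {
    abort("sets disagree on peptide sequences; were they built on the same library?")
  }
  ratio_of <- function(s, i) {
    if ("ratio" %in% names(s$members)) s$members$ratio[i] else NA_real_
  }
  peptide_set(name %||% paste0(a$name, "&", b$name),
              tibble(peptide_id = shared,
                     sequence = a$members$sequence[ia],
                     ratio_study1 = ratio_of(a, ia),
                     ratio_study2 = ratio_of(b, ib)),
              provenance = list(parents = c(a$name, b$name)))
}

#' Differential binding: per-peptide t-tests with BH correction
#'
#' Two-sample t-test (Welch by default) between case and control mice on the
#' log10 scale, with Benjamini-Hochberg false-discovery-rate correction.
#' Technical replicates must already be averaged (one column per mouse).
#'
#' @param m Log10-scale, replicate-averaged [intensity_matrix()].
#' @param contrast A [contrast_spec()] with >= 2 mice per group.
#' @param alpha FDR level; `significant = q <= alpha` (default 0.05).
#' @param var_equal Pooled-variance t-test instead of Welch.
#' @return Tibble `(peptide_id, t, p, q, significant)`.
#' @export
differential_binding <- function(m, contrast, alpha = 0.05,
                                 var_equal = FALSE) {
  stop_if_not_scale(m, "log10", "differential_binding")
  if (anyDuplicated(replicate_unit(m$samples))) {
    abort("average technical replicates before differential_binding()")
  }
  cols <- contrast_columns(m, contrast)
  x <- m$values[, cols$case, drop = FALSE]
  y <- m$values[, cols$control, drop = FALSE]
  n1 <- ncol(x); n2 <- ncol(y)
  if (n1 < 2 || n2 < 2) abort("differential_binding needs >= 2 mice per group")
  m1 <- rowMeans(x); m2 <- rowMeans(y)
  v1 <- apply(x, 1, stats::var); v2 <- apply(y, 1, stats::var)
  if (var_equal) {
    sp <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  t <- unname((m1 - m2) / se)
  p <- unname(2 * pt(-abs(t), df))
  q <- p.adjust(p, method = "BH")
  tibble(peptide_id = m$peptides$peptide_id, t = t, p = p, q = q,
         significant = q <= alpha)
}

#' ELISA S-value
#'
#' Signal of an antigen-coated (odd) well relative to its paired uncoated
#' control (even) well: `odd_od - even_od`. S-values are a relative measure
#' and may be negative.
#'
#' @param odd_od,even_od Optical densities (>= 0), vectorized.
#' @return `odd_od - even_od`.
#' @export
s_value <- function(odd_od, even_od) {
  if (any(odd_od < 0) || any(even_od < 0)) abort("optical densities must be >= 0")
  odd_od - even_od
}

#' Clone positivity by S-value
#'
#' @param s S-values from [s_value()].
#' @param threshold Positivity cutoff in OD units (default 0.1).
#' @return Logical: `s > threshold` (strict).
#' @export
s_positive <- function(s, threshold = 0.1) {
  s > threshold
}
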