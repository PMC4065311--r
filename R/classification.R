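#' Leave-one-out cross-validation with a linear SVM
#'
#' Each mouse in turn is held out; a linear support vector machine
#' (`e1071::svm`, C-classification, fixed cost) is trained on all remaining
#' mice restricted to the signature peptides, and the held-out mouse is
#' predicted. Per-peptide centering and scaling are computed on the training
#' fold only, so the held-out sample never informs training, scaling, or (in
#' `nested` mode) feature selection.
#'
#' Two modes: `"asis"` uses the feature set as given - replicating the
#' original procedure, which selected peptides on the full data before
#' cross-validating, and therefore carries that procedure's selection bias -
#' while `"nested"` re-selects features inside every training fold via
#' `selector` and gives an unbiased error estimate.
#'
#' @param m Log10-scale, replicate-averaged [intensity_matrix()], one column
#'   per mouse.
#' @param labels Binary labels: factor/character vector aligned to columns,
#'   or named by `sample_id`.
#' @param features A [peptide_set()] or character vector of peptide ids
#'   (ignored in `nested` mode when `selector` is given).
#' @param mode `"asis"` (default) or `"nested"`.
#' @param selector For `nested` mode: `function(train_matrix, train_labels)`
#'   returning peptide ids.
#' @param cost SVM regularization constant (default 1).
#' @param seed Integer seed (the fit is deterministic; recorded for the
#'   reproducibility contract).
#' @return List of class `cv_result`: `n_samples`, `n_errors`, `error_rate`,
#'   `per_sample` tibble of `(sample_id, true_label, predicted_label)`.
#' @export
loocv <- function(m, labels, features, mode = c("asis", "nested"),
                  selector = NULL, cost = 1, seed = 1) {
  mode <- match.arg(mode)
  stop_if_not_scale(m, "log10", "loocv")
  if (anyDuplicated(replicate_unit(m$samples))) {
    abort("average technical replicates before loocv()")
  }
  n <- ncol(m$values)
  if (!is.null(names(labels))) labels <- labels[m$samples$sample_id]
  if (length(labels) != n) abort("labels must cover every sample column")
  labels <- factor(labels)
  if (nlevels(labels) != 2) abort("loocv needs exactly two classes")
  if (any(table(labels) < 2)) abort("loocv needs >= 2 mice per class")
  feature_ids <- if (inherits(features, "peptide_set")) {
    features$members$peptide_id
  } else {
    as.character(features)
  }
  if (mode == "asis") {
    if (length(feature_ids) == 0) abort("feature set is empty")
    missing <- setdiff(feature_ids, m$peptides$peptide_id)
    if (length(missing) > 0) {
      abort(sprintf("feature peptide(s) not in library: %s",
                    paste(head(missing, 3), collapse = ", ")))
    }
  } else if (is.null(selector)) {
    abort("nested mode needs a selector function")
  }

  withr::with_seed(seed, {
    predicted <- vapply(seq_len(n), function(i) {
      train_lab <- labels[-i]
      if (nlevels(droplevels(train_lab)) < 2) {
        abort(sprintf("training fold %d (holding out '%s') has a single class",
                      i, m$samples$sample_id[i]))
      }
      ids <- if (mode == "nested") {
        train_m <- intensity_matrix(m$values[, -i, drop = FALSE], m$peptides,
                                    m$samples[-i, , drop = FALSE], m$scale)
        selector(train_m, train_lab)
      } else {
        feature_ids
      }
      rows <- match(ids, m$peptides$peptide_id)
      x_train <- t(m$values[rows, -i, drop = FALSE])
      x_test <- m$values[rows, i, drop = FALSE]
      mu <- colMeans(x_train)
      sigma <- apply(x_train, 2, sd)
      sigma[sigma == 0] <- 1
      x_train <- scale(x_train, center = mu, scale = sigma)
      fit <- e1071::svm(x_train, train_lab, kernel = "linear", cost = cost,
                        scale = FALSE, type = "C-classification")
      as.character(predict(fit, t((x_test - mu) / sigma)))
    }, character(1))
  })

  per_sample <- tibble(sample_id = m$samples$sample_id,
                       true_label = as.character(labels),
                       predicted_label = predicted)
  n_errors <- sum(per_sample$true_label != per_sample$predicted_label)
  structure(list(n_samples = n, n_errors = n_errors,
                 error_rate = n_errors / n, per_sample = per_sample),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %d/%d misclassified (error rate %.1f%%)\n",
              x$n_errors, x$n_samples, 100 * x$error_rate))
  invisible(x)
}

#' Serialize a cross-validation result as TSV
#' @param cv A `cv_result` from [loocv()].
#' @param path Output path.
#' @export
write_cv_result <- function(cv, path) {
  write.table(as.data.frame(cv$per_sample), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
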