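mn_matrix <- function(values, ...) {
  manual_matrix(values, ..., scale = "median_normalized")
}

test_that("binding ratios are case-mean over control-mean per peptide", {
  m <- mn_matrix(matrix(c(4, 4, 2, 2), nrow = 1),
                 mice = c("c1", "c2", "k1", "k2"),
                 strain = c("MRL/lpr", "MRL/lpr", "C3H/HeJ", "C3H/HeJ"))
  ct <- contrast_spec(list(strain = "MRL/lpr"), list(strain = "C3H/HeJ"))
  expect_equal(unname(binding_ratio(m, ct)), 2)

  # identical case and control values: all ratios exactly 1
  withr::with_seed(1, vals <- matrix(10^rnorm(20), nrow = 10))
  m2 <- mn_matrix(cbind(vals, vals), mice = paste0("m", 1:4),
                  strain = rep(c("MRL/lpr", "C3H/HeJ"), each = 2))
  expect_equal(unname(binding_ratio(m2, ct)), rep(1, 10))

  # brute-force loop oracle on a random 50-peptide matrix
  withr::with_seed(2, vals <- matrix(10^rnorm(50 * 6, 0, 0.4), nrow = 50))
  m3 <- mn_matrix(vals, mice = paste0("m", 1:6),
                  strain = rep(c("MRL/lpr", "C3H/HeJ"), each = 3))
  r <- binding_ratio(m3, ct)
  for (p in c(1, 17, 50)) {
    expect_equal(unname(r[p]), mean(vals[p, 1:3]) / mean(vals[p, 4:6]))
  }
  expect_error(binding_ratio(m3, contrast_spec(list(strain = "MRL/lpr"),
                                               list(strain = "BALB/c"))),
               "non-empty")
})

test_that("ratios average replicates within mouse before across mice", {
  # mouse c1 has 2 replicates, c2 has 1: each mouse must weigh equally
  m <- mn_matrix(matrix(c(2, 4, 9, 1, 1), nrow = 1),
                 mice = c("c1", "c1", "c2", "k1", "k2"),
                 replicates = c(1, 2, 1, 1, 1),
                 strain = c(rep("MRL/lpr", 3), rep("C3H/HeJ", 2)))
  ct <- contrast_spec(list(strain = "MRL/lpr"), list(strain = "C3H/HeJ"))
  expect_equal(unname(binding_ratio(m, ct)), mean(c(mean(c(2, 4)), 9)))
})

test_that("threshold cutoffs match their reference definitions", {
  # control intensities all equal: SD 0, tau = the common value
  m <- mn_matrix(matrix(c(5, 5, 5, 2, 2, 2), nrow = 3),
                 mice = c("a", "b"), strain = c("MRL/lpr", "C3H/HeJ"))
  ct <- contrast_spec(list(strain = "MRL/lpr"), list(strain = "C3H/HeJ"))
  r <- binding_ratio(m, ct)
  rule <- compute_threshold(m, ct, r, threshold_rule(7, "control_intensity_distribution"))
  expect_equal(rule$tau, 2)

  # control per-peptide means {1,2,3}, k = 1.5: tau = 2 + 1.5 * sd
  m2 <- mn_matrix(matrix(c(9, 9, 9, 1, 2, 3), nrow = 3),
                  mice = c("a", "b"), strain = c("MRL/lpr", "C3H/HeJ"))
  r2 <- binding_ratio(m2, ct)
  rule2 <- compute_threshold(m2, ct, r2,
                             threshold_rule(1.5, "control_intensity_distribution"))
  expect_equal(rule2$tau, mean(c(1, 2, 3)) + 1.5 * sd(c(1, 2, 3)))

  # ratio_distribution reference works off the ratio vector itself
  rule3 <- compute_threshold(m2, ct, r2, threshold_rule(2, "ratio_distribution"))
  expect_equal(rule3$tau, mean(r2) + 2 * sd(r2))

  # per-peptide control reference: (mu_p + k sigma_p) / mu_p
  m3 <- mn_matrix(matrix(c(9, 9, 1, 3, 2, 2), nrow = 2),
                  mice = c("a", "b", "c"),
                  strain = c("MRL/lpr", "C3H/HeJ", "C3H/HeJ"))
  r3 <- binding_ratio(m3, ct)
  rule4 <- compute_threshold(m3, ct, r3, threshold_rule(1, "per_peptide_control"))
  expect_equal(unname(rule4$tau),
               c((1.5 + sd(c(1, 2))) / 1.5, (2.5 + sd(c(3, 2))) / 2.5))

  single <- mn_matrix(matrix(c(5, 2), nrow = 1), mice = c("a", "b"),
                      strain = c("MRL/lpr", "C3H/HeJ"))
  expect_error(compute_threshold(single, ct, binding_ratio(single, ct),
                                 threshold_rule(1.5)), "single peptide")
})

test_that("selection is strict and honors the prefilter mask", {
  lib <- tiny_library(n = 3)
  rule <- threshold_rule(1.5, "ratio_distribution")
  rule$tau <- 2.0
  ratios <- c(p1 = 1.0, p2 = 2.0, p3 = 5.0)
  set <- select_signature(ratios, rule, lib)
  expect_identical(set$members$peptide_id, "p3")  # 2.0 == tau is excluded
  expect_equal(set$members$ratio, 5.0)

  # all ratios equal with SD-0 reference: nothing strictly exceeds
  rule$tau <- 1.0
  none <- select_signature(c(p1 = 1, p2 = 1, p3 = 1), rule, lib)
  expect_length(none, 0)

  masked <- select_signature(ratios, rule, lib,
                             prefilter_mask = c(TRUE, TRUE, FALSE))
  expect_identical(masked$members$peptide_id, "p2")
  expect_error(select_signature(ratios, threshold_rule(1), lib), "cutoff")
})

test_that("prefilter_greater is a strict elementwise mean comparison", {
  m <- mn_matrix(matrix(c(3, 1, 2, 2, 1, 2, 2, 2), nrow = 2),
                 mice = c("h1", "h2", "l1", "l2"),
                 phenotype = c("high_floater", "high_floater",
                               "low_floater", "low_floater"))
  high <- list(phenotype = "high_floater")
  low <- list(phenotype = "low_floater")
  mask <- prefilter_greater(m, high, low)
  # peptide 1: mean(3,2) > mean(1,2) TRUE; peptide 2: 1.5 > 2 FALSE
  expect_identical(unname(mask), c(TRUE, FALSE))
  # A identical to B: strictness makes everything FALSE
  m2 <- mn_matrix(matrix(c(1, 2, 1, 2), nrow = 2), mice = c("h1", "l1"),
                  phenotype = c("high_floater", "low_floater"))
  expect_identical(unname(prefilter_greater(m2, high, low)), c(FALSE, FALSE))
  expect_error(prefilter_greater(m2, high, list(phenotype = "x")), "non-empty")

  withr::with_seed(4, vals <- matrix(10^rnorm(40), nrow = 10))
  m3 <- mn_matrix(vals, mice = paste0("m", 1:4),
                  phenotype = rep(c("high_floater", "low_floater"), each = 2))
  expect_identical(unname(prefilter_greater(m3, high, low)),
                   unname(rowMeans(vals[, 1:2]) > rowMeans(vals[, 3:4])))
})

test_that("signature intersection behaves like set intersection on ids", {
  mk <- function(name, ids, ratios) {
    peptide_set(name, tibble::tibble(
      peptide_id = ids, sequence = paste0(ids, "_SEQ"), ratio = ratios))
  }
  a <- mk("a", c("p1", "p2", "p3"), c(2.1, 2.2, 2.3))
  b <- mk("b", c("p2", "p3", "p4"), c(3.2, 3.3, 3.4))
  ab <- intersect_signatures(a, b)
  expect_setequal(ab$members$peptide_id, c("p2", "p3"))
  expect_equal(ab$members$ratio_study1[ab$members$peptide_id == "p2"], 2.2)
  expect_equal(ab$members$ratio_study2[ab$members$peptide_id == "p2"], 3.2)

  expect_length(intersect_signatures(mk("x", "p9", 1), a), 0)

  # commutative and associative on member ids
  c_ <- mk("c", c("p3", "p4", "p1"), c(4.3, 4.4, 4.1))
  expect_setequal(intersect_signatures(b, a)$members$peptide_id,
                  ab$members$peptide_id)
  left <- intersect_signatures(intersect_signatures(a, b), c_)
  right <- intersect_signatures(a, intersect_signatures(b, c_))
  expect_setequal(left$members$peptide_id, right$members$peptide_id)

  # same ids but different sequences: not the same library
  bad <- peptide_set("bad", tibble::tibble(
    peptide_id = "p2", sequence = "OTHER", ratio = 1))
  expect_error(intersect_signatures(a, bad), "library")
})

test_that("differential binding matches t.test and a hand-rolled BH oracle", {
  withr::with_seed(5, vals <- matrix(rnorm(10 * 8), nrow = 10))
  m <- manual_matrix(vals, mice = paste0("m", 1:8),
                     strain = rep(c("MRL/lpr", "C3H/HeJ"), each = 4),
                     scale = "log10")
  ct <- contrast_spec(list(strain = "MRL/lpr"), list(strain = "C3H/HeJ"))
  tab <- differential_binding(m, ct)
  # cross-check the vectorized Welch test against stats::t.test
  for (p in c(1, 4, 10)) {
    ref <- t.test(vals[p, 1:4], vals[p, 5:8])
    expect_equal(tab$t[p], unname(ref$statistic))
    expect_equal(tab$p[p], ref$p.value)
  }
  # BH q-values equal the step-up definition
  expect_equal(tab$q, bh_stepup_oracle(tab$p))
  expect_identical(tab$significant, tab$q <= 0.05)

  # case and control drawn from the same columns duplicated: nothing moves
  m2 <- manual_matrix(cbind(vals[, 1:4], vals[, 1:4] * (1 + 1e-9)),
                      mice = paste0("m", 1:8),
                      strain = rep(c("MRL/lpr", "C3H/HeJ"), each = 4),
                      scale = "log10")
  expect_identical(sum(differential_binding(m2, ct)$significant), 0L)

  small <- manual_matrix(vals[, 1:3], mice = paste0("m", 1:3),
                         strain = c("MRL/lpr", "C3H/HeJ", "C3H/HeJ"),
                         scale = "log10")
  expect_error(differential_binding(small, ct), "2 mice")
})

test_that("S-values are plain well differences with a strict positivity call", {
  expect_equal(s_value(0.5, 0.2), 0.3)
  expect_equal(s_value(0.1, 0.2), -0.1)     # negative S-values are valid
  expect_identical(s_positive(c(0.3, 0.1, -0.1, 0.100001)),
                   c(TRUE, FALSE, FALSE, TRUE))
  expect_error(s_value(-0.1, 0.2), ">= 0")
})

test_that("raising k never grows a signature", {
  lib <- generate_library(n = 400, seed = 6)
  eff <- effect_model(lib, n_diagnostic = 8, n_behavior = 4, n_predictive = 2,
                      seed = 7)
  m <- generate_cohort(lib, default_design(studies = 1), eff,
                       noise_model(seed = 8))
  mn <- median_normalize(m)
  ct <- contrast_spec(list(strain = "MRL/lpr", age_months = 4),
                      list(strain = "C3H/HeJ"))
  r <- binding_ratio(mn, ct)
  for (ref in c("control_intensity_distribution", "ratio_distribution",
                "per_peptide_control")) {
    prev <- NULL
    for (k in c(0.25, 1.5, 2.5)) {
      rule <- compute_threshold(mn, ct, r, threshold_rule(k, ref))
      sel <- select_signature(r, rule, lib)$members$peptide_id
      if (!is.null(prev)) expect_true(all(sel %in% prev))
      prev <- sel
    }
  }
})

test_that("per-slide rescaling leaves ratios and signatures unchanged", {
  lib <- generate_library(n = 300, seed = 9)
  eff <- effect_model(lib, n_diagnostic = 6, n_behavior = 3, n_predictive = 2,
                      seed = 10)
  raw <- generate_cohort(lib, default_design(studies = 1), eff,
                         noise_model(seed = 11))
  withr::with_seed(12, scales <- runif(ncol(raw$values), 0.2, 5))
  rescaled <- intensity_matrix(sweep(raw$values, 2, scales, "*"),
                               raw$peptides, raw$samples, "raw")
  ct <- contrast_spec(list(strain = "MRL/lpr", age_months = 4),
                      list(strain = "C3H/HeJ"))
  r1 <- binding_ratio(median_normalize(raw), ct)
  r2 <- binding_ratio(median_normalize(rescaled), ct)
  expect_equal(r1, r2, tolerance = 1e-12)
})

test_that("noise-free selection recovers exactly the spiked diagnostics", {
  lib <- generate_library(n = 500, seed = 13)
  eff <- effect_model(lib, n_diagnostic = 40, n_behavior = 0,
                      n_predictive = 0, fold_min = 2.5, seed = 14)
  m <- generate_cohort(lib, default_design(studies = 1), eff, noise_free())
  mn <- median_normalize(m)
  ct <- contrast_spec(list(strain = "MRL/lpr", age_months = 4),
                      list(strain = "C3H/HeJ"))
  r <- binding_ratio(mn, ct)
  rule <- compute_threshold(mn, ct, r, threshold_rule(1.5, "ratio_distribution"))
  sel <- select_signature(r, rule, lib)
  expect_setequal(sel$members$peptide_id, eff$diagnostic$peptide_id)
})
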