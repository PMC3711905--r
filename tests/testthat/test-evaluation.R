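test_that("confusion matrices follow the rows=true, columns=predicted layout", {
  cm <- confusion_matrix(c("A", "A", "B"), c("A", "B", "B"), c("A", "B"))
  expect_equal(unclass(cm), matrix(c(1L, 0L, 1L, 1L), 2,
               dimnames = list(true = c("A", "B"),
                               predicted = c("A", "B"))),
               ignore_attr = TRUE)
  # perfect prediction is diagonal with the class sizes
  tr <- rep(c("A", "B", "C"), times = c(2, 3, 4))
  cmp <- confusion_matrix(tr, tr, c("A", "B", "C"))
  expect_equal(diag(unclass(cmp)), c(A = 2L, B = 3L, C = 4L))
  expect_equal(sum(cmp) - sum(diag(cmp)), 0L)
  expect_error(confusion_matrix(character(0), character(0), "A"), "empty")
  expect_error(confusion_matrix("A", "D", c("A", "B")), "unknown label")
})

test_that("balanced metrics agree with a naive per-cell hand computation", {
  set.seed(31)
  for (rep in 1:5) {
    C <- matrix(rpois(16, 3) + diag(4), 4, 4)
    dimnames(C) <- list(true = letters[1:4], predicted = letters[1:4])
    mt <- compute_metrics(structure(C, class = c("confusion_matrix", "matrix")))
    sens <- sapply(1:4, function(i) C[i, i] / sum(C[i, ]))
    pv <- sapply(1:4, function(i) C[i, i] / sum(C[, i]))
    expect_equal(unname(mt$sensitivity), sens)
    expect_equal(unname(mt$predictive_value), pv)
    expect_equal(mt$balanced_accuracy, mean(sens))
    expect_equal(mt$overall_predictive_value, mean(pv))
  }
  # identity pattern scores 1 everywhere
  mt1 <- compute_metrics(confusion_matrix(c("A", "B"), c("A", "B"),
                                          c("A", "B")))
  expect_equal(mt1$balanced_accuracy, 1)
  expect_equal(mt1$overall_predictive_value, 1)
  # never-predicted class: PV 0 with a warning
  cm0 <- confusion_matrix(c("A", "A", "B"), c("A", "A", "A"), c("A", "B"))
  expect_warning(mt0 <- compute_metrics(cm0), "never predicted")
  expect_equal(unname(mt0$predictive_value["B"]), 0)
  expect_error(compute_metrics(matrix(0, 2, 2)), "no predictions")
})

test_that("balanced accuracy is invariant to duplicating a whole class", {
  C <- matrix(c(14L, 3L, 0L, 1L, 13L, 0L, 0L, 0L, 19L), 3, byrow = TRUE,
              dimnames = list(true = c("PSP", "IPD", "MSA"),
                              predicted = c("PSP", "IPD", "MSA")))
  C2 <- C
  C2[2, ] <- 2L * C[2, ]  # every IPD member duplicated
  m1 <- compute_metrics(structure(C, class = c("confusion_matrix", "matrix")))
  m2 <- compute_metrics(structure(C2, class = c("confusion_matrix", "matrix")))
  expect_identical(m1$sensitivity, m2$sensitivity)
  expect_identical(m1$balanced_accuracy, m2$balanced_accuracy)
})

test_that("chance levels give 1/m aggregate and training-proportion per class", {
  expect_equal(chance_levels(rep("x", 9), 3)$chance_accuracy, 1 / 3)
  expect_equal(chance_levels(rep("x", 9), 5)$chance_accuracy, 0.2)
  lab <- rep(c("PSP", "IPD", "MSA"), times = c(17, 14, 19))
  pc <- chance_levels(lab, 3)$per_class_chance
  expect_equal(unname(pc[c("PSP", "IPD", "MSA")]),
               c(17, 14, 19) / 50)
})

test_that("LOO harness runs one fold per subject with fold-local preprocessing", {
  at <- tiny_atlas()
  co <- generate_cohort(at, planted_design(n_per_class = 4, seed = 51))
  fm <- extract_features(co$images, at, "region:brainstem")
  cv <- loo_cross_validate(fm, co$labels$class, fast_config(seed = 3))
  expect_equal(cv$n_folds, nrow(fm$values))
  expect_equal(nrow(cv$probabilities), cv$n_folds)
  # confusion row sums equal the true class sizes
  expect_equal(unname(rowSums(cv$confusion)),
               unname(as.integer(table(co$labels$class))))
  # a singleton class is refused before any computation
  expect_error(loo_cross_validate(fm, c(co$labels$class[-1], "Z"),
                                  fast_config()),
               "fewer than 2")
})

test_that("label-leaking feature column drives accuracy to ceiling, shuffling restores chance", {
  set.seed(77)
  n <- 18
  lab <- rep(c("A", "B", "C"), each = 6)
  noise <- matrix(rnorm(n * 10), n, 10)
  onehot <- 10 * stats::model.matrix(~ 0 + factor(lab))
  cv_leak <- loo_cross_validate(as_feature_matrix(cbind(noise, onehot)), lab,
                                fast_config(seed = 5))
  expect_gte(cv_leak$metrics$balanced_accuracy, 0.9)
  cv_shuf <- suppressWarnings(
    loo_cross_validate(as_feature_matrix(cbind(noise, onehot[sample(n), ])),
                       lab, fast_config(seed = 5)))
  expect_lte(cv_shuf$metrics$balanced_accuracy, 0.67)
})

test_that("permutation p-values follow the add-one formula at the extremes", {
  at <- tiny_atlas()
  co <- generate_cohort(at, planted_design(n_per_class = 4, effect = 4,
                                           seed = 61))
  fm <- extract_features(co$images, at, "subcortical_network")
  cfg <- fast_config(seed = 9, n_samples = 60, n_burnin = 30)
  pr <- suppressWarnings(
    permutation_test(fm, co$labels$class, n_perm = 19, seed = 13,
                     config = cfg))
  # strongly separable: observed exceeds every permuted value
  expect_true(all(pr$permuted < pr$observed))
  expect_equal(pr$p, 1 / 20)
  expect_length(pr$permuted, 19)
  # negated metric puts the observed value at the bottom: p = 1
  pr2 <- suppressWarnings(
    permutation_test(fm, co$labels$class,
                     metric = function(cv) -cv$metrics$balanced_accuracy,
                     n_perm = 19, seed = 13, config = cfg))
  expect_equal(pr2$p, 1)
  # identical seeds reproduce the permutation set exactly
  pr3 <- suppressWarnings(
    permutation_test(fm, co$labels$class, n_perm = 19, seed = 13,
                     config = cfg))
  expect_identical(pr$permuted, pr3$permuted)
})

test_that("balanced-accuracy Beta interval behaves across regimes", {
  # degenerate single-subject class, predicted correctly: wide, upper near 1
  cm1 <- confusion_matrix(c("A", "B"), c("A", "B"), c("A", "B"))
  # upper quantile of the mean of two Beta(2, 1) draws is ~0.945
  ci1 <- balanced_accuracy_interval(cm1, seed = 2)
  expect_gt(ci1$upper, 0.9)
  expect_lt(ci1$lower, 0.5)
  # perfect 3 x 20 diagonal: lower bound above 0.85
  tr <- rep(c("A", "B", "C"), each = 20)
  ci2 <- balanced_accuracy_interval(confusion_matrix(tr, tr, c("A", "B", "C")),
                                    seed = 3)
  expect_gt(ci2$lower, 0.85)
  # interval contains the plug-in balanced accuracy for imperfect matrices
  set.seed(41)
  for (rep in 1:10) {
    C <- matrix(rpois(9, 3) + 1L, 3, 3) + diag(3) * rpois(3, 6)
    dimnames(C) <- list(true = letters[1:3], predicted = letters[1:3])
    cm <- structure(C, class = c("confusion_matrix", "matrix"))
    ci <- balanced_accuracy_interval(cm, seed = rep)
    expect_gte(ci$point, ci$lower)
    expect_lte(ci$point, ci$upper)
  }
})

test_that("Pearson chi-square reproduces closed-form cases", {
  # perfectly proportional table is exactly independent
  tab <- outer(c(10, 20), c(3, 7)) / 10
  expect_equal(pearson_chi_square(tab)$statistic, 0)
  # complete association in a 2x2
  res <- pearson_chi_square(matrix(c(10, 0, 0, 10), 2))
  expect_equal(res$statistic, 20)
  expect_equal(res$dof, 1)
  expect_error(pearson_chi_square(matrix(c(0, 0, 1, 2), 2)), "margin")
})

test_that("report markers follow the significance legend", {
  expect_identical(significance_marker(0.005), "*")
  expect_identical(significance_marker(0.03), "#")
  expect_identical(significance_marker(0.07), "+")
  expect_identical(significance_marker(0.5), "")
})
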