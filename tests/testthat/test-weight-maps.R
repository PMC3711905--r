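test_that("a single informative voxel receives the largest weight magnitude", {
  at <- tiny_atlas()
  co <- generate_cohort(at, planted_design(n_per_class = 6, effect = 0,
                                           seed = 71, subject_scale_sd = 0))
  # plant the only discriminative signal at one brainstem voxel (grey channel)
  bs_vox <- which(at$labels == region_label_of(at, "brainstem"))
  target <- bs_vox[5]
  cls <- co$labels$class
  for (i in which(cls == "A"))
    co$images[[i]]$channels$grey[target] <-
      co$images[[i]]$channels$grey[target] + 8
  fm <- extract_features(co$images, at, "region:brainstem")
  prep <- fit_fold_preprocessor(fm)
  fmc <- apply_preprocessor(prep, fm)
  K <- linear_kernel(fmc)
  post <- fit_mnp(K, factor(cls), mnp_config(500, 200, seed = 3))
  wm <- compute_weight_maps(post, fmc, at, "region:brainstem")
  w_grey <- abs(wm$maps[["A"]]$grey)
  expect_equal(which.max(w_grey), target)
})

test_that("weight maps localize planted class-specific atrophy (rank test)", {
  at <- tiny_atlas()
  d <- cohort_design(class_names = c("HC", "PSP", "IPD", "MSA-P"),
                     n_per_class = c(HC = 6, PSP = 6, IPD = 6, `MSA-P` = 6),
                     effect_matrix = default_effect_matrix()[
                       c("HC", "PSP", "IPD", "MSA-P"), ],
                     seed = 404)
  co <- generate_cohort(at, d)
  fm <- extract_features(co$images, at, "subcortical_network")
  prep <- fit_fold_preprocessor(fm)
  fmc <- apply_preprocessor(prep, fm)
  post <- fit_mnp(linear_kernel(fmc), factor(co$labels$class),
                  mnp_config(500, 200, seed = 13))
  wm <- compute_weight_maps(post, fmc, at, "subcortical_network")
  lab <- at$labels[fm$feature_index$voxel]
  planted <- lab %in% vapply(c("brainstem", "caudate", "putamen", "pallidum"),
                             function(r) region_label_of(at, r), 0L)
  w_psp <- abs(wm$weights[, "PSP"])
  mw <- wilcox.test(w_psp[planted], w_psp[!planted], alternative = "greater")
  expect_lt(mw$p.value, 0.01)
})

test_that("the IPD-vs-HC weight difference concentrates in the brainstem", {
  at <- tiny_atlas()
  em <- matrix(0, 2, 6, dimnames = list(c("HC", "IPD"), region_names6))
  em["IPD", "brainstem"] <- 1.5
  d <- cohort_design(class_names = c("HC", "IPD"),
                     n_per_class = c(HC = 10, IPD = 10),
                     effect_matrix = em, seed = 303)
  co <- generate_cohort(at, d)
  fm <- extract_features(co$images, at, "subcortical_network")
  prep <- fit_fold_preprocessor(fm)
  fmc <- apply_preprocessor(prep, fm)
  post <- fit_mnp(linear_kernel(fmc), factor(co$labels$class),
                  mnp_config(500, 200, seed = 9))
  wm <- compute_weight_maps(post, fmc, at, "subcortical_network")
  dif <- abs(wm$weights[, "IPD"] - wm$weights[, "HC"])
  lab <- at$labels[fm$feature_index$voxel]
  region_means <- vapply(region_names6, function(r)
    mean(dif[lab == region_label_of(at, r)]), 0)
  expect_identical(names(which.max(region_means)), "brainstem")
  mw <- wilcox.test(dif[lab == region_label_of(at, "brainstem")],
                    dif[lab != region_label_of(at, "brainstem")],
                    alternative = "greater")
  expect_lt(mw$p.value, 0.01)
})

test_that("training-order permutation leaves posterior-mean maps unchanged up to MC error", {
  set.seed(12)
  n <- 12
  X <- matrix(rnorm(n * 8), n, 8)
  lab <- rep(c("A", "B"), each = 6)
  X[lab == "A", 1] <- X[lab == "A", 1] + 3
  at <- tiny_atlas()
  # map features onto the accumbens region (7 voxels -> 14 columns); use 7
  acc <- which(at$labels == region_label_of(at, "accumbens"))
  fm <- as_feature_matrix(X[, 1:7])
  fm$feature_index <- data.frame(channel = 1L, voxel = acc)
  fm$mask_name <- "region:accumbens"
  fit_maps <- function(ord, seed) {
    fmo <- fm
    fmo$values <- fm$values[ord, ]
    fmo$subject_ids <- fm$subject_ids[ord]
    prep <- fit_fold_preprocessor(fmo)
    fmc <- apply_preprocessor(prep, fmo)
    post <- fit_mnp(linear_kernel(fmc), factor(lab[ord]),
                    mnp_config(3000, 500, seed = seed))
    compute_weight_maps(post, fmc, at, "region:accumbens")$weights
  }
  w1 <- fit_maps(seq_len(n), seed = 4)
  w2 <- fit_maps(sample(n), seed = 4)
  expect_lt(max(abs(w1 - w2)), 0.1 * max(abs(w1)))
})

test_that("maps of two interchangeable classes differ only by MC noise", {
  # classes B and C share identical training rows, so the posterior is
  # exchangeable in them and their maps must agree up to sampling noise
  set.seed(15)
  rowsA <- matrix(rnorm(8 * 10), 8, 10) + 3
  rowsBC <- matrix(rnorm(4 * 10), 4, 10)
  X <- rbind(rowsA, rowsBC, rowsBC)
  lab <- rep(c("A", "B", "C"), times = c(8, 4, 4))
  fm <- as_feature_matrix(X)
  prep <- fit_fold_preprocessor(fm)
  fmc <- apply_preprocessor(prep, fm)
  at <- tiny_atlas()
  bs <- which(at$labels == region_label_of(at, "brainstem"))
  fmc$feature_index <- data.frame(channel = 1L, voxel = bs[1:10])
  fmc$mask_name <- "region:brainstem"
  post <- fit_mnp(linear_kernel(fmc), factor(lab),
                  mnp_config(4000, 500, seed = 6))
  wm <- compute_weight_maps(post, fmc, at, "region:brainstem")
  spread_bc <- max(abs(wm$weights[, "B"] - wm$weights[, "C"]))
  contrast_ab <- max(abs(wm$weights[, "A"] - wm$weights[, "B"]))
  expect_lt(spread_bc, 0.2 * contrast_ab)
})

test_that("weight maps demand a linear kernel and round-trip through NIfTI", {
  set.seed(18)
  at <- tiny_atlas()
  co <- generate_cohort(at, planted_design(n_per_class = 3, seed = 81))
  fm <- extract_features(co$images, at, "region:putamen")
  prep <- fit_fold_preprocessor(fm)
  fmc <- apply_preprocessor(prep, fm)
  post <- fit_mnp(linear_kernel(fmc), factor(co$labels$class),
                  fast_config(seed = 2))
  wm <- compute_weight_maps(post, fmc, at, "region:putamen")
  # nonzero only inside the mask
  outside <- at$labels != region_label_of(at, "putamen")
  for (cn in wm$class_names) {
    expect_true(all(wm$maps[[cn]]$grey[outside] == 0))
    expect_true(all(wm$maps[[cn]]$white[outside] == 0))
  }
  dir <- withr::local_tempdir()
  export_weight_maps(wm, at, dir)
  nii <- list.files(dir, pattern = "\\.nii\\.gz$")
  expect_length(nii, 3 * 2 * 2)  # classes x channels x {raw, unit-norm}
  back <- read_weight_maps(dir)
  for (cn in wm$class_names)
    expect_lt(max(abs(back[[cn]]$grey - wm$maps[[cn]]$grey)), 1e-6)
  # nonlinear kernel flag is refused
  post$kernel_type <- "rbf"
  expect_error(compute_weight_maps(post, fmc, at, "region:putamen"),
               "linear")
  # grid mismatch on export
  at2 <- default_atlas(c(12, 12, 12))
  expect_error(export_weight_maps(wm, at2, dir), "grid mismatch")
})
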