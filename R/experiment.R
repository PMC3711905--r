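# End-to-end experiment drivers: YAML-configured, contrast-aware wrappers
# over the cohort generator, feature extraction, LOO-CV, permutation
# testing and weight maps. A thin command-line wrapper over these functions
# ships in inst/cli/neuroprobit.R.

#' Class structure of the four diagnostic contrasts
#'
#' Contrast I separates the disease groups only (PSP vs IPD vs MSA, the MSA
#' variants pooled; chance 33%); II adds healthy controls (chance 25%); III
#' and IV repeat I and II with MSA split into MSA-P and MSA-C (chance 25%
#' and 20%).
#'
#' @param contrast one of \code{"I"}, \code{"II"}, \code{"III"}, \code{"IV"}.
#' @return list with \code{classes} (ordered names), \code{pool_msa},
#'   \code{include_hc} and \code{chance}.
#' @export
contrast_classes <- function(contrast) {
  switch(as.character(contrast),
    I   = list(classes = c("PSP", "IPD", "MSA"), pool_msa = TRUE,
               include_hc = FALSE, chance = 1 / 3),
    II  = list(classes = c("PSP", "IPD", "HC", "MSA"), pool_msa = TRUE,
               include_hc = TRUE, chance = 1 / 4),
    III = list(classes = c("PSP", "IPD", "MSA-P", "MSA-C"), pool_msa = FALSE,
               include_hc = FALSE, chance = 1 / 4),
    IV  = list(classes = c("PSP", "IPD", "HC", "MSA-P", "MSA-C"),
               pool_msa = FALSE, include_hc = TRUE, chance = 1 / 5),
    stop("unknown contrast '", contrast, "' (use I, II, III or IV)"))
}

#' Map cohort subtype labels onto a contrast's class structure
#'
#' Pools MSA-P/MSA-C into MSA where the contrast requires it and drops
#' subjects from classes the contrast excludes (HCs for contrasts I/III).
#'
#' @param labels character vector of subtype labels (HC, PSP, IPD, MSA-P,
#'   MSA-C; an already-pooled MSA is accepted).
#' @param contrast contrast id, see [contrast_classes()].
#' @return list with \code{labels} (factor over the contrast's classes) and
#'   \code{keep} (logical index into the input).
#' @export
map_contrast_labels <- function(labels, contrast) {
  ct <- contrast_classes(contrast)
  labels <- as.character(labels)
  if (ct$pool_msa) labels[labels %in% c("MSA-P", "MSA-C")] <- "MSA"
  keep <- labels %in% ct$classes
  list(labels = factor(labels[keep], levels = ct$classes), keep = keep)
}

#' Default experiment configuration
#'
#' One top-level seed derives all component seeds through [derive_seed()]
#' (offsets: 1 cohort, 2 classifier, 3 permutations).
#'
#' @param out_dir output directory.
#' @param seed top-level seed.
#' @param grid_dims cohort grid.
#' @param mask mask name for feature extraction.
#' @param contrast diagnostic contrast (I-IV).
#' @param n_samples,n_burnin sampler settings.
#' @param n_perm permutation count for [cmd_permute()].
#' @param n_per_class optional named per-class size override.
#' @param effect_scale multiplier applied to the default effect matrix.
#' @return an \code{experiment_config} list.
#' @export
experiment_config <- function(out_dir = "neuroprobit-run", seed = 1L,
                              grid_dims = c(32, 32, 32),
                              mask = "subcortical_network",
                              contrast = "II",
                              n_samples = 2000, n_burnin = 500,
                              n_perm = 999,
                              n_per_class = NULL,
                              effect_scale = 1) {
  cfg <- list(out_dir = out_dir, seed = as.integer(seed),
              grid_dims = as.integer(grid_dims), mask = mask,
              contrast = contrast, n_samples = n_samples,
              n_burnin = n_burnin, n_perm = n_perm,
              n_per_class = n_per_class, effect_scale = effect_scale)
  structure(cfg, class = "experiment_config")
}

#' Read / write an experiment configuration as YAML
#'
#' @param path YAML file path.
#' @return an \code{experiment_config}.
#' @export
read_experiment_config <- function(path) {
  if (!file.exists(path)) stop("missing config file '", path, "'")
  raw <- yaml::read_yaml(path)
  cfg <- experiment_config()
  for (nm in intersect(names(raw), names(cfg))) cfg[[nm]] <- raw[[nm]]
  cfg$seed <- as.integer(cfg$seed)
  cfg$grid_dims <- as.integer(cfg$grid_dims)
  if (!is.null(cfg$n_per_class)) cfg$n_per_class <- unlist(cfg$n_per_class)
  cfg
}

#' @rdname read_experiment_config
#' @param cfg an \code{experiment_config}.
#' @export
write_experiment_config <- function(cfg, path) {
  lst <- unclass(cfg)
  # named counts must serialize as a YAML map, not a bare sequence
  if (!is.null(lst$n_per_class)) lst$n_per_class <- as.list(lst$n_per_class)
  yaml::write_yaml(lst, path)
  invisible(path)
}

.experiment_design <- function(cfg) {
  em <- default_effect_matrix() * cfg$effect_scale
  npc <- c(HC = 19, PSP = 17, IPD = 14, `MSA-P` = 12, `MSA-C` = 7)
  if (!is.null(cfg$n_per_class)) npc[names(cfg$n_per_class)] <- cfg$n_per_class
  cohort_design(n_per_class = npc, effect_matrix = em,
                seed = derive_seed(cfg$seed, 1L))
}

#' Simulate a cohort to disk
#'
#' With default settings this writes a 69-subject cohort (19 HC, 17 PSP,
#' 14 IPD, 12 MSA-P, 7 MSA-C) of two-channel volumes plus atlas, label CSV
#' and manifest under \code{file.path(cfg$out_dir, "cohort")}.
#'
#' @param cfg an \code{experiment_config}.
#' @return (invisibly) the cohort directory.
#' @export
cmd_simulate <- function(cfg) {
  atlas <- default_atlas(cfg$grid_dims)
  cohort <- generate_cohort(atlas, .experiment_design(cfg))
  dir <- file.path(cfg$out_dir, "cohort")
  write_cohort(cohort, atlas, dir)
  message("wrote ", length(cohort$images), "-subject cohort to ", dir)
  invisible(dir)
}

.load_or_fail <- function(cfg) {
  dir <- file.path(cfg$out_dir, "cohort")
  if (!file.exists(file.path(dir, "manifest.json")))
    stop("no cohort at '", dir, "'; run cmd_simulate first")
  read_cohort(dir)
}

.experiment_features <- function(cfg, cohort) {
  mp <- map_contrast_labels(cohort$labels$class, cfg$contrast)
  fm <- extract_features(cohort$images[mp$keep], cohort$atlas, cfg$mask)
  list(features = fm, labels = mp$labels)
}

#' Run the cross-validated classifier for a configured contrast
#'
#' Loads the cohort, maps labels onto the contrast, extracts masked
#' features, runs LOO-CV and writes JSON metrics plus CSV confusion matrix
#' and per-class metric tables to the output directory.
#'
#' @param cfg an \code{experiment_config}.
#' @return the \code{cv_result}, invisibly.
#' @export
cmd_run <- function(cfg) {
  cohort <- .load_or_fail(cfg)
  ef <- .experiment_features(cfg, cohort)
  config <- mnp_config(n_samples = cfg$n_samples, n_burnin = cfg$n_burnin,
                       seed = derive_seed(cfg$seed, 2L))
  cv <- loo_cross_validate(ef$features, ef$labels, config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  base <- sprintf("contrast_%s_%s", cfg$contrast,
                  gsub("[^A-Za-z0-9]+", "_", cfg$mask))
  write.csv(as.data.frame.matrix(cv$confusion),
            file.path(cfg$out_dir, paste0(base, "_confusion.csv")))
  mt <- cv$metrics
  write.csv(data.frame(class = names(mt$sensitivity),
                       sensitivity = mt$sensitivity,
                       predictive_value = mt$predictive_value,
                       chance = mt$per_class_chance),
            file.path(cfg$out_dir, paste0(base, "_metrics.csv")),
            row.names = FALSE)
  jsonlite::write_json(
    list(contrast = cfg$contrast, mask = cfg$mask,
         seed = cfg$seed, classifier_seed = config$seed,
         n_folds = cv$n_folds,
         class_names = cv$class_names,
         confusion = unclass(as.matrix(cv$confusion)),
         probabilities = cv$probabilities,
         balanced_accuracy = mt$balanced_accuracy,
         overall_predictive_value = mt$overall_predictive_value,
         chance_accuracy = mt$chance_accuracy,
         sensitivity = as.list(mt$sensitivity),
         predictive_value = as.list(mt$predictive_value)),
    file.path(cfg$out_dir, paste0(base, "_cv.json")),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(cv)
}

#' Permutation significance of the configured contrast
#'
#' @param cfg an \code{experiment_config}.
#' @return the \code{permutation_result}, invisibly.
#' @export
cmd_permute <- function(cfg) {
  cohort <- .load_or_fail(cfg)
  ef <- .experiment_features(cfg, cohort)
  config <- mnp_config(n_samples = cfg$n_samples, n_burnin = cfg$n_burnin,
                       seed = derive_seed(cfg$seed, 2L))
  pr <- permutation_test(ef$features, ef$labels, n_perm = cfg$n_perm,
                         seed = derive_seed(cfg$seed, 3L), config = config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(
    list(contrast = cfg$contrast, mask = cfg$mask, seed = cfg$seed,
         observed = pr$observed, p = pr$p, n_perm = pr$n_perm,
         marker = significance_marker(pr$p), permuted = pr$permuted),
    file.path(cfg$out_dir, sprintf("contrast_%s_permutation.json",
                                   cfg$contrast)),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(pr)
}

#' Fit on the full cohort and export voxel weight maps
#'
#' @param cfg an \code{experiment_config}.
#' @return the \code{weight_map}, invisibly.
#' @export
cmd_maps <- function(cfg) {
  cohort <- .load_or_fail(cfg)
  ef <- .experiment_features(cfg, cohort)
  prep <- fit_fold_preprocessor(ef$features)
  fm <- apply_preprocessor(prep, ef$features)
  K <- linear_kernel(fm)
  config <- mnp_config(n_samples = cfg$n_samples, n_burnin = cfg$n_burnin,
                       seed = derive_seed(cfg$seed, 2L))
  post <- fit_mnp(K, ef$labels, config)
  maps <- compute_weight_maps(post, fm, cohort$atlas, cfg$mask)
  export_weight_maps(maps, cohort$atlas, file.path(cfg$out_dir, "maps"))
  invisible(maps)
}
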