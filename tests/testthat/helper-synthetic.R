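# Shared fixtures: small atlases and cohort designs built in code.

tiny_atlas <- function(n = 16) default_atlas(c(n, n, n))

region_names6 <- colnames(default_effect_matrix())

# Three artificial classes, each with a planted shift (in noise-SD units)
# in its own region; effect = 0 gives a null cohort.
planted_design <- function(n_per_class = 8, effect = 3, seed = 1,
                           subject_scale_sd = 0.05) {
  em <- matrix(0, 3, 6, dimnames = list(c("A", "B", "C"), region_names6))
  em["A", "brainstem"] <- effect
  em["B", "cerebellum"] <- effect
  em["C", "putamen"] <- effect
  cohort_design(class_names = c("A", "B", "C"),
                n_per_class = setNames(rep(n_per_class, 3), c("A", "B", "C")),
                effect_matrix = em, seed = seed,
                subject_scale_sd = subject_scale_sd)
}

# sampler settings small enough for per-fold use in loops
fast_config <- function(seed = 1, n_samples = 100, n_burnin = 50) {
  mnp_config(n_samples = n_samples, n_burnin = n_burnin, seed = seed)
}

region_label_of <- function(atlas, region) {
  as.integer(names(atlas$region_names)[atlas$region_names == region])
}
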