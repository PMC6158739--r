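# Shared fixture builders for the test suite (all generated in code).

# minimal single-region cohort configuration; tract-level noise is
# noise_sd / sqrt(n skeleton voxels)
single_region_config <- function(onset = -10, slope = 1.5e-6,
                                 noise_sd = 1.8e-4, seed = 1,
                                 n_carriers = 64, n_noncarriers = 45, ...) {
  cohort_config(
    n_carriers = n_carriers, n_noncarriers = n_noncarriers,
    grid_shape = c(16L, 16L, 8L), skeleton_fraction = 0.15,
    effect_map = list(whole_skeleton = list(onset = onset, slope = slope)),
    effect_heterogeneity = 0,
    noise_sd = noise_sd, seed = seed, ...
  )
}

# small subject table with both groups and covariates
small_subjects <- function(n = 40, seed = 1) {
  withr::with_seed(seed, data.frame(
    subject_id = sprintf("s%02d", seq_len(n)),
    mutation_carrier = rep(c(TRUE, FALSE), length.out = n),
    eyo = runif(n, -25, 10),
    sex = rbinom(n, 1, 0.5),
    education = sample(10:20, n, replace = TRUE),
    cdr_positive = FALSE,
    stringsAsFactors = FALSE
  ))
}

# random t-like 3-D map and mask
random_map <- function(d = c(6, 6, 6), seed = 1, p_mask = 0.8) {
  withr::with_seed(seed, {
    list(stat = array(rnorm(prod(d)), dim = d),
         mask = array(runif(prod(d)) < p_mask, dim = d))
  })
}
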