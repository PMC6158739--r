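test_that("design matrix follows the fixed coding", {
  sub <- small_subjects(12, seed = 20)
  sub$mutation_carrier[1:2] <- c(TRUE, FALSE)
  sub$eyo[1:2] <- c(-10, 4)
  sub$sex[1:2] <- c(0, 1)
  sub$education[1:2] <- c(14, 12)
  X <- build_design(sub)
  expect_equal(colnames(X), c("intercept", "eyo", "mutation",
                              "eyo_x_mutation", "sex", "education"))
  expect_equal(unname(X[1, ]), c(1, -10, 1, -10, 0, 14))
  # non-carrier rows have a zero interaction entry
  expect_equal(unname(X[2, "eyo_x_mutation"]), 0)
  # single-group cohorts are rank deficient
  allcar <- small_subjects(10)
  allcar$mutation_carrier <- TRUE
  expect_error(build_design(allcar), "rank deficient")
  allcar$mutation_carrier[1] <- NA
  expect_error(build_design(allcar), "missing covariate")
})

test_that("GLM t-statistics match the lm() oracle", {
  sub <- small_subjects(200, seed = 21)
  X <- build_design(sub)
  withr::with_seed(22, {
    Y <- matrix(2 + 3 * sub$eyo + rnorm(200), ncol = 1)
  })
  for (cvec in list(c(0, 1, 0, 0, 0, 0), c(0, 0, 0, 1, 0, 0),
                    c(0, 1, 0, 1, 0, 0))) {
    sm <- fit_glm_tmap(Y, X, cvec)
    expect_equal(sm$t[1], oracle_ols_t(Y[, 1], X, cvec), tolerance = 1e-8)
  }
  expect_equal(sm$dof, 200 - 6)
  expect_error(fit_glm_tmap(Y, X, rep(0, 6)), "zero vector")
  expect_error(fit_glm_tmap(Y[1:100, , drop = FALSE], X, c(0, 1, 0, 0, 0, 0)),
               "misaligned")
})

test_that("null t-maps are calibrated and zero-variance voxels are flagged", {
  sub <- small_subjects(100, seed = 23)
  X <- build_design(sub)
  withr::with_seed(24, Y <- matrix(rnorm(100 * 2000), nrow = 100))
  sm <- fit_glm_tmap(Y, X, c(0, 0, 0, 1, 0, 0))
  rate <- mean(abs(sm$t) > qt(0.975, sm$dof))
  expect_gt(rate, 0.03)
  expect_lt(rate, 0.07)
  # a constant voxel yields t = 0 with a warning
  Y[, 1] <- 5
  expect_warning(sm0 <- fit_glm_tmap(Y, X, c(0, 0, 0, 1, 0, 0)),
                 "zero residual variance")
  expect_equal(sm0$t[1], 0)
  expect_true(sm0$zero_variance[1])
})

test_that("TFCE reproduces closed-form and constructed cases", {
  d <- c(5, 5, 5)
  full <- array(TRUE, dim = d)
  zero <- array(0, dim = d)
  expect_equal(tfce_enhance(zero, full), zero)
  # single voxel of height 1, H=2, E=0.5, dh=0.1:
  # sum_{h=0.1..1.0} 1^0.5 * h^2 * 0.1 = 0.385
  tm <- zero; tm[3, 3, 3] <- 1
  enh <- tfce_enhance(tm, full, tfce_params(dh = 0.1))
  expect_equal(enh[3, 3, 3], 0.385, tolerance = 1e-10)
  # two adjacent equal voxels beat the same voxels far apart (extent term)
  near <- zero; near[2, 2, 2] <- 1; near[3, 2, 2] <- 1
  far <- zero; far[1, 1, 1] <- 1; far[5, 5, 5] <- 1
  e_near <- tfce_enhance(near, full, tfce_params(dh = 0.1))
  e_far <- tfce_enhance(far, full, tfce_params(dh = 0.1))
  expect_gt(e_near[2, 2, 2], e_far[1, 1, 1])
  expect_equal(e_near[2, 2, 2], sqrt(2) * 0.385, tolerance = 1e-10)
  # negative lobes are enhanced on the negated map
  neg <- zero; neg[3, 3, 3] <- -1
  expect_equal(tfce_enhance(neg, full, tfce_params(dh = 0.1))[3, 3, 3],
               -0.385, tolerance = 1e-10)
  expect_error(tfce_params(dh = 0), "dh")
})

test_that("fast TFCE equals the naive per-threshold oracle", {
  for (s in 1:20) {
    rm <- random_map(c(6, 6, 6), seed = s)
    for (conn in c(6L, 26L)) {
      fast <- tfce_enhance(rm$stat, rm$mask,
                           tfce_params(connectivity = conn, dh = 0.05))
      naive <- oracle_tfce(rm$stat * rm$mask, rm$mask, dh = 0.05,
                           connectivity = conn)
      expect_equal(fast, naive, tolerance = 1e-10)
    }
  }
})

test_that("TFCE is monotone and respects component relabelling", {
  rm <- random_map(c(6, 6, 6), seed = 99)
  pos <- abs(rm$stat)
  e1 <- tfce_enhance(pos, rm$mask, tfce_params(dh = 0.05))
  e2 <- tfce_enhance(pos + 0.5, rm$mask, tfce_params(dh = 0.05))
  on <- rm$mask
  expect_true(all(e2[on] >= e1[on] - 1e-12))
  # mirroring the grid relabels disconnected components without changing values
  flip <- function(a) a[dim(a)[1]:1, , ]
  e_flip <- tfce_enhance(flip(pos), flip(rm$mask), tfce_params(dh = 0.05))
  expect_equal(flip(e1), e_flip, tolerance = 1e-12)
})

test_that("permutation p-values respect their bounds and reproduce", {
  co <- generate_cohort(single_region_config(seed = 31, n_carriers = 12,
                                             n_noncarriers = 12))
  X <- build_design(co$subjects)
  cvec <- c(0, 0, 0, 1, 0, 0)
  # n_perm = 1: every p-value is 1
  r1 <- permutation_fwe(co$md, X, cvec, co$mask, n_perm = 1, seed = 1)
  expect_true(all(r1$fwe_p == 1))
  r <- permutation_fwe(co$md, X, cvec, co$mask, n_perm = 25, seed = 7)
  expect_true(all(r$fwe_p >= 1 / 25 & r$fwe_p <= 1))
  expect_length(r$max_stat_null, 25)
  r2 <- permutation_fwe(co$md, X, cvec, co$mask, n_perm = 25, seed = 7)
  expect_identical(r$fwe_p, r2$fwe_p)
  expect_error(permutation_fwe(co$md, X, rep(0, 6), co$mask, n_perm = 5),
               "zero vector")
})

test_that("a strongly planted interaction is detected where planted", {
  cfg <- single_region_config(onset = -25, slope = 1e-5, noise_sd = 1e-5,
                              seed = 32, n_carriers = 30, n_noncarriers = 30)
  co <- generate_cohort(cfg)
  X <- build_design(co$subjects)
  r <- permutation_fwe(co$md, X, c(0, 0, 0, 1, 0, 0), co$mask,
                       n_perm = 100, seed = 5)
  expect_lt(min(r$fwe_p), 0.05)
  expect_gt(mean(r$fwe_p <= 0.05), 0.95)  # nearly all planted voxels found
})

test_that("group contrasts find group-specific effects only where planted", {
  co <- generate_cohort(single_region_config(slope = 0, noise_sd = 2e-5,
                                             seed = 33, n_carriers = 30,
                                             n_noncarriers = 20))
  sub <- co$subjects
  sub$cdr_positive <- sub$mutation_carrier & seq_len(nrow(sub)) %% 2 == 0
  md <- co$md
  # plant an increase in symptomatic carriers only
  md[sub$cdr_positive, ] <- md[sub$cdr_positive, ] + 1e-4
  maps <- group_contrast_maps(md, sub)
  expect_named(maps, c("symptomatic_vs_noncarrier",
                       "asymptomatic_vs_noncarrier",
                       "symptomatic_vs_asymptomatic"))
  expect_gt(median(maps$symptomatic_vs_noncarrier$t), 5)
  expect_lt(abs(median(maps$asymptomatic_vs_noncarrier$t)), 2)
  # an empty/singleton group errors
  sub2 <- sub
  sub2$cdr_positive <- FALSE
  sub2$cdr_positive[1] <- TRUE
  sub2$mutation_carrier[1] <- TRUE
  expect_error(group_contrast_maps(md, sub2), ">= 2 subjects")
})

test_that("binarized map intersection is a logical AND", {
  a <- array(c(TRUE, TRUE, FALSE, FALSE), dim = c(2, 2, 1))
  b <- array(c(TRUE, FALSE, TRUE, FALSE), dim = c(2, 2, 1))
  expect_equal(intersect_binarized_maps(list(a, a)), a)
  expect_equal(sum(intersect_binarized_maps(list(a, !a))), 0)
  expect_equal(intersect_binarized_maps(list(a & b, b)), a & b)  # subset wins
  expect_error(intersect_binarized_maps(list(a, array(TRUE, c(3, 1, 1)))),
               "common grid")
})
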