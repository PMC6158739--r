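toy_atlas <- function() {
  labels <- array(0L, dim = c(10, 10, 1))
  labels[1:5, , 1] <- 1L
  labels[6:10, , 1] <- 2L
  list(labels = labels,
       tracts = data.frame(label = 1:2, tract = c("alpha", "beta"),
                           stringsAsFactors = FALSE))
}

test_that("tract ROI construction applies the exclusion rule", {
  atlas <- toy_atlas()
  full <- array(TRUE, dim = dim(atlas$labels))
  rois <- build_tract_rois(atlas, full)
  expect_equal(rois[[1]]$frac_sig, 1)
  expect_equal(sum(rois[[1]]$mask), 50)
  # disjoint significance, not a priori -> excluded
  none <- array(FALSE, dim = dim(atlas$labels))
  rois0 <- build_tract_rois(atlas, none)
  expect_false(rois0[[1]]$included)
  # 12 significant of 1000 -> frac 0.012 < 0.02 threshold (exclusion band)
  labels <- array(1L, dim = c(10, 10, 10))
  atlas2 <- list(labels = labels,
                 tracts = data.frame(label = 1L, tract = "gamma"))
  sig <- array(FALSE, dim = dim(labels))
  sig[1:12] <- TRUE
  roi <- build_tract_rois(atlas2, sig)[[1]]
  expect_equal(roi$frac_sig, 0.012)
  expect_false(roi$included)
  # ... but an a-priori tract stays in
  roi_ap <- build_tract_rois(atlas2, sig, a_priori = "gamma")[[1]]
  expect_true(roi_ap$included)
  expect_error(build_tract_rois(atlas, full, a_priori = "nope"), "unknown")
})

test_that("ROI averaging is the arithmetic mean", {
  atlas <- toy_atlas()
  roi <- build_tract_rois(atlas, array(TRUE, dim = dim(atlas$labels)))[[1]]
  vol <- array(0, dim = dim(atlas$labels))
  expect_equal(average_md(vol + 3, roi), 3)
  vol[1] <- 2; vol[2] <- 8
  two <- roi
  two$mask <- array(FALSE, dim = dim(vol)); two$mask[1:2] <- TRUE
  expect_equal(average_md(vol, two), 5)
  withr::with_seed(41, vals <- rnorm(prod(dim(vol))))
  expect_equal(average_md(array(vals, dim = dim(vol)), roi),
               sum(vals[roi$mask]) / sum(roi$mask))
  two$mask[] <- FALSE
  expect_error(average_md(vol, two), "empty")
})

test_that("Tukey filter removes the documented upper-tail cases", {
  # hand-computed: median 4, Q1 3, Q3 5, IQR 2, cutoff 7 -> remove the 30
  v <- c(2, 3, 4, 5, 30)
  f <- tukey_filter(v, rep("g", 5))
  expect_equal(f$removed, 5L)
  expect_equal(f$kept, 1:4)
  # all equal: IQR 0 but nothing exceeds the median
  f0 <- tukey_filter(rep(1, 6), rep("g", 6))
  expect_length(f0$removed, 0)
  # groups are filtered independently
  v2 <- c(2, 3, 4, 5, 30, 100, 100, 100, 100)
  f2 <- tukey_filter(v2, rep(c("a", "b"), c(5, 4)))
  expect_equal(f2$removed, 5L)  # the 100s are normal for group b
  expect_error(tukey_filter(1:3, rep("a", 3)), "fewer than 4")
})

test_that("Tukey filter matches a direct re-implementation on Gaussian data", {
  withr::with_seed(42, x <- rnorm(1000))
  f <- tukey_filter(x, rep("g", 1000))
  cut <- median(x) + 1.5 * (quantile(x, 0.75, type = 7) -
                              quantile(x, 0.25, type = 7))
  expect_equal(sort(f$removed), which(x > cut))
  # nothing removed when all data lie inside the fences
  y <- pmin(x, cut - 0.01)
  expect_length(tukey_filter(y, rep("g", 1000))$removed, 0)
  # the median-anchored fence sits at ~2.02 sigma on Gaussians, so the
  # expected upper-tail removal rate is ~2.2%
  expect_lt(length(f$removed) / 1000, 0.04)
  expect_gt(length(f$removed) / 1000, 0.005)
})

test_that("robust regression equals OLS on clean data and resists outliers", {
  withr::with_seed(43, {
    x <- runif(50, 0, 10)
    y <- 1 + 2 * x + rnorm(50, 0, 0.3)
  })
  X <- cbind(intercept = 1, x = x)
  # huge tuning constant -> OLS
  fit <- robust_fit(y, X, k = 1e9)
  ols <- lm(y ~ x)
  expect_equal(unname(fit$beta), unname(coef(ols)), tolerance = 1e-8)
  expect_true(fit$converged)
  expect_true(all(eigen(fit$cov, symmetric = TRUE)$values >= -1e-12))
  expect_equal(fit$se, sqrt(diag(fit$cov)), tolerance = 1e-12)
  # one gross high-leverage outlier: robust slope stays near 2, OLS doesn't
  xo <- c(x, 20); yo <- c(y, -200)
  Xo <- cbind(intercept = 1, x = xo)
  fro <- robust_fit(yo, Xo)
  olso <- coef(lm(yo ~ xo))[2]
  expect_lt(abs(fro$beta[["x"]] - 2), 0.05)
  expect_gt(abs(olso - 2), 0.2)
  # constant response: zero slope, intercept equals the constant
  fc <- robust_fit(rep(4, 20), cbind(intercept = 1, x = seq_len(20)))
  expect_equal(unname(fc$beta), c(4, 0))
  expect_error(robust_fit(y[1:2], X[1:2, ]), "more observations")
})

test_that("EYO ordering follows the closed-form difference arithmetic", {
  mk_fit <- function(bm, bi, vm, vi, cmi) {
    beta <- c(intercept = 0, eyo = 0, mutation = bm, eyo_x_mutation = bi,
              sex = 0, education = 0)
    cov <- diag(1e-12, 6)
    dimnames(cov) <- list(names(beta), names(beta))
    cov["mutation", "mutation"] <- vm
    cov["eyo_x_mutation", "eyo_x_mutation"] <- vi
    cov["mutation", "eyo_x_mutation"] <- cmi
    cov["eyo_x_mutation", "mutation"] <- cmi
    structure(list(beta = beta, cov = cov, se = sqrt(diag(cov))),
              class = "robust_fit")
  }
  grid <- seq(-25, 10, 5)
  # zero effects: no abnormality at any grid point
  ord0 <- eyo_ordering(mk_fit(0, 0, 1, 0.01, 0), grid)
  expect_true(is.na(ord0$earliest_abnormal))
  # positive interaction, vanishing covariance: diff(e) = e * bi, so the
  # first positive-diff grid point is the earliest abnormal one
  ordp <- eyo_ordering(mk_fit(0, 1, 1e-12, 1e-12, 0), grid)
  expect_equal(ordp$table$diff, grid)
  expect_equal(ordp$earliest_abnormal, 5)   # first e > 0 on the grid
  expect_equal(ordp$interval, c(0, 5))
  # two-sided rule also flags the negative lobe
  ord2 <- eyo_ordering(mk_fit(0, 1, 1e-12, 1e-12, 0), grid,
                       direction = "two.sided")
  expect_equal(ord2$earliest_abnormal, -25)
  # diff is affine in e and the CI width is convex, minimised at -cov/var
  fit <- mk_fit(2, 0.5, 1, 0.04, 0.1)
  ord <- eyo_ordering(fit, grid)
  expect_equal(ord$table$diff, 2 + grid * 0.5)
  w <- ord$table$ci_high - ord$table$ci_low
  estar <- -0.1 / 0.04
  expect_equal(grid[which.min(w)], grid[which.min(abs(grid - estar))])
  expect_true(all(diff(w)[grid[-1] <= estar] <= 1e-9))
  expect_error(eyo_ordering(fit, numeric(0)), "grid is empty")
})

test_that("ordering is equivariant to shifting EYO and grid together", {
  co <- generate_cohort(single_region_config(seed = 44))
  sub <- co$subjects
  avg <- rowMeans(co$md)
  fit1 <- robust_fit(avg, build_design(sub))
  shift <- 7
  sub2 <- sub
  sub2$eyo <- sub$eyo + shift
  fit2 <- robust_fit(avg, build_design(sub2))
  g <- seq(-25, 10, 5)
  o1 <- eyo_ordering(fit1, g)
  o2 <- eyo_ordering(fit2, g + shift)
  expect_equal(o1$table$diff, o2$table$diff, tolerance = 1e-6)
  expect_equal(o1$earliest_abnormal + shift, o2$earliest_abnormal)
})

test_that("the ordering suite recovers planted onsets and their ranking", {
  # planted onsets at -10 and 0 in one cohort: the -10 region is detected
  # earlier; tract-level sigma/slope ~ 7 (design point from the power
  # analysis in the methods vignette)
  cfg <- cohort_config(
    n_carriers = 64, n_noncarriers = 45,
    grid_shape = c(16L, 16L, 8L), skeleton_fraction = 0.3,
    effect_map = list(early = list(onset = -10, slope = 1.5e-6),
                      late = list(onset = 0, slope = 1.5e-6)),
    effect_heterogeneity = 0, noise_sd = 1.6e-4, seed = 45
  )
  co <- generate_cohort(cfg)
  meas <- tract_md_table(co$md, co$mask,
                         build_tract_rois(co$atlas,
                                          array(TRUE, dim = dim(co$mask))),
                         co$subjects$subject_id)
  suite <- run_ordering_suite(meas, co$subjects)
  s <- suite$summary
  expect_equal(nrow(s), 2)
  early <- s$earliest_abnormal[s$measure == "early"]
  late <- s$earliest_abnormal[s$measure == "late"]
  expect_lt(early, late)
  # single measure input gives a single row
  one <- run_ordering_suite(meas[meas$measure == "early", ], co$subjects)
  expect_equal(nrow(one$summary), 1)
})

test_that("bootstrap CIs agree with delta-method CIs on regular data", {
  co <- generate_cohort(single_region_config(seed = 47))
  meas <- data.frame(subject_id = co$subjects$subject_id,
                     measure = "region", value = rowMeans(co$md))
  delta <- run_ordering_suite(meas, co$subjects)
  boot <- run_ordering_suite(meas, co$subjects, ci_method = "bootstrap",
                             n_boot = 400, boot_seed = 3)
  td <- delta$details$region$ordering$table
  tb <- boot$details$region$ordering$table
  # same point estimates; CI widths of the same order (the bootstrap also
  # propagates the per-draw Tukey filtering, so it runs somewhat wider where
  # the filter bites)
  expect_equal(tb$diff, td$diff, tolerance = 1e-9)
  wd <- td$ci_high - td$ci_low
  wb <- tb$ci_high - tb$ci_low
  expect_true(all(wb / wd > 0.6 & wb / wd < 1.7))
  # bootstrap reruns reproduce under the same seed
  boot2 <- run_ordering_suite(meas, co$subjects, ci_method = "bootstrap",
                              n_boot = 400, boot_seed = 3)
  expect_identical(tb, boot2$details$region$ordering$table)
})

test_that("noiseless planted data is recovered to grid resolution", {
  # with sigma -> 0 the linear fit to a ramp crosses significance one grid
  # step before the true onset; recovery is exact to one 5-EYO step
  cfg <- single_region_config(onset = -10, slope = 1e-6, noise_sd = 1e-9,
                              seed = 46)
  co <- generate_cohort(cfg)
  meas <- data.frame(subject_id = co$subjects$subject_id,
                     measure = "region", value = rowMeans(co$md))
  # without noise the late-EYO carriers genuinely exceed the Tukey fence,
  # so the ">5 removed" warning is expected here
  suite <- suppressWarnings(run_ordering_suite(meas, co$subjects))
  expect_true(abs(suite$summary$earliest_abnormal - (-10)) <= 5)
})
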