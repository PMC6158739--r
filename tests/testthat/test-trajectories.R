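test_that("ICV adjustment removes head-size dependence", {
  withr::with_seed(51, {
    icv <- rnorm(80, 1.5e6, 1e5)
    noise <- rnorm(80, 0, 10)
  })
  # volumes exactly orthogonal to icv (b = 0): adjustment is the identity
  ortho <- 5000 + resid(lm(noise ~ icv))
  adj0 <- adjust_for_icv(ortho, icv)
  expect_equal(adj0, ortho, tolerance = 1e-9, ignore_attr = TRUE)
  # volumes = 2 * icv exactly: adjusted values are constant
  adj <- adjust_for_icv(2 * icv, icv)
  expect_equal(diff(range(adj)), 0, tolerance = 1e-6)
  expect_error(adjust_for_icv(1, 1.5e6), ">= 2")
  expect_error(adjust_for_icv(c(1, 2), c(1e6, 1e6)), "degenerate")
  # slope is estimated in the reference group only
  vol <- 2 * icv
  vol[1:40] <- vol[1:40] + 100  # group effect, not head size
  adj_ref <- adjust_for_icv(vol, icv, reference = c(rep(FALSE, 40),
                                                    rep(TRUE, 40)))
  expect_equal(diff(range(adj_ref[41:80])), 0, tolerance = 1e-6)
  expect_equal(mean(adj_ref[1:40]) - mean(adj_ref[41:80]), 100,
               tolerance = 1e-6)
})

test_that("AIC forward selection recovers the generating order", {
  sub <- small_subjects(300, seed = 52)
  recover <- function(gen_order, nrep = 20) {
    hits <- 0
    for (r in seq_len(nrep)) {
      withr::with_seed(1000 + r, {
        g <- as.numeric(sub$mutation_carrier)
        y <- 1 + 0.3 * sub$eyo + 0.5 * g + 0.4 * sub$eyo * g +
          (if (gen_order >= 2) 0.05 * sub$eyo^2 + 0.04 * sub$eyo^2 * g else 0) +
          rnorm(300, 0, 2)
      })
      m <- fit_trajectory(y, sub, max_order = 3)
      hits <- hits + (m$selected_order == gen_order)
    }
    hits / nrep
  }
  # with a two-parameter step and an AIC penalty of 4, the chance of one
  # spurious extra order is P(chisq_2 > 4) ~ 13.5%, so recovery sits near 86%
  expect_gte(recover(1), 0.7)
  expect_gte(recover(2), 0.7)
})

test_that("pure noise stops at the starting (linear) model", {
  sub <- small_subjects(200, seed = 53)
  withr::with_seed(54, y <- rnorm(200))
  m <- fit_trajectory(y, sub, max_order = 3)
  expect_equal(m$selected_order, 1L)
  # interaction coefficient is consistent with zero
  b <- m$fit$beta[["carrier_eyo1"]]
  expect_lt(abs(b) / m$fit$se[["carrier_eyo1"]], 3)
  expect_true(all(is.finite(m$aic_path)))
  # deterministic stopping: same data, same path
  m2 <- fit_trajectory(y, sub, max_order = 3)
  expect_identical(m$aic_path, m2$aic_path)
  onegrp <- sub
  onegrp$mutation_carrier <- TRUE
  expect_error(fit_trajectory(y, onegrp), "both groups")
})

test_that("curve prediction is exact polynomial evaluation", {
  sub <- small_subjects(100, seed = 55)
  g <- as.numeric(sub$mutation_carrier)
  y <- 2 - 0.1 * sub$eyo + 1.5 * g + 0.3 * sub$eyo * g
  m <- fit_trajectory(y, sub, max_order = 2)
  grid <- c(-20, -5, 5)
  cv <- predict_curves(m, grid)
  b <- m$fit$beta
  horner <- function(e, carrier) {
    # independent evaluation: Horner on the fitted coefficients
    base <- c(b[["intercept"]], b[grep("^eyo", names(b))])
    int <- c(b[["carrier"]], b[grep("^carrier_eyo", names(b))])
    co <- base + carrier * int
    Reduce(function(acc, ck) acc * e + ck, rev(co), accumulate = FALSE)
  }
  expect_equal(cv$carrier, vapply(grid, horner, numeric(1), carrier = 1),
               tolerance = 1e-12)
  expect_equal(cv$noncarrier, vapply(grid, horner, numeric(1), carrier = 0),
               tolerance = 1e-12)
  # noiseless linear truth: curves match the generating polynomials
  expect_equal(cv$noncarrier, 2 - 0.1 * grid, tolerance = 1e-8)
  expect_equal(cv$carrier, 3.5 + 0.2 * grid, tolerance = 1e-8)
})

test_that("zero interaction gives identical group curves", {
  sub <- small_subjects(150, seed = 56)
  y <- 1 + 0.2 * sub$eyo
  m <- fit_trajectory(y, sub, max_order = 2)
  cv <- predict_curves(m, seq(-20, 5, 5))
  expect_equal(cv$carrier, cv$noncarrier, tolerance = 1e-6)
})

test_that("standardized non-carrier curves are centred on the cohort", {
  sub <- small_subjects(200, seed = 57)
  withr::with_seed(58, y <- 5 + 0.3 * sub$eyo + rnorm(200))
  m <- fit_trajectory(y, sub)
  nc_eyo <- sub$eyo[!sub$mutation_carrier]
  cv <- suppressWarnings(predict_curves(m, nc_eyo, standardize = TRUE))
  expect_equal(mean(cv$noncarrier), 0, tolerance = 1e-8)
  # sign flip points the abnormal direction upward
  cv_dn <- suppressWarnings(predict_curves(m, nc_eyo, standardize = TRUE,
                                           abnormal_direction = -1))
  expect_equal(cv_dn$noncarrier, -cv$noncarrier)
})

test_that("PSMD-biomarker associations are calibrated and recover effects", {
  sub <- small_subjects(128, seed = 59)
  ids <- sub$subject_id
  withr::with_seed(60, {
    psmd_vals <- rnorm(128, 2e-4, 2e-5)
    null_bm <- rnorm(128, 100, 10)
    # planted standardized B = -0.5
    linked <- -0.5 * as.numeric(scale(psmd_vals)) * 10 + rnorm(128, 0, 8.66)
  })
  psmd <- data.frame(subject_id = ids, psmd = psmd_vals)
  bm <- rbind(data.frame(subject_id = ids, measure = "null_marker",
                         value = null_bm),
              data.frame(subject_id = ids, measure = "linked_marker",
                         value = linked))
  res <- associate_psmd_biomarkers(psmd, bm, sub, carrier_only = FALSE)
  expect_equal(nrow(res), 2)
  null_row <- res[res$measure == "null_marker", ]
  link_row <- res[res$measure == "linked_marker", ]
  expect_lt(abs(null_row$B), 0.3)
  expect_gt(null_row$p, 0.001)
  expect_lt(abs(link_row$B - (-0.5)), 2 * link_row$SE + 0.1)
  expect_lt(link_row$p, 0.01)
  # single biomarker -> single row; empty group errors
  one <- associate_psmd_biomarkers(psmd, bm, sub, measures = "null_marker",
                                   carrier_only = FALSE)
  expect_equal(nrow(one), 1)
  nocar <- sub
  nocar$mutation_carrier <- FALSE
  expect_error(associate_psmd_biomarkers(psmd, bm, nocar), "no subjects")
})

test_that("standardized associations are invariant to affine assay rescaling", {
  sub <- small_subjects(100, seed = 61)
  ids <- sub$subject_id
  withr::with_seed(62, {
    psmd_vals <- rnorm(100)
    bmv <- 0.4 * psmd_vals + rnorm(100)
  })
  psmd <- data.frame(subject_id = ids, psmd = psmd_vals)
  mk <- function(v) data.frame(subject_id = ids, measure = "m", value = v)
  r1 <- associate_psmd_biomarkers(psmd, mk(bmv), sub, carrier_only = FALSE)
  r2 <- associate_psmd_biomarkers(psmd, mk(1000 + 37 * bmv), sub,
                                  carrier_only = FALSE)
  expect_equal(r1$B, r2$B, tolerance = 1e-8)
  expect_equal(r1$p, r2$p, tolerance = 1e-8)
})
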