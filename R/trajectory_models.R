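# Biomarker-vs-EYO trajectory curves by forward polynomial-term addition with
# AIC stopping, curve standardization for the cascade figure, and
# PSMD <-> biomarker association regressions.

#' Adjust volumes for intracranial volume by the regression approach
#'
#' `adjusted = raw - b * (icv - mean(icv))`, with the slope `b` estimated by
#' least squares within the reference (non-carrier) group so that disease
#' effects do not leak into the head-size correction.
#'
#' @param volumes raw volumes.
#' @param icv total intracranial volumes (> 0).
#' @param reference logical vector marking the reference-group subjects.
#' @return adjusted volumes (same length as `volumes`).
#' @export
adjust_for_icv <- function(volumes, icv, reference = rep(TRUE, length(icv))) {
  stopifnot(length(volumes) == length(icv), length(reference) == length(icv))
  if (any(icv <= 0)) stopf("icv must be positive")
  if (sum(reference) < 2) stopf("need >= 2 reference subjects")
  icv_ref <- icv[reference]
  if (sd(icv_ref) == 0) stopf("degenerate icv variance in reference group")
  b <- coef(lm(volumes[reference] ~ icv_ref))[2]
  volumes - b * (icv - mean(icv_ref))
}

# model matrix for a group-specific polynomial of a given order:
# intercept, carrier, eyo^1..eyo^d, carrier:eyo^1..carrier:eyo^d
trajectory_design <- function(eyo, carrier, order) {
  base <- sapply(seq_len(order), function(k) eyo^k)
  X <- cbind(1, as.numeric(carrier), base, base * as.numeric(carrier))
  colnames(X) <- c("intercept", "carrier",
                   paste0("eyo", seq_len(order)),
                   paste0("carrier_eyo", seq_len(order)))
  X
}

# Gaussian quasi-likelihood AIC of a fitted robust model
robust_aic <- function(fit) {
  n <- fit$n_used
  rss <- sum(fit$residuals^2)
  p <- length(fit$beta)
  n * log(rss / n) + n * (1 + log(2 * pi)) + 2 * (p + 1)
}

#' Fit a biomarker trajectory by forward polynomial addition with AIC
#'
#' Starting from a linear model (group main effect, EYO, group x EYO), higher
#' polynomial orders are added one at a time -- jointly for the base and the
#' carrier-interaction polynomial -- and fitting stops as soon as the AIC
#' fails to decrease; the last improving model is returned. Fits use robust
#' M-estimation, with the AIC computed from the fit's Gaussian
#' quasi-likelihood (configurable to a plain least-squares fit).
#'
#' @param values biomarker values, aligned with `subjects` rows.
#' @param subjects subject table (`mutation_carrier`, `eyo`).
#' @param max_order highest polynomial order considered (default 3).
#' @param k Huber tuning constant for the robust fits.
#' @param engine `"robust"` (default) or `"ols"`.
#' @return list of class `trajectory_model`: `selected_order`, `fit`
#'   (a [robust_fit()] result), `aic_path` (AIC per candidate order),
#'   `eyo_range` of the data, and `noncarrier_reference` (mean/SD of the
#'   fitted non-carrier values, for standardization).
#' @export
fit_trajectory <- function(values, subjects, max_order = 3L, k = 1.345,
                           engine = c("robust", "ols")) {
  engine <- match.arg(engine)
  stopifnot(length(values) == nrow(subjects))
  if (length(unique(subjects$mutation_carrier)) < 2)
    stopf("both groups must be represented")
  n <- length(values)
  if (n < 2 * (max_order + 1) + 4)
    stopf("too few observations (%d) for max_order = %d", n, max_order)
  fit_one <- function(order) {
    X <- trajectory_design(subjects$eyo, subjects$mutation_carrier, order)
    f <- robust_fit(values, X, k = if (engine == "ols") 1e9 else k)
    list(fit = f, aic = robust_aic(f), order = order)
  }
  best <- fit_one(1L)
  aic_path <- setNames(best$aic, "order1")
  if (max_order > 1) {
    for (d in 2:max_order) {
      cand <- fit_one(d)
      aic_path <- c(aic_path, setNames(cand$aic, paste0("order", d)))
      if (cand$aic < best$aic) best <- cand else break
    }
  }
  nc <- !subjects$mutation_carrier
  Xnc <- trajectory_design(subjects$eyo[nc], subjects$mutation_carrier[nc],
                           best$order)
  fitted_nc <- drop(Xnc %*% best$fit$beta)
  structure(list(
    selected_order = best$order,
    fit = best$fit,
    aic_path = aic_path,
    eyo_range = range(subjects$eyo),
    noncarrier_reference = c(mean = mean(fitted_nc),
                             sd = if (length(fitted_nc) > 1) sd(values[nc]) else 1)
  ), class = "trajectory_model")
}

#' Evaluate fitted trajectory curves on an EYO grid
#'
#' Exact polynomial evaluation per group. With `standardize = TRUE` both
#' curves are z-scored against the non-carrier reference (mean of the fitted
#' non-carrier values over the cohort's EYOs, SD of the observed non-carrier
#' values) and sign-flipped so that the abnormal direction points upward,
#' which makes heterogeneous biomarkers co-plottable in one cascade figure.
#'
#' @param model a [fit_trajectory()] result.
#' @param eyo_grid EYO values; points outside the fitted range trigger an
#'   extrapolation warning.
#' @param standardize z-score against the non-carrier reference.
#' @param abnormal_direction +1 if the pathological change is an increase,
#'   -1 for a decrease (used only when standardizing).
#' @return data frame: `eyo`, `carrier`, `noncarrier`.
#' @export
predict_curves <- function(model, eyo_grid, standardize = FALSE,
                           abnormal_direction = 1) {
  stopifnot(inherits(model, "trajectory_model"))
  if (any(eyo_grid < model$eyo_range[1] | eyo_grid > model$eyo_range[2]))
    warnf("grid extends beyond the fitted EYO range [%g, %g]",
          model$eyo_range[1], model$eyo_range[2])
  ev <- function(carrier) {
    X <- trajectory_design(eyo_grid, rep(carrier, length(eyo_grid)),
                           model$selected_order)
    drop(X %*% model$fit$beta)
  }
  car <- ev(TRUE)
  nc <- ev(FALSE)
  if (standardize) {
    ref <- model$noncarrier_reference
    s <- if (ref[["sd"]] > 0) ref[["sd"]] else 1
    car <- abnormal_direction * (car - ref[["mean"]]) / s
    nc <- abnormal_direction * (nc - ref[["mean"]]) / s
  }
  data.frame(eyo = eyo_grid, carrier = car, noncarrier = nc)
}

#' PSMD - biomarker association regressions
#'
#' One robust regression per biomarker with PSMD as outcome, the biomarker as
#' main predictor, and sex and education as covariates, within the carrier
#' group by default. Outcome and predictor are z-standardized so the
#' coefficients are comparable across assays.
#'
#' @param psmd data frame `subject_id`, `psmd`.
#' @param biomarkers long data frame `subject_id`, `measure`, `value`.
#' @param subjects subject table.
#' @param measures which biomarkers to test (default: all except `icv`).
#' @param carrier_only restrict to mutation carriers (default TRUE).
#' @param k Huber tuning constant.
#' @return data frame: `measure`, `B`, `SE`, `p`, `n` (normal-theory p from
#'   the robust fit).
#' @export
associate_psmd_biomarkers <- function(psmd, biomarkers, subjects,
                                      measures = NULL, carrier_only = TRUE,
                                      k = 1.345) {
  measures <- measures %||% setdiff(unique(biomarkers$measure), "icv")
  keep_ids <- subjects$subject_id[!carrier_only | subjects$mutation_carrier]
  if (!length(keep_ids)) stopf("no subjects in the analysis group")
  rows <- lapply(measures, function(m) {
    bm <- biomarkers[biomarkers$measure == m, ]
    dat <- merge(merge(psmd, bm, by = "subject_id"), subjects,
                 by = "subject_id")
    dat <- dat[dat$subject_id %in% keep_ids & complete.cases(
      dat[, c("psmd", "value", "sex", "education")]), ]
    if (nrow(dat) < 6) stopf("too few subjects (%d) for biomarker '%s'",
                             nrow(dat), m)
    y <- as.numeric(scale(dat$psmd))
    x <- as.numeric(scale(dat$value))
    X <- cbind(intercept = 1, biomarker = x, sex = dat$sex,
               education = dat$education)
    fit <- robust_fit(y, X, k = k)
    B <- fit$beta[["biomarker"]]
    SE <- fit$se[["biomarker"]]
    data.frame(measure = m, B = B, SE = SE,
               p = 2 * pnorm(-abs(B / SE)), n = nrow(dat),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
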