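# Tract-level analysis: ROI construction from atlas x significance map,
# outlier filtering, robust M-estimation regression and the EYO-grid
# earliest-abnormality ordering.

#' Build tract regions of interest from an atlas and a significance mask
#'
#' Each ROI is the intersection of a labelled atlas tract with the
#' significant-voxel mask. Tracts whose significant fraction falls below
#' `threshold` are excluded unless listed a priori (mirrors the exclusion of
#' tracts with only ~1% significant voxels, and the a-priori retention of the
#' hippocampal cingulum).
#'
#' @param atlas list with `labels` (3-D integer array, 0 = background) and
#'   `tracts` (data frame with `label`, `tract`).
#' @param sig_mask logical array on the same grid.
#' @param a_priori character vector of tract names always included.
#' @param threshold minimum significant fraction for inclusion (default 0.02).
#' @return list of `tract_roi` objects: `tract`, `mask`, `n_voxels`,
#'   `n_sig_voxels`, `frac_sig`, `included`, `a_priori`.
#' @export
build_tract_rois <- function(atlas, sig_mask, a_priori = character(),
                             threshold = 0.02) {
  if (!all(dim(atlas$labels) == dim(sig_mask)))
    stopf("atlas and significance mask are not on the same grid")
  unknown <- setdiff(a_priori, atlas$tracts$tract)
  if (length(unknown))
    stopf("unknown a-priori tract name(s): %s", paste(unknown, collapse = ", "))
  lapply(seq_len(nrow(atlas$tracts)), function(i) {
    lab <- atlas$tracts$label[i]
    name <- atlas$tracts$tract[i]
    tract_mask <- atlas$labels == lab
    roi_mask <- tract_mask & sig_mask
    n_tot <- sum(tract_mask)
    n_sig <- sum(roi_mask)
    frac <- if (n_tot > 0) n_sig / n_tot else 0
    ap <- name %in% a_priori
    # an a-priori tract keeps its full atlas extent if the significance map
    # misses it entirely (it would otherwise have no voxels to average)
    if (ap && n_sig == 0) roi_mask <- tract_mask
    structure(list(tract = name, mask = roi_mask, n_voxels = n_tot,
                   n_sig_voxels = n_sig, frac_sig = frac,
                   included = frac >= threshold || ap, a_priori = ap),
              class = "tract_roi")
  })
}

#' Average MD within a tract ROI
#'
#' @param volume a [skeleton_volume()] or a 3-D numeric array.
#' @param roi a `tract_roi` (or logical array).
#' @return arithmetic mean over the ROI voxels.
#' @export
average_md <- function(volume, roi) {
  dat <- if (inherits(volume, "skeleton_volume")) volume$data else volume
  m <- if (inherits(roi, "tract_roi")) roi$mask else roi
  if (!any(m)) stopf("ROI is empty")
  mean(dat[m])
}

#' Tract-average MD per subject
#'
#' @param md subjects x skeleton-voxels matrix.
#' @param mask logical skeleton mask (defines the voxel order of `md`).
#' @param rois list of `tract_roi`s; only `included` ROIs are used.
#' @param subject_ids subject identifiers.
#' @return long data frame: `subject_id`, `measure` (tract name), `value`.
#' @export
tract_md_table <- function(md, mask, rois, subject_ids) {
  rois <- Filter(function(r) r$included, rois)
  if (!length(rois)) stopf("no included ROI")
  rows <- lapply(rois, function(r) {
    sel <- r$mask[mask]
    if (!any(sel)) stopf("ROI '%s' has no voxels on the skeleton", r$tract)
    data.frame(subject_id = subject_ids, measure = r$tract,
               value = rowMeans(md[, sel, drop = FALSE]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Tukey outlier filter, applied within groups
#'
#' Within each group independently, removes values exceeding
#' `median + 1.5 * IQR`. The rule is one-tailed by default because the
#' pathological direction for MD is an increase; `two_sided = TRUE` also
#' removes values below `median - 1.5 * IQR`.
#'
#' @param values numeric vector.
#' @param groups grouping vector, same length.
#' @param k multiplier of the IQR (default 1.5).
#' @param two_sided also trim the lower tail.
#' @return list with `kept` and `removed` integer indices into `values`, and
#'   `n_removed_by_group`.
#' @export
tukey_filter <- function(values, groups, k = 1.5, two_sided = FALSE) {
  stopifnot(length(values) == length(groups))
  groups <- as.factor(groups)
  removed <- integer(0)
  for (g in levels(groups)) {
    idx <- which(groups == g)
    if (length(idx) < 4)
      stopf("group '%s' has fewer than 4 values", g)
    v <- values[idx]
    med <- median(v)
    iqr <- IQR(v, type = 7)
    out <- v > med + k * iqr
    if (two_sided) out <- out | v < med - k * iqr
    removed <- c(removed, idx[out])
  }
  removed <- sort(removed)
  list(
    kept = setdiff(seq_along(values), removed),
    removed = removed,
    n_removed_by_group = vapply(levels(groups), function(g)
      sum(groups[removed] == g), integer(1))
  )
}

#' Robust linear regression by M-estimation
#'
#' Iteratively reweighted least squares with the Huber psi function
#' (via [MASS::rlm()]): MAD residual scale, coefficient covariance from the
#' standard asymptotic M-estimation form. With a very large tuning constant
#' the fit coincides with OLS.
#'
#' @param y response vector.
#' @param X design matrix (with intercept column; full rank).
#' @param k Huber tuning constant (default 1.345, 95% Gaussian efficiency).
#' @param maxit maximum IRLS iterations.
#' @return list of class `robust_fit`: `beta`, `se`, `cov`, `scale`,
#'   `n_used`, `n_outliers_removed` (0 here; filled by callers that
#'   pre-filter), `converged`, `residuals`, `fitted`.
#' @export
robust_fit <- function(y, X, k = 1.345, maxit = 100L) {
  if (!is.matrix(X)) stopf("X must be a matrix")
  if (length(y) != nrow(X)) stopf("length(y) != nrow(X)")
  if (nrow(X) <= ncol(X)) stopf("need more observations than parameters")
  if (qr(X)$rank < ncol(X)) stopf("design matrix is rank deficient")
  if (sd(y) == 0) {
    # constant response: exact fit, zero slopes
    beta <- rep(0, ncol(X))
    names(beta) <- colnames(X)
    ic <- which(apply(X, 2, function(col) all(col == col[1]) && col[1] != 0))
    if (length(ic)) beta[ic[1]] <- y[1] / X[1, ic[1]]
    covb <- matrix(0, ncol(X), ncol(X),
                   dimnames = list(colnames(X), colnames(X)))
    return(structure(list(beta = beta, se = rep(0, ncol(X)), cov = covb,
                          scale = 0, n_used = length(y),
                          n_outliers_removed = 0L, converged = TRUE,
                          residuals = rep(0, length(y)), fitted = y),
                     class = "robust_fit"))
  }
  fit <- MASS::rlm(X, y, psi = MASS::psi.huber, k = k, maxit = maxit,
                   scale.est = "MAD")
  if (!fit$converged)
    warnf("IRLS did not converge in %d iterations", maxit)
  sm <- summary(fit, method = "XtX")
  covb <- sm$stddev^2 * sm$cov.unscaled
  dimnames(covb) <- list(colnames(X), colnames(X))
  beta <- coef(fit)
  names(beta) <- colnames(X)
  structure(list(beta = beta, se = sqrt(diag(covb)), cov = covb,
                 scale = fit$s, n_used = length(y),
                 n_outliers_removed = 0L, converged = fit$converged,
                 residuals = fit$residuals, fitted = fit$fitted.values),
            class = "robust_fit")
}

#' Earliest-abnormality ordering on the EYO grid
#'
#' From a fitted model containing `mutation` and `eyo_x_mutation` terms, the
#' carrier-minus-non-carrier difference at EYO = e is
#' `diff(e) = beta_mut + e * beta_int` (covariates cancel in the difference).
#' Its delta-method variance is
#' `var(b_mut) + e^2 var(b_int) + 2 e cov(b_mut, b_int)`; normal-quantile
#' confidence intervals are evaluated at each grid point and the earliest
#' abnormal point is the smallest e whose CI excludes zero.
#'
#' @param fit a [robust_fit()] whose design used [build_design()] column
#'   names.
#' @param grid EYO grid (default -25 to +10 in 5-year steps).
#' @param level confidence level (default 0.95).
#' @param direction `"increase"` (abnormal = CI entirely above zero; the
#'   pathological direction for MD) or `"two.sided"` (CI excludes zero).
#' @return list of class `eyo_ordering`: data frame `table` (`eyo`, `diff`,
#'   `ci_low`, `ci_high`, `abnormal`), `earliest_abnormal` (NA if none), and
#'   the reporting interval `interval = (previous grid value, earliest]`.
#' @export
eyo_ordering <- function(fit, grid = seq(-25, 10, by = 5), level = 0.95,
                         direction = c("increase", "two.sided")) {
  direction <- match.arg(direction)
  if (!length(grid)) stopf("EYO grid is empty")
  grid <- sort(grid)
  need <- c("mutation", "eyo_x_mutation")
  if (!all(need %in% names(fit$beta)))
    stopf("fit lacks mutation and eyo_x_mutation terms")
  bm <- fit$beta[["mutation"]]
  bi <- fit$beta[["eyo_x_mutation"]]
  vm <- fit$cov["mutation", "mutation"]
  vi <- fit$cov["eyo_x_mutation", "eyo_x_mutation"]
  cmi <- fit$cov["mutation", "eyo_x_mutation"]
  z <- qnorm(1 - (1 - level) / 2)
  diff <- bm + grid * bi
  var_d <- pmax(vm + grid^2 * vi + 2 * grid * cmi, 0)
  half <- z * sqrt(var_d)
  lo <- diff - half
  hi <- diff + half
  abnormal <- if (direction == "increase") lo > 0 else (lo > 0 | hi < 0)
  earliest <- if (any(abnormal)) grid[which(abnormal)[1]] else NA_real_
  interval <- if (is.na(earliest)) c(NA_real_, NA_real_) else {
    i <- which(grid == earliest)
    c(if (i == 1) -Inf else grid[i - 1], earliest)
  }
  structure(list(
    table = data.frame(eyo = grid, diff = diff, ci_low = lo, ci_high = hi,
                       abnormal = abnormal),
    earliest_abnormal = earliest,
    interval = interval,
    direction = direction,
    level = level
  ), class = "eyo_ordering")
}

#' Run the tract/PSMD earliest-abnormality suite
#'
#' For each measure (tract-average MD, PSMD): Tukey-filter within groups,
#' fit the robust EYO x mutation model with sex and education covariates,
#' and locate the earliest abnormal EYO grid point.
#'
#' @param measures long data frame: `subject_id`, `measure`, `value`.
#' @param subjects subject table (see [build_design()]).
#' @param grid EYO grid.
#' @param direction passed to [eyo_ordering()].
#' @param k Huber tuning constant.
#' @param max_removed warn if the Tukey filter removes more than this many
#'   subjects for one measure (the study observed at most five).
#' @param ci_method `"delta"` (default: normal-quantile CIs from the robust
#'   coefficient covariance) or `"bootstrap"` (percentile CIs from resampling
#'   subjects and re-running the filter + fit per draw).
#' @param n_boot bootstrap draws (used when `ci_method = "bootstrap"`).
#' @param boot_seed RNG seed for the bootstrap.
#' @return list: `summary` data frame (`measure`, `n_used`, `n_removed`,
#'   `beta_interaction`, `se_interaction`, `earliest_abnormal`,
#'   `interval_low`), `details` (per-measure list with the fit and ordering).
#' @export
run_ordering_suite <- function(measures, subjects, grid = seq(-25, 10, 5),
                               direction = "increase", k = 1.345,
                               max_removed = 5L,
                               ci_method = c("delta", "bootstrap"),
                               n_boot = 2000L, boot_seed = 1L) {
  ci_method <- match.arg(ci_method)
  stopifnot(all(c("subject_id", "measure", "value") %in% names(measures)))
  meas_names <- unique(measures$measure)
  details <- list()
  rows <- lapply(meas_names, function(m) {
    dat <- measures[measures$measure == m, ]
    ord <- match(dat$subject_id, subjects$subject_id)
    if (anyNA(ord)) stopf("measure '%s' has unknown subject ids", m)
    sub <- subjects[ord, ]
    filt <- tukey_filter(dat$value,
                         ifelse(sub$mutation_carrier, "carrier", "noncarrier"))
    if (length(filt$removed) > max_removed)
      warnf("measure '%s': %d subjects removed as outliers (> %d)",
            m, length(filt$removed), max_removed)
    keep <- filt$kept
    X <- build_design(sub[keep, ])
    fit <- robust_fit(dat$value[keep], X, k = k)
    fit$n_outliers_removed <- length(filt$removed)
    ordering <- if (ci_method == "delta") {
      eyo_ordering(fit, grid = grid, direction = direction)
    } else {
      bootstrap_ordering(dat$value, sub, grid = grid, direction = direction,
                         k = k, n_boot = n_boot,
                         seed = derive_seed(boot_seed, m),
                         point_fit = fit)
    }
    details[[m]] <<- list(fit = fit, ordering = ordering, filter = filt)
    data.frame(
      measure = m,
      n_used = fit$n_used,
      n_removed = length(filt$removed),
      beta_interaction = fit$beta[["eyo_x_mutation"]],
      se_interaction = fit$se[[which(names(fit$beta) == "eyo_x_mutation")]],
      earliest_abnormal = ordering$earliest_abnormal,
      interval_low = ordering$interval[1],
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  list(summary = out, details = details)
}

# percentile-bootstrap variant of the EYO ordering: subjects are resampled
# with replacement and the whole per-measure procedure (Tukey filter + robust
# fit + grid differences) is repeated per draw
bootstrap_ordering <- function(values, subjects, grid, direction = "increase",
                               k = 1.345, n_boot = 2000L, seed = 1L,
                               point_fit = NULL) {
  grid <- sort(grid)
  one_diff <- function(v, sub) {
    filt <- tukey_filter(v, ifelse(sub$mutation_carrier, "carrier",
                                   "noncarrier"))
    fit <- robust_fit(v[filt$kept], build_design(sub[filt$kept, ]), k = k)
    fit$beta[["mutation"]] + grid * fit$beta[["eyo_x_mutation"]]
  }
  if (is.null(point_fit)) {
    diff_hat <- one_diff(values, subjects)
  } else {
    diff_hat <- point_fit$beta[["mutation"]] +
      grid * point_fit$beta[["eyo_x_mutation"]]
  }
  n <- length(values)
  draws <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(n, replace = TRUE)
      tryCatch(suppressWarnings(one_diff(values[idx], subjects[idx, ])),
               error = function(e) rep(NA_real_, length(grid)))
    }, numeric(length(grid)))
  })
  lo <- apply(draws, 1, quantile, probs = 0.025, na.rm = TRUE, names = FALSE)
  hi <- apply(draws, 1, quantile, probs = 0.975, na.rm = TRUE, names = FALSE)
  abnormal <- if (direction == "increase") lo > 0 else (lo > 0 | hi < 0)
  earliest <- if (any(abnormal)) grid[which(abnormal)[1]] else NA_real_
  interval <- if (is.na(earliest)) c(NA_real_, NA_real_) else {
    i <- which(grid == earliest)
    c(if (i == 1) -Inf else grid[i - 1], earliest)
  }
  structure(list(
    table = data.frame(eyo = grid, diff = diff_hat, ci_low = lo,
                       ci_high = hi, abnormal = abnormal),
    earliest_abnormal = earliest,
    interval = interval,
    direction = direction,
    level = 0.95,
    n_boot = n_boot
  ), class = "eyo_ordering")
}
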