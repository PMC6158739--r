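# Voxel-wise GLM of skeleton MD on EYO x mutation status with TFCE and
# Freedman-Lane permutation family-wise-error inference.

DESIGN_COLUMNS <- c("intercept", "eyo", "mutation", "eyo_x_mutation",
                    "sex", "education")

#' Build the EYO x mutation design matrix
#'
#' Fixed column order: intercept, EYO, mutation (1 = carrier), EYO x mutation,
#' sex (1 = female), years of education.
#'
#' @param subjects data frame with columns `mutation_carrier` (logical),
#'   `eyo`, `sex` (0/1), `education`.
#' @return numeric matrix with full column rank, rows aligned with `subjects`.
#' @export
build_design <- function(subjects) {
  req <- c("mutation_carrier", "eyo", "sex", "education")
  miss <- setdiff(req, names(subjects))
  if (length(miss)) stopf("subject table lacks columns: %s",
                          paste(miss, collapse = ", "))
  if (anyNA(subjects[req])) stopf("missing covariate values in subject table")
  X <- cbind(
    intercept = 1,
    eyo = subjects$eyo,
    mutation = as.numeric(subjects$mutation_carrier),
    eyo_x_mutation = subjects$eyo * as.numeric(subjects$mutation_carrier),
    sex = as.numeric(subjects$sex),
    education = as.numeric(subjects$education)
  )
  if (qr(X)$rank < ncol(X))
    stopf("design matrix is rank deficient (e.g. a single group, or constant covariate)")
  X
}

#' Voxel-wise OLS t-statistic map
#'
#' Fits the same linear model at every voxel and returns the t-statistic for
#' `contrast' beta`. Voxels with zero residual variance get t = 0 (with a
#' warning): they carry no evidence.
#'
#' @param Y subjects x voxels matrix of MD values.
#' @param X design matrix (rows aligned with `Y`).
#' @param contrast numeric contrast vector, length `ncol(X)`.
#' @return list of class `stat_map`: `t` (vector over voxels), `beta_c`
#'   (contrast estimates), `dof`, `contrast`, `zero_variance` (logical).
#' @export
fit_glm_tmap <- function(Y, X, contrast) {
  if (!is.matrix(Y)) Y <- matrix(Y, ncol = 1)
  if (nrow(Y) != nrow(X)) stopf("Y rows (%d) misaligned with design rows (%d)",
                                nrow(Y), nrow(X))
  if (length(contrast) != ncol(X)) stopf("contrast length != design columns")
  if (all(contrast == 0)) stopf("contrast is the zero vector")
  if (!all(is.finite(Y))) stopf("non-finite values in Y")
  XtX_inv <- chol2inv(chol(crossprod(X)))
  H <- XtX_inv %*% t(X)            # (X'X)^-1 X'
  B <- H %*% Y                     # coefficients, p x V
  resid <- Y - X %*% B
  dof <- nrow(X) - qr(X)$rank
  sigma2 <- colSums(resid^2) / dof
  cvar <- drop(t(contrast) %*% XtX_inv %*% contrast)
  beta_c <- drop(crossprod(contrast, B))
  se <- sqrt(sigma2 * cvar)
  zero_var <- se <= .Machine$double.eps^0.5 * max(abs(Y))
  t <- ifelse(zero_var, 0, beta_c / se)
  if (any(zero_var))
    warnf("%d voxel(s) with zero residual variance set to t = 0",
          sum(zero_var))
  structure(list(t = t, beta_c = beta_c, dof = dof, contrast = contrast,
                 zero_variance = zero_var),
            class = "stat_map")
}

#' TFCE parameters
#'
#' Standard defaults of the threshold-free cluster enhancement method:
#' height exponent H = 2, extent exponent E = 0.5, 26-neighbour connectivity,
#' and integration step `dh = max(stat)/100` when `dh = NULL`.
#'
#' @param H height exponent (>= 0).
#' @param E extent exponent (>= 0).
#' @param dh integration step; `NULL` = a hundredth of the map maximum.
#' @param connectivity 6, 18 or 26.
#' @return list of class `tfce_params`.
#' @export
tfce_params <- function(H = 2, E = 0.5, dh = NULL, connectivity = 26L) {
  if (H < 0 || E < 0) stopf("H and E must be >= 0")
  if (!is.null(dh) && dh <= 0) stopf("dh must be > 0")
  if (!connectivity %in% c(6L, 18L, 26L)) stopf("connectivity must be 6, 18 or 26")
  structure(list(H = H, E = E, dh = dh, connectivity = as.integer(connectivity)),
            class = "tfce_params")
}

#' Threshold-free cluster enhancement
#'
#' For each voxel v, `enhanced(v) = sum_h extent(v,h)^E * h^H * dh` over
#' thresholds `h = dh, 2dh, ... <= max(stat)`, where `extent(v,h)` is the size
#' of the suprathreshold (`stat >= h`) connected component containing v.
#' Negative values are enhanced on the negated map and returned with a minus
#' sign, so the output is signed.
#'
#' @param tmap numeric 3-D array (or vector matching `mask`).
#' @param mask logical 3-D array.
#' @param params a [tfce_params()].
#' @return numeric 3-D array of enhanced values (zero off the mask).
#' @export
tfce_enhance <- function(tmap, mask, params = tfce_params()) {
  if (!is.array(tmap)) tmap <- vec_to_vol(tmap, mask)
  if (!all(dim(tmap) == dim(mask))) stopf("tmap/mask dimension mismatch")
  if (!all(is.finite(tmap[mask]))) stopf("non-finite statistics inside mask")
  d <- dim(mask)
  enh_one <- function(v) {
    mx <- max(v[mask], 0)
    if (mx <= 0) return(array(0, dim = d))
    dh <- params$dh %||% (mx / 100)
    out <- .tfce_enhance_cpp(as.numeric(v), as.logical(mask), as.integer(d),
                             params$H, params$E, dh, params$connectivity)
    array(out, dim = d)
  }
  pos <- enh_one(tmap)
  neg <- enh_one(-tmap)
  pos - neg
}

#' Permutation-based FWE-corrected inference with TFCE
#'
#' Freedman-Lane scheme: the data are residualized against the nuisance
#' columns (all design columns with zero contrast weight), the residuals are
#' row-permuted, refitted under the full model, TFCE-enhanced, and the image
#' maximum is recorded. The observed statistic counts as one permutation, so
#' `fwe_p >= 1/n_perm`.
#'
#' @param Y subjects x voxels MD matrix (voxels in mask order).
#' @param X design matrix.
#' @param contrast contrast vector.
#' @param mask logical 3-D array with `sum(mask) == ncol(Y)`.
#' @param params a [tfce_params()].
#' @param n_perm total number of permutations including the observed one
#'   (the study default is 500).
#' @param seed RNG seed.
#' @param alternative `"greater"` (default: enhancement of positive t) or
#'   `"two.sided"` (maximum of |enhanced|).
#' @return list of class `permutation_result`: `fwe_p` (vector over mask
#'   voxels), `tfce_obs`, `tmap_obs`, `max_stat_null` (length `n_perm`,
#'   observed first), `n_permutations`, `seed`.
#' @export
permutation_fwe <- function(Y, X, contrast, mask, params = tfce_params(),
                            n_perm = 500L, seed = 1L,
                            alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  if (n_perm < 1) stopf("n_perm must be >= 1")
  if (length(contrast) != ncol(X)) stopf("contrast length != design columns")
  if (all(contrast == 0)) stopf("contrast is the zero vector")
  if (sum(mask) != ncol(Y)) stopf("mask voxel count != ncol(Y)")

  test_cols <- which(contrast != 0)
  Z <- X[, -test_cols, drop = FALSE]
  # residualize against nuisance (Freedman-Lane reduced model)
  if (ncol(Z) > 0) {
    HZ <- Z %*% chol2inv(chol(crossprod(Z))) %*% t(Z)
    fitted_red <- HZ %*% Y
    E <- Y - fitted_red
  } else {
    fitted_red <- matrix(0, nrow(Y), ncol(Y))
    E <- Y
  }

  stat_of <- function(Ymat) {
    sm <- suppressWarnings(fit_glm_tmap(Ymat, X, contrast))
    enh <- tfce_enhance(vec_to_vol(sm$t, mask), mask, params)
    v <- enh[mask]
    v[sm$zero_variance] <- 0
    list(enh = v, t = sm$t,
         max = if (alternative == "greater") max(v, 0) else max(abs(v), 0))
  }

  obs <- stat_of(Y)
  max_null <- numeric(n_perm)
  max_null[1] <- obs$max
  if (n_perm > 1) {
    with_seed(seed, {
      for (j in 2:n_perm) {
        perm <- sample.int(nrow(Y))
        Yp <- fitted_red + E[perm, , drop = FALSE]
        max_null[j] <- stat_of(Yp)$max
      }
    })
  }
  obs_v <- if (alternative == "greater") obs$enh else abs(obs$enh)
  exceed <- vapply(obs_v, function(o) sum(max_null[-1] >= o), numeric(1))
  fwe_p <- (1 + exceed) / n_perm
  structure(list(fwe_p = fwe_p, tfce_obs = obs$enh, tmap_obs = obs$t,
                 max_stat_null = max_null, n_permutations = n_perm,
                 seed = seed, alternative = alternative),
            class = "permutation_result")
}

#' Pairwise group-contrast t-maps
#'
#' Two-group GLM comparisons (sex and education as covariates) between
#' symptomatic carriers (CDR > 0), asymptomatic carriers (CDR = 0) and
#' non-carriers.
#'
#' @param Y subjects x voxels MD matrix.
#' @param subjects subject table with `mutation_carrier`, `cdr_positive`,
#'   `sex`, `education`.
#' @return named list of `stat_map` objects, one per group pair, each with a
#'   `rows` attribute giving the subject rows used.
#' @export
group_contrast_maps <- function(Y, subjects) {
  grp <- ifelse(!subjects$mutation_carrier, "noncarrier",
                ifelse(subjects$cdr_positive, "symptomatic", "asymptomatic"))
  counts <- table(factor(grp, levels = c("symptomatic", "asymptomatic",
                                         "noncarrier")))
  if (any(counts < 2))
    stopf("each group needs >= 2 subjects (have %s)",
          paste(sprintf("%s=%d", names(counts), counts), collapse = ", "))
  pairs <- list(
    symptomatic_vs_noncarrier = c("symptomatic", "noncarrier"),
    asymptomatic_vs_noncarrier = c("asymptomatic", "noncarrier"),
    symptomatic_vs_asymptomatic = c("symptomatic", "asymptomatic")
  )
  lapply(pairs, function(p) {
    rows <- which(grp %in% p)
    g <- as.numeric(grp[rows] == p[1])
    X <- cbind(intercept = 1, group = g,
               sex = as.numeric(subjects$sex[rows]),
               education = as.numeric(subjects$education[rows]))
    sm <- fit_glm_tmap(Y[rows, , drop = FALSE], X, c(0, 1, 0, 0))
    attr(sm, "rows") <- rows
    sm
  })
}

#' Intersection of binarized significance masks
#'
#' @param maps list of logical arrays/vectors on a common grid.
#' @return logical AND of all maps.
#' @export
intersect_binarized_maps <- function(maps) {
  stopifnot(length(maps) >= 1)
  dims <- lapply(maps, function(m) dim(m) %||% length(m))
  if (!all(vapply(dims, identical, logical(1), dims[[1]])))
    stopf("maps are not on a common grid")
  Reduce(`&`, maps)
}

#' Significance mask from a permutation result
#'
#' Binarizes at FWE-corrected p <= alpha; an uncorrected voxel-wise mode
#' (`mode = "uncorrected"`, normal-theory p on the t map) mirrors the relaxed
#' criterion used for thin tracts such as the hippocampal cingulum.
#'
#' @param result a [permutation_fwe()] result.
#' @param alpha significance level.
#' @param mask logical 3-D array the result lives on.
#' @param mode `"fwe"` or `"uncorrected"`.
#' @param dof residual degrees of freedom (needed for `"uncorrected"`).
#' @return logical 3-D array.
#' @export
significance_mask <- function(result, mask, alpha = 0.05,
                              mode = c("fwe", "uncorrected"), dof = NULL) {
  mode <- match.arg(mode)
  if (mode == "fwe") {
    sig <- result$fwe_p <= alpha
  } else {
    if (is.null(dof)) stopf("dof required for uncorrected thresholding")
    p <- stats::pt(result$tmap_obs, df = dof, lower.tail = FALSE)
    sig <- p < alpha
  }
  vec_to_vol(as.numeric(sig), mask) > 0
}
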