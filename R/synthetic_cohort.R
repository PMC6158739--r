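# Synthetic cohort generator: a familial-AD-style two-group dataset with planted
# regional MD divergence, group-dependent biomarker trajectories and
# posterior/periventricular WMH, so that every downstream stage has ground
# truth.

DEFAULT_TRACTS <- c(
  "forceps_major", "forceps_minor",
  "ifof_left", "ifof_right",
  "ilf_left", "ilf_right",
  "slf_left", "atr_left",
  "cingulum_hippocampus",
  "cst_left", "uncinate_left"
)

default_effect_map <- function() {
  list(
    forceps_major        = list(onset = -10, slope = 1.5e-6),
    forceps_minor        = list(onset = -10, slope = 1.2e-6),
    ifof_left            = list(onset = -5,  slope = 1.5e-6),
    ifof_right           = list(onset = -5,  slope = 1.5e-6),
    ilf_left             = list(onset = -5,  slope = 1.2e-6),
    ilf_right            = list(onset = -5,  slope = 1.2e-6),
    slf_left             = list(onset = -5,  slope = 1.5e-6),
    atr_left             = list(onset = -5,  slope = 1.2e-6),
    cingulum_hippocampus = list(onset = 0,   slope = 0.8e-6),
    cst_left             = list(onset = 0,   slope = 0),
    uncinate_left        = list(onset = 0,   slope = 0)
  )
}

default_biomarker_params <- function() {
  # onsets follow the published cascade ordering: amyloid and tau markers
  # first, then microglial activation, then hippocampal atrophy
  list(
    pib_precuneus      = list(baseline = 0.05, sd = 0.05,  onset = -20,
                              slope = 0.06,  direction = +1),
    csf_ttau           = list(baseline = 60,   sd = 15,    onset = -20,
                              slope = 4,     direction = +1),
    csf_ptau181        = list(baseline = 30,   sd = 8,     onset = -18,
                              slope = 2,     direction = +1),
    csf_abeta42        = list(baseline = 400,  sd = 60,    onset = -15,
                              slope = 15,    direction = -1),
    csf_strem2         = list(baseline = 3000, sd = 800,   onset = -10,
                              slope = 150,   direction = +1),
    hippocampal_volume = list(baseline = 8800, sd = 500,   onset = -5,
                              slope = 80,    direction = -1)
  )
}

#' Configuration for the synthetic cohort generator
#'
#' Defaults emulate the structure of the study cohort: 64 mutation carriers
#' and 45 non-carriers with EYO spanning roughly -25 to +10 years, a
#' white-matter skeleton covering ~15% of a 32 x 32 x 16 grid, tract-specific
#' MD divergence onsets (earliest in the callosal forceps), monotone
#' group-dependent biomarker trajectories and posterior/periventricular WMH.
#'
#' @param n_carriers,n_noncarriers group sizes.
#' @param eyo_range numeric length 2; EYO is sampled uniformly on this range.
#' @param grid_shape integer length 3, voxel grid dimensions.
#' @param skeleton_fraction proportion of grid voxels on the skeleton,
#'   in (0, 1].
#' @param baseline_md mean MD on the skeleton (mm^2/s).
#' @param baseline_spread_sd SD of the smooth spatial baseline variation
#'   (mm^2/s); gives the skeleton histogram a realistic width.
#' @param effect_map named list, one entry per tract:
#'   `list(onset = <EYO years>, slope = <MD mm^2/s per year>)`. Carriers gain
#'   `slope * max(0, eyo - onset)` (ramp) in every voxel of the tract.
#' @param effect_shape `"ramp"` (default; unambiguous true onset) or
#'   `"sigmoid"`.
#' @param effect_heterogeneity SD of the per-voxel slope modulation within a
#'   tract: voxel slopes are `slope * max(0, 1 + effect_heterogeneity * z(v))`
#'   with `z` a fixed fine-scale spatial field. Zero gives spatially uniform
#'   tract effects; positive values concentrate damage in cluster cores so
#'   that disease widens the skeleton MD histogram (the property PSMD
#'   measures) instead of merely shifting it.
#' @param noise_sd per-voxel iid Gaussian noise SD (mm^2/s).
#' @param smooth_noise if `TRUE`, spatially smooth the noise field
#'   (Gaussian, `noise_fwhm_vox`) to stress cluster-based inference.
#' @param noise_fwhm_vox smoothing FWHM in voxels when `smooth_noise`.
#' @param covariate_effects named numeric: additive MD effects of `sex`
#'   (female = 1) and `education` (per year); both default 0.
#' @param biomarker_params named list of per-biomarker trajectory parameters
#'   (`baseline`, `sd`, `onset`, `slope`, `direction`).
#' @param wmh_base_rate baseline per-voxel WMH probability.
#' @param wmh_posterior_gradient strength of the posterior/periventricular
#'   probability increase (>= 0).
#' @param wmh_eyo_slope per-year multiplicative increase of carrier WMH
#'   probability past `eyo_range[1]`.
#' @param seed integer RNG seed; identical seeds give bit-identical cohorts.
#' @param eyo_values optional numeric vector of length
#'   `n_carriers + n_noncarriers` (carriers first) pinning each subject's EYO
#'   instead of sampling; useful for closed-form checks.
#' @return object of class `cohort_config` (a validated list).
#' @export
cohort_config <- function(n_carriers = 64L,
                          n_noncarriers = 45L,
                          eyo_range = c(-25, 10),
                          grid_shape = c(32L, 32L, 16L),
                          skeleton_fraction = 0.15,
                          baseline_md = 7.5e-4,
                          baseline_spread_sd = 5e-5,
                          effect_map = default_effect_map(),
                          effect_shape = c("ramp", "sigmoid"),
                          effect_heterogeneity = 1.0,
                          noise_sd = 3e-5,
                          smooth_noise = FALSE,
                          noise_fwhm_vox = 2,
                          covariate_effects = c(sex = 0, education = 0),
                          biomarker_params = default_biomarker_params(),
                          wmh_base_rate = 0.03,
                          wmh_posterior_gradient = 3,
                          wmh_eyo_slope = 0.03,
                          seed = 1L,
                          eyo_values = NULL) {
  effect_shape <- match.arg(effect_shape)
  if (n_carriers <= 0 || n_noncarriers <= 0)
    stopf("group sizes must be positive (got %d carriers, %d non-carriers)",
          n_carriers, n_noncarriers)
  if (length(grid_shape) != 3L || any(grid_shape < 4L))
    stopf("grid_shape must be 3 dimensions, each >= 4")
  if (!(skeleton_fraction > 0 && skeleton_fraction <= 1))
    stopf("skeleton_fraction must lie in (0, 1]")
  if (noise_sd < 0) stopf("noise_sd must be >= 0")
  if (diff(eyo_range) <= 0) stopf("eyo_range must be increasing")
  n_tracts <- length(effect_map)
  if (prod(grid_shape) * skeleton_fraction < 4 * n_tracts)
    stopf("grid too small to host %d tract regions", n_tracts)
  if (is.null(names(effect_map)) || any(names(effect_map) == ""))
    stopf("effect_map must be a named list (one entry per tract)")
  if (!is.null(eyo_values) &&
      length(eyo_values) != n_carriers + n_noncarriers)
    stopf("eyo_values must have one entry per subject")
  cfg <- list(
    n_carriers = as.integer(n_carriers),
    n_noncarriers = as.integer(n_noncarriers),
    eyo_range = as.numeric(eyo_range),
    grid_shape = as.integer(grid_shape),
    skeleton_fraction = skeleton_fraction,
    baseline_md = baseline_md,
    baseline_spread_sd = baseline_spread_sd,
    effect_map = effect_map,
    effect_shape = effect_shape,
    effect_heterogeneity = effect_heterogeneity,
    noise_sd = noise_sd,
    smooth_noise = smooth_noise,
    noise_fwhm_vox = noise_fwhm_vox,
    covariate_effects = covariate_effects,
    biomarker_params = biomarker_params,
    wmh_base_rate = wmh_base_rate,
    wmh_posterior_gradient = wmh_posterior_gradient,
    wmh_eyo_slope = wmh_eyo_slope,
    seed = as.integer(seed),
    eyo_values = eyo_values
  )
  class(cfg) <- "cohort_config"
  cfg
}

# circular FFT convolution with a separable Gaussian kernel
smooth_field_3d <- function(arr, sigma) {
  d <- dim(arr)
  k1d <- function(n, s) {
    x <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1))
    k <- exp(-x^2 / (2 * s^2))
    k / sum(k)
  }
  kern <- outer(outer(k1d(d[1], sigma), k1d(d[2], sigma)), k1d(d[3], sigma))
  dim(kern) <- d
  Re(fft(fft(arr) * fft(kern), inverse = TRUE)) / prod(d)
}

# skeleton mask: smoothed random field thresholded at the requested fraction
make_skeleton <- function(grid_shape, fraction) {
  field <- array(rnorm(prod(grid_shape)), dim = grid_shape)
  field <- smooth_field_3d(field, sigma = 1.5)
  thr <- quantile(field, probs = 1 - fraction, names = FALSE)
  field > thr
}

# partition the skeleton into contiguous slabs along x, one per tract
make_atlas <- function(mask, tract_names) {
  idx <- which(mask)
  d <- dim(mask)
  coord <- arrayInd(idx, d)
  ord <- order(coord[, 1], coord[, 2], coord[, 3])
  n_t <- length(tract_names)
  bounds <- round(seq(0, length(idx), length.out = n_t + 1))
  labels_vec <- integer(length(idx))
  for (t in seq_len(n_t))
    labels_vec[ord[(bounds[t] + 1):bounds[t + 1]]] <- t
  labels <- array(0L, dim = d)
  labels[idx] <- labels_vec
  list(
    labels = labels,
    tracts = data.frame(
      label = seq_len(n_t),
      tract = tract_names,
      n_voxels = as.integer(table(factor(labels_vec, levels = seq_len(n_t)))),
      stringsAsFactors = FALSE
    )
  )
}

effect_ramp <- function(eyo, onset, shape) {
  if (shape == "ramp") {
    pmax(0, eyo - onset)
  } else {
    # sigmoid with unit-per-year asymptotic slope matched around the onset;
    # width 5 years
    10 / (1 + exp(-(eyo - onset) / 2.5))
  }
}

#' Per-voxel WMH probability map of the generator
#'
#' Exposes the Bernoulli probabilities used when drawing WMH masks, for
#' calibration checks: probability rises toward posterior (high y) and
#' periventricular (mid z) coordinates.
#'
#' @param config a [cohort_config()].
#' @param mask logical skeleton mask the probabilities live on.
#' @return numeric vector, one probability per masked voxel.
#' @export
wmh_probability_map <- function(config, mask) {
  d <- dim(mask)
  coord <- arrayInd(which(mask), d)
  ynorm <- (coord[, 2] - 1) / (d[2] - 1)
  zc <- abs((coord[, 3] - 1) / (d[3] - 1) - 0.5) * 2  # 0 centre .. 1 edge
  g <- config$wmh_posterior_gradient
  p <- config$wmh_base_rate * (1 + g * ynorm) * (1 - 0.6 * zc)
  pmin(p, 1)
}

#' Generate a synthetic two-group cohort with planted effects
#'
#' Per-voxel MD is `baseline(v) + carrier * ramp(eyo - onset_t) * slope_t +
#' covariate terms + iid Gaussian noise`; only carriers receive effect terms.
#' WMH masks are voxel-wise Bernoulli draws whose probability increases toward
#' posterior/periventricular coordinates and, in carriers, with EYO.
#' Biomarkers follow monotone group-dependent trajectories. The same seed
#' yields bit-identical output.
#'
#' @param config a [cohort_config()].
#' @return object of class `wm_cohort`: list with `subjects` (data frame),
#'   `md` (subjects x skeleton-voxels matrix, mm^2/s), `mask` (logical 3-D
#'   array), `affine` (4 x 4), `atlas` (`labels` 3-D integer array + `tracts`
#'   data frame), `wmh` (logical subjects x voxels matrix on the skeleton),
#'   `biomarkers` (long data frame), and `truth` (planted parameters and
#'   noiseless per-subject tract means).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  with_seed(config$seed, {
    n <- config$n_carriers + config$n_noncarriers
    subjects <- data.frame(
      subject_id = sprintf("sub-%03d", seq_len(n)),
      mutation_carrier = rep(c(TRUE, FALSE),
                             c(config$n_carriers, config$n_noncarriers)),
      eyo = if (is.null(config$eyo_values))
        runif(n, config$eyo_range[1], config$eyo_range[2])
      else as.numeric(config$eyo_values),
      sex = rbinom(n, 1, 0.5),
      education = pmax(8, round(rnorm(n, 14.5, 2.8))),
      stringsAsFactors = FALSE
    )
    # symptomatic once past the estimated onset (carriers only)
    subjects$cdr_positive <- subjects$mutation_carrier & subjects$eyo > 0

    mask <- make_skeleton(config$grid_shape, config$skeleton_fraction)
    v_n <- sum(mask)
    atlas <- make_atlas(mask, names(config$effect_map))
    label_vec <- atlas$labels[mask]

    baseline <- config$baseline_md +
      config$baseline_spread_sd * scale_field(mask)

    onset_v <- vapply(config$effect_map, `[[`, numeric(1), "onset")[label_vec]
    slope_v <- vapply(config$effect_map, `[[`, numeric(1), "slope")[label_vec]
    slope_w <- if (config$effect_heterogeneity > 0)
      pmax(0, 1 + config$effect_heterogeneity * scale_field(mask))
    else rep(1, v_n)
    slope_v <- slope_v * slope_w

    ramp <- outer(subjects$eyo, onset_v,
                  function(e, o) effect_ramp(e, o, config$effect_shape))
    signal <- sweep(ramp, 2, slope_v, `*`) * subjects$mutation_carrier
    cov_term <- config$covariate_effects[["sex"]] * subjects$sex +
      config$covariate_effects[["education"]] * subjects$education
    md_clean <- sweep(signal, 2, baseline, `+`) + cov_term

    if (config$noise_sd > 0) {
      if (config$smooth_noise) {
        sig <- config$noise_fwhm_vox / 2.3548
        noise <- t(vapply(seq_len(n), function(i) {
          f <- smooth_field_3d(array(rnorm(prod(config$grid_shape)),
                                     dim = config$grid_shape), sig)
          f <- f / sd(f)
          f[mask]
        }, numeric(v_n)))
        noise <- noise * config$noise_sd
      } else {
        noise <- matrix(rnorm(n * v_n, sd = config$noise_sd), n, v_n)
      }
      md <- md_clean + noise
    } else {
      md <- md_clean
    }

    p_vox <- wmh_probability_map(config, mask)
    subj_fac <- ifelse(
      subjects$mutation_carrier,
      1 + config$wmh_eyo_slope * (subjects$eyo - config$eyo_range[1]),
      1
    )
    pmat <- pmin(outer(subj_fac, p_vox), 1)
    wmh <- matrix(rbinom(length(pmat), 1, pmat) == 1L, nrow = n)

    biomarkers <- generate_biomarkers(subjects, config$biomarker_params)

    # noiseless tract means, for planted-truth checks downstream
    tract_truth <- vapply(seq_along(config$effect_map), function(t) {
      rowMeans(md_clean[, label_vec == t, drop = FALSE])
    }, numeric(n))
    colnames(tract_truth) <- names(config$effect_map)

    cohort <- list(
      subjects = subjects,
      md = md,
      mask = mask,
      affine = diag(c(2.5, 2.5, 2.5, 1)),
      atlas = atlas,
      wmh = wmh,
      biomarkers = biomarkers,
      truth = list(
        effect_map = config$effect_map,
        effect_shape = config$effect_shape,
        biomarker_params = config$biomarker_params,
        baseline = baseline,
        slope_weights = slope_w,
        noiseless_tract_md = tract_truth,
        wmh_probability = p_vox
      ),
      config = config
    )
    class(cohort) <- "wm_cohort"
    cohort
  })
}

# zero-mean unit-SD spatial field over masked voxels; short correlation
# length so every tract spans the full baseline-MD distribution (a planted
# regional increase then widens the skeleton histogram instead of merely
# shifting one tract's anchor within it)
scale_field <- function(mask) {
  f <- smooth_field_3d(array(rnorm(prod(dim(mask))), dim = dim(mask)), 0.8)
  v <- f[mask]
  (v - mean(v)) / sd(v)
}

generate_biomarkers <- function(subjects, params) {
  n <- nrow(subjects)
  icv <- rnorm(n, 1.5e6, 1.2e5)
  icv_slope <- 4e-3  # hippocampal volume scales with head size
  rows <- lapply(names(params), function(m) {
    p <- params[[m]]
    traj <- p$direction * p$slope * pmax(0, subjects$eyo - p$onset) *
      subjects$mutation_carrier
    value <- p$baseline + traj + rnorm(n, 0, p$sd)
    if (m == "hippocampal_volume")
      value <- value + icv_slope * (icv - mean(icv))
    data.frame(subject_id = subjects$subject_id, measure = m, value = value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- rbind(out, data.frame(subject_id = subjects$subject_id,
                               measure = "icv", value = icv,
                               stringsAsFactors = FALSE))
  rownames(out) <- NULL
  out
}

#' Generate synthetic streamlines and a grey-matter slab
#'
#' Fixture generator for the projection-zone module: straight lines
#' terminating at known offsets and orientations relative to a grey-matter
#' slab, lines pointing away from it, and curved (circular-arc) lines. The
#' slab geometry and per-streamline expectations are recorded in `truth`.
#'
#' @param n number of streamlines (>= 1); the first two are the canonical
#'   "points at the slab" / "points away" constructions.
#' @param gm_slab list: `dims` (grid), `axis` (1-3), `from` (first 0-based
#'   slab voxel index along `axis`). The slab spans `from` .. `dims[axis]-1`.
#' @param seed RNG seed.
#' @return list with `streamlines` (each a points matrix, 0-based continuous
#'   voxel coordinates), `gm_mask` (logical array), and `truth` (per-line
#'   geometry records).
#' @export
generate_streamlines <- function(n, gm_slab = list(dims = c(24L, 24L, 24L),
                                                   axis = 1L, from = 16L),
                                 seed = 1L) {
  if (n < 1) stopf("n must be >= 1")
  d <- gm_slab$dims
  ax <- gm_slab$axis
  if (gm_slab$from >= d[ax] || gm_slab$from < 1)
    stopf("degenerate grey-matter slab (zero thickness)")
  gm <- array(FALSE, dim = d)
  idx <- slice.index(gm, ax) - 1L  # 0-based coordinate along the slab axis
  gm[idx >= gm_slab$from] <- TRUE

  with_seed(seed, {
    mid <- (d - 1) / 2
    lines <- list()
    truth <- list()
    # 1: straight line along +axis ending one voxel before the slab
    p_end <- mid
    p_end[ax] <- gm_slab$from - 1
    t_seq <- seq(-8, 0, by = 1)
    pts <- matrix(rep(p_end, each = length(t_seq)), ncol = 3)
    pts[, ax] <- p_end[ax] + t_seq
    lines[[1]] <- pts
    dir1 <- c(0, 0, 0); dir1[ax] <- 1
    entry <- floor(p_end + 0.5); entry[ax] <- gm_slab$from
    truth[[1]] <- list(kind = "straight_toward", direction = dir1,
                       expected_entry = entry, expects_projection = TRUE)
    if (n >= 2) {
      # 2: same construction pointing away from the slab
      pts2 <- pts[rev(seq_len(nrow(pts))), , drop = FALSE]
      lines[[2]] <- pts2
      truth[[2]] <- list(kind = "straight_away", direction = -dir1,
                         expects_projection = FALSE)
    }
    if (n >= 3) {
      for (k in 3:n) {
        if (k %% 2 == 1) {
          # straight line, random orientation, terminal in the interior
          u <- rnorm(3); u <- u / sqrt(sum(u^2))
          start <- runif(3, 4, pmin(d - 5, gm_slab$from - 2))
          npts <- 9
          pts_k <- t(sapply(0:(npts - 1), function(i) start + i * u))
          lines[[k]] <- pts_k
          truth[[k]] <- list(kind = "straight_random", direction = u)
        } else {
          # planar circular arc in the (axis, next-axis) plane
          r <- runif(1, 4, 8)
          centre <- runif(3, 8, pmax(9, d - 9))
          th <- seq(0, pi / 2, length.out = 12)
          pts_k <- matrix(rep(centre, each = length(th)), ncol = 3)
          a2 <- if (ax == 3) 1L else ax + 1L
          pts_k[, ax] <- centre[ax] + r * cos(th)
          pts_k[, a2] <- centre[a2] + r * sin(th)
          # outward tangent at the last point
          tang <- c(0, 0, 0)
          tang[ax] <- -sin(th[length(th)]); tang[a2] <- cos(th[length(th)])
          lines[[k]] <- pts_k
          truth[[k]] <- list(kind = "arc", direction = tang,
                             radius = r, centre = centre)
        }
      }
    }
    list(streamlines = lines[seq_len(n)], gm_mask = gm,
         truth = truth[seq_len(n)], gm_slab = gm_slab)
  })
}

#' Synthetic per-subject grey-matter density images with planted MD coupling
#'
#' For pipeline validation: builds one grey-matter density image per subject
#' in which density inside each tract's projection zone decreases linearly
#' with that subject's tract MD (standardized), on top of iid noise. A
#' negative `coupling` plants the "higher tract MD, lower grey-matter volume"
#' association.
#'
#' @param tract_md subjects x tracts matrix of tract-average MD.
#' @param zones named list of projection zones (as from
#'   [build_projection_zones()]), one per tract column.
#' @param gm_mask logical grey-matter array the zones live in.
#' @param base_density grey-matter density outside any planted modulation.
#' @param coupling density change per SD of tract MD (negative = atrophy).
#' @param noise_sd iid voxel noise SD.
#' @param seed RNG seed.
#' @return list of 3-D density arrays, one per subject (zero outside GM).
#' @export
generate_gm_images <- function(tract_md, zones, gm_mask,
                               base_density = 0.6, coupling = -0.002,
                               noise_sd = 0.05, seed = 1L) {
  stopifnot(is.matrix(tract_md), length(zones) >= 1)
  zs <- scale(tract_md)
  with_seed(seed, {
    lapply(seq_len(nrow(tract_md)), function(i) {
      img <- array(0, dim = dim(gm_mask))
      img[gm_mask] <- base_density + rnorm(sum(gm_mask), 0, noise_sd)
      for (t in seq_along(zones)) {
        zone <- zones[[t]]
        if (length(zone$voxels) == 0) next
        img[zone$voxels] <- img[zone$voxels] + coupling * zs[i, t]
      }
      img[!gm_mask] <- 0
      img
    })
  })
}
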