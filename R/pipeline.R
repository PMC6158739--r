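# End-to-end orchestration: simulate -> psmd -> voxelwise -> ordering ->
# trajectories -> projection zones -> wmh, with a machine-readable manifest.

#' Pipeline run configuration
#'
#' @param seed global seed; each stochastic stage derives its own child seed
#'   from it, so a config+seed pair fully determines the manifest.
#' @param cohort a [cohort_config()]; its seed is overridden by the derived
#'   simulate-stage seed.
#' @param stages named logical list toggling the seven stages.
#' @param input_dir when the simulate stage is disabled, a directory laid out
#'   as written by [write_cohort()].
#' @param out_dir optional output directory; when given, volumes, tables and
#'   `manifest.json` are written there.
#' @param n_perm permutations for the voxel-wise stage (default 500).
#' @param tfce a [tfce_params()].
#' @param alpha FWE significance level.
#' @param eyo_grid EYO grid for the ordering stage.
#' @param roi_threshold minimum significant fraction for tract inclusion.
#' @param a_priori tracts always included (default the hippocampal cingulum).
#' @param max_order maximum polynomial order for trajectory fits.
#' @param direction abnormality direction for [eyo_ordering()].
#' @param gm_coupling planted GM-density change per SD of tract MD in the
#'   synthetic grey-matter images (negative = atrophy with higher MD).
#' @return list of class `run_config`.
#' @export
run_config <- function(seed = 1L,
                       cohort = cohort_config(),
                       stages = list(simulate = TRUE, psmd = TRUE,
                                     voxelwise = TRUE, ordering = TRUE,
                                     trajectories = TRUE, projection = TRUE,
                                     wmh = TRUE),
                       input_dir = NULL,
                       out_dir = NULL,
                       n_perm = 500L,
                       tfce = tfce_params(),
                       alpha = 0.05,
                       eyo_grid = seq(-25, 10, 5),
                       roi_threshold = 0.02,
                       a_priori = "cingulum_hippocampus",
                       max_order = 3L,
                       direction = "increase",
                       gm_coupling = -0.002) {
  defaults <- list(simulate = TRUE, psmd = TRUE, voxelwise = TRUE,
                   ordering = TRUE, trajectories = TRUE, projection = TRUE,
                   wmh = TRUE)
  defaults[names(stages)] <- stages
  if (!defaults$simulate && is.null(input_dir))
    stopf("simulate stage disabled but no input_dir given")
  cfg <- list(seed = as.integer(seed), cohort = cohort, stages = defaults,
              input_dir = input_dir, out_dir = out_dir,
              n_perm = as.integer(n_perm), tfce = tfce, alpha = alpha,
              eyo_grid = eyo_grid, roi_threshold = roi_threshold,
              a_priori = a_priori, max_order = as.integer(max_order),
              direction = direction, gm_coupling = gm_coupling)
  class(cfg) <- "run_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the [run_config()] arguments; `cohort` and `tfce`
#' sub-maps override the respective defaults field-wise.
#'
#' @param path YAML file.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  cohort_args <- y$cohort %||% list()
  if (!is.null(cohort_args$covariate_effects))
    cohort_args$covariate_effects <- unlist(cohort_args$covariate_effects)
  cohort <- do.call(cohort_config, cohort_args)
  tfce <- do.call(tfce_params, y$tfce %||% list())
  args <- y[setdiff(names(y), c("cohort", "tfce"))]
  args$cohort <- cohort
  args$tfce <- tfce
  do.call(run_config, args)
}

# straight streamline bundles aimed at the GM slab, one bundle per tract
tract_streamline_bundles <- function(tract_names, gm_slab, per_bundle = 6L,
                                     seed = 1L) {
  d <- gm_slab$dims
  ax <- gm_slab$axis
  n_t <- length(tract_names)
  lanes <- seq(4, d[2] - 5, length.out = max(n_t, 2))[seq_len(n_t)]
  with_seed(seed, {
    setNames(lapply(seq_len(n_t), function(t) {
      lapply(seq_len(per_bundle), function(j) {
        off <- runif(2, -0.8, 0.8)
        start <- c(0, 0, 0)
        start[ax] <- 4
        a2 <- if (ax == 3) 1L else ax + 1L
        a3 <- setdiff(1:3, c(ax, a2))
        start[a2] <- lanes[t] + off[1]
        start[a3] <- (d[a3] - 1) / 2 + off[2]
        npts <- 10
        pts <- matrix(rep(start, each = npts), ncol = 3)
        pts[, ax] <- start[ax] + seq(0, gm_slab$from - 6, length.out = npts)
        pts
      })
    }), tract_names)
  })
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in dependency order and assembles a manifest:
#' simulate (synthetic cohort), psmd, voxel-wise TFCE permutation inference on
#' the EYO x mutation interaction, tract/PSMD earliest-abnormality ordering,
#' biomarker trajectory models and PSMD-biomarker associations, grey-matter
#' projection zones with MD-volume associations, and the WMH frequency and
#' inside/outside sensitivity analysis. Identical config and seed give an
#' identical manifest.
#'
#' @param config a [run_config()].
#' @return list with `manifest` (plain, JSON-serializable), and `results`
#'   (full R objects per stage). When `config$out_dir` is set, tables, maps
#'   and `manifest.json` are written there.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  st <- config$stages
  manifest <- list(package = "wmcascade",
                   version = as.character(utils::packageVersion("wmcascade")),
                   seed = config$seed,
                   stages = list())
  results <- list()

  # ---- stage 1: simulate (or load) -----------------------------------------
  if (st$simulate) {
    cc <- config$cohort
    cc$seed <- derive_seed(config$seed, "simulate")
    cohort <- generate_cohort(cc)
    manifest$stages$simulate <- list(
      enabled = TRUE,
      n_carriers = cc$n_carriers, n_noncarriers = cc$n_noncarriers,
      grid = cc$grid_shape, skeleton_voxels = sum(cohort$mask),
      n_tracts = nrow(cohort$atlas$tracts), seed = cc$seed
    )
  } else {
    cohort <- load_cohort(config$input_dir)
    manifest$stages$simulate <- list(
      enabled = FALSE, input_dir = config$input_dir,
      n_subjects = nrow(cohort$subjects)
    )
  }
  results$cohort <- cohort
  subjects <- cohort$subjects
  mask <- cohort$mask

  # ---- stage 2: psmd -------------------------------------------------------
  if (st$psmd) {
    psmd <- psmd_table(cohort$md, subjects$subject_id)
    manifest$stages$psmd <- list(
      enabled = TRUE, n_subjects = nrow(psmd),
      mean = mean(psmd$psmd), sd = sd(psmd$psmd)
    )
    results$psmd <- psmd
  } else {
    psmd <- NULL
    manifest$stages$psmd <- list(enabled = FALSE)
  }

  # ---- stage 3: voxelwise --------------------------------------------------
  if (st$voxelwise) {
    X <- build_design(subjects)
    contrast <- as.numeric(DESIGN_COLUMNS == "eyo_x_mutation")
    perm <- permutation_fwe(cohort$md, X, contrast, mask,
                            params = config$tfce, n_perm = config$n_perm,
                            seed = derive_seed(config$seed, "voxelwise"))
    sig <- significance_mask(perm, mask, alpha = config$alpha)
    groups <- tryCatch(group_contrast_maps(cohort$md, subjects),
                       error = function(e) NULL)
    manifest$stages$voxelwise <- list(
      enabled = TRUE, n_permutations = config$n_perm,
      n_significant_voxels = sum(sig), alpha = config$alpha,
      max_t = max(perm$tmap_obs), min_fwe_p = min(perm$fwe_p),
      group_max_t = if (is.null(groups)) NULL else
        lapply(groups, function(g) max(g$t))
    )
    results$voxelwise <- list(perm = perm, sig_mask = sig, groups = groups)
  } else {
    sig <- NULL
    manifest$stages$voxelwise <- list(enabled = FALSE)
  }

  # ---- stage 4: ordering ---------------------------------------------------
  if (st$ordering) {
    if (is.null(sig))
      stopf("ordering stage requires the voxelwise stage (significance mask); enable 'voxelwise' or disable 'ordering'")
    if (is.null(psmd))
      stopf("ordering stage requires the psmd stage; enable 'psmd' or disable 'ordering'")
    rois <- build_tract_rois(cohort$atlas, sig, a_priori = config$a_priori,
                             threshold = config$roi_threshold)
    included <- Filter(function(r) r$included, rois)
    measures <- rbind(
      if (length(included))
        tract_md_table(cohort$md, mask, rois, subjects$subject_id),
      data.frame(subject_id = psmd$subject_id, measure = "psmd",
                 value = psmd$psmd, stringsAsFactors = FALSE)
    )
    suite <- run_ordering_suite(measures, subjects, grid = config$eyo_grid,
                                direction = config$direction)
    manifest$stages$ordering <- list(
      enabled = TRUE,
      tracts_included = vapply(included, `[[`, character(1), "tract"),
      tracts_excluded = vapply(Filter(function(r) !r$included, rois),
                               `[[`, character(1), "tract"),
      summary = suite$summary
    )
    results$ordering <- list(rois = rois, suite = suite, measures = measures)
  } else {
    manifest$stages$ordering <- list(enabled = FALSE)
  }

  # ---- stage 5: trajectories -----------------------------------------------
  if (st$trajectories) {
    bm <- cohort$biomarkers
    wide <- function(m) bm$value[bm$measure == m][
      match(subjects$subject_id, bm$subject_id[bm$measure == m])]
    hip <- adjust_for_icv(wide("hippocampal_volume"), wide("icv"),
                          reference = !subjects$mutation_carrier)
    traj_measures <- list(csf_abeta42 = wide("csf_abeta42"),
                          csf_ttau = wide("csf_ttau"),
                          csf_ptau181 = wide("csf_ptau181"),
                          csf_strem2 = wide("csf_strem2"),
                          pib_precuneus = wide("pib_precuneus"),
                          hippocampal_volume = hip)
    if (!is.null(psmd)) traj_measures$psmd <- psmd$psmd
    if (st$ordering && "forceps_major" %in% unique(results$ordering$measures$measure)) {
      fm <- results$ordering$measures
      fm <- fm[fm$measure == "forceps_major", ]
      traj_measures$forceps_major_md <-
        fm$value[match(subjects$subject_id, fm$subject_id)]
    }
    models <- lapply(traj_measures, fit_trajectory, subjects = subjects,
                     max_order = config$max_order)
    curves <- lapply(names(models), function(m) {
      dirn <- if (m %in% c("csf_abeta42", "hippocampal_volume")) -1 else 1
      # grid endpoints routinely sit just outside the sampled EYO range;
      # the extrapolation warning is expected here
      cv <- suppressWarnings(
        predict_curves(models[[m]], config$eyo_grid, standardize = TRUE,
                       abnormal_direction = dirn))
      cv$measure <- m
      cv
    })
    curves <- do.call(rbind, curves)
    assoc <- if (!is.null(psmd))
      associate_psmd_biomarkers(psmd, bm, subjects) else NULL
    manifest$stages$trajectories <- list(
      enabled = TRUE,
      selected_order = lapply(models, `[[`, "selected_order"),
      psmd_associations = assoc
    )
    results$trajectories <- list(models = models, curves = curves,
                                 associations = assoc)
  } else {
    manifest$stages$trajectories <- list(enabled = FALSE)
  }

  # ---- stage 6: projection zones -------------------------------------------
  if (st$projection) {
    if (!st$ordering)
      stopf("projection stage requires the ordering stage (tract set); enable 'ordering' or disable 'projection'")
    included <- Filter(function(r) r$included, results$ordering$rois)
    tract_names <- vapply(included, `[[`, character(1), "tract")
    gm_slab <- list(dims = c(32L, 32L, 32L), axis = 1L, from = 22L)
    gm_mask <- generate_streamlines(1, gm_slab,
                                    seed = derive_seed(config$seed, "gm"))$gm_mask
    bundles <- tract_streamline_bundles(tract_names, gm_slab,
                                        seed = derive_seed(config$seed, "bundles"))
    zones <- lapply(bundles, build_projection_zones, gm_mask = gm_mask)
    md_wide <- do.call(cbind, lapply(tract_names, function(tr) {
      m <- results$ordering$measures
      m <- m[m$measure == tr, ]
      m$value[match(subjects$subject_id, m$subject_id)]
    }))
    colnames(md_wide) <- tract_names
    gm_imgs <- generate_gm_images(md_wide, zones, gm_mask,
                                  coupling = config$gm_coupling,
                                  seed = derive_seed(config$seed, "gmimg"))
    voxvol <- prod(diag(cohort$affine)[1:3])
    vol_rows <- lapply(tract_names, function(tr) data.frame(
      subject_id = subjects$subject_id, measure = tr,
      volume = vapply(gm_imgs, gm_volume_in_zone, numeric(1),
                      zone = zones[[tr]], voxel_volume = voxvol),
      stringsAsFactors = FALSE))
    volumes <- do.call(rbind, vol_rows)
    md_long <- results$ordering$measures
    md_long <- md_long[md_long$measure %in% tract_names, ]
    assoc <- md_gm_association(md_long, volumes, subjects)
    manifest$stages$projection <- list(
      enabled = TRUE,
      zone_sizes = lapply(zones, function(z) length(z$voxels)),
      associations = assoc,
      n_fdr_significant = sum(assoc$fdr_p < 0.05)
    )
    results$projection <- list(zones = zones, volumes = volumes,
                               associations = assoc, gm_mask = gm_mask)
  } else {
    manifest$stages$projection <- list(enabled = FALSE)
  }

  # ---- stage 7: wmh --------------------------------------------------------
  if (st$wmh) {
    carriers <- subjects$mutation_carrier
    freq_c <- wmh_frequency(cohort$wmh[carriers, , drop = FALSE])
    freq_nc <- wmh_frequency(cohort$wmh[!carriers, , drop = FALSE])
    cmp <- if (st$ordering)
      tryCatch(compare_wmh_interactions(cohort$md, cohort$wmh, mask,
                                        results$ordering$rois, subjects),
               error = function(e) NULL) else NULL
    manifest$stages$wmh <- list(
      enabled = TRUE,
      mean_frequency_carriers = mean(freq_c),
      mean_frequency_noncarriers = mean(freq_nc),
      max_frequency_carriers = max(freq_c),
      interaction_comparison = cmp
    )
    results$wmh <- list(freq_carriers = freq_c, freq_noncarriers = freq_nc,
                        comparison = cmp)
  } else {
    manifest$stages$wmh <- list(enabled = FALSE)
  }

  if (!is.null(config$out_dir))
    write_pipeline_outputs(config, manifest, results)
  list(manifest = manifest, results = results)
}

load_cohort <- function(dir) {
  mask <- read_volume(file.path(dir, "skeleton_mask.nii.gz"), as_mask = TRUE)
  labels_num <- read_volume(file.path(dir, "atlas_labels.nii.gz"))
  labels <- array(as.integer(round(labels_num)), dim = dim(labels_num))
  tracts <- read.csv(file.path(dir, "atlas_tracts.csv"),
                     stringsAsFactors = FALSE)
  subjects <- read_subject_table(file.path(dir, "subjects.csv"))
  md <- read_md_matrix(file.path(dir, "md"), mask)
  md <- md[subjects$subject_id, , drop = FALSE]
  wmh_dir <- file.path(dir, "wmh")
  wmh <- if (dir.exists(wmh_dir)) {
    w <- read_md_matrix(wmh_dir, mask) > 0
    w[subjects$subject_id, , drop = FALSE]
  } else {
    message("no WMH masks found; subjects treated as lesion-free")
    matrix(FALSE, nrow(subjects), sum(mask))
  }
  biomarkers <- read.csv(file.path(dir, "biomarkers.csv"),
                         stringsAsFactors = FALSE)
  list(subjects = subjects, md = md, mask = mask,
       affine = attr(mask, "affine") %||% diag(c(2.5, 2.5, 2.5, 1)),
       atlas = list(labels = labels, tracts = tracts),
       wmh = wmh, biomarkers = biomarkers, truth = NULL, config = NULL)
}

write_pipeline_outputs <- function(config, manifest, results) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- config$out_dir
  if (!is.null(results$cohort$truth))
    write_cohort(results$cohort, file.path(out, "cohort"))
  if (!is.null(results$psmd))
    write.csv(results$psmd, file.path(out, "psmd.csv"), row.names = FALSE)
  if (!is.null(results$voxelwise)) {
    aff <- results$cohort$affine
    mask <- results$cohort$mask
    write_volume(vec_to_vol(results$voxelwise$perm$tmap_obs, mask),
                 file.path(out, "interaction_tmap.nii.gz"), aff)
    write_volume(vec_to_vol(results$voxelwise$perm$fwe_p, mask, fill = 1),
                 file.path(out, "interaction_fwe_p.nii.gz"), aff)
    write_volume(results$voxelwise$sig_mask,
                 file.path(out, "interaction_sig_mask.nii.gz"), aff,
                 datatype = "uint8")
  }
  if (!is.null(results$ordering))
    write.csv(results$ordering$suite$summary,
              file.path(out, "ordering_summary.csv"), row.names = FALSE)
  if (!is.null(results$trajectories)) {
    write.csv(results$trajectories$curves,
              file.path(out, "trajectory_curves.csv"), row.names = FALSE)
    if (!is.null(results$trajectories$associations))
      write.csv(results$trajectories$associations,
                file.path(out, "psmd_biomarker_associations.csv"),
                row.names = FALSE)
  }
  if (!is.null(results$projection))
    write.csv(results$projection$associations,
              file.path(out, "md_gm_associations.csv"), row.names = FALSE)
  if (!is.null(results$wmh) && !is.null(results$wmh$comparison))
    write.csv(results$wmh$comparison,
              file.path(out, "wmh_interaction_comparison.csv"),
              row.names = FALSE)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out)
}
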