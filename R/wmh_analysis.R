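# White-matter-hyperintensity frequency maps and the inside/outside-WMH
# sensitivity analysis of the EYO x mutation interaction.

#' Voxel-wise WMH frequency map for a group
#'
#' The number of participants exhibiting a WMH at each voxel divided by the
#' group size.
#'
#' @param masks subjects x voxels logical matrix (or list of logical arrays on
#'   a shared grid).
#' @return numeric vector (or array) of proportions in `[0, 1]`, with
#'   attribute `n_subjects`.
#' @export
wmh_frequency <- function(masks) {
  if (is.list(masks)) {
    d <- dim(masks[[1]])
    if (!all(vapply(masks, function(m) all(dim(m) == d), logical(1))))
      stopf("WMH masks are not on a shared grid")
    masks <- t(vapply(masks, as.logical, logical(prod(d))))
    out <- array(colMeans(masks), dim = d)
  } else {
    if (nrow(masks) == 0) stopf("empty group")
    out <- colMeans(masks)
  }
  attr(out, "n_subjects") <- if (is.matrix(masks)) nrow(masks) else NULL
  out
}

#' Split tract MD into within-WMH and normal-appearing means
#'
#' @param md_values MD values over the skeleton voxels (one subject).
#' @param wmh logical WMH indicator over the same voxels.
#' @param roi logical tract indicator over the same voxels.
#' @param min_voxels minimum voxels for a side to be reported (default 5);
#'   an undefined side is `NA`, never zero.
#' @return named numeric: `inside`, `outside`.
#' @export
split_md_by_wmh <- function(md_values, wmh, roi, min_voxels = 5L) {
  stopifnot(length(md_values) == length(wmh), length(wmh) == length(roi))
  if (!any(roi)) stopf("tract ROI is empty")
  inside_idx <- roi & wmh
  outside_idx <- roi & !wmh
  c(
    inside = if (sum(inside_idx) >= min_voxels)
      mean(md_values[inside_idx]) else NA_real_,
    outside = if (sum(outside_idx) >= min_voxels)
      mean(md_values[outside_idx]) else NA_real_
  )
}

#' Compare EYO x mutation interactions inside vs outside WMH
#'
#' For each tract, tract-average MD is computed separately within WMH voxels
#' and within the normal-appearing remainder, and the robust EYO x mutation
#' model is fitted to each side. Subjects without a WMH mask are treated as
#' lesion-free. Tracts with too few subjects on either side are skipped with
#' a message.
#'
#' @param md subjects x skeleton-voxels MD matrix.
#' @param wmh subjects x skeleton-voxels logical WMH matrix.
#' @param mask logical skeleton mask (voxel order of the matrices).
#' @param rois list of `tract_roi`s (included ones are analysed).
#' @param subjects subject table.
#' @param min_voxels per-side voxel minimum for a subject to contribute.
#' @param min_subjects minimum subjects per side for a fit (default 20).
#' @param k Huber tuning constant.
#' @return data frame: `tract`, `side`, `beta_interaction`, `se_interaction`,
#'   `ci_low`, `ci_high`, `n`.
#' @export
compare_wmh_interactions <- function(md, wmh, mask, rois, subjects,
                                     min_voxels = 5L, min_subjects = 20L,
                                     k = 1.345) {
  rois <- Filter(function(r) r$included, rois)
  rows <- list()
  for (r in rois) {
    sel <- r$mask[mask]
    if (!any(sel)) next
    sides <- t(vapply(seq_len(nrow(md)), function(i)
      split_md_by_wmh(md[i, sel], wmh[i, sel], rep(TRUE, sum(sel)),
                      min_voxels = min_voxels), numeric(2)))
    for (side in c("inside", "outside")) {
      ok <- is.finite(sides[, side])
      if (sum(ok) < min_subjects) {
        message(sprintf("tract '%s': side '%s' skipped (%d usable subjects)",
                        r$tract, side, sum(ok)))
        next
      }
      sub <- subjects[ok, ]
      if (length(unique(sub$mutation_carrier)) < 2) next
      X <- build_design(sub)
      fit <- robust_fit(sides[ok, side], X, k = k)
      b <- fit$beta[["eyo_x_mutation"]]
      se <- fit$se[["eyo_x_mutation"]]
      rows[[length(rows) + 1]] <- data.frame(
        tract = r$tract, side = side, beta_interaction = b,
        se_interaction = se, ci_low = b - qnorm(0.975) * se,
        ci_high = b + qnorm(0.975) * se, n = sum(ok),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) stopf("no tract had a usable inside/outside pair")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
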