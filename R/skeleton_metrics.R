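# Skeletonized MD volumes and the PSMD global white-matter marker.

#' Construct a skeleton volume
#'
#' A 3-D scalar map (typically mean diffusivity in mm^2/s) restricted to a
#' white-matter skeleton mask, with a voxel-to-world affine.
#'
#' @param data numeric 3-D array.
#' @param mask logical 3-D array of the same dimensions; must be non-empty and
#'   `data` must be finite on it.
#' @param affine 4 x 4 voxel-to-world transform (default 2.5 mm isotropic).
#' @return object of class `skeleton_volume`.
#' @export
skeleton_volume <- function(data, mask, affine = diag(c(2.5, 2.5, 2.5, 1))) {
  if (length(dim(data)) != 3L || !all(dim(data) == dim(mask)))
    stopf("data and mask must be 3-D arrays of equal dimensions")
  if (!any(mask)) stopf("mask is empty")
  if (!all(is.finite(data[mask])))
    stopf("non-finite values inside the mask")
  structure(list(data = data, mask = mask, affine = affine),
            class = "skeleton_volume")
}

#' @export
print.skeleton_volume <- function(x, ...) {
  cat(sprintf("<skeleton_volume> %s grid, %d masked voxels\n",
              paste(dim(x$data), collapse = "x"), sum(x$mask)))
  invisible(x)
}

#' Exclude regions from a skeleton volume's mask
#'
#' Removes partial-volume-prone regions (e.g. the fornix) from the analysis
#' mask. The data are unchanged; only the mask shrinks.
#'
#' @param volume a [skeleton_volume()].
#' @param exclusion_mask logical array of the same dimensions; `TRUE` voxels
#'   are removed from the mask.
#' @return a `skeleton_volume` with mask `mask & !exclusion_mask`.
#' @export
apply_custom_mask <- function(volume, exclusion_mask) {
  stopifnot(inherits(volume, "skeleton_volume"))
  if (!all(dim(exclusion_mask) == dim(volume$mask)))
    stopf("exclusion mask dimensions differ from the volume's")
  new_mask <- volume$mask & !exclusion_mask
  if (!any(new_mask))
    stopf("exclusion removes every masked voxel")
  volume$mask <- new_mask
  volume
}

#' Peak-width of skeletonized mean diffusivity (PSMD)
#'
#' PSMD is the width of the skeleton MD distribution: the difference between
#' its 95th and 5th percentiles within the (custom) white-matter mask. Higher
#' values indicate greater dispersion of MD, i.e. more heterogeneous
#' white-matter damage. Percentiles use linear interpolation between closest
#' ranks (`stats::quantile` type 7); no histogram binning is applied.
#'
#' @param volume a [skeleton_volume()], or a plain numeric vector of masked
#'   MD values.
#' @param min_voxels minimum masked voxels for the percentiles to be
#'   meaningful (default 20).
#' @return list with `value` (mm^2/s) and `n_voxels`.
#' @export
compute_psmd <- function(volume, min_voxels = 20L) {
  vals <- if (inherits(volume, "skeleton_volume"))
    volume$data[volume$mask] else as.numeric(volume)
  if (length(vals) < min_voxels)
    stopf("PSMD needs >= %d masked voxels, got %d", min_voxels, length(vals))
  if (!all(is.finite(vals)))
    stopf("non-finite MD values inside the mask")
  q <- quantile(vals, probs = c(0.05, 0.95), names = FALSE, type = 7)
  list(value = q[2] - q[1], n_voxels = length(vals))
}

#' PSMD for every subject of a cohort
#'
#' @param md subjects x voxels matrix of skeleton MD values.
#' @param subject_ids optional ids for the output table.
#' @return data frame with `subject_id` and `psmd`.
#' @export
psmd_table <- function(md, subject_ids = rownames(md)) {
  stopifnot(is.matrix(md))
  if (is.null(subject_ids)) subject_ids <- sprintf("sub-%03d", seq_len(nrow(md)))
  data.frame(
    subject_id = subject_ids,
    psmd = apply(md, 1, function(v) compute_psmd(v)$value),
    stringsAsFactors = FALSE
  )
}
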