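# Projection of fibre-tract terminal segments into grey matter, grey-matter
# volume extraction per projection zone, and tract-MD -> GM-volume
# association testing with FDR correction.
#
# Streamlines are matrices of ordered 3-D points in continuous, 0-based voxel
# coordinates.

validate_streamline <- function(s) {
  if (!is.matrix(s) || ncol(s) != 3 || nrow(s) < 3)
    stopf("a streamline needs >= 3 points with 3 coordinates each")
  steps <- diff(s)
  if (any(rowSums(steps^2) == 0))
    stopf("consecutive streamline points must be distinct")
  invisible(s)
}

#' Outward direction of a streamline's terminal section
#'
#' The direction of fibre projection is the normalized average of
#' finite-difference tangents taken at regularly spaced points within the
#' terminal section of the streamline, oriented outward (from the interior
#' toward the endpoint).
#'
#' @param s streamline points matrix (0-based continuous voxel coordinates).
#' @param end `"last"` or `"first"` endpoint.
#' @param k_points number of tangent sample points (default 5).
#' @param spacing index spacing between samples (default 1).
#' @return unit 3-vector.
#' @export
terminal_direction <- function(s, end = c("last", "first"), k_points = 5L,
                               spacing = 1L) {
  end <- match.arg(end)
  validate_streamline(s)
  n <- nrow(s)
  if (end == "first") s <- s[n:1, , drop = FALSE]
  needed <- k_points * spacing + 1
  if (n < needed)
    stopf("streamline too short (%d points) for %d tangents at spacing %d",
          n, k_points, spacing)
  idx <- n - (k_points - 1):0 * spacing           # regularly spaced, at the end
  tangents <- s[idx, , drop = FALSE] - s[idx - spacing, , drop = FALSE]
  v <- colMeans(tangents)
  nv <- sqrt(sum(v^2))
  if (nv == 0) stopf("degenerate terminal section (zero mean tangent)")
  v / nv
}

#' Project a streamline terminal into grey matter
#'
#' Marches from the terminal point along `direction` in sub-voxel steps (up to
#' `max_extension` voxels), collects the traversed voxels that fall inside the
#' grey-matter mask, and adds the surrounding neighbourhood
#' (Chebyshev radius `dilation_radius`) intersected with the mask. If the ray
#' never enters grey matter the contribution is empty (a valid result).
#'
#' @param s streamline points matrix.
#' @param direction unit 3-vector (e.g. from [terminal_direction()]).
#' @param gm_mask logical 3-D grey-matter mask.
#' @param end `"last"` or `"first"`.
#' @param max_extension maximum march length in voxels (default 10).
#' @param dilation_radius neighbourhood radius in voxels (default 1).
#' @param step march step in voxels (default 0.5).
#' @return list of class `projection_zone`: `voxels` (linear indices into
#'   `gm_mask`), `endpoint_count` (1 if the ray entered GM, else 0).
#' @export
project_into_gm <- function(s, direction, gm_mask, end = c("last", "first"),
                            max_extension = 10, dilation_radius = 1L,
                            step = 0.5) {
  end <- match.arg(end)
  validate_streamline(s)
  if (abs(sqrt(sum(direction^2)) - 1) > 1e-6)
    stopf("direction must be unit norm")
  d <- dim(gm_mask)
  terminal <- if (end == "last") s[nrow(s), ] else s[1, ]
  ts <- seq(0, max_extension, by = step)
  pos <- matrix(rep(terminal, each = length(ts)), ncol = 3) +
    outer(ts, direction)
  # voxel containing a continuous 0-based coordinate: centres at integers,
  # half-up so that integer translations commute with voxelization
  vox <- floor(pos + 0.5) + 1
  inb <- vox[, 1] >= 1 & vox[, 1] <= d[1] &
         vox[, 2] >= 1 & vox[, 2] <= d[2] &
         vox[, 3] >= 1 & vox[, 3] <= d[3]
  vox <- vox[inb, , drop = FALSE]
  if (nrow(vox) == 0)
    return(structure(list(voxels = integer(0), endpoint_count = 0L),
                     class = "projection_zone"))
  lin <- unique(vox[, 1] + d[1] * (vox[, 2] - 1) + d[1] * d[2] * (vox[, 3] - 1))
  gm_hit <- lin[gm_mask[lin]]
  if (!length(gm_hit))
    return(structure(list(voxels = integer(0), endpoint_count = 0L),
                     class = "projection_zone"))
  zone <- dilate_voxels(gm_hit, d, dilation_radius)
  zone <- zone[gm_mask[zone]]
  structure(list(voxels = sort(zone), endpoint_count = 1L),
            class = "projection_zone")
}

# Chebyshev dilation of a set of linear voxel indices
dilate_voxels <- function(lin, dims, radius) {
  if (radius <= 0) return(unique(lin))
  coord <- arrayInd(lin, dims)
  offs <- as.matrix(expand.grid(dx = -radius:radius, dy = -radius:radius,
                                dz = -radius:radius))
  out <- do.call(rbind, lapply(seq_len(nrow(offs)), function(k)
    sweep(coord, 2, offs[k, ], `+`)))
  keep <- out[, 1] >= 1 & out[, 1] <= dims[1] &
          out[, 2] >= 1 & out[, 2] <= dims[2] &
          out[, 3] >= 1 & out[, 3] <= dims[3]
  out <- out[keep, , drop = FALSE]
  unique(out[, 1] + dims[1] * (out[, 2] - 1) + dims[1] * dims[2] * (out[, 3] - 1))
}

#' Pool per-streamline projection zones into one tract zone
#'
#' Both streamline ends are projected and the per-streamline contributions are
#' unioned into a single tract projection-zone mask.
#'
#' @param streamlines list of streamline point matrices.
#' @param gm_mask logical grey-matter mask.
#' @param ends which endpoints to project (default both).
#' @param ... passed to [terminal_direction()] and [project_into_gm()]
#'   (`k_points`, `spacing`, `max_extension`, `dilation_radius`, `step`).
#' @param k_points,spacing tangent sampling (see [terminal_direction()]).
#' @param max_extension,dilation_radius,step marching parameters (see
#'   [project_into_gm()]).
#' @return `projection_zone` with pooled `voxels` and total `endpoint_count`.
#' @export
build_projection_zones <- function(streamlines, gm_mask,
                                   ends = c("last", "first"),
                                   k_points = 5L, spacing = 1L,
                                   max_extension = 10, dilation_radius = 1L,
                                   step = 0.5) {
  vox <- integer(0)
  count <- 0L
  for (s in streamlines) {
    for (e in ends) {
      dir <- terminal_direction(s, end = e, k_points = k_points,
                                spacing = spacing)
      z <- project_into_gm(s, dir, gm_mask, end = e,
                           max_extension = max_extension,
                           dilation_radius = dilation_radius, step = step)
      vox <- c(vox, z$voxels)
      count <- count + z$endpoint_count
    }
  }
  structure(list(voxels = sort(unique(vox)), endpoint_count = count),
            class = "projection_zone")
}

#' Grey-matter volume within a projection zone
#'
#' @param gm_density 3-D grey-matter density/probability map.
#' @param zone a `projection_zone`.
#' @param voxel_volume volume of one voxel (mm^3).
#' @return sum of density over the zone times `voxel_volume`.
#' @export
gm_volume_in_zone <- function(gm_density, zone, voxel_volume = 1) {
  if (!length(zone$voxels)) stopf("projection zone is empty")
  sum(gm_density[zone$voxels]) * voxel_volume
}

#' Tract MD - grey-matter volume associations with FDR correction
#'
#' Per tract, a robust regression of projection-zone grey-matter volume on
#' tract-average MD with sex and education covariates; Benjamini-Hochberg
#' adjustment across tracts.
#'
#' @param md_table long data frame `subject_id`, `measure` (tract), `value`.
#' @param volumes long data frame `subject_id`, `measure` (tract), `volume`.
#' @param subjects subject table.
#' @param k Huber tuning constant.
#' @return data frame: `tract`, `B`, `SE`, `p`, `fdr_p`, `n`.
#' @export
md_gm_association <- function(md_table, volumes, subjects, k = 1.345) {
  tracts <- intersect(unique(md_table$measure), unique(volumes$measure))
  if (!length(tracts)) stopf("no tract present in both tables")
  rows <- lapply(tracts, function(tr) {
    a <- md_table[md_table$measure == tr, c("subject_id", "value")]
    b <- volumes[volumes$measure == tr, c("subject_id", "volume")]
    dat <- merge(merge(a, b, by = "subject_id"), subjects, by = "subject_id")
    y <- as.numeric(scale(dat$volume))
    x <- as.numeric(scale(dat$value))
    X <- cbind(intercept = 1, md = x, sex = dat$sex, education = dat$education)
    fit <- robust_fit(y, X, k = k)
    B <- fit$beta[["md"]]
    SE <- fit$se[["md"]]
    data.frame(tract = tr, B = B, SE = SE, p = 2 * pnorm(-abs(B / SE)),
               n = nrow(dat), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr_p <- stats::p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  out
}

#' Read/write streamlines as plain text
#'
#' The format is the common per-streamline text dump: one `x y z` point per
#' line, streamlines separated by blank lines.
#'
#' @param path file path.
#' @return list of streamline matrices.
#' @export
read_streamlines <- function(path) {
  lines <- readLines(path)
  groups <- split(lines, cumsum(lines == ""))
  sl <- lapply(groups, function(g) {
    g <- g[g != ""]
    if (!length(g)) return(NULL)
    m <- do.call(rbind, lapply(strsplit(trimws(g), "\\s+"), as.numeric))
    if (ncol(m) != 3 || anyNA(m)) stopf("malformed streamline block in %s", path)
    m
  })
  Filter(Negate(is.null), unname(sl))
}

#' @rdname read_streamlines
#' @param streamlines list of point matrices.
#' @export
write_streamlines <- function(streamlines, path) {
  blocks <- vapply(streamlines, function(s)
    paste(apply(s, 1, paste, collapse = " "), collapse = "\n"), character(1))
  writeLines(paste(blocks, collapse = "\n\n"), path)
  invisible(path)
}
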