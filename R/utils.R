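# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Embed a vector of masked-voxel values into a full 3-D array
#'
#' Values are assigned to the `TRUE` voxels of `mask` in column-major order,
#' the convention used throughout the package for flattening skeleton data.
#'
#' @param values numeric vector, one value per `TRUE` voxel of `mask`.
#' @param mask logical 3-D array.
#' @param fill value used off the mask (default 0).
#' @return numeric array with `dim(mask)`.
#' @export
vec_to_vol <- function(values, mask, fill = 0) {
  if (!is.logical(mask) || length(dim(mask)) != 3L)
    stopf("mask must be a logical 3-D array")
  if (length(values) != sum(mask))
    stopf("length(values) [%d] != number of masked voxels [%d]",
          length(values), sum(mask))
  vol <- array(fill, dim = dim(mask))
  vol[mask] <- values
  vol
}

#' Extract masked-voxel values from a 3-D array
#'
#' @param vol numeric 3-D array.
#' @param mask logical 3-D array of the same dimensions.
#' @return numeric vector in column-major voxel order.
#' @export
vol_to_vec <- function(vol, mask) {
  if (!all(dim(vol) == dim(mask)))
    stopf("volume and mask dimensions differ")
  vol[mask]
}

# deterministic child seed for a named pipeline stage, kept below 2^31
derive_seed <- function(seed, label) {
  offs <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  (as.integer(seed) + offs * 1009L) %% 2147483647L
}

# run code under a seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}
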