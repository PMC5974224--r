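# Thin R wrappers around the compiled 3D kernels.  All take/return plain
# 3D arrays dim = c(nx, ny, nz); 26-connectivity throughout.

.dims3 <- function(x) {
  d <- dim(x)
  if (is.null(d) || length(d) != 3L)
    stop("expected a 3D array", call. = FALSE)
  as.integer(d)
}

#' Squared Euclidean distance transform of a 3D set
#'
#' Distance from every voxel to the nearest `TRUE` voxel, with per-axis
#' physical spacing, computed by a separable lower-envelope algorithm.
#' Voxels with no source anywhere in the volume get `Inf`.
#'
#' @param mask logical 3D array (the source set).
#' @param voxel_size numeric length-3, physical size of a voxel per axis
#'   (same units as the returned distances); default unit voxels.
#' @return numeric 3D array of squared distances.
#' @export
edt_sq <- function(mask, voxel_size = c(1, 1, 1)) {
  d <- .dims3(mask)
  out <- cpp_edt_sq(as.logical(mask), d, as.numeric(voxel_size))
  out[out >= 1e14] <- Inf
  array(out, dim = d)
}

#' Label 26-connected components of a 3D mask
#'
#' @param mask logical 3D array.
#' @return integer 3D array; background 0, components 1..K in raster order.
#' @export
label_components <- function(mask) {
  d <- .dims3(mask)
  array(cpp_label_components(as.logical(mask), d), dim = d)
}

#' Dilate a 3D set by a Euclidean ball
#'
#' Grid-space dilation: a voxel belongs to the result iff its Euclidean
#' distance (in voxel units, anisotropy-naive) to the set is at most
#' `radius`.  `radius = 0` returns the set itself.
#'
#' @param mask logical 3D array.
#' @param radius ball radius in voxels.
#' @return logical 3D array containing `mask`.
#' @export
dilate_ball <- function(mask, radius) {
  stopifnot(radius >= 0)
  if (radius == 0) return(mask & TRUE)
  d2 <- edt_sq(mask, c(1, 1, 1))
  d2 <= radius^2 + 1e-9
}

# Dilation of a voxel index set, computed on a cropped padded bounding box
# so large stacks stay cheap.  Returns linear indices of the dilated set.
.dilate_indices <- function(idx, dims, radius) {
  if (length(idx) == 0L) return(integer(0))
  r <- ceiling(radius)
  co <- arrayInd(idx, dims)
  lo <- pmax(apply(co, 2, min) - r, 1L)
  hi <- pmin(apply(co, 2, max) + r, dims)
  sub <- array(FALSE, hi - lo + 1L)
  sub[cbind(co[, 1] - lo[1] + 1L, co[, 2] - lo[2] + 1L, co[, 3] - lo[3] + 1L)] <- TRUE
  dil <- dilate_ball(sub, radius)
  ci <- which(dil, arr.ind = TRUE)
  as.integer((ci[, 1] + lo[1] - 2L) +
             dims[1] * ((ci[, 2] + lo[2] - 2L) +
             dims[2] * (ci[, 3] + lo[3] - 2L)) + 1L)
}

#' Separable Gaussian blur of a 3D array
#'
#' @param img numeric 3D array.
#' @param sigma per-axis standard deviation in voxel units (length 1 or 3);
#'   zero disables the pass along that axis.
#' @return blurred array of the same shape.
#' @export
gaussian_blur <- function(img, sigma) {
  d <- .dims3(img)
  if (length(sigma) == 1L) sigma <- rep(sigma, 3)
  array(cpp_gaussian_blur(as.numeric(img), d, as.numeric(sigma)), dim = d)
}

# h-maxima seeds: suppress maxima shallower than h via grayscale
# reconstruction, then label the regional maxima of the result.
.hmax_seeds <- function(f, mask, h) {
  d <- .dims3(f)
  rec <- cpp_reconstruct(as.numeric(f - h), as.numeric(f), d)
  rmax <- cpp_regional_maxima(rec, as.logical(mask), d)
  array(cpp_label_components(rmax & as.logical(mask), d), dim = d)
}
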