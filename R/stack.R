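# ImageStack container: one 4-channel 3D acquisition plus geometry and
# provenance.  Voxels are stored as a 4D array dim = c(nx, ny, nz, 4) in
# acquisition channel order DAPI, OX42, GR, GFAP.

#' Construct an image stack
#'
#' @param voxels numeric 4D array `c(nx, ny, nz, 4)`, nonnegative
#'   intensities, channels in acquisition order DAPI, OX-42, GR, GFAP.
#' @param voxel_size physical voxel size in micrometres, named or ordered
#'   `(x, y, z)`.
#' @param meta list with provenance fields `animal_id`, `age`
#'   (`"young"`/`"aged"`), `stress` (`"control"`/`"stress"`/`"recovery"`),
#'   `image_id`.
#' @return object of class `glia_stack`.
#' @export
glia_stack <- function(voxels, voxel_size = c(0.2, 0.2, 0.5), meta = list()) {
  d <- dim(voxels)
  if (length(d) != 4L || d[4] != 4L)
    stop("voxels must be a 4D array with exactly 4 channels", call. = FALSE)
  if (any(voxels < 0)) stop("intensities must be nonnegative", call. = FALSE)
  stopifnot(length(voxel_size) == 3L, all(voxel_size > 0))
  structure(list(
    voxels = voxels,
    channels = CHANNELS,
    voxel_size = setNames(as.numeric(voxel_size), c("x", "y", "z")),
    meta = meta
  ), class = "glia_stack")
}

#' Extract one channel of a stack as a 3D array
#'
#' @param stack a `glia_stack`.
#' @param channel channel name (`"DAPI"`, `"OX42"`, `"GR"`, `"GFAP"`) or index.
#' @return numeric 3D array.
#' @export
get_channel <- function(stack, channel) {
  stopifnot(inherits(stack, "glia_stack"))
  if (is.character(channel)) channel <- match(channel, stack$channels)
  if (is.na(channel) || channel < 1 || channel > 4)
    stop("unknown channel", call. = FALSE)
  stack$voxels[, , , channel, drop = TRUE]
}

#' @export
print.glia_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<glia_stack> %d x %d x %d voxels, 4 channels (%s)\n",
              d[1], d[2], d[3], paste(x$channels, collapse = ", ")))
  cat(sprintf("  voxel size: %.3g x %.3g x %.3g um\n",
              x$voxel_size[1], x$voxel_size[2], x$voxel_size[3]))
  if (length(x$meta))
    cat("  meta:", paste(names(x$meta), unlist(lapply(x$meta, format)),
                         sep = "=", collapse = ", "), "\n")
  invisible(x)
}
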