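# Per-channel noise thresholding and binarization.  Thresholds are always
# computed per image (never per cohort), and the value actually used is
# carried on the resulting mask so every downstream number is reproducible.

#' Compute a noise-exclusion threshold for one channel
#'
#' The intensity distribution of the channel is reduced to a single scalar
#' cut separating background noise from signal.  Three methods are
#' available:
#' \describe{
#'   \item{`otsu`}{maximises the between-class variance over a 256-bin
#'     histogram of the channel (default);}
#'   \item{`percentile`}{the `p`-th percentile of all intensities
#'     (`params$p`, type-7 quantile);}
#'   \item{`fixed`}{a user-supplied constant (`params$value`).}
#' }
#'
#' @param channel numeric 3D intensity array.
#' @param method `"otsu"`, `"percentile"` or `"fixed"`.
#' @param params list of method parameters (`p` for percentile, `value`
#'   for fixed).
#' @return scalar threshold, with attribute `method`.
#' @export
compute_threshold <- function(channel, method = c("otsu", "percentile", "fixed"),
                              params = list()) {
  method <- match.arg(method)
  v <- as.numeric(channel)
  if (length(v) == 0L) stop("empty channel", call. = FALSE)
  thr <- switch(method,
    fixed = {
      if (is.null(params$value)) stop("fixed threshold needs params$value",
                                      call. = FALSE)
      as.numeric(params$value)
    },
    percentile = {
      if (is.null(params$p)) stop("percentile threshold needs params$p",
                                  call. = FALSE)
      as.numeric(quantile(v, params$p / 100, names = FALSE))
    },
    otsu = .otsu(v)
  )
  structure(thr, method = method)
}

# Otsu's method on a 256-bin histogram spanning the channel's range.
# Returns the bin-centre cut maximising between-class variance; ties are
# broken toward the lowest cut for determinism.
.otsu <- function(v, nbins = 256L) {
  lo <- min(v); hi <- max(v)
  if (hi <= lo)
    stop("degenerate histogram: channel is constant, Otsu undefined",
         call. = FALSE)
  br <- seq(lo, hi, length.out = nbins + 1L)
  h <- tabulate(pmin(pmax(findInterval(v, br, rightmost.closed = TRUE), 1L),
                     nbins), nbins)
  mids <- (br[-1] + br[-(nbins + 1L)]) / 2
  w <- cumsum(h)
  m <- cumsum(h * mids)
  n <- w[nbins]; mtot <- m[nbins]
  w0 <- w[-nbins]; m0 <- m[-nbins]
  w1 <- n - w0
  valid <- w0 > 0 & w1 > 0
  bc <- rep(-Inf, nbins - 1L)
  bc[valid] <- (mtot * w0[valid] / n - m0[valid])^2 /
    (w0[valid] / n * w1[valid] / n) / n^2
  k <- which.max(bc)
  mids[k]
}

#' Binarize a channel at a threshold
#'
#' A voxel is foreground iff its intensity is strictly greater than the
#' threshold, so fixed-threshold results are bit-exact and raising the
#' threshold can only remove voxels.
#'
#' @param channel numeric 3D intensity array.
#' @param threshold finite scalar (e.g. from [compute_threshold()]).
#' @param channel_name optional channel label recorded on the mask.
#' @return object of class `binary_mask`: list with `mask` (logical 3D
#'   array), `source_channel`, `threshold_used`, `method`.
#' @export
binarize <- function(channel, threshold, channel_name = NA_character_) {
  stopifnot(is.finite(threshold))
  structure(list(
    mask = channel > as.numeric(threshold),
    source_channel = channel_name,
    threshold_used = as.numeric(threshold),
    method = attr(threshold, "method") %||% "fixed"
  ), class = "binary_mask")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Accept either a binary_mask or a bare logical array in mask-consuming
# operations.
.as_mask_array <- function(m) {
  if (inherits(m, "binary_mask")) m$mask else (m & TRUE)
}

#' Threshold and binarize all four channels of a stack
#'
#' Applies [compute_threshold()] + [binarize()] channel by channel, on an
#' image-by-image basis.  Per-channel method overrides come from
#' `config$threshold`, a named list like
#' `list(DAPI = list(method = "percentile", p = 90))`.
#'
#' @param stack a `glia_stack`.
#' @param config optional pipeline configuration (see [pipeline_config()]).
#' @return named list of `binary_mask`, one per channel.
#' @export
preprocess_stack <- function(stack, config = pipeline_config()) {
  stopifnot(inherits(stack, "glia_stack"))
  out <- lapply(stack$channels, function(ch) {
    cfg <- config$threshold[[ch]] %||% list(method = "otsu")
    v <- get_channel(stack, ch)
    # a constant channel (e.g. a marker absent from the scene) has no
    # histogram to threshold: everything is background
    if (cfg$method == "otsu" && max(v) == min(v)) {
      thr <- structure(max(v), method = "constant_channel")
      return(binarize(v, thr, channel_name = ch))
    }
    thr <- compute_threshold(v, cfg$method, params = cfg)
    binarize(v, thr, channel_name = ch)
  })
  names(out) <- stack$channels
  out
}
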