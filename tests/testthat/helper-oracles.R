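# Brute-force oracles, written independently of the package internals:
# explicit per-voxel loops and closed-form arithmetic only.

# squared distance from every voxel to the nearest TRUE voxel, by
# exhaustive pairwise search (tiny arrays only)
oracle_edt_sq <- function(mask, w = c(1, 1, 1)) {
  d <- dim(mask)
  src <- which(mask, arr.ind = TRUE)
  out <- array(Inf, d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (nrow(src) == 0) next
    dd <- (w[1] * (src[, 1] - i))^2 + (w[2] * (src[, 2] - j))^2 +
      (w[3] * (src[, 3] - k))^2
    out[i, j, k] <- min(dd)
  }
  out
}

# Euclidean-ball dilation by direct offset enumeration
oracle_dilate <- function(mask, radius) {
  d <- dim(mask)
  out <- array(FALSE, d)
  r <- ceiling(radius)
  offs <- expand.grid(dx = -r:r, dy = -r:r, dz = -r:r)
  offs <- offs[offs$dx^2 + offs$dy^2 + offs$dz^2 <= radius^2 + 1e-9, ]
  src <- which(mask, arr.ind = TRUE)
  for (s in seq_len(nrow(src))) {
    x <- src[s, 1] + offs$dx; y <- src[s, 2] + offs$dy; z <- src[s, 3] + offs$dz
    ok <- x >= 1 & y >= 1 & z >= 1 & x <= d[1] & y <= d[2] & z <= d[3]
    out[cbind(x[ok], y[ok], z[ok])] <- TRUE
  }
  out
}

# Otsu by exhaustive search over all distinct cut points: maximize
# between-class variance of the two groups induced by value > cut
oracle_otsu_bc <- function(v, cut) {
  g1 <- v[v <= cut]; g2 <- v[v > cut]
  if (!length(g1) || !length(g2)) return(-Inf)
  w1 <- length(g1) / length(v); w2 <- length(g2) / length(v)
  w1 * w2 * (mean(g1) - mean(g2))^2
}

# a small random logical stack
random_mask <- function(dims, p = 0.3) {
  array(runif(prod(dims)) < p, dims)
}

# quiet scene specs used across test files
spec_noise_free <- function(...) {
  scene_spec(noise = c(0, 0), psf_sigma = c(0, 0, 0), ...)
}
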