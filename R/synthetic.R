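# Synthetic 4-channel confocal scene generator with full ground truth.
#
# The generator emulates the statistical structure the analysis assumes,
# not microscopy physics: ellipsoidal nuclei of controlled voxel volume,
# microglial OX-42 as a soma shell (nucleus dilation, guaranteeing the
# 100%-colocalization property) plus random-walk processes, astrocytic
# GFAP as star filaments that may deliberately fail to cover the nucleus
# (the GFAP/DAPI colocalization failure mode), and GR split between a
# contiguous nuclear blob and cytoplasmic puncta.  Poisson-then-Gaussian
# noise and an anisotropic Gaussian PSF are independently switchable so
# noise-free runs serve as oracles.

#' Specify one synthetic 4-channel scene
#'
#' All geometric defaults mirror the acquisition the pipeline targets:
#' 0.5 um z-step and (by configuration, not measurement) 0.2 um xy pixel
#' pitch.  Intensities are flat per channel before PSF/noise so that with
#' both disabled, binarizing any channel at `signal_floor` recovers the
#' true mask exactly.
#'
#' @param stack_shape voxel counts `(x, y, z)`.
#' @param voxel_size physical voxel size in micrometres `(x, y, z)`.
#' @param n_microglia,n_astrocytes,n_other_nuclei cell counts.
#' @param nucleus_volume_range accepted voxelized nucleus volume (voxels).
#' @param soma_thickness microglial soma shell thickness beyond the
#'   nucleus, in voxels.
#' @param arbor_extent maximum reach of glial processes from the nucleus
#'   centre, in micrometres.
#' @param arbor_volume mean microglial process volume per cell (voxels);
#'   per-cell draws have 15% relative SD.
#' @param gr_nuclear_fill named list of mean nuclear GR fill fraction per
#'   cell type (`microglia`, `astrocyte`, `other`); per-cell draws have
#'   SD 0.08, clamped to `[0, 1]`.
#' @param gr_cytoplasmic_density expected cytoplasmic GR puncta per cell
#'   (Poisson).
#' @param gfap_nucleus_coverage fraction of astrocytes whose nucleus is
#'   fully covered by GFAP; the rest are only partially covered.
#' @param noise `c(poisson_scale, gaussian_sd)`; zero disables each part.
#' @param psf_sigma Gaussian PSF sigma in voxels per axis (z broader than
#'   xy); zeros disable blurring.
#' @param levels per-channel foreground intensity.
#' @param signal_floor binarization floor separating signal from empty
#'   background in the noise-free regime.
#' @param placement_margin minimum gap (voxels) enforced between nuclei.
#' @param seed integer RNG seed; identical spec + seed reproduces the
#'   stack bit-exactly.
#' @return object of class `scene_spec`.
#' @export
scene_spec <- function(stack_shape = c(128, 128, 24),
                       voxel_size = c(0.2, 0.2, 0.5),
                       n_microglia = 4, n_astrocytes = 3, n_other_nuclei = 5,
                       nucleus_volume_range = c(1100, 1400),
                       soma_thickness = 3,
                       arbor_extent = 10,
                       arbor_volume = 2000,
                       gr_nuclear_fill = list(microglia = 0.85,
                                              astrocyte = 0.6, other = 0.85),
                       gr_cytoplasmic_density = 8,
                       gfap_nucleus_coverage = 0.2,
                       noise = c(poisson_scale = 0.5, gaussian_sd = 5),
                       psf_sigma = c(0.6, 0.6, 0.4),
                       levels = c(DAPI = 160, OX42 = 180, GR = 200, GFAP = 170),
                       signal_floor = 50,
                       placement_margin = 3,
                       seed = 1L) {
  stopifnot(length(stack_shape) == 3L, all(stack_shape >= 1),
            length(voxel_size) == 3L, all(voxel_size > 0),
            n_microglia >= 0, n_astrocytes >= 0, n_other_nuclei >= 0,
            length(nucleus_volume_range) == 2L,
            nucleus_volume_range[1] <= nucleus_volume_range[2],
            soma_thickness >= 0, arbor_extent > 0, arbor_volume >= 0,
            gr_cytoplasmic_density >= 0,
            gfap_nucleus_coverage >= 0, gfap_nucleus_coverage <= 1,
            length(noise) == 2L, all(noise >= 0),
            placement_margin >= 0)
  fills <- unlist(gr_nuclear_fill)
  if (any(fills < 0 | fills > 1))
    stop("gr_nuclear_fill fractions must lie in [0, 1]", call. = FALSE)
  if (length(psf_sigma) == 1L) psf_sigma <- rep(psf_sigma, 3)
  structure(list(
    stack_shape = as.integer(stack_shape),
    voxel_size = setNames(as.numeric(voxel_size), c("x", "y", "z")),
    n_microglia = as.integer(n_microglia),
    n_astrocytes = as.integer(n_astrocytes),
    n_other_nuclei = as.integer(n_other_nuclei),
    nucleus_volume_range = as.numeric(nucleus_volume_range),
    soma_thickness = as.numeric(soma_thickness),
    arbor_extent = as.numeric(arbor_extent),
    arbor_volume = as.numeric(arbor_volume),
    gr_nuclear_fill = as.list(gr_nuclear_fill),
    gr_cytoplasmic_density = as.numeric(gr_cytoplasmic_density),
    gfap_nucleus_coverage = as.numeric(gfap_nucleus_coverage),
    noise = setNames(as.numeric(noise), c("poisson_scale", "gaussian_sd")),
    psf_sigma = as.numeric(psf_sigma),
    levels = levels,
    signal_floor = as.numeric(signal_floor),
    placement_margin = as.numeric(placement_margin),
    seed = as.integer(seed)
  ), class = "scene_spec")
}

# --- geometric helpers --------------------------------------------------

# Linear voxel indices of an ellipsoid; centre and semi-axes in voxel
# coordinates.
.ellipsoid_idx <- function(center, semi, dims) {
  lo <- pmax(floor(center - semi), 1)
  hi <- pmin(ceiling(center + semi), dims)
  if (any(lo > hi)) return(integer(0))
  xs <- lo[1]:hi[1]; ys <- lo[2]:hi[2]; zs <- lo[3]:hi[3]
  gx <- ((xs - center[1]) / semi[1])^2
  gy <- ((ys - center[2]) / semi[2])^2
  gz <- ((zs - center[3]) / semi[3])^2
  inside <- outer(outer(gx, gy, `+`), gz, `+`) <= 1
  ci <- which(inside, arr.ind = TRUE)
  if (nrow(ci) == 0L) return(integer(0))
  as.integer((xs[ci[, 1]] - 1L) +
             dims[1] * ((ys[ci[, 2]] - 1L) + dims[2] * (zs[ci[, 3]] - 1L)) + 1L)
}

# Sample ellipsoid semi-axes whose voxelized volume falls in vol_range.
# aspect = z semi-axis relative to xy (physically round nuclei on an
# anisotropic grid).  Returns list(semi, idx) for the given centre, or
# NULL after bounded retries.
.sample_nucleus_shape <- function(center, vol_range, aspect, dims,
                                  max_tries = 100L) {
  for (t in seq_len(max_tries)) {
    v <- runif(1, vol_range[1], vol_range[2])
    r <- (3 * v / (4 * pi * aspect))^(1 / 3)
    jit <- runif(3, 0.92, 1.08)
    jit <- jit / prod(jit)^(1 / 3)
    semi <- c(r * jit[1], r * jit[2], aspect * r * jit[3])
    idx <- .ellipsoid_idx(center, semi, dims)
    n <- length(idx)
    if (n >= vol_range[1] && n <= vol_range[2]) return(list(semi = semi, idx = idx))
  }
  NULL
}

# Random unit vector (physical space).
.runit <- function() {
  repeat {
    u <- rnorm(3)
    n <- sqrt(sum(u^2))
    if (n > 1e-8) return(u / n)
  }
}

# Random-walk arbor from the soma: branches start on the soma surface and
# wander with a mild outward drift (processes radiate from the soma, and
# unpainted territory lies at larger radius), constrained to the stack
# and to arbor_extent (um) of the nucleus centre, painting 3x3x3 blocks.
# New branches are started until target_voxels are newly set; a branch
# that stops finding fresh voxels is abandoned, and a global step cap
# guards against pathological confinement.  Painting is inlined (no
# helper call) so the canvas is modified in place.
.grow_arbor <- function(canvas, soma_idx, center, spec, target_voxels) {
  dims <- spec$stack_shape
  vs <- spec$voxel_size
  steps_cap <- 200L * max(1L, ceiling(target_voxels / 9))
  steps <- 0L
  added <- 0L
  while (added < target_voxels && steps < steps_cap) {
    s <- soma_idx[sample.int(length(soma_idx), 1L)]
    pos <- as.numeric(arrayInd(s, dims))
    dir <- .runit()
    stall <- 0L
    while (steps < steps_cap && added < target_voxels && stall < 80L) {
      steps <- steps + 1L
      # physical step of ~1 xy-voxel, converted to voxel displacement
      pos_new <- pos + dir * vs[1] / vs
      phys <- (pos_new - center) * vs
      if (any(pos_new < 2) || any(pos_new > dims - 1) ||
          sqrt(sum(phys^2)) > spec$arbor_extent) {
        dir <- .runit()   # bounce: pick a fresh direction
        stall <- stall + 1L
        next
      }
      pos <- pos_new
      p <- as.integer(round(pos))
      xs <- (p[1] - 1L):(p[1] + 1L)
      ys <- (p[2] - 1L):(p[2] + 1L)
      zs <- (p[3] - 1L):(p[3] + 1L)
      block <- canvas[xs, ys, zs]
      new_here <- sum(!block)
      added <- added + new_here
      stall <- if (new_here > 0L) 0L else stall + 1L
      canvas[xs, ys, zs] <- TRUE
      # outward drift plus occasional random kinks
      out <- (pos - center) * vs
      on <- sqrt(sum(out^2))
      if (on > 1e-6) {
        dir <- dir + 0.12 * out / on
        dir <- dir / sqrt(sum(dir^2))
      }
      if (runif(1) < 0.15) {
        dir <- dir + 0.8 * .runit()
        dir <- dir / sqrt(sum(dir^2))
      }
    }
  }
  canvas
}

# Star-shaped GFAP filaments radiating from the astrocyte centre.
.grow_star <- function(canvas, center, spec, n_rays = 8L) {
  dims <- spec$stack_shape
  vs <- spec$voxel_size
  for (r in seq_len(n_rays)) {
    dir <- .runit()
    len <- runif(1, 0.5, 1) * spec$arbor_extent
    tt <- seq(0, len, by = vs[1] / 2)
    for (s in tt) {
      p <- as.integer(round(center + dir * s / vs))
      if (any(p < 2) || any(p > dims - 1)) break
      canvas[(p[1] - 1L):(p[1] + 1L),
             (p[2] - 1L):(p[2] + 1L),
             (p[3] - 1L):(p[3] + 1L)] <- TRUE
    }
  }
  canvas
}

# Contiguous subset of a nucleus: its voxels ordered by distance from a
# seed voxel, first k taken.
.contiguous_subset <- function(idx, k, dims) {
  if (k <= 0L) return(integer(0))
  if (k >= length(idx)) return(idx)
  co <- arrayInd(idx, dims)
  seed <- co[sample.int(nrow(co), 1L), ]
  d2 <- (co[, 1] - seed[1])^2 + (co[, 2] - seed[2])^2 + (co[, 3] - seed[3])^2
  idx[order(d2, idx)[seq_len(k)]]
}

# --- stack generation ---------------------------------------------------

#' Generate one synthetic 4-channel stack with ground truth
#'
#' Places the requested cells without overlap (bounded retries; an
#' overcrowded scene raises a placement-failure error rather than
#' silently dropping cells), draws the four channels, records every
#' placement in the ground truth, then applies PSF and noise.
#'
#' Guarantees, by construction, before PSF/noise:
#' every microglial nucleus voxel is OX-42-positive (the soma shell is a
#' dilation of the nucleus); cytoplasmic GR puncta never intersect any
#' nucleus; nuclear GR voxels are a subset of their nucleus.
#'
#' @param spec a [scene_spec()].
#' @return list with `stack` (a [glia_stack()]) and `truth`: per-cell
#'   records (`id`, `type`, `nucleus_voxels`, `nucleus_volume`,
#'   `soma_voxels`, `nuclear_gr_fraction`, `nuclear_gr_voxels`,
#'   `cyto_gr_voxels`, `center`) plus per-channel true total volumes
#'   (`totals`), the `signal_floor`, and `dims`.
#' @export
generate_stack <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  set.seed(spec$seed)
  dims <- spec$stack_shape
  vs <- spec$voxel_size
  aspect <- vs[["x"]] / vs[["z"]]

  n_cells <- spec$n_microglia + spec$n_astrocytes + spec$n_other_nuclei
  types <- rep(c("microglia", "astrocyte", "other"),
               c(spec$n_microglia, spec$n_astrocytes, spec$n_other_nuclei))

  occupied <- array(FALSE, dims)   # nuclei only, used for spacing checks
  nuclei_all <- array(FALSE, dims)
  cells <- vector("list", n_cells)

  # rough semi-axis bound used for boundary margins
  r_max <- (3 * spec$nucleus_volume_range[2] / (4 * pi * aspect))^(1 / 3) * 1.1
  semi_max <- c(r_max, r_max, aspect * r_max)
  if (n_cells > 0 && any(2 * (semi_max + spec$placement_margin) + 2 > dims))
    stop("stack_shape too small to hold a nucleus of the requested volume",
         call. = FALSE)

  for (ci in seq_len(n_cells)) {
    placed <- FALSE
    for (try in seq_len(200L)) {
      margin <- semi_max + spec$placement_margin + 1
      center <- c(runif(1, margin[1], dims[1] - margin[1]),
                  runif(1, margin[2], dims[2] - margin[2]),
                  runif(1, margin[3], dims[3] - margin[3]))
      shape <- .sample_nucleus_shape(center, spec$nucleus_volume_range,
                                     aspect, dims)
      if (is.null(shape)) next
      halo <- .ellipsoid_idx(center, shape$semi + spec$placement_margin, dims)
      if (any(occupied[halo])) next
      occupied[halo] <- TRUE
      nuclei_all[shape$idx] <- TRUE
      cells[[ci]] <- list(id = ci, type = types[ci],
                          nucleus_voxels = shape$idx,
                          nucleus_volume = length(shape$idx),
                          center = center)
      placed <- TRUE
      break
    }
    if (!placed)
      stop(sprintf(paste0("placement failure: could not place cell %d of %d ",
                          "without overlap; reduce cell count or enlarge ",
                          "the stack"), ci, n_cells), call. = FALSE)
  }

  dapi <- nuclei_all
  ox42 <- array(FALSE, dims)
  gfap <- array(FALSE, dims)
  gr <- array(FALSE, dims)

  for (ci in seq_len(n_cells)) {
    cell <- cells[[ci]]
    idx <- cell$nucleus_voxels

    if (cell$type == "microglia") {
      soma <- .dilate_indices(idx, dims, spec$soma_thickness)
      ox42[soma] <- TRUE
      before <- ox42
      target <- max(0, rnorm(1, spec$arbor_volume, 0.15 * spec$arbor_volume))
      if (target > 0)
        ox42 <- .grow_arbor(ox42, soma, cell$center, spec, target)
      cell$soma_voxels <- soma
      cell$arbor_voxels <- which(ox42 & !before)
    } else if (cell$type == "astrocyte") {
      gfap <- .grow_star(gfap, cell$center, spec)
      if (runif(1) < spec$gfap_nucleus_coverage) {
        cover <- .dilate_indices(idx, dims, 1)
      } else {
        q <- runif(1, 0.2, 0.7)
        cover <- .contiguous_subset(idx, floor(q * length(idx)), dims)
      }
      gfap[cover] <- TRUE
      cell$soma_voxels <- integer(0)
    } else {
      cell$soma_voxels <- integer(0)
    }

    # nuclear GR: contiguous blob filling a per-cell fraction
    fill_mean <- spec$gr_nuclear_fill[[cell$type]] %||% 0.8
    f <- min(1, max(0, rnorm(1, fill_mean, 0.08)))
    k <- round(f * length(idx))
    nuc_gr <- .contiguous_subset(idx, k, dims)
    gr[nuc_gr] <- TRUE
    cell$nuclear_gr_voxels <- nuc_gr
    cell$nuclear_gr_fraction <- length(nuc_gr) / length(idx)

    # cytoplasmic GR puncta in a perinuclear shell, never inside a nucleus
    n_p <- rpois(1, spec$gr_cytoplasmic_density)
    shell <- setdiff(.dilate_indices(idx, dims, spec$soma_thickness + 2),
                     which(nuclei_all))
    cyto <- integer(0)
    if (n_p > 0 && length(shell) > 0) {
      for (p in seq_len(n_p)) {
        at <- as.numeric(arrayInd(shell[sample.int(length(shell), 1L)], dims))
        punct <- .ellipsoid_idx(at + runif(3, -0.4, 0.4),
                                c(1.4, 1.4, 1.0), dims)
        punct <- punct[!nuclei_all[punct]]
        cyto <- union(cyto, punct)
      }
      gr[cyto] <- TRUE
    }
    cell$cyto_gr_voxels <- cyto
    cells[[ci]] <- cell
  }

  truth <- list(
    cells = cells,
    totals = c(DAPI = sum(dapi), OX42 = sum(ox42),
               GR = sum(gr), GFAP = sum(gfap)),
    signal_floor = spec$signal_floor,
    dims = dims
  )

  vox <- array(0, c(dims, 4L))
  masks <- list(dapi, ox42, gr, gfap)
  for (ch in 1:4) {
    img <- array(0, dims)
    img[masks[[ch]]] <- spec$levels[[ch]]
    if (any(spec$psf_sigma > 0))
      img <- gaussian_blur(img, spec$psf_sigma)
    if (spec$noise[["poisson_scale"]] > 0) {
      sc <- spec$noise[["poisson_scale"]]
      img[] <- rpois(length(img), pmax(img, 0) * sc) / sc
    }
    if (spec$noise[["gaussian_sd"]] > 0)
      img[] <- img + rnorm(length(img), 0, spec$noise[["gaussian_sd"]])
    img[img < 0] <- 0
    vox[, , , ch] <- img
  }

  stack <- glia_stack(vox, voxel_size = vs,
                      meta = list(seed = spec$seed))
  list(stack = stack, truth = truth)
}
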