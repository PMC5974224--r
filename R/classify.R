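# Cell-type assignment and GR compartment accounting.
#
# A nucleus is microglial iff it is completely covered (100% voxel
# colocalization) by the thresholded OX-42 channel; a relaxation fraction
# is available in config but defaults to strict.  GR colocalization uses
# the binarized GR channel throughout (foci are an additional descriptive
# output, not the colocalization currency).

#' Identify microglial nuclei by complete OX-42 coverage
#'
#' @param nuclei a `labeled_nuclei` (volume-filtered).
#' @param ox42_mask `binary_mask` or logical array of the OX-42 channel.
#' @param overlap_fraction minimum fraction of nucleus voxels that must be
#'   OX-42-positive; default 1.0 = the strict 100%-colocalization rule.
#' @return integer vector of nucleus labels classified as microglia.
#' @export
classify_microglial_nuclei <- function(nuclei, ox42_mask,
                                       overlap_fraction = 1.0) {
  stopifnot(inherits(nuclei, "labeled_nuclei"),
            overlap_fraction > 0, overlap_fraction <= 1)
  ox <- .as_mask_array(ox42_mask)
  stopifnot(all(dim(ox) == dim(nuclei$labels)))
  idx <- which(nuclei$labels > 0L)
  if (length(idx) == 0L) return(integer(0))
  lab <- nuclei$labels[idx]
  inside <- tapply(ox[idx], lab, sum)
  total <- tapply(rep(1L, length(idx)), lab, sum)
  labs <- as.integer(names(total))
  frac <- as.numeric(inside) / as.numeric(total)
  if (overlap_fraction >= 1) labs[frac >= 1] else labs[frac >= overlap_fraction]
}

#' Fraction of a nucleus colocalized with GR signal
#'
#' @param nucleus_voxels integer vector of linear voxel indices of one
#'   nucleus (see [nucleus_voxels()]).
#' @param gr_mask `binary_mask` or logical array of the GR channel.
#' @return `|nucleus intersect GR| / |nucleus|`, in `[0, 1]`.
#' @export
nuclear_gr_fraction <- function(nucleus_voxels, gr_mask) {
  if (length(nucleus_voxels) == 0L)
    stop("empty nucleus voxel set", call. = FALSE)
  g <- .as_mask_array(gr_mask)
  sum(g[nucleus_voxels]) / length(nucleus_voxels)
}

#' Bin a nuclear GR fraction into quartiles Q1-Q4
#'
#' Bins are right-closed with Q1 closed at zero:
#' Q1 = \[0, 0.25\], Q2 = (0.25, 0.5\], Q3 = (0.5, 0.75\], Q4 = (0.75, 1\].
#' "Highly GR dense" nuclei are Q4, i.e. more than 75% of the nucleus
#' volume colocalized with GR.
#'
#' @param fraction numeric vector of fractions in `[0, 1]`.
#' @return character vector of `"Q1"`..`"Q4"`.
#' @export
quartile_bin <- function(fraction) {
  if (any(fraction < 0 | fraction > 1))
    stop("fraction outside [0, 1]", call. = FALSE)
  ifelse(fraction <= 0.25, "Q1",
  ifelse(fraction <= 0.50, "Q2",
  ifelse(fraction <= 0.75, "Q3", "Q4")))
}

#' Microglial soma volume through a dilation shell
#'
#' The nucleus voxel set is dilated by a Euclidean ball of
#' `dilation_radius` voxels (anisotropy-naive: the rule is stated in
#' pixels, not micrometres), and the OX-42-positive volume inside the
#' dilated mask - nucleus footprint included - is the soma volume.
#'
#' @param nucleus_voxels integer vector of linear voxel indices.
#' @param ox42_mask `binary_mask` or logical 3D array.
#' @param dilation_radius ball radius in voxels (default 3).
#' @param include_nucleus set `FALSE` to restrict to the shell outside the
#'   nucleus (sensitivity analysis only).
#' @return OX-42-positive voxel count inside the (dilated) soma mask.
#' @export
soma_volume <- function(nucleus_voxels, ox42_mask, dilation_radius = 3,
                        include_nucleus = TRUE) {
  ox <- .as_mask_array(ox42_mask)
  dil <- .dilate_indices(nucleus_voxels, dim(ox), dilation_radius)
  if (!include_nucleus) dil <- setdiff(dil, nucleus_voxels)
  sum(ox[dil])
}

#' Image-level non-nuclear GR volume within a glial channel
#'
#' Total GR/glia colocalization minus its DAPI-colocalized (nuclear)
#' part: `|GR & glia| - |GR & glia & DAPI|`.  The subtraction is
#' restricted to glia-overlapping GR, so the result is never negative.
#' Applied with `glia` = OX-42 for microglia and `glia` = GFAP for
#' astrocytes.
#'
#' @param gr_mask,glia_mask,dapi_mask `binary_mask` or logical arrays of
#'   identical shape.
#' @return non-nuclear GR volume in voxels.
#' @export
nonnuclear_gr_volume <- function(gr_mask, glia_mask, dapi_mask) {
  g <- .as_mask_array(gr_mask)
  a <- .as_mask_array(glia_mask)
  d <- .as_mask_array(dapi_mask)
  stopifnot(all(dim(g) == dim(a)), all(dim(g) == dim(d)))
  sum(g & a) - sum(g & a & d)
}

#' Count highly GR-dense microglial nuclei
#'
#' Number of microglial cell records in the top quartile (more than 75% of
#' the nucleus colocalized with GR).
#'
#' @param cells data.frame of cell records (see [classify_cells()]).
#' @return integer count.
#' @export
count_high_gr_nuclei <- function(cells) {
  if (is.null(cells) || nrow(cells) == 0L) return(0L)
  sum(cells$cell_type == "microglia" & cells$gr_quartile == "Q4")
}

#' Build per-cell records for one image
#'
#' Combines classification, nuclear GR fraction/quartile, soma volumetry
#' and a per-cell non-nuclear GR measure for every retained nucleus.
#'
#' @param nuclei volume-filtered `labeled_nuclei`.
#' @param masks named list of `binary_mask` from [preprocess_stack()].
#' @param config pipeline configuration ([pipeline_config()]).
#' @param image_id,animal_id provenance labels carried into the table.
#' @return data.frame with one row per nucleus: `label`, `cell_type`
#'   (`"microglia"`/`"unclassified"`), `nucleus_volume`,
#'   `nuclear_gr_fraction`, `gr_quartile`, `soma_volume` (microglia only,
#'   else `NA`), `nonnuclear_gr_cell`, `image_id`, `animal_id`.
#' @export
classify_cells <- function(nuclei, masks, config = pipeline_config(),
                           image_id = NA_character_,
                           animal_id = NA_character_) {
  tab <- nuclei$table
  if (nrow(tab) == 0L)
    return(data.frame(label = integer(0), cell_type = character(0),
                      nucleus_volume = integer(0),
                      cx = numeric(0), cy = numeric(0), cz = numeric(0),
                      nuclear_gr_fraction = numeric(0),
                      gr_quartile = character(0), soma_volume = numeric(0),
                      nonnuclear_gr_cell = numeric(0),
                      image_id = character(0), animal_id = character(0)))
  micro <- classify_microglial_nuclei(nuclei, masks$OX42,
                                      config$overlap_fraction)
  gr <- .as_mask_array(masks$GR)
  ox <- .as_mask_array(masks$OX42)
  rows <- lapply(seq_len(nrow(tab)), function(r) {
    lb <- tab$label[r]
    vox <- nucleus_voxels(nuclei, lb)
    frac <- nuclear_gr_fraction(vox, gr)
    is_m <- lb %in% micro
    sv <- NA_real_
    nn <- NA_real_
    if (is_m) {
      dil <- .dilate_indices(vox, dim(ox), config$dilation_radius)
      sv <- sum(ox[dil])
      # per-cell analogue of the image-level subtraction, within the soma
      nn <- sum(gr[dil] & ox[dil]) - sum(gr[vox] & ox[vox])
    }
    data.frame(label = lb,
               cell_type = if (is_m) "microglia" else "unclassified",
               nucleus_volume = tab$volume[r],
               cx = tab$cx[r], cy = tab$cy[r], cz = tab$cz[r],
               nuclear_gr_fraction = frac,
               gr_quartile = quartile_bin(frac),
               soma_volume = sv,
               nonnuclear_gr_cell = nn,
               image_id = image_id, animal_id = animal_id)
  })
  do.call(rbind, rows)
}

#' Image-level GR and volume summary
#'
#' @param cells cell table from [classify_cells()].
#' @param masks named list of `binary_mask` from [preprocess_stack()].
#' @param image_id,animal_id provenance labels.
#' @return one-row data.frame: microglia/astrocyte channel volumes,
#'   microglia count, Q4 count, image-level non-nuclear GR for both glial
#'   channels, and the thresholds used.
#' @export
image_gr_summary <- function(cells, masks, image_id = NA_character_,
                             animal_id = NA_character_) {
  data.frame(
    image_id = image_id,
    animal_id = animal_id,
    n_nuclei = nrow(cells),
    n_microglia = sum(cells$cell_type == "microglia"),
    n_high_gr_nuclei = count_high_gr_nuclei(cells),
    microglia_volume = as.integer(measure_channel_volume(masks$OX42)),
    astrocyte_volume = as.integer(measure_channel_volume(masks$GFAP)),
    nonnuclear_gr_microglia = nonnuclear_gr_volume(masks$GR, masks$OX42,
                                                   masks$DAPI),
    nonnuclear_gr_astrocyte = nonnuclear_gr_volume(masks$GR, masks$GFAP,
                                                   masks$DAPI),
    mean_soma_volume = if (any(cells$cell_type == "microglia"))
      mean(cells$soma_volume[cells$cell_type == "microglia"]) else NA_real_,
    threshold_dapi = masks$DAPI$threshold_used,
    threshold_ox42 = masks$OX42$threshold_used,
    threshold_gr = masks$GR$threshold_used,
    threshold_gfap = masks$GFAP$threshold_used
  )
}
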