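# File interfaces: multi-page TIFF stacks with a JSON sidecar carrying
# voxel geometry, channel order and provenance; cohort manifests and
# result tables as CSV; configs as YAML or JSON.
#
# TIFF pages are written channel-interleaved in z-major order (all four
# channels of z-plane 1, then z-plane 2, ...), 16-bit, declared in the
# sidecar so readers never have to guess.

.TIFF_MAXVAL <- 65535

#' Write a stack as multi-page TIFF plus JSON sidecar
#'
#' Intensities are stored as 16-bit samples; `intensity_scale` in the
#' sidecar maps them back so `read_stack(write_stack(x))` round-trips to
#' within 16-bit quantization (exactly, for integer-valued intensities
#' below the scale).
#'
#' @param stack a [glia_stack()].
#' @param path output TIFF path; the sidecar goes to `<path>.json`.
#' @param intensity_scale intensity mapped to the maximum sample value.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, intensity_scale = 1024) {
  stopifnot(inherits(stack, "glia_stack"))
  d <- dim(stack$voxels)
  pages <- vector("list", d[3] * 4L)
  n <- 0L
  for (k in seq_len(d[3]))
    for (ch in 1:4) {
      n <- n + 1L
      # TIFF pages are row-major images: transpose x/y
      pages[[n]] <- t(pmin(stack$voxels[, , k, ch] / intensity_scale, 1))
    }
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  sidecar <- list(
    channels = as.list(stack$channels),
    page_order = "z_major_channel_interleaved",
    shape = as.integer(d[1:3]),
    voxel_size_um = as.numeric(stack$voxel_size),
    intensity_scale = intensity_scale,
    meta = stack$meta
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a stack written by [write_stack()]
#'
#' @param path TIFF path with `<path>.json` sidecar alongside.
#' @return a [glia_stack()].
#' @export
read_stack <- function(path) {
  sidecar <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  d <- as.integer(sidecar$shape)
  vox <- array(0, c(d, 4L))
  n <- 0L
  for (k in seq_len(d[3]))
    for (ch in 1:4) {
      n <- n + 1L
      vox[, , k, ch] <- t(pages[[n]]) * sidecar$intensity_scale
    }
  # quantization: snap back to the 16-bit grid to keep round-trips exact
  vox <- round(vox * .TIFF_MAXVAL / sidecar$intensity_scale) *
    (sidecar$intensity_scale / .TIFF_MAXVAL)
  glia_stack(vox, voxel_size = sidecar$voxel_size_um,
             meta = as.list(sidecar$meta))
}

#' Write a cohort (stacks, truth, manifest) to a directory
#'
#' One TIFF + sidecar per image, the manifest as `manifest.csv`, and the
#' per-cell ground truth as compact JSON (voxel index sets included).
#'
#' @param cohort output of [generate_cohort()].
#' @param dir output directory (created if missing).
#' @param write_truth also serialize ground truth JSON per image.
#' @return the manifest with a `file` column, invisibly.
#' @export
write_cohort <- function(cohort, dir, write_truth = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  man <- cohort$manifest
  man$file <- file.path(dir, paste0(man$image_id, ".tif"))
  for (i in seq_along(cohort$images)) {
    write_stack(cohort$images[[i]]$stack, man$file[i])
    if (write_truth) {
      tr <- cohort$images[[i]]$truth
      jsonlite::write_json(
        list(totals = as.list(tr$totals), dims = tr$dims,
             signal_floor = tr$signal_floor,
             cells = lapply(tr$cells, function(cl)
               list(id = cl$id, type = cl$type,
                    nucleus_volume = cl$nucleus_volume,
                    nuclear_gr_fraction = cl$nuclear_gr_fraction,
                    nucleus_voxels = cl$nucleus_voxels,
                    cyto_gr_voxels = cl$cyto_gr_voxels))),
        file.path(dir, paste0(man$image_id[i], ".truth.json")),
        auto_unbox = TRUE, digits = NA)
    }
  }
  write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(man)
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Unknown keys are rejected; missing keys take the [pipeline_config()]
#' defaults.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return a [pipeline_config()].
#' @export
read_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(pipeline_config))
  extra <- setdiff(names(raw), known)
  if (length(extra))
    stop("unknown config keys: ", paste(extra, collapse = ", "),
         call. = FALSE)
  do.call(pipeline_config, raw)
}

#' Write the tables of a run report to a directory
#'
#' @param report a `run_report` from [run_pipeline()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "run_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(report$cells, file.path(dir, "cells.csv"), row.names = FALSE)
  write.csv(report$image_summaries, file.path(dir, "images.csv"),
            row.names = FALSE)
  write.csv(report$animals, file.path(dir, "animals.csv"), row.names = FALSE)
  if (!is.null(report$stats))
    write.csv(report$stats, file.path(dir, "stats.csv"), row.names = FALSE)
  writeLines(report$log, file.path(dir, "run.log"))
  jsonlite::write_json(unclass(report$config),
                       file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
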