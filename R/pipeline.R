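# End-to-end orchestration: stacks -> preprocess -> segmentation ->
# classification -> per-animal summaries -> group statistics, plus the
# simulate-then-analyze loop and the power/type-I simulation used to
# validate effect recovery.

#' Pipeline configuration
#'
#' Collects every tunable of the analysis with its default.  The nucleus
#' volume window defaults to 1000-1500 voxels and the soma dilation
#' radius to 3 voxels, the documented analysis constants; thresholds are
#' computed per image with Otsu unless overridden per channel.
#'
#' @param threshold named per-channel list, e.g.
#'   `list(GR = list(method = "percentile", p = 95))`; channels not named
#'   use Otsu.
#' @param nucleus_volume_bounds inclusive voxel-volume window for
#'   retained nuclei.
#' @param overlap_fraction minimum OX-42 coverage for a microglial call
#'   (1.0 = strict 100% colocalization).
#' @param dilation_radius soma dilation radius in voxels.
#' @param watershed_h h-maxima depth (micrometres) for nucleus splitting.
#' @param watershed_sigma distance-map smoothing sigma (voxels).
#' @param foci list of foci-detector parameters (`min_size`, `max_size`,
#'   `local_max_tolerance`).
#' @param ss_type ANOVA sums-of-squares type.
#' @param seed seed for any stochastic stage.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(threshold = list(),
                            nucleus_volume_bounds = c(1000, 1500),
                            overlap_fraction = 1.0,
                            dilation_radius = 3,
                            watershed_h = 0.5,
                            watershed_sigma = 1,
                            foci = list(min_size = 5, max_size = 5000,
                                        local_max_tolerance = 10),
                            ss_type = 2,
                            seed = 1L) {
  stopifnot(length(nucleus_volume_bounds) == 2L,
            nucleus_volume_bounds[1] <= nucleus_volume_bounds[2],
            overlap_fraction > 0, overlap_fraction <= 1,
            dilation_radius >= 0, watershed_h > 0)
  structure(list(threshold = threshold,
                 nucleus_volume_bounds = as.numeric(nucleus_volume_bounds),
                 overlap_fraction = overlap_fraction,
                 dilation_radius = dilation_radius,
                 watershed_h = watershed_h,
                 watershed_sigma = watershed_sigma,
                 foci = foci, ss_type = ss_type, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Analyze a single 4-channel stack
#'
#' Runs preprocess -> nucleus segmentation -> volume filter ->
#' classification/GR partitioning on one stack and returns the per-image
#' tables.
#'
#' @param stack a [glia_stack()].
#' @param config a [pipeline_config()].
#' @param detect_gr_foci also run the descriptive GR puncta detector.
#' @return list: `cells` (per-cell records), `summary` (one-row image
#'   summary), `nuclei` (`labeled_nuclei` after filtering), `masks`,
#'   and optionally `foci`.
#' @export
analyze_stack <- function(stack, config = pipeline_config(),
                          detect_gr_foci = FALSE) {
  masks <- preprocess_stack(stack, config)
  nuclei <- segment_nuclei(masks$DAPI, voxel_size = stack$voxel_size,
                           h = config$watershed_h,
                           smooth_sigma = config$watershed_sigma)
  n_before <- nrow(nuclei$table)
  nuclei <- filter_nuclei_by_volume(nuclei,
                                    config$nucleus_volume_bounds[1],
                                    config$nucleus_volume_bounds[2])
  image_id <- stack$meta$image_id %||% NA_character_
  animal_id <- stack$meta$animal_id %||% NA_character_
  cells <- classify_cells(nuclei, masks, config, image_id, animal_id)
  summ <- image_gr_summary(cells, masks, image_id, animal_id)
  summ$n_nuclei_prefilter <- n_before
  out <- list(cells = cells, summary = summ, nuclei = nuclei, masks = masks)
  if (detect_gr_foci)
    out$foci <- detect_foci(get_channel(stack, "GR"),
                            masks$GR$threshold_used,
                            min_size = config$foci$min_size,
                            max_size = config$foci$max_size,
                            local_max_tolerance = config$foci$local_max_tolerance)
  out
}

#' Run the full pipeline over a cohort of stacks
#'
#' @param stacks list of [glia_stack()] objects (e.g. from
#'   [generate_cohort()]`$images` or [read_stack()]).
#' @param manifest data.frame mapping `image_id` to `animal_id`, `age`,
#'   `stress`; every stack's image id must appear.
#' @param config a [pipeline_config()].
#' @param covariates optional per-animal covariate data.frame.
#' @return `run_report` list: `cells`, `image_summaries`, `animals`
#'   (per-animal table), `stats` (test-result table, `NULL` when the
#'   design cannot support group tests), `config`, `log` (per-image
#'   diagnostics), `failed` (image ids that errored).
#' @export
run_pipeline <- function(stacks, manifest, config = pipeline_config(),
                         covariates = NULL) {
  if (length(stacks) == 0L) stop("empty manifest: no stacks to analyze",
                                 call. = FALSE)
  cells <- list(); summaries <- list(); log <- list(); failed <- character(0)
  for (i in seq_along(stacks)) {
    st <- stacks[[i]]
    res <- tryCatch(analyze_stack(st, config), error = function(e) e)
    if (inherits(res, "error")) {
      failed <- c(failed, st$meta$image_id %||% sprintf("stack%03d", i))
      log[[length(log) + 1L]] <- sprintf("image %s FAILED: %s",
                                         st$meta$image_id %||% i,
                                         conditionMessage(res))
      next
    }
    cells[[length(cells) + 1L]] <- res$cells
    summaries[[length(summaries) + 1L]] <- res$summary
    log[[length(log) + 1L]] <-
      sprintf("image %s: %d nuclei (%d pre-filter), %d microglia, thr DAPI=%.1f OX42=%.1f",
              res$summary$image_id, res$summary$n_nuclei,
              res$summary$n_nuclei_prefilter, res$summary$n_microglia,
              res$summary$threshold_dapi, res$summary$threshold_ox42)
  }
  if (length(failed) > length(stacks) / 2)
    stop(sprintf("more than half of the images failed (%d of %d); aborting",
                 length(failed), length(stacks)), call. = FALSE)
  cells <- do.call(rbind, cells)
  summaries <- do.call(rbind, summaries)
  animals <- per_animal_summary(cells, summaries, manifest, covariates)
  stats_tab <- NULL
  if (nrow(animals) >= 4 && length(unique(animals$age)) >= 2) {
    stats_tab <- group_statistics(animals,
                                  covariate_cols = setdiff(names(covariates),
                                                           "animal_id"))
  } else {
    log[[length(log) + 1L]] <-
      "statistics stage skipped: fewer than 4 animals or a single age group"
  }
  structure(list(cells = cells, image_summaries = summaries,
                 animals = animals, stats = stats_tab, config = config,
                 log = unlist(log), failed = failed),
            class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> %d images, %d animals, %d cells\n",
              nrow(x$image_summaries), nrow(x$animals), nrow(x$cells)))
  if (!is.null(x$stats))
    cat(sprintf("  %d test results\n", nrow(x$stats)))
  if (length(x$failed)) cat("  failed images:", length(x$failed), "\n")
  invisible(x)
}

#' Simulate a cohort and analyze it end to end
#'
#' Runs [generate_cohort()], feeds the stacks through [run_pipeline()],
#' and scores the recovery of the injected ground truth: microglial
#' channel-volume error, cell-type classification accuracy, and (when an
#' arbor multiplier was injected) the recovered aged/young volume ratio.
#'
#' @param design a [cohort_design()].
#' @param config a [pipeline_config()].
#' @return list: `report` (the [run_pipeline()] output), `recovery`
#'   (named numerics), `manifest`.
#' @export
simulate_and_analyze <- function(design, config = pipeline_config()) {
  sim <- generate_cohort(design)
  stacks <- lapply(sim$images, `[[`, "stack")
  report <- run_pipeline(stacks, sim$manifest, config)

  # centroid-based classification scoring against truth, per image
  acc <- c(correct = 0L, total = 0L)
  vol_err <- numeric(0)
  for (i in seq_along(sim$images)) {
    img_id <- sim$manifest$image_id[i]
    cc <- report$cells[report$cells$image_id == img_id, , drop = FALSE]
    a <- .score_image(cc, sim$images[[i]]$truth)
    acc <- acc + a$acc
    vol_err <- c(vol_err, a$vol_err)
  }
  mvol <- report$image_summaries$microglia_volume
  tvol <- sim$manifest$true_ox42_volume
  recovery <- c(
    classification_accuracy = if (acc[["total"]] > 0)
      acc[["correct"]] / acc[["total"]] else NA_real_,
    mean_volume_rel_error = mean(abs(mvol - tvol) / pmax(tvol, 1)),
    n_images = length(sim$images)
  )
  ages <- sim$manifest$age
  if (length(unique(ages)) == 2) {
    r_meas <- mean(mvol[ages == "aged"]) / mean(mvol[ages == "young"])
    r_true <- mean(tvol[ages == "aged"]) / mean(tvol[ages == "young"])
    recovery <- c(recovery, measured_aged_young_ratio = r_meas,
                  true_aged_young_ratio = r_true)
  }
  list(report = report, recovery = recovery, manifest = sim$manifest)
}

# Per-image truth scoring: each truth cell is matched to the nearest
# detected nucleus centroid (within max_dist voxels); a missed or
# mistyped cell counts as incorrect.
.score_image <- function(cc, truth, max_dist = 6) {
  acc <- c(correct = 0L, total = length(truth$cells))
  vol_err <- numeric(0)
  for (tc in truth$cells) {
    if (nrow(cc) == 0L) next
    co <- colMeans(arrayInd(tc$nucleus_voxels, truth$dims))
    d <- sqrt((cc$cx - co[1])^2 + (cc$cy - co[2])^2 + (cc$cz - co[3])^2)
    j <- which.min(d)
    if (length(j) == 0L || d[j] > max_dist) next
    want <- if (tc$type == "microglia") "microglia" else "unclassified"
    if (cc$cell_type[j] == want) {
      acc[["correct"]] <- acc[["correct"]] + 1L
      vol_err <- c(vol_err, abs(cc$nucleus_volume[j] - tc$nucleus_volume) /
                     tc$nucleus_volume)
    }
  }
  list(acc = acc, vol_err = vol_err)
}

#' Power / type-I-error simulation for the injected age effect
#'
#' Repeatedly simulates a reduced two-by-two cohort (age x stress,
#' `n_per_cell` animals per cell, one 64 x 64 x 16 stack per animal, a
#' compact three-cell scene), measures each animal's total microglial
#' volume through the thresholding pipeline, runs the two-way ANOVA, and
#' records the age-term p-value.  With `arbor_multiplier = 1` the
#' rejection rate estimates the type-I error at `alpha`; with a real
#' multiplier it estimates power.
#'
#' @param arbor_multiplier multiplicative aged-vs-young shift on
#'   microglial process volume.
#' @param n_replicates simulation replicates.
#' @param n_per_cell animals per age x stress cell (10 per age group by
#'   default).
#' @param alpha significance level.
#' @param seed master seed; replicate r uses `seed + r` internally.
#' @param base_spec reduced-scene generator spec shared by all animals.
#' @return list: `p_age` (vector of age-term p-values), `reject_rate`,
#'   `alpha`, `n_replicates`.
#' @export
power_simulation <- function(arbor_multiplier = 1.4, n_replicates = 100,
                             n_per_cell = 5, alpha = 0.05, seed = 1L,
                             base_spec = scene_spec(
                               stack_shape = c(64, 64, 16),
                               n_microglia = 2, n_astrocytes = 0,
                               n_other_nuclei = 1,
                               arbor_volume = 3000, arbor_extent = 10,
                               placement_margin = 1,
                               psf_sigma = c(0, 0, 0))) {
  groups <- expand.grid(age = c("young", "aged"),
                        stress = c("control", "stress"),
                        stringsAsFactors = FALSE)
  effects <- data.frame(age = "aged", stress = c("control", "stress"),
                        arbor = arbor_multiplier, soma = 1, gr_density = 1)
  p_age <- numeric(n_replicates)
  for (r in seq_len(n_replicates)) {
    design <- cohort_design(groups = groups, n_animals_per_group = n_per_cell,
                            images_per_animal = 1, effects = effects,
                            base_spec = base_spec,
                            seed = (seed + 7681L * r) %% 2147483629L)
    sim <- generate_cohort(design)
    vol <- vapply(sim$images, function(im) {
      ox <- get_channel(im$stack, "OX42")
      thr <- compute_threshold(ox, "otsu")
      as.numeric(measure_channel_volume(binarize(ox, thr)))
    }, 0)
    an <- two_way_anova(vol, sim$manifest$age, sim$manifest$stress)
    p_age[r] <- an$p[an$term == "age"]
  }
  list(p_age = p_age, reject_rate = mean(p_age < alpha), alpha = alpha,
       n_replicates = n_replicates)
}
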