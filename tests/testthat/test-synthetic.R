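# Scene and cohort generator: determinism, volume control, compartment
# bookkeeping, coverage guarantee, injected effects.

test_that("empty scene yields a noise-only stack and zero cells", {
  res <- generate_stack(scene_spec(stack_shape = c(24, 24, 8),
                                   n_microglia = 0, n_astrocytes = 0,
                                   n_other_nuclei = 0, seed = 1))
  expect_length(res$truth$cells, 0)
  expect_equal(unname(res$truth$totals), rep(0, 4))
  expect_equal(dim(res$stack$voxels), c(24, 24, 8, 4))
})

test_that("generated nucleus volumes fall in the requested range (direct voxel count)", {
  res <- generate_stack(spec_noise_free(stack_shape = c(160, 160, 24),
                                        n_microglia = 5, n_astrocytes = 0,
                                        n_other_nuclei = 0,
                                        nucleus_volume_range = c(1100, 1400),
                                        seed = 8))
  vols <- vapply(res$truth$cells, function(cl) length(cl$nucleus_voxels), 0L)
  expect_length(vols, 5)
  expect_true(all(vols >= 1100 & vols <= 1400))
  expect_equal(vols, vapply(res$truth$cells, `[[`, 0L, "nucleus_volume"))
})

test_that("identical spec and seed reproduce the stack bit-exactly", {
  spec <- scene_spec(stack_shape = c(64, 64, 16), n_microglia = 2,
                     n_astrocytes = 1, n_other_nuclei = 1,
                     placement_margin = 1, seed = 33)
  a <- generate_stack(spec)
  b <- generate_stack(spec)
  expect_identical(a$stack$voxels, b$stack$voxels)
  expect_identical(a$truth$totals, b$truth$totals)
})

test_that("compartment bookkeeping: nuclei disjoint, nuclear GR inside, cytoplasmic GR outside", {
  res <- generate_stack(spec_noise_free(stack_shape = c(128, 128, 20),
                                        n_microglia = 3, n_astrocytes = 2,
                                        n_other_nuclei = 2, seed = 5))
  cells <- res$truth$cells
  all_nuc <- unlist(lapply(cells, `[[`, "nucleus_voxels"))
  expect_equal(anyDuplicated(all_nuc), 0)
  expect_true(all(all_nuc >= 1 & all_nuc <= prod(res$truth$dims)))
  for (cl in cells) {
    expect_true(all(cl$nuclear_gr_voxels %in% cl$nucleus_voxels))
    expect_length(intersect(cl$cyto_gr_voxels, all_nuc), 0)
    expect_equal(cl$nuclear_gr_fraction,
                 length(cl$nuclear_gr_voxels) / length(cl$nucleus_voxels))
  }
})

test_that("noise/PSF off: binarizing OX-42 at the signal floor recovers the true microglial mask", {
  res <- generate_stack(spec_noise_free(stack_shape = c(96, 96, 20),
                                        n_microglia = 3, n_astrocytes = 1,
                                        n_other_nuclei = 1, seed = 6))
  ox <- get_channel(res$stack, "OX42")
  rec <- which(ox > res$truth$signal_floor)
  truth_ox <- sort(unique(unlist(lapply(res$truth$cells, function(cl)
    c(cl$soma_voxels, cl$arbor_voxels)))))
  expect_setequal(rec, truth_ox)
  expect_equal(length(rec), unname(res$truth$totals["OX42"]))
  # microglial nuclei are fully covered
  for (cl in res$truth$cells)
    if (cl$type == "microglia")
      expect_true(all(ox[cl$nucleus_voxels] > res$truth$signal_floor))
})

test_that("a configurable fraction of astrocyte nuclei is left only partially GFAP-covered", {
  res <- generate_stack(spec_noise_free(stack_shape = c(160, 160, 20),
                                        n_microglia = 0, n_astrocytes = 6,
                                        n_other_nuclei = 0,
                                        gfap_nucleus_coverage = 0,
                                        seed = 9))
  gf <- get_channel(res$stack, "GFAP")
  covered <- vapply(res$truth$cells, function(cl)
    all(gf[cl$nucleus_voxels] > res$truth$signal_floor), FALSE)
  expect_false(any(covered))
})

test_that("overcrowded scenes raise an explicit placement error", {
  expect_error(
    generate_stack(scene_spec(stack_shape = c(40, 40, 14), n_microglia = 12,
                              n_astrocytes = 0, n_other_nuclei = 0,
                              placement_margin = 1, seed = 2)),
    "placement failure")
  expect_error(
    generate_stack(scene_spec(stack_shape = c(20, 20, 8), n_microglia = 1,
                              n_astrocytes = 0, n_other_nuclei = 0, seed = 2)),
    "too small")
})

test_that("cohort generation: counts, manifest, determinism, duplicate ids", {
  base <- spec_noise_free(stack_shape = c(64, 64, 16), n_microglia = 1,
                          n_astrocytes = 0, n_other_nuclei = 1,
                          placement_margin = 1)
  design <- cohort_design(groups = data.frame(age = c("young", "aged"),
                                              stress = "control"),
                          n_animals_per_group = 3, images_per_animal = 1,
                          base_spec = base, seed = 10)
  sim <- generate_cohort(design)
  expect_length(sim$images, 6)
  expect_equal(nrow(sim$manifest), 6)
  expect_equal(anyDuplicated(sim$manifest$animal_id), 0)
  sim2 <- generate_cohort(design)
  expect_identical(sim$manifest, sim2$manifest)
  expect_identical(sim$images[[3]]$stack$voxels, sim2$images[[3]]$stack$voxels)

  expect_error(cohort_design(groups = data.frame(age = "young",
                                                 stress = "control"),
                             n_animals_per_group = 2,
                             animal_ids = c("a", "a"), base_spec = base),
               "duplicate")
})

test_that("injected arbor multiplier shows up in the ground-truth group means", {
  base <- spec_noise_free(stack_shape = c(64, 64, 16), n_microglia = 2,
                          n_astrocytes = 0, n_other_nuclei = 0,
                          arbor_volume = 3000, arbor_extent = 10,
                          placement_margin = 1)
  groups <- data.frame(age = c("young", "aged"), stress = "control")
  effects <- data.frame(age = "aged", stress = "control",
                        arbor = 1.5, soma = 1, gr_density = 1)
  design <- cohort_design(groups = groups, n_animals_per_group = 8,
                          effects = effects, base_spec = base, seed = 20)
  sim <- generate_cohort(design)
  m <- sim$manifest
  # soma volume is unshifted; the arbor itself must scale by ~1.5
  soma <- vapply(sim$images, function(im)
    sum(vapply(im$truth$cells, function(cl) length(cl$soma_voxels), 0L)), 0L)
  arbor <- m$true_ox42_volume - soma
  ratio <- mean(arbor[m$age == "aged"]) / mean(arbor[m$age == "young"])
  expect_gt(ratio, 1.35)
  expect_lt(ratio, 1.65)

  # null multipliers: no group difference in truth beyond sampling error
  design0 <- cohort_design(groups = groups, n_animals_per_group = 8,
                           base_spec = base, seed = 21)
  m0 <- generate_cohort(design0)$manifest
  r0 <- mean(m0$true_ox42_volume[m0$age == "aged"]) /
    mean(m0$true_ox42_volume[m0$age == "young"])
  expect_gt(r0, 0.9)
  expect_lt(r0, 1.1)
})
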