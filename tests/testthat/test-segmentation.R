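# Watershed nucleus segmentation, volume filter, channel volume, foci.

# solid sphere mask helper
sphere_mask <- function(dims, center, r) {
  g <- expand.grid(x = 1:dims[1], y = 1:dims[2], z = 1:dims[3])
  m <- (g$x - center[1])^2 + (g$y - center[2])^2 + (g$z - center[3])^2 <= r^2
  array(m, dims)
}

test_that("two well-separated nuclei are recovered with exact volumes", {
  res <- generate_stack(spec_noise_free(stack_shape = c(96, 96, 20),
                                        n_microglia = 0, n_astrocytes = 0,
                                        n_other_nuclei = 2, seed = 14))
  dapi <- binarize(get_channel(res$stack, "DAPI"), res$truth$signal_floor)
  nuc <- segment_nuclei(dapi, voxel_size = res$stack$voxel_size)
  expect_equal(nrow(nuc$table), 2)
  true_vols <- sort(vapply(res$truth$cells, `[[`, 0L, "nucleus_volume"))
  expect_equal(sort(nuc$table$volume), true_vols)   # noise-free: exact
})

test_that("a single sphere yields one label; a thin-neck fusion is split into two", {
  dims <- c(40, 24, 24)
  s1 <- sphere_mask(dims, c(12, 12, 12), 7)
  nuc1 <- segment_nuclei(s1, voxel_size = c(1, 1, 1), h = 1)
  expect_equal(nrow(nuc1$table), 1)

  fused <- sphere_mask(dims, c(13, 12, 12), 7) | sphere_mask(dims, c(28, 12, 12), 7)
  # centers 15 apart, radii 7: a one-voxel-thin neck region joins them
  fused[20:21, 11:13, 11:13] <- TRUE
  expect_equal(max(label_components(fused)), 1)   # genuinely fused
  nuc2 <- segment_nuclei(fused, voxel_size = c(1, 1, 1), h = 1)
  expect_equal(nrow(nuc2$table), 2)
  # split should be near-symmetric
  expect_lt(abs(diff(nuc2$table$volume)) / sum(nuc2$table$volume), 0.2)
})

test_that("label conservation: per-nucleus volumes sum to the foreground count", {
  res <- generate_stack(spec_noise_free(stack_shape = c(96, 96, 20),
                                        n_microglia = 2, n_astrocytes = 0,
                                        n_other_nuclei = 2, seed = 15))
  dapi <- binarize(get_channel(res$stack, "DAPI"), res$truth$signal_floor)
  nuc <- segment_nuclei(dapi, voxel_size = res$stack$voxel_size)
  expect_equal(sum(nuc$table$volume), sum(dapi$mask))
  expect_equal(sum(nuc$labels > 0), sum(dapi$mask))
})

test_that("empty DAPI mask yields zero nuclei without error", {
  nuc <- segment_nuclei(array(FALSE, c(10, 10, 5)))
  expect_equal(nrow(nuc$table), 0)
})

test_that("volume filter keeps the inclusive 1000-1500 window and recompacts labels", {
  # five synthetic labels with volumes 800, 1000, 1200, 1500, 1600
  dims <- c(30, 30, 30)
  labels <- array(0L, dims)
  vols <- c(800, 1000, 1200, 1500, 1600)
  at <- 0L
  for (i in seq_along(vols)) {
    labels[(at + 1):(at + vols[i])] <- i
    at <- at + vols[i]
  }
  nuc <- structure(list(labels = labels,
                        table = gliaquant:::.nuclei_table(labels)),
                   class = "labeled_nuclei")
  kept <- filter_nuclei_by_volume(nuc, 1000, 1500)
  expect_equal(sort(kept$table$volume), c(1000, 1200, 1500))
  expect_equal(kept$table$label, 1:3)
  # idempotent
  again <- filter_nuclei_by_volume(kept, 1000, 1500)
  expect_identical(again$labels, kept$labels)
  # identity bounds and empty input
  expect_equal(nrow(filter_nuclei_by_volume(nuc, 0, Inf)$table), 5)
  empty <- segment_nuclei(array(FALSE, c(5, 5, 5)))
  expect_equal(nrow(filter_nuclei_by_volume(empty, 1000, 1500)$table), 0)
})

test_that("channel volume equals the brute-force voxel count", {
  expect_equal(measure_channel_volume(array(FALSE, c(4, 4, 4))), 0)
  expect_equal(measure_channel_volume(array(TRUE, c(10, 10, 10))), 1000)
  set.seed(31)
  m <- random_mask(c(9, 8, 7), 0.4)
  cnt <- 0
  for (i in 1:9) for (j in 1:8) for (k in 1:7) if (m[i, j, k]) cnt <- cnt + 1
  expect_equal(measure_channel_volume(m), cnt)
  v <- measure_channel_volume(m, voxel_size = c(0.2, 0.2, 0.5))
  expect_equal(attr(v, "um3"), cnt * 0.02)
})

test_that("foci detector finds symmetric blobs at their centres and honours size bounds", {
  img <- array(0, c(30, 30, 10))
  for (p in list(c(8, 8, 5), c(22, 22, 5)))
    for (dx in -2:2) for (dy in -2:2) for (dz in -1:1)
      img[p[1] + dx, p[2] + dy, p[3] + dz] <- 100 * exp(-(dx^2 + dy^2 + dz^2) / 4)
  f <- detect_foci(img, threshold = 10, min_size = 3, max_size = 500,
                   local_max_tolerance = 5)
  expect_equal(nrow(f), 2)
  expect_equal(sort(f$cx), c(8, 22))
  expect_equal(f$peak_brightness, c(100, 100))

  expect_equal(nrow(detect_foci(array(0, c(8, 8, 4)), 0)), 0)
  # blob smaller than min_size is dropped
  small <- array(0, c(10, 10, 6)); small[5, 5, 3] <- 50
  expect_equal(nrow(detect_foci(small, 10, min_size = 5)), 0)
  expect_error(detect_foci(small, 10, min_size = 10, max_size = 5), "min_size")
})

test_that("segmentation recovery on a noise-free 12-nucleus stack is exact", {
  res <- generate_stack(spec_noise_free(stack_shape = c(192, 192, 24),
                                        n_microglia = 4, n_astrocytes = 4,
                                        n_other_nuclei = 4, seed = 16))
  dapi <- binarize(get_channel(res$stack, "DAPI"), res$truth$signal_floor)
  nuc <- segment_nuclei(dapi, voxel_size = res$stack$voxel_size)
  expect_equal(nrow(nuc$table), 12)
  got <- sort(nuc$table$volume)
  want <- sort(vapply(res$truth$cells, `[[`, 0L, "nucleus_volume"))
  expect_true(all(abs(got - want) / want <= 0.02))
})
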