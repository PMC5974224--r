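# Statistical wrappers against hand-computed / enumeration oracles, plus
# rank-test invariances and the per-animal aggregation rules.

test_that("two-way ANOVA matches an explicit sums-of-squares computation on a balanced 2x3 design", {
  # 2 ages x 3 stress levels, 2 observations per cell
  age <- rep(c("young", "aged"), each = 6)
  stress <- rep(rep(c("control", "stress", "recovery"), each = 2), 2)
  y <- c(10, 12, 9, 11, 14, 16, 18, 20, 15, 17, 22, 24)

  # oracle: classical balanced two-way ANOVA by explicit group means
  gm <- mean(y)
  m_age <- tapply(y, age, mean)
  m_str <- tapply(y, stress, mean)
  m_cell <- tapply(y, interaction(age, stress), mean)
  ss_age <- 6 * sum((m_age - gm)^2)
  ss_str <- 4 * sum((m_str - gm)^2)
  ss_cell <- 2 * sum((m_cell - gm)^2)
  ss_int <- ss_cell - ss_age - ss_str
  ss_res <- sum((y - rep(m_cell[interaction(age, stress)], 1))^2)
  f_age <- (ss_age / 1) / (ss_res / 6)
  f_str <- (ss_str / 2) / (ss_res / 6)
  f_int <- (ss_int / 2) / (ss_res / 6)

  an <- two_way_anova(y, age, stress)
  expect_equal(an$F[an$term == "age"], f_age, tolerance = 1e-10)
  expect_equal(an$F[an$term == "stress"], f_str, tolerance = 1e-10)
  expect_equal(an$F[an$term == "age:stress"], f_int, tolerance = 1e-10)
  expect_equal(an$p[an$term == "age"],
               pf(f_age, 1, 6, lower.tail = FALSE), tolerance = 1e-10)
})

test_that("ANOVA degenerate cases: all-identical data and perfect additive fit", {
  y <- rep(5, 8)
  age <- rep(c("young", "aged"), 4)
  stress <- rep(c("control", "stress"), each = 4)
  an <- two_way_anova(y, age, stress)
  expect_equal(an$F, c(0, 0, 0))

  # additive means, zero within-cell noise: interaction 0, main effects degenerate
  y2 <- c(1, 1, 2, 2, 3, 3, 4, 4)
  age2 <- rep(c("young", "aged"), each = 4)
  stress2 <- rep(rep(c("control", "stress"), each = 2), 2)
  an2 <- two_way_anova(y2, age2, stress2)
  expect_equal(an2$F[an2$term == "age:stress"], 0)
  expect_true(attr(an2, "degenerate"))
  expect_true(is.infinite(an2$F[an2$term == "age"]))
})

test_that("ANOVA names the empty cell in an incomplete design", {
  y <- c(1, 2, 3, 4, 5, 6)
  age <- c("young", "young", "young", "aged", "aged", "aged")
  stress <- c("control", "control", "stress", "control", "control", "control")
  expect_error(two_way_anova(y, age, stress), "empty cell age=aged, stress=stress")
})

test_that("Mann-Whitney U follows the min(Ux, Uy) convention with exact small-sample p", {
  expect_equal(mann_whitney_u(c(1, 2), c(3, 4))$U, 0)   # complete separation
  expect_equal(mann_whitney_u(c(1, 3), c(2, 4))$U, 1)   # one discordant pair
  # identical samples of equal size: U = n^2/2 under midranks
  r <- mann_whitney_u(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(r$U, 8)
  # exact p by full enumeration for x={1,2}, y={3,4}: 1 of C(4,2)=6
  # orderings is as extreme, two-sided p = 2/6
  expect_equal(mann_whitney_u(c(1, 2), c(3, 4))$p, 2 / 6, tolerance = 1e-12)
  expect_equal(mann_whitney_u(c(1, 2), c(3, 4))$method, "exact")
  expect_equal(mann_whitney_u(rnorm(20), rnorm(20))$method, "normal")
})

test_that("Kruskal-Wallis H matches the closed-form rank arithmetic", {
  # three singleton groups {1},{2},{3}: H = 12/(3*4) * (1+4+9) - 3*4 = 2
  expect_equal(kruskal_wallis(list(1, 2, 3))$H, 2)
  expect_equal(kruskal_wallis(list(c(1, 2), c(1, 2)))$H, 0)   # all tied info
  expect_equal(kruskal_wallis(list(rep(7, 3), rep(7, 4)))$H, 0)
  expect_error(kruskal_wallis(list(1)), "length")
})

test_that("KS statistic equals the brute-force maximum over pooled breakpoints", {
  expect_equal(ks_test(c(1, 2, 3), c(1, 2, 3))$D, 0)
  expect_equal(ks_test(c(0, 0), c(1, 1))$D, 1)
  set.seed(51)
  x <- rnorm(7); y <- rnorm(9, 0.5)
  bp <- sort(c(x, y))
  d_oracle <- max(vapply(bp, function(t)
    abs(mean(x <= t) - mean(y <= t)), 0))
  expect_equal(ks_test(x, y)$D, d_oracle, tolerance = 1e-12)
})

test_that("Pearson r matches direct covariance arithmetic", {
  x <- c(1, 2, 3); y <- c(1, 3, 2)
  # cov = 0.5, sd_x = 1, sd_y = 1 -> r = 0.5
  expect_equal(pearson_r(x, y)$r, 0.5, tolerance = 1e-12)
  expect_equal(pearson_r(1:5, 2 * (1:5) + 1)$r, 1)
  expect_equal(pearson_r(1:5, -(1:5))$r, -1)
  expect_error(pearson_r(1:5, rep(3, 5)), "zero variance")
  # pairwise deletion of missing covariates
  r <- pearson_r(c(1, 2, 3, 4, NA), c(1, 2, 3, NA, 5))
  expect_equal(r$n, 3)
})

test_that("rank statistics are invariant under strictly increasing transforms", {
  set.seed(52)
  x <- rnorm(8); y <- rnorm(10, 0.8)
  for (f in list(function(v) exp(v), function(v) v^3,
                 function(v) 5 * v + 2)) {
    expect_equal(mann_whitney_u(f(x), f(y))$U, mann_whitney_u(x, y)$U)
    expect_equal(kruskal_wallis(list(f(x), f(y)))$H,
                 kruskal_wallis(list(x, y))$H)
    expect_equal(ks_test(f(x), f(y))$D, ks_test(x, y)$D)
  }
  # relabelling group order only flips which sample is "x"
  expect_equal(mann_whitney_u(y, x)$U, mann_whitney_u(x, y)$U)
  expect_equal(kruskal_wallis(list(y, x))$H, kruskal_wallis(list(x, y))$H)
})

test_that("eCDF table counts duplicates and ends at one", {
  expect_equal(ecdf_table(5), data.frame(value = 5, fraction = 1))
  t2 <- ecdf_table(c(1, 2, 2, 4))
  expect_equal(t2$value, c(1, 2, 4))
  expect_equal(t2$fraction, c(0.25, 0.75, 1))
  set.seed(53)
  t3 <- ecdf_table(rnorm(40))
  expect_true(all(diff(t3$fraction) > 0))
  expect_equal(t3$fraction[nrow(t3)], 1)
})

test_that("per-animal aggregation averages images and flags missing microglia as NA", {
  mk_summary <- function(image_id, animal_id, n_micro, vol, soma) {
    data.frame(image_id = image_id, animal_id = animal_id,
               n_nuclei = 5, n_microglia = n_micro, n_high_gr_nuclei = 1,
               microglia_volume = vol, astrocyte_volume = 100,
               nonnuclear_gr_microglia = 10, nonnuclear_gr_astrocyte = 5,
               mean_soma_volume = soma,
               threshold_dapi = 1, threshold_ox42 = 1, threshold_gr = 1,
               threshold_gfap = 1)
  }
  sums <- rbind(mk_summary("i1", "a1", 2, 1000, 100),
                mk_summary("i2", "a1", 2, 2000, 200),
                mk_summary("i3", "a2", 0, 500, NA))
  cells <- data.frame(cell_type = c("microglia", "microglia", "microglia"),
                      soma_volume = c(100, 100, 200),
                      image_id = c("i1", "i1", "i2"),
                      animal_id = "a1")
  man <- data.frame(image_id = c("i1", "i2", "i3"),
                    animal_id = c("a1", "a1", "a2"),
                    age = c("young", "young", "aged"),
                    stress = "control")
  s <- per_animal_summary(cells, sums, man)
  expect_equal(nrow(s), 2)
  a1 <- s[s$animal_id == "a1", ]
  expect_equal(a1$microglia_volume, 1500)          # mean of two images
  expect_equal(a1$mean_soma_volume, mean(c(100, 100, 200)))  # over cells
  a2 <- s[s$animal_id == "a2", ]
  expect_true(is.na(a2$mean_soma_volume))          # zero microglia -> NA
  expect_true(is.na(a2$nonnuclear_gr_microglia))

  # an image the manifest does not know is an error
  expect_error(per_animal_summary(cells, mk_summary("ix", "a9", 1, 1, 1),
                                  man), "manifest")
})
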