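test_that("digital balls carry their diameter as modal thickness", {
  for (r in c(5, 8)) {
    tm <- local_thickness(ball_mask(r), "air", floor = 0, cap = Inf)
    tt <- round(tm$tau[tm$tau > 0], 6)
    mode_tau <- as.numeric(names(sort(table(tt), decreasing = TRUE))[1])
    expect_lte(abs(mode_tau - 2 * r), 1)
  }
})

test_that("a slab carries its height on the central plane", {
  slab <- binary_volume(array(FALSE, c(5, 20, 20)), 1)
  tm <- local_thickness(slab, "air", floor = 0, cap = Inf)
  expect_lte(abs(tm$tau[3, 10, 10] - 5), 1)
})

test_that("a single phase voxel has thickness equal to the spacing", {
  m <- array(TRUE, c(5, 5, 5))
  m[3, 3, 3] <- FALSE
  tm <- brute_force_thickness(binary_volume(m, 1.5), "air", 0, Inf)
  expect_equal(tm$tau[3, 3, 3], 1.5)
})

test_that("disjoint balls are measured independently", {
  m <- array(TRUE, c(15, 15, 30))
  co <- expand.grid(z = 0:14, y = 0:14, x = 0:29)
  m[sqrt((co$z - 7)^2 + (co$y - 7)^2 + (co$x - 7)^2) <= 5] <- FALSE
  m[sqrt((co$z - 7)^2 + (co$y - 7)^2 + (co$x - 22)^2) <= 3] <- FALSE
  tm <- brute_force_thickness(binary_volume(m, 1), "air", 0, Inf)
  expect_lte(abs(max(tm$tau[, , 1:15]) - 10), 1)
  expect_lte(abs(max(tm$tau[, , 16:30]) - 6), 1)
})

test_that("the fast algorithm equals the brute-force oracle voxelwise", {
  for (s in 1:4) {
    set.seed(s)
    m <- array(runif(14^3) > 0.45, c(14, 14, 14))
    bv <- binary_volume(m, 1.1)
    fast <- local_thickness(bv, "air", 0, Inf)$tau
    slow <- brute_force_thickness(bv, "air", 0, Inf)$tau
    expect_lt(max(abs(fast - slow)), 1e-9)
  }
  expect_error(local_thickness(binary_volume(array(TRUE, c(3, 3, 3)), 1),
                               "air"), "empty")
})

test_that("thickness is monotone under air dilation", {
  set.seed(6)
  m <- array(runif(16^3) > 0.4, c(16, 16, 16))
  bv <- binary_volume(m, 1)
  t0 <- local_thickness(bv, "air", 0, Inf)$tau
  # dilate air by one face-neighbourhood step (array shifts)
  air <- !m
  dil_air <- air
  n <- 16
  dil_air[1:(n - 1), , ] <- dil_air[1:(n - 1), , ] | air[2:n, , ]
  dil_air[2:n, , ] <- dil_air[2:n, , ] | air[1:(n - 1), , ]
  dil_air[, 1:(n - 1), ] <- dil_air[, 1:(n - 1), ] | air[, 2:n, ]
  dil_air[, 2:n, ] <- dil_air[, 2:n, ] | air[, 1:(n - 1), ]
  dil_air[, , 1:(n - 1)] <- dil_air[, , 1:(n - 1)] | air[, , 2:n]
  dil_air[, , 2:n] <- dil_air[, , 2:n] | air[, , 1:(n - 1)]
  t1 <- local_thickness(binary_volume(!dil_air, 1), "air", 0, Inf)$tau
  air0 <- !m
  expect_true(all(t1[air0] >= t0[air0] - 1e-9))
})

test_that("thickness is scale-equivariant and translation-invariant", {
  set.seed(8)
  m <- array(runif(12^3) > 0.45, c(12, 12, 12))
  t1 <- local_thickness(binary_volume(m, 1), "air", 0, Inf)$tau
  t2 <- local_thickness(binary_volume(m, 2), "air", 0, Inf)$tau
  expect_equal(t2, 2 * t1)
  padded <- array(TRUE, c(16, 16, 16))
  padded[3:14, 3:14, 3:14] <- m
  tp <- local_thickness(binary_volume(padded, 1), "air", 0, Inf)$tau
  expect_equal(tp[3:14, 3:14, 3:14], t1)
})

test_that("thickness densities are normalised and located correctly", {
  tau <- array(0, c(6, 6, 6))
  tau[2:5, 2:5, 2:5] <- 60
  tm <- thickness_map(tau, 1)
  de <- thickness_density(tm)
  expect_equal(trapz_num(de$grid, de$density), 1, tolerance = 1e-3)
  expect_lte(abs(de$grid[which.max(de$density)] - 60), de$bandwidth / 2 + 0.3)
  expect_error(thickness_density(thickness_map(array(0, c(3, 3, 3)), 1)))
})

test_that("range fractions integrate the distribution correctly", {
  tau <- array(0, c(6, 6, 6))
  tau[2:5, 2:5, 2:5] <- 60
  fr <- range_fractions(thickness_map(tau, 1))
  expect_equal(fr$fraction, c(0, 100, 0, 0))
  # uniform on [20, 110): each 30-um range gets a third
  set.seed(9)
  tau2 <- array(runif(20^3, 20, 110), c(20, 20, 20))
  fr2 <- range_fractions(thickness_map(tau2, 1))
  expect_equal(fr2$fraction[1:3], rep(100 / 3, 3), tolerance = 0.02)
  expect_equal(sum(fr2$fraction), 100, tolerance = 1e-9)
  expect_error(range_fractions(thickness_map(tau2, 1),
                               list(c(20, 60), c(50, 90))), "overlap")
})

test_that("ensemble statistics follow the sample formulas", {
  f1 <- data.frame(lo = 1, hi = 2, fraction = 40)
  f2 <- data.frame(lo = 1, hi = 2, fraction = 60)
  st <- ensemble_stats(list(f1, f2))
  expect_equal(st$mean, 50)
  expect_equal(st$sd, sd(c(40, 60)))
  same <- ensemble_stats(list(f1, f1, f1))
  expect_equal(same$sd, 0)
  g <- seq(0, 1, length.out = 11)
  d <- density_estimate(g, rep(1, 11), 0.1, 5)
  expect_equal(ensemble_stats(list(d, d))$sd, rep(0, 11))
})

test_that("the colour-index overlay quantises and round-trips", {
  tau <- array(0, c(4, 4, 4))
  tau[2, 2, 2] <- 30
  tau[3, 3, 3] <- 90
  vol <- gray_volume(array(0, c(4, 4, 4)), 1)
  ov <- export_thickness_overlay(thickness_map(tau, 1), vol, n_bins = 16)
  expect_equal(ov$index$data[1, 1, 1], 0)
  expect_equal(ov$index$data[3, 3, 3], 16)
  idx <- ov$index$data[2, 2, 2]
  expect_lte(abs(ov$legend$mid[idx] - 30), diff(ov$legend$lo[1:2]) + 1e-9)
  expect_error(export_thickness_overlay(thickness_map(tau, 1),
                                        gray_volume(array(0, c(3, 3, 3)), 1)),
               "mismatch")
})
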