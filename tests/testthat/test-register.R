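rot_z <- function(deg) {
  th <- deg * pi / 180
  rbind(c(1, 0, 0), c(0, cos(th), -sin(th)), c(0, sin(th), cos(th)))
}

test_that("identical landmark sets give the identity transform", {
  set.seed(1)
  L <- matrix(runif(15, 0, 50), 5, 3)
  tf <- estimate_rigid(L, L)
  expect_equal(tf$rotation, diag(3), tolerance = 1e-10)
  expect_equal(tf$translation, c(0, 0, 0), tolerance = 1e-10)
})

test_that("a known rotation + translation is recovered to tiny RMS", {
  set.seed(2)
  Lm <- matrix(runif(30, 0, 100), 10, 3)
  R <- rot_z(10)
  tv <- c(5, 0, 0)
  Lf <- t(R %*% t(Lm)) + matrix(tv, 10, 3, byrow = TRUE)
  tf <- estimate_rigid(Lf, Lm)
  rms <- sqrt(mean(rowSums((transform_points(tf, Lm) - Lf)^2)))
  expect_lt(rms, 1e-6)
  expect_equal(tf$rotation, R, tolerance = 1e-9)
  expect_equal(tf$translation, tv, tolerance = 1e-8)
})

test_that("degenerate landmark configurations are rejected", {
  line <- cbind(1:3, 2 * (1:3), 3 * (1:3))
  expect_error(estimate_rigid(line, line + 1), "collinear")
  expect_error(estimate_rigid(line[1:2, ], line[1:2, ]), "at least 3")
  expect_error(rigid_transform(diag(c(1, 1, -1)), c(0, 0, 0)), "proper")
})

test_that("the estimated transform is a local optimum over random rigids", {
  set.seed(3)
  Lm <- matrix(runif(24, 0, 80), 8, 3)
  Lf <- t(rot_z(7) %*% t(Lm)) + matrix(c(1, -2, 3), 8, 3, byrow = TRUE) +
    matrix(rnorm(24, 0, 0.5), 8, 3) # noisy correspondence
  tf <- estimate_rigid(Lf, Lm)
  rms <- function(t_) sqrt(mean(rowSums((transform_points(t_, Lm) - Lf)^2)))
  best <- rms(tf)
  for (i in 1:100) {
    d <- rot_z(rnorm(1, 0, 2))
    pert <- rigid_transform(tf$rotation %*% d, tf$translation + rnorm(3, 0, 1))
    expect_gte(rms(pert), best - 1e-12)
  }
})

test_that("transform composition matches sequential estimation", {
  set.seed(4)
  A <- matrix(runif(24, 0, 60), 8, 3)
  tAB <- rigid_transform(rot_z(5), c(1, 2, 3))
  tBC <- rigid_transform(rot_z(-12), c(-3, 0, 4))
  B <- transform_points(tAB, A)
  C <- transform_points(tBC, B)
  est <- compose_rigid(estimate_rigid(C, B), estimate_rigid(B, A))
  expect_lt(max(abs(transform_points(est, A) - C)), 1e-6)
})

test_that("resampling honours exact lattice shifts and identity", {
  set.seed(5)
  g <- gray_volume(array(rnorm(30^3), c(30, 30, 30)), 1)
  id <- rigid_transform(diag(3), c(0, 0, 0))
  expect_equal(apply_rigid(g, id)$data, g$data)
  shifted <- apply_rigid(g, rigid_transform(diag(3), c(0, 0, 1)))
  expect_equal(shifted$data[, , 2:30], g$data[, , 1:29])
  expect_error(apply_rigid(g, id, out_shape = c(0, 5, 5)))
})

test_that("a rotated mask survives the round trip with high Dice", {
  tr <- generate_foam(phantom_spec(c(64, 64, 64), 1.1, 6, 2.2, 0.1,
                                   shell_thickness = 4.4, weight_spread = 0.8,
                                   fillet_radius = 6.6, seed = 3))
  R <- rot_z(10)
  tv <- c(0, 0, 5)
  fwd <- rigid_transform(R, tv)
  bwd <- rigid_transform(t(R), -as.vector(t(R) %*% tv))
  back <- apply_rigid(apply_rigid(tr$mask, fwd), bwd)
  interior <- array(FALSE, c(64, 64, 64))
  interior[14:50, 14:50, 14:50] <- TRUE
  a <- tr$mask$data & interior
  b <- back$data & interior
  expect_gte(dice_coef(a, b), 0.98)
})

test_that("landmark CSVs round-trip through the reader", {
  d <- data.frame(fixed_z = 1:3, fixed_y = 4:6, fixed_x = 7:9,
                  moving_z = 2:4, moving_y = 5:7, moving_x = 8:10)
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(d, path, row.names = FALSE)
  lm <- read_landmarks(path)
  expect_equal(unname(lm$fixed[, 1]), 1:3)
  expect_equal(unname(lm$moving[, 3]), 8:10)
})
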