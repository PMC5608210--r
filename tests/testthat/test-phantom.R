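small_spec <- function(...) {
  phantom_spec(shape = c(48, 48, 48), spacing = 1.1, n_cells = 5,
               wall_thickness = 2.2, duct_fraction = 0, shell_thickness = 2.2,
               seed = 3, ...)
}

test_that("foam generation is deterministic and honours its invariants", {
  tr1 <- generate_foam(small_spec())
  tr2 <- generate_foam(small_spec())
  expect_identical(tr1$mask$data, tr2$mask$data)
  tf <- mean(tr1$mask$data)
  expect_gt(tf, 0)
  expect_lt(tf, 1)
  # every cell centre lies in air
  vox <- round(tr1$cell_centers / tr1$mask$spacing) + 1
  expect_true(all(!tr1$mask$data[vox]))
})

test_that("a single-cell foam has tissue only at the border shell", {
  tr <- generate_foam(phantom_spec(c(24, 24, 24), 1, 1, 2, 0,
                                   shell_thickness = 2, seed = 1))
  interior <- array(FALSE, c(24, 24, 24))
  interior[4:21, 4:21, 4:21] <- TRUE
  expect_false(any(tr$mask$data & interior))
  expect_true(any(tr$mask$data)) # the shell itself
})

test_that("the study phantom's tissue fraction matches the reference run", {
  # frozen from the reference run of this spec and seed
  expect_equal(mean(study_truth()$mask$data), 0.3536, tolerance = 0.01)
})

test_that("inflation is identity at factor 1 and scales diameters", {
  tr <- generate_foam(small_spec())
  expect_identical(inflate(tr, 1)$mask$data, tr$mask$data)
  ti <- inflate(tr, 1.5)
  expect_equal(mean(ti$nominal_diameters) / mean(tr$nominal_diameters), 1.5,
               tolerance = 0.02)
  expect_error(inflate(tr, 0.8))
  # air fraction non-decreasing with factor
  af <- sapply(c(1, 1.2, 1.4), function(f) mean(!inflate(tr, f)$mask$data))
  expect_true(all(diff(af) >= -1e-12))
})

test_that("inflation shifts the ground-truth thickness mode strictly upward", {
  tr <- generate_foam(study_phantom_spec("low"))
  ti <- inflate(tr, 1.5)
  m0 <- thickness_density(local_thickness(tr$mask, "air"))
  m1 <- thickness_density(local_thickness(ti$mask, "air"))
  expect_gt(m1$grid[which.max(m1$density)], m0$grid[which.max(m0$density)])
})

test_that("rendering reproduces the requested gray structure", {
  tr <- generate_foam(small_spec())
  clean <- render_image(tr, imaging_params(gray_air = 50, gray_tissue = 150,
                                           gradient = c(0, 0, 0),
                                           blur_sigma = 0, noise_sigma = 0))
  expect_setequal(unique(as.vector(clean$data)), c(50, 150))
  # plane gradient on an all-air region: row-constant, column-linear
  one_cell <- generate_foam(phantom_spec(c(24, 24, 24), 1, 1, 2, 0,
                                         shell_thickness = 1, seed = 1))
  grad <- render_image(one_cell,
                       imaging_params(gradient = c(0.5, 0, 0), blur_sigma = 0,
                                      noise_sigma = 0))
  sl <- grad$data[12, 5:20, 5:20] # interior, air only
  expect_lt(max(apply(sl, 2, function(col) diff(range(col)))), 1e-9)
  expect_equal(unname(diff(sl[1, ])), rep(0.5, 15), tolerance = 1e-9)
})

test_that("rendering is deterministic and hits the requested SNR", {
  tr <- generate_foam(small_spec())
  im <- imaging_params(gradient = c(0, 0, 0), blur_sigma = 0, noise_sigma = 8,
                       seed = 5)
  v1 <- render_image(tr, im)
  v2 <- render_image(tr, im)
  expect_identical(v1$data, v2$data)
  # measure noise and contrast on pure-phase voxels (no blur: all pure)
  air_vals <- v1$data[!tr$mask$data]
  tis_vals <- v1$data[tr$mask$data]
  snr_req <- (160 - 60) / 8
  snr_obs <- (mean(tis_vals) - mean(air_vals)) /
    sqrt(mean(c(var(air_vals), var(tis_vals))))
  expect_equal(snr_obs, snr_req, tolerance = 0.05)
})
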