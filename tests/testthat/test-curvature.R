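test_that("the extracted ball surface is closed, oriented and consistent", {
  mask <- ball_mask(20, 52)
  mesh <- extract_surface(mask)
  V <- nrow(mesh$vertices)
  Fc <- nrow(mesh$triangles)
  expect_equal(V - 3 * Fc / 2 + Fc, 2) # Euler characteristic of a sphere
  ctr <- rep((52 - 1) / 2, 3)
  rad <- sweep(mesh$vertices, 2, ctr)
  expect_true(all(rowSums(mesh$vertex_normals * rad) > 0)) # air -> tissue
  expect_error(extract_surface(binary_volume(array(TRUE, c(4, 4, 4)), 1)))
})

test_that("smoothing regularises the ball mesh without collapsing it", {
  mask <- ball_mask(20, 52)
  raw <- extract_surface(mask)
  sm <- smooth_mesh(raw, 20, 0.5)
  expect_identical(smooth_mesh(raw, 0)$vertices, raw$vertices)
  ctr <- rep((52 - 1) / 2, 3)
  rms_dev <- function(m) {
    rr <- sqrt(rowSums(sweep(m$vertices, 2, ctr)^2))
    sd(rr)
  }
  expect_lt(rms_dev(sm), rms_dev(raw))
  expect_lt(abs(sm$meta$smoothing$volume_change), 0.05)
  # smoothed mesh area approaches the analytic sphere area
  area <- function(m) {
    e1 <- m$vertices[m$triangles[, 2], ] - m$vertices[m$triangles[, 1], ]
    e2 <- m$vertices[m$triangles[, 3], ] - m$vertices[m$triangles[, 1], ]
    cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
                e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
                e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
    sum(sqrt(rowSums(cr^2))) / 2
  }
  expect_equal(area(sm) / (4 * pi * 20^2), 1, tolerance = 0.05)
  expect_error(smooth_mesh(raw, 5, step = 1.5))
})

test_that("a flat patch has zero curvature at interior vertices", {
  cf <- normal_cycle_curvature(flat_patch(), 3)
  expect_gt(sum(cf$included), 50)
  expect_lt(max(abs(c(cf$kappa1[cf$included], cf$kappa2[cf$included]))), 1e-6)
})

test_that("an air ball recovers the analytic sphere curvature", {
  cf <- normal_cycle_curvature(smoothed_ball_mesh(), 5)
  k1 <- median(cf$kappa1[cf$included])
  k2 <- median(cf$kappa2[cf$included])
  expect_equal(k1, 0.04, tolerance = 0.1)
  expect_equal(k2, 0.04, tolerance = 0.1)
  expect_equal(median(cf$K[cf$included]), 1.6e-3, tolerance = 0.15)
  # sign convention: air sphere = region 1; embedded tissue sphere = region 4
  lab <- classify_regions(cf)
  expect_gt(mean(lab[cf$included] == 1), 0.95)
  tis <- array(FALSE, c(40, 40, 40))
  co <- expand.grid(z = 0:39, y = 0:39, x = 0:39)
  tis[sqrt((co$z - 19.5)^2 + (co$y - 19.5)^2 + (co$x - 19.5)^2) <= 12] <- TRUE
  cft <- normal_cycle_curvature(smooth_mesh(extract_surface(
    binary_volume(tis, 1)), 20, 0.5), 4)
  labt <- classify_regions(cft)
  expect_gt(mean(labt[cft$included] == 4), 0.9)
})

test_that("an air cylinder recovers curvatures 0 and 1/r", {
  nz <- 40; nyx <- 52; ctr <- (nyx - 1) / 2
  co <- expand.grid(y = 0:(nyx - 1), x = 0:(nyx - 1))
  circ <- matrix(sqrt((co$y - ctr)^2 + (co$x - ctr)^2) <= 20, nyx, nyx)
  cyl <- array(rep(circ, each = nz), c(nz, nyx, nyx))
  mesh <- smooth_mesh(extract_surface(binary_volume(!cyl, 1)), 20, 0.5)
  cf <- normal_cycle_curvature(mesh, 5)
  expect_lt(abs(median(cf$kappa1[cf$included])), 0.005)
  expect_equal(median(cf$kappa2[cf$included]), 0.05, tolerance = 0.1)
  # the open tube ends are boundary-excluded
  expect_gt(sum(!cf$included), 0)
})

test_that("principal curvatures invert H and K exactly", {
  expect_equal(principal_from_HK(1, 1), list(kappa1 = 1, kappa2 = 1),
               ignore_attr = TRUE)
  expect_equal(principal_from_HK(0, -1), list(kappa1 = -1, kappa2 = 1),
               ignore_attr = TRUE)
  expect_equal(principal_from_HK(2, 3), list(kappa1 = 1, kappa2 = 3),
               ignore_attr = TRUE)
  clamped <- principal_from_HK(c(1, 0), c(1.5, 0))
  expect_equal(attr(clamped, "clamped"), 1)
  expect_equal(clamped$kappa1[1], clamped$kappa2[1])
})

test_that("the tensor field satisfies the algebraic identities everywhere", {
  cf <- normal_cycle_curvature(smoothed_ball_mesh(), 5)
  expect_true(all(cf$kappa1 <= cf$kappa2 + 1e-12))
  expect_equal(cf$H, (cf$kappa1 + cf$kappa2) / 2, tolerance = 1e-12)
  expect_equal(cf$K, cf$kappa1 * cf$kappa2, tolerance = 1e-12)
  pk <- principal_from_HK(cf$H, cf$K)
  rel <- abs(pk$kappa1 - cf$kappa1) / pmax(abs(cf$kappa1), 1e-12)
  expect_lt(max(rel[cf$included]), 1e-9)
  expect_lt(attr(pk, "clamped") / length(cf$H), 0.001)
})

test_that("curvature is scale-equivariant", {
  mesh <- smoothed_ball_mesh()
  cf1 <- normal_cycle_curvature(mesh, 5)
  mesh2 <- surface_mesh(mesh$vertices * 2, mesh$triangles, mesh$spacing * 2)
  cf2 <- normal_cycle_curvature(mesh2, 10)
  i <- cf1$included & cf2$included
  expect_equal(cf2$kappa2[i], cf1$kappa2[i] / 2, tolerance = 1e-9)
  expect_equal(cf2$K[i], cf1$K[i] / 4, tolerance = 1e-9)
})

test_that("more smoothing never increases high-frequency curvature noise", {
  mask <- ball_mask(15, 40)
  raw <- extract_surface(mask)
  p95 <- sapply(c(5, 20), function(it) {
    cf <- normal_cycle_curvature(smooth_mesh(raw, it, 0.5), 4)
    quantile(abs(cf$K[cf$included]), 0.95)
  })
  expect_lte(p95[2], p95[1])
})

test_that("region classification follows the quadrant rules", {
  fake <- curvature_field(flat_patch(4), kappa1 = c(0.02, -0.02, -0.01, -0.03),
                          kappa2 = c(0.02, -0.02, 0.03, 0.01),
                          geodesic_radius = 1, included = rep(TRUE, 4))
  expect_equal(classify_regions(fake)[1:4], c(1L, 4L, 2L, 3L))
})

test_that("ISDs live below the diagonal and normalise", {
  cf <- normal_cycle_curvature(smoothed_ball_mesh(), 5)
  isd <- isd_density(cf)
  cell <- diff(isd$grid_k1[1:2]) * diff(isd$grid_k2[1:2])
  expect_equal(sum(isd$density) * cell, 1, tolerance = 1e-2)
  above <- outer(isd$grid_k1, isd$grid_k2, ">")
  expect_lt(sum(isd$density[above]) * cell, 1e-6)
  # region-1 mass for the air sphere
  pos <- outer(isd$grid_k1 > 0, isd$grid_k2 > 0, "&")
  expect_gt(sum(isd$density[pos]) * cell, 0.95)
})

test_that("H and K densities sit at the analytic sphere values", {
  cf <- normal_cycle_curvature(smoothed_ball_mesh(), 5)
  cd <- curvature_densities(cf)
  expect_equal(trapz_num(cd$H$grid, cd$H$density), 1, tolerance = 1e-3)
  expect_equal(trapz_num(cd$K$grid, cd$K$density), 1, tolerance = 1e-3)
  expect_lte(abs(cd$H$grid[which.max(cd$H$density)] - 0.04),
             cd$H$bandwidth + 0.002)
  expect_lte(abs(cd$K$grid[which.max(cd$K$density)] - 1.6e-3),
             cd$K$bandwidth + 2e-4)
})

test_that("vertex labels rasterise back onto a thin voxel shell", {
  mesh <- smoothed_ball_mesh(15, 40)
  cf <- normal_cycle_curvature(mesh, 4)
  lab <- classify_regions(cf)
  vol <- map_to_slices(mesh, lab, c(40, 40, 40))
  expect_true(all(vol$data %in% 0:4))
  filled <- which(vol$data > 0, arr.ind = TRUE)
  rr <- sqrt(rowSums(sweep(filled - 1, 2, rep(19.5, 3))^2))
  expect_lt(diff(range(rr)), 4) # 1-2 voxel shell around the surface
  single <- surface_mesh(rbind(c(2, 3, 4), c(2, 3, 4) + 0.01,
                               c(2, 3, 4) + c(0, 0.01, 0)),
                         matrix(c(1, 2, 3), 1), spacing = 1)
  lv <- map_to_slices(single, c(2L, 2L, 2L), c(6, 6, 6))
  expect_equal(sum(lv$data > 0), 1)
  expect_equal(lv$data[3, 4, 5], 2)
})

test_that("ISD ensembles average correctly", {
  cf <- normal_cycle_curvature(smoothed_ball_mesh(15, 40), 4)
  lims <- c(-0.2, 0.2, -0.2, 0.2)
  d1 <- isd_density(cf, lims = lims)
  ens <- ensemble_isd(list(d1, d1, d1))
  expect_equal(max(ens$sd), 0)
  cell <- diff(ens$grid_k1[1:2]) * diff(ens$grid_k2[1:2])
  expect_equal(sum(ens$mean) * cell, 1, tolerance = 1e-3)
})
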