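# Shared fixtures, built once per test run and cached across test files.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixture_env))
    assign(name, expr, envir = .fixture_env)
  get(name, envir = .fixture_env)
}

# digital ball of radius r voxels (air inside, tissue outside), odd grid so
# the centre falls on a lattice point
ball_mask <- function(r, n = 2 * r + 7, spacing = 1) {
  ctr <- (n - 1) / 2  # odd n puts the centre on a lattice point
  co <- expand.grid(z = 0:(n - 1), y = 0:(n - 1), x = 0:(n - 1))
  ball <- array(sqrt((co$z - ctr)^2 + (co$y - ctr)^2 + (co$x - ctr)^2) <= r,
                c(n, n, n))
  binary_volume(!ball, spacing)
}

dice_coef <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

trapz_num <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)

# the study phantom and its default-artifact rendering, shared by the
# segmentation and ensemble tests
study_truth <- function() fixture("study_truth",
                                  generate_foam(study_phantom_spec("high")))
study_render <- function() fixture("study_render",
                                   render_image(study_truth(),
                                                imaging_params(seed = 11L)))

# septal (interior wall) voxels of a phantom truth: tissue minus the shell
septal_voxels <- function(truth) {
  dims <- dim(truth$mask$data)
  sh <- ceiling(truth$spec$shell_thickness / truth$spec$spacing)
  interior <- array(FALSE, dims)
  interior[(sh + 1):(dims[1] - sh), (sh + 1):(dims[2] - sh),
           (sh + 1):(dims[3] - sh)] <- TRUE
  truth$mask$data & interior
}

# independent flood-fill component labelling (plain R queue), used as an
# oracle against the C++ labelling
flood_label <- function(mask, connectivity = 26) {
  dims <- dim(mask)
  lab <- array(0L, dims)
  nbr <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
  nbr <- nbr[rowSums(abs(nbr)) > 0, ]
  if (connectivity == 6) nbr <- nbr[rowSums(abs(nbr)) == 1, ]
  cur <- 0L
  for (i in which(mask)) {
    if (lab[i] > 0) next
    cur <- cur + 1L
    queue <- i
    lab[i] <- cur
    while (length(queue) > 0) {
      j <- queue[length(queue)]
      queue <- queue[-length(queue)]
      zj <- (j - 1) %% dims[1]
      yj <- ((j - 1) %/% dims[1]) %% dims[2]
      xj <- (j - 1) %/% (dims[1] * dims[2])
      for (k in seq_len(nrow(nbr))) {
        z <- zj + nbr[k, 1]; y <- yj + nbr[k, 2]; x <- xj + nbr[k, 3]
        if (z < 0 || z >= dims[1] || y < 0 || y >= dims[2] ||
            x < 0 || x >= dims[3]) next
        jj <- 1L + z + dims[1] * (y + dims[2] * x)
        if (mask[jj] && lab[jj] == 0L) {
          lab[jj] <- cur
          queue <- c(queue, jj)
        }
      }
    }
  }
  lab
}

flat_patch <- function(g = 20) {
  vs <- as.matrix(expand.grid(z = 0, y = 0:g, x = 0:g))[, c("z", "y", "x")]
  id <- function(y, x) y * (g + 1) + x + 1
  tris <- matrix(0L, 0, 3)
  for (y in 0:(g - 1)) for (x in 0:(g - 1))
    tris <- rbind(tris,
                  c(id(y, x), id(y + 1, x), id(y, x + 1)),
                  c(id(y + 1, x), id(y + 1, x + 1), id(y, x + 1)))
  surface_mesh(vs, tris, 1)
}

smoothed_ball_mesh <- function(r = 25, n = 64)
  fixture(paste0("ballmesh", r),
          smooth_mesh(extract_surface(ball_mask(r, n)), 20, 0.5))

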