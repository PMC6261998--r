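test_that("make_phantom handles the empty case and rejects bad parameters", {
  ph <- make_phantom(350, 0, 90, seed = 1)
  expect_s3_class(ph, "embryo_phantom")
  expect_identical(nrow(ph$nuclei), 0L)
  expect_equal(ph$sphere_radius, 350)

  expect_error(make_phantom(-1, 10, 90), class = "orientspim_invalid_parameter")
  expect_error(make_phantom(350, -5, 90), class = "orientspim_invalid_parameter")
  expect_error(make_phantom(350, 10, 0), class = "orientspim_invalid_parameter")
  expect_error(make_phantom(350, 10, 181), class = "orientspim_invalid_parameter")
})

test_that("make_phantom is deterministic and respects its invariants", {
  a <- make_phantom(350, 500, 90, seed = 7, shell_thickness = 100)
  b <- make_phantom(350, 500, 90, seed = 7, shell_thickness = 100)
  expect_identical(a, b)

  ## brute-force geometric checks over every nucleus
  rel <- as.matrix(a$nuclei[, c("x", "y", "z")])
  expect_true(all(sqrt(rowSums(rel^2)) <= 350))
  expect_true(all(a$nuclei$radius > 0))
  expect_true(all(a$nuclei$intensity > 0))

  narrow <- make_phantom(350, 500, 30, seed = 7)
  rel <- as.matrix(narrow$nuclei[, c("x", "y", "z")])
  ang <- sapply(seq_len(nrow(rel)), function(i) {
    v <- rel[i, ] / sqrt(sum(rel[i, ]^2))
    acos(min(1, sum(v * narrow$cap_axis))) * 180 / pi
  })
  expect_lte(max(ang), 30 + 1e-9)
})

test_that("rotate_phantom preserves geometry and rejects improper rotations", {
  ph <- make_phantom(100, 50, 90, seed = 3)
  expect_equal(rotate_phantom(ph, diag(3)), ph)

  r <- rotation_axis_angle(c(1, 2, 3), 180)
  back <- rotate_phantom(rotate_phantom(ph, r), r)
  expect_equal(as.matrix(back$nuclei[, c("x", "y", "z")]),
               as.matrix(ph$nuclei[, c("x", "y", "z")]), tolerance = 1e-9)

  ## pairwise distance matrix preserved under a random rotation (seed 3)
  set.seed(3)
  rr <- rotation_axis_angle(rnorm(3), runif(1, 0, 360))
  rot <- rotate_phantom(ph, rr)
  expect_equal(as.matrix(dist(ph$nuclei[, c("x", "y", "z")])),
               as.matrix(dist(rot$nuclei[, c("x", "y", "z")])),
               tolerance = 1e-6)

  mirror <- diag(c(-1, 1, 1))   # determinant -1
  expect_error(rotate_phantom(ph, mirror), class = "orientspim_invalid_parameter")
})

test_that("render_view reaches the degradation-free peak and is deterministic", {
  nuc <- data.frame(x = 0, y = 0, z = 0, radius = 8, intensity = 500)
  ph <- embryo_phantom(c(0, 0, 0), 50, nuc, c(0, 0, -1), 90)
  opt <- optics_model(attenuation_length = Inf, blur_growth = 0,
                      surface_aberration = 0, background_mean = 40,
                      background_sd = 0)
  st <- render_view(ph, opt, c(33, 65, 65), 1, 1, seed = 1)
  expect_equal(max(st$voxels), 40 + 500, tolerance = 0.01)

  st2 <- render_view(ph, opt, c(33, 65, 65), 1, 1, seed = 1)
  expect_identical(st$voxels, st2$voxels)
})

test_that("rendering is mirror-symmetric for a mirror-symmetric phantom", {
  nuc <- data.frame(x = c(10, 10), y = c(15, -15), z = c(-5, -5),
                    radius = c(6, 6), intensity = c(800, 800))
  ph <- embryo_phantom(c(0, 0, 0), 40, nuc, c(0, 0, -1), 120)
  opt <- optics_model(background_sd = 0, background_mean = 0)
  st <- render_view(ph, opt, c(16, 40, 40), 2, 4, seed = 1)
  flipped <- st$voxels[, rev(seq_len(40)), ]
  expect_equal(st$voxels, flipped, tolerance = 1e-6)
})

test_that("blob widths track the detection tissue path (ray-sphere oracle)", {
  R <- 200
  zpos <- c(-150, 100)                      # detection paths 50 and 300 um
  nuc <- data.frame(x = c(0, 0), y = c(0, 0), z = zpos,
                    radius = 1, intensity = 1000)
  ph <- embryo_phantom(c(0, 0, 0), R, nuc, c(0, 0, -1), 180)
  g <- 0.05
  opt <- optics_model(attenuation_length = Inf, blur_sigma0 = 2,
                      blur_growth = g, surface_aberration = 0,
                      background_mean = 0, background_sd = 0)
  st <- render_view(ph, opt, c(100, 120, 120), 2, 4, seed = 1)

  l_det <- sapply(zpos, function(z)
    oracle_chord(c(0, 0, z), c(0, 0, -1), c(0, 0, 0), R))
  expect_equal(l_det, c(50, 300))
  expected_sigma <- 2 + g * l_det

  fit_sigma <- function(zc) {
    k <- which.min(abs((seq_len(100) - 0.5) * 4 - 200 - zc))
    pl <- st$voxels[k, , ]
    xs <- (seq_len(120) - 0.5) * 2 - 120
    w <- colSums(pl)
    mu <- sum(w * xs) / sum(w)
    sqrt(sum(w * (xs - mu)^2) / sum(w))
  }
  fitted <- sapply(zpos, fit_sigma)
  expect_equal(fitted, expected_sigma, tolerance = 0.1)
  expect_gt(fitted[2], fitted[1])
})

test_that("blob energy follows illumination attenuation monotonically", {
  ## single-sided illumination; energy must be non-increasing in the
  ## illumination chord, and blur must not change total energy
  R <- 80
  xs <- seq(-60, 60, by = 20)
  opt <- optics_model(attenuation_length = 100, blur_growth = 0.05,
                      surface_aberration = 0, background_mean = 0,
                      background_sd = 0, dual_sided_illumination = FALSE)
  energy <- l_illum <- numeric(length(xs))
  for (i in seq_along(xs)) {
    nuc <- data.frame(x = xs[i], y = 0, z = 0, radius = 4, intensity = 1000)
    ph <- embryo_phantom(c(0, 0, 0), R, nuc, c(0, 0, -1), 180)
    st <- render_view(ph, opt, c(50, 100, 100), 2, 4, seed = 1)
    energy[i] <- sum(st$voxels)
    l_illum[i] <- oracle_chord(c(xs[i], 0, 0), c(-1, 0, 0), c(0, 0, 0), R)
  }
  ord <- order(l_illum)
  expect_true(all(diff(energy[ord]) <= energy[ord][1] * 1e-6))
  ## and the attenuation law itself, against the analytic chord
  expect_equal(energy / energy[1], exp(-(l_illum - l_illum[1]) / 100),
               tolerance = 0.01)
})

test_that("dual-sided illumination never underperforms either single side", {
  R <- 80
  for (x in c(-50, -20, 0, 35, 60)) {
    nuc <- data.frame(x = x, y = 10, z = -10, radius = 4, intensity = 1000)
    ph <- embryo_phantom(c(0, 0, 0), R, nuc, c(0, 0, -1), 180)
    peaks <- sapply(c("dual", "minus", "plus"), function(side) {
      opt <- optics_model(attenuation_length = 60, blur_growth = 0,
                          surface_aberration = 0, background_mean = 0,
                          background_sd = 0,
                          dual_sided_illumination = (side == "dual"))
      st <- if (side == "plus") {
        ## mirror the phantom in x to probe the opposite single side
        render_view(rotate_phantom(ph, rotation_axis_angle(c(0, 0, 1), 180)),
                    opt, c(40, 80, 80), 2, 4, seed = 1)
      } else {
        render_view(ph, opt, c(40, 80, 80), 2, 4, seed = 1)
      }
      max(st$voxels)
    })
    expect_gte(peaks["dual"] + 1e-9, peaks["minus"])
  }
})

test_that("empty-phantom stacks carry the stated Gaussian background", {
  ph <- make_phantom(100, 0, 90, seed = 2)
  opt <- optics_model(background_mean = 100, background_sd = 2)
  st <- render_view(ph, opt, c(16, 64, 64), 2, 4, seed = 9)
  v <- as.numeric(st$voxels)
  expect_gte(length(v), 1e4)
  expect_equal(mean(v), 100, tolerance = 0.05)
  expect_equal(sd(v), 2, tolerance = 0.05)
  ## clipping at zero is negligible when mean >= 5 sd
  expect_equal(min(v) > 0, TRUE)
  ks <- suppressWarnings(stats::ks.test(v, "pnorm", 100, 2))
  expect_gt(ks$p.value, 0.001)
})
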