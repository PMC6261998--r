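test_that("max_projection matches forced cases and the loop oracle", {
  one <- array(runif(25), c(1, 5, 5))
  expect_equal(max_projection(one), one[1, , ])

  two <- array(0, c(2, 4, 4)); two[2, , ] <- 5
  expect_equal(max_projection(two), matrix(5, 4, 4))

  set.seed(11)
  v <- array(rnorm(8^3), c(8, 8, 8))
  expect_equal(max_projection(v), oracle_max_projection(v))

  expect_error(max_projection("nope"), class = "orientspim_invalid_input")
})

test_that("background_model reproduces hand-computed corner thresholds", {
  expect_equal(background_model(matrix(7, 300, 300))$threshold, 7)

  ## corners engineered to exact (mean, sd) pairs: half the pixels at
  ## mean + sd, half at mean - sd gives population SD = sd exactly
  mk_corner <- function(mean, sd, n = 100) {
    m <- matrix(mean - sd, n, n)
    m[seq_len(n * n) %% 2 == 0] <- mean + sd
    m
  }
  img <- matrix(10, 300, 300)
  img[1:100, 1:100] <- mk_corner(10, 2)
  img[1:100, 201:300] <- mk_corner(11, 1)
  img[201:300, 1:100] <- mk_corner(9, 3)
  img[201:300, 201:300] <- mk_corner(10, 2.5)
  bm <- background_model(img, 100)
  expect_equal(sort(bm$corner_stats$mean + 3 * bm$corner_stats$sd),
               sort(c(16, 14, 18, 17.5)))
  expect_equal(bm$threshold, 18)
})

test_that("the worst-corner threshold keeps >99.7% of Gaussian noise below it", {
  set.seed(2)
  img <- matrix(rnorm(512 * 512, 100, 5), 512, 512)
  bm <- background_model(img, 100)
  expect_gte(mean(img < bm$threshold), 0.997)
})

test_that("small images shrink or overlap corners with a warning", {
  expect_warning(bm <- background_model(matrix(1, 60, 60), 100),
                 "shrinking")
  expect_identical(bm$corner_size, 30L)
  expect_warning(background_model(matrix(1, 150, 150), 100), "overlap")
})

test_that("foreground_mask is a strict per-pixel comparison", {
  expect_false(any(foreground_mask(matrix(3, 5, 5), 3)))

  m <- matrix(0, 6, 6); m[2, 4] <- 4
  expect_identical(sum(foreground_mask(m, 3)), 1L)

  set.seed(5)
  pl <- matrix(rnorm(100), 10, 10)
  ref <- matrix(FALSE, 10, 10)
  for (i in 1:10) for (j in 1:10) ref[i, j] <- pl[i, j] > 0.2
  expect_identical(foreground_mask(pl, 0.2), ref)
})

test_that("local_entropy matches closed forms and the neighbourhood oracle", {
  expect_true(all(local_entropy(matrix(4.2, 20, 20), 5) == 0))

  ## two-valued checkerboard at an interior pixel: entropy equals the closed
  ## form for the disk's exact two-class pixel counts, enumerated brute-force
  cb <- outer(1:30, 1:30, function(i, j) (i + j) %% 2)
  ent <- local_entropy(cb, 5, levels = 2, range = c(0, 1 + 1e-9))
  offs <- expand.grid(dy = -5:5, dx = -5:5)
  offs <- offs[offs$dy^2 + offs$dx^2 <= 25, ]
  cls <- (15 + offs$dy + 15 + offs$dx) %% 2
  p <- table(cls) / length(cls)              # 44/37 split over the 81-px disk
  expect_equal(ent[15, 15], -sum(p * log2(p)), tolerance = 1e-10)
  expect_equal(unname(-sum(p * log2(p))), 1, tolerance = 0.01)

  ## entropy depends only on histogram counts: monotone relabeling invariance
  set.seed(8)
  q <- matrix(sample(0:7, 14 * 14, replace = TRUE), 14, 14)
  e1 <- local_entropy(q, 3, levels = 8, range = c(0, 8 - 1e-9))
  e2 <- local_entropy(q * 3, 3, levels = 24, range = c(0, 24 - 3e-9))
  expect_equal(e1, e2, tolerance = 1e-12)

  ## brute-force enumeration oracle, borders included
  expect_equal(local_entropy(q, 3, levels = 8, range = c(0, 8 - 1e-9)),
               oracle_local_entropy(q, 3), tolerance = 1e-10)
})

test_that("plane_score is the masked mean with an explicit undefined marker", {
  e <- matrix(runif(36), 6, 6)
  expect_true(is.na(plane_score(e, matrix(FALSE, 6, 6))))

  mask <- matrix(c(TRUE, FALSE), 6, 6)
  expect_equal(plane_score(matrix(2.5, 6, 6), mask), 2.5)

  set.seed(9)
  em <- matrix(runif(400), 20, 20)
  mk <- matrix(sample(c(TRUE, FALSE), 400, replace = TRUE), 20, 20)
  acc <- 0; n <- 0
  for (i in 1:20) for (j in 1:20) if (mk[i, j]) { acc <- acc + em[i, j]; n <- n + 1 }
  expect_equal(plane_score(em, mk), acc / n)

  expect_error(plane_score(em, mk[, 1:10]), class = "orientspim_invalid_input")
})

test_that("otsu_threshold separates a bimodal image and matches the scan oracle", {
  img <- matrix(c(rep(10, 1000), rep(200, 1000)), 40, 50)
  thr <- otsu_threshold(img)
  expect_gt(thr, 10); expect_lt(thr, 200)
  expect_equal(thr, oracle_otsu(img))

  set.seed(12)
  noisy <- matrix(c(rnorm(600, 30, 4), rnorm(400, 150, 12)), 25, 40)
  expect_equal(otsu_threshold(noisy), oracle_otsu(noisy))
})

test_that("boundary_plane finds z = 0 and errors when nothing exceeds Otsu", {
  v <- array(rnorm(4 * 10 * 10, 10, 1), c(4, 10, 10))
  v[v < 0] <- 0
  v[1, 5, 5] <- 100                         # global max in the first plane
  bp <- boundary_plane(image_stack(v, 1, 1))
  expect_identical(bp$z0_index, 1L)

  expect_error(boundary_plane(image_stack(array(3, c(3, 8, 8)), 1, 1)),
               class = "orientspim_boundary_not_found")
})

test_that("boundary_plane locates a rendered sphere's entry plane (ray oracle)", {
  nuc <- data.frame(x = 0, y = 0, z = -60, radius = 5, intensity = 1000)
  ph <- embryo_phantom(c(0, 0, 0), 80, nuc, c(0, 0, -1), 170)
  opt <- optics_model(attenuation_length = Inf, blur_growth = 0,
                      surface_aberration = 0, background_mean = 0,
                      background_sd = 0)
  st <- render_view(ph, opt, c(40, 40, 40), 2, 4, seed = 1)
  bp <- boundary_plane(st)
  ## plane centres (k - 0.5)*4 - 80; the nucleus sits between planes 5 and 6
  k_expect <- (-60 + 80) / 4 + 0.5
  expect_lte(abs(bp$z0_index - k_expect), 1)
})

test_that("quality_profile composes the sub-operations and applies the rules", {
  ## identical planes: all scores equal, z0 = 1
  pl <- matrix(2, 20, 20); pl[8:12, 8:12] <- 150
  v <- array(0, c(5, 20, 20)); for (k in 1:5) v[k, , ] <- pl
  qp <- suppressWarnings(quality_profile(image_stack(v, 1, 1), corner_size = 4))
  expect_identical(qp$z0_index, 1L)
  expect_true(all(abs(qp$plane_scores$score_bits - qp$plane_scores$score_bits[1]) < 1e-12))

  ## planes beyond k fall below the Otsu rule: exactly those are omitted
  v2 <- v
  v2[4:5, , ] <- 2
  qp2 <- suppressWarnings(quality_profile(image_stack(v2, 1, 1), corner_size = 4))
  expect_identical(qp2$plane_scores$omitted, c(FALSE, FALSE, FALSE, TRUE, TRUE))
  expect_true(all(is.na(qp2$plane_scores$score_bits[4:5])))

  ## pipeline equivalence against a manual composition
  st <- tiny_stack(seed = 4)
  qp3 <- quality_profile(st, radius = 3, corner_size = 5)
  proj <- max_projection(st)
  bm <- background_model(proj, 5)
  bp <- boundary_plane(st)
  rng <- range(st$voxels)
  expect_identical(qp3$z0_index, bp$z0_index)
  for (i in seq_len(nrow(qp3$plane_scores))) {
    z <- qp3$plane_scores$z_index[i]
    pl <- st$voxels[z, , ]
    if (qp3$plane_scores$omitted[i]) {
      expect_false(any(pl > bp$otsu_threshold))
    } else {
      manual <- plane_score(local_entropy(pl, 3, range = rng),
                            foreground_mask(pl, bm$threshold))
      expect_equal(qp3$plane_scores$score_bits[i], manual)
    }
  }
})

test_that("scores drop monotonically under increasing blur of textured planes", {
  scores <- sapply(c(0, 2, 8), function(extra) {
    img <- blob_field(sigma = sqrt(4^2 + extra^2), seed = 1)
    plane_score(local_entropy(img, 5, range = range(img)),
                foreground_mask(img, 100 + 3 * 2))
  })
  expect_true(all(diff(scores) < 0))
})

test_that("adding a constant offset shifts thresholds but not scores", {
  st <- tiny_stack(seed = 6)
  stc <- image_stack(st$voxels + 50, st$pixel_size, st$plane_spacing)
  qp1 <- quality_profile(st, corner_size = 5)
  qp2 <- quality_profile(stc, corner_size = 5)
  expect_equal(qp2$background$threshold, qp1$background$threshold + 50)
  expect_equal(qp2$otsu_threshold, qp1$otsu_threshold + 50, tolerance = 1e-9)
  expect_identical(qp1$z0_index, qp2$z0_index)
  expect_equal(qp1$plane_scores$score_bits, qp2$plane_scores$score_bits,
               tolerance = 1e-12)
})

test_that("all scores stay inside [0, log2(levels)]", {
  st <- tiny_stack(seed = 10)
  for (lev in c(16L, 256L)) {
    qp <- quality_profile(st, corner_size = 5, levels = lev)
    s <- qp$plane_scores$score_bits
    s <- s[!is.na(s)]
    expect_true(all(s >= 0 & s <= log2(lev)))
  }
})

test_that("rendered single-view quality degrades with depth (Spearman)", {
  ph <- make_phantom(seed = 2, cap_axis = c(0, 0, -1))
  st <- render_view(ph, optics_model(), c(64, 128, 128), 2, 4, seed = 2)
  qp <- quality_profile(st, corner_size = 16)
  ps <- qp$plane_scores
  ok <- !ps$omitted & !is.na(ps$score_bits) & ps$depth_um <= 100
  expect_gt(sum(ok), 10)
  rho <- cor(ps$depth_um[ok], ps$score_bits[ok], method = "spearman")
  expect_lt(rho, 0)
})
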