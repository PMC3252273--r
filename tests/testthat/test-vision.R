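# Spherical projection, rasterization, down-sampling and view utilities.

test_that("projection maps known points to known sphere coordinates", {
  # a small patch 1 m due north at eye height: azimuth ~0, elevation ~0
  eps <- 1e-6
  tri <- matrix(c(0, 1, 0.01, eps, 1, 0.01, 0, 1, 0.01 + eps), 1, 9)
  sph <- project_to_sphere(tri, pose(0, 0, 0))
  expect_equal(sph[1, 1], 0, tolerance = 1e-4)
  expect_equal(sph[1, 2], 0, tolerance = 1e-4)

  # elevation is atan(h / d): doubling distance halves tan(elevation)
  p <- pose(0, 0, 0, eye_height = 0.01)
  tri_at <- function(d, h) {
    matrix(c(0, d, 0.01 + h, eps, d, 0.01 + h, 0, d, 0.01 + h + eps), 1, 9)
  }
  e1 <- project_to_sphere(tri_at(1, 0.5), p)[1, 2]
  e2 <- project_to_sphere(tri_at(2, 0.5), p)[1, 2]
  expect_equal(e1, atan(0.5) * 180 / pi, tolerance = 1e-3)
  expect_equal(tan(e2 * pi / 180), tan(e1 * pi / 180) / 2, tolerance = 1e-3)

  # point directly overhead: elevation 90, azimuth 0 by the pole convention
  over <- matrix(c(0, 0, 1, eps, 0, 1, 0, eps, 1), 1, 9)
  sph_o <- project_to_sphere(over, pose(0, 0, 137))
  expect_equal(sph_o[1, 2], 90, tolerance = 1e-3)

  # a patch exactly at the eye point is degenerate and skipped with warning
  degen <- rbind(matrix(c(0, 0, 0.01, 1, 1, 0.5, 1, 0, 0.5), 1, 9),
                 tri_at(1, 0.2))
  expect_warning(sph_d <- project_to_sphere(degen, p), "skipped")
  expect_equal(nrow(sph_d), 1L)
})

test_that("rasterizer sets exactly the pixel centres inside a rectangle", {
  # rectangle in spherical coordinates: azimuth [10, 30], elevation [8, 24]
  sph <- rbind(c(10, 8, 30, 8, 30, 24),
               c(10, 8, 30, 24, 10, 24))
  h <- rasterize_view(sph, oversample = 1)    # 4 deg pixels, 17 x 90
  az_c <- -180 + (seq_len(90) - 0.5) * 4
  el_c <- (seq_len(17) - 0.5) * 4
  inside <- outer(el_c, az_c, function(e, a) {
    a >= 10 & a <= 30 & e >= 8 & e <= 24
  })
  expect_identical(h == 1, inside)
})

test_that("empty scenes rasterize to all-sky images", {
  h <- rasterize_view(matrix(numeric(0), 0, 6), oversample = 2)
  expect_true(all(h == 0))
  expect_equal(dim(h), c(34L, 180L))
})

test_that("rendering is rotation-equivariant at column multiples", {
  w <- fx$world
  for (p0 in list(pose(0.4, -1, 10), pose(-1.2, 0.7, 233))) {
    base <- render_view(w, p0, oversample = 4)
    for (delta in c(4, 48, -92, 180)) {
      turned <- render_view(w, pose(p0$x, p0$y, p0$heading + delta,
                                    p0$eye_height), oversample = 4)
      expect_identical(turned, rotate_view(base, delta))
    }
  }
})

test_that("a triangle straddling the seam renders like its rotated twin", {
  p0 <- pose(0, 0, 180)  # looking south: north objects at the +-180 seam
  p1 <- pose(0, 0, 0)
  tri <- matrix(c(-0.5, 2, 0, 0.5, 2, 0, 0, 2, 1.2), 1, 9)
  h0 <- rasterize_view(project_to_sphere(tri, p0), oversample = 4)
  h1 <- rasterize_view(project_to_sphere(tri, p1), oversample = 4)
  expect_gt(sum(h0), 0)
  expect_identical(h0, rotate_view(h1, 180))
})

test_that("block-average down-sampling preserves means and bounds", {
  set.seed(4)
  h <- matrix(as.integer(runif(34 * 180) < 0.3), 34, 180)
  pano <- downsample_view(h)
  expect_equal(dim(pano), c(17L, 90L))
  expect_length(pano, 1530L)
  expect_true(all(pano >= 0 & pano <= 1))
  expect_equal(mean(pano), mean(h))             # global mean preserved
  ones <- matrix(1L, 34, 180)
  expect_true(all(downsample_view(ones) == 1))
  expect_error(downsample_view(matrix(0L, 30, 180)), "multiples")
})

test_that("view rotation is a circular shift with identities", {
  v <- render_view(fx$world, pose(0.3, -0.8, 77), oversample = 4)
  expect_identical(rotate_view(v, 0), v)
  expect_identical(rotate_view(v, 360), v)
  expect_identical(rotate_view(rotate_view(v, 48), -48), v)
  expect_equal(sum(rotate_view(v, 96)), sum(v))
  expect_error(rotate_view(v, 3), "multiple")
})

test_that("sky profile matches direct counting and its edge cases", {
  h <- rasterize_view(matrix(numeric(0), 0, 6), oversample = 4)
  expect_equal(sky_profile(h), rep(1, 90))      # empty world: all sky
  # full-height occluder over azimuth [0, 4): sky 0 in that direction
  occ <- rbind(c(0, 0, 4, 0, 4, 68), c(0, 0, 4, 68, 0, 68))
  ho <- rasterize_view(occ, oversample = 4)
  s <- sky_profile(ho)
  expect_equal(s[46], 0)                        # column centred at +2 deg
  # counting oracle on a real view
  hr <- render_view(fx$world, pose(0.2, -1, 0), oversample = 4,
                    highres = TRUE)$raster
  s2 <- sky_profile(hr, 90)
  manual <- 1 - vapply(seq_len(90), function(d) {
    mean(hr[, ((d - 1) * 4 + 1):(d * 4)])
  }, numeric(1))
  expect_equal(s2, manual)
})

test_that("rendered panoramas respect the type contract", {
  v <- render_view(fx$world, pose(0.5, -0.5, 12.3), oversample = 4)
  expect_equal(dim(v), c(17L, 90L))
  expect_true(all(v >= 0 & v <= 1))
  # pure function: identical inputs give identical output
  expect_identical(v, render_view(fx$world, pose(0.5, -0.5, 12.3),
                                  oversample = 4))
})
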