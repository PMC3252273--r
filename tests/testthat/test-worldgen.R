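# Procedural world construction.

test_that("base tussock is a 26-patch inverted cone inside its bounds", {
  tpl <- tussock_template()
  base <- make_base_tussock(tpl)
  expect_equal(nrow(base), 26L)
  # corner 1 of every patch is the apex, on the ground
  expect_true(all(base[, 1:3] == 0))
  # rim vertices sit at base_height and radius base_radius
  expect_equal(unname(base[, 6]), rep(tpl$base_height, 26))
  expect_equal(sqrt(base[, 4]^2 + base[, 5]^2), rep(tpl$base_radius, 26),
               tolerance = 1e-12)
  # everything inside the bounding cylinder
  r <- sqrt(base[, c(1, 4, 7)]^2 + base[, c(2, 5, 8)]^2)
  expect_true(all(r <= tpl$base_radius + 1e-12))
  # deterministic: no RNG involved
  expect_identical(base, make_base_tussock(tpl))
})

test_that("tussock perturbation respects template invariants", {
  tpl0 <- tussock_template(jitter_fraction = 0, scale_range = c(1, 1))
  set.seed(1)
  expect_equal(make_tussock(tpl0), make_base_tussock(tpl0))

  tpl <- tussock_template()
  set.seed(1)
  t1 <- make_tussock(tpl)
  set.seed(2)
  t2 <- make_tussock(tpl)
  expect_equal(nrow(t1), 26L)
  expect_false(isTRUE(all.equal(t1, t2)))        # different seeds differ
  expect_true(all(t1[, c(3, 6, 9)] >= 0))        # nothing below ground
})

test_that("tussock placement count and uniformity follow the density", {
  region <- c(-10, 10, -10, 10)
  set.seed(1)
  expect_equal(nrow(place_tussocks(region, 0)), 0L)
  pos <- place_tussocks(region, 0.75)
  expect_equal(nrow(pos), 300L)                  # round(0.75 * 400)
  # uniformity: mean of many layouts close to the region centre
  set.seed(42)
  means <- t(replicate(1000, colMeans(place_tussocks(region, 0.05))))
  se <- sqrt((20^2 / 12) / (20 * 1000))          # var of uniform / n draws
  expect_true(all(abs(colMeans(means)) < 3 * se))
})

test_that("corridor rejection retries and eventually errors", {
  region <- c(-10, 10, -10, 10)
  corridor <- list(from = c(0, -8), to = c(0, 0), width = 1, k_min = 5L)
  set.seed(3)
  pos <- place_tussocks(region, 0.75, corridor = corridor)
  d <- antroute:::point_segment_distance(pos, corridor$from, corridor$to)
  expect_gte(sum(d <= 1), 5)
  # unsatisfiable: demands more tussocks than exist
  set.seed(3)
  expect_error(
    place_tussocks(region, 0.01, corridor = list(from = c(0, -8), to = c(0, 0),
                                                 width = 0.5, k_min = 4L),
                   retry_cap = 20L),
    "unsatisfiable")
})

test_that("distant panorama objects sit in the prescribed annulus", {
  set.seed(7)
  pano <- make_distant_panorama(50, c(20, 50), focus = c(0, 0))
  expect_length(pano, 50L)
  cen <- t(vapply(pano, function(m) {
    c(mean(m[, c(1, 4, 7)]), mean(m[, c(2, 5, 8)]))
  }, numeric(2)))
  d <- sqrt(rowSums(cen^2))
  expect_true(all(d >= 20 - 1e-9 & d <= 50 + 1e-9))
  # each object is planar: its in-plane normal is radial (points at focus)
  expect_true(all(vapply(pano, function(m) {
    v <- cbind(c(m[, c(1, 4, 7)]), c(m[, c(2, 5, 8)]), c(m[, c(3, 6, 9)]))
    qr(sweep(v, 2, colMeans(v)))$rank <= 2
  }, logical(1))))
  expect_length(make_distant_panorama(0), 0L)
})

test_that("world assembly is seeded, bookkept and bounded", {
  cfg <- world_config(region_size = 10, density = 0.2, n_panorama = 10,
                      n_landmarks = 2)
  w1 <- build_world(cfg, seed = 5)
  w2 <- build_world(cfg, seed = 5)
  expect_identical(w1$patches, w2$patches)       # bit-identical regeneration
  expect_equal(nrow(w1$patches), sum(w1$object_patch_count))
  expect_equal(w1$nest, c(0, 0))                 # nest at region centre
  # tussock centres inside the central region
  expect_true(all(w1$tussock_centres[, 1] >= -5 & w1$tussock_centres[, 1] <= 5))
  expect_true(all(w1$tussock_centres[, 2] >= -5 & w1$tussock_centres[, 2] <= 5))
  # tussock meshes all have 26 patches; no vertex below ground anywhere
  expect_true(all(w1$object_patch_count[w1$object_kind == "tussock"] == 26L))
  expect_true(all(w1$patches[, c(3, 6, 9)] >= 0))
  expect_error(world_config(density = -1), "density")
  expect_error(world_config(panorama_range = c(5, 50)), "panorama_range")
})

test_that("empty panorama renders a flat horizon", {
  w <- build_world(world_config(density = 0, n_panorama = 0), seed = 1)
  v <- render_view(w, pose(0, 0, 0), oversample = 2)
  expect_true(all(v == 0))
})
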