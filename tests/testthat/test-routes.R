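# Training-route generation, learning walks and training-set assembly.

test_that("movement distribution is the sky-modulated renormalised Gaussian", {
  p <- pose(0, -2, 0)                  # nest due north: home bearing 0
  prm <- route_params(sigma_pi = 15)
  # open sky: discretised Gaussian on the home bearing (independent oracle)
  mv <- movement_distribution(p, c(0, 0), rep(1, 90), prm)
  expect_equal(sum(mv$p), 1)
  g <- exp(-0.5 * (((mv$headings + 180) %% 360 - 180) / 15)^2)
  expect_equal(mv$p, g / sum(g))
  expect_equal(mv$headings[which.max(mv$p)] %% 360,
               mv$headings[which.min(abs(((mv$headings + 180) %% 360) - 180))])

  # fully occluded directions get exactly zero probability
  sky <- rep(1, 90)
  sky[c(3, 40)] <- 0
  mv2 <- movement_distribution(p, c(0, 0), sky, prm)
  expect_equal(mv2$p[c(3, 40)], c(0, 0))
  expect_equal(sum(mv2$p), 1)

  # sky proportion enters at the fourth power
  sky3 <- rep(1, 90)
  sky3[46] <- 0.5                      # the home-bearing column
  mv3 <- movement_distribution(p, c(0, 0), sky3, prm)
  expect_equal(mv3$p[46] / mv3$p[45],
               (g[46] * 0.5^4) / g[45], tolerance = 1e-12)

  # no visible sky anywhere: trapped
  expect_error(movement_distribution(p, c(0, 0), rep(0, 90), prm), "trapped")
})

test_that("training routes step 4 cm, reach the nest, and are seed-exact", {
  set.seed(31)
  r <- generate_training_route(fx$world, c(0, -1.2), oversample = 2)
  steps <- sqrt(diff(r$poses$x)^2 + diff(r$poses$y)^2)
  expect_true(all(abs(steps - 0.04) < 1e-9))
  expect_true(r$complete)
  expect_lt(sqrt(sum(unlist(tail(r$poses[, 1:2], 1))^2)), 0.04)
  expect_equal(length(r$views), nrow(r$poses))
  # same seed reproduces the path bit-exactly
  set.seed(31)
  r2 <- generate_training_route(fx$world, c(0, -1.2), oversample = 2)
  expect_identical(r$poses, r2$poses)
})

test_that("in an open world routes are near-straight and unbiased", {
  open <- build_world(world_config(density = 0, n_panorama = 0), seed = 1)
  set.seed(99)
  lens <- replicate(100, {
    r <- generate_training_route(open, c(0, -1), oversample = 1)
    (nrow(r$poses) - 1) * 0.04
  })
  # path length within 10% of the 1 m straight-line distance on average
  expect_lt(mean(lens), 1.1)
  # heading errors relative to the home bearing are symmetric around zero
  set.seed(7)
  r <- generate_training_route(open, c(0, -1.5), oversample = 1)
  home <- atan2(-r$poses$x, -r$poses$y) * 180 / pi
  err <- ((r$poses$heading - home + 180) %% 360) - 180
  expect_lt(abs(mean(err[-1])), 3 * 15 / sqrt(length(err) - 1))
})

test_that("learning walks loop outbound and return straight at 2 cm spacing", {
  lw <- fx$walk
  steps <- sqrt(diff(lw$poses$x)^2 + diff(lw$poses$y)^2)
  expect_true(all(steps < 0.02 + 1e-9))
  # arc samples are spaced 2 cm along the arc; chords are a hair shorter
  expect_lt(median(abs(steps - 0.02)), 1e-4)
  # first sample starts at the nest, last returns to it
  expect_lt(sqrt(sum(unlist(lw$poses[1, 1:2])^2)), 1e-9)
  expect_lt(sqrt(sum(unlist(tail(lw$poses[, 1:2], 1))^2)), 0.02)

  # outbound curvature ~ step / loop radius; inbound headings point at nest
  walk <- generate_learning_walk(
    build_world(world_config(density = 0, n_panorama = 0), seed = 1),
    params = walk_params(n_loops = 2L), oversample = 1)
  n_arc <- length(seq(0, 270, by = 0.02 / 0.5 * 180 / pi))
  turn <- diff(walk$poses$heading[seq_len(n_arc)])
  turn <- ((turn + 180) %% 360) - 180
  expect_equal(abs(turn), rep(0.02 / 0.5 * 180 / pi, n_arc - 1),
               tolerance = 1e-6)
  # inbound: headings equal the bearing to the nest; the leg runs from the
  # arc exit back to the first return to the nest
  d_nest <- sqrt(walk$poses$x^2 + walk$poses$y^2)
  end1 <- which(d_nest[-1] < 1e-9)[1] + 1L
  inbound <- (n_arc + 1):(end1 - 1L)
  b <- atan2(-walk$poses$x[inbound], -walk$poses$y[inbound]) * 180 / pi
  d_in <- ((walk$poses$heading[inbound] - b + 180) %% 360) - 180
  expect_true(all(abs(d_in) < 1e-6))
})

test_that("training sets concatenate walk and route views in order", {
  expect_identical(assemble_training_set(NULL, fx$route), fx$route$views)
  combined <- assemble_training_set(fx$walk, fx$route)
  nw <- length(fx$walk$views)
  expect_length(combined, nw + length(fx$route$views))
  expect_identical(combined[[nw + 5]], fx$route$views[[5]])
  two <- assemble_training_set(NULL, list(fx$route, fx$route))
  expect_length(two, 2 * length(fx$route$views))
})
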