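# Experiment drivers, fixture determinism and result bookkeeping.

test_that("fixtures are bit-identical under a fixed seed", {
  f1 <- make_fixture(seed = 2)
  expect_identical(f1$world$patches, fx$world$patches)
  expect_identical(f1$route$poses, fx$route$poses)
  expect_identical(f1$views, fx$views)
})

test_that("the fixture route holds one view per 4 cm step plus the start", {
  expect_equal(length(fx$route$views), 1.6 / 0.04 + 1)
  expect_equal(nrow(fx$route$poses), 41L)
  expect_equal(fx$world$config$n_panorama, 12L)
  expect_equal(sum(fx$world$object_kind == "tussock"), 6L)
})

test_that("perfect-memory experiment reports consistent success tables", {
  cfg <- experiment_config(seed = 4, region_size = 8, density = 6 / 64,
                           n_panorama = 12L, route_length = 1.6,
                           heading_noise_sd = 0, n_recaps = 2L,
                           memory = "perfect", scan = "full", oversample = 2L)
  res <- exp_perfect_memory(cfg, n_routes = 2L)
  expect_equal(nrow(res$success), 4L)           # 2 routes x 2 attempts
  expect_length(res$recaps, 4L)
  # recount: the table matches the stored recap results
  expect_equal(res$success$success,
               vapply(res$recaps, function(r) r$success, logical(1)))
  expect_equal(res$success$min_goal_distance,
               vapply(res$recaps, function(r) r$min_goal_distance, numeric(1)))
  expect_true(all(res$success$seed == vapply(res$recaps, function(r) r$seed,
                                             numeric(1))))
  # zero-noise recapitulation of freshly stored routes succeeds
  expect_true(all(res$success$success))
})

test_that("experience experiment trains a fresh network per condition", {
  cfg <- experiment_config(seed = 5, region_size = 8, density = 6 / 64,
                           n_panorama = 12L, route_length = 1.6,
                           n_novelty = 60L, n_recaps = 1L, oversample = 2L,
                           learning_walk = FALSE)
  res <- exp_experience(cfg, conditions = c(1L, 2L))
  expect_equal(res$success$training_runs, c(1L, 2L))
  expect_length(res$networks, 2L)
  # each condition's network saw exactly its own views
  expect_equal(res$networks[[1]]$n_trained < res$networks[[2]]$n_trained, TRUE)
  expect_true(all(res$success$steps >= 0))
})

test_that("multiroute trains one network sequentially and retests", {
  cfg <- experiment_config(seed = 6, region_size = 8, density = 6 / 64,
                           n_panorama = 12L, route_length = 1.6,
                           n_novelty = 60L, n_recaps = 1L, oversample = 2L,
                           learning_walk = FALSE)
  res <- exp_multiroute(cfg, n_routes = 2L, runs_per_route = 1L,
                        include_controls = TRUE)
  ph <- res$success$phase
  expect_equal(ph, c("train1", "train2", "retest1", "control1",
                     "retest2", "control2"))
  # one shared weight matrix encodes all routes
  expect_s3_class(res$network, "infomax_net")
  expect_gt(res$network$n_trained, 0L)
  # controls come from an untrained network and are scored like retests
  expect_equal(sum(ph == "control1") + sum(ph == "control2"), 2L)
})

test_that("experiment results are reproducible from (config, seed)", {
  cfg <- experiment_config(seed = 7, region_size = 8, density = 6 / 64,
                           n_panorama = 12L, route_length = 1.6,
                           heading_noise_sd = 5, n_recaps = 1L,
                           memory = "perfect", oversample = 2L)
  r1 <- exp_perfect_memory(cfg, n_routes = 1L)
  r2 <- exp_perfect_memory(cfg, n_routes = 1L)
  expect_identical(r1$success, r2$success)
  expect_identical(r1$recaps[[1]]$path$poses, r2$recaps[[1]]$path$poses)
})
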