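# Perfect-memory and Infomax route memories.

test_that("perfect familiarity self-matches and undoes rotations", {
  v <- fx$route$views[[10]]
  store <- view_store(fx$route$views[1:12])
  self <- perfect_familiarity(v, store)
  expect_equal(self$familiarity, 0)
  expect_equal(self$best_rotation, 0)
  expect_equal(self$best_index, 10L)
  # a probe rotated by delta is recovered at rotation -delta with SSD 0
  for (delta in c(8, 44, -96)) {
    res <- perfect_familiarity(rotate_view(v, delta), store)
    expect_equal(res$familiarity, 0)
    expect_equal(res$best_rotation, ((-delta + 180) %% 360) - 180)
    expect_equal(res$best_index, 10L)
  }
  expect_error(view_store(list()), "length")
})

test_that("perfect familiarity equals the brute-force triple loop", {
  set.seed(21)
  small <- lapply(1:6, function(i) matrix(runif(5 * 12), 5, 12))
  store <- view_store(small)
  for (k in 1:4) {
    probe <- if (k <= 2) {
      matrix(runif(5 * 12), 5, 12)
    } else {
      rotate_view(small[[k]], 30 * k)   # exact-match probes exercise ties
    }
    got <- perfect_familiarity(probe, store)
    want <- brute_perfect_familiarity(probe, small)
    expect_equal(got$familiarity, want$familiarity, tolerance = 1e-12)
    expect_equal(got$best_rotation, want$best_rotation)
    expect_equal(got$best_index, want$best_index)
  }
})

test_that("network initialisation normalises each unit and is seeded", {
  set.seed(5)
  net <- infomax_init(1530, 40)
  expect_equal(dim(net$W), c(40L, 1530L))
  expect_lt(max(abs(rowMeans(net$W))), 1e-9)
  expect_lt(max(abs(apply(net$W, 1, sd) - 1)), 1e-9)
  expect_equal(net$n_input, 1530L)      # panorama dimensionality
  set.seed(5)
  expect_identical(infomax_init(1530, 40)$W, net$W)
})

test_that("novelty is the summed absolute activation", {
  set.seed(6)
  net <- infomax_init(20, 8, normalize_input = "none")
  x <- runif(20)
  expect_equal(infomax_novelty(net, x), sum(abs(net$W %*% x)))
  expect_gte(infomax_novelty(net, runif(20)), 0)
  net0 <- net
  net0$W[] <- 0
  expect_equal(infomax_novelty(net0, x), 0)
  expect_error(infomax_novelty(net, runif(7)), "length")
})

test_that("the learning step matches the elementwise oracle", {
  set.seed(8)
  for (rep in 1:3) {
    net <- infomax_init(12, 5, eta = 0.01, normalize_input = "none")
    x <- runif(12, -0.5, 0.5)
    got <- infomax_update(net, x)
    want <- brute_infomax_update(net$W, x, 0.01)
    expect_equal(got$W, want, tolerance = 1e-12)
  }
  # eta = 0 leaves the weights untouched
  net <- infomax_init(12, 5, eta = 0)
  expect_identical(infomax_update(net, runif(12))$W, net$W)
})

test_that("repeated presentation of one view makes it less novel", {
  set.seed(12)
  net <- infomax_init(1530, 60)
  x <- fx$views[[7]]
  d <- infomax_novelty(net, x)
  for (i in 1:10) {
    net <- infomax_update(net, x)
    d_new <- infomax_novelty(net, x)
    expect_lt(d_new, d)                 # strict decrease, all 10 updates
    d <- d_new
  }
})

test_that("training is single-pass, composable and constant-size", {
  set.seed(13)
  net <- infomax_init(1530, 30)
  expect_identical(train_route_network(net, list()), net)
  a <- fx$views[1:5]
  b <- fx$views[6:12]
  seq_ab <- train_route_network(train_route_network(net, a), b)
  once <- train_route_network(net, c(a, b))
  expect_identical(seq_ab$W, once$W)
  expect_equal(seq_ab$n_trained, 12L)
  # memory does not grow with route length
  long <- train_route_network(net, fx$views)
  expect_identical(dim(long$W), dim(net$W))
})

test_that("a trained network prefers on-route views over distant ones", {
  hits <- logical(8)
  decorr <- logical(8)
  for (s in seq_along(hits)) {
    f <- make_fixture(seed = 100 + s, oversample = 2)
    net0 <- with(list(), {
      set.seed(s)
      infomax_init(1530, 100)
    })
    net <- train_route_network(net0, f$views)
    d_on <- vapply(f$route$views, function(v) infomax_novelty(net, v),
                   numeric(1))
    set.seed(1000 + s)
    d_off <- replicate(10, {
      repeat {
        q <- runif(2, -4, 4)
        if (min(sqrt((q[1] - f$route$poses$x)^2 +
                     (q[2] - f$route$poses$y)^2)) >= 2) break
      }
      infomax_novelty(net, render_view(f$world,
                                       pose(q[1], q[2], runif(1, 0, 360)),
                                       oversample = 2))
    })
    hits[s] <- mean(d_on) < mean(d_off)
    off_abs <- function(n) {
      cc <- cor(t(infomax_activations(n, f$views)))
      mean(abs(cc[upper.tri(cc)]))
    }
    decorr[s] <- off_abs(net) < off_abs(net0)
  }
  expect_true(all(hits))
  expect_true(all(decorr))
})
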