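# Shared fixtures, built once per test run. All worlds and views are
# generated in code; nothing is read from disk.

# miniature end-to-end scenario (world + straight route + learning walk)
fx <- make_fixture(seed = 2)

# small random panoramas for memory-backend tests (values in [0, 1])
random_panorama <- function() {
  matrix(runif(17 * 90), 17, 90)
}

# brute-force perfect-memory familiarity: triple loop over stored views,
# rotations and pixels (the independent oracle for perfect_familiarity)
brute_perfect_familiarity <- function(current, views) {
  best <- Inf
  best_rot <- NA
  best_idx <- NA
  for (k in 0:(ncol(current) - 1)) {
    delta <- k * 360 / ncol(current)
    rot <- rotate_view(current, delta)
    for (i in seq_along(views)) {
      ssd <- 0
      for (px in seq_along(rot)) {
        ssd <- ssd + (rot[px] - views[[i]][px])^2
      }
      better <- ssd < best - 1e-12
      tie <- abs(ssd - best) <= 1e-12 &&
        (abs(wrap_signed(delta)) < abs(best_rot) ||
           (abs(wrap_signed(delta)) == abs(best_rot) && i < best_idx))
      if (better || tie) {
        best <- ssd
        best_rot <- wrap_signed(delta)
        best_idx <- i
      }
    }
  }
  list(familiarity = -best, best_rotation = best_rot, best_index = best_idx)
}

wrap_signed <- function(x) ((x + 180) %% 360) - 180

# elementwise Infomax update oracle:
#   dw_ij = scale * (w_ij - (y_i + h_i) * sum_k h_k w_kj)
brute_infomax_update <- function(W, x, eta) {
  M <- nrow(W)
  h <- as.numeric(W %*% x)
  y <- tanh(h)
  out <- W
  for (i in seq_len(M)) {
    for (j in seq_len(ncol(W))) {
      s <- 0
      for (k in seq_len(M)) {
        s <- s + h[k] * W[k, j]
      }
      out[i, j] <- W[i, j] + (eta / M) * (W[i, j] - (y[i] + h[i]) * s)
    }
  }
  out
}
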