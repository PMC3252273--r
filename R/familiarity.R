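# Route memories.
#
# Two back-ends score how familiar a panoramic view is:
#   * view_store: perfect memory. Familiarity of a view is minus the
#     minimum sum-squared pixel difference (SSD) against every stored
#     training view; perfect_familiarity() additionally searches all
#     column-shift rotations of the probe (the rotational image difference
#     function).
#   * infomax_net: a two-layer novelty network trained by a single ordered
#     pass over the training views with the natural-gradient Infomax rule.
#     The summed absolute activation of the novelty units is a novelty
#     score d; familiarity is -d, and memory size is fixed at M x N
#     weights no matter how long the route is.

flatten_view <- function(v) {
  if (is.matrix(v)) as.numeric(v) else as.numeric(v)
}

#' Perfect-memory view store
#'
#' Stores training views verbatim, one per 0.04 m step along the training
#' path (so memory load grows with route length, unlike the Infomax
#' network).
#'
#' @param views list of 17 x 90 panorama matrices (or a single matrix).
#' @return an object of class `view_store`.
#' @export
view_store <- function(views) {
  if (is.matrix(views)) {
    views <- list(views)
  }
  stopifnot(length(views) > 0)
  nr <- nrow(views[[1]])
  nc <- ncol(views[[1]])
  V <- t(vapply(views, flatten_view, numeric(nr * nc)))
  structure(list(V = V, nrow = nr, ncol = nc, n = length(views)),
            class = "view_store")
}

#' @export
print.view_store <- function(x, ...) {
  cat(sprintf("<view_store> %d stored views (%d x %d)\n", x$n, x$nrow, x$ncol))
  invisible(x)
}

#' Perfect-memory familiarity of a view (rotational search)
#'
#' Computes minus the minimum sum-squared pixel difference between
#' column-shift rotations of `current` and every stored view, together
#' with the rotation and stored index achieving it. Ties are broken
#' deterministically: smallest rotation magnitude first, then earliest
#' stored index. For a probe equal to a stored view rotated by `delta`,
#' the best rotation is `-delta` with SSD 0 (the visual-compass property).
#'
#' @param current 17 x 90 panorama.
#' @param store a [view_store()].
#' @return list with `familiarity` (-min SSD), `best_rotation` (degrees, in
#'   [-180, 180)) and `best_index` (stored view attaining the minimum).
#' @export
perfect_familiarity <- function(current, store) {
  stopifnot(inherits(store, "view_store"),
            nrow(current) == store$nrow, ncol(current) == store$ncol)
  nc <- store$ncol
  colw <- 360 / nc
  # SSD for all (stored view, rotation) pairs in one crossproduct
  X <- vapply(seq_len(nc) - 1L,
              function(s) flatten_view(rotate_view(current, s * colw)),
              numeric(store$nrow * nc))              # N x nc rotations
  ssd <- outer(rowSums(store$V^2), colSums(X^2), `+`) - 2 * (store$V %*% X)
  ssd[ssd < 0] <- 0                                  # numeric guard
  best <- min(ssd)
  hits <- which(ssd <= best + 1e-12, arr.ind = TRUE)
  deltas <- wrap180((hits[, 2] - 1L) * colw)
  ord <- order(abs(deltas), hits[, 1])
  list(familiarity = -best,
       best_rotation = unname(deltas[ord[1]]),
       best_index = unname(hits[ord[1], 1]))
}

#' Familiarity scores for a batch of candidate views
#'
#' Scores each candidate view as-is (no internal rotation search -- during
#' scanning, the rotations ARE the candidates). For a `view_store` the
#' score is minus the minimum SSD against the stored views; for an
#' `infomax_net` it is minus the novelty response. Higher = more familiar
#' for both back-ends.
#'
#' @param memory a `view_store` or `infomax_net`.
#' @param views_flat matrix with one flattened view (length 1530) per
#'   column.
#' @return numeric vector of familiarity scores, one per column.
#' @export
familiarity_scores <- function(memory, views_flat) {
  UseMethod("familiarity_scores")
}

#' @export
familiarity_scores.view_store <- function(memory, views_flat) {
  ssd <- outer(rowSums(memory$V^2), colSums(views_flat^2), `+`) -
    2 * (memory$V %*% views_flat)
  ssd[ssd < 0] <- 0
  -apply(ssd, 2, min)
}

#' @export
familiarity_scores.infomax_net <- function(memory, views_flat) {
  -colSums(abs(memory$W %*% condition_batch(views_flat, memory)))
}

# vectorised condition_input over the columns of a matrix
condition_batch <- function(X, net) {
  if (nrow(X) != net$n_input) {
    stop("input length ", nrow(X), " does not match network input count ",
         net$n_input)
  }
  if (net$normalize_input == "none") {
    return(X)
  }
  Xc <- X - rep(colMeans(X), each = nrow(X))
  s <- if (net$normalize_input == "norm") {
    sqrt(colSums(Xc^2))
  } else {
    sqrt(colSums(Xc^2) / (nrow(X) - 1))
  }
  s[s < 1e-12] <- 1
  Xc / rep(s, each = nrow(X))
}

# ---- Infomax novelty network ----------------------------------------------

#' Initialise an Infomax novelty network
#'
#' Creates the fully connected feedforward weight matrix W (one row per
#' novelty unit). Weights are drawn uniformly and then affinely normalised
#' per unit so that each unit's incoming weights have mean 0 and standard
#' deviation 1. Uses the caller's RNG stream.
#'
#' @param n_input number of input units; 1530, the panorama pixel count
#'   (90 x 17).
#' @param n_novelty number of novelty units M. Defaults to `n_input`; as
#'   few as 200 work well and are much cheaper.
#' @param eta learning rate (0.01).
#' @param eta_scale scaling of the weight update: `"M"` divides `eta` by
#'   the novelty-unit count (the default natural-gradient convention used
#'   here), `"N"` by the input count, `"none"` applies `eta` unscaled.
#' @param normalize_input input conditioning applied to every view before
#'   presentation or scoring. `"norm"` (default): centre to mean 0 and
#'   scale to unit Euclidean norm. The update shrinks the weight component
#'   along a presented input by a factor of about `eta * ||x||^2`, so unit
#'   norm makes learning scale-free and stable at `eta = 0.01` and keeps
#'   the tanh units out of hard saturation; unit-variance (`"sd"`) or raw
#'   `[0, 1]` (`"none"`) inputs make `eta * ||x||^2 >> 1` at 1530 inputs
#'   and the weights diverge within a few presentations. Conditioning
#'   changes the numeric scale of the novelty score, not the familiarity
#'   ordering behaviour.
#' @param init_range range of the uniform initial weight draw (normalised
#'   away up to the affine rescaling).
#' @return an object of class `infomax_net`.
#' @export
infomax_init <- function(n_input = 1530L, n_novelty = n_input, eta = 0.01,
                         eta_scale = c("M", "N", "none"),
                         normalize_input = c("norm", "sd", "none"),
                         init_range = c(-0.5, 0.5)) {
  stopifnot(n_input >= 1, n_novelty >= 1, eta >= 0)
  eta_scale <- match.arg(eta_scale)
  normalize_input <- match.arg(normalize_input)
  W <- matrix(runif(n_novelty * n_input, init_range[1], init_range[2]),
              as.integer(n_novelty), as.integer(n_input))
  mu <- rowMeans(W)
  sdev <- apply(W, 1, sd)
  W <- (W - mu) / sdev
  structure(list(W = W, n_input = as.integer(n_input),
                 n_novelty = as.integer(n_novelty),
                 eta = eta, eta_scale = eta_scale,
                 normalize_input = normalize_input,
                 n_trained = 0L),
            class = "infomax_net")
}

#' @export
print.infomax_net <- function(x, ...) {
  cat(sprintf(
    "<infomax_net> %d novelty units x %d inputs, eta %g (scale 1/%s), %d views trained\n",
    x$n_novelty, x$n_input, x$eta, x$eta_scale, x$n_trained))
  invisible(x)
}

# flatten + optional per-view standardisation
condition_input <- function(x, net) {
  x <- flatten_view(x)
  if (length(x) != net$n_input) {
    stop("input length ", length(x), " does not match network input count ",
         net$n_input)
  }
  switch(net$normalize_input,
    norm = {
      x <- x - mean(x)
      nrm <- sqrt(sum(x^2))
      if (nrm < 1e-12) x else x / nrm
    },
    sd = {
      s <- sd(x)
      if (s < 1e-12) x - mean(x) else (x - mean(x)) / s
    },
    none = x)
}

#' Novelty response of the network to a view
#'
#' The activation of novelty unit i is \eqn{h_i = \sum_j W_{ij} x_j}; the
#' network response is \eqn{d = \sum_i |h_i|}, low for inputs well
#' described by the learned components (familiar) and high otherwise. No
#' familiarity threshold is ever computed: navigation only needs to rank a
#' scan's candidate views, so raw scores are returned.
#'
#' @param net an [infomax_init()] network.
#' @param view panorama matrix or flattened view vector of length
#'   `net$n_input`.
#' @return non-negative novelty scalar d (familiarity is `-d`).
#' @export
infomax_novelty <- function(net, view) {
  stopifnot(inherits(net, "infomax_net"))
  x <- condition_input(view, net)
  sum(abs(net$W %*% x))
}

#' One Infomax learning step
#'
#' Presents a single view and adjusts the weights by the natural-gradient
#' Infomax rule (gradient ascent on the mutual information between inputs
#' and outputs, which tends to decorrelate the novelty units):
#' \deqn{h = W x, \quad y = \tanh(h),}
#' \deqn{\Delta W = \frac{\eta}{M} \left( W - (y + h) h^\top W \right),}
#' with the `eta_scale` option controlling the 1/M factor. The view is
#' used once and can then be discarded: training is strictly single-pass
#' and memory stays O(M x N) plus one view.
#'
#' @inheritParams infomax_novelty
#' @return the updated network.
#' @export
infomax_update <- function(net, view) {
  stopifnot(inherits(net, "infomax_net"))
  x <- condition_input(view, net)
  scale <- switch(net$eta_scale,
                  M = net$eta / net$n_novelty,
                  N = net$eta / net$n_input,
                  none = net$eta)
  W <- cpp_infomax_step(net$W, x, scale)
  if (!all(is.finite(W))) {
    stop("Infomax weights diverged (non-finite values); ",
         "lower eta or enable input normalisation")
  }
  net$W <- W
  net$n_trained <- net$n_trained + 1L
  net
}

#' Train the network on an ordered view sequence
#'
#' Applies one [infomax_update()] per view, in order, exactly once each.
#' The weight matrix keeps its dimensions regardless of sequence length,
#' and training can be resumed with further sequences (multi-route
#' experiments train one network across several routes).
#'
#' @param net an `infomax_net`.
#' @param views list of panoramas (e.g. from [assemble_training_set()]).
#' @return the trained network.
#' @export
train_route_network <- function(net, views) {
  for (v in views) {
    net <- infomax_update(net, v)
  }
  net
}

#' Novelty-unit activations over a set of views
#'
#' Utility for inspecting the network, e.g. measuring how decorrelated the
#' novelty units are across the training set.
#'
#' @inheritParams train_route_network
#' @return M x length(views) matrix of activations h.
#' @export
infomax_activations <- function(net, views) {
  X <- vapply(views, flatten_view, numeric(net$n_input))
  net$W %*% condition_batch(X, net)
}
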