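# Training-data generation: path-integration-scaffolded homeward routes with
# skyline obstacle avoidance, and nest-centred learning walks.

#' Route generation parameters
#'
#' @param sigma_pi standard deviation (degrees) of the path-integration
#'   Gaussian centred on the home bearing.
#' @param avoid_exponent exponent applied to the per-direction sky
#'   proportion before it modulates the Gaussian (4: strongly biases
#'   movement towards low skyline and forbids fully occluded directions).
#' @param step step length in metres (0.04; a view is collected after every
#'   step).
#' @param terminate_radius distance from the nest (m) at which the homeward
#'   path is complete.
#' @param step_cap_factor the step cap is `step_cap_factor *
#'   (straight-line distance / step)`; exceeding it marks the agent as
#'   trapped.
#' @return an object of class `route_params`.
#' @export
route_params <- function(sigma_pi = 15, avoid_exponent = 4, step = 0.04,
                         terminate_radius = 0.04, step_cap_factor = 10) {
  stopifnot(sigma_pi > 0, avoid_exponent >= 0, step > 0,
            terminate_radius > 0, step_cap_factor > 0)
  structure(list(sigma_pi = sigma_pi, avoid_exponent = avoid_exponent,
                 step = step, terminate_radius = terminate_radius,
                 step_cap_factor = step_cap_factor),
            class = "route_params")
}

#' Learning-walk parameters
#'
#' @param loop_radius radius (m) of the circular outbound section (0.5).
#' @param n_loops number of loops; loops sweep alternately left and right.
#' @param sample_spacing spacing (m) between view samples (0.02; ants walk
#'   slower on learning walks than on routes, hence denser sampling than
#'   the 0.04 m route step).
#' @param arc_degrees arc swept by the outbound circular section before the
#'   straight inbound leg back to the nest.
#' @return an object of class `walk_params`.
#' @export
walk_params <- function(loop_radius = 0.5, n_loops = 3L,
                        sample_spacing = 0.02, arc_degrees = 270) {
  stopifnot(loop_radius > 0, n_loops >= 1, sample_spacing > 0,
            arc_degrees > 0, arc_degrees <= 360)
  structure(list(loop_radius = loop_radius, n_loops = as.integer(n_loops),
                 sample_spacing = sample_spacing, arc_degrees = arc_degrees),
            class = "walk_params")
}

#' Movement distribution: path integration modulated by obstacle avoidance
#'
#' Builds the discrete probability distribution over candidate headings
#' from which the next training step is drawn: a Gaussian centred on the
#' home bearing (the path-integration estimate), multiplied by the
#' proportion of sky visible in each direction raised to
#' `avoid_exponent`, and renormalised. Directions whose visual field is
#' completely filled by objects (sky proportion 0) get probability exactly
#' 0, so movement straight into a wall of vegetation is impossible.
#'
#' @param p current [pose()].
#' @param nest 2-D nest position (m).
#' @param sky per-direction sky proportions from [sky_profile()], computed
#'   on a view rendered at `p`'s heading (directions are egocentric,
#'   ordered like view columns).
#' @param params a [route_params()].
#' @return list with `headings` (absolute candidate headings, degrees) and
#'   `p` (their probabilities, summing to 1).
#' @export
movement_distribution <- function(p, nest, sky, params = route_params()) {
  stopifnot(inherits(p, "ant_pose"), all(sky >= 0), all(sky <= 1))
  home <- bearing_deg(c(p$x, p$y), nest)
  headings <- wrap360(p$heading + pano_col_centres(length(sky)))
  g <- exp(-0.5 * (wrap180(headings - home) / params$sigma_pi)^2)
  w <- g * sky^params$avoid_exponent
  total <- sum(w)
  if (total <= 0) {
    stop("agent trapped: no direction with visible sky has any probability mass")
  }
  list(headings = headings, p = w / total)
}

new_ant_path <- function(poses, views, kind, step_length, view_spacing,
                         complete = TRUE) {
  structure(list(poses = poses, views = views, kind = kind,
                 step_length = step_length, view_spacing = view_spacing,
                 complete = complete),
            class = "ant_path")
}

#' Generate a homeward training route
#'
#' Iteratively walks from `start` towards the nest: at each position a
#' panoramic view is rendered facing the current heading, the sky profile
#' extracted, a heading drawn from [movement_distribution()], and a
#' `params$step` metre step taken in that direction. The view rendered
#' after each step (facing the direction of travel, exactly as experienced
#' -- there is no scanning during learning) is appended to the path. The
#' route ends when the agent comes within `params$terminate_radius` of the
#' nest; if the step cap is exceeded first the agent is considered trapped
#' and the partial path is returned with `complete = FALSE`. Uses the
#' caller's RNG stream.
#'
#' @param world an `ant_world`.
#' @param start 2-D start position (m), inside the central region.
#' @param params a [route_params()].
#' @param oversample raster refinement factor passed to [render_view()].
#' @param eye_height eye height (m).
#' @return an `ant_path` with `kind = "route"`: `poses` (data.frame of
#'   x, y, heading) and `views` (list of panoramas aligned with the poses,
#'   including the view at the start pose).
#' @export
generate_training_route <- function(world, start, params = route_params(),
                                    oversample = 8L, eye_height = 0.01) {
  nest <- world$nest
  d0 <- sqrt(sum((start - nest)^2))
  cap <- ceiling(params$step_cap_factor * d0 / params$step)
  cur <- pose(start[1], start[2], bearing_deg(start, nest), eye_height)
  view <- render_view(world, cur, oversample = oversample)
  xs <- ys <- hs <- numeric(cap + 1)
  views <- vector("list", cap + 1)
  xs[1] <- cur$x; ys[1] <- cur$y; hs[1] <- cur$heading
  views[[1]] <- view
  n <- 1L
  complete <- FALSE
  while (n <= cap) {
    sky <- sky_profile(view)
    mv <- movement_distribution(cur, nest, sky, params)
    theta <- mv$headings[sample.int(length(mv$p), 1L, prob = mv$p)]
    step_v <- params$step * heading_vec(theta)
    cur <- pose(cur$x + step_v[1], cur$y + step_v[2], theta, eye_height)
    view <- render_view(world, cur, oversample = oversample)
    n <- n + 1L
    xs[n] <- cur$x; ys[n] <- cur$y; hs[n] <- cur$heading
    views[[n]] <- view
    if (sqrt((cur$x - nest[1])^2 + (cur$y - nest[2])^2) <
        params$terminate_radius) {
      complete <- TRUE
      break
    }
  }
  poses <- data.frame(x = xs[seq_len(n)], y = ys[seq_len(n)],
                      heading = hs[seq_len(n)])
  new_ant_path(poses, views[seq_len(n)], "route", params$step, params$step,
               complete)
}

#' Generate a nest-centred learning walk
#'
#' Builds the looping excursion a naive forager performs around the nest
#' before foraging: each loop is an outbound circular arc of radius
#' `loop_radius` starting at the nest, followed by a straight inbound
#' segment back to the nest. Consecutive loops sweep in alternating
#' (left/right) directions and their centres are spread around the nest.
#' Views are sampled every `sample_spacing` metres facing the direction of
#' travel, so only the inbound legs supply consistent, nest-directed views
#' -- the feature that later enables visually driven nest search.
#'
#' @param world an `ant_world`.
#' @param nest 2-D nest position; defaults to the world's nest.
#' @param params a [walk_params()].
#' @inheritParams generate_training_route
#' @return an `ant_path` with `kind = "learning_walk"`, ordered
#'   nest-outward (loop 1 outbound, loop 1 inbound, loop 2 outbound, ...).
#' @export
generate_learning_walk <- function(world, nest = world$nest,
                                   params = walk_params(),
                                   oversample = 8L, eye_height = 0.01) {
  R <- params$loop_radius
  sp <- params$sample_spacing
  xs <- ys <- hs <- numeric(0)
  for (i in seq_len(params$n_loops)) {
    dir <- if (i %% 2 == 1) 1 else -1          # alternate sweep side
    phi <- (i - 1) * 360 / params$n_loops      # bearing of loop centre
    centre <- nest + R * heading_vec(phi)
    psi0 <- phi + 180                          # circle angle of the nest
    dpsi <- sp / R * 180 / pi                  # 2 cm of arc, in degrees
    t_arc <- seq(0, params$arc_degrees, by = dpsi)
    psi <- psi0 + dir * t_arc
    px <- centre[1] + R * sin(psi * pi / 180)
    py <- centre[2] + R * cos(psi * pi / 180)
    ph <- wrap360(psi + dir * 90)              # tangent travel direction
    xs <- c(xs, px); ys <- c(ys, py); hs <- c(hs, ph)
    # straight inbound leg back to the nest
    exit <- c(px[length(px)], py[length(py)])
    d_in <- sqrt(sum((nest - exit)^2))
    if (d_in > sp) {
      b <- bearing_deg(exit, nest)
      t_in <- seq(sp, d_in, by = sp)
      if (d_in - t_in[length(t_in)] > sp / 2) {
        t_in <- c(t_in, d_in)     # land back on the nest
      }
      xs <- c(xs, exit[1] + t_in * heading_vec(b)[1])
      ys <- c(ys, exit[2] + t_in * heading_vec(b)[2])
      hs <- c(hs, rep(b, length(t_in)))
    }
  }
  poses <- data.frame(x = xs, y = ys, heading = hs)
  views <- lapply(seq_len(nrow(poses)), function(k) {
    render_view(world, pose(xs[k], ys[k], hs[k], eye_height),
                oversample = oversample)
  })
  new_ant_path(poses, views, "learning_walk", sp, sp)
}

#' Assemble the ordered training-view sequence
#'
#' Concatenates views in the order they are experienced during training:
#' the learning-walk views first (nest-outward order), then each training
#' route's views in experienced order. This is the exact presentation
#' order for single-pass network training.
#'
#' @param walk an `ant_path` of kind `learning_walk`, or `NULL` for
#'   route-only training.
#' @param routes a single `ant_path` or a list of them, in training order.
#' @return list of 17 x 90 panorama matrices.
#' @export
assemble_training_set <- function(walk = NULL, routes = list()) {
  if (inherits(routes, "ant_path")) {
    routes <- list(routes)
  }
  views <- list()
  if (!is.null(walk)) {
    stopifnot(inherits(walk, "ant_path"))
    views <- walk$views
  }
  for (r in routes) {
    stopifnot(inherits(r, "ant_path"))
    views <- c(views, r$views)
  }
  views
}

#' @export
print.ant_path <- function(x, ...) {
  len <- (nrow(x$poses) - 1) * x$step_length
  cat(sprintf("<ant_path> kind %s: %d poses (~%.2f m), %d views%s\n",
              x$kind, nrow(x$poses), len,
              length(x$views),
              if (isTRUE(x$complete)) "" else " [incomplete]"))
  invisible(x)
}
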