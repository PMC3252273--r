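# The behavioural routine: scan, pick the most familiar direction, step.
#
# The navigator's only state is the current pose; it reads no compass and
# no path-integration variable during recapitulation -- position enters
# solely through the world renderer.

#' Scanning policy
#'
#' @param mode `"full"`: candidate headings cover the whole 360 degrees
#'   (used with the perfect-memory system and for familiarity maps);
#'   `"frontal"`: candidates span `width` degrees centred on the previous
#'   direction of travel (the more realistic scan used with the Infomax
#'   system; turns sharper than `width / 2` become impossible to follow).
#' @param width scan width in degrees (frontal mode; 90 by default).
#' @param step angular spacing of candidates in degrees. The default 4 is
#'   one panorama column, so every candidate view is an exact column shift
#'   of a single rendered view.
#' @return an object of class `scan_policy`.
#' @export
scan_policy <- function(mode = c("full", "frontal"), width = NULL, step = 4) {
  mode <- match.arg(mode)
  if (is.null(width)) {
    width <- if (mode == "full") 360 else 90
  }
  stopifnot(step > 0, width > 0, width <= 360)
  offsets <- if (mode == "full") {
    if (abs(360 / step - round(360 / step)) > 1e-9) {
      stop("step must divide 360 for a full scan")
    }
    wrap180(seq(0, 360 - step, by = step))
  } else {
    # candidates at multiples of `step` within +- width/2 of the previous
    # heading (frontal 90 deg at 4 deg steps: 23 candidates, +-44 deg)
    k <- floor((width / 2) / step)
    seq(-k, k) * step
  }
  structure(list(mode = mode, width = width, step = step, offsets = offsets),
            class = "scan_policy")
}

#' Motor parameters
#'
#' @param step_length recapitulation step length (m; 0.10).
#' @param heading_noise_sd standard deviation (degrees) of the Gaussian
#'   noise added to the chosen heading at each step.
#' @param goal_radius distance (m) from the nest counted as arrival.
#' @param max_steps step cap; `NULL` means 5 x (start distance /
#'   step_length), decided at the start of a recapitulation.
#' @return an object of class `motor_params`.
#' @export
motor_params <- function(step_length = 0.10, heading_noise_sd = 10,
                         goal_radius = 0.20, max_steps = NULL) {
  stopifnot(step_length > 0, heading_noise_sd >= 0, goal_radius > 0)
  structure(list(step_length = step_length,
                 heading_noise_sd = heading_noise_sd,
                 goal_radius = goal_radius, max_steps = max_steps),
            class = "motor_params")
}

# cache of flattened column-shift index matrices, keyed by view shape and
# offset list: building every candidate view is then one vector indexing
.scan_idx_cache <- new.env(parent = emptyenv())

scan_shift_index <- function(nr, nc, offsets) {
  key <- paste(nr, nc, paste(offsets, collapse = ","), sep = "|")
  idx <- .scan_idx_cache[[key]]
  if (is.null(idx)) {
    colw <- 360 / nc
    shifts <- offsets / colw
    if (any(abs(shifts - round(shifts)) > 1e-9)) {
      stop("scan step must be a multiple of the view column width (",
           colw, " deg) for shift-derived candidate views")
    }
    idx <- vapply(as.integer(round(shifts)), function(s) {
      cols <- (seq_len(nc) - 1L + s) %% nc
      as.integer(rep(cols * nr, each = nr) + rep(seq_len(nr), nc))
    }, integer(nr * nc))
    .scan_idx_cache[[key]] <- idx
  }
  idx
}

# score all scan candidates from one rendered view; returns the chosen
# offset (deterministic tie-break: smallest |turn|, then clockwise)
choose_scan_offset <- function(view, memory, policy) {
  idx <- scan_shift_index(nrow(view), ncol(view), policy$offsets)
  X <- matrix(view[idx], nrow = length(view))
  scores <- familiarity_scores(memory, X)
  best <- max(scores)
  cand <- which(scores >= best - 1e-12)
  cand <- cand[order(abs(policy$offsets[cand]), -sign(policy$offsets[cand]))]
  list(offset = policy$offsets[cand[1]], score = best, scores = scores)
}

#' One scan-and-step of the navigating agent
#'
#' Renders the panorama at the current pose, derives the candidate views
#' for every scan direction by exact column shifts, scores each with the
#' memory back-end, turns to the most familiar direction (ties: smallest
#' absolute turn, then clockwise), adds Gaussian heading noise, and
#' advances `step_length` metres. Placed exactly on a stored training pose
#' with a perfect memory and zero noise, the chosen heading is the stored
#' training heading. Uses the caller's RNG stream for the noise.
#'
#' @param world an `ant_world`.
#' @param p current [pose()].
#' @param memory a `view_store` or trained `infomax_net`.
#' @param policy a [scan_policy()].
#' @param motor a [motor_params()].
#' @param oversample raster refinement factor for rendering.
#' @return list with `pose` (the new pose), `chosen_heading` (before
#'   noise), `offset` (turn relative to the previous heading) and `score`
#'   (familiarity of the chosen direction).
#' @export
scan_step <- function(world, p, memory, policy = scan_policy("full"),
                      motor = motor_params(), oversample = 8L) {
  view <- render_view(world, p, oversample = oversample)
  ch <- choose_scan_offset(view, memory, policy)
  chosen <- wrap360(p$heading + ch$offset)
  noisy <- wrap360(chosen + rnorm(1, 0, motor$heading_noise_sd))
  v <- motor$step_length * heading_vec(noisy)
  list(pose = pose(p$x + v[1], p$y + v[2], noisy, p$eye_height),
       chosen_heading = chosen, offset = ch$offset, score = ch$score)
}

#' Recapitulate a route by scanning for familiar views
#'
#' Repeats [scan_step()] from `start` until the agent comes within
#' `goal_radius` of the nest (success) or the step cap is reached
#' (failure). With `blocked_nest = TRUE` the run does not stop on arrival
#' -- the analogue of blocking the nest entrance in a behavioural
#' experiment -- and continues for `post_steps` further steps, recording
#' the distance to the nest after each; with learning-walk views in
#' memory the agent is pulled into loops and searches near the nest, while
#' without them it overshoots and walks away roughly linearly.
#'
#' @inheritParams scan_step
#' @param start 2-D start position (m).
#' @param nest 2-D goal position; defaults to the world's nest.
#' @param start_heading initial heading (degrees). Defaults to the bearing
#'   from start to nest (the agent is released facing roughly homeward).
#' @param seed optional seed for the heading noise, recorded in the
#'   result.
#' @param blocked_nest continue past the goal (see above).
#' @param post_steps number of post-arrival steps in blocked-nest mode.
#' @param eye_height eye height (m).
#' @return an object of class `recap_result`: `path` (an `ant_path` of
#'   kind `"recapitulation"`, poses only), `success`, `steps_taken`,
#'   `min_goal_distance`, `seed`, and in blocked-nest mode `arrival_step`
#'   and `post_distances`.
#' @export
recapitulate <- function(world, memory, start, nest = world$nest,
                         policy = scan_policy("full"),
                         motor = motor_params(), start_heading = NULL,
                         seed = NULL, blocked_nest = FALSE, post_steps = 100L,
                         oversample = 8L, eye_height = 0.01) {
  if (!is.null(seed)) {
    set.seed(seed)
  }
  d0 <- sqrt(sum((start - nest)^2))
  max_steps <- motor$max_steps %||% ceiling(5 * d0 / motor$step_length)
  if (blocked_nest) {
    max_steps <- max_steps + post_steps + 1L   # room for the search phase
  }
  cur <- pose(start[1], start[2],
              start_heading %||% bearing_deg(start, nest), eye_height)
  xs <- ys <- hs <- numeric(max_steps + 1)
  xs[1] <- cur$x; ys[1] <- cur$y; hs[1] <- cur$heading
  n <- 1L
  min_d <- d0
  success <- d0 <= motor$goal_radius
  arrival <- if (success) 0L else NA_integer_
  post <- numeric(0)
  while (n <= max_steps) {
    st <- scan_step(world, cur, memory, policy, motor, oversample)
    cur <- st$pose
    n <- n + 1L
    xs[n] <- cur$x; ys[n] <- cur$y; hs[n] <- cur$heading
    d <- sqrt((cur$x - nest[1])^2 + (cur$y - nest[2])^2)
    min_d <- min(min_d, d)
    if (is.na(arrival) && d <= motor$goal_radius) {
      success <- TRUE
      arrival <- n - 1L
      if (!blocked_nest) {
        break
      }
    }
    if (blocked_nest && !is.na(arrival)) {
      post <- c(post, d)
      if (length(post) > post_steps) {
        break
      }
    }
  }
  path <- new_ant_path(data.frame(x = xs[seq_len(n)], y = ys[seq_len(n)],
                                  heading = hs[seq_len(n)]),
                       views = NULL, kind = "recapitulation",
                       step_length = motor$step_length,
                       view_spacing = NA_real_, complete = success)
  structure(list(path = path, success = success, steps_taken = n - 1L,
                 min_goal_distance = min_d, seed = seed,
                 arrival_step = arrival,
                 post_distances = if (blocked_nest) post else NULL),
            class = "recap_result")
}

#' @export
print.recap_result <- function(x, ...) {
  cat(sprintf(
    "<recap_result> %s after %d steps (min goal distance %.3f m)\n",
    if (x$success) "reached goal" else "failed", x$steps_taken,
    x$min_goal_distance))
  invisible(x)
}

#' Familiarity and best-heading map over a grid
#'
#' At every point of a regular grid the navigator performs a full 360
#' degree scan (there is no current heading at an arbitrary grid point)
#' and records the best familiarity score and the heading that attains it
#' -- the data behind pseudocolour-plus-quiver route maps. On grid cells
#' lying exactly on stored training poses the best score for a perfect
#' memory is 0 (an exact match) and the best heading is the local training
#' direction.
#'
#' @inheritParams recapitulate
#' @param xlim,ylim map extent (m).
#' @param n number of grid points per axis (length-1 or length-2).
#' @param step scan step in degrees.
#' @return an object of class `familiarity_map`: list with `x`, `y` (grid
#'   coordinates), `familiarity` and `heading` (length(x) x length(y)
#'   matrices).
#' @export
familiarity_map <- function(world, memory, xlim, ylim, n = 21L, step = 4,
                            oversample = 8L, eye_height = 0.01) {
  n <- rep(as.integer(n), length.out = 2)
  gx <- seq(xlim[1], xlim[2], length.out = n[1])
  gy <- seq(ylim[1], ylim[2], length.out = n[2])
  pol <- scan_policy("full", step = step)
  fam <- hea <- matrix(NA_real_, n[1], n[2])
  for (j in seq_along(gy)) {
    for (i in seq_along(gx)) {
      p <- pose(gx[i], gy[j], 0, eye_height)
      view <- render_view(world, p, oversample = oversample)
      ch <- choose_scan_offset(view, memory, pol)
      fam[i, j] <- ch$score
      hea[i, j] <- wrap360(ch$offset)
    }
  }
  structure(list(x = gx, y = gy, familiarity = fam, heading = hea),
            class = "familiarity_map")
}
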