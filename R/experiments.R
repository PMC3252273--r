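# Scripted experiments: reproducible end-to-end studies combining world
# generation, training, memory and navigation. Every random draw is
# traceable to the config seed through named sub-streams, so a result is
# reproducible bit-exactly from (config, seed).

#' Experiment configuration
#'
#' One flat configuration object shared by the experiment drivers; each
#' driver uses the fields relevant to it and ignores the rest.
#'
#' @param seed master seed; all world, route, network and noise seeds are
#'   derived from it.
#' @param region_size,density,n_panorama,panorama_range,n_landmarks world
#'   parameters, see [world_config()].
#' @param route_length training-route length: straight-line start-to-nest
#'   distance (m).
#' @param route_step training step / view spacing (m). 0.04 by default;
#'   0.01 reproduces the denser storage variant.
#' @param sigma_pi path-integration Gaussian sd (degrees).
#' @param learning_walk include a learning walk at the start of training.
#' @param n_walk_loops learning-walk loop count.
#' @param memory `"perfect"` or `"infomax"`.
#' @param n_novelty novelty-unit count M for the Infomax memory.
#' @param eta Infomax learning rate.
#' @param scan `"full"` or `"frontal"` scanning during recapitulation.
#' @param scan_width frontal scan width (degrees).
#' @param heading_noise_sd recapitulation heading noise sd (degrees).
#' @param step_length recapitulation step length (m).
#' @param goal_radius arrival radius (m).
#' @param n_recaps recapitulation attempts per condition.
#' @param oversample raster refinement factor used for every rendered view.
#' @param eye_height eye height (m).
#' @return an object of class `experiment_config`.
#' @export
experiment_config <- function(seed = 1L,
                              region_size = 20, density = 0.75,
                              n_panorama = 50L, panorama_range = c(20, 50),
                              n_landmarks = 0L,
                              route_length = 12, route_step = 0.04,
                              sigma_pi = 15,
                              learning_walk = TRUE, n_walk_loops = 3L,
                              memory = c("infomax", "perfect"),
                              n_novelty = 1530L, eta = 0.01,
                              scan = c("frontal", "full"), scan_width = 90,
                              heading_noise_sd = 10, step_length = 0.10,
                              goal_radius = 0.20,
                              n_recaps = 4L,
                              oversample = 8L, eye_height = 0.01) {
  structure(list(seed = as.integer(seed), region_size = region_size,
                 density = density, n_panorama = as.integer(n_panorama),
                 panorama_range = panorama_range,
                 n_landmarks = as.integer(n_landmarks),
                 route_length = route_length, route_step = route_step,
                 sigma_pi = sigma_pi,
                 learning_walk = isTRUE(learning_walk),
                 n_walk_loops = as.integer(n_walk_loops),
                 memory = match.arg(memory),
                 n_novelty = as.integer(n_novelty), eta = eta,
                 scan = match.arg(scan), scan_width = scan_width,
                 heading_noise_sd = heading_noise_sd,
                 step_length = step_length, goal_radius = goal_radius,
                 n_recaps = as.integer(n_recaps),
                 oversample = as.integer(oversample),
                 eye_height = eye_height),
            class = "experiment_config")
}

# start position `length` metres from the nest at the given bearing
route_start <- function(config, bearing) {
  config$route_length * heading_vec(bearing)
}

exp_world <- function(config, start = NULL, world_seed = NULL) {
  corridor <- NULL
  if (!is.null(start) && config$density > 0) {
    # reject layouts leaving the training corridor nearly empty; only ask
    # for what the density can plausibly supply in small test worlds
    expected <- config$density * 2 * sqrt(sum(start^2))
    k_min <- min(5L, floor(expected / 2))
    if (k_min >= 1L) {
      corridor <- list(from = start, to = c(0, 0), width = 1, k_min = k_min)
    }
  }
  build_world(world_config(region_size = config$region_size,
                           density = config$density,
                           n_panorama = config$n_panorama,
                           panorama_range = config$panorama_range,
                           n_landmarks = config$n_landmarks,
                           corridor = corridor),
              seed = world_seed %||% sub_seed(config$seed, 1L))
}

exp_route <- function(config, world, start, k) {
  with_seed(sub_seed(config$seed, 100L + k), {
    generate_training_route(
      world, start,
      route_params(sigma_pi = config$sigma_pi, step = config$route_step),
      oversample = config$oversample, eye_height = config$eye_height)
  })
}

exp_walk <- function(config, world) {
  if (!config$learning_walk) {
    return(NULL)
  }
  generate_learning_walk(world,
                         params = walk_params(n_loops = config$n_walk_loops),
                         oversample = config$oversample,
                         eye_height = config$eye_height)
}

exp_policy <- function(config) {
  scan_policy(if (config$scan == "full") "full" else "frontal",
              width = if (config$scan == "full") 360 else config$scan_width)
}

exp_motor <- function(config) {
  motor_params(step_length = config$step_length,
               heading_noise_sd = config$heading_noise_sd,
               goal_radius = config$goal_radius)
}

exp_recap <- function(config, world, memory, start, seed_k, heading = NULL) {
  recapitulate(world, memory, start,
               policy = exp_policy(config), motor = exp_motor(config),
               start_heading = heading,
               seed = sub_seed(config$seed, 500L + seed_k),
               oversample = config$oversample,
               eye_height = config$eye_height)
}

new_experiment_result <- function(kind, config, training_paths, recaps,
                                  success, extra = list()) {
  structure(c(list(kind = kind, config = config,
                   training_paths = training_paths, recaps = recaps,
                   success = success), extra),
            class = "experiment_result")
}

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf("<experiment_result> %s: %d/%d recapitulations successful\n",
              x$kind, sum(x$success$success), nrow(x$success)))
  invisible(x)
}

#' Perfect-memory route recapitulation experiment
#'
#' Learns three separate routes to the nest in a world mixing small
#' tussocks and large landmarks, storing every training view, and runs
#' `n_recaps` noisy full-scan recapitulations per route.
#'
#' @param config an [experiment_config()]; `memory` is forced to
#'   `"perfect"`, `scan` to `"full"`, and `n_landmarks` defaults to 3 if
#'   unset. The default of 3 recapitulations per route gives the classic
#'   nine-path layout.
#' @param n_routes number of separate routes (3).
#' @return an `experiment_result` with one `view_store` per route and a
#'   per-recap success table.
#' @export
exp_perfect_memory <- function(config = experiment_config(memory = "perfect",
                                                          scan = "full",
                                                          n_recaps = 3L),
                               n_routes = 3L) {
  config$memory <- "perfect"
  config$scan <- "full"
  if (config$n_landmarks == 0L) {
    config$n_landmarks <- 3L
  }
  bearings <- wrap360(180 + seq(-40, 40, length.out = n_routes))
  starts <- lapply(bearings, route_start, config = config)
  world <- exp_world(config, start = starts[[1]])
  routes <- list()
  recaps <- list()
  rows <- list()
  for (r in seq_len(n_routes)) {
    routes[[r]] <- exp_route(config, world, starts[[r]], k = r)
    store <- view_store(routes[[r]]$views)
    for (a in seq_len(config$n_recaps)) {
      k <- (r - 1L) * config$n_recaps + a
      rec <- exp_recap(config, world, store, starts[[r]], seed_k = k,
                       heading = routes[[r]]$poses$heading[1])
      recaps[[k]] <- rec
      rows[[k]] <- data.frame(route = r, attempt = a, success = rec$success,
                              steps = rec$steps_taken,
                              min_goal_distance = rec$min_goal_distance,
                              seed = rec$seed)
    }
  }
  new_experiment_result("perfect_memory", config, routes, recaps,
                        do.call(rbind, rows))
}

#' Experience-curve experiment
#'
#' Trains one fresh Infomax network per condition on 1, 2, 4 and 8
#' independently sampled training routes of the same start (views
#' concatenated in experienced order, learning-walk views first), then
#' runs `n_recaps` noisy frontal-scan recapitulations per condition.
#' Success counts typically improve with the number of training runs as
#' the network sees a broader sample of the route corridor.
#'
#' @param config an [experiment_config()].
#' @param conditions training-run counts to compare.
#' @return an `experiment_result`; `success` has one row per (condition,
#'   attempt).
#' @export
exp_experience <- function(config = experiment_config(),
                           conditions = c(1L, 2L, 4L, 8L)) {
  start <- route_start(config, 180 + 45)
  world <- exp_world(config, start = start)
  walk <- exp_walk(config, world)
  recaps <- list()
  rows <- list()
  nets <- list()
  k_route <- 0L
  for (ci in seq_along(conditions)) {
    n_runs <- conditions[ci]
    routes <- lapply(seq_len(n_runs), function(j) {
      exp_route(config, world, start, k = k_route + j)
    })
    k_route <- k_route + n_runs
    views <- assemble_training_set(walk, routes)
    net <- with_seed(sub_seed(config$seed, 300L + ci), {
      infomax_init(n_input = 1530L, n_novelty = config$n_novelty,
                   eta = config$eta)
    })
    net <- train_route_network(net, views)
    nets[[ci]] <- net
    for (a in seq_len(config$n_recaps)) {
      k <- (ci - 1L) * config$n_recaps + a
      rec <- exp_recap(config, world, net, start, seed_k = k)
      recaps[[k]] <- rec
      rows[[k]] <- data.frame(training_runs = n_runs, attempt = a,
                              success = rec$success, steps = rec$steps_taken,
                              min_goal_distance = rec$min_goal_distance,
                              seed = rec$seed)
    }
  }
  new_experiment_result("experience", config, NULL, recaps,
                        do.call(rbind, rows), extra = list(networks = nets))
}

#' Multiple-route retention experiment
#'
#' Sequentially trains a single Infomax network on three routes to the
#' same nest (several training runs per route), testing each route
#' immediately after its training phase, and finally retesting routes 1
#' and 2 after all training to measure retention. The route memories are
#' not held separately: one weight matrix encodes all three.
#'
#' @param config an [experiment_config()]; `route_length` defaults here to
#'   10 m.
#' @param n_routes number of routes (3).
#' @param runs_per_route training runs per route phase.
#' @param include_controls also retest routes 1 and 2 with an untrained
#'   (freshly initialised) network, as a chance-level control.
#' @return an `experiment_result`; `success` has columns `phase`
#'   (`"train1"`..., `"retest1"`, `"retest2"`, optionally `"control1"`,
#'   `"control2"`), `route`, `attempt`, `success`.
#' @export
exp_multiroute <- function(config = experiment_config(route_length = 10),
                           n_routes = 3L, runs_per_route = 4L,
                           include_controls = FALSE) {
  bearings <- wrap360(180 + seq(-60, 60, length.out = n_routes))
  starts <- lapply(bearings, route_start, config = config)
  world <- exp_world(config, start = starts[[1]])
  walk <- exp_walk(config, world)
  net <- with_seed(sub_seed(config$seed, 300L), {
    infomax_init(n_input = 1530L, n_novelty = config$n_novelty,
                 eta = config$eta)
  })
  control <- if (include_controls) {
    with_seed(sub_seed(config$seed, 301L), {
      infomax_init(n_input = 1530L, n_novelty = config$n_novelty,
                   eta = config$eta)
    })
  }
  recaps <- list()
  rows <- list()
  add_recaps <- function(phase, route_i, memory, seed_base) {
    for (a in seq_len(config$n_recaps)) {
      rec <- exp_recap(config, world, memory, starts[[route_i]],
                       seed_k = seed_base + a)
      recaps[[length(recaps) + 1L]] <<- rec
      rows[[length(rows) + 1L]] <<-
        data.frame(phase = phase, route = route_i, attempt = a,
                   success = rec$success, steps = rec$steps_taken,
                   min_goal_distance = rec$min_goal_distance, seed = rec$seed)
    }
  }
  for (r in seq_len(n_routes)) {
    routes <- lapply(seq_len(runs_per_route), function(j) {
      exp_route(config, world, starts[[r]], k = (r - 1L) * runs_per_route + j)
    })
    views <- assemble_training_set(if (r == 1L) walk else NULL, routes)
    net <- train_route_network(net, views)
    add_recaps(paste0("train", r), r, net, seed_base = r * 20L)
  }
  for (r in seq_len(min(2L, n_routes))) {
    add_recaps(paste0("retest", r), r, net, seed_base = 100L + r * 20L)
    if (include_controls) {
      add_recaps(paste0("control", r), r, control, seed_base = 200L + r * 20L)
    }
  }
  new_experiment_result("multiroute", config, NULL, recaps,
                        do.call(rbind, rows), extra = list(network = net))
}

#' Deterministic test fixture
#'
#' Builds a miniature scenario that exercises the whole pipeline in
#' seconds: a small world (6 tussocks over an 8 x 8 m region, 12 distant
#' panorama objects), a straight 1.6 m training route sampled every 4 cm
#' (so the route holds exactly `1.6 / 0.04 + 1` views), and a one-loop
#' learning walk. Identical seeds give bit-identical fixtures.
#'
#' @param seed integer seed.
#' @param oversample raster refinement factor for the fixture views.
#' @param learning_walk also build the learning walk (default `TRUE`).
#' @return list with `world`, `route`, `walk` and `views` (the assembled
#'   walk-then-route training sequence).
#' @export
make_fixture <- function(seed = 1L, oversample = 4L, learning_walk = TRUE) {
  world <- build_world(world_config(region_size = 8, density = 6 / 64,
                                    n_panorama = 12L,
                                    corridor = list(from = c(0, -1.6),
                                                    to = c(0, 0),
                                                    width = 1.5, k_min = 2L)),
                       seed = seed)
  ys <- seq(-1.6, 0, by = 0.04)
  poses <- data.frame(x = 0, y = ys, heading = 0)
  views <- lapply(ys, function(y) {
    render_view(world, pose(0, y, 0), oversample = oversample)
  })
  route <- new_ant_path(poses, views, "route", 0.04, 0.04)
  walk <- if (learning_walk) {
    generate_learning_walk(world, params = walk_params(n_loops = 1L),
                           oversample = oversample)
  }
  list(world = world, route = route, walk = walk,
       views = assemble_training_set(walk, route))
}
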