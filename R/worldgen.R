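# World generation: procedural tussock grassland with a distant panorama.
#
# Meshes are numeric matrices with 9 columns (x1,y1,z1,x2,y2,z2,x3,y3,z3),
# one flat triangular patch per row, in metres. World axes: x east, y north,
# z up; the ground plane is z = 0.

#' Tussock construction template
#'
#' Parameters for building grass-tussock meshes. A tussock starts from a
#' deterministic base model: an inverted cone of `base_patch_count`
#' triangular patches whose apex touches the ground and whose rim sits at
#' `base_height`. Individual tussocks are produced by randomly perturbing
#' and rescaling this base model.
#'
#' @param base_patch_count number of triangular patches in the base model
#'   (26, the fixed size of the base tussock).
#' @param base_radius rim radius of the unscaled base cone (m).
#' @param base_height rim height of the unscaled base cone (m).
#' @param jitter_fraction per-vertex perturbation magnitude, as a fraction
#'   of `base_radius` per coordinate.
#' @param scale_range range of the uniform draw used to rescale each
#'   tussock. With the defaults the rim radius spans roughly 0.15-0.6 m and
#'   the height 0.125-0.5 m, desert-grass scale.
#' @return an object of class `tussock_template`.
#' @export
#' @examples
#' tpl <- tussock_template()
#' nrow(make_base_tussock(tpl))  # 26 patches
tussock_template <- function(base_patch_count = 26L,
                             base_radius = 0.3,
                             base_height = 0.25,
                             jitter_fraction = 0.1,
                             scale_range = c(0.5, 2)) {
  stopifnot(base_patch_count >= 3L,
            base_radius > 0, base_height > 0,
            jitter_fraction >= 0,
            length(scale_range) == 2L,
            all(scale_range > 0),
            scale_range[1] <= scale_range[2])
  structure(list(base_patch_count = as.integer(base_patch_count),
                 base_radius = base_radius,
                 base_height = base_height,
                 jitter_fraction = jitter_fraction,
                 scale_range = scale_range),
            class = "tussock_template")
}

#' Build the deterministic base tussock mesh
#'
#' The base model is an inverted cone: the apex vertex sits on the ground
#' plane at the origin and a rim of `base_patch_count` vertices sits at
#' height `base_height` and radius `base_radius`. Each patch connects the
#' apex to two neighbouring rim vertices, giving exactly
#' `base_patch_count` triangular patches.
#'
#' @param template a [tussock_template()].
#' @return mesh matrix (one patch per row, 9 columns).
#' @export
make_base_tussock <- function(template = tussock_template()) {
  stopifnot(inherits(template, "tussock_template"))
  k <- template$base_patch_count
  phi <- (seq_len(k) - 1) * 2 * pi / k
  rim <- cbind(template$base_radius * sin(phi),
               template$base_radius * cos(phi),
               rep(template$base_height, k))
  nxt <- c(seq_len(k)[-1], 1L)
  cbind(0, 0, 0, rim, rim[nxt, , drop = FALSE])
}

#' Build a randomly perturbed, rescaled tussock
#'
#' Each unique vertex of the base model (shared vertices move together, so
#' the mesh stays connected) is displaced by a uniform perturbation of at
#' most `jitter_fraction * base_radius` per coordinate, and the whole mesh
#' is rescaled by a single uniform draw from `scale_range`. Vertices are
#' clamped to the ground plane so nothing dips below z = 0. Uses the
#' caller's RNG stream.
#'
#' @inheritParams make_base_tussock
#' @return mesh matrix with the same number of patches as the base model.
#' @export
make_tussock <- function(template = tussock_template()) {
  base <- make_base_tussock(template)
  k <- template$base_patch_count
  j <- template$jitter_fraction * template$base_radius
  # unique vertices: apex + k rim points; rim vertex i appears as corner 2 of
  # patch i and corner 3 of patch (i-1)
  d_apex <- runif(3, -j, j)
  d_rim <- matrix(runif(3 * k, -j, j), k, 3)
  s <- runif(1, template$scale_range[1], template$scale_range[2])
  prv <- c(k, seq_len(k)[-k])
  out <- base
  out[, 1:3] <- out[, 1:3] + rep(d_apex, each = k)
  out[, 4:6] <- out[, 4:6] + d_rim
  out[, 7:9] <- out[, 7:9] + d_rim[c(seq_len(k)[-1], 1L), , drop = FALSE]
  out <- out * s
  out[, c(3, 6, 9)] <- pmax(out[, c(3, 6, 9)], 0)
  out
}

#' Sample tussock positions uniformly over a region
#'
#' Places `round(density * area)` tussocks i.i.d. uniformly over the
#' rectangle. When a `corridor` is supplied, whole layouts are rejected and
#' resampled until at least `corridor$k_min` tussocks fall within
#' `corridor$width` metres of the straight segment from `corridor$from` to
#' `corridor$to`; this reproduces the convention of discarding environments
#' whose training-path surroundings are nearly empty.
#'
#' @param region rectangle bounds `c(xmin, xmax, ymin, ymax)` (m).
#' @param density tussocks per square metre.
#' @param corridor optional list with fields `from`, `to` (2-D points),
#'   `width` (m, default 1) and `k_min` (default 5).
#' @param retry_cap maximum number of layout resamples before the corridor
#'   constraint is declared unsatisfiable.
#' @return matrix of 2-D positions (one row per tussock; 0 rows when
#'   `density` is 0).
#' @export
place_tussocks <- function(region, density, corridor = NULL, retry_cap = 100L) {
  stopifnot(length(region) == 4L, region[1] < region[2], region[3] < region[4],
            density >= 0)
  area <- (region[2] - region[1]) * (region[4] - region[3])
  n <- round(density * area)
  if (n == 0) {
    return(matrix(numeric(0), 0, 2))
  }
  draw <- function() {
    cbind(runif(n, region[1], region[2]), runif(n, region[3], region[4]))
  }
  if (is.null(corridor)) {
    return(draw())
  }
  width <- corridor$width %||% 1
  k_min <- corridor$k_min %||% 5L
  for (i in seq_len(retry_cap)) {
    pos <- draw()
    d <- point_segment_distance(pos, corridor$from, corridor$to)
    if (sum(d <= width) >= k_min) {
      return(pos)
    }
  }
  stop("corridor constraint unsatisfiable: fewer than ", k_min,
       " tussocks within ", width, " m of the segment after ", retry_cap,
       " layouts")
}

# distance of each row of `p` (n x 2) from segment a-b
point_segment_distance <- function(p, a, b) {
  ab <- b - a
  len2 <- sum(ab^2)
  if (len2 == 0) {
    return(sqrt((p[, 1] - a[1])^2 + (p[, 2] - a[2])^2))
  }
  t <- ((p[, 1] - a[1]) * ab[1] + (p[, 2] - a[2]) * ab[2]) / len2
  t <- pmin(1, pmax(0, t))
  sqrt((p[, 1] - (a[1] + t * ab[1]))^2 + (p[, 2] - (a[2] + t * ab[2]))^2)
}

# ---- distant panorama ------------------------------------------------------

# Four parameterized trunk silhouettes in the local (x, z) plane, centred on
# x = 0. Aesthetic templates: a tapered stem plus one or two branch quads.
trunk_template <- function(k) {
  stem <- function(w0, w1, h) {
    rbind(c(-w0 / 2, 0, w0 / 2, 0, w1 / 2, h),
          c(-w0 / 2, 0, w1 / 2, h, -w1 / 2, h))
  }
  branch <- function(x0, z0, x1, z1, w) {
    # thin quad from (x0,z0) to (x1,z1)
    n <- c(-(z1 - z0), x1 - x0)
    n <- 0.5 * w * n / sqrt(sum(n^2))
    rbind(c(x0 - n[1], z0 - n[2], x0 + n[1], z0 + n[2], x1 + n[1], z1 + n[2]),
          c(x0 - n[1], z0 - n[2], x1 + n[1], z1 + n[2], x1 - n[1], z1 - n[2]))
  }
  m <- switch(k,
    rbind(stem(0.5, 0.25, 3.2), branch(0, 1.8, 1.1, 2.8, 0.15)),
    rbind(stem(0.7, 0.3, 4.2), branch(0, 2.2, -1.3, 3.4, 0.18),
          branch(0, 2.8, 1.2, 3.9, 0.15)),
    rbind(stem(0.4, 0.2, 2.6), branch(0, 1.4, -0.9, 2.3, 0.12)),
    rbind(stem(0.8, 0.35, 5.0), branch(0, 2.6, 1.5, 4.1, 0.2),
          branch(0, 3.4, -1.4, 4.6, 0.18))
  )
  # interleave into (x1,z1,x2,z2,x3,z3) rows
  m
}

# Fixed leaf-patch base template: many small triangles scattered in an
# ellipse around (0, 0) of the local plane; a random subset is kept per
# object. Deterministic by construction (private seed, caller RNG untouched).
leaf_template <- function(n = 80) {
  with_seed(987123L, {
    th <- runif(n, 0, 2 * pi)
    r <- sqrt(runif(n))
    cx <- r * cos(th)
    cz <- r * sin(th) * 0.6
    sz <- runif(n, 0.12, 0.35)
    a1 <- runif(n, 0, 2 * pi)
    a2 <- a1 + runif(n, 1.5, 2.8)
    a3 <- a2 + runif(n, 1.5, 2.8)
    cbind(cx + sz * cos(a1), cz + sz * sin(a1),
          cx + sz * cos(a2), cz + sz * sin(a2),
          cx + sz * cos(a3), cz + sz * sin(a3))
  })
}

# one flat tree or bush silhouette in local (x, z) coordinates
make_flat_object <- function(kind = c("tree", "bush")) {
  kind <- match.arg(kind)
  leaves <- leaf_template()
  keep <- which(runif(nrow(leaves)) < runif(1, 0.4, 0.8))
  lv <- leaves[keep, , drop = FALSE]
  if (kind == "tree") {
    trunk <- trunk_template(sample.int(4, 1))
    if (runif(1) < 0.5) {          # random flip
      trunk[, c(1, 3, 5)] <- -trunk[, c(1, 3, 5)]
    }
    s <- runif(1, 0.7, 1.4)        # random rescale
    trunk <- trunk * s
    h <- max(trunk[, c(2, 4, 6)])
    canopy_w <- runif(1, 1.6, 2.6) * s
    lv[, c(1, 3, 5)] <- lv[, c(1, 3, 5)] * canopy_w
    lv[, c(2, 4, 6)] <- lv[, c(2, 4, 6)] * canopy_w * 0.7 + h
    m <- rbind(trunk, lv)
  } else {
    w <- runif(1, 1.2, 2.4)
    lv[, c(1, 3, 5)] <- lv[, c(1, 3, 5)] * w
    lv[, c(2, 4, 6)] <- lv[, c(2, 4, 6)] * w * 0.5 + w * 0.35
    m <- lv
  }
  m[, c(2, 4, 6)] <- pmax(m[, c(2, 4, 6)], 0)
  m[, c(1, 3, 5)] <- m[, c(1, 3, 5)] - mean(m[, c(1, 3, 5)])  # centre on x = 0
  m
}

#' Generate the distant panorama of trees and bushes
#'
#' Creates `n` flat silhouette objects (trees with randomly flipped and
#' rescaled trunks, bushes as random subsets of a leaf-patch template), each
#' placed at a uniformly random distance in `dist_range` and uniformly
#' random azimuth about `focus`, and rotated so that its plane normal points
#' at `focus` (maximally visible from the central region). Objects this far
#' away barely change over route-scale movement, providing a stable visual
#' frame of reference. Uses the caller's RNG stream.
#'
#' @param n number of objects.
#' @param dist_range distance range in metres, minimum at least 20 m so the
#'   panorama never enters the central region.
#' @param focus 2-D point the panorama surrounds (usually the nest).
#' @return list of mesh matrices, one per object.
#' @export
make_distant_panorama <- function(n = 50L, dist_range = c(20, 50),
                                  focus = c(0, 0)) {
  stopifnot(n >= 0, length(dist_range) == 2L, dist_range[1] >= 20,
            dist_range[1] <= dist_range[2])
  n <- as.integer(n)
  if (n == 0L) {
    return(list())
  }
  lapply(seq_len(n), function(i) {
    kind <- if (runif(1) < 0.5) "tree" else "bush"
    flat <- make_flat_object(kind)
    d <- runif(1, dist_range[1], dist_range[2])
    a <- runif(1, 0, 360) * pi / 180
    pos <- focus + d * c(sin(a), cos(a))
    tang <- c(cos(a), -sin(a))  # in-plane direction; normal points at focus
    out <- matrix(0, nrow(flat), 9)
    for (v in 0:2) {
      x_loc <- flat[, 2 * v + 1]
      z_loc <- flat[, 2 * v + 2]
      out[, 3 * v + 1] <- pos[1] + x_loc * tang[1]
      out[, 3 * v + 2] <- pos[2] + x_loc * tang[2]
      out[, 3 * v + 3] <- z_loc
    }
    out
  })
}

#' World configuration
#'
#' @param region_size side length (m) of the square central region, centred
#'   on the nest, inside which tussocks are placed.
#' @param density tussock density (per square metre).
#' @param n_panorama number of distant panorama objects.
#' @param panorama_range panorama distance range (m), minimum 20 m.
#' @param n_landmarks number of large in-region 3-D landmarks (scaled-up
#'   tussock cones, tree-sized), as used in the mixed small/large worlds.
#' @param tussock tussock template, see [tussock_template()].
#' @param corridor optional corridor constraint passed to
#'   [place_tussocks()]: a list with `from`, `to` and optionally `width`,
#'   `k_min`.
#' @return an object of class `world_config`.
#' @export
world_config <- function(region_size = 20,
                         density = 0.75,
                         n_panorama = 50L,
                         panorama_range = c(20, 50),
                         n_landmarks = 0L,
                         tussock = tussock_template(),
                         corridor = NULL) {
  bad <- character(0)
  if (!is.numeric(region_size) || length(region_size) != 1 || region_size <= 0)
    bad <- c(bad, "region_size")
  if (!is.numeric(density) || length(density) != 1 || density < 0)
    bad <- c(bad, "density")
  if (!is.numeric(n_panorama) || length(n_panorama) != 1 || n_panorama < 0)
    bad <- c(bad, "n_panorama")
  if (!is.numeric(panorama_range) || length(panorama_range) != 2 ||
      panorama_range[1] < 20 || panorama_range[1] > panorama_range[2])
    bad <- c(bad, "panorama_range")
  if (!is.numeric(n_landmarks) || length(n_landmarks) != 1 || n_landmarks < 0)
    bad <- c(bad, "n_landmarks")
  if (!inherits(tussock, "tussock_template"))
    bad <- c(bad, "tussock")
  if (length(bad)) {
    stop("invalid world_config field(s): ", paste(bad, collapse = ", "))
  }
  structure(list(region_size = region_size, density = density,
                 n_panorama = as.integer(n_panorama),
                 panorama_range = panorama_range,
                 n_landmarks = as.integer(n_landmarks),
                 tussock = tussock, corridor = corridor),
            class = "world_config")
}

#' Build a complete simulated world
#'
#' Composes a seeded world: tussocks scattered uniformly over the central
#' region (optionally subject to the corridor rejection rule), a distant
#' panorama of trees and bushes, and optionally a few large 3-D landmarks.
#' The nest sits at the origin, the centre of the region. Rebuilding with
#' the same `(config, seed)` reproduces the patch list bit-identically.
#'
#' @param config a [world_config()].
#' @param seed integer seed controlling every random draw in the build.
#' @return an object of class `ant_world`: a list with elements `patches`
#'   (all patches, one mesh matrix), `patch_object` (integer object id per
#'   patch), `object_kind` (`"tussock"`, `"panorama"` or `"landmark"` per
#'   object), `tussock_centres`, `nest`, `region` (xmin, xmax, ymin, ymax),
#'   `config` and `seed`.
#' @export
#' @examples
#' w <- build_world(world_config(region_size = 6, density = 0.2,
#'                               n_panorama = 5), seed = 1)
#' w
build_world <- function(config = world_config(), seed = 1L) {
  stopifnot(inherits(config, "world_config"))
  half <- config$region_size / 2
  region <- c(-half, half, -half, half)
  with_seed(seed, {
    centres <- place_tussocks(region, config$density, config$corridor)
    meshes <- list()
    kinds <- character(0)
    if (nrow(centres) > 0) {
      for (i in seq_len(nrow(centres))) {
        m <- make_tussock(config$tussock)
        m[, c(1, 4, 7)] <- m[, c(1, 4, 7)] + centres[i, 1]
        m[, c(2, 5, 8)] <- m[, c(2, 5, 8)] + centres[i, 2]
        meshes[[length(meshes) + 1L]] <- m
        kinds <- c(kinds, "tussock")
      }
    }
    if (config$n_landmarks > 0) {
      # tree-sized cones inside the region, kept off the region centre
      for (i in seq_len(config$n_landmarks)) {
        m <- make_tussock(config$tussock) * runif(1, 6, 10)
        ang <- runif(1, 0, 2 * pi)
        r <- runif(1, 0.35, 0.85) * half
        m[, c(1, 4, 7)] <- m[, c(1, 4, 7)] + r * sin(ang)
        m[, c(2, 5, 8)] <- m[, c(2, 5, 8)] + r * cos(ang)
        meshes[[length(meshes) + 1L]] <- m
        kinds <- c(kinds, "landmark")
      }
    }
    pano <- make_distant_panorama(config$n_panorama, config$panorama_range,
                                  focus = c(0, 0))
    meshes <- c(meshes, pano)
    kinds <- c(kinds, rep("panorama", length(pano)))
    counts <- vapply(meshes, nrow, integer(1))
    patches <- do.call(rbind, meshes)
    if (is.null(patches)) {
      patches <- matrix(numeric(0), 0, 9)
    }
    structure(list(patches = patches,
                   patch_object = rep(seq_along(meshes), counts),
                   object_kind = kinds,
                   object_patch_count = counts,
                   tussock_centres = centres,
                   nest = c(0, 0),
                   region = region,
                   config = config,
                   seed = as.integer(seed)),
              class = "ant_world")
  })
}

#' @export
print.ant_world <- function(x, ...) {
  cat("<ant_world>\n")
  cat(sprintf("  region: %g x %g m, nest at (%g, %g), seed %d\n",
              diff(x$region[1:2]), diff(x$region[3:4]),
              x$nest[1], x$nest[2], x$seed))
  tab <- table(factor(x$object_kind,
                      levels = c("tussock", "landmark", "panorama")))
  cat(sprintf("  objects: %d tussocks, %d landmarks, %d panorama\n",
              tab[["tussock"]], tab[["landmark"]], tab[["panorama"]]))
  cat(sprintf("  patches: %d\n", nrow(x$patches)))
  invisible(x)
}
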