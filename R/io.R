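# Plain-text interchange: worlds as Wavefront OBJ (+ JSON metadata
# sidecar), paths and familiarity maps as delimited text.

#' Export a world as OBJ plus a metadata sidecar
#'
#' Writes the patch mesh as a standard Wavefront OBJ (each patch a
#' triangular face) and a JSON sidecar `<file>.meta.json` recording nest,
#' region, seed and per-object bookkeeping, so the world can be re-imported
#' or inspected in any mesh viewer.
#'
#' @param world an `ant_world`.
#' @param file output OBJ path.
#' @return `file`, invisibly.
#' @export
write_world_obj <- function(world, file) {
  stopifnot(inherits(world, "ant_world"))
  p <- world$patches
  n <- nrow(p)
  verts <- rbind(p[, 1:3, drop = FALSE], p[, 4:6, drop = FALSE],
                 p[, 7:9, drop = FALSE])
  # vertex order: the three corners of patch i are rows i, n+i, 2n+i
  vl <- sprintf("v %.9g %.9g %.9g", verts[, 1], verts[, 2], verts[, 3])
  fl <- sprintf("f %d %d %d", seq_len(n), n + seq_len(n), 2L * n + seq_len(n))
  writeLines(c("# antroute world", vl, fl), file)
  meta <- list(nest = world$nest, region = world$region, seed = world$seed,
               object_kind = world$object_kind,
               object_patch_count = world$object_patch_count,
               region_size = world$config$region_size,
               density = world$config$density,
               n_panorama = world$config$n_panorama,
               panorama_range = world$config$panorama_range,
               n_landmarks = world$config$n_landmarks)
  jsonlite::write_json(meta, paste0(file, ".meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' Import a world written by [write_world_obj()]
#'
#' @param file OBJ path (the `<file>.meta.json` sidecar must sit next to
#'   it).
#' @return an `ant_world`.
#' @export
read_world_obj <- function(file) {
  lines <- readLines(file)
  vl <- lines[startsWith(lines, "v ")]
  fl <- lines[startsWith(lines, "f ")]
  verts <- matrix(as.numeric(unlist(strsplit(sub("^v ", "", vl), " "))),
                  ncol = 3, byrow = TRUE)
  faces <- matrix(as.integer(unlist(strsplit(sub("^f ", "", fl), " "))),
                  ncol = 3, byrow = TRUE)
  patches <- cbind(verts[faces[, 1], , drop = FALSE],
                   verts[faces[, 2], , drop = FALSE],
                   verts[faces[, 3], , drop = FALSE])
  meta <- jsonlite::read_json(paste0(file, ".meta.json"), simplifyVector = TRUE)
  counts <- as.integer(meta$object_patch_count)
  structure(list(patches = patches,
                 patch_object = rep(seq_along(counts), counts),
                 object_kind = meta$object_kind,
                 object_patch_count = counts,
                 tussock_centres = NULL,
                 nest = as.numeric(meta$nest),
                 region = as.numeric(meta$region),
                 config = world_config(region_size = meta$region_size,
                                       density = meta$density,
                                       n_panorama = meta$n_panorama,
                                       panorama_range =
                                         as.numeric(meta$panorama_range),
                                       n_landmarks = meta$n_landmarks),
                 seed = as.integer(meta$seed)),
            class = "ant_world")
}

#' Write a path as delimited text
#'
#' Columns: `step` (0-based), `x`, `y`, `heading_deg`.
#'
#' @param path an `ant_path` or `recap_result`.
#' @param file output path (tab-separated).
#' @return `file`, invisibly.
#' @export
write_path_tsv <- function(path, file) {
  if (inherits(path, "recap_result")) {
    path <- path$path
  }
  stopifnot(inherits(path, "ant_path"))
  df <- data.frame(step = seq_len(nrow(path$poses)) - 1L,
                   x = path$poses$x, y = path$poses$y,
                   heading_deg = path$poses$heading)
  write.table(df, file, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Read a path written by [write_path_tsv()]
#'
#' @param file input path.
#' @param kind path kind to record.
#' @return an `ant_path` (poses only).
#' @export
read_path_tsv <- function(file, kind = "route") {
  df <- read.table(file, header = TRUE, sep = "\t")
  step_length <- if (nrow(df) > 1) {
    sqrt(diff(df$x[1:2])^2 + diff(df$y[1:2])^2)
  } else {
    NA_real_
  }
  new_ant_path(data.frame(x = df$x, y = df$y, heading = df$heading_deg),
               views = NULL, kind = kind, step_length = step_length,
               view_spacing = NA_real_)
}

#' Write a path's views as delimited text
#'
#' One archive per path: each row is one flattened 17 x 90 panorama (1530
#' columns, column-major), in pose order. Readable back with
#' [read_views_tsv()] or by any array tool.
#'
#' @param path an `ant_path` whose `views` are populated.
#' @param file output path (tab-separated, no header).
#' @return `file`, invisibly.
#' @export
write_views_tsv <- function(path, file) {
  stopifnot(inherits(path, "ant_path"), length(path$views) > 0)
  m <- t(vapply(path$views, as.numeric, numeric(length(path$views[[1]]))))
  write.table(m, file, sep = "\t", row.names = FALSE, col.names = FALSE)
  invisible(file)
}

#' Read a view archive written by [write_views_tsv()]
#'
#' @param file input path.
#' @return list of 17 x 90 panorama matrices.
#' @export
read_views_tsv <- function(file) {
  m <- as.matrix(read.table(file, header = FALSE, sep = "\t"))
  lapply(seq_len(nrow(m)), function(i) matrix(m[i, ], 17, 90))
}

#' Write a familiarity map as delimited text
#'
#' Long format: one row per grid cell with `x`, `y`, `familiarity`,
#' `heading_deg`.
#'
#' @param map a `familiarity_map`.
#' @param file output path (tab-separated).
#' @return `file`, invisibly.
#' @export
write_familiarity_map <- function(map, file) {
  stopifnot(inherits(map, "familiarity_map"))
  grid <- expand.grid(xi = seq_along(map$x), yi = seq_along(map$y))
  df <- data.frame(x = map$x[grid$xi], y = map$y[grid$yi],
                   familiarity = map$familiarity[cbind(grid$xi, grid$yi)],
                   heading_deg = map$heading[cbind(grid$xi, grid$yi)])
  write.table(df, file, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(file)
}
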