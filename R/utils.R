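# Internal helpers shared across modules.

#' Wrap angles to [-180, 180)
#' @param x angles in degrees.
#' @return angles wrapped to the half-open interval [-180, 180).
#' @keywords internal
#' @noRd
wrap180 <- function(x) {
  ((x + 180) %% 360) - 180
}

#' Wrap angles to [0, 360)
#' @keywords internal
#' @noRd
wrap360 <- function(x) {
  x %% 360
}

#' Bearing (degrees clockwise from north) from point a to point b
#' @keywords internal
#' @noRd
bearing_deg <- function(a, b) {
  wrap360(atan2(b[1] - a[1], b[2] - a[2]) * 180 / pi)
}

#' Unit step vector for a heading in degrees clockwise from north
#' @keywords internal
#' @noRd
heading_vec <- function(heading_deg) {
  th <- heading_deg * pi / 180
  c(sin(th), cos(th))
}

#' Evaluate code under a temporary RNG seed, restoring the caller's stream
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

#' Derive a reproducible sub-seed from a base seed and a stream label
#'
#' Keeps derived seeds inside the 32-bit integer range so they remain valid
#' arguments to [set.seed()].
#' @keywords internal
#' @noRd
sub_seed <- function(seed, k) {
  as.integer((as.double(seed) * 7919 + as.double(k) * 104729) %% 2147483629) + 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a
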