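#' One simulation snapshot
#'
#' Positions are stored wrapped into [0, L) with integer periodic-image
#' counters, so the unwrapped position of particle i is
#' \code{pos[i, ] + image[i, ] * L}.
#'
#' @param pos N x 2 matrix of positions (sigma); wrapped into [0, L).
#' @param phi length-N orientation angles (radians); wrapped to (-pi, pi].
#' @param L box side length (sigma).
#' @param image N x 2 integer matrix of periodic-image counters.
#' @param t time stamp (tau_R).
#' @return An object of class \code{particle_state}.
#' @export
particle_state <- function(pos, phi, L, image = NULL, t = 0) {
  pos <- as.matrix(pos)
  if (ncol(pos) != 2) stop("pos must be an N x 2 matrix")
  N <- nrow(pos)
  if (length(phi) != N) stop("phi must have one angle per particle")
  if (is.null(image)) image <- matrix(0L, N, 2)
  storage.mode(image) <- "integer"
  if (!all(dim(image) == c(N, 2))) stop("image must be N x 2")
  if (any(pos < 0 | pos >= L)) {
    w <- floor(pos / L)
    image <- image + matrix(as.integer(w), N, 2)
    pos <- pos - w * L
  }
  phi <- wrap_angle(phi)
  structure(list(pos = pos, phi = phi, image = image, L = L, t = t),
            class = "particle_state")
}

#' @export
print.particle_state <- function(x, ...) {
  cat(sprintf("particle_state: N = %d, L = %.4g sigma, t = %g tau_R\n",
              nrow(x$pos), x$L, x$t))
  invisible(x)
}

# wrap angles to (-pi, pi]
wrap_angle <- function(a) {
  a <- a - 2 * pi * floor((a + pi) / (2 * pi))
  a[a <= -pi] <- a[a <= -pi] + 2 * pi
  a
}

#' Unit orientation vectors of a state
#'
#' @param phi orientation angles (radians).
#' @return length(phi) x 2 matrix of unit vectors (cos phi, sin phi).
#' @export
orientation_vectors <- function(phi) {
  cbind(cos(phi), sin(phi))
}

#' Unwrapped positions of a state
#'
#' @param state a \code{particle_state}.
#' @return N x 2 matrix \code{pos + image * L}.
#' @export
unwrapped_positions <- function(state) {
  state$pos + state$image * state$L
}

# minimum-image displacement(s): rows of d mapped into [-L/2, L/2)
min_image_disp <- function(d, L) {
  d - L * floor(d / L + 0.5)
}
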