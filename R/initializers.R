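#' Initial conditions
#'
#' Four initial-condition families used to probe multistability: random
#' orientations on a box-spanning triangular lattice, a hexagonally packed
#' cluster with inward ("aster") or random orientations, and an elongated
#' worm formation. All constructions keep pairwise distances >= 0.9 sigma and
#' positions inside [0, L)^2.
#'
#' @param kind one of \code{"lattice_random"}, \code{"hex_cluster_inward"},
#'   \code{"hex_cluster_random"}, \code{"worm"}.
#' @param params a \code{sim_params}.
#' @param ... forwarded to the specific initializer.
#' @return a \code{particle_state}.
#' @export
make_initial_state <- function(kind, params, ...) {
  switch(kind,
    lattice_random     = init_lattice_random(params, ...),
    hex_cluster_inward = init_hex_cluster(params, inward = TRUE, ...),
    hex_cluster_random = init_hex_cluster(params, inward = FALSE, ...),
    worm               = init_worm(params, ...),
    stop("unknown initializer: ", kind)
  )
}

#' Random orientations on a box-spanning triangular lattice
#'
#' @param params a \code{sim_params}.
#' @param seed optional seed; if NULL the current RNG stream is used.
#' @return a \code{particle_state} with N lattice sites spanning [0, L)^2 and
#'   orientations drawn uniformly from (-pi, pi].
#' @export
init_lattice_random <- function(params, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  N <- params$N; L <- params$L
  # triangular aspect: row spacing ~ sqrt(3)/2 * column spacing
  nx <- max(1L, ceiling(sqrt(N * 2 / sqrt(3))))
  ny <- ceiling(N / nx)
  ax <- L / nx
  ay <- L / ny
  if (min(ax / 2, ay) < 0.9 * params$sigma)
    stop("lattice too dense: sites closer than 0.9 sigma")
  iy <- rep(seq_len(ny) - 1L, each = nx)[seq_len(N)]
  ix <- rep(seq_len(nx) - 1L, times = ny)[seq_len(N)]
  pos <- cbind((ix + 0.5 * (iy %% 2) + 0.25) * ax, (iy + 0.5) * ay) %% L
  phi <- runif(N, -pi, pi)
  particle_state(pos, phi, L)
}

# hexagonal close-packed sites at given spacing, the N sites nearest the
# origin (deterministic tie-break on (distance, angle))
hex_sites <- function(N, spacing) {
  m <- ceiling(sqrt(N)) + 2L
  ij <- expand.grid(i = -m:m, j = -m:m)
  x <- spacing * (ij$i + ij$j / 2)
  y <- spacing * ij$j * sqrt(3) / 2
  d <- sqrt(x^2 + y^2)
  o <- order(round(d, 9), round(atan2(y, x), 9))
  cbind(x[o], y[o])[seq_len(N), , drop = FALSE]
}

#' Hexagonally packed cluster, inward-oriented (aster) or random
#'
#' Particles occupy a hexagonally close-packed disk with nearest-neighbor
#' spacing r_c (contact at the WCA potential minimum, so no initial force
#' spikes), centered in the box. With \code{inward = TRUE} each orientation
#' points from the particle toward the cluster center (aster initialization);
#' the central particle, whose direction is undefined, gets a random angle.
#'
#' @param params a \code{sim_params}.
#' @param inward logical; point all orientations at the cluster center.
#' @param seed optional seed; if NULL the current RNG stream is used.
#' @return a \code{particle_state}.
#' @export
init_hex_cluster <- function(params, inward = FALSE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  N <- params$N; L <- params$L
  sites <- hex_sites(N, params$r_c)
  if (max(abs(sites)) >= L / 2 - params$r_c)
    stop("hexagonal cluster does not fit in the box")
  ctr <- c(L / 2, L / 2)
  pos <- sweep(sites, 2, ctr, `+`)
  if (inward) {
    phi <- atan2(-sites[, 2], -sites[, 1])
    at_center <- rowSums(sites^2) == 0
    phi[at_center] <- runif(sum(at_center), -pi, pi)
  } else {
    phi <- runif(N, -pi, pi)
  }
  particle_state(pos, phi, L)
}

#' Worm (elongated strip) initialization
#'
#' A hexagonally packed strip of the given width (rows), axis along +x,
#' spacing r_c, centered in the box (long strips wrap through the periodic
#' boundary). Orientations point along the strip axis with small Gaussian
#' jitter, giving initial polar order close to 1.
#'
#' @param params a \code{sim_params}.
#' @param width strip width in particle rows.
#' @param jitter standard deviation of the orientation jitter (radians).
#' @param seed optional seed; if NULL the current RNG stream is used.
#' @return a \code{particle_state}.
#' @export
init_worm <- function(params, width = 5, jitter = 0.1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  N <- params$N; L <- params$L
  a <- params$r_c
  n_len <- ceiling(N / width)
  row <- rep(seq_len(width) - 1L, times = n_len)[seq_len(N)]
  col <- rep(seq_len(n_len) - 1L, each = width)[seq_len(N)]
  x <- (col + 0.5 * (row %% 2)) * a
  y <- row * a * sqrt(3) / 2
  if (max(y) - min(y) >= L - a)
    stop("worm strip wider than the box")
  pos <- cbind(x - mean(range(x)) + L / 2, y - mean(range(y)) + L / 2)
  phi <- rnorm(N, 0, jitter)
  particle_state(pos, phi, L)
}
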