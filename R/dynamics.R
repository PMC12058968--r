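#' WCA repulsive force
#'
#' Force on the particle located at \code{+r_vec} exerted by a particle at the
#' origin, from the Weeks-Chandler-Andersen potential
#' U(r) = 4 eps ((sigma/r)^12 - (sigma/r)^6) + eps for r <= r_c = 2^(1/6) sigma
#' and 0 beyond. Always repulsive (parallel to \code{+r_vec}).
#'
#' @param r_vec 2-vector separation r_i - r_j (sigma).
#' @param eps energy scale (kBT).
#' @param sigma particle diameter.
#' @param min_sep separations below this signal an overlap error
#'   (time step too large).
#' @return 2-vector force.
#' @examples
#' wca_force(c(1, 0), eps = 100)   # magnitude 24 * eps at contact
#' @export
wca_force <- function(r_vec, eps, sigma = 1, min_sep = 0.5 * sigma) {
  r <- sqrt(sum(r_vec^2))
  if (r <= 0) stop("coincident particles: |r_vec| = 0")
  if (r < min_sep)
    stop(sprintf("overlap: pair distance %.4g below minimum %.4g; reduce dt",
                 r, min_sep))
  r_c <- 2^(1 / 6) * sigma
  if (r > r_c) return(c(0, 0))
  s6 <- (sigma / r)^6
  # -dU/dr * rhat = 24 eps (2 (sigma/r)^12 - (sigma/r)^6) / r^2 * r_vec
  24 * eps * (2 * s6^2 - s6) / r^2 * r_vec
}

#' Signed angle between two vectors
#'
#' Counterclockwise angle in (-pi, pi] that rotates \code{u} onto \code{v}:
#' sin = u_x v_y - u_y v_x, cos = u . v.
#'
#' @param u,v non-zero 2-vectors (need not be normalized).
#' @return angle in radians.
#' @examples
#' signed_angle(c(1, 0), c(0, 1))  # +pi/2
#' @export
signed_angle <- function(u, v) {
  if (all(u == 0) || all(v == 0)) stop("zero vector has no direction")
  atan2(u[1] * v[2] - u[2] * v[1], u[1] * v[1] + u[2] * v[2])
}

#' Alignment torque on particle i from particle j
#'
#' T_A * Theta(R - dist) * sin(phi_j - phi_i): turns i parallel to j.
#' Reciprocal: the torque j receives from i is the exact negative.
#' The Heaviside support is strictly inside (zero at dist = R).
#'
#' @param phi_i,phi_j orientation angles (radians).
#' @param dist pair distance (sigma).
#' @param T_A alignment torque strength (kBT).
#' @param R interaction radius (sigma).
#' @return scalar torque (counterclockwise positive).
#' @export
alignment_torque <- function(phi_i, phi_j, dist, T_A, R) {
  ifelse(dist < R, T_A * sin(phi_j - phi_i), 0)
}

#' Cohesive torque on particle i from particle j
#'
#' -T_C * Theta(R - |r_ij|) * sin(theta) with theta the signed angle from u_i
#' to rhat_ij = r_ij / |r_ij| and r_ij = r_i - r_j: turns u_i toward the
#' neighbor j (i.e. toward -rhat_ij). Non-reciprocal: the torque on j from i
#' is generally not the negative of this.
#'
#' @param u_i unit orientation vector of particle i.
#' @param r_ij 2-vector separation r_i - r_j (minimum image, sigma).
#' @param T_C cohesive torque strength (kBT).
#' @param R interaction radius (sigma).
#' @return scalar torque (counterclockwise positive).
#' @export
cohesion_torque <- function(u_i, r_ij, T_C, R) {
  d <- sqrt(sum(r_ij^2))
  if (d == 0) stop("coincident particles: |r_ij| = 0")
  if (d >= R) return(0)
  -T_C * sin(signed_angle(u_i, r_ij / d))
}

#' Neighbor pairs under the minimum-image convention
#'
#' All ordered pairs with distance strictly below \code{cutoff}, found with a
#' periodic cell list. The table contains (i, j) iff it contains (j, i) with
#' the separation vector negated.
#'
#' @param state a \code{particle_state}.
#' @param cutoff pair distance cutoff (sigma); must be <= L/2 for the
#'   minimum image to be unambiguous.
#' @return data.frame with columns \code{i}, \code{j}, \code{dx}, \code{dy}
#'   (components of r_i - r_j) and \code{r}.
#' @export
build_pairs <- function(state, cutoff) {
  if (cutoff > state$L / 2)
    stop("cutoff exceeds L/2: box too small for the minimum-image convention")
  m <- cpp_build_pairs(state$pos, state$L, cutoff)
  data.frame(i = as.integer(m[, 1]), j = as.integer(m[, 2]),
             dx = m[, 3], dy = m[, 4], r = m[, 5])
}

#' Interaction forces and torques for one snapshot
#'
#' Sums, per particle, the pairwise WCA forces and the total torque
#' T0 * Theta(R - |r_ij|) * (sin(phi_j - phi_i) - (1/ratio) sin(theta_ij)),
#' i.e. alignment at strength T_A = T0 plus cohesion at T_C = T0 / ratio.
#'
#' @param state a \code{particle_state}.
#' @param params a \code{sim_params}.
#' @return list with \code{force} (N x 2) and \code{torque} (length N).
#' @export
forces_and_torques <- function(state, params) {
  check_cutoffs(state$L, params)
  cpp_forces_torques(state$pos, state$phi, state$L, params$eps, params$sigma,
                     params$T0, params$ratio, params$R_abs, params$min_sep)
}

#' Total torque on every particle
#'
#' @inheritParams forces_and_torques
#' @return length-N vector of torques (kBT, counterclockwise positive).
#' @export
total_torque <- function(state, params) {
  forces_and_torques(state, params)$torque
}

check_cutoffs <- function(L, params) {
  cutoff <- max(params$r_c, if (params$T0 > 0) params$R_abs else 0)
  if (cutoff > L / 2)
    stop("interaction cutoff exceeds L/2: box too small for minimum image")
  invisible(cutoff)
}

#' Advance a snapshot by one Euler-Maruyama step
#'
#' r <- r + [v0 u + mu F] dt + sqrt(2 D dt) xi,
#' phi <- phi + mu_R T dt + sqrt(2 D_R dt) eta, with xi, eta standard normal;
#' positions rewrapped into [0, L) (image counters updated) and phi wrapped to
#' (-pi, pi]. Noise terms can be switched off to test deterministic limits.
#'
#' @param state a \code{particle_state}.
#' @param params a \code{sim_params}.
#' @param translational_noise,rotational_noise logical; include the
#'   corresponding noise term.
#' @return the updated \code{particle_state}, with \code{t} advanced by dt.
#' @export
step_state <- function(state, params, translational_noise = TRUE,
                       rotational_noise = TRUE) {
  check_cutoffs(state$L, params)
  out <- cpp_simulate(state$pos, state$phi, state$image, state$L,
                      params$v0, params$mu, params$D, params$mu_R, params$D_R,
                      params$eps, params$sigma, params$T0, params$ratio,
                      params$R_abs, params$dt,
                      0L, 1L, 1L, params$min_sep,
                      as.numeric(translational_noise),
                      as.numeric(rotational_noise))
  particle_state(pos = cbind(out$pos[2, , 1], out$pos[2, , 2]),
                 phi = out$phi[2, ],
                 L = state$L,
                 image = cbind(out$image[2, , 1], out$image[2, , 2]),
                 t = state$t + params$dt)
}

#' Run a full simulation
#'
#' Integrates \code{t_equil} of equilibration followed by \code{t_collect} of
#' data collection, recording a frame every \code{sample_interval} (the state
#' at the start of collection is always recorded). Fully reproducible: the
#' seed in \code{params} initializes one RNG stream shared by the initializer
#' and the thermal noise.
#'
#' @param params a \code{sim_params}.
#' @param init either a \code{particle_state}, or the name of an initializer:
#'   \code{"lattice_random"}, \code{"hex_cluster_inward"} (aster),
#'   \code{"hex_cluster_random"} or \code{"worm"}.
#' @param ... passed to the chosen initializer (e.g. \code{worm_width}).
#' @return a \code{trajectory}: list with \code{times} (tau_R, measured from
#'   the start of collection), \code{pos} (frames x N x 2, wrapped),
#'   \code{image}, \code{phi} (frames x N), \code{params} and \code{init}.
#' @examples
#' p <- sim_params(N = 20, Phi = 0.05, T0 = 0, dt = 1e-4,
#'                 t_equil = 0.01, t_collect = 0.05, sample_interval = 0.01)
#' traj <- run_simulation(p, "lattice_random")
#' dim(traj$pos)
#' @export
run_simulation <- function(params, init = "lattice_random", ...) {
  set.seed(params$seed)
  init_kind <- if (is.character(init)) init else "custom"
  state <- if (is.character(init)) {
    make_initial_state(init, params, ...)
  } else if (inherits(init, "particle_state")) {
    init
  } else stop("init must be an initializer name or a particle_state")
  check_cutoffs(state$L, params)

  n_equil <- round(params$t_equil / params$dt)
  n_collect <- round(params$t_collect / params$dt)
  sample_every <- max(1L, round(params$sample_interval / params$dt))

  out <- cpp_simulate(state$pos, state$phi, state$image, state$L,
                      params$v0, params$mu, params$D, params$mu_R, params$D_R,
                      params$eps, params$sigma, params$T0, params$ratio,
                      params$R_abs, params$dt,
                      as.integer(n_equil), as.integer(n_collect),
                      as.integer(sample_every), params$min_sep, 1, 1)

  structure(list(times = out$times, pos = out$pos, image = out$image,
                 phi = out$phi, params = params, init = init_kind),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("trajectory: %d frames, N = %d, t in [%g, %g] tau_R, init '%s'\n",
              length(x$times), dim(x$pos)[2], min(x$times), max(x$times),
              x$init))
  invisible(x)
}

#' Extract one frame of a trajectory as a particle_state
#'
#' @param traj a \code{trajectory}.
#' @param frame frame index (1-based).
#' @return a \code{particle_state}.
#' @export
trajectory_frame <- function(traj, frame) {
  stopifnot(frame >= 1, frame <= length(traj$times))
  particle_state(pos = cbind(traj$pos[frame, , 1], traj$pos[frame, , 2]),
                 phi = traj$phi[frame, ],
                 L = traj$params$L,
                 image = cbind(traj$image[frame, , 1], traj$image[frame, , 2]),
                 t = traj$times[frame])
}

#' Unwrapped coordinates of a whole trajectory
#'
#' @param traj a \code{trajectory}.
#' @return frames x N x 2 array \code{pos + image * L}.
#' @export
trajectory_unwrapped <- function(traj) {
  traj$pos + traj$image * traj$params$L
}
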