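#' Polar order of one frame
#'
#' Psi = |sum_i u_i| / N: 1 for a common heading, ~ N^(-1/2) for random
#' orientations.
#'
#' @param phi orientation angles (radians).
#' @return scalar in [0, 1].
#' @export
polar_order <- function(phi) {
  sqrt(sum(cos(phi))^2 + sum(sin(phi))^2) / length(phi)
}

#' Center of mass under periodic boundaries
#'
#' Each coordinate is mapped onto a circle (angle 2 pi x / L) and the mean
#' angle of the averaged unit-circle embedding provides a reference point;
#' the center of mass is then the arithmetic mean of the minimum-image
#' displacements about that reference, mapped back into [0, L). This is
#' exact for any cluster of extent below L/2, including clusters straddling
#' the boundary, and reduces to the plain arithmetic mean away from it.
#' Degenerate (mass-balanced antipodal) coordinates fall back to the
#' arithmetic mean with a warning.
#'
#' @param points M x 2 matrix of wrapped positions (sigma).
#' @param L box side length.
#' @return 2-vector in [0, L)^2.
#' @export
periodic_com <- function(points, L) {
  points <- rbind(points)  # tolerate a single point given as a vector
  vapply(1:2, function(k) {
    th <- 2 * pi * points[, k] / L
    cm <- mean(cos(th)); sm <- mean(sin(th))
    if (sqrt(cm^2 + sm^2) < 1e-9) {
      warning("degenerate antipodal configuration: falling back to arithmetic mean")
      return(mean(points[, k]) %% L)
    }
    ref <- atan2(sm, cm) / (2 * pi) * L
    (ref + mean(min_image_disp(points[, k] - ref, L))) %% L
  }, numeric(1))
}

#' Density-based clusters under the minimum-image metric
#'
#' With a minimum sample count of 1, density-based clustering at cutoff
#' \code{eps} is exactly the set of connected components of the graph whose
#' edges join particles closer than \code{eps} (no noise label); components
#' are computed on the minimum-image distance matrix.
#'
#' @param state a \code{particle_state} (or N x 2 wrapped positions via
#'   \code{pos =} with \code{L =}).
#' @param eps clustering cutoff distance (sigma); must be <= L/2.
#' @return object of class \code{cluster_labeling}: list with \code{labels}
#'   (per-particle cluster id, dense in 1..n_clusters), \code{com}
#'   (n_clusters x 2 periodic centers of mass), \code{n_clusters}, \code{t}.
#' @export
find_clusters <- function(state, eps = 1.5) {
  pos <- state$pos; L <- state$L
  if (eps > L / 2) stop("eps exceeds L/2: invalid for minimum image")
  N <- nrow(pos)
  dx <- min_image_disp(outer(pos[, 1], pos[, 1], `-`), L)
  dy <- min_image_disp(outer(pos[, 2], pos[, 2], `-`), L)
  adj <- (dx^2 + dy^2) < eps^2
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           diag = FALSE)
  memb <- igraph::components(g)$membership
  labels <- as.integer(factor(memb, levels = unique(memb)))
  n_c <- max(labels)
  com <- t(vapply(seq_len(n_c), function(c)
    periodic_com(pos[labels == c, , drop = FALSE], L), numeric(2)))
  structure(list(labels = labels, com = com, n_clusters = n_c, t = state$t),
            class = "cluster_labeling")
}

#' @export
print.cluster_labeling <- function(x, ...) {
  cat(sprintf("cluster_labeling: %d clusters over %d particles (t = %g)\n",
              x$n_clusters, length(x$labels), x$t))
  invisible(x)
}

#' Mean cluster size of one frame
#'
#' Average over clusters of the maximum minimum-image distance from a member
#' to the cluster's periodic center of mass. Singleton clusters contribute 0.
#'
#' @param labeling a \code{cluster_labeling}.
#' @param state the \code{particle_state} it was computed from.
#' @return scalar extent (sigma).
#' @export
cluster_size <- function(labeling, state) {
  ext <- vapply(seq_len(labeling$n_clusters), function(c) {
    p <- state$pos[labeling$labels == c, , drop = FALSE]
    d <- min_image_disp(sweep(p, 2, labeling$com[c, ]), state$L)
    max(sqrt(rowSums(d^2)))
  }, numeric(1))
  mean(ext)
}

#' System size of one frame
#'
#' Average over all particles (rather than over clusters) of the extent of
#' the cluster each particle belongs to: S = (1/N) sum_i ext(c(i)), with
#' ext the maximum minimum-image member distance to the cluster's periodic
#' center of mass. Weighting by particles rather than clusters makes S jump
#' toward L/2 when most particles merge into one box-spanning line and drop
#' again when the line breaks into multiple worms, which is what detects the
#' transient worm/line transition; the cluster-weighted \code{cluster_size}
#' is diluted by background singletons and cannot.
#'
#' @param state a \code{particle_state}.
#' @param labeling optional precomputed \code{cluster_labeling}.
#' @param eps clustering cutoff used when \code{labeling} is NULL.
#' @return scalar extent (sigma).
#' @export
system_size <- function(state, labeling = NULL, eps = 1.5) {
  if (is.null(labeling)) labeling <- find_clusters(state, eps)
  ext <- vapply(seq_len(labeling$n_clusters), function(c) {
    p <- state$pos[labeling$labels == c, , drop = FALSE]
    d <- min_image_disp(sweep(p, 2, labeling$com[c, ]), state$L)
    max(sqrt(rowSums(d^2)))
  }, numeric(1))
  mean(ext[labeling$labels])
}

# default log-spaced frame offsets for time-correlation estimators
default_lag_frames <- function(n_frames, n_lags = 60) {
  k <- unique(round(exp(seq(0, log(n_frames - 1), length.out = n_lags))))
  k[k >= 1 & k <= n_frames - 1]
}

#' Mean squared displacement
#'
#' MSD(t) = < (r(t0 + t) - r(t0))^2 >, averaged over all time origins at the
#' sampling spacing and over particles, using unwrapped coordinates. The
#' standard error is taken across particles (per-particle time averages).
#'
#' @param traj a \code{trajectory}.
#' @param lag_frames frame offsets to evaluate; default ~60 log-spaced.
#' @return data.frame with columns \code{lag} (tau_R), \code{value},
#'   \code{se}, \code{n}; lag 0 is always present with value 0.
#' @export
msd <- function(traj, lag_frames = NULL) {
  up <- trajectory_unwrapped(traj)
  S <- dim(up)[1]; N <- dim(up)[2]
  if (is.null(lag_frames)) lag_frames <- default_lag_frames(S)
  if (any(lag_frames >= S)) stop("lag beyond trajectory length")
  dt_frame <- if (S > 1) diff(traj$times[1:2]) else NA_real_
  rows <- lapply(lag_frames, function(k) {
    d1 <- up[(1 + k):S, , 1, drop = FALSE] - up[1:(S - k), , 1, drop = FALSE]
    d2 <- up[(1 + k):S, , 2, drop = FALSE] - up[1:(S - k), , 2, drop = FALSE]
    sq <- d1^2 + d2^2
    per_particle <- colMeans(matrix(sq, S - k, N))
    data.frame(lag = k * dt_frame, value = mean(per_particle),
               se = sd(per_particle) / sqrt(N), n = N * (S - k))
  })
  rbind(data.frame(lag = 0, value = 0, se = 0, n = N * S),
        do.call(rbind, rows))
}

#' Orientation correlation function
#'
#' OCF(t) = < u(t0 + t) . u(t0) >, averaged over time origins and particles;
#' standard error across particles.
#'
#' @inheritParams msd
#' @return data.frame as in \code{\link{msd}}; lag 0 always present with
#'   value 1.
#' @export
ocf <- function(traj, lag_frames = NULL) {
  S <- dim(traj$phi)[1]; N <- dim(traj$phi)[2]
  if (is.null(lag_frames)) lag_frames <- default_lag_frames(S)
  if (any(lag_frames >= S)) stop("lag beyond trajectory length")
  dt_frame <- if (S > 1) diff(traj$times[1:2]) else NA_real_
  rows <- lapply(lag_frames, function(k) {
    cc <- cos(traj$phi[(1 + k):S, , drop = FALSE] -
              traj$phi[1:(S - k), , drop = FALSE])
    per_particle <- colMeans(matrix(cc, S - k, N))
    data.frame(lag = k * dt_frame, value = mean(per_particle),
               se = sd(per_particle) / sqrt(N), n = N * (S - k))
  })
  rbind(data.frame(lag = 0, value = 1, se = 0, n = N * S),
        do.call(rbind, rows))
}

#' Analytic free active-Brownian-particle baselines
#'
#' Closed forms for an isolated standard ABP without torque interactions:
#' MSD(t) = 4 D t + (2 v0^2 / D_R^2)(D_R t - 1 + exp(-D_R t)) and
#' OCF(t) = exp(-D_R t).
#'
#' @param params a \code{sim_params} (supplies D, D_R, v0).
#' @param lags lag times (tau_R).
#' @return list with data.frames \code{msd} and \code{ocf}
#'   (columns \code{lag}, \code{value}).
#' @export
abp_baselines <- function(params, lags) {
  list(msd = data.frame(lag = lags, value = abp_msd(lags, params)),
       ocf = data.frame(lag = lags, value = exp(-params$D_R * lags)))
}

abp_msd <- function(t, params) {
  4 * params$D * t +
    (2 * params$v0^2 / params$D_R^2) * (params$D_R * t - 1 + exp(-params$D_R * t))
}

#' Cluster shape asymmetry
#'
#' A = |I1 - I2| / (I1 + I2) with I1 >= I2 the eigenvalues of the 2 x 2
#' second-moment (gyration) tensor of minimum-image displacements about the
#' cluster's periodic center of mass: 0 for an isotropic cluster, 1 for a
#' collinear one. Undefined (NA) when all members coincide.
#'
#' @param points M x 2 wrapped member positions, M >= 2.
#' @param L box side length.
#' @return scalar in [0, 1], or NA if degenerate.
#' @export
cluster_asymmetry <- function(points, L) {
  if (nrow(points) < 2) stop("asymmetry needs at least 2 cluster members")
  com <- periodic_com(points, L)
  d <- min_image_disp(sweep(points, 2, com), L)
  G <- crossprod(d) / nrow(d)
  ev <- eigen(G, symmetric = TRUE, only.values = TRUE)$values
  if (sum(ev) <= 0) return(NA_real_)
  abs(ev[1] - ev[2]) / (ev[1] + ev[2])
}

#' Radial orientation order of one frame
#'
#' Mean over particles of u_i . rhat_i, where rhat_i points from the periodic
#' center of mass of particle i's cluster outward to particle i: +1 when all
#' orientations point radially outward, -1 when all point inward (aster).
#' Particles in singleton clusters (and any particle sitting exactly on its
#' cluster's center of mass) are excluded; returns NA if none remain.
#'
#' @param state a \code{particle_state}.
#' @param labeling optional precomputed \code{cluster_labeling}.
#' @param eps clustering cutoff used when \code{labeling} is NULL.
#' @return scalar in [-1, 1] or NA.
#' @export
radial_order <- function(state, labeling = NULL, eps = 1.5) {
  if (is.null(labeling)) labeling <- find_clusters(state, eps)
  u <- orientation_vectors(state$phi)
  d <- min_image_disp(state$pos - labeling$com[labeling$labels, , drop = FALSE],
                      state$L)
  r <- sqrt(rowSums(d^2))
  sizes <- tabulate(labeling$labels)
  keep <- r > 1e-12 & sizes[labeling$labels] > 1
  if (!any(keep)) return(NA_real_)
  mean(rowSums(u[keep, , drop = FALSE] * d[keep, , drop = FALSE]) / r[keep])
}

#' Neighbor turnover of a focal particle
#'
#' Fraction of the particles within interaction distance R of particle i at
#' time t0 that are no longer within R at time t1; also reports the particle's
#' front-to-back rank along its cluster's mean heading at both times
#' (rank 1 = frontmost), for leadership tracking.
#'
#' @param traj a \code{trajectory}.
#' @param i focal particle index.
#' @param t0,t1 times (tau_R) within the trajectory; the nearest recorded
#'   frames are used.
#' @param R neighbor radius (sigma); defaults to the run's interaction radius.
#' @param eps clustering cutoff for the rank computation.
#' @return list with \code{turnover}, \code{n_neighbors},
#'   \code{rank_start}, \code{rank_end}.
#' @export
neighbor_turnover <- function(traj, i, t0, t1, R = traj$params$R_abs,
                              eps = 1.5) {
  stopifnot(t0 <= t1)
  f0 <- which.min(abs(traj$times - t0))
  f1 <- which.min(abs(traj$times - t1))
  s0 <- trajectory_frame(traj, f0)
  s1 <- trajectory_frame(traj, f1)
  nb <- function(state) {
    d <- min_image_disp(sweep(state$pos, 2, state$pos[i, ]), state$L)
    which(sqrt(rowSums(d^2)) < R & seq_len(nrow(state$pos)) != i)
  }
  n0 <- nb(s0)
  turnover <- if (length(n0) == 0) 0 else {
    if (f1 == f0) 0 else mean(!(n0 %in% nb(s1)))
  }
  rank_along_heading <- function(state) {
    lab <- find_clusters(state, eps)
    members <- which(lab$labels == lab$labels[i])
    u_mean <- colMeans(orientation_vectors(state$phi[members]))
    if (sqrt(sum(u_mean^2)) < 1e-12) return(NA_integer_)
    u_mean <- u_mean / sqrt(sum(u_mean^2))
    d <- min_image_disp(sweep(state$pos[members, , drop = FALSE], 2,
                              lab$com[lab$labels[i], ]), state$L)
    proj <- d %*% u_mean
    match(i, members[order(-proj)])
  }
  list(turnover = turnover, n_neighbors = length(n0),
       rank_start = rank_along_heading(s0), rank_end = rank_along_heading(s1))
}
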