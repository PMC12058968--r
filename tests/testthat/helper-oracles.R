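# Independent brute-force oracles used across the suite.

# O(N^2) minimum-image pair scan
brute_pairs <- function(pos, L, cutoff) {
  N <- nrow(pos)
  out <- list()
  for (i in seq_len(N)) for (j in seq_len(N)) {
    if (i == j) next
    d <- pos[i, ] - pos[j, ]
    d <- d - L * floor(d / L + 0.5)
    r <- sqrt(sum(d^2))
    if (r < cutoff)
      out[[length(out) + 1]] <- data.frame(i = i, j = j, dx = d[1],
                                           dy = d[2], r = r)
  }
  if (length(out) == 0)
    return(data.frame(i = integer(), j = integer(), dx = numeric(),
                      dy = numeric(), r = numeric()))
  do.call(rbind, out)
}

# O(N^2) double-loop total torque built from the scalar pair operations
brute_total_torque <- function(state, params) {
  N <- nrow(state$pos)
  tq <- numeric(N)
  T_A <- params$T0
  T_C <- params$T0 / params$ratio
  for (i in seq_len(N)) for (j in seq_len(N)) {
    if (i == j) next
    d <- state$pos[i, ] - state$pos[j, ]
    d <- d - state$L * floor(d / state$L + 0.5)
    r <- sqrt(sum(d^2))
    if (r < params$R_abs) {
      u_i <- c(cos(state$phi[i]), sin(state$phi[i]))
      tq[i] <- tq[i] +
        alignment_torque(state$phi[i], state$phi[j], r, T_A, params$R_abs) +
        cohesion_torque(u_i, d, T_C, params$R_abs)
    }
  }
  tq
}

# union-find connected components of the minimum-image eps-graph
brute_components <- function(pos, L, eps) {
  N <- nrow(pos)
  parent <- seq_len(N)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (i in seq_len(N - 1)) for (j in (i + 1):N) {
    d <- pos[i, ] - pos[j, ]
    d <- d - L * floor(d / L + 0.5)
    if (sum(d^2) < eps^2) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  roots <- vapply(seq_len(N), find, integer(1))
  as.integer(factor(roots, levels = unique(roots)))
}

# random sparse wrapped configuration in a box of side L
random_state <- function(N, L, seed) {
  set.seed(seed)
  particle_state(pos = cbind(runif(N, 0, L), runif(N, 0, L)),
                 phi = runif(N, -pi, pi), L = L)
}

# same partition up to relabeling?
same_partition <- function(a, b) {
  length(a) == length(b) &&
    nrow(unique(cbind(a, b))) == length(unique(a)) &&
    length(unique(a)) == length(unique(b))
}

# random but overlap-free configuration: jittered square lattice
random_spaced_state <- function(N, L, seed, jitter = 0.25) {
  set.seed(seed)
  n_side <- ceiling(sqrt(N))
  a <- L / n_side
  stopifnot(a > 1.5)  # room for jitter without overlaps
  idx <- seq_len(N) - 1L
  pos <- cbind((idx %% n_side + 0.5) * a, (idx %/% n_side + 0.5) * a)
  pos <- (pos + matrix(runif(2 * N, -jitter * a, jitter * a), N, 2)) %% L
  particle_state(pos, runif(N, -pi, pi), L)
}
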