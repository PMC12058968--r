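test_that("WCA force vanishes at the cutoff and is 24*eps at contact", {
  rc <- 2^(1 / 6)
  expect_equal(wca_force(c(rc, 0), eps = 100), c(0, 0))
  expect_equal(wca_force(c(0, 1.5), eps = 50), c(0, 0))
  f <- wca_force(c(1, 0), eps = 100)
  expect_equal(f, c(2400, 0))
  # always repulsive: parallel to +r_vec below the cutoff
  f2 <- wca_force(c(0.6, 0.6), eps = 10)
  expect_gt(f2[1], 0)
  expect_equal(f2[1], f2[2])
})

test_that("WCA force matches a central-difference derivative of the potential", {
  U <- function(r, eps, sigma = 1) {
    ifelse(r <= 2^(1 / 6) * sigma,
           4 * eps * ((sigma / r)^12 - (sigma / r)^6) + eps, 0)
  }
  h <- 1e-7
  for (r in c(0.9, 1.0, 1.05, 1.1)) {
    f_num <- -(U(r + h, 100) - U(r - h, 100)) / (2 * h)
    f_pkg <- wca_force(c(r, 0), eps = 100)[1]
    expect_equal(f_pkg, f_num, tolerance = 1e-6)
  }
})

test_that("WCA force errors on overlaps and coincidence", {
  expect_error(wca_force(c(0.3, 0), eps = 100), "overlap")
  expect_error(wca_force(c(0, 0), eps = 100), "coincident")
})

test_that("signed angle is the CCW rotation angle with atan2 convention", {
  expect_equal(signed_angle(c(1, 0), c(1, 0)), 0)
  expect_equal(signed_angle(c(1, 0), c(0, 1)), pi / 2)
  expect_equal(signed_angle(c(1, 0), c(0, -1)), -pi / 2)
  set.seed(11)
  for (k in 1:50) {
    a <- runif(1, -pi, pi); b <- runif(1, -pi, pi)
    u <- c(cos(a), sin(a)); v <- c(cos(b), sin(b))
    th <- signed_angle(u, v)
    # rotation-matrix oracle: rotating u by th must give v
    Rm <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    expect_equal(as.numeric(Rm %*% u), v, tolerance = 1e-12)
    expect_true(th > -pi && th <= pi)
  }
  expect_error(signed_angle(c(0, 0), c(1, 0)), "zero")
})

test_that("alignment torque: parallel/antiparallel zeros, sine amplitude, support", {
  expect_equal(alignment_torque(0.3, 0.3, dist = 1, T_A = 5, R = 2), 0)
  expect_equal(alignment_torque(0, pi / 2, dist = 1, T_A = 2, R = 2), 2)
  expect_equal(alignment_torque(0, pi, dist = 1, T_A = 2, R = 2),
               0, tolerance = 1e-15)
  expect_equal(alignment_torque(0, pi / 2, dist = 2, T_A = 2, R = 2), 0)
})

test_that("cohesion torque turns the orientation toward the neighbor", {
  # pointing straight at j: no torque
  expect_equal(cohesion_torque(c(1, 0), r_ij = c(1, 0), T_C = 1, R = 2),
               0, tolerance = 1e-15)
  # j straight above: CCW torque +T_C
  expect_equal(cohesion_torque(c(1, 0), r_ij = c(0, -1), T_C = 1, R = 2), 1)
  # out of range
  expect_equal(cohesion_torque(c(1, 0), r_ij = c(0, -3), T_C = 1, R = 2), 0)
  expect_error(cohesion_torque(c(1, 0), r_ij = c(0, 0), T_C = 1, R = 2),
               "coincident")
})

test_that("alignment is reciprocal, cohesion is not", {
  set.seed(21)
  R <- 2.5
  for (k in 1:50) {
    phi_i <- runif(1, -pi, pi); phi_j <- runif(1, -pi, pi)
    d <- runif(2, -1, 1)
    r <- sqrt(sum(d^2))
    expect_equal(alignment_torque(phi_i, phi_j, r, 3, R) +
                 alignment_torque(phi_j, phi_i, r, 3, R), 0, tolerance = 1e-14)
  }
  # documented non-reciprocal configuration: u_i perpendicular to r_ij,
  # u_j parallel to r_ij
  u_i <- c(0, 1); u_j <- c(1, 0); d <- c(1, 0)  # r_i - r_j
  s <- cohesion_torque(u_i, d, 1, R) + cohesion_torque(u_j, -d, 1, R)
  expect_gt(abs(s), 0.5)
})

test_that("vectorized total torque equals the brute-force double loop", {
  for (seed in 1:6) {
    p <- sim_params(N = 5, Phi = 0.05, T0 = 10, R = 2, seed = seed)
    st <- random_spaced_state(5, p$L, seed + 100)
    expect_equal(total_torque(st, p), brute_total_torque(st, p),
                 tolerance = 1e-12)
  }
  # larger config exercising the cell list
  p <- sim_params(N = 200, Phi = 0.1, T0 = 7, R = 3, ratio = 2.5, seed = 1)
  st <- random_spaced_state(200, p$L, 9)
  expect_equal(total_torque(st, p), brute_total_torque(st, p),
               tolerance = 1e-12)
  # torque off
  p0 <- update_params(p, T0 = 0)
  expect_equal(total_torque(st, p0), rep(0, 200))
})

test_that("two particles aligned head-to-head feel zero torque", {
  p <- sim_params(N = 2, Phi = 0.001, T0 = 10, R = 2, seed = 1)
  # both oriented +x, one behind the other: parallel and pointing at each other
  st <- particle_state(pos = rbind(c(5, 5), c(6.5, 5)), phi = c(0, 0), L = p$L)
  expect_equal(total_torque(st, p), c(0, 0), tolerance = 1e-14)
})

test_that("pair table: strict cutoff, wrap-around, symmetric entries", {
  L <- 20
  st <- particle_state(pos = rbind(c(1, 1), c(1 + 3 * (1 + 1e-9), 1)),
                       phi = c(0, 0), L = L)
  expect_equal(nrow(build_pairs(st, cutoff = 3)), 0)
  st2 <- particle_state(pos = rbind(c(0.1, 5), c(L - 0.1, 5)),
                        phi = c(0, 0), L = L)
  pr <- build_pairs(st2, cutoff = 1)
  expect_equal(nrow(pr), 2)
  expect_equal(pr$r, c(0.2, 0.2), tolerance = 1e-12)
  expect_error(build_pairs(st2, cutoff = 11), "L/2")
})

test_that("cell-list pair search is identical to the O(N^2) scan", {
  for (seed in 1:8) {
    N <- 300; L <- 30
    st <- random_state(N, L, seed)
    cutoff <- c(1.5, 2.5, 6)[seed %% 3 + 1]
    got <- build_pairs(st, cutoff)
    want <- brute_pairs(st$pos, L, cutoff)
    key <- function(d) do.call(order, d[c("i", "j")])
    got <- got[key(got), ]; want <- want[key(want), ]
    expect_equal(nrow(got), nrow(want))
    expect_equal(got$i, want$i)
    expect_equal(got$j, want$j)
    expect_equal(got$dx, want$dx, tolerance = 1e-12)
    expect_equal(got$r, want$r, tolerance = 1e-12)
  }
})

test_that("forces and torques are invariant under rotation and translation", {
  p <- sim_params(N = 40, Phi = 0.05, T0 = 8, R = 2, seed = 3)
  st <- random_spaced_state(40, p$L, 5)
  ft <- forces_and_torques(st, p)
  # global translation (mod L)
  shift <- c(3.7, -1.2)
  st_t <- particle_state(pos = sweep(st$pos, 2, shift, `+`) %% p$L,
                         phi = st$phi, L = p$L)
  ft_t <- forces_and_torques(st_t, p)
  expect_equal(ft_t$force, ft$force, tolerance = 1e-10)
  expect_equal(ft_t$torque, ft$torque, tolerance = 1e-10)
  # global rotation: rotate a compact cluster about the box center
  # (rotation does not commute with the periodic wrap, so keep points central)
  set.seed(8)
  Nc <- 25
  ctr <- p$L / 2
  # compact but overlap-free cluster: jittered grid around the center
  g <- expand.grid(x = seq(-4, 4, by = 2), y = seq(-4, 4, by = 2))[1:Nc, ]
  pos_c <- cbind(ctr + g$x, ctr + g$y) +
    matrix(runif(2 * Nc, -0.4, 0.4), Nc, 2)
  phi_c <- runif(Nc, -pi, pi)
  stc <- particle_state(pos_c, phi_c, p$L)
  ftc <- forces_and_torques(stc, p)
  th <- 0.77
  Rm <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  pos_r <- t(Rm %*% (t(pos_c) - ctr)) + ctr
  str <- particle_state(pos_r, phi_c + th, p$L)
  ftr <- forces_and_torques(str, p)
  expect_equal(sqrt(rowSums(ftr$force^2)), sqrt(rowSums(ftc$force^2)),
               tolerance = 1e-12)
  expect_equal(ftr$torque, ftc$torque, tolerance = 1e-12)
})

test_that("deterministic single-particle step is pure self-propulsion", {
  p <- sim_params(N = 1, Phi = 0.001, T0 = 0, Pe = 80, eps = 0.1, dt = 1e-3,
                  seed = 1)
  st <- particle_state(pos = rbind(c(2, 2)), phi = 0.7, L = p$L)
  st2 <- step_state(st, p, translational_noise = FALSE,
                    rotational_noise = FALSE)
  expect_equal(unwrapped_positions(st2) - unwrapped_positions(st),
               rbind(p$v0 * c(cos(0.7), sin(0.7)) * p$dt), tolerance = 1e-13)
  expect_equal(st2$phi, st$phi)
})

test_that("overlapping pair is pushed apart symmetrically along its axis", {
  p <- sim_params(N = 2, Phi = 0.001, Pe = 0, T0 = 0, dt = 1e-5, seed = 1)
  st <- particle_state(pos = rbind(c(10, 10), c(11, 10)), phi = c(0, 0),
                       L = p$L)
  st2 <- step_state(st, p, translational_noise = FALSE,
                    rotational_noise = FALSE)
  d1 <- st2$pos[1, ] - st$pos[1, ]
  d2 <- st2$pos[2, ] - st$pos[2, ]
  expect_lt(d1[1], 0)
  expect_gt(d2[1], 0)
  expect_equal(d1, -d2, tolerance = 1e-14)
  expect_equal(d1[2], 0)
})

test_that("orientation-increment variance matches 2 D_R dt", {
  p <- sim_params(N = 1000, Phi = 1e-4, Pe = 0, T0 = 0, dt = 1e-4,
                  t_equil = 0, t_collect = 0.01, sample_interval = 1e-4,
                  seed = 4)
  tr <- run_simulation(p, "lattice_random")
  dphi <- diff(tr$phi)
  dphi <- dphi - 2 * pi * round(dphi / (2 * pi))
  expect_equal(var(as.vector(dphi)), 2 * p$D_R * p$dt, tolerance = 0.05)
})

test_that("free-particle orientation increments over a finite lag pass a KS test", {
  p <- sim_params(N = 400, Phi = 1e-4, Pe = 0, T0 = 0, eps = 0.1, dt = 1e-3,
                  t_equil = 0, t_collect = 0.2, sample_interval = 0.2,
                  seed = 12)
  tr <- run_simulation(p, "lattice_random")
  inc <- tr$phi[2, ] - tr$phi[1, ]
  inc <- inc - 2 * pi * round(inc / (2 * pi))  # wrapped increments
  # lag 0.2 tau_R: sd sqrt(2 D_R t) = 0.63, wrapping negligible
  ks <- suppressWarnings(stats::ks.test(inc, "pnorm", 0,
                                        sqrt(2 * p$D_R * 0.2)))
  expect_gt(ks$p.value, 0.01)
})

test_that("run_simulation is reproducible and honors t_collect = 0", {
  p <- sim_params(N = 30, Phi = 0.05, T0 = 5, R = 2, dt = 1e-4,
                  t_equil = 0.02, t_collect = 0.05, sample_interval = 0.01,
                  seed = 99)
  t1 <- run_simulation(p, "lattice_random")
  t2 <- run_simulation(p, "lattice_random")
  expect_identical(t1$pos, t2$pos)
  expect_identical(t1$phi, t2$phi)
  p0 <- update_params(p, t_collect = 0)
  t3 <- run_simulation(p0, "lattice_random")
  expect_equal(dim(t3$pos)[1], 1)
  # unwrapped minus wrapped positions are integer multiples of L
  up <- trajectory_unwrapped(t1)
  expect_true(all(abs((up - t1$pos) / p$L - round((up - t1$pos) / p$L)) < 1e-9))
})
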