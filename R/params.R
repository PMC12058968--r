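#' Simulation parameters
#'
#' Collects all model and protocol constants and computes the derived unit
#' values under the convention sigma = kBT = tau_R = 1 (so mu_R = 1,
#' mu = sigma^2/3 = 1/3, D = mu kBT = 1/3, D_R = 1, v0 = Pe D / sigma).
#'
#' @param N particle count.
#' @param Pe Peclet number sigma v0 / D (dimensionless).
#' @param Phi packing fraction N pi sigma^2 / (4 L^2); must lie in
#'   (0, 0.9069] (hexagonal close packing bound).
#' @param eps WCA energy scale in kBT.
#' @param T0 torque strength (alignment strength T_A) in kBT.
#' @param ratio alignment-to-cohesion torque ratio T_A / T_C.
#' @param R interaction radius of both torques, in units of r_c = 2^(1/6) sigma.
#' @param dt integration time step in tau_R.
#' @param t_equil,t_collect equilibration and data-collection durations in tau_R.
#' @param sample_interval sampling period for recorded frames, in tau_R.
#' @param seed integer RNG seed.
#' @param min_sep smallest allowed pair distance (sigma); closer approaches
#'   abort the run with advice to reduce dt.
#'
#' @return An object of class \code{sim_params}: the inputs plus derived
#'   fields \code{mu}, \code{mu_R}, \code{D}, \code{D_R}, \code{v0},
#'   \code{r_c}, \code{R_abs} (radius in sigma) and box length \code{L}.
#' @examples
#' p <- sim_params(N = 100, T0 = 20, R = 2)
#' p$L
#' @export
sim_params <- function(N = 1000, Pe = 80, Phi = 0.025, eps = 100,
                       T0 = 0, ratio = 2, R = 1, dt = 5e-5,
                       t_equil = 1000, t_collect = 1000,
                       sample_interval = 0.1, seed = 1L,
                       min_sep = 0.5) {
  stopifnot(length(N) == 1, length(Pe) == 1, length(Phi) == 1)
  if (N < 1 || N != round(N)) stop("N must be a positive integer")
  if (Phi <= 0 || Phi > 0.9069) stop("Phi must lie in (0, 0.9069]")
  if (Pe < 0) stop("Pe must be >= 0")
  if (eps <= 0) stop("eps must be > 0")
  if (T0 < 0) stop("T0 must be >= 0")
  if (ratio <= 0) stop("ratio must be > 0")
  if (R < 1) stop("R must be >= 1 (in r_c units)")
  if (dt <= 0) stop("dt must be > 0")
  if (t_equil < 0 || t_collect < 0) stop("durations must be >= 0")
  if (sample_interval <= 0) stop("sample_interval must be > 0")
  if (min_sep <= 0 || min_sep >= 1) stop("min_sep must lie in (0, 1)")

  sigma <- 1
  mu_R <- 1
  mu <- sigma^2 / 3
  D <- mu          # D = mu * kBT, kBT = 1
  D_R <- 1
  v0 <- Pe * D / sigma
  r_c <- 2^(1 / 6) * sigma
  L <- sqrt(N * pi * sigma^2 / (4 * Phi))

  # explicit Euler-Maruyama stability heuristic at the steepest sampled
  # WCA separation: displacement mu * 24 eps * dt should stay well under sigma
  if (mu * 24 * eps * dt / sigma > 0.1)
    warning("mu * 24 * eps * dt / sigma > 0.1: time step likely too large")

  structure(list(
    N = as.integer(N), Pe = Pe, Phi = Phi, eps = eps, T0 = T0,
    ratio = ratio, R = R, dt = dt, t_equil = t_equil,
    t_collect = t_collect, sample_interval = sample_interval,
    seed = as.integer(seed), min_sep = min_sep,
    sigma = sigma, mu = mu, mu_R = mu_R, D = D, D_R = D_R, v0 = v0,
    r_c = r_c, R_abs = R * r_c, L = L
  ), class = "sim_params")
}

#' @export
print.sim_params <- function(x, ...) {
  cat("Simulation parameters (sigma = kBT = tau_R = 1)\n")
  cat(sprintf("  N = %d, Pe = %g (v0 = %.4g), Phi = %g (L = %.4g sigma)\n",
              x$N, x$Pe, x$v0, x$Phi, x$L))
  cat(sprintf("  eps = %g kBT, T0 = %g kBT, T_A/T_C = %g, R = %g r_c (%.4g sigma)\n",
              x$eps, x$T0, x$ratio, x$R, x$R_abs))
  cat(sprintf("  dt = %g, t_equil = %g, t_collect = %g, sample every %g tau_R, seed %d\n",
              x$dt, x$t_equil, x$t_collect, x$sample_interval, x$seed))
  invisible(x)
}
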