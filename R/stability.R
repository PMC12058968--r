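#' Idealized sheet geometry for torque-balance analysis
#'
#' A probe particle sits at the origin on the boundary of a sheet of
#' particles all oriented along +x. Three geometries are supported: a uniform
#' half-plane sheet filling y < 0 (probe on the straight edge), a hexagonally
#' close-packed half-plane (probe a member of the top lattice row), and a
#' uniform semi-infinite isosceles wedge opening toward -x (probe at the
#' apex/tip, the foremost particle of a worm modeled as a triangle oriented
#' along its symmetry axis).
#'
#' @param kind \code{"uniform_halfplane"}, \code{"hex_halfplane"} or
#'   \code{"uniform_triangle"}.
#' @param R interaction radius in r_c units.
#' @param spacing lattice constant of the hex sheet (sigma); also sets the
#'   uniform sheets' number density to the matching hex-packing density
#'   2 / (sqrt(3) spacing^2), for comparability.
#' @param apex_half_angle triangle half-opening angle (radians).
#' @return object of class \code{sheet_geometry}.
#' @export
sheet_geometry <- function(kind = c("uniform_halfplane", "hex_halfplane",
                                    "uniform_triangle"),
                           R = 2, spacing = 2^(1 / 6),
                           apex_half_angle = pi / 6) {
  kind <- match.arg(kind)
  if (R <= 0 || spacing <= 0) stop("R and spacing must be positive")
  if (kind == "uniform_triangle" &&
      (apex_half_angle <= 0 || apex_half_angle >= pi / 2))
    stop("apex_half_angle must lie in (0, pi/2)")
  structure(list(kind = kind, R = R, R_abs = R * 2^(1 / 6),
                 spacing = spacing,
                 density = 2 / (sqrt(3) * spacing^2),
                 apex_half_angle = apex_half_angle),
            class = "sheet_geometry")
}

# hex lattice sites of the half-plane sheet within |s| < R_abs of the probe
# at the origin (probe row is y = 0; rows below at y = -j sqrt(3)/2 a with
# alternating x offset); excludes the probe site itself
hex_sheet_sites <- function(geom) {
  a <- geom$spacing
  R <- geom$R_abs
  jmax <- ceiling(R / (a * sqrt(3) / 2)) + 1
  imax <- ceiling(R / a) + 1
  sites <- do.call(rbind, lapply(0:jmax, function(j) {
    x <- (seq(-imax, imax) + 0.5 * (j %% 2)) * a
    cbind(x, -j * a * sqrt(3) / 2)
  }))
  d2 <- rowSums(sites^2)
  sites[d2 > 1e-18 & d2 < R^2, , drop = FALSE]
}

#' Net interaction torque on the probe particle
#'
#' Evaluates the pairwise torque (alignment at strength T0 plus cohesion at
#' T0/ratio, all sheet particles oriented along +x) summed over the sheet
#' within the interaction radius: a 2D Gauss-Legendre quadrature in polar
#' coordinates for the uniform geometries, an explicit lattice sum for the
#' hexagonal sheet. The quadrature is re-evaluated at doubled resolution and
#' a warning reports any relative change above 1e-6.
#'
#' @param geom a \code{sheet_geometry}.
#' @param probe_angle probe orientation angle(s), radians (0 = sheet
#'   orientation).
#' @param T0 torque strength (kBT); the equilibrium angle is independent of
#'   it at fixed \code{ratio}.
#' @param ratio alignment-to-cohesion torque ratio.
#' @param n_quad quadrature nodes per dimension.
#' @return net torque, same length as \code{probe_angle} (counterclockwise
#'   positive).
#' @export
net_torque_on_probe <- function(geom, probe_angle, T0 = 1, ratio = 2,
                                n_quad = 64) {
  T_A <- T0
  T_C <- T0 / ratio
  # torque density from a sheet point seen at polar angle psi from the probe:
  # alignment -T_A sin(alpha); cohesion T_C sin(psi - alpha)
  # (r_ij = probe - point, so rhat_ij = -(cos psi, sin psi))
  integrand <- function(psi, alpha) -T_A * sin(alpha) + T_C * sin(psi - alpha)

  if (geom$kind == "hex_halfplane") {
    s <- hex_sheet_sites(geom)
    psi <- atan2(s[, 2], s[, 1])
    return(vapply(probe_angle,
                  function(a) sum(integrand(psi, a)), numeric(1)))
  }

  psi_lim <- if (geom$kind == "uniform_halfplane") c(pi, 2 * pi)
             else pi + c(-1, 1) * geom$apex_half_angle
  quad <- function(n) {
    gr <- pracma::gaussLegendre(n, 0, geom$R_abs)
    gp <- pracma::gaussLegendre(n, psi_lim[1], psi_lim[2])
    vapply(probe_angle, function(a) {
      # integral of r dr dpsi * density * integrand (independent of r)
      geom$density * sum(gr$w * gr$x) * sum(gp$w * integrand(gp$x, a))
    }, numeric(1))
  }
  v1 <- quad(n_quad)
  v2 <- quad(2 * n_quad)
  # compare against the overall torque scale, not the (possibly ~0)
  # pointwise value near an equilibrium
  scale <- max(abs(v2), T0 * geom$density * geom$R_abs^2 / 2)
  rel <- abs(v2 - v1) / scale
  if (any(rel > 1e-6))
    warning(sprintf("quadrature not converged: relative change %.2g", max(rel)))
  v2
}

#' Stable probe orientation and inward tilt
#'
#' Root of the net torque as a function of the probe angle, bracketed in
#' (-pi/2, pi/2) around the sheet orientation and solved to 1e-8 rad;
#' stability requires a negative torque derivative at the root. The tilt is
#' reported relative to the sheet orientation; for these geometries the sheet
#' interior lies at negative angles, so \code{tilt_inward = -angle}.
#'
#' @inheritParams net_torque_on_probe
#' @return list with \code{angle} (signed equilibrium angle, radians),
#'   \code{tilt_inward} and \code{stable} (logical).
#' @export
stable_orientation <- function(geom, ratio = 2, T0 = 1, n_quad = 64) {
  f <- function(a) net_torque_on_probe(geom, a, T0 = T0, ratio = ratio,
                                       n_quad = n_quad)
  lo <- -pi / 2 + 1e-9; hi <- pi / 2 - 1e-9
  flo <- f(lo); fhi <- f(hi)
  if (flo * fhi > 0)
    stop("no torque root bracketed in (-pi/2, pi/2)")
  root <- uniroot(f, c(lo, hi), tol = 1e-10)$root
  h <- 1e-5
  deriv <- (f(root + h) - f(root - h)) / (2 * h)
  list(angle = root, tilt_inward = -root, stable = deriv < 0)
}

#' Inward tilt of a hex-sheet edge particle vs interaction radius
#'
#' @param R_values interaction radii (r_c units), each >= 1.
#' @param ratio alignment-to-cohesion torque ratio.
#' @param spacing lattice constant (sigma).
#' @return data.frame with columns \code{R}, \code{angle},
#'   \code{tilt_inward}, \code{stable}.
#' @export
tilt_vs_radius <- function(R_values, ratio = 2, spacing = 2^(1 / 6)) {
  rows <- lapply(R_values, function(R) {
    g <- sheet_geometry("hex_halfplane", R = R, spacing = spacing)
    s <- stable_orientation(g, ratio = ratio)
    data.frame(R = R, angle = s$angle, tilt_inward = s$tilt_inward,
               stable = s$stable)
  })
  do.call(rbind, rows)
}
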