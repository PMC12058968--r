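#' Local log-log slope of a positive curve
#'
#' Centered differences of log(value) against log(lag) (one-sided at the
#' ends); lag-0 and non-positive entries are dropped.
#' @keywords internal
loglog_slope <- function(curve) {
  ok <- curve$lag > 0 & curve$value > 0
  l <- log(curve$lag[ok]); v <- log(curve$value[ok])
  n <- length(l)
  if (n < 3) stop("curve too short for slope estimation")
  s <- numeric(n)
  s[1] <- (v[2] - v[1]) / (l[2] - l[1])
  s[n] <- (v[n] - v[n - 1]) / (l[n] - l[n - 1])
  if (n > 2) s[2:(n - 1)] <- (v[3:n] - v[1:(n - 2)]) / (l[3:n] - l[1:(n - 2)])
  data.frame(lag = curve$lag[ok], slope = s)
}

#' Ballistic-to-diffusive crossover time of an MSD curve
#'
#' The crossover is the first lag at which the local log-log slope falls
#' below \code{slope_thresh} and stays below it for the following decade of
#' lag (at least the available part of it, requiring coverage out to 3x the
#' candidate lag). Returns NA when the curve never leaves the ballistic
#' regime.
#'
#' @param msd_curve data.frame with columns \code{lag}, \code{value},
#'   spanning at least two decades of positive lag.
#' @param slope_thresh slope below which motion no longer counts as
#'   ballistic (default 1.5, halfway between ballistic 2 and diffusive 1).
#' @return crossover lag (tau_R) or NA.
#' @export
estimate_crossover <- function(msd_curve, slope_thresh = 1.5) {
  sl <- loglog_slope(msd_curve)
  if (max(sl$lag) / min(sl$lag) < 100)
    stop("MSD curve must span at least two decades of lag")
  lmax <- max(sl$lag)
  for (k in seq_len(nrow(sl))) {
    l <- sl$lag[k]
    if (sl$slope[k] >= slope_thresh) next
    upper <- min(10 * l, lmax)
    if (upper < 3 * l) next  # not enough curve left to confirm
    win <- sl$slope[sl$lag >= l & sl$lag <= upper]
    if (all(win < slope_thresh)) return(l)
  }
  NA_real_
}

#' Detect oscillatory MSD/OCF signatures (rotary motion)
#'
#' Flags a run as oscillatory when the OCF reaches values below
#' \code{ocf_depth} and its discrete spectrum (after interpolation onto a
#' uniform lag grid) has a dominant nonzero-frequency peak at least
#' \code{peak_factor} times the background (median nonzero-frequency power),
#' or when the MSD shows two or more local maxima after its plateau onset
#' (first lag with log-log slope < 0.5). Returns the dominant period.
#'
#' @param msd_curve,ocf_curve data.frames with \code{lag}, \code{value}.
#' @param ocf_depth OCF value that must be undershot (default -0.1).
#' @param peak_factor spectral peak-to-background factor (default 3).
#' @return list with \code{oscillatory} (logical) and \code{period}
#'   (tau_R; NA when not detected).
#' @export
detect_oscillation <- function(msd_curve, ocf_curve,
                               ocf_depth = -0.1, peak_factor = 3) {
  ok <- ocf_curve$lag >= 0
  lag <- ocf_curve$lag[ok]; val <- ocf_curve$value[ok]
  n_grid <- 256
  grid <- seq(0, max(lag), length.out = n_grid)
  y <- approx(lag, val, xout = grid)$y
  sp <- Mod(fft(y - mean(y)))[2:(n_grid %/% 2)]
  peak_idx <- which.max(sp)
  bg <- median(sp[-peak_idx])
  peak_ratio <- if (bg > 0) sp[peak_idx] / bg else Inf
  # a single slow swing of the heading is not an oscillation: demand at
  # least two full cycles inside the observation window (peak_idx >= 2)
  ocf_flag <- min(val) < ocf_depth && peak_ratio >= peak_factor &&
    peak_idx >= 2
  period_ocf <- max(grid) / peak_idx  # frequency peak_idx cycles per window

  msd_flag <- FALSE; period_msd <- NA_real_
  sl <- tryCatch(loglog_slope(msd_curve), error = function(e) NULL)
  if (!is.null(sl) && any(sl$slope < 0.5)) {
    onset <- sl$lag[which(sl$slope < 0.5)[1]]
    v <- msd_curve$value[msd_curve$lag >= onset]
    l <- msd_curve$lag[msd_curve$lag >= onset]
    if (length(v) >= 3) {
      imax <- which(diff(sign(diff(v))) == -2) + 1
      msd_flag <- length(imax) >= 2
      if (msd_flag) period_msd <- mean(diff(l[imax]))
    }
  }
  list(oscillatory = ocf_flag || msd_flag,
       period = if (ocf_flag) period_ocf else period_msd)
}

#' Classification thresholds
#'
#' The published groupings are visual; these numeric boundaries separate
#' them and are exposed for sensitivity analysis. \code{psi_lo}/\code{psi_hi}
#' split low from high polar order, \code{s_lo} (sigma) splits compact from
#' extended clusters, \code{radial_in} is the radial-order value below which
#' a low-polar-order cluster counts as an aster, and \code{line_frac} is the
#' range of the time fraction spent box-spanning that counts as an
#' intermittent (transition) line.
#'
#' @param psi_lo,psi_hi polar-order boundaries.
#' @param s_lo cluster-size boundary (sigma).
#' @param radial_in radial-order boundary for asters.
#' @param line_size_frac fraction of the box length L that a cluster extent
#'   (or the system size) must exceed to count as box-spanning. A spanning
#'   line's extent approaches L/2 from below (minimum-image distances are
#'   capped at L/2), so this sits a little under 0.5.
#' @param line_frac length-2 range for the intermittent-line time fraction.
#' @return named list of thresholds.
#' @export
classify_thresholds <- function(psi_lo = 0.3, psi_hi = 0.6, s_lo = 5,
                                radial_in = -0.5, line_size_frac = 0.45,
                                line_frac = c(0.05, 0.95)) {
  list(psi_lo = psi_lo, psi_hi = psi_hi, s_lo = s_lo,
       radial_in = radial_in, line_size_frac = line_size_frac,
       line_frac = line_frac)
}

#' Compute the per-run summary metrics of a trajectory
#'
#' Produces the static metrics (time-averaged polar order, cluster size,
#' system size, radial order, asymmetry), the MSD/OCF curves with the
#' matching analytic ABP baselines, the crossover and oscillation
#' diagnostics, and the state label.
#'
#' @param traj a \code{trajectory}.
#' @param eps clustering cutoff (sigma).
#' @param cluster_stride evaluate cluster-based metrics on every
#'   \code{cluster_stride}-th frame (default: at most ~200 frames).
#' @param thresholds see \code{\link{classify_thresholds}}.
#' @return object of class \code{state_record}.
#' @export
analyze_trajectory <- function(traj, eps = 1.5, cluster_stride = NULL,
                               thresholds = classify_thresholds()) {
  S <- length(traj$times)
  L <- traj$params$L
  if (is.null(cluster_stride)) cluster_stride <- max(1L, S %/% 200L)
  frames <- seq(1, S, by = cluster_stride)

  psi <- mean(apply(traj$phi, 1, polar_order))

  s_c <- s_sys <- rad <- asym <- n_cl <- rep(NA_real_, length(frames))
  for (k in seq_along(frames)) {
    st <- trajectory_frame(traj, frames[k])
    lab <- find_clusters(st, eps)
    s_c[k] <- cluster_size(lab, st)
    s_sys[k] <- system_size(st, lab)
    rad[k] <- radial_order(st, lab)
    n_cl[k] <- lab$n_clusters
    a <- vapply(seq_len(lab$n_clusters), function(c) {
      p <- st$pos[lab$labels == c, , drop = FALSE]
      if (nrow(p) < 2) NA_real_ else cluster_asymmetry(p, L)
    }, numeric(1))
    asym[k] <- if (all(is.na(a))) NA_real_ else mean(a, na.rm = TRUE)
  }

  msd_curve <- msd(traj)
  ocf_curve <- ocf(traj)
  base <- abp_baselines(traj$params, msd_curve$lag)
  span_ok <- sum(msd_curve$lag > 0) >= 3 &&
    max(msd_curve$lag) / min(msd_curve$lag[msd_curve$lag > 0]) >= 100
  cross_raw <- if (span_ok)
    tryCatch(estimate_crossover(msd_curve), error = function(e) NA_real_)
    else NA_real_
  abp_cross <- if (span_ok)
    tryCatch(estimate_crossover(base$msd), error = function(e) NA_real_)
    else NA_real_
  # slope over the last decade of lag separates a crossover to diffusion
  # (tail slope ~1) from an arrest at a plateau (tail slope ~0)
  sl <- tryCatch(loglog_slope(msd_curve), error = function(e) NULL)
  tail_slope <- if (is.null(sl)) NA_real_ else
    mean(sl$slope[sl$lag >= max(sl$lag) / 10])
  # an oscillating plateau never sustains any slope band, so arrest is
  # judged from the tail slope alone, not from a detected crossover
  plateau <- !is.na(tail_slope) && tail_slope < 0.5
  crossover <- if (plateau) NA_real_ else cross_raw
  osc <- detect_oscillation(msd_curve, ocf_curve)

  rec <- structure(list(
    params = traj$params, init = traj$init, seed = traj$params$seed,
    psi = psi,
    s_c = mean(s_c), s_sys = mean(s_sys),
    line_fraction = mean(s_sys > thresholds$line_size_frac * L),
    radial_order = if (all(is.na(rad))) NA_real_ else mean(rad, na.rm = TRUE),
    asymmetry = if (all(is.na(asym))) NA_real_ else mean(asym, na.rm = TRUE),
    n_clusters = mean(n_cl), L = L,
    msd = msd_curve, ocf = ocf_curve,
    crossover = crossover, abp_crossover = abp_cross,
    tail_slope = tail_slope, plateau = plateau,
    dynamics_ok = span_ok,
    oscillation = osc, thresholds = thresholds
  ), class = "state_record")
  rec$label <- classify_state(rec, thresholds)
  rec
}

#' Assign a collective-behavior state label
#'
#' Pure decision rule on a \code{state_record}'s stored metrics. Static
#' split: aster (low polar order, extended cluster, inward radial order),
#' disperse (low polar order, compact clusters), line (high polar order,
#' box-spanning cluster extent), intermittent worm/line transition
#' (box-spanning only part of the time), multiple worm (high polar order,
#' compact clusters). Everything else is the worm family, split by dynamics:
#' persistent (diffusive crossover later than the matching free-ABP
#' crossover), rotary (no crossover, oscillatory MSD/OCF), or the
#' persistent/rotary transition (crossover at or before the ABP's, or
#' crossover coexisting with oscillations). Records matching no branch get
#' the explicit label \code{"unclassified"}, never a silent guess.
#'
#' @param record a \code{state_record} (or any list with the same metric
#'   fields).
#' @param thresholds see \code{\link{classify_thresholds}}.
#' @return one of \code{"disperse"}, \code{"multiple_worm"}, \code{"line"},
#'   \code{"persistent_worm"}, \code{"rotary_worm"}, \code{"aster"},
#'   \code{"trans_worm_line"}, \code{"trans_persistent_rotary"},
#'   \code{"unclassified"}.
#' @export
classify_state <- function(record, thresholds = classify_thresholds()) {
  th <- thresholds
  psi <- record$psi; s_c <- record$s_c; L <- record$L
  radial <- record$radial_order
  lf <- record$line_fraction
  if (psi < th$psi_lo && s_c > th$s_lo &&
      !is.na(radial) && radial < th$radial_in) return("aster")
  if (psi < th$psi_lo && s_c <= th$s_lo) return("disperse")
  if (psi >= th$psi_hi &&
      (s_c > th$line_size_frac * L ||
       (!is.na(lf) && lf >= th$line_frac[2]))) return("line")
  if (psi >= th$psi_hi && !is.na(lf) &&
      lf > th$line_frac[1] && lf < th$line_frac[2]) return("trans_worm_line")
  if (psi >= th$psi_hi && s_c <= th$s_lo) return("multiple_worm")
  # the worm-family split needs usable dynamics (an MSD spanning enough
  # decades); without it no dynamic label can be justified
  if (isFALSE(record$dynamics_ok)) return("unclassified")
  # worm family, split by dynamics. `crossover` is the ballistic-to-DIFFUSIVE
  # crossover (NA when the MSD either stays ballistic or arrests at a
  # plateau); `plateau` marks the arrested case.
  cross <- record$crossover; abp <- record$abp_crossover
  osc <- isTRUE(record$oscillation$oscillatory)
  plateau <- isTRUE(record$plateau)
  if (is.na(cross) && osc) return("rotary_worm")
  if (!osc && !is.na(cross) && !is.na(abp) && cross > abp)
    return("persistent_worm")
  if (!osc && is.na(cross) && !plateau)
    return("persistent_worm")  # ballistic through the whole window
  if (!is.na(cross) && (osc || (!is.na(abp) && cross <= abp)))
    return("trans_persistent_rotary")
  "unclassified"
}

#' @export
print.state_record <- function(x, ...) {
  cat(sprintf("state_record: label '%s'\n", x$label))
  cat(sprintf("  <Psi> = %.3f, <S_c> = %.3g, <S> = %.3g (L/2 = %.3g), line fraction %.2f\n",
              x$psi, x$s_c, x$s_sys, x$L / 2, x$line_fraction))
  cat(sprintf("  radial order %.3f, asymmetry %.3f, mean clusters %.1f\n",
              x$radial_order, x$asymmetry, x$n_clusters))
  cat(sprintf("  crossover %.3g (ABP %.3g), oscillatory %s\n",
              x$crossover, x$abp_crossover, x$oscillation$oscillatory))
  invisible(x)
}

#' Modify simulation parameters
#'
#' Re-derives all unit values after changing fields.
#'
#' @param params a \code{sim_params}.
#' @param ... fields of \code{\link{sim_params}} to change.
#' @return a new \code{sim_params}.
#' @export
update_params <- function(params, ...) {
  keep <- c("N", "Pe", "Phi", "eps", "T0", "ratio", "R", "dt", "t_equil",
            "t_collect", "sample_interval", "seed", "min_sep")
  args <- modifyList(unclass(params)[keep], list(...))
  do.call(sim_params, args)
}

#' Sweep the (R, T0) plane and build a state diagram
#'
#' Runs one simulation per (interaction radius, torque strength,
#' initialization, seed) combination, classifies each, and aggregates label
#' occurrence counts per parameter cell. Failed runs are recorded with label
#' \code{"failed"}, never dropped.
#'
#' @param base a \code{sim_params} supplying everything except R and T0.
#' @param R_values interaction radii (r_c units).
#' @param T0_values torque strengths (kBT).
#' @param inits character vector of initializer names.
#' @param seeds integer seeds (one run per seed per cell per init).
#' @param init_args optional named list keyed by initializer name, each an
#'   argument list forwarded to that initializer (e.g.
#'   \code{list(worm = list(width = 2))}).
#' @param eps clustering cutoff for the analysis.
#' @param thresholds see \code{\link{classify_thresholds}}.
#' @param verbose print one line per completed run.
#' @return object of class \code{state_diagram}: list with \code{runs}
#'   (one row per run: R, T0, init, seed, label and key metrics) and
#'   \code{counts} (per-cell label multisets).
#' @export
sweep_state_diagram <- function(base, R_values, T0_values,
                                inits = "lattice_random", seeds = 1L,
                                init_args = list(), eps = 1.5,
                                thresholds = classify_thresholds(),
                                verbose = FALSE) {
  grid <- expand.grid(R = R_values, T0 = T0_values, init = inits,
                      seed = seeds, stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(k) {
    g <- grid[k, ]
    res <- tryCatch({
      p <- update_params(base, R = g$R, T0 = g$T0, seed = g$seed)
      extra <- if (g$init %in% names(init_args)) init_args[[g$init]]
               else list()
      rec <- analyze_trajectory(
        do.call(run_simulation, c(list(p, g$init), extra)),
        eps = eps, thresholds = thresholds)
      data.frame(g, label = rec$label, psi = rec$psi, s_c = rec$s_c,
                 radial = rec$radial_order, asym = rec$asymmetry,
                 error = NA_character_)
    }, error = function(e) {
      data.frame(g, label = "failed", psi = NA, s_c = NA, radial = NA,
                 asym = NA, error = conditionMessage(e))
    })
    if (verbose)
      message(sprintf("R=%g T0=%g %s seed=%d -> %s",
                      g$R, g$T0, g$init, g$seed, res$label))
    res
  })
  runs <- do.call(rbind, rows)
  counts <- table(cell = paste0("R=", runs$R, ",T0=", runs$T0), runs$label)
  structure(list(runs = runs, counts = counts), class = "state_diagram")
}

#' @export
print.state_diagram <- function(x, ...) {
  cat(sprintf("state_diagram: %d runs over %d cells\n", nrow(x$runs),
              nrow(x$counts)))
  print(x$counts)
  invisible(x)
}
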