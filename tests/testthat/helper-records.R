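# synthetic state records built straight from the decision-rule definitions
make_record <- function(label, L = 56, seed = 1) {
  set.seed(seed)
  lags <- c(0, exp(seq(log(0.05), log(100), length.out = 50)))
  p <- sim_params(N = 100, Phi = 0.025, seed = seed)
  abp <- abp_baselines(p, lags)
  noise <- function(x, rel = 0.02) x * exp(rnorm(length(x), 0, rel))
  ballistic <- function(t) (p$v0 * t)^2
  # diffusive beyond a crossover tc, ballistic before
  cross_msd <- function(t, tc) ifelse(t < tc, ballistic(t),
                                      ballistic(tc) * pmax(t, tc) / tc)
  plateau_osc <- function(t, tc, per) {
    ifelse(t < tc, ballistic(t),
           ballistic(tc) * (1 + 0.3 * sin(2 * pi * (t - tc) / per)))
  }
  slow_ocf <- function(t) exp(-t / 50)
  osc_ocf <- function(t, per) cos(2 * pi * t / per) * exp(-t / 200)

  base <- list(psi = 0.9, s_c = 10, s_sys = 10, line_fraction = 0,
               radial_order = 0, asymmetry = 0.9, n_clusters = 1, L = L,
               crossover = NA_real_, abp_crossover = 2.2,
               tail_slope = 2, plateau = FALSE,
               oscillation = list(oscillatory = FALSE, period = NA_real_))
  mk_curves <- function(msd_v, ocf_v) {
    list(msd = data.frame(lag = lags, value = msd_v),
         ocf = data.frame(lag = lags, value = ocf_v))
  }
  rec <- switch(label,
    disperse = {
      base$psi <- runif(1, 0.02, 0.2); base$s_c <- runif(1, 0, 3)
      cv <- mk_curves(noise(abp$msd$value), abp$ocf$value)
      base$crossover <- 2.2; base$tail_slope <- 1
      c(base, cv)
    },
    aster = {
      base$psi <- runif(1, 0.02, 0.2); base$s_c <- runif(1, 8, 15)
      base$radial_order <- runif(1, -1, -0.7)
      base$plateau <- TRUE; base$tail_slope <- 0.1
      cv <- mk_curves(plateau_osc(lags, 0.3, 1e9), slow_ocf(lags))
      c(base, cv)
    },
    multiple_worm = {
      base$psi <- runif(1, 0.65, 0.95); base$s_c <- runif(1, 0.5, 4)
      cv <- mk_curves(noise(ballistic(pmax(lags, 1e-9))), slow_ocf(lags))
      c(base, cv)
    },
    line = {
      base$psi <- runif(1, 0.8, 0.99); base$s_c <- runif(1, 0.46, 0.5) * L
      base$line_fraction <- 1; base$s_sys <- base$s_c
      cv <- mk_curves(noise(ballistic(pmax(lags, 1e-9))), slow_ocf(lags))
      c(base, cv)
    },
    trans_worm_line = {
      base$psi <- runif(1, 0.7, 0.95); base$s_c <- runif(1, 6, 20)
      base$line_fraction <- runif(1, 0.2, 0.8)
      cv <- mk_curves(noise(ballistic(pmax(lags, 1e-9))), slow_ocf(lags))
      c(base, cv)
    },
    persistent_worm = {
      base$psi <- runif(1, 0.7, 0.95); base$s_c <- runif(1, 6, 20)
      tc <- runif(1, 8, 30)
      base$crossover <- tc; base$tail_slope <- 1
      cv <- mk_curves(noise(cross_msd(lags, tc)), slow_ocf(lags))
      c(base, cv)
    },
    rotary_worm = {
      base$psi <- runif(1, 0.35, 0.6); base$s_c <- runif(1, 6, 12)
      per <- runif(1, 5, 15)
      base$plateau <- TRUE; base$tail_slope <- 0.05
      base$oscillation <- list(oscillatory = TRUE, period = per)
      cv <- mk_curves(plateau_osc(lags, 2, per), osc_ocf(lags, per))
      c(base, cv)
    },
    trans_persistent_rotary = {
      base$psi <- runif(1, 0.45, 0.7); base$s_c <- runif(1, 6, 12)
      tc <- runif(1, 0.5, 1.5)
      base$crossover <- tc; base$tail_slope <- 0.8
      base$oscillation <- list(oscillatory = TRUE,
                               period = runif(1, 5, 15))
      cv <- mk_curves(noise(cross_msd(lags, tc)), osc_ocf(lags, 10))
      c(base, cv)
    },
    stop("unknown label"))
  structure(rec, class = "state_record")
}
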