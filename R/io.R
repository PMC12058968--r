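#' Load a run configuration from YAML
#'
#' An empty (or absent-key) file yields the default parameter set
#' (Pe = 80, Phi = 0.025, N = 1000, eps = 100, ratio = 2, ...). Unknown keys
#' are rejected with their paths. Recognized top-level keys are the fields of
#' \code{\link{sim_params}}, plus \code{init} (initializer name),
#' \code{init_args} (list passed to the initializer) and \code{analysis}
#' (currently \code{eps}).
#'
#' @param path YAML file path.
#' @return list with \code{params} (a \code{sim_params}), \code{init},
#'   \code{init_args} and \code{analysis}.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  # YAML 1.1 parses a bare key `N` as a boolean; map it back
  names(cfg)[names(cfg) == "FALSE"] <- "N"
  param_keys <- setdiff(names(formals(sim_params)), "...")
  known <- c(param_keys, "init", "init_args", "analysis")
  bad <- setdiff(names(cfg), known)
  if (length(bad))
    stop("unknown config keys: ", paste(bad, collapse = ", "))
  if (!is.null(cfg$analysis)) {
    bad_a <- setdiff(names(cfg$analysis), "eps")
    if (length(bad_a))
      stop("unknown config keys: ", paste0("analysis.", bad_a, collapse = ", "))
  }
  params <- do.call(sim_params, cfg[intersect(names(cfg), param_keys)])
  init <- if (is.null(cfg$init)) "lattice_random" else cfg$init
  if (!init %in% c("lattice_random", "hex_cluster_inward",
                   "hex_cluster_random", "worm"))
    stop("unknown initializer in config: ", init)
  list(params = params,
       init = init,
       init_args = if (is.null(cfg$init_args)) list() else cfg$init_args,
       analysis = list(eps = if (is.null(cfg$analysis$eps)) 1.5
                             else cfg$analysis$eps))
}

#' Save a run configuration to YAML
#'
#' Writes only the primary fields of \code{sim_params} (derived values are
#' recomputed on load), so save/load round-trips are exact.
#'
#' @param config a list as returned by \code{\link{load_config}}.
#' @param path output YAML path.
#' @return \code{path}, invisibly.
#' @export
save_config <- function(config, path) {
  keys <- setdiff(names(formals(sim_params)), "...")
  out <- unclass(config$params)[keys]
  out$init <- config$init
  if (length(config$init_args)) out$init_args <- config$init_args
  out$analysis <- config$analysis
  yaml::write_yaml(out, path)
  invisible(path)
}

.traj_format <- "cohesim-trajectory"
.traj_version <- 1L

#' Write / read a trajectory container
#'
#' Lossless round trip of times, wrapped positions, image counters,
#' orientations and the full parameter set, in a versioned serialized
#' container. Corrupt or version-mismatched files are rejected.
#'
#' @param traj a \code{trajectory}.
#' @param path file path.
#' @return \code{path} invisibly (write); the \code{trajectory} (read).
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory"))
  saveRDS(list(format = .traj_format, version = .traj_version,
               times = traj$times, pos = traj$pos, image = traj$image,
               phi = traj$phi, params = unclass(traj$params),
               init = traj$init),
          path)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  obj <- tryCatch(readRDS(path), error = function(e)
    stop("corrupt or unreadable trajectory file: ", path, call. = FALSE))
  if (!identical(obj$format, .traj_format))
    stop("not a trajectory container: ", path)
  if (!identical(obj$version, .traj_version))
    stop("trajectory container version mismatch in ", path)
  structure(list(times = obj$times, pos = obj$pos, image = obj$image,
                 phi = obj$phi,
                 params = structure(obj$params, class = "sim_params"),
                 init = obj$init),
            class = "trajectory")
}

#' Export a trajectory as extended XYZ text
#'
#' One block per frame: an atom count line, a comment line carrying the time
#' stamp and box length, then N lines "P x y 0 phi" (z = 0 for visualization
#' tools expecting 3D coordinates).
#'
#' @param traj a \code{trajectory}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_xyz <- function(traj, path) {
  S <- length(traj$times); N <- dim(traj$pos)[2]
  con <- file(path, "w")
  on.exit(close(con))
  for (s in seq_len(S)) {
    writeLines(c(as.character(N),
                 sprintf("t=%g L=%g", traj$times[s], traj$params$L)), con)
    writeLines(sprintf("P %.8g %.8g 0 %.8g",
                       traj$pos[s, , 1], traj$pos[s, , 2], traj$phi[s, ]), con)
  }
  invisible(path)
}

#' Write the scalar metrics of a state record as JSON
#'
#' @param record a \code{state_record}.
#' @param path output JSON path.
#' @return \code{path}, invisibly.
#' @export
write_metrics_json <- function(record, path) {
  out <- list(label = record$label, psi = record$psi, s_c = record$s_c,
              s_sys = record$s_sys, line_fraction = record$line_fraction,
              radial_order = record$radial_order,
              asymmetry = record$asymmetry, n_clusters = record$n_clusters,
              crossover = record$crossover,
              abp_crossover = record$abp_crossover,
              oscillatory = record$oscillation$oscillatory,
              oscillation_period = record$oscillation$period)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
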