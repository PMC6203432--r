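#' Network configuration presets
#'
#' `"full"` is the published architecture: five 128 x 128 grid modules
#' (gains `module_gain(1:5)`), 32 border units, 64 place units with 500
#' grid afferents each, Bernoulli spiking, 60 min familiarization and
#' 30 min test trials.  `"desk"` is a scaled-down profile for interactive
#' use and CI: two 64 x 64 modules, 10 min familiarization, 10 min test
#' trials.  All dynamics constants are identical across presets.
#'
#' @param preset `"full"` or `"desk"`.
#' @param ... overrides (any of the returned fields, plus any
#'   [dynamics_constants()] name passed through).
#' @return named list: `n_modules`, `nside`, `gains`, `n_border`,
#'   `n_place`, `familiarize_s`, `test_s`, `settle_s`, `orientation_deg`,
#'   `seed_period_units`, `rate_based`, `rec_per_module`, `constants`.
#' @export
network_config <- function(preset = c("full", "desk"), ...) {
  preset <- match.arg(preset)
  cfg <- switch(preset,
    full = list(n_modules = 5L, nside = 128L, n_border = 32L, n_place = 64L,
                familiarize_s = 3600, test_s = 1800, settle_s = 2,
                orientation_deg = -7.5, seed_period_units = 16.7,
                rate_based = FALSE, rec_per_module = 30L),
    desk = list(n_modules = 2L, nside = 64L, n_border = 32L, n_place = 64L,
                familiarize_s = 600, test_s = 600, settle_s = 2,
                orientation_deg = -7.5, seed_period_units = 16.7,
                rate_based = FALSE, rec_per_module = 30L))
  cfg$gains <- module_gain(seq_len(cfg$n_modules))
  dots <- list(...)
  const_names <- names(dynamics_constants())
  cfg$constants <- do.call(dynamics_constants,
                           dots[names(dots) %in% const_names])
  rest <- dots[!(names(dots) %in% const_names)]
  unknown <- setdiff(names(rest), names(cfg))
  if (length(unknown) > 0)
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  cfg[names(rest)] <- rest
  cfg$preset <- preset
  cfg
}

#' Initialise a naive network
#'
#' Draws initial border-to-grid weights uniformly on `[0, 0.025]`,
#' grid-to-place weights uniformly on `[0, 0.022]` over 500 grid afferents
#' per place unit (sampled uniformly at random across modules, without
#' replacement), and zero activations everywhere.
#'
#' @param config a [network_config()].
#' @param seed optional RNG seed (wiring + weights).
#' @return object of class `gt_network`.
#' @export
init_network <- function(config = network_config("desk"), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  k <- config$constants
  nm <- config$n_modules
  nunit <- config$nside^2
  modules <- lapply(seq_len(nm), function(m) {
    list(nside = as.integer(config$nside), gain = config$gains[m],
         a = numeric(nunit),
         w_bg = matrix(stats::runif(nunit * config$n_border, 0, k$w_bg_max),
                       nunit, config$n_border))
  })
  place <- init_place_layer(n_grid = nm * nunit, n_place = config$n_place,
                            n_aff = k$n_place_aff, w_max = k$w_gp_max)
  structure(list(config = config, modules = modules, place = place,
                 a_border = numeric(config$n_border),
                 cache = NULL, familiar_env = NULL, settled = FALSE),
            class = "gt_network")
}

#' @export
print.gt_network <- function(x, ...) {
  cat(sprintf(
    "<gt_network %d module(s) of %d^2 units, %d border, %d place units%s>\n",
    x$config$n_modules, x$config$nside, x$config$n_border,
    x$config$n_place,
    if (!is.null(x$cache)) ", familiarized" else ""))
  invisible(x)
}

# shared runner: packs network + trajectory into the C++ core
.run_network <- function(net, env, traj, learn, snapshot, rate_based,
                         rec_grid = integer(0), record_place = TRUE,
                         use_border = TRUE) {
  k <- net$config$constants
  n <- length(traj$t)
  disp <- cbind(c(0, diff(traj$x)), c(0, diff(traj$y)))
  ras <- rasterize_positions(env, traj$x, traj$y)
  pix <- as.integer(ras$idx - 1L)
  npix <- as.integer(ras$nx * ras$ny)
  bdrive <- if (use_border) border_drive(traj, env)
            else list(ptr = integer(n + 1), idx = integer(0))
  # sample 1 is the start state; the engine consumes one step per
  # subsequent sample, with border drive evaluated at the new position
  disp_steps <- disp[-1, , drop = FALSE]
  counts <- diff(bdrive$ptr)[-1]
  csr <- list(ptr = as.integer(c(0L, cumsum(counts))),
              idx = as.integer(bdrive$idx[seq.int(bdrive$ptr[2] + 1,
                                                  length.out = sum(counts))]))
  place_arg <- if (record_place && !is.null(net$place))
    list(aff = net$place$aff - 1L, w_gp = net$place$w_gp,
         a = net$place$a %||% numeric(net$config$n_place))
  else NULL
  mods <- lapply(net$modules, function(m)
    list(nside = m$nside, gain = m$gain, a = m$a,
         w_bg = if (use_border) m$w_bg else NULL))
  res <- .sim_core_cpp(disp_steps, pix[-1], npix, mods, csr, place_arg,
                       as.integer(rec_grid - 1L),
                       .engine_cfg(k, learn = learn, rate_based = rate_based,
                                   snapshot = snapshot))
  res$ras <- ras
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Familiarize a naive network with an environment
#'
#' Implements the familiarization protocol: the grid sheets first settle
#' into their orientation-biased attractor state for `settle_s` seconds
#' with zero velocity and no learning; the virtual rat then explores the
#' environment along a bounded random walk with Hebbian learning on.
#' Full sheet activation snapshots are recorded per visited 2.5 cm pixel
#' (last visit wins), forming the position-state cache used to reinstate
#' grid activity at the start of later test trials.
#'
#' @param net a naive `gt_network`.
#' @param env the familiar environment.
#' @param duration_s exploration time (default from the config preset).
#' @param seed RNG seed for path + spiking.
#' @param traj optional externally generated trajectory (overrides the
#'   random walk).
#' @return the familiarized network, with `cache`, `familiar_env`,
#'   `familiar_traj` and updated weights.
#' @export
familiarize <- function(net, env, duration_s = net$config$familiarize_s,
                        seed = NULL, traj = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cfg <- net$config
  # settle each module (no learning, zero velocity, no border input)
  for (m in seq_along(net$modules)) {
    st <- settle_module(cfg$nside, cfg$gains[m], duration_s = cfg$settle_s,
                        orientation_deg = cfg$orientation_deg,
                        period_units = cfg$seed_period_units,
                        config = cfg$constants)
    net$modules[[m]]$a <- st$a
  }
  if (is.null(traj)) traj <- random_walk(env, duration_s,
                                         dt_s = cfg$constants$dt)
  res <- .run_network(net, env, traj, learn = TRUE, snapshot = TRUE,
                      rate_based = cfg$rate_based)
  for (m in seq_along(net$modules)) {
    net$modules[[m]]$a <- res$modules[[m]]$a
    net$modules[[m]]$w_bg <- res$modules[[m]]$w_bg
  }
  net$place$w_gp <- res$w_gp
  net$place$a <- res$a_place
  net$a_border <- res$a_border
  net$cache <- list(snapshots = res$snapshots, seen = res$snapshot_seen,
                    ras = res$ras)
  net$familiar_env <- env
  net$familiar_traj <- traj
  net
}

#' Run a post-familiarization test trial
#'
#' Weights are the (fixed) post-familiarization weights; learning is off.
#' Grid activity is reinstated from the position-state cache entry of the
#' pixel containing the rat's start location (nearest cached pixel on a
#' miss), then the rat explores the test environment.  Spikes of
#' `rec_per_module` randomly chosen grid units per module and of all
#' place units are recorded.
#'
#' @param net a familiarized `gt_network`.
#' @param env test environment (possibly deformed).
#' @param duration_s test duration (default from config).
#' @param seed RNG seed (unit sampling, path, spiking).
#' @param traj optional externally supplied trajectory.
#' @param rec_grid optional explicit global grid unit ids (1-based) to
#'   record; default samples `rec_per_module` per module.
#' @return list with `traj`, `spikes` (list: `grid` data frame
#'   `unit`,`t` with `unit` the global grid id; `place`; `border`),
#'   `rec_grid` (recorded ids), `rate_counts` (rate-based runs only),
#'   `env`.
#' @export
test_trial <- function(net, env, duration_s = net$config$test_s,
                       seed = NULL, traj = NULL, rec_grid = NULL) {
  if (is.null(net$cache)) stop("network has not been familiarized")
  if (!is.null(seed)) set.seed(seed)
  cfg <- net$config
  nunit <- cfg$nside^2
  if (is.null(rec_grid)) {
    rec_grid <- unlist(lapply(seq_len(cfg$n_modules), function(m)
      sample.int(nunit, cfg$rec_per_module) + (m - 1) * nunit))
  }
  if (is.null(traj)) traj <- random_walk(env, duration_s,
                                         dt_s = cfg$constants$dt)
  # reinstate grid state from the cache at the start pixel
  start <- c(traj$x[1], traj$y[1])
  net <- reinstate_from_cache(net, start)
  res <- .run_network(net, env, traj, learn = FALSE, snapshot = FALSE,
                      rate_based = cfg$rate_based, rec_grid = rec_grid)
  dt <- cfg$constants$dt
  out <- list(traj = traj, env = env, rec_grid = rec_grid)
  if (cfg$rate_based) {
    out$rate_counts <- list(grid = res$rec_counts, place = res$place_counts,
                            ras = res$ras)
  } else {
    out$spikes <- list(
      grid = data.frame(unit = rec_grid[res$grid_spikes$slot + 1],
                        t = traj$t[res$grid_spikes$step + 2]),
      place = data.frame(unit = res$place_spikes$unit + 1,
                         t = traj$t[res$place_spikes$step + 2]),
      border = data.frame(unit = res$border_spikes$unit + 1,
                          t = traj$t[res$border_spikes$step + 2]))
  }
  out
}

#' Reinstate grid activity from the familiarization cache
#'
#' Sets each module's sheet activation to the cached familiar-environment
#' state at the pixel containing `point` (cm, familiar-environment
#' coordinates); if that pixel was never visited during familiarization
#' the nearest cached pixel is used.
#'
#' @param net familiarized network.
#' @param point length-2 numeric (x, y) in cm.
#' @return network with reinstated activations.
#' @export
reinstate_from_cache <- function(net, point) {
  if (is.null(net$cache)) stop("empty cache")
  ras <- net$cache$ras
  seen <- which(net$cache$seen)
  if (length(seen) == 0) stop("empty cache")
  p <- net$familiar_env$pixel_cm
  ix <- pmin(pmax(floor(point[1] / p), 0), ras$nx - 1) + 1
  iy <- pmin(pmax(floor(point[2] / p), 0), ras$ny - 1) + 1
  idx <- (iy - 1) * ras$nx + ix
  if (!net$cache$seen[idx]) {
    sx <- (seen - 1) %% ras$nx + 1; sy <- (seen - 1) %/% ras$nx + 1
    idx <- seen[which.min((sx - ix)^2 + (sy - iy)^2)]
  }
  for (m in seq_along(net$modules))
    net$modules[[m]]$a <- net$cache$snapshots[[m]][, idx]
  net
}

#' Simulate settled grid modules along a trajectory (path integration only)
#'
#' Convenience runner for grid-scale and orientation measurements: settles
#' one module per gain, runs the sheet dynamics along the trajectory with
#' no border input and no learning, and accumulates spike (or expected
#' spike) counts per pixel for a random sample of units.
#'
#' Several trajectory segments may be given (a list); each segment is run
#' from the same settled state, so segments that share a start position
#' share the same spatial phase and their maps pool coherently.  Short
#' segments curb the slow loss of pattern coherence that accumulates
#' along long uncorrected paths (without border input nothing re-anchors
#' the phase).
#'
#' @param gains numeric vector of module gains.
#' @param nside sheet side (power of two).
#' @param traj a `gt_trajectory`, or a list of them (segments with a
#'   common start position).
#' @param env the environment the trajectory lives in.
#' @param n_record units sampled per module.
#' @param rate_based run fully deterministic expected-spike dynamics
#'   (default FALSE: Bernoulli spiking, the published dynamics; the
#'   recorded units' maps are still built from per-step expected counts,
#'   which denoises them without altering the network evolution).
#' @param seed optional RNG seed.
#' @param orientation_deg rate-map axis bias passed to [settle_module()].
#' @param constants dynamics constants.
#' @return list of per-module lists with `counts` (n_record x npix),
#'   `ras` (rasterisation info), `units` (sampled unit ids).
#' @export
simulate_grid_modules <- function(gains, nside, traj, env, n_record = 15,
                                  rate_based = FALSE, seed = NULL,
                                  orientation_deg = -7.5,
                                  constants = dynamics_constants()) {
  if (!is.null(seed)) set.seed(seed)
  segs <- if (inherits(traj, "gt_trajectory")) list(traj) else traj
  nunit <- nside^2
  ras1 <- rasterize_positions(env, segs[[1]]$x, segs[[1]]$y)
  npix <- as.integer(ras1$nx * ras1$ny)
  out <- vector("list", length(gains))
  for (m in seq_along(gains)) {
    st <- settle_module(nside, gains[m], orientation_deg = orientation_deg,
                        config = constants)
    units <- sample.int(nunit, n_record)
    counts <- matrix(0, n_record, npix)
    seg_counts <- vector("list", length(segs))
    for (k in seq_along(segs)) {
      sg <- segs[[k]]
      n <- length(sg$t)
      disp <- cbind(diff(sg$x), diff(sg$y))
      pix <- as.integer(rasterize_positions(env, sg$x, sg$y)$idx - 1L)[-1]
      mod <- list(nside = as.integer(nside), gain = gains[m], a = st$a,
                  w_bg = NULL)
      res <- .sim_core_cpp(disp, pix, npix, list(mod),
                           list(ptr = integer(n), idx = integer(0)), NULL,
                           as.integer(units - 1L),
                           .engine_cfg(constants, learn = FALSE,
                                       rate_based = rate_based,
                                       snapshot = FALSE,
                                       record_expected = TRUE))
      seg_counts[[k]] <- res$rec_counts
      counts <- counts + res$rec_counts
    }
    out[[m]] <- list(counts = counts, seg_counts = seg_counts, ras = ras1,
                     units = units, gain = gains[m])
  }
  out
}

#' Pool trajectory segments under a spatial-stability criterion
#'
#' The standard session-stability inclusion criterion applied to
#' segments: each segment's rate map (all recorded units pooled) is
#' correlated with the map pooled over the remaining segments, and
#' segments whose correlation falls below `min_r` are excluded.  This
#' rejects the occasional segment in which accumulated path-integration
#' error displaced the grid phase.
#'
#' @param sim_module one element of the [simulate_grid_modules()] result
#'   (with `seg_counts`).
#' @param segs the list of trajectory segments it was run on.
#' @param env the environment.
#' @param min_r inclusion threshold (default 0.4).
#' @return list with `counts` (pooled over kept segments), `traj`
#'   (concatenated kept segments), `kept` (logical per segment).
#' @export
pool_stable_segments <- function(sim_module, segs, env, min_r = 0.4) {
  K <- length(sim_module$seg_counts)
  if (K == 1) {
    return(list(counts = sim_module$counts, traj = segs[[1]],
                kept = TRUE))
  }
  n_rec <- nrow(sim_module$seg_counts[[1]])
  u_probe <- seq_len(min(n_rec, 5))      # a few units suffice
  seg_map <- function(counts, sg, u) {
    rate_map(sg, NULL, env, spike_counts = counts[u, ])$rate
  }
  keep <- logical(K)
  for (k in seq_len(K)) {
    rest_counts <- Reduce(`+`, sim_module$seg_counts[-k])
    rest_traj <- concat_trajectories(segs[-k])
    rs <- vapply(u_probe, function(u) {
      a <- seg_map(sim_module$seg_counts[[k]], segs[[k]], u)
      b <- seg_map(rest_counts, rest_traj, u)
      ok <- !is.na(a) & !is.na(b)
      if (sum(ok) < 50) return(NA_real_)
      suppressWarnings(stats::cor(a[ok], b[ok]))
    }, numeric(1))
    keep[k] <- mean(rs, na.rm = TRUE) >= min_r
  }
  keep[is.na(keep)] <- FALSE
  if (!any(keep)) keep <- rep(TRUE, K)   # degenerate: keep everything
  counts <- Reduce(`+`, sim_module$seg_counts[keep])
  list(counts = counts, traj = concat_trajectories(segs[keep]),
       kept = keep)
}

#' Concatenate trajectory segments
#'
#' Joins segments end to end on a common clock (for occupancy maps over
#' pooled segments).
#'
#' @param segs list of `gt_trajectory` objects with equal `dt_s`.
#' @return a `gt_trajectory`.
#' @export
concat_trajectories <- function(segs) {
  dt <- segs[[1]]$dt_s
  structure(list(
    t = seq(0, by = dt,
            length.out = sum(vapply(segs, function(s) length(s$t),
                                    integer(1)))),
    x = unlist(lapply(segs, `[[`, "x")),
    y = unlist(lapply(segs, `[[`, "y")),
    dt_s = dt,
    speed_cms = unlist(lapply(segs, `[[`, "speed_cms")),
    heading_deg = unlist(lapply(segs, `[[`, "heading_deg"))),
    class = "gt_trajectory")
}

#' Save / load a network checkpoint
#'
#' Checkpoints (weights, cache, config) are runtime artifacts stored with
#' R's native serialisation.
#'
#' @param net a `gt_network`.
#' @param path file path.
#' @export
save_checkpoint <- function(net, path) {
  saveRDS(net, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  net <- readRDS(path)
  stopifnot(inherits(net, "gt_network"))
  net
}
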