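#' Velocity gain of a grid module
#'
#' Gains follow a geometric series across modules with ratio `1/sqrt(2)`,
#' starting from the smallest-scale (largest-gain) module:
#' `g_m = g1 * 2^(-(m-1)/2)`.  Because grid spatial scale is inversely
#' proportional to the gain, consecutive module scales have ratio
#' `sqrt(2) ~ 1.42`.
#'
#' @param m module index, 1 to `n_max` (vectorised).
#' @param g1 gain of module 1 (default 0.45).
#' @param n_max number of modules (default 5).
#' @return numeric gain(s).
#' @export
module_gain <- function(m, g1 = 0.45, n_max = 5) {
  if (any(m < 1 | m > n_max)) stop("module index out of range")
  g1 * 2^(-(m - 1) / 2)
}

#' Movement-direction-specific excitatory input
#'
#' `v_j = gamma + g_m * d * cos(theta - phi_j)` where `d` is the distance
#' moved since the previous timestep (cm), `theta` the movement direction
#' and `phi_j` the unit's preferred direction.
#'
#' @param d_cm distance moved this step (cm).
#' @param theta_deg movement direction, degrees ccw from east.
#' @param phi_deg preferred direction, degrees ccw from east.
#' @param gain module gain g_m.
#' @param gamma baseline drive (default 0.6).
#' @return numeric.
#' @export
velocity_input <- function(d_cm, theta_deg, phi_deg, gain, gamma = 0.6) {
  stopifnot(all(d_cm >= 0))
  gamma + gain * d_cm * cos((theta_deg - phi_deg) * pi / 180)
}

#' Preferred directions of sheet units
#'
#' Each 2x2 tile of the sheet carries one unit of each preferred direction
#' in a fixed layout (within a tile: NW unit prefers N, NE prefers E, SW
#' prefers W, SE prefers S, with row index increasing northwards).
#'
#' @param nside sheet side in units (power of two).
#' @return character vector length `nside^2` of `"E","N","W","S"`, in
#'   row-major unit order (unit index = row * nside + col, 0-based).
#' @export
sheet_directions <- function(nside) {
  c("E", "N", "W", "S")[.unit_dirs_cpp(as.integer(nside)) + 1]
}

#' Shifted radial inhibition: out-neighbourhood of one unit
#'
#' Unit `j` inhibits all units within toroidal Euclidean distance
#' `radius` (inclusive) of the point `shift` units away from `j` along its
#' preferred direction, with uniform weight `weight`.
#'
#' @param nside sheet side.
#' @param unit 0-based unit index (row-major, row = y).
#' @param radius inhibition radius in units (default 12).
#' @param shift centre shift in units (default 2).
#' @return 0-based integer vector of inhibited unit indices.
#' @export
inhibition_targets <- function(nside, unit, radius = 12, shift = 2) {
  r <- unit %/% nside; c0 <- unit %% nside
  dir <- sheet_directions(nside)[unit + 1]
  dv <- switch(dir, E = c(1, 0), N = c(0, 1), W = c(-1, 0), S = c(0, -1))
  cr <- r + shift * dv[2]; cc <- c0 + shift * dv[1]
  off <- expand.grid(dr = -radius:radius, dc = -radius:radius)
  off <- off[off$dr^2 + off$dc^2 <= radius^2, ]
  rr <- (cr + off$dr) %% nside
  cc2 <- (cc + off$dc) %% nside
  sort(rr * nside + cc2)
}

#' Out-degree of the inhibition disc
#'
#' Number of lattice points within Euclidean distance `radius` of a point;
#' identical for every unit by translation invariance on the torus.
#'
#' @param radius inhibition radius (default 12).
#' @return integer.
#' @export
inhibition_outdegree <- function(radius = 12) {
  .disc_size_cpp(as.integer(radius))
}

#' Hexagonal seed template for orientation-biased initialisation
#'
#' A weak hexagonal activation pattern used to bias the orientation of the
#' attractor state before settling: the sum of three plane-wave cosines
#' with wavevectors 60 degrees apart.  `axis_deg` is the desired direction
#' of a lattice axis (peak-to-peak direction) on the sheet, measured ccw
#' from the +column direction; the wavevectors are placed 30 degrees off
#' the axes.
#'
#' @param nside sheet side.
#' @param axis_deg lattice axis angle on the sheet, degrees.
#' @param period_units lattice period in sheet units.
#' @param amp template amplitude.
#' @param noise_amp uniform noise amplitude added on top.
#' @return numeric vector length `nside^2` (row-major), non-negative.
#' @export
hex_template <- function(nside, axis_deg = -7.5, period_units = 16.7,
                         amp = 0.3, noise_amp = 0.02) {
  idx <- 0:(nside * nside - 1)
  r <- idx %/% nside; c0 <- idx %% nside
  k <- 4 * pi / (sqrt(3) * period_units)    # wavevector magnitude
  tot <- numeric(length(idx))
  for (ang in (axis_deg + 30) + c(0, 60, 120)) {
    a <- ang * pi / 180
    tot <- tot + cos(k * (cos(a) * c0 + sin(a) * r))
  }
  pmax(amp * (tot + 1.5) / 4.5, 0) + noise_amp * stats::runif(length(idx))
}

#' Settle a grid module into its attractor state
#'
#' Runs the sheet dynamics with zero velocity for `duration_s` seconds
#' (no learning, no border input) from an orientation-biased hexagonal
#' seed, and returns the settled activation state.  Settling is verified
#' by requiring a positive gridness of the sheet-activation
#' autocorrelogram; failure raises an error.
#'
#' @param nside sheet side (power of two).
#' @param gain module gain (irrelevant at zero velocity but stored).
#' @param duration_s settling time (default 2 s).
#' @param orientation_deg desired rate-map axis angle nearest east, in
#'   degrees ccw (default -7.5).  Sheet row index maps to north and
#'   column index to east; the rate-map axis matches the settled sheet
#'   axis, so the template targets the same angle.
#' @param period_units seed lattice period on the sheet.
#' @param seed optional RNG seed.
#' @param config dynamics constants, see [dynamics_constants()].
#' @param check verify the settled pattern is grid-like (default TRUE).
#' @param refine probe a few seed angles around the target and keep the
#'   settled state whose axis is closest (default TRUE); the torus only
#'   admits discrete stable orientations.
#' @return list with `a` (settled activations), `nside`, `gain`,
#'   `orientation_deg`, `sheet_axis_deg` (the axis actually attained).
#' @export
settle_module <- function(nside, gain, duration_s = 2,
                          orientation_deg = -7.5, period_units = 16.7,
                          seed = NULL, config = dynamics_constants(),
                          check = TRUE, refine = TRUE) {
  if (!is.null(seed)) set.seed(seed)
  target <- .sheet_axis_angle(orientation_deg)
  offsets <- if (refine) c(0, -1.5, 1.5, -3, 3) else 0
  n_steps <- round(duration_s / config$dt)
  disp <- matrix(0, n_steps, 2)
  cand <- list()
  for (off in offsets) {
    a0 <- hex_template(nside, axis_deg = target + off,
                       period_units = period_units)
    mod <- list(nside = as.integer(nside), gain = gain, a = a0, w_bg = NULL)
    res <- .sim_core_cpp(disp, rep(-1L, n_steps), 0L, list(mod),
                         list(ptr = integer(n_steps + 1), idx = integer(0)),
                         NULL, integer(0),
                         .engine_cfg(config, learn = FALSE,
                                     rate_based = FALSE, snapshot = FALSE))
    a <- res$modules[[1]]$a
    ax <- tryCatch(.sheet_axis(a, nside), error = function(e) NA_real_)
    g <- .sheet_gridness(a, nside)
    cand[[length(cand) + 1]] <- list(a = a, axis = ax, grid = g)
    if (is.finite(ax) && is.finite(g) && g > 0.5 && abs(ax - target) < 0.5)
      break
  }
  # prefer well-formed lattices (sheet gridness > 0.5) with the axis
  # closest to the target; fall back to the highest-quality state
  grids <- vapply(cand, function(x)
    ifelse(is.finite(x$grid), x$grid, -Inf), numeric(1))
  errs <- vapply(cand, function(x)
    ifelse(is.finite(x$axis), abs(x$axis - target), Inf), numeric(1))
  ok <- grids > 0.5 & is.finite(errs)
  best <- if (any(ok)) cand[[which(ok)[which.min(errs[ok])]]]$a
          else cand[[which.max(grids)]]$a
  if (check) {
    g <- .sheet_gridness(best, nside)
    if (!is.finite(g) || g <= 0)
      stop("settling failed to produce a periodic pattern (gridness <= 0)")
  }
  list(a = best, nside = nside, gain = gain,
       orientation_deg = orientation_deg,
       sheet_axis_deg = tryCatch(.sheet_axis(best, nside),
                                 error = function(e) NA_real_))
}

# The sheet-to-space mapping preserves orientation: a lattice axis at
# sheet angle t appears in the spatial rate map near t (verified
# empirically; see the methods vignette).  The periodic sheet only admits
# a discrete set of stable lattice orientations, so the settled axis is
# the stable orientation nearest the seeded one; settle_module()
# therefore probes a few seed angles around the target and keeps the
# settled state whose axis is closest.
.sheet_axis_angle <- function(spatial_axis_deg) {
  spatial_axis_deg
}

# mean lattice-axis angle nearest 0 (east), degrees, from the sheet
# activation autocorrelation
.sheet_axis <- function(a, nside) {
  corr <- .sheet_autocorr(a, nside)
  sc <- grid_scale(corr)
  ang <- atan2(sc$peaks_cm[, 2], sc$peaks_cm[, 1]) * 180 / pi
  mean(((ang + 30) %% 60) - 30)
}

.sheet_autocorr <- function(a, nside) {
  m <- matrix(a, nside, nside)
  m <- m - mean(m)
  f <- stats::fft(m)
  ac <- Re(stats::fft(f * Conj(f), inverse = TRUE)) / length(m)
  ac <- ac / ac[1, 1]
  sh <- nside / 2
  ac <- ac[c((sh + 1):nside, 1:sh), c((sh + 1):nside, 1:sh)]
  structure(list(r = ac, valid = matrix(TRUE, nside, nside),
                 n = matrix(nside^2, nside, nside),
                 center = c(sh + 1, sh + 1), pixel_cm = 1),
            class = "gt_correlogram")
}

# quick gridness of a sheet activation pattern via its circular
# autocorrelation (used only as a settling diagnostic)
.sheet_gridness <- function(a, nside) {
  cg <- .sheet_autocorr(a, nside)
  sc <- tryCatch(grid_scale(cg), error = function(e) NULL)
  if (is.null(sc)) return(NA_real_)
  tryCatch(gridness(cg, sc$scale_cm), error = function(e) NA_real_)
}
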