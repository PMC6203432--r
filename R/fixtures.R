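#' Deterministic synthetic fixtures with known ground truth
#'
#' Generates synthetic inputs whose true scale / shift / rescaling
#' parameters are embedded in the returned metadata, for testing the
#' analysis toolbox independently of the network model:
#' \describe{
#'   \item{`hex_map`}{a hexagonal-lattice rate map of known spacing.}
#'   \item{`shifted_pair`}{two hex maps with a known relative translation.}
#'   \item{`compressed_pair`}{a hex map and a copy uniformly compressed
#'     along x by a known factor.}
#'   \item{`toy_path`}{a short hand-built trajectory visiting the north
#'     then the south wall band of a small arena.}
#'   \item{`two_phase_mixture`}{a deformation-trial data set in which
#'     spiking follows a west-anchored (unrescaled) phase after west
#'     contact and an east-anchored phase after east contact, the
#'     boundary-tethered mechanism in its purest form.}
#' }
#'
#' @param kind fixture kind, see above.
#' @param seed RNG seed (default 1).
#' @param ... kind-specific overrides: `spacing_cm`, `size_cm`,
#'   `shift_cm`, `factor`, `angle_deg`.
#' @return list with kind-specific elements plus `meta` (ground truth).
#' @export
make_fixtures <- function(kind = c("hex_map", "shifted_pair",
                                   "compressed_pair", "toy_path",
                                   "two_phase_mixture"),
                          seed = 1, ...) {
  kind <- match.arg(kind)
  set.seed(seed)
  dots <- list(...)
  arg <- function(name, default) dots[[name]] %||% default
  switch(kind,
    hex_map = {
      sp <- arg("spacing_cm", 50); sz <- arg("size_cm", 150)
      ang <- arg("angle_deg", 0)
      m <- .hex_rate_matrix(sz, sz, sp, ang, phase = c(0, 0))
      list(map = m, meta = list(spacing_cm = sp, angle_deg = ang))
    },
    shifted_pair = {
      sp <- arg("spacing_cm", 50); sz <- arg("size_cm", 150)
      dx <- arg("shift_cm", 5)
      a <- .hex_rate_matrix(sz, sz, sp, 0, phase = c(0, 0))
      b <- .hex_rate_matrix(sz, sz, sp, 0, phase = c(dx, 0))
      list(map_a = a, map_b = b, meta = list(shift_cm = dx,
                                             spacing_cm = sp))
    },
    compressed_pair = {
      sp <- arg("spacing_cm", 50); sz <- arg("size_cm", 100)
      fac <- arg("factor", 0.7)
      a <- .hex_rate_matrix(sz, sz, sp, 0, phase = c(0, 0))
      nxd <- round(sz * fac / 2.5)
      b <- rescale_map_axis(a$rate, 1, nxd)
      bm <- structure(list(rate = b, rate_raw = b, mask = !is.na(b),
                           pixel_cm = 2.5, duration_s = 1, n_spikes = NA),
                      class = "gt_ratemap")
      list(map_familiar = a, map_deformed = bm,
           meta = list(factor = fac, fam_len = sz, def_len = sz * fac))
    },
    toy_path = {
      env <- make_environment("rectangle", 60, 60)
      xs <- c(30, 30, 30, 30, 30, 30, 30)
      ys <- c(30, 52, 55, 30, 10, 5, 30)
      n <- 40
      x <- stats::approx(seq_along(xs), xs, n = n)$y
      y <- stats::approx(seq_along(ys), ys, n = n)$y
      dt <- 0.1
      traj <- structure(list(t = seq(0, by = dt, length.out = n), x = x,
                             y = y, dt_s = dt,
                             speed_cms = c(0, sqrt(diff(x)^2 + diff(y)^2)) / dt,
                             heading_deg = rep(0, n)),
                        class = "gt_trajectory")
      list(traj = traj, env = env,
           meta = list(first_contact = "N", second_contact = "S"))
    },
    two_phase_mixture = {
      # default spacing 60 cm: the 30 cm compression displacement is then
      # half a grid period, where the two-phase time average most closely
      # resembles a rescaling
      sp <- arg("spacing_cm", 60)
      fam <- arg("size_cm", 100); fac <- arg("factor", 0.7)
      def <- fam * fac
      env_def <- make_environment("rectangle", def, fam)
      traj <- random_walk(env_def, arg("duration_s", 240), dt_s = 0.01)
      # Idealised contact sequence with realistic recency statistics:
      # labels are piecewise constant in ~2 s blocks; at each block start
      # the probability of the W label ramps from 1 at the west wall to 0
      # at the east wall (the probability gradient that makes the
      # time-averaged mixture resemble a rescaling), while every pixel
      # still samples both phases (no hard segregation).
      n <- length(traj$x)
      labels <- rep("none", n)
      block <- round(arg("block_s", 2) / traj$dt_s)
      i <- round(2 / traj$dt_s)
      while (i <= n) {
        j <- min(n, i + block - 1)
        p_w <- 1 - traj$x[i] / def
        labels[i:j] <- if (stats::runif(1) < p_w) "W" else "E"
        i <- j + 1
      }
      labels <- structure(labels, class = "gt_labels")
      # west-anchored hex phase after W contact, east-anchored after E
      lam_w <- .hex_intensity(traj$x, traj$y, sp, 0, phase = c(0, 0))
      lam_e <- .hex_intensity(traj$x - (def - fam), traj$y, sp, 0,
                              phase = c(0, 0))
      lam <- ifelse(labels == "E", lam_e, lam_w)
      lam[labels == "none"] <- 0
      peak_hz <- arg("peak_hz", 40)
      p <- pmin(lam * peak_hz * traj$dt_s, 1)
      spk <- which(stats::runif(length(p)) < p)
      list(traj = traj, spike_t = traj$t[spk], labels = labels,
           env = env_def,
           familiar_map = .hex_rate_matrix(fam, fam, sp, 0, c(0, 0)),
           meta = list(spacing_cm = sp, fam_len = fam, def_len = def,
                       factor = fac))
    })
}

# hexagonal firing intensity in [0, 1] at positions (x, y)
.hex_intensity <- function(x, y, spacing_cm, angle_deg, phase = c(0, 0)) {
  k <- 4 * pi / (sqrt(3) * spacing_cm)
  tot <- 0
  for (ang in (angle_deg + 30) + c(0, 60, 120)) {
    a <- ang * pi / 180
    tot <- tot + cos(k * (cos(a) * (x - phase[1]) + sin(a) * (y - phase[2])))
  }
  pmax((tot + 1.5) / 4.5, 0)^2
}

# rate map object holding an ideal hexagonal lattice pattern
.hex_rate_matrix <- function(w_cm, h_cm, spacing_cm, angle_deg, phase,
                             pixel_cm = 2.5, peak_hz = 20) {
  nx <- round(w_cm / pixel_cm); ny <- round(h_cm / pixel_cm)
  cx <- (seq_len(nx) - 0.5) * pixel_cm
  cy <- (seq_len(ny) - 0.5) * pixel_cm
  m <- outer(cx, cy, function(px, py)
    peak_hz * .hex_intensity(px, py, spacing_cm, angle_deg, phase))
  structure(list(rate = m, rate_raw = m, mask = matrix(TRUE, nx, ny),
                 occupancy_s = matrix(1, nx, ny),
                 spike_count = NULL, pixel_cm = pixel_cm,
                 duration_s = 1, n_spikes = NA),
            class = "gt_ratemap")
}
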