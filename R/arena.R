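#' Environment geometries
#'
#' Constructs an arena geometry: an axis-aligned rectangle, a right
#' trapezoid (one slanted wall replacing the east wall), or a linear track.
#' Coordinates are continuous centimetres with the origin at the south-west
#' corner, x increasing east and y increasing north.  Optional inserted
#' walls are straight segments lying strictly inside the outer boundary.
#'
#' The four outer walls carry allocentric direction labels N/S/E/W.  For
#' the right trapezoid the slanted wall inherits the direction of the
#' axis-aligned wall it replaces (east): it is the boundary of eastward
#' travel.
#'
#' @param kind one of `"rectangle"`, `"right_trapezoid"`, `"linear_track"`.
#' @param width_cm extent along the east-west axis (for the trapezoid, the
#'   length of the long parallel wall, the south wall).
#' @param height_cm extent along the north-south axis (ignored for the
#'   linear track, which is one pixel high).
#' @param trapezoid_short_wall_cm length of the short (north) parallel wall;
#'   required when `kind = "right_trapezoid"`.
#' @param inserted_walls optional matrix with columns `x0,y0,x1,y1` (or a
#'   list of length-4 vectors), each row an internal wall segment in cm.
#' @param pixel_cm rasterisation pitch for maps (default 2.5 cm).
#' @return an object of class `gt_env`.
#' @export
make_environment <- function(kind = c("rectangle", "right_trapezoid",
                                      "linear_track"),
                             width_cm, height_cm = NULL,
                             trapezoid_short_wall_cm = NULL,
                             inserted_walls = NULL, pixel_cm = 2.5) {
  kind <- match.arg(kind)
  if (kind == "linear_track") height_cm <- pixel_cm
  if (is.null(height_cm)) stop("height_cm is required")
  if (width_cm <= 0 || height_cm <= 0 || pixel_cm <= 0)
    stop("dimensions must be positive")
  w <- width_cm; h <- height_cm
  if (kind == "right_trapezoid") {
    if (is.null(trapezoid_short_wall_cm))
      stop("right trapezoid needs both parallel wall lengths")
    if (trapezoid_short_wall_cm <= 0 || trapezoid_short_wall_cm >= w)
      stop("trapezoid short wall must be positive and shorter than width_cm")
  }
  ws <- trapezoid_short_wall_cm
  # outer polygon, counter-clockwise from SW corner
  poly <- switch(kind,
    rectangle    = rbind(c(0, 0), c(w, 0), c(w, h), c(0, h)),
    linear_track = rbind(c(0, 0), c(w, 0), c(w, h), c(0, h)),
    right_trapezoid = rbind(c(0, 0), c(w, 0), c(ws, h), c(0, h)))
  # outer wall segments with direction labels; each: x0,y0,x1,y1,dir
  walls <- switch(kind,
    rectangle = ,
    linear_track = list(
      W = c(0, 0, 0, h), N = c(0, h, w, h), E = c(w, 0, w, h),
      S = c(0, 0, w, 0)),
    right_trapezoid = list(
      W = c(0, 0, 0, h), N = c(0, h, ws, h), E = c(w, 0, ws, h),
      S = c(0, 0, w, 0)))
  iw <- NULL
  if (!is.null(inserted_walls)) {
    if (is.list(inserted_walls)) inserted_walls <- do.call(rbind, inserted_walls)
    iw <- matrix(as.numeric(inserted_walls), ncol = 4)
    colnames(iw) <- c("x0", "y0", "x1", "y1")
    for (i in seq_len(nrow(iw))) {
      for (pt in list(iw[i, 1:2], iw[i, 3:4])) {
        if (!.point_strictly_inside(poly, pt[1], pt[2]))
          stop("inserted wall endpoint not strictly inside the outer boundary")
      }
    }
  }
  env <- structure(list(kind = kind, width_cm = w, height_cm = h,
                        short_wall_cm = ws, inserted_walls = iw,
                        pixel_cm = pixel_cm, poly = poly, walls = walls),
                   class = "gt_env")
  env
}

.point_strictly_inside <- function(poly, x, y, eps = 1e-9) {
  # winding test plus distance to every edge > eps
  n <- nrow(poly)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]; xj <- poly[j, 1]; yj <- poly[j, 2]
    if (((yi > y) != (yj > y)) && (x < (xj - xi) * (y - yi) / (yj - yi) + xi))
      inside <- !inside
    if (.dist_point_segment(x, y, xi, yi, xj, yj) <= eps) return(FALSE)
    j <- i
  }
  inside
}

.dist_point_segment <- function(px, py, ax, ay, bx, by) {
  vx <- bx - ax; vy <- by - ay
  tt <- ((px - ax) * vx + (py - ay) * vy) / (vx * vx + vy * vy)
  tt <- pmin(pmax(tt, 0), 1)
  sqrt((px - (ax + tt * vx))^2 + (py - (ay + tt * vy))^2)
}

#' Test whether points lie inside an environment
#'
#' @param env a `gt_env`.
#' @param x,y coordinate vectors in cm.
#' @return logical vector.
#' @export
env_contains <- function(env, x, y) {
  w <- env$width_cm; h <- env$height_cm
  inside <- x >= 0 & x <= w & y >= 0 & y <= h
  if (env$kind == "right_trapezoid") {
    xe <- w + (env$short_wall_cm - w) * (y / h)  # east edge at height y
    inside <- inside & x <= xe + 1e-9
  }
  inside
}

#' Perpendicular distance and along-wall position for each outer wall
#'
#' For every sample, the perpendicular distance to each of the four outer
#' walls and the projection coordinate along that wall's dimension (x for
#' N/S walls, y for E/W walls; arc length for a slanted wall).  Walls that
#' do not exist (linear track N/S) get `Inf` distance.
#'
#' @keywords internal
.wall_distances <- function(env, x, y) {
  w <- env$width_cm; h <- env$height_cm
  d <- cbind(N = h - y, S = y, E = w - x, W = x)
  along <- cbind(N = x, S = x, E = y, W = y)
  if (env$kind == "right_trapezoid") {
    # slanted east wall from (w,0) to (short,h)
    sw <- env$short_wall_cm
    vx <- sw - w; vy <- h
    len <- sqrt(vx^2 + vy^2)
    # signed perpendicular distance (positive inside)
    d[, "E"] <- ((x - w) * (-vy) + y * vx) / len
    along[, "E"] <- ((x - w) * vx + y * vy) / len
  }
  if (env$kind == "linear_track") {
    d[, "N"] <- Inf; d[, "S"] <- Inf
  }
  list(dist = d, along = along)
}

#' Bounded random-walk trajectory
#'
#' Generates an open-field exploration path.  The path starts at the centre
#' of the environment, stationary, with a random heading.  Per 3 ms
#' timestep, Gaussian noise is added to speed (sd `sigma_speed_cmms`
#' cm/ms) and to heading (sd `sigma_heading_deg_ms` deg/ms, scaled by the
#' timestep when `heading_noise_per = "ms"`).  Speed is clipped to
#' `[0, 40]` cm/s.  Steps that would cross a wall (outer or inserted) are
#' re-drawn by resampling the heading noise, up to `max_retry` times, after
#' which the heading is reflected; if even the reflected step is illegal
#' the rat stands still for that step.
#'
#' @param env a `gt_env` (open arena).
#' @param duration_s path duration in seconds.
#' @param dt_s timestep (default 0.003 s).
#' @param seed optional integer seed (calls `set.seed`).
#' @param sigma_speed_cmms speed noise sd in cm/ms, applied once per step.
#' @param sigma_heading_deg_ms heading noise sd in degrees per ms.
#' @param heading_noise_per `"ms"` scales the heading sd by the step length
#'   in ms (default, 1.5 deg/ms * 3 ms = 4.5 deg/step); `"step"` uses the
#'   sd as a per-step value unscaled.
#' @param max_retry collision resampling budget per step.
#' @return a `gt_trajectory`: list with `t`, `x`, `y`, `dt_s`,
#'   `speed_cms`, `heading_deg`.
#' @export
random_walk <- function(env, duration_s, dt_s = 0.003, seed = NULL,
                        sigma_speed_cmms = 0.001,
                        sigma_heading_deg_ms = 1.5,
                        heading_noise_per = c("ms", "step"),
                        max_retry = 1000L) {
  stopifnot(inherits(env, "gt_env"), duration_s > 0)
  heading_noise_per <- match.arg(heading_noise_per)
  if (!is.null(seed)) set.seed(seed)
  n_steps <- round(duration_s / dt_s)
  dt_ms <- dt_s * 1000
  sig_h <- if (heading_noise_per == "ms") sigma_heading_deg_ms * dt_ms
           else sigma_heading_deg_ms
  start <- env_center(env)
  iw <- if (is.null(env$inserted_walls)) matrix(numeric(0), ncol = 4)
        else env$inserted_walls
  res <- .rw_path_cpp(env$poly, iw, start[1], start[2], as.integer(n_steps),
                      dt_ms, sigma_speed_cmms, sig_h, 0.04,
                      as.integer(max_retry))
  structure(list(t = seq(0, by = dt_s, length.out = n_steps + 1),
                 x = res$pos[, 1], y = res$pos[, 2], dt_s = dt_s,
                 speed_cms = res$speed_cms, heading_deg = res$heading_deg),
            class = "gt_trajectory")
}

#' Centre of an environment
#' @param env a `gt_env`.
#' @return length-2 numeric (x, y) in cm.
#' @export
env_center <- function(env) {
  c(env$width_cm / 2, env$height_cm / 2)
}

#' Linear-track lap trajectory
#'
#' Straight end-to-end laps at a constant running speed, starting at the
#' west end heading east.  Track position is folded at the ends, so the
#' along-track speed is exactly `speed_cm_per_s` at every step (the net
#' displacement is smaller only at the single sample where the rat turns).
#'
#' @param length_cm track length.
#' @param duration_s total duration.
#' @param speed_cm_per_s running speed (default 20).
#' @param dt_s timestep.
#' @return a `gt_trajectory`; `y` is constant at half a pixel.
#' @export
track_laps <- function(length_cm, duration_s, speed_cm_per_s = 20,
                       dt_s = 0.003) {
  stopifnot(length_cm > 0, duration_s > 0, speed_cm_per_s > 0)
  n <- round(duration_s / dt_s)
  s <- seq(0, by = speed_cm_per_s * dt_s, length.out = n + 1)
  # fold onto [0, L]: triangle wave of period 2L
  p <- s %% (2 * length_cm)
  x <- ifelse(p <= length_cm, p, 2 * length_cm - p)
  heading <- ifelse(p <= length_cm, 0, 180)
  structure(list(t = seq(0, by = dt_s, length.out = n + 1), x = x,
                 y = rep(1.25, n + 1), dt_s = dt_s,
                 speed_cms = c(0, rep(speed_cm_per_s, n)),
                 heading_deg = heading),
            class = "gt_trajectory")
}

#' @export
as.data.frame.gt_trajectory <- function(x, ...) {
  data.frame(t = x$t, x = x$x, y = x$y)
}

#' @export
print.gt_env <- function(x, ...) {
  cat(sprintf("<gt_env %s %.0f x %.0f cm", x$kind, x$width_cm, x$height_cm))
  if (!is.null(x$short_wall_cm))
    cat(sprintf(", short wall %.0f cm", x$short_wall_cm))
  if (!is.null(x$inserted_walls))
    cat(sprintf(", %d inserted wall(s)", nrow(x$inserted_walls)))
  cat(">\n")
  invisible(x)
}

#' @export
print.gt_trajectory <- function(x, ...) {
  cat(sprintf("<gt_trajectory %d samples, %.1f s at dt = %g s>\n",
              length(x$t), max(x$t), x$dt_s))
  invisible(x)
}

#' Write / read a trajectory as a delimited text table
#'
#' The file has a header `t,x,y` with times in seconds and positions in cm.
#' Reading recovers the timestep from the time column.
#'
#' @param traj a `gt_trajectory`.
#' @param path file path.
#' @export
write_trajectory <- function(traj, path) {
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  d <- utils::read.csv(path)
  stopifnot(all(c("t", "x", "y") %in% names(d)))
  dt <- if (nrow(d) > 1) stats::median(diff(d$t)) else 0.003
  dx <- c(0, diff(d$x)); dy <- c(0, diff(d$y))
  structure(list(t = d$t, x = d$x, y = d$y, dt_s = dt,
                 speed_cms = sqrt(dx^2 + dy^2) / dt,
                 heading_deg = (atan2(dy, dx) * 180 / pi) %% 360),
            class = "gt_trajectory")
}

#' Label each sample with the most recently contacted boundary
#'
#' Boundary contact is defined as the rat being within `threshold_cm`
#' (default 12 cm) of an outer wall.  Each sample is labelled with the
#' boundary most recently contacted; samples before the first contact are
#' labelled `"none"`.  When two walls are within threshold simultaneously
#' (a corner), the nearer wall wins; on an exact distance tie the wall
#' contacted first (i.e. the current label, if tied) is kept, and a
#' simultaneous first entry is broken by the fixed priority N, S, E, W.
#'
#' @param traj a `gt_trajectory`.
#' @param env the environment the path was generated in.
#' @param threshold_cm contact distance (default 12).
#' @param include_inserted also treat inserted-wall faces as contacts with
#'   the matching allocentric boundary (default `FALSE`: outer walls only).
#' @return an object of class `gt_labels`: a character vector (one of
#'   `"none"`, `"N"`, `"S"`, `"E"`, `"W"` per sample) with the threshold
#'   stored as an attribute.
#' @export
label_boundary_contacts <- function(traj, env, threshold_cm = 12,
                                    include_inserted = FALSE) {
  wd <- .wall_distances(env, traj$x, traj$y)
  d <- wd$dist
  if (include_inserted && !is.null(env$inserted_walls)) {
    for (i in seq_len(nrow(env$inserted_walls))) {
      seg <- env$inserted_walls[i, ]
      fd <- .inserted_face_distances(seg, traj$x, traj$y)
      for (dir in names(fd)) d[, dir] <- pmin(d[, dir], fd[[dir]])
    }
  }
  dirs <- c("N", "S", "E", "W")
  within <- d <= threshold_cm
  any_within <- rowSums(within) > 0
  dmask <- d
  dmask[!within] <- Inf
  nearest <- dirs[max.col(-dmask, ties.method = "first")]
  nearest[!any_within] <- NA_character_
  # resolve exact ties in favour of the wall contacted first (the current
  # label) where possible
  tie_rows <- which(any_within &
                    rowSums(dmask == apply(dmask, 1, min)) > 1)
  lab <- nearest
  if (length(tie_rows) > 0) {
    filled_so_far <- nearest
    for (i in tie_rows) {
      tied <- dirs[dmask[i, ] == min(dmask[i, ])]
      prev <- if (i > 1) .locf_single(lab, i - 1) else NA_character_
      lab[i] <- if (!is.na(prev) && prev %in% tied) prev else tied[1]
    }
  }
  out <- .locf(lab)
  out[is.na(out)] <- "none"
  structure(out, threshold_cm = threshold_cm, class = "gt_labels")
}

.locf <- function(x) {
  idx <- cummax(ifelse(is.na(x), 0L, seq_along(x)))
  out <- rep(NA_character_, length(x))
  ok <- idx > 0
  out[ok] <- x[idx[ok]]
  out
}

.locf_single <- function(x, i) {
  while (i >= 1 && is.na(x[i])) i <- i - 1
  if (i >= 1) x[i] else NA_character_
}

.inserted_face_distances <- function(seg, x, y, depth = 12) {
  # Each face of an inserted wall blocks travel in one allocentric
  # direction; a point south of a horizontal wall has the wall as its
  # *north* boundary, etc.  Distances only count within the segment's
  # lateral extent and within `depth`.
  x0 <- seg[1]; y0 <- seg[2]; x1 <- seg[3]; y1 <- seg[4]
  out <- list()
  if (abs(y1 - y0) < 1e-9) {          # horizontal wall
    yw <- y0
    in_span <- x >= min(x0, x1) & x <= max(x0, x1)
    dN <- ifelse(in_span & y <= yw, yw - y, Inf)       # south side: N face
    dS <- ifelse(in_span & y >= yw, y - yw, Inf)       # north side: S face
    out$N <- ifelse(dN <= depth, dN, Inf)
    out$S <- ifelse(dS <= depth, dS, Inf)
  } else if (abs(x1 - x0) < 1e-9) {   # vertical wall
    xw <- x0
    in_span <- y >= min(y0, y1) & y <= max(y0, y1)
    dE <- ifelse(in_span & x <= xw, xw - x, Inf)       # west side: E face
    dW <- ifelse(in_span & x >= xw, x - xw, Inf)       # east side: W face
    out$E <- ifelse(dE <= depth, dE, Inf)
    out$W <- ifelse(dW <= depth, dW, Inf)
  } else {
    stop("inserted walls must be axis-aligned")
  }
  out
}

#' Rasterise positions to pixel indices
#'
#' Pixels are half-open `[k*pitch, (k+1)*pitch)` squares; points exactly on
#' the east/north extreme edge fall in the last pixel.  Returns 1-based
#' linear indices into an `nx * ny` grid stored x-major (index =
#' `(iy-1)*nx + ix`).
#'
#' @param env a `gt_env`.
#' @param x,y positions in cm.
#' @return list with `ix`, `iy`, `idx`, `nx`, `ny`.
#' @export
rasterize_positions <- function(env, x, y) {
  p <- env$pixel_cm
  nx <- ceiling(env$width_cm / p - 1e-9)
  ny <- ceiling(env$height_cm / p - 1e-9)
  ix <- pmin(pmax(floor(x / p), 0), nx - 1) + 1
  iy <- pmin(pmax(floor(y / p), 0), ny - 1) + 1
  list(ix = ix, iy = iy, idx = (iy - 1L) * nx + ix, nx = nx, ny = ny)
}

#' Most-recent-boundary probability map
#'
#' For each visited pixel, the probability of having most recently
#' contacted each of the four boundaries (over samples carrying a non-none
#' label), plus a joint count table over heading bin and boundary.
#'
#' @param labels a `gt_labels` vector.
#' @param traj the matching trajectory.
#' @param env the environment.
#' @param heading_bins number of equal heading bins over \[0, 360).
#' @return list with `prob` (nx x ny x 4 array, dims x, y, boundary
#'   N/S/E/W; `NA` where no labelled sample), `counts` (same shape,
#'   integer), and `joint` (heading_bins x 4 count matrix).
#' @export
recency_bias_map <- function(labels, traj, env, heading_bins = 8) {
  stopifnot(length(labels) == length(traj$x))
  ras <- rasterize_positions(env, traj$x, traj$y)
  keep <- labels != "none"
  dirs <- c("N", "S", "E", "W")
  counts <- array(0L, dim = c(ras$nx, ras$ny, 4),
                  dimnames = list(NULL, NULL, dirs))
  for (k in seq_along(dirs)) {
    sel <- keep & labels == dirs[k]
    if (any(sel)) {
      tb <- tabulate(ras$idx[sel], nbins = ras$nx * ras$ny)
      counts[, , k] <- tb
    }
  }
  tot <- counts[, , 1] + counts[, , 2] + counts[, , 3] + counts[, , 4]
  prob <- array(NA_real_, dim = dim(counts), dimnames = dimnames(counts))
  for (k in 1:4) prob[, , k] <- ifelse(tot > 0, counts[, , k] / tot, NA_real_)
  hb <- pmin(floor((traj$heading_deg %% 360) / (360 / heading_bins)),
             heading_bins - 1) + 1
  joint <- matrix(0L, heading_bins, 4, dimnames = list(NULL, dirs))
  for (k in seq_along(dirs)) {
    sel <- keep & labels == dirs[k]
    if (any(sel)) joint[, k] <- tabulate(hb[sel], nbins = heading_bins)
  }
  list(prob = prob, counts = counts, joint = joint)
}
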