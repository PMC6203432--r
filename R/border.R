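#' Border-layer brick partition
#'
#' The band within 12 cm of each outer wall is divided into 8 "bricks" per
#' allocentric direction (N, S, E, W), each covering 12.5% of that wall's
#' length, giving 32 bricks.  Bricks are numbered around the perimeter
#' clockwise when viewed from above, starting at the south-west corner of
#' the west wall: global ids 0-7 run up the west wall (south to north),
#' 8-15 along the north wall (west to east), 16-23 down the east wall
#' (north to south) and 24-31 along the south wall (east to west).
#'
#' Inserted walls contribute additional brick *surfaces* on both faces: a
#' face that blocks travel in some allocentric direction activates the
#' outer bricks of that direction at the positions given by the face's
#' projection onto that wall's dimension, so wall insertion elicits border
#' fields at analogous locations.
#'
#' Under a deformation, brick widths rescale proportionally with their wall
#' because the partition is recomputed from the current geometry.
#'
#' @param env a `gt_env`.
#' @param depth_cm band depth perpendicular to the wall (default 12).
#' @return an object of class `gt_bricks`: a data frame with one row per
#'   brick surface (`id` 0-31, `dir`, `along0`, `along1` in cm along the
#'   wall dimension, `surface` = `"outer"` or `"inserted"`, plus face
#'   geometry columns for inserted surfaces), with `env` and `depth_cm`
#'   attached as attributes.
#' @export
brick_partition <- function(env, depth_cm = 12) {
  dirs <- c("W", "N", "E", "S")
  rows <- list()
  for (dir in dirs) {
    len <- .wall_length(env, dir)
    if (!is.finite(len)) next
    edges <- seq(0, len, length.out = 9)
    for (k in 1:8) {
      rows[[length(rows) + 1]] <- data.frame(
        id = .brick_global_id(dir, k - 1), dir = dir, along_idx = k - 1,
        along0 = edges[k], along1 = edges[k + 1], surface = "outer",
        face_x = NA_real_, face_y0 = NA_real_, face_y1 = NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  part <- do.call(rbind, rows)
  if (!is.null(env$inserted_walls)) {
    for (i in seq_len(nrow(env$inserted_walls))) {
      seg <- env$inserted_walls[i, ]
      part <- rbind(part, .inserted_surfaces(env, seg))
    }
  }
  structure(part, env = env, depth_cm = depth_cm, class = c("gt_bricks",
                                                            "data.frame"))
}

.wall_length <- function(env, dir) {
  w <- env$width_cm; h <- env$height_cm
  if (env$kind == "linear_track" && dir %in% c("N", "S")) return(Inf)
  switch(dir,
    N = if (env$kind == "right_trapezoid") env$short_wall_cm else w,
    S = w,
    W = h,
    E = if (env$kind == "right_trapezoid")
          sqrt((env$short_wall_cm - w)^2 + h^2) else h)
}

# perimeter ordering: W (S->N) 0-7, N (W->E) 8-15, E (N->S) 16-23,
# S (E->W) 24-31; along_idx always ascends with the wall coordinate
.brick_global_id <- function(dir, along_idx) {
  switch(dir,
    W = along_idx,
    N = 8 + along_idx,
    E = 16 + (7 - along_idx),
    S = 24 + (7 - along_idx))
}

.inserted_surfaces <- function(env, seg) {
  # map each face of an inserted wall to the brick ids of the matching
  # allocentric direction, using the face's projection onto that wall's
  # dimension
  x0 <- seg[1]; y0 <- seg[2]; x1 <- seg[3]; y1 <- seg[4]
  rows <- list()
  add <- function(dir, lo, hi, fx, fy0, fy1) {
    len <- .wall_length(env, dir)
    edges <- seq(0, len, length.out = 9)
    for (k in 1:8) {
      a0 <- max(edges[k], lo); a1 <- min(edges[k + 1], hi)
      if (a1 > a0 + 1e-9) {
        rows[[length(rows) + 1]] <<- data.frame(
          id = .brick_global_id(dir, k - 1), dir = dir, along_idx = k - 1,
          along0 = a0, along1 = a1, surface = "inserted",
          face_x = fx, face_y0 = fy0, face_y1 = fy1,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (abs(y1 - y0) < 1e-9) {
    yw <- y0; lo <- min(x0, x1); hi <- max(x0, x1)
    add("N", lo, hi, yw, NA, NA)   # south side acts as a north boundary
    add("S", lo, hi, yw, NA, NA)   # north side acts as a south boundary
  } else if (abs(x1 - x0) < 1e-9) {
    xw <- x0; lo <- min(y0, y1); hi <- max(y0, y1)
    add("E", lo, hi, xw, NA, NA)
    add("W", lo, hi, xw, NA, NA)
  } else stop("inserted walls must be axis-aligned")
  do.call(rbind, rows)
}

#' Which bricks contain given points
#'
#' @param part a `gt_bricks` partition.
#' @param x,y coordinates in cm (vectors).
#' @return a logical matrix, samples x brick-surface rows.
#' @keywords internal
.brick_membership <- function(part, x, y) {
  env <- attr(part, "env")
  depth <- attr(part, "depth_cm")
  wd <- .wall_distances(env, x, y)
  out <- matrix(FALSE, length(x), nrow(part))
  for (r in seq_len(nrow(part))) {
    dir <- part$dir[r]
    if (part$surface[r] == "outer") {
      d <- wd$dist[, dir]; al <- wd$along[, dir]
      # last brick closed at the far end so the wall band tiles exactly
      hi_ok <- if (part$along_idx[r] == 7) al <= part$along1[r] + 1e-9
               else al < part$along1[r]
      out[, r] <- d >= 0 & d <= depth & al >= part$along0[r] & hi_ok
    } else {
      fw <- part$face_x[r]
      if (dir %in% c("N", "S")) {
        dd <- if (dir == "N") fw - y else y - fw
        al <- x
      } else {
        dd <- if (dir == "E") fw - x else x - fw
        al <- y
      }
      hi_ok <- if (part$along_idx[r] == 7) al <= part$along1[r] + 1e-9
               else al < part$along1[r]
      out[, r] <- dd >= 0 & dd <= depth & al >= part$along0[r] & hi_ok
    }
  }
  out
}

#' Border-unit spans
#'
#' Unit `j` (0-31) responds to the four consecutive perimeter bricks
#' `{j, j+1, j+2, j+3} mod 32`, so each unit's field covers 50% of the
#' length of one wall; some spans wrap corners.
#'
#' @param unit_id integer 0-31 (vectorised).
#' @return integer matrix, one row per unit, the four global brick ids.
#' @export
border_unit_span <- function(unit_id) {
  stopifnot(all(unit_id >= 0 & unit_id <= 31))
  t(vapply(unit_id, function(j) (j + 0:3) %% 32L, integer(4)))
}

#' Feed-forward border input at a point
#'
#' Unit `j` receives the uniform input `amplitude` (default 0.1) whenever
#' the point lies inside any brick of its span, else 0.
#'
#' @param env a `gt_env`.
#' @param point length-2 numeric (x, y) in cm.
#' @param part optional precomputed `gt_bricks`.
#' @param amplitude input amplitude b_j (default 0.1).
#' @return numeric vector of length 32.
#' @export
border_input <- function(env, point, part = NULL, amplitude = 0.1) {
  if (!env_contains(env, point[1], point[2]))
    stop("point outside the environment")
  if (is.null(part)) part <- brick_partition(env)
  memb <- .brick_membership(part, point[1], point[2])
  active_bricks <- unique(part$id[memb[1, ]])
  out <- numeric(32)
  if (length(active_bricks) > 0) {
    units <- unique(unlist(lapply(active_bricks,
                                  function(g) (g - 0:3) %% 32L)))
    out[units + 1] <- amplitude
  }
  out
}

#' Wall-length coverage of a border unit's field
#'
#' The active band of a unit spans 4 bricks, each 12.5% of its own wall's
#' length, so the coverage expressed in wall-length fractions is 0.5 (50%
#' of the length of one side), possibly split across two walls at a
#' corner.
#'
#' @param env a `gt_env`.
#' @param unit_id 0-31.
#' @return list with `fraction` (sum of per-brick fractional coverages)
#'   and `arc_cm` (absolute arc length of the span).
#' @export
border_field_coverage <- function(env, unit_id) {
  span <- border_unit_span(unit_id)[1, ]
  part <- brick_partition(env)
  outer <- part[part$surface == "outer", ]
  frac <- 0; arc <- 0
  for (g in span) {
    row <- outer[outer$id == g, ][1, ]
    len <- row$along1 - row$along0
    frac <- frac + len / .wall_length(env, row$dir)
    arc <- arc + len
  }
  list(fraction = frac, arc_cm = arc)
}

#' Per-step border drive for the simulation engine
#'
#' Computes, for every trajectory sample, the set of active border units
#' (those whose brick span contains the sample position) and packs them in
#' compressed sparse row form for the C++ engine.
#'
#' @param traj a `gt_trajectory`.
#' @param env a `gt_env`.
#' @param part optional precomputed partition.
#' @return list with `ptr` (int, length n_samples + 1) and `idx`
#'   (0-based active unit ids, concatenated per sample).
#' @export
border_drive <- function(traj, env, part = NULL) {
  if (is.null(part)) part <- brick_partition(env)
  memb <- .brick_membership(part, traj$x, traj$y)
  n <- length(traj$x)
  # collapse brick-surface columns to the 32 global bricks
  brick_active <- matrix(FALSE, n, 32)
  for (r in seq_len(ncol(memb))) {
    g <- part$id[r] + 1
    brick_active[, g] <- brick_active[, g] | memb[, r]
  }
  # unit active iff any span brick active; span of unit j is {j..j+3}
  unit_active <- matrix(FALSE, n, 32)
  for (j in 0:31) {
    cols <- ((j + 0:3) %% 32L) + 1L
    unit_active[, j + 1] <- brick_active[, cols[1]] | brick_active[, cols[2]] |
      brick_active[, cols[3]] | brick_active[, cols[4]]
  }
  nz <- which(t(unit_active)) # column-major over transposed: per-sample runs
  counts <- rowSums(unit_active)
  ptr <- c(0L, cumsum(as.integer(counts)))
  idx <- as.integer((nz - 1L) %% 32L)
  list(ptr = ptr, idx = idx)
}
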