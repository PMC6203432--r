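#' Boundary-conditioned rate maps
#'
#' Divides spiking according to the most recently contacted boundary and
#' builds one rate map per boundary from the samples (and spikes falling
#' in them) carrying that label.  Samples before the first boundary
#' contact (label `"none"`) enter no map, so pre-contact spikes are
#' discarded.  With `matched = TRUE`, opposing-pair maps are built from
#' random subsets of the data such that the number of samples used at
#' each pixel is `min(n_A, n_B)` for the two maps, removing differential
#' sampling as a confound; the draw is repeated `iterations` times and
#' downstream statistics are averaged over iterations.
#'
#' @param traj a `gt_trajectory` (deformation trial).
#' @param spike_t spike times of one unit (s).
#' @param labels a `gt_labels` vector for `traj`.
#' @param env the trial environment.
#' @param matched build occupancy-matched opposing-pair maps.
#' @param pair for `matched = TRUE`: `c("E","W")` or `c("N","S")`.
#' @param iterations subsampling repetitions (default 100).
#' @param seed optional RNG seed.
#' @param smooth smooth the maps (default TRUE).
#' @return unmatched: named list (`N`,`S`,`E`,`W`) of `gt_ratemap` or
#'   `NULL` for never-contacted boundaries.  Matched: list of length
#'   `iterations`, each a named list of the two maps.
#' @export
boundary_rate_maps <- function(traj, spike_t, labels, env, matched = FALSE,
                               pair = c("E", "W"), iterations = 100,
                               seed = NULL, smooth = TRUE) {
  stopifnot(length(labels) == length(traj$x))
  if (!is.null(seed)) set.seed(seed)
  spk_idx <- spike_sample_index(spike_t, traj)
  if (!matched) {
    out <- stats::setNames(vector("list", 4), c("N", "S", "E", "W"))
    for (d in names(out)) {
      sel <- which(labels == d)
      if (length(sel) == 0) next
      out[[d]] <- .map_from_samples(traj, env, sel, spk_idx, smooth)
    }
    return(out)
  }
  stopifnot(length(pair) == 2)
  selA <- which(labels == pair[1]); selB <- which(labels == pair[2])
  if (length(selA) == 0 || length(selB) == 0)
    stop("a boundary in the pair was never contacted")
  ras <- rasterize_positions(env, traj$x, traj$y)
  pxA <- ras$idx[selA]; pxB <- ras$idx[selB]
  byA <- split(selA, pxA); byB <- split(selB, pxB)
  common <- union(names(byA), names(byB))
  lapply(seq_len(iterations), function(it) {
    subA <- integer(0); subB <- integer(0)
    for (p in common) {
      a <- byA[[p]]; b <- byB[[p]]
      k <- min(length(a), length(b))
      if (k == 0) next
      subA <- c(subA, if (length(a) == k) a else sample(a, k))
      subB <- c(subB, if (length(b) == k) b else sample(b, k))
    }
    stats::setNames(list(.map_from_samples(traj, env, subA, spk_idx, smooth),
                         .map_from_samples(traj, env, subB, spk_idx, smooth)),
                    pair)
  })
}

# rate map built from a subset of trajectory samples; spikes are counted
# when their sample is in the subset
.map_from_samples <- function(traj, env, samples, spk_idx, smooth = TRUE) {
  ras <- rasterize_positions(env, traj$x, traj$y)
  npx <- ras$nx * ras$ny
  occ_n <- tabulate(ras$idx[samples], nbins = npx)
  keep <- spk_idx[spk_idx %in% samples]
  cnt <- tabulate(ras$idx[keep], nbins = npx)
  occ_s <- occ_n * traj$dt_s
  rate_raw <- matrix(ifelse(occ_n > 0, cnt / ifelse(occ_s > 0, occ_s, 1),
                            NA_real_), ras$nx, ras$ny)
  mask <- matrix(occ_n > 0, ras$nx, ras$ny)
  rate <- if (smooth) smooth_map(rate_raw, mask) else rate_raw
  structure(list(rate = rate, rate_raw = rate_raw, mask = mask,
                 occupancy_s = matrix(occ_s, ras$nx, ras$ny),
                 spike_count = matrix(cnt, ras$nx, ras$ny),
                 sample_count = matrix(occ_n, ras$nx, ras$ny),
                 pixel_cm = env$pixel_cm,
                 duration_s = length(samples) * traj$dt_s,
                 n_spikes = length(keep)),
            class = "gt_ratemap")
}

#' Grid shift between opposing boundary rate maps
#'
#' Opposing boundary rate maps (occupancy-matched per iteration) are
#' cross-correlated at single-pixel lags within plus/minus half the grid
#' scale.  The positive-correlation region of the windowed
#' cross-correlogram is partitioned into contiguous blobs; the peak is the
#' maximum-r pixel inside the blob nearest the centre (blob distance =
#' minimum distance from the centre to any blob pixel).  Shift is the
#' absolute peak lag component along the dimension of interest, and is
#' also reported as the ratio shift / (scale / 2), which the lag window
#' bounds at 1.
#'
#' @param traj,spike_t,labels,env as in [boundary_rate_maps()].
#' @param scale_cm familiar-trial grid scale of the unit.
#' @param dimension `"x"` (uses the E/W pair) or `"y"` (N/S pair).
#' @param iterations occupancy-matching repetitions (default 100).
#' @param seed optional RNG seed.
#' @return list with `shift_cm`, `shift_ratio` (means across iterations),
#'   `per_iteration` (vector, NA where no positive blob), `iterations`.
#' @export
grid_shift <- function(traj, spike_t, labels, env, scale_cm,
                       dimension = c("x", "y"), iterations = 100,
                       seed = NULL) {
  dimension <- match.arg(dimension)
  pair <- if (dimension == "x") c("E", "W") else c("N", "S")
  pairs <- boundary_rate_maps(traj, spike_t, labels, env, matched = TRUE,
                              pair = pair, iterations = iterations,
                              seed = seed)
  shifts <- vapply(pairs, function(pp)
    shift_between_maps(pp[[1]], pp[[2]], scale_cm, dimension), numeric(1))
  list(shift_cm = mean(shifts, na.rm = TRUE),
       shift_ratio = mean(shifts, na.rm = TRUE) / (scale_cm / 2),
       per_iteration = shifts, iterations = iterations)
}

#' Shift between two rate maps (one subsample draw)
#'
#' @param map_a,map_b `gt_ratemap`s.
#' @param scale_cm grid scale defining the lag window.
#' @param dimension `"x"` or `"y"`.
#' @return absolute shift in cm along the dimension, `NA` if the windowed
#'   cross-correlogram has no positive blob.
#' @export
shift_between_maps <- function(map_a, map_b, scale_cm, dimension) {
  cg <- correlogram(map_a, map_b)
  lg <- correlogram_lags(cg)
  half <- scale_cm / 2
  win_x <- abs(lg$dx) <= half + 1e-9
  win_y <- abs(lg$dy) <= half + 1e-9
  r <- cg$r[win_x, win_y, drop = FALSE]
  valid <- cg$valid[win_x, win_y, drop = FALSE]
  ci <- which(abs(lg$dx[win_x]) < 1e-9)
  cj <- which(abs(lg$dy[win_y]) < 1e-9)
  pos <- valid & !is.na(r) & r > 0
  if (!any(pos)) return(NA_real_)
  lab <- .label_blobs(pos)
  nr <- nrow(lab)
  ids <- setdiff(unique(as.integer(lab)), 0L)
  # blob nearest the centre: min distance from centre to any blob pixel
  bd <- vapply(ids, function(id) {
    w <- which(lab == id)
    i <- (w - 1L) %% nr + 1L; j <- (w - 1L) %/% nr + 1L
    min(sqrt((i - ci)^2 + (j - cj)^2))
  }, numeric(1))
  best <- ids[which.min(bd)]
  w <- which(lab == best)
  pk <- w[which.max(r[w])]
  pi_ <- (pk - 1L) %% nr + 1L; pj <- (pk - 1L) %/% nr + 1L
  dx <- lg$dx[win_x][pi_]; dy <- lg$dy[win_y][pj]
  abs(if (dimension == "x") dx else dy)
}

# ---- alignment / rescaling ------------------------------------------------

# overlap of two maps registered at one edge along one axis;
# returns row/col index vectors into A and B
.edge_align_index <- function(nA, nB, side) {
  n <- min(nA, nB)
  if (side == "low") list(a = seq_len(n), b = seq_len(n))
  else list(a = seq.int(nA - n + 1, nA), b = seq.int(nB - n + 1, nB))
}

# Pearson r between two maps at zero lag over jointly valid pixels
.map_overlap_r <- function(A, B, min_overlap = 20) {
  ok <- !is.na(A) & !is.na(B)
  if (sum(ok) < min_overlap) return(NA_real_)
  if (stats::sd(A[ok]) < 1e-12 || stats::sd(B[ok]) < 1e-12) return(NA_real_)
  stats::cor(A[ok], B[ok])
}

#' Boundary alignment test
#'
#' Compares a deformed-trial boundary rate map against the familiar
#' whole-trial rate map under two registrations along the deformed
#' dimension: aligned by the conditioned (corresponding) boundary, or by
#' the opposing boundary.  Returns which alignment yields the higher
#' overlap correlation (ties go to `"corresponding"`).
#'
#' @param boundary_map boundary-conditioned `gt_ratemap` (deformed trial).
#' @param familiar_map whole-trial familiar `gt_ratemap`.
#' @param boundary the conditioned boundary (`"N"`,`"S"`,`"E"`,`"W"`),
#'   which must lie along the deformed dimension.
#' @param deformed_dim `"x"` or `"y"`.
#' @return list with `alignment` (`"corresponding"` or `"opposite"`),
#'   `r_corresponding`, `r_opposite`.
#' @export
alignment_test <- function(boundary_map, familiar_map, boundary,
                           deformed_dim = c("x", "y")) {
  deformed_dim <- match.arg(deformed_dim)
  if (deformed_dim == "x" && !(boundary %in% c("E", "W")))
    stop("boundary must lie along the deformed dimension")
  if (deformed_dim == "y" && !(boundary %in% c("N", "S")))
    stop("boundary must lie along the deformed dimension")
  low_side <- boundary %in% c("W", "S")   # wall at coordinate zero
  r_low_high <- vapply(c("low", "high"), function(side) {
    A <- boundary_map$rate; B <- familiar_map$rate
    if (deformed_dim == "x") {
      ix <- .edge_align_index(nrow(A), nrow(B), side)
      ny <- min(ncol(A), ncol(B))
      .map_overlap_r(A[ix$a, seq_len(ny)], B[ix$b, seq_len(ny)])
    } else {
      iy <- .edge_align_index(ncol(A), ncol(B), side)
      nx <- min(nrow(A), nrow(B))
      .map_overlap_r(A[seq_len(nx), iy$a], B[seq_len(nx), iy$b])
    }
  }, numeric(1))
  r_corr <- if (low_side) r_low_high["low"] else r_low_high["high"]
  r_opp <- if (low_side) r_low_high["high"] else r_low_high["low"]
  alignment <- if (!is.na(r_opp) && !is.na(r_corr) && r_opp > r_corr)
    "opposite" else "corresponding"
  list(alignment = alignment, r_corresponding = unname(r_corr),
       r_opposite = unname(r_opp))
}

#' Uniformly rescale a rate map along one axis
#'
#' Coordinate resampling with mask-aware linear interpolation onto the
#' unchanged 2.5 cm pixel grid: the new map has `round(new_len / pitch)`
#' pixels along the axis and each new pixel centre samples the source at
#' the proportionally mapped position.
#'
#' @param m matrix (may contain `NA`).
#' @param axis 1 to rescale rows (x), 2 for columns (y).
#' @param n_new new pixel count along the axis.
#' @return resampled matrix.
#' @export
rescale_map_axis <- function(m, axis = 1, n_new) {
  if (axis == 2) return(t(rescale_map_axis(t(m), 1, n_new)))
  n_old <- nrow(m)
  if (n_new == n_old) return(m)
  # pixel-centre positions in [0, 1]
  src <- (seq_len(n_old) - 0.5) / n_old
  dst <- (seq_len(n_new) - 0.5) / n_new
  out <- matrix(NA_real_, n_new, ncol(m))
  pos <- stats::approx(src, seq_len(n_old), xout = dst, rule = 2)$y
  lo <- pmax(floor(pos), 1); hi <- pmin(lo + 1, n_old)
  f <- pos - lo
  for (j in seq_len(ncol(m))) {
    v_lo <- m[lo, j]; v_hi <- m[hi, j]
    w_lo <- (1 - f) * !is.na(v_lo); w_hi <- f * !is.na(v_hi)
    v_lo[is.na(v_lo)] <- 0; v_hi[is.na(v_hi)] <- 0
    tot <- w_lo + w_hi
    out[, j] <- ifelse(tot > 1e-9, (w_lo * v_lo + w_hi * v_hi) / tot,
                       NA_real_)
  }
  out
}

#' Grid rescaling factor
#'
#' The familiar rate map is uniformly rescaled along the deformed
#' dimension to a series of candidate chamber lengths, from 10 cm below
#' the smaller of the deformed and familiar lengths through 10 cm above
#' the larger, in 5 cm steps.  Each rescaled map is correlated with the
#' deformed-trial map under each permitted edge alignment; the rescaling
#' factor is the candidate length yielding the highest correlation,
#' divided by the familiar length.  The normalised rescaling maps 1.0 to
#' 0% (no rescaling) and `def_len/fam_len` to 100% (matched rescaling);
#' it is undefined (NA) for undeformed trials.
#'
#' @param familiar_map familiar whole-trial `gt_ratemap`.
#' @param deformed_map deformed-trial `gt_ratemap` (whole-trial or
#'   boundary-conditioned).
#' @param fam_len,def_len chamber lengths along the deformed dimension, cm.
#' @param dimension `"x"` or `"y"`.
#' @param alignments `"both"` (default), or a boundary (`"N"`, `"S"`,
#'   `"E"`, `"W"`) to fix the registration to that wall.
#' @param step_cm candidate increment (default 5 cm, 2 pixels).
#' @param margin_cm search margin beyond the chamber lengths (default 10).
#' @return list with `factor`, `normalized_pct`, `best_len_cm`, `r_best`,
#'   `candidates` (data frame of length, alignment, r).
#' @export
rescaling_factor <- function(familiar_map, deformed_map, fam_len, def_len,
                             dimension = c("x", "y"), alignments = "both",
                             step_cm = 5, margin_cm = 10) {
  dimension <- match.arg(dimension)
  pitch <- familiar_map$pixel_cm
  lens <- seq(min(fam_len, def_len) - margin_cm,
              max(fam_len, def_len) + margin_cm, by = step_cm)
  lens <- lens[lens >= 2 * pitch]
  axis <- if (dimension == "x") 1 else 2
  sides <- if (identical(alignments, "both")) c("low", "high")
           else if (alignments %in% c("W", "S")) "low"
           else if (alignments %in% c("E", "N")) "high"
           else stop("bad alignments")
  D <- deformed_map$rate
  res <- expand.grid(len = lens, side = sides, stringsAsFactors = FALSE)
  res$r <- NA_real_
  for (k in seq_len(nrow(res))) {
    n_new <- round(res$len[k] / pitch)
    Rm <- rescale_map_axis(familiar_map$rate, axis, n_new)
    if (axis == 1) {
      ix <- .edge_align_index(nrow(Rm), nrow(D), res$side[k])
      ny <- min(ncol(Rm), ncol(D))
      res$r[k] <- .map_overlap_r(Rm[ix$a, seq_len(ny)], D[ix$b, seq_len(ny)])
    } else {
      iy <- .edge_align_index(ncol(Rm), ncol(D), res$side[k])
      nx <- min(nrow(Rm), nrow(D))
      res$r[k] <- .map_overlap_r(Rm[seq_len(nx), iy$a], D[seq_len(nx), iy$b])
    }
  }
  if (all(is.na(res$r))) stop("all candidate correlations undefined")
  best <- which.max(res$r)
  factor <- res$len[best] / fam_len
  norm <- if (abs(def_len - fam_len) < 1e-9) NA_real_
          else (factor - 1) / (def_len / fam_len - 1) * 100
  list(factor = factor, normalized_pct = norm,
       best_len_cm = res$len[best], r_best = res$r[best], candidates = res)
}

#' Boundary-conditioned versus occupancy-matched whole-trial rescaling
#'
#' The rescaling factor of a boundary rate map (alignment fixed to the
#' conditioned boundary) compared with the factor of whole-trial rate
#' maps subsampled so that the number of samples at each pixel matches
#' the boundary map's sampling distribution; the whole-trial factor is
#' the mean over `iterations` random subsamples.
#'
#' @param traj,spike_t,labels,env deformation-trial data.
#' @param familiar_map familiar whole-trial `gt_ratemap`.
#' @param boundary conditioned boundary (must lie on the deformed
#'   dimension).
#' @param fam_len,def_len chamber lengths along the deformed dimension.
#' @param dimension `"x"` or `"y"`.
#' @param iterations subsample repetitions (default 100).
#' @param seed optional RNG seed.
#' @return list with `boundary_factor`, `matched_whole_factor`,
#'   `per_iteration`, `boundary_map`.
#' @export
boundary_conditioned_rescaling <- function(traj, spike_t, labels, env,
                                           familiar_map, boundary,
                                           fam_len, def_len,
                                           dimension = c("x", "y"),
                                           iterations = 100, seed = NULL) {
  dimension <- match.arg(dimension)
  if (!is.null(seed)) set.seed(seed)
  spk_idx <- spike_sample_index(spike_t, traj)
  sel_b <- which(labels == boundary)
  if (length(sel_b) == 0) stop("conditioned boundary never contacted")
  bmap <- .map_from_samples(traj, env, sel_b, spk_idx)
  bfac <- rescaling_factor(familiar_map, bmap, fam_len, def_len, dimension,
                           alignments = boundary)$factor
  ras <- rasterize_positions(env, traj$x, traj$y)
  target <- tabulate(ras$idx[sel_b], nbins = ras$nx * ras$ny)
  all_by_px <- split(seq_along(ras$idx), ras$idx)
  iters <- vapply(seq_len(iterations), function(it) {
    sub <- integer(0)
    for (p in names(all_by_px)) {
      k <- min(target[as.integer(p)], length(all_by_px[[p]]))
      if (k == 0) next
      s <- all_by_px[[p]]
      sub <- c(sub, if (length(s) == k) s else sample(s, k))
    }
    wm <- .map_from_samples(traj, env, sub, spk_idx)
    rescaling_factor(familiar_map, wm, fam_len, def_len, dimension,
                     alignments = boundary)$factor
  }, numeric(1))
  list(boundary_factor = bfac, matched_whole_factor = mean(iters),
       per_iteration = iters, boundary_map = bmap)
}

#' Boundary-tethered prediction of a deformed-trial rate map
#'
#' For each boundary, a predicted boundary rate map is the familiar rate
#' map registered at that boundary's (possibly displaced) position; for
#' boundaries whose own length changed, the centred portion of the
#' familiar map is used.  Each predicted boundary map is weighted by the
#' per-pixel probability of the rat having most recently contacted that
#' boundary during the deformation trial (computed from the per-label
#' occupancy maps), the weighted maps are summed and the result is
#' smoothed with the standard kernel.  All pixels are retained (no
#' visited-mask exclusion).  Only compressions (and the undeformed case)
#' are supported, as in the underlying analysis.
#'
#' @param familiar_map familiar whole-trial `gt_ratemap`.
#' @param traj_def deformation-trial trajectory.
#' @param labels boundary-contact labels for `traj_def`.
#' @param env_fam,env_def familiar and deformed environments.
#' @return a `gt_ratemap` (mask all TRUE) on the deformed pixel grid.
#' @export
predict_deformed_map <- function(familiar_map, traj_def, labels, env_fam,
                                 env_def) {
  ras <- rasterize_positions(env_def, traj_def$x, traj_def$y)
  nx_d <- ras$nx; ny_d <- ras$ny
  nx_f <- nrow(familiar_map$rate); ny_f <- ncol(familiar_map$rate)
  if (nx_d > nx_f || ny_d > ny_f)
    stop("prediction supports compressions only")
  offs <- function(dir) {
    ox <- switch(dir, W = 0L, E = nx_f - nx_d,
                 as.integer(floor((nx_f - nx_d) / 2)))
    oy <- switch(dir, S = 0L, N = ny_f - ny_d,
                 as.integer(floor((ny_f - ny_d) / 2)))
    c(ox, oy)
  }
  dirs <- c("N", "S", "E", "W")
  npx <- nx_d * ny_d
  acc <- matrix(0, nx_d, ny_d)
  wtot <- matrix(0, nx_d, ny_d)
  for (d in dirs) {
    sel <- which(labels == d)
    if (length(sel) == 0) next        # weight zero for unobserved labels
    occ <- matrix(tabulate(ras$idx[sel], nbins = npx), nx_d, ny_d)
    w <- smooth_map(occ, matrix(TRUE, nx_d, ny_d), fill_all = TRUE)
    o <- offs(d)
    crop <- familiar_map$rate[o[1] + seq_len(nx_d), o[2] + seq_len(ny_d)]
    crop[is.na(crop)] <- 0
    acc <- acc + w * crop
    wtot <- wtot + w
  }
  pred <- ifelse(wtot > 1e-12, acc / wtot, 0)
  pred <- smooth_map(pred, matrix(TRUE, nx_d, ny_d), fill_all = TRUE)
  structure(list(rate = pred, rate_raw = pred,
                 mask = matrix(TRUE, nx_d, ny_d),
                 occupancy_s = NULL, spike_count = NULL,
                 pixel_cm = env_def$pixel_cm,
                 duration_s = max(traj_def$t), n_spikes = NA),
            class = "gt_ratemap")
}

#' Matched-rescaling comparator map
#'
#' The familiar rate map uniformly rescaled to the deformed chamber
#' dimensions (both axes), on the unchanged 2.5 cm pixel grid.
#'
#' @param familiar_map familiar `gt_ratemap`.
#' @param env_def deformed environment.
#' @return a `gt_ratemap`.
#' @export
matched_rescaling_map <- function(familiar_map, env_def) {
  pitch <- familiar_map$pixel_cm
  nx <- ceiling(env_def$width_cm / pitch - 1e-9)
  ny <- ceiling(env_def$height_cm / pitch - 1e-9)
  m <- rescale_map_axis(familiar_map$rate, 1, nx)
  m <- rescale_map_axis(m, 2, ny)
  structure(list(rate = m, rate_raw = m, mask = !is.na(m),
                 occupancy_s = NULL, spike_count = NULL,
                 pixel_cm = pitch, duration_s = familiar_map$duration_s,
                 n_spikes = familiar_map$n_spikes),
            class = "gt_ratemap")
}

#' Similarity between recorded and predicted maps
#'
#' Overlap Pearson correlation and its Fisher z transform (capped to
#' avoid infinities at r = 1).
#'
#' @param recorded_map,predicted_map `gt_ratemap`s of equal dimensions.
#' @return list with `r`, `z`.
#' @export
prediction_similarity <- function(recorded_map, predicted_map) {
  if (!all(dim(recorded_map$rate) == dim(predicted_map$rate)))
    stop("maps must have equal dimensions")
  A <- recorded_map$rate; A[!recorded_map$mask] <- NA
  B <- predicted_map$rate; B[!predicted_map$mask] <- NA
  r <- .map_overlap_r(A, B, min_overlap = 3)
  if (is.na(r)) stop("degenerate maps")
  cap <- 1 - 1e-10
  list(r = r, z = atanh(pmin(pmax(r, -cap), cap)))
}

#' Population-vector correlation between conditions
#'
#' For each location, the Pearson correlation across units between the
#' familiar and deformed rate vectors, with the deformed map registered
#' inside the familiar frame at a pixel offset (default: shared
#' south-west corner).  Pixels with fewer than 2 jointly valid units or
#' zero variance are masked.
#'
#' @param maps_familiar,maps_deformed lists of `gt_ratemap`s for the same
#'   units, in the same order.
#' @param offset_px integer (dx, dy) pixel offset of the deformed map's
#'   origin within the familiar frame.
#' @return list with `r` (matrix on the deformed grid), `column_means`
#'   (mean r along the east-west axis, one value per x column).
#' @export
population_vector_correlation <- function(maps_familiar, maps_deformed,
                                          offset_px = c(0L, 0L)) {
  stopifnot(length(maps_familiar) == length(maps_deformed),
            length(maps_familiar) > 1)
  nu <- length(maps_familiar)
  nx_d <- nrow(maps_deformed[[1]]$rate); ny_d <- ncol(maps_deformed[[1]]$rate)
  F_ <- array(NA_real_, c(nx_d, ny_d, nu))
  D_ <- array(NA_real_, c(nx_d, ny_d, nu))
  for (u in seq_len(nu)) {
    fm <- maps_familiar[[u]]$rate
    fmask <- maps_familiar[[u]]$mask
    fm[!fmask] <- NA
    dm <- maps_deformed[[u]]$rate
    dm[!maps_deformed[[u]]$mask] <- NA
    xr <- offset_px[1] + seq_len(nx_d); yr <- offset_px[2] + seq_len(ny_d)
    ok <- xr >= 1 & xr <= nrow(fm)
    ok2 <- yr >= 1 & yr <= ncol(fm)
    F_[ok, ok2, u] <- fm[xr[ok], yr[ok2]]
    D_[, , u] <- dm
  }
  r <- matrix(NA_real_, nx_d, ny_d)
  for (i in seq_len(nx_d)) for (j in seq_len(ny_d)) {
    f <- F_[i, j, ]; d <- D_[i, j, ]
    ok <- !is.na(f) & !is.na(d)
    if (sum(ok) < 2) next
    if (stats::sd(f[ok]) < 1e-12 || stats::sd(d[ok]) < 1e-12) next
    r[i, j] <- stats::cor(f[ok], d[ok])
  }
  list(r = r, column_means = rowMeans(r, na.rm = TRUE))
}
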