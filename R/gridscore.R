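#' Connected components of a logical matrix (8-connectivity)
#'
#' @param m logical matrix.
#' @return integer matrix of component labels (0 = background).
#' @keywords internal
.label_blobs <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  stack <- integer(nr * nc)
  for (start in which(m)) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    sp <- 1L; stack[1] <- start
    lab[start] <- cur
    while (sp > 0L) {
      p <- stack[sp]; sp <- sp - 1L
      i <- (p - 1L) %% nr + 1L; j <- (p - 1L) %/% nr + 1L
      for (dj in -1:1) for (di in -1:1) {
        ii <- i + di; jj <- j + dj
        if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc) {
          q <- (jj - 1L) * nr + ii
          if (m[q] && lab[q] == 0L) {
            lab[q] <- cur
            sp <- sp + 1L; stack[sp] <- q
          }
        }
      }
    }
  }
  lab
}

#' Grid scale from an autocorrelogram
#'
#' Positive-correlation pixels are partitioned into contiguous blobs
#' (8-connectivity).  Excluding the central blob, each surrounding blob's
#' centre of mass (correlation-weighted) is a candidate peak; the scale is
#' the mean distance from the centre of the autocorrelogram to the six
#' closest surrounding peaks.  Distance ties among candidates are broken
#' by angle ascending from east.  Fewer than six surrounding peaks raises
#' an error (the cell is excluded downstream).
#'
#' @param corr a `gt_correlogram` (autocorrelogram).
#' @param method `"blob"` (default: blob centres of mass) or
#'   `"localmax"` (strict 8-neighbourhood local maxima of r).
#' @return list with `scale_cm`, `peaks_cm` (6 x 2 matrix of peak
#'   positions relative to the centre, cm), `n_blobs`.
#' @export
grid_scale <- function(corr, method = c("blob", "localmax")) {
  method <- match.arg(method)
  pos <- corr$valid & !is.na(corr$r) & corr$r > 0
  lab <- .label_blobs(pos)
  ci <- corr$center[1]; cj <- corr$center[2]
  central <- lab[ci, cj]
  if (central == 0L) {
    # centre not positive (cross-correlograms): nearest blob is central
    stop("autocorrelogram centre is not inside a positive blob")
  }
  if (method == "blob") {
    ids <- setdiff(sort(unique(as.integer(lab))), c(0L, central))
    if (length(ids) < 6) stop("fewer than 6 surrounding peaks")
    pk <- t(vapply(ids, function(id) {
      w <- which(lab == id)
      i <- (w - 1L) %% nrow(lab) + 1L; j <- (w - 1L) %/% nrow(lab) + 1L
      rw <- corr$r[w]
      c(sum(i * rw) / sum(rw), sum(j * rw) / sum(rw))
    }, numeric(2)))
  } else {
    nr <- nrow(corr$r); nc <- ncol(corr$r)
    r0 <- corr$r; r0[!pos] <- -Inf
    ismax <- matrix(TRUE, nr, nc)
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      shifted <- matrix(-Inf, nr, nc)
      si <- max(1, 1 + di):min(nr, nr + di)
      sj <- max(1, 1 + dj):min(nc, nc + dj)
      shifted[si, sj] <- r0[si - di, sj - dj]
      ismax <- ismax & (r0 > shifted)
    }
    w <- which(ismax & pos & lab != central)
    if (length(w) < 6) stop("fewer than 6 surrounding peaks")
    pk <- cbind((w - 1L) %% nr + 1L, (w - 1L) %/% nr + 1L)
  }
  dx <- (pk[, 1] - ci) * corr$pixel_cm
  dy <- (pk[, 2] - cj) * corr$pixel_cm
  d <- sqrt(dx^2 + dy^2)
  ang <- atan2(dy, dx) %% (2 * pi)
  ord <- order(d, ang)[1:6]
  list(scale_cm = mean(d[ord]), peaks_cm = cbind(dx = dx[ord], dy = dy[ord]),
       n_blobs = max(lab))
}

#' Rotate a matrix about a centre point (bilinear interpolation)
#' @keywords internal
.rotate_about <- function(m, angle_deg, ci, cj) {
  nr <- nrow(m); nc <- ncol(m)
  th <- angle_deg * pi / 180
  co <- cos(th); si <- sin(th)
  out <- matrix(NA_real_, nr, nc)
  j <- rep(seq_len(nc), each = nr)
  i <- rep(seq_len(nr), nc)
  # source position: rotate backwards
  x <- i - ci; y <- j - cj
  sx <- co * x + si * y + ci
  sy <- -si * x + co * y + cj
  x0 <- floor(sx); y0 <- floor(sy)
  fx <- sx - x0; fy <- sy - y0
  ok <- x0 >= 1 & x0 + 1 <= nr & y0 >= 1 & y0 + 1 <= nc
  g <- function(ii, jj) m[cbind(ii, jj)]
  val <- rep(NA_real_, length(i))
  o <- which(ok)
  v00 <- g(x0[o], y0[o]); v10 <- g(x0[o] + 1, y0[o])
  v01 <- g(x0[o], y0[o] + 1); v11 <- g(x0[o] + 1, y0[o] + 1)
  val[o] <- v00 * (1 - fx[o]) * (1 - fy[o]) + v10 * fx[o] * (1 - fy[o]) +
    v01 * (1 - fx[o]) * fy[o] + v11 * fx[o] * fy[o]
  out[cbind(i, j)] <- val
  out
}

#' Gridness score
#'
#' The autocorrelogram is masked to an annulus between 0.5 and 1.5 times
#' the grid scale, correlated with itself rotated by 30, 60, 90, 120 and
#' 150 degrees, and scored as `min(r60, r120) - max(r30, r90, r150)`.
#' Hexagonal patterns score positive, square patterns negative, radially
#' symmetric patterns zero.
#'
#' @param corr a `gt_correlogram` (autocorrelogram).
#' @param scale_cm grid scale from [grid_scale()].
#' @return numeric gridness score.
#' @export
gridness <- function(corr, scale_cm) {
  ci <- corr$center[1]; cj <- corr$center[2]
  nr <- nrow(corr$r); nc <- ncol(corr$r)
  d <- sqrt((outer(seq_len(nr) - ci, rep(0, nc), "+"))^2 +
            (outer(rep(0, nr), seq_len(nc) - cj, "+"))^2) * corr$pixel_cm
  ann <- d >= 0.5 * scale_cm & d <= 1.5 * scale_cm
  base <- corr$r
  base[!corr$valid] <- NA
  base[!ann] <- NA
  if (all(is.na(base))) stop("empty annulus")
  rots <- vapply(c(30, 60, 90, 120, 150), function(a) {
    rot <- .rotate_about(base, a, ci, cj)
    ok <- !is.na(base) & !is.na(rot)
    if (sum(ok) < 3) return(NA_real_)
    stats::cor(base[ok], rot[ok])
  }, numeric(1))
  min(rots[c(2, 4)]) - max(rots[c(1, 3, 5)])
}

#' Field length along one dimension
#'
#' The central autocorrelogram peak is the set of contiguous pixels with
#' correlation above 10% of the maximum correlation; field length is the
#' distance between the most extreme pixels of that peak along the chosen
#' dimension.
#'
#' @param corr a `gt_correlogram` (autocorrelogram).
#' @param dimension `"x"` (east-west) or `"y"` (north-south).
#' @return length in cm.
#' @export
field_length <- function(corr, dimension = c("x", "y")) {
  dimension <- match.arg(dimension)
  r <- corr$r
  r[!corr$valid] <- NA
  thr <- 0.1 * max(r, na.rm = TRUE)
  lab <- .label_blobs(!is.na(r) & r > thr)
  central <- lab[corr$center[1], corr$center[2]]
  if (central == 0L) stop("centre pixel below threshold")
  w <- which(lab == central)
  i <- (w - 1L) %% nrow(r) + 1L; j <- (w - 1L) %/% nrow(r) + 1L
  v <- if (dimension == "x") i else j
  (max(v) - min(v)) * corr$pixel_cm
}

#' Peak and mean firing rate
#'
#' Peak rate is the maximum of the smoothed whole-trial rate map over
#' visited pixels; mean rate is the total spike count divided by trial
#' duration.
#'
#' @param map a `gt_ratemap`.
#' @param duration_s trial duration (default: from the map).
#' @return list with `peak_hz`, `mean_hz`.
#' @export
firing_rates <- function(map, duration_s = map$duration_s) {
  list(peak_hz = max(map$rate[map$mask], na.rm = TRUE),
       mean_hz = map$n_spikes / duration_s)
}

#' Grid-cell inclusion criterion
#'
#' A cell is included when its mean gridness across the familiar trials is
#' strictly greater than 0.4; missing trials are dropped from the mean.
#'
#' @param gridness_familiar numeric vector of familiar-trial gridness
#'   scores (NAs allowed).
#' @param threshold inclusion threshold (default 0.4, strict).
#' @return logical.
#' @export
include_cell <- function(gridness_familiar, threshold = 0.4) {
  g <- gridness_familiar[!is.na(gridness_familiar)]
  if (length(g) == 0) return(FALSE)
  mean(g) > threshold
}
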