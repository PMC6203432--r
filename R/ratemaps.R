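#' Occupancy-normalised firing-rate map
#'
#' Divides the environment into `pixel_cm` (default 2.5 cm) square pixels,
#' computes mean firing rate per pixel (spike count / occupancy time) and
#' smooths with an isotropic Gaussian kernel (sd 1.5 pixels, 9 x 9 pixel
#' support) renormalised over the valid support at map edges.  Pixels that
#' were never visited are masked (`NA`) and excluded from later
#' correlations, except for prediction maps where all pixels are retained.
#'
#' @param traj a `gt_trajectory`.
#' @param spike_t spike times in seconds (within the trajectory span), or
#'   `NULL` if `spike_counts` is given.
#' @param env a `gt_env`.
#' @param smooth apply the Gaussian smoothing (default TRUE).
#' @param sigma_px kernel sd in pixels (default 1.5).
#' @param support_px kernel support side in pixels (default 9).
#' @param spike_counts optional precomputed per-pixel spike counts (length
#'   `nx * ny`, x-major), e.g. expected counts from a rate-based run.
#' @param sample_idx optional precomputed sample index per spike.
#' @param keep_sample_counts keep per-pixel sample counts (occupancy in
#'   samples) for subsampling analyses.
#' @return object of class `gt_ratemap`: list with `rate` (nx x ny matrix,
#'   Hz; `[ix, iy]`, x east / y north), `rate_raw` (unsmoothed), `mask`
#'   (visited), `occupancy_s`, `spike_count`, `pixel_cm`, `duration_s`,
#'   `n_spikes`.
#' @export
rate_map <- function(traj, spike_t = NULL, env, smooth = TRUE,
                     sigma_px = 1.5, support_px = 9, spike_counts = NULL,
                     sample_idx = NULL, keep_sample_counts = FALSE) {
  if (length(traj$t) == 0) stop("empty trajectory")
  ras <- rasterize_positions(env, traj$x, traj$y)
  npx <- ras$nx * ras$ny
  occ_n <- tabulate(ras$idx, nbins = npx)
  occ_s <- occ_n * traj$dt_s
  if (is.null(spike_counts)) {
    if (is.null(sample_idx))
      sample_idx <- spike_sample_index(spike_t, traj)
    cnt <- tabulate(ras$idx[sample_idx], nbins = npx)
    n_spk <- length(sample_idx)
  } else {
    cnt <- spike_counts
    n_spk <- sum(spike_counts)
  }
  rate_raw <- matrix(ifelse(occ_n > 0, cnt / ifelse(occ_s > 0, occ_s, 1),
                            NA_real_), ras$nx, ras$ny)
  mask <- matrix(occ_n > 0, ras$nx, ras$ny)
  rate <- if (smooth) smooth_map(rate_raw, mask, sigma_px, support_px)
          else rate_raw
  out <- list(rate = rate, rate_raw = matrix_or_na(rate_raw, mask),
              mask = mask,
              occupancy_s = matrix(occ_s, ras$nx, ras$ny),
              spike_count = matrix(cnt, ras$nx, ras$ny),
              pixel_cm = env$pixel_cm,
              duration_s = max(traj$t) - min(traj$t) + traj$dt_s,
              n_spikes = n_spk)
  if (keep_sample_counts) out$sample_count <- matrix(occ_n, ras$nx, ras$ny)
  structure(out, class = "gt_ratemap")
}

matrix_or_na <- function(m, mask) { m[!mask] <- NA_real_; m }

#' Map spike times to trajectory sample indices
#'
#' Each spike is assigned to the sample whose time bin `[t_i, t_{i+1})`
#' contains it.
#'
#' @param spike_t spike times (s).
#' @param traj a `gt_trajectory`.
#' @return integer vector of sample indices.
#' @export
spike_sample_index <- function(spike_t, traj) {
  if (is.null(spike_t) || length(spike_t) == 0) return(integer(0))
  idx <- findInterval(spike_t, traj$t)
  idx[idx < 1] <- 1
  idx[idx > length(traj$t)] <- length(traj$t)
  idx
}

#' Gaussian smoothing over a masked map
#'
#' The kernel is renormalised over the valid (visited) pixels under its
#' support, so edge pixels are unbiased; masked pixels stay `NA`.
#'
#' @param m matrix with possible `NA`s.
#' @param mask logical matrix of valid pixels (default: `!is.na(m)`).
#' @param sigma_px kernel sd in pixels.
#' @param support_px kernel support side (odd).
#' @param fill_all if `TRUE`, also fill masked pixels from the
#'   kernel-weighted valid neighbourhood (used by prediction maps).
#' @return smoothed matrix.
#' @export
smooth_map <- function(m, mask = NULL, sigma_px = 1.5, support_px = 9,
                       fill_all = FALSE) {
  if (is.null(mask)) mask <- !is.na(m)
  half <- (support_px - 1) / 2
  g <- stats::dnorm(-half:half, sd = sigma_px)
  k <- outer(g, g)
  mm <- m; mm[!mask] <- 0
  num <- .conv2_same(mm, k)
  den <- .conv2_same(mask * 1, k)
  out <- ifelse(den > 1e-12, num / den, NA_real_)
  if (!fill_all) out[!mask] <- NA_real_
  out
}

# zero-padded 'same' 2-D convolution via FFT
.conv2_same <- function(m, k) {
  nr <- nrow(m) + nrow(k) - 1
  nc <- ncol(m) + ncol(k) - 1
  pm <- matrix(0, nr, nc); pm[1:nrow(m), 1:ncol(m)] <- m
  pk <- matrix(0, nr, nc); pk[1:nrow(k), 1:ncol(k)] <- k
  full <- Re(stats::fft(stats::fft(pm) * stats::fft(pk), inverse = TRUE)) /
    (nr * nc)
  r0 <- (nrow(k) - 1) / 2; c0 <- (ncol(k) - 1) / 2
  full[(r0 + 1):(r0 + nrow(m)), (c0 + 1):(c0 + ncol(m))]
}

#' Auto/cross-correlogram of rate maps
#'
#' Pearson correlation between overlapping valid pixels of `map_a` and
#' `map_b` displaced by every integer pixel lag; lags with fewer than
#' `min_overlap` overlapping pixels (default 20) or degenerate variance
#' are masked.  With `map_a = map_b` this is the spatial
#' autocorrelogram.
#'
#' Implemented with FFT cross-correlations of the maps, their squares and
#' their masks, which reproduces the per-lag Pearson formula exactly (up
#' to floating point).
#'
#' @param map_a,map_b `gt_ratemap` objects (or lists with `rate`, `mask`,
#'   `pixel_cm`) on the same pixel pitch.
#' @param min_overlap minimum overlapping pixel count per lag.
#' @return object of class `gt_correlogram`: list with `r` (matrix over
#'   lags, rows = x lags), `valid`, `n` (overlap counts), `center` (index
#'   of the zero lag), `pixel_cm`.
#' @export
correlogram <- function(map_a, map_b = map_a, min_overlap = 20) {
  if (!isTRUE(all.equal(map_a$pixel_cm, map_b$pixel_cm)))
    stop("maps must share pixel pitch")
  A <- map_a$rate; B <- map_b$rate
  MA <- map_a$mask & !is.na(A); MB <- map_b$mask & !is.na(B)
  A[!MA] <- 0; B[!MB] <- 0
  # lag l: overlap of A(x) and B(x - l); cross-correlation via FFT
  xc <- function(X, Y) .xcorr2(X, Y)
  n   <- xc(MA * 1, MB * 1)
  SA  <- xc(A, MB * 1)
  SB  <- xc(MA * 1, B)
  SAB <- xc(A, B)
  SA2 <- xc(A^2, MB * 1)
  SB2 <- xc(MA * 1, B^2)
  n <- round(n)
  num <- n * SAB - SA * SB
  v1 <- n * SA2 - SA^2
  v2 <- n * SB2 - SB^2
  denom <- sqrt(pmax(v1, 0) * pmax(v2, 0))
  valid <- n >= min_overlap & v1 > 1e-9 & v2 > 1e-9
  r <- ifelse(valid, num / denom, NA_real_)
  r <- pmin(pmax(r, -1), 1)
  structure(list(r = r, valid = valid, n = n,
                 center = c(nrow(B), ncol(B)),
                 pixel_cm = map_a$pixel_cm),
            class = "gt_correlogram")
}

# full 2-D cross-correlation: out[dx + nxb, dy + nyb] =
#   sum_x X[x] * Y[x - (dx, dy)], dx in -(nxb-1) .. (nxa-1)
.xcorr2 <- function(X, Y) {
  nxa <- nrow(X); nya <- ncol(X); nxb <- nrow(Y); nyb <- ncol(Y)
  nr <- nxa + nxb - 1; nc <- nya + nyb - 1
  pX <- matrix(0, nr, nc); pX[1:nxa, 1:nya] <- X
  pY <- matrix(0, nr, nc); pY[1:nxb, 1:nyb] <- Y
  out <- Re(stats::fft(stats::fft(pX) * Conj(stats::fft(pY)),
                       inverse = TRUE)) / (nr * nc)
  # wrap so index (nxb, nyb) is zero lag
  out[c((nr - nxb + 2):nr, 1:(nr - nxb + 1)),
      c((nc - nyb + 2):nc, 1:(nc - nyb + 1))]
}

#' Lags of a correlogram in cm
#' @param corr a `gt_correlogram`.
#' @return list `dx`, `dy` (vectors, cm).
#' @export
correlogram_lags <- function(corr) {
  list(dx = (seq_len(nrow(corr$r)) - corr$center[1]) * corr$pixel_cm,
       dy = (seq_len(ncol(corr$r)) - corr$center[2]) * corr$pixel_cm)
}

#' @export
print.gt_ratemap <- function(x, ...) {
  cat(sprintf(
    "<gt_ratemap %d x %d px (%.1f cm), %d spikes, peak %.2f Hz>\n",
    nrow(x$rate), ncol(x$rate), x$pixel_cm, x$n_spikes,
    suppressWarnings(max(x$rate, na.rm = TRUE))))
  invisible(x)
}

#' @export
print.gt_correlogram <- function(x, ...) {
  cat(sprintf("<gt_correlogram %d x %d lags, %d valid>\n",
              nrow(x$r), ncol(x$r), sum(x$valid)))
  invisible(x)
}
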