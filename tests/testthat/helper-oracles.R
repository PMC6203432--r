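# Independent brute-force oracles used to validate the fast implementations.

# Per-lag Pearson correlogram by direct looping (the definition, verbatim):
# for each integer lag, collect overlapping jointly-valid pixels and apply
# cor(); lags with < min_overlap pixels or zero variance are NA.
brute_correlogram <- function(A, B, maskA = !is.na(A), maskB = !is.na(B),
                              min_overlap = 20) {
  nxa <- nrow(A); nya <- ncol(A); nxb <- nrow(B); nyb <- ncol(B)
  out <- matrix(NA_real_, nxa + nxb - 1, nya + nyb - 1)
  for (dx in -(nxb - 1):(nxa - 1)) for (dy in -(nyb - 1):(nya - 1)) {
    va <- c(); vb <- c()
    for (i in 1:nxa) for (j in 1:nya) {
      ib <- i - dx; jb <- j - dy
      if (ib >= 1 && ib <= nxb && jb >= 1 && jb <= nyb &&
          maskA[i, j] && maskB[ib, jb]) {
        va <- c(va, A[i, j]); vb <- c(vb, B[ib, jb])
      }
    }
    if (length(va) >= min_overlap && stats::sd(va) > 1e-12 &&
        stats::sd(vb) > 1e-12)
      out[dx + nxb, dy + nyb] <- stats::cor(va, vb)
  }
  out
}

# map object wrapper for plain matrices
as_map <- function(m, pixel_cm = 2.5, mask = !is.na(m)) {
  structure(list(rate = m, rate_raw = m, mask = mask,
                 occupancy_s = matrix(1, nrow(m), ncol(m)),
                 pixel_cm = pixel_cm, duration_s = 1, n_spikes = NA),
            class = "gt_ratemap")
}

# hand-rolled trajectory constructor
toy_traj <- function(x, y, dt = 0.1) {
  n <- length(x)
  structure(list(t = seq(0, by = dt, length.out = n), x = x, y = y,
                 dt_s = dt,
                 speed_cms = c(0, sqrt(diff(x)^2 + diff(y)^2)) / dt,
                 heading_deg = (atan2(c(0, diff(y)), c(1, diff(x))) *
                                  180 / pi) %% 360),
            class = "gt_trajectory")
}

# distance (sheet units) from zero displacement to the nearest strong
# cross-correlation peak between two sheet states: phase displacement is
# only defined modulo the bump lattice
phase_displacement <- function(a0, a1, nside, thr_frac = 0.8) {
  m0 <- matrix(a0, nside, nside) - mean(a0)
  m1 <- matrix(a1, nside, nside) - mean(a1)
  cc <- Re(stats::fft(stats::fft(m1) * Conj(stats::fft(m0)),
                      inverse = TRUE))
  strong <- which(cc >= thr_frac * max(cc), arr.ind = TRUE)
  sx <- ((strong[, 1] - 1 + nside / 2) %% nside) - nside / 2
  sy <- ((strong[, 2] - 1 + nside / 2) %% nside) - nside / 2
  min(sqrt(sx^2 + sy^2))
}
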