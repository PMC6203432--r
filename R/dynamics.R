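#' Network dynamics constants
#'
#' The fixed constants of the spiking dynamics and learning rule:
#' `kappa = 500` (rate scale, so `kappa * dt = 1.5`), `dt = 0.003` s,
#' `alpha = 0.5` (activation increment per spike), `c = 0.03` s
#' (integration time constant, giving a per-step decay of
#' `1 - dt/c = 0.9`), spike thresholds `beta` of 0 (border), 0.1 (grid)
#' and 0.05 (place), learning rate `lambda = 1e-5`, competitive totals
#' `xi` of 0.4 (border-to-grid) and 0.5 (grid-to-place), baseline grid
#' drive `gamma = 0.6`, shifted radial inhibition (radius 12 units,
#' weight -0.02, centre shift 2 units), border input amplitude 0.1 and
#' uniform place-layer recurrent inhibition -0.15.
#'
#' @param ... overrides for individual constants.
#' @return named list of constants.
#' @export
dynamics_constants <- function(...) {
  cfg <- list(kappa = 500, dt = 0.003, alpha = 0.5, c = 0.03,
              beta_border = 0, beta_grid = 0.1, beta_place = 0.05,
              lambda = 1e-5, xi_bg = 0.4, xi_gp = 0.5, gamma = 0.6,
              inhib_radius = 12L, inhib_shift = 2L, inhib_w = -0.02,
              border_amp = 0.1, place_inhib_w = -0.15,
              w_bg_max = 0.025, w_gp_max = 0.022, n_place_aff = 500L)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown) > 0)
    stop("unknown dynamics constant(s): ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  cfg
}

.engine_cfg <- function(config, learn, rate_based, snapshot,
                        record_expected = FALSE) {
  list(dt = config$dt, kappa = config$kappa, alpha = config$alpha,
       decay = 1 - config$dt / config$c, gamma = config$gamma,
       beta_border = config$beta_border, beta_grid = config$beta_grid,
       beta_place = config$beta_place,
       inhib_radius = as.integer(config$inhib_radius),
       inhib_shift = as.integer(config$inhib_shift),
       inhib_w = config$inhib_w, border_amp = config$border_amp,
       lambda = config$lambda, xi_bg = config$xi_bg, xi_gp = config$xi_gp,
       place_inhib_w = config$place_inhib_w,
       learn = isTRUE(learn), rate_based = isTRUE(rate_based),
       snapshot = isTRUE(snapshot),
       record_expected = isTRUE(record_expected))
}

#' Total synaptic input to a population (reference implementation)
#'
#' Grid units: `b_j = v_j + sum_i a_i w_ij`, where the sum runs over all
#' afferents (border units and the recurrent inhibition entering through
#' the same summed synaptic drive).  Place units:
#' `b_j = sum_i a_i w_ij + w_rec * sum_i a_i` over grid afferents and the
#' uniform recurrent place inhibition (self included).  Border units:
#' `b_j = amplitude * [in field]`.
#'
#' This is the plain-R reference used in tests; the engine computes the
#' same quantity in compiled code.
#'
#' @param population one of `"grid"`, `"place"`, `"border"`.
#' @param activations presynaptic activation vector.
#' @param weights matrix (presyn x postsyn) of feed-forward weights.
#' @param velocity per-unit velocity input `v_j` (grid only).
#' @param recurrent per-unit recurrent drive already summed (grid), or the
#'   uniform recurrent weight (place).
#' @param in_field logical per-unit (border only).
#' @param amplitude border input amplitude.
#' @param place_activations place-layer activation vector (place only).
#' @return numeric vector of total inputs `b_j`.
#' @export
total_input <- function(population = c("grid", "place", "border"),
                        activations = NULL, weights = NULL,
                        velocity = NULL, recurrent = 0,
                        in_field = NULL, amplitude = 0.1,
                        place_activations = NULL) {
  population <- match.arg(population)
  switch(population,
    border = amplitude * as.numeric(in_field),
    grid = {
      ff <- if (is.null(weights)) 0 else drop(crossprod(weights, activations))
      velocity + ff + recurrent
    },
    place = {
      ff <- drop(crossprod(weights, activations))
      ff + recurrent * sum(place_activations)
    })
}

#' Stochastic spike generation (reference implementation)
#'
#' A unit spikes when `kappa * (b - beta) * dt` exceeds a fresh
#' uniform(0,1) draw, i.e. with probability
#' `clip(kappa * (b - beta) * dt, 0, 1)`; at `b = beta` the probability
#' is exactly zero.
#'
#' @param b total input vector.
#' @param beta spike threshold.
#' @param kappa rate scale (default 500).
#' @param dt timestep (default 0.003).
#' @param rate_based if `TRUE`, return the expected spike count (the
#'   clipped probability) instead of a Bernoulli draw.
#' @return 0/1 vector (or probabilities when `rate_based`).
#' @export
spike_step <- function(b, beta, kappa = 500, dt = 0.003,
                       rate_based = FALSE) {
  p <- pmin(pmax(kappa * (b - beta) * dt, 0), 1)
  if (rate_based) return(p)
  as.numeric(p > stats::runif(length(p)))
}

#' Leaky integration of spiking into activation
#'
#' `a' = a - a * dt / c + alpha * s` (with the defaults, `0.9 a + 0.5 s`).
#'
#' @param a activation vector (non-negative).
#' @param s spike vector.
#' @param dt timestep.
#' @param c integration time constant.
#' @param alpha spike increment.
#' @return updated activations.
#' @export
integrate_activation <- function(a, s, dt = 0.003, c = 0.03, alpha = 0.5) {
  a - a * dt / c + alpha * s
}

#' Competitive Hebbian weight update (reference implementation)
#'
#' For the incoming weights of one postsynaptic unit `j`:
#' `w_ij <- w_ij + lambda * a_j * ((xi - w_ij) * a_i - w_ij * sum_{n != i} a_n)`
#' with the sum over the presynaptic pool (units with Hebbian weights onto
#' `j`), clamped at zero.  Coactive inputs grow toward `xi` at the expense
#' of the rest; the per-unit incoming total converges to `xi`.
#'
#' @param w presyn-length weight vector (incoming weights of unit j).
#' @param pre presynaptic activation vector.
#' @param post postsynaptic activation (scalar).
#' @param xi competitive total for this pathway.
#' @param lambda learning rate (default 1e-5).
#' @return updated weight vector.
#' @export
hebbian_update <- function(w, pre, post, xi, lambda = 1e-5) {
  stopifnot(length(w) == length(pre), length(post) == 1)
  w2 <- w + lambda * post * ((xi - w) * pre - w * (sum(pre) - pre))
  pmax(w2, 0)
}

#' @rdname hebbian_update
#' @param W presyn x postsyn weight matrix (the matrix form applies the
#'   rule to every postsynaptic unit at once).
#' @export
hebbian_update_matrix <- function(W, pre, post, xi, lambda = 1e-5) {
  stopifnot(nrow(W) == length(pre), ncol(W) == length(post))
  A <- sum(pre)
  W2 <- W + lambda * ((xi * pre) %o% post - W * A * rep(post, each = nrow(W)))
  W2[W2 < 0] <- 0
  W2
}

#' Iterate the competitive Hebbian rule to its equilibrium
#'
#' Drives a weight matrix with sustained random positive pre/postsynaptic
#' activity until the mean per-unit incoming weight total plateaus, and
#' reports the plateau.  The rule's fixed point puts the incoming total at
#' `xi` regardless of the activity statistics.
#'
#' @param n_pre,n_post pool sizes.
#' @param xi competitive total.
#' @param w_max initial weight upper bound.
#' @param lambda learning rate (default 1e-5).
#' @param max_steps iteration budget.
#' @param tol relative plateau criterion on the mean incoming total over
#'   a 1000-step window.
#' @param seed optional RNG seed.
#' @return list with `mean_total` (plateau value), `totals` (per unit),
#'   `steps_used`.
#' @export
hebbian_equilibrium <- function(n_pre, n_post, xi, w_max,
                                lambda = 1e-5, max_steps = 200000,
                                tol = 1e-4, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  W <- matrix(stats::runif(n_pre * n_post, 0, w_max), n_pre, n_post)
  last <- mean(colSums(W))
  check_every <- 1000
  used <- max_steps
  for (s in seq_len(max_steps)) {
    pre <- stats::runif(n_pre)
    post <- stats::runif(n_post)
    W <- hebbian_update_matrix(W, pre, post, xi, lambda)
    if (s %% check_every == 0) {
      cur <- mean(colSums(W))
      if (abs(cur - last) < tol * max(cur, 1e-12) && s > 10 * check_every) {
        used <- s
        break
      }
      last <- cur
    }
  }
  list(mean_total = mean(colSums(W)), totals = colSums(W), steps_used = used)
}
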