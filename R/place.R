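#' Initialise the place layer
#'
#' Each of the 64 place units receives excitatory projections from 500
#' grid units drawn uniformly at random across all modules (without
#' replacement, per unit), with initial weights uniform on `[0, 0.022]`.
#' All place units are subject to uniform recurrent inhibition (weight
#' -0.15, self included).
#'
#' @param n_grid total number of grid units across modules.
#' @param n_place number of place units (default 64).
#' @param n_aff afferents per place unit (default 500).
#' @param w_max initial weight upper bound (default 0.022).
#' @param seed optional RNG seed.
#' @return list with `aff` (n_aff x n_place, 1-based global grid unit
#'   ids), `w_gp` (n_aff x n_place weights), `a` (activations, zero).
#' @export
init_place_layer <- function(n_grid, n_place = 64, n_aff = 500,
                             w_max = 0.022, seed = NULL) {
  if (n_grid < n_aff) stop("grid population smaller than n_aff")
  if (!is.null(seed)) set.seed(seed)
  aff <- vapply(seq_len(n_place),
                function(j) sample.int(n_grid, n_aff), integer(n_aff))
  w <- matrix(stats::runif(n_aff * n_place, 0, w_max), n_aff, n_place)
  list(aff = aff, w_gp = w, a = numeric(n_place))
}

#' Total input to the place layer (reference implementation)
#'
#' `b_j = sum_i a_i w_ij` over each unit's grid afferents plus the uniform
#' recurrent inhibition `w_rec * sum(place activations)` (self included).
#'
#' @param place_activations place-layer activation vector.
#' @param grid_activations global grid activation vector.
#' @param weights n_aff x n_place weight matrix.
#' @param aff n_aff x n_place afferent index matrix (1-based).
#' @param inhib_w recurrent weight (default -0.15).
#' @return per-unit input vector.
#' @export
place_input <- function(place_activations, grid_activations, weights, aff,
                        inhib_w = -0.15) {
  ff <- colSums(matrix(grid_activations[aff], nrow(aff), ncol(aff)) * weights)
  ff + inhib_w * sum(place_activations)
}

#' Place-field summary of a rate map
#'
#' Fields are contiguous pixel blobs (8-connectivity) above a fraction of
#' the unit's peak rate (default 20%); used to count fields and classify
#' qualitative deformation responses.
#'
#' @param map a `gt_ratemap`.
#' @param frac_of_peak field threshold (default 0.2).
#' @param min_pixels minimum blob size to count as a field (default 4).
#' @return list with `n_fields`, `peak_hz`, `field_pixels` (list of pixel
#'   index vectors).
#' @export
place_fields <- function(map, frac_of_peak = 0.2, min_pixels = 4) {
  r <- map$rate
  r[!map$mask] <- NA
  pk <- suppressWarnings(max(r, na.rm = TRUE))
  if (!is.finite(pk) || pk <= 0)
    return(list(n_fields = 0L, peak_hz = 0, field_pixels = list()))
  lab <- .label_blobs(!is.na(r) & r > frac_of_peak * pk)
  ids <- setdiff(unique(as.integer(lab)), 0L)
  keep <- ids[vapply(ids, function(i) sum(lab == i), integer(1)) >= min_pixels]
  list(n_fields = length(keep), peak_hz = pk,
       field_pixels = lapply(keep, function(i) which(lab == i)))
}
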