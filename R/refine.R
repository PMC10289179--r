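#' Parameters for probability-map region growing
#'
#' @param seed_threshold Probability at or above which a voxel belongs to the
#'   seed region (maximum-probability classification, default 0.5).
#' @param outer_radius Chebyshev radius of the seed-shell neighborhood used
#'   for the adaptive threshold; the default 2 gives the 5x5x5-minus-center
#'   neighborhood of 124 voxels.
#' @param connectivity Growth connectivity: 6, 18, 26 (3D, default) or 8
#'   (the literal in-plane 8-neighborhood applied per XY slice).
#' @param max_grow_iters Cap on frontier-expansion rounds.
#' @param per_component Compute one adaptive threshold per connected seed
#'   component (default) instead of a single global threshold.
#' @param single_step Perform one expansion round only instead of iterating
#'   to a fixed point.
#' @return A list of class `"grow_params"`.
#' @export
grow_params <- function(seed_threshold = 0.5, outer_radius = 2L,
                        connectivity = 26L, max_grow_iters = 1000L,
                        per_component = TRUE, single_step = FALSE) {
  if (!connectivity %in% c(6L, 18L, 26L, 8L))
    stop("connectivity must be one of 6, 18, 26, 8", call. = FALSE)
  structure(list(
    seed_threshold = seed_threshold, outer_radius = as.integer(outer_radius),
    connectivity = as.integer(connectivity),
    max_grow_iters = as.integer(max_grow_iters),
    per_component = isTRUE(per_component), single_step = isTRUE(single_step)
  ), class = "grow_params")
}

#' Seed region of a probability map
#'
#' Maximum-probability classification: voxels with foreground probability at
#' or above the threshold (default 0.5) form the seed region.
#'
#' @param prob Probability map in `[0, 1]`.
#' @param threshold Inclusive seed threshold.
#' @return Logical 3D array.
#' @export
seed_region <- function(prob, threshold = 0.5) {
  assert_volume(prob)
  array(prob >= threshold, dim(prob))
}

label_seed <- function(seed, params) {
  lab <- label_components_cpp(as.vector(seed), dim(seed), 26L)
  if (!params$per_component && lab$n_components > 1L) {
    merged <- ifelse(lab$labels > 0L, 1L, 0L)
    lab <- list(labels = merged, n_components = 1L)
  }
  lab
}

#' Adaptive growth threshold(s) near the seed region
#'
#' For each connected seed component (26-connectivity), the shell is the
#' union of the 5x5x5-minus-center neighborhoods of its voxels, excluding
#' every seed voxel; the component's threshold `rho` is the mean probability
#' over its shell. A component whose shell is empty (seed fills the volume)
#' gets `rho = 1` with a warning, so no growth is possible there.
#'
#' @param prob Probability map in `[0, 1]`.
#' @param seed Logical seed mask ([seed_region()]).
#' @param params A [grow_params()].
#' @return List with `rho` (numeric, one entry per component), `labels`
#'   (integer component array) and `shell` (logical mask of all shells).
#' @export
adaptive_threshold <- function(prob, seed, params = grow_params()) {
  same_shape(prob, seed, "prob and seed")
  lab <- label_seed(seed, params)
  if (lab$n_components == 0L)
    return(list(rho = numeric(0),
                labels = array(0L, dim(prob)),
                shell = array(FALSE, dim(prob))))
  sm <- shell_means_cpp(as.vector(prob), lab$labels, dim(prob),
                        lab$n_components, params$outer_radius)
  rho <- sm$mean
  if (anyNA(rho)) {
    warning("seed component with empty shell; rho set to 1 (no growth)")
    rho[is.na(rho)] <- 1
  }
  list(rho = rho,
       labels = array(lab$labels, dim(prob)),
       shell = array(sm$shell, dim(prob)))
}

#' Grow the seed region over the probability map
#'
#' Layer-synchronous frontier expansion: a voxel joins the region when it is
#' adjacent (under the growth connectivity) to an absorbed voxel of some
#' component and its probability strictly exceeds that component's `rho`.
#' Rounds repeat until a fixed point or `max_grow_iters`. Conflicts between
#' components resolve to the smallest `rho`, making the grown set
#' independent of traversal order.
#'
#' @param prob Probability map in `[0, 1]`.
#' @param seed Logical seed mask.
#' @param rho Numeric vector of per-component thresholds (recycled if a
#'   single global value is given), ordered as the components of
#'   [adaptive_threshold()].
#' @param params A [grow_params()].
#' @return A list of class `"grow_result"`: `seed` (Oreg), `shell` (Nreg),
#'   `rho`, `grown` (Greg), `labels` (grown component array), `iterations`
#'   and `truncated`.
#' @export
region_grow <- function(prob, seed, rho = NULL, params = grow_params()) {
  same_shape(prob, seed, "prob and seed")
  at <- adaptive_threshold(prob, seed, params)
  if (is.null(rho)) rho <- at$rho
  k <- max(1L, length(at$rho))
  if (length(rho) == 1L) rho <- rep(rho, k)
  if (length(at$rho) > 0 && length(rho) != length(at$rho))
    stop("rho must have one entry per seed component", call. = FALSE)
  if (length(at$rho) == 0L) {
    warning("empty seed region; nothing to grow")
    return(structure(list(seed = seed, shell = at$shell, rho = numeric(0),
                          grown = seed, labels = at$labels,
                          iterations = 0L, truncated = FALSE),
                     class = "grow_result"))
  }
  gr <- region_grow_cpp(as.vector(prob), as.vector(at$labels), dim(prob),
                        rho, params$connectivity, params$max_grow_iters,
                        params$single_step)
  if (gr$truncated)
    warning("region growing stopped at max_grow_iters before a fixed point")
  structure(list(seed = seed, shell = at$shell, rho = rho,
                 grown = array(gr$labels > 0L, dim(prob)),
                 labels = array(gr$labels, dim(prob)),
                 iterations = gr$iterations, truncated = gr$truncated),
            class = "grow_result")
}

#' Refine pseudo-labels by region growing on a probability map
#'
#' The full mining step: seed by maximum-probability classification, compute
#' per-component adaptive thresholds from the seed shells, grow to a fixed
#' point, and return the grown region as the refined pseudo-label. The
#' grown region always contains the seed, so recall against any reference
#' can only improve.
#'
#' @param prob Probability map in `[0, 1]`.
#' @param params A [grow_params()].
#' @return Logical 3D array (the grown region) with attributes `rho`,
#'   `iterations` and `truncated`; an empty mask (with a warning) when no
#'   voxel reaches the seed threshold.
#' @export
refine_labels <- function(prob, params = grow_params()) {
  assert_volume(prob)
  seed <- seed_region(prob, params$seed_threshold)
  if (!any(seed)) {
    warning("empty seed region; returning empty mask")
    out <- array(FALSE, dim(prob))
    attr(out, "rho") <- numeric(0)
    return(out)
  }
  gr <- region_grow(prob, seed, NULL, params)
  out <- gr$grown
  attr(out, "rho") <- gr$rho
  attr(out, "iterations") <- gr$iterations
  attr(out, "truncated") <- gr$truncated
  out
}
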