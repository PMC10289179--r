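#' Parameters of probability/intensity fusion
#'
#' @param alpha Weight of the original intensity term, in `[0, 1]`
#'   (default 0.8).
#' @param beta Weight of the probability term, in `[0, 1]` (default
#'   `1 - alpha`).
#' @param delta Foreground screening threshold on the 0-255 probability
#'   scale (default 2): voxels with `255 * P <= delta` contribute no
#'   original intensity.
#' @param im Maximum image intensity (default 255).
#' @return A list of class `"fusion_params"`.
#' @export
fusion_params <- function(alpha = 0.8, beta = 1 - alpha, delta = 2, im = 255) {
  if (alpha < 0 || alpha > 1 || beta < 0 || beta > 1)
    stop("alpha and beta must lie in [0, 1]", call. = FALSE)
  if (alpha + beta == 0)
    stop("invalid config: alpha + beta must be > 0", call. = FALSE)
  if (delta < 0 || delta > im)
    stop("delta must lie in [0, im]", call. = FALSE)
  structure(list(alpha = alpha, beta = beta, delta = delta, im = im),
            class = "fusion_params")
}

#' Screen an image by foreground probability
#'
#' Zeroes the intensity of every voxel whose probability (on the 0-255
#' scale) does not strictly exceed `delta`, keeping the rest unchanged.
#'
#' @param image Intensity volume on `[0, im]`.
#' @param prob Probability map in `[0, 1]`.
#' @param delta Screening threshold on the 0-255 probability scale.
#' @return Screened intensity volume.
#' @export
screen_foreground <- function(image, prob, delta = 2) {
  same_shape(image, prob, "image and prob")
  image[255 * prob <= delta] <- 0
  image
}

#' Fuse original intensities with a probability map
#'
#' The enhanced training input of the iterative loop:
#' `F = alpha/(alpha+beta) * Theta * I + beta/(alpha+beta) *
#' floor((1-alpha) * IM * P)`, where `Theta` is the indicator of the
#' probability screen `255 * P > delta`. The first term preserves local
#' image detail on probable foreground; the second injects the network's
#' global structure. Output is clipped to `[0, IM]`.
#'
#' @param image Intensity volume on `[0, im]`.
#' @param prob Probability map in `[0, 1]`.
#' @param params A [fusion_params()].
#' @return Fused intensity volume in `[0, im]`.
#' @export
fuse_probability <- function(image, prob, params = fusion_params()) {
  assert_volume(image)
  same_shape(image, prob, "image and prob")
  ab <- params$alpha + params$beta
  theta <- (255 * prob) > params$delta
  # the epsilon keeps exactly-representable products (e.g. 0.2 * 255 = 51)
  # from dropping a whole intensity level to floating-point rounding
  fused <- (params$alpha / ab) * theta * image +
    (params$beta / ab) * floor((1 - params$alpha) * params$im * prob + 1e-9)
  fused <- pmin(pmax(fused, 0), params$im)
  array(fused, dim(image))
}
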