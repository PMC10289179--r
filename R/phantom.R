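#' Configuration for the synthetic neuron phantom generator
#'
#' Defines a synthetic fMOST-like scene: bright tubular neurites of varying
#' radius whose intensity peaks on the centerline and decays radially,
#' spherical somata attached to a subset of neurite endpoints, a flat or
#' linearly ramped background, and additive Gaussian noise.
#'
#' @param shape Integer triple `(z, y, x)`, each at least 16 voxels.
#' @param n_neurites Number of tubular neurites.
#' @param radius_range Tube radius range in voxels, minimum at least 1.
#' @param soma_radius_range Soma ball radius range in voxels.
#' @param centerline_intensity Peak neurite intensity (8-bit level).
#' @param soma_intensity Soma intensity (8-bit level).
#' @param background_level Background intensity (8-bit level).
#' @param illumination_gradient Linear background ramp along x, expressed as a
#'   fraction of `background_level` across the volume span. 0 gives a flat
#'   background.
#' @param noise_sigma Standard deviation of additive Gaussian noise (8-bit
#'   levels). 0 disables noise.
#' @param intensity_falloff Radial decay factor: the structure intensity at
#'   distance `d` from the centerline of a tube with radius `r` is
#'   `centerline_intensity * exp(-(d/r)^2 * intensity_falloff)` (truncated at
#'   `d > r`), so the middle of a fiber is brighter than its edge.
#' @param soma_prob Probability that a neurite carries a soma at one endpoint.
#' @param seed RNG seed; the same seed and configuration give a bit-identical
#'   `(image, mask)` pair.
#' @return A list of class `"phantom_config"`.
#' @seealso [generate_phantom()]
#' @export
phantom_config <- function(shape = c(64, 64, 64),
                           n_neurites = 5,
                           radius_range = c(1, 2),
                           soma_radius_range = c(4, 6),
                           centerline_intensity = 200,
                           soma_intensity = 255,
                           background_level = 20,
                           illumination_gradient = 0.2,
                           noise_sigma = 15,
                           intensity_falloff = 0.5,
                           soma_prob = 0.4,
                           seed = 1) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 16L))
    stop("`shape` must be a (z, y, x) triple with each extent >= 16", call. = FALSE)
  if (radius_range[1] < 1 || radius_range[2] < radius_range[1])
    stop("`radius_range` must satisfy 1 <= min <= max", call. = FALSE)
  ints <- c(centerline_intensity, soma_intensity, background_level)
  if (any(ints < 0) || any(ints > 255))
    stop("intensities must lie in [0, 255]", call. = FALSE)
  if (noise_sigma < 0) stop("`noise_sigma` must be >= 0", call. = FALSE)
  if (min(shape) < 2 * radius_range[1])
    stop("`shape` too small to contain the minimum tube radius", call. = FALSE)
  structure(list(
    shape = shape, n_neurites = as.integer(n_neurites),
    radius_range = radius_range, soma_radius_range = soma_radius_range,
    centerline_intensity = centerline_intensity, soma_intensity = soma_intensity,
    background_level = background_level,
    illumination_gradient = illumination_gradient,
    noise_sigma = noise_sigma, intensity_falloff = intensity_falloff,
    soma_prob = soma_prob, seed = seed
  ), class = "phantom_config")
}

# bounded-turning random walk through the volume, unit steps, resampled at
# sub-voxel spacing; returns an n x 3 matrix of (z, y, x) points. Walks
# enter at a random face heading inward, so fibers traverse the volume the
# way neurites cross an imaged block.
phantom_centerline <- function(shape, max_turn = 30 * pi / 180, step = 1,
                               resample = 0.25) {
  start <- runif(3, min = 2, max = shape - 1)
  face_axis <- sample.int(3, 1)
  at_min <- runif(1) < 0.5
  start[face_axis] <- if (at_min) 2 else shape[face_axis] - 1
  dir <- rnorm(3)
  dir[face_axis] <- abs(dir[face_axis]) * (if (at_min) 1 else -1)
  dir <- dir / sqrt(sum(dir^2))
  pts <- list(start)
  pos <- start
  max_len <- 3 * max(shape)
  for (i in seq_len(max_len)) {
    # perturb direction by an angle <= max_turn about a random orthogonal axis
    u <- rnorm(3)
    u <- u - sum(u * dir) * dir
    nu <- sqrt(sum(u^2))
    if (nu > 1e-12) {
      u <- u / nu
      theta <- runif(1, 0, max_turn)
      dir <- cos(theta) * dir + sin(theta) * u
      dir <- dir / sqrt(sum(dir^2))
    }
    pos <- pos + step * dir
    if (any(pos < 1) || any(pos > shape)) break
    pts[[length(pts) + 1L]] <- pos
  }
  poly <- do.call(rbind, pts)
  if (nrow(poly) < 2) return(poly)
  # subdivide each unit segment at `resample` spacing
  k <- max(1L, round(step / resample))
  t <- seq(0, 1, length.out = k + 1L)[-(k + 1L)]
  fine <- lapply(seq_len(nrow(poly) - 1L), function(i) {
    p0 <- poly[i, ]
    p1 <- poly[i + 1L, ]
    outer(1 - t, p0) + outer(t, p1)
  })
  rbind(do.call(rbind, fine), poly[nrow(poly), , drop = FALSE])
}

#' Rasterize tubes around polyline centerlines
#'
#' Marks the voxels nearest to each centerline sample point, then uses the
#' exact Euclidean distance transform to find every voxel within the tube
#' radius of its centerline. Also returns the radial intensity profile
#' `peak * exp(-(d/r)^2 * falloff)` truncated at the tube surface.
#'
#' @param shape `(z, y, x)` extents.
#' @param centerlines List of `n x 3` matrices of `(z, y, x)` points (may be
#'   fractional; points are snapped to the voxel grid).
#' @param radii Numeric vector, one tube radius per centerline.
#' @param peak Peak (centerline) intensity.
#' @param falloff Radial decay factor.
#' @return List with logical `mask` and numeric `intensity`, both 3D arrays.
#' @export
rasterize_tubes <- function(shape, centerlines, radii, peak = 200, falloff = 1) {
  shape <- as.integer(shape)
  mask <- array(FALSE, shape)
  intens <- array(0, shape)
  for (i in seq_along(centerlines)) {
    pts <- centerlines[[i]]
    if (is.null(pts) || nrow(pts) == 0) next
    idx <- pmin(pmax(round_half_up(pts), 1), matrix(shape, nrow(pts), 3, byrow = TRUE))
    cl <- array(FALSE, shape)
    cl[cbind(idx[, 1], idx[, 2], idx[, 3])] <- TRUE
    # distance of every voxel to the nearest centerline voxel
    d <- edt_cpp(as.vector(!cl), shape, FALSE)
    dim(d) <- shape
    r <- radii[i]
    inside <- d <= r
    mask <- mask | inside
    prof <- peak * exp(-(d / r)^2 * falloff)
    prof[!inside] <- 0
    intens <- pmax(intens, prof)
  }
  list(mask = mask, intensity = intens)
}

#' Generate a synthetic 3D neuron volume with ground truth
#'
#' Builds an fMOST-like phantom: smooth random-walk neurites rasterized as
#' tubes with radially decaying intensity, optional somata at neurite
#' endpoints, a linear illumination ramp, and additive Gaussian noise. The
#' geometry (and hence the mask) depends only on the seed and the geometric
#' parameters, never on `noise_sigma`.
#'
#' @param config A [phantom_config()].
#' @return List with `image` (numeric 3D array, values in `[0, 255]`) and
#'   `mask` (logical 3D array, the ground-truth segmentation).
#' @examples
#' ph <- generate_phantom(phantom_config(shape = c(32, 32, 32), n_neurites = 2))
#' range(ph$image)
#' mean(ph$mask)
#' @export
generate_phantom <- function(config = phantom_config()) {
  if (!inherits(config, "phantom_config"))
    stop("`config` must be a phantom_config", call. = FALSE)
  shape <- config$shape
  local_seed(config$seed, {
    ncl <- config$n_neurites
    centerlines <- vector("list", ncl)
    radii <- numeric(ncl)
    if (ncl > 0) {
      for (i in seq_len(ncl)) {
        centerlines[[i]] <- phantom_centerline(shape)
        radii[i] <- runif(1, config$radius_range[1], config$radius_range[2])
      }
    }
    has_soma <- if (ncl > 0) runif(ncl) < config$soma_prob else logical(0)
    soma_radii <- if (ncl > 0) runif(ncl, config$soma_radius_range[1],
                                     config$soma_radius_range[2]) else numeric(0)
    # soma sits at a random interior point of its fiber (walks enter and
    # leave at the faces, so endpoints would truncate the ball)
    soma_pos <- if (ncl > 0) runif(ncl, 0.25, 0.75) else numeric(0)

    tubes <- rasterize_tubes(shape, centerlines, radii,
                             peak = config$centerline_intensity,
                             falloff = config$intensity_falloff)
    mask <- tubes$mask
    intens <- tubes$intensity

    if (any(has_soma)) {
      zc <- slice.index(mask, 1)
      yc <- slice.index(mask, 2)
      xc <- slice.index(mask, 3)
      for (i in which(has_soma)) {
        pts <- centerlines[[i]]
        if (is.null(pts) || nrow(pts) == 0) next
        ctr <- pts[max(1L, round(soma_pos[i] * nrow(pts))), ]
        d <- sqrt((zc - ctr[1])^2 + (yc - ctr[2])^2 + (xc - ctr[3])^2)
        ball <- d <= soma_radii[i]
        mask <- mask | ball
        intens <- pmax(intens, config$soma_intensity * ball)
      }
    }

    nx <- shape[3]
    xnorm <- if (nx > 1) (slice.index(mask, 3) - 1) / (nx - 1) else 0
    bg <- config$background_level *
      (1 + config$illumination_gradient * (xnorm - 0.5))
    img <- bg + intens
    if (config$noise_sigma > 0)
      img <- img + rnorm(length(img), sd = config$noise_sigma)
    img <- pmin(pmax(img, 0), 255)
    dim(img) <- shape
    list(image = img, mask = mask)
  })
}
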