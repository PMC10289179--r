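#' Parameters of the adaptive Hessian enhancement filter
#'
#' Controls the distance-transform-driven Hessian analysis that turns a raw
#' volume into a line-enhanced response, the soma hole-filling rule, and the
#' threshold segmentation that yields pseudo-labels.
#'
#' @param a,b,c Sensitivity constants of the three response factors (line
#'   anisotropy, blobness, second-order energy). Defaults 5.55, 2 and 2e6;
#'   `c` is calibrated to second derivatives of 0-255 intensities.
#' @param fg_threshold_i1 8-bit level binarizing the volume for the thickness
#'   distance transform.
#' @param soma_threshold_i2 Higher 8-bit level localizing somata; must exceed
#'   `fg_threshold_i1`.
#' @param soma_dt_threshold Distance (voxels) above which a voxel of the
#'   high-threshold distance field is declared soma interior and filled.
#' @param radius_min,radius_max Clamp range of the per-voxel Hessian window
#'   radius (voxels).
#' @param pseudo_label_method `"fixed"` (default) or `"otsu"` threshold
#'   segmentation of the enhanced response. The fixed low threshold is the
#'   default because the enhanced response of a sparse neurite scene is a
#'   near-zero background plus a long foreground tail (plus the 255 soma
#'   plateau), a histogram shape on which Otsu's between-class criterion
#'   locks onto the soma plateau instead of the background/neurite split.
#' @param pseudo_label_value 8-bit level used when `pseudo_label_method` is
#'   `"fixed"` (mask is `response >= value`).
#' @param derivative_scale Gain applied to the Hessian eigenvalues before
#'   the response function (default 10). It matches the dynamic range of
#'   discrete second derivatives of 8-bit microscopy data to the
#'   second-order energy constant `c`: an ideal bright thin fiber
#'   (peak 255, unit radius) then reaches `|lambda| ~ 2.5e3 ~ sqrt(c)`, the
#'   saturation point of the third response factor.
#' @param scale_floor Minimum Gaussian scale (voxels) of the derivative
#'   kernels, `s = max(R/2, scale_floor)`; sub-voxel scales alias on the
#'   integer grid, so the floor defaults to 1.
#' @param p2_literal Use the literal product form
#'   `|lambda1| * |lambda2 * lambda3|` for the blobness measure instead of the
#'   ratio `|lambda1| / sqrt(|lambda2 * lambda3|)`. Off by default; the ratio
#'   form is the one whose limiting behaviour matches an ideal line.
#' @return A list of class `"enhancer_params"`.
#' @export
enhancer_params <- function(a = 5.55, b = 2, c = 2e6,
                            fg_threshold_i1 = 40,
                            soma_threshold_i2 = 150,
                            soma_dt_threshold = 1,
                            radius_min = 1L, radius_max = 8L,
                            pseudo_label_method = c("fixed", "otsu"),
                            pseudo_label_value = 20,
                            derivative_scale = 10,
                            scale_floor = 1,
                            p2_literal = FALSE) {
  if (a <= 0 || b <= 0 || c <= 0) stop("a, b, c must be > 0", call. = FALSE)
  if (soma_threshold_i2 <= fg_threshold_i1)
    stop("invalid config: soma_threshold_i2 must exceed fg_threshold_i1",
         call. = FALSE)
  if (!(radius_min >= 1 && radius_min <= radius_max))
    stop("need 1 <= radius_min <= radius_max", call. = FALSE)
  structure(list(
    a = a, b = b, c = c,
    fg_threshold_i1 = fg_threshold_i1,
    soma_threshold_i2 = soma_threshold_i2,
    soma_dt_threshold = soma_dt_threshold,
    radius_min = as.integer(radius_min), radius_max = as.integer(radius_max),
    pseudo_label_method = match.arg(pseudo_label_method),
    pseudo_label_value = pseudo_label_value,
    derivative_scale = derivative_scale,
    scale_floor = scale_floor,
    p2_literal = isTRUE(p2_literal)
  ), class = "enhancer_params")
}

#' Euclidean distance transform of a thresholded volume
#'
#' Binarizes the volume at `threshold` (foreground is `I >= threshold`) and
#' returns, for every foreground voxel, the exact Euclidean distance to the
#' nearest background voxel; background voxels are 0. With
#' `border_background = TRUE` (default) the volume border counts as adjacent
#' to background, which keeps the transform finite on all-foreground input.
#'
#' @param vol Numeric 3D array on the 0-255 scale.
#' @param threshold Binarization level.
#' @param border_background Treat the voxels just outside the volume as
#'   background?
#' @return Numeric 3D array of distances in voxels.
#' @export
distance_transform <- function(vol, threshold, border_background = TRUE) {
  assert_volume(vol)
  fg <- as.vector(vol >= threshold)
  d <- edt_cpp(fg, dim(vol), isTRUE(border_background))
  dim(d) <- dim(vol)
  d
}

#' Normalize a distance field onto \[1, 256\]
#'
#' Affinely maps the positive (foreground) distances onto `[1, 256]`:
#' `DN = 1 + 255 * (DT - DTmin) / (DTmax - DTmin)`. Background voxels get
#' `DN = 1`. A constant positive field (degenerate span) maps to 1
#' everywhere.
#'
#' @param field Distance field from [distance_transform()].
#' @return Numeric 3D array with values in `[1, 256]`.
#' @export
normalize_dt <- function(field) {
  assert_volume(field)
  fg <- field > 0
  if (!any(fg)) stop("distance field has no positive values", call. = FALSE)
  dn <- array(1, dim(field))
  dmin <- min(field[fg])
  dmax <- max(field[fg])
  if (dmax > dmin)
    dn[fg] <- 1 + 255 * (field[fg] - dmin) / (dmax - dmin)
  dn
}

#' Per-voxel adaptive Hessian window radius
#'
#' `R = clamp(round(log2 DN), radius_min, radius_max)` with round-half-up,
#' and window diameter `DI = 2R + 1`, so the analysis window tracks the
#' local fiber thickness measured by the normalized distance transform.
#'
#' @param dn Normalized distance field in `[1, 256]` ([normalize_dt()]).
#' @param radius_min,radius_max Clamp range (defaults 1 and 8).
#' @return List with integer arrays `R` (radius) and `DI` (diameter).
#' @export
adaptive_radius <- function(dn, radius_min = 1L, radius_max = 8L) {
  if (any(dn < 1 - 1e-9) || any(dn > 256 + 1e-9))
    stop("normalized distances must lie in [1, 256]", call. = FALSE)
  r <- round_half_up(log2(dn))
  r <- pmin(pmax(r, radius_min), radius_max)
  storage.mode(r) <- "integer"
  list(R = r, DI = 2L * r + 1L)
}

#' Gaussian derivative kernels for a window radius
#'
#' Builds the smoothing, first-derivative and second-derivative kernels of
#' scale `s = max(R/2, scale_floor)`, truncated to the window diameter
#' `2R + 1`. The discrete taps are corrected so that the smoothing kernel
#' sums to 1, the derivative kernels annihilate constants, and first/second
#' derivatives of linear and quadratic ramps are reproduced exactly.
#'
#' @param r Window radius (integer >= 1).
#' @param scale_floor Minimum Gaussian scale in voxels (default 1).
#' @return List with numeric vectors `g0`, `g1`, `g2` of length `2r + 1`.
#' @export
gaussian_deriv_kernels <- function(r, scale_floor = 1) {
  r <- as.integer(r)
  stopifnot(r >= 1)
  s <- max(r / 2, scale_floor)
  x <- seq(-r, r)
  g0 <- exp(-x^2 / (2 * s^2))
  g0 <- g0 / sum(g0)
  g1 <- -x / s^2 * g0
  g1 <- g1 - mean(g1)
  g1 <- g1 / sum(g1 * x)
  g2 <- (x^2 - s^2) / s^4 * g0
  g2 <- g2 - mean(g2)
  g2 <- g2 / sum(g2 * x^2 / 2)
  list(g0 = g0, g1 = g1, g2 = g2)
}

#' Hessian eigenvalues with a per-voxel analysis window
#'
#' Computes the six second-order Gaussian derivative responses by separable
#' correlation (symmetric boundary reflection) at every distinct window
#' radius present in `R`, solves the per-voxel symmetric 3x3 eigenproblem,
#' and gathers each voxel's eigenvalues at its own radius. Eigenvalues are
#' sorted by increasing absolute value.
#'
#' @param vol Numeric 3D array (intensity scale is arbitrary; eigenvalues
#'   carry intensity per squared voxel units).
#' @param R Integer array of window radii (from [adaptive_radius()]) or a
#'   single radius applied everywhere.
#' @param scale_floor Minimum Gaussian kernel scale in voxels.
#' @return List of numeric 3D arrays `l1`, `l2`, `l3` with
#'   `|l1| <= |l2| <= |l3|` voxel-wise.
#' @export
hessian_eigen <- function(vol, R, scale_floor = 1) {
  assert_volume(vol)
  d <- dim(vol)
  if (length(R) == 1L) R <- array(as.integer(R), d)
  storage.mode(R) <- "integer"
  same_shape(vol, R, "volume and radius field")
  l1 <- array(0, d); l2 <- array(0, d); l3 <- array(0, d)
  for (r in sort(unique(as.vector(R)))) {
    k <- gaussian_deriv_kernels(r, scale_floor)
    # axis order: 1 = z, 2 = y, 3 = x
    smooth_z <- conv_axis_cpp(vol, d, k$g0, 1L)
    hzz <- conv_axis_cpp(conv_axis_cpp(conv_axis_cpp(vol, d, k$g2, 1L),
                                       d, k$g0, 2L), d, k$g0, 3L)
    hyy <- conv_axis_cpp(conv_axis_cpp(smooth_z, d, k$g2, 2L), d, k$g0, 3L)
    hxx <- conv_axis_cpp(conv_axis_cpp(smooth_z, d, k$g0, 2L), d, k$g2, 3L)
    hzy <- conv_axis_cpp(conv_axis_cpp(conv_axis_cpp(vol, d, k$g1, 1L),
                                       d, k$g1, 2L), d, k$g0, 3L)
    hzx <- conv_axis_cpp(conv_axis_cpp(conv_axis_cpp(vol, d, k$g1, 1L),
                                       d, k$g0, 2L), d, k$g1, 3L)
    hyx <- conv_axis_cpp(conv_axis_cpp(smooth_z, d, k$g1, 2L), d, k$g1, 3L)
    ev <- eig3_sym_cpp(hxx, hyy, hzz, hyx, hzx, hzy)
    sel <- as.vector(R == r)
    l1[sel] <- ev$l1[sel]
    l2[sel] <- ev$l2[sel]
    l3[sel] <- ev$l3[sel]
  }
  list(l1 = l1, l2 = l2, l3 = l3)
}

#' Line-structure response from Hessian eigenvalues
#'
#' For eigenvalues sorted by absolute value the response is 0 whenever
#' `lambda2 > 0` or `lambda3 > 0` (bright structures on dark background have
#' negative principal curvatures), and otherwise
#' `(1 - exp(-a p1^2)) * exp(-b p2^2) * (1 - exp(-p3sq / c))` with
#' `p1 = |l2|/|l3|` (line anisotropy), `p2 = |l1|/sqrt(|l2 l3|)` (blobness;
#' see `p2_literal` in [enhancer_params()]), and
#' `p3sq = l1^2 + l2^2 + l3^2` (second-order energy). `p1` and `p2` are 0
#' when their denominators vanish. Plates (`p1 = 0`) and background
#' (`p3sq` small) get no response; ideal lines approach
#' `(1 - exp(-a))`.
#'
#' @param l1,l2,l3 Eigenvalue arrays (or scalars) with `|l1|<=|l2|<=|l3|`.
#' @param params An [enhancer_params()].
#' @return Array of responses in `[0, 1)`.
#' @export
vesselness_response <- function(l1, l2, l3, params = enhancer_params()) {
  p1 <- ifelse(l3 != 0, abs(l2) / abs(l3), 0)
  denom <- sqrt(abs(l2 * l3))
  p2 <- if (params$p2_literal) abs(l1) * abs(l2 * l3)
        else ifelse(denom > 0, abs(l1) / denom, 0)
  p3sq <- l1^2 + l2^2 + l3^2
  resp <- (1 - exp(-params$a * p1^2)) * exp(-params$b * p2^2) *
    (1 - exp(-p3sq / params$c))
  resp[l2 > 0 | l3 > 0] <- 0
  resp
}

#' Fill soma interiors in an enhanced volume
#'
#' Line filters hollow blob-like somata into rings. The distance transform of
#' the volume binarized at the higher threshold `I2` localizes soma (and
#' thick-fiber) interiors: wherever it exceeds `soma_dt_threshold`, the
#' enhanced response is forced to 255.
#'
#' @param enhanced Enhanced response array on the 0-255 scale.
#' @param vol The original intensity volume (0-255).
#' @param params An [enhancer_params()].
#' @return The enhanced array with soma interiors set to 255; the filled
#'   voxels are recorded in the `"soma_filled"` attribute.
#' @export
soma_fill <- function(enhanced, vol, params = enhancer_params()) {
  same_shape(enhanced, vol, "enhanced and vol")
  if (params$soma_threshold_i2 <= params$fg_threshold_i1)
    stop("invalid config: soma_threshold_i2 must exceed fg_threshold_i1",
         call. = FALSE)
  d2 <- distance_transform(vol, params$soma_threshold_i2)
  sel <- d2 > params$soma_dt_threshold
  enhanced[sel] <- 255
  attr(enhanced, "soma_filled") <- sel
  enhanced
}

#' Adaptive Hessian enhancement of a neuron volume
#'
#' The full filter: binarize at `I1`, take the Euclidean distance transform
#' as a thickness proxy, normalize it onto `[1, 256]`, derive a per-voxel
#' window radius `R = clamp(round(log2 DN), 1, 8)`, compute Hessian
#' eigenvalues at that radius, evaluate the line response, rescale to 0-255,
#' and fill soma interiors. Deterministic.
#'
#' @param vol Numeric 3D array on the 0-255 scale.
#' @param params An [enhancer_params()].
#' @return Enhanced response array in `[0, 255]` with attributes `radius`
#'   (the per-voxel window radius) and `soma_filled`.
#' @export
enhance_volume <- function(vol, params = enhancer_params()) {
  assert_volume(vol)
  d1 <- distance_transform(vol, params$fg_threshold_i1)
  if (any(d1 > 0)) {
    dn <- normalize_dt(d1)
    rr <- adaptive_radius(dn, params$radius_min, params$radius_max)$R
  } else {
    rr <- array(params$radius_min, dim(vol))
    storage.mode(rr) <- "integer"
  }
  ev <- hessian_eigen(vol, rr, params$scale_floor)
  g <- params$derivative_scale
  resp <- vesselness_response(ev$l1 * g, ev$l2 * g, ev$l3 * g, params)
  out <- resp * 255
  out <- soma_fill(out, vol, params)
  attr(out, "radius") <- rr
  out
}

#' Otsu threshold of a 0-255 volume
#'
#' Maximizes the between-class variance over 256 intensity bins and returns
#' the threshold level: the mask convention is `value > threshold`. Ties
#' resolve to the smallest level.
#'
#' @param x Numeric array or vector on the 0-255 scale.
#' @return Threshold level in `[0, 255]`.
#' @export
otsu_threshold <- function(x) {
  bins <- pmin(pmax(floor(as.vector(x)), 0), 255)
  counts <- tabulate(bins + 1L, nbins = 256L)
  n <- sum(counts)
  levels <- 0:255
  w0 <- cumsum(counts)
  m0 <- cumsum(counts * levels)
  mu <- m0[256]
  w1 <- n - w0
  num <- (mu * w0 - m0 * n)^2
  den <- as.numeric(w0) * as.numeric(w1)
  sigma_b <- ifelse(den > 0, num / den, 0)
  levels[which.max(sigma_b)]
}

#' Threshold segmentation of an enhanced volume into pseudo-labels
#'
#' Binarizes the enhanced response with an Otsu threshold (default) or a
#' fixed level, giving the initial training labels of the weakly supervised
#' loop. A constant response yields an empty mask.
#'
#' @param enhanced Enhanced response array (0-255), e.g. from
#'   [enhance_volume()].
#' @param params An [enhancer_params()].
#' @return Logical 3D array; the threshold used is stored in the
#'   `"threshold"` attribute.
#' @export
make_pseudolabels <- function(enhanced, params = enhancer_params()) {
  assert_volume(enhanced)
  d <- dim(enhanced)
  if (max(enhanced) == min(enhanced)) {
    out <- array(FALSE, d)
    attr(out, "threshold") <- NA_real_
    return(out)
  }
  if (params$pseudo_label_method == "otsu") {
    thr <- otsu_threshold(enhanced)
    mask <- enhanced > thr
  } else {
    thr <- params$pseudo_label_value
    mask <- enhanced >= thr
  }
  mask <- array(as.logical(mask), d)
  attr(mask, "threshold") <- thr
  mask
}
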