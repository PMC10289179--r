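#' Read a multi-page grayscale TIFF stack as a 3D volume
#'
#' Pages become z-slices: the result is a numeric array indexed `[z, y, x]`.
#' Integer sample values are preserved as stored (no rescaling); the sample
#' bit depth is recorded in the `"bits"` attribute.
#'
#' @param path Path to a multi-page grayscale TIFF.
#' @param spacing Physical voxel size `(z, y, x)` in micrometres, kept as
#'   metadata only.
#' @return Numeric 3D array with attributes `bits` and `spacing`.
#' @export
read_stack <- function(path, spacing = c(1, 1, 1)) {
  info <- tiff::readTIFF(path, payload = FALSE)
  bps <- if (is.data.frame(info)) info$bits.per.sample[1] else attr(info, "bits.per.sample")
  is_float <- isTRUE(bps >= 32)  # 32-bit samples are float-format maps
  # float samples are read as-stored; integer samples keep their raw levels
  pages <- tiff::readTIFF(path, all = TRUE, as.is = !is_float, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (any(!vapply(pages, function(p) length(dim(p)) == 2L, logical(1))))
    stop("unsupported format: expected single-channel grayscale pages", call. = FALSE)
  ny <- nrow(pages[[1]])
  nx <- ncol(pages[[1]])
  nz <- length(pages)
  vol <- array(0, c(nz, ny, nx))
  for (z in seq_len(nz)) vol[z, , ] <- pages[[z]]
  bits <- attr(pages[[1]], "bits.per.sample") %||% 8L
  attr(vol, "bits") <- as.integer(bits)
  attr(vol, "spacing") <- spacing
  vol
}

#' Write a 3D volume as a multi-page grayscale TIFF
#'
#' @param vol Numeric 3D array `[z, y, x]`. For integer bit depths values are
#'   interpreted on the `[0, 2^bits - 1]` scale; for `bits = 32` values are
#'   written as float samples as-is (probability maps in `[0, 1]`).
#' @param path Output path.
#' @param bits Bits per sample: 8, 16, or 32 (float).
#' @return The path, invisibly.
#' @export
write_stack <- function(vol, path, bits = 8L) {
  assert_volume(vol)
  if (!bits %in% c(8L, 16L, 32L)) stop("`bits` must be 8, 16 or 32", call. = FALSE)
  scale <- if (bits == 32L) 1 else (2^bits - 1)
  pages <- lapply(seq_len(dim(vol)[1]), function(z) vol[z, , ] / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = as.integer(bits))
  invisible(path)
}

#' Write a binary mask as an 8-bit \{0, 255\} TIFF stack
#'
#' @param mask Logical 3D array.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_mask <- function(mask, path) {
  assert_mask(mask)
  vol <- array(as.numeric(mask) * 255, dim(mask))
  write_stack(vol, path, bits = 8L)
}

#' Preprocess an 8-bit volume for network input
#'
#' Optionally applies global (per-volume) 256-bin histogram equalization to
#' strengthen contrast, then normalizes to `[0, 1]` by dividing by 255.
#' Equalization uses the classic monotone CDF remapping
#' `(cdf(v) - cdf_min) / (n - cdf_min) * 255`; a constant volume is left
#' unchanged (no threshold separates a single occupied bin).
#'
#' @param vol Numeric 3D array on the 0-255 scale.
#' @param equalize Apply histogram equalization before normalizing?
#' @return Numeric 3D array in `[0, 1]`.
#' @export
preprocess <- function(vol, equalize = FALSE) {
  assert_volume(vol)
  if (isTRUE(equalize)) {
    bins <- pmin(pmax(floor(as.vector(vol)), 0), 255)
    counts <- tabulate(bins + 1L, nbins = 256L)
    cdf <- cumsum(counts)
    cdf_min <- min(cdf[cdf > 0])
    n <- length(bins)
    if (n > cdf_min) {
      lut <- (cdf - cdf_min) / (n - cdf_min) * 255
      lut[lut < 0] <- 0
      out <- lut[bins + 1L]
      dim(out) <- dim(vol)
      vol <- out
    }
  }
  array(as.vector(vol) / 255, dim = dim(vol))
}

#' The augmentation transform group
#'
#' Seven invertible spatial transforms used both for training augmentation
#' and for test-time prediction averaging: the identity, rotations by +90,
#' -90 and 180 degrees in the XY plane, horizontal and vertical XY mirrors,
#' and a flip along z.
#'
#' @return Character vector of transform names.
#' @export
augment_transforms <- function() {
  c("identity", "rot90_xy", "rot-90_xy", "rot180_xy",
    "mirror_h_xy", "mirror_v_xy", "flip_z")
}

check_transform <- function(name) {
  if (!name %in% augment_transforms())
    stop(sprintf("unknown transform '%s'", name), call. = FALSE)
  name
}

#' Apply a spatial transform to a volume
#'
#' XY-plane operations act on the last two axes of the `[z, y, x]` array;
#' rotations by 90 degrees swap the y and x extents.
#'
#' @param vol 3D array (any mode).
#' @param name Transform name, one of [augment_transforms()].
#' @return Transformed array.
#' @export
apply_transform <- function(vol, name) {
  check_transform(name)
  d <- dim(vol)
  switch(name,
    identity = vol,
    rot90_xy = {
      t <- aperm(vol, c(1, 3, 2))
      t[, dim(t)[2]:1, , drop = FALSE]
    },
    `rot-90_xy` = {
      t <- aperm(vol, c(1, 3, 2))
      t[, , dim(t)[3]:1, drop = FALSE]
    },
    rot180_xy = vol[, d[2]:1, d[3]:1, drop = FALSE],
    mirror_h_xy = vol[, , d[3]:1, drop = FALSE],
    mirror_v_xy = vol[, d[2]:1, , drop = FALSE],
    flip_z = vol[d[1]:1, , , drop = FALSE]
  )
}

#' Name of the inverse of a transform
#'
#' Every element of the augmentation group is an involution except the two
#' 90-degree rotations, which are mutual inverses.
#'
#' @param name Transform name.
#' @return The inverse transform's name.
#' @export
inverse_transform <- function(name) {
  check_transform(name)
  switch(name, rot90_xy = "rot-90_xy", `rot-90_xy` = "rot90_xy", name)
}

#' Apply transforms jointly to an image and its label
#'
#' @param image Numeric 3D array.
#' @param label Mask array of the same shape.
#' @param transforms Character vector of transform names.
#' @return List of `(image, label)` pairs, one per transform, each pair
#'   transformed identically.
#' @export
augment_pair <- function(image, label, transforms = augment_transforms()) {
  same_shape(image, label, "image and label")
  lapply(transforms, function(tr) {
    list(image = apply_transform(image, tr),
         label = apply_transform(label, tr),
         transform = tr)
  })
}

#' Prediction averaging over the augmentation group
#'
#' Runs `predict_fn` on each transformed copy of the volume, applies the
#' inverse transform to each probability map, and averages. The identity is
#' always included, so an empty transform list reduces to a single plain
#' prediction.
#'
#' @param predict_fn Function mapping a volume to a probability map of the
#'   same shape.
#' @param vol Numeric 3D array.
#' @param transforms Character vector of transform names.
#' @return Numeric 3D array in `[0, 1]`.
#' @export
predict_averaged <- function(predict_fn, vol,
                             transforms = augment_transforms()) {
  ts <- unique(c("identity", transforms))
  vapply(ts, check_transform, character(1))
  acc <- NULL
  for (tr in ts) {
    p <- predict_fn(apply_transform(vol, tr))
    p <- apply_transform(p, inverse_transform(tr))
    same_shape(p, vol, "prediction and volume")
    acc <- if (is.null(acc)) p else acc + p
  }
  acc / length(ts)
}
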