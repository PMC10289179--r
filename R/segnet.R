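#' Training configuration for the volumetric segmentation network
#'
#' @param batch_size Mini-batch size (default 4).
#' @param base_lr SGD learning rate (default 0.01).
#' @param momentum SGD momentum (default 0.9).
#' @param init_std Standard deviation of the Gaussian weight initialization
#'   (default 0.01).
#' @param max_steps Number of SGD steps. The desk-scale default is 300; the
#'   full-scale regime uses 30000.
#' @param sigma_wce Weight of the weighted-cross-entropy term in the combined
#'   loss (default 1).
#' @param patch_shape Training patch extents `(z, y, x)`; each must be
#'   divisible by the network's total downsampling factor (2).
#' @param width Base channel width of the encoder (default 8); the deeper
#'   level uses twice this.
#' @param seed RNG seed for weight initialization and patch sampling.
#' @param prob_clip Lower clamp applied inside logarithms (default 1e-7).
#' @param wce_variant Cross-entropy form used as the training objective:
#'   `"balanced"` (default) uses inverse-frequency weights `1/(2 gamma)` on
#'   foreground and `1/(2 (1 - gamma))` on background so both classes carry
#'   equal total mass; `"foreground"` is the foreground-only form with weight
#'   `gamma` that [wce_loss()] implements by default.
#' @param wce_mean Normalize the cross-entropy term of the training
#'   objective by the patch voxel count (default `TRUE`). The
#'   cross-entropy is a voxel sum while the Dice term is bounded by 1, so
#'   without normalization any `sigma_wce` of order 1 makes the
#'   cross-entropy gradient drown the Dice gradient at realistic patch
#'   sizes. The reported loss values follow the same convention.
#' @param grad_clip Global L2 gradient-norm clip applied before each SGD
#'   update; `Inf` disables.
#' @param fg_patch_frac Fraction of training patches centered on a random
#'   foreground pseudo-label voxel rather than sampled uniformly.
#' @param augment Sample a random transform from [augment_transforms()] for
#'   every training patch?
#' @return A list of class `"train_config"`.
#' @export
train_config <- function(batch_size = 4L, base_lr = 0.01, momentum = 0.9,
                         init_std = 0.01, max_steps = 300L, sigma_wce = 1,
                         patch_shape = c(32L, 32L, 32L), width = 8L,
                         seed = 1L, prob_clip = 1e-7,
                         wce_variant = c("balanced", "foreground"),
                         wce_mean = TRUE,
                         grad_clip = 5, fg_patch_frac = 0.5,
                         augment = TRUE) {
  if (batch_size < 1) stop("batch_size must be >= 1", call. = FALSE)
  if (base_lr <= 0) stop("base_lr must be > 0", call. = FALSE)
  if (sigma_wce < 0) stop("sigma_wce must be >= 0", call. = FALSE)
  patch_shape <- as.integer(patch_shape)
  if (length(patch_shape) != 3L || any(patch_shape %% 2L != 0L))
    stop("patch_shape extents must be divisible by 2", call. = FALSE)
  structure(list(
    batch_size = as.integer(batch_size), base_lr = base_lr,
    momentum = momentum, init_std = init_std,
    max_steps = as.integer(max_steps), sigma_wce = sigma_wce,
    patch_shape = patch_shape, width = as.integer(width),
    seed = as.integer(seed), prob_clip = prob_clip,
    wce_variant = match.arg(wce_variant), wce_mean = isTRUE(wce_mean),
    grad_clip = grad_clip,
    fg_patch_frac = fg_patch_frac, augment = isTRUE(augment)
  ), class = "train_config")
}

#' Weighted cross-entropy loss
#'
#' The foreground-weighted cross-entropy over a volume:
#' `sum(-gamma * g * log(clip(p)))` with `gamma` the foreground fraction
#' `sum(g) / n`. This form has no background term; the `"balanced"` variant
#' uses inverse-frequency weights (`1/(2 gamma)` on foreground,
#' `1/(2 (1 - gamma))` on background) so each class carries half the total
#' mass.
#'
#' @param p Predicted foreground probabilities in `[0, 1]`.
#' @param g Binary labels (same shape).
#' @param clip Lower clamp inside the logarithms.
#' @param variant `"foreground"` (default) or `"balanced"`.
#' @return Non-negative scalar; 0 when `gamma = 0` under `"foreground"`.
#' @export
wce_loss <- function(p, g, clip = 1e-7, variant = c("foreground", "balanced")) {
  variant <- match.arg(variant)
  same_shape(p, g, "p and g")
  g <- as.numeric(g)
  n <- length(g)
  gamma <- sum(g) / n
  if (variant == "foreground") {
    if (gamma == 0) return(0)
    sum(-gamma * g * log(pmax(as.numeric(p), clip)))
  } else {
    pn <- as.numeric(p)
    w_fg <- if (gamma > 0) 1 / (2 * gamma) else 0
    w_bg <- if (gamma < 1) 1 / (2 * (1 - gamma)) else 0
    sum(-w_fg * g * log(pmax(pn, clip))) +
      sum(-w_bg * (1 - g) * log(pmax(1 - pn, clip)))
  }
}

#' Dice loss
#'
#' `1 - (2 * sum(p*g) + eps) / (sum(p) + sum(g) + eps)` with smoothing
#' `eps = 1`, so a perfect binary prediction and the doubly-empty case both
#' give 0.
#'
#' @param p Predicted foreground probabilities.
#' @param g Binary labels (same shape).
#' @param eps Smoothing parameter.
#' @return Scalar in `[0, 1)`.
#' @export
dice_loss <- function(p, g, eps = 1) {
  same_shape(p, g, "p and g")
  p <- as.numeric(p)
  g <- as.numeric(g)
  1 - (2 * sum(p * g) + eps) / (sum(p) + sum(g) + eps)
}

#' Combined segmentation loss
#'
#' `sigma * WCE + Dice`, the mixed objective balancing voxel-wise
#' cross-entropy against regional overlap.
#'
#' @inheritParams wce_loss
#' @param sigma Weight of the cross-entropy term.
#' @param eps Dice smoothing parameter.
#' @return Scalar loss.
#' @export
combined_loss <- function(p, g, sigma = 1, clip = 1e-7, eps = 1,
                          variant = c("foreground", "balanced")) {
  sigma * wce_loss(p, g, clip, variant) + dice_loss(p, g, eps)
}

net_param_shapes <- function(width) {
  w <- as.integer(width)
  list(
    w_in = c(w, 27L), b_in = w,
    w_r1a = c(w, 27L * w), b_r1a = w,
    w_r1b = c(w, 27L * w), b_r1b = w,
    w_d = c(2L * w, 27L * w), b_d = 2L * w,
    w_r2a = c(2L * w, 27L * 2L * w), b_r2a = 2L * w,
    w_r2b = c(2L * w, 27L * 2L * w), b_r2b = 2L * w,
    w_up = c(w, 27L * 2L * w), b_up = w,
    w_r3a = c(w, 27L * w), b_r3a = w,
    w_r3b = c(w, 27L * w), b_r3b = w,
    w_head = c(2L, 27L * w), b_head = 2L
  )
}

#' Build the compact volumetric segmentation network
#'
#' A two-level 3D residual encoder-decoder: an input convolution and
#' residual block at full resolution, 2x average-pool to a double-width
#' residual level, nearest-neighbour upsampling with an additive skip
#' connection, a final residual block, and a two-channel SoftMax head.
#' All kernels are 3x3x3. Convolution weights are initialized from
#' `N(0, init_std^2)` under the config seed; biases start at zero.
#'
#' @param config A [train_config()].
#' @return A list of class `"seg_model"` holding `weights` and `config`.
#' @export
build_model <- function(config = train_config()) {
  shapes <- net_param_shapes(config$width)
  weights <- local_seed(config$seed, {
    lapply(shapes, function(s) {
      if (length(s) == 2L)
        matrix(rnorm(prod(s), sd = config$init_std), s[1], s[2])
      else
        numeric(s)
    })
  })
  structure(list(weights = weights, config = config, history = NULL),
            class = "seg_model")
}

clip_global_norm <- function(grads, max_norm) {
  if (!is.finite(max_norm)) return(grads)
  total <- sqrt(sum(vapply(grads, function(g) sum(g^2), numeric(1))))
  if (total > max_norm) grads <- lapply(grads, function(g) g * (max_norm / total))
  grads
}

sample_patch_start <- function(dims, patch, label = NULL, fg_centered = FALSE) {
  if (fg_centered && !is.null(label) && any(label)) {
    idx <- which(label)
    v <- idx[sample.int(length(idx), 1L)]
    pos <- arrayInd(v, dims)
    start <- pos - patch %/% 2L
  } else {
    start <- vapply(seq_len(3L), function(k) {
      if (dims[k] > patch[k]) sample.int(dims[k] - patch[k] + 1L, 1L) else 1L
    }, integer(1))
  }
  pmin(pmax(as.integer(start), 1L), pmax(dims - patch + 1L, 1L))
}

extract_patch <- function(vol, start, patch) {
  vol[start[1]:(start[1] + patch[1] - 1L),
      start[2]:(start[2] + patch[2] - 1L),
      start[3]:(start[3] + patch[3] - 1L), drop = FALSE]
}

# reflect-pad a volume up to at least `target` extents
pad_reflect <- function(vol, target) {
  d <- dim(vol)
  for (ax in 1:3) {
    while (dim(vol)[ax] < target[ax]) {
      n <- dim(vol)[ax]
      take <- min(n, target[ax] - n)
      idx_ref <- seq(n, by = -1L, length.out = take)
      vol <- switch(ax,
        abind_axis(vol, vol[idx_ref, , , drop = FALSE], 1L),
        abind_axis(vol, vol[, idx_ref, , drop = FALSE], 2L),
        abind_axis(vol, vol[, , idx_ref, drop = FALSE], 3L))
    }
  }
  vol
}

abind_axis <- function(a, b, axis) {
  da <- dim(a); db <- dim(b)
  perm <- switch(axis, c(1, 2, 3), c(2, 1, 3), c(3, 1, 2))
  inv <- order(perm)
  ap <- aperm(a, perm); bp <- aperm(b, perm)
  out <- array(c(ap, bp), c(dim(ap)[1] + dim(bp)[1], dim(ap)[2], dim(ap)[3]))
  aperm(out, inv)
}

#' Train the segmentation network on image/pseudo-label pairs
#'
#' SGD with momentum on the combined loss over randomly sampled (and
#' optionally augmented) patches. Half the patches are centered on a random
#' foreground pseudo-label voxel to counteract class imbalance. Gradients
#' are averaged over the mini-batch and clipped to a global L2 norm.
#' Training is deterministic given the config seed.
#'
#' @param model A [build_model()] result.
#' @param pairs Non-empty list of `list(image =, label =)` pairs; images on
#'   the `[0, 1]` scale, labels logical, matching shapes.
#' @param config A [train_config()]; defaults to the model's own.
#' @return The trained model; the per-step loss history (step, wce, dice,
#'   loss) is stored in `$history`.
#' @export
train_model <- function(model, pairs, config = model$config) {
  stopifnot(inherits(model, "seg_model"))
  if (length(pairs) == 0) stop("`pairs` must be non-empty", call. = FALSE)
  for (pr in pairs) same_shape(pr$image, pr$label, "image and label")
  patch <- config$patch_shape
  weights <- model$weights
  if (config$max_steps == 0L) return(model)
  velocity <- lapply(weights, function(w) w * 0)
  wv <- if (config$wce_variant == "balanced") 1L else 0L
  hist <- matrix(NA_real_, config$max_steps, 4,
                 dimnames = list(NULL, c("step", "wce", "dice", "loss")))
  trs <- augment_transforms()
  local_seed(config$seed, {
    pairs <- lapply(pairs, function(pr) {
      img <- pad_reflect(pr$image, patch)
      lab <- pad_reflect(pr$label, patch)
      list(image = img, label = lab)
    })
    for (step in seq_len(config$max_steps)) {
      acc <- NULL
      wce_b <- dice_b <- loss_b <- 0
      for (bi in seq_len(config$batch_size)) {
        pr <- pairs[[sample.int(length(pairs), 1L)]]
        fg_c <- runif(1) < config$fg_patch_frac
        start <- sample_patch_start(dim(pr$image), patch, pr$label, fg_c)
        img <- extract_patch(pr$image, start, patch)
        lab <- extract_patch(pr$label, start, patch)
        if (config$augment) {
          tr <- trs[sample.int(length(trs), 1L)]
          img <- apply_transform(img, tr)
          lab <- apply_transform(lab, tr)
        }
        res <- net_fwdbwd_cpp(weights, as.numeric(img), as.numeric(lab),
                              dim(img), config$sigma_wce, config$prob_clip, wv,
                              config$wce_mean)
        if (!is.finite(res$loss))
          stop(sprintf("non-finite loss at step %d; lower base_lr or tighten grad_clip",
                       step), call. = FALSE)
        acc <- if (is.null(acc)) res$grads
               else mapply(function(a, g) a + g, acc, res$grads, SIMPLIFY = FALSE)
        wce_b <- wce_b + res$wce; dice_b <- dice_b + res$dice
        loss_b <- loss_b + res$loss
      }
      acc <- lapply(acc, function(g) g / config$batch_size)
      acc <- clip_global_norm(acc, config$grad_clip)
      velocity <- mapply(function(v, g) config$momentum * v + g,
                         velocity, acc, SIMPLIFY = FALSE)
      weights <- mapply(function(w, v) w - config$base_lr * v,
                        weights, velocity, SIMPLIFY = FALSE)
      hist[step, ] <- c(step, wce_b, dice_b, loss_b) / c(1, rep(config$batch_size, 3))
    }
  })
  model$weights <- weights
  model$history <- as.data.frame(hist)
  model
}

#' Predict a foreground probability map
#'
#' Tiled sliding-window inference with half-patch stride and uniform overlap
#' blending; volumes smaller than the patch are reflect-padded and the
#' result cropped. With `tta = TRUE` predictions are averaged over the
#' augmentation group via [predict_averaged()].
#'
#' @param object A `"seg_model"`.
#' @param vol Numeric 3D array on the `[0, 1]` scale.
#' @param tta Average predictions over the augmentation transform group?
#' @param transforms Transform set used when `tta` is `TRUE`.
#' @param ... Unused.
#' @return Numeric 3D array of foreground probabilities in `[0, 1]`.
#' @export
predict.seg_model <- function(object, vol, tta = FALSE,
                              transforms = augment_transforms(), ...) {
  assert_volume(vol)
  if (isTRUE(tta))
    return(predict_averaged(function(v) predict.seg_model(object, v), vol,
                            transforms))
  patch <- object$config$patch_shape
  d <- dim(vol)
  padded <- pad_reflect(vol, patch)
  dp <- dim(padded)
  starts <- lapply(1:3, function(k) {
    if (dp[k] <= patch[k]) return(1L)
    st <- seq(1L, dp[k] - patch[k] + 1L, by = max(1L, patch[k] %/% 2L))
    unique(c(st, dp[k] - patch[k] + 1L))
  })
  num <- array(0, dp)
  den <- array(0, dp)
  for (sz in starts[[1]]) for (sy in starts[[2]]) for (sx in starts[[3]]) {
    st <- c(sz, sy, sx)
    tile <- extract_patch(padded, st, patch)
    p <- net_forward_cpp(object$weights, as.numeric(tile), patch)
    iz <- st[1]:(st[1] + patch[1] - 1L)
    iy <- st[2]:(st[2] + patch[2] - 1L)
    ix <- st[3]:(st[3] + patch[3] - 1L)
    num[iz, iy, ix] <- num[iz, iy, ix] + array(p, patch)
    den[iz, iy, ix] <- den[iz, iy, ix] + 1
  }
  out <- num / den
  out[seq_len(d[1]), seq_len(d[2]), seq_len(d[3]), drop = FALSE]
}
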