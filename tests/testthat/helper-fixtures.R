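# shared fixtures, generated in code

# small deterministic phantom used across tests
small_phantom <- function(noise_sigma = 0, seed = 42, shape = c(32, 32, 32),
                          n_neurites = 3) {
  generate_phantom(phantom_config(shape = shape, n_neurites = n_neurites,
                                  noise_sigma = noise_sigma, seed = seed))
}

# brute-force Euclidean distance transform: pairwise minimum over all
# background voxels, plus the virtual border shell when requested
brute_edt <- function(fg, border_background = TRUE) {
  d <- dim(fg)
  out <- array(0, d)
  bgi <- which(!fg, arr.ind = TRUE)
  fgi <- which(fg, arr.ind = TRUE)
  for (r in seq_len(nrow(fgi))) {
    p <- fgi[r, ]
    db <- if (nrow(bgi) > 0) sqrt(min(colSums((t(bgi) - p)^2))) else Inf
    if (border_background) db <- min(db, min(p, d - p + 1))
    out[p[1], p[2], p[3]] <- db
  }
  out
}

# scalar-loop loss oracles (no vectorized shortcuts)
loop_wce <- function(p, g, clip = 1e-7) {
  n <- length(p)
  gamma <- 0
  for (i in seq_len(n)) gamma <- gamma + g[i]
  gamma <- gamma / n
  acc <- 0
  for (i in seq_len(n)) acc <- acc - gamma * g[i] * log(max(p[i], clip))
  acc
}

loop_dice <- function(p, g, eps = 1) {
  num <- 0; sp <- 0; sg <- 0
  for (i in seq_along(p)) {
    num <- num + p[i] * g[i]
    sp <- sp + p[i]
    sg <- sg + g[i]
  }
  1 - (2 * num + eps) / (sp + sg + eps)
}

# exhaustive-threshold Otsu oracle: maximize between-class variance over all
# 256 candidate levels by direct class statistics
brute_otsu <- function(x) {
  bins <- pmin(pmax(floor(as.vector(x)), 0), 255)
  best <- -1; best_t <- 0
  for (t in 0:255) {
    lo <- bins[bins <= t]
    hi <- bins[bins > t]
    if (length(lo) == 0 || length(hi) == 0) next
    w0 <- length(lo) / length(bins)
    sb <- w0 * (1 - w0) * (mean(lo) - mean(hi))^2
    if (sb > best + 1e-12) { best <- sb; best_t <- t }
  }
  best_t
}

# voxel-loop confusion-count oracle
loop_metrics <- function(pred, gt) {
  tp <- fp <- fn <- tn <- 0L
  for (i in seq_along(pred)) {
    if (pred[i] && gt[i]) tp <- tp + 1L
    else if (pred[i] && !gt[i]) fp <- fp + 1L
    else if (!pred[i] && gt[i]) fn <- fn + 1L
    else tn <- tn + 1L
  }
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  rec <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  jac <- if (tp + fp + fn > 0) tp / (tp + fp + fn) else 0
  list(tp = tp, fp = fp, fn = fn, tn = tn,
       precision = prec, recall = rec, f1 = f1, jaccard = jac)
}

# breadth-first region-growing reference: layer-synchronous, shuffled
# within-layer order, smallest-rho conflict resolution
bfs_grow <- function(prob, labels, rho, conn_offsets, order_seed = 1) {
  d <- dim(prob)
  lab <- labels
  frontier <- which(lab > 0)
  set.seed(order_seed)
  repeat {
    cand_idx <- integer(0); cand_lab <- integer(0)
    frontier <- frontier[sample.int(length(frontier))]
    for (v in frontier) {
      pos <- arrayInd(v, d)
      c <- lab[v]
      for (k in seq_len(nrow(conn_offsets))) {
        q <- pos + conn_offsets[k, ]
        if (any(q < 1) || any(q > d)) next
        w <- q[1] + d[1] * (q[2] - 1) + d[1] * d[2] * (q[3] - 1)
        if (lab[w] > 0) next
        if (prob[w] > rho[c]) { cand_idx <- c(cand_idx, w); cand_lab <- c(cand_lab, c) }
      }
    }
    if (length(cand_idx) == 0) break
    new <- unique(cand_idx)
    for (w in new) {
      cs <- cand_lab[cand_idx == w]
      best <- cs[order(rho[cs], cs)][1]
      lab[w] <- best
    }
    frontier <- new
  }
  lab
}

offsets_for <- function(conn) {
  g <- expand.grid(dz = -1:1, dy = -1:1, dx = -1:1)
  g <- g[!(g$dz == 0 & g$dy == 0 & g$dx == 0), ]
  keep <- switch(as.character(conn),
    "6" = rowSums(abs(g)) == 1,
    "18" = rowSums(abs(g)) <= 2,
    "26" = rep(TRUE, nrow(g)),
    "8" = g$dz == 0)
  as.matrix(g[keep, c("dz", "dy", "dx")])
}
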