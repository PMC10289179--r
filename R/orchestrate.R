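#' Configuration of the iterative weakly supervised loop
#'
#' Bundles the per-module parameter blocks with the loop controls: the
#' iteration budget, the double-delta F1 convergence rule, the z-axis
#' train/validation/test split, and how convergence is judged when no
#' ground truth exists.
#'
#' @param max_iterations Maximum number of train/predict/refine/fuse
#'   iterations (default 8).
#' @param f1_tolerance Convergence tolerance on successive F1 differences
#'   (default 0.005).
#' @param convergence_source `"ground_truth"` scores each iteration's
#'   binarized prediction against a supplied reference mask on the test
#'   split; `"label_stability"` (the label-free fallback) scores the Dice
#'   coefficient between successive pseudo-labels under the same rule.
#' @param split Train/validation/test fractions along z (default
#'   0.6/0.2/0.2).
#' @param seed Base RNG seed; iteration `t` trains under `seed + t`.
#' @param tta Use test-time augmentation averaging for predictions?
#' @param equalize Apply histogram equalization in preprocessing?
#' @param enhance An [enhancer_params()].
#' @param train A [train_config()]; the loop default trains on 16^3 patches
#'   to keep desk-scale volumes fast on one CPU.
#' @param refine A [grow_params()].
#' @param fuse A [fusion_params()].
#' @return A list of class `"loop_config"`.
#' @export
loop_config <- function(max_iterations = 8L, f1_tolerance = 0.005,
                        convergence_source = c("ground_truth", "label_stability"),
                        split = c(0.6, 0.2, 0.2), seed = 1L, tta = FALSE,
                        equalize = FALSE,
                        enhance = enhancer_params(),
                        train = train_config(patch_shape = c(16L, 16L, 16L)),
                        refine = grow_params(),
                        fuse = fusion_params()) {
  if (max_iterations < 1) stop("max_iterations must be >= 1", call. = FALSE)
  if (f1_tolerance <= 0) stop("f1_tolerance must be > 0", call. = FALSE)
  if (length(split) != 3L || any(split < 0) || abs(sum(split) - 1) > 1e-8)
    stop("split must be three non-negative fractions summing to 1", call. = FALSE)
  structure(list(
    max_iterations = as.integer(max_iterations), f1_tolerance = f1_tolerance,
    convergence_source = match.arg(convergence_source),
    split = split, seed = as.integer(seed), tta = isTRUE(tta),
    equalize = isTRUE(equalize),
    enhance = enhance, train = train, refine = refine, fuse = fuse
  ), class = "loop_config")
}

split_ranges <- function(nz, split) {
  n_train <- max(1L, floor(nz * split[1]))
  n_val <- floor(nz * split[2])
  n_test <- nz - n_train - n_val
  if (n_test < 1L) { n_test <- 1L; n_train <- nz - n_val - 1L }
  list(train = seq_len(n_train),
       val = if (n_val > 0) seq(n_train + 1L, n_train + n_val) else integer(0),
       test = seq(nz - n_test + 1L, nz))
}

#' Double-delta convergence rule on an F1 history
#'
#' Finds the smallest interior index `t` with `F[t] - F[t-1] < tol` and
#' `F[t+1] - F[t] < tol`: the iteration after which further training stops
#' improving. Detection is retrospective (it needs `F[t+1]`), so histories
#' of length 2 or less never converge.
#'
#' @param f1_history Numeric vector of per-iteration scores.
#' @param tolerance Convergence tolerance (default 0.005).
#' @return The 1-based index of the convergence-optimal iteration, or
#'   `NULL` if no interior index qualifies.
#' @export
check_convergence <- function(f1_history, tolerance = 0.005) {
  n <- length(f1_history)
  if (n < 3L) return(NULL)
  for (t in 2:(n - 1L)) {
    if ((f1_history[t] - f1_history[t - 1L] < tolerance) &&
        (f1_history[t + 1L] - f1_history[t] < tolerance))
      return(t)
  }
  NULL
}

iteration_score <- function(state, prev, gt, test_z, config) {
  if (config$convergence_source == "ground_truth" && !is.null(gt)) {
    pred <- binarize_prob(state$prob * 255, 200)
    seg_metrics(pred[test_z, , , drop = FALSE],
                gt[test_z, , , drop = FALSE])$f1
  } else {
    dice_coef(state$pseudo_label, prev$pseudo_label)
  }
}

#' Run one iteration of the weakly supervised loop
#'
#' Trains the network from scratch on the previous state's input image and
#' pseudo-labels (train split only), predicts a full-volume probability
#' map, mines weak neurites by region growing, fuses the original
#' intensities with the refined probability map, and re-enhances the fused
#' volume to produce the next pseudo-label.
#'
#' @param prev Previous iteration state (for the first iteration, the
#'   output of [init_state()]).
#' @param raw The original intensity volume (0-255); fusion always uses the
#'   original intensities.
#' @param config A [loop_config()].
#' @param gt Optional ground-truth mask for scoring.
#' @return An iteration state: list with `t`, `input`, `pseudo_label`,
#'   `model`, `prob`, `grown`, `fused` and `f1`.
#' @export
run_iteration <- function(prev, raw, config = loop_config(), gt = NULL) {
  t <- prev$t + 1L
  if (!any(prev$pseudo_label))
    stop(sprintf("iteration %d: empty pseudo-label (degenerate filter output)", t),
         call. = FALSE)
  nz <- dim(raw)[1]
  zr <- split_ranges(nz, config$split)
  tc <- config$train
  tc$seed <- config$seed + t
  model <- build_model(tc)
  img <- preprocess(prev$input, equalize = config$equalize)
  pairs <- list(list(image = img[zr$train, , , drop = FALSE],
                     label = prev$pseudo_label[zr$train, , , drop = FALSE]))
  model <- train_model(model, pairs, tc)
  prob <- predict(model, img, tta = config$tta)
  grown <- refine_labels(prob, config$refine)
  # grown weak neurites are marked as confident foreground for fusion
  prob_ref <- pmax(prob, as.numeric(grown))
  dim(prob_ref) <- dim(prob)
  fused <- fuse_probability(raw, prob_ref, config$fuse)
  enhanced <- enhance_volume(fused, config$enhance)
  pl_next <- make_pseudolabels(enhanced, config$enhance)
  state <- list(t = t, input = fused, pseudo_label = pl_next, model = model,
                prob = prob, grown = grown, fused = fused, f1 = NA_real_)
  state$f1 <- iteration_score(state, prev, gt, zr$test, config)
  state
}

#' Initial loop state from the raw volume
#'
#' Iteration 0 of the loop: enhance the raw volume and threshold-segment it
#' into the initial pseudo-labels; no network is involved yet.
#'
#' @param raw Intensity volume (0-255).
#' @param config A [loop_config()].
#' @param gt Optional ground-truth mask; when present the initial
#'   pseudo-label F1 on the test split is recorded.
#' @return The iteration-0 state.
#' @export
init_state <- function(raw, config = loop_config(), gt = NULL) {
  enhanced <- enhance_volume(raw, config$enhance)
  pl <- make_pseudolabels(enhanced, config$enhance)
  f0 <- NA_real_
  if (!is.null(gt)) {
    zr <- split_ranges(dim(raw)[1], config$split)
    f0 <- seg_metrics(pl[zr$test, , , drop = FALSE],
                      gt[zr$test, , , drop = FALSE])$f1
  }
  list(t = 0L, input = raw, pseudo_label = pl, model = NULL,
       prob = NULL, grown = NULL, fused = NULL, f1 = f0)
}

write_iteration_artifacts <- function(state, workdir) {
  dir <- file.path(workdir, sprintf("iter_%d", state$t))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_mask(state$pseudo_label, file.path(dir, "pseudo.tif"))
  if (!is.null(state$prob)) write_stack(state$prob, file.path(dir, "prob.tif"), 32L)
  if (!is.null(state$fused)) write_stack(state$fused, file.path(dir, "fused.tif"))
  if (!is.null(state$model))
    saveRDS(state$model, file.path(dir, "model.rds"))
  write.csv(data.frame(iteration = state$t, f1 = state$f1),
            file.path(dir, "metrics.csv"), row.names = FALSE)
}

#' Run the full weakly supervised segmentation pipeline
#'
#' Drives the loop: initial pseudo-labels from the enhancement filter, then
#' iterations of train / predict / region-grow / fuse / re-enhance until
#' the double-delta convergence rule fires or the iteration budget is
#' exhausted. The final mask is the convergence-optimal iteration's
#' probability map binarized at 200/255 (falling back to the best-scoring
#' iteration when no convergence is detected).
#'
#' @param raw Intensity volume (0-255).
#' @param gt Optional ground-truth mask. When absent, convergence is judged
#'   by pseudo-label stability (successive Dice under the same rule).
#' @param config A [loop_config()].
#' @param workdir Optional directory; when given, each iteration's
#'   pseudo-label, probability map, fused volume, model and metrics are
#'   written under `iter_<t>/`.
#' @param verbose Print per-iteration progress?
#' @return A list of class `"neuroseg_run"`: `mask` (final logical array),
#'   `best_iteration`, `converged`, `f1_history` (including the iteration-0
#'   pseudo-label score), `metrics` (final [seg_metrics()] vs `gt` on the
#'   test split, when `gt` given), `states` and `config`.
#' @export
run_pipeline <- function(raw, gt = NULL, config = loop_config(),
                         workdir = NULL, verbose = FALSE) {
  assert_volume(raw)
  if (!is.null(gt)) {
    assert_mask(gt)
    same_shape(raw, gt, "raw and gt")
  }
  if (is.null(gt) && config$convergence_source == "ground_truth")
    config$convergence_source <- "label_stability"
  t0 <- Sys.time()
  state <- init_state(raw, config, gt)
  if (!is.null(workdir)) write_iteration_artifacts(state, workdir)
  if (verbose)
    message(sprintf("iteration 0: pseudo-label score %.4f", state$f1))
  states <- list(state)
  f_hist <- numeric(0)
  for (t in seq_len(config$max_iterations)) {
    state <- run_iteration(state, raw, config, gt)
    states[[t + 1L]] <- state
    f_hist <- c(f_hist, state$f1)
    if (!is.null(workdir)) write_iteration_artifacts(state, workdir)
    if (verbose) message(sprintf("iteration %d: score %.4f", t, state$f1))
    conv <- check_convergence(f_hist, config$f1_tolerance)
    if (!is.null(conv)) break
  }
  conv <- check_convergence(f_hist, config$f1_tolerance)
  best <- conv %||% which.max(f_hist)
  best_state <- states[[best + 1L]]
  mask <- binarize_prob(best_state$prob * 255, 200)
  metrics <- NULL
  if (!is.null(gt)) {
    zr <- split_ranges(dim(raw)[1], config$split)
    metrics <- seg_metrics(mask[zr$test, , , drop = FALSE],
                           gt[zr$test, , , drop = FALSE])
  }
  structure(list(mask = mask, best_iteration = best,
                 converged = !is.null(conv),
                 f1_history = c(iter0 = states[[1]]$f1, f_hist),
                 metrics = metrics, states = states, config = config,
                 elapsed = as.numeric(difftime(Sys.time(), t0, units = "secs"))),
            class = "neuroseg_run")
}

#' @export
print.neuroseg_run <- function(x, ...) {
  cat("Weakly supervised segmentation run\n")
  cat(sprintf("  iterations: %d (best: %d, %s)\n",
              length(x$f1_history) - 1L, x$best_iteration,
              if (x$converged) "converged" else "budget exhausted"))
  cat("  score history:", paste(sprintf("%.4f", x$f1_history), collapse = " "), "\n")
  if (!is.null(x$metrics)) {
    cat("  final test-split metrics:\n")
    print(x$metrics)
  }
  invisible(x)
}

#' Plot the per-iteration score history of a run
#'
#' @param x A `"neuroseg_run"`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.neuroseg_run <- function(x, ...) {
  h <- x$f1_history
  graphics::plot(seq_along(h) - 1L, h, type = "b", xlab = "iteration",
                 ylab = "score (F1 or label stability)", ...)
  graphics::abline(v = x$best_iteration, lty = 2)
}
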