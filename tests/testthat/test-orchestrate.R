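test_that("the double-delta rule finds the documented convergence index", {
  expect_identical(check_convergence(c(0.90, 0.95, 0.953, 0.955)), 3L)
  # too short: no interior point
  expect_null(check_convergence(c(0.9)))
  expect_null(check_convergence(c(0.9, 0.91)))
  # strictly jumping history never converges
  expect_null(check_convergence(c(0.5, 0.6, 0.7, 0.8)))
  # plateau converges at its first interior point
  expect_identical(check_convergence(c(0.7, 0.7, 0.7)), 2L)
})

test_that("the convergence rule is correct on exhaustive delta grids", {
  # every length-6 history built from deltas in {-0.01 ... +0.01}
  deltas <- c(-0.01, -0.004, 0.004, 0.01)
  grid <- expand.grid(rep(list(deltas), 5))
  for (r in seq_len(nrow(grid))) {
    h <- cumsum(c(0.8, as.numeric(grid[r, ])))
    got <- check_convergence(h, 0.005)
    ref <- NULL
    for (t in 2:5) {
      if (h[t] - h[t - 1] < 0.005 && h[t + 1] - h[t] < 0.005) { ref <- t; break }
    }
    expect_identical(got, if (is.null(ref)) NULL else as.integer(ref))
  }
})

test_that("iteration 0 is exactly the enhancement-filter pseudo-label", {
  ph <- small_phantom(noise_sigma = 10)
  cfg <- loop_config(seed = 3)
  st <- init_state(ph$image, cfg, ph$mask)
  ref <- make_pseudolabels(enhance_volume(ph$image, cfg$enhance), cfg$enhance)
  expect_identical(array(st$pseudo_label, dim(ref)), array(ref, dim(ref)))
  expect_identical(st$t, 0L)
  expect_true(is.finite(st$f1))
  # degenerate filter output aborts the loop with a diagnostic
  empty <- st
  empty$pseudo_label <- array(FALSE, dim(ph$image))
  expect_error(run_iteration(empty, ph$image, cfg, ph$mask), "empty pseudo-label")
})

test_that("a short pipeline run is deterministic and well-formed", {
  ph <- generate_phantom(phantom_config(shape = c(24, 24, 24), n_neurites = 2,
                                        noise_sigma = 10, seed = 6))
  cfg <- loop_config(max_iterations = 1L, seed = 5,
                     train = train_config(patch_shape = c(12, 12, 12),
                                          max_steps = 40L, width = 6L))
  r1 <- suppressWarnings(run_pipeline(ph$image, ph$mask, cfg))
  r2 <- suppressWarnings(run_pipeline(ph$image, ph$mask, cfg))
  expect_identical(r1$f1_history, r2$f1_history)
  expect_identical(r1$mask, r2$mask)
  expect_identical(r1$best_iteration, 1L)
  expect_length(r1$f1_history, 2L)  # iteration 0 plus one loop iteration
  expect_identical(dim(r1$mask), dim(ph$image))
  expect_s3_class(r1$metrics, "seg_metrics")
})

test_that("without ground truth the loop falls back to label stability", {
  ph <- generate_phantom(phantom_config(shape = c(24, 24, 24), n_neurites = 2,
                                        noise_sigma = 10, seed = 6))
  cfg <- loop_config(max_iterations = 1L, seed = 5,
                     train = train_config(patch_shape = c(12, 12, 12),
                                          max_steps = 20L, width = 6L))
  r <- suppressWarnings(run_pipeline(ph$image, gt = NULL, config = cfg))
  # the stability score is a Dice coefficient between successive pseudo-labels
  expect_true(all(r$f1_history[-1] >= 0 & r$f1_history[-1] <= 1))
  expect_null(r$metrics)
})

test_that("iteration artifacts are written to the workdir", {
  ph <- generate_phantom(phantom_config(shape = c(24, 24, 24), n_neurites = 2,
                                        noise_sigma = 10, seed = 6))
  cfg <- loop_config(max_iterations = 1L, seed = 5,
                     train = train_config(patch_shape = c(12, 12, 12),
                                          max_steps = 20L, width = 6L))
  wd <- tempfile("workdir")
  on.exit(unlink(wd, recursive = TRUE))
  r <- suppressWarnings(run_pipeline(ph$image, ph$mask, cfg, workdir = wd))
  expect_true(file.exists(file.path(wd, "iter_0", "pseudo.tif")))
  expect_true(file.exists(file.path(wd, "iter_1", "prob.tif")))
  expect_true(file.exists(file.path(wd, "iter_1", "fused.tif")))
  expect_true(file.exists(file.path(wd, "iter_1", "metrics.csv")))
  # written probability map reads back as the in-memory one (float32)
  prob <- read_stack(file.path(wd, "iter_1", "prob.tif"))
  expect_equal(array(as.numeric(prob), dim(prob)),
               array(r$states[[2]]$prob, dim(prob)), tolerance = 1e-6)
})

test_that("config files round-trip through the YAML reader", {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  writeLines(c(
    "phantom:", "  noise_sigma: 10", "  seed: 3",
    "enhance:", "  fg_threshold_i1: 50",
    "train:", "  max_steps: 25", "  width: 6",
    "refine:", "  connectivity: 6",
    "fuse:", "  alpha: 0.7",
    "loop:", "  max_iterations: 2"), tmp)
  cfg <- read_config(tmp)
  expect_identical(cfg$phantom$noise_sigma, 10L)
  expect_identical(cfg$loop$enhance$fg_threshold_i1, 50L)
  expect_identical(cfg$loop$train$max_steps, 25L)
  expect_identical(cfg$loop$refine$connectivity, 6L)
  expect_equal(cfg$loop$fuse$alpha, 0.7)
  expect_identical(cfg$loop$max_iterations, 2L)
  writeLines(c("train:", "  bogus_key: 1"), tmp)
  expect_error(read_config(tmp), "unknown config keys")
})
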