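test_that("loss functions reproduce hand-computed values", {
  # two-voxel volume, g = (1, 0), p = (0.5, 0.5): gamma = 0.5
  p <- array(c(0.5, 0.5), c(2, 1, 1))
  g <- array(c(1, 0), c(2, 1, 1))
  expect_equal(wce_loss(p, g), -0.5 * log(0.5), tolerance = 1e-12)
  # p = (1, 0) vs g = (0, 1): Dice = 1 - (0 + 1)/(1 + 1 + 1) = 2/3
  expect_equal(dice_loss(array(c(1, 0), c(2, 1, 1)), array(c(0, 1), c(2, 1, 1))),
               2 / 3, tolerance = 1e-12)
  expect_equal(combined_loss(p, g, sigma = 1),
               wce_loss(p, g) + dice_loss(p, g), tolerance = 1e-12)
})

test_that("loss identities hold in the degenerate limits", {
  d <- c(3, 3, 3)
  zero <- array(0, d)
  ones <- array(1, d)
  g <- array(rep(c(1, 0), length.out = 27), d)
  # no foreground labels: gamma = 0 kills the foreground-only WCE
  expect_identical(wce_loss(array(0.3, d), zero), 0)
  # perfect prediction on the foreground: WCE vanishes
  expect_equal(wce_loss(g, g), 0, tolerance = 1e-12)
  # Dice: perfect binary prediction and the doubly-empty smoothed case
  expect_equal(dice_loss(g, g), 0, tolerance = 1e-12)
  expect_equal(dice_loss(zero, zero), 0, tolerance = 1e-12)
  expect_lt(dice_loss(array(runif(27), d), g), 1)
  # sigma = 0 reduces the combined loss to Dice
  p <- array(runif(27), d)
  expect_equal(combined_loss(p, g, sigma = 0), dice_loss(p, g), tolerance = 1e-14)
  # perfect binary prediction zeroes the combined loss
  expect_equal(combined_loss(g, g), 0, tolerance = 1e-12)
})

test_that("losses agree with scalar-loop oracles on random batches", {
  set.seed(17)
  for (rep in 1:8) {
    d <- c(4, 4, 4)
    p <- array(runif(64), d)
    g <- array(as.numeric(runif(64) > 0.6), d)
    expect_equal(wce_loss(p, g), loop_wce(as.numeric(p), as.numeric(g)),
                 tolerance = 1e-10)
    expect_equal(dice_loss(p, g), loop_dice(as.numeric(p), as.numeric(g)),
                 tolerance = 1e-10)
    expect_equal(combined_loss(p, g, sigma = 1.7),
                 1.7 * loop_wce(as.numeric(p), as.numeric(g)) +
                   loop_dice(as.numeric(p), as.numeric(g)),
                 tolerance = 1e-10)
  }
})

test_that("the C++ training losses match the R reference implementations", {
  cfg <- train_config(patch_shape = c(4, 4, 4), width = 3, seed = 5)
  m <- build_model(cfg)
  set.seed(2)
  x <- runif(64)
  g <- as.numeric(runif(64) > 0.7)
  p <- array(neuroseg:::net_forward_cpp(m$weights, x, c(4L, 4L, 4L)), c(4, 4, 4))
  ga <- array(g, c(4, 4, 4))
  fg_form <- neuroseg:::net_fwdbwd_cpp(m$weights, x, g, c(4L, 4L, 4L), 1, 1e-7, 0L, FALSE)
  expect_equal(fg_form$wce, wce_loss(p, ga), tolerance = 1e-10)
  expect_equal(fg_form$dice, dice_loss(p, ga), tolerance = 1e-10)
  balanced <- neuroseg:::net_fwdbwd_cpp(m$weights, x, g, c(4L, 4L, 4L), 1, 1e-7, 1L, FALSE)
  expect_equal(balanced$wce, wce_loss(p, ga, variant = "balanced"),
               tolerance = 1e-8)
})

test_that("model construction is deterministic and shapes are validated", {
  cfg <- train_config(patch_shape = c(8, 8, 8), width = 4, seed = 11)
  a <- build_model(cfg)
  b <- build_model(cfg)
  expect_identical(a$weights, b$weights)
  c2 <- build_model(train_config(patch_shape = c(8, 8, 8), width = 4, seed = 12))
  expect_false(identical(a$weights, c2$weights))
  expect_error(train_config(patch_shape = c(7, 8, 8)), "divisible")
})

test_that("the forward pass is a per-voxel probability of matching shape", {
  cfg <- train_config(patch_shape = c(8, 8, 8), width = 4, seed = 11)
  m <- build_model(cfg)
  vol <- array(runif(512), c(8, 8, 8))
  p <- predict(m, vol)
  expect_identical(dim(p), dim(vol))
  expect_true(all(p >= 0 & p <= 1))
  # volumes smaller than the patch are padded and cropped back
  small <- array(runif(4 * 6 * 8), c(4, 6, 8))
  ps <- predict(m, small)
  expect_identical(dim(ps), dim(small))
})

test_that("training reduces the loss and is reproducible; zero steps is a no-op", {
  ph <- small_phantom()
  pl <- make_pseudolabels(enhance_volume(ph$image))
  img <- preprocess(ph$image)
  cfg <- train_config(patch_shape = c(16, 16, 16), max_steps = 60, seed = 7)
  m0 <- build_model(cfg)

  frozen <- train_model(m0, list(list(image = img, label = pl)),
                        train_config(patch_shape = c(16, 16, 16), max_steps = 0L,
                                     seed = 7))
  expect_identical(frozen$weights, m0$weights)

  m1 <- train_model(m0, list(list(image = img, label = pl)), cfg)
  m2 <- train_model(m0, list(list(image = img, label = pl)), cfg)
  expect_identical(m1$weights, m2$weights)
  expect_identical(m1$history$loss, m2$history$loss)
  h <- m1$history$loss
  expect_lt(mean(h[41:60]), mean(h[1:10]))
})

test_that("an overfit run memorizes its pseudo-labels", {
  ph <- small_phantom()
  pl <- make_pseudolabels(enhance_volume(ph$image))
  img <- preprocess(ph$image)
  cfg <- train_config(patch_shape = c(16, 16, 16), max_steps = 300, seed = 7,
                      augment = FALSE)
  m <- train_model(build_model(cfg), list(list(image = img, label = pl)), cfg)
  h <- m$history$loss
  expect_lt(mean(h[281:300]), mean(h[1:20]))
  p <- predict(m, img)
  dice <- 2 * sum((p >= 0.5) & pl) / (sum(p >= 0.5) + sum(pl))
  # computed on the fixed-seed run: 0.855; the floor leaves numeric headroom
  expect_gt(dice, 0.8)
  # the memorization errors are dilation only: the labels are fully recalled
  expect_gt(sum((p >= 0.5) & pl) / sum(pl), 0.95)
})
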