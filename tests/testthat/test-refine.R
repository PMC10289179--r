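test_that("seed classification is an inclusive 0.5 threshold", {
  d <- c(3, 1, 1)
  expect_false(any(seed_region(array(0.4, c(2, 2, 2)))))
  expect_true(all(seed_region(array(0.9, c(2, 2, 2)))))
  mixed <- array(c(0.3, 0.5, 0.7), d)
  expect_identical(as.vector(seed_region(mixed)), c(FALSE, TRUE, TRUE))
})

test_that("the adaptive threshold equals the shell mean, per component", {
  # single seed voxel centered in 7^3: shell is the 124-voxel neighborhood
  d <- c(7, 7, 7)
  set.seed(4)
  prob <- array(runif(343), d)
  prob[4, 4, 4] <- 1
  seed <- array(FALSE, d); seed[4, 4, 4] <- TRUE
  at <- adaptive_threshold(prob, seed)
  expect_length(at$rho, 1L)
  expect_identical(sum(at$shell), 124L)
  shell_vals <- prob[abs(slice.index(prob, 1) - 4) <= 2 &
                     abs(slice.index(prob, 2) - 4) <= 2 &
                     abs(slice.index(prob, 3) - 4) <= 2 & !seed]
  expect_equal(at$rho, mean(shell_vals), tolerance = 1e-12)

  # constant probability outside the seed
  prob2 <- array(0.2, d); prob2[4, 4, 4] <- 1
  expect_equal(adaptive_threshold(prob2, seed)$rho, 0.2, tolerance = 1e-12)

  # two far-apart components get their own shell means
  d2 <- c(16, 16, 16)
  prob3 <- array(0, d2)
  prob3[1:8, , ] <- 0.1; prob3[9:16, , ] <- 0.6
  seed2 <- array(FALSE, d2); seed2[3, 8, 8] <- TRUE; seed2[14, 8, 8] <- TRUE
  prob3[seed2] <- 1
  at2 <- adaptive_threshold(prob3, seed2)
  expect_length(at2$rho, 2L)
  expect_equal(sort(at2$rho), c(0.1, 0.6), tolerance = 1e-12)
})

test_that("region growing matches the shuffled-order BFS reference", {
  set.seed(31)
  for (conn in c(6L, 26L)) {
    for (rep in 1:4) {
      d <- c(8, 8, 8)
      prob <- array(runif(512), d)
      seed <- array(FALSE, d)
      seed[sample(512, 3)] <- TRUE
      prob[seed] <- 1
      at <- adaptive_threshold(prob, seed, grow_params(connectivity = conn))
      gr <- region_grow(prob, seed, params = grow_params(connectivity = conn))
      ref <- bfs_grow(prob, at$labels, at$rho, offsets_for(conn), order_seed = rep)
      expect_identical(array(gr$labels > 0, d), array(ref > 0, d))
    }
  }
})

test_that("growth respects its contract: containment, threshold, monotonicity", {
  set.seed(12)
  d <- c(10, 10, 10)
  prob <- array(runif(1000), d)
  seed <- seed_region(prob, 0.92)
  gr <- region_grow(prob, seed)
  expect_true(all(gr$grown[seed]))                   # Oreg subset of Greg
  expect_false(any(gr$shell & seed))                 # Nreg disjoint from Oreg
  added <- gr$grown & !seed
  rho_of <- gr$rho[gr$labels[added]]
  expect_true(all(prob[added] > rho_of))             # grown voxels exceed rho
  # single-step growth is contained in the fixed point
  gr1 <- region_grow(prob, seed, params = grow_params(single_step = TRUE))
  expect_true(all(gr$grown[gr1$grown]))
  # raising rho never enlarges the region
  hi <- region_grow(prob, seed, rho = pmin(1, 2 * gr$rho))
  expect_lte(sum(hi$grown), sum(gr$grown))
  # rho = 1 is vacuous: nothing exceeds it
  none <- region_grow(prob, seed, rho = 1)
  expect_identical(none$grown, array(seed, d))
})

test_that("a thin low-probability path is absorbed transitively", {
  d <- c(5, 5, 12)
  prob <- array(0, d)
  prob[3, 3, 1] <- 0.9              # seed
  prob[3, 3, 2:12] <- 0.45          # weak path leading away
  seed <- seed_region(prob)
  gr <- region_grow(prob, seed, rho = 0.4)
  expect_true(all(gr$grown[3, 3, ]))
  # strict inequality: values exactly at rho are excluded
  gr_eq <- region_grow(prob, seed, rho = 0.45)
  expect_identical(sum(gr_eq$grown), 1L)
})

test_that("refine_labels grows the seed and improves recall on a halo fixture", {
  ph <- small_phantom()
  # synthetic probability map: confident core plus a decaying halo
  dmap <- distance_transform(255 * (1 - ph$mask), 128)  # distance outside mask
  prob <- exp(-dmap^2 / 8)
  prob[ph$mask] <- 0.95
  seed <- seed_region(prob)
  grown <- refine_labels(prob)
  expect_gte(sum(grown), sum(seed))
  rec <- function(m) seg_metrics(m, ph$mask)$recall
  expect_gte(rec(grown), rec(seed))
  # idempotence: growing the indicator of the grown region returns it
  ind <- array(as.numeric(grown), dim(grown))
  again <- refine_labels(ind)
  expect_identical(array(again, dim(again)), array(grown, dim(grown)))
  # all-low map: empty mask with a warning
  expect_warning(out <- refine_labels(array(0.2, c(6, 6, 6))), "empty seed")
  expect_false(any(out))
})
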