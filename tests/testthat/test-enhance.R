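test_that("distance transform matches the brute-force pairwise oracle", {
  # degenerate cases
  allbg <- array(0, c(5, 5, 5))
  expect_true(all(distance_transform(allbg, 40) == 0))
  one <- array(0, c(5, 5, 5)); one[3, 3, 3] <- 100
  expect_identical(distance_transform(one, 40)[3, 3, 3], 1)
  # solid 5^3 cube centered in a larger volume: center is 3 from the faces
  cube <- array(0, c(11, 11, 11)); cube[4:8, 4:8, 4:8] <- 255
  expect_identical(distance_transform(cube, 40)[6, 6, 6], 3)

  # random volumes up to 12^3, exact agreement with exhaustive minimum
  set.seed(11)
  for (rep in 1:6) {
    d <- sample(3:12, 3, replace = TRUE)
    vol <- array(runif(prod(d)) * 255, d)
    got <- distance_transform(vol, 128)
    expect_equal(got, brute_edt(vol >= 128), tolerance = 1e-12)
  }

  # all-foreground: distances run to the virtual border shell
  full <- array(255, c(4, 4, 4))
  got <- distance_transform(full, 40)
  expect_identical(got, brute_edt(array(TRUE, c(4, 4, 4))))
})

test_that("distance normalization maps foreground onto [1, 256]", {
  f <- array(c(0, 1, 3, 5, 0, 1, 1, 1), c(8, 1, 1))
  dn <- normalize_dt(f)
  expect_equal(dn[2, 1, 1], 1)         # DT minimum -> 1
  expect_equal(dn[4, 1, 1], 256)       # DT maximum -> 256
  expect_equal(dn[3, 1, 1], 1 + 255 * 0.5)  # midpoint affine value 128.5
  expect_equal(dn[1, 1, 1], 1)         # background -> 1
  # degenerate constant span maps to 1 everywhere
  const <- array(c(0, 1, 1), c(3, 1, 1))
  expect_true(all(normalize_dt(const) == 1))
  expect_error(normalize_dt(array(0, c(2, 2, 2))), "positive")
})

test_that("adaptive radius follows log2 with round-half-up and clamping", {
  dn <- array(c(256, 1, 16, 2, 181), c(5, 1, 1))
  ar <- adaptive_radius(dn)
  expect_identical(as.vector(ar$R), c(8L, 1L, 4L, 1L, 7L))
  expect_identical(as.vector(ar$DI), c(17L, 3L, 9L, 3L, 15L))
  expect_error(adaptive_radius(array(300, c(1, 1, 1))), "\\[1, 256\\]")
  expect_error(adaptive_radius(array(0.5, c(1, 1, 1))), "\\[1, 256\\]")
})

test_that("Hessian eigenvalues are exact on constants and quadratics", {
  expect_true(all(abs(unlist(hessian_eigen(array(7, c(9, 9, 9)), 2L))) < 1e-12))
  # bright ridge along z: I = -k (x^2 + y^2) has eigenvalues (0, -2k, -2k)
  k <- 1.5
  d <- c(13, 13, 13)
  xc <- slice.index(array(0, d), 3); yc <- slice.index(array(0, d), 2)
  vol <- -k * ((xc - 7)^2 + (yc - 7)^2)
  ev <- hessian_eigen(vol, 2L)
  expect_equal(ev$l1[7, 7, 7], 0, tolerance = 1e-9)
  expect_equal(ev$l2[7, 7, 7], -2 * k, tolerance = 1e-9)
  expect_equal(ev$l3[7, 7, 7], -2 * k, tolerance = 1e-9)
  expect_lt(abs(ev$l1[7, 7, 7]), abs(ev$l3[7, 7, 7]) + 1e-12)
})

test_that("Hessian eigenvalues match a brute-force convolution + eigen oracle", {
  set.seed(3)
  vol <- array(rnorm(729) * 50 + 100, c(9, 9, 9))
  ev <- hessian_eigen(vol, 2L)
  k <- gaussian_deriv_kernels(2L)
  refl <- function(i, n) { while (i < 1 || i > n) { if (i < 1) i <- 1 - i; if (i > n) i <- 2 * n - i + 1 }; i }
  conv1 <- function(a, kern, ax) {
    d <- dim(a); out <- array(0, d); h <- (length(kern) - 1) / 2
    for (z in 1:d[1]) for (y in 1:d[2]) for (x in 1:d[3]) {
      s <- 0
      for (t in -h:h) {
        zz <- z; yy <- y; xx <- x
        if (ax == 1) zz <- refl(z + t, d[1])
        if (ax == 2) yy <- refl(y + t, d[2])
        if (ax == 3) xx <- refl(x + t, d[3])
        s <- s + kern[t + h + 1] * a[zz, yy, xx]
      }
      out[z, y, x] <- s
    }
    out
  }
  hxx <- conv1(conv1(conv1(vol, k$g2, 3), k$g0, 2), k$g0, 1)
  hyy <- conv1(conv1(conv1(vol, k$g0, 3), k$g2, 2), k$g0, 1)
  hzz <- conv1(conv1(conv1(vol, k$g0, 3), k$g0, 2), k$g2, 1)
  hxy <- conv1(conv1(conv1(vol, k$g1, 3), k$g1, 2), k$g0, 1)
  hxz <- conv1(conv1(conv1(vol, k$g1, 3), k$g0, 2), k$g1, 1)
  hyz <- conv1(conv1(conv1(vol, k$g0, 3), k$g1, 2), k$g1, 1)
  worst <- 0
  for (z in 1:9) for (y in 1:9) for (x in 1:9) {
    H <- matrix(c(hxx[z, y, x], hxy[z, y, x], hxz[z, y, x],
                  hxy[z, y, x], hyy[z, y, x], hyz[z, y, x],
                  hxz[z, y, x], hyz[z, y, x], hzz[z, y, x]), 3, 3)
    e <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
    e <- e[order(abs(e))]
    worst <- max(worst, max(abs(e - c(ev$l1[z, y, x], ev$l2[z, y, x], ev$l3[z, y, x]))))
  }
  expect_lt(worst, 1e-6)
})

test_that("the line response obeys its analytic limiting cases", {
  # sign gate: any positive principal curvature kills the response
  expect_identical(vesselness_response(0, 1, -2), 0)
  expect_identical(vesselness_response(0, -1, 2), 0)
  # ideal plate: anisotropy ratio 0 -> first factor 0
  expect_identical(vesselness_response(0, 0, -10), 0)
  # degenerate background: all zero eigenvalues
  expect_identical(vesselness_response(0, 0, 0), 0)
  # ideal line with defaults a = 5.55, c = 2e6
  got <- vesselness_response(0, -1000, -1000)
  expect_equal(got, (1 - exp(-5.55)) * (1 - exp(-1)), tolerance = 1e-9)
  # p1, p2 are scale invariant; the energy factor is monotone in scale
  l <- c(-1, -40, -50)
  r1 <- vesselness_response(l[1], l[2], l[3])
  r2 <- vesselness_response(2 * l[1], 2 * l[2], 2 * l[3])
  expect_gte(r2, r1)
  # the literal product p2 form is exposed as an option and differs
  lit <- enhancer_params(p2_literal = TRUE)
  expect_lt(vesselness_response(-1, -1000, -1000, lit),
            vesselness_response(-1, -1000, -1000))
})

test_that("soma filling forces deep high-intensity interiors to 255", {
  d <- c(17, 17, 17)
  zc <- slice.index(array(0, d), 1); yc <- slice.index(array(0, d), 2)
  xc <- slice.index(array(0, d), 3)
  ball <- sqrt((zc - 9)^2 + (yc - 9)^2 + (xc - 9)^2) <= 6
  vol <- array(20, d); vol[ball] <- 250
  enh <- array(0, d)
  out <- soma_fill(enh, vol, enhancer_params(soma_dt_threshold = 3))
  d2 <- brute_edt(vol >= 150)
  expect_identical(array(out == 255, d), array(d2 > 3, d))
  expect_true(any(out == 255))
  # ring voxels with D2 <= 3 keep their line response
  expect_true(all(out[ball & d2 <= 3] == 0))
  # no voxel reaches the higher threshold -> unchanged
  lo <- array(100, d)
  expect_true(all(soma_fill(enh, lo, enhancer_params()) == 0))
  # infinite threshold is vacuous
  expect_true(all(soma_fill(enh, vol, enhancer_params(soma_dt_threshold = Inf)) == 0))
})

test_that("the full enhancement pipeline highlights tubes and fills somata", {
  ph <- small_phantom(noise_sigma = 0)
  enh <- enhance_volume(ph$image)
  expect_true(all(enh >= 0 & enh <= 255))
  expect_gt(mean(enh[ph$mask]), mean(enh[!ph$mask]))
  # all-background volume: response stays at (numerical) zero
  flat <- array(20, c(24, 24, 24))
  expect_lt(max(enhance_volume(flat)), 1e-6)
  # a soma-bearing phantom gets a filled (255) interior
  cfg <- phantom_config(shape = c(32, 32, 32), n_neurites = 2, soma_prob = 1,
                        noise_sigma = 0, seed = 3)
  ph2 <- generate_phantom(cfg)
  enh2 <- enhance_volume(ph2$image)
  filled <- attr(enh2, "soma_filled")
  expect_true(any(filled))
  expect_true(all(enh2[filled] == 255))
})

test_that("enhancement is equivariant under the augmentation group", {
  ph <- generate_phantom(phantom_config(shape = c(24, 24, 24), n_neurites = 2,
                                        noise_sigma = 0, seed = 9))
  enh <- enhance_volume(ph$image)
  for (tr in c("rot90_xy", "mirror_h_xy", "flip_z")) {
    enh_t <- enhance_volume(apply_transform(ph$image, tr))
    back <- apply_transform(enh_t, inverse_transform(tr))
    # compare away from the volume border (reflection padding differs there)
    i <- 5:20
    expect_equal(back[i, i, i], enh[i, i, i], tolerance = 1e-8)
  }
})

test_that("Otsu thresholding matches the exhaustive between-class oracle", {
  set.seed(21)
  # bimodal: two Gaussians well separated
  x <- c(rnorm(600, 30, 5), rnorm(400, 200, 5))
  thr <- otsu_threshold(x)
  expect_identical(thr, brute_otsu(x))
  # threshold lies strictly between the modes and recovers the high mode
  expect_gt(thr, 30); expect_lt(thr, 200)
  expect_true(all((x > thr)[601:1000]))
  expect_true(sum((x > thr)[1:600]) <= 2)  # at most stray upper-tail draws
  # random histograms agree with the oracle
  for (rep in 1:5) {
    y <- sample(0:255, 500, replace = TRUE, prob = runif(256))
    expect_identical(otsu_threshold(y), brute_otsu(y))
  }
})

test_that("pseudo-label segmentation handles bimodal, constant and fixed cases", {
  otsu <- enhancer_params(pseudo_label_method = "otsu")
  bim <- array(rep(c(0, 255), c(200, 56)), c(4, 8, 8))
  pl <- make_pseudolabels(bim, otsu)
  expect_identical(array(pl, dim(bim)), array(bim == 255, dim(bim)))
  # constant response: no threshold separates -> empty mask
  expect_false(any(make_pseudolabels(array(0, c(4, 4, 4)), otsu)))
  expect_false(any(make_pseudolabels(array(128, c(4, 4, 4)), otsu)))
  # fixed threshold method
  fx <- enhancer_params(pseudo_label_method = "fixed", pseudo_label_value = 100)
  vol <- array(c(50, 100, 150, 250), c(4, 1, 1))
  expect_identical(as.vector(make_pseudolabels(vol, fx)), c(FALSE, TRUE, TRUE, TRUE))
})

test_that("pseudo-labels reach the quality floor on the default noiseless suite", {
  f1 <- vapply(1:3, function(seed) {
    ph <- generate_phantom(phantom_config(noise_sigma = 0, seed = seed))
    pl <- make_pseudolabels(enhance_volume(ph$image))
    seg_metrics(pl, ph$mask)$f1
  }, numeric(1))
  expect_true(all(f1 >= 0.6))
})

test_that("invalid enhancer configurations are rejected", {
  expect_error(enhancer_params(a = 0), "a, b, c")
  expect_error(enhancer_params(soma_threshold_i2 = 30, fg_threshold_i1 = 40),
               "exceed")
  expect_error(enhancer_params(radius_min = 0), "radius_min")
})
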