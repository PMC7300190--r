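# Image containers, unsharp mask, automatic thresholds, binarization and
# cleanup.

test_that("unsharp mask leaves constants alone and is the identity at weight 0", {
  img <- calibrated_image(matrix(7, 32, 32), 0.1)
  out <- unsharp_mask(img, sigma_px = 1.5, weight = 0.6)
  expect_equal(out$pixels, img$pixels, tolerance = 1e-12)
  rimg <- calibrated_image(matrix(runif(32 * 32), 32), 0.1)
  expect_equal(unsharp_mask(rimg, 1, 0)$pixels, rimg$pixels)
})

test_that("unsharp mask on a unit impulse matches the direct convolution form", {
  n <- 21L
  m <- matrix(0, n, n); m[11, 11] <- 1
  out <- unsharp_mask(calibrated_image(m, 0.1), sigma_px = 1, weight = 0.6)
  # discrete 2D Gaussian center coefficient, computed independently
  r <- 3L; x <- (-r):r
  k1 <- exp(-x^2 / 2); k1 <- k1 / sum(k1)
  g0 <- k1[r + 1L]^2
  expect_equal(out$pixels[11, 11], (1 - 0.6 * g0) / 0.4, tolerance = 1e-12)
})

test_that("unsharp mask is linear before clipping", {
  set.seed(4)
  m <- matrix(runif(900, 10, 50), 30)
  a <- unsharp_mask(calibrated_image(m, 0.1), 1.2, 0.5)$pixels
  b <- unsharp_mask(calibrated_image(2 * m, 0.1), 1.2, 0.5)$pixels
  expect_equal(b, 2 * a, tolerance = 1e-10)
})

test_that("unsharp mask rejects invalid weight and sigma", {
  img <- calibrated_image(matrix(1, 8, 8), 0.1)
  expect_error(unsharp_mask(img, 1, 1), "weight")
  expect_error(unsharp_mask(img, -1, 0.5), "sigma")
})

test_that("max projection takes the per-pixel maximum across slices", {
  set.seed(5)
  st <- array(runif(16 * 16 * 4), c(16, 16, 4))
  img <- calibrated_image(st, 0.2)
  proj <- max_project(img)
  # brute-force loop oracle
  oracle <- matrix(0, 16, 16)
  for (i in 1:16) for (j in 1:16) oracle[i, j] <- max(st[i, j, ])
  expect_equal(proj$pixels, oracle)
  # identical slices reduce to the slice; a single bright pixel survives
  st2 <- array(rep(st[, , 1], 3), c(16, 16, 3))
  expect_equal(max_project(calibrated_image(st2, 0.2))$pixels, st[, , 1])
  st3 <- array(0, c(8, 8, 4)); st3[3, 5, 3] <- 9
  expect_equal(max_project(calibrated_image(st3, 0.2))$pixels[3, 5], 9)
  expect_error(max_project(calibrated_image(matrix(0, 4, 4), 0.2)), "2D")
})

test_that("Huang threshold matches the exhaustive naive scan", {
  # two spikes: threshold strictly between them (middle of the tied plateau)
  h <- integer(256); h[1] <- 100; h[256] <- 100
  t2 <- huang_threshold(h)
  expect_gt(t2, 0); expect_lt(t2, 255)
  expect_true(t2 %in% oracle_huang(h))
  # Gaussian mixture with modes 30 and 200
  set.seed(11)
  v <- c(round(rnorm(4000, 30, 8)), round(rnorm(4000, 200, 20)))
  v <- pmin(pmax(v, 0), 255)
  hm <- tabulate(v + 1L, 256)
  tm <- huang_threshold(hm)
  expect_gt(tm, 30); expect_lt(tm, 200)
  expect_true(tm %in% oracle_huang(hm))   # empty gap between modes ties
  # random histograms
  for (i in 1:10) {
    set.seed(i)
    hr <- integer(256)
    hr[sample(256, 40)] <- rpois(40, 30)
    if (sum(hr > 0) < 2) next
    o <- oracle_huang(hr)
    expect_true(huang_threshold(hr) %in% o)
    if (length(o) == 1L) expect_identical(huang_threshold(hr), o)
  }
})

test_that("IsoData threshold solves the intermeans fixed point", {
  h <- integer(256); h[11] <- 50; h[21] <- 50   # spikes at levels 10 and 20
  expect_identical(isodata_threshold(h), 15L)
  set.seed(21)
  for (i in 1:8) {
    v <- c(round(rnorm(3000, 60, 15)), round(rnorm(1500, 190, 12)))
    v <- pmin(pmax(v, 0), 255)
    hb <- tabulate(v + 1L, 256)
    t_iso <- isodata_threshold(hb)
    expect_true(t_iso %in% oracle_isodata_fixed_points(hb))
    expect_gt(t_iso, 60); expect_lt(t_iso, 190)
  }
})

test_that("degenerate histograms raise errors and thresholds stay in range", {
  h1 <- integer(256); h1[42] <- 10
  expect_error(huang_threshold(h1), "degenerate")
  expect_error(isodata_threshold(h1), "degenerate")
  set.seed(31)
  for (i in 1:5) {
    h <- integer(256)
    lo <- sample(0:100, 1); hi <- sample(150:255, 1)
    idx <- sort(sample(lo:hi, 12))
    h[idx + 1L] <- rpois(12, 20) + 1L
    for (fn in list(huang_threshold, isodata_threshold)) {
      t_ <- fn(h)
      expect_gte(t_, lo); expect_lt(t_, hi)
      expect_identical(fn(h * 3L), t_)   # invariance to count scaling
    }
  }
})

test_that("8-connected labeling joins diagonal chains", {
  m <- matrix(FALSE, 20, 20)
  for (i in 3:15) m[i, i] <- TRUE
  expect_equal(max(label_components(m)), 1L)
  m[18, 2] <- TRUE
  expect_equal(max(label_components(m)), 2L)
})

test_that("binarize_and_clean removes small and border objects and is idempotent", {
  img <- matrix(0, 30, 30)
  img[5:6, 5:6] <- 10          # 4 px, below min_area
  img[12:18, 12:19] <- 10      # 56 px
  bm <- binarize_and_clean(img, threshold = 5, min_area_px = 10,
                           pixel_size_um = 0.1)
  expect_equal(max(label_components(bm$mask)), 1L)
  expect_equal(sum(bm$mask), 56L)
  # idempotent cleanup
  again <- binarize_and_clean(bm$mask * 10, threshold = 5, min_area_px = 10,
                              pixel_size_um = 0.1)
  expect_identical(again$mask, bm$mask)
  # all below threshold: empty mask, no error
  empty <- binarize_and_clean(img, threshold = 100, min_area_px = 5,
                              pixel_size_um = 0.1)
  expect_false(any(empty$mask))
  # border clearing
  imgb <- matrix(0, 20, 20); imgb[1:5, 8:12] <- 10; imgb[10:14, 8:12] <- 10
  bb <- binarize_and_clean(imgb, 5, min_area_px = 3, clear_border = TRUE,
                           pixel_size_um = 0.1)
  expect_equal(max(label_components(bb$mask)), 1L)
  expect_false(any(bb$mask[1, ]))
  expect_error(binarize_and_clean(img, 5, min_area_px = -1,
                                  pixel_size_um = 0.1), "min_area")
})

test_that("segmentation recovers the planted object count", {
  m <- matrix(0, 64, 64)
  centers <- list(c(10, 10), c(10, 40), c(35, 20), c(50, 50), c(55, 12))
  for (ct in centers) m[ct[1] + 0:4, ct[2] + 0:4] <- 120
  noisy <- m + matrix(rnorm(64 * 64, 10, 2), 64)
  bm <- binarize_and_clean(noisy, threshold = 60, min_area_px = 10,
                           pixel_size_um = 0.1)
  expect_equal(max(label_components(bm$mask)), length(centers))
})
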