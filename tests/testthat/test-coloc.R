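test_that("mask creation thresholds strictly and records provenance", {
  img <- matrix(c(0, 10, 0, 10), 2)
  m <- make_mask(img, 5)
  expect_true(all(m == (img > 5)))
  expect_equal(attr(m, "threshold"), 5)
  # threshold at the maximum: empty mask with warning
  expect_warning(m2 <- make_mask(img, 10), "empty mask")
  expect_false(any(m2))
})

test_that("otsu threshold separates a bimodal image", {
  set.seed(4)
  img <- matrix(c(rnorm(800, 10, 2), rnorm(200, 100, 5)), 40, 25)
  thr <- otsu_threshold(img)
  expect_gt(thr, 20)
  expect_lt(thr, 90)
  if (requireNamespace("EBImage", quietly = TRUE)) {
    ref <- EBImage::otsu(EBImage::Image(img / max(img)),
      range = c(0, 1), levels = 256
    ) * max(img)
    expect_lt(abs(thr - ref) / ref, 0.1)
  }
})

test_that("component labelling matches an independent implementation", {
  set.seed(9)
  mask <- matrix(runif(400) < 0.35, 20, 20)
  lab8 <- label_components(mask, 8L)
  lab4 <- label_components(mask, 4L)
  expect_identical(lab8 > 0, unclass(mask))
  # two pixels touching diagonally: one component under 8, two under 4
  m2 <- matrix(FALSE, 3, 3)
  m2[1, 1] <- m2[2, 2] <- TRUE
  expect_equal(max(label_components(m2, 8L)), 1L)
  expect_equal(max(label_components(m2, 4L)), 2L)
  if (requireNamespace("EBImage", quietly = TRUE)) {
    # EBImage::bwlabel is the 4-connectivity oracle: same partition
    ref <- EBImage::bwlabel(mask)
    expect_equal(max(lab4), max(ref))
    # identical membership up to label numbering
    expect_true(all(tapply(ref[mask], lab4[mask], function(v) {
      length(unique(v)) == 1L
    })))
  }
})

test_that("the 0.1 um^2 area filter cuts exactly at the 62/63-pixel boundary", {
  mk_blob <- function(n_px) {
    # a compact blob of exactly n_px pixels in a 40 x 40 frame
    m <- matrix(FALSE, 40, 40)
    side <- floor(sqrt(n_px))
    m[1:side, 1:side] <- TRUE
    left <- n_px - side^2
    if (left > 0) m[side + 1L, seq_len(left)] <- TRUE
    m
  }
  b62 <- filter_small_components(mk_blob(62), 0.1, pixel_size_nm = 40)
  expect_false(any(b62)) # 62 * 0.0016 = 0.0992 um^2 < 0.1
  b63 <- filter_small_components(mk_blob(63), 0.1, pixel_size_nm = 40)
  expect_equal(sum(b63), 63L) # 0.1008 um^2 >= 0.1
  # empty in, empty out; idempotence
  e <- filter_small_components(matrix(FALSE, 5, 5), 0.1, 40)
  expect_false(any(e))
  once <- filter_small_components(mk_blob(80), 0.1, 40)
  expect_identical(
    unclass(filter_small_components(once, 0.1, 40)),
    unclass(once)
  )
})

test_that("signal density is the mask area fraction", {
  m <- matrix(FALSE, 10, 10)
  m[1:5, 1:5] <- TRUE
  expect_equal(signal_density(m), 0.25)
  expect_equal(signal_density(matrix(TRUE, 3, 3)), 1)
})

test_that("overlap mask conjoins then re-filters", {
  a <- matrix(FALSE, 40, 40)
  b <- matrix(FALSE, 40, 40)
  a[1:10, 1:10] <- TRUE # 100 px
  b[1:10, 6:15] <- TRUE # 100 px, sharing a 10 x 5 strip
  ov <- overlap_mask(a, b, 0.1, pixel_size_nm = 40)
  expect_false(any(ov)) # 50 px < 62.5 px: strip removed
  ov2 <- overlap_mask(a, a, 0.1, pixel_size_nm = 40)
  expect_true(all(ov2 == a)) # identical masks survive
  expect_error(overlap_mask(a, b[1:20, ]), "shapes")
  # disjoint
  d <- matrix(FALSE, 40, 40)
  d[30:39, 30:39] <- TRUE
  expect_false(any(overlap_mask(a, d, 0.1, 40)))
})

test_that("relative density handles full, empty and undefined references", {
  ref <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2)
  expect_equal(relative_density(ref, ref), 1)
  expect_equal(relative_density(matrix(FALSE, 2, 2), ref), 0)
  expect_warning(
    expect_true(is.na(relative_density(ref, matrix(FALSE, 2, 2)))),
    "empty reference"
  )
})

test_that("raising the threshold never grows the mask", {
  set.seed(13)
  img <- matrix(rexp(900, 1 / 50), 30, 30)
  prev <- Inf
  for (thr in c(10, 30, 60, 120)) {
    a <- sum(make_mask(img, thr))
    expect_lte(a, prev)
    prev <- a
  }
})

test_that("punctum image generator honours counts, geometry and noise limits", {
  # density 0.5 / um^2 on a 20.48 um field: 210 A puncta
  p <- punctum_field_params(density_A = 0.5, density_B = 0.5, noise_sd = 0)
  pair <- generate_punctum_image_pair(p, seed = 2)
  area <- (512 * 0.04)^2
  expect_equal(sum(pair$truth$channel == "A"), round(0.5 * area))

  # density 0: pure noise channel, empty truth
  p0 <- punctum_field_params(density_A = 0, coloc_fraction = 0, noise_sd = 5)
  pair0 <- generate_punctum_image_pair(p0, seed = 3)
  expect_equal(sum(pair0$truth$channel == "A"), 0)
  expect_lt(max(pair0$image_A), 5 * 6)

  # coloc_fraction 1: every A centroid within the pairing radius of a B
  p1 <- punctum_field_params(coloc_fraction = 1, noise_sd = 0)
  pair1 <- generate_punctum_image_pair(p1, seed = 4)
  a <- pair1$truth[pair1$truth$channel == "A", ]
  b <- pair1$truth[pair1$truth$channel == "B", ]
  dmin <- vapply(seq_len(nrow(a)), function(i) {
    min(sqrt((a$x_um[i] - b$x_um)^2 + (a$y_um[i] - b$y_um)^2))
  }, numeric(1))
  expect_true(all(dmin <= p1$coloc_radius_nm / 1000 + 1e-9))
  expect_true(all(a$colocalized))

  # ground-truth labels always respect the pairing geometry
  pm <- punctum_field_params(coloc_fraction = 0.4, noise_sd = 0)
  pm_pair <- generate_punctum_image_pair(pm, seed = 5)
  am <- pm_pair$truth[pm_pair$truth$channel == "A", ]
  bm <- pm_pair$truth[pm_pair$truth$channel == "B", ]
  dmin2 <- vapply(seq_len(nrow(am)), function(i) {
    min(sqrt((am$x_um[i] - bm$x_um)^2 + (am$y_um[i] - bm$y_um)^2))
  }, numeric(1))
  r_um <- pm$coloc_radius_nm / 1000
  expect_true(all(dmin2[am$colocalized] <= r_um + 1e-9))
  expect_true(all(dmin2[!am$colocalized] > r_um))

  expect_warning(punctum_field_params(coloc_radius_nm = 10), "sub-pixel")
})

test_that("auto-threshold recovers the planted punctum count at high SNR", {
  # sparse field so that merged neighboring puncta (a geometric effect,
  # not a thresholding one) stay below the count tolerance
  p <- punctum_field_params(
    density_A = 0.02, density_B = 0.02,
    coloc_fraction = 0, noise_sd = 50
  ) # amplitude 1000: SNR 20
  found <- 0
  truth <- 0
  for (s in 1:10) {
    pair <- generate_punctum_image_pair(p, seed = s)
    m <- filter_small_components(
      make_mask(pair$image_A, "auto"), 0.1, p$pixel_size_nm
    )
    found <- found + max(label_components(m))
    truth <- truth + sum(pair$truth$channel == "A")
  }
  expect_lt(abs(found - truth) / truth, 0.05)
})

test_that("centroid matching is mutual-nearest-neighbor and capped at 2 um", {
  a <- rbind(c(0, 0))
  expect_equal(
    centroid_colocalization(a, rbind(c(0, 1.9)))$matched_fraction_a, 1
  )
  expect_equal(
    centroid_colocalization(a, rbind(c(0, 2.1)))$matched_fraction_a, 0
  )
  # two A points nearest to one B: exactly one match
  res <- centroid_colocalization(rbind(c(0, 0), c(0.2, 0)), rbind(c(0.1, 0)))
  expect_equal(nrow(res$pairs), 1L)
  # greedy agrees here
  res_g <- centroid_colocalization(rbind(c(0, 0), c(0.2, 0)), rbind(c(0.1, 0)),
    method = "greedy"
  )
  expect_equal(nrow(res_g$pairs), 1L)
  # empty inputs
  expect_equal(
    nrow(centroid_colocalization(a[0, , drop = FALSE], a)$pairs), 0L
  )
})

test_that("relative density recovers the planted colocalization fraction", {
  # full pipeline at a known threshold, noiseless
  est <- vapply(1:3, function(s) {
    p <- punctum_field_params(coloc_fraction = 0.15, noise_sd = 0)
    pair <- generate_punctum_image_pair(p, seed = s)
    res <- coloc_densitometry(pair$image_A, pair$image_B, 40,
      threshold_a = 500, threshold_b = 500
    )
    res$relative_to_b
  }, numeric(1))
  expect_lt(abs(mean(est) - 0.15), 0.05)
})
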