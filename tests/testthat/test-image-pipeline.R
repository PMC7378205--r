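test_that("grayscale conversion matches a per-pixel weighted-sum oracle and is idempotent", {
  set.seed(1)
  arr <- array(sample(0:255, 3 * 20 * 15, replace = TRUE), dim = c(20, 15, 3))
  g <- to_grayscale(arr)
  oracle <- round(0.299 * arr[, , 1] + 0.587 * arr[, , 2] + 0.114 * arr[, , 3])
  expect_equal(g, oracle)
  expect_identical(to_grayscale(g), g)
  # channel-equal RGB maps to the common value
  v <- matrix(sample(0:255, 25, replace = TRUE), 5, 5)
  eqrgb <- array(rep(v, 3), dim = c(5, 5, 3))
  expect_equal(to_grayscale(eqrgb), v)
  expect_error(to_grayscale(array(0, dim = c(4, 4, 2))), "RGB")
})

test_that("normalization hits the target moments exactly before clipping", {
  set.seed(2)
  img <- matrix(sample(60:180, 400, replace = TRUE), 20, 20)
  spec <- normalization_spec(target_mean = 40, target_sd = 10,
                             scale_convention = "intensity")
  out <- normalize_image(img, spec)
  # targets chosen so no pixel clips: achieved moments are the real moments
  expect_false(any(out == 0 | out == 255))
  expect_equal(mean(out), 40, tolerance = 1e-6)
  expect_equal(stats::sd(out), 10, tolerance = 1e-6)
  expect_equal(attr(out, "achieved_mean"), 40, tolerance = 1e-9)
  # fixed point: image already at target has identity transform
  out2 <- normalize_image(out, spec)
  expect_equal(attr(out2, "gain"), 1, tolerance = 1e-9)
  expect_equal(attr(out2, "offset"), 0, tolerance = 1e-6)
  # percent convention rescales targets to the 0-255 range
  outp <- normalize_image(img, normalization_spec(20, 5, "percent"))
  expect_equal(attr(outp, "achieved_mean"), 51, tolerance = 1e-9)
  expect_error(normalize_image(matrix(7, 4, 4)), "contrast undefined")
})

test_that("entropy features match exhaustive per-window recomputation", {
  set.seed(3)
  img <- matrix(sample(0:255, 49, replace = TRUE), 7, 7)
  got <- entropy_features(img, radii = 2)[, , 1]
  expect_equal(got, oracle_entropy(img, 2), tolerance = 1e-6)
  # larger window on a rectangular image, including the border
  img2 <- matrix(sample(0:255, 9 * 13, replace = TRUE), 9, 13)
  got2 <- entropy_features(img2, radii = 3)[, , 1]
  expect_equal(got2, oracle_entropy(img2, 3), tolerance = 1e-6)
})

test_that("entropy is 0 on constant and 1 bit on balanced two-valued windows", {
  expect_equal(entropy_features(matrix(77, 10, 10), radii = 2)[, , 1],
               matrix(0, 10, 10), tolerance = 1e-9)
  # alternating columns of 0 and 255: an interior radius-2 disk window
  # (13 pixels) holds 6 of one value and 7 of the other
  img <- matrix(0, 8, 8); img[, seq(2, 8, by = 2)] <- 255
  got <- entropy_features(img, radii = 2)[, , 1]
  oracle <- oracle_entropy(img, 2)
  expect_equal(got, oracle, tolerance = 1e-6)
  # interior windows of a radius-2 disk over alternating columns hold 6 or 7
  # of each value: entropy within [0.99, 1] bits
  interior <- got[3:6, 3:6]
  expect_true(all(interior >= 0.99 & interior <= 1))
  expect_error(entropy_features(matrix(0, 5, 5), radii = 10), "larger")
})

test_that("isodata threshold satisfies the fixed-point equation found by exhaustive scan", {
  set.seed(4)
  for (rep in 1:25) {
    n <- sample(50:400, 1)
    v <- sample(0:255, n, replace = TRUE,
                prob = stats::runif(256)^sample(1:3, 1))
    if (length(unique(v)) < 2) next
    thr <- isodata_threshold(v)
    fps <- oracle_isodata_fixed_points(v)
    expect_true(floor(thr) %in% fps)
    # and the fixed-point identity holds for the returned threshold itself
    expect_equal(thr, (mean(v[v <= thr]) + mean(v[v > thr])) / 2,
                 tolerance = 1e-6)
  }
})

test_that("isodata threshold is shift-equivariant and separates a bimodal foreground", {
  v <- rep(c(50, 200), each = 100)
  thr <- isodata_threshold(v)
  expect_gt(thr, 50); expect_lt(thr, 200)
  expect_identical(sum(v > thr), 100L)
  set.seed(5)
  v2 <- sample(0:200, 300, replace = TRUE)
  expect_equal(isodata_threshold(v2 + 10), isodata_threshold(v2) + 10,
               tolerance = 1e-6)
  expect_error(isodata_threshold(rep(3, 10)), "threshold undefined")
})

test_that("connected-component labeling agrees with a flood-fill oracle", {
  set.seed(6)
  for (rep in 1:12) {
    m <- random_mask()
    for (conn in c(8, 4)) {
      lab <- label_components(m, conn)
      orc <- oracle_label(m, conn)
      # same partition: labels must be a bijection of oracle labels
      expect_identical(max(lab), max(orc))
      expect_identical(lab > 0, orc > 0)
      key <- paste(lab[m], orc[m])
      expect_identical(length(unique(key)), max(orc))
      expect_identical(sort(unname(attr(lab, "areas"))),
                       sort(unname(tabulate(orc[m]))))
    }
  }
})

test_that("size filtering deletes regions smaller than min_area and keeps the boundary case", {
  # three separated blocks of areas 2999, 3000, 5000
  m <- matrix(FALSE, 170, 170)
  m[1:60, 1:50] <- TRUE; m[1, 1] <- FALSE               # 60*50 - 1 = 2999
  expect_identical(sum(m), 2999L)
  m2 <- matrix(FALSE, 170, 170); m2[62:121, 1:50] <- TRUE  # 60*50 = 3000
  m3 <- matrix(FALSE, 170, 170)
  m3[123:160, 1:132] <- TRUE; m3[123, 1:16] <- FALSE    # 38*132 - 16 = 5000
  expect_identical(sum(m3), 5000L)
  all_m <- m | m2 | m3
  seg <- worm_segmentation(all_m)
  expect_identical(sort(unname(seg$areas)), c(2999L, 3000L, 5000L))
  filt <- remove_small_regions(seg, 3000)
  expect_identical(sort(unname(filt$areas)), c(3000L, 5000L))
  # the 2999 region is gone from the mask
  expect_false(any(filt$mask & m))
  expect_true(all(filt$mask == (m2 | m3)))
  # empty mask is allowed
  empty <- remove_small_regions(worm_segmentation(matrix(FALSE, 5, 5)))
  expect_identical(sum(empty$mask), 0L)
})

test_that("size filtering agrees with brute-force component enumeration on random masks", {
  set.seed(7)
  for (rep in 1:12) {
    m <- random_mask(20, 20, p = 0.45)
    min_area <- sample(2:8, 1)
    filt <- remove_small_regions(worm_segmentation(m), min_area)
    orc <- oracle_label(m, 8)
    keep_ids <- which(tabulate(orc[m]) >= min_area)
    expect_identical(filt$mask, matrix(orc %in% keep_ids & m, 20, 20))
    expect_true(all(filt$areas >= min_area))
  }
})

test_that("mask multiplication zeroes the background and preserves the foreground", {
  set.seed(8)
  img <- matrix(stats::runif(100, 0, 255), 10, 10)
  m <- random_mask(10, 10)
  seg <- worm_segmentation(m)
  out <- apply_mask(seg, img)
  expect_true(all(out[!m] == 0))
  expect_equal(out[m], img[m])
  full <- worm_segmentation(matrix(TRUE, 10, 10))
  expect_equal(apply_mask(full, img), img, ignore_attr = TRUE)
  none <- worm_segmentation(matrix(FALSE, 10, 10))
  expect_true(all(apply_mask(none, img) == 0))
  expect_error(apply_mask(seg, img[1:5, ]), "shapes differ")
})

test_that("fluorescent units are the white-pixel count", {
  bin <- matrix(FALSE, 40, 40)
  expect_identical(quantify_fluorescence(bin)$fluorescent_units, 0L)
  bin[seq_len(1234)] <- TRUE
  expect_identical(quantify_fluorescence(bin)$fluorescent_units, 1234L)
})
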