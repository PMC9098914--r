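test_that("quantization bins the in-mask range into equal-width levels", {
  px <- matrix(100, 4, 4)
  q <- quantize(px, matrix(TRUE, 4, 4), 8)
  expect_true(all(q$grid == 1L))
  px2 <- matrix(c(0, 255, 0, 255), 2, 2)
  q2 <- quantize(px2, matrix(TRUE, 2, 2), 2)
  expect_equal(as.vector(q2$grid), c(1L, 2L, 1L, 2L))
  set.seed(1)
  for (i in 1:10) {
    px3 <- matrix(runif(64, 0, 255), 8, 8)
    L <- sample(2:16, 1)
    q3 <- quantize(px3, matrix(TRUE, 8, 8), L)
    expect_true(all(q3$grid >= 1L & q3$grid <= L))
  }
  expect_error(quantize(px, matrix(FALSE, 4, 4)), "empty")
})

test_that("co-occurrence counts match hand enumeration on the worked example", {
  g <- matrix(c(1L, 1L, 2L, 2L), 2, 2)   # [[1,2],[1,2]] row-wise
  q <- as_qroi(g, 2L)
  m <- glcm(q, "0")
  expect_equal(m$counts, matrix(c(0L, 2L, 2L, 0L), 2, 2))
  expect_equal(m$prob[1, 2], 0.5)
  expect_equal(m$prob[2, 1], 0.5)
  # constant grid: all mass on the diagonal, contrast 0
  qc <- as_qroi(matrix(1L, 3, 3), 2L)
  mc <- glcm(qc, "0")
  expect_equal(sum(mc$prob) - mc$prob[1, 1], 0)
  # 1-pixel mask: degenerate zero matrix
  expect_true(glcm(as_qroi(matrix(c(1L, NA, NA, NA), 2, 2), 2L), "0")$degenerate)
})

test_that("all four matrix builders equal brute-force enumeration on random grids", {
  set.seed(7)
  for (i in 1:50) {
    L <- sample(2:5, 1)
    g <- random_qgrid(8, 8, L)
    q <- as_qroi(g, L)
    for (d in c("0", "45", "90", "135")) {
      expect_identical(glcm(q, d)$counts, oracle_glcm(g, d, L))
      expect_identical(glrlm(q, d)$counts, oracle_glrlm(g, d, L))
    }
    expect_identical(glszm(q)$counts, oracle_glszm(g, L, 8L))
    expect_identical(glszm(q, connectivity = 4L)$counts,
                     oracle_glszm(g, L, 4L))
    ng <- ngtdm(q); or <- oracle_ngtdm(g, L)
    expect_equal(ng$s, or$s)
    expect_equal(ng$n, or$n)
  }
})

test_that("conservation identities hold on random grids", {
  set.seed(11)
  for (i in 1:20) {
    L <- sample(2:6, 1)
    g <- random_qgrid(10, 10, L, mask_prob = 0.8)
    q <- as_qroi(g, L)
    n_px <- q$n_pixels
    for (d in c("0", "45", "90", "135")) {
      gc <- glcm(q, d)
      if (!gc$degenerate) expect_equal(sum(gc$prob), 1)
      R <- glrlm(q, d)$counts
      expect_equal(sum(R %*% seq_len(ncol(R))), n_px)
    }
    Z <- glszm(q)$counts
    expect_equal(sum(Z %*% seq_len(ncol(Z))), n_px)
    ng <- ngtdm(q)
    expect_lte(sum(ng$n), n_px)
    if (sum(ng$n) > 0) expect_equal(sum(ng$p), 1)
  }
})

test_that("run-length and size-zone worked examples decompose as expected", {
  q <- as_qroi(matrix(c(1L, 1L, 2L), 1, 3), 2L)
  R <- glrlm(q, "0")$counts
  expect_equal(R[1, 2], 1L)  # one run of level 1, length 2
  expect_equal(R[2, 1], 1L)
  expect_equal(sum(R %*% seq_len(ncol(R))), 3)
  # constant row: a single maximal run
  qc <- as_qroi(matrix(1L, 1, 7), 1L)
  expect_equal(glrlm(qc, "0")$counts[1, 7], 1L)
  # zones: [[1,1],[2,1]] column-major -> levels 1,2,1,1
  qz <- as_qroi(matrix(c(1L, 2L, 1L, 1L), 2, 2), 2L)
  Z <- glszm(qz)$counts
  expect_equal(Z[1, 3], 1L)
  expect_equal(Z[2, 1], 1L)
  # checkerboard under 4-connectivity: every zone has size 1
  cb <- outer(1:6, 1:6, function(r, c) ((r + c) %% 2) + 1L)
  Z4 <- glszm(as_qroi(cb, 2L), connectivity = 4L)$counts
  expect_equal(ncol(Z4), 1L)
  expect_equal(sum(Z4[, 1]), 36)
})

test_that("gray-tone difference sums match the 3x3 worked example", {
  g <- matrix(1L, 3, 3); g[2, 2] <- 2L
  ng <- ngtdm(as_qroi(g, 2L))
  expect_equal(ng$s[2], 1)         # |2 - mean(eight 1s)| = 1
  border <- oracle_ngtdm(g, 2L)
  expect_equal(ng$s[1], border$s[1])
  expect_equal(ng$n, c(8L, 1L))
  qc <- ngtdm(as_qroi(matrix(3L, 4, 4), 4L))
  expect_true(all(qc$s == 0))
})

test_that("the feature catalogue has exactly 134 unique, finite features", {
  man <- feature_manifest()
  expect_equal(nrow(man), 134)
  expect_false(anyDuplicated(man$name) > 0)
  ph <- gen_phantom(phantom_spec(speckle_scale = 0.25, seed = 4))
  fv <- radiomic_features(ph$image, ph$lesion_mask)
  expect_length(fv, 134)
  expect_true(all(is.finite(fv)))
  expect_identical(names(fv), man$name)
})

test_that("constant ROIs give the closed-form co-occurrence features", {
  fv <- radiomic_features(matrix(42, 10, 10), matrix(TRUE, 10, 10))
  for (d in c("0", "45", "90", "135")) {
    expect_equal(fv[[paste0("glcm.contrast.", d)]], 0)
    expect_equal(fv[[paste0("glcm.energy.", d)]], 1)
  }
  expect_true(all(is.finite(fv)))
})

test_that("features are deterministic and translation invariant", {
  ph <- gen_phantom(phantom_spec(speckle_scale = 0.3, seed = 6,
                                 image_height = 64, image_width = 64,
                                 lesion_radii = c(9, 11)))
  a <- radiomic_features(ph$image, ph$lesion_mask)
  b <- radiomic_features(ph$image, ph$lesion_mask)
  expect_identical(a, b)
  # shift image and mask together by (3, 5)
  px <- ph$image$pixels; mk <- ph$lesion_mask
  px2 <- matrix(0, 70, 70); mk2 <- matrix(FALSE, 70, 70)
  px2[4:67, 6:69] <- px; mk2[4:67, 6:69] <- mk
  shifted <- radiomic_features(us_image(px2), mk2)
  expect_equal(a, shifted)
})

test_that("symmetric statistics are invariant under gray inversion with bin relabeling", {
  set.seed(3)
  g <- random_qgrid(10, 10, 4, mask_prob = 1)
  q <- as_qroi(g, 4L)
  qi <- as_qroi(5L - g, 4L)   # invert levels 1..4 -> 4..1
  for (d in c("0", "90")) {
    a <- slnradiomics:::glcm_stats(glcm(q, d)$prob, 4L)
    b <- slnradiomics:::glcm_stats(glcm(qi, d)$prob, 4L)
    for (st in c("energy", "entropy", "contrast", "maximum_probability"))
      expect_equal(a[[st]], b[[st]])
  }
})

test_that("per-ROI extraction is local to each mask and covers all four ROIs", {
  ph <- gen_phantom(phantom_spec(speckle_scale = 0.2, seed = 8,
                                 image_height = 72, image_width = 72,
                                 lesion_radii = c(8, 10)))
  rs <- build_roi_set(ph$image, ph$lesion_mask, ring_mm = 4)
  fx <- extract_roi_features(ph$image, rs, levels = 16)
  expect_named(fx, c("original", "intra", "peri", "combined"))
  expect_true(all(vapply(fx, length, integer(1)) == 134))
  # zeroing peri pixels must not change intra features (mask locality)
  img2 <- ph$image
  img2$pixels[rs$peri_mask] <- 0
  fx2 <- radiomic_features(img2, rs$intra_mask, levels = 16)
  expect_identical(fx$intra, fx2)
})
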