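test_that("superpixels partition the image and respect homogeneous regions", {
  img <- array(0, c(64L, 64L, 3L)); img[, 1:32, ] <- 50; img[, 33:64, ] <- 200
  cfg <- seg_config(felzenszwalb_scale = 100, felzenszwalb_sigma = 0,
                    felzenszwalb_min_size = 10L)
  sp <- compute_superpixels(img, cfg)
  expect_equal(sp$n_segments, 2L)
  expect_setequal(unique(as.integer(sp$labels)), 0:1)
  # the two superpixels coincide with the two halves
  expect_equal(length(unique(as.integer(sp$labels[, 1:32]))), 1L)
  expect_equal(length(unique(as.integer(sp$labels[, 33:64]))), 1L)
  # uniform image -> one superpixel
  spu <- compute_superpixels(array(100, c(32L, 32L, 3L)), cfg)
  expect_equal(spu$n_segments, 1L)
  # partition property: contiguous labels 0..n-1, every pixel labelled
  s <- generate_sample(test_skin_params(seed = 4L))
  sp2 <- compute_superpixels(s$image, test_seg_config())
  expect_setequal(unique(as.integer(sp2$labels)), 0:(sp2$n_segments - 1L))
})

test_that("superpixels are layer-pure on the synthetic three-band image", {
  s <- generate_sample(test_skin_params(seed = 3L))
  sp <- compute_superpixels(s$image, test_seg_config())
  expect_gte(sp$n_segments, 3L)
  h <- nrow(s$epidermis_mask); w <- ncol(s$epidermis_mask)
  rowm <- matrix(seq_len(h), h, w)
  truth <- matrix(3L, h, w)                     # dermis
  truth[rowm <= s$params$corneum_thickness] <- 1L
  truth[s$epidermis_mask > 0] <- 2L
  purity <- vapply(0:(sp$n_segments - 1L), function(id) {
    t <- truth[sp$labels == id]
    max(tabulate(t, 3L)) / length(t)
  }, numeric(1))
  expect_gte(mean(purity), 0.95)
})

test_that("iterative self-training recovers the epidermis band", {
  s <- generate_sample(test_skin_params(seed = 3L))
  cfg <- test_seg_config(seed = 103L)
  sp <- compute_superpixels(s$image, cfg)
  lab <- iterative_unsupervised_segment(s$image, sp, cfg)
  expect_gte(attr(lab, "n_clusters"), 3L)
  best <- max(vapply(unique(as.integer(lab)), function(id)
    iou(lab == id, s$epidermis_mask > 0), numeric(1)))
  expect_gte(best, 0.80)
  # determinism under a fixed seed
  lab2 <- iterative_unsupervised_segment(s$image, sp, cfg)
  expect_identical(lab, lab2)
})

test_that("a uniform image yields a single cluster and an explicit error downstream", {
  img <- array(128, c(48L, 48L, 3L))
  cfg <- test_seg_config()
  sp <- compute_superpixels(img, cfg)
  expect_warning(lab <- iterative_unsupervised_segment(img, sp, cfg),
                 "single cluster")
  expect_error(select_epidermis_cluster(lab, img), "no epidermis")
})

test_that("cluster selection honours overrides and documented tie-breaks", {
  s <- generate_sample(test_skin_params(seed = 5L))
  cfg <- test_seg_config(seed = 105L)
  sp <- compute_superpixels(s$image, cfg)
  lab <- iterative_unsupervised_segment(s$image, sp, cfg)
  sel <- select_epidermis_cluster(lab, s$image)
  expect_gte(iou(sel$mask > 0, s$epidermis_mask > 0), 0.80)
  # explicit override returns that cluster verbatim
  other <- setdiff(unique(as.integer(lab)), sel$cluster_id)[1L]
  sel2 <- select_epidermis_cluster(lab, s$image, cluster_id = other)
  expect_equal(sel2$cluster_id, other)
  expect_identical(sel2$mask, matrix(as.integer(lab == other), nrow(lab), ncol(lab)))
  # exact tie: two mirror-image clusters with identical scores -> lower id wins
  img <- array(100, c(40L, 40L, 3L))
  lab_tie <- matrix(2L, 40L, 40L)
  lab_tie[11:15, ] <- 1L
  lab_tie[26:30, ] <- 3L
  sel3 <- select_epidermis_cluster(lab_tie, img)
  expect_equal(sel3$cluster_id, 1L)
})

test_that("diagonal-span filter accepts spanning shapes and rejects corner blobs", {
  n <- 100L
  d <- matrix(0L, n, n); for (i in seq_len(n)) d[i, i] <- 1L
  expect_true(diagonal_span_filter(d))
  blob <- matrix(0L, n, n); blob[1:10, 1:10] <- 1L
  expect_false(diagonal_span_filter(blob))
  anti <- matrix(0L, n, n)
  for (i in seq_len(n)) anti[max(1L, n - i - 3L):min(n, n - i + 3L), i] <- 1L
  expect_true(diagonal_span_filter(anti))
  expect_false(diagonal_span_filter(matrix(0L, n, n)))
})

test_that("mask refinement removes specks, keeps the band, never dilates beyond the envelope", {
  m <- band_mask(100L, 100L, 40L, 60L)
  set.seed(1)
  specks <- cbind(sample(1:30, 10L), sample(1:100, 10L))
  m2 <- m; m2[specks] <- 1L
  r <- refine_mask(m2, kernel_radius = 3L, min_area = 50L)
  expect_equal(sum(r[1:30, ]), 0L)                        # specks gone
  expect_gte(sum(r[41:59, ]), 0.98 * sum(m[41:59, ]))     # band preserved
  # monotonicity: refinement stays inside the dilation envelope of the input
  for (seed in 1:3) {
    set.seed(seed)
    rnd <- matrix(as.integer(runif(60 * 60) < 0.3), 60L, 60L)
    rr <- suppressWarnings(refine_mask(rnd, kernel_radius = 2L, min_area = 10L))
    env <- EBImage::dilate(rnd, EBImage::makeBrush(5L, "disc"))
    expect_true(all(rr <= env))
  }
  expect_warning(out <- refine_mask(matrix(0L, 10L, 10L)), "empty")
  expect_equal(sum(out), 0L)
  # solid full-frame mask passes through pixel-equal
  solid <- matrix(1L, 64L, 64L)
  expect_identical(refine_mask(solid), solid)
})

test_that("level-1 extraction orients the band diagonally and rejects blobs", {
  s <- generate_sample(test_skin_params(seed = 2L))
  res <- extract_level1(s$image, s$epidermis_mask)
  expect_true(res$accepted)
  ang <- episcope:::mask_principal_angle(res$mask)
  d <- episcope:::diagonal_angle(nrow(res$mask), ncol(res$mask))
  expect_lte(min(abs(ang - d), abs(ang + d)), 10)
  expect_false(is.null(res$level1_image))
  expect_equal(dim(res$level1_image)[1:2], dim(res$mask))
  # corner blob -> rejected, no level-1 image, not an error
  blob <- matrix(0L, 96L, 96L); blob[1:12, 1:12] <- 1L
  img <- array(128, c(96L, 96L, 3L))
  res2 <- extract_level1(img, blob)
  expect_false(res2$accepted)
  expect_null(res2$level1_image)
  # a sample generated already diagonal is accepted without rotation
  big <- 260L; crop <- 140L
  p45 <- synthetic_skin_params(image_height = big, image_width = big,
                               corneum_thickness = big / 2 - 13,
                               epidermis_thickness = 26, ridge_amplitude = 4,
                               ridge_wavelength = 48, orientation_deg = 45,
                               seed = 2L)
  s45 <- generate_sample(p45)
  off <- (big - crop) / 2
  res3 <- extract_level1(s45$image[off + 1:crop, off + 1:crop, , drop = FALSE],
                         s45$epidermis_mask[off + 1:crop, off + 1:crop])
  expect_true(res3$accepted)
  expect_equal(res3$rotation_deg, 0)
})
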