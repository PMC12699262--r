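# Independent center-enumeration oracle: walk an ordered pixel path,
# accumulate arc length, take a center every `stride`, clamp the crop into
# bounds and de-duplicate -- written against the path directly, not against
# the package's sampling code.
enumerate_centers <- function(path, h, w, size, stride) {
  if (nrow(path) == 0L) return(matrix(numeric(0), 0L, 2L))
  seg <- sqrt(diff(path[, 1L])^2 + diff(path[, 2L])^2)
  s <- c(0, cumsum(seg))
  at <- if (s[length(s)] < stride) s[length(s)] / 2 else seq(0, s[length(s)], by = stride)
  idx <- vapply(at, function(a) which.min(abs(s - a)), integer(1))
  cand <- round(path[idx, , drop = FALSE])
  half <- size %/% 2L
  r0 <- pmin(pmax(cand[, 1L] - half, 1L), h - size + 1L)
  c0 <- pmin(pmax(cand[, 2L] - half, 1L), w - size + 1L)
  ctr <- cbind(r0 + half, c0 + half)
  ctr[!duplicated(ctr), , drop = FALSE]
}

test_that("mask path tracing follows the band midline", {
  m <- band_mask(100L, 200L, 31L, 70L)
  path <- trace_mask_path(m)
  expect_gt(nrow(path), 2L)
  expect_true(all(abs(path[, 1L] - 50.5) <= 2.5))
  # path spans most of the band length (thinning shortens the ends a little)
  expect_gte(diff(range(path[, 2L])), 200L - 2L * 40L)
  # deterministic orientation: starts at the lexicographically smaller end
  expect_true(path[1L, 2L] < path[nrow(path), 2L])
  # empty mask -> empty path
  expect_equal(nrow(trace_mask_path(matrix(0L, 10L, 10L))), 0L)
})

test_that("an L-shaped band yields one path traversing both arms", {
  m <- matrix(0L, 120L, 120L)
  m[10:30, 10:110] <- 1L     # horizontal arm, midline length ~100
  m[10:110, 10:30] <- 1L     # vertical arm
  path <- trace_mask_path(m)
  len <- sum(sqrt(diff(path[, 1L])^2 + diff(path[, 2L])^2))
  # expected: two arm midlines (~90 each after the shared corner), thinning
  # erodes the free ends by about the band half-width
  expect_gt(len, 120)
  expect_lt(len, 220)
  # both arms are visited
  expect_gt(max(path[, 2L]), 90); expect_gt(max(path[, 1L]), 90)
})

test_that("level-2 sampling matches brute-force center enumeration on a diagonal band", {
  n <- 768L
  mask <- diag_band_mask(n, 40L)
  img <- array(120, c(n, n, 3L))
  cfg <- sampler_config(level2_size = 256L, stride2 = 256L)
  ps <- sample_level2(img, mask, cfg, wsi_id = "t")
  path <- trace_mask_path(mask)
  oracle <- enumerate_centers(path, n, n, 256L, 256L)
  expect_equal(length(ps), nrow(oracle))
  # postcondition audit over every patch
  for (p in ps) {
    expect_equal(dim(p$pixels)[1:2], c(256L, 256L))
    expect_equal(dim(p$mask_crop), c(256L, 256L))
    expect_equal(mask[p$center[1L], p$center[2L]], 1L)
    half <- 128L
    expect_gte(p$center[1L] - half, 0L)
    expect_lte(p$center[1L] - half + 256L, n + 1L)
  }
  # determinism (ordering included)
  ps2 <- sample_level2(img, mask, cfg, wsi_id = "t")
  expect_identical(lapply(ps, `[[`, "center"), lapply(ps2, `[[`, "center"))
  # empty mask -> no patches
  expect_length(sample_level2(img, matrix(0L, n, n), cfg), 0L)
})

test_that("level-2 footprints cover the mask path when stride <= size", {
  n <- 600L
  mask <- diag_band_mask(n, 30L)
  img <- array(100, c(n, n, 3L))
  cfg <- sampler_config(level2_size = 200L, stride2 = 150L)
  ps <- sample_level2(img, mask, cfg)
  cov <- matrix(FALSE, n, n)
  for (p in ps) {
    r0 <- p$center[1L] - 100L; c0 <- p$center[2L] - 100L
    cov[r0:(r0 + 199L), c0:(c0 + 199L)] <- TRUE
  }
  path <- trace_mask_path(mask)
  on_path <- cov[round(path)]
  expect_gte(mean(on_path), 0.90)
})

test_that("the BMZ inclusion filter requires both tissues and diagonal orientation", {
  n <- 256L
  cfg <- sampler_config(level2_size = n, min_mask_frac = 0.1, diag_angle_tol_deg = 25)
  mk <- function(mask) patch(array(100, c(n, n, 3L)), mask, 2L, c(n / 2, n / 2), "p", "l1", "w")
  expect_false(bmz_inclusion_filter(mk(matrix(1L, n, n)), cfg))      # no dermis
  diagm <- diag_band_mask(n, 40L)
  expect_true(bmz_inclusion_filter(mk(diagm), cfg))                  # 45 degree band
  horiz <- band_mask(n, n, 100L, 160L)
  expect_false(bmz_inclusion_filter(mk(horiz), cfg))                 # 0 degree axis
})

test_that("level-3 patches lie inside their parent with resolvable provenance", {
  n <- 512L
  mask <- diag_band_mask(n, 48L)
  img <- array(0, c(n, n, 3L))
  img[, , 1L] <- 200; img[, , 2L] <- 150; img[, , 3L] <- 180
  # darker dermis side below the band so boundary roles are assignable
  below <- row(mask) > col(mask) + 48L
  for (k in 1:3) { pl <- img[, , k]; pl[below] <- pl[below] * 0.5; img[, , k] <- pl }
  cfg <- sampler_config(level2_size = 256L, stride2 = 256L,
                        level3_size = 128L, stride3 = 128L)
  ps <- sample_level2(img, mask, cfg, wsi_id = "w1")
  p2 <- ps[[2L]]
  p3s <- sample_level3(p2, cfg)
  expect_gt(length(p3s), 0L)
  for (q in p3s) {
    expect_equal(dim(q$pixels)[1:2], c(128L, 128L))
    expect_equal(q$parent_id, p2$patch_id)
    expect_equal(q$wsi_id, "w1")
    expect_gte(q$center[1L] - 64L, 0L)
    expect_lte(q$center[1L] + 63L, 256L)
    expect_equal(p2$mask_crop[q$center[1L], q$center[2L]], 1L)
  }
  # count matches the boundary-walk oracle along the dermis-side boundary
  b <- extract_boundaries(p2$mask_crop, p2$pixels)
  oracle <- enumerate_centers(b$eb$points, 256L, 256L, 128L, 128L)
  expect_equal(length(p3s), nrow(oracle))
  # strict mode: a parent failing the mask-fraction precondition is refused
  full <- patch(array(100, c(256L, 256L, 3L)), matrix(1L, 256L, 256L), 2L,
                c(128, 128), "pf", "l1", "w1")
  expect_warning(out <- sample_level3(full, cfg, strict = TRUE), "mask-fraction")
  expect_length(out, 0L)
})
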