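const_patch <- function(value = 128, n = 32L) array(value, c(n, n, 3L))

# Patches with controllable mean gray intensity and texture noise, grouped
# into slides (several patches share one wsi_id).
intensity_patch <- function(mu, sd, seed, n = 32L, patch_id = "p", wsi_id = "w") {
  set.seed(seed)
  img <- array(pmin(pmax(rnorm(n * n * 3L, mu, sd), 0), 255), c(n, n, 3L))
  patch(img, matrix(1L, n, n), 2L, c(n / 2, n / 2), patch_id, "l1", wsi_id)
}

test_that("every extraction yields the pinned 106-name schema", {
  manifest <- radiomic_feature_manifest()
  expect_length(manifest, 106L)
  expect_equal(sum(grepl("^firstorder_", manifest)), 18L)
  set.seed(2)
  inputs <- list(const_patch(),
                 array(runif(64 * 64 * 3, 0, 255), c(64L, 64L, 3L)),
                 intensity_patch(100, 20, 3, n = 48L))
  for (x in inputs) {
    fv <- extract_features(x)
    expect_identical(names(fv$values), manifest)
    expect_true(all(is.finite(fv$values)))
  }
  # mask-restricted mode keeps the identical schema
  s <- generate_sample(test_skin_params(seed = 2L))
  fvm <- extract_features(s, mask_mode = "mask_crop")
  expect_identical(names(fvm$values), manifest)
  # and an empty region is an explicit error
  empty <- patch(const_patch(), matrix(0L, 32L, 32L), 2L, c(16, 16), "p", "l", "w")
  expect_error(extract_features(empty, mask_mode = "mask_crop"), "empty region")
})

test_that("degenerate constant patches produce the expected first-order values", {
  fv <- extract_features(const_patch(128))
  v <- fv$values
  expect_equal(unname(v["firstorder_Median"]), 128)
  expect_equal(unname(v["firstorder_10Percentile"]), 128)
  expect_equal(unname(v["firstorder_Variance"]), 0)
  expect_equal(unname(v["glcm_ClusterShade"]), 0)
  expect_true("firstorder_Skewness" %in% fv$nan_flags)
  expect_equal(unname(v["firstorder_Skewness"]), 0)
})

test_that("checkerboard GLCM cluster shade and skewness match brute-force enumeration", {
  n <- 8L
  g <- (outer(seq_len(n), seq_len(n), `+`) %% 2L) * 100 + 50   # 50 / 150 checkerboard
  img <- array(rep(g, 3L), c(n, n, 3L))
  fv <- extract_features(img, bin_width = 25)
  # oracle: explicit co-occurrence enumeration, distance 1, 4 directions,
  # symmetric, on the discretized levels
  lev <- floor((g - min(g)) / 25) + 1L
  Ng <- max(lev)
  P <- matrix(0, Ng, Ng)
  offs <- list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(-1L, 1L))
  for (o in offs) for (r in seq_len(n)) for (c2 in seq_len(n)) {
    r2 <- r + o[1L]; c3 <- c2 + o[2L]
    if (r2 >= 1L && r2 <= n && c3 >= 1L && c3 <= n) {
      P[lev[r, c2], lev[r2, c3]] <- P[lev[r, c2], lev[r2, c3]] + 1
      P[lev[r2, c3], lev[r, c2]] <- P[lev[r2, c3], lev[r, c2]] + 1
    }
  }
  p <- P / sum(P)
  i <- matrix(seq_len(Ng), Ng, Ng); j <- t(i)
  mux <- sum(i * p); muy <- sum(j * p)
  shade_or <- sum((i + j - mux - muy)^3 * p)
  expect_equal(unname(fv$values["glcm_ClusterShade"]), shade_or, tolerance = 1e-9)
  x <- as.numeric(g)
  m2 <- mean((x - mean(x))^2); m3 <- mean((x - mean(x))^3)
  expect_equal(unname(fv$values["firstorder_Skewness"]), m3 / m2^1.5, tolerance = 1e-9)
})

test_that("first-order statistics equal direct order-statistic computation", {
  set.seed(9)
  img <- array(runif(40 * 40 * 3, 0, 255), c(40L, 40L, 3L))
  fv <- extract_features(img)
  gray <- rgb_to_gray(img)
  expect_equal(unname(fv$values["firstorder_Median"]), median(gray), tolerance = 1e-9)
  expect_equal(unname(fv$values["firstorder_Mean"]), mean(gray), tolerance = 1e-9)
  expect_equal(unname(fv$values["firstorder_10Percentile"]),
               unname(quantile(gray, 0.1)), tolerance = 1e-9)
  # determinism: bit-identical values on repeat extraction
  fv2 <- extract_features(img)
  expect_identical(fv$values, fv2$values)
})

test_that("the random forest separates intensity-shifted classes and ranks sensibly", {
  build_cohort <- function(seed) {
    fvs <- list()
    k <- 0L
    for (cl in c("dim", "bright")) {
      mu <- if (cl == "dim") 100 else 130
      for (w in 1:10) for (rep in 1:5) {
        k <- k + 1L
        p <- intensity_patch(mu, 10, seed * 10000L + k, n = 24L,
                             patch_id = sprintf("p%03d", k),
                             wsi_id = sprintf("%s_w%02d", cl, w))
        fv <- extract_features(p)
        fv$label <- cl
        fvs[[k]] <- fv
      }
    }
    fvs
  }
  # Features that respond directly to an intensity-location shift; the two
  # classes differ only in mean intensity, so the forest's top ranks should
  # be filled from this family (the schema deliberately carries several
  # interchangeable location features, so importance spreads among them).
  loc_feats <- c(paste0("firstorder_", c("Mean", "Median", "Minimum", "Maximum",
                                         "10Percentile", "90Percentile",
                                         "RootMeanSquared", "TotalEnergy", "Energy")),
                 paste0("diagnostics_", c("image_Mean", "image_Minimum",
                                          "image_Maximum", "gray_Minimum",
                                          "gray_Maximum")))
  hits <- 0L; top5_hit <- 0L
  for (seed in 1:5) {
    fvs <- build_cohort(seed)
    cv <- rf_group_cv_auc(fvs, k = 5L, n_trees = 150L, seed = seed)
    if (!is.na(cv$auc) && cv$auc >= 0.95) hits <- hits + 1L
    fit <- fit_rf_classifier(fvs, n_trees = 300L, seed = seed)
    top5 <- fit$ranking$feature[fit$ranking$selected]
    if (all(top5 %in% loc_feats) &&
        any(c("firstorder_Median", "firstorder_Mean") %in% fit$ranking$feature[1:15]))
      top5_hit <- top5_hit + 1L
    if (seed == 1L) {
      expect_equal(sum(fit$ranking$selected), 5L)
      expect_equal(sum(fit$ranking$importance), 1, tolerance = 1e-6)
      expect_true(all(diff(fit$ranking$importance) <= 1e-12))
      # seed determinism of the ranking
      fit2 <- fit_rf_classifier(fvs, n_trees = 300L, seed = seed)
      expect_identical(fit$ranking$feature, fit2$ranking$feature)
    }
  }
  expect_gte(hits, 4L)
  expect_gte(top5_hit, 4L)
})

test_that("identical class distributions give chance-level cross-validated AUC", {
  fvs <- list(); k <- 0L
  for (cl in c("a", "b")) for (w in 1:10) for (rep in 1:5) {
    k <- k + 1L
    p <- intensity_patch(115, 10, 777000L + k, n = 24L,
                         patch_id = sprintf("p%03d", k),
                         wsi_id = sprintf("%s_w%02d", cl, w))
    fv <- extract_features(p); fv$label <- cl
    fvs[[k]] <- fv
  }
  cv <- rf_group_cv_auc(fvs, k = 5L, n_trees = 150L, seed = 4L)
  expect_gte(cv$auc, 0.35); expect_lte(cv$auc, 0.65)
})

test_that("single-class labels are a degenerate-label error", {
  fvs <- lapply(1:4, function(i) {
    fv <- extract_features(intensity_patch(100, 10, i))
    fv$label <- "only"
    fv
  })
  expect_error(fit_rf_classifier(fvs), "degenerate")
})

test_that("feature group summaries report one row per schema feature", {
  fvs <- list(); k <- 0L
  for (cl in c("dim", "bright")) for (i in 1:8) {
    k <- k + 1L
    mu <- if (cl == "dim") 100 else 130
    fv <- extract_features(intensity_patch(mu, 8, 5000L + k, n = 24L))
    fv$label <- cl
    fvs[[k]] <- fv
  }
  gs <- feature_group_summary(fvs)
  expect_equal(nrow(gs$table), 106L)
  med <- gs$table[gs$table$feature == "firstorder_Median", ]
  expect_equal(abs(med$delta), 30, tolerance = 5)
  expect_length(gs$densities, 106L)
})
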