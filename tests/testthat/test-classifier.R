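test_that("slide-level folds are stratified, disjoint and deterministic", {
  ids <- sprintf("w%02d", 1:10)
  labs <- rep(c("young", "aged"), each = 5L)
  folds <- make_folds(ids, labs, k = 5L, seed = 3L)
  expect_length(folds, 5L)
  tested <- character(0)
  for (f in folds) {
    expect_length(f$test_wsi_ids, 2L)
    expect_setequal(labs[match(f$test_wsi_ids, ids)], c("young", "aged"))
    expect_length(intersect(f$train_wsi_ids, f$test_wsi_ids), 0L)
    tested <- c(tested, f$test_wsi_ids)
  }
  expect_setequal(tested, ids)          # each slide tests exactly once
  expect_equal(anyDuplicated(tested), 0L)
  folds2 <- make_folds(ids, labs, k = 5L, seed = 3L)
  expect_identical(folds, folds2)
  expect_error(make_folds(ids[1:6], labs[1:6], k = 5L), "stratification")
})

test_that("ROC / PR / F1 match hand computation and a reference implementation", {
  # perfect scores
  truth <- c(rep(TRUE, 5L), rep(FALSE, 5L))
  expect_equal(roc_auc(truth, as.numeric(truth)), 1)
  expect_equal(pr_auc(truth, as.numeric(truth)), 1)
  # hand-built 3-class prediction table (12 rows)
  true3 <- c("a", "a", "a", "a", "b", "b", "b", "b", "c", "c", "c", "c")
  pred3 <- c("a", "a", "b", "c", "b", "b", "b", "a", "c", "c", "a", "a")
  # confusion: a: tp2 fp3 fn2; b: tp3 fp1 fn1; c: tp2 fp1 fn2
  f1_hand <- mean(c(2 * 2 / (2 * 2 + 3 + 2), 2 * 3 / (2 * 3 + 1 + 1), 2 * 2 / (2 * 2 + 1 + 2)))
  expect_equal(f1_macro(true3, pred3), f1_hand)
  expect_equal(mean(true3 == pred3), 7 / 12)
  # random scores at n = 2000: chance-level AUC
  set.seed(5)
  t2 <- rep(c(TRUE, FALSE), each = 1000L)
  s2 <- runif(2000L)
  a <- roc_auc(t2, s2)
  expect_gte(a, 0.45); expect_lte(a, 0.55)
  # independent reference: pROC agreement on ties-free and tied data
  for (seed in 1:3) {
    set.seed(seed)
    tt <- runif(300L) > 0.5
    ss <- round(runif(300L), 2L)        # ties present
    expect_equal(roc_auc(tt, ss),
                 as.numeric(pROC::auc(pROC::roc(tt, ss, quiet = TRUE))),
                 tolerance = 1e-12)
  }
  # degenerate folds: single-class truth has no AUC
  expect_true(is.na(roc_auc(rep(TRUE, 4L), runif(4L))))
})

test_that("training learns a separable toy with non-increasing loss", {
  mk <- function(value, id, wsi) patch(array(value, c(16L, 16L, 3L)),
                                       matrix(1L, 16L, 16L), 2L, c(8, 8),
                                       id, "l1", wsi)
  patches <- c(lapply(1:6, function(i) mk(60, sprintf("a%d", i), sprintf("wa%d", i))),
               lapply(1:6, function(i) mk(190, sprintf("b%d", i), sprintf("wb%d", i))))
  labels <- rep(c("dark", "bright"), each = 6L)
  cfg <- train_config(epochs = 5L, input_size = 16L, seed = 2L)
  model <- train_cnn(patches, labels, cfg)
  expect_true(all(diff(model$loss_history) <= 1e-8))
  probs <- predict_cnn(model, patches)
  expect_equal(colnames(probs)[max.col(probs)], ifelse(labels == "bright", "bright", "dark"))
  # all-one-class training predicts that class everywhere
  m1 <- train_cnn(patches[1:6], rep("dark", 6L), train_config(epochs = 2L,
                                                              input_size = 16L, seed = 2L),
                  classes = c("bright", "dark"))
  p1 <- predict_cnn(m1, patches)
  expect_true(all(colnames(p1)[max.col(p1)] == "dark"))
})

test_that("the residual backbone builds, steps once, and keeps shapes", {
  cfg <- train_config(backbone = "resnet_small", epochs = 1L, input_size = 16L,
                      seed = 1L, n_classes = 3L)
  p <- patch(array(runif(16 * 16 * 3, 0, 255), c(16L, 16L, 3L)),
             matrix(1L, 16L, 16L), 2L, c(8, 8), "p", "l", "w")
  model <- train_cnn(list(p, p), c("x", "y"), cfg, classes = c("x", "y", "z"))
  probs <- predict_cnn(model, list(p))
  expect_equal(dim(probs), c(1L, 3L))
  expect_equal(sum(probs), 1, tolerance = 1e-9)
  expect_warning(train_config(pretrained = TRUE), "pretrained")
})

test_that("evaluation pools out-of-fold predictions and guards against leakage", {
  mk <- function(value, id, wsi) patch(array(value + rnorm(16 * 16 * 3, 0, 8),
                                             c(16L, 16L, 3L)),
                                       matrix(1L, 16L, 16L), 2L, c(8, 8), id, "l1", wsi)
  set.seed(7)
  patches <- list(); labels <- character(0); wsis <- character(0)
  k <- 0L
  for (cl in c("dark", "bright")) for (w in 1:5) for (r in 1:3) {
    k <- k + 1L
    patches[[k]] <- mk(if (cl == "dark") 60 else 190, sprintf("p%02d", k),
                       sprintf("%s_w%d", cl, w))
    labels <- c(labels, cl); wsis <- c(wsis, sprintf("%s_w%d", cl, w))
  }
  wsi_ids <- unique(wsis)
  wsi_labs <- labels[match(wsi_ids, wsis)]
  folds <- make_folds(wsi_ids, wsi_labs, k = 5L, seed = 1L)
  cfg <- train_config(epochs = 2L, input_size = 16L, seed = 3L)
  models <- train_cnn_folds(patches, labels, folds, cfg)
  rep_ <- evaluate_cnn_folds(models, patches, labels, folds)
  expect_equal(rep_$pooled$n, 30L)
  # metric cross-check: pooled accuracy equals mean row correctness
  expect_equal(rep_$pooled$accuracy,
               mean(rep_$predictions$true == rep_$predictions$predicted))
  expect_true(all(rep_$per_fold$accuracy >= 0 & rep_$per_fold$accuracy <= 1))
  # every test slide was absent from its fold's training slides
  for (f in folds) {
    te <- rep_$predictions$wsi_id[rep_$predictions$fold == f$fold_id]
    expect_length(intersect(unique(te), f$train_wsi_ids), 0L)
  }
  # tampered folds trip the leakage guard
  bad <- folds
  bad[[1L]]$train_wsi_ids <- c(bad[[1L]]$train_wsi_ids, bad[[1L]]$test_wsi_ids[1L])
  expect_error(evaluate_cnn_folds(models, patches, labels, bad), "leakage")
  # slide-level aggregation collapses to one row per slide
  rep_w <- evaluate_cnn_folds(models, patches, labels, folds, aggregate = "wsi")
  expect_equal(rep_w$pooled$n, 10L)
})
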