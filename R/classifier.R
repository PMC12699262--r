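# ---------------------------------------------------------------------------
# Patch-level CNN classification under slide-level cross-validation
# ---------------------------------------------------------------------------
# Patches inherit their slide's fold (no slide ever contributes to both the
# train and the test side of a split), training uses plain SGD with the
# protocol defaults (learning rate 0.01, mini-batch size 1), and evaluation
# reports accuracy, trapezoidal ROC-AUC, step-envelope PR-AUC and macro-F1,
# per fold and pooled over the concatenated out-of-fold predictions.

#' Training configuration for the patch classifier
#'
#' @param backbone \code{"small_cnn"} (3 conv blocks + pooling + linear
#'   head; the first-class CPU backbone) or \code{"resnet_small"} (residual
#'   blocks in the ResNet style).
#' @param pretrained logical; pretrained weights are not distributed with
#'   the package, so TRUE warns and falls back to random initialization.
#' @param learning_rate SGD learning rate (default 0.01).
#' @param batch_size gradient-accumulation size (default 1).
#' @param epochs training epochs per fold (default 10).
#' @param seed RNG seed for initialization and epoch shuffling.
#' @param n_classes number of classes.
#' @param input_size patches are bilinearly resized to this edge length
#'   before entering the network.
#' @return object of class \code{train_config}.
#' @export
train_config <- function(backbone = c("small_cnn", "resnet_small"),
                         pretrained = FALSE, learning_rate = 0.01,
                         batch_size = 1L, epochs = 10L, seed = 1L,
                         n_classes = 2L, input_size = 64L) {
  backbone <- match.arg(backbone)
  stopifnot(learning_rate > 0, batch_size >= 1L, epochs >= 1L, n_classes >= 2L)
  if (isTRUE(pretrained)) {
    warning("pretrained weights are not available; using random initialization")
    pretrained <- FALSE
  }
  structure(list(backbone = backbone, pretrained = pretrained,
                 learning_rate = learning_rate, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), seed = as.integer(seed),
                 n_classes = as.integer(n_classes),
                 input_size = as.integer(input_size)),
            class = "train_config")
}

# Fixed input normalization: pixels to [0,1], then (x - 0.5) / 0.25.
preprocess_patch <- function(pixels, input_size) {
  x <- resize_bilinear(pixels, input_size, input_size) / 255
  (x - 0.5) / 0.25
}

build_backbone <- function(config) {
  K <- config$n_classes
  if (config$backbone == "small_cnn") {
    list(nn_init_conv(3L, 8L, 3L), nn_relu(), nn_init_bn(8L), nn_pool(),
         nn_init_conv(8L, 16L, 3L), nn_relu(), nn_init_bn(16L), nn_pool(),
         nn_init_conv(16L, 32L, 3L), nn_relu(), nn_init_bn(32L), nn_pool(),
         nn_gap(), nn_init_linear(32L, K))
  } else {
    res_block <- function(ch)
      nn_residual(list(nn_init_conv(ch, ch, 3L), nn_relu(), nn_init_bn(ch),
                       nn_init_conv(ch, ch, 3L), nn_init_bn(ch)))
    list(nn_init_conv(3L, 16L, 3L), nn_relu(), nn_init_bn(16L),
         res_block(16L), nn_relu(), nn_pool(),
         res_block(16L), nn_relu(), nn_pool(),
         nn_gap(), nn_init_linear(16L, K))
  }
}

#' Stratified slide-level cross-validation folds
#'
#' Slides (WSIs) are partitioned into \code{k} folds stratified by label;
#' every patch later inherits its slide's fold assignment.
#'
#' @param wsi_ids character vector of slide identifiers.
#' @param labels_per_wsi label of each slide (same order).
#' @param k number of folds (default 5).
#' @param seed RNG seed; identical seeds give identical folds.
#' @return list of fold objects: \code{fold_id}, \code{train_wsi_ids},
#'   \code{test_wsi_ids}.
#' @export
make_folds <- function(wsi_ids, labels_per_wsi, k = 5L, seed = 1L) {
  stopifnot(length(wsi_ids) == length(labels_per_wsi))
  wsi_ids <- as.character(wsi_ids)
  if (anyDuplicated(wsi_ids)) stop("wsi_ids must be unique")
  y <- factor(labels_per_wsi)
  cnt <- table(y)
  if (any(cnt < k))
    stop("stratification error: class '", names(cnt)[which.min(cnt)],
         "' has fewer than ", k, " slides")
  assign <- integer(length(wsi_ids))
  with_seed(seed, {
    for (cl in levels(y)) {
      ids <- which(y == cl)
      ids <- ids[sample.int(length(ids))]
      assign[ids] <- rep_len(seq_len(k), length(ids))
    }
  })
  lapply(seq_len(k), function(f)
    list(fold_id = f,
         train_wsi_ids = wsi_ids[assign != f],
         test_wsi_ids = wsi_ids[assign == f]))
}

# Forward a single patch through a model; returns class probabilities.
model_probs <- function(model, pixels) {
  x <- preprocess_patch(pixels, model$config$input_size)
  logits <- nn_forward(model$net, x)$out
  z <- logits - max(logits)
  exp(z) / sum(exp(z))
}

#' Train the patch classifier per cross-validation fold
#'
#' Each fold's model is trained only on patches from that fold's training
#' slides, with cross-entropy loss and SGD (gradient accumulation when
#' \code{batch_size > 1}). Folds without trainable patches are skipped and
#' recorded.
#'
#' @param patches list of \code{\link{patch}} objects.
#' @param labels label per patch.
#' @param folds from \code{\link{make_folds}}.
#' @param config a \code{\link{train_config}}.
#' @return list of per-fold models (class \code{cnn_model}): \code{net},
#'   \code{config}, \code{classes}, \code{fold_id}, \code{loss_history},
#'   \code{skipped}.
#' @export
train_cnn_folds <- function(patches, labels, folds, config = train_config()) {
  y <- factor(labels)
  classes <- levels(y)
  if (length(classes) > config$n_classes)
    stop("more classes than config$n_classes")
  wsi <- vapply(patches, `[[`, "", "wsi_id")
  lapply(folds, function(fold) {
    tr <- which(wsi %in% fold$train_wsi_ids)
    if (length(tr) == 0L)
      return(structure(list(net = NULL, config = config, classes = classes,
                            fold_id = fold$fold_id, loss_history = numeric(0),
                            skipped = TRUE),
                       class = "cnn_model"))
    model <- train_cnn(patches[tr], y[tr], config, classes = classes)
    model$fold_id <- fold$fold_id
    model
  })
}

#' Train a single CNN classifier
#'
#' @param patches list of \code{\link{patch}} objects.
#' @param labels label per patch.
#' @param config a \code{\link{train_config}}.
#' @param classes optional fixed class-level ordering.
#' @return a \code{cnn_model}.
#' @export
train_cnn <- function(patches, labels, config = train_config(), classes = NULL) {
  y <- factor(labels, levels = if (is.null(classes)) sort(unique(as.character(labels))) else classes)
  targets <- as.integer(y)
  n <- length(patches)
  loss_history <- numeric(config$epochs)
  with_seed(config$seed, {
    net <- build_backbone(config)
    xs <- lapply(patches, function(p) preprocess_patch(p$pixels, config$input_size))
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(n)
      losses <- numeric(n)
      acc_grads <- NULL; acc_count <- 0L
      for (ii in seq_along(ord)) {
        i <- ord[ii]
        fw <- nn_forward(net, xs[[i]])
        ce <- softmax_xent_vec(fw$out, targets[i])
        losses[ii] <- ce$loss
        bw <- nn_backward(net, fw$caches, ce$dlogits)
        acc_grads <- if (is.null(acc_grads)) bw$grads else add_grads(acc_grads, bw$grads)
        acc_count <- acc_count + 1L
        if (acc_count == config$batch_size || ii == length(ord)) {
          net <- nn_sgd_step(net, scale_grads(acc_grads, 1 / acc_count),
                             config$learning_rate)
          acc_grads <- NULL; acc_count <- 0L
        }
      }
      loss_history[ep] <- mean(losses)
    }
  })
  structure(list(net = net, config = config, classes = levels(y),
                 fold_id = NA_integer_, loss_history = loss_history,
                 skipped = FALSE),
            class = "cnn_model")
}

add_grads <- function(a, b) {
  for (i in seq_along(a)) {
    if (is.null(a[[i]])) next
    if (!is.null(a[[i]]$sub_grads)) a[[i]]$sub_grads <- add_grads(a[[i]]$sub_grads, b[[i]]$sub_grads)
    else for (nm in names(a[[i]])) a[[i]][[nm]] <- a[[i]][[nm]] + b[[i]][[nm]]
  }
  a
}

scale_grads <- function(g, s) {
  for (i in seq_along(g)) {
    if (is.null(g[[i]])) next
    if (!is.null(g[[i]]$sub_grads)) g[[i]]$sub_grads <- scale_grads(g[[i]]$sub_grads, s)
    else for (nm in names(g[[i]])) g[[i]][[nm]] <- g[[i]][[nm]] * s
  }
  g
}

#' @export
print.cnn_model <- function(x, ...) {
  cat(sprintf("<cnn_model %s: %d classes%s%s>\n", x$config$backbone,
              length(x$classes),
              if (!is.na(x$fold_id)) sprintf(", fold %d", x$fold_id) else "",
              if (x$skipped) ", SKIPPED" else ""))
  invisible(x)
}

#' Class probabilities for a list of patches
#'
#' @param model a \code{cnn_model}.
#' @param patches list of \code{\link{patch}} objects.
#' @return n x n_classes probability matrix (columns named by class).
#' @export
predict_cnn <- function(model, patches) {
  if (model$skipped) stop("model was skipped (no trainable patches)")
  probs <- t(vapply(patches, function(p) model_probs(model, p$pixels),
                    numeric(length(model$classes))))
  colnames(probs) <- model$classes
  probs
}

# ---- metrics ---------------------------------------------------------------

#' Area under the ROC curve (trapezoidal)
#'
#' @param truth logical (or 0/1) vector: positive-class membership.
#' @param scores numeric scores, larger = more positive.
#' @return AUC in \code{[0, 1]}; \code{NA} if only one class is present.
#' @export
roc_auc <- function(truth, scores) {
  truth <- as.logical(truth)
  P <- sum(truth); N <- sum(!truth)
  if (P == 0L || N == 0L) return(NA_real_)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; t <- truth[ord]
  # group tied scores so the curve steps through ties diagonally
  grp <- cumsum(c(TRUE, diff(s) != 0))
  tp <- cumsum(t); fp <- cumsum(!t)
  last <- !duplicated(grp, fromLast = TRUE)
  tpr <- c(0, tp[last] / P); fpr <- c(0, fp[last] / N)
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

#' Area under the precision-recall curve (step-wise envelope)
#'
#' @inheritParams roc_auc
#' @return PR-AUC in \code{[0, 1]}; \code{NA} if no positives.
#' @export
pr_auc <- function(truth, scores) {
  truth <- as.logical(truth)
  P <- sum(truth)
  if (P == 0L || all(truth)) return(NA_real_)
  ord <- order(scores, decreasing = TRUE)
  t <- truth[ord]; s <- scores[ord]
  grp <- cumsum(c(TRUE, diff(s) != 0))
  tp <- cumsum(t); fp <- cumsum(!t)
  last <- !duplicated(grp, fromLast = TRUE)
  rec <- tp[last] / P
  prec <- tp[last] / (tp[last] + fp[last])
  # step-wise precision envelope: at each recall use the best precision
  # achievable at that recall or higher
  env <- rev(cummax(rev(prec)))
  sum(diff(c(0, rec)) * env)
}

#' Macro-averaged F1 score
#'
#' @param truth true class labels.
#' @param predicted predicted class labels.
#' @return mean over classes of the per-class F1 (classes with no true or
#'   predicted instances contribute 0).
#' @export
f1_macro <- function(truth, predicted) {
  cls <- union(unique(as.character(truth)), unique(as.character(predicted)))
  f1s <- vapply(cls, function(cl) {
    tp <- sum(truth == cl & predicted == cl)
    fp <- sum(truth != cl & predicted == cl)
    fn <- sum(truth == cl & predicted != cl)
    if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  }, numeric(1))
  mean(f1s)
}

# Macro one-vs-rest AUC helper for multi-class score matrices.
macro_ovr_auc <- function(truth, probs, fun) {
  cls <- colnames(probs)
  vals <- vapply(cls, function(cl) fun(truth == cl, probs[, cl]), numeric(1))
  if (all(is.na(vals))) NA_real_ else mean(vals, na.rm = TRUE)
}

#' Evaluate fold models on their test patches
#'
#' Computes per-fold and pooled (concatenated out-of-fold) accuracy,
#' ROC-AUC, PR-AUC and macro-F1. Multi-class AUCs are macro-averaged
#' one-vs-rest. A leakage guard verifies that no test patch's slide
#' appears in its fold's training slides.
#'
#' @param models list of \code{cnn_model} from \code{\link{train_cnn_folds}}.
#' @param patches list of \code{\link{patch}} objects.
#' @param labels label per patch.
#' @param folds the folds used for training.
#' @param aggregate \code{"patch"} (default) or \code{"wsi"} (mean class
#'   score over each slide's patches before scoring).
#' @return object of class \code{eval_report}: list with \code{per_fold}
#'   (data.frame), \code{pooled} (named list) and \code{predictions}
#'   (data.frame with one row per evaluated unit).
#' @export
evaluate_cnn_folds <- function(models, patches, labels, folds,
                               aggregate = c("patch", "wsi")) {
  aggregate <- match.arg(aggregate)
  y <- as.character(labels)
  wsi <- vapply(patches, `[[`, "", "wsi_id")
  pid <- vapply(patches, `[[`, "", "patch_id")
  preds <- NULL
  for (j in seq_along(folds)) {
    fold <- folds[[j]]
    model <- models[[j]]
    if (model$skipped) next
    if (length(intersect(fold$train_wsi_ids, fold$test_wsi_ids)) > 0L)
      stop("leakage: train and test slides overlap in fold ", fold$fold_id)
    te <- which(wsi %in% fold$test_wsi_ids)
    if (length(te) == 0L) next
    probs <- predict_cnn(model, patches[te])
    df <- data.frame(patch_id = pid[te], wsi_id = wsi[te], fold = fold$fold_id,
                     true = y[te],
                     predicted = colnames(probs)[max.col(probs, ties.method = "first")],
                     stringsAsFactors = FALSE)
    df <- cbind(df, as.data.frame(probs, optional = TRUE))
    preds <- rbind(preds, df)
  }
  if (is.null(preds)) stop("no folds produced predictions")
  classes <- models[[which(!vapply(models, `[[`, TRUE, "skipped"))[1L]]]$classes
  if (aggregate == "wsi") {
    agg <- stats::aggregate(preds[, classes, drop = FALSE],
                            by = list(wsi_id = preds$wsi_id, fold = preds$fold,
                                      true = preds$true), FUN = mean)
    agg$predicted <- classes[max.col(agg[, classes, drop = FALSE], ties.method = "first")]
    agg$patch_id <- agg$wsi_id
    preds <- agg
  }
  metr <- function(d) {
    probs <- as.matrix(d[, classes, drop = FALSE])
    roc <- if (length(classes) == 2L) roc_auc(d$true == classes[2L], probs[, 2L])
           else macro_ovr_auc(d$true, probs, roc_auc)
    pr <- if (length(classes) == 2L) pr_auc(d$true == classes[2L], probs[, 2L])
          else macro_ovr_auc(d$true, probs, pr_auc)
    list(n = nrow(d), accuracy = mean(d$true == d$predicted),
         roc_auc = roc, pr_auc = pr, f1_macro = f1_macro(d$true, d$predicted))
  }
  per_fold <- do.call(rbind, lapply(split(preds, preds$fold), function(d)
    data.frame(fold = d$fold[1L], as.data.frame(metr(d)))))
  pooled <- metr(preds)
  structure(list(per_fold = per_fold, pooled = pooled, predictions = preds,
                 classes = classes),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report: %d predictions, pooled accuracy %.3f, ROC-AUC %s, PR-AUC %s, F1 %.3f>\n",
              x$pooled$n, x$pooled$accuracy,
              formatC(x$pooled$roc_auc, digits = 3, format = "f"),
              formatC(x$pooled$pr_auc, digits = 3, format = "f"),
              x$pooled$f1_macro))
  invisible(x)
}
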