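# ---------------------------------------------------------------------------
# Grad-CAM hotspot tracing
# ---------------------------------------------------------------------------
# For a trained classifier, channel weights are the spatial means of the
# gradient of the target-class score at a chosen convolutional layer; the
# heatmap is the ReLU of the weighted channel sum, min-max normalized and
# bilinearly upsampled to the input size.  The gradient source is the
# pre-softmax class logit by default, with a loss-gradient mode as an
# alternative; the tap point defaults to the last convolutional layer, with
# the first one available as an option (the two conventions highlight the
# same structures at different resolutions).

find_conv_layers <- function(net) which(vapply(net, function(l) l$type == "conv", logical(1)))

#' Grad-CAM heatmap for one patch
#'
#' @param model a \code{cnn_model}.
#' @param p a \code{\link{patch}} (or bare H x W x 3 array).
#' @param target_class class name or index whose score is traced.
#' @param target_layer \code{"last_conv"} (default), \code{"first_conv"},
#'   or an integer layer index into the model's layer list; the layer must
#'   produce spatial activations.
#' @param mode \code{"score"} (gradient of the pre-softmax logit, default)
#'   or \code{"loss"} (gradient of the cross-entropy loss).
#' @return object of class \code{heatmap}: list with \code{values} (matrix
#'   in \code{[0, 1]}, same spatial shape as the preprocessed input patch,
#'   upsampled to the patch's own size), \code{target_class},
#'   \code{target_layer}, \code{raw_min}, \code{raw_max}.
#' @export
gradcam <- function(model, p, target_class = NULL,
                    target_layer = c("last_conv", "first_conv"), mode = c("score", "loss")) {
  mode <- match.arg(mode)
  pixels <- if (inherits(p, "patch")) p$pixels else as_rgb_image(p)
  if (is.character(target_layer)) target_layer <- match.arg(target_layer)
  net <- model$net
  convs <- find_conv_layers(net)
  li <- if (identical(target_layer, "last_conv")) convs[length(convs)]
        else if (identical(target_layer, "first_conv")) convs[1L]
        else as.integer(target_layer)
  if (!length(li) || is.na(li) || li < 1L || li > length(net))
    stop("layer error: no such layer")
  cls <- if (is.null(target_class)) model$classes[1L]
         else if (is.numeric(target_class)) model$classes[target_class]
         else target_class
  k <- match(cls, model$classes)
  if (is.na(k)) stop("class error: unknown class '", target_class, "'")
  x <- preprocess_patch(pixels, model$config$input_size)
  fw <- nn_forward(net, x)
  A <- fw$outputs[[li]]
  if (length(dim(A)) != 3L)
    stop("layer error: layer ", li, " has no spatial activations")
  dlogits <- if (mode == "score") {
    d <- numeric(length(model$classes)); d[k] <- 1; d
  } else softmax_xent_vec(fw$out, k)$dlogits
  bw <- nn_backward(net, fw$caches, dlogits)
  dA <- bw$d_outputs[[li]]
  wts <- colMeans(matrix(dA, prod(dim(A)[1:2]), dim(A)[3L]))
  raw <- matrix(matrix(A, prod(dim(A)[1:2]), dim(A)[3L]) %*% wts,
                dim(A)[1L], dim(A)[2L])
  raw <- pmax(raw, 0)
  rmin <- min(raw); rmax <- max(raw)
  vals <- if (rmax - rmin < 1e-12) matrix(0, nrow(raw), ncol(raw))
          else (raw - rmin) / (rmax - rmin)
  vals <- resize_bilinear(vals, dim(pixels)[1L], dim(pixels)[2L])
  vals <- pmin(pmax(vals, 0), 1)
  structure(list(values = vals, target_class = cls, target_layer = li,
                 raw_min = rmin, raw_max = rmax),
            class = "heatmap")
}

#' @export
print.heatmap <- function(x, ...) {
  cat(sprintf("<heatmap %dx%d for class '%s' at layer %d, raw range [%.3g, %.3g]>\n",
              nrow(x$values), ncol(x$values), x$target_class, x$target_layer,
              x$raw_min, x$raw_max))
  invisible(x)
}

#' Blue-to-red colormap of a heat value matrix
#'
#' Heat 0 maps to pure blue, heat 1 to pure red (the convention: red =
#' important for the classification, blue = unimportant).
#'
#' @param v matrix with values in \code{[0, 1]}.
#' @return H x W x 3 array, 0-255.
#' @export
heat_colormap <- function(v) {
  out <- array(0, c(nrow(v), ncol(v), 3L))
  out[, , 1L] <- 255 * v
  out[, , 3L] <- 255 * (1 - v)
  out
}

#' Overlay a heatmap on a patch
#'
#' Alpha-blends the blue-to-red colormap over the patch:
#' \code{out = (1 - alpha) * patch + alpha * colormap(heat)}.
#'
#' @param p a \code{\link{patch}} or H x W x 3 array.
#' @param hm a \code{heatmap}.
#' @param alpha blend weight in \code{[0, 1]} (default 0.4).
#' @return H x W x 3 array, 0-255.
#' @export
overlay_heatmap <- function(p, hm, alpha = 0.4) {
  pixels <- if (inherits(p, "patch")) p$pixels else as_rgb_image(p)
  if (!all(dim(hm$values) == dim(pixels)[1:2]))
    stop("shape mismatch between heatmap and patch")
  (1 - alpha) * pixels + alpha * heat_colormap(hm$values)
}

#' Inside/outside-mask heat summary over a set of patches
#'
#' @param heatmaps list of \code{heatmap} objects.
#' @param masks list of 0/1 mask matrices (same spatial shapes).
#' @return list with \code{table} (per patch: mean heat inside and outside
#'   the mask, their ratio, and a \code{flagged} column for empty masks or
#'   zero outside-heat) and \code{cohort_mean_ratio} (mean of the finite,
#'   unflagged ratios).
#' @export
hotspot_summary <- function(heatmaps, masks) {
  stopifnot(length(heatmaps) == length(masks))
  rows <- lapply(seq_along(heatmaps), function(i) {
    v <- heatmaps[[i]]$values
    m <- masks[[i]] > 0
    if (!any(m))
      return(data.frame(patch = i, inside = NA_real_, outside = NA_real_,
                        ratio = NA_real_, flagged = TRUE))
    inside <- mean(v[m])
    outside <- if (all(m)) NA_real_ else mean(v[!m])
    ratio <- if (is.na(outside)) NA_real_
             else if (outside == 0) Inf else inside / outside
    data.frame(patch = i, inside = inside, outside = outside, ratio = ratio,
               flagged = !is.finite(ratio))
  })
  tab <- do.call(rbind, rows)
  ok <- !tab$flagged & is.finite(tab$ratio)
  list(table = tab,
       cohort_mean_ratio = if (any(ok)) mean(tab$ratio[ok]) else NA_real_)
}
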