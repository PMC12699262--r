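# ---------------------------------------------------------------------------
# Unsupervised epidermis extraction
# ---------------------------------------------------------------------------
# Three stages: (1) Felzenszwalb superpixels group visually similar pixels;
# (2) a small per-image CNN (conv/ReLU/instance-norm blocks ending in a 1x1
# convolution + softmax) is trained against its own superpixel-majority-
# refined argmax labels, iteratively sharpening a per-pixel clustering;
# (3) the cluster picked as epidermis is cleaned up morphologically and
# gated by a diagonal-span filter that discards masks dominated by hair
# follicles / glands / vessels (which do not traverse the image diagonal).

#' Configuration for the unsupervised epidermis segmentation
#'
#' @param felzenszwalb_scale merge-threshold scale of the superpixel stage
#'   (larger = fewer, larger superpixels; intensities are on the 0-255
#'   scale).
#' @param felzenszwalb_sigma Gaussian pre-smoothing sigma in pixels.
#' @param felzenszwalb_min_size minimum superpixel area in pixels.
#' @param n_channels CNN feature channels (also the number of candidate
#'   cluster classes of the 1x1 head).
#' @param n_conv_blocks number of conv/ReLU/norm blocks.
#' @param max_iterations iteration cap for the self-training loop.
#' @param min_clusters stop once the number of distinct predicted labels
#'   drops to this value (3 = corneum / epidermis / dermis).
#' @param learning_rate SGD learning rate of the self-training loop.
#' @param momentum SGD momentum of the self-training loop.
#' @param seed RNG seed controlling the CNN initialization.
#' @return object of class \code{seg_config}.
#' @export
seg_config <- function(felzenszwalb_scale = 300, felzenszwalb_sigma = 0.8,
                       felzenszwalb_min_size = 64L, n_channels = 100L,
                       n_conv_blocks = 3L, max_iterations = 100L,
                       min_clusters = 3L, learning_rate = 0.1, momentum = 0.9,
                       seed = 1L) {
  stopifnot(n_channels >= 1L, n_conv_blocks >= 1L, max_iterations >= 1L,
            min_clusters >= 1L)
  structure(list(felzenszwalb_scale = felzenszwalb_scale,
                 felzenszwalb_sigma = felzenszwalb_sigma,
                 felzenszwalb_min_size = as.integer(felzenszwalb_min_size),
                 n_channels = as.integer(n_channels),
                 n_conv_blocks = as.integer(n_conv_blocks),
                 max_iterations = as.integer(max_iterations),
                 min_clusters = as.integer(min_clusters),
                 learning_rate = learning_rate, momentum = momentum,
                 seed = as.integer(seed)),
            class = "seg_config")
}

#' Felzenszwalb superpixels
#'
#' Graph-based segmentation on the (optionally Gaussian-smoothed) RGB image.
#' Labels are contiguous integers starting at 0.
#'
#' @param image H x W x 3 array, 0-255.
#' @param config a \code{\link{seg_config}}.
#' @return object of class \code{superpixel_map}: list with \code{labels}
#'   (integer matrix, 0-based) and \code{n_segments}.
#' @export
compute_superpixels <- function(image, config = seg_config()) {
  img <- gaussian_blur(image, config$felzenszwalb_sigma)
  labels <- .felzenszwalb_cpp(img[, , 1L], img[, , 2L], img[, , 3L],
                              config$felzenszwalb_scale,
                              config$felzenszwalb_min_size)
  structure(list(labels = labels, n_segments = attr(labels, "n_segments")),
            class = "superpixel_map")
}

#' @export
print.superpixel_map <- function(x, ...) {
  cat(sprintf("<superpixel_map: %d segments over %d x %d>\n",
              x$n_segments, nrow(x$labels), ncol(x$labels)))
  invisible(x)
}

# Majority label within each superpixel (ties -> smallest label id).
superpixel_majority <- function(labels_vec, sp_vec, n_sp, K) {
  idx <- (labels_vec - 1L) * n_sp + sp_vec
  cnt <- matrix(tabulate(idx, nbins = n_sp * K), n_sp, K)
  max.col(cnt, ties.method = "first")
}

#' Iterative superpixel-guided unsupervised segmentation
#'
#' Trains a small CNN on the image itself: each iteration the per-pixel
#' argmax labels are refined by majority vote within each superpixel, and
#' the cross-entropy between the CNN scores and the refined labels is
#' backpropagated (plain SGD). The loop stops when the number of distinct
#' labels reaches \code{config$min_clusters} or at
#' \code{config$max_iterations}.
#'
#' @param image H x W x 3 array, 0-255.
#' @param superpixels a \code{\link{compute_superpixels}} result.
#' @param config a \code{\link{seg_config}}.
#' @return integer matrix of cluster labels (1-based, superpixel-refined),
#'   with attributes \code{iterations} and \code{n_clusters}.
#' @export
iterative_unsupervised_segment <- function(image, superpixels, config = seg_config()) {
  stopifnot(inherits(superpixels, "superpixel_map"))
  if (!all(dim(superpixels$labels) == dim(image)[1:2]))
    stop("superpixels must partition the image (shape mismatch)")
  # standardize channels so stain contrast, not absolute intensity, drives
  # the features
  x <- image / 255
  for (k in 1:3) {
    mu <- mean(x[, , k]); sdv <- stats::sd(x[, , k])
    x[, , k] <- (x[, , k] - mu) / max(sdv, 1e-6)
  }
  K <- config$n_channels
  sp1 <- as.integer(superpixels$labels) + 1L
  n_sp <- superpixels$n_segments
  refined_raster <- NULL
  with_seed(config$seed, {
    net <- list()
    in_ch <- 3L
    for (b in seq_len(config$n_conv_blocks)) {
      net <- c(net, list(nn_init_conv(in_ch, K, 3L), nn_relu(), nn_init_bn(K)))
      in_ch <- K
    }
    # trailing normalization keeps the K class logits comparable and stops
    # the clustering from collapsing into one class in the first iterations
    net <- c(net, list(nn_init_conv1x1(K, K), nn_init_bn(K)))
    iterations <- 0L
    velocity <- NULL
    for (it in seq_len(config$max_iterations)) {
      iterations <- it
      fw <- nn_forward(net, x)
      logits <- fw$out
      lab <- max.col(matrix(logits, length(sp1), K), ties.method = "first")
      refined <- superpixel_majority(lab, sp1, n_sp, K)[sp1]
      n_distinct <- length(unique(refined))
      refined_raster <- matrix(as.integer(refined), nrow(superpixels$labels),
                               ncol(superpixels$labels))
      if (n_distinct <= config$min_clusters) break
      ce <- softmax_xent_raster(logits, refined)
      bw <- nn_backward(net, fw$caches, ce$dlogits)
      velocity <- if (is.null(velocity)) bw$grads
                  else add_grads(scale_grads(velocity, config$momentum), bw$grads)
      net <- nn_sgd_step(net, velocity, config$learning_rate)
    }
    attr(refined_raster, "iterations") <- iterations
  })
  n_final <- length(unique(as.integer(refined_raster)))
  attr(refined_raster, "n_clusters") <- n_final
  if (n_final == 1L)
    warning("segmentation collapsed to a single cluster")
  refined_raster
}

#' Pick the epidermis cluster among unsupervised clusters
#'
#' The identification rule is this package's own heuristic (the clustering
#' itself is unsupervised and does not name its clusters): each cluster is
#' scored by mean hematoxylin-like optical density times the elongation of
#' its largest connected component — the epidermis is the nucleus-dense,
#' band-shaped cluster. Ties break toward the smaller cluster id, and an
#' explicit \code{cluster_id} overrides the heuristic entirely.
#'
#' @param labels integer cluster raster from
#'   \code{\link{iterative_unsupervised_segment}}.
#' @param image the RGB image the labels came from.
#' @param cluster_id optional explicit cluster id to select.
#' @param min_cluster_frac clusters covering less than this fraction of the
#'   image are ineligible for the heuristic (thin slivers can otherwise win
#'   on elongation alone); ignored when every cluster is below it.
#' @return object of class \code{epidermis_mask_result} with fields
#'   \code{mask}, \code{cluster_id}, \code{accepted} (NA until the diagonal
#'   filter runs) and \code{level1_image} (NULL until extraction).
#' @export
select_epidermis_cluster <- function(labels, image, cluster_id = NULL,
                                     min_cluster_frac = 0.02) {
  ids <- sort(unique(as.integer(labels)))
  if (length(ids) < 2L && is.null(cluster_id))
    stop("no epidermis cluster: segmentation produced a single cluster")
  if (!is.null(cluster_id)) {
    if (!cluster_id %in% ids) stop("cluster_id ", cluster_id, " not present")
    best <- cluster_id
  } else {
    sizes <- vapply(ids, function(id) sum(labels == id), numeric(1))
    eligible <- sizes >= min_cluster_frac * length(labels)
    if (any(eligible)) ids <- ids[eligible]
    scores <- vapply(ids, function(id) {
      m <- labels == id
      od <- mean_hematoxylin_od(image, m)
      comp <- EBImage::bwlabel(matrix(as.integer(m), nrow(labels), ncol(labels)))
      sizes <- tabulate(comp[comp > 0])
      big <- which.max(sizes)
      el <- coords_elongation(which(comp == big, arr.ind = TRUE))
      od * el
    }, numeric(1))
    best <- ids[which.max(scores)]   # which.max -> first max -> lowest id wins ties
  }
  structure(list(mask = matrix(as.integer(labels == best), nrow(labels), ncol(labels)),
                 cluster_id = best, accepted = NA, level1_image = NULL),
            class = "epidermis_mask_result")
}

#' @export
print.epidermis_mask_result <- function(x, ...) {
  cat(sprintf("<epidermis_mask_result: cluster %s, %d px, accepted=%s>\n",
              x$cluster_id, sum(x$mask), x$accepted))
  invisible(x)
}

#' Diagonal-span filter
#'
#' Accepts a mask iff one of its connected components touches both corner
#' regions (squares of side \code{tolerance_frac * min(H, W)}) at the two
#' ends of either image diagonal. Masks that fail are the follicle/gland/
#' vessel-dominated cases the extraction pipeline discards.
#'
#' @param mask 0/1 matrix.
#' @param tolerance_frac corner-region side as a fraction of the short image
#'   side (default 0.15).
#' @return logical scalar.
#' @export
diagonal_span_filter <- function(mask, tolerance_frac = 0.15) {
  h <- nrow(mask); w <- ncol(mask)
  s <- max(1L, round(tolerance_frac * min(h, w)))
  comp <- label_components8(mask)
  if (max(comp) == 0L) return(FALSE)
  corner_ids <- function(rows, cols) setdiff(unique(as.integer(comp[rows, cols])), 0L)
  tl <- corner_ids(1:s, 1:s)
  br <- corner_ids((h - s + 1L):h, (w - s + 1L):w)
  tr <- corner_ids(1:s, (w - s + 1L):w)
  bl <- corner_ids((h - s + 1L):h, 1:s)
  length(intersect(tl, br)) > 0L || length(intersect(tr, bl)) > 0L
}

#' Morphological cleanup of a segmentation mask
#'
#' Erosion-then-dilation (opening) with a disc kernel, followed by removal
#' of small connected components — the "corrosion-expansion" cleanup that
#' eliminates specks and thin flaws.
#'
#' @param mask 0/1 matrix.
#' @param kernel_radius disc radius in pixels (default 3).
#' @param min_area connected components smaller than this (pixels) are
#'   dropped (default 256).
#' @return cleaned 0/1 matrix; if everything vanished, the empty mask is
#'   returned with a warning.
#' @export
refine_mask <- function(mask, kernel_radius = 3L, min_area = 256L) {
  m <- matrix(as.integer(mask > 0), nrow(mask), ncol(mask))
  if (sum(m) == 0L) {
    warning("refine_mask: empty input mask")
    return(m)
  }
  kern <- EBImage::makeBrush(2L * kernel_radius + 1L, shape = "disc")
  op <- EBImage::dilate(EBImage::erode(m, kern), kern)
  comp <- EBImage::bwlabel(op)
  if (max(comp) > 0L) {
    sizes <- tabulate(comp[comp > 0L])
    drop <- which(sizes < min_area)
    if (length(drop)) op[comp %in% drop] <- 0L
  }
  out <- matrix(as.integer(op > 0), nrow(mask), ncol(mask))
  if (sum(out) == 0L) warning("refine_mask: mask vanished after cleanup")
  out
}

# Angle (degrees) of the image main diagonal measured like
# mask_principal_angle (from the col-axis, positive toward increasing row).
diagonal_angle <- function(h, w) atan2(h, w) * 180 / pi

#' Extract the level-1 image (epidermis-oriented crop)
#'
#' Runs the diagonal-span filter; on acceptance, optionally rotates image
#' and mask so the mask's principal axis aligns with the image diagonal
#' (applied when the deviation exceeds \code{rotate_threshold_deg}), then
#' crops to the mask bounding box padded by \code{margin}.
#'
#' @param image H x W x 3 array.
#' @param mask refined 0/1 mask.
#' @param tolerance_frac corner tolerance of the diagonal-span filter.
#' @param rotate_to_diagonal logical; enable the alignment rotation.
#' @param rotate_threshold_deg principal-axis deviation (degrees) above
#'   which rotation is applied (default 20).
#' @param margin bounding-box padding in pixels.
#' @param cluster_id carried through into the result.
#' @return an \code{epidermis_mask_result}; \code{accepted = FALSE} results
#'   carry no level-1 image (this is not an error).
#' @export
extract_level1 <- function(image, mask, tolerance_frac = 0.15,
                           rotate_to_diagonal = TRUE, rotate_threshold_deg = 20,
                           margin = 16L, cluster_id = NA_integer_) {
  if (sum(mask > 0) == 0L)
    return(structure(list(mask = mask, cluster_id = cluster_id,
                          accepted = FALSE, level1_image = NULL,
                          rotation_deg = 0),
                     class = "epidermis_mask_result"))
  rot <- 0
  if (rotate_to_diagonal) {
    cen <- colMeans(which(mask > 0, arr.ind = TRUE))
    ang <- mask_principal_angle(mask)
    d <- diagonal_angle(nrow(mask), ncol(mask))
    dev_main <- abs(ang - d); dev_anti <- abs(ang + d)
    if (min(dev_main, dev_anti) > rotate_threshold_deg) {
      target <- if (dev_main <= dev_anti) d else -d
      rot <- ang - target   # rotate content so principal axis lands on target
    }
    # recenter the mask centroid (and rotate if needed) so the diagonal-span
    # criterion judges the mask's shape, not its position in the frame
    image <- rotate_raster(image, rot, mask = FALSE, center_from = cen)
    mask <- rotate_raster(mask, rot, mask = TRUE, center_from = cen)
  }
  accepted <- diagonal_span_filter(mask, tolerance_frac)
  if (!accepted)
    return(structure(list(mask = mask, cluster_id = cluster_id,
                          accepted = FALSE, level1_image = NULL,
                          rotation_deg = rot),
                     class = "epidermis_mask_result"))
  idx <- which(mask > 0, arr.ind = TRUE)
  r0 <- max(1L, min(idx[, 1L]) - margin); r1 <- min(nrow(mask), max(idx[, 1L]) + margin)
  c0 <- max(1L, min(idx[, 2L]) - margin); c1 <- min(ncol(mask), max(idx[, 2L]) + margin)
  structure(list(mask = mask[r0:r1, c0:c1],
                 cluster_id = cluster_id, accepted = TRUE,
                 level1_image = image[r0:r1, c0:c1, , drop = FALSE],
                 rotation_deg = rot, bbox = c(r0, r1, c0, c1)),
            class = "epidermis_mask_result")
}

#' End-to-end epidermis segmentation
#'
#' Convenience wrapper: superpixels, iterative CNN clustering, epidermis
#' cluster selection, morphological refinement, and level-1 extraction.
#'
#' @param image H x W x 3 array, 0-255.
#' @param config a \code{\link{seg_config}}.
#' @param min_area small-component threshold of \code{\link{refine_mask}}.
#' @param ... passed to \code{\link{extract_level1}}.
#' @return an \code{epidermis_mask_result} with an \code{iterations}
#'   attribute.
#' @export
segment_epidermis <- function(image, config = seg_config(), min_area = 256L, ...) {
  sp <- compute_superpixels(image, config)
  labels <- iterative_unsupervised_segment(image, sp, config)
  sel <- select_epidermis_cluster(labels, image)
  refined <- refine_mask(sel$mask, min_area = min_area)
  res <- extract_level1(image, refined, cluster_id = sel$cluster_id, ...)
  attr(res, "iterations") <- attr(labels, "iterations")
  res
}
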