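# ---------------------------------------------------------------------------
# Epidermis-guided hierarchical patch sampling
# ---------------------------------------------------------------------------
# Level-2 patches (512 x 512 by default) are cropped with centers placed at
# uniform arc-length steps along the skeleton path of the epidermis mask of
# a level-1 image.  Level-3 patches (128 x 128) are cropped inside a level-2
# patch with centers along the EB-side boundary of the mask — the side
# adjoining the dermis, i.e. the basement-membrane zone the framework is
# built around.  Crops are half-open [r0, r0 + size) x [c0, c0 + size) in
# 0-based terms; centers too near a border are shifted inward to the nearest
# valid position and de-duplicated.

#' Patch-sampler configuration
#'
#' @param level2_size,level3_size patch edge lengths in pixels (512 / 128).
#' @param stride2,stride3 arc-length spacing of patch centers in pixels;
#'   defaults equal the patch sizes (non-overlapping).
#' @param bmz_filter_on apply \code{\link{bmz_inclusion_filter}} before
#'   level-3 sampling.
#' @param diag_angle_tol_deg tolerance (degrees) on the mask principal axis
#'   vs the patch diagonal in the inclusion filter.
#' @param min_mask_frac minimum (and 1 - maximum) epidermis fraction of an
#'   included level-2 patch.
#' @return object of class \code{sampler_config}.
#' @export
sampler_config <- function(level2_size = 512L, level3_size = 128L,
                           stride2 = level2_size, stride3 = level3_size,
                           bmz_filter_on = TRUE, diag_angle_tol_deg = 25,
                           min_mask_frac = 0.1) {
  stopifnot(stride2 >= 1L, stride3 >= 1L, level2_size >= 2L, level3_size >= 2L)
  structure(list(level2_size = as.integer(level2_size),
                 level3_size = as.integer(level3_size),
                 stride2 = as.integer(stride2), stride3 = as.integer(stride3),
                 bmz_filter_on = isTRUE(bmz_filter_on),
                 diag_angle_tol_deg = diag_angle_tol_deg,
                 min_mask_frac = min_mask_frac),
            class = "sampler_config")
}

#' A sampled patch
#'
#' @param pixels s x s x 3 crop.
#' @param mask_crop s x s 0/1 mask crop.
#' @param level 2 or 3.
#' @param center (row, col) center in parent coordinates (1-based).
#' @param patch_id,parent_id,wsi_id provenance identifiers.
#' @return object of class \code{patch}.
#' @export
patch <- function(pixels, mask_crop, level, center, patch_id, parent_id, wsi_id) {
  stopifnot(level %in% c(2L, 3L),
            dim(pixels)[1L] == dim(pixels)[2L],
            all(dim(mask_crop) == dim(pixels)[1:2]))
  structure(list(pixels = pixels, mask_crop = mask_crop, level = as.integer(level),
                 center = as.numeric(center), patch_id = patch_id,
                 parent_id = parent_id, wsi_id = wsi_id),
            class = "patch")
}

#' @export
print.patch <- function(x, ...) {
  cat(sprintf("<patch %s: level %d, %dx%d at (%g, %g), parent %s>\n",
              x$patch_id, x$level, dim(x$pixels)[1L], dim(x$pixels)[2L],
              x$center[1L], x$center[2L], x$parent_id))
  invisible(x)
}

# Pick centers at uniform arc-length spacing along an ordered path, shift
# them inward so the full crop fits, snap off-mask centers to the nearest
# valid mask pixel, and de-duplicate while preserving order.
centers_along_path <- function(path, mask, size, stride) {
  h <- nrow(mask); w <- ncol(mask)
  if (h < size || w < size)
    stop("image (", h, "x", w, ") smaller than the patch size ", size)
  if (nrow(path) == 0L) return(matrix(numeric(0), 0L, 2L))
  half <- size %/% 2L
  if (nrow(path) == 1L) {
    cand <- path
  } else {
    seg <- sqrt(diff(path[, 1L])^2 + diff(path[, 2L])^2)
    s <- c(0, cumsum(seg))
    total <- s[length(s)]
    at <- if (total < stride) total / 2 else seq(0, total, by = stride)
    idx <- vapply(at, function(a) which.min(abs(s - a)), integer(1))
    cand <- path[idx, , drop = FALSE]
  }
  cand <- round(cand)
  # inward shift: r0 in [1, h - size + 1], center = r0 + half
  r0 <- pmin(pmax(cand[, 1L] - half, 1L), h - size + 1L)
  c0 <- pmin(pmax(cand[, 2L] - half, 1L), w - size + 1L)
  ctr <- cbind(r0 + half, c0 + half)
  # snap centers that left the mask back to the nearest valid mask pixel
  valid <- which(mask > 0, arr.ind = TRUE)
  valid <- valid[valid[, 1L] >= 1L + half & valid[, 1L] <= h - size + 1L + half &
                 valid[, 2L] >= 1L + half & valid[, 2L] <= w - size + 1L + half, ,
                 drop = FALSE]
  for (i in seq_len(nrow(ctr))) {
    if (mask[ctr[i, 1L], ctr[i, 2L]] == 0) {
      if (nrow(valid) == 0L) next
      d2 <- (valid[, 1L] - ctr[i, 1L])^2 + (valid[, 2L] - ctr[i, 2L])^2
      ctr[i, ] <- valid[which.min(d2), ]
    }
  }
  ctr[!duplicated(ctr), , drop = FALSE]
}

crop_at <- function(image, mask, center, size) {
  half <- size %/% 2L
  r0 <- center[1L] - half; c0 <- center[2L] - half
  list(pixels = image[r0:(r0 + size - 1L), c0:(c0 + size - 1L), , drop = FALSE],
       mask = mask[r0:(r0 + size - 1L), c0:(c0 + size - 1L)])
}

#' Sample level-2 patches along the epidermis mask
#'
#' @param level1 level-1 RGB image (H x W x 3).
#' @param mask refined epidermis 0/1 mask of the same shape.
#' @param config a \code{\link{sampler_config}}.
#' @param wsi_id,parent_id provenance identifiers.
#' @return list of level-2 \code{\link{patch}} objects (possibly empty).
#' @export
sample_level2 <- function(level1, mask, config = sampler_config(),
                          wsi_id = "wsi", parent_id = "level1") {
  path <- trace_mask_path(mask)
  if (nrow(path) == 0L) return(list())
  ctr <- centers_along_path(path, mask, config$level2_size, config$stride2)
  lapply(seq_len(nrow(ctr)), function(i) {
    cr <- crop_at(level1, mask, ctr[i, ], config$level2_size)
    patch(cr$pixels, cr$mask, 2L, ctr[i, ],
          patch_id = sprintf("%s_L2_%03d", wsi_id, i),
          parent_id = parent_id, wsi_id = wsi_id)
  })
}

#' Basement-membrane-zone inclusion filter for level-2 patches
#'
#' A patch is kept iff (a) its epidermis mask fraction lies in
#' \code{[min_mask_frac, 1 - min_mask_frac]} — both epidermis and
#' non-epidermis tissue are present — and (b) the mask's principal axis is
#' within \code{diag_angle_tol_deg} of either patch diagonal.
#'
#' @param p a level-2 \code{\link{patch}}.
#' @param config a \code{\link{sampler_config}}.
#' @return logical scalar.
#' @export
bmz_inclusion_filter <- function(p, config = sampler_config()) {
  f <- mean(p$mask_crop > 0)
  if (f < config$min_mask_frac || f > 1 - config$min_mask_frac) return(FALSE)
  ang <- mask_principal_angle(p$mask_crop)
  if (is.na(ang)) return(FALSE)
  d <- diagonal_angle(nrow(p$mask_crop), ncol(p$mask_crop))
  min(abs(ang - d), abs(ang + d)) <= config$diag_angle_tol_deg
}

#' Sample level-3 patches inside a level-2 patch
#'
#' Centers are placed along the EB-side boundary of the mask crop (the
#' boundary adjoining the dermis — the basement-membrane zone), at
#' \code{stride3} arc-length spacing; every crop lies fully inside the
#' parent patch. If the two-sided boundary cannot be extracted the skeleton
#' path is used as a fallback sampling path.
#'
#' @param p a level-2 \code{\link{patch}}.
#' @param config a \code{\link{sampler_config}}.
#' @param strict if TRUE, a parent failing the mask-fraction precondition
#'   yields an empty list with a warning.
#' @return list of level-3 \code{\link{patch}} objects.
#' @export
sample_level3 <- function(p, config = sampler_config(), strict = FALSE) {
  stopifnot(inherits(p, "patch"))
  if (strict) {
    f <- mean(p$mask_crop > 0)
    if (f < config$min_mask_frac || f > 1 - config$min_mask_frac) {
      warning("parent patch fails the mask-fraction precondition; no level-3 patches")
      return(list())
    }
  }
  path <- tryCatch({
    b <- extract_boundaries(p$mask_crop, p$pixels)
    b$eb$points
  }, error = function(e) trace_mask_path(p$mask_crop))
  if (nrow(path) == 0L) return(list())
  ctr <- centers_along_path(path, p$mask_crop, config$level3_size, config$stride3)
  lapply(seq_len(nrow(ctr)), function(i) {
    cr <- crop_at(p$pixels, p$mask_crop, ctr[i, ], config$level3_size)
    patch(cr$pixels, cr$mask, 3L, ctr[i, ],
          patch_id = sprintf("%s_L3_%03d", p$patch_id, i),
          parent_id = p$patch_id, wsi_id = p$wsi_id)
  })
}
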