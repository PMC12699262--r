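#' @useDynLib episcope, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats var sd quantile median rnorm runif predict setNames
#' @importFrom utils head tail
NULL

# ---------------------------------------------------------------------------
# Raster conventions used throughout the package
# ---------------------------------------------------------------------------
# * An RGB image is a plain H x W x 3 double array with intensities in
#   [0, 255].  Row 1 is the top of the image; coordinates are (row, col),
#   1-based in R code, and crops are half-open in the 0-based sense used by
#   the patch sampler (documented there).
# * A mask is an H x W integer/logical matrix with values 0/1.
# These are deliberately plain base-R objects (as EBImage does with its
# array-backed Image class) so that all of base R's array tooling applies.

#' Coerce to the package's RGB image convention
#'
#' Accepts an H x W x 3 array scaled either to \code{[0, 1]} (as returned by
#' \code{png::readPNG}) or \code{[0, 255]}, or an H x W grayscale matrix
#' (replicated over channels), and returns an H x W x 3 double array in
#' \code{[0, 255]}.
#'
#' @param x array or matrix as described above.
#' @return H x W x 3 double array with values in \code{[0, 255]}.
#' @export
as_rgb_image <- function(x) {
  if (is.matrix(x)) x <- array(rep(x, 3L), dim = c(dim(x), 3L))
  if (length(dim(x)) != 3L || dim(x)[3L] < 3L)
    stop("expected an H x W x 3 array or an H x W matrix")
  x <- x[, , 1:3, drop = FALSE]
  storage.mode(x) <- "double"
  if (max(x, na.rm = TRUE) <= 1 + 1e-8) x <- x * 255
  pmin(pmax(x, 0), 255)
}

#' Coerce to a binary mask matrix
#'
#' @param x numeric/logical matrix; any value > 0 counts as foreground.
#' @return integer 0/1 matrix of the same shape.
#' @export
as_mask_image <- function(x) {
  if (length(dim(x)) == 3L) x <- x[, , 1L]
  if (!is.matrix(x)) stop("expected an H x W matrix")
  m <- matrix(as.integer(x > 0), nrow(x), ncol(x))
  m
}

#' Read an RGB image or a binary mask from a PNG file
#'
#' @param path PNG file path.
#' @return For \code{read_image_png} an H x W x 3 array in \code{[0, 255]};
#'   for \code{read_mask_png} an integer 0/1 matrix.
#' @export
read_image_png <- function(path) as_rgb_image(png::readPNG(path))

#' @rdname read_image_png
#' @export
read_mask_png <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 3L) x <- x[, , 1L]
  as_mask_image(x > 0.5)
}

#' Write an RGB image or a binary mask to a PNG file
#'
#' @param x image array (\code{[0, 255]}) or 0/1 mask matrix.
#' @param path output PNG path.
#' @return \code{path}, invisibly.
#' @export
write_image_png <- function(x, path) {
  png::writePNG(pmin(pmax(x / 255, 0), 1), target = path)
  invisible(path)
}

#' @rdname write_image_png
#' @export
write_mask_png <- function(x, path) {
  png::writePNG(matrix(as.numeric(x > 0), nrow(x), ncol(x)), target = path)
  invisible(path)
}

#' Convert an RGB image to grayscale luminance
#'
#' Uses the fixed luminance weights 0.299 R + 0.587 G + 0.114 B so that
#' every downstream consumer (radiomics, CNN preprocessing) sees an
#' identical, reproducible channel reduction.
#'
#' @param img H x W x 3 array in \code{[0, 255]}.
#' @return H x W matrix in \code{[0, 255]}.
#' @export
rgb_to_gray <- function(img) {
  0.299 * img[, , 1L] + 0.587 * img[, , 2L] + 0.114 * img[, , 3L]
}

# Reflect an index vector into [1, n] (mirror boundary, period 2n-2).
reflect_index <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  p <- 2L * n - 2L
  i <- (i - 1L) %% p
  i <- ifelse(i < 0, i + p, i)
  as.integer(ifelse(i >= n, p - i, i) + 1L)
}

#' Bilinear resize of a matrix or RGB image
#'
#' @param x H x W matrix or H x W x 3 array.
#' @param out_h,out_w output dimensions in pixels.
#' @return resized matrix/array of the same kind.
#' @export
resize_bilinear <- function(x, out_h, out_w) {
  is_arr <- length(dim(x)) == 3L
  h <- dim(x)[1L]; w <- dim(x)[2L]
  # map output pixel centers into input coordinates (align centers)
  rr <- if (out_h == 1L) rep((h + 1) / 2, 1L) else (seq_len(out_h) - 0.5) * h / out_h + 0.5
  cc <- if (out_w == 1L) rep((w + 1) / 2, 1L) else (seq_len(out_w) - 0.5) * w / out_w + 0.5
  r0 <- pmin(pmax(floor(rr), 1L), h); r1 <- pmin(r0 + 1L, h); fr <- rr - r0
  c0 <- pmin(pmax(floor(cc), 1L), w); c1 <- pmin(c0 + 1L, w); fc <- cc - c0
  fr <- pmin(pmax(fr, 0), 1); fc <- pmin(pmax(fc, 0), 1)
  interp_plane <- function(m) {
    a <- m[r0, c0, drop = FALSE]; b <- m[r0, c1, drop = FALSE]
    cM <- m[r1, c0, drop = FALSE]; d <- m[r1, c1, drop = FALSE]
    top <- a + sweep(b - a, 2L, fc, `*`)
    bot <- cM + sweep(d - cM, 2L, fc, `*`)
    top + sweep(bot - top, 1L, fr, `*`)
  }
  if (!is_arr) return(interp_plane(x))
  out <- array(0, c(out_h, out_w, dim(x)[3L]))
  for (k in seq_len(dim(x)[3L])) out[, , k] <- interp_plane(x[, , k])
  out
}

# Rotate (row, col) points by angle_deg about a center, in image coordinates
# (row grows downward; positive angle rotates the content counter-clockwise
# on screen, matching rotate_raster below).
rotate_points <- function(pts, angle_deg, center) {
  th <- angle_deg * pi / 180
  dr <- pts[, 1L] - center[1L]; dc <- pts[, 2L] - center[2L]
  cbind(center[1L] + dr * cos(th) - dc * sin(th),
        center[2L] + dr * sin(th) + dc * cos(th))
}

#' Rotate a raster about its center
#'
#' Inverse-mapping rotation with reflective padding. Masks use
#' nearest-neighbour interpolation (binary output preserved); RGB images use
#' bilinear interpolation.
#'
#' @param x H x W matrix (mask) or H x W x 3 array (image).
#' @param angle_deg rotation angle in degrees (counter-clockwise on screen).
#' @param mask logical; force nearest-neighbour (default auto: matrices yes).
#' @param center_from (row, col) pivot in the source raster (default: raster
#'   center).
#' @param center_to (row, col) the pivot maps to in the output (default:
#'   raster center); lets callers recenter content while rotating.
#' @return rotated raster, same dimensions.
#' @export
rotate_raster <- function(x, angle_deg, mask = is.matrix(x),
                          center_from = NULL, center_to = NULL) {
  is_arr <- length(dim(x)) == 3L
  h <- dim(x)[1L]; w <- dim(x)[2L]
  if (is.null(center_to)) center_to <- c((h + 1) / 2, (w + 1) / 2)
  if (is.null(center_from)) center_from <- center_to
  th <- -angle_deg * pi / 180   # inverse map
  g <- expand.grid(r = seq_len(h), c = seq_len(w))
  dr <- g$r - center_to[1L]; dc <- g$c - center_to[2L]
  sr <- center_from[1L] + dr * cos(th) - dc * sin(th)
  sc <- center_from[2L] + dr * sin(th) + dc * cos(th)
  if (mask && !is_arr) {
    ri <- reflect_index(as.integer(round(sr)), h)
    ci <- reflect_index(as.integer(round(sc)), w)
    out <- matrix(x[cbind(ri, ci)], h, w)
    return(out)
  }
  r0 <- floor(sr); c0 <- floor(sc); fr <- sr - r0; fc <- sc - c0
  ra <- reflect_index(as.integer(r0), h); rb <- reflect_index(as.integer(r0) + 1L, h)
  ca <- reflect_index(as.integer(c0), w); cb <- reflect_index(as.integer(c0) + 1L, w)
  interp <- function(m) {
    v <- m[cbind(ra, ca)] * (1 - fr) * (1 - fc) +
      m[cbind(rb, ca)] * fr * (1 - fc) +
      m[cbind(ra, cb)] * (1 - fr) * fc +
      m[cbind(rb, cb)] * fr * fc
    matrix(v, h, w)
  }
  if (!is_arr) return(interp(x))
  out <- array(0, dim(x))
  for (k in seq_len(dim(x)[3L])) out[, , k] <- interp(x[, , k])
  out
}

#' Separable Gaussian blur
#'
#' @param x H x W matrix or H x W x 3 array.
#' @param sigma Gaussian standard deviation in pixels; \code{sigma <= 0}
#'   returns the input unchanged.
#' @return blurred raster of the same shape (reflective boundary).
#' @export
gaussian_blur <- function(x, sigma) {
  if (sigma <= 0) return(x)
  rad <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- exp(-(-rad:rad)^2 / (2 * sigma^2)); k <- k / sum(k)
  blur_plane <- function(m) {
    h <- nrow(m); w <- ncol(m)
    out <- matrix(0, h, w)
    for (o in -rad:rad) out <- out + k[o + rad + 1L] * m[reflect_index(seq_len(h) + o, h), , drop = FALSE]
    m2 <- out; out <- matrix(0, h, w)
    for (o in -rad:rad) out <- out + k[o + rad + 1L] * m2[, reflect_index(seq_len(w) + o, w), drop = FALSE]
    out
  }
  if (is.matrix(x)) return(blur_plane(x))
  out <- array(0, dim(x))
  for (ch in seq_len(dim(x)[3L])) out[, , ch] <- blur_plane(x[, , ch])
  out
}

# Mean hematoxylin-like optical density of an RGB image region: OD of the
# blue-absorbing component, used by cluster selection and boundary-role rules.
mean_hematoxylin_od <- function(img, which_pixels = NULL) {
  od <- -log10((img + 1) / 256)
  # hematoxylin absorbs mostly in red/green channels -> high OD there;
  # a simple proxy: mean OD across channels weighted toward red+blue balance.
  m <- (od[, , 1L] + od[, , 3L]) / 2
  if (is.null(which_pixels)) mean(m) else mean(m[which_pixels])
}

# Principal-axis angle (degrees in [-90, 90), measured from the horizontal
# col-axis, positive toward increasing row) of the foreground of a mask,
# from second-order central moments.
mask_principal_angle <- function(mask) {
  idx <- which(mask > 0, arr.ind = TRUE)
  if (nrow(idx) < 2L) return(NA_real_)
  r <- idx[, 1L] - mean(idx[, 1L]); c <- idx[, 2L] - mean(idx[, 2L])
  mrr <- mean(r * r); mcc <- mean(c * c); mrc <- mean(r * c)
  0.5 * atan2(2 * mrc, mcc - mrr) * 180 / pi
}

# 8-connected component labelling: 4-connected labels (EBImage::bwlabel)
# merged across diagonal adjacencies with a union-find.
label_components8 <- function(m) {
  comp <- EBImage::bwlabel(matrix(as.integer(m > 0), nrow(m), ncol(m)))
  n <- max(comp)
  if (n <= 1L) return(comp)
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  h <- nrow(m); w <- ncol(m)
  for (o in list(c(1L, 1L), c(-1L, 1L))) {
    rs <- max(1L, 1L - o[1L]):min(h, h - o[1L])
    cs <- max(1L, 1L - o[2L]):min(w, w - o[2L])
    a <- comp[rs, cs, drop = FALSE]
    b <- comp[rs + o[1L], cs + o[2L], drop = FALSE]
    touch <- a > 0L & b > 0L & a != b
    if (any(touch)) {
      pairs <- unique(cbind(a[touch], b[touch]))
      for (k in seq_len(nrow(pairs))) {
        ra <- find(pairs[k, 1L]); rb <- find(pairs[k, 2L])
        if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  relab <- match(roots, sort(unique(roots)))
  out <- comp
  out[comp > 0L] <- relab[comp[comp > 0L]]
  out
}

# Elongation (major/minor axis ratio) of a set of pixel coordinates.
coords_elongation <- function(idx) {
  if (nrow(idx) < 3L) return(1)
  r <- idx[, 1L] - mean(idx[, 1L]); c <- idx[, 2L] - mean(idx[, 2L])
  S <- matrix(c(mean(r * r), mean(r * c), mean(r * c), mean(c * c)), 2L)
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  sqrt(max(ev[1L], 1e-12) / max(ev[2L], 1e-12))
}
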