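# ---------------------------------------------------------------------------
# Macenko stain-colour normalization
# ---------------------------------------------------------------------------
# Works in optical density (OD) space, OD = -log10((I + 1) / 256): the +1
# avoids log(0) and 256 plays the role of the white point.  Tissue pixels
# (OD above a transparency threshold in every channel) form a point cloud
# whose principal plane contains the two stain directions; the extreme-angle
# directions within that plane at a small percentile are taken as the
# hematoxylin and eosin vectors.

OD_I0 <- 256

rgb_to_od <- function(img) -log10((img + 1) / OD_I0)
od_to_rgb <- function(od) pmin(pmax(10^(-od) * OD_I0 - 1, 0), 255)

#' Stain model (stain matrix + robust concentration maxima)
#'
#' @param stain_matrix 3 x 2 matrix of unit-norm OD stain vectors, columns
#'   ordered hematoxylin then eosin.
#' @param max_concentrations length-2 positive vector of robust (99th
#'   percentile) per-stain concentration maxima.
#' @return object of class \code{stain_model}.
#' @export
stain_model <- function(stain_matrix, max_concentrations) {
  stain_matrix <- matrix(as.numeric(stain_matrix), 3L, 2L)
  nrm <- sqrt(colSums(stain_matrix^2))
  if (any(nrm <= 0)) stop("stain vectors must be non-zero")
  stain_matrix <- sweep(stain_matrix, 2L, nrm, `/`)
  structure(list(stain_matrix = stain_matrix,
                 max_concentrations = as.numeric(max_concentrations)),
            class = "stain_model")
}

#' @export
print.stain_model <- function(x, ...) {
  cat("<stain_model>\n  H vector:", round(x$stain_matrix[, 1L], 3),
      "\n  E vector:", round(x$stain_matrix[, 2L], 3),
      "\n  max conc:", round(x$max_concentrations, 3), "\n")
  invisible(x)
}

#' Serialize / deserialize a stain model as JSON
#'
#' @param model a \code{stain_model}.
#' @param path file path.
#' @return \code{write_stain_model} returns \code{path} invisibly;
#'   \code{read_stain_model} returns a \code{stain_model}.
#' @export
write_stain_model <- function(model, path) {
  jsonlite::write_json(list(stain_matrix = as.numeric(model$stain_matrix),
                            max_concentrations = model$max_concentrations),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_stain_model
#' @export
read_stain_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  stain_model(matrix(x$stain_matrix, 3L, 2L), x$max_concentrations)
}

# Tissue criterion shared by estimation and normalization: a pixel counts as
# tissue when all three OD channels exceed the transparency threshold.
tissue_pixels <- function(od_flat, od_threshold) {
  rowSums(od_flat > od_threshold) == 3L
}

#' Estimate the two stain vectors of an image (Macenko)
#'
#' @param image H x W x 3 array, intensities 0-255.
#' @param od_threshold transparency threshold in OD units (default 0.15):
#'   pixels below it in any channel are treated as background.
#' @param angle_percentile percentile (default 1) used for the robust
#'   extreme angles; the stain vectors are the directions at the
#'   \code{angle_percentile} and \code{100 - angle_percentile} percentiles
#'   of the projected angle distribution.
#' @param min_tissue_pixels minimum number of tissue pixels required.
#' @return a \code{\link{stain_model}}; columns ordered hematoxylin first
#'   (larger blue-channel OD component).
#' @export
estimate_stains <- function(image, od_threshold = 0.15, angle_percentile = 1,
                            min_tissue_pixels = 100L) {
  od <- rgb_to_od(image)
  od_flat <- cbind(as.numeric(od[, , 1L]), as.numeric(od[, , 2L]), as.numeric(od[, , 3L]))
  keep <- tissue_pixels(od_flat, od_threshold)
  if (sum(keep) < min_tissue_pixels)
    stop("degenerate input: fewer than ", min_tissue_pixels,
         " tissue pixels above the OD threshold")
  X <- od_flat[keep, , drop = FALSE]
  ev <- eigen(stats::cov(X), symmetric = TRUE)
  plane <- ev$vectors[, 1:2, drop = FALSE]
  # orient basis vectors into the positive OD half-space for a stable sign
  for (j in 1:2) if (sum(plane[, j]) < 0) plane[, j] <- -plane[, j]
  proj <- X %*% plane
  phi <- atan2(proj[, 2L], proj[, 1L])
  qs <- stats::quantile(phi, c(angle_percentile, 100 - angle_percentile) / 100,
                        names = FALSE, type = 7)
  if (abs(qs[2L] - qs[1L]) < 1e-4)
    stop("degenerate input: single-stain image (extreme-angle directions collapse)")
  v <- sapply(qs, function(a) plane %*% c(cos(a), sin(a)))
  v <- pmax(v, 0)
  nrm <- sqrt(colSums(v^2))
  if (any(nrm < 1e-8))
    stop("degenerate input: stain direction collapsed to zero after clipping")
  v <- sweep(v, 2L, nrm, `/`)
  # hematoxylin = column with the larger blue OD component
  if (v[3L, 1L] < v[3L, 2L]) v <- v[, 2:1]
  conc <- solve_concentrations(v, X, exact_nnls = FALSE)
  stain_model(v, pmax(apply(conc, 2L, stats::quantile, probs = 0.99, names = FALSE), 1e-6))
}

# Solve OD = M %*% t(C) for per-pixel concentrations C (n x 2).
# Default: unconstrained least squares, negatives clipped at zero.
# exact_nnls: tiny active-set solve, exact for the 2-variable case.
solve_concentrations <- function(stain_matrix, od_flat, exact_nnls = FALSE) {
  M <- stain_matrix
  C <- t(qr.solve(M, t(od_flat)))          # n x 2 least squares
  if (!exact_nnls) return(pmax(C, 0))
  neg1 <- C[, 1L] < 0; neg2 <- C[, 2L] < 0
  # if one coefficient is negative, the NNLS optimum sets it to 0 and
  # projects onto the remaining single stain vector
  if (any(neg1)) C[neg1, 2L] <- pmax(od_flat[neg1, , drop = FALSE] %*% M[, 2L], 0)
  if (any(neg2)) C[neg2, 1L] <- pmax(od_flat[neg2, , drop = FALSE] %*% M[, 1L], 0)
  C[neg1, 1L] <- 0; C[neg2, 2L] <- 0
  C
}

#' Normalize an image's stain colours to a reference stain model
#'
#' Estimates the image's own stain model, solves per-pixel stain
#' concentrations, rescales them by the ratio of reference to source robust
#' maxima, and re-renders through the reference stain matrix. Background
#' pixels (below the OD transparency threshold) pass through unmodified so
#' white regions never acquire a stain tint.
#'
#' @param image H x W x 3 array, 0-255.
#' @param reference a \code{\link{stain_model}} (e.g. from
#'   \code{\link{estimate_stains}} on a reference image).
#' @param od_threshold,angle_percentile passed to \code{estimate_stains}.
#' @param exact_nnls use the exact non-negative solve instead of
#'   clipped least squares.
#' @param source_model optional pre-estimated source \code{stain_model};
#'   skips re-estimation.
#' @return normalized H x W x 3 array, 0-255.
#' @export
normalize_to_reference <- function(image, reference, od_threshold = 0.15,
                                   angle_percentile = 1, exact_nnls = FALSE,
                                   source_model = NULL) {
  if (!inherits(reference, "stain_model")) stop("reference must be a stain_model")
  if (is.null(source_model))
    source_model <- estimate_stains(image, od_threshold, angle_percentile)
  od <- rgb_to_od(image)
  od_flat <- cbind(as.numeric(od[, , 1L]), as.numeric(od[, , 2L]), as.numeric(od[, , 3L]))
  keep <- tissue_pixels(od_flat, od_threshold)
  C <- solve_concentrations(source_model$stain_matrix, od_flat[keep, , drop = FALSE],
                            exact_nnls = exact_nnls)
  src_max <- pmax(apply(C, 2L, stats::quantile, probs = 0.99, names = FALSE), 1e-6)
  C <- sweep(C, 2L, reference$max_concentrations / src_max, `*`)
  od_new <- C %*% t(reference$stain_matrix)
  out_flat <- od_flat
  out_flat[keep, ] <- od_new
  out <- image
  h <- dim(image)[1L]; w <- dim(image)[2L]
  rgb_new <- od_to_rgb(out_flat)
  for (k in 1:3) {
    plane <- image[, , k]
    plane[keep] <- matrix(rgb_new[, k], h, w)[keep]
    out[, , k] <- plane
  }
  out
}
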