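# ---------------------------------------------------------------------------
# Epidermal morphometrics: thickness and rete ridge score
# ---------------------------------------------------------------------------
# Two statistics computed from the two epidermis boundaries:
#   thickness        = mean over points of the epidermis-corneum boundary
#                      (ES) of the shortest distance to the epidermis-dermis
#                      boundary (EB);
#   rete ridge score = population variance over points of EB of the shortest
#                      distance to ES (pixels^2).  A flat junction gives
#                      score 0; pronounced rete ridges give a large score.
# Both are in pixel units; boundaries are resampled at 1-px arc steps so the
# point sets are reproducible.

# Minimum Euclidean distances from points (m x 2) to a polyline (n x 2),
# point-to-segment (not point-to-vertex), computed in chunks.
dist_points_to_polyline <- function(points, poly, chunk = 256L) {
  if (nrow(poly) < 2L) stop("target polyline needs at least 2 points")
  a <- poly[-nrow(poly), , drop = FALSE]
  b <- poly[-1L, , drop = FALSE]
  d <- b - a
  len2 <- pmax(rowSums(d^2), 1e-24)
  m <- nrow(points)
  out <- numeric(m)
  for (s in seq(1L, m, by = chunk)) {
    e <- min(s + chunk - 1L, m)
    pr <- points[s:e, 1L]; pc <- points[s:e, 2L]
    # t = ((p - a) . d) / |d|^2, clamped to [0, 1]
    tr <- outer(pr, a[, 1L], `-`) * matrix(d[, 1L], e - s + 1L, nrow(a), byrow = TRUE)
    tc <- outer(pc, a[, 2L], `-`) * matrix(d[, 2L], e - s + 1L, nrow(a), byrow = TRUE)
    tt <- pmin(pmax((tr + tc) / matrix(len2, e - s + 1L, nrow(a), byrow = TRUE), 0), 1)
    qr_ <- matrix(a[, 1L], e - s + 1L, nrow(a), byrow = TRUE) +
      tt * matrix(d[, 1L], e - s + 1L, nrow(a), byrow = TRUE)
    qc_ <- matrix(a[, 2L], e - s + 1L, nrow(a), byrow = TRUE) +
      tt * matrix(d[, 2L], e - s + 1L, nrow(a), byrow = TRUE)
    dist2 <- (qr_ - pr)^2 + (qc_ - pc)^2
    out[s:e] <- sqrt(apply(dist2, 1L, min))
  }
  out
}

#' Shortest distance from a point to a boundary polyline
#'
#' @param point length-2 numeric (row, col).
#' @param target a \code{\link{boundary_polyline}} or n x 2 matrix.
#' @return minimum Euclidean point-to-segment distance in pixels.
#' @export
shortest_distance <- function(point, target) {
  poly <- if (inherits(target, "boundary_polyline")) target$points else target
  dist_points_to_polyline(matrix(as.numeric(point), 1L, 2L), poly)
}

#' Extract the two epidermis boundaries from a mask
#'
#' Splits the outer contour of the (refined, band-shaped) mask at the two
#' endpoints of its skeleton path, yielding the two long opposite sides.
#' Role assignment: with an image, the side whose 10-px outer band is more
#' hematoxylin-dense (darker-stained exterior = dermis) becomes EB; without
#' an image, the side with greater arc length per unit chord (the more
#' undulating one) becomes EB. Both polylines are resampled at
#' \code{resample_step}-px arc steps.
#'
#' @param mask 0/1 epidermis mask (band topology).
#' @param image optional H x W x 3 image for the stain-based role rule.
#' @param resample_step arc-length resampling step in pixels (default 1).
#' @param outer_band_px depth of the exterior band probed by the stain rule.
#' @return list with elements \code{eb} and \code{es}
#'   (\code{\link{boundary_polyline}} objects).
#' @export
extract_boundaries <- function(mask, image = NULL, resample_step = 1,
                               outer_band_px = 10) {
  path <- trace_mask_path(mask)
  if (nrow(path) < 4L)
    stop("topology error: mask boundary cannot be split into two sides")
  e1 <- path[1L, ]; e2 <- path[nrow(path), ]
  band_width <- sum(mask > 0) / max(polyline_length(path), 1)
  # a band's skeleton endpoints are far apart relative to its area; compact
  # blob-like masks (disk topology) fail this and cannot be split into sides
  if (sqrt(sum((e1 - e2)^2)) < sqrt(sum(mask > 0)))
    stop("topology error: mask boundary cannot be split into two sides")
  contour <- trace_contour(mask)
  if (nrow(contour) < 8L)
    stop("topology error: mask boundary cannot be split into two sides")
  d1 <- rowSums(sweep(contour, 2L, e1)^2)
  d2 <- rowSums(sweep(contour, 2L, e2)^2)
  i1 <- which.min(d1); i2 <- which.min(d2)
  lo <- min(i1, i2); hi <- max(i1, i2)
  side_a <- contour[lo:hi, , drop = FALSE]
  side_b <- rbind(contour[hi:nrow(contour), , drop = FALSE],
                  contour[1:lo, , drop = FALSE])
  # trim the short end caps (the contour stretches crossing the band ends):
  # drop points within half a band width of either skeleton endpoint
  cap_r <- band_width / 2 + 3
  trim <- function(side) {
    d1 <- sqrt(rowSums(sweep(side, 2L, e1)^2))
    d2 <- sqrt(rowSums(sweep(side, 2L, e2)^2))
    keep <- d1 > cap_r & d2 > cap_r
    side[keep, , drop = FALSE]
  }
  side_a <- trim(side_a); side_b <- trim(side_b)
  if (nrow(side_a) < 2L || nrow(side_b) < 2L)
    stop("topology error: mask boundary cannot be split into two sides")
  a_is_eb <- if (!is.null(image)) {
    outer_od(side_a, mask, image, outer_band_px) >
      outer_od(side_b, mask, image, outer_band_px)
  } else {
    undulation(side_a) > undulation(side_b)
  }
  ra <- resample_polyline(side_a, resample_step)
  rb <- resample_polyline(side_b, resample_step)
  if (a_is_eb) list(eb = boundary_polyline(ra, "EB"), es = boundary_polyline(rb, "ES"))
  else list(eb = boundary_polyline(rb, "EB"), es = boundary_polyline(ra, "ES"))
}

# Arc length per unit chord (>= 1; larger = more undulating).
undulation <- function(pts) {
  chord <- sqrt(sum((pts[nrow(pts), ] - pts[1L, ])^2))
  polyline_length(pts) / max(chord, 1e-9)
}

# Mean hematoxylin-like OD just outside the mask along a boundary side:
# samples along the outward normal at offsets 2..depth px.
outer_od <- function(side, mask, image, depth) {
  n <- nrow(side)
  if (n < 3L) return(0)
  sub <- side[seq(1L, n, by = max(1L, n %/% 200L)), , drop = FALSE]
  k <- nrow(sub)
  nxt <- rbind(sub[-1L, , drop = FALSE], sub[k, , drop = FALSE])
  prv <- rbind(sub[1L, , drop = FALSE], sub[-k, , drop = FALSE])
  tg <- nxt - prv
  tln <- pmax(sqrt(rowSums(tg^2)), 1e-9)
  nrm <- cbind(-tg[, 2L], tg[, 1L]) / tln
  h <- nrow(mask); w <- ncol(mask)
  od <- -log10((image + 1) / 256)
  odm <- (od[, , 1L] + od[, , 3L]) / 2
  vals <- c()
  for (off in seq(2, depth, by = 2)) {
    for (sgn in c(1, -1)) {
      r <- round(sub[, 1L] + sgn * off * nrm[, 1L])
      c2 <- round(sub[, 2L] + sgn * off * nrm[, 2L])
      ok <- r >= 1 & r <= h & c2 >= 1 & c2 <= w
      ok[ok] <- mask[cbind(r[ok], c2[ok])] == 0   # outside the mask only
      if (any(ok)) vals <- c(vals, odm[cbind(r[ok], c2[ok])])
    }
  }
  if (length(vals) == 0L) 0 else mean(vals)
}

#' Compute epidermal thickness and rete ridge score
#'
#' Thickness is the mean over ES points of the shortest distance to EB;
#' the rete ridge score is the population variance (divisor n) over EB
#' points of the shortest distance to ES. The definition is deliberately
#' asymmetric — swapping the boundaries changes both statistics.
#'
#' @param eb,es \code{\link{boundary_polyline}} objects (roles EB and ES).
#' @return object of class \code{morphometric_result}: list with
#'   \code{thickness} (pixels), \code{rete_ridge_score} (pixels^2),
#'   \code{m}, \code{n}, and \code{per_point_distances} (list with
#'   \code{es_to_eb} and \code{eb_to_es}).
#' @export
compute_morphometrics <- function(eb, es) {
  ebp <- if (inherits(eb, "boundary_polyline")) eb$points else eb
  esp <- if (inherits(es, "boundary_polyline")) es$points else es
  if (nrow(ebp) < 2L || nrow(esp) < 2L)
    stop("insufficient boundary: both polylines need at least 2 points")
  d_es <- dist_points_to_polyline(esp, ebp)
  d_eb <- dist_points_to_polyline(ebp, esp)
  n <- length(d_eb)
  structure(list(thickness = mean(d_es),
                 rete_ridge_score = sum((d_eb - mean(d_eb))^2) / n,
                 m = length(d_es), n = n,
                 per_point_distances = list(es_to_eb = d_es, eb_to_es = d_eb)),
            class = "morphometric_result")
}

#' @export
print.morphometric_result <- function(x, ...) {
  cat(sprintf("<morphometric_result: thickness %.2f px (m=%d), rete ridge score %.2f px^2 (n=%d)>\n",
              x$thickness, x$m, x$rete_ridge_score, x$n))
  invisible(x)
}

#' Morphometrics straight from a mask
#'
#' Convenience wrapper: boundary extraction then
#' \code{\link{compute_morphometrics}}.
#'
#' @param mask 0/1 epidermis mask.
#' @param image optional RGB image for boundary role assignment.
#' @param ... passed to \code{\link{extract_boundaries}}.
#' @return a \code{morphometric_result}.
#' @export
mask_morphometrics <- function(mask, image = NULL, ...) {
  b <- extract_boundaries(mask, image, ...)
  compute_morphometrics(b$eb, b$es)
}
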