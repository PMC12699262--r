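# ---------------------------------------------------------------------------
# Synthetic H&E-like skin tissue generator
# ---------------------------------------------------------------------------
# Emulates a three-layer section: stratum corneum on top, an epidermis band
# whose lower boundary (the epidermis-dermis junction, "EB") is a sinusoid
# mimicking rete ridges, and dermis below.  Nuclei are drawn as dark ellipses
# inside the epidermis so that texture features have something to measure.
# Every sample carries its exact ground truth (mask + boundary polylines),
# which is what makes the downstream segmentation, sampling, morphometry and
# learning stages testable without real slides.

#' Parameters of the synthetic skin generator
#'
#' @param image_height,image_width canvas size in pixels.
#' @param corneum_thickness stratum corneum depth in pixels.
#' @param epidermis_thickness mean vertical width of the epidermis band in
#'   pixels (distance between the flat epidermis-corneum boundary and the
#'   mean line of the sinusoidal epidermis-dermis boundary).
#' @param ridge_amplitude half peak-to-trough of the sinusoidal
#'   epidermis-dermis boundary, pixels; 0 gives a flat band.
#' @param ridge_wavelength sinusoid wavelength in pixels (>= 4).
#' @param nucleus_density nuclei per 10^4 pixels of epidermis area.
#' @param orientation_deg rotation of the whole layer stack in degrees;
#'   0 keeps the layers horizontal.
#' @param stain_palette list of three RGB triples (0-255) for corneum,
#'   epidermis and dermis, in that order.
#' @param noise_sd additive Gaussian pixel noise standard deviation
#'   (intensity units on the 0-255 scale).
#' @param n_distractors optional count of dermal distractor blobs
#'   (follicle/gland stand-ins) drawn in epidermis-like colour.
#' @param seed integer RNG seed; identical parameters and seed give
#'   bit-identical output.
#' @return an object of class \code{synthetic_skin_params}.
#' @export
synthetic_skin_params <- function(image_height = 512L, image_width = 512L,
                                  corneum_thickness = 30, epidermis_thickness = 60,
                                  ridge_amplitude = 15, ridge_wavelength = 128,
                                  nucleus_density = 60, orientation_deg = 0,
                                  stain_palette = list(corneum  = c(236, 208, 220),
                                                       epidermis = c(168, 118, 176),
                                                       dermis    = c(232, 165, 193)),
                                  noise_sd = 4, n_distractors = 0L, seed = 1L) {
  p <- list(image_height = as.integer(image_height), image_width = as.integer(image_width),
            corneum_thickness = corneum_thickness, epidermis_thickness = epidermis_thickness,
            ridge_amplitude = ridge_amplitude, ridge_wavelength = ridge_wavelength,
            nucleus_density = nucleus_density, orientation_deg = orientation_deg,
            stain_palette = stain_palette, noise_sd = noise_sd,
            n_distractors = as.integer(n_distractors), seed = as.integer(seed))
  class(p) <- "synthetic_skin_params"
  validate_skin_params(p)
  p
}

validate_skin_params <- function(p) {
  if (!(p$epidermis_thickness > p$ridge_amplitude))
    stop("invalid parameters: epidermis_thickness must exceed ridge_amplitude")
  if (p$ridge_amplitude < 0)
    stop("invalid parameters: ridge_amplitude must be >= 0")
  if (p$corneum_thickness < 1 || p$epidermis_thickness < 1)
    stop("invalid parameters: all thicknesses must be >= 1 pixel")
  if (p$ridge_wavelength < 4)
    stop("invalid parameters: ridge_wavelength must be >= 4 pixels")
  if (p$image_height < 4L || p$image_width < 4L)
    stop("invalid parameters: image must be at least 4 x 4 pixels")
  invisible(p)
}

#' A boundary polyline (ordered sub-pixel path)
#'
#' Carrier of the epidermis-dermis boundary (role \code{"EB"}) or the
#' epidermis-corneum boundary (role \code{"ES"}) as an ordered list of
#' (row, col) coordinates.
#'
#' @param points n x 2 matrix of (row, col) coordinates.
#' @param role \code{"EB"} or \code{"ES"}.
#' @return object of class \code{boundary_polyline}.
#' @export
boundary_polyline <- function(points, role = c("EB", "ES")) {
  role <- match.arg(role)
  points <- matrix(as.numeric(points), ncol = 2L,
                   dimnames = list(NULL, c("row", "col")))
  if (nrow(points) < 2L) stop("a boundary polyline needs at least 2 points")
  structure(list(points = points, role = role, m_or_n = nrow(points)),
            class = "boundary_polyline")
}

#' @export
print.boundary_polyline <- function(x, ...) {
  cat(sprintf("<boundary_polyline %s: %d points>\n", x$role, x$m_or_n))
  invisible(x)
}

# Continuous row coordinate of the two interfaces at column c (1-based).
# Pixel row r belongs to the epidermis iff es_row < r < eb_row(c).
es_row_at <- function(p, cols) rep(p$corneum_thickness + 0.5, length(cols))
eb_row_at <- function(p, cols) {
  p$corneum_thickness + p$epidermis_thickness + 0.5 +
    p$ridge_amplitude * sin(2 * pi * cols / p$ridge_wavelength)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion", sample.kind = "Rejection")
  force(code)
}

#' Generate one synthetic skin sample
#'
#' Builds the layered image, draws nuclei inside the epidermis by rejection
#' sampling (non-overlapping ellipses with 4-8 px axes, at most 100 placement
#' attempts each), adds clipped Gaussian noise, and finally rotates the whole
#' stack if \code{orientation_deg != 0} (nearest-neighbour rotation with
#' reflective padding; polylines rotated analytically so ground truth stays
#' exact).
#'
#' @param params a \code{\link{synthetic_skin_params}} object.
#' @return object of class \code{synthetic_skin_sample}: list with
#'   \code{image} (H x W x 3, 0-255), \code{epidermis_mask} (0/1 matrix),
#'   \code{eb_polyline}, \code{es_polyline} and \code{params}.
#' @export
generate_sample <- function(params) {
  validate_skin_params(params)
  p <- params
  h <- p$image_height; w <- p$image_width
  cols <- seq_len(w)
  es <- es_row_at(p, cols); eb <- eb_row_at(p, cols)

  rowm <- matrix(seq_len(h), h, w)
  esM <- matrix(es, h, w, byrow = TRUE); ebM <- matrix(eb, h, w, byrow = TRUE)
  mask <- matrix(as.integer(rowm > esM & rowm < ebM), h, w)

  img <- array(0, c(h, w, 3L))
  pal <- lapply(p$stain_palette, as.numeric)
  for (k in 1:3) {
    plane <- matrix(pal[[3L]][k], h, w)          # dermis
    plane[rowm <= esM] <- pal[[1L]][k]           # corneum
    plane[mask > 0] <- pal[[2L]][k]              # epidermis
    img[, , k] <- plane
  }

  with_seed(p$seed, {
    img <- draw_nuclei(img, mask, p)
    if (p$n_distractors > 0L)
      img <- draw_distractors(img, rowm > ebM, pal[[2L]], p$n_distractors)
    if (p$noise_sd > 0)
      img <- pmin(pmax(img + array(rnorm(length(img), 0, p$noise_sd), dim(img)), 0), 255)
  })

  es_pts <- cbind(es, cols); eb_pts <- cbind(eb, cols)
  if (p$orientation_deg != 0) {
    ctr <- c((h + 1) / 2, (w + 1) / 2)
    img <- rotate_raster(img, p$orientation_deg, mask = FALSE)
    mask <- rotate_raster(mask, p$orientation_deg, mask = TRUE)
    es_pts <- rotate_points(es_pts, p$orientation_deg, ctr)
    eb_pts <- rotate_points(eb_pts, p$orientation_deg, ctr)
  }

  structure(list(image = img, epidermis_mask = mask,
                 eb_polyline = boundary_polyline(eb_pts, "EB"),
                 es_polyline = boundary_polyline(es_pts, "ES"),
                 params = p),
            class = "synthetic_skin_sample")
}

#' @export
print.synthetic_skin_sample <- function(x, ...) {
  cat(sprintf("<synthetic_skin_sample %dx%d, epidermis area %d px, seed %d>\n",
              x$params$image_height, x$params$image_width,
              sum(x$epidermis_mask), x$params$seed))
  invisible(x)
}

nucleus_color <- c(72, 42, 112)

# Draw non-overlapping dark ellipses inside the epidermis band.
draw_nuclei <- function(img, mask, p) {
  area <- sum(mask)
  n <- round(p$nucleus_density * area / 1e4)
  if (n < 1L || area == 0L) return(img)
  h <- nrow(mask); w <- ncol(mask)
  inside <- which(mask > 0)
  occ <- matrix(FALSE, h, w)
  placed <- 0L
  for (i in seq_len(n)) {
    for (attempt in seq_len(100L)) {
      ctr <- inside[[sample.int(length(inside), 1L)]]
      r0 <- ((ctr - 1L) %% h) + 1L; c0 <- ((ctr - 1L) %/% h) + 1L
      a <- runif(1, 2, 4); b <- runif(1, 2, 4); th <- runif(1, 0, pi)
      rad <- ceiling(max(a, b))
      rr <- max(1L, r0 - rad):min(h, r0 + rad)
      cc <- max(1L, c0 - rad):min(w, c0 + rad)
      dr <- outer(rr - r0, rep(1, length(cc))); dc <- outer(rep(1, length(rr)), cc - c0)
      u <- (dc * cos(th) + dr * sin(th)) / a
      v <- (-dc * sin(th) + dr * cos(th)) / b
      ell <- u * u + v * v <= 1
      if (!any(ell)) next
      sub_idx <- cbind(dr[ell] + r0, dc[ell] + c0)
      lin <- (sub_idx[, 2L] - 1L) * h + sub_idx[, 1L]
      if (all(mask[lin] > 0) && !any(occ[lin])) {
        occ[lin] <- TRUE
        for (k in 1:3) {
          plane <- img[, , k]; plane[lin] <- nucleus_color[k]; img[, , k] <- plane
        }
        placed <- placed + 1L
        break
      }
    }
  }
  img
}

# Epidermis-coloured blobs in the dermis, standing in for follicles/glands.
draw_distractors <- function(img, dermis, color, n) {
  h <- nrow(dermis); w <- ncol(dermis)
  inside <- which(dermis)
  if (length(inside) == 0L) return(img)
  for (i in seq_len(n)) {
    ctr <- inside[[sample.int(length(inside), 1L)]]
    r0 <- ((ctr - 1L) %% h) + 1L; c0 <- ((ctr - 1L) %/% h) + 1L
    a <- runif(1, 8, 20); b <- runif(1, 8, 20)
    rad <- ceiling(max(a, b))
    rr <- max(1L, r0 - rad):min(h, r0 + rad)
    cc <- max(1L, c0 - rad):min(w, c0 + rad)
    dr <- outer(rr - r0, rep(1, length(cc))); dc <- outer(rep(1, length(rr)), cc - c0)
    ell <- (dc / a)^2 + (dr / b)^2 <= 1
    sub_idx <- cbind(dr[ell] + r0, dc[ell] + c0)
    lin <- (sub_idx[, 2L] - 1L) * h + sub_idx[, 1L]
    keep <- dermis[lin]
    lin <- lin[keep]
    for (k in 1:3) { plane <- img[, , k]; plane[lin] <- color[k]; img[, , k] <- plane }
  }
  img
}

#' Generate a labelled two-group cohort
#'
#' Draws \code{n_young + n_aged} samples whose per-sample epidermis thickness
#' and ridge amplitude are jittered around the group means with a relative
#' standard deviation \code{jitter_rel} (multiplicative Gaussian jitter,
#' truncated so parameter invariants keep holding). Aged defaults are thinner
#' and flatter than young ones, mirroring the morphometric differences the
#' framework is built to detect.
#'
#' @param n_young,n_aged per-group sample counts (>= 1).
#' @param young_params,aged_params group-mean \code{synthetic_skin_params}.
#' @param seed cohort seed; per-sample seeds are derived from it.
#' @param jitter_rel relative standard deviation of the per-sample jitter.
#' @return list of \code{synthetic_skin_sample} objects, each with an extra
#'   \code{$label} field (\code{"young"} or \code{"aged"}) and
#'   \code{$sample_id}.
#' @export
generate_cohort <- function(n_young, n_aged,
                            young_params = synthetic_skin_params(epidermis_thickness = 40,
                                                                 ridge_amplitude = 10),
                            aged_params = synthetic_skin_params(epidermis_thickness = 20,
                                                                ridge_amplitude = 2),
                            seed = 1L, jitter_rel = 0.1) {
  stopifnot(n_young >= 1L, n_aged >= 1L)
  groups <- c(rep("young", n_young), rep("aged", n_aged))
  base <- list(young = young_params, aged = aged_params)
  out <- vector("list", length(groups))
  jit <- with_seed(seed, matrix(rnorm(2L * length(groups)), ncol = 2L))
  for (i in seq_along(groups)) {
    p <- base[[groups[i]]]
    p$epidermis_thickness <- max(2, p$epidermis_thickness * (1 + jitter_rel * jit[i, 1L]))
    p$ridge_amplitude <- max(0, min(p$ridge_amplitude * (1 + jitter_rel * jit[i, 2L]),
                                    p$epidermis_thickness - 1))
    p$seed <- (seed * 1009L + i) %% .Machine$integer.max
    s <- generate_sample(p)
    s$label <- groups[i]
    s$sample_id <- sprintf("wsi_%03d", i)
    out[[i]] <- s
  }
  out
}
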