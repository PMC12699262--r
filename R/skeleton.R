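# ---------------------------------------------------------------------------
# Mask skeleton, path tracing and contour utilities
# ---------------------------------------------------------------------------

# Zhang-Suen morphological thinning of a binary matrix.
thin_mask <- function(mask) {
  m <- matrix(as.integer(mask > 0), nrow(mask), ncol(mask))
  h <- nrow(m); w <- ncol(m)
  pad <- function(x) {
    xp <- matrix(0L, h + 2L, w + 2L)
    xp[2:(h + 1L), 2:(w + 1L)] <- x
    xp
  }
  repeat {
    changed <- FALSE
    for (sub in 1:2) {
      xp <- pad(m)
      ctr <- xp[2:(h + 1L), 2:(w + 1L)]
      p2 <- xp[1:h, 2:(w + 1L)]         # N
      p3 <- xp[1:h, 3:(w + 2L)]         # NE
      p4 <- xp[2:(h + 1L), 3:(w + 2L)]  # E
      p5 <- xp[3:(h + 2L), 3:(w + 2L)]  # SE
      p6 <- xp[3:(h + 2L), 2:(w + 1L)]  # S
      p7 <- xp[3:(h + 2L), 1:w]         # SW
      p8 <- xp[2:(h + 1L), 1:w]         # W
      p9 <- xp[1:h, 1:w]                # NW
      B <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      A <- (p2 == 0L & p3 == 1L) + (p3 == 0L & p4 == 1L) + (p4 == 0L & p5 == 1L) +
        (p5 == 0L & p6 == 1L) + (p6 == 0L & p7 == 1L) + (p7 == 0L & p8 == 1L) +
        (p8 == 0L & p9 == 1L) + (p9 == 0L & p2 == 1L)
      if (sub == 1L) {
        cond <- ctr == 1L & B >= 2L & B <= 6L & A == 1L &
          (p2 * p4 * p6 == 0L) & (p4 * p6 * p8 == 0L)
      } else {
        cond <- ctr == 1L & B >= 2L & B <= 6L & A == 1L &
          (p2 * p4 * p8 == 0L) & (p2 * p6 * p8 == 0L)
      }
      if (any(cond)) {
        m[cond] <- 0L
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m
}

# Build the 8-connected weighted graph over foreground pixels and return the
# longest shortest path (graph diameter path) as ordered (row, col) coords.
longest_skeleton_path <- function(skel) {
  idx <- which(skel > 0, arr.ind = TRUE)
  n <- nrow(idx)
  if (n == 0L) return(matrix(numeric(0), 0L, 2L, dimnames = list(NULL, c("row", "col"))))
  if (n == 1L) return(matrix(as.numeric(idx), 1L, 2L, dimnames = list(NULL, c("row", "col"))))
  h <- nrow(skel)
  lin <- (idx[, 2L] - 1L) * h + idx[, 1L]
  id_of <- integer(h * ncol(skel)); id_of[lin] <- seq_len(n)
  edges <- NULL; weights <- NULL
  offs <- rbind(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))
  for (k in 1:4) {
    nr <- idx[, 1L] + offs[k, 1L]; nc <- idx[, 2L] + offs[k, 2L]
    ok <- nr >= 1L & nr <= h & nc >= 1L & nc <= ncol(skel)
    nlin <- (nc[ok] - 1L) * h + nr[ok]
    present <- id_of[nlin] > 0L
    from <- which(ok)[present]; to <- id_of[nlin[present]]
    if (length(from)) {
      edges <- rbind(edges, cbind(from, to))
      weights <- c(weights, rep(if (k <= 2L) 1 else sqrt(2), length(from)))
    }
  }
  if (is.null(edges))
    return(matrix(as.numeric(idx[1L, , drop = FALSE]), 1L, 2L,
                  dimnames = list(NULL, c("row", "col"))))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  if (igraph::vcount(g) < n) g <- igraph::add_vertices(g, n - igraph::vcount(g))
  igraph::E(g)$weight <- weights
  comp <- igraph::components(g)
  main <- which.max(comp$csize)
  vs <- which(comp$membership == main)
  d1 <- igraph::distances(g, v = vs[1L], to = vs)[1L, ]
  a <- vs[which.max(d1)]
  d2 <- igraph::distances(g, v = a, to = vs)[1L, ]
  b <- vs[which.max(d2)]
  path <- igraph::shortest_paths(g, from = a, to = b, output = "vpath")$vpath[[1L]]
  pts <- idx[as.integer(path), , drop = FALSE]
  matrix(as.numeric(pts), ncol = 2L, dimnames = list(NULL, c("row", "col")))
}

#' Trace an ordered path through a mask
#'
#' Skeletonizes the mask (Zhang-Suen thinning) and returns the longest path
#' through the skeleton's 8-connected pixel graph as ordered (row, col)
#' coordinates. The path is oriented so its first point is lexicographically
#' smaller than its last.
#'
#' @param mask 0/1 matrix.
#' @return k x 2 numeric matrix of (row, col) coordinates; 0 rows for an
#'   empty mask.
#' @export
trace_mask_path <- function(mask) {
  if (sum(mask > 0) == 0L)
    return(matrix(numeric(0), 0L, 2L, dimnames = list(NULL, c("row", "col"))))
  pts <- longest_skeleton_path(thin_mask(mask))
  k <- nrow(pts)
  if (k >= 2L) {
    a <- pts[1L, ]; b <- pts[k, ]
    if (b[1L] < a[1L] || (b[1L] == a[1L] && b[2L] < a[2L])) pts <- pts[k:1L, , drop = FALSE]
  }
  pts
}

# Moore-neighbour tracing of the outer contour of the largest foreground
# component; returns ordered closed contour pixel coordinates.
trace_contour <- function(mask) {
  comp <- EBImage::bwlabel(matrix(as.integer(mask > 0), nrow(mask), ncol(mask)))
  if (max(comp) == 0L) return(matrix(numeric(0), 0L, 2L))
  big <- which.max(tabulate(comp[comp > 0L]))
  m <- comp == big
  h <- nrow(m); w <- ncol(m)
  at <- function(r, c) r >= 1L && r <= h && c >= 1L && c <= w && m[r, c]
  # start: first foreground pixel in column-major scan
  start_lin <- which(m)[1L]
  sr <- ((start_lin - 1L) %% h) + 1L; sc <- ((start_lin - 1L) %/% h) + 1L
  # Moore neighbourhood clockwise starting W
  nb <- rbind(c(0L, -1L), c(-1L, -1L), c(-1L, 0L), c(-1L, 1L),
              c(0L, 1L), c(1L, 1L), c(1L, 0L), c(1L, -1L))
  contour <- matrix(0L, 0L, 2L)
  cur <- c(sr, sc); backtrack <- 1L  # came from the west
  repeat {
    contour <- rbind(contour, cur)
    found <- FALSE
    k <- backtrack
    for (s in 0:7) {
      j <- ((k - 1L + s) %% 8L) + 1L
      r2 <- cur[1L] + nb[j, 1L]; c2 <- cur[2L] + nb[j, 2L]
      if (at(r2, c2)) {
        backtrack <- ((j - 1L + 8L - 2L) %% 8L) + 1L  # re-enter search just before found dir
        cur <- c(r2, c2)
        found <- TRUE
        break
      }
    }
    if (!found) break                       # isolated pixel
    if (all(cur == c(sr, sc)) && nrow(contour) > 2L) break
    if (nrow(contour) > 4L * (h * w)) break # safety
  }
  matrix(as.numeric(contour), ncol = 2L, dimnames = list(NULL, c("row", "col")))
}

# Resample an open polyline at uniform arc-length steps.
resample_polyline <- function(pts, step = 1) {
  if (nrow(pts) < 2L) return(pts)
  seg <- sqrt(diff(pts[, 1L])^2 + diff(pts[, 2L])^2)
  keep <- seg > 0
  if (!all(keep)) {
    pts <- pts[c(TRUE, keep), , drop = FALSE]
    seg <- seg[keep]
  }
  if (nrow(pts) < 2L) return(pts)
  s <- c(0, cumsum(seg))
  total <- s[length(s)]
  at <- unique(c(seq(0, total, by = step), total))
  r <- stats::approx(s, pts[, 1L], xout = at)$y
  c2 <- stats::approx(s, pts[, 2L], xout = at)$y
  cbind(row = r, col = c2)
}

polyline_length <- function(pts) {
  if (nrow(pts) < 2L) return(0)
  sum(sqrt(diff(pts[, 1L])^2 + diff(pts[, 2L])^2))
}
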