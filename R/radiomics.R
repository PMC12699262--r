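# ---------------------------------------------------------------------------
# Radiomic feature extraction and random-forest feature ranking
# ---------------------------------------------------------------------------
# A fixed 106-feature schema per patch: 18 first-order intensity statistics,
# 24 gray-level co-occurrence (GLCM), 16 run-length (GLRLM), 16 size-zone
# (GLSZM), 5 neighbourhood gray-tone difference (NGTDM) and 14 dependence
# (GLDM) texture features, plus 13 image/mask diagnostics.  Texture matrices
# are computed on the luminance channel discretized at a fixed bin width
# (default 25 intensity units), distance 1, the four 2-D directions merged
# symmetrically.  The schema is pinned by radiomic_feature_manifest(): every
# successful extraction yields exactly these names in exactly this order.

firstorder_names <- c("Energy", "TotalEnergy", "Entropy", "Minimum", "10Percentile",
                      "90Percentile", "Maximum", "Mean", "Median",
                      "InterquartileRange", "Range", "MeanAbsoluteDeviation",
                      "RobustMeanAbsoluteDeviation", "RootMeanSquared", "Skewness",
                      "Kurtosis", "Variance", "Uniformity")

glcm_names <- c("Autocorrelation", "ClusterProminence", "ClusterShade",
                "ClusterTendency", "Contrast", "Correlation", "DifferenceAverage",
                "DifferenceEntropy", "DifferenceVariance", "Id", "Idm", "Idmn",
                "Idn", "Imc1", "Imc2", "InverseVariance", "JointAverage",
                "JointEnergy", "JointEntropy", "MCC", "MaximumProbability",
                "SumAverage", "SumEntropy", "SumSquares")

glrlm_names <- c("GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
                 "GrayLevelVariance", "HighGrayLevelRunEmphasis", "LongRunEmphasis",
                 "LongRunHighGrayLevelEmphasis", "LongRunLowGrayLevelEmphasis",
                 "LowGrayLevelRunEmphasis", "RunEntropy", "RunLengthNonUniformity",
                 "RunLengthNonUniformityNormalized", "RunPercentage", "RunVariance",
                 "ShortRunEmphasis", "ShortRunHighGrayLevelEmphasis",
                 "ShortRunLowGrayLevelEmphasis")

glszm_names <- c("GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
                 "GrayLevelVariance", "HighGrayLevelZoneEmphasis",
                 "LargeAreaEmphasis", "LargeAreaHighGrayLevelEmphasis",
                 "LargeAreaLowGrayLevelEmphasis", "LowGrayLevelZoneEmphasis",
                 "SizeZoneNonUniformity", "SizeZoneNonUniformityNormalized",
                 "SmallAreaEmphasis", "SmallAreaHighGrayLevelEmphasis",
                 "SmallAreaLowGrayLevelEmphasis", "ZoneEntropy", "ZonePercentage",
                 "ZoneVariance")

ngtdm_names <- c("Busyness", "Coarseness", "Complexity", "Contrast", "Strength")

gldm_names <- c("DependenceEntropy", "DependenceNonUniformity",
                "DependenceNonUniformityNormalized", "DependenceVariance",
                "GrayLevelNonUniformity", "GrayLevelVariance",
                "HighGrayLevelEmphasis", "LargeDependenceEmphasis",
                "LargeDependenceHighGrayLevelEmphasis",
                "LargeDependenceLowGrayLevelEmphasis", "LowGrayLevelEmphasis",
                "SmallDependenceEmphasis", "SmallDependenceHighGrayLevelEmphasis",
                "SmallDependenceLowGrayLevelEmphasis")

diagnostics_names <- c("image_Mean", "image_Minimum", "image_Maximum", "image_Range",
                       "image_Rows", "image_Columns", "image_NPixels",
                       "mask_NPixels", "mask_Fraction", "gray_NLevels",
                       "gray_BinWidth", "gray_Minimum", "gray_Maximum")

#' The pinned 106-feature schema
#'
#' @return character vector of the 106 feature names in their fixed order.
#' @export
radiomic_feature_manifest <- function() {
  c(paste0("firstorder_", firstorder_names),
    paste0("glcm_", glcm_names),
    paste0("glrlm_", glrlm_names),
    paste0("glszm_", glszm_names),
    paste0("ngtdm_", ngtdm_names),
    paste0("gldm_", gldm_names),
    paste0("diagnostics_", diagnostics_names))
}

safe_log2 <- function(p) ifelse(p > 0, log2(p), 0)

features_firstorder <- function(x, bw) {
  n <- length(x)
  lev <- discretize_gray(x, bw)
  p <- tabulate(lev) / n
  qs <- stats::quantile(x, c(0.10, 0.25, 0.75, 0.90), names = FALSE, type = 7)
  mu <- mean(x)
  m2 <- mean((x - mu)^2); m3 <- mean((x - mu)^3); m4 <- mean((x - mu)^4)
  rob <- x[x >= qs[1L] & x <= qs[4L]]
  c(Energy = sum(x^2),
    TotalEnergy = sum(x^2),
    Entropy = -sum(p * safe_log2(p)),
    Minimum = min(x),
    `10Percentile` = qs[1L],
    `90Percentile` = qs[4L],
    Maximum = max(x),
    Mean = mu,
    Median = stats::median(x),
    InterquartileRange = qs[3L] - qs[2L],
    Range = max(x) - min(x),
    MeanAbsoluteDeviation = mean(abs(x - mu)),
    RobustMeanAbsoluteDeviation = if (length(rob)) mean(abs(rob - mean(rob))) else 0,
    RootMeanSquared = sqrt(mean(x^2)),
    Skewness = if (m2 > 0) m3 / m2^1.5 else NaN,
    Kurtosis = if (m2 > 0) m4 / m2^2 else NaN,
    Variance = m2,
    Uniformity = sum(p^2))
}

discretize_gray <- function(x, bw) as.integer(floor((x - min(x)) / bw) + 1L)

# Gray-level matrix with NA outside the region.
level_matrix <- function(gray, region, bw) {
  x <- gray[region]
  L <- matrix(NA_integer_, nrow(gray), ncol(gray))
  L[region] <- discretize_gray(x, bw)
  L
}

# Symmetric co-occurrence matrix, distance 1, four directions merged.
glcm_matrix <- function(L, Ng) {
  H <- nrow(L); W <- ncol(L)
  P <- matrix(0, Ng, Ng)
  offs <- list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(-1L, 1L))
  for (o in offs) {
    dr <- o[1L]; dc <- o[2L]
    r1 <- max(1L, 1L - dr):min(H, H - dr)
    c1 <- max(1L, 1L - dc):min(W, W - dc)
    A <- L[r1, c1, drop = FALSE]
    B <- L[r1 + dr, c1 + dc, drop = FALSE]
    ok <- !is.na(A) & !is.na(B)
    if (!any(ok)) next
    idx <- (A[ok] - 1L) * Ng + B[ok]
    tab <- tabulate(idx, nbins = Ng * Ng)
    M <- matrix(tab, Ng, Ng, byrow = TRUE)
    P <- P + M + t(M)
  }
  P
}

features_glcm <- function(L, Ng) {
  P <- glcm_matrix(L, Ng)
  s <- sum(P)
  if (s == 0) return(setNames(rep(NaN, length(glcm_names)), glcm_names))
  p <- P / s
  i <- matrix(seq_len(Ng), Ng, Ng)
  j <- t(i)
  px <- rowSums(p); py <- colSums(p)
  mux <- sum(seq_len(Ng) * px); muy <- sum(seq_len(Ng) * py)
  sx <- sqrt(sum((seq_len(Ng) - mux)^2 * px)); sy <- sqrt(sum((seq_len(Ng) - muy)^2 * py))
  # p_{x+y} indexed k = 2..2Ng, p_{x-y} indexed k = 0..Ng-1
  ksum <- 2:(2 * Ng)
  pxy_sum <- vapply(ksum, function(k) sum(p[(i + j) == k]), numeric(1))
  kdiff <- 0:(Ng - 1L)
  pxy_diff <- vapply(kdiff, function(k) sum(p[abs(i - j) == k]), numeric(1))
  HX <- -sum(px * safe_log2(px)); HY <- -sum(py * safe_log2(py))
  HXY <- -sum(p * safe_log2(p))
  pxpy <- outer(px, py)
  HXY1 <- -sum(p * safe_log2(pxpy))
  HXY2 <- -sum(pxpy * safe_log2(pxpy))
  DA <- sum(kdiff * pxy_diff)
  corr <- if (sx > 0 && sy > 0) (sum(i * j * p) - mux * muy) / (sx * sy) else NaN
  imc1 <- if (max(HX, HY) > 0) (HXY - HXY1) / max(HX, HY) else NaN
  imc2 <- sqrt(pmax(1 - exp(-2 * (HXY2 - HXY)), 0))
  mcc <- {
    nz <- px > 0
    if (sum(nz) < 2L) 1 else {
      Q <- matrix(0, Ng, Ng)
      denom <- outer(px, py)
      W <- p / ifelse(denom > 0, denom, 1)   # w(i,k) = p(i,k)/(px_i py_k)
      Q <- W %*% t(p)
      ev <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
      if (length(ev) >= 2L) sqrt(max(ev[2L], 0)) else 1
    }
  }
  off_diag <- abs(i - j) > 0
  c(Autocorrelation = sum(i * j * p),
    ClusterProminence = sum((i + j - mux - muy)^4 * p),
    ClusterShade = sum((i + j - mux - muy)^3 * p),
    ClusterTendency = sum((i + j - mux - muy)^2 * p),
    Contrast = sum((i - j)^2 * p),
    Correlation = corr,
    DifferenceAverage = DA,
    DifferenceEntropy = -sum(pxy_diff * safe_log2(pxy_diff)),
    DifferenceVariance = sum((kdiff - DA)^2 * pxy_diff),
    Id = sum(p / (1 + abs(i - j))),
    Idm = sum(p / (1 + (i - j)^2)),
    Idmn = sum(p / (1 + (i - j)^2 / Ng^2)),
    Idn = sum(p / (1 + abs(i - j) / Ng)),
    Imc1 = imc1,
    Imc2 = imc2,
    InverseVariance = sum(p[off_diag] / (i[off_diag] - j[off_diag])^2),
    JointAverage = mux,
    JointEnergy = sum(p^2),
    JointEntropy = HXY,
    MCC = mcc,
    MaximumProbability = max(p),
    SumAverage = sum(ksum * pxy_sum),
    SumEntropy = -sum(pxy_sum * safe_log2(pxy_sum)),
    SumSquares = sum((i - mux)^2 * p))
}

# Runs along the four 2-D directions, NA-broken.
glrlm_matrix <- function(L, Ng) {
  H <- nrow(L); W <- ncol(L)
  maxlen <- max(H, W)
  R <- matrix(0, Ng, maxlen)
  ri <- matrix(seq_len(H), H, W); ci <- matrix(rep(seq_len(W), each = H), H, W)
  lines <- c(split(L, ci),            # vertical runs (within a column)
             split(L, ri),            # horizontal runs (within a row)
             split(L, ri - ci),       # diagonal
             split(L, ri + ci))       # anti-diagonal
  for (v in lines) {
    v <- as.integer(v)
    if (!length(v)) next
    enc <- rle(ifelse(is.na(v), -1L, v))
    keep <- enc$values > 0
    if (!any(keep)) next
    idx <- (enc$values[keep] - 1L) * maxlen + pmin(enc$lengths[keep], maxlen)
    tab <- tabulate(idx, nbins = Ng * maxlen)
    R <- R + matrix(tab, Ng, maxlen, byrow = TRUE)
  }
  R
}

features_glrlm <- function(L, Ng, Np) {
  R <- glrlm_matrix(L, Ng)
  Nr <- sum(R)
  if (Nr == 0) return(setNames(rep(NaN, length(glrlm_names)), glrlm_names))
  iv <- seq_len(nrow(R)); lv <- seq_len(ncol(R))
  ri <- rowSums(R); rl <- colSums(R)
  p <- R / Nr
  mu_i <- sum(iv * rowSums(p)); mu_l <- sum(lv * colSums(p))
  c(GrayLevelNonUniformity = sum(ri^2) / Nr,
    GrayLevelNonUniformityNormalized = sum(ri^2) / Nr^2,
    GrayLevelVariance = sum((iv - mu_i)^2 * rowSums(p)),
    HighGrayLevelRunEmphasis = sum(ri * iv^2) / Nr,
    LongRunEmphasis = sum(rl * lv^2) / Nr,
    LongRunHighGrayLevelEmphasis = sum(R * outer(iv^2, lv^2)) / Nr,
    LongRunLowGrayLevelEmphasis = sum(R * outer(1 / iv^2, lv^2)) / Nr,
    LowGrayLevelRunEmphasis = sum(ri / iv^2) / Nr,
    RunEntropy = -sum(p * safe_log2(p)),
    RunLengthNonUniformity = sum(rl^2) / Nr,
    RunLengthNonUniformityNormalized = sum(rl^2) / Nr^2,
    RunPercentage = Nr / (4 * Np),
    RunVariance = sum((lv - mu_l)^2 * colSums(p)),
    ShortRunEmphasis = sum(rl / lv^2) / Nr,
    ShortRunHighGrayLevelEmphasis = sum(R * outer(iv^2, 1 / lv^2)) / Nr,
    ShortRunLowGrayLevelEmphasis = sum(R * outer(1 / iv^2, 1 / lv^2)) / Nr)
}

# 8-connected zones of equal gray level: returns (level, size) pairs.
gray_zones <- function(L, Ng) {
  h <- nrow(L); w <- ncol(L)
  out_lev <- integer(0); out_size <- integer(0)
  for (g in seq_len(Ng)) {
    m <- !is.na(L) & L == g
    if (!any(m)) next
    sizes <- zone_sizes8(m)
    out_lev <- c(out_lev, rep(g, length(sizes)))
    out_size <- c(out_size, sizes)
  }
  cbind(level = out_lev, size = out_size)
}

zone_sizes8 <- function(m) {
  lab <- label_components8(m)
  if (max(lab) == 0L) return(integer(0))
  tabulate(lab[lab > 0L])
}

features_glszm <- function(L, Ng, Np) {
  Z <- gray_zones(L, Ng)
  Nz <- nrow(Z)
  if (Nz == 0L) return(setNames(rep(NaN, length(glszm_names)), glszm_names))
  lev <- Z[, 1L]; sz <- Z[, 2L]
  gi <- tabulate(lev, nbins = Ng)                       # zones per gray level
  us <- sort(unique(sz)); sjc <- vapply(us, function(s) sum(sz == s), numeric(1))
  p_lev <- gi / Nz
  p_sz <- sjc / Nz
  mu_g <- sum(seq_len(Ng) * p_lev); mu_s <- sum(us * p_sz)
  pj <- table(factor(paste(lev, sz))) / Nz
  c(GrayLevelNonUniformity = sum(gi^2) / Nz,
    GrayLevelNonUniformityNormalized = sum(gi^2) / Nz^2,
    GrayLevelVariance = sum((seq_len(Ng) - mu_g)^2 * p_lev),
    HighGrayLevelZoneEmphasis = sum(lev^2) / Nz,
    LargeAreaEmphasis = sum(sz^2) / Nz,
    LargeAreaHighGrayLevelEmphasis = sum(sz^2 * lev^2) / Nz,
    LargeAreaLowGrayLevelEmphasis = sum(sz^2 / lev^2) / Nz,
    LowGrayLevelZoneEmphasis = sum(1 / lev^2) / Nz,
    SizeZoneNonUniformity = sum(sjc^2) / Nz,
    SizeZoneNonUniformityNormalized = sum(sjc^2) / Nz^2,
    SmallAreaEmphasis = sum(1 / sz^2) / Nz,
    SmallAreaHighGrayLevelEmphasis = sum(lev^2 / sz^2) / Nz,
    SmallAreaLowGrayLevelEmphasis = sum(1 / (lev^2 * sz^2)) / Nz,
    ZoneEntropy = -sum(as.numeric(pj) * safe_log2(as.numeric(pj))),
    ZonePercentage = Nz / Np,
    ZoneVariance = sum((sz - mu_s)^2) / Nz)
}

features_ngtdm <- function(L, Ng, Np) {
  h <- nrow(L); w <- ncol(L)
  Lp <- matrix(NA_integer_, h + 2L, w + 2L)
  Lp[2:(h + 1L), 2:(w + 1L)] <- L
  ssum <- matrix(0, h, w); cnt <- matrix(0, h, w)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    Nn <- Lp[(2:(h + 1L)) + dr, (2:(w + 1L)) + dc]
    ok <- !is.na(Nn)
    ssum[ok] <- ssum[ok] + Nn[ok]
    cnt <- cnt + ok
  }
  valid <- !is.na(L) & cnt > 0
  if (!any(valid)) return(setNames(rep(NaN, length(ngtdm_names)), ngtdm_names))
  abar <- ssum[valid] / cnt[valid]
  lv <- L[valid]
  N <- length(lv)
  s_i <- vapply(seq_len(Ng), function(g) sum(abs(g - abar[lv == g])), numeric(1))
  n_i <- tabulate(lv, nbins = Ng)
  p_i <- n_i / N
  pres <- which(p_i > 0)
  Ngp <- length(pres)
  iv <- seq_len(Ng)
  contrast <- if (Ngp > 1L) {
    (sum(outer(p_i[pres], p_i[pres]) * outer(iv[pres], iv[pres], `-`)^2) /
       (Ngp * (Ngp - 1L))) * (sum(s_i) / N)
  } else 0
  busy_den <- sum(abs(outer(iv[pres] * p_i[pres], iv[pres] * p_i[pres], `-`)))
  complexity <- if (Ngp > 1L) {
    acc <- 0
    for (a in pres) for (b in pres) {
      acc <- acc + abs(a - b) * (p_i[a] * s_i[a] + p_i[b] * s_i[b]) / (p_i[a] + p_i[b])
    }
    acc / N
  } else 0
  strength_num <- sum(outer(p_i[pres], p_i[pres], `+`) * outer(iv[pres], iv[pres], `-`)^2)
  c(Busyness = if (busy_den > 0) sum(p_i * s_i) / busy_den else 0,
    Coarseness = if (sum(p_i * s_i) > 0) 1 / sum(p_i * s_i) else 1e6,
    Complexity = complexity,
    Contrast = contrast,
    Strength = if (sum(s_i) > 0) strength_num / sum(s_i) else 0)
}

features_gldm <- function(L, Ng, alpha = 0) {
  h <- nrow(L); w <- ncol(L)
  Lp <- matrix(NA_integer_, h + 2L, w + 2L)
  Lp[2:(h + 1L), 2:(w + 1L)] <- L
  dep <- matrix(0L, h, w)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    Nn <- Lp[(2:(h + 1L)) + dr, (2:(w + 1L)) + dc]
    ok <- !is.na(Nn) & !is.na(L) & abs(Nn - L) <= alpha
    dep <- dep + ok
  }
  valid <- !is.na(L)
  if (!any(valid)) return(setNames(rep(NaN, length(gldm_names)), gldm_names))
  lv <- L[valid]; jv <- dep[valid] + 1L      # dependence size incl. the centre
  Nd <- max(jv)
  P <- matrix(tabulate((lv - 1L) * Nd + jv, nbins = Ng * Nd), Ng, Nd, byrow = TRUE)
  Nz <- sum(P)
  p <- P / Nz
  iv <- seq_len(Ng); dv <- seq_len(Nd)
  gi <- rowSums(P); dj <- colSums(P)
  mu_g <- sum(iv * rowSums(p)); mu_d <- sum(dv * colSums(p))
  c(DependenceEntropy = -sum(p * safe_log2(p)),
    DependenceNonUniformity = sum(dj^2) / Nz,
    DependenceNonUniformityNormalized = sum(dj^2) / Nz^2,
    DependenceVariance = sum((dv - mu_d)^2 * colSums(p)),
    GrayLevelNonUniformity = sum(gi^2) / Nz,
    GrayLevelVariance = sum((iv - mu_g)^2 * rowSums(p)),
    HighGrayLevelEmphasis = sum(gi * iv^2) / Nz,
    LargeDependenceEmphasis = sum(dj * dv^2) / Nz,
    LargeDependenceHighGrayLevelEmphasis = sum(P * outer(iv^2, dv^2)) / Nz,
    LargeDependenceLowGrayLevelEmphasis = sum(P * outer(1 / iv^2, dv^2)) / Nz,
    LowGrayLevelEmphasis = sum(gi / iv^2) / Nz,
    SmallDependenceEmphasis = sum(dj / dv^2) / Nz,
    SmallDependenceHighGrayLevelEmphasis = sum(P * outer(iv^2, 1 / dv^2)) / Nz,
    SmallDependenceLowGrayLevelEmphasis = sum(P * outer(1 / iv^2, 1 / dv^2)) / Nz)
}

#' Extract the 106-feature radiomic vector of a patch
#'
#' @param p a \code{\link{patch}}, a \code{synthetic_skin_sample}, or a
#'   plain H x W x 3 array.
#' @param mask_mode \code{"full"} (whole patch, the default) or
#'   \code{"mask_crop"} (restrict to the epidermis mask crop).
#' @param bin_width gray-level discretization bin width (intensity units).
#' @param alpha GLDM dependence tolerance in gray levels.
#' @return object of class \code{radiomic_feature_vector}: list with
#'   \code{values} (named numeric of length 106, order pinned by
#'   \code{\link{radiomic_feature_manifest}}), \code{patch_id},
#'   \code{wsi_id}, \code{label} and \code{nan_flags} (names of features
#'   that were NaN/Inf and were replaced by 0).
#' @export
extract_features <- function(p, mask_mode = c("full", "mask_crop"),
                             bin_width = 25, alpha = 0) {
  mask_mode <- match.arg(mask_mode)
  if (inherits(p, "patch")) {
    pixels <- p$pixels; mcrop <- p$mask_crop
    patch_id <- p$patch_id; wsi_id <- p$wsi_id; label <- p$label
  } else if (inherits(p, "synthetic_skin_sample")) {
    pixels <- p$image; mcrop <- p$epidermis_mask
    patch_id <- p$sample_id; wsi_id <- p$sample_id; label <- p$label
  } else {
    pixels <- as_rgb_image(p); mcrop <- NULL
    patch_id <- NA_character_; wsi_id <- NA_character_; label <- NULL
  }
  gray <- rgb_to_gray(pixels)
  region <- if (mask_mode == "mask_crop") {
    if (is.null(mcrop) || sum(mcrop > 0) == 0L)
      stop("empty region: mask_crop mode requires a non-empty mask crop")
    mcrop > 0
  } else matrix(TRUE, nrow(gray), ncol(gray))
  x <- gray[region]
  L <- level_matrix(gray, region, bin_width)
  Ng <- max(L, na.rm = TRUE)
  Np <- length(x)
  vals <- c(setNames(features_firstorder(x, bin_width),
                     paste0("firstorder_", firstorder_names)),
            setNames(features_glcm(L, Ng), paste0("glcm_", glcm_names)),
            setNames(features_glrlm(L, Ng, Np), paste0("glrlm_", glrlm_names)),
            setNames(features_glszm(L, Ng, Np), paste0("glszm_", glszm_names)),
            setNames(features_ngtdm(L, Ng, Np), paste0("ngtdm_", ngtdm_names)),
            setNames(features_gldm(L, Ng, alpha), paste0("gldm_", gldm_names)),
            setNames(c(mean(gray), min(gray), max(gray), max(gray) - min(gray),
                       nrow(gray), ncol(gray), length(gray),
                       if (is.null(mcrop)) 0 else sum(mcrop > 0),
                       if (is.null(mcrop)) 0 else mean(mcrop > 0),
                       Ng, bin_width, min(x), max(x)),
                     paste0("diagnostics_", diagnostics_names)))
  vals <- vals[radiomic_feature_manifest()]
  bad <- !is.finite(vals)
  nan_flags <- names(vals)[bad]
  vals[bad] <- 0
  structure(list(values = vals, patch_id = patch_id, wsi_id = wsi_id,
                 label = if (is.null(label)) NA_character_ else label,
                 nan_flags = nan_flags),
            class = "radiomic_feature_vector")
}

#' @export
print.radiomic_feature_vector <- function(x, ...) {
  cat(sprintf("<radiomic_feature_vector %s: %d features, %d NaN-replaced>\n",
              x$patch_id, length(x$values), length(x$nan_flags)))
  invisible(x)
}

#' Assemble feature vectors into a data frame
#'
#' @param fvs list of \code{radiomic_feature_vector} objects.
#' @return data.frame with columns \code{patch_id}, \code{wsi_id},
#'   \code{label} and one column per feature.
#' @export
features_to_df <- function(fvs) {
  X <- do.call(rbind, lapply(fvs, function(f) f$values))
  data.frame(patch_id = vapply(fvs, `[[`, "", "patch_id"),
             wsi_id = vapply(fvs, `[[`, "", "wsi_id"),
             label = vapply(fvs, `[[`, "", "label"),
             X, check.names = FALSE)
}

#' Fit a random-forest classifier on radiomic features and rank them
#'
#' Impurity importances are normalized to sum 1 and sorted non-increasing;
#' the top \code{top_k} (default 5) features are flagged as selected.
#'
#' @param features list of \code{radiomic_feature_vector} or the data frame
#'   from \code{\link{features_to_df}}.
#' @param labels optional label vector (defaults to the embedded labels).
#' @param n_trees number of trees (default 500).
#' @param top_k size of the selected feature set.
#' @param seed RNG seed (forest is deterministic given the seed).
#' @return list with \code{model} (a ranger fit) and \code{ranking}
#'   (class \code{feature_ranking}: data.frame \code{feature},
#'   \code{importance}, \code{selected}).
#' @export
fit_rf_classifier <- function(features, labels = NULL, n_trees = 500L,
                              top_k = 5L, seed = 1L) {
  df <- if (is.data.frame(features)) features else features_to_df(features)
  if (is.null(labels)) labels <- df$label
  y <- factor(labels)
  if (nlevels(y) < 2L)
    stop("degenerate labels: need at least 2 classes")
  X <- df[, radiomic_feature_manifest(), drop = FALSE]
  dat <- data.frame(.class = y, X, check.names = FALSE)
  fit <- ranger::ranger(dependent.variable.name = ".class", data = dat,
                        num.trees = n_trees, importance = "impurity",
                        probability = TRUE, seed = seed, num.threads = 1L)
  imp <- fit$variable.importance
  imp <- pmax(imp, 0)
  imp <- if (sum(imp) > 0) imp / sum(imp) else rep(1 / length(imp), length(imp))
  ord <- order(imp, decreasing = TRUE)
  ranking <- data.frame(feature = names(imp)[ord], importance = as.numeric(imp[ord]),
                        selected = seq_along(imp) <= top_k,
                        row.names = NULL)
  class(ranking) <- c("feature_ranking", "data.frame")
  attr(ranking, "top_k") <- as.integer(top_k)
  list(model = fit, ranking = ranking)
}

#' Grouped (slide-level) cross-validated AUC of the radiomic forest
#'
#' Folds are made at the slide (wsi_id) level so patches from one slide
#' never straddle a train/test split.
#'
#' @param features list of feature vectors or their data frame.
#' @param k folds (default 5).
#' @param n_trees forest size per fold.
#' @param seed RNG seed.
#' @return list with pooled out-of-fold \code{auc} and the out-of-fold
#'   \code{scores} data frame.
#' @export
rf_group_cv_auc <- function(features, k = 5L, n_trees = 200L, seed = 1L) {
  df <- if (is.data.frame(features)) features else features_to_df(features)
  y <- factor(df$label)
  if (nlevels(y) != 2L) stop("grouped CV AUC is defined for 2 classes")
  wsi_lab <- tapply(as.character(y), df$wsi_id, function(v) v[1L])
  folds <- make_folds(names(wsi_lab), as.character(wsi_lab), k = k, seed = seed)
  pos <- levels(y)[2L]
  scores <- rep(NA_real_, nrow(df))
  for (f in folds) {
    tr <- df$wsi_id %in% f$train_wsi_ids
    te <- df$wsi_id %in% f$test_wsi_ids
    fit <- fit_rf_classifier(df[tr, , drop = FALSE], n_trees = n_trees, seed = seed)
    pr <- predict(fit$model, data = df[te, radiomic_feature_manifest(), drop = FALSE],
                  num.threads = 1L)$predictions
    scores[te] <- pr[, pos]
  }
  list(auc = roc_auc(df$label == pos, scores),
       scores = data.frame(patch_id = df$patch_id, wsi_id = df$wsi_id,
                           label = df$label, score = scores))
}

#' Per-feature class summaries and density curves
#'
#' @param features list of feature vectors or their data frame.
#' @param labels optional label vector.
#' @param n_density points per density curve.
#' @return list with \code{table} (one row per feature: class means, mean
#'   difference, standardized mean difference) and \code{densities} (per
#'   feature, per class, \code{x}/\code{y} curves).
#' @export
feature_group_summary <- function(features, labels = NULL, n_density = 64L) {
  df <- if (is.data.frame(features)) features else features_to_df(features)
  if (is.null(labels)) labels <- df$label
  y <- factor(labels)
  feats <- radiomic_feature_manifest()
  cls <- levels(y)
  means <- sapply(cls, function(cl) colMeans(df[y == cl, feats, drop = FALSE]))
  sds <- sapply(cls, function(cl) apply(df[y == cl, feats, drop = FALSE], 2L, stats::sd))
  if (length(cls) == 2L) {
    delta <- means[, 2L] - means[, 1L]
    pooled <- sqrt(rowMeans(sds^2))
    smd <- ifelse(pooled > 0, delta / pooled, 0)
  } else {
    delta <- rep(0, length(feats)); smd <- rep(0, length(feats))
  }
  tab <- data.frame(feature = feats, means, delta = delta, smd = smd,
                    check.names = FALSE, row.names = NULL)
  densities <- lapply(feats, function(fn) {
    lapply(setNames(cls, cls), function(cl) {
      v <- df[y == cl, fn]
      if (length(unique(v)) < 2L) list(x = unique(v), y = 1)
      else { d <- stats::density(v, n = n_density); list(x = d$x, y = d$y) }
    })
  })
  names(densities) <- feats
  list(table = tab, densities = densities)
}
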