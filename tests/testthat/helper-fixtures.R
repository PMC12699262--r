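# Shared fixtures and small independent oracles used across the suite.

iou <- function(a, b) sum(a & b) / sum(a | b)

# A horizontal band mask (rows r0..r1 set).
band_mask <- function(h, w, r0, r1) {
  m <- matrix(0L, h, w)
  m[r0:r1, ] <- 1L
  m
}

# A diagonal band mask of half-width hw around the main diagonal.
diag_band_mask <- function(n, hw = 40L) {
  m <- matrix(0L, n, n)
  for (c0 in seq_len(n)) {
    rr <- max(1L, c0 - hw):min(n, c0 + hw)
    m[rr, c0] <- 1L
  }
  m
}

# Small, fast segmentation config used by the fixture-scale tests.
test_seg_config <- function(seed = 1L) {
  seg_config(felzenszwalb_scale = 150, felzenszwalb_min_size = 120,
             n_channels = 10L, n_conv_blocks = 1L, max_iterations = 60L,
             learning_rate = 0.1, momentum = 0.9, seed = seed)
}

# Small synthetic sample emulating the three-layer skin geometry; any
# generator parameter can be overridden through ...
test_skin_params <- function(seed = 1L, ...) {
  args <- list(image_height = 96L, image_width = 96L,
               corneum_thickness = 16, epidermis_thickness = 26,
               ridge_amplitude = 6, ridge_wavelength = 48,
               nucleus_density = 60, seed = seed)
  ov <- list(...)
  args[names(ov)] <- ov
  do.call(synthetic_skin_params, args)
}

# Beer-Lambert forward model: render an image from a stain matrix and
# per-pixel concentrations (the independent oracle for stain estimation).
forward_stain_image <- function(M, C, h, w) {
  od <- C %*% t(M)
  img <- array(0, c(h, w, 3L))
  for (k in 1:3) img[, , k] <- matrix(10^(-od[, k]) * 256 - 1, h, w)
  img
}

unit_cols <- function(M) sweep(M, 2L, sqrt(colSums(M^2)), `/`)

vec_angle_deg <- function(a, b) acos(pmin(abs(sum(a * b)), 1)) * 180 / pi

# Wrap a bare layer list as a cnn_model so gradcam/predict can use it.
manual_cnn_model <- function(net, classes, input_size) {
  structure(list(net = net, config = train_config(input_size = input_size,
                                                  n_classes = length(classes)),
                 classes = classes, fold_id = NA_integer_,
                 loss_history = numeric(0), skipped = FALSE),
            class = "cnn_model")
}

# Hand-derivable toy classifier: a 3x3 conv whose kernel is the identity on
# input channel 1, global average pooling, and a linear head with weight w
# on the positive class.
toy_model_acc <- function(w = 1, n = 16L) {
  conv <- episcope:::nn_init_conv(3L, 1L, 3L)
  conv$W[] <- 0
  conv$W[5L, 1L] <- 1          # center tap of channel 1
  conv$b[] <- 0
  lin <- episcope:::nn_init_linear(1L, 2L)
  lin$W[] <- 0; lin$W[2L, 1L] <- w; lin$b[] <- 0
  manual_cnn_model(list(conv, episcope:::nn_gap(), lin),
                   classes = c("neg", "pos"), input_size = n)
}

toy_patch_acc <- function(n = 16L, seed = 31L) {
  set.seed(seed)
  patch(array(runif(n * n * 3, 0, 255), c(n, n, 3L)), matrix(1L, n, n), 2L,
        c(n / 2, n / 2), "p", "l", "w")
}

# Numeric finite-difference gradient of f at x (array), central differences.
num_grad <- function(f, x, eps = 1e-5) {
  g <- array(0, dim(x) %||% length(x))
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

`%||%` <- function(a, b) if (is.null(a)) b else a
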