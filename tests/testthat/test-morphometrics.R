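# Dense brute-force distance oracle: minimum distance from each point to a
# very finely resampled target curve (point-to-point), independent of the
# package's point-to-segment code.
dense_min_dist <- function(points, target_fun, t_range, n_dense = 200000L) {
  tt <- seq(t_range[1L], t_range[2L], length.out = n_dense)
  trg <- target_fun(tt)
  vapply(seq_len(nrow(points)), function(i) {
    sqrt(min((trg[, 1L] - points[i, 1L])^2 + (trg[, 2L] - points[i, 2L])^2))
  }, numeric(1))
}

test_that("point-to-polyline distance handles feet, endpoints and random cases", {
  seg <- rbind(c(3, 0), c(3, 10))
  expect_equal(shortest_distance(c(0, 0), seg), 3)
  expect_equal(shortest_distance(c(0, -5), seg), sqrt(34), tolerance = 1e-9)
  # random polylines vs dense-resampling oracle
  set.seed(21)
  for (rep in 1:5) {
    poly <- cbind(cumsum(runif(8, 0.5, 2)), cumsum(runif(8, -1, 2)))
    pts <- cbind(runif(20, -2, 12), runif(20, -2, 12))
    d_imp <- vapply(seq_len(nrow(pts)), function(i) shortest_distance(pts[i, ], poly),
                    numeric(1))
    # dense piecewise resampling of the same polyline
    dense <- do.call(rbind, lapply(seq_len(nrow(poly) - 1L), function(j) {
      t <- seq(0, 1, length.out = 20000L)
      cbind(poly[j, 1L] + t * (poly[j + 1L, 1L] - poly[j, 1L]),
            poly[j, 2L] + t * (poly[j + 1L, 2L] - poly[j, 2L]))
    }))
    d_or <- vapply(seq_len(nrow(pts)), function(i)
      sqrt(min((dense[, 1L] - pts[i, 1L])^2 + (dense[, 2L] - pts[i, 2L])^2)),
      numeric(1))
    expect_lt(max(abs(d_imp - d_or)), 1e-6)
  }
})

test_that("parallel lines give thickness = gap and score = 0 exactly", {
  es <- boundary_polyline(cbind(10, seq(0, 1024)), "ES")
  eb <- boundary_polyline(cbind(50, seq(0, 1024)), "EB")
  r <- compute_morphometrics(eb, es)
  expect_equal(r$thickness, 40)
  expect_equal(r$rete_ridge_score, 0)
  expect_equal(r$m, 1025L)
  expect_equal(r$n, 1025L)
  # statistics are recomputable from the per-point lists
  expect_equal(mean(r$per_point_distances$es_to_eb), r$thickness)
  d <- r$per_point_distances$eb_to_es
  expect_equal(sum((d - mean(d))^2) / length(d), r$rete_ridge_score)
})

test_that("sinusoidal junction statistics match the dense analytic oracle", {
  A <- 10; wl <- 128; offset <- 50; len <- 1024
  eb_fun <- function(x) cbind(offset + A * sin(2 * pi * x / wl), x)
  # implementation input: polylines resampled at 1-px arc steps
  xs <- seq(0, len, by = 0.25)
  eb <- boundary_polyline(episcope:::resample_polyline(eb_fun(xs), 1), "EB")
  es <- boundary_polyline(cbind(0, seq(0, len)), "ES")
  r <- compute_morphometrics(eb, es)
  # oracle: same sampling convention, distances by dense enumeration
  d_es <- dense_min_dist(es$points, eb_fun, c(-50, len + 50))
  d_eb <- vapply(seq_len(nrow(eb$points)), function(i)
    abs(eb$points[i, 1L]), numeric(1))          # ES is the line row = 0
  thick_or <- mean(d_es)
  score_or <- sum((d_eb - mean(d_eb))^2) / length(d_eb)
  expect_lt(abs(r$thickness - thick_or) / thick_or, 0.02)
  expect_lt(abs(r$rete_ridge_score - score_or) / score_or, 0.02)
  # the definition is asymmetric: swapping the boundaries changes both
  r_sw <- compute_morphometrics(es, eb)
  expect_false(isTRUE(all.equal(r_sw$thickness, r$thickness)))
  expect_false(isTRUE(all.equal(r_sw$rete_ridge_score, r$rete_ridge_score)))
})

test_that("both statistics are rigid-motion invariant", {
  A <- 8; wl <- 96; len <- 512
  eb_pts <- episcope:::resample_polyline(cbind(40 + A * sin(2 * pi * (0:len) / wl), 0:len), 1)
  es_pts <- cbind(0, seq(0, len))
  r0 <- compute_morphometrics(boundary_polyline(eb_pts, "EB"),
                              boundary_polyline(es_pts, "ES"))
  th <- 33 * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2L)
  move <- function(p) sweep(p %*% R, 2L, c(123.4, -56.7), `+`)
  r1 <- compute_morphometrics(boundary_polyline(move(eb_pts), "EB"),
                              boundary_polyline(move(es_pts), "ES"))
  expect_lt(abs(r1$thickness - r0$thickness) / r0$thickness, 1e-6)
  expect_lt(abs(r1$rete_ridge_score - r0$rete_ridge_score) / max(r0$rete_ridge_score, 1), 1e-6)
})

test_that("boundary extraction recovers the two sides and assigns roles", {
  # flat band: the two horizontal edges, within 1 px of ground truth
  s <- generate_sample(test_skin_params(seed = 6L, ridge_amplitude = 0))
  b <- extract_boundaries(s$epidermis_mask, s$image)
  true_es_row <- s$params$corneum_thickness + 0.5
  true_eb_row <- s$params$corneum_thickness + s$params$epidermis_thickness + 0.5
  expect_lt(abs(mean(b$es$points[, 1L]) - true_es_row), 1)
  expect_lt(abs(mean(b$eb$points[, 1L]) - true_eb_row), 1)
  # sinusoidal sample: EB must be the undulating side under both rules
  s2 <- generate_sample(test_skin_params(seed = 6L))
  b_stain <- extract_boundaries(s2$epidermis_mask, s2$image)
  b_undul <- extract_boundaries(s2$epidermis_mask, NULL)
  for (b2 in list(b_stain, b_undul)) {
    expect_gt(stats::sd(b2$eb$points[, 1L]), stats::sd(b2$es$points[, 1L]))
  }
  # disk mask has no two opposite sides
  disk <- matrix(0L, 60L, 60L)
  disk[(row(disk) - 30)^2 + (col(disk) - 30)^2 <= 400] <- 1L
  expect_error(extract_boundaries(disk), "topology")
})

test_that("rete ridge score increases strictly with ridge amplitude", {
  scores <- vapply(c(0, 5, 10, 15), function(a) {
    s <- generate_sample(test_skin_params(seed = 8L, ridge_amplitude = a,
                                          epidermis_thickness = 26))
    eb <- episcope:::resample_polyline(s$eb_polyline$points, 1)
    es <- episcope:::resample_polyline(s$es_polyline$points, 1)
    compute_morphometrics(boundary_polyline(eb, "EB"),
                          boundary_polyline(es, "ES"))$rete_ridge_score
  }, numeric(1))
  expect_true(all(diff(scores) > 0))
})

test_that("degenerate polylines are rejected", {
  expect_error(compute_morphometrics(rbind(c(0, 0)), rbind(c(1, 0), c(1, 1))),
               "insufficient|at least 2")
})
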