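test_that("segmentation keeps only the largest component", {
  img <- matrix(0, 60, 60)
  img[10:30, 10:34] <- 1          # area 525
  img[45:51, 45:51] <- 1          # area 49
  mask <- segment_epithelium(img, 0.5)
  expect_equal(sum(mask), 21 * 25)
  expect_false(any(mask[45:51, 45:51]))
  expect_error(segment_epithelium(matrix(0, 5, 5), 0.5),
               class = "budmorph_input_error")
})

test_that("segmentation of a noisy rasterised bud recovers the boundary", {
  shp <- make_bud_shape(base = c(20, 14), buds = list(c(0.5, 8, 0.5)))
  ras <- rasterize(shp, resolution = 1, noise_sigma = 0.05, seed = 3,
                   distractors = 2)
  mask <- segment_epithelium(ras$image, 0.5)
  border <- extract_border(mask, origin = ras$origin,
                           pixel_size = ras$pixel_size)
  truth <- curve_resample(shp, 600)
  # directed Hausdorff border -> truth
  d <- vapply(seq_len(nrow(border)), function(i)
    sqrt(min((truth[, 1] - border[i, 1])^2 + (truth[, 2] - border[i, 2])^2)), 0)
  expect_lt(max(d), 2)
})

test_that("extract_border traces simple shapes with analytic measures", {
  sq <- matrix(FALSE, 30, 30)
  sq[6:25, 6:25] <- TRUE          # 20 x 20 square
  b <- extract_border(sq)
  per <- sum(sqrt(rowSums((b[c(2:nrow(b), 1), ] - b)^2)))
  expect_equal(per, 4 * 19, tolerance = 0.05)   # pixel-centre perimeter
  expect_gt(budmorph:::polygon_signed_area(b), 0)          # counter-clockwise
  one <- matrix(FALSE, 9, 9); one[5, 5] <- TRUE
  expect_error(extract_border(one), class = "budmorph_geometry_error")
  two <- matrix(FALSE, 9, 9); two[2:3, 2:3] <- TRUE; two[7:8, 7:8] <- TRUE
  expect_error(extract_border(two), class = "budmorph_input_error")
  disc <- rasterize(boundary_curve(circle_points(300, 30)), resolution = 2)
  bd <- extract_border(disc$image > 0.5, origin = disc$origin,
                       pixel_size = disc$pixel_size)
  # pixel-centre tracing biases the radius by half a pixel
  expect_equal(abs(budmorph:::polygon_signed_area(bd)), pi * 30^2, tolerance = 0.02)
})

test_that("displacement field: dilation, identity, and analytic ellipse oracle", {
  c10 <- fit_boundary_spline(circle_points(240, 10))
  c11 <- fit_boundary_spline(circle_points(240, 11))
  df <- displacement_field(c10, c11, n_points = 100)
  expect_true(all(abs(df$magnitudes - 1) < 1e-3))
  df0 <- displacement_field(c10, c10, n_points = 50)
  expect_true(all(abs(df0$magnitudes) < 1e-6))
  # ellipse (20,10) -> (22,11): oracle = analytic ray/ellipse intersection
  e1 <- fit_boundary_spline(ellipse_points(300, 20, 10))
  e2 <- fit_boundary_spline(ellipse_points(300, 22, 11))
  df_e <- displacement_field(e1, e2, n_points = 80)
  L <- curve_length(e1)
  s <- df_e$arc
  oracle <- vapply(seq_along(s), function(i) {
    p <- df_e$base_points[i, ]; d <- df_e$normals[i, ]
    A <- (d[1] / 22)^2 + (d[2] / 11)^2
    B <- 2 * (p[1] * d[1] / 22^2 + p[2] * d[2] / 11^2)
    C <- (p[1] / 22)^2 + (p[2] / 11)^2 - 1
    (-B + sqrt(B^2 - 4 * A * C)) / (2 * A)
  }, 0)
  expect_lt(max(abs(df_e$magnitudes - oracle)) / max(oracle), 0.01)
})

test_that("growth field zeroes inward and missing vectors only", {
  df <- structure(list(base_points = matrix(0, 3, 2),
                       normals = matrix(rep(c(1, 0), each = 3), 3, 2),
                       magnitudes = c(1, -0.5, 2), arc = c(0, 1, 2),
                       vectors = NULL, length = 3),
                  class = "displacement_field")
  gf <- growth_field(df)
  expect_equal(gf$magnitudes, c(1, 0, 2))
  df$magnitudes <- c(-1, NA, -3)
  expect_equal(growth_field(df)$magnitudes, c(0, 0, 0))
  df$magnitudes <- c(1, 2, 3)
  expect_equal(growth_field(df)$magnitudes, c(1, 2, 3))
})

test_that("growth-field magnitudes are invariant under rigid motion", {
  shp <- make_bud_shape(base = c(15, 10), buds = list(c(1, 5, 0.5)))
  tl <- make_timelapse(shp, growth_centres = c(10), rates = 1.5, widths = 8,
                       n_frames = 2, n_points = 150)
  gf0 <- growth_field(displacement_field(tl$frames[[1]], tl$frames[[2]],
                                         n_points = 80))
  rot <- 0.8; Rm <- matrix(c(cos(rot), sin(rot), -sin(rot), cos(rot)), 2)
  mv <- function(crv) fit_boundary_spline(
    sweep(crv$points %*% t(Rm), 2, c(5, -3), "+"), check_simple = FALSE)
  gf1 <- growth_field(displacement_field(mv(tl$frames[[1]]), mv(tl$frames[[2]]),
                                         n_points = 80))
  expect_equal(gf1$magnitudes, gf0$magnitudes, tolerance = 1e-2)
})

test_that("applying the displacement field reproduces the next frame", {
  shp <- make_bud_shape(base = c(15, 10), buds = list(c(0, 5, 0.5)))
  tl <- make_timelapse(shp, growth_centres = c(0), rates = 1.2, widths = 6,
                       n_frames = 2, n_points = 200)
  df <- displacement_field(tl$frames[[1]], tl$frames[[2]], n_points = 150)
  moved <- df$base_points + df$vectors
  truth <- curve_resample(tl$frames[[2]], 600)
  d <- vapply(seq_len(nrow(moved)), function(i)
    sqrt(min((truth[, 1] - moved[i, 1])^2 + (truth[, 2] - moved[i, 2])^2)), 0)
  bb <- apply(shp$points, 2, range)
  expect_lt(max(d), 0.02 * sqrt(sum((bb[2, ] - bb[1, ])^2)))
})

test_that("interbud distances with edge-discard rule", {
  b1 <- boundary_curve(circle_points(120, 5, center = c(0, 0)))
  b2 <- boundary_curve(circle_points(120, 5, center = c(20, 0)))
  res <- interbud_min_distance(list(b1, b2),
                               image_extent = c(-60, 80, -60, 60))
  expect_equal(res$overall_min, 10, tolerance = 1e-2)
  expect_error(interbud_min_distance(list(b1)), class = "budmorph_input_error")
  # image edge 3 units from bud 1's left rim: its outward-facing points drop
  res2 <- interbud_min_distance(list(b1, b2), image_extent = c(-8, 80, -60, 60))
  expect_lt(res2$per_bud$n_retained[1], res2$per_bud$n_retained[2])
  expect_equal(res2$overall_min, 10, tolerance = 1e-2)
  # three buds with pairwise gaps {10, 4, 7}: overall minimum 4, matching a
  # brute-force oracle over all point pairs
  b3 <- boundary_curve(circle_points(120, 5, center = c(34, 0)))   # gap 4 to b2
  res3 <- interbud_min_distance(list(b1, b2, b3),
                                image_extent = c(-100, 140, -100, 100))
  expect_equal(res3$overall_min, 4, tolerance = 1e-2)
  polys <- lapply(list(b1, b2, b3), curve_resample, n = 200)
  oracle <- min(vapply(1:3, function(i) {
    other <- do.call(rbind, polys[-i])
    min(vapply(seq_len(200), function(k)
      min(sqrt((other[, 1] - polys[[i]][k, 1])^2 +
                 (other[, 2] - polys[[i]][k, 2])^2)), 0))
  }, 0))
  expect_equal(res3$overall_min, oracle, tolerance = 1e-9)
})

test_that("end-to-end growth-field recovery from a synthetic time-lapse", {
  shp <- make_bud_shape(base = c(22, 15), buds = list(c(0, 8, 0.5), c(pi, 8, 0.5)))
  L <- curve_length(shp)
  tl <- make_timelapse(shp, growth_centres = c(0, L / 2), rates = c(2, 1.4),
                       widths = c(9, 9), n_frames = 3, n_points = 250)
  for (fr in 1:2) {
    # rasterise -> segment -> border -> spline -> displacement -> growth
    r1 <- rasterize(tl$frames[[fr]], resolution = 2, noise_sigma = 0.04, seed = fr)
    r2 <- rasterize(tl$frames[[fr + 1]], resolution = 2, noise_sigma = 0.04,
                    seed = fr + 10)
    c1 <- fit_boundary_spline(extract_border(segment_epithelium(r1$image, 0.5),
                                             origin = r1$origin,
                                             pixel_size = r1$pixel_size))
    c2 <- fit_boundary_spline(extract_border(segment_epithelium(r2$image, 0.5),
                                             origin = r2$origin,
                                             pixel_size = r2$pixel_size))
    gf <- growth_field(displacement_field(c1, c2, n_points = 200))
    truth <- tl$truth[[fr]]
    # align by nearest ground-truth base point
    idx <- vapply(seq_len(nrow(gf$base_points)), function(i)
      which.min((truth$base_points[, 1] - gf$base_points[i, 1])^2 +
                  (truth$base_points[, 2] - gf$base_points[i, 2])^2), 0L)
    expect_gt(stats::cor(gf$magnitudes, truth$magnitudes[idx]), 0.95)
  }
})
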