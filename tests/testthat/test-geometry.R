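test_that("periodic spline fit reproduces a dense circle to 1e-3", {
  crv <- fit_boundary_spline(circle_points(200, r = 50))
  s <- seq(0, curve_length(crv), length.out = 500)
  pts <- curve_point(crv, s)
  expect_lt(max(abs(sqrt(rowSums(pts^2)) - 50)), 1e-3)
  expect_equal(curve_length(crv), 2 * pi * 50, tolerance = 1e-4)
  # outward normal of a CCW circle is radial
  nr <- curve_normal(crv, s[1:10])
  rad <- pts[1:10, ] / sqrt(rowSums(pts[1:10, ]^2))
  expect_lt(max(abs(nr - rad)), 1e-3)
  expect_equal(mean(curve_curvature(crv, s[1:50])), 1 / 50, tolerance = 1e-3)
})

test_that("spline fit input validation", {
  expect_error(fit_boundary_spline(circle_points(3)), "points")
  bow_tie <- rbind(c(0, 0), c(2, 2), c(2, 0), c(0, 2), c(0.1, 1.8),
                   c(0.05, 1), c(0.02, 0.5))
  expect_error(boundary_curve(bow_tie), class = "budmorph_geometry_error")
})

test_that("noisy ellipse fit smooths below the noise level", {
  set.seed(7)
  th <- seq(0, 2 * pi, length.out = 241)[-241]
  r_noise <- stats::rnorm(240, 0, 0.5)
  pts <- cbind((20 + r_noise) * cos(th), (10 + r_noise / 2) * sin(th))
  crv <- fit_boundary_spline(pts, check_simple = FALSE)
  # oracle: dense point-to-curve distance
  dense <- curve_point(crv, seq(0, curve_length(crv), length.out = 4000))
  d <- vapply(seq_len(nrow(pts)), function(i)
    sqrt(min((dense[, 1] - pts[i, 1])^2 + (dense[, 2] - pts[i, 2])^2)), 0)
  expect_lt(sqrt(mean(d^2)), 0.5)
})

test_that("mesenchyme ellipse from second moments: closed-form cases", {
  # uniform ellipse second moments are (a^2/4, b^2/4), so r_i = alpha * (a, b)
  e <- mesenchyme_ellipse(boundary_curve(ellipse_points(400, 10, 5)), alpha = 3)
  expect_equal(e$semi_axes, c(30, 15), tolerance = 2e-3)
  expect_equal(e$center, c(0, 0), tolerance = 1e-6)
  # disc: circle of radius alpha * r for any alpha, by symmetry
  d2 <- mesenchyme_ellipse(boundary_curve(circle_points(300, 8)), alpha = 2)
  expect_equal(d2$semi_axes, c(16, 16), tolerance = 1e-2)
  # doubling alpha doubles both semi-axes, centre unchanged
  e2 <- mesenchyme_ellipse(boundary_curve(ellipse_points(400, 10, 5)), alpha = 6)
  expect_equal(e2$semi_axes, 2 * e$semi_axes, tolerance = 1e-9)
  expect_equal(e2$center, e$center)
})

test_that("mesenchyme ellipse is equivariant under rigid motions", {
  shp <- make_bud_shape(base = c(12, 8), buds = list(c(0.7, 5, 0.5)),
                        fit_spline = FALSE)
  e0 <- mesenchyme_ellipse(shp, alpha = 3)
  for (rot in c(0.4, 1.9)) {
    Rm <- matrix(c(cos(rot), sin(rot), -sin(rot), cos(rot)), 2)
    shift <- c(11, -7)
    moved <- boundary_curve(sweep(shp$points %*% t(Rm), 2, shift, "+"),
                            check_simple = FALSE)
    e1 <- mesenchyme_ellipse(moved, alpha = 3)
    expect_equal(e1$semi_axes, e0$semi_axes, tolerance = 1e-6)
    expect_equal(e1$center, as.numeric(Rm %*% e0$center + shift),
                 tolerance = 1e-6)
  }
})

test_that("second moments are sampling-density invariant and non-negative", {
  shp <- make_bud_shape(base = c(12, 8), buds = list(c(2, 4, 0.4)))
  e_lo <- mesenchyme_ellipse(shp, n_points = 256)
  e_hi <- mesenchyme_ellipse(shp, n_points = 2048)
  expect_equal(e_lo$semi_axes, e_hi$semi_axes, tolerance = 1e-3)
  expect_true(all(e_lo$semi_axes > 0))
  # boundary-point mass option also works and differs from filled mass
  e_b <- mesenchyme_ellipse(shp, mass = "boundary")
  expect_true(all(e_b$semi_axes > 0))
})

test_that("remove_stalk re-closes across the cut with a chord", {
  r <- 20
  crv <- boundary_curve(circle_points(720, r))
  L <- curve_length(crv)
  # empty interval: identity
  expect_equal(remove_stalk(crv)$points, crv$points)
  # 10% arc removed: area = full disc minus the circular segment
  crv$stalk_interval <- c(0.2 * L, 0.3 * L)
  cut <- remove_stalk(crv)
  theta <- 2 * pi * 0.1
  seg_area <- r^2 / 2 * (theta - sin(theta))
  expect_equal(abs(budmorph:::polygon_signed_area(cut$points)), pi * r^2 - seg_area,
               tolerance = 1e-2)
  expect_lt(abs(budmorph:::polygon_signed_area(cut$points)),
            abs(budmorph:::polygon_signed_area(crv$points)))
  # full-curve interval is rejected
  crv$stalk_interval <- c(0, L)
  expect_error(remove_stalk(crv), class = "budmorph_input_error")
})

test_that("build_mesh produces a labelled conforming mesh at target size", {
  dom <- two_layer_domain(boundary_curve(ellipse_points(400, 10, 5)))
  mesh <- build_mesh(dom, 1)
  expect_setequal(unique(mesh$subdomain), c("epithelium", "mesenchyme"))
  # interface is a closed loop of epithelial-boundary nodes
  expect_gt(length(mesh$interface_nodes), 12)
  ip <- mesh$nodes[mesh$interface_nodes, ]
  expect_lt(max(abs(sqrt((ip[, 1] / 10)^2 + (ip[, 2] / 5)^2) - 1)), 0.02)
  expect_true(abs(mesh$median_edge - 1) < 0.25)
  # subdomain areas match the analytic areas within 1%
  areas <- abs(budmorph:::mesh_areas(mesh))
  a_epi <- sum(areas[mesh$subdomain == "epithelium"])
  a_mes <- sum(areas[mesh$subdomain == "mesenchyme"])
  expect_equal(a_epi, pi * 10 * 5, tolerance = 0.01)
  expect_equal(a_mes, pi * 30 * 15 - pi * 10 * 5, tolerance = 0.01)
})

test_that("mesh refinement scales triangle count ~4x per halving", {
  dom <- small_bud_domain()
  n1 <- nrow(build_mesh(dom, 2)$triangles)
  n2 <- nrow(build_mesh(dom, 1)$triangles)
  expect_gt(n2 / n1, 4 * 0.7)
  expect_lt(n2 / n1, 4 * 1.3)
})

test_that("invalid domains are rejected", {
  big <- boundary_curve(circle_points(100, 20))
  small_ell <- ellipse2d(c(0, 0), c(10, 8))
  expect_error(two_layer_domain(big, small_ell),
               class = "budmorph_geometry_error")
  dom <- small_bud_domain()
  expect_error(build_mesh(dom, -1), class = "budmorph_input_error")
})

test_that("curve CSV and time-lapse JSON round-trip", {
  crv <- make_bud_shape(base = c(10, 6), buds = list(c(1, 3, 0.5)))
  f <- withr::local_tempfile(fileext = ".csv")
  write_boundary_csv(crv, f)
  back <- read_boundary_csv(f)
  expect_equal(back$points, crv$points, tolerance = 1e-12)
  tl <- make_timelapse(crv, growth_centres = 5, rates = 0.5, widths = 4,
                       n_frames = 3, n_points = 80)
  fj <- withr::local_tempfile(fileext = ".json")
  write_timelapse_json(tl, fj)
  tl2 <- read_timelapse_json(fj)
  expect_equal(length(tl2$frames), 3)
  expect_equal(tl2$timestamps, c(0, 2, 4))
  expect_equal(tl2$frames[[2]]$points, tl$frames[[2]]$points, tolerance = 1e-9)
})

test_that("gmsh export writes a well-formed v2 file", {
  mesh <- build_mesh(small_bud_domain(), 3)
  f <- withr::local_tempfile(fileext = ".msh")
  write_msh(mesh, f)
  lines <- readLines(f)
  expect_equal(lines[1], "$MeshFormat")
  expect_equal(as.integer(lines[5]), nrow(mesh$nodes))
})
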