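test_that("tip detection: circle, three-lobed flower, infinite threshold", {
  circ <- fit_boundary_spline(circle_points(300, 20))
  expect_equal(nrow(detect_tips(circ)), 0)
  th <- seq(0, 2 * pi, length.out = 361)[-361]
  r <- 10 + 2 * cos(3 * th)
  flower <- fit_boundary_spline(cbind(r * cos(th), r * sin(th)))
  tips <- detect_tips(flower)
  expect_equal(nrow(tips), 3)
  ang <- sort(atan2(tips$y, tips$x) %% (2 * pi))
  expect_equal(ang, c(0, 2 * pi / 3, 4 * pi / 3), tolerance = 0.05)
  expect_equal(nrow(detect_tips(flower, curvature_threshold = Inf)), 0)
})

test_that("elongation classification follows the three printed criteria", {
  s <- seq(0, 40, length.out = 201)
  flat <- make_profile(s, rep(1, 201), closed = FALSE, 40)
  expect_false(classify_elongation(list(flat, flat))$elongation)
  single <- make_profile(s, 1 + 19 * exp(-0.5 * ((s - 20) / 4)^2), FALSE, 40)
  res <- classify_elongation(list(single, single))
  expect_true(res$elongation)
  expect_true(res$per_tip[[1]]$amplitude)
  expect_true(res$per_tip[[1]]$single_peak)
  expect_true(res$per_tip[[1]]$centred)
  # off-centre peak fails the centring criterion
  off <- make_profile(s, 1 + 19 * exp(-0.5 * ((s - 8) / 4)^2), FALSE, 40)
  res_off <- classify_elongation(list(off, off))
  expect_false(res_off$elongation)
  expect_false(res_off$per_tip[[1]]$centred)
  # two peaks on one tip fail the peak-count criterion
  two <- make_profile(s, 1 + 19 * (exp(-0.5 * ((s - 12) / 3)^2) +
                                     exp(-0.5 * ((s - 28) / 3)^2)), FALSE, 40)
  res2 <- classify_elongation(list(single, two))
  expect_false(res2$elongation)
  expect_false(res2$per_tip[[2]]$single_peak)
  expect_error(classify_elongation(list()), class = "budmorph_input_error")
})

test_that("Lambda is the elongating fraction", {
  mk <- function(flag) structure(list(elongation = flag), class = "classification_result")
  expect_equal(lambda_fraction(lapply(c(FALSE, FALSE), mk)), 0)
  expect_equal(lambda_fraction(lapply(rep(TRUE, 5), mk)), 1)
  expect_equal(lambda_fraction(lapply(c(TRUE, TRUE, TRUE, rep(FALSE, 5)), mk)),
               0.375)
  expect_error(lambda_fraction(list()), class = "budmorph_input_error")
})

test_that("grow_step: zero signal freezes the interface; constant signal dilates", {
  crv <- fit_boundary_spline(circle_points(120, 10))
  dom <- two_layer_domain(crv, alpha = 3)
  mesh <- build_mesh(dom, 2)
  n <- nrow(mesh$nodes)
  law <- growth_law(v_g = 0.04, K_g = 1, h_g = 2)
  zero_state <- structure(list(R = rep(0, n), L = rep(1, n), L1 = NULL,
                               converged = TRUE, readout_exponents = c(2L, 1L)),
                          class = "steady_state")
  gs0 <- grow_step(zero_state, dom, law, dt = 5, mesh = mesh)
  expect_equal(gs0$domain$epithelium$points, crv$points, tolerance = 1e-9)
  expect_equal(gs0$domain$mesenchyme$semi_axes, dom$mesenchyme$semi_axes + 0.2,
               tolerance = 1e-9)
  const_state <- structure(list(R = rep(1, n), L = rep(1, n), L1 = NULL,
                                converged = TRUE, readout_exponents = c(2L, 1L)),
                           class = "steady_state")
  gs1 <- grow_step(const_state, dom, law, dt = 5, mesh = mesh)
  r_new <- sqrt(rowSums(gs1$domain$epithelium$points^2))
  expect_equal(r_new, rep(10 + 0.04 * 0.5 * 5, length(r_new)), tolerance = 1e-3)
})

test_that("ligand sources: validation and uniform limit", {
  m <- fixture_T1_model()
  expect_identical(add_ligand_source(m, "uniform", rate = 0), m)
  expect_error(add_ligand_source(m, "bead", rate = 1),
               class = "budmorph_input_error")
  mesh <- build_mesh(small_bud_domain(), 3)
  # bead far outside the mesenchyme is rejected at solve time
  m_bad <- add_ligand_source(m, "bead", location = c(500, 500), rate = 1,
                             radius = 3)
  expect_error(solve_steady(m_bad, mesh, seed = 1),
               class = "budmorph_input_error")
  # bead inside the epithelium (no mesenchymal mass there) is also rejected
  m_epi <- add_ligand_source(m, "bead", location = c(0, 0), rate = 1, radius = 2)
  expect_error(solve_steady(m_epi, mesh, seed = 1),
               class = "budmorph_input_error")
})

test_that("two-bud mirror domain geometry", {
  dom <- two_bud_domain(l0 = 10)
  expect_s3_class(dom$mesenchyme, "boundary_curve")
  # mirror plane at bud tip + l0/2
  expect_equal(max(dom$mesenchyme$points[, 1]), 14 + 5, tolerance = 0.05)
  # large l0: no cut, plain ellipse
  dom_far <- two_bud_domain(l0 = 200)
  expect_s3_class(dom_far$mesenchyme, "ellipse2d")
  expect_error(two_bud_domain(0), class = "budmorph_input_error")
  mesh <- build_mesh(dom, 2)
  expect_gt(mesh$min_angle, 10)
})

test_that("T5 with inactive feedback reproduces T1 exactly", {
  p0 <- fixture_parameters()$T5
  p0$b1 <- 0; p0$gamma <- 0
  dom <- two_bud_domain(l0 = 12)
  mesh <- build_mesh(dom, 2.5)
  st1 <- solve_steady(fixture_T1_model(), mesh, seed = 4, tol = 1e-7)
  st5 <- solve_steady(model_spec("T5", p0), mesh, seed = 4, tol = 1e-7)
  p1 <- signal_on_interface(st1, mesh)
  p5 <- signal_on_interface(st5, mesh)
  expect_equal(p5$values, p1$values, tolerance = 1e-4)
})
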