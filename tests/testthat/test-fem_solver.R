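test_that("non-Turing set relaxes to the uniform well-mixed fixed point", {
  # regime where the well-mixed collapse is valid: ligand decay length
  # sqrt(D_L/delta_L) ~ 160 >> domain, weak receptor-ligand coupling
  dom <- two_layer_domain(boundary_curve(circle_points(200, 14)), alpha = 3)
  mesh <- build_mesh(dom, 2)
  p3 <- parameter_set(D_R = 50, D_L = 50, rho_R = 0.02, rho_L = 0.08,
                      delta_R = 0.25, delta_L = 0.002, mu = 0.003, v = 0.01)
  m3 <- model_spec("T3", p3)
  st <- solve_steady(m3, mesh, seed = 2)
  expect_true(st$converged)
  ss <- steady_state_wellmixed(m3)
  expect_lt(max(abs(st$R - ss$R), na.rm = TRUE) / ss$R, 0.01)
  prof <- signal_on_interface(st, mesh)
  expect_lt(max(prof$values) / min(prof$values), 1.01)
})

test_that("fixture Turing set patterns the interface", {
  sol <- small_T1_solution()
  expect_true(sol$state$converged)
  prof <- signal_on_interface(sol$state, sol$mesh)
  expect_gt(max(prof$values) / max(min(prof$values), 1e-15), 1.5)
})

test_that("zero sources with zero init give the zero solution", {
  mesh <- build_mesh(small_bud_domain(), 3)
  p <- parameter_set(rho_R = 0, rho_L = 0, D_R = 1, D_L = 10,
                     delta_R = 0.1, delta_L = 0.1, mu = 0.3, v = 1)
  st <- solve_steady(model_spec("T1", p), mesh,
                     init = list(R = rep(0, sum(mesh$epi_nodes)),
                                 L = rep(0, nrow(mesh$nodes))))
  expect_true(st$converged)
  expect_equal(max(abs(st$R), na.rm = TRUE), 0)
  expect_equal(max(abs(st$L)), 0)
})

test_that("signal_on_interface: constant states, resolution independence", {
  mesh <- build_mesh(small_bud_domain(), 2)
  n <- nrow(mesh$nodes)
  fake <- structure(list(R = rep(2, n), L = rep(0.5, n), L1 = NULL,
                         converged = TRUE, readout_exponents = c(2L, 1L)),
                    class = "steady_state")
  prof <- signal_on_interface(fake, mesh, n_samples = 100)
  expect_equal(prof$values, rep(2^2 * 0.5, 100))
  # doubling n_samples leaves shared positions unchanged
  sol <- small_T1_solution()
  p1 <- signal_on_interface(sol$state, sol$mesh, n_samples = 200)
  p2 <- signal_on_interface(sol$state, sol$mesh, n_samples = 400)
  v2_at_p1 <- stats::approx(p2$arc, p2$values, xout = p1$arc)$y
  expect_lt(max(abs(v2_at_p1 - p1$values)) / max(p1$values), 1e-6)
  # unconverged states are refused
  fake$converged <- FALSE
  expect_error(signal_on_interface(fake, mesh), class = "budmorph_input_error")
})

test_that("ligand mass is conserved without reactions (zero-flux)", {
  mesh <- build_mesh(small_bud_domain(), 2.5)
  p <- parameter_set(rho_R = 0, rho_L = 0, delta_R = 0, delta_L = 0,
                     mu = 0, v = 0, D_R = 1, D_L = 10)
  n <- nrow(mesh$nodes)
  L0 <- 1 + budmorph:::perturbation_field(mesh$nodes, seed = 5)^2
  st <- solve_steady(model_spec("T1", p), mesh,
                     init = list(R = rep(1, sum(mesh$epi_nodes)), L = L0),
                     t_max = 10, tol = 0, max_steps = 50)
  ml <- budmorph:::fem_operators(mesh)$ml_all
  expect_equal(sum(ml * st$L), sum(ml * L0), tolerance = 1e-6)
})

test_that("steady interface profile is stable under mesh refinement", {
  # sanity bound on a marginally resolved small domain (quadratic elements);
  # the tight convergence statement is criterion C2 on the reference domain
  dom <- small_bud_domain()
  casc <- solve_cascade(fixture_T1_model(), dom, c(2, 1), seed = 1,
                        tol = 1e-8, element = "P2")
  p_c <- signal_on_interface(casc[["2"]]$state, casc[["2"]]$mesh)
  p_f <- signal_on_interface(casc[["1"]]$state, casc[["1"]]$mesh)
  expect_lt(max(abs(p_c$values - p_f$values)) / max(p_f$values), 0.08)
})

test_that("T2/T4 deviation approaches a limiting value at high production", {
  # as production parameters grow, the normalised signalling profile of the
  # non-Turing variants freezes (geometry effect), so Delta flattens
  dom <- small_bud_domain()
  mesh <- build_mesh(dom, 2.5)
  Efun <- function(s) 0.5 + 0 * s
  delta_at <- function(fac, variant) {
    p <- fixture_parameters()$T1
    p$rho_R <- p$rho_R * fac
    p$rho_L <- p$rho_L * fac
    mod <- model_spec(variant, p, enforce = TRUE)
    st <- solve_steady(mod, mesh, seed = 3, tol = 1e-7)
    prof <- signal_on_interface(st, mesh)
    C <- normalize_signal(prof)
    deviation(make_profile(prof$arc, C, prof$closed, prof$length),
              make_profile(prof$arc, Efun(prof$arc), prof$closed, prof$length))
  }
  for (variant in c("T2", "T4")) {
    d <- vapply(c(1, 10, 100), delta_at, 0, variant = variant)
    # Cauchy-like flattening: successive differences shrink along the ramp
    expect_lt(abs(d[3] - d[2]), abs(d[2] - d[1]) + 1e-9)
  }
})

test_that("deterministic: identical seeds give bit-identical results", {
  mesh <- build_mesh(small_bud_domain(), 3)
  st1 <- solve_steady(fixture_T1_model(), mesh, seed = 9, tol = 1e-7)
  st2 <- solve_steady(fixture_T1_model(), mesh, seed = 9, tol = 1e-7)
  expect_identical(st1$L, st2$L)
  expect_identical(st1$R, st2$R)
})
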