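# Shared lightweight fixtures for the test suite.  Heavier objects are
# memoised so that multiple test files can reuse them within one run.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_env)) assign(key, expr, envir = .fixture_env)
  get(key, envir = .fixture_env)
}

circle_points <- function(n = 200, r = 50, center = c(0, 0)) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(center[1] + r * cos(th), center[2] + r * sin(th))
}

ellipse_points <- function(n = 200, a = 10, b = 5, center = c(0, 0), rot = 0) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  x <- a * cos(th); y <- b * sin(th)
  cbind(center[1] + x * cos(rot) - y * sin(rot),
        center[2] + x * sin(rot) + y * cos(rot))
}

# small two-bud test domain (length scale ~40, cheap to mesh and solve)
small_bud_domain <- function() memo("small_bud_domain", {
  shp <- make_bud_shape(base = c(14, 9), buds = list(c(0, 6, 0.5), c(pi, 6, 0.5)))
  two_layer_domain(shp, alpha = 3)
})

fixture_T1_model <- function() model_spec("T1", fixture_parameters()$T1)
fixture_T5_model <- function() model_spec("T5", fixture_parameters()$T5)

# converged fixture T1 state on the small domain at h = 1.5
small_T1_solution <- function() memo("small_T1_solution", {
  dom <- small_bud_domain()
  mesh <- build_mesh(dom, 1.5)
  state <- solve_steady(fixture_T1_model(), mesh, seed = 1, tol = 1e-7)
  list(domain = dom, mesh = mesh, state = state)
})
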