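test_that("parameter and model constructors validate their inputs", {
  expect_error(parameter_set(D_L = -1), class = "budmorph_input_error")
  expect_error(parameter_set(m = 2, n = 2), class = "budmorph_input_error")
  expect_error(parameter_set(mu = -0.1), class = "budmorph_input_error")
  p <- fixture_parameters()$T1
  expect_error(model_spec("T2", p, enforce = FALSE), class = "budmorph_input_error")
  # enforcement coerces the structural constraints
  expect_equal(model_spec("T2", p)$params$v, 0)
  expect_equal(model_spec("T3", p)$params$D_L, p$D_R)
  expect_equal(model_spec("T4", p)$params$m, 1L)
  expect_equal(model_spec("T4", p)$readout_exponents, c(1L, 1L))
})

test_that("reaction terms: sources at zero, T2 differs from T1 by v*S", {
  p <- fixture_parameters()$T1
  m1 <- model_spec("T1", p)
  r0 <- reaction_terms(m1, 0, 0, subdomain = "epithelium")
  expect_equal(r0$dR, p$rho_R)
  expect_equal(r0$dL, 0)
  rm0 <- reaction_terms(m1, 0, 0, subdomain = "mesenchyme")
  expect_equal(rm0$dL, p$rho_L)
  R <- 0.7; L <- 1.3
  m2 <- model_spec("T2", p)
  d1 <- reaction_terms(m1, R, L, subdomain = "epithelium")
  d2 <- reaction_terms(m2, R, L, subdomain = "epithelium")
  expect_equal(d1$dR - d2$dR, p$v * R^2 * L, tolerance = 1e-12)
  expect_equal(d1$dL, d2$dL)
  expect_error(reaction_terms(m1, -1, 0), class = "budmorph_input_error")
})

test_that("well-mixed steady state solves the collapsed system", {
  # mu = v = 0: linear, decoupled closed form
  p0 <- parameter_set(D_R = 1, D_L = 10, rho_R = 2, rho_L = 3,
                      delta_R = 0.5, delta_L = 0.25, mu = 0, v = 0)
  ss0 <- steady_state_wellmixed(model_spec("T1", p0))
  expect_equal(ss0$R, 4, tolerance = 1e-10)
  expect_equal(ss0$L, 12, tolerance = 1e-10)
  # fixture set: positive root with tiny residual, agreeing with an
  # independent 2-variable Newton oracle
  m1 <- fixture_T1_model()
  ss <- steady_state_wellmixed(m1)
  expect_true(ss$R > 0 && ss$L > 0)
  expect_lt(ss$residual, 1e-10)
  oracle <- function(u0) {
    u <- u0
    for (i in 1:200) {
      f <- unlist(reaction_terms(m1, u[1], u[2], subdomain = "epithelium"))[1:2]
      f[2] <- f[2] + m1$params$rho_L       # well-mixed ligand reservoir source
      if (max(abs(f)) < 1e-13) break
      Jn <- matrix(0, 2, 2)
      h <- 1e-7
      for (j in 1:2) {
        up <- u; up[j] <- up[j] + h
        fp <- unlist(reaction_terms(m1, up[1], up[2], subdomain = "epithelium"))[1:2]
        fp[2] <- fp[2] + m1$params$rho_L
        Jn[, j] <- (fp - f) / h
      }
      u <- u - solve(Jn, f)
    }
    u
  }
  u_orc <- oracle(c(ss$R * 1.1, ss$L * 0.9))
  expect_equal(c(ss$R, ss$L), u_orc, tolerance = 1e-6)
})

test_that("dispersion relation behaves at limits and under equal diffusion", {
  m1 <- fixture_T1_model()
  lam <- dispersion_relation(m1, c(0, 1e3))
  expect_lt(Re(lam[1]), 0)             # stable to uniform perturbations
  expect_lt(Re(lam[2]), -100)          # diffusive damping dominates
  # T3 (equal diffusion): max over k is attained at k = 0
  m3 <- model_spec("T3", fixture_parameters()$T1)
  kk <- seq(0, 2, length.out = 300)
  re3 <- Re(dispersion_relation(m3, kk))
  expect_lte(max(re3), re3[1] + 1e-12)
})

test_that("turing_conditions flags the fixture set and its degenerations", {
  st <- turing_conditions(fixture_T1_model())
  expect_true(st$turing_unstable)
  expect_gt(st$k_max, 0)
  expect_true(all(unlist(st$necessary_conditions)))
  p <- fixture_parameters()$T1
  for (v in c("T2", "T3", "T4")) {
    sv <- turing_conditions(model_spec(v, p))
    expect_false(sv$turing_unstable)
  }
  expect_false(turing_conditions(model_spec("T2", p))$necessary_conditions$feedback)
  expect_false(turing_conditions(model_spec("T3", p))$necessary_conditions$diffusion)
  expect_false(turing_conditions(model_spec("T4", p))$necessary_conditions$cooperativity)
})

test_that("dispersion relation is finite and continuous over random sets", {
  rng <- default_screen_ranges(decades = 0.7)
  sets <- sample_parameters(rng, 20, seed = 11)
  for (i in seq_len(nrow(sets))) {
    ps <- row_to_params(sets[i, ])
    st <- tryCatch(turing_conditions(model_spec("T1", ps)),
                   error = function(e) NULL)
    if (is.null(st)) next                  # no positive fixed point: allowed
    expect_false(anyNA(st$re_lambda))
    jumps <- abs(diff(st$re_lambda)) /
      pmax(abs(st$re_lambda[-1]), abs(st$re_lambda[-length(st$re_lambda)]), 1e-6)
    expect_lt(stats::median(jumps), 0.5)   # piecewise continuity
  }
})

test_that("T5 collapsed steady state activates the feedback", {
  m5 <- fixture_T5_model()
  ss5 <- steady_state_wellmixed(m5)
  expect_gt(ss5$L1, 0)
  expect_lt(ss5$residual, 1e-10)
  # with b1 = gamma = 0, T5 collapses to the T1 fixed point
  p50 <- fixture_parameters()$T5
  p50$b1 <- 0; p50$gamma <- 0
  ss50 <- steady_state_wellmixed(model_spec("T5", p50))
  ss1 <- steady_state_wellmixed(fixture_T1_model())
  expect_equal(c(ss50$R, ss50$L), c(ss1$R, ss1$L), tolerance = 1e-9)
})
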