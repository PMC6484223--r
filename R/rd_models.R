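#' Kinetic and transport parameters of the ligand-receptor model
#'
#' Parameters of the ligand-receptor reaction-diffusion system: the receptor
#' `R` is produced at rate `rho_R` in the epithelium, the ligand `L` at rate
#' `rho_L` (alias `b`, the constitutive production rate) in the mesenchyme;
#' both decay linearly (`delta_R`, `delta_L`).  Complex formation `R^m L^n`
#' removes `m*mu` receptors and `n*mu` ligands per complex and up-regulates
#' receptor production at rate `v`, giving the net receptor reaction term
#' `(v - m*mu) R^m L^n`.  The optional second ligand `L1` (WNT11-like) is
#' produced in the epithelium at `b1 * R^m L^n`, decays at `delta_L1`,
#' diffuses with `D_L1` and feeds back on mesenchymal ligand production as
#' `b + gamma * L1 / (K_fb + L1)`.
#'
#' @param D_R,D_L diffusion coefficients (length^2/time), `D_L, D_R > 0`.
#' @param rho_R receptor production rate (epithelium).
#' @param rho_L ligand production rate (mesenchyme); alias `b`.
#' @param delta_R,delta_L linear decay rates.
#' @param mu complex-removal rate scale.
#' @param v receptor up-regulation rate.
#' @param m,n complex stoichiometry, integers in `{1, 2}` with `m + n <= 3`.
#' @param D_L1,b1,delta_L1,gamma,K_fb second-ligand (feedback) parameters.
#' @return A `parameter_set`.
#' @export
parameter_set <- function(D_R = 1, D_L = 20, rho_R = 1, rho_L = 1,
                          delta_R = 0.01, delta_L = 0.01, mu = 1, v = 2.5,
                          m = 2L, n = 1L, D_L1 = D_L, b1 = 0,
                          delta_L1 = 0.1, gamma = 0, K_fb = 1) {
  vals <- c(D_R = D_R, D_L = D_L, rho_R = rho_R, rho_L = rho_L,
            delta_R = delta_R, delta_L = delta_L, mu = mu, v = v,
            D_L1 = D_L1, b1 = b1, delta_L1 = delta_L1, gamma = gamma,
            K_fb = K_fb)
  if (anyNA(vals) || any(!is.finite(vals))) stop_input("non-finite parameter")
  if (any(vals < 0)) stop_input("all rates must be non-negative")
  if (D_R <= 0 || D_L <= 0) stop_input("diffusion coefficients must be positive")
  m <- as.integer(m); n <- as.integer(n)
  if (!m %in% 1:2 || !n %in% 1:2 || m + n > 3)
    stop_input("stoichiometry must satisfy m, n in {1, 2} and m + n <= 3")
  structure(list(D_R = D_R, D_L = D_L, rho_R = rho_R, rho_L = rho_L,
                 delta_R = delta_R, delta_L = delta_L, mu = mu, v = v,
                 m = m, n = n, D_L1 = D_L1, b1 = b1, delta_L1 = delta_L1,
                 gamma = gamma, K_fb = K_fb), class = "parameter_set")
}

#' Model variant specification (T1-T5)
#'
#' The model family shares one set of equations; the variants differ in which
#' Turing necessary condition holds: `T1` is the full ligand-receptor Turing
#' model (`m = 2, n = 1`); `T2` removes receptor up-regulation (`v = 0`);
#' `T3` equalises the diffusion coefficients (`D_L = D_R`); `T4` removes
#' cooperativity (`m = n = 1`); `T5` extends `T1` with the second-ligand
#' positive feedback on ligand production (`b1, gamma > 0`).
#'
#' @param variant one of `"T1"`..`"T5"`.
#' @param params a [parameter_set()]; structural constraints of the variant
#'   are enforced (`enforce = TRUE`, default) or validated strictly.
#' @param readout_exponents exponents `(m, n)` of the signalling readout
#'   `R^m L^n`; defaults to the model's own stoichiometry.
#' @param enforce if `TRUE`, coerce the parameter set to the variant
#'   (e.g. set `v = 0` for T2); if `FALSE`, reject inconsistent sets.
#' @return A `model_spec`.
#' @export
model_spec <- function(variant = c("T1", "T2", "T3", "T4", "T5"),
                       params = parameter_set(), readout_exponents = NULL,
                       enforce = TRUE) {
  variant <- match.arg(variant)
  if (!inherits(params, "parameter_set")) stop_input("params must be a parameter_set")
  p <- params
  fix <- function(cond, msg, fixup) {
    if (!cond) {
      if (enforce) return(fixup) else stop_input("variant ", variant, ": ", msg)
    }
    p
  }
  if (variant %in% c("T1", "T5")) {
    p <- fix(p$m == 2 && p$n == 1, "requires m = 2, n = 1",
             { q <- p; q$m <- 2L; q$n <- 1L; q })
  }
  if (variant == "T2") p <- fix(p$v == 0, "requires v = 0", { q <- p; q$v <- 0; q })
  if (variant == "T3") p <- fix(p$D_L == p$D_R, "requires D_L = D_R",
                                { q <- p; q$D_L <- q$D_R; q$D_L1 <- q$D_R; q })
  if (variant == "T4") p <- fix(p$m == 1 && p$n == 1, "requires m = n = 1",
                                { q <- p; q$m <- 1L; q$n <- 1L; q })
  if (variant != "T5") { p$b1 <- 0; p$gamma <- 0 }
  if (is.null(readout_exponents)) readout_exponents <- c(p$m, p$n)
  structure(list(variant = variant, params = p,
                 readout_exponents = as.integer(readout_exponents),
                 extra_sources = list()),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  p <- x$params
  cat(sprintf("model_spec %s: m=%d n=%d, D_R=%.3g D_L=%.3g, v=%.3g mu=%.3g\n",
              x$variant, p$m, p$n, p$D_R, p$D_L, p$v, p$mu))
  invisible(x)
}

#' Reaction terms of the model at given concentrations
#'
#' Epithelium: `dR = rho_R - delta_R R + (v - m mu) R^m L^n`,
#' `dL = -n mu R^m L^n - delta_L L` (plus `dL1 = b1 R^m L^n - delta_L1 L1`
#' for T5).  Mesenchyme: `dL = rho_L_eff - delta_L L` with
#' `rho_L_eff = b` for T1-T4 and `b + gamma L1/(K_fb + L1)` for T5.
#'
#' @param model a [model_spec()].
#' @param R,L,L1 concentrations (vectors recycled to common length).
#' @param subdomain `"epithelium"` or `"mesenchyme"`.
#' @return list with components `dR`, `dL`, `dL1`.
#' @export
reaction_terms <- function(model, R, L, L1 = 0,
                           subdomain = c("epithelium", "mesenchyme")) {
  subdomain <- match.arg(subdomain)
  if (any(R < 0) || any(L < 0) || any(L1 < 0))
    stop_input("concentrations must be non-negative")
  p <- model$params
  if (subdomain == "epithelium") {
    S <- R^p$m * L^p$n
    list(dR = p$rho_R - p$delta_R * R + (p$v - p$m * p$mu) * S,
         dL = -p$n * p$mu * S - p$delta_L * L,
         dL1 = p$b1 * S - p$delta_L1 * L1)
  } else {
    rho_eff <- p$rho_L + if (model$variant == "T5")
      p$gamma * L1 / (p$K_fb + L1) else 0
    list(dR = 0 * R,
         dL = rho_eff - p$delta_L * L,
         dL1 = -p$delta_L1 * L1)
  }
}

# Collapsed (well-mixed reservoir) reaction system used for the linear
# stability analysis: the epithelial pair with the mesenchymal ligand source
# rho_L added to the ligand equation.  For T5 the second ligand is included.
collapsed_rhs <- function(model, u) {
  p <- model$params
  R <- u[1]; L <- u[2]; L1 <- if (length(u) > 2) u[3] else 0
  S <- R^p$m * L^p$n
  rho_eff <- p$rho_L + if (model$variant == "T5")
    p$gamma * L1 / (p$K_fb + L1) else 0
  out <- c(p$rho_R - p$delta_R * R + (p$v - p$m * p$mu) * S,
           rho_eff - p$delta_L * L - p$n * p$mu * S)
  if (model$variant == "T5") out <- c(out, p$b1 * S - p$delta_L1 * L1)
  out
}

#' Homogeneous steady state of the collapsed system
#'
#' Finds the positive fixed point of the spatially homogeneous system in
#' which the mesenchyme acts as a well-mixed ligand reservoir (the ligand
#' source `rho_L` is added to the epithelial ligand equation).  The fixed
#' point is reduced to a scalar root problem in the complex concentration
#' `S = R^m L^n` and solved by bracketed root finding; if several positive
#' roots exist the smallest (continuation of the binding-free state) is
#' returned and all roots are reported.
#'
#' @param model a [model_spec()].
#' @return list with `R`, `L` (and `L1` for T5), `S`, `residual` (max
#'   relative residual of the reaction terms) and `roots` (all bracketed
#'   roots in `S`).
#' @export
steady_state_wellmixed <- function(model) {
  p <- model$params
  mm <- p$m; nn <- p$n
  coefR <- p$v - mm * p$mu
  L1_of_S <- function(S) if (model$variant == "T5") p$b1 * S / p$delta_L1 else 0
  rho_eff <- function(S) {
    L1 <- L1_of_S(S)
    p$rho_L + if (model$variant == "T5") p$gamma * L1 / (p$K_fb + L1) else 0
  }
  R_of_S <- function(S) (p$rho_R + coefR * S) / p$delta_R
  L_of_S <- function(S) (rho_eff(S) - nn * p$mu * S) / p$delta_L
  F <- function(S) R_of_S(S)^mm * L_of_S(S)^nn - S
  # positivity bracket in S
  hi <- Inf
  if (p$mu > 0) {
    # L > 0: rho_eff(S) - n mu S > 0; rho_eff is bounded by rho_L + gamma
    hi <- min(hi, (p$rho_L + p$gamma) / (nn * p$mu))
  }
  if (coefR < 0) hi <- min(hi, p$rho_R / (-coefR))
  if (!is.finite(hi)) hi <- 1e6 * max(1, p$rho_R / p$delta_R * (p$rho_L / p$delta_L)^nn)
  hi <- hi * (1 - 1e-12)
  grid <- unique(c(0, 10^seq(log10(hi) - 12, log10(hi), length.out = 400), hi))
  fv <- vapply(grid, F, 0)
  sgn <- sign(fv)
  flips <- which(sgn[-1] * sgn[-length(sgn)] < 0)
  roots <- numeric(0)
  for (i in flips) {
    r <- tryCatch(stats::uniroot(F, c(grid[i], grid[i + 1]), tol = 1e-14)$root,
                  error = function(e) NA_real_)
    if (!is.na(r)) roots <- c(roots, r)
  }
  # roots at S = 0 occur when rho_R = 0 or rho_L = 0
  if (abs(F(0)) < 1e-30) roots <- c(0, roots)
  roots <- sort(unique(roots))
  keep <- vapply(roots, function(S) R_of_S(S) >= 0 && L_of_S(S) >= 0, TRUE)
  roots <- roots[keep]
  if (!length(roots))
    stop(sprintf(
      "no positive homogeneous fixed point found in S bracket [0, %.3g]", hi))
  S <- roots[1]
  u <- c(R = R_of_S(S), L = L_of_S(S))
  if (model$variant == "T5") u <- c(u, L1 = L1_of_S(S))
  res <- collapsed_rhs(model, u)
  scale <- pmax(abs(u) * pmax(p$delta_R, p$delta_L), p$rho_R + p$rho_L, 1e-300)
  out <- as.list(u)
  out$S <- S
  out$residual <- max(abs(res) / scale)
  out$roots <- roots
  out
}

# Jacobian of the collapsed reaction system at state u.
collapsed_jacobian <- function(model, u) {
  p <- model$params
  R <- u[["R"]]; L <- u[["L"]]
  S_R <- p$m * R^(p$m - 1) * L^p$n
  S_L <- p$n * R^p$m * L^(p$n - 1)
  cR <- p$v - p$m * p$mu
  J <- matrix(c(-p$delta_R + cR * S_R, cR * S_L,
                -p$n * p$mu * S_R, -p$delta_L - p$n * p$mu * S_L),
              2, 2, byrow = TRUE)
  if (model$variant == "T5") {
    L1 <- u[["L1"]]
    J <- rbind(cbind(J, c(0, p$gamma * p$K_fb / (p$K_fb + L1)^2)),
               c(p$b1 * S_R, p$b1 * S_L, -p$delta_L1))
  }
  J
}

#' Dispersion relation of the collapsed system
#'
#' Growth rate of spatial perturbations `exp(i k x)` about the homogeneous
#' steady state: the dominant eigenvalue of `J - k^2 diag(D)`.
#'
#' @param model a [model_spec()].
#' @param k wavenumber(s).
#' @param steady optional precomputed [steady_state_wellmixed()] result.
#' @return complex vector of dominant eigenvalues, one per `k`.
#' @export
dispersion_relation <- function(model, k, steady = NULL) {
  ss <- steady %||% steady_state_wellmixed(model)
  J <- collapsed_jacobian(model, ss)
  p <- model$params
  D <- if (model$variant == "T5") c(p$D_R, p$D_L, p$D_L1) else c(p$D_R, p$D_L)
  vapply(k, function(kk) {
    ev <- eigen(J - kk^2 * diag(D, nrow(J)), only.values = TRUE)$values
    ev[which.max(Re(ev))]
  }, complex(1))
}

#' Turing-instability test for a model variant
#'
#' Evaluates the linear stability analysis of the collapsed system over a
#' wavenumber grid and flags the three necessary conditions for a
#' diffusion-driven instability in the ligand-receptor model: (i) faster
#' ligand than receptor diffusion, `D_L > D_R`; (ii) positive feedback of
#' signalling on receptor abundance, `v > m mu`; (iii) cooperative complex
#' formation (`m + n > 2`).  The system is Turing-unstable when the
#' homogeneous state is stable to uniform perturbations (`Re lambda(0) < 0`)
#' but unstable at some `k > 0`.
#'
#' @param model a [model_spec()].
#' @param k_grid wavenumber grid; the default spans `[0, k_hi]` with `k_hi`
#'   chosen from the reaction rates and diffusion coefficients so that the
#'   diffusive branch is fully resolved.
#' @return A `stability_result` with `steady_state`, `turing_unstable`,
#'   `k_max`, `max_growth_rate`, `lambda0` and `necessary_conditions`.
#' @export
turing_conditions <- function(model, k_grid = NULL) {
  p <- model$params
  ss <- steady_state_wellmixed(model)
  J <- collapsed_jacobian(model, ss)
  if (is.null(k_grid)) {
    k_hi <- 10 * sqrt(max(abs(J)) / min(p$D_R, p$D_L))
    k_grid <- c(0, 10^seq(log10(k_hi) - 5, log10(k_hi), length.out = 600))
  }
  lam <- dispersion_relation(model, k_grid, steady = ss)
  re <- Re(lam)
  pos <- k_grid > 0
  imax <- which.max(re[pos])
  kmax <- k_grid[pos][imax]
  gmax <- re[pos][imax]
  nc <- list(diffusion = p$D_L > p$D_R,
             feedback = p$v > p$m * p$mu,
             cooperativity = (p$m + p$n) > 2)
  structure(list(steady_state = ss,
                 turing_unstable = (re[1] < 0) && (gmax > 0),
                 k_max = kmax, max_growth_rate = gmax, lambda0 = re[1],
                 necessary_conditions = nc,
                 k_grid = k_grid, re_lambda = re),
            class = "stability_result")
}

#' @export
print.stability_result <- function(x, ...) {
  nc <- x$necessary_conditions
  cat(sprintf(paste0("stability_result: turing_unstable = %s\n",
                     "  Re lambda(0) = %.4g, max growth = %.4g at k = %.4g\n",
                     "  conditions: D_L > D_R %s, v > m*mu %s, cooperativity %s\n"),
              x$turing_unstable, x$lambda0, x$max_growth_rate, x$k_max,
              nc$diffusion, nc$feedback, nc$cooperativity))
  invisible(x)
}
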