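# P1 finite-element machinery for the two-layer reaction-diffusion system.
#
# Discretisation: linear triangles, lumped mass.  Steady states are reached
# by linearised-implicit pseudo-transient continuation (one Newton iteration
# of implicit Euler per step; sparse LU with factor reuse on a power-of-two
# step-size ladder).  The receptor is assembled only on epithelial elements,
# which imposes a natural zero-flux condition at the epithelium-mesenchyme
# interface; the ligand is continuous across the interface (shared nodes).
# All outer boundaries are natural zero-flux.  On single-layer meshes (no
# mesenchymal triangles) the ligand source applies everywhere, matching the
# well-mixed-reservoir system used by the linear stability analysis.

# Edge table of a triangulation: unique vertex pairs plus the per-triangle
# edge indices in the local order (e1 opposite v1, e2 opposite v2, e3
# opposite v3), as needed for quadratic elements.
mesh_edges <- function(triangles, n_vertex) {
  ea <- rbind(triangles[, c(2, 3)], triangles[, c(3, 1)], triangles[, c(1, 2)])
  lo <- pmin(ea[, 1], ea[, 2]); hi <- pmax(ea[, 1], ea[, 2])
  key <- (lo - 1) * n_vertex + hi
  uk <- unique(key)
  eid <- match(key, uk)
  m <- nrow(triangles)
  list(edges = cbind(lo, hi)[match(uk, key), , drop = FALSE],
       tri_edges = cbind(eid[1:m], eid[(m + 1):(2 * m)], eid[(2 * m + 1):(3 * m)]))
}

# Consistent P2 mass matrix on the reference triangle (factor area), node
# order v1 v2 v3 m1 m2 m3 with m_i opposite v_i.
p2_mass_ref <- function() {
  matrix(c(6, -1, -1, -4, 0, 0,
           -1, 6, -1, 0, -4, 0,
           -1, -1, 6, 0, 0, -4,
           -4, 0, 0, 32, 16, 16,
           0, -4, 0, 16, 32, 16,
           0, 0, -4, 16, 16, 32), 6, 6, byrow = TRUE) / 180
}

# Assemble stiffness and consistent mass over a triangle subset for P1 or
# P2 elements on the extended node set.
fem_assemble_elem <- function(mesh, conn, n_ext, tri_subset = NULL,
                              element = "P1") {
  tr <- conn
  keep <- tri_subset %||% rep(TRUE, nrow(tr))
  tr <- tr[keep, , drop = FALSE]
  tv <- mesh$triangles[keep, , drop = FALSE]
  x <- matrix(mesh$nodes[tv, 1], ncol = 3)
  y <- matrix(mesh$nodes[tv, 2], ncol = 3)
  b <- cbind(y[, 2] - y[, 3], y[, 3] - y[, 1], y[, 1] - y[, 2])
  cc <- cbind(x[, 3] - x[, 2], x[, 1] - x[, 3], x[, 2] - x[, 1])
  A <- abs(x[, 1] * b[, 1] + x[, 2] * b[, 2] + x[, 3] * b[, 3]) / 2
  nloc <- ncol(tr)
  if (element == "P1") {
    Ke <- function(a, d) (b[, a] * b[, d] + cc[, a] * cc[, d]) / (4 * A)
    Mref <- matrix(c(2, 1, 1, 1, 2, 1, 1, 1, 2), 3, 3) / 12
    Me <- function(a, d) A * Mref[a, d]
  } else {
    # P2: gradients are linear; 3-midpoint quadrature is exact for the
    # quadratic integrand grad(phi_a) . grad(phi_b)
    gx <- b / (2 * A); gy <- cc / (2 * A)
    qp <- rbind(c(0, .5, .5), c(.5, 0, .5), c(.5, .5, 0))
    Gx <- array(0, c(nrow(tr), 6, 3)); Gy <- array(0, c(nrow(tr), 6, 3))
    for (q in 1:3) {
      lam <- qp[q, ]
      for (vtx in 1:3) {
        Gx[, vtx, q] <- (4 * lam[vtx] - 1) * gx[, vtx]
        Gy[, vtx, q] <- (4 * lam[vtx] - 1) * gy[, vtx]
      }
      oth <- list(c(2, 3), c(3, 1), c(1, 2))
      for (mid in 1:3) {
        o <- oth[[mid]]
        Gx[, 3 + mid, q] <- 4 * (lam[o[2]] * gx[, o[1]] + lam[o[1]] * gx[, o[2]])
        Gy[, 3 + mid, q] <- 4 * (lam[o[2]] * gy[, o[1]] + lam[o[1]] * gy[, o[2]])
      }
    }
    Ke <- function(a, d) {
      out <- 0
      for (q in 1:3) out <- out + Gx[, a, q] * Gx[, d, q] + Gy[, a, q] * Gy[, d, q]
      out * A / 3
    }
    Mref <- p2_mass_ref()
    Me <- function(a, d) A * Mref[a, d]
  }
  # assemble in chunks of local-pair blocks to bound the triplet transients
  # on large meshes
  build <- function(fun) {
    out <- NULL
    pairs <- expand.grid(a = seq_len(nloc), d = seq_len(nloc))
    chunk <- max(1L, floor(4e6 / max(nrow(tr), 1)))
    for (start in seq(1, nrow(pairs), by = chunk)) {
      sel <- start:min(start + chunk - 1, nrow(pairs))
      ii <- jj <- vv <- vector("list", length(sel))
      for (q in seq_along(sel)) {
        a <- pairs$a[sel[q]]; d <- pairs$d[sel[q]]
        ii[[q]] <- tr[, a]; jj[[q]] <- tr[, d]; vv[[q]] <- fun(a, d)
      }
      part <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj),
                                   x = unlist(vv), dims = c(n_ext, n_ext))
      out <- if (is.null(out)) part else out + part
    }
    out
  }
  list(K = build(Ke), M = build(Me))
}

# Build all operators for a mesh once.  `element` selects linear (P1) or
# quadratic (P2) Lagrange triangles; for P2 the node set is extended by the
# edge midpoints (appended after the vertex nodes).
fem_operators <- function(mesh, element = c("P1", "P2")) {
  element <- match.arg(element)
  epi <- mesh$subdomain == "epithelium"
  mes <- mesh$subdomain == "mesenchyme"
  nv <- nrow(mesh$nodes)
  if (element == "P1") {
    conn <- mesh$triangles
    n_ext <- nv
    coords <- mesh$nodes
    edge_ends <- NULL
  } else {
    ed <- mesh_edges(mesh$triangles, nv)
    conn <- cbind(mesh$triangles, nv + ed$tri_edges)
    n_ext <- nv + nrow(ed$edges)
    coords <- rbind(mesh$nodes,
                    (mesh$nodes[ed$edges[, 1], , drop = FALSE] +
                       mesh$nodes[ed$edges[, 2], , drop = FALSE]) / 2)
    edge_ends <- ed$edges
  }
  all_ops <- fem_assemble_elem(mesh, conn, n_ext, NULL, element)
  gc(FALSE)
  epi_ops <- fem_assemble_elem(mesh, conn, n_ext, epi, element)
  mes_M <- if (any(mes))
    fem_assemble_elem(mesh, conn, n_ext, mes, element)$M
  else all_ops$M
  collapsed <- !any(mes)
  epi_nodes_ext <- sort(unique(as.vector(conn[epi, ])))
  if (!any(epi)) epi_nodes_ext <- integer(0)
  gc(FALSE)
  list(K_all = all_ops$K, Mc_all = all_ops$M,
       K_epi = epi_ops$K[epi_nodes_ext, epi_nodes_ext, drop = FALSE],
       Mc_epi_full = epi_ops$M,
       Mc_epi = epi_ops$M[epi_nodes_ext, epi_nodes_ext, drop = FALSE],
       Mc_mes = mes_M,
       ml_all = Matrix::colSums(all_ops$M),
       enodes = epi_nodes_ext, n_ext = n_ext, n_vertex = nv,
       coords = coords, edge_ends = edge_ends,
       collapsed = collapsed, element = element)
}

# Smooth, mesh-independent seeded perturbation field evaluated at points.
# A fixed sum of random plane waves keeps refinement studies comparable
# across meshes (the same continuous initial condition is sampled).
perturbation_field <- function(points, seed, n_waves = 8, k_scale = 0.15) {
  coef <- with_seed(seed, list(a = stats::runif(n_waves, -1, 1),
                               th = stats::runif(n_waves, 0, 2 * pi),
                               ph = stats::runif(n_waves, 0, 2 * pi),
                               kk = stats::runif(n_waves, 0.3, 1.5)))
  out <- numeric(nrow(points))
  for (w in seq_len(n_waves)) {
    kx <- coef$kk[w] * k_scale * cos(coef$th[w])
    ky <- coef$kk[w] * k_scale * sin(coef$th[w])
    out <- out + coef$a[w] * cos(kx * points[, 1] + ky * points[, 2] + coef$ph[w])
  }
  out / sqrt(n_waves / 2)
}

#' Steady state of a reaction-diffusion model on a mesh
#'
#' Integrates the model to steady state by linearised-implicit pseudo-
#' transient continuation: each step solves one Newton iteration of the
#' implicit-Euler system `(M/dt + A(u)) du = -F(u)` with a sparse LU
#' factorisation that is reused across steps and refreshed on step-size
#' changes.  The step size grows geometrically once the pattern-forming
#' transient is over (it is capped near `1 / growth rate` while the linear
#' instability is still amplifying, so that the unstable mode is tracked
#' rather than Newton-collapsed back onto the unstable homogeneous state).
#' Reaction and source terms are integrated with the consistent mass matrix
#' (group finite elements).  Zero-flux boundary conditions hold on all outer
#' boundaries; the receptor is confined to the epithelium.  The initial
#' state is the homogeneous well-mixed steady state plus a small smooth
#' seeded perturbation (relative amplitude `perturb`), or `init` when
#' supplied.
#'
#' @param model a [model_spec()].
#' @param mesh an `rd_mesh` from [build_mesh()] or [rectangle_mesh()].
#' @param init optional named list of nodal vectors `R` (epithelial nodes or
#'   all nodes), `L`, `L1` (vertex values; extended internally for P2).
#' @param seed integer seed for the initial perturbation.
#' @param tol steady-state tolerance: maximum relative change per unit time.
#' @param perturb relative amplitude of the initial perturbation.
#' @param max_steps step budget.
#' @param t_max optional cap on integrated pseudo-time.
#' @param burst_efolds minimum amplification (in e-folds of the fastest
#'   unstable mode) integrated before convergence may be declared.
#' @param element `"P1"` (default) or `"P2"` Lagrange triangles; `"P2"` is
#'   used by the mesh-convergence studies.
#' @param method `"newton"` (pseudo-transient continuation with a coupled
#'   sparse LU), `"krylov"` (inexact Newton with lumped-Jacobian BiCGSTAB
#'   preconditioned by the SPD diffusion blocks; memory-lean, requires a
#'   warm `init`), or `"auto"` (default: `"krylov"` for warm-started
#'   systems beyond ~150k unknowns, where the fill of a coupled sparse LU
#'   becomes large and run-to-run variable).
#' @param verbose print progress every 20 steps.
#' @return A `steady_state` object: vertex-nodal `R` (NA outside the
#'   epithelium), `L`, `L1` (T5 only), `converged`, `residual_norm`,
#'   `steps`, `t_total`.
#' @export
solve_steady <- function(model, mesh, init = NULL, seed = 0, tol = 1e-6,
                         perturb = 1e-3, max_steps = 1e5, t_max = Inf,
                         burst_efolds = 30, element = "P1",
                         method = c("auto", "newton", "krylov"),
                         verbose = FALSE) {
  method <- match.arg(method)
  p <- model$params
  ops <- fem_operators(mesh, element)
  n <- ops$n_ext
  nv <- ops$n_vertex
  en <- ops$enodes
  t5 <- model$variant == "T5"

  ss <- tryCatch(steady_state_wellmixed(model), error = function(e) NULL)
  R0 <- if (!is.null(ss)) ss$R else p$rho_R / max(p$delta_R, 1e-8)
  L0 <- if (!is.null(ss)) ss$L else p$rho_L / max(p$delta_L, 1e-8)
  L10 <- if (t5) (if (!is.null(ss)) ss$L1 else 0) else 0

  extend <- function(v) {
    if (length(v) == n || is.null(ops$edge_ends)) return(v)
    c(v, (v[ops$edge_ends[, 1]] + v[ops$edge_ends[, 2]]) / 2)
  }
  if (is.null(init)) {
    pf_R <- perturbation_field(ops$coords[en, , drop = FALSE], seed)
    pf_L <- perturbation_field(ops$coords, seed + 1000L)
    R <- pmax(R0 * (1 + perturb * pf_R), 0)
    L <- pmax(L0 * (1 + perturb * pf_L), 0)
    L1 <- rep(L10, n)
  } else {
    Rin <- init$R
    Lfull <- extend(init$L)
    if (length(Rin) == nv || length(Rin) == n) {
      Rfullv <- extend(Rin)
      R <- Rfullv[en]
    } else if (length(Rin) == sum(mesh$epi_nodes)) {
      tmp <- rep(NA_real_, nv)
      tmp[which(mesh$epi_nodes)] <- Rin
      tmp[is.na(tmp)] <- 0
      R <- extend(tmp)[en]
    } else stop_input("init vectors do not match the mesh")
    if (length(Lfull) != n) stop_input("init vectors do not match the mesh")
    L <- Lfull
    L1 <- if (t5) extend(init$L1 %||% rep(L10, nv)) else rep(0, n)
    R <- pmax(R, 0); L <- pmax(L, 0); L1 <- pmax(L1, 0)
  }

  # block layout of the coupled state vector
  nE <- length(en)
  iR <- seq_len(nE)
  iL <- nE + seq_len(n)
  iL1 <- if (t5) nE + n + seq_len(n) else integer(0)
  nU <- nE + n + if (t5) n else 0

  # linear part: diffusion + linear decay (consistent mass); kept as
  # per-species blocks to avoid duplicating the large operators
  A_RR <- p$D_R * ops$K_epi + p$delta_R * ops$Mc_epi
  A_LL <- p$D_L * ops$K_all + p$delta_L * ops$Mc_all
  A_L1 <- if (t5) p$D_L1 * ops$K_all + p$delta_L1 * ops$Mc_all else NULL

  extra_src <- extra_source_vector(model, ops)
  cR <- p$v - p$m * p$mu

  # nonlinear + source loads; F(u) = A_lin u - b_nl(u)
  b_nl <- function(R, L, L1) {
    S <- R^p$m * L[en]^p$n
    Sfull <- numeric(n); Sfull[en] <- S
    bf <- numeric(nU)
    bf[iR] <- as.numeric(ops$Mc_epi %*% (p$rho_R + cR * S))
    rho_eff <- rep(p$rho_L, n) + if (t5) p$gamma * L1 / (p$K_fb + L1) else 0
    bf[iL] <- as.numeric(ops$Mc_mes %*% rho_eff) -
      p$n * p$mu * as.numeric(ops$Mc_epi_full %*% Sfull)[seq_len(n)] + extra_src
    if (t5)
      bf[iL1] <- p$b1 * as.numeric(ops$Mc_epi_full %*% Sfull)
    bf
  }
  residual <- function(R, L, L1) {
    lin <- c(as.numeric(A_RR %*% R), as.numeric(A_LL %*% L),
             if (t5) as.numeric(A_L1 %*% L1))
    lin - b_nl(R, L, L1)
  }

  # Jacobian of b_nl (consistent-mass weighted nodal derivatives)
  nl_jacobian <- function(R, L, L1) {
    Le <- L[en]
    S_R <- p$m * R^(p$m - 1) * Le^p$n
    S_L <- p$n * R^p$m * Le^(p$n - 1)
    SRf <- numeric(n); SRf[en] <- S_R
    SLf <- numeric(n); SLf[en] <- S_L
    pad_cols <- function(Msub) {
      # nE x nE matrix -> nE x n (columns at epithelial node positions)
      Tm <- as(as(Msub, "generalMatrix"), "TsparseMatrix")
      Matrix::sparseMatrix(i = Tm@i + 1L, j = en[Tm@j + 1L], x = Tm@x,
                           dims = c(nE, n))
    }
    J_RR <- ops$Mc_epi %*% Matrix::Diagonal(x = cR * S_R)
    J_RL <- pad_cols(ops$Mc_epi %*% Matrix::Diagonal(x = cR * S_L))
    MepiSR <- (ops$Mc_epi_full %*% Matrix::Diagonal(x = SRf))[, en, drop = FALSE]
    MepiSL <- ops$Mc_epi_full %*% Matrix::Diagonal(x = SLf)
    J_LR <- -p$n * p$mu * MepiSR
    J_LL <- -p$n * p$mu * MepiSL
    if (!t5) {
      rbind(cbind(J_RR, J_RL),
            cbind(J_LR, J_LL))
    } else {
      dfb <- p$gamma * p$K_fb / (p$K_fb + L1)^2
      J_LL1 <- ops$Mc_mes %*% Matrix::Diagonal(x = dfb)
      Z_RL1 <- Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                    x = numeric(0), dims = c(nE, n))
      J_L1R <- p$b1 * MepiSR
      J_L1L <- p$b1 * MepiSL
      Z_L1 <- Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                   x = numeric(0), dims = c(n, n))
      rbind(cbind(J_RR, J_RL, Z_RL1),
            cbind(J_LR, J_LL, J_LL1),
            cbind(J_L1R, J_L1L, Z_L1))
    }
  }

  # pseudo-time scales
  S0 <- max(R0, 0)^p$m * max(L0, 0)^p$n
  rate <- max(p$delta_R, p$delta_L, if (t5) p$delta_L1 else 0,
              abs(cR) * max(S0, 1e-12) / max(R0, 1e-12),
              p$n * p$mu * max(S0, 1e-12) / max(L0, 1e-12), 1e-6)
  if (method == "auto")
    method <- if (!is.null(init) && nU > 1.5e5) "krylov" else "newton"
  if (method != "imex") {
    # the raw stiffness matrices are folded into A_RR/A_LL; free the copies
    ops$K_all <- NULL; ops$K_epi <- NULL
    gc(FALSE); gc(FALSE)
  }
  if (method == "krylov") {
    if (is.null(init))
      stop_input("the Krylov method needs a warm initial state")
    # inexact Newton for very large warm-started systems: the Jacobian uses
    # HRZ-lumped reaction weights (diagonal coupling blocks) and each Newton
    # system is solved by BiCGSTAB preconditioned with the two SPD
    # diffusion+decay blocks (CHOLMOD Cholesky) -- a fraction of the memory
    # of a coupled sparse LU
    dml_all <- Matrix::diag(ops$Mc_all)
    dml_all <- dml_all * sum(ops$ml_all) / sum(dml_all)
    dml_epi_full <- Matrix::diag(ops$Mc_epi_full)
    sc_e <- sum(Matrix::colSums(ops$Mc_epi_full)) / max(sum(dml_epi_full), 1e-300)
    dml_epi_full <- dml_epi_full * sc_e
    dml_epi <- dml_epi_full[en]
    dml_mes <- pmax(dml_all - dml_epi_full, 0)
    dt <- 500 / rate
    S_R <- A_RR
    S_L <- A_LL
    if (t5) S_L1 <- A_L1
    make_prec <- function(dt) {
      fR <- Matrix::Cholesky(Matrix::forceSymmetric(
        S_R + Matrix::Diagonal(x = dml_epi / dt)), LDL = FALSE, perm = TRUE)
      fL <- Matrix::Cholesky(Matrix::forceSymmetric(
        S_L + Matrix::Diagonal(x = dml_all / dt)), LDL = FALSE, perm = TRUE)
      fL1 <- if (t5) Matrix::Cholesky(Matrix::forceSymmetric(
        S_L1 + Matrix::Diagonal(x = dml_all / dt)), LDL = FALSE, perm = TRUE)
      else NULL
      function(v) {
        out <- numeric(nU)
        out[iR] <- as.numeric(Matrix::solve(fR, v[iR], system = "A"))
        out[iL] <- as.numeric(Matrix::solve(fL, v[iL], system = "A"))
        if (t5) out[iL1] <- as.numeric(Matrix::solve(fL1, v[iL1], system = "A"))
        out
      }
    }
    prec <- make_prec(dt)
    gc(FALSE)
    apply_A <- function(v, jd) {
      # jd: list of lumped-diagonal Jacobian pieces at the current state
      out <- numeric(nU)
      out[iR] <- as.numeric(S_R %*% v[iR]) + dml_epi / dt * v[iR] -
        jd$RR * v[iR] - jd$RL * v[iL][en]
      out[iL] <- as.numeric(S_L %*% v[iL]) + dml_all / dt * v[iL]
      out[iL][en] <- out[iL][en] - jd$LR * v[iR] - jd$LL * v[iL][en]
      if (t5) {
        out[iL] <- out[iL] - jd$LL1 * v[iL1]
        out[iL1] <- as.numeric(S_L1 %*% v[iL1]) + dml_all / dt * v[iL1]
        out[iL1][en] <- out[iL1][en] - jd$L1R * v[iR] - jd$L1L * v[iL][en]
      }
      out
    }
    bicgstab <- function(bvec, jd, tol_lin = 1e-2, maxit = 200) {
      x <- numeric(nU)
      r <- bvec
      rtld <- r
      rho <- alpha <- omega <- 1
      v <- pvec <- numeric(nU)
      bnorm <- sqrt(sum(bvec^2))
      if (bnorm == 0) return(x)
      for (it in seq_len(maxit)) {
        rho1 <- sum(rtld * r)
        if (abs(rho1) < 1e-300) break
        beta <- if (it == 1) 0 else (rho1 / rho) * (alpha / omega)
        pvec <- r + beta * (pvec - omega * v)
        phat <- prec(pvec)
        v <- apply_A(phat, jd)
        alpha <- rho1 / sum(rtld * v)
        svec <- r - alpha * v
        x <- x + alpha * phat
        if (sqrt(sum(svec^2)) < tol_lin * bnorm) break
        shat <- prec(svec)
        tvec <- apply_A(shat, jd)
        omega <- sum(tvec * svec) / sum(tvec * tvec)
        x <- x + omega * shat
        r <- svec - omega * tvec
        rho <- rho1
        if (sqrt(sum(r^2)) < tol_lin * bnorm) break
      }
      x
    }
    lumped_jd <- function(R, L, L1) {
      Le <- L[en]
      S_Rd <- p$m * R^(p$m - 1) * Le^p$n
      S_Ld <- p$n * R^p$m * pmax(Le, 1e-300)^(p$n - 1)
      jd <- list(RR = dml_epi * cR * S_Rd,
                 RL = dml_epi * cR * S_Ld,
                 LR = -dml_epi * p$n * p$mu * S_Rd,
                 LL = -dml_epi * p$n * p$mu * S_Ld)
      if (t5) {
        jd$LL1 <- dml_mes * p$gamma * p$K_fb / (p$K_fb + L1)^2
        jd$L1R <- dml_epi * p$b1 * S_Rd
        jd$L1L <- dml_epi * p$b1 * S_Ld
      }
      jd
    }
    scaleR <- max(R0, max(R), 1e-12); scaleL <- max(L0, max(L), 1e-12)
    rc <- Inf; ok_streak <- 0L; step <- 0L; t_total <- 0
    Fn <- residual(R, L, L1)
    fn <- sqrt(mean(Fn^2))
    while (step < max_steps && t_total < t_max) {
      jd <- lumped_jd(R, L, L1)
      du <- bicgstab(-Fn, jd)
      step <- step + 1L
      lam <- 1
      repeat {
        Rn <- pmax(R + lam * du[iR], 0)
        Ln <- pmax(L + lam * du[iL], 0)
        L1n <- if (t5) pmax(L1 + lam * du[iL1], 0) else L1
        Fn_new <- residual(Rn, Ln, L1n)
        fn_new <- sqrt(mean(Fn_new^2))
        if (is.finite(fn_new) && fn_new <= (1 + 1e-6) * fn || lam < 0.05) break
        lam <- lam / 2
      }
      if (!is.finite(fn_new) || fn_new > 2 * fn) {
        dt <- dt / 4
        if (dt < 1e-9 / rate) stop("Krylov-Newton iteration diverged")
        prec <- make_prec(dt)
        Fn <- residual(R, L, L1); fn <- sqrt(mean(Fn^2))
        next
      }
      chg <- max(max(abs(Rn - R)) / scaleR, max(abs(Ln - L)) / scaleL) / dt
      R <- Rn; L <- Ln; if (t5) L1 <- L1n
      Fn <- Fn_new; fn <- fn_new
      t_total <- t_total + dt
      rc <- chg
      if (rc < tol) ok_streak <- ok_streak + 1L else ok_streak <- 0L
      if (ok_streak >= 2L) break
      if (verbose)
        cat(sprintf("  krylov step %d |F|=%.3g rc=%.3g lam=%.2f\n",
                    step, fn, rc, lam))
    }
    Rext <- rep(NA_real_, n); Rext[en] <- R
    return(structure(list(R = Rext[seq_len(nv)], L = L[seq_len(nv)],
                          L1 = if (t5) L1[seq_len(nv)] else NULL,
                          residual_norm = rc, converged = (ok_streak >= 2L),
                          steps = step, t_total = t_total, model = model,
                          readout_exponents = model$readout_exponents,
                          element = element), class = "steady_state"))
  }
  fixed_dt <- FALSE
  dt0 <- if (!is.null(init)) 50 / rate else 0.2 / rate
  dt_ladder <- dt0 * 2^(seq(-40, 40))
  lvl0 <- 41L
  lvl <- lvl0
  lsa_growth <- if (!is.null(ss)) {
    st <- tryCatch(turing_conditions(model), error = function(e) NULL)
    if (!is.null(st) && st$turing_unstable) st$max_growth_rate else 0
  } else 0
  t_min <- if (lsa_growth > 0 && is.null(init)) burst_efolds / lsa_growth else 0
  lvl_cap_growth <- if (lsa_growth > 0 && !fixed_dt)
    max(lvl0, 1L + floor(log2(max(1 / lsa_growth / dt_ladder[1], 1)))) else 81L
  big <- nU > 3e5

  scaleR <- max(R0, 1e-12); scaleL <- max(L0, 1e-12)
  t_total <- 0; step <- 0L; rc <- Inf; ok_streak <- 0L; accepted <- 0L
  fac <- NULL; fac_lvl <- -1L; fac_age <- 0L
  Fn <- residual(R, L, L1)
  fn <- sqrt(mean(Fn^2))

  while (step < max_steps && t_total < t_max) {
    if (t_total < t_min && lvl > lvl_cap_growth) lvl <- lvl_cap_growth
    dt <- dt_ladder[lvl]
    if (is.null(fac) || fac_lvl != lvl || fac_age >= 10L) {
      if (big) { fac <- NULL; gc(FALSE) }
      A <- (if (t5) Matrix::bdiag(ops$Mc_epi / dt + A_RR, ops$Mc_all / dt + A_LL,
                                  ops$Mc_all / dt + A_L1)
            else Matrix::bdiag(ops$Mc_epi / dt + A_RR, ops$Mc_all / dt + A_LL)) -
        nl_jacobian(R, L, L1)
      fac <- Matrix::lu(A)
      rm(A)
      fac_lvl <- lvl; fac_age <- 0L
    }
    du <- as.numeric(Matrix::solve(fac, -Fn))
    step <- step + 1L
    Rn <- R + du[iR]; Ln <- L + du[iL]
    L1n <- if (t5) L1 + du[iL1] else L1
    # small negative undershoots are projected to zero; only a gross
    # violation (beyond 5% of the species scale) rejects the step
    fn_new <- NA_real_
    bad <- anyNA(du) || any(!is.finite(du)) ||
      min(Rn) < -0.05 * scaleR || min(Ln) < -0.05 * scaleL ||
      (t5 && min(L1n) < -0.05 * max(max(L1), 1e-12))
    if (!bad) {
      Fn_new <- residual(pmax(Rn, 0), pmax(Ln, 0), pmax(L1n, 0))
      fn_new <- sqrt(mean(Fn_new^2))
      # residual may grow during fast physical transients; reject only on
      # clear divergence
      bad <- !is.finite(fn_new) || fn_new > 4 * fn + 1e-300
    }
    if (bad) {
      if (lvl == 1L)
        stop("solver blow-up at minimal step size (variant ", model$variant, ")")
      drop <- if (is.finite(fn_new) && fn_new > 0)
        max(2L, min(10L, as.integer(ceiling(log2(fn_new / fn))))) else 4L
      lvl <- max(1L, lvl - drop)
      fac <- NULL
      next
    }
    chg <- max(max(abs(Rn - R)) / scaleR, max(abs(Ln - L)) / scaleL) / dt
    R <- pmax(Rn, 0); L <- pmax(Ln, 0); if (t5) L1 <- pmax(L1n, 0)
    Fn <- Fn_new; fn <- fn_new
    scaleR <- max(scaleR, max(R)); scaleL <- max(scaleL, max(L))
    t_total <- t_total + dt
    accepted <- accepted + 1L
    fac_age <- fac_age + 1L
    rc <- chg
    if (rc < tol) ok_streak <- ok_streak + 1L else ok_streak <- 0L
    if (ok_streak >= 2L && t_total >= t_min) break
    if (!fixed_dt && accepted %% 3L == 0L && lvl < length(dt_ladder) - 1L)
      lvl <- lvl + 1L
    if (verbose && step %% 20L == 0L)
      cat(sprintf("  step %d t=%.4g dt=%.4g rc=%.3g |F|=%.3g ampR=%.3g\n",
                  step, t_total, dt, rc, fn, max(R) / max(min(R), 1e-300)))
  }

  # report vertex values; keep the extended state for warm restarts
  Rext <- rep(NA_real_, n); Rext[en] <- R
  Rfull <- Rext[seq_len(nv)]
  structure(list(R = Rfull, L = L[seq_len(nv)],
                 L1 = if (t5) L1[seq_len(nv)] else NULL,
                 residual_norm = rc, converged = (ok_streak >= 2L),
                 steps = step, t_total = t_total, model = model,
                 readout_exponents = model$readout_exponents,
                 element = element), class = "steady_state")
}

#' @export
print.steady_state <- function(x, ...) {
  cat(sprintf("steady_state: converged = %s after %d steps (t = %.3g), residual %.3g\n",
              x$converged, x$steps, x$t_total, x$residual_norm))
  invisible(x)
}

# Load vector for uniform/bead ligand sources attached to the model
# (consistent-mass weighted over the mesenchyme).
extra_source_vector <- function(model, ops) {
  out <- numeric(ops$n_ext)
  for (src in model$extra_sources) {
    if (src$kind == "uniform") {
      out <- out + as.numeric(ops$Mc_mes %*% rep(src$rate, ops$n_ext))
    } else {
      d2 <- (ops$coords[, 1] - src$location[1])^2 +
        (ops$coords[, 2] - src$location[2])^2
      ind <- as.numeric(d2 < src$radius^2)
      load <- as.numeric(ops$Mc_mes %*% (src$rate * ind))
      if (max(abs(load)) == 0)
        stop_input("bead source lies outside the mesenchyme")
      out <- out + load
    }
  }
  out
}


#' Signalling profile on the epithelium-mesenchyme interface
#'
#' Interpolates the signalling readout `R^m L^n` to uniformly arc-length
#' spaced positions along the interface (the epithelial boundary minus any
#' stalk edges).
#'
#' @param state a converged `steady_state`.
#' @param mesh the mesh the state was computed on.
#' @param n_samples number of output samples (default 400).
#' @param allow_unconverged set `TRUE` to bypass the convergence guard.
#' @return A `signal_profile`: `arc` (strictly increasing arc positions),
#'   `values`, `closed` flag, `length` of the sampled interface.
#' @export
signal_on_interface <- function(state, mesh, n_samples = 400,
                                allow_unconverged = FALSE) {
  if (!isTRUE(state$converged) && !allow_unconverged)
    stop_input("state is not converged; refusing to extract a profile")
  if (is.null(mesh$interface_nodes)) stop_input("mesh has no interface")
  ex <- state$readout_exponents
  idx <- mesh$interface_nodes
  vals <- state$R[idx]^ex[1] * state$L[idx]^ex[2]
  arc <- mesh$interface_arc
  stalk <- mesh$interface_stalk
  L <- curve_length(mesh$domain$epithelium)
  if (any(stalk)) {
    # keep the contiguous non-stalk arc, re-anchored at its start
    nodes_in_stalk <- stalk | c(stalk[length(stalk)], stalk[-length(stalk)])
    keep <- !nodes_in_stalk
    if (!any(keep)) stop_input("stalk covers the whole interface")
    start <- which(keep & c(!keep[length(keep)], !keep[-length(keep)]))[1]
    ord <- ((seq_along(keep) + start - 2L) %% length(keep)) + 1L
    keep <- keep[ord]
    arc0 <- (arc[ord] - arc[ord][1]) %% L
    vals <- vals[ord][keep]
    arc0 <- arc0[keep]
    s_out <- seq(0, max(arc0), length.out = n_samples)
    v_out <- stats::approx(arc0, vals, xout = s_out, rule = 2)$y
    closed <- FALSE
    len <- max(arc0)
  } else {
    s_out <- seq(0, L, length.out = n_samples + 1)[-(n_samples + 1)]
    v_out <- stats::approx(c(arc, L), c(vals, vals[1]), xout = s_out)$y
    closed <- TRUE
    len <- L
  }
  structure(list(arc = s_out, values = pmax(v_out, 0), closed = closed,
                 length = len), class = "signal_profile")
}

#' @export
print.signal_profile <- function(x, ...) {
  cat(sprintf("signal_profile: %d samples over %.3g (%s), range [%.3g, %.3g]\n",
              length(x$arc), x$length, if (x$closed) "closed" else "open",
              min(x$values), max(x$values)))
  invisible(x)
}

#' Mesh-convergence study of the deviation metric
#'
#' Recomputes the deviation between the normalised signalling profile `C`
#' and a fixed growth profile `E` at several mesh sizes and reports the
#' relative error against the finest (reference) mesh, reproducing the
#' standard convergence check (mesh size 1 on a length-100 domain gives a
#' deviation accurate to about 0.5%).
#'
#' @param model a [model_spec()].
#' @param domain a [two_layer_domain()].
#' @param h_values coarse mesh sizes to test.
#' @param reference_h reference (finest) mesh size.
#' @param profile_E fixed growth profile: list with `arc` positions and
#'   `values` on the interface, or a function of arc length.
#' @param seed seed of the initial perturbation (shared across meshes).
#' @param n_samples interface sampling resolution for the deviation.
#' @param tol steady-state tolerance.
#' @return data.frame with columns `h`, `delta`, `rel_error`.
#' @export
check_convergence <- function(model, domain, h_values, reference_h,
                              profile_E, seed = 0, n_samples = 400,
                              tol = 1e-8, verbose = FALSE,
                              mesh_args = list(), element = "P2") {
  if (any(h_values <= reference_h))
    stop_input("h_values must be coarser than reference_h")
  cascade <- solve_cascade(model, domain, c(h_values, reference_h),
                           seed = seed, tol = tol, verbose = verbose,
                           mesh_args = mesh_args, element = element)
  delta_of <- function(lev) {
    prof <- signal_on_interface(lev$state, lev$mesh, n_samples = n_samples)
    C <- normalize_signal(prof)
    Ev <- if (is.function(profile_E)) profile_E(prof$arc)
          else stats::approx(profile_E$arc, profile_E$values, xout = prof$arc,
                             rule = 2)$y
    E <- Ev / max(Ev)
    deviation(make_profile(prof$arc, C, prof$closed, prof$length),
              make_profile(prof$arc, E, prof$closed, prof$length))
  }
  d_ref <- delta_of(cascade[[sprintf("%g", reference_h)]])
  d <- vapply(h_values, function(h) delta_of(cascade[[sprintf("%g", h)]]), 0)
  data.frame(h = c(h_values, reference_h), delta = c(d, d_ref),
             rel_error = c(abs(d - d_ref) / d_ref, 0))
}

# Nearest-node index map from mesh_from nodes to arbitrary points, via a
# uniform grid hash (avoids the quadratic brute-force distance matrix).
nearest_node_map <- function(from_pts, to_pts, cell = NULL) {
  if (is.null(cell)) {
    bb <- apply(from_pts, 2, range)
    cell <- max(sqrt(prod(bb[2, ] - bb[1, ]) / nrow(from_pts)) * 2, 1e-9)
  }
  kx <- floor(from_pts[, 1] / cell); ky <- floor(from_pts[, 2] / cell)
  key <- paste(kx, ky)
  buckets <- split(seq_len(nrow(from_pts)), key)
  tx <- floor(to_pts[, 1] / cell); ty <- floor(to_pts[, 2] / cell)
  out <- integer(nrow(to_pts))
  tkey <- paste(tx, ty)
  groups <- split(seq_len(nrow(to_pts)), tkey)
  for (g in groups) {
    cx <- tx[g[1]]; cy <- ty[g[1]]
    cand <- integer(0)
    r <- 1L
    repeat {
      keys <- as.vector(outer((cx - r):(cx + r), (cy - r):(cy + r), paste))
      cand <- unlist(buckets[keys], use.names = FALSE)
      if (length(cand) || r > 64L) break
      r <- r * 2L
    }
    if (!length(cand)) { out[g] <- 1L; next }
    d2 <- outer(to_pts[g, 1], from_pts[cand, 1], "-")^2 +
      outer(to_pts[g, 2], from_pts[cand, 2], "-")^2
    out[g] <- cand[max.col(-d2, ties.method = "first")]
  }
  out
}

#' Transfer a steady state onto another mesh
#'
#' Nearest-node interpolation of the nodal fields, used to initialise a
#' solve on a refined (or remeshed) domain from a previously converged
#' solution.
#'
#' @param state a `steady_state` computed on `mesh_from`.
#' @param mesh_from,mesh_to source and target meshes.
#' @return list with `R`, `L` (and `L1`) on `mesh_to`'s nodes, usable as
#'   `init` for [solve_steady()].
#' @export
interp_state <- function(state, mesh_from, mesh_to) {
  map_all <- nearest_node_map(mesh_from$nodes, mesh_to$nodes)
  en_from <- which(mesh_from$epi_nodes)
  en_to <- which(mesh_to$epi_nodes)
  map_epi <- nearest_node_map(mesh_from$nodes[en_from, , drop = FALSE],
                              mesh_to$nodes[en_to, , drop = FALSE])
  out <- list(R = state$R[en_from][map_epi],
              L = state$L[map_all])
  if (!is.null(state$L1)) out$L1 <- state$L1[map_all]
  out
}

#' Coarse-to-fine cascade of steady-state solves
#'
#' Solves the model from scratch on the coarsest mesh and then continues the
#' same solution branch onto successively finer meshes (each initialised
#' from the previous level), so that refinement levels discretise the same
#' steady pattern rather than independently selected ones.  Intermediate
#' levels are inserted automatically so that consecutive refinement ratios
#' stay at or below 2.
#'
#' @param model a [model_spec()].
#' @param domain a [two_layer_domain()].
#' @param h_levels decreasing mesh sizes to report.
#' @param seed perturbation seed for the coarsest solve.
#' @param tol steady-state tolerance.
#' @param verbose print progress.
#' @return Named list (by `h`) of lists with `mesh` and `state`.
#' @export
solve_cascade <- function(model, domain, h_levels, seed = 0, tol = 1e-8,
                          verbose = FALSE, mesh_args = list(),
                          element = "P1") {
  h_levels <- sort(unique(h_levels), decreasing = TRUE)
  # insert intermediate levels (ratio <= 2)
  full <- h_levels[1]
  for (i in seq_along(h_levels)[-1]) {
    prev <- full[length(full)]
    while (prev / h_levels[i] > 2 + 1e-9) {
      prev <- prev / 2
      full <- c(full, prev)
    }
    full <- c(full, h_levels[i])
  }
  full <- unique(full)
  out <- list()
  prev <- NULL
  for (h in full) {
    mesh <- do.call(build_mesh, c(list(domain, h), mesh_args))
    init <- if (is.null(prev)) NULL else interp_state(prev$state, prev$mesh, mesh)
    st <- solve_steady(model, mesh, init = init, seed = seed, tol = tol,
                       element = element, verbose = verbose)
    if (verbose)
      cat(sprintf("h = %.3g: %d nodes, converged = %s in %d steps\n",
                  h, nrow(mesh$nodes), st$converged, st$steps))
    prev <- list(mesh = mesh, state = st)
    if (h %in% h_levels) out[[sprintf("%g", h)]] <- prev
    gc(FALSE)
  }
  out
}
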