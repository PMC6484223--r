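#' Closed epithelial boundary curve
#'
#' Constructs a `boundary_curve`: an ordered, counter-clockwise, simple closed
#' polygon describing the outline of the ureteric epithelium, optionally with
#' an arc-length interval marking the stalk and a fitted periodic spline.
#'
#' @param points n x 2 matrix (or data frame) of ordered boundary coordinates.
#' @param closed logical; only closed curves are currently supported.
#' @param stalk_interval optional numeric length-2 arc-length interval
#'   `c(s0, s1)` marking the stalk (may wrap past the curve start).
#' @param spline_degree spline degree used when a spline is fitted (default 3).
#' @param check_simple verify that the polygon has no self-intersections.
#' @return An object of class `boundary_curve` with elements `points`,
#'   `closed`, `stalk_interval`, `spline_degree` and (after fitting) `spline`.
#' @seealso [fit_boundary_spline()], [remove_stalk()], [mesenchyme_ellipse()]
#' @export
boundary_curve <- function(points, closed = TRUE, stalk_interval = NULL,
                           spline_degree = 3, check_simple = TRUE) {
  p <- as_point_matrix(points)
  if (!closed) stop_input("only closed boundary curves are supported")
  # drop consecutive duplicates (incl. an explicit closing point)
  keep <- c(TRUE, rowSums(abs(diff(p))) > 1e-12)
  p <- p[keep, , drop = FALSE]
  if (nrow(p) > 1 && all(abs(p[nrow(p), ] - p[1, ]) < 1e-12))
    p <- p[-nrow(p), , drop = FALSE]
  if (nrow(p) < 3) stop_input("a closed curve needs at least 3 distinct points")
  if (polygon_signed_area(p) < 0) p <- p[nrow(p):1, , drop = FALSE]
  if (check_simple) {
    q <- if (nrow(p) > 600) resample_closed(p, 600) else p
    if (!polygon_is_simple(q))
      stop_geometry("boundary curve is self-intersecting")
  }
  if (!is.null(stalk_interval)) {
    stalk_interval <- as.numeric(stalk_interval)
    if (length(stalk_interval) != 2 || anyNA(stalk_interval))
      stop_input("stalk_interval must be c(s0, s1)")
  }
  structure(list(points = p, closed = TRUE, stalk_interval = stalk_interval,
                 spline_degree = as.integer(spline_degree), spline = NULL),
            class = "boundary_curve")
}

#' @export
print.boundary_curve <- function(x, ...) {
  cat(sprintf("boundary_curve: %d points, length %.3g, area %.3g%s%s\n",
              nrow(x$points), curve_length(x),
              abs(polygon_signed_area(x$points)),
              if (is.null(x$spline)) "" else ", spline fitted",
              if (is.null(x$stalk_interval)) "" else ", stalk marked"))
  invisible(x)
}

# --- periodic B-spline machinery -------------------------------------------

# Periodic uniform B-spline basis of degree d with K independent control
# points, evaluated at parameters u in [0, 1).  Returns an n x K matrix.
periodic_bspline_basis <- function(u, K, d = 3, deriv = 0) {
  knots <- seq.int(-d, K + d) / K
  u <- u %% 1
  B <- splines::splineDesign(knots, u, ord = d + 1,
                             derivs = rep(deriv, length(u)), outer.ok = TRUE)
  nb <- ncol(B)                     # K + d basis functions
  A <- matrix(0, length(u), K)
  for (j in seq_len(nb)) {
    jj <- ((j - 1) %% K) + 1
    A[, jj] <- A[, jj] + B[, j]
  }
  A
}

# Derivatives are taken w.r.t. the unit parameter; all downstream formulas
# (normals, curvature) are parameterisation-invariant.
eval_periodic_spline <- function(sp, u, deriv = 0) {
  A <- periodic_bspline_basis(u, sp$K, sp$degree, deriv)
  cbind(A %*% sp$coef_x, A %*% sp$coef_y)
}

#' Least-squares periodic spline fit of a closed boundary
#'
#' Fits a periodic (closed) least-squares B-spline, degree 3 by default, to
#' ordered boundary samples, as used to smooth pixel-level epithelial borders
#' before normal and curvature computations.  The fitted curve is stored on
#' the returned [boundary_curve()] together with a dense arc-length
#' reparameterisation table.
#'
#' @param points ordered boundary samples (n x 2), or a `boundary_curve`.
#' @param degree spline degree (default 3).
#' @param n_control number of periodic control points; default
#'   `min(max(12, n/5), 120)`.
#' @param check_simple verify simplicity of the input polygon.
#' @return A `boundary_curve` with a `$spline` component.
#' @export
fit_boundary_spline <- function(points, degree = 3, n_control = NULL,
                                check_simple = TRUE) {
  crv <- if (inherits(points, "boundary_curve")) points
         else boundary_curve(points, check_simple = check_simple)
  p <- crv$points
  n <- nrow(p)
  if (n < degree + 2)
    stop_input("need at least degree + 2 = ", degree + 2, " points")
  if (is.null(n_control)) n_control <- min(max(12, round(n / 5)), 120)
  K <- max(degree + 1, min(n_control, n - 1))
  s <- polyline_arclength(p, closed = TRUE)
  u <- s[seq_len(n)] / s[n + 1]             # chord-length parameter in [0,1)
  A <- periodic_bspline_basis(u, K, degree)
  # tiny ridge guards rank deficiency for clustered samples
  AtA <- crossprod(A) + diag(1e-10, K)
  cx <- solve(AtA, crossprod(A, p[, 1]))
  cy <- solve(AtA, crossprod(A, p[, 2]))
  sp <- list(K = K, degree = degree, coef_x = cx, coef_y = cy)
  # arc-length table
  ug <- seq(0, 1, length.out = 4096 + 1)
  pg <- eval_periodic_spline(sp, ug[-length(ug)])
  sg <- polyline_arclength(pg, closed = TRUE)
  sp$arc_u <- ug
  sp$arc_s <- sg
  sp$length <- sg[length(sg)]
  fitted <- eval_periodic_spline(sp, u)
  sp$rms_residual <- sqrt(mean(rowSums((fitted - p)^2)))
  crv$spline <- sp
  crv$spline_degree <- as.integer(degree)
  crv
}

# Map arc length -> unit parameter for a fitted curve.
arc_to_param <- function(crv, s) {
  sp <- crv$spline
  if (is.null(sp)) stop_input("curve has no fitted spline")
  s <- s %% sp$length
  stats::approx(sp$arc_s, sp$arc_u, xout = s, ties = "ordered")$y
}

#' Evaluate a fitted boundary curve at arc-length positions
#'
#' @param crv a `boundary_curve` with fitted spline (see
#'   [fit_boundary_spline()]); raw polygons are interpolated linearly.
#' @param s arc-length positions (wrapped modulo the curve length).
#' @return n x 2 matrix of points.
#' @export
curve_point <- function(crv, s) {
  if (!is.null(crv$spline))
    return(eval_periodic_spline(crv$spline, arc_to_param(crv, s)))
  p <- crv$points
  sa <- polyline_arclength(p, closed = TRUE)
  s <- s %% sa[length(sa)]
  cbind(stats::approx(sa, c(p[, 1], p[1, 1]), xout = s)$y,
        stats::approx(sa, c(p[, 2], p[1, 2]), xout = s)$y)
}

#' Outward unit normals of a boundary curve at arc-length positions
#'
#' Normals are computed from the fitted spline derivative; for a
#' counter-clockwise curve they point away from the enclosed region.
#' @inheritParams curve_point
#' @return n x 2 matrix of unit normals.
#' @export
curve_normal <- function(crv, s) {
  if (!is.null(crv$spline)) {
    d1 <- eval_periodic_spline(crv$spline, arc_to_param(crv, s), deriv = 1)
  } else {
    h <- curve_length(crv) * 1e-4
    d1 <- (curve_point(crv, s + h) - curve_point(crv, s - h))
  }
  len <- sqrt(rowSums(d1^2))
  cbind(d1[, 2], -d1[, 1]) / len
}

#' Signed curvature at arc-length positions (positive = locally convex)
#' @inheritParams curve_point
#' @export
curve_curvature <- function(crv, s) {
  if (is.null(crv$spline)) {
    h <- curve_length(crv) * 2e-3
    p0 <- curve_point(crv, s); pp <- curve_point(crv, s + h)
    pm <- curve_point(crv, s - h)
    d1 <- (pp - pm) / (2 * h); d2 <- (pp - 2 * p0 + pm) / h^2
  } else {
    u <- arc_to_param(crv, s)
    d1 <- eval_periodic_spline(crv$spline, u, deriv = 1)
    d2 <- eval_periodic_spline(crv$spline, u, deriv = 2)
  }
  (d1[, 1] * d2[, 2] - d1[, 2] * d2[, 1]) / (rowSums(d1^2))^1.5
}

#' Total arc length of a boundary curve
#' @param crv a `boundary_curve`.
#' @export
curve_length <- function(crv) {
  if (!is.null(crv$spline)) return(crv$spline$length)
  s <- polyline_arclength(crv$points, closed = TRUE)
  s[length(s)]
}

#' Resample a boundary curve uniformly in arc length
#' @param crv a `boundary_curve`.
#' @param n number of points.
#' @return n x 2 matrix.
#' @export
curve_resample <- function(crv, n) {
  if (!is.null(crv$spline)) {
    s <- seq(0, crv$spline$length, length.out = n + 1)[-(n + 1)]
    curve_point(crv, s)
  } else resample_closed(crv$points, n)
}

# --- ellipse ----------------------------------------------------------------

#' Ellipse with centre, semi-axes and orientation
#'
#' @param center length-2 centre.
#' @param semi_axes length-2, `r1 >= r2 > 0`.
#' @param orientation unit vector of the first principal axis.
#' @return An `ellipse2d` object.
#' @export
ellipse2d <- function(center, semi_axes, orientation = c(1, 0)) {
  if (any(semi_axes <= 0)) stop_input("semi-axes must be positive")
  if (semi_axes[1] < semi_axes[2]) {
    semi_axes <- rev(semi_axes)
    orientation <- c(-orientation[2], orientation[1])
  }
  orientation <- orientation / sqrt(sum(orientation^2))
  structure(list(center = as.numeric(center),
                 semi_axes = as.numeric(semi_axes),
                 orientation = as.numeric(orientation)),
            class = "ellipse2d")
}

#' @export
print.ellipse2d <- function(x, ...) {
  cat(sprintf("ellipse2d: center (%.3g, %.3g), semi-axes (%.3g, %.3g)\n",
              x$center[1], x$center[2], x$semi_axes[1], x$semi_axes[2]))
  invisible(x)
}

#' Points on an ellipse at parameter angles
#' @param ell an `ellipse2d`.
#' @param theta parameter angles (radians).
#' @export
ellipse_point <- function(ell, theta) {
  e1 <- ell$orientation
  e2 <- c(-e1[2], e1[1])
  a <- ell$semi_axes[1]; b <- ell$semi_axes[2]
  cbind(ell$center[1] + a * cos(theta) * e1[1] + b * sin(theta) * e2[1],
        ell$center[2] + a * cos(theta) * e1[2] + b * sin(theta) * e2[2])
}

# Radial extent of the ellipse from its centre along direction angle phi
# (measured in the global frame).
ellipse_radius <- function(ell, phi) {
  e1 <- ell$orientation
  rot <- atan2(e1[2], e1[1])
  psi <- phi - rot
  a <- ell$semi_axes[1]; b <- ell$semi_axes[2]
  (a * b) / sqrt((b * cos(psi))^2 + (a * sin(psi))^2)
}

#' Elliptical mesenchyme from the epithelial second moments
#'
#' Approximates the metanephric mesenchyme by an ellipse derived from the
#' second central moments of the epithelial region: semi-axes
#' `r_i = 2 * alpha * sqrt(lambda_i)` where `lambda_i` are the eigenvalues of
#' the second-moment matrix of the uniformly filled epithelium (total mass 1),
#' and the orientation follows the eigenvectors.  The stalk, when marked, is
#' cut before the moments are computed.
#'
#' @param epithelium a `boundary_curve`.
#' @param alpha size factor (default 3, the value used throughout).
#' @param mass `"filled"` (uniform mass in the enclosed region; default) or
#'   `"boundary"` (uniform mass on equally spaced boundary points).
#' @param n_points resampling density used for moment computation.
#' @return An `ellipse2d`.
#' @export
mesenchyme_ellipse <- function(epithelium, alpha = 3, mass = c("filled", "boundary"),
                               n_points = 512) {
  mass <- match.arg(mass)
  if (alpha <= 0) stop_input("alpha must be positive")
  crv <- epithelium
  if (!is.null(crv$stalk_interval)) crv <- remove_stalk(crv)
  p <- curve_resample(crv, n_points)
  if (mass == "filled") {
    mom <- polygon_moments(p)
    ctr <- mom$centroid
    cv <- mom$cov
  } else {
    ctr <- colMeans(p)
    q <- sweep(p, 2, ctr)
    cv <- crossprod(q) / nrow(q)
  }
  eg <- eigen(cv, symmetric = TRUE)
  if (any(eg$values <= 0)) stop_geometry("degenerate epithelial region")
  ellipse2d(center = ctr, semi_axes = 2 * alpha * sqrt(eg$values),
            orientation = eg$vectors[, 1])
}

#' Excise the stalk interval from a boundary curve
#'
#' Removes the arc-length interval marked as the stalk and re-closes the curve
#' with a straight chord across the cut, as done before computing the centre
#' of mass and second moments of the epithelium.
#'
#' @param curve a `boundary_curve` with `stalk_interval` set (a `NULL`
#'   interval returns the curve unchanged).
#' @return A `boundary_curve` without stalk interval.
#' @export
remove_stalk <- function(curve) {
  iv <- curve$stalk_interval
  if (is.null(iv)) return(curve)
  L <- curve_length(curve)
  s0 <- iv[1] %% L; s1 <- iv[2] %% L
  arc <- (s1 - s0) %% L
  if (arc <= 0 || arc >= L - 1e-9 * L)
    stop_input("stalk_interval must cover a strict sub-arc of the curve")
  n <- max(nrow(curve$points), 200)
  s <- seq(0, L, length.out = n + 1)[-(n + 1)]
  inside <- ((s - s0) %% L) < arc
  if (all(inside)) stop_input("stalk_interval covers the whole curve")
  pts <- curve_point(curve, s)
  keep <- !inside
  # rotate so that the kept run is contiguous
  first_gap <- which(inside & c(!inside[n], !inside[-n]))[1]
  ord <- ((seq_len(n) + first_gap - 2) %% n) + 1
  pts <- pts[ord, , drop = FALSE]
  keep <- keep[ord]
  out <- pts[keep, , drop = FALSE]
  boundary_curve(out, check_simple = FALSE)
}

# --- two-layer domain -------------------------------------------------------

#' Two-layer epithelium/mesenchyme computational domain
#'
#' Bundles the epithelial boundary with the elliptical outer mesenchyme
#' boundary.  The interface on which signalling profiles are read out is the
#' epithelial boundary minus any marked stalk interval.
#'
#' @param epithelium a `boundary_curve`.
#' @param mesenchyme an `ellipse2d`, or `NULL` to derive it via
#'   [mesenchyme_ellipse()] with `alpha`.
#' @param alpha mesenchyme size factor when `mesenchyme` is derived.
#' @return A `two_layer_domain`.
#' @export
two_layer_domain <- function(epithelium, mesenchyme = NULL, alpha = 3) {
  if (!inherits(epithelium, "boundary_curve")) stop_input("epithelium must be a boundary_curve")
  if (is.null(mesenchyme)) mesenchyme <- mesenchyme_ellipse(epithelium, alpha)
  p <- curve_resample(epithelium, 256)
  if (inherits(mesenchyme, "ellipse2d")) {
    e1 <- mesenchyme$orientation; e2 <- c(-e1[2], e1[1])
    q <- sweep(p, 2, mesenchyme$center)
    xi <- q %*% e1 / mesenchyme$semi_axes[1]
    eta <- q %*% e2 / mesenchyme$semi_axes[2]
    inside <- all(xi^2 + eta^2 < 1)
  } else if (inherits(mesenchyme, "boundary_curve")) {
    inside <- all(points_in_polygon(p, mesenchyme$points))
  } else stop_input("mesenchyme must be an ellipse2d or boundary_curve")
  if (!inside)
    stop_geometry("epithelium is not strictly inside the mesenchyme boundary")
  structure(list(epithelium = epithelium, mesenchyme = mesenchyme),
            class = "two_layer_domain")
}

# Even-odd point-in-polygon test, vectorised over points.
points_in_polygon <- function(pts, poly) {
  n <- nrow(poly)
  xs <- poly[, 1]; ys <- poly[, 2]
  xe <- c(xs[-1], xs[1]); ye <- c(ys[-1], ys[1])
  out <- logical(nrow(pts))
  for (i in seq_len(nrow(pts))) {
    x <- pts[i, 1]; y <- pts[i, 2]
    cross <- (ys <= y & ye > y) | (ye <= y & ys > y)
    xx <- xs[cross] + (y - ys[cross]) / (ye[cross] - ys[cross]) *
      (xe[cross] - xs[cross])
    out[i] <- (sum(xx > x) %% 2) == 1
  }
  out
}

#' @export
print.two_layer_domain <- function(x, ...) {
  cat("two_layer_domain:\n  ")
  print(x$epithelium)
  cat("  ")
  print(x$mesenchyme)
  invisible(x)
}
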