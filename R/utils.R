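# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_input <- function(...) {
  stop(structure(class = c("budmorph_input_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_geometry <- function(...) {
  stop(structure(class = c("budmorph_geometry_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

#' @noRd
as_point_matrix <- function(points) {
  if (is.data.frame(points)) points <- as.matrix(points[, 1:2])
  if (!is.matrix(points) || ncol(points) < 2)
    stop_input("points must be an n x 2 matrix of coordinates")
  storage.mode(points) <- "double"
  if (anyNA(points) || any(!is.finite(points)))
    stop_input("points contain non-finite coordinates")
  unname(points[, 1:2, drop = FALSE])
}

# Signed area of a closed polygon (positive for counter-clockwise).
polygon_signed_area <- function(p) {
  x <- p[, 1]; y <- p[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

# Exact area, centroid and second central moments of a uniformly filled
# simple polygon via Green's theorem.  Moments are normalised to total
# mass one, i.e. cov is the covariance matrix of the uniform density.
polygon_moments <- function(p) {
  x <- p[, 1]; y <- p[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  A <- sum(cr) / 2
  if (abs(A) < .Machine$double.eps * 100 * max(1, max(abs(p))))
    stop_geometry("degenerate polygon: enclosed area is zero")
  cx <- sum((x + xn) * cr) / (6 * A)
  cy <- sum((y + yn) * cr) / (6 * A)
  # second moments about the origin
  Ixx <- sum((x^2 + x * xn + xn^2) * cr) / 12
  Iyy <- sum((y^2 + y * yn + yn^2) * cr) / 12
  Ixy <- sum((x * yn + 2 * x * y + 2 * xn * yn + xn * y) * cr) / 24
  # central, mass-normalised
  xx <- Ixx / A - cx^2
  yy <- Iyy / A - cy^2
  xy <- Ixy / A - cx * cy
  list(area = abs(A), centroid = c(cx, cy),
       cov = matrix(c(xx, xy, xy, yy), 2, 2))
}

# Do any two non-adjacent edges of the closed polyline intersect?
polygon_is_simple <- function(p, tol = 0) {
  n <- nrow(p)
  if (n < 3) return(FALSE)
  a <- p
  b <- p[c(2:n, 1), , drop = FALSE]
  # coarse spatial filter then exact segment test, chunked to bound memory
  idx <- seq_len(n)
  for (i in idx) {
    j <- idx[idx > i + 1 & !(i == 1 & idx == n)]
    if (!length(j)) next
    if (any(segments_intersect(a[i, ], b[i, ],
                               a[j, , drop = FALSE], b[j, , drop = FALSE])))
      return(FALSE)
  }
  TRUE
}

# Vectorised proper/improper segment intersection: segment (p1,p2) against
# rows of (q1,q2).  Touching at shared endpoints counts as intersection here;
# callers exclude adjacent edges.
segments_intersect <- function(p1, p2, q1, q2) {
  d1 <- p2 - p1
  o1 <- (q1[, 1] - p1[1]) * d1[2] - (q1[, 2] - p1[2]) * d1[1]
  o2 <- (q2[, 1] - p1[1]) * d1[2] - (q2[, 2] - p1[2]) * d1[1]
  dqx <- q2[, 1] - q1[, 1]; dqy <- q2[, 2] - q1[, 2]
  o3 <- (p1[1] - q1[, 1]) * dqy - (p1[2] - q1[, 2]) * dqx
  o4 <- (p2[1] - q1[, 1]) * dqy - (p2[2] - q1[, 2]) * dqx
  (o1 * o2 < 0) & (o3 * o4 < 0)
}

# Cumulative arc length of a polyline (optionally closed).
polyline_arclength <- function(p, closed = FALSE) {
  q <- if (closed) rbind(p, p[1, ]) else p
  d <- sqrt(rowSums((q[-1, , drop = FALSE] - q[-nrow(q), , drop = FALSE])^2))
  c(0, cumsum(d))
}

# Resample a closed polygon at n points uniformly spaced in arc length.
resample_closed <- function(p, n) {
  m <- nrow(p)
  seg <- sqrt(rowSums((p[c(2:m, 1), ] - p)^2))
  s <- c(0, cumsum(seg))
  P <- s[m + 1]
  target <- seq(0, P, length.out = n + 1)[-(n + 1)]
  xs <- stats::approx(s, c(p[, 1], p[1, 1]), xout = target)$y
  ys <- stats::approx(s, c(p[, 2], p[1, 2]), xout = target)$y
  cbind(xs, ys)
}

# Deterministic RNG scope: evaluate expr with a local seed without
# disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
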