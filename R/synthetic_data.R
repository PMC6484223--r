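# Synthetic inputs with ground truth: parametric bud shapes, time-lapse
# sequences with known growth fields, rasterised noisy masks, tip point
# clouds with controlled minimum spacing, and frozen fixture parameter sets.

#' Fixture parameter sets
#'
#' Frozen reference parameter sets: a T1 set that is Turing-unstable by
#' linear stability analysis (pattern wavelength about 34 length units, so a
#' handful of wavelengths fit on a length-100 domain), whose T2/T3/T4
#' degenerations are all linearly stable, and a T5 set adding an active
#' second-ligand positive feedback on ligand production.  The T1 set was
#' found by a seeded log-uniform LSA scan restricted to the weakly
#' supercritical regime (`v/(m mu)` close to 1, short ligand range) so that
#' its steady patterns are smooth, moderate-amplitude signal fields like the
#' published ones rather than near-singular receptor spikes, and rounded.
#'
#' @return Named list of [parameter_set()] objects (`T1`, `T5`).
#' @export
fixture_parameters <- function() {
  T1 <- parameter_set(D_R = 3.5, D_L = 77, rho_R = 0.085, rho_L = 0.27,
                      delta_R = 0.44, delta_L = 0.17, mu = 0.47, v = 1.96,
                      m = 2L, n = 1L)
  T5 <- parameter_set(D_R = 3.5, D_L = 77, rho_R = 0.085, rho_L = 0.27,
                      delta_R = 0.44, delta_L = 0.17, mu = 0.47, v = 1.96,
                      m = 2L, n = 1L, D_L1 = 2, b1 = 1, delta_L1 = 0.1,
                      gamma = 0.5, K_fb = 100)
  list(T1 = T1, T5 = T5)
}

#' Parametric bud shape
#'
#' A smooth closed curve: a base ellipse radially perturbed by Gaussian bumps
#' ("buds") at given angular positions, emulating ureteric bud outlines.
#'
#' @param base semi-axes `c(a, b)` of the base ellipse.
#' @param buds list (or 3-column matrix `angle, amplitude, width`) of bud
#'   bumps; `angle` in radians, `width` the Gaussian sigma in radians.
#' @param stalk_interval optional arc-length interval marking the stalk.
#' @param center centre of the shape.
#' @param n_points sampling density of the generated polygon.
#' @param fit_spline attach a fitted periodic spline (default `TRUE`).
#' @return A [boundary_curve()].
#' @export
make_bud_shape <- function(base = c(30, 18), buds = list(),
                           stalk_interval = NULL, center = c(0, 0),
                           n_points = 400, fit_spline = TRUE) {
  if (length(base) != 2 || any(base <= 0)) stop_input("base must be two positive semi-axes")
  if (is.matrix(buds)) buds <- lapply(seq_len(nrow(buds)), function(i) buds[i, ])
  for (bd in buds) {
    if (bd[[2]] < 0) stop_input("bud amplitudes must be non-negative")
    if (bd[[3]] <= 0) stop_input("bud widths must be positive")
  }
  th <- seq(0, 2 * pi, length.out = n_points + 1)[-(n_points + 1)]
  a <- base[1]; b <- base[2]
  r <- (a * b) / sqrt((b * cos(th))^2 + (a * sin(th))^2)
  for (bd in buds) {
    d <- ((th - bd[[1]] + pi) %% (2 * pi)) - pi
    r <- r + bd[[2]] * exp(-0.5 * (d / bd[[3]])^2)
  }
  pts <- cbind(center[1] + r * cos(th), center[2] + r * sin(th))
  crv <- tryCatch(boundary_curve(pts, stalk_interval = stalk_interval),
                  error = function(e)
                    stop_geometry("bud shape self-intersects; reduce bud amplitudes (",
                                  conditionMessage(e), ")"))
  if (fit_spline) {
    si <- crv$stalk_interval
    crv <- fit_boundary_spline(crv, check_simple = FALSE)
    crv$stalk_interval <- si
  }
  crv
}

#' Synthetic time-lapse with ground-truth growth fields
#'
#' Advances a boundary along its outward normals with per-point growth
#' magnitudes given by Gaussian arc-length profiles around growth centres
#' (anchored to material points of the first frame), producing a sequence of
#' frames and the exact per-frame-pair growth field.
#'
#' @param shape initial [boundary_curve()].
#' @param growth_centres arc-length positions of growth maxima on the first
#'   frame.
#' @param rates peak outward displacement per frame (length units/frame).
#' @param widths Gaussian widths (arc length units).
#' @param n_frames number of frames (>= 2 for field computation).
#' @param frame_dt hours between frames (nominal 2 h).
#' @param n_points material points used to track the boundary.
#' @return A `time_lapse`: `frames` (list of `boundary_curve`), `timestamps`
#'   (hours), `truth` (per frame pair: base points, vectors, magnitudes).
#' @export
make_timelapse <- function(shape, growth_centres, rates, widths,
                           n_frames = 3, frame_dt = 2, n_points = 300) {
  if (length(rates) == 1) rates <- rep(rates, length(growth_centres))
  if (length(widths) == 1) widths <- rep(widths, length(growth_centres))
  if (any(rates < 0)) stop_input("growth rates must be non-negative")
  if (n_frames < 2) stop_input("need at least two frames")
  L <- curve_length(shape)
  s0 <- seq(0, L, length.out = n_points + 1)[-(n_points + 1)]
  # per-material-point magnitude, frozen from the first frame arc positions
  g <- numeric(n_points)
  for (j in seq_along(growth_centres)) {
    d <- abs(((s0 - growth_centres[j] + L / 2) %% L) - L / 2)
    g <- g + rates[j] * exp(-0.5 * (d / widths[j])^2)
  }
  pts <- curve_point(shape, s0)
  frames <- vector("list", n_frames)
  truth <- vector("list", n_frames - 1)
  frames[[1]] <- fit_boundary_spline(pts, check_simple = FALSE)
  cur <- pts
  for (f in 2:n_frames) {
    crv <- fit_boundary_spline(cur, check_simple = FALSE)
    sa <- polyline_arclength(cur, closed = TRUE)
    nrm <- curve_normal(crv, sa[seq_len(n_points)])
    nxt <- cur + nrm * g
    if (!polygon_is_simple(if (nrow(nxt) > 600) resample_closed(nxt, 600) else nxt))
      stop_geometry("growth produced a self-intersecting boundary")
    truth[[f - 1]] <- list(base_points = cur, vectors = nrm * g, magnitudes = g)
    frames[[f]] <- fit_boundary_spline(nxt, check_simple = FALSE)
    cur <- nxt
  }
  structure(list(frames = frames,
                 timestamps = seq(0, by = frame_dt, length.out = n_frames),
                 pixel_size = 1, truth = truth), class = "time_lapse")
}

#' Rasterise a boundary curve to a noisy grayscale mask image
#'
#' Fills the polygon on a pixel grid (pixel centres at half-integer
#' coordinates, row 1 at the bottom so that y increases with row index),
#' optionally adds small distractor blobs (to exercise largest-component
#' selection) and Gaussian noise clipped to `[0, 1]`.
#'
#' @param curve a [boundary_curve()].
#' @param resolution pixels per length unit (default 1).
#' @param noise_sigma Gaussian noise standard deviation.
#' @param seed noise seed.
#' @param distractors number of small distractor discs outside the shape.
#' @param margin empty margin (length units) around the shape.
#' @return list with `image` (matrix, rows = y from bottom), `origin` (world
#'   coordinates of the centre of pixel [1,1]) and `pixel_size`.
#' @export
rasterize <- function(curve, resolution = 1, noise_sigma = 0, seed = 0,
                      distractors = 0, margin = 10) {
  if (resolution <= 0) stop_input("resolution must be positive")
  poly <- curve_resample(curve, max(400, nrow(curve$points)))
  px <- 1 / resolution
  x0 <- min(poly[, 1]) - margin; x1 <- max(poly[, 1]) + margin
  y0 <- min(poly[, 2]) - margin; y1 <- max(poly[, 2]) + margin
  nx <- ceiling((x1 - x0) / px); ny <- ceiling((y1 - y0) / px)
  xc <- x0 + (seq_len(nx) - 0.5) * px
  yc <- y0 + (seq_len(ny) - 0.5) * px
  img <- matrix(0, nrow = ny, ncol = nx)
  # scanline fill: for each pixel row find polygon edge crossings
  xs <- poly[, 1]; ys <- poly[, 2]
  xe <- c(xs[-1], xs[1]); ye <- c(ys[-1], ys[1])
  for (i in seq_len(ny)) {
    y <- yc[i]
    cross <- which((ys <= y & ye > y) | (ye <= y & ys > y))
    if (!length(cross)) next
    xx <- sort(xs[cross] + (y - ys[cross]) / (ye[cross] - ys[cross]) *
                 (xe[cross] - xs[cross]))
    for (j in seq(1, length(xx) - 1, by = 2)) {
      cols <- which(xc > xx[j] & xc < xx[j + 1])
      img[i, cols] <- 1
    }
  }
  main_area <- sum(img)
  with_seed(seed, {
    if (distractors > 0) {
      blob_r <- sqrt(0.05 * main_area / pi)   # each blob < 10% of main area
      placed <- 0; tries <- 0
      while (placed < distractors && tries < 200) {
        tries <- tries + 1
        ci <- sample.int(ny, 1); cj <- sample.int(nx, 1)
        wx <- xc[cj]; wy <- yc[ci]
        d <- sqrt((poly[, 1] - wx)^2 + (poly[, 2] - wy)^2)
        if (min(d) < (blob_r + 2) * px) next
        ii <- which(abs(yc - wy) <= blob_r * px)
        jj <- which(abs(xc - wx) <= blob_r * px)
        sub <- outer(yc[ii] - wy, rep(1, length(jj)))^2 +
          outer(rep(1, length(ii)), xc[jj] - wx)^2
        img[ii, jj][sub <= (blob_r * px)^2] <- 1
        placed <- placed + 1
      }
    }
    if (noise_sigma > 0)
      img <- matrix(pmin(pmax(img + stats::rnorm(nx * ny, 0, noise_sigma), 0), 1),
                    ny, nx)
  })
  list(image = img, origin = c(xc[1], yc[1]), pixel_size = px)
}

#' Poisson-disk tip cloud on an ellipsoid surface
#'
#' Dart-throwing sampling of points on an ellipsoid surface with a hard
#' minimum pairwise spacing, emulating ureteric tip point clouds.  Sampling
#' is area-uniform (rejection against the surface-element distortion).
#'
#' @param n_target requested number of tips.
#' @param d_min minimum pairwise distance (same units as the semi-axes).
#' @param semi_axes ellipsoid semi-axes `c(a, b, c)` (micrometres in the
#'   kidney application).
#' @param seed integer seed.
#' @param sample_id,genotype labels stored on the cloud.
#' @param max_failures consecutive rejected darts before declaring the
#'   surface saturated (returns fewer tips with a warning).
#' @return A `tip_cloud`: `tips` (n x 3 matrix), `sample_id`, `genotype`,
#'   `d_min`, `semi_axes`.
#' @export
make_tip_cloud <- function(n_target, d_min, semi_axes = c(300, 200, 150),
                           seed = 0, sample_id = "synthetic", genotype = "wt",
                           max_failures = 2000) {
  if (d_min <= 0) stop_input("d_min must be positive")
  if (length(semi_axes) != 3 || any(semi_axes <= 0))
    stop_input("semi_axes must be three positive values")
  a <- semi_axes[1]; b <- semi_axes[2]; cc <- semi_axes[3]
  wmax <- max(b * cc, a * cc, a * b)
  tips <- matrix(numeric(0), 0, 3)
  with_seed(seed, {
    fails <- 0
    while (nrow(tips) < n_target && fails < max_failures) {
      u <- stats::rnorm(3)
      u <- u / sqrt(sum(u^2))
      w <- sqrt((u[1] * b * cc)^2 + (u[2] * a * cc)^2 + (u[3] * a * b)^2)
      if (stats::runif(1) > w / wmax) next
      p <- c(a * u[1], b * u[2], cc * u[3])
      if (nrow(tips) > 0 &&
          min(sqrt(colSums((t(tips) - p)^2))) < d_min) {
        fails <- fails + 1
        next
      }
      tips <- rbind(tips, p)
      fails <- 0
    }
  })
  if (nrow(tips) < n_target)
    warning(sprintf("surface saturated at %d of %d requested tips",
                    nrow(tips), n_target))
  structure(list(tips = unname(tips), sample_id = sample_id,
                 genotype = genotype, d_min = d_min, semi_axes = semi_axes),
            class = "tip_cloud")
}

#' @export
print.tip_cloud <- function(x, ...) {
  cat(sprintf("tip_cloud '%s' (%s): %d tips, min spacing >= %.3g\n",
              x$sample_id, x$genotype, nrow(x$tips), x$d_min))
  invisible(x)
}

#' Convergence-study fixture: two-bud domain and fixed growth profile
#'
#' The reference configuration for mesh-convergence checks of the deviation
#' metric: a two-bud epithelium of length scale 100 (base ellipse 32 x 20
#' with two antipodal Gaussian bud lobes of amplitude 16) inside its
#' alpha = 3 mesenchyme ellipse, together with a fixed synthetic growth
#' profile `E(s)`: Gaussian arc-length bumps of width 12 centred on the two
#' bud tips.
#'
#' @return list with `domain` (a [two_layer_domain()]), `shape`, and `E_fun`
#'   (function of arc length returning unnormalised growth magnitudes).
#' @export
fixture_convergence_domain <- function() {
  shape <- make_bud_shape(base = c(32, 20),
                          buds = list(c(0, 16, 0.45), c(pi, 16, 0.45)))
  domain <- two_layer_domain(shape, alpha = 3)
  L <- curve_length(shape)
  centres <- c(0, L / 2)
  width <- 12
  E_fun <- function(s) {
    out <- numeric(length(s))
    for (ctr in centres) {
      d <- abs(((s - ctr + L / 2) %% L) - L / 2)
      out <- out + exp(-0.5 * (d / width)^2)
    }
    out
  }
  list(domain = domain, shape = shape, E_fun = E_fun)
}
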