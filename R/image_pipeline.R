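# Boundary extraction from mask images and displacement/growth fields from
# consecutive time-lapse frames.

#' Segment the epithelium from a grayscale image
#'
#' Contrast-stretches the image to `[0, 1]`, thresholds it and keeps only
#' the connected component with the largest area, eliminating islands of
#' bright pixels that a plain threshold would wrongly assign to the
#' epithelium.
#'
#' @param image numeric matrix (any range; stretched internally), rows
#'   indexing y from the bottom as produced by [rasterize()].
#' @param threshold threshold in `[0, 1]` applied after contrast stretch.
#' @return logical matrix: the largest foreground component.
#' @export
segment_epithelium <- function(image, threshold = 0.5) {
  if (!is.matrix(image) || !length(image)) stop_input("image must be a non-empty matrix")
  rng <- range(image)
  img <- if (rng[2] > rng[1]) (image - rng[1]) / (rng[2] - rng[1]) else image * 0
  mask <- img >= threshold
  if (!any(mask))
    stop_input("empty mask after thresholding at ", threshold)
  lab <- label_components(mask)
  sizes <- tabulate(lab[lab > 0])
  lab == which.max(sizes)
}

# 4-connected component labelling by row-run merging (union-find).
label_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  parent <- integer(0)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  unite <- function(a, b) { ra <- find(a); rb <- find(b); if (ra != rb) parent[ra] <<- rb }
  prev_runs <- NULL
  all_runs <- vector("list", nr)
  for (r in seq_len(nr)) {
    v <- mask[r, ]
    if (!any(v)) { all_runs[r] <- list(NULL); prev_runs <- NULL; next }
    d <- diff(c(FALSE, v, FALSE))
    starts <- which(d == 1); ends <- which(d == -1) - 1L
    ids <- integer(length(starts))
    for (k in seq_along(starts)) {
      parent[length(parent) + 1L] <- length(parent) + 1L
      ids[k] <- length(parent)
      if (!is.null(prev_runs)) {
        for (pr in seq_len(nrow(prev_runs))) {
          if (starts[k] <= prev_runs[pr, 2] && ends[k] >= prev_runs[pr, 1])
            unite(ids[k], prev_runs[pr, 3])
        }
      }
    }
    prev_runs <- cbind(starts, ends, ids)
    all_runs[[r]] <- prev_runs
  }
  lab <- matrix(0L, nr, nc)
  roots <- integer(length(parent))
  for (i in seq_along(parent)) roots[i] <- find(i)
  uroot <- unique(roots)
  remap <- integer(length(parent))
  remap[uroot] <- seq_along(uroot)
  for (r in seq_len(nr)) {
    rr <- all_runs[[r]]
    if (is.null(rr)) next
    for (k in seq_len(nrow(rr)))
      lab[r, rr[k, 1]:rr[k, 2]] <- remap[roots[rr[k, 3]]]
  }
  lab
}

#' Ordered outer boundary of a binary mask
#'
#' Moore-neighbour boundary tracing of the single foreground component,
#' returning an ordered counter-clockwise loop of boundary pixel centres in
#' world coordinates (pixel `[i, j]` centre at `(j - 0.5, i - 0.5)` pixel
#' units, y up).
#'
#' @param mask logical matrix with exactly one 4-connected component.
#' @param origin world coordinates of pixel `[1, 1]`'s centre (default
#'   `c(0.5, 0.5)` pixel units).
#' @param pixel_size length units per pixel.
#' @return n x 2 matrix of ordered boundary points.
#' @export
extract_border <- function(mask, origin = c(0.5, 0.5), pixel_size = 1) {
  lab <- label_components(mask)
  ncomp <- max(lab)
  if (ncomp == 0) stop_input("mask is empty")
  if (ncomp > 1) stop_input("mask has ", ncomp, " components; segment first")
  fg <- which(lab == 1L, arr.ind = TRUE)
  if (nrow(fg) < 4) stop_geometry("component too small to trace a boundary loop")
  nr <- nrow(mask); nc <- ncol(mask)
  inside <- function(r, c) r >= 1 && r <= nr && c >= 1 && c <= nc && mask[r, c]
  # start: bottom-most then left-most foreground pixel
  r0 <- min(fg[, 1]); c0 <- min(fg[fg[, 1] == r0, 2])
  # Moore neighbourhood in CCW order starting from "east"
  moves <- rbind(c(0, 1), c(1, 1), c(1, 0), c(1, -1),
                 c(0, -1), c(-1, -1), c(-1, 0), c(-1, 1))
  path <- matrix(0L, 0, 2)
  cur <- c(r0, c0); backtrack <- 5L   # came from west
  repeat {
    path <- rbind(path, cur)
    found <- FALSE
    start_dir <- (backtrack %% 8L) + 1L
    for (k in 0:7) {
      dir <- ((start_dir - 1L + k) %% 8L) + 1L
      cand <- cur + moves[dir, ]
      if (inside(cand[1], cand[2])) {
        backtrack <- ((dir + 3L) %% 8L) + 1L   # direction pointing back
        cur <- cand
        found <- TRUE
        break
      }
    }
    if (!found) break                          # isolated pixel
    if (all(cur == c(r0, c0)) && nrow(path) > 2) break
    if (nrow(path) > 8 * nrow(fg)) stop_geometry("boundary tracing failed to close")
  }
  if (nrow(path) < 3) stop_geometry("degenerate boundary (isolated pixel)")
  pts <- cbind(origin[1] + (path[, 2] - 1) * pixel_size,
               origin[2] + (path[, 1] - 1) * pixel_size)
  if (polygon_signed_area(pts) < 0) pts <- pts[nrow(pts):1, , drop = FALSE]
  pts
}

#' Displacement field between consecutive boundary curves
#'
#' At `n_points` uniformly arc-length-spaced base points of the earlier
#' curve, casts the outward spline normal up to `max_ray`; the first
#' intersection with the later curve gives a positive (outward) displacement.
#' If the outward ray misses, the inward ray is cast and the magnitude is
#' negative (shrinkage); if both miss within `max_ray` the point is flagged
#' missing (`NA`).
#'
#' @param curve_t,curve_next closed `boundary_curve`s (splines fitted on the
#'   fly when absent).
#' @param n_points number of base points (default 200).
#' @param max_ray maximum ray length; default 20% of the bounding-box
#'   diagonal of `curve_t`.
#' @return A `displacement_field`: `base_points`, `normals`, `magnitudes`
#'   (signed, `NA` = missing), `vectors`, `arc` positions.
#' @export
displacement_field <- function(curve_t, curve_next, n_points = 200,
                               max_ray = NULL) {
  if (is.null(curve_t$spline)) curve_t <- fit_boundary_spline(curve_t)
  if (is.null(curve_next$spline)) curve_next <- fit_boundary_spline(curve_next)
  bb <- apply(curve_t$points, 2, range)
  if (is.null(max_ray)) max_ray <- 0.2 * sqrt(sum((bb[2, ] - bb[1, ])^2))
  L <- curve_length(curve_t)
  s <- seq(0, L, length.out = n_points + 1)[-(n_points + 1)]
  base <- curve_point(curve_t, s)
  nrm <- curve_normal(curve_t, s)
  target <- curve_resample(curve_next, max(800, n_points * 4))
  mags <- numeric(n_points)
  for (i in seq_len(n_points)) {
    tpos <- ray_polygon_first_hit(base[i, ], nrm[i, ], target, max_ray)
    if (!is.na(tpos)) { mags[i] <- tpos; next }
    tneg <- ray_polygon_first_hit(base[i, ], -nrm[i, ], target, max_ray)
    mags[i] <- if (!is.na(tneg)) -tneg else NA_real_
  }
  structure(list(base_points = base, normals = nrm, magnitudes = mags,
                 vectors = nrm * ifelse(is.na(mags), 0, mags), arc = s,
                 length = L), class = "displacement_field")
}

# Distance along ray (origin + t * dir, t > 0) to the first crossing of a
# closed polygon; NA if none within max_t.
ray_polygon_first_hit <- function(origin, dir, poly, max_t) {
  a <- poly
  b <- poly[c(2:nrow(poly), 1), , drop = FALSE]
  ex <- b[, 1] - a[, 1]; ey <- b[, 2] - a[, 2]
  denom <- dir[1] * (-ey) + dir[2] * ex
  wx <- a[, 1] - origin[1]; wy <- a[, 2] - origin[2]
  tt <- (wx * (-ey) + wy * ex) / denom
  uu <- (dir[1] * wy - dir[2] * wx) / denom
  ok <- is.finite(tt) & tt > -1e-9 & tt <= max_t & uu >= 0 & uu < 1
  if (!any(ok)) return(NA_real_)
  max(min(tt[ok]), 0)
}

#' Growth field: zeroed-shrinkage displacement field
#'
#' Replaces inward (negative) and missing displacement vectors by zero;
#' outward vectors are kept unchanged.  Shrinkage dynamics are not modelled,
#' so this information is removed before model comparison.
#'
#' @param displacements a `displacement_field`.
#' @return A `growth_field` with non-negative `magnitudes` and `vectors`
#'   along the outward normals.
#' @export
growth_field <- function(displacements) {
  if (!inherits(displacements, "displacement_field"))
    stop_input("expected a displacement_field")
  mags <- displacements$magnitudes
  mags[is.na(mags) | mags < 0] <- 0
  structure(list(base_points = displacements$base_points,
                 normals = displacements$normals,
                 magnitudes = mags,
                 vectors = displacements$normals * mags,
                 arc = displacements$arc, length = displacements$length),
            class = "growth_field")
}

#' Minimal interbud distances between separate bud outlines
#'
#' For every boundary point of every bud, computes the minimal distance to
#' the boundaries of all other buds; points closer to the image edge than to
#' any other bud are discarded (their nearest neighbour may lie outside the
#' field of view).  Reports per-bud minima over the retained points and the
#' overall minimum.
#'
#' @param buds list (>= 2) of `boundary_curve`s.
#' @param image_extent `c(xmin, xmax, ymin, ymax)` of the image, or `NULL`
#'   to skip the edge-discard rule.
#' @param n_points boundary sampling density per bud.
#' @return list with `per_bud` (data.frame bud, min_distance, n_retained),
#'   `overall_min`, and `point_distances` (per-bud vectors, `NA` =
#'   discarded).
#' @export
interbud_min_distance <- function(buds, image_extent = NULL, n_points = 200) {
  if (length(buds) < 2) stop_input("need at least two buds")
  polys <- lapply(buds, curve_resample, n = n_points)
  dists <- vector("list", length(buds))
  for (i in seq_along(buds)) {
    pts <- polys[[i]]
    other <- do.call(rbind, polys[-i])
    d_other <- point_set_min_dist(pts, other)
    if (!is.null(image_extent)) {
      d_edge <- pmin(pts[, 1] - image_extent[1], image_extent[2] - pts[, 1],
                     pts[, 2] - image_extent[3], image_extent[4] - pts[, 2])
      d_other[d_other > d_edge] <- NA
    }
    dists[[i]] <- d_other
  }
  per_bud <- data.frame(
    bud = seq_along(buds),
    min_distance = vapply(dists, function(d)
      if (all(is.na(d))) NA_real_ else min(d, na.rm = TRUE), 0),
    n_retained = vapply(dists, function(d) sum(!is.na(d)), 0L))
  overall <- if (all(is.na(per_bud$min_distance))) NA_real_
             else min(per_bud$min_distance, na.rm = TRUE)
  list(per_bud = per_bud, overall_min = overall, point_distances = dists)
}

# For each row of pts, minimal distance to the point set `other`
# (dense boundary sampling stands in for exact point-to-segment distance).
point_set_min_dist <- function(pts, other) {
  out <- numeric(nrow(pts))
  for (i in seq_len(nrow(pts)))
    out[i] <- sqrt(min((other[, 1] - pts[i, 1])^2 + (other[, 2] - pts[i, 2])^2))
  out
}
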