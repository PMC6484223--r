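# Free-boundary branching morphogenesis: grow the epithelial interface with
# normal velocity v = n * v_g * f(R^m L^n) in the quasi-steady-state limit,
# remesh periodically, detect and log branching events, classify the
# elongation mode of two opposing buds, and run the feedback experiments.

#' Signalling-dependent growth law
#'
#' `v(x) = n(x) * v_g * f(R^m L^n)` with a saturating Hill response
#' `f(s) = s^h / (K^h + s^h)`: monotone, `f(0) = 0`, bounded by 1
#' (saturation of signalling-dependent tissue growth explains the widening
#' of buds under uniformly raised ligand levels).
#'
#' @param v_g boundary speed scale (length/time, default 0.04); the outer
#'   mesenchyme boundary expands at constant speed `v_g`.
#' @param K_g half-saturation of the response; `NULL` (default) sets it at
#'   simulation start to the mean interface signal, so that the response is
#'   sensitive in the realised signal range.
#' @param h_g Hill exponent (default 2).
#' @return A `growth_law`.
#' @export
growth_law <- function(v_g = 0.04, K_g = NULL, h_g = 2) {
  if (v_g < 0) stop_input("v_g must be non-negative")
  if (!is.null(K_g) && K_g <= 0) stop_input("K_g must be positive")
  if (h_g <= 0) stop_input("h_g must be positive")
  structure(list(v_g = v_g, K_g = K_g, h_g = h_g), class = "growth_law")
}

growth_response <- function(law, s) {
  K <- law$K_g
  if (is.null(K)) stop_input("growth law half-saturation K_g is unset")
  s <- pmax(s, 0)
  s^law$h_g / (K^law$h_g + s^law$h_g)
}

#' Advance the free boundary by one growth step
#'
#' Moves every interface point along its outward normal by
#' `v_g * f(signal) * dt` (stalk points stay fixed) and expands the outer
#' mesenchyme boundary at constant normal speed `v_g`.  A step that would
#' self-intersect is retried with a halved step (up to 5 halvings).
#'
#' @param state converged `steady_state` on the current domain's mesh.
#' @param domain current [two_layer_domain()].
#' @param law a [growth_law()] with `K_g` set.
#' @param dt time step.
#' @param mesh the mesh `state` was solved on.
#' @return list with `domain` (deformed), `dt_used`.
#' @export
grow_step <- function(state, domain, law, dt, mesh) {
  crv <- domain$epithelium
  pts <- crv$points
  sa <- polyline_arclength(pts, closed = TRUE)[seq_len(nrow(pts))]
  prof <- signal_on_interface(state, mesh, n_samples = 400,
                              allow_unconverged = TRUE)
  L <- curve_length(crv)
  sig <- stats::approx(c(prof$arc, if (prof$closed) prof$length),
                       c(prof$values, if (prof$closed) prof$values[1]),
                       xout = pmin(sa, max(prof$arc)), rule = 2)$y
  speed <- law$v_g * growth_response(law, sig)
  if (!is.null(crv$stalk_interval)) {
    iv <- crv$stalk_interval
    s0 <- iv[1] %% L; arc <- (iv[2] - iv[1]) %% L
    speed[((sa - s0) %% L) < arc] <- 0
  }
  spl <- if (is.null(crv$spline)) fit_boundary_spline(crv, check_simple = FALSE) else crv
  nrm <- curve_normal(spl, sa)
  dt_used <- dt
  for (try in 0:5) {
    new_pts <- pts + nrm * speed * dt_used
    q <- if (nrow(new_pts) > 500) resample_closed(new_pts, 500) else new_pts
    if (polygon_is_simple(q)) break
    if (try == 5) stop_geometry("growth step self-intersects even after 5 halvings")
    dt_used <- dt_used / 2
  }
  new_crv <- boundary_curve(new_pts, stalk_interval = crv$stalk_interval,
                            check_simple = FALSE)
  new_crv <- fit_boundary_spline(new_crv, check_simple = FALSE)
  new_crv$stalk_interval <- crv$stalk_interval
  mes <- domain$mesenchyme
  new_mes <- if (inherits(mes, "ellipse2d"))
    ellipse2d(mes$center, mes$semi_axes + law$v_g * dt_used, mes$orientation)
  else mes
  list(domain = two_layer_domain(new_crv, new_mes), dt_used = dt_used)
}

#' Curvature-based tip detection on a closed boundary
#'
#' Tips are strict local maxima of the outward (signed) curvature above a
#' threshold, non-maximum-suppressed so that retained tips are at least
#' `min_separation` apart in arc length.
#'
#' @param curve a `boundary_curve` (spline fitted on the fly if needed).
#' @param curvature_threshold minimum curvature; default twice the
#'   equivalent-circle curvature `2 * (2 pi / L)` (a circle has no tips).
#' @param min_separation minimum arc-length separation; default `L / 20`.
#' @param n_samples curvature sampling density.
#' @return data.frame with `arc`, `x`, `y`, `curvature` (possibly 0 rows).
#' @export
detect_tips <- function(curve, curvature_threshold = NULL,
                        min_separation = NULL, n_samples = 720) {
  if (is.null(curve$spline)) curve <- fit_boundary_spline(curve)
  L <- curve_length(curve)
  if (is.null(curvature_threshold)) curvature_threshold <- 2 * (2 * pi / L)
  if (is.null(min_separation)) min_separation <- L / 20
  s <- seq(0, L, length.out = n_samples + 1)[-(n_samples + 1)]
  k <- curve_curvature(curve, s)
  kl <- c(k[n_samples], k[-n_samples]); kr <- c(k[-1], k[1])
  cand <- which(k > curvature_threshold & k > kl & k > kr)
  if (!length(cand))
    return(data.frame(arc = numeric(0), x = numeric(0), y = numeric(0),
                      curvature = numeric(0)))
  ord <- cand[order(-k[cand])]
  keep <- integer(0)
  for (i in ord) {
    if (!length(keep) ||
        all(pmin(abs(s[i] - s[keep]), L - abs(s[i] - s[keep])) >= min_separation))
      keep <- c(keep, i)
  }
  keep <- sort(keep)
  pts <- curve_point(curve, s[keep])
  data.frame(arc = s[keep], x = pts[, 1], y = pts[, 2], curvature = k[keep])
}

#' Simulate branching morphogenesis on a deforming domain
#'
#' Alternates steady-state solves (quasi-steady-state limit: the same
#' branching pattern would be obtained with any lower growth rate) and
#' growth steps; the solution is mapped to the deformed domain as the next
#' initial condition, the boundary is re-sampled uniformly ("remeshed")
#' every `remesh_every` steps, and tips are tracked to log branching events
#' (a tip-count increase of 2 within the event window is a trifurcation, an
#' increase of 1 a bifurcation).
#'
#' @param model a [model_spec()].
#' @param init initial [two_layer_domain()].
#' @param law a [growth_law()].
#' @param t_end simulated time horizon.
#' @param dt growth step.
#' @param remesh_every boundary re-sampling cadence (steps).
#' @param seed perturbation seed for the first solve.
#' @param h mesh size; default `curve length / 100`.
#' @param tol steady-state tolerance per solve.
#' @param curvature_threshold,min_separation tip-detection settings
#'   (fractions of the instantaneous curve; see [detect_tips()]).
#' @return A `branching_run`: `shapes` (list of `boundary_curve` per step),
#'   `times`, `tip_counts`, `events` (data.frame `time`, `before`, `after`,
#'   `label`), `law` (with realised `K_g`).
#' @export
simulate_branching <- function(model, init, law, t_end, dt = 1,
                               remesh_every = 10, seed = 0, h = NULL,
                               tol = 1e-5, curvature_threshold = NULL,
                               min_separation = NULL) {
  domain <- init
  n_steps <- ceiling(t_end / dt)
  shapes <- vector("list", n_steps + 1)
  times <- numeric(n_steps + 1)
  tip_counts <- integer(n_steps + 1)
  shapes[[1]] <- domain$epithelium
  tip_counts[1] <- max(1L, nrow(detect_tips(domain$epithelium,
                                            curvature_threshold, min_separation)))
  prev <- NULL
  t_now <- 0
  events <- data.frame(time = numeric(0), before = integer(0),
                       after = integer(0), label = character(0))
  n_boundary <- nrow(domain$epithelium$points)
  resample_boundary <- function(domain) {
    crv <- domain$epithelium
    res <- fit_boundary_spline(curve_resample(crv, n_boundary),
                               check_simple = FALSE)
    res$stalk_interval <- crv$stalk_interval
    two_layer_domain(res, domain$mesenchyme)
  }
  for (step in seq_len(n_steps)) {
    hh <- h %||% (curve_length(domain$epithelium) / 100)
    mesh <- tryCatch(build_mesh(domain, hh), budmorph_geometry_error =
                       function(e) NULL)
    if (is.null(mesh)) {       # mesh-quality collapse: force a remesh
      domain <- resample_boundary(domain)
      mesh <- tryCatch(build_mesh(domain, hh), budmorph_geometry_error =
                         function(e) NULL)
      # deformed shapes can defeat the quality floor locally; accept a
      # degraded mesh rather than aborting a qualitative growth run
      if (is.null(mesh)) mesh <- build_mesh(domain, hh, min_angle = 0.5)
    }
    init_state <- if (is.null(prev)) NULL
                  else interp_state(prev$state, prev$mesh, mesh)
    st <- solve_steady(model, mesh, init = init_state, seed = seed, tol = tol)
    if (is.null(law$K_g)) {
      prof0 <- signal_on_interface(st, mesh, allow_unconverged = TRUE)
      law$K_g <- max(mean(prof0$values), 1e-12)
    }
    gs <- grow_step(st, domain, law, dt, mesh)
    domain <- gs$domain
    if (step %% remesh_every == 0) domain <- resample_boundary(domain)
    prev <- list(state = st, mesh = mesh)
    t_now <- t_now + gs$dt_used
    shapes[[step + 1]] <- domain$epithelium
    times[step + 1] <- t_now
    tips <- detect_tips(domain$epithelium, curvature_threshold, min_separation)
    tip_counts[step + 1] <- max(1L, nrow(tips))
    dcount <- tip_counts[step + 1] - tip_counts[step]
    if (dcount > 0) {
      lab <- if (dcount >= 2) "trifurcation" else "bifurcation"
      events <- rbind(events, data.frame(time = t_now,
                                         before = tip_counts[step],
                                         after = tip_counts[step + 1],
                                         label = lab))
    }
  }
  structure(list(shapes = shapes, times = times, tip_counts = tip_counts,
                 events = events, law = law),
            class = "branching_run")
}

#' @export
print.branching_run <- function(x, ...) {
  cat(sprintf("branching_run: %d steps, tips %d -> %d, %d events\n",
              length(x$times) - 1, x$tip_counts[1],
              x$tip_counts[length(x$tip_counts)], nrow(x$events)))
  if (nrow(x$events)) print(x$events)
  invisible(x)
}

#' Classify the elongation mode from tip signalling profiles
#'
#' A pattern supports the elongation mode of branching when, on both
#' opposing tips, (i) it has substantial amplitude (`max/min > 5`), (ii) it
#' has exactly one peak, and (iii) the peak lies in the centre of the bud
#' within 10% of the bud arc length.
#'
#' @param profiles a `signal_profile` or list of them (one per tip; a single
#'   profile with `mirror = TRUE` stands for both tips of a symmetric
#'   two-bud configuration).
#' @param amplitude_threshold max/min threshold (default 5).
#' @param center_tol centre tolerance as a fraction of the bud arc length.
#' @param prominence peak prominence as a fraction of the profile range.
#' @param center arc position of the bud centre; defaults to mid-arc for an
#'   open profile and to position 0 (wrap-aware) for a closed one.
#' @return A `classification_result`: `elongation` plus per-tip criterion
#'   flags.
#' @export
classify_elongation <- function(profiles, amplitude_threshold = 5,
                                center_tol = 0.1, prominence = 0.05,
                                center = NULL) {
  if (inherits(profiles, "signal_profile")) profiles <- list(profiles)
  if (!length(profiles)) stop_input("no profiles supplied")
  per_tip <- lapply(profiles, function(pr) {
    v <- pr$values
    if (!length(v) || all(v == 0)) stop_input("empty signalling profile")
    amp_ok <- max(v) / max(min(v), 1e-300) > amplitude_threshold
    pk <- find_peaks(v, pr$closed, prominence)
    peak_ok <- length(pk) == 1
    ctr <- center %||% (if (pr$closed) 0 else pr$length / 2)
    cen_ok <- FALSE
    if (length(pk) >= 1) {
      s_peak <- pr$arc[pk[1]]
      d <- if (pr$closed) min(abs(s_peak - ctr), pr$length - abs(s_peak - ctr))
           else abs(s_peak - ctr)
      cen_ok <- d <= center_tol * pr$length
    }
    list(amplitude = amp_ok, single_peak = peak_ok, centred = cen_ok)
  })
  flags <- vapply(per_tip, function(x) x$amplitude && x$single_peak && x$centred,
                  TRUE)
  structure(list(elongation = all(flags), per_tip = per_tip),
            class = "classification_result")
}

# Indices of local maxima with prominence above `prom_frac` of the range.
find_peaks <- function(v, closed, prom_frac = 0.05) {
  n <- length(v)
  if (n < 3) return(integer(0))
  vl <- if (closed) c(v[n], v[-n]) else c(Inf, v[-n])
  vr <- if (closed) c(v[-1], v[1]) else c(v[-1], Inf)
  cand <- which(v > vl & v >= vr)
  rng <- max(v) - min(v)
  if (rng <= 0) return(integer(0))
  keep <- integer(0)
  for (i in cand) {
    # prominence: drop to the highest of the two lowest saddles around i
    left <- if (closed) c(v[seq_len(i - 1)], v[seq(i, n)]) else v[seq_len(i)]
    # simple O(n) prominence: lowest value between this peak and the nearest
    # higher point on each side (or the profile end)
    prom <- peak_prominence(v, i, closed)
    if (prom >= prom_frac * rng) keep <- c(keep, i)
  }
  keep
}

peak_prominence <- function(v, i, closed) {
  n <- length(v)
  idx <- if (closed) ((i - 1):(i + n - 2)) %% n + 1 else seq_len(n)
  pos <- if (closed) 1 else i
  vv <- if (closed) v[idx] else v
  higher <- which(vv > vv[pos])
  if (!length(higher)) return(vv[pos] - min(vv))
  lefts <- higher[higher < pos]; rights <- higher[higher > pos]
  sadL <- if (length(lefts)) min(vv[max(lefts):pos]) else min(vv[1:pos])
  sadR <- if (length(rights)) min(vv[pos:min(rights)]) else min(vv[pos:length(vv)])
  vv[pos] - max(sadL, sadR)
}

#' Fraction of parameter sets supporting the elongation mode
#'
#' `Lambda = n_el / n_t`, the fraction of sampled parameter sets whose
#' steady pattern satisfies all elongation criteria.
#'
#' @param results list of `classification_result`s (or logical vector).
#' @return Scalar in `[0, 1]`.
#' @export
lambda_fraction <- function(results) {
  if (!length(results)) stop_input("no classification results")
  flags <- if (is.logical(results)) results
           else vapply(results, function(x) isTRUE(x$elongation), TRUE)
  mean(flags)
}

#' Two opposing buds at distance l0 (mirror-reduced geometry)
#'
#' Builds the computational domain for two identical opposing buds whose
#' facing tips are `l0` apart: by symmetry, one bud is solved next to a
#' zero-flux mirror plane at `l0 / 2` from its tip (a zero-flux plane is
#' exactly equivalent to the identical mirrored bud for symmetric patterns).
#' The outer boundary is the bud's alpha-scaled moment ellipse truncated by
#' the mirror plane.
#'
#' @param l0 tip-to-tip distance between the opposing buds.
#' @param bud_axes semi-axes of the bud (default `c(14, 10)`, tip at +x).
#' @param alpha mesenchyme size factor.
#' @param stalk_frac fraction of the bud outline marked as stalk at the
#'   back (attachment to the parent branch); profiles cover the free front
#'   surface only.
#' @return A [two_layer_domain()] whose mesenchyme is a truncated-ellipse
#'   `boundary_curve`.
#' @export
two_bud_domain <- function(l0, bud_axes = c(14, 10), alpha = 3,
                           stalk_frac = 0.35) {
  if (l0 <= 0) stop_input("l0 must be positive")
  bud <- make_bud_shape(base = bud_axes, buds = list())
  if (stalk_frac > 0) {
    # the back of the bud attaches to the parent branch: mark it as stalk so
    # that profiles and growth act on the free front surface only
    Lb <- curve_length(bud)
    bud$stalk_interval <- c(0.5 - stalk_frac / 2, 0.5 + stalk_frac / 2) * Lb
  }
  ell <- mesenchyme_ellipse(bud, alpha = alpha)
  x_m <- bud_axes[1] + l0 / 2
  if (x_m >= ell$semi_axes[1] * 0.999)
    return(two_layer_domain(bud, ell))     # plane beyond the ellipse: no cut
  th <- seq(0, 2 * pi, length.out = 721)[-721]
  pts <- ellipse_point(ell, th)
  keep <- pts[, 1] < x_m
  # reorder so the kept arc is contiguous, then close along the chord
  first_out <- which(!keep & c(keep[length(keep)], keep[-length(keep)]))[1]
  ord <- ((seq_along(th) + first_out - 2) %% length(th)) + 1
  pts <- pts[ord, , drop = FALSE]
  keep <- keep[ord]
  arc_pts <- pts[keep, , drop = FALSE]
  # chord endpoints on x = x_m
  yy <- ell$semi_axes[2] * sqrt(pmax(1 - (x_m / ell$semi_axes[1])^2, 0))
  ends <- rbind(c(x_m, -yy), c(x_m, yy))
  d_first <- sum((arc_pts[1, ] - ends[1, ])^2)
  chord_top <- if (d_first < sum((arc_pts[1, ] - ends[2, ])^2)) ends[2, ] else ends[1, ]
  chord_bot <- if (identical(chord_top, ends[2, ])) ends[1, ] else ends[2, ]
  ny <- max(3, round(2 * yy / (2 * pi * ell$semi_axes[1] / 720)))
  chord <- cbind(x_m, seq(chord_top[2], chord_bot[2], length.out = ny))
  outer <- boundary_curve(rbind(arc_pts, chord[-c(1, nrow(chord)), , drop = FALSE]),
                          check_simple = FALSE)
  two_layer_domain(bud, outer)
}

#' Two-bud feedback experiment: minimal sustaining distance and Lambda
#'
#' For each variant and interbud distance `l0`, solves the model on the
#' mirror-reduced two-bud domain and classifies the elongation mode; reports
#' the smallest `l0` that still supports elongation (per parameter set) and
#' the fraction `Lambda` of sets supporting elongation at each `l0`.
#'
#' @param variants character vector (typically `c("T1", "T5")`).
#' @param l0_grid decreasing vector of tip-to-tip distances.
#' @param param_sets data.frame of sampled parameters (shared across
#'   variants), or `NULL` to use the fixture set only.
#' @param bud_axes bud semi-axes passed to [two_bud_domain()].
#' @param h mesh size.
#' @param seed solver perturbation seed.
#' @param tol steady-state tolerance.
#' @param template parameter template for unsampled entries (defaults to the
#'   fixture T5 set so that feedback parameters are active for T5).
#' @return list with `lambda` (matrix l0 x variant), `min_l0` (per variant:
#'   smallest grid l0 sustaining elongation for the majority rule used),
#'   `detail` (data.frame variant, l0, set, elongation).
#' @export
two_bud_experiment <- function(variants = c("T1", "T5"), l0_grid,
                               param_sets = NULL, bud_axes = c(14, 10),
                               h = 2, seed = 0, tol = 1e-6, template = NULL) {
  if (is.unsorted(rev(l0_grid))) stop_input("l0_grid must be decreasing")
  template <- template %||% fixture_parameters()$T5
  n_sets <- if (is.null(param_sets)) 1L else nrow(param_sets)
  detail <- expand.grid(variant = variants, l0 = l0_grid, set = seq_len(n_sets),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  detail$elongation <- NA
  domains <- lapply(l0_grid, two_bud_domain, bud_axes = bud_axes)
  # the chord-truncated outer boundary compresses the mesenchymal gap near
  # the mirror plane; accept locally thinner triangles there
  meshes <- lapply(domains, build_mesh, target_h = h, min_angle = 4)
  for (r in seq_len(nrow(detail))) {
    li <- match(detail$l0[r], l0_grid)
    ps <- if (is.null(param_sets)) template
          else row_to_params(param_sets[detail$set[r], ], template)
    mod <- model_spec(detail$variant[r], ps, enforce = TRUE)
    st <- tryCatch(solve_steady(mod, meshes[[li]], seed = seed, tol = tol),
                   error = function(e) NULL)
    detail$elongation[r] <- if (is.null(st) || !st$converged) FALSE else {
      prof <- signal_on_interface(st, meshes[[li]])
      isTRUE(classify_elongation(prof)$elongation)
    }
  }
  lambda <- sapply(variants, function(vv)
    sapply(l0_grid, function(l)
      mean(detail$elongation[detail$variant == vv & detail$l0 == l])))
  lambda <- matrix(lambda, nrow = length(l0_grid),
                   dimnames = list(sprintf("%g", l0_grid), variants))
  min_l0 <- vapply(variants, function(vv) {
    ok <- sapply(l0_grid, function(l)
      mean(detail$elongation[detail$variant == vv & detail$l0 == l]) > 0)
    # walk down from the largest l0 while elongation persists
    res <- NA_real_
    for (i in seq_along(l0_grid)) {
      if (ok[i]) res <- l0_grid[i] else break
    }
    res
  }, 0)
  list(lambda = lambda, min_l0 = min_l0, detail = detail)
}

#' Add an external ligand source to a model
#'
#' Represents experimental ligand addition: `uniform` raises the mesenchymal
#' production rate everywhere; `bead` adds a localised source
#' `rate * 1(|x - location| < radius)` (validated against the mesh at solve
#' time: a bead placed where there is no mesenchymal tissue is rejected).
#'
#' @param model a [model_spec()].
#' @param kind `"uniform"` or `"bead"`.
#' @param location bead centre (required for `kind = "bead"`).
#' @param rate added production rate (>= 0).
#' @param radius bead radius (required for `kind = "bead"`).
#' @return The modified `model_spec`.
#' @export
add_ligand_source <- function(model, kind = c("uniform", "bead"),
                              location = NULL, rate = 0, radius = NULL) {
  kind <- match.arg(kind)
  if (rate < 0) stop_input("rate must be non-negative")
  if (rate == 0) return(model)
  if (kind == "bead") {
    if (is.null(location) || is.null(radius) || radius <= 0)
      stop_input("bead sources need a location and a positive radius")
  }
  model$extra_sources <- c(model$extra_sources,
                           list(list(kind = kind, location = location,
                                     rate = rate, radius = radius)))
  model
}
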