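# Quantitative comparison of predicted signalling and measured growth:
# C (normalised R^m L^n), E (normalised growth magnitude), the per-frame
# boundary-integral deviation Delta and its sum Delta_g over frames, and
# log-uniform parameter screening of the model variants.

#' Construct a signal profile from arc positions and values
#'
#' Builds the `signal_profile` container used by [deviation()] and
#' [classify_elongation()], e.g. to wrap a measured growth profile on the
#' same grid as a computed signalling profile.
#'
#' @param arc strictly increasing arc-length positions.
#' @param values non-negative profile values.
#' @param closed whether the profile wraps around a closed interface.
#' @param length_ total interface length (defaults to the grid extent plus
#'   one spacing for closed profiles).
#' @return A `signal_profile`.
#' @export
make_profile <- function(arc, values, closed, length_ = NULL) {
  structure(list(arc = arc, values = values, closed = closed,
                 length = length_ %||% (max(arc) + if (closed) diff(arc)[1] else 0)),
            class = "signal_profile")
}

#' Normalised signalling profile C
#'
#' `C = R^m L^n / max(R^m L^n)` over the interface, so that `max(C) = 1`.
#'
#' @param profile a `signal_profile` (see [signal_on_interface()]).
#' @return Numeric vector of `C` values on the profile's arc grid.
#' @export
normalize_signal <- function(profile) {
  mx <- max(profile$values)
  if (!is.finite(mx) || mx <= 0)
    stop_input("cannot normalise an all-zero signalling profile")
  profile$values / mx
}

#' Normalised growth profile E
#'
#' `E = |v| / max(|v|)` of the growth-field magnitudes sampled along the
#' interface.
#'
#' @param field a `growth_field` (see [growth_field()]) or a numeric vector
#'   of magnitudes.
#' @return Numeric vector of `E` values.
#' @export
normalize_growth <- function(field) {
  mags <- if (inherits(field, "growth_field")) field$magnitudes else field
  mx <- max(mags)
  if (!is.finite(mx) || mx <= 0) stop_input("cannot normalise an all-zero growth field")
  mags / mx
}

#' Boundary-integral deviation between C and E
#'
#' `Delta = sqrt( integral over the interface of (C - E)^2 ds )`, computed by
#' trapezoidal quadrature on the common arc-length grid (periodic closure for
#' a closed interface).
#'
#' @param C,E numeric vectors on the same arc grid, or `C` may be a
#'   `signal_profile` whose `arc` supplies the grid when `E` is a profile too.
#' @param interface arc-length grid; defaults to the grid carried by `C`
#'   when `C` is a profile.
#' @param closed whether the grid wraps around (closed interface).
#' @return The deviation `Delta` (non-negative scalar).
#' @export
deviation <- function(C, E, interface = NULL, closed = NULL) {
  if (inherits(C, "signal_profile")) {
    interface <- interface %||% C$arc
    closed <- closed %||% C$closed
    total_len <- C$length
    C <- C$values
  } else total_len <- NULL
  if (inherits(E, "signal_profile")) {
    if (!is.null(interface) && (length(E$arc) != length(interface) ||
                                max(abs(E$arc - interface)) > 1e-9 * max(interface, 1)))
      stop_input("C and E are sampled on different arc grids")
    E <- E$values
  }
  if (length(C) != length(E)) stop_input("C and E have different lengths")
  if (is.null(interface)) stop_input("an arc-length grid is required")
  closed <- closed %||% FALSE
  d2 <- (C - E)^2
  s <- interface
  if (closed) {
    total_len <- total_len %||% (max(s) + stats::median(diff(s)))
    s <- c(s, total_len)
    d2 <- c(d2, d2[1])
  }
  w <- diff(s)
  sqrt(sum(w * (d2[-length(d2)] + d2[-1]) / 2))
}

#' Global deviation over a time-lapse
#'
#' `Delta_g(p) = sum over frames of Delta_frame(p)`; requires every
#' parameter set to be evaluated on every frame.
#'
#' @param per_frame numeric vector (one set) or matrix (frames x sets) of
#'   per-frame deviations.
#' @return Named vector of `Delta_g` per parameter set.
#' @export
global_deviation <- function(per_frame) {
  if (is.list(per_frame) && !is.data.frame(per_frame))
    per_frame <- do.call(rbind, per_frame)
  if (is.null(dim(per_frame))) per_frame <- matrix(per_frame, ncol = 1)
  if (anyNA(per_frame)) stop_input("missing per-frame deviation for a parameter set")
  colSums(per_frame)
}

#' Log-uniform parameter sampling
#'
#' Draws each parameter as `10^U(log10 lo, log10 hi)`, reproducibly under a
#' seed, emulating the log-uniform screening of the model family.
#'
#' @param ranges named list of `c(lo, hi)` ranges with `0 < lo <= hi`.
#' @param n_sets number of sets.
#' @param seed integer seed.
#' @return data.frame with one column per parameter plus a `seed` column.
#' @export
sample_parameters <- function(ranges, n_sets, seed = 0) {
  if (!length(ranges) || is.null(names(ranges)))
    stop_input("ranges must be a named list of c(lo, hi)")
  for (r in ranges) if (r[1] <= 0 || r[2] < r[1])
    stop_input("ranges require 0 < lo <= hi")
  draws <- with_seed(seed, lapply(ranges, function(r)
    10^stats::runif(n_sets, log10(r[1]), log10(r[2]))))
  out <- as.data.frame(draws)
  out$seed <- rep(as.integer(seed), nrow(out))
  out
}

#' Default log-uniform screening ranges
#'
#' Two decades around the fixture Turing set for each kinetic parameter,
#' with the ligand/receptor diffusion ratio kept at or above 10 for the
#' variants that require differential diffusion.
#'
#' @param decades half-width of each range in decades (default 1).
#' @return Named list of ranges accepted by [sample_parameters()].
#' @export
default_screen_ranges <- function(decades = 1) {
  base <- fixture_parameters()$T1
  nm <- c("D_R", "D_L", "rho_R", "rho_L", "delta_R", "delta_L", "mu", "v")
  out <- lapply(nm, function(k) base[[k]] * 10^c(-decades, decades))
  names(out) <- nm
  out
}

#' Materialise a sampled parameter row as a parameter set
#'
#' Converts one row of a [sample_parameters()] table into a
#' [parameter_set()], recycling values from a template (default: the
#' fixture Turing set) for parameters absent from the sample.
#'
#' @param row one-row data.frame (or named list) of parameter values.
#' @param template optional `parameter_set` supplying unsampled parameters.
#' @return A `parameter_set`.
#' @export
row_to_params <- function(row, template = NULL) {
  tpl <- template %||% fixture_parameters()$T1
  args <- as.list(tpl)[c("D_R", "D_L", "rho_R", "rho_L", "delta_R", "delta_L",
                         "mu", "v", "m", "n", "D_L1", "b1", "delta_L1",
                         "gamma", "K_fb")]
  for (k in intersect(names(row), names(args))) args[[k]] <- as.numeric(row[[k]])
  do.call(parameter_set, args)
}

#' Screen model variants against measured growth fields
#'
#' For every variant and sampled parameter set, solves the model to steady
#' state on each frame's two-layer domain, extracts the normalised interface
#' signalling `C`, and accumulates the deviation from the frame's normalised
#' growth profile `E` into the global deviation `Delta_g`.  Variants are
#' ranked by their minimal `Delta_g` over the sampled sets.
#'
#' @param variants character vector of variant names (subset of T1-T5).
#' @param frames list of frames, each a list with `domain` (a
#'   [two_layer_domain()]) and `E` (growth profile: list with `arc`,
#'   `values` on that frame's interface, or a function of arc length).
#' @param param_sets data.frame from [sample_parameters()] (shared across
#'   variants; each variant enforces its structural constraints on the set).
#' @param h mesh size.
#' @param n_samples interface sampling resolution.
#' @param seed perturbation seed passed to the solver.
#' @param tol steady-state tolerance.
#' @param template optional `parameter_set` supplying unsampled parameters.
#' @return A `screen_result`: `table` (data.frame variant x set with
#'   `delta_g`), `per_frame` array, `best` (per-variant minimal `Delta_g`),
#'   `ranking` (variants ordered by minimal `Delta_g`), `n_unconverged`.
#' @export
screen_models <- function(variants, frames, param_sets, h = 2,
                          n_samples = 400, seed = 0, tol = 1e-5,
                          template = NULL, mesh_args = list(),
                          solver_args = list()) {
  stopifnot(length(frames) >= 1)
  meshes <- lapply(frames, function(fr)
    do.call(build_mesh, c(list(fr$domain, h), mesh_args)))
  Egrids <- vector("list", length(frames))
  n_sets <- nrow(param_sets)
  delta <- array(NA_real_, c(length(frames), n_sets, length(variants)),
                 dimnames = list(NULL, NULL, variants))
  uncv <- 0L
  for (vi in seq_along(variants)) {
    for (si in seq_len(n_sets)) {
      ps <- row_to_params(param_sets[si, ], template)
      mod <- model_spec(variants[vi], ps, enforce = TRUE)
      for (fi in seq_along(frames)) {
        st <- tryCatch(do.call(solve_steady,
                 c(list(mod, meshes[[fi]], seed = seed, tol = tol), solver_args)),
                       error = function(e) NULL)
        if (is.null(st) || !st$converged) { uncv <- uncv + 1L; next }
        prof <- signal_on_interface(st, meshes[[fi]], n_samples = n_samples)
        if (max(prof$values) <= 0) next
        C <- normalize_signal(prof)
        Ev <- if (is.function(frames[[fi]]$E)) frames[[fi]]$E(prof$arc)
              else stats::approx(frames[[fi]]$E$arc, frames[[fi]]$E$values,
                                 xout = prof$arc, rule = 2)$y
        E <- Ev / max(Ev)
        delta[fi, si, vi] <- deviation(
          make_profile(prof$arc, C, prof$closed, prof$length),
          make_profile(prof$arc, E, prof$closed, prof$length))
      }
    }
  }
  dg <- apply(delta, c(2, 3), function(x) if (anyNA(x)) NA_real_ else sum(x))
  best <- apply(dg, 2, function(x) if (all(is.na(x))) NA_real_ else min(x, na.rm = TRUE))
  ranking <- names(sort(best))
  structure(list(table = data.frame(variant = rep(variants, each = n_sets),
                                    set = rep(seq_len(n_sets), length(variants)),
                                    delta_g = as.vector(dg)),
                 per_frame = delta, best = best, ranking = ranking,
                 n_unconverged = uncv), class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  cat("screen_result: minimal Delta_g per variant\n")
  print(round(x$best, 4))
  cat("ranking:", paste(x$ranking, collapse = " < "),
      sprintf("(%d unconverged solves excluded)\n", x$n_unconverged))
  invisible(x)
}
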