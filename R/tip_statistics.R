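# Tip-density morphometrics: minimum-volume enclosing ellipsoid, area per
# tip, neighbourhood median tip-to-tip distance, volume binning, and Welch's
# t-test from group summaries.

#' Tip cloud constructor
#'
#' @param tips n x 3 (or n x 2) matrix of tip coordinates (micrometres).
#' @param sample_id,genotype labels.
#' @return A `tip_cloud`.
#' @export
tip_cloud <- function(tips, sample_id = "sample", genotype = "wt") {
  tips <- as.matrix(tips)
  storage.mode(tips) <- "double"
  if (anyNA(tips) || any(!is.finite(tips))) stop_input("tip coordinates must be finite")
  if (!ncol(tips) %in% 2:3) stop_input("tips must have 2 or 3 coordinates")
  structure(list(tips = unname(tips), sample_id = sample_id,
                 genotype = genotype), class = "tip_cloud")
}

#' Group summary statistics (n, mean, SD)
#'
#' @param n number of tips.
#' @param mean,sd group mean and standard deviation (micrometres).
#' @param median,se optional extra summaries.
#' @return A `group_summary`.
#' @export
group_summary <- function(n, mean, sd, median = NA_real_, se = NA_real_) {
  if (n < 2) stop_input("group summaries require n >= 2")
  if (sd < 0) stop_input("sd must be non-negative")
  structure(list(n = as.integer(n), mean = mean, sd = sd, median = median,
                 se = se), class = "group_summary")
}

#' Minimum-volume enclosing ellipsoid (Khachiyan algorithm)
#'
#' Iteratively reweights the points until the Loewner ellipsoid is found to
#' tolerance; returns centre, semi-axes, orientation, volume and surface
#' area (Thomsen's approximation with exponent 1.6075; exact for spheres).
#'
#' @param points n x d matrix (d = 2 or 3); for d = 3 at least 4 points in
#'   general position are required.
#' @param tol convergence tolerance of the Khachiyan iteration.
#' @return list with `center`, `semi_axes` (decreasing), `axes` (columns =
#'   directions), `volume`, `surface_area`, `A` (shape matrix:
#'   `(x-c)' A (x-c) <= 1`).
#' @export
min_enclosing_ellipsoid <- function(points, tol = 1e-4) {
  if (inherits(points, "tip_cloud")) points <- points$tips
  P <- t(as.matrix(points))
  d <- nrow(P); n <- ncol(P)
  if (n < d + 1) stop_input("need at least ", d + 1, " points in ", d, "D")
  if (qr(sweep(t(P), 2, rowMeans(P)))$rank < d)
    stop_geometry("points are degenerate (coplanar/collinear); use a lower dimension")
  Q <- rbind(P, 1)
  u <- rep(1 / n, n)
  for (it in seq_len(5000)) {
    X <- Q %*% (u * t(Q))
    Minv <- solve(X)
    mdist <- colSums(Q * (Minv %*% Q))
    j <- which.max(mdist)
    step <- (mdist[j] - d - 1) / ((d + 1) * (mdist[j] - 1))
    if (step < tol / (d + 1)) break
    u <- (1 - step) * u
    u[j] <- u[j] + step
  }
  ctr <- as.numeric(P %*% u)
  Pc <- P - ctr
  A <- solve(Pc %*% (u * t(Pc))) / d
  eg <- eigen(A, symmetric = TRUE)
  semi <- 1 / sqrt(eg$values)          # increasing eigenvalues of A
  ord <- order(semi, decreasing = TRUE)
  semi <- semi[ord]
  axes <- eg$vectors[, ord, drop = FALSE]
  if (d == 3) {
    a <- semi[1]; b <- semi[2]; cc <- semi[3]
    p <- 1.6075
    sa <- 4 * pi * (((a * b)^p + (a * cc)^p + (b * cc)^p) / 3)^(1 / p)
    vol <- 4 / 3 * pi * a * b * cc
  } else {
    # 2D: "surface area" is the enclosed area, perimeter via Ramanujan
    sa <- pi * semi[1] * semi[2]
    vol <- sa
  }
  list(center = ctr, semi_axes = semi, axes = axes, volume = vol,
       surface_area = sa, A = A)
}

#' Enclosing-ellipsoid surface area per tip, S / n_tips
#'
#' Surface area of the smallest ellipsoid enclosing all tips divided by the
#' number of tips; one of the two interbud-distance measures.
#'
#' @param cloud a [tip_cloud()].
#' @return Scalar (square micrometres per tip in the kidney application).
#' @export
area_per_tip <- function(cloud) {
  ell <- min_enclosing_ellipsoid(cloud$tips)
  ell$surface_area / nrow(cloud$tips)
}

#' Neighbourhood median tip-to-tip distance
#'
#' For each tip, the median distance to the tips in its immediate
#' neighbourhood (k nearest neighbours, capped at `cap_factor` times the
#' cloud's global median nearest-neighbour spacing); the cloud summary is
#' the median of the per-tip values.
#'
#' @param cloud a [tip_cloud()].
#' @param k neighbourhood size (default 6).
#' @param cap_factor distance cap multiplier (default 3; `Inf` disables).
#' @return list with `per_tip` (vector of per-tip medians) and `median`
#'   (cloud summary).
#' @export
median_t2t <- function(cloud, k = 6, cap_factor = 3) {
  pts <- cloud$tips
  n <- nrow(pts)
  if (n < 2) stop_input("need at least two tips")
  D <- as.matrix(stats::dist(pts))
  diag(D) <- Inf
  nn1 <- apply(D, 1, min)
  cap <- cap_factor * stats::median(nn1)
  per_tip <- numeric(n)
  for (i in seq_len(n)) {
    nb <- sort(D[i, ])[seq_len(min(k, n - 1))]
    nb <- nb[nb <= cap]
    if (!length(nb)) nb <- sort(D[i, ])[1]
    per_tip[i] <- stats::median(nb)
  }
  list(per_tip = per_tip, median = stats::median(per_tip))
}

#' Welch's t-test from group summaries
#'
#' `t = (m1 - m2) / sqrt(s1^2/n1 + s2^2/n2)` with Welch-Satterthwaite
#' degrees of freedom and a two-sided p-value, for comparing interbud
#' distances between genotypes from published summary rows.
#'
#' @param g1,g2 [group_summary()] objects (or lists with `n`, `mean`, `sd`).
#' @return list with `t`, `df`, `p_value`.
#' @export
welch_t_from_summary <- function(g1, g2) {
  for (g in list(g1, g2)) {
    if (g$n < 2) stop_input("Welch's test requires n >= 2 per group")
    if (g$sd < 0) stop_input("sd must be non-negative")
  }
  v1 <- g1$sd^2 / g1$n; v2 <- g2$sd^2 / g2$n
  if (v1 + v2 == 0) {
    eq <- isTRUE(all.equal(g1$mean, g2$mean))
    return(list(t = if (eq) 0 else Inf * sign(g1$mean - g2$mean),
                df = g1$n + g2$n - 2, p_value = if (eq) 1 else 0))
  }
  tstat <- (g1$mean - g2$mean) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (g1$n - 1) + v2^2 / (g2$n - 1))
  p <- 2 * stats::pt(-abs(tstat), df)
  list(t = tstat, df = df, p_value = p)
}

#' Standard error from summary statistics
#' @param sd standard deviation.
#' @param n sample size (>= 1).
#' @return `sd / sqrt(n)`.
#' @export
se_from_summary <- function(sd, n) {
  if (any(n < 1)) stop_input("n must be >= 1")
  if (any(sd < 0)) stop_input("sd must be non-negative")
  sd / sqrt(n)
}

#' Group samples into volume bins
#'
#' Assigns each sample to a half-open volume bin `[lo, hi)` (a volume
#' exactly at an edge goes to the upper bin).
#'
#' @param samples list of samples (any objects).
#' @param volumes numeric vector of volume proxies (one per sample).
#' @param bin_edges increasing numeric vector of bin edges.
#' @return list with `bins` (list of per-bin sample lists), `assignment`
#'   (bin index per sample, `NA` = outside all bins).
#' @export
bin_by_volume <- function(samples, volumes, bin_edges) {
  if (length(samples) != length(volumes))
    stop_input("samples and volumes must have equal length")
  if (any(volumes <= 0)) stop_input("volumes must be positive")
  if (is.unsorted(bin_edges, strictly = TRUE)) stop_input("bin_edges must be increasing")
  nb <- length(bin_edges) - 1
  assign_bin <- findInterval(volumes, bin_edges, left.open = FALSE,
                             rightmost.closed = FALSE)
  assign_bin[assign_bin == 0 | assign_bin > nb] <- NA
  bins <- lapply(seq_len(nb), function(b) samples[which(assign_bin == b)])
  names(bins) <- paste0("bin", seq_len(nb))
  list(bins = bins, assignment = assign_bin)
}

#' Table of interbud-distance group summaries (wild type and Wnt11 mutants)
#'
#' The published per-genotype tip-to-tip distance summaries used by the
#' consistency tests: sample count, tip count, mean, median, SD and SE of
#' the tip-to-tip distance (micrometres) for wild type, Wnt11+/- and
#' Wnt11-/- kidneys, for all data and for two volume bins.
#'
#' @return data.frame with one row per (subset, genotype).
#' @export
interbud_distance_table <- function() {
  data.frame(
    subset = c("ALL", "ALL", "ALL", "Bin1", "Bin1", "Bin2", "Bin2", "Bin2"),
    genotype = c("wt", "Wnt11+/-", "Wnt11-/-", "wt", "Wnt11-/-",
                 "wt", "Wnt11+/-", "Wnt11-/-"),
    n_samples = c(24, 4, 10, 12, 8, 11, 3, 2),
    n_tips = c(4507, 701, 587, 966, 374, 2687, 490, 213),
    mean = c(108.2, 133.6, 147.3, 130.5, 144.4, 108.1, 131.8, 152.3),
    median = c(108.9, 136.2, 155.5, 133.0, 154.1, 109.7, 133.8, 158.0),
    sd = c(29.3, 30.2, 43.5, 28.2, 44.5, 25.6, 29.2, 41.2),
    se = c(0.4, 1.1, 1.8, 0.9, 2.3, 0.5, 1.3, 2.8))
}
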