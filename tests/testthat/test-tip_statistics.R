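test_that("minimum enclosing ellipsoid: sphere, known ellipsoid, degeneracy", {
  set.seed(2)
  u <- matrix(stats::rnorm(300 * 3), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  r <- 120
  ell <- min_enclosing_ellipsoid(u * r)
  expect_equal(ell$surface_area, 4 * pi * r^2, tolerance = 2e-3)
  expect_equal(ell$semi_axes, rep(r, 3), tolerance = 2e-3)
  # known ellipsoid with axis-extreme points included
  ax <- c(200, 150, 90)
  inner <- sweep(u[1:200, ], 2, ax * 0.95, "*")
  extremes <- rbind(diag(ax), -diag(ax))
  ell2 <- min_enclosing_ellipsoid(rbind(inner, extremes))
  expect_equal(sort(ell2$semi_axes, decreasing = TRUE), sort(ax, decreasing = TRUE),
               tolerance = 0.01)
  expect_error(min_enclosing_ellipsoid(matrix(stats::rnorm(9), 3, 3)),
               class = "budmorph_input_error")
  flat <- cbind(matrix(stats::rnorm(40), ncol = 2), 0)
  expect_error(min_enclosing_ellipsoid(flat), class = "budmorph_geometry_error")
})

test_that("area per tip: sphere case and duplication", {
  set.seed(3)
  u <- matrix(stats::rnorm(80 * 3), ncol = 3); u <- u / sqrt(rowSums(u^2))
  cl <- tip_cloud(u * 50)
  expect_equal(area_per_tip(cl), 4 * pi * 50^2 / 80, tolerance = 5e-3)
  cl2 <- tip_cloud(rbind(cl$tips, cl$tips))
  expect_equal(area_per_tip(cl2), area_per_tip(cl) / 2, tolerance = 1e-9)
})

test_that("median tip-to-tip distance on constructed clouds", {
  # regular 2D grid with spacing d: interior tips report d
  d <- 7
  g <- as.matrix(expand.grid(x = (0:6) * d, y = (0:6) * d))
  res <- median_t2t(tip_cloud(g), k = 4, cap_factor = 1.5)
  expect_equal(res$median, d, tolerance = 1e-12)
  # two tips at distance d: both report d
  res2 <- median_t2t(tip_cloud(rbind(c(0, 0, 0), c(0, 0, 11))))
  expect_equal(res2$per_tip, c(11, 11))
  expect_error(median_t2t(tip_cloud(matrix(0, 1, 3))),
               class = "budmorph_input_error")
  # Poisson-disk cloud respects its minimum spacing
  cl <- make_tip_cloud(150, d_min = 40, semi_axes = c(300, 220, 160), seed = 5)
  expect_gte(median_t2t(cl)$median, 40)
})

test_that("Welch's t-test from summaries matches a raw-sample oracle", {
  tt <- welch_t_from_summary(group_summary(4507, 108.2, 29.3),
                             group_summary(587, 147.3, 43.5))
  expect_lt(tt$p_value, 0.001)
  expect_equal(abs(tt$t), 21, tolerance = 0.5)
  same <- welch_t_from_summary(group_summary(10, 5, 2), group_summary(8, 5, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p_value, 1)
  # oracle: raw normal samples rescaled to the exact summary moments
  set.seed(11)
  mk <- function(n, m, s) { x <- stats::rnorm(n); m + s * (x - mean(x)) / stats::sd(x) }
  x1 <- mk(40, 10, 3); x2 <- mk(55, 12, 4)
  ours <- welch_t_from_summary(group_summary(40, 10, 3), group_summary(55, 12, 4))
  ref <- stats::t.test(x1, x2)
  expect_equal(ours$t, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(ours$df, unname(ref$parameter), tolerance = 1e-10)
  expect_equal(ours$p_value, ref$p.value, tolerance = 1e-10)
})

test_that("Welch p-value decreases monotonically with mean separation", {
  p <- vapply(c(1, 2, 4, 8), function(dm)
    welch_t_from_summary(group_summary(50, 100, 15),
                         group_summary(50, 100 + dm, 15))$p_value, 0)
  expect_true(all(diff(p) < 0))
})

test_that("every published SE equals sd/sqrt(n) at one-decimal rounding", {
  tab <- interbud_distance_table()
  expect_equal(round(se_from_summary(tab$sd, tab$n_tips), 1), tab$se)
  expect_equal(se_from_summary(0, 10), 0)
  expect_error(se_from_summary(1, 0), class = "budmorph_input_error")
})

test_that("volume binning follows half-open edge convention", {
  b <- bin_by_volume(list("a", "b"), c(5, 15), c(0, 10, 20))
  expect_equal(b$assignment, c(1, 2))
  expect_equal(b$bins$bin1, list("a"))
  # a volume exactly at an edge goes to the upper bin
  b2 <- bin_by_volume(list("x"), 10, c(0, 10, 20))
  expect_equal(b2$assignment, 2)
  b3 <- bin_by_volume(list(), numeric(0), c(0, 10))
  expect_equal(lengths(b3$bins), c(bin1 = 0L))
  b4 <- bin_by_volume(list("y"), 25, c(0, 10, 20))
  expect_true(is.na(b4$assignment))
})

test_that("tip metrics transform correctly under rigid motion and scaling", {
  cl <- make_tip_cloud(60, d_min = 50, semi_axes = c(280, 200, 150), seed = 9)
  ang <- 0.7
  Rm <- rbind(c(cos(ang), -sin(ang), 0), c(sin(ang), cos(ang), 0), c(0, 0, 1))
  moved <- tip_cloud(sweep(cl$tips %*% t(Rm), 2, c(10, -20, 5), "+"))
  expect_equal(median_t2t(moved)$median, median_t2t(cl)$median, tolerance = 1e-9)
  expect_equal(area_per_tip(moved), area_per_tip(cl), tolerance = 1e-4)
  scaled <- tip_cloud(cl$tips * 2)
  expect_equal(median_t2t(scaled)$median, 2 * median_t2t(cl)$median,
               tolerance = 1e-9)
  expect_equal(area_per_tip(scaled), 4 * area_per_tip(cl), tolerance = 1e-4)
})

test_that("tip cloud CSV round-trips", {
  cl <- make_tip_cloud(25, d_min = 60, seed = 2, sample_id = "s1",
                       genotype = "wt")
  f <- withr::local_tempfile(fileext = ".csv")
  write_tipcloud_csv(cl, f)
  back <- read_tipcloud_csv(f)
  expect_equal(back[["s1"]]$tips, cl$tips, tolerance = 1e-9)
  expect_equal(back[["s1"]]$genotype, "wt")
})
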