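# paint a Gaussian auxin bump centred at polar position (r_frac, angle_deg)
paint_bump <- function(mesh, r_frac, angle_deg, height = 10, width = 3) {
  ctr_cells <- cell_centroids(mesh)
  areas <- cell_areas(mesh)
  tc <- colSums(ctr_cells * areas) / sum(areas)
  rel <- sweep(ctr_cells, 2L, tc)
  R <- max(sqrt(rowSums(rel^2)))
  a <- angle_deg * pi / 180
  target <- tc + r_frac * R * c(cos(a), sin(a))
  d2 <- rowSums(sweep(ctr_cells, 2L, target)^2)
  mesh$aux <- mesh$aux + height * exp(-d2 / (2 * width^2))
  mesh
}

test_that("a uniform auxin field yields no middle-ring maxima", {
  m <- load_default_disk()
  m$aux <- rep(2, n_cells(m))
  mx <- extract_auxin_maxima(m)
  expect_identical(nrow(mx), 0L)   # one central component, outside the ring
  m$aux <- rep(0, n_cells(m))
  expect_identical(nrow(extract_auxin_maxima(m)), 0L)
})

test_that("localized bumps in the ring are found with correct angles", {
  m <- load_default_disk()
  m1 <- paint_bump(m, 0.5, 70)
  mx <- extract_auxin_maxima(m1)
  expect_identical(nrow(mx), 1L)
  expect_lt(abs(mx$angle - 70), 5)
  expect_gt(mx$r_frac, 1 / 3); expect_lt(mx$r_frac, 2 / 3)
  # two equal patches 180 degrees apart
  m2 <- paint_bump(paint_bump(m, 0.5, 30), 0.5, 210)
  mx2 <- extract_auxin_maxima(m2)
  expect_identical(nrow(mx2), 2L)
  gap <- abs(diff(mx2$angle))
  # cell-level discretisation of the bump shifts component centroids slightly
  expect_lt(abs(gap - 180), 6)
})

test_that("maxima extraction is stable across a range of thresholds", {
  m <- load_default_disk()
  m <- paint_bump(paint_bump(paint_bump(m, 0.5, 0), 0.5, 120), 0.5, 240)
  for (th in c(0.35, 0.5, 0.65))
    expect_identical(nrow(extract_auxin_maxima(m, threshold_frac = th)), 3L)
})

test_that("maxima extraction commutes with rigid rotation", {
  m <- paint_bump(load_default_disk(), 0.5, 40)
  mx <- extract_auxin_maxima(m)
  mr <- rotate_mesh(m, 25)
  mxr <- extract_auxin_maxima(mr)
  expect_identical(nrow(mxr), nrow(mx))
  expect_equal((mxr$angle - mx$angle) %% 360, 25, tolerance = 1e-6)
  expect_equal(mxr$mean_aux, mx$mean_aux, tolerance = 1e-9)
})

test_that("angular CV matches direct computation and its invariances", {
  expect_equal(angular_cv(c(0, 90, 180, 270)), 0)
  # gaps 45, 135, 90, 90 -> sample sd / mean = sqrt(1350)/90
  expect_equal(angular_cv(c(0, 45, 180, 270)), sqrt(1350) / 90, tolerance = 1e-12)
  expect_warning(cv1 <- angular_cv(10), "fewer than 2")
  expect_true(is.na(cv1))
  set.seed(3)
  for (i in 1:10) {
    a <- stats::runif(sample(3:8, 1L), 0, 360)
    # rotation and relabeling invariance
    expect_equal(angular_cv(a), angular_cv(sample(a)), tolerance = 1e-12)
    expect_equal(angular_cv(a), angular_cv((a + 77) %% 360), tolerance = 1e-9)
    # gaps partition the circle
    s <- sort(a)
    expect_equal(sum(c(diff(s), 360 - (s[length(s)] - s[1]))), 360)
  }
})

test_that("run summaries report counts, mean maxima auxin and CV", {
  m <- paint_bump(paint_bump(load_default_disk(), 0.5, 0), 0.5, 180)
  traj <- structure(list(snapshots = list("0" = m), config = NULL,
                         diagnostics = NULL), class = "trajectory")
  s <- summarize_run(traj)
  expect_identical(s$maxima_count, 2L)
  mx <- extract_auxin_maxima(m)
  expect_equal(s$mean_max_aux, mean(mx$mean_aux))
  expect_equal(s$angular_cv, 0, tolerance = 0.12)   # near-even two-point spacing
  m0 <- load_default_disk()
  traj0 <- structure(list(snapshots = list("0" = m0)), class = "trajectory")
  s0 <- summarize_run(traj0)
  expect_identical(s0$maxima_count, 0L)
  expect_true(is.na(s0$mean_max_aux))
})

test_that("circular histograms bin by degree and conserve total signal", {
  pt <- rbind(c(cos(46.2 * pi / 180), sin(46.2 * pi / 180)))
  h <- circular_histogram(pt, intensity = 7)
  expect_equal(h$fine_bins[46 + 1L], 7)
  expect_equal(h$coarse_bins[11 + 1L], 7)   # coarse bin 11 covers [44, 48)
  expect_equal(h$total, 7)
  expect_equal(sum(h$fine_bins), h$total)
  expect_equal(sum(h$coarse_bins), h$total)
  # many random points: totals conserved, coarse refines fine exactly
  set.seed(9)
  pts <- matrix(stats::rnorm(400), ncol = 2L)
  w <- stats::runif(200)
  h2 <- circular_histogram(pts, w)
  expect_equal(h2$total, sum(w))
  expect_equal(sum(h2$fine_bins), sum(w), tolerance = 1e-12)
  expect_equal(h2$coarse_bins, colSums(matrix(h2$fine_bins, 4L)), tolerance = 1e-12)
})

test_that("rotating points by 4 degrees shifts the coarse bins by one", {
  set.seed(4)
  ang <- stats::runif(50, 0, 360)
  r <- stats::runif(50, 0.5, 2)
  w <- stats::runif(50)
  # place points mid-bin so the 4-degree rotation cannot straddle bin edges
  ang <- floor(ang) + 0.5
  p1 <- cbind(r * cos(ang * pi / 180), r * sin(ang * pi / 180))
  a2 <- ang + 4
  p2 <- cbind(r * cos(a2 * pi / 180), r * sin(a2 * pi / 180))
  h1 <- circular_histogram(p1, w)
  h2 <- circular_histogram(p2, w)
  expect_equal(h2$coarse_bins, h1$coarse_bins[c(90, 1:89)], tolerance = 1e-12)
})

test_that("a point at the centre is binned at zero with a warning", {
  expect_warning(h <- circular_histogram(rbind(c(0, 0), c(1, 0)), c(3, 2)),
                 "centre")
  expect_equal(h$total, 5)
  expect_equal(h$fine_bins[1L], 5)
})

test_that("ensemble comparisons detect mean shifts and report all groups", {
  set.seed(12)
  tab <- data.frame(
    genotype = rep(c("a", "b", "c"), each = 50),
    maxima_count = c(stats::rnorm(50, 0), stats::rnorm(50, 5), stats::rnorm(50, 0.2)))
  cmpres <- compare_ensembles(tab, "maxima_count", "genotype")
  expect_identical(nrow(cmpres$groups), 3L)
  ab <- cmpres$means[cmpres$means$pair %in% c("b-a", "a-b"), ]
  expect_lt(ab$p_adj, 1e-6)
  ac <- cmpres$means[cmpres$means$pair %in% c("c-a", "a-c"), ]
  expect_gt(ac$p_adj, 0.05)
  expect_identical(nrow(cmpres$variances), 3L)
})

test_that("identical groups show no significant differences", {
  set.seed(13)
  x <- stats::rnorm(40)
  tab <- data.frame(genotype = rep(c("g1", "g2"), each = 40),
                    maxima_count = c(x, x))
  cmpres <- compare_ensembles(tab, "maxima_count", "genotype")
  expect_gt(cmpres$means$p_adj[1L], 0.9)
  expect_gt(cmpres$variances$p_value[1L], 0.9)
})
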