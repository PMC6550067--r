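test_that("line_scan: constants, step edges, degenerate input", {
  img <- matrix(5, 20, 20)
  prof <- line_scan(img, c(2, 2), c(18, 18), n_samples = 50)
  expect_equal(prof$intensities, rep(5, 50))
  expect_equal(diff(prof$positions),
               rep(prof$positions[2] - prof$positions[1], 49))
  # step edge at the pixel boundary col = 10 (physical 10 um at unit pitch)
  step <- cbind(matrix(0, 20, 10), matrix(100, 20, 10))
  pr <- line_scan(step, c(10, 1), c(10, 19), n_samples = 400)
  mid_cross <- pr$positions[min(which(pr$intensities >= 50))]
  expect_lt(abs((1 + mid_cross) - 10), 1)   # within one pixel of the edge
  expect_true(all(diff(pr$intensities) >= -1e-9))  # monotone transition
  expect_error(line_scan(img, c(5, 5), c(5, 5)), "zero-length")
  expect_error(line_scan(img, c(-1, 5), c(5, 5)), "outside")
})

test_that("profile_to_diameters is exact on the trapezoid fixture", {
  prof <- trapezoid_profile(d = 1.2, D = 2.0)
  dp <- profile_to_diameters(prof)
  expect_equal(dp$d_um, 1.2, tolerance = 1e-9)
  expect_equal(dp$D_um, 2.0, tolerance = 1e-9)
  # flat profile is a reported measurement error
  flat <- line_profile(seq(0, 1, by = 0.01), rep(3, 101))
  expect_measurement_error(profile_to_diameters(flat))
})

test_that("noiseless EM render recovers d and D within one EM pixel", {
  ph <- make_cylinder(d = 1.2, D = 2.0, length = 2, vx = 0.02)
  ext <- grid_extent(ph$grid)
  emg <- grid_spec(pmax(1L, floor(ext / c(0.0138, 0.0138, 0.08))),
                   c(0.0138, 0.0138, 0.08))
  em <- render_em(ph$labels, emg, noise_sd = 0)
  sc <- scan_fibre_diameters(em, n_scans = 20)
  expect_gt(nrow(sc), 10)
  expect_lt(max(abs(sc$d_um - 1.2)), 0.0138)
  expect_lt(max(abs(sc$D_um - 2.0)), 0.0138)
})

test_that("diameter g-ratio arithmetic and end-to-end recovery", {
  expect_equal(g_ratio_diameter(data.frame(d_um = 1.2, D_um = 2.0))$mean, 0.6)
  eps <- 1e-9
  expect_equal(g_ratio_diameter(data.frame(d_um = 2 - eps, D_um = 2))$mean,
               1, tolerance = 1e-6)
  ph <- make_cylinder(d = 1.2, D = 2.0, length = 2, vx = 0.04)
  em <- render_em(ph$labels, noise_sd = 0)
  g <- g_ratio_diameter(scan_fibre_diameters(em, n_scans = 15))
  expect_lt(abs(g$mean - ph$truth$fibres$g), 0.02)
  expect_equal(g$sem, g$sd / sqrt(g$n))
})

test_that("area g-ratio: circular identity and elliptical closed form", {
  expect_equal(g_ratio_area(pi * 0.36, pi)$mean, 0.6)
  # any circular pair: g_area == g_diameter exactly
  d <- runif(20, 0.5, 2); D <- d / runif(20, 0.3, 0.9)
  ga <- g_ratio_area(pi * (d / 2)^2, pi * (D / 2)^2)
  expect_equal(ga$values, d / D, tolerance = 1e-12)
  # ellipse 1.2 x 1.0 um axes inside circular D = 2.0
  g_ell <- g_ratio_area(pi * 0.6 * 0.5, pi * 1.0^2)
  expect_equal(g_ell$mean, sqrt(0.3), tolerance = 1e-12)
  expect_error(g_ratio_area(2, 1), "axon < fibre")
})

test_that("volume g-ratio: cylinder identity and taper invariance", {
  expect_equal(g_ratio_volume(22.62, 62.83)$mean, 0.6, tolerance = 1e-3)
  # analytic cylinder volumes
  expect_equal(g_ratio_volume(pi * 0.6^2 * 20, pi * 1^2 * 20)$mean, 0.6)
  # conical taper with constant local d/D = 0.6: frustum volumes share
  # the factor (r0^2 + r0 r1 + r1^2) h/3 so g_volume stays exactly 0.6
  r0 <- 1.0; r1 <- 0.5; h <- 10
  vf <- pi * h / 3 * (r0^2 + r0 * r1 + r1^2)
  va <- pi * h / 3 * ((0.6 * r0)^2 + 0.36 * r0 * r1 + (0.6 * r1)^2)
  expect_equal(g_ratio_volume(va, vf)$mean, 0.6, tolerance = 1e-12)
  # rasterized straight cylinder at >= 20 voxels/diameter: within 2% of d/D
  ph <- make_cylinder(d = 1.2, D = 2.0, length = 2, vx = 0.05)
  v <- ph$truth$volumes_um3
  gv <- g_ratio_volume(v[["axon"]], v[["axon"]] + v[["myelin"]])
  expect_lt(abs(gv$mean / 0.6 - 1), 0.02)
})

test_that("lamella counting on constructed and flat profiles", {
  pos <- seq(0, 1, by = 0.002)
  x <- rep(200, length(pos))
  centers <- seq(0.15, 0.85, length.out = 10)
  for (c0 in centers) x <- pmin(x, 200 - 170 * (abs(pos - c0) < 0.015))
  prof <- line_profile(pos, x, polarity = "dark-myelin")
  expect_identical(count_lamellae(prof, 0.2), 10L)
  expect_identical(count_lamellae(line_profile(pos, rep(7, length(pos)))), 0L)
  # prominence threshold suppresses shallow ripples riding on deep troughs
  base <- rep(200, length(pos))
  for (c0 in c(0.25, 0.5, 0.75)) base <- pmin(base, 200 - 170 * (abs(pos - c0) < 0.02))
  rippled <- base - 5 * (1 + sin(pos * 60 * pi))
  expect_identical(count_lamellae(line_profile(pos, rippled), 0.2), 3L)
})

test_that("ANOVA: degenerate cases, t^2 = F identity, lm oracle", {
  g1 <- c(0.58, 0.61, 0.60, 0.62)
  same <- compare_gratio_groups(list(a = g1, b = g1))
  expect_equal(same$anova$F[1], 0)
  expect_equal(same$anova$p[1], 1)
  sep <- compare_gratio_groups(list(a = rep(0, 4), b = rep(1, 4)))
  expect_lt(sep$anova$p[1], 1e-6)
  all_const <- compare_gratio_groups(list(a = rep(0.6, 3), b = rep(0.6, 3)))
  expect_true(is.na(all_const$anova$F[1]))
  # two groups: F equals the squared equal-variance t statistic
  set.seed(21)
  x <- rnorm(12, 0.6, 0.05); y <- rnorm(9, 0.63, 0.05)
  got <- compare_gratio_groups(list(x = x, y = y))
  tt <- stats::t.test(x, y, var.equal = TRUE)
  expect_equal(got$anova$F[1], unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(got$anova$p[1], tt$p.value, tolerance = 1e-10)
  # three groups against the lm/anova oracle
  z <- rnorm(10, 0.61, 0.04)
  got3 <- compare_gratio_groups(list(x = x, y = y, z = z))
  fit <- stats::anova(stats::lm(v ~ g, data.frame(
    v = c(x, y, z), g = rep(c("x", "y", "z"), c(12, 9, 10)))))
  expect_equal(got3$anova$F[1], fit$`F value`[1], tolerance = 1e-10)
  expect_equal(got3$anova$p[1], fit$`Pr(>F)`[1], tolerance = 1e-10)
  expect_error(compare_gratio_groups(list(a = 1:3)), "2 groups")
  expect_error(compare_gratio_groups(list(a = 1:3, b = 2)), "n >= 2")
})

test_that("ANOVA p-values are calibrated under the null", {
  set.seed(33)
  reps <- 1000
  p <- vapply(seq_len(reps), function(i) {
    g <- list(a = rnorm(8, 0.6, 0.05), b = rnorm(8, 0.6, 0.05),
              c = rnorm(8, 0.6, 0.05))
    compare_gratio_groups(g)$anova$p[1]
  }, numeric(1))
  expect_lt(abs(mean(p < 0.05) - 0.05), 0.02)
})

test_that("estimators agree on circular geometry", {
  d <- runif(30, 1, 2); D <- d / 0.6
  gd <- g_ratio_diameter(data.frame(d_um = d, D_um = D))
  ga <- g_ratio_area(pi * (d / 2)^2, pi * (D / 2)^2)
  expect_lt(max(abs(gd$values - ga$values)), 1e-12)
})
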