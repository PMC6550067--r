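test_that("rasterized cylinder volumes match analytic values", {
  # d=1.2, D=2.0, L=4 at 0.05 um voxels: diameter = 24 voxels
  ph <- make_cylinder(d = 1.2, D = 2.0, length = 4, vx = 0.05)
  v <- ph$truth$volumes_um3
  expect_lt(abs(v[["axon"]] / (pi * 0.6^2 * 4) - 1), 0.01)
  expect_lt(abs((v[["axon"]] + v[["myelin"]]) / (pi * 1.0^2 * 4) - 1), 0.01)
  expect_identical(ph$truth$fibres$g, 1.2 / 2.0)  # g = d/D to machine precision
})

test_that("myelin voxel count vanishes in the zero-thickness limit", {
  vx <- 0.05
  ph <- lapply(c(2 * vx, vx / 2, 1e-9), function(eps)
    make_cylinder(d = 1.2, D = 1.2 + eps, length = 2, vx = vx)$truth)
  counts <- vapply(ph, function(t) t$voxel_counts[["myelin"]], numeric(1))
  expect_true(all(diff(counts) < 0))
  # at eps = 1e-9 only exact-boundary voxels (float ties) can remain
  expect_lt(counts[3] / ph[[3]]$voxel_counts[["axon"]], 0.005)
})

test_that("out-of-bounds fibres error naming the axis", {
  grid <- grid_spec(c(40, 40, 40), rep(0.05, 3))
  fs <- fibre_spec(rbind(c(1, 1, 0.2), c(1, 1, 1.8)), d = 1.2, D = 2.0)
  expect_error(build_fibre_phantom(fs, grid), "axis 1")
  fs2 <- fibre_spec(rbind(c(1, 1, -0.5), c(1, 1, 1.5)), d = 0.3, D = 0.5)
  expect_error(build_fibre_phantom(fs2, grid), "axis 3")
})

test_that("fibre and node spec invariants are enforced", {
  expect_error(fibre_spec(rbind(c(0, 0, 0), c(0, 0, 1)), d = 2, D = 1.5),
               "0 < d < D")
  expect_error(fibre_spec(rbind(c(0, 0, 0)), d = 1, D = 2), "n >= 2")
  expect_error(node_spec(0, 10, 0.05), "gap_length")
  expect_error(node_spec(1, 0, 0.05), "n_lamellae")
})

test_that("node phantom: gap is bare axon and paranode has n loop bands", {
  vx <- 0.025
  grid <- grid_spec(c(124, 124, 200), rep(vx, 3))
  fs <- straight_fibre(grid, d = 1.5, D = 2.7, length = 4.4)
  nd <- node_spec(gap_length = 0.8, n_lamellae_per_side = 10,
                  lamellar_period = 0.05, paranode_length = 1.2)
  ph <- build_node_phantom(fs, nd, grid)
  lab <- ph$labels$data
  mats <- ph$labels$materials
  # gap interval: only axon/background
  zmid <- round(grid$shape[3] / 2)
  gap_planes <- which(abs(axis_coords(grid, 3) - (grid_extent(grid)[3] / 2)) <
                        0.8 / 2 - vx)
  expect_true(all(lab[, , gap_planes] %in% c(0L, mats[["axon"]])))
  # radial ray near the outer paranode end crosses exactly 10 loop bands
  ctr_px <- round(grid$shape[1:2] / 2)
  a_outer <- 0.8 / 2 + 1.2 * 0.97
  k <- round((grid_extent(grid)[3] / 2 + a_outer) / vx)
  ray <- lab[ctr_px[1], ctr_px[2]:grid$shape[2], k]
  bands <- rle(ray == mats[["loop"]])
  expect_identical(sum(bands$values), 10L)
  # innermost lamella reaches closest to the node: just outside the gap
  # only band 1 is present
  k_in <- round((grid_extent(grid)[3] / 2 + 0.8 / 2 + 0.05) / vx)
  ray_in <- lab[ctr_px[1], ctr_px[2]:grid$shape[2], k_in]
  expect_identical(sum(rle(ray_in == mats[["loop"]])$values), 1L)
})

test_that("single lamella gives a single band; misfit lamellae error", {
  vx <- 0.025
  grid <- grid_spec(c(100, 100, 120), rep(vx, 3))
  fs <- straight_fibre(grid, d = 1.2, D = 2.0, length = 2.4)
  nd <- node_spec(gap_length = 0.5, n_lamellae_per_side = 1,
                  lamellar_period = 0.1, paranode_length = 0.5)
  ph <- build_node_phantom(fs, nd, grid)
  ctr_px <- round(grid$shape[1:2] / 2)
  k <- round((grid_extent(grid)[3] / 2 + 0.25 + 0.45) / vx)
  ray <- ph$labels$data[ctr_px[1], ctr_px[2]:grid$shape[2], k]
  expect_identical(sum(rle(ray == 3L)$values), 1L)
  nd_bad <- node_spec(0.5, 10, 0.1)   # 10*0.1 > (2.0-1.2)/2
  expect_error(build_node_phantom(fs, nd_bad, grid), "lamellae do not fit")
})

test_that("fiducials: deterministic, disjoint, inside walls", {
  grid <- grid_spec(c(100, 100, 100), rep(0.5, 3))  # 50^3 um volume
  empty <- empty_labels(grid)
  a <- add_fiducials(empty, 5, 0, seed = 7)
  b <- add_fiducials(empty, 5, 0, seed = 7)
  expect_identical(a$labels$data, b$labels$data)
  expect_identical(a$fiducials, b$fiducials)
  expect_false(identical(a$labels$data,
                         add_fiducials(empty, 5, 0, seed = 8)$labels$data))
  expect_identical(nrow(a$fiducials), 5L)
  # centers at least their semi-axes from the walls
  f <- a$fiducials
  for (ax in 1:3) {
    expect_true(all(f[[paste0("axis", ax, "_um")]] -
                      f[[paste0("semi", ax, "_um")]] >= 0))
    expect_true(all(f[[paste0("axis", ax, "_um")]] +
                      f[[paste0("semi", ax, "_um")]] <= 50))
  }
  # oracle: re-rasterized ellipsoids are pairwise disjoint and cover the
  # soma voxels exactly
  vox_sets <- lapply(seq_len(5), function(i) {
    ctr <- as.numeric(f[i, 1:3]); sa <- as.numeric(f[i, 4:6])
    dy <- (axis_coords(grid, 1) - ctr[1]) / sa[1]
    dx <- (axis_coords(grid, 2) - ctr[2]) / sa[2]
    dz <- (axis_coords(grid, 3) - ctr[3]) / sa[3]
    which(outer(outer(dy^2, dx^2, "+"), dz^2, "+") <= 1)
  })
  all_vox <- unlist(vox_sets)
  expect_identical(anyDuplicated(all_vox), 0L)
  expect_setequal(all_vox, which(a$labels$data == 4L))
  # n = 0 leaves labels untouched
  z <- add_fiducials(empty, 0, 0)
  expect_identical(z$labels$data, empty$data)
})

test_that("EM rendering: noiseless LUT image, noise determinism, clipping", {
  ph <- make_cylinder(d = 1.0, D = 1.6, length = 1.5, vx = 0.05)
  cm <- default_em_contrast()
  em0 <- render_em(ph$labels, noise_sd = 0)
  # piecewise-constant equal to contrast_map of the labels
  expect_identical(sort(unique(as.vector(em0$data))),
                   sort(unname(cm[c("myelin", "axon", "background")])))
  expect_true(all((em0$data == cm[["myelin"]]) == (ph$labels$data == 2L)))
  em_a <- render_em(ph$labels, noise_sd = 10, seed = 3)
  em_b <- render_em(ph$labels, noise_sd = 10, seed = 3)
  em_c <- render_em(ph$labels, noise_sd = 10, seed = 4)
  expect_identical(em_a$data, em_b$data)
  expect_false(identical(em_a$data, em_c$data))
  expect_true(all(em_a$data >= 0 & em_a$data <= 255))
  # per-material intensity distributions sit at their means (normal mixture)
  for (m in c("background", "axon", "myelin")) {
    sel <- ph$labels$data == default_materials()[[m]]
    expect_lt(abs(mean(em_a$data[sel]) - cm[[m]]), 1)
    expect_lt(abs(stats::sd(em_a$data[sel]) - 10), 1)
  }
  bad <- cm; bad[["myelin"]] <- 250
  expect_error(render_em(ph$labels, contrast_map = bad), "myelin < axon")
})

test_that("EM resampling maps grids correctly (nearest neighbour)", {
  ph <- make_cylinder(d = 1.0, D = 1.6, length = 1, vx = 0.04)
  ext <- grid_extent(ph$grid)
  emg <- grid_spec(pmax(1, floor(ext / c(0.02, 0.02, 0.1))),
                   c(0.02, 0.02, 0.1))
  em <- render_em(ph$labels, emg, noise_sd = 0)
  expect_identical(dim(em$data), emg$shape)
  # center voxel is axon-valued in both grids
  c_src <- round(ph$grid$shape / 2)
  c_dst <- round(emg$shape / 2)
  expect_equal(em$data[c_dst[1], c_dst[2], c_dst[3]],
               default_em_contrast()[["axon"]], ignore_attr = TRUE)
})

test_that("LM rendering: identity limit and PSF broadening", {
  ph <- make_cylinder(d = 1.2, D = 2.0, length = 1.2, vx = 0.04)
  lm0 <- render_lm(ph$labels, psf_model("ideal"))
  expect_identical(lm0$myelin$data,
                   array(as.numeric(ph$labels$data == 2L), ph$grid$shape))
  expect_true(all(lm0$nuclei$data == 0))
  # blurring the ideal radial profile (1-D Gaussian convolution oracle)
  # pushes the apparent outer half-max diameter beyond D and pulls the
  # inner one below d, biasing g downward
  sigma <- 0.25 / (2 * sqrt(2 * log(2)))
  pos <- seq(-1.6, 1.6, by = 0.01)
  ideal <- as.numeric(abs(pos) > 0.6 & abs(pos) <= 1.0)
  rad <- ceiling(4 * sigma / 0.01)
  kern <- dnorm(seq(-rad, rad) * 0.01, sd = sigma)
  kern <- kern / sum(kern)
  blurred <- stats::filter(c(rep(0, rad), ideal, rep(0, rad)), kern,
                           sides = 2)
  blurred <- as.numeric(blurred[(rad + 1):(rad + length(pos))])
  dp <- profile_to_diameters(line_profile(pos - pos[1], blurred,
                                          modality = "lm",
                                          polarity = "bright-myelin"))
  expect_gt(dp$D_um, 2.0)
  expect_lt(dp$d_um, 1.2)
  # full-2D render: boundary curvature counteracts part of the 1-D
  # broadening; the apparent D still lies within one FWHM of truth
  lm <- render_lm(ph$labels, psf_model("ideal", fwhm_lateral = 0.25,
                                       fwhm_axial = 0))
  k <- round(ph$grid$shape[3] / 2)
  ctr <- grid_extent(ph$grid)[1:2] / 2
  prof <- line_scan(lm$myelin$data[, , k], c(ctr[1], 0.06),
                    c(ctr[1], 2 * ctr[2] - 0.06), n_samples = 600,
                    pixel_size = ph$grid$voxel_size[1:2],
                    modality = "lm", polarity = "bright-myelin")
  dp2 <- profile_to_diameters(prof)
  expect_lt(abs(dp2$D_um - 2.0), 0.25)
  expect_lt(dp2$d_um / dp2$D_um, 0.6)   # net bias on g is downward
  # noiseless renders identical across seeds
  lm2 <- render_lm(ph$labels, psf_model("ideal", 0.25, 0), seed = 99)
  expect_identical(lm$myelin$data, lm2$myelin$data)
})

test_that("modality transforms: closed forms and exact inversion", {
  pts <- cbind(runif(20, -30, 30), runif(20, -30, 30))
  expect_identical(apply_modality_transform(pts, modality_transform()), pts)
  tr <- modality_transform(translation = c(0.3, 0.4))
  moved <- apply_modality_transform(pts, tr)
  expect_equal(sqrt(rowSums((moved - pts)^2)), rep(0.5, 20))
  # 2% uniaxial scale about the origin: displacement 0.02 * |x| on axis 1
  sc <- modality_transform(scale = c(0.98, 1))
  scaled <- apply_modality_transform(pts, sc)
  expect_equal(abs(scaled[, 1] - pts[, 1]), 0.02 * abs(pts[, 1]))
  # inverse recovers input to <= 1e-9 for random full transforms
  set.seed(11)
  for (i in 1:10) {
    t3 <- modality_transform(translation = runif(3, -5, 5),
                             scale = runif(3, 0.9, 1.1),
                             rotation = runif(1, -pi, pi))
    p3 <- cbind(pts, runif(20, -3, 3))
    back <- apply_modality_transform(apply_modality_transform(p3, t3), t3,
                                     inverse = TRUE)
    expect_lt(max(abs(back - p3)), 1e-9)
  }
})
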