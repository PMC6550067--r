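make_disk_image <- function(n = 41, r = 10, fg = 10, bg = 200,
                            center = c(21, 21)) {
  img <- matrix(bg, n, n)
  d2 <- outer((seq_len(n) - center[1])^2, (seq_len(n) - center[2])^2, "+")
  img[d2 <= r^2] <- fg
  img
}

test_that("blow_segment equals the flood-fill oracle on piecewise-constant images", {
  params4 <- blow_params(1000, 50, 100, "face")
  params8 <- blow_params(1000, 50, 100, "face+edge")
  fixtures <- list(
    disk = list(img = make_disk_image(), seed = c(21, 21)),
    off_center_seed = list(img = make_disk_image(), seed = c(25, 18)),
    square = list(img = {m <- matrix(200, 31, 31); m[8:24, 8:24] <- 30; m},
                  seed = c(15, 15)),
    annulus = list(img = {
      m <- matrix(200, 41, 41)
      d2 <- outer((-20:20)^2, (-20:20)^2, "+")
      m[d2 <= 15^2 & d2 > 9^2] <- 20
      m
    }, seed = c(21, 4)),
    two_disks = list(img = {
      m <- make_disk_image(center = c(12, 12), r = 6)
      d2 <- outer((seq_len(41) - 30)^2, (seq_len(41) - 30)^2, "+")
      m[d2 <= 6^2] <- 10
      m
    }, seed = c(12, 12)))
  for (nm in names(fixtures)) {
    fx <- fixtures[[nm]]
    for (params in list(params4, params8)) {
      got <- blow_segment(fx$img, fx$seed, params)
      want <- blow_oracle(fx$img, fx$seed, params)
      expect_identical(unclass(got)[, ], want, label = nm)
      expect_true(got[fx$seed[1], fx$seed[2]])
      expect_identical(count_components(unclass(got)[, ],
                                        params$connectivity == "face+edge"),
                       1L)
    }
  }
  # with high gradient threshold + tolerance the disk is recovered exactly
  img <- make_disk_image()
  mask <- blow_segment(img, c(21, 21), params4)
  expect_identical(unclass(mask)[, ], img == 10)
  expect_false(attr(mask, "capped"))
})

test_that("gradient threshold stops growth at contrast boundaries", {
  img <- make_disk_image(fg = 100, bg = 200)
  # tolerance would admit everything, the gradient wall must not
  params <- blow_params(gradient_threshold = 20, intensity_tolerance = 500,
                        max_radius = 100)
  mask <- blow_segment(img, c(21, 21), params)
  expect_identical(unclass(mask)[, ], blow_oracle(img, c(21, 21), params))
  expect_true(all(which(mask, arr.ind = TRUE) |>
                    apply(1, function(p) sum((p - 21)^2)) < 10^2))
})

test_that("uniform image growth is capped at max_radius and flagged", {
  img <- matrix(50, 41, 41)
  mask <- blow_segment(img, c(21, 21), blow_params(10, 10, max_radius = 5),
                       pixel_size = 1)
  expect_true(attr(mask, "capped"))
  d <- sqrt(outer((seq_len(41) - 21)^2, (seq_len(41) - 21)^2, "+"))
  expect_identical(unclass(mask)[, ], d <= 5)
  expect_error(blow_segment(img, c(0, 5), blow_params(10, 10, 5)),
               "out of slice bounds")
})

test_that("blow recovers phantom myelin on a noiseless EM section", {
  ph <- make_cylinder(d = 1.2, D = 2.0, length = 1, vx = 0.02)
  em <- render_em(ph$labels, noise_sd = 0)
  k <- round(ph$grid$shape[3] / 2)
  truth_my <- ph$labels$data[, , k] == 2L
  seed <- which(truth_my, arr.ind = TRUE)[1, ]
  mask <- blow_segment(em$data[, , k], seed,
                       blow_params(1000, 50, 3),
                       pixel_size = ph$grid$voxel_size[1:2])
  dice <- 2 * sum(mask & truth_my) / (sum(mask) + sum(truth_my))
  expect_gte(dice, 0.95)
})

test_that("propagation tracks a cylinder and reports gap stops", {
  ph <- make_cylinder(d = 1.2, D = 2.0, length = 3, vx = 0.04)
  em <- render_em(ph$labels, noise_sd = 0)
  params <- blow_params(1000, 30, 3)
  k1 <- which(apply(ph$labels$data == 1L, 3, any))[1]
  first <- blow_segment(em$data[, , k1],
                        round(ph$grid$shape[1:2] / 2), params,
                        pixel_size = ph$grid$voxel_size[1:2])
  seg <- propagate_segmentation(em, first, params, start_slice = k1,
                                label = 1L)
  planes_with_axon <- which(apply(ph$labels$data == 1L, 3, any))
  expect_identical(attr(seg, "stop_slice"), max(planes_with_axon))
  got_planes <- which(apply(seg$data == 1L, 3, any))
  expect_identical(got_planes, k1:max(planes_with_axon))
  vol <- measure_labels(seg)$summary
  truth_vol <- ph$truth$volumes_um3[["axon"]]
  # propagated volume misses only the planes before the start slice
  frac_covered <- length(got_planes) / length(planes_with_axon)
  expect_lt(abs(vol$volume_um3[vol$material == "axon"] /
                  (truth_vol * frac_covered) - 1), 0.05)
})

test_that("propagation through myelin halts inside the nodal gap", {
  vx <- 0.025
  grid <- grid_spec(c(110, 110, 170), rep(vx, 3))
  fs <- straight_fibre(grid, d = 1.2, D = 2.2, length = 3.6)
  nd <- node_spec(gap_length = 0.7, n_lamellae_per_side = 3,
                  lamellar_period = 0.1, paranode_length = 0.6)
  ph <- build_node_phantom(fs, nd, grid)
  em <- render_em(ph$labels, noise_sd = 0)
  params <- blow_params(1000, 20, 3)
  k1 <- which(apply(ph$labels$data == 2L, 3, any))[1]
  seed <- which(ph$labels$data[, , k1] == 2L, arr.ind = TRUE)[1, ]
  first <- blow_segment(em$data[, , k1], seed, params,
                        pixel_size = grid$voxel_size[1:2])
  seg <- propagate_segmentation(em, first, params, start_slice = k1,
                                label = 2L)
  stop_k <- attr(seg, "stop_slice")
  # compact myelin ends where the paranode begins; the propagation must
  # halt before the far side of the gap
  gap <- ph$truth$node_interval_um
  z_stop <- (stop_k - 0.5) * vx
  expect_lt(z_stop, gap[2])
  expect_identical(attr(seg, "stop_reason"), "empty")
})

test_that("single-slice propagation equals blow_segment", {
  img <- make_disk_image()
  st <- image_stack(array(img, c(41, 41, 1)), grid_spec(c(41, 41, 1), rep(1, 3)))
  params <- blow_params(1000, 50, 100)
  first <- blow_segment(img, c(21, 21), params)
  seg <- propagate_segmentation(st, first, params, label = 1L)
  expect_identical(seg$data[, , 1] == 1L, unclass(first)[, ])
  expect_error(propagate_segmentation(st, matrix(FALSE, 41, 41), params),
               "empty")
})

test_that("measure_labels: analytic areas, additivity, axis permutation", {
  expect_true(all(measure_labels(empty_labels(
    grid_spec(c(5, 5, 5), rep(1, 3))))$summary$volume_um3 == 0))
  ph <- make_cylinder(d = 1.2, D = 2.0, length = 1, vx = 0.02)
  m <- measure_labels(ph$labels)
  ax <- m$summary[m$summary$material == "axon", ]
  expect_lt(abs(ax$mean_slice_area_um2 / (pi * 0.6^2) - 1), 0.01)
  my <- m$summary[m$summary$material == "myelin", ]
  # disjoint additivity: fibre volume = axon + myelin exactly
  fibre_vox <- sum(ph$labels$data %in% c(1L, 2L))
  expect_identical(ax$voxel_count + my$voxel_count, as.numeric(fibre_vox))
  # volumes invariant under axis permutation with permuted voxel sizes
  g2 <- grid_spec(ph$grid$shape[c(3, 1, 2)], ph$grid$voxel_size[c(3, 1, 2)])
  lv2 <- label_volume(aperm(ph$labels$data, c(3, 1, 2)), g2)
  m2 <- measure_labels(lv2)
  expect_equal(m2$summary$volume_um3, m$summary$volume_um3)
})
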