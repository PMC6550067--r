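# Shared fixtures (built in code) and independent oracles.

# Straight-cylinder phantom centred in a cubic-ish grid.
make_cylinder <- function(d = 1.2, D = 2.0, length = 4, vx = 0.05,
                          margin = 0.5) {
  side <- D + 2 * margin
  grid <- grid_spec(c(ceiling(side / vx), ceiling(side / vx),
                      ceiling((length + 2 * margin) / vx)), rep(vx, 3))
  fs <- straight_fibre(grid, d, D, length)
  c(build_fibre_phantom(fs, grid), list(grid = grid, fibre = fs))
}

# Independent region-growing oracle: connected component (4- or 8-conn)
# of {|I - I[seed]| <= tol AND grad < gthresh} containing the seed,
# via an explicit scan-queue flood fill (different algorithm from the
# dilation-based implementation under test).
blow_oracle <- function(slice, seed, params, pixel_size = c(1, 1)) {
  if (length(pixel_size) == 1L) pixel_size <- rep(pixel_size, 2)
  grad <- gradient_magnitude(slice)
  accept <- abs(slice - slice[seed[1], seed[2]]) <= params$intensity_tolerance &
    grad < params$gradient_threshold
  n1 <- nrow(slice); n2 <- ncol(slice)
  dist_ok <- outer(((seq_len(n1) - seed[1]) * pixel_size[1])^2,
                   ((seq_len(n2) - seed[2]) * pixel_size[2])^2, "+") <=
    params$max_radius^2
  grow <- accept & dist_ok
  mask <- matrix(FALSE, n1, n2)
  mask[seed[1], seed[2]] <- TRUE
  queue <- list(seed)
  nb <- if (params$connectivity == "face")
    rbind(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  else as.matrix(expand.grid(-1:1, -1:1))[-5, ]
  while (length(queue)) {
    p <- queue[[length(queue)]]
    queue[[length(queue)]] <- NULL
    for (q in seq_len(nrow(nb))) {
      i <- p[1] + nb[q, 1]; j <- p[2] + nb[q, 2]
      if (i < 1 || i > n1 || j < 1 || j > n2) next
      if (mask[i, j] || !grow[i, j]) next
      mask[i, j] <- TRUE
      queue[[length(queue) + 1L]] <- c(i, j)
    }
  }
  mask
}

# Count connected components of a logical mask (flood-fill oracle).
count_components <- function(mask, eight = FALSE) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  n <- 0L
  nb <- if (eight) as.matrix(expand.grid(-1:1, -1:1))[-5, ]
  else rbind(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  for (s in which(mask)) {
    if (lab[s] != 0L) next
    n <- n + 1L
    queue <- s
    lab[s] <- n
    while (length(queue)) {
      p <- queue[1]; queue <- queue[-1]
      pi <- (p - 1L) %% nrow(mask) + 1L
      pj <- (p - 1L) %/% nrow(mask) + 1L
      for (q in seq_len(nrow(nb))) {
        i <- pi + nb[q, 1]; j <- pj + nb[q, 2]
        if (i < 1 || i > nrow(mask) || j < 1 || j > ncol(mask)) next
        l <- (j - 1L) * nrow(mask) + i
        if (mask[l] && lab[l] == 0L) { lab[l] <- n; queue <- c(queue, l) }
      }
    }
  }
  n
}

# Trapezoidal full-fibre EM profile with half-depth crossings at exactly
# +/- d/2 and +/- D/2 around the scan midpoint.
trapezoid_profile <- function(d = 1.2, D = 2.0, bg = 200, trough = 0,
                              lumen = 150, half_width = 1.6, step = 0.01,
                              edge = 0.1) {
  pos <- seq(-half_width, half_width, by = step)
  ramp <- function(p, lo, hi, v0, v1) {
    # linear transition from v0 (at lo) to v1 (at hi)
    w <- pmin(pmax((p - lo) / (hi - lo), 0), 1)
    v0 + w * (v1 - v0)
  }
  x <- rep(bg, length(pos))
  a <- abs(pos)
  # outer edge centred at D/2: bg -> trough; inner edge centred at d/2:
  # trough -> lumen.  Half levels are (bg+trough)/2 and (lumen+trough)/2,
  # crossed exactly at D/2 and d/2 because the edges are linear and
  # symmetric about them.
  x <- ramp(a, D / 2 - edge / 2, D / 2 + edge / 2, trough, bg)
  inner <- ramp(a, d / 2 - edge / 2, d / 2 + edge / 2, lumen, trough)
  x[a < d / 2 + edge / 2] <- inner[a < d / 2 + edge / 2]
  line_profile(pos - pos[1], x, modality = "em", polarity = "dark-myelin")
}

expect_measurement_error <- function(expr) {
  expect_error(expr, class = "myelo_measurement_error")
}
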