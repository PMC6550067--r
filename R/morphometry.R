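# Line-scan ("pixel density scan") morphometry: axon/fibre diameters,
# three g-ratio estimators, lamella counting and group comparison.

#' Intensity profile along a line scan
#'
#' @param positions strictly increasing, uniformly spaced sample positions
#'   along the scan (um).
#' @param intensities sampled intensities.
#' @param modality `"em"` or `"lm"`.
#' @param polarity `"dark-myelin"` (EM: osmium-stained myelin is dark) or
#'   `"bright-myelin"` (LM: dye-labelled myelin is bright).
#' @export
line_profile <- function(positions, intensities, modality = "em",
                         polarity = c("dark-myelin", "bright-myelin")) {
  polarity <- match.arg(polarity)
  if (length(positions) != length(intensities))
    stop("positions and intensities differ in length")
  dp <- diff(positions)
  if (any(dp <= 0)) stop("positions must be strictly increasing")
  if (length(dp) > 1 && max(abs(dp - dp[1])) > 1e-6 * dp[1])
    stop("positions must be uniformly spaced")
  structure(list(positions = positions, intensities = intensities,
                 modality = modality, polarity = polarity),
            class = "line_profile")
}

#' Sample an image along a physical line (pixel density scan)
#'
#' Bilinear interpolation at `n_samples` uniformly spaced positions
#' between two physical endpoints.
#'
#' @param image numeric matrix; pixel `(i, j)` is centred at
#'   `(i - 0.5, j - 0.5) * pixel_size`.
#' @param p0,p1 physical endpoints (um pairs, row/col axes); must lie
#'   inside the image and be distinct.
#' @param n_samples number of samples (>= 2).
#' @param pixel_size in-plane pitch (um), pair or scalar.
#' @inheritParams line_profile
#' @return a [line_profile()].
#' @export
line_scan <- function(image, p0, p1, n_samples = 200L, pixel_size = c(1, 1),
                      modality = "em",
                      polarity = c("dark-myelin", "bright-myelin")) {
  polarity <- match.arg(polarity)
  if (length(pixel_size) == 1L) pixel_size <- rep(pixel_size, 2L)
  L <- sqrt(sum((p1 - p0)^2))
  if (L <= 0) stop("zero-length scan")
  if (n_samples < 2L) stop("n_samples must be >= 2")
  ext <- dim(image) * pixel_size
  for (p in list(p0, p1))
    if (any(p < 0) || any(p > ext)) stop("scan endpoint outside the image")
  t <- seq(0, 1, length.out = n_samples)
  pts <- cbind(p0[1] + t * (p1[1] - p0[1]), p0[2] + t * (p1[2] - p0[2]))
  f <- sweep(pts, 2, pixel_size, "/") + 0.5
  d <- dim(image)
  v <- numeric(n_samples)
  fa <- pmin(pmax(f[, 1], 1), d[1]); fb <- pmin(pmax(f[, 2], 1), d[2])
  i0 <- pmin(floor(fa), d[1] - 1L); j0 <- pmin(floor(fb), d[2] - 1L)
  wi <- fa - i0; wj <- fb - j0
  v <- image[cbind(i0, j0)] * (1 - wi) * (1 - wj) +
    image[cbind(i0 + 1L, j0)] * wi * (1 - wj) +
    image[cbind(i0, j0 + 1L)] * (1 - wi) * wj +
    image[cbind(i0 + 1L, j0 + 1L)] * wi * wj
  line_profile(t * L, v, modality = modality, polarity = polarity)
}

moving_average <- function(x, window) {
  if (window <= 1L) return(x)
  k <- rep(1 / window, window)
  n <- length(x)
  xp <- c(rep(x[1], window), x, rep(x[n], window))  # edge padding
  y <- stats::filter(xp, k, sides = 2)
  as.numeric(y[(window + 1):(window + n)])
}

# Plateau-aware local extrema with prominences, on a signal where the
# features of interest are maxima.  Returns data.frame(index, value,
# prominence); plateaus are reduced to their center sample.
find_peaks <- function(x) {
  n <- length(x)
  if (n < 3L) return(data.frame(index = integer(0), value = numeric(0),
                                prominence = numeric(0)))
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  m <- length(r$values)
  peaks <- integer(0)
  for (q in seq_len(m)) {
    if (q == 1L || q == m) next
    if (r$values[q] > r$values[q - 1L] && r$values[q] > r$values[q + 1L])
      peaks <- c(peaks, as.integer(round((starts[q] + ends[q]) / 2)))
  }
  if (!length(peaks)) return(data.frame(index = integer(0),
                                        value = numeric(0),
                                        prominence = numeric(0)))
  prom <- vapply(peaks, function(p) {
    v <- x[p]
    higher_l <- which(x[seq_len(p - 1L)] > v)
    lo_l <- if (length(higher_l)) min(x[(max(higher_l) + 1L):(p - 1L)])
    else min(x[seq_len(p - 1L)])
    higher_r <- which(x[(p + 1L):n] > v) + p
    lo_r <- if (length(higher_r)) min(x[(p + 1L):(min(higher_r) - 1L)])
    else min(x[(p + 1L):n])
    v - max(lo_l, lo_r)
  }, numeric(1))
  data.frame(index = peaks, value = x[peaks], prominence = prom)
}

# Linear sub-sample crossing of level `lev` on signal x (positions pos):
# scanning from index i in direction dir (+1/-1), the first crossing
# below lev.
crossing_position <- function(x, pos, i, lev, dir) {
  n <- length(x)
  j <- i
  while (j + dir >= 1L && j + dir <= n && x[j + dir] > lev) j <- j + dir
  jn <- j + dir
  if (jn < 1L || jn > n) return(NA_real_)
  if (x[j] == x[jn]) return(pos[jn])
  pos[j] + (pos[jn] - pos[j]) * (x[j] - lev) / (x[j] - x[jn])
}

#' Axon and fibre diameters from a full-fibre line profile
#'
#' The scan must cross the whole fibre, with background at both ends.
#' The two principal myelin extrema (troughs for dark-myelin EM, peaks
#' for bright-myelin LM) are located; the fibre diameter D is the
#' distance between the outer half-level crossings of the two extrema and
#' the axon diameter d the distance between the inner crossings.  Half
#' levels are taken midway between the extremum and the adjacent plateau
#' (outer background, or the axoplasm/lumen between the extrema), with
#' sub-sample positions by linear interpolation.
#'
#' @param profile a [line_profile()].
#' @param smooth_window moving-average width in samples applied before
#'   feature detection (1 = none); use ~5 for noisy EM scans.
#' @param min_prominence_frac minimum prominence of the myelin extrema as
#'   a fraction of the profile dynamic range.
#' @return list of class `diameter_pair`: `d_um`, `D_um`, plus the
#'   detected edge positions.  Throws a condition of class
#'   `myelo_measurement_error` when the two myelin extrema cannot be
#'   found or the edges are inconsistent (such scans are skipped, and
#'   counted, by the batch helpers).
#' @export
profile_to_diameters <- function(profile, smooth_window = 1L,
                                 min_prominence_frac = 0.2) {
  x0 <- moving_average(profile$intensities, smooth_window)
  pos <- profile$positions
  x <- if (profile$polarity == "dark-myelin") -x0 else x0
  rng <- max(x) - min(x)
  fail <- function(msg) stop(structure(class = c("myelo_measurement_error",
                                                 "error", "condition"),
                                       list(message = msg, call = sys.call(-1))))
  if (!is.finite(rng) || rng <= 1e-6 * max(1, abs(max(x)), abs(min(x))))
    fail("flat profile: no myelin extrema")
  # noise floor from robust lagged differences of the unsmoothed profile
  # (lag >= smooth_window so oversampled, interpolation-correlated
  # samples do not hide the pixel noise); myelin extrema must clear
  # 4 sigma so a scan through pure background noise is rejected, not
  # measured
  lag <- min(max(2L, smooth_window), length(profile$intensities) - 1L)
  sigma_hat <- stats::median(abs(diff(profile$intensities, lag = lag))) /
    0.9539
  pk <- find_peaks(x)
  pk <- pk[pk$prominence >= max(min_prominence_frac * rng, 4 * sigma_hat), ,
           drop = FALSE]
  if (nrow(pk) < 2L) fail("fewer than two myelin extrema detected")
  pk <- pk[order(-pk$prominence), ][1:2, ]
  iL <- min(pk$index); iR <- max(pk$index)
  if (iL == iR) fail("myelin extrema not separated")
  n <- length(x)
  edge <- max(3L, round(0.05 * n))
  bgL <- stats::median(x[seq_len(min(edge, iL))])
  bgR <- stats::median(x[seq(max(iR, n - edge + 1L), n)])
  lum_idx <- iL:iR
  q <- floor(length(lum_idx) / 4)
  if (length(lum_idx) > 2 * q + 2) lum_idx <- lum_idx[(q + 1):(length(lum_idx) - q)]
  lumen <- stats::median(x[lum_idx])
  pLo <- crossing_position(x, pos, iL, (bgL + x[iL]) / 2, -1L)
  pLi <- crossing_position(x, pos, iL, (lumen + x[iL]) / 2, +1L)
  pRi <- crossing_position(x, pos, iR, (lumen + x[iR]) / 2, -1L)
  pRo <- crossing_position(x, pos, iR, (bgR + x[iR]) / 2, +1L)
  if (anyNA(c(pLo, pLi, pRi, pRo))) fail("edge crossing not found")
  D <- pRo - pLo
  d <- pRi - pLi
  if (!(d > 0 && D > d)) fail("inconsistent edge ordering (d !< D)")
  structure(list(d_um = d, D_um = D,
                 edges_um = c(outer_left = pLo, inner_left = pLi,
                              inner_right = pRi, outer_right = pRo)),
            class = "diameter_pair")
}

#' Scan a straight fibre stack and collect (d, D) pairs
#'
#' Convenience batch helper for an axis-3-aligned fibre: takes `n_scans`
#' orthogonal (in-plane) pixel density scans through the fibre center at
#' uniformly spaced sections, converts each to a [profile_to_diameters()]
#' measurement, and records scans whose edges could not be measured
#' (skipped, never imputed).
#'
#' @param stack an [image_stack()].
#' @param center in-plane physical center of the fibre (um pair);
#'   defaults to the stack center.
#' @param n_scans number of line scans (default 100).
#' @param plane_range range of section indices to span (default: middle
#'   80% of the stack, avoiding fibre end caps).
#' @param angle scan direction in-plane (radians).
#' @param n_samples samples per scan.
#' @param smooth_window passed to [profile_to_diameters()].
#' @inheritParams line_profile
#' @return data.frame (d_um, D_um, position_um, plane) with attribute
#'   `n_failed`.
#' @export
scan_fibre_diameters <- function(stack, center = NULL, n_scans = 100L,
                                 plane_range = NULL, angle = 0,
                                 n_samples = 400L, smooth_window = 1L,
                                 polarity = c("dark-myelin", "bright-myelin")) {
  polarity <- match.arg(polarity)
  grid <- stack$grid
  ext <- grid_extent(grid)
  if (is.null(center)) center <- ext[1:2] / 2
  if (is.null(plane_range))
    plane_range <- c(ceiling(grid$shape[3] * 0.1) + 1L,
                     floor(grid$shape[3] * 0.9))
  planes <- unique(round(seq(plane_range[1], plane_range[2],
                             length.out = n_scans)))
  half <- min(center[1], center[2], ext[1] - center[1], ext[2] - center[2])
  u <- c(cos(angle), sin(angle))
  p0 <- center - half * u
  p1 <- center + half * u
  rows <- vector("list", length(planes))
  n_failed <- 0L
  for (t in seq_along(planes)) {
    k <- planes[t]
    prof <- line_scan(stack$data[, , k], p0, p1, n_samples = n_samples,
                      pixel_size = grid$voxel_size[1:2],
                      modality = stack$modality, polarity = polarity)
    dp <- tryCatch(profile_to_diameters(prof, smooth_window = smooth_window),
                   myelo_measurement_error = function(e) NULL)
    if (is.null(dp)) { n_failed <- n_failed + 1L; next }
    rows[[t]] <- data.frame(d_um = dp$d_um, D_um = dp$D_um,
                            position_um = (k - 0.5) * grid$voxel_size[3],
                            plane = k)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(d_um = numeric(0), D_um = numeric(0),
                                      position_um = numeric(0),
                                      plane = integer(0))
  attr(out, "n_failed") <- n_failed
  out
}

g_ratio_result <- function(method, values) {
  values <- values[is.finite(values)]
  if (!length(values)) stop("no g-ratio values")
  if (any(values <= 0 | values >= 1))
    warning("g-ratio values outside (0, 1)")
  n <- length(values)
  s <- stats::sd(values)
  structure(list(method = method, values = values, n = n,
                 mean = mean(values), sd = s,
                 sem = if (n > 1) s / sqrt(n) else NA_real_),
            class = "g_ratio_result")
}

#' @export
print.g_ratio_result <- function(x, ...) {
  cat(sprintf("g-ratio (%s method): %.3f +/- %.3f (sd), sem %.3f, n = %d\n",
              x$method, x$mean, x$sd, x$sem, x$n))
  invisible(x)
}

#' Diameter-based g-ratio (d/D)
#'
#' @param pairs data.frame with columns `d_um`, `D_um` (as returned by
#'   [scan_fibre_diameters()]), or a list of `diameter_pair`s.
#' @return `g_ratio_result` (per-scan g = d/D with mean, sd, sem).
#' @export
g_ratio_diameter <- function(pairs) {
  if (is.data.frame(pairs)) {
    d <- pairs$d_um; D <- pairs$D_um
  } else {
    d <- vapply(pairs, `[[`, numeric(1), "d_um")
    D <- vapply(pairs, `[[`, numeric(1), "D_um")
  }
  if (!length(d)) stop("no diameter pairs")
  g_ratio_result("diameter", d / D)
}

#' Cross-sectional-area-based g-ratio (sqrt(ca/CA))
#'
#' The square root makes the estimator commensurate with d/D: for
#' circular cross-sections sqrt(ca/CA) = d/D exactly.
#'
#' @param axon_areas,fibre_areas paired cross-sectional areas (um^2),
#'   axon < fibre, both > 0.
#' @export
g_ratio_area <- function(axon_areas, fibre_areas) {
  if (length(axon_areas) != length(fibre_areas))
    stop("area vectors must be paired")
  if (any(axon_areas <= 0) || any(fibre_areas <= 0) ||
      any(axon_areas >= fibre_areas))
    stop("areas must satisfy 0 < axon < fibre")
  g_ratio_result("area", sqrt(axon_areas / fibre_areas))
}

#' Volume-based g-ratio (sqrt(V_axon/V_fibre))
#'
#' Both volumes must cover the same axial extent of the fibre; the square
#' root again makes the estimator commensurate with d/D (exact for a
#' straight cylinder, and averaging out local deviations along bent
#' fibres).
#'
#' @param axon_volumes,fibre_volumes per-fibre volumes (um^3),
#'   axon < fibre.
#' @export
g_ratio_volume <- function(axon_volumes, fibre_volumes) {
  if (length(axon_volumes) != length(fibre_volumes))
    stop("volume vectors must be paired")
  if (any(axon_volumes <= 0) || any(fibre_volumes <= 0) ||
      any(axon_volumes >= fibre_volumes))
    stop("volumes must satisfy 0 < axon < fibre")
  g_ratio_result("volume", sqrt(axon_volumes / fibre_volumes))
}

#' Count paranodal lamellae on a radial profile
#'
#' Counts local extrema of the lamellar polarity (troughs on dark-myelin
#' EM profiles) whose prominence exceeds `prominence_fraction` times the
#' profile dynamic range.  A flat profile counts 0.
#'
#' @param profile a [line_profile()] taken radially through a paranode.
#' @param prominence_fraction prominence cutoff as a fraction of the
#'   dynamic range.
#' @param smooth_window optional moving-average width (samples).
#' @return integer lamella count.
#' @export
count_lamellae <- function(profile, prominence_fraction = 0.2,
                           smooth_window = 1L) {
  x <- moving_average(profile$intensities, smooth_window)
  if (profile$polarity == "dark-myelin") x <- -x
  rng <- max(x) - min(x)
  if (rng <= 1e-6 * max(1, abs(max(x)), abs(min(x)))) return(0L)
  pk <- find_peaks(x)
  as.integer(sum(pk$prominence >= prominence_fraction * rng))
}

#' One-way ANOVA comparison of g-ratio groups
#'
#' Fixed-effects one-way ANOVA computed from group sums of squares, plus
#' a per-group mean +/- SEM table.
#'
#' @param groups named list; each element a `g_ratio_result` or a numeric
#'   vector of g values (>= 2 groups, each n >= 2).
#' @return list `anova` (data.frame: term, df, sum_sq, mean_sq, F, p) and
#'   `means` (data.frame: group, n, mean, sd, sem).  When all values are
#'   identical the F statistic is undefined and reported as `NA`.
#' @export
compare_gratio_groups <- function(groups) {
  vals <- lapply(groups, function(g)
    if (inherits(g, "g_ratio_result")) g$values else as.numeric(g))
  if (length(vals) < 2L) stop("need at least 2 groups")
  if (any(vapply(vals, length, integer(1)) < 2L))
    stop("each group needs n >= 2")
  if (is.null(names(vals)) || any(names(vals) == ""))
    names(vals) <- paste0("group", seq_along(vals))
  k <- length(vals)
  ns <- vapply(vals, length, numeric(1))
  N <- sum(ns)
  gm <- sum(vapply(vals, sum, numeric(1))) / N
  means <- vapply(vals, mean, numeric(1))
  ssb <- sum(ns * (means - gm)^2)
  ssw <- sum(vapply(vals, function(v) sum((v - mean(v))^2), numeric(1)))
  dfb <- k - 1; dfw <- N - k
  msw <- ssw / dfw
  if (msw == 0 && ssb == 0) {
    Fv <- NA_real_; p <- NA_real_
  } else if (msw == 0) {
    Fv <- Inf; p <- 0
  } else {
    Fv <- (ssb / dfb) / msw
    p <- stats::pf(Fv, dfb, dfw, lower.tail = FALSE)
  }
  anova_tab <- data.frame(
    term = c("between", "within"), df = c(dfb, dfw),
    sum_sq = c(ssb, ssw), mean_sq = c(ssb / dfb, msw),
    F = c(Fv, NA), p = c(p, NA))
  mt <- data.frame(group = names(vals), n = as.integer(ns), mean = means,
                   sd = vapply(vals, stats::sd, numeric(1)),
                   row.names = NULL)
  mt$sem <- mt$sd / sqrt(mt$n)
  list(anova = anova_tab, means = mt)
}
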