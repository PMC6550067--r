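# Ground-truthed phantoms of myelinated fibres, nodes of Ranvier and
# somatic fiducials, rendered as EM-like and LM-like stacks.
#
# Rasterization rule: a voxel belongs to a material iff its *center* lies
# inside the analytic region (voxel-center convention).  This makes
# voxel-count volumes asymptotically unbiased estimates of the analytic
# volumes.

#' Geometry of a single myelinated fibre
#'
#' @param centerline n x 3 matrix of physical points (um) along the package
#'   axis convention; at least 2 points, all segments of positive length.
#' @param d axon (inner) diameter, um.
#' @param D fibre (outer, axon + myelin) diameter, um; must exceed `d`.
#'   Healthy fibres sit near the theoretical optimum g = d/D of about 0.6.
#' @param axon_label,myelin_label integer ids used when rasterizing.
#' @return object of class `fibre_spec`.
#' @export
fibre_spec <- function(centerline, d, D, axon_label = 1L, myelin_label = 2L) {
  centerline <- rbind(centerline)
  if (nrow(centerline) < 2L || ncol(centerline) != 3L)
    stop("`centerline` must be an n x 3 matrix with n >= 2")
  seg <- diff(centerline)
  if (any(sqrt(rowSums(seg^2)) <= 0))
    stop("centerline segments must have positive length")
  if (!(d > 0 && D > d))
    stop("diameters must satisfy 0 < d < D")
  structure(list(centerline = centerline, d = d, D = D,
                 axon_label = as.integer(axon_label),
                 myelin_label = as.integer(myelin_label)),
            class = "fibre_spec")
}

#' Straight fibre along the plane axis, centred in a grid
#'
#' Convenience constructor: an axis-3-aligned fibre of the given length,
#' centred in-plane and in depth.
#' @param grid a [grid_spec()].
#' @param d,D axon and fibre diameters (um).
#' @param length fibre length (um); default spans the grid minus a margin.
#' @export
straight_fibre <- function(grid, d, D, length = NULL) {
  ext <- grid_extent(grid)
  if (is.null(length)) length <- ext[3] - 4 * grid$voxel_size[3]
  c12 <- grid$origin[1:2] + ext[1:2] / 2
  z0 <- grid$origin[3] + (ext[3] - length) / 2
  fibre_spec(rbind(c(c12, z0), c(c12, z0 + length)), d = d, D = D)
}

#' Node of Ranvier specification
#'
#' Describes the nodal gap and the flanking paranodes where the myelin
#' lamellae terminate as a stack of loops, the innermost lamella reaching
#' closest to the node.
#'
#' @param gap_length axial length of the unmyelinated nodal gap (um).
#' @param n_lamellae_per_side number of lamellae (myelin wraps) terminating
#'   on each side of the node; about 10-11 for small (1-2 um) axons.
#' @param lamellar_period radial spacing between successive lamellae (um);
#'   default 0.016 um, the order of the major dense line period of compact
#'   myelin.  Tests and phantoms that need resolvable lamellae at coarser
#'   voxels pass their own period.
#' @param paranode_length axial extent of each paranode (um).
#' @export
node_spec <- function(gap_length, n_lamellae_per_side,
                      lamellar_period = 0.016,
                      paranode_length = n_lamellae_per_side * 0.25) {
  if (!(gap_length > 0)) stop("gap_length must be > 0")
  n <- as.integer(n_lamellae_per_side)
  if (is.na(n) || n < 1L) stop("n_lamellae_per_side must be >= 1")
  if (!(lamellar_period > 0)) stop("lamellar_period must be > 0")
  if (!(paranode_length > 0)) stop("paranode_length must be > 0")
  structure(list(gap_length = gap_length, n_lamellae_per_side = n,
                 lamellar_period = lamellar_period,
                 paranode_length = paranode_length),
            class = "node_spec")
}

# Polyline arc-length of each vertex (um), first = 0.
polyline_arclen <- function(centerline) {
  c(0, cumsum(sqrt(rowSums(diff(centerline)^2))))
}

# Chunked rasterization driver.  For each plane chunk, computes the
# distance r (um) of every voxel center to the polyline (perpendicular
# foot inside a segment, plus joint spheres restricted to the *wedge*
# between adjacent segments — past the end of one and before the start
# of the next — so bent fibres have no gaps while straight fibres stay
# exact flat-ended cylinders with nothing protruding at the caps) and
# the arc-length position s of the closest point, then calls
# `assign(r, s)` which returns integer labels for the chunk.
rasterize_along_fibre <- function(spec, grid, assign,
                                  labels = NULL, chunk_voxels = 4e6) {
  cl <- spec$centerline
  nseg <- nrow(cl) - 1L
  arclen <- polyline_arclen(cl)
  a <- cl[-nrow(cl), , drop = FALSE]
  b <- cl[-1L, , drop = FALSE]
  u <- b - a
  seg_len <- sqrt(rowSums(u^2))
  u <- u / seg_len

  lab <- if (is.null(labels)) array(0L, grid$shape) else labels$data
  y <- axis_coords(grid, 1); x <- axis_coords(grid, 2); z <- axis_coords(grid, 3)
  n1 <- grid$shape[1]; n2 <- grid$shape[2]; n3 <- grid$shape[3]
  chunk <- max(1L, as.integer(chunk_voxels / (n1 * n2)))
  for (k0 in seq(1L, n3, by = chunk)) {
    ks <- k0:min(n3, k0 + chunk - 1L)
    nk <- length(ks)
    N <- n1 * n2 * nk
    P1 <- rep(y, times = n2 * nk)
    P2 <- rep(rep(x, each = n1), times = nk)
    P3 <- rep(z[ks], each = n1 * n2)
    r2 <- rep(Inf, N)
    s <- numeric(N)
    t_prev <- NULL
    for (m in seq_len(nseg)) {
      d1 <- P1 - a[m, 1]; d2 <- P2 - a[m, 2]; d3 <- P3 - a[m, 3]
      t <- d1 * u[m, 1] + d2 * u[m, 2] + d3 * u[m, 3]
      perp2 <- d1 * d1 + d2 * d2 + d3 * d3 - t * t
      ok <- t >= 0 & t <= seg_len[m] & perp2 < r2
      r2[ok] <- perp2[ok]
      s[ok] <- arclen[m] + t[ok]
      if (m > 1L) {
        # joint sphere at vertex m, only in the wedge between segments
        wedge <- t_prev > seg_len[m - 1L] & t < 0
        if (any(wedge)) {
          dv2 <- (P1 - cl[m, 1])^2 + (P2 - cl[m, 2])^2 + (P3 - cl[m, 3])^2
          okv <- wedge & dv2 < r2
          r2[okv] <- dv2[okv]
          s[okv] <- arclen[m]
        }
      }
      t_prev <- t
    }
    out <- assign(sqrt(r2), s)
    keep <- out > 0L
    if (any(keep)) {
      idx <- which(keep) + (k0 - 1L) * n1 * n2
      lab[idx] <- out[keep]
    }
  }
  lab
}

check_fibre_bounds <- function(spec, grid) {
  # exact bounding box of the flat-ended tube: a segment with unit
  # direction u extends r * sqrt(1 - u_a^2) beyond its endpoints on axis
  # a; interior joints carry full-radius spheres.
  cl <- spec$centerline
  r <- spec$D / 2
  seg <- diff(cl)
  u <- seg / sqrt(rowSums(seg^2))
  lo <- rep(Inf, 3); hi <- rep(-Inf, 3)
  for (m in seq_len(nrow(u))) {
    expand <- r * sqrt(pmax(0, 1 - u[m, ]^2))
    lo <- pmin(lo, pmin(cl[m, ], cl[m + 1L, ]) - expand)
    hi <- pmax(hi, pmax(cl[m, ], cl[m + 1L, ]) + expand)
  }
  if (nrow(cl) > 2L) {
    inner <- cl[2:(nrow(cl) - 1L), , drop = FALSE]
    lo <- pmin(lo, apply(inner, 2, min) - r)
    hi <- pmax(hi, apply(inner, 2, max) + r)
  }
  glo <- grid$origin + grid$voxel_size
  ghi <- grid$origin + grid_extent(grid) - grid$voxel_size
  bad <- which(lo < glo | hi > ghi)
  if (length(bad))
    stop(sprintf("fibre exceeds volume bounds (with one-voxel margin) on axis %s",
                 paste(bad, collapse = ", ")))
  invisible(TRUE)
}

make_ground_truth <- function(labels, fibres, fiducials = NULL,
                              transform = NULL) {
  meas <- material_voxel_counts(labels)
  vols <- meas * voxel_volume(labels$grid)
  structure(list(fibres = fibres,
                 volumes_um3 = vols,
                 voxel_counts = meas,
                 fiducials = fiducials %||% data.frame(),
                 transform = transform),
            class = "ground_truth")
}

material_voxel_counts <- function(labels) {
  mat <- labels$materials
  counts <- vapply(mat, function(id) sum(labels$data == id), numeric(1))
  counts[names(mat) != "background"]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Rasterize a myelinated fibre into a label volume
#'
#' Voxels whose centers lie within `d/2` of the centerline are labelled
#' axon; within `(d/2, D/2]`, myelin.  Ground-truth volumes are voxel
#' counts times the voxel volume.
#'
#' @param spec a [fibre_spec()].
#' @param grid a [grid_spec()]; the fibre must fit inside it with at least
#'   a one-voxel margin on every axis.
#' @param labels optional existing [label_volume()] to draw into.
#' @return list with elements `labels` (a [label_volume()]) and `truth`
#'   (class `ground_truth`: per-fibre d, D, g = d/D, per-material volumes).
#' @export
build_fibre_phantom <- function(spec, grid, labels = NULL) {
  check_fibre_bounds(spec, grid)
  ra <- spec$d / 2; rm_ <- spec$D / 2
  al <- spec$axon_label; ml <- spec$myelin_label
  lab <- rasterize_along_fibre(spec, grid, function(r, s) {
    out <- integer(length(r))
    out[r <= rm_] <- ml
    out[r <= ra] <- al
    out
  }, labels = labels)
  lv <- label_volume(lab, grid)
  truth <- make_ground_truth(
    lv, data.frame(d_um = spec$d, D_um = spec$D, g = spec$d / spec$D))
  list(labels = lv, truth = truth)
}

#' Rasterize a fibre interrupted by a node of Ranvier
#'
#' The node (gap of `gap_length`) is centred on the arc-length midpoint of
#' the centerline.  Within each flanking paranode the compact myelin is
#' replaced by `n_lamellae_per_side` concentric loop-labelled shells,
#' radially spaced by `lamellar_period` (each shell occupies half a period,
#' leaving an unlabelled gap between neighbours so shells are resolvable),
#' terminating sequentially toward the node: the innermost lamella reaches
#' the nodal gap, the outermost stops furthest from it.
#'
#' @param fibre a [fibre_spec()].
#' @param node a [node_spec()]; requires
#'   `n_lamellae_per_side * lamellar_period <= (D - d) / 2`.
#' @param grid a [grid_spec()].
#' @param loop_label integer id for the paranodal loops.
#' @inherit build_fibre_phantom return
#' @export
build_node_phantom <- function(fibre, node, grid, loop_label = 3L) {
  check_fibre_bounds(fibre, grid)
  if (node$n_lamellae_per_side * node$lamellar_period >
      (fibre$D - fibre$d) / 2 + 1e-12)
    stop("lamellae do not fit in the myelin thickness: need ",
         "n_lamellae_per_side * lamellar_period <= (D - d)/2")
  total <- polyline_arclen(fibre$centerline)[nrow(fibre$centerline)]
  s_mid <- total / 2
  half_gap <- node$gap_length / 2
  P <- node$paranode_length
  n <- node$n_lamellae_per_side
  per <- node$lamellar_period
  ra <- fibre$d / 2; rm_ <- fibre$D / 2
  al <- fibre$axon_label; ml <- fibre$myelin_label; ll <- as.integer(loop_label)

  lab <- rasterize_along_fibre(fibre, grid, function(r, s) {
    out <- integer(length(r))
    ax <- abs(s - s_mid)              # axial distance from node center
    sheath <- r > ra & r <= rm_
    # compact myelin outside gap + paranodes
    out[sheath & ax > half_gap + P] <- ml
    # paranode: concentric terminating loops
    in_para <- sheath & ax > half_gap & ax <= half_gap + P
    if (any(in_para)) {
      i <- floor((r[in_para] - ra) / per) + 1          # lamella index, 1 innermost
      in_band <- (r[in_para] - ra) - (i - 1) * per <= per / 2
      a_rel <- ax[in_para] - half_gap                  # 0 at gap edge .. P
      present <- i <= n & a_rel > (i - 1) * (P / n)
      idx <- which(in_para)[in_band & present]
      out[idx] <- ll
    }
    out[r <= ra] <- al
    out
  })
  lv <- label_volume(lab, grid)
  truth <- make_ground_truth(
    lv, data.frame(d_um = fibre$d, D_um = fibre$D, g = fibre$d / fibre$D))
  truth$node <- node
  truth$node_interval_um <- c(s_mid - half_gap, s_mid + half_gap)
  truth$centerline_length_um <- total
  list(labels = lv, truth = truth)
}

#' Add ellipsoidal soma and nucleus fiducials
#'
#' Large, morphologically distinct cell bodies and nuclei serve as
#' biological fiducials visible in both modalities.  Blobs are placed by
#' bounded rejection sampling (at most `max_retries` draws each), never
#' overlapping any existing nonzero label or each other, with centers at
#' least their semi-axes away from the volume walls.
#'
#' @param labels a [label_volume()].
#' @param n_somata,n_nuclei how many of each to place (>= 0).
#' @param seed integer seed; placements are reproducible for a fixed seed.
#' @param soma_axes,nucleus_axes length-2 ranges (um) from which each
#'   ellipsoid semi-axis is drawn uniformly.
#' @param max_retries rejection-sampling budget per blob.
#' @return list `labels` (updated volume) and `fiducials`
#'   (data.frame: center axis1_um..axis3_um, semi-axes semi1_um..semi3_um,
#'   material).
#' @export
add_fiducials <- function(labels, n_somata, n_nuclei, seed = 1L,
                          soma_axes = c(2, 4), nucleus_axes = c(1, 2),
                          max_retries = 1000L) {
  stopifnot(n_somata >= 0, n_nuclei >= 0)
  if (n_somata + n_nuclei == 0)
    return(list(labels = labels, fiducials = data.frame(
      axis1_um = numeric(0), axis2_um = numeric(0), axis3_um = numeric(0),
      semi1_um = numeric(0), semi2_um = numeric(0), semi3_um = numeric(0),
      material = character(0))))
  set.seed(as.integer(seed))
  grid <- labels$grid
  lab <- labels$data
  mats <- labels$materials
  lo <- grid$origin
  hi <- grid$origin + grid_extent(grid)
  rows <- list()
  place_one <- function(material, axes_range) {
    id <- mats[[material]]
    for (try in seq_len(max_retries)) {
      ax <- stats::runif(3, axes_range[1], axes_range[2])
      if (any(hi - lo < 2 * ax)) next
      ctr <- stats::runif(3, lo + ax, hi - ax)
      # bounding index box
      i0 <- pmax(1L, floor(points_to_index(grid, ctr - ax)))
      i1 <- pmin(grid$shape, ceiling(points_to_index(grid, ctr + ax)))
      ii <- i0[1]:i1[1]; jj <- i0[2]:i1[2]; kk <- i0[3]:i1[3]
      dy <- (axis_coords(grid, 1)[ii] - ctr[1]) / ax[1]
      dx <- (axis_coords(grid, 2)[jj] - ctr[2]) / ax[2]
      dz <- (axis_coords(grid, 3)[kk] - ctr[3]) / ax[3]
      inside <- outer(outer(dy^2, dx^2, "+"), dz^2, "+") <= 1
      sub <- lab[ii, jj, kk]
      if (any(sub[inside] != 0L)) next
      sub[inside] <- id
      lab[ii, jj, kk] <<- sub
      rows[[length(rows) + 1L]] <<- data.frame(
        axis1_um = ctr[1], axis2_um = ctr[2], axis3_um = ctr[3],
        semi1_um = ax[1], semi2_um = ax[2], semi3_um = ax[3],
        material = material)
      return(invisible(TRUE))
    }
    stop(sprintf("could not place %s without overlap after %d retries",
                 material, max_retries))
  }
  for (i in seq_len(n_somata)) place_one("soma", soma_axes)
  for (i in seq_len(n_nuclei)) place_one("nucleus", nucleus_axes)
  list(labels = label_volume(lab, grid, mats),
       fiducials = do.call(rbind, rows))
}

# Nearest-neighbour resample of a label volume onto another grid; voxels
# outside the source volume become background (0).
resample_labels_nearest <- function(labels, grid) {
  if (identical(labels$grid, grid)) return(labels)
  src <- labels$grid
  idx <- lapply(1:3, function(axis) {
    i <- round((axis_coords(grid, axis) - src$origin[axis]) /
                 src$voxel_size[axis] + 0.5)
    i
  })
  valid <- lapply(1:3, function(axis)
    idx[[axis]] >= 1L & idx[[axis]] <= src$shape[axis])
  cl <- lapply(1:3, function(axis) pmin(pmax(idx[[axis]], 1L), src$shape[axis]))
  out <- labels$data[cl[[1]], cl[[2]], cl[[3]], drop = FALSE]
  out[!valid[[1]], , ] <- 0L
  out[, !valid[[2]], ] <- 0L
  out[, , !valid[[3]]] <- 0L
  label_volume(out, grid, labels$materials)
}

#' Default EM contrast map
#'
#' Mean grey levels per material for EM-like rendering on a 0-255 scale.
#' Osmium-stained myelin is the darkest compartment; background resin the
#' brightest.
#' @export
default_em_contrast <- function() {
  c(background = 200, axon = 150, myelin = 30, loop = 45,
    soma = 120, nucleus = 80)
}

#' Render a label volume as an EM-like stack
#'
#' Labels are resampled to `em_grid` by nearest neighbour, each material
#' gets its mean grey level from `contrast_map`, and i.i.d. Gaussian
#' detector noise is added before clipping to `[0, 255]`.
#'
#' @param labels a [label_volume()].
#' @param em_grid output [grid_spec()]; default the label grid.  The
#'   SBF-SEM acquisition this emulates used a 13.8 nm pixel and 80 nm
#'   section thickness.
#' @param contrast_map named vector of mean intensities per material; must
#'   satisfy myelin < axon < background.
#' @param noise_sd Gaussian noise standard deviation (intensity units).
#' @param seed integer seed for the noise realisation.
#' @return an [image_stack()] with modality `"em"`.
#' @export
render_em <- function(labels, em_grid = labels$grid,
                      contrast_map = default_em_contrast(),
                      noise_sd = 0, seed = 1L) {
  need <- c("background", "axon", "myelin")
  if (!all(need %in% names(contrast_map)))
    stop("contrast_map must name at least background, axon and myelin")
  if (!(contrast_map[["myelin"]] < contrast_map[["axon"]] &&
        contrast_map[["axon"]] < contrast_map[["background"]]))
    stop("contrast_map must satisfy myelin < axon < background")
  rl <- resample_labels_nearest(labels, em_grid)
  lut <- rep(contrast_map[["background"]], max(rl$materials) + 1L)
  for (nm in names(rl$materials))
    if (nm %in% names(contrast_map))
      lut[rl$materials[[nm]] + 1L] <- contrast_map[[nm]]
  img <- array(lut[rl$data + 1L], em_grid$shape)
  if (noise_sd > 0) {
    set.seed(as.integer(seed))
    img <- img + stats::rnorm(length(img), sd = noise_sd)
  }
  img[img < 0] <- 0; img[img > 255] <- 255
  image_stack(img, em_grid, modality = "em")
}

#' Point-spread-function model for LM rendering
#'
#' An anisotropic Gaussian PSF parameterized by lateral and axial FWHM.
#' Defaults reflect typical high-NA confocal (0.25/0.6 um) and
#' Airyscan-style super-resolution (0.14/0.35 um) performance; `"ideal"`
#' is a zero-width PSF.
#'
#' @param modality one of `"confocal"`, `"airyscan"`, `"ideal"`.
#' @param fwhm_lateral,fwhm_axial full width at half maximum (um) in-plane
#'   and along the optical axis; `NULL` takes the modality default.
#' @export
psf_model <- function(modality = c("confocal", "airyscan", "ideal"),
                      fwhm_lateral = NULL, fwhm_axial = NULL) {
  modality <- match.arg(modality)
  defaults <- list(confocal = c(0.25, 0.6), airyscan = c(0.14, 0.35),
                   ideal = c(0, 0))
  fl <- fwhm_lateral %||% defaults[[modality]][1]
  fa <- fwhm_axial %||% defaults[[modality]][2]
  if (fl < 0 || fa < 0) stop("FWHMs must be >= 0")
  structure(list(modality = modality, fwhm_lateral = fl, fwhm_axial = fa),
            class = "psf_model")
}

# Separable Gaussian blur of a 3D array; sigma in voxels per axis
# (zero-padded boundaries, kernel normalized to unit sum).
gaussian_blur3 <- function(arr, sigma_vox) {
  for (axis in 1:3) {
    s <- sigma_vox[axis]
    if (s <= 0) next
    rad <- max(1L, ceiling(3.5 * s))
    k <- stats::dnorm(seq(-rad, rad), sd = s)
    k <- k / sum(k)
    arr <- convolve_axis(arr, k, axis)
  }
  arr
}

convolve_axis <- function(arr, kernel, axis) {
  d <- dim(arr)
  perm <- c(axis, setdiff(1:3, axis))
  a <- aperm(arr, perm)
  n <- d[axis]
  rad <- (length(kernel) - 1L) / 2
  m <- matrix(a, nrow = n)
  out <- matrix(0, nrow = n, ncol = ncol(m))
  for (t in seq_along(kernel)) {
    off <- t - rad - 1L
    src <- seq_len(n) + off
    ok <- src >= 1L & src <= n
    out[ok, ] <- out[ok, ] + kernel[t] * m[src[ok], ]
  }
  a <- array(out, dim(a))
  aperm(a, order(perm))
}

# Separable (tri)linear resample of an intensity array between grids;
# samples outside the source are edge-clamped.
resample_linear <- function(arr, src, dst) {
  for (axis in 1:3) {
    xs <- axis_coords(src, axis)
    xt <- axis_coords(dst, axis)
    if (length(xs) == length(xt) && max(abs(xs - xt)) < 1e-12) next
    f <- (xt - src$origin[axis]) / src$voxel_size[axis] + 0.5
    f <- pmin(pmax(f, 1), length(xs))
    i0 <- pmin(floor(f), length(xs) - 1L)
    if (length(xs) == 1L) i0 <- rep(1L, length(f))
    w <- f - i0
    i1 <- pmin(i0 + 1L, length(xs))
    d <- dim(arr)
    perm <- c(axis, setdiff(1:3, axis))
    a <- aperm(arr, perm)
    m <- matrix(a, nrow = d[axis])
    out <- m[i0, , drop = FALSE] * (1 - w) + m[i1, , drop = FALSE] * w
    dnew <- dim(a); dnew[1] <- length(xt)
    arr <- aperm(array(out, dnew), order(perm))
  }
  arr
}

#' Render a label volume as a two-channel LM-like stack
#'
#' The myelin-dye channel images the union of myelin and paranodal-loop
#' labels (Fluoromyelin-style); the nuclear-dye channel images nucleus
#' labels (DAPI-style).  Each binary source is convolved with a separable
#' Gaussian PSF on the label grid, resampled to `lm_grid` (trilinear), and
#' corrupted with Poisson shot noise plus Gaussian read noise.
#'
#' With an ideal PSF (zero FWHM), matched grids and no noise the output
#' equals the binarized source.
#'
#' @param labels a [label_volume()].
#' @param psf a [psf_model()].
#' @param lm_grid output [grid_spec()]; default the label grid.  The
#'   acquisition emulated here used 0.068 x 0.068 x 0.3 um voxels.
#' @param photons expected photon count at unit signal for Poisson noise;
#'   `0` disables shot noise.
#' @param read_noise_sd Gaussian read noise sd (signal units, signal is
#'   0-1); `0` disables.
#' @param seed integer seed.
#' @return named list of two [image_stack()]s (`myelin`, `nuclei`),
#'   modality `"lm"`.
#' @export
render_lm <- function(labels, psf = psf_model("confocal"),
                      lm_grid = labels$grid,
                      photons = 0, read_noise_sd = 0, seed = 1L) {
  mats <- labels$materials
  src_my <- array(as.numeric(labels$data == mats[["myelin"]] |
                               labels$data == mats[["loop"]]),
                  labels$grid$shape)
  src_nu <- array(as.numeric(labels$data == mats[["nucleus"]]),
                  labels$grid$shape)
  sig <- c(rep(psf$fwhm_lateral, 2), psf$fwhm_axial) / (2 * sqrt(2 * log(2)))
  sigma_vox <- sig / labels$grid$voxel_size
  set.seed(as.integer(seed))
  render_one <- function(src) {
    if (any(sigma_vox > 0)) src <- gaussian_blur3(src, sigma_vox)
    out <- resample_linear(src, labels$grid, lm_grid)
    if (photons > 0)
      out <- stats::rpois(length(out), lambda = pmax(out, 0) * photons) / photons
    if (read_noise_sd > 0)
      out <- out + stats::rnorm(length(out), sd = read_noise_sd)
    image_stack(array(out, lm_grid$shape), lm_grid, modality = "lm")
  }
  list(myelin = render_one(src_my), nuclei = render_one(src_nu))
}

#' Affine misregistration between imaging modalities
#'
#' Models the residual LM-to-EM distortion left by sample processing
#' (anisotropic shrinkage, seating differences): a translation, a rotation
#' about the plane normal, and per-axis scale factors, applied to physical
#' points as scale(rotate(translate(p))).
#'
#' @param translation numeric pair or triple (um).
#' @param scale per-axis scale factors (> 0), same length as `translation`.
#' @param rotation angle in radians about the plane normal (axes 1-2
#'   plane).
#' @export
modality_transform <- function(translation = c(0, 0),
                               scale = rep(1, length(translation)),
                               rotation = 0) {
  nd <- length(translation)
  if (!nd %in% 2:3) stop("translation must have length 2 or 3")
  if (length(scale) != nd) stop("scale must match translation length")
  if (any(scale <= 0)) stop("scale factors must be > 0")
  structure(list(translation = as.numeric(translation),
                 scale = as.numeric(scale), rotation = as.numeric(rotation)),
            class = "modality_transform")
}

rot_mat2 <- function(theta)
  matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)

#' Apply (or invert) a modality transform to physical points
#'
#' @param points n x 2 or n x 3 matrix of physical points (um).  3D points
#'   with a 2D transform are transformed in-plane (axis 3 untouched).
#' @param transform a [modality_transform()].
#' @param inverse if `TRUE`, applies the exact inverse mapping.
#' @return matrix of the same shape.
#' @export
apply_modality_transform <- function(points, transform, inverse = FALSE) {
  points <- rbind(points)
  nd <- length(transform$translation)
  np <- ncol(points)
  if (np < nd) stop("points have fewer dimensions than the transform")
  p <- points[, seq_len(nd), drop = FALSE]
  R <- diag(nd)
  R[1:2, 1:2] <- rot_mat2(transform$rotation)
  if (!inverse) {
    p <- sweep(p, 2, transform$translation, "+")
    p <- p %*% t(R)
    p <- sweep(p, 2, transform$scale, "*")
  } else {
    p <- sweep(p, 2, transform$scale, "/")
    p <- p %*% R
    p <- sweep(p, 2, transform$translation, "-")
  }
  out <- points
  out[, seq_len(nd)] <- p
  out
}
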