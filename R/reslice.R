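# Digital re-sectioning of anisotropic stacks: arbitrary-plane reslicing,
# centerline-orthogonal cross-sections, and thickness-matched projections.

#' Sampling plane for multiplanar reslicing
#'
#' @param origin physical point (um) at the center of the output image.
#' @param normal unit plane normal.
#' @param up in-plane unit vector giving the output row direction; must be
#'   orthogonal to `normal` (both orthonormal within 1e-9).
#' @param pixel_size output pixel pitch (um).
#' @param extent physical output size (um pair: along `up`, along the
#'   second in-plane axis).
#' @export
plane_spec <- function(origin, normal, up, pixel_size, extent) {
  normal <- as.numeric(normal); up <- as.numeric(up)
  if (abs(sqrt(sum(normal^2)) - 1) > 1e-9 || abs(sqrt(sum(up^2)) - 1) > 1e-9)
    stop("normal and up must be unit vectors")
  if (abs(sum(normal * up)) > 1e-9)
    stop("normal and up must be orthogonal")
  if (!(pixel_size > 0)) stop("pixel_size must be > 0")
  extent <- rep(as.numeric(extent), length.out = 2L)
  if (any(extent <= 0)) stop("extent must be positive")
  structure(list(origin = as.numeric(origin), normal = normal, up = up,
                 pixel_size = pixel_size, extent = extent),
            class = "plane_spec")
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Trilinear interpolation of a stack at physical points
#'
#' @param stack an [image_stack()].
#' @param points n x 3 matrix of physical points (um).
#' @param fill value for samples outside the volume.
#' @return numeric vector with attribute `inside` (logical mask).
#' @export
interp_trilinear <- function(stack, points, fill = 0) {
  grid <- stack$grid
  f <- points_to_index(grid, points)
  n <- nrow(f)
  inside <- rep(TRUE, n)
  idx0 <- matrix(0L, n, 3)
  w <- matrix(0, n, 3)
  for (a in 1:3) {
    fa <- f[, a]
    inside <- inside & fa >= 0.5 & fa <= grid$shape[a] + 0.5
    fa <- pmin(pmax(fa, 1), grid$shape[a])   # clamp for edge voxels
    i0 <- pmin(floor(fa), max(grid$shape[a] - 1L, 1L))
    idx0[, a] <- i0
    w[, a] <- if (grid$shape[a] == 1L) 0 else fa - i0
  }
  d <- grid$shape
  lin <- function(di, dj, dk) {
    i <- pmin(idx0[, 1] + di, d[1]); j <- pmin(idx0[, 2] + dj, d[2])
    k <- pmin(idx0[, 3] + dk, d[3])
    stack$data[cbind(i, j, k)]
  }
  v <-
    lin(0L, 0L, 0L) * (1 - w[, 1]) * (1 - w[, 2]) * (1 - w[, 3]) +
    lin(1L, 0L, 0L) * w[, 1] * (1 - w[, 2]) * (1 - w[, 3]) +
    lin(0L, 1L, 0L) * (1 - w[, 1]) * w[, 2] * (1 - w[, 3]) +
    lin(1L, 1L, 0L) * w[, 1] * w[, 2] * (1 - w[, 3]) +
    lin(0L, 0L, 1L) * (1 - w[, 1]) * (1 - w[, 2]) * w[, 3] +
    lin(1L, 0L, 1L) * w[, 1] * (1 - w[, 2]) * w[, 3] +
    lin(0L, 1L, 1L) * (1 - w[, 1]) * w[, 2] * w[, 3] +
    lin(1L, 1L, 1L) * w[, 1] * w[, 2] * w[, 3]
  v[!inside] <- fill
  attr(v, "inside") <- inside
  v
}

#' Reslice a stack along an arbitrary plane
#'
#' Samples the volume by trilinear interpolation on a regular in-plane
#' lattice centred on the plane origin.  Out-of-volume samples take the
#' fill value and are marked in the `inside` attribute.
#'
#' @param stack an [image_stack()].
#' @param plane a [plane_spec()].
#' @param fill fill value for out-of-volume samples.
#' @return numeric matrix (rows along `up`) with attributes `inside`
#'   (logical matrix), `pixel_size` and `plane`.
#' @export
multiplanar_reslice <- function(stack, plane, fill = 0) {
  e_row <- plane$up
  e_col <- cross3(plane$normal, plane$up)
  nr <- max(2L, round(plane$extent[1] / plane$pixel_size))
  nc <- max(2L, round(plane$extent[2] / plane$pixel_size))
  ur <- (seq_len(nr) - (nr + 1) / 2) * plane$pixel_size
  uc <- (seq_len(nc) - (nc + 1) / 2) * plane$pixel_size
  pts <- cbind(rep(ur, times = nc)) %*% rbind(e_row) +
    cbind(rep(uc, each = nr)) %*% rbind(e_col)
  pts <- sweep(pts, 2, plane$origin, "+")
  v <- interp_trilinear(stack, pts, fill = fill)
  img <- matrix(v, nr, nc)
  structure(img, inside = matrix(attr(v, "inside"), nr, nc),
            pixel_size = plane$pixel_size, plane = plane)
}

# Resample a polyline at uniform arc-length steps; returns points and
# unit tangents (central differences).
resample_polyline <- function(centerline, spacing) {
  s <- polyline_arclen(centerline)
  total <- s[length(s)]
  if (total < spacing) stop("centerline shorter than the section spacing")
  sv <- seq(0, total, by = spacing)
  pts <- sapply(1:3, function(a) stats::approx(s, centerline[, a], xout = sv)$y)
  pts <- rbind(pts)
  n <- nrow(pts)
  tg <- rbind(pts[2, ] - pts[1, ],
              if (n > 2) pts[3:n, , drop = FALSE] - pts[1:(n - 2), , drop = FALSE],
              pts[n, ] - pts[n - 1, ])
  tg <- tg / sqrt(rowSums(tg^2))
  list(points = pts, tangents = tg, arc = sv)
}

#' Cross-sections orthogonal to a fibre centerline
#'
#' One reslice per arc-length step, the plane normal following the local
#' tangent (central difference) and the in-plane up vector carried along
#' by parallel transport to minimize twist between consecutive sections.
#'
#' @param stack an [image_stack()].
#' @param centerline n x 3 matrix of physical points (um).
#' @param spacing arc-length step (um); must not exceed the centerline
#'   length.
#' @param pixel_size,extent geometry of each cross-section (as in
#'   [plane_spec()]).
#' @param fill out-of-volume fill value.
#' @return 3D array (rows, cols, sections) with attributes `arc_um`
#'   (positions along the fibre) and `pixel_size`.
#' @export
orthogonal_sections <- function(stack, centerline, spacing, pixel_size,
                                extent, fill = 0) {
  rs <- resample_polyline(centerline, spacing)
  n <- nrow(rs$points)
  # initial up: least-aligned coordinate axis, orthogonalized
  t1 <- rs$tangents[1, ]
  ax <- diag(3)[, which.min(abs(t1))]
  up <- ax - sum(ax * t1) * t1
  up <- up / sqrt(sum(up^2))
  out <- NULL
  for (i in seq_len(n)) {
    tg <- rs$tangents[i, ]
    up <- up - sum(up * tg) * tg
    up <- up / sqrt(sum(up^2))
    pl <- plane_spec(rs$points[i, ], tg, up, pixel_size, extent)
    img <- multiplanar_reslice(stack, pl, fill = fill)
    if (is.null(out)) out <- array(0, c(dim(img), n))
    out[, , i] <- img
  }
  structure(out, arc_um = rs$arc, pixel_size = pixel_size)
}

#' Projection window over serial sections
#'
#' @param start first section index.
#' @param n number of sections (>= 1).
#' @param thickness physical thickness of one section (um).
#' @param reducer `"mean"` or `"max"`.
#' @export
projection_spec <- function(start, n, thickness, reducer = c("mean", "max")) {
  reducer <- match.arg(reducer)
  if (n < 1L) stop("n must be >= 1")
  if (!(thickness > 0)) stop("thickness must be > 0")
  structure(list(start = as.integer(start), n = as.integer(n),
                 thickness = thickness, reducer = reducer),
            class = "projection_spec")
}

#' Project a window of sections into one image
#'
#' @param stack an [image_stack()].
#' @param spec a [projection_spec()]; the window must lie inside the
#'   stack.
#' @return list `image` (matrix) and `thickness_um` (= n x thickness).
#' @export
project <- function(stack, spec) {
  k0 <- spec$start; k1 <- spec$start + spec$n - 1L
  if (k0 < 1L || k1 > stack$grid$shape[3])
    stop("projection window out of bounds")
  sub <- stack$data[, , k0:k1, drop = FALSE]
  img <- if (spec$reducer == "mean") apply(sub, c(1, 2), mean)
  else apply(sub, c(1, 2), max)
  list(image = img, thickness_um = spec$n * spec$thickness)
}

#' Match a projection thickness across modalities
#'
#' Sections of thickness `t_other` are stacked to approach a reference
#' projection thickness `t_ref` without exceeding it:
#' `n = floor(t_ref / t_other)`.  (With a 2.7 um optical reference and
#' 80 nm EM sections this gives 33 sections, 2.64 um.)
#'
#' @param t_ref reference projection thickness (um).
#' @param t_other section thickness of the other modality (um).
#' @return list `n` and `achieved_um`.
#' @export
match_projection_thickness <- function(t_ref, t_other) {
  if (!(t_ref > 0 && t_other > 0)) stop("thicknesses must be > 0")
  n <- floor(t_ref / t_other + 1e-9)
  if (n < 1L)
    stop("other sections are thicker than the reference projection")
  list(n = as.integer(n), achieved_um = n * t_other)
}
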