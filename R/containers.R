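# Core spatial containers: grids, image stacks and label volumes.
#
# Axis convention used throughout the package: axis 1 = array rows, axis 2 =
# array columns, axis 3 = planes (serial sections).  A physical point is a
# length-3 numeric vector (micrometres) along these axes, and the voxel with
# 1-based index (i, j, k) has its *center* at
#   origin + (c(i, j, k) - 0.5) * voxel_size.

#' Grid specification for a 3D image volume
#'
#' Describes the sampling lattice of a stack: array shape, anisotropic voxel
#' pitch, and the physical offset of the volume corner.  All physical
#' quantities are micrometres.
#'
#' @param shape integer triple `(rows, cols, planes)`, each >= 1.
#' @param voxel_size numeric triple of voxel pitches in um along
#'   `(rows, cols, planes)`; all > 0.  Serial-section stacks typically have
#'   the section thickness on axis 3 (e.g. 0.08 um for fine SBF-SEM
#'   sections, 0.3 um for optical sections).
#' @param origin physical position (um) of the volume corner; voxel
#'   `(1,1,1)` is centred at `origin + voxel_size / 2`.
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(shape, voxel_size, origin = c(0, 0, 0)) {
  shape <- as.integer(shape)
  voxel_size <- as.numeric(voxel_size)
  origin <- as.numeric(origin)
  if (length(shape) != 3L || any(is.na(shape)) || any(shape < 1L))
    stop("`shape` must be an integer triple with all components >= 1")
  if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) ||
      any(voxel_size <= 0))
    stop("`voxel_size` must be a positive numeric triple (um)")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be a finite numeric triple (um)")
  structure(list(shape = shape, voxel_size = voxel_size, origin = origin),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d x %d voxels, pitch %s um, origin %s um\n",
              x$shape[1], x$shape[2], x$shape[3],
              paste(signif(x$voxel_size, 4), collapse = " x "),
              paste(signif(x$origin, 4), collapse = ", ")))
  invisible(x)
}

#' Physical extent of a grid (um), per axis
#' @param grid a [grid_spec()].
#' @return numeric triple, the physical side lengths of the volume.
#' @export
grid_extent <- function(grid) grid$shape * grid$voxel_size

#' Voxel-center coordinates along one axis
#' @param grid a [grid_spec()].
#' @param axis axis index (1 rows, 2 cols, 3 planes).
#' @return numeric vector of um positions of the voxel centers.
#' @export
axis_coords <- function(grid, axis) {
  grid$origin[axis] + (seq_len(grid$shape[axis]) - 0.5) * grid$voxel_size[axis]
}

#' Volume of one voxel in um^3
#' @param grid a [grid_spec()].
#' @export
voxel_volume <- function(grid) prod(grid$voxel_size)

# Map physical points (n x 3, um) to fractional 1-based array indices.
points_to_index <- function(grid, points) {
  points <- rbind(points)
  sweep(sweep(points, 2, grid$origin, "-"), 2, grid$voxel_size, "/") + 0.5
}

# Map 1-based array indices (n x 3) to physical voxel-center points (um).
index_to_points <- function(grid, idx) {
  idx <- rbind(idx)
  sweep(sweep(idx - 0.5, 2, grid$voxel_size, "*"), 2, grid$origin, "+")
}

#' 3D intensity stack with physical calibration
#'
#' @param data 3D numeric array `(rows, cols, planes)`.
#' @param grid the [grid_spec()] the data is sampled on; its shape must
#'   match `dim(data)`.
#' @param modality free-text tag, e.g. `"em"` or `"lm"`.
#' @return An object of class `image_stack` (fields `data`, `grid`,
#'   `modality`).
#' @export
image_stack <- function(data, grid, modality = "em") {
  if (length(dim(data)) == 2L) dim(data) <- c(dim(data), 1L)
  if (length(dim(data)) != 3L)
    stop("`data` must be a 2D or 3D array")
  if (!identical(as.integer(dim(data)), grid$shape))
    stop(sprintf("data dim (%s) does not match grid shape (%s)",
                 paste(dim(data), collapse = "x"),
                 paste(grid$shape, collapse = "x")))
  structure(list(data = data, grid = grid, modality = modality),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  cat(sprintf("<image_stack> modality=%s, range [%.3g, %.3g]\n",
              x$modality, min(x$data), max(x$data)))
  print(x$grid)
  invisible(x)
}

#' Default material table
#'
#' Integer label ids used across the package for phantom compartments.
#' @return named integer vector: background 0, axon 1, myelin 2, paranodal
#'   loop 3, soma 4, nucleus 5.
#' @export
default_materials <- function() {
  c(background = 0L, axon = 1L, myelin = 2L, loop = 3L,
    soma = 4L, nucleus = 5L)
}

#' Integer label volume sharing a grid with an image stack
#'
#' @param data 3D integer array of material ids.
#' @param grid the [grid_spec()].
#' @param materials named integer vector mapping material name -> id; every
#'   nonzero id present in `data` must appear in it.
#' @return An object of class `label_volume`.
#' @export
label_volume <- function(data, grid, materials = default_materials()) {
  if (length(dim(data)) == 2L) dim(data) <- c(dim(data), 1L)
  if (!identical(as.integer(dim(data)), grid$shape))
    stop("label data dim does not match grid shape")
  storage.mode(data) <- "integer"
  if (any(data < 0L)) stop("label ids must be non-negative")
  present <- setdiff(unique(as.vector(data)), 0L)
  missing <- setdiff(present, materials)
  if (length(missing))
    stop("label ids not in material table: ", paste(missing, collapse = ", "))
  structure(list(data = data, grid = grid, materials = materials),
            class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  counts <- tabulate(x$data + 1L, nbins = max(x$materials) + 1L)
  nz <- x$materials[x$materials > 0 & counts[x$materials + 1L] > 0]
  cat(sprintf("<label_volume> materials present: %s\n",
              if (length(nz)) paste(names(nz), collapse = ", ") else "none"))
  print(x$grid)
  invisible(x)
}

#' Empty label volume on a grid
#' @inheritParams label_volume
#' @export
empty_labels <- function(grid, materials = default_materials()) {
  label_volume(array(0L, grid$shape), grid, materials)
}
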