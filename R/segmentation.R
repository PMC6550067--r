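# Semi-automated "blow" segmentation: contrast-gradient-bounded region
# growing from a seed, propagated across serial sections.

#' Parameters of the blow segmenter
#'
#' The blow gesture expands a polygon from a seed until a contrast
#' boundary halts the growth.  This implementation formalizes that as
#' region growing accepting a pixel iff its intensity stays within
#' `intensity_tolerance` of the seed intensity AND its local gradient
#' magnitude stays below `gradient_threshold`.
#'
#' @param gradient_threshold central-difference gradient magnitude bound
#'   (intensity units per pixel), > 0.
#' @param intensity_tolerance allowed deviation from the seed intensity
#'   (intensity units), > 0.
#' @param max_radius physical cap (um) on the region radius around the
#'   seed; growth beyond it is truncated and flagged `capped`.
#' @param connectivity `"face"` (4-neighbour) or `"face+edge"`
#'   (8-neighbour) in-plane connectivity.
#' @export
blow_params <- function(gradient_threshold, intensity_tolerance, max_radius,
                        connectivity = c("face", "face+edge")) {
  connectivity <- match.arg(connectivity)
  if (!(gradient_threshold > 0)) stop("gradient_threshold must be > 0")
  if (!(intensity_tolerance > 0)) stop("intensity_tolerance must be > 0")
  if (!(max_radius > 0)) stop("max_radius must be > 0")
  structure(list(gradient_threshold = gradient_threshold,
                 intensity_tolerance = intensity_tolerance,
                 max_radius = max_radius, connectivity = connectivity),
            class = "blow_params")
}

#' Central-difference gradient magnitude of a 2D image
#'
#' One-sided differences at the borders; units are intensity per pixel.
#' @param img numeric matrix.
#' @export
gradient_magnitude <- function(img) {
  n1 <- nrow(img); n2 <- ncol(img)
  gi <- img[pmin(seq_len(n1) + 1L, n1), , drop = FALSE] -
    img[pmax(seq_len(n1) - 1L, 1L), , drop = FALSE]
  gi <- gi / ifelse(seq_len(n1) > 1L & seq_len(n1) < n1, 2, 1)
  gj <- img[, pmin(seq_len(n2) + 1L, n2), drop = FALSE] -
    img[, pmax(seq_len(n2) - 1L, 1L), drop = FALSE]
  gj <- sweep(gj, 2, ifelse(seq_len(n2) > 1L & seq_len(n2) < n2, 2, 1), "/")
  sqrt(gi^2 + gj^2)
}

dilate_mask <- function(mask, eight = FALSE) {
  n1 <- nrow(mask); n2 <- ncol(mask)
  up <- rbind(mask[-1L, , drop = FALSE], FALSE)
  dn <- rbind(FALSE, mask[-n1, , drop = FALSE])
  lf <- cbind(mask[, -1L, drop = FALSE], FALSE)
  rt <- cbind(FALSE, mask[, -n2, drop = FALSE])
  out <- mask | up | dn | lf | rt
  if (eight) {
    out <- out |
      rbind(cbind(mask[-1L, -1L, drop = FALSE], FALSE), FALSE) |
      rbind(FALSE, cbind(mask[-n1, -1L, drop = FALSE], FALSE)) |
      rbind(cbind(FALSE, mask[-1L, -n2, drop = FALSE]), FALSE) |
      rbind(FALSE, cbind(FALSE, mask[-n1, -n2, drop = FALSE]))
  }
  out
}

#' Grow a region from a seed by contrast-bounded dilation
#'
#' Repeated one-pixel dilation from the seed, keeping a pixel iff
#' `|I - I[seed]| <= intensity_tolerance` and the central-difference
#' gradient magnitude is `< gradient_threshold`, stopping when no pixel is
#' added.  Growth never leaves the `max_radius` disk around the seed; if
#' an otherwise acceptable pixel lies just beyond it the result is
#' flagged capped (mirroring the interactive tool, where the user
#' re-seeds).  The result depends only on the acceptance set, not on
#' visitation order.
#'
#' @param slice numeric matrix (one section).
#' @param seed integer pair `(row, col)` inside the slice.
#' @param params a [blow_params()].
#' @param pixel_size in-plane pitch (um), pair `(row, col)` or scalar.
#' @param ref_intensity intensity the tolerance band is centred on.
#'   Default (`NULL`) is the seed pixel's own intensity, in which case the
#'   mask always contains the seed.  [propagate_segmentation()] passes the
#'   previous section's material intensity instead, so a section where the
#'   material is absent (a nodal gap, a fibre end) yields an *empty* mask
#'   rather than regrowing from whatever tissue now lies under the seed.
#' @return logical mask matrix with attributes `capped` (logical) and
#'   `seed`.
#' @export
blow_segment <- function(slice, seed, params, pixel_size = c(1, 1),
                         ref_intensity = NULL) {
  n1 <- nrow(slice); n2 <- ncol(slice)
  seed <- as.integer(seed)
  if (length(pixel_size) == 1L) pixel_size <- rep(pixel_size, 2L)
  if (seed[1] < 1L || seed[1] > n1 || seed[2] < 1L || seed[2] > n2)
    stop("seed out of slice bounds")
  ref <- ref_intensity %||% slice[seed[1], seed[2]]
  grad <- gradient_magnitude(slice)
  accept <- abs(slice - ref) <= params$intensity_tolerance &
    grad < params$gradient_threshold
  dist <- sqrt(outer(((seq_len(n1) - seed[1]) * pixel_size[1])^2,
                     ((seq_len(n2) - seed[2]) * pixel_size[2])^2, "+"))
  in_disk <- dist <= params$max_radius
  eight <- params$connectivity == "face+edge"
  grow <- accept & in_disk
  mask <- matrix(FALSE, n1, n2)
  if (is.null(ref_intensity)) {
    mask[seed[1], seed[2]] <- TRUE       # seed always retained
  } else {
    # with an external reference, growth starts from the acceptable
    # pixels in a 5x5 window around the seed (one noisy pixel must not
    # abort a propagation); none acceptable means the material is
    # absent at this section and the mask comes back empty
    wi <- max(1L, seed[1] - 2L):min(n1, seed[1] + 2L)
    wj <- max(1L, seed[2] - 2L):min(n2, seed[2] + 2L)
    mask[wi, wj] <- grow[wi, wj]
    if (!any(mask))
      return(structure(mask, capped = FALSE, seed = seed))
  }
  repeat {
    nxt <- (dilate_mask(mask, eight) & grow) | mask  # seed always retained
    if (sum(nxt) == sum(mask)) break
    mask <- nxt
  }
  frontier <- dilate_mask(mask, eight) & accept & !in_disk
  structure(mask, capped = any(frontier), seed = seed)
}

# Propagation seed for a mask: the most interior mask pixel (deepest
# surviving shell under iterated erosion), tie-broken toward the mask
# centroid.  For disks this is the centroid; for annuli it is a
# mid-sheath pixel — the nearest-to-centroid rule the interactive tool
# suggests would land on the knife-edge inner boundary, where one voxel
# of drift between sections aborts the propagation.
mask_interior_seed <- function(mask) {
  core <- mask
  repeat {
    eroded <- !dilate_mask(!core)
    if (!any(eroded)) break
    core <- eroded
  }
  idx <- which(core, arr.ind = TRUE)
  ctr <- colMeans(which(mask, arr.ind = TRUE))
  d2 <- (idx[, 1] - ctr[1])^2 + (idx[, 2] - ctr[2])^2
  as.integer(idx[which.min(d2), ])
}

#' Propagate a blow segmentation through a serial stack
#'
#' Starting from a segmented first section, each subsequent section is
#' seeded at the previous mask's most interior pixel nearest its
#' centroid (for a disk this is the centroid; for an annulus, a
#' mid-sheath pixel rather than a fragile inner-boundary one) and
#' re-segmented with the tolerance band centred on the previous
#' section's mean mask intensity, so the propagation follows the
#' material, not whatever happens to lie under the seed.  Propagation
#' stops at the stack end, or when a section yields an empty or capped
#' region.
#'
#' @param stack an [image_stack()].
#' @param first_mask nonempty logical mask of the starting section.
#' @param params a [blow_params()].
#' @param start_slice plane index of `first_mask`.
#' @param label integer id written into the output volume.
#' @return a [label_volume()] with attributes `stop_slice` (last section
#'   segmented) and `stop_reason` (`"end"`, `"empty"` or `"capped"`).
#' @export
propagate_segmentation <- function(stack, first_mask, params,
                                   start_slice = 1L, label = 2L) {
  if (!any(first_mask)) stop("first_mask is empty")
  grid <- stack$grid
  out <- array(0L, grid$shape)
  px <- grid$voxel_size[1:2]
  mask <- first_mask
  out[, , start_slice][mask] <- label
  stop_slice <- start_slice
  stop_reason <- "end"
  k <- start_slice + 1L
  while (k <= grid$shape[3]) {
    seed <- mask_interior_seed(mask)
    ref <- mean(stack$data[, , k - 1L][mask])
    m <- blow_segment(stack$data[, , k], seed, params, pixel_size = px,
                      ref_intensity = ref)
    if (!any(m)) { stop_reason <- "empty"; break }
    if (isTRUE(attr(m, "capped"))) { stop_reason <- "capped"; break }
    out[, , k][m] <- label
    mask <- m
    stop_slice <- k
    k <- k + 1L
  }
  lv <- label_volume(out, grid)
  attr(lv, "stop_slice") <- stop_slice
  attr(lv, "stop_reason") <- stop_reason
  lv
}

#' Per-material voxel counts, volumes and per-section areas
#'
#' @param labels a [label_volume()].
#' @return list of class `label_measurements`: `summary` (data.frame with
#'   material, label, voxel_count, volume_um3, mean_slice_area_um2 over
#'   sections where the material is present) and `slice_areas_um2`
#'   (materials x planes matrix).  Background is excluded.
#' @export
measure_labels <- function(labels) {
  grid <- labels$grid
  mats <- labels$materials[labels$materials > 0]
  vv <- voxel_volume(grid)
  pa <- prod(grid$voxel_size[1:2])
  n3 <- grid$shape[3]
  flat <- matrix(labels$data, ncol = n3)
  areas <- matrix(0, nrow = length(mats), ncol = n3,
                  dimnames = list(names(mats), NULL))
  for (m in seq_along(mats))
    areas[m, ] <- colSums(flat == mats[m]) * pa
  counts <- rowSums(areas) / pa
  mean_area <- apply(areas, 1, function(a)
    if (any(a > 0)) mean(a[a > 0]) else 0)
  summary <- data.frame(material = names(mats), label = as.integer(mats),
                        voxel_count = as.numeric(counts),
                        volume_um3 = as.numeric(counts) * vv,
                        mean_slice_area_um2 = as.numeric(mean_area),
                        row.names = NULL)
  structure(list(summary = summary, slice_areas_um2 = areas),
            class = "label_measurements")
}

#' @export
print.label_measurements <- function(x, ...) {
  print(x$summary)
  invisible(x)
}
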