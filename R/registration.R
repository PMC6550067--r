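# Finder-grid relocation arithmetic and landmark shift analysis
# quantifying LM <-> EM correlation accuracy.

#' Finder-grid coordinate map
#'
#' Gridded culture dishes carry an alphanumeric finder grid (e.g. "4M")
#' embossed on the substrate.  Given one visible anchor coordinate, the
#' centers of neighbouring coordinates follow from the grid pitch:
#' numbers step along the first axis, letters along the second.
#'
#' @param anchor_label e.g. `"4M"`: one numeric run and one single-letter
#'   alphabetic run, in either order.
#' @param anchor_center physical center of the anchor square (um pair).
#' @param pitch grid pitch (um); the default 500 um is configurable, not
#'   a measured value.
#' @export
grid_map <- function(anchor_label, anchor_center = c(0, 0), pitch = 500) {
  if (!(pitch > 0)) stop("pitch must be > 0")
  parsed <- parse_grid_label(anchor_label)
  structure(list(anchor_label = anchor_label, anchor = parsed,
                 anchor_center = as.numeric(anchor_center), pitch = pitch),
            class = "grid_map")
}

parse_grid_label <- function(label) {
  label <- toupper(trimws(label))
  m <- regmatches(label, regexec("^([0-9]+)([A-Z]+)$|^([A-Z]+)([0-9]+)$",
                                 label))[[1]]
  if (!length(m)) stop("unparseable grid label: '", label, "'")
  num <- if (m[2] != "") m[2] else m[5]
  let <- if (m[3] != "") m[3] else m[4]
  if (nchar(let) != 1L)
    stop("multi-letter grid label '", label,
         "' not supported (the letter axis does not wrap past Z)")
  list(number = as.integer(num), letter = utf8ToInt(let) - utf8ToInt("A") + 1L)
}

#' Predict finder-grid square centers from one visible anchor
#'
#' @param map a [grid_map()].
#' @param labels character vector of target coordinates (e.g. `"5N"`).
#' @return data.frame (label, axis1_um from the numeric index, axis2_um
#'   from the letter index).
#' @export
predict_grid_coordinates <- function(map, labels) {
  rows <- lapply(labels, function(lb) {
    p <- parse_grid_label(lb)
    data.frame(label = lb,
               axis1_um = map$anchor_center[1] +
                 map$pitch * (p$number - map$anchor$number),
               axis2_um = map$anchor_center[2] +
                 map$pitch * (p$letter - map$anchor$letter))
  })
  do.call(rbind, rows)
}

#' Assign points to concentric rings
#'
#' Emulates the concentric-circles overlay used during landmark marking:
#' ring index `ceil(distance / spacing)`, with points exactly on a ring
#' boundary belonging to the inner ring (closed outer boundary) and the
#' center belonging to ring 1.
#'
#' @param points n x 2 matrix of positions (um).
#' @param center ring center (um pair).
#' @param spacing ring spacing (um); 6.5 um matches the overlay used
#'   during correlation scoring.
#' @return integer ring indices (>= 1).
#' @export
assign_rings <- function(points, center = c(0, 0), spacing = 6.5) {
  if (!(spacing > 0)) stop("spacing must be > 0")
  points <- rbind(points)
  d <- sqrt((points[, 1] - center[1])^2 + (points[, 2] - center[2])^2)
  pmax(1L, as.integer(ceiling(d / spacing - 1e-12)))
}

#' Paired LM/EM landmark correspondences
#'
#' @param lm,em n x 2 matrices of landmark positions (um) in the LM and
#'   EM projections.
#' @param origin_index index of the shared origin landmark (the clear
#'   structure both projections were centred on); always explicit, never
#'   auto-chosen.
#' @param class optional character vector (`"myelin"` / `"nucleus"`).
#' @export
correspondence_set <- function(lm, em, origin_index = 1L, class = NULL) {
  lm <- rbind(lm); em <- rbind(em)
  if (nrow(lm) != nrow(em)) stop("LM and EM point counts differ")
  if (ncol(lm) != 2L || ncol(em) != 2L) stop("points must be 2D (um pairs)")
  origin_index <- as.integer(origin_index)
  if (origin_index < 1L || origin_index > nrow(lm))
    stop("origin_index out of range")
  if (is.null(class)) class <- rep("myelin", nrow(lm))
  structure(list(lm = lm, em = em, origin_index = origin_index,
                 class = as.character(class)),
            class = "correspondence_set")
}

#' Per-landmark LM-to-EM shift analysis
#'
#' Both point sets are re-centred on the shared origin landmark; the
#' per-point shift is then (dx, dy) = EM - LM with distance
#' `sqrt(dx^2 + dy^2)`.  The distance from origin r of each point is
#' measured at the mean of its two centred positions.  The direction is
#' reported both as `asin(dy / shift)` (the convention used when scoring
#' correlation accuracy by eye) and as the full-quadrant `atan2(dy, dx)`.
#'
#' @param set a [correspondence_set()] with n >= 2.
#' @param ring_spacing concentric-ring spacing (um) for the ring index.
#' @return list of class `shift_result`: `table` (data.frame: dx_um,
#'   dy_um, shift_um, r_um, angle_asin, angle_atan2, ring, class),
#'   `mean_shift_um`, `sd_shift_um`, `n`.
#' @export
compute_shifts <- function(set, ring_spacing = 6.5) {
  n <- nrow(set$lm)
  if (n < 2L) stop("need at least 2 correspondences")
  # common re-centring on the shared origin landmark (midpoint of its two
  # marked positions): differencing then preserves genuine inter-modality
  # offsets while a rigid translation applied to BOTH modalities cancels.
  ctr <- (set$lm[set$origin_index, ] + set$em[set$origin_index, ]) / 2
  lm <- sweep(set$lm, 2, ctr, "-")
  em <- sweep(set$em, 2, ctr, "-")
  dxy <- em - lm
  shift <- sqrt(rowSums(dxy^2))
  mid <- (lm + em) / 2
  r <- sqrt(rowSums(mid^2))
  angle_asin <- ifelse(shift > 0, asin(pmin(pmax(dxy[, 2] / shift, -1), 1)),
                       NA_real_)
  angle_atan2 <- ifelse(shift > 0, atan2(dxy[, 2], dxy[, 1]), NA_real_)
  tab <- data.frame(dx_um = dxy[, 1], dy_um = dxy[, 2], shift_um = shift,
                    r_um = r, angle_asin = angle_asin,
                    angle_atan2 = angle_atan2,
                    ring = assign_rings(mid, c(0, 0), ring_spacing),
                    class = set$class)
  structure(list(table = tab, mean_shift_um = mean(shift),
                 sd_shift_um = stats::sd(shift), n = n,
                 ring_spacing_um = ring_spacing),
            class = "shift_result")
}

#' @export
print.shift_result <- function(x, ...) {
  cat(sprintf("<shift_result> n = %d, mean shift %.3f um (+/- %.3f um sd)\n",
              x$n, x$mean_shift_um, x$sd_shift_um))
  invisible(x)
}

#' Trend of the landmark shift with position
#'
#' Pearson correlation (two-sided t-based p) of the shift distance
#' against (a) the distance from origin and (b) the direction angle.
#' Directionally uniform (isotropic) misregistration shows neither
#' relationship.
#'
#' @param result a [compute_shifts()] result with n >= 3.
#' @param alpha significance level for the verdict.
#' @return list `vs_r` and `vs_angle` (each: r, p, n; `NA` with
#'   `zero_variance = TRUE` when undefined), and `verdict`:
#'   `"isotropic"` (both p > alpha), `"anisotropic"` (either p <= alpha)
#'   or `"indeterminate"` (a correlation is undefined).
#' @export
shift_trend <- function(result, alpha = 0.05) {
  tab <- result$table
  ok <- is.finite(tab$angle_atan2)
  if (result$n < 3L) stop("need at least 3 correspondences for a trend")
  one <- function(xv, yv) {
    keep <- is.finite(xv) & is.finite(yv)
    xv <- xv[keep]; yv <- yv[keep]
    tol <- function(v) 1e-9 * max(1, abs(v))
    if (length(xv) < 3L || stats::sd(xv) <= tol(mean(xv)) ||
        stats::sd(yv) <= tol(mean(yv)))
      return(list(r = NA_real_, p = NA_real_, n = length(xv),
                  zero_variance = TRUE))
    ct <- stats::cor.test(xv, yv)
    list(r = unname(ct$estimate), p = ct$p.value, n = length(xv),
         zero_variance = FALSE)
  }
  vs_r <- one(tab$r_um, tab$shift_um)
  vs_angle <- one(tab$angle_atan2, tab$shift_um)
  verdict <- if (vs_r$zero_variance || vs_angle$zero_variance) "indeterminate"
  else if (vs_r$p > alpha && vs_angle$p > alpha) "isotropic"
  else "anisotropic"
  list(vs_r = vs_r, vs_angle = vs_angle, verdict = verdict, alpha = alpha)
}

#' Write / read a correspondence set as CSV
#'
#' Columns: landmark_id, class, lm_x_um, lm_y_um, em_x_um, em_y_um,
#' is_origin.
#' @param set a [correspondence_set()].
#' @param path CSV path.
#' @export
write_correspondences <- function(set, path) {
  n <- nrow(set$lm)
  df <- data.frame(landmark_id = seq_len(n), class = set$class,
                   lm_x_um = set$lm[, 1], lm_y_um = set$lm[, 2],
                   em_x_um = set$em[, 1], em_y_um = set$em[, 2],
                   is_origin = seq_len(n) == set$origin_index)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_correspondences
#' @export
read_correspondences <- function(path) {
  df <- utils::read.csv(path)
  correspondence_set(as.matrix(df[, c("lm_x_um", "lm_y_um")]),
                     as.matrix(df[, c("em_x_um", "em_y_um")]),
                     origin_index = which(df$is_origin)[1],
                     class = df$class)
}
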