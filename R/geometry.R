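#' Sample labels along a segment
#'
#' Samples the segment at uniform arc-length spacing `step_mm` from start to
#' end inclusive, reading the label of the nearest voxel at each sample. Any
#' structure whose intersection with the segment has extent of at least
#' `step_mm` is guaranteed to be reported; thinner grazing intersections may
#' be missed.
#'
#' @param volume a [labeled_volume()].
#' @param start,end world points (mm), inside the volume bounds.
#' @param step_mm sampling step; must not exceed the smallest voxel spacing.
#' @return data.frame with columns `x`, `y`, `z`, `t` (arc length from start,
#'   mm) and `label`.
#' @export
trace_segment <- function(volume, start, end, step_mm = min(volume$spacing) / 2) {
  check_inside(volume, rbind(start, end))
  if (step_mm > min(volume$spacing)) {
    stop("step_mm must not exceed the smallest voxel spacing")
  }
  if (sum((end - start)^2) == 0) stop("segment length must be > 0")
  tr <- cpp_trace(volume$labels, dim(volume$labels), volume$spacing,
                  volume$origin, as.numeric(start), as.numeric(end), step_mm)
  p <- tr$points
  data.frame(x = p[, 1], y = p[, 2], z = p[, 3],
             t = sqrt(rowSums(sweep(p, 2, as.numeric(start))^2)),
             label = tr$labels)
}

check_inside <- function(volume, pts) {
  pts <- matrix(as.numeric(pts), ncol = 3)
  lo <- volume$origin - volume$spacing / 2
  hi <- volume$origin + (dim(volume$labels) - 1) * volume$spacing +
    volume$spacing / 2
  for (a in 1:3) {
    if (any(pts[, a] < lo[a] - 1e-9 | pts[, a] > hi[a] + 1e-9)) {
      stop("point outside volume bounds")
    }
  }
  invisible(TRUE)
}

#' First crossing of a segment into a label set
#'
#' Walks the segment from `start` toward `end` at `step_mm`; the first sample
#' whose label belongs to `label_set` is refined by bisection between the
#' bracketing samples to within 0.1 mm of the label boundary.
#'
#' @inheritParams trace_segment
#' @param label_set integer vector of labels to detect.
#' @return world point (numeric length 3) of the crossing with attribute
#'   `"t"` (distance from start, mm), or `NULL` if the set is never entered.
#' @export
first_crossing <- function(volume, start, end, label_set,
                           step_mm = min(volume$spacing) / 2) {
  check_inside(volume, rbind(start, end))
  if (length(label_set) == 0L) return(NULL)
  set <- label_flag_vector(volume, label_set)
  hit <- cpp_first_hit(volume$labels, dim(volume$labels), volume$spacing,
                       volume$origin, matrix(as.numeric(start), 1),
                       matrix(as.numeric(end), 1), set, step_mm, 0.05)
  if (hit[1, 1] < 1) return(NULL)
  structure(as.numeric(hit[1, 3:5]), t = hit[1, 2])
}

# Logical membership vector indexed by label value + 1 (label l -> set[l+1]).
label_flag_vector <- function(volume, label_set) {
  maxlab <- max(volume$labels, 1L, label_set)
  set <- rep(FALSE, maxlab + 1L)
  set[as.integer(label_set) + 1L] <- TRUE
  set
}

#' Outward surface normal of a labeled structure
#'
#' The normal is the normalized negative gradient of the Gaussian-smoothed
#' (sigma = 1 voxel) binary mask of the role, oriented to point out of the
#' structure. `point` must lie within one voxel diagonal of the structure
#' surface.
#'
#' @param scene an `anatomy_scene`.
#' @param role role name whose surface is queried, or an integer label vector.
#' @param point world point (mm) on or near the surface.
#' @return unit-length numeric vector of length 3.
#' @export
surface_normal <- function(scene, role, point) {
  labs <- if (is.character(role)) role_labels(scene, role) else as.integer(role)
  vol <- scene$volume
  sm <- smoothed_mask(vol, labs)
  n <- normals_at(sm, vol, matrix(as.numeric(point), 1))
  if (any(is.na(n))) stop("zero mask gradient at the query point; ",
                          "the point is not near the surface")
  as.numeric(n)
}

# Smoothed (sigma = 1 voxel) double mask of a label set.
smoothed_mask <- function(volume, labels) {
  m <- array(as.numeric(volume$labels %in% labels), dim(volume$labels))
  array(cpp_smooth3d(m, dim(volume$labels), 1.0), dim(volume$labels))
}

# Outward unit normals of a smoothed mask at world points (n x 3); rows of
# NA where the gradient vanishes.
normals_at <- function(sm, volume, pts) {
  dm <- dim(volume$labels)
  g <- matrix(0, nrow(pts), 3)
  for (a in 1:3) {
    h <- volume$spacing[a]
    pp <- pm <- pts
    pp[, a] <- pp[, a] + h
    pm[, a] <- pm[, a] - h
    g[, a] <- (cpp_trilinear(sm, dm, volume$spacing, volume$origin, pp) -
                 cpp_trilinear(sm, dm, volume$spacing, volume$origin, pm)) /
      (2 * h)
  }
  nrm <- sqrt(rowSums(g^2))
  out <- -g / nrm  # mask decreases outward, so -gradient points outward
  out[nrm < 1e-8, ] <- NA_real_
  out
}

#' Angle between a path and a surface
#'
#' Returns the insertion angle alpha in degrees: 90 minus the acute angle
#' between the path direction and the surface normal. Alpha is 90 for a
#' perpendicular insertion and 0 for a tangential one, and is invariant under
#' negation of either vector.
#'
#' @param direction,normal numeric length-3 vectors (need not be normalized,
#'   but must be nonzero).
#' @return angle in degrees, in `[0, 90]`.
#' @export
path_surface_angle <- function(direction, normal) {
  nd <- sqrt(sum(direction^2))
  nn <- sqrt(sum(normal^2))
  if (nd < 1e-12 || nn < 1e-12) stop("zero vector")
  ct <- abs(sum(direction * normal)) / (nd * nn)
  90 - acos(min(1, ct)) * 180 / pi
}

#' Euclidean distance transform of a labeled volume
#'
#' Exact Euclidean distance (mm, voxel center to voxel center) from every
#' voxel to the nearest voxel carrying one of `obstacle_labels`, honoring
#' anisotropic spacing.
#'
#' @param volume a [labeled_volume()].
#' @param obstacle_labels nonempty integer vector of obstacle labels present
#'   in the volume.
#' @return a `distance_field`: list with `values` (3D numeric array, mm),
#'   `spacing`, `origin`.
#' @export
distance_transform <- function(volume, obstacle_labels) {
  obst <- volume$labels %in% as.integer(obstacle_labels)
  if (!any(obst)) stop("obstacle label set is empty within the volume")
  vals <- cpp_edt3d(array(obst, dim(volume$labels)), dim(volume$labels),
                    volume$spacing)
  structure(list(values = array(vals, dim(volume$labels)),
                 spacing = volume$spacing, origin = volume$origin),
            class = "distance_field")
}

#' Write a distance field to NIfTI for inspection
#' @param field a `distance_field`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_distance_field <- function(field, path) {
  img <- RNifti::asNifti(field$values)
  RNifti::pixdim(img) <- field$spacing
  xf <- diag(4)
  diag(xf)[1:3] <- field$spacing
  xf[1:3, 4] <- field$origin
  RNifti::qform(img) <- structure(xf, code = 2L)
  RNifti::sform(img) <- structure(xf, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

seg_extreme <- function(field, start, end, step_mm, want_min) {
  vol_like <- list(labels = field$values, spacing = field$spacing,
                   origin = field$origin)
  check_inside(vol_like, rbind(start, end))
  cpp_seg_extreme(field$values, dim(field$values), field$spacing,
                  field$origin, matrix(as.numeric(start), 1),
                  matrix(as.numeric(end), 1), step_mm, want_min)[1]
}

#' Minimum of a distance field along a segment (per-ray MinIP)
#'
#' Minimum of trilinearly interpolated field values over uniform samples
#' (endpoints included) along the segment.
#'
#' @param field a `distance_field` (or any list with `values`, `spacing`,
#'   `origin`).
#' @param start,end world points (mm).
#' @param step_mm sampling step (mm).
#' @return minimum value (mm).
#' @export
min_along_segment <- function(field, start, end,
                              step_mm = min(field$spacing) / 2) {
  seg_extreme(field, start, end, step_mm, TRUE)
}

#' Maximum of a scalar field along a segment (per-ray MIP)
#'
#' @inheritParams min_along_segment
#' @return maximum value.
#' @export
max_along_segment <- function(field, start, end,
                              step_mm = min(field$spacing) / 2) {
  seg_extreme(field, start, end, step_mm, FALSE)
}
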