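# Enumerate every boundary voxel of a grid exactly once, assigned to one of
# the six bounding-box faces with priority x-, x+, y-, y+, z-, z+.
boundary_cells <- function(dim, spacing, origin) {
  n1 <- dim[1]; n2 <- dim[2]; n3 <- dim[3]
  idx <- rbind(
    # x- and x+ faces: full j,k extent
    cbind(0L, rep(0:(n2 - 1), times = n3), rep(0:(n3 - 1), each = n2)),
    cbind(n1 - 1L, rep(0:(n2 - 1), times = n3), rep(0:(n3 - 1), each = n2)),
    # y- / y+: interior i only
    cbind(rep(1:(n1 - 2), times = n3), 0L, rep(0:(n3 - 1), each = n1 - 2)),
    cbind(rep(1:(n1 - 2), times = n3), n2 - 1L, rep(0:(n3 - 1), each = n1 - 2)),
    # z- / z+: interior i and j
    cbind(rep(1:(n1 - 2), times = n2 - 2), rep(1:(n2 - 2), each = n1 - 2), 0L),
    cbind(rep(1:(n1 - 2), times = n2 - 2), rep(1:(n2 - 2), each = n1 - 2),
          n3 - 1L)
  )
  face <- rep(c("x-", "x+", "y-", "y+", "z-", "z+"),
              c(n2 * n3, n2 * n3, (n1 - 2) * n3, (n1 - 2) * n3,
                (n1 - 2) * (n2 - 2), (n1 - 2) * (n2 - 2)))
  w <- sweep(sweep(matrix(as.numeric(idx), ncol = 3), 2, spacing, "*"),
             2, origin, "+")
  data.frame(cell = seq_len(nrow(idx)),
             face = factor(face, levels = c("x-", "x+", "y-", "y+",
                                            "z-", "z+")),
             i = idx[, 1], j = idx[, 2], k = idx[, 3],
             Ix = w[, 1], Iy = w[, 2], Iz = w[, 3])
}

#' Build the six bounding-box face maps
#'
#' Enumerates one candidate insertion point per boundary voxel of the volume
#' (deduplicated edges and corners, assigned to a single face with priority
#' x-, x+, y-, y+, z-, z+), so that every sight line from the target C to the
#' bounding-box surface is represented exactly once. The total number of
#' cells is `W*H*D - (W-2)*(H-2)*(D-2)`.
#'
#' @param scene an `anatomy_scene`.
#' @param C target world point (mm), strictly inside the bounding box.
#' @return an object of class `face_map_set`: list with `cells` (data.frame
#'   of cell id, face, 0-based voxel index, world insertion point), `C`,
#'   `dim`, `spacing`, `origin`.
#' @export
build_face_maps <- function(scene, C = tumor_centroid(scene)) {
  vol <- scene$volume
  lo <- vol$origin
  hi <- vol$origin + (dim(vol$labels) - 1) * vol$spacing
  if (any(C <= lo) || any(C >= hi)) {
    stop("target point must lie strictly inside the volume bounding box")
  }
  structure(list(cells = boundary_cells(dim(vol$labels), vol$spacing,
                                        vol$origin),
                 C = as.numeric(C), dim = dim(vol$labels),
                 spacing = vol$spacing, origin = vol$origin),
            class = "face_map_set")
}

#' @export
print.face_map_set <- function(x, ...) {
  cat("<face_map_set> ", nrow(x$cells), " cells over 6 faces, target C = (",
      paste(signif(x$C, 6), collapse = ", "), ") mm\n", sep = "")
  invisible(x)
}

# ---------------------------------------------------------------------------
# Sub-voxel structure membership. Collision tests against labeled structures
# use the 0.5-level set of the trilinearly interpolated binary mask -- the
# implicit surface a marching-cubes reconstruction of the mask would produce.
# This localizes boundaries to sub-voxel accuracy instead of dilating every
# structure by the voxel half-diagonal as nearest-voxel lookup would.
# ---------------------------------------------------------------------------

# Binary mask of a label set as a double array (for interpolation).
role_mask <- function(volume, labels) {
  array(as.numeric(volume$labels %in% as.integer(labels)),
        dim(volume$labels))
}

# Does each segment start->end enter the 0.5-isosurface of `mask`?
segments_hit_mask <- function(volume, mask, starts, ends, step_mm) {
  cpp_seg_extreme(mask, dim(volume$labels), volume$spacing, volume$origin,
                  starts, ends, step_mm, FALSE) >= 0.5
}

# First 0.5-isosurface crossing per segment; N x 5 (hit, t, x, y, z).
segments_first_iso <- function(volume, mask, starts, ends, step_mm) {
  cpp_first_iso(mask, dim(volume$labels), volume$spacing, volume$origin,
                starts, ends, step_mm, 0.5, 0.05)
}

#' Occlusion layer of the H1 constraint over all face cells
#'
#' For every boundary-voxel insertion point, tests whether the sight line to
#' the target crosses any risk structure (the binary classification the
#' cube-mapped projection of the vital structures encodes). This is the raw
#' H1 occlusion layer; [plan_paths()] additionally fails paths that never
#' reach the target lobe.
#'
#' @param scene an `anatomy_scene`.
#' @param C target world point, default the tumor centroid.
#' @param step_mm sampling step along rays.
#' @return logical vector over face cells (ordered as
#'   [build_face_maps()]`$cells`): TRUE where occluded.
#' @export
occlusion_map <- function(scene, C = tumor_centroid(scene),
                          step_mm = min(scene$volume$spacing) / 2) {
  vol <- scene$volume
  risk <- role_labels(scene, scene$risk_roles)
  cells <- boundary_cells(dim(vol$labels), vol$spacing, vol$origin)
  if (length(risk) == 0L) return(rep(FALSE, nrow(cells)))
  starts <- as.matrix(cells[, c("Ix", "Iy", "Iz")])
  segments_hit_mask(vol, role_mask(vol, risk), starts,
                    matrix(C, nrow(starts), 3, byrow = TRUE), step_mm)
}

# ---------------------------------------------------------------------------
# Per-path hard-constraint checks (single-candidate API). The batch planner
# in plan_paths() applies the same rules across all face cells at once.
# ---------------------------------------------------------------------------

#' Hard constraint H1: the path must not cross a vital structure
#'
#' Fails iff the segment from the insertion point I to the target C enters
#' any risk structure (0.5-isosurface of the combined risk mask). Tumor and
#' target-lobe labels never trigger H1; structures beyond C on the extended
#' line are not tested.
#'
#' @param scene an `anatomy_scene`.
#' @param I,C world points (mm): insertion point and target.
#' @param step_mm sampling step.
#' @return `TRUE` if the constraint FAILS (path blocked).
#' @export
check_h1 <- function(scene, I, C, step_mm = min(scene$volume$spacing) / 2) {
  risk <- role_labels(scene, scene$risk_roles)
  if (length(risk) == 0L) return(FALSE)
  segments_hit_mask(scene$volume, role_mask(scene$volume, risk),
                    matrix(as.numeric(I), 1), matrix(as.numeric(C), 1),
                    step_mm)
}

#' Hard constraint H2: percutaneous length strictly less than needle length
#'
#' Finds the skin entry point E (first skin crossing from I toward C) and the
#' percutaneous length `l = ||E - C||`. Fails iff `l >= needle_length_mm`
#' (equality fails: the requirement is strict).
#'
#' @inheritParams check_h1
#' @param needle_length_mm usable needle length (mm).
#' @return list with `fail`, `l_mm`, `E`.
#' @export
check_h2 <- function(scene, I, C, needle_length_mm,
                     step_mm = min(scene$volume$spacing) / 2) {
  hit <- segments_first_iso(scene$volume,
                            role_mask(scene$volume,
                                      role_labels(scene, "skin")),
                            matrix(as.numeric(I), 1),
                            matrix(as.numeric(C), 1), step_mm)
  if (hit[1, 1] < 1) stop("no skin crossing on the segment; ",
                          "is the insertion point inside the body?")
  E <- as.numeric(hit[1, 3:5])
  l <- sqrt(sum((E - C)^2))
  list(fail = l >= needle_length_mm, l_mm = l, E = E)
}

#' Hard constraint H3: pleural entry angle above threshold
#'
#' Finds the lung entry point P (first target-lobe crossing after the skin
#' entry E) and the angle between the path and the lung surface there. Fails
#' iff the angle is less than or equal to `angle_threshold_deg` (boundary
#' equality fails). A path that never enters the target lobe is reported via
#' `no_lung = TRUE` (treated as an H1-style failure by the planner).
#'
#' @inheritParams check_h2
#' @param E skin entry point from [check_h2()].
#' @param angle_threshold_deg threshold (deg), default 20.
#' @return list with `fail`, `no_lung`, `alpha_deg`, `P`.
#' @export
check_h3 <- function(scene, E, C, angle_threshold_deg = 20,
                     step_mm = min(scene$volume$spacing) / 2) {
  lobe <- role_labels(scene, c("lung_target_lobe", "tumor"))
  hit <- segments_first_iso(scene$volume, role_mask(scene$volume, lobe),
                            matrix(as.numeric(E), 1),
                            matrix(as.numeric(C), 1), step_mm)
  if (hit[1, 1] < 1) {
    return(list(fail = TRUE, no_lung = TRUE, alpha_deg = NA_real_, P = NULL))
  }
  P <- as.numeric(hit[1, 3:5])
  n <- surface_normal(scene, c("lung_target_lobe", "tumor"), P)
  alpha <- path_surface_angle(C - as.numeric(E), n)
  list(fail = alpha <= angle_threshold_deg, no_lung = FALSE,
       alpha_deg = alpha, P = P)
}

# Voxel mask of the H4 risk region: the expected ablation zone (tumor dilated
# by ablation_margin_mm) grown by depth_margin_mm, minus the lung parenchyma
# (and tumor). Paths crossing this shell would enter the ablation margin with
# too little lung between it and the pleura.
h4_risk_mask <- function(scene, depth_margin_mm, ablation_margin_mm) {
  vol <- scene$volume
  dt <- distance_transform(vol, role_labels(scene, "tumor"))
  lung <- vol$labels %in% role_labels(scene, c("lung_target_lobe",
                                               "lung_other", "tumor"))
  array(dt$values <= ablation_margin_mm + depth_margin_mm & !lung,
        dim(vol$labels))
}

#' Hard constraint H4: sufficient insertion depth into the lung
#'
#' The expected ablation zone (tumor plus `ablation_margin_mm`) is expanded
#' by `depth_margin_mm`; any expanded region that falls outside the lung
#' parenchyma is treated as a vital structure. Fails iff the segment I->C
#' crosses that region.
#'
#' @inheritParams check_h1
#' @param depth_margin_mm,ablation_margin_mm margins in mm (defaults 5).
#' @param mask optional precomputed mask from an earlier call (same scene and
#'   margins), to avoid recomputing the distance transform.
#' @return `TRUE` if the constraint FAILS.
#' @export
check_h4 <- function(scene, I, C, depth_margin_mm = 5, ablation_margin_mm = 5,
                     step_mm = min(scene$volume$spacing) / 2, mask = NULL) {
  if (is.null(mask)) {
    mask <- h4_risk_mask(scene, depth_margin_mm, ablation_margin_mm)
  }
  if (!any(mask)) return(FALSE)
  segments_hit_mask(scene$volume, array(as.numeric(mask), dim(mask)),
                    matrix(as.numeric(I), 1), matrix(as.numeric(C), 1),
                    step_mm)
}

#' Integrate hard-constraint failure layers into a feasibility mask
#'
#' OR-combination of the four failure layers: a cell is feasible iff no hard
#' constraint failed (blocked cells carry 0, open cells 1).
#'
#' @param h1,h2,h3,h4 logical failure vectors (TRUE = constraint failed),
#'   one element per face cell.
#' @return logical vector: TRUE where feasible.
#' @export
integrate_hard <- function(h1, h2, h3, h4) {
  !(h1 | h2 | h3 | h4)
}

# ---------------------------------------------------------------------------
# Soft-constraint normalization (grayscale constraint maps).
# ---------------------------------------------------------------------------

# (x - min)/(max - min) over the feasible subset; degenerate range -> 1.
normalize_feasible <- function(raw, feasible, higher_is_better = TRUE) {
  out <- rep(NA_real_, length(raw))
  v <- raw[feasible]
  if (!length(v)) return(list(scores = out, min = NA_real_, max = NA_real_))
  lo <- min(v); hi <- max(v)
  if (hi - lo < 1e-12) {
    out[feasible] <- 1.0
  } else {
    sc <- (v - lo) / (hi - lo)
    out[feasible] <- if (higher_is_better) sc else 1 - sc
  }
  list(scores = out, min = lo, max = hi)
}

#' Grayscale constraint map S1: distance from vital structures
#'
#' Raw value per feasible cell: minimum of the risk-structure distance field
#' along the percutaneous portion E->C of the path (or the full sight line
#' I->C when `full_ray`). Normalized score `R = (d - dmin)/(dmax - dmin)`
#' with extrema over the feasible set; larger distance scores higher.
#'
#' @param raw numeric vector of per-cell minimum risk distances (mm); NA on
#'   infeasible cells.
#' @param feasible logical feasibility vector.
#' @return list with `scores` (NA on infeasible cells), `min`, `max`.
#' @export
soft_map_s1 <- function(raw, feasible) {
  normalize_feasible(raw, feasible, higher_is_better = TRUE)
}

#' Grayscale constraint map S2: percutaneous path length
#'
#' Normalized score `L = 1 - (l - lmin)/(lmax - lmin)`: shorter paths score
#' higher.
#'
#' @param raw numeric vector of per-cell percutaneous lengths (mm).
#' @inheritParams soft_map_s1
#' @export
soft_map_s2 <- function(raw, feasible) {
  normalize_feasible(raw, feasible, higher_is_better = FALSE)
}

#' Grayscale constraint map S3: pleural entry angle
#'
#' Normalized score `A = (alpha - amin)/(amax - amin)` by default: larger
#' entry angles score higher, matching the clinical preference for steep
#' insertion. `printed_form = TRUE` inverts the orientation.
#'
#' @param raw numeric vector of per-cell entry angles (deg).
#' @param printed_form logical; score smaller angles higher instead.
#' @inheritParams soft_map_s1
#' @export
soft_map_s3 <- function(raw, feasible, printed_form = FALSE) {
  normalize_feasible(raw, feasible, higher_is_better = !printed_form)
}
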