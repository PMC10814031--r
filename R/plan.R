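#' Plan ablation needle paths for a scene
#'
#' Runs the full planning pipeline: face-map construction (one candidate
#' insertion point per boundary voxel), hard-constraint filtering (H1
#' vital-structure avoidance, H2 needle length, H3 pleural entry angle, H4
#' insertion depth), soft-constraint grayscale maps (S1 risk distance, S2
#' percutaneous length, S3 entry angle), Pareto-front intersection and
#' weighted ranking.
#'
#' @param scene an [anatomy_scene()].
#' @param config a [plan_config()].
#' @return an object of class `plan_result`: list with `status`
#'   (`"ok"` or `"no-feasible-path"`), `paths` (ranked data.frame with full
#'   provenance), `counts` (per-stage candidate counts), `extrema`
#'   (normalization extrema), `fallback` (TRUE when the pairwise Pareto
#'   intersection was empty and the 3D front was used), `C`, `config`,
#'   `cells` (per-cell feasibility and scores for map export).
#' @export
plan_paths <- function(scene, config = plan_config()) {
  stopifnot(inherits(scene, "anatomy_scene"), inherits(config, "plan_config"))
  vol <- scene$volume
  dm <- dim(vol$labels)
  step <- effective_step(config, vol)

  C <- tumor_centroid(scene)
  fm <- build_face_maps(scene, C)
  cells <- fm$cells
  n <- nrow(cells)
  starts <- as.matrix(cells[, c("Ix", "Iy", "Iz")])
  ends <- matrix(C, n, 3, byrow = TRUE)

  risk <- role_labels(scene, scene$risk_roles)
  skin <- role_labels(scene, "skin")
  lobe <- role_labels(scene, c("lung_target_lobe", "tumor"))

  # H1: any risk structure on I -> C (0.5-isosurface of the risk mask)
  if (length(risk)) {
    h1 <- segments_hit_mask(vol, role_mask(vol, risk), starts, ends, step)
  } else {
    h1 <- rep(FALSE, n)
  }

  # skin entry E and percutaneous length (H2)
  sk <- segments_first_iso(vol, role_mask(vol, skin), starts, ends, step)
  has_skin <- sk[, 1] > 0
  E <- sk[, 3:5, drop = FALSE]
  E[!has_skin, ] <- NA_real_
  l_i <- sqrt(rowSums(sweep(E, 2, C)^2))
  h2 <- !has_skin | (l_i >= config$needle_length_mm)
  h2[is.na(h2)] <- TRUE

  # lung entry P and entry angle (H3); paths that never reach the target
  # lobe are H1-style failures
  from <- E
  from[!has_skin, ] <- starts[!has_skin, ]
  lg <- segments_first_iso(vol, role_mask(vol, lobe), from, ends, step)
  has_lung <- lg[, 1] > 0
  P <- lg[, 3:5, drop = FALSE]
  P[!has_lung, ] <- NA_real_
  h1 <- h1 | !has_lung
  alpha_i <- rep(NA_real_, n)
  if (any(has_lung)) {
    sm <- smoothed_mask(vol, lobe)
    nrm <- normals_at(sm, vol, P[has_lung, , drop = FALSE])
    dirs <- sweep(-from[has_lung, , drop = FALSE], 2, C, "+")
    dirs <- dirs / pmax(sqrt(rowSums(dirs^2)), 1e-12)
    ct <- abs(rowSums(dirs * nrm))
    a <- 90 - acos(pmin(1, ct)) * 180 / pi
    a[is.na(rowSums(nrm))] <- 0  # vanished gradient: treat as tangential
    alpha_i[has_lung] <- a
  }
  h3 <- is.na(alpha_i) | alpha_i <= config$angle_threshold_deg

  # H4: insertion depth via the expanded-ablation-zone shell
  mask <- h4_risk_mask(scene, config$depth_margin_mm,
                       config$ablation_margin_mm)
  if (any(mask)) {
    h4 <- segments_hit_mask(vol, array(as.numeric(mask), dm), starts, ends,
                            step)
  } else {
    h4 <- rep(FALSE, n)
  }

  feasible <- integrate_hard(h1, h2, h3, h4)
  counts <- list(candidates = n, h1_fail = sum(h1), h2_fail = sum(h2),
                 h3_fail = sum(h3), h4_fail = sum(h4),
                 feasible = sum(feasible))

  base <- list(C = C, config = config, counts = counts,
               scene_checksum = scene_checksum(scene))
  if (!any(feasible)) {
    fails <- unlist(counts[c("h1_fail", "h2_fail", "h3_fail", "h4_fail")])
    return(structure(c(base, list(
      status = "no-feasible-path",
      dominant_constraint = c("H1", "H2", "H3", "H4")[which.max(fails)],
      paths = data.frame(), fallback = FALSE, extrema = NULL,
      cells = cbind(cells, feasible = feasible, h1 = h1, h2 = h2, h3 = h3,
                    h4 = h4))), class = "plan_result"))
  }

  # S1: minimum risk distance over the percutaneous portion E -> C
  d_i <- rep(NA_real_, n)
  if (length(risk)) {
    rf <- distance_transform(vol, risk)
    s1_from <- if (config$s1_full_ray) starts else E
    fi <- which(feasible)
    d_i[fi] <- cpp_seg_extreme(rf$values, dm, vol$spacing, vol$origin,
                               s1_from[fi, , drop = FALSE],
                               ends[fi, , drop = FALSE], step, TRUE)
  } else {
    d_i[feasible] <- Inf
  }

  s1 <- soft_map_s1(ifelse(is.finite(d_i), d_i, NA), feasible)
  if (all(!is.finite(d_i[feasible]))) {
    s1$scores[feasible] <- 1.0  # no risk structures: S1 equally satisfied
  }
  s2 <- soft_map_s2(l_i, feasible)
  s3 <- soft_map_s3(alpha_i, feasible, printed_form = config$s3_printed_form)

  cand <- data.frame(cell = cells$cell[feasible],
                     R = s1$scores[feasible], L = s2$scores[feasible],
                     A = s3$scores[feasible])
  sel <- select_top_k(cand, config$weights, config$top_k,
                      config$product_form)

  m <- match(sel$cell, cells$cell)
  paths <- data.frame(
    rank = sel$rank, cell = sel$cell, face = as.character(cells$face[m]),
    Ix = cells$Ix[m], Iy = cells$Iy[m], Iz = cells$Iz[m],
    Cx = C[1], Cy = C[2], Cz = C[3],
    Ex = E[m, 1], Ey = E[m, 2], Ez = E[m, 3],
    Px = P[m, 1], Py = P[m, 2], Pz = P[m, 3],
    d_mm = d_i[m], l_mm = l_i[m], alpha_deg = alpha_i[m],
    R = sel$R, L = sel$L, A = sel$A, G = sel$G)

  cellinfo <- cbind(cells, feasible = feasible, h1 = h1, h2 = h2, h3 = h3,
                    h4 = h4, d_mm = d_i, l_mm = l_i, alpha_deg = alpha_i,
                    R = s1$scores, L = s2$scores, A = s3$scores)
  structure(c(base, list(
    status = "ok", paths = paths,
    fallback = isTRUE(attr(sel, "fallback")),
    extrema = list(d_min = s1$min, d_max = s1$max, l_min = s2$min,
                   l_max = s2$max, alpha_min = s3$min, alpha_max = s3$max),
    cells = cellinfo)), class = "plan_result")
}

#' @export
print.plan_result <- function(x, ...) {
  cat("<plan_result>", x$status, "\n")
  cat("  candidates:", x$counts$candidates, "| feasible:",
      x$counts$feasible, "\n")
  if (x$status == "ok") {
    cat("  top", nrow(x$paths), "paths (G = weighted score):\n")
    print(x$paths[, c("rank", "face", "d_mm", "l_mm", "alpha_deg", "G")],
          digits = 4)
  } else {
    cat("  dominant eliminating constraint:", x$dominant_constraint, "\n")
  }
  invisible(x)
}

scene_checksum <- function(scene) {
  v <- as.double(scene$volume$labels)
  sprintf("%.0f-%.6f", sum(v), sum(v * seq_along(v)) %% 1e12)
}

#' S2 cross-check: percutaneous length by distance-field MIP
#'
#' Recomputes the per-cell percutaneous length through the alternative
#' distance-transform formulation: a field holding the Euclidean distance of
#' every voxel center from the target C, clipped to 0 outside the body, whose
#' maximum along the sight line I->C (per-ray maximum intensity projection)
#' equals the skin-entry-to-target distance up to voxelization error
#' (nearest-voxel sampling of the rendered field).
#'
#' @param scene an [anatomy_scene()].
#' @param C target point; default tumor centroid.
#' @param cells matrix (n x 3) of insertion points; default all boundary
#'   voxel centers.
#' @param step_mm sampling step, default half the smallest spacing.
#' @return numeric vector of lengths (mm), one per cell.
#' @export
s2_dtf_mip <- function(scene, C = tumor_centroid(scene), cells = NULL,
                       step_mm = min(scene$volume$spacing) / 2) {
  vol <- scene$volume
  dm <- dim(vol$labels)
  if (is.null(cells)) {
    cells <- as.matrix(boundary_cells(dm, vol$spacing,
                                      vol$origin)[, c("Ix", "Iy", "Iz")])
  }
  cells <- matrix(as.numeric(cells), ncol = 3)
  idx <- which(array(TRUE, dm), arr.ind = TRUE) - 1L
  w <- world_from_index(vol, idx)
  fld <- sqrt((w[, 1] - C[1])^2 + (w[, 2] - C[2])^2 + (w[, 3] - C[3])^2)
  fld[as.vector(vol$labels) == 0L] <- 0  # outside the body: lowest gray value
  fld <- array(fld, dm)
  cpp_seg_extreme(fld, dm, vol$spacing, vol$origin, cells,
                  matrix(C, nrow(cells), 3, byrow = TRUE), step_mm, FALSE,
                  nearest = TRUE)
}

# ---------------------------------------------------------------------------
# Independent verification (separate, pure-R segment tracer and interpolator;
# shares no code with the planner's C++ classification path).
# ---------------------------------------------------------------------------

# Pure R nearest-voxel sampler.
r_trace_labels <- function(volume, start, end, step_mm) {
  d <- end - start
  len <- sqrt(sum(d^2))
  ts <- unique(c(seq(0, len, by = step_mm), len))
  pts <- cbind(start[1] + ts / len * d[1], start[2] + ts / len * d[2],
               start[3] + ts / len * d[3])
  idx <- index_from_world(volume, pts)
  dmv <- dim(volume$labels)
  lin <- idx[, 1] + idx[, 2] * dmv[1] + idx[, 3] * dmv[1] * dmv[2] + 1L
  list(t = ts, pts = pts, labels = volume$labels[lin])
}

# Pure R trilinear interpolation of a 3D array at world points (n x 3).
r_trilinear <- function(arr, spacing, origin, pts) {
  dmv <- dim(arr)
  u <- sweep(sweep(matrix(as.numeric(pts), ncol = 3), 2, origin, "-"),
             2, spacing, "/")
  for (a in 1:3) u[, a] <- pmin(pmax(u[, a], 0), dmv[a] - 1)
  i0 <- pmin(floor(u), rep(dmv - 2L, each = nrow(u)))
  fr <- u - i0
  val <- numeric(nrow(u))
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- (if (dx) fr[, 1] else 1 - fr[, 1]) *
      (if (dy) fr[, 2] else 1 - fr[, 2]) *
      (if (dz) fr[, 3] else 1 - fr[, 3])
    lin <- (i0[, 1] + dx) + (i0[, 2] + dy) * dmv[1] +
      (i0[, 3] + dz) * dmv[1] * dmv[2] + 1
    val <- val + w * arr[lin]
  }
  val
}

# Sample points of a segment at uniform arc length (both endpoints).
r_seg_points <- function(start, end, step_mm) {
  d <- end - start
  len <- sqrt(sum(d^2))
  ts <- unique(c(seq(0, len, by = step_mm), len))
  list(t = ts, pts = cbind(start[1] + ts / len * d[1],
                           start[2] + ts / len * d[2],
                           start[3] + ts / len * d[3]))
}

# First crossing of the 0.5-level of a mask array along a segment (pure R).
r_first_iso <- function(arr, spacing, origin, start, end, step_mm,
                        tol_mm = 0.05) {
  sg <- r_seg_points(start, end, step_mm)
  vals <- r_trilinear(arr, spacing, origin, sg$pts)
  inside <- vals >= 0.5
  if (!any(inside)) return(NULL)
  s <- which(inside)[1]
  if (s == 1L) return(list(point = start, t = 0))
  lo <- sg$t[s - 1L]; hi <- sg$t[s]
  d <- (end - start) / sqrt(sum((end - start)^2))
  while (hi - lo > tol_mm) {
    mid <- (lo + hi) / 2
    if (r_trilinear(arr, spacing, origin,
                    matrix(start + mid * d, 1)) >= 0.5) hi <- mid
    else lo <- mid
  }
  list(point = start + hi * d, t = hi)
}

# Brute-force sub-volume reconstruction of the H4 shell around the tumor:
# voxel is in the shell iff its center lies within `margin` of some tumor
# voxel center (exhaustive minimum) and carries no lung/tumor label.
r_h4_submask <- function(volume, tumor_w, lung_labels, margin) {
  dmv <- dim(volume$labels)
  lo_w <- apply(tumor_w, 2, min) - margin - 2 * volume$spacing
  hi_w <- apply(tumor_w, 2, max) + margin + 2 * volume$spacing
  lo <- pmax(floor((lo_w - volume$origin) / volume$spacing), 0)
  hi <- pmin(ceiling((hi_w - volume$origin) / volume$spacing), dmv - 1)
  rng <- lapply(1:3, function(a) lo[a]:hi[a])
  grid <- as.matrix(expand.grid(rng[[1]], rng[[2]], rng[[3]]))
  w <- world_from_index(volume, grid)
  dmin <- rep(Inf, nrow(w))
  for (q in seq_len(nrow(tumor_w))) {
    dq <- sqrt((w[, 1] - tumor_w[q, 1])^2 + (w[, 2] - tumor_w[q, 2])^2 +
                 (w[, 3] - tumor_w[q, 3])^2)
    dmin <- pmin(dmin, dq)
  }
  lin <- grid[, 1] + grid[, 2] * dmv[1] + grid[, 3] * dmv[1] * dmv[2] + 1
  shell <- dmin <= margin & !(volume$labels[lin] %in% lung_labels)
  list(arr = array(as.numeric(shell), vapply(rng, length, 1L)),
       origin = volume$origin + lo * volume$spacing,
       spacing = volume$spacing)
}

# Local-patch surface normal: smooth a small neighborhood of the mask in R
# and take central differences (independent of the planner's volume-wide
# smoothed-gradient normals).
r_patch_normal <- function(volume, label_set, point, halfwidth = 5L) {
  ctr <- as.integer(index_from_world(volume, point))
  dmv <- dim(volume$labels)
  rng <- lapply(1:3, function(a) {
    max(0L, ctr[a] - halfwidth):min(dmv[a] - 1L, ctr[a] + halfwidth)
  })
  patch <- array(as.numeric(
    volume$labels[rng[[1]] + 1L, rng[[2]] + 1L, rng[[3]] + 1L] %in%
      label_set), vapply(rng, length, 1L))
  g <- seq(-3, 3)
  kern <- exp(-0.5 * g^2)
  kern <- kern / sum(kern)
  conv1 <- function(a, axis) {
    out <- array(0, dim(a))
    nl <- dim(a)[axis]
    for (t in seq_along(g)) {
      sh <- pmin(pmax(seq_len(nl) + g[t], 1L), nl)
      out <- out + kern[t] * switch(axis,
        a[sh, , , drop = FALSE], a[, sh, , drop = FALSE],
        a[, , sh, drop = FALSE])
    }
    out
  }
  sm <- conv1(conv1(conv1(patch, 1L), 2L), 3L)
  loc <- ctr - c(rng[[1]][1], rng[[2]][1], rng[[3]][1]) + 1L
  grad <- numeric(3)
  for (a in 1:3) {
    ip <- im <- loc
    ip[a] <- min(ip[a] + 1L, dim(sm)[a])
    im[a] <- max(im[a] - 1L, 1L)
    grad[a] <- (sm[ip[1], ip[2], ip[3]] - sm[im[1], im[2], im[3]]) /
      ((ip[a] - im[a]) * volume$spacing[a])
  }
  nn <- sqrt(sum(grad^2))
  if (nn < 1e-9) return(c(NA_real_, NA_real_, NA_real_))
  -grad / nn
}

#' Independently re-verify planned paths against the hard constraints
#'
#' Re-traces every returned path with a separate, pure-R segment tracer that
#' shares no code with the planner's classification, re-checks H1-H4, and
#' evaluates the three excellence criteria (risk distance > 10 mm, length
#' < 100 mm, entry angle > 70 degrees). H4 is re-checked by brute-force
#' nearest-tumor-voxel distances rather than the planner's distance
#' transform.
#'
#' @param plan a `plan_result`.
#' @param scene the `anatomy_scene` the plan was computed on.
#' @param config the `plan_config` used (defaults to the one stored in the
#'   plan).
#' @return an object of class `run_report`: list with `paths` (per-path
#'   pass/fail and excellence flags), `pass_rate`, `excellent_rate` (fraction
#'   of paths meeting all three excellence criteria) and per-criterion
#'   excellence rates.
#' @export
verify_plan <- function(plan, scene, config = plan$config) {
  stopifnot(inherits(plan, "plan_result"))
  if (!identical(scene_checksum(scene), plan$scene_checksum)) {
    stop("scene does not match the one the plan was computed on")
  }
  if (plan$status != "ok" || nrow(plan$paths) == 0L) {
    stop("plan contains no paths to verify")
  }
  vol <- scene$volume
  step <- min(vol$spacing) / 4
  risk <- role_labels(scene, scene$risk_roles)
  skin <- role_labels(scene, "skin")
  lobe <- role_labels(scene, c("lung_target_lobe", "tumor"))
  lungish <- role_labels(scene, c("lung_target_lobe", "lung_other", "tumor"))
  tum_idx <- which(array(vol$labels %in% role_labels(scene, "tumor"),
                         dim(vol$labels)), arr.ind = TRUE) - 1L
  tum_w <- world_from_index(vol, tum_idx)
  risk_idx <- which(array(vol$labels %in% risk, dim(vol$labels)),
                    arr.ind = TRUE) - 1L
  risk_w <- world_from_index(vol, risk_idx)
  margin <- config$ablation_margin_mm + config$depth_margin_mm
  risk_arr <- array(as.numeric(vol$labels %in% risk), dim(vol$labels))
  skin_arr <- array(as.numeric(vol$labels %in% skin), dim(vol$labels))
  lobe_arr <- array(as.numeric(vol$labels %in% lobe), dim(vol$labels))
  h4sub <- if (nrow(tum_w)) r_h4_submask(vol, tum_w, lungish, margin) else
    NULL

  res <- lapply(seq_len(nrow(plan$paths)), function(r) {
    p <- plan$paths[r, ]
    I <- c(p$Ix, p$Iy, p$Iz)
    C <- c(p$Cx, p$Cy, p$Cz)
    sg <- r_seg_points(I, C, step)
    h1_pass <- length(risk) == 0L ||
      max(r_trilinear(risk_arr, vol$spacing, vol$origin, sg$pts)) < 0.5
    ec <- r_first_iso(skin_arr, vol$spacing, vol$origin, I, C, step)
    if (is.null(ec)) {
      return(data.frame(rank = p$rank, h1_pass = h1_pass, h2_pass = FALSE,
                        h3_pass = FALSE, h4_pass = FALSE, qualified = FALSE,
                        l_mm = NA_real_, alpha_deg = NA_real_,
                        d_mm = NA_real_, exc_distance = FALSE,
                        exc_length = FALSE, exc_angle = FALSE))
    }
    l_v <- sqrt(sum((ec$point - C)^2))
    h2_pass <- l_v < config$needle_length_mm
    pc <- r_first_iso(lobe_arr, vol$spacing, vol$origin, ec$point, C, step)
    if (is.null(pc)) {
      h1_pass <- FALSE
      alpha_v <- NA_real_
      h3_pass <- FALSE
    } else {
      nrm <- r_patch_normal(vol, lobe, pc$point)
      alpha_v <- if (any(is.na(nrm))) 0 else
        path_surface_angle(C - ec$point, nrm)
      h3_pass <- alpha_v > config$angle_threshold_deg
    }
    # H4: brute-force shell reconstruction around the tumor
    h4_pass <- TRUE
    if (!is.null(h4sub) && any(h4sub$arr > 0)) {
      vals <- r_trilinear(h4sub$arr, h4sub$spacing, h4sub$origin, sg$pts)
      # points outside the sub-volume clamp onto its zero-valued border
      h4_pass <- max(vals) < 0.5
    }
    # excellence: brute-force minimum distance to risk voxel centers over
    # the percutaneous portion
    d_v <- Inf
    if (nrow(risk_w)) {
      inb <- which(sg$t >= ec$t)
      for (q in inb) {
        dq <- sqrt(min((risk_w[, 1] - sg$pts[q, 1])^2 +
                         (risk_w[, 2] - sg$pts[q, 2])^2 +
                         (risk_w[, 3] - sg$pts[q, 3])^2))
        if (dq < d_v) d_v <- dq
      }
    }
    data.frame(rank = p$rank, h1_pass = h1_pass, h2_pass = h2_pass,
               h3_pass = h3_pass, h4_pass = h4_pass,
               qualified = h1_pass && h2_pass && h3_pass && h4_pass,
               l_mm = l_v, alpha_deg = alpha_v, d_mm = d_v,
               exc_distance = is.finite(d_v) && d_v > 10,
               exc_length = l_v < 100,
               exc_angle = !is.na(alpha_v) && alpha_v > 70)
  })
  paths <- do.call(rbind, res)
  structure(list(
    paths = paths,
    pass_rate = mean(paths$qualified),
    excellent_rate = mean(paths$exc_distance & paths$exc_length &
                            paths$exc_angle),
    excellence_rates = c(distance = mean(paths$exc_distance),
                         length = mean(paths$exc_length),
                         angle = mean(paths$exc_angle))),
    class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report> pass rate:", sprintf("%.1f%%", 100 * x$pass_rate),
      "| excellent rate:", sprintf("%.1f%%", 100 * x$excellent_rate), "\n")
  print(x$paths, digits = 4)
  invisible(x)
}

# ---------------------------------------------------------------------------
# Serialization
# ---------------------------------------------------------------------------

#' Write a plan result to JSON
#'
#' Deterministic: identical plans serialize to byte-identical files.
#'
#' @param plan a `plan_result`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_plan_json <- function(plan, path) {
  obj <- list(
    status = plan$status,
    target = plan$C,
    counts = plan$counts,
    fallback = plan$fallback,
    extrema = plan$extrema,
    scene_checksum = plan$scene_checksum,
    config = unclass(plan$config),
    paths = plan$paths)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", null = "null", pretty = TRUE)
  invisible(path)
}

#' Export per-face grayscale constraint maps as 16-bit TIFF
#'
#' Writes one image per face for the chosen per-cell quantity (feasibility or
#' a normalized soft-constraint score), plus a JSON sidecar holding the
#' normalization extrema and the grid-to-world binding. Values are scaled to
#' the full 16-bit range; infeasible or unassigned cells are 0.
#'
#' @param plan a `plan_result` (from [plan_paths()]).
#' @param what one of `"feasible"`, `"R"`, `"L"`, `"A"`.
#' @param out_dir output directory.
#' @return character vector of written files, invisibly.
#' @export
write_face_maps <- function(plan, what = c("feasible", "R", "L", "A"),
                            out_dir) {
  what <- match.arg(what)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cells <- plan$cells
  vals <- if (what == "feasible") as.numeric(cells$feasible) else
    ifelse(is.na(cells[[what]]), 0, cells[[what]])
  files <- character(0)
  for (f in levels(cells$face)) {
    sub <- cells[cells$face == f, ]
    if (!nrow(sub)) next
    ax <- switch(f, "x-" = , "x+" = c("j", "k"), "y-" = , "y+" = c("i", "k"),
                 c("i", "j"))
    u <- sub[[ax[1]]]; v <- sub[[ax[2]]]
    img <- matrix(0, max(u) - min(u) + 1, max(v) - min(v) + 1)
    img[cbind(u - min(u) + 1, v - min(v) + 1)] <- vals[cells$face == f]
    fn <- file.path(out_dir, paste0("facemap_", what, "_",
                                    gsub("[+]", "p", gsub("-", "m", f)),
                                    ".tif"))
    tiff::writeTIFF(t(img[, ncol(img):1, drop = FALSE]), fn,
                    bits.per.sample = 16L)
    files <- c(files, fn)
  }
  sidecar <- file.path(out_dir, paste0("facemap_", what, ".json"))
  jsonlite::write_json(list(
    quantity = what, extrema = plan$extrema, target = plan$C,
    convention = paste("pixel (u,v) of face F holds the cell at the",
                       "0-based boundary voxel index shown; world point =",
                       "origin + index*spacing")), sidecar,
    auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null")
  invisible(c(files, sidecar))
}

#' Export planned paths as VTK legacy polydata polylines
#'
#' One polyline per planned path (insertion point to target), viewable in
#' ParaView/3D Slicer alongside the exported volumes.
#'
#' @param plan a `plan_result` with status `"ok"`.
#' @param path output `.vtk` path.
#' @return `path`, invisibly.
#' @export
write_vtk_paths <- function(plan, path) {
  stopifnot(plan$status == "ok", nrow(plan$paths) > 0)
  p <- plan$paths
  npts <- 2L * nrow(p)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "needleplan planned trajectories", "ASCII",
               "DATASET POLYDATA", paste("POINTS", npts, "float")), con)
  for (r in seq_len(nrow(p))) {
    writeLines(c(paste(p$Ix[r], p$Iy[r], p$Iz[r]),
                 paste(p$Cx[r], p$Cy[r], p$Cz[r])), con)
  }
  writeLines(paste("LINES", nrow(p), 3L * nrow(p)), con)
  for (r in seq_len(nrow(p))) {
    writeLines(paste(2L, 2L * (r - 1L), 2L * r - 1L), con)
  }
  invisible(path)
}
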