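#' Synthetic thorax phantom specification
#'
#' Describes a deterministic analytic thorax scene: a body ellipsoid with a
#' skin shell, two lung ellipsoids, a mediastinal compartment, a heart
#' ellipsoid, branching bronchi and vessels as capsules (cylinders with
#' spherical caps), ribs as circular arc tubes that follow the body taper,
#' and a spherical tumor inside one lung. All primitives are analytic, so an
#' exact geometric occlusion oracle ([shadow_oracle()]) exists independently
#' of voxelization.
#'
#' Presets:
#' \describe{
#'   \item{default}{128^3 voxels at 2 mm: full structure set, 12 ribs,
#'     15 mm diameter tumor in the right lung.}
#'   \item{ribcage}{64^3 at 2 mm: body, lungs, ribs and tumor only; a fast
#'     multi-rib scene for occlusion tests.}
#'   \item{ribarc}{128^3 at 2 mm: adult-scale body and lungs with a single
#'     anatomically thick rib arc; the oracle-equivalence scene on which
#'     voxelized occlusion is compared with the analytic shadow oracle.}
#'   \item{mini}{48^3 at 2 mm: full structure set at reduced scale, for fast
#'     end-to-end runs.}
#' }
#'
#' @param preset one of `"default"`, `"ribcage"`, `"mini"`.
#' @param ... named top-level fields replacing the preset's (e.g.
#'   `tumor = list(center = c(160,124,132), radius = 7.5)`, `ribs = NULL`,
#'   `vessels = list()`).
#' @param seed integer seed for the optional tumor-position jitter.
#' @param jitter_mm half-width (mm) of the uniform jitter applied to the
#'   tumor center; 0 (default) disables jitter.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(preset = c("default", "ribcage", "ribarc", "mini"),
                         ..., seed = 0L, jitter_mm = 0) {
  preset <- match.arg(preset)
  spec <- switch(preset,
    default = list(
      shape = c(128L, 128L, 128L), spacing = c(2, 2, 2),
      body = list(center = c(127, 127, 127), half = c(92, 72, 115),
                  shell = 4),
      mediastinum = list(center = c(127, 127, 117), half = c(9, 34, 80)),
      lungs = list(offset_mm = 33, half = c(23, 36, 76)),
      heart = list(center = c(127, 141, 100), half = c(26, 26, 32)),
      bronchi = list(
        list(a = c(127, 117, 150), b = c(127, 117, 225), r = 8),
        list(a = c(127, 117, 155), b = c(108, 120, 144), r = 5),
        list(a = c(127, 117, 155), b = c(146, 120, 144), r = 5)),
      vessels = list(
        list(a = c(111, 135, 105), b = c(84, 135, 118), r = 4.5),
        list(a = c(143, 135, 105), b = c(170, 135, 118), r = 4.5)),
      ribs = list(count = 12L, z0_mm = 60, dz_mm = 12, tube_mm = 4,
                  ring_frac = 0.90, gap_deg = c(60, 120)),
      tumor = list(center = c(160, 124, 132), radius = 7.5)),
    ribcage = list(
      shape = c(64L, 64L, 64L), spacing = c(2, 2, 2),
      body = list(center = c(63, 63, 63), half = c(46, 36, 57), shell = 3),
      mediastinum = NULL,
      lungs = list(offset_mm = 14.5, half = c(8.5, 16, 34)),
      heart = NULL, bronchi = NULL, vessels = NULL,
      ribs = list(count = 5L, z0_mm = 41, dz_mm = 11, tube_mm = 4,
                  ring_frac = 0.85, gap_deg = c(60, 120)),
      tumor = list(center = c(78, 62, 65), radius = 4)),
    ribarc = list(
      shape = c(128L, 128L, 128L), spacing = c(2, 2, 2),
      body = list(center = c(127, 127, 127), half = c(92, 72, 115),
                  shell = 4),
      mediastinum = NULL,
      lungs = list(offset_mm = 32, half = c(20, 36, 76)),
      heart = NULL, bronchi = NULL, vessels = NULL,
      ribs = list(count = 1L, z0_mm = 100, dz_mm = 18, tube_mm = 6,
                  ring_frac = 0.8824, gap_deg = c(60, 120)),
      tumor = list(center = c(159, 124, 132), radius = 5)),
    mini = list(
      shape = c(48L, 48L, 48L), spacing = c(2, 2, 2),
      body = list(center = c(47, 47, 47), half = c(34, 27, 42), shell = 3),
      mediastinum = list(center = c(47, 47, 43), half = c(3.5, 12, 28)),
      lungs = list(offset_mm = 11.5, half = c(7, 13, 28)),
      heart = list(center = c(47, 52, 37), half = c(9, 9, 11)),
      bronchi = list(
        list(a = c(47, 43, 55), b = c(47, 43, 80), r = 3),
        list(a = c(47, 43, 57), b = c(40, 45, 51), r = 2),
        list(a = c(47, 43, 57), b = c(54, 45, 51), r = 2)),
      vessels = list(
        list(a = c(41, 50, 39), b = c(33, 50, 44), r = 1.6),
        list(a = c(53, 50, 39), b = c(61, 50, 44), r = 1.6)),
      ribs = list(count = 6L, z0_mm = 22, dz_mm = 9, tube_mm = 2,
                  ring_frac = 0.88, gap_deg = c(60, 120)),
      tumor = list(center = c(59, 46, 49), radius = 3))
  )
  mods <- list(...)
  for (nm in names(mods)) spec[nm] <- mods[nm]  # keeps explicit NULLs
  spec$seed <- as.integer(seed)
  spec$jitter_mm <- jitter_mm
  class(spec) <- "phantom_spec"
  validate_phantom_spec(effective_spec(spec))
  spec
}

# Applies the seeded tumor jitter; everything downstream (rasterizer, oracle,
# centroid) works from the effective spec so the two stay consistent.
effective_spec <- function(spec) {
  if (spec$jitter_mm > 0) {
    old <- if (exists(".Random.seed", .GlobalEnv))
      get(".Random.seed", .GlobalEnv) else NULL
    set.seed(spec$seed)
    jit <- runif(3, -spec$jitter_mm, spec$jitter_mm)
    if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv) else
      rm(".Random.seed", envir = .GlobalEnv)
    spec$tumor$center <- spec$tumor$center + jit
  }
  spec
}

lung_centers <- function(spec) {
  off <- c(spec$lungs$offset_mm, 0, 0)
  list(left = spec$body$center - off, right = spec$body$center + off)
}

rib_rings <- function(spec) {
  if (is.null(spec$ribs) || spec$ribs$count == 0L) return(list())
  rb <- spec$ribs
  inner_y <- min(spec$body$half[1], spec$body$half[2]) - spec$body$shell
  inner_z <- spec$body$half[3] - spec$body$shell
  cz <- spec$body$center[3]
  lapply(seq_len(rb$count), function(k) {
    z <- rb$z0_mm + (k - 1) * rb$dz_mm
    sc <- sqrt(max(0, 1 - ((z - cz) / inner_z)^2))
    list(z = z, ring = rb$ring_frac * inner_y * sc, tube = rb$tube_mm,
         center = spec$body$center[1:2], gap_deg = rb$gap_deg)
  })
}

# Conservative test that a sphere lies fully inside an ellipsoid.
sphere_in_ellipsoid <- function(scenter, sradius, ecenter, ehalf) {
  f <- sum(((scenter - ecenter) / ehalf)^2)
  f < 1 && sradius <= (1 - sqrt(f)) * min(ehalf)
}

validate_phantom_spec <- function(spec) {
  stopifnot(length(spec$shape) == 3L, all(spec$shape >= 3),
            all(spec$spacing > 0))
  extent <- (spec$shape - 1) * spec$spacing
  if (any(spec$body$center + spec$body$half > extent) ||
      any(spec$body$center - spec$body$half < 0)) {
    stop("body ellipsoid must fit inside the volume")
  }
  lc <- lung_centers(spec)
  tu <- spec$tumor
  in_left <- sphere_in_ellipsoid(tu$center, tu$radius, lc$left,
                                 spec$lungs$half)
  in_right <- sphere_in_ellipsoid(tu$center, tu$radius, lc$right,
                                  spec$lungs$half)
  if (!in_left && !in_right) {
    stop("tumor sphere must lie fully inside one lung ellipsoid")
  }
  for (ring in rib_rings(spec)) {
    inner_y <- min(spec$body$half[1], spec$body$half[2]) - spec$body$shell
    inner_z <- spec$body$half[3] - spec$body$shell
    sc <- sqrt(max(0, 1 - ((ring$z - spec$body$center[3]) / inner_z)^2))
    if (ring$ring + ring$tube > inner_y * sc + 1e-6) {
      stop("rib at z=", ring$z, " extends into the skin shell")
    }
  }
  invisible(TRUE)
}

# label ids used by the rasterizer
.phantom_labels <- c(skin = 1L, interior = 2L, mediastinum = 3L,
                     lung_left = 4L, lung_right = 5L, heart = 6L,
                     bronchi = 7L, vessels = 8L, bone = 9L, tumor = 10L)

ellipsoid_mask <- function(xs, ys, zs, center, half) {
  e1 <- ((xs - center[1]) / half[1])^2
  e2 <- ((ys - center[2]) / half[2])^2
  e3 <- ((zs - center[3]) / half[3])^2
  outer(outer(e1, e2, "+"), e3, "+") <= 1
}

paint_capsule <- function(labels, xs, ys, zs, cap, value) {
  lo <- pmin(cap$a, cap$b) - cap$r
  hi <- pmax(cap$a, cap$b) + cap$r
  ii <- which(xs >= lo[1] & xs <= hi[1])
  jj <- which(ys >= lo[2] & ys <= hi[2])
  kk <- which(zs >= lo[3] & zs <= hi[3])
  if (!length(ii) || !length(jj) || !length(kk)) return(labels)
  X <- array(xs[ii], c(length(ii), length(jj), length(kk)))
  Y <- array(rep(ys[jj], each = length(ii)),
             c(length(ii), length(jj), length(kk)))
  Z <- array(rep(zs[kk], each = length(ii) * length(jj)),
             c(length(ii), length(jj), length(kk)))
  d <- cap$b - cap$a
  dd <- max(sum(d^2), 1e-12)
  t <- ((X - cap$a[1]) * d[1] + (Y - cap$a[2]) * d[2] +
          (Z - cap$a[3]) * d[3]) / dd
  t <- pmin(pmax(t, 0), 1)
  dist2 <- (X - cap$a[1] - t * d[1])^2 + (Y - cap$a[2] - t * d[2])^2 +
    (Z - cap$a[3] - t * d[3])^2
  sub <- labels[ii, jj, kk, drop = FALSE]
  sub[dist2 <= cap$r^2] <- value
  labels[ii, jj, kk] <- sub
  labels
}

theta_in_arc <- function(theta_deg, gap_deg) {
  !(theta_deg > gap_deg[1] & theta_deg < gap_deg[2])
}

paint_rib <- function(labels, xs, ys, zs, ring, value) {
  kk <- which(zs >= ring$z - ring$tube & zs <= ring$z + ring$tube)
  if (!length(kk)) return(labels)
  nx <- length(xs); ny <- length(ys); nk <- length(kk)
  X <- array(xs, c(nx, ny, nk))
  Y <- array(rep(ys, each = nx), c(nx, ny, nk))
  Z <- array(rep(zs[kk], each = nx * ny), c(nx, ny, nk))
  rx <- X - ring$center[1]
  ry <- Y - ring$center[2]
  rho <- sqrt(rx^2 + ry^2)
  theta <- (atan2(ry, rx) * 180 / pi) %% 360
  inarc <- theta_in_arc(theta, ring$gap_deg)
  d2 <- (rho - ring$ring)^2 + (Z - ring$z)^2
  hit <- inarc & d2 <= ring$tube^2
  # spherical caps at the arc ends
  for (ang in ring$gap_deg) {
    ex <- ring$center[1] + ring$ring * cos(ang * pi / 180)
    ey <- ring$center[2] + ring$ring * sin(ang * pi / 180)
    hit <- hit | ((X - ex)^2 + (Y - ey)^2 + (Z - ring$z)^2 <= ring$tube^2)
  }
  sub <- labels[, , kk, drop = FALSE]
  sub[hit] <- value
  labels[, , kk] <- sub
  labels
}

#' Generate a synthetic thorax scene from a phantom specification
#'
#' Rasterizes the analytic primitives onto the voxel grid (origin at 0,
#' voxel-center convention). Later structures overwrite earlier ones in the
#' fixed order body < mediastinum < lungs < heart < bronchi < vessels < ribs
#' < tumor, and roles are pre-bound for all structures present. Identical
#' spec and seed give bit-identical volumes.
#'
#' @param spec a [phantom_spec()].
#' @return an [anatomy_scene()]; the jitter-applied specification is attached
#'   as attribute `"spec_effective"`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  spec <- effective_spec(spec)
  validate_phantom_spec(spec)
  n <- spec$shape
  xs <- (0:(n[1] - 1)) * spec$spacing[1]
  ys <- (0:(n[2] - 1)) * spec$spacing[2]
  zs <- (0:(n[3] - 1)) * spec$spacing[3]
  L <- .phantom_labels
  labels <- array(0L, n)
  labels[ellipsoid_mask(xs, ys, zs, spec$body$center, spec$body$half)] <-
    L[["skin"]]
  labels[ellipsoid_mask(xs, ys, zs, spec$body$center,
                        spec$body$half - spec$body$shell)] <- L[["interior"]]
  if (!is.null(spec$mediastinum)) {
    labels[ellipsoid_mask(xs, ys, zs, spec$mediastinum$center,
                          spec$mediastinum$half)] <- L[["mediastinum"]]
  }
  lc <- lung_centers(spec)
  labels[ellipsoid_mask(xs, ys, zs, lc$left, spec$lungs$half)] <-
    L[["lung_left"]]
  labels[ellipsoid_mask(xs, ys, zs, lc$right, spec$lungs$half)] <-
    L[["lung_right"]]
  if (!is.null(spec$heart)) {
    labels[ellipsoid_mask(xs, ys, zs, spec$heart$center, spec$heart$half)] <-
      L[["heart"]]
  }
  for (cap in spec$bronchi) {
    labels <- paint_capsule(labels, xs, ys, zs, cap, L[["bronchi"]])
  }
  for (cap in spec$vessels) {
    labels <- paint_capsule(labels, xs, ys, zs, cap, L[["vessels"]])
  }
  for (ring in rib_rings(spec)) {
    labels <- paint_rib(labels, xs, ys, zs, ring, L[["bone"]])
  }
  tu <- spec$tumor
  tcap <- list(a = tu$center, b = tu$center, r = tu$radius)
  labels <- paint_capsule(labels, xs, ys, zs, tcap, L[["tumor"]])

  vol <- labeled_volume(labels, spacing = spec$spacing, origin = c(0, 0, 0))
  tumor_right <- sphere_in_ellipsoid(tu$center, tu$radius, lc$right,
                                     spec$lungs$half)
  target <- if (tumor_right) L[["lung_right"]] else L[["lung_left"]]
  other <- if (tumor_right) L[["lung_left"]] else L[["lung_right"]]
  roles <- list(skin = L[["skin"]], lung_target_lobe = target,
                lung_other = other, tumor = L[["tumor"]])
  if (!is.null(spec$mediastinum)) roles$mediastinum <- L[["mediastinum"]]
  if (!is.null(spec$heart)) roles$heart <- L[["heart"]]
  if (length(spec$bronchi)) roles$bronchi <- L[["bronchi"]]
  if (length(spec$vessels)) roles$vessels <- L[["vessels"]]
  if (!is.null(spec$ribs) && spec$ribs$count > 0L) roles$bone <- L[["bone"]]
  roles <- lapply(roles, function(l) {
    l[l %in% as.integer(sort(unique(as.vector(labels))))]
  })
  roles <- roles[vapply(roles, length, 1L) > 0]
  scene <- anatomy_scene(vol, roles)
  attr(scene, "spec_effective") <- spec
  scene
}

# Risk primitives of a phantom spec (for the analytic occlusion oracle):
# everything a trajectory must avoid, i.e. all structures bound to the
# default risk roles, expressed analytically.
risk_primitives <- function(spec) {
  spec <- effective_spec(spec)
  prim <- list()
  add <- function(p) prim[[length(prim) + 1]] <<- p
  lc <- lung_centers(spec)
  tumor_right <- sphere_in_ellipsoid(spec$tumor$center, spec$tumor$radius,
                                     lc$right, spec$lungs$half)
  other_center <- if (tumor_right) lc$left else lc$right
  add(list(type = "ellipsoid", center = other_center, half = spec$lungs$half))
  if (!is.null(spec$mediastinum)) {
    add(list(type = "ellipsoid", center = spec$mediastinum$center,
             half = spec$mediastinum$half))
  }
  if (!is.null(spec$heart)) {
    add(list(type = "ellipsoid", center = spec$heart$center,
             half = spec$heart$half))
  }
  for (cap in c(spec$bronchi, spec$vessels)) add(c(list(type = "capsule"), cap))
  for (ring in rib_rings(spec)) add(c(list(type = "rib"), ring))
  prim
}

prim_bounding_sphere <- function(p) {
  switch(p$type,
    ellipsoid = list(center = p$center, r = max(p$half)),
    capsule = list(center = (p$a + p$b) / 2,
                   r = sqrt(sum((p$b - p$a)^2)) / 2 + p$r),
    rib = list(center = c(p$center, p$z), r = p$ring + p$tube))
}

# membership of points (n x 3) in a primitive
prim_member <- function(p, pts) {
  if (p$type == "ellipsoid") {
    return(((pts[, 1] - p$center[1]) / p$half[1])^2 +
             ((pts[, 2] - p$center[2]) / p$half[2])^2 +
             ((pts[, 3] - p$center[3]) / p$half[3])^2 <= 1)
  }
  if (p$type == "capsule") {
    d <- p$b - p$a
    dd <- max(sum(d^2), 1e-12)
    t <- ((pts[, 1] - p$a[1]) * d[1] + (pts[, 2] - p$a[2]) * d[2] +
            (pts[, 3] - p$a[3]) * d[3]) / dd
    t <- pmin(pmax(t, 0), 1)
    return((pts[, 1] - p$a[1] - t * d[1])^2 +
             (pts[, 2] - p$a[2] - t * d[2])^2 +
             (pts[, 3] - p$a[3] - t * d[3])^2 <= p$r^2)
  }
  # rib arc tube
  rx <- pts[, 1] - p$center[1]
  ry <- pts[, 2] - p$center[2]
  rho <- sqrt(rx^2 + ry^2)
  theta <- (atan2(ry, rx) * 180 / pi) %% 360
  hit <- theta_in_arc(theta, p$gap_deg) &
    (rho - p$ring)^2 + (pts[, 3] - p$z)^2 <= p$tube^2
  for (ang in p$gap_deg) {
    ex <- p$center[1] + p$ring * cos(ang * pi / 180)
    ey <- p$center[2] + p$ring * sin(ang * pi / 180)
    hit <- hit | ((pts[, 1] - ex)^2 + (pts[, 2] - ey)^2 +
                    (pts[, 3] - p$z)^2 <= p$tube^2)
  }
  hit
}

#' Analytic occlusion oracle for a phantom
#'
#' For each candidate insertion point I, reports whether the segment from I
#' to the target C intersects any analytic risk primitive of the phantom
#' (other lung, mediastinum, heart, bronchi, vessels, ribs). Computed from
#' closed-form point-primitive membership sampled at `step_mm` (default
#' 0.1 mm) inside analytically clipped per-primitive intervals, entirely
#' independent of any voxelization.
#'
#' @param spec a [phantom_spec()].
#' @param C target world point; default is the analytic tumor center (after
#'   jitter).
#' @param cells matrix (n x 3) of insertion points; default is every boundary
#'   voxel center of the phantom grid, in the same order as
#'   [build_face_maps()].
#' @param step_mm sampling step inside each candidate interval.
#' @return logical vector: `TRUE` where the sight line is occluded.
#' @export
shadow_oracle <- function(spec, C = NULL, cells = NULL, step_mm = 0.1) {
  stopifnot(inherits(spec, "phantom_spec"))
  eff <- effective_spec(spec)
  if (is.null(C)) C <- eff$tumor$center
  if (is.null(cells)) {
    cells <- as.matrix(boundary_cells(eff$shape, eff$spacing,
                                      c(0, 0, 0))[, c("Ix", "Iy", "Iz")])
  }
  cells <- matrix(as.numeric(cells), ncol = 3)
  n <- nrow(cells)
  occluded <- rep(FALSE, n)
  D <- sweep(-cells, 2, C, "+")          # C - I
  len <- sqrt(rowSums(D^2))
  Du <- D / pmax(len, 1e-12)
  for (p in risk_primitives(eff)) {
    bs <- prim_bounding_sphere(p)
    act <- which(!occluded)
    if (!length(act)) break
    oc <- sweep(cells[act, , drop = FALSE], 2, bs$center, "-")
    b <- rowSums(oc * Du[act, , drop = FALSE])
    cc <- rowSums(oc^2) - bs$r^2
    disc <- b^2 - cc
    has <- disc > 0
    if (!any(has)) next
    sq <- sqrt(disc[has])
    t0 <- pmax(-b[has] - sq, 0)
    t1 <- pmin(-b[has] + sq, len[act][has])
    ok <- t1 > t0
    act <- act[has][ok]
    t0 <- t0[ok]; t1 <- t1[ok]
    if (!length(act)) next
    nstep <- ceiling((t1 - t0) / step_mm)
    alive <- seq_along(act)
    s <- 0
    while (length(alive)) {
      tt <- pmin(t0[alive] + s * step_mm, t1[alive])
      idx <- act[alive]
      pts <- cells[idx, , drop = FALSE] + Du[idx, , drop = FALSE] * tt
      hit <- prim_member(p, pts)
      occluded[idx[hit]] <- TRUE
      alive <- alive[!hit & s < nstep[alive]]
      s <- s + 1
    }
  }
  occluded
}

#' Write a phantom to disk (volume, roles, spec)
#'
#' @param spec a [phantom_spec()].
#' @param out_dir output directory (created if needed).
#' @return named character vector of the three file paths, invisibly.
#' @export
write_phantom <- function(spec, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  scene <- generate_phantom(spec)
  vol_path <- file.path(out_dir, "phantom.nii.gz")
  roles_path <- file.path(out_dir, "roles.json")
  spec_path <- file.path(out_dir, "phantom_spec.json")
  write_volume(scene$volume, vol_path)
  write_roles(scene, roles_path)
  jsonlite::write_json(unclass(attr(scene, "spec_effective")), spec_path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(c(volume = vol_path, roles = roles_path, spec = spec_path))
}
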