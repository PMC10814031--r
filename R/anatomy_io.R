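#' Labeled volume container
#'
#' A 3D integer label map with voxel spacing and world origin. Voxel indices
#' are 0-based; the world coordinate of voxel `(i,j,k)` is
#' `origin + c(i,j,k) * spacing` (voxel-center convention, mm). Label 0 is
#' background/air.
#'
#' @param labels 3D integer array of non-negative labels (each dim >= 3).
#' @param spacing numeric length-3, mm per voxel, all > 0.
#' @param origin numeric length-3, world position (mm) of the center of voxel
#'   (0,0,0).
#' @return An object of class `labeled_volume`.
#' @export
labeled_volume <- function(labels, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (length(dim(labels)) != 3L) stop("labels must be a 3D array")
  if (any(dim(labels) < 3L)) stop("each volume dimension must be >= 3")
  if (length(spacing) != 3L || any(spacing <= 0)) {
    stop("spacing must be 3 positive reals")
  }
  if (length(origin) != 3L) stop("origin must have length 3")
  if (any(labels != round(labels)) || any(labels < 0)) {
    stop("labels must be non-negative integers")
  }
  storage.mode(labels) <- "integer"
  structure(
    list(labels = labels, spacing = as.numeric(spacing),
         origin = as.numeric(origin)),
    class = "labeled_volume"
  )
}

#' @export
print.labeled_volume <- function(x, ...) {
  cat("<labeled_volume> ", paste(dim(x$labels), collapse = " x "),
      " voxels, spacing ", paste(x$spacing, collapse = "/"),
      " mm, labels: ", paste(sort(unique(as.vector(x$labels))),
                             collapse = " "), "\n", sep = "")
  invisible(x)
}

#' World coordinates of 0-based voxel indices
#'
#' @param volume a `labeled_volume`.
#' @param ijk integer matrix (n x 3) or length-3 vector of 0-based indices.
#' @return numeric matrix (n x 3) of world points in mm.
#' @export
world_from_index <- function(volume, ijk) {
  ijk <- matrix(as.numeric(ijk), ncol = 3)
  sweep(sweep(ijk, 2, volume$spacing, "*"), 2, volume$origin, "+")
}

#' Nearest 0-based voxel index for world points
#'
#' @inheritParams world_from_index
#' @param xyz numeric matrix (n x 3) or length-3 vector of world points (mm).
#' @return integer matrix (n x 3) of 0-based indices, clamped to the grid.
#' @export
index_from_world <- function(volume, xyz) {
  xyz <- matrix(as.numeric(xyz), ncol = 3)
  idx <- round(sweep(sweep(xyz, 2, volume$origin, "-"), 2, volume$spacing,
                     "/"))
  dm <- dim(volume$labels)
  for (a in 1:3) idx[, a] <- pmin(pmax(idx[, a], 0), dm[a] - 1)
  storage.mode(idx) <- "integer"
  idx
}

.role_names <- c("skin", "lung_target_lobe", "lung_other", "tumor", "bone",
                 "heart", "vessels", "bronchi", "mediastinum")
.default_risk_roles <- c("bone", "bronchi", "vessels", "heart", "mediastinum",
                         "lung_other")
.mandatory_roles <- c("tumor", "skin", "lung_target_lobe")

#' Bind anatomical roles to a labeled volume
#'
#' Roles name the clinical meaning of label values. `tumor`, `skin` and
#' `lung_target_lobe` are mandatory. `risk_roles` lists the roles a trajectory
#' must not cross (hard constraint H1); it defaults to bone, bronchi, vessels,
#' heart, mediastinum and the non-target lung lobes, restricted to the roles
#' actually present.
#'
#' @param volume a [labeled_volume()].
#' @param roles named list mapping role names to integer label vectors. Valid
#'   role names: skin, lung_target_lobe, lung_other, tumor, bone, heart,
#'   vessels, bronchi, mediastinum.
#' @param risk_roles character vector of roles to avoid; default described
#'   above.
#' @return An object of class `anatomy_scene`.
#' @export
anatomy_scene <- function(volume, roles, risk_roles = NULL) {
  stopifnot(inherits(volume, "labeled_volume"))
  if (is.null(names(roles)) || any(names(roles) == "")) {
    stop("roles must be a named list")
  }
  unknown <- setdiff(names(roles), .role_names)
  if (length(unknown)) {
    stop("unknown role name(s): ", paste(unknown, collapse = ", "))
  }
  missing <- setdiff(.mandatory_roles, names(roles))
  if (length(missing)) {
    stop("missing mandatory role(s): ", paste(missing, collapse = ", "))
  }
  roles <- lapply(roles, function(v) as.integer(v))
  present <- sort(unique(as.vector(volume$labels)))
  for (r in names(roles)) {
    if (length(roles[[r]]) == 0L && r %in% .mandatory_roles) {
      stop("mandatory role '", r, "' has no labels")
    }
    absent <- setdiff(roles[[r]], present)
    if (length(absent)) {
      stop("role '", r, "' references label(s) absent from the volume: ",
           paste(absent, collapse = ", "))
    }
  }
  if (is.null(risk_roles)) {
    risk_roles <- intersect(.default_risk_roles, names(roles))
  } else {
    bad <- setdiff(risk_roles, names(roles))
    if (length(bad)) stop("risk role(s) not bound: ",
                          paste(bad, collapse = ", "))
  }
  structure(list(volume = volume, roles = roles,
                 risk_roles = as.character(risk_roles)),
            class = "anatomy_scene")
}

#' @export
print.anatomy_scene <- function(x, ...) {
  cat("<anatomy_scene> roles:", paste(names(x$roles), collapse = ", "), "\n")
  cat("  risk roles:", paste(x$risk_roles, collapse = ", "), "\n")
  print(x$volume)
  invisible(x)
}

#' All labels bound to a set of roles
#' @param scene an `anatomy_scene`.
#' @param roles character vector of role names (absent roles are ignored).
#' @return integer vector of labels.
#' @export
role_labels <- function(scene, roles) {
  as.integer(sort(unique(unlist(scene$roles[intersect(roles,
                                                      names(scene$roles))]))))
}

#' Read a labeled volume from NIfTI
#'
#' Spacing and origin are taken from the image header. Only axis-aligned
#' (identity-orientation) volumes with integer voxel values are accepted.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return a [labeled_volume()].
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) != 3L) stop("expected a 3D volume: ", path)
  if (any(arr != round(arr))) stop("non-integer voxel values in ", path)
  pix <- RNifti::pixdim(img)[1:3]
  xf <- RNifti::xform(img)
  rot <- xf[1:3, 1:3]
  ortho <- abs(rot) / pmax(sqrt(colSums(rot^2)), 1e-12)[col(rot)]
  if (max(abs(ortho - diag(3))) > 1e-3) {
    stop("oblique orientation matrices are not supported; ",
         "resample to axis-aligned first")
  }
  # NIfTI stores LPS->RAS sign flips in the xform; labels are geometry-free
  # here so the world frame is taken as index*spacing + origin with the
  # header's translation magnitudes.
  origin <- as.numeric(xf[1:3, 4])
  labeled_volume(round(arr), spacing = as.numeric(pix), origin = origin)
}

#' Write a labeled volume to NIfTI
#'
#' Round-trips exactly through [read_volume()]: shape, spacing, origin and
#' every voxel label are preserved.
#'
#' @param volume a [labeled_volume()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  arr <- volume$labels
  storage.mode(arr) <- "integer"
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- volume$spacing
  xf <- diag(4)
  diag(xf)[1:3] <- volume$spacing
  xf[1:3, 4] <- volume$origin
  RNifti::qform(img) <- structure(xf, code = 2L)
  RNifti::sform(img) <- structure(xf, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read an anatomy scene from a volume file plus a roles JSON file
#'
#' The roles file is a JSON object mapping role names to arrays of label
#' values, optionally with a `"risk_roles"` array of role names.
#'
#' @param volume_path NIfTI path (see [read_volume()]).
#' @param roles_path JSON path.
#' @return an [anatomy_scene()].
#' @export
read_scene <- function(volume_path, roles_path) {
  vol <- read_volume(volume_path)
  spec <- jsonlite::fromJSON(roles_path, simplifyVector = TRUE)
  risk <- NULL
  if (!is.null(spec$risk_roles)) {
    risk <- as.character(spec$risk_roles)
    spec$risk_roles <- NULL
  }
  roles <- lapply(spec, as.integer)
  anatomy_scene(vol, roles, risk_roles = risk)
}

#' Write the roles of a scene to JSON
#' @param scene an `anatomy_scene`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_roles <- function(scene, path) {
  obj <- c(scene$roles, list(risk_roles = scene$risk_roles))
  jsonlite::write_json(obj, path, auto_unbox = FALSE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Tumor centroid (target point) in world coordinates
#'
#' Unweighted mean of the world coordinates of all tumor voxel centers; this
#' is the target point every candidate trajectory aims at.
#'
#' @param scene an `anatomy_scene`.
#' @return numeric length-3 world point (mm).
#' @export
tumor_centroid <- function(scene) {
  labs <- role_labels(scene, "tumor")
  idx <- which(array(scene$volume$labels %in% labs,
                     dim(scene$volume$labels)), arr.ind = TRUE) - 1L
  if (nrow(idx) == 0L) stop("tumor mask is empty")
  colMeans(world_from_index(scene$volume, idx))
}

#' Planner configuration
#'
#' @param needle_length_mm usable needle shaft length (mm); the percutaneous
#'   path length must be strictly less than this. Default 150 mm, a typical
#'   microwave ablation antenna shaft length.
#' @param angle_threshold_deg minimum pleural entry angle (deg); paths with
#'   entry angle less than or equal to this fail hard constraint H3.
#'   Default 20.
#' @param depth_margin_mm minimum insertion depth into the lung (mm) demanded
#'   beyond the ablation zone, default 5.
#' @param ablation_margin_mm safety margin added around the tumor to form the
#'   expected ablation zone (mm), default 5.
#' @param weights numeric length-3 soft-constraint weights (risk distance,
#'   path length, entry angle). Renormalized to sum to 1 with a warning if
#'   needed. Default `c(1,1,1)/3`.
#' @param top_k number of ranked paths to return, default 5.
#' @param ray_step_mm sampling step along rays (mm); default (NULL) is half
#'   the smallest voxel spacing at planning time. Must not exceed the smallest
#'   spacing.
#' @param s1_full_ray logical; if TRUE the S1 minimum risk distance is taken
#'   over the whole insertion-point-to-target sight line instead of only the
#'   percutaneous (skin-to-target) portion. Default FALSE.
#' @param s3_printed_form logical; if TRUE the S3 normalization scores
#'   smaller entry angles higher (the inverted form); the default FALSE
#'   scores larger angles higher, matching the clinical goal.
#' @param product_form logical; if TRUE aggregate scores multiplicatively
#'   (`prod(s^w)`) instead of the default weighted sum. Sensitivity analysis
#'   only.
#' @return an object of class `plan_config`.
#' @export
plan_config <- function(needle_length_mm = 150, angle_threshold_deg = 20,
                        depth_margin_mm = 5, ablation_margin_mm = 5,
                        weights = c(1, 1, 1) / 3, top_k = 5,
                        ray_step_mm = NULL, s1_full_ray = FALSE,
                        s3_printed_form = FALSE, product_form = FALSE) {
  stopifnot(needle_length_mm > 0, depth_margin_mm > 0, ablation_margin_mm > 0,
            top_k >= 1)
  if (length(weights) != 3L || any(weights < 0) || sum(weights) <= 0) {
    stop("weights must be 3 non-negative reals with positive sum")
  }
  if (abs(sum(weights) - 1) > 1e-9) {
    warning("weights renormalized to sum to 1")
    weights <- weights / sum(weights)
  }
  if (!is.null(ray_step_mm) && ray_step_mm <= 0) {
    stop("ray_step_mm must be positive")
  }
  structure(list(needle_length_mm = needle_length_mm,
                 angle_threshold_deg = angle_threshold_deg,
                 depth_margin_mm = depth_margin_mm,
                 ablation_margin_mm = ablation_margin_mm,
                 weights = weights / sum(weights),
                 top_k = as.integer(top_k),
                 ray_step_mm = ray_step_mm,
                 s1_full_ray = isTRUE(s1_full_ray),
                 s3_printed_form = isTRUE(s3_printed_form),
                 product_form = isTRUE(product_form)),
            class = "plan_config")
}

#' Read a planner configuration from JSON
#' @param path JSON file whose keys are [plan_config()] arguments.
#' @return a `plan_config`.
#' @export
read_config <- function(path) {
  vals <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  ok <- intersect(names(vals), names(formals(plan_config)))
  do.call(plan_config, vals[ok])
}

# Effective ray step for a volume: configured value or half the min spacing.
effective_step <- function(config, volume) {
  st <- config$ray_step_mm
  if (is.null(st)) st <- min(volume$spacing) / 2
  if (st > min(volume$spacing)) {
    stop("ray_step_mm must not exceed the smallest voxel spacing")
  }
  st
}
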