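test_that("face maps enumerate every boundary voxel exactly once", {
  lab <- array(1L, c(4, 4, 4)); lab[2, 2, 2] <- 10L; lab[3, 3, 3] <- 4L
  sc <- anatomy_scene(labeled_volume(lab, spacing = c(1, 1, 1)),
                      list(skin = 1L, lung_target_lobe = 4L, tumor = 10L))
  fm <- build_face_maps(sc, C = c(1.5, 1.5, 1.5))
  expect_equal(nrow(fm$cells), 4^3 - 2^3)  # 56
  expect_false(any(duplicated(fm$cells[, c("i", "j", "k")])))

  for (dm in list(c(5L, 7L, 9L), c(12L, 9L, 7L))) {
    cells <- needleplan:::boundary_cells(dm, c(1, 1, 1), c(0, 0, 0))
    expect_equal(nrow(cells),
                 prod(dm) - prod(dm - 2L))
    expect_false(any(duplicated(cells[, c("i", "j", "k")])))
    # every enumerated voxel is on the boundary
    on_b <- cells$i %in% c(0, dm[1] - 1) | cells$j %in% c(0, dm[2] - 1) |
      cells$k %in% c(0, dm[3] - 1)
    expect_true(all(on_b))
  }
  # CT-scale bounding box: enumeration matches the counting formula
  big <- needleplan:::boundary_cells(c(512L, 512L, 300L), c(1, 1, 1),
                                     c(0, 0, 0))
  expect_equal(nrow(big), 512 * 512 * 300 - 510 * 510 * 298)

  expect_error(build_face_maps(sc, C = c(0, 1.5, 1.5)), "strictly inside")
})

test_that("H2 honors the strict needle-length boundary", {
  sc <- sphere_scene()
  C <- tumor_centroid(sc)
  I <- c(0, C[2], C[3])
  h2 <- check_h2(sc, I, C, needle_length_mm = 150)
  expect_false(h2$fail)
  # skin entry on a radius-36 sphere: percutaneous length 36 +/- 0.5 mm
  expect_equal(h2$l_mm, 36, tolerance = 0.5)
  expect_true(check_h2(sc, I, C, needle_length_mm = h2$l_mm)$fail)
  expect_false(check_h2(sc, I, C, needle_length_mm = h2$l_mm + 1e-6)$fail)
})

test_that("H3 honors the strict angle threshold and radial geometry", {
  sc <- sphere_scene()
  C <- tumor_centroid(sc)
  h2 <- check_h2(sc, c(0, C[2], C[3]), C, 150)
  h3 <- check_h3(sc, h2$E, C, angle_threshold_deg = 20)
  expect_false(h3$fail)
  expect_equal(h3$alpha_deg, 90, tolerance = 5)   # radial insertion
  # boundary equality fails
  expect_true(check_h3(sc, h2$E, C,
                       angle_threshold_deg = h3$alpha_deg)$fail)
})

test_that("H4 flags paths through the subpleural expansion shell", {
  # tumor close to the lung boundary: the expanded ablation zone pokes out
  sp <- phantom_spec("mini", tumor = list(center = c(62, 46, 48), radius = 3))
  sc <- generate_phantom(sp)
  C <- tumor_centroid(sc)
  mask <- needleplan:::h4_risk_mask(sc, 5, 5)
  expect_true(any(mask))
  # a path entering through the thin pleural side crosses the shell
  expect_true(check_h4(sc, c(94, C[2], C[3]), C, mask = mask))
  # deep tumor with small margins: the expansion stays inside the lung
  sc2 <- generate_phantom(phantom_spec("mini"))
  m2 <- needleplan:::h4_risk_mask(sc2, 1, 1)
  expect_false(any(m2))
  expect_false(check_h4(sc2, c(0, 47, 47), tumor_centroid(sc2), mask = m2))
})

test_that("hard-constraint integration is the elementwise OR complement", {
  set.seed(1)
  for (i in 1:5) {
    h <- replicate(4, runif(50) < 0.3, simplify = FALSE)
    feas <- integrate_hard(h[[1]], h[[2]], h[[3]], h[[4]])
    expect_identical(feas, !(h[[1]] | h[[2]] | h[[3]] | h[[4]]))
  }
})

test_that("soft-map normalization reproduces the endpoint arithmetic", {
  feas <- c(TRUE, TRUE, TRUE, FALSE)
  s1 <- soft_map_s1(c(2, 5, 8, 4), feas)
  expect_equal(s1$scores, c(0, 0.5, 1, NA))
  expect_equal(c(s1$min, s1$max), c(2, 8))
  s2 <- soft_map_s2(c(60, 80, 100, 70), feas)
  expect_equal(s2$scores, c(1, 0.5, 0, NA))
  s3 <- soft_map_s3(c(30, 60, 90, 45), feas)
  expect_equal(s3$scores, c(0, 0.5, 1, NA))
  # printed orientation inverts S3
  s3p <- soft_map_s3(c(30, 60, 90, 45), feas, printed_form = TRUE)
  expect_equal(s3p$scores, c(1, 0.5, 0, NA))
  # degenerate range: every feasible candidate satisfies equally
  sdeg <- soft_map_s1(c(3, 3, 3, 1), feas)
  expect_equal(sdeg$scores, c(1, 1, 1, NA))
})

test_that("adding risk voxels never converts an occluded cell to clear", {
  set.seed(21)
  sc <- generate_phantom(phantom_spec("mini"))
  C <- tumor_centroid(sc)
  occ0 <- occlusion_map(sc, C)
  lab <- sc$volume$labels
  interior <- which(lab == 2L)
  for (i in 1:8) {
    sc2 <- sc
    add <- sample(interior, 40)
    sc2$volume$labels[add] <- 9L  # extend the bone role
    if (!"bone" %in% names(sc2$roles)) sc2$roles$bone <- 9L
    occ1 <- occlusion_map(sc2, C)
    expect_true(all(occ1[occ0]))  # occluded stays occluded
  }
})

test_that("mirrored phantom yields a mirrored feasibility mask", {
  spL <- phantom_spec("mini", tumor = list(center = c(35, 46, 49),
                                           radius = 3))
  spR <- phantom_spec("mini", tumor = list(center = c(59, 46, 49),
                                           radius = 3))
  scL <- generate_phantom(spL)
  scR <- generate_phantom(spR)
  plL <- plan_paths(scL, plan_config())
  plR <- plan_paths(scR, plan_config())
  cl <- plL$cells
  cr <- plR$cells
  n1 <- dim(scL$volume$labels)[1]
  # mirror x index; face assignment may move between x-/x+ under the
  # dedup priority, so match cells by (i,j,k)
  key <- function(i, j, k) paste(i, j, k)
  mirL <- setNames(cl$feasible, key(n1 - 1L - cl$i, cl$j, cl$k))
  same <- mirL[key(cr$i, cr$j, cr$k)] == cr$feasible
  # identical up to a narrow band of boundary cells
  expect_gte(mean(same, na.rm = TRUE), 0.98)
})
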