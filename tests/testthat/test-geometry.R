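test_that("trace_segment reports slab crossings at the guaranteed density", {
  lab <- array(0L, c(40, 9, 9))     # 1 mm spacing, slab of label 3
  lab[11:20, , ] <- 3L              # x in [9.5, 19.5] mm
  vol <- labeled_volume(lab, spacing = c(1, 1, 1))
  tr <- trace_segment(vol, c(0, 4, 4), c(39, 4, 4), step_mm = 0.5)
  runs <- rle(tr$label)
  expect_true(max(runs$lengths[runs$values == 3]) >= 20)

  tr0 <- trace_segment(vol, c(0, 1, 1), c(8, 1, 1), step_mm = 0.5)
  expect_true(all(tr0$label == 0))

  expect_error(trace_segment(vol, c(0, 4, 4), c(100, 4, 4)), "outside")
  expect_error(trace_segment(vol, c(0, 4, 4), c(39, 4, 4), step_mm = 2),
               "step_mm")
})

test_that("first_crossing localizes a rasterized sphere surface", {
  # fine grid so voxelization error stays below the 0.1 mm refinement:
  # sphere of radius 3 mm centered on the ray, 0.2 mm voxels
  n <- c(111L, 41L, 41L)
  sp <- 0.2
  ctr <- c(11, 4, 4)
  xs <- (0:(n[1] - 1)) * sp
  ys <- (0:(n[2] - 1)) * sp
  r2 <- outer(outer((xs - ctr[1])^2, (ys - ctr[2])^2, "+"),
              (ys - ctr[3])^2, "+")
  lab <- array(0L, n)
  lab[r2 <= 3^2] <- 5L
  vol <- labeled_volume(lab, spacing = rep(sp, 3))
  hit <- first_crossing(vol, c(0.4, 4, 4), c(21, 4, 4), 5L, step_mm = 0.1)
  expect_false(is.null(hit))
  # analytic crossing at distance (11 - 0.4) - 3 = 7.6 from the start
  expect_equal(attr(hit, "t"), 7.6, tolerance = 0.2)
  expect_equal(hit[1], 8.0, tolerance = 0.2)

  # degenerate start already inside the set
  hit2 <- first_crossing(vol, c(11, 4, 4), c(21, 4, 4), 5L)
  expect_equal(attr(hit2, "t"), 0)
  # empty label set
  expect_null(first_crossing(vol, c(0.4, 4, 4), c(21, 4, 4), integer(0)))
  # label never present on the segment
  expect_null(first_crossing(vol, c(0.4, 1, 1), c(21, 1, 1), 5L))
})

test_that("surface normals match analytic sphere and plane normals", {
  n <- 41L
  ctr <- 20
  xs <- 0:(n - 1)
  r2 <- outer(outer((xs - ctr)^2, (xs - ctr)^2, "+"), (xs - ctr)^2, "+")
  lab <- array(0L, c(n, n, n))
  lab[r2 <= 14^2] <- 4L
  lab[r2 <= 3^2] <- 10L
  lab[1, 1, 1] <- 1L
  sc <- anatomy_scene(labeled_volume(lab),
                      list(skin = 1L, lung_target_lobe = 4L, tumor = 10L))
  for (dirv in list(c(1, 0, 0), c(0, 1, 0), c(1, 1, 1) / sqrt(3),
                    c(-1, 2, 2) / 3)) {
    p <- c(ctr, ctr, ctr) + 14 * dirv
    nrm <- surface_normal(sc, "lung_target_lobe", p)
    ang <- acos(min(1, sum(nrm * dirv))) * 180 / pi
    expect_lt(ang, 5)
  }
  expect_error(surface_normal(sc, "lung_target_lobe", c(ctr, ctr, ctr)),
               "gradient")

  # axis-aligned half-space: exact planar normal
  lab2 <- array(0L, c(20, 20, 20))
  lab2[, , 1:10] <- 4L
  lab2[1, 1, 15] <- 1L
  lab2[2, 2, 2] <- 10L
  sc2 <- anatomy_scene(labeled_volume(lab2),
                       list(skin = 1L, lung_target_lobe = 4L, tumor = 10L))
  nrm <- surface_normal(sc2, "lung_target_lobe", c(10, 10, 9.5))
  expect_equal(nrm, c(0, 0, 1), tolerance = 1e-6)
})

test_that("path-surface angle follows the complement convention", {
  expect_equal(path_surface_angle(c(0, 0, 1), c(0, 0, 1)), 90)
  expect_equal(path_surface_angle(c(1, 0, 0), c(0, 0, 1)), 0)
  expect_equal(path_surface_angle(c(1, 0, 1) / sqrt(2), c(0, 0, 1)), 45)
  expect_error(path_surface_angle(c(0, 0, 0), c(0, 0, 1)), "zero")
  # invariance under negation of either vector
  set.seed(5)
  for (i in 1:20) {
    d <- rnorm(3); nv <- rnorm(3)
    a <- path_surface_angle(d, nv)
    expect_equal(path_surface_angle(-d, nv), a)
    expect_equal(path_surface_angle(d, -nv), a)
    expect_gte(a, 0)
    expect_lte(a, 90)
  }
})

test_that("distance transform is exact for simple geometries", {
  lab <- array(0L, c(10, 10, 10))
  lab[1, 1, 1] <- 1L
  vol <- labeled_volume(lab, spacing = c(1, 1, 1))
  f <- distance_transform(vol, 1L)
  expect_equal(f$values[4, 5, 1], 5)           # 3-4-5 triangle
  expect_equal(f$values[1, 1, 1], 0)
  vol2 <- labeled_volume(lab, spacing = c(1, 1, 1.25))
  f2 <- distance_transform(vol2, 1L)
  expect_equal(f2$values[1, 1, 5], 5)          # anisotropic spacing
  expect_error(distance_transform(vol, 9L), "empty")
})

test_that("distance transform equals the brute-force oracle", {
  set.seed(42)
  for (i in 1:6) {
    dm <- sample(5:14, 3, replace = TRUE)
    spc <- runif(3, 0.5, 2)
    mask <- array(runif(prod(dm)) < 0.08, dm)
    if (!any(mask)) mask[1] <- TRUE
    vol <- labeled_volume(array(as.integer(mask), dm), spacing = spc)
    f <- distance_transform(vol, 1L)
    expect_equal(f$values, brute_edt(mask, spc), tolerance = 1e-9)
  }
})

test_that("segment extrema match dense sampling and bound every sample", {
  set.seed(9)
  dm <- c(16, 16, 16)
  vol <- labeled_volume(array(0L, dm), spacing = c(1, 1, 1))
  vol$labels[8, 8, 8] <- 1L
  f <- distance_transform(vol, 1L)
  a <- c(1, 2, 3); b <- c(14, 13, 11)
  mn <- min_along_segment(f, a, b, step_mm = 0.5)
  mx <- max_along_segment(f, a, b, step_mm = 0.5)
  dense <- sapply(seq(0, 1, length.out = 400), function(t) {
    p <- a + t * (b - a)
    needleplan:::cpp_trilinear(f$values, dm, f$spacing, f$origin,
                               matrix(p, 1))
  })
  # the segment extrema bound the dense refinement from inside and agree
  # with it up to half the sampling step times the field's unit gradient
  expect_gte(mn, min(dense) - 1e-9)
  expect_lte(mx, max(dense) + 1e-9)
  expect_lt(abs(mn - min(dense)), 0.3)
  expect_lt(abs(mx - max(dense)), 0.3)

  # constant field
  cf <- list(values = array(7, dm), spacing = c(1, 1, 1), origin = c(0, 0, 0))
  expect_equal(min_along_segment(cf, a, b), 7)
  expect_equal(max_along_segment(cf, a, b), 7)

  # monotone field from a point: max over E->C equals the start distance
  expect_equal(max_along_segment(f, c(1, 7, 7), c(7, 7, 7)),
               6, tolerance = 0.5)
})
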