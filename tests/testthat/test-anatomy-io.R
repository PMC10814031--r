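test_that("labeled_volume validates its invariants", {
  expect_error(labeled_volume(array(0L, c(2, 3, 3))), "dimension")
  expect_error(labeled_volume(array(0L, c(3, 3, 3)), spacing = c(1, 0, 1)),
               "spacing")
  expect_error(labeled_volume(array(-1L, c(3, 3, 3))), "non-negative")
  expect_error(labeled_volume(array(0.5, c(3, 3, 3))), "non-negative")
  v <- labeled_volume(array(2L, c(3, 4, 5)), spacing = c(1, 1, 1.25))
  expect_equal(dim(v$labels), c(3L, 4L, 5L))
})

test_that("NIfTI round-trip preserves shape, spacing, origin and labels", {
  set.seed(11)
  lab <- array(sample(0:6, 5 * 6 * 7, replace = TRUE), c(5, 6, 7))
  vol <- labeled_volume(lab, spacing = c(0.7, 0.7, 1.25),
                        origin = c(-12, 3.5, 40))
  path <- tempfile(fileext = ".nii.gz")
  on.exit(unlink(path))
  write_volume(vol, path)
  back <- read_volume(path)
  expect_identical(dim(back$labels), dim(vol$labels))
  expect_equal(back$spacing, vol$spacing, tolerance = 1e-6)
  expect_equal(back$origin, vol$origin, tolerance = 1e-6)
  expect_identical(as.vector(back$labels), as.vector(vol$labels))
})

test_that("read_scene binds roles and rejects bad configurations", {
  lab <- array(0L, c(6, 6, 6))
  lab[2:5, 2:5, 2:5] <- 1L
  lab[3:4, 3:4, 3:4] <- 4L
  lab[4, 4, 4] <- 7L
  vol <- labeled_volume(lab, spacing = c(1, 1, 1))
  vp <- tempfile(fileext = ".nii.gz")
  rp <- tempfile(fileext = ".json")
  on.exit(unlink(c(vp, rp)))
  write_volume(vol, vp)

  jsonlite::write_json(list(skin = 1L, lung_target_lobe = 4L, tumor = 7L),
                       rp, auto_unbox = FALSE)
  sc <- read_scene(vp, rp)
  expect_s3_class(sc, "anatomy_scene")
  expect_setequal(names(sc$roles), c("skin", "lung_target_lobe", "tumor"))

  jsonlite::write_json(list(skin = 1L, lung_target_lobe = 4L), rp,
                       auto_unbox = FALSE)
  expect_error(read_scene(vp, rp), "mandatory")

  jsonlite::write_json(list(skin = 1L, lung_target_lobe = 4L, tumor = 7L,
                            gizzard = 3L), rp, auto_unbox = FALSE)
  expect_error(read_scene(vp, rp), "unknown role")

  jsonlite::write_json(list(skin = 1L, lung_target_lobe = 4L, tumor = 99L),
                       rp, auto_unbox = FALSE)
  expect_error(read_scene(vp, rp), "absent")
})

test_that("tumor centroid is the mean tumor voxel center in world mm", {
  mk <- function(dim, at, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
    lab <- array(0L, dim)
    lab[, , ] <- 1L  # body everywhere so skin role binds
    lab[dim[1], dim[2], dim[3]] <- 4L
    for (r in seq_len(nrow(at))) {
      lab[at[r, 1] + 1, at[r, 2] + 1, at[r, 3] + 1] <- 10L
    }
    anatomy_scene(labeled_volume(lab, spacing, origin),
                  list(skin = 1L, lung_target_lobe = 4L, tumor = 10L))
  }
  # single voxel
  sc <- mk(c(21, 21, 21), cbind(10, 10, 10))
  expect_equal(tumor_centroid(sc), c(10, 10, 10))
  # symmetric cube
  cube <- as.matrix(expand.grid(19:21, 19:21, 19:21))
  sc <- mk(c(30, 30, 30), cube)
  expect_equal(tumor_centroid(sc), c(20, 20, 20))
  # anisotropic spacing
  sc <- mk(c(8, 8, 8), rbind(c(0, 0, 0), c(0, 0, 4)),
           spacing = c(1, 1, 1.25))
  expect_equal(tumor_centroid(sc), c(0, 0, 2.5))
})

test_that("tumor centroid is equivariant under origin translation", {
  set.seed(7)
  lab <- array(1L, c(12, 12, 12))
  lab[sample(12, 3) + 1, 5, 5] <- 10L
  lab[1, 1, 1] <- 4L
  roles <- list(skin = 1L, lung_target_lobe = 4L, tumor = 10L)
  c0 <- tumor_centroid(anatomy_scene(labeled_volume(lab), roles))
  t <- c(-7.5, 3.25, 100)
  c1 <- tumor_centroid(anatomy_scene(labeled_volume(lab, origin = t), roles))
  expect_equal(c1, c0 + t)
})

test_that("plan_config validates and renormalizes weights", {
  cfg <- plan_config()
  expect_equal(sum(cfg$weights), 1, tolerance = 1e-12)
  expect_warning(cfg2 <- plan_config(weights = c(2, 1, 1)), "renormalized")
  expect_equal(cfg2$weights, c(0.5, 0.25, 0.25))
  expect_error(plan_config(weights = c(-1, 1, 1)), "non-negative")
  expect_error(plan_config(needle_length_mm = 0))
  expect_error(plan_config(top_k = 0))
})
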