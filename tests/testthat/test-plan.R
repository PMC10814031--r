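test_that("planning the small phantom returns verified ranked paths", {
  sc <- generate_phantom(phantom_spec("mini"))
  pl <- plan_paths(sc, plan_config())
  expect_equal(pl$status, "ok")
  expect_equal(nrow(pl$paths), 5)
  expect_equal(pl$paths$rank, 1:5)
  expect_true(all(diff(pl$paths$G) <= 1e-12))
  # candidate counts shrink monotonically through integration
  expect_lte(pl$counts$feasible, pl$counts$candidates)
  # scores of returned paths lie in [0,1]; infeasible cells carry none
  expect_true(all(pl$paths$R >= 0 & pl$paths$R <= 1))
  expect_true(all(is.na(pl$cells$R[!pl$cells$feasible])))
  expect_true(all(pl$cells$R[pl$cells$feasible] >= 0 &
                    pl$cells$R[pl$cells$feasible] <= 1))
  # hard constraints for returned paths hold with the strict inequalities
  expect_true(all(pl$paths$l_mm < plan_config()$needle_length_mm))
  expect_true(all(pl$paths$alpha_deg > plan_config()$angle_threshold_deg))

  rep <- verify_plan(pl, sc)
  expect_equal(rep$pass_rate, 1)
  expect_true(all(rep$paths$qualified))
  # planner and verifier agree on the measured quantities
  expect_equal(rep$paths$l_mm, pl$paths$l_mm, tolerance = 0.5)
  expect_equal(rep$paths$alpha_deg, pl$paths$alpha_deg, tolerance = 5)
})

test_that("an impossibly short needle yields the no-feasible-path outcome", {
  sc <- generate_phantom(phantom_spec("mini"))
  pl <- plan_paths(sc, plan_config(needle_length_mm = 10))
  expect_equal(pl$status, "no-feasible-path")
  expect_equal(pl$dominant_constraint, "H2")
  expect_equal(nrow(pl$paths), 0)
})

test_that("top-1 is the prefix of top-5", {
  sc <- generate_phantom(phantom_spec("mini"))
  p5 <- plan_paths(sc, plan_config(top_k = 5))
  p1 <- plan_paths(sc, plan_config(top_k = 1))
  expect_equal(nrow(p1$paths), 1)
  expect_equal(p1$paths$cell, p5$paths$cell[1])
  expect_equal(p1$paths$G, p5$paths$G[1])
})

test_that("the verifier flags a hand-crafted path through a rib", {
  sc <- generate_phantom(phantom_spec("mini"))
  pl <- plan_paths(sc, plan_config())
  occ <- occlusion_map(sc, pl$C)
  cells <- pl$cells
  bad <- cells[occ & cells$face == "y-", ][1, ]
  forged <- pl
  forged$paths[1, c("Ix", "Iy", "Iz")] <- bad[, c("Ix", "Iy", "Iz")]
  rep <- verify_plan(forged, sc)
  expect_false(rep$paths$h1_pass[1])
  expect_false(rep$paths$qualified[1])
  expect_lt(rep$pass_rate, 1)
})

test_that("verification rejects a mismatched scene", {
  sc <- generate_phantom(phantom_spec("mini"))
  pl <- plan_paths(sc, plan_config())
  other <- generate_phantom(phantom_spec("mini", seed = 9L, jitter_mm = 1.5))
  expect_error(verify_plan(pl, other), "does not match")
})

test_that("DTF+MIP length formulation agrees with the direct entry length", {
  sc <- generate_phantom(phantom_spec("mini"))
  pl <- plan_paths(sc, plan_config())
  feas <- which(pl$cells$feasible)
  mip <- s2_dtf_mip(sc, C = pl$C,
                    cells = as.matrix(pl$cells[feas, c("Ix", "Iy", "Iz")]))
  diag_vox <- sqrt(sum(sc$volume$spacing^2))
  expect_true(all(abs(mip - pl$cells$l_mm[feas]) <= diag_vox))
})

test_that("plan serialization is deterministic and complete", {
  f1 <- tempfile(fileext = ".json"); f2 <- tempfile(fileext = ".json")
  on.exit(unlink(c(f1, f2)))
  write_plan_json(plan_paths(generate_phantom(phantom_spec("mini")),
                             plan_config()), f1)
  write_plan_json(plan_paths(generate_phantom(phantom_spec("mini")),
                             plan_config()), f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  obj <- jsonlite::fromJSON(f1)
  expect_equal(obj$status, "ok")
  expect_equal(nrow(obj$paths), 5)
  expect_true(all(c("d_mm", "l_mm", "alpha_deg", "R", "L", "A", "G") %in%
                    names(obj$paths)))
})

test_that("face maps and trajectory polylines export to disk", {
  sc <- generate_phantom(phantom_spec("mini"))
  pl <- plan_paths(sc, plan_config())
  out <- tempfile()
  files <- write_face_maps(pl, "feasible", out)
  expect_true(all(file.exists(files)))
  img <- tiff::readTIFF(files[1])
  expect_true(all(img >= 0 & img <= 1))
  vtk <- file.path(out, "paths.vtk")
  write_vtk_paths(pl, vtk)
  head <- readLines(vtk, n = 5)
  expect_match(head[1], "vtk DataFile")
  expect_match(head[4], "POLYDATA")
  unlink(out, recursive = TRUE)
})
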