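test_that("2D front retains exactly the non-dominated points", {
  pts <- data.frame(v1 = c(0.2, 0.5, 0.9, 0.4), v2 = c(0.9, 0.5, 0.2, 0.4))
  fr <- pareto_front_2d(pts, c("v1", "v2"))
  expect_equal(sort(fr$v1), c(0.2, 0.5, 0.9))
  # single point
  expect_equal(nrow(pareto_front_2d(pts[2, ], c("v1", "v2"))), 1)
  # all identical: no strict domination, all retained
  same <- data.frame(v1 = rep(0.3, 5), v2 = rep(0.7, 5))
  expect_equal(nrow(pareto_front_2d(same, c("v1", "v2"))), 5)
  # empty input
  expect_equal(nrow(pareto_front_2d(pts[0, ], c("v1", "v2"))), 0)
})

test_that("sort-and-prune front equals the O(n^2) dominance oracle", {
  set.seed(13)
  for (i in 1:40) {
    n <- sample(1:120, 1)
    pts <- random_objectives(n)
    fr <- pareto_front_2d(pts, c("v1", "v2"))
    keep <- pareto_oracle(pts)
    expect_identical(sort(as.integer(rownames(fr))), which(keep))
  }
})

test_that("pairwise-front intersection falls back to the 3D front", {
  # one point dominating everything
  pts <- data.frame(cell = 1:4, R = c(1, 0.2, 0.3, 0.1),
                    L = c(1, 0.5, 0.2, 0.1), A = c(1, 0.1, 0.6, 0.1))
  pi1 <- pareto_intersection(pts)
  expect_equal(pi1$cell, 1)
  expect_false(attr(pi1, "fallback"))

  # mutually non-dominated unit vectors: every pairwise front misses one
  # point, the intersection is empty, the 3D front is returned
  tri <- data.frame(cell = 1:3, R = c(1, 0, 0), L = c(0, 1, 0),
                    A = c(0, 0, 1))
  pi2 <- pareto_intersection(tri)
  expect_true(attr(pi2, "fallback"))
  expect_setequal(pi2$cell, 1:3)

  # points on a spherical trade-off octant are all 3D non-dominated
  set.seed(31)
  v <- matrix(abs(rnorm(3 * 40)), ncol = 3)
  v <- v / sqrt(rowSums(v^2))
  oct <- data.frame(cell = 1:40, R = v[, 1], L = v[, 2], A = v[, 3])
  pi3 <- pareto_intersection(oct)
  nd <- needleplan:::nondominated(v)
  expect_true(all(nd))
  expect_setequal(pi3$cell, oct$cell[nd])
})

test_that("weighted aggregation follows the stated formula", {
  expect_equal(weighted_score(c(0.9, 0.6, 0.3)), 0.6)
  expect_equal(weighted_score(c(1, 1, 1), c(0.2, 0.5, 0.3)), 1)
  expect_error(weighted_score(c(1, 1, 1), c(0.5, 0.5, 0.5)), "sum to 1")
  # degenerate weights rank purely by the weighted objective
  set.seed(2)
  m <- matrix(runif(30), ncol = 3)
  g <- weighted_score(m, c(1, 0, 0))
  expect_equal(order(-g), order(-m[, 1]))
  # product form
  expect_equal(weighted_score(c(0.25, 1, 1), c(1, 0, 0) * 1, TRUE), 0.25)
})

test_that("top-k selection is deterministic and matches the brute pipeline", {
  set.seed(77)
  pts <- data.frame(cell = 1:100, R = round(runif(100), 2),
                    L = round(runif(100), 2), A = round(runif(100), 2))
  sel <- select_top_k(pts, k = 5)
  expect_equal(nrow(sel), 5)
  expect_equal(sel$rank, 1:5)
  expect_true(all(diff(sel$G) <= 1e-12))

  # brute oracle: 3D-checked pairwise-front intersection sorted by G
  in2d <- function(m) pareto_oracle(m)
  f1 <- in2d(pts[, c("R", "L")]); f2 <- in2d(pts[, c("R", "A")])
  f3 <- in2d(pts[, c("L", "A")])
  front <- pts[f1 & f2 & f3, ]
  if (nrow(front) == 0) front <- pts[pareto_oracle(pts[, 2:4]), ]
  front$G <- (front$R + front$L + front$A) / 3
  ord <- front[order(-front$G, -front$R, -front$L, -front$A, front$cell), ]
  expect_equal(sel$cell, head(ord$cell, 5))
  expect_equal(sel$G, head(ord$G, 5), tolerance = 1e-12)

  # invariance under permutation of the input
  perm <- pts[sample(nrow(pts)), ]
  expect_equal(select_top_k(perm, k = 5)$cell, sel$cell)

  # k exceeding the front returns the whole front, ordered
  selall <- select_top_k(pts, k = 1e6)
  expect_equal(selall$cell, ord$cell)

  # raising one objective never lowers a retained path's score
  pts2 <- pts
  pts2$A[pts2$cell == sel$cell[3]] <-
    min(1, pts2$A[pts2$cell == sel$cell[3]] + 0.2)
  sel2 <- select_top_k(pts2, k = 100)
  g_old <- sel$G[sel$cell == sel$cell[3]]
  g_new <- sel2$G[sel2$cell == sel$cell[3]]
  expect_gte(g_new, g_old)
})
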