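# Small synthetic scenes and brute-force oracles used across the test files.
# All fixtures are built in code; nothing is read from disk.

# Concentric spherical phantom: body sphere with a skin shell, one spherical
# "lung", a small tumor at the common center. No risk structures, so every
# candidate ray is radial up to face-cell discretization.
sphere_scene <- function(n = 40L, spacing = 2, body_r = 36, shell = 3,
                         lung_r = 20, tumor_r = 4) {
  ctr <- (n - 1) * spacing / 2
  xs <- (0:(n - 1)) * spacing
  r2 <- outer(outer((xs - ctr)^2, (xs - ctr)^2, "+"), (xs - ctr)^2, "+")
  lab <- array(0L, c(n, n, n))
  lab[r2 <= body_r^2] <- 1L
  lab[r2 <= (body_r - shell)^2] <- 2L
  lab[r2 <= lung_r^2] <- 4L
  lab[r2 <= tumor_r^2] <- 10L
  vol <- labeled_volume(lab, spacing = rep(spacing, 3))
  anatomy_scene(vol, list(skin = 1L, lung_target_lobe = 4L, tumor = 10L))
}

# O(n^2) brute-force Euclidean distance transform oracle (mm).
brute_edt <- function(mask, spacing) {
  dm <- dim(mask)
  idx <- which(array(TRUE, dm), arr.ind = TRUE) - 1L
  w <- sweep(matrix(as.numeric(idx), ncol = 3), 2, spacing, "*")
  obs <- w[as.vector(mask), , drop = FALSE]
  out <- rep(Inf, nrow(w))
  for (q in seq_len(nrow(obs))) {
    out <- pmin(out, sqrt((w[, 1] - obs[q, 1])^2 + (w[, 2] - obs[q, 2])^2 +
                            (w[, 3] - obs[q, 3])^2))
  }
  array(out, dm)
}

# O(n^2) dominance oracle: TRUE for rows not strictly dominated (weak
# inequality on all objectives, strict on at least one).
pareto_oracle <- function(m) {
  m <- as.matrix(m)
  n <- nrow(m)
  keep <- rep(TRUE, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j && all(m[j, ] >= m[i, ]) && any(m[j, ] > m[i, ])) {
        keep[i] <- FALSE
        break
      }
    }
  }
  keep
}

# Random 2D objective sets with forced ties on both axes.
random_objectives <- function(n, tie_fraction = 0.3) {
  v1 <- runif(n)
  v2 <- runif(n)
  if (n >= 4 && tie_fraction > 0) {
    k <- max(1L, floor(n * tie_fraction))
    v1[sample(n, k, replace = TRUE)] <-
      sample(round(runif(3), 2), k, replace = TRUE)
    v2[sample(n, k, replace = TRUE)] <-
      sample(round(runif(3), 2), k, replace = TRUE)
  }
  data.frame(v1 = v1, v2 = v2)
}
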