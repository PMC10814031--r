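#' 2D Pareto front by sort-and-prune
#'
#' Returns exactly the points not strictly dominated in the chosen objective
#' pair, where `y` dominates `x` iff `y >= x` on both axes and `y > x` on at
#' least one. Duplicate objective vectors are all retained. Implemented as a
#' sort-and-prune sweep: points are sorted descending by the first objective
#' (ties broken by the second); the unprocessed point with maximal first
#' objective is moved to the front together with its exact duplicates, and
#' every remaining point whose second objective is less than or equal to the
#' selected one is pruned; this repeats until the input is exhausted.
#'
#' @param points data.frame (or matrix) with at least the two objective
#'   columns; both objectives are maximized.
#' @param axes character or integer vector of length 2 naming the objective
#'   columns.
#' @return the subset of rows forming the front (original order preserved).
#' @export
pareto_front_2d <- function(points, axes = 1:2) {
  points <- as.data.frame(points)
  if (nrow(points) == 0L) return(points)
  a <- points[[axes[1]]]
  b <- points[[axes[2]]]
  ord <- order(-a, -b)
  keep <- logical(nrow(points))
  pos <- 1L
  n <- length(ord)
  while (pos <= n) {
    sel <- ord[pos]
    ra <- a[sel]; rb <- b[sel]
    # exact duplicates of the selected vector are retained on the front
    while (pos <= n && a[ord[pos]] == ra && b[ord[pos]] == rb) {
      keep[ord[pos]] <- TRUE
      pos <- pos + 1L
    }
    # prune everything whose second objective does not exceed the selection
    while (pos <= n && b[ord[pos]] <= rb) pos <- pos + 1L
    # remaining points have strictly larger b; compress the tail in place
    if (pos <= n) {
      tail_idx <- ord[pos:n]
      tail_idx <- tail_idx[b[tail_idx] > rb]
      n <- pos - 1L + length(tail_idx)
      if (length(tail_idx)) ord[pos:n] <- tail_idx
    }
  }
  points[keep, , drop = FALSE]
}

# n-dimensional non-dominated subset (weak dominance with one strict);
# used as the fallback when the pairwise-front intersection is empty.
nondominated <- function(m) {
  m <- as.matrix(m)
  n <- nrow(m)
  if (n <= 1L) return(rep(TRUE, n))
  ord <- do.call(order, c(lapply(seq_len(ncol(m)), function(j) -m[, j])))
  keep_rows <- matrix(numeric(0), 0, ncol(m))
  keep <- logical(n)
  for (idx in ord) {
    p <- m[idx, ]
    if (nrow(keep_rows)) {
      ge <- keep_rows >= rep(p, each = nrow(keep_rows))
      gt <- keep_rows > rep(p, each = nrow(keep_rows))
      dominated <- any(rowSums(ge) == ncol(m) & rowSums(gt) > 0)
      if (dominated) next
    }
    keep[idx] <- TRUE
    keep_rows <- rbind(keep_rows, p)
  }
  keep
}

#' Intersection of the pairwise Pareto fronts
#'
#' Computes the 2D fronts of the objective pairs (R,L), (R,A) and (L,A) and
#' intersects them. If the intersection is empty (the fronts of different
#' pairs need not share points), the full 3D non-dominated set is returned
#' instead and flagged: every 2D-front member is also 3D non-dominated, so
#' the 3D front is a superset of the intended set.
#'
#' @param points data.frame with objective columns `R`, `L`, `A` (all
#'   maximized) and any id columns.
#' @return the selected subset, with attribute `"fallback"` set to TRUE when
#'   the 3D fallback was used.
#' @export
pareto_intersection <- function(points) {
  points <- as.data.frame(points)
  if (nrow(points) == 0L) {
    return(structure(points, fallback = FALSE))
  }
  key <- seq_len(nrow(points))
  in_front <- function(ax) {
    sub <- pareto_front_2d(data.frame(v1 = points[[ax[1]]],
                                      v2 = points[[ax[2]]], .k = key),
                           c("v1", "v2"))
    key %in% sub$.k
  }
  sel <- in_front(c("R", "L")) & in_front(c("R", "A")) & in_front(c("L", "A"))
  if (any(sel)) {
    return(structure(points[sel, , drop = FALSE], fallback = FALSE))
  }
  nd <- nondominated(points[, c("R", "L", "A")])
  structure(points[nd, , drop = FALSE], fallback = TRUE)
}

#' Aggregate soft-constraint scores into a single path score
#'
#' Weighted sum `G = w1*R + w2*L + w3*A` (the default), or the weighted
#' product `R^w1 * L^w2 * A^w3` when `product_form` is TRUE (sensitivity
#' analysis only).
#'
#' @param scores numeric length-3 vector or 3-column matrix/data.frame of
#'   (R, L, A) scores in `[0,1]`.
#' @param weights numeric length-3 non-negative weights summing to 1.
#' @param product_form logical.
#' @return numeric vector of aggregate scores in `[0,1]`.
#' @export
weighted_score <- function(scores, weights = c(1, 1, 1) / 3,
                           product_form = FALSE) {
  if (length(weights) != 3L || any(weights < 0)) {
    stop("weights must be 3 non-negative reals")
  }
  if (abs(sum(weights) - 1) > 1e-9) stop("weights must sum to 1")
  m <- matrix(as.numeric(as.matrix(scores)), ncol = 3)
  if (product_form) {
    apply(m, 1, function(s) prod(s^weights))
  } else {
    as.numeric(m %*% weights)
  }
}

#' Rank the Pareto-selected candidates and keep the top k
#'
#' Candidates from [pareto_intersection()] are sorted by aggregate score G
#' descending; ties are broken by (R, L, A, cell id) lexicographically so the
#' result is deterministic and invariant under input permutation.
#'
#' @param candidates data.frame with columns `cell`, `R`, `L`, `A`.
#' @param weights soft-constraint weights (length 3, sum 1).
#' @param k number of paths to keep.
#' @param product_form logical, see [weighted_score()].
#' @return the top `min(k, n)` rows with columns `G` and `rank` added and
#'   attribute `"fallback"` carried over.
#' @export
select_top_k <- function(candidates, weights = c(1, 1, 1) / 3, k = 5,
                         product_form = FALSE) {
  if (nrow(candidates) == 0L) stop("no feasible candidates to rank")
  front <- pareto_intersection(candidates)
  front$G <- weighted_score(front[, c("R", "L", "A")], weights, product_form)
  ord <- order(-front$G, -front$R, -front$L, -front$A, front$cell)
  front <- front[ord, , drop = FALSE]
  n <- min(as.integer(k), nrow(front))
  out <- front[seq_len(n), , drop = FALSE]
  out$rank <- seq_len(n)
  rownames(out) <- NULL
  structure(out, fallback = isTRUE(attr(front, "fallback")))
}
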