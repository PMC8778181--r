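# Parametric lattice-computing distance between face trees.
#
# Each node carries an interval pair ([a,b] for r, [c,d] for phi); a trivial
# tree has all intervals degenerate. The per-node distance uses the positive
# valuation v(x) = lambda * x with dual isomorphism theta(x) = 1 - x:
#
#   d([a,b],[c,e]) = [v(theta(a ^ c)) - v(theta(a v c))] + [v(b v e) - v(b ^ e)]
#                  = lambda * (|a - c| + |b - e|)
#
# Branch distances accumulate from the leaves to the root: a primary node's
# own term plus k_child times the sum of its children's terms. The tree
# distance is computed separately for r and phi and combined as
# k_r * D_r + k_phi * D_phi; the normalized nose root contributes zero
# (k_c = 1 at the root).

#' Construct an interval tree
#'
#' An interval tree carries, per node, an interval for the nondimensional
#' length `r` and one for the orientation `phi`; it represents an
#' information granule — a neighborhood of faces such as a head-pose
#' prototype. A trivial tree is the degenerate case with all intervals
#' collapsed to points.
#'
#' @param r_lo,r_hi numeric vectors of length 59, interval endpoints for r.
#' @param phi_lo,phi_hi numeric vectors of length 59, endpoints for phi.
#' @param label optional class label.
#' @return an object of class `interval_tree`.
#' @export
interval_tree <- function(r_lo, r_hi, phi_lo, phi_hi, label = NULL) {
  stopifnot(length(r_lo) == .N_NODES, length(r_hi) == .N_NODES,
            length(phi_lo) == .N_NODES, length(phi_hi) == .N_NODES)
  if (any(r_lo > r_hi) || any(phi_lo > phi_hi))
    stop("interval_tree: lower endpoints must not exceed upper endpoints")
  structure(list(r_lo = as.numeric(r_lo), r_hi = as.numeric(r_hi),
                 phi_lo = as.numeric(phi_lo), phi_hi = as.numeric(phi_hi),
                 label = label),
            class = "interval_tree")
}

#' Coerce a trivial face tree to a degenerate interval tree
#' @param tree a `face_tree`.
#' @param label optional class label.
#' @return an `interval_tree` with all intervals degenerate.
#' @export
as_interval_tree <- function(tree, label = NULL) {
  if (inherits(tree, "interval_tree")) {
    if (!is.null(label)) tree$label <- label
    return(tree)
  }
  stopifnot(inherits(tree, "face_tree"))
  interval_tree(tree$r, tree$r, tree$phi, tree$phi, label = label)
}

#' @export
print.interval_tree <- function(x, ...) {
  trivial <- all(x$r_lo == x$r_hi) && all(x$phi_lo == x$phi_hi)
  cat("Interval face tree (59 nodes",
      if (trivial) ", trivial" else "", ")\n", sep = "")
  if (!is.null(x$label)) cat("  label:", x$label, "\n")
  cat(sprintf("  mean r width %.4g, mean phi width %.4g\n",
              mean(x$r_hi - x$r_lo), mean(x$phi_hi - x$phi_lo)))
  invisible(x)
}

#' Metric parameters of the lattice tree distance
#'
#' The distance has 126 tunable nonnegative weights: a `lambda` per node and
#' per coordinate (2 x 59), the hierarchy weights `k1, k2, k3` per coordinate
#' (applied to the children of the eye and mouth primaries), and the two
#' combiner weights `k_r`, `k_phi`. The default (all ones) is the plain
#' linear case.
#'
#' @param lambda_r,lambda_phi numeric vectors of length 59, per-node weights.
#' @param k_r123,k_phi123 numeric vectors of length 3, child-branch weights
#'   for the three primaries with children.
#' @param k_r,k_phi scalar combiner weights for the r and phi parts.
#' @return an object of class `metric_params`.
#' @examples
#' p <- metric_params()          # all-ones default
#' @export
metric_params <- function(lambda_r = rep(1, 59), lambda_phi = rep(1, 59),
                          k_r123 = rep(1, 3), k_phi123 = rep(1, 3),
                          k_r = 1, k_phi = 1) {
  p <- list(lambda_r = as.numeric(lambda_r),
            lambda_phi = as.numeric(lambda_phi),
            k_r123 = as.numeric(k_r123), k_phi123 = as.numeric(k_phi123),
            k_r = as.numeric(k_r), k_phi = as.numeric(k_phi))
  .validate_params(p)
  structure(p, class = "metric_params")
}

.validate_params <- function(p) {
  lens <- c(length(p$lambda_r), length(p$lambda_phi),
            length(p$k_r123), length(p$k_phi123),
            length(p$k_r), length(p$k_phi))
  if (!identical(lens, c(59L, 59L, 3L, 3L, 1L, 1L)))
    stop("metric_params: wrong field lengths")
  v <- unlist(p, use.names = FALSE)
  if (any(!is.finite(v)) || any(v < 0))
    stop("metric_params: all weights must be finite and nonnegative")
  invisible(TRUE)
}

#' @export
print.metric_params <- function(x, ...) {
  cat("Lattice-metric parameters (126 weights)\n")
  cat(sprintf("  lambda_r   in [%.3g, %.3g]\n", min(x$lambda_r), max(x$lambda_r)))
  cat(sprintf("  lambda_phi in [%.3g, %.3g]\n", min(x$lambda_phi), max(x$lambda_phi)))
  cat(sprintf("  k1..k3 (r): %s   k1..k3 (phi): %s\n",
              paste(signif(x$k_r123, 3), collapse = " "),
              paste(signif(x$k_phi123, 3), collapse = " ")))
  cat(sprintf("  k_r = %.3g, k_phi = %.3g\n", x$k_r, x$k_phi))
  invisible(x)
}

#' Weighted lattice distance between two intervals
#'
#' Evaluates the positive-valuation interval distance with v(x) = lambda * x
#' and theta(x) = 1 - x, term by term:
#' `[v(theta(min(a,c))) - v(theta(max(a,c)))] + [v(max(b,e)) - v(min(b,e))]`,
#' which equals `lambda * (|a - c| + |b - e|)`.
#'
#' @param x,y length-2 numeric vectors `c(lo, hi)`; a point value may be
#'   passed as a length-1 vector (degenerate interval).
#' @param lambda nonnegative weight.
#' @return nonnegative scalar distance.
#' @examples
#' interval_distance(c(0.2, 0.4), c(0.3, 0.7), lambda = 2)  # 0.8
#' @export
interval_distance <- function(x, y, lambda = 1) {
  if (length(x) == 1L) x <- c(x, x)
  if (length(y) == 1L) y <- c(y, y)
  stopifnot(length(x) == 2L, length(y) == 2L, x[1] <= x[2], y[1] <= y[2])
  if (!is.finite(lambda) || lambda < 0)
    stop("interval_distance: lambda must be nonnegative")
  v <- function(z) lambda * z
  theta <- function(z) 1 - z
  (v(theta(min(x[1], y[1]))) - v(theta(max(x[1], y[1])))) +
    (v(max(x[2], y[2])) - v(min(x[2], y[2])))
}

# node intervals of a tree for one coordinate, as lo/hi vectors
.coord_intervals <- function(tree, coord) {
  if (inherits(tree, "face_tree")) {
    v <- if (coord == "r") tree$r else tree$phi
    list(lo = v, hi = v)
  } else if (inherits(tree, "interval_tree")) {
    if (coord == "r") list(lo = tree$r_lo, hi = tree$r_hi)
    else list(lo = tree$phi_lo, hi = tree$phi_hi)
  } else stop("expected a face_tree or interval_tree")
}

#' Distance between two corresponding branches of the face tree
#'
#' One branch is the subtree rooted at a primary node. Its distance is the
#' primary node's own interval distance plus the child weight times the sum
#' of its children's interval distances, accumulated from the leaves up.
#' Leaf primaries (nodes 4-8) contribute only their own term.
#'
#' @param ta,tb trees (`face_tree` or `interval_tree`) sharing the topology.
#' @param primary primary node id, 1-8.
#' @param params a [metric_params()] object.
#' @param coord `"r"` or `"phi"`.
#' @return nonnegative scalar branch distance.
#' @export
branch_distance <- function(ta, tb, primary, params = metric_params(),
                            coord = c("r", "phi")) {
  coord <- match.arg(coord)
  stopifnot(primary %in% 1:8)
  .validate_params(params)
  a <- .coord_intervals(ta, coord)
  b <- .coord_intervals(tb, coord)
  lam <- if (coord == "r") params$lambda_r else params$lambda_phi
  kck <- if (coord == "r") params$k_r123 else params$k_phi123
  own <- interval_distance(c(a$lo[primary], a$hi[primary]),
                           c(b$lo[primary], b$hi[primary]), lam[primary])
  if (primary > 3L) return(own)
  kids <- which(.TREE_PARENT == primary)
  child_sum <- sum(vapply(kids, function(i)
    interval_distance(c(a$lo[i], a$hi[i]), c(b$lo[i], b$hi[i]), lam[i]),
    numeric(1L)))
  own + kck[primary] * child_sum
}

#' Lattice distance between two face trees
#'
#' Sums the eight branch distances separately for the r and phi coordinates
#' and combines them as `k_r * D_r + k_phi * D_phi`. The normalized nose root
#' contributes zero. With all weights 1 this is the plain (linear) case.
#'
#' @param ta,tb trees (`face_tree` or `interval_tree`).
#' @param params a [metric_params()] object.
#' @return nonnegative scalar distance; 0 iff the trees' node intervals agree.
#' @examples
#' lm <- generate_pose_landmarks("Up", n = 2, noise = "near_normal", seed = 2)
#' tree_distance(build_face_tree(lm[[1]]), build_face_tree(lm[[2]]))
#' @export
tree_distance <- function(ta, tb, params = metric_params()) {
  .validate_params(params)
  dr <- sum(vapply(1:8, function(p)
    branch_distance(ta, tb, p, params, "r"), numeric(1L)))
  dphi <- sum(vapply(1:8, function(p)
    branch_distance(ta, tb, p, params, "phi"), numeric(1L)))
  params$k_r * dr + params$k_phi * dphi
}

# Effective per-column weights on the 118-column layout: the closed form of
# the hierarchical distance is a flat weighted L1 over interval endpoints,
# with node weight k_coord * lambda_i * (1 for primaries, k_g for secondaries
# under primary g). Used by the vectorized distance paths.
.param_weights <- function(params) {
  g <- .TREE_GROUP
  wr <- ifelse(g == 0L, 1, params$k_r123[pmax(g, 1L)])
  wp <- ifelse(g == 0L, 1, params$k_phi123[pmax(g, 1L)])
  c(params$k_r * params$lambda_r * wr,
    params$k_phi * params$lambda_phi * wp)
}

# interval-endpoint matrices (n x 118) for a list of trees/prototypes
.lo_hi_matrices <- function(trees) {
  if (inherits(trees, "face_tree") || inherits(trees, "interval_tree"))
    trees <- list(trees)
  lo <- t(vapply(trees, function(tr) {
    ci_r <- .coord_intervals(tr, "r"); ci_p <- .coord_intervals(tr, "phi")
    c(ci_r$lo, ci_p$lo)
  }, numeric(118L)))
  hi <- t(vapply(trees, function(tr) {
    ci_r <- .coord_intervals(tr, "r"); ci_p <- .coord_intervals(tr, "phi")
    c(ci_r$hi, ci_p$hi)
  }, numeric(118L)))
  list(lo = lo, hi = hi)
}

# n x m distance matrix between n trivial trees (matrix X, n x 118) and m
# prototypes given as lo/hi matrices (m x 118); equals tree_distance per pair
.dist_matrix <- function(X, proto_lo, proto_hi, params) {
  w <- .param_weights(params)
  n <- nrow(X); m <- nrow(proto_lo)
  D <- matrix(0, n, m)
  for (j in seq_len(m)) {
    D[, j] <- abs(X - matrix(proto_lo[j, ], n, 118L, byrow = TRUE)) %*% w +
      abs(X - matrix(proto_hi[j, ], n, 118L, byrow = TRUE)) %*% w
  }
  D
}

#' Centroid (mean tree) of a set of trivial trees
#'
#' Coordinate-wise arithmetic mean of `r` and `phi` per node; `phi` is
#' re-wrapped into `[-pi, pi]`.
#'
#' @param trees a nonempty list of `face_tree` objects.
#' @return a `face_tree`.
#' @export
tree_centroid <- function(trees) {
  if (inherits(trees, "face_tree")) trees <- list(trees)
  if (length(trees) == 0L) stop("tree_centroid: empty tree list")
  X <- .trees_to_matrix(trees)
  m <- colMeans(X)
  structure(list(r = m[1:59], phi = .wrap_angle(m[60:118]),
                 provenance = NULL),
            class = "face_tree")
}

#' Write metric parameters to JSON
#'
#' The layout mirrors the 126-gene chromosome: `lambda_r` (nodes 1-59),
#' `lambda_phi` (nodes 60-118 of the chromosome), `k_r123`, `k_phi123`,
#' `k_r`, `k_phi`, so parameter files round-trip losslessly with
#' [encode_params()]/[decode_chromosome()].
#'
#' @param params a [metric_params()] object.
#' @param path output file; if `NULL` the JSON string is returned.
#' @export
params_to_json <- function(params, path = NULL) {
  .validate_params(params)
  txt <- jsonlite::toJSON(unclass(params), auto_unbox = TRUE, digits = I(17))
  if (is.null(path)) return(as.character(txt))
  writeLines(as.character(txt), path)
  invisible(as.character(txt))
}

#' Read metric parameters from JSON
#' @param path file written by [params_to_json()] (or a JSON string).
#' @return a [metric_params()] object.
#' @export
params_from_json <- function(path) {
  obj <- jsonlite::fromJSON(path)
  metric_params(lambda_r = obj$lambda_r, lambda_phi = obj$lambda_phi,
                k_r123 = obj$k_r123, k_phi123 = obj$k_phi123,
                k_r = obj$k_r, k_phi = obj$k_phi)
}
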