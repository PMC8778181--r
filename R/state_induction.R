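# Behavioral-state induction: k-means over trivial face trees under the
# lattice tree distance. Clusters are initialized from the 11 pose-prototype
# centroids; the three Front subclusters merge into one reported state, so
# 11 clusters yield the 9 behavioral states 0-8.

#' k-means clustering of trivial trees under the lattice distance
#'
#' Alternates nearest-centroid assignment (by [tree_distance()]) and centroid
#' update ([tree_centroid()] of members, i.e. the per-coordinate arithmetic
#' mean) until assignments stabilize or `max_iter` is reached. Assignment
#' ties resolve to the lowest centroid index; empty clusters keep their
#' previous centroid. A median update is available as an option (the true
#' minimizer of the weighted-L1 objective), the mean being the classical
#' default.
#'
#' @param trees nonempty list of `face_tree` objects.
#' @param centers list of initial centroid `face_tree`s (optionally named by
#'   subclass label), or a `pose_prototypes` object whose prototype interval
#'   midpoints are used.
#' @param params a [metric_params()] object used for all distances.
#' @param max_iter iteration cap (default 300).
#' @param update `"mean"` (default) or `"median"` centroid update.
#' @return an object of class `lattice_kmeans`: `centroids` (list of
#'   `face_tree`), `labels` (centroid subclass labels, if supplied),
#'   `states` (merged state numeral per centroid), `cluster` (per-tree
#'   cluster index 1..k), `size`, `objective` (per-iteration total
#'   within-cluster distance), `iterations`, `converged`, `params`.
#' @export
lattice_kmeans <- function(trees, centers, params = metric_params(),
                           max_iter = 300, update = c("mean", "median")) {
  update <- match.arg(update)
  if (inherits(trees, "face_tree")) trees <- list(trees)
  if (length(trees) == 0L) stop("lattice_kmeans: empty tree list")
  if (inherits(centers, "pose_prototypes")) {
    labels <- centers$labels
    centers <- lapply(centers$prototypes, prototype_midpoint)
  } else {
    labels <- names(centers)
    if (inherits(centers, "face_tree")) centers <- list(centers)
  }
  k <- length(centers)
  if (k < 1L) stop("lattice_kmeans: need at least one initial centroid")
  states <- if (!is.null(labels) && all(labels %in% POSE_SUBCLASSES))
    pose_state(labels) else seq_len(k) - 1L

  X <- .trees_to_matrix(trees)
  C <- .trees_to_matrix(centers)
  n <- nrow(X)
  assign_prev <- rep(-1L, n)
  objective <- numeric(0)
  iter <- 0L
  converged <- FALSE
  repeat {
    iter <- iter + 1L
    D <- .dist_matrix(X, C, C, params)  # trivial-vs-trivial tree distance
    cl <- apply(D, 1L, which.min)
    objective <- c(objective, sum(D[cbind(seq_len(n), cl)]))
    if (identical(cl, assign_prev)) { converged <- TRUE; break }
    assign_prev <- cl
    for (j in seq_len(k)) {
      member <- cl == j
      if (any(member)) {
        C[j, ] <- if (update == "mean")
          colMeans(X[member, , drop = FALSE])
        else apply(X[member, , drop = FALSE], 2L, stats::median)
        C[j, 60:118] <- .wrap_angle(C[j, 60:118])
      }
    }
    if (iter >= max_iter) break
  }

  structure(list(centroids = .matrix_to_trees(C), labels = labels,
                 states = states, cluster = cl,
                 size = tabulate(cl, nbins = k),
                 objective = objective, iterations = iter,
                 converged = converged, params = params,
                 update = update),
            class = "lattice_kmeans")
}

#' Midpoint trivial tree of an interval-tree prototype
#' @param proto an `interval_tree`.
#' @return a `face_tree` whose coordinates are the interval midpoints.
#' @export
prototype_midpoint <- function(proto) {
  stopifnot(inherits(proto, "interval_tree"))
  structure(list(r = (proto$r_lo + proto$r_hi) / 2,
                 phi = (proto$phi_lo + proto$phi_hi) / 2,
                 provenance = NULL),
            class = "face_tree")
}

#' @export
print.lattice_kmeans <- function(x, ...) {
  cat("Lattice k-means state model:", length(x$centroids), "clusters ->",
      length(unique(x$states)), "states\n")
  cat(sprintf("  %d trees, %d iterations (%s), objective %.4f\n",
              length(x$cluster), x$iterations,
              if (x$converged) "converged" else "iteration cap",
              x$objective[length(x$objective)]))
  sz <- x$size
  names(sz) <- if (!is.null(x$labels)) x$labels else paste0("c", seq_along(sz))
  print(sz)
  invisible(x)
}

#' Assign behavioral states to trees with a fitted state model
#'
#' Nearest-centroid assignment under the model's metric parameters, followed
#' by the merge map (three Front subclusters to state 0).
#'
#' @param object a fitted `lattice_kmeans` model.
#' @param newdata list of `face_tree` objects (or a single tree).
#' @param ... unused.
#' @return integer vector of merged states 0-8, with the unmerged cluster
#'   index in attribute `"cluster"`.
#' @export
predict.lattice_kmeans <- function(object, newdata, ...) {
  if (inherits(newdata, "face_tree")) newdata <- list(newdata)
  X <- .trees_to_matrix(newdata)
  C <- .trees_to_matrix(object$centroids)
  D <- .dist_matrix(X, C, C, object$params)
  cl <- apply(D, 1L, which.min)
  structure(object$states[cl], cluster = cl)
}

#' @rdname predict.lattice_kmeans
#' @param trees list of `face_tree` objects.
#' @param model a fitted `lattice_kmeans` model.
#' @export
assign_states <- function(trees, model) {
  predict(model, trees)
}

#' Tabulate state counts with the Front merge
#'
#' Aggregates per-cluster counts onto the nine reported states; the Front
#' state's count is the sum of its three subcluster counts.
#'
#' @param cluster_counts named or ordered numeric vector of counts per
#'   subclass cluster (names in [POSE_SUBCLASSES] order when unnamed).
#' @return named integer vector of counts per the nine pose states, in
#'   [POSE_LABELS] order.
#' @export
merge_state_counts <- function(cluster_counts) {
  if (is.null(names(cluster_counts))) {
    if (length(cluster_counts) != length(POSE_SUBCLASSES))
      stop("unnamed counts must cover the 11 pose subclasses")
    names(cluster_counts) <- POSE_SUBCLASSES
  }
  st <- pose_state(names(cluster_counts))
  out <- vapply(0:8, function(s) sum(cluster_counts[st == s]), numeric(1L))
  names(out) <- POSE_LABELS
  out
}
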