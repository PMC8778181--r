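# Face-tree representation: 68 facial landmarks -> 59-node polar-feature tree.
#
# Landmark indexing follows the standard 68-point convention (0-based):
# jaw 0-16, left brow 17-21, right brow 22-26, nose bridge 27-30,
# lower nose 31-35, left eye 36-41, right eye 42-47, outer mouth 48-59,
# inner mouth 60-67. "Left" is image-left throughout.

# 0-based landmark index groups (converted to 1-based rows internally)
.LM <- list(
  jaw         = 0:16,
  left_brow   = 17:21,
  right_brow  = 22:26,
  nose_top    = 27L,
  nose_tip    = 30L,
  lower_nose  = 31:35,
  left_eye    = 36:41,
  right_eye   = 42:47,
  outer_mouth = 48:59,
  inner_mouth = 60:67
)

# Tree topology: nodes 1..59; primaries 1-8, secondaries 9-59.
# Parent of each secondary node (a primary id); primaries 4-8 are leaves.
.TREE_PARENT <- c(rep(0L, 8L), rep(1L, 11L), rep(2L, 11L), rep(3L, 29L))

# Child-weight group per node: 0 for primaries (weight 1 at tree level),
# 1/2/3 for secondaries under primaries 1/2/3 (weights k1/k2/k3).
.TREE_GROUP <- c(rep(0L, 8L), rep(1L, 11L), rep(2L, 11L), rep(3L, 29L))

.N_NODES <- 59L

#' Centroid of a set of planar points
#'
#' Arithmetic mean of the coordinates, used for the eye and mouth centers
#' of the face tree (the center of mass of the respective contour points).
#'
#' @param points numeric matrix with two columns (x, y), one row per point.
#' @return numeric vector of length 2, the mean (x, y).
#' @examples
#' centroid_point(rbind(c(0, 0), c(2, 0)))
#' @export
centroid_point <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 1L) stop("centroid_point: empty point set")
  if (ncol(points) != 2L) stop("centroid_point: points must be n x 2")
  colMeans(points)
}

# wrap an angle (radians) into [-pi, pi)
.wrap_angle <- function(x) {
  ((x + pi) %% (2 * pi)) - pi
}

.validate_landmarks <- function(landmarks) {
  landmarks <- as.matrix(landmarks)
  if (nrow(landmarks) != 68L || ncol(landmarks) != 2L)
    stop("landmarks must be a 68 x 2 matrix of (x, y) coordinates, got ",
         nrow(landmarks), " x ", ncol(landmarks))
  if (!all(is.finite(landmarks)))
    stop("landmarks contain non-finite coordinates")
  landmarks
}

#' Build the 59-node polar-feature face tree from 68 landmarks
#'
#' The nose, defined by its bridge-top and tip landmarks, is the tree root
#' and the unit of measurement: every feature vector's length is divided by
#' the top-to-tip nose length and every orientation is measured relative to
#' the nose direction, which makes the tree invariant to uniform scaling,
#' rotation and translation of the input.
#'
#' Primary features (nodes 1-8): nose-top to left/right eye center (centroids
#' of the 6-point eye contours), nose-tip to mouth center (centroid of the
#' 12-point outer mouth contour), and nose-tip to each of the five lower-nose
#' points. Secondary features hang off the first three primaries: nodes 9-19
#' left eye contour (6) + left brow (5), nodes 20-30 right eye (6) + right
#' brow (5), nodes 31-59 outer mouth (12) + jaw (17); each is the vector from
#' its parent's endpoint to the raw landmark, in ascending landmark order.
#'
#' @param landmarks numeric 68 x 2 matrix of (x, y) landmark coordinates in
#'   the standard 68-point order, or a length-136 vector ordered
#'   x0, y0, ..., x67, y67.
#' @param provenance optional identifier (e.g. frame id) stored on the tree.
#' @return an object of class `face_tree`: a list with numeric vectors `r`
#'   and `phi` of length 59 (node ids 1-59; the root is implicit with r = 0),
#'   all `phi` in `[-pi, pi]`.
#' @examples
#' lm <- generate_pose_landmarks("FrontProper", n = 1, noise = 0, seed = 1)[[1]]
#' tr <- build_face_tree(lm)
#' length(tr$r)
#' @export
build_face_tree <- function(landmarks, provenance = NULL) {
  if (is.numeric(landmarks) && is.null(dim(landmarks)) &&
      length(landmarks) == 136L) {
    landmarks <- matrix(landmarks, ncol = 2L, byrow = TRUE)
  }
  lm <- .validate_landmarks(landmarks)
  row <- function(idx0) lm[idx0 + 1L, , drop = FALSE]

  nose_top <- as.numeric(row(.LM$nose_top))
  nose_tip <- as.numeric(row(.LM$nose_tip))
  nose_vec <- nose_tip - nose_top
  nose_len <- sqrt(sum(nose_vec^2))
  if (nose_len <= 0 || !is.finite(nose_len))
    stop("degenerate geometry: zero-length nose vector")
  nose_ang <- atan2(nose_vec[2L], nose_vec[1L])

  left_eye_c  <- centroid_point(row(.LM$left_eye))
  right_eye_c <- centroid_point(row(.LM$right_eye))
  mouth_c     <- centroid_point(row(.LM$outer_mouth))

  # endpoint and origin of each node's vector
  origins   <- matrix(0, .N_NODES, 2L)
  endpoints <- matrix(0, .N_NODES, 2L)
  origins[1L, ] <- nose_top;  endpoints[1L, ] <- left_eye_c
  origins[2L, ] <- nose_top;  endpoints[2L, ] <- right_eye_c
  origins[3L, ] <- nose_tip;  endpoints[3L, ] <- mouth_c
  origins[4:8, ] <- matrix(nose_tip, 5L, 2L, byrow = TRUE)
  endpoints[4:8, ] <- row(.LM$lower_nose)

  sec_pts <- rbind(
    row(.LM$left_eye),  row(.LM$left_brow),
    row(.LM$right_eye), row(.LM$right_brow),
    row(.LM$outer_mouth), row(.LM$jaw)
  )
  sec_parent_end <- rbind(
    matrix(left_eye_c,  11L, 2L, byrow = TRUE),
    matrix(right_eye_c, 11L, 2L, byrow = TRUE),
    matrix(mouth_c,     29L, 2L, byrow = TRUE)
  )
  origins[9:59, ]   <- sec_parent_end
  endpoints[9:59, ] <- sec_pts

  vec <- endpoints - origins
  r   <- sqrt(rowSums(vec^2)) / nose_len
  phi <- .wrap_angle(atan2(vec[, 2L], vec[, 1L]) - nose_ang)

  structure(list(r = r, phi = phi, provenance = provenance),
            class = "face_tree")
}

#' @export
print.face_tree <- function(x, ...) {
  cat("Face tree: 59 nodes (8 primary + 51 secondary)\n")
  cat(sprintf("  r   in [%.4f, %.4f]\n", min(x$r), max(x$r)))
  cat(sprintf("  phi in [%.4f, %.4f] rad\n", min(x$phi), max(x$phi)))
  if (!is.null(x$provenance)) cat("  provenance:", x$provenance, "\n")
  invisible(x)
}

# stack a list of face_tree objects into an n x 118 matrix (r cols 1-59,
# phi cols 60-118); the internal layout used by all vectorized paths
.trees_to_matrix <- function(trees) {
  if (inherits(trees, "face_tree")) trees <- list(trees)
  stopifnot(length(trees) >= 1L)
  t(vapply(trees, function(tr) c(tr$r, tr$phi), numeric(2L * .N_NODES)))
}

.matrix_to_trees <- function(X) {
  lapply(seq_len(nrow(X)), function(i) {
    structure(list(r = X[i, 1:59], phi = X[i, 60:118], provenance = NULL),
              class = "face_tree")
  })
}

#' Export a face tree (or interval tree) to JSON
#'
#' Trees serialize as an object keyed by node id with fields `r`, `phi`
#' (intervals serialize both endpoints) and `parent`.
#'
#' @param tree a `face_tree` or `interval_tree`.
#' @param path file to write; if `NULL`, the JSON string is returned.
#' @return the JSON string, invisibly when written to a file.
#' @export
tree_to_json <- function(tree, path = NULL) {
  ids <- seq_len(.N_NODES)
  if (inherits(tree, "face_tree")) {
    obj <- lapply(ids, function(i) list(
      r = tree$r[i], phi = tree$phi[i], parent = .TREE_PARENT[i]))
  } else if (inherits(tree, "interval_tree")) {
    obj <- lapply(ids, function(i) list(
      r = c(tree$r_lo[i], tree$r_hi[i]),
      phi = c(tree$phi_lo[i], tree$phi_hi[i]),
      parent = .TREE_PARENT[i]))
  } else stop("tree must be a face_tree or interval_tree")
  names(obj) <- as.character(ids)
  txt <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = I(17))
  if (is.null(path)) return(as.character(txt))
  writeLines(as.character(txt), path)
  invisible(as.character(txt))
}

#' Read a face tree or interval tree from JSON
#'
#' @param path file written by [tree_to_json()] (or a JSON string).
#' @return a `face_tree` if all node intervals are degenerate, otherwise an
#'   `interval_tree`.
#' @export
tree_from_json <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (length(obj) != .N_NODES) stop("tree JSON must have 59 nodes")
  ids <- as.character(seq_len(.N_NODES))
  get2 <- function(field) {
    lo <- hi <- numeric(.N_NODES)
    for (i in seq_len(.N_NODES)) {
      v <- unlist(obj[[ids[i]]][[field]])
      lo[i] <- v[1L]; hi[i] <- v[length(v)]
    }
    list(lo = lo, hi = hi)
  }
  r <- get2("r"); phi <- get2("phi")
  if (all(r$lo == r$hi) && all(phi$lo == phi$hi)) {
    structure(list(r = r$lo, phi = phi$lo, provenance = NULL),
              class = "face_tree")
  } else {
    interval_tree(r$lo, r$hi, phi$lo, phi$hi)
  }
}
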