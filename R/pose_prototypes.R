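# Interval-tree prototypes for head-pose classification.
#
# Nine head poses, numbered 0-8: Front(0), UpperLeft(1), Up(2),
# UpperRight(3), Right(4), LowerRight(5), Down(6), LowerLeft(7), Left(8).
# Front splits into three subclasses (FrontLeft, FrontProper, FrontRight),
# giving 11 prototype subclasses that merge back to 9 reported labels.

#' The 11 pose subclasses (canonical prototype order)
#' @format character vector of length 11.
#' @export
POSE_SUBCLASSES <- c("FrontLeft", "FrontProper", "FrontRight",
                     "UpperLeft", "Up", "UpperRight", "Right",
                     "LowerRight", "Down", "LowerLeft", "Left")

#' The nine reported pose labels, in numeral order 0-8
#' @format character vector of length 9.
#' @export
POSE_LABELS <- c("Front", "UpperLeft", "Up", "UpperRight", "Right",
                 "LowerRight", "Down", "LowerLeft", "Left")

# merged numeral per subclass (Front subclasses -> 0)
.SUBCLASS_STATE <- c(0L, 0L, 0L, 1L, 2L, 3L, 4L, 5L, 6L, 7L, 8L)
names(.SUBCLASS_STATE) <- POSE_SUBCLASSES

#' Merge pose subclasses to the nine reported labels
#'
#' Maps the three Front subclasses to `"Front"`; other labels pass through.
#'
#' @param labels character vector of subclass or pose labels.
#' @return character vector of the nine pose labels.
#' @export
merge_pose <- function(labels) {
  out <- as.character(labels)
  out[out %in% c("FrontLeft", "FrontProper", "FrontRight")] <- "Front"
  bad <- setdiff(unique(out), POSE_LABELS)
  if (length(bad)) stop("unknown pose label(s): ", paste(bad, collapse = ", "))
  out
}

#' Numeral of a pose label
#'
#' Front = 0, UpperLeft = 1, Up = 2, UpperRight = 3, Right = 4,
#' LowerRight = 5, Down = 6, LowerLeft = 7, Left = 8. Subclass labels are
#' merged first.
#'
#' @param labels character vector of pose or subclass labels.
#' @return integer vector of state numerals 0-8.
#' @export
pose_state <- function(labels) {
  m <- merge_pose(labels)
  match(m, POSE_LABELS) - 1L
}

#' Induce an interval-tree prototype from labeled trivial trees
#'
#' Per node, the prototype's r interval is the min-max envelope of the
#' training trees' r values, and likewise for phi.
#'
#' @param trees nonempty list of `face_tree` objects of one class.
#' @param label class label stored on the prototype (if the trees carry
#'   mixed labels an error is raised when `labels` is supplied).
#' @param labels optional vector of per-tree labels used to assert purity.
#' @return an `interval_tree` prototype.
#' @export
induce_prototype <- function(trees, label = NULL, labels = NULL) {
  if (inherits(trees, "face_tree")) trees <- list(trees)
  if (length(trees) == 0L) stop("induce_prototype: empty tree list")
  if (!is.null(labels)) {
    u <- unique(as.character(labels))
    if (length(u) != 1L)
      stop("induce_prototype: mixed labels: ", paste(u, collapse = ", "))
    if (is.null(label)) label <- u
  }
  X <- .trees_to_matrix(trees)
  lo <- apply(X, 2L, min); hi <- apply(X, 2L, max)
  interval_tree(lo[1:59], hi[1:59], lo[60:118], hi[60:118], label = label)
}

#' Fit the head-pose prototype classifier
#'
#' Induces one min-max interval-tree prototype per label present in the
#' training data (up to the 11 pose subclasses) in canonical subclass order.
#'
#' @param trees list of `face_tree` training examples.
#' @param labels per-tree subclass labels (subset of [POSE_SUBCLASSES], or
#'   any label set for generic use).
#' @return an object of class `pose_prototypes` with elements `prototypes`
#'   (named list of `interval_tree`), `labels`, and `n_train` per class.
#' @seealso [predict.pose_prototypes()], [cross_validate()]
#' @export
fit_pose_prototypes <- function(trees, labels) {
  labels <- as.character(labels)
  stopifnot(length(trees) == length(labels), length(trees) >= 1L)
  u <- unique(labels)
  canon <- c(POSE_SUBCLASSES, setdiff(sort(u), POSE_SUBCLASSES))
  u <- canon[canon %in% u]
  protos <- lapply(u, function(lb)
    induce_prototype(trees[labels == lb], label = lb))
  names(protos) <- u
  structure(list(prototypes = protos, labels = u,
                 n_train = as.integer(table(factor(labels, levels = u)))),
            class = "pose_prototypes")
}

#' @export
print.pose_prototypes <- function(x, ...) {
  cat("Head-pose prototype set:", length(x$prototypes),
      "interval-tree prototypes\n")
  cat("  classes:", paste(x$labels, collapse = ", "), "\n")
  cat("  training trees per class:", paste(x$n_train, collapse = ", "), "\n")
  invisible(x)
}

#' Classify trees by the nearest interval-tree prototype
#'
#' Each tree is assigned the label of the prototype minimizing the lattice
#' tree distance; ties resolve to the lowest prototype index. For pose
#' subclass prototypes the merged nine-pose label is also reported.
#'
#' @param object a fitted [fit_pose_prototypes()] model.
#' @param newdata a list of `face_tree` objects (or a single tree).
#' @param params a [metric_params()] object; defaults to all ones.
#' @param ... unused.
#' @return a data.frame with columns `subclass`, `label` (merged if the
#'   subclasses are pose subclasses, otherwise equal to `subclass`) and
#'   `distance` (to the winning prototype).
#' @export
predict.pose_prototypes <- function(object, newdata,
                                    params = metric_params(), ...) {
  if (inherits(newdata, "face_tree")) newdata <- list(newdata)
  if (length(object$prototypes) == 0L) stop("empty prototype set")
  X <- .trees_to_matrix(newdata)
  lh <- .lo_hi_matrices(object$prototypes)
  D <- .dist_matrix(X, lh$lo, lh$hi, params)
  idx <- apply(D, 1L, which.min)
  sub <- object$labels[idx]
  merged <- if (all(object$labels %in% POSE_SUBCLASSES)) merge_pose(sub) else sub
  data.frame(subclass = sub, label = merged,
             distance = D[cbind(seq_len(nrow(D)), idx)],
             stringsAsFactors = FALSE)
}

#' Classify a tree into a head pose
#'
#' Convenience wrapper around [predict.pose_prototypes()] returning labels.
#'
#' @inheritParams predict.pose_prototypes
#' @param trees list of `face_tree` objects.
#' @param protos a `pose_prototypes` object.
#' @return character vector of merged pose labels.
#' @export
classify_pose <- function(trees, protos, params = metric_params()) {
  predict(protos, trees, params = params)$label
}

#' Stratified k-fold cross-validated pose-classification accuracy
#'
#' Folds are stratified by class and seeded; prototypes are induced on the
#' training split of each fold only. Accuracy is computed on merged labels
#' (Front subclasses count as correct when the merged pose matches).
#'
#' @param trees list of `face_tree` objects.
#' @param labels per-tree subclass labels.
#' @param params a [metric_params()] object.
#' @param folds number of folds (>= 2).
#' @param seed integer seed controlling the fold assignment.
#' @return mean accuracy over folds (scalar in `[0, 1]`), with per-fold
#'   accuracies in attribute `"folds"`.
#' @export
cross_validate <- function(trees, labels, params = metric_params(),
                           folds = 10, seed = 1) {
  labels <- as.character(labels)
  stopifnot(length(trees) == length(labels))
  if (folds < 2) stop("cross_validate: folds must be >= 2")
  if (length(unique(labels)) < 2L)
    stop("cross_validate: need at least two classes")
  if (min(table(labels)) < folds)
    stop("cross_validate: folds exceed the smallest class size")
  fold_id <- .stratified_folds(labels, folds, seed)
  acc <- vapply(seq_len(folds), function(f) {
    tr <- fold_id != f
    fit <- fit_pose_prototypes(trees[tr], labels[tr])
    pred <- predict(fit, trees[!tr], params = params)
    truth <- labels[!tr]
    if (all(fit$labels %in% POSE_SUBCLASSES)) truth <- merge_pose(truth)
    mean(pred$label == truth)
  }, numeric(1L))
  structure(mean(acc), folds = acc)
}

.stratified_folds <- function(labels, folds, seed) {
  fold_id <- integer(length(labels))
  .with_seed(seed, {
    for (lb in unique(labels)) {
      idx <- which(labels == lb)
      fold_id[idx] <- sample(rep_len(seq_len(folds), length(idx)))
    }
  })
  fold_id
}

# run code under a seeded RNG, restoring the caller's RNG state afterwards
.with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Export a prototype set to JSON
#' @param protos a `pose_prototypes` object.
#' @param path output file; if `NULL` the JSON string is returned.
#' @export
prototypes_to_json <- function(protos, path = NULL) {
  obj <- lapply(protos$prototypes, function(p)
    list(r_lo = p$r_lo, r_hi = p$r_hi,
         phi_lo = p$phi_lo, phi_hi = p$phi_hi))
  txt <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = I(17))
  if (is.null(path)) return(as.character(txt))
  writeLines(as.character(txt), path)
  invisible(as.character(txt))
}

#' Read a prototype set from JSON
#' @param path file written by [prototypes_to_json()].
#' @return a `pose_prototypes` object.
#' @export
prototypes_from_json <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  protos <- lapply(names(obj), function(lb) {
    p <- obj[[lb]]
    interval_tree(p$r_lo, p$r_hi, p$phi_lo, p$phi_hi, label = lb)
  })
  names(protos) <- names(obj)
  structure(list(prototypes = protos, labels = names(obj),
                 n_train = rep(NA_integer_, length(obj))),
            class = "pose_prototypes")
}
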