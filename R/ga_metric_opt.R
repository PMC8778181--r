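# Genetic-algorithm tuning of the 126 lattice-metric weights.
#
# A chromosome holds, in order: lambda_1..59 for r, lambda_60..118 for phi,
# k1,k2,k3 for r, k1,k2,k3 for phi, k_r, k_phi — 126 genes, each in [0, 10].
# Fitness is the stratified cross-validated pose-classification accuracy.

.N_GENES <- 126L
.GENE_BOUNDS <- c(0, 10)

#' Decode a 126-gene chromosome into metric parameters
#'
#' @param genes numeric vector of length 126 with all values in `[0, 10]`,
#'   ordered lambda(r) 1-59, lambda(phi) 60-118, k1-k3 (r), k1-k3 (phi),
#'   k_r, k_phi.
#' @return a [metric_params()] object.
#' @export
decode_chromosome <- function(genes) {
  genes <- as.numeric(genes)
  if (length(genes) != .N_GENES)
    stop("chromosome must have exactly 126 genes, got ", length(genes))
  if (any(!is.finite(genes)) || any(genes < .GENE_BOUNDS[1]) ||
      any(genes > .GENE_BOUNDS[2]))
    stop("chromosome genes must lie in [0, 10]")
  metric_params(lambda_r = genes[1:59], lambda_phi = genes[60:118],
                k_r123 = genes[119:121], k_phi123 = genes[122:124],
                k_r = genes[125], k_phi = genes[126])
}

#' Encode metric parameters as a 126-gene chromosome
#'
#' Inverse of [decode_chromosome()].
#'
#' @param params a [metric_params()] object.
#' @return numeric vector of length 126.
#' @export
encode_params <- function(params) {
  .validate_params(params)
  c(params$lambda_r, params$lambda_phi, params$k_r123, params$k_phi123,
    params$k_r, params$k_phi)
}

#' Optimize the lattice-metric weights with a genetic algorithm
#'
#' Real-coded GA over the 126 metric weights, maximizing the stratified
#' k-fold cross-validated pose accuracy on the supplied labeled trees.
#' Tournament selection, uniform crossover, per-gene Gaussian mutation with
#' clipping to `[0, 10]`, and elitist carryover of the single best
#' chromosome, so the best-so-far fitness never decreases. Fitness values
#' are cached per chromosome; the cross-validation fold assignment is fixed
#' by `seed` so fitness is a deterministic function of the genes.
#'
#' @param trees list of `face_tree` training examples.
#' @param labels per-tree subclass labels.
#' @param population population size (>= 2). Desk-scale default 50; the
#'   full-scale setting is 500.
#' @param generations number of generations (>= 1). Desk-scale default 10;
#'   full scale 50.
#' @param folds cross-validation folds for the fitness (default 10).
#' @param seed integer seed for the whole run.
#' @param p_crossover probability of uniform crossover per mating pair.
#' @param mut_sigma standard deviation of the Gaussian gene mutation.
#' @param mut_rate per-gene mutation probability (default 1/126).
#' @param tournament tournament size for selection.
#' @param include_default if `TRUE`, the all-ones (default-metric) chromosome
#'   is injected into generation 0, so the final fitness is never below the
#'   default metric's accuracy.
#' @return object of class `metric_ga`: `params` (best [metric_params()]),
#'   `fitness` (its accuracy), `history` (data.frame with per-generation
#'   best and mean fitness) and the configuration.
#' @export
optimize_metric <- function(trees, labels, population = 50, generations = 10,
                            folds = 10, seed = 1, p_crossover = 0.9,
                            mut_sigma = 0.5, mut_rate = 1 / 126,
                            tournament = 3, include_default = TRUE) {
  labels <- as.character(labels)
  stopifnot(length(trees) == length(labels))
  if (population < 2) stop("optimize_metric: population must be >= 2")
  if (generations < 1) stop("optimize_metric: generations must be >= 1")
  if (min(table(labels)) < folds)
    stop("optimize_metric: folds exceed the smallest class size")

  # precompute fold split and matrices once: fitness is then deterministic
  fold_id <- .stratified_folds(labels, folds, seed)
  X <- .trees_to_matrix(trees)
  cache <- new.env(parent = emptyenv())
  fitness <- function(genes) {
    key <- paste(sprintf("%.17g", genes), collapse = ",")
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    val <- .cv_accuracy_fast(X, labels, decode_chromosome(genes),
                             fold_id, folds)
    cache[[key]] <- val
    val
  }

  res <- .with_seed(seed + 1L, {
    pop <- lapply(seq_len(population), function(i)
      stats::runif(.N_GENES, .GENE_BOUNDS[1], .GENE_BOUNDS[2]))
    if (include_default) pop[[1L]] <- rep(1, .N_GENES)
    fit <- vapply(pop, fitness, numeric(1L))
    hist_best <- numeric(generations + 1L)
    hist_mean <- numeric(generations + 1L)
    hist_best[1L] <- max(fit); hist_mean[1L] <- mean(fit)
    for (g in seq_len(generations)) {
      elite_i <- which.max(fit)
      newpop <- vector("list", population)
      newpop[[1L]] <- pop[[elite_i]]
      i <- 2L
      while (i <= population) {
        p1 <- .tournament_pick(fit, tournament)
        p2 <- .tournament_pick(fit, tournament)
        c1 <- pop[[p1]]; c2 <- pop[[p2]]
        if (stats::runif(1) < p_crossover) {
          mask <- stats::runif(.N_GENES) < 0.5
          tmp <- c1[mask]; c1[mask] <- c2[mask]; c2[mask] <- tmp
        }
        newpop[[i]] <- .mutate_genes(c1, mut_sigma, mut_rate)
        i <- i + 1L
        if (i <= population) {
          newpop[[i]] <- .mutate_genes(c2, mut_sigma, mut_rate)
          i <- i + 1L
        }
      }
      pop <- newpop
      fit <- vapply(pop, fitness, numeric(1L))
      hist_best[g + 1L] <- max(hist_best[g], max(fit))
      hist_mean[g + 1L] <- mean(fit)
      # elitism: the carried-over elite guarantees max(fit) >= hist_best[g]
    }
    best_i <- which.max(fit)
    list(best = pop[[best_i]], fit = fit[best_i],
         history = data.frame(generation = 0:generations,
                              best = hist_best, mean = hist_mean))
  })

  structure(list(params = decode_chromosome(res$best),
                 chromosome = res$best, fitness = res$fit,
                 history = res$history,
                 config = list(population = population,
                               generations = generations, folds = folds,
                               seed = seed, p_crossover = p_crossover,
                               mut_sigma = mut_sigma, mut_rate = mut_rate,
                               tournament = tournament)),
            class = "metric_ga")
}

.tournament_pick <- function(fit, k) {
  cand <- sample.int(length(fit), k, replace = TRUE)
  cand[which.max(fit[cand])]
}

.mutate_genes <- function(genes, sigma, rate) {
  hit <- stats::runif(.N_GENES) < rate
  if (any(hit))
    genes[hit] <- pmin(pmax(genes[hit] + stats::rnorm(sum(hit), 0, sigma),
                            .GENE_BOUNDS[1]), .GENE_BOUNDS[2])
  genes
}

# vectorized CV accuracy on a precomputed tree matrix and fold assignment
.cv_accuracy_fast <- function(X, labels, params, fold_id, folds) {
  merged_all <- if (all(unique(labels) %in% POSE_SUBCLASSES))
    merge_pose(labels) else labels
  canon <- c(POSE_SUBCLASSES, setdiff(sort(unique(labels)), POSE_SUBCLASSES))
  acc <- vapply(seq_len(folds), function(f) {
    tr <- fold_id != f
    lb_tr <- labels[tr]
    u <- canon[canon %in% unique(lb_tr)]
    lo <- matrix(0, length(u), 118L); hi <- matrix(0, length(u), 118L)
    for (j in seq_along(u)) {
      Xu <- X[tr, , drop = FALSE][lb_tr == u[j], , drop = FALSE]
      lo[j, ] <- apply(Xu, 2L, min); hi[j, ] <- apply(Xu, 2L, max)
    }
    D <- .dist_matrix(X[!tr, , drop = FALSE], lo, hi, params)
    pred <- u[apply(D, 1L, which.min)]
    merged_pred <- if (all(u %in% POSE_SUBCLASSES)) merge_pose(pred) else pred
    mean(merged_pred == merged_all[!tr])
  }, numeric(1L))
  mean(acc)
}

#' @export
print.metric_ga <- function(x, ...) {
  cat("GA-optimized lattice-metric parameters\n")
  cat(sprintf("  population %d, generations %d, folds %d, seed %d\n",
              x$config$population, x$config$generations, x$config$folds,
              x$config$seed))
  cat(sprintf("  best cross-validated accuracy: %.4f\n", x$fitness))
  invisible(x)
}

#' @export
plot.metric_ga <- function(x, ...) {
  graphics::plot(x$history$generation, x$history$best, type = "s",
                 ylim = range(c(x$history$best, x$history$mean)),
                 xlab = "generation", ylab = "CV accuracy",
                 main = "GA fitness history", ...)
  graphics::lines(x$history$generation, x$history$mean, lty = 2)
  graphics::legend("bottomright", legend = c("best-so-far", "mean"),
                   lty = c(1, 2), bty = "n")
  invisible(x)
}
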