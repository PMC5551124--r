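#' @name cluster_engine
#' @title Multi-restart k-means and the decrease-in-overall-deviation (DiD)
#'
#' @description
#' Locations are partitioned by k-means in the space of the z-scaled selected
#' covariates. Because Lloyd's algorithm converges to local optima, the
#' clustering is restarted many times from random initial centers and the
#' restart with the lowest total within-cluster sum of squares (SSW) is kept.
#' The number of clusters is guided by the DiD statistic: the percent
#' reduction of within-cluster relative to total variability, averaged over a
#' set of characteristics — 0 when all locations share one cluster, 100 when
#' every location is its own.
NULL

as_feature_matrix <- function(features) {
  if (is.matrix(features)) return(features)
  m <- as.matrix(features[feature_vars(features)])
  rownames(m) <- features$location_id
  m
}

# n x K matrix of squared Euclidean distances
dist2_to_centers <- function(X, centers) {
  d <- outer(rowSums(X^2), rep(1, nrow(centers))) +
    outer(rep(1, nrow(X)), rowSums(centers^2)) - 2 * X %*% t(centers)
  pmax(d, 0)
}

# One Lloyd run from given centers; assignments to the nearest center
# (lowest index on ties), centers recomputed as means, empty clusters
# reseeded at the point currently farthest from its assigned center.
lloyd <- function(X, centers, max_iter = 200L) {
  n <- nrow(X)
  K <- nrow(centers)
  assignment <- integer(n)
  trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    d2 <- dist2_to_centers(X, centers)
    new_assignment <- max.col(-d2, ties.method = "first")
    empty <- setdiff(seq_len(K), unique(new_assignment))
    if (length(empty)) {
      point_d2 <- d2[cbind(seq_len(n), new_assignment)]
      for (k in empty) {
        far <- which.max(point_d2)
        centers[k, ] <- X[far, ]
        new_assignment[far] <- k
        point_d2[far] <- 0
      }
      d2 <- dist2_to_centers(X, centers)
      new_assignment <- max.col(-d2, ties.method = "first")
    }
    trace <- c(trace, sum(d2[cbind(seq_len(n), new_assignment)]))
    converged <- it > 1 && all(new_assignment == assignment)
    assignment <- new_assignment
    for (k in seq_len(K)) {
      members <- assignment == k
      # a cluster can lose all members when another was reseeded this
      # iteration; keep its center so next iteration's reseed can handle it
      if (any(members)) centers[k, ] <- colMeans(X[members, , drop = FALSE])
    }
    if (converged) break
  }
  ssw_total <- sum((X - centers[assignment, , drop = FALSE])^2)
  list(assignment = assignment, centers = centers, total_ssw = ssw_total,
       n_iterations = it, ssw_trace = trace)
}

ssw_matrix <- function(X, assignment) {
  K <- max(assignment)
  out <- matrix(0, ncol(X), K, dimnames = list(colnames(X), paste0("k", seq_len(K))))
  for (k in seq_len(K)) {
    Xk <- X[assignment == k, , drop = FALSE]
    out[, k] <- colSums((Xk - rep(colMeans(Xk), each = nrow(Xk)))^2)
  }
  out
}

#' Best-of-many-restarts k-means
#'
#' Runs Lloyd's algorithm `n_restarts` times, each initialized from `K`
#' distinct data rows sampled at random, and keeps the solution with the
#' lowest total within-cluster sum of squares. Deterministic for a given
#' seed: the restart initializations are the only use of randomness.
#'
#' @param features Scaled feature tibble (`location_id` + covariate columns)
#'   from [zscale()], or a plain numeric matrix.
#' @param K Number of clusters (between 1 and the number of distinct rows).
#' @param n_restarts Number of random initializations.
#' @param seed Integer seed.
#' @param max_iter Iteration cap per restart (convergence is assignment
#'   stability, normally reached much earlier).
#' @return A `cluster_solution`: `K`, `assignment` (cluster index per
#'   location), `location_id`, `centers` (K x J, scaled space), `ssw`
#'   (per-characteristic-per-cluster J x K matrix), `total_ssw`,
#'   `n_iterations` and `restart_index` of the winning restart, and its
#'   per-iteration `ssw_trace`.
#' @export
kmeans_best <- function(features, K, n_restarts = 1000L, seed = 1L,
                        max_iter = 200L) {
  X <- as_feature_matrix(features)
  if (nrow(X) == 0) abort("empty input", class = "sitenet_cluster_error")
  n_distinct_rows <- nrow(unique(X))
  if (K < 1 || K > n_distinct_rows) {
    abort(paste0("K must be between 1 and the number of distinct rows (",
                 n_distinct_rows, ")"), class = "sitenet_cluster_error")
  }
  set.seed(seed)
  best <- NULL
  if (K == 1) {
    ctr <- matrix(colMeans(X), 1, ncol(X), dimnames = list(NULL, colnames(X)))
    best <- list(assignment = rep(1L, nrow(X)), centers = ctr,
                 total_ssw = sum((X - rep(colMeans(X), each = nrow(X)))^2),
                 n_iterations = 1L, ssw_trace = numeric(0), restart = 1L)
  } else {
    dup <- duplicated(X)
    candidates_idx <- which(!dup)
    for (r in seq_len(n_restarts)) {
      init <- X[sample(candidates_idx, K), , drop = FALSE]
      run <- lloyd(X, init, max_iter = max_iter)
      if (is.null(best) || run$total_ssw < best$total_ssw) {
        best <- c(run, restart = r)
      }
    }
  }
  structure(
    list(K = as.integer(K),
         assignment = best$assignment,
         location_id = rownames(X),
         centers = best$centers,
         ssw = ssw_matrix(X, best$assignment),
         total_ssw = best$total_ssw,
         n_iterations = best$n_iterations,
         restart_index = best$restart,
         ssw_trace = best$ssw_trace,
         n_restarts = n_restarts,
         seed = as.integer(seed)),
    class = "cluster_solution")
}

#' @export
print.cluster_solution <- function(x, ...) {
  cat("k-means solution: K =", x$K, ", n =", length(x$assignment),
      ", total SSW =", format(x$total_ssw, digits = 6),
      "(best of", x$n_restarts, "restarts )\n")
  print(table(cluster = x$assignment))
  invisible(x)
}

#' @method tidy cluster_solution
#' @export
tidy.cluster_solution <- function(x, ...) {
  tibble(cluster = seq_len(x$K),
         size = as.integer(tabulate(x$assignment, x$K)),
         ssw = colSums(x$ssw))
}

#' @method glance cluster_solution
#' @export
glance.cluster_solution <- function(x, ...) {
  tibble(K = x$K, total_ssw = x$total_ssw, n_iterations = x$n_iterations,
         restart_index = x$restart_index, n_restarts = x$n_restarts)
}

#' Decrease in overall deviation of a partition
#'
#' For characteristics `Y` (locations x J), computes
#' `100 * (1 - (1/J) * sum_j sum_k SSW_jk / SSE_j)`, where `SSW_jk` is the
#' within-cluster sum of squares of characteristic j in cluster k and
#' `SSE_j` its total sum of squares about the grand mean. Ranges from 0
#' (single cluster) to 100 (each location its own cluster).
#'
#' @param assignment Cluster index per location, or a `cluster_solution`.
#' @param characteristics Numeric matrix or tibble of characteristics, rows
#'   aligned with the assignment. Constant columns are rejected.
#' @return DiD in percent.
#' @export
did <- function(assignment, characteristics) {
  if (inherits(assignment, "cluster_solution")) assignment <- assignment$assignment
  Y <- if (is.matrix(characteristics)) characteristics else
    as.matrix(as_tibble(characteristics)[vapply(as_tibble(characteristics),
                                                is.numeric, logical(1))])
  stopifnot(length(assignment) == nrow(Y))
  sse <- colSums((Y - rep(colMeans(Y), each = nrow(Y)))^2)
  if (any(sse == 0)) {
    abort("constant characteristic column (zero SSE)", class = "sitenet_cluster_error")
  }
  ssw <- ssw_matrix(Y, assignment)
  100 * (1 - mean(rowSums(ssw) / sse))
}

#' DiD against the number of clusters
#'
#' For each k from 1 to `k_max`, clusters all locations on the scaled
#' selected covariates with [kmeans_best()] and evaluates the DiD twice:
#' with the predicted concentrations as the single characteristic (J = 1)
#' and with the selected covariates themselves (J = 5 in the standard
#' design). The number of clusters is then chosen at the beginning of the
#' common plateau of the two curves ([suggest_k()] automates this; the
#' choice remains user-overridable).
#'
#' @inheritParams kmeans_best
#' @param predictions Numeric vector of predicted concentrations at the same
#'   locations (from [predict.lur_model()]).
#' @param k_max Largest cluster count to evaluate.
#' @return A `did_curve` tibble: `k`, `did_predictions`, `did_covariates`,
#'   `total_ssw`.
#' @export
did_curve <- function(features, predictions, k_max = 50L, n_restarts = 1000L,
                      seed = 1L) {
  stopifnot(k_max >= 2)
  X <- as_feature_matrix(features)
  stopifnot(length(predictions) == nrow(X))
  set.seed(seed)
  k_seeds <- sample.int(.Machine$integer.max - 1L, k_max)
  rows <- purrr::map(seq_len(k_max), function(k) {
    sol <- kmeans_best(X, k, n_restarts = n_restarts, seed = k_seeds[k])
    tibble(k = k,
           did_predictions = did(sol$assignment, matrix(predictions, ncol = 1)),
           did_covariates = did(sol$assignment, X),
           total_ssw = sol$total_ssw)
  })
  out <- bind_rows(rows)
  class(out) <- c("did_curve", class(out))
  out
}

#' Suggest the number of clusters from a DiD curve
#'
#' Advisory plateau rule: the smallest k (at least 2) from which the forward
#' marginal DiD gains of *both* curves stay below `threshold` percentage
#' points over a `lookahead` window. Falls back to the largest k evaluated,
#' with a warning, when no plateau is found.
#'
#' @param curve A `did_curve`.
#' @param threshold Maximum marginal gain (DiD percentage points) still
#'   counted as plateau.
#' @param lookahead Number of consecutive forward gains inspected.
#' @return Suggested k.
#' @export
suggest_k <- function(curve, threshold = 1, lookahead = 3L) {
  ks <- curve$k
  for (k in ks[ks >= 2]) {
    idx <- which(ks > k & ks <= k + lookahead)
    gains <- c(curve$did_predictions[idx] - curve$did_predictions[idx - 1L],
               curve$did_covariates[idx] - curve$did_covariates[idx - 1L])
    if (length(gains) && all(gains < threshold)) return(k)
  }
  warn("no DiD plateau found; returning the largest k evaluated")
  max(ks)
}

#' Per-cluster profiles of the scaled covariates
#'
#' Mean of every scaled covariate within each cluster — the matrix behind
#' the cluster-characterisation heatmap. On scaled data the size-weighted
#' average of the rows is the zero vector.
#'
#' @param assignment Cluster index per location, or a `cluster_solution`.
#' @param features Scaled feature tibble or matrix, rows aligned.
#' @return Tibble: `cluster`, `size`, one column per covariate.
#' @export
cluster_profiles <- function(assignment, features) {
  if (inherits(assignment, "cluster_solution")) assignment <- assignment$assignment
  X <- as_feature_matrix(features)
  stopifnot(length(assignment) == nrow(X))
  K <- max(assignment)
  sizes <- tabulate(assignment, K)
  if (any(sizes == 0)) abort("empty cluster", class = "sitenet_cluster_error")
  prof <- t(vapply(seq_len(K),
                   function(k) colMeans(X[assignment == k, , drop = FALSE]),
                   numeric(ncol(X))))
  colnames(prof) <- colnames(X)
  dplyr::bind_cols(tibble(cluster = seq_len(K), size = as.integer(sizes)),
                   as_tibble(prof))
}
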