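#' Adjusted Rand index between two partitions
#'
#' Chance-corrected pair-counting agreement (Hubert-Arabie form) computed
#' from the contingency table of the two partitions: 1 for identical
#' partitions, about 0 for agreement expected by chance. Values above 0.90,
#' 0.80 and 0.65 are conventionally read as excellent, good and moderate
#' agreement.
#'
#' @param a,b Cluster labels over the same items (any label types).
#' @return The adjusted Rand index (at most 1; can be slightly negative).
#' @export
adjusted_rand <- function(a, b) {
  if (length(a) != length(b)) {
    abort("partitions cover different numbers of items", class = "sitenet_ari_error")
  }
  n <- length(a)
  if (n < 2) abort("need at least two items", class = "sitenet_ari_error")
  tab <- table(a, b)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  n_pairs <- choose(n, 2)
  expected <- sum_a * sum_b / n_pairs
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)  # both partitions trivial
  (sum_ij - expected) / (max_index - expected)
}

#' Clustering robustness under subsampling
#'
#' Repeats the k-means clustering on random subsamples (90% of the locations
#' by default), and compares each subsample solution with the full-data
#' solution, restricted to the retained locations, via the adjusted Rand
#' index. Per-replicate seeds are derived from the master seed so individual
#' replicates are reproducible.
#'
#' @param features Scaled feature tibble or matrix (all locations).
#' @param reference A full-data `cluster_solution` on `features` (computed
#'   with `K` and `n_restarts` if omitted).
#' @param K Number of clusters.
#' @param n_reps Number of subsample replicates.
#' @param keep_frac Fraction of locations retained per replicate, in (0, 1].
#' @param n_restarts Restarts per replicate clustering.
#' @param seed Master seed.
#' @return A `stability_report`: `replicates` tibble (`replicate`, `ari`)
#'   and a `summary` row (mean/min/max ARI, fraction at or above 0.90,
#'   fraction below 0.65).
#' @export
subsample_stability <- function(features, K, reference = NULL, n_reps = 100L,
                                keep_frac = 0.90, n_restarts = 1000L,
                                seed = 1L) {
  if (keep_frac <= 0 || keep_frac > 1) {
    abort("keep_frac must be in (0, 1]", class = "sitenet_stability_error")
  }
  X <- as_feature_matrix(features)
  if (is.null(reference)) {
    reference <- kmeans_best(X, K, n_restarts = n_restarts, seed = seed)
  }
  stopifnot(inherits(reference, "cluster_solution"),
            length(reference$assignment) == nrow(X))
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, n_reps)
  n_keep <- max(2L, round(keep_frac * nrow(X)))
  ari <- vapply(seq_len(n_reps), function(r) {
    set.seed(rep_seeds[r])
    keep <- sort(sample.int(nrow(X), n_keep))
    sub <- kmeans_best(X[keep, , drop = FALSE], K, n_restarts = n_restarts,
                       seed = rep_seeds[r])
    adjusted_rand(sub$assignment, reference$assignment[keep])
  }, numeric(1))
  replicates <- tibble(replicate = seq_len(n_reps), ari = ari)
  structure(
    list(replicates = replicates,
         summary = tibble(n_reps = n_reps, keep_frac = keep_frac,
                          mean_ari = mean(ari), min_ari = min(ari),
                          max_ari = max(ari),
                          frac_excellent = mean(ari >= 0.90),
                          frac_below_moderate = mean(ari < 0.65)),
         K = K, seed = seed),
    class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "Clustering stability (K = %d, %d reps, %.0f%% subsamples):\n", x$K,
    s$n_reps, 100 * s$keep_frac))
  cat(sprintf("  mean ARI %.3f (range %.3f-%.3f); %.0f%% >= 0.90 (excellent), %.0f%% < 0.65 (below moderate)\n",
              s$mean_ari, s$min_ari, s$max_ari, 100 * s$frac_excellent,
              100 * s$frac_below_moderate))
  invisible(x)
}

#' @method tidy stability_report
#' @export
tidy.stability_report <- function(x, ...) x$replicates

#' @method glance stability_report
#' @export
glance.stability_report <- function(x, ...) x$summary
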