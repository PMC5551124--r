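#' Current-to-subject proportion of a cluster
#'
#' The proportion of existing monitors ("current" locations) to residences
#' ("subject" locations) in a cluster, multiplied by 10^4 for display. A low
#' value flags a cluster whose residences are under-represented by monitors.
#'
#' @param n_current,n_subject Counts (vectorized); `n_subject` must be > 0.
#' @return `10^4 * n_current / n_subject`.
#' @export
current_subject_ratio <- function(n_current, n_subject) {
  if (any(n_subject <= 0)) abort("n_subject must be > 0", class = "sitenet_alloc_error")
  1e4 * n_current / n_subject
}

#' Allocate new monitoring sites to clusters
#'
#' Greedy allocation of `n_new` new monitoring sites: at each step, among
#' clusters that still have candidate locations (and any subjects), the
#' cluster with the minimum unrounded current-to-subject proportion receives
#' one site. The placed site then counts as a current location, so the
#' proportions are recomputed before the next pick. Clusters with no
#' remaining candidates are skipped regardless of their proportion.
#'
#' @param counts Tibble with columns `cluster`, `n_current`, `n_subject`,
#'   `n_candidate` (e.g. from [cluster_location_counts()] or
#'   [load_cluster_counts()]).
#' @param n_new Number of new sites to place.
#' @param tie_rule `"lowest_index"` (default, deterministic) or `"random"`
#'   when several clusters share the minimum proportion.
#' @param seed Seed used for random tie-breaks and candidate draws.
#' @param candidate_pool Optional tibble (`location_id`, `cluster`) of
#'   concrete candidate locations; when supplied, each pick also draws a
#'   location uniformly at random from the chosen cluster's remaining pool.
#' @return An `allocation` object: `counts` (input plus `new_sites` and the
#'   final display `ratio`), `log` (one row per pick: `step`, `cluster`,
#'   `ratio_before` on the x 10^4 scale, and `location_id` if a pool was
#'   given), `n_new`, `tie_rule`.
#' @export
allocate <- function(counts, n_new = 20L, tie_rule = c("lowest_index", "random"),
                     seed = 1L, candidate_pool = NULL) {
  tie_rule <- match.arg(tie_rule)
  stopifnot(all(c("cluster", "n_current", "n_subject", "n_candidate") %in% names(counts)))
  if (any(counts$n_current < 0 | counts$n_subject < 0 | counts$n_candidate < 0)) {
    abort("counts must be non-negative", class = "sitenet_alloc_error")
  }
  available <- sum(counts$n_candidate[counts$n_subject > 0])
  if (available < n_new) {
    abort(paste0("site_allocator: only ", available,
                 " candidate locations available in eligible clusters, but n_new = ",
                 n_new), class = "sitenet_alloc_error")
  }
  set.seed(seed)
  cur <- counts$n_current
  cand <- counts$n_candidate
  sub <- counts$n_subject
  new_sites <- integer(nrow(counts))
  pool <- candidate_pool
  log <- vector("list", n_new)
  for (s in seq_len(n_new)) {
    eligible <- cand > 0 & sub > 0
    prop <- ifelse(eligible, cur / sub, Inf)
    hit <- which(prop == min(prop))
    k <- if (length(hit) == 1 || tie_rule == "lowest_index") hit[1] else
      hit[sample.int(length(hit), 1)]
    picked_id <- NA_character_
    if (!is.null(pool)) {
      in_k <- which(pool$cluster == counts$cluster[k])
      picked <- if (length(in_k) == 1) in_k else in_k[sample.int(length(in_k), 1)]
      picked_id <- pool$location_id[picked]
      pool <- pool[-picked, ]
    }
    log[[s]] <- tibble(step = s, cluster = counts$cluster[k],
                       ratio_before = 1e4 * cur[k] / sub[k],
                       location_id = picked_id)
    new_sites[k] <- new_sites[k] + 1L
    cand[k] <- cand[k] - 1L
    cur[k] <- cur[k] + 1L
  }
  out_counts <- counts %>%
    mutate(ratio = ifelse(.data$n_subject > 0,
                          1e4 * .data$n_current / .data$n_subject, NA_real_),
           new_sites = new_sites)
  structure(list(counts = out_counts, log = bind_rows(log),
                 n_new = as.integer(n_new), tie_rule = tie_rule, seed = seed),
            class = "allocation")
}

#' Randomly pick a candidate location from a pool
#'
#' Uniform draw (without replacement semantics are the caller's: remove the
#' returned id before drawing again). Deterministic for a given seed.
#'
#' @param pool Character vector of candidate location ids (nonempty).
#' @param seed Integer seed.
#' @return One location id.
#' @export
pick_candidate <- function(pool, seed = 1L) {
  if (length(pool) == 0) abort("empty candidate pool", class = "sitenet_alloc_error")
  set.seed(seed)
  pool[sample.int(length(pool), 1)]
}

#' Cross-tabulate location roles by cluster
#'
#' @param locations Location tibble (`id`, `role`, ...).
#' @param solution A `cluster_solution` over the same locations (or an
#'   assignment vector aligned with `locations`).
#' @return Counts tibble ready for [allocate()]: `cluster`, `n_current`,
#'   `n_subject`, `n_candidate`.
#' @export
cluster_location_counts <- function(locations, solution) {
  assignment <- if (inherits(solution, "cluster_solution")) solution$assignment else solution
  stopifnot(length(assignment) == nrow(locations))
  K <- max(assignment)
  tibble(cluster = seq_len(K)) %>%
    mutate(n_current = tabulate(assignment[locations$role == "current"], K),
           n_subject = tabulate(assignment[locations$role == "subject"], K),
           n_candidate = tabulate(assignment[locations$role == "candidate"], K))
}

#' @export
print.allocation <- function(x, digits = 1, ...) {
  cat("Allocation of", x$n_new, "new monitoring sites\n")
  tab <- x$counts %>%
    mutate(ratio = round(.data$ratio, digits))
  print(as.data.frame(tab), row.names = FALSE)
  invisible(x)
}

#' @method tidy allocation
#' @export
tidy.allocation <- function(x, ...) as_tibble(x$counts)

#' @method glance allocation
#' @export
glance.allocation <- function(x, ...) {
  tibble(n_new = x$n_new, n_clusters = nrow(x$counts),
         n_clusters_receiving = sum(x$counts$new_sites > 0),
         tie_rule = x$tie_rule)
}
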