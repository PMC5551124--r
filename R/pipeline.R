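#' Configure an end-to-end monitoring-design run
#'
#' Bundles every stage parameter of [run_pipeline()]. Defaults follow the
#' standard design: daily averages need 18 of 24 hours, annual averages need
#' 10 months / at most 91 missing days / missing runs under 45 days; forward
#' selection is capped at five variables with VIF <= 10 and |r| <= 0.7;
#' k-means uses 1000 restarts with DiD evaluated for k = 1..50; and 20 new
#' sites are allocated. Tests and examples scale `n_restarts`, `k_max` and
#' the city size down explicitly.
#'
#' @param city A [city_config()] describing the synthetic inputs.
#' @param seed Master seed for every stochastic stage.
#' @param out_dir Directory for stage artifacts (CSV) and the manifest.
#' @param min_hours,min_months,max_missing_days,max_consecutive Completeness
#'   thresholds, see [daily_averages()] and [site_eligibility()].
#' @param selection A [selection_config()].
#' @param K Fixed number of clusters; `NULL` to take [suggest_k()]'s advice.
#' @param k_max,did_threshold,did_lookahead DiD-curve settings.
#' @param n_restarts Restarts per k-means run.
#' @param n_new Number of new monitoring sites to allocate.
#' @param tie_rule Allocation tie rule, see [allocate()].
#' @param stability_reps,stability_keep_frac Subsample-stability settings
#'   (`stability_reps = 0` skips the stage).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(city = city_config(),
                            seed = 1L,
                            out_dir = tempfile("sitenet_run_"),
                            min_hours = 18, min_months = 10,
                            max_missing_days = 91, max_consecutive = 45,
                            selection = selection_config(),
                            K = NULL, k_max = 50L,
                            did_threshold = 1, did_lookahead = 3L,
                            n_restarts = 1000L,
                            n_new = 20L, tie_rule = "lowest_index",
                            stability_reps = 100L,
                            stability_keep_frac = 0.90) {
  stopifnot(inherits(city, "city_config"), inherits(selection, "selection_config"))
  structure(as.list(environment()), class = "pipeline_config")
}

write_artifact <- function(x, out_dir, name) {
  path <- file.path(out_dir, name)
  readr::write_csv(x, path)
  path
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(paste0("pipeline stage '", name, "' failed: ", conditionMessage(e)),
          class = "sitenet_pipeline_error", parent = e)
  })
}

#' Run the monitoring-network design pipeline
#'
#' Executes the stages in order — simulate, qc, features, lur, cluster,
#' allocate, stability — writing each stage's tabular artifacts under
#' `config$out_dir` and returning the in-memory results plus a manifest with
#' a parameter echo and MD5 content hashes. Rerunning with the same
#' configuration reproduces the hashes.
#'
#' @param config A [pipeline_config()].
#' @return A `sitenet_pipeline` object: `city`, `annual`, `screened`
#'   (feature screening report), `model`, `predictions`, `curve`
#'   (`NULL` when `K` is fixed), `K`, `solution`, `profiles`, `allocation`,
#'   `stability`, and `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  artifacts <- character()

  city <- run_stage("simulate", {
    city <- generate_city(config$city)
    artifacts["locations"] <- write_artifact(city$locations, config$out_dir, "locations.csv")
    artifacts["features"] <- write_artifact(city$features, config$out_dir, "features.csv")
    city
  })

  annual <- run_stage("qc", {
    cur <- filter(city$locations, .data$role == "current")
    truth <- city$concentration$value[match(cur$id, city$concentration$location_id)]
    hourly <- purrr::map2(cur$id, truth, function(sid, mu) {
      generate_hourly_series(seed = config$seed + match(sid, cur$id),
                             sites = sid, mean_level = mu)
    }) %>% bind_rows()
    annual <- site_eligibility(daily_averages(hourly, min_hours = config$min_hours),
                               min_months = config$min_months,
                               max_missing_days = config$max_missing_days,
                               max_consecutive = config$max_consecutive)
    artifacts["annual"] <- write_artifact(annual, config$out_dir, "annual.csv")
    annual
  })

  screened <- run_stage("features", {
    exclude_low_variability(city$features)
  })
  artifacts["feature_report"] <- write_artifact(screened$report, config$out_dir,
                                                "feature_screening.csv")

  model <- run_stage("lur", {
    cur <- filter(city$locations, .data$role == "current")
    monitors <- screened$features %>%
      filter(.data$location_id %in% cur$id) %>%
      left_join(annual %>% filter(.data$eligible) %>%
                  select("site_id", "annual_mean"),
                by = c(location_id = "site_id")) %>%
      filter(!is.na(.data$annual_mean))
    cands <- setdiff(names(monitors), c("location_id", "annual_mean"))
    # density covariates can be constant over the few monitor locations even
    # when variable city-wide; they cannot enter the regression
    cands <- cands[vapply(monitors[cands], sd, numeric(1)) > 0]
    model <- forward_select(monitors, "annual_mean", candidates = cands,
                            config = config$selection)
    writeLines(jsonlite::toJSON(list(
      variables = model$variables, intercept = model$intercept,
      coefficients = as.list(model$coefficients),
      p_values = as.list(model$p_values),
      r_squared = model$r_squared, loocv_r2 = model$loocv_r2,
      std_coefficients = model$std_coefficients,
      percentiles = "p90 - p10, linear interpolation (type 7)"),
      auto_unbox = TRUE, digits = NA),
      file.path(config$out_dir, "lur_model.json"))
    artifacts["lur_model"] <- file.path(config$out_dir, "lur_model.json")
    model
  })

  clusterres <- run_stage("cluster", {
    if (length(model$variables) == 0) {
      abort("no variables selected; cannot cluster on an empty covariate set")
    }
    selected <- screened$features[, c("location_id", model$variables)]
    scaled <- zscale(selected)
    predictions <- predict(model, screened$features)
    curve <- NULL
    K <- config$K
    if (is.null(K)) {
      curve <- did_curve(scaled, predictions, k_max = config$k_max,
                         n_restarts = config$n_restarts, seed = config$seed)
      artifacts["did_curve"] <- write_artifact(as_tibble(curve), config$out_dir,
                                                "did_curve.csv")
      K <- suggest_k(curve, threshold = config$did_threshold,
                     lookahead = config$did_lookahead)
    }
    solution <- kmeans_best(scaled, K, n_restarts = config$n_restarts,
                            seed = config$seed)
    profiles <- cluster_profiles(solution, scaled)
    artifacts["assignment"] <- write_artifact(
      tibble(location_id = solution$location_id, cluster = solution$assignment),
      config$out_dir, "assignment.csv")
    artifacts["profiles"] <- write_artifact(profiles, config$out_dir,
                                             "cluster_profiles.csv")
    list(scaled = scaled, predictions = predictions, curve = curve, K = K,
         solution = solution, profiles = profiles)
  })

  alloc <- run_stage("allocate", {
    counts <- cluster_location_counts(city$locations, clusterres$solution)
    pool <- tibble(location_id = city$locations$id,
                   cluster = clusterres$solution$assignment) %>%
      filter(city$locations$role == "candidate")
    alloc <- allocate(counts, n_new = config$n_new, tie_rule = config$tie_rule,
                      seed = config$seed, candidate_pool = pool)
    artifacts["allocation"] <- write_artifact(alloc$counts, config$out_dir,
                                               "allocation.csv")
    artifacts["picks"] <- write_artifact(alloc$log, config$out_dir, "picks.csv")
    alloc
  })

  stab <- NULL
  if (config$stability_reps > 0) {
    stab <- run_stage("stability", {
      s <- subsample_stability(clusterres$scaled, K = clusterres$K,
                               reference = clusterres$solution,
                               n_reps = config$stability_reps,
                               keep_frac = config$stability_keep_frac,
                               n_restarts = config$n_restarts,
                               seed = config$seed)
      artifacts["stability"] <- write_artifact(s$replicates, config$out_dir,
                                                "stability.csv")
      s
    })
  }

  manifest <- list(
    parameters = list(
      seed = config$seed, min_hours = config$min_hours,
      min_months = config$min_months,
      max_missing_days = config$max_missing_days,
      max_consecutive = config$max_consecutive,
      selection = unclass(config$selection), K = clusterres$K,
      k_fixed = !is.null(config$K), k_max = config$k_max,
      did_threshold = config$did_threshold,
      did_lookahead = config$did_lookahead,
      n_restarts = config$n_restarts, n_new = config$n_new,
      tie_rule = config$tie_rule,
      stability_reps = config$stability_reps,
      stability_keep_frac = config$stability_keep_frac,
      city_seed = config$city$seed,
      n_locations = nrow(city$locations)),
    artifacts = as.list(unname(artifacts)),
    hashes = as.list(tools::md5sum(unname(artifacts))))
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA),
             file.path(config$out_dir, "manifest.json"))

  structure(list(city = city, annual = annual, screened = screened,
                 model = model, predictions = clusterres$predictions,
                 curve = clusterres$curve, K = clusterres$K,
                 solution = clusterres$solution, profiles = clusterres$profiles,
                 allocation = alloc, stability = stab, manifest = manifest,
                 config = config),
            class = "sitenet_pipeline")
}

#' Summarise a pipeline run
#'
#' Prints the design summary: the selected land-use-regression variables
#' with standardized effects and LOOCV R-squared, the per-cluster location
#' counts with current-to-subject proportions and allocated new sites, the
#' DiD values at the chosen k, and the stability summary.
#'
#' @param x A `sitenet_pipeline` from [run_pipeline()].
#' @param ... Unused.
#' @export
print.sitenet_pipeline <- function(x, ...) {
  cat("== Monitoring-network design ==\n\n-- Land-use regression --\n")
  print(x$model)
  cat("\n-- Clustering (K =", x$K, ") --\n")
  if (!is.null(x$curve)) {
    at_k <- filter(as_tibble(x$curve), .data$k == x$K)
    cat(sprintf("DiD at K: %.1f%% (predictions), %.1f%% (covariates)\n",
                at_k$did_predictions, at_k$did_covariates))
  }
  cat("\n-- Allocation --\n")
  print(x$allocation)
  if (!is.null(x$stability)) {
    cat("\n-- Stability --\n")
    print(x$stability)
  }
  invisible(x)
}
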