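#' Configure a synthetic city
#'
#' Builds the configuration for [generate_city()]: a rectangular study area in
#' planar metres containing three kinds of locations — "current" (existing
#' regulatory monitors), "subject" (residences whose exposure the network must
#' represent) and "candidate" (potential spots for new monitors) — together
#' with pollution sources, covariates derived from them, and a linear
#' concentration model with known coefficients.
#'
#' Role counts default to the study conditions the method was developed for:
#' 37 monitors, 31,097 residences and 412 candidate sites. Tests and examples
#' pass smaller counts explicitly.
#'
#' @param seed Integer seed; the same seed reproduces the city exactly.
#' @param extent Named numeric vector `c(xmin, xmax, ymin, ymax)` in metres.
#' @param n_current,n_subject,n_candidate Location counts per role (all >= 1).
#' @param n_sources Named integer vector of source counts per kind. Kinds
#'   listed in `line_kinds` are line segments (roads); the rest are points.
#' @param line_kinds Character vector of source kinds drawn as line segments.
#' @param n_noise_covariates Number of covariates unrelated to concentration,
#'   included so variable selection has something to reject.
#' @param true_coefficients Named numeric vector of nonzero effects on the
#'   recoded covariate scale (log-transformed capped proximity, raw density);
#'   units are micrograms per cubic metre per covariate unit.
#' @param intercept Baseline concentration in micrograms per cubic metre.
#' @param noise_sd Standard deviation of i.i.d. Gaussian concentration noise.
#' @param buffer_radius Buffer radius in metres for density covariates.
#' @param proximity_cap Truncation cap in metres applied before the log
#'   transform of proximity covariates.
#' @param n_subject_blobs Number of Gaussian residential districts subjects
#'   are drawn from.
#' @param blob_sd Spatial standard deviation of each residential district, m.
#'
#' @return A `city_config` list, validated.
#' @seealso [generate_city()]
#' @export
city_config <- function(seed = 1L,
                        extent = c(xmin = 0, xmax = 20000, ymin = 0, ymax = 20000),
                        n_current = 37L,
                        n_subject = 31097L,
                        n_candidate = 412L,
                        n_sources = c(major_road = 8L, bus_stop = 40L, construction = 15L),
                        line_kinds = "major_road",
                        n_noise_covariates = 3L,
                        true_coefficients = c(dist_major_road = -1.5,
                                              bus_stop_buffer = 0.3,
                                              dist_bus_stop = -0.5),
                        intercept = 35,
                        noise_sd = 1.5,
                        buffer_radius = 500,
                        proximity_cap = 1000,
                        n_subject_blobs = 6L,
                        blob_sd = 1200) {
  stopifnot(length(extent) == 4, extent["xmax"] > extent["xmin"],
            extent["ymax"] > extent["ymin"])
  counts <- c(n_current = n_current, n_subject = n_subject, n_candidate = n_candidate)
  if (any(counts < 1)) {
    abort("role counts must all be >= 1", class = "sitenet_config_error")
  }
  if (any(n_sources < 0) || is.null(names(n_sources))) {
    abort("n_sources must be a named non-negative vector", class = "sitenet_config_error")
  }
  if (noise_sd < 0) abort("noise_sd must be >= 0", class = "sitenet_config_error")
  if (length(true_coefficients) == 0 || all(true_coefficients == 0)) {
    abort("at least one true coefficient must be nonzero", class = "sitenet_config_error")
  }
  structure(
    list(seed = as.integer(seed), extent = extent,
         n_current = as.integer(n_current), n_subject = as.integer(n_subject),
         n_candidate = as.integer(n_candidate),
         n_sources = n_sources, line_kinds = line_kinds,
         n_noise_covariates = as.integer(n_noise_covariates),
         true_coefficients = true_coefficients,
         intercept = intercept, noise_sd = noise_sd,
         buffer_radius = buffer_radius, proximity_cap = proximity_cap,
         n_subject_blobs = as.integer(n_subject_blobs), blob_sd = blob_sd),
    class = "city_config")
}

runif_in <- function(n, lo, hi) lo + (hi - lo) * runif(n)

# currents on a jittered grid (regulatory networks cover a city evenly),
# subjects clumped in residential districts, candidates uniform
sample_locations <- function(config) {
  e <- config$extent
  ncur <- config$n_current
  grid_n <- ceiling(sqrt(ncur))
  gx <- seq(e["xmin"], e["xmax"], length.out = grid_n + 2L)[-c(1L, grid_n + 2L)]
  gy <- seq(e["ymin"], e["ymax"], length.out = grid_n + 2L)[-c(1L, grid_n + 2L)]
  grid <- expand.grid(x = gx, y = gy)
  pick <- sample.int(nrow(grid), ncur)
  jit <- min(diff(gx)[1], diff(gy)[1], na.rm = TRUE) / 4
  if (!is.finite(jit)) jit <- (e["xmax"] - e["xmin"]) / 10
  cur <- tibble(
    x = pmin(pmax(grid$x[pick] + rnorm(ncur, 0, jit), e["xmin"]), e["xmax"]),
    y = pmin(pmax(grid$y[pick] + rnorm(ncur, 0, jit), e["ymin"]), e["ymax"]),
    role = "current")

  nb <- config$n_subject_blobs
  centers_x <- runif_in(nb, e["xmin"], e["xmax"])
  centers_y <- runif_in(nb, e["ymin"], e["ymax"])
  blob <- sample.int(nb, config$n_subject, replace = TRUE)
  sub <- tibble(
    x = pmin(pmax(centers_x[blob] + rnorm(config$n_subject, 0, config$blob_sd), e["xmin"]), e["xmax"]),
    y = pmin(pmax(centers_y[blob] + rnorm(config$n_subject, 0, config$blob_sd), e["ymin"]), e["ymax"]),
    role = "subject")

  cand <- tibble(
    x = runif_in(config$n_candidate, e["xmin"], e["xmax"]),
    y = runif_in(config$n_candidate, e["ymin"], e["ymax"]),
    role = "candidate")

  bind_rows(cur, sub, cand) %>%
    mutate(id = sprintf("L%05d", row_number())) %>%
    select("id", "role", "x", "y")
}

sample_sources <- function(config) {
  e <- config$extent
  lines <- points <- list()
  for (kind in names(config$n_sources)) {
    nk <- config$n_sources[[kind]]
    if (nk == 0) next
    if (kind %in% config$line_kinds) {
      lines[[kind]] <- tibble(
        kind = kind,
        x1 = runif_in(nk, e["xmin"], e["xmax"]), y1 = runif_in(nk, e["ymin"], e["ymax"]),
        x2 = runif_in(nk, e["xmin"], e["xmax"]), y2 = runif_in(nk, e["ymin"], e["ymax"]))
    } else {
      points[[kind]] <- tibble(
        kind = kind,
        x = runif_in(nk, e["xmin"], e["xmax"]), y = runif_in(nk, e["ymin"], e["ymax"]))
    }
  }
  list(lines = bind_rows(lines), points = bind_rows(points))
}

#' Generate a synthetic city
#'
#' Draws locations, pollution sources and covariates, and computes a ground
#' truth annual-average concentration at every location as a sparse linear
#' function of the recoded covariates plus Gaussian noise. The result carries
#' everything downstream stages consume, with the generating coefficients
#' attached so recovery can be verified.
#'
#' Covariates come in the two families the design expects: proximity
#' (`dist_<kind>`, distance in metres to the nearest source of that kind) and
#' density (`<kind>_buffer`, clipped segment length or point count within a
#' circular buffer), plus noise covariates unrelated to concentration.
#' `features` holds the modelling state — proximity columns truncated at
#' `proximity_cap` and natural-log transformed with a 1 m offset — while
#' `features_raw` keeps untransformed distances for testing the recoding.
#'
#' @param config A [city_config()].
#' @return A list with class `synthetic_city`:
#'   `locations` (tibble: id, role, x, y), `sources` (list of `lines` and
#'   `points` tibbles), `features` and `features_raw` (tibbles: location_id +
#'   covariate columns, with variable metadata in `attr(, "meta")`),
#'   `concentration` (tibble: location_id, value), and the `config`.
#' @export
generate_city <- function(config) {
  stopifnot(inherits(config, "city_config"))
  set.seed(config$seed)
  locations <- sample_locations(config)
  sources <- sample_sources(config)

  raw <- list(location_id = locations$id)
  meta <- list()
  for (kind in names(config$n_sources)) {
    if (config$n_sources[[kind]] == 0) next
    vn_prox <- paste0("dist_", kind)
    vn_dens <- paste0(kind, "_buffer")
    raw[[vn_prox]] <- proximity_variable(locations, sources, kind)
    raw[[vn_dens]] <- density_variable(locations, sources, kind, radius = config$buffer_radius)
    meta[[vn_prox]] <- tibble(name = vn_prox, category = "traffic", metric = "proximity",
                              buffer_radius = NA_real_, truncation_cap = config$proximity_cap,
                              land_use_flag = FALSE)
    meta[[vn_dens]] <- tibble(name = vn_dens, category = "traffic", metric = "density",
                              buffer_radius = config$buffer_radius, truncation_cap = NA_real_,
                              land_use_flag = FALSE)
  }
  if (config$n_noise_covariates > 0) {
    for (i in seq_len(config$n_noise_covariates)) {
      vn <- paste0("noise_cov_", i)
      raw[[vn]] <- rnorm(nrow(locations))
      meta[[vn]] <- tibble(name = vn, category = "demographic", metric = "density",
                           buffer_radius = config$buffer_radius, truncation_cap = NA_real_,
                           land_use_flag = FALSE)
    }
  }
  features_raw <- as_tibble(raw)
  meta <- bind_rows(meta)

  features <- features_raw
  for (vn in meta$name[meta$metric == "proximity"]) {
    features[[vn]] <- recode_proximity(features[[vn]], cap = config$proximity_cap)
  }
  attr(features_raw, "meta") <- meta
  attr(features_raw, "state") <- "raw"
  attr(features, "meta") <- meta
  attr(features, "state") <- "recoded"

  beta <- config$true_coefficients
  missing_vars <- setdiff(names(beta), names(features))
  if (length(missing_vars) > 0) {
    abort(paste0("true coefficients name covariates absent from the city: ",
                 paste(missing_vars, collapse = ", ")),
          class = "sitenet_config_error")
  }
  xb <- as.matrix(features[names(beta)]) %*% beta
  conc <- config$intercept + drop(xb) + rnorm(nrow(locations), 0, config$noise_sd)
  structure(
    list(locations = locations, sources = sources,
         features = features, features_raw = features_raw,
         concentration = tibble(location_id = locations$id, value = conc),
         config = config),
    class = "synthetic_city")
}

#' @export
print.synthetic_city <- function(x, ...) {
  cat("Synthetic city:", nrow(x$locations), "locations (",
      sum(x$locations$role == "current"), "current /",
      sum(x$locations$role == "subject"), "subject /",
      sum(x$locations$role == "candidate"), "candidate ),",
      ncol(x$features) - 1L, "covariates\n")
  invisible(x)
}

#' Generate an hourly measurement series
#'
#' Produces one calendar year of hourly concentrations for a set of sites,
#' with specified gaps removed — the raw-input shape the completeness
#' screening of [daily_averages()] and [site_eligibility()] consumes.
#'
#' @param seed Integer seed.
#' @param year Calendar year.
#' @param sites Character vector of site ids.
#' @param gaps Optional tibble of whole-day gaps to inject, with columns
#'   `site_id` (or `NA` meaning every site), `from`, `to` (inclusive Dates
#'   within `year`).
#' @param mean_level,diurnal_amplitude,sd Level, within-day sinusoidal swing
#'   and noise scale of the simulated concentrations (micrograms per cubic
#'   metre); values are floored at zero.
#' @return Tibble with columns `site_id`, `datetime` (UTC, hour resolution),
#'   `value`; one row per non-missing site-hour.
#' @export
generate_hourly_series <- function(seed = 1L, year = 2010L, sites = "S01",
                                   gaps = NULL, mean_level = 27,
                                   diurnal_amplitude = 5, sd = 4) {
  set.seed(seed)
  start <- lubridate::make_datetime(year, 1, 1, 0, tz = "UTC")
  end <- lubridate::make_datetime(year, 12, 31, 23, tz = "UTC")
  hours <- seq(start, end, by = "hour")
  out <- tidyr::expand_grid(site_id = sites, datetime = hours) %>%
    mutate(value = pmax(0, mean_level +
                          diurnal_amplitude * sin(2 * pi * lubridate::hour(.data$datetime) / 24) +
                          rnorm(dplyr::n(), 0, sd)))
  if (!is.null(gaps)) {
    stopifnot(all(c("from", "to") %in% names(gaps)))
    if (any(lubridate::year(gaps$from) != year | lubridate::year(gaps$to) != year)) {
      abort("gap outside the simulated year", class = "sitenet_gap_error")
    }
    for (i in seq_len(nrow(gaps))) {
      g <- gaps[i, ]
      hit <- lubridate::as_date(out$datetime) >= g$from &
        lubridate::as_date(out$datetime) <= g$to
      if ("site_id" %in% names(gaps) && !is.na(g$site_id)) {
        hit <- hit & out$site_id == g$site_id
      }
      out <- out[!hit, ]
    }
  }
  out
}
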