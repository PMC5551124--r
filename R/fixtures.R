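#' Published Seoul cluster-count tables
#'
#' Loads the per-cluster counts of current (regulatory monitor), subject
#' (residence) and candidate (community service center) locations published
#' for the Seoul monitoring-network design, for PM2.5 (nine clusters) and
#' NO2 (eight clusters), together with the number of new sites the published
#' design placed in each cluster. These serve as exact regression fixtures
#' for [allocate()]: the greedy allocation run on the count rows reproduces
#' the published new-site rows.
#'
#' @param name `"seoul_pm25"` or `"seoul_no2"`.
#' @return Tibble with columns `cluster`, `n_current`, `n_subject`,
#'   `n_candidate`, `published_new_sites`; the pollutant label is in
#'   `attr(, "pollutant")`.
#' @export
load_cluster_counts <- function(name = c("seoul_pm25", "seoul_no2")) {
  name <- tryCatch(match.arg(name),
                   error = function(e) abort(
                     paste0("unknown fixture '", paste(name, collapse = ","),
                            "'; available: seoul_pm25, seoul_no2"),
                     class = "sitenet_fixture_error"))
  path <- system.file("extdata", paste0(name, "_cluster_counts.csv"),
                      package = "sitenet", mustWork = TRUE)
  out <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_integer()))
  attr(out, "pollutant") <- if (name == "seoul_pm25") "PM2.5" else "NO2"
  out
}
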