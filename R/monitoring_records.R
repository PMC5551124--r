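#' Daily averages from hourly measurements
#'
#' Collapses hourly concentrations to daily means, keeping a day only when
#' enough of it was observed: a daily average exists iff the day has at least
#' `min_hours` non-missing hourly values (default 18 of 24, i.e. 75%), and is
#' the arithmetic mean of the hours present.
#'
#' @param hourly Tibble with columns `site_id`, `datetime` (hour resolution,
#'   one calendar year), `value` (concentration; `NA` = missing).
#' @param min_hours Minimum non-missing hours for a day to qualify.
#' @return Tibble with one row per site-day that has any record: `site_id`,
#'   `date`, `n_hours` (non-missing hours), `value` (daily mean, `NA` when
#'   the day does not qualify), `valid`.
#' @export
daily_averages <- function(hourly, min_hours = 18) {
  stopifnot(all(c("site_id", "datetime", "value") %in% names(hourly)))
  dup <- hourly %>%
    count(.data$site_id, hour = lubridate::floor_date(.data$datetime, "hour")) %>%
    filter(n > 1)
  if (nrow(dup) > 0) {
    abort(paste0("duplicate site-hour records, e.g. ", dup$site_id[1], " at ",
                 format(dup$hour[1])),
          class = "sitenet_qc_error")
  }
  hourly %>%
    group_by(.data$site_id, date = lubridate::as_date(.data$datetime)) %>%
    summarise(n_hours = sum(!is.na(.data$value)),
              value = mean(.data$value, na.rm = TRUE), .groups = "drop") %>%
    mutate(valid = .data$n_hours >= min_hours,
           value = ifelse(.data$valid, .data$value, NA_real_))
}

longest_run <- function(x) {
  if (!any(x)) return(0L)
  r <- rle(x)
  max(r$lengths[r$values])
}

#' Annual summary and completeness screening per site
#'
#' Aggregates a site-year of daily averages into an annual mean and checks
#' the completeness criteria an annual average must meet to be considered
#' representative: a daily average in at least `min_months` distinct months,
#' at most `max_missing_days` missing days, and every run of consecutive
#' missing days shorter than `max_consecutive` days. The annual mean — the
#' unweighted mean of the valid daily averages — is reported for every site
#' regardless, with `eligible` flagging whether all criteria pass.
#'
#' @param daily Daily table from [daily_averages()] (any number of sites).
#' @param year Calendar year; inferred from the dates when `NULL`.
#' @param min_months Minimum months containing at least one daily average.
#' @param max_missing_days Maximum missing days in the year.
#' @param max_consecutive Missing-day runs must be strictly shorter than this.
#' @return Tibble, one row per site: `site_id`, `annual_mean`,
#'   `n_valid_days`, `n_missing_days`, `max_consecutive_missing_days`,
#'   `months_with_daily_average`, `eligible`.
#' @export
site_eligibility <- function(daily, year = NULL, min_months = 10,
                             max_missing_days = 91, max_consecutive = 45) {
  if (nrow(daily) == 0) abort("empty daily table", class = "sitenet_qc_error")
  year <- year %||% lubridate::year(daily$date[1])
  calendar <- seq(lubridate::make_date(year, 1, 1),
                  lubridate::make_date(year, 12, 31), by = "day")
  daily %>%
    group_by(.data$site_id) %>%
    dplyr::group_modify(function(d, key) {
      valid_dates <- d$date[d$valid]
      missing <- !(calendar %in% valid_dates)
      tibble(
        annual_mean = mean(d$value[d$valid]),
        n_valid_days = sum(!missing),
        n_missing_days = sum(missing),
        max_consecutive_missing_days = longest_run(missing),
        months_with_daily_average = dplyr::n_distinct(lubridate::month(valid_dates)))
    }) %>%
    ungroup() %>%
    mutate(eligible = .data$months_with_daily_average >= min_months &
             .data$n_missing_days <= max_missing_days &
             .data$max_consecutive_missing_days < max_consecutive)
}
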