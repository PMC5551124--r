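# Shared fixtures and independent oracles, built in code.

# small synthetic city for fast tests
small_city_config <- function(seed = 42L, n_subject = 400L, noise_sd = 0.5,
                              n_sources = c(major_road = 6L, bus_stop = 25L,
                                            construction = 10L), ...) {
  city_config(seed = seed, n_current = 37L, n_subject = n_subject,
              n_candidate = 50L, n_sources = n_sources,
              noise_sd = noise_sd, ...)
}

# well-separated Gaussian blobs in J dimensions; returns matrix + labels
make_blobs <- function(n_per = 30, centers = rbind(c(0, 0), c(20, 0), c(10, 20)),
                       sd = 0.5, seed = 1) {
  set.seed(seed)
  X <- do.call(rbind, lapply(seq_len(nrow(centers)), function(b) {
    sweep(matrix(rnorm(n_per * ncol(centers), 0, sd), n_per), 2, centers[b, ], `+`)
  }))
  colnames(X) <- paste0("v", seq_len(ncol(centers)))
  list(X = X, labels = rep(seq_len(nrow(centers)), each = n_per))
}

# naive double-loop evaluation of the DiD formula
brute_did <- function(assignment, Y) {
  Y <- as.matrix(Y)
  total <- 0
  for (j in seq_len(ncol(Y))) {
    sse <- sum((Y[, j] - mean(Y[, j]))^2)
    s <- 0
    for (k in unique(assignment)) {
      yk <- Y[assignment == k, j]
      s <- s + sum((yk - mean(yk))^2)
    }
    total <- total + s / sse
  }
  100 * (1 - total / ncol(Y))
}

# adjusted Rand via exhaustive enumeration of item pairs
pair_counting_ari <- function(a, b) {
  n <- length(a)
  n11 <- n00 <- n10 <- n01 <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      sa <- a[i] == a[j]
      sb <- b[i] == b[j]
      if (sa && sb) n11 <- n11 + 1
      else if (!sa && !sb) n00 <- n00 + 1
      else if (sa) n10 <- n10 + 1
      else n01 <- n01 + 1
    }
  }
  den <- (n11 + n10) * (n10 + n00) + (n11 + n01) * (n01 + n00)
  if (den == 0) return(NA_real_)  # degenerate; convention handled separately
  2 * (n11 * n00 - n10 * n01) / den
}

# one day of hourly records for one site
hours_of_day <- function(site, date, values) {
  tibble::tibble(
    site_id = site,
    datetime = lubridate::make_datetime(lubridate::year(date),
                                        lubridate::month(date),
                                        lubridate::mday(date),
                                        seq_along(values) - 1, tz = "UTC"),
    value = values)
}

# a complete year of daily rows for one site, then apply tweaks
full_daily <- function(site = "S1", year = 2010, value = 25) {
  dates <- seq(lubridate::make_date(year, 1, 1),
               lubridate::make_date(year, 12, 31), by = "day")
  tibble::tibble(site_id = site, date = dates, n_hours = 24L,
                 value = value, valid = TRUE)
}

# mark a span of days missing in a daily table
blank_days <- function(daily, from, to) {
  hit <- daily$date >= from & daily$date <= to
  daily$valid[hit] <- FALSE
  daily$value[hit] <- NA_real_
  daily$n_hours[hit] <- 0L
  daily
}
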