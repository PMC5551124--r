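point_sources <- function(xy, kind = "bus_stop") {
  list(lines = NULL, points = tibble::tibble(kind = kind, x = xy[, 1], y = xy[, 2]))
}

test_that("proximity is the distance to the nearest source geometry", {
  locs <- tibble::tibble(x = c(0, 3), y = c(0, 4))
  src <- point_sources(rbind(c(3, 4), c(6, 8)))
  d <- proximity_variable(locs, src, "bus_stop")
  expect_equal(d, c(5, 0))

  # segment: nearest point is the perpendicular foot or an endpoint
  seg <- list(lines = tibble::tibble(kind = "major_road",
                                     x1 = 0, y1 = 2, x2 = 10, y2 = 2),
              points = NULL)
  locs2 <- tibble::tibble(x = c(5, -3, 14), y = c(0, 2, 5))
  expect_equal(proximity_variable(locs2, seg, "major_road"), c(2, 3, 5))

  expect_error(proximity_variable(locs, src, "no_such_kind"),
               class = "sitenet_source_error")
})

test_that("proximity equals a dense-sampling oracle on random geometry", {
  set.seed(31)
  locs <- tibble::tibble(x = runif(40, 0, 100), y = runif(40, 0, 100))
  lines <- tibble::tibble(kind = "major_road",
                          x1 = runif(5, 0, 100), y1 = runif(5, 0, 100),
                          x2 = runif(5, 0, 100), y2 = runif(5, 0, 100))
  src <- list(lines = lines, points = NULL)
  got <- proximity_variable(locs, src, "major_road")
  # oracle: min distance over 20,001 sampled points per segment
  t <- seq(0, 1, length.out = 20001)
  oracle <- sapply(seq_len(nrow(locs)), function(i) {
    min(sapply(seq_len(nrow(lines)), function(s) {
      px <- lines$x1[s] + t * (lines$x2[s] - lines$x1[s])
      py <- lines$y1[s] + t * (lines$y2[s] - lines$y1[s])
      sqrt(min((locs$x[i] - px)^2 + (locs$y[i] - py)^2))
    }))
  })
  expect_equal(got, oracle, tolerance = 1e-4)
})

test_that("density counts points and clips segment length to the buffer", {
  locs <- tibble::tibble(x = c(0, 50), y = c(0, 50))
  src <- point_sources(rbind(c(1, 0), c(0, 3), c(10, 0)))
  expect_equal(density_variable(locs, src, "bus_stop", radius = 5), c(2, 0))
  expect_error(density_variable(locs, src, "bus_stop", radius = 0),
               class = "sitenet_buffer_error")

  # chord through the buffer center has clipped length 2 * radius
  seg <- list(lines = tibble::tibble(kind = "major_road",
                                     x1 = -100, y1 = 0, x2 = 100, y2 = 0),
              points = NULL)
  expect_equal(density_variable(tibble::tibble(x = 0, y = 0), seg,
                                "major_road", radius = 7), 14)
})

test_that("clipped segment length matches numeric integration within 1%", {
  set.seed(12)
  locs <- tibble::tibble(x = runif(25, 0, 60), y = runif(25, 0, 60))
  lines <- tibble::tibble(kind = "major_road",
                          x1 = runif(6, 0, 60), y1 = runif(6, 0, 60),
                          x2 = runif(6, 0, 60), y2 = runif(6, 0, 60))
  src <- list(lines = lines, points = NULL)
  radius <- 15
  got <- density_variable(locs, src, "major_road", radius = radius)
  t <- seq(0, 1, length.out = 40001)
  oracle <- sapply(seq_len(nrow(locs)), function(i) {
    sum(sapply(seq_len(nrow(lines)), function(s) {
      px <- lines$x1[s] + t * (lines$x2[s] - lines$x1[s])
      py <- lines$y1[s] + t * (lines$y2[s] - lines$y1[s])
      inside <- (locs$x[i] - px)^2 + (locs$y[i] - py)^2 <= radius^2
      seg_len <- sqrt((lines$x2[s] - lines$x1[s])^2 + (lines$y2[s] - lines$y1[s])^2)
      mean(inside) * seg_len
    }))
  })
  expect_equal(got, oracle, tolerance = 0.01)
})

test_that("proximity recoding truncates, logs and stays monotone", {
  expect_equal(recode_proximity(5000, cap = 1000), log(1001))
  expect_equal(recode_proximity(0), 0)
  x <- c(0, 1, 10, 999, 1000, 1500, 1e6)
  r <- recode_proximity(x)
  expect_true(all(diff(r) >= 0))
  expect_true(all(r <= log(1001)))
  expect_equal(r, log(pmin(x, 1000) + 1))
  expect_error(recode_proximity(-1), class = "sitenet_recode_error")
})

test_that("low-variability screening applies its two rules with a report", {
  n <- 100
  set.seed(4)
  f <- tibble::tibble(location_id = sprintf("L%03d", 1:n),
                      constant = rep(7, n),
                      few_values = rep(c(1, 2), length.out = n),
                      rich = rnorm(n),
                      land_low = runif(n, 0, 8),     # area share max < 10%
                      land_ok = runif(n, 0, 60))
  meta <- tibble::tibble(name = c("constant", "few_values", "rich", "land_low", "land_ok"),
                         category = "land use", metric = "density",
                         buffer_radius = 500, truncation_cap = NA,
                         land_use_flag = c(FALSE, FALSE, FALSE, TRUE, TRUE))
  attr(f, "meta") <- meta
  out <- exclude_low_variability(f)
  expect_setequal(setdiff(names(out$features), "location_id"),
                  c("rich", "land_ok"))
  expect_setequal(out$report$variable, c("constant", "few_values", "land_low"))
  expect_equal(out$report$reason[out$report$variable == "land_low"],
               "low_land_use_share")
  # a variable with >= 10% distinct values that is not land-use is never dropped
  expect_false("rich" %in% out$report$variable)
})

test_that("z-scaling gives mean 0 / sd 1, is invertible and reapplicable", {
  f <- tibble::tibble(location_id = c("a", "b", "c"), v = c(1, 2, 3))
  s <- zscale(f)
  expect_equal(s$v, c(-1, 0, 1))

  set.seed(8)
  g <- tibble::tibble(location_id = sprintf("L%02d", 1:50),
                      a = rnorm(50, 100, 20), b = runif(50))
  sg <- zscale(g)
  expect_equal(mean(sg$a), 0, tolerance = 1e-8)
  expect_equal(sd(sg$a), 1, tolerance = 1e-8)
  expect_equal(mean(sg$b), 0, tolerance = 1e-8)
  expect_equal(sd(sg$b), 1, tolerance = 1e-8)

  # scaling an already-scaled matrix changes nothing
  sg2 <- zscale(sg)
  expect_equal(sg2$a, sg$a, tolerance = 1e-12)

  # round trip and out-of-sample application
  back <- zscale_invert(sg)
  expect_equal(back$a, g$a, tolerance = 1e-8)
  new <- tibble::tibble(location_id = "new", a = 120, b = 0.5)
  applied <- zscale_apply(new, attr(sg, "scaling"))
  expect_equal(applied$a, (120 - mean(g$a)) / sd(g$a))

  const <- tibble::tibble(location_id = c("a", "b"), v = c(1, 1))
  expect_error(zscale(const), class = "sitenet_scale_error")
})

test_that("population-denominator scaling is available and consistent", {
  g <- tibble::tibble(location_id = letters[1:10], v = rnorm(10))
  s <- zscale(g, denominator = "population")
  expect_equal(sd(s$v) * sqrt(9 / 10), 1, tolerance = 1e-8)
})
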