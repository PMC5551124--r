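# data with a known sparse linear signal among decoy covariates
make_lur_data <- function(seed, n = 37, p = 20, active = c(x1 = 4, x2 = -2),
                          noise_sd = 0.1) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("x", seq_len(p))))
  y <- 10 + drop(X[, names(active), drop = FALSE] %*% active) +
    rnorm(n, 0, noise_sd)
  dplyr::bind_cols(tibble::tibble(annual_mean = y), tibble::as_tibble(X))
}

test_that("forward selection recovers a sparse signal in marginal-R2 order", {
  d <- make_lur_data(1)
  m <- forward_select(d, "annual_mean")
  expect_equal(m$variables[1:2], c("x1", "x2"))  # |beta| 4 before 2
  expect_true(length(m$variables) <= 5)
  expect_gt(m$loocv_r2, 0.95)
  # selection path never decreases in-sample R2
  added <- m$path[m$path$action == "added", ]
  expect_true(all(diff(added$r2) >= -1e-12))
})

test_that("a duplicated selected variable is barred by the correlation guard", {
  d <- make_lur_data(2)
  d$x1_copy <- d$x1
  m <- forward_select(d, "annual_mean")
  expect_false("x1_copy" %in% m$variables && "x1" %in% m$variables)
  first <- intersect(c("x1", "x1_copy"), m$variables)[1]
  other <- setdiff(c("x1", "x1_copy"), first)
  expect_false(other %in% m$variables)
  expect_true(other %in% m$barred ||
                !other %in% m$path$variable)  # barred if it was ever attempted
})

test_that("selected sets respect the size, correlation and VIF constraints", {
  for (seed in 1:8) {
    d <- make_lur_data(seed, active = c(x1 = 3, x3 = 2, x5 = -2), noise_sd = 0.5)
    m <- forward_select(d, "annual_mean")
    expect_lte(length(m$variables), 5)
    if (length(m$variables) >= 2) {
      cm <- abs(stats::cor(as.matrix(d[m$variables])))
      expect_lte(max(cm[upper.tri(cm)]), 0.7)
      expect_true(all(diag(solve(stats::cor(as.matrix(d[m$variables])))) <= 10))
    }
  }
})

test_that("final-model VIFs agree with the car package", {
  skip_if_not_installed("car")
  d <- make_lur_data(3, active = c(x1 = 3, x2 = 2, x4 = -1), noise_sd = 0.3)
  m <- forward_select(d, "annual_mean")
  skip_if(length(m$variables) < 2)
  ours <- diag(solve(stats::cor(as.matrix(d[m$variables]))))
  theirs <- car::vif(m$fit)
  expect_equal(unname(ours[names(theirs)]), unname(theirs), tolerance = 1e-8)
})

test_that("pure-noise responses enter variables at about the alpha rate", {
  set.seed(99)
  entered <- replicate(400, {
    n <- 30; p <- 8
    X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("x", 1:p)))
    y <- rnorm(n)
    # first-step entry happens iff any single-variable fit is significant
    pvals <- apply(X, 2, function(xj) {
      summary(lm(y ~ xj))$coefficients["xj", "Pr(>|t|)"]
    })
    any(pvals <= 0.05)
  })
  # P(enter) = 1 - (1 - alpha)^p for independent N(0,1) decoys:
  # about 0.34 at p = 8, alpha = 0.05
  expect_lt(abs(mean(entered) - (1 - 0.95^8)), 0.06)

  # and the selector itself returns an empty model when nothing is significant
  d <- make_lur_data(4, active = c(x1 = 5), noise_sd = 0.1)
  d$annual_mean <- rnorm(nrow(d)) # sever the signal
  m <- suppressWarnings(forward_select(d, "annual_mean",
                                       config = selection_config(entry_alpha = 1e-6)))
  expect_length(m$variables, 0)
  expect_equal(predict(m, d), rep(m$intercept, nrow(d)))
})

test_that("LOOCV R2 matches a hand-computed four-point case and its bounds", {
  d <- tibble::tibble(annual_mean = c(2.1, 3.9, 6.2, 7.8), x = c(1, 2, 3, 4))
  expect_equal(loocv_r2(d, "annual_mean", "x"), 0.98529077, tolerance = 1e-7)

  # exact linear signal cross-validates to 1
  d2 <- tibble::tibble(x = 1:10, annual_mean = 3 + 2 * (1:10))
  expect_equal(loocv_r2(d2, "annual_mean", "x"), 1, tolerance = 1e-10)

  # null model on noise: score near 0, can dip below
  set.seed(5)
  d3 <- tibble::tibble(annual_mean = rnorm(40))
  score <- loocv_r2(d3, "annual_mean", character(0))
  expect_lt(score, 0.15)
  expect_lte(score, 1)

  expect_error(loocv_r2(tibble::tibble(annual_mean = rep(1, 5), x = 1:5),
                        "annual_mean", "x"), class = "sitenet_lur_error")
})

test_that("predictions are linear and fail cleanly on missing covariates", {
  d <- make_lur_data(6)
  m <- forward_select(d, "annual_mean")
  # covariates at fitting means predict the response mean
  at_means <- tibble::as_tibble(lapply(d[m$variables], function(v) mean(v)))
  expect_equal(predict(m, at_means), mean(d$annual_mean), tolerance = 1e-10)
  expect_error(predict(m, at_means[, -1, drop = FALSE]),
               class = "sitenet_lur_error")
})

test_that("noiseless synthetic cities are predicted exactly", {
  cfg <- small_city_config(
    seed = 13, noise_sd = 0,
    n_sources = c(major_road = 6L, bus_stop = 60L, construction = 10L),
    buffer_radius = 3000,
    true_coefficients = c(dist_major_road = -2, bus_stop_buffer = 1.5))
  city <- generate_city(cfg)
  cur <- city$locations$role == "current"
  monitors <- city$features[cur, ]
  monitors$annual_mean <- city$concentration$value[cur]
  cands <- setdiff(names(monitors), c("location_id", "annual_mean"))
  cands <- cands[sapply(monitors[cands], sd) > 0]
  # zero-residual fits along the way warn about perfect fits; expected here
  m <- suppressWarnings(forward_select(monitors, "annual_mean", candidates = cands))
  expect_setequal(m$variables, c("dist_major_road", "bus_stop_buffer"))
  expect_equal(m$loocv_r2, 1, tolerance = 1e-6)
  preds <- predict(m, city$features)
  expect_equal(preds, city$concentration$value, tolerance = 1e-6)
})

test_that("standardized coefficients multiply by the p90-p10 increment", {
  d <- make_lur_data(7, active = c(x1 = 4), noise_sd = 0.05)
  m <- forward_select(d, "annual_mean")
  std <- standardize_coefficients(m, d)
  for (i in seq_len(nrow(std))) {
    v <- std$variable[i]
    inc <- unname(diff(quantile(d[[v]], c(0.1, 0.9), type = 7)))
    expect_equal(std$increment[i], inc)
    expect_equal(std$std_coefficient[i], m$coefficients[[v]] * inc)
  }
  # degenerate increment gives a zero standardized effect
  m2 <- m
  m2$variables <- "x2"; m2$coefficients <- c(x2 = 2); m2$p_values <- c(x2 = 0.5)
  dd <- d; dd$x2 <- 1
  expect_equal(standardize_coefficients(m2, dd)$std_coefficient, 0)
  dd$x2 <- d$x2
  m2$coefficients <- c(x2 = 2)
  dd$x2 <- rep(c(0, 1.5), length.out = nrow(dd)) # p90 - p10 = 1.5
  expect_equal(standardize_coefficients(m2, dd)$std_coefficient, 3)
})

test_that("tidy and glance expose the model in broom shape", {
  d <- make_lur_data(8)
  m <- forward_select(d, "annual_mean")
  td <- tidy(m)
  expect_true(all(c("term", "estimate", "std_estimate", "p.value") %in% names(td)))
  g <- glance(m)
  expect_equal(g$nobs, 37)
  expect_lte(g$loocv_r2, 1)
})

test_that("degenerate inputs are rejected with informative errors", {
  d <- make_lur_data(9)
  d$flat <- 1
  expect_error(forward_select(d, "annual_mean"), class = "sitenet_lur_error")
  expect_error(forward_select(make_lur_data(10, n = 5), "annual_mean"),
               class = "sitenet_lur_error")
})
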