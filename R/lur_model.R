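#' Selection settings for the land-use regression
#'
#' @param max_vars Maximum number of covariates in the model; kept small
#'   because the model is fitted on few monitoring sites.
#' @param vif_max Variance-inflation-factor ceiling for an entering variable.
#' @param cor_max Maximum absolute Pearson correlation an entering variable
#'   may have with any already-selected variable.
#' @param entry_alpha Significance level a candidate's coefficient (t-test)
#'   must reach to enter.
#' @return A `selection_config` list.
#' @export
selection_config <- function(max_vars = 5, vif_max = 10, cor_max = 0.7,
                             entry_alpha = 0.05) {
  stopifnot(max_vars >= 1, entry_alpha > 0, entry_alpha < 1)
  structure(list(max_vars = max_vars, vif_max = vif_max, cor_max = cor_max,
                 entry_alpha = entry_alpha), class = "selection_config")
}

bt <- function(x) paste0("`", x, "`")

fit_ols <- function(data, response, variables) {
  f <- stats::reformulate(if (length(variables)) bt(variables) else "1",
                          response = bt(response))
  lm(f, data = data)
}

vif_of <- function(data, variables) {
  # VIFs from the inverse correlation matrix of the selected covariates
  if (length(variables) < 2) return(setNames(rep(1, length(variables)), variables))
  cm <- stats::cor(as.matrix(data[variables]))
  setNames(diag(solve(cm)), variables)
}

#' Forward variable selection with multicollinearity guards
#'
#' Builds a land-use regression for annual-average concentrations at the
#' monitoring sites by forward selection: starting from the null model, the
#' candidate giving the largest increase in explained variability enters at
#' each step, provided its coefficient is significant at `entry_alpha`.
#' An entering variable whose variance inflation factor exceeds `vif_max`,
#' or whose absolute Pearson correlation with an already-selected variable
#' exceeds `cor_max`, is removed again and permanently barred from re-entry.
#' Selection stops at `max_vars` variables or when no candidate qualifies;
#' the final model is refit on all sites and evaluated by leave-one-out
#' cross-validation.
#'
#' @param data Tibble of monitoring sites: covariate columns plus the
#'   response column. Covariates must be recoded already and non-constant.
#' @param response Name of the response column (annual mean concentration).
#' @param candidates Candidate covariate names; default every numeric column
#'   except the response and `location_id`.
#' @param config A [selection_config()].
#' @return A `lur_model` object: ordered `variables`, `intercept`, raw
#'   `coefficients`, per-variable `p_values`, `loocv_r2`, standardized
#'   coefficients (raw coefficient times the variable's 90th-10th percentile
#'   spread), the selection `path`, and variables `barred` by the guards.
#' @seealso [loocv_r2()], [standardize_coefficients()], [predict.lur_model()]
#' @export
forward_select <- function(data, response, candidates = NULL,
                           config = selection_config()) {
  stopifnot(inherits(config, "selection_config"), response %in% names(data))
  candidates <- candidates %||%
    setdiff(names(data)[vapply(data, is.numeric, logical(1))],
            c(response, "location_id"))
  if (!all(candidates %in% names(data))) abort("unknown candidate columns")
  if (nrow(data) <= config$max_vars + 1) {
    abort("need more sites than max_vars + 1", class = "sitenet_lur_error")
  }
  if (anyNA(data[c(response, candidates)])) {
    abort("missing values in response or candidates", class = "sitenet_lur_error")
  }
  csd <- vapply(data[candidates], sd, numeric(1))
  if (any(csd == 0)) {
    abort(paste0("constant candidate column(s): ",
                 paste(candidates[csd == 0], collapse = ", "),
                 "; screen features first"), class = "sitenet_lur_error")
  }

  y <- data[[response]]
  selected <- character()
  barred <- character()
  path <- list()
  step <- 0L
  while (length(selected) < config$max_vars) {
    pool <- setdiff(candidates, c(selected, barred))
    if (!length(pool)) break
    trials <- purrr::map(pool, function(v) {
      fit <- fit_ols(data, response, c(selected, v))
      sm <- summary(fit)
      # aliased candidates (exactly collinear with the selected set) drop out
      # of the coefficient table; treat them as non-significant
      p <- if (v %in% rownames(sm$coefficients)) {
        sm$coefficients[v, "Pr(>|t|)"]
      } else 1
      tibble(variable = v, r2 = sm$r.squared, p_value = p)
    }) %>% bind_rows()
    ok <- filter(trials, .data$p_value <= config$entry_alpha)
    if (nrow(ok) == 0) break
    best <- ok$variable[which.max(ok$r2)]
    # multicollinearity guards on the tentatively added variable
    guard <- NULL
    if (length(selected)) {
      cors <- abs(stats::cor(data[[best]], as.matrix(data[selected])))
      if (max(cors) > config$cor_max) guard <- "correlation"
    }
    if (is.null(guard) && length(selected)) {
      if (vif_of(data, c(selected, best))[best] > config$vif_max) guard <- "vif"
    }
    step <- step + 1L
    if (!is.null(guard)) {
      barred <- c(barred, best)
      path[[step]] <- tibble(step = step, variable = best, action = guard,
                             r2 = ok$r2[ok$variable == best],
                             p_value = ok$p_value[ok$variable == best])
      next
    }
    selected <- c(selected, best)
    path[[step]] <- tibble(step = step, variable = best, action = "added",
                           r2 = ok$r2[ok$variable == best],
                           p_value = ok$p_value[ok$variable == best])
  }

  fit <- fit_ols(data, response, selected)
  cf <- coef(fit)
  pvals <- if (length(selected)) {
    setNames(summary(fit)$coefficients[selected, "Pr(>|t|)"], selected)
  } else setNames(numeric(0), character(0))
  model <- structure(
    list(variables = selected,
         intercept = unname(cf["(Intercept)"]),
         coefficients = if (length(selected)) setNames(unname(cf[selected]), selected)
                        else setNames(numeric(0), character(0)),
         p_values = pvals,
         r_squared = summary(fit)$r.squared,
         path = if (length(path)) bind_rows(path) else
           tibble(step = integer(), variable = character(), action = character(),
                  r2 = double(), p_value = double()),
         barred = barred,
         response = response,
         config = config,
         n = nrow(data),
         fit = fit),
    class = "lur_model")
  model$loocv_r2 <- loocv_r2(data, response, selected)
  model$std_coefficients <- standardize_coefficients(model, data)
  model
}

#' Leave-one-out cross-validated R-squared
#'
#' For each site, the fixed variable set is refit on the remaining sites and
#' a prediction made at the left-out site; the score is one minus the mean
#' squared prediction error divided by the variance of the observations.
#' Because the score is MSE-based (predictions judged against the identity
#' line) it can be negative when predictions are worse than the mean.
#'
#' @inheritParams forward_select
#' @param variables Covariate set to evaluate (may be empty: the null model
#'   predicts the training mean).
#' @param var_denominator `"n"` (default) or `"n-1"` denominator for the
#'   observation variance.
#' @return Cross-validated R-squared, at most 1.
#' @export
loocv_r2 <- function(data, response, variables,
                     var_denominator = c("n", "n-1")) {
  var_denominator <- match.arg(var_denominator)
  n <- nrow(data)
  stopifnot(n >= 3)
  y <- data[[response]]
  if (var(y) == 0) abort("response has zero variance", class = "sitenet_lur_error")
  preds <- vapply(seq_len(n), function(i) {
    fit <- fit_ols(data[-i, ], response, variables)
    unname(predict(fit, newdata = data[i, ]))
  }, numeric(1))
  mse <- mean((y - preds)^2)
  vy <- var(y) * if (var_denominator == "n") (n - 1) / n else 1
  1 - mse / vy
}

#' Predict concentrations from a fitted land-use regression
#'
#' @param object A `lur_model`.
#' @param new_data Tibble containing every selected covariate, recoded
#'   identically to the fitting data.
#' @param ... Unused.
#' @return Numeric vector of linear predictions.
#' @export
predict.lur_model <- function(object, new_data, ...) {
  missing_vars <- setdiff(object$variables, names(new_data))
  if (length(missing_vars)) {
    abort(paste0("new_data lacks selected variable(s): ",
                 paste(missing_vars, collapse = ", ")),
          class = "sitenet_lur_error")
  }
  if (!length(object$variables)) return(rep(object$intercept, nrow(new_data)))
  object$intercept +
    drop(as.matrix(new_data[object$variables]) %*% object$coefficients)
}

#' Standardized coefficients on an interquantile increment
#'
#' Reports each raw coefficient multiplied by the 90th minus 10th percentile
#' of its covariate over the fitting locations, so effects are comparable
#' across covariates with different units. Percentiles use linear
#' interpolation (quantile type 7).
#'
#' @param model A `lur_model`.
#' @param data The fitting data (or any reference location set).
#' @return Tibble: `variable`, `coefficient`, `increment` (p90 - p10),
#'   `std_coefficient`, `p_value`.
#' @export
standardize_coefficients <- function(model, data) {
  if (!length(model$variables)) {
    return(tibble(variable = character(), coefficient = double(),
                  increment = double(), std_coefficient = double(),
                  p_value = double()))
  }
  increments <- vapply(model$variables, function(v) {
    q <- quantile(data[[v]], c(0.1, 0.9), names = FALSE, type = 7)
    q[2] - q[1]
  }, numeric(1))
  tibble(variable = model$variables,
         coefficient = unname(model$coefficients),
         increment = unname(increments),
         std_coefficient = unname(model$coefficients * increments),
         p_value = unname(model$p_values))
}

#' @export
print.lur_model <- function(x, ...) {
  cat("Land-use regression:", length(x$variables), "variable(s) selected from",
      x$n, "sites\n")
  if (length(x$variables)) {
    print(x$std_coefficients)
  } else {
    cat("  (intercept-only model; no candidate met the entry criterion)\n")
  }
  cat(sprintf("In-sample R2 = %.3f, LOOCV R2 = %.3f\n", x$r_squared, x$loocv_r2))
  invisible(x)
}

#' Tidy a land-use regression
#'
#' @param x A `lur_model`.
#' @param ... Unused.
#' @return One row per selected variable with raw and standardized effects.
#' @method tidy lur_model
#' @export
tidy.lur_model <- function(x, ...) {
  x$std_coefficients %>%
    rename(term = "variable", estimate = "coefficient",
           std_estimate = "std_coefficient", p.value = "p_value")
}

#' @rdname tidy.lur_model
#' @return For `glance()`: a one-row model summary.
#' @method glance lur_model
#' @export
glance.lur_model <- function(x, ...) {
  tibble(n_variables = length(x$variables), r.squared = x$r_squared,
         loocv_r2 = x$loocv_r2, nobs = x$n)
}
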