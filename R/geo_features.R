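#' @name geo_features
#' @title Geographic covariates: proximity, density, recoding, screening, scaling
#'
#' @description
#' Covariates describing pollution sources around a location come in two
#' metric families: *proximity* (distance to the nearest source of a kind)
#' and *density* (how much of a kind falls inside a circular buffer). Raw
#' proximity is truncated and log-transformed before modelling; variables
#' with too little spatial variability are screened out; and the retained
#' matrix is z-scaled so clustering is not driven by units.
NULL

feature_vars <- function(features) setdiff(names(features), "location_id")

# squared distance from points (px, py) to segment (x1,y1)-(x2,y2)
dist2_point_segment <- function(px, py, x1, y1, x2, y2) {
  dx <- x2 - x1; dy <- y2 - y1
  len2 <- dx * dx + dy * dy
  t <- if (len2 == 0) rep(0, length(px)) else
    pmin(1, pmax(0, ((px - x1) * dx + (py - y1) * dy) / len2))
  (px - (x1 + t * dx))^2 + (py - (y1 + t * dy))^2
}

# length of segment (x1,y1)-(x2,y2) inside the circle centred at (cx, cy);
# closed form from the quadratic |a + t(b-a) - c|^2 = r^2, t clipped to [0,1]
segment_length_in_circle <- function(cx, cy, x1, y1, x2, y2, radius) {
  dx <- x2 - x1; dy <- y2 - y1
  seg_len <- sqrt(dx * dx + dy * dy)
  if (seg_len == 0) return(rep(0, length(cx)))
  fx <- x1 - cx; fy <- y1 - cy
  a <- dx * dx + dy * dy
  b <- 2 * (fx * dx + fy * dy)
  cc <- fx * fx + fy * fy - radius^2
  disc <- b * b - 4 * a * cc
  out <- numeric(length(cx))
  ok <- disc > 0
  if (any(ok)) {
    sq <- sqrt(disc[ok])
    t1 <- pmax(0, (-b[ok] - sq) / (2 * a))
    t2 <- pmin(1, (-b[ok] + sq) / (2 * a))
    out[ok] <- pmax(0, t2 - t1) * seg_len
  }
  out
}

#' Distance to the nearest pollution source of a kind
#'
#' @param locations Tibble with columns `x`, `y` (planar metres).
#' @param sources Source set as produced by [generate_city()]: a list with
#'   tibbles `lines` (`kind`, `x1`, `y1`, `x2`, `y2`) and `points`
#'   (`kind`, `x`, `y`).
#' @param kind Source kind to measure against.
#' @return Numeric vector of Euclidean distances in metres (nearest point on
#'   a segment for line sources).
#' @export
proximity_variable <- function(locations, sources, kind) {
  lines <- if (!is.null(sources$lines) && nrow(sources$lines)) {
    filter(sources$lines, .data$kind == .env$kind)
  }
  pts <- if (!is.null(sources$points) && nrow(sources$points)) {
    filter(sources$points, .data$kind == .env$kind)
  }
  n_geom <- (if (is.null(lines)) 0L else nrow(lines)) +
    (if (is.null(pts)) 0L else nrow(pts))
  if (n_geom == 0) {
    abort(paste0("no sources of kind '", kind, "'"), class = "sitenet_source_error")
  }
  d2 <- rep(Inf, nrow(locations))
  if (!is.null(pts) && nrow(pts)) {
    for (i in seq_len(nrow(pts))) {
      d2 <- pmin(d2, (locations$x - pts$x[i])^2 + (locations$y - pts$y[i])^2)
    }
  }
  if (!is.null(lines) && nrow(lines)) {
    for (i in seq_len(nrow(lines))) {
      d2 <- pmin(d2, dist2_point_segment(locations$x, locations$y,
                                         lines$x1[i], lines$y1[i],
                                         lines$x2[i], lines$y2[i]))
    }
  }
  sqrt(d2)
}

#' Source density within a circular buffer
#'
#' Point sources are counted; line sources contribute their clipped length
#' inside the buffer, in metres.
#'
#' @inheritParams proximity_variable
#' @param radius Buffer radius in metres (> 0).
#' @return Numeric vector, one value per location.
#' @export
density_variable <- function(locations, sources, kind, radius) {
  if (radius <= 0) abort("radius must be > 0", class = "sitenet_buffer_error")
  out <- numeric(nrow(locations))
  if (!is.null(sources$points) && nrow(sources$points)) {
    pts <- filter(sources$points, .data$kind == .env$kind)
    for (i in seq_len(nrow(pts))) {
      out <- out + (((locations$x - pts$x[i])^2 + (locations$y - pts$y[i])^2) <= radius^2)
    }
  }
  if (!is.null(sources$lines) && nrow(sources$lines)) {
    lines <- filter(sources$lines, .data$kind == .env$kind)
    for (i in seq_len(nrow(lines))) {
      out <- out + segment_length_in_circle(locations$x, locations$y,
                                            lines$x1[i], lines$y1[i],
                                            lines$x2[i], lines$y2[i], radius)
    }
  }
  out
}

#' Recode a proximity variable
#'
#' Truncates distances at `cap` metres, then log-transforms:
#' `log(min(d, cap) + offset)`. The 1 m offset keeps zero distances finite;
#' the default cap of 1 km (2 km is conventional for large physical features
#' such as coastlines and rivers) reflects that source influence decays
#' within about a kilometre.
#'
#' @param column Numeric vector of non-negative distances in metres.
#' @param cap Truncation cap in metres.
#' @param offset Offset added before the log, metres.
#' @param base Logarithm base (natural log by default).
#' @return Recoded numeric vector, bounded above by `log(cap + offset)`.
#' @export
recode_proximity <- function(column, cap = 1000, offset = 1, base = exp(1)) {
  if (any(column < 0, na.rm = TRUE)) {
    abort("distances must be >= 0", class = "sitenet_recode_error")
  }
  log(pmin(column, cap) + offset, base = base)
}

#' Screen out low-variability covariates
#'
#' Applies two independent rules to a recoded feature matrix: (1) drop any
#' variable whose fraction of distinct values across locations is below
#' `unique_frac`; (2) drop any land-use area-share variable whose maximum
#' buffer-area percentage is below `100 * land_use_frac`. Land-use variables
#' are identified by `land_use_flag` in the matrix's `meta` attribute (or by
#' the `meta` argument).
#'
#' @param features Feature tibble (`location_id` + covariate columns).
#' @param unique_frac Minimum fraction of distinct values to keep a variable.
#' @param land_use_frac Minimum maximum area share (on the 0-1 scale; the
#'   variable itself is in percent) to keep a land-use variable.
#' @param meta Optional variable metadata overriding `attr(features, "meta")`.
#' @return List with `features` (screened tibble, metadata subset accordingly)
#'   and `report` (tibble: variable, reason) listing each dropped variable.
#' @export
exclude_low_variability <- function(features, unique_frac = 0.10,
                                    land_use_frac = 0.10, meta = NULL) {
  meta <- meta %||% attr(features, "meta")
  vars <- feature_vars(features)
  n <- nrow(features)
  report <- list()
  drop <- character()
  for (vn in vars) {
    uf <- dplyr::n_distinct(features[[vn]]) / n
    if (uf < unique_frac) {
      drop <- c(drop, vn)
      report[[vn]] <- tibble(variable = vn, reason = "low_unique_fraction",
                             value = uf)
      next
    }
    is_lu <- !is.null(meta) && vn %in% meta$name &&
      isTRUE(meta$land_use_flag[match(vn, meta$name)])
    if (is_lu && max(features[[vn]]) < 100 * land_use_frac) {
      drop <- c(drop, vn)
      report[[vn]] <- tibble(variable = vn, reason = "low_land_use_share",
                             value = max(features[[vn]]))
    }
  }
  kept <- features[, c("location_id", setdiff(vars, drop))]
  if (!is.null(meta)) attr(kept, "meta") <- filter(meta, !.data$name %in% drop)
  attr(kept, "state") <- attr(features, "state")
  list(features = kept,
       report = if (length(report)) bind_rows(report) else
         tibble(variable = character(), reason = character(), value = double()))
}

#' Z-scale a feature matrix
#'
#' Centres each covariate to mean zero and scales to unit standard deviation.
#' The per-variable means and SDs are stored so the identical transform can
#' be applied to new locations ([zscale_apply()]) or inverted
#' ([zscale_invert()]). Scaling statistics should be computed over the pooled
#' current + subject + candidate set, since clustering runs on all locations.
#'
#' @param features Feature tibble (`location_id` + covariate columns), no
#'   zero-SD columns (screen with [exclude_low_variability()] first).
#' @param denominator `"sample"` (n-1, default) or `"population"` (n) SD.
#' @return Scaled tibble with the per-variable statistics in
#'   `attr(, "scaling")` (tibble: variable, mean, sd).
#' @export
zscale <- function(features, denominator = c("sample", "population")) {
  denominator <- match.arg(denominator)
  vars <- feature_vars(features)
  n <- nrow(features)
  mus <- vapply(features[vars], mean, numeric(1))
  sds <- vapply(features[vars], sd, numeric(1))
  if (denominator == "population") sds <- sds * sqrt((n - 1) / n)
  if (any(sds == 0)) {
    abort(paste0("zero-SD column(s): ", paste(vars[sds == 0], collapse = ", "),
                 "; run exclude_low_variability() first"),
          class = "sitenet_scale_error")
  }
  scaling <- tibble(variable = vars, mean = unname(mus), sd = unname(sds))
  out <- zscale_apply(features, scaling)
  attr(out, "meta") <- attr(features, "meta")
  out
}

#' @rdname zscale
#' @param scaling Statistics tibble from a previous [zscale()].
#' @export
zscale_apply <- function(features, scaling) {
  missing_vars <- setdiff(scaling$variable, names(features))
  if (length(missing_vars)) {
    abort(paste0("features lack scaled variable(s): ",
                 paste(missing_vars, collapse = ", ")),
          class = "sitenet_scale_error")
  }
  out <- features[, c("location_id", scaling$variable)]
  for (i in seq_len(nrow(scaling))) {
    vn <- scaling$variable[i]
    out[[vn]] <- (out[[vn]] - scaling$mean[i]) / scaling$sd[i]
  }
  attr(out, "scaling") <- scaling
  attr(out, "state") <- "scaled"
  out
}

#' @rdname zscale
#' @export
zscale_invert <- function(features, scaling = attr(features, "scaling")) {
  stopifnot(!is.null(scaling))
  out <- features
  for (i in seq_len(nrow(scaling))) {
    vn <- scaling$variable[i]
    out[[vn]] <- out[[vn]] * scaling$sd[i] + scaling$mean[i]
  }
  attr(out, "scaling") <- NULL
  attr(out, "state") <- "recoded"
  out
}
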