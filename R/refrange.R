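#' @importFrom stats shapiro.test
#' @importFrom grDevices chull
NULL

transform_funs <- list(
  identity = list(f = function(x) x, inv = function(x) x,
                  admissible = function(x) TRUE),
  log = list(f = log, inv = exp,
             admissible = function(x) all(x > 0)),
  sqrt = list(f = sqrt, inv = function(x) pmax(x, 0)^2,
              admissible = function(x) all(x >= 0)),
  inverse = list(f = function(x) 1 / x, inv = function(x) 1 / x,
                 admissible = function(x) all(x != 0))
)

shapiro_p <- function(x) {
  # Shapiro-Wilk is defined for 3..5000 values; larger samples are thinned
  # deterministically to 5000 evenly spaced observations
  if (length(x) > 5000) x <- x[round(seq(1, length(x), length.out = 5000))]
  if (stats::sd(x) == 0) return(0)
  shapiro.test(x)$p.value
}

#' Select a normalizing transformation by the Shapiro-Wilk test
#'
#' Tries identity, log, square root and inverse in that order; a
#' transformation is admissible only when defined for every value (log
#' needs positives, square root non-negatives, inverse non-zeros). The
#' first admissible transformation whose transformed values pass the
#' Shapiro-Wilk normality test at `alpha` is returned; when none passes,
#' `"none"` signals that percentile bounds must be used instead.
#'
#' @param values Numeric vector, at least 3 finite values.
#' @param alpha Shapiro-Wilk significance level (default 0.05; p-values at
#'   or above `alpha` are consistent with normality).
#' @return A list with `transform` (one of `"identity"`, `"log"`,
#'   `"sqrt"`, `"inverse"`, `"none"`) and `shapiro_p` (for the chosen
#'   transform; the best attempt when `"none"`).
#' @export
select_transform <- function(values, alpha = 0.05) {
  values <- values[is.finite(values)]
  if (length(values) < 3) {
    stop("select_transform needs at least 3 finite values", call. = FALSE)
  }
  best_p <- -Inf
  for (nm in names(transform_funs)) {
    tr <- transform_funs[[nm]]
    if (!tr$admissible(values)) next
    p <- shapiro_p(tr$f(values))
    if (p >= alpha) return(list(transform = nm, shapiro_p = p))
    best_p <- max(best_p, p)
  }
  list(transform = "none", shapiro_p = if (is.finite(best_p)) best_p else NA_real_)
}

#' rr95 reference range for one variable
#'
#' The interval expected to contain 95% of control values. When the values
#' are normal under one of the candidate transformations (Shapiro-Wilk
#' gate, see [select_transform()]), the bounds are mean +/- 2 standard
#' deviations on the transformed scale, back-transformed to the original
#' scale (bound order swapped for the inverse transform). Otherwise the
#' bounds are the 2.5th and 97.5th empirical percentiles (type-7 linear
#' interpolation, so bounds are reproducible bit for bit). Cohorts below
#' 120 animals get a `small_n_warning`, following the CLSI EP28
#' recommendation for stable reference limits.
#'
#' @param values Numeric vector of control values (>= 3 finite).
#' @param transform `NULL` to select automatically, or one of
#'   `"identity"`, `"log"`, `"sqrt"`, `"inverse"`, `"none"` to force.
#' @param alpha Shapiro-Wilk level for automatic selection.
#' @param min_n Cohort size below which `small_n_warning` is set.
#' @return A one-row tibble: `transform`, `method`
#'   (`"parametric"`/`"percentile"`), `lower`, `upper` (original scale),
#'   `n`, `shapiro_p`, `small_n_warning`.
#' @export
rr95 <- function(values, transform = NULL, alpha = 0.05, min_n = 120) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 3) stop("rr95 needs at least 3 finite values", call. = FALSE)
  if (stats::sd(values) == 0) {
    stop("rr95 undefined: zero variance (bounds would collapse)",
         call. = FALSE)
  }
  if (is.null(transform)) {
    sel <- select_transform(values, alpha = alpha)
    transform <- sel$transform
    sp <- sel$shapiro_p
  } else {
    transform <- match.arg(transform,
                           c("identity", "log", "sqrt", "inverse", "none"))
    sp <- if (transform == "none") NA_real_ else {
      tr <- transform_funs[[transform]]
      if (!tr$admissible(values)) {
        stop("transform '", transform, "' is not defined for these values",
             call. = FALSE)
      }
      shapiro_p(tr$f(values))
    }
  }
  if (transform == "none") {
    b <- unname(quantile(values, c(0.025, 0.975), type = 7))
    lower <- b[1]; upper <- b[2]
    method <- "percentile"
  } else {
    tr <- transform_funs[[transform]]
    t_vals <- tr$f(values)
    m <- mean(t_vals); s <- sd(t_vals)
    lo_t <- m - 2 * s; hi_t <- m + 2 * s
    if (transform == "inverse") {
      # 1/x reverses order; with bounds straddling 0 the upper limit is open
      lower <- if (hi_t > 0) 1 / hi_t else -Inf
      upper <- if (lo_t > 0 || hi_t < 0) 1 / lo_t else Inf
    } else {
      lower <- tr$inv(lo_t)
      upper <- tr$inv(hi_t)
    }
    method <- "parametric"
  }
  tibble::tibble(transform = transform, method = method,
                 lower = lower, upper = upper, n = n, shapiro_p = sp,
                 small_n_warning = n < min_n)
}

numeric_variables <- function(tab) {
  nm <- setdiff(names(tab), c("animal_id", "sex", "cohort"))
  nm[vapply(tab[nm], is.numeric, logical(1))]
}

#' Screen project control animals against historical reference ranges
#'
#' For each quantitative variable, the rr95 is computed per sex from the
#' historical controls, and the project-control mean (per sex, original
#' scale) is compared with it. A variable is discarded when its project
#' mean falls strictly outside the rr95 for males or for females; a mean
#' exactly on a bound is kept.
#'
#' @param historical,project Tibbles with `animal_id`, `sex` (`M`/`F`) and
#'   one numeric column per variable (a `cohort` column is ignored). The
#'   two tables must share all variables.
#' @param alpha,min_n Passed to [rr95()].
#' @return A tibble with one row per variable x sex: the range used, the
#'   project mean, `outside` (that sex), and `discard` (the per-variable
#'   decision, identical across the variable's rows).
#' @export
flag_project_controls <- function(historical, project, alpha = 0.05,
                                  min_n = 120) {
  vars_h <- numeric_variables(historical)
  vars_p <- numeric_variables(project)
  miss <- union(setdiff(vars_h, vars_p), setdiff(vars_p, vars_h))
  if (length(miss)) {
    stop("variable(s) absent from one of the tables: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  out <- purrr::map_dfr(vars_h, function(v) {
    purrr::map_dfr(c("M", "F"), function(sx) {
      hv <- historical[[v]][historical$sex == sx]
      rng <- rr95(hv, alpha = alpha, min_n = min_n)
      pm <- mean(project[[v]][project$sex == sx], na.rm = TRUE)
      dplyr::mutate(rng, variable = v, sex = sx, project_mean = pm,
                    outside = is.finite(pm) &
                      (pm < rng$lower | pm > rng$upper),
                    .before = 1)
    })
  })
  out |>
    dplyr::group_by(.data$variable) |>
    dplyr::mutate(discard = any(.data$outside)) |>
    dplyr::ungroup()
}

# TRUE for each row of `points` lying inside (or on) the convex hull of
# `ref` (both two-column matrices); half-plane test with tolerance.
in_convex_hull <- function(points, ref, tol = 1e-9) {
  h <- chull(ref)
  if (length(h) < 3) {
    warning("degenerate (collinear) historical score cloud")
    return(rep(FALSE, nrow(points)))
  }
  v <- ref[h, , drop = FALSE]
  nh <- nrow(v)
  # consistent orientation sign from the polygon's signed area
  area2 <- sum(v[, 1] * v[c(2:nh, 1), 2] - v[c(2:nh, 1), 1] * v[, 2])
  sgn <- sign(area2)
  scale_tol <- tol * max(abs(ref))
  apply(points, 1, function(p) {
    for (i in seq_len(nh)) {
      a <- v[i, ]; b <- v[if (i == nh) 1 else i + 1, ]
      cross <- (b[1] - a[1]) * (p[2] - a[2]) - (b[2] - a[2]) * (p[1] - a[1])
      if (sgn * cross < -scale_tol) return(FALSE)
    }
    TRUE
  })
}

#' PCA overlay of project controls on the historical control cloud
#'
#' Fits a PCA (centered, unit-variance scaled) on the historical control
#' animals and projects the project controls into the same space; each
#' project animal is classified as inside or outside the 2D convex hull of
#' the historical scores. Missing values are imputed by the historical
#' per-variable mean for the decomposition.
#'
#' @param historical,project Tibbles as in [flag_project_controls()].
#' @param n_components Components to return (hull test uses the first 2).
#' @return A list with `historical_scores`, `project_scores` (tibbles,
#'   the latter with an `inside` flag) and `prop_inside`.
#' @export
control_pca_overlay <- function(historical, project, n_components = 2) {
  vars <- intersect(numeric_variables(historical), numeric_variables(project))
  if (length(vars) == 0) {
    stop("historical and project tables share no numeric variables",
         call. = FALSE)
  }
  if (nrow(historical) < 3) {
    stop("need at least 3 historical animals", call. = FALSE)
  }
  hx <- as.matrix(historical[vars])
  px <- as.matrix(project[vars])
  for (j in seq_len(ncol(hx))) {
    mj <- mean(hx[, j], na.rm = TRUE)
    hx[is.na(hx[, j]), j] <- mj
    px[is.na(px[, j]), j] <- mj
  }
  keep <- apply(hx, 2, stats::sd) > 0
  hx <- hx[, keep, drop = FALSE]; px <- px[, keep, drop = FALSE]
  p <- prcomp(hx, center = TRUE, scale. = TRUE)
  k <- min(n_components, ncol(p$x))
  hs <- p$x[, seq_len(k), drop = FALSE]
  ps <- predict(p, px)[, seq_len(k), drop = FALSE]
  inside <- in_convex_hull(ps[, 1:2, drop = FALSE], hs[, 1:2, drop = FALSE])
  list(
    historical_scores = dplyr::bind_cols(
      tibble::tibble(animal_id = historical$animal_id),
      tibble::as_tibble(hs)),
    project_scores = dplyr::bind_cols(
      tibble::tibble(animal_id = project$animal_id),
      tibble::as_tibble(ps), tibble::tibble(inside = inside)),
    prop_inside = mean(inside))
}
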