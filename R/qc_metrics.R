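#' @importFrom stats cor.test cov mahalanobis p.adjust prcomp quantile var
NULL

# Samples entering the quality metrics: all non-blank injections except the
# pool-dilution series, whose intensities vary by design and would be read
# as drift. Returned in injection order.
metric_samples <- function(data) {
  samples_of_type(data, c("pool", "sample"))
}

# samples x features PCA score matrix. Missing values are mean-imputed per
# feature for the decomposition only; constant features are dropped when
# scaling to unit variance.
pca_scores <- function(data, sample_ids, n_components = 3, scale = TRUE) {
  x <- t(data$intensities[, sample_ids, drop = FALSE])
  for (j in seq_len(ncol(x))) {
    miss <- is.na(x[, j])
    if (any(miss)) x[miss, j] <- mean(x[, j], na.rm = TRUE)
  }
  keep <- apply(x, 2, function(v) !anyNA(v) && stats::sd(v) > 0)
  x <- x[, keep, drop = FALSE]
  if (ncol(x) == 0) stop("no informative features for PCA", call. = FALSE)
  p <- prcomp(x, center = TRUE, scale. = scale)
  k <- min(n_components, ncol(p$x))
  p$x[, seq_len(k), drop = FALSE]
}

new_qc_metric <- function(metric, score, detail) {
  structure(list(metric = metric, score = score, detail = detail),
            class = "qc_metric")
}

#' @export
print.qc_metric <- function(x, ...) {
  cat(sprintf("<qc_metric> %s: %.1f\n", x$metric, x$score))
  invisible(x)
}

#' Drift Spearman: share of features uncorrelated with injection order
#'
#' For every feature, the Spearman rank correlation between intensity and
#' injection order is tested over the non-blank injections (pooled QCs and
#' biological samples; the dilution series is excluded). P-values are
#' adjusted by Benjamini-Hochberg and the score is
#' `(1 - p_correlated / p_total) * 100`, the percentage of features *not*
#' significantly drifting at the given false-discovery rate. 100 is ideal.
#'
#' Exact permutation p-values are used for 10 or fewer observations, the
#' t approximation otherwise. Features with fewer than 4 observed values
#' are excluded from the denominator.
#'
#' @param data An [ms_dataset()] with `injection_order`.
#' @param fdr False-discovery-rate level (default 0.05).
#' @return A `qc_metric` with `score` and `detail` (`p_correlated`,
#'   `p_total`, per-feature tibble of rho and adjusted p).
#' @export
drift_spearman <- function(data, fdr = 0.05) {
  ids <- metric_samples(data)
  if (length(ids) < 4) {
    stop("drift_spearman requires at least 4 non-blank samples", call. = FALSE)
  }
  ord <- data$samples$injection_order[match(ids, data$samples$sample_id)]
  mat <- data$intensities[, ids, drop = FALSE]
  res <- apply(mat, 1, function(v) {
    ok <- !is.na(v)
    if (sum(ok) < 4) return(c(NA_real_, NA_real_))
    ct <- suppressWarnings(
      cor.test(v[ok], ord[ok], method = "spearman",
               exact = sum(ok) <= 10)
    )
    c(unname(ct$estimate), ct$p.value)
  })
  rho <- res[1, ]; p <- res[2, ]
  eligible <- !is.na(p)
  if (!any(eligible)) stop("no feature with enough observations", call. = FALSE)
  padj <- rep(NA_real_, length(p))
  padj[eligible] <- p.adjust(p[eligible], method = "BH")
  p_total <- sum(eligible)
  p_correlated <- sum(padj <= fdr, na.rm = TRUE)
  score <- (1 - p_correlated / p_total) * 100
  new_qc_metric("drift_spearman", score,
                list(p_correlated = p_correlated, p_total = p_total,
                     fdr = fdr,
                     per_feature = tibble::tibble(
                       feature_id = rownames(mat), rho = rho, p = p,
                       p_adj = padj)))
}

#' Drift PCA: injection-order variance outside the first components
#'
#' Principal component analysis (features centered and unit-variance
#' scaled) of the non-blank injections; the centered injection-order
#' vector is projected onto the span of the first `n_components` score
#' vectors. With `cos2_alpha` the squared cosine of the angle between the
#' injection-order direction and its projection, the score is
#' `(1 - cos2_alpha) * 100`: 100 means the injection-order gradient is
#' orthogonal to the principal subspace (no multivariate drift).
#'
#' @param data An [ms_dataset()] with `injection_order`.
#' @param n_components Dimension of the principal subspace (default 3).
#' @param scale Scale features to unit variance before PCA (default TRUE).
#' @return A `qc_metric` with `detail` holding `cos2_alpha` and the score
#'   matrix.
#' @export
drift_pca <- function(data, n_components = 3, scale = TRUE) {
  ids <- metric_samples(data)
  if (length(ids) < n_components + 2) {
    stop("drift_pca requires at least n_components + 2 samples", call. = FALSE)
  }
  ord <- data$samples$injection_order[match(ids, data$samples$sample_id)]
  if (length(unique(ord)) < 2) stop("degenerate injection order", call. = FALSE)
  scores <- pca_scores(data, ids, n_components, scale = scale)
  o <- ord - mean(ord)
  # qr-based projection tolerates rank-deficient score matrices (fewer
  # informative components than requested)
  proj <- qr.fitted(qr(scores), o)
  cos2 <- sum(proj^2) / sum(o^2)
  cos2 <- min(max(cos2, 0), 1)
  new_qc_metric("drift_pca", (1 - cos2) * 100,
                list(cos2_alpha = cos2, scores = scores,
                     injection_order = ord))
}

#' QC spread: pooled-QC compactness in the principal subspace
#'
#' PCA (as in [drift_pca()]) of pooled QCs and biological samples jointly;
#' each sample's score vector gets a Mahalanobis distance to the score
#' centroid under the covariance of all included samples' scores. The
#' score is `(1 - max(d_QC) / max(d_sample)) * 100`, clamped below at 0:
#' 100 means every pooled QC sits at the centroid, 0 that a pooled QC is
#' at least as far out as the farthest biological sample.
#'
#' @inheritParams drift_pca
#' @return A `qc_metric` with `detail` holding `max_d_qc`, `max_d_sample`
#'   and the per-sample distances.
#' @export
qc_spread <- function(data, n_components = 3, scale = TRUE) {
  pools <- samples_of_type(data, "pool")
  bios <- samples_of_type(data, "sample")
  if (length(pools) < 2 || length(bios) < 2) {
    stop("qc_spread requires >= 2 pool and >= 2 sample injections",
         call. = FALSE)
  }
  ids <- c(pools, bios)
  scores <- pca_scores(data, ids, n_components, scale = scale)
  # discard numerically dead components so the score covariance stays
  # invertible when the data have fewer informative dimensions
  sdev <- apply(scores, 2, stats::sd)
  scores <- scores[, sdev > 1e-10 * max(sdev), drop = FALSE]
  ctr <- colMeans(scores)
  S <- cov(scores)
  d2 <- tryCatch(mahalanobis(scores, ctr, S),
                 error = function(e) stop("singular score covariance",
                                          call. = FALSE))
  d <- sqrt(pmax(d2, 0))
  names(d) <- ids
  max_d_qc <- max(d[pools])
  max_d_sample <- max(d[bios])
  score <- max(0, (1 - max_d_qc / max_d_sample) * 100)
  new_qc_metric("qc_spread", score,
                list(max_d_qc = max_d_qc, max_d_sample = max_d_sample,
                     distances = tibble::tibble(
                       sample_id = ids,
                       sample_type = rep(c("pool", "sample"),
                                         c(length(pools), length(bios))),
                       mahalanobis = unname(d))))
}

#' QC CV: share of features reliable in the pooled QCs
#'
#' Percentage of features whose raw-scale coefficient of variation over the
#' pooled QC injections is at or below `cv_threshold` (conventionally 30%).
#' Only features with at least 3 observed pool values enter the
#' denominator. The detail includes the cumulative percentage-of-features
#' versus CV curve.
#'
#' @param data A raw-scale [ms_dataset()].
#' @param cv_threshold CV cut-off (default 0.30, boundary inclusive).
#' @return A `qc_metric` with `detail` holding `p_cv_le`, `p_total`, the
#'   per-feature CVs and the cumulative curve.
#' @export
qc_cv <- function(data, cv_threshold = 0.30) {
  pools <- samples_of_type(data, "pool")
  if (length(pools) < 3) {
    stop("qc_cv requires at least 3 pool injections", call. = FALSE)
  }
  cv <- feature_cv(data$intensities[, pools, drop = FALSE])
  eligible <- !is.na(cv)
  if (!any(eligible)) stop("no feature with 3 observed pool values",
                           call. = FALSE)
  p_total <- sum(eligible)
  p_le <- sum(cv[eligible] <= cv_threshold)
  grid <- seq(0, 1, by = 0.01)
  curve <- tibble::tibble(
    cv = grid,
    cum_pct = vapply(grid, function(g) 100 * mean(cv[eligible] <= g),
                     numeric(1)))
  new_qc_metric("qc_cv", 100 * p_le / p_total,
                list(p_cv_le = p_le, p_total = p_total,
                     cv_threshold = cv_threshold,
                     per_feature = tibble::tibble(
                       feature_id = rownames(data$intensities), qc_cv = cv),
                     curve = curve))
}

# ICC(A,1): two-way random effects, absolute agreement, single rater.
# y is an n (subjects/features) x k (raters/injections) complete matrix.
icc_a1 <- function(y) {
  n <- nrow(y); k <- ncol(y)
  if (n < 2 || k < 2) stop("ICC needs at least a 2 x 2 matrix", call. = FALSE)
  grand <- mean(y)
  rm <- rowMeans(y); cm <- colMeans(y)
  ssr <- k * sum((rm - grand)^2)
  ssc <- n * sum((cm - grand)^2)
  sst <- sum((y - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse + (k / n) * (msc - mse)
  if (!is.finite(denom) || denom == 0) {
    stop("ICC undefined: no variance in the matrix", call. = FALSE)
  }
  (msr - mse) / denom
}

#' QC ICC: pooled-QC reliability at the most probable abundance
#'
#' Features with complete pooled-QC values are binned into `n_bins`
#' equal-width bins of log2 median pool intensity; within each bin the
#' intraclass correlation ICC(A,1) — two-way random effects, absolute
#' agreement, single measurement — is computed on the bin's features x
#' pool-injections matrix. The score is 100 times the ICC of the modal
#' (most populated) bin, clamped to \[0, 100\].
#'
#' @param data A raw-scale [ms_dataset()].
#' @param n_bins Number of equal-width intensity bins (default 10).
#' @return A `qc_metric` with `detail` holding the per-bin ICCs and the
#'   modal bin.
#' @export
qc_icc <- function(data, n_bins = 10) {
  pools <- samples_of_type(data, "pool")
  if (length(pools) < 3) {
    stop("qc_icc requires at least 3 pool injections", call. = FALSE)
  }
  mat <- data$intensities[, pools, drop = FALSE]
  complete <- apply(mat, 1, function(v) !anyNA(v) && all(v > 0))
  mat <- mat[complete, , drop = FALSE]
  if (nrow(mat) < n_bins) {
    stop("qc_icc requires at least n_bins features with complete positive ",
         "pool values", call. = FALSE)
  }
  med <- log2(apply(mat, 1, median))
  if (diff(range(med)) == 0) {
    bin <- rep(1L, length(med))
    breaks <- c(med[1] - 0.5, med[1] + 0.5, seq_len(n_bins - 1) + med[1] + 0.5)
  } else {
    breaks <- seq(min(med), max(med), length.out = n_bins + 1)
    bin <- cut(med, breaks = breaks, include.lowest = TRUE, labels = FALSE)
  }
  counts <- tabulate(bin, nbins = n_bins)
  modal <- which.max(counts)
  if (counts[modal] < 3) {
    stop("modal intensity bin holds fewer than 3 features", call. = FALSE)
  }
  icc_by_bin <- vapply(seq_len(n_bins), function(b) {
    idx <- which(bin == b)
    if (length(idx) < 3) return(NA_real_)
    tryCatch(icc_a1(mat[idx, , drop = FALSE]), error = function(e) NA_real_)
  }, numeric(1))
  icc_modal <- icc_a1(mat[bin == modal, , drop = FALSE])
  score <- min(max(icc_modal, 0), 1) * 100
  new_qc_metric("qc_icc", score,
                list(icc_by_bin = tibble::tibble(
                       bin = seq_len(n_bins),
                       midpoint = (breaks[-1] + breaks[-(n_bins + 1)]) / 2,
                       n_features = counts, icc = icc_by_bin),
                     modal_bin = modal, icc_modal = icc_modal,
                     n_bins = n_bins))
}

#' Assemble the five-metric quality report
#'
#' Computes Drift Spearman, Drift PCA, QC spread, QC CV and QC ICC on a
#' dataset that has been drift-corrected but not yet feature-filtered on
#' the pooled-QC CVs (the state at which the metrics are meaningful). All
#' scores lie in \[0, 100\]; 100 is the highest quality.
#'
#' @param data A raw-scale [ms_dataset()] with pools, biological samples
#'   and injection order.
#' @param fdr FDR level for Drift Spearman.
#' @param n_components Principal-subspace dimension for the PCA metrics.
#' @param cv_threshold Pooled-QC CV cut-off.
#' @param n_bins Intensity bins for QC ICC.
#' @param scale Unit-variance scaling for the PCA metrics.
#' @return An object of class `quality_report`; `tidy()` gives the
#'   metric/score table, `glance()` a one-row summary, `autoplot()` the
#'   radar plot.
#' @export
quality_report <- function(data, fdr = 0.05, n_components = 3,
                           cv_threshold = 0.30, n_bins = 10, scale = TRUE) {
  if (length(samples_of_type(data, "pool")) == 0) {
    stop("no samples with sample_type 'pool'; the QC metrics need pooled QCs",
         call. = FALSE)
  }
  metrics <- list(
    drift_spearman(data, fdr = fdr),
    drift_pca(data, n_components = n_components, scale = scale),
    qc_spread(data, n_components = n_components, scale = scale),
    qc_cv(data, cv_threshold = cv_threshold),
    qc_icc(data, n_bins = n_bins)
  )
  names(metrics) <- vapply(metrics, `[[`, character(1), "metric")
  structure(list(metrics = metrics), class = "quality_report")
}

#' @export
print.quality_report <- function(x, ...) {
  cat("<quality_report>\n")
  print(as.data.frame(tidy(x)), row.names = FALSE)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.quality_report <- function(x, ...) {
  tibble::tibble(
    metric = names(x$metrics),
    score = vapply(x$metrics, `[[`, numeric(1), "score"))
}

#' @exportS3Method generics::glance
glance.quality_report <- function(x, ...) {
  s <- tidy(x)
  out <- tibble::as_tibble(as.list(stats::setNames(s$score, s$metric)))
  out$mean_score <- mean(s$score)
  out
}

#' Radar plot of the five quality metrics
#'
#' @param object A [quality_report()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.quality_report <- function(object, ...) {
  s <- tidy(object)
  s$metric <- factor(s$metric, levels = s$metric)
  ggplot2::ggplot(s, ggplot2::aes(x = .data$metric, y = .data$score,
                                  group = 1)) +
    ggplot2::geom_polygon(fill = "steelblue", alpha = 0.3) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::geom_point(color = "steelblue") +
    ggplot2::coord_polar() +
    ggplot2::ylim(0, 100) +
    ggplot2::labs(x = NULL, y = "score") +
    ggplot2::theme_minimal()
}

#' PCA score plot colored by injection order
#'
#' Scores of the non-blank injections on the first two principal
#' components, pooled QCs marked by shape, a color gradient tracking the
#' injection order so drift shows as a color sweep across the plot.
#'
#' @param data An [ms_dataset()].
#' @param scale Unit-variance scaling before PCA.
#' @return A ggplot object.
#' @export
plot_pca_scores <- function(data, scale = TRUE) {
  ids <- metric_samples(data)
  scores <- pca_scores(data, ids, n_components = 2, scale = scale)
  df <- tibble::tibble(
    pc1 = scores[, 1], pc2 = scores[, 2],
    injection_order = data$samples$injection_order[
      match(ids, data$samples$sample_id)],
    sample_type = data$samples$sample_type[
      match(ids, data$samples$sample_id)])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pc1, y = .data$pc2,
                                   color = .data$injection_order,
                                   shape = .data$sample_type)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_color_viridis_c() +
    ggplot2::labs(x = "PC1", y = "PC2") +
    ggplot2::theme_minimal()
}

#' Screen spiked standards for outlying samples
#'
#' For each spiked standard (internal or external), intensities across the
#' non-blank samples are z-scored; (sample, standard) pairs with |z| above
#' `z_threshold` are returned for manual review, together with the
#' per-standard CV summary used to report overall signal consistency.
#'
#' @param data An [ms_dataset()].
#' @param standards Character vector of feature identifiers of the spiked
#'   standards; each must have at least 3 observed values.
#' @param z_threshold Flagging threshold on |z| (default 3, strict).
#' @return A list with `flagged` (tibble of sample_id, standard, z) and
#'   `summary` (per-standard mean, sd, cv).
#' @export
flag_standard_outliers <- function(data, standards, z_threshold = 3) {
  missing <- setdiff(standards, rownames(data$intensities))
  if (length(missing)) {
    stop("standard(s) absent from the dataset: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  ids <- samples_of_type(data, c("pool", "sample"))
  flagged <- list()
  summ <- list()
  for (st in standards) {
    v <- data$intensities[st, ids]
    ok <- !is.na(v)
    if (sum(ok) < 3) {
      stop("standard ", st, " has fewer than 3 observed values", call. = FALSE)
    }
    m <- mean(v[ok]); s <- sd(v[ok])
    z <- if (s == 0) rep(0, sum(ok)) else (v[ok] - m) / s
    hit <- abs(z) > z_threshold
    if (any(hit)) {
      flagged[[st]] <- tibble::tibble(sample_id = ids[ok][hit],
                                      standard = st, z = unname(z[hit]))
    }
    summ[[st]] <- tibble::tibble(standard = st, mean = m, sd = s,
                                 cv = if (m == 0) NA_real_ else s / m)
  }
  list(flagged = if (length(flagged)) dplyr::bind_rows(flagged) else
         tibble::tibble(sample_id = character(0), standard = character(0),
                        z = numeric(0)),
       summary = dplyr::bind_rows(summ))
}
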