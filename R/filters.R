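#' @importFrom stats cor loess median predict sd approx
NULL

new_filter_report <- function(step, data_in, discarded, params,
                              skipped = FALSE, note = NULL) {
  if (is.null(discarded)) {
    discarded <- tibble::tibble(feature_id = character(0),
                                reason = character(0))
  }
  structure(
    list(step = step,
         n_features_in = nrow(data_in$intensities),
         n_features_out = nrow(data_in$intensities) - nrow(discarded),
         discarded = discarded,
         params = params,
         skipped = skipped,
         note = note),
    class = "filter_report"
  )
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("<filter_report> %s: %d -> %d features (%d discarded)%s\n",
              x$step, x$n_features_in, x$n_features_out, nrow(x$discarded),
              if (x$skipped) " [skipped]" else ""))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.filter_report <- function(x, ...) x$discarded

#' @exportS3Method generics::glance
glance.filter_report <- function(x, ...) {
  tibble::tibble(step = x$step,
                 n_features_in = x$n_features_in,
                 n_features_out = x$n_features_out,
                 n_discarded = nrow(x$discarded),
                 skipped = x$skipped)
}

add_flag <- function(data, ids, flag) {
  i <- match(ids, data$features$feature_id)
  data$features$flags[i] <- lapply(data$features$flags[i],
                                   function(f) union(f, flag))
  data
}

drop_features <- function(data, ids, reason, step, params, flag = NULL) {
  discarded <- tibble::tibble(feature_id = ids, reason = reason)
  report <- new_filter_report(step, data, discarded, params)
  if (!is.null(flag) && length(ids)) data <- add_flag(data, ids, flag)
  out <- subset_dataset(data,
                        features = setdiff(rownames(data$intensities), ids))
  list(dataset = out, report = report)
}

# row means over a set of sample columns, NA-ignoring; all-NA rows -> NA
row_means_over <- function(data, ids) {
  if (length(ids) == 0) return(rep(NA_real_, nrow(data$intensities)))
  rowMeans(data$intensities[, ids, drop = FALSE], na.rm = TRUE)
}

#' Blank filter: discard features dominated by solvent background
#'
#' A feature is kept when its mean intensity over the biological samples is
#' at least `ratio_threshold` times its mean over the blank injections
#' (equality passes; only strictly smaller is discarded). Missing values
#' are ignored in both means; a blank mean that cannot be computed
#' (all missing) counts as 0, so the feature is kept.
#'
#' @param data A raw-scale [ms_dataset()] with `sample_type` metadata.
#' @param ratio_threshold Required bio/blank mean ratio (default 3).
#' @return A list with elements `dataset` (filtered) and `report`
#'   (a `filter_report`).
#' @export
blank_filter <- function(data, ratio_threshold = 3) {
  params <- list(ratio_threshold = ratio_threshold)
  if (data$log_transformed) {
    stop("blank_filter requires raw-scale intensities", call. = FALSE)
  }
  blanks <- samples_of_type(data, "blank")
  bios <- samples_of_type(data, "sample")
  if (length(blanks) == 0 || length(bios) == 0) {
    warning("no blank or no biological samples; blank filter skipped")
    return(list(dataset = data,
                report = new_filter_report("blank_filter", data, NULL,
                                           params, skipped = TRUE,
                                           note = "no blanks")))
  }
  blank_mean <- row_means_over(data, blanks)
  blank_mean[is.na(blank_mean) | is.nan(blank_mean)] <- 0
  bio_mean <- row_means_over(data, bios)
  fail <- !is.na(bio_mean) & bio_mean < ratio_threshold * blank_mean
  fail[is.na(bio_mean)] <- TRUE   # no biological signal at all
  ids <- rownames(data$intensities)[fail]
  drop_features(data, ids,
                reason = sprintf("bio mean < %g x blank mean", ratio_threshold),
                step = "blank_filter", params = params, flag = "blank_fail")
}

#' Dilution-series filter: discard features blind to pool dilution
#'
#' Over the diluted pooled-QC injections, a quantitative feature's
#' intensity should be proportional to the inverse of the dilution factor.
#' Features whose Pearson correlation with 1/dilution_factor falls below
#' `r_threshold` are discarded; a correlation that is undefined because the
#' intensities have zero variance also fails (a feature that does not
#' respond to an 8-fold dilution is not quantitative).
#'
#' Skipped with a warning when fewer than 3 dilution points with distinct
#' factors are available.
#'
#' @param data An [ms_dataset()] whose `pool_dilution` samples carry
#'   `dilution_factor`.
#' @param r_threshold Minimum Pearson r (default 0.7).
#' @return A list with `dataset` and `report`.
#' @export
dilution_filter <- function(data, r_threshold = 0.7) {
  params <- list(r_threshold = r_threshold)
  dil <- samples_of_type(data, "pool_dilution")
  facs <- data$samples$dilution_factor[match(dil, data$samples$sample_id)]
  if (length(dil) < 3 || length(unique(facs)) < 3) {
    warning("fewer than 3 distinct pool-dilution points; dilution filter skipped")
    return(list(dataset = data,
                report = new_filter_report("dilution_filter", data, NULL,
                                           params, skipped = TRUE,
                                           note = "insufficient dilution series")))
  }
  inv <- 1 / facs
  mat <- data$intensities[, dil, drop = FALSE]
  r <- apply(mat, 1, function(v) {
    ok <- !is.na(v)
    if (sum(ok) < 3 || sd(v[ok]) == 0 || sd(inv[ok]) == 0) return(NA_real_)
    cor(v[ok], inv[ok])
  })
  fail <- is.na(r) | r < r_threshold
  ids <- rownames(data$intensities)[fail]
  drop_features(data, ids,
                reason = sprintf("Pearson r with 1/dilution < %g (or undefined)",
                                 r_threshold),
                step = "dilution_filter", params = params,
                flag = "dilution_fail")
}

# Per-feature loess drift estimate evaluated at arbitrary injection orders.
# Fitted on (ref_order, ref_values); outside the reference range the
# nearest fitted value is carried forward.
loess_drift_fit <- function(ref_order, ref_values, all_order, span, degree) {
  o <- order(ref_order)
  x <- ref_order[o]; y <- ref_values[o]
  fit <- loess(y ~ x, span = span, degree = degree,
               family = "gaussian",
               control = stats::loess.control(surface = "direct"))
  # evaluate inside the reference range; carry the end fitted values
  # forward outside it rather than trusting polynomial extrapolation
  xq <- pmin(pmax(all_order, min(x)), max(x))
  predict(fit, newdata = data.frame(x = xq))
}

#' Correct injection-order signal drift by loess regression
#'
#' For each feature, a loess curve of intensity versus injection order is
#' fitted on the reference samples (pooled QCs, or the biological samples
#' where pooled-QC normalization corrects the drift poorly). The correction
#' is multiplicative with renormalization to the reference median:
#' `corrected = raw * median(reference) / fitted(order)`, the fitted value
#' being clipped below at `1e-6 * median(reference)` and extrapolated as
#' the nearest fitted value outside the reference injection range. This
#' preserves the intensity scale so that the blank-ratio and CV rules keep
#' their meaning downstream.
#'
#' Features with fewer than 5 observed reference values are left
#' uncorrected and flagged.
#'
#' @param data A raw-scale [ms_dataset()] with `injection_order`.
#' @param reference `"pool"` or `"sample"`: which injections anchor the
#'   loess fit.
#' @param span Loess span in (0, 1] (default 1).
#' @param degree Local polynomial degree (default 2).
#' @return A list with `dataset` (corrected; features flagged
#'   `drift_corrected` or `drift_uncorrected`) and `report`.
#' @export
drift_correct <- function(data, reference = c("pool", "sample"),
                          span = 1, degree = 2) {
  reference <- match.arg(reference)
  if (!is.numeric(span) || span <= 0 || span > 1) {
    stop("`span` must be in (0, 1]", call. = FALSE)
  }
  params <- list(reference = reference, span = span, degree = degree)
  ref_ids <- samples_of_type(data, reference)
  if (!"injection_order" %in% names(data$samples)) {
    stop("drift_correct requires `injection_order` sample metadata",
         call. = FALSE)
  }
  all_order <- data$samples$injection_order
  ref_order <- all_order[match(ref_ids, data$samples$sample_id)]

  mat <- data$intensities
  uncorrected <- character(0)
  for (i in seq_len(nrow(mat))) {
    v_ref <- mat[i, ref_ids]
    ok <- !is.na(v_ref)
    if (sum(ok) < 5) {
      uncorrected <- c(uncorrected, rownames(mat)[i])
      next
    }
    m_ref <- median(v_ref[ok])
    fhat <- loess_drift_fit(ref_order[ok], v_ref[ok], all_order,
                            span = span, degree = degree)
    fhat <- pmax(fhat, 1e-6 * m_ref)
    mat[i, ] <- mat[i, ] * m_ref / fhat
  }
  data$intensities <- mat
  corrected <- setdiff(rownames(mat), uncorrected)
  data <- add_flag(data, corrected, "drift_corrected")
  if (length(uncorrected)) data <- add_flag(data, uncorrected, "drift_uncorrected")
  report <- new_filter_report("drift_correct", data, NULL, params,
                              note = sprintf("%d corrected, %d left uncorrected",
                                             length(corrected),
                                             length(uncorrected)))
  list(dataset = data, report = report)
}

# sd/mean over observed values; NA when < min_n observed or mean == 0
feature_cv <- function(mat, min_n = 3) {
  apply(mat, 1, function(v) {
    v <- v[!is.na(v)]
    if (length(v) < min_n || mean(v) == 0) return(NA_real_)
    sd(v) / mean(v)
  })
}

#' Pooled-QC coefficient-of-variation filter
#'
#' Discards features whose intensity CV (sd/mean, raw scale) over the
#' pooled QC injections exceeds `cv_threshold`, or exceeds the CV over the
#' biological samples — a feature more variable in identical QC aliquots
#' than across animals carries no usable signal. Features with fewer than
#' 3 observed pool values are discarded as unreliable.
#'
#' @param data A raw-scale [ms_dataset()].
#' @param cv_threshold Maximum pooled-QC CV (default 0.30).
#' @return A list with `dataset` and `report`; the surviving features carry
#'   their `qc_cv` and `sample_cv` in the feature metadata.
#' @export
cv_filter <- function(data, cv_threshold = 0.30) {
  params <- list(cv_threshold = cv_threshold)
  if (data$log_transformed) {
    stop("cv_filter requires raw-scale intensities", call. = FALSE)
  }
  pools <- samples_of_type(data, "pool")
  bios <- samples_of_type(data, "sample")
  if (length(pools) < 3) {
    warning("fewer than 3 pooled QC samples; CV filter skipped")
    return(list(dataset = data,
                report = new_filter_report("cv_filter", data, NULL, params,
                                           skipped = TRUE,
                                           note = "insufficient pools")))
  }
  cv_pool <- feature_cv(data$intensities[, pools, drop = FALSE])
  cv_bio <- feature_cv(data$intensities[, bios, drop = FALSE], min_n = 2)
  data$features$qc_cv <- cv_pool
  data$features$sample_cv <- cv_bio
  fail <- is.na(cv_pool) | cv_pool > cv_threshold |
    (!is.na(cv_bio) & cv_pool > cv_bio)
  ids <- rownames(data$intensities)[fail]
  drop_features(data, ids,
                reason = sprintf("QC CV > %g or > sample CV", cv_threshold),
                step = "cv_filter", params = params, flag = "cv_fail")
}

#' Collapse chemically redundant features
#'
#' Isotopes, adducts and in-source fragments of one metabolite appear as
#' several features. Two features are linked when all three criteria hold:
#' Pearson correlation of their biological-sample profiles above `r_min`,
#' retention-time difference below `rt_tol_s` seconds, and m/z difference
#' matching the reference list within its tolerance. Connected components
#' of the link graph are collapsed to a single representative — the member
#' with the highest median biological intensity (ties broken by lowest
#' m/z); the others are flagged `redundant` and removed.
#'
#' @param data An [ms_dataset()] whose features carry `mz` and `rt`.
#' @param mzdiff Reference-difference table, see [default_mzdiff_table()].
#' @param r_min Profile-correlation threshold (default 0.9, strict).
#' @param rt_tol_s Retention-time window in seconds (default 6, strict).
#' @return A list with `dataset`, `report`, and `groups` (tibble of
#'   `group`, `representative`, `member`).
#' @export
redundancy_filter <- function(data, mzdiff = default_mzdiff_table(),
                              r_min = 0.9, rt_tol_s = 6) {
  params <- list(r_min = r_min, rt_tol_s = rt_tol_s,
                 mz_tolerance = mzdiff$tolerance[1])
  if (!all(c("mz", "rt") %in% names(data$features)) ||
      anyNA(data$features$mz) || anyNA(data$features$rt)) {
    stop("redundancy_filter requires complete `mz` and `rt` feature metadata",
         call. = FALSE)
  }
  bios <- samples_of_type(data, "sample")
  if (length(bios) < 3) {
    stop("redundancy_filter requires at least 3 biological samples",
         call. = FALSE)
  }
  n <- nrow(data$intensities)
  fid <- rownames(data$intensities)
  mz <- data$features$mz
  rt <- data$features$rt
  mat <- t(data$intensities[, bios, drop = FALSE])

  # candidate pairs by rt window first (cheap), then mz list, then correlation
  adj <- vector("list", n)
  ord <- order(rt)
  for (a in seq_len(n - 1)) {
    i <- ord[a]
    for (b in (a + 1):n) {
      j <- ord[b]
      if (rt[j] - rt[i] >= rt_tol_s) break
      if (!mzdiff_match(abs(mz[i] - mz[j]), mzdiff)) next
      r <- suppressWarnings(cor(mat[, i], mat[, j],
                                use = "pairwise.complete.obs"))
      if (!is.na(r) && r > r_min) {
        adj[[i]] <- c(adj[[i]], j)
        adj[[j]] <- c(adj[[j]], i)
      }
    }
  }

  # connected components by breadth-first search
  comp <- integer(n)
  cid <- 0L
  for (i in seq_len(n)) {
    if (comp[i] != 0L) next
    cid <- cid + 1L
    queue <- i
    comp[i] <- cid
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      nb <- adj[[v]]
      new <- nb[comp[nb] == 0L]
      comp[new] <- cid
      queue <- c(queue, new)
    }
  }

  med_bio <- apply(data$intensities[, bios, drop = FALSE], 1, median,
                   na.rm = TRUE)
  groups <- tibble::tibble(group = comp, feature_id = fid,
                           med = med_bio, mz = mz) |>
    dplyr::group_by(.data$group) |>
    dplyr::filter(dplyr::n() > 1) |>
    dplyr::mutate(representative = .data$feature_id[
      order(-.data$med, .data$mz)][1]) |>
    dplyr::ungroup() |>
    dplyr::select("group", "representative", member = "feature_id")

  redundant <- groups$member[groups$member != groups$representative]
  res <- drop_features(data, redundant, reason = "redundant (isotope/adduct/fragment)",
                       step = "redundancy_filter", params = params,
                       flag = "redundant")
  res$groups <- groups
  res
}

#' Log2-transform intensities
#'
#' The final post-processing step. Present intensities `v > 0` become
#' `log2(v)`; zeros become missing; negative values are an error. Guarded
#' against double application via the dataset's `log_transformed` flag.
#'
#' @param data A raw-scale [ms_dataset()].
#' @return The transformed [ms_dataset()] with `log_transformed = TRUE`.
#' @export
log2_transform <- function(data) {
  if (data$log_transformed) {
    stop("dataset is already log2-transformed", call. = FALSE)
  }
  if (any(data$intensities < 0, na.rm = TRUE)) {
    stop("negative intensities cannot be log2-transformed", call. = FALSE)
  }
  m <- data$intensities
  m[!is.na(m) & m == 0] <- NA_real_
  data$intensities <- log2(m)
  data$log_transformed <- TRUE
  data
}

#' Run the full statistical post-processing chain
#'
#' Applies, in this fixed order: blank filter, dilution-series filter,
#' loess drift correction, pooled-QC CV filter, redundancy collapsing,
#' log2 transformation. Any step can be disabled via `steps`; the order
#' itself cannot be changed. Returns the processed dataset together with
#' the per-step reports, which reproduce a feature-count cascade.
#'
#' @param data A raw-scale [ms_dataset()].
#' @param steps Character vector of steps to run, a subset of
#'   `c("blank", "dilution", "drift", "cv", "redundancy", "log2")`, in any
#'   order (execution order is fixed).
#' @param blank_ratio,dilution_r,cv_threshold,r_min,rt_tol_s Step
#'   thresholds, see the individual filters.
#' @param drift_reference,span Drift-correction parameters, see
#'   [drift_correct()].
#' @param mzdiff Reference m/z-difference table for redundancy collapsing.
#' @return An object of class `postprocess_result`: list with `dataset`,
#'   `reports` (list of `filter_report`), and `cascade` (tibble).
#' @export
run_pipeline <- function(data,
                         steps = c("blank", "dilution", "drift", "cv",
                                   "redundancy", "log2"),
                         blank_ratio = 3, dilution_r = 0.7,
                         drift_reference = "pool", span = 1,
                         cv_threshold = 0.30,
                         mzdiff = default_mzdiff_table(),
                         r_min = 0.9, rt_tol_s = 6) {
  known <- c("blank", "dilution", "drift", "cv", "redundancy", "log2")
  bad <- setdiff(steps, known)
  if (length(bad)) {
    stop("unknown step(s): ", paste(bad, collapse = ", "),
         "; the execution order is fixed and steps can only be disabled",
         call. = FALSE)
  }
  reports <- list()
  run <- function(name, f) {
    if (!name %in% steps) return(invisible(NULL))
    res <- f(data)
    if (is.list(res) && !is.null(res$report)) {
      reports[[res$report$step]] <<- res$report
      data <<- res$dataset
    } else {
      data <<- res
    }
    invisible(NULL)
  }
  run("blank", function(d) blank_filter(d, ratio_threshold = blank_ratio))
  run("dilution", function(d) dilution_filter(d, r_threshold = dilution_r))
  run("drift", function(d) drift_correct(d, reference = drift_reference,
                                         span = span))
  run("cv", function(d) cv_filter(d, cv_threshold = cv_threshold))
  run("redundancy", function(d) redundancy_filter(d, mzdiff = mzdiff,
                                                  r_min = r_min,
                                                  rt_tol_s = rt_tol_s))
  run("log2", log2_transform)

  cascade <- purrr::map_dfr(reports, glance)
  structure(list(dataset = data, reports = reports, cascade = cascade),
            class = "postprocess_result")
}

#' @export
print.postprocess_result <- function(x, ...) {
  cat("<postprocess_result>\n")
  if (nrow(x$cascade)) print(as.data.frame(x$cascade), row.names = FALSE)
  print(x$dataset)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.postprocess_result <- function(x, ...) {
  purrr::map_dfr(x$reports, function(r) {
    if (nrow(r$discarded) == 0) return(NULL)
    dplyr::mutate(r$discarded, step = r$step, .before = 1)
  })
}

#' @exportS3Method generics::glance
glance.postprocess_result <- function(x, ...) x$cascade
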