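#' Construct an LC-MS feature dataset
#'
#' Bundles a features x samples intensity matrix with per-sample and
#' per-feature metadata, the in-memory form of the tabular "triplet"
#' convention (dataMatrix / sampleMetadata / variableMetadata) used to
#' exchange processed untargeted metabolomics data.
#'
#' @param intensities Numeric matrix, features in rows and samples in
#'   columns, with row and column names. Missing values allowed; on the raw
#'   scale all present values must be non-negative.
#' @param samples Data frame with one row per sample. Must contain
#'   `sample_id` matching the matrix column names in order. Recognised
#'   columns: `sample_type` (one of `"blank"`, `"pool"`, `"pool_dilution"`,
#'   `"sample"`), `injection_order` (unique positive integers),
#'   `dilution_factor` (pool dilutions only), `genotype`, `sex`, `batch`.
#' @param features Data frame with one row per feature. Must contain
#'   `feature_id` matching the matrix row names in order. Recognised
#'   columns: `mz` (Da), `rt` (seconds), `annotation`, `flags`.
#' @param log_transformed Logical; `TRUE` once intensities are on the log2
#'   scale (set by [log2_transform()], never manually in normal use).
#'
#' @return An object of class `ms_dataset`: a list with elements
#'   `intensities`, `samples`, `features`, `log_transformed`.
#' @seealso [read_triplet()], [write_triplet()], [validate_dataset()]
#' @export
ms_dataset <- function(intensities, samples, features,
                       log_transformed = FALSE) {
  if (!is.matrix(intensities) || !is.numeric(intensities)) {
    stop("`intensities` must be a numeric matrix", call. = FALSE)
  }
  samples <- tibble::as_tibble(samples)
  features <- tibble::as_tibble(features)
  if (!"sample_id" %in% names(samples)) {
    stop("`samples` must have a `sample_id` column", call. = FALSE)
  }
  if (!"feature_id" %in% names(features)) {
    stop("`features` must have a `feature_id` column", call. = FALSE)
  }
  if ((nrow(intensities) > 0 && is.null(rownames(intensities))) ||
      (ncol(intensities) > 0 && is.null(colnames(intensities)))) {
    stop("`intensities` must have row (feature) and column (sample) names",
         call. = FALSE)
  }
  # R normalizes zero-length dimnames to NULL; compare as character vectors
  rn <- rownames(intensities) %||% character(0)
  cn <- colnames(intensities) %||% character(0)
  if (!identical(cn, as.character(samples$sample_id))) {
    stop("column names of `intensities` must equal `samples$sample_id` ",
         "in the same order", call. = FALSE)
  }
  if (!identical(rn, as.character(features$feature_id))) {
    stop("row names of `intensities` must equal `features$feature_id` ",
         "in the same order", call. = FALSE)
  }
  if (!"flags" %in% names(features)) {
    features$flags <- replicate(nrow(features), character(0),
                                simplify = FALSE)
  }
  x <- structure(
    list(intensities = intensities, samples = samples, features = features,
         log_transformed = isTRUE(log_transformed)),
    class = "ms_dataset"
  )
  viol <- validate_dataset(x)
  if (length(viol) > 0) {
    stop("invalid ms_dataset:\n", paste0("- ", viol, collapse = "\n"),
         call. = FALSE)
  }
  x
}

#' Check the invariants of an `ms_dataset`
#'
#' Returns violation messages rather than raising, so callers can report
#' all problems in a file at once.
#'
#' @param data An [ms_dataset()].
#' @return Character vector of violation messages; `character(0)` when the
#'   dataset is valid. Each message names the offending entity and rule.
#' @export
validate_dataset <- function(data) {
  viol <- character(0)
  sid <- as.character(data$samples$sample_id)
  fid <- as.character(data$features$feature_id)
  if (anyDuplicated(sid)) {
    viol <- c(viol, paste0("duplicate sample identifiers: ",
                           paste(unique(sid[duplicated(sid)]), collapse = ", ")))
  }
  if (anyDuplicated(fid)) {
    viol <- c(viol, paste0("duplicate feature identifiers: ",
                           paste(unique(fid[duplicated(fid)]), collapse = ", ")))
  }
  if (any(!nzchar(sid)) || anyNA(sid)) {
    viol <- c(viol, "empty or missing sample identifier")
  }
  if (any(!nzchar(fid)) || anyNA(fid)) {
    viol <- c(viol, "empty or missing feature identifier")
  }
  if (!data$log_transformed &&
      any(data$intensities < 0, na.rm = TRUE)) {
    bad <- which(apply(data$intensities < 0, 1, any, na.rm = TRUE))
    viol <- c(viol, paste0("negative raw intensity in feature(s): ",
                           paste(utils::head(fid[bad], 5), collapse = ", ")))
  }
  if ("sample_type" %in% names(data$samples)) {
    ok <- data$samples$sample_type %in%
      c("blank", "pool", "pool_dilution", "sample") |
      is.na(data$samples$sample_type)
    if (!all(ok)) {
      viol <- c(viol, paste0("unknown sample_type for sample(s): ",
                             paste(sid[!ok], collapse = ", ")))
    }
  }
  if ("injection_order" %in% names(data$samples)) {
    io <- data$samples$injection_order
    dup <- duplicated(io) & !is.na(io)
    if (any(dup)) {
      offenders <- sid[io %in% io[dup] & !is.na(io)]
      viol <- c(viol, paste0("duplicate injection_order for samples: ",
                             paste(offenders, collapse = ", ")))
    }
    if (any(io <= 0, na.rm = TRUE)) {
      viol <- c(viol, "injection_order must be positive")
    }
  }
  if (all(c("sample_type", "dilution_factor") %in% names(data$samples))) {
    is_dil <- data$samples$sample_type %in% "pool_dilution"
    if (any(is_dil & is.na(data$samples$dilution_factor))) {
      viol <- c(viol, paste0("pool_dilution sample(s) without dilution_factor: ",
                             paste(sid[is_dil & is.na(data$samples$dilution_factor)],
                                   collapse = ", ")))
    }
    if (any(!is_dil & !is.na(data$samples$dilution_factor))) {
      viol <- c(viol, paste0("dilution_factor set on non-dilution sample(s): ",
                             paste(sid[!is_dil & !is.na(data$samples$dilution_factor)],
                                   collapse = ", ")))
    }
    if (any(data$samples$dilution_factor <= 0, na.rm = TRUE)) {
      viol <- c(viol, "dilution_factor must be positive")
    }
  }
  if ("mz" %in% names(data$features) &&
      any(data$features$mz <= 0, na.rm = TRUE)) {
    viol <- c(viol, paste0("non-positive m/z for feature(s): ",
                           paste(fid[which(data$features$mz <= 0)], collapse = ", ")))
  }
  if ("rt" %in% names(data$features) &&
      any(data$features$rt < 0, na.rm = TRUE)) {
    viol <- c(viol, paste0("negative retention time for feature(s): ",
                           paste(fid[which(data$features$rt < 0)], collapse = ", ")))
  }
  viol
}

#' @export
print.ms_dataset <- function(x, ...) {
  cat(sprintf("<ms_dataset> %d features x %d samples (%s scale)\n",
              nrow(x$intensities), ncol(x$intensities),
              if (x$log_transformed) "log2" else "raw"))
  if ("sample_type" %in% names(x$samples)) {
    tab <- table(x$samples$sample_type)
    cat("  samples:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' @export
dim.ms_dataset <- function(x) dim(x$intensities)

# Subset a dataset to a set of features and/or samples, preserving order.
# Internal: ids are character vectors of identifiers to keep.
subset_dataset <- function(data, features = NULL, samples = NULL) {
  fid <- rownames(data$intensities)
  sid <- colnames(data$intensities)
  keep_f <- if (is.null(features)) fid else fid[fid %in% features]
  keep_s <- if (is.null(samples)) sid else sid[sid %in% samples]
  ms_dataset(
    intensities = data$intensities[keep_f, keep_s, drop = FALSE],
    samples = data$samples[match(keep_s, sid), , drop = FALSE],
    features = data$features[match(keep_f, fid), , drop = FALSE],
    log_transformed = data$log_transformed
  )
}

# Sample ids of a given type, in injection order when available.
samples_of_type <- function(data, types) {
  s <- data$samples
  ids <- as.character(s$sample_id[s$sample_type %in% types])
  if ("injection_order" %in% names(s)) {
    ord <- s$injection_order[match(ids, s$sample_id)]
    ids <- ids[order(ord)]
  }
  ids
}
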