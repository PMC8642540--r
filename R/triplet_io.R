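#' Default metadata column mapping for triplet files
#'
#' Sample-metadata header names differ between deposits and tools; a column
#' map translates the dialect's names onto the fields used here. The
#' defaults follow the common Workflow4Metabolomics-style headers.
#'
#' @param ... Named overrides, e.g. `injection_order = "injectionOrder"`.
#' @return Named character vector mapping internal field names
#'   (`sample_type`, `injection_order`, `dilution_factor`, `genotype`,
#'   `sex`, `batch`) to file column names.
#' @export
#' @examples
#' default_column_map(sample_type = "sampleType")
default_column_map <- function(...) {
  map <- c(sample_type = "sampleType",
           injection_order = "injectionOrder",
           dilution_factor = "dilution",
           genotype = "genotype",
           sex = "sex",
           batch = "batch")
  over <- c(...)
  map[names(over)] <- over
  map
}

read_tsv_quiet <- function(path) {
  readr::read_tsv(path, na = c("NA", ""), show_col_types = FALSE,
                  progress = FALSE, name_repair = "minimal")
}

#' Read a dataMatrix / sampleMetadata / variableMetadata triplet
#'
#' Reads the three tab-separated tables, checks that their identifiers
#' agree, and assembles an [ms_dataset()]. Sample and feature order is
#' taken from the dataMatrix and never changed.
#'
#' @param data_matrix,sample_metadata,variable_metadata Paths to the three
#'   tab-separated files. The first column of each holds identifiers.
#' @param column_map Named character vector translating metadata column
#'   names onto the `sample_type` / `injection_order` / `dilution_factor` /
#'   `genotype` / `sex` / `batch` fields; see [default_column_map()].
#'   Mapped columns that are absent from the file are silently skipped
#'   (the dilution filter is then skipped downstream with a warning).
#' @param sample_type_levels Named character vector recoding the file's
#'   sample-type vocabulary onto `blank` / `pool` / `pool_dilution` /
#'   `sample`; values already in that vocabulary pass through.
#' @param log_transformed Logical; set `TRUE` when the stored matrix is
#'   already on the log2 scale.
#'
#' @return An [ms_dataset()].
#' @export
read_triplet <- function(data_matrix, sample_metadata, variable_metadata,
                         column_map = default_column_map(),
                         sample_type_levels = c(blank = "blank",
                                                pool = "pool",
                                                pool_dilution = "pool_dilution",
                                                sample = "sample"),
                         log_transformed = FALSE) {
  dm <- read_tsv_quiet(data_matrix)
  sm <- read_tsv_quiet(sample_metadata)
  vm <- read_tsv_quiet(variable_metadata)

  fid <- as.character(dm[[1]])
  sid <- colnames(dm)[-1]
  if (anyDuplicated(fid)) {
    stop("duplicate feature identifiers in dataMatrix: ",
         paste(unique(fid[duplicated(fid)]), collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(sid)) {
    stop("duplicate sample identifiers in dataMatrix: ",
         paste(unique(sid[duplicated(sid)]), collapse = ", "), call. = FALSE)
  }
  smid <- as.character(sm[[1]])
  vmid <- as.character(vm[[1]])
  miss_s <- setdiff(sid, smid)
  extra_s <- setdiff(smid, sid)
  if (length(miss_s) || length(extra_s)) {
    stop("sample identifier mismatch between dataMatrix and sampleMetadata",
         if (length(miss_s)) paste0("; missing from sampleMetadata: ",
                                    paste(miss_s, collapse = ", ")),
         if (length(extra_s)) paste0("; absent from dataMatrix: ",
                                     paste(extra_s, collapse = ", ")),
         call. = FALSE)
  }
  miss_f <- setdiff(fid, vmid)
  extra_f <- setdiff(vmid, fid)
  if (length(miss_f) || length(extra_f)) {
    stop("feature identifier mismatch between dataMatrix and variableMetadata",
         if (length(miss_f)) paste0("; missing from variableMetadata: ",
                                    paste(miss_f, collapse = ", ")),
         if (length(extra_f)) paste0("; absent from dataMatrix: ",
                                     paste(extra_f, collapse = ", ")),
         call. = FALSE)
  }

  vals <- as.matrix(dm[, -1, drop = FALSE])
  if (nrow(vals) == 0) storage.mode(vals) <- "double"
  if (!is.numeric(vals)) {
    bad <- colnames(dm)[-1][!vapply(dm[, -1, drop = FALSE], is.numeric,
                                    logical(1))]
    stop("non-numeric intensity column(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  rownames(vals) <- fid
  storage.mode(vals) <- "double"

  # align metadata to dataMatrix order
  sm <- sm[match(sid, smid), , drop = FALSE]
  vm <- vm[match(fid, vmid), , drop = FALSE]

  samples <- tibble::tibble(sample_id = sid)
  for (field in names(column_map)) {
    col <- column_map[[field]]
    if (col %in% names(sm)) samples[[field]] <- sm[[col]]
  }
  if ("sample_type" %in% names(samples)) {
    st <- as.character(samples$sample_type)
    idx <- match(st, sample_type_levels)
    samples$sample_type <- ifelse(is.na(idx), st, names(sample_type_levels)[idx])
  }
  # carry through any unmapped metadata columns untouched
  other <- setdiff(names(sm)[-1], unname(column_map))
  for (col in other) samples[[col]] <- sm[[col]]

  features <- tibble::tibble(feature_id = fid)
  for (col in names(vm)[-1]) features[[col]] <- vm[[col]]

  ms_dataset(vals, samples, features, log_transformed = log_transformed)
}

#' Write a dataset as a triplet of tab-separated files
#'
#' Inverse of [read_triplet()]: writes `dataMatrix.tsv`,
#' `sampleMetadata.tsv` and `variableMetadata.tsv` into `out_dir`. Missing
#' intensities are serialized as `NA`. Re-reading the files reproduces the
#' dataset up to floating-point text round-trip.
#'
#' @param data An [ms_dataset()].
#' @param out_dir Output directory, created if needed.
#' @return Invisibly, a named character vector of the three file paths.
#' @export
write_triplet <- function(data, out_dir) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create directory: ", out_dir, call. = FALSE)
  }
  paths <- c(data_matrix = file.path(out_dir, "dataMatrix.tsv"),
             sample_metadata = file.path(out_dir, "sampleMetadata.tsv"),
             variable_metadata = file.path(out_dir, "variableMetadata.tsv"))

  dm <- tibble::as_tibble(data$intensities, rownames = "feature_id")
  readr::write_tsv(dm, paths[["data_matrix"]], na = "NA", progress = FALSE)

  sm <- data$samples
  names(sm)[names(sm) == "sample_type"] <- "sampleType"
  names(sm)[names(sm) == "injection_order"] <- "injectionOrder"
  names(sm)[names(sm) == "dilution_factor"] <- "dilution"
  readr::write_tsv(sm, paths[["sample_metadata"]], na = "NA", progress = FALSE)

  vm <- data$features
  if ("flags" %in% names(vm) && is.list(vm$flags)) {
    vm$flags <- vapply(vm$flags, paste, character(1), collapse = ",")
  }
  readr::write_tsv(vm, paths[["variable_metadata"]], na = "NA",
                   progress = FALSE)
  invisible(paths)
}

#' Read a preclinical phenotyping table
#'
#' One TSV with animals in rows: an identifier column, `sex` (`M`/`F`),
#' an optional `cohort` column (e.g. `historical` vs `project`), and one
#' numeric column per quantitative variable.
#'
#' @param path Path to the tab-separated file.
#' @return A tibble with columns `animal_id`, `sex`, `cohort` (if present)
#'   and the variable columns.
#' @export
read_preclinical <- function(path) {
  x <- read_tsv_quiet(path)
  names(x)[1] <- "animal_id"
  if (!"sex" %in% names(x)) {
    stop("preclinical table must have a `sex` column", call. = FALSE)
  }
  bad <- !x$sex %in% c("M", "F")
  if (any(bad)) {
    stop("sex must be 'M' or 'F'; offending animal(s): ",
         paste(x$animal_id[bad], collapse = ", "), call. = FALSE)
  }
  tibble::as_tibble(x)
}
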