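#' Feature tables: subjects x features with block metadata and covariates
#'
#' A `feature_tbl` is a tibble with one row per subject. The first columns are
#' the covariates `subject_id`, `age` (years), `sex` (0/1) and `site`
#' (categorical identifier); the remaining columns are numeric features.
#' Per-feature metadata (feature block, e.g. DAT/NET/SERT/SMF, and the
#' grouping key used for subgroup-wise harmonization) travels in the
#' `feature_meta` attribute, a tibble with columns `name`, `block`, `group`.
#'
#' @param values numeric matrix, subjects x features, with column names.
#' @param meta tibble with columns `name`, `block`, `group`; one row per
#'   feature column, in the same order as `colnames(values)`.
#' @param covariates tibble with columns `subject_id`, `age`, `sex`, `site`;
#'   one row per subject.
#' @return a `feature_tbl` (a tibble subclass).
#' @export
feature_table <- function(values, meta, covariates) {
  values <- as.matrix(values)
  if (is.null(colnames(values))) {
    abort("feature matrix must have column names")
  }
  meta <- as_tibble(meta)
  req_meta <- c("name", "block", "group")
  if (!all(req_meta %in% names(meta))) {
    abort("feature_meta needs columns name, block, group")
  }
  if (!identical(meta$name, colnames(values))) {
    abort("feature_meta$name must match the feature columns in order")
  }
  if (anyDuplicated(meta$name)) {
    abort("duplicate feature names")
  }
  covariates <- as_tibble(covariates)
  check_covariates(covariates)
  if (nrow(covariates) != nrow(values)) {
    abort("covariates and feature matrix disagree on the number of subjects")
  }
  if (any(!is.finite(values))) {
    abort("feature values must be finite (no missing values allowed)")
  }
  out <- dplyr::bind_cols(covariates[covariate_cols()], as_tibble(values))
  attr(out, "feature_meta") <- meta
  class(out) <- c("feature_tbl", class(tibble()))
  out
}

covariate_cols <- function() c("subject_id", "age", "sex", "site")

check_covariates <- function(covariates) {
  missing <- setdiff(covariate_cols(), names(covariates))
  if (length(missing)) {
    abort(paste0("missing covariate column(s): ", paste(missing, collapse = ", ")))
  }
  if (any(!is.finite(covariates$age))) abort("age must be finite")
  if (!all(covariates$sex %in% c(0, 1))) abort("sex must be coded 0/1")
  invisible(covariates)
}

#' Per-feature metadata of a feature table
#' @param x a `feature_tbl`.
#' @return tibble with columns `name`, `block`, `group`.
#' @export
feature_meta <- function(x) {
  m <- attr(x, "feature_meta")
  if (is.null(m)) abort("not a feature_tbl: no feature_meta attribute")
  m
}

#' Feature values of a feature table as a numeric matrix
#' @param x a `feature_tbl`.
#' @return numeric matrix, subjects x features.
#' @export
feature_matrix <- function(x) {
  m <- feature_meta(x)
  out <- as.matrix(as.data.frame(x)[, m$name, drop = FALSE])
  rownames(out) <- x$subject_id
  out
}

#' Replace the feature values of a feature table
#' @param x a `feature_tbl`.
#' @param values numeric matrix with the same shape and column names.
#' @return a `feature_tbl`.
#' @export
set_feature_matrix <- function(x, values) {
  m <- feature_meta(x)
  stopifnot(identical(colnames(values), m$name), nrow(values) == nrow(x))
  feature_table(values, m, covariates_of(x))
}

#' Covariates of a feature table
#' @param x a `feature_tbl`.
#' @return tibble with `subject_id`, `age`, `sex`, `site`.
#' @export
covariates_of <- function(x) {
  as_tibble(as.data.frame(x)[, covariate_cols()])
}

#' Select a subset of feature columns, keeping metadata consistent
#' @param x a `feature_tbl`.
#' @param names character vector of feature names to keep (in this order).
#' @return a `feature_tbl`.
#' @export
select_features <- function(x, names) {
  m <- feature_meta(x)
  missing <- setdiff(names, m$name)
  if (length(missing)) {
    abort(paste0("unknown feature(s): ", paste(utils::head(missing, 5), collapse = ", ")))
  }
  vals <- feature_matrix(x)[, names, drop = FALSE]
  meta <- m[match(names, m$name), ]
  feature_table(vals, meta, covariates_of(x))
}

#' @export
print.feature_tbl <- function(x, ...) {
  m <- attr(x, "feature_meta")
  cat(sprintf(
    "<feature_tbl> %d subjects x %d features (blocks: %s)\n",
    nrow(x), nrow(m), paste(unique(m$block), collapse = ", ")
  ))
  NextMethod()
}

#' Write a feature table to TSV (with a JSON metadata sidecar)
#'
#' Values go to a tab-separated file with a header row (`subject_id`, `age`,
#' `sex`, `site`, then one column per feature, full precision); the feature
#' metadata goes to `<path>.meta.json`. The round trip through
#' [read_feature_table()] is lossless.
#'
#' @param x a `feature_tbl`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(x, path) {
  stopifnot(inherits(x, "feature_tbl"))
  out <- as_tibble(as.data.frame(x))
  # %.17g round-trips IEEE doubles exactly
  out[] <- lapply(out, function(col) if (is.double(col)) sprintf("%.17g", col) else col)
  readr::write_tsv(out, path)
  jsonlite::write_json(feature_meta(x), paste0(path, ".meta.json"), digits = NA)
  invisible(path)
}

#' Read a feature table written by [write_feature_table()]
#' @param path TSV path; `<path>.meta.json` must exist alongside.
#' @return a `feature_tbl`.
#' @export
read_feature_table <- function(path) {
  # parse numerics with base strtod (correctly rounded) for a lossless
  # round-trip of full-precision values
  dat <- readr::read_tsv(path, col_types = readr::cols(.default = "c"))
  num_cols <- setdiff(names(dat), c("subject_id", "site"))
  dat[num_cols] <- lapply(dat[num_cols], as.numeric)
  if ("sex" %in% names(dat)) dat$sex <- as.integer(dat$sex)
  check_covariates(dat)
  meta_path <- paste0(path, ".meta.json")
  feat_cols <- setdiff(names(dat), covariate_cols())
  if (file.exists(meta_path)) {
    meta <- as_tibble(jsonlite::read_json(meta_path, simplifyVector = TRUE))
  } else {
    meta <- tibble(name = feat_cols, block = NA_character_, group = NA_character_)
  }
  feature_table(as.matrix(dat[, feat_cols, drop = FALSE]), meta, dat[covariate_cols()])
}
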