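#' Parcellate enriched maps into regional means
#'
#' Entry (r, k) is the arithmetic mean of map k over the voxels carrying
#' label r, intersected with the map's mask. Parcellation is a linear
#' operator on maps.
#'
#' @param maps an `enriched_maps` object.
#' @param atlas a `parcellation_atlas`.
#' @return numeric matrix R x K with ROI names as row names and target names
#'   as column names.
#' @export
parcellate <- function(maps, atlas) {
  stopifnot(inherits(maps, "enriched_maps"), inherits(atlas, "parcellation_atlas"))
  if (!all(maps$dim == atlas$dim)) {
    abort("atlas and maps are on different grids; resampling is not supported")
  }
  lab <- as.vector(atlas$labels)
  inmask <- as.vector(maps$mask)
  r_ids <- atlas$roi_info$roi_id
  out <- matrix(NA_real_, length(r_ids), length(maps$target_names),
                dimnames = list(atlas$roi_info$roi_name, maps$target_names))
  keep <- inmask & lab > 0
  counts <- tabulate(lab[keep], max(r_ids))
  empty <- which(counts[r_ids] == 0L)
  if (length(empty)) {
    abort(sprintf("ROI '%s' (id %d) has no in-mask voxels",
                  atlas$roi_info$roi_name[empty[1]], r_ids[empty[1]]))
  }
  sums <- rowsum(maps$values[keep, , drop = FALSE], lab[keep])
  out[] <- sums[match(r_ids, as.integer(rownames(sums))), , drop = FALSE] / counts[r_ids]
  out
}

#' Assemble feature blocks from parcellated maps and structural tables
#'
#' Builds any of the six model configurations from per-target regional
#' matrices and an optional structural table: the three transporter-specific
#' blocks (DAT, NET, SERT; R features each), the stacked molecular-enriched
#' block MEF (K x R features), the structural block SMF, and the multimodal
#' union MMF (MEF plus SMF). Functional feature metadata records the
#' transporter and the ROI's parcel-set group, the key later used for
#' subgroup-wise harmonization.
#'
#' @param per_target named list (one entry per transporter) of subjects x R
#'   matrices of regional means; row names are subject ids, column order
#'   follows `atlas$roi_info`.
#' @param atlas the `parcellation_atlas` the matrices were computed on.
#' @param covariates covariate tibble (`subject_id`, `age`, `sex`, `site`)
#'   for the same subjects.
#' @param structural optional `feature_tbl` with the structural block (same
#'   subjects).
#' @param blocks character vector of configurations to emit; defaults to all
#'   that are constructible.
#' @return named list of `feature_tbl`, one per requested block.
#' @export
assemble_blocks <- function(per_target, atlas, covariates,
                            structural = NULL, blocks = NULL) {
  stopifnot(inherits(atlas, "parcellation_atlas"))
  covariates <- as_tibble(covariates)
  check_covariates(covariates)
  targets <- names(per_target)
  if (is.null(targets) || any(!nzchar(targets))) abort("per_target must be a named list")
  roi <- atlas$roi_info
  func_tbls <- list()
  for (tg in targets) {
    m <- as.matrix(per_target[[tg]])
    if (ncol(m) != nrow(roi)) abort(sprintf("block %s: expected %d ROI columns", tg, nrow(roi)))
    if (is.null(rownames(m))) abort("per-target matrices need subject ids as row names")
    if (!identical(rownames(m), covariates$subject_id)) {
      abort(sprintf("block %s: subject set does not match the covariates", tg))
    }
    colnames(m) <- paste(tg, roi$roi_name, sep = "_")
    meta <- tibble(name = colnames(m), block = tg,
                   group = paste(tg, roi$roi_group, sep = ":"))
    func_tbls[[tg]] <- feature_table(m, meta, covariates)
  }
  if (!is.null(structural)) {
    stopifnot(inherits(structural, "feature_tbl"))
    if (!identical(structural$subject_id, covariates$subject_id)) {
      abort("structural block: subject set does not match the covariates")
    }
  }
  if (is.null(blocks)) {
    blocks <- c(targets, if (length(targets) > 1) "MEF",
                if (!is.null(structural)) c("SMF", if (length(targets) > 1) "MMF"))
  }
  bind_blocks <- function(tbls) {
    mats <- lapply(tbls, feature_matrix)
    metas <- lapply(tbls, feature_meta)
    vals <- do.call(cbind, mats)
    if (anyDuplicated(colnames(vals))) abort("duplicate feature names across blocks")
    feature_table(vals, dplyr::bind_rows(metas), covariates)
  }
  out <- list()
  for (b in blocks) {
    out[[b]] <- switch(b,
      MEF = bind_blocks(func_tbls),
      SMF = structural %||% abort("SMF requested but no structural table supplied"),
      MMF = bind_blocks(c(func_tbls, list(SMF = structural %||%
        abort("MMF requested but no structural table supplied")))),
      func_tbls[[b]] %||% abort(sprintf("unknown block '%s'", b))
    )
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Flag image-quality metrics outside the inner Tukey fences
#'
#' For each metric column, computes the first and third quartiles (type-7
#' quantiles, linear interpolation), the interquartile range, and flags
#' values below `Q1 - 1.5 IQR` or above `Q3 + 1.5 IQR`. A zero IQR yields no
#' flags. Flags are invariant under adding a constant to a metric and under
#' positive rescaling.
#'
#' @param iqms tibble with a `subject_id` column and numeric metric columns
#'   (at least 4 subjects per metric).
#' @return a `qc_flags` object: `flags` (tibble, `subject_id` + one logical
#'   column per metric) and `fences` (tibble `metric`, `lower`, `upper`).
#' @export
tukey_fence_flags <- function(iqms) {
  iqms <- as_tibble(iqms)
  if (!"subject_id" %in% names(iqms)) {
    iqms <- dplyr::bind_cols(tibble(subject_id = sprintf("sub-%04d", seq_len(nrow(iqms)))), iqms)
  }
  metric_cols <- setdiff(names(iqms), "subject_id")
  x <- as.matrix(iqms[, metric_cols, drop = FALSE])
  if (nrow(x) < 4L) abort("need at least 4 subjects per metric")
  if (any(!is.finite(x))) abort("non-finite IQM values")
  q1 <- apply(x, 2, quantile, probs = 0.25, type = 7)
  q3 <- apply(x, 2, quantile, probs = 0.75, type = 7)
  iqr <- q3 - q1
  lower <- q1 - 1.5 * iqr
  upper <- q3 + 1.5 * iqr
  flags <- sweep(x, 2, lower, "<") | sweep(x, 2, upper, ">")
  flag_tbl <- dplyr::bind_cols(iqms["subject_id"], as_tibble(flags))
  structure(list(
    flags = flag_tbl,
    fences = tibble(metric = metric_cols, lower = unname(lower), upper = unname(upper))
  ), class = "qc_flags")
}

#' Subjects with at least one flagged metric
#' @param qc a `qc_flags` object.
#' @return character vector of subject ids.
#' @export
qc_flagged_subjects <- function(qc) {
  stopifnot(inherits(qc, "qc_flags"))
  any_flag <- rowSums(as.matrix(qc$flags[, -1, drop = FALSE])) > 0
  qc$flags$subject_id[any_flag]
}
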