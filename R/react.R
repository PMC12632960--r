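#' Min-max rescale a template map to \[0, 1\] within a mask
#'
#' Applies `(x - min) / (max - min)` over in-mask voxels and zeroes everything
#' outside the mask, the convention used for receptor-density templates
#' before they enter the dual regression.
#'
#' @param raw_map numeric 3D array.
#' @param mask logical 3D array of the same shape.
#' @return numeric 3D array, values in \[0, 1\] inside the mask, 0 outside.
#' @export
rescale_template <- function(raw_map, mask) {
  stopifnot(identical(dim(raw_map), dim(mask)))
  if (!any(mask)) abort("mask is empty")
  v <- raw_map[mask]
  if (any(!is.finite(v))) abort("template has non-finite values inside the mask")
  rng <- range(v)
  if (rng[1] == rng[2]) abort("degenerate template: constant within the mask")
  out <- array(0, dim(raw_map))
  out[mask] <- (v - rng[1]) / (rng[2] - rng[1])
  out
}

#' Build the stage masks for the two-stage regression
#'
#' Stage-1 support for target k is the intersection of the template's
#' positive support with the gray-matter mask; the joint stage-1 mask used by
#' the multivariate fit is the intersection across all targets. The stage-2
#' mask is the gray-matter mask itself.
#'
#' @param templates a `receptor_templates` object.
#' @param gm_mask logical 3D array (gray matter).
#' @return a `stage_masks` list: `stage1` (named list of per-target logical
#'   arrays), `stage1_joint`, `stage2`.
#' @export
build_stage_masks <- function(templates, gm_mask) {
  stopifnot(inherits(templates, "receptor_templates"))
  if (!identical(dim(gm_mask), as.integer(templates$dim)) &&
      !identical(dim(gm_mask), templates$dim)) {
    abort("gray-matter mask geometry does not match the templates")
  }
  k <- length(templates$target_names)
  stage1 <- vector("list", k)
  names(stage1) <- templates$target_names
  joint <- gm_mask & templates$mask
  for (j in seq_len(k)) {
    support <- array(templates$values[, j] > 0, templates$dim)
    s1 <- support & gm_mask & templates$mask
    if (!any(s1)) {
      abort(sprintf("empty stage-1 intersection for target '%s'", templates$target_names[j]))
    }
    stage1[[j]] <- s1
    joint <- joint & s1
  }
  if (!any(joint)) abort("empty joint stage-1 mask across targets")
  structure(list(stage1 = stage1, stage1_joint = joint, stage2 = gm_mask & templates$mask),
            class = "stage_masks")
}

standardize_cols <- function(x) {
  mu <- colMeans(x)
  sg <- apply(x, 2, sd)
  if (any(sg == 0)) abort("constant design column: cannot standardize")
  sweep(sweep(x, 2, mu), 2, sg, "/")
}

check_design <- function(x, names) {
  qx <- qr(x)
  if (qx$rank < ncol(x)) {
    dropped <- names[qx$pivot[(qx$rank + 1):ncol(x)]]
    abort(paste0("rank-deficient design; collinear target(s): ", paste(dropped, collapse = ", ")))
  }
  kp <- kappa(x, exact = TRUE)
  if (kp > 1e6) warn(sprintf("design condition number %.3g exceeds 1e6", kp))
  qx
}

#' Stage 1: spatial regression of each BOLD frame onto the templates
#'
#' For every time frame, the voxel vector (demeaned over the joint stage-1
#' mask) is regressed jointly on all K template columns, each standardized to
#' zero mean and unit variance within that mask. The result is the
#' subject-specific weight time series: one column per molecular target,
#' quantifying how strongly that density distribution modulates the ongoing
#' BOLD fluctuations.
#'
#' @param bold a `bold_run`.
#' @param templates a `receptor_templates` object.
#' @param masks a `stage_masks` object (see [build_stage_masks()]).
#' @return a `molecular_timeseries`: `values` (T x K), `target_names`.
#' @export
stage1_spatial_regression <- function(bold, templates, masks) {
  stopifnot(inherits(bold, "bold_run"), inherits(masks, "stage_masks"))
  k <- length(templates$target_names)
  if (nrow(bold$values) < k + 2L) abort("need at least K + 2 time points")
  idx <- which(masks$stage1_joint)
  x <- standardize_cols(templates$values[idx, , drop = FALSE])
  check_design(x, templates$target_names)
  y <- bold$values[, idx, drop = FALSE]
  yc <- y - rowMeans(y)
  beta <- t(qr.coef(qr(x), t(yc)))
  colnames(beta) <- templates$target_names
  structure(list(values = beta, target_names = templates$target_names),
            class = "molecular_timeseries")
}

#' Stage 2: temporal regression of each voxel onto the weight time series
#'
#' Every in-mask voxel's time series (demeaned in time) is regressed jointly
#' on the K weight time series, each standardized to zero mean and unit
#' variance. The coefficients are the molecular-enriched connectivity maps;
#' units are BOLD change per 1 SD of the weight time series.
#'
#' @param bold a `bold_run`.
#' @param ts a `molecular_timeseries` (stage-1 output).
#' @param masks a `stage_masks` object.
#' @return an `enriched_maps` object: `values` (full-grid voxels x K, zero
#'   outside the stage-2 mask), `target_names`, `mask`, `dim`.
#' @export
stage2_temporal_regression <- function(bold, ts, masks) {
  stopifnot(inherits(bold, "bold_run"), inherits(ts, "molecular_timeseries"))
  if (nrow(ts$values) != nrow(bold$values)) abort("time dimension mismatch")
  if (any(apply(ts$values, 2, sd) == 0)) abort("constant weight time-series column")
  s <- standardize_cols(ts$values)
  check_design(s, ts$target_names)
  idx <- which(masks$stage2)
  y <- bold$values[, idx, drop = FALSE]
  yc <- sweep(y, 2, colMeans(y))
  beta <- qr.coef(qr(s), yc)
  full <- matrix(0, prod(bold$dim), ncol(s))
  full[idx, ] <- t(beta)
  colnames(full) <- ts$target_names
  structure(list(values = full, target_names = ts$target_names,
                 mask = masks$stage2, dim = bold$dim),
            class = "enriched_maps")
}

#' Run the full two-stage dual regression
#'
#' Rescales templates to \[0, 1\] where needed, builds the stage masks, and
#' chains the spatial (stage 1) and temporal (stage 2) regressions.
#'
#' @param bold a `bold_run`.
#' @param templates a `receptor_templates` object.
#' @param gm_mask logical 3D gray-matter mask; defaults to the template mask.
#' @return list with `timeseries` (T x K `molecular_timeseries`), `maps`
#'   (V x K `enriched_maps`), and `masks`.
#' @export
run_react <- function(bold, templates, gm_mask = NULL) {
  if (is.null(gm_mask)) gm_mask <- templates$mask
  vals <- templates$values
  for (j in seq_len(ncol(vals))) {
    inm <- vals[templates$mask, j]
    if (min(inm) < 0 || max(inm) > 1) {
      resc <- rescale_template(array(vals[, j], templates$dim), templates$mask)
      vals[, j] <- as.vector(resc)
    }
  }
  templates$values <- vals
  masks <- build_stage_masks(templates, gm_mask)
  ts <- stage1_spatial_regression(bold, templates, masks)
  maps <- stage2_temporal_regression(bold, ts, masks)
  list(timeseries = ts, maps = maps, masks = masks)
}
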