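#' Partition features into homogeneous harmonization subgroups
#'
#' Empirical-Bayes pooling borrows strength across features, which is only
#' sensible among features of the same type. Functional features are grouped
#' by transporter x parcel set (one of the seven cortical networks, the
#' subcortical set, or the cerebellar set); structural features by source
#' .stats file x measure nature. Both keys are carried in the `group` column
#' of the feature metadata, so the partition is simply the distinct values of
#' that column.
#'
#' @param meta feature metadata tibble (`name`, `block`, `group`).
#' @return tibble `name`, `subgroup` covering every feature.
#' @export
partition_subgroups <- function(meta) {
  meta <- as_tibble(meta)
  if (!all(c("name", "block", "group") %in% names(meta))) {
    abort("feature metadata needs columns name, block, group")
  }
  bad <- is.na(meta$group) | !nzchar(meta$group)
  if (any(bad)) {
    abort(paste0("feature(s) with unknown group: ",
                 paste(utils::head(meta$name[bad], 5), collapse = ", ")))
  }
  tibble(name = meta$name, subgroup = meta$group)
}

combat_design <- function(tbl, batch_key, covariate_keys) {
  covs <- as.data.frame(tbl)[, c(batch_key, covariate_keys), drop = FALSE]
  batch <- factor(covs[[batch_key]])
  n_i <- table(batch)
  if (any(n_i < 3L)) abort("every batch needs at least 3 subjects")
  if (nlevels(batch) == 1L) {
    bmat <- matrix(1, length(batch), 1)
  } else {
    bmat <- stats::model.matrix(~ 0 + batch)
  }
  colnames(bmat) <- levels(batch)
  xmat <- NULL
  if (length(covariate_keys)) {
    xmat <- as.matrix(as.data.frame(lapply(covs[covariate_keys], as.numeric)))
  }
  design <- cbind(bmat, xmat)
  if (qr(design)$rank < ncol(design)) {
    abort("singular design: covariates are confounded with batch")
  }
  list(batch = batch, levels = levels(batch), n_i = as.numeric(n_i),
       bmat = bmat, xmat = xmat, design = design)
}

# Parametric EB conditional estimates for one batch within one subgroup:
# normal prior on the location effects, inverse-gamma on the scale effects,
# method-of-moments hyperparameters, iterated to a joint fixed point.
eb_solve <- function(g_hat, d_hat, z_batch, conv = 1e-4, maxit = 100L) {
  n <- nrow(z_batch)
  g_bar <- mean(g_hat)
  t2 <- var(g_hat)
  m <- mean(d_hat)
  s2 <- var(d_hat)
  a_prior <- (2 * s2 + m^2) / s2
  b_prior <- (m * s2 + m^3) / s2
  g_old <- g_hat
  d_old <- d_hat
  it <- 0L
  repeat {
    it <- it + 1L
    g_new <- (t2 * n * g_hat + d_old * g_bar) / (t2 * n + d_old)
    sum2 <- colSums(sweep(z_batch, 2, g_new)^2)
    d_new <- (0.5 * sum2 + b_prior) / (n / 2 + a_prior - 1)
    # relative-change criterion of the standard iterative scheme
    change <- max(abs(g_new - g_old) / g_old, abs(d_new - d_old) / d_old)
    g_old <- g_new
    d_old <- d_new
    if (change < conv || it >= maxit) break
  }
  list(gamma_star = g_new, delta_star = d_new, iterations = it,
       hyper = c(gamma_bar = g_bar, tau2 = t2, a_prior = a_prior, b_prior = b_prior))
}

#' Fit a ComBat location/scale harmonization model
#'
#' Per feature g, fits `x = alpha_g + X beta_g + gamma_(batch,g) +
#' delta_(batch,g) eps` with batch intercepts constrained by a
#' batch-size-weighted sum to zero, standardizes the data by the pooled
#' residual scale, and estimates per-batch location (`gamma`) and scale
#' (`delta^2`) effects. Without EB (`eb = FALSE`) these are the batch mean
#' and variance of the standardized data. With EB (`eb = TRUE`) the
#' parametric empirical-Bayes conditional estimates are computed by the
#' standard iterative scheme, with method-of-moments hyperparameters
#' estimated separately within each subgroup, so borrowing of strength
#' happens only among features of the same type. Covariate effects (age,
#' sex) are estimated on all data and re-added on adjustment.
#'
#' @param tbl a `feature_tbl`.
#' @param batch_key covariate naming the batch (default `"site"`).
#' @param covariate_keys covariates to preserve (default `c("age", "sex")`;
#'   age enters linearly in years).
#' @param eb use empirical-Bayes pooling?
#' @param subgroups optional tibble `name`, `subgroup` (see
#'   [partition_subgroups()]); required when `eb = TRUE` with more than one
#'   intended pool, defaults to a single subgroup.
#' @param conv EB convergence threshold on the maximum relative parameter
#'   change (default 1e-4).
#' @param maxit EB iteration cap (default 100).
#' @return a `combat_model`.
#' @export
fit_combat <- function(tbl, batch_key = "site", covariate_keys = c("age", "sex"),
                       eb = FALSE, subgroups = NULL, conv = 1e-4, maxit = 100L) {
  stopifnot(inherits(tbl, "feature_tbl"))
  x <- feature_matrix(tbl)
  g_names <- colnames(x)
  d <- combat_design(tbl, batch_key, covariate_keys)
  n <- nrow(x)
  n_batch <- length(d$levels)
  # per-feature OLS with full batch + covariate design (multi-response fit)
  b_hat <- qr.coef(qr(d$design), x)
  grand_alpha <- as.vector(crossprod(d$n_i / n, b_hat[seq_len(n_batch), , drop = FALSE]))
  fitted <- d$design %*% b_hat
  sigma2 <- colMeans((x - fitted)^2)
  if (any(sigma2 <= 0)) abort("zero pooled residual variance for some feature")
  cov_part <- if (is.null(d$xmat)) 0 else d$xmat %*% b_hat[-seq_len(n_batch), , drop = FALSE]
  stand_mean <- matrix(grand_alpha, n, length(g_names), byrow = TRUE) + cov_part
  z <- (x - stand_mean) / matrix(sqrt(sigma2), n, length(g_names), byrow = TRUE)

  gamma_hat <- rowsum(z, d$batch) / d$n_i
  delta_hat <- (rowsum(z^2, d$batch) - d$n_i * gamma_hat^2) / (d$n_i - 1)
  dimnames(gamma_hat) <- dimnames(delta_hat) <- list(d$levels, g_names)
  if (n_batch == 1L) {
    # a single batch carries no batch effect to remove: identity adjustment
    gamma_hat[] <- 0
    delta_hat[] <- 1
    eb <- FALSE
  }

  if (is.null(subgroups)) {
    subgroups <- tibble(name = g_names, subgroup = "all")
  }
  sg <- subgroups$subgroup[match(g_names, subgroups$name)]
  if (any(is.na(sg))) abort("subgroup assignment does not cover every feature")

  hyper <- list()
  iters <- integer(0)
  if (eb) {
    gamma_star <- gamma_hat
    delta_star <- delta_hat
    for (grp in unique(sg)) {
      cols <- which(sg == grp)
      if (length(cols) < 2L) {
        abort(sprintf("subgroup '%s' has < 2 features: EB hyperparameters undefined", grp))
      }
      for (i in seq_len(n_batch)) {
        zb <- z[d$batch == d$levels[i], cols, drop = FALSE]
        sol <- eb_solve(gamma_hat[i, cols], delta_hat[i, cols], zb,
                        conv = conv, maxit = maxit)
        gamma_star[i, cols] <- sol$gamma_star
        delta_star[i, cols] <- sol$delta_star
        hyper[[paste(grp, d$levels[i], sep = "|")]] <- sol$hyper
        iters[paste(grp, d$levels[i], sep = "|")] <- sol$iterations
      }
    }
  } else {
    if (any(delta_hat == 0)) abort("a batch has zero variance in some feature; cannot scale-adjust without EB")
    gamma_star <- gamma_hat
    delta_star <- delta_hat
  }

  structure(list(
    mode = if (eb) "CBE" else "CBI",
    batch_key = batch_key, covariate_keys = covariate_keys,
    batch_levels = d$levels, n_i = setNames(d$n_i, d$levels),
    feature_names = g_names,
    alpha = setNames(grand_alpha, g_names),
    beta = if (is.null(d$xmat)) NULL else
      structure(b_hat[-seq_len(n_batch), , drop = FALSE],
                dimnames = list(covariate_keys, g_names)),
    sigma2 = sigma2,
    gamma_hat = gamma_hat, delta_hat = delta_hat,
    gamma_star = gamma_star, delta_star = delta_star,
    subgroups = setNames(sg, g_names), eb = eb,
    eb_hyper = hyper, eb_iterations = iters
  ), class = "combat_model")
}

#' Apply a fitted ComBat model to a feature table
#'
#' Adjusts `x* = sigma_g * (z - gamma*) / sqrt(delta*^2) + alpha_g + X
#' beta_g`, where z is the standardized data under the fitted model.
#' Metadata and covariates pass through unchanged.
#'
#' @param model a `combat_model`.
#' @param tbl a `feature_tbl` with the same features and batch levels.
#' @return the adjusted `feature_tbl`.
#' @export
apply_combat <- function(model, tbl) {
  stopifnot(inherits(model, "combat_model"), inherits(tbl, "feature_tbl"))
  x <- feature_matrix(tbl)
  if (!identical(colnames(x), model$feature_names)) {
    abort("feature set differs from the fitted model")
  }
  batch <- as.character(as.data.frame(tbl)[[model$batch_key]])
  unseen <- setdiff(unique(batch), model$batch_levels)
  if (length(unseen)) {
    abort(paste0("unseen batch level(s): ", paste(unseen, collapse = ", ")))
  }
  n <- nrow(x)
  g <- length(model$feature_names)
  cov_part <- 0
  if (!is.null(model$beta)) {
    xmat <- as.matrix(as.data.frame(lapply(
      as.data.frame(tbl)[model$covariate_keys], as.numeric)))
    cov_part <- xmat %*% model$beta
  }
  stand_mean <- matrix(model$alpha, n, g, byrow = TRUE) + cov_part
  sig <- matrix(sqrt(model$sigma2), n, g, byrow = TRUE)
  z <- (x - stand_mean) / sig
  bi <- match(batch, model$batch_levels)
  z_adj <- (z - model$gamma_star[bi, , drop = FALSE]) /
    sqrt(model$delta_star[bi, , drop = FALSE])
  set_feature_matrix(tbl, z_adj * sig + stand_mean)
}

#' Harmonize a multi-site feature table
#'
#' The three strategies compared in multi-site brain-age work: `"none"`
#' (identity), `"cbi"` (per-feature location/scale adjustment without
#' empirical-Bayes pooling), and `"cbe"` (EB pooling applied separately
#' within homogeneous feature subgroups derived from the feature metadata,
#' then recombined in the original column order).
#'
#' @param tbl a `feature_tbl`.
#' @param strategy one of `"none"`, `"cbi"`, `"cbe"`.
#' @param batch_key batch covariate (default `"site"`).
#' @param covariate_keys covariates to preserve (default `c("age", "sex")`).
#' @return the harmonized `feature_tbl`; for cbi/cbe the fitted
#'   `combat_model` is attached as attribute `"combat_model"`.
#' @export
harmonize <- function(tbl, strategy = c("none", "cbi", "cbe"),
                      batch_key = "site", covariate_keys = c("age", "sex")) {
  strategy <- match.arg(strategy)
  if (strategy == "none") return(tbl)
  eb <- strategy == "cbe"
  subgroups <- if (eb) partition_subgroups(feature_meta(tbl)) else NULL
  model <- fit_combat(tbl, batch_key, covariate_keys, eb = eb, subgroups = subgroups)
  out <- apply_combat(model, tbl)
  attr(out, "combat_model") <- model
  out
}

#' Serialize a fitted ComBat model to JSON
#' @param model a `combat_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_combat_model <- function(model, path) {
  stopifnot(inherits(model, "combat_model"))
  jsonlite::write_json(
    list(
      mode = model$mode, batch_key = model$batch_key,
      covariate_keys = model$covariate_keys,
      batch_levels = model$batch_levels, n_i = model$n_i,
      feature_names = model$feature_names,
      alpha = model$alpha, beta = model$beta, sigma2 = model$sigma2,
      gamma_star = model$gamma_star, delta_star = model$delta_star,
      subgroups = model$subgroups
    ),
    path, auto_unbox = TRUE, digits = NA, matrix = "rowmajor"
  )
  invisible(path)
}

#' @export
print.combat_model <- function(x, ...) {
  cat(sprintf(
    "<combat_model> mode %s: %d features, %d batches (%s), covariates: %s\n",
    x$mode, length(x$feature_names), length(x$batch_levels),
    paste(x$batch_levels, collapse = ", "),
    paste(x$covariate_keys, collapse = ", ")
  ))
  if (x$eb) cat(sprintf("  %d EB subgroup x batch pools\n", length(x$eb_hyper)))
  invisible(x)
}

#' @rdname tidy
#' @method tidy combat_model
#' @export
tidy.combat_model <- function(x, ...) {
  long <- tidyr::expand_grid(batch = x$batch_levels, feature = x$feature_names)
  long$gamma_star <- as.vector(t(x$gamma_star))[
    (match(long$batch, x$batch_levels) - 1) * length(x$feature_names) +
      match(long$feature, x$feature_names)]
  long$delta_star <- as.vector(t(x$delta_star))[
    (match(long$batch, x$batch_levels) - 1) * length(x$feature_names) +
      match(long$feature, x$feature_names)]
  long$subgroup <- x$subgroups[long$feature]
  long
}

#' @rdname glance
#' @method glance combat_model
#' @export
glance.combat_model <- function(x, ...) {
  tibble(
    mode = x$mode, n_features = length(x$feature_names),
    n_batches = length(x$batch_levels),
    n_subgroups = length(unique(x$subgroups)),
    eb = x$eb,
    max_eb_iterations = if (length(x$eb_iterations)) max(x$eb_iterations) else NA_integer_
  )
}
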