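#' Default SVR hyperparameter grid
#'
#' Cost `C` in \{0.1, 1, 10, 100\}, RBF kernel width `gamma` in
#' \{0.1, 1, 10\}/d with d the feature count, tube width `epsilon` in
#' \{0.1, 1, 2\} years. Rows are ordered by (C, gamma, epsilon) ascending;
#' grid-search ties are broken toward the first row, i.e. smallest C, then
#' gamma, then epsilon.
#'
#' @param n_features feature count d used to scale gamma.
#' @return tibble with columns `C`, `gamma`, `epsilon`.
#' @export
default_svr_grid <- function(n_features) {
  g <- expand.grid(epsilon = c(0.1, 1, 2), gamma = c(0.1, 1, 10) / n_features,
                   C = c(0.1, 1, 10, 100))
  as_tibble(g[order(g$C, g$gamma, g$epsilon), c("C", "gamma", "epsilon")])
}

#' Cross-validation configuration for brain-age models
#'
#' @param n_folds outer folds (default 10).
#' @param n_repeats repeats of the whole CV (default 10).
#' @param inner_folds folds of the inner grid-search CV (default 5).
#' @param grid hyperparameter tibble (`C`, `gamma`, `epsilon`); defaults to
#'   [default_svr_grid()] at fit time.
#' @param n_strat_bins age-stratification quantile bins (default `n_folds`).
#' @param seed integer seed fixing all randomness.
#' @return a `cv_config` list.
#' @export
cv_config <- function(n_folds = 10L, n_repeats = 10L, inner_folds = 5L,
                      grid = NULL, n_strat_bins = n_folds, seed = 42L) {
  if (n_folds < 2L) abort("n_folds must be >= 2")
  if (n_repeats < 1L || inner_folds < 2L) abort("invalid repeat/inner-fold counts")
  if (!is.null(grid) && nrow(grid) == 0L) abort("empty hyperparameter grid")
  structure(list(
    n_folds = as.integer(n_folds), n_repeats = as.integer(n_repeats),
    inner_folds = as.integer(inner_folds), grid = grid,
    n_strat_bins = as.integer(n_strat_bins), seed = as.integer(seed)
  ), class = "cv_config")
}

#' Robust (median/IQR) feature scaling
#'
#' Per feature: `(x - median) / IQR`, with median and IQR (type-7 quantiles,
#' 25th to 75th percentile) fitted on the training rows only and applied to
#' both matrices. A zero IQR (constant feature) gets scale 1, leaving the
#' column at zero after centering.
#'
#' @param train numeric matrix used to fit center/scale.
#' @param apply_to optional second matrix to transform with the fitted
#'   parameters.
#' @return list with `train` (scaled training matrix), `applied` (scaled
#'   `apply_to`, or NULL), `center` (medians), `scale` (IQRs, zeros replaced
#'   by 1).
#' @export
robust_scale <- function(train, apply_to = NULL) {
  train <- as.matrix(train)
  if (nrow(train) == 0L) abort("empty training matrix")
  ctr <- apply(train, 2, median)
  q <- apply(train, 2, quantile, probs = c(0.25, 0.75), type = 7)
  scl <- q[2, ] - q[1, ]
  scl[scl == 0] <- 1
  tf <- function(m) sweep(sweep(m, 2, ctr), 2, scl, "/")
  list(train = tf(train),
       applied = if (is.null(apply_to)) NULL else tf(as.matrix(apply_to)),
       center = ctr, scale = scl)
}

#' Age-stratified fold assignment
#'
#' Ages are cut into quantile bins; within each bin subjects are shuffled
#' (seeded) and dealt round-robin across folds, so every fold spans the age
#' range. Each repeat redraws the shuffle with a seed derived from the base
#' seed.
#'
#' @param ages numeric vector of ages.
#' @param n_folds number of folds.
#' @param n_repeats number of repeats.
#' @param n_strat_bins number of quantile bins (default `n_folds`).
#' @param seed integer seed.
#' @return integer matrix, subjects x repeats, entries in 1..n_folds.
#' @export
age_stratified_folds <- function(ages, n_folds, n_repeats = 1L,
                                 n_strat_bins = n_folds, seed = 42L) {
  n <- length(ages)
  if (n_folds > n) abort("more folds than subjects")
  breaks <- unique(quantile(ages, probs = seq(0, 1, length.out = n_strat_bins + 1), type = 7))
  bins <- cut(ages, breaks = breaks, include.lowest = TRUE, labels = FALSE)
  out <- matrix(NA_integer_, n, n_repeats)
  for (r in seq_len(n_repeats)) {
    withr::with_seed(as.integer(seed) + r - 1L, {
      fold_counter <- 0L
      for (b in sort(unique(bins))) {
        idx <- which(bins == b)
        idx <- idx[sample.int(length(idx))]
        out[idx, r] <- (fold_counter + seq_along(idx) - 1L) %% n_folds + 1L
        fold_counter <- (fold_counter + length(idx)) %% n_folds
      }
    })
  }
  out
}

fit_svr <- function(x, y, par) {
  e1071::svm(x = x, y = y, type = "eps-regression", kernel = "radial",
             cost = par$C, gamma = par$gamma, epsilon = par$epsilon,
             scale = FALSE)
}

select_hyperparameters <- function(x, y, grid, inner_folds, n_strat_bins, seed) {
  inner <- age_stratified_folds(y, inner_folds, 1L, n_strat_bins = min(n_strat_bins, inner_folds),
                                seed = seed)[, 1]
  best <- NULL
  best_mae <- Inf
  for (i in seq_len(nrow(grid))) {
    par <- grid[i, ]
    abs_err <- numeric(0)
    for (f in seq_len(inner_folds)) {
      tr <- inner != f
      fit <- fit_svr(x[tr, , drop = FALSE], y[tr], par)
      pred <- predict(fit, x[!tr, , drop = FALSE])
      abs_err <- c(abs_err, abs(pred - y[!tr]))
    }
    mae <- mean(abs_err)
    if (mae < best_mae) {  # strict: ties keep the earlier (smaller) row
      best_mae <- mae
      best <- par
    }
  }
  best
}

#' Nested cross-validated SVR brain-age prediction
#'
#' Repeated age-stratified k-fold CV with a nested grid search: for every
#' repeat and outer fold, features are robust-scaled on the training portion
#' only, an inner CV selects `(C, gamma, epsilon)` by inner mean absolute
#' error (ties broken toward smaller values), the model is refit on the full
#' outer-training portion, and the held-out fold is predicted. The total
#' number of fitted outer models is `n_folds * n_repeats`.
#'
#' @param tbl a `feature_tbl` with an `age` covariate.
#' @param cfg a [cv_config()].
#' @return a `prediction_set`: tibble with one row per (repeat, fold,
#'   subject) — columns `repeat_id`, `fold`, `subject_id`, `age`,
#'   `predicted`, `C`, `gamma`, `epsilon` — carrying the config as an
#'   attribute.
#' @export
nested_cv_svr <- function(tbl, cfg = cv_config()) {
  stopifnot(inherits(tbl, "feature_tbl"), inherits(cfg, "cv_config"))
  x_all <- feature_matrix(tbl)
  if (ncol(x_all) < 2L) abort("need at least 2 features")
  if (any(!is.finite(x_all))) abort("non-finite feature values")
  y_all <- tbl$age
  grid <- cfg$grid %||% default_svr_grid(ncol(x_all))
  folds <- age_stratified_folds(y_all, cfg$n_folds, cfg$n_repeats,
                                cfg$n_strat_bins, cfg$seed)
  res <- vector("list", cfg$n_repeats * cfg$n_folds)
  ri <- 0L
  for (r in seq_len(cfg$n_repeats)) {
    for (f in seq_len(cfg$n_folds)) {
      tr <- folds[, r] != f
      sc <- robust_scale(x_all[tr, , drop = FALSE], x_all[!tr, , drop = FALSE])
      par <- select_hyperparameters(
        sc$train, y_all[tr], grid, cfg$inner_folds, cfg$n_strat_bins,
        seed = cfg$seed + 1000L * r + f
      )
      fit <- fit_svr(sc$train, y_all[tr], par)
      pred <- predict(fit, sc$applied)
      ri <- ri + 1L
      res[[ri]] <- tibble(
        repeat_id = r, fold = f,
        subject_id = tbl$subject_id[!tr],
        age = y_all[!tr], predicted = as.numeric(pred),
        C = par$C, gamma = par$gamma, epsilon = par$epsilon
      )
    }
  }
  out <- dplyr::bind_rows(res)
  class(out) <- c("prediction_set", class(tibble()))
  attr(out, "cv_config") <- cfg
  out
}

metric_row <- function(y, yhat) {
  delta <- yhat - y
  safe_cor <- function(a, b, method) {
    if (sd(a) == 0 || sd(b) == 0) NA_real_ else cor(a, b, method = method)
  }
  tibble(
    mae = mean(abs(delta)),
    rmse = sqrt(mean(delta^2)),
    r = safe_cor(y, yhat, "pearson"),
    r2 = 1 - sum(delta^2) / sum((y - mean(y))^2),
    rho = safe_cor(delta, y, "spearman")
  )
}

#' Evaluation metrics for a prediction set
#'
#' Five complementary statistics computed in every test fold: MAE, RMSE,
#' Pearson r between true and predicted age, the prediction R-squared
#' `1 - SS_res / SS_tot`, and the age-bias Spearman rho between the
#' prediction error (predicted minus true) and chronological age (values
#' near zero mean errors are not systematically age-dependent). Summaries
#' follow the usual table convention: mean over all folds and repeats, SD
#' across the per-repeat means only, plus a pooled value over all
#' predictions. Correlations of constant vectors are reported as NA, never
#' silently 0.
#'
#' @param pred a `prediction_set`.
#' @return a `metrics_report`: list with `per_fold`, `per_repeat`, `summary`
#'   tibbles.
#' @export
compute_metrics <- function(pred) {
  stopifnot(inherits(pred, "prediction_set") || all(c("repeat_id", "fold", "age", "predicted") %in% names(pred)))
  pred <- as_tibble(pred)
  per_fold <- pred |>
    dplyr::group_by(.data$repeat_id, .data$fold) |>
    dplyr::group_modify(~ metric_row(.x$age, .x$predicted)) |>
    dplyr::ungroup()
  per_repeat <- per_fold |>
    dplyr::group_by(.data$repeat_id) |>
    dplyr::summarise(dplyr::across(c("mae", "rmse", "r", "r2", "rho"), mean), .groups = "drop")
  pooled <- metric_row(pred$age, pred$predicted)
  summary <- tibble(
    metric = c("mae", "rmse", "r", "r2", "rho"),
    mean = unname(vapply(c("mae", "rmse", "r", "r2", "rho"), function(m) mean(per_fold[[m]]), 0)),
    sd = unname(vapply(c("mae", "rmse", "r", "r2", "rho"), function(m) sd(per_repeat[[m]]), 0)),
    pooled = as.numeric(pooled[1, ])
  )
  structure(list(per_fold = per_fold, per_repeat = per_repeat, summary = summary),
            class = "metrics_report")
}

#' Per-subject brain-age gap
#'
#' The brain-age gap is the signed difference between predicted and
#' chronological age (years); a positive gap indicates an older-appearing
#' brain. Predictions are averaged over repeats before differencing.
#'
#' @param pred a `prediction_set`.
#' @return a `brain_age_gap` tibble: `subject_id`, `age`, `predicted`
#'   (mean over repeats), `delta`.
#' @export
brain_age_delta <- function(pred) {
  out <- as_tibble(pred) |>
    dplyr::group_by(.data$subject_id, .data$age) |>
    dplyr::summarise(predicted = mean(.data$predicted), .groups = "drop") |>
    dplyr::mutate(delta = .data$predicted - .data$age)
  class(out) <- c("brain_age_gap", class(tibble()))
  out
}

#' Run the block-by-strategy brain-age experiment
#'
#' Loops feature-block configurations (e.g. DAT, NET, SERT, MEF, SMF, MMF)
#' under a harmonization strategy, running harmonization then nested-CV SVR
#' on each, and emits one metrics row per configuration.
#'
#' @param blocks named list of `feature_tbl` (one per configuration), e.g.
#'   from [assemble_blocks()].
#' @param strategy harmonization strategy, one of `"none"`, `"cbi"`, `"cbe"`.
#' @param cfg a [cv_config()].
#' @return an `experiment_result` tibble: one row per block with columns
#'   `block`, `strategy`, and `<metric>` / `<metric>_sd` for the five
#'   metrics; prediction sets attached as attribute `"predictions"`.
#' @export
run_experiment <- function(blocks, strategy = "none", cfg = cv_config()) {
  stopifnot(is.list(blocks), !is.null(names(blocks)))
  rows <- list()
  preds <- list()
  for (b in names(blocks)) {
    harmonized <- harmonize(blocks[[b]], strategy)
    p <- nested_cv_svr(harmonized, cfg)
    m <- compute_metrics(p)
    s <- m$summary
    row <- tibble(block = b, strategy = strategy)
    for (i in seq_len(nrow(s))) {
      row[[s$metric[i]]] <- s$mean[i]
      row[[paste0(s$metric[i], "_sd")]] <- s$sd[i]
    }
    rows[[b]] <- row
    preds[[b]] <- p
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("experiment_result", class(tibble()))
  attr(out, "predictions") <- preds
  out
}

#' @rdname tidy
#' @method tidy metrics_report
#' @export
tidy.metrics_report <- function(x, ...) {
  tidyr::pivot_longer(x$per_fold, cols = c("mae", "rmse", "r", "r2", "rho"),
                      names_to = "metric", values_to = "value")
}

#' @rdname glance
#' @method glance metrics_report
#' @export
glance.metrics_report <- function(x, ...) {
  wide <- tidyr::pivot_wider(x$summary[, c("metric", "mean")],
                             names_from = "metric", values_from = "mean")
  sds <- tidyr::pivot_wider(x$summary[, c("metric", "sd")],
                            names_from = "metric", values_from = "sd")
  names(sds) <- paste0(names(sds), "_sd")
  dplyr::bind_cols(wide, sds)
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("<metrics_report> mean over folds/repeats (SD across repeats):\n")
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-5s %8.3f (%.3f)\n", s$metric[i], s$mean[i], s$sd[i]))
  }
  invisible(x)
}

#' Broom-style tidiers and summaries
#'
#' `tidy()` returns per-component long tibbles (per-batch ComBat effects,
#' per-fold metrics); `glance()` returns a one-row summary.
#'
#' @param x a fitted object from this package.
#' @param ... unused.
#' @name tidy
NULL

#' @name glance
#' @rdname tidy
NULL
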