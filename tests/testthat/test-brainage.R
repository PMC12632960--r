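test_that("robust scaling centers by median and scales by IQR, train-only", {
  withr::with_seed(71, train <- matrix(rnorm(40 * 3, 10, 5), 40, 3))
  sc <- robust_scale(train)
  expect_equal(unname(apply(sc$train, 2, median)), rep(0, 3), tolerance = 1e-12)
  iqr <- apply(sc$train, 2, function(v) diff(quantile(v, c(0.25, 0.75), type = 7)))
  expect_equal(unname(iqr), rep(1, 3), tolerance = 1e-12)

  # hand-computed spot values for {1, 2, 3, 100} (type-7 quantiles)
  sc2 <- robust_scale(matrix(c(1, 2, 3, 100), 4, 1))
  expect_equal(unname(sc2$center), 2.5)
  expect_equal(unname(sc2$scale), 25.5)  # Q3 = 27.25, Q1 = 1.75
  expect_equal(sc2$train[1, 1], (1 - 2.5) / 25.5)

  # constant features get scale 1 and become all zeros
  sc3 <- robust_scale(cbind(rep(4, 5), 1:5))
  expect_equal(sc3$train[, 1], rep(0, 5))
  expect_equal(unname(sc3$scale[1]), 1)

  # parameters are fitted on the training rows only
  sc4 <- robust_scale(train, apply_to = train + 100)
  expect_equal(sc4$applied, sc$train + 100 / matrix(sc$scale, 40, 3, byrow = TRUE),
               tolerance = 1e-12)
})

test_that("age-stratified folds balance sizes and age distributions", {
  withr::with_seed(73, ages <- runif(100, 18, 90))
  f <- age_stratified_folds(ages, 10, n_repeats = 1, seed = 5)
  expect_equal(as.integer(table(f[, 1])), rep(10L, 10))
  expect_identical(age_stratified_folds(ages, 10, seed = 5), f)

  withr::with_seed(74, big <- runif(1000, 18, 90))
  fb <- age_stratified_folds(big, 10, seed = 6)
  fold_means <- tapply(big, fb[, 1], mean)
  expect_lte(max(fold_means) - min(fold_means), 0.25 * sd(big))

  expect_error(age_stratified_folds(ages[1:5], 10), "more folds")
})

test_that("nested CV is deterministic, leakage-free, and counts models correctly", {
  meta <- tibble::tibble(name = sprintf("f%02d", 1:5), block = "DAT", group = "all")
  cfg_sim <- sim_config(n_subjects = 60, sites = c(a = 30, b = 30),
                        site_shift = 0, site_scale = 1, beta_age = 0.4,
                        beta_sex = 0, noise_sd = 0.5, seed = 81)
  tbl <- make_cohort(cfg_sim, meta)$table
  cfg <- cv_config(n_folds = 3, n_repeats = 2, inner_folds = 3,
                   grid = tibble::tibble(C = c(1, 10), gamma = 0.05, epsilon = 0.5),
                   seed = 9)
  p1 <- nested_cv_svr(tbl, cfg)
  p2 <- nested_cv_svr(tbl, cfg)
  expect_identical(as.data.frame(p1), as.data.frame(p2))
  # every subject predicted exactly once per repeat; models = folds x repeats
  counts <- table(p1$subject_id, p1$repeat_id)
  expect_true(all(counts == 1L))
  expect_equal(nrow(dplyr::distinct(p1, .data$repeat_id, .data$fold)), 6L)
  # sanity bound on the predictions
  expect_true(all(p1$predicted >= min(tbl$age) - 20 & p1$predicted <= max(tbl$age) + 20))
})

test_that("a feature informative only in test rows cannot leak into training", {
  # canary: equals age exactly on fold-1 rows, pure noise elsewhere; with
  # leakage-free scaling/selection/fitting, fold-1 predictions stay poor
  withr::with_seed(83, {
    n <- 60
    ages <- runif(n, 18, 90)
    x <- matrix(rnorm(n * 5), n, 5)
  })
  cfg <- cv_config(n_folds = 3, n_repeats = 1, inner_folds = 3,
                   grid = tibble::tibble(C = 10, gamma = 0.1, epsilon = 0.5),
                   seed = 15)
  folds <- age_stratified_folds(ages, 3, 1, n_strat_bins = 3, seed = 15)[, 1]
  canary <- rnorm(n, 50, 10)
  canary[folds == 1] <- ages[folds == 1]
  x <- cbind(x, canary)
  colnames(x) <- sprintf("f%02d", 1:6)
  tbl <- feature_table(
    x, tibble::tibble(name = colnames(x), block = "DAT", group = "all"),
    tibble::tibble(subject_id = sprintf("s%03d", 1:n), age = ages,
                   sex = 0, site = "s1")
  )
  p <- nested_cv_svr(tbl, cfg)
  fold1_mae <- mean(abs(p$predicted[p$fold == 1] - p$age[p$fold == 1]))
  # features carry no real age signal, so honest fold-1 error stays large;
  # a leaky pipeline would drive it toward zero through the canary
  expect_gt(fold1_mae, 5)
})

test_that("metric identities hold for perfect, constant, and toy predictors", {
  y <- c(20, 35, 50, 65, 80)
  perfect <- compute_metrics(manual_prediction_set(y, y))
  s <- perfect$summary
  expect_equal(s$mean[s$metric == "mae"], 0)
  expect_equal(s$mean[s$metric == "rmse"], 0)
  expect_equal(s$mean[s$metric == "r"], 1)
  expect_equal(s$mean[s$metric == "r2"], 1)
  expect_true(is.na(s$mean[s$metric == "rho"]))  # undefined, never silently 0

  const <- compute_metrics(manual_prediction_set(y, rep(mean(y), 5)))
  sc <- const$summary
  expect_equal(sc$mean[sc$metric == "r2"], 0)
  expect_equal(sc$mean[sc$metric == "rho"], -1)
  expect_true(is.na(sc$mean[sc$metric == "r"]))

  toy <- compute_metrics(manual_prediction_set(c(20, 40, 60), c(25, 35, 65)))
  st <- toy$summary
  expect_equal(st$mean[st$metric == "mae"], 5)
  expect_equal(st$mean[st$metric == "rmse"], 5)

  delta <- brain_age_delta(manual_prediction_set(c(20, 40, 60), c(25, 35, 65)))
  expect_equal(delta$delta[match(sprintf("s%03d", 1:3), delta$subject_id)],
               c(5, -5, 5))
  d0 <- brain_age_delta(manual_prediction_set(y, y))
  expect_true(all(d0$delta == 0))
  d3 <- brain_age_delta(manual_prediction_set(y, y + 3))
  expect_true(all(d3$delta == 3))
})

test_that("RMSE dominates MAE and summaries follow the mean/SD convention", {
  withr::with_seed(91, {
    for (i in 1:5) {
      y <- runif(30, 18, 90)
      yhat <- y + rnorm(30, 0, 5)
      p <- manual_prediction_set(y, yhat,
                                 repeat_id = rep(1:2, 15), fold = rep(1:3, 10))
      m <- compute_metrics(p)
      expect_true(all(m$per_fold$rmse >= m$per_fold$mae))
      s <- m$summary
      expect_equal(s$mean[s$metric == "mae"], mean(m$per_fold$mae))
      expect_equal(s$sd[s$metric == "mae"], sd(m$per_repeat$mae))
    }
  })
})

test_that("experiment loop ranks blocks by their planted signal", {
  withr::with_seed(95, {
    n <- 80
    age <- runif(n, 18, 90)
    sex <- rbinom(n, 1, 0.5)
    noise_block <- matrix(rnorm(n * 6), n, 6)
    signal_block <- outer(age, rep(0.5, 6)) + matrix(rnorm(n * 6, 0, 2), n, 6)
  })
  covs <- tibble::tibble(subject_id = sprintf("s%03d", 1:n), age = age,
                         sex = sex, site = rep(c("a", "b"), each = 40))
  mk <- function(x, block) {
    colnames(x) <- paste0(block, "_", seq_len(ncol(x)))
    feature_table(x, tibble::tibble(name = colnames(x), block = block, group = block), covs)
  }
  blocks <- list(DAT = mk(noise_block, "DAT"), SMF = mk(signal_block, "SMF"))
  cfg <- cv_config(n_folds = 3, n_repeats = 1, inner_folds = 3,
                   grid = tibble::tibble(C = c(10, 100), gamma = 0.1, epsilon = 0.5),
                   seed = 21)
  res <- run_experiment(blocks, strategy = "none", cfg = cfg)
  expect_equal(nrow(res), 2L)
  expect_gt(res$r2[res$block == "SMF"], res$r2[res$block == "DAT"])
})
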