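test_that("subgroup partition covers transporter x parcel-set and stats-file x nature", {
  # 3 transporters x (7 networks + subcortical + cerebellar) = 27 subgroups
  roi_groups <- c("Vis", "SomMot", "DorsAttn", "SalVentAttn", "Limbic",
                  "Cont", "Default", "subcortical", "cerebellar")
  meta <- tidyr::expand_grid(block = c("DAT", "NET", "SERT"), grp = roi_groups,
                             i = 1:2)
  meta <- tibble::tibble(
    name = paste(meta$block, meta$grp, meta$i, sep = "_"),
    block = meta$block, group = paste(meta$block, meta$grp, sep = ":")
  )
  sg <- partition_subgroups(meta)
  expect_equal(dplyr::n_distinct(sg$subgroup), 27L)

  # identical metadata collapses to one subgroup
  one <- tibble::tibble(name = paste0("f", 1:5), block = "DAT", group = "same")
  expect_equal(dplyr::n_distinct(partition_subgroups(one)$subgroup), 1L)

  # the structural fixture declares 18 (file, nature) pairs
  smf <- structural_feature_meta()
  expect_equal(dplyr::n_distinct(partition_subgroups(smf)$subgroup), 18L)

  expect_error(partition_subgroups(tibble::tibble(name = "f1", block = "DAT", group = NA)),
               "unknown group")
})

test_that("no-EB adjustment equalizes per-batch location and scale in closed form", {
  # planted pure mean shift, no covariates
  withr::with_seed(41, {
    n <- 60
    x <- matrix(rnorm(n * 8), n, 8)
    x[1:30, ] <- x[1:30, ] + 2
  })
  colnames(x) <- sprintf("f%02d", 1:8)
  covs <- tibble::tibble(subject_id = sprintf("s%02d", 1:n), age = 0, sex = 0,
                         site = rep(c("A", "B"), each = 30))
  tbl <- feature_table(x, tibble::tibble(name = colnames(x), block = "DAT", group = "all"),
                       covs)
  m <- fit_combat(tbl, covariate_keys = character(0), eb = FALSE)
  adj <- feature_matrix(apply_combat(m, tbl))
  for (g in seq_len(ncol(adj))) {
    pooled_mean <- mean(adj[, g])
    expect_equal(mean(adj[1:30, g]), pooled_mean, tolerance = 1e-10)
    expect_equal(mean(adj[31:60, g]), pooled_mean, tolerance = 1e-10)
    # per-batch variances equal each other and the model's pooled residual scale
    expect_equal(var(adj[1:30, g]), var(adj[31:60, g]), tolerance = 1e-8)
    expect_equal(var(adj[1:30, g]), unname(m$sigma2[g]), tolerance = 1e-8)
  }

  # refitting on adjusted data: location effects vanish; scale effects are
  # flat across batches at the n/(n - B) ratio implied by the pooled-/n vs
  # per-batch-/(n_i - 1) variance conventions of the reference model
  m2 <- fit_combat(apply_combat(m, tbl), covariate_keys = character(0), eb = FALSE)
  expect_lt(max(abs(m2$gamma_hat)), 1e-10)
  expect_equal(unname(m2$delta_hat[1, ]), rep(n / (n - 2), 8), tolerance = 1e-8)
  expect_equal(unname(m2$delta_hat[2, ]), rep(n / (n - 2), 8), tolerance = 1e-8)
})

test_that("a single batch adjusts to the identity", {
  tbl <- random_feature_table(n = 20, g = 5, n_sites = 1, seed = 3)
  m <- fit_combat(tbl, eb = FALSE)
  adj <- apply_combat(m, tbl)
  expect_equal(feature_matrix(adj), feature_matrix(tbl), tolerance = 1e-10)
})

test_that("EB estimates match the independent iterative oracle and shrink correctly", {
  meta <- tibble::tibble(name = sprintf("f%03d", 1:400), block = "DAT",
                         group = rep(c("g1", "g2"), each = 200))
  cfg <- sim_config(n_subjects = 100, sites = c(a = 50, b = 50),
                    site_shift = c(-1, 1), site_scale = c(1, 1.4),
                    beta_age = 0.3, beta_sex = 0.5, seed = 43)
  coh <- make_cohort(cfg, meta)
  tbl <- coh$table
  m <- fit_combat(tbl, eb = TRUE, subgroups = partition_subgroups(feature_meta(tbl)))
  x <- feature_matrix(tbl)
  for (grp in c("g1", "g2")) {
    cols <- which(feature_meta(tbl)$group == grp)
    ref <- oracle_combat_eb(x[, cols], tbl$site, tbl$age, tbl$sex, eb = TRUE)
    expect_lt(max(abs(m$gamma_star[, cols] - ref$gamma_star)), 1e-6)
    expect_lt(max(abs(m$delta_star[, cols] - ref$delta_star)), 1e-6)
    # shrinkage: EB location estimates lie between per-feature estimate and
    # the subgroup prior mean
    for (i in 1:2) {
      g_bar <- mean(m$gamma_hat[i, cols])
      lower <- pmin(m$gamma_hat[i, cols], g_bar) - 1e-12
      upper <- pmax(m$gamma_hat[i, cols], g_bar) + 1e-12
      expect_true(all(m$gamma_star[i, cols] >= lower & m$gamma_star[i, cols] <= upper))
    }
  }
})

test_that("single-subgroup EB agrees with the reference ComBat implementation", {
  tbl <- random_feature_table(n = 60, g = 40, n_sites = 3, seed = 99)
  m <- fit_combat(tbl, eb = TRUE)
  mine <- feature_matrix(apply_combat(m, tbl))
  x <- feature_matrix(tbl)
  ref <- suppressMessages(t(sva::ComBat(
    dat = t(x), batch = tbl$site,
    mod = stats::model.matrix(~ age + sex, data = as.data.frame(tbl)),
    par.prior = TRUE
  )))
  expect_lt(max(abs(mine - ref)), 1e-6)

  # CBI (no EB) against its closed form on the same table
  m0 <- fit_combat(tbl, eb = FALSE)
  ref0 <- oracle_combat_eb(x, tbl$site, tbl$age, tbl$sex, eb = FALSE)
  expect_lt(max(abs(m0$gamma_star - ref0$gamma_star)), 1e-8)
  expect_lt(max(abs(m0$delta_star - ref0$delta_star)), 1e-8)
})

test_that("harmonization preserves the planted age slope and removes site separability", {
  meta <- tibble::tibble(name = sprintf("f%02d", 1:20), block = "DAT", group = "all")
  cfg <- sim_config(n_subjects = 400, sites = c(a = 200, b = 200),
                    site_shift = c(-2, 2), site_scale = c(1, 1.5),
                    beta_age = 0.5, beta_sex = 1, seed = 47)
  coh <- make_cohort(cfg, meta)
  adj <- harmonize(coh$table, "cbi")
  slope <- coef(lm(feature_matrix(adj)[, 1] ~ adj$age))[2]
  expect_lt(abs(slope - 0.5), 0.1)

  # site classification from adjusted features drops to about chance
  withr::with_seed(48, idx <- sample.int(400, 200))
  xa <- feature_matrix(adj)
  df_tr <- data.frame(site = factor(adj$site[idx]), xa[idx, ])
  df_te <- data.frame(xa[-idx, ])
  fit <- suppressWarnings(stats::glm(site ~ ., data = df_tr, family = binomial()))
  pred <- ifelse(predict(fit, df_te, type = "response") > 0.5,
                 levels(df_tr$site)[2], levels(df_tr$site)[1])
  acc <- mean(pred == adj$site[-idx])
  expect_lte(acc, 0.55)
})

test_that("CBE beats CBI on gamma recovery in an EB-favorable regime", {
  # many features, small batches: pooling should stabilize the estimates
  meta <- tibble::tibble(name = sprintf("f%03d", 1:300), block = "DAT", group = "all")
  cfg <- sim_config(n_subjects = 16, sites = c(a = 8, b = 8),
                    site_shift = c(-0.5, 0.5), site_scale = 1,
                    beta_age = 0, beta_sex = 0, noise_sd = 1, seed = 53)
  coh <- make_cohort(cfg, meta)
  m_cbi <- fit_combat(coh$table, eb = FALSE)
  m_cbe <- fit_combat(coh$table, eb = TRUE)
  # planted gamma on the standardized scale: site shift / residual scale
  truth_z <- sweep(coh$truth$gamma - colMeans(coh$truth$gamma),
                   2, sqrt(m_cbi$sigma2), "/")
  rmse <- function(est) sqrt(mean((est - truth_z)^2))
  expect_lt(rmse(m_cbe$gamma_star), rmse(m_cbi$gamma_star))
})

test_that("harmonize strategies behave as an identity / CBI / ordered CBE", {
  tbl <- random_feature_table(n = 40, g = 12, n_sites = 2, seed = 61,
                              groups = c("DAT:Vis", "DAT:Default"))
  expect_identical(harmonize(tbl, "none"), tbl)
  adj <- harmonize(tbl, "cbe")
  expect_identical(feature_meta(adj)$name, feature_meta(tbl)$name)
  expect_identical(covariates_of(adj), covariates_of(tbl))
  # column order invariance: permuting features and adjusting gives the same
  # values per feature
  perm <- rev(feature_meta(tbl)$name)
  tblp <- select_features(tbl, perm)
  adjp <- harmonize(tblp, "cbe")
  expect_equal(feature_matrix(adjp)[, perm], feature_matrix(adj)[, perm],
               tolerance = 1e-10)
  # unseen batch level on apply is an error
  m <- attr(adj, "combat_model")
  tbl_bad <- tbl
  tbl_bad$site[1] <- "siteX"
  expect_error(apply_combat(m, tbl_bad), "unseen batch")
})
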