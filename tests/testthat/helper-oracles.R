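# Independent oracles, deliberately coded along different paths than the
# package (pseudo-inverse / normal equations instead of QR; explicit
# per-feature lm() loops instead of vectorized multi-response fits).

# Moore-Penrose pseudo-inverse least squares: coef = pinv(X) %*% Y
oracle_ols <- function(X, Y) {
  MASS::ginv(X) %*% Y
}

# ComBat standardization + EB conditional estimates, one subgroup at a time,
# feature-by-feature lm() fits and explicit iteration loops.
oracle_combat_eb <- function(x, batch, age = NULL, sex = NULL,
                             eb = TRUE, conv = 1e-4, maxit = 100L) {
  batch <- factor(batch)
  n <- nrow(x)
  g_n <- ncol(x)
  lv <- levels(batch)
  n_b <- length(lv)
  n_i <- as.numeric(table(batch))
  z <- matrix(0, n, g_n)
  sig2 <- numeric(g_n)
  for (g in seq_len(g_n)) {
    if (is.null(age)) {
      fit <- lm(x[, g] ~ 0 + batch)
      cov_part <- 0
    } else {
      fit <- lm(x[, g] ~ 0 + batch + age + sex)
      cov_part <- coef(fit)["age"] * age + coef(fit)["sex"] * sex
    }
    alpha <- sum(n_i / n * coef(fit)[seq_len(n_b)])
    sig2[g] <- mean((x[, g] - fitted(fit))^2)
    z[, g] <- (x[, g] - alpha - cov_part) / sqrt(sig2[g])
  }
  gamma_hat <- matrix(0, n_b, g_n)
  delta_hat <- matrix(0, n_b, g_n)
  for (i in seq_len(n_b)) {
    for (g in seq_len(g_n)) {
      zi <- z[batch == lv[i], g]
      gamma_hat[i, g] <- mean(zi)
      delta_hat[i, g] <- var(zi)
    }
  }
  gamma_star <- gamma_hat
  delta_star <- delta_hat
  iters <- integer(n_b)
  if (eb) {
    for (i in seq_len(n_b)) {
      g_bar <- mean(gamma_hat[i, ])
      t2 <- var(gamma_hat[i, ])
      m <- mean(delta_hat[i, ])
      s2 <- var(delta_hat[i, ])
      a_pr <- (2 * s2 + m^2) / s2
      b_pr <- (m * s2 + m^3) / s2
      zi <- z[batch == lv[i], , drop = FALSE]
      ni <- nrow(zi)
      g_old <- gamma_hat[i, ]
      d_old <- delta_hat[i, ]
      it <- 0L
      repeat {
        it <- it + 1L
        g_new <- numeric(g_n)
        d_new <- numeric(g_n)
        for (g in seq_len(g_n)) {
          g_new[g] <- (t2 * ni * gamma_hat[i, g] + d_old[g] * g_bar) / (t2 * ni + d_old[g])
          d_new[g] <- (0.5 * sum((zi[, g] - g_new[g])^2) + b_pr) / (ni / 2 + a_pr - 1)
        }
        change <- max(abs(g_new - g_old) / g_old, abs(d_new - d_old) / d_old)
        g_old <- g_new
        d_old <- d_new
        if (change < conv || it >= maxit) break
      }
      gamma_star[i, ] <- g_new
      delta_star[i, ] <- d_new
      iters[i] <- it
    }
  }
  list(gamma_hat = gamma_hat, delta_hat = delta_hat,
       gamma_star = gamma_star, delta_star = delta_star,
       z = z, sigma2 = sig2, levels = lv, iterations = iters)
}

# Brute-force Tukey inner fences with type-7 quantiles, scalar loops.
oracle_tukey <- function(v) {
  q1 <- as.numeric(quantile(v, 0.25, type = 7))
  q3 <- as.numeric(quantile(v, 0.75, type = 7))
  iqr <- q3 - q1
  flags <- logical(length(v))
  for (i in seq_along(v)) {
    flags[i] <- v[i] < q1 - 1.5 * iqr || v[i] > q3 + 1.5 * iqr
  }
  flags
}

# Small random feature table for harmonization tests.
random_feature_table <- function(n = 60, g = 20, n_sites = 2, seed = 1,
                                 groups = "all") {
  withr::with_seed(seed, {
    age <- runif(n, 20, 80)
    sex <- rbinom(n, 1, 0.5)
    site <- sort(rep_len(paste0("site", seq_len(n_sites)), n))
    x <- matrix(rnorm(n * g), n, g) +
      outer(age, runif(g, 0, 0.2)) +
      outer(match(site, unique(site)), runif(g, -1, 1))
  })
  colnames(x) <- sprintf("f%03d", seq_len(g))
  meta <- tibble::tibble(name = colnames(x), block = "DAT",
                         group = rep_len(groups, g))
  covs <- tibble::tibble(subject_id = sprintf("s%03d", seq_len(n)),
                         age = age, sex = sex, site = site)
  feature_table(x, meta, covs)
}

# A prediction_set built by hand, for metric identity checks.
manual_prediction_set <- function(y, yhat, repeat_id = 1L, fold = 1L) {
  out <- tibble::tibble(
    repeat_id = repeat_id, fold = fold,
    subject_id = sprintf("s%03d", seq_along(y)),
    age = y, predicted = yhat, C = 1, gamma = 0.1, epsilon = 0.1
  )
  class(out) <- c("prediction_set", class(tibble::tibble()))
  out
}
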