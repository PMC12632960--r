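#' Simulation configuration for the synthetic study
#'
#' Collects every knob of the synthetic-data generators: the voxel grid, the
#' number of transporter targets K and time points T, the cohort layout
#' (per-site sample counts, age range), the planted effects (per-feature age
#' slope in feature units per year, sex offset, per-site location shift gamma
#' and scale factor delta), the residual noise level, and the seed.
#'
#' The per-site batch effects follow the ComBat generative model exactly:
#' `x = alpha + beta_age*age + beta_sex*sex + gamma_site + delta_site*eps`,
#' so harmonization parameter recovery is well-posed. `site_shift` and
#' `site_scale` may be scalars (same for every site and feature), vectors of
#' length `n_sites` (per site, shared across features), or `n_sites x
#' n_features` matrices.
#'
#' @param grid_shape integer(3), voxel grid dimensions.
#' @param n_targets number of molecular templates K.
#' @param n_timepoints BOLD frames T.
#' @param n_subjects total cohort size (must equal `sum(sites)`).
#' @param sites named integer vector of per-site sample counts.
#' @param age_range numeric(2), years; ages are uniform on this interval.
#' @param beta_age per-feature age slope (recycled across features).
#' @param beta_sex per-feature sex offset (recycled).
#' @param site_shift per-site location effect gamma (see Details).
#' @param site_scale per-site positive scale effect delta.
#' @param noise_sd residual standard deviation (>= 0).
#' @param seed integer seed; the same seed reproduces every generated artifact
#'   bit for bit.
#' @return a `sim_config` list.
#' @export
sim_config <- function(grid_shape = c(12L, 12L, 12L),
                       n_targets = 3L,
                       n_timepoints = 200L,
                       n_subjects = 200L,
                       sites = c(siteA = 100L, siteB = 100L),
                       age_range = c(18, 90),
                       beta_age = 0.5,
                       beta_sex = 1,
                       site_shift = NULL,
                       site_scale = NULL,
                       noise_sd = 1,
                       seed = 1L) {
  if (length(grid_shape) != 3L || any(grid_shape < 1)) abort("grid_shape must be 3 positive integers")
  if (n_targets < 1 || n_timepoints < 1 || n_subjects < 1) abort("all counts must be >= 1")
  if (is.null(names(sites)) || any(sites < 1)) abort("sites must be a named vector of positive counts")
  if (sum(sites) != n_subjects) abort("sum(sites) must equal n_subjects")
  if (age_range[1] >= age_range[2]) abort("age_range must satisfy min < max")
  if (noise_sd < 0) abort("noise_sd must be non-negative")
  n_sites <- length(sites)
  # default multi-site effects: symmetric location shifts of +/-1 unit and
  # scale factors spread around 1, the regime the harmonization stage targets
  if (is.null(site_shift)) {
    site_shift <- (seq_len(n_sites) - (n_sites + 1) / 2) * 2
  }
  if (is.null(site_scale)) {
    site_scale <- seq(1, 1.5, length.out = n_sites)
  }
  if (any(site_scale <= 0)) abort("site_scale must be > 0")
  structure(list(
    grid_shape = as.integer(grid_shape), n_targets = as.integer(n_targets),
    n_timepoints = as.integer(n_timepoints), n_subjects = as.integer(n_subjects),
    sites = sites, age_range = as.numeric(age_range),
    beta_age = beta_age, beta_sex = beta_sex,
    site_shift = site_shift, site_scale = site_scale,
    noise_sd = noise_sd, seed = as.integer(seed)
  ), class = "sim_config")
}

default_target_names <- function(k) {
  base <- c("DAT", "NET", "SERT")
  if (k <= 3L) base[seq_len(k)] else c(base, paste0("TGT", seq_len(k - 3L)))
}

#' Generate smooth, spatially distinct receptor-density templates
#'
#' Builds K non-negative 3D maps as sums of Gaussian blobs at random centers,
#' then min-max rescales each to \[0, 1\] within the mask. Templates are
#' resampled until every pairwise voxel-wise Pearson correlation is at most
#' 0.5, keeping spatial collinearity among the molecular maps low (joint
#' regression on strongly collinear templates is unstable).
#'
#' @param cfg a [sim_config()].
#' @param max_tries resampling attempts before giving up.
#' @return a `receptor_templates` object: `values` (full-grid voxels x K
#'   matrix, zero outside the mask), `target_names`, `mask` (logical 3D
#'   array), `dim`.
#' @export
make_templates <- function(cfg, max_tries = 200L) {
  stopifnot(inherits(cfg, "sim_config"))
  dm <- cfg$grid_shape
  v <- prod(dm)
  k <- cfg$n_targets
  if (k > max(1L, v %/% 8L)) abort("n_targets too large for this grid: too few voxels to build distinct patterns")
  mask <- array(TRUE, dm)
  coords <- as.matrix(expand.grid(x = seq_len(dm[1]), y = seq_len(dm[2]), z = seq_len(dm[3])))
  sigma <- mean(dm) / 5
  withr::with_seed(cfg$seed, {
    one_map <- function() {
      centers <- coords[sample.int(v, 3L), , drop = FALSE]
      m <- rep(0, v)
      for (i in seq_len(nrow(centers))) {
        d2 <- rowSums(sweep(coords, 2, centers[i, ])^2)
        m <- m + exp(-d2 / (2 * sigma^2))
      }
      m
    }
    vals <- matrix(0, v, k)
    vals[, 1] <- one_map()
    if (k > 1) {
      for (j in 2:k) {
        ok <- FALSE
        for (try in seq_len(max_tries)) {
          cand <- one_map()
          if (max(abs(cor(cand, vals[, 1:(j - 1), drop = FALSE]))) <= 0.5) {
            vals[, j] <- cand
            ok <- TRUE
            break
          }
        }
        if (!ok) abort("could not draw enough spatially distinct templates on this grid")
      }
    }
  })
  for (j in seq_len(k)) {
    vals[, j] <- (vals[, j] - min(vals[, j])) / (max(vals[, j]) - min(vals[, j]))
  }
  structure(list(
    values = vals, target_names = default_target_names(k),
    mask = mask, dim = dm
  ), class = "receptor_templates")
}

#' Default atlas composition: 247 ROIs in nine parcel-set groups
#'
#' Mirrors the composite parcellation used for the enriched connectivity
#' maps: 200 cortical parcels split over the seven canonical resting-state
#' networks, 15 subcortical regions, and 32 cerebellar regions.
#'
#' @return tibble with columns `group`, `n_parcels`.
#' @export
default_atlas_composition <- function() {
  tibble(
    group = c("Vis", "SomMot", "DorsAttn", "SalVentAttn", "Limbic", "Cont",
              "Default", "subcortical", "cerebellar"),
    n_parcels = c(31L, 29L, 29L, 28L, 27L, 28L, 28L, 15L, 32L)
  )
}

#' Generate a parcellation atlas on the simulation grid
#'
#' Partitions the in-mask voxels into contiguous runs of near-equal size, one
#' per parcel, labelled 1..R in composition order. Group metadata records the
#' parcel-set membership (network / subcortical / cerebellar) used for
#' subgroup-wise harmonization.
#'
#' @param cfg a [sim_config()].
#' @param composition tibble with columns `group`, `n_parcels`; defaults to
#'   [default_atlas_composition()] (247 parcels).
#' @return a `parcellation_atlas`: `labels` (integer 3D array, 0 =
#'   background), `roi_info` tibble (`roi_id`, `roi_name`, `roi_group`),
#'   `dim`.
#' @export
make_atlas <- function(cfg, composition = default_atlas_composition()) {
  stopifnot(inherits(cfg, "sim_config"))
  composition <- as_tibble(composition)
  r_total <- sum(composition$n_parcels)
  v <- prod(cfg$grid_shape)
  if (r_total > v) abort("more parcels than voxels in the mask")
  sizes <- rep(v %/% r_total, r_total)
  extra <- v - sum(sizes)
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  labels <- rep.int(seq_len(r_total), sizes)
  lab_img <- array(labels, cfg$grid_shape)
  roi_group <- rep(composition$group, composition$n_parcels)
  roi_name <- unlist(lapply(seq_len(nrow(composition)), function(i) {
    sprintf("%s_%03d", composition$group[i], seq_len(composition$n_parcels[i]))
  }))
  if (any(tabulate(lab_img, r_total) == 0L)) abort("empty parcel after assignment")
  structure(list(
    labels = lab_img,
    roi_info = tibble(roi_id = seq_len(r_total), roi_name = roi_name, roi_group = roi_group),
    dim = cfg$grid_shape
  ), class = "parcellation_atlas")
}

#' Generate smooth per-target weight time series
#'
#' Convenience ground-truth generator: K independent AR(1) series (lag-one
#' correlation 0.6, unit marginal variance), T frames each.
#'
#' @param cfg a [sim_config()].
#' @return numeric matrix T x K.
#' @export
make_weight_timeseries <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  t_n <- cfg$n_timepoints
  k <- cfg$n_targets
  phi <- 0.6
  withr::with_seed(cfg$seed + 11L, {
    ts <- matrix(0, t_n, k)
    innov <- matrix(rnorm(t_n * k, sd = sqrt(1 - phi^2)), t_n, k)
    ts[1, ] <- rnorm(k)
    for (t in 2:t_n) ts[t, ] <- phi * ts[t - 1, ] + innov[t, ]
    ts
  })
}

#' Generate a BOLD run containing planted template-weighted signal
#'
#' Simulates `Y[t, v] = sum_k truth_ts[t, k] * Z[v, k] + eps` with i.i.d.
#' Gaussian noise of standard deviation `noise_sd`, where Z is the template
#' matrix standardized (zero mean, unit variance) within the stage-1
#' intersection mask — the same standardization the dual-regression stage
#' applies, so with `noise_sd = 0` the planted time series and maps are
#' recovered exactly.
#'
#' @param cfg a [sim_config()].
#' @param templates a `receptor_templates` object.
#' @param truth_ts numeric T x K matrix of planted weight time series.
#' @return a `bold_run` with attribute `ground_truth`: list with `Z`
#'   (standardized template maps over the full grid), `truth_ts`, and the
#'   stage-1 mask used for standardization.
#' @export
make_bold_run <- function(cfg, templates, truth_ts) {
  stopifnot(inherits(cfg, "sim_config"), inherits(templates, "receptor_templates"))
  truth_ts <- as.matrix(truth_ts)
  if (nrow(truth_ts) != cfg$n_timepoints || ncol(truth_ts) != cfg$n_targets) {
    abort("truth_ts must be T x K per the config")
  }
  if (cfg$noise_sd < 0) abort("noise_sd must be non-negative")
  masks <- build_stage_masks(templates, templates$mask)
  m1 <- which(masks$stage1_joint)
  mu <- colMeans(templates$values[m1, , drop = FALSE])
  sg <- apply(templates$values[m1, , drop = FALSE], 2, sd)
  z_full <- sweep(sweep(templates$values, 2, mu), 2, sg, "/")
  z_full[!templates$mask, ] <- 0
  y <- truth_ts %*% t(z_full)
  if (cfg$noise_sd > 0) {
    withr::with_seed(cfg$seed + 23L, {
      y <- y + matrix(rnorm(length(y), sd = cfg$noise_sd), nrow(y), ncol(y))
    })
  }
  y[, !templates$mask] <- 0
  run <- structure(list(
    values = y, repetition_time = 2, mask = templates$mask, dim = templates$dim
  ), class = "bold_run")
  attr(run, "ground_truth") <- list(Z = z_full, truth_ts = truth_ts, stage1_mask = masks$stage1_joint)
  run
}

expand_site_effect <- function(x, n_sites, n_feat, what) {
  if (is.matrix(x)) {
    if (!all(dim(x) == c(n_sites, n_feat))) abort(paste0(what, " matrix must be n_sites x n_features"))
    return(x)
  }
  if (length(x) == 1L) return(matrix(x, n_sites, n_feat))
  if (length(x) == n_sites) return(matrix(x, n_sites, n_feat))
  abort(paste0(what, " must be scalar, per-site vector, or site x feature matrix"))
}

#' Generate a multi-site cohort feature table with known ground truth
#'
#' Draws ages uniformly on `age_range`, sex as Bernoulli(0.5), assigns
#' subjects to sites per `cfg$sites`, and generates every feature from the
#' ComBat generative model:
#' `x = alpha_g + beta_age_g*age + beta_sex_g*sex + gamma_(site,g) +
#' delta_(site,g) * eps`, with `eps ~ N(0, noise_sd^2)`.
#'
#' @param cfg a [sim_config()].
#' @param feature_meta tibble with columns `name`, `block`, `group` defining
#'   the feature columns and their harmonization subgroups.
#' @return list with `table` (a [feature_table()]) and `truth` (per-feature
#'   intercepts and slopes, per-site gamma/delta matrices, and the covariate
#'   draws).
#' @export
make_cohort <- function(cfg, feature_meta) {
  stopifnot(inherits(cfg, "sim_config"))
  feature_meta <- as_tibble(feature_meta)
  if (any(cfg$sites < 3L)) abort("every site needs at least 3 subjects (harmonization would be degenerate)")
  g <- nrow(feature_meta)
  n <- cfg$n_subjects
  n_sites <- length(cfg$sites)
  beta_age <- rep_len(cfg$beta_age, g)
  beta_sex <- rep_len(cfg$beta_sex, g)
  gamma <- expand_site_effect(cfg$site_shift, n_sites, g, "site_shift")
  delta <- expand_site_effect(cfg$site_scale, n_sites, g, "site_scale")
  site <- rep(names(cfg$sites), cfg$sites)
  site_idx <- match(site, names(cfg$sites))
  withr::with_seed(cfg$seed + 37L, {
    age <- runif(n, cfg$age_range[1], cfg$age_range[2])
    sex <- rbinom(n, 1L, 0.5)
    alpha <- rnorm(g, 0, 1)
    eps <- matrix(rnorm(n * g, sd = cfg$noise_sd), n, g)
  })
  x <- matrix(alpha, n, g, byrow = TRUE) +
    outer(age, beta_age) + outer(as.numeric(sex), beta_sex) +
    gamma[site_idx, , drop = FALSE] +
    delta[site_idx, , drop = FALSE] * eps
  colnames(x) <- feature_meta$name
  covs <- tibble(
    subject_id = sprintf("sub-%04d", seq_len(n)),
    age = age, sex = sex, site = site
  )
  tbl <- feature_table(x, feature_meta, covs)
  truth <- list(
    alpha = setNames(alpha, feature_meta$name),
    beta_age = setNames(beta_age, feature_meta$name),
    beta_sex = setNames(beta_sex, feature_meta$name),
    gamma = structure(gamma, dimnames = list(names(cfg$sites), feature_meta$name)),
    delta = structure(delta, dimnames = list(names(cfg$sites), feature_meta$name)),
    age = age, sex = sex, site = site
  )
  list(table = tbl, truth = truth)
}

#' Feature metadata for the structural morphometry block (649 features)
#'
#' The composition mirrors a standard FreeSurfer-derived feature set:
#' 85 subcortical/global volumetric indices (`aseg.stats`), 8 surface metrics
#' for each of 31 cortical regions per hemisphere (`lh.aparc.stats`,
#' `rh.aparc.stats`; 496 features), and 68 regional white-matter volumes
#' (`wmparc.stats`). The `group` key encodes "same .stats file, same nature"
#' — the subgroup definition used for EB harmonization of structural
#' features (18 distinct subgroups).
#'
#' @return tibble with columns `name`, `block`, `group`, `stats_file`,
#'   `nature`.
#' @export
structural_feature_meta <- function() {
  natures <- c("volume", "area", "thickness", "thickness_sd",
               "folding_index", "mean_curvature", "gaussian_curvature", "curvature_index")
  aseg <- tibble(
    name = sprintf("aseg_vol_%03d", 1:85),
    stats_file = "aseg.stats", nature = "volume"
  )
  cort <- tidyr::expand_grid(hemi = c("lh", "rh"), region = sprintf("ctx_%02d", 1:31), nature = natures)
  cort <- tibble(
    name = paste(cort$hemi, cort$region, cort$nature, sep = "_"),
    stats_file = paste0(cort$hemi, ".aparc.stats"), nature = cort$nature
  )
  wm <- tibble(
    name = sprintf("wm_vol_%03d", 1:68),
    stats_file = "wmparc.stats", nature = "volume"
  )
  out <- dplyr::bind_rows(aseg, cort, wm)
  out$block <- "SMF"
  out$group <- paste(out$stats_file, out$nature, sep = "|")
  out[, c("name", "block", "group", "stats_file", "nature")]
}

nature_scales <- function() {
  c(volume = 500, area = 300, thickness = 0.25, thickness_sd = 0.1,
    folding_index = 5, mean_curvature = 0.03, gaussian_curvature = 0.02,
    curvature_index = 1)
}

nature_baselines <- function() {
  c(volume = 4000, area = 2500, thickness = 2.5, thickness_sd = 0.5,
    folding_index = 20, mean_curvature = 0.13, gaussian_curvature = 0.15,
    curvature_index = 5)
}

#' Generate the structural morphometry fixture block
#'
#' Draws Gaussian features at nature-appropriate scales for the 649-column
#' composition of [structural_feature_meta()], optionally with a linear age
#' effect. Covariates are taken from `covariates` when supplied (so the block
#' can be concatenated with a functional cohort), otherwise generated.
#'
#' @param n_subjects number of subjects.
#' @param seed integer seed.
#' @param covariates optional covariate tibble (`subject_id`, `age`, `sex`,
#'   `site`).
#' @param beta_age age slope applied to every structural feature, in units of
#'   the feature's nature scale per year (default 0).
#' @return a `feature_tbl` with 649 feature columns.
#' @export
make_structural_block <- function(n_subjects, seed = 1L, covariates = NULL, beta_age = 0) {
  meta <- structural_feature_meta()
  g <- nrow(meta)
  withr::with_seed(as.integer(seed) + 51L, {
    if (is.null(covariates)) {
      covariates <- tibble(
        subject_id = sprintf("sub-%04d", seq_len(n_subjects)),
        age = runif(n_subjects, 18, 90),
        sex = rbinom(n_subjects, 1L, 0.5),
        site = "siteA"
      )
    }
    sc <- nature_scales()[meta$nature]
    base <- nature_baselines()[meta$nature]
    x <- matrix(base, n_subjects, g, byrow = TRUE) +
      outer(covariates$age, rep_len(beta_age, g) * sc) +
      matrix(rnorm(n_subjects * g), n_subjects, g) * matrix(sc, n_subjects, g, byrow = TRUE)
  })
  colnames(x) <- meta$name
  feature_table(x, meta[, c("name", "block", "group")], covariates)
}

#' Generate an image-quality-metric table with planted outliers
#'
#' Six IQM columns (anatomical SNR, gray-white CNR, entropy-focus criterion,
#' temporal SNR, mean framewise displacement, DVARS). Background values are
#' drawn from a normal distribution truncated at +/- 2 SD, which lies
#' strictly inside the inner Tukey fences, so the rule's false-positive rate
#' is zero by construction and planted-outlier recovery is exact. For each of
#' `n_outliers` randomly chosen subjects, one randomly chosen metric is
#' displaced 6.5 column standard deviations from the column mean — far
#' beyond the fences — and the planted rows are recorded in the `outliers`
#' attribute.
#'
#' @param n_subjects number of subjects.
#' @param n_outliers number of planted outlier subjects (< `n_subjects`).
#' @param seed integer seed.
#' @return tibble with `subject_id` and six metric columns; attribute
#'   `outliers` is a tibble of the planted (`subject_id`, `metric`) pairs.
#' @export
make_iqm_table <- function(n_subjects, n_outliers = 0L, seed = 1L) {
  if (n_outliers >= n_subjects) abort("n_outliers must be < n_subjects")
  metrics <- c(snr = 12, cnr = 3.2, efc = 0.45, tsnr = 50, fd_mean = 0.15, dvars = 1.2)
  sds <- c(snr = 2, cnr = 0.5, efc = 0.05, tsnr = 8, fd_mean = 0.05, dvars = 0.2)
  withr::with_seed(as.integer(seed) + 67L, {
    rtruncnorm2 <- function(n, mean, sd) {
      p <- runif(n, stats::pnorm(-2), stats::pnorm(2))
      mean + sd * stats::qnorm(p)
    }
    x <- sapply(names(metrics), function(m) rtruncnorm2(n_subjects, metrics[m], sds[m]))
    rows <- if (n_outliers > 0) sample.int(n_subjects, n_outliers) else integer(0)
    planted <- tibble(subject_id = character(0), metric = character(0))
    for (r in rows) {
      m <- sample(names(metrics), 1L)
      sign <- sample(c(-1, 1), 1L)
      x[r, m] <- metrics[m] + sign * 6.5 * sds[m]
      planted <- dplyr::bind_rows(planted, tibble(
        subject_id = sprintf("sub-%04d", r), metric = m
      ))
    }
  })
  out <- dplyr::bind_cols(
    tibble(subject_id = sprintf("sub-%04d", seq_len(n_subjects))),
    as_tibble(x)
  )
  attr(out, "outliers") <- planted
  out
}
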