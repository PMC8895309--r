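## default per-tract, per-hemisphere metric parameters.  Means and SDs are
## typical pediatric DTI values (FA unitless; diffusivities in mm^2/s);
## age loadings are the target metric-age Pearson correlations, strongest
## (negative) for radial diffusivity of the late-maturing tracts and near
## zero for the early-maturing fornix diffusivities.
.default_metric_params <- function() {
  g <- expand.grid(metric = METRICS, hemisphere = HEMISPHERES,
                   tract = TRACTS, stringsAsFactors = FALSE)[, 3:1]
  g$mean <- c(fa = 0.42, rd = 6.0e-4, ad = 1.25e-3)[g$metric]
  g$mean[g$tract == "fornix"] <-
    c(fa = 0.35, rd = 7.0e-4, ad = 1.30e-3)[g$metric[g$tract == "fornix"]]
  g$sd <- c(fa = 0.03, rd = 4e-5, ad = 6e-5)[g$metric]
  loadings <- c(
    uncinate_fasciculus = c(fa = 0.24, rd = -0.46, ad = -0.32,
                            fa = 0.35, rd = -0.61, ad = -0.34),
    dorsal_cingulum     = c(fa = 0.36, rd = -0.61, ad = -0.30,
                            fa = 0.33, rd = -0.56, ad = -0.38),
    ventral_cingulum    = c(fa = 0.16, rd = -0.31, ad = -0.09,
                            fa = 0.14, rd = -0.29, ad = -0.11),
    fornix              = c(fa = 0.44, rd = -0.27, ad = 0.06,
                            fa = 0.28, rd = -0.21, ad = 0.02)
  )
  g$age_loading <- unname(loadings)
  g
}

#' Configuration of the synthetic cohort generator
#'
#' Describes the generative model of a developmental cohort: ages drawn
#' uniformly on \code{age_range}; one latent "maturation" factor per tract
#' that correlates \code{maturation_age_cor} with age; each diffusion
#' metric loading on its tract's factor so that its population correlation
#' with age equals the configured \code{age_loading}; recall scores linear
#' in age (population R-squared \code{em_age_r2}) plus a configurable
#' coupling to the age-orthogonal part of a tract's maturation factor -
#' the structure that makes tract maturity informative about memory
#' beyond age alone.
#'
#' Defaults emulate the target study conditions: 37 children aged 4-12
#' (uniform ages give mean 8 and SD 2.31), recall-on-age R-squared of
#' 0.251/0.239/0.35, Table-2-like metric-age correlations (radial
#' diffusivity down to -0.61), a latent factor coupling the uncinate to
#' the delayed-recall scores and the dorsal cingulum to short-delay free
#' recall, and one subject whose uncinate and fornix reconstructions
#' failed.
#'
#' @param n_subjects Number of subjects (at least 10).
#' @param age_range Numeric length-2, years.
#' @param seed Default root seed used by \code{\link{generate_cohort}}.
#' @param metric_params data.frame with columns \code{tract, hemisphere,
#'   metric, mean, sd, age_loading}.
#' @param maturation_age_cor Named vector: correlation of each tract's
#'   maturation factor with age, in (0, 1); must exceed the largest
#'   absolute age loading of the tract's metrics.
#' @param em_age_r2 Named vector (sdfr, ldfr, ldcr): population R-squared
#'   of each recall score on age.
#' @param em_mean,em_sd Location and scale of the recall scores on the
#'   0-15 task scale.
#' @param em_tract_coupling data.frame \code{tract, score, strength}:
#'   loading of each recall score on the age-orthogonal maturation
#'   residual of a tract.
#' @param discrimination Logical: generate a memory-discrimination score
#'   (standardized scale, weak age dependence, no tract coupling - the
#'   specificity control).
#' @param discrimination_age_r2 Population R-squared of the discrimination
#'   score on age.
#' @param discrete_scores Logical: round and clip recall scores to integer
#'   0-15.  Off by default because rounding distorts the calibrated
#'   R-squared targets at small n.
#' @param failed_tracts Tracts affected by reconstruction failure.
#' @param n_failures Number of subjects whose \code{failed_tracts} rows
#'   are dropped from the metrics table.
#' @return A list of class \code{"sim_config"}.
#' @export
sim_config <- function(n_subjects = 37L,
                       age_range = c(4, 12),
                       seed = 1L,
                       metric_params = .default_metric_params(),
                       maturation_age_cor = c(uncinate_fasciculus = 0.75,
                                              dorsal_cingulum = 0.75,
                                              ventral_cingulum = 0.75,
                                              fornix = 0.75),
                       em_age_r2 = c(sdfr = 0.251, ldfr = 0.239,
                                     ldcr = 0.35),
                       em_mean = c(sdfr = 7.5, ldfr = 7.5, ldcr = 8.5),
                       em_sd = c(sdfr = 2.2, ldfr = 2.2, ldcr = 2.2),
                       em_tract_coupling = data.frame(
                         tract = c("uncinate_fasciculus",
                                   "uncinate_fasciculus",
                                   "dorsal_cingulum"),
                         score = c("ldfr", "ldcr", "sdfr"),
                         strength = c(0.22, 0.07, 0.13),
                         stringsAsFactors = FALSE),
                       discrimination = TRUE,
                       discrimination_age_r2 = 0.1,
                       discrete_scores = FALSE,
                       failed_tracts = c("uncinate_fasciculus", "fornix"),
                       n_failures = 1L) {
  n_subjects <- as.integer(n_subjects)
  if (n_subjects < 10L)
    stop("config error: n_subjects must be at least 10", call. = FALSE)
  if (length(age_range) != 2L || diff(age_range) <= 0 || age_range[1] <= 0)
    stop("config error: invalid age_range", call. = FALSE)
  .require_columns(metric_params,
                   c("tract", "hemisphere", "metric", "mean", "sd",
                     "age_loading"), "metric_params")
  if (any(metric_params$sd <= 0))
    stop("config error: metric SDs must be positive", call. = FALSE)
  if (any(abs(metric_params$age_loading) >= 1))
    stop("config error: age loadings must lie in (-1, 1)", call. = FALSE)
  if (any(maturation_age_cor <= 0 | maturation_age_cor >= 1))
    stop("config error: maturation_age_cor must lie in (0, 1)",
         call. = FALSE)
  if (any(em_age_r2 < 0 | em_age_r2 >= 1))
    stop("config error: em_age_r2 must lie in [0, 1)", call. = FALSE)
  if (any(em_sd <= 0)) stop("config error: em_sd must be positive",
                            call. = FALSE)
  ## calibration feasibility: metric factor weight is age_loading divided
  ## by the tract's maturation-age correlation and must leave positive
  ## residual variance
  for (i in seq_len(nrow(metric_params))) {
    tr <- metric_params$tract[i]
    alpha <- maturation_age_cor[[tr]]
    w <- metric_params$age_loading[i] / alpha
    if (1 - w^2 <= 0)
      stop("config error: unsatisfiable calibration for ", tr, " ",
           metric_params$hemisphere[i], " ", metric_params$metric[i],
           " (|age_loading| must be below maturation_age_cor)",
           call. = FALSE)
  }
  for (sc in EM_SCORES) {
    c2 <- sum(em_tract_coupling$strength[em_tract_coupling$score == sc]^2)
    if (1 - em_age_r2[[sc]] - c2 <= 0)
      stop("config error: unsatisfiable calibration for score ", sc,
           " (em_age_r2 + squared couplings must stay below 1)",
           call. = FALSE)
  }
  structure(
    list(n_subjects = n_subjects, age_range = as.numeric(age_range),
         seed = as.integer(seed), metric_params = metric_params,
         maturation_age_cor = maturation_age_cor, em_age_r2 = em_age_r2,
         em_mean = em_mean, em_sd = em_sd,
         em_tract_coupling = em_tract_coupling,
         discrimination = isTRUE(discrimination),
         discrimination_age_r2 = discrimination_age_r2,
         discrete_scores = isTRUE(discrete_scores),
         failed_tracts = failed_tracts,
         n_failures = as.integer(n_failures)),
    class = "sim_config"
  )
}

#' Generate a synthetic cohort with known ground truth
#'
#' Draws a cohort and tract-metrics table from the generative model of a
#' \code{\link{sim_config}}.  Standardized age is computed against the
#' population moments of the uniform age distribution, so configured
#' correlations are population values; sample correlations fluctuate with
#' n as they would in a real study.
#'
#' Randomness uses one root seed and five child streams in a fixed,
#' documented order: (1) ages and sex, (2) tract maturation residuals,
#' (3) metric noise, (4) memory-score noise, (5) reconstruction failures.
#' Identical (config, seed) gives byte-identical output.
#'
#' @param config A \code{\link{sim_config}}.
#' @param seed Optional root seed overriding \code{config$seed}.
#' @return A list with elements \code{cohort} (a \code{"cohort"}
#'   data.frame), \code{metrics} (a \code{"tract_metrics"} data.frame) and
#'   \code{truth} (a \code{"sim_truth"} list recording every generative
#'   parameter plus realized sample correlations).
#' @examples
#' sim <- generate_cohort(sim_config(seed = 7))
#' head(sim$cohort)
#' sim$truth$realized$em_age_r2
#' @export
generate_cohort <- function(config = sim_config(), seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  root <- if (is.null(seed)) config$seed else as.integer(seed)
  set.seed(root)
  block_seeds <- sample.int(2147483646L, 5L)

  n <- config$n_subjects
  ids <- sprintf("S%0*d", max(3L, nchar(n)), seq_len(n))

  ## block 1: ages (uniform) and sex
  set.seed(block_seeds[1])
  age <- stats::runif(n, config$age_range[1], config$age_range[2])
  sex <- sample(c("F", "M"), n, replace = TRUE)
  mu_age <- mean(config$age_range)
  sd_age <- diff(config$age_range) / sqrt(12)
  z <- (age - mu_age) / sd_age

  ## block 2: age-orthogonal maturation residuals u_t, one per tract;
  ## maturation factor f_t = alpha * z + sqrt(1 - alpha^2) * u_t
  set.seed(block_seeds[2])
  U <- matrix(stats::rnorm(n * length(TRACTS)), n,
              dimnames = list(NULL, TRACTS))
  alpha <- config$maturation_age_cor[TRACTS]
  FT <- sweep(U, 2L, sqrt(1 - alpha^2), "*") +
    outer(z, alpha)

  ## block 3: metrics; standardized metric = (lambda/alpha) f_t + noise
  set.seed(block_seeds[3])
  mp <- config$metric_params
  metrics_long <- mp[rep(seq_len(nrow(mp)), each = n),
                     c("tract", "hemisphere", "metric")]
  metrics_long$subject_id <- rep(ids, nrow(mp))
  value <- numeric(n * nrow(mp))
  weight <- numeric(nrow(mp))
  for (i in seq_len(nrow(mp))) {
    tr <- mp$tract[i]
    w <- mp$age_loading[i] / alpha[[tr]]
    weight[i] <- w
    std <- w * FT[, tr] + sqrt(1 - w^2) * stats::rnorm(n)
    value[(i - 1) * n + seq_len(n)] <- mp$mean[i] + mp$sd[i] * std
  }
  metrics_long$value <- value
  wide <- stats::reshape(
    metrics_long, idvar = c("subject_id", "tract", "hemisphere"),
    timevar = "metric", direction = "wide")
  names(wide) <- sub("^value\\.", "", names(wide))
  wide <- wide[, c("subject_id", "tract", "hemisphere", METRICS)]
  rownames(wide) <- NULL

  ## block 4: memory scores
  set.seed(block_seeds[4])
  beta <- sqrt(config$em_age_r2[EM_SCORES])
  em <- matrix(NA_real_, n, length(EM_SCORES),
               dimnames = list(NULL, EM_SCORES))
  for (sc in EM_SCORES) {
    cp <- config$em_tract_coupling[config$em_tract_coupling$score == sc, ,
                                   drop = FALSE]
    coupled <- if (nrow(cp)) U[, cp$tract, drop = FALSE] %*% cp$strength
               else 0
    resid_sd <- sqrt(1 - beta[[sc]]^2 - sum(cp$strength^2))
    std <- beta[[sc]] * z + as.numeric(coupled) +
      resid_sd * stats::rnorm(n)
    em[, sc] <- config$em_mean[[sc]] + config$em_sd[[sc]] * std
  }
  ## recall scores live on the bounded task scale; continuous values are
  ## truncated at the bounds (a negligible tail event at the default
  ## location and scale), integers only under the discrete flag
  em[] <- pmin(CVLT_MAX, pmax(0, em))
  if (config$discrete_scores) em[] <- round(em)
  disc <- NULL
  if (config$discrimination) {
    bd <- sqrt(config$discrimination_age_r2)
    disc <- bd * z + sqrt(1 - bd^2) * stats::rnorm(n)
  }

  ## block 5: reconstruction failures
  set.seed(block_seeds[5])
  failed_subjects <- character(0)
  if (config$n_failures > 0L && length(config$failed_tracts)) {
    failed_subjects <- sample(ids, min(config$n_failures, n))
    drop <- wide$subject_id %in% failed_subjects &
      wide$tract %in% config$failed_tracts
    wide <- wide[!drop, , drop = FALSE]
    rownames(wide) <- NULL
  }

  cohort <- data.frame(subject_id = ids, age = age, sex = sex,
                       stringsAsFactors = FALSE)
  cohort <- cbind(cohort, as.data.frame(em))
  if (!is.null(disc)) cohort$discrimination <- disc
  cohort <- as_cohort(cohort)
  metrics <- as_tract_metrics(wide)

  ## ground truth: planted parameters and realized sample statistics
  mp$factor_weight <- weight
  planted_salience <- lapply(TRACTS, function(tr) {
    lam <- numeric(length(X_COLUMNS))
    names(lam) <- X_COLUMNS
    sel <- mp$tract == tr
    lam[paste(mp$hemisphere[sel], mp$metric[sel], sep = "_")] <-
      mp$age_loading[sel]
    nrm <- sqrt(sum(lam^2))
    if (nrm > 0) lam / nrm else lam
  })
  names(planted_salience) <- TRACTS
  realized_load <- mp[, c("tract", "hemisphere", "metric", "age_loading")]
  realized_load$sample_cor <- vapply(seq_len(nrow(mp)), function(i) {
    v <- value[(i - 1) * n + seq_len(n)]
    stats::cor(v, age)
  }, numeric(1))
  truth <- structure(
    list(seed = root, block_seeds = block_seeds,
         age_loadings = mp,
         maturation_age_cor = alpha,
         planted_salience = planted_salience,
         em_beta = beta,
         em_tract_coupling = config$em_tract_coupling,
         maturation_factors = FT,
         realized = list(
           metric_age_cor = realized_load,
           em_age_r2 = vapply(EM_SCORES, function(sc)
             stats::cor(em[, sc], age)^2, numeric(1)),
           maturation_age_cor = vapply(TRACTS, function(tr)
             stats::cor(FT[, tr], age), numeric(1))),
         failed_subjects = failed_subjects,
         config = config),
    class = "sim_truth"
  )
  list(cohort = cohort, metrics = metrics, truth = truth)
}

#' Independent-null blocks for calibration studies
#'
#' Draws X and Y as independent standard-normal blocks - the exact null of
#' no cross-block association - packaged as an
#' \code{\link{build_analysis_matrix}} result so the inference machinery
#' can run on it unchanged.  Used for type-I-error calibration of the
#' permutation test.
#'
#' @param n,p,q Dimensions; requires n > max(p, q) + 2.
#' @param seed Integer seed.
#' @return An \code{"analysis_matrix"} object.
#' @export
null_cohort <- function(n, p, q, seed = 1L) {
  n <- as.integer(n)
  if (n <= max(p, q) + 2L)
    stop("need n > max(p, q) + 2", call. = FALSE)
  set.seed(as.integer(seed))
  ids <- sprintf("S%0*d", max(3L, nchar(n)), seq_len(n))
  X <- matrix(stats::rnorm(n * p), n, p,
              dimnames = list(ids, paste0("x", seq_len(p))))
  Y <- matrix(stats::rnorm(n * q), n, q,
              dimnames = list(ids, paste0("y", seq_len(q))))
  structure(
    list(subject_ids = ids, X = X, x_names = colnames(X), Y = Y,
         y_names = colnames(Y), tract = NULL, y_spec = "null",
         dropped = character(0)),
    class = "analysis_matrix"
  )
}
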