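#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values (monotone, capped at 1), returned in the
#' input order.  Thin, domain-checked front end to
#' \code{stats::p.adjust(method = "BH")}.
#'
#' @param p_values Numeric vector of raw p-values in [0, 1].
#' @return Adjusted p-values, same length and order.
#' @examples
#' fdr_adjust(c(0.01, 0.02, 0.04))  # 0.03 0.03 0.04
#' @export
fdr_adjust <- function(p_values) {
  p_values <- as.numeric(p_values)
  if (any(!is.finite(p_values) | p_values < 0 | p_values > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p_values, method = "BH")
}

#' Metric-age correlations across all tracts
#'
#' The univariate age screen: one Pearson correlation per tract x
#' hemisphere x metric cell (4 x 2 x 3 = 24 rows with the canonical tract
#' set), with Benjamini-Hochberg adjustment across the whole family.
#' Each cell uses the subjects whose row for that tract and hemisphere is
#' present.  Degenerate cells (constant metric, or fewer than 4 paired
#' observations) are flagged and excluded from the FDR family.
#'
#' @param metrics A \code{"tract_metrics"} data.frame.
#' @param cohort A \code{"cohort"} data.frame (provides age).
#' @return A data.frame of class \code{"age_correlation_table"}:
#'   \code{tract, hemisphere, metric, n, r, p_raw, p_fdr, degenerate}.
#' @export
correlate_with_age <- function(metrics, cohort) {
  ages <- stats::setNames(cohort$age, cohort$subject_id)
  tracts <- intersect(TRACTS, unique(metrics$tract))
  grid <- expand.grid(metric = METRICS, hemisphere = HEMISPHERES,
                      tract = tracts, stringsAsFactors = FALSE)[, 3:1]
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    sel <- metrics$tract == grid$tract[i] &
      metrics$hemisphere == grid$hemisphere[i] &
      metrics$subject_id %in% names(ages)
    v <- metrics[[grid$metric[i]]][sel]
    a <- ages[metrics$subject_id[sel]]
    ok <- is.finite(v) & is.finite(a)
    v <- v[ok]; a <- a[ok]
    if (length(v) < 4L || stats::sd(v) == 0 || stats::sd(a) == 0)
      return(data.frame(n = length(v), r = NA_real_, p_raw = NA_real_,
                        degenerate = TRUE))
    ct <- stats::cor.test(v, a)
    data.frame(n = length(v), r = unname(ct$estimate), p_raw = ct$p.value,
               degenerate = FALSE)
  })
  out <- cbind(grid, do.call(rbind, rows))
  out$p_fdr <- NA_real_
  live <- !out$degenerate
  out$p_fdr[live] <- fdr_adjust(out$p_raw[live])
  out <- out[, c("tract", "hemisphere", "metric", "n", "r", "p_raw",
                 "p_fdr", "degenerate")]
  class(out) <- c("age_correlation_table", "data.frame")
  out
}

#' Ordinary least squares of a score on age
#'
#' Fits \code{score ~ age} (plus optional covariates such as sex) and
#' reports the F statistic of the age term, the model R-squared, and the
#' standardized slope of age.  Without covariates the reported quantities
#' obey the exact identities \eqn{F = (n-2) R^2 / (1 - R^2)} and
#' \eqn{\beta_{std}^2 = R^2}.
#'
#' @param score Numeric outcome vector.
#' @param age Numeric predictor (years).
#' @param covariates Optional data.frame of additional predictors.
#' @param outcome Label carried into the result.
#' @return Object of class \code{"age_regression"}: list with
#'   \code{outcome}, \code{F}, \code{r_squared}, \code{beta_std},
#'   \code{p}, \code{n}, \code{covariates}.
#' @export
regress_on_age <- function(score, age, covariates = NULL,
                           outcome = "score") {
  score <- as.numeric(score)
  age <- as.numeric(age)
  if (length(score) != length(age))
    stop("'score' and 'age' have different lengths", call. = FALSE)
  if (length(score) < 4L) stop("need at least 4 observations",
                               call. = FALSE)
  dat <- data.frame(.y = score, age = age)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    if (nrow(covariates) != length(score))
      stop("covariates have the wrong number of rows", call. = FALSE)
    dat <- cbind(dat, covariates)
  }
  fit <- stats::lm(.y ~ ., data = dat)
  if (any(is.na(stats::coef(fit))))
    stop("rank-deficient model: a covariate is collinear", call. = FALSE)
  sm <- summary(fit)
  ct <- stats::coef(sm)["age", ]
  structure(
    list(outcome = outcome,
         F = unname(ct["t value"]^2),
         r_squared = sm$r.squared,
         beta_std = unname(stats::coef(fit)["age"] * stats::sd(age) /
                             stats::sd(score)),
         p = unname(ct["Pr(>|t|)"]),
         n = length(score),
         covariates = if (is.null(covariates)) character(0)
                      else names(covariates)),
    class = "age_regression"
  )
}

#' @export
print.age_regression <- function(x, ...) {
  cat(sprintf("%s ~ age%s: F = %.2f, R2 = %.3f, beta = %.2f, p = %.3g (n = %d)\n",
              x$outcome,
              if (length(x$covariates))
                paste0(" + ", paste(x$covariates, collapse = " + "))
              else "",
              x$F, x$r_squared, x$beta_std, x$p, x$n))
  invisible(x)
}

#' Maturity-memory association table
#'
#' Correlates each tract's maturity score with each recall score, adjusts
#' the whole tract x score family with Benjamini-Hochberg FDR (the
#' default family is all pairs jointly; \code{fdr_family = "per_tract"}
#' adjusts within tract), and attaches the default Bayes factor
#' \code{\link{bayes_factor_correlation}} to every test.  When the cohort
#' carries a \code{discrimination} column the same correlations are
#' computed against it as a specificity panel, FDR-adjusted as its own
#' family in the same report; a missing column skips the panel with a
#' warning.
#'
#' @param scores A \code{"maturity_scores"} object or a list of them
#'   (one per tract).  Tracts whose scores were withheld are refused.
#' @param cohort A \code{"cohort"} data.frame.
#' @param em_scores Recall columns to test (default sdfr, ldfr, ldcr).
#' @param specificity Include the discrimination panel when available.
#' @param alpha FDR level for the \code{pass_fdr} flag (default 0.05).
#' @param kappa Prior width for the Bayes factors (default 1).
#' @param fdr_family \code{"joint"} (default) or \code{"per_tract"}.
#' @return A data.frame of class \code{"association_table"}: one row per
#'   (tract, behavior) with \code{panel} (\code{"em"} or
#'   \code{"specificity"}), \code{n}, \code{r}, \code{p_raw},
#'   \code{p_fdr}, \code{pass_fdr}, \code{bf10}.
#' @export
maturity_em_association <- function(scores, cohort,
                                    em_scores = EM_SCORES,
                                    specificity = TRUE, alpha = 0.05,
                                    kappa = 1,
                                    fdr_family = c("joint", "per_tract")) {
  fdr_family <- match.arg(fdr_family)
  if (inherits(scores, "maturity_scores")) scores <- list(scores)
  for (ms in scores) {
    stopifnot(inherits(ms, "maturity_scores"))
    if (is.null(ms$score))
      stop("maturity scores for tract '", ms$tract, "' were withheld ",
           "(non-significant latent variable)", call. = FALSE)
  }
  one_panel <- function(behavior_cols, panel) {
    rows <- list()
    for (ms in scores) {
      sc <- stats::setNames(ms$score, ms$subject_ids)
      for (b in behavior_cols) {
        bh <- stats::setNames(cohort[[b]], cohort$subject_id)
        common <- intersect(names(sc), names(bh))
        common <- common[is.finite(bh[common])]
        ct <- stats::cor.test(sc[common], bh[common])
        rows[[length(rows) + 1L]] <- data.frame(
          tract = if (is.null(ms$tract)) NA_character_ else ms$tract,
          behavior = b, panel = panel, n = length(common),
          r = unname(ct$estimate), p_raw = ct$p.value,
          stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows)
  }
  out <- one_panel(em_scores, "em")
  if (fdr_family == "joint") {
    out$p_fdr <- fdr_adjust(out$p_raw)
  } else {
    out$p_fdr <- NA_real_
    for (tr in unique(out$tract)) {
      sel <- out$tract == tr
      out$p_fdr[sel] <- fdr_adjust(out$p_raw[sel])
    }
  }
  if (specificity) {
    if (!"discrimination" %in% names(cohort)) {
      warning("cohort has no 'discrimination' column; ",
              "specificity panel skipped", call. = FALSE)
    } else {
      sp <- one_panel("discrimination", "specificity")
      sp$p_fdr <- fdr_adjust(sp$p_raw)
      out <- rbind(out, sp)
    }
  }
  out$pass_fdr <- out$p_fdr <= alpha
  out$bf10 <- vapply(seq_len(nrow(out)), function(i)
    bayes_factor_correlation(out$r[i], out$n[i], kappa = kappa),
    numeric(1))
  rownames(out) <- NULL
  attr(out, "alpha") <- alpha
  attr(out, "fdr_family") <- fdr_family
  class(out) <- c("association_table", "data.frame")
  out
}

#' Age-group interaction on the maturity-memory relation
#'
#' Tests whether the slope of a recall score on a tract maturity score
#' differs between younger and older children: an ordinary least squares
#' fit of \code{em ~ maturity + group + maturity:group}, with the group
#' defined by an age cutoff (7 years by default, roughly the offset of
#' childhood amnesia).  Children at exactly the cutoff age join the older
#' group.  The maturity score is not re-standardized within group, so the
#' two reported slopes are directly comparable.
#'
#' @param scores Maturity-score vector, or a \code{"maturity_scores"}
#'   object (its stored subject order is used as-is).
#' @param em_score Recall-score vector aligned with \code{scores}.
#' @param age Age vector aligned with \code{scores}.
#' @param cutoff Age-group boundary in years (default 7).
#' @return Object of class \code{"interaction_result"}: list with
#'   \code{cutoff}, \code{n_younger}, \code{n_older},
#'   \code{slope_younger}, \code{slope_older},
#'   \code{interaction_coefficient}, \code{interaction_p}.
#' @export
age_group_interaction <- function(scores, em_score, age, cutoff = 7) {
  if (inherits(scores, "maturity_scores")) {
    if (is.null(scores$score))
      stop("maturity scores were withheld", call. = FALSE)
    scores <- scores$score
  }
  scores <- as.numeric(scores)
  em_score <- as.numeric(em_score)
  age <- as.numeric(age)
  if (length(scores) != length(em_score) || length(scores) != length(age))
    stop("'scores', 'em_score' and 'age' must have equal length",
         call. = FALSE)
  older <- age >= cutoff
  if (sum(older) < 3L || sum(!older) < 3L)
    stop("grouping error: each age group needs at least 3 subjects ",
         "(younger n = ", sum(!older), ", older n = ", sum(older), ")",
         call. = FALSE)
  group <- as.integer(older)  # 0 = younger, 1 = older
  fit <- stats::lm(em_score ~ scores * group)
  co <- stats::coef(fit)
  sm <- stats::coef(summary(fit))
  structure(
    list(cutoff = cutoff,
         n_younger = sum(!older), n_older = sum(older),
         slope_younger = unname(co["scores"]),
         slope_older = unname(co["scores"] + co["scores:group"]),
         interaction_coefficient = unname(co["scores:group"]),
         interaction_p = unname(sm["scores:group", "Pr(>|t|)"])),
    class = "interaction_result"
  )
}

#' @export
print.interaction_result <- function(x, ...) {
  cat(sprintf("Age-group interaction (cutoff %g y; younger n = %d, older n = %d)\n",
              x$cutoff, x$n_younger, x$n_older))
  cat(sprintf("slopes: younger %.3f, older %.3f; interaction %.3f (p = %.3g)\n",
              x$slope_younger, x$slope_older, x$interaction_coefficient,
              x$interaction_p))
  invisible(x)
}
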