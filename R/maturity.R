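#' Per-subject tract maturity scores
#'
#' Runs the diffusion-by-age PLSC (Y = age, q = 1) for one tract and
#' returns each subject's projection on the first latent variable.  With a
#' single Y column the decomposition has a closed form: the predictor
#' salience is the vector of metric-age correlations scaled to unit norm,
#' and the singular value is that vector's Euclidean norm.  The projection
#' summarizes, in one number per subject, how much their tract
#' microstructure resembles that of older versus younger children - a
#' statistical proxy for microstructural maturity.
#'
#' Because the SVD sign is arbitrary, the score is aligned so that it
#' correlates non-negatively with age (when radial diffusivity dominates
#' the salience the raw projection correlates negatively with age and is
#' negated, with \code{sign_flipped = TRUE}).  The latent variable's
#' permutation p-value and the bootstrap reliability ratios of the six
#' metrics are attached.
#'
#' Maturity is only considered defined when the latent variable passes
#' permutation significance; for a non-significant tract the scores are
#' withheld unless \code{force = TRUE}, in which case they are returned
#' flagged non-significant (exploration only).
#'
#' @param x Either an \code{"analysis_matrix"} built with
#'   \code{y_spec = "age"}, or a raw n x p metric matrix.
#' @param age Subject ages; ignored (taken from \code{x}) when \code{x} is
#'   an analysis matrix.
#' @param tract Optional tract label carried into the result.
#' @param n_perm,n_boot Permutation and bootstrap counts (default 5000).
#' @param seed Optional root seed; child seeds for the permutation and
#'   bootstrap stages are derived from it.
#' @param alpha Significance level for the permutation test (default 0.05).
#' @param force Compute scores even when the latent variable is not
#'   significant.
#' @return An object of class \code{"maturity_scores"}: list with
#'   \code{tract}, \code{subject_ids}, \code{score} (NULL when withheld),
#'   \code{age_correlation}, \code{sign_flipped}, \code{salience},
#'   \code{lv_p_value}, \code{significant}, \code{bootstrap}, \code{n}.
#' @export
maturity_scores <- function(x, age = NULL, tract = NULL, n_perm = 5000L,
                            n_boot = 5000L, seed = NULL, alpha = 0.05,
                            force = FALSE) {
  if (inherits(x, "analysis_matrix")) {
    if (!identical(x$y_spec, "age"))
      stop("analysis matrix must be built with y_spec = \"age\"",
           call. = FALSE)
    X <- x$X
    age <- as.numeric(x$Y[, 1])
    ids <- x$subject_ids
    if (is.null(tract)) tract <- x$tract
  } else {
    X <- as.matrix(x)
    if (is.null(age)) stop("'age' is required", call. = FALSE)
    age <- as.numeric(age)
    ids <- rownames(X)
    if (is.null(ids)) ids <- as.character(seq_len(nrow(X)))
  }
  if (nrow(X) != length(age))
    stop("'x' and 'age' have different lengths", call. = FALSE)
  Y <- matrix(age, ncol = 1, dimnames = list(NULL, "age"))

  if (!is.null(seed)) set.seed(as.integer(seed))
  child <- if (!is.null(seed)) sample.int(2147483646L, 2L) else c(NULL, NULL)

  fit <- plsc_decompose(X, Y)
  score <- as.numeric(fit$Lx[, 1])
  salience <- fit$V[, 1]
  r_age <- stats::cor(score, age)
  flipped <- FALSE
  if (!is.na(r_age) && r_age < 0) {
    score <- -score
    salience <- -salience
    r_age <- -r_age
    flipped <- TRUE
  }
  perm <- permutation_test(X, Y, lv_index = 1L, n_perm = n_perm,
                           seed = child[1])
  boot <- bootstrap_ratios(X, Y, lv_index = 1L, n_boot = n_boot,
                           seed = child[2])
  if (flipped) {
    ## report bootstrap saliences/ratios in the aligned orientation
    boot$salience <- -boot$salience
    boot$bootstrap_ratio <- -boot$bootstrap_ratio
  }
  significant <- perm$p_value <= alpha
  if (!significant && !force) {
    message("tract ", if (is.null(tract)) "" else paste0("'", tract, "' "),
            "age latent variable not significant (p = ",
            signif(perm$p_value, 3), "); maturity scores withheld ",
            "(use force = TRUE to compute them anyway)")
    score <- NULL
    r_age <- NA_real_
  }
  structure(
    list(tract = tract, subject_ids = ids, score = score,
         age_correlation = r_age, sign_flipped = flipped,
         salience = salience, singular_value = fit$S[1],
         lv_p_value = perm$p_value, significant = significant,
         alpha = alpha, bootstrap = boot, n = nrow(X),
         age = age),
    class = "maturity_scores"
  )
}

#' Maturity-age summary
#'
#' Pearson correlation (non-negative after sign alignment) between the
#' maturity score and age, with its two-sided p-value.
#'
#' @param scores A \code{"maturity_scores"} object with computed scores.
#' @param age Optional age vector; defaults to the ages stored in
#'   \code{scores}.
#' @return List with \code{r}, \code{p_value}, \code{n}.
#' @export
maturity_age_report <- function(scores, age = NULL) {
  stopifnot(inherits(scores, "maturity_scores"))
  if (is.null(scores$score))
    stop("maturity scores were withheld (non-significant latent ",
         "variable); rerun maturity_scores() with force = TRUE",
         call. = FALSE)
  if (is.null(age)) age <- scores$age
  ct <- stats::cor.test(scores$score, age)
  list(r = unname(ct$estimate), p_value = ct$p.value,
       n = length(scores$score))
}

#' @export
print.maturity_scores <- function(x, ...) {
  cat("Tract maturity scores",
      if (!is.null(x$tract)) paste0("for '", x$tract, "'"), "- n =", x$n,
      "\n")
  cat(sprintf("LV1 permutation p = %.4g (%s at alpha = %g)%s\n",
              x$lv_p_value,
              if (x$significant) "significant" else "not significant",
              x$alpha,
              if (x$sign_flipped) "; score multiplied by -1 to correlate positively with age" else ""))
  if (!is.null(x$score))
    cat(sprintf("Correlation with age: %.3f\n", x$age_correlation))
  else cat("Scores withheld (non-significant latent variable)\n")
  invisible(x)
}
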