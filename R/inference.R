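#' Permutation test of a PLSC singular value
#'
#' Assesses whether a latent variable captures more cross-block correlation
#' than expected under the null of no association.  Rows of \code{Y} are
#' permuted uniformly at random while \code{X} is held fixed, the full
#' decomposition is recomputed each time, and the singular value at
#' \code{lv_index} is compared with its permutation null at the same index.
#' The p-value uses the add-one Monte-Carlo rule
#' \eqn{p = (\#\{null \ge observed\} + 1) / (P + 1)}, which never returns 0.
#'
#' Because z-scores are invariant to row permutation, permuting the rows of
#' the standardized block is identical to permuting the raw block and
#' re-standardizing.
#'
#' @param X Raw n x p predictor block.
#' @param Y Raw n x q behavior block.
#' @param lv_index Index of the tested latent variable (default 1).
#' @param n_perm Number of permutations (default 5000).
#' @param seed Optional integer seed for reproducibility.
#' @return An object of class \code{"plsc_perm"}: list with
#'   \code{lv_index}, \code{observed} singular value, \code{null}
#'   (vector of length \code{n_perm}), \code{p_value} and \code{n_perm}.
#' @export
permutation_test <- function(X, Y, lv_index = 1L, n_perm = 5000L,
                             seed = NULL) {
  X <- as.matrix(X)
  Y <- as.matrix(Y)
  n_perm <- as.integer(n_perm)
  if (n_perm < 1L) stop("'n_perm' must be at least 1", call. = FALSE)
  k <- min(ncol(X), ncol(Y))
  if (lv_index < 1L || lv_index > k)
    stop("'lv_index' out of range: must be in 1..", k, call. = FALSE)
  Xz <- zscore_columns(X)
  Yz <- zscore_columns(Y)
  n <- nrow(Xz)
  obs <- svd(crossprod(Yz, Xz) / (n - 1), nu = 0, nv = 0)$d[lv_index]
  if (!is.null(seed)) set.seed(seed)
  null <- vapply(seq_len(n_perm), function(b) {
    idx <- sample.int(n)
    svd(crossprod(Yz[idx, , drop = FALSE], Xz) / (n - 1),
        nu = 0, nv = 0)$d[lv_index]
  }, numeric(1))
  structure(
    list(lv_index = as.integer(lv_index), observed = obs, null = null,
         p_value = (sum(null >= obs) + 1) / (n_perm + 1), n_perm = n_perm),
    class = "plsc_perm"
  )
}

#' @export
print.plsc_perm <- function(x, ...) {
  cat(sprintf("Permutation test of LV%d: singular value %.4f, p = %.4g (%d permutations)\n",
              x$lv_index, x$observed, x$p_value, x$n_perm))
  invisible(x)
}

#' Bootstrap salience-reliability ratios
#'
#' Resamples subjects with replacement jointly in both blocks,
#' re-standardizes the blocks within each resample (the statistic is
#' defined on correlations, so the whole estimator is recomputed), and
#' recomputes the predictor salience of the tested latent variable.  Each
#' resampled salience is sign-aligned to the original via the sign of
#' their dot product, since the SVD sign is arbitrary and unaligned flips
#' would inflate the standard error.  The bootstrap ratio of a variable is
#' its original salience divided by the bootstrap standard deviation of
#' the aligned resampled saliences; |ratio| > \code{critical} (1.96 by
#' convention) marks a reliable contribution.
#'
#' Resamples that produce a constant column in either block are redrawn
#' and counted.
#'
#' @inheritParams permutation_test
#' @param n_boot Number of bootstrap resamples (at least 100; default 5000).
#' @param critical Reliability cutoff applied to |ratio| (default 1.96).
#' @return A data.frame of class \code{"plsc_bootstrap"} with one row per
#'   predictor variable: \code{variable}, \code{salience}, \code{se},
#'   \code{bootstrap_ratio}, \code{reliable}.  Attributes record
#'   \code{lv_index}, \code{n_boot}, \code{n_redraws} and \code{critical}.
#' @export
bootstrap_ratios <- function(X, Y, lv_index = 1L, n_boot = 5000L,
                             seed = NULL, critical = 1.96) {
  X <- as.matrix(X)
  Y <- as.matrix(Y)
  n_boot <- as.integer(n_boot)
  if (n_boot < 100L) stop("'n_boot' must be at least 100", call. = FALSE)
  fit <- plsc_decompose(X, Y)
  k <- length(fit$S)
  if (lv_index < 1L || lv_index > k)
    stop("'lv_index' out of range: must be in 1..", k, call. = FALSE)
  v0 <- fit$V[, lv_index]
  n <- nrow(X)
  p <- ncol(X)
  if (!is.null(seed)) set.seed(seed)
  B <- matrix(NA_real_, p, n_boot)
  redraws <- 0L
  for (b in seq_len(n_boot)) {
    repeat {
      idx <- sample.int(n, replace = TRUE)
      Xb <- .zscore(X[idx, , drop = FALSE])
      Yb <- .zscore(Y[idx, , drop = FALSE])
      if (is.null(Xb) || is.null(Yb)) {
        redraws <- redraws + 1L
        if (redraws > 100L * n_boot)
          stop("too many degenerate bootstrap resamples", call. = FALSE)
        next
      }
      break
    }
    vb <- svd(crossprod(Yb, Xb) / (n - 1))$v[, lv_index]
    if (sum(vb * v0) < 0) vb <- -vb
    B[, b] <- vb
  }
  se <- apply(B, 1L, stats::sd)
  ratio <- v0 / se
  out <- data.frame(
    variable = fit$x_names,
    salience = unname(v0),
    se = se,
    bootstrap_ratio = unname(ratio),
    reliable = abs(unname(ratio)) > critical,
    stringsAsFactors = FALSE
  )
  attr(out, "lv_index") <- as.integer(lv_index)
  attr(out, "n_boot") <- n_boot
  attr(out, "n_redraws") <- redraws
  attr(out, "critical") <- critical
  class(out) <- c("plsc_bootstrap", "data.frame")
  out
}

#' Behavior-score weights on a latent variable
#'
#' The weight of each behavior variable is its Pearson correlation with
#' the latent-variable score, together with the two-sided t-based p-value.
#' By default the predictor-side latent score \eqn{L_x} is used (the
#' saliences describe the predictor block, so its latent score is the
#' natural reference), but any score vector can be supplied.
#'
#' @param Y Raw n x q behavior block.
#' @param lx_scores Numeric vector of length n: the latent-variable score
#'   each behavior column is correlated with.
#' @param alpha Significance level for the flag column (default 0.05).
#' @return data.frame with columns \code{variable}, \code{weight},
#'   \code{p_value}, \code{significant}.
#' @export
behavior_weights <- function(Y, lx_scores, alpha = 0.05) {
  Y <- as.matrix(Y)
  lx_scores <- as.numeric(lx_scores)
  if (nrow(Y) != length(lx_scores))
    stop("'Y' and 'lx_scores' have different lengths", call. = FALSE)
  nm <- .default_names(Y, "y")
  sds <- apply(Y, 2L, stats::sd)
  if (any(sds == 0))
    stop("degenerate (zero-variance) behavior column: ",
         paste(nm[sds == 0], collapse = ", "), call. = FALSE)
  res <- lapply(seq_len(ncol(Y)), function(j) {
    ct <- stats::cor.test(Y[, j], lx_scores)
    c(r = unname(ct$estimate), p = ct$p.value)
  })
  res <- do.call(rbind, res)
  data.frame(
    variable = nm,
    weight = res[, "r"],
    p_value = res[, "p"],
    significant = res[, "p"] < alpha,
    stringsAsFactors = FALSE
  )
}
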