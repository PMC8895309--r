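#' Column-wise z-scoring
#'
#' Standardizes every column of a numeric matrix to mean 0 and unit
#' variance, using the sample (n - 1) standard deviation.  PLSC is defined
#' on the cross-correlation matrix of two blocks, so both blocks pass
#' through this transform before decomposition.
#'
#' @param M A numeric matrix (or something coercible to one) with at least
#'   two rows.
#' @return A numeric matrix of the same dimension with column means 0 and
#'   column variances 1.
#' @examples
#' zscore_columns(cbind(a = 1:3, b = c(2, 8, 5)))
#' @export
zscore_columns <- function(M) {
  M <- as.matrix(M)
  if (!is.numeric(M)) stop("'M' must be a numeric matrix", call. = FALSE)
  if (nrow(M) < 2L) stop("need at least 2 rows to standardize", call. = FALSE)
  mu <- colMeans(M)
  sds <- apply(M, 2L, stats::sd)
  bad <- which(!is.finite(sds) | sds == 0)
  if (length(bad)) {
    nm <- colnames(M)[bad]
    if (is.null(nm) || any(!nzchar(nm))) nm <- as.character(bad)
    stop("degenerate (constant or non-finite) column: ",
         paste(nm, collapse = ", "), call. = FALSE)
  }
  sweep(sweep(M, 2L, mu, "-"), 2L, sds, "/")
}

## fast, unchecked standardization for resampling loops; returns NULL when
## a column is constant so callers can redraw
.zscore <- function(M) {
  n <- nrow(M)
  mu <- colMeans(M)
  Mc <- M - rep(mu, each = n)
  ss <- sqrt(colSums(Mc^2) / (n - 1))
  if (any(ss == 0 | !is.finite(ss))) return(NULL)
  Mc / rep(ss, each = n)
}

#' Cross-correlation matrix of two standardized blocks
#'
#' Computes the q x p matrix whose (k, j) entry is the Pearson correlation
#' between behavior variable k (column of \code{Yz}) and predictor variable
#' j (column of \code{Xz}).  With both blocks z-scored using the n - 1
#' denominator, \code{t(Yz) \%*\% Xz / (n - 1)} is exactly the Pearson
#' correlation matrix.
#'
#' @param Xz Standardized n x p predictor block.
#' @param Yz Standardized n x q behavior block.
#' @return A q x p correlation matrix with behavior variables as rows.
#' @export
cross_correlation <- function(Xz, Yz) {
  Xz <- as.matrix(Xz)
  Yz <- as.matrix(Yz)
  if (nrow(Xz) != nrow(Yz))
    stop("blocks have different numbers of rows (", nrow(Xz), " vs ",
         nrow(Yz), ")", call. = FALSE)
  n <- nrow(Xz)
  R <- crossprod(Yz, Xz) / (n - 1)
  dimnames(R) <- list(colnames(Yz), colnames(Xz))
  R
}

.default_names <- function(M, prefix) {
  nm <- colnames(M)
  if (is.null(nm)) nm <- paste0(prefix, seq_len(ncol(M)))
  nm
}

#' Partial least squares correlation (PLS-SVD) of two blocks
#'
#' Standardizes both blocks, forms their cross-correlation matrix
#' \eqn{R = corr(Y, X)} (behavior rows, predictor columns), and decomposes
#' it by singular value decomposition \eqn{R = U S V'}.  Columns of
#' \eqn{V} (predictor saliences) and \eqn{U} (behavior saliences) are paired
#' latent variables; the singular values order them by the amount of
#' cross-block correlation they capture.  Subject-level latent scores are
#' the projections \eqn{L_x = X_z V} and \eqn{L_y = Y_z U}.
#'
#' SVD signs are arbitrary, so a deterministic convention is applied: each
#' column of \eqn{V} is flipped so that its largest-magnitude element is
#' positive (ties broken by the first index), and the paired column of
#' \eqn{U} is flipped jointly, which leaves the reconstruction
#' \eqn{U S V'} unchanged.
#'
#' @param X Raw n x p predictor block (e.g. diffusion metrics of one tract,
#'   both hemispheres).
#' @param Y Raw n x q behavior block (e.g. the three recall scores, or age).
#' @return An object of class \code{"plsc"}: a list with elements
#'   \code{x_names}, \code{y_names}, \code{R} (q x p), \code{U} (q x k),
#'   \code{V} (p x k), \code{S} (k singular values, descending),
#'   \code{Lx}, \code{Ly} (n x k latent scores) and \code{n}, where
#'   k = min(p, q).
#' @examples
#' set.seed(1)
#' X <- matrix(rnorm(60), 20, 3)
#' Y <- cbind(X[, 1] + rnorm(20, sd = 0.5), rnorm(20))
#' fit <- plsc_decompose(X, Y)
#' fit$S
#' @export
plsc_decompose <- function(X, Y) {
  X <- as.matrix(X)
  Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y))
    stop("X and Y have different numbers of rows", call. = FALSE)
  if (nrow(X) < 3L) stop("need at least 3 subjects", call. = FALSE)
  x_names <- .default_names(X, "x")
  y_names <- .default_names(Y, "y")
  Xz <- zscore_columns(X)
  Yz <- zscore_columns(Y)
  R <- cross_correlation(Xz, Yz)
  sv <- svd(R)
  U <- sv$u
  V <- sv$v
  S <- sv$d
  for (j in seq_along(S)) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) {
      V[, j] <- -V[, j]
      U[, j] <- -U[, j]
    }
  }
  rownames(V) <- x_names
  rownames(U) <- y_names
  Lx <- Xz %*% V
  Ly <- Yz %*% U
  structure(
    list(x_names = x_names, y_names = y_names, R = R, U = U, V = V, S = S,
         Lx = Lx, Ly = Ly, n = nrow(X)),
    class = "plsc"
  )
}

#' Latent scores of a standardized block
#'
#' Projects subjects onto salience vectors: \code{Mz \%*\% saliences}.
#'
#' @param Mz Standardized n x m block.
#' @param saliences m x k salience matrix (columns are latent variables).
#' @return n x k matrix of latent scores.
#' @export
latent_scores <- function(Mz, saliences) {
  Mz <- as.matrix(Mz)
  saliences <- as.matrix(saliences)
  if (ncol(Mz) != nrow(saliences))
    stop("shape mismatch: block has ", ncol(Mz), " columns but saliences ",
         "have ", nrow(saliences), " rows", call. = FALSE)
  Mz %*% saliences
}

#' @export
print.plsc <- function(x, ...) {
  k <- length(x$S)
  cat("PLSC decomposition:", length(x$x_names), "predictor x",
      length(x$y_names), "behavior variables, n =", x$n, "\n")
  cat("Singular values:", paste(signif(x$S, 4), collapse = ", "), "\n")
  cat("LV1 predictor saliences:\n")
  print(round(stats::setNames(x$V[, 1], x$x_names), 3))
  invisible(x)
}
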