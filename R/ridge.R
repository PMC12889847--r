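#' Closed-form ridge solution
#'
#' Solves `argmin ||X W - Y||^2 + lambda ||W||^2` for all target columns at
#' once via the economy SVD of `X` (shared across targets and across the
#' lambda grid). No intercept, no standardization — this is the raw solver
#' the higher-level fitters build on.
#'
#' @param X `n x p` design matrix.
#' @param Y `n x v` target matrix (a vector is treated as one column).
#' @param lambda nonnegative penalty (scalar or vector; one solution per
#'   value).
#' @return For scalar `lambda`, the `p x v` weight matrix; for a vector, a
#'   list of weight matrices.
#' @examples
#' ridge_solve(diag(2), c(1, 2), 1)   # (X'X + I)^-1 X'y = c(0.5, 1)
#' @export
ridge_solve <- function(X, Y, lambda) {
  Y <- as.matrix(Y)
  sv <- svd(X)
  keep <- sv$d > max(sv$d[1], 1e-300) * 1e-12
  U <- sv$u[, keep, drop = FALSE]; D <- sv$d[keep]
  Vm <- sv$v[, keep, drop = FALSE]
  UtY <- crossprod(U, Y)
  out <- lapply(lambda, function(l)
    Vm %*% ((D / (D^2 + l)) * UtY))
  if (length(lambda) == 1L) out[[1]] else out
}

#' Fit a ridge readout with penalty selection
#'
#' Features are standardized by train statistics (constant columns left
#' unscaled), the per-target intercept is unpenalized (train means), and the
#' penalty is chosen from `lambda_grid` to maximize the mean validation
#' Pearson correlation across targets, breaking ties toward the smallest
#' penalty.
#'
#' @param features `n x p` train feature matrix.
#' @param targets `n x v` train target matrix.
#' @param lambda_grid candidate penalties (default `10^(-2:6)`).
#' @param val_features,val_targets validation split used only for penalty
#'   selection; when `NULL`, the smallest penalty is used.
#' @return An object of class `linear_readout` (variant `"ridge"`) with
#'   `weights` (`p x v`), `intercept` (`v`), the chosen `lambda`, and the
#'   standardization statistics.
#' @export
fit_ridge <- function(features, targets, lambda_grid = 10^seq(-2, 6),
                      val_features = NULL, val_targets = NULL) {
  if (!length(lambda_grid)) stop("fit_ridge: empty lambda grid")
  if (any(lambda_grid < 0)) stop("fit_ridge: lambda must be >= 0")
  lambda_grid <- sort(lambda_grid)
  features <- as.matrix(features); targets <- as.matrix(targets)
  mu <- colMeans(features)
  sdev <- apply(features, 2, stats::sd)
  sdev[!is.finite(sdev) | sdev < 1e-12] <- 1
  Xs <- sweep(sweep(features, 2, mu), 2, sdev, "/")
  ybar <- colMeans(targets)
  Yc <- sweep(targets, 2, ybar)
  Ws <- ridge_solve(Xs, Yc, lambda_grid)
  if (length(lambda_grid) == 1L) Ws <- list(Ws)
  pick <- 1L
  if (length(lambda_grid) > 1L && !is.null(val_features)) {
    Xv <- sweep(sweep(as.matrix(val_features), 2, mu), 2, sdev, "/")
    score <- vapply(Ws, function(W) {
      pred <- sweep(Xv %*% W, 2, ybar, "+")
      mean(colwise_pearson(pred, as.matrix(val_targets)), na.rm = TRUE)
    }, 0)
    pick <- which(score >= max(score) - 1e-12)[1]  # smallest lambda among ties
  }
  W <- Ws[[pick]] / sdev   # fold standardization into the weights
  intercept <- ybar - as.numeric(mu %*% W)
  structure(list(variant = "ridge", weights = W, intercept = intercept,
                 lambda = lambda_grid[pick], lambda_grid = lambda_grid,
                 feature_mean = mu, feature_sd = sdev),
            class = "linear_readout")
}

#' @export
print.linear_readout <- function(x, ...) {
  cat(sprintf("<linear_readout '%s': %d features -> %d targets%s>\n",
              x$variant, nrow(x$weights), ncol(x$weights),
              if (!is.null(x$lambda)) sprintf(", lambda = %g", x$lambda) else ""))
  invisible(x)
}

#' @export
predict.linear_readout <- function(object, features, ...) {
  features <- as.matrix(features)
  if (!is.null(object$pca_rotation)) {
    features <- sweep(features, 2, object$pca_center) %*% object$pca_rotation
  }
  sweep(features %*% object$weights, 2, object$intercept, "+")
}

#' Fit a PCA-reduced ridge readout
#'
#' Principal components are estimated on the (flattened) train features only;
#' a ridge readout is then fit on the component scores.
#'
#' @param features `n x p` train features (already flattened).
#' @param targets `n x v` train targets.
#' @param n_components number of components (`<= min(n, p)`).
#' @inheritParams fit_ridge
#' @return A `linear_readout` (variant `"pca"`) carrying the component basis.
#' @export
fit_pca_regression <- function(features, targets, n_components,
                               lambda_grid = 10^seq(-2, 6),
                               val_features = NULL, val_targets = NULL) {
  features <- as.matrix(features)
  if (n_components > min(dim(features)))
    stop("fit_pca_regression: n_components exceeds feature rank bound")
  ctr <- colMeans(features)
  Xc <- sweep(features, 2, ctr)
  sv <- svd(Xc, nu = 0, nv = n_components)
  rot <- sv$v
  fit <- fit_ridge(Xc %*% rot, targets, lambda_grid,
                   if (!is.null(val_features))
                     sweep(as.matrix(val_features), 2, ctr) %*% rot,
                   val_targets)
  fit$variant <- "pca"
  fit$pca_rotation <- rot
  fit$pca_center <- ctr
  fit$singular_values <- sv$d
  fit
}

#' Saliency-weighted token pooling
#'
#' Collapses a token grid to a single d-vector using an externally supplied
#' nonnegative saliency map over the grid (renormalized to sum 1).
#'
#' @param grid a [token_grid].
#' @param saliency nonnegative numeric vector over the grid tokens (row-major)
#'   or a matrix of the grid shape.
#' @return pooled numeric vector of length `d`.
#' @export
saliency_pool <- function(grid, saliency) {
  if (is.matrix(saliency)) saliency <- as.vector(t(saliency))
  if (length(saliency) != nrow(grid$tokens))
    stop("saliency_pool: saliency length does not match token count")
  if (any(saliency < 0)) stop("saliency_pool: negative saliency values")
  tot <- sum(saliency)
  if (tot <= 0) stop("saliency_pool: all-zero saliency map")
  as.numeric((saliency / tot) %*% grid$tokens)
}

# Column-wise Pearson correlation between two aligned matrices; returns NA
# for degenerate (constant) columns.
colwise_pearson <- function(A, B) {
  A <- as.matrix(A); B <- as.matrix(B)
  Ac <- sweep(A, 2, colMeans(A)); Bc <- sweep(B, 2, colMeans(B))
  num <- colSums(Ac * Bc)
  den <- sqrt(colSums(Ac^2) * colSums(Bc^2))
  ifelse(den > 0, num / den, NA_real_)
}
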