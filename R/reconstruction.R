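# Dense (PCA) and sparse (L1) reconstruction errors against the background
# dictionary.

new_error_vector <- function(values, kind, raw = values) {
  structure(list(values = values, kind = kind, normalized = TRUE, raw = raw),
            class = "error_vector")
}

#' Min-max normalize non-negative error values to [0, 1]
#'
#' `(v - min) / (max - min)`; a constant input maps to all zeros. The
#' operation is idempotent on already-normalized vectors. A spread below
#' `1e-6 * max(1, max(v))` is treated as constant: reconstruction errors on
#' the feature scales used here (CIE-Lab magnitudes up to ~100) are only
#' solver-accurate to about that level, and normalizing a homogeneous
#' image's numerical dust to [0, 1] would manufacture saliency out of noise.
#'
#' @param values non-negative numeric vector.
#' @param kind `"dense"` or `"sparse"` provenance tag.
#' @return an `error_vector` with fields `values`, `kind`, `normalized`,
#'   and `raw` (the input).
#' @export
normalize_errors <- function(values, kind = "dense") {
  if (any(values < 0)) stop("error values must be non-negative")
  rng <- range(values)
  if (rng[2] - rng[1] <= 1e-6 * max(1, rng[2]))
    return(new_error_vector(values * 0, kind, raw = values))
  new_error_vector(minmax01(values), kind, raw = values)
}

#' Fit the dense (PCA) appearance model of the background dictionary
#'
#' Eigendecomposition of the covariance of the dictionary atoms' feature
#' rows; the basis keeps the smallest number of leading eigenvectors whose
#' cumulative eigenvalue share reaches `explained_fraction`. Reconstruction
#' centers on `f_bar`, the mean feature of *all* superpixels (not the
#' dictionary mean), as the saliency model prescribes.
#'
#' @param atoms m x d matrix of dictionary feature rows (m >= 2).
#' @param f_bar length-d mean feature of all superpixels.
#' @param explained_fraction eigenvalue share to retain, in `(0, 1]`;
#'   default 0.95.
#' @return a `dense_model`: list with `V` (d x D' orthonormal basis),
#'   `f_bar`, `eigenvalues`, `n_components`, `explained_fraction`, and
#'   `zero_eigen` (TRUE when all atoms were identical).
#' @export
fit_dense_model <- function(atoms, f_bar, explained_fraction = 0.95) {
  if (nrow(atoms) < 2L) stop("need at least 2 dictionary atoms for PCA")
  if (explained_fraction <= 0 || explained_fraction > 1)
    stop("explained_fraction must be in (0, 1]")
  C <- stats::cov(atoms)
  eig <- eigen(C, symmetric = TRUE)
  vals <- pmax(eig$values, 0)
  total <- sum(vals)
  if (total <= .Machine$double.eps) {
    np <- 1L
    zero <- TRUE
  } else {
    np <- which(cumsum(vals) / total >= explained_fraction - 1e-12)[1]
    zero <- FALSE
  }
  structure(
    list(V = eig$vectors[, seq_len(np), drop = FALSE],
         f_bar = f_bar, eigenvalues = vals, n_components = np,
         explained_fraction = explained_fraction, zero_eigen = zero),
    class = "dense_model"
  )
}

#' Dense reconstruction errors
#'
#' Projects each feature row onto the dictionary's PCA basis,
#' `gamma_i = V^T (f_i - f_bar)`, and scores the squared residual
#' `eps_i = || f_i - (V gamma_i + f_bar) ||^2`, then min-max normalizes.
#' Regions the background subspace cannot reconstruct score high and are
#' likely salient.
#'
#' @param model a `dense_model`.
#' @param features a `feature_matrix` or plain k x d matrix.
#' @return a normalized `error_vector` of kind `"dense"` (raw residuals in
#'   `$raw`).
#' @export
dense_errors <- function(model, features) {
  Fm <- if (inherits(features, "feature_matrix")) features$F else features
  centered <- sweep(Fm, 2, model$f_bar)
  gamma <- centered %*% model$V
  resid <- centered - gamma %*% t(model$V)
  normalize_errors(rowSums(resid^2), kind = "dense")
}

#' Sparse coding configuration
#'
#' @param lambda L1 penalty weight; default 0.01. Zero (plain least squares
#'   on the atoms) is only allowed with `allow_zero_lambda = TRUE`, meant
#'   for tests.
#' @param tol coordinate-descent convergence tolerance: a sweep converges
#'   when the largest single-coordinate objective move falls below
#'   `tol * max(||f||^2, 1)` (the glmnet-style criterion).
#' @param maxit maximum coordinate-descent sweeps per problem.
#' @param allow_zero_lambda permit `lambda = 0`.
#' @return a `sparse_config` list.
#' @export
sparse_config <- function(lambda = 0.01, tol = 1e-9, maxit = 10000L,
                          allow_zero_lambda = FALSE) {
  if (lambda < 0 || (lambda == 0 && !allow_zero_lambda))
    stop("lambda must be positive (lambda = 0 requires allow_zero_lambda)")
  structure(list(lambda = lambda, tol = tol, maxit = as.integer(maxit),
                 allow_zero_lambda = allow_zero_lambda),
            class = "sparse_config")
}

#' Sparse reconstruction errors
#'
#' Encodes each feature row over the dictionary atoms by the L1-regularized
#' least squares `alpha_i = argmin ||f_i - B alpha||^2 + lambda ||alpha||_1`
#' and scores the squared residual `eps_i = ||f_i - B alpha_i||^2`, then
#' min-max normalizes. The solver works on the lasso dual (projection of
#' `f_i` onto `{v : ||B' v||_inf <= lambda/2}` by a log-barrier Newton
#' method), because the residual -- the only quantity the error needs -- is
#' unique and numerically stable there even for the near-collinear
#' dictionaries that homogeneous backgrounds produce, where coordinate
#' descent stalls. Because every atom is available, sparse errors suppress
#' cluttered backgrounds more aggressively than the dense subspace model.
#'
#' @param atoms m x d matrix of dictionary feature rows (used as basis
#'   columns `B = t(atoms)`).
#' @param features a `feature_matrix` or plain k x d matrix.
#' @param config a [sparse_config()].
#' @return a normalized `error_vector` of kind `"sparse"`, with the
#'   coefficient matrix in attribute `"alpha"` (m x k).
#' @export
sparse_errors <- function(atoms, features, config = sparse_config()) {
  Fm <- if (inherits(features, "feature_matrix")) features$F else features
  if (nrow(atoms) < 1L) stop("dictionary is empty")
  B <- t(atoms)            # d x m, atoms as columns
  Y <- t(Fm)               # d x k
  fit <- .lasso_dual_cpp(B, Y, config$lambda)
  if (!all(fit$converged)) {
    bad <- which(!fit$converged)[1]
    stop(sprintf("sparse solver did not converge for superpixel %d after %d iterations",
                 bad, fit$iters[bad]))
  }
  out <- normalize_errors(as.numeric(fit$eps), kind = "sparse")
  attr(out, "alpha") <- fit$alpha
  out
}

#' Write per-superpixel reconstruction errors as CSV
#'
#' @param dense,sparse `error_vector`s for the same scale.
#' @param path destination CSV path.
#' @export
write_error_csv <- function(dense, sparse, path) {
  df <- data.frame(label = seq_along(dense$values) - 1L,
                   dense = dense$values, dense_raw = dense$raw,
                   sparse = sparse$values, sparse_raw = sparse$raw)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
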