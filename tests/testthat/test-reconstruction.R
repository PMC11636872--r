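test_that("normalization maps to [0,1] with declared conventions", {
  e <- normalize_errors(c(2, 4, 6))
  expect_equal(e$values, c(0, 0.5, 1))
  expect_equal(e$raw, c(2, 4, 6))
  expect_equal(normalize_errors(c(3, 3))$values, c(0, 0))
  idem <- normalize_errors(c(0, 0.25, 1))
  expect_equal(idem$values, c(0, 0.25, 1)) # idempotent on [0,1] with 0/1 hit
  expect_error(normalize_errors(c(-1, 2)), "non-negative")
})

test_that("dense model retains leading eigenvectors by explained share", {
  # 1-D spread in 2-D test mode: principal axis (1, 0)
  m <- fit_dense_model(rbind(c(0, 0), c(2, 0)), f_bar = c(0, 0))
  expect_equal(abs(m$V[, 1]), c(1, 0))
  expect_equal(m$n_components, 1L)
  # identical atoms: degenerate covariance flagged, one component kept
  mz <- fit_dense_model(rbind(c(1, 2), c(1, 2)), f_bar = c(0, 0))
  expect_true(mz$zero_eigen)
  expect_equal(mz$n_components, 1L)
  # full retention on full-rank atoms recovers the feature dimension
  set.seed(6)
  A <- matrix(rnorm(80), 10, 8)
  mf <- fit_dense_model(A, colMeans(A), explained_fraction = 1)
  expect_equal(mf$n_components, 8L)
  expect_equal(crossprod(mf$V), diag(8), tolerance = 1e-8)
  expect_true(all(diff(mf$eigenvalues) <= 1e-12))
  expect_error(fit_dense_model(A[1, , drop = FALSE], colMeans(A)), "at least 2")
})

test_that("dense errors follow the projection residual", {
  # V = (1,0), f_bar = (1,1): hand-computed gammas and residuals
  model <- structure(list(V = matrix(c(1, 0), 2, 1), f_bar = c(1, 1),
                          eigenvalues = c(1, 0), n_components = 1L,
                          explained_fraction = 0.95, zero_eigen = FALSE),
                     class = "dense_model")
  e <- dense_errors(model, rbind(c(3, 1), c(1, 3), c(1, 1)))
  expect_equal(e$raw, c(0, 4, 0))
  expect_equal(e$values, c(0, 1, 0))
  expect_equal(e$kind, "dense")
})

test_that("full eigenbasis reconstructs exactly; error shrinks with D'", {
  set.seed(42)
  atoms <- matrix(rnorm(96), 12, 8)
  F <- matrix(rnorm(240), 30, 8)
  f_bar <- colMeans(F)
  full <- fit_dense_model(atoms, f_bar, explained_fraction = 1)
  expect_lt(max(dense_errors(full, F)$raw), 1e-9)
  # nested projections: raw error non-increasing in the component count
  prev <- NULL
  for (j in 1:8) {
    mj <- full
    mj$V <- full$V[, seq_len(j), drop = FALSE]
    ej <- dense_errors(mj, F)$raw
    if (!is.null(prev)) expect_true(all(ej <= prev + 1e-10))
    prev <- ej
  }
})

test_that("sparse coding matches closed forms", {
  # single atom b = 1, target 1, lambda = 1: soft threshold gives 0.5
  ev <- sparse_errors(matrix(1, 1, 1), matrix(1, 1, 1),
                      sparse_config(lambda = 1))
  expect_equal(ev$raw, 0.25, tolerance = 1e-6)
  expect_equal(as.numeric(attr(ev, "alpha")), 0.5, tolerance = 1e-6)
  # target equal to an atom with lambda -> 0 reconstructs exactly
  atoms <- rbind(c(1, 0, 2), c(0, 1, 1))
  ev0 <- sparse_errors(atoms, atoms[1, , drop = FALSE],
                       sparse_config(lambda = 1e-8))
  expect_lt(ev0$raw, 1e-6)
  # lambda -> infinity zeroes the code: error = ||f||^2
  f <- matrix(c(3, -1, 2), 1, 3)
  evi <- sparse_errors(atoms, f, sparse_config(lambda = 1e8))
  expect_equal(evi$raw, sum(f^2))
  expect_equal(as.numeric(attr(evi, "alpha")), c(0, 0))
})

test_that("lambda = 0 is gated behind test mode", {
  expect_error(sparse_config(lambda = 0), "allow_zero_lambda")
  cfg <- sparse_config(lambda = 0, allow_zero_lambda = TRUE)
  atoms <- rbind(c(1, 0), c(0, 1))
  ev <- sparse_errors(atoms, matrix(c(2, 3), 1, 2), cfg)
  expect_lt(ev$raw, 1e-12) # plain least squares on a full-rank dictionary
})

test_that("sparse error is non-decreasing in lambda and tracks the CD oracle", {
  set.seed(123)
  lambdas <- c(0.01, 0.1, 0.5, 2)
  for (rep in 1:25) {
    m <- sample(1:3, 1); d <- sample(2:4, 1)
    atoms <- matrix(rnorm(m * d), m, d)
    f <- matrix(rnorm(d), 1, d)
    prev <- -Inf
    for (lam in lambdas) {
      ev <- sparse_errors(atoms, f, sparse_config(lambda = lam))
      oracle <- lasso_cd_oracle(t(atoms), as.numeric(f), lam)
      expect_lt(abs(ev$raw - oracle$eps), 1e-4 * (1 + oracle$eps))
      expect_gte(ev$raw, prev - 1e-9)
      prev <- ev$raw
    }
  }
})

test_that("sparse solver agrees with glmnet on realistic sizes", {
  skip_if_not_installed("glmnet")
  set.seed(31)
  for (rep in 1:20) {
    d <- 8; m <- sample(4:30, 1)
    X <- matrix(rnorm(d * m), d, m)
    y <- rnorm(d)
    lam <- runif(1, 0.005, 1)
    fit <- bgsal:::.lasso_dual_cpp(X, matrix(y), lam)
    beta <- as.numeric(glmnet::glmnet(
      X, y, lambda = lam / (2 * d), standardize = FALSE,
      intercept = FALSE, thresh = 1e-13, maxit = 1e6)$beta)
    obj <- function(a) sum((y - X %*% a)^2) + lam * sum(abs(a))
    expect_lte(obj(as.numeric(fit$alpha)), obj(beta) + 1e-6 * (1 + obj(beta)))
  }
})

test_that("background atoms score lower errors than object superpixels", {
  suite_scenes <- lapply(c(101L, 202L), function(s) small_scene(s))
  for (sc in suite_scenes) {
    sp <- segment_superpixels(sc$image, 60)
    fe <- extract_features(sc$image, sp)
    bo <- boundary_indices(sp)
    f <- boundary_conductivity(geodesic_distances(build_graph(sp, fe)), bo)
    dic <- refine_dictionary(f, bo)
    atoms <- fe$F[dic$atoms + 1L, , drop = FALSE]
    gtfrac <- tapply(as.vector(sc$gt), as.vector(sp$labels), mean)
    obj_labs <- which(gtfrac > 0.5)
    de <- dense_errors(fit_dense_model(atoms, fe$f_bar), fe)
    se <- sparse_errors(atoms, fe, sparse_config())
    for (e in list(de, se)) {
      expect_gt(mean(e$values[obj_labs]),
                mean(e$values[dic$atoms + 1L]))
    }
  }
})
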