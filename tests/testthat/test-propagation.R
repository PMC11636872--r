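test_that("propagation follows the declared cluster recurrence", {
  # two identical-feature members, errors {1, 0}, nu = 0.5, descending order:
  # first 0.5*0 + 0.5*1 = 0.5, then 0.5*0.5 + 0.5*0 = 0.25
  fe <- feature_stub(matrix(0.4, 2, 8))
  err <- normalize_errors(c(1, 0))
  out <- propagate_errors(fe, err, propagation_config(n_clusters = 1))
  expect_equal(out$raw, c(0.5, 0.25))
  expect_equal(out$values, c(1, 0)) # after min-max re-normalization
})

test_that("nu = 0 leaves errors unchanged; constant clusters stay constant", {
  set.seed(8)
  F <- matrix(runif(40 * 8), 40, 8)
  e0 <- normalize_errors(runif(40))
  out0 <- propagate_errors(feature_stub(F), e0,
                           propagation_config(nu = 0, seed = 2))
  expect_equal(out0$raw, e0$values)
  outc <- propagate_errors(feature_stub(matrix(runif(96), 12, 8)),
                           structure(list(values = rep(0.6, 12), kind = "dense",
                                          normalized = TRUE, raw = rep(0.6, 12)),
                                     class = "error_vector"),
                           propagation_config(n_clusters = 2, seed = 3))
  expect_equal(outc$raw, rep(0.6, 12)) # convex combination of equal values
})

test_that("propagated errors stay within each cluster's input range", {
  set.seed(77)
  for (rep in 1:5) {
    F <- matrix(runif(30 * 8), 30, 8)
    e <- normalize_errors(runif(30))
    cfg <- propagation_config(n_clusters = 4, seed = rep)
    out <- propagate_errors(feature_stub(F), e, cfg)
    set.seed(cfg$seed)
    cl <- stats::kmeans(F, centers = 4, iter.max = 100L, nstart = 3L)$cluster
    for (c in unique(cl)) {
      idx <- cl == c
      expect_gte(min(out$raw[idx]), min(e$values[idx]) - 1e-12)
      expect_lte(max(out$raw[idx]), max(e$values[idx]) + 1e-12)
    }
  }
})

test_that("multiscale pixel lifting computes the similarity-weighted mean", {
  img <- solid_image(1, 1, c(0.5, 0.5, 0.5))
  sp <- structure(list(labels = matrix(0L, 1, 1), k = 1L, scale_id = 1L),
                  class = "superpixel_map")
  pf <- bgsal:::pixel_features(img)
  fe1 <- feature_stub(pf)                  # identical: weight 1
  f2 <- pf; f2[1] <- f2[1] + 20            # squared distance 400 = 2*sigma^2*2
  fe2 <- feature_stub(f2)
  e0 <- structure(list(values = 0, kind = "dense", normalized = TRUE, raw = 0),
                  class = "error_vector")
  e1 <- structure(list(values = 1, kind = "dense", normalized = TRUE, raw = 1),
                  class = "error_vector")
  out <- pixel_errors_multiscale(list(e0, e1), list(sp, sp), list(fe1, fe2),
                                 img, sigma_f = 10)
  expect_equal(out$values[1, 1], exp(-2) / (1 + exp(-2)), tolerance = 1e-9)
  # single scale, uniform errors: constant map
  outc <- pixel_errors_multiscale(list(e1), list(sp), list(fe1), img)
  expect_equal(outc$values[1, 1], 1)
  expect_error(pixel_errors_multiscale(list(), list(), list(), img),
               "at least one")
})

test_that("pixel lifting averages plainly when the pixel matches its superpixel", {
  img <- solid_image(8, 8, c(0.3, 0.6, 0.2))
  sp <- structure(list(labels = matrix(0L, 8, 8), k = 1L, scale_id = 1L),
                  class = "superpixel_map")
  fe <- extract_features(img, sp)
  # spatial feature differs per pixel; drop it by matching features exactly
  evs <- lapply(c(0.2, 0.8), function(v)
    structure(list(values = v, kind = "dense", normalized = TRUE, raw = v),
              class = "error_vector"))
  out <- pixel_errors_multiscale(evs, list(sp, sp), list(fe, fe), img)
  # center pixel features are closest to the superpixel mean: near-plain average
  expect_equal(out$values[4, 4], 0.5, tolerance = 1e-6)
})

test_that("object-biased Gaussian centers on the error-weighted centroid", {
  m <- structure(list(values = matrix(0, 64, 64), provenance = "dense"),
                 class = "pixel_error_map")
  m$values[21, 11] <- 1 # 0-based (x, y) = (10, 20)
  out <- object_biased_reweight(m)
  expect_equal(out$center, c(10, 20))
  expect_equal(out$values[21, 11], 1)
  # symmetric map: center at the image center, values shrink outward
  sym <- structure(list(values = matrix(1, 33, 33), provenance = "dense"),
                   class = "pixel_error_map")
  outs <- object_biased_reweight(sym)
  expect_equal(outs$center, c(16, 16))
  expect_gt(outs$values[17, 17], outs$values[1, 1])
  # all-zero map passes through
  zero <- structure(list(values = matrix(0, 8, 8), provenance = "dense"),
                    class = "pixel_error_map")
  expect_equal(object_biased_reweight(zero)$values, matrix(0, 8, 8))
})

test_that("Bayesian integration fuses and stays in [0, 1]", {
  G <- matrix(0, 32, 32); G[10:20, 8:25] <- 1
  # identical binary maps reproduce themselves
  out <- bayesian_integrate(G, G)
  expect_equal(unclass(out), G, ignore_attr = TRUE)
  # constant second map: posterior is a monotone transform of the prior
  expect_message(
    outc <- bayesian_integrate(G, matrix(0.5, 32, 32)), "degenerate")
  expect_equal(unclass(outc), G, ignore_attr = TRUE)
  set.seed(10)
  Pd <- matrix(runif(32 * 32), 32)
  outg <- suppressMessages(bayesian_integrate(Pd, matrix(0.5, 32, 32)))
  expect_equal(cor(as.vector(outg), as.vector(Pd), method = "spearman"), 1)
  # bounded for random pairs
  for (s in 1:100) {
    set.seed(s)
    A <- matrix(runif(16 * 16), 16)
    B <- matrix(runif(16 * 16), 16)
    out <- bayesian_integrate(A, B)
    expect_gte(min(out), 0)
    expect_lte(max(out), 1)
  }
  expect_error(bayesian_integrate(matrix(0.5, 2, 2), matrix(0.5, 3, 3)),
               "shapes")
})
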