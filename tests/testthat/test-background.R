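test_that("graph edges follow spatial adjacency with feature weights", {
  # 1x3 strip, Lab rows giving d(0,1) = 1, d(1,2) = 2, no (0,2) edge
  sp <- grid_spmap(4, 12, 1, 3)
  F <- matrix(0, 3, 8)
  F[, 4] <- c(0, 1, 3) # L channel
  g <- build_graph(sp, feature_stub(F), "lab")
  ed <- g$edges[order(g$edges$from), ]
  expect_equal(ed$from, c(0, 1))
  expect_equal(ed$to, c(1, 2))
  expect_equal(ed$weight, c(1, 2))
  d <- geodesic_distances(g)
  expect_equal(d[1, 3], 3)
  expect_equal(d, t(d))
  expect_equal(diag(d), rep(0, 3))
})

test_that("uniform features give zero weights and zero geodesics", {
  sp <- grid_spmap(8, 8, 2, 2)
  F <- matrix(0.3, 4, 8)
  g <- build_graph(sp, feature_stub(F))
  expect_true(all(g$edges$weight == 0))
  expect_true(all(geodesic_distances(g) == 0))
})

test_that("two-region step gives cross-edges of weight D, within-region 0", {
  sp <- grid_spmap(8, 8, 2, 2) # labels: 0 1 / 2 3, columns split left-right
  D <- 25
  F <- matrix(0, 4, 8)
  F[c(2, 4), 4] <- D # right column superpixels differ by D in L
  g <- build_graph(sp, feature_stub(F))
  ed <- g$edges
  cross <- (ed$from %in% c(0, 2)) & (ed$to %in% c(1, 3))
  expect_true(all(ed$weight[cross] == D))
  expect_true(all(ed$weight[!cross] == 0))
})

test_that("geodesic distance routes around a heavy edge", {
  # 4-cycle with weights 1, 1, 1, 10: shortest path across the heavy edge
  # accumulates the three light edges [oracle: hand evaluation]
  g <- graph_stub(4, rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 1)),
                  c(1, 1, 1, 10))
  d <- geodesic_distances(g)
  expect_equal(d[4, 1], 3)
  expect_equal(d[1, 3], 2)
})

test_that("boundary conductivity matches closed forms", {
  # zero geodesics, k = 16, k' = 12: area 16, length 12, bc = 3 for every p
  b <- structure(list(indices = 0:11, k_prime = 12L), class = "boundary_set")
  f <- boundary_conductivity(matrix(0, 16, 16), b, sigma = 10)
  expect_equal(f$area, rep(16, 16))
  expect_equal(f$length, rep(12, 16))
  expect_equal(f$bc, rep(3, 16))
  # constant bc flags bc_norm to all ones
  expect_message(
    f2 <- boundary_conductivity(matrix(0, 16, 16), b, 10), "constant")
  expect_equal(f2$bc_norm, rep(1, 16))
  # two boundary superpixels at d_geo 20, sigma 10 [oracle: hand evaluation]
  d <- matrix(c(0, 20, 20, 0), 2, 2)
  b2 <- structure(list(indices = 0:1, k_prime = 2L), class = "boundary_set")
  f3 <- suppressMessages(boundary_conductivity(d, b2, 10))
  expect_equal(f3$area, rep(1 + exp(-2), 2), tolerance = 1e-9)
  expect_equal(f3$bc, rep(sqrt(1 + exp(-2)), 2), tolerance = 1e-9)
  expect_equal(f3$bc[1], 1.06552, tolerance = 1e-5)
  # an isolated interior superpixel has vanishing conductivity
  d4 <- matrix(1e6, 4, 4) - diag(1e6, 4)
  b4 <- structure(list(indices = 0:2, k_prime = 3L), class = "boundary_set")
  f4 <- boundary_conductivity(d4, b4, 10)
  expect_lt(f4$bc[4], 1e-10)
  expect_error(boundary_conductivity(d4, b4, sigma = 0), "sigma")
})

test_that("dictionary refinement applies the adaptive threshold", {
  # bc_norm over B = {1.0, 0.9, 0.2}: population variance 0.126667,
  # tau = 1 - 4 * 0.126667 = 0.493333, kept = the two high-BC members
  field <- list(bc_norm = c(1.0, 0.9, 0.2))
  b <- structure(list(indices = 0:2, k_prime = 3L), class = "boundary_set")
  d <- refine_dictionary(field, b, K = 4)
  expect_equal(d$tau, 1 - 4 * mean((c(1, .9, .2) - mean(c(1, .9, .2)))^2))
  expect_equal(d$tau, 0.4933333, tolerance = 1e-6)
  expect_equal(d$kept, c(0L, 1L))
  expect_true(d$fallback_applied) # 2 < 8 atoms
  expect_equal(d$atoms, 0:2)      # fallback keeps all of a small B
  # zero variance: tau = max, everything kept (>= comparison)
  dz <- refine_dictionary(list(bc_norm = rep(0.7, 5)),
                          structure(list(indices = 0:4, k_prime = 5L),
                                    class = "boundary_set"), K = 4)
  expect_equal(dz$kept, 0:4)
  # variance large enough that tau < 0: everything kept
  dn <- refine_dictionary(list(bc_norm = c(1, 0, 0.5, 0.2, 0.8)),
                          structure(list(indices = 0:4, k_prime = 5L),
                                    class = "boundary_set"), K = 50)
  expect_lt(dn$tau, 0)
  expect_equal(dn$kept, 0:4)
})

test_that("fallback keeps the min_atoms highest-conductivity members", {
  set.seed(9)
  bc <- c(runif(11), 1) # max at label 11
  field <- list(bc_norm = bc)
  b <- structure(list(indices = 0:11, k_prime = 12L), class = "boundary_set")
  d <- refine_dictionary(field, b, K = 0.0001, min_atoms = 8L)
  expect_lt(length(d$kept), 8L)
  expect_equal(d$atoms, sort(order(bc, decreasing = TRUE)[1:8] - 1L))
})

test_that("bc values are invariant to label permutation", {
  sc <- small_scene()
  sp <- segment_superpixels(sc$image, 30)
  fe <- extract_features(sc$image, sp)
  bo <- boundary_indices(sp)
  f1 <- boundary_conductivity(geodesic_distances(build_graph(sp, fe)), bo)
  set.seed(21)
  perm <- sample(sp$k) - 1L # perm[old + 1] = new label
  sp2 <- sp
  sp2$labels <- matrix(perm[sp$labels + 1L], nrow(sp$labels))
  fe2 <- extract_features(sc$image, sp2)
  bo2 <- boundary_indices(sp2)
  f2 <- boundary_conductivity(geodesic_distances(build_graph(sp2, fe2)), bo2)
  expect_equal(f2$bc[perm + 1L], f1$bc, tolerance = 1e-9)
})

test_that("adding a nearby boundary superpixel never decreases length", {
  set.seed(4)
  pts <- matrix(runif(20), 10, 2)
  dg <- as.matrix(stats::dist(pts)) * 30
  for (nb in 3:8) {
    b1 <- structure(list(indices = 0:(nb - 1), k_prime = nb),
                    class = "boundary_set")
    b2 <- structure(list(indices = 0:nb, k_prime = nb + 1L),
                    class = "boundary_set")
    l1 <- boundary_conductivity(dg, b1, 10)$length
    l2 <- boundary_conductivity(dg, b2, 10)$length
    expect_true(all(l2 >= l1 - 1e-12))
  }
})
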