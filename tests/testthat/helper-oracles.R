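# Shared fixtures and independent oracles, built in code.

# H x W label matrix tiling the image into an nrows x ncols block grid,
# labels 0..(nrows*ncols - 1) in row-major block order
make_grid_labels <- function(H, W, nrows, ncols) {
  ri <- findInterval(seq_len(H) - 1, seq(0, H, length.out = nrows + 1),
                     rightmost.closed = TRUE)
  ci <- findInterval(seq_len(W) - 1, seq(0, W, length.out = ncols + 1),
                     rightmost.closed = TRUE)
  outer(ri - 1, ci - 1, function(r, c) r * ncols + c)
}

grid_spmap <- function(H, W, nrows, ncols) {
  labels <- make_grid_labels(H, W, nrows, ncols)
  structure(list(labels = labels, k = nrows * ncols, scale_id = 1L),
            class = "superpixel_map")
}

solid_image <- function(H, W, rgb) {
  array(rep(rgb, each = H * W), dim = c(H, W, 3))
}

# plain feature_matrix around a given k x 8 matrix
feature_stub <- function(F) {
  structure(list(F = F, f_bar = colMeans(F), k = nrow(F)),
            class = "feature_matrix")
}

# wrap an igraph into the superpixel_graph contract (for geodesic tests)
graph_stub <- function(k, edges, weights) {
  g <- igraph::make_empty_graph(n = k, directed = FALSE)
  g <- igraph::add_edges(g, as.vector(t(edges)))
  igraph::E(g)$weight <- weights
  structure(list(graph = g,
                 edges = data.frame(from = edges[, 1] - 1L,
                                    to = edges[, 2] - 1L, weight = weights),
                 k = k, feature_subset = "lab"),
            class = "superpixel_graph")
}

# brute-force coordinate-descent lasso oracle (R implementation, independent
# of the package's dual-barrier solver); adequate on small well-conditioned
# problems only
lasso_cd_oracle <- function(X, y, lambda, tol = 1e-13, maxit = 100000L) {
  X <- as.matrix(X)
  m <- ncol(X)
  xn <- colSums(X^2)
  alpha <- numeric(m)
  r <- y
  for (it in seq_len(maxit)) {
    delta <- 0
    for (j in seq_len(m)) {
      if (xn[j] <= 0) next
      old <- alpha[j]
      rho <- sum(X[, j] * r) + xn[j] * old
      new <- sign(rho) * max(abs(rho) - lambda / 2, 0) / xn[j]
      if (new != old) {
        r <- r + X[, j] * (old - new)
        alpha[j] <- new
        delta <- max(delta, xn[j] * (old - new)^2)
      }
    }
    if (delta < tol * max(sum(y^2), 1)) break
  }
  list(alpha = alpha, eps = sum((y - X %*% alpha)^2))
}

# rank-based (Mann-Whitney) AUC with midrank tie handling
rank_auc_oracle <- function(s, g) {
  s <- as.vector(s); g <- as.vector(g)
  np <- sum(g == 1); nn <- sum(g == 0)
  r <- rank(s)
  (sum(r[g == 1]) - np * (np + 1) / 2) / (np * nn)
}

# one small object scene for quick pipeline checks
small_scene <- function(seed = 5L) {
  spec <- scene_spec(
    size = c(64L, 64L), background = "uniform",
    objects = list(list(shape = "ellipse", center = c(31, 31),
                        size = c(12, 10), touches_border = FALSE)),
    contrast = 60, noise_sd = 0.02, seed = seed)
  make_scene(spec)
}
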