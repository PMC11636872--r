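# Error propagation, multiscale pixel lifting, object-biased Gaussian, and
# Bayesian fusion of the dense and sparse maps.

#' Propagation configuration
#'
#' @param n_clusters number of K-means clusters over the 8-dim features;
#'   default 8 (reduced automatically when fewer distinct rows exist).
#' @param nu mix weight between the cluster-context average and a
#'   superpixel's own error, in `[0, 1]`; default 0.5.
#' @param sigma_f Gaussian similarity bandwidth in feature units; default 10.
#' @param seed integer seed for the K-means initialization.
#' @return a `propagation_config` list.
#' @export
propagation_config <- function(n_clusters = 8L, nu = 0.5, sigma_f = 10,
                               seed = 1L) {
  if (nu < 0 || nu > 1) stop("nu must be in [0, 1]")
  if (n_clusters < 1L) stop("n_clusters must be >= 1")
  if (sigma_f <= 0) stop("sigma_f must be positive")
  structure(list(n_clusters = as.integer(n_clusters), nu = nu,
                 sigma_f = sigma_f, seed = as.integer(seed)),
            class = "propagation_config")
}

#' Smooth reconstruction errors by cluster-context propagation
#'
#' Superpixels are grouped into appearance clusters by K-means on their
#' 8-dim features. Within each cluster, members are visited in descending
#' order of initial error and updated to
#' `e_i <- nu * weighted_mean(e_j, j != i) + (1 - nu) * e_i`, where the
#' weights `w_ij = exp(-||f_i - f_j||^2 / (2 sigma_f^2))` favor look-alike
#' members and already-visited members contribute their updated values.
#' High errors leaking onto look-alike background regions (and vice versa)
#' are thereby pulled toward their cluster context. The result is min-max
#' re-normalized; pre-normalization values are kept in `$raw`.
#'
#' @param features a `feature_matrix`.
#' @param errors a normalized `error_vector`.
#' @param config a [propagation_config()].
#' @return an `error_vector` with the same `kind`.
#' @export
propagate_errors <- function(features, errors, config = propagation_config()) {
  Fm <- features$F
  e0 <- errors$values
  k <- nrow(Fm)
  n_distinct <- nrow(unique(Fm))
  N <- min(config$n_clusters, n_distinct)
  if (N < 2L || k < 2L) {
    cl <- rep(1L, k)
  } else {
    set.seed(config$seed)
    cl <- stats::kmeans(Fm, centers = N, iter.max = 100L, nstart = 3L)$cluster
  }
  e <- e0
  s2 <- 2 * config$sigma_f^2
  for (c in unique(cl)) {
    members <- which(cl == c)
    if (length(members) < 2L) next
    ord <- members[order(e0[members], decreasing = TRUE)]
    for (i in ord) {
      others <- members[members != i]
      w <- exp(-rowSums((Fm[others, , drop = FALSE] -
                         matrix(Fm[i, ], length(others), ncol(Fm), byrow = TRUE))^2) / s2)
      ctx <- if (sum(w) <= .Machine$double.xmin) mean(e[others])
             else sum(w * e[others]) / sum(w)
      e[i] <- config$nu * ctx + (1 - config$nu) * e0[i]
    }
  }
  new_error_vector(minmax01(e), errors$kind, raw = e)
}

# per-pixel [R,G,B,L,a,b,x,y] features, rows in column-major pixel order
pixel_features <- function(image) {
  H <- dim(image)[1]; W <- dim(image)[2]
  rgb <- cbind(as.vector(image[, , 1]), as.vector(image[, , 2]),
               as.vector(image[, , 3]))
  xy <- pixel_coords(H, W)
  cbind(rgb, srgb_to_lab(rgb), xy$x, xy$y)
}

#' Lift multiscale superpixel errors to a pixel-level error map
#'
#' Every pixel receives the similarity-weighted mean of its superpixel's
#' propagated error across scales:
#' `E(z) = sum_s w_s(z) e_s(sp_s(z)) / sum_s w_s(z)` with
#' `w_s(z) = exp(-||feat(z) - f_(sp_s(z))||^2 / (2 sigma_f^2))`, where
#' `feat(z)` is the pixel's own 8-dim feature. Scales where the pixel is
#' atypical for its superpixel are down-weighted, which sharpens object
#' boundaries. The output stays in `[0, 1]` (convex combination of
#' normalized errors).
#'
#' @param errors list of `error_vector`s, one per scale.
#' @param spmaps list of matching `superpixel_map`s.
#' @param features list of matching `feature_matrix`s.
#' @param image the H x W x 3 source image.
#' @param sigma_f similarity bandwidth; default 10.
#' @return a `pixel_error_map`: list with `values` (H x W matrix in
#'   `[0, 1]`) and `provenance` (the kind of the input errors).
#' @export
pixel_errors_multiscale <- function(errors, spmaps, features, image,
                                    sigma_f = 10) {
  ns <- length(errors)
  if (ns == 0L) stop("need at least one scale")
  if (length(spmaps) != ns || length(features) != ns)
    stop("errors, spmaps and features must align by scale")
  assert_image(image)
  H <- dim(image)[1]; W <- dim(image)[2]
  pf <- pixel_features(image)
  s2 <- 2 * sigma_f^2
  num <- den <- numeric(H * W)
  plain <- numeric(H * W)
  for (s in seq_len(ns)) {
    lab1 <- as.vector(spmaps[[s]]$labels) + 1L
    fs <- features[[s]]$F[lab1, , drop = FALSE]
    w <- exp(-rowSums((pf - fs)^2) / s2)
    v <- errors[[s]]$values[lab1]
    num <- num + w * v
    den <- den + w
    plain <- plain + v / ns
  }
  vals <- ifelse(den > .Machine$double.xmin, num / den, plain)
  structure(list(values = matrix(vals, H, W), provenance = errors[[1]]$kind),
            class = "pixel_error_map")
}

#' Re-weight a pixel error map by an object-biased Gaussian
#'
#' A 2-D Gaussian centered at the error-weighted centroid of the map itself
#' (not the image center) multiplies the map, concentrating saliency around
#' the estimated object location without assuming the object is centered.
#' The result is min-max re-normalized.
#'
#' @param map a `pixel_error_map`.
#' @param sigma_x,sigma_y Gaussian widths in pixels; default `W/4`, `H/4`.
#' @return a `pixel_error_map` with the centroid in `$center` (0-based
#'   `(x, y)` pixel coordinates).
#' @export
object_biased_reweight <- function(map, sigma_x = NULL, sigma_y = NULL) {
  v <- map$values
  H <- nrow(v); W <- ncol(v)
  if (is.null(sigma_x)) sigma_x <- W / 4
  if (is.null(sigma_y)) sigma_y <- H / 4
  x <- rep(seq_len(W) - 1L, each = H)
  y <- rep(seq_len(H) - 1L, times = W)
  tot <- sum(v)
  if (tot <= 0) {
    center <- c((W - 1) / 2, (H - 1) / 2)
    out <- v
  } else {
    center <- c(sum(v * x) / tot, sum(v * y) / tot)
    g <- exp(-((x - center[1])^2 / (2 * sigma_x^2) +
               (y - center[2])^2 / (2 * sigma_y^2)))
    out <- matrix(minmax01(as.vector(v) * g), H, W)
  }
  structure(list(values = out, provenance = map$provenance, center = center),
            class = "pixel_error_map")
}

# posterior of Q given prior P: split pixels at mean(P) into putative
# foreground/background, model Q by Laplace-smoothed histograms inside each
# region, and apply Bayes' rule pixelwise
posterior_with_prior <- function(P, Q, bins) {
  p <- as.vector(P); q <- as.vector(Q)
  fg <- p >= mean(p)
  nf <- sum(fg); nb <- length(p) - nf
  if (nf == 0L || nb == 0L) {
    message("degenerate prior split; posterior falls back to the prior")
    return(P)
  }
  bin <- pmin(floor(q * bins) + 1L, bins)
  cf <- tabulate(bin[fg], nbins = bins)
  cb <- tabulate(bin[!fg], nbins = bins)
  lf <- (cf[bin] + 1) / (nf + bins)
  lb <- (cb[bin] + 1) / (nb + bins)
  post <- p * lf / (p * lf + (1 - p) * lb)
  matrix(post, nrow(P), ncol(P))
}

#' Fuse dense and sparse pixel error maps by Bayesian integration
#'
#' Each map serves as the prior for the other: pixels are split at the
#' prior's mean into putative foreground/background regions, the other
#' map's values are modeled by Laplace-smoothed histograms within each
#' region, and the pixelwise posterior is computed from Bayes' rule. The
#' two posteriors are averaged and min-max normalized into the final
#' saliency map.
#'
#' @param S_d,S_s `pixel_error_map`s (or plain H x W matrices in `[0, 1]`)
#'   of dense and sparse provenance.
#' @param bins histogram resolution for the likelihoods; default 64.
#' @return a `saliency_map` (H x W matrix in `[0, 1]` with a class
#'   attribute).
#' @export
bayesian_integrate <- function(S_d, S_s, bins = 64L) {
  Pd <- if (inherits(S_d, "pixel_error_map")) S_d$values else S_d
  Ps <- if (inherits(S_s, "pixel_error_map")) S_s$values else S_s
  if (!identical(dim(Pd), dim(Ps))) stop("map shapes differ")
  if (min(Pd, Ps) < 0 || max(Pd, Ps) > 1) stop("maps must lie in [0, 1]")
  post1 <- posterior_with_prior(Pd, Ps, bins)
  post2 <- posterior_with_prior(Ps, Pd, bins)
  out <- matrix(minmax01(as.vector((post1 + post2) / 2)), nrow(Pd), ncol(Pd))
  structure(out, class = c("saliency_map", "matrix"))
}
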