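# Saliency mask initialization and the pluggable refinement hook.

new_binary_mask <- function(values, source = "initial") {
  structure(list(values = values, source = source), class = "binary_mask")
}

#' Otsu threshold of a [0, 1] map
#'
#' Exhaustive search over the 256-bin histogram for the threshold
#' maximizing between-class variance; ties resolve to the smallest
#' threshold. Returns the threshold on the `[0, 1]` scale.
#'
#' @param v numeric vector or matrix of values in `[0, 1]`.
#' @return scalar threshold `t` such that `v >= t` is the foreground class.
#' @export
otsu_threshold <- function(v) {
  b <- pmin(pmax(as.integer(round(as.vector(v) * 255)), 0L), 255L)
  counts <- tabulate(b + 1L, nbins = 256L)
  n <- sum(counts)
  csum <- cumsum(counts)
  cmu <- cumsum(counts * (0:255))
  mu <- cmu[256]
  # class split at T: background bins 0..T-1, foreground bins T..255
  Tcand <- 1:255
  n0 <- csum[Tcand]
  n1 <- n - n0
  m0 <- ifelse(n0 > 0, cmu[Tcand] / n0, 0)
  m1 <- ifelse(n1 > 0, (mu - cmu[Tcand]) / n1, 0)
  sb <- n0 * n1 * (m0 - m1)^2
  Tcand[which.max(sb)] / 255
}

#' Threshold a saliency map into a binary mask
#'
#' @param map a `saliency_map` or H x W matrix in `[0, 1]`.
#' @param method `"otsu"` (parameter-free, default) or `"fixed"`.
#' @param fixed_t threshold used when `method = "fixed"`.
#' @return a `binary_mask` with `source = "initial"`. A constant map yields
#'   an all-zero mask with attribute `degenerate = TRUE` and a message.
#' @export
threshold_mask <- function(map, method = c("otsu", "fixed"), fixed_t = 0.5) {
  method <- match.arg(method)
  v <- unclass(map)
  if (min(v) < 0 || max(v) > 1) stop("map values must lie in [0, 1]")
  if (diff(range(v)) == 0) {
    message("constant saliency map; returning an empty mask")
    out <- new_binary_mask(matrix(0L, nrow(v), ncol(v)))
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  t <- if (method == "otsu") otsu_threshold(v) else fixed_t
  out <- new_binary_mask((v >= t) + 0L)
  attr(out, "threshold") <- t
  out
}

remove_small_components <- function(v, min_frac = 0.10) {
  comp <- .label_components_cpp(v, 8L)
  if (max(comp) == 0L) return(v)
  areas <- tabulate(comp[comp > 0L])
  keep <- areas >= min_frac * max(areas) # strict removal of < 10%
  out <- matrix(0L, nrow(v), ncol(v))
  out[comp > 0L][keep[comp[comp > 0L]]] <- 1L
  out
}

fill_holes <- function(v) {
  bg <- 1L - v
  comp <- .label_components_cpp(bg, 4L)
  H <- nrow(v); W <- ncol(v)
  border <- unique(c(comp[1, ], comp[H, ], comp[, 1], comp[, W]))
  border <- border[border > 0L]
  holes <- comp > 0L & !(comp %in% border)
  v[holes] <- 1L
  v
}

#' Clean a binary mask: drop speckle components, fill holes
#'
#' Removes 8-connected components whose area is strictly below 10% of the
#' largest component's area, fills interior holes (4-connected background
#' regions not reaching the image border), then applies the size rule once
#' more so the result is a fixed point of the operation (filling can grow
#' the largest component and re-expose undersized ones).
#'
#' @param mask a `binary_mask` or 0/1 matrix.
#' @param min_frac area fraction below which a component is removed.
#' @return a `binary_mask`; an empty mask is returned unchanged.
#' @export
clean_mask <- function(mask, min_frac = 0.10) {
  v <- if (inherits(mask, "binary_mask")) mask$values else mask
  assert_binary(v)
  src <- if (inherits(mask, "binary_mask")) mask$source else "initial"
  if (sum(v) == 0) return(new_binary_mask(v, src))
  v <- remove_small_components(v, min_frac)
  v <- fill_holes(v)
  v <- remove_small_components(v, min_frac)
  new_binary_mask(v, src)
}

#' Apply an external mask refiner
#'
#' Stand-in hook for heavyweight segmentation-refinement models: `refiner`
#' is any callable taking `(image, mask_matrix)` and returning a same-shape
#' binary matrix. The default is the identity.
#'
#' @param image H x W x 3 array in `[0, 1]`.
#' @param mask a `binary_mask` or 0/1 matrix.
#' @param refiner `function(image, mask_values) -> 0/1 matrix`, or `NULL`
#'   for identity.
#' @return a `binary_mask` with `source = "refined"`.
#' @export
apply_refiner <- function(image, mask, refiner = NULL) {
  v <- if (inherits(mask, "binary_mask")) mask$values else mask
  assert_binary(v)
  if (is.null(refiner)) return(new_binary_mask(v, "refined"))
  out <- refiner(image, v)
  if (inherits(out, "binary_mask")) out <- out$values
  if (!is.matrix(out) || !identical(dim(out), dim(v)))
    stop("refiner returned a mask of the wrong shape")
  if (!all(out %in% c(0, 1)))
    stop("refiner returned a non-binary mask")
  new_binary_mask(out + 0L, "refined")
}
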