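# Image abstraction: SLIC superpixels, per-region features, boundary set.

#' Segment an image into SLIC superpixels
#'
#' Runs Simple Linear Iterative Clustering in CIE-Lab space: cluster centers
#' are seeded on a regular grid (spacing ~ sqrt(HW/n)), pixels are assigned
#' within a 2S x 2S window by the joint color + compactness-weighted spatial
#' distance for a fixed number of sweeps, and connectivity is enforced by
#' merging fragments below a quarter of the nominal cell area into an
#' adjacent superpixel. The procedure is fully deterministic; `seed` is
#' accepted for interface stability but grid seeding does not consume it.
#'
#' @param image H x W x 3 array, values in `[0, 1]`.
#' @param n_segments requested superpixel count (>= 4); the realized count
#'   `k` can differ slightly after connectivity enforcement.
#' @param compactness spatial regularization weight `m`; larger values give
#'   squarer superpixels. Default 10.
#' @param seed integer, kept for reproducibility bookkeeping.
#' @param scale_id integer tag identifying the scale this map belongs to.
#' @param n_iter number of assignment/update sweeps.
#' @return a `superpixel_map`: list with `labels` (H x W integer matrix,
#'   values `0..k-1`), `k`, and `scale_id`.
#' @export
segment_superpixels <- function(image, n_segments, compactness = 10,
                                seed = 1L, scale_id = 1L, n_iter = 10L) {
  assert_image(image)
  H <- dim(image)[1]; W <- dim(image)[2]
  if (H < 4L || W < 4L)
    stop(sprintf("image too small to segment (%d x %d; need >= 4 x 4)", H, W))
  if (n_segments < 4L)
    stop("n_segments must be >= 4")
  if (n_segments > H * W)
    stop("n_segments exceeds the pixel count")
  if (compactness <= 0) stop("compactness must be positive")
  lab <- srgb_to_lab(cbind(as.vector(image[, , 1]),
                           as.vector(image[, , 2]),
                           as.vector(image[, , 3])))
  labels <- .slic_cpp(matrix(lab[, 1], H, W), matrix(lab[, 2], H, W),
                      matrix(lab[, 3], H, W),
                      as.integer(n_segments), compactness, as.integer(n_iter))
  structure(
    list(labels = labels, k = max(labels) + 1L, scale_id = as.integer(scale_id)),
    class = "superpixel_map"
  )
}

#' @export
print.superpixel_map <- function(x, ...) {
  cat(sprintf("superpixel_map: %d x %d pixels, k = %d (scale %d)\n",
              nrow(x$labels), ncol(x$labels), x$k, x$scale_id))
  invisible(x)
}

#' Extract per-superpixel feature descriptors
#'
#' Each superpixel is described by the 8-vector
#' `f = [R, G, B, L, a, b, x, y]`: mean RGB (in `[0, 1]`), mean CIE-Lab
#' (native units), and the centroid of its pixel centers with 0-based
#' coordinates normalized by `(W-1, H-1)` so the spatial features are
#' resolution independent.
#'
#' @param image H x W x 3 array in `[0, 1]`.
#' @param spmap matching `superpixel_map`.
#' @return a `feature_matrix`: list with `F` (k x 8 matrix), `f_bar`
#'   (column mean of `F`), and `k`.
#' @export
extract_features <- function(image, spmap) {
  assert_image(image)
  if (!identical(dim(image)[1:2], dim(spmap$labels)))
    stop("label map shape does not match the image")
  H <- dim(image)[1]; W <- dim(image)[2]
  lab1 <- as.vector(spmap$labels) + 1L
  rgb <- cbind(as.vector(image[, , 1]), as.vector(image[, , 2]),
               as.vector(image[, , 3]))
  labv <- srgb_to_lab(rgb)
  xy <- pixel_coords(H, W)
  feats <- cbind(rgb, labv, xy$x, xy$y)
  counts <- tabulate(lab1, nbins = spmap$k)
  Fm <- rowsum(feats, lab1, reorder = TRUE) / counts
  colnames(Fm) <- c("R", "G", "B", "L", "a", "b", "x", "y")
  rownames(Fm) <- NULL
  structure(
    list(F = Fm, f_bar = colMeans(Fm), k = spmap$k),
    class = "feature_matrix"
  )
}

#' Superpixels touching the image border
#'
#' @param spmap a `superpixel_map`.
#' @return a `boundary_set`: list with `indices` (sorted 0-based labels
#'   owning at least one border pixel) and `k_prime` (its size).
#' @export
boundary_indices <- function(spmap) {
  l <- spmap$labels
  H <- nrow(l); W <- ncol(l)
  idx <- sort(unique(c(l[1, ], l[H, ], l[, 1], l[, W])))
  structure(list(indices = as.integer(idx), k_prime = length(idx)),
            class = "boundary_set")
}
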