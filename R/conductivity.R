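# Boundary conductivity and background-dictionary refinement.

#' Boundary conductivity of every superpixel
#'
#' Soft connectivity to the image border over the geodesic graph. With
#' `A(p, q) = exp(-d_geo(p, q)^2 / (2 sigma^2))`, the soft area of `p` is
#' `Area(p) = sum_i A(p, p_i)` over all k superpixels, its border length is
#' `Length(p) = sum_i A(p, p_i) * delta(p_i on border)`, and the boundary
#' conductivity is `BC(p) = Length(p) / sqrt(Area(p))` -- the square root
#' makes the measure scale invariant, so on a homogeneous image
#' `BC = k' / sqrt(k)` at every patch scale. High conductivity means the
#' region is strongly linked to the border and therefore likely background.
#'
#' @param d_geo k x k geodesic distance matrix from [geodesic_distances()].
#' @param boundary a `boundary_set`.
#' @param sigma bandwidth of the area kernel, in appearance-distance units;
#'   default 10.
#' @return a `conductivity_field`: list with `d_geo`, `A`, `area`, `length`,
#'   `bc`, `bc_norm` (min-max over all k superpixels; all ones when `bc` is
#'   constant), and `sigma`.
#' @export
boundary_conductivity <- function(d_geo, boundary, sigma = 10) {
  if (sigma <= 0) stop("sigma must be positive")
  k <- nrow(d_geo)
  A <- exp(-d_geo^2 / (2 * sigma^2))
  area <- rowSums(A)
  len <- rowSums(A[, boundary$indices + 1L, drop = FALSE])
  bc <- len / sqrt(area)
  rng <- range(bc)
  if (rng[2] - rng[1] == 0) {
    message("boundary conductivity is constant; bc_norm set to all ones")
    bc_norm <- rep(1, k)
  } else {
    bc_norm <- (bc - rng[1]) / (rng[2] - rng[1])
  }
  structure(
    list(d_geo = d_geo, A = A, area = area, length = len, bc = bc,
         bc_norm = bc_norm, sigma = sigma),
    class = "conductivity_field"
  )
}

#' Refine the background dictionary by thresholding conductivity
#'
#' Boundary superpixels whose normalized conductivity falls below the
#' adaptive threshold `tau = max(bc_norm over B) - K * var(bc_norm over B)`
#' (population variance) are deemed parts of a near-boundary salient object
#' and dropped from the dictionary. `kept` is this pure threshold set; the
#' pipeline consumes `atoms`, which falls back to the `min_atoms`
#' highest-conductivity members of `B` (or all of `B` when `k' < min_atoms`)
#' so the downstream PCA/L1 models never degenerate.
#'
#' @param field a `conductivity_field`.
#' @param boundary the `boundary_set` B.
#' @param K threshold strength; default 4.
#' @param min_atoms minimum dictionary size before the fallback engages.
#' @return a `refined_dictionary`: list with `initial`, `kept`, `atoms`,
#'   `tau`, `K`, `bc_values` (bc_norm over B, named by label), and
#'   `fallback_applied`.
#' @export
refine_dictionary <- function(field, boundary, K = 4, min_atoms = 8L) {
  idx <- boundary$indices
  if (length(idx) == 0L) stop("boundary set is empty")
  v <- field$bc_norm[idx + 1L]
  names(v) <- idx
  tau <- max(v) - K * mean((v - mean(v))^2)
  kept <- idx[v >= tau]
  fallback <- length(kept) < min_atoms
  atoms <- if (fallback) {
    ord <- order(v, decreasing = TRUE)
    sort(idx[ord[seq_len(min(min_atoms, length(idx)))]])
  } else {
    kept
  }
  structure(
    list(initial = boundary, kept = sort(kept), atoms = atoms, tau = tau,
         K = K, bc_values = v, fallback_applied = fallback),
    class = "refined_dictionary"
  )
}

#' @export
print.refined_dictionary <- function(x, ...) {
  cat(sprintf(
    "refined_dictionary: %d of %d boundary superpixels kept (tau = %.4f%s)\n",
    length(x$kept), x$initial$k_prime, x$tau,
    if (x$fallback_applied) "; min-atom fallback applied" else ""))
  invisible(x)
}

#' Write per-superpixel conductivity diagnostics as CSV
#'
#' @param field a `conductivity_field`.
#' @param dict a `refined_dictionary` for the same image.
#' @param path destination CSV path.
#' @export
write_conductivity_csv <- function(field, dict, path) {
  k <- length(field$bc)
  lab <- 0:(k - 1)
  df <- data.frame(
    label = lab,
    bc = field$bc,
    bc_norm = field$bc_norm,
    on_boundary = lab %in% dict$initial$indices,
    kept = lab %in% dict$kept,
    atom = lab %in% dict$atoms
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
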