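# End-to-end saliency detection pipeline.

#' Pipeline configuration
#'
#' Bundles every tunable of the detection pipeline with its default.
#'
#' @param scales superpixel counts, one per scale; default
#'   `c(50, 100, 150, 200, 250, 300, 350, 400)`.
#' @param compactness SLIC spatial regularization; default 10.
#' @param feature_subset appearance distance on the geodesic graph:
#'   `"lab"` (default) or `"full"`.
#' @param sigma boundary-conductivity area bandwidth; default 10.
#' @param K conductivity threshold strength; default 4.
#' @param min_atoms minimum background-dictionary size; default 8.
#' @param refine_dict refine the boundary dictionary (TRUE, default) or use
#'   the whole boundary set (the naive background prior, kept for ablation).
#' @param lambda sparse-coding L1 penalty; default 0.01.
#' @param explained_fraction PCA eigenvalue share retained; default 0.95.
#' @param n_clusters,nu,sigma_f error-propagation parameters (K-means
#'   cluster count, context mix weight, similarity bandwidth).
#' @param bins histogram resolution of the Bayesian fusion; default 64.
#' @param sigma_x,sigma_y object-biased Gaussian widths in pixels; `NULL`
#'   (default) means `W/4` and `H/4`.
#' @param threshold_method `"otsu"` (default) or `"fixed"`.
#' @param fixed_t threshold when `threshold_method = "fixed"`.
#' @param seed master seed for every stochastic stage (K-means).
#' @return a `sod_config` list.
#' @export
sod_config <- function(scales = c(50L, 100L, 150L, 200L, 250L, 300L, 350L, 400L),
                       compactness = 10, feature_subset = "lab",
                       sigma = 10, K = 4, min_atoms = 8L, refine_dict = TRUE,
                       lambda = 0.01, explained_fraction = 0.95,
                       n_clusters = 8L, nu = 0.5, sigma_f = 10,
                       bins = 64L, sigma_x = NULL, sigma_y = NULL,
                       threshold_method = "otsu", fixed_t = 0.5, seed = 1L) {
  feature_subset <- match.arg(feature_subset, c("lab", "full"))
  threshold_method <- match.arg(threshold_method, c("otsu", "fixed"))
  stopifnot(length(scales) >= 1, all(scales >= 4), compactness > 0,
            sigma > 0, K >= 0, min_atoms >= 1, lambda > 0,
            explained_fraction > 0, explained_fraction <= 1,
            n_clusters >= 1, nu >= 0, nu <= 1, sigma_f > 0, bins >= 2,
            fixed_t >= 0, fixed_t <= 1)
  structure(list(
    scales = as.integer(scales), compactness = compactness,
    feature_subset = feature_subset, sigma = sigma, K = K,
    min_atoms = as.integer(min_atoms), refine_dict = isTRUE(refine_dict),
    lambda = lambda, explained_fraction = explained_fraction,
    n_clusters = as.integer(n_clusters), nu = nu, sigma_f = sigma_f,
    bins = as.integer(bins), sigma_x = sigma_x, sigma_y = sigma_y,
    threshold_method = threshold_method, fixed_t = fixed_t,
    seed = as.integer(seed)
  ), class = "sod_config")
}

#' Write a pipeline configuration to JSON
#' @param config a [sod_config()].
#' @param path destination path.
#' @export
write_sod_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' Read a pipeline configuration from JSON
#' @param path a file written by [write_sod_config()].
#' @return a validated `sod_config`.
#' @export
read_sod_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(sod_config, raw)
}

#' Detect the salient object in an image
#'
#' Runs the full pipeline at each superpixel scale -- segmentation, feature
#' extraction, geodesic graph, boundary-conductivity dictionary refinement,
#' dense and sparse reconstruction errors, cluster-context propagation --
#' then lifts the per-scale errors to pixel level, applies the object-biased
#' Gaussian, fuses the dense and sparse maps by Bayesian integration, and
#' thresholds/cleans the result into the initial mask. Deterministic for a
#' fixed config.
#'
#' @param image H x W x 3 array in `[0, 1]`.
#' @param config a [sod_config()].
#' @param refiner optional external mask refiner, see [apply_refiner()].
#' @param keep_intermediates also return per-scale and per-branch objects.
#' @return list with `saliency` (`saliency_map`), `initial_mask`,
#'   `refined_mask` (both `binary_mask`), `config`, and (optionally)
#'   `intermediates`.
#' @export
detect <- function(image, config = sod_config(), refiner = NULL,
                   keep_intermediates = FALSE) {
  assert_image(image)
  npix <- prod(dim(image)[1:2])
  scales <- config$scales[config$scales <= npix / 4]
  if (length(scales) == 0) stop("image too small for every configured scale")
  spmaps <- features <- dicts <- list()
  dense_list <- sparse_list <- list()
  scfg <- sparse_config(config$lambda)
  for (s in seq_along(scales)) {
    spmap <- with_stage("segmentation",
      segment_superpixels(image, scales[s], config$compactness,
                          seed = config$seed, scale_id = s))
    feats <- with_stage("features", extract_features(image, spmap))
    boundary <- with_stage("boundary", boundary_indices(spmap))
    graph <- with_stage("graph",
      build_graph(spmap, feats, config$feature_subset))
    d_geo <- with_stage("geodesic", geodesic_distances(graph))
    field <- with_stage("conductivity",
      boundary_conductivity(d_geo, boundary, config$sigma))
    dict <- with_stage("refine_dictionary",
      refine_dictionary(field, boundary, config$K, config$min_atoms))
    atom_idx <- if (config$refine_dict) dict$atoms else boundary$indices
    atoms <- feats$F[atom_idx + 1L, , drop = FALSE]
    dmodel <- with_stage("dense_model",
      fit_dense_model(atoms, feats$f_bar, config$explained_fraction))
    de <- with_stage("dense_errors", dense_errors(dmodel, feats))
    se <- with_stage("sparse_errors", sparse_errors(atoms, feats, scfg))
    pcfg <- propagation_config(config$n_clusters, config$nu, config$sigma_f,
                               seed = config$seed + 97L * s)
    de <- with_stage("propagation", propagate_errors(feats, de, pcfg))
    se <- with_stage("propagation", propagate_errors(feats, se, pcfg))
    spmaps[[s]] <- spmap; features[[s]] <- feats; dicts[[s]] <- dict
    dense_list[[s]] <- de; sparse_list[[s]] <- se
  }
  dmap <- with_stage("pixel_errors",
    pixel_errors_multiscale(dense_list, spmaps, features, image, config$sigma_f))
  smap <- with_stage("pixel_errors",
    pixel_errors_multiscale(sparse_list, spmaps, features, image, config$sigma_f))
  dmap_b <- with_stage("object_bias",
    object_biased_reweight(dmap, config$sigma_x, config$sigma_y))
  smap_b <- with_stage("object_bias",
    object_biased_reweight(smap, config$sigma_x, config$sigma_y))
  sal <- with_stage("bayesian_integration",
    bayesian_integrate(dmap_b, smap_b, config$bins))
  initial <- with_stage("threshold",
    threshold_mask(sal, config$threshold_method, config$fixed_t))
  initial <- with_stage("clean", clean_mask(initial))
  refined <- with_stage("refiner", apply_refiner(image, initial, refiner))
  out <- list(saliency = sal, initial_mask = initial, refined_mask = refined,
              config = config)
  if (keep_intermediates) {
    out$intermediates <- list(
      spmaps = spmaps, features = features, dicts = dicts,
      dense_errors = dense_list, sparse_errors = sparse_list,
      dense_map = dmap, sparse_map = smap,
      dense_map_biased = dmap_b, sparse_map_biased = smap_b)
  }
  out
}
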