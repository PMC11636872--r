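# Saliency evaluation suite: MAE, PR/F-measures, ROC/AUC, S-measure,
# E-measure, IOU, and dataset-level aggregation.

#' Metric configuration
#'
#' @param beta_sq beta^2 of the weighted F-measure; default 0.3 (emphasizes
#'   precision).
#' @param s_alpha mixing weight between object- and region-aware structure
#'   similarity in the S-measure; default 0.5.
#' @param eps numerical guard added to denominators; default 1e-8.
#' @return a `metric_config` list.
#' @export
metric_config <- function(beta_sq = 0.3, s_alpha = 0.5, eps = 1e-8) {
  if (beta_sq <= 0) stop("beta_sq must be positive")
  if (s_alpha < 0 || s_alpha > 1) stop("s_alpha must be in [0, 1]")
  structure(list(beta_sq = beta_sq, s_alpha = s_alpha, eps = eps),
            class = "metric_config")
}

check_pair <- function(S, G) {
  S <- unclass(S)
  if (inherits(G, "binary_mask")) G <- G$values
  if (!identical(dim(S), dim(G))) stop("saliency map and ground truth shapes differ")
  assert_binary(G, "ground truth")
  if (min(S) < 0 || max(S) > 1) stop("saliency values must lie in [0, 1]")
  list(S = S, G = G)
}

#' Mean absolute error between a saliency map and ground truth
#'
#' @param S H x W saliency map in `[0, 1]` (graded or binary).
#' @param G H x W binary ground truth (matrix or `binary_mask`).
#' @return the average per-pixel absolute difference.
#' @export
mae <- function(S, G) {
  p <- check_pair(S, G)
  mean(abs(p$S - p$G))
}

#' Precision-recall curve over the 0..255 threshold sweep
#'
#' The map is scaled by 255 and binarized at every integer threshold `T`
#' (`S*255 >= T`); precision and recall are eps-guarded so an empty
#' prediction or empty ground truth yields 0 rather than NaN.
#'
#' @param S,G as in [mae()].
#' @param config a [metric_config()].
#' @return data.frame with columns `threshold`, `precision`, `recall`.
#' @export
pr_curve <- function(S, G, config = metric_config()) {
  p <- check_pair(S, G)
  s255 <- as.vector(p$S) * 255
  g <- as.vector(p$G) == 1
  npos <- sum(g)
  prec <- rec <- numeric(256)
  for (T in 0:255) {
    pred <- s255 >= T
    tp <- sum(pred & g)
    prec[T + 1] <- tp / (sum(pred) + config$eps)
    rec[T + 1] <- tp / (npos + config$eps)
  }
  data.frame(threshold = 0:255, precision = prec, recall = rec)
}

#' F1 and weighted F-beta scores from precision and recall
#'
#' `F1 = 2PR / (P + R + eps)` and
#' `Fb = (1 + b^2) P R / (b^2 P + R + eps)` with `b^2 = 0.3` by default.
#'
#' @param precision,recall numeric vectors in `[0, 1]` (recycled together).
#' @param config a [metric_config()].
#' @return list with vectors `F1` and `Fbeta`.
#' @export
f_scores <- function(precision, recall, config = metric_config()) {
  b2 <- config$beta_sq
  list(
    F1 = 2 * precision * recall / (precision + recall + config$eps),
    Fbeta = (1 + b2) * precision * recall / (b2 * precision + recall + config$eps)
  )
}

#' Area under the ROC curve over the 0..255 threshold sweep
#'
#' Trapezoidal area under (FPR, TPR) with the endpoints (0,0) and (1,1)
#' appended. Errors when the ground truth has no positive or no negative
#' pixels (the curve is undefined).
#'
#' @param S,G as in [mae()].
#' @param config a [metric_config()].
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(S, G, config = metric_config()) {
  p <- check_pair(S, G)
  g <- as.vector(p$G) == 1
  npos <- sum(g); nneg <- sum(!g)
  if (npos == 0 || nneg == 0)
    stop("AUC undefined: ground truth is all-one or all-zero")
  s255 <- as.vector(p$S) * 255
  tpr <- fpr <- numeric(256)
  for (T in 0:255) {
    pred <- s255 >= T
    tpr[T + 1] <- sum(pred & g) / npos
    fpr[T + 1] <- sum(pred & !g) / nneg
  }
  fpr <- c(0, fpr, 1); tpr <- c(0, tpr, 1)
  ord <- order(fpr, tpr)
  fpr <- fpr[ord]; tpr <- tpr[ord]
  sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
}

# SSIM-style region similarity used by the region-aware S-measure term
ssim_region <- function(pred, gt, eps) {
  n <- length(pred)
  x <- mean(pred); y <- mean(gt)
  if (n <= 1) {
    sx <- sy <- sxy <- 0
  } else {
    sx <- sum((pred - x)^2) / (n - 1)
    sy <- sum((gt - y)^2) / (n - 1)
    sxy <- sum((pred - x) * (gt - y)) / (n - 1)
  }
  a <- 4 * x * y * sxy
  b <- (x^2 + y^2) * (sx + sy)
  if (a != 0) a / (b + eps) else if (b == 0) 1 else 0
}

s_object_term <- function(x, eps) {
  if (length(x) == 0) return(0)
  mu <- mean(x)
  sig <- if (length(x) > 1) stats::sd(x) else 0
  2 * mu / (mu^2 + 1 + sig + eps)
}

#' Structure measure (S-measure)
#'
#' `S = alpha * So + (1 - alpha) * Sr`: `So` compares the map against the
#' object and background regions of the ground truth (mean/dispersion
#' similarity of foreground values and of inverted background values,
#' mixed by foreground prevalence); `Sr` splits both maps into four blocks
#' at the ground-truth centroid and averages an SSIM-style similarity with
#' block-area weights. Degenerate ground truths score `1 - mean(S)` (empty)
#' or `mean(S)` (full).
#'
#' @param S,G as in [mae()].
#' @param config a [metric_config()].
#' @return S-measure in `[0, 1]`.
#' @export
s_measure <- function(S, G, config = metric_config()) {
  p <- check_pair(S, G)
  S <- p$S; G <- p$G
  y <- mean(G)
  if (y == 0) return(max(0, 1 - mean(S)))
  if (y == 1) return(max(0, mean(S)))
  eps <- config$eps
  # object-aware term
  o_fg <- s_object_term(S[G == 1], eps)
  o_bg <- s_object_term(1 - S[G == 0], eps)
  So <- y * o_fg + (1 - y) * o_bg
  # region-aware term: split at the GT centroid
  H <- nrow(G); W <- ncol(G)
  idx <- which(G == 1, arr.ind = TRUE)
  Yc <- round(mean(idx[, 1])); Xc <- round(mean(idx[, 2]))
  Yc <- min(max(Yc, 1), H - 1); Xc <- min(max(Xc, 1), W - 1)
  rows1 <- 1:Yc; rows2 <- (Yc + 1):H
  cols1 <- 1:Xc; cols2 <- (Xc + 1):W
  w <- c(length(rows1) * length(cols1), length(rows1) * length(cols2),
         length(rows2) * length(cols1), length(rows2) * length(cols2)) / (H * W)
  q <- c(
    ssim_region(S[rows1, cols1], G[rows1, cols1], eps),
    ssim_region(S[rows1, cols2], G[rows1, cols2], eps),
    ssim_region(S[rows2, cols1], G[rows2, cols1], eps),
    ssim_region(S[rows2, cols2], G[rows2, cols2], eps)
  )
  Sr <- sum(w * q)
  max(0, config$s_alpha * So + (1 - config$s_alpha) * Sr)
}

#' Enhanced-alignment measure (E-measure)
#'
#' The map is binarized at the adaptive threshold `min(2 * mean(S), 1)`;
#' the alignment between the mean-centered binary map and ground truth is
#' enhanced quadratically and averaged over pixels, capturing both the
#' global foreground proportion and local pixel agreement.
#'
#' @param S,G as in [mae()].
#' @param eps numerical guard.
#' @return E-measure in `[0, 1]`.
#' @export
e_measure <- function(S, G, eps = 1e-8) {
  p <- check_pair(S, G)
  thr <- min(2 * mean(p$S), 1)
  FM <- (p$S >= thr) + 0
  GT <- p$G
  if (sum(GT) == 0) {
    enhanced <- 1 - FM
  } else if (sum(1 - GT) == 0) {
    enhanced <- FM
  } else {
    dFM <- FM - mean(FM)
    dGT <- GT - mean(GT)
    align <- 2 * dGT * dFM / (dGT^2 + dFM^2 + eps)
    enhanced <- (align + 1)^2 / 4
  }
  mean(enhanced)
}

#' Intersection over union of two binary masks
#'
#' @param mask predicted `binary_mask` or 0/1 matrix.
#' @param G ground-truth 0/1 matrix or `binary_mask`.
#' @param eps numerical guard.
#' @return IOU in `[0, 1]` (0 when both masks are empty).
#' @export
iou <- function(mask, G, eps = 1e-8) {
  m <- if (inherits(mask, "binary_mask")) mask$values else mask
  if (inherits(G, "binary_mask")) G <- G$values
  assert_binary(m); assert_binary(G, "ground truth")
  if (!identical(dim(m), dim(G))) stop("mask shapes differ")
  sum(m == 1 & G == 1) / (sum(m == 1 | G == 1) + eps)
}

#' Evaluate one saliency map (and optionally a mask) against ground truth
#'
#' Scalar F-scores are the maxima over the 256-threshold sweep (the
#' standard max-F protocol); `iou` is computed from `mask` when given, else
#' from the map binarized at its adaptive threshold `min(2 mean, 1)`.
#'
#' @param S saliency map in `[0, 1]`.
#' @param G binary ground truth.
#' @param mask optional `binary_mask` to score IOU/MAE on instead of a map.
#' @param config a [metric_config()].
#' @return list with scalars `mae`, `f1`, `fbeta`, `auc` (NA when
#'   undefined), `s_measure`, `e_measure`, `iou`, and the `pr` data.frame
#'   (with per-threshold `f1`, `fbeta` columns appended).
#' @export
evaluate_pair <- function(S, G, mask = NULL, config = metric_config()) {
  p <- check_pair(S, G)
  pr <- pr_curve(p$S, p$G, config)
  fs <- f_scores(pr$precision, pr$recall, config)
  pr$f1 <- fs$F1
  pr$fbeta <- fs$Fbeta
  auc <- tryCatch(roc_auc(p$S, p$G, config), error = function(e) NA_real_)
  m <- if (is.null(mask)) (p$S >= min(2 * mean(p$S), 1)) + 0L
       else if (inherits(mask, "binary_mask")) mask$values else mask
  list(
    mae = mae(p$S, p$G),
    f1 = max(pr$f1),
    fbeta = max(pr$fbeta),
    auc = auc,
    s_measure = s_measure(p$S, p$G, config),
    e_measure = e_measure(p$S, p$G, config$eps),
    iou = iou(m, p$G),
    pr = pr
  )
}

#' Aggregate per-image evaluation results into a dataset report
#'
#' PR curves are averaged per threshold across images; scalar metrics are
#' arithmetic means; the report also includes the fraction of images with
#' `IOU > iou_cutoff` / `MAE < mae_cutoff` and the fractions relative to
#' the dataset means.
#'
#' @param results list of [evaluate_pair()] outputs.
#' @param iou_cutoff,mae_cutoff cutoffs for the fraction summaries.
#' @return an `eval_report` list with `n`, `means`, `fractions`, and the
#'   averaged `pr` curve.
#' @export
aggregate_dataset <- function(results, iou_cutoff = 0.9, mae_cutoff = 0.1) {
  if (length(results) == 0) stop("need at least one image result")
  scal <- function(f) vapply(results, function(r) r[[f]], numeric(1))
  ious <- scal("iou"); maes <- scal("mae")
  pr_mat <- function(col)
    rowMeans(vapply(results, function(r) r$pr[[col]], numeric(256)))
  pr <- data.frame(threshold = 0:255,
                   precision = pr_mat("precision"), recall = pr_mat("recall"),
                   f1 = pr_mat("f1"), fbeta = pr_mat("fbeta"))
  structure(list(
    n = length(results),
    means = list(mae = mean(maes), f1 = mean(scal("f1")),
                 fbeta = mean(scal("fbeta")), auc = mean(scal("auc")),
                 s_measure = mean(scal("s_measure")),
                 e_measure = mean(scal("e_measure")), iou = mean(ious)),
    fractions = list(
      iou_above_cutoff = mean(ious > iou_cutoff),
      mae_below_cutoff = mean(maes < mae_cutoff),
      iou_above_mean = mean(ious > mean(ious)),
      mae_below_mean = mean(maes < mean(maes))
    ),
    iou_cutoff = iou_cutoff, mae_cutoff = mae_cutoff,
    pr = pr
  ), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("eval_report over %d image(s)\n", x$n))
  m <- x$means
  cat(sprintf("  MAE %.4f | F1 %.4f | Fb %.4f | AUC %.4f | S %.4f | E %.4f | IOU %.4f\n",
              m$mae, m$f1, m$fbeta, m$auc, m$s_measure, m$e_measure, m$iou))
  cat(sprintf("  IOU > %.2f: %.1f%% | MAE < %.2f: %.1f%%\n",
              x$iou_cutoff, 100 * x$fractions$iou_above_cutoff,
              x$mae_cutoff, 100 * x$fractions$mae_below_cutoff))
  invisible(x)
}
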