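#' Convert sRGB colors to CIE-Lab
#'
#' Standard sRGB (IEC 61966-2-1) to CIE-Lab conversion under the D65 white
#' point: gamma linearization, the sRGB RGB-to-XYZ matrix, then the CIE f()
#' cube-root transfer. Pure red `c(1, 0, 0)` maps to approximately
#' `(53.24, 80.09, 67.20)`.
#'
#' @param rgb numeric matrix with n rows and 3 columns (R, G, B in `[0, 1]`),
#'   or a length-3 vector.
#' @return an n x 3 matrix with columns `L`, `a`, `b`.
#' @export
srgb_to_lab <- function(rgb) {
  if (is.null(dim(rgb))) rgb <- matrix(rgb, ncol = 3)
  stopifnot(ncol(rgb) == 3)
  lin <- ifelse(rgb <= 0.04045, rgb / 12.92, ((rgb + 0.055) / 1.055)^2.4)
  M <- matrix(c(
    0.4124564, 0.3575761, 0.1804375,
    0.2126729, 0.7151522, 0.0721750,
    0.0193339, 0.1191920, 0.9503041
  ), nrow = 3, byrow = TRUE)
  xyz <- lin %*% t(M)
  white <- c(0.95047, 1.00000, 1.08883)
  t3 <- sweep(xyz, 2, white, "/")
  delta <- 6 / 29
  f <- ifelse(t3 > delta^3, t3^(1 / 3), t3 / (3 * delta^2) + 4 / 29)
  out <- cbind(
    L = 116 * f[, 2] - 16,
    a = 500 * (f[, 1] - f[, 2]),
    b = 200 * (f[, 2] - f[, 3])
  )
  out
}

#' Convert CIE-Lab colors to sRGB
#'
#' Inverse of [srgb_to_lab()]. Out-of-gamut results are clipped to `[0, 1]`.
#'
#' @param lab numeric matrix with n rows and 3 columns (L, a, b), or a
#'   length-3 vector.
#' @return an n x 3 matrix of R, G, B values in `[0, 1]`.
#' @export
lab_to_srgb <- function(lab) {
  if (is.null(dim(lab))) lab <- matrix(lab, ncol = 3)
  stopifnot(ncol(lab) == 3)
  delta <- 6 / 29
  fy <- (lab[, 1] + 16) / 116
  fx <- fy + lab[, 2] / 500
  fz <- fy - lab[, 3] / 200
  finv <- function(t) ifelse(t > delta, t^3, 3 * delta^2 * (t - 4 / 29))
  white <- c(0.95047, 1.00000, 1.08883)
  xyz <- cbind(finv(fx) * white[1], finv(fy) * white[2], finv(fz) * white[3])
  Minv <- matrix(c(
    3.2404542, -1.5371385, -0.4985314,
    -0.9692660, 1.8760108, 0.0415560,
    0.0556434, -0.2040259, 1.0572252
  ), nrow = 3, byrow = TRUE)
  lin <- xyz %*% t(Minv)
  lin <- pmin(pmax(lin, 0), 1)
  out <- ifelse(lin <= 0.0031308, 12.92 * lin, 1.055 * lin^(1 / 2.4) - 0.055)
  out <- pmin(pmax(out, 0), 1)
  colnames(out) <- c("R", "G", "B")
  out
}
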