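# shared internal helpers

# min-max rescale to [0,1]; constant input maps to all zeros (declared
# convention used by every re-normalization in the pipeline)
minmax01 <- function(v) {
  rng <- range(v)
  if (!is.finite(rng[1]) || !is.finite(rng[2]))
    stop("non-finite values in normalization input")
  d <- rng[2] - rng[1]
  if (d == 0) return(v * 0)
  (v - rng[1]) / d
}

assert_image <- function(image) {
  if (!is.array(image) || length(dim(image)) != 3L || dim(image)[3] != 3L)
    stop("image must be an H x W x 3 array")
  if (min(image) < 0 || max(image) > 1)
    stop("image values must lie in [0, 1]")
  invisible(image)
}

assert_binary <- function(m, what = "mask") {
  if (!all(m %in% c(0, 1)))
    stop(sprintf("%s must be binary (0/1)", what))
  invisible(m)
}

# pixel-center coordinates of an H x W matrix laid out column-major,
# 0-based, normalized to [0,1] by (W-1, H-1)
pixel_coords <- function(H, W) {
  list(
    x = rep(seq_len(W) - 1L, each = H) / max(W - 1L, 1L),
    y = rep(seq_len(H) - 1L, times = W) / max(H - 1L, 1L)
  )
}

# run a pipeline stage, attaching the stage name to any error
with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[stage %s] %s", stage, conditionMessage(e)), call. = FALSE)
  })
}
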