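# Seeded synthetic scenes with known ground truth, emulating the regimes a
# salient-object-detection benchmark exercises: single and multiple objects,
# low object-background contrast, cluttered (textured) backgrounds, and
# objects touching the image border.

#' Specify a synthetic scene
#'
#' @param size `c(H, W)` in pixels.
#' @param background `"uniform"`, `"gradient"`, or `"textured-clutter"`
#'   (seeded multi-octave color noise).
#' @param bg_color base background RGB in `[0, 1]`.
#' @param objects list of object specs, each a list with `shape`
#'   (`"ellipse"`, `"rectangle"`, `"blob"`), `center` (`c(x, y)`, 0-based
#'   pixels), `size` (`c(rx, ry)` semi-axes in pixels), optional `color`
#'   (RGB; derived from `contrast` when `NULL`), and `touches_border`
#'   (logical).
#' @param contrast target CIE-Lab distance between object and background
#'   colors, used when an object's color is not given.
#' @param noise_sd standard deviation of additive Gaussian pixel noise
#'   (image scale `[0, 1]`).
#' @param seed integer seed; identical specs render bit-identically.
#' @return a `scene_spec` list.
#' @export
scene_spec <- function(size = c(128L, 128L), background = "uniform",
                       bg_color = c(0.45, 0.50, 0.55), objects = list(),
                       contrast = 60, noise_sd = 0.02, seed = 1L) {
  background <- match.arg(background,
                          c("uniform", "gradient", "textured-clutter"))
  stopifnot(length(size) == 2, all(size >= 16), length(bg_color) == 3)
  structure(list(size = as.integer(size), background = background,
                 bg_color = bg_color, objects = objects, contrast = contrast,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "scene_spec")
}

shape_support <- function(shape, H, W, center, size, phases = c(0, 0)) {
  x <- rep(seq_len(W) - 1L, each = H)
  y <- rep(seq_len(H) - 1L, times = W)
  dx <- (x - center[1]) / size[1]
  dy <- (y - center[2]) / size[2]
  inside <- switch(shape,
    ellipse = dx^2 + dy^2 <= 1,
    rectangle = abs(dx) <= 1 & abs(dy) <= 1,
    blob = {
      th <- atan2(dy, dx)
      r <- 1 + 0.25 * sin(3 * th + phases[1]) + 0.15 * sin(5 * th + phases[2])
      sqrt(dx^2 + dy^2) <= r
    },
    stop(sprintf("unknown shape '%s'", shape))
  )
  matrix(inside, H, W)
}

# pick an RGB color at a target Lab distance from `base`, trying several
# random directions and keeping the in-gamut candidate closest to target
color_at_lab_distance <- function(base, contrast) {
  lab0 <- srgb_to_lab(base)
  best <- NULL; best_err <- Inf
  for (i in 1:24) {
    u <- stats::rnorm(3)
    u <- u / sqrt(sum(u^2))
    cand <- lab_to_srgb(as.numeric(lab0) + contrast * u)
    d <- sqrt(sum((srgb_to_lab(cand) - lab0)^2))
    err <- abs(d - contrast)
    if (err < best_err) { best <- as.numeric(cand); best_err <- err }
    if (err < 0.05 * contrast) break
  }
  best
}

bilinear_upsample <- function(grid, H, W) {
  gh <- nrow(grid); gw <- ncol(grid)
  ry <- seq(1, gh, length.out = H)
  rx <- seq(1, gw, length.out = W)
  y0 <- pmin(floor(ry), gh - 1); x0 <- pmin(floor(rx), gw - 1)
  fy <- ry - y0; fx <- rx - x0
  a <- grid[y0, x0, drop = FALSE] * outer(1 - fy, 1 - fx) +
       grid[y0 + 1, x0, drop = FALSE] * outer(fy, 1 - fx) +
       grid[y0, x0 + 1, drop = FALSE] * outer(1 - fy, fx) +
       grid[y0 + 1, x0 + 1, drop = FALSE] * outer(fy, fx)
  a
}

render_background <- function(spec) {
  H <- spec$size[1]; W <- spec$size[2]
  img <- array(0, dim = c(H, W, 3))
  if (spec$background == "uniform") {
    for (c in 1:3) img[, , c] <- spec$bg_color[c]
  } else if (spec$background == "gradient") {
    ang <- stats::runif(1, 0, 2 * pi)
    x <- rep(seq_len(W) - 1L, each = H) / max(W - 1, 1)
    y <- rep(seq_len(H) - 1L, times = W) / max(H - 1, 1)
    ramp <- matrix(minmax01(cos(ang) * x + sin(ang) * y), H, W)
    for (c in 1:3)
      img[, , c] <- pmin(pmax(spec$bg_color[c] + 0.16 * (ramp - 0.5), 0), 1)
  } else { # textured-clutter: multi-octave seeded value noise
    for (c in 1:3) {
      tex <- matrix(0, H, W)
      amp <- 0.12
      for (g in c(5L, 9L, 17L)) {
        tex <- tex + amp * bilinear_upsample(
          matrix(stats::runif(g * g, -1, 1), g, g), H, W)
        amp <- amp / 2
      }
      img[, , c] <- pmin(pmax(spec$bg_color[c] + tex, 0), 1)
    }
  }
  img
}

#' Render a synthetic scene and its ground-truth mask
#'
#' Paints the declared objects over the background, adds Gaussian pixel
#' noise, and quantizes to 8 bits (as a decoded image file would be).
#' Identical `spec` (including `seed`) renders bit-identically.
#'
#' @param spec a [scene_spec()].
#' @return list with `image` (H x W x 3 array), `gt` (H x W 0/1 matrix, the
#'   union of object supports), and `spec`.
#' @export
make_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  set.seed(spec$seed)
  H <- spec$size[1]; W <- spec$size[2]
  img <- render_background(spec)
  gt <- matrix(0L, H, W)
  bg_ref <- spec$bg_color
  for (ob in spec$objects) {
    phases <- stats::runif(2, 0, 2 * pi)
    sup <- shape_support(ob$shape, H, W, ob$center, ob$size, phases)
    if (sum(sup) < 25)
      stop("degenerate object: painted support under 25 pixels")
    col <- if (!is.null(ob$color)) ob$color
           else color_at_lab_distance(bg_ref, spec$contrast)
    for (c in 1:3) {
      ch <- img[, , c]
      ch[sup] <- col[c]
      img[, , c] <- ch
    }
    gt[sup] <- 1L
    tb <- isTRUE(ob$touches_border)
    touches <- any(sup[1, ], sup[H, ], sup[, 1], sup[, W])
    if (tb && !touches)
      stop("object declared touches_border but its support misses the border")
  }
  if (mean(gt) > 0.8)
    stop("objects cover more than 80% of the image; background prior is meaningless")
  if (spec$noise_sd > 0)
    img <- img + array(stats::rnorm(length(img), 0, spec$noise_sd), dim = dim(img))
  img <- pmin(pmax(img, 0), 1)
  img <- round(img * 255) / 255
  list(image = img, gt = gt, spec = spec)
}

#' Generate the fixed 20-scene synthetic test suite
#'
#' Four regimes of five 128 x 128 scenes each: `centered` (one high-contrast
#' object away from the border), `multi` (2-3 objects, some over cluttered
#' backgrounds), `lowcontrast` (Lab distance 25 instead of 60), and
#' `nearboundary` (one high-contrast object overlapping the image border --
#' the failure mode the refined background dictionary addresses).
#'
#' @param seed integer master seed; the same seed regenerates the identical
#'   suite.
#' @return list of 20 scenes, each a list with `name`, `image`, `gt`, `spec`.
#' @export
make_suite <- function(seed = 1L) {
  set.seed(seed)
  sub <- sample.int(.Machine$integer.max - 1L, 40L)
  H <- W <- 128L
  scenes <- list()
  shapes <- c("ellipse", "blob", "rectangle", "ellipse", "blob")
  bgs <- c("uniform", "gradient", "uniform", "gradient", "uniform")
  si <- 0L
  nxt <- function() { si <<- si + 1L; sub[si] }
  for (i in 1:5) {
    s <- nxt(); set.seed(s)
    ctr <- c(63.5, 63.5) + stats::runif(2, -8, 8)
    sz <- stats::runif(2, 22, 32)
    spec <- scene_spec(c(H, W), bgs[i],
                       bg_color = c(0.45, 0.5, 0.55) + stats::runif(3, -0.05, 0.05),
                       objects = list(list(shape = shapes[i], center = ctr,
                                           size = sz, touches_border = FALSE)),
                       contrast = 60, noise_sd = 0.02, seed = s)
    scenes[[length(scenes) + 1L]] <-
      c(list(name = sprintf("centered_%d", i)), make_scene(spec))
  }
  multibgs <- c("uniform", "textured-clutter", "gradient", "textured-clutter",
                "uniform")
  for (i in 1:5) {
    s <- nxt(); set.seed(s)
    nobj <- sample(2:3, 1)
    objs <- lapply(seq_len(nobj), function(j) {
      list(shape = sample(c("ellipse", "rectangle", "blob"), 1),
           center = c(stats::runif(1, 30, W - 31), stats::runif(1, 30, H - 31)),
           size = stats::runif(2, 13, 20), touches_border = FALSE)
    })
    spec <- scene_spec(c(H, W), multibgs[i],
                       bg_color = c(0.5, 0.48, 0.46) + stats::runif(3, -0.05, 0.05),
                       objects = objs, contrast = 60, noise_sd = 0.02, seed = s)
    scenes[[length(scenes) + 1L]] <-
      c(list(name = sprintf("multi_%d", i)), make_scene(spec))
  }
  for (i in 1:5) {
    s <- nxt(); set.seed(s)
    ctr <- c(63.5, 63.5) + stats::runif(2, -8, 8)
    sz <- stats::runif(2, 22, 32)
    spec <- scene_spec(c(H, W), bgs[i],
                       bg_color = c(0.45, 0.5, 0.55) + stats::runif(3, -0.05, 0.05),
                       objects = list(list(shape = shapes[i], center = ctr,
                                           size = sz, touches_border = FALSE)),
                       contrast = 25, noise_sd = 0.02, seed = s)
    scenes[[length(scenes) + 1L]] <-
      c(list(name = sprintf("lowcontrast_%d", i)), make_scene(spec))
  }
  sides <- c("left", "top", "right", "bottom", "left")
  for (i in 1:5) {
    s <- nxt(); set.seed(s)
    sz <- stats::runif(2, 20, 28)
    along <- stats::runif(1, 40, 88)
    ctr <- switch(sides[i],
      left = c(0.35 * sz[1], along),
      right = c(W - 1 - 0.35 * sz[1], along),
      top = c(along, 0.35 * sz[2]),
      bottom = c(along, H - 1 - 0.35 * sz[2]))
    spec <- scene_spec(c(H, W), bgs[i],
                       bg_color = c(0.45, 0.5, 0.55) + stats::runif(3, -0.05, 0.05),
                       objects = list(list(shape = shapes[i], center = ctr,
                                           size = sz, touches_border = TRUE)),
                       contrast = 60, noise_sd = 0.02, seed = s)
    scenes[[length(scenes) + 1L]] <-
      c(list(name = sprintf("nearboundary_%d", i)), make_scene(spec))
  }
  scenes
}
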