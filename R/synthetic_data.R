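# Seeded generator of dermoscopy-like scenes with exact ground-truth masks.
# A scene is an irregular dark elliptical lesion on a lighter skin background
# with Gaussian texture noise, an optional linear illumination gradient,
# optional dark hair strokes and optional bright "bubble" circles. Artifacts
# corrupt the image only; the mask is the exact rasterized lesion region.

#' Synthetic scene specification
#'
#' Defaults describe a plausible dermoscopic photograph: a lesion covering
#' 5-40% of the frame with a smoothly irregular border, mean lesion intensity
#' ~0.3 (brown/dark) against skin at ~0.75, mild texture noise, a gentle
#' illumination gradient and a few dark hairs.
#'
#' @param size image side in pixels (default 256).
#' @param lesion_area_fraction length-2 range of the lesion area as a fraction
#'   of the frame; each scene draws uniformly from it.
#' @param border_irregularity non-negative amplitude of the radial harmonic
#'   perturbation of the lesion border (0 = exact ellipse).
#' @param lesion_color,skin_color per-channel RGB means in `[0,1]`.
#' @param color_spread per-pixel Gaussian colour texture sd.
#' @param hair_count number of dark hair strokes (image-only artifact).
#' @param hair_width hair stroke width in pixels.
#' @param bubble_count number of small bright circles (default 0).
#' @param illumination_gradient peak-to-peak amplitude of a linear
#'   illumination ramp across the frame.
#' @param noise_sigma additive Gaussian noise sd.
#' @param seed optional integer seed; fixed seed gives a bit-identical scene.
#' @return object of class `scene_spec`.
#' @export
scene_spec <- function(size = 256L,
                       lesion_area_fraction = c(0.05, 0.4),
                       border_irregularity = 0.15,
                       lesion_color = c(0.40, 0.28, 0.22),
                       skin_color = c(0.87, 0.74, 0.64),
                       color_spread = 0.02,
                       hair_count = 3L,
                       hair_width = 2,
                       bubble_count = 0L,
                       illumination_gradient = 0.1,
                       noise_sigma = 0.03,
                       seed = NULL) {
  if (any(lesion_area_fraction <= 0) || any(lesion_area_fraction >= 1) ||
      lesion_area_fraction[1] > lesion_area_fraction[2]) {
    stop("lesion_area_fraction must be an increasing range inside (0,1)")
  }
  if (any(c(lesion_color, skin_color) < 0 | c(lesion_color, skin_color) > 1)) {
    stop("colors must lie in [0,1]")
  }
  if (border_irregularity < 0 || noise_sigma < 0 || hair_count < 0) {
    stop("invalid scene spec")
  }
  structure(list(size = as.integer(size),
                 lesion_area_fraction = lesion_area_fraction,
                 border_irregularity = border_irregularity,
                 lesion_color = lesion_color, skin_color = skin_color,
                 color_spread = color_spread,
                 hair_count = as.integer(hair_count),
                 hair_width = hair_width,
                 bubble_count = as.integer(bubble_count),
                 illumination_gradient = illumination_gradient,
                 noise_sigma = noise_sigma, seed = seed),
            class = "scene_spec")
}

stamp_disk <- function(canvas, cy, cx, radius) {
  s <- nrow(canvas)
  r <- ceiling(radius)
  ii <- max(1, floor(cy - r)):min(s, ceiling(cy + r))
  jj <- max(1, floor(cx - r)):min(s, ceiling(cx + r))
  if (!length(ii) || !length(jj)) return(canvas)
  d2 <- outer((ii - cy)^2, (jj - cx)^2, "+")
  canvas[ii, jj][d2 <= radius^2] <- TRUE
  canvas
}

#' Generate one synthetic dermoscopy-like scene
#'
#' Rasterizes a lesion whose elliptical radius is modulated by smooth
#' harmonic noise \eqn{r(\theta) = r_0 (1 + \sum_k a_k \sin(k\theta +
#' \phi_k))}, `k <= 8`, renders it darker than the skin background with
#' texture noise, then overlays the optional image-only artifacts (hairs,
#' bubbles, illumination ramp). The returned mask is the exact pre-artifact
#' lesion raster.
#'
#' @param spec a [scene_spec()].
#' @return list with `image` (`size x size x 3`, values in `[0,1]`) and
#'   `mask` (`size x size` 0/1 matrix).
#' @export
make_scene <- function(spec = scene_spec()) {
  stopifnot(inherits(spec, "scene_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  s <- spec$size
  frac <- stats::runif(1, spec$lesion_area_fraction[1],
                       spec$lesion_area_fraction[2])
  r0 <- sqrt(frac * s^2 / pi)
  if (2 * r0 > 0.95 * s) stop("infeasible lesion area fraction for this size")
  q <- stats::runif(1, 0.6, 1)           # aspect ratio
  ax <- r0 / sqrt(q); ay <- r0 * sqrt(q) # semi-axes, pi*ax*ay = frac*s^2
  phi <- stats::runif(1, 0, pi)          # orientation
  cy <- s / 2 + stats::runif(1, -0.08, 0.08) * s
  cx <- s / 2 + stats::runif(1, -0.08, 0.08) * s
  nk <- 7L
  amp <- spec$border_irregularity * stats::rnorm(nk) / (2L:8L)
  pha <- stats::runif(nk, 0, 2 * pi)

  yy <- matrix(seq_len(s) - cy, s, s)
  xx <- matrix(seq_len(s) - cx, s, s, byrow = TRUE)
  u <- cos(phi) * xx + sin(phi) * yy
  v <- -sin(phi) * xx + cos(phi) * yy
  rho <- sqrt((u / ax)^2 + (v / ay)^2)
  theta <- atan2(v / ay, u / ax)
  mult <- matrix(1, s, s)
  for (k in seq_len(nk)) mult <- mult + amp[k] * sin((k + 1L) * theta + pha[k])
  mult[mult < 0.25] <- 0.25
  mask <- (rho <= mult) * 1

  gdir <- stats::runif(1, 0, 2 * pi)
  ramp <- spec$illumination_gradient *
    (cos(gdir) * (xx / s) + sin(gdir) * (yy / s))
  img <- array(0, c(s, s, 3))
  for (c in 1:3) {
    base <- ifelse(mask == 1, spec$lesion_color[c], spec$skin_color[c])
    tex <- matrix(stats::rnorm(s * s, 0, spec$color_spread), s, s)
    img[, , c] <- base + tex + ramp
  }
  img <- gaussian_smooth(img, 0.8) # soften the lesion edge slightly

  hair <- matrix(FALSE, s, s)
  if (spec$hair_count > 0) {
    for (h in seq_len(spec$hair_count)) {
      p0 <- stats::runif(2, 0.05, 0.95) * s
      ang <- stats::runif(1, 0, 2 * pi)
      len <- stats::runif(1, 0.5, 1.1) * s
      bend <- stats::runif(1, -0.15, 0.15) * s
      tgrid <- seq(0, 1, by = 0.75 / len)
      py <- p0[1] + tgrid * len * sin(ang) + bend * sin(pi * tgrid) * cos(ang)
      px <- p0[2] + tgrid * len * cos(ang) - bend * sin(pi * tgrid) * sin(ang)
      keep <- py >= 1 & py <= s & px >= 1 & px <= s
      for (t in which(keep)) {
        hair <- stamp_disk(hair, py[t], px[t], spec$hair_width / 2)
      }
    }
    for (c in 1:3) {
      ch <- img[, , c]
      ch[hair] <- 0.7 * 0.12 + 0.3 * ch[hair]
      img[, , c] <- ch
    }
  }
  if (spec$bubble_count > 0) {
    for (b in seq_len(spec$bubble_count)) {
      bc <- stats::runif(2, 0.1, 0.9) * s
      br <- stats::runif(1, 0.01, 0.03) * s
      bub <- stamp_disk(matrix(FALSE, s, s), bc[1], bc[2], br)
      for (c in 1:3) {
        ch <- img[, , c]
        ch[bub] <- 0.6 * 0.95 + 0.4 * ch[bub]
        img[, , c] <- ch
      }
    }
  }
  if (spec$noise_sigma > 0) {
    img <- img + array(stats::rnorm(length(img), 0, spec$noise_sigma),
                       dim(img))
  }
  img[img < 0] <- 0
  img[img > 1] <- 1
  list(image = img, mask = mask)
}

#' Generate a seeded synthetic dataset
#'
#' Draws `n` scenes from per-scene seeds derived deterministically from the
#' master seed, so the whole dataset is reproducible bit-for-bit.
#'
#' @param n number of scenes (>= 1).
#' @param spec a [scene_spec()]; its own `seed` field is ignored here.
#' @param seed master integer seed.
#' @return list of `n` `list(image=, mask=)` scenes.
#' @export
make_dataset <- function(n, spec = scene_spec(), seed = 1L) {
  stopifnot(n >= 1)
  set.seed(seed)
  scene_seeds <- sample.int(.Machine$integer.max, n)
  lapply(seq_len(n), function(i) {
    sp <- spec
    sp$seed <- scene_seeds[i]
    make_scene(sp)
  })
}
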