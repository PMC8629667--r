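#' Specify a synthetic lung-slice phantom
#'
#' Describes a textured 2-D phantom emulating a single axial chest CT slice:
#' a bright soft-tissue "body" disk on a dark background, two dark elliptical
#' lung fields inside the body, and one tumor blob inside a lung. Each region
#' carries a multiplicative smoothed-noise texture with its own correlation
#' length, so that the tumor can be distinguishable by intensity, by texture
#' grain, or both. Additive Gaussian noise and impulse (salt-and-pepper)
#' corruption model acquisition noise.
#'
#' Ellipses are given as `c(row, col, semi_row, semi_col, rotation_rad)`.
#'
#' @param size `c(height, width)` in pixels.
#' @param body_mean,lung_mean,tumor_mean,background_mean Mean intensities in
#'   \[0, 1\] of the four regions.
#' @param lung_ellipses List of two ellipse vectors (the lung fields).
#' @param tumor Ellipse vector for the tumor, fully inside a lung field.
#' @param texture_grain Named list of per-region texture correlation lengths
#'   in pixels (`body`, `lung`, `tumor`); 0 disables that region's texture.
#' @param texture_amp Relative amplitude of the multiplicative texture.
#' @param gaussian_sigma Additive Gaussian noise scale.
#' @param impulse_rate Fraction of pixels replaced by 0 or 1 (must be < 0.5).
#' @param seed Integer seed; all randomness in [phantom_generate()] derives
#'   from it.
#' @return An object of class `"phantom_spec"`.
#' @export
phantom_spec <- function(size = c(128L, 128L),
                         body_mean = 0.55, lung_mean = 0.25, tumor_mean = 0.65,
                         background_mean = 0.05,
                         lung_ellipses = NULL, tumor = NULL,
                         texture_grain = list(body = 2, lung = 1, tumor = 1),
                         texture_amp = 0.25,
                         gaussian_sigma = 0.02, impulse_rate = 0,
                         seed = 1L) {
  h <- size[1]; w <- size[2]
  if (is.null(lung_ellipses)) {
    lung_ellipses <- list(
      c(0.50 * h, 0.32 * w, 0.30 * h, 0.16 * w, 0.0),
      c(0.50 * h, 0.68 * w, 0.30 * h, 0.16 * w, 0.0))
  }
  if (is.null(tumor)) tumor <- c(0.44 * h, 0.32 * w, 0.09 * h, 0.07 * w, 0.3)
  spec <- structure(list(
    size = as.integer(size), body_mean = body_mean, lung_mean = lung_mean,
    tumor_mean = tumor_mean, background_mean = background_mean,
    lung_ellipses = lung_ellipses, tumor = tumor,
    texture_grain = texture_grain, texture_amp = texture_amp,
    gaussian_sigma = gaussian_sigma, impulse_rate = impulse_rate,
    seed = as.integer(seed)), class = "phantom_spec")
  validate_phantom_spec(spec)
  spec
}

ellipse_mask <- function(h, w, e) {
  rr <- matrix(seq_len(h), h, w) - e[1]
  cc <- matrix(seq_len(w), h, w, byrow = TRUE) - e[2]
  co <- cos(e[5]); si <- sin(e[5])
  u <- co * rr + si * cc
  v <- -si * rr + co * cc
  ((u / e[3])^2 + (v / e[4])^2 <= 1) * 1
}

validate_phantom_spec <- function(spec) {
  h <- spec$size[1]; w <- spec$size[2]
  if (h < 8 || w < 8) stop("phantom size too small", call. = FALSE)
  if (spec$impulse_rate < 0 || spec$impulse_rate >= 0.5)
    stop("impulse_rate must be in [0, 0.5)", call. = FALSE)
  for (m in c(spec$body_mean, spec$lung_mean, spec$tumor_mean, spec$background_mean))
    if (m < 0 || m > 1) stop("region means must lie in [0, 1]", call. = FALSE)
  if (length(spec$lung_ellipses) != 2)
    stop("exactly two lung ellipses are required", call. = FALSE)
  l1 <- ellipse_mask(h, w, spec$lung_ellipses[[1]])
  l2 <- ellipse_mask(h, w, spec$lung_ellipses[[2]])
  if (any(l1 * l2 > 0)) stop("lung ellipses must be disjoint", call. = FALSE)
  tum <- ellipse_mask(h, w, spec$tumor)
  if (any(tum > (l1 + l2)))
    stop("tumor ellipse must lie fully inside a lung field", call. = FALSE)
  body <- body_mask_of(spec)
  if (any((l1 + l2) > body))
    stop("lung ellipses must lie inside the body", call. = FALSE)
  invisible(spec)
}

body_mask_of <- function(spec) {
  h <- spec$size[1]; w <- spec$size[2]
  ellipse_mask(h, w, c(0.5 * h, 0.5 * w, 0.46 * h, 0.46 * w, 0))
}

# Smoothed standardized noise field: unit variance, zero mean, correlation
# length ~ grain pixels.
texture_field <- function(h, w, grain) {
  n <- matrix(stats::rnorm(h * w), h, w)
  if (grain > 0) n <- gauss_blur(n, grain)
  s <- stats::sd(n)
  if (s > 0) n <- (n - mean(n)) / s
  n
}

#' Generate a phantom slice and its ground-truth masks
#'
#' Rasterizes the regions at their mean intensities, applies per-region
#' multiplicative texture, then Gaussian noise, then impulse corruption, and
#' clips to \[0, 1\]. The masks are exact rasterizations and do not depend on
#' the noise. Identical specs (including the seed) give identical output.
#'
#' @param spec A [phantom_spec()].
#' @return A list with `image` (matrix), `lobe_mask` (both lung fields),
#'   `tumor_mask`, `body_mask`, and the `spec`.
#' @export
phantom_generate <- function(spec) {
  validate_phantom_spec(spec)
  h <- spec$size[1]; w <- spec$size[2]
  body <- body_mask_of(spec)
  l1 <- ellipse_mask(h, w, spec$lung_ellipses[[1]])
  l2 <- ellipse_mask(h, w, spec$lung_ellipses[[2]])
  lobe <- pmin(l1 + l2, 1)
  tumor <- ellipse_mask(h, w, spec$tumor)
  region <- matrix("background", h, w)
  region[body == 1] <- "body"
  region[lobe == 1] <- "lung"
  region[tumor == 1] <- "tumor"
  means <- c(background = spec$background_mean, body = spec$body_mean,
             lung = spec$lung_mean, tumor = spec$tumor_mean)
  img <- matrix(means[region], h, w)

  # named substreams so each noise component is independently reproducible
  set.seed(derive_seed(spec$seed, "texture"))
  for (reg in c("body", "lung", "tumor")) {
    g <- spec$texture_grain[[reg]] %||% 0
    tf <- texture_field(h, w, g)        # drawn regardless, to keep substreams aligned
    if (g > 0 && spec$texture_amp > 0) {
      sel <- region == reg
      img[sel] <- img[sel] * (1 + spec$texture_amp * tf[sel])
    }
  }
  if (spec$gaussian_sigma > 0) {
    set.seed(derive_seed(spec$seed, "gaussian"))
    img <- img + matrix(stats::rnorm(h * w, sd = spec$gaussian_sigma), h, w)
  }
  if (spec$impulse_rate > 0) {
    set.seed(derive_seed(spec$seed, "impulse"))
    hit <- matrix(stats::runif(h * w) < spec$impulse_rate, h, w)
    salt <- matrix(stats::runif(h * w) < 0.5, h, w)
    img[hit] <- ifelse(salt[hit], 1, 0)
  }
  list(image = clip01(img), lobe_mask = lobe, tumor_mask = tumor,
       body_mask = body, spec = spec)
}

#' The fixed phantom evaluation suite
#'
#' Three difficulty conditions used throughout the package's evaluation:
#' \describe{
#'   \item{easy}{tumor brighter than the lung parenchyma (intensity cue).}
#'   \item{texture}{tumor mean equals the lung mean; only the texture
#'     correlation length differs (texture cue only).}
#'   \item{noisy}{the easy geometry plus 5\% impulse noise, exercising the
#'     median-filter preprocessing.}
#' }
#'
#' @param seed Integer seed from which all three specs derive.
#' @param size `c(height, width)` of each phantom.
#' @return A named list of three [phantom_spec()] objects, with a
#'   `difficulty` attribute on each.
#' @export
phantom_suite <- function(seed = 1L, size = c(128L, 128L)) {
  mk <- function(tag, ...) {
    s <- phantom_spec(size = size, seed = derive_seed(seed, tag), ...)
    attr(s, "difficulty") <- tag
    s
  }
  list(
    easy = mk("easy"),
    texture = mk("texture", tumor_mean = 0.25, lung_mean = 0.25,
                 texture_grain = list(body = 2, lung = 0.6, tumor = 3),
                 texture_amp = 0.35),
    noisy = mk("noisy", impulse_rate = 0.05))
}
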