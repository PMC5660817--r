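#' Synthetic head-phantom specification
#'
#' A seeded recipe for a head-like 2-D phantom: nested tissue ellipses
#' (background, cortical "GM" ellipse, inner "WM" ellipse, a dark ventricle
#' blob), one or more hyperintense lesion disks, a smooth second-order
#' multiplicative bias field emulating MR coil inhomogeneity, and additive
#' noise. Identical spec and seed give bit-identical images.
#'
#' The default recipe (background 10, GM 90, WM 140, ventricle 40, lesion
#' 210, bias amplitude 15%, Gaussian noise sd 8) reproduces the contrast
#' ordering of a contrast-enhanced T1/FLAIR slice in which the lesion is the
#' brightest structure.
#'
#' @param size image size `c(H, W)`.
#' @param tissues list of tissue ellipses, each
#'   `list(center = c(r, c), semi = c(a, b), mean = intensity)`, painted in
#'   order.
#' @param lesions list of lesion disks, each
#'   `list(center = c(r, c), radius, mean)`.
#' @param background background intensity.
#' @param bias_amp peak relative amplitude of the second-order polynomial
#'   bias field (0 disables it).
#' @param noise_model `"gaussian"` or `"rician"`.
#' @param noise_sd noise scale in intensity levels (0 disables noise).
#' @param seed RNG seed.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(size = c(128L, 128L),
                         tissues = NULL,
                         lesions = list(list(center = c(78, 74), radius = 9,
                                             mean = 210)),
                         background = 10,
                         bias_amp = 0.15,
                         noise_model = c("gaussian", "rician"),
                         noise_sd = 8,
                         seed = 0L) {
  noise_model <- match.arg(noise_model)
  ctr <- size / 2
  if (is.null(tissues)) {
    tissues <- list(
      gm = list(center = ctr, semi = c(0.72, 0.60) * ctr, mean = 90),
      wm = list(center = ctr, semi = c(0.50, 0.41) * ctr, mean = 140),
      ventricle = list(center = ctr - c(4, 2), semi = c(7, 5), mean = 40))
  }
  spec <- structure(list(size = as.integer(size), tissues = tissues,
                         lesions = lesions, background = background,
                         bias_amp = bias_amp, noise_model = noise_model,
                         noise_sd = noise_sd, seed = as.integer(seed)),
                    class = "phantom_spec")
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  means <- c(spec$background,
             vapply(spec$tissues, function(t) t$mean, numeric(1)),
             vapply(spec$lesions, function(l) l$mean, numeric(1)))
  if (any(means < 0) || any(means > 255))
    stop_input("all mean intensities must lie in [0, 255]", "ugfc_spec_error")
  brain <- spec$tissues[[1L]]
  for (l in spec$lesions) {
    extremes <- rbind(l$center + c(l$radius, 0), l$center - c(l$radius, 0),
                      l$center + c(0, l$radius), l$center - c(0, l$radius))
    inside <- ((extremes[, 1] - brain$center[1]) / brain$semi[1])^2 +
              ((extremes[, 2] - brain$center[2]) / brain$semi[2])^2 <= 1
    if (!all(inside))
      stop_input("lesion blob extends outside the brain ellipse",
                 "ugfc_spec_error")
  }
  invisible(spec)
}

ellipse_mask <- function(size, center, semi) {
  r <- matrix(seq_len(size[1]), size[1], size[2])
  c_ <- matrix(seq_len(size[2]), size[1], size[2], byrow = TRUE)
  ((r - center[1]) / semi[1])^2 + ((c_ - center[2]) / semi[2])^2 <= 1
}

# smooth second-order polynomial scaled to [-1, 1]
bias_profile <- function(size) {
  u <- matrix(seq_len(size[2]) / size[2] * 2 - 1, size[1], size[2], byrow = TRUE)
  v <- matrix(seq_len(size[1]) / size[1] * 2 - 1, size[1], size[2])
  q <- 0.8 * u + 0.5 * v + 0.6 * u * v - 0.4 * u^2 + 0.3 * v^2
  2 * (q - min(q)) / (max(q) - min(q)) - 1
}

#' Generate a phantom image with ground truth
#'
#' @param spec a [phantom_spec()].
#' @return List with `image` (integer-valued matrix in `[0, 255]`), `truth`
#'   (binary lesion mask) and `labels` (tissue label map: 0 background, then
#'   tissues in recipe order, lesions last).
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  validate_phantom_spec(spec)
  size <- spec$size
  img <- matrix(spec$background, size[1], size[2])
  labels <- matrix(0L, size[1], size[2])
  k <- 0L
  for (t in spec$tissues) {
    k <- k + 1L
    m <- ellipse_mask(size, t$center, t$semi)
    img[m] <- t$mean; labels[m] <- k
  }
  truth <- matrix(0, size[1], size[2])
  for (l in spec$lesions) {
    m <- ellipse_mask(size, l$center, c(l$radius, l$radius))
    img[m] <- l$mean; truth[m] <- 1; labels[m] <- k + 1L
  }
  if (spec$bias_amp != 0)
    img <- img * (1 + spec$bias_amp * bias_profile(size))
  set.seed(spec$seed)
  if (spec$noise_sd > 0) {
    if (spec$noise_model == "gaussian") {
      img <- img + matrix(stats::rnorm(length(img), 0, spec$noise_sd),
                          size[1], size[2])
    } else {
      n1 <- matrix(stats::rnorm(length(img), 0, spec$noise_sd), size[1], size[2])
      n2 <- matrix(stats::rnorm(length(img), 0, spec$noise_sd), size[1], size[2])
      img <- sqrt((img + n1)^2 + n2^2)
    }
  }
  list(image = round_half_up(clamp(img, 0, 255)), truth = truth,
       labels = labels)
}

#' Sample a clamped 1-D Gaussian mixture
#'
#' Supports clustering and density-estimation tests with a known ground
#' truth. Draws are clamped to the intensity range `[0, 255]`.
#'
#' @param means,sigmas,weights component parameters; weights must sum to 1.
#' @param n number of draws.
#' @param seed RNG seed.
#' @return Numeric vector of length `n`.
#' @export
sample_mixture_1d <- function(means, sigmas, weights, n, seed = 0L) {
  if (length(means) != length(sigmas) || length(means) != length(weights))
    stop_input("means, sigmas and weights must have equal length", "ugfc_spec_error")
  if (abs(sum(weights) - 1) > 1e-8)
    stop_input("weights must sum to 1", "ugfc_spec_error")
  set.seed(seed)
  comp <- sample.int(length(means), n, replace = TRUE, prob = weights)
  clamp(stats::rnorm(n, means[comp], sigmas[comp]), 0, 255)
}

#' Randomized multi-lesion phantom specification
#'
#' Places `k` non-overlapping lesion disks at seeded random positions inside
#' the white-matter ellipse of the default recipe.
#'
#' @param k number of lesions, `>= 1`.
#' @param seed RNG seed (also used for the phantom noise).
#' @param radius_range lesion radius range (pixels).
#' @param ... further arguments passed to [phantom_spec()].
#' @return A `phantom_spec` with `k` lesions.
#' @export
multiple_lesion_spec <- function(k, seed = 0L, radius_range = c(7, 11), ...) {
  if (k < 1L) stop_input("k must be at least 1", "ugfc_spec_error")
  base <- phantom_spec(seed = seed, ...)
  wm <- base$tissues[[2L]]
  set.seed(seed)
  placed <- list()
  tries <- 0L
  while (length(placed) < k) {
    tries <- tries + 1L
    if (tries > 2000L)
      stop_input(sprintf("cannot place %d non-overlapping lesions", k),
                 "ugfc_spec_error")
    r <- stats::runif(1, radius_range[1], radius_range[2])
    # sample inside the WM ellipse with margin r
    theta <- stats::runif(1, 0, 2 * pi)
    s <- sqrt(stats::runif(1))
    ctr <- wm$center + s * c((wm$semi[1] - r - 1) * cos(theta),
                             (wm$semi[2] - r - 1) * sin(theta))
    ok <- TRUE
    for (p in placed) {
      if (sqrt(sum((ctr - p$center)^2)) < r + p$radius + 2) { ok <- FALSE; break }
    }
    if (ok) placed[[length(placed) + 1L]] <- list(center = ctr, radius = r,
                                                  mean = 210)
  }
  spec <- base
  spec$lesions <- placed
  validate_phantom_spec(spec)
  spec
}
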