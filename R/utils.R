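# Internal helpers: conditions, finite-difference stencils, validation.

stop_input <- function(msg, class = "ugfc_input_error") {
  stop(structure(class = c(class, "ugfc_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

stop_validation <- function(msg) stop_input(msg, class = "ugfc_validation_error")
stop_numerical <- function(msg) stop_input(msg, class = "ugfc_numerical_error")

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# round half away from zero (base round() is banker's)
round_half_up <- function(x) floor(x + 0.5)

check_gray_image <- function(img, levels = 256L) {
  if (!is.matrix(img) || !is.numeric(img))
    stop_input("image must be a numeric matrix")
  if (nrow(img) < 1L || ncol(img) < 1L)
    stop_input("image must have at least one row and one column")
  if (any(!is.finite(img)))
    stop_input("image contains non-finite values")
  if (any(img < 0) || any(img > levels - 1))
    stop_input(sprintf("pixel values must lie in [0, %d]", levels - 1L))
  invisible(img)
}

check_binary_mask <- function(mask, name = "mask") {
  if (!is.matrix(mask) || !is.numeric(mask))
    stop_input(sprintf("%s must be a numeric matrix", name))
  if (!all(mask %in% c(0, 1)))
    stop_input(sprintf("%s must contain only 0/1 values", name))
  invisible(mask)
}

# central differences with replicate padding (Neumann boundary)
grad_x <- function(m) {                       # along rows (first index)
  n <- nrow(m)
  up <- m[c(1L, seq_len(n - 1L)), , drop = FALSE]
  dn <- m[c(seq_len(n)[-1L], n), , drop = FALSE]
  (dn - up) / 2
}

grad_y <- function(m) {                       # along columns (second index)
  n <- ncol(m)
  lf <- m[, c(1L, seq_len(n - 1L)), drop = FALSE]
  rt <- m[, c(seq_len(n)[-1L], n), drop = FALSE]
  (rt - lf) / 2
}

divergence <- function(fx, fy) grad_x(fx) + grad_y(fy)

# 5-point Laplacian, replicate padding
laplacian <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  up <- m[c(1L, seq_len(nr - 1L)), , drop = FALSE]
  dn <- m[c(seq_len(nr)[-1L], nr), , drop = FALSE]
  lf <- m[, c(1L, seq_len(nc - 1L)), drop = FALSE]
  rt <- m[, c(seq_len(nc)[-1L], nc), drop = FALSE]
  up + dn + lf + rt - 4 * m
}

# Gaussian smoothing with replicate boundary; brush capped to image size
gaussian_smooth <- function(m, sigma) {
  if (sigma <= 0) stop_input("sigma must be positive")
  size <- 2L * ceiling(3 * sigma) + 1L
  size <- min(size, 2L * (min(dim(m)) %/% 2L) - 1L)
  size <- max(size, 3L)
  brush <- EBImage::makeBrush(size = size, shape = "gaussian", sigma = sigma)
  as.matrix(EBImage::filter2(m, brush, boundary = "replicate"))
}
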