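# Independent reference implementations used as oracles. These deliberately
# share no code with the package: plain loops, textbook formulas.

# piecewise-linear membership by hand (no approx())
oracle_membership <- function(z, x, mu) {
  if (z < x[1] || z > x[length(x)]) return(0)
  for (i in seq_len(length(x) - 1)) {
    if (z >= x[i] && z <= x[i + 1]) {
      if (x[i + 1] == x[i]) return(mu[i])
      return(mu[i] + (mu[i + 1] - mu[i]) * (z - x[i]) / (x[i + 1] - x[i]))
    }
  }
  0
}

# from-scratch max-min-centroid evaluation of the enhancement map at level z
oracle_enhance <- function(z, rules) {
  y <- rules$y_grid
  q <- rep(0, length(y))
  for (r in 1:3) {
    inset <- rules$input_sets[[r]]
    outset <- rules$output_sets[[r]]
    s <- oracle_membership(z, inset$x, inset$mu)
    for (k in seq_along(y)) {
      v <- min(s, oracle_membership(y[k], outset$x, outset$mu))
      if (v > q[k]) q[k] <- v
    }
  }
  if (sum(q) == 0) return(z)
  sum(y * q) / sum(q)
}

# textbook fuzzy C-means on a 1-D sample: returns centroid/membership history
oracle_fcm <- function(x, v0, w, n_iter) {
  v <- v0
  hist_v <- matrix(NA_real_, n_iter, length(v0))
  u <- NULL
  for (t in seq_len(n_iter)) {
    d <- abs(outer(v, x, "-"))
    u <- matrix(0, length(v), length(x))
    for (j in seq_along(x)) {
      if (any(d[, j] == 0)) {
        u[d[, j] == 0, j] <- 1 / sum(d[, j] == 0)
      } else {
        for (i in seq_along(v))
          u[i, j] <- 1 / sum((d[i, j] / d[, j])^(2 / (w - 1)))
      }
    }
    for (i in seq_along(v)) v[i] <- sum(u[i, ]^w * x) / sum(u[i, ]^w)
    hist_v[t, ] <- v
  }
  list(v = v, u = u, history = hist_v)
}

# signed distance function of a disk on an n x n grid
disk_sdf <- function(n, center, radius) {
  r <- matrix(seq_len(n), n, n)
  c_ <- matrix(seq_len(n), n, n, byrow = TRUE)
  sqrt((r - center[1])^2 + (c_ - center[2])^2) - radius
}

# binary disk mask
disk_mask <- function(n, center, radius) {
  matrix(as.numeric(disk_sdf(n, center, radius) <= 0), n, n)
}

grad_mag <- function(phi) {
  n <- nrow(phi); m <- ncol(phi)
  gx <- (phi[c(2:n, n), ] - phi[c(1, 1:(n - 1)), ]) / 2
  gy <- (phi[, c(2:m, m)] - phi[, c(1, 1:(m - 1))]) / 2
  sqrt(gx^2 + gy^2)
}

# equivalent-circle radius of the inside region
zero_set_radius <- function(phi) sqrt(sum(phi < 0) / pi)

n_components <- function(mask) {
  max(EBImage::bwlabel(matrix(as.numeric(mask > 0), nrow(mask), ncol(mask))))
}

# head phantom with a uniform brain (no internal tissue edges) and two
# separated lesions: exercises contour splitting without intervening edges
two_lesion_flat_phantom <- function(seed = 4) {
  make_phantom(phantom_spec(
    tissues = list(list(center = c(64, 64), semi = c(46, 38), mean = 60)),
    background = 60,
    lesions = list(list(center = c(50, 50), radius = 9, mean = 210),
                   list(center = c(80, 82), radius = 9, mean = 210)),
    seed = seed))
}

default_detect <- function(seed, cfg = pipeline_config()) {
  ph <- make_phantom(multiple_lesion_spec(1, seed = seed))
  res <- suppressWarnings(run_pipeline(ph$image, cfg, ph$truth))
  list(phantom = ph, result = res)
}
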