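#' Gaussian kernel estimate of the image histogram
#'
#' Smooths the intensity histogram with a standard-normal kernel:
#' `p(x) = 1/(N h) * sum_j psi((x - x_j) / h)` evaluated on the `L`-point
#' intensity grid. The sum runs over histogram bins weighted by their counts
#' rather than over pixels; by linearity the result is identical.
#'
#' @param img numeric matrix (or vector) of intensities in `[0, L - 1]`.
#' @param h kernel bandwidth, `h > 0`.
#' @param levels number of gray levels `L`.
#' @return Object of class `kde_profile`: `grid`, `density`, `h` and `modes`
#'   (grid locations of local density maxima, endpoints included).
#' @export
kde_histogram <- function(img, h, levels = 256L) {
  if (!is.numeric(h) || length(h) != 1L || h <= 0)
    stop_input("bandwidth h must be a single positive number")
  x <- round_half_up(as.numeric(img))
  if (any(x < 0) || any(x > levels - 1))
    stop_input(sprintf("intensities must lie in [0, %d]", levels - 1L))
  n <- length(x)
  counts <- tabulate(x + 1L, nbins = levels)
  grid <- 0:(levels - 1L)
  u <- outer(grid, grid, "-") / h
  dens <- as.vector((exp(-u^2 / 2) / sqrt(2 * pi)) %*% counts) / (n * h)
  structure(list(grid = grid, density = dens, h = h,
                 modes = grid[local_maxima(dens)]),
            class = "kde_profile")
}

# indices of strict local maxima, endpoints included
local_maxima <- function(d) {
  n <- length(d)
  left <- c(-Inf, d[-n])
  right <- c(d[-1L], -Inf)
  which(d > left & d > right)
}

#' Critical-bandwidth centroid initialization
#'
#' Scans bandwidths and returns the smallest `h` at which the kernel density
#' estimate of the histogram shows exactly `c` modes (the critical bandwidth);
#' the mode locations seed the cluster centroids. If no scanned bandwidth
#' yields exactly `c` modes, the `c` highest-density modes at the smallest
#' scanned bandwidth are used instead (with a warning).
#'
#' @param img numeric matrix of intensities.
#' @param c number of clusters (modes) wanted, `c >= 2`.
#' @param h_grid bandwidths to scan, within `(0, 50)`.
#' @param levels number of gray levels.
#' @return List with `h_crit`, `centroids` (ascending) and the `kde_profile`
#'   at `h_crit`.
#' @export
find_critical_bandwidth <- function(img, c, h_grid = seq(50, 0.5, by = -0.5),
                                    levels = 256L) {
  if (c < 2L) stop_input("c must be at least 2")
  if (any(h_grid <= 0) || any(h_grid >= 50 + 1e-9))
    stop_input("h_grid must lie in (0, 50]")
  x <- round_half_up(as.numeric(img))
  if (length(unique(x)) < c)
    stop_input(sprintf("image has fewer than %d distinct levels", c),
               class = "ugfc_init_error")
  hs <- sort(unique(h_grid))            # ascending: first hit is the minimum h
  for (h in hs) {
    prof <- kde_histogram(x, h, levels)
    if (length(prof$modes) == c)
      return(list(h_crit = h, centroids = sort(prof$modes), profile = prof))
  }
  prof <- kde_histogram(x, hs[1L], levels)
  if (length(prof$modes) < c)
    stop_input(sprintf("no bandwidth yields %d modes (at most %d found)",
                       c, length(prof$modes)), class = "ugfc_init_error")
  keep <- prof$modes[order(prof$density[prof$modes + 1L],
                           decreasing = TRUE)][seq_len(c)]
  warning(sprintf(
    "no scanned bandwidth gave exactly %d modes; using the %d strongest modes at h = %g",
    c, c, hs[1L]))
  list(h_crit = hs[1L], centroids = sort(keep), profile = prof)
}
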