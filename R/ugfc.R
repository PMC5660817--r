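#' Fuzzy C-means membership matrix
#'
#' `mu_ij = 1 / sum_k (d_ij / d_kj)^(2/(w-1))`; columns (pixels) sum to 1.
#' A pixel at zero distance from one or more centroids splits its membership
#' equally among those centroids.
#'
#' @param dist `c x N` matrix of non-negative pixel-to-centroid distances.
#' @param w fuzzifier, `w > 1`.
#' @return `c x N` membership matrix.
#' @export
fcm_memberships <- function(dist, w) {
  if (!is.matrix(dist)) stop_input("dist must be a c x N matrix")
  if (any(dist < 0)) stop_input("distances must be non-negative")
  if (w <= 1) stop_input("fuzzifier w must exceed 1")
  p <- -2 / (w - 1)
  zero <- dist == 0
  any_zero <- colSums(zero) > 0
  u <- matrix(0, nrow(dist), ncol(dist))
  if (any(!any_zero)) {
    dp <- dist[, !any_zero, drop = FALSE]^p
    u[, !any_zero] <- sweep(dp, 2L, colSums(dp), "/")
  }
  if (any(any_zero)) {
    z <- zero[, any_zero, drop = FALSE]
    u[, any_zero] <- sweep(z * 1, 2L, colSums(z), "/")
  }
  u
}

#' Newtonian attraction between a pixel and a cluster
#'
#' `F = l * m / d2` with every pixel carrying unit mass, so a cluster's mass
#' is its hard-assigned pixel count. The squared distance is floored at
#' `d2_floor` (one pixel spacing squared) so the force stays finite.
#'
#' @param mass cluster mass (hard-assigned pixel count), `>= 0`.
#' @param d2 squared distance(s) from the pixel to the cluster core.
#' @param l gravity coefficient standing in for Newton's constant (default 2).
#' @param d2_floor minimum squared distance.
#' @return Attraction force(s).
#' @export
gravity_force <- function(mass, d2, l = 2, d2_floor = 1) {
  if (any(mass < 0)) stop_input("mass must be non-negative")
  if (any(d2 < 0)) stop_input("squared distance must be non-negative")
  l * mass / pmax(d2, d2_floor)
}

#' Gravitational fuzzy clustering objectives
#'
#' `J_GC` sums squared intensity distances of hard-assigned pixels to their
#' centroid; `J_CM` is the fuzzy C-means objective `sum mu^w d^2` over fuzzy
#' pixels; the unified objective is their product `J_GFC = J_GC * J_CM`.
#' When no pixel is hard-assigned the empty `J_GC` is replaced by 1 so the
#' product reduces to `J_CM`.
#'
#' @param intensities length-`N` pixel intensities.
#' @param centroids length-`c` centroid intensities.
#' @param memberships `c x N` membership matrix.
#' @param hard_labels length-`N` integer labels in `1..c`, `NA` for fuzzy
#'   pixels.
#' @param w fuzzifier.
#' @return List with `j_gc`, `j_cm`, `j_gfc`.
#' @export
ugfc_objective <- function(intensities, centroids, memberships, hard_labels, w) {
  hard <- !is.na(hard_labels)
  j_gc <- if (any(hard)) {
    sum((intensities[hard] - centroids[hard_labels[hard]])^2)
  } else 1
  if (any(!hard)) {
    d2 <- (outer(centroids, intensities[!hard], "-"))^2
    j_cm <- sum(memberships[, !hard, drop = FALSE]^w * d2)
  } else {
    j_cm <- 0
  }
  list(j_gc = j_gc, j_cm = j_cm, j_gfc = j_gc * j_cm)
}

#' Unified gravitational fuzzy clustering
#'
#' Alternating segmentation of a grayscale image into `c` intensity clusters.
#' Each iteration: (1) intensity distances to the centroids; (2) fuzzy C-means
#' memberships; (3) pixels whose top membership reaches `theta_hard` are
#' hard-clustered to it; (4) remaining fuzzy pixels are additionally captured
#' by a cluster whose Newtonian pull (cluster mass over squared planar
#' distance to the cluster's hard-core spatial centroid) dominates every
#' other cluster's pull by the factor `gamma`; (5) centroids are updated as
#' the intensity mean weighted 1 for hard pixels and `mu^w` for fuzzy pixels;
#' (6) masses, core centroids and the objectives are recomputed. Iteration
#' stops when no centroid moves more than `rho` intensity levels.
#'
#' Centroids are seeded at the modes of the kernel density estimate of the
#' histogram at the critical bandwidth (see [find_critical_bandwidth()])
#' unless `init` is given. Setting `theta_hard > 1` and `gamma = Inf`
#' disables hard clustering and gravity capture, reducing the loop to
#' standard fuzzy C-means.
#'
#' @param img numeric intensity matrix.
#' @param c number of clusters, `>= 2`.
#' @param w fuzzifier in `(1.4, 2.6)` (1.7 default).
#' @param rho convergence threshold on centroid movement, intensity levels.
#' @param theta_hard membership threshold for hard clustering, in `(0.5, 1]`
#'   (values `> 1` disable hard clustering).
#' @param gamma gravity dominance factor (`Inf` disables gravity capture).
#' @param max_iter iteration cap.
#' @param init optional initial centroids (ascending).
#' @param levels number of gray levels.
#' @param l gravity coefficient.
#' @return Object of class `ugfc_state`: `centroids`, `memberships` (`c x N`,
#'   column-major pixel order), `hard_labels` (matrix, `NA` = fuzzy),
#'   `masses`, `core_xy`, `iterations`, `converged`, and a per-iteration
#'   `trace` data frame (`t`, `j_gc`, `j_cm`, `j_gfc`, centroids,
#'   `hard_count`).
#' @export
ugfc_cluster <- function(img, c = 4L, w = 1.7, rho = 0.01, theta_hard = 0.85,
                         gamma = 2, max_iter = 100L, init = NULL,
                         levels = 256L, l = 2) {
  check_gray_image(img, levels)
  if (c < 2L) stop_input("c must be at least 2")
  if (w <= 1) stop_input("fuzzifier w must exceed 1")
  if (rho <= 0) stop_input("rho must be positive")
  if (theta_hard <= 0.5) stop_input("theta_hard must exceed 0.5")

  x <- as.numeric(img)
  n <- length(x)
  rows <- as.numeric(row(img))
  cols <- as.numeric(col(img))
  v <- if (is.null(init)) {
    as.numeric(find_critical_bandwidth(img, c, levels = levels)$centroids)
  } else {
    if (length(init) != c) stop_input("init must supply one centroid per cluster")
    as.numeric(init)
  }

  trace <- vector("list", max_iter)
  converged <- FALSE
  u <- NULL; labels <- rep(NA_integer_, n)
  masses <- integer(c); core_xy <- matrix(NA_real_, c, 2L)

  for (t in seq_len(max_iter)) {
    d <- abs(outer(v, x, "-"))
    u <- fcm_memberships(d, w)
    top <- apply(u, 2L, which.max)          # ties -> lower index
    utop <- u[cbind(top, seq_len(n))]
    labels <- ifelse(utop >= theta_hard, top, NA_integer_)

    # gravity capture of fuzzy pixels by a dominating cluster core
    hard <- !is.na(labels)
    masses <- tabulate(labels[hard], nbins = c)
    core_xy <- t(vapply(seq_len(c), function(i) {
      sel <- hard & labels == i
      if (any(sel)) c(mean(rows[sel]), mean(cols[sel])) else c(NA_real_, NA_real_)
    }, numeric(2L)))
    if (is.finite(gamma) && any(masses > 0) && any(!hard)) {
      fuzzy_idx <- which(!hard)
      f <- matrix(0, c, length(fuzzy_idx))
      for (i in seq_len(c)) {
        if (masses[i] == 0L) next
        d2 <- (rows[fuzzy_idx] - core_xy[i, 1L])^2 +
              (cols[fuzzy_idx] - core_xy[i, 2L])^2
        f[i, ] <- gravity_force(masses[i], d2, l = l)
      }
      fbest <- apply(f, 2L, which.max)
      fmax <- f[cbind(fbest, seq_along(fuzzy_idx))]
      fsec <- apply(f, 2L, function(col) sort(col, decreasing = TRUE)[2L])
      captured <- fmax >= gamma * fsec & fmax > 0
      labels[fuzzy_idx[captured]] <- fbest[captured]
      hard <- !is.na(labels)
      masses <- tabulate(labels[hard], nbins = c)
      core_xy <- t(vapply(seq_len(c), function(i) {
        sel <- hard & labels == i
        if (any(sel)) c(mean(rows[sel]), mean(cols[sel])) else c(NA_real_, NA_real_)
      }, numeric(2L)))
    }

    # centroid update: weight 1 for hard members, mu^w for fuzzy pixels
    v_new <- v
    uw <- u^w
    for (i in seq_len(c)) {
      sel_hard <- hard & labels == i
      wf <- uw[i, !hard]
      num <- sum(x[sel_hard]) + sum(wf * x[!hard])
      den <- sum(sel_hard) + sum(wf)
      if (den > 0) v_new[i] <- num / den
    }

    obj <- ugfc_objective(x, v_new, u, labels, w)
    trace[[t]] <- c(t = t, j_gc = obj$j_gc, j_cm = obj$j_cm, j_gfc = obj$j_gfc,
                    stats::setNames(v_new, paste0("v_", seq_len(c))),
                    hard_count = sum(hard))
    delta <- max(abs(v_new - v))
    v <- v_new
    if (delta < rho) { converged <- TRUE; break }
  }

  trace <- as.data.frame(do.call(rbind, trace[!vapply(trace, is.null, logical(1))]))
  if (!converged)
    warning(sprintf("UGFC did not converge within %d iterations", max_iter))
  structure(list(
    centroids = v, memberships = u,
    hard_labels = matrix(labels, nrow(img), ncol(img)),
    masses = masses, core_xy = core_xy,
    iterations = nrow(trace), converged = converged, trace = trace,
    params = list(c = c, w = w, rho = rho, theta_hard = theta_hard,
                  gamma = gamma, l = l, levels = levels),
    dims = dim(img)), class = "ugfc_state")
}

#' Extract the region of interest from a clustering state
#'
#' Selects the candidate lesion cluster — by default the cluster with the
#' highest centroid, since enhanced lesions are hyperintense — and returns
#' the binary mask of pixels hard-assigned or argmax-assigned to it.
#'
#' @param state a [ugfc_cluster()] result.
#' @param rule `"brightest"` or a cluster index (1-based).
#' @param exclude_border drop connected components touching the image border
#'   (suppresses skull/scalp picks).
#' @return Binary 0/1 matrix with attributes `selected_cluster` and `empty`.
#' @export
extract_roi <- function(state, rule = "brightest", exclude_border = FALSE) {
  stopifnot(inherits(state, "ugfc_state"))
  sel <- if (identical(rule, "brightest")) {
    which.max(state$centroids)
  } else {
    k <- as.integer(rule)
    if (is.na(k) || k < 1L || k > length(state$centroids))
      stop_input("rule must be 'brightest' or a valid cluster index")
    k
  }
  labels <- as.vector(state$hard_labels)
  top <- apply(state$memberships, 2L, which.max)
  assigned <- ifelse(is.na(labels), top, labels)
  mask <- matrix(as.numeric(assigned == sel), state$dims[1L], state$dims[2L])
  if (exclude_border && any(mask > 0)) {
    lab <- EBImage::bwlabel(mask)
    border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
    mask[lab %in% setdiff(border, 0)] <- 0
  }
  empty <- !any(mask > 0)
  if (empty) warning("extracted ROI is empty")
  attr(mask, "selected_cluster") <- sel
  attr(mask, "empty") <- empty
  mask
}

#' @export
print.ugfc_state <- function(x, ...) {
  cat(sprintf("UGFC state: %d clusters, %d iterations (%s)\n",
              length(x$centroids), x$iterations,
              if (x$converged) "converged" else "not converged"))
  cat("centroids:", paste(sprintf("%.2f", x$centroids), collapse = ", "), "\n")
  cat("masses:   ", paste(x$masses, collapse = ", "), "\n")
  invisible(x)
}
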