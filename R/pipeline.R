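#' Pipeline configuration
#'
#' Bundles and range-checks every stage parameter of the detection cascade.
#' Violated ranges are rejected with the offending key named.
#'
#' @param levels gray levels of the working image.
#' @param clusters number of intensity clusters `c` (default 4: background,
#'   dark tissue, bright tissue, lesion).
#' @param fuzzifier FCM fuzzifier `w`, restricted to `(1.4, 2.6)`.
#' @param rho UGFC convergence threshold (intensity levels on the 0-255
#'   scale).
#' @param theta_hard hard-core membership threshold, in `(0.5, 1]`.
#' @param gamma gravity dominance factor, `>= 1` (may be `Inf`).
#' @param max_iter_cluster UGFC iteration cap.
#' @param roi_rule `"brightest"` or a cluster index.
#' @param exclude_border drop ROI components touching the image border.
#' @param beta internal-energy weight, in `[0.04, 0.1]`.
#' @param lambda length-term weight, in `[2, 6]`.
#' @param nu area-term weight, `|nu|` in `[1, 3.5]`.
#' @param sigma edge-indicator Gaussian scale, `> 0`.
#' @param dt level-set time step (`beta * dt < 0.25`).
#' @param eps Dirac/Heaviside regularization width.
#' @param c0 binary-step initialization height.
#' @param max_iter_levelset level-set iteration cap.
#' @param stop_tol level-set stopping tolerance (pixels per 10 iterations).
#' @param grad_tol level-set distance-regularity tolerance (see
#'   [levelset_params()]).
#' @param dirac Dirac factor mode for the evolution (see [levelset_params()]).
#' @param seed seed recorded in run reports (the cascade itself is
#'   deterministic).
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(levels = 256L, clusters = 4L, fuzzifier = 1.7,
                            rho = 0.01, theta_hard = 0.85, gamma = 2,
                            max_iter_cluster = 100L, roi_rule = "brightest",
                            exclude_border = FALSE, beta = 0.04, lambda = 5,
                            nu = 1.5, sigma = 1.5, dt = 5, eps = 1.5, c0 = 2,
                            max_iter_levelset = 1500L, stop_tol = 2, grad_tol = 0.2,
                            dirac = "cosine", seed = 0L) {
  fail <- function(key, why) stop_validation(sprintf("config key '%s' %s", key, why))
  if (levels < 2) fail("levels", "must be at least 2")
  if (clusters < 2) fail("clusters", "must be at least 2")
  if (fuzzifier <= 1.4 || fuzzifier >= 2.6) fail("fuzzifier", "must lie in (1.4, 2.6)")
  if (rho <= 0) fail("rho", "must be positive")
  if (theta_hard <= 0.5 || theta_hard > 1) fail("theta_hard", "must lie in (0.5, 1]")
  if (gamma < 1) fail("gamma", "must be at least 1")
  if (beta < 0.04 || beta > 0.1) fail("beta", "must lie in [0.04, 0.1]")
  if (lambda < 2 || lambda > 6) fail("lambda", "must lie in [2, 6]")
  if (abs(nu) < 1 || abs(nu) > 3.5) fail("nu", "must have |nu| in [1, 3.5]")
  if (sigma <= 0) fail("sigma", "must be positive")
  if (dt <= 0) fail("dt", "must be positive")
  if (beta * dt >= 0.25) fail("dt", "must satisfy beta * dt < 0.25")
  if (eps <= 0) fail("eps", "must be positive")
  if (c0 <= 0) fail("c0", "must be positive")
  if (stop_tol <= 0) fail("stop_tol", "must be positive")
  if (grad_tol <= 0) fail("grad_tol", "must be positive")
  if (!identical(roi_rule, "brightest") && is.na(suppressWarnings(as.integer(roi_rule))))
    fail("roi_rule", "must be 'brightest' or a cluster index")
  if (!dirac %in% c("geometric", "cosine")) fail("dirac", "must be 'geometric' or 'cosine'")
  structure(list(levels = as.integer(levels), clusters = as.integer(clusters),
                 fuzzifier = fuzzifier, rho = rho, theta_hard = theta_hard,
                 gamma = gamma, max_iter_cluster = as.integer(max_iter_cluster),
                 roi_rule = roi_rule, exclude_border = isTRUE(exclude_border),
                 beta = beta, lambda = lambda, nu = nu, sigma = sigma, dt = dt,
                 eps = eps, c0 = c0,
                 max_iter_levelset = as.integer(max_iter_levelset),
                 stop_tol = stop_tol, grad_tol = grad_tol, dirac = dirac,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full lesion-detection cascade
#'
#' Enhance -> cluster -> refine, with optional evaluation against a ground
#' truth mask. An empty ROI from the clustering stage short-circuits the
#' refinement and yields an empty final mask (with a warning).
#'
#' @param img grayscale matrix with values in `[0, levels - 1]`.
#' @param cfg a [pipeline_config()].
#' @param truth optional binary ground-truth mask for evaluation.
#' @return Object of class `lesion_detection`: `mask` (final binary mask),
#'   `roi` (clustering-stage mask), `enhanced`, `metrics` (or `NULL`),
#'   `state` (the `ugfc_state`) and a `report` recording per-stage timings,
#'   the objective trace, level-set iteration count and all effective
#'   parameters.
#' @export
run_pipeline <- function(img, cfg = pipeline_config(), truth = NULL) {
  stopifnot(inherits(cfg, "pipeline_config"))
  check_gray_image(img, cfg$levels)
  timings <- c()
  tic <- function() proc.time()[["elapsed"]]

  t0 <- tic()
  enhanced <- enhance_image(img, levels = cfg$levels)
  timings["enhance"] <- tic() - t0

  t0 <- tic()
  state <- ugfc_cluster(enhanced, c = cfg$clusters, w = cfg$fuzzifier,
                        rho = cfg$rho, theta_hard = cfg$theta_hard,
                        gamma = cfg$gamma, max_iter = cfg$max_iter_cluster,
                        levels = cfg$levels)
  roi <- extract_roi(state, rule = cfg$roi_rule,
                     exclude_border = cfg$exclude_border)
  timings["cluster"] <- tic() - t0

  ls_iters <- 0L
  if (attr(roi, "empty")) {
    warning("empty ROI; skipping contour refinement")
    mask <- roi
  } else {
    t0 <- tic()
    g <- edge_indicator(enhanced, cfg$sigma)
    params <- levelset_params(beta = cfg$beta, lambda = cfg$lambda,
                              nu = cfg$nu, sigma = cfg$sigma, dt = cfg$dt,
                              eps = cfg$eps, c0 = cfg$c0,
                              max_iter = cfg$max_iter_levelset,
                              stop_tol = cfg$stop_tol, grad_tol = cfg$grad_tol,
                              dirac = cfg$dirac)
    phi0 <- init_phi(roi, cfg$c0)
    ev <- evolve(phi0, g, params)
    mask <- ev$mask
    ls_iters <- ev$iterations
    timings["refine"] <- tic() - t0
  }

  metrics <- if (!is.null(truth)) overlap_metrics(truth, mask) else NULL
  structure(list(
    mask = mask, roi = roi, enhanced = enhanced, state = state,
    phi = if (exists("ev")) ev$phi else NULL,
    metrics = metrics,
    report = list(timings = timings, trace = state$trace,
                  levelset_iterations = ls_iters,
                  cluster_converged = state$converged,
                  parameters = unclass(cfg))),
    class = "lesion_detection")
}

#' @export
print.lesion_detection <- function(x, ...) {
  cat(sprintf("lesion detection: final mask %d px (ROI %d px), %d level-set iterations\n",
              sum(x$mask), sum(x$roi), x$report$levelset_iterations))
  if (!is.null(x$metrics)) print(x$metrics)
  invisible(x)
}

#' Segmentation quality as a function of the fuzzifier
#'
#' Runs the full cascade for each fuzzifier value and reports the Dice
#' overlap against the ground truth, exposing the sensitivity of the
#' segmentation to `w`.
#'
#' @param img grayscale matrix.
#' @param truth binary ground-truth mask.
#' @param w_values fuzzifier values to sweep.
#' @param cfg base configuration.
#' @return data.frame with columns `w` and `dice`.
#' @export
sweep_fuzzifier <- function(img, truth, w_values = c(1.5, 1.6, 1.7, 1.8, 1.9),
                            cfg = pipeline_config()) {
  dice <- vapply(w_values, function(w) {
    cfg$fuzzifier <- w
    run_pipeline(img, cfg, truth)$metrics$dice
  }, numeric(1))
  data.frame(w = w_values, dice = dice)
}
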