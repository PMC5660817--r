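#' Piecewise-linear fuzzy set
#'
#' A fuzzy set over the intensity axis, defined by ordered knots `(x, mu)`.
#' Membership is linearly interpolated between knots and zero outside the
#' first/last knot.
#'
#' @param x strictly increasing intensity knots in `[0, levels - 1]`.
#' @param mu membership values in `[0, 1]`, one per knot.
#' @param kind label, e.g. `"dark"` or `"brighter"`.
#' @param levels number of gray levels `L` (intensities live on `[0, L-1]`).
#' @return An object of class `fuzzy_set`.
#' @export
fuzzy_set <- function(x, mu, kind = "unnamed", levels = 256L) {
  if (length(x) != length(mu) || length(x) < 2L)
    stop_input("need at least two (x, mu) knots of equal length")
  if (any(diff(x) <= 0)) stop_input("knots must be strictly increasing")
  if (any(x < 0) || any(x > levels - 1))
    stop_input(sprintf("knots must lie in [0, %d]", levels - 1L))
  if (any(mu < 0) || any(mu > 1)) stop_input("memberships must lie in [0, 1]")
  structure(list(x = as.numeric(x), mu = as.numeric(mu),
                 kind = kind, levels = as.integer(levels)),
            class = "fuzzy_set")
}

#' Evaluate a fuzzy membership function
#'
#' @param z intensity value(s) in `[0, levels - 1]`.
#' @param fset a [fuzzy_set()].
#' @return Membership degree(s) in `[0, 1]`; 0 outside the set's support.
#' @export
membership_eval <- function(z, fset) {
  stopifnot(inherits(fset, "fuzzy_set"))
  if (any(z < 0) || any(z > fset$levels - 1))
    stop_input(sprintf("z must lie in [0, %d]", fset$levels - 1L))
  stats::approx(fset$x, fset$mu, xout = z, yleft = 0, yright = 0,
                ties = "ordered")$y
}

#' Three-rule fuzzy rule base for contrast enhancement
#'
#' Builds the rule base "IF dark THEN darker; IF gray THEN gray; IF bright
#' THEN brighter". Input sets: `dark` is 1 on `[0, L/4]` and falls linearly
#' to 0 at the midpoint; `gray` is a triangle peaking at the midpoint with
#' half-width `L/4`; `bright` mirrors `dark` (0 at the midpoint, 1 from
#' `3L/4` up). Output sets are unit triangles peaking at 0, the midpoint and
#' `L - 1`, each with half-width `L/4`. The input plateaus make the induced
#' intensity map an expanding S-curve — dark pixels mapped darker, bright
#' pixels brighter, mid-gray preserved; without them the centroid
#' defuzzification is dominated by the (two-sided) gray output triangle and
#' the map contracts toward mid-gray instead. All knots can be overridden.
#'
#' @param levels number of gray levels `L`.
#' @param input_sets,output_sets optional lists of three [fuzzy_set()]s
#'   (ordered dark/gray/bright and darker/gray_out/brighter) replacing the
#'   defaults.
#' @param p number of discrete output levels used for aggregation and
#'   centroid defuzzification (default `L`).
#' @return An object of class `fuzzy_rule_base`.
#' @export
fuzzy_rule_base <- function(levels = 256L, input_sets = NULL,
                            output_sets = NULL, p = levels) {
  L <- as.integer(levels)
  if (p < 2L) stop_input("p must be at least 2")
  mid <- floor((L - 1L) / 2)
  hw <- L / 4
  if (is.null(input_sets)) {
    input_sets <- list(
      dark   = fuzzy_set(c(0, hw, mid), c(1, 1, 0), "dark", L),
      gray   = fuzzy_set(c(mid - hw, mid, mid + hw), c(0, 1, 0), "gray", L),
      bright = fuzzy_set(c(mid, mid + hw, L - 1), c(0, 1, 1), "bright", L))
  }
  if (is.null(output_sets)) {
    output_sets <- list(
      darker   = fuzzy_set(c(0, hw), c(1, 0), "darker", L),
      gray_out = fuzzy_set(c(mid - hw, mid, mid + hw), c(0, 1, 0), "gray_out", L),
      brighter = fuzzy_set(c(L - 1 - hw, L - 1), c(0, 1), "brighter", L))
  }
  if (length(input_sets) != 3L || length(output_sets) != 3L)
    stop_input("exactly three input and three output sets are required")
  structure(list(input_sets = input_sets, output_sets = output_sets,
                 y_grid = seq(0, L - 1, length.out = p), levels = L),
            class = "fuzzy_rule_base")
}

#' Aggregate the fuzzy response to one input intensity
#'
#' Max-min composition: each rule's output set is clipped (min) at the firing
#' strength of its antecedent evaluated at `z0`, and the three clipped sets
#' are united (max) on the output grid.
#'
#' @param z0 input intensity in `[0, L - 1]`.
#' @param rules a [fuzzy_rule_base()].
#' @return An object of class `fuzzy_output` with fields `y` (grid) and
#'   `values` (aggregated response `Q(y)` in `[0, 1]`).
#' @export
aggregate_response <- function(z0, rules) {
  stopifnot(inherits(rules, "fuzzy_rule_base"))
  if (length(z0) != 1L || z0 < 0 || z0 > rules$levels - 1)
    stop_input(sprintf("z0 must be a single value in [0, %d]", rules$levels - 1L))
  y <- rules$y_grid
  q <- rep(0, length(y))
  for (r in 1:3) {
    strength <- membership_eval(z0, rules$input_sets[[r]])
    q <- pmax(q, pmin(strength, membership_eval(y, rules$output_sets[[r]])))
  }
  structure(list(y = y, values = q), class = "fuzzy_output")
}

#' Centroid (center-of-gravity) defuzzification
#'
#' @param Q a `fuzzy_output` from [aggregate_response()].
#' @return The crisp output intensity `sum(y * Q) / sum(Q)`.
#' @export
defuzzify_centroid <- function(Q) {
  stopifnot(inherits(Q, "fuzzy_output"))
  s <- sum(Q$values)
  if (s <= 0)
    stop_input("aggregated response is identically zero; no centroid exists",
               class = "ugfc_degenerate_output")
  sum(Q$y * Q$values) / s
}

#' Intensity lookup table induced by a fuzzy rule base
#'
#' The enhancement mapping depends only on the pixel value, so the whole
#' transform is an `L`-entry table: entry `z + 1` is the defuzzified response
#' to input `z`. Levels whose aggregated response is identically zero map to
#' themselves (with a warning); this cannot happen when the input sets cover
#' the intensity axis.
#'
#' @param rules a [fuzzy_rule_base()].
#' @return Numeric vector of length `L` (unrounded intensities).
#' @export
fuzzy_lut <- function(rules) {
  stopifnot(inherits(rules, "fuzzy_rule_base"))
  L <- rules$levels
  lut <- numeric(L)
  degenerate <- 0L
  for (z in 0:(L - 1)) {
    q <- aggregate_response(z, rules)
    if (sum(q$values) <= 0) {
      lut[z + 1L] <- z
      degenerate <- degenerate + 1L
    } else {
      lut[z + 1L] <- defuzzify_centroid(q)
    }
  }
  if (degenerate > 0L)
    warning(sprintf("%d levels had an all-zero response; identity used", degenerate))
  lut
}

#' Fuzzy rule-based contrast enhancement
#'
#' Applies the max-min-centroid fuzzy transform pointwise: dark pixels are
#' pushed darker, mid-gray pixels are preserved, bright pixels are pushed
#' brighter, expanding the dynamic range of a low-contrast scan.
#'
#' @param img numeric matrix with values in `[0, L - 1]`.
#' @param rules a [fuzzy_rule_base()]; default built for `levels`.
#' @param levels number of gray levels.
#' @param round if `TRUE` (default) round half-up to integer levels; set
#'   `FALSE` to keep the unrounded ("float") output for later clustering.
#' @return Enhanced image, same shape, values in `[0, L - 1]`.
#' @export
enhance_image <- function(img, rules = NULL, levels = 256L, round = TRUE) {
  check_gray_image(img, levels)
  if (is.null(rules)) rules <- fuzzy_rule_base(levels)
  if (rules$levels != levels) stop_input("rule base levels do not match image levels")
  lut <- fuzzy_lut(rules)
  if (round) lut <- clamp(round_half_up(lut), 0, levels - 1)
  out <- matrix(lut[round_half_up(img) + 1L], nrow(img), ncol(img))
  out
}
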