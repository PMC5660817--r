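test_that("FCM memberships follow the closed form and sum to one", {
  # all distances equal -> uniform memberships
  d <- matrix(3, 4, 5)
  u <- fcm_memberships(d, w = 2)
  expect_true(all(abs(u - 0.25) < 1e-12))

  # zero distance -> full membership there
  d2 <- rbind(c(0, 1), c(2, 2))
  u2 <- fcm_memberships(d2, w = 2)
  expect_equal(u2[, 1], c(1, 0))

  # c = 2, d = (1, 2), w = 2 -> exponent 2, memberships (0.8, 0.2)
  u3 <- fcm_memberships(matrix(c(1, 2), 2, 1), w = 2)
  expect_equal(as.vector(u3), c(0.8, 0.2))

  # ties at zero split equally
  u4 <- fcm_memberships(matrix(c(0, 0, 5), 3, 1), w = 1.7)
  expect_equal(as.vector(u4), c(0.5, 0.5, 0))

  # columns always sum to 1
  set.seed(1)
  d5 <- matrix(rexp(300), 3, 100)
  expect_equal(colSums(fcm_memberships(d5, 1.7)), rep(1, 100))

  expect_error(fcm_memberships(matrix(-1, 2, 1), 2), class = "ugfc_input_error")
})

test_that("gravity force is Newtonian with l = 2, unit pixel mass, floored d2", {
  expect_equal(gravity_force(1, 1), 2)
  expect_equal(gravity_force(8, 4), 4)        # 2 * 8 / 4
  expect_equal(gravity_force(0, 9), 0)        # empty cluster attracts nothing
  # linearity in mass: doubling the mass doubles the pull at fixed d2
  expect_equal(gravity_force(10, 7), 2 * gravity_force(5, 7))
  # floor prevents singular attraction
  expect_equal(gravity_force(3, 0), gravity_force(3, 1))
  expect_error(gravity_force(-1, 4), class = "ugfc_input_error")
})

test_that("objectives: J_GC over hard pixels, J_CM over fuzzy, product J_GFC", {
  x <- c(0, 0, 10, 10)
  v <- c(0, 10)
  u <- fcm_memberships(abs(outer(v, x, "-")), 2)
  # all hard, every pixel at its centroid -> J_GC = 0 -> J_GFC = 0
  obj <- ugfc_objective(x, v, u, hard_labels = c(1L, 1L, 2L, 2L), w = 2)
  expect_equal(obj$j_gc, 0)
  expect_equal(obj$j_gfc, 0)

  # no hard pixels: J_GC substituted by 1 so J_GFC reduces to J_CM
  obj2 <- ugfc_objective(x, v, u, hard_labels = rep(NA_integer_, 4), w = 2)
  expect_equal(obj2$j_gc, 1)
  expect_equal(obj2$j_gfc, obj2$j_cm)

  # mixed case: hand-computed sums
  x3 <- c(1, 9, 5)
  v3 <- c(0, 10)
  d3 <- abs(outer(v3, x3, "-"))
  u3 <- fcm_memberships(d3, 2)
  obj3 <- ugfc_objective(x3, v3, u3, c(1L, 2L, NA), w = 2)
  expect_equal(obj3$j_gc, 1 + 1)
  expect_equal(obj3$j_cm, u3[1, 3]^2 * 25 + u3[2, 3]^2 * 25)
  expect_equal(obj3$j_gfc, obj3$j_gc * obj3$j_cm)
})

test_that("separable two-level image converges to exact centroids, all hard", {
  img <- matrix(c(rep(50, 32), rep(200, 32)), 8, 8)
  st <- ugfc_cluster(img, c = 2)
  expect_true(st$converged)
  expect_equal(st$centroids, c(50, 200))
  expect_true(all(!is.na(st$hard_labels)))
  expect_equal(sum(st$masses), 64)
})

test_that("membership normalization and mass conservation hold every iteration", {
  ph <- make_phantom(phantom_spec(seed = 2, noise_sd = 10))
  st <- ugfc_cluster(ph$image, c = 4, max_iter = 30)
  expect_equal(colSums(st$memberships), rep(1, length(ph$image)))
  expect_equal(sum(st$masses) + sum(is.na(st$hard_labels)), length(ph$image))
})

test_that("with hard clustering and gravity disabled, UGFC is textbook FCM", {
  for (seed in 1:3) {
    x <- sample_mixture_1d(c(60, 180), c(10, 15), c(0.5, 0.5), n = 150,
                           seed = seed)
    v0 <- c(60, 180)
    st <- suppressWarnings(
      ugfc_cluster(matrix(x, 10, 15), c = 2, w = 1.7, theta_hard = 2,
                   gamma = Inf, max_iter = 12, rho = 1e-12, init = v0))
    ref <- oracle_fcm(x, v0, w = 1.7, n_iter = nrow(st$trace))
    # centroid trajectory matches the oracle iterate by iterate
    expect_equal(unname(as.matrix(st$trace[, c("v_1", "v_2")])),
                 ref$history, tolerance = 1e-6)
    expect_equal(st$memberships, ref$u, tolerance = 1e-6)
  }
})

test_that("J_CM is non-increasing in the FCM limit", {
  x <- sample_mixture_1d(c(50, 120, 200), c(10, 10, 10), rep(1 / 3, 3),
                         n = 200, seed = 11)
  st <- suppressWarnings(
    ugfc_cluster(matrix(x, 10, 20), c = 3, theta_hard = 2, gamma = Inf,
                 max_iter = 25, rho = 1e-10, init = c(50, 120, 200)))
  expect_true(all(diff(st$trace$j_cm) <= 1e-8))
})

test_that("parameter recovery on the three-class phantom", {
  spec <- phantom_spec(seed = 5, lesions = list(), bias_amp = 0,
                       noise_sd = 10,
                       tissues = list(
                         a = list(center = c(64, 64), semi = c(46, 38), mean = 120),
                         b = list(center = c(64, 64), semi = c(32, 26), mean = 200)),
                       background = 50)
  ph <- make_phantom(spec)
  st <- ugfc_cluster(ph$image, c = 3, w = 1.7)
  expect_true(all(abs(sort(st$centroids) - c(50, 120, 200)) <= 5))
})

test_that("ROI extraction selects the brightest cluster and flags empties", {
  img <- matrix(c(rep(50, 40), rep(200, 24)), 8, 8)
  st <- ugfc_cluster(img, c = 2)
  roi <- extract_roi(st)
  expect_equal(as.vector(roi), as.numeric(img == 200))
  expect_equal(attr(roi, "selected_cluster"), which.max(st$centroids))
  expect_false(attr(roi, "empty"))

  # explicit index rule selects the other cluster
  roi1 <- extract_roi(st, rule = which.min(st$centroids))
  expect_equal(as.vector(roi1), as.numeric(img == 50))

  # exclude-border removes components touching the frame
  roi2 <- suppressWarnings(extract_roi(st, exclude_border = TRUE))
  expect_true(attr(roi2, "empty") || sum(roi2) <= sum(roi))
})

test_that("gravity capture hardens fuzzy pixels near a dominant core", {
  # two spatially separated blobs + intermediate-intensity pixels midway in
  # value: without gravity they stay fuzzy, with gravity they join a core
  img <- matrix(50, 12, 12)
  img[, 7:12] <- 200
  img[6, 6] <- 125; img[7, 7] <- 125
  st_g <- ugfc_cluster(img, c = 2, theta_hard = 0.9, gamma = 1.5,
                       init = c(50, 200))
  st_ng <- ugfc_cluster(img, c = 2, theta_hard = 0.9, gamma = Inf,
                        init = c(50, 200))
  expect_gte(sum(st_g$masses), sum(st_ng$masses))
})
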