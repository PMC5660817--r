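test_that("edge indicator is 1 on flat images and small on strong edges", {
  flat <- matrix(80, 32, 32)
  expect_true(all(edge_indicator(flat, 1) == 1))

  step <- matrix(0, 64, 64); step[, 33:64] <- 100
  g <- edge_indicator(step, sigma = 1)
  expect_true(all(g > 0 & g <= 1))
  expect_lt(max(g[, 32:34]), 0.05)           # at the step
  expect_gt(min(g[, c(1:20, 45:64)]), 0.99)  # far from it

  set.seed(3)
  noisy <- matrix(runif(400, 0, 255), 20, 20)
  gn <- edge_indicator(noisy, 2)
  expect_true(all(gn > 0 & gn <= 1))
})

test_that("binary-step initialization places the zero crossing on the ROI edge", {
  full <- matrix(1, 8, 8)
  expect_true(all(init_phi(full, 2) == -2))

  single <- matrix(0, 9, 9); single[5, 5] <- 1
  expect_equal(sum(init_phi(single, 2) < 0), 1)

  disk <- disk_mask(64, c(32, 32), 10)
  phi <- init_phi(disk, 2)
  # sign flips exactly across the rasterized disk boundary
  expect_equal(matrix(as.numeric(phi < 0), 64, 64), disk)

  expect_error(init_phi(matrix(0, 4, 4)), class = "ugfc_init_error")
})

test_that("internal energy measures deviation from the Eikonal property", {
  n <- 64
  sdf <- disk_sdf(n, c(32, 32), 15)
  # interior of the grid: the SDF satisfies |grad phi| = 1 almost everywhere
  expect_lt(internal_energy(sdf) / n^2, 0.02)
  # constant field: |grad| = 0 everywhere -> P = area / 2
  expect_equal(internal_energy(matrix(5, n, n)), n^2 / 2)
  # doubled SDF: |grad| = 2 -> (2 - 1)^2 contributes area / 2 (up to the
  # kink at the center and grid boundary)
  expect_equal(internal_energy(2 * sdf), n^2 / 2, tolerance = 0.08)
})

test_that("external energies recover area and length of a disk when g = 1", {
  n <- 128; r <- 20
  sdf <- disk_sdf(n, c(64, 64), r)
  g1 <- matrix(1, n, n)
  en <- external_energy(sdf, g1, lambda = 1, nu = 1)
  expect_equal(en$a_g, pi * r^2, tolerance = 0.02)
  expect_equal(en$l_g, 2 * pi * r, tolerance = 0.05)
  expect_equal(en$total, en$l_g + en$a_g)

  # contour absent: far-positive field has no Dirac band and no inside
  en0 <- external_energy(matrix(10, n, n), g1, 5, 1.5)
  expect_equal(en0$l_g, 0)
  expect_equal(en0$a_g, 0)
})

test_that("a signed distance function is a fixed point of the internal term", {
  n <- 96
  sdf <- disk_sdf(n, c(48, 48), 20)
  p <- levelset_params(beta = 0.04, lambda = 0, nu = 0, dt = 1)
  phi1 <- evolve_step(sdf, matrix(1, n, n), p)
  core <- abs(sdf) < 15 & abs(sdf) > 2     # away from kink and boundary
  expect_lt(max(abs(phi1 - sdf)[core]), 0.02)
})

test_that("curvature flow in geometric mode follows the analytic radius law", {
  n <- 128; r0 <- 30; lam <- 1
  phi <- disk_sdf(n, c(64.5, 64.5), r0)
  g1 <- matrix(1, n, n)
  p <- levelset_params(beta = 0, lambda = lam, nu = 0, dt = 0.2,
                       dirac = "geometric")
  t_check <- c(100, 200)
  t_now <- 0
  for (tc in t_check) {
    steps <- round((tc - t_now) / p$dt)
    for (s in seq_len(steps)) phi <- evolve_step(phi, g1, p)
    t_now <- tc
    expect_equal(zero_set_radius(phi), sqrt(r0^2 - 2 * lam * tc),
                 tolerance = 0.05)
  }
})

test_that("positive area weight shrinks a contour placed outside a target", {
  n <- 64
  phi <- disk_sdf(n, c(32, 32), 20)
  g1 <- matrix(1, n, n)
  p <- levelset_params(beta = 0.04, lambda = 2, nu = 1.5, dt = 2)
  areas <- numeric(50)
  for (s in 1:50) {
    phi <- evolve_step(phi, g1, p)
    areas[s] <- sum(phi < 0)
  }
  expect_true(all(diff(areas) <= 0))
  expect_lt(areas[50], pi * 400)
})

test_that("evolution locks onto a strong edge ring and collapses without edges", {
  # annulus of low g exactly on the initial ROI boundary: contour stays put
  n <- 96
  img <- matrix(60, n, n)
  disk <- disk_mask(n, c(48, 48), 24)
  img[disk > 0] <- 220
  g <- edge_indicator(img, 1)
  phi0 <- init_phi(disk, 2)
  ev <- evolve(phi0, g, levelset_params(sigma = 1))
  expect_gte(overlap_metrics(disk, ev$mask)$dice, 0.98)

  # no edges, strong shrinkage: the contour collapses
  phi1 <- init_phi(disk_mask(n, c(48, 48), 20), 2)
  ev2 <- evolve(phi1, matrix(1, n, n),
                levelset_params(nu = 3.5, max_iter = 200, dt = 2))
  expect_lt(sum(ev2$mask), sum(disk_mask(n, c(48, 48), 20)))
})

test_that("contours split naturally across two separate lesions", {
  ph <- two_lesion_flat_phantom(seed = 4)
  expect_equal(n_components(ph$truth), 2)
  enh <- enhance_image(ph$image)
  g <- edge_indicator(enh, 1.5)
  # one big disk covering both lesions; evolution must split it in two
  phi0 <- init_phi(disk_mask(128, c(64, 64), 40), 2)
  ev <- evolve(phi0, g, levelset_params())
  expect_equal(n_components(ev$mask), 2)
  expect_gte(overlap_metrics(ph$truth, ev$mask)$dice, 0.9)
})

test_that("numerical failure raises a classed error", {
  p <- levelset_params(beta = 0, lambda = 6, nu = 0, dt = 1e6,
                       dirac = "geometric")
  phi <- disk_sdf(32, c(16, 16), 8)
  g <- matrix(1, 32, 32)
  expect_error({
    for (i in 1:50) phi <- evolve_step(phi, g, p)
  }, class = "ugfc_numerical_error")
})
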