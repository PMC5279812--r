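test_that("sphere solid angle has the exact special cases", {
  expect_equal(solid_angle_sphere(1, 1), 2 * pi)               # tangent half space
  expect_equal(solid_angle_sphere(2, 1), 2 * pi * (1 - sqrt(3) / 2))
  # far field ~ pi R^2 / d^2 within 1% beyond d = 10 R
  for (d in c(10, 30, 100)) {
    expect_equal(solid_angle_sphere(d, 1), pi / d^2, tolerance = 1e-2)
  }
  expect_error(solid_angle_sphere(0.5, 1), "inside")
})

test_that("region sampling stays inside the shell sector", {
  set.seed(3)
  cr <- loop_criteria(4.6, 9.2, 2 * pi * 0.1, anchor = c(1, 2, 3),
                      axis = c(0, 1, 0))
  pts <- sample_loop_region(5000, cr)
  dr <- sweep(pts, 2, cr$anchor)
  r <- sqrt(rowSums(dr^2))
  expect_true(all(r >= 4.6 - 1e-9 & r <= 13.8 + 1e-9))
  ct <- dr[, 2] / r
  expect_true(all(ct >= 1 - 0.1 - 1e-9))
  # radial density uniform in volume: mean of r^3 is the interval midpoint
  m <- mean(r^3)
  expect_lt(abs(m - (4.6^3 + 13.8^3) / 2), 4 * sd(r^3) / sqrt(5000))
  # negative domega samples about the -axis
  crn <- loop_criteria(4.6, 9.2, -2 * pi * 0.1, axis = c(0, 1, 0))
  ptsn <- sample_loop_region(1000, crn)
  expect_true(all(ptsn[, 2] < 0))
})

test_that("static eclipse estimate has the physical limits", {
  cr <- loop_criteria(4.6, 9.2, 4 * pi)
  set.seed(5)
  near0 <- f_inf_static(c(41.45, 0, 0), 1e-6, cr, w = 0, n_points = 2e4)
  expect_equal(near0$f_inf, 1, tolerance = 1e-6)
  far <- f_inf_static(c(1e5, 0, 0), 23, cr, w = 4.6, n_points = 2e4)
  expect_equal(far$f_inf, 1, tolerance = 1e-6)
  expect_error(f_inf_static(c(10, 0, 0), 23, cr, w = 4.6), "intersects")
  # monotone: larger object, smaller F; farther object, larger F
  f1 <- f_inf_static(c(41.45, 0, 0), 10, cr, 4.6, n_points = 5e4)$f_inf
  f2 <- f_inf_static(c(41.45, 0, 0), 20, cr, 4.6, n_points = 5e4)$f_inf
  f3 <- f_inf_static(c(80, 0, 0), 10, cr, 4.6, n_points = 5e4)$f_inf
  expect_lt(f2, f1)
  expect_gt(f3, f1)
})

test_that("ray-cast eclipse reduces to the static form without a chain", {
  set.seed(11)
  cr <- loop_criteria(4.6, 9.2, 4 * pi)
  st <- f_inf_static(c(41.45, 0, 0), 23, cr, 4.6, n_points = 2e5)
  ec <- f_inf_eclipse(cr, c(41.45, 0, 0), 23, chain_joints = NULL, w = 4.6,
                      n_points = 2e4, n_dir = 60)
  expect_equal(ec$p_chain, 0)
  expect_equal(ec$p_both, 0)
  expect_lt(abs(ec$f_inf - st$f_inf), 3 * sqrt(ec$se^2 + st$se^2) + 1e-4)
})

test_that("an object fully shadowed by the chain does not reduce F", {
  # small object hidden behind a larger chain sphere: every ray that reaches
  # the object passes through the chain, so the correction term cancels
  set.seed(13)
  cr <- loop_criteria(0.2, 0.3, 4 * pi)
  ec <- f_inf_eclipse(cr, c(100, 0, 0), 2, chain_joints = rbind(c(40, 0, 0)),
                      w = 24, n_points = 5e3, n_dir = 40)
  expect_gt(ec$p_chain, 0)
  expect_equal(ec$p_object, ec$p_both)
  expect_equal(ec$f_inf, 1)
})

test_that("the intersection term is nearly size-independent", {
  # occluding chain run between the looping region and the object: the
  # chain's narrow cone is contained in the object's cone, so doubling R_o
  # inflates the object term roughly as (R_o + w/2)^2 while the
  # chain-object overlap barely moves
  set.seed(17)
  cr <- loop_criteria(4.6, 9.2, 4 * pi)
  joints <- cbind(0, 0, seq(30, 50, by = 4.6))
  e1 <- f_inf_eclipse(cr, c(0, 0, 60), 20, joints, w = 4.6,
                      n_points = 3e4, n_dir = 60)
  e2 <- f_inf_eclipse(cr, c(0, 0, 60), 40, joints, w = 4.6,
                      n_points = 3e4, n_dir = 60)
  expect_lt(abs(e2$p_both - e1$p_both) / e1$p_both, 0.15)
  ratio_pred <- ((40 + 2.3) / (20 + 2.3))^2
  expect_equal(e2$p_object / e1$p_object, ratio_pred, tolerance = 0.4)
})

test_that("terminating-segments correction collapses to the rod model", {
  cr <- loop_criteria(4.6, 9.2, 4 * pi)
  set.seed(19)
  # a single link is a rod: the correction is exactly one
  one <- terminating_segments_correction(p_dna$l2, cr, c(41.45, 0, 0), 23,
                                         p_dna, n_pairs = 2e4)
  expect_equal(one$correction, 1)
  expect_equal(one$f_inf, one$rod$f_inf)
  # with no object in range both survival fractions are one
  off <- terminating_segments_correction(20, cr, c(1e4, 0, 0), 23, p_dna,
                                         n_pairs = 5e3)
  expect_equal(off$correction, 1)
  # flexibility can only lower the estimate
  expect_warning(
    ts <- terminating_segments_correction(64.45, cr, c(41.45, 0, 0), 23,
                                          p_dna, n_pairs = 5e4),
    "rod-like")
  expect_lte(ts$f_inf, ts$rod$f_inf)
})

test_that("quadratic eclipse fit recovers exact coefficients", {
  w <- 4.6
  radii <- c(5, 9.2, 13.8, 18.4, 23)
  A <- 1e-4; B <- 0.01
  f <- 1 - A * (radii + w / 2)^2 + B
  fit <- fit_quadratic_eclipse(radii, f, w = w)
  expect_equal(fit$A, A, tolerance = 1e-10)
  expect_equal(fit$B, B, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  # two points: exact interpolation
  fit2 <- fit_quadratic_eclipse(radii[c(1, 5)], f[c(1, 5)], w = w)
  expect_equal(fit2$fitted, f[c(1, 5)], tolerance = 1e-10)
  expect_error(fit_quadratic_eclipse(c(5, 5, 5), c(1, 1, 1)), "singular")
  # weighted fit uses the stated errors
  set.seed(23)
  fn <- f + rnorm(5, 0, 0.002)
  fitw <- fit_quadratic_eclipse(radii, fn, errors = rep(0.002, 5), w = w)
  expect_equal(fitw$A, A, tolerance = 0.3)
  expect_gt(fitw$r_squared, 0.95)
})
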