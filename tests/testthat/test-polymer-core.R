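test_that("bending energy is a(1 - cos theta) and ignores azimuth", {
  expect_equal(bending_energy(0, 5), 0)
  expect_equal(bending_energy(pi, 5), 10)
  expect_equal(bending_energy(pi / 2, 2), 2)
  expect_equal(bending_energy(c(0, pi), 3), c(0, 6))
})

test_that("bending constant inverts the Kuhn-length relation", {
  # freely jointed limit
  expect_equal(bending_constant_from_kuhn(1, 1), 0)
  expect_equal(bending_constant_from_kuhn(4.6, 4.6), 0)
  # stiff limit: a ~ (b/l + 1)/2
  a <- bending_constant_from_kuhn(1000, 1)
  expect_equal(a, (1000 + 1) / 2, tolerance = 1e-3)
  # dsDNA values: residual of the defining relation below 1e-10
  a <- bending_constant_from_kuhn(106, 4.6)
  expect_lt(abs(kuhn_ratio_from_a(a) - 106 / 4.6), 1e-10)
  # independent bisection oracle
  bisect <- function(r) {
    lo <- 1e-9; hi <- r + 2
    for (i in 1:200) {
      mid <- (lo + hi) / 2
      if (kuhn_ratio_from_a(mid) < r) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }
  expect_equal(a, bisect(106 / 4.6), tolerance = 1e-8)
  # no solution below the freely jointed line
  expect_error(bending_constant_from_kuhn(0.9, 1), "b/l")
})

test_that("round trip a <-> b/l is the identity over a wide range", {
  for (r in c(1.01, 1.5, 3, 10, 100, 1000)) {
    a <- bending_constant_from_kuhn(r, 1)
    expect_equal(kuhn_ratio_from_a(a), r, tolerance = 1e-8)
  }
})

test_that("bend sampling follows the elastic Boltzmann density", {
  # inverse-CDF endpoint: u = 1 gives theta = 0
  s <- sample_bend(3, u = cbind(1, 0.5))
  expect_equal(s$theta, 0)
  set.seed(4)
  n <- 2e5
  s0 <- sample_bend(0, n)
  expect_lt(abs(mean(cos(s0$theta))), 3 / sqrt(3 * n))  # sd = 1/sqrt(3)
  s5 <- sample_bend(5, n)
  m <- mean(cos(s5$theta))
  se <- sd(cos(s5$theta)) / sqrt(n)
  expect_lt(abs(m - mean_bend_cosine(5)), 3 * se)
  # Langevin reference against numerical quadrature
  f <- function(th) cos(th) * exp(-5 * (1 - cos(th))) * sin(th)
  g <- function(th) exp(-5 * (1 - cos(th))) * sin(th)
  ref <- integrate(f, 0, pi)$value / integrate(g, 0, pi)$value
  expect_equal(mean_bend_cosine(5), ref, tolerance = 1e-8)
})

test_that("frame propagation respects the zenith convention and transport", {
  id <- list(u = c(1, 0, 0), v = c(0, 1, 0), t = c(0, 0, 1))
  f <- propagate_frame(id, 0, 1.234)
  expect_equal(f$t, id$t)
  expect_equal(f$u, id$u)
  f <- propagate_frame(id, pi / 2, 0)
  expect_equal(f$t, c(1, 0, 0), tolerance = 1e-12)
  # orthonormality preserved over many random steps
  set.seed(1)
  fr <- id
  for (i in 1:2000) fr <- propagate_frame(fr, runif(1, 0, 0.5), runif(1, 0, 2 * pi))
  expect_lt(abs(sum(fr$t^2) - 1), 1e-10)
  expect_lt(abs(sum(fr$u^2) - 1), 1e-10)
  expect_lt(abs(sum(fr$u * fr$t)), 1e-10)
  # straight continuation transports u unchanged
  fr2 <- fr
  for (i in 1:5000) fr2 <- propagate_frame(fr2, 0, runif(1, 0, 2 * pi))
  expect_equal(fr2$u, fr$u, tolerance = 1e-10)
})

test_that("protrusion centre follows the phased offset construction", {
  w <- 4.6; Ro <- 9.2
  r <- c(1, 2, 3); u <- c(1, 0, 0); t <- c(0, 0, 1)
  expect_equal(protrusion_center(r, u, t, 0, w, Ro), r + (w / 2 + Ro) * u)
  expect_equal(protrusion_center(r, u, t, pi, w, Ro), r - (w / 2 + Ro) * u,
               tolerance = 1e-12)
  # gamma = pi/2: right-handed rotation about t maps u to t x u
  expect_equal(protrusion_center(r, u, t, pi / 2, w, Ro),
               r + (w / 2 + Ro) * c(0, 1, 0), tolerance = 1e-12)
  # generic frame: compare against an explicit rotation-matrix evaluation
  set.seed(2)
  th <- runit(); uu <- runit(); uu <- uu - sum(uu * th) * th
  uu <- uu / sqrt(sum(uu^2))
  g <- 0.77
  K <- matrix(c(0, -th[3], th[2], th[3], 0, -th[1], -th[2], th[1], 0), 3, 3,
              byrow = TRUE)
  Rm <- diag(3) + sin(g) * K + (1 - cos(g)) * K %*% K
  expect_equal(protrusion_center(r, uu, th, g, w, Ro),
               r + (w / 2 + Ro) * drop(Rm %*% uu), tolerance = 1e-12)
})

test_that("hard-wall overlap honours the exclusion window and tangency", {
  w <- 4.6
  # straight chain with l = w: touching neighbours never overlap
  joints <- cbind(0, 0, seq(0, 10 * w, by = w))
  for (i in 1:10) expect_false(hard_wall_overlap(joints, i, 1, w))
  # a close pair with compatible indices overlaps
  joints2 <- rbind(c(0, 0, 0), c(0, 0, w), c(0.99 * w, 0, w), c(0.99 * w, 0, 0.01))
  expect_true(hard_wall_overlap(joints2, 3, 1, w))
  # but the exclusion window can hide it
  expect_false(hard_wall_overlap(joints2, 3, 4, w))
  # protrusion tangency is allowed, interpenetration is not
  pr <- list(center = c(w / 2 + 9.2, 0, 0), radius = 9.2, link = 0)
  expect_false(hard_wall_overlap(rbind(c(9, 9, 9), c(0, 0, 0)), 1, 99, w, list(pr)))
  pr2 <- list(center = c(w / 2 + 9.2 - 0.01, 0, 0), radius = 9.2, link = 0)
  expect_true(hard_wall_overlap(rbind(c(9, 9, 9), c(0, 0, 0)), 1, 99, w, list(pr2)))
})

test_that("phantom chain closed form matches a direct correlation sum", {
  expect_equal(phantom_chain_r2(1, 2.5, 7), 2.5^2)
  expect_equal(phantom_chain_r2(100, 1, 0), 100)
  # <R^2> = N l^2 + 2 l^2 sum_{i<j} c^(j-i), c = <cos theta>
  direct <- function(N, l, a) {
    c <- mean_bend_cosine(a)
    s <- 0
    for (i in 1:(N - 1)) s <- s + sum(c^(seq_len(N - i)))
    N * l^2 + 2 * l^2 * s
  }
  expect_equal(phantom_chain_r2(50, 1.3, 2), direct(50, 1.3, 2), tolerance = 1e-12)
  expect_equal(phantom_chain_r2(200, 4.6, 12), direct(200, 4.6, 12), tolerance = 1e-12)
})
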