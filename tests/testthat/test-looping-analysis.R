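test_that("the looping test combines a radial shell with an angular cap", {
  cr <- loop_criteria(d_min = 4.6, epsilon = 9.2, domega = 2 * pi * 0.1)
  mid <- 4.6 + 9.2 / 2
  expect_true(is_looped(mid * c(1, 0, 0), cr))
  expect_false(is_looped(0.9 * 4.6 * c(1, 0, 0), cr))       # below d_min
  expect_false(is_looped(1.01 * (4.6 + 9.2) * c(1, 0, 0), cr))  # beyond shell
  expect_false(is_looped(mid * c(0, 1, 0), cr))             # outside the cap
  # negative domega flips the cap to the -axis side
  crn <- loop_criteria(4.6, 9.2, -2 * pi * 0.1)
  expect_true(is_looped(-mid * c(1, 0, 0), crn))
  expect_false(is_looped(mid * c(1, 0, 0), crn))
  # 4*pi accepts every direction in the shell
  cra <- loop_criteria(4.6, 9.2, 4 * pi)
  expect_true(is_looped(mid * c(0, 0, -1), cra))
})

test_that("cap acceptance fraction matches |domega| / 4pi", {
  set.seed(7)
  mid <- 9
  for (dom in c(2 * pi * 0.1, 2 * pi, -pi)) {
    cr <- loop_criteria(4.6, 9.2, dom)
    dirs <- uniform_directions(2e5)
    acc <- mean(vapply(seq_len(nrow(dirs)), function(i)
      is_looped(mid * dirs[i, ], cr), logical(1)))
    ref <- abs(dom) / (4 * pi)
    expect_lt(abs(acc - ref), 3 * sqrt(ref * (1 - ref) / 2e5))
  }
})

test_that("looping probability has the trivial limits", {
  sch <- growth_schedule(seg2(30), params = p_dna)
  # an empty shell accepts nothing
  none <- list(loop_criteria(d_min = 500, epsilon = 1, domega = 4 * pi))
  all_of_it <- list(loop_criteria(d_min = 0, epsilon = 500, domega = 4 * pi))
  ens <- generate_ensemble(sch, p_dna, 2000, seed = 5,
                           criteria = c(none, all_of_it), groups = list(1L, 2L))
  expect_true(all(looping_probability(ens, group = 1)$p == 0))
  expect_true(all(looping_probability(ens, group = 2)$p == 1))
})

test_that("F of identical ensembles is exactly one with no error", {
  sch <- growth_schedule(seg2(30), params = p_dna)
  crit <- list(loop_criteria(0, 40, 4 * pi))
  ens <- generate_ensemble(sch, p_dna, 3000, seed = 13, criteria = crit,
                           ensembles = list(integer(0), integer(0)))
  pc <- paired_f_curve(ens, 2)
  expect_true(all(pc$f == 1))
  expect_true(all(pc$se < 1e-6))   # zero up to rounding in the cell algebra
  # same through the independent-ratio route
  cv <- looping_probability(ens, 1)
  expect_true(all(f_ratio(cv, cv)$f == 1))
  # grid mismatch is an error
  sch2 <- growth_schedule(seg2(20), params = p_dna)
  ens2 <- generate_ensemble(sch2, p_dna, 1000, seed = 13, criteria = crit)
  expect_error(f_ratio(looping_probability(ens2), cv), "grids")
})

test_that("plateau estimation averages a trailing window", {
  cons <- data.frame(length_nm = seq(10, 1000, by = 10), f = 0.7)
  est <- estimate_f_infinity(cons, window = 20)
  expect_equal(est$f_inf, 0.7)
  expect_equal(est$halfwidth, 0)
  one <- estimate_f_infinity(cons, window = 1)
  expect_equal(one$f_inf, 0.7)
  expect_true(is.nan(one$halfwidth))
  expect_error(estimate_f_infinity(cons, window = 1000), "window")
  # synthetic curve with known plateau: mean over the window is analytic
  set.seed(9)
  L <- seq(46, 46 * 250, by = 46)
  b <- 106
  noise <- rnorm(length(L), 0, 0.004)
  curve <- data.frame(length_nm = L, f = 1 - 0.3 * exp(-L / b) + noise)
  idx <- L > 8 * b
  est <- estimate_f_infinity(curve, window = sum(idx), b = b)
  ref <- mean(1 - 0.3 * exp(-L[idx] / b))
  expect_lt(abs(est$f_inf - ref), 3 * 0.004 / sqrt(sum(idx)))
  expect_equal(ref, 1, tolerance = 1e-3)   # effectively flat out there
})

test_that("window statistics agree with the per-length paired estimator", {
  prot <- list(protrusion("on_chain", link = 40, radius = 11.9, enforce = FALSE))
  sch <- growth_schedule(two_stage(50, 30), prot, params = p_dna)
  crit <- list(loop_criteria(0, 60, 4 * pi))
  g <- 25L
  win <- list(list(list(ensemble = 2, group = 1, lo = g, hi = g),
                   list(ensemble = 1, group = 1, lo = g, hi = g)))
  ens <- generate_ensemble(sch, p_dna, 30000, seed = 19, criteria = crit,
                           ensembles = list(integer(0), 1L), windows = win)
  wf <- window_f(ens, 1, 1, 2)
  pc <- paired_f_curve(ens, 2)
  expect_equal(wf$value, pc$f[g], tolerance = 1e-12)
  expect_equal(wf$se, pc$se[g], tolerance = 0.2)   # two delta-method routes
  wp <- window_prob(ens, 1, 2)
  expect_equal(wp$value, ens$W[g, 1, 1] / ens$Z[1, g], tolerance = 1e-12)
})

test_that("multi-activator looping sums per-activator probabilities", {
  acts <- list(
    protrusion("on_chain", link = 30, radius = 3.04, enforce = FALSE),
    protrusion("on_chain", link = 60, radius = 3.75, enforce = FALSE),
    protrusion("on_chain", link = 90, radius = 3.04, enforce = FALSE))
  sch <- growth_schedule(two_stage(100, 40), acts, params = p_dna)
  crits <- lapply(1:3, function(i)
    loop_criteria(d_min = p_dna$w / 2 + acts[[i]]$radius, epsilon = 3,
                  domega = 2 * pi, type = "activator", activator = i))
  ens <- generate_ensemble(sch, p_dna, 60000, seed = 23, criteria = crits,
                           groups = list(1L, 2L, 3L, 1:3),
                           ensembles = list(integer(0)))
  # group value is the exact sum of the member indicators
  Wsum <- ens$W[, 1, 1] + ens$W[, 2, 1] + ens$W[, 3, 1]
  expect_equal(ens$W[, 4, 1], Wsum)
  pe <- eve_looping_probability(ens, group = 4)
  expect_true(all(pe$dup_fraction >= 0 & pe$dup_fraction <= 1, na.rm = TRUE))
  # one activator reduces to the plain looping probability
  p1 <- looping_probability(ens, group = 1)
  expect_equal(eve_looping_probability(ens, group = 1)$p, p1$p)
})
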