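test_that("phantom ensembles carry unit weights and full partition sums", {
  sch <- growth_schedule(seg2(40), params = p_dna)
  ens <- generate_ensemble(sch, p_dna, 500, seed = 3, self_avoid = FALSE)
  expect_equal(ens$n_discarded, 0)
  expect_true(all(ens$Z[1, ] == 500))
  expect_error(generate_ensemble(sch, p_dna, 0, seed = 1), "at least 1")
})

test_that("ensembles are deterministic and merge additively", {
  sch <- growth_schedule(two_stage(30, 30), params = p_dna)
  e1 <- generate_ensemble(sch, p_dna, 3000, seed = 17)
  e2 <- generate_ensemble(sch, p_dna, 3000, seed = 17)
  expect_identical(e1$Z, e2$Z)
  expect_identical(e1$W, e2$W)
  ea <- generate_ensemble(sch, p_dna, 1000, seed = 17, chain_offset = 0)
  eb <- generate_ensemble(sch, p_dna, 2000, seed = 17, chain_offset = 1000)
  em <- merge_ensembles(ea, eb)
  expect_identical(em$Z, e1$Z)
  expect_identical(em$W, e1$W)
  expect_equal(em$n_generated, 3000)
  # a different seed changes the stream
  e3 <- generate_ensemble(sch, p_dna, 3000, seed = 18)
  expect_false(identical(e3$Z, e1$Z))
})

test_that("a virtual condition selects exactly the enforced-run subset", {
  prot_v <- list(protrusion("on_chain", link = 60, radius = 11.9, enforce = FALSE))
  prot_e <- list(protrusion("on_chain", link = 60, radius = 11.9, enforce = TRUE))
  sv <- growth_schedule(two_stage(70, 40), prot_v, params = p_dna)
  se <- growth_schedule(two_stage(70, 40), prot_e, params = p_dna)
  ev <- generate_ensemble(sv, p_dna, 20000, seed = 8,
                          ensembles = list(integer(0), 1L))
  ee <- generate_ensemble(se, p_dna, 20000, seed = 8)
  expect_identical(ev$Z[2, ], ee$Z[1, ])
  expect_identical(ev$W[, 1, 2], ee$W[, 1, 1])
  expect_true(all(ev$Z[2, ] <= ev$Z[1, ]))
})

test_that("single-chain growth exposes a valid configuration", {
  prot <- list(protrusion("on_chain", link = 20, radius = 5, phase = pi / 3))
  sch <- growth_schedule(two_stage(30, 20), prot, params = p_dna)
  ch <- grow_chain(sch, p_dna, seed = 12, index = 4)
  if (!ch$discarded) {
    expect_equal(nrow(ch$joints), 51)
    expect_equal(ch$rosenbluth_weight, 1)
    # link lengths match the schedule
    d <- sqrt(rowSums(diff(ch$joints)^2))
    expect_equal(d, c(rep(p_dna$l1, 30), rep(p_dna$l2, 20)), tolerance = 1e-9)
    # frames are unit length and orthogonal to the link directions
    expect_true(all(abs(rowSums(ch$t_fwd^2) - 1) < 1e-10))
    expect_true(all(abs(rowSums(ch$u_fwd * ch$t_fwd)) < 1e-10))
    # the protrusion centre reproduces the phased-offset construction
    cen <- ch$prot_centers[[1]]
    expect_equal(sqrt(sum((cen - ch$joints[21, ])^2)), p_dna$w / 2 + 5,
                 tolerance = 1e-9)
  }
  # different indices give different chains
  ch2 <- grow_chain(sch, p_dna, seed = 12, index = 5)
  expect_false(isTRUE(all.equal(ch$joints[10, ], ch2$joints[10, ])))
})

test_that("frame orthonormality survives very long chains", {
  sch <- growth_schedule(seg2(1e5), params = p_dna,
                         record_joints = 1e5L)
  ch <- grow_chain(sch, p_dna, seed = 2, index = 1, self_avoid = FALSE)
  expect_false(ch$discarded)
  err_t <- max(abs(rowSums(ch$t_fwd^2) - 1))
  err_o <- max(abs(rowSums(ch$u_fwd * ch$t_fwd)))
  expect_lt(err_t, 1e-10)
  expect_lt(err_o, 1e-10)
})

test_that("backward segments grow in the -t1 direction from joint 0", {
  bwd <- data.frame(n_links = 25, link_length = p_dna$l2, delta_i = 1L)
  sch <- growth_schedule(seg2(20), backward_segments = bwd, params = p_dna)
  ch <- grow_chain(sch, p_dna, seed = 6, index = 1, self_avoid = FALSE)
  expect_equal(ch$n_backward, 25)
  expect_true(all(ch$contour[2:26] < 0))       # backward joints first
  # first backward link heads into the lower half space
  expect_lt(ch$joints[2, 3], 0)
  # contour coordinates step by the link length
  expect_equal(ch$contour[2], -p_dna$l2)
})

test_that("prefix statistics equal an independent shorter ensemble", {
  crit <- list(loop_criteria(0, 40, 4 * pi))
  long <- growth_schedule(seg2(60), params = p_dna)
  short <- growth_schedule(seg2(30), params = p_dna)
  el <- generate_ensemble(long, p_dna, 40000, seed = 21, criteria = crit)
  es <- generate_ensemble(short, p_dna, 40000, seed = 99, criteria = crit)
  g <- 30
  pl <- el$W[g, 1, 1] / el$Z[1, g]
  ps <- es$W[30, 1, 1] / es$Z[1, 30]
  se <- sqrt(pl * (1 - pl) / el$Z[1, g] + ps * (1 - ps) / es$Z[1, 30])
  expect_lt(abs(pl - ps), 3 * se)
  # recorded-length grid: lengths increase and the chain survives to L_max
  expect_true(all(diff(el$lengths_nm) > 0))
})

test_that("whole ensembles are rejected when nothing can survive", {
  # protrusion sphere larger than the confining sphere: no chain fits
  prot <- list(protrusion("on_chain", link = 5, radius = 50))
  sch <- growth_schedule(seg2(20), prot, confinement_radius = 30,
                         params = p_dna)
  expect_error(generate_ensemble(sch, p_dna, 200, seed = 1), "discarded")
})

test_that("confinement keeps whole joint spheres inside", {
  expect_true(confinement_check(c(0, 0, 0), radius = 10, w = 4.6))
  expect_false(confinement_check(c(10, 0, 0), radius = 10, w = 4.6))
  expect_false(confinement_check(c(8.5, 0, 0), radius = 10, w = 4.6))
  expect_true(confinement_check(c(7, 0, 0), radius = 10, w = 4.6))
  # enforced confinement trims the ensemble
  sch_f <- growth_schedule(seg2(40), params = p_dna)
  sch_c <- growth_schedule(seg2(40), confinement_radius = 40, params = p_dna)
  ef <- generate_ensemble(sch_f, p_dna, 5000, seed = 31)
  ec <- generate_ensemble(sch_c, p_dna, 5000, seed = 31)
  expect_lt(ec$Z[1, 40], ef$Z[1, 40])
})

test_that("ensemble averages are weighted and fail on empty ensembles", {
  chains <- lapply(1:40, function(i) {
    sch <- growth_schedule(seg2(10), params = p_dna)
    grow_chain(sch, p_dna, seed = i, index = 1)
  })
  expect_equal(ensemble_average(chains, function(ch) 1), 1)
  r2 <- ensemble_average(chains, function(ch)
    sum((ch$joints[nrow(ch$joints), ] - ch$joints[1, ])^2))
  expect_gt(r2, 0)
  dead <- list(list(rosenbluth_weight = 0))
  expect_error(ensemble_average(dead, function(ch) 1), "Z = 0")
})

test_that("trailing links act as a loop-inside-a-chain requirement", {
  # with trailing links, a chain must survive past L to count at L
  prot <- list(protrusion("on_chain", link = 60, radius = 11.9, enforce = FALSE))
  s0 <- growth_schedule(two_stage(70, 44), prot, trailing_links = 4,
                        params = p_dna)
  expect_equal(length(s0$record_joints), 40)
  e0 <- generate_ensemble(s0, p_dna, 5000, seed = 41,
                          ensembles = list(integer(0), 1L))
  # Z at the last recorded length counts chains alive 4 links further on
  expect_true(all(e0$Z[1, ] <= 5000))
  expect_equal(max(e0$lengths_nm), 70 * p_dna$l1 + 40 * p_dna$l2)
})

test_that("a few trailing links saturate the flank effect on F", {
  # a trailing flank beyond the recorded loop suppresses F slightly; four
  # extra links already carry the entire effect, so longer flanks add
  # nothing (overlapping 95% intervals)
  prot <- list(protrusion("on_chain", link = 60, radius = 11.9,
                          phase = 0, enforce = FALSE))
  crit <- list(loop_criteria(p_dna$d_min, p_dna$epsilon, 2 * pi))
  f_with_trail <- function(trail, n) {
    segs <- two_stage(70, 60 + trail)
    sch <- growth_schedule(segs, prot, trailing_links = trail,
                           params = p_dna)
    ng <- length(sch$record_joints)
    win <- list(list(list(ensemble = 2, group = 1, lo = ng - 25, hi = ng),
                     list(ensemble = 1, group = 1, lo = ng - 25, hi = ng)))
    ens <- generate_ensemble(sch, p_dna, n, seed = 77, criteria = crit,
                             ensembles = list(integer(0), 1L), windows = win)
    window_f(ens, 1, 1, 2)
  }
  f4 <- f_with_trail(4L, 7e5)
  f30 <- f_with_trail(30L, 7e5)
  expect_lt(abs(f4$value - f30$value),
            1.96 * f4$se + 1.96 * f30$se)
})
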