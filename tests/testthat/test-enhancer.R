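test_that("the built-in protein table matches the documented radii", {
  tab <- builtin_protein_radii()
  expect_equal(tab[["Knirps"]], 2.38)
  expect_equal(tab[["full_complex"]], 5.83)
  expect_equal(protein_radius("Zld"), 3.75)
  expect_error(protein_radius("Bicoid"), "unknown protein")
})

test_that("mass-to-radius scaling reproduces the table to within 8%", {
  masses <- c(86, 146, 46, 130, 450)
  radii <- c(3.04, 3.75, 2.38, 3.59, 5.83)
  pred <- vapply(masses, mass_to_radius, numeric(1))
  expect_true(all(abs(pred - radii) / radii < 0.08))
  expect_gt(mass_to_radius(900), mass_to_radius(450))
})

test_that("helical phase follows native twist with 10.5 bp periodicity", {
  expect_equal(phase_from_position(0), 0)
  expect_equal(phase_from_position(21), 0, tolerance = 1e-12)  # two full turns
  g1 <- phase_from_position(17)
  g2 <- phase_from_position(17 + 2 * 10.5)
  expect_equal(g1, g2, tolerance = 1e-12)
  # fractional positions round to the nearest addressable link
  expect_equal(phase_from_position(5.25), phase_from_position(5))
  expect_equal(phase_from_position(5.75), phase_from_position(6))
})

test_that("layouts translate to schedules and round trip in bp", {
  sites <- data.frame(position_bp = c(120, 300),
                      name = c("dStat", "Zld"),
                      role = c("activator", "activator"),
                      occupied = c(TRUE, TRUE))
  lay <- enhancer_layout(sites, chain_length_bp = 1200)
  ls <- layout_to_schedule(lay, p_dna, state = "fully_bound")
  expect_length(ls$schedule$protrusions, 2)
  expect_equal(schedule_site_positions(ls$schedule, p_dna), c(120, 300))
  expect_equal(ls$activators, c(1L, 2L))
  expect_length(ls$criteria, 2)
  expect_equal(ls$criteria[[1]]$d_min, p_dna$w / 2 + 3.04)
  # bare state: no enforced hard walls
  lb <- layout_to_schedule(lay, p_dna, state = "bare")
  enforced <- vapply(lb$schedule$protrusions, function(p) p$enforce, logical(1))
  expect_false(any(enforced))
  # radius sweep: schedules differ only in the repressor radius
  sites2 <- rbind(sites,
                  data.frame(position_bp = 500, name = "Knirps",
                             role = "repressor", occupied = TRUE))
  for (r in c(2.38, 3.59, 5.83)) {
    s2 <- sites2
    s2$radius_nm <- c(3.04, 3.75, r)
    l2 <- layout_to_schedule(enhancer_layout(s2, 1200), p_dna)
    expect_equal(l2$schedule$protrusions[[3]]$radius, r)
  }
})

test_that("infeasible straight-chain placements are rejected", {
  sites <- data.frame(position_bp = c(100, 102),
                      name = c("full_complex", "full_complex"),
                      role = c("repressor", "repressor"),
                      occupied = c(TRUE, TRUE))
  lay <- enhancer_layout(sites, chain_length_bp = 1000)
  expect_error(layout_to_schedule(lay, p_dna, state = "fully_bound"),
               "infeasible")
  # unoccupied sites cannot collide
  sites$occupied <- c(TRUE, FALSE)
  lay2 <- enhancer_layout(sites, chain_length_bp = 1000)
  expect_silent(layout_to_schedule(lay2, p_dna, state = "fully_bound"))
})

test_that("BED-like intervals map midpoints to 1-based bp positions", {
  bed <- data.frame(start = c(10, 100), end = c(20, 121),
                    name = c("dStat", "Zld"))
  s <- sites_from_bed(bed)
  expect_equal(s$position_bp, c(16, 112))   # (10+20)/2 -> 15 (0-based) -> 16
  expect_true(all(s$occupied))
  expect_error(sites_from_bed(data.frame(start = 5, end = 5, name = "x")))
})

test_that("the shipped synthetic layout loads and is feasible", {
  path <- system.file("extdata", "eve37_synthetic_layout.tsv",
                      package = "loopsis")
  expect_true(nzchar(path))
  lay <- read_enhancer_layout(path, chain_length_bp = 3900)
  expect_equal(nrow(lay$sites), 5)
  expect_equal(sum(lay$sites$role == "activator"), 3)
  expect_equal(sum(lay$sites$role == "repressor"), 2)
  ls <- layout_to_schedule(lay, p_dna, state = "fully_bound", enforce = FALSE)
  expect_length(ls$activators, 3)
  expect_equal(schedule_site_positions(ls$schedule, p_dna),
               lay$sites$position_bp)
  # chain length matches 3900 bp
  tot <- sum(ls$schedule$segments$n_links * ls$schedule$segments$link_length)
  expect_equal(tot, 3900 * p_dna$bp_nm, tolerance = p_dna$l2)
})
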