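test_that("noise-free septal schedule is exact: plateau at angle_mid, crowded tail", {
  p <- shell_params(angle_mid = 25, crowding_chambers = 2L, angle_noise_sd = 0)
  a <- septal_schedule(p, seed = 1L)
  expect_length(a, p$n_chambers - 1L)
  h <- p$hatching_chamber
  mid <- a[h:(length(a) - 2L)]
  expect_true(all(mid == 25))
  tl <- a[(length(a) - 1L):length(a)]
  expect_lt(tl[2L], tl[1L])
  # monotone rise to the peak at series position h - 2 (chamber h - 1)
  expect_true(all(diff(a[1:(h - 2L)]) >= 0))
  expect_equal(which.max(a[1:10]), h - 2L)
  # drop of at least 20 percent right after the peak
  expect_lte(a[h - 1L], 0.8 * max(a[1:(h - 2L)]))
})

test_that("schedule contract holds across many random seeds", {
  p <- shell_params()
  h <- p$hatching_chamber; m <- p$n_chambers - 1L; cc <- p$crowding_chambers
  for (seed in 1:1000) {
    a <- septal_schedule(p, seed = seed)
    expect_length(a, m)
    expect_true(all(a > 0))
    expect_true(all(diff(a[1:(h - 2L)]) >= 0))          # monotone rise
    expect_true(which.max(a[1:10]) %in% c(h - 2L, h - 1L))
    expect_lte(a[h - 1L], 0.8 * max(a[1:(h - 2L)]))      # hatching drop
    expect_true(all(diff(a[(m - cc + 1L):m]) < 0))       # crowding tail
    mid <- a[(h - 1L):(m - cc)]
    expect_lt(abs(mean(mid) - p$angle_mid), 3)           # stationary band
  }
})

test_that("schedules are deterministic given a seed and reject bad parameters", {
  p <- shell_params()
  expect_identical(septal_schedule(p, seed = 42L), septal_schedule(p, seed = 42L))
  expect_error(shell_params(hatching_chamber = 30L, n_chambers = 27L),
               "n_chambers")
  expect_error(shell_params(angle_mid = 33, angle_band = c(20, 35)), "0.8")
  expect_error(shell_params(whorl_expansion_rate = 0.9), "whorl_expansion_rate")
  expect_error(shell_params(umbilical_ratio = 1.2), "umbilical_ratio")
})

test_that("zero-variance conspecific specimens are identical up to their id", {
  sp <- zero_noise_spec()
  r1 <- generate_shell(sp, "a", seed = 3L, n_points = 128L)
  r2 <- generate_shell(sp, "b", seed = 99L, n_points = 128L)
  expect_identical(r1$septal_angles, r2$septal_angles)
  expect_equal(r1$suture_curves[[5L]]$points, r2$suture_curves[[5L]]$points)
  expect_equal(r1$section_outlines[[3L]]$points, r2$section_outlines[[3L]]$points)
  # downstream zero-noise collapse: Procrustes distance 0 at equal index
  c1 <- resample_equidistant(r1$suture_curves[[8L]], 20L)
  c2 <- resample_equidistant(r2$suture_curves[[8L]], 20L)
  expect_lt(procrustes_distance(c1, c2), 1e-8)
})

test_that("diameters increase strictly and follow the expansion rate", {
  r <- generate_shell(default_species_specs()[[2L]], "x", seed = 8L,
                      n_points = 96L)
  expect_true(all(diff(r$diameters_at_chamber) > 0))
  expect_true(all(diff(r$diameters_at_section) > 0))
  expect_equal(r$max_diameter,
               unname(r$diameters_at_section[length(r$diameters_at_section)]))

  # sections sit every 45 degrees: 8 sections apart = one whorl = factor W
  sp <- zero_noise_spec(whorl_expansion_rate = 2.0)
  r2 <- generate_shell(sp, "w", seed = 1L, n_points = 96L)
  d <- unname(r2$diameters_at_section)
  expect_equal(d[9L] / d[1L], 2.0, tolerance = 1e-9)
})

test_that("dataset generation is deterministic and validates its design", {
  specs <- default_species_specs()
  d1 <- generate_dataset(specs, n_per_species = 2L, seed = 5L, n_points = 64L)
  expect_length(d1$specimens, 18L)
  d2 <- generate_dataset(specs, n_per_species = 2L, seed = 5L, n_points = 64L)
  expect_identical(d1$specimens[[7L]]$septal_angles,
                   d2$specimens[[7L]]$septal_angles)
  expect_equal(d1$specimens[[18L]]$suture_curves[[4L]]$points,
               d2$specimens[[18L]]$suture_curves[[4L]]$points)
  expect_error(generate_dataset(specs, n_per_species = 0L), "n_per_species")
  expect_error(generate_dataset(specs[c(1L, 1L)], seed = 1L), "duplicate")
})

test_that("self-intersecting outlines raise an error naming the parameter", {
  sp <- zero_noise_spec(section_shape_coeffs = c(0.9, 0, 0))
  expect_error(generate_shell(sp, "bad", seed = 1L, n_points = 96L),
               "section_shape_coeffs")
})

test_that("hatching diameter separates pre- and post-hatching chambers", {
  r <- generate_shell(default_species_specs()[[1L]], "x", seed = 2L,
                      n_points = 64L)
  h <- r$hatching_chamber
  d <- unname(r$diameters_at_chamber)  # chambers 2..n
  expect_lt(d[h - 1L], r$hatching_diameter)   # chamber h
  expect_gt(d[h], r$hatching_diameter)        # chamber h + 1
})
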