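test_that("septal angles are differences of rotational positions", {
  expect_equal(septal_angles(c(0, 25, 50)), c(25, 25))
  expect_equal(septal_angles(seq(0, 300, by = 30)), rep(30, 10L))
  expect_error(septal_angles(c(0, 30, 20)), "increasing")

  # generator contract: record angles equal the noise-free schedule exactly
  sp <- zero_noise_spec()
  r <- generate_shell(sp, "z", seed = 4L, n_points = 64L)
  expect_equal(septal_angles(r), septal_schedule(sp$mean_params, noise_sd = 0))
})

test_that("stage assignment follows the three-stage diameter/position rule", {
  d <- c(18, 24, 29.9, 30.0, 45, 80, 120, 150)
  st <- assign_stage(d)
  expect_equal(st$stage,
               c("pre_hatching", "pre_hatching", "pre_hatching",
                 "juvenile_submature", "juvenile_submature",
                 "juvenile_submature", "mature", "mature"))
  # boundary: exactly 30 mm mid-series is juvenile (rule is < 30 / >= 30)
  expect_equal(st$stage[d == 30], "juvenile_submature")
  # the last chamber is always mature, even below 30 mm
  st2 <- assign_stage(c(10, 15, 20, 25, 28))
  expect_equal(st2$stage[4:5], c("mature", "mature"))
  expect_error(assign_stage(c(10, 20, 30)), "fewer than 4")
  # partition property: every chamber gets exactly one stage
  expect_equal(sum(table(st$stage)), length(d))
})

test_that("stage-point selection picks the two nearest diameters", {
  expect_equal(select_stage_points(c(18.2, 19.5, 21.0, 33.0), 20), c(2L, 3L))
  expect_equal(select_stage_points(c(18.2, 19.5, 21.0, 33.0), "max"), c(3L, 4L))
  # exact tie: both tied points chosen, smaller diameter first
  expect_equal(select_stage_points(c(19, 21, 30), 20), c(1L, 2L))
  expect_error(select_stage_points(42, 20), "at least 2")
})

test_that("one-way ANOVA reproduces hand-computed sums of squares", {
  g <- list(a = c(1, 2, 3), b = c(4, 5, 6))
  # oracle by definition: SSB = 3*(2-3.5)^2 + 3*(5-3.5)^2 = 13.5, SSW = 4,
  # F = (13.5/1) / (4/4) = 13.5 on (1, 4) df
  ssb <- 3 * (2 - 3.5)^2 + 3 * (5 - 3.5)^2
  ssw <- sum((g$a - 2)^2) + sum((g$b - 5)^2)
  fo <- (ssb / 1) / (ssw / 4)
  res <- anova_oneway(g)
  expect_equal(res$F, fo)
  expect_equal(res$F, 13.5)
  expect_equal(res$df_between, 1L)
  expect_equal(res$df_within, 4L)
  expect_equal(res$p_value, stats::pf(13.5, 1, 4, lower.tail = FALSE),
               tolerance = 1e-12)

  same <- list(a = c(1, 2, 3), b = c(1, 2, 3))
  expect_equal(anova_oneway(same)$F,
               0)  # identical group means
  expect_equal(anova_oneway(same)$p_value, 1)
  flat <- list(a = c(2, 2), b = c(2, 2, 2))
  expect_equal(anova_oneway(flat)$F, 0)
  expect_equal(anova_oneway(flat)$p_value, 1)
  expect_error(anova_oneway(list(a = 1:3)), "2 non-empty groups")
})

test_that("null ANOVA p-values are uniform (Kolmogorov-Smirnov)", {
  set.seed(61)
  p <- replicate(2000L, {
    g <- split(rnorm(27L), rep(letters[1:9], each = 3L))
    anova_oneway(g)$p_value
  })
  ks <- suppressWarnings(stats::ks.test(p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("Tukey-Kramer comparisons behave at the edge cases", {
  same <- list(a = c(1, 2, 3), b = c(1, 2, 3), c = c(1, 2, 3))
  pw <- pairwise_comparisons(same)
  expect_true(all(!pw$significant))
  expect_true(all(pw$adjusted_p > 0.999))
  # interval/significance consistency
  expect_equal(pw$significant, pw$lower > 0 | pw$upper < 0)

  # with two groups the studentized range reduces to the pooled t test
  set.seed(62)
  g2 <- list(a = rnorm(7L), b = rnorm(9L, mean = 0.8))
  pw2 <- pairwise_comparisons(g2)
  tt <- stats::t.test(g2$a, g2$b, var.equal = TRUE)
  expect_equal(pw2$adjusted_p, tt$p.value, tolerance = 1e-6)

  # separation: only the pairs involving the shifted group are significant
  g3 <- list(a = c(1, 1.1, 0.9), b = c(1, 1.05, 0.95), c = c(9, 9.1, 8.9))
  pw3 <- pairwise_comparisons(g3)
  sig <- pw3[pw3$significant, ]
  expect_equal(nrow(sig), 2L)
  expect_true(all(apply(sig[, c("group_a", "group_b")], 1L, function(r) "c" %in% r)))

  expect_warning(pairwise_comparisons(list(a = 1:3, b = 2, c = 4:6)),
                 "excluding")
})

test_that("hatching detection finds the configured drop chamber", {
  # angle series index i belongs to chamber i + 1
  a <- c(18, 22, 26, 30, 36, 24, 25, 26, 25, 24, 25, 26)
  expect_equal(hatching_chamber(a), 7L)  # 24 <= 0.8 * 36 at position 6
  expect_true(is.na(hatching_chamber(seq(10, 43, by = 3))))
  expect_error(hatching_chamber(1:5), "at least 10")

  set.seed(63)
  sp <- default_species_specs()[[4L]]
  hits <- vapply(1:50, function(i) {
    p <- conchmorph:::draw_specimen_params(sp)
    isTRUE(hatching_chamber(septal_schedule(p)) == p$hatching_chamber)
  }, NA)
  expect_gte(mean(hits), 0.95)
})

test_that("stage-stratified groups pool angles by species label", {
  ds <- generate_dataset(default_species_specs()[1:3], n_per_species = 2L,
                         seed = 9L, n_points = 64L)
  for (stg in c("pre_hatching", "juvenile_submature", "mature")) {
    g <- stage_angle_groups(ds, stg)
    expect_length(g, 3L)
  }
  g <- stage_angle_groups(ds, "mature")
  expect_true(all(lengths(g) == 4L))  # 2 specimens x last two chambers
  total <- sum(lengths(stage_angle_groups(ds, "pre_hatching"))) +
    sum(lengths(stage_angle_groups(ds, "juvenile_submature"))) +
    sum(lengths(stage_angle_groups(ds, "mature")))
  expect_equal(total, sum(vapply(ds$specimens, function(r)
    length(r$septal_angles), 0L)))
})
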