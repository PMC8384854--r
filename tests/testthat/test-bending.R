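test_that("bending-energy matrix annihilates affine terms and is PSD", {
  set.seed(31)
  for (d in 2:3) {
    for (rep in 1:5) {
      ref <- rand_landmarks(12L, d)
      m <- bending_energy_matrix(ref)
      aff <- cbind(1, ref$coords)
      expect_lt(max(abs(m$energy_matrix %*% aff)), 1e-8)
      ev <- eigen(m$energy_matrix, symmetric = TRUE, only.values = TRUE)$values
      expect_gt(min(ev), -1e-10)
    }
  }
})

test_that("bending energy is zero exactly on affine transforms of the reference", {
  set.seed(32)
  ref2 <- rand_landmarks(10L, 2L)
  m2 <- bending_energy_matrix(ref2)
  expect_equal(bending_energy(m2, ref2), 0, tolerance = 1e-10)
  th <- 30 * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2L)
  expect_lt(bending_energy(m2, 2 * ref2$coords %*% R), 1e-8)
  # general random affine maps, both dimensions
  for (d in 2:3) {
    ref <- rand_landmarks(11L, d)
    m <- bending_energy_matrix(ref)
    for (rep in 1:20) {
      A <- matrix(rnorm(d * d), d)
      b <- rnorm(d)
      tgt <- sweep(ref$coords %*% A, 2L, b, "+")
      expect_lt(bending_energy(m, tgt), 1e-8)
    }
    # and a non-affine target has strictly positive energy
    tgt <- ref$coords
    tgt[1L, 1L] <- tgt[1L, 1L] + 0.5
    expect_gt(bending_energy(m, tgt), 1e-6)
  }
})

test_that("bending energy matches the dense bordered-system oracle", {
  # the worked unit-square case first
  sq <- landmarks(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1), c(0.5, 0.5)))
  m <- bending_energy_matrix(sq)
  tgt <- sq$coords
  tgt[2L, ] <- tgt[2L, ] + c(0.1, 0)
  expect_equal(bending_energy(m, tgt), tps_energy_oracle(sq, tgt),
               tolerance = 1e-8)
  set.seed(33)
  for (rep in 1:20) {
    d <- if (rep %% 2L) 2L else 3L
    ref <- rand_landmarks(4L + sample(10L, 1L), d)
    tgt <- landmarks(ref$coords + matrix(rnorm(length(ref$coords), sd = 0.3),
                                         ncol = d))
    m <- bending_energy_matrix(ref)
    expect_equal(bending_energy(m, tgt), tps_energy_oracle(ref, tgt),
                 tolerance = 1e-8)
  }
})

test_that("degenerate references are rejected informatively", {
  dup <- landmarks(rbind(c(0, 0), c(0, 0), c(1, 1), c(2, 0), c(1, 3)))
  expect_error(bending_energy_matrix(dup), "duplicate landmarks 1 and 2")
  ref <- rand_landmarks(8L, 2L)
  m <- bending_energy_matrix(ref)
  expect_error(bending_energy(m, rand_landmarks(9L, 2L)), "match")
  expect_error(bending_energy_matrix(landmarks(rbind(c(0, 0), c(1, 1), c(2, 2)))),
               "landmarks")
})

test_that("sliding never increases bending energy and stays on the curve", {
  set.seed(34)
  ref_cu <- rand_closed_curve(300L, 2L)
  ref <- resample_equidistant(ref_cu, 15L, start_rule = "first")
  model <- bending_energy_matrix(ref)
  for (rep in 1:30) {
    cu <- rand_closed_curve(300L, 2L)
    cf <- resample_equidistant(cu, 15L, start_rule = "first")
    e0 <- bending_energy(model, cf)
    out <- slide_semilandmarks(cf, cu, model)
    tr <- attr(out, "energy_trace")
    expect_true(all(diff(tr) <= 1e-8 * pmax(tr[-length(tr)], 1e-12)))
    expect_lte(attr(out, "energy"), e0 * (1 + 1e-8))
    offs <- vapply(seq_len(15L), function(i)
      project_to_curve(out$coords[i, ], cu)$distance, 0)
    expect_lt(max(offs), 1e-8)
  }
})

test_that("sliding a configuration against itself is a fixed point", {
  set.seed(35)
  cu <- rand_closed_curve(300L, 3L)
  ref <- resample_equidistant(cu, 12L, start_rule = "first")
  model <- bending_energy_matrix(ref)
  out <- slide_semilandmarks(ref, cu, model)
  expect_lt(max(abs(out$coords - ref$coords)), 1e-6)
})

test_that("a single sliding landmark matches 1-D scalar minimization", {
  # square outline: landmark 6 sits on the straight bottom side; all others
  # fixed. Its optimal position is found independently by optimize().
  side <- seq(0, 1, length.out = 26L)[-26L]
  sq_pts <- rbind(cbind(side, 0), cbind(1, side), cbind(1 - side, 1),
                  cbind(0, 1 - side))
  cu <- conch_curve(sq_pts, closed = TRUE)
  cf <- resample_equidistant(cu, 12L, start_rule = "first")
  expect_equal(unname(cf$coords[2L, 2L]), 0)  # landmark 2 is on the bottom side
  ref_coords <- cf$coords
  ref_coords[2L, ] <- ref_coords[2L, ] + c(0.05, 0.08)  # non-affine reference
  model <- bending_energy_matrix(landmarks(ref_coords))
  fixed <- setdiff(seq_len(12L), 2L)
  out <- slide_semilandmarks(cf, cu, model, fixed_indices = fixed,
                             max_iter = 50L, tol = 1e-14)
  expect_equal(unname(out$coords[2L, 2L]), 0)  # stayed on the bottom side
  f <- function(x) {
    y <- cf$coords; y[2L, ] <- c(x, 0)
    bending_energy(model, y)
  }
  opt <- stats::optimize(f, c(0, 1), tol = 1e-12)
  expect_equal(unname(out$coords[2L, 1L]), opt$minimum, tolerance = 1e-6)
  expect_equal(out$coords[fixed, ], cf$coords[fixed, ])
})

test_that("landmarks far from their curve are rejected", {
  cu <- rand_closed_curve(200L, 2L)
  cf <- resample_equidistant(cu, 10L, start_rule = "first")
  cf$coords[3L, ] <- cf$coords[3L, ] + 5
  model <- bending_energy_matrix(resample_equidistant(cu, 10L, "first"))
  expect_error(slide_semilandmarks(cf, cu, model), "lies")
})
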