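# Independent oracles, kept deliberately separate from the package's own
# implementation paths.

# Dense bordered-system TPS oracle: solve the full interpolation system for
# the weights w (K w + P a = y, P' w = 0) and evaluate the energy as
# sum_dims w' K w. The package instead extracts the bending-energy matrix
# from the inverse of the bordered system; the two routes must agree.
tps_energy_oracle <- function(ref, target) {
  x <- if (inherits(ref, "landmarks")) ref$coords else as.matrix(ref)
  y <- if (inherits(target, "landmarks")) target$coords else as.matrix(target)
  k <- nrow(x); d <- ncol(x)
  r <- as.matrix(stats::dist(x))
  K <- if (d == 2L) { u <- r^2 * log(r); u[r == 0] <- 0; u } else -r
  P <- cbind(1, x)
  M <- rbind(cbind(K, P), cbind(t(P), matrix(0, d + 1L, d + 1L)))
  rhs <- rbind(y, matrix(0, d + 1L, d))
  z <- solve(M, rhs)
  w <- z[1:k, , drop = FALSE]
  sum(vapply(seq_len(d), function(j) drop(w[, j] %*% K %*% w[, j]), 0))
}

# brute-force nearest point on a polyline: dense grid of points along every
# segment (independent of the package's closed-form per-segment projection)
brute_project <- function(point, curve, grid = 400L) {
  v <- curve$points
  if (curve$closed) v <- rbind(v, v[1L, ])
  best <- Inf
  for (i in seq_len(nrow(v) - 1L)) {
    t <- seq(0, 1, length.out = grid)
    pts <- outer(1 - t, v[i, ]) + outer(t, v[i + 1L, ])
    d2 <- rowSums(sweep(pts, 2L, point)^2)
    best <- min(best, min(d2))
  }
  sqrt(best)
}

rand_rotation <- function(d) {
  Q <- qr.Q(qr(matrix(stats::rnorm(d * d), d)))
  if (det(Q) < 0) Q[, 1L] <- -Q[, 1L]
  Q
}

# random smooth closed curve (2D or 3D) for sliding / resampling tests
rand_closed_curve <- function(n = 300L, d = 2L) {
  t <- 2 * pi * (0:(n - 1L)) / n
  r <- 1 + 0.3 * cos(2 * t + stats::runif(1, 0, 2 * pi)) +
    0.15 * sin(3 * t + stats::runif(1, 0, 2 * pi))
  if (d == 2L) conch_curve(cbind(r * cos(t), r * sin(t)))
  else conch_curve(cbind(r * cos(t), 0.3 * sin(2 * t + stats::runif(1, 0, 2 * pi)),
                         r * sin(t)))
}

rand_landmarks <- function(k = 10L, d = 2L, label = "") {
  landmarks(matrix(stats::rnorm(k * d), ncol = d), label = label)
}

# independent alternating GPA for small 2D sets: rotation step by 1-D
# minimization over the rotation angle rather than the SVD construction
gpa_oracle_2d <- function(mats, iters = 400L) {
  norm1 <- function(x) { x <- sweep(x, 2L, colMeans(x)); x / sqrt(sum(x^2)) }
  X <- lapply(mats, norm1)
  cons <- X[[1L]]
  rotate_onto <- function(x, target) {
    f <- function(th) {
      R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2L)
      sum((x %*% R - target)^2)
    }
    best <- stats::optimize(f, c(-pi, pi), tol = 1e-14)
    cand <- lapply(c(best$minimum, best$minimum + pi, best$minimum - pi),
                   function(th) list(th = th, v = f(th)))
    th <- cand[[which.min(vapply(cand, `[[`, 0, "v"))]]$th
    x %*% matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2L)
  }
  for (i in seq_len(iters)) {
    X <- lapply(X, rotate_onto, target = cons)
    m <- Reduce(`+`, X) / length(X)
    cons <- m / sqrt(sum(sweep(m, 2L, colMeans(m))^2))
  }
  m <- Reduce(`+`, X) / length(X)
  cs <- sqrt(sum(sweep(m, 2L, colMeans(m))^2))
  X <- lapply(X, function(x) x / cs)
  cons <- Reduce(`+`, X) / length(X)
  list(aligned = X, consensus = cons,
       residuals = t(vapply(X, function(x) as.vector(x - cons),
                            numeric(length(cons)))))
}

# random additive distance matrix from a random tree with positive lengths
rand_additive <- function(n) {
  tr <- ape::rtree(n, br = function(k) stats::runif(k, 0.1, 2))
  tr <- ape::unroot(tr)
  list(tree = tr, D = ape::cophenetic.phylo(tr))
}

expect_same_tree <- function(a, b) {
  expect_equal(ape::dist.topo(ape::unroot(a), ape::unroot(b)), 0,
               ignore_attr = TRUE)
}
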