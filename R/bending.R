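# Thin-plate-spline bending energy and sliding semi-landmarks.
#
# The bending energy of a target configuration relative to a reference is the
# quadratic form t(y) %*% L %*% y summed over coordinate dimensions, where L
# (the bending-energy matrix) is the upper-left k x k block of the inverse of
# the bordered TPS system of the reference. It vanishes exactly on affine
# transforms of the reference. Kernels: U(r) = r^2 log r in 2D, U(r) = r in
# 3D, U(0) = 0 (the 3D block is sign-corrected so L stays positive
# semidefinite).

tps_kernel <- function(r, d) {
  if (d == 2L) {
    u <- r^2 * log(r)
    u[r == 0] <- 0
    u
  } else {
    -r  # negative radial kernel keeps the bordered-system energy block PSD
  }
}

#' Bending-energy model of a reference configuration
#'
#' Builds the bordered thin-plate-spline system of the reference (kernel
#' matrix plus affine terms) and extracts the k x k bending-energy matrix.
#' The matrix annihilates affine terms: its product with the reference
#' coordinates augmented by a constant column is zero.
#'
#' @param reference a [landmarks()] object (k > d + 1, landmarks not
#'   degenerate).
#' @return an object of class `bending_energy_model` with fields `reference`,
#'   `kernel_dim`, `energy_matrix`.
#' @export
bending_energy_matrix <- function(reference) {
  x <- if (inherits(reference, "landmarks")) reference$coords else as.matrix(reference)
  k <- nrow(x); d <- ncol(x)
  if (k <= d + 1L) stop("need more than d + 1 landmarks")
  dm <- as.matrix(stats::dist(x))
  if (any(dm[upper.tri(dm)] < 1e-12)) {
    ij <- which(dm < 1e-12 & upper.tri(dm), arr.ind = TRUE)[1L, ]
    stop(sprintf("duplicate landmarks %d and %d make the TPS system singular",
                 ij[1L], ij[2L]))
  }
  K <- tps_kernel(dm, d)
  P <- cbind(1, x)
  M <- rbind(cbind(K, P), cbind(t(P), matrix(0, d + 1L, d + 1L)))
  Minv <- tryCatch(solve(M), error = function(e)
    stop("singular TPS system: ", conditionMessage(e)))
  L <- Minv[1:k, 1:k, drop = FALSE]
  L <- (L + t(L)) / 2
  structure(list(reference = landmarks(x, label = if (inherits(reference, "landmarks")) reference$label else ""),
                 kernel_dim = d, energy_matrix = L),
            class = "bending_energy_model")
}

#' @export
print.bending_energy_model <- function(x, ...) {
  cat(sprintf("<bending_energy_model> reference k=%d, d=%d\n",
              nrow(x$reference$coords), x$kernel_dim))
  invisible(x)
}

#' Bending energy of a target relative to the reference
#'
#' Sum over coordinate dimensions of the quadratic form of the target in the
#' reference's bending-energy matrix. Zero (to numerical precision) if and
#' only if the target is an affine transform of the reference.
#'
#' @param model a [bending_energy_matrix()] result.
#' @param target a [landmarks()] object or coordinate matrix with the same
#'   k and d as the reference.
#' @return nonnegative scalar.
#' @export
bending_energy <- function(model, target) {
  y <- if (inherits(target, "landmarks")) target$coords else as.matrix(target)
  L <- model$energy_matrix
  if (nrow(y) != nrow(L) || ncol(y) != model$kernel_dim)
    stop("target dimensions do not match the reference")
  e <- sum(vapply(seq_len(ncol(y)), function(j) drop(y[, j] %*% L %*% y[, j]), 0))
  max(e, 0)
}

#' Slide semi-landmarks along their curves
#'
#' Iteratively slides each configuration's landmarks along the tangent
#' directions of its own curve so as to minimize the bending energy relative
#' to the reference, then re-projects the slid points onto the curve. The
#' minimization in the tangent directions is an exact linear solve of the
#' quadratic bending-energy objective; a backtracking step guarantees the
#' energy is non-increasing across iterations.
#'
#' @param configs list of [landmarks()] (or a single one).
#' @param curves matching list of [conch_curve()] the landmarks lie on.
#' @param model [bending_energy_matrix()] of the reference configuration.
#' @param max_iter maximum sliding iterations.
#' @param tol relative bending-energy decrease below which iteration stops.
#' @param fixed_indices landmarks never moved (default: the start landmark).
#' @param max_offset error if a landmark starts farther than this fraction of
#'   the curve's arc length from the curve.
#' @return list of slid [landmarks()] objects (a single object if a single
#'   config was supplied), each with attributes `iterations` and `energy`.
#' @export
slide_semilandmarks <- function(configs, curves, model, max_iter = 10L,
                                tol = 1e-8, fixed_indices = 1L,
                                max_offset = 0.05) {
  single <- inherits(configs, "landmarks")
  if (single) { configs <- list(configs); curves <- list(curves) }
  if (length(configs) != length(curves))
    stop("configs and curves must match one to one")
  out <- vector("list", length(configs))
  for (ii in seq_along(configs)) {
    out[[ii]] <- slide_one(configs[[ii]], curves[[ii]], model, max_iter, tol,
                           fixed_indices, max_offset)
  }
  names(out) <- names(configs)
  if (single) out[[1L]] else out
}

slide_one <- function(config, curve, model, max_iter, tol, fixed_indices,
                      max_offset) {
  X <- config$coords
  k <- nrow(X); d <- ncol(X)
  L <- model$energy_matrix
  if (nrow(L) != k || model$kernel_dim != d)
    stop("configuration does not match the bending-energy model")
  Ltot <- arc_length(curve)
  off <- vapply(seq_len(k), function(i) project_to_curve(X[i, ], curve)$distance, 0)
  if (any(off > max_offset * Ltot))
    stop(sprintf("landmark %d of '%s' lies %.3g from its curve (limit %.3g)",
                 which.max(off), config$label, max(off), max_offset * Ltot))
  free <- setdiff(seq_len(k), fixed_indices)
  energy <- bending_energy(model, X)
  trace <- energy
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    Tm <- t(vapply(seq_len(k), function(i) curve_tangent_at(curve, X[i, ]),
                   numeric(d)))
    H <- L * (Tm %*% t(Tm))
    b <- rowSums(Tm * (L %*% X))
    Hf <- H[free, free, drop = FALSE]
    tvec <- numeric(k)
    sol <- tryCatch(
      solve(Hf + diag(1e-10 * max(diag(Hf), 1e-300), nrow(Hf)), -b[free]),
      error = function(e) qr.solve(Hf, -b[free], tol = 1e-12))
    tvec[free] <- sol
    improved <- FALSE
    step <- 1
    for (bt in 1:12) {
      Xc <- X + (step * tvec) * Tm
      Xn <- t(vapply(seq_len(k), function(i)
        if (i %in% free) project_to_curve(Xc[i, ], curve)$point else X[i, ],
        numeric(d)))
      en <- bending_energy(model, Xn)
      if (en <= energy * (1 + tol)) { improved <- en < energy; break }
      step <- step / 2
    }
    if (en <= energy) {
      delta <- energy - en
      X <- Xn
      prev <- energy
      energy <- en
      trace <- c(trace, energy)
      if (prev > 0 && delta / prev < tol) break
    } else break
  }
  res <- landmarks(X, label = config$label)
  attr(res, "iterations") <- iter
  attr(res, "energy") <- energy
  attr(res, "energy_trace") <- trace
  res
}
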