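# Generalized Procrustes analysis: translation to the centroid, scaling to
# unit centroid size, and iterative proper rotation onto a consensus.

#' Optimal proper rotation of one configuration onto another
#'
#' Returns the rotation with determinant +1 (reflections excluded) minimizing
#' the summed squared distance between the rotated source and the target, by
#' the standard singular-value construction.
#'
#' @param source,target centered k x d coordinate matrices (or [landmarks()]).
#' @return list with `rotation` (d x d), `fitted` (source %*% rotation), and
#'   `rss` (residual sum of squares).
#' @export
orthogonal_align <- function(source, target) {
  s <- if (inherits(source, "landmarks")) source$coords else as.matrix(source)
  t_ <- if (inherits(target, "landmarks")) target$coords else as.matrix(target)
  sv <- svd(crossprod(s, t_))
  d <- ncol(s)
  sgn <- diag(c(rep(1, d - 1L), sign(det(sv$u %*% t(sv$v)))), d)
  R <- sv$u %*% sgn %*% t(sv$v)
  fitted <- s %*% R
  list(rotation = R, fitted = fitted, rss = sum((fitted - t_)^2))
}

# center rows and scale to unit centroid size; errors on zero size
center_scale <- function(x, label = "") {
  x <- sweep(x, 2L, colMeans(x))
  cs <- sqrt(sum(x^2))
  if (cs <= 0) stop(sprintf("configuration '%s' has zero centroid size", label))
  x / cs
}

# deterministic canonical orientation: rotate the configuration set so the
# consensus lies along its principal axes with a fixed sign rule (the largest
# projected coordinate on each axis is positive) and determinant +1, so GPA
# output does not depend on the original orientation of the inputs.
canonical_rotation <- function(consensus) {
  d <- ncol(consensus)
  eg <- eigen(crossprod(consensus), symmetric = TRUE)
  V <- eg$vectors
  for (j in seq_len(d - 1L)) {
    proj <- consensus %*% V[, j]
    if (proj[which.max(abs(proj))] < 0) V[, j] <- -V[, j]
  }
  if (det(V) < 0) V[, d] <- -V[, d]
  V
}

#' Generalized Procrustes analysis
#'
#' Centers every configuration, scales it to unit centroid size, and
#' iteratively rotates all configurations onto the running consensus until the
#' consensus stabilizes. After convergence all configurations are rescaled by
#' a single common factor so that the consensus (their mean) has exactly unit
#' centroid size and the residual vectors average exactly to zero, and the
#' whole set is rotated to a canonical orientation so the result is invariant
#' to similarity transforms of the inputs.
#'
#' @param configs list of [landmarks()] (same k and d, nonzero size).
#' @param max_iter maximum consensus iterations.
#' @param tol root-mean-square consensus change at which to stop.
#' @return an object of class `gpa`: `aligned` (list of [landmarks()]),
#'   `consensus` (k x d, unit centroid size), `residuals` (n x (k d) matrix of
#'   flattened deviations from the consensus, one row per configuration),
#'   `labels`, `centroid_sizes` (original sizes), `iterations`, `converged`.
#' @export
gpa <- function(configs, max_iter = 100L, tol = 1e-12) {
  if (length(configs) < 2L) stop("need at least 2 configurations")
  labels <- vapply(seq_along(configs), function(i) {
    l <- configs[[i]]$label
    if (nzchar(l)) l else sprintf("config_%d", i)
  }, "")
  k <- nrow(configs[[1L]]$coords); d <- ncol(configs[[1L]]$coords)
  sizes <- vapply(configs, function(cf) cf$centroid_size, 0)
  X <- lapply(seq_along(configs), function(i) {
    cf <- configs[[i]]
    if (nrow(cf$coords) != k || ncol(cf$coords) != d)
      stop("configurations differ in k or d")
    center_scale(cf$coords, labels[i])
  })
  consensus <- X[[1L]]
  iterations <- 0L; converged <- FALSE
  while (iterations < max_iter) {
    iterations <- iterations + 1L
    X <- lapply(X, function(x) orthogonal_align(x, consensus)$fitted)
    m <- Reduce(`+`, X) / length(X)
    new_cons <- m / sqrt(sum(m^2))
    change <- sqrt(mean((new_cons - consensus)^2))
    consensus <- new_cons
    if (change < tol) { converged <- TRUE; break }
  }
  # common rescale so mean(aligned) has exactly unit centroid size
  m <- Reduce(`+`, X) / length(X)
  cs_m <- sqrt(sum(sweep(m, 2L, colMeans(m))^2))
  R <- canonical_rotation(m / cs_m)
  X <- lapply(X, function(x) (x %*% R) / cs_m)
  consensus <- Reduce(`+`, X) / length(X)
  res <- t(vapply(X, function(x) as.vector(x - consensus), numeric(k * d)))
  rownames(res) <- labels
  aligned <- lapply(seq_along(X), function(i) landmarks(X[[i]], label = labels[i]))
  names(aligned) <- labels
  structure(list(aligned = aligned, consensus = consensus, residuals = res,
                 labels = labels, centroid_sizes = sizes,
                 iterations = iterations, converged = converged,
                 k = k, d = d),
            class = "gpa")
}

#' @export
print.gpa <- function(x, ...) {
  cat(sprintf("<gpa> %d configurations (k=%d, d=%d), %d iterations%s\n",
              length(x$aligned), x$k, x$d, x$iterations,
              if (x$converged) ", converged" else ""))
  invisible(x)
}

#' @export
summary.gpa <- function(object, ...) {
  rss <- rowSums(object$residuals^2)
  cat(sprintf("Generalized Procrustes analysis: %d configurations, k=%d, d=%d\n",
              length(object$aligned), object$k, object$d))
  cat(sprintf("consensus centroid size: %.6f\n", centroid_size(object$consensus)))
  cat(sprintf("Procrustes distances to consensus: min %.4g, median %.4g, max %.4g\n",
              sqrt(min(rss)), sqrt(stats::median(rss)), sqrt(max(rss))))
  invisible(object)
}

#' Full Procrustes distance between two configurations
#'
#' Root summed squared difference after centering, unit-size scaling and
#' optimal proper rotation; symmetric in its arguments.
#'
#' @param a,b [landmarks()] objects or coordinate matrices.
#' @return nonnegative scalar.
#' @export
procrustes_distance <- function(a, b) {
  xa <- center_scale(if (inherits(a, "landmarks")) a$coords else as.matrix(a))
  xb <- center_scale(if (inherits(b, "landmarks")) b$coords else as.matrix(b))
  sqrt(orthogonal_align(xa, xb)$rss)
}

#' Export Procrustes residuals to CSV
#'
#' One row per configuration: label, then the flattened residual vector.
#'
#' @param fit a [gpa()] result.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_residuals_csv <- function(fit, path) {
  df <- data.frame(label = fit$labels, fit$residuals, check.names = FALSE)
  colnames(df) <- c("label", paste0("r", seq_len(ncol(fit$residuals))))
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}
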