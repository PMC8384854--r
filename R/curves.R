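#' Curve objects
#'
#' A curve is an ordered polyline in 2 or 3 dimensions (coordinates in mm).
#' Closed curves are stored without repeating the first point at the end;
#' closure is implicit. Curves are the interface between segmentation (or the
#' synthetic generator) and landmarking: suture lines are closed 3D curves,
#' whorl cross-section outlines are closed 2D curves.
#'
#' @param points numeric matrix, one row per vertex, 2 or 3 columns.
#' @param closed logical; is the curve closed?
#' @param label provenance label (specimen / chamber / section).
#' @return an object of class `conch_curve`.
#' @export
conch_curve <- function(points, closed = TRUE, label = "") {
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  if (ncol(points) < 2L || ncol(points) > 3L)
    stop("curve must be 2- or 3-dimensional")
  if (nrow(points) < 3L)
    stop("curve needs at least 3 points")
  if (closed && isTRUE(all(points[1L, ] == points[nrow(points), ])))
    points <- points[-nrow(points), , drop = FALSE]
  seg <- diff(points)
  if (any(rowSums(seg^2) == 0))
    stop("curve has consecutive duplicate points")
  structure(list(points = points, closed = isTRUE(closed), label = label),
            class = "conch_curve")
}

#' @export
print.conch_curve <- function(x, ...) {
  cat(sprintf("<conch_curve> %s: %d points, %dD, %s, length %.3f mm\n",
              if (nzchar(x$label)) x$label else "(unlabelled)",
              nrow(x$points), ncol(x$points),
              if (x$closed) "closed" else "open", arc_length(x)))
  invisible(x)
}

# vertex matrix including the closing vertex for closed curves
curve_vertices <- function(curve) {
  p <- curve$points
  if (curve$closed) rbind(p, p[1L, ]) else p
}

#' Total arc length of a curve
#'
#' Piecewise-linear arc length, including the closing segment for closed
#' curves. No spline fitting is done; input curves are expected to be densely
#' sampled so the polyline error is negligible.
#'
#' @param curve a [conch_curve()].
#' @return total length in mm.
#' @export
arc_length <- function(curve) {
  v <- curve_vertices(curve)
  sum(sqrt(rowSums(diff(v)^2)))
}

# cumulative arc-length at each vertex of curve_vertices(curve); first is 0
cum_arc <- function(v) c(0, cumsum(sqrt(rowSums(diff(v)^2))))

#' Landmark configurations
#'
#' An ordered set of k landmarks in d dimensions with a provenance label.
#' Centroid size is computed at construction.
#'
#' @param coords k x d numeric matrix of landmark coordinates (mm).
#' @param label provenance label.
#' @return an object of class `landmarks` with fields `coords`, `label`,
#'   `centroid_size`.
#' @export
landmarks <- function(coords, label = "") {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (nrow(coords) < 1L) stop("empty landmark configuration")
  structure(list(coords = coords, label = label,
                 centroid_size = centroid_size(coords)),
            class = "landmarks")
}

#' @export
print.landmarks <- function(x, ...) {
  cat(sprintf("<landmarks> %s: k=%d, d=%d, centroid size %.4f\n",
              if (nzchar(x$label)) x$label else "(unlabelled)",
              nrow(x$coords), ncol(x$coords), x$centroid_size))
  invisible(x)
}

#' Centroid size
#'
#' Square root of the summed squared distances of the landmarks from their
#' centroid; the size measure removed by Procrustes superimposition. It is
#' translation- and rotation-invariant and homogeneous of degree one in scale.
#'
#' @param config a [landmarks()] object or a k x d coordinate matrix.
#' @return centroid size in mm (0 for fully coincident landmarks).
#' @export
centroid_size <- function(config) {
  x <- if (inherits(config, "landmarks")) config$coords else as.matrix(config)
  ctr <- colMeans(x)
  sqrt(sum(sweep(x, 2L, ctr)^2))
}

# resolve the starting vertex index for resampling a closed curve
resolve_start <- function(curve, start_rule) {
  p <- curve$points
  switch(start_rule,
    first = 1L,
    ventral = {
      # distance from the coiling axis in the median plane: for 2D section
      # outlines the first coordinate is radial; for 3D curves the coiling
      # axis is the y axis, so radial distance is sqrt(x^2 + z^2).
      r <- if (ncol(p) == 2L) p[, 1L] else sqrt(p[, 1L]^2 + p[, 3L]^2)
      which.max(r)  # ties: smallest index, which.max's rule
    },
    stop("unknown start_rule: ", start_rule)
  )
}

#' Resample a curve into equidistant landmarks
#'
#' Places `k` points on the polyline at equal arc-length spacing, following
#' the curve's orientation. For closed curves the spacing is L/k starting at
#' the vertex chosen by `start_rule`; for open curves both endpoints are kept
#' and the spacing is L/(k-1).
#'
#' @param curve a [conch_curve()].
#' @param k number of landmarks (>= 3).
#' @param start_rule for closed curves, where landmark 1 sits: `"ventral"`
#'   (vertex farthest from the coiling axis, the conchological venter; ties
#'   broken by smallest index) or `"first"` (first stored vertex).
#' @return a [landmarks()] object with `k` rows.
#' @export
resample_equidistant <- function(curve, k, start_rule = c("ventral", "first")) {
  start_rule <- match.arg(start_rule)
  k <- as.integer(k)
  if (k < 3L) stop("k must be at least 3")
  if (k > 10L * nrow(curve$points))
    stop("k exceeds the resolution representable by this curve")
  p <- curve$points
  if (curve$closed) {
    i0 <- resolve_start(curve, start_rule)
    if (i0 > 1L) p <- p[c(i0:nrow(p), 1L:(i0 - 1L)), , drop = FALSE]
    v <- rbind(p, p[1L, ])
  } else {
    v <- p
  }
  s <- cum_arc(v)
  L <- s[length(s)]
  if (L <= 0) stop("curve has zero length")
  targets <- if (curve$closed) L * (0:(k - 1L)) / k else L * (0:(k - 1L)) / (k - 1L)
  idx <- findInterval(targets, s, rightmost.closed = TRUE)
  idx <- pmin(pmax(idx, 1L), nrow(v) - 1L)
  seg_len <- s[idx + 1L] - s[idx]
  t <- (targets - s[idx]) / seg_len
  coords <- v[idx, , drop = FALSE] * (1 - t) + v[idx + 1L, , drop = FALSE] * t
  landmarks(coords, label = curve$label)
}

#' Project a point onto a curve
#'
#' Finds the closest point on the polyline (segment-wise orthogonal
#' projection, clamped to segment ends) and its arc-length coordinate.
#'
#' @param point numeric vector of length d.
#' @param curve a [conch_curve()] of the same dimension.
#' @return list with `point` (the foot of the projection), `arc` (arc-length
#'   position from the first vertex), `distance`, and `segment` (index).
#' @export
project_to_curve <- function(point, curve) {
  v <- curve_vertices(curve)
  a <- v[-nrow(v), , drop = FALSE]
  b <- v[-1L, , drop = FALSE]
  ab <- b - a
  len2 <- rowSums(ab^2)
  ap <- sweep(a, 2L, point, "-")
  t <- pmin(pmax(-rowSums(ap * ab) / len2, 0), 1)
  foot <- a + ab * t
  d2 <- rowSums(sweep(foot, 2L, point, "-")^2)
  i <- which.min(d2)
  s <- cum_arc(v)
  list(point = foot[i, ], arc = s[i] + t[i] * sqrt(len2[i]),
       distance = sqrt(d2[i]), segment = i)
}

# unit tangent of the segment a landmark projects onto
curve_tangent_at <- function(curve, point) {
  v <- curve_vertices(curve)
  pr <- project_to_curve(point, curve)
  seg <- v[pr$segment + 1L, ] - v[pr$segment, ]
  seg / sqrt(sum(seg^2))
}
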