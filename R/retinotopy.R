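#' Moments-based 2D Gaussian fit to a point cloud
#'
#' Center is the sample mean; the standard deviations are the square
#' roots of the sample covariance eigenvalues (major/minor axes), with
#' the major-axis orientation in degrees CCW from +x. Deterministic.
#'
#' @param points n x 2 matrix (or data.frame with `x_um`/`y_um` or two
#'   numeric columns) of positions (um).
#' @return A [Gaussian2DFit-class].
#' @export
fitGaussian2D <- function(points) {
  if (is.data.frame(points)) {
    points <- if (all(c("x_um", "y_um") %in% names(points)))
      cbind(points$x_um, points$y_um) else as.matrix(points[, 1:2])
  }
  points <- matrix(as.numeric(points), ncol = 2)
  n <- nrow(points)
  if (n == 0) stop("cannot fit a Gaussian to 0 points")
  center <- colMeans(points)
  if (n == 1) {
    cv <- matrix(0, 2, 2)
  } else {
    cv <- stats::cov(points)
  }
  eg <- eigen(cv, symmetric = TRUE)
  sds <- sqrt(pmax(eg$values, 0))
  v <- eg$vectors[, 1]
  orient <- (atan2(v[2], v[1]) * 180 / pi) %% 180
  new("Gaussian2DFit", center = unname(center), sdMajor = sds[1],
      sdMinor = sds[2], orientation = orient, cov = cv,
      nPoints = as.integer(n))
}

#' Vector from the optic nerve head to a fitted population center
#'
#' @param fit A [Gaussian2DFit-class].
#' @param onh Optic nerve head position (x, y um); default the origin.
#' @return List: `angle` (deg CCW from +x, in \[0, 360), `NA` when the
#'   center coincides with the optic nerve head) and `distance` (um).
#' @export
centroidVector <- function(fit, onh = c(0, 0)) {
  stopifnot(is(fit, "Gaussian2DFit"), length(onh) == 2)
  d <- fit@center - onh
  dist <- sqrt(sum(d^2))
  if (dist == 0)
    return(list(angle = NA_real_, distance = 0))
  list(angle = (atan2(d[2], d[1]) * 180 / pi) %% 360, distance = dist)
}

#' Angular separation of two centroid vectors
#'
#' Smallest rotation between the two angles: `min(|d|, 360 - |d|)`,
#' in \[0, 180\]. Symmetric in its arguments.
#'
#' @param angle1,angle2 Angles in degrees.
#' @return Separation in degrees.
#' @export
angularSeparation <- function(angle1, angle2) {
  d <- abs(angle1 - angle2) %% 360
  pmin(d, 360 - d)
}

#' Euclidean distance between two fitted population centers
#'
#' @param fit1,fit2 [Gaussian2DFit-class] objects.
#' @return Distance (um).
#' @export
centroidDistance <- function(fit1, fit2) {
  stopifnot(is(fit1, "Gaussian2DFit"), is(fit2, "Gaussian2DFit"))
  sqrt(sum((fit1@center - fit2@center)^2))
}

#' Count points within k standard deviations of a fitted center
#'
#' Mahalanobis criterion under the fit's covariance: a point on the k-sd
#' ellipse is counted (<= rule). A count of 0 replicates the spatial
#' separation criterion used for dual-injection maps.
#'
#' @param fit A [Gaussian2DFit-class] with positive spread.
#' @param points n x 2 matrix (or data.frame) of positions (um).
#' @param k Number of standard deviations (default 2).
#' @return Integer count.
#' @export
twoSdOverlap <- function(fit, points, k = 2) {
  stopifnot(is(fit, "Gaussian2DFit"))
  if (fit@sdMinor <= 0) stop("degenerate fit: zero standard deviation")
  if (is.data.frame(points)) {
    points <- if (all(c("x_um", "y_um") %in% names(points)))
      cbind(points$x_um, points$y_um) else as.matrix(points[, 1:2])
  }
  points <- matrix(as.numeric(points), ncol = 2)
  if (!nrow(points)) return(0L)
  d2 <- stats::mahalanobis(points, fit@center, fit@cov)
  sum(sqrt(d2) <= k)
}
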