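# Geometry and summaries of the 2-D coordination space (relative phase vs.
# normalized range): boundary curve of the within-band region, inside/outside
# classification, coverage ellipses and distribution summaries.

#' Boundary of the within-band region of the coordination space
#'
#' Magnitude of relative phase at which, under the sinusoidal model, the bow
#' change falls exactly on the edge of the string-crossing band:
#' `asin(r)` in degrees. Bow changes with `|delta_phi| <= boundary_phase(r)`
#' take place inside the crossing band.
#'
#' @param r normalized range in `[0, 1]`
#' @return degrees in `[0, 90]`
#' @export
boundary_phase <- function(r) {
  if (any(r < 0 | r > 1)) stop("r must lie in [0, 1]")
  asin(r) * 180 / pi
}

#' Classify a coordination point as inside/outside the crossing band region
#'
#' @param delta_phi_deg relative phase in degrees
#' @param r normalized range in `[0, 1]`
#' @return logical: TRUE iff `|delta_phi_deg| <= boundary_phase(r)`
#' @export
classify_inside <- function(delta_phi_deg, r) {
  abs(delta_phi_deg) <= boundary_phase(r)
}

#' Coverage ellipse of a bivariate point cloud
#'
#' Ellipse from the sample mean and covariance, scaled so that the requested
#' fraction of a bivariate normal falls inside (radius = sqrt of the
#' chi-square 2-df quantile). The default 0.68 corresponds to "one
#' multivariate standard deviation" in the sense that 68% of the data fall
#' within the ellipse; note a plain 1-SD Mahalanobis ellipse would cover only
#' about 39% of a bivariate normal.
#'
#' @param x,y coordinates (e.g. relative phase and normalized range), at
#'   least 3 non-collinear points
#' @param coverage target coverage fraction in (0, 1)
#' @return object of class `coverage_ellipse`: list with `center`,
#'   `semi_axes` (major, minor), `orientation_deg`, `coverage`, `cov` and
#'   `radius` (the Mahalanobis radius used)
#' @export
coverage_ellipse <- function(x, y, coverage = 0.68) {
  stopifnot(coverage > 0, coverage < 1)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 finite points")
  S <- stats::cov(cbind(x, y))
  if (!all(is.finite(S)) || det(S) <= .Machine$double.eps)
    stop("degenerate covariance: points are (nearly) collinear or identical")
  e <- eigen(S, symmetric = TRUE)
  radius <- sqrt(stats::qchisq(coverage, df = 2))
  structure(list(
    center = c(mean(x), mean(y)),
    semi_axes = radius * sqrt(e$values),
    orientation_deg = atan2(e$vectors[2, 1], e$vectors[1, 1]) * 180 / pi,
    coverage = coverage,
    cov = S,
    radius = radius
  ), class = "coverage_ellipse")
}

#' Points inside a coverage ellipse
#'
#' Squared Mahalanobis distance test against the ellipse radius; used both
#' for empirical-coverage checks and for plotting masks.
#'
#' @param ellipse a [coverage_ellipse()]
#' @param x,y coordinates
#' @return logical vector
#' @export
ellipse_contains <- function(ellipse, x, y) {
  d <- cbind(x - ellipse$center[1], y - ellipse$center[2])
  md2 <- rowSums((d %*% solve(ellipse$cov)) * d)
  md2 <= ellipse$radius^2
}

#' Outline of a coverage ellipse for plotting
#'
#' @param ellipse a [coverage_ellipse()]
#' @param n number of points
#' @return data.frame with columns `x`, `y`
#' @export
ellipse_outline <- function(ellipse, n = 180) {
  th <- seq(0, 2 * pi, length.out = n)
  a <- ellipse$orientation_deg * pi / 180
  R <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
  pts <- R %*% rbind(ellipse$semi_axes[1] * cos(th),
                     ellipse$semi_axes[2] * sin(th))
  data.frame(x = ellipse$center[1] + pts[1, ],
             y = ellipse$center[2] + pts[2, ])
}

#' Median and 10/90 percentiles of a feature distribution
#'
#' Percentiles use linear interpolation between order statistics (R's default
#' type-7 quantile definition).
#'
#' @param values numeric vector with at least one finite value
#' @return named list: `median`, `p10`, `p90`, `n`
#' @export
distribution_summary <- function(values) {
  v <- values[is.finite(values)]
  if (!length(v)) stop("no finite values")
  q <- stats::quantile(v, c(0.1, 0.5, 0.9), names = FALSE, type = 7)
  list(median = q[2], p10 = q[1], p90 = q[3], n = length(v))
}
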