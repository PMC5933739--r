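#' Pool and platform geometry
#'
#' Describes the circular pool, the hidden escape platform and the perimeter
#' release points. Defaults follow common mouse water-maze dimensions: a
#' 1.2 m diameter pool with a 10 cm platform centred at mid-radius of the
#' north-east quadrant. All downstream features are scale-free ratios, so
#' analyses are robust to the absolute dimensions.
#'
#' @param pool_radius pool radius in metres.
#' @param platform_center planar platform centre (metres, pool-centred
#'   coordinates). Default: mid-radius at 45 degrees.
#' @param platform_radius platform radius in metres.
#' @param start_points list of release points on the pool perimeter. Default:
#'   the four compass points, cycled across trials.
#' @return an object of class `pool_geometry`.
#' @examples
#' pool_geometry()
#' @export
pool_geometry <- function(pool_radius = 0.6,
                          platform_center = NULL,
                          platform_radius = 0.05,
                          start_points = NULL) {
  if (pool_radius <= 0) abort("pool_radius must be positive")
  if (is.null(platform_center)) {
    platform_center <- pool_radius / 2 * c(cos(pi / 4), sin(pi / 4))
  }
  platform_center <- as.numeric(platform_center)
  if (length(platform_center) != 2) abort("platform_center must be length 2")
  if (sqrt(sum(platform_center^2)) + platform_radius >= pool_radius) {
    abort("platform circle must lie strictly inside the pool")
  }
  if (is.null(start_points)) {
    ang <- c(pi / 2, pi, 3 * pi / 2, 0)
    start_points <- lapply(ang, function(a) pool_radius * c(cos(a), sin(a)))
  }
  tol <- 1e-9 * pool_radius
  for (p in start_points) {
    if (abs(sqrt(sum(p^2)) - pool_radius) > tol) {
      abort("every start point must lie on the pool perimeter")
    }
  }
  structure(
    list(pool_radius = pool_radius,
         platform_center = platform_center,
         platform_radius = platform_radius,
         start_points = start_points),
    class = "pool_geometry"
  )
}

#' @export
print.pool_geometry <- function(x, ...) {
  cat(sprintf(
    "<pool_geometry> pool radius %.3f m; platform r=%.3f m at (%.3f, %.3f); %d start points\n",
    x$pool_radius, x$platform_radius, x$platform_center[1],
    x$platform_center[2], length(x$start_points)))
  invisible(x)
}

.check_geometry <- function(geometry) {
  if (!inherits(geometry, "pool_geometry")) {
    abort("geometry must be a pool_geometry object")
  }
  invisible(geometry)
}

#' Reflect a proposed step at the pool wall
#'
#' Keeps a simulated swimmer inside the pool: a step whose endpoint would
#' leave the pool is reflected about the local wall tangent by folding the
#' radial coordinate at the wall (a purely radial outward overshoot becomes
#' an equal inward displacement). A total function: any finite step yields a
#' point inside the pool.
#'
#' @param point current position (length-2 numeric, inside the pool).
#' @param proposed_step planar displacement to apply.
#' @param geometry a [pool_geometry()].
#' @return the new position, always with `|p| <= pool_radius`.
#' @examples
#' g <- pool_geometry()
#' reflect_at_wall(c(0.6, 0), c(0.01, 0), g)
#' @export
reflect_at_wall <- function(point, proposed_step, geometry) {
  .check_geometry(geometry)
  R <- geometry$pool_radius
  p <- point + proposed_step
  r <- sqrt(sum(p^2))
  if (r <= R) return(p)
  # fold the radial coordinate at the wall until inside; a fold through the
  # centre (for very large steps) is handled by taking the absolute value
  while (r > R) {
    r <- 2 * R - r
    if (r < 0) r <- -r
  }
  if (sqrt(sum(p^2)) < 1e-12) return(c(0, 0))
  p * (r / sqrt(sum(p^2)))
}
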