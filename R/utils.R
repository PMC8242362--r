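# shared helpers: angle arithmetic, axial von Mises sampling, seeded evaluation

`%||%` <- function(a, b) if (is.null(a)) b else a

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Wrap angles to the axial range (-90, 90]
#'
#' Orientation (headless) angles are defined modulo 180 degrees.
#'
#' @param theta numeric vector of angles in degrees.
#' @return angles wrapped into `(-90, 90]`.
#' @export
wrap_axial <- function(theta) {
  out <- (theta + 90) %% 180 - 90
  out[out == -90] <- 90
  out
}

#' Axial angular distance
#'
#' Minimal distance between two orientations, in `[0, 90]` degrees.
#'
#' @param a,b angles in degrees (axial, i.e. modulo 180).
#' @return numeric vector of distances.
#' @export
axial_distance <- function(a, b) {
  d <- abs((a - b) %% 180)
  pmin(d, 180 - d)
}

#' Sample from the von Mises distribution
#'
#' Best-Fisher rejection sampler on the circle (period 2*pi). `kappa = 0`
#' reduces to the circular uniform distribution.
#'
#' @param n number of draws.
#' @param mu mean direction, radians.
#' @param kappa concentration, >= 0.
#' @return numeric vector of angles in `(-pi, pi]`.
#' @export
rvonmises <- function(n, mu = 0, kappa = 0) {
  stopifnot(kappa >= 0, n >= 0)
  if (n == 0) return(numeric(0))
  if (kappa == 0) return((runif(n, -pi, pi) + mu + pi) %% (2 * pi) - pi)
  if (kappa > 5e5) {
    # essentially degenerate; normal approximation sd = 1/sqrt(kappa)
    return(((rnorm(n, 0, 1 / sqrt(kappa)) + mu + pi) %% (2 * pi)) - pi)
  }
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  got <- 0L
  while (got < n) {
    m <- n - got
    u1 <- runif(m); u2 <- runif(m); u3 <- runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    c0 <- kappa * (r - f)
    ok <- (c0 * (2 - c0) - u2 > 0) | (log(c0 / u2) + 1 - c0 >= 0)
    th <- sign(u3 - 0.5)[ok] * acos(f[ok])
    k <- min(length(th), n - got)
    if (k > 0) out[(got + 1):(got + k)] <- th[seq_len(k)]
    got <- got + k
  }
  ((out + mu + pi) %% (2 * pi)) - pi
}

#' Sample axial (orientation) angles
#'
#' Draws orientations with 180-degree symmetry by the angle-doubling
#' construction: phi ~ von Mises(2 * mean_axis, kappa) on the full circle,
#' theta = phi / 2 wrapped to `(-90, 90]`.
#'
#' @param n number of draws.
#' @param mean_axis preferred axis, degrees.
#' @param kappa axial concentration, >= 0 (0 = isotropic).
#' @return orientations in degrees, `(-90, 90]`.
#' @export
sample_axial_angles <- function(n, mean_axis = 0, kappa = 0) {
  phi <- rvonmises(n, deg2rad(2 * mean_axis), kappa)
  wrap_axial(rad2deg(phi / 2))
}

#' Expected axial fraction within a band
#'
#' Probability that an axial von Mises orientation falls within
#' `half_width` degrees of its mean axis, by numeric quadrature of the
#' doubled-angle density exp(kappa * cos(2 theta)).
#'
#' @param kappa axial concentration.
#' @param half_width band half-width, degrees in `(0, 90]`.
#' @return probability in `[0, 1]`.
#' @export
axial_band_probability <- function(kappa, half_width = 30) {
  stopifnot(half_width > 0, half_width <= 90, kappa >= 0)
  dens <- function(th) exp(kappa * cos(2 * th))
  num <- integrate(dens, -deg2rad(half_width), deg2rad(half_width))$value
  den <- integrate(dens, -pi / 2, pi / 2)$value
  num / den
}

# evaluate expr under a fixed RNG state, restoring the caller's state after
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# distance from points (px, py) to segment (x0,y0)-(x1,y1); vectorized in points
point_segment_distance <- function(px, py, x0, y0, x1, y1) {
  vx <- x1 - x0; vy <- y1 - y0
  l2 <- vx * vx + vy * vy
  if (l2 == 0) return(sqrt((px - x0)^2 + (py - y0)^2))
  t <- pmin(1, pmax(0, ((px - x0) * vx + (py - y0) * vy) / l2))
  sqrt((px - (x0 + t * vx))^2 + (py - (y0 + t * vy))^2)
}

# minimal distance between two segments (scalar)
segment_segment_distance <- function(a0, a1, b0, b1) {
  # sample-free exact test via endpoint projections + intersection check
  d <- function(p, q0, q1) point_segment_distance(p[1], p[2], q0[1], q0[2], q1[1], q1[2])
  ccw <- function(p, q, r) (q[1] - p[1]) * (r[2] - p[2]) - (q[2] - p[2]) * (r[1] - p[1])
  inter <- ccw(a0, a1, b0) * ccw(a0, a1, b1) < 0 && ccw(b0, b1, a0) * ccw(b0, b1, a1) < 0
  if (inter) return(0)
  min(d(b0, a0, a1), d(b1, a0, a1), d(a0, b0, b1), d(a1, b0, b1))
}

stop_if_not_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop(sprintf("'%s' must be a positive finite scalar", name), call. = FALSE)
  invisible(x)
}
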