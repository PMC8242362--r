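# magnetostatics of the cylindrical magnet pair in the gelation chamber
#
# Magnets are modeled as uniformly magnetized cylinders (equivalent solenoid
# with azimuthal surface current K = Br / mu0), in free space (mu_r = 1,
# open boundary). On the symmetry axis the field has the classic closed form;
# off axis it is obtained by quadrature of the current-loop field (complete
# elliptic integrals) over the sheet. SI units throughout: metres, tesla.

#' Cylindrical permanent magnet
#'
#' Constructs a uniformly magnetized cylinder from its radius, length and
#' either the remanent flux density `Br` or the measurable face-center
#' surface field (from which `Br` is calibrated).
#'
#' @param R radius, m.
#' @param L length, m.
#' @param Br remanence, T. Exactly one of `Br`/`surface_field` is given.
#' @param surface_field on-axis flux density at the face center, T.
#' @param polarity +1 or -1, magnetization direction along the axis.
#' @return an object of class `cyl_magnet`.
#' @examples
#' m <- cyl_magnet(R = 0.01905, L = 0.0381, surface_field = 0.6619)
#' m$Br          # calibrated remanence, ~1.48 T
#' @export
cyl_magnet <- function(R, L, Br = NULL, surface_field = NULL, polarity = 1L) {
  stop_if_not_scalar_pos(R, "R"); stop_if_not_scalar_pos(L, "L")
  if (is.null(Br) == is.null(surface_field))
    stop("give exactly one of 'Br' or 'surface_field'")
  if (is.null(Br)) Br <- calibrate_remanence(R, L, surface_field)
  stop_if_not_scalar_pos(Br, "Br")
  stopifnot(polarity %in% c(-1L, 1L))
  structure(list(R = R, L = L, Br = Br, polarity = as.integer(polarity)),
            class = "cyl_magnet")
}

#' @export
print.cyl_magnet <- function(x, ...) {
  cat(sprintf("cyl_magnet: R = %.4g cm, L = %.4g cm, Br = %.4g T (surface %.4g mT)\n",
              100 * x$R, 100 * x$L, x$Br, 1000 * magnet_surface_field(x)))
  invisible(x)
}

#' Remanence from the face-center surface field
#'
#' Inverts the on-axis closed form at z = 0:
#' `Bs = (Br/2) * L / sqrt(L^2 + R^2)`, so `Br = 2 Bs sqrt(L^2+R^2) / L`.
#'
#' @param R,L magnet radius and length, m.
#' @param surface_field measured/datasheet face-center field, T.
#' @return remanence Br, T.
#' @export
calibrate_remanence <- function(R, L, surface_field) {
  stop_if_not_scalar_pos(R, "R"); stop_if_not_scalar_pos(L, "L")
  stop_if_not_scalar_pos(surface_field, "surface_field")
  2 * surface_field * sqrt(L^2 + R^2) / L
}

#' Face-center surface field of a magnet
#' @param magnet a [cyl_magnet()].
#' @return flux density at z = 0 on the face, T.
#' @export
magnet_surface_field <- function(magnet) axial_field(magnet, 0)

#' On-axis flux density of a cylindrical magnet
#'
#' Closed form for the field magnitude on the symmetry axis at distance `z`
#' outside the magnet face:
#' `B(z) = (Br/2) * ((z+L)/sqrt((z+L)^2+R^2) - z/sqrt(z^2+R^2))`.
#' Strictly decreasing in `z`; approaches the dipole law `Br R^2 L / (2 z^3)`
#' far away.
#'
#' @param magnet a [cyl_magnet()].
#' @param z distance from the face along the axis, m; `z >= 0` (the interior
#'   is not modeled).
#' @return flux density, T (vectorized over `z`).
#' @export
axial_field <- function(magnet, z) {
  stopifnot(inherits(magnet, "cyl_magnet"))
  if (any(z < 0)) stop("z < 0: on-axis field is defined outside the face only")
  R <- magnet$R; L <- magnet$L
  (magnet$Br / 2) * ((z + L) / sqrt((z + L)^2 + R^2) - z / sqrt(z^2 + R^2))
}

#' On-axis field by Biot-Savart quadrature (independent numerical route)
#'
#' Integrates the on-axis field of the equivalent solenoid current sheet,
#' `dB = (Br/2) R^2 / (R^2 + (z - z')^2)^(3/2) dz'`, with Gauss-Legendre
#' quadrature. Used as a cross-check of [axial_field()].
#'
#' @param magnet a [cyl_magnet()].
#' @param z distance from the face, m (vectorized).
#' @param n_nodes quadrature nodes.
#' @return flux density, T.
#' @export
axial_field_quadrature <- function(magnet, z, n_nodes = 200) {
  stopifnot(inherits(magnet, "cyl_magnet"))
  if (any(z < 0)) stop("z < 0: on-axis field is defined outside the face only")
  R <- magnet$R; L <- magnet$L
  gl <- pracma::gaussLegendre(n_nodes, -L, 0)   # sheet spans z' in [-L, 0]
  vapply(z, function(zi) {
    sum(gl$w * (magnet$Br / 2) * R^2 / (R^2 + (zi - gl$x)^2)^1.5)
  }, numeric(1))
}

#' Coaxial attracting magnet pair
#'
#' Two magnets on a common axis, faces separated by `spacing`, poles set
#' attracting so the fields aid in the air gap. Axial coordinate 0 is the
#' gap midpoint.
#'
#' @param magnet a [cyl_magnet()] (both magnets identical), or a list of two.
#' @param spacing face-to-face gap d, m.
#' @return an object of class `magnet_pair`.
#' @export
magnet_pair <- function(magnet, spacing) {
  if (inherits(magnet, "cyl_magnet")) magnet <- list(magnet, magnet)
  stopifnot(length(magnet) == 2L, all(vapply(magnet, inherits, TRUE, "cyl_magnet")))
  stop_if_not_scalar_pos(spacing, "spacing")
  structure(list(magnets = magnet, d = spacing), class = "magnet_pair")
}

#' Axial flux-density profile of a magnet pair
#'
#' Superposition of the two single-magnet on-axis fields across the air gap.
#' For identical magnets the profile is symmetric about the midpoint, where
#' it attains its minimum `2 * axial_field(magnet, d/2)`.
#'
#' @param pair a [magnet_pair()].
#' @param z axial positions, m, with 0 at the gap midpoint; all must lie in
#'   the open gap `(-d/2, d/2)` (faces included).
#' @return a `data.frame` of class `field_profile` with columns `z_m`, `B_T`.
#' @export
pair_axial_profile <- function(pair, z) {
  stopifnot(inherits(pair, "magnet_pair"))
  h <- pair$d / 2
  if (any(abs(z) > h + 1e-15))
    stop("grid point inside a magnet: profile is defined on the air gap only")
  z <- pmin(pmax(z, -h), h)
  B <- axial_field(pair$magnets[[1]], h + z) + axial_field(pair$magnets[[2]], h - z)
  structure(data.frame(z_m = z, B_T = B),
            class = c("field_profile", "data.frame"), spacing = pair$d)
}

#' Midpoint flux density of a magnet pair
#' @param pair a [magnet_pair()].
#' @return flux density at the gap midpoint, T.
#' @export
pair_midpoint_field <- function(pair) pair_axial_profile(pair, 0)$B_T

# field of a single current loop of radius a carrying current I, at (rho, zeta)
# relative to the loop plane; complete elliptic integrals K, E. Returns
# mu0 I absorbed into 'amp' (amp = Br * dz' for a sheet element).
loop_field <- function(a, rho, zeta, amp) {
  eps <- 1e-12 * a
  rho <- pmax(rho, 0)
  alpha2 <- a^2 + rho^2 + zeta^2 - 2 * a * rho
  beta2  <- a^2 + rho^2 + zeta^2 + 2 * a * rho
  beta <- sqrt(beta2)
  m <- pmin(pmax(1 - alpha2 / beta2, 0), 1 - 1e-15)
  ke <- pracma::ellipke(m)
  Bz <- amp / (2 * pi) * ((a^2 - rho^2 - zeta^2) * ke$e + alpha2 * ke$k) / (alpha2 * beta)
  Brho <- numeric(length(rho))
  off <- rho > eps
  Brho[off] <- amp / (2 * pi) * zeta[off] / rho[off] *
    ((a^2 + rho[off]^2 + zeta[off]^2) * ke$e[off] - alpha2[off] * ke$k[off]) /
    (alpha2[off] * beta[off])
  list(Bz = Bz, Brho = Brho)
}

# off-axis field of one magnet whose near face sits at z = z_face and body
# occupies [z_face, z_face + L] * sign. Magnetization along +z when polarity=1.
magnet_field_offaxis <- function(magnet, rho, z, z0, z1, n_nodes = 64) {
  gl <- pracma::gaussLegendre(n_nodes, z0, z1)
  Bz <- numeric(length(rho)); Brho <- numeric(length(rho))
  for (i in seq_len(n_nodes)) {
    lf <- loop_field(magnet$R, rho, z - gl$x[i], magnet$Br * gl$w[i])
    Bz <- Bz + lf$Bz; Brho <- Brho + lf$Brho
  }
  list(Bz = Bz * magnet$polarity, Brho = Brho * magnet$polarity)
}

#' Flux density on a plane containing the magnet axis
#'
#' Computes the field of the pair on an x-z grid (x transverse, z axial with
#' 0 at the gap midpoint) by Biot-Savart quadrature over each magnet's
#' equivalent solenoid sheet. Grid cells inside a magnet volume are masked
#' (`NA`) with a warning.
#'
#' @param pair a [magnet_pair()].
#' @param x transverse coordinates, m.
#' @param z axial coordinates, m.
#' @param n_nodes quadrature nodes per magnet.
#' @return list of class `field_slice` with matrices `Bx`, `Bz`, `B`
#'   (`length(x)` rows by `length(z)` columns), the grids, and `d`.
#' @export
field_slice <- function(pair, x, z, n_nodes = 64) {
  stopifnot(inherits(pair, "magnet_pair"))
  g <- expand.grid(x = x, z = z)
  rho <- abs(g$x)
  h <- pair$d / 2
  m1 <- pair$magnets[[1]]; m2 <- pair$magnets[[2]]
  f1 <- magnet_field_offaxis(m1, rho, g$z, -h - m1$L, -h, n_nodes)
  f2 <- magnet_field_offaxis(m2, rho, g$z,  h,  h + m2$L, n_nodes)
  Bz <- f1$Bz + f2$Bz
  Brho <- f1$Brho + f2$Brho
  Bx <- Brho * sign(g$x)
  inside <- (rho <= m1$R & g$z >= -h - m1$L & g$z <= -h) |
            (rho <= m2$R & g$z >=  h & g$z <=  h + m2$L)
  if (any(inside)) {
    warning(sprintf("%d grid cells intersect a magnet volume; masked", sum(inside)))
    Bx[inside] <- NA_real_; Bz[inside] <- NA_real_
  }
  dim(Bx) <- dim(Bz) <- c(length(x), length(z))
  structure(list(x = x, z = z, Bx = Bx, Bz = Bz, B = sqrt(Bx^2 + Bz^2),
                 d = pair$d), class = "field_slice")
}

#' Dipole-limit diagnostic
#'
#' Far from the magnet the field follows the point-dipole law
#' `B = Br R^2 L / (2 z_c^3)` with `z_c` measured from the magnet center.
#' Returns the ratio of the exact on-axis field to this law; it tends to 1.
#'
#' @param magnet a [cyl_magnet()].
#' @param z_center distance from the magnet center, m (`> L/2`).
#' @return dimensionless ratio (vectorized).
#' @export
dipole_ratio <- function(magnet, z_center) {
  stopifnot(all(z_center > magnet$L / 2))
  B <- axial_field(magnet, z_center - magnet$L / 2)
  B * z_center^3 / (magnet$Br * magnet$R^2 * magnet$L / 2)
}

#' Plot an axial field profile
#' @param x a `field_profile`.
#' @param ... passed to [plot()].
#' @export
plot.field_profile <- function(x, ...) {
  plot(100 * x$z_m, 1000 * x$B_T, type = "l", xlab = "z (cm)",
       ylab = "B (mT)", ...)
  invisible(x)
}

#' Plot a field slice as a magnitude map with direction arrows
#'
#' Arrow lengths are logarithmically scaled with the local field magnitude.
#'
#' @param x a `field_slice`.
#' @param arrow_every subsampling stride for arrows.
#' @param ... passed to [graphics::image()].
#' @export
plot.field_slice <- function(x, arrow_every = 6, ...) {
  graphics::image(100 * x$z, 100 * x$x, t(log10(pmax(x$B, 1e-6))),
                  xlab = "z (cm)", ylab = "x (cm)", ...)
  ix <- seq(1, length(x$x), by = arrow_every)
  iz <- seq(1, length(x$z), by = arrow_every)
  for (i in ix) for (j in iz) {
    b <- x$B[i, j]
    if (!is.finite(b) || b <= 0) next
    len <- 0.4 * (log10(b) + 6) / 6
    ux <- x$Bz[i, j] / b; uy <- x$Bx[i, j] / b
    graphics::arrows(100 * x$z[j], 100 * x$x[i],
                     100 * x$z[j] + len * ux, 100 * x$x[i] + len * uy,
                     length = 0.02, col = "white")
  }
  invisible(x)
}
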