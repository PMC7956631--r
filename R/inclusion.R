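#' Geometry of a rigid cone-like membrane inclusion
#'
#' An anisotropic rigid protein embedded in one monolayer, with cone angle
#' varying with the azimuth as `theta(omega) = theta_bar + dtheta cos(2 omega)`,
#' core radius `r0`, and the membrane perturbation decay length `zeta`.
#' The model is stated for `r0 >= zeta`; smaller radii are allowed but
#' produce a warning when mapped to effective parameters.
#'
#' @param theta_bar mean cone angle (radians).
#' @param dtheta cone-angle anisotropy (radians).
#' @param r0 inclusion core radius (length).
#' @param zeta decay length of the monolayer perturbation (length, > 0).
#' @param kappa0 monolayer bending stiffness (energy, > 0).
#' @param C0 monolayer spontaneous curvature (1/length).
#' @return object of class `inclusion_geometry`.
#' @export
inclusion_geometry <- function(theta_bar, dtheta = 0, r0, zeta, kappa0, C0 = 0) {
  if (zeta <= 0) stop("zeta must be positive")
  if (kappa0 <= 0) stop("kappa0 must be positive")
  structure(list(theta_bar = theta_bar, dtheta = dtheta, r0 = r0,
                 zeta = zeta, kappa0 = kappa0, C0 = C0, L = 2 * pi * r0),
            class = "inclusion_geometry")
}

#' Effective nanodomain parameters of a rigid inclusion (closed form)
#'
#' Maps the inclusion geometry to the intrinsic curvatures and elastic
#' constants of the induced flexible nanodomain:
#' \deqn{H_m = \frac{\bar\theta}{r_0}\frac{r_0+\zeta}{r_0+2\zeta}
#'       + \frac{\zeta C_0}{r_0+2\zeta},\quad
#'       D_m = \frac{\Delta\theta}{r_0}\frac{r_0+\zeta}{r_0+2\zeta},}
#' \deqn{K_1 = \frac{3\pi}{4} r_0^2 \kappa_0 (r_0/\zeta + 2),\quad
#'       K_2 = -\frac{\pi}{2} r_0^2 \kappa_0 (r_0/\zeta + 2),}
#' so `K2/K1 = -2/3` for every geometry.
#'
#' @param geom an [inclusion_geometry()].
#' @return a [deviatoric_params()] object.
#' @export
effective_params <- function(geom) {
  if (geom$r0 < geom$zeta)
    warning("r0 < zeta: outside the stated validity range of the wall model")
  r0 <- geom$r0; z <- geom$zeta
  Hm <- (geom$theta_bar / r0) * (r0 + z) / (r0 + 2 * z) +
    z * geom$C0 / (r0 + 2 * z)
  Dm <- (geom$dtheta / r0) * (r0 + z) / (r0 + 2 * z)
  K1 <- 3 * pi / 4 * r0^2 * geom$kappa0 * (r0 / z + 2)
  K2 <- -pi / 2 * r0^2 * geom$kappa0 * (r0 / z + 2)
  deviatoric_params(K1 = K1, K2 = K2, Hm = Hm, Dm = Dm)
}

#' Monolayer-wall energy density around an inclusion, per unit circumference
#'
#' The elastic interaction of a bent lipid monolayer of curvature `C` with
#' a rigid wall tilted by `theta`:
#' `f~ = kappa0/(2 zeta) (theta - C r0)^2 + kappa0 (C0 - C)(theta - C r0)`.
#'
#' @param geom an [inclusion_geometry()].
#' @param C line curvature of the normal cross section.
#' @param theta wall tilt at that azimuth.
#' @return energy per unit length of the inclusion circumference.
#' @export
wall_density <- function(geom, C, theta) {
  u <- theta - C * geom$r0
  geom$kappa0 / (2 * geom$zeta) * u^2 + geom$kappa0 * (geom$C0 - C) * u
}

#' Effective nanodomain parameters by direct azimuthal quadrature
#'
#' Numerically integrates the wall energy density over the azimuth with
#' `theta(omega) = theta_bar + dtheta cos(2 omega)` and
#' `C(omega) = H + D cos(2 omega)` substituted, on a grid of `(H, D)`
#' values, and least-squares fits the resulting per-inclusion energy
#' `E(H, D) = L/(2 pi) * integral f~ domega * 2 pi = L <f~>` to the
#' quadratic single-element form (additive constant discarded). Serves as
#' the independent numerical route to [effective_params()].
#'
#' @param geom an [inclusion_geometry()].
#' @param H_grid,D_grid curvature grids for the fit (defaults: 5 points
#'   each around 0, spaced by `0.02/r0`).
#' @param n_omega azimuthal quadrature points (the integrand is a low-order
#'   trigonometric polynomial, so a modest uniform grid is exact to
#'   machine precision).
#' @return list with fitted `Hm`, `Dm`, `K1`, `K2`, the fit residual
#'   (RMS, relative to the energy scale), and the raw energy table.
#' @export
wall_energy_quadrature <- function(geom,
                                   H_grid = seq(-2, 2, length.out = 5) * 0.01 / geom$r0,
                                   D_grid = seq(-2, 2, length.out = 5) * 0.01 / geom$r0,
                                   n_omega = 512L) {
  om <- seq(0, 2 * pi, length.out = n_omega + 1L)[-(n_omega + 1L)]
  th <- geom$theta_bar + geom$dtheta * cos(2 * om)
  HD <- expand.grid(H = H_grid, D = D_grid)
  E <- vapply(seq_len(nrow(HD)), function(i) {
    C <- HD$H[i] + HD$D[i] * cos(2 * om)
    geom$L * mean(wall_density(geom, C, th))
  }, numeric(1))
  # quadratic basis in (H, D); no cross term arises for aligned frames
  X <- cbind(1, HD$H, HD$H^2, HD$D, HD$D^2)
  fit <- stats::lm.fit(X, E)
  cf <- fit$coefficients
  c2 <- cf[3]; c4 <- cf[5]                 # 2K1+K2 and -K2
  K2 <- -c4
  K1 <- (c2 + c4) / 2
  Hm <- -cf[2] / (2 * c2)
  Dm <- cf[4] / (2 * K2)
  resid <- sqrt(mean(fit$residuals^2)) / max(abs(E - mean(E)), 1e-300)
  list(Hm = unname(Hm), Dm = unname(Dm), K1 = unname(K1), K2 = unname(K2),
       residual = resid, table = cbind(HD, E = E))
}
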