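## Continuum curvature-energy terms evaluated on a surface_grid.
## Unit system: lengths in units of R0, curvatures in 1/R0, energies in
## units of the reference bending modulus (kc or kappa_B) unless stated.

#' Deviatoric (mismatch-tensor) elastic parameters
#'
#' Parameters of the single-element energy density
#' `w = (2K1+K2)(H-Hm)^2 - K2 (D^2 - 2 D Dm cos 2w + Dm^2)`, obtained from
#' the trace and determinant invariants of the curvature mismatch tensor.
#' The local stability of the minimum at `(Hm, Dm)` requires
#' `-K2 (2K1 + K2) > 0`; a violation triggers a warning, not an error.
#'
#' @param K1,K2 elastic constants (energy x length^2); `K1 > 0`.
#' @param Hm intrinsic mean curvature of the element (1/length).
#' @param Dm intrinsic curvature deviator (1/length).
#' @return object of class `deviatoric_params` with derived fields
#'   `xi = 4K1 + 2K2`, and the isotropic-limit map `kc = K1`, `kG = K2`,
#'   `C0 = (2K1+K2) Hm / K1`.
#' @export
deviatoric_params <- function(K1, K2, Hm = 0, Dm = 0) {
  if (K1 <= 0) stop("K1 must be positive")
  if (-K2 * (2 * K1 + K2) <= 0)
    warning("local stability condition -K2(2K1+K2) > 0 violated")
  structure(list(K1 = K1, K2 = K2, Hm = Hm, Dm = Dm,
                 xi = 4 * K1 + 2 * K2,
                 kc = K1, kG = K2, C0 = (2 * K1 + K2) * Hm / K1),
            class = "deviatoric_params")
}

#' Helfrich bending parameters
#' @param kc bending modulus (> 0), `kG` Gaussian modulus, `C0` spontaneous
#'   curvature.
#' @param kG,C0 see above.
#' @return object of class `helfrich_params`.
#' @export
helfrich_params <- function(kc = 1, kG = 0, C0 = 0) {
  if (kc <= 0) stop("kc must be positive")
  structure(list(kc = kc, kG = kG, C0 = C0), class = "helfrich_params")
}

#' Single-element deviatoric energy density
#'
#' `w = (2K1+K2)(H-Hm)^2 - K2 (D^2 - 2 D Dm cos(2 omega) + Dm^2)`, where
#' `omega` is the in-plane rotation between the element's principal frame
#' and the surface's.
#'
#' @param params [deviatoric_params()].
#' @param H,D local mean curvature and (signed) curvature deviator.
#' @param omega element orientation (radians).
#' @return energy per element (same units as K1 curvature^2).
#' @export
deviatoric_density <- function(params, H, D, omega = 0) {
  (2 * params$K1 + params$K2) * (H - params$Hm)^2 -
    params$K2 * (D^2 - 2 * D * params$Dm * cos(2 * omega) + params$Dm^2)
}

#' Orientation-minimized (aligned) deviatoric density for K2 = -K1
#'
#' With `K2 = -K1` the density minimized over the free in-plane orientation
#' omega equals `K1 (H-Hm)^2 + K1 (|D| - |Dm|)^2`. The unsigned-deviator
#' form is used because the element reorients freely: the signed form
#' `(D - Dm)^2` is recovered with `signed = TRUE` (principal frames locked,
#' omega = 0).
#'
#' @param params [deviatoric_params()] with `K2 = -K1`.
#' @param H,D local curvature invariants.
#' @param signed lock omega = 0 instead of minimizing over orientation.
#' @return energy density.
#' @export
deviatoric_density_aligned <- function(params, H, D, signed = FALSE) {
  if (abs(params$K2 + params$K1) > 1e-9 * params$K1)
    stop("aligned form assumes K2 = -K1")
  dev <- if (signed) (D - params$Dm)^2 else (abs(D) - abs(params$Dm))^2
  params$K1 * (H - params$Hm)^2 + params$K1 * dev
}

#' Helfrich bending energy density
#'
#' `wb = kc/2 (2H - C0)^2 + kG K`.
#'
#' @param params [helfrich_params()].
#' @param H mean curvature; `K` Gaussian curvature.
#' @param K see above.
#' @return energy per area.
#' @export
helfrich_density <- function(params, H, K = 0) {
  params$kc / 2 * (2 * H - params$C0)^2 + params$kG * K
}

#' Total Helfrich energy of a closed surface
#' @param grid a `surface_grid`.
#' @param params [helfrich_params()].
#' @param gaussian include the Gaussian term (constant 4 pi kG for closed
#'   sphere-topology shapes; reported for completeness, default off).
#' @return total bending energy.
#' @export
helfrich_total <- function(grid, params, gaussian = FALSE) {
  w <- params$kc / 2 * (2 * grid$H - params$C0)^2
  if (gaussian) w <- w + params$kG * grid$K
  sum(w * grid$dS)
}

#' Map isotropic deviatoric parameters to Helfrich parameters
#'
#' For `Dm = 0`: `kc = K1`, `kG = K2`, `C0 = (2 + K2/K1) Hm`.
#'
#' @param params [deviatoric_params()] with `Dm = 0`.
#' @return [helfrich_params()].
#' @export
isotropic_map <- function(params) {
  if (params$Dm != 0) stop("isotropic map requires Dm = 0")
  helfrich_params(kc = params$K1, kG = params$K2,
                  C0 = (2 + params$K2 / params$K1) * params$Hm)
}

#' Two-component membrane parameters
#'
#' Components A and B with bending rigidities `kappaA`, `kappaB` and
#' intrinsic curvatures `(HmA, DmA)`, `(HmB, DmB)`; the local rigidity and
#' intrinsic curvatures interpolate linearly in the local relative area
#' density `phi` of component A. `a0` is the area per nanodomain and `kT`
#' the thermal energy entering the mixing entropy (both in the reduced
#' units of the run: lengths in R0, energies in kappaB).
#'
#' @param kappaA,kappaB component bending rigidities (> 0).
#' @param HmA,HmB,DmA,DmB intrinsic curvatures (1/R0).
#' @param a0 area per nanodomain; `kT` thermal energy.
#' @param kT see above.
#' @return object of class `two_component_params`.
#' @export
two_component_params <- function(kappaA, kappaB, HmA = 0, HmB = 0,
                                 DmA = 0, DmB = 0, a0 = 1, kT = 0) {
  if (kappaA <= 0 || kappaB <= 0) stop("rigidities must be positive")
  if (a0 <= 0) stop("a0 must be positive")
  structure(list(kappaA = kappaA, kappaB = kappaB, HmA = HmA, HmB = HmB,
                 DmA = DmA, DmB = DmB, a0 = a0, kT = kT),
            class = "two_component_params")
}

## linear interpolations in phi
kc_of_phi <- function(p, phi) (p$kappaA - p$kappaB) * phi + p$kappaB
Hm_of_phi <- function(p, phi) (p$HmA - p$HmB) * phi + p$HmB
Dm_of_phi <- function(p, phi) (p$DmA - p$DmB) * phi + p$DmB

#' Tanh density profile of component A along the contour
#'
#' `phi(s) = (phi2 - phi1) (-tanh(chi (s - s0)) + 1)/2 + phi1`: two regions
#' with densities `phi2` (before `s0`) and `phi1` (after), with a border of
#' width `1/chi` at `s0`.
#'
#' @param s arc-length positions.
#' @param phi1,phi2 asymptotic densities in `[0, 1]`.
#' @param chi border sharpness (1/length); `s0` border position.
#' @param s0 see above.
#' @return density values in `[0, 1]`.
#' @export
phi_profile <- function(s, phi1, phi2, chi, s0) {
  (phi2 - phi1) * (-tanh(chi * (s - s0)) + 1) / 2 + phi1
}

#' Area-weighted average density over the membrane surface
#' @param grid a `surface_grid`.
#' @param phi per-point density.
#' @return scalar average (Eq.-style surface integral over S).
#' @export
phi_average <- function(grid, phi) sum(phi * grid$dS) / grid$S

## x log x with 0 log 0 := 0, phi clipped inside the logarithm only
.xlogx <- function(x) {
  eps <- 1e-12
  x * log(pmin(pmax(x, eps), 1 - eps))
}

#' Mixing-entropy free energy of a two-component membrane
#' @param grid a `surface_grid`.
#' @param phi local density of component A in `[0,1]`.
#' @param kT thermal energy; `a0` area per nanodomain.
#' @param a0 see above.
#' @return `Fmix = kT/a0 * integral(phi ln phi + (1-phi) ln(1-phi)) dS`, <= 0.
#' @export
mixing_energy <- function(grid, phi, kT, a0) {
  if (kT == 0) return(0)
  kT / a0 * sum((.xlogx(phi) + .xlogx(1 - phi)) * grid$dS)
}

#' Two-component deviatoric bending + mixing free energy
#'
#' `Fb = integral kc(phi) [ (H - Hm(phi))^2 + (|D| - |Dm(phi)|)^2 ] dS`
#' (the orientation-minimized aligned form; set `signed_deviator = TRUE`
#' for the frame-locked `(D - Dm)^2` variant) plus the mixing entropy,
#' which can be toggled off.
#'
#' @param grid a `surface_grid`.
#' @param phi per-point density of component A in `[0, 1]`.
#' @param params [two_component_params()].
#' @param include_mixing include `Fmix` (default TRUE).
#' @param signed_deviator use the signed `(D - Dm)^2` mismatch.
#' @return list with `Fb`, `Fmix`, `F`.
#' @export
two_component_energy <- function(grid, phi, params, include_mixing = TRUE,
                                 signed_deviator = FALSE) {
  if (any(phi < -1e-9 | phi > 1 + 1e-9)) stop("phi outside [0, 1]")
  phi <- pmin(pmax(phi, 0), 1)
  kcp <- kc_of_phi(params, phi)
  Hm <- Hm_of_phi(params, phi)
  Dm <- Dm_of_phi(params, phi)
  dev <- if (signed_deviator) (grid$D - Dm)^2 else (abs(grid$D) - abs(Dm))^2
  Fb <- sum(kcp * ((grid$H - Hm)^2 + dev) * grid$dS)
  Fmix <- if (include_mixing) mixing_energy(grid, phi, params$kT, params$a0) else 0
  list(Fb = Fb, Fmix = Fmix, F = Fb + Fmix)
}

#' BAR-domain parameters
#' @param KpL0 product of flexural rigidity and domain length (`Kp L0`,
#'   energy x length); the per-domain density is `wbar = KpL0/2 (C - Cp)^2`.
#' @param Cp intrinsic curvature of the BAR domain (1/length).
#' @return object of class `bar_params`.
#' @export
bar_params <- function(KpL0, Cp) {
  if (KpL0 <= 0) stop("KpL0 must be positive")
  structure(list(KpL0 = KpL0, Cp = Cp), class = "bar_params")
}

#' Energy-minimizing orientation of a BAR domain
#'
#' From Euler's relation `C(omega) = H + D cos(2 omega)`, the orientation
#' minimizing `(C - Cp)^2` satisfies `cos(2 omega) = (Cp - H)/D` when that
#' ratio lies in `[-1, 1]`; otherwise the boundary angle (0 or pi/2) with
#' the lower energy is returned. `D = 0` leaves omega undefined (all
#' orientations see the same curvature); 0 is returned with a flag.
#'
#' @param H,D local mean curvature and signed deviator.
#' @param Cp BAR intrinsic curvature.
#' @return list with `omega` (radians), `C` (curvature seen), and
#'   `degenerate` flag (TRUE where D = 0).
#' @export
bar_orientation <- function(H, D, Cp) {
  n <- max(length(H), length(D))
  H <- rep_len(H, n); D <- rep_len(D, n)
  ratio <- ifelse(D == 0, 0, (Cp - H) / D)
  omega <- numeric(n)
  inside <- abs(ratio) <= 1 & D != 0
  omega[inside] <- acos(ratio[inside]) / 2
  out <- !inside & D != 0
  # boundary: omega = 0 sees C = H + D, omega = pi/2 sees C = H - D
  omega[out] <- ifelse((H[out] + D[out] - Cp)^2 <= (H[out] - D[out] - Cp)^2,
                       0, pi / 2)
  Cseen <- H + D * cos(2 * omega)
  list(omega = omega, C = Cseen, degenerate = D == 0)
}

#' Total energy of a membrane with attached BAR domains
#'
#' `F = Fiso + Fbar + Fmix` with
#' `Fbar = integral phi KpL0/2 (C(omega*) - Cp)^2 dS`, the orientation
#' `omega*` set pointwise by [bar_orientation()].
#'
#' @param grid a `surface_grid`.
#' @param phi per-point BAR area density in `[0, 1]`.
#' @param bar [bar_params()].
#' @param helfrich [helfrich_params()] of the bare membrane.
#' @param kT,a0 thermal energy and area per domain for the mixing term.
#' @param include_mixing include `Fmix`.
#' @return list with `Fiso`, `Fbar`, `Fmix`, `F`, and `omega` per point.
#' @export
bar_energy <- function(grid, phi, bar, helfrich, kT = 0, a0 = 1,
                       include_mixing = TRUE) {
  if (any(phi < -1e-9 | phi > 1 + 1e-9)) stop("phi outside [0, 1]")
  phi <- pmin(pmax(phi, 0), 1)
  ori <- bar_orientation(grid$H, grid$D, bar$Cp)
  Fbar <- sum(phi * bar$KpL0 / 2 * (ori$C - bar$Cp)^2 * grid$dS)
  Fiso <- helfrich_total(grid, helfrich)
  Fmix <- if (include_mixing) mixing_energy(grid, phi, kT, a0) else 0
  list(Fiso = Fiso, Fbar = Fbar, Fmix = Fmix, F = Fiso + Fbar + Fmix,
       omega = ori$omega)
}

#' Membrane-skeleton shear parameters
#'
#' The reference (unsheared) skeleton is a shape of equal area, by default
#' the sphere of radius `R0`. Material points are mapped by equal
#' area-from-pole; local lateral incompressibility of the skeleton gives
#' `lambda_phi = r(s)/r_ref(s_ref)` and `lambda_m = 1/lambda_phi`.
#'
#' @param mu skeleton area shear modulus (energy/area).
#' @param reference optional `surface_grid` of the reference shape (equal
#'   area); `NULL` means the equal-area sphere.
#' @return object of class `shear_params`.
#' @export
shear_params <- function(mu, reference = NULL) {
  if (mu < 0) stop("mu must be non-negative")
  structure(list(mu = mu, reference = reference), class = "shear_params")
}

#' Meridional extension ratio field by the equal-area-from-pole map
#' @param grid deformed `surface_grid`.
#' @param params [shear_params()].
#' @return per-point `lambda_m` (poles set to the adjacent interior value).
#' @export
shear_extension <- function(grid, params) {
  Acum <- .cumtrapz(2 * pi * grid$r, grid$h)   # area from north pole
  Acum <- pmin(Acum, grid$S)
  if (is.null(params$reference)) {
    R0 <- sqrt(grid$S / (4 * pi))
    # sphere: A(s_ref) = 2 pi R0^2 (1 - cos(s_ref/R0)); r_ref = R0 sin(s_ref/R0)
    cosu <- 1 - Acum / (2 * pi * R0^2)
    r_ref <- R0 * sqrt(pmax(1 - cosu^2, 0))
  } else {
    ref <- params$reference
    if (abs(ref$S - grid$S) > 1e-6 * grid$S)
      stop("reference shape must have equal area")
    Aref <- .cumtrapz(2 * pi * ref$r, ref$h)
    r_ref <- stats::approx(Aref, ref$r, xout = Acum, rule = 2)$y
  }
  lam_phi <- grid$r / pmax(r_ref, 1e-12)
  lam_m <- 1 / pmax(lam_phi, 1e-12)
  # both radii vanish at the poles (0/0); the quotient is unreliable
  # wherever either radius is tiny, so fill from the nearest interior
  # point where it is well conditioned
  rmax <- max(grid$r)
  good <- which(grid$r > 1e-2 * rmax & r_ref > 1e-2 * rmax)
  if (length(good) >= 2) {
    lam_m[seq_len(good[1] - 1L)] <- lam_m[good[1]]
    lg <- good[length(good)]
    if (lg < grid$n) lam_m[(lg + 1L):grid$n] <- lam_m[lg]
  }
  lam_m
}

#' Membrane-skeleton shear energy
#'
#' `Fshear = mu/2 * integral (lambda_m^2 + lambda_m^-2 - 2) dS >= 0`,
#' zero iff the deformed shape matches the reference.
#'
#' @param grid deformed `surface_grid`.
#' @param params [shear_params()].
#' @return shear energy.
#' @export
shear_energy <- function(grid, params) {
  lam <- shear_extension(grid, params)
  if (any(lam <= 0)) stop("lambda_m must be positive")
  params$mu / 2 * sum((lam^2 + lam^-2 - 2) * grid$dS)
}

#' Non-local (area-difference) bending parameters
#'
#' @param kn non-local bending rigidity (energy).
#' @param H0 effective spontaneous mean curvature (1/length). Use
#'   [ds0_to_h0()] to convert a normalized optimal area difference.
#' @return object of class `nonlocal_params`.
#' @export
nonlocal_params <- function(kn, H0) {
  structure(list(kn = kn, H0 = H0), class = "nonlocal_params")
}

#' Convert normalized optimal area difference to spontaneous mean curvature
#'
#' In reduced units (lengths in R0) the normalized effective spontaneous
#' mean curvature equals the normalized optimal monolayer area difference:
#' `h0 = R0 H0 = Ds0 = DeltaS0 / (8 pi delta R0)`.
#'
#' @param Ds0 normalized optimal area difference (dimensionless).
#' @param R0 reference radius (default 1, reduced units).
#' @return `H0` in 1/length.
#' @export
ds0_to_h0 <- function(Ds0, R0 = 1) Ds0 / R0

#' Area-averaged mean curvature
#' @param grid a `surface_grid`.
#' @return `<H> = (1/S) integral H dS`.
#' @export
mean_curvature_average <- function(grid) sum(grid$H * grid$dS) / grid$S

#' Local + non-local bending energy
#'
#' `Fh = kc/2 integral (2H)^2 dS + kn S (<H> - H0)^2`.
#'
#' @param grid a `surface_grid`.
#' @param params [nonlocal_params()].
#' @param kc local bending modulus.
#' @return list with `Flocal`, `Fnl`, `F`, and `<H>`.
#' @export
nonlocal_bending <- function(grid, params, kc = 1) {
  Hbar <- mean_curvature_average(grid)
  Flocal <- kc / 2 * sum((2 * grid$H)^2 * grid$dS)
  Fnl <- params$kn * grid$S * (Hbar - params$H0)^2
  list(Flocal = Flocal, Fnl = Fnl, F = Flocal + Fnl, H_avg = Hbar)
}
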