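test_that("deviatoric density vanishes for a perfectly fitting element", {
  p <- deviatoric_params(K1 = 2, K2 = -1.5, Hm = 0.8, Dm = 0.5)
  expect_equal(deviatoric_density(p, H = 0.8, D = 0.5, omega = 0), 0)
  # isotropic element: no omega dependence
  pi0 <- deviatoric_params(K1 = 2, K2 = -1.5, Hm = 0.8, Dm = 0)
  om <- seq(0, pi, length.out = 11)
  w <- deviatoric_density(pi0, H = 0.3, D = 0.7, omega = om)
  expect_equal(max(w) - min(w), 0, tolerance = 1e-14)
  # orientation minimum at omega = 0 when K2 < 0 and D*Dm > 0
  p2 <- deviatoric_params(K1 = 1, K2 = -0.8, Hm = 0, Dm = 0.6)
  scan <- deviatoric_density(p2, H = 0.1, D = 0.4,
                             omega = seq(0, pi, length.out = 2001))
  expect_equal(which.min(scan), 1L)
})

test_that("aligned form equals the omega-minimized density for K2 = -K1", {
  set.seed(42)
  for (k in 1:200) {
    K1 <- runif(1, 0.5, 3)
    p <- deviatoric_params(K1 = K1, K2 = -K1, Hm = rnorm(1), Dm = rnorm(1))
    H <- rnorm(1); D <- rnorm(1)
    expect_equal(deviatoric_density_aligned(p, H, D),
                 omega_scan_min(p, H, D), tolerance = 1e-9)
  }
  p <- deviatoric_params(1, -1, Hm = 0.5, Dm = 0)
  expect_equal(deviatoric_density_aligned(p, 0.5, 0), 0)
  expect_error(deviatoric_density_aligned(deviatoric_params(1, -0.5), 1, 1),
               "K2")
})

test_that("global minimum of the aligned density sits at (Hm, Dm)", {
  p <- deviatoric_params(K1 = 1.5, K2 = -1.5, Hm = 0.7, Dm = 0.4)
  Hg <- seq(-2, 2, length.out = 81); Dg <- seq(-2, 2, length.out = 81)
  w <- outer(Hg, Dg, function(H, D) deviatoric_density_aligned(p, H, D))
  ij <- which(w == min(w), arr.ind = TRUE)
  expect_true(any(abs(Hg[ij[, 1]] - p$Hm) < 0.03))
  expect_true(any(abs(abs(Dg[ij[, 2]]) - p$Dm) < 0.03))
})

test_that("Helfrich density and totals match analytic sphere results", {
  hp <- helfrich_params(kc = 2, kG = 0, C0 = 0)
  expect_equal(helfrich_density(hp, H = 0.5, K = 0.25), 2 / 2 * 1)
  expect_equal(helfrich_density(helfrich_params(1, 0, C0 = 1), H = 0.5), 0)
  g <- sphere_grid()
  expect_equal(helfrich_total(g, hp), 8 * pi * 2, tolerance = 1e-8)
  # radius independence: total on a scaled sphere is unchanged
  g3 <- integrate_profile(shape_profile(rep(0, 10), Ls = 3 * pi))
  expect_equal(helfrich_total(g3, hp), 8 * pi * 2, tolerance = 1e-8)
  # with the Gaussian term: 8 pi kc + 4 pi kG
  hpg <- helfrich_params(kc = 1, kG = -0.5, C0 = 0)
  expect_equal(helfrich_total(g, hpg, gaussian = TRUE),
               8 * pi - 2 * pi, tolerance = 1e-6)
})

test_that("equilibrium curvature of the Helfrich density is kc C0/(2kc+kG)", {
  hp <- helfrich_params(kc = 1.3, kG = -0.9, C0 = 1.7)
  f <- function(C) helfrich_density(hp, H = C, K = C^2)  # sphere: C1=C2=C
  Heq <- stats::optimize(f, c(-5, 5), tol = 1e-10)$minimum
  expect_equal(Heq, hp$kc * hp$C0 / (2 * hp$kc + hp$kG), tolerance = 1e-6)
})

test_that("isotropic map reproduces the Helfrich parameters", {
  p <- deviatoric_params(K1 = 1, K2 = -1, Hm = 2, Dm = 0)
  hp <- isotropic_map(p)
  expect_equal(hp$C0, 2)               # C0 = Hm = 1/Rm for K2 = -K1
  expect_equal(hp$kc, 1); expect_equal(hp$kG, -1)
  # K2 = 0 sits on the stability boundary and triggers the warning
  expect_equal(suppressWarnings(
    isotropic_map(deviatoric_params(1, 0, Hm = 2))$C0), 4)
  expect_equal(isotropic_map(deviatoric_params(1, -0.5, Hm = 2))$C0, 3)
  expect_error(isotropic_map(deviatoric_params(1, -1, Hm = 1, Dm = 1)),
               "Dm")
})

test_that("two-component energy has the correct endpoints and mixing term", {
  g <- sphere_grid()
  p <- two_component_params(kappaA = 2, kappaB = 1, HmA = 1.5, HmB = 0,
                            DmA = 0.5, DmB = 0, a0 = 0.01, kT = 0.2)
  # phi = 1: pure A
  eA <- two_component_energy(g, rep(1, g$n), p)
  wA <- 2 * ((g$H - 1.5)^2 + (abs(g$D) - 0.5)^2)
  expect_equal(eA$Fb, sum(wA * g$dS), tolerance = 1e-12)
  expect_equal(eA$Fmix, 0)             # x ln x -> 0 at the endpoints
  e0 <- two_component_energy(g, rep(0, g$n), p)
  expect_equal(e0$Fmix, 0)
  # phi = 1/2 uniform: closed-form mixing entropy
  eh <- two_component_energy(g, rep(0.5, g$n), p)
  expect_equal(eh$Fmix, -0.2 / 0.01 * g$S * log(2), tolerance = 1e-10)
  expect_lte(eh$Fmix, 0)
  expect_equal(eh$F, eh$Fb + eh$Fmix)
  # mixing toggle
  expect_equal(two_component_energy(g, rep(0.5, g$n), p,
                                    include_mixing = FALSE)$Fmix, 0)
  expect_error(two_component_energy(g, rep(1.2, g$n), p), "phi")
})

test_that("tanh density profile and its surface average behave", {
  g <- sphere_grid()
  phi <- phi_profile(g$s, phi1 = 0.1, phi2 = 0.9, chi = 50, s0 = g$Ls / 2)
  expect_true(all(phi >= 0.1 - 1e-9 & phi <= 0.9 + 1e-9))
  expect_equal(phi[1], 0.9, tolerance = 1e-6)       # phi2 before s0
  expect_equal(phi[g$n], 0.1, tolerance = 1e-6)     # phi1 after
  expect_equal(phi_average(g, rep(0.3, g$n)), 0.3, tolerance = 1e-12)
})

test_that("BAR orientation follows Euler's relation", {
  # Cp = H: the domain sits at 45 degrees
  o <- bar_orientation(H = 1, D = 0.5, Cp = 1)
  expect_equal(o$omega, pi / 4)
  # tube of radius Rp with Cp = 1/Rp: signed convention gives
  # H = 1/(2Rp), D = -1/(2Rp); cos 2w = -1 -> perpendicular to the axis
  Rp <- 0.4
  o2 <- bar_orientation(H = 1 / (2 * Rp), D = -1 / (2 * Rp), Cp = 1 / Rp)
  expect_equal(o2$omega, pi / 2)
  expect_equal(o2$C, 1 / Rp, tolerance = 1e-12)
  # stretched tube thinner than 1/Cp: tilt toward the axis
  Rp2 <- 0.25
  o3 <- bar_orientation(H = 1 / (2 * Rp2), D = -1 / (2 * Rp2), Cp = 1 / 0.4)
  expect_lt(o3$omega, pi / 2)
  expect_gt(o3$omega, 0)
  # out-of-range ratio falls back to the better boundary angle
  o4 <- bar_orientation(H = 0, D = 0.1, Cp = 5)
  expect_equal(o4$omega, 0)            # C = H + D closest to Cp
  o5 <- bar_orientation(H = 0, D = -0.1, Cp = 5)
  expect_equal(o5$omega, pi / 2)
  # degenerate D = 0
  o6 <- bar_orientation(H = 1, D = 0, Cp = 2)
  expect_true(o6$degenerate)
  expect_equal(o6$omega, 0)
})

test_that("BAR energy vanishes when the seen curvature matches Cp", {
  g <- sphere_grid()                       # H = 1, D = 0 -> C(w) = 1 always
  bp <- bar_params(KpL0 = 2, Cp = 1)
  e <- bar_energy(g, rep(0.5, g$n), bp, helfrich_params(1))
  expect_equal(e$Fbar, 0, tolerance = 1e-8)
  expect_equal(e$F, e$Fiso + e$Fbar + e$Fmix)
  # phi = 0 kills the BAR term
  e0 <- bar_energy(g, rep(0, g$n), bar_params(2, 3), helfrich_params(1))
  expect_equal(e0$Fbar, 0)
  expect_equal(e0$Fmix, 0)
  expect_gte(bar_energy(g, rep(0.5, g$n), bar_params(2, 3),
                        helfrich_params(1))$Fbar, 0)
})

test_that("shear energy is zero at the reference and symmetric in lambda", {
  g <- sphere_grid()
  sp <- shear_params(mu = 2)
  expect_lt(shear_energy(g, sp) / (sp$mu * g$S), 1e-5)
  lam <- shear_extension(g, sp)
  expect_lt(max(abs(lam - 1)), 0.02)        # pole-adjacent conditioning
  expect_lt(stats::median(abs(lam - 1)), 1e-6)
  # uniform lambda = 2 patch: integrand mu/2 (4 + 1/4 - 2) = 9 mu / 8
  expect_equal(2 / 2 * (4 + 1 / 4 - 2), 9 * 2 / 8)
  # lambda <-> 1/lambda symmetry of the integrand
  f <- function(l) (l^2 + l^-2 - 2)
  expect_equal(f(1.7), f(1 / 1.7))
  # a deformed (spheroid) shape has positive shear energy
  gd <- integrate_profile(spheroid_profile(1.6), n_grid = 1500)
  expect_gt(shear_energy(gd, sp), 0)
})

test_that("non-local bending penalizes deviation of the average curvature", {
  g <- sphere_grid()
  expect_equal(mean_curvature_average(g), 1, tolerance = 1e-9)
  nl <- nonlocal_params(kn = 8, H0 = 1)
  e <- nonlocal_bending(g, nl, kc = 1)
  expect_equal(e$Fnl, 0, tolerance = 1e-10)
  expect_equal(e$Flocal, 8 * pi, tolerance = 1e-6)   # kc/2 (2H)^2 on sphere
  nl2 <- nonlocal_params(kn = 8, H0 = ds0_to_h0(1.5))
  e2 <- nonlocal_bending(g, nl2, kc = 1)
  expect_equal(e2$Fnl, 8 * g$S * (1 - 1.5)^2, tolerance = 1e-6)
})

test_that("total energies are invariant under vertical translation", {
  # z enters no energy term; shifting the profile height changes nothing
  g <- integrate_profile(spheroid_profile(1.4), n_grid = 800)
  g2 <- g; g2$z <- g$z + 5
  hp <- helfrich_params(1, 0, 0.5)
  expect_equal(helfrich_total(g2, hp), helfrich_total(g, hp))
  p <- two_component_params(1, 1, HmA = 2, a0 = 0.01, kT = 0.1)
  phi <- rep(0.4, g$n)
  expect_equal(two_component_energy(g2, phi, p)$F,
               two_component_energy(g, phi, p)$F)
})
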