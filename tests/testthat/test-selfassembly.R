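test_that("monomer energy and the aggregated/dispersed difference agree", {
  sys <- aggregation_system(rho = 0.05, xi = 2, a0 = 1, H0 = 0, r = 1 / 3,
                            R0 = 100, w = 1, kT = 1)
  expect_equal(monomer_energy(sys, 0), 0)
  expect_equal(monomer_energy(sys, 3), 2 / 2 * 9 * 1)
  # delta f computed directly vs via the closed form
  direct <- monomer_energy(sys, 1 / sys$r) - monomer_energy(sys, 1 / sys$R0)
  form <- with(sys, xi * a0 / (2 * r) * (1 / r - 2 * H0) -
                 xi * a0 / (2 * R0) * (1 / R0 - 2 * H0))
  expect_equal(delta_f_isotropic(sys), direct, tolerance = 1e-12)
  expect_equal(delta_f_isotropic(sys), form, tolerance = 1e-12)
})

test_that("limit form of delta f: sign set by c0 r, exact form converges", {
  mk <- function(r, R0, H0) aggregation_system(0.05, xi = 4, a0 = 0.1,
                                               H0 = H0, r = r, R0 = R0,
                                               w = 0.5, kT = 1)
  # c0 = 2 H0; c0 r = 1 makes the limit form vanish
  expect_equal(delta_f_isotropic(mk(1, 1e6, 0.5), limit = TRUE), 0,
               tolerance = 1e-12)
  expect_lt(delta_f_isotropic(mk(1, 1e6, 0.7), limit = TRUE), 0)  # c0 r > 1
  expect_gt(delta_f_isotropic(mk(1, 1e6, 0.3), limit = TRUE), 0)  # c0 r < 1
  # R0/r = 1e6: exact and limit forms agree to 1e-5 relative
  s <- mk(1, 1e6, 0.3)
  expect_equal(delta_f_isotropic(s), delta_f_isotropic(s, limit = TRUE),
               tolerance = 1e-5)
  agg <- aggregate_helfrich(s)
  expect_equal(agg$kc, 1); expect_equal(agg$c0, 0.6)
})

test_that("anisotropic delta f uses the Bessel orientational average", {
  # Dm = 0: the log term drops
  expect_equal(delta_f_anisotropic(xi = 2, a0 = 0.5, H = 1.5, Hm = 1,
                                   D = 2, Dm = 0, kT = 1),
               2 * 0.5 * 1.5 * 0.5)
  # monotone decreasing in Dm at fixed D > 0
  vals <- vapply(c(0, 0.5, 1, 2, 4), function(Dm)
    delta_f_anisotropic(2, 0.5, 1.5, 1, 2, Dm, 1), numeric(1))
  expect_true(all(diff(vals) < 0))
  # small-argument expansion: ln I0(x) ~ x^2/4
  x <- 1e-3
  lhs <- delta_f_anisotropic(1, 1, 0, 0, x, 1, 1)
  expect_lt(abs(lhs + x^2 / 4), 1e-10)
  # numerically stable at large argument
  expect_true(is.finite(delta_f_anisotropic(10, 1, 1, 0, 50, 50, 1)))
})

test_that("equilibrium distribution conserves nanodomains against brute force", {
  set.seed(99)
  for (k in 1:100) {
    sys <- aggregation_system(rho = runif(1, 1e-4, 0.5),
                              xi = runif(1, 0.5, 6), a0 = runif(1, 0.05, 1),
                              H0 = rnorm(1, 0, 0.5), r = runif(1, 0.2, 1),
                              R0 = runif(1, 50, 500), w = runif(1, 0, 2),
                              kT = runif(1, 0.5, 2))
    d <- equilibrium_distribution(sys)
    expect_lt(abs(d$residual), 1e-10)
    # brute-force truncated sum reproduces the closed-form tail
    imax <- min(1e6, ceiling(log(1e-18) / log(max(d$q, 1e-12))))
    i <- seq_len(max(imax, 10))
    expect_equal(d$x1 + sum(i * d$q^i), sys$rho, tolerance = 1e-9)
    expect_true(all(d$xi >= 0))
  }
})

test_that("sub-critical distributions decrease and the Eq-33 form holds", {
  sys <- aggregation_system(rho = 0.01, xi = 4, a0 = 0.1, H0 = 0.2,
                            r = 0.5, R0 = 100, w = 0.5, kT = 1)
  d <- equilibrium_distribution(sys)
  expect_false(d$supersaturated)
  expect_gt(d$xi[1], d$xi[2]); expect_gt(d$xi[2], d$xi[3])
  # x_i = i x1~^i exp(i (fsp + w - fc)/kT): check via q = x1~/x_c~
  expect_equal(d$q, d$x1 / d$x_crit, tolerance = 1e-10)
  expect_equal(d$xi[3], 3 * d$q^3, tolerance = 1e-12)
  # neutral case fsp + w = fc: x_i = i x1^i
  expect_equal(3 * 0.1^3, 0.003)        # printed reference for x1 = 0.1
})

test_that("critical concentration forms are consistent", {
  sys <- aggregation_system(rho = 0.05, xi = 4, a0 = 0.1, H0 = 0.3,
                            r = 1, R0 = 1e6, w = 0.5, kT = 1)
  # w = delta f makes the critical concentration unity
  sysw <- sys; sysw$w <- function(i) rep(delta_f_isotropic(sys), length(i))
  sysw$w_const <- delta_f_isotropic(sys)
  expect_equal(critical_concentration(sysw), 1, tolerance = 1e-12)
  # delta f < w gives x_c < 1
  sys2 <- aggregation_system(0.05, 4, 0.1, H0 = 0.7, r = 1, R0 = 1e6,
                             w = 0.5, kT = 1)   # delta f < 0 < w
  expect_lt(critical_concentration(sys2), 1)
  # exact vs limit form at R0/r = 1e6
  expect_equal(critical_concentration(sys), critical_concentration(sys, TRUE),
               tolerance = 1e-6)
})

test_that("supersaturation signal coincides with monomer density reaching x_c", {
  base <- function(rho) aggregation_system(rho, xi = 4, a0 = 0.1, H0 = 0.45,
                                           r = 1, R0 = 1e3, w = 0.4, kT = 1)
  rhos <- seq(0.005, 0.6, by = 0.005)
  flags <- ratio <- numeric(length(rhos))
  for (i in seq_along(rhos)) {
    d <- equilibrium_distribution(base(rhos[i]))
    flags[i] <- d$supersaturated
    ratio[i] <- d$x1 / d$x_crit
  }
  # the flag switches on once and stays on as density grows
  expect_true(all(diff(flags) >= 0))
  if (any(flags == 1) && any(flags == 0)) {
    i0 <- max(which(flags == 0)); i1 <- min(which(flags == 1))
    # at the switch the monomer density is near the critical concentration
    expect_gt(ratio[i1], 0.6)
    expect_lt(ratio[i0], 1)
  }
  # approaching the boundary from below, mass in large aggregates grows
  mass_large <- vapply(c(0.05, 0.15, 0.3), function(r) {
    d <- equilibrium_distribution(base(r))
    sum(d$xi[10:100])
  }, numeric(1))
  expect_true(all(diff(mass_large) > 0))
})

test_that("phase boundary scan reports the favorability flag", {
  sys <- aggregation_system(0.05, xi = 4, a0 = 0.1, H0 = 0.45, r = 1,
                            R0 = 1e3, w = 0.4, kT = 1)
  tab <- phase_boundary_scan(sys, rho_grid = c(0.01, 0.4),
                             kT_grid = c(0.5, 1.5))
  expect_equal(nrow(tab), 4L)
  expect_true(all(c("x1", "x_crit", "favorable") %in% names(tab)))
  # growth is favorable at high density / low temperature first
  expect_gte(tab$favorable[tab$rho == 0.4 & tab$kT == 0.5],
             tab$favorable[tab$rho == 0.01 & tab$kT == 1.5])
})
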