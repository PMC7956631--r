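test_that("tangent angle obeys its boundary conditions and closed forms", {
  p <- shape_profile(rep(0, 10), Ls = pi)
  expect_equal(theta_of_s(p, pi / 2), pi / 2)
  expect_equal(theta_of_s(p, 0), 0)
  expect_equal(theta_of_s(p, pi), pi)
  p1 <- shape_profile(c(0.3, rep(0, 9)), Ls = pi)
  expect_equal(theta_of_s(p1, pi / 2), pi / 2 + 0.3)
  # the south-pole value is exact for any amplitudes
  set.seed(1)
  for (k in 1:5) {
    pr <- shape_profile(rnorm(8, 0, 0.5), Ls = runif(1, 1, 5))
    expect_equal(theta_of_s(pr, pr$Ls), pi, tolerance = 1e-14)
  }
  expect_error(theta_of_s(p, -0.1), "outside")
  expect_error(theta_of_s(p, pi + 0.1), "outside")
  expect_error(shape_profile(numeric(0)), "mode")
  expect_error(shape_profile(0, Ls = -1), "positive")
})

test_that("the zero-amplitude profile integrates to the unit sphere", {
  g <- sphere_grid()
  expect_equal(g$S, 4 * pi, tolerance = 1e-10)
  expect_equal(g$V, 4 * pi / 3, tolerance = 1e-9)
  expect_equal(g$v, 1, tolerance = 1e-9)
  expect_equal(max(abs(g$r - sin(g$s))), 0, tolerance = 1e-10)
  # curvatures: C1 = C2 = 1 everywhere, H = 1, D = 0, K = 1
  k <- 500
  cv <- curvatures_at(g, k)
  expect_equal(unname(cv), c(1, 1, 1, 0, 1), tolerance = 1e-6)
  # pole regularization: C2 -> C1
  expect_equal(g$C2[1], g$C1[1])
})

test_that("spheroid grids match closed-form area, volume, reduced volume", {
  for (cax in c(0.5, 2, 3.5)) {
    g <- integrate_profile(spheroid_profile(cax, n_modes = 40), n_grid = 2000)
    cf <- spheroid_closed_form(1, cax)
    expect_equal(g$v, cf$v, tolerance = 2e-6)
  }
})

test_that("quadrature converges and v is scale invariant", {
  p <- spheroid_profile(1.8, n_modes = 30)
  g1 <- integrate_profile(p, n_grid = 1000)
  g2 <- integrate_profile(p, n_grid = 2000)
  expect_lt(abs(g2$S - g1$S) / g1$S, 1e-8)
  expect_lt(abs(g2$V - g1$V) / g1$V, 1e-8)
  expect_lt(abs(g2$v - g1$v), 1e-8)
  # uniform rescaling of all lengths leaves v unchanged
  p3 <- shape_profile(p$a, Ls = 3 * p$Ls)
  g3 <- integrate_profile(p3, n_grid = 1000)
  expect_equal(g3$v, g1$v, tolerance = 1e-10)
  expect_equal(reduced_volume(g3), g3$v)
})

test_that("Gauss-Bonnet holds on closed profiles and v <= 1", {
  shapes <- list(sphere_grid(),
                 integrate_profile(spheroid_profile(0.6), n_grid = 1500),
                 integrate_profile(spheroid_profile(2.5), n_grid = 1500),
                 integrate_profile(seed_profile("stomatocyte"),
                                   n_grid = 1500, r_tol = 0.05))
  for (g in shapes) {
    expect_equal(sum(g$K * g$dS) / (4 * pi), 1, tolerance = 1e-5)
    expect_lte(g$v, 1 + 1e-8)
  }
  # equality only at the sphere
  expect_lt(shapes[[2]]$v, 1)
  expect_lt(shapes[[4]]$v, 1)
})

test_that("pole limit C2 - C1 vanishes on an analytic spheroid", {
  g <- integrate_profile(spheroid_profile(1.5, n_modes = 40), n_grid = 4000)
  # series expansion at the pole: both principal curvatures tend to c/a^2
  d <- abs(g$C2[2:6] - g$C1[2:6])
  expect_lt(max(d), 0.02)
  # the gap shrinks approaching the pole relative to mid-latitudes
  expect_lt(d[1], abs(g$C2[200] - g$C1[200]) + 0.01)
})

test_that("invalid and degenerate profiles are rejected", {
  # a profile driven far negative in radius
  bad <- shape_profile(c(3, rep(0, 5)), Ls = pi)
  expect_error(integrate_profile(bad), "negative radius")
  expect_error(integrate_profile(shape_profile(rep(0, 5)), n_grid = 32),
               "n_grid")
})

test_that("branch seed profiles land near their nominal reduced volumes", {
  for (v in c(0.6, 0.75, 0.9)) {
    go <- integrate_profile(seed_profile("oblate", v = v))
    gp <- integrate_profile(seed_profile("prolate", v = v))
    expect_equal(go$v, v, tolerance = 5e-3)
    expect_equal(gp$v, v, tolerance = 5e-3)
  }
  gs <- integrate_profile(seed_profile("stomatocyte"), r_tol = 0.05)
  expect_gt(max(gs$theta), pi * 1.3)   # genuinely invaginated
  expect_lt(abs(gs$closure) / gs$Ls, 1e-3)
})

test_that("profile CSV and revolved mesh writers round-trip", {
  g <- integrate_profile(spheroid_profile(1.5), n_grid = 500)
  tf <- tempfile(fileext = ".csv")
  write_profile_csv(g, tf, phi = rep(0.5, g$n))
  df <- read_profile_csv(tf)
  expect_equal(df$r, g$r, tolerance = 1e-12)
  expect_equal(df$H, g$H, tolerance = 1e-12)
  expect_equal(df$phi, rep(0.5, g$n))
  m <- revolve_mesh(g, n_phi = 16, n_s = 30)
  # closed triangulation of sphere topology
  ne <- nrow(mesh_edges(m$triangles))
  expect_equal(nrow(m$vertices) - ne + nrow(m$triangles), 2L)
})
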