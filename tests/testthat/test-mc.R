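test_that("icosphere construction has the stated combinatorics", {
  m3 <- build_icosphere(3)
  expect_equal(nrow(m3$vertices), 642L)        # 10 * 4^n + 2
  expect_equal(nrow(m3$triangles), 1280L)
  E <- mesh_edges(m3$triangles)
  expect_equal(nrow(E), 1920L)
  expect_equal(642L - 1920L + 1280L, 2L)       # Euler characteristic
  # all bonds inside the tether band after scaling
  bl <- sqrt(rowSums((m3$vertices[E[, 1], ] - m3$vertices[E[, 2], ])^2))
  expect_gte(min(bl), m3$dmin)
  expect_lte(max(bl), m3$dmax)
  expect_error(build_icosphere(0), "subdivisions")
})

test_that("discrete bending energy converges to the continuum sphere value", {
  errs <- vapply(2:4, function(sub) {
    m <- build_icosphere(sub)
    abs(bending_energy(m, kappa = 25) / (8 * pi * 25) - 1)
  }, numeric(1))
  expect_lt(errs[2], 0.05)                     # within 5% at subdivision 3
  expect_true(all(diff(errs) < 0))             # monotone error decrease
  # matched spontaneous curvature kills the energy
  m <- build_icosphere(3)
  wb <- bending_energy(m, kappa = 25, c = 2 / m$radius,
                       domains = rep(TRUE, nrow(m$vertices)))
  expect_lt(wb / (8 * pi * 25), 0.05)
})

test_that("direct interaction energy counts pairs like brute force", {
  set.seed(5)
  m <- build_icosphere(2)
  n <- nrow(m$vertices)
  for (k in 1:50) {
    dom <- rep(FALSE, n); dom[sample.int(n, 12)] <- TRUE
    snap <- list(vertices = m$vertices + matrix(rnorm(3 * n, 0, 0.05), n),
                 domains = dom)
    r0 <- runif(1, 1, 3)
    w <- runif(1, 0.5, 2)
    # brute force O(n^2) over all vertex pairs
    idx <- which(dom)
    cnt <- 0
    for (a in seq_along(idx)) for (b in seq_along(idx)) if (a < b) {
      d <- sqrt(sum((snap$vertices[idx[a], ] - snap$vertices[idx[b], ])^2))
      if (d <= r0) cnt <- cnt + 1
    }
    expect_equal(direct_interaction_energy(snap, w = w, r0 = r0), -w * cnt)
  }
  # boundary inclusive and simple cases
  snap2 <- list(vertices = rbind(c(0, 0, 0), c(0.9, 0, 0)),
                domains = c(TRUE, TRUE))
  expect_equal(direct_interaction_energy(snap2, w = 2, r0 = 1), -2)
  expect_equal(direct_interaction_energy(snap2, w = 2, r0 = 0.9), -2)
  snap3 <- list(vertices = snap2$vertices, domains = c(FALSE, FALSE))
  expect_equal(direct_interaction_energy(snap3, w = 2, r0 = 1), 0)
})

test_that("active-force energy matches the normal projection on a sphere", {
  set.seed(2)
  cfg <- mc_config(sweeps = 0, rho = 0, force = 1.5, subdivisions = 2)
  m <- build_icosphere(2)
  n <- nrow(m$vertices)
  dom <- rep(FALSE, n); dom[7] <- TRUE
  st <- mc_init(cfg, mesh = m, domains = dom)
  # on the untouched icosphere, n_i is parallel to x_i: WF = -F |x_i|
  wf <- active_force_energy(st)
  expect_equal(wf, -1.5 * sqrt(sum(m$vertices[7, ]^2)), tolerance = 1e-6)
  expect_equal(active_force_energy(st, force = 0), 0)
})

test_that("Metropolis acceptance matches the analytic rate", {
  set.seed(11)
  expect_equal(ms_metropolis_rate(0, 1, 1e5), 1)         # dW = 0 accepted
  r <- ms_metropolis_rate(1, 1, 1e5)                     # dW = +kT
  expect_equal(r, exp(-1), tolerance = 0.01)
  expect_lt(ms_metropolis_rate(50, 1, 1e4), 1e-3)        # frozen limit
})

test_that("the move kernel samples the Boltzmann density (1 DOF)", {
  set.seed(123)
  x <- ms_harmonic_chain(1e5, kconst = 1, kT = 1, step = 1.2, thin = 10)
  # chi-squared against N(0, 1) with 20 equal-probability bins
  br <- qnorm(seq(0, 1, length.out = 21))
  obs <- table(cut(x, br))
  p <- chisq.test(as.vector(obs), p = rep(1 / 20, 20))$p.value
  expect_gt(p, 0.01)
  expect_equal(var(x), 1, tolerance = 0.05)
})

test_that("mesh invariants hold across sweeps and bookkeeping stays exact", {
  set.seed(31)
  cfg <- mc_config(sweeps = 10000, rho = 0.05, c = -1, w = 1.25,
                   subdivisions = 2, audit_every = 100, check_every = 1,
                   swap_rate = 1)
  run <- run_simulation(cfg, stats_every = 1000)       # errors on breach
  ck <- mc_check(run$state)
  expect_true(ck$bonds_ok)
  expect_equal(ck$euler, 2L)
  expect_true(ck$manifold)
  expect_gte(ck$min_degree, 3L)
  expect_lt(run$max_drift, 1e-8)
  # incremental totals equal full recomputation
  snap <- mc_snapshot(run$state)
  full <- mc_energies(run$state)
  expect_equal(snap$Wb, full$Wb, tolerance = 1e-9)
  expect_equal(snap$Wd, full$Wd, tolerance = 1e-12)
  # bond flips preserved counts
  expect_equal(nrow(snap$triangles), 320L)
  expect_equal(nrow(snap$edges), 480L)
})

test_that("simulations are reproducible given the seed", {
  cfg <- mc_config(sweeps = 200, rho = 0.05, subdivisions = 2, seed = 17,
                   audit_every = 0)
  r1 <- run_simulation(cfg, stats_every = 100)
  r2 <- run_simulation(cfg, stats_every = 100)
  expect_identical(mc_snapshot(r1$state)$vertices,
                   mc_snapshot(r2$state)$vertices)
  expect_identical(r1$energy$W, r2$energy$W)
})

test_that("thermalized bending energy sits modestly above the ground state", {
  set.seed(7)
  cfg <- mc_config(sweeps = 4000, rho = 0, w = 0, subdivisions = 2,
                   audit_every = 500, warmup = 2000)
  run <- run_simulation(cfg, stats_every = 200)
  late <- run$energy[run$energy$sweep > 2000, ]
  ratio <- mean(late$Wb) / (8 * pi * 25)
  expect_gt(ratio, 1)                  # thermal excess above 8 pi kappa
  expect_lt(ratio, 2)                  # but bounded
  expect_lt(run$max_drift, 1e-8)
})

test_that("cluster counting agrees with brute-force union-find", {
  set.seed(77)
  m <- build_icosphere(2)
  n <- nrow(m$vertices)
  E <- mesh_edges(m$triangles)
  for (k in 1:100) {
    dom <- rep(FALSE, n); dom[sample.int(n, sample(2:30, 1))] <- TRUE
    snap <- list(vertices = m$vertices, domains = dom, edges = E)
    cs <- cluster_sizes(snap)
    idx <- which(dom)
    keep <- dom[E[, 1]] & dom[E[, 2]]
    pairs <- cbind(match(E[keep, 1], idx), match(E[keep, 2], idx))
    oracle <- uf_components(length(idx), pairs)
    expect_equal(sort(cs$sizes), sort(oracle))
    expect_equal(sum(cs$sizes), cs$n_domains)
    expect_equal(sum(seq_along(cs$histogram) * cs$histogram), cs$n_domains)
  }
  # hand-built cases
  snap0 <- list(vertices = m$vertices, domains = rep(FALSE, n),
                edges = E)
  expect_equal(cluster_sizes(snap0)$n_domains, 0L)
  # a bonded chain of 5 forms one cluster of size 5
  chain <- c(1)
  while (length(chain) < 5) {
    nb <- setdiff(c(E[E[, 1] %in% chain, 2], E[E[, 2] %in% chain, 1]), chain)
    chain <- c(chain, nb[1])
  }
  domc <- rep(FALSE, n); domc[chain] <- TRUE
  csc <- cluster_sizes(list(vertices = m$vertices, domains = domc,
                            edges = E))
  expect_equal(csc$largest, 5L)
  # distance-based adjacency variant
  csd <- cluster_sizes(list(vertices = m$vertices, domains = domc),
                       r_adj = 2 * m$dmax)
  expect_gte(csd$largest, 5L)
})

test_that("curvature-increasing moves freeze out at large rigidity", {
  set.seed(41)
  cfg <- mc_config(sweeps = 50, rho = 0, w = 0, kappa = 1e6,
                   subdivisions = 2, audit_every = 0)
  run <- run_simulation(cfg, stats_every = 50)
  # at kappa -> infinity only curvature-neutral moves survive; on a
  # discrete sphere most displacements raise Wb, so acceptance collapses
  # and the energy stays at the ground state
  expect_lt(run$acc_move, 0.1)
  expect_lt(run$energy$Wb[nrow(run$energy)] / 1e6 / (8 * pi), 1.01)
})
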