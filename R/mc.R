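## Dynamically triangulated Monte-Carlo vesicle simulator: R surface over
## the compiled engine. Lengths in units of dmin, energies in units of kT.

#' Build an icosphere triangle mesh
#'
#' Subdivides an icosahedron `subdivisions` times, projects onto the
#' sphere, and scales the mesh so every bond length lies inside the tether
#' band `[dmin, dmax]` with `dmax = 1.7 dmin`.
#'
#' @param subdivisions number of 4-to-1 subdivision passes (>= 1);
#'   vertices number `10 * 4^n + 2`.
#' @param dmin minimal bond length (unit of length).
#' @return object of class `tri_mesh`: `vertices` (n x 3), `triangles`
#'   (m x 3, 1-based, outward-oriented), `dmin`, `dmax`, `radius`.
#' @export
build_icosphere <- function(subdivisions = 3L, dmin = 1) {
  if (subdivisions < 1L) stop("subdivisions must be >= 1")
  phi <- (1 + sqrt(5)) / 2
  V <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  V <- V / sqrt(rowSums(V^2))
  Tm <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivisions)) {
    mid_cache <- new.env(hash = TRUE)
    nv <- nrow(V)
    newV <- list()
    midpoint <- function(a, b) {
      key <- paste(min(a, b), max(a, b))
      id <- mid_cache[[key]]
      if (!is.null(id)) return(id)
      p <- (V[a, ] + V[b, ]) / 2
      p <- p / sqrt(sum(p^2))
      newV[[length(newV) + 1L]] <<- p
      id <- nv + length(newV)
      mid_cache[[key]] <- id
      id
    }
    newT <- matrix(0L, 4 * nrow(Tm), 3)
    for (t in seq_len(nrow(Tm))) {
      a <- Tm[t, 1]; b <- Tm[t, 2]; c <- Tm[t, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c); ca <- midpoint(c, a)
      newT[4 * t - 3, ] <- c(a, ab, ca)
      newT[4 * t - 2, ] <- c(b, bc, ab)
      newT[4 * t - 1, ] <- c(c, ca, bc)
      newT[4 * t, ] <- c(ab, bc, ca)
    }
    V <- rbind(V, do.call(rbind, newV))
    Tm <- newT
  }
  # bond lengths on the unit sphere
  E <- mesh_edges(Tm)
  bl <- sqrt(rowSums((V[E[, 1], ] - V[E[, 2], ])^2))
  ratio <- max(bl) / min(bl)
  dmax <- 1.7 * dmin
  if (ratio >= dmax / dmin)
    stop(sprintf(
      "bond-length band unreachable at subdivision %d (spread %.3f > 1.7)",
      subdivisions, ratio))
  # scale so the band is straddled with equal margins
  scale <- sqrt(dmin * dmax / (min(bl) * max(bl)))
  V <- V * scale
  structure(list(vertices = V, triangles = Tm, dmin = dmin, dmax = dmax,
                 radius = scale),
            class = "tri_mesh")
}

#' Edge list of a triangle mesh
#' @param triangles m x 3 integer matrix (1-based).
#' @return 2-column matrix of unique undirected edges.
#' @export
mesh_edges <- function(triangles) {
  E <- rbind(triangles[, c(1, 2)], triangles[, c(2, 3)], triangles[, c(3, 1)])
  E <- t(apply(E, 1, sort))
  unique(E)
}

#' @export
print.tri_mesh <- function(x, ...) {
  ne <- nrow(mesh_edges(x$triangles))
  cat(sprintf("tri_mesh: %d vertices, %d edges, %d triangles (chi = %d)\n",
              nrow(x$vertices), ne, nrow(x$triangles),
              nrow(x$vertices) - ne + nrow(x$triangles)))
  invisible(x)
}

#' Monte-Carlo simulation settings
#'
#' Defaults follow the nanodomain-budding study conditions: bending
#' rigidity 25 kT, nanodomain intrinsic curvature -1/dmin, 5% vertex
#' coverage, direct attraction 1.25 kT with range dmax, no active force,
#' step radius 0.15 dmin.
#'
#' @param kappa bending rigidity (kT).
#' @param c nanodomain intrinsic curvature (1/dmin).
#' @param rho nanodomain vertex fraction in `[0, 1]`.
#' @param w direct attraction per neighbouring nanodomain pair (kT).
#' @param r0 attraction range (units of dmin; default the tether maximum).
#' @param force active normal force magnitude on nanodomain vertices
#'   (kT/dmin; positive = outward/protrusive).
#' @param kT thermal energy (energy unit).
#' @param step vertex-move radius (units of dmin).
#' @param sweeps Monte-Carlo sweeps to run.
#' @param subdivisions icosphere subdivision level of the initial mesh.
#' @param seed RNG seed.
#' @param frame_every save a frame every this many sweeps (0 = none).
#' @param audit_every incremental-energy audit cadence (sweeps).
#' @param check_every mesh-invariant check cadence (sweeps, 0 = off).
#' @param warmup sweeps discarded before cluster statistics are taken.
#' @param swap_rate attribute-swap attempts per vertex per sweep
#'   (Metropolis-accepted exchange of the nanodomain flag along a random
#'   bond). The swap move preserves the equilibrium distribution and adds
#'   lateral nanodomain mobility beyond what bond flips provide; default 0
#'   (off).
#' @return config list.
#' @export
mc_config <- function(kappa = 25, c = -1, rho = 0.05, w = 1.25,
                      r0 = 1.7, force = 0, kT = 1, step = 0.15,
                      sweeps = 5000L, subdivisions = 3L, seed = 1L,
                      frame_every = 0L, audit_every = 100L,
                      check_every = 0L, warmup = NULL, swap_rate = 0) {
  if (kappa <= 0) stop("kappa must be positive")
  if (rho < 0 || rho > 1) stop("rho must lie in [0, 1]")
  if (is.null(warmup)) warmup <- floor(sweeps / 2)
  list(kappa = kappa, c = c, rho = rho, w = w, r0 = r0, force = force,
       kT = kT, step = step, sweeps = as.integer(sweeps),
       subdivisions = as.integer(subdivisions), seed = as.integer(seed),
       frame_every = as.integer(frame_every),
       audit_every = as.integer(audit_every),
       check_every = as.integer(check_every),
       warmup = as.integer(warmup), swap_rate = swap_rate)
}

#' Initialize a Monte-Carlo membrane state
#'
#' Builds the icosphere, assigns `round(rho * n)` nanodomain vertices at
#' random (under the current RNG state), and constructs the compiled
#' engine with incremental energy bookkeeping.
#'
#' @param config an [mc_config()].
#' @param mesh optional [build_icosphere()] mesh (default built from the
#'   config).
#' @param domains optional logical vector of nanodomain flags.
#' @return object of class `mc_state`.
#' @export
mc_init <- function(config, mesh = NULL, domains = NULL) {
  if (is.null(mesh)) mesh <- build_icosphere(config$subdivisions, dmin = 1)
  n <- nrow(mesh$vertices)
  if (is.null(domains)) {
    domains <- rep(FALSE, n)
    nd <- round(config$rho * n)
    if (nd > 0) domains[sample.int(n, nd)] <- TRUE
  }
  ptr <- ms_state_new(mesh$vertices, mesh$triangles - 1L, domains,
                      config$kappa, config$c, config$w, config$r0,
                      config$force, config$kT, mesh$dmin, mesh$dmax,
                      config$step * mesh$dmin, config$swap_rate)
  structure(list(ptr = ptr, config = config, mesh0 = mesh,
                 sweeps_done = 0L),
            class = "mc_state")
}

#' Advance a Monte-Carlo state by whole sweeps
#'
#' One sweep = one attempted move per vertex (uniform displacement in a
#' sphere of radius `step * dmin`, rejected outright on tether or
#' triangle-inversion violation) followed by `3N` random bond-flip
#' attempts; each attempt accepted with probability `min(1, exp(-dW/kT))`.
#'
#' @param state an [mc_init()] state (modified in place via the engine).
#' @param n_sweeps number of sweeps.
#' @return the state, with `last` acceptance/energy summary attached.
#' @export
mc_sweep <- function(state, n_sweeps = 1L) {
  cfg <- state$config
  out <- ms_sweep(state$ptr, as.integer(n_sweeps),
                  recenter_every = 1L,
                  audit_every = cfg$audit_every,
                  check_every = cfg$check_every)
  state$sweeps_done <- state$sweeps_done + as.integer(n_sweeps)
  state$last <- out
  state
}

#' Snapshot of the current mesh, domains and tracked energies
#' @param state an `mc_state`.
#' @return list with `vertices`, `triangles`, `edges` (1-based),
#'   `domains`, `Wb`, `Wd`, `WF`.
#' @export
mc_snapshot <- function(state) ms_get(state$ptr)

#' Fully recomputed energies of the current state
#' @param state an `mc_state`.
#' @return list with `Wb`, `Wd`, `WF`, `W` (independent of the
#'   incremental bookkeeping).
#' @export
mc_energies <- function(state) ms_energies(state$ptr)

#' Mesh validity diagnostics
#' @param state an `mc_state`.
#' @return list: bond band, Euler characteristic, 2-manifoldness, degrees.
#' @export
mc_check <- function(state) ms_check(state$ptr)

#' Discrete Helfrich bending energy of a mesh
#'
#' Vertex-based estimate of `(kappa/2) int (2H - c_v)^2 dA` with the
#' cotangent Laplace operator and barycentric dual areas; `c_v = c` at
#' nanodomain vertices and 0 elsewhere. Gaussian term omitted (fixed
#' topology).
#'
#' @param mesh a [build_icosphere()] mesh (or list with `vertices`,
#'   `triangles`).
#' @param kappa bending rigidity.
#' @param c nanodomain intrinsic curvature.
#' @param domains logical nanodomain flags (default none).
#' @return total bending energy.
#' @export
bending_energy <- function(mesh, kappa = 25, c = 0, domains = NULL) {
  n <- nrow(mesh$vertices)
  if (is.null(domains)) domains <- rep(FALSE, n)
  ptr <- ms_state_new(mesh$vertices, mesh$triangles - 1L, domains,
                      kappa, c, 0, 1.7, 0, 1,
                      0, Inf, 0.15)
  ms_energies(ptr)$Wb
}

#' Direct nanodomain attraction energy of a state
#'
#' `Wd = -w * #[nanodomain pairs with 3D distance <= r0]`, boundary
#' inclusive.
#'
#' @param state an `mc_state` (or [mc_snapshot()] list).
#' @param w attraction constant; `r0` range.
#' @param r0 see above.
#' @return energy.
#' @export
direct_interaction_energy <- function(state, w = NULL, r0 = NULL) {
  snap <- if (inherits(state, "mc_state")) mc_snapshot(state) else state
  cfg <- if (inherits(state, "mc_state")) state$config else NULL
  if (is.null(w)) w <- cfg$w
  if (is.null(r0)) r0 <- cfg$r0
  idx <- which(snap$domains)
  if (length(idx) < 2 || w == 0) return(0)
  X <- snap$vertices[idx, , drop = FALSE]
  d <- as.matrix(stats::dist(X))
  -w * sum(d[upper.tri(d)] <= r0)
}

#' Active-force pseudo-energy of a state
#'
#' `WF = -F * sum over nanodomains of n_i . x_i` with outward vertex
#' normals; frame-dependence is handled by pinning the enclosed-volume
#' centroid at the origin each sweep.
#'
#' @param state an `mc_state`.
#' @param force force magnitude (default from the config).
#' @return energy.
#' @export
active_force_energy <- function(state, force = NULL) {
  if (is.null(force)) force <- state$config$force
  if (force == 0) return(0)
  snap <- mc_snapshot(state)
  nrm <- ms_vertex_normals(state$ptr)
  idx <- which(snap$domains)
  -force * sum(rowSums(nrm[idx, , drop = FALSE] *
                         snap$vertices[idx, , drop = FALSE]))
}

#' Nanodomain cluster-size statistics
#'
#' Connected components of the nanodomain adjacency graph: by default two
#' nanodomains are adjacent when they share a mesh bond; alternatively a
#' 3D distance rule `r_adj` can be used.
#'
#' @param state an `mc_state` or [mc_snapshot()] list.
#' @param r_adj optional distance threshold replacing bond adjacency.
#' @return object of class `cluster_stats`: `sizes` (per cluster),
#'   `histogram` (count of clusters per size), `largest`, `n_domains`.
#' @export
cluster_sizes <- function(state, r_adj = NULL) {
  snap <- if (inherits(state, "mc_state")) mc_snapshot(state) else state
  idx <- which(snap$domains)
  nd <- length(idx)
  if (nd == 0)
    return(structure(list(sizes = integer(0), histogram = integer(0),
                          largest = 0L, n_domains = 0L),
                     class = "cluster_stats"))
  if (is.null(r_adj)) {
    E <- snap$edges
    keep <- snap$domains[E[, 1]] & snap$domains[E[, 2]]
    E <- E[keep, , drop = FALSE]
  } else {
    X <- snap$vertices[idx, , drop = FALSE]
    d <- as.matrix(stats::dist(X))
    pairs <- which(upper.tri(d) & d <= r_adj, arr.ind = TRUE)
    E <- cbind(idx[pairs[, 1]], idx[pairs[, 2]])
  }
  g <- igraph::graph_from_edgelist(
    matrix(match(as.vector(E), idx), ncol = 2), directed = FALSE)
  g <- igraph::add_vertices(g, nd - igraph::vcount(g))
  comp <- igraph::components(g)
  sizes <- as.integer(comp$csize)
  hist <- tabulate(sizes, nbins = max(sizes))
  structure(list(sizes = sizes, histogram = hist,
                 largest = max(sizes), n_domains = nd),
            class = "cluster_stats")
}

#' @export
print.cluster_stats <- function(x, ...) {
  cat(sprintf("cluster_stats: %d nanodomains in %d clusters (largest %d)\n",
              x$n_domains, length(x$sizes), x$largest))
  invisible(x)
}

#' Gyration-tensor shape anisotropy of the vesicle
#'
#' Relative shape anisotropy `kappa^2` of the vertex cloud (0 for
#' spherically symmetric, up to 1 for a line); used to detect flattened
#' (pancake) and elongated morphologies.
#'
#' @param state an `mc_state` or snapshot.
#' @return scalar in `[0, 1]`.
#' @export
shape_anisotropy <- function(state) {
  snap <- if (inherits(state, "mc_state")) mc_snapshot(state) else state
  X <- scale(snap$vertices, scale = FALSE)
  lam <- eigen(crossprod(X) / nrow(X), symmetric = TRUE)$values
  1.5 * sum(lam^2) / sum(lam)^2 - 0.5
}

#' Run a Monte-Carlo vesicle simulation
#'
#' Develops the vesicle toward thermal (or, with an active force, steady)
#' state, collecting an energy time series, periodic frames and the
#' ensemble-averaged nanodomain cluster-size histogram over the
#' post-warmup frames. Reproducible given `config$seed`.
#'
#' @param config an [mc_config()].
#' @param mesh,domains optional initial mesh / nanodomain flags.
#' @param stats_every cadence (sweeps) of energy/cluster sampling.
#' @return object of class `mc_run`: final `state`, `energy` time series
#'   data.frame, `cluster_hist` (ensemble-averaged counts per size),
#'   acceptance rates, `max_drift`, `anisotropy` of the final frame.
#' @export
run_simulation <- function(config, mesh = NULL, domains = NULL,
                           stats_every = 100L) {
  set.seed(config$seed)
  state <- mc_init(config, mesh = mesh, domains = domains)
  n_blocks <- ceiling(config$sweeps / stats_every)
  energy <- vector("list", n_blocks)
  hists <- list()
  frames <- list()
  aniso_acc <- numeric(0)
  done <- 0L
  for (b in seq_len(n_blocks)) {
    todo <- min(stats_every, config$sweeps - done)
    state <- mc_sweep(state, todo)
    done <- done + todo
    en <- state$last
    energy[[b]] <- data.frame(sweep = done, W = en$W, Wb = en$Wb,
                              Wd = en$Wd, WF = en$WF,
                              acc_move = en$acc_move,
                              acc_flip = en$acc_flip)
    if (done > config$warmup) {
      cs <- cluster_sizes(state)
      if (cs$n_domains > 0) hists[[length(hists) + 1L]] <- cs$histogram
      aniso_acc <- c(aniso_acc, shape_anisotropy(state))
    }
    if (config$frame_every > 0 && done %% config$frame_every == 0)
      frames[[length(frames) + 1L]] <- mc_snapshot(state)
  }
  cluster_hist <- NULL
  if (length(hists) > 0) {
    mx <- max(vapply(hists, length, integer(1)))
    M <- t(vapply(hists, function(h) c(h, rep(0, mx - length(h))),
                  numeric(mx)))
    cluster_hist <- colMeans(M)
  }
  structure(list(state = state, config = config,
                 energy = do.call(rbind, energy),
                 cluster_hist = cluster_hist, frames = frames,
                 acc_move = state$last$acc_move,
                 acc_flip = state$last$acc_flip,
                 max_drift = state$last$max_drift,
                 anisotropy = shape_anisotropy(state),
                 anisotropy_mean = if (length(aniso_acc) > 0)
                   mean(aniso_acc) else NA_real_),
            class = "mc_run")
}

#' @export
print.mc_run <- function(x, ...) {
  cat(sprintf(
    "mc_run: %d sweeps, W = %.4g (Wb %.4g, Wd %.4g, WF %.4g)\n",
    x$config$sweeps, x$state$last$W, x$state$last$Wb, x$state$last$Wd,
    x$state$last$WF))
  cat(sprintf("  acceptance: moves %.2f, flips %.2f; audit drift %.2g\n",
              x$acc_move, x$acc_flip, x$max_drift))
  invisible(x)
}
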