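## Constrained minimization of total membrane energies over the Fourier
## tangent-angle shape variables (and, for models with a lateral density
## field, the tanh-profile variables chi, s0, phi1, phi2).
##
## The profile length is held at Ls = pi: the shape depends on s/Ls only,
## and all dimensional models are evaluated after rescaling the surface to
## unit reference radius (R0 = 1), which removes the area constraint.
## Closure r(Ls) = 0, the reduced volume, the average density and the
## minimal pole distance are enforced by an augmented-Lagrangian scheme
## (quadratic penalties with multipliers and adaptive weights) around a
## BFGS core.

#' Energy model selectors for the shape minimizer
#'
#' @param params model parameter object (see each constructor).
#' @return a model object consumed by [minimization_problem()].
#' @name energy_models
NULL

#' @rdname energy_models
#' @export
helfrich_model <- function(params = helfrich_params()) {
  structure(list(type = "helfrich", params = params,
                 has_density = FALSE), class = "energy_model")
}

#' @rdname energy_models
#' @param include_mixing include the mixing-entropy term.
#' @export
two_component_model <- function(params, include_mixing = TRUE) {
  structure(list(type = "two_component", params = params,
                 include_mixing = include_mixing, has_density = TRUE),
            class = "energy_model")
}

#' @rdname energy_models
#' @param bar [bar_params()]; `helfrich` the bare-membrane
#'   [helfrich_params()]; `kT`, `a0` mixing-entropy constants.
#' @param helfrich,kT,a0 see above.
#' @export
bar_model <- function(bar, helfrich = helfrich_params(), kT = 0, a0 = 1,
                      include_mixing = TRUE) {
  structure(list(type = "bar", bar = bar, helfrich = helfrich,
                 kT = kT, a0 = a0, include_mixing = include_mixing,
                 has_density = TRUE), class = "energy_model")
}

#' @rdname energy_models
#' @param kc local bending modulus; `shear` a [shear_params()];
#'   `nonlocal` a [nonlocal_params()].
#' @param shear,nonlocal see above.
#' @export
shear_nonlocal_model <- function(kc = 1, shear, nonlocal) {
  structure(list(type = "shear_nonlocal", kc = kc, shear = shear,
                 nonlocal = nonlocal, has_density = FALSE),
            class = "energy_model")
}

#' Rescale a surface grid to unit reference radius
#'
#' Rescales all lengths by `1/R0` so that the sphere of equal area has
#' radius 1; curvatures are scaled by `R0`. The reduced volume is
#' invariant.
#'
#' @param grid a `surface_grid`.
#' @return the rescaled `surface_grid` (with `R0 = 1`).
#' @export
rescale_grid <- function(grid) {
  lam <- 1 / grid$R0
  grid$s <- grid$s * lam; grid$r <- grid$r * lam; grid$z <- grid$z * lam
  grid$h <- grid$h * lam; grid$Ls <- grid$Ls * lam
  grid$C1 <- grid$C1 / lam; grid$C2 <- grid$C2 / lam
  grid$H <- grid$H / lam; grid$D <- grid$D / lam; grid$K <- grid$K / lam^2
  grid$dS <- grid$dS * lam^2; grid$S <- grid$S * lam^2
  grid$V <- grid$V * lam^3; grid$R0 <- 1
  grid$closure <- grid$closure * lam
  grid
}

## evaluate a model energy on a (rescaled) grid, with optional density field
model_energy <- function(model, grid, phi = NULL) {
  switch(model$type,
    helfrich = list(Fiso = helfrich_total(grid, model$params),
                    F = helfrich_total(grid, model$params)),
    two_component = {
      e <- two_component_energy(grid, phi, model$params,
                                include_mixing = model$include_mixing)
      list(Fb = e$Fb, Fmix = e$Fmix, F = e$F)
    },
    bar = {
      e <- bar_energy(grid, phi, model$bar, model$helfrich,
                      kT = model$kT, a0 = model$a0,
                      include_mixing = model$include_mixing)
      e
    },
    shear_nonlocal = {
      nl <- nonlocal_bending(grid, model$nonlocal, kc = model$kc)
      Fsh <- shear_energy(grid, model$shear)
      list(Flocal = nl$Flocal, Fnl = nl$Fnl, Fshear = Fsh,
           F = nl$F + Fsh)
    },
    stop("unknown model type"))
}

#' Minimizer settings
#'
#' @param n_grid arc-length quadrature intervals.
#' @param maxit BFGS iterations per augmented-Lagrangian round.
#' @param rounds maximum multiplier/weight update rounds.
#' @param w0 initial penalty weights (closure, v, phi, h).
#' @param tol_v,tol_phi reduced-volume / average-density tolerances.
#' @param tol_closure closure tolerance relative to `Ls`.
#' @param tol_h pole-distance tolerance.
#' @param reltol BFGS relative tolerance.
#' @return settings list.
#' @export
minimizer_settings <- function(n_grid = 1000L, maxit = 400L, rounds = 10L,
                               w0 = c(closure = 1e6, v = 1e5,
                                      phi = 1e5, h = 1e5),
                               tol_v = 1e-4, tol_phi = 1e-4,
                               tol_closure = 1e-6, tol_h = 1e-6,
                               reltol = 1e-13) {
  list(n_grid = n_grid, maxit = maxit, rounds = rounds, w0 = w0,
       tol_v = tol_v, tol_phi = tol_phi, tol_closure = tol_closure,
       tol_h = tol_h, reltol = reltol)
}

#' Constrained shape-minimization problem
#'
#' @param model an energy model ([helfrich_model()],
#'   [two_component_model()], [bar_model()], [shear_nonlocal_model()]).
#' @param seed starting [shape_profile()] (closure defect below `0.1 Ls`).
#' @param v target reduced volume in (0, 1].
#' @param phi_ave target average relative area density (models with a
#'   density field), or `NULL`.
#' @param h_min minimal pole-to-pole height `z(Ls) - z(0)` in units of R0
#'   (the cytoskeleton-rod constraint), or `NULL`.
#' @param density_seed starting values `list(phi1, phi2, chi, s0)` for the
#'   tanh density profile (s0 as a fraction of Ls).
#' @param settings [minimizer_settings()].
#' @return object of class `minimization_problem`.
#' @export
minimization_problem <- function(model, seed, v,
                                 phi_ave = NULL, h_min = NULL,
                                 density_seed = list(phi1 = 0.02,
                                                     phi2 = 0.9,
                                                     chi = 8, s0 = 0.25),
                                 settings = minimizer_settings()) {
  if (v <= 0 || v > 1) stop("v must lie in (0, 1]")
  if (!is.null(phi_ave) && (phi_ave < 0 || phi_ave > 1))
    stop("phi_ave must lie in [0, 1]")
  if (!is.null(h_min) && h_min < 0) stop("h_min must be non-negative")
  if (model$has_density && is.null(phi_ave))
    stop("models with a density field need a phi_ave target")
  structure(list(model = model, seed = seed, v = v, phi_ave = phi_ave,
                 h_min = h_min, density_seed = density_seed,
                 settings = settings),
            class = "minimization_problem")
}

## ---- parameter vector packing ------------------------------------------
## shape amplitudes a[1..N]; density block (logit phi1, logit phi2,
## log chi, s0 fraction) appended when the model carries a density field.

.pack <- function(a, dens = NULL) {
  if (is.null(dens)) return(a)
  c(a, stats::qlogis(min(max(dens$phi1, 1e-6), 1 - 1e-6)),
    stats::qlogis(min(max(dens$phi2, 1e-6), 1 - 1e-6)),
    log(dens$chi), stats::qlogis(min(max(dens$s0, 1e-4), 1 - 1e-4)))
}

.unpack <- function(par, n_modes, has_density) {
  a <- par[seq_len(n_modes)]
  if (!has_density) return(list(a = a, dens = NULL))
  d <- par[(n_modes + 1L):(n_modes + 4L)]
  list(a = a, dens = list(phi1 = stats::plogis(d[1]),
                          phi2 = stats::plogis(d[2]),
                          chi = exp(pmin(d[3], 9)),   # border no sharper than ~e9/Ls
                          s0 = stats::plogis(d[4])))
}

## ---- fast analytic-gradient path: Helfrich with C0 = 0 ------------------
## E is scale invariant, so no rescaling is needed; objective and gradient
## are exact derivatives of the discretized functional.

.helfrich_machinery <- function(n_modes, n_grid, kc) {
  n <- n_grid + 1L
  t <- seq(0, 1, length.out = n)
  h <- pi / n_grid                      # Ls = pi
  im <- seq_len(n_modes)
  SM <- sin(outer(pi * t, im))          # dTheta/da
  CM <- cos(outer(pi * t, im))
  DM <- sweep(CM, 2, im, `*`)           # dC1/da (Ls = pi)
  w <- .trap_w(n, h)
  colcum <- function(M) .cumquad_mat(M, h)
  list(n = n, t = t, h = h, im = im, SM = SM, DM = DM, w = w,
       colcum = colcum, kc = kc)
}

.helfrich_eval <- function(a, mach, v_target, lam, wt, want_grad = TRUE) {
  n <- mach$n; h <- mach$h; w <- mach$w
  th <- pi * mach$t + drop(mach$SM %*% a)
  dth <- 1 + drop(mach$DM %*% a)                   # C1 (Ls = pi, ramp slope 1)
  cth <- cos(th); sth <- sin(th)
  r <- .cumquad(cth, h)
  C1 <- dth
  sg <- ifelse(r >= 0, 1, -1)
  rabs <- abs(r)
  rs <- sg * pmax(rabs, 1e-9)                      # signed, safe denominator
  C2 <- sth / rs
  C2[c(1L, n)] <- C1[c(1L, n)]
  Hsum <- C1 + C2                                  # 2H
  # |r| as area factor keeps the bending integrand nonnegative when an
  # iterate transiently crosses r = 0; exact on valid (r >= 0) shapes
  E <- mach$kc / 2 * sum(w * 2 * pi * rabs * Hsum^2)
  S <- 2 * pi * sum(w * rabs)
  V <- pi * sum(w * r^2 * sth)
  vred <- 6 * sqrt(pi) * V * S^(-1.5)
  gc_ <- r[n] / pi                                 # closure / Ls
  gv <- vred - v_target
  rneg <- pmin(r, 0)
  Pneg <- 1e3 * sum(w * rneg^2)                    # push iterates to r >= 0
  obj <- E + Pneg + lam[1] * gc_ + wt[1] * gc_^2 + lam[2] * gv + wt[2] * gv^2
  if (!want_grad)
    return(list(obj = obj, E = E, v = vred, closure = r[n], S = S, V = V))
  SM <- mach$SM; DM <- mach$DM
  R <- -mach$colcum(sth * SM)                      # dr/da  (n x N)
  # dE/da
  dC2 <- (cth * SM) / rs - (sth / rs^2) * R
  # endpoint regularization: C2 := C1 there
  dC2[1L, ] <- DM[1L, ]; dC2[n, ] <- DM[n, ]
  dHsum <- DM + dC2
  dE <- mach$kc * drop((w * rabs * Hsum * 2) %*% dHsum) +
    mach$kc * drop((w * sg * Hsum^2) %*% R)
  dE <- pi * dE                                    # 2pi r ds, kc/2 * 2 = kc
  dS <- 2 * pi * drop((w * sg) %*% R)
  dV <- pi * (drop((w * 2 * r * sth) %*% R) + drop((w * r^2 * cth) %*% SM))
  dv <- 6 * sqrt(pi) * (dV * S^(-1.5) - 1.5 * V * S^(-2.5) * dS)
  dgc <- R[n, ] / pi
  dPneg <- 1e3 * 2 * drop((w * rneg) %*% R)
  grad <- dE + dPneg +
    (lam[1] + 2 * wt[1] * gc_) * dgc + (lam[2] + 2 * wt[2] * gv) * dv
  list(obj = obj, grad = grad, E = E, v = vred, closure = r[n], S = S, V = V)
}

## ---- generic objective (numeric gradient) -------------------------------

.generic_objective <- function(problem) {
  model <- problem$model
  set <- problem$settings
  n_modes <- problem$seed$n_modes
  function(par, lam, wt) {
    up <- .unpack(par, n_modes, model$has_density)
    prof <- shape_profile(up$a, Ls = pi)
    # negative-radius excursions are clamped and penalized smoothly via
    # neg_r2 rather than rejected: a hard cliff strands the line search
    grid <- tryCatch(integrate_profile(prof, n_grid = set$n_grid, r_tol = Inf),
                     error = function(e) NULL)
    if (is.null(grid)) return(1e8)
    neg_pen <- 1e4 * grid$neg_r2 / grid$R0^2
    grid <- rescale_grid(grid)
    phi <- NULL
    if (model$has_density)
      phi <- phi_profile(grid$s, up$dens$phi1, up$dens$phi2,
                         up$dens$chi, up$dens$s0 * grid$Ls)
    en <- model_energy(model, grid, phi)
    gc_ <- grid$closure / grid$Ls
    gv <- grid$v - problem$v
    obj <- en$F + neg_pen + lam["closure"] * gc_ + wt["closure"] * gc_^2 +
      lam["v"] * gv + wt["v"] * gv^2
    if (!is.null(problem$phi_ave)) {
      gp <- phi_average(grid, phi) - problem$phi_ave
      obj <- obj + lam["phi"] * gp + wt["phi"] * gp^2
    }
    if (!is.null(problem$h_min)) {
      gh <- max(0, problem$h_min - (grid$z[grid$n] - grid$z[1]))
      obj <- obj + lam["h"] * gh + wt["h"] * gh^2
    }
    if (!is.finite(obj)) 1e8 else obj
  }
}

## residuals of the current iterate
.residuals <- function(problem, par) {
  model <- problem$model
  set <- problem$settings
  up <- .unpack(par, problem$seed$n_modes, model$has_density)
  grid <- rescale_grid(integrate_profile(shape_profile(up$a, Ls = pi),
                                         n_grid = set$n_grid, r_tol = Inf))
  phi <- NULL
  if (model$has_density)
    phi <- phi_profile(grid$s, up$dens$phi1, up$dens$phi2,
                       up$dens$chi, up$dens$s0 * grid$Ls)
  res <- c(closure = abs(grid$closure) / grid$Ls,
           v = abs(grid$v - problem$v))
  if (!is.null(problem$phi_ave))
    res["phi"] <- abs(phi_average(grid, phi) - problem$phi_ave)
  if (!is.null(problem$h_min))
    res["h"] <- max(0, problem$h_min - (grid$z[grid$n] - grid$z[1]))
  list(res = res, grid = grid, phi = phi, up = up)
}

#' Minimize a constrained membrane-shape problem
#'
#' Augmented-Lagrangian outer loop (multiplier and adaptive-weight updates
#' on the closure, reduced-volume, average-density and pole-distance
#' constraints) around a BFGS inner minimization. Deterministic given the
#' seed profile and settings. Uses an exact analytic gradient for the
#' pure Helfrich model with `C0 = 0`; other models use finite-difference
#' gradients.
#'
#' @param problem a [minimization_problem()].
#' @return object of class `minimization_result`: optimal `profile`,
#'   `grid` (rescaled to R0 = 1), `phi` and density parameters (density
#'   models), `energy` breakdown, constraint `residuals`, `converged`
#'   flag, `omega` per point (BAR model).
#' @export
minimize_shape <- function(problem) {
  model <- problem$model
  set <- problem$settings
  seed <- problem$seed
  sg <- integrate_profile(seed, n_grid = set$n_grid, r_tol = 0.2)
  if (abs(sg$closure) > 0.1 * sg$Ls)
    stop("seed profile closure defect exceeds 0.1 Ls")
  fast <- model$type == "helfrich" && model$params$C0 == 0 &&
    is.null(problem$h_min)
  n_modes <- seed$n_modes
  if (fast) {
    mach <- .helfrich_machinery(n_modes, set$n_grid, model$params$kc)
    a <- seed$a
    lam <- c(0, 0); wt <- c(set$w0["closure"], set$w0["v"])
    prev <- NULL
    for (round in seq_len(set$rounds)) {
      opt <- stats::optim(a,
        fn = function(p) .helfrich_eval(p, mach, problem$v, lam, wt,
                                        want_grad = FALSE)$obj,
        gr = function(p) .helfrich_eval(p, mach, problem$v, lam, wt)$grad,
        method = "BFGS",
        control = list(maxit = set$maxit, reltol = set$reltol))
      a <- opt$par
      ev <- .helfrich_eval(a, mach, problem$v, lam, wt, want_grad = FALSE)
      g <- c(ev$closure / pi, ev$v - problem$v)
      lam <- lam + 2 * wt * g
      if (abs(g[1]) <= set$tol_closure && abs(g[2]) <= set$tol_v) break
      if (!is.null(prev)) {
        if (abs(g[1]) > abs(prev[1]) / 4) wt[1] <- wt[1] * 10
        if (abs(g[2]) > abs(prev[2]) / 4) wt[2] <- wt[2] * 10
      }
      prev <- g
    }
    prof <- shape_profile(a, Ls = pi)
    grid <- rescale_grid(integrate_profile(prof, n_grid = set$n_grid,
                                           r_tol = 0.05))
    en <- model_energy(model, grid)
    res <- c(closure = abs(grid$closure) / grid$Ls,
             v = abs(grid$v - problem$v))
    conv <- res["closure"] <= set$tol_closure && res["v"] <= set$tol_v
    return(structure(list(profile = prof, grid = grid, phi = NULL,
                          density = NULL, energy = en,
                          residuals = res, converged = unname(conv),
                          omega = NULL, rounds = round),
                     class = "minimization_result"))
  }
  ## generic path
  par <- .pack(seed$a, if (model$has_density) problem$density_seed)
  obj <- .generic_objective(problem)
  lam <- c(closure = 0, v = 0, phi = 0, h = 0)
  wt <- c(closure = set$w0["closure"], v = set$w0["v"],
          phi = set$w0["phi"], h = set$w0["h"])
  names(wt) <- c("closure", "v", "phi", "h")
  prev <- NULL
  for (round in seq_len(set$rounds)) {
    par_prev <- par
    opt <- stats::optim(par, fn = obj, lam = lam, wt = wt, method = "BFGS",
                        control = list(maxit = set$maxit,
                                       reltol = max(set$reltol, 1e-12),
                                       ndeps = rep(1e-6, length(par))))
    par <- opt$par
    rr <- tryCatch(.residuals(problem, par), error = function(e) NULL)
    if (is.null(rr)) {            # inner solve ran into a degenerate iterate
      par <- par_prev
      break
    }
    g <- c(closure = rr$grid$closure / rr$grid$Ls,
           v = rr$grid$v - problem$v, phi = 0, h = 0)
    if (!is.null(problem$phi_ave))
      g["phi"] <- phi_average(rr$grid, rr$phi) - problem$phi_ave
    if (!is.null(problem$h_min))
      g["h"] <- max(0, problem$h_min - (rr$grid$z[rr$grid$n] - rr$grid$z[1]))
    lam <- lam + 2 * wt * g
    tolv <- c(closure = set$tol_closure, v = set$tol_v,
              phi = set$tol_phi, h = set$tol_h)
    if (all(abs(g) <= tolv)) break
    if (!is.null(prev)) {
      esc <- abs(g) > abs(prev) / 4 & abs(g) > tolv
      wt[esc] <- wt[esc] * 10
    }
    prev <- g
  }
  rr <- .residuals(problem, par)
  en <- model_energy(model, rr$grid, rr$phi)
  omega <- if (model$type == "bar")
    bar_orientation(rr$grid$H, rr$grid$D, model$bar$Cp)$omega else NULL
  conv <- all(rr$res <= c(closure = set$tol_closure, v = set$tol_v,
                          phi = set$tol_phi,
                          h = set$tol_h)[names(rr$res)])
  structure(list(profile = shape_profile(rr$up$a, Ls = pi),
                 grid = rr$grid, phi = rr$phi, density = rr$up$dens,
                 energy = en, residuals = rr$res, converged = conv,
                 omega = omega, rounds = round),
            class = "minimization_result")
}

#' @export
print.minimization_result <- function(x, ...) {
  cat(sprintf("minimization_result: F = %.8g, v = %.5f, converged: %s\n",
              x$energy$F, x$grid$v, x$converged))
  cat("  residuals:", paste(names(x$residuals),
                            signif(x$residuals, 3), collapse = ", "), "\n")
  invisible(x)
}

#' Energy of a shape branch along a reduced-volume grid
#'
#' Warm-starts each reduced volume from the previous converged profile
#' (branch following); flags possible branch jumps as discontinuities in
#' the energy along the scan.
#'
#' @param problem template [minimization_problem()] (its `v` is
#'   overridden).
#' @param v_grid reduced volumes to scan (traversed in the given order).
#' @param branch_seed seed [shape_profile()] for the first grid point.
#' @return data.frame with `v`, `E`, `converged`, `jump`; converged
#'   profiles attached as attribute `"profiles"`.
#' @export
branch_energy <- function(problem, v_grid, branch_seed) {
  seed <- branch_seed
  profs <- vector("list", length(v_grid))
  E <- numeric(length(v_grid)); conv <- logical(length(v_grid))
  for (i in seq_along(v_grid)) {
    p <- problem; p$v <- v_grid[i]; p$seed <- seed
    fit <- minimize_shape(p)
    E[i] <- fit$energy$F; conv[i] <- fit$converged
    profs[[i]] <- fit$profile
    seed <- fit$profile
  }
  jump <- c(FALSE, abs(diff(E)) > 10 * stats::median(abs(diff(E)) + 1e-12))
  out <- data.frame(v = v_grid, E = E, converged = conv, jump = jump)
  attr(out, "profiles") <- profs
  out
}

#' Locate the reduced volume where two shape branches exchange stability
#'
#' Bisection on `E_A(v) - E_B(v)`, warm-starting each evaluation from the
#' nearest converged profile of the corresponding branch table.
#'
#' @param problem template [minimization_problem()].
#' @param branchA,branchB [branch_energy()] tables (with profiles).
#' @param dv_tol bisection tolerance on v.
#' @return the crossing reduced volume `v*`.
#' @export
find_phase_boundary <- function(problem, branchA, branchB, dv_tol = 0.005) {
  # branches may have been traversed in opposite directions; align by v
  oA <- order(branchA$v); oB <- order(branchB$v)
  pA_all <- attr(branchA, "profiles")[oA]
  pB_all <- attr(branchB, "profiles")[oB]
  branchA <- branchA[oA, ]; attr(branchA, "profiles") <- pA_all
  branchB <- branchB[oB, ]; attr(branchB, "profiles") <- pB_all
  if (!isTRUE(all.equal(branchA$v, branchB$v)))
    stop("branch tables must share the same reduced-volume grid")
  dE <- branchA$E - branchB$E
  # grid points where the two minimizations landed on the same branch
  # (energy difference numerically zero) carry no crossing information
  tol_same <- 1e-6 * max(abs(branchA$E), abs(branchB$E))
  valid <- which(abs(dE) > tol_same)
  if (length(valid) < 2) stop("branches coincide on the scanned grid")
  sgn <- sign(dE[valid])
  flip <- which(diff(sgn) != 0)
  if (length(flip) == 0) stop("branches do not cross on the scanned grid")
  i <- valid[flip[1]]; j <- valid[flip[1] + 1L]
  lo <- branchA$v[i]; hi <- branchA$v[j]
  f_lo <- dE[i]
  pA <- attr(branchA, "profiles"); pB <- attr(branchB, "profiles")
  seedA <- pA[[i]]; seedB <- pB[[i]]
  eval_diff <- function(v, sA, sB) {
    p <- problem; p$v <- v
    p$seed <- sA; fitA <- minimize_shape(p)
    p$seed <- sB; fitB <- minimize_shape(p)
    list(d = fitA$energy$F - fitB$energy$F,
         pA = fitA$profile, pB = fitB$profile)
  }
  while (hi - lo > dv_tol) {
    mid <- (lo + hi) / 2
    ev <- eval_diff(mid, seedA, seedB)
    if (sign(ev$d) == sign(f_lo)) {
      lo <- mid; f_lo <- ev$d
    } else hi <- mid
    seedA <- ev$pA; seedB <- ev$pB
  }
  (lo + hi) / 2
}

## geometric descriptors of the protrusion: the pole side (above or below
## the widest point) carrying the higher mean density, or the top side for
## density-free models
.protrusion_metrics <- function(grid, phi = NULL, omega = NULL) {
  iw <- which.max(grid$r)                      # widest point (body equator)
  n <- grid$n
  side_top <- TRUE
  if (!is.null(phi) && iw > 1 && iw < n) {
    ti <- iw:n; bi <- 1:iw
    mtop <- sum(phi[ti] * grid$dS[ti]) / sum(grid$dS[ti])
    mbot <- sum(phi[bi] * grid$dS[bi]) / sum(grid$dS[bi])
    side_top <- mtop >= mbot
  }
  idx <- if (side_top) iw:n else 1:iw
  zpole <- if (side_top) grid$z[n] else grid$z[1]
  len <- abs(zpole - grid$z[iw])
  sel <- idx[abs(grid$z[idx] - zpole) <= 0.3 * len]   # protrusion tip region
  if (length(sel) < 2) sel <- idx
  wts <- grid$dS[sel]
  radius <- sum(grid$r[sel] * wts) / max(sum(wts), 1e-300)
  out <- list(length = len, radius = radius, side_top = side_top)
  if (!is.null(phi)) {
    out$phi_protrusion <- sum(phi[idx] * grid$dS[idx]) / sum(grid$dS[idx])
    pav <- sum(phi * grid$dS) / grid$S
    out$segregation <- sqrt(sum((phi - pav)^2 * grid$dS) / grid$S)
  }
  if (!is.null(omega)) {
    wsel <- if (!is.null(phi)) phi[sel] * wts else wts
    out$omega_mean <- sum(omega[sel] * wsel) / max(sum(wsel), 1e-300)
  }
  out
}

#' Stretch a vesicle by a growing internal rod (pole-distance sequence)
#'
#' Warm-started sequence of constrained equilibria at increasing minimal
#' pole distance `h_min` and fixed reduced volume; models the membrane
#' stretched from the inside by a growing cytoskeletal rod. Reports the
#' protrusion radius and length, the density segregation measure and
#' (for the BAR model) the mean orientation angle on the protrusion.
#'
#' @param problem template [minimization_problem()].
#' @param h_min_grid increasing pole-distance constraints (units of R0).
#' @return data.frame of per-step descriptors; results attached as
#'   attribute `"results"`.
#' @export
stretch_sequence <- function(problem, h_min_grid) {
  seed <- problem$seed
  dens <- problem$density_seed
  out <- vector("list", length(h_min_grid))
  fits <- vector("list", length(h_min_grid))
  for (i in seq_along(h_min_grid)) {
    p <- problem; p$h_min <- h_min_grid[i]; p$seed <- seed
    p$density_seed <- dens
    fit <- minimize_shape(p)
    m <- .protrusion_metrics(fit$grid, fit$phi, fit$omega)
    out[[i]] <- data.frame(h_min = h_min_grid[i],
                           height = fit$grid$z[fit$grid$n] - fit$grid$z[1],
                           E = fit$energy$F,
                           radius = m$radius, length = m$length,
                           segregation = m$segregation %||% NA_real_,
                           phi_protrusion = m$phi_protrusion %||% NA_real_,
                           omega_mean = m$omega_mean %||% NA_real_,
                           converged = fit$converged)
    fits[[i]] <- fit
    seed <- fit$profile
    if (!is.null(fit$density)) dens <- fit$density
  }
  res <- do.call(rbind, out)
  attr(res, "results") <- fits
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a
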