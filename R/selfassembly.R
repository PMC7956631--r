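## Aggregation thermodynamics of curved membrane nanodomains: equilibrium
## monomer/aggregate densities on a lattice of M sites with a multiplier
## enforcing conservation, and the critical aggregation concentration.

#' Self-assembly system of curved membrane nanodomains
#'
#' `N` laterally mobile curved nanodomains on `M` lattice sites of a weakly
#' curved parent membrane (mean curvature `1/R0`); aggregates are highly
#' curved protrusions of mean curvature `1/r` (spherical beads or
#' necklaces, `r << R0`). The single-nanodomain elastic energy is
#' `f(H) = xi/2 (H - H0)^2 a0`; the per-monomer gain from sitting in an
#' aggregate is the direct interaction `w >= 0` (taken independent of
#' aggregate size; a callable `w(i)` is accepted for extensions).
#'
#' @param rho total number density `N/M` in (0, 1).
#' @param xi single-element elastic constant (`xi = 4 K1 + 2 K2`).
#' @param a0 area per nanodomain.
#' @param H0 intrinsic (spontaneous) mean curvature of the nanodomain.
#' @param r protrusion curvature radius; `R0` parent-membrane radius.
#' @param R0 see above.
#' @param w direct interaction energy per monomer in an aggregate
#'   (scalar, or a function of aggregate size `i`).
#' @param kT thermal energy.
#' @return object of class `aggregation_system`.
#' @export
aggregation_system <- function(rho, xi, a0, H0, r, R0, w, kT = 1) {
  if (rho <= 0 || rho >= 1) stop("rho must lie in (0, 1)")
  if (r <= 0 || R0 <= 0) stop("r and R0 must be positive")
  wfun <- if (is.function(w)) w else function(i) rep_len(w, length(i))
  if (any(wfun(1:3) < 0)) stop("w must be non-negative")
  structure(list(rho = rho, xi = xi, a0 = a0, H0 = H0, r = r, R0 = R0,
                 w = wfun, w_const = if (is.function(w)) NA_real_ else w,
                 kT = kT),
            class = "aggregation_system")
}

#' Elastic energy of a single isotropic nanodomain at mean curvature H
#' @param system an [aggregation_system()].
#' @param H local mean curvature.
#' @return `f = xi/2 (H - H0)^2 a0`.
#' @export
monomer_energy <- function(system, H) {
  system$xi / 2 * (H - system$H0)^2 * system$a0
}

#' Energy difference between aggregated and dispersed nanodomains
#'
#' `Delta f = f(1/r) - f(1/R0)`, exactly
#' `(xi a0 / 2r)(1/r - 2 H0) - (xi a0 / 2 R0)(1/R0 - 2 H0)`; with
#' `limit = TRUE` the leading form for `R0 >> r`,
#' `(xi a0 / 2r)(1/r - 2 H0) = (2 kc a0 / r)(1/r - c0)` with `kc = xi/4`
#' and `c0 = 2 H0` (the aggregate-level bending constant and spontaneous
#' curvature under which the exact and limit forms coincide). `Delta f < 0`
#' whenever `c0 r > 1` in the limit form.
#'
#' @param system an [aggregation_system()].
#' @param limit use the `R0 >> r` limit form.
#' @return energy difference.
#' @export
delta_f_isotropic <- function(system, limit = FALSE) {
  if (limit)
    return(with(system, xi * a0 / (2 * r) * (1 / r - 2 * H0)))
  monomer_energy(system, 1 / system$r) - monomer_energy(system, 1 / system$R0)
}

#' Aggregate-level bending constant and spontaneous curvature
#' @param system an [aggregation_system()].
#' @return list with `kc = xi/4` and `c0 = 2 H0`.
#' @export
aggregate_helfrich <- function(system) {
  list(kc = system$xi / 4, c0 = 2 * system$H0)
}

#' Per-monomer energy difference for anisotropic cylindrical aggregates
#'
#' For cylindrical aggregates where the membrane has `H = D = 1/(2r)`:
#' `Delta f = a0 xi H (H - Hm) - kT ln I0(a0 xi Dm D / kT)`, `I0` the
#' modified Bessel function of order zero (orientational averaging of the
#' deviatoric coupling).
#'
#' @param xi,a0 elastic constant and area per nanodomain.
#' @param H,D membrane mean curvature and deviator at the aggregate.
#' @param Hm,Dm intrinsic mean and deviatoric curvature of the nanodomain.
#' @param kT thermal energy.
#' @return energy difference.
#' @export
delta_f_anisotropic <- function(xi, a0, H, Hm, D, Dm, kT = 1) {
  x <- a0 * xi * Dm * D / kT
  # log I0 computed stably via the exponentially scaled Bessel function
  logI0 <- log(besselI(abs(x), 0, expon.scaled = TRUE)) + abs(x)
  a0 * xi * H * (H - Hm) - kT * logI0
}

#' Critical aggregation concentration
#'
#' `x_c~ = exp((Delta f - w)/kT)`: the monomer density in the weakly curved
#' membrane above which unbounded growth of curved (necklace) aggregates
#' becomes favorable. With `limit = TRUE`, the `R0 >> r` form
#' `exp(2 kc a0 (1 - c0 r)/(kT r^2) - w/kT)`.
#'
#' @param system an [aggregation_system()] (constant `w` required).
#' @param limit use the limit form of `Delta f`.
#' @return dimensionless critical concentration.
#' @export
critical_concentration <- function(system, limit = FALSE) {
  w <- system$w(1L)
  exp((delta_f_isotropic(system, limit = limit) - w) / system$kT)
}

#' Equilibrium monomer and aggregate-size distribution
#'
#' Minimizing the lattice free energy with a Lagrange multiplier `mu`
#' enforcing nanodomain conservation gives
#' `x1~ = exp(-(fsp - mu)/kT)` and `x_i = i q^i` with
#' `q = exp(-(fc - w - mu)/kT)`; the conservation condition
#' `x1~ + sum_i x_i = N/M` is solved for `mu` using the closed-form
#' geometric tail `sum i q^i = q/(1-q)^2`. A solution with `q < 1` always
#' exists for finite density, but the distribution is physical only while
#' every `x_i <= 1`; once the root crosses the density at which
#' `max_i i q^i` reaches unity the input is flagged supersaturated
#' (unbounded-growth regime, `x1~` above the critical concentration up to
#' the approximation's prefactor).
#'
#' @param system an [aggregation_system()] with constant `w`.
#' @param i_max number of aggregate sizes to tabulate in the output.
#' @param tol root tolerance on the conservation residual.
#' @return object of class `aggregate_distribution`: `x1` (monomers in the
#'   weakly curved region), `xi` (densities for sizes `1..i_max`), `mu`,
#'   `q`, `x_crit`, `supersaturated`, `residual`.
#' @export
equilibrium_distribution <- function(system, i_max = 100L, tol = 1e-12) {
  if (is.na(system$w_const))
    stop("equilibrium_distribution requires constant w")
  kT <- system$kT
  fc <- monomer_energy(system, 1 / system$r)
  fsp <- monomer_energy(system, 1 / system$R0)
  w <- system$w(1L)
  # x1~ = q * exp((fc - w - fsp)/kT) = q / x_c~ * ... : express via q
  A <- exp((fc - w - fsp) / kT)    # x1~ = A q ; A = 1/x_c~
  total <- function(q) A * q + q / (1 - q)^2
  rho <- system$rho
  # lower bracket guaranteed below the root even for very large A
  # (q/(1-q)^2 <= 2q on q < 0.3)
  eps <- min(1e-15, rho / (2 * (A + 2)))
  f <- function(q) total(q) - rho
  sol <- stats::uniroot(f, lower = eps, upper = 1 - 1e-9, tol = tol,
                        extendInt = "no")
  q <- sol$root
  # polish with a few Newton steps on the smooth monotone total()
  for (it in 1:8) {
    g <- total(q) - rho
    dg <- A + (1 + q) / (1 - q)^3
    qn <- q - g / dg
    if (qn > 0 && qn < 1) q <- qn
  }
  x1 <- A * q
  xi <- seq_len(i_max) * q^seq_len(i_max)
  x_crit <- exp((fc - fsp - w) / kT)
  # physical bound x_i <= 1: the largest x_i sits at i* = -1/ln(q)
  xi_peak <- if (q < 1) {
    istar <- max(1, round(-1 / log(q)))
    istar * q^istar
  } else Inf
  supersat <- xi_peak > 1 || q >= 1 - 1e-9
  structure(list(x1 = x1, xi = xi, mu = fc - w + kT * log(q), q = q,
                 x_crit = x_crit, supersaturated = supersat,
                 residual = total(q) - rho,
                 rho = rho),
            class = "aggregate_distribution")
}

#' @export
print.aggregate_distribution <- function(x, ...) {
  cat(sprintf(
    "aggregate_distribution: x1~ = %.4g, q = %.4g, x_c~ = %.4g%s\n",
    x$x1, x$q, x$x_crit,
    if (x$supersaturated) " [supersaturated]" else ""))
  invisible(x)
}

#' Scan the growth-favorability boundary over density and temperature
#'
#' For each `(rho, kT)` pair, solves the equilibrium distribution and
#' reports whether the monomer density has reached the critical
#' concentration (growth of long necklace aggregates favorable).
#'
#' @param system template [aggregation_system()]; `rho` and `kT` are
#'   overridden by the scan grids.
#' @param rho_grid densities to scan; `kT_grid` temperatures to scan.
#' @param kT_grid see above.
#' @return data.frame with columns `rho`, `kT`, `x1`, `x_crit`,
#'   `favorable`.
#' @export
phase_boundary_scan <- function(system, rho_grid, kT_grid) {
  out <- expand.grid(rho = rho_grid, kT = kT_grid)
  res <- lapply(seq_len(nrow(out)), function(i) {
    sys <- system
    sys$rho <- out$rho[i]; sys$kT <- out$kT[i]
    d <- equilibrium_distribution(sys)
    c(x1 = d$x1, x_crit = d$x_crit, favorable = as.numeric(d$supersaturated))
  })
  cbind(out, do.call(rbind, res))
}
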