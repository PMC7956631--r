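#' Tangent-angle Fourier profile of an axisymmetric closed membrane
#'
#' An axisymmetric closed surface is described by the angle `Theta(s)` of the
#' tangent to the meridional contour, as a function of arc length
#' `s in [0, Ls]`:
#' \deqn{\Theta(s) = \Theta_0 s/L_s + \sum_{i=1}^N a_i \sin(\pi i s / L_s),}
#' with `Theta_0 = pi` fixed so that `Theta(0) = 0` and `Theta(Ls) = pi`
#' hold exactly by construction. The contour radius and height follow by
#' quadrature of `cos Theta` and `sin Theta`; closure of the south pole
#' (`r(Ls) = 0`) is *not* automatic and is enforced as a constraint during
#' minimization.
#'
#' @param amplitudes numeric vector of Fourier amplitudes `a_i`.
#' @param Ls profile length (sets the overall scale; the shape depends on
#'   `s/Ls` only). Must be positive.
#' @return an object of class `shape_profile`.
#' @export
shape_profile <- function(amplitudes, Ls = pi) {
  amplitudes <- as.numeric(amplitudes)
  if (length(amplitudes) < 1L) stop("need at least one Fourier mode")
  if (!is.finite(Ls) || Ls <= 0) stop("Ls must be positive")
  structure(list(a = amplitudes, Ls = Ls, theta0 = pi,
                 n_modes = length(amplitudes)),
            class = "shape_profile")
}

#' @export
print.shape_profile <- function(x, ...) {
  cat(sprintf("shape_profile: %d Fourier modes, Ls = %.6g\n", x$n_modes, x$Ls))
  cat("  a[1..min(6,N)] =", signif(utils::head(x$a, 6), 4), "\n")
  invisible(x)
}

#' Evaluate the tangent angle Theta(s)
#'
#' @param profile a [shape_profile()].
#' @param s arc-length position(s), all in `[0, Ls]`.
#' @return tangent angle(s) in radians.
#' @export
theta_of_s <- function(profile, s) {
  if (any(s < -1e-12 * profile$Ls | s > profile$Ls * (1 + 1e-12)))
    stop("s outside [0, Ls]")
  t <- s / profile$Ls
  th <- profile$theta0 * t
  for (i in seq_along(profile$a))
    th <- th + profile$a[i] * sin(pi * i * t)
  th
}

.basis_cache <- new.env(parent = emptyenv())

# 4th-order end-corrected trapezoid weights (Euler-Maclaurin corrected)
.trap_w <- function(n, h) {
  w <- rep(h, n)
  w[c(1L, n)] <- 3 / 8 * h
  w[c(2L, n - 1L)] <- 7 / 6 * h
  w[c(3L, n - 2L)] <- 23 / 24 * h
  w
}

# 4th-order cumulative quadrature on a uniform grid: each subinterval
# integrates the local cubic through its four nearest points
.cumquad <- function(y, h) {
  n <- length(y)
  if (n < 4L) return(c(0, cumsum((y[-1] + y[-n]) * h / 2)))
  inc <- numeric(n - 1L)
  i <- 2:(n - 2L)
  inc[i] <- h / 24 * (-y[i - 1L] + 13 * y[i] + 13 * y[i + 1L] - y[i + 2L])
  inc[1L] <- h / 24 * (9 * y[1L] + 19 * y[2L] - 5 * y[3L] + y[4L])
  inc[n - 1L] <- h / 24 * (9 * y[n] + 19 * y[n - 1L] - 5 * y[n - 2L] +
                             y[n - 3L])
  c(0, cumsum(inc))
}

# column-wise 4th-order cumulative quadrature for an n x m matrix
.cumquad_mat <- function(Y, h) {
  n <- nrow(Y)
  inc <- matrix(0, n - 1L, ncol(Y))
  i <- 2:(n - 2L)
  inc[i, ] <- h / 24 * (-Y[i - 1L, , drop = FALSE] +
                          13 * Y[i, , drop = FALSE] +
                          13 * Y[i + 1L, , drop = FALSE] -
                          Y[i + 2L, , drop = FALSE])
  inc[1L, ] <- h / 24 * (9 * Y[1L, ] + 19 * Y[2L, ] - 5 * Y[3L, ] + Y[4L, ])
  inc[n - 1L, ] <- h / 24 * (9 * Y[n, ] + 19 * Y[n - 1L, ] -
                               5 * Y[n - 2L, ] + Y[n - 3L, ])
  rbind(0, apply(inc, 2, cumsum))
}

# plain trapezoid kept for non-smooth integrands (fixture projection)
.cumtrapz <- function(y, h) {
  n <- length(y)
  c(0, cumsum((y[-1] + y[-n]) * h / 2))
}

#' Discretize a shape profile into a surface grid
#'
#' Computes `r`, `z` by cumulative trapezoid quadrature of `cos Theta`,
#' `sin Theta` on a uniform arc-length grid, the principal curvatures
#' (`C1 = dTheta/ds` meridional, `C2 = sin Theta / r` azimuthal, the pole
#' limit `C2 -> C1` applied at the end points), mean curvature, curvature
#' deviator, Gaussian curvature, area elements, total area/volume and the
#' reduced volume.
#'
#' @param profile a [shape_profile()].
#' @param n_grid number of grid intervals (>= 64); the grid has
#'   `n_grid + 1` points including both poles.
#' @param r_tol negative-radius tolerance (relative to `Ls`); a radius below
#'   `-r_tol*Ls` raises an invalid-profile error.
#' @return an object of class `surface_grid`.
#' @export
integrate_profile <- function(profile, n_grid = 1000L, r_tol = 1e-6) {
  if (n_grid < 64L) stop("n_grid must be >= 64")
  Ls <- profile$Ls
  n <- as.integer(n_grid) + 1L
  s <- seq(0, Ls, length.out = n)
  h <- Ls / n_grid
  t <- s / Ls
  a <- profile$a
  N <- length(a)
  im <- seq_len(N)
  # Theta and its exact derivative (sine/cosine basis cached per grid size)
  key <- paste(n, N)
  bas <- .basis_cache[[key]]
  if (is.null(bas)) {
    bas <- list(SM = sin(outer(pi * t, im)), CM = cos(outer(pi * t, im)))
    .basis_cache[[key]] <- bas
  }
  th  <- pi * t + drop(bas$SM %*% a)
  dth <- pi / Ls + drop(bas$CM %*% (a * pi * im / Ls))
  cth <- cos(th); sth <- sin(th)
  r <- .cumquad(cth, h)
  z <- .cumquad(sth, h)
  if (min(r) < -r_tol * Ls)
    stop("invalid profile: negative radius (self-penetrating parameterization)")
  neg_r2 <- sum(.trap_w(n, h) * pmin(r, 0)^2)   # pre-clamp defect measure
  r[r < 0] <- 0
  C1 <- dth
  C2 <- sth / pmax(r, 1e-9)
  C2[c(1L, n)] <- C1[c(1L, n)]          # removable singularity at the poles
  H <- (C1 + C2) / 2
  D <- (C1 - C2) / 2
  K <- C1 * C2
  w <- .trap_w(n, h)
  dS <- 2 * pi * r * w                  # quadrature weight for surface integrals
  S <- sum(dS)
  V <- pi * sum(w * r^2 * sth)
  if (S <= 1e-14) stop("degenerate surface: zero area")
  R0 <- sqrt(S / (4 * pi))
  v <- V / (4 * pi * R0^3 / 3)
  structure(list(s = s, theta = th, r = r, z = z,
                 C1 = C1, C2 = C2, H = H, D = D, K = K,
                 dS = dS, S = S, V = V, R0 = R0, v = v,
                 closure = r[n], Ls = Ls, h = h, n = n, neg_r2 = neg_r2),
            class = "surface_grid")
}

#' @export
print.surface_grid <- function(x, ...) {
  cat(sprintf(
    "surface_grid: %d points, S = %.6g, V = %.6g, v = %.4f, |r(Ls)| = %.3g\n",
    x$n, x$S, x$V, x$v, abs(x$closure)))
  invisible(x)
}

#' Principal curvatures at a grid point
#'
#' Meridional-first convention: `C1 = dTheta/ds`, `C2 = sin(Theta)/r`; the
#' deviator `D = (C1 - C2)/2` is signed.
#'
#' @param grid a [integrate_profile()] result.
#' @param k grid point index (1-based).
#' @return named numeric vector `(C1, C2, H, D, K)`.
#' @export
curvatures_at <- function(grid, k) {
  c(C1 = grid$C1[k], C2 = grid$C2[k], H = grid$H[k],
    D = grid$D[k], K = grid$K[k])
}

#' Reduced volume of a closed surface
#'
#' `v = V / (4 pi R0^3 / 3)` with `R0 = sqrt(S / 4 pi)`; scale-invariant,
#' equal to 1 only for the sphere.
#'
#' @param grid a `surface_grid`.
#' @return dimensionless reduced volume.
#' @export
reduced_volume <- function(grid) {
  if (grid$S <= 1e-14) stop("degenerate surface")
  grid$v
}

#' Project a spheroid contour onto the Fourier tangent-angle basis
#'
#' Builds a `shape_profile` whose contour approximates the spheroid with
#' equatorial semi-axis 1 and polar semi-axis `c_axis` (prolate for
#' `c_axis > 1`, oblate for `c_axis < 1`). The spheroid tangent angle is
#' sampled along arc length and its deviation from the linear ramp is
#' expanded in the sine basis.
#'
#' @param c_axis polar-to-equatorial axis ratio.
#' @param n_modes number of Fourier modes retained.
#' @param n_sample number of contour samples used in the projection.
#' @return a [shape_profile()].
#' @export
spheroid_profile <- function(c_axis, n_modes = 30L, n_sample = 4000L) {
  # contour: r = sin(u), z = -c*cos(u), u in [0, pi]
  u <- seq(0, pi, length.out = n_sample + 1L)
  dr <- cos(u); dz <- c_axis * sin(u)
  ds <- sqrt(dr^2 + dz^2)
  s <- .cumtrapz(ds, u[2] - u[1])
  Ls <- s[length(s)]
  th <- atan2(dz, dr)   # in [0, pi] for this contour
  t <- s / Ls
  resid <- th - pi * t
  a <- vapply(seq_len(n_modes), function(i) {
    y <- resid * sin(pi * i * t)
    # trapezoid in t with non-uniform spacing
    2 * sum((y[-1] + y[-length(y)]) / 2 * diff(t))
  }, numeric(1))
  shape_profile(a, Ls = Ls)
}

#' Spheroid surface area and volume (closed form)
#'
#' Oracle used in tests: area and volume of a spheroid with equatorial
#' semi-axis `a` and polar semi-axis `c`.
#'
#' @param a equatorial semi-axis.
#' @param c polar semi-axis.
#' @return list with `S`, `V`, and reduced volume `v`.
#' @export
spheroid_closed_form <- function(a, c) {
  V <- 4 / 3 * pi * a^2 * c
  if (abs(c - a) < 1e-12 * a) {
    S <- 4 * pi * a^2
  } else if (c < a) {            # oblate
    e <- sqrt(1 - c^2 / a^2)
    S <- 2 * pi * a^2 * (1 + (1 - e^2) / e * atanh(e))
  } else {                       # prolate
    e <- sqrt(1 - a^2 / c^2)
    S <- 2 * pi * a^2 * (1 + c / (a * e) * asin(e))
  }
  R0 <- sqrt(S / (4 * pi))
  list(S = S, V = V, v = V / (4 * pi * R0^3 / 3))
}

#' Seed profiles for the shape branches
#'
#' Named starting contours used by the branch-following minimizer:
#' `"sphere"` (all amplitudes zero), `"oblate"` (flattened spheroid),
#' `"prolate"` (elongated spheroid), and `"stomatocyte"` (an axisymmetric
#' invaginated contour whose tangent angle overshoots `pi` and returns).
#' For the spheroids, `v` selects the axis ratio reproducing that reduced
#' volume.
#'
#' @param type one of `"sphere"`, `"oblate"`, `"prolate"`, `"stomatocyte"`.
#' @param v target reduced volume used to pick the spheroid axis ratio
#'   (ignored for `"sphere"`; for `"stomatocyte"` a fixed deeply invaginated
#'   seed is returned and `v` is only used by the caller's constraints).
#' @param n_modes number of Fourier modes.
#' @return a [shape_profile()].
#' @export
seed_profile <- function(type = c("sphere", "oblate", "prolate", "stomatocyte"),
                         v = 0.65, n_modes = 30L) {
  type <- match.arg(type)
  if (type == "sphere") return(shape_profile(rep(0, n_modes), Ls = pi))
  if (type == "stomatocyte") {
    # deeply invaginated contour (near-complete outer sphere, narrow mouth,
    # inner cap of about half the outer radius; reduced volume about 0.59),
    # built by projecting a piecewise circular-arc tangent-angle curve onto
    # the sine basis and verifying closure numerically
    a_sto <- c(1.571293, -1.160777, 0.597403, 0.014102, -0.319098,
               0.235148, 0.010399, -0.147556, 0.102692, 0.009764,
               -0.063262, 0.040262, -0.000114, -0.015077, 0.012843,
               -0.011822, 0.009294, 0.004101, -0.019259, 0.01705,
               0.003335, -0.019961, 0.015057, 0.003738, -0.014926,
               0.009481, 0.002235, -0.00723, 0.004595, -0.001192)
    a <- rep(0, max(n_modes, length(a_sto)))
    a[seq_along(a_sto)] <- a_sto
    return(shape_profile(a[seq_len(max(n_modes, length(a_sto)))], Ls = pi))
  }
  if (v > 0.999) return(shape_profile(rep(0, n_modes), Ls = pi))
  target <- function(c_axis) spheroid_closed_form(1, c_axis)$v - v
  interval <- if (type == "oblate") c(0.05, 0.999) else c(1.001, 12)
  c_axis <- stats::uniroot(target, interval, tol = 1e-10)$root
  spheroid_profile(c_axis, n_modes = n_modes)
}

#' Write a shape profile table to CSV
#'
#' Columns: `s, theta, r, z, C1, C2, H, D` and optionally `phi`.
#'
#' @param grid a `surface_grid`.
#' @param path output file path.
#' @param phi optional per-point relative area density column.
#' @return the path, invisibly.
#' @export
write_profile_csv <- function(grid, path, phi = NULL) {
  df <- data.frame(s = grid$s, theta = grid$theta, r = grid$r, z = grid$z,
                   C1 = grid$C1, C2 = grid$C2, H = grid$H, D = grid$D)
  if (!is.null(phi)) df$phi <- phi
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a profile table written by [write_profile_csv()]
#' @param path CSV path.
#' @return data.frame of the profile columns.
#' @export
read_profile_csv <- function(path) utils::read.csv(path)

#' Revolve a contour into a triangulated surface mesh
#'
#' Rotates the meridional contour about the z axis and triangulates the
#' resulting quad strips, capping the poles with triangle fans.
#'
#' @param grid a `surface_grid`.
#' @param n_phi number of azimuthal divisions.
#' @param n_s number of contour samples used (subsampled from the grid).
#' @return list with `vertices` (n x 3) and `triangles` (m x 3, 1-based).
#' @export
revolve_mesh <- function(grid, n_phi = 64L, n_s = 100L) {
  idx <- unique(round(seq(1, grid$n, length.out = n_s)))
  r <- grid$r[idx]; z <- grid$z[idx]
  ns <- length(idx)
  phi <- seq(0, 2 * pi, length.out = n_phi + 1L)[-(n_phi + 1L)]
  # interior rings (exclude poles)
  rings <- 2:(ns - 1L)
  nv <- length(rings) * n_phi + 2L
  Vm <- matrix(0, nv, 3)
  Vm[1, ] <- c(0, 0, z[1])
  k <- 2L
  for (i in rings) {
    Vm[k:(k + n_phi - 1L), ] <- cbind(r[i] * cos(phi), r[i] * sin(phi), z[i])
    k <- k + n_phi
  }
  Vm[nv, ] <- c(0, 0, z[ns])
  ring_start <- function(j) 2L + (j - 1L) * n_phi   # j-th interior ring
  tri <- list()
  # top fan
  s1 <- ring_start(1L)
  for (p in seq_len(n_phi)) {
    q <- p %% n_phi + 1L
    tri[[length(tri) + 1L]] <- c(1L, s1 + p - 1L, s1 + q - 1L)
  }
  for (j in seq_len(length(rings) - 1L)) {
    sa <- ring_start(j); sb <- ring_start(j + 1L)
    for (p in seq_len(n_phi)) {
      q <- p %% n_phi + 1L
      tri[[length(tri) + 1L]] <- c(sa + p - 1L, sb + p - 1L, sb + q - 1L)
      tri[[length(tri) + 1L]] <- c(sa + p - 1L, sb + q - 1L, sa + q - 1L)
    }
  }
  sl <- ring_start(length(rings))
  for (p in seq_len(n_phi)) {
    q <- p %% n_phi + 1L
    tri[[length(tri) + 1L]] <- c(nv, sl + q - 1L, sl + p - 1L)
  }
  list(vertices = Vm, triangles = do.call(rbind, tri))
}
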