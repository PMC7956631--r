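---
title: "Membrane mechanics of closed vesicle shapes: models and numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Membrane mechanics of closed vesicle shapes: models and numerics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(memshape)
```

# Scope

`memshape` models closed lipid-membrane shapes at two levels of
description: a continuum axisymmetric level, where equilibrium shapes are
found by constrained minimization of curvature-elastic free energies over
a Fourier tangent-angle parameterization, and a discrete level, where a
dynamically triangulated fluid surface is evolved by Metropolis Monte
Carlo. Around these sit an analytic self-assembly theory for laterally
mobile curved nanodomains and a microscopic mapping from rigid cone-like
inclusion geometry to effective nanodomain elastic parameters.

# The continuum models

## Shape representation

An axisymmetric closed surface is generated by rotating a meridional
contour about the z axis. The contour is described by the tangent angle
$\Theta(s)$ as a function of arc length $s \in [0, L_s]$,

$$\Theta(s) = \pi\,\frac{s}{L_s} + \sum_{i=1}^{N} a_i
  \sin\!\left(\frac{\pi i s}{L_s}\right),$$

so $\Theta(0)=0$ and $\Theta(L_s)=\pi$ hold identically; the radius and
height follow by quadrature of $\cos\Theta$ and $\sin\Theta$. Closure of
the second pole, $r(L_s)=0$, is *not* automatic in this basis and is
enforced as a constraint. The principal curvatures are
$C_1 = d\Theta/ds$ (meridional) and $C_2 = \sin\Theta/r$ (azimuthal);
$H=(C_1+C_2)/2$, and the curvature deviator $D=(C_1-C_2)/2$ is kept
*signed* in this convention (it changes sign across necks). At the poles
$C_2$ has a removable singularity and is replaced by its limit $C_1$.

Because the shape depends on $s/L_s$ only, the package fixes $L_s=\pi$
and removes the overall scale by rescaling every computed surface to unit
reference radius $R_0=\sqrt{S/4\pi}$. All lengths are therefore reported
in units of $R_0$, curvatures in $1/R_0$, and energies in units of the
reference bending modulus ($k_c$ for Helfrich and BAR runs, $\kappa_B$
for two-component runs). The reduced volume $v = V/(4\pi R_0^3/3)$ is
scale invariant; $v=1$ only for the sphere.

## Energy functionals

* **Single-element (deviatoric) density.** The energy of a membrane
  element with intrinsic curvatures $(H_m, D_m)$ rotated by $\omega$
  relative to the surface principal frame is
  $w = (2K_1+K_2)(H-H_m)^2 - K_2\,(D^2 - 2DD_m\cos 2\omega + D_m^2)$,
  derived from the trace and determinant of the curvature mismatch
  tensor. Stability of the minimum at $(H_m, D_m)$ requires
  $-K_2(2K_1+K_2) > 0$.
* **Helfrich limit.** For isotropic elements ($D_m=0$) the density
  reduces, up to curvature-independent constants, to
  $w_b = \tfrac{k_c}{2}(2H-C_0)^2 + k_G K$ with $k_c=K_1$, $k_G=K_2$ and
  $C_0=(2+K_2/K_1)H_m$. The Gaussian term is a topological constant for
  closed shapes and is excluded from minimization (computed on request
  for reporting).
* **Two-component membranes.** Components A and B with local area
  fraction $\phi$ of A: the rigidity and intrinsic curvatures
  interpolate linearly in $\phi$, and the mixing entropy
  $F_{mix} = \frac{k_BT}{a_0}\int [\phi\ln\phi + (1-\phi)\ln(1-\phi)]\,dS$
  is added (toggleable; some study conditions exclude it). $0\ln 0$ is
  defined as 0 and $\phi$ is clipped to $[10^{-12}, 1-10^{-12}]$ inside
  the logarithms only.
* **BAR domains.** An attached rod-like domain of intrinsic curvature
  $C_p$ sees, by Euler's relation, the line curvature
  $C(\omega)=H+D\cos 2\omega$ and carries
  $w_{bar} = \tfrac{K_pL_0}{2}(C-C_p)^2$. Its equilibrium orientation
  satisfies $\cos 2\omega = (C_p - H)/D$ where that ratio lies in
  $[-1,1]$; otherwise the better of the boundary angles $0$, $\pi/2$ is
  taken, and $D=0$ leaves the orientation undefined (flagged, not an
  error).
* **Skeleton shear.**
  $F_{shear} = \tfrac{\mu}{2}\int(\lambda_m^2+\lambda_m^{-2}-2)\,dS$.
  The source model states lateral incompressibility of the skeleton but
  not how $\lambda_m$ follows from a shape; here the reference skeleton
  is the equal-area sphere (configurable), material circles are matched
  by equal area-from-pole, and incompressibility closes the system via
  $\lambda_\phi = r/r_{ref}$, $\lambda_m = 1/\lambda_\phi$. The quotient
  $r/r_{ref}$ is ill-conditioned where both radii vanish (the poles);
  values there are filled from the nearest well-conditioned interior
  point, which affects the energy negligibly since the area element also
  vanishes.
* **Non-local (area-difference) bending.**
  $F_h = \tfrac{k_c}{2}\int (2H)^2 dS + k_n S(\langle H\rangle - H_0)^2$
  with $\langle H\rangle$ the area-averaged mean curvature; in reduced
  units the normalized spontaneous average curvature equals the
  normalized optimal monolayer area difference, $h_0 = \Delta s_0$.

## The signed-deviator question

The aligned two-component density is written in the source model as
$(D-D_m)^2$ after setting $\omega=0$, but the element orientation is a
free degree of freedom, and minimizing the full $\omega$-dependent
density with $K_2=-K_1$ gives exactly
$K_1(H-H_m)^2 + K_1(|D|-|D_m|)^2$. The package treats the unsigned form
as the default physical choice (elements reorient freely) and verifies
the identity against a brute-force $\omega$ scan in the tests; the
signed, frame-locked form is available via `signed_deviator = TRUE`.
With the meridional-first convention the two differ precisely where $D$
changes sign (necks), which is where saddle-like components act.

## Constrained minimization

The free energy is minimized over the Fourier amplitudes (and, for
models with a lateral density field, over the tanh-profile variables
$\chi$, $s_0$, $\phi_{1A}$, $\phi_{2A}$, co-optimized in one vector) at
nonlinear constraints on closure, the reduced volume, the average
density $\phi_{ave}$, and, when a cytoskeletal rod is modelled, a
minimal pole-to-pole height $h_{min}$. Constraints are handled by an
augmented-Lagrangian scheme — quadratic penalties with multipliers,
weights escalated tenfold when a residual fails to shrink — around a
BFGS core. The pure Helfrich model with $C_0=0$ uses an exact analytic
gradient of the discretized functional; other models use central finite
differences. Two numerical safeguards matter:

* transient iterates can push the radius negative; the bending integrand
  uses $|r|$ as the area factor (exact on valid shapes, nonnegative
  always) together with a smooth negative-radius penalty, because a hard
  rejection wall strands the line search;
* the density-profile variables are transformed ($\phi_{1A}$,
  $\phi_{2A}$, $s_0/L_s$ through a logistic map, $\chi$ through a capped
  exponential) so every trial point is admissible.

Defaults: 30 Fourier modes (protrusion-rich problems use 36–40), 1000
quadrature intervals (600 for the multi-step scan problems), composite
4th-order quadrature (end-corrected trapezoid weights and a cubic
cumulative rule), gradient-stage tolerance $10^{-13}$, constraint
tolerances $10^{-4}$ on $v$ and $\phi_{ave}$, $10^{-6} L_s$ on closure.
Branch structure (oblate/prolate/stomatocyte) is handled by
warm-started continuation from branch-specific seed contours — flattened
and elongated spheroids projected onto the sine basis, and a deeply
invaginated piecewise circular-arc contour for the stomatocyte branch —
each continued from its stable end of the scan range. Phase boundaries
are located by bisection on the branch energy difference; grid points at
which the two minimizations collapse onto the same branch are detected
(energy difference numerically zero) and carry no crossing information.

Stability boundaries recomputed this way land at $v^\ast = 0.651$
(oblate–prolate) and $v^\ast = 0.591$ (oblate–stomatocyte) on a
$\Delta v = 0.01$ scan with bisection refinement to $\Delta v \le 0.005$.

## Protrusion descriptors

For rod-stretching sequences the package reports the protrusion radius
(area-weighted mean radius over the tip 30% of the protrusion side), the
pole-to-pole height, the density segregation, and the density-weighted
mean BAR orientation on the protrusion. The protrusion side is the pole
side of the widest circle carrying the higher mean density. Protrusion
*elongation* is tracked by the pole-to-pole height: at fixed reduced
volume and fixed body size this is the tube growth, and it is monotone
through bead-to-tube transitions where a tip-to-waist distance is not.

# Self-assembly of curved nanodomains

$N$ laterally mobile nanodomains on $M$ lattice sites, single-domain
elastic energy $f(H) = \tfrac{\xi}{2}(H-H_0)^2 a_0$. Monomers in the
weakly curved parent membrane ($H = 1/R_0$) exchange with aggregates of
constant high curvature $H=1/r$ (spherical beads or necklaces,
$r \ll R_0$), each aggregated monomer gaining a direct interaction
energy $w \ge 0$ (size-independent by default; a callable $w(i)$ is
accepted). Minimizing the lattice free energy with a Lagrange multiplier
enforcing conservation gives $\tilde x_1 = e^{-(f_{sp}-\mu)/kT}$ and
$x_i = i\,q^i$ with $q = e^{-(f_c - w - \mu)/kT}$; conservation is
solved for $\mu$ through the closed-form geometric tail
$\sum_i i q^i = q/(1-q)^2$ with a bracketed root in $q$ (the lower
bracket is scaled as $\rho/2(A+2)$ so extreme energy scales cannot break
the bracket). A mathematical root with $q<1$ exists for any finite
density, so "supersaturation" is flagged through the physical bound
$x_i \le 1$: once $\max_i i q^i$ would exceed unity the distribution is
unphysical and unbounded aggregate growth is favorable; this coincides
with the monomer density reaching the critical aggregation concentration
$\tilde x_c = e^{(\Delta f - w)/kT}$ up to the order-one prefactor that
the approximate form of $\tilde x_c$ leaves open.

One parameterization subtlety: the $R_0 \gg r$ limit of $\Delta f$ is
quoted in the literature both as
$\tfrac{\xi a_0}{2r}(1/r - 2H_0)$ and as
$\tfrac{2 k_c a_0}{r}(1/r - c_0)$. These coincide only under the
correspondence $k_c = \xi/4$, $c_0 = 2H_0$, which the package adopts for
the aggregate-level Helfrich form (`aggregate_helfrich()`); with it the
exact and limit expressions for the critical concentration agree to
$10^{-6}$ at $R_0/r = 10^6$, as asserted in the tests.

For anisotropic (cylindrical) aggregates with $H=D=1/2r$ the per-monomer
difference acquires an orientational-average term,
$\Delta f = a_0\xi H(H-H_m) - kT\ln I_0(a_0\xi D_m D/kT)$, computed with
the exponentially scaled Bessel function for stability.

# Rigid-inclusion parameter map

A cone-like rigid protein with azimuthally varying cone angle
$\theta(\omega)=\bar\theta + \Delta\theta\cos 2\omega$, core radius
$r_0$ and monolayer decay length $\zeta$ perturbs the surrounding
monolayer with a wall-contact energy density per unit circumference

$$\tilde f(C, \theta) = \frac{\kappa_0}{2\zeta}(\theta - Cr_0)^2
   + \kappa_0 (C_0 - C)(\theta - C r_0).$$

(The second term carries the modulus $\kappa_0$; without it the
expression is dimensionally inconsistent, and with it the closed-form
parameter map below follows exactly.) Averaging over the azimuth with
$C(\omega) = H + D\cos 2\omega$ and matching the quadratic form of the
single-element density yields

$$H_m = \frac{\bar\theta}{r_0}\frac{r_0+\zeta}{r_0+2\zeta}
      + \frac{\zeta C_0}{r_0+2\zeta},\quad
  D_m = \frac{\Delta\theta}{r_0}\frac{r_0+\zeta}{r_0+2\zeta},\quad
  K_1 = \frac{3\pi}{4} r_0^2 \kappa_0\left(\frac{r_0}{\zeta}+2\right),
  \quad K_2 = -\frac{2}{3}K_1.$$

`wall_energy_quadrature()` recomputes the same parameters by numerical
azimuthal integration (512 uniform points — exact to machine precision
for this low-order trigonometric polynomial) and a least-squares fit on
a 5×5 grid of $(H, D)$ around zero, discarding the additive constant;
the module's central test matches the two routes to $10^{-8}$ over three
decades of $r_0/\zeta$. The decay length $\zeta$ is a direct input
(typically about 1 nm for a lipid monolayer); its microscopic origin is
outside this package's scope.

# The triangulated Monte-Carlo vesicle

A fixed-topology closed triangulated surface of $N$ vertices (icosphere
initial condition, $10\cdot 4^n + 2$ vertices at subdivision $n$,
default 2–3 for desk-scale runs) with hard tether constraints
$d_{min} \le |b| \le d_{max} = 1.7\,d_{min}$ on every bond. One sweep is
one attempted displacement per vertex, uniform in a sphere of radius
$0.15\,d_{min}$ (rejected outright if a tether leaves the band or an
incident triangle degenerates or inverts), followed by $3N$ random
bond-flip attempts (rejected if the new bond violates the band, the new
edge already exists, an endpoint would drop below degree 3, or a new
triangle degenerates). Each surviving attempt is accepted with
probability $\min(1, e^{-\Delta W/kT})$.

The energy is $W = W_b + W_d + W_F$:

* $W_b$: vertex-based Helfrich estimate
  $\sum_i \tfrac{\kappa}{2}(2H_i - c_i)^2 A_i$ with the cotangent
  Laplace operator and barycentric dual areas, the sign of $H_i$ taken
  from the outward vertex normal; $c_i = c$ at nanodomain vertices and 0
  elsewhere; the Gaussian term is omitted (fixed topology). The operator
  reproduces $8\pi\kappa$ on icospheres within 2% at subdivision 2 with
  monotonically decreasing error under refinement.
* $W_d = -w \sum_{i<j} \Theta(r_0 - r_{ij})$ over nanodomain pairs,
  boundary inclusive, with $r_{ij}$ the 3D Euclidean distance (an
  in-plane distance is not well defined on a discrete mesh at a range of
  a few bond lengths); default $r_0 = d_{max}$.
* $W_F = -F\sum_i \hat n_i \cdot x_i$ over nanodomain vertices, the
  active-force pseudo-energy ($F>0$ protrusive). This term is frame
  dependent; the enclosed-volume centroid is pinned to the origin at the
  start of every sweep before it is evaluated. With $F=0$ the sampler is
  a proper equilibrium method; with $F\neq 0$ it is used exactly as a
  steady-state driving term, and only the $F=0$ path is required to pass
  the equilibrium statistics tests.

Energy changes are evaluated incrementally over the affected vertex set
(the moved vertex and its neighbours; the four quad vertices for a
flip), and audited against full recomputation at a configurable cadence;
the observed drift is below $10^{-13}$ relative over $10^4$-sweep runs.
Mesh invariants (tether band, Euler characteristic 2, two triangles per
edge, minimum degree) can be checked after every sweep.

## Nanodomain mobility and the swap move

Nanodomains are vertex attributes; bond flips alone give them only slow
lateral mobility, and at $\kappa = 25\,kT$, $c = -1/d_{min}$ the
membrane relaxes so strongly around each domain that attribute moves
face multi-$kT$ barriers — from random initial conditions the dispersed
state survives $10^5$ sweeps essentially unchanged. The package
therefore provides an optional explicit swap move (Metropolis-accepted
exchange of the nanodomain flag along a random bond, preserving the
equilibrium distribution; `swap_rate` attempts per vertex per sweep,
default off). Even with swaps, nucleation of the aggregated state is
slower than desk-scale budgets, so the budding regime is validated by
*persistence*: a nucleated cluster (a bonded patch plus dispersed
remainder) is evolved at the stated parameters, yielding an ensemble
cluster-size histogram with a monomer peak and a separated large-size
peak and an inward-displaced cluster (invagination), while a control
with $w=0$, $c=0$ dissolves the same initial cluster. This demonstrates
what the equilibrium favours at those parameters without claiming to
traverse the nucleation barrier.

The active-force comparison (flattening/elongation at low nanodomain
density) contrasts time-averaged gyration-tensor shape anisotropy at
$F = 4\,kT/d_{min}$, $\kappa = 10\,kT$ against $F=0$: the driven runs
show a several-fold higher anisotropy. The force magnitude sits in the
strongly driven corner of the phase diagram, where the trend is robust
across seeds at desk scale.

# What the synthetic conditions do and do not show

The study conditions are carried by presets (`preset("fig21")`, etc.):
two-component runs use $\kappa_A = 8\kappa_B$, $\kappa_B = 30\,k_BT$,
$R_0 = 250$ nm, $a_0 = 100$ nm² (hence $a_0 = 0.0016\,R_0^2$ and
$k_BT = \kappa_B/30$ in reduced units); BAR runs use $C_p = 3/R_0$,
$K_pL_0/2 = k_c$, $\phi_{ave} = 0.25$; MC runs use $\kappa = 25\,kT$,
$w = 1.25\,kT$, $c = \pm 1/d_{min}$, 5% coverage. Continuum scans use
600–1000 quadrature intervals and 24–40 modes; MC correctness runs use
subdivision-2 meshes (162 vertices) and $10^4$–$2\times 10^4$ sweeps.
These sizes resolve the shape families and trends tested here; they do
not resolve fine necklace bead counts, echinocyte spicule fields
(non-axisymmetric by nature), or the slow aggregation kinetics of large
vesicles, and no test here speaks to the behaviour of real membranes
beyond the models' assumptions (fluid, tensionless, fixed topology,
single or two components).

# Known limitations

* The tanh density profile can represent one A-rich region only; a bump
  strictly interior to the arc (a neck between two B-rich caps) is
  approximated by placing the plateau edge at the neck.
* The unsigned-deviator two-component functional admits near-degenerate
  rippled minimizers at large $D_m\phi$ (microstructure the reduced
  model cannot penalize); trend metrics smooth $|D(s)|$ over 5% of the
  arc and exclude pole neighbourhoods.
* Stomatocyte contours touch themselves geometrically at deep
  invagination; self-contact is permitted, as is standard for these
  calculations.
* The MC simulator carries no volume or area constraint; vesicle shape
  is controlled by bending, attraction and force terms alone. With an
  active force it is a driven, not equilibrium, sampler.
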