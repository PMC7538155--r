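---
title: "Modelling interkinetic nuclear migration as nonlinear diffusion"
author: "iknm package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling interkinetic nuclear migration as nonlinear diffusion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iknm)
```

## The biological problem

In pseudostratified neuroepithelia such as the early zebrafish retina,
nuclei of proliferating progenitor cells shuttle between the apical and
basal tissue surfaces in step with the cell cycle (interkinetic nuclear
migration, IKNM). Mitosis happens only at the apical surface; during G1
and S the nuclei wander basally in an apparently random fashion. This
package treats that basal wandering as a tissue-scale transport problem:
divisions act as a localized apical source of nuclei, the resulting
concentration gradient drives a net basalward flux, and each individual
trajectory remains a random walk.

The package provides, as testable code, the whole chain from synthetic
3-D nuclear tracks to a fitted effective diffusion constant and its
physical interpretation:

1. a seeded generator of nuclear tracks with the statistical structure
   the analysis assumes (`simulate_population()`),
2. track geometry and kinematics (`to_radial()`,
   `cycle_normalized_kinematics()`, `neighbor_speed_correlation()`,
   `experimental_msd()`),
3. radial concentration profiles with a principled count-uncertainty
   model (`concentration_profile()`),
4. an exact eigenfunction solution of linear diffusion in a spherical
   shell with exponential apical influx (`linear_solution()`,
   `evaluate_linear()`),
5. a conservative solver for the nonlinear lattice-gas diffusion
   equation with a maximum packing concentration (`solve_nonlinear()`),
6. minimal chi-square estimation of the diffusion constant
   (`scan_D()`, `sigma_D()`, `p_chi()`, `welch_test()`),
7. closed-form biophysics (`stokes_einstein()`, `tube_drag()`,
   `gamma_strength()`, `close_packed_cmax()`),
8. equilibrium cell-membrane shapes (`solve_shape()`), and
9. Langevin simulations of single nuclei with crowding-dependent noise
   (`langevin_spec()`, `msd_envelope()`).

The numbered scripts under `analysis/` run these pieces in order as a
narrative workflow and write their tables under `results/`.

## Geometry and the diffusion models

The retina is idealized as a sector of a spherical shell around the
lens: basal surface at radius $b$, apical surface at $a$, observed solid
angle $\Omega$. With $\xi = r/a$, $\rho = b/a$ and $s = Dt/a^2$, the
linear model is

$$\partial_t c = \frac{D}{r^2}\,\partial_r\!\left(r^2 \partial_r c\right),$$

with a no-flux basal boundary and an apical influx equal to the division
rate per apical area, $D\,\partial_r c|_{r=a} = \frac{N_0}{S\tau}
e^{t/\tau}$, where $N(t) = N_0 e^{t/\tau}$, $\tau = T_P/\ln 2$, and $S =
\Omega a^2$. The solution is an eigenfunction series plus a quadratic
particular term growing as $e^{\sigma s}$:

* Eigenmodes $H_i(\xi) = \sin(\lambda_i(\xi - \rho) + \phi_i)/\xi$ with
  $\phi_i = \arctan(\rho\lambda_i)$; the no-flux pair makes the
  eigenvalues roots of $\lambda(1-\rho) = \arctan\lambda -
  \arctan(\rho\lambda) + k\pi$, solved by bracketed root finding (each
  branch is monotone). The zero mode is excluded; the modes are
  normalized under the weight $\xi^2$.
* The dimensionless influx amplitude and growth rate are $f_0 =
  N_0 a/(S\tau D)$ and $\sigma = a^2/(D\tau)$. The constant $g_0$ in the
  particular term is fixed by requiring that the particular term carries
  the entire mass $N_0 e^{\sigma s}$ — equivalently, that the constant-
  mode component of the particular term's PDE residual vanishes. The
  mode forcings $\alpha_i$ are the $\xi^2$-weighted projections of that
  residual onto the modes. These closed forms are validated against an
  independent method-of-lines integration (relative agreement better
  than 1% over 200 min; see `test-linear-model.R`), which we treat as
  the source of truth.
* The initial condition is projected from the measured $t=0$ profile by
  discrete quadrature over the profile bins. Because the modes carry no
  mass, the projected solution automatically integrates to $N_0$; for
  this to be consistent, $N_0$ must be the observed initial count. The
  default truncation is $M = 8$ modes — enough for smooth profiles
  (reconstruction error a few percent in $L^2$), few enough not to chase
  bin noise.

The nonlinear model replaces Fick's law with the lattice-gas form

$$\partial_t c = \frac{D}{r^2}\,\partial_r\!\left(r^2
\frac{c_{\max}}{c_{\max}-c}\,\partial_r c\right),$$

which diverges as the concentration approaches the close-packing limit
$c_{\max}$, and carries the same crowding factor in the influx boundary
condition. `solve_nonlinear()` discretizes this as a conservative finite
volume scheme on a staggered grid (the spherical metric $r^2$ handled
exactly, the mobility factor evaluated at face-averaged concentrations)
and integrates the stiff system implicitly (`deSolve::lsoda`, banded
Jacobian) with dense output at the native 2-min cadence. Defaults: 400
cells for stand-alone solves, 150–200 inside fitting loops; halving the
resolution changes the 200-min solution by well under 0.2% (order
$\geq 1.8$ self-convergence). If a solution reaches
$(1-10^{-6})c_{\max}$ the solver aborts naming the time — the model has
a genuine finite-time singularity there, and during a `scan_D()` such
candidate values of $D$ are scored as infinitely poor rather than
failing the scan. Setting `cmax = Inf` recovers the linear equation and
doubles as the method-of-lines oracle for the series solution.

## Profiles and the error model

Each measured radial position carries a uniform positional uncertainty
of $\pm\Delta r$ ($\Delta r = 3\,\mu$m by default). A nucleus therefore
contributes to a bin the fractional overlap of its error box, giving
$E(N_{\text{bin}}) = \sum_n p_{n,\text{bin}}$ and
$\mathrm{Var}(N_{\text{bin}}) = \sum_n p_{n,\text{bin}}
(1-p_{n,\text{bin}})$. Concentrations divide by the exact spherical
shell volumes $V_{\text{bin}} = \tfrac{\Omega}{3}(r_o^3 - r_i^3)$. Bins
are laid from the basal edge upward; a final partial apical bin keeps
its true, smaller volume. Bins within the apical/basal exclusion zones
(default 4 µm; nuclear centers cannot be closer to a surface than one
nuclear radius) are kept in the profile but dropped from fits.

The per-bin positional uncertainty entering the fits is taken as
$\sigma_x = \sqrt{\Delta r_{\text{bin}} \cdot 1\,\mu\text{m}}$ — i.e.
numerically the square root of the bin width in µm — converted to $\xi$
units by $1/a$. The "square root of the bin size" prescription is
dimensionally odd on its face; this convention makes it concrete, and
the scaling is exposed so a user can substitute another. The fit
quality is insensitive to the exclusion-width choice (checked in
`test-fitting.R`).

## Fitting D

`scan_D()` evaluates, for each candidate $D$ on a grid (default step
$\Delta D = 0.01\ \mu\mathrm{m}^2/\mathrm{min}$, as a grid search rather
than a continuous optimizer so the chi-square curve itself is the
product), the chosen model from the common initial condition — the
linear projection of the $t=0$ profile, recomputed per candidate since
$f_0, \sigma, g_0$ depend on $D$ — and accumulates the effective-variance
chi-square

$$\chi^2 = \sum_m \frac{(c_{\exp}(\xi_m) - c(\xi_m))^2}
{\sigma_{y,m}^2 + \left(\sigma_{x,m}\, \partial_\xi c|_{\xi_m}\right)^2}.$$

Pooled fits sum the curves over time points and divide by their number
for the reported average; $\sigma_D$ comes from the quadratic width of
the averaged curve at $\chi^2_{\min}+1$,
$\sigma_D = \Delta D\sqrt{2/(\chi^2_{-} - 2\chi^2_{0} + \chi^2_{+})}$,
which agrees with the direct crossing on smooth curves. Ties on the grid
break toward smaller $D$ and are flagged, as are boundary minima.
`p_chi()` is the upper chi-square tail; `select_binning()` chooses the
bin width whose per-time-point $P_\chi$ median is closest to 0.5.
`welch_test()` implements the unequal-variance two-sample test from
summary statistics (the only form available when each condition yields
one fitted $D^\*$ with a $\sigma_D$; the sample size is the number of
pooled time points, which are not strictly independent — the resulting
p-values are indicative, and no correction is applied).

## The synthetic-data generator

`simulate_population()` is the package's replacement for microscopy
tracks, and its defaults define the study conditions used by the tests
and the acceptance script:

* geometry $a = 100\,\mu$m, $b = 45\,\mu$m (55 µm accessible tissue
  depth; neither radius is directly observable, so all geometry-bound
  quantities are self-consistency checks, not numeric matches to tissue
  measurements), observed sector $\Omega = 0.8$ sr — a patch of roughly
  $90 \times 90\,\mu$m at the apical surface, sized so a few hundred
  tracked nuclei produce concentrations of order the packing limit, as
  in curated experimental regions;
* growth $N_0 = 300$, $T_P = 300$ min; per-cell cycle lengths are drawn
  from a truncated normal with CV 0.15 (only the mean is constrained by
  data), ages initialized from the stable exponential-growth age
  distribution;
* stochastic G1/S radial motion by Euler–Maruyama steps (0.2 min) with
  reflecting boundaries one nuclear radius ($R = 3.5\,\mu$m) from each
  surface; the `gamma_c` variant scales the noise by
  $c_{\max}/(c_{\max}-c)$ at the local empirical concentration
  (particle-in-cell estimate on an 18-bin radial grid with light
  smoothing), the `external_force` variant adds the matching mean-field
  drift at constant noise;
* a deterministic apical run during the final 8% of the cycle, at a
  speed that traverses the full depth within that window; division at
  one nuclear radius below the apical surface into two daughters offset
  laterally by one radius;
* a division-blocked mode (no G2 runs, no divisions, constant
  population) emulating an S-phase arrest;
* uniform $\pm 3\,\mu$m radial export noise via
  `apply_measurement_noise()`.

What the generator does **not** model: lateral motility beyond the fixed
angular position of each lineage, the early-G1 basal "burst" as a
separate mechanism (in the `gamma_c` variant an abrupt basal departure
emerges from crowding at the birth site), nuclear shape changes around
mitosis, cell-fate exit, and any active apical return other than the G2
run. Passing tests therefore show that the analysis chain recovers the
parameters of *this* idealized tissue; they cannot certify the biology
of real retinas.

One deliberate interpretation: when synthetic profiles are built for
parameter-recovery studies, positions drawn from the model density are
binned with the $\pm 3\,\mu$m error-box count model but no second
independent perturbation is added. The error box *is* the model of the
measurement uncertainty; adding noise *and* box-spreading convolves the
data twice with the same kernel and inflates the recovered $D$ by about
one $\sigma_D$ at the slow end. The track-level pipeline keeps the
explicit perturbation, since there the exported coordinates play the
role of the measured data.

## Langevin layer and its conventions

The single-nucleus simulations use the overdamped Langevin equation
$\zeta\,\dot r = \mathcal F(t)$, discretized by Euler–Maruyama with
$dt = 0.2$ min, 40 nuclei per cohort with prescribed birth times, 150
min per nucleus, and min/max envelopes of the cohort-mean MSD across
repetitions (2500 by default; the tests and scripts use a few hundred,
which changes the extreme envelopes but not the central bands — the
separation statements are therefore phrased on the central 80% of the
per-repetition late-lag distribution, which is robust to the repetition
count). Three variants: constant noise (`low_c`); noise strength scaled
by $c_{\max}/(c_{\max}-c(r,t))$ (`gamma_c`), which corresponds to
$\Gamma = 6\zeta^2 D\,c_{\max}/(c_{\max}-c)$; and constant noise plus an
external drift (`external_force`). The concentration field comes from
the fitted nonlinear model and is averaged over the two closest spatial
grid points.

Two reconstructions are config-exposed because the original procedure
does not pin them down: reflecting boundaries at $b$ and $a$ (on by
default), and the functional form of the external force, implemented as
$F/\zeta = D\,\partial_r \ln(c_{\max}-c)$ — the unique drift whose
Fokker–Planck equation coincides with the nonlinear diffusion equation
at constant noise. The multiplicative noise is evaluated at the
pre-step position (Itô convention, as Euler–Maruyama implies). An
ensemble of drift-free `gamma_c` walkers consequently obeys
$\partial_t c = \partial_{rr}(D_{\text{eff}} c)$ rather than
$\partial_r(D_{\text{eff}}\partial_r c)$; on the fitted fields the
difference stays within the count error bars of a 300-nucleus profile
(median relative deviation about 10%, largest at the excluded apical
edge), and it is reported by the test suite rather than corrected,
because the scientific claims rest on MSD ordering, not on closure.

In one dimension the radial MSD of a free walker is $2Dt$; the
$\Gamma = 6\zeta^2 D$ bookkeeping in the biophysics layer is
three-dimensional. The two conventions never mix: trajectories and MSDs
are 1-D radial throughout, force strengths are 3-D.

## Membrane shapes

`solve_shape()` finds the equilibrium shape of the tube-like cell
membrane around the nucleus by direct minimization of the discretized
Helfrich energy $\mathcal E = \int dS\,(\tfrac\kappa2 \mathcal H^2 +
\gamma)$ for an axisymmetric radius profile $\delta(z)$, rather than by
collocation of the fourth-order shape equation: the minimizer of the
discrete energy satisfies the discrete Euler–Lagrange equation (checked
numerically in the tests), the bound $\delta \geq$ nucleus radius is
trivial to impose, and the approach is robust in the thin-neck regime.
Free regions are clamped (radius and slope) at the cell poles and at the
contact points with the spherical arc around the nucleus; the contact
points themselves minimize the total energy, which is the variational
counterpart of matching the free-side mean curvature to the arc's. The
optimizer is L-BFGS-B with an analytic gradient and continuation in
$\gamma$.

With this sign convention the mean curvature of a sphere of radius $R$
is $-2/R$ while a circle's line curvature is $-1/R$; the contact-match
diagnostic (`H_mismatch`) is reported against the surface value $-2/R$,
and the residual factor-of-order-one mismatch at the junction reflects
the one-sided finite differences there, not a failure of the energy
minimum. The demonstration tension is $\gamma = 4\kappa/\mu\text{m}^2$
($\gamma R^2/\kappa \approx 50$), giving necks of radius about
$\sqrt{\kappa/\gamma} = 0.5\,\mu$m that a uniform grid resolves;
physiological tensions are orders of magnitude larger and the necks
correspondingly narrower — the neck-width scaling
$\delta_{\text{neck}} \sim \sqrt{\kappa/\gamma}$ (the square-root
reading of the "$\kappa/\gamma$" order-of-magnitude statement, which is
the dimensionally consistent one) is verified across a tension sweep.
The membrane–nucleus gap defaults to zero and is a free parameter.

## Worked example

A complete parameter-recovery run (the same computation as
`analysis/04_fit_diffusion.R` and the acceptance script): solve the
nonlinear model at a known $D$, sample noisy binned profiles from it,
and scan the chi-square.

```{r example, eval = FALSE}
geom <- shell_geometry(a = 100, b = 45, Omega = 0.8)
growth <- growth_law(N0 = 300, TP = 300)
cmax <- close_packed_cmax(3.5)
ic <- function(xi) 2.1e-3 * exp(-(1 - xi) * 3) # apically weighted start
tg <- seq(0, 200, by = 2)
truth <- solve_nonlinear(ic, D = 0.09, cmax, geom, growth, tg,
                         influx = "on")
set.seed(1)
profs <- lapply(seq_along(tg), function(k) {
  n <- round(growth$N0 * exp(tg[k] / growth$tau))
  cdf <- cumsum(truth$c[k, ] * truth$xi^2)
  r <- approx(c(0, cdf / max(cdf)), c(geom$rho, truth$xi + truth$dxi / 2),
              xout = runif(n))$y * geom$a
  concentration_profile(r, tg[k], geom, bin_spec(3, 4, 4), delta_r = 3)
})
fit <- scan_D(profs, geom, growth, model = "nonlinear", cmax = cmax,
              D_grid = seq(0.01, 0.35, by = 0.01))
fit
```

## Numerical choices at a glance

| Quantity | Default | Why |
|---|---|---|
| frame interval | 2 min | imaging cadence the analysis assumes |
| fit window | first 100 time points (200 min) | the linear model's validity window; the nonlinear fit uses the same for comparability |
| $\Delta r$ | 3 µm | stated positional uncertainty |
| bin width | 3 µm | fit-probability criterion selects 3–4 µm |
| exclusions | 4 µm | one nuclear radius, result-insensitive |
| modes $M$ | 8 | smooth-profile reconstruction vs over-fitting |
| $D$ grid | 0.01–10, step 0.01 µm²/min | grid search; scripts scan the sub-range 0.01–0.35 (or 0.6 for the linear comparison) that brackets all observed minima, for runtime |
| PDE cells | 400 (150–200 in scans) | <0.2% self-convergence |
| Langevin $dt$ | 0.2 min | halving changes ensemble MSD <2% |
| cohort / reps | 40 nuclei, 2500 reps | reps reduced to 150–400 in tests/scripts; central-band statements are rep-robust |
| $c_{\max}$ | $4.12\times10^{-3}\,\mu\text{m}^{-3}$ | close packing of 3.5-µm spheres; admissible range $1.41$–$6.55\times10^{-3}$ for 5–3 µm radii |

## Known limitations

* The tissue geometry ($a$, $b$, $\Omega$) of the real retina is not
  measurable from the package's inputs; every geometry-dependent number
  (e.g. the eigenmode decay times) is reproducible only as a
  self-consistent chain, not as an external match.
* The effective-variance chi-square treats time points as independent;
  they are not, and $\sigma_D$ and the Welch p-values inherit that
  optimism.
* The estimator has a small positive bias (fraction of $\sigma_D$) for
  slow diffusion, traceable to fitting unconvolved models to
  error-box-convolved data; it is documented, measured in the tests,
  and left uncorrected to keep the procedure faithful.
* The particle generator over-packs a thin apical layer where G2
  runners and fresh daughters park; the mean-field bound $c < c_{\max}$
  holds for the G1/S interior, which is also the fitted region.
* The diffusion models deliberately contain no advection, but the
  particle tissue recalls every cell apically at the end of its cycle
  (the G2 run). Over observation windows comparable to the cycle length
  this recall visibly drains the basal half of the particle tissue, and
  fitting the mean-field models to full agent-based track sets then
  underestimates $D$ with a poor fit probability. The quantitative
  $D$-estimation chain is therefore validated on profiles sampled from
  the nonlinear model itself (where the error model is exact), while
  the track pipeline validates the descriptive statistics — speeds,
  neighbour correlations, MSD cohorts, growth, and the division-block
  relaxation. Real tissue sits between these idealizations.
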