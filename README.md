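# iknm — tissue-scale diffusion analysis of interkinetic nuclear migration

During early retinal development, nuclei of proliferating neuroepithelial
cells divide only at the apical tissue surface and wander basally through
G1 and S in an apparently random fashion (interkinetic nuclear migration,
IKNM). This package models that motion as a tissue-scale transport
process and provides the full analysis chain as tested R code, for
quantitative developmental biologists and biophysicists who want to
estimate and interpret an effective nuclear diffusion constant from
dense 3-D nuclear tracks — or to study the estimator itself on synthetic
tissue where the truth is known.

## The models

The retina is idealized as a spherical-shell sector (basal radius `b`,
apical radius `a`, solid angle `Ω`). Apical divisions with exponential
population growth `N(t) = N₀ e^{t/τ}`, `τ = T_P/ln 2`, enter as an influx
boundary condition, and the nuclear concentration `c(r, t)` obeys either
ordinary diffusion,

    ∂c/∂t = (D/r²) ∂/∂r (r² ∂c/∂r),        D ∂c/∂r |_{r=a} = N₀/(Sτ) e^{t/τ},

solved exactly as an eigenfunction series, or the lattice-gas
(crowding) extension with a maximum packing concentration `c_max`,

    ∂c/∂t = (D/r²) ∂/∂r (r² c_max/(c_max − c) ∂c/∂r),

solved by a conservative stiff finite-volume scheme. `D` is estimated by
a grid-scan minimal-χ² fit of either model to binned concentration
profiles, with an effective-variance error model combining count
uncertainty and positional uncertainty. A biophysics layer interprets
the fitted `D` (Stokes–Einstein reference, membrane-tube drag, the
stochastic force strength `Γ = 6ζ²D`), a Helfrich energy minimizer
computes the equilibrium membrane shape around the nucleus, and a
Langevin layer simulates single nuclei with crowding-dependent noise.
A seeded synthetic-track generator supplies datasets with the assumed
statistical structure (divisions at the apical surface, stochastic G1/S
motion, rapid apical G2 runs, drug-block mode, ±3 µm export noise).

## Worked example

Recover the diffusion constant from synthetic profiles generated by the
nonlinear model at `D = 0.09 µm²/min` under the package's study
conditions (300 nuclei, 300-min cycle, 0.8-sr sector, 3-µm bins, ±3 µm
positional uncertainty, 100 time points over 200 min):

```r
library(iknm)
geom   <- shell_geometry(a = 100, b = 45, Omega = 0.8)
growth <- growth_law(N0 = 300, TP = 300)
cmax   <- close_packed_cmax(3.5)
ic     <- function(xi) 2.1e-3 * exp(-(1 - xi) * 3)
tg     <- seq(0, 200, by = 2)
truth  <- solve_nonlinear(ic, D = 0.09, cmax, geom, growth, tg, influx = "on")
set.seed(1)
profs <- lapply(seq_along(tg), function(k) {
  n   <- round(growth$N0 * exp(tg[k] / growth$tau))
  cdf <- cumsum(truth$c[k, ] * truth$xi^2)
  r   <- approx(c(0, cdf / max(cdf)), c(geom$rho, truth$xi + truth$dxi / 2),
                xout = runif(n))$y * geom$a
  concentration_profile(r, tg[k], geom, bin_spec(3, 4, 4), delta_r = 3)
})
fit <- scan_D(profs, geom, growth, model = "nonlinear", cmax = cmax,
              D_grid = seq(0.01, 0.35, by = 0.01))
fit
```

```
nonlinear fit (pooled): D* = 0.11 +/- 0.0601013 um^2/min; <chi2> = 16.5 (nu = 14, chi2/nu = 1.18, P_chi = 0.287)
```

The scan recovers the generating value within its one-sigma width
(`0.11 ± 0.06` vs the true `0.09`), with a reduced χ² near 1 — the error
model is correctly sized. Interpreting the fitted value:

```r
biophysics_report(D = fit$D_star, R = 3.5)
```

reports a free thermal diffusivity of `4.2 µm²/min` — a nuclear-sized
sphere in water would be ~40× more mobile than the fit allows — a
membrane-confined diffusivity another six orders of magnitude smaller,
and stochastic forces of roughly `1–60 nN` (at 10 ms–1 s correlation
times): nuclear motion is actively driven at cytoskeletal force scales,
not thermal.

## The analysis workflow

The numbered scripts under `analysis/` run the study end to end and
write tables under `results/`:

1. `01_simulate_tracks.R` — synthetic normal and division-blocked track
   sets;
2. `02_track_statistics.R` — cycle-normalized speeds (mid-cycle mean
   ~0), neighbour-speed correlations (~0 at lags −1, 0, +1), cohort MSD;
3. `03_concentration_profiles.R` — profile series, growth fit,
   mean apical distance (drifts basally only when divisions are
   blocked);
4. `04_fit_diffusion.R` — the χ² scans (nonlinear recovers the truth;
   the linear fit returns a larger effective `D`, as crowding inflates
   apparent mobility), eigenmode decay times, Welch comparisons across
   temperature conditions;
5. `05_biophysics.R` — the interpretation report;
6. `06_cell_shape.R` — the equilibrium membrane shape (bulge over the
   nucleus, ~0.3 µm necks);
7. `07_langevin_msd.R` — MSD envelopes of the three single-nucleus
   noise models: only concentration-dependent noise reaches the
   observed displacement scale.

The methods vignette (`vignettes/iknm-methods.Rmd`) documents the
models, the error model, every numerical choice, and the limitations of
the synthetic tissue.

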