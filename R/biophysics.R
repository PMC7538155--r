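#' Physical constants and unit helpers
#'
#' Boltzmann constant in J/K.
#' @keywords internal
kB <- 1.38e-23

um2min_to_m2s <- function(D) D * 1e-12 / 60
m2s_to_um2min <- function(D) D * 1e12 * 60

#' Stokes drag coefficient of a sphere
#'
#' `zeta0 = 6 pi eta R` for a sphere of radius `R` in a fluid of viscosity
#' `eta`.
#'
#' @param eta viscosity (Pa s); water at 25 °C is about 9e-4.
#' @param R radius (µm).
#' @return Drag coefficient (kg/s).
#' @export
stokes_drag <- function(eta = 9e-4, R = 3.5) {
  stopifnot(eta > 0, R >= 0)
  6 * pi * eta * (R * 1e-6)
}

#' Stokes-Einstein diffusivity
#'
#' `D = kB T / zeta`, returned in µm²/min. The reference case (a nuclear-
#' sized sphere in water at 25 °C) gives the free thermal diffusivity a
#' nucleus would have without confinement or crowding.
#'
#' @param T_K absolute temperature (K); default 298.15 (25 °C).
#' @param zeta drag coefficient (kg/s).
#' @return Diffusivity (µm²/min).
#' @export
stokes_einstein <- function(T_K = 298.15, zeta = stokes_drag()) {
  stopifnot(T_K > 0, zeta > 0)
  m2s_to_um2min(kB * T_K / zeta)
}

#' Close-packing maximum nuclear concentration
#'
#' Aligned ellipsoids pack like spheres at fraction `pi / (3 sqrt(2)) ~
#' 0.74`, so a nucleus of effective radius `R` bounds the concentration at
#' `cmax = 0.74 / ((4/3) pi R^3)`.
#'
#' @param R nuclear radius (µm).
#' @return `cmax` (µm⁻³).
#' @export
close_packed_cmax <- function(R = 3.5) {
  stopifnot(R > 0)
  packing_fraction() / ((4 / 3) * pi * R^3)
}

#' Close-packing fraction of spheres
#'
#' @return `pi / (3 sqrt(2))`, about 0.74.
#' @export
packing_fraction <- function() {
  pi / (3 * sqrt(2))
}

#' Drag of a sphere inside a fluctuating membrane tube
#'
#' A tight-fitting membrane tube with bending modulus `kappa` and tension
#' `gamma` hinders the motion of an enclosed sphere; in the large-tension
#' limit the drag is
#' `zeta_tube = (3/2) zeta0 * (kappa/kBT * gamma R^2/kBT)^(2/3)`,
#' expressed through the two dimensionless ratios.
#'
#' @param zeta0 free Stokes drag (kg/s).
#' @param kappa_over_kBT bending modulus in thermal units (about 20 for
#'   fluid membranes).
#' @param gammaR2_over_kBT tension times squared nuclear radius in thermal
#'   units; with `gamma = kBT / l^2` and a molecular length `l = 1` nm this
#'   is `(R / l)^2`, about 1.2e7 for a micron-scale nucleus.
#' @return `zeta_tube` (kg/s).
#' @export
tube_drag <- function(zeta0 = stokes_drag(), kappa_over_kBT = 20,
                      gammaR2_over_kBT = (3.5e-6 / 1e-9)^2) {
  stopifnot(zeta0 > 0, kappa_over_kBT >= 0, gammaR2_over_kBT > 0)
  1.5 * zeta0 * (kappa_over_kBT * gammaR2_over_kBT)^(2 / 3)
}

#' Integrated strength of the stochastic force
#'
#' For an overdamped walker, `MSD = Gamma t / zeta^2` with `Gamma` the
#' integral of the force autocorrelation; matching the 3-D diffusive law
#' `MSD = 6 D t` gives `Gamma = 6 zeta^2 D`.
#'
#' @param zeta drag coefficient (kg/s).
#' @param D diffusion constant (µm²/min); converted to m²/s internally.
#' @return `Gamma` (N² s).
#' @export
gamma_strength <- function(zeta, D) {
  stopifnot(zeta > 0, D >= 0)
  6 * zeta^2 * um2min_to_m2s(D)
}

#' Characteristic force from the noise strength
#'
#' If the stochastic force decorrelates over `tau_c`, its typical magnitude
#' is `F = sqrt(Gamma / tau_c)`.
#'
#' @param Gamma noise strength (N² s).
#' @param tau_c correlation time (s).
#' @return Force (N).
#' @export
force_scale <- function(Gamma, tau_c) {
  stopifnot(Gamma >= 0, tau_c > 0)
  sqrt(Gamma / tau_c)
}

#' Biophysical interpretation report for a fitted diffusion constant
#'
#' Derives, from a fitted `D` and nuclear radius `R`: the free thermal
#' diffusivity, its ratio to `D`, the close-packing `cmax`, the
#' membrane-tube drag ratio and confined diffusivity, the stochastic force
#' strength `Gamma` over a drag range, and the implied force scale over a
#' correlation-time range.
#'
#' @param D fitted diffusion constant (µm²/min).
#' @param R nuclear radius (µm).
#' @param T_K temperature (K).
#' @param eta viscosity (Pa s).
#' @param kappa_over_kBT membrane bending modulus in thermal units.
#' @param ell molecular length (m) setting the tension `kBT / ell^2`.
#' @param zeta_factors multiples of the free Stokes drag bracketing the
#'   effective drag used for `Gamma`.
#' @param tau_c_range force correlation-time range (s).
#' @return A named list of derived quantities with units in the names.
#' @export
biophysics_report <- function(D = 0.09, R = 3.5, T_K = 298.15, eta = 9e-4,
                              kappa_over_kBT = 20, ell = 1e-9,
                              zeta_factors = c(2e5, 1e6),
                              tau_c_range = c(0.01, 1)) {
  zeta0 <- stokes_drag(eta, R)
  D_th <- stokes_einstein(T_K, zeta0)
  gR2 <- (R * 1e-6 / ell)^2
  z_tube <- tube_drag(zeta0, kappa_over_kBT, gR2)
  Gam <- gamma_strength(zeta0 * zeta_factors, D)
  list(
    zeta0_kg_s = zeta0,
    D_thermal_um2_min = D_th,
    thermal_ratio = D_th / D,
    cmax_um3 = close_packed_cmax(R),
    packing_fraction = packing_fraction(),
    zeta_tube_ratio = z_tube / zeta0,
    D_tube_over_D_thermal = zeta0 / z_tube,
    D_tube_um2_min = D_th * zeta0 / z_tube,
    Gamma_N2s = Gam,
    force_range_nN = sqrt(range(outer(Gam, 1 / tau_c_range))) * 1e9
  )
}
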