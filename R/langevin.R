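#' Specification of single-nucleus Langevin simulations
#'
#' Overdamped stochastic motion of individual nuclei in the radial
#' coordinate, discretized by the Euler-Maruyama scheme, under one of three
#' variants:
#' * `low_c`: constant noise, `dr = sqrt(2 D dt) xi` (non-interacting);
#' * `gamma_c`: concentration-dependent noise strength,
#'   `D_eff = D cmax / (cmax - c(r, t))` evaluated at the pre-step position;
#' * `external_force`: constant noise plus the mean-field drift
#'   `D d/dr ln(cmax - c) = -D c_r / (cmax - c)` (the unique drift whose
#'   Fokker-Planck equation matches the nonlinear diffusion equation at
#'   constant noise).
#'
#' The concentration field `c(r, t)` comes from a [solve_nonlinear()] grid
#' and is averaged over the two closest spatial grid points.
#'
#' @param variant `"low_c"`, `"gamma_c"` or `"external_force"`.
#' @param D diffusion constant (µm²/min).
#' @param cmax maximum packing concentration (µm⁻³).
#' @param field a [solve_nonlinear()] `pde_grid` (required by the two
#'   interacting variants).
#' @param geometry a [shell_geometry()] (defaults to the field's).
#' @param dt time step (min); default 0.2.
#' @param duration simulated span per nucleus (min); default 150.
#' @param birth_times birth times (min) of the simulated cohort; default 40
#'   nuclei born at 0.
#' @param r0 initial radius (µm); default the apical division position
#'   `a - 3.5`.
#' @param n_reps number of cohort repetitions for envelopes; default 2500.
#' @param reflect reflecting boundaries at `b` and `a` (on by default;
#'   config-exposed reconstruction).
#' @return A list of class `langevin_spec`.
#' @export
langevin_spec <- function(variant = c("low_c", "gamma_c", "external_force"),
                          D = 0.09, cmax = 4.12e-3, field = NULL,
                          geometry = NULL, dt = 0.2, duration = 150,
                          birth_times = rep(0, 40), r0 = NULL,
                          n_reps = 2500L, reflect = TRUE) {
  variant <- match.arg(variant)
  if (is.null(geometry)) {
    if (is.null(field)) stop("need geometry or field")
    geometry <- field$geometry
  }
  if (variant != "low_c" && is.null(field)) {
    stop("variant '", variant, "' needs a concentration field")
  }
  stopifnot(dt > 0, duration > 0, n_reps >= 1)
  if (!is.null(field)) {
    if (max(birth_times) + duration > max(field$t) + 1e-9) {
      stop("field does not cover the simulated time span")
    }
    if (any(field$c >= cmax)) stop("field values must lie below cmax")
  }
  if (is.null(r0)) r0 <- geometry$a - 3.5
  structure(
    list(variant = variant, D = D, cmax = cmax, field = field,
         geometry = geometry, dt = dt, duration = duration,
         birth_times = birth_times, r0 = r0, n_reps = as.integer(n_reps),
         reflect = reflect),
    class = "langevin_spec"
  )
}

# field lookup: mean of the two closest spatial grid values, nearest time
field_at <- function(field, r, t_exp) {
  xi <- r / field$geometry$a
  k <- which.min(abs(field$t - t_exp))
  cc <- field$c[k, ]
  n <- length(cc)
  j <- findInterval(xi, field$xi, all.inside = TRUE)
  (cc[j] + cc[pmin(j + 1L, n)]) / 2
}

field_gradient_at <- function(field, r, t_exp) {
  # dc/dr = (dc/dxi) / a
  xi <- r / field$geometry$a
  model_gradient(field, pmin(pmax(xi, field$geometry$rho), 1), field$t[
    which.min(abs(field$t - t_exp))
  ]) / field$geometry$a
}

# advance a vector of walkers one Euler-Maruyama step at experimental time t
step_walkers <- function(r, spec, t_exp, noise) {
  D_eff <- spec$D
  drift <- 0
  if (spec$variant == "gamma_c") {
    cc <- pmin(field_at(spec$field, r, t_exp), 0.999 * spec$cmax)
    D_eff <- spec$D * spec$cmax / (spec$cmax - cc)
  } else if (spec$variant == "external_force") {
    cc <- pmin(field_at(spec$field, r, t_exp), 0.999 * spec$cmax)
    dcdr <- field_gradient_at(spec$field, r, t_exp)
    drift <- -spec$D * dcdr / (spec$cmax - cc)
  }
  r_new <- r + drift * spec$dt + sqrt(2 * D_eff * spec$dt) * noise
  if (spec$reflect) {
    r_new <- reflect_into(r_new, spec$geometry$b, spec$geometry$a)
  }
  r_new
}

#' Simulate one nucleus
#'
#' @param spec a [langevin_spec()].
#' @param birth_t birth time (min).
#' @param r0 initial radius (µm); default the spec's.
#' @return Data frame `t_min` (experimental time), `lag_min` (cell-cycle
#'   time), `r_um`. Uses the current RNG state; seed outside for
#'   reproducibility.
#' @export
simulate_nucleus <- function(spec, birth_t = 0, r0 = NULL) {
  if (is.null(r0)) r0 <- spec$r0
  stopifnot(r0 >= spec$geometry$b, r0 <= spec$geometry$a)
  n_steps <- round(spec$duration / spec$dt)
  r <- numeric(n_steps + 1L)
  r[1] <- r0
  for (k in seq_len(n_steps)) {
    t_exp <- birth_t + (k - 1) * spec$dt
    r[k + 1] <- step_walkers(r[k], spec, t_exp, stats::rnorm(1))
  }
  lag <- (0:n_steps) * spec$dt
  data.frame(t_min = birth_t + lag, lag_min = lag, r_um = r)
}

#' Simulate a cohort aligned to birth
#'
#' One repetition: each birth time spawns one nucleus at the apical division
#' position; trajectories are returned as cell-cycle-time tracks (birth time
#' subtracted).
#'
#' @param spec a [langevin_spec()].
#' @param seed integer seed.
#' @return A matrix of radii with one row per lag step (`0, dt, ...,
#'   duration`) and one column per nucleus; attribute `lag_min`.
#' @export
simulate_cohort <- function(spec, seed = 1L) {
  set.seed(seed)
  n_steps <- round(spec$duration / spec$dt)
  n <- length(spec$birth_times)
  out <- matrix(NA_real_, nrow = n_steps + 1L, ncol = n)
  out[1, ] <- spec$r0
  # group walkers sharing a birth time so each group sees one field clock
  groups <- split(seq_len(n), spec$birth_times)
  for (g in names(groups)) {
    idx <- groups[[g]]
    b <- as.numeric(g)
    r <- rep(spec$r0, length(idx))
    for (k in seq_len(n_steps)) {
      r <- step_walkers(r, spec, b + (k - 1) * spec$dt,
                        stats::rnorm(length(r)))
      out[k + 1L, idx] <- r
    }
  }
  attr(out, "lag_min") <- (0:n_steps) * spec$dt
  out
}

# cohort-mean MSD per lag for every repetition (lags x reps matrix)
cohort_msd_matrix <- function(spec, seed = 1L) {
  set.seed(seed)
  n_steps <- round(spec$duration / spec$dt)
  n_nuclei <- length(spec$birth_times)
  reps <- spec$n_reps
  acc <- matrix(0, nrow = n_steps + 1L, ncol = reps)
  groups <- split(seq_len(n_nuclei), spec$birth_times)
  for (g in names(groups)) {
    idx <- groups[[g]]
    b <- as.numeric(g)
    n_walk <- length(idx) * reps # walkers: rep-major layout
    r <- rep(spec$r0, n_walk)
    rep_of <- rep(seq_len(reps), each = length(idx))
    for (k in seq_len(n_steps)) {
      r <- step_walkers(r, spec, b + (k - 1) * spec$dt,
                        stats::rnorm(n_walk))
      d2 <- (r - spec$r0)^2
      acc[k + 1L, ] <- acc[k + 1L, ] +
        as.numeric(rowsum(d2, rep_of, reorder = TRUE))
    }
  }
  acc / n_nuclei
}

#' Min/max envelope of cohort-mean MSD curves over repetitions
#'
#' Runs `n_reps` independent cohort repetitions and reports, per cell-cycle
#' lag, the minimum and maximum of the cohort-mean MSD across repetitions.
#'
#' @param spec a [langevin_spec()].
#' @param seed integer seed.
#' @return Data frame `lag_min`, `lower`, `upper`, `mean` (µm²).
#' @export
msd_envelope <- function(spec, seed = 1L) {
  msd <- cohort_msd_matrix(spec, seed = seed)
  data.frame(
    lag_min = (seq_len(nrow(msd)) - 1L) * spec$dt,
    lower = apply(msd, 1, min),
    upper = apply(msd, 1, max),
    mean = rowMeans(msd)
  )
}
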