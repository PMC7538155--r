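#' Configuration for the synthetic nuclear-track generator
#'
#' Bundles the tissue geometry, population growth law and single-nucleus
#' dynamics used by [simulate_population()]. The generator emulates the
#' statistical structure of experimental IKNM tracks: nuclei confined to a
#' half-spherical shell, stochastic G1/S radial motion, a brief rapid apical
#' G2 run covering the final fraction of the cycle, divisions exclusively at
#' the apical surface with exponential population growth, and an optional
#' division-blocked mode emulating an S-phase drug arrest (hydroxyurea +
#' aphidicolin), in which nuclei neither enter G2 nor divide.
#'
#' @param geometry a [shell_geometry()]; default `a = 100`, `b = 45` µm
#'   (55 µm tissue thickness) with a tracked sector of `Omega = 0.8` sr — a
#'   patch of roughly 90 x 90 µm at the apical surface, sized so that a few
#'   hundred tracked nuclei reach concentrations of the order of the packing
#'   limit, as in curated experimental regions.
#' @param growth a [growth_law()]; default 300 nuclei with a 300 min cycle.
#' @param frame_dt frame interval of the exported tracks (min); default 2.
#' @param duration total simulated time (min).
#' @param D diffusion constant of the stochastic radial motion (µm²/min).
#' @param cmax maximum nuclear packing concentration (µm⁻³), used by the
#'   crowding-coupled variants.
#' @param variant `"low_c"` (constant noise, no interaction), `"gamma_c"`
#'   (noise strength scaled by `cmax / (cmax - c)` at the local empirical
#'   concentration), or `"external_force"` (constant noise plus the
#'   mean-field drift `-D c_r / (cmax - c)`).
#' @param g2_fraction fraction of the cycle spent in the deterministic apical
#'   G2 run; default 0.08.
#' @param v_apical apical run speed (µm/min); default chosen so the run
#'   traverses the full accessible depth within the G2 window.
#' @param delta_r_noise half-width of the uniform measurement noise applied
#'   on export by [apply_measurement_noise()] (µm); default 3.
#' @param divisions_enabled `FALSE` gives the drug-block mode: constant
#'   population, no G2 runs, no divisions.
#' @param nuclear_radius nuclear radius R (µm); nuclear centers reflect at
#'   `b + R` and `a - R`. Default 3.5.
#' @param cycle_cv coefficient of variation of per-cell cycle lengths
#'   (truncated normal, floored at the G2 duration); default 0.15.
#' @param init initial radial placement: `"apical"` (exponentially weighted
#'   toward the apical surface) or `"uniform"` (uniform in volume).
#' @param init_scale decay length (µm) of the apical initial weighting.
#' @param sde_dt Euler-Maruyama time step (min); default 0.2.
#' @param pop_cap hard cap on the expected final population; configurations
#'   whose expected growth exceeds it are rejected.
#'
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(geometry = shell_geometry(Omega = 0.8),
                              growth = growth_law(N0 = 300, TP = 300),
                              frame_dt = 2,
                              duration = 300,
                              D = 0.09,
                              cmax = 4.12e-3,
                              variant = c("low_c", "gamma_c", "external_force"),
                              g2_fraction = 0.08,
                              v_apical = NULL,
                              delta_r_noise = 3,
                              divisions_enabled = TRUE,
                              nuclear_radius = 3.5,
                              cycle_cv = 0.15,
                              init = c("apical", "uniform"),
                              init_scale = 15,
                              sde_dt = 0.2,
                              pop_cap = 20000) {
  variant <- match.arg(variant)
  init <- match.arg(init)
  stopifnot(
    inherits(geometry, "shell_geometry"), inherits(growth, "growth_law"),
    frame_dt > 0, duration >= 0, D >= 0, cmax > 0,
    g2_fraction >= 0, g2_fraction < 1, delta_r_noise >= 0,
    nuclear_radius > 0, sde_dt > 0
  )
  depth <- geometry$a - geometry$b - 2 * nuclear_radius
  if (depth <= 0) stop("nuclear radius too large for the shell thickness")
  if (is.null(v_apical)) {
    v_apical <- depth / (g2_fraction * growth$TP)
  }
  structure(
    list(
      geometry = geometry, growth = growth, frame_dt = frame_dt,
      duration = duration, D = D, cmax = cmax, variant = variant,
      g2_fraction = g2_fraction, v_apical = v_apical,
      delta_r_noise = delta_r_noise, divisions_enabled = divisions_enabled,
      nuclear_radius = nuclear_radius, cycle_cv = cycle_cv, init = init,
      init_scale = init_scale, sde_dt = sde_dt, pop_cap = pop_cap
    ),
    class = "simulation_config"
  )
}

# reflect positions into [lo, hi]
reflect_into <- function(r, lo, hi) {
  span <- hi - lo
  y <- (r - lo) %% (2 * span)
  y <- ifelse(y > span, 2 * span - y, y)
  lo + y
}

# truncated-normal cycle lengths, floored at the G2 duration
draw_cycle_lengths <- function(n, TP, cv, floor_len) {
  out <- stats::rnorm(n, mean = TP, sd = cv * TP)
  bad <- out < floor_len
  while (any(bad)) {
    out[bad] <- stats::rnorm(sum(bad), mean = TP, sd = cv * TP)
    bad <- out < floor_len
  }
  out
}

# empirical radial concentration of the current ensemble on a fixed grid
empirical_field <- function(r, edges, V_bin) {
  counts <- tabulate(
    findInterval(r, edges, rightmost.closed = TRUE, all.inside = TRUE),
    nbins = length(V_bin)
  )
  c_raw <- counts / V_bin
  # light 3-point smoothing to tame shot noise in the local field
  n <- length(c_raw)
  if (n >= 3L) {
    sm <- c_raw
    sm[2:(n - 1)] <- (c_raw[1:(n - 2)] + c_raw[2:(n - 1)] + c_raw[3:n]) / 3
    sm[1] <- (2 * c_raw[1] + c_raw[2]) / 3
    sm[n] <- (c_raw[n - 1] + 2 * c_raw[n]) / 3
    sm
  } else {
    c_raw
  }
}

#' Simulate a nuclear population in the shell
#'
#' Agent-based simulation of radial nuclear motion. Each nucleus performs an
#' Euler-Maruyama random walk in its radial coordinate (variant-dependent
#' noise/drift, reflecting boundaries one nuclear radius from either
#' surface), runs apically at constant speed during the final `g2_fraction`
#' of its cycle, and divides at the apical surface into two daughters offset
#' laterally by one nuclear radius. With `divisions_enabled = FALSE` the
#' population is constant and purely stochastic (drug-block mode).
#'
#' @param config a [simulation_config()].
#' @param seed integer seed; the simulation is a deterministic function of
#'   `(config, seed)`.
#' @return A track data frame (see [tracks]) with attribute `meta`: one row
#'   per track with `track_id`, `parent_id`, `birth_t`, `fate`
#'   (`"divided"`/`"censored"`) and `cycle_len`.
#' @export
simulate_population <- function(config, seed = 1L) {
  stopifnot(inherits(config, "simulation_config"))
  geom <- config$geometry
  growth <- config$growth
  if (config$divisions_enabled &&
      expected_count(growth, config$duration) > config$pop_cap) {
    stop("expected population exceeds the configured cap (runaway growth)")
  }
  set.seed(seed)

  R <- config$nuclear_radius
  lo <- geom$b + R
  hi <- geom$a - R
  n0 <- growth$N0
  g2_len <- config$g2_fraction * growth$TP

  # state vectors
  id <- seq_len(n0)
  parent <- rep(-1L, n0)
  birth <- rep(0, n0)
  cyc <- draw_cycle_lengths(n0, growth$TP, config$cycle_cv, g2_len)
  # stable age distribution of an exponentially growing population,
  # truncated to each cell's own cycle length
  u <- stats::runif(n0)
  age <- -growth$tau * log(1 - u * (1 - exp(-cyc / growth$tau)))
  if (config$init == "apical") {
    r <- hi - stats::rexp(n0, rate = 1 / config$init_scale)
    r <- reflect_into(r, lo, hi)
  } else {
    r <- (stats::runif(n0, lo^3, hi^3))^(1 / 3)
  }
  # founders already in their G2 window sit on the apical run path
  if (config$divisions_enabled) {
    in_g2_0 <- age >= cyc - g2_len
    r[in_g2_0] <- pmax(lo, hi - config$v_apical * (cyc - age)[in_g2_0])
  }
  # area-uniform directions within the observed polar sector
  cos_min <- 1 - geom$Omega / (2 * pi)
  cos_th <- stats::runif(n0, cos_min, 1)
  phi <- stats::runif(n0, 0, 2 * pi)
  alive <- rep(TRUE, n0)
  fate <- rep("censored", n0)
  cycle_len_rec <- cyc
  parent_rec <- parent
  birth_rec <- birth
  next_id <- n0 + 1L

  # concentration grid for the interacting variants
  n_field <- 18L
  f_edges <- seq(geom$b, geom$a, length.out = n_field + 1L)
  f_V <- shell_volumes(geom, f_edges)$V_bin
  f_mid <- (f_edges[-1] + f_edges[-(n_field + 1L)]) / 2

  frames <- seq(0, config$duration, by = config$frame_dt)
  n_sub <- max(1L, ceiling(config$frame_dt / config$sde_dt))
  dt <- config$frame_dt / n_sub
  samples <- vector("list", length(frames))

  record <- function(k) {
    idx <- which(alive)
    sin_th <- sqrt(1 - cos_th[idx]^2)
    data.frame(
      track_id = id[idx], parent_id = parent[idx], t_min = frames[k],
      x_um = r[idx] * sin_th * cos(phi[idx]),
      y_um = r[idx] * sin_th * sin(phi[idx]),
      z_um = r[idx] * cos_th[idx]
    )
  }
  samples[[1L]] <- record(1L)

  for (k in seq_along(frames)[-1L]) {
    for (s in seq_len(n_sub)) {
      idx <- which(alive)
      n <- length(idx)
      if (n == 0L) break
      in_g2 <- config$divisions_enabled & (age[idx] >= cyc[idx] - g2_len)
      free <- idx[!in_g2]
      if (length(free)) {
        if (config$variant == "low_c") {
          d_eff <- rep(config$D, length(free))
          drift <- 0
        } else {
          cf <- empirical_field(r[idx], f_edges, f_V)
          cf <- pmin(cf, 0.95 * config$cmax)
          j <- findInterval(r[free], f_edges,
                            rightmost.closed = TRUE, all.inside = TRUE)
          if (config$variant == "gamma_c") {
            d_eff <- config$D * config$cmax / (config$cmax - cf[j])
            drift <- 0
          } else { # external_force
            d_eff <- rep(config$D, length(free))
            dcdr <- c(diff(cf) / diff(f_mid), 0)
            drift <- -config$D * dcdr[j] / (config$cmax - cf[j])
          }
        }
        r[free] <- r[free] + drift * dt +
          sqrt(2 * d_eff * dt) * stats::rnorm(length(free))
        r[free] <- reflect_into(r[free], lo, hi)
      }
      run <- idx[in_g2]
      if (length(run)) {
        r[run] <- pmin(r[run] + config$v_apical * dt, hi)
      }
      age[idx] <- age[idx] + dt
    }

    # divisions at the frame boundary
    if (config$divisions_enabled) {
      done <- which(alive & age >= cyc)
      for (i in done) {
        alive[i] <- FALSE
        fate[i] <- "divided"
        r_div <- hi # mitosis at the apical surface
        for (sgn in c(-1, 1)) {
          id <- c(id, next_id)
          parent <- c(parent, id[i])
          birth <- c(birth, frames[k])
          new_cyc <- draw_cycle_lengths(1L, growth$TP, config$cycle_cv, g2_len)
          cyc <- c(cyc, new_cyc)
          age <- c(age, 0)
          r <- c(r, r_div)
          # lateral offset by one nuclear radius
          new_cos <- cos_th[i] + sgn * R / r_div * sqrt(1 - cos_th[i]^2)
          new_cos <- min(max(new_cos, cos_min), 1)
          cos_th <- c(cos_th, new_cos)
          phi <- c(phi, phi[i])
          alive <- c(alive, TRUE)
          fate <- c(fate, "censored")
          parent_rec <- c(parent_rec, id[i])
          birth_rec <- c(birth_rec, frames[k])
          cycle_len_rec <- c(cycle_len_rec, new_cyc)
          next_id <- next_id + 1L
        }
      }
      if (sum(alive) > config$pop_cap) {
        stop("population exceeded the configured cap (runaway growth)")
      }
    }
    samples[[k]] <- record(k)
  }

  tracks <- do.call(rbind, samples)
  tracks <- tracks[order(tracks$track_id, tracks$t_min), , drop = FALSE]
  rownames(tracks) <- NULL
  attr(tracks, "meta") <- data.frame(
    track_id = id, parent_id = parent, birth_t = birth,
    fate = fate, cycle_len = cycle_len_rec
  )
  attr(tracks, "config") <- config
  validate_tracks(tracks, check_divisions = FALSE)
  tracks
}

#' Apply uniform radial measurement noise to exported tracks
#'
#' Each radial coordinate is perturbed by an independent uniform draw on
#' `[-delta_r, +delta_r]`, emulating the combined uncertainty of nuclear
#' center detection and apical-surface placement. Lineage and times are
#' untouched; the Cartesian coordinates are rescaled along the radial
#' direction.
#'
#' @param tracks a track data frame.
#' @param delta_r half-width of the uniform perturbation (µm).
#' @param seed integer seed.
#' @return The perturbed track table.
#' @export
apply_measurement_noise <- function(tracks, delta_r = 3, seed = 1L) {
  stopifnot(delta_r >= 0)
  if (delta_r == 0 || nrow(tracks) == 0L) {
    return(tracks)
  }
  set.seed(seed)
  r <- sqrt(tracks$x_um^2 + tracks$y_um^2 + tracks$z_um^2)
  u <- stats::runif(nrow(tracks), -delta_r, delta_r)
  scale <- (r + u) / r
  out <- tracks
  out$x_um <- tracks$x_um * scale
  out$y_um <- tracks$y_um * scale
  out$z_um <- tracks$z_um * scale
  out
}
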