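# Shared fixtures: the study-scale geometry, a smooth apically-weighted
# initial profile, and synthetic noisy profile series sampled from a PDE
# solution. Everything is generated in code at test time.

fixture_geometry <- function() shell_geometry(a = 100, b = 45, Omega = 0.8)

fixture_growth <- function(N0 = 300, TP = 300) growth_law(N0 = N0, TP = TP)

# apically weighted initial concentration with total mass N0
fixture_ic <- function(geom, N0, decay = 3) {
  raw <- function(xi) exp(-(1 - xi) * decay)
  m_raw <- geom$Omega * geom$a^3 *
    stats::integrate(function(x) x^2 * raw(x), geom$rho, 1)$value
  function(xi) N0 / m_raw * raw(xi)
}

# memoized reference nonlinear solution (shared across tests)
.fixture_cache <- new.env(parent = emptyenv())

fixture_field <- function(D = 0.09, cmax = 4.12e-3, t_max = 200,
                          n_nodes = 300L) {
  key <- paste(D, cmax, t_max, n_nodes, sep = "_")
  if (!is.null(.fixture_cache[[key]])) {
    return(.fixture_cache[[key]])
  }
  geom <- fixture_geometry()
  growth <- fixture_growth()
  ic <- fixture_ic(geom, growth$N0)
  field <- solve_nonlinear(ic, D, cmax, geom, growth,
                           t_grid = seq(0, t_max, by = 2), influx = "on",
                           n_nodes = n_nodes)
  .fixture_cache[[key]] <- field
  field
}

# draw radial nuclear positions from a stored PDE solution at time index k
sample_positions_from <- function(field, k, n) {
  geom <- field$geometry
  dens <- field$c[k, ] * field$xi^2
  cdf <- cumsum(dens)
  cdf <- cdf / cdf[length(cdf)]
  u <- stats::runif(n)
  stats::approx(c(0, cdf), c(geom$rho, field$xi + field$dxi / 2),
                xout = u)$y * geom$a
}

# noisy binned profile series sampled from a PDE solution: bin-count noise
# comes from the random nuclear positions; the stated positional
# uncertainty delta_r enters once, through the error-box count model
fixture_profiles <- function(field, growth, binspec = bin_spec(3, 4, 4),
                             delta_r = 3, seed = 1L, thin = 1L) {
  set.seed(seed)
  geom <- field$geometry
  idx <- seq(1L, length(field$t), by = thin)
  lapply(idx, function(k) {
    n <- round(growth$N0 * exp(field$t[k] / growth$tau))
    r <- sample_positions_from(field, k, n)
    concentration_profile(r, field$t[k], geom, binspec, delta_r = delta_r)
  })
}
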