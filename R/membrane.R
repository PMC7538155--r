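#' Mean and Gaussian curvature of an axisymmetric surface
#'
#' For a surface of revolution `delta(z)` (radius as a function of the
#' axis), with `delta_z = d delta / dz`:
#' mean curvature `H = delta_zz / (1 + delta_z^2)^(3/2) -
#' 1 / (delta sqrt(1 + delta_z^2))` and Gaussian curvature
#' `K = -delta_zz / (delta (1 + delta_z^2)^2)`. With this sign convention a
#' cylinder of radius `c` has `H = -1/c`, `K = 0`, and a sphere of radius
#' `R` has `H = -2/R`, `K = 1/R^2`.
#'
#' @param delta radius (µm), > 0.
#' @param delta_z,delta_zz first and second z-derivatives.
#' @return Curvature (µm⁻¹ for `H`, µm⁻² for `K`).
#' @export
mean_curvature <- function(delta, delta_z, delta_zz) {
  delta_zz / (1 + delta_z^2)^1.5 - 1 / (delta * sqrt(1 + delta_z^2))
}

#' @rdname mean_curvature
#' @export
gaussian_curvature <- function(delta, delta_z, delta_zz) {
  -delta_zz / (delta * (1 + delta_z^2)^2)
}

#' Parameters of the cell-membrane shape problem
#'
#' An elongated cell of length `L` with clamped radii `delta_a` (apical,
#' `z = 0`) and `delta_b` (basal, `z = L`) wraps a spherical nucleus of
#' radius `R` centered on the axis at `nucleus_z`. The membrane energy is
#' Helfrich bending plus tension; around the nucleus the membrane is a
#' spherical arc of radius `Rtube = R + gap`.
#'
#' @param kappa bending modulus (energy units).
#' @param gamma surface tension (energy / µm²); the neck regime needs
#'   `gamma R^2 / kappa >> 1`. The default `gamma = 4 kappa / µm²`
#'   (`gamma R^2 / kappa ~ 50` for the default nucleus) gives necks of
#'   radius about `sqrt(kappa / gamma) = 0.5` µm, resolvable on a uniform
#'   grid; physiological tensions are far larger and the necks
#'   correspondingly narrower.
#' @param delta_a,delta_b clamped end radii (µm).
#' @param L cell length (µm).
#' @param R nuclear radius (µm); 0 for a nucleus-free cell.
#' @param nucleus_z axial nucleus position (µm); default mid-cell.
#' @param gap membrane-nucleus gap (µm); default 0.
#' @return A list of class `membrane_params`.
#' @export
membrane_params <- function(kappa = 1, gamma = NULL,
                            delta_a = 1.98, delta_b = 0.94, L = 55,
                            R = 3.5, nucleus_z = NULL, gap = 0) {
  if (is.null(nucleus_z)) nucleus_z <- L / 2
  if (is.null(gamma)) gamma <- 4 * kappa
  stopifnot(kappa > 0, gamma > 0, delta_a > 0, delta_b > 0, L > 0,
            R >= 0, gap >= 0, R < L / 2)
  structure(
    list(kappa = kappa, gamma = gamma, delta_a = delta_a,
         delta_b = delta_b, L = L, R = R, nucleus_z = nucleus_z,
         gap = gap, Rtube = R + gap),
    class = "membrane_params"
  )
}

# finite-difference derivatives on a uniform grid (one-sided at ends)
fd_derivs <- function(delta, h) {
  n <- length(delta)
  dz <- numeric(n)
  dzz <- numeric(n)
  dz[2:(n - 1)] <- (delta[3:n] - delta[1:(n - 2)]) / (2 * h)
  dz[1] <- (-3 * delta[1] + 4 * delta[2] - delta[3]) / (2 * h)
  dz[n] <- (3 * delta[n] - 4 * delta[n - 1] + delta[n - 2]) / (2 * h)
  dzz[2:(n - 1)] <- (delta[3:n] - 2 * delta[2:(n - 1)] +
                       delta[1:(n - 2)]) / h^2
  dzz[1] <- (2 * delta[1] - 5 * delta[2] + 4 * delta[3] - delta[4]) / h^2
  dzz[n] <- (2 * delta[n] - 5 * delta[n - 1] + 4 * delta[n - 2] -
               delta[n - 3]) / h^2
  list(dz = dz, dzz = dzz)
}

#' Helfrich energy of an axisymmetric shape
#'
#' `E = int dS (kappa/2 H^2 + gamma)` with `dS = 2 pi delta
#' sqrt(1 + delta_z^2) dz`, by trapezoidal quadrature on the sampled shape.
#'
#' @param z axial samples (µm), increasing.
#' @param delta radii at `z` (µm).
#' @param kappa,gamma moduli as in [membrane_params()].
#' @return Energy (units of `kappa`).
#' @export
shape_energy <- function(z, delta, kappa, gamma) {
  h <- diff(z)
  if (any(h <= 0)) stop("z must be increasing")
  d <- fd_derivs(delta, h[1])
  H <- mean_curvature(delta, d$dz, d$dzz)
  integrand <- 2 * pi * delta * sqrt(1 + d$dz^2) *
    (kappa / 2 * H^2 + gamma)
  sum((integrand[-1] + integrand[-length(z)]) / 2 * h)
}

# energy of the spherical contact arc between axial positions z1 < z2
# (on the arc delta*sqrt(1+dz^2) = Rtube and H = -2/Rtube)
arc_energy <- function(z1, z2, Rtube, kappa, gamma) {
  2 * pi * Rtube * (kappa / 2 * (2 / Rtube)^2 + gamma) * (z2 - z1)
}

# dense first/second-derivative matrices on a uniform grid
# (centered interior, second-order one-sided ends)
fd_matrices <- function(n, h) {
  Dz <- matrix(0, n, n)
  Dzz <- matrix(0, n, n)
  for (j in 2:(n - 1)) {
    Dz[j, j - 1] <- -1 / (2 * h)
    Dz[j, j + 1] <- 1 / (2 * h)
    Dzz[j, (j - 1):(j + 1)] <- c(1, -2, 1) / h^2
  }
  Dz[1, 1:3] <- c(-3, 4, -1) / (2 * h)
  Dz[n, (n - 2):n] <- c(1, -4, 3) / (2 * h)
  Dzz[1, 1:4] <- c(2, -5, 4, -1) / h^2
  Dzz[n, (n - 3):n] <- c(-1, 4, -5, 2) / h^2
  list(Dz = Dz, Dzz = Dzz)
}

# Helfrich energy of a discrete profile plus its analytic gradient
energy_and_grad <- function(delta, Dz, Dzz, w, kappa, gamma) {
  dz <- drop(Dz %*% delta)
  dzz <- drop(Dzz %*% delta)
  u <- 1 + dz^2
  su <- sqrt(u)
  H <- dzz / u^1.5 - 1 / (delta * su)
  g <- delta * su
  dens <- kappa / 2 * H^2 + gamma
  E <- sum(w * 2 * pi * g * dens)
  dH_dd <- 1 / (delta^2 * su)
  dH_ddz <- -3 * dzz * dz / u^2.5 + dz / (delta * u^1.5)
  dH_ddzz <- 1 / u^1.5
  A <- 2 * pi * (su * dens + g * kappa * H * dH_dd)
  B <- 2 * pi * (delta * dz / su * dens + g * kappa * H * dH_ddz)
  C <- 2 * pi * g * kappa * H * dH_ddzz
  grad <- w * A + drop(crossprod(Dz, w * B)) + drop(crossprod(Dzz, w * C))
  list(E = E, grad = grad)
}

# minimize the clamped free-region energy on [z_lo, z_hi]
# with delta and slope fixed at both ends; lower_bound (a function of z)
# keeps the membrane outside the nucleus; returns z, delta, energy
minimize_free_region <- function(z_lo, z_hi, d_lo, s_lo, d_hi, s_hi,
                                 kappa, gamma, n = 81L, init = NULL,
                                 lower_bound = NULL) {
  z <- seq(z_lo, z_hi, length.out = n)
  h <- z[2] - z[1]
  lb <- if (is.null(lower_bound)) rep(1e-3, n) else
    pmax(lower_bound(z), 1e-3)
  fd <- fd_matrices(n, h)
  w_trap <- c(h / 2, rep(h, n - 2), h / 2)
  # clamp both delta and slope at the ends by eliminating the nodes
  # adjacent to the boundaries via second-order one-sided differences
  assemble <- function(free) {
    delta <- numeric(n)
    delta[1] <- d_lo
    delta[n] <- d_hi
    delta[3:(n - 2)] <- free
    delta[2] <- (3 * delta[1] + delta[3] + 2 * h * s_lo) / 4
    delta[n - 1] <- (3 * delta[n] + delta[n - 2] - 2 * h * s_hi) / 4
    delta
  }
  eval_energy <- function(free) {
    delta <- assemble(free)
    if (any(delta <= 1e-4)) {
      return(1e8)
    }
    shape_energy(z, delta, kappa, gamma)
  }
  if (is.null(init)) {
    init <- pmax(seq(d_lo, d_hi, length.out = n), lb + 1e-3)[3:(n - 2)]
  }
  # continuation in gamma stabilizes the thin-neck regime
  gammas <- gamma * c(0.05, 0.2, 1)
  free <- init
  lb_free <- lb[3:(n - 2)]
  for (g in gammas) {
    eg <- function(fr) {
      delta <- assemble(fr)
      if (any(delta <= 1e-4)) {
        return(1e8)
      }
      energy_and_grad(delta, fd$Dz, fd$Dzz, w_trap, kappa, g)$E
    }
    gg <- function(fr) {
      delta <- assemble(fr)
      gr <- energy_and_grad(delta, fd$Dz, fd$Dzz, w_trap, kappa, g)$grad
      # chain rule through the slope-clamping elimination of nodes 2, n-1
      out <- gr[3:(n - 2)]
      out[1] <- out[1] + gr[2] / 4
      out[length(out)] <- out[length(out)] + gr[n - 1] / 4
      out
    }
    opt <- stats::optim(free, eg, gg, method = "L-BFGS-B",
                        lower = lb_free,
                        control = list(maxit = 500, factr = 1e9))
    free <- opt$par
  }
  delta <- assemble(free)
  list(z = z, delta = delta, energy = shape_energy(z, delta, kappa, gamma))
}

#' Equilibrium axisymmetric cell-membrane shape around a nucleus
#'
#' The domain is split into free membrane regions and a spherical contact
#' arc of radius `Rtube` around the nucleus. Each free region minimizes the
#' Helfrich energy with clamped radius and slope at both ends (clamped to
#' the end radii at the cell poles and to the arc value/slope at the
#' contact point); the contact points on either side are then chosen by
#' one-dimensional minimization of the total energy, which is the
#' variational counterpart of requiring the free-side mean curvature to
#' approach the arc curvature at contact. With `R = 0` the whole domain is
#' a single free region (no contact).
#'
#' @param params a [membrane_params()].
#' @param n_nodes grid nodes per free region.
#' @return Object of class `cell_shape`: `z`, `delta`, `z_contact`
#'   (left/right, `NA` without a nucleus), `H` (mean curvature along `z`),
#'   `energy`, `H_mismatch` (free-side `H` at contact minus the arc value
#'   `-2/Rtube`, per side), and `params`.
#' @export
solve_shape <- function(params, n_nodes = 81L) {
  stopifnot(inherits(params, "membrane_params"))
  kappa <- params$kappa
  gamma <- params$gamma
  L <- params$L
  if (params$R <= 0) {
    # nucleus-free: single clamped region across the cell
    fr <- minimize_free_region(0, L, params$delta_a, 0, params$delta_b, 0,
                               kappa, gamma, n = 2L * n_nodes - 1L)
    d <- fd_derivs(fr$delta, fr$z[2] - fr$z[1])
    return(structure(
      list(z = fr$z, delta = fr$delta, z_contact = c(NA, NA),
           H = mean_curvature(fr$delta, d$dz, d$dzz),
           energy = fr$energy, H_mismatch = c(NA, NA), params = params),
      class = "cell_shape"
    ))
  }
  z0 <- params$nucleus_z
  Rt <- params$Rtube
  arc_val <- function(z) sqrt(pmax(Rt^2 - (z - z0)^2, 0))
  arc_slope <- function(z) -(z - z0) / arc_val(z)
  nucleus_bound <- arc_val # membrane may not penetrate the nucleus

  side <- function(left) {
    # contact point z_c in (z0 - Rt, z0) on the left, mirrored on the right
    if (left) {
      lo <- z0 - Rt
      rng <- c(lo + 0.05 * Rt, z0 - 0.02 * Rt)
      e_tot <- function(zc) {
        fr <- minimize_free_region(0, zc, params$delta_a, 0,
                                   arc_val(zc), arc_slope(zc),
                                   kappa, gamma, n = n_nodes,
                                   lower_bound = nucleus_bound)
        fr$energy + arc_energy(zc, z0, Rt, kappa, gamma)
      }
    } else {
      hi <- z0 + Rt
      rng <- c(z0 + 0.02 * Rt, hi - 0.05 * Rt)
      e_tot <- function(zc) {
        fr <- minimize_free_region(zc, L, arc_val(zc), arc_slope(zc),
                                   params$delta_b, 0,
                                   kappa, gamma, n = n_nodes,
                                   lower_bound = nucleus_bound)
        fr$energy + arc_energy(z0, zc, Rt, kappa, gamma)
      }
    }
    opt <- stats::optimize(e_tot, rng, tol = 1e-4 * Rt)
    zc <- opt$minimum
    fr <- if (left) {
      minimize_free_region(0, zc, params$delta_a, 0,
                           arc_val(zc), arc_slope(zc), kappa, gamma,
                           n = n_nodes, lower_bound = nucleus_bound)
    } else {
      minimize_free_region(zc, L, arc_val(zc), arc_slope(zc),
                           params$delta_b, 0, kappa, gamma, n = n_nodes,
                           lower_bound = nucleus_bound)
    }
    list(zc = zc, fr = fr)
  }

  Lside <- side(TRUE)
  Rside <- side(FALSE)

  # assemble full profile: free left + arc + free right
  z_arc <- seq(Lside$zc, Rside$zc, length.out = n_nodes)
  d_arc <- arc_val(z_arc)
  z_all <- c(Lside$fr$z, z_arc[-1], Rside$fr$z[-1])
  d_all <- c(Lside$fr$delta, d_arc[-1], Rside$fr$delta[-1])

  # H along z: free regions by finite differences, arc analytically
  H_free_L <- {
    d <- fd_derivs(Lside$fr$delta, Lside$fr$z[2] - Lside$fr$z[1])
    mean_curvature(Lside$fr$delta, d$dz, d$dzz)
  }
  H_free_R <- {
    d <- fd_derivs(Rside$fr$delta, Rside$fr$z[2] - Rside$fr$z[1])
    mean_curvature(Rside$fr$delta, d$dz, d$dzz)
  }
  H_all <- c(H_free_L, rep(-2 / Rt, length(z_arc) - 1L),
             H_free_R[-1])

  energy <- Lside$fr$energy + Rside$fr$energy +
    arc_energy(Lside$zc, Rside$zc, Rt, kappa, gamma)

  structure(
    list(
      z = z_all, delta = d_all, z_contact = c(Lside$zc, Rside$zc),
      H = H_all, energy = energy,
      H_mismatch = c(H_free_L[length(H_free_L)] - (-2 / Rt),
                     H_free_R[1] - (-2 / Rt)),
      params = params
    ),
    class = "cell_shape"
  )
}

#' @export
print.cell_shape <- function(x, ...) {
  cat(sprintf(
    "Axisymmetric cell shape: %d samples on [0, %g] um, energy = %.4g\n",
    length(x$z), max(x$z), x$energy
  ))
  if (!anyNA(x$z_contact)) {
    cat(sprintf("  contact points: %.2f / %.2f um; min neck radius %.3f um\n",
                x$z_contact[1], x$z_contact[2], min(x$delta)))
  }
  invisible(x)
}
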