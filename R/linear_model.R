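#' Eigensystem of radial diffusion in a shell with no-flux ends
#'
#' Solves `(1/xi^2) d/dxi (xi^2 dH/dxi) = -lambda^2 H` on `[rho, 1]` with
#' `dH/dxi = 0` at both ends. Substituting `u = xi H` reduces the problem to
#' `u'' = -lambda^2 u` with mixed boundary conditions, whose eigenvalues
#' satisfy the transcendental condition
#' `lambda (1 - rho) = atan(lambda) - atan(rho lambda) + k pi`, k = 1, 2, ...
#' (the zero mode, a constant, is excluded). Each branch is bracketed on
#' `[k pi / (1 - rho), (k pi + pi/2) / (1 - rho)]` and solved by root
#' finding. Eigenfunctions are
#' `H_k(xi) = sin(lambda (xi - rho) + phi) / xi` with `phi = atan(rho
#' lambda)`, normalized to unit norm under the weight `xi^2`.
#'
#' @param rho basal-to-apical radius ratio `b/a`, in (0, 1).
#' @param M truncation order (number of modes); default 8.
#' @return Object of class `eigen_system`: `rho`, `lambdas` (ascending),
#'   `phis`, `norms` (pre-normalization norms), `M`, and functions
#'   `H(xi, i)` and `dH(xi, i)` evaluating the i-th normalized mode and its
#'   derivative.
#' @export
solve_eigenproblem <- function(rho, M = 8L) {
  stopifnot(rho > 0, rho < 1, M >= 1)
  g <- function(lam, k) {
    lam * (1 - rho) - atan(lam) + atan(rho * lam) - k * pi
  }
  lambdas <- vapply(seq_len(M), function(k) {
    lo <- k * pi / (1 - rho)
    hi <- (k * pi + pi / 2) / (1 - rho)
    # widen the bracket slightly for numerical safety
    f_lo <- g(lo, k)
    f_hi <- g(hi, k)
    if (f_lo > 0 || f_hi < 0) {
      stop(sprintf(
        "eigenvalue bracketing failed for mode %d on [%g, %g]", k, lo, hi
      ))
    }
    stats::uniroot(g, c(lo, hi), k = k, tol = 1e-12)$root
  }, numeric(1))
  phis <- atan(rho * lambdas)
  # norm^2 = int_rho^1 sin^2(lambda (xi - rho) + phi) dxi, closed form
  norm2 <- (1 - rho) / 2 -
    (sin(2 * (lambdas * (1 - rho) + phis)) - sin(2 * phis)) / (4 * lambdas)
  norms <- sqrt(norm2)
  H <- function(xi, i) {
    sin(lambdas[i] * (xi - rho) + phis[i]) / (xi * norms[i])
  }
  dH <- function(xi, i) {
    (lambdas[i] * xi * cos(lambdas[i] * (xi - rho) + phis[i]) -
       sin(lambdas[i] * (xi - rho) + phis[i])) / (xi^2 * norms[i])
  }
  structure(
    list(rho = rho, lambdas = lambdas, phis = phis, norms = norms, M = M,
         H = H, dH = dH),
    class = "eigen_system"
  )
}

#' Dimensionless influx amplitude and growth rate
#'
#' Nondimensionalizing the apical influx boundary condition
#' `D dc/dr|_{r=a} = N0 / (S tau) * exp(t / tau)` with `xi = r/a`,
#' `s = D t / a^2` gives `dc/dxi|_{xi=1} = f0 exp(sigma s)` with
#' `sigma = a^2 / (D tau)` and `f0 = N0 a / (S tau D)` (µm⁻³, since the
#' concentration stays dimensional).
#'
#' @param geometry a [shell_geometry()].
#' @param growth a [growth_law()].
#' @param D diffusion constant (µm²/min), > 0.
#' @return List with `f0` (µm⁻³) and `sigma` (dimensionless).
#' @export
influx_params <- function(geometry, growth, D) {
  stopifnot(D > 0)
  list(
    f0 = growth$N0 * geometry$a / (geometry$S * growth$tau * D),
    sigma = geometry$a^2 / (D * growth$tau)
  )
}

# g0 such that the quadratic particular term carries the full mass
# N0 exp(sigma s): sigma * int_rho^1 xi^2 P(xi) dxi = 1 with
# P = (xi^2/2 - rho xi + g0) / (1 - rho).
solve_g0 <- function(rho, sigma) {
  ((1 - rho) / sigma - (1 - rho^5) / 10 + rho * (1 - rho^4) / 4) *
    3 / (1 - rho^3)
}

# particular spatial profile and its PDE residual projections
particular_P <- function(xi, rho, g0) {
  (xi^2 / 2 - rho * xi + g0) / (1 - rho)
}

particular_LP <- function(xi, rho) {
  (3 - 2 * rho / xi) / (1 - rho)
}

# alpha_i: xi^2-weighted projection of (L P - sigma P) onto mode i
alphas_for <- function(es, sigma, g0) {
  rho <- es$rho
  vapply(seq_len(es$M), function(i) {
    stats::integrate(function(xi) {
      xi^2 * (particular_LP(xi, rho) - sigma * particular_P(xi, rho, g0)) *
        es$H(xi, i)
    }, rho, 1, rel.tol = 1e-10)$value
  }, numeric(1))
}

#' Assemble the full linear-diffusion solution from a measured profile
#'
#' Builds the exact series solution of linear diffusion in the shell with
#' exponential apical influx and basal no-flux: eigensystem, influx
#' parameters, the mass-fixing constant `g0`, the mode forcings `alpha_i`,
#' and the initial-condition coefficients projected from the measured
#' profile at `t = 0`.
#'
#' @param profile0 a [concentration_profile()] at the initial time.
#' @param geometry a [shell_geometry()].
#' @param growth a [growth_law()].
#' @param D diffusion constant (µm²/min).
#' @param M truncation order; default 8.
#' @param use which profile bins enter the projection quadrature: all bins
#'   (default, so the full domain is covered) or only fitting bins.
#' @return Object of class `linear_solution`: the eigensystem plus `f0`,
#'   `sigma`, `g0`, `alpha`, `h_tilde`, `h`, `D`, `geometry`, `growth`.
#' @export
linear_solution <- function(profile0, geometry, growth, D, M = 8L,
                            use = c("all", "fit")) {
  use <- match.arg(use)
  es <- solve_eigenproblem(geometry$rho, M)
  ip <- influx_params(geometry, growth, D)
  g0 <- solve_g0(geometry$rho, ip$sigma)
  alpha <- alphas_for(es, ip$sigma, g0)
  proj <- project_initial(profile0, es, ip$f0, g0, use = use)
  h <- proj$h_tilde - alpha * ip$f0 / (ip$sigma + es$lambdas^2)
  structure(
    list(eigensystem = es, f0 = ip$f0, sigma = ip$sigma, g0 = g0,
         alpha = alpha, h_tilde = proj$h_tilde, h = h, D = D,
         geometry = geometry, growth = growth),
    class = "linear_solution"
  )
}

#' Project a measured initial profile onto the eigenmodes
#'
#' Discrete quadrature over the profile bins:
#' `h_tilde_i = sum_m xi_m^2 H_i(xi_m) c(xi_m) dxi_m - f0/(1-rho) *
#' int_rho^1 xi^2 H_i(xi) (xi^2/2 - rho xi + g0) dxi`, the integral by
#' adaptive quadrature. The initial-condition coefficients are
#' `h_i = h_tilde_i - alpha_i f0 / (sigma + lambda_i^2)`, obtained by
#' [linear_solution()].
#'
#' @param profile0 a [concentration_profile()].
#' @param eigensystem an [solve_eigenproblem()] result.
#' @param f0,g0 influx amplitude and mass constant.
#' @param use `"all"` or `"fit"` bins.
#' @return List with `h_tilde`.
#' @export
project_initial <- function(profile0, eigensystem, f0, g0,
                            use = c("all", "fit")) {
  use <- match.arg(use)
  if (!nrow(profile0)) stop("empty profile")
  rows <- if (use == "fit") profile0[profile0$fit, ] else profile0
  rho <- eigensystem$rho
  h_tilde <- vapply(seq_len(eigensystem$M), function(i) {
    data_term <- sum(
      rows$xi^2 * eigensystem$H(rows$xi, i) * rows$c * rows$dxi
    )
    int_term <- stats::integrate(function(xi) {
      xi^2 * eigensystem$H(xi, i) * (xi^2 / 2 - rho * xi + g0)
    }, rho, 1, rel.tol = 1e-10)$value
    data_term - f0 / (1 - rho) * int_term
  }, numeric(1))
  list(h_tilde = h_tilde)
}

#' Evaluate the linear-diffusion series solution
#'
#' `c(xi, s) = sum_i (h_i e^{-lambda_i^2 s} + alpha_i f0 / (sigma +
#' lambda_i^2) e^{sigma s}) H_i(xi) + (xi^2/2 - rho xi + g0) f0 e^{sigma s}
#' / (1 - rho)`, truncated at `M` modes.
#'
#' @param xi dimensionless radii in `[rho, 1]`.
#' @param s dimensionless times `D t / a^2`, >= 0.
#' @param params a [linear_solution()].
#' @param deriv if `TRUE`, return `dc/dxi` instead of `c`.
#' @return Matrix of concentrations (µm⁻³) with `length(xi)` rows and
#'   `length(s)` columns (dropped to a vector when `length(s) == 1`).
#' @export
evaluate_linear <- function(xi, s, params, deriv = FALSE) {
  stopifnot(inherits(params, "linear_solution"))
  if (any(s < 0)) stop("s must be non-negative")
  es <- params$eigensystem
  rho <- es$rho
  modes <- vapply(seq_len(es$M), function(i) {
    if (deriv) es$dH(xi, i) else es$H(xi, i)
  }, numeric(length(xi)))
  modes <- matrix(modes, nrow = length(xi))
  out <- vapply(s, function(sj) {
    coef <- params$h * exp(-es$lambdas^2 * sj) +
      params$alpha * params$f0 / (params$sigma + es$lambdas^2) *
        exp(params$sigma * sj)
    series <- drop(modes %*% coef)
    part <- if (deriv) {
      (xi - rho) / (1 - rho)
    } else {
      particular_P(xi, rho, params$g0)
    }
    series + part * params$f0 * exp(params$sigma * sj)
  }, numeric(length(xi)))
  out <- matrix(out, nrow = length(xi))
  if (ncol(out) == 1L) drop(out) else out
}

#' Evaluate the linear solution in dimensional coordinates
#'
#' @param r radii (µm) in `[b, a]`.
#' @param t times (min).
#' @param params a [linear_solution()].
#' @return Concentrations (µm⁻³), as in [evaluate_linear()].
#' @export
evaluate_linear_rt <- function(r, t, params) {
  a <- params$geometry$a
  evaluate_linear(r / a, params$D * t / a^2, params)
}

#' Decay times of the eigenmodes
#'
#' The i-th transient of the series decays as `exp(-lambda_i^2 D t / a^2)`,
#' i.e. with time constant `T_i = a^2 / (D lambda_i^2)` (min), strictly
#' decreasing in i.
#'
#' @param eigensystem an [solve_eigenproblem()] result.
#' @param D diffusion constant (µm²/min), > 0.
#' @param a apical radius (µm).
#' @return Vector of decay times (min).
#' @export
decay_times <- function(eigensystem, D, a) {
  stopifnot(D > 0)
  a^2 / (D * eigensystem$lambdas^2)
}
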