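#' Effective-variance chi-square of a model against a profile
#'
#' `chi^2 = sum_m (c_exp(xi_m) - c_model(xi_m))^2 / sigma_m^2` over the
#' fitting bins, with the effective variance combining the count error and
#' the positional error propagated through the model slope:
#' `sigma_m^2 = sigma_y_m^2 + (sigma_x_m * dc/dxi|_m)^2`. Degrees of
#' freedom are the number of fitted bins minus one (one fitted parameter).
#'
#' @param profile a [concentration_profile()].
#' @param model_curve model concentrations (µm⁻³) at the profile's fitting
#'   bin centers.
#' @param model_gradient model `dc/dxi` at the same bins (0 to ignore the
#'   x-error channel).
#' @return List with `chi2` and `nu`.
#' @export
chi2_profile <- function(profile, model_curve, model_gradient = 0) {
  rows <- profile[profile$fit, , drop = FALSE]
  if (!nrow(rows)) stop("no fitting bins in profile")
  sig2 <- rows$sigma_y^2 + (rows$sigma_x * model_gradient)^2
  if (any(sig2 <= 0)) stop("degenerate weight: sigma_m = 0 in some bin")
  list(
    chi2 = sum((rows$c - model_curve)^2 / sig2),
    nu = nrow(rows) - 1L
  )
}

#' Grid-scan minimal-chi-square estimate of the diffusion constant
#'
#' For each candidate `D` the chosen model (linear series or nonlinear PDE)
#' is solved from the common initial condition (the linear model's
#' projection of the `t = 0` profile, recomputed per `D` since the influx
#' parameters depend on it) and the chi-square against every profile is
#' accumulated. `D*` is the grid argmin (ties broken toward smaller `D` and
#' flagged); the pooled scope divides the summed curve by the number of
#' time points for the reported average chi-square.
#'
#' @param profiles list of [concentration_profile()]s; the first must be at
#'   `t = 0` (it provides the initial condition).
#' @param geometry a [shell_geometry()].
#' @param growth a [growth_law()] with `N0` equal to the observed initial
#'   count (the series carries exactly that mass).
#' @param model `"linear"` or `"nonlinear"`.
#' @param cmax maximum packing concentration (µm⁻³), nonlinear model only.
#' @param D_grid candidate diffusion constants (µm²/min); default
#'   `seq(0.01, 10, by = 0.01)`.
#' @param scope `"pooled"` (all time points jointly; default) or
#'   `"single"` (each time point separately; returns a list of fits).
#' @param influx `"on"` unless fitting a division-blocked series.
#' @param M truncation order of the linear series.
#' @param n_nodes PDE resolution for the nonlinear model.
#' @return Object of class `fit_result`: `D_star`, `sigma_D`, `chi2`
#'   (average over time points), `nu`, `chi2_red`, `P_chi`, `chi2_curve`
#'   (data frame `D`, `chi2_sum`, `chi2_avg`), `boundary` flag, `tie` flag,
#'   `scope`, `model`.
#' @export
scan_D <- function(profiles, geometry, growth,
                   model = c("nonlinear", "linear"),
                   cmax = 4.12e-3,
                   D_grid = seq(0.01, 10, by = 0.01),
                   scope = c("pooled", "single"),
                   influx = c("on", "off"),
                   M = 8L, n_nodes = 200L) {
  model <- match.arg(model)
  scope <- match.arg(scope)
  influx <- match.arg(influx)
  stopifnot(length(profiles) >= 1L)
  times <- vapply(profiles, function(p) attr(p, "t"), numeric(1))
  if (times[1] != 0) stop("first profile must be at t = 0")
  nt <- length(profiles)

  chi2_mat <- matrix(NA_real_, nrow = length(D_grid), ncol = nt)
  nus <- integer(nt)
  for (gi in seq_along(D_grid)) {
    D <- D_grid[gi]
    ls <- linear_solution(profiles[[1]], geometry, growth, D, M = M)
    if (model == "nonlinear") {
      ic <- function(xi) pmin(
        pmax(evaluate_linear(xi, 0, ls), 0), 0.999 * cmax
      )
      grid <- tryCatch(
        solve_nonlinear(ic, D, cmax, geometry, growth,
                        t_grid = times, influx = influx,
                        n_nodes = n_nodes),
        error = function(e) {
          if (!grepl("close-packing", conditionMessage(e))) stop(e)
          NULL # this D drives the model into the packing singularity
        }
      )
      if (is.null(grid)) {
        chi2_mat[gi, ] <- Inf
        next
      }
    }
    for (k in seq_len(nt)) {
      p <- profiles[[k]]
      rows <- p[p$fit, , drop = FALSE]
      if (model == "linear") {
        s <- D * times[k] / geometry$a^2
        curve <- evaluate_linear(rows$xi, s, ls)
        gradient <- evaluate_linear(rows$xi, s, ls, deriv = TRUE)
      } else {
        curve <- model_concentration(grid, rows$xi, times[k])
        gradient <- model_gradient(grid, rows$xi, times[k])
      }
      cs <- chi2_profile(p, curve, gradient)
      chi2_mat[gi, k] <- cs$chi2
      nus[k] <- cs$nu
    }
  }

  build_fit <- function(chi2_vec, nu, n_avg) {
    chi2_avg <- chi2_vec / n_avg
    i_min <- which(chi2_vec == min(chi2_vec))
    tie <- length(i_min) > 1L
    i_min <- i_min[1] # ties broken toward smaller D
    boundary <- i_min == 1L || i_min == length(D_grid)
    sd <- if (!boundary && length(D_grid) >= 3L) {
      tryCatch(
        sigma_D(data.frame(D = D_grid, chi2 = chi2_avg), D_grid[i_min]),
        error = function(e) NA_real_
      )
    } else {
      NA_real_
    }
    chi2_star <- chi2_avg[i_min]
    structure(
      list(
        D_star = D_grid[i_min], sigma_D = sd, chi2 = chi2_star, nu = nu,
        chi2_red = chi2_star / nu, P_chi = p_chi(chi2_star, nu),
        chi2_curve = data.frame(D = D_grid, chi2_sum = chi2_vec,
                                chi2_avg = chi2_avg),
        boundary = boundary, tie = tie, scope = scope, model = model,
        grid = c(D_min = min(D_grid), D_max = max(D_grid),
                 delta_D = if (length(D_grid) > 1) min(diff(D_grid)) else NA)
      ),
      class = "fit_result"
    )
  }

  if (scope == "pooled") {
    build_fit(rowSums(chi2_mat), nus[1], nt)
  } else {
    lapply(seq_len(nt), function(k) build_fit(chi2_mat[, k], nus[k], 1))
  }
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf(
    "%s fit (%s): D* = %g +/- %g um^2/min; <chi2> = %.3g (nu = %d, chi2/nu = %.3g, P_chi = %.3g)\n",
    x$model, x$scope, x$D_star, x$sigma_D, x$chi2, x$nu, x$chi2_red, x$P_chi
  ))
  if (x$boundary) cat("  warning: minimum at grid boundary\n")
  if (x$tie) cat("  note: grid tie broken toward smaller D\n")
  invisible(x)
}

#' Standard deviation of D* from the curvature of the chi-square curve
#'
#' Quadratic approximation of the (time-averaged) chi-square scan around
#' its minimum: the width at `chi2 = chi2_min + 1` is
#' `sigma_D = Delta_D * sqrt(2 / (chi2(D* - Delta_D) - 2 chi2(D*) +
#' chi2(D* + Delta_D)))`.
#'
#' @param chi2_curve data frame with columns `D` and `chi2` (the averaged
#'   curve for pooled fits).
#' @param D_star grid minimum; must be interior.
#' @param delta_D grid spacing; inferred from the curve when omitted.
#' @return `sigma_D` (µm²/min).
#' @export
sigma_D <- function(chi2_curve, D_star, delta_D = NULL) {
  D <- chi2_curve$D
  chi2 <- if ("chi2" %in% names(chi2_curve)) {
    chi2_curve$chi2
  } else {
    chi2_curve$chi2_avg
  }
  i <- which.min(abs(D - D_star))
  if (i == 1L || i == length(D)) stop("D_star must be interior to the grid")
  if (is.null(delta_D)) delta_D <- D[i + 1] - D[i]
  second_diff <- chi2[i - 1] - 2 * chi2[i] + chi2[i + 1]
  if (second_diff <= 0) stop("no local minimum: non-positive second difference")
  delta_D * sqrt(2 / second_diff)
}

#' Probability of exceeding a chi-square value
#'
#' Upper tail of the chi-square distribution with `nu` degrees of freedom;
#' about 0.5 for a correct model with correctly sized errors.
#'
#' @param chi2 observed chi-square (>= 0).
#' @param nu degrees of freedom (>= 1).
#' @return `P(X > chi2)` for `X ~ chi^2_nu`.
#' @export
p_chi <- function(chi2, nu) {
  stopifnot(nu >= 1)
  stats::pchisq(chi2, df = nu, lower.tail = FALSE)
}

#' Select a bin width by the fit-probability criterion
#'
#' For each candidate bin width (and exclusion width) the nonlinear model is
#' fitted to the binned data; the returned specification is the one whose
#' median-over-time `P_chi` is closest to 0.5 (a correct error model makes
#' the chi-square per time point median-consistent).
#'
#' @param radial_tracks output of [to_radial()].
#' @param geometry,growth as in [scan_D()].
#' @param widths candidate bin widths (µm).
#' @param exclusions candidate exclusion widths (µm); default 4.
#' @param times time points to fit.
#' @param cmax,D_grid,n_nodes passed to [scan_D()].
#' @param delta_r positional error half-width (µm).
#' @return The selected [bin_spec()], with attribute `table` summarizing
#'   the candidates.
#' @export
select_binning <- function(radial_tracks, geometry, growth,
                           widths = c(3, 4, 5), exclusions = 4,
                           times = NULL, cmax = 4.12e-3,
                           D_grid = seq(0.02, 0.3, by = 0.01),
                           n_nodes = 150L, delta_r = 3) {
  cands <- expand.grid(width = widths, exclusion = exclusions)
  if (nrow(cands) < 1L) stop("no candidates")
  if (nrow(cands) == 1L) {
    return(bin_spec(cands$width[1], cands$exclusion[1], cands$exclusion[1]))
  }
  scores <- numeric(nrow(cands))
  for (ci in seq_len(nrow(cands))) {
    bs <- bin_spec(cands$width[ci], cands$exclusion[ci], cands$exclusion[ci])
    profs <- profile_series(radial_tracks, geometry, bs,
                            times = times, delta_r = delta_r)
    fits <- tryCatch(
      scan_D(profs, geometry, growth, model = "nonlinear", cmax = cmax,
             D_grid = D_grid, scope = "single", n_nodes = n_nodes),
      error = function(e) NULL
    )
    scores[ci] <- if (is.null(fits)) {
      Inf
    } else {
      abs(stats::median(vapply(fits, function(f) f$P_chi, numeric(1))) - 0.5)
    }
  }
  if (all(!is.finite(scores))) stop("all candidates degenerate")
  best <- which.min(scores)
  out <- bin_spec(cands$width[best], cands$exclusion[best],
                  cands$exclusion[best])
  attr(out, "table") <- cbind(cands, score = scores)
  out
}

#' Welch's unequal-variances t-test from summary statistics
#'
#' Two-sided test for a difference of means given per-group mean, SD and
#' sample size, with Welch-Satterthwaite degrees of freedom. This is the
#' form needed when only fitted values and their standard deviations are
#' available (sample size set to the number of time points entering each
#' pooled fit).
#'
#' @param m1,s1,n1 mean, SD, size of group 1.
#' @param m2,s2,n2 mean, SD, size of group 2.
#' @return List with `t`, `df`, `p` (two-sided).
#' @export
welch_test <- function(m1, s1, n1, m2, s2, n2) {
  stopifnot(s1 > 0, s2 > 0, n1 >= 2, n2 >= 2)
  v1 <- s1^2 / n1
  v2 <- s2^2 / n2
  t_stat <- (m1 - m2) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  list(t = t_stat, df = df,
       p = 2 * stats::pt(-abs(t_stat), df = df))
}
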