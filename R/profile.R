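#' Bin specification for radial concentration profiles
#'
#' @param bin_width radial bin width (µm); 3-4 µm is a sensible default
#'   range for nuclear-scale data.
#' @param apical_exclusion width (µm) of the zone below the apical surface
#'   excluded from fitting (nuclear centers cannot approach a surface closer
#'   than one radius, so counts there are measurement artifacts).
#' @param basal_exclusion same on the basal side.
#' @return A list of class `bin_spec`.
#' @export
bin_spec <- function(bin_width = 3, apical_exclusion = 4,
                     basal_exclusion = 4) {
  stopifnot(bin_width > 0, apical_exclusion >= 0, basal_exclusion >= 0)
  structure(
    list(bin_width = bin_width, apical_exclusion = apical_exclusion,
         basal_exclusion = basal_exclusion),
    class = "bin_spec"
  )
}

#' Expected bin counts and variances under uniform positional error
#'
#' Each measured radial position carries a uniform error distribution on
#' `[r - delta_r, r + delta_r]`. The probability of nucleus `n` lying in a
#' bin is the fractional overlap `p = |overlap| / (2 delta_r)`; expected
#' counts are `E(N_bin) = sum_n p`, and since each nucleus contributes a
#' Bernoulli indicator, `Var(N_bin) = sum_n p (1 - p)`.
#'
#' @param radial_positions measured radial positions (µm).
#' @param delta_r half-width of the uniform positional error (µm); 0 gives
#'   an exact histogram with zero variance.
#' @param edges strictly increasing bin edges (µm).
#' @return List with vectors `E` and `Var`, one entry per bin.
#' @export
bin_positions <- function(radial_positions, delta_r, edges) {
  if (any(diff(edges) <= 0)) stop("edges must be strictly increasing")
  stopifnot(delta_r >= 0)
  nb <- length(edges) - 1L
  E <- numeric(nb)
  V <- numeric(nb)
  if (!length(radial_positions)) {
    return(list(E = E, Var = V))
  }
  if (delta_r == 0) {
    inside <- radial_positions >= edges[1] & radial_positions <= edges[nb + 1]
    j <- findInterval(radial_positions[inside], edges,
                      rightmost.closed = TRUE)
    E <- tabulate(j, nbins = nb)
    return(list(E = as.numeric(E), Var = V))
  }
  lo <- radial_positions - delta_r
  hi <- radial_positions + delta_r
  for (jb in seq_len(nb)) {
    ov <- pmin(hi, edges[jb + 1]) - pmax(lo, edges[jb])
    p <- pmax(ov, 0) / (2 * delta_r)
    E[jb] <- sum(p)
    V[jb] <- sum(p * (1 - p))
  }
  list(E = E, Var = V)
}

#' Radial nuclear concentration profile at one time point
#'
#' Bins measured radial positions (laid from the basal edge upward; a final
#' partial bin at the apical side keeps its true, smaller volume), applies
#' the uniform positional-error count model, divides by spherical-shell bin
#' volumes to obtain concentrations, and attaches the error model used for
#' fitting: `sigma_y = sqrt(Var(N_bin)) / V_bin` and a positional
#' uncertainty `sigma_x` equal to `sqrt(bin width in µm)` µm (converted to
#' dimensionless ξ units by 1/a).
#'
#' @param radial_positions measured radial positions (µm) at time `t`.
#' @param t time point (min).
#' @param geometry a [shell_geometry()].
#' @param binspec a [bin_spec()].
#' @param delta_r positional error half-width (µm); default 3.
#' @return Object of class `concentration_profile`: data frame with
#'   `xi` (bin centers, r/a), `dxi`, `E_N`, `Var_N`, `V_bin`, `c`
#'   (µm⁻³), `sigma_y`, `sigma_x` (ξ units), and logical `fit` marking bins
#'   outside the exclusion zones; attributes `t`, `geometry`, `binspec`.
#' @export
concentration_profile <- function(radial_positions, t, geometry, binspec,
                                  delta_r = 3) {
  stopifnot(inherits(geometry, "shell_geometry"),
            inherits(binspec, "bin_spec"))
  if (!length(radial_positions)) stop("empty time point")
  a <- geometry$a
  b <- geometry$b
  edges <- seq(b, a, by = binspec$bin_width)
  if (edges[length(edges)] < a) edges <- c(edges, a)
  counts <- bin_positions(radial_positions, delta_r, edges)
  vols <- shell_volumes(geometry, edges)
  nb <- length(edges) - 1L
  centers <- (edges[-1] + edges[-(nb + 1L)]) / 2
  widths <- diff(edges)
  fit_ok <- (edges[-(nb + 1L)] >= b + binspec$basal_exclusion - 1e-9) &
    (edges[-1] <= a - binspec$apical_exclusion + 1e-9)
  out <- data.frame(
    xi = centers / a,
    dxi = widths / a,
    E_N = counts$E,
    Var_N = counts$Var,
    V_bin = vols$V_bin,
    c = counts$E / vols$V_bin,
    sigma_y = sqrt(counts$Var) / vols$V_bin,
    sigma_x = sqrt(widths) / a,
    fit = fit_ok
  )
  structure(out, t = t, geometry = geometry, binspec = binspec,
            delta_r = delta_r, class = c("concentration_profile",
                                         "data.frame"))
}

#' Profiles for a radial track table over time
#'
#' @param radial_tracks output of [to_radial()].
#' @param times time points (min) at which to build profiles; default all
#'   frame times present.
#' @param geometry,binspec,delta_r passed to [concentration_profile()].
#' @return A list of `concentration_profile`s, one per time point.
#' @export
profile_series <- function(radial_tracks, geometry, binspec,
                           times = NULL, delta_r = 3) {
  if (is.null(times)) times <- sort(unique(radial_tracks$t_min))
  lapply(times, function(t0) {
    r <- radial_tracks$r_um[radial_tracks$t_min == t0]
    concentration_profile(r, t0, geometry, binspec, delta_r)
  })
}

#' Fit the exponential growth law to nucleus counts over time
#'
#' Least squares on `ln N(t) = ln N0 + (ln 2 / TP) t`. When the initial
#' tracked count `N0` is known, the intercept is fixed and only the slope is
#' fitted.
#'
#' @param counts data frame with columns `t` (min) and `N` (> 0).
#' @param N0 known initial count, or `NULL` to fit the intercept.
#' @return A [growth_law()]; for a non-positive slope the cycle length is
#'   `Inf` and the result carries attribute `divisions_absent = TRUE`.
#' @export
fit_growth <- function(counts, N0 = NULL) {
  stopifnot(all(c("t", "N") %in% names(counts)))
  if (nrow(counts) < 3L) stop("need at least 3 time points")
  if (any(counts$N <= 0)) stop("all counts must be positive")
  y <- log(counts$N)
  t <- counts$t
  if (is.null(N0)) {
    fit <- stats::lm(y ~ t)
    slope <- unname(stats::coef(fit)[2])
    N0 <- exp(unname(stats::coef(fit)[1]))
  } else {
    slope <- sum((y - log(N0)) * t) / sum(t^2)
  }
  if (slope <= .Machine$double.eps) {
    gl <- structure(
      list(N0 = N0, TP = Inf, tau = Inf), class = "growth_law"
    )
    attr(gl, "divisions_absent") <- TRUE
    return(gl)
  }
  growth_law(N0 = N0, TP = log(2) / slope)
}

#' Mean distance of nuclei from the apical surface
#'
#' Expected-count-weighted mean of `a - r` over the profile bins; the
#' summary used to demonstrate basalward relaxation when divisions are
#' blocked.
#'
#' @param profile a [concentration_profile()].
#' @return Mean apical distance (µm).
#' @export
mean_apical_distance <- function(profile) {
  geom <- attr(profile, "geometry")
  r_centers <- profile$xi * geom$a
  sum(profile$E_N * (geom$a - r_centers)) / sum(profile$E_N)
}
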