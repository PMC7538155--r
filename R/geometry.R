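#' Spherical-shell tissue geometry
#'
#' The retinal neuroepithelium is idealized as a sector of a spherical shell
#' around the lens: basal surface at radius `b`, apical surface at radius `a`,
#' observed over a solid angle `Omega`. The solid angle is fixed either
#' directly or through the total observed tissue volume `Vtotal` via
#' `Omega = 3 * Vtotal / (a^3 - b^3)`.
#'
#' @param a apical radius (µm), distance from the lens center to the apical
#'   surface.
#' @param b basal radius (µm), `0 < b < a`.
#' @param Omega solid angle of the observed sector (sr); default a half
#'   sphere, `2*pi`.
#' @param Vtotal total sector volume (µm³); if given, overrides `Omega`.
#'
#' @return An object of class `shell_geometry` with fields `a`, `b`,
#'   `rho = b/a`, `Omega`, `S = Omega * a^2` (apical influx area, µm²) and
#'   `Vtotal = Omega * (a^3 - b^3) / 3` (µm³).
#' @export
#' @examples
#' geom <- shell_geometry(a = 100, b = 45)
#' geom$S / geom$a^2  # = Omega
shell_geometry <- function(a = 100, b = 45, Omega = 2 * pi, Vtotal = NULL) {
  stopifnot(is.numeric(a), is.numeric(b), length(a) == 1L, length(b) == 1L)
  if (!(b > 0 && a > b)) stop("require 0 < b < a")
  if (!is.null(Vtotal)) {
    Omega <- 3 * Vtotal / (a^3 - b^3)
  }
  if (!(Omega > 0 && Omega <= 4 * pi + 1e-12)) {
    stop("Omega must lie in (0, 4*pi]")
  }
  structure(
    list(
      a = a, b = b, rho = b / a, Omega = Omega,
      S = Omega * a^2, Vtotal = Omega * (a^3 - b^3) / 3
    ),
    class = "shell_geometry"
  )
}

#' @export
print.shell_geometry <- function(x, ...) {
  cat(sprintf(
    "Spherical-shell geometry: a = %g um, b = %g um (rho = %.3f)\n",
    x$a, x$b, x$rho
  ))
  cat(sprintf(
    "  Omega = %.4f sr, S = %.1f um^2, Vtotal = %.1f um^3\n",
    x$Omega, x$S, x$Vtotal
  ))
  invisible(x)
}

#' Volumes of radial bins in a spherical-shell sector
#'
#' Each bin `[edges[j], edges[j+1]]` is a spherical-shell sector of volume
#' `Omega/3 * (r_outer^3 - r_inner^3)`.
#'
#' @param geometry a [shell_geometry()].
#' @param edges strictly increasing bin edges (µm) within `[b, a]`.
#' @return A list with `V_bin` (µm³ per bin), `Omega`, and `S`.
#' @export
shell_volumes <- function(geometry, edges) {
  stopifnot(inherits(geometry, "shell_geometry"))
  if (any(diff(edges) <= 0)) stop("edges must be strictly increasing")
  tol <- 1e-9 * geometry$a
  if (min(edges) < geometry$b - tol || max(edges) > geometry$a + tol) {
    stop("edges must lie within [b, a]")
  }
  n <- length(edges) - 1L
  V <- geometry$Omega / 3 * (edges[-1L]^3 - edges[-(n + 1L)]^3)
  list(V_bin = V, Omega = geometry$Omega, S = geometry$S)
}

#' Exponential nuclear population growth law
#'
#' Apical divisions with neither death nor cycle exit give
#' `N(t) = N0 * exp(t / tau)` with `tau = TP / log(2)`, `TP` the mean cell
#' cycle length.
#'
#' @param N0 initial nucleus count (>= 1).
#' @param TP mean cell-cycle length (min).
#' @return An object of class `growth_law` with fields `N0`, `TP`, `tau`.
#' @export
growth_law <- function(N0, TP) {
  stopifnot(N0 >= 1, TP > 0)
  structure(list(N0 = N0, TP = TP, tau = TP / log(2)), class = "growth_law")
}

#' @export
print.growth_law <- function(x, ...) {
  cat(sprintf(
    "Exponential growth: N0 = %g, TP = %g min (tau = %.2f min)\n",
    x$N0, x$TP, x$tau
  ))
  invisible(x)
}

#' Expected nucleus count at time t
#'
#' @param growth a [growth_law()].
#' @param t time (min).
#' @return `N0 * exp(t / tau)`.
#' @export
expected_count <- function(growth, t) {
  stopifnot(inherits(growth, "growth_law"))
  growth$N0 * exp(t / growth$tau)
}
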