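test_that("eigenpairs satisfy the radial problem and its limits", {
  rho <- 0.45
  es <- solve_eigenproblem(rho, 8)
  expect_true(all(diff(es$lambdas) > 0))

  # no-flux boundary pair for every mode
  for (i in 1:8) {
    expect_lt(abs(es$dH(rho, i)), 1e-8)
    expect_lt(abs(es$dH(1, i)), 1e-8)
  }

  # ODE residual on a fine grid: (1/xi^2)(xi^2 H')' + lambda^2 H ~ 0
  xi <- seq(rho + 0.02, 0.98, length.out = 200)
  h <- 1e-5
  for (i in c(1, 4, 8)) {
    d2 <- (es$H(xi + h, i) - 2 * es$H(xi, i) + es$H(xi - h, i)) / h^2
    d1 <- (es$H(xi + h, i) - es$H(xi - h, i)) / (2 * h)
    resid <- d2 + 2 / xi * d1 + es$lambdas[i]^2 * es$H(xi, i)
    expect_lt(max(abs(resid)) / max(abs(es$lambdas[i]^2 * es$H(xi, i))),
              1e-4)
  }

  # orthonormality under the xi^2 weight
  G <- outer(1:4, 1:4, Vectorize(function(i, j) {
    stats::integrate(function(x) x^2 * es$H(x, i) * es$H(x, j),
                     rho, 1, rel.tol = 1e-12)$value
  }))
  expect_lt(max(abs(G - diag(4))), 1e-8)

  # agreement with an independent finite-difference eigensolver (4 digits)
  n <- 1200
  dx <- (1 - rho) / n
  xc <- rho + dx * (seq_len(n) - 0.5)
  xf <- rho + dx * (0:n)
  # conservative FV Laplacian with no-flux faces
  main <- -(c(0, xf[2:n]^2) + c(xf[2:n]^2, 0)) / (dx^2 * xc^2)
  off <- xf[2:n]^2 / (dx^2 * sqrt(xc[-n]^2 * xc[-1]^2))
  A <- diag(main)
  A[cbind(1:(n - 1), 2:n)] <- off
  A[cbind(2:n, 1:(n - 1))] <- off
  ev <- sort(abs(eigen(A, symmetric = TRUE, only.values = TRUE)$values))
  lam_fd <- sqrt(ev[2:4]) # skip the zero mode
  expect_equal(lam_fd, es$lambdas[1:3], tolerance = 1e-4)

  # thin-shell planar limit
  es_thin <- solve_eigenproblem(0.99, 4)
  expect_equal(es_thin$lambdas, (1:4) * pi / 0.01, tolerance = 1e-3)
})

test_that("influx parameters scale correctly and vanish without growth", {
  geom <- fixture_geometry()
  growth <- fixture_growth()
  ip1 <- influx_params(geom, growth, 0.1)
  ip2 <- influx_params(geom, growth, 0.2)
  expect_equal(ip2$f0, ip1$f0 / 2)
  expect_equal(ip2$sigma, ip1$sigma / 2)
  expect_equal(ip1$sigma, geom$a^2 / (0.1 * growth$tau))
  # influx amplitude is linear in the number of dividing cells
  ip_small <- influx_params(geom, growth_law(1, 300), 0.1)
  expect_equal(influx_params(geom, growth_law(100, 300), 0.1)$f0,
               100 * ip_small$f0)
  expect_equal(ip_small$sigma, ip1$sigma * 0.1 / 0.1)
})

test_that("initial-condition projection reproduces known decompositions", {
  geom <- fixture_geometry()
  growth <- fixture_growth()
  D <- 0.17
  es <- solve_eigenproblem(geom$rho, 8)
  ip <- influx_params(geom, growth, D)
  g0 <- iknm:::solve_g0(geom$rho, ip$sigma)

  # fine "profile" sampling the pure particular solution: all h_tilde ~ 0
  edges <- seq(geom$b, geom$a, by = 0.5)
  ctr <- (edges[-1] + edges[-length(edges)]) / 2
  mk_prof <- function(cvals) {
    structure(
      data.frame(xi = ctr / geom$a, dxi = diff(edges) / geom$a, c = cvals,
                 fit = TRUE),
      class = c("concentration_profile", "data.frame")
    )
  }
  part <- ip$f0 * iknm:::particular_P(ctr / geom$a, geom$rho, g0)
  proj <- project_initial(mk_prof(part), es, ip$f0, g0)
  expect_lt(max(abs(proj$h_tilde)), 1e-4 * max(part))

  # particular solution plus one unit of mode 1: h_tilde_1 ~ 1 (normalized)
  amp <- max(part)
  proj1 <- project_initial(
    mk_prof(part + amp * es$H(ctr / geom$a, 1)), es, ip$f0, g0
  )
  expect_equal(proj1$h_tilde[1], amp, tolerance = 1e-3)
  expect_lt(max(abs(proj1$h_tilde[-1])), 1e-3 * amp)

  # smooth boundary-compatible profile reconstructs within 5% L2 at M = 8
  rho <- geom$rho
  smooth_ic <- function(xi) {
    1e-3 * (1 + 0.5 * cos(pi * (xi - rho) / (1 - rho))) +
      ip$f0 * iknm:::particular_P(xi, rho, g0)
  }
  m_ic <- geom$Omega * geom$a^3 * stats::integrate(
    function(x) x^2 * smooth_ic(x), rho, 1
  )$value
  growth_ic <- growth_law(m_ic, growth$TP)
  ls <- linear_solution(mk_prof(smooth_ic(ctr / geom$a)), geom, growth_ic,
                        D, M = 8)
  xi_t <- seq(rho + 0.005, 0.995, length.out = 120)
  rec <- evaluate_linear(xi_t, 0, ls)
  rel <- sqrt(mean((rec - smooth_ic(xi_t))^2)) /
    sqrt(mean(smooth_ic(xi_t)^2))
  expect_lt(rel, 0.05)
  # the projected solution carries the initial mass N0 (volume constraint)
  xi_full <- seq(rho, 1, length.out = 2001)
  rec_full <- evaluate_linear(xi_full, 0, ls)
  w <- xi_full^2
  mass <- geom$Omega * geom$a^3 *
    sum((rec_full * w)[-1] + (rec_full * w)[-2001]) / 2 * diff(xi_full)[1]
  expect_equal(mass, m_ic, tolerance = 0.01)
})

test_that("series solution matches eigen decay, boundary conditions and an
           independent method-of-lines integration", {
  geom <- fixture_geometry()
  growth <- fixture_growth()
  D <- 0.17
  edges <- seq(geom$b, geom$a, by = 0.5)
  ctr <- (edges[-1] + edges[-length(edges)]) / 2
  ic <- fixture_ic(geom, growth$N0)
  prof0 <- structure(
    data.frame(xi = ctr / geom$a, dxi = diff(edges) / geom$a,
               c = ic(ctr / geom$a), fit = TRUE),
    class = c("concentration_profile", "data.frame")
  )
  ls <- linear_solution(prof0, geom, growth, D, M = 8)

  # pure single-mode initial condition decays as exp(-lambda^2 s)
  ls1 <- ls
  ls1$f0 <- 0
  ls1$alpha <- rep(0, 8)
  ls1$h <- c(1, rep(0, 7))
  xi <- seq(geom$rho, 1, length.out = 30)
  s <- 0.01
  expect_equal(
    evaluate_linear(xi, s, ls1),
    ls$eigensystem$H(xi, 1) * exp(-ls$eigensystem$lambdas[1]^2 * s),
    tolerance = 1e-10
  )

  # basal no-flux at all times
  for (s in c(0, 0.005, 0.02)) {
    expect_lt(abs(evaluate_linear(geom$rho, s, ls, deriv = TRUE)), 1e-6)
  }

  # apical influx flux in dimensional variables
  for (t in c(0, 100, 200)) {
    s <- D * t / geom$a^2
    lhs <- D * evaluate_linear(1, s, ls, deriv = TRUE) / geom$a
    rhs <- growth$N0 / (geom$S * growth$tau) * exp(t / growth$tau)
    expect_equal(lhs, rhs, tolerance = 1e-10)
  }

  # brute-force method-of-lines oracle from the same initial condition
  tg <- seq(0, 200, by = 20)
  mol <- solve_nonlinear(function(x) evaluate_linear(x, 0, ls),
                         D, Inf, geom, growth, tg, influx = "on",
                         n_nodes = 400)
  series <- vapply(tg, function(t) {
    evaluate_linear(mol$xi, D * t / geom$a^2, ls)
  }, numeric(length(mol$xi)))
  err <- abs(t(series) - mol$c) / max(abs(mol$c))
  expect_lt(max(err), 0.01)

  # global mass balance: volume integral growth equals the influx
  mass <- grid_mass(mol)
  expected <- mass[1] + geom$Omega * geom$a^3 * ls$f0 / ls$sigma *
    (exp(ls$sigma * D * tg / geom$a^2) - 1)
  expect_equal(mass, expected, tolerance = 0.01)
})

test_that("decay times scale as a^2 / (D lambda^2)", {
  geom <- fixture_geometry()
  es <- solve_eigenproblem(geom$rho, 5)
  T1 <- decay_times(es, 0.1, geom$a)
  T2 <- decay_times(es, 0.2, geom$a)
  expect_equal(T2, T1 / 2)
  expect_true(all(diff(T1) < 0))
  # thin-shell planar closed form for the slowest mode
  es_thin <- solve_eigenproblem(0.995, 2)
  expect_equal(decay_times(es_thin, 0.1, 100)[1],
               (1 - 0.995)^2 * 100^2 / (pi^2 * 0.1),
               tolerance = 1e-3)
})
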