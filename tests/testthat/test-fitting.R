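# a hand-built profile object with prescribed values and errors
toy_profile <- function(xi, c, sigma_y, sigma_x = 0, t = 0,
                        geom = fixture_geometry()) {
  structure(
    data.frame(xi = xi, dxi = c(diff(xi), diff(xi)[1]), E_N = NA,
               Var_N = NA, V_bin = NA, c = c, sigma_y = sigma_y,
               sigma_x = sigma_x, fit = TRUE),
    t = t, geometry = geom,
    class = c("concentration_profile", "data.frame")
  )
}

test_that("effective-variance chi-square reduces to the textbook cases", {
  xi <- seq(0.5, 0.95, by = 0.05)
  prof <- toy_profile(xi, c = rep(2e-3, length(xi)), sigma_y = 1e-4)
  # model identical to data
  expect_equal(chi2_profile(prof, rep(2e-3, length(xi)))$chi2, 0)
  # flat data offset by one sigma in each of m bins
  out <- chi2_profile(prof, rep(2e-3 + 1e-4, length(xi)))
  expect_equal(out$chi2, length(xi))
  expect_equal(out$nu, length(xi) - 1L)
  # a positional error with a steep model gradient deflates chi-square
  prof_x <- toy_profile(xi, c = rep(2e-3, length(xi)), sigma_y = 1e-4,
                        sigma_x = 0.02)
  steep <- chi2_profile(prof_x, rep(2e-3 + 1e-4, length(xi)),
                        model_gradient = rep(5e-3, length(xi)))
  expect_lt(steep$chi2, out$chi2)
  # degenerate weights are an error
  bad <- toy_profile(xi, c = rep(2e-3, length(xi)), sigma_y = 0)
  expect_error(chi2_profile(bad, rep(2e-3, length(xi))), "degenerate")
})

test_that("tail probability of the chi-square distribution is exact", {
  expect_equal(p_chi(0, 5), 1)
  expect_equal(p_chi(stats::qchisq(0.5, 10), 10), 0.5)
  expect_equal(p_chi(9.342, 10), 0.5, tolerance = 1e-3)
  expect_lt(p_chi(1e4, 10), 1e-12)
})

test_that("sigma_D matches the parabola width and the crossing point", {
  D <- seq(0.01, 0.3, by = 0.01)
  w <- 0.04
  curve <- data.frame(D = D, chi2 = 50 + (D - 0.15)^2 / w^2)
  expect_equal(sigma_D(curve, 0.15), w, tolerance = 1e-10)
  # agreement with the direct chi2_min + 1 crossing on a smooth curve
  smooth <- data.frame(D = D, chi2 = 30 + 400 * (sqrt(D) - sqrt(0.16))^2)
  sd_quad <- sigma_D(smooth, 0.16)
  i <- which.min(smooth$chi2)
  target <- smooth$chi2[i] + 1
  right <- stats::approx(smooth$chi2[i:length(D)], D[i:length(D)],
                         xout = target)$y
  expect_equal(sd_quad, right - D[i], tolerance = 0.1)
  # halving the grid step barely changes the estimate
  D2 <- seq(0.01, 0.3, by = 0.005)
  smooth2 <- data.frame(D = D2, chi2 = 30 + 400 * (sqrt(D2) - sqrt(0.16))^2)
  expect_equal(sigma_D(smooth2, 0.16), sd_quad, tolerance = 0.02)
  # pathological curvature errors out
  flat <- data.frame(D = D, chi2 = rep(1, length(D)))
  expect_error(sigma_D(flat, 0.15), "second difference")
})

test_that("noise-free model profiles are recovered exactly on the grid", {
  geom <- fixture_geometry()
  growth <- fixture_growth()
  cmax <- 4.12e-3
  D_true <- 0.05
  tg <- seq(0, 200, by = 10)
  edges <- seq(geom$b, geom$a, by = 3)
  ctr <- (edges[-1] + edges[-length(edges)]) / 2
  ic <- fixture_ic(geom, growth$N0)
  prof0 <- toy_profile(ctr / geom$a, ic(ctr / geom$a), sigma_y = 1e-5,
                       t = 0, geom = geom)
  prof0$dxi <- diff(edges) / geom$a
  ls0 <- linear_solution(prof0, geom, growth, D_true, M = 8)
  # the t = 0 data are the mode-projected profile itself, so the scanned
  # pipeline reproduces its own initial condition exactly at D_true
  prof0 <- toy_profile(ctr / geom$a,
                       pmin(pmax(evaluate_linear(ctr / geom$a, 0, ls0), 0),
                            0.999 * cmax),
                       sigma_y = 1e-5, t = 0, geom = geom)
  prof0$dxi <- diff(edges) / geom$a
  ls <- linear_solution(prof0, geom, growth, D_true, M = 8)
  truth <- solve_nonlinear(function(x) {
    pmin(pmax(evaluate_linear(x, 0, ls), 0), 0.999 * cmax)
  }, D_true, cmax, geom, growth, tg, "on", n_nodes = 200)
  profs <- c(list(prof0), lapply(seq_along(tg)[-1], function(k) {
    p <- toy_profile(ctr / geom$a,
                     model_concentration(truth, ctr / geom$a, tg[k]),
                     sigma_y = 1e-5, t = tg[k], geom = geom)
    p$dxi <- diff(edges) / geom$a
    p
  }))
  fit <- scan_D(profs, geom, growth, model = "nonlinear", cmax = cmax,
                D_grid = seq(0.03, 0.08, by = 0.01), n_nodes = 200)
  expect_equal(fit$D_star, D_true)
  expect_false(fit$boundary)
  # local convexity around the minimum
  cc <- fit$chi2_curve
  i <- which.min(cc$chi2_sum)
  expect_gt(cc$chi2_sum[i - 1] - 2 * cc$chi2_sum[i] + cc$chi2_sum[i + 1], 0)
})

test_that("pooled scans on noisy synthetic data recover D without bias", {
  growth <- fixture_growth()
  cmax <- 4.12e-3
  for (D_true in c(0.05, 0.09, 0.17)) {
    field <- fixture_field(D = D_true, cmax = cmax)
    fits <- lapply(1:3, function(s) {
      profs <- fixture_profiles(field, growth, seed = s, thin = 2L)
      scan_D(profs, field$geometry, growth, model = "nonlinear",
             cmax = cmax, D_grid = seq(0.01, 0.35, by = 0.01),
             n_nodes = 120)
    })
    D_hat <- vapply(fits, function(f) f$D_star, numeric(1))
    sd_hat <- vapply(fits, function(f) f$sigma_D, numeric(1))
    expect_lt(abs(stats::median(D_hat) - D_true), stats::median(sd_hat))
  }
})

test_that("the linear model over-estimates D on crowded data", {
  growth <- fixture_growth()
  cmax <- 4.12e-3
  field <- fixture_field(D = 0.09, cmax = cmax)
  profs <- fixture_profiles(field, growth, seed = 4, thin = 2L)
  nl <- scan_D(profs, field$geometry, growth, model = "nonlinear",
               cmax = cmax, D_grid = seq(0.02, 0.6, by = 0.02),
               n_nodes = 120)
  li <- scan_D(profs, field$geometry, growth, model = "linear",
               D_grid = seq(0.02, 0.6, by = 0.02))
  expect_gt(li$D_star, nl$D_star)
})

test_that("exclusion-width choice does not move the nonlinear estimate", {
  growth <- fixture_growth()
  cmax <- 4.12e-3
  field <- fixture_field(D = 0.09, cmax = cmax)
  fit_with <- function(excl) {
    profs <- fixture_profiles(field, growth,
                              binspec = bin_spec(3, excl, excl),
                              seed = 11, thin = 4L)
    scan_D(profs, field$geometry, growth, model = "nonlinear",
           cmax = cmax, D_grid = seq(0.02, 0.3, by = 0.02), n_nodes = 120)
  }
  f3 <- fit_with(3)
  f5 <- fit_with(5)
  expect_lt(abs(f3$D_star - f5$D_star), max(f3$sigma_D, f5$sigma_D))
})

test_that("bin-width selection tracks the fit probability criterion", {
  growth <- fixture_growth()
  cmax <- 4.12e-3
  field <- fixture_field(D = 0.09, cmax = cmax)
  geom <- field$geometry
  # single candidate passes through unchanged
  cfg <- simulation_config(geometry = geom, growth = growth,
                           duration = 40, D = 0.09)
  tr <- simulate_population(cfg, seed = 2)
  rad <- to_radial(apply_measurement_noise(tr, 3, 2), geom)
  single <- select_binning(rad, geom, growth, widths = 3.5, exclusions = 4,
                           times = c(0, 20, 40))
  expect_equal(single$bin_width, 3.5)
  # among candidate widths, the chosen one yields P_chi nearest 0.5
  sel <- select_binning(rad, geom, growth, widths = c(3, 9),
                        exclusions = 4, times = c(0, 20, 40),
                        D_grid = seq(0.03, 0.21, by = 0.03),
                        n_nodes = 100)
  tab <- attr(sel, "table")
  expect_equal(sel$bin_width, tab$width[which.min(tab$score)])
})

test_that("summary-statistic Welch test matches the reference t-test", {
  # identical groups
  same <- welch_test(0.1, 0.05, 100, 0.1, 0.05, 100)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  # agreement with stats::t.test on samples constructed to given moments
  set.seed(3)
  x <- rnorm(60)
  x <- (x - mean(x)) / sd(x) * 0.05 + 0.09
  y <- rnorm(80)
  y <- (y - mean(y)) / sd(y) * 0.08 + 0.13
  ref <- stats::t.test(x, y)
  ours <- welch_test(mean(x), sd(x), 60, mean(y), sd(y), 80)
  expect_equal(ours$p, ref$p.value, tolerance = 1e-12)
  expect_equal(ours$df, unname(ref$parameter), tolerance = 1e-9)
})
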