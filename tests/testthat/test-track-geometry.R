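test_that("apical surface fit recovers planes, spheres and noise levels", {
  set.seed(1)
  x <- seq(-30, 30, length.out = 40)
  # planar contour: quadratic coefficients vanish
  flat <- data.frame(x = x, y = 0.5 * x + 2, z = -0.1 * x + 5)
  fit <- fit_apical_surface(
    data.frame(x = flat$x, y = flat$y, z = rep(1, 40))
  )
  expect_lt(abs(fit$coeffs_xy[3]), 1e-10)
  expect_lt(fit$rmse, 1e-8)

  # circle of radius 100 near its pole: fitted curvature ~ 1/100
  a <- 100
  circ <- data.frame(x = x, y = sqrt(a^2 - x^2), z = 0)
  fit2 <- fit_apical_surface(data.frame(x = circ$x, y = circ$y,
                                        z = rep(0, 40)))
  expect_equal(abs(2 * fit2$coeffs_xy[3]), 1 / a, tolerance = 0.05)

  # isotropic noise sigma appears as the residual rmse
  sigma <- 0.8
  noisy <- data.frame(x = x, y = circ$y + rnorm(40, 0, sigma),
                      z = circ$y + rnorm(40, 0, sigma))
  fit3 <- fit_apical_surface(noisy)
  expect_equal(fit3$rmse, sigma, tolerance = 0.35)

  expect_error(
    fit_apical_surface(data.frame(x = rep(1, 6), y = 1:6, z = 1:6)),
    "degenerate"
  )
  # radius estimate from the two fitted planes
  expect_equal(apical_radius_from_fit(fit2), a, tolerance = 10)
})

test_that("radial conversion inverts the spherical export", {
  geom <- fixture_geometry()
  cfg <- simulation_config(geometry = geom, growth = growth_law(50, 300),
                           duration = 60, divisions_enabled = FALSE)
  tr <- simulate_population(cfg, seed = 2)
  rad0 <- to_radial(tr, geom)
  # noiseless round trip is exact
  expect_equal(rad0$r_um, sqrt(tr$x_um^2 + tr$y_um^2 + tr$z_um^2))
  expect_equal(rad0$l_um, geom$a - rad0$r_um)
  expect_false(any(rad0$flagged))
  # with export noise the recovered radii differ by at most the noise bound
  noisy <- apply_measurement_noise(tr, 3, seed = 3)
  rad <- to_radial(noisy, geom)
  expect_true(all(abs(rad$r_um - rad0$r_um) <= 3 + 1e-9))
  # positions pushed beyond the tolerance window are flagged, not clipped
  shifted <- tr
  shifted$x_um <- shifted$x_um * 1.2
  shifted$y_um <- shifted$y_um * 1.2
  shifted$z_um <- shifted$z_um * 1.2
  expect_true(any(to_radial(shifted, geom)$flagged))
})

test_that("cycle-normalized speeds are signed, centered differences", {
  # constant-velocity synthetic track: constant speed, basalward positive
  tr <- data.frame(
    track_id = 1L, parent_id = -1L, t_min = seq(0, 20, by = 2),
    x_um = 0, y_um = 0, z_um = 90 - 0.5 * seq(0, 20, by = 2)
  )
  geom <- fixture_geometry()
  rad <- to_radial(tr, geom)
  attr(rad, "meta") <- data.frame(
    track_id = 1L, parent_id = -1L, birth_t = 0, fate = "divided",
    cycle_len = 20
  )
  kin <- cycle_normalized_kinematics(rad)
  expect_true(all(abs(kin$speed_um_min - 0.5) < 1e-10))
  expect_equal(range(kin$t_norm), c(0, 1))

  # time reversal negates the signed speeds
  rev_tr <- tr
  rev_tr$z_um <- rev(tr$z_um)
  rad_rev <- to_radial(rev_tr, geom)
  attr(rad_rev, "meta") <- attr(rad, "meta")
  kin_rev <- cycle_normalized_kinematics(rad_rev)
  expect_equal(kin_rev$speed_um_min, -kin$speed_um_min)
})

test_that("mid-cycle signed speeds of a dividing cohort are centered on 0", {
  geom <- fixture_geometry()
  cfg <- simulation_config(geometry = geom, growth = growth_law(80, 150),
                           duration = 300, D = 0.09, variant = "gamma_c",
                           pop_cap = 2000)
  tr <- simulate_population(cfg, seed = 6)
  rad <- to_radial(tr, geom)
  kin <- cycle_normalized_kinematics(rad)
  mid <- kin[kin$t_norm > 0.2 & kin$t_norm < 0.7, ]
  se <- stats::sd(mid$speed_um_min) / sqrt(nrow(mid))
  expect_lt(abs(mean(mid$speed_um_min)), 2 * se + 0.02)
})

test_that("neighbour speed correlations behave under null and identity", {
  geom <- fixture_geometry()
  # two co-moving tracks one micron apart: pooled correlation 1
  t <- seq(0, 40, by = 2)
  set.seed(3)
  r1 <- 90 + cumsum(rnorm(length(t), 0, 0.8))
  co <- rbind(
    data.frame(track_id = 1L, parent_id = -1L, t_min = t, x_um = 0,
               y_um = 0, z_um = r1),
    data.frame(track_id = 2L, parent_id = -1L, t_min = t, x_um = 1,
               y_um = 0, z_um = r1)
  )
  out <- neighbor_speed_correlation(co, geom)
  pooled <- out[out$category == "pooled", ]
  expect_equal(pooled$correlation, 1, tolerance = 1e-6)

  # independent random walks: pooled correlation within the null bound
  set.seed(9)
  n_tracks <- 30
  walks <- do.call(rbind, lapply(seq_len(n_tracks), function(id) {
    ang <- runif(1, 0, 0.06)
    data.frame(
      track_id = id, parent_id = -1L, t_min = t,
      x_um = 75 * sin(ang), y_um = 0,
      z_um = (70 + cumsum(rnorm(length(t), 0, 1))) * cos(ang)
    )
  }))
  for (lag in c(0L, 1L)) {
    out0 <- neighbor_speed_correlation(walks, geom, long_axis = 40,
                                       short_axis = 40, lag = lag)
    pooled0 <- out0[out0$category == "pooled", ]
    expect_lt(abs(pooled0$correlation), 3 / sqrt(pooled0$n_pairs))
  }
  # sparse categories are NA, not zero
  few <- neighbor_speed_correlation(co, geom, min_pairs = 1000L)
  expect_true(all(is.na(few$correlation)))
})

test_that("experimental MSD handles degenerate and ballistic tracks", {
  geom <- fixture_geometry()
  t <- seq(0, 160, by = 2)
  mk <- function(id, r) data.frame(track_id = id, parent_id = -1L,
                                   t_min = t, r_um = r,
                                   l_um = geom$a - r, flagged = FALSE)
  still <- mk(1L, rep(80, length(t)))
  attr(still, "meta") <- data.frame(track_id = 1L, parent_id = -1L,
                                    birth_t = 0, fate = "censored",
                                    cycle_len = NA)
  msd <- experimental_msd(still, n_select = 1L, min_len = 10L, window = 200)
  expect_true(all(msd$msd_um2 == 0))
  expect_equal(msd$msd_um2[1], 0)
  expect_true(all(diff(msd$n_contributing) <= 0))

  ball <- mk(1L, 50 + 0.2 * t)
  attr(ball, "meta") <- attr(still, "meta")
  msd2 <- experimental_msd(ball, n_select = 1L, min_len = 10L, window = 200)
  expect_equal(msd2$msd_um2, (0.2 * msd2$lag_min)^2, tolerance = 1e-10)

  expect_error(
    experimental_msd(still, n_select = 5L, min_len = 10L, window = 200),
    "qualifying"
  )
})

test_that("MSD of the non-interacting population grows linearly in lag", {
  geom <- fixture_geometry()
  cfg <- simulation_config(geometry = geom, growth = growth_law(60, 300),
                           duration = 100, D = 0.09,
                           divisions_enabled = FALSE, init = "uniform")
  msds <- lapply(1:4, function(s) {
    rad <- to_radial(simulate_population(cfg, seed = s), geom)
    meta <- attr(rad, "meta")
    experimental_msd(rad, n_select = 60L, min_len = 50L, window = 100)
  })
  lag <- msds[[1]]$lag_min
  m <- rowMeans(vapply(msds, function(x) x$msd_um2, numeric(length(lag))))
  dec <- lag >= 4 & lag <= 40 # one decade of lags
  fit <- stats::lm(log(m[dec]) ~ log(lag[dec]))
  expect_equal(unname(coef(fit)[2]), 1, tolerance = 0.1)
  # and the amplitude matches 2 D lag
  expect_equal(mean(m[dec] / (2 * cfg$D * lag[dec])), 1, tolerance = 0.2)
})
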