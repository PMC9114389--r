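test_that("central age model recovers dose and overdispersion", {
  cam <- central_age_model(rep(100, 5), rep(5, 5))
  expect_equal(cam$delta, 100, tolerance = 1e-6)
  expect_lt(cam$od, 1e-3)

  d <- gen_de_distribution(500, od = 0.25, n = 200, rel_err = 0.05, seed = 3)
  cam2 <- central_age_model(d)
  expect_lt(abs(cam2$od - 0.25), 0.05)
  expect_lt(abs(cam2$delta / 500 - 1), 0.1)

  expect_error(central_age_model(c(100, 110), c(5, 5)), "at least 3")
  expect_error(central_age_model(c(-1, 100, 110), c(5, 5, 5)), "log space")
  # unlogged fallback is flagged
  un <- central_age_model(c(-1, 100, 110, 105), rep(5, 4), log = FALSE)
  expect_false(un$logged)
})

test_that("CAM overdispersion recovery is unbiased across simulations", {
  for (od in c(0.1, 0.25, 0.4)) {
    est <- vapply(1:100, function(i) {
      central_age_model(gen_de_distribution(500, od = od, n = 100,
                                            rel_err = 0.05,
                                            seed = 5000 + i))$od
    }, numeric(1))
    expect_lt(abs(mean(est) - od), 3 * sd(est) / sqrt(100) + 0.015)
  }
})

test_that("minimum age model finds the bleached population", {
  # degenerate mixture: MAM gamma agrees with CAM delta
  d <- gen_de_distribution(500, od = 0.1, n = 100, bleach_frac = 1, seed = 6)
  cam <- central_age_model(d)
  mam <- minimum_age_model(d, sigma_b = 0.1)
  expect_lt(abs(mam$gamma - cam$delta), 2 * (mam$gamma_sigma + cam$delta_sigma))

  # 70/30 partially bleached mixture: gamma recovers the burial dose
  d2 <- gen_de_distribution(500, od = 0.1, n = 100, bleach_frac = 0.7,
                            inflation_max = 1500, seed = 7)
  mam2 <- minimum_age_model(d2, sigma_b = 0.2)
  expect_lt(abs(mam2$gamma - 500), 3 * mam2$gamma_sigma)

  # MAM <= CAM on any sample (minimum never exceeds the centre)
  cam2 <- central_age_model(d2)
  expect_lte(mam2$gamma, cam2$delta * 1.02)

  expect_error(minimum_age_model(d2[1:4, ]), "at least 5")
})

test_that("MAM maximum likelihood beats a brute-force grid search", {
  d <- gen_de_distribution(400, od = 0.15, n = 8, bleach_frac = 0.75,
                           inflation_max = 1200, rel_err = 0.08, seed = 8)
  fit <- minimum_age_model(d, sigma_b = 0.15)
  oracle <- mam3_grid_oracle(d$de, d$de_sd, sigma_b = 0.15)
  expect_gte(fit$loglik, oracle$loglik - 1e-6)
  # and the grid argmax dose is in the same region
  expect_lt(abs(log(fit$gamma) - log(oracle$gamma)), 0.5)
})

test_that("g-value regression and span warning behave as specified", {
  delays <- c(1, 10, 100, 1000) * 48
  expect_equal(g_value(delays, rep(1, 4))$g, 0)
  g <- g_value(delays, 1 - 0.02 * log10(delays / 48), tc = 48)
  expect_equal(g$g, 2, tolerance = 1e-10)
  expect_false(g$short_span)
  expect_warning(g_value(c(48, 60, 72), c(1, 0.99, 0.985)), "decade")
  expect_error(g_value(c(48, 96), c(1, 0.99)), "at least 3")
})

test_that("fading correction solves the Huntley-Lamothe relation and round-trips", {
  expect_equal(fading_correct(100, 0, g = 0)$age, 100)

  # independent root-finder oracle for (100 kyr, 2 %/decade, tc 48 h)
  oracle <- uniroot(function(t) forward_fade(t, 2, 48) - 100,
                    c(100, 200), tol = 1e-8)$root
  corr <- fading_correct(100, 0, g = 2, tc = 48)
  expect_equal(corr$age, oracle, tolerance = 1e-4)
  expect_equal(round(corr$age), 116)

  # forward-fade the corrected age: round trip < 0.1%
  for (t_meas in c(20, 100, 300)) {
    tc <- fading_correct(t_meas, 0, g = 1.5)$age
    expect_lt(abs(forward_fade(tc, 1.5) - t_meas) / t_meas, 0.001)
  }

  # corrected age strictly increases with g
  ages <- vapply(c(0.5, 1, 2, 3), function(g) fading_correct(80, 0, g)$age,
                 numeric(1))
  expect_true(all(diff(ages) > 0))

  # too-strong fading for the age: outside method validity
  expect_error(fading_correct(1e5, 0, g = 25), "validity")
})

test_that("cosmic dose rate follows the configured parameterization", {
  cfg <- cosmic_config()
  # surface value at the geomagnetic pole = hard + soft constants
  surf <- cosmic_dose_rate(0, 0, cfg$pole_lat, cfg$pole_lon)
  expect_equal(surf, cfg$hard_surface + cfg$soft_surface, tolerance = 1e-9)
  # monotone attenuation with depth
  expect_lt(cosmic_dose_rate(2000, 0, 45, 0), cosmic_dose_rate(500, 0, 45, 0))
  # the cave configuration: 20 m limestone + sediment, 1116 m asl
  depth <- 2000 * 1.2 + c(30, 130) * 2.0
  rate <- cosmic_dose_rate(depth, 1116, 20, 103)
  expect_true(all(rate > 0 & rate < 0.1))
  expect_error(cosmic_dose_rate(-1))
})

test_that("dose-rate assembly applies water attenuation and quadrature errors", {
  # W = 0: simple sum
  expect_equal(assemble_dose_rate(2, 1, 0.84, 0.1, 0)$total, 3.94)
  # worked example: 2/1.05 + 1/1.0456 + 0.84 + 0.1 = 3.801
  expect_equal(assemble_dose_rate(2, 1, 0.84, 0.1, 0.04)$total, 3.801,
               tolerance = 1e-3)
  # monotone decreasing in W; linear in each dry component
  tots <- vapply(c(0, 0.03, 0.06, 0.1), function(w) {
    assemble_dose_rate(2, 1, 0.84, 0.1, w)$total
  }, numeric(1))
  expect_true(all(diff(tots) < 0))
  t1 <- assemble_dose_rate(2, 1, 0, 0, 0.04)$total
  t2 <- assemble_dose_rate(4, 2, 0, 0, 0.04)$total
  expect_equal(t2, 2 * t1)
  # quadrature
  s <- assemble_dose_rate(2, 1, 0.84, 0.1, 0, beta_dry_sd = 0.2,
                          gamma_dry_sd = 0.1)$sigma
  expect_equal(s, sqrt(0.04 + 0.01))
})

test_that("luminescence age divides dose by dose rate with propagated error", {
  expect_equal(lum_age(500, 0, 5, 0)$age, 100)
  expect_equal(lum_age(0, 0, 5, 0)$age, 0)
  a <- lum_age(515, 60, 3.6, 0.4)
  expect_equal(a$age, 515 / 3.6, tolerance = 1e-10)
  expect_equal(a$sigma, a$age * sqrt((60 / 515)^2 + (0.4 / 3.6)^2),
               tolerance = 1e-10)
  expect_error(lum_age(500, 0, 0, 0))
})
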