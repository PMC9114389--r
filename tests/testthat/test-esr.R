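test_that("SSE fit inverts a noiseless dose-response curve exactly", {
  curve <- gen_esr_curve(100, 600, 500, noise_rel = 0, seed = 1)
  f <- fit_sse(curve, n_mc = 0)
  expect_lt(abs(f$de / 500 - 1), 1e-3)
  expect_lt(abs(f$d0 / 600 - 1), 1e-3)
  expect_lt(abs(f$i_max / 100 - 1), 1e-3)
  expect_false(f$at_bound)

  # Dmax truncation: estimates agree with the full fit
  f2 <- fit_sse(curve, d_max = 832.5, n_mc = 0)
  expect_lt(abs(f2$de - f$de), 5)

  expect_error(fit_sse(curve[1:4, ]), "at least 5")
  expect_error(fit_sse(curve, d_max = 5000), "exceeds")
})

test_that("SSE De is unbiased over noisy replicates", {
  des <- vapply(1:50, function(i) {
    fit_sse(gen_esr_curve(100, 600, 500, noise_rel = 0.02, seed = 100 + i),
            n_mc = 0)$de
  }, numeric(1))
  # mean within 2 standard errors of truth
  expect_lt(abs(mean(des) - 500), 2 * sd(des) / sqrt(50))
})

test_that("Bayesian SSE mode yields a posterior consistent with the least-squares fit", {
  curve <- gen_esr_curve(100, 600, 500, noise_rel = 0.02, seed = 3)
  fb <- fit_sse(curve, mode = "bayesian", n_mc = 3000, seed = 4)
  expect_gt(fb$de_sigma, 0)
  expect_lt(abs(fb$de - 500), 4 * fb$de_sigma + 25)
  # reproducible
  fb2 <- fit_sse(curve, mode = "bayesian", n_mc = 3000, seed = 4)
  expect_equal(fb$de, fb2$de)
})

test_that("uptake fraction integral is the closed form 1/(p+2)", {
  expect_equal(uptake_fraction_integral(-1), 1)
  expect_equal(uptake_fraction_integral(0), 1 / 2)
  expect_equal(uptake_fraction_integral(2), 1 / 4)
  expect_error(uptake_fraction_integral(-2), "> -2")
})

test_that("uptake ratios match a brute-force Riemann refinement", {
  # p = -1 limit: closed-system ratios
  r <- uptake_useries_ratios(-1, 150, a234_init = 1.2)
  cs <- useries_forward(150, 200)
  expect_equal(r$a234_238, cs$a234_238, tolerance = 1e-10)
  expect_equal(r$a230_238, cs$a230_238, tolerance = 1e-10)

  # age -> 0: no ingrowth
  expect_lt(uptake_useries_ratios(0.5, 1e-6, 1.2)$a230_238, 1e-8)

  # p = 0, T = 150 kyr vs dense Riemann sum (1e6 parcels, uniform in u)
  k <- decay_constants()
  u <- (seq_len(1e6) - 0.5) / 1e6
  s <- 150000 * (1 - u)
  e4 <- exp(-k$lambda_234 * s)
  a230_ref <- mean(1 - exp(-k$lambda_230 * s) +
                     (1.2 - 1) * (k$lambda_230 / (k$lambda_230 - k$lambda_234)) *
                       (e4 - exp(-k$lambda_230 * s)))
  r0 <- uptake_useries_ratios(0, 150, 1.2, quad_steps = 2000)
  expect_equal(r0$a230_238, a230_ref, tolerance = 1e-4)
})

test_that("US-ESR age collapses to De / dose-rate in the closed-system limit", {
  cs <- useries_forward(150, 100)
  tis <- tibble::tibble(tissue = c("enamel", "dentine"),
                        a234_238 = cs$a234_238, a234_238_sd = 0,
                        a230_238 = cs$a230_238, a230_238_sd = 0)
  bud <- list(internal = 200, beta_dentine = 150, beta_sediment = 100,
              gamma_external = 500, cosmic = 50)
  total <- 1000 # mGy/kyr
  res <- us_esr_age(150 * total / 1000, 0, tis, bud, n_mc = 3, seed = 1)
  expect_equal(res$age_central, 150, tolerance = 1e-3)
  expect_equal(res$p_enamel, -1)
  expect_equal(res$p_dentine, -1)

  # De = 0 -> age 0
  res0 <- us_esr_age(0, 0, tis, bud, n_mc = 3, seed = 1)
  expect_equal(res0$age_central, 0)
})

test_that("US-ESR forward-simulate then invert recovers age and uptake exponents", {
  T_true <- 150
  r_en <- uptake_useries_ratios(-0.5, T_true, a234_init = 1.4)
  r_de <- uptake_useries_ratios(0, T_true, a234_init = 1.4)
  tis <- tibble::tibble(
    tissue = c("enamel", "dentine"),
    a234_238 = c(r_en$a234_238, r_de$a234_238), a234_238_sd = 0.01,
    a230_238 = c(r_en$a230_238, r_de$a230_238), a230_238_sd = 0.01)
  bud <- list(internal = 300, internal_sd = 30,
              beta_dentine = 200, beta_dentine_sd = 20,
              beta_sediment = 150, gamma_external = 500,
              gamma_external_sd = 50, cosmic = 50)
  f <- function(p) uptake_fraction_integral(p)
  de_true <- T_true * (300 * f(-0.5) / f(-1) + 200 * f(0) / f(-1) + 700) / 1000
  res <- us_esr_age(de_true, de_true * 0.05, tis, bud, n_mc = 200, seed = 2)
  expect_lt(abs(res$age - T_true), res$sigma)
  expect_lt(abs(res$p_enamel - (-0.5)), 0.15)
  expect_lt(abs(res$p_dentine - 0), 0.3)
  expect_lt(res$rejection_rate, 0.2)
})

test_that("US-ESR age is monotone in De and in total dose rate", {
  cs <- useries_forward(120, 150)
  tis <- tibble::tibble(tissue = "enamel",
                        a234_238 = cs$a234_238, a234_238_sd = 0,
                        a230_238 = cs$a230_238, a230_238_sd = 0)
  age_at <- function(de, gamma) {
    us_esr_age(de, 0, tis,
               list(internal = 200, gamma_external = gamma, cosmic = 50),
               n_mc = 2, seed = 1)$age_central
  }
  ages_de <- vapply(c(50, 100, 200, 400), age_at, numeric(1), gamma = 500)
  expect_true(all(diff(ages_de) > 0))
  ages_dr <- vapply(c(300, 500, 800), function(g) age_at(150, g), numeric(1))
  expect_true(all(diff(ages_dr) < 0))
})

test_that("external gamma geometry scales linearly with the scenario fraction", {
  expect_equal(external_gamma_geometry(0, 0, 0)$gamma, 0)
  full <- external_gamma_geometry(2, 8, 1.5, scenario = "full_sphere")
  half <- external_gamma_geometry(2, 8, 1.5, scenario = "current_burial",
                                  fraction = 0.5)
  expect_equal(half$gamma, full$gamma / 2)
  # lower external rate -> older age for the same De
  cs <- useries_forward(150, 100)
  tis <- tibble::tibble(tissue = "enamel", a234_238 = cs$a234_238,
                        a234_238_sd = 0, a230_238 = cs$a230_238,
                        a230_238_sd = 0)
  a_full <- us_esr_age(200, 0, tis,
                       list(internal = 200, gamma_external = full$gamma,
                            cosmic = 50), n_mc = 2, seed = 1)$age_central
  a_half <- us_esr_age(200, 0, tis,
                       list(internal = 200, gamma_external = half$gamma,
                            cosmic = 50), n_mc = 2, seed = 1)$age_central
  expect_gt(a_half, a_full)
  expect_error(external_gamma_geometry(1, 1, 1, scenario = "orbital"))
})
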