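test_that("230Th/U age solves the ingrowth equation and round-trips the forward model", {
  # trivial anchors
  expect_equal(th230_age(0, 1.5)$age, 0)
  expect_error(th230_age(1, 1), "non-finite age")

  # forward-model round trip at the flowstone-like point
  r <- useries_forward(104, 500)
  expect_lt(abs(th230_age(r$a230_238, r$a234_238)$age - 104), 0.1)

  # round trip over a grid of ages and initial enrichments, < 0.1%
  grid <- expand.grid(t = c(1, 5, 20, 50, 100, 150, 250, 350, 450, 500),
                      d = c(0, 100, 250, 500, 750, 900, 1000))
  fw <- useries_forward(grid$t, grid$d)
  t_hat <- cavechron:::th230_solve(fw$a230_238, fw$a234_238) / 1000
  expect_lt(max(abs(t_hat - grid$t) / grid$t), 0.001)

  # strictly increasing in a230_238 at fixed a234_238
  a230 <- seq(0.05, 1.0, by = 0.05)
  ages <- cavechron:::th230_solve(a230, rep(1.3, length(a230)))
  expect_true(all(diff(ages) > 0))
})

test_that("Monte-Carlo age uncertainty is seeded and reproducible", {
  a <- th230_age(0.6, 1.4, 0.02, 0.02, n_mc = 2000, seed = 11)
  b <- th230_age(0.6, 1.4, 0.02, 0.02, n_mc = 2000, seed = 11)
  expect_identical(a, b)
  expect_gt(a$sigma, 0)
  # draws at/beyond equilibrium are counted, not silently dropped
  c <- th230_age(0.995, 1.0, 0.05, 0.001, n_mc = 2000, seed = 1)
  expect_gt(c$n_rejected, 0)
})

test_that("detrital correction recovers the true age of contaminated sub-samples", {
  # r0 = 0 is the identity on the age
  d0 <- detrital_correct(1.0, 1.5, 0.9, r0 = 0, n_mc = 0)
  expect_equal(d0$age, d0$age_uncorr, tolerance = 1e-5)

  # no detectable 232Th: corrected = uncorrected
  dn <- detrital_correct(0.6, 1.4, Inf, n_mc = 0)
  expect_equal(dn$age, dn$age_uncorr)

  # forward-contaminate then invert, both r0 conventions
  for (conv in c("present", "initial")) {
    s <- gen_useries_set(100, 200, r0 = 0.5,
                         contamination_fracs = c(0, 0.2, 0.4),
                         noise_rel = 0, seed = 2, detrital_at = conv)
    for (i in 2:3) {
      d <- detrital_correct(s$a230_238[i], s$a234_238[i], s$a230_232[i],
                            r0 = 0.5, r0_at = conv, n_mc = 0)
      expect_lt(abs(d$age - 100), 0.05)
    }
  }
})

test_that("over-correction is flagged and bulk-Earth correction magnifies errors", {
  # subtracting more 230Th than is present drives the corrected ratio
  # negative -> flagged, age NA
  d <- detrital_correct(0.3, 1.3, 0.4, r0 = 0.825, r0_at = "present", n_mc = 0)
  expect_true(d$overcorrected)
  expect_true(is.na(d$age))

  # heavy contamination + 50% r0 uncertainty: corrected sigma >> uncorrected
  s <- gen_useries_set(100, 200, r0 = 0.5,
                       contamination_fracs = c(0, 0.15, 0.25, 0.35),
                       noise_rel = 0, seed = 2, detrital_at = "present")
  dm <- detrital_correct(s$a230_238[4], s$a234_238[4], s$a230_232[4],
                         a230_238_sd = 0.01, r0 = 0.825, r0_sigma = 0.4125,
                         r0_at = "present", n_mc = 1000, seed = 5)
  du <- th230_age(s$a230_238[4], s$a234_238[4], 0.01, 0, n_mc = 1000, seed = 5)
  expect_gt(dm$sigma, 3 * du$sigma)
})

test_that("isochron intercept estimates the shared detrital ratio", {
  # exact line y = 0.5 + 2x
  x <- c(1, 2, 3, 5)
  f <- fit_detrital_intercept(tibble::tibble(a234_232 = x, a230_232 = 0.5 + 2 * x))
  expect_equal(f$r0, 0.5, tolerance = 1e-10)
  expect_lt(f$r0_sigma, 1e-8)

  # noiseless generator: intercept exactly r0 (present-day convention)
  s <- gen_useries_set(100, 200, r0 = 0.5,
                       contamination_fracs = c(0.1, 0.25, 0.4, 0.55),
                       noise_rel = 0, seed = 3)
  f2 <- fit_detrital_intercept(s)
  expect_equal(f2$r0, 0.5, tolerance = 1e-6)

  # 2% noise: recovery within the fit error
  s3 <- gen_useries_set(100, 200, r0 = 0.5,
                        contamination_fracs = c(0.1, 0.25, 0.4, 0.55),
                        noise_rel = 0.02, seed = 4)
  f3 <- fit_detrital_intercept(s3)
  expect_lt(abs(f3$r0 - 0.5), 4 * f3$r0_sigma + 0.05)

  # preconditions
  expect_error(fit_detrital_intercept(s[1:2, ]), "at least 3")
  expect_error(
    fit_detrital_intercept(tibble::tibble(a234_232 = c(1, 1, 1),
                                          a230_232 = c(1, 2, 3))),
    "no isochron")
})

test_that("inverse-variance weighted mean and MSWD follow the hand formulas", {
  # {90+-5, 110+-5}: mean 100, internal 5/sqrt(2), MSWD 8
  w <- weighted_mean_age(c(90, 110), c(5, 5))
  expect_equal(w$mean, 100)
  expect_equal(w$sigma_internal, 5 / sqrt(2))
  expect_equal(w$mswd, 8)
  expect_equal(w$sigma, 5 / sqrt(2) * sqrt(8))

  # equal sigmas: arithmetic mean; permutation invariant
  w2 <- weighted_mean_age(c(100, 100, 100), c(10, 10, 10))
  expect_equal(w2$mean, 100)
  expect_equal(w2$sigma_internal, 10 / sqrt(3))
  a <- c(164, 149, 140)
  s <- c(24, 22, 23)
  p <- sample(3)
  expect_equal(weighted_mean_age(a, s)$mean, weighted_mean_age(a[p], s[p])$mean)

  expect_error(weighted_mean_age(c(1, 2), c(0, 1)))
  expect_error(weighted_mean_age(100, 10), "at least 2")
})

test_that("the measurement reader normalises 2-sigma tables to 1-sigma", {
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(
    label = c("a", "b"), a230_238 = c(0.5, 0.6), a230_238_sd = c(0.02, 0.02),
    a234_238 = c(1.3, 1.3), a234_238_sd = c(0.02, 0.02),
    sigma_level = c(2, 1)), path)
  d <- read_useries_csv(path)
  expect_equal(d$a230_238_sd, c(0.01, 0.02))

  path2 <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(label = "a", a230_238 = 0.5), path2)
  expect_error(read_useries_csv(path2), "missing columns")
})

test_that("per-sample workflow flags over-corrected sub-samples and averages the rest", {
  s <- gen_useries_set(120, 300, r0 = 0.5,
                       contamination_fracs = c(0.05, 0.15, 0.25, 0.35),
                       noise_rel = 0.01, seed = 6)
  res <- useries_ages(s, r0 = 0.5, r0_at = "present", n_mc = 300, seed = 9)
  expect_equal(nrow(res$samples), 4)
  expect_false(any(res$samples$overcorrected))
  expect_lt(abs(res$weighted_mean$mean - 120), 10)
})
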