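#' Construct an age estimate record
#'
#' The common currency of the dating modules: an age in kyr with a 1-sigma
#' uncertainty, a role describing how the age constrains the stratigraphy,
#' and a unit label.
#'
#' @param age Age in kyr (before present; larger = older).
#' @param sigma 1-sigma uncertainty in kyr (non-negative).
#' @param role One of `"direct"`, `"minimum"`, `"maximum"`.
#' @param unit_label Optional stratigraphic unit label.
#' @param label Optional sample label.
#' @return A one-row tibble with columns `label`, `age`, `sigma`, `role`,
#'   `unit_label`.
#' @export
age_estimate <- function(age, sigma, role = c("direct", "minimum", "maximum"),
                         unit_label = NA_character_, label = NA_character_) {
  role <- match.arg(role)
  check_scalar(sigma, "sigma", lower = 0)
  if (role == "direct") check_scalar(age, "age")
  tibble(label = label, age = age, sigma = sigma, role = role,
         unit_label = unit_label)
}

# Vectorised bisection solver for the single-stage 230Th ingrowth equation
#   a230 = 1 - exp(-l0 t) + (a234 - 1) * l0/(l0-l4) * (1 - exp(-(l0-l4) t))
# Returns t in years; NA where no root exists in (0, t_max].
th230_solve <- function(a230_238, a234_238, k = decay_constants(),
                        t_max = 1e7, tol = 1) {
  l0 <- k$lambda_230
  l4 <- k$lambda_234
  f <- function(t) {
    1 - exp(-l0 * t) +
      (a234_238 - 1) * (l0 / (l0 - l4)) * (1 - exp(-(l0 - l4) * t)) -
      a230_238
  }
  lo <- rep(0, length(a230_238))
  hi <- rep(t_max, length(a230_238))
  out <- rep(NA_real_, length(a230_238))
  zero <- !is.na(a230_238) & a230_238 <= 0
  out[zero] <- ifelse(a230_238[zero] == 0, 0, NA_real_)
  # analytic asymptote guard: at/beyond secular equilibrium there is no
  # root, even where floating-point underflow makes f(t_max) == 0
  asym <- 1 + (a234_238 - 1) * (l0 / (l0 - l4))
  bad <- is.na(a230_238) | is.na(a234_238) | zero | f(t_max) < 0 |
    a230_238 >= asym * (1 - 1e-9)
  n_it <- ceiling(log2(t_max / tol)) + 2
  for (i in seq_len(n_it)) {
    mid <- (lo + hi) / 2
    up <- f(mid) < 0
    lo[up] <- mid[up]
    hi[!up] <- mid[!up]
  }
  res <- (lo + hi) / 2
  out[!bad] <- res[!bad]
  out
}

#' Forward 230Th ingrowth model
#'
#' Predicts present-day (230Th/238U) and (234U/238U) activity ratios for a
#' closed-system carbonate of known age and initial 234U enrichment.
#'
#' @param t_kyr True age in kyr.
#' @param delta234_init Initial d234U in permil (0 = secular 234U/238U).
#' @param k [decay_constants()].
#' @return Tibble with columns `a234_238`, `a230_238`.
#' @export
useries_forward <- function(t_kyr, delta234_init = 0, k = decay_constants()) {
  t <- t_kyr * 1000
  l0 <- k$lambda_230
  l4 <- k$lambda_234
  a234 <- 1 + (delta234_init / 1000) * exp(-l4 * t)
  a230 <- 1 - exp(-l0 * t) +
    (a234 - 1) * (l0 / (l0 - l4)) * (1 - exp(-(l0 - l4) * t))
  tibble(a234_238 = a234, a230_238 = a230)
}

#' Closed-form 230Th/U age with Monte-Carlo uncertainty
#'
#' Solves the standard single-stage ingrowth equation for the age of a
#' carbonate from its measured activity ratios, by bisection on
#' t in (0, 10 Myr] to a tolerance of 1 yr. The 1-sigma age uncertainty is
#' propagated by seeded Monte-Carlo resampling of the input ratios.
#'
#' @param a230_238,a234_238 Measured activity ratios.
#' @param a230_238_sd,a234_238_sd Their 1-sigma uncertainties.
#' @param k [decay_constants()].
#' @param n_mc Number of Monte-Carlo draws for the uncertainty.
#' @param seed Integer seed for the Monte-Carlo resampling.
#' @return A one-row tibble (see [age_estimate()]) with extra columns
#'   `mc_mean` (mean of the age draws, kyr) and `n_rejected` (draws with no
#'   root, e.g. at/beyond secular equilibrium).
#' @examples
#' r <- useries_forward(104, 500)
#' th230_age(r$a230_238, r$a234_238)$age # ~104
#' @export
th230_age <- function(a230_238, a234_238, a230_238_sd = 0, a234_238_sd = 0,
                      k = decay_constants(), n_mc = 10000, seed = NULL) {
  check_scalar(a230_238, "a230_238", lower = 0)
  check_scalar(a234_238, "a234_238", lower = .Machine$double.eps)
  check_scalar(a230_238_sd, "a230_238_sd", lower = 0)
  check_scalar(a234_238_sd, "a234_238_sd", lower = 0)
  t0 <- th230_solve(a230_238, a234_238, k)
  if (is.na(t0)) {
    abort("non-finite age: no root in (0, 10 Myr]; ratios at or beyond secular equilibrium")
  }
  if (a230_238_sd == 0 && a234_238_sd == 0) {
    est <- age_estimate(t0 / 1000, 0)
    est$mc_mean <- t0 / 1000
    est$n_rejected <- 0L
    return(est)
  }
  draws <- with_seed(seed, {
    a230 <- rnorm(n_mc, a230_238, a230_238_sd)
    a234 <- rnorm(n_mc, a234_238, a234_238_sd)
    a230[a230 < 0] <- 0
    th230_solve(a230, a234, k)
  })
  ok <- is.finite(draws)
  est <- age_estimate(t0 / 1000, sd(draws[ok]) / 1000)
  est$mc_mean <- mean(draws[ok]) / 1000
  est$n_rejected <- sum(!ok)
  est
}

#' Detrital-thorium correction of a 230Th/U age
#'
#' Subtracts the non-radiogenic 230Th contributed by detritus, assuming an
#' initial (230Th/232Th) activity ratio `r0`. The detrital 230Th decays with
#' exp(-lambda230 t), so the correction and the age are iterated to
#' convergence (|dt| < 0.01 kyr). Uncertainty is propagated by seeded
#' Monte-Carlo over the measured ratios and `r0`. Detrital uranium is not
#' corrected.
#'
#' @inheritParams th230_age
#' @param a230_232 Measured (230Th/232Th) activity ratio; `Inf` or `NA`
#'   means no detectable 232Th (no correction).
#' @param a230_232_sd Its 1-sigma uncertainty.
#' @param r0 Assumed initial/detrital (230Th/232Th) activity ratio
#'   (0.825 = Bulk Earth; an isochron intercept may give a site value).
#' @param r0_sigma 1-sigma uncertainty on `r0`.
#' @param r0_at `"initial"` (default): `r0` is the detrital ratio at
#'   formation, and the detrital 230Th decays with exp(-lambda230 t)
#'   during the iteration. `"present"`: `r0` is the present-day detrital
#'   ratio (what [fit_detrital_intercept()] on measured ratios
#'   estimates), subtracted without a decay factor.
#' @return A one-row tibble with `age`, `sigma` (corrected, kyr), the
#'   corrected ratio `a230_238_corr`, logical `overcorrected` (the
#'   correction drove the corrected ratio negative), and `age_uncorr`.
#' @export
detrital_correct <- function(a230_238, a234_238, a230_232,
                             a230_238_sd = 0, a234_238_sd = 0, a230_232_sd = 0,
                             r0 = 0.825, r0_sigma = 0,
                             r0_at = c("initial", "present"),
                             k = decay_constants(), n_mc = 10000, seed = NULL) {
  r0_at <- match.arg(r0_at)
  check_scalar(a230_238, "a230_238", lower = 0)
  check_scalar(a234_238, "a234_238", lower = .Machine$double.eps)
  check_scalar(r0, "r0", lower = 0)
  t_uncorr <- th230_solve(a230_238, a234_238, k)
  decay_l <- if (r0_at == "initial") k$lambda_230 else 0

  correct_once <- function(a230, a234, a232_238, r0v) {
    # the corrected age solves ingrowth(t) = a230 - r0 a232 exp(-l t).
    # With decaying detrital Th (initial convention) the root function
    # h(t) = ingrowth(t) + detrital(t) - a230 need not be monotone: under
    # heavy contamination it starts positive, dips, and recrosses zero.
    # The physically meaningful solution - the one the age<->correction
    # iteration from the uncorrected age converges to - is the upper
    # root, bracketed on a coarse grid and then bisected to < 0.01 kyr.
    l0 <- k$lambda_230
    l4 <- k$lambda_234
    n <- length(a230)
    h <- function(t) {
      1 - exp(-l0 * t) +
        (a234 - 1) * (l0 / (l0 - l4)) * (1 - exp(-(l0 - l4) * t)) -
        a230 + r0v * a232_238 * exp(-decay_l * t)
    }
    t_max <- 1e7
    grid <- seq(0, t_max, length.out = 501)
    hg <- vapply(grid, h, numeric(n))
    hg <- matrix(hg, nrow = n)
    lo <- rep(NA_real_, n)
    hi <- rep(NA_real_, n)
    for (i in seq_len(n)) {
      neg <- which(hg[i, ] < 0)
      if (!length(neg)) next            # h > 0 everywhere: over-correction
      j <- max(neg)
      if (j == ncol(hg)) next           # still negative at t_max: no root
      lo[i] <- grid[j]
      hi[i] <- grid[j + 1]
    }
    over <- h(0) > 0 & is.na(lo)
    bad <- is.na(lo)
    lo[bad] <- 0
    hi[bad] <- t_max
    for (i in seq_len(30)) {
      mid <- (lo + hi) / 2
      up <- h(mid) < 0
      lo[up] <- mid[up]
      hi[!up] <- mid[!up]
    }
    t <- (lo + hi) / 2
    t[bad] <- NA_real_
    a230c <- a230 - r0v * a232_238 * exp(-decay_l * ifelse(is.na(t), 0, t))
    list(t = t, a230c = a230c, over = over)
  }

  if (!is.finite(a230_232)) {
    est <- age_estimate(t_uncorr / 1000, 0)
    base <- th230_age(a230_238, a234_238, a230_238_sd, a234_238_sd,
                      k = k, n_mc = n_mc, seed = seed)
    est$sigma <- base$sigma
    est$a230_238_corr <- a230_238
    est$overcorrected <- FALSE
    est$age_uncorr <- t_uncorr / 1000
    return(est)
  }
  check_scalar(a230_232, "a230_232", lower = .Machine$double.eps)
  a232_238 <- a230_238 / a230_232

  central <- correct_once(a230_238, a234_238, a232_238, r0)
  over <- isTRUE(central$over)
  need_mc <- any(c(a230_238_sd, a234_238_sd, a230_232_sd, r0_sigma) > 0)
  sig <- 0
  if (need_mc) {
    draws <- with_seed(seed, {
      a230 <- pmax(rnorm(n_mc, a230_238, a230_238_sd), 0)
      a234 <- rnorm(n_mc, a234_238, a234_238_sd)
      a230_232_d <- pmax(rnorm(n_mc, a230_232, a230_232_sd), 1e-12)
      r0v <- pmax(rnorm(n_mc, r0, r0_sigma), 0)
      correct_once(a230, a234, a230 / a230_232_d, r0v)$t
    })
    sig <- sd(draws[is.finite(draws)]) / 1000
  }
  est <- tibble(label = NA_character_,
                age = if (over) NA_real_ else central$t / 1000,
                sigma = sig, role = "direct", unit_label = NA_character_)
  est$a230_238_corr <- central$a230c
  est$overcorrected <- over
  est$age_uncorr <- t_uncorr / 1000
  est
}

#' Isochron intercept estimate of the detrital (230Th/232Th) ratio
#'
#' Fits a line of measured (230Th/232Th) on (234U/232Th) across coeval
#' sub-samples sharing a common detrital component; the intercept on the
#' (230Th/232Th) axis estimates the initial/detrital ratio r0.
#'
#' @param data Data frame with columns `a234_232` and `a230_232` (one row
#'   per sub-sample); at least 3 rows.
#' @param weighted If `TRUE`, weight by `1/a230_232_sd^2` (requires an
#'   `a230_232_sd` column); default is ordinary least squares.
#' @return List with `r0` (intercept), `r0_sigma` (its standard error),
#'   `slope` and the `lm` fit.
#' @export
fit_detrital_intercept <- function(data, weighted = FALSE) {
  data <- as_tibble(data)
  keep <- is.finite(data$a234_232) & is.finite(data$a230_232)
  data <- data[keep, ]
  if (nrow(data) < 3) abort("need at least 3 sub-samples with finite Th-normalised ratios")
  if (sd(data$a234_232) < 1e-12 * max(1, abs(mean(data$a234_232)))) {
    abort("no isochron: degenerate spread in a234_232")
  }
  fit <- if (weighted) {
    if (!"a230_232_sd" %in% names(data)) abort("weighted fit needs an `a230_232_sd` column")
    lm(a230_232 ~ a234_232, data = data, weights = 1 / data$a230_232_sd^2)
  } else {
    lm(a230_232 ~ a234_232, data = data)
  }
  sm <- suppressWarnings(summary(fit))$coefficients
  list(r0 = unname(coef(fit)[1]), r0_sigma = unname(sm[1, 2]),
       slope = unname(coef(fit)[2]), fit = fit)
}

#' Inverse-variance weighted mean age with MSWD
#'
#' @param age Vector of ages (kyr) or a data frame with `age` and `sigma`
#'   columns.
#' @param sigma Vector of 1-sigma uncertainties (> 0), if `age` is numeric.
#' @return A one-row tibble with `mean`, `sigma_internal`
#'   (1/sqrt(sum of weights)), `mswd`, and `sigma` = the reported error:
#'   internal, inflated by sqrt(MSWD) when MSWD > 1.
#' @examples
#' weighted_mean_age(c(164, 149, 140), c(24, 22, 23))$mean # ~151
#' @export
weighted_mean_age <- function(age, sigma = NULL) {
  if (is.data.frame(age)) {
    sigma <- age$sigma
    age <- age$age
  }
  if (length(age) < 2) abort("need at least 2 ages")
  if (any(!is.finite(age)) || any(!is.finite(sigma))) abort("ages and sigmas must be finite")
  if (any(sigma <= 0)) abort("all sigmas must be > 0")
  w <- 1 / sigma^2
  m <- sum(age * w) / sum(w)
  se_int <- sqrt(1 / sum(w))
  mswd <- sum((age - m)^2 * w) / (length(age) - 1)
  tibble(mean = m, sigma_internal = se_int, mswd = mswd,
         sigma = se_int * max(1, sqrt(mswd)), n = length(age))
}

#' Read a U-series measurement table
#'
#' Expected columns: `label`, `a230_238`, `a230_238_sd`, `a234_238`,
#' `a234_238_sd`, optionally `a230_232`, `a230_232_sd`, `a234_232`,
#' `a234_232_sd`, and `sigma_level` (1 or 2; reported uncertainties are
#' divided by it so everything is stored at 1 sigma).
#'
#' @param path CSV file path.
#' @return Tibble with uncertainties at 1 sigma.
#' @export
read_useries_csv <- function(path) {
  data <- readr::read_csv(path, show_col_types = FALSE)
  req <- c("a230_238", "a230_238_sd", "a234_238", "a234_238_sd")
  miss <- setdiff(req, names(data))
  if (length(miss)) abort(paste("missing columns:", paste(miss, collapse = ", ")))
  lev <- if ("sigma_level" %in% names(data)) data$sigma_level else 1
  if (any(!lev %in% c(1, 2))) abort("sigma_level must be 1 or 2")
  for (col in grep("_sd$", names(data), value = TRUE)) {
    if (any(data[[col]] < 0, na.rm = TRUE)) abort(paste(col, "has negative values"))
    data[[col]] <- data[[col]] / lev
  }
  data$sigma_level <- NULL
  as_tibble(data)
}

#' Per-sample U-series ages with a common detrital correction
#'
#' Applies [th230_age()] and [detrital_correct()] to each row of a
#' measurement table and summarises the corrected ages with
#' [weighted_mean_age()].
#'
#' @param data Measurement tibble (see [read_useries_csv()]).
#' @inheritParams detrital_correct
#' @return List with `samples` (per-row tibble of uncorrected and corrected
#'   ages), `weighted_mean` (tibble), and `r0` used.
#' @export
useries_ages <- function(data, r0 = 0.825, r0_sigma = 0,
                         r0_at = c("initial", "present"),
                         k = decay_constants(), n_mc = 10000, seed = NULL) {
  r0_at <- match.arg(r0_at)
  data <- as_tibble(data)
  rows <- purrr::map(seq_len(nrow(data)), function(i) {
    d <- data[i, ]
    a230_232 <- if ("a230_232" %in% names(d)) d$a230_232 else NA_real_
    a230_232_sd <- if ("a230_232_sd" %in% names(d)) d$a230_232_sd else 0
    corr <- detrital_correct(
      d$a230_238, d$a234_238, a230_232,
      d$a230_238_sd, d$a234_238_sd, ifelse(is.na(a230_232_sd), 0, a230_232_sd),
      r0 = r0, r0_sigma = r0_sigma, r0_at = r0_at, k = k,
      n_mc = n_mc, seed = if (is.null(seed)) NULL else derive_seed(seed, i)
    )
    tibble(
      label = if ("label" %in% names(d)) as.character(d$label) else as.character(i),
      age_uncorr = corr$age_uncorr, age = corr$age, sigma = corr$sigma,
      overcorrected = corr$overcorrected
    )
  })
  samples <- dplyr::bind_rows(rows)
  usable <- samples[!samples$overcorrected & is.finite(samples$age) &
                      samples$sigma > 0, ]
  wm <- if (nrow(usable) >= 2) weighted_mean_age(usable) else NULL
  list(samples = samples, weighted_mean = wm, r0 = r0, r0_sigma = r0_sigma)
}
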