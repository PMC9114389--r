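#' Central age model for single-grain equivalent doses
#'
#' Log-space maximum-likelihood central dose and overdispersion for a
#' single-grain De distribution: log-doses are modelled as Gaussian around a
#' central log-dose with variance (relative grain error)^2 + od^2.
#'
#' @param de Equivalent doses (Gy), or a data frame with `de` and `de_sd`.
#' @param de_sd 1-sigma dose uncertainties (Gy), if `de` is numeric.
#' @param log Fit in log-dose space (default). Non-positive doses are not
#'   representable in log space; set `log = FALSE` for the unlogged variant
#'   (flagged in the result).
#' @return A one-row tibble: `delta` (central dose, Gy), `delta_sigma`,
#'   `od` (overdispersion as a fraction of dose, or in Gy when unlogged),
#'   `od_sigma`, `n`, `logged`.
#' @examples
#' central_age_model(rep(100, 5), rep(5, 5))$delta
#' @export
central_age_model <- function(de, de_sd = NULL, log = TRUE) {
  if (is.data.frame(de)) {
    de_sd <- de$de_sd
    de <- de$de
  }
  n <- length(de)
  if (n < 3) abort("central age model needs at least 3 grains")
  if (any(!is.finite(de)) || any(!is.finite(de_sd)) || any(de_sd <= 0)) {
    abort("doses must be finite and dose errors strictly positive")
  }
  if (log) {
    if (any(de <= 0)) {
      abort("non-positive De present: cannot fit in log space (use log = FALSE)")
    }
    z <- base::log(de)
    s <- de_sd / de
  } else {
    z <- de
    s <- de_sd
  }
  nll <- function(par) {
    v <- s^2 + par[2]^2
    0.5 * sum(base::log(v) + (z - par[1])^2 / v)
  }
  start <- c(mean(z), max(sd(z), 1e-3))
  fit <- optim(start, nll, method = "L-BFGS-B",
               lower = c(-Inf, 0), upper = c(Inf, 10))
  mu <- fit$par[1]
  od <- fit$par[2]
  h <- numDeriv::hessian(nll, c(mu, max(od, 1e-4)))
  se <- tryCatch(sqrt(diag(solve(h))), error = function(e) c(NA_real_, NA_real_))
  if (log) {
    tibble(delta = exp(mu), delta_sigma = exp(mu) * se[1],
           od = od, od_sigma = se[2], n = n, logged = TRUE)
  } else {
    tibble(delta = mu, delta_sigma = se[1], od = od, od_sigma = se[2],
           n = n, logged = FALSE)
  }
}

# MAM-3 log-likelihood (Galbraith-style, log-dose space). par = (p, gamma,
# sigma); z, s in log space with sigma_b already folded into s.
mam3_loglik <- function(par, z, s) {
  p <- par[1]
  gam <- par[2]
  sig <- par[3]
  if (p <= 0 || p >= 1 || sig < 0) return(-Inf)
  s2 <- s^2
  sig2 <- sig^2
  mu0 <- (gam / sig2 + z / s2) / (1 / sig2 + 1 / s2)
  sig0 <- 1 / sqrt(1 / sig2 + 1 / s2)
  f <- p * dnorm(z, gam, s) +
    (1 - p) * 2 * dnorm(z, gam, sqrt(sig2 + s2)) * pnorm((gam - mu0) / sig0,
                                                         lower.tail = FALSE)
  if (any(f <= 0) || any(!is.finite(f))) return(-Inf)
  sum(base::log(f))
}

#' Minimum age model (3-parameter) for partially bleached De distributions
#'
#' Maximum-likelihood fit of the 3-parameter minimum age model in log-dose
#' space: a proportion of grains sits at the minimum dose gamma and the rest
#' follow a truncated log-normal above it. `sigma_b` (the expected
#' overdispersion of a well-bleached sample) is added in quadrature to the
#' relative grain errors. The uncertainty on gamma is a profile-likelihood
#' interval (drop of 1/2 log-likelihood unit).
#'
#' @inheritParams central_age_model
#' @param sigma_b Additional relative error added in quadrature (default
#'   0.2).
#' @return A one-row tibble: `gamma` (minimum dose, Gy), `gamma_sigma`,
#'   `p` (proportion at the minimum), `od` (sigma of the upper component,
#'   log units), `loglik`, `n`, `at_bound` (optimizer pinned at a
#'   parameter bound - treat the fit as flagged).
#' @export
minimum_age_model <- function(de, de_sd = NULL, sigma_b = 0.2) {
  if (is.data.frame(de)) {
    de_sd <- de$de_sd
    de <- de$de
  }
  n <- length(de)
  if (n < 5) abort("minimum age model needs at least 5 grains")
  if (sigma_b < 0) abort("sigma_b must be non-negative")
  if (any(de <= 0)) abort("non-positive De present: MAM is fit in log space")
  z <- base::log(de)
  s <- sqrt((de_sd / de)^2 + sigma_b^2)

  nll <- function(par) -mam3_loglik(par, z, s)
  starts <- list(
    c(0.5, quantile(z, 0.05, names = FALSE), max(sd(z), 0.05)),
    c(0.2, quantile(z, 0.25, names = FALSE), max(sd(z), 0.05)),
    c(0.8, min(z), max(sd(z) / 2, 0.05))
  )
  lower <- c(0.001, min(z) - 2, 1e-4)
  upper <- c(0.999, max(z) + 0.5, 5)
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      optim(st, nll, method = "L-BFGS-B", lower = lower, upper = upper),
      error = function(e) NULL
    )
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) abort("minimum age model failed to converge")
  par <- best$par
  at_bound <- par[1] <= lower[1] + 1e-6 || par[1] >= upper[1] - 1e-6 ||
    par[3] >= upper[3] - 1e-6 || par[2] >= upper[2] - 1e-6
  ll_hat <- -best$value

  # profile likelihood on gamma
  prof <- function(gam) {
    f <- tryCatch(
      optim(c(par[1], par[3]),
            function(q) -mam3_loglik(c(q[1], gam, q[2]), z, s),
            method = "L-BFGS-B",
            lower = c(lower[1], lower[3]), upper = c(upper[1], upper[3])),
      error = function(e) NULL
    )
    if (is.null(f)) -Inf else -f$value
  }
  target <- ll_hat - 0.5
  step <- max(0.5 * sd(z), 0.05)
  find_edge <- function(dir) {
    g1 <- par[2]
    for (i in 1:40) {
      g2 <- g1 + dir * step
      if (prof(g2) < target) {
        r <- tryCatch(
          uniroot(function(g) prof(g) - target, sort(c(g1, g2)), tol = 1e-3)$root,
          error = function(e) g2
        )
        return(r)
      }
      g1 <- g2
    }
    g1
  }
  lo <- find_edge(-1)
  hi <- find_edge(1)
  gam_sd_log <- (hi - lo) / 2
  tibble(gamma = exp(par[2]), gamma_sigma = exp(par[2]) * gam_sd_log,
         p = par[1], od = par[3], loglik = ll_hat, n = n,
         at_bound = at_bound)
}

#' Anomalous-fading rate (g-value) from a delayed-measurement series
#'
#' Weighted linear regression of the sensitivity-corrected remnant-signal
#' ratio on log10(delay/tc); g is percent signal loss per decade of time,
#' normalised to the prompt measurement delay `tc`.
#'
#' @param delays Delays since irradiation (hours), increasing.
#' @param ratios Remnant intensity relative to the prompt measurement.
#' @param ratio_sd 1-sigma uncertainties of the ratios (default equal
#'   weights).
#' @param tc Prompt-measurement delay in hours.
#' @return One-row tibble: `g` (%/decade), `g_sigma`, `span_decades`,
#'   `short_span` flag (series spans less than one decade).
#' @export
g_value <- function(delays, ratios, ratio_sd = NULL, tc = 48) {
  if (length(delays) < 3) abort("g-value needs at least 3 delay points")
  if (any(diff(delays) <= 0)) abort("delays must be strictly increasing")
  check_scalar(tc, "tc", lower = .Machine$double.eps)
  x <- log10(delays / tc)
  span <- diff(range(x))
  short <- span < 1
  if (short) warn("fading series spans less than one decade; g-value poorly constrained")
  w <- if (is.null(ratio_sd)) rep(1, length(ratios)) else 1 / ratio_sd^2
  fit <- lm(ratios ~ x, weights = w)
  sm <- suppressWarnings(summary(fit))$coefficients
  tibble(g = -100 * unname(coef(fit)[2]), g_sigma = 100 * unname(sm[2, 2]),
         span_decades = span, short_span = short)
}

# kyr per hour, for putting tc on the age scale
KYR_PER_HOUR <- 1 / (24 * 365.25 * 1000)

#' Huntley-Lamothe anomalous-fading correction of a luminescence age
#'
#' Solves the faded-age relation T_meas = T * (1 - kappa * (ln(T/tc) - 1)),
#' kappa = g / (100 ln 10), for the corrected age T by fixed-point iteration
#' to |dT| < 0.01 kyr. Uncertainty by Monte-Carlo over (age, g).
#'
#' @param age Measured (faded) age, kyr.
#' @param sigma Its 1-sigma uncertainty, kyr.
#' @param g Fading rate, %/decade (>= 0).
#' @param g_sigma 1-sigma uncertainty of g.
#' @param tc Prompt-measurement delay, hours.
#' @param n_mc Monte-Carlo draws.
#' @param seed Seed for the draws.
#' @return An [age_estimate()] tibble for the corrected age.
#' @examples
#' fading_correct(100, 0, g = 2)$age # ~116 kyr
#' @export
fading_correct <- function(age, sigma = 0, g = 0, g_sigma = 0, tc = 48,
                           n_mc = 5000, seed = NULL) {
  check_scalar(g, "g", lower = 0)
  check_scalar(age, "age", lower = 0)
  solve_one <- function(t_meas, gv) {
    if (t_meas <= 0) return(0)
    kappa <- gv / 100 / base::log(10)
    tc_kyr <- tc * KYR_PER_HOUR
    t <- t_meas
    for (i in 1:200) {
      fac <- 1 - kappa * (base::log(t / tc_kyr) - 1)
      if (!is.finite(fac) || fac <= 0) {
        abort("outside method validity: fading correction factor <= 0")
      }
      t_new <- t_meas / fac
      if (abs(t_new - t) < 0.01) return(t_new)
      t <- t_new
    }
    t
  }
  t_corr <- solve_one(age, g)
  sig <- 0
  if (sigma > 0 || g_sigma > 0) {
    draws <- with_seed(seed, {
      a <- rnorm(n_mc, age, sigma)
      gv <- pmax(rnorm(n_mc, g, g_sigma), 0)
      purrr::map2_dbl(pmax(a, 0), gv, function(ai, gi) {
        tryCatch(solve_one(ai, gi), error = function(e) NA_real_)
      })
    })
    sig <- sd(draws[is.finite(draws)])
  }
  age_estimate(t_corr, sig)
}

#' Configuration for the cosmic dose-rate parameterization
#'
#' Constants of the hard/soft cosmic-ray dose parameterization used by
#' [cosmic_dose_rate()]. The hard (muon) component follows the classic
#' published exponential-quadratic attenuation with depth; the soft
#' (electron/photon) component is a surface term absorbed in the uppermost
#' decimetres of overburden; altitude scales exponentially and the
#' geomagnetic-latitude effect at sea level is a few percent.
#'
#' @return Named list of constants (dose rates in Gy/kyr, depths in
#'   hg/cm^2 = 100 g/cm^2, altitude scale in km).
#' @export
cosmic_config <- function() {
  list(
    hard_surface = 0.21,    # Gy/kyr at sea level, high geomagnetic latitude
    hard_mu1 = 0.070,       # per hg/cm^2
    hard_mu2 = 0.0005,      # quadratic term, per (hg/cm^2)^2
    soft_surface = 0.11,    # Gy/kyr
    soft_efold = 0.1,       # hg/cm^2
    altitude_scale_km = 4.4,
    latitude_amplitude = 0.07,
    pole_lat = 78.3, pole_lon = 291
  )
}

#' Cosmic-ray dose rate at depth
#'
#' Hard + soft component parameterization with altitude and
#' geomagnetic-latitude scaling; constants from [cosmic_config()].
#'
#' @param depth_gcm2 Total overburden in g/cm^2 (rock + sediment).
#' @param altitude_m Altitude above sea level, m.
#' @param latitude_deg,longitude_deg Geographic coordinates (degrees; north
#'   and east positive).
#' @param config Constant set, see [cosmic_config()].
#' @return Dose rate in Gy/kyr.
#' @export
cosmic_dose_rate <- function(depth_gcm2, altitude_m = 0, latitude_deg = 45,
                             longitude_deg = 0, config = cosmic_config()) {
  if (any(depth_gcm2 < 0)) abort("depth must be non-negative")
  x <- depth_gcm2 / 100 # hg/cm^2
  hard <- config$hard_surface * exp(-config$hard_mu1 * x + config$hard_mu2 * x^2)
  soft <- config$soft_surface * exp(-x / config$soft_efold)
  # dipole geomagnetic latitude
  rad <- pi / 180
  gm_lat <- asin(
    sin(latitude_deg * rad) * sin(config$pole_lat * rad) +
      cos(latitude_deg * rad) * cos(config$pole_lat * rad) *
        cos((longitude_deg - config$pole_lon) * rad)
  ) / rad
  lat_fac <- 1 - config$latitude_amplitude * cos(gm_lat * rad)^2
  alt_fac <- exp((altitude_m / 1000) / config$altitude_scale_km)
  (hard + soft) * lat_fac * alt_fac
}

#' Assemble a total luminescence dose rate
#'
#' Total = beta_dry/(1 + 1.25 W) + gamma_dry/(1 + 1.14 W) + internal +
#' cosmic, with W the long-term water mass fraction; 1-sigma by first-order
#' propagation in quadrature (including the water-content term).
#'
#' @param beta_dry,gamma_dry Dry beta and gamma dose rates, Gy/kyr.
#' @param internal Internal (40K + 87Rb) dose rate, Gy/kyr (default 0.84
#'   for coarse K-feldspar grains).
#' @param cosmic Cosmic dose rate, Gy/kyr.
#' @param water_w Water content as a mass fraction in [0, 1).
#' @param beta_dry_sd,gamma_dry_sd,internal_sd,cosmic_sd,water_w_sd
#'   1-sigma uncertainties.
#' @param beta_att,gamma_att Water attenuation coefficients (conventional
#'   1.25 and 1.14).
#' @return One-row tibble: `total`, `sigma`, and the wet components.
#' @examples
#' assemble_dose_rate(2, 1, internal = 0.84, cosmic = 0.1, water_w = 0.04)
#' @export
assemble_dose_rate <- function(beta_dry, gamma_dry, internal = 0.84,
                               cosmic = 0, water_w = 0,
                               beta_dry_sd = 0, gamma_dry_sd = 0,
                               internal_sd = 0, cosmic_sd = 0,
                               water_w_sd = 0,
                               beta_att = 1.25, gamma_att = 1.14) {
  check_scalar(water_w, "water_w", lower = 0, upper = 1 - 1e-9)
  for (v in c(beta_dry, gamma_dry, internal, cosmic)) {
    check_scalar(v, "dose-rate component", lower = 0)
  }
  beta_wet <- beta_dry / (1 + beta_att * water_w)
  gamma_wet <- gamma_dry / (1 + gamma_att * water_w)
  total <- beta_wet + gamma_wet + internal + cosmic
  dW <- -beta_dry * beta_att / (1 + beta_att * water_w)^2 -
    gamma_dry * gamma_att / (1 + gamma_att * water_w)^2
  sig <- sqrt(
    (beta_dry_sd / (1 + beta_att * water_w))^2 +
      (gamma_dry_sd / (1 + gamma_att * water_w))^2 +
      internal_sd^2 + cosmic_sd^2 + (dW * water_w_sd)^2
  )
  tibble(total = total, sigma = sig, beta_wet = beta_wet,
         gamma_wet = gamma_wet, internal = internal, cosmic = cosmic)
}

#' Luminescence age from a burial dose and a dose rate
#'
#' @param de Burial dose (Gy), e.g. the MAM minimum dose.
#' @param de_sigma Its 1-sigma uncertainty (Gy).
#' @param total Total dose rate (Gy/kyr), > 0.
#' @param total_sigma Its 1-sigma uncertainty.
#' @return An [age_estimate()] tibble; sigma by relative errors in
#'   quadrature.
#' @examples
#' lum_age(500, 0, 5, 0)$age # 100 kyr
#' @export
lum_age <- function(de, de_sigma = 0, total = NULL, total_sigma = 0) {
  check_scalar(de, "de", lower = 0)
  check_scalar(total, "total", lower = .Machine$double.eps)
  age <- de / total
  rel <- if (de > 0) sqrt((de_sigma / de)^2 + (total_sigma / total)^2) else 0
  age_estimate(age, age * rel)
}

#' Read a single-grain De distribution
#'
#' Expected columns: `grain_id`, `de`, `de_sd`. `n_accepted` is recorded as
#' an attribute for logging; the table is assumed already screened by the
#' upstream single-grain acceptance criteria.
#'
#' @param path CSV file path.
#' @return Tibble with `grain_id`, `de`, `de_sd`.
#' @export
read_de_csv <- function(path) {
  data <- readr::read_csv(path, show_col_types = FALSE)
  miss <- setdiff(c("de", "de_sd"), names(data))
  if (length(miss)) abort(paste("missing columns:", paste(miss, collapse = ", ")))
  if (any(data$de_sd <= 0)) abort("de_sd must be strictly positive")
  attr(data, "n_accepted") <- nrow(data)
  as_tibble(data)
}
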