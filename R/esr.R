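#' Fit a single saturating exponential (SSE) to an additive-dose ESR curve
#'
#' Fits I(D) = I_max (1 - exp(-(D + De)/D0)) to the dose-response points
#' with added dose at or below the fitting cut-off `d_max`. The equivalent
#' dose De is the back-extrapolated natural dose.
#'
#' @param data Data frame with columns `dose` (added Gy, first = 0,
#'   strictly increasing), `intensity`, and optionally `intensity_sd`.
#' @param d_max Maximum added dose used in the fit (default: all points).
#' @param mode `"least_squares"` (weighted nonlinear fit, Monte-Carlo
#'   errors) or `"bayesian"` (random-walk MCMC posterior with flat positive
#'   priors on I_max, D0, De).
#' @param n_mc Monte-Carlo replicates (least squares) or posterior draws
#'   kept after burn-in (bayesian).
#' @param seed Seed.
#' @return Object of class `sse_fit`: list with `de`, `de_sigma`, `d0`,
#'   `i_max`, `mode`, `n_points`, `at_bound` flag, and (bayesian) the
#'   posterior `draws`.
#' @examples
#' curve <- gen_esr_curve(100, 600, 500, noise_rel = 0, seed = 1)
#' fit_sse(curve)$de # ~500
#' @export
fit_sse <- function(data, d_max = NULL, mode = c("least_squares", "bayesian"),
                    n_mc = 1000, seed = NULL) {
  mode <- match.arg(mode)
  data <- as_tibble(data)
  if (!"intensity_sd" %in% names(data)) data$intensity_sd <- rep(NA_real_, nrow(data))
  if (any(diff(data$dose) <= 0)) abort("doses must be strictly increasing")
  if (!is.null(d_max)) {
    if (d_max > max(data$dose)) abort("d_max exceeds the largest added dose")
    data <- data[data$dose <= d_max, ]
  }
  if (nrow(data) < 5) abort("need at least 5 dose points within d_max")
  dose <- data$dose
  inten <- data$intensity
  isd <- data$intensity_sd
  have_sd <- all(is.finite(isd)) && all(isd > 0)
  w <- if (have_sd) 1 / isd^2 else rep(1, length(dose))

  sse <- function(par, d) par[1] * (1 - exp(-(d + par[3]) / par[2]))
  lower <- c(1e-9, 1e-6, 0)
  upper <- c(Inf, 1e7, 1e6)

  obj <- function(par, y) sum(w * (y - sse(par, dose))^2)
  ls_fit <- function(y) {
    # coarse grid over (d0, de) with the amplitude solved in closed form
    # (linear in i_max), then local refinement from the grid optimum
    dmax <- max(dose)
    best <- NULL
    for (d0 in dmax * c(0.05, 0.1, 0.2, 0.35, 0.6, 1, 2, 5)) {
      for (de in dmax * c(0, 0.02, 0.05, 0.1, 0.2, 0.4, 0.8, 1.5)) {
        g <- 1 - exp(-(dose + de) / d0)
        im <- sum(w * g * y) / sum(w * g^2)
        if (!is.finite(im) || im <= 0) next
        v <- obj(c(im, d0, de), y)
        if (is.null(best) || v < best$v) best <- list(par = c(im, d0, de), v = v)
      }
    }
    if (is.null(best)) abort("SSE fit did not converge")
    fit <- optim(best$par, obj, y = y, method = "L-BFGS-B",
                 lower = lower, upper = upper,
                 control = list(maxit = 5000, factr = 1e3))
    if (fit$convergence != 0 && fit$value > best$v + 1e-8) {
      abort("SSE fit did not converge")
    }
    if (fit$value <= best$v) fit$par else best$par
  }

  if (mode == "least_squares") {
    par <- ls_fit(inten)
    de_sig <- 0
    if (have_sd && n_mc > 0) {
      draws <- with_seed(seed, {
        purrr::map_dbl(seq_len(n_mc), function(i) {
          y <- rnorm(length(inten), sse(par, dose), isd)
          tryCatch(ls_fit(y)[3], error = function(e) NA_real_)
        })
      })
      de_sig <- sd(draws, na.rm = TRUE)
    }
    out <- list(de = unname(par[3]), de_sigma = de_sig, d0 = unname(par[2]),
                i_max = unname(par[1]), mode = mode, n_points = length(dose),
                at_bound = par[3] <= 1e-9 || par[3] >= upper[3] - 1,
                dose = dose, intensity = inten, intensity_sd = isd)
  } else {
    sig <- if (have_sd) isd else rep(max(sd(inten) * 0.05, 1e-6), length(inten))
    loglik <- function(par) {
      if (any(par <= 0)) return(-Inf)
      -0.5 * sum(((inten - sse(par, dose)) / sig)^2)
    }
    par0 <- ls_fit(inten)
    step <- pmax(abs(par0) * 0.03, 1e-3)
    n_burn <- max(500, n_mc %/% 2)
    draws <- with_seed(seed, {
      cur <- par0
      ll <- loglik(cur)
      keep <- matrix(NA_real_, n_mc, 3)
      for (i in seq_len(n_burn + n_mc)) {
        prop <- cur + rnorm(3) * step
        llp <- loglik(prop)
        if (is.finite(llp) && base::log(runif(1)) < llp - ll) {
          cur <- prop
          ll <- llp
        }
        if (i > n_burn) keep[i - n_burn, ] <- cur
      }
      keep
    })
    out <- list(de = mean(draws[, 3]), de_sigma = sd(draws[, 3]),
                d0 = mean(draws[, 2]), i_max = mean(draws[, 1]),
                mode = mode, n_points = length(dose),
                at_bound = FALSE, draws = draws,
                dose = dose, intensity = inten, intensity_sd = isd)
  }
  class(out) <- "sse_fit"
  out
}

#' @export
print.sse_fit <- function(x, ...) {
  cat(sprintf("SSE dose-response fit (%s, %d points)\n", x$mode, x$n_points))
  cat(sprintf("  De    = %.2f +/- %.2f Gy\n", x$de, x$de_sigma))
  cat(sprintf("  D0    = %.2f Gy\n  I_max = %.3f\n", x$d0, x$i_max))
  if (isTRUE(x$at_bound)) cat("  [flag] De at parameter bound\n")
  invisible(x)
}

#' Fraction of the closed-system dose accrued under power-law uranium uptake
#'
#' Under the uptake law U(t) = U_final (t/T)^(p+1), the time-integrated
#' uranium (hence the dose from that uranium) is 1/(p+2) of the
#' closed-system (p = -1, early-uptake) value.
#'
#' @param p Uptake exponent (> -2); p = -1 early uptake, p = 0 linear,
#'   larger p = increasingly late ("recent") uptake.
#' @return 1/(p + 2).
#' @export
uptake_fraction_integral <- function(p) {
  if (any(p <= -2)) abort("uptake exponent must be > -2")
  1 / (p + 2)
}

#' Present-day U-series ratios of a tissue under power-law uranium uptake
#'
#' Each uranium increment taken up at time t carries an initial
#' (234U/238U) activity `a234_init` and ingrows 230Th for the remaining
#' (T - t). Bulk present-day activity ratios are averaged over increments
#' by trapezoid quadrature in the cumulative-uptake variable (which is
#' uniform under the power law, so the p -> -1 early-uptake limit is
#' exact).
#'
#' @param p Uptake exponent (>= -1; values below -1 are treated as the
#'   early-uptake limit).
#' @param age_kyr Age T in kyr (>= 0).
#' @param a234_init Initial (234U/238U) activity of incoming uranium.
#' @param k [decay_constants()].
#' @param quad_steps Trapezoid panels.
#' @return Tibble with `a234_238`, `a230_238`.
#' @export
uptake_useries_ratios <- function(p, age_kyr, a234_init = 1.5,
                                  k = decay_constants(), quad_steps = 200) {
  if (age_kyr < 0) abort("age must be non-negative")
  p <- max(p, -1)
  T <- age_kyr * 1000
  l0 <- k$lambda_230
  l4 <- k$lambda_234
  u <- seq(0, 1, length.out = quad_steps + 1)
  s <- if (p == -1) rep(T, length(u)) else T * (1 - u^(1 / (p + 1)))
  e4 <- exp(-l4 * s)
  a230_parcel <- 1 - exp(-l0 * s) +
    (a234_init - 1) * (l0 / (l0 - l4)) * (e4 - exp(-l0 * s))
  trap <- function(y) mean((y[-1] + y[-length(y)]) / 2)
  tibble(
    a234_238 = 1 + (a234_init - 1) * trap(e4),
    a230_238 = trap(a230_parcel)
  )
}

# Solve the uptake exponent p for one tissue at trial age T so the
# predicted present-day ratios match the measured ones. a234_init is
# eliminated by matching the measured a234 ratio exactly at each p
# (back-projection of the tissue's measured value). Returns p clamped to
# [-1, p_max] when the measured 230Th is outside the attainable range.
solve_uptake_p <- function(a234_meas, a230_meas, age_kyr, k,
                           quad_steps = 120, p_max = 6) {
  T <- age_kyr * 1000
  l0 <- k$lambda_230
  l4 <- k$lambda_234
  u <- seq(0, 1, length.out = quad_steps + 1)
  trap <- function(y) mean((y[-1] + y[-length(y)]) / 2)
  pred_a230 <- function(p) {
    s <- if (p <= -1) rep(T, length(u)) else T * (1 - u^(1 / (p + 1)))
    e4 <- exp(-l4 * s)
    e0 <- exp(-l0 * s)
    ai <- 1 + (a234_meas - 1) / trap(e4)
    trap(1 - e0 + (ai - 1) * (l0 / (l0 - l4)) * (e4 - e0))
  }
  f_lo <- pred_a230(-1) - a230_meas
  if (f_lo <= 0) return(-1) # more 230Th than even early uptake: clamp
  f_hi <- pred_a230(p_max) - a230_meas
  if (f_hi >= 0) return(p_max)
  uniroot(function(p) pred_a230(p) - a230_meas, c(-1, p_max),
          f.lower = f_lo, f.upper = f_hi, tol = 1e-4)$root
}

#' Coupled US-ESR age with uranium-uptake modelling
#'
#' Monte-Carlo age model for a fossil tooth: for each draw (all inputs
#' resampled from their Gaussians) the uptake exponent p of each dental
#' tissue is solved from its measured U-series ratios at the trial age, the
#' uranium-borne dose-rate components are scaled by the uptake fraction
#' 1/(p+2), and the age is the root of accumulated dose = equivalent dose.
#'
#' @param de,de_sigma ESR equivalent dose, Gy (1-sigma).
#' @param tissues Data frame with one row per tissue: columns `tissue`
#'   ("enamel", "dentine"), `a234_238`, `a234_238_sd`, `a230_238`,
#'   `a230_238_sd`. Enamel must be present.
#' @param budget Named list or one-row data frame of present-day dose-rate
#'   components in mGy/kyr: `internal` (enamel uranium), `beta_dentine`,
#'   `beta_sediment`, `gamma_external`, `cosmic`, each with an optional
#'   `<name>_sd`.
#' @param k [decay_constants()].
#' @param n_mc Monte-Carlo draws.
#' @param seed Seed.
#' @param t_max_kyr Upper search bound for the age (default 3000 kyr).
#' @param quad_steps Quadrature panels for the uptake integrals.
#' @return Object of class `us_esr_result`: list with `age`, `sigma` (mean
#'   and sd of the age draws, kyr), `age_central` (all inputs at their
#'   central values), `p_enamel`, `p_dentine` (medians over draws),
#'   `n_rejected`, `rejection_rate`, and the age `draws`.
#' @export
us_esr_age <- function(de, de_sigma, tissues, budget, k = decay_constants(),
                       n_mc = 1000, seed = NULL, t_max_kyr = 3000,
                       quad_steps = 120) {
  tissues <- as_tibble(tissues)
  if (!"enamel" %in% tissues$tissue) abort("tissues must include enamel")
  if (is.data.frame(budget)) budget <- as.list(budget)
  comp_names <- c("internal", "beta_dentine", "beta_sediment",
                  "gamma_external", "cosmic")
  comp <- purrr::map_dbl(comp_names, function(nm) {
    v <- budget[[nm]]
    if (is.null(v)) 0 else v
  })
  comp_sd <- purrr::map_dbl(comp_names, function(nm) {
    v <- budget[[paste0(nm, "_sd")]]
    if (is.null(v)) 0 else v
  })
  if (sum(comp) <= 0) abort("total dose rate must be positive")
  i_en <- match("enamel", tissues$tissue)
  i_de <- match("dentine", tissues$tissue)

  age_for <- function(de_gy, comps, t234_en, t230_en, t234_de, t230_de) {
    if (de_gy <= 0) return(list(age = 0, p_en = NA_real_, p_de = NA_real_))
    de_mgy <- de_gy * 1000
    p_en <- NA_real_
    p_de <- NA_real_
    # uranium-borne components scale by 1/(p+2), normalised so the
    # early-uptake (closed-system) limit p = -1 leaves them unchanged
    dose_at <- function(T_kyr) {
      p_en <<- solve_uptake_p(t234_en, t230_en, T_kyr, k, quad_steps)
      rates <- comps
      rates[1] <- rates[1] * uptake_fraction_integral(p_en) /
        uptake_fraction_integral(-1)
      if (!is.na(i_de)) {
        p_de <<- solve_uptake_p(t234_de, t230_de, T_kyr, k, quad_steps)
        rates[2] <- rates[2] * uptake_fraction_integral(p_de) /
          uptake_fraction_integral(-1)
      }
      T_kyr * sum(rates)
    }
    if (dose_at(t_max_kyr) < de_mgy) return(NULL) # no root: draw rejected
    lo <- 0
    hi <- t_max_kyr
    for (i in 1:40) {
      mid <- (lo + hi) / 2
      if (dose_at(mid) < de_mgy) lo <- mid else hi <- mid
    }
    T_hat <- (lo + hi) / 2
    dose_at(T_hat)
    list(age = T_hat, p_en = p_en, p_de = p_de)
  }

  central <- age_for(de, comp,
                     tissues$a234_238[i_en], tissues$a230_238[i_en],
                     if (!is.na(i_de)) tissues$a234_238[i_de] else NA,
                     if (!is.na(i_de)) tissues$a230_238[i_de] else NA)
  if (is.null(central)) abort("no age in (0, t_max]: dose rate cannot accumulate the equivalent dose")

  for (sc in c("a234_238_sd", "a230_238_sd")) {
    if (is.null(tissues[[sc]])) tissues[[sc]] <- 0
  }
  res <- with_seed(seed, {
    purrr::map(seq_len(n_mc), function(i) {
      de_i <- rnorm(1, de, de_sigma)
      comps <- pmax(rnorm(length(comp), comp, comp_sd), 0)
      r <- function(j, col, sdc) {
        max(rnorm(1, tissues[[col]][j], tissues[[sdc]][j]), 1e-6)
      }
      age_for(max(de_i, 0), comps,
              r(i_en, "a234_238", "a234_238_sd"),
              r(i_en, "a230_238", "a230_238_sd"),
              if (!is.na(i_de)) r(i_de, "a234_238", "a234_238_sd") else NA,
              if (!is.na(i_de)) r(i_de, "a230_238", "a230_238_sd") else NA)
    })
  })
  ok <- !purrr::map_lgl(res, is.null)
  n_rej <- sum(!ok)
  if (n_rej / n_mc > 0.2) {
    abort(sprintf(
      "US-ESR failure: %.0f%% of Monte-Carlo draws had no age solution in (0, %g kyr]",
      100 * n_rej / n_mc, t_max_kyr))
  }
  ages <- purrr::map_dbl(res[ok], "age")
  p_en <- purrr::map_dbl(res[ok], "p_en")
  p_de <- purrr::map_dbl(res[ok], "p_de")
  out <- list(
    age = mean(ages), sigma = sd(ages), age_central = central$age,
    p_enamel = median(p_en, na.rm = TRUE),
    p_dentine = if (!is.na(i_de)) median(p_de, na.rm = TRUE) else NA_real_,
    n_mc = n_mc, n_rejected = n_rej, rejection_rate = n_rej / n_mc,
    draws = ages
  )
  class(out) <- "us_esr_result"
  out
}

#' @export
print.us_esr_result <- function(x, ...) {
  cat(sprintf("US-ESR age: %.1f +/- %.1f kyr (2-sigma %.1f)\n",
              x$age, x$sigma, 2 * x$sigma))
  cat(sprintf("  p(enamel)  = %.2f\n", x$p_enamel))
  if (is.finite(x$p_dentine)) cat(sprintf("  p(dentine) = %.2f\n", x$p_dentine))
  cat(sprintf("  rejected draws: %d/%d\n", x$n_rejected, x$n_mc))
  invisible(x)
}

#' External gamma dose rate under a burial-geometry scenario
#'
#' Infinite-matrix gamma dose rate from the sediment radioelement
#' concentrations, scaled by the solid-angle fraction of the chosen burial
#' geometry: a full sphere of sediment (fraction 1) or the partially eroded
#' "current burial" configuration (configured fraction < 1).
#'
#' @param u_ppm,th_ppm,k_pct Sediment uranium (ppm), thorium (ppm) and
#'   potassium (percent).
#' @param u_ppm_sd,th_ppm_sd,k_pct_sd 1-sigma uncertainties.
#' @param scenario `"full_sphere"` or `"current_burial"`.
#' @param fraction Solid-angle fraction for `current_burial` (default 0.5).
#' @param factors Conversion constants, see [dose_conversion_factors()].
#' @return One-row tibble: `gamma` (mGy/kyr), `sigma`, `scenario`,
#'   `fraction`.
#' @export
external_gamma_geometry <- function(u_ppm, th_ppm, k_pct,
                                    u_ppm_sd = 0, th_ppm_sd = 0, k_pct_sd = 0,
                                    scenario = c("full_sphere", "current_burial"),
                                    fraction = 0.5,
                                    factors = dose_conversion_factors()) {
  scenario <- match.arg(scenario)
  for (v in c(u_ppm, th_ppm, k_pct)) check_scalar(v, "concentration", lower = 0)
  frac <- switch(scenario, full_sphere = 1, current_burial = fraction)
  check_scalar(frac, "fraction", lower = 0, upper = 1)
  g <- factors$gamma
  rate <- (u_ppm * g$u_ppm + th_ppm * g$th_ppm + k_pct * g$k_pct) * frac
  sig <- sqrt((u_ppm_sd * g$u_ppm)^2 + (th_ppm_sd * g$th_ppm)^2 +
                (k_pct_sd * g$k_pct)^2) * frac
  tibble(gamma = rate, sigma = sig, scenario = scenario, fraction = frac)
}

#' Read an ESR dose-response table
#'
#' Expected columns: `dose`, `intensity`, optionally `intensity_sd`.
#'
#' @param path CSV file path.
#' @return Tibble ordered by dose.
#' @export
read_esr_csv <- function(path) {
  data <- readr::read_csv(path, show_col_types = FALSE)
  miss <- setdiff(c("dose", "intensity"), names(data))
  if (length(miss)) abort(paste("missing columns:", paste(miss, collapse = ", ")))
  dplyr::arrange(as_tibble(data), .data$dose)
}
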