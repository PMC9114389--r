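#' Build a Bayesian ordered-sequence stratigraphic age model
#'
#' Sets up the uniform-phase sequence model: stratigraphic units are
#' ordered (unit 0 = oldest), each pair of adjacent units is separated by a
#' latent boundary age, and an outer boundary closes the sequence at each
#' end. Within a unit, true event ages are uniform between its bounding
#' boundaries. Each dated event contributes a Gaussian likelihood centred
#' on its latent true age; minimum/maximum-age estimates constrain the true
#' age through a Gaussian auxiliary variable (the measurement bounds the
#' true age from below/above). The calendar scale is kyr before present,
#' larger = older.
#'
#' @param events Data frame with columns `age_kyr`, `sigma_kyr`, `role`
#'   (`direct`, `minimum`, `maximum`), `unit` (ordinal stratum, 0 =
#'   oldest), optionally `label`.
#' @param span_prior `"one_over_span"` (default; overall depositional span
#'   penalised as 1/span, the standard end-correction) or `"uniform_span"`.
#' @param t_min,t_max Calendar support in kyr (all latent ages and
#'   boundaries live in \[t_min, t_max\]).
#' @return Object of class `strat_model`.
#' @export
build_model <- function(events, span_prior = c("one_over_span", "uniform_span"),
                        t_min = 0, t_max = 500) {
  span_prior <- match.arg(span_prior)
  events <- as_tibble(events)
  req <- c("age_kyr", "sigma_kyr", "role", "unit")
  miss <- setdiff(req, names(events))
  if (length(miss)) abort(paste("missing event columns:", paste(miss, collapse = ", ")))
  if (nrow(events) < 1) abort("need at least one event")
  if (any(events$sigma_kyr <= 0)) abort("all event sigmas must be > 0")
  if (!all(events$role %in% c("direct", "minimum", "maximum"))) {
    abort("role must be direct, minimum or maximum")
  }
  units <- sort(unique(events$unit))
  if (!identical(as.integer(units), seq_along(units) - 1L)) {
    abort("unit indices must be contiguous integers starting at 0 (0 = oldest)")
  }
  if (t_max <= t_min) abort("t_max must exceed t_min")
  if (!"label" %in% names(events)) events$label <- paste0("event_", seq_len(nrow(events)))
  # canonical internal order: posteriors are invariant to the input
  # ordering of the event rows (fixed-seed sampling then visits the same
  # parameters in the same sequence)
  events <- events[order(events$unit, events$age_kyr, events$sigma_kyr,
                         events$role, events$label), ]
  n_units <- length(units)
  boundary_labels <- c(
    sprintf("below_unit0"),
    if (n_units > 1) sprintf("unit%d/unit%d", seq_len(n_units - 1) - 1,
                             seq_len(n_units - 1)),
    sprintf("above_unit%d", n_units - 1)
  )
  structure(
    list(events = events, n_units = n_units, span_prior = span_prior,
         t_min = t_min, t_max = t_max, boundary_labels = boundary_labels),
    class = "strat_model"
  )
}

#' @export
print.strat_model <- function(x, ...) {
  cat(sprintf("Stratigraphic sequence model: %d units, %d events, %s prior\n",
              x$n_units, nrow(x$events), x$span_prior))
  cat(sprintf("  support [%g, %g] kyr; %d boundaries (incl. outer)\n",
              x$t_min, x$t_max, x$n_units + 1))
  invisible(x)
}

# One MCMC chain: Metropolis-within-Gibbs over (theta, aux, boundaries).
# State: theta[i] in (B[u_i + 2], B[u_i + 1]) where B is the decreasing
# boundary vector B[1] > ... > B[n_units + 1] (B[1] below/older than unit
# 0). Returns a matrix of kept draws: boundaries then thetas.
run_chain <- function(model, n_iter, burn, thin, seed) {
  ev <- model$events
  n_ev <- nrow(ev)
  nu <- model$n_units
  t_min <- model$t_min
  t_max <- model$t_max
  obs <- ev$age_kyr
  sig <- ev$sigma_kyr
  unit <- as.integer(ev$unit)
  role <- ev$role
  has_aux <- role != "direct"
  span_pen <- model$span_prior == "one_over_span"

  set.seed(seed)
  # initial state: boundaries evenly bracket the unit-wise observations
  B <- numeric(nu + 1)
  unit_mid <- purrr::map_dbl(0:(nu - 1), function(j) {
    m <- obs[unit == j]
    if (length(m)) mean(m) else NA_real_
  })
  if (anyNA(unit_mid)) {
    if (sum(is.finite(unit_mid)) >= 2) {
      unit_mid <- approx(seq_along(unit_mid), unit_mid, seq_along(unit_mid),
                         rule = 2)$y
    } else if (sum(is.finite(unit_mid)) == 1) {
      unit_mid[!is.finite(unit_mid)] <- unit_mid[is.finite(unit_mid)][1]
    } else {
      unit_mid <- seq(t_max * 0.75, t_min + (t_max - t_min) * 0.25,
                      length.out = nu)
    }
  }
  for (j in 1:(nu + 1)) {
    if (j == 1) {
      B[1] <- min(t_max, unit_mid[1] + 3 * max(sig))
    } else if (j == nu + 1) {
      B[nu + 1] <- max(t_min, unit_mid[nu] - 3 * max(sig))
    } else {
      B[j] <- (unit_mid[j - 1] + unit_mid[j]) / 2
    }
  }
  B <- sort(pmin(pmax(B, t_min), t_max), decreasing = TRUE)
  if (any(diff(B) >= 0)) B <- seq(t_max * 0.9, t_min + (t_max - t_min) * 0.05, length.out = nu + 1)
  theta <- pmin(pmax(obs, B[unit + 2] + 1e-6), B[unit + 1] - 1e-6)
  aux <- obs

  n_units_ev <- tabulate(unit + 1L, nbins = nu)

  i_dir <- which(role == "direct")
  i_max <- which(role == "maximum")
  i_min <- which(role == "minimum")
  i_aux <- which(has_aux)
  log_post <- function(B, theta, aux) {
    if (any(diff(B) >= 0)) return(-Inf)
    if (B[1] > t_max || B[nu + 1] < t_min) return(-Inf)
    lo <- B[unit + 2]
    hi <- B[unit + 1]
    if (any(theta <= lo | theta >= hi)) return(-Inf)
    if (length(i_max) && any(aux[i_max] < theta[i_max])) return(-Inf)
    if (length(i_min) && any(aux[i_min] > theta[i_min])) return(-Inf)
    ll <- sum(dnorm(obs[i_dir], theta[i_dir], sig[i_dir], log = TRUE)) +
      sum(dnorm(obs[i_aux], aux[i_aux], sig[i_aux], log = TRUE))
    spans <- B[1:nu] - B[2:(nu + 1)]
    ll <- ll - sum(n_units_ev * base::log(spans))
    if (span_pen) ll <- ll - base::log(B[1] - B[nu + 1])
    ll
  }

  lp <- log_post(B, theta, aux)
  if (!is.finite(lp)) abort("could not initialise MCMC at a finite posterior point")
  step_theta <- sig
  step_aux <- sig
  step_B <- rep(max(sig) , nu + 1)

  n_keep <- floor((n_iter - burn) / thin)
  keep <- matrix(NA_real_, n_keep, nu + 1 + n_ev)
  kr <- 0
  acc <- 0
  tot <- 0
  for (it in seq_len(n_iter)) {
    for (i in seq_len(n_ev)) {
      prop <- theta
      prop[i] <- theta[i] + rnorm(1, 0, step_theta[i])
      lp2 <- log_post(B, prop, aux)
      tot <- tot + 1
      if (lp2 - lp > base::log(runif(1))) {
        theta <- prop
        lp <- lp2
        acc <- acc + 1
      }
      if (has_aux[i]) {
        propa <- aux
        propa[i] <- aux[i] + rnorm(1, 0, step_aux[i])
        lp2 <- log_post(B, theta, propa)
        if (lp2 - lp > base::log(runif(1))) {
          aux <- propa
          lp <- lp2
        }
      }
    }
    for (j in seq_len(nu + 1)) {
      propB <- B
      propB[j] <- B[j] + rnorm(1, 0, step_B[j])
      lp2 <- log_post(propB, theta, aux)
      if (lp2 - lp > base::log(runif(1))) {
        B <- propB
        lp <- lp2
      }
    }
    if (it > burn && (it - burn) %% thin == 0 && kr < n_keep) {
      kr <- kr + 1
      keep[kr, ] <- c(B, theta)
    }
  }
  keep[seq_len(kr), , drop = FALSE]
}

# split-Rhat over a list of per-chain draw vectors
split_rhat <- function(chains) {
  halves <- list()
  for (ch in chains) {
    n <- length(ch)
    halves <- c(halves, list(ch[1:(n %/% 2)], ch[(n %/% 2 + 1):n]))
  }
  m <- length(halves)
  n <- min(lengths(halves))
  halves <- purrr::map(halves, ~ .x[1:n])
  means <- purrr::map_dbl(halves, mean)
  vars <- purrr::map_dbl(halves, var)
  b <- n * var(means)
  w <- mean(vars)
  if (w <= 0) return(1)
  sqrt(((n - 1) / n * w + b / n) / w)
}

#' Run the stratigraphic MCMC
#'
#' Metropolis-within-Gibbs sampler over latent event ages, auxiliary
#' variables of minimum/maximum constraints, and the ordered boundary
#' vector. Seeded and reproducible; convergence is monitored with
#' split-Rhat across chains.
#'
#' @param model A [build_model()] object.
#' @param n_iter Iterations per chain (>= 10^4 recommended; default 50,000).
#' @param n_chains Number of chains (>= 2; default 4).
#' @param burn_frac Fraction of each chain discarded as burn-in (0.2).
#' @param thin Keep every `thin`-th draw (5).
#' @param seed Integer seed; chain c uses a seed derived from it.
#' @return Object of class `chrono_fit`: `boundaries` tibble (label, mean,
#'   sd, 68% central interval, rhat, converged flag), `boundary_draws`
#'   (pooled matrix), `theta` summary tibble, and the run settings.
#' @export
run_mcmc <- function(model, n_iter = 50000, n_chains = 4, burn_frac = 0.2,
                     thin = 5, seed = 1) {
  if (n_chains < 2) abort("need at least 2 chains for convergence monitoring")
  if (n_iter < 1000) abort("n_iter too small")
  burn <- floor(n_iter * burn_frac)
  chains <- purrr::map(seq_len(n_chains), function(c) {
    run_chain(model, n_iter, burn, thin, derive_seed(seed, c))
  })
  nu <- model$n_units
  n_ev <- nrow(model$events)
  n_b <- nu + 1
  pooled <- do.call(rbind, chains)
  b_stats <- purrr::map(seq_len(n_b), function(j) {
    per_chain <- purrr::map(chains, ~ .x[, j])
    draws <- pooled[, j]
    ci <- quantile(draws, c(0.16, 0.84), names = FALSE)
    tibble(
      boundary = model$boundary_labels[j],
      mean = mean(draws), sd = sd(draws),
      lo_68 = ci[1], hi_68 = ci[2],
      rhat = split_rhat(per_chain)
    )
  })
  boundaries <- dplyr::bind_rows(b_stats)
  boundaries$converged <- boundaries$rhat <= 1.05
  theta_stats <- purrr::map(seq_len(n_ev), function(i) {
    draws <- pooled[, n_b + i]
    tibble(label = model$events$label[i], mean = mean(draws), sd = sd(draws))
  })
  out <- list(
    boundaries = boundaries,
    boundary_draws = pooled[, seq_len(n_b), drop = FALSE],
    theta = dplyr::bind_rows(theta_stats),
    model = model,
    n_iter = n_iter, n_chains = n_chains, thin = thin, seed = seed,
    converged = all(boundaries$converged)
  )
  class(out) <- "chrono_fit"
  out
}

#' @export
print.chrono_fit <- function(x, ...) {
  cat(sprintf("Stratigraphic age model (%d chains x %d iterations)\n",
              x$n_chains, x$n_iter))
  print(as.data.frame(x$boundaries), digits = 4)
  if (!x$converged) cat("  [flag] not converged: some split-Rhat > 1.05\n")
  invisible(x)
}

#' Summarise a posterior sample
#'
#' Mean, sd and a central quantile interval (default 68%) of a posterior
#' draw vector; quantiles use the standard type-7 definition. Optionally
#' the highest-density interval.
#'
#' @param samples Numeric vector of posterior draws.
#' @param level Central-interval probability (default 0.68).
#' @param hdi Also compute the highest-density interval.
#' @return One-row tibble: `mean`, `sd`, `lo`, `hi`, and `hdi_lo`/`hdi_hi`
#'   when requested.
#' @export
summarize_posterior <- function(samples, level = 0.68, hdi = FALSE) {
  if (!length(samples)) abort("empty posterior sample")
  check_scalar(level, "level", lower = 0, upper = 1)
  a <- (1 - level) / 2
  ci <- quantile(samples, c(a, 1 - a), names = FALSE)
  out <- tibble(mean = mean(samples), sd = sd(samples),
                lo = ci[1], hi = ci[2], level = level)
  if (hdi) {
    s <- sort(samples)
    n <- length(s)
    w <- max(1, floor(level * n))
    if (w >= n) {
      out$hdi_lo <- s[1]
      out$hdi_hi <- s[n]
    } else {
      widths <- s[(w + 1):n] - s[1:(n - w)]
      i <- which.min(widths)
      out$hdi_lo <- s[i]
      out$hdi_hi <- s[i + w]
    }
  }
  out
}
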