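# Shared oracles and fixture builders, independent of the implementation
# paths they check.

# UV-sphere triangle mesh (closed), radius r
uv_sphere <- function(r, n = 24) {
  th <- seq(0, pi, length.out = n + 1)[2:n]
  ph <- seq(0, 2 * pi, length.out = 2 * n + 1)[seq_len(2 * n)]
  g <- expand.grid(ph = ph, th = th)
  v <- cbind(r * sin(g$th) * cos(g$ph), r * sin(g$th) * sin(g$ph),
             r * cos(g$th))
  v <- rbind(c(0, 0, r), v, c(0, 0, -r))
  np <- length(ph)
  nr <- n - 1
  vid <- function(ip, ir) 1L + (ir - 1L) * np + ((ip - 1L) %% np) + 1L
  f <- list()
  for (ip in seq_len(np)) f[[length(f) + 1]] <- c(1L, vid(ip + 1, 1), vid(ip, 1))
  for (ir in seq_len(nr - 1)) {
    for (ip in seq_len(np)) {
      a <- vid(ip, ir); b <- vid(ip + 1, ir)
      c2 <- vid(ip + 1, ir + 1); d <- vid(ip, ir + 1)
      f[[length(f) + 1]] <- c(a, c2, b)
      f[[length(f) + 1]] <- c(a, d, c2)
    }
  }
  nv <- nrow(v)
  for (ip in seq_len(np)) f[[length(f) + 1]] <- c(nv, vid(ip, nr), vid(ip + 1, nr))
  crown_mesh(v, do.call(rbind, f))
}

# Brute-force Mahalanobis classifier with pooled within-group covariance,
# in the original variable space (oracle for cva()'s classification)
mahalanobis_classify <- function(x, groups, newdata = x) {
  lev <- sort(unique(groups))
  n <- nrow(x)
  k <- ncol(x)
  W <- matrix(0, k, k)
  for (g in lev) {
    xi <- x[groups == g, , drop = FALSE]
    xi <- sweep(xi, 2, colMeans(xi))
    W <- W + crossprod(xi)
  }
  W <- W / (n - length(lev))
  Winv <- solve(W)
  d2 <- vapply(lev, function(g) {
    mu <- colMeans(x[groups == g, , drop = FALSE])
    dd <- sweep(as.matrix(newdata), 2, mu)
    rowSums((dd %*% Winv) * dd)
  }, numeric(nrow(as.matrix(newdata))))
  lev[apply(matrix(d2, ncol = length(lev)), 1, which.min)]
}

# Huntley-Lamothe forward fade: measured age from a true age (kyr)
forward_fade <- function(t_true_kyr, g, tc_hours = 48) {
  kappa <- g / 100 / log(10)
  tc_kyr <- tc_hours / (24 * 365.25 * 1000)
  t_true_kyr * (1 - kappa * (log(t_true_kyr / tc_kyr) - 1))
}

# MAM-3 grid-search oracle: best log-likelihood over a coarse grid, using
# an independent re-statement of the likelihood
mam3_grid_oracle <- function(de, de_sd, sigma_b) {
  z <- log(de)
  s <- sqrt((de_sd / de)^2 + sigma_b^2)
  ll <- function(p, gam, sig) {
    mu0 <- (gam / sig^2 + z / s^2) / (1 / sig^2 + 1 / s^2)
    sig0 <- 1 / sqrt(1 / sig^2 + 1 / s^2)
    f <- p * dnorm(z, gam, s) +
      (1 - p) * 2 * dnorm(z, gam, sqrt(sig^2 + s^2)) *
        (1 - pnorm((gam - mu0) / sig0))
    if (any(f <= 0)) -Inf else sum(log(f))
  }
  best <- -Inf
  best_g <- NA
  for (p in seq(0.05, 0.95, by = 0.05)) {
    for (gam in seq(min(z), max(z), length.out = 60)) {
      for (sig in seq(0.02, 1.5, length.out = 30)) {
        v <- ll(p, gam, sig)
        if (v > best) {
          best <- v
          best_g <- gam
        }
      }
    }
  }
  list(loglik = best, gamma = exp(best_g))
}
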