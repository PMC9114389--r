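# broom-style tidiers for the fitted objects

#' @describeIn run_mcmc Tidy boundary posterior summaries.
#' @param x A `chrono_fit`.
#' @param ... Unused.
#' @export
tidy.chrono_fit <- function(x, ...) {
  x$boundaries
}

#' @describeIn run_mcmc One-row model-level summary.
#' @export
glance.chrono_fit <- function(x, ...) {
  tibble(n_iter = x$n_iter, n_chains = x$n_chains, thin = x$thin,
         n_boundaries = nrow(x$boundaries),
         max_rhat = max(x$boundaries$rhat), converged = x$converged)
}

#' @describeIn fit_sse Tidy parameter estimates.
#' @param x An `sse_fit`.
#' @param ... Unused.
#' @export
tidy.sse_fit <- function(x, ...) {
  tibble(term = c("de", "d0", "i_max"),
         estimate = c(x$de, x$d0, x$i_max),
         std.error = c(x$de_sigma, NA_real_, NA_real_))
}

#' @describeIn fit_sse One-row fit summary.
#' @export
glance.sse_fit <- function(x, ...) {
  tibble(mode = x$mode, n_points = x$n_points, at_bound = x$at_bound)
}

#' @describeIn us_esr_age Tidy age and uptake-parameter estimates.
#' @param x A `us_esr_result`.
#' @param ... Unused.
#' @export
tidy.us_esr_result <- function(x, ...) {
  tibble(term = c("age_kyr", "p_enamel", "p_dentine"),
         estimate = c(x$age, x$p_enamel, x$p_dentine),
         std.error = c(x$sigma, NA_real_, NA_real_))
}

#' @describeIn us_esr_age One-row run summary.
#' @export
glance.us_esr_result <- function(x, ...) {
  tibble(n_mc = x$n_mc, n_rejected = x$n_rejected,
         rejection_rate = x$rejection_rate, age_central = x$age_central)
}

#' @describeIn shape_pca Tidy ordination scores (one row per specimen and
#'   axis).
#' @param x An `ordination`.
#' @param ... Unused.
#' @export
tidy.ordination <- function(x, ...) {
  sc <- x$scores
  out <- tidyr::pivot_longer(
    dplyr::mutate(as_tibble(sc, .name_repair = ~ paste0("axis", seq_along(.x))),
                  specimen = seq_len(nrow(sc)),
                  group = if (!is.null(x$groups)) x$groups else NA_character_),
    dplyr::starts_with("axis"), names_to = "axis", values_to = "score",
    names_prefix = "axis")
  out$axis <- as.integer(out$axis)
  out
}

#' @describeIn shape_pca One-row ordination summary.
#' @export
glance.ordination <- function(x, ...) {
  tibble(kind = x$kind, n = nrow(x$scores), n_axes = ncol(x$scores),
         explained_1 = x$explained[1],
         explained_cum2 = sum(head(x$explained, 2)))
}
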