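# ggplot2 diagnostics for the main result types

#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_line geom_density
#'   geom_errorbar geom_vline labs facet_wrap theme_minimal
#' @export
ggplot2::autoplot

#' Boundary posterior densities of a stratigraphic age model
#'
#' @param object A `chrono_fit` from [run_mcmc()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.chrono_fit <- function(object, ...) {
  d <- object$boundary_draws
  colnames(d) <- object$model$boundary_labels
  long <- tidyr::pivot_longer(as_tibble(d), dplyr::everything(),
                              names_to = "boundary", values_to = "age_kyr")
  ggplot(long, aes(x = .data$age_kyr)) +
    geom_density() +
    facet_wrap(~boundary, scales = "free") +
    labs(x = "age (kyr)", y = "posterior density",
         title = "Stratigraphic boundary posteriors") +
    theme_minimal()
}

#' Dose-response curve with the fitted saturating exponential
#'
#' @param object An `sse_fit` from [fit_sse()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.sse_fit <- function(object, ...) {
  pts <- tibble(dose = object$dose, intensity = object$intensity,
                sd = object$intensity_sd)
  grid <- tibble(dose = seq(0, max(pts$dose), length.out = 200))
  grid$intensity <- object$i_max * (1 - exp(-(grid$dose + object$de) / object$d0))
  p <- ggplot(pts, aes(x = .data$dose, y = .data$intensity)) +
    geom_line(data = grid, colour = "grey40") +
    geom_point() +
    labs(x = "added dose (Gy)", y = "ESR intensity",
         title = sprintf("SSE fit: De = %.0f +/- %.0f Gy", object$de,
                         object$de_sigma)) +
    theme_minimal()
  if (all(is.finite(pts$sd))) {
    p <- p + geom_errorbar(aes(ymin = .data$intensity - .data$sd,
                               ymax = .data$intensity + .data$sd), width = 0)
  }
  p
}

#' Ordination scatter (first two axes)
#'
#' @param object An `ordination` (PCA, bgPCA or CVA result).
#' @param axes Which two axes to plot.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ordination <- function(object, axes = c(1, 2), ...) {
  sc <- object$scores
  if (ncol(sc) < 2) abort("need at least 2 axes to plot")
  d <- tibble(x = sc[, axes[1]], y = sc[, axes[2]],
              group = if (!is.null(object$groups)) object$groups else "all")
  p <- ggplot(d, aes(x = .data$x, y = .data$y, colour = .data$group)) +
    geom_point() +
    labs(x = sprintf("%s %d (%.1f%%)", toupper(object$kind), axes[1],
                     100 * object$explained[axes[1]]),
         y = sprintf("%s %d (%.1f%%)", toupper(object$kind), axes[2],
                     100 * object$explained[min(axes[2], length(object$explained))])) +
    theme_minimal()
  if (!is.null(object$unknown_scores)) {
    u <- tibble(x = object$unknown_scores[, axes[1]],
                y = object$unknown_scores[, axes[2]])
    p <- p + geom_point(data = u, aes(x = .data$x, y = .data$y),
                        inherit.aes = FALSE, shape = 8, size = 3)
  }
  p
}

#' Ranked single-grain De plot
#'
#' Grains ordered by equivalent dose with 1-sigma bars; a quick look at
#' dispersion and partial-bleaching structure, with optional CAM/MAM dose
#' lines.
#'
#' @param data De tibble (`de`, `de_sd`).
#' @param cam_delta,mam_gamma Optional reference doses (Gy) drawn as
#'   vertical lines on the dose axis.
#' @return A ggplot.
#' @export
plot_de_distribution <- function(data, cam_delta = NULL, mam_gamma = NULL) {
  d <- dplyr::arrange(as_tibble(data), .data$de)
  d$rank <- seq_len(nrow(d))
  p <- ggplot(d, aes(x = .data$de, y = .data$rank)) +
    geom_errorbar(aes(xmin = .data$de - .data$de_sd,
                      xmax = .data$de + .data$de_sd),
                  width = 0, colour = "grey60") +
    geom_point() +
    labs(x = "equivalent dose (Gy)", y = "grain rank") +
    theme_minimal()
  if (!is.null(cam_delta)) p <- p + geom_vline(xintercept = cam_delta, linetype = 2)
  if (!is.null(mam_gamma)) p <- p + geom_vline(xintercept = mam_gamma, linetype = 3)
  p
}
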