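#' Adjusted Z-score against a small comparative sample
#'
#' Compares a single measurement with a reference sample of size n using
#' the t-based tolerance-band score
#' \deqn{z_{adj} = \frac{(x - m) / (s \sqrt{1 + 1/n})}{t_{crit}(n-1)}}
#' where the critical value is two-tailed at alpha = 0.05 by default, so
#' |score| > 1 places x outside the reference 95% tolerance band. Designed
#' for the unbalanced, small samples typical of the fossil record.
#'
#' @param x Measurement value(s).
#' @param m Reference sample mean.
#' @param s Reference sample standard deviation (> 0).
#' @param n Reference sample size (>= 2).
#' @param alpha Band level (0.05).
#' @param tail `"two"` (default: critical value with alpha/2 in each tail)
#'   or `"one"`.
#' @return Numeric score(s).
#' @examples
#' adjusted_z(12, 10, 1, 10) # 0.843
#' @export
adjusted_z <- function(x, m, s, n, alpha = 0.05, tail = c("two", "one")) {
  tail <- match.arg(tail)
  if (any(n < 2)) abort("reference sample size must be at least 2")
  if (any(s <= 0)) abort("reference standard deviation must be > 0")
  tcrit <- if (tail == "two") qt(1 - alpha / 2, n - 1) else qt(1 - alpha, n - 1)
  ((x - m) / (s * sqrt(1 + 1 / n))) / tcrit
}

#' Adjusted Z-scores of one specimen against a reference table
#'
#' @param x Measurement value of the specimen.
#' @param refs Data frame with columns `m`, `s`, `n` and optionally
#'   `label` (one row per comparative group).
#' @inheritParams adjusted_z
#' @return Tibble `label`, `score`, `outside_band`.
#' @export
adjusted_z_table <- function(x, refs, alpha = 0.05, tail = c("two", "one")) {
  refs <- as_tibble(refs)
  sc <- adjusted_z(x, refs$m, refs$s, refs$n, alpha = alpha,
                   tail = match.arg(tail))
  tibble(
    label = if ("label" %in% names(refs)) refs$label else as.character(seq_along(sc)),
    score = sc, outside_band = abs(sc) > 1
  )
}

#' Crown tissue proportions
#'
#' From enamel volume, dentine+pulp crown volume and EDJ surface area:
#' the percent crown dentine (Vcdp/Vc), the 3D average enamel thickness
#' (AET = Ve/SEDJ, mm) and the scale-free relative enamel thickness
#' (RET = 100 AET / Vcdp^(1/3)).
#'
#' @param ve Enamel volume, mm^3 (>= 0).
#' @param vcdp Crown dentine + pulp volume, mm^3 (> 0).
#' @param sedj EDJ surface area, mm^2 (> 0).
#' @return One-row tibble: `vcdp_pct`, `aet`, `ret`.
#' @examples
#' tissue_proportions(269.5, 334.4, 228.4) # 55.4%, 1.18 mm, 17.00
#' @export
tissue_proportions <- function(ve, vcdp, sedj) {
  check_scalar(ve, "ve", lower = 0)
  check_scalar(vcdp, "vcdp", lower = .Machine$double.eps)
  check_scalar(sedj, "sedj", lower = .Machine$double.eps)
  aet <- ve / sedj
  tibble(
    vcdp_pct = 100 * vcdp / (ve + vcdp),
    aet = aet,
    ret = 100 * aet / vcdp^(1 / 3)
  )
}

#' Topographic enamel-thickness map
#'
#' For each vertex of the outer enamel surface, the minimum Euclidean
#' (point-to-triangle) distance to the enamel-dentine junction surface.
#' Nearest-point distance is used rather than normal-ray casting: it is
#' robust on strongly wrinkled crowns (a documented convention difference
#' from some commercial tools).
#'
#' @param oes Outer enamel surface, a [crown_mesh()].
#' @param edj Enamel-dentine junction surface, a [crown_mesh()].
#' @return Tibble `vertex`, `thickness` (mm) with attribute `"summary"`
#'   containing percentiles (5/25/50/75/95) and the mean.
#' @export
thickness_map <- function(oes, edj) {
  if (!inherits(oes, "crown_mesh") || !inherits(edj, "crown_mesh")) {
    abort("oes and edj must be crown_mesh objects")
  }
  if (!mesh_is_closed(oes) || !mesh_is_closed(edj)) {
    warn("open mesh: thickness map computed on a non-watertight surface")
  }
  th <- point_mesh_distance(oes$vertices, edj)
  out <- tibble(vertex = seq_along(th), thickness = th)
  attr(out, "summary") <- c(
    quantile(th, c(0.05, 0.25, 0.5, 0.75, 0.95)), mean = mean(th)
  )
  out
}

#' Half-maximum-height segmentation threshold
#'
#' Midpoint between the grey values of two material peaks in a microCT
#' histogram (the HMH rule).
#'
#' @param peak_a,peak_b Grey values of the two material peaks (vectors are
#'   paired). Must differ.
#' @return Threshold grey value(s).
#' @examples
#' hmh_threshold(100, 200) # 150
#' @export
hmh_threshold <- function(peak_a, peak_b) {
  if (any(peak_a == peak_b)) abort("material peaks must differ")
  (peak_a + peak_b) / 2
}

#' HMH threshold from repeated slice measurements
#'
#' Averages per-slice HMH estimates and reports their spread, following the
#' practice of taking repeated measurements on different slices of the
#' virtual stack.
#'
#' @param peak_a,peak_b Per-slice peak grey values (equal length), or a
#'   data frame with columns `peak_a`, `peak_b`.
#' @return One-row tibble: `threshold` (mean), `sd`, `n_slices`.
#' @export
hmh_batch <- function(peak_a, peak_b = NULL) {
  if (is.data.frame(peak_a)) {
    peak_b <- peak_a$peak_b
    peak_a <- peak_a$peak_a
  }
  th <- hmh_threshold(peak_a, peak_b)
  tibble(threshold = mean(th), sd = sd(th), n_slices = length(th))
}
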