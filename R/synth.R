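# Seeded generators producing inputs with the statistical structure each
# analysis assumes. Every generator emits its ground truth (as attribute
# "truth") so recovery tests can close the loop without external data.

#' Generate coeval U-series sub-samples sharing a detrital component
#'
#' Forward-models a set of carbonate sub-samples of common true age and
#' common detrital (230Th/232Th) ratio `r0`, with varying detrital
#' fraction, then adds Gaussian relative noise. With
#' `detrital_at = "present"` the detrital 230Th is added at ratio `r0`
#' today (what an isochron intercept of the measured ratios estimates);
#' with `"initial"` the detritus carried ratio `r0` at formation and its
#' 230Th has decayed since (the initial-Th convention used by
#' [detrital_correct()]'s default).
#'
#' @param true_age_kyr Common true age, kyr.
#' @param delta234_init Initial d234U, permil.
#' @param r0 Shared detrital (230Th/232Th) activity ratio.
#' @param contamination_fracs Per-sub-sample detrital fraction in \[0, 1):
#'   the fraction of measured 230Th that is detrital. 0 = clean
#'   (a230_232 = Inf).
#' @param noise_rel Relative (1-sigma) measurement noise.
#' @param seed Seed.
#' @param detrital_at `"present"` or `"initial"` (see above).
#' @param k [decay_constants()].
#' @return Tibble in [read_useries_csv()] layout; attribute `"truth"`
#'   holds the generator parameters.
#' @export
gen_useries_set <- function(true_age_kyr, delta234_init = 0, r0 = 0.5,
                            contamination_fracs = c(0, 0.1, 0.3, 0.5),
                            noise_rel = 0.02, seed = 1,
                            detrital_at = c("present", "initial"),
                            k = decay_constants()) {
  detrital_at <- match.arg(detrital_at)
  if (any(contamination_fracs < 0 | contamination_fracs >= 1)) {
    abort("contamination fractions must be in [0, 1)")
  }
  fw <- useries_forward(true_age_kyr, delta234_init, k)
  decay <- if (detrital_at == "initial") {
    exp(-k$lambda_230 * true_age_kyr * 1000)
  } else 1
  with_seed(seed, {
    rows <- purrr::map(seq_along(contamination_fracs), function(i) {
      fr <- contamination_fracs[i]
      a230_det <- fw$a230_238 * fr / (1 - fr)
      a232_238 <- if (fr > 0) a230_det / (r0 * decay) else 0
      a230 <- fw$a230_238 + a230_det
      a234 <- fw$a234_238
      nz <- function(x) x * (1 + rnorm(1, 0, noise_rel))
      a230_m <- nz(a230)
      a234_m <- nz(a234)
      a232_m <- if (fr > 0) nz(a232_238) else 0
      tibble(
        label = sprintf("sub%02d", i),
        a230_238 = a230_m, a230_238_sd = noise_rel * a230,
        a234_238 = a234_m, a234_238_sd = noise_rel * a234,
        a230_232 = if (fr > 0) a230_m / a232_m else Inf,
        a230_232_sd = if (fr > 0) noise_rel * sqrt(2) * a230 / a232_238 else 0,
        a234_232 = if (fr > 0) a234_m / a232_m else Inf,
        a234_232_sd = if (fr > 0) noise_rel * sqrt(2) * a234 / a232_238 else 0
      )
    })
    out <- dplyr::bind_rows(rows)
    attr(out, "truth") <- list(true_age_kyr = true_age_kyr, r0 = r0,
                               delta234_init = delta234_init,
                               detrital_at = detrital_at,
                               contamination_fracs = contamination_fracs)
    out
  })
}

#' Generate a saturating-exponential ESR dose-response curve
#'
#' Intensities follow I(D) = I_max (1 - exp(-(D + De)/D0)) with
#' multiplicative Gaussian noise. Default added doses follow the
#' exponentially increasing irradiation-time scheme typical of X-ray
#' additive-dose protocols (0 to ~2.9 kGy).
#'
#' @param i_max,d0,de SSE parameters (arbitrary units, Gy, Gy).
#' @param doses Added laboratory doses (first must be 0).
#' @param noise_rel Relative noise (1-sigma).
#' @param seed Seed.
#' @return Tibble `dose`, `intensity`, `intensity_sd`; `"truth"`
#'   attribute.
#' @export
gen_esr_curve <- function(i_max = 100, d0 = 600, de = 500,
                          doses = c(0, 20.8, 90.1, 225.2, 436.8, 832.5,
                                    1704.8, 2860.2),
                          noise_rel = 0.02, seed = 1) {
  if (de < 0) abort("de must be non-negative")
  if (doses[1] != 0) abort("first added dose must be 0 (natural signal)")
  mu <- i_max * (1 - exp(-(doses + de) / d0))
  with_seed(seed, {
    y <- mu * (1 + rnorm(length(mu), 0, noise_rel))
    sdv <- if (noise_rel > 0) noise_rel * mu else rep(NA_real_, length(mu))
    out <- tibble(dose = doses, intensity = y, intensity_sd = sdv)
    attr(out, "truth") <- list(i_max = i_max, d0 = d0, de = de,
                               noise_rel = noise_rel)
    out
  })
}

#' Generate a partially bleached single-grain De distribution
#'
#' A fraction `bleach_frac` of grains was fully bleached at burial and
#' scatters log-normally around the burial dose with overdispersion `od`;
#' the remainder carries unbleached residuals, inflated uniformly up to
#' `inflation_max`.
#'
#' @param burial_dose True burial dose, Gy.
#' @param od Overdispersion of the bleached population (fraction).
#' @param n Number of grains (> 0).
#' @param bleach_frac Fraction of bleached grains in (0, 1].
#' @param inflation_max Upper bound of residual-inflated doses, Gy.
#' @param rel_err Relative single-grain measurement error.
#' @param seed Seed.
#' @return Tibble `grain_id`, `de`, `de_sd`; `"truth"` attribute.
#' @export
gen_de_distribution <- function(burial_dose = 500, od = 0.25, n = 100,
                                bleach_frac = 1, inflation_max = 1500,
                                rel_err = 0.1, seed = 1) {
  if (n < 1) abort("n must be positive")
  if (bleach_frac <= 0 || bleach_frac > 1) abort("bleach_frac must be in (0, 1]")
  with_seed(seed, {
    n_b <- round(n * bleach_frac)
    true <- c(
      rlnorm(n_b, base::log(burial_dose), od),
      if (n - n_b > 0) runif(n - n_b, burial_dose, inflation_max)
    )
    de <- true * (1 + rnorm(n, 0, rel_err))
    de <- pmax(de, burial_dose * 1e-3)
    out <- tibble(grain_id = seq_len(n), de = de, de_sd = rel_err * true)
    attr(out, "truth") <- list(burial_dose = burial_dose, od = od,
                               bleach_frac = bleach_frac,
                               inflation_max = inflation_max)
    out
  })
}

#' Generate a stratigraphic event series with known boundaries
#'
#' True event ages are uniform within each unit's boundary interval;
#' measurements add Gaussian noise.
#'
#' @param true_boundaries Decreasing vector of length (units + 1): outer
#'   and internal boundary ages, kyr (larger = older).
#' @param events_per_unit Events per unit (recycled).
#' @param sigmas Measurement sigmas (recycled across events).
#' @param roles Roles per event (default all `"direct"`).
#' @param seed Seed.
#' @return Event tibble for [build_model()]; `"truth"` attribute with the
#'   boundaries and true ages.
#' @export
gen_strat_series <- function(true_boundaries, events_per_unit = 3,
                             sigmas = 10, roles = NULL, seed = 1) {
  if (any(diff(true_boundaries) >= 0)) {
    abort("true boundaries must be strictly decreasing (old to young)")
  }
  nu <- length(true_boundaries) - 1
  epu <- rep_len(events_per_unit, nu)
  with_seed(seed, {
    rows <- purrr::map(seq_len(nu), function(j) {
      th <- runif(epu[j], true_boundaries[j + 1], true_boundaries[j])
      tibble(unit = j - 1L, theta = sort(th, decreasing = TRUE))
    })
    ev <- dplyr::bind_rows(rows)
    ev$sigma_kyr <- rep_len(sigmas, nrow(ev))
    ev$age_kyr <- rnorm(nrow(ev), ev$theta, ev$sigma_kyr)
    ev$role <- if (is.null(roles)) "direct" else rep_len(roles, nrow(ev))
    ev$label <- sprintf("ev%02d", seq_len(nrow(ev)))
    out <- ev[, c("label", "age_kyr", "sigma_kyr", "role", "unit")]
    attr(out, "truth") <- list(boundaries = true_boundaries,
                               theta = ev$theta)
    out
  })
}

# Internal crown surface parameterisation shared by mesh and truth
# computation. v in [-1, 1]: lower pole (shallow cervical dome), v = 0 the
# cervix ring (z = 0, maximum girth), v = 1 the occlusal apex. Smooth
# everywhere so a normal offset of moderate thickness stays embedded.
crown_surface <- function(theta, v, cusp_heights, cusp_angles, base_radius,
                          base_height, superellipse_m, horn_v, horn_sigma) {
  se_r <- function(th) {
    base_radius * (abs(cos(th))^superellipse_m +
                     abs(sin(th))^superellipse_m)^(-1 / superellipse_m)
  }
  r <- se_r(theta) * cos(v * pi / 2)
  x <- r * cos(theta)
  y <- r * sin(theta)
  z <- ifelse(v >= 0, base_height, 0.35 * base_height) * sin(v * pi / 2)
  # cusp bumps are Gaussian blobs in the planform (x, y) coordinates, so
  # their lateral width - hence their curvature - is bounded everywhere
  for (kk in seq_along(cusp_heights)) {
    rk <- se_r(cusp_angles[kk]) * cos(horn_v * pi / 2)
    xk <- rk * cos(cusp_angles[kk])
    yk <- rk * sin(cusp_angles[kk])
    z <- z + cusp_heights[kk] *
      exp(-((x - xk)^2 + (y - yk)^2) / (2 * horn_sigma^2))
  }
  cbind(x, y, z)
}

#' Generate a synthetic tooth crown (EDJ and OES surface pair)
#'
#' The enamel-dentine junction is a smooth dome on a superellipsoidal base
#' with four Gaussian cusp bumps (the dentine horns: protoconid,
#' metaconid, entoconid, hypoconid); the outer enamel surface is the EDJ
#' offset along vertex normals by a smooth, strictly positive thickness
#' field. Both meshes are closed. Ground-truth tissue volumes and EDJ
#' area are measured on a densely refined version of the same surfaces
#' (quadrature truth), alongside the true horn positions and the
#' marginal-ridge and cervix paths used for template building.
#'
#' @param seed Seed (reserved; the surface itself is deterministic in its
#'   parameters).
#' @param cusp_heights Heights (mm) of the 4 cusp bumps.
#' @param thickness List `t0` (base enamel thickness, mm) and `amp`
#'   (smooth modulation amplitude, < t0).
#' @param base_radius,base_height Crown base half-width and dome height,
#'   mm.
#' @param n_theta,n_v Mesh resolution (delivered mesh).
#' @param refine Refinement factor for the quadrature-truth mesh.
#' @return List: `edj`, `oes` ([crown_mesh()]), `horns` (4 x 3), `ridge_path`,
#'   `cervix_path`, `truth` (list `ve`, `vcdp`, `sedj`, `thickness_range`).
#' @export
gen_crown <- function(seed = 1, cusp_heights = c(1.3, 1.0, 1.15, 1.1),
                      thickness = list(t0 = 0.5, amp = 0.1),
                      base_radius = 4, base_height = 2.5,
                      n_theta = 72, n_v = 36, refine = 4) {
  if (length(cusp_heights) != 4) abort("need 4 cusp heights")
  if (thickness$t0 <= 0 || thickness$amp < 0 || thickness$amp >= thickness$t0) {
    abort("thickness field must be strictly positive (amp < t0)")
  }
  cusp_angles <- c(1, 3, 5, 7) * pi / 4
  horn_v <- 0.75
  horn_sigma <- 1.0
  superellipse_m <- 3
  thick_at <- function(theta, v) {
    thickness$t0 +
      thickness$amp * sin(pmax(v, 0) * pi) * cos(theta - cusp_angles[4])
  }

  build <- function(nt, nv) {
    th <- seq(0, 2 * pi, length.out = nt + 1)[seq_len(nt)]
    vv <- seq(-1 + 1 / nv, 1 - 1 / nv, length.out = 2 * nv - 1)
    n_ring <- length(vv)
    gr <- expand.grid(theta = th, v = vv)
    verts <- crown_surface(gr$theta, gr$v, cusp_heights, cusp_angles,
                           base_radius, base_height, superellipse_m,
                           horn_v, horn_sigma)
    apex <- crown_surface(0, 1, cusp_heights, cusp_angles, base_radius,
                          base_height, superellipse_m, horn_v, horn_sigma)
    apex[1:2] <- 0
    bottom <- crown_surface(0, -1, cusp_heights, cusp_angles, base_radius,
                            base_height, superellipse_m, horn_v, horn_sigma)
    bottom[1:2] <- 0
    verts <- rbind(verts, apex, bottom)
    i_apex <- nt * n_ring + 1L
    i_bot <- nt * n_ring + 2L
    vid <- function(it, iv) (iv - 1L) * nt + ((it - 1L) %% nt) + 1L
    f <- vector("list", 2 * nt * (n_ring - 1) + 2 * nt)
    fi <- 0
    for (iv in seq_len(n_ring - 1)) {
      for (it in seq_len(nt)) {
        a <- vid(it, iv); b <- vid(it + 1, iv)
        c2 <- vid(it + 1, iv + 1); d <- vid(it, iv + 1)
        f[[fi + 1]] <- c(a, b, c2)
        f[[fi + 2]] <- c(a, c2, d)
        fi <- fi + 2
      }
    }
    for (it in seq_len(nt)) { # apex fan (top ring -> apex)
      f[[fi + 1]] <- c(vid(it, n_ring), vid(it + 1, n_ring), i_apex)
      fi <- fi + 1
    }
    for (it in seq_len(nt)) { # bottom fan (lowest ring -> bottom pole)
      f[[fi + 1]] <- c(vid(it + 1, 1), vid(it, 1), i_bot)
      fi <- fi + 1
    }
    mesh <- crown_mesh(verts, do.call(rbind, f))
    tfield <- c(thick_at(gr$theta, gr$v), thick_at(0, 1), thick_at(0, -1))
    list(mesh = mesh, tfield = tfield, theta = th, v = vv)
  }

  offset_mesh <- function(b) {
    nrm <- mesh_vertex_normals(b$mesh)
    v2 <- b$mesh$vertices + nrm * b$tfield
    oes <- crown_mesh(v2, b$mesh$faces)
    # self-intersection guard: offset must not flip any face normal
    fn <- function(m) {
      v <- m$vertices; f <- m$faces
      e1 <- v[f[, 2], ] - v[f[, 1], ]; e2 <- v[f[, 3], ] - v[f[, 1], ]
      cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
            e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
            e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
    }
    if (any(rowSums(fn(oes) * fn(b$mesh)) < 0)) {
      abort("self-intersecting offset: thickness too large for surface curvature")
    }
    oes
  }

  coarse <- build(n_theta, n_v)
  oes <- offset_mesh(coarse)
  dense <- build(n_theta * refine, n_v * refine)
  oes_dense <- offset_mesh(dense)
  vcdp_true <- mesh_volume(dense$mesh)
  ve_true <- mesh_volume(oes_dense) - vcdp_true
  sedj_true <- mesh_area(dense$mesh)

  ridge_theta <- seq(0, 2 * pi, length.out = 241)[1:240]
  ridge_path <- crown_surface(ridge_theta, horn_v, cusp_heights, cusp_angles,
                              base_radius, base_height, superellipse_m,
                              horn_v, horn_sigma)
  cervix_path <- crown_surface(ridge_theta, 0, cusp_heights, cusp_angles,
                               base_radius, base_height, superellipse_m,
                               horn_v, horn_sigma)
  horns <- crown_surface(cusp_angles, horn_v, cusp_heights, cusp_angles,
                         base_radius, base_height, superellipse_m,
                         horn_v, horn_sigma)
  list(
    edj = coarse$mesh, oes = oes, horns = horns,
    ridge_path = ridge_path, cervix_path = cervix_path,
    truth = list(ve = ve_true, vcdp = vcdp_true, sedj = sedj_true,
                 thickness_range = range(coarse$tfield))
  )
}

#' Generate multi-group 3D landmark samples
#'
#' Isotropic Gaussian landmark noise around per-group mean configurations;
#' an `overlap` parameter shrinks the between-group mean differences
#' toward the grand mean (overlap 1 = identical means).
#'
#' @param group_means List of k x 3 mean configurations (one per group),
#'   or `NULL` to draw random means for `n_groups` groups of `k`
#'   landmarks with between-group spread `mean_spread`.
#' @param n_per_group Specimens per group (recycled).
#' @param covariance_scale Isotropic landmark noise sd.
#' @param overlap In \[0, 1\]: shrinkage of mean differences.
#' @param n_groups,k,mean_spread Used when `group_means` is `NULL`.
#' @param seed Seed.
#' @return List of k x 3 matrices with `group`/`label` attributes;
#'   `"truth"` attribute holds the (shrunk) group means.
#' @export
gen_landmark_groups <- function(group_means = NULL, n_per_group = 10,
                                covariance_scale = 0.05, overlap = 0,
                                n_groups = 3, k = 20, mean_spread = 0.3,
                                seed = 1) {
  check_scalar(overlap, "overlap", lower = 0, upper = 1)
  with_seed(seed, {
    if (is.null(group_means)) {
      base <- matrix(rnorm(k * 3), k, 3)
      group_means <- purrr::map(seq_len(n_groups), function(g) {
        base + matrix(rnorm(k * 3, 0, mean_spread), k, 3)
      })
    }
    ks <- purrr::map_int(group_means, nrow)
    if (length(unique(ks)) != 1) abort("group means must share landmark count")
    grand <- Reduce(`+`, group_means) / length(group_means)
    means <- purrr::map(group_means, function(m) grand + (m - grand) * (1 - overlap))
    npg <- rep_len(n_per_group, length(means))
    configs <- list()
    for (g in seq_along(means)) {
      for (i in seq_len(npg[g])) {
        m <- means[[g]] + matrix(rnorm(ks[1] * 3, 0, covariance_scale), ks[1], 3)
        attr(m, "group") <- paste0("G", g)
        attr(m, "label") <- sprintf("G%d_%02d", g, i)
        configs[[length(configs) + 1]] <- m
      }
    }
    attr(configs, "truth") <- list(means = means)
    configs
  })
}

#' Synthetic enamel protein set, AMELY markers and diagnostic-site panel
#'
#' Small invented ("_SYN") protein sequences with the residue composition
#' the proteomic screening operations exercise: serines in and out of
#' S-x-E contexts, deamidatable N/Q, an AMELX/AMELY pair differing in a
#' short Y-specific stretch, and a pair of illustrative diagnostic sites.
#' These are synthetic stand-ins, not biological sequences.
#'
#' @return List: `proteins` (named character), `amely_peptides`
#'   (AMELY-specific), `panel` (tibble protein/position/lineage/residue).
#' @export
synth_protein_set <- function() {
  proteins <- c(
    AMELX_SYN = "MPLPPHSAESMNRPLAQSQEWLTPSKEPYQNSLEHGSQEPLMPNSAETQKSHE",
    AMELY_SYN = "MPLPPHSAESMNRPWYRPNDGEWLTPSKEPYQNSLEHGSQEPLMPNSAETQKSHE",
    ENAM_SYN  = "MKTGSNEVDFQSREALNSYEKQPFSGELMNQWRDTSVESAEKLNPQRSTEYMGH",
    AMBN_SYN  = "MFSLKEQNGAWSPELTDRSQEYVNKMPSAEHGLQNRFSTEWKDPSLEMQAYRHG"
  )
  amely_peptides <- c("PWYRPNDGEWLTP", "WYRPNDGE")
  # positions match the synthetic "sample" sequences: ENAM_SYN[5] = "S"
  # (shared by Homo, differs in the outgroup), AMBN_SYN[20] = "Q"
  # (Denisovan-clade residue; sapiens/Neanderthal/outgroup carry E)
  panel <- tibble(
    protein = c(rep("ENAM_SYN", 5), rep("AMBN_SYN", 5)),
    position = c(rep(5L, 5), rep(20L, 5)),
    lineage = rep(c("H_sapiens", "Neanderthal", "Denisovan",
                    "Xiahe_Denisovan", "Pongo"), 2),
    residue = c("S", "S", "S", "S", "A",
                "E", "E", "Q", "Q", "E")
  )
  list(proteins = proteins, amely_peptides = amely_peptides, panel = panel)
}

#' Generate a synthetic PSM table
#'
#' Peptides are random subsequences of the synthetic protein set; PTMs are
#' assigned so that, among PSMs containing a modifiable residue, a
#' fraction `ptm_rates[ptm]` carries the modification. Optionally enriches
#' phospho-serine contexts for the S-x-E motif, forces coverage of
#' diagnostic panel sites, appends AMELY-specific and blank-run PSMs.
#'
#' @param n_psm Number of sample PSMs (before extras).
#' @param ptm_rates Named vector of PTM rates in \[0, 1\], e.g.
#'   `c(Phospho = 0.3, Deamidation = 0.5)`.
#' @param motif_enrichment Probability that a phospho-site is chosen from
#'   serines with E at +2 (when available).
#' @param diagnostic_sites_covered Data frame `protein`, `position` of
#'   panel sites to cover with supported PSMs (or `NULL`).
#' @param amely_present Append PSMs containing an AMELY-specific peptide.
#' @param support_rate Probability that a position of a random PSM has
#'   fragmentation support (default 0: only the forced diagnostic PSMs
#'   are supported, mirroring incomplete fragmentation around sites of
#'   interest).
#' @param n_blank Number of blank-run PSMs appended.
#' @param proteins Named character of protein sequences (default
#'   [synth_protein_set()]).
#' @param seed Seed.
#' @return A [psm_table()]; `"truth"` attribute with the generator
#'   parameters.
#' @export
gen_psm_table <- function(n_psm = 200, ptm_rates = c(Phospho = 0.3),
                          motif_enrichment = 0, diagnostic_sites_covered = NULL,
                          amely_present = FALSE, n_blank = 0, support_rate = 0,
                          proteins = synth_protein_set()$proteins, seed = 1) {
  if (any(ptm_rates < 0 | ptm_rates > 1)) abort("ptm rates must be in [0, 1]")
  targets <- list(Phospho = c("S"), Deamidation = c("N", "Q"),
                  Hydroxyproline = c("P"), Oxidation = c("M", "W"))
  # AMELY-specific sequence never enters the random pool, so its presence
  # is controlled solely by `amely_present`
  pool <- setdiff(names(proteins), "AMELY_SYN")
  with_seed(seed, {
    pep_rows <- purrr::map(seq_len(n_psm), function(i) {
      pr <- sample(pool, 1)
      seqc <- proteins[[pr]]
      len <- sample(8:20, 1)
      st <- sample(seq_len(max(1, nchar(seqc) - len + 1)), 1)
      tibble(peptide = substr(seqc, st, st + len - 1), protein = pr, start = st)
    })
    tb <- dplyr::bind_rows(pep_rows)
    mods <- purrr::map(tb$peptide, function(pep) {
      out <- tibble(pos = integer(), val = character())
      for (ptm in names(ptm_rates)) {
        res <- targets[[ptm]]
        if (is.null(res)) res <- "S"
        sites <- which(strsplit(pep, "")[[1]] %in% res)
        if (!length(sites)) next
        if (runif(1) < ptm_rates[[ptm]]) {
          pick <- sites
          if (ptm == "Phospho" && motif_enrichment > 0) {
            sxe <- sites[sites + 2 <= nchar(pep) &
                           substr(pep, sites + 2, sites + 2) == "E"]
            if (length(sxe) && runif(1) < motif_enrichment) pick <- sxe
          }
          out <- dplyr::bind_rows(out, tibble(pos = sample(rep(pick, 2), 1),
                                              val = ptm))
        }
      }
      out
    })
    support <- purrr::map(nchar(tb$peptide), function(len) {
      tibble(pos = seq_len(len),
             val = ifelse(runif(len) < support_rate, "1", "0"))
    })
    if (!is.null(diagnostic_sites_covered)) {
      for (i in seq_len(nrow(diagnostic_sites_covered))) {
        pr <- diagnostic_sites_covered$protein[i]
        pos <- diagnostic_sites_covered$position[i]
        st <- max(1, pos - 5)
        pep <- substr(proteins[[pr]], st, min(nchar(proteins[[pr]]), pos + 5))
        tb <- dplyr::bind_rows(tb, tibble(peptide = pep, protein = pr, start = st))
        mods[[length(mods) + 1]] <- tibble(pos = integer(), val = character())
        support[[length(support) + 1]] <- tibble(pos = seq_len(nchar(pep)), val = "1")
      }
    }
    if (amely_present) {
      ap <- synth_protein_set()$amely_peptides[1]
      st <- regexpr(ap, proteins[["AMELY_SYN"]], fixed = TRUE)
      tb <- dplyr::bind_rows(tb, tibble(peptide = ap, protein = "AMELY_SYN",
                                        start = as.integer(st)))
      mods[[length(mods) + 1]] <- tibble(pos = integer(), val = character())
      support[[length(support) + 1]] <- tibble(pos = seq_len(nchar(ap)), val = "1")
    }
    blank <- rep(FALSE, nrow(tb))
    if (n_blank > 0) {
      bl <- purrr::map(seq_len(n_blank), function(i) {
        pr <- sample(pool, 1)
        tibble(peptide = substr(proteins[[pr]], 1, 12), protein = pr, start = 1L)
      })
      tb <- dplyr::bind_rows(tb, dplyr::bind_rows(bl))
      for (i in seq_len(n_blank)) {
        mods[[length(mods) + 1]] <- tibble(pos = 1L, val = "Phospho")
        support[[length(support) + 1]] <- tibble(pos = 1L, val = "1")
      }
      blank <- c(blank, rep(TRUE, n_blank))
    }
    out <- psm_table(tb$peptide, tb$protein, tb$start,
                     modifications = mods, site_support = support,
                     is_blank = blank)
    attr(out, "truth") <- list(ptm_rates = ptm_rates,
                               motif_enrichment = motif_enrichment,
                               amely_present = amely_present)
    out
  })
}
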