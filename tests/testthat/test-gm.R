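test_that("curve resampling is exact on lines and uniform on circles", {
  seg <- cbind(seq(0, 10, length.out = 7), 0, 0)
  r <- resample_curve(seg, 11)
  expect_equal(r[, 1], 0:10, tolerance = 1e-8)
  expect_equal(r[, 2], rep(0, 11))

  th <- seq(0, 2 * pi, length.out = 101)[1:100]
  circ <- cbind(cos(th), sin(th), 0)
  rc <- resample_curve(circ, 30, closed = TRUE)
  radii <- sqrt(rowSums(rc^2))
  expect_lt(max(abs(radii - 1)), 1e-3)
  gaps <- sqrt(rowSums((rc - rc[c(2:30, 1), ])^2))
  expect_lt(diff(range(gaps)) / mean(gaps), 1e-3)

  expect_error(resample_curve(circ[1:3, ], 10), "at least 4")
  expect_warning(resample_curve(rbind(seg, seg[7, ]), 5), "duplicate")
})

test_that("template assembly yields the 94-point configuration with exact horns", {
  cr <- gen_crown(seed = 2, n_theta = 48, n_v = 24, refine = 1)
  tpl <- build_template(cr$horns, cr$ridge_path, cr$cervix_path)
  expect_equal(nrow(tpl$coords), 94)
  expect_equal(as.integer(table(tpl$roles)[c("horn", "ridge", "cervix")]),
               c(4L, 60L, 30L))
  expect_equal(unname(tpl$coords[1:4, ]), unname(cr$horns),
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(tpl$chirality, "left")

  # mirrored input is reflected into left-side convention and recorded
  mir <- function(m) {
    m2 <- m
    m2[, 1] <- -m2[, 1]
    m2
  }
  tpl_m <- build_template(mir(cr$horns), mir(cr$ridge_path),
                          mir(cr$cervix_path), mirror = TRUE)
  expect_equal(unname(tpl_m$coords), unname(tpl$coords), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(tpl_m$chirality, "mirrored_right")

  # horn order inconsistent with path direction names the offending cusp
  expect_error(build_template(cr$horns[c(1, 3, 2, 4), ], cr$ridge_path,
                              cr$cervix_path), "metaconid|entoconid")
})

test_that("GPA removes rigid motion and scale; distances match the pairwise oracle", {
  set.seed(1)
  cfg <- matrix(rnorm(30), 10, 3)
  rot <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(rot) < 0) rot[, 1] <- -rot[, 1]
  copies <- list(cfg, cfg %*% rot * 2 + 5, cfg %*% rot - 3, cfg * 0.25)
  space <- gpa(copies)
  expect_lt(max(procrustes_distances(space)), 1e-10)
  # unit centroid size, centred at the origin
  for (i in 1:4) {
    al <- space$aligned[i, , ]
    expect_lt(max(abs(colMeans(al))), 1e-12)
    expect_equal(sqrt(sum(al^2)), 1, tolerance = 1e-12)
  }

  # perturbed configurations: GPA tangent distances track pairwise OPA
  cfgs <- purrr::map(1:6, ~ cfg + matrix(rnorm(30, 0, 0.003), 10, 3))
  sp <- gpa(cfgs)
  d_gpa <- as.matrix(procrustes_distances(sp))
  opa <- function(a, b) {
    a <- scale(a, scale = FALSE) / cavechron:::centroid_size(a)
    b <- scale(b, scale = FALSE) / cavechron:::centroid_size(b)
    sqrt(sum((a %*% cavechron:::kabsch(a, b) - b)^2))
  }
  for (i in 1:5) {
    expect_lt(abs(d_gpa[i, i + 1] - opa(cfgs[[i]], cfgs[[i + 1]])), 1e-6)
  }
  expect_error(gpa(copies[1]), "at least 2")
  expect_error(gpa(list(cfg, cbind(1:10, 2 * (1:10), 3 * (1:10)))),
               "collinear|degenerate")
})

test_that("shape PCA is complete and 1-D trajectories load on one axis", {
  set.seed(2)
  base <- matrix(rnorm(30), 10, 3)
  dir1 <- matrix(rnorm(30, 0, 0.02), 10, 3)
  traj <- purrr::map(seq(-1, 1, length.out = 8), ~ base + .x * dir1)
  p <- shape_pca(gpa(traj))
  expect_gt(p$explained[1], 0.999)
  expect_equal(sum(p$explained), 1)

  # reconstruction from all retained axes reproduces the flattened data
  sp <- gpa(gen_landmark_groups(n_per_group = 5, seed = 3))
  p2 <- shape_pca(sp)
  x <- cavechron:::flatten_space(sp)
  rec <- sweep(p2$scores %*% t(p2$axes), 2, p2$center, "+")
  expect_lt(max(abs(rec - x)), 1e-10)

  expect_equal(select_pcs(list(explained = c(0.5, 0.3, 0.15, 0.05)), 0.90), 3)
  expect_equal(select_pcs(p2, 1), length(p2$explained))
  expect_equal(select_pcs(p2, 0), 1)
})

test_that("between-group PCA projects means linearly and finds the offset axis", {
  g <- gen_landmark_groups(n_per_group = 8, seed = 4)
  sp <- gpa(g)
  x <- cavechron:::flatten_space(sp)
  bg <- bgpca(x, sp$groups)
  expect_lte(ncol(bg$scores), 2)
  # projection of a group mean equals the mean of the projected members
  for (j in seq_along(bg$group_levels)) {
    gm <- colMeans(bg$scores[sp$groups == bg$group_levels[j], , drop = FALSE])
    expect_equal(gm, unname(bg$group_means[j, ]), tolerance = 1e-8)
  }
  # synthetic 2-group data offset along a known direction: bgPC1 aligns
  set.seed(5)
  base <- matrix(rnorm(40), 20, 2)
  d <- rnorm(2)
  d <- d / sqrt(sum(d^2))
  xx <- rbind(base, sweep(base, 2, 3 * d, "+"))
  grp <- rep(c("A", "B"), each = 20)
  bg2 <- bgpca(xx, grp)
  expect_gt(abs(sum(bg2$axes[, 1] * d)), 0.99)
  expect_error(bgpca(xx, rep("A", 40)), "2 groups")

  # bgPCA scores from residuals equal those from full-rank PC scores
  p <- shape_pca(sp)
  bg_pc <- bgpca(p$scores, sp$groups)
  flip <- sign(diag(crossprod(bg$scores, bg_pc$scores)))
  expect_equal(bg$scores, sweep(bg_pc$scores, 2, flip, "*"),
               tolerance = 1e-8)
})

test_that("CVA whitens within-group variation and classifies like the Mahalanobis oracle", {
  g <- gen_landmark_groups(n_per_group = 10, covariance_scale = 0.08, seed = 6)
  sp <- gpa(g)
  p <- shape_pca(sp)
  k <- min(select_pcs(p, 0.9), 8)
  x <- p$scores[, seq_len(k), drop = FALSE]
  fit <- cva(x, sp$groups)
  # pooled within-group covariance in canonical space = identity
  W <- matrix(0, ncol(fit$scores), ncol(fit$scores))
  for (gg in unique(sp$groups)) {
    s <- fit$scores[sp$groups == gg, , drop = FALSE]
    s <- sweep(s, 2, colMeans(s))
    W <- W + crossprod(s)
  }
  W <- W / (nrow(x) - length(unique(sp$groups)))
  expect_equal(W, diag(ncol(fit$scores)), tolerance = 1e-8)
  # classification equals the brute-force pooled-Mahalanobis oracle
  expect_equal(fit$classification$predicted,
               mahalanobis_classify(x, sp$groups))
  # unknowns are projected and classified a posteriori
  unk <- x[1:2, , drop = FALSE] + 0.01
  fit2 <- cva(x, sp$groups, unknowns = unk)
  expect_equal(fit2$unknown_classification$predicted,
               mahalanobis_classify(x, sp$groups, unk))
  post <- as.matrix(fit$classification$posterior)
  expect_equal(unname(rowSums(post)), rep(1, nrow(post)))
  expect_error(cva(p$scores, sp$groups), "fewer PCs|k < n - g")
})

test_that("leave-one-out rates are perfect when separated and degrade with overlap", {
  rates <- purrr::map_dbl(c(0, 0.6, 0.9), function(ov) {
    g <- gen_landmark_groups(n_per_group = 8, covariance_scale = 0.05,
                             overlap = ov, seed = 7)
    sp <- gpa(g)
    p <- shape_pca(sp)
    x <- p$scores[, 1:5, drop = FALSE]
    cross_validate(x, sp$groups, method = "cva")$overall
  })
  expect_equal(rates[1], 1)
  expect_true(all(diff(rates) <= 0))
  expect_lt(rates[3], 1)

  # invariant to specimen order
  g <- gen_landmark_groups(n_per_group = 6, overlap = 0.5, seed = 8)
  sp <- gpa(g)
  x <- shape_pca(sp)$scores[, 1:4]
  r1 <- cross_validate(x, sp$groups, "bgpca")
  perm <- sample(nrow(x))
  r2 <- cross_validate(x[perm, ], sp$groups[perm], "bgpca")
  expect_equal(r1$rates, r2$rates)
})

test_that("allometry regression finds true slopes and calibrated null p-values", {
  set.seed(9)
  n <- 40
  cs <- runif(n, 5, 15)
  scores <- cbind(2 * cs + rnorm(n, 0, 0.5), rnorm(n))
  res <- allometry_regression(scores, cs, n_perm = 2000, seed = 1)
  expect_equal(res$slope[1], 2, tolerance = 0.1)
  expect_lt(res$p_perm[1], 0.001)
  expect_gt(res$p_perm[2], 0.01)
  # permutation p approximates the classical F p under normality
  expect_lt(abs(res$p_perm[2] - res$p_f[2]), 0.15)
  # n_perm = 0: classical test only
  res0 <- allometry_regression(scores, cs, n_perm = 0)
  expect_true(all(is.na(res0$p_perm)))
  expect_error(allometry_regression(scores, rep(1, n)), "constant")

  # null calibration: p roughly uniform over replicates
  ps <- vapply(1:120, function(i) {
    set.seed(i + 400)
    allometry_regression(cbind(rnorm(12)), runif(12), n_perm = 300,
                         seed = i)$p_perm[1]
  }, numeric(1))
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("landmark IO round-trips CSV and TPS", {
  g <- gen_landmark_groups(n_per_group = 2, n_groups = 2, k = 5, seed = 10)
  long <- purrr::imap(g, function(m, i) {
    tibble::tibble(specimen = attr(m, "label"), index = 1:5,
                   x = m[, 1], y = m[, 2], z = m[, 3],
                   group = attr(m, "group"))
  })
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(dplyr::bind_rows(long), path)
  back <- read_landmarks_csv(path)
  expect_equal(length(back), 4)
  expect_equal(back[["G1_01"]], g[[1]][, 1:3], tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(attr(back[["G2_01"]], "group"), "G2")

  tps <- withr::local_tempfile(fileext = ".tps")
  writeLines(c("LM3=3", "0 0 0", "1 0 0", "0 1 0", "ID=sp1", "GROUP=A",
               "LM3=3", "0 0 1", "1 0 1", "0 1 1", "ID=sp2"), tps)
  lt <- read_landmarks_tps(tps)
  expect_equal(names(lt), c("sp1", "sp2"))
  expect_equal(lt$sp1[2, ], c(1, 0, 0))
  expect_equal(attr(lt$sp1, "group"), "A")
})
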