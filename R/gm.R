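# Enamel-dentine junction landmark/semilandmark geometric morphometrics.
# A landmark configuration is a k x 3 coordinate matrix; samples are lists
# of configurations (equal k), optionally with "group" and "label"
# attributes.

#' Resample a 3D polyline to equally spaced points
#'
#' Interpolates a cubic spline through the polyline (per coordinate,
#' against cumulative chord length), reparameterises by arc length, and
#' returns `n_out` points at equal arc-length spacing. Open curves include
#' both endpoints; closed curves start at the first input point.
#'
#' @param points Ordered n x 3 matrix (>= 4 distinct points). Duplicate
#'   consecutive points are removed with a warning.
#' @param n_out Number of output points.
#' @param closed Treat the polyline as a closed loop.
#' @param dense Number of dense samples used for the arc-length
#'   reparameterisation (default `50 * n_out`).
#' @return `n_out` x 3 matrix.
#' @export
resample_curve <- function(points, n_out, closed = FALSE, dense = NULL) {
  points <- as.matrix(points)
  if (ncol(points) != 3) abort("points must be n x 3")
  dup <- c(FALSE, rowSums(abs(diff(points))) < 1e-12)
  if (any(dup)) {
    warn(sprintf("removed %d duplicate consecutive points", sum(dup)))
    points <- points[!dup, , drop = FALSE]
  }
  if (nrow(points) < 4) abort("need at least 4 distinct points to fit a cubic spline")
  if (closed && sum(abs(points[1, ] - points[nrow(points), ])) > 1e-12) {
    points <- rbind(points, points[1, ])
  }
  tt <- c(0, cumsum(sqrt(rowSums(diff(points)^2))))
  method <- if (closed) "periodic" else "natural"
  if (is.null(dense)) dense <- max(50 * n_out, 1000)
  td <- seq(0, max(tt), length.out = dense)
  dmat <- vapply(1:3, function(j) {
    spline(tt, points[, j], xout = td, method = method)$y
  }, numeric(length(td)))
  arc <- c(0, cumsum(sqrt(rowSums(diff(dmat)^2))))
  total <- max(arc)
  targets <- if (closed) {
    seq(0, total, length.out = n_out + 1)[seq_len(n_out)]
  } else {
    seq(0, total, length.out = n_out)
  }
  out <- vapply(1:3, function(j) approx(arc, dmat[, j], xout = targets)$y,
                numeric(length(targets)))
  out
}

#' Assemble the 94-point EDJ landmark configuration
#'
#' Splits the marginal-ridge curve at the four dentine-horn landmarks
#' (protoconid, metaconid, entoconid, hypoconid, in the lingual-direction
#' order of the ridge path), resamples each of the four segments to
#' 12/12/24/12 equally spaced semilandmarks (the shared cusp points belong
#' to the anatomical-landmark set and are not double-counted), and places
#' 30 equally spaced semilandmarks along the cervix curve. Total: 4 + 60 +
#' 30 = 94 points.
#'
#' @param horns 4 x 3 matrix: protoconid, metaconid, entoconid, hypoconid
#'   dentine-horn tips, in that order.
#' @param ridge_path Polyline along the top of the marginal ridge,
#'   beginning at (or near) the protoconid and moving lingually; treated as
#'   a closed loop.
#' @param cervix_path Polyline along the cervix, starting mesio-buccally
#'   below the protoconid horn and moving mesially; closed loop.
#' @param segment_counts Semilandmarks per ridge segment (12, 12, 24, 12).
#' @param n_cervix Cervix semilandmarks (30).
#' @param mirror Reflect a right-side tooth into left-side convention
#'   (negates the first coordinate) before assembly.
#' @return Object of class `landmark_config`: list with `coords` (94 x 3),
#'   `roles` (`"horn"`, `"ridge"`, `"cervix"`), `chirality`.
#' @export
build_template <- function(horns, ridge_path, cervix_path,
                           segment_counts = c(12, 12, 24, 12),
                           n_cervix = 30, mirror = FALSE) {
  horns <- as.matrix(horns)
  ridge_path <- as.matrix(ridge_path)
  cervix_path <- as.matrix(cervix_path)
  if (nrow(horns) != 4) abort("need exactly 4 horn landmarks")
  if (mirror) {
    horns[, 1] <- -horns[, 1]
    ridge_path[, 1] <- -ridge_path[, 1]
    cervix_path[, 1] <- -cervix_path[, 1]
  }
  cusp_names <- c("protoconid", "metaconid", "entoconid", "hypoconid")
  # nearest ridge vertex to each horn
  idx <- vapply(1:4, function(i) {
    which.min(colSums((t(ridge_path) - horns[i, ])^2))
  }, integer(1))
  n_r <- nrow(ridge_path)
  # cyclic order along the path must match the cusp order
  rel <- (idx - idx[1]) %% n_r
  if (any(duplicated(idx))) abort("two horns map to the same ridge point")
  ord <- order(rel)
  if (!identical(ord, 1:4)) {
    bad <- cusp_names[which(ord != 1:4)[1]]
    abort(sprintf("horn ordering inconsistent with ridge path direction at the %s", bad))
  }
  seg_pts <- function(i1, i2) {
    ii <- if (i1 <= i2) i1:i2 else c(i1:n_r, 1:i2)
    ridge_path[ii, , drop = FALSE]
  }
  pairs <- cbind(idx, idx[c(2:4, 1)])
  ridge_lms <- purrr::map(1:4, function(s) {
    seg <- seg_pts(pairs[s, 1], pairs[s, 2])
    # pin the segment ends to the horn landmarks, resample, drop the ends
    seg[1, ] <- horns[s, ]
    seg[nrow(seg), ] <- horns[c(2:4, 1)[s], ]
    if (nrow(seg) < 4) abort("ridge segment too short to resample")
    rs <- resample_curve(seg, segment_counts[s] + 2, closed = FALSE)
    rs[-c(1, nrow(rs)), , drop = FALSE]
  })
  cervix_lms <- resample_curve(cervix_path, n_cervix, closed = TRUE)
  coords <- rbind(horns, do.call(rbind, ridge_lms), cervix_lms)
  roles <- c(rep("horn", 4), rep("ridge", sum(segment_counts)),
             rep("cervix", n_cervix))
  stopifnot(nrow(coords) == 4 + sum(segment_counts) + n_cervix)
  structure(list(coords = coords, roles = roles,
                 chirality = if (mirror) "mirrored_right" else "left"),
            class = "landmark_config")
}

centroid_size <- function(x) sqrt(sum(scale(x, scale = FALSE)^2))

# Optimal rotation (no reflection) aligning x onto y, both centred.
kabsch <- function(x, y) {
  s <- svd(crossprod(x, y))
  d <- sign(det(s$u %*% t(s$v)))
  s$u %*% diag(c(1, 1, d)) %*% t(s$v)
}

#' Generalised Procrustes analysis
#'
#' Removes translation (centroid to origin), size (unit centroid size) and
#' rotation (iterative alignment to the evolving mean shape, rotations
#' only) from a sample of landmark configurations. Iterates until the mean
#' shape changes by less than `tol` (default 1e-8).
#'
#' @param configs List of k x 3 matrices (or `landmark_config` objects)
#'   with equal landmark count; length >= 2.
#' @param groups Optional group labels (recycled onto the result).
#' @param tol Convergence tolerance on the mean shape.
#' @return Object of class `shape_space`: `aligned` (n x k x 3 array),
#'   `centroid_sizes`, `mean_shape` (k x 3), `groups`, `labels`.
#' @export
gpa <- function(configs, groups = NULL, tol = 1e-8) {
  mats <- purrr::map(configs, function(ci) {
    if (inherits(ci, "landmark_config")) ci$coords else as.matrix(ci)
  })
  n <- length(mats)
  if (n < 2) abort("need at least 2 configurations")
  k <- nrow(mats[[1]])
  if (any(purrr::map_int(mats, nrow) != k)) abort("landmark counts differ")
  if (any(purrr::map_lgl(mats, ~ any(!is.finite(.x))))) abort("non-finite coordinates")
  cs <- purrr::map_dbl(mats, centroid_size)
  if (any(cs < 1e-12)) abort("degenerate configuration (zero centroid size)")
  scaled <- purrr::map2(mats, cs, function(m, s) scale(m, scale = FALSE) / s)
  if (any(purrr::map_dbl(scaled, ~ qr(.x)$rank) < 2)) {
    abort("degenerate (collinear) configuration")
  }
  ref <- scaled[[1]]
  for (it in 1:200) {
    aligned <- purrr::map(scaled, ~ .x %*% kabsch(.x, ref))
    m <- Reduce(`+`, aligned) / n
    m <- scale(m, scale = FALSE) / centroid_size(m)
    if (sqrt(sum((m - ref)^2)) < tol) {
      ref <- m
      break
    }
    ref <- m
  }
  aligned <- purrr::map(scaled, ~ .x %*% kabsch(.x, ref))
  arr <- array(NA_real_, c(n, k, 3))
  for (i in seq_len(n)) arr[i, , ] <- aligned[[i]]
  labels <- purrr::map_chr(seq_len(n), function(i) {
    lb <- attr(configs[[i]], "label")
    if (inherits(configs[[i]], "landmark_config") && !is.null(configs[[i]]$label)) {
      lb <- configs[[i]]$label
    }
    if (is.null(lb)) paste0("spec_", i) else as.character(lb)
  })
  if (is.null(groups)) {
    groups <- purrr::map_chr(configs, function(ci) {
      g <- attr(ci, "group")
      if (is.null(g)) NA_character_ else as.character(g)
    })
    if (all(is.na(groups))) groups <- NULL
  }
  structure(list(aligned = arr, centroid_sizes = cs, mean_shape = ref,
                 groups = groups, labels = labels),
            class = "shape_space")
}

#' @export
print.shape_space <- function(x, ...) {
  cat(sprintf("Procrustes shape space: %d specimens x %d landmarks\n",
              dim(x$aligned)[1], dim(x$aligned)[2]))
  invisible(x)
}

# Flatten the aligned array to an n x 3k matrix (landmark-major).
flatten_space <- function(space) {
  d <- dim(space$aligned)
  matrix(space$aligned, d[1], d[2] * d[3])
}

#' Procrustes distance matrix of a shape space
#'
#' Euclidean distances between aligned configurations (tangent-space
#' approximation of Procrustes distance).
#' @param space A [gpa()] result.
#' @return `dist` object.
#' @export
procrustes_distances <- function(space) {
  stats::dist(flatten_space(space))
}

#' Principal component analysis of Procrustes shape coordinates
#'
#' Eigen-decomposition of the covariance of the aligned coordinates
#' (orthogonal tangent projection at the mean shape).
#'
#' @param space A [gpa()] result with n >= 3 specimens.
#' @return Object of class `ordination`: `scores` (n x k), `axes`
#'   (loadings), `explained` (variance fractions over non-null axes),
#'   `center`, `kind = "pca"`, `groups`.
#' @export
shape_pca <- function(space) {
  x <- flatten_space(space)
  if (nrow(x) < 3) abort("PCA needs at least 3 specimens")
  ctr <- colMeans(x)
  xc <- sweep(x, 2, ctr)
  s <- svd(xc)
  keep <- s$d > max(s$d) * 1e-10
  scores <- (s$u %*% diag(s$d, length(s$d)))[, keep, drop = FALSE]
  ev <- s$d[keep]^2
  structure(list(scores = scores, axes = s$v[, keep, drop = FALSE],
                 explained = ev / sum(ev), center = ctr,
                 kind = "pca", groups = space$groups,
                 labels = space$labels,
                 centroid_sizes = space$centroid_sizes),
            class = "ordination")
}

#' @export
print.ordination <- function(x, ...) {
  cat(sprintf("%s ordination: %d specimens, %d axes\n",
              toupper(x$kind), nrow(x$scores), ncol(x$scores)))
  cat("  explained:", paste(sprintf("%.1f%%", 100 * head(x$explained, 5)),
                            collapse = " "), "\n")
  invisible(x)
}

#' Number of leading PCs reaching a target explained variance
#'
#' @param result An `ordination` (PCA) result.
#' @param target Cumulative explained-variance target (default 0.90).
#' @return Integer k: the smallest number of axes whose cumulative
#'   explained variance reaches `target` (at least 1).
#' @export
select_pcs <- function(result, target = 0.90) {
  check_scalar(target, "target", lower = 0, upper = 1)
  max(1L, which(cumsum(result$explained) >= target - 1e-12)[1])
}

#' Between-group principal component analysis
#'
#' PCA of the (equally weighted) group means; all individuals and any
#' unknown specimens are projected a posteriori onto the resulting axes.
#' Unknowns never influence axis estimation.
#'
#' @param x n x p data matrix (PC scores or flattened Procrustes
#'   residuals).
#' @param groups Group labels, length n; each group needs n >= 2.
#' @param unknowns Optional matrix of unknown specimens (m x p).
#' @return `ordination` (kind `"bgpca"`) with `scores`, `axes`,
#'   `explained` (between-group variance fractions), `group_means`
#'   (projected), `unknown_scores`.
#' @export
bgpca <- function(x, groups, unknowns = NULL) {
  x <- as.matrix(x)
  groups <- as.character(groups)
  tab <- table(groups)
  if (length(tab) < 2) abort("between-group PCA needs at least 2 groups")
  if (any(tab < 2)) abort(sprintf("group '%s' has fewer than 2 members",
                                  names(tab)[tab < 2][1]))
  gm <- do.call(rbind, purrr::map(names(tab), function(g) {
    colMeans(x[groups == g, , drop = FALSE])
  }))
  ctr <- colMeans(gm) # equal-weight grand mean of group means
  gmc <- sweep(gm, 2, ctr)
  s <- svd(gmc)
  keep <- which(s$d > max(s$d) * 1e-10)
  keep <- head(keep, length(tab) - 1)
  axes <- s$v[, keep, drop = FALSE]
  ev <- s$d[keep]^2
  proj <- function(mat) sweep(as.matrix(mat), 2, ctr) %*% axes
  structure(list(scores = proj(x), axes = axes, explained = ev / sum(ev),
                 center = ctr, kind = "bgpca", groups = groups,
                 group_means = proj(gm), group_levels = names(tab),
                 unknown_scores = if (!is.null(unknowns)) proj(unknowns)),
            class = "ordination")
}

#' Canonical variate analysis with Mahalanobis classification
#'
#' Canonical axes maximising the between- over pooled within-group
#' variance; in canonical space the pooled within-group covariance is the
#' identity, so classification of members and unknowns is by smallest
#' Euclidean (= Mahalanobis) distance to the group means, with posterior
#' probabilities under equal priors.
#'
#' @param x n x k matrix of PC scores; k must be < n - g.
#' @param groups Group labels (each n >= 2).
#' @param unknowns Optional m x k matrix projected and classified a
#'   posteriori.
#' @return `ordination` (kind `"cva"`) with `scores`, `axes`, `explained`,
#'   `group_means`, `classification` (tibble: label, predicted, posterior
#'   columns), `unknown_scores`, `unknown_classification`.
#' @export
cva <- function(x, groups, unknowns = NULL) {
  x <- as.matrix(x)
  groups <- as.character(groups)
  n <- nrow(x)
  g <- length(unique(groups))
  k <- ncol(x)
  if (g < 2) abort("CVA needs at least 2 groups")
  if (any(table(groups) < 2)) abort("each group needs at least 2 members")
  if (k >= n - g) abort("too many variables: need k < n - g (use fewer PCs)")
  lev <- sort(unique(groups))
  gm <- do.call(rbind, purrr::map(lev, function(gg) {
    colMeans(x[groups == gg, , drop = FALSE])
  }))
  W <- matrix(0, k, k)
  for (gg in lev) {
    xi <- x[groups == gg, , drop = FALSE]
    xi <- sweep(xi, 2, colMeans(xi))
    W <- W + crossprod(xi)
  }
  W <- W / (n - g)
  ok <- tryCatch({
    ch <- chol(W)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) abort("singular pooled within-group covariance: use fewer PCs")
  Winv_half <- solve(chol(W)) # W^{-1/2} (upper-chol inverse)
  ctr <- colMeans(gm)
  B <- crossprod(sweep(gm, 2, ctr)) # between-group (equal weights)
  M <- t(Winv_half) %*% B %*% Winv_half
  e <- eigen((M + t(M)) / 2)
  n_ax <- min(g - 1, sum(e$values > max(e$values) * 1e-10))
  axes <- Winv_half %*% e$vectors[, seq_len(n_ax), drop = FALSE]
  proj <- function(mat) sweep(as.matrix(mat), 2, ctr) %*% axes
  scores <- proj(x)
  means_c <- proj(gm)
  classify <- function(sc) {
    d2 <- vapply(seq_along(lev), function(j) {
      rowSums(sweep(sc, 2, means_c[j, ])^2)
    }, numeric(nrow(sc)))
    d2 <- matrix(d2, nrow = nrow(sc))
    post <- exp(-d2 / 2)
    post <- post / rowSums(post)
    colnames(post) <- lev
    tibble(predicted = lev[apply(d2, 1, which.min)],
           mahalanobis_min = sqrt(apply(d2, 1, min)),
           posterior = as_tibble(post))
  }
  cl <- classify(scores)
  cl$observed <- groups
  structure(list(scores = scores, axes = axes,
                 explained = e$values[seq_len(n_ax)] / sum(e$values[seq_len(n_ax)]),
                 center = ctr, kind = "cva", groups = groups,
                 group_means = means_c, group_levels = lev,
                 classification = cl,
                 unknown_scores = if (!is.null(unknowns)) proj(unknowns),
                 unknown_classification = if (!is.null(unknowns)) classify(proj(unknowns))),
            class = "ordination")
}

#' Leave-one-out cross-validated classification
#'
#' For each specimen the ordination (CVA or bgPCA) is refit without it,
#' the held-out specimen is projected a posteriori and classified by the
#' refit model; per-group and overall correct-classification rates are
#' reported.
#'
#' @param x n x k data matrix (PC scores or residuals).
#' @param groups Group labels (each group n >= 3).
#' @param method `"cva"` or `"bgpca"` (bgPCA classifies by nearest group
#'   mean in bgPC space).
#' @return List: `confusion` (tibble observed x predicted counts), `rates`
#'   (per-group correct-classification), `overall`.
#' @export
cross_validate <- function(x, groups, method = c("cva", "bgpca")) {
  method <- match.arg(method)
  x <- as.matrix(x)
  groups <- as.character(groups)
  if (any(table(groups) < 3)) abort("each group needs at least 3 members for LOO")
  n <- nrow(x)
  pred <- character(n)
  for (i in seq_len(n)) {
    xt <- x[-i, , drop = FALSE]
    gt <- groups[-i]
    if (method == "cva") {
      fit <- cva(xt, gt, unknowns = x[i, , drop = FALSE])
      pred[i] <- fit$unknown_classification$predicted
    } else {
      fit <- bgpca(xt, gt, unknowns = x[i, , drop = FALSE])
      d2 <- rowSums(sweep(fit$group_means, 2, fit$unknown_scores[1, ])^2)
      pred[i] <- fit$group_levels[which.min(d2)]
    }
  }
  lev <- sort(unique(groups))
  conf <- as_tibble(as.data.frame(table(observed = factor(groups, lev),
                                        predicted = factor(pred, lev))))
  rates <- purrr::map_dbl(lev, function(g) mean(pred[groups == g] == g))
  names(rates) <- lev
  list(confusion = conf, rates = rates, overall = mean(pred == groups),
       predicted = pred)
}

#' Allometry test: ordination scores on centroid size
#'
#' Per-axis least-squares regression of the score on centroid size, with a
#' permutation p-value (sizes permuted, two-sided on the slope) and the
#' classical F-test alternative.
#'
#' @param scores n x k score matrix (PCs or bgPCs).
#' @param centroid_sizes Length-n centroid sizes (must vary).
#' @param n_perm Permutations (default 10,000; 0 = classical test only).
#' @param seed Seed for the permutations.
#' @return Tibble per axis: `axis`, `slope`, `r_squared`, `p_f`,
#'   `p_perm` (NA when `n_perm = 0`).
#' @export
allometry_regression <- function(scores, centroid_sizes, n_perm = 10000,
                                 seed = NULL) {
  scores <- as.matrix(scores)
  n <- nrow(scores)
  if (n < 4) abort("need at least 4 specimens")
  if (sd(centroid_sizes) < 1e-12) abort("centroid sizes are constant")
  cs <- centroid_sizes - mean(centroid_sizes)
  sxx <- sum(cs^2)
  fit_axis <- function(y, x) sum(x * (y - mean(y))) / sxx
  res <- purrr::map(seq_len(ncol(scores)), function(j) {
    y <- scores[, j]
    fit <- lm(y ~ centroid_sizes)
    slope <- unname(coef(fit)[2])
    r2 <- summary(fit)$r.squared
    p_f <- anova(fit)[["Pr(>F)"]][1]
    p_perm <- NA_real_
    if (n_perm > 0) {
      obs <- abs(slope)
      perm <- with_seed(if (is.null(seed)) NULL else derive_seed(seed, j), {
        vapply(seq_len(n_perm), function(i) {
          abs(fit_axis(y, sample(cs)))
        }, numeric(1))
      })
      p_perm <- (sum(perm >= obs) + 1) / (n_perm + 1)
    }
    tibble(axis = j, slope = slope, r_squared = r2, p_f = p_f, p_perm = p_perm)
  })
  dplyr::bind_rows(res)
}

#' Read landmark configurations from a long-format CSV
#'
#' Columns: `specimen`, `index`, `x`, `y`, `z`, optionally `role` and
#' `group`.
#'
#' @param path CSV file path.
#' @return Named list of k x 3 matrices with `group` attributes.
#' @export
read_landmarks_csv <- function(path) {
  data <- readr::read_csv(path, show_col_types = FALSE)
  miss <- setdiff(c("specimen", "index", "x", "y", "z"), names(data))
  if (length(miss)) abort(paste("missing columns:", paste(miss, collapse = ", ")))
  sp <- split(data, data$specimen)
  purrr::map(sp, function(d) {
    d <- d[order(d$index), ]
    m <- as.matrix(d[, c("x", "y", "z")])
    if ("group" %in% names(d)) attr(m, "group") <- as.character(d$group[1])
    attr(m, "label") <- as.character(d$specimen[1])
    m
  })
}

#' Read landmark configurations from a TPS file
#'
#' Minimal TPS reader: `LM3=` blocks of x y z rows with optional `ID=` and
#' `GROUP=` (non-standard but accepted) lines.
#'
#' @param path TPS file path.
#' @return Named list of k x 3 matrices with `group` attributes.
#' @export
read_landmarks_tps <- function(path) {
  lines <- readLines(path)
  out <- list()
  i <- 1
  spec <- 0
  while (i <= length(lines)) {
    ln <- trimws(lines[i])
    if (grepl("^LM3?=", ln, ignore.case = TRUE)) {
      k <- as.integer(sub("^LM3?=", "", ln, ignore.case = TRUE))
      rows <- lines[(i + 1):(i + k)]
      m <- do.call(rbind, purrr::map(rows, function(r) {
        as.numeric(strsplit(trimws(r), "\\s+")[[1]])
      }))
      if (ncol(m) == 2) m <- cbind(m, 0)
      i <- i + k + 1
      id <- NULL
      grp <- NULL
      while (i <= length(lines) && grepl("=", lines[i]) &&
             !grepl("^LM3?=", trimws(lines[i]), ignore.case = TRUE)) {
        kv <- strsplit(trimws(lines[i]), "=")[[1]]
        if (toupper(kv[1]) == "ID") id <- kv[2]
        if (toupper(kv[1]) == "GROUP") grp <- kv[2]
        i <- i + 1
      }
      spec <- spec + 1
      if (is.null(id)) id <- paste0("spec_", spec)
      if (!is.null(grp)) attr(m, "group") <- grp
      attr(m, "label") <- id
      out[[id]] <- m
    } else {
      i <- i + 1
    }
  }
  if (!length(out)) abort("no LM3= blocks found")
  out
}
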