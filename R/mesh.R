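# Minimal triangle-mesh helpers for the crown-surface operations.
# A mesh is a list(vertices = n x 3 numeric, faces = m x 3 integer,
# 1-based) with class "crown_mesh".

#' Construct a triangle mesh
#'
#' @param vertices n x 3 numeric matrix of coordinates (mm).
#' @param faces m x 3 integer matrix of 1-based vertex indices, consistently
#'   oriented (counter-clockwise seen from outside).
#' @return Object of class `crown_mesh`.
#' @export
crown_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  faces <- matrix(as.integer(as.matrix(faces)), ncol = 3)
  if (ncol(vertices) != 3) abort("vertices must be n x 3")
  if (nrow(faces) < 1 || nrow(vertices) < 3) abort("empty mesh")
  if (max(faces) > nrow(vertices) || min(faces) < 1) abort("face index out of range")
  structure(list(vertices = vertices, faces = faces), class = "crown_mesh")
}

#' @export
print.crown_mesh <- function(x, ...) {
  cat(sprintf("Triangle mesh: %d vertices, %d faces, %s\n",
              nrow(x$vertices), nrow(x$faces),
              if (mesh_is_closed(x)) "closed" else "open"))
  invisible(x)
}

#' Is a mesh closed (watertight)?
#'
#' Every edge must be shared by exactly two faces.
#' @param mesh A [crown_mesh()].
#' @return Logical.
#' @export
mesh_is_closed <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  all(table(key) == 2)
}

#' Enclosed volume of a closed triangle mesh
#'
#' Signed-tetrahedron (divergence theorem) volume; positive for outward
#' consistently oriented faces.
#' @param mesh A [crown_mesh()].
#' @return Volume (mm^3).
#' @export
mesh_volume <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c <- v[f[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * c[, 3] - b[, 3] * c[, 2]) -
        a[, 2] * (b[, 1] * c[, 3] - b[, 3] * c[, 1]) +
        a[, 3] * (b[, 1] * c[, 2] - b[, 2] * c[, 1])) / 6
}

#' Surface area of a triangle mesh
#' @param mesh A [crown_mesh()].
#' @return Area (mm^2).
#' @export
mesh_area <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  cy <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  cz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  sum(sqrt(cx^2 + cy^2 + cz^2)) / 2
}

# Area-weighted vertex normals (unit length).
mesh_vertex_normals <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  fn <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  n <- matrix(0, nrow(v), 3)
  for (j in 1:3) {
    for (k in 1:3) {
      n[, k] <- n[, k] + unname(tapply(fn[, k], factor(f[, j], levels = seq_len(nrow(v))),
                                       sum, default = 0))
    }
  }
  n[is.na(n)] <- 0
  len <- sqrt(rowSums(n^2))
  len[len == 0] <- 1
  n / len
}

# Minimum distances from query points to a triangle soup. The closest
# point on a triangle is either the orthogonal projection (if it falls
# inside) or lies on one of the edges, so the minimum over the in-plane
# projection and the three edge segments is exact.
point_mesh_distance <- function(points, mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  A <- v[f[, 1], , drop = FALSE]
  B <- v[f[, 2], , drop = FALSE]
  C <- v[f[, 3], , drop = FALSE]
  E0 <- B - A
  E1 <- C - A
  a <- rowSums(E0 * E0)
  b <- rowSums(E0 * E1)
  c <- rowSums(E1 * E1)
  det <- pmax(a * c - b^2, 1e-30)
  seg_dist2 <- function(P, S0, D, dd) {
    # squared distance from point P (recycled) to segments S0 + t D
    W <- sweep(-S0, 2, P, "+")
    t <- pmin(pmax(rowSums(W * D) / pmax(dd, 1e-30), 0), 1)
    R <- W - D * t
    rowSums(R * R)
  }
  E2 <- C - B
  dd0 <- rowSums(E0 * E0)
  dd1 <- rowSums(E1 * E1)
  dd2 <- rowSums(E2 * E2)
  apply(points, 1, function(P) {
    W <- sweep(-A, 2, P, "+") # A - P ... careful: we want P - A
    W <- -W
    d <- rowSums(W * E0)
    e <- rowSums(W * E1)
    s <- (c * d - b * e) / det
    t <- (a * e - b * d) / det
    inside <- s >= 0 & t >= 0 & (s + t) <= 1
    proj <- W - (E0 * s + E1 * t)
    d2 <- rowSums(proj * proj)
    d2[!inside] <- Inf
    d2e <- pmin(seg_dist2(P, A, E0, dd0),
                seg_dist2(P, A, E1, dd1),
                seg_dist2(P, B, E2, dd2))
    sqrt(min(pmin(d2, d2e)))
  })
}
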