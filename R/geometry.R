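#' Rigid transform (rotation + translation)
#'
#' @param rotation 3 x 3 proper orthonormal matrix (checked to 1e-9).
#' @param translation numeric length-3 vector, mm.
#' @return object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  if (!all(dim(rotation) == c(3L, 3L))) stop("rotation must be 3 x 3")
  if (length(translation) != 3L) stop("translation must have length 3")
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9)
    stop("rotation columns are not orthonormal")
  if (abs(det(rotation) - 1) > 1e-9)
    stop("rotation must be proper (determinant +1)")
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' Rotation matrix about an arbitrary axis
#'
#' Rodrigues' formula; right-handed positive angle about `axis`.
#'
#' @param axis numeric length-3 direction (normalized internally).
#' @param angle_deg rotation angle in degrees.
#' @return 3 x 3 rotation matrix.
#' @export
rotation_about_axis <- function(axis, angle_deg) {
  a <- as.numeric(axis)
  n <- sqrt(sum(a^2))
  if (n < 1e-12) stop("rotation axis must be nonzero")
  a <- a / n
  th <- angle_deg * pi / 180
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Apply a rigid transform to points or a mesh
#'
#' Vertices are mapped by rotation then translation; areas, volumes and
#' pairwise distances are preserved.
#'
#' @param x a [tri_mesh()] or an n x 3 point matrix.
#' @param transform a [rigid_transform()].
#' @return transformed object of the same kind.
#' @export
apply_transform <- function(x, transform) {
  stopifnot(inherits(transform, "rigid_transform"))
  if (inherits(x, "trimesh")) {
    x$vertices <- transform_points(x$vertices, transform)
    return(x)
  }
  transform_points(x, transform)
}

transform_points <- function(points, transform) {
  p <- points
  vec <- is.null(dim(p))
  if (vec) p <- matrix(p, ncol = 3L)
  out <- p %*% t(transform$rotation) +
    matrix(transform$translation, nrow(p), 3L, byrow = TRUE)
  if (vec) out[1, ] else out
}

#' Centroid of the solid enclosed by a watertight mesh
#'
#' Divergence-theorem sum over signed origin tetrahedra; invariant to
#' tessellation refinement. The mesh must be watertight; inward-pointing
#' normals (negative signed volume) are tolerated with a warning since the
#' centroid is unaffected.
#'
#' @param mesh a watertight [tri_mesh()].
#' @return numeric length-3 centroid (mm). Attribute `"volume"` carries the
#'   enclosed volume in mm^3 (positive).
#' @export
volume_centroid <- function(mesh) {
  wt <- is_watertight(mesh)
  if (!wt)
    stop(sprintf("mesh '%s' is not watertight: %d open/non-manifold edges",
                 mesh$name, attr(wt, "open_edges")))
  v1 <- mesh$vertices[mesh$faces[, 1], , drop = FALSE]
  v2 <- mesh$vertices[mesh$faces[, 2], , drop = FALSE]
  v3 <- mesh$vertices[mesh$faces[, 3], , drop = FALSE]
  # signed volume of tetra (0, v1, v2, v3): det/6
  cx <- v2[, 2] * v3[, 3] - v2[, 3] * v3[, 2]
  cy <- v2[, 3] * v3[, 1] - v2[, 1] * v3[, 3]
  cz <- v2[, 1] * v3[, 2] - v2[, 2] * v3[, 1]
  vol6 <- v1[, 1] * cx + v1[, 2] * cy + v1[, 3] * cz
  vol <- sum(vol6) / 6
  if (abs(vol) < 1e-9) stop("mesh encloses no volume")
  if (vol < 0)
    warning(sprintf("mesh '%s' has inward normals; flipping for volume computation",
                    mesh$name))
  cent <- colSums((v1 + v2 + v3) / 4 * vol6) / sum(vol6)
  structure(as.numeric(cent), volume = abs(vol))
}

#' Extreme point of a mesh along a direction
#'
#' Returns the vertex maximizing the dot product with `direction`. Vertices
#' tying within `tol` of the maximum are averaged: flat plantar surfaces are
#' common and the centroid of the tied set is stabler than an arbitrary
#' first-index pick.
#'
#' @param mesh a [tri_mesh()].
#' @param direction numeric length-3, need not be normalized but must be
#'   nonzero.
#' @param tol tie tolerance in mm along `direction` (default 1e-6).
#' @return numeric length-3 point. Attribute `"n_tied"` counts the averaged
#'   vertices.
#' @export
extreme_point <- function(mesh, direction, tol = 1e-6) {
  d <- as.numeric(direction)
  n <- sqrt(sum(d^2))
  if (n < 1e-12) stop("direction must be a nonzero vector")
  d <- d / n
  s <- as.numeric(mesh$vertices %*% d)
  m <- max(s)
  tied <- which(s >= m - tol)
  structure(colMeans(mesh$vertices[tied, , drop = FALSE]), n_tied = length(tied))
}

#' Deterministic area-weighted surface samples
#'
#' Each triangle is subdivided by uniform midpoint subdivision (power-of-two
#' division of every edge) until all sub-edges are at most `max_edge`; each
#' sub-triangle then contributes its three edge midpoints, each weighted by a
#' third of its area. The edge-midpoint rule integrates quadratics exactly on
#' flat faces, so weighted means and covariances of polyhedral surfaces are
#' exact (the one-point centroid rule is only first order and leaves an
#' O(max_edge^2) covariance bias). Sub-areas of one parent are exactly
#' equal, so total weight equals the mesh area exactly and principal
#' component analysis of these weighted samples reproduces the true
#' surface-integral covariance instead of the vertex distribution.
#'
#' @param mesh a [tri_mesh()].
#' @param max_edge maximum sub-triangle edge length, mm (default 1.0).
#' @return object of class `surface_samples`: list with `points` (n x 3) and
#'   `weights` (mm^2, summing to the mesh area).
#' @export
surface_quadrature <- function(mesh, max_edge = 1.0) {
  if (!is.numeric(max_edge) || max_edge <= 0) stop("max_edge must be > 0")
  A <- mesh$vertices[mesh$faces[, 1], , drop = FALSE]
  B <- mesh$vertices[mesh$faces[, 2], , drop = FALSE]
  C <- mesh$vertices[mesh$faces[, 3], , drop = FALSE]
  longest <- pmax(sqrt(rowSums((B - A)^2)), sqrt(rowSums((C - B)^2)),
                  sqrt(rowSums((A - C)^2)))
  ndiv <- 2L^pmax(0L, ceiling(log2(longest / max_edge)))
  areas <- face_areas(mesh$vertices, mesh$faces)
  pts_list <- list()
  w_list <- list()
  k <- 0L
  for (n in sort(unique(ndiv))) {
    idx <- ndiv == n
    a <- A[idx, , drop = FALSE]
    u <- B[idx, , drop = FALSE] - a
    v <- C[idx, , drop = FALSE] - a
    w_sub <- areas[idx] / n^2 / 3
    # sub-triangle lattice in units of 1/n: upward (i,j), i+j <= n-1, has
    # vertices (i,j), (i+1,j), (i,j+1); downward (i,j), i+j <= n-2, has
    # (i+1,j), (i,j+1), (i+1,j+1); emit the three edge midpoints of each
    ij_up <- expand.grid(i = 0:(n - 1L), j = 0:(n - 1L))
    ij_up <- ij_up[ij_up$i + ij_up$j <= n - 1L, , drop = FALSE]
    bary <- rbind(cbind(ij_up$i + 0.5, ij_up$j),
                  cbind(ij_up$i, ij_up$j + 0.5),
                  cbind(ij_up$i + 0.5, ij_up$j + 0.5))
    if (n >= 2L) {
      ij_dn <- expand.grid(i = 0:(n - 2L), j = 0:(n - 2L))
      ij_dn <- ij_dn[ij_dn$i + ij_dn$j <= n - 2L, , drop = FALSE]
      bary <- rbind(bary,
                    cbind(ij_dn$i + 0.5, ij_dn$j + 0.5),
                    cbind(ij_dn$i + 0.5, ij_dn$j + 1),
                    cbind(ij_dn$i + 1, ij_dn$j + 0.5))
    }
    bary <- bary / n
    ns <- nrow(bary)
    px <- outer(a[, 1], rep(1, ns)) + outer(u[, 1], bary[, 1]) + outer(v[, 1], bary[, 2])
    py <- outer(a[, 2], rep(1, ns)) + outer(u[, 2], bary[, 1]) + outer(v[, 2], bary[, 2])
    pz <- outer(a[, 3], rep(1, ns)) + outer(u[, 3], bary[, 1]) + outer(v[, 3], bary[, 2])
    k <- k + 1L
    pts_list[[k]] <- cbind(as.vector(px), as.vector(py), as.vector(pz))
    w_list[[k]] <- rep(w_sub, times = ns)
  }
  structure(list(points = do.call(rbind, pts_list), weights = unlist(w_list)),
            class = "surface_samples")
}

#' @export
print.surface_samples <- function(x, ...) {
  cat(sprintf("<surface_samples: %d points, total weight %.2f mm^2>\n",
              nrow(x$points), sum(x$weights)))
  invisible(x)
}

# Subdivided vertex lattice of a mesh: the vertices of the same power-of-two
# subdivision used by surface_quadrature (spacing <= max_edge), including the
# original vertices and edge points. Unlike centroid quadrature samples these
# lie on face boundaries and corners, which extreme-point searches (silhouette
# contours) need; integral quantities keep using the weighted centroids.
# Shared-edge points are emitted once per incident face; duplicates are
# harmless for extremes and symmetric for tie centroids.
surface_lattice <- function(mesh, max_edge = 1.0) {
  if (!is.numeric(max_edge) || max_edge <= 0) stop("max_edge must be > 0")
  A <- mesh$vertices[mesh$faces[, 1], , drop = FALSE]
  B <- mesh$vertices[mesh$faces[, 2], , drop = FALSE]
  C <- mesh$vertices[mesh$faces[, 3], , drop = FALSE]
  longest <- pmax(sqrt(rowSums((B - A)^2)), sqrt(rowSums((C - B)^2)),
                  sqrt(rowSums((A - C)^2)))
  ndiv <- 2L^pmax(0L, ceiling(log2(longest / max_edge)))
  out <- list()
  k <- 0L
  for (n in sort(unique(ndiv))) {
    idx <- ndiv == n
    a <- A[idx, , drop = FALSE]
    u <- B[idx, , drop = FALSE] - a
    v <- C[idx, , drop = FALSE] - a
    ij <- expand.grid(i = 0:n, j = 0:n)
    ij <- ij[ij$i + ij$j <= n, , drop = FALSE]
    bi <- ij$i / n; bj <- ij$j / n
    px <- outer(a[, 1], rep(1, length(bi))) + outer(u[, 1], bi) + outer(v[, 1], bj)
    py <- outer(a[, 2], rep(1, length(bi))) + outer(u[, 2], bi) + outer(v[, 2], bj)
    pz <- outer(a[, 3], rep(1, length(bi))) + outer(u[, 3], bi) + outer(v[, 3], bj)
    k <- k + 1L
    out[[k]] <- cbind(as.vector(px), as.vector(py), as.vector(pz))
  }
  do.call(rbind, out)
}

#' Weighted covariance of points
#'
#' @param points n x 3 matrix.
#' @param weights nonnegative weights (default uniform).
#' @return 3 x 3 covariance matrix; attribute `"centroid"` is the weighted
#'   mean.
#' @export
weighted_covariance <- function(points, weights = NULL) {
  if (is.null(weights)) weights <- rep(1, nrow(points))
  w <- weights / sum(weights)
  mu <- colSums(points * w)
  d <- sweep(points, 2, mu)
  structure(crossprod(d * sqrt(w), d * sqrt(w)), centroid = mu)
}
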