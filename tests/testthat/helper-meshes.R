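# shared fixtures (built in code) and independent oracles

deg <- function(x) x * 180 / pi

angle_between_deg <- function(a, b) {
  a <- a / sqrt(sum(a^2)); b <- b / sqrt(sum(b^2))
  deg(acos(pmin(1, abs(sum(a * b)))))
}

tetra_mesh <- function() {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  f <- rbind(c(1, 3, 2), c(1, 2, 4), c(1, 4, 3), c(2, 3, 4))
  tri_mesh(v, f)
}

# axis-aligned closed box [lo, hi], outward normals
box_mesh_t <- function(lo, hi, name = "other") {
  v <- unname(as.matrix(expand.grid(x = c(lo[1], hi[1]), y = c(lo[2], hi[2]),
                                    z = c(lo[3], hi[3]))))
  f <- rbind(c(1, 3, 4), c(1, 4, 2), c(5, 6, 8), c(5, 8, 7),
             c(1, 2, 6), c(1, 6, 5), c(3, 7, 8), c(3, 8, 4),
             c(1, 5, 7), c(1, 7, 3), c(2, 4, 8), c(2, 8, 6))
  m <- tri_mesh(v, f, name)
  if (attr(suppressWarnings(volume_centroid(m)), "volume") < 0)
    m$faces <- m$faces[, c(1, 3, 2)]
  m
}

# closed prism along x from a (y, z) cross-section polygon (CCW or CW)
prism_mesh <- function(poly_yz, x0 = 0, x1 = 40, name = "calcaneus") {
  n <- nrow(poly_yz)
  v <- rbind(cbind(x0, poly_yz), cbind(x1, poly_yz),
             c(x0, colMeans(poly_yz)), c(x1, colMeans(poly_yz)))
  i0 <- 2L * n + 1L; i1 <- 2L * n + 2L
  wrap <- function(j) (j - 1L) %% n + 1L
  f <- do.call(rbind, lapply(seq_len(n), function(j) {
    a <- j; b <- wrap(j + 1L); an <- j + n; bn <- wrap(j + 1L) + n
    rbind(c(a, b, bn), c(a, bn, an), c(i0, b, a), c(i1, an, bn))
  }))
  m <- tri_mesh(v, f, name)
  vc <- suppressWarnings(volume_centroid(m))
  if (isTRUE(attr(vc, "volume") < 0)) m$faces <- m$faces[, c(1, 3, 2)]
  m
}

# analytic covariance of the surface of an axis-aligned box with full
# extents (Lx, Ly, Lz): per-axis surface-integral variance
box_surface_covariance <- function(L) {
  S <- c(L[2] * L[3], L[1] * L[3], L[1] * L[2]) # areas of the x/y/z face pairs
  tot <- 2 * sum(S)
  v <- vapply(1:3, function(i) {
    own <- 2 * S[i] * (L[i] / 2)^2          # the two faces at +-L/2
    others <- 2 * sum(S[-i]) * L[i]^2 / 12  # uniform along axis i
    (own + others) / tot
  }, numeric(1))
  diag(v)
}

# independent PCA oracle: uniform-by-area random points on the mesh surface,
# stratified over triangles (counts by largest remainder), unweighted
# covariance eigen-decomposition
sample_surface_uniform <- function(mesh, n, seed) {
  set.seed(seed)
  v1 <- mesh$vertices[mesh$faces[, 1], , drop = FALSE]
  v2 <- mesh$vertices[mesh$faces[, 2], , drop = FALSE]
  v3 <- mesh$vertices[mesh$faces[, 3], , drop = FALSE]
  e1 <- v2 - v1; e2 <- v3 - v1
  cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  ar <- 0.5 * sqrt(rowSums(cr^2))
  exp_n <- n * ar / sum(ar)
  cnt <- floor(exp_n)
  short <- n - sum(cnt)
  if (short > 0) {
    idx <- order(exp_n - cnt, decreasing = TRUE)[seq_len(short)]
    cnt[idx] <- cnt[idx] + 1
  }
  fi <- rep(seq_along(ar), cnt)
  u <- stats::runif(length(fi)); v <- stats::runif(length(fi))
  flip <- u + v > 1
  u[flip] <- 1 - u[flip]; v[flip] <- 1 - v[flip]
  v1[fi, , drop = FALSE] + u * e1[fi, , drop = FALSE] + v * e2[fi, , drop = FALSE]
}

# canonical form for comparing meshes regardless of vertex/face order
canonical_mesh <- function(mesh) {
  v <- round(mesh$vertices, 9)
  ord <- order(v[, 1], v[, 2], v[, 3])
  rank <- match(seq_len(nrow(v)), ord)
  f <- matrix(rank[mesh$faces], ncol = 3)
  f <- t(apply(f, 1, function(r) { # rotate smallest index first, keep winding
    i <- which.min(r); r[c(i, i %% 3 + 1, (i + 1) %% 3 + 1)]
  }))
  f <- f[order(f[, 1], f[, 2], f[, 3]), , drop = FALSE]
  list(vertices = v[ord, , drop = FALSE], faces = f)
}

phantom_angles <- function(phantom, ...) {
  r <- suppressWarnings(measure_phantom(phantom, ...))
  vapply(r, function(x) x$angle_deg, numeric(1))
}

# valgus-positive rotation about an axis through a point
valgus_rotation <- function(axis, point, angle_deg) {
  R <- rotation_about_axis(axis, -angle_deg)
  rigid_transform(R, as.numeric(point) - as.numeric(R %*% as.numeric(point)))
}
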