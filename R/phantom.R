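#' Synthetic foot phantom specification
#'
#' Describes a parametric hindfoot phantom with analytically known
#' frontal-plane inclinations: a rounded-box calcaneus whose posterior
#' tuberosity slab can be tilted independently of the bone body, an
#' ellipsoidal talus placed at a configurable offset above the calcaneal
#' plantar point, a capped-cylinder distal tibia, a second-metatarsal-head
#' sphere and a flat ground slab. All angles are degrees, valgus positive;
#' offsets and dimensions are mm.
#'
#' @param body_valgus_deg frontal tilt of the whole calcaneus.
#' @param tuberosity_valgus_deg extra tilt of the posterior tuberosity slab,
#'   applied about the anterior axis through the slab's own surface centroid
#'   with a 2 mm blend so the mesh stays watertight.
#' @param tibia_tilt_deg frontal tilt of the tibial diaphysis.
#' @param talus_offset `(medial, dorsal)` mm of the talus centroid relative
#'   to the calcaneal most-plantar point.
#' @param facet_offset `(medial, dorsal)` mm of the talar middle-facet
#'   landmark relative to the same point.
#' @param calc_dims `(length, width, height)` of the calcaneus, mm.
#' @param tuberosity_fraction posterior slab fraction of the length, in
#'   (0, 0.5); the plantar keel apex sits at this fraction of the length so
#'   technique E's plantar-bounded box matches the tuberosity slab.
#' @param side `"right"` or `"left"` (left phantoms are mirrored meshes).
#' @param seed integer seed driving the (optional) vertex jitter.
#' @param noise_mm vertex jitter amplitude (uniform in +/- noise_mm per
#'   coordinate); 0 for exact geometry.
#' @return validated list of class `phantom_spec`.
#' @export
phantom_spec <- function(body_valgus_deg = 0, tuberosity_valgus_deg = 0,
                         tibia_tilt_deg = 0, talus_offset = c(10, 50),
                         facet_offset = c(15, 45),
                         calc_dims = c(80, 30, 45),
                         tuberosity_fraction = 0.20,
                         side = c("right", "left"), seed = 1L,
                         noise_mm = 0) {
  side <- match.arg(side)
  if (any(calc_dims <= 0)) stop("calc_dims must be positive")
  if (tuberosity_fraction <= 0 || tuberosity_fraction >= 0.5)
    stop("tuberosity_fraction must be in (0, 0.5)")
  if (noise_mm < 0) stop("noise_mm must be >= 0")
  if (length(talus_offset) != 2L || talus_offset[2] <= 0)
    stop("talus_offset must be (medial, dorsal) with dorsal > 0")
  if (length(facet_offset) != 2L || facet_offset[2] <= 0)
    stop("facet_offset must be (medial, dorsal) with dorsal > 0")
  structure(list(body_valgus_deg = body_valgus_deg,
                 tuberosity_valgus_deg = tuberosity_valgus_deg,
                 tibia_tilt_deg = tibia_tilt_deg,
                 talus_offset = as.numeric(talus_offset),
                 facet_offset = as.numeric(facet_offset),
                 calc_dims = as.numeric(calc_dims),
                 tuberosity_fraction = tuberosity_fraction,
                 side = side, seed = as.integer(seed),
                 noise_mm = noise_mm),
            class = "phantom_spec")
}

with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# --- primitive closed meshes ------------------------------------------------

# closed mesh by sweeping per-station cross-section polygons along x and
# capping both ends with triangle fans; sections: list of n_u x 2 (y, z)
sweep_mesh <- function(xs, sections, name) {
  n_u <- nrow(sections[[1]])
  n_x <- length(xs)
  verts <- do.call(rbind, lapply(seq_len(n_x), function(i)
    cbind(xs[i], sections[[i]])))
  cap0 <- c(xs[1], colMeans(sections[[1]]))
  cap1 <- c(xs[n_x], colMeans(sections[[n_x]]))
  verts <- rbind(verts, cap0, cap1)
  i_cap0 <- n_u * n_x + 1L
  i_cap1 <- n_u * n_x + 2L
  idx <- function(i, j) (i - 1L) * n_u + ((j - 1L) %% n_u) + 1L
  faces <- vector("list", n_x + 1L)
  for (i in seq_len(n_x - 1L)) {
    j <- seq_len(n_u)
    a <- idx(i, j); b <- idx(i, j + 1L)
    c2 <- idx(i + 1L, j); d <- idx(i + 1L, j + 1L)
    faces[[i]] <- rbind(cbind(a, b, d), cbind(a, d, c2))
  }
  j <- seq_len(n_u)
  faces[[n_x]] <- cbind(i_cap0, idx(1L, j + 1L), idx(1L, j))
  faces[[n_x + 1L]] <- cbind(i_cap1, idx(n_x, j), idx(n_x, j + 1L))
  orient_outward(tri_mesh(verts, do.call(rbind, faces), name))
}

orient_outward <- function(mesh) {
  v1 <- mesh$vertices[mesh$faces[, 1], , drop = FALSE]
  v2 <- mesh$vertices[mesh$faces[, 2], , drop = FALSE]
  v3 <- mesh$vertices[mesh$faces[, 3], , drop = FALSE]
  vol6 <- sum(v1[, 1] * (v2[, 2] * v3[, 3] - v2[, 3] * v3[, 2]) +
              v1[, 2] * (v2[, 3] * v3[, 1] - v2[, 1] * v3[, 3]) +
              v1[, 3] * (v2[, 1] * v3[, 2] - v2[, 2] * v3[, 1]))
  if (vol6 < 0) mesh$faces <- mesh$faces[, c(1L, 3L, 2L)]
  mesh
}

# UV-sphere ellipsoid with semi-axes (a, b, c), closed
ellipsoid_mesh <- function(center, semi = c(20, 14, 11), n_lat = 20L,
                           n_lon = 40L, name = "talus") {
  th <- seq(0, pi, length.out = n_lat + 1L)[2:n_lat] # interior rings
  ph <- seq(0, 2 * pi, length.out = n_lon + 1L)[seq_len(n_lon)]
  grid <- expand.grid(ph = ph, th = th)
  verts <- cbind(semi[1] * sin(grid$th) * cos(grid$ph),
                 semi[2] * sin(grid$th) * sin(grid$ph),
                 semi[3] * cos(grid$th))
  n_ring <- n_lat - 1L
  top <- c(0, 0, semi[3]); bot <- c(0, 0, -semi[3])
  verts <- rbind(verts, top, bot)
  i_top <- n_lon * n_ring + 1L
  i_bot <- n_lon * n_ring + 2L
  idx <- function(i, j) (i - 1L) * n_lon + ((j - 1L) %% n_lon) + 1L
  faces <- list()
  j <- seq_len(n_lon)
  faces[[1]] <- cbind(i_top, idx(1L, j), idx(1L, j + 1L))
  for (i in seq_len(n_ring - 1L)) {
    a <- idx(i, j); b <- idx(i, j + 1L)
    c2 <- idx(i + 1L, j); d <- idx(i + 1L, j + 1L)
    faces[[i + 1L]] <- rbind(cbind(a, d, b), cbind(a, c2, d))
  }
  faces[[n_ring + 1L]] <- cbind(i_bot, idx(n_ring, j + 1L), idx(n_ring, j))
  m <- orient_outward(tri_mesh(sweep_shift(verts, center),
                               do.call(rbind, faces), name))
  m
}

sweep_shift <- function(verts, center)
  sweep(verts, 2, as.numeric(center), "+")

# capped cylinder along unit direction `axis` through `center`
cylinder_mesh <- function(center, axis, radius = 15, length = 100,
                          n_circ = 40L, n_len = 10L, name = "tibia") {
  axis <- axis / sqrt(sum(axis^2))
  # orthonormal basis
  ref <- if (abs(axis[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- ref - sum(ref * axis) * axis
  u <- u / sqrt(sum(u^2))
  v <- c(axis[2] * u[3] - axis[3] * u[2], axis[3] * u[1] - axis[1] * u[3],
         axis[1] * u[2] - axis[2] * u[1])
  ts <- seq(-length / 2, length / 2, length.out = n_len + 1L)
  ph <- seq(0, 2 * pi, length.out = n_circ + 1L)[seq_len(n_circ)]
  ring <- cbind(radius * cos(ph), radius * sin(ph))
  verts <- do.call(rbind, lapply(ts, function(t)
    sweep_shift(outer(ring[, 1], u) + outer(ring[, 2], v) +
                  matrix(t * axis, n_circ, 3, byrow = TRUE), center)))
  i_c0 <- n_circ * (n_len + 1L) + 1L
  i_c1 <- i_c0 + 1L
  verts <- rbind(verts, center - length / 2 * axis, center + length / 2 * axis)
  idx <- function(i, j) (i - 1L) * n_circ + ((j - 1L) %% n_circ) + 1L
  faces <- list()
  j <- seq_len(n_circ)
  for (i in seq_len(n_len)) {
    a <- idx(i, j); b <- idx(i, j + 1L)
    c2 <- idx(i + 1L, j); d <- idx(i + 1L, j + 1L)
    faces[[i]] <- rbind(cbind(a, b, d), cbind(a, d, c2))
  }
  faces[[n_len + 1L]] <- cbind(i_c0, idx(1L, j + 1L), idx(1L, j))
  faces[[n_len + 2L]] <- cbind(i_c1, idx(n_len + 1L, j), idx(n_len + 1L, j + 1L))
  orient_outward(tri_mesh(verts, do.call(rbind, faces), name))
}

box_mesh <- function(lo, hi, name = "ground") {
  v <- unname(as.matrix(expand.grid(x = c(lo[1], hi[1]), y = c(lo[2], hi[2]),
                                    z = c(lo[3], hi[3]))))
  f <- rbind(c(1, 3, 4), c(1, 4, 2), c(5, 6, 8), c(5, 8, 7),
             c(1, 2, 6), c(1, 6, 5), c(3, 7, 8), c(3, 8, 4),
             c(1, 5, 7), c(1, 7, 3), c(2, 4, 8), c(2, 8, 6))
  orient_outward(tri_mesh(v, f, name))
}

# --- calcaneus --------------------------------------------------------------

# rounded-box calcaneus with chamfered edges, tapered (rounded) posterior
# heel and anterior end, and a sharp plantar keel (the medial process of the
# tuberosity) whose apex sits at `tuberosity_fraction` of the length from
# the posterior end; posterior at x = 0, dorsal +z, medial +y (right side)
build_calcaneus <- function(spec) {
  L <- spec$calc_dims[1]; W <- spec$calc_dims[2]; H <- spec$calc_dims[3]
  keel_depth <- H * 6.5 / 45
  hw <- W / 2
  z_hi <- H - 22.5 * H / 45           # body top
  z_lo <- z_hi - (H - keel_depth)     # body bottom (keel hangs below)
  ch <- 0.27 * hw                     # chamfer cut
  kw <- 0.27 * hw                     # keel half-width
  cz <- (z_lo + z_hi) / 2
  x_keel <- spec$tuberosity_fraction * L
  base <- rbind(c(-(hw - ch), z_lo), c(-kw, z_lo), c(0, z_lo), c(kw, z_lo),
                c(hw - ch, z_lo), c(hw, z_lo + ch), c(hw, z_hi - ch),
                c(hw - ch, z_hi), c(-(hw - ch), z_hi), c(-hw, z_hi - ch),
                c(-hw, z_lo + ch))
  heel_len <- 0.10 * L; ant_len <- 0.075 * L
  scale_at <- function(x) {
    if (x < heel_len) {
      max(0.15, sqrt(max(0, 1 - ((heel_len - x) / heel_len)^2)))
    } else if (x > L - ant_len) {
      max(0.30, sqrt(max(0, 1 - ((x - (L - ant_len)) / ant_len)^2)))
    } else 1
  }
  keel_at <- function(x)
    max(0.05, keel_depth * max(0, 1 - ((x - x_keel) / (0.3 * L))^2)^1.5)
  xs <- seq(0, L, by = L / 40)
  sections <- lapply(xs, function(x) {
    s <- scale_at(x)
    sec <- cbind(base[, 1] * s, cz + (base[, 2] - cz) * s)
    sec[3, 2] <- sec[3, 2] - keel_at(x)  # keel apex below scaled bottom
    sec
  })
  mesh <- sweep_mesh(xs, sections, "calcaneus")
  # tuberosity tilt: vertex-wise valgus rotation about the anterior (x) axis
  # through the slab's own surface centroid, blended over 2 mm at the cut
  th_t <- spec$tuberosity_valgus_deg
  if (th_t != 0) {
    fc <- (mesh$vertices[mesh$faces[, 1], 1] +
           mesh$vertices[mesh$faces[, 2], 1] +
           mesh$vertices[mesh$faces[, 3], 1]) / 3
    ar <- face_areas(mesh$vertices, mesh$faces)
    in_slab <- fc < x_keel
    fcent <- (mesh$vertices[mesh$faces[, 1], , drop = FALSE] +
              mesh$vertices[mesh$faces[, 2], , drop = FALSE] +
              mesh$vertices[mesh$faces[, 3], , drop = FALSE]) / 3
    pivot <- colSums(fcent[in_slab, , drop = FALSE] * ar[in_slab]) /
      sum(ar[in_slab])
    t <- pmin(1, pmax(0, (x_keel + 1 - mesh$vertices[, 1]) / 2))
    alpha <- (th_t * pi / 180) * t^2 * (3 - 2 * t)
    dy <- mesh$vertices[, 2] - pivot[2]
    dz <- mesh$vertices[, 3] - pivot[3]
    mesh$vertices[, 2] <- pivot[2] + dy * cos(alpha) + dz * sin(alpha)
    mesh$vertices[, 3] <- pivot[3] - dy * sin(alpha) + dz * cos(alpha)
  }
  th_b <- spec$body_valgus_deg
  if (th_b != 0) {
    R <- rotation_about_axis(c(1, 0, 0), -th_b)
    mesh$vertices <- mesh$vertices %*% t(R)
  }
  mesh
}

mirror_mesh <- function(mesh) {
  mesh$vertices[, 2] <- -mesh$vertices[, 2]
  mesh$faces <- mesh$faces[, c(1L, 3L, 2L)]
  mesh
}

jitter_mesh <- function(mesh, amp) {
  if (amp > 0)
    mesh$vertices <- mesh$vertices +
      matrix(stats::runif(length(mesh$vertices), -amp, amp),
             ncol = 3L)
  mesh
}

#' Generate a synthetic foot phantom
#'
#' Builds the five meshes (calcaneus, talus, tibia, second metatarsal head,
#' ground), the two landmarks, and the analytic expected HAA per technique.
#' Identical specs (including seed) give bitwise-identical meshes. The
#' construction places the talus centroid and the facet landmark relative to
#' the *measured* most-plantar point of the generated calcaneus, so the
#' B-family truths `arctan(medial/dorsal) - tibia_tilt` hold exactly by
#' construction; A/C truths equal the body tilt and D/E truths the body plus
#' tuberosity tilt (all minus the tibial tilt).
#'
#' @param spec a [phantom_spec()].
#' @return list of class `phantom_set`: `meshes` (named list), `landmarks`,
#'   `truth` (named numeric, degrees), `spec`.
#' @export
generate_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_seed(spec$seed, {
    calc <- build_calcaneus(spec)
    calc <- jitter_mesh(calc, spec$noise_mm)
    calc$vertices[, 3] <- calc$vertices[, 3] - min(calc$vertices[, 3])
    plantar <- as.numeric(extreme_point(calc, c(0, 0, -1)))
    talus_c <- plantar + c(0, spec$talus_offset[1], spec$talus_offset[2])
    talus <- jitter_mesh(ellipsoid_mesh(talus_c), spec$noise_mm)
    tau <- spec$tibia_tilt_deg * pi / 180
    tib_axis <- c(0, sin(tau), cos(tau))
    tibia <- jitter_mesh(
      cylinder_mesh(talus_c + c(0, 0, 90), tib_axis), spec$noise_mm)
    met_c <- c(plantar[1] + 150, plantar[2], 6)
    met <- jitter_mesh(ellipsoid_mesh(met_c, semi = c(6, 6, 6), n_lat = 12L,
                                      n_lon = 24L, name = "metatarsal2"),
                       spec$noise_mm)
    ground <- box_mesh(c(plantar[1] - 60, plantar[2] - 60, -4),
                       c(plantar[1] + 180, plantar[2] + 60, 0))
    landmarks <- list(
      second_met_head_plantar = c(plantar[1] + 150, plantar[2], 0),
      talus_middle_facet_center =
        plantar + c(0, spec$facet_offset[1], spec$facet_offset[2]))
    meshes <- list(tibia = tibia, calcaneus = calc, talus = talus,
                   ground = ground, metatarsal2 = met)
    if (spec$side == "left") {
      meshes <- lapply(meshes, mirror_mesh)
      landmarks <- lapply(landmarks, function(p) p * c(1, -1, 1))
    }
    bt <- spec$body_valgus_deg - spec$tibia_tilt_deg
    dt <- spec$body_valgus_deg + spec$tuberosity_valgus_deg -
      spec$tibia_tilt_deg
    truth <- c(
      A = bt,
      B1 = atan2(spec$talus_offset[1], spec$talus_offset[2]) * 180 / pi -
        spec$tibia_tilt_deg,
      B2 = atan2(spec$facet_offset[1], spec$facet_offset[2]) * 180 / pi -
        spec$tibia_tilt_deg,
      C = bt, D10 = dt, D15 = dt, D20 = dt, E = dt)
    structure(list(meshes = meshes, landmarks = landmarks, truth = truth,
                   spec = spec),
              class = "phantom_set")
  })
}

#' @export
print.phantom_set <- function(x, ...) {
  cat(sprintf("<phantom_set (%s): body %g, tuberosity %g, tibia %g deg>\n",
              x$spec$side, x$spec$body_valgus_deg,
              x$spec$tuberosity_valgus_deg, x$spec$tibia_tilt_deg))
  print(round(x$truth, 2))
  invisible(x)
}

#' Write a phantom to disk
#'
#' One binary STL per mesh plus `landmarks.json` and `truth.json`.
#'
#' @param phantom a `phantom_set`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_phantom <- function(phantom, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(phantom$meshes))
    write_stl(phantom$meshes[[nm]], file.path(dir, paste0(nm, ".stl")))
  write_landmarks(phantom$landmarks, file.path(dir, "landmarks.json"))
  jsonlite::write_json(as.list(phantom$truth), file.path(dir, "truth.json"),
                       digits = NA, auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Run the full measurement pipeline on a phantom
#'
#' @param phantom a `phantom_set`.
#' @param max_edge quadrature edge length, mm.
#' @return an `haa_results` list (see [compute_all()]).
#' @export
measure_phantom <- function(phantom, max_edge = 1.0) {
  compute_all(phantom$meshes, phantom$landmarks, side = phantom$spec$side,
              max_edge = max_edge)
}

# --- cohort simulation ------------------------------------------------------

#' Default per-technique cohort moments
#'
#' Pre/post means and standard deviations (degrees) representative of a
#' severe adult flatfoot cohort measured before and after subtalar
#' arthrodesis, for the eight mesh-based techniques plus the two external
#' goniometer measures (CLINICAL on the patient, RENDER on a posterior view
#' of the CT rendering), which this package accepts as plain data columns.
#'
#' @return data frame with columns `technique`, `pre_mean`, `pre_std`,
#'   `post_mean`, `post_std`.
#' @export
default_cohort_params <- function() {
  data.frame(
    technique = c("A", "B1", "B2", "C", "D10", "D15", "D20", "E",
                  "CLINICAL", "RENDER"),
    pre_mean = c(51.19, 27.49, 43.58, 37.94, 16.49, 10.06, 9.92, 10.26,
                 14.40, 18.70),
    pre_std = c(10.27, 10.09, 10.10, 5.73, 12.81, 4.86, 5.63, 6.74,
                4.25, 5.74),
    post_mean = c(38.32, 11.53, 22.10, 26.38, 24.40, 10.21, 7.42, 8.64,
                  5.20, 9.08),
    post_std = c(10.42, 8.90, 11.15, 8.99, 13.92, 4.93, 3.03, 6.13,
                 2.53, 4.85),
    stringsAsFactors = FALSE)
}

#' Simulate a pre/post cohort of HAA measurements
#'
#' Per subject and technique, `(pre, post)` is drawn from a bivariate normal
#' with the stated marginal moments and correlation `rho`. The paired-test
#' power of the simulated cohort depends on `rho`, so it is an explicit
#' parameter (default 0.7) rather than a hidden choice.
#'
#' @param n_subjects number of subjects (>= 2).
#' @param params data frame as [default_cohort_params()].
#' @param rho pre/post correlation in `[-1, 1]`.
#' @param seed integer seed; identical seeds give identical tables.
#' @return long data frame (`cohort_table`): `subject_id`, `session`
#'   (`"pre"`/`"post"`), `technique`, `angle_deg`.
#' @export
simulate_cohort <- function(n_subjects = 10, params = default_cohort_params(),
                            rho = 0.7, seed = 1L) {
  if (n_subjects < 2) stop("n_subjects must be >= 2")
  if (!is.numeric(rho) || rho < -1 || rho > 1) stop("rho must be in [-1, 1]")
  if (any(params$pre_std < 0) || any(params$post_std < 0))
    stop("standard deviations must be >= 0")
  with_seed(seed, {
    rows <- lapply(seq_len(nrow(params)), function(i) {
      z1 <- stats::rnorm(n_subjects)
      z2 <- stats::rnorm(n_subjects)
      pre <- params$pre_mean[i] + params$pre_std[i] * z1
      post <- params$post_mean[i] +
        params$post_std[i] * (rho * z1 + sqrt(1 - rho^2) * z2)
      data.frame(subject_id = rep(sprintf("S%02d", seq_len(n_subjects)), 2L),
                 session = rep(c("pre", "post"), each = n_subjects),
                 technique = params$technique[i],
                 angle_deg = c(pre, post), stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    class(out) <- c("cohort_table", "data.frame")
    out
  })
}
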