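#' @title HAA measurement techniques
#' @description
#' Six techniques mapping realigned hindfoot bone meshes (plus landmarks) to
#' one signed hindfoot alignment angle each, all sharing the same frontal
#' projection and sign convention (valgus positive). The tibial reference is
#' always the projected diaphyseal axis from [tibia_vertical_axis()], so the
#' techniques differ only in how the hindfoot vertical axis is constructed:
#'
#' * **A** - vertical axis of the whole-calcaneus surface PCA frame.
#' * **B1** - line from the most plantar point of the calcaneus to the talus
#'   volume centroid.
#' * **B2** - as B1 with the centre of the talar middle facet (the subtalar
#'   joint centre) replacing the centroid; the point comes from a landmark.
#' * **C** - bisector of the medial and lateral contour segments of the
#'   frontal silhouette of the calcaneus.
#' * **D10/D15/D20** - vertical PCA axis of the posterior 10/15/20% of the
#'   calcaneus, clipped by a box orthogonal to its longitudinal axis.
#' * **E** - as D with the box width set by the most plantar point.
#' @name haa-techniques
NULL

haa_result <- function(technique, angle_deg, tibia_2d, hindfoot_2d,
                       provenance = list()) {
  structure(list(technique = technique, angle_deg = angle_deg,
                 tibia_axis_2d = tibia_2d, hindfoot_axis_2d = hindfoot_2d,
                 provenance = provenance),
            class = "haa_result")
}

#' @export
print.haa_result <- function(x, ...) {
  cat(sprintf("<HAA %s: %+.2f deg (%s)>\n", x$technique, x$angle_deg,
              if (x$angle_deg >= 0) "valgus" else "varus"))
  invisible(x)
}

finish_result <- function(technique, hind_axis_3d, tibia_axis, frame,
                          provenance = list()) {
  t2 <- project_frontal(tibia_axis, frame)
  h2 <- project_frontal(hind_axis_3d, frame)
  haa_result(technique, signed_haa(t2, h2), t2, h2,
             c(provenance, list(hindfoot_axis_3d = as.numeric(hind_axis_3d))))
}

#' Technique A: whole-calcaneus PCA vertical axis
#'
#' @param calcaneus calcaneus [tri_mesh()] (realigned, i.e. measured within
#'   `frame`).
#' @param tibia_axis tibial vertical axis from [tibia_vertical_axis()].
#' @param frame a `foot_frame`.
#' @param max_edge quadrature edge length, mm.
#' @param samples optional precomputed [surface_quadrature()] of the
#'   calcaneus (shared by [compute_all()]).
#' @return an `haa_result`.
#' @export
technique_A <- function(calcaneus, tibia_axis, frame, max_edge = 1.0,
                        samples = NULL) {
  if (is.null(samples)) samples <- surface_quadrature(calcaneus, max_edge)
  pf <- pca_frame(samples, frame)
  finish_result("A", pca_axis(pf, "vertical"), tibia_axis, frame,
                list(calc_pca_variances = pf$variances))
}

#' Technique B1: calcaneal plantar point to talus centroid
#'
#' @inheritParams technique_A
#' @param talus watertight talus [tri_mesh()].
#' @return an `haa_result`.
#' @export
technique_B1 <- function(calcaneus, talus, tibia_axis, frame) {
  plantar <- extreme_point(calcaneus, -frame$dorsal_axis)
  cent <- volume_centroid(talus)
  finish_result("B1", as.numeric(cent) - as.numeric(plantar), tibia_axis, frame,
                list(plantar_point = as.numeric(plantar),
                     talus_centroid = as.numeric(cent)))
}

#' Technique B2: calcaneal plantar point to subtalar joint centre
#'
#' The centre of the talar middle facet stands in for the subtalar joint
#' centre; it must be supplied via the landmark file
#' (`"talus_middle_facet_center"`) or phantom ground truth.
#'
#' @inheritParams technique_A
#' @param middle_facet_center length-3 point.
#' @return an `haa_result`.
#' @export
technique_B2 <- function(calcaneus, middle_facet_center, tibia_axis, frame) {
  if (is.null(middle_facet_center))
    stop("landmark required: talus_middle_facet_center")
  plantar <- extreme_point(calcaneus, -frame$dorsal_axis)
  finish_result("B2", as.numeric(middle_facet_center) - as.numeric(plantar),
                tibia_axis, frame,
                list(plantar_point = as.numeric(plantar),
                     middle_facet_center = as.numeric(middle_facet_center)))
}

extreme_2d <- function(pts2, coord_sign, tol = 1e-6) {
  # most medial (coord_sign = +1) or lateral (-1) point with the same tie
  # rule as extreme_point: centroid of the tied set
  s <- coord_sign * pts2[, 1]
  m <- max(s)
  tied <- s >= m - tol
  colMeans(pts2[tied, , drop = FALSE])
}

#' Medial and lateral contour segments of the frontal calcaneal silhouette
#'
#' The surface point lattice (subdivided to `max_edge`, boundary points
#' included) is projected onto the frontal plane; the silhouette is split at
#' the mid-height of its dorsal extent, and in each half the most medial and
#' most lateral points are found (ties averaged as in [extreme_point()]).
#' Extremes are searched on the vertex lattice rather than on centroid
#' quadrature samples: centroids sit about `max_edge/3` inside face
#' boundaries, which biases a boundary-extreme method, while the lattice
#' contains the exact silhouette corners. The medial segment joins the
#' bottom-half and top-half most-medial points; the lateral segment
#' likewise. Segment directions are oriented dorsal-positive.
#'
#' @inheritParams technique_A
#' @return list with `medial` and `lateral` 2 x 2 matrices (rows: bottom,
#'   top point in (medial, dorsal) mm) and unit direction vectors
#'   `medial_dir`, `lateral_dir`.
#' @export
frontal_silhouette_contours <- function(calcaneus, frame, max_edge = 1.0,
                                        samples = NULL) {
  pts <- surface_lattice(calcaneus, max_edge)
  pts2 <- cbind(pts %*% frame$medial_axis, pts %*% frame$dorsal_axis)
  zr <- range(pts2[, 2])
  split <- mean(zr)
  bottom <- pts2[pts2[, 2] <= split, , drop = FALSE]
  top <- pts2[pts2[, 2] > split, , drop = FALSE]
  if (nrow(bottom) == 0L || nrow(top) == 0L)
    stop("contour error: empty silhouette half")
  seg <- function(sgn) {
    p <- rbind(extreme_2d(bottom, sgn), extreme_2d(top, sgn))
    d <- p[2, ] - p[1, ]
    d <- d / sqrt(sum(d^2))
    if (d[2] < 0) d <- -d
    list(points = p, dir = d)
  }
  med <- seg(1)
  lat <- seg(-1)
  list(medial = med$points, lateral = lat$points,
       medial_dir = med$dir, lateral_dir = lat$dir)
}

#' Technique C: bisector of the silhouette contour segments
#'
#' @inheritParams technique_A
#' @return an `haa_result`.
#' @export
technique_C <- function(calcaneus, tibia_axis, frame, max_edge = 1.0) {
  ct <- frontal_silhouette_contours(calcaneus, frame, max_edge)
  bis <- ct$medial_dir + ct$lateral_dir
  bis <- bis / sqrt(sum(bis^2))
  t2 <- project_frontal(tibia_axis, frame)
  haa_result("C", signed_haa(t2, bis), t2, bis,
             list(medial_segment = ct$medial, lateral_segment = ct$lateral))
}

#' Posterior clipping box of the calcaneus
#'
#' Defines the box, orthogonal to the whole-calcaneus longitudinal PCA axis,
#' that encapsulates the posterior part of the bone: either a stated fraction
#' of the bone length (techniques D10/D15/D20) or the width needed to reach
#' the most plantar point (technique E).
#'
#' @inheritParams technique_A
#' @param mode `"fraction"` or `"plantar"`.
#' @param fraction box width as a fraction of the calcaneal length along the
#'   longitudinal axis (fraction mode).
#' @return object of class `posterior_box`: `axis` (unit, anterior-positive),
#'   `posterior_limit` (axis coordinate of the most posterior sample),
#'   `width` (mm), `fraction`, `length` (total extent), and `vertical_axis`
#'   of the whole-calcaneus PCA frame.
#' @export
posterior_box <- function(calcaneus, frame, mode = c("fraction", "plantar"),
                          fraction = 0.20, max_edge = 1.0, samples = NULL) {
  mode <- match.arg(mode)
  if (mode == "fraction" && (fraction <= 0 || fraction > 1))
    stop("fraction must be in (0, 1]")
  if (is.null(samples)) samples <- surface_quadrature(calcaneus, max_edge)
  pf <- pca_frame(samples, frame)
  axis <- pca_axis(pf, "longitudinal")       # anterior-positive by labelling
  s <- as.numeric(samples$points %*% axis)
  post <- min(s)
  len <- max(s) - post
  if (mode == "fraction") {
    width <- fraction * len
  } else {
    plantar <- extreme_point(calcaneus, -frame$dorsal_axis)
    width <- sum(plantar * axis) - post
    if (width < 0.02 * len) {
      warning("plantar point at or behind the posterior extreme: box width clamped to 0.02 * length")
      width <- 0.02 * len
    }
    fraction <- width / len
  }
  structure(list(axis = as.numeric(axis), posterior_limit = post,
                 width = width, fraction = fraction, length = len,
                 vertical_axis = pca_axis(pf, "vertical")),
            class = "posterior_box")
}

slab_technique <- function(label, box, samples, tibia_axis, frame) {
  s <- as.numeric(samples$points %*% box$axis)
  keep <- s <= box$posterior_limit + box$width
  pts <- samples$points[keep, , drop = FALSE]
  w <- samples$weights[keep]
  if (nrow(pts) < 4L) stop("slab-rank error: too few samples in the posterior box")
  cv <- weighted_covariance(pts, w)
  ev <- eigen(cv, symmetric = TRUE)
  if (ev$values[3] < 1e-9 * max(ev$values[1], 1))
    stop("slab-rank error: posterior-box samples are (nearly) coplanar")
  # for a thin slab the variance ranking differs from the whole bone; take
  # the principal axis best aligned with the whole-calcaneus vertical axis
  cosines <- abs(as.numeric(t(ev$vectors) %*% box$vertical_axis))
  axis <- ev$vectors[, which.max(cosines)]
  if (sum(axis * frame$dorsal_axis) < 0) axis <- -axis
  finish_result(label, axis, tibia_axis, frame,
                list(box = unclass(box), n_samples_kept = sum(keep)))
}

#' Technique D: PCA of a posterior fraction of the calcaneus
#'
#' @inheritParams technique_A
#' @param fraction posterior box width as a fraction of the calcaneal length;
#'   the published variants use 0.10, 0.15 and 0.20 (labels D10/D15/D20);
#'   other values are labelled by their rounded percentage.
#' @return an `haa_result`.
#' @export
technique_D <- function(calcaneus, tibia_axis, frame, fraction = 0.20,
                        max_edge = 1.0, samples = NULL) {
  if (is.null(samples)) samples <- surface_quadrature(calcaneus, max_edge)
  box <- posterior_box(calcaneus, frame, "fraction", fraction,
                       max_edge, samples)
  slab_technique(sprintf("D%d", floor(100 * fraction)), box, samples,
                 tibia_axis, frame)
}

#' Technique E: PCA of the posterior part up to the plantar point
#'
#' @inheritParams technique_A
#' @return an `haa_result`.
#' @export
technique_E <- function(calcaneus, tibia_axis, frame, max_edge = 1.0,
                        samples = NULL) {
  if (is.null(samples)) samples <- surface_quadrature(calcaneus, max_edge)
  box <- posterior_box(calcaneus, frame, "plantar", max_edge = max_edge,
                       samples = samples)
  slab_technique("E", box, samples, tibia_axis, frame)
}

#' Run every applicable technique on one foot
#'
#' Computes results for A, B1, B2, C, D10, D15, D20 and E, in that fixed
#' order, deterministically. B1 is skipped with a warning when no talus mesh
#' is supplied, B2 when the `talus_middle_facet_center` landmark is missing.
#'
#' @param bones named list of [tri_mesh()]es; `tibia` and `calcaneus` are
#'   required, `talus`, `ground`, `metatarsal2` optional.
#' @param landmarks named list of length-3 points (see [read_landmarks()]).
#' @param frame a `foot_frame`; built from the inputs when `NULL`.
#' @param side foot side, used only when `frame` is `NULL`.
#' @param max_edge quadrature edge length, mm.
#' @return named list of `haa_result` objects (class `haa_results`).
#' @export
compute_all <- function(bones, landmarks = list(), frame = NULL,
                        side = c("right", "left"), max_edge = 1.0) {
  side <- match.arg(side)
  if (is.null(bones$tibia) || is.null(bones$calcaneus))
    stop("fatal input error: tibia and calcaneus meshes are required")
  if (is.null(frame)) {
    plane <- fit_ground_plane(bones$ground,
                              bones[intersect(names(bones),
                                              c("tibia", "calcaneus", "talus"))])
    met <- if (!is.null(bones$metatarsal2)) {
      as.numeric(extreme_point(bones$metatarsal2, -plane$normal))
    } else if (!is.null(landmarks$second_met_head_plantar)) {
      landmarks$second_met_head_plantar
    } else {
      stop("fatal input error: second metatarsal head required (mesh or landmark)")
    }
    frame <- build_foot_frame(bones$calcaneus, met, plane, side)
  }
  tib_axis <- tibia_vertical_axis(bones$tibia, frame, max_edge)
  calc_samples <- surface_quadrature(bones$calcaneus, max_edge)
  res <- list()
  res$A <- technique_A(bones$calcaneus, tib_axis, frame, samples = calc_samples)
  if (!is.null(bones$talus)) {
    res$B1 <- technique_B1(bones$calcaneus, bones$talus, tib_axis, frame)
  } else {
    warning("technique B1 skipped: no talus mesh supplied")
  }
  if (!is.null(landmarks$talus_middle_facet_center)) {
    res$B2 <- technique_B2(bones$calcaneus, landmarks$talus_middle_facet_center,
                           tib_axis, frame)
  } else {
    warning("technique B2 skipped: landmark talus_middle_facet_center missing")
  }
  res$C <- technique_C(bones$calcaneus, tib_axis, frame, max_edge)
  for (f in c(0.10, 0.15, 0.20)) {
    r <- technique_D(bones$calcaneus, tib_axis, frame, fraction = f,
                     samples = calc_samples)
    res[[r$technique]] <- r
  }
  res$E <- technique_E(bones$calcaneus, tib_axis, frame, samples = calc_samples)
  structure(res, class = "haa_results", frame = frame, tibia_axis = tib_axis)
}

#' @export
print.haa_results <- function(x, ...) {
  cat("<haa_results>\n")
  for (r in x) cat(sprintf("  %-4s %+7.2f deg\n", r$technique, r$angle_deg))
  invisible(x)
}

#' Convert technique results to a one-row data frame
#'
#' @param results an `haa_results` list from [compute_all()].
#' @param subject_id,session,side metadata columns.
#' @return data frame with one column per technique (degrees, valgus
#'   positive).
#' @export
results_to_df <- function(results, subject_id = "subject", session = "pre",
                          side = "right") {
  angles <- vapply(results, function(r) r$angle_deg, numeric(1))
  df <- data.frame(subject_id = subject_id, session = session, side = side,
                   stringsAsFactors = FALSE)
  for (i in seq_along(angles)) df[[names(angles)[i]]] <- angles[[i]]
  df
}

#' Write technique results as CSV and JSON
#'
#' The CSV has one row (angles at 2 decimals); the JSON carries full
#' precision plus the projected axes. Both are byte-deterministic for
#' identical inputs.
#'
#' @inheritParams results_to_df
#' @param csv_path,json_path output paths (`NULL` to skip one of them).
#' @return invisibly, the one-row data frame.
#' @export
write_results <- function(results, csv_path = NULL, json_path = NULL,
                          subject_id = "subject", session = "pre",
                          side = "right") {
  df <- results_to_df(results, subject_id, session, side)
  if (!is.null(csv_path)) {
    angles <- vapply(results, function(r) r$angle_deg, numeric(1))
    hdr <- paste(c("subject_id", "session", "side", names(angles)),
                 collapse = ",")
    row <- paste(c(subject_id, session, side, sprintf("%.2f", angles)),
                 collapse = ",")
    writeLines(c(hdr, row), csv_path)
  }
  if (!is.null(json_path)) {
    payload <- lapply(results, function(r)
      list(technique = r$technique, angle_deg = r$angle_deg,
           tibia_axis_2d = r$tibia_axis_2d,
           hindfoot_axis_2d = r$hindfoot_axis_2d))
    jsonlite::write_json(list(subject_id = subject_id, session = session,
                              side = side, results = payload),
                         json_path, digits = NA, auto_unbox = TRUE,
                         pretty = TRUE)
  }
  invisible(df)
}
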