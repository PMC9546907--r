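#' Fit the ground plane under the foot
#'
#' Least-squares plane through the ground-mesh vertices (smallest-variance
#' principal direction), with the normal oriented upward, i.e. toward the
#' bone centroids when bones are supplied, else toward +z.
#'
#' @param ground a [tri_mesh()] of the segmented ground, or `NULL` for the
#'   default plane z = 0.
#' @param bones optional list of bone [tri_mesh()]es used to orient the
#'   normal.
#' @return list with `point` (on the plane) and `normal` (unit, upward);
#'   class `ground_plane`.
#' @export
fit_ground_plane <- function(ground = NULL, bones = NULL) {
  if (is.null(ground))
    return(structure(list(point = c(0, 0, 0), normal = c(0, 0, 1)),
                     class = "ground_plane"))
  V <- ground$vertices
  cv <- weighted_covariance(V)
  ev <- eigen(cv, symmetric = TRUE)
  if (ev$values[2] < 1e-9)
    stop("ground vertices are collinear: cannot fit a plane")
  normal <- ev$vectors[, 3]
  up <- c(0, 0, 1)
  if (!is.null(bones) && length(bones)) {
    bc <- colMeans(do.call(rbind, lapply(bones, function(m) colMeans(m$vertices))))
    up <- bc - attr(cv, "centroid")
  }
  if (sum(normal * up) < 0) normal <- -normal
  structure(list(point = as.numeric(attr(cv, "centroid")),
                 normal = as.numeric(normal)),
            class = "ground_plane")
}

#' Default ground plane z = 0
#' @return a `ground_plane` with point (0,0,0) and normal (0,0,1).
#' @export
default_ground_plane <- function() fit_ground_plane(NULL)

project_on_plane <- function(p, plane) {
  p - sum((p - plane$point) * plane$normal) * plane$normal
}

#' Build the whole-foot anatomical frame (FootAF)
#'
#' Dorsal axis = upward ground normal; anterior axis = unit vector on the
#' ground from the projected most-plantar point of the calcaneus to the
#' projected second-metatarsal-head point; medial axis completes the triad.
#' For a left foot the medial axis is negated so that valgus is positive on
#' both sides; the left-foot triad (anterior, medial, dorsal) is therefore
#' left-handed by construction.
#'
#' @param calcaneus calcaneus [tri_mesh()].
#' @param second_met_head length-3 point: most plantar point of the second
#'   metatarsal head (from a landmark file or a metatarsal mesh).
#' @param ground a `ground_plane` (default z = 0).
#' @param side `"right"` or `"left"`.
#' @return object of class `foot_frame`: list with `origin`,
#'   `anterior_axis`, `medial_axis`, `dorsal_axis`, `side`.
#' @export
build_foot_frame <- function(calcaneus, second_met_head,
                             ground = default_ground_plane(),
                             side = c("right", "left")) {
  side <- match.arg(side)
  dorsal <- ground$normal / sqrt(sum(ground$normal^2))
  plantar <- extreme_point(calcaneus, -dorsal)
  origin <- project_on_plane(as.numeric(plantar), ground)
  met <- project_on_plane(as.numeric(second_met_head), ground)
  ap <- met - origin
  if (sqrt(sum(ap^2)) < 10)
    stop("degenerate foot frame: projected calcaneus and metatarsal points are closer than 10 mm")
  anterior <- ap / sqrt(sum(ap^2))
  medial <- c(dorsal[2] * anterior[3] - dorsal[3] * anterior[2],
              dorsal[3] * anterior[1] - dorsal[1] * anterior[3],
              dorsal[1] * anterior[2] - dorsal[2] * anterior[1])
  if (side == "left") medial <- -medial
  structure(list(origin = origin, anterior_axis = anterior,
                 medial_axis = medial, dorsal_axis = dorsal, side = side),
            class = "foot_frame")
}

#' @export
print.foot_frame <- function(x, ...) {
  cat(sprintf("<foot_frame (%s): origin (%.2f, %.2f, %.2f)>\n", x$side,
              x$origin[1], x$origin[2], x$origin[3]))
  cat(sprintf("  anterior (%.4f, %.4f, %.4f)\n", x$anterior_axis[1],
              x$anterior_axis[2], x$anterior_axis[3]))
  cat(sprintf("  medial   (%.4f, %.4f, %.4f)\n", x$medial_axis[1],
              x$medial_axis[2], x$medial_axis[3]))
  cat(sprintf("  dorsal   (%.4f, %.4f, %.4f)\n", x$dorsal_axis[1],
              x$dorsal_axis[2], x$dorsal_axis[3]))
  invisible(x)
}

#' Export a foot frame (or any axes list) as JSON
#' @param frame a `foot_frame`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_frame_json <- function(frame, path) {
  jsonlite::write_json(lapply(unclass(frame), function(v) v), path,
                       digits = NA, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Anatomically labelled principal-component frame of a bone surface
#'
#' Eigen-decomposition of the area-weighted covariance of surface samples
#' about their weighted centroid. Principal axes are labelled greedily
#' (largest variance first) by the FootAF axis with which each has the
#' largest absolute cosine: anterior -> "longitudinal", dorsal -> "vertical",
#' medial -> "transverse"; each axis is then sign-flipped to point along its
#' matched anatomical direction. For a typical long bone surface the
#' longitudinal axis carries the largest variance and the vertical the second
#' largest; a warning is emitted when the alignment-based labels disagree
#' with that ordering, since the labels (not the rank) are authoritative.
#'
#' @param samples a [surface_quadrature()] result.
#' @param reference a `foot_frame`.
#' @return object of class `pca_frame`: `centroid`, `axes` (3 x 3, columns in
#'   descending variance order), `variances`, `labels`.
#' @export
pca_frame <- function(samples, reference) {
  cv <- weighted_covariance(samples$points, samples$weights)
  ev <- eigen(cv, symmetric = TRUE)
  if (ev$values[3] < 1e-9 * max(ev$values[1], 1))
    stop("rank error: surface samples are (nearly) coplanar")
  ref_axes <- cbind(longitudinal = reference$anterior_axis,
                    vertical = reference$dorsal_axis,
                    transverse = reference$medial_axis)
  labels <- character(3)
  taken <- logical(3)
  for (k in 1:3) {
    cosines <- abs(as.numeric(t(ref_axes) %*% ev$vectors[, k]))
    cosines[taken] <- -Inf
    pick <- which.max(cosines)
    labels[k] <- colnames(ref_axes)[pick]
    taken[pick] <- TRUE
    if (sum(ev$vectors[, k] * ref_axes[, pick]) < 0)
      ev$vectors[, k] <- -ev$vectors[, k]
  }
  if (!identical(labels[1:2], c("longitudinal", "vertical")))
    warning(sprintf(
      "variance ordering (%s) differs from the expected longitudinal > vertical > transverse",
      paste(labels, collapse = " > ")))
  structure(list(centroid = as.numeric(attr(cv, "centroid")),
                 axes = ev$vectors, variances = ev$values, labels = labels),
            class = "pca_frame")
}

#' Extract a labelled axis from a `pca_frame`
#' @param frame a `pca_frame`.
#' @param label `"longitudinal"`, `"vertical"` or `"transverse"`.
#' @return unit length-3 vector.
#' @export
pca_axis <- function(frame, label) {
  i <- match(label, frame$labels)
  if (is.na(i)) stop("no axis labelled ", label)
  frame$axes[, i]
}

#' Project a 3D axis onto the frontal plane of the FootAF
#'
#' Returns the (medial, dorsal) components, normalized, with the dorsal
#' component made positive first: anatomical axes are undirected lines and
#' eigenvectors carry arbitrary sign.
#'
#' @param v length-3 vector.
#' @param frame a `foot_frame`.
#' @return unit length-2 vector `(medial, dorsal)`.
#' @export
project_frontal <- function(v, frame) {
  p <- c(sum(v * frame$medial_axis), sum(v * frame$dorsal_axis))
  n <- sqrt(sum(p^2))
  if (n < 1e-9)
    stop("projection error: axis is (nearly) parallel to the anterior axis")
  p <- p / n
  if (p[2] < 0) p <- -p
  p
}

#' Signed hindfoot alignment angle between two frontal-plane axes
#'
#' Both inputs must be unit 2-vectors in (medial, dorsal) coordinates with
#' positive dorsal component. The sign convention is valgus positive: the
#' angle is positive when the hindfoot axis' dorsal tip is rotated toward
#' medial relative to the tibial axis (heel tilted laterally), on either
#' side once the frame's side normalization has been applied.
#'
#' @param tibia_2d,hindfoot_2d unit length-2 vectors from
#'   [project_frontal()].
#' @return signed angle in degrees.
#' @export
signed_haa <- function(tibia_2d, hindfoot_2d) {
  cross <- hindfoot_2d[1] * tibia_2d[2] - hindfoot_2d[2] * tibia_2d[1]
  dot <- sum(tibia_2d * hindfoot_2d)
  atan2(cross, dot) * 180 / pi
}

#' Longitudinal (vertical) axis of the distal tibial diaphysis
#'
#' The largest-variance principal axis of the area-weighted tibial surface
#' samples: a diaphyseal tube's long axis. Oriented with positive dot product
#' toward dorsal. A warning is emitted when the segment is stubby
#' (longitudinal extent < 2 x transverse extent) since the axis is then
#' unreliable.
#'
#' @param tibia tibia [tri_mesh()].
#' @param frame a `foot_frame`.
#' @param max_edge quadrature edge length, mm.
#' @return unit length-3 vector.
#' @export
tibia_vertical_axis <- function(tibia, frame, max_edge = 1.0) {
  s <- surface_quadrature(tibia, max_edge)
  cv <- weighted_covariance(s$points, s$weights)
  ev <- eigen(cv, symmetric = TRUE)
  if (ev$values[3] < 1e-9 * max(ev$values[1], 1))
    stop("rank error: tibial surface samples are (nearly) coplanar")
  axis <- ev$vectors[, 1]
  ext <- apply(s$points %*% ev$vectors, 2, function(x) diff(range(x)))
  if (ext[1] < 2 * max(ext[2:3]))
    warning("tibial segment is short relative to its width: longitudinal axis may be unreliable")
  if (sum(axis * frame$dorsal_axis) < 0) axis <- -axis
  as.numeric(axis)
}
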