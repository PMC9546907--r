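#' Triangulated bone surface mesh
#'
#' Lightweight container for a closed triangulated surface, coordinates in
#' millimetres. Construction validates the basic invariants: finite
#' coordinates, in-range face indices, and no degenerate (near-zero-area)
#' faces. Watertightness is *not* assumed here; operations that need an
#' enclosed volume check it themselves (see [volume_centroid()]).
#'
#' @param vertices numeric matrix, n x 3, vertex coordinates in mm.
#' @param faces integer matrix, m x 3, 1-based vertex indices per triangle.
#' @param name bone label, one of `"tibia"`, `"calcaneus"`, `"talus"`,
#'   `"ground"`, `"metatarsal2"` or `"other"`.
#' @return An object of class `trimesh`: a list with elements `vertices`,
#'   `faces` and `name`.
#' @seealso [read_stl()], [clean_mesh()], [mesh_area()], [is_watertight()]
#' @export
tri_mesh <- function(vertices, faces, name = "other") {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stop("vertices must be an n x 3 matrix")
  if (ncol(faces) != 3L) stop("faces must be an m x 3 matrix")
  if (!all(is.finite(vertices))) stop("mesh vertices contain non-finite coordinates")
  if (nrow(faces) == 0L) stop("empty mesh: no faces")
  if (min(faces) < 1L || max(faces) > nrow(vertices))
    stop("face indices out of range")
  name <- match.arg(name, c("tibia", "calcaneus", "talus", "ground",
                            "metatarsal2", "other"))
  a <- face_areas(vertices, faces)
  keep <- a >= 1e-12
  if (!all(keep)) faces <- faces[keep, , drop = FALSE]
  if (nrow(faces) == 0L) stop("empty mesh: all faces degenerate")
  structure(list(vertices = vertices, faces = faces, name = name),
            class = "trimesh")
}

#' @export
print.trimesh <- function(x, ...) {
  bb <- apply(x$vertices, 2, range)
  cat(sprintf("<trimesh '%s': %d vertices, %d faces, area %.1f mm^2>\n",
              x$name, nrow(x$vertices), nrow(x$faces), mesh_area(x)))
  cat(sprintf("  bounding box [%.1f, %.1f] x [%.1f, %.1f] x [%.1f, %.1f] mm\n",
              bb[1, 1], bb[2, 1], bb[1, 2], bb[2, 2], bb[1, 3], bb[2, 3]))
  invisible(x)
}

face_areas <- function(vertices, faces) {
  v1 <- vertices[faces[, 1], , drop = FALSE]
  e1 <- vertices[faces[, 2], , drop = FALSE] - v1
  e2 <- vertices[faces[, 3], , drop = FALSE] - v1
  cx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  cy <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  cz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

#' Total surface area of a mesh
#' @param mesh a [tri_mesh()].
#' @return area in mm^2.
#' @export
mesh_area <- function(mesh) sum(face_areas(mesh$vertices, mesh$faces))

#' Merge duplicate vertices and drop degenerate faces
#'
#' Vertices closer than `tol` (snapped to a grid of spacing `tol`) are merged;
#' faces that collapse (repeated indices or area below 1e-12 mm^2) are
#' dropped. A short report of merges and drops is emitted as a message.
#'
#' @param vertices,faces,name as in [tri_mesh()].
#' @param tol merge tolerance in mm (default 1e-6).
#' @param quiet suppress the merge/drop report.
#' @return a validated [tri_mesh()].
#' @export
clean_mesh <- function(vertices, faces, name = "other", tol = 1e-6,
                       quiet = FALSE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  if (nrow(faces) == 0L) stop("empty mesh: no faces")
  key <- paste(round(vertices[, 1] / tol), round(vertices[, 2] / tol),
               round(vertices[, 3] / tol))
  first <- !duplicated(key)
  map <- match(key, key[first])
  n_merged <- nrow(vertices) - sum(first)
  vertices <- vertices[first, , drop = FALSE]
  faces <- matrix(map[faces], ncol = 3L)
  collapsed <- faces[, 1] == faces[, 2] | faces[, 2] == faces[, 3] |
    faces[, 1] == faces[, 3]
  faces <- faces[!collapsed, , drop = FALSE]
  if (nrow(faces) == 0L) stop("empty mesh: all faces degenerate after cleaning")
  a <- face_areas(vertices, faces)
  small <- a < 1e-12
  n_dropped <- sum(collapsed) + sum(small)
  faces <- faces[!small, , drop = FALSE]
  if (nrow(faces) == 0L) stop("empty mesh: all faces degenerate after cleaning")
  if (!quiet && (n_merged > 0L || n_dropped > 0L))
    message(sprintf("clean_mesh: merged %d duplicate vertices, dropped %d degenerate faces",
                    n_merged, n_dropped))
  tri_mesh(vertices, faces, name)
}

#' Read an STL file (ASCII or binary)
#'
#' Auto-detects the dialect. Coordinates are assumed to be in millimetres
#' (STL carries no unit); the bounding box is reported so gross unit errors
#' are visible (an adult foot spans roughly 100-350 mm). Duplicate vertices
#' within 1e-6 mm are merged and degenerate faces dropped.
#'
#' @param path STL file path.
#' @param name bone label passed to [tri_mesh()].
#' @param quiet suppress the cleaning/bounding-box report.
#' @return a [tri_mesh()].
#' @export
read_stl <- function(path, name = "other", quiet = TRUE) {
  if (!file.exists(path)) stop("STL file not found: ", path)
  sz <- file.info(path)$size
  if (is.na(sz) || sz < 15) stop("unreadable or truncated STL file: ", path)
  head_raw <- readBin(path, "raw", n = min(sz, 512))
  head_txt <- suppressWarnings(rawToChar(head_raw[head_raw != as.raw(0)]))
  is_ascii <- identical(substr(head_txt, 1, 5), "solid") &&
    grepl("facet|endsolid", head_txt)
  tri <- if (is_ascii) read_stl_ascii(path) else read_stl_binary(path, sz)
  nt <- nrow(tri) / 3L
  if (nt < 1L) stop("empty mesh: STL file ", path, " contains no facets")
  faces <- matrix(seq_len(3L * nt), ncol = 3L, byrow = TRUE)
  mesh <- clean_mesh(tri, faces, name = name, quiet = quiet)
  if (!quiet) {
    bb <- apply(mesh$vertices, 2, range)
    message(sprintf("read_stl: '%s' bounding box %.1f x %.1f x %.1f mm",
                    path, diff(bb[, 1]), diff(bb[, 2]), diff(bb[, 3])))
  }
  mesh
}

read_stl_ascii <- function(path) {
  toks <- scan(path, what = character(), quiet = TRUE)
  iv <- which(toks == "vertex")
  if (length(iv) == 0L) stop("empty mesh: STL file ", path, " contains no facets")
  if (length(iv) %% 3L != 0L) stop("unreadable or truncated ASCII STL: ", path)
  xyz <- suppressWarnings(as.numeric(toks[rep(iv, each = 3L) + 1:3]))
  if (anyNA(xyz)) stop("unreadable or truncated ASCII STL: ", path)
  matrix(xyz, ncol = 3L, byrow = TRUE)
}

read_stl_binary <- function(path, sz) {
  if (sz < 84) stop("unreadable or truncated binary STL: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", n = 80L)
  nt <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
  if (length(nt) != 1L || is.na(nt) || nt < 0L || sz != 84 + 50 * as.double(nt))
    stop("unreadable or truncated binary STL: ", path)
  if (nt == 0L) stop("empty mesh: STL file ", path, " contains no facets")
  rec <- readBin(con, "raw", n = 50L * nt)
  rec <- matrix(rec, nrow = 50L)
  coords <- readBin(as.vector(rec[1:48, ]), "numeric", n = 12L * nt, size = 4L,
                    endian = "little")
  coords <- matrix(coords, ncol = 12L, byrow = TRUE) # nx ny nz v1 v2 v3
  rbind_verts <- matrix(t(coords[, 4:12, drop = FALSE]), ncol = 3L, byrow = TRUE)
  rbind_verts
}

#' Write a mesh to an STL file
#'
#' @param mesh a [tri_mesh()].
#' @param path output path.
#' @param ascii write the ASCII dialect instead of binary (default binary).
#'   Binary output is byte-deterministic for identical input.
#' @return `path`, invisibly.
#' @export
write_stl <- function(mesh, path, ascii = FALSE) {
  v1 <- mesh$vertices[mesh$faces[, 1], , drop = FALSE]
  v2 <- mesh$vertices[mesh$faces[, 2], , drop = FALSE]
  v3 <- mesh$vertices[mesh$faces[, 3], , drop = FALSE]
  e1 <- v2 - v1; e2 <- v3 - v1
  nrm <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
               e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
               e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  len <- sqrt(rowSums(nrm^2))
  len[len == 0] <- 1
  nrm <- nrm / len
  nt <- nrow(mesh$faces)
  if (ascii) {
    lines <- character(nt * 7L + 2L)
    lines[1] <- sprintf("solid %s", mesh$name)
    body <- sprintf(
      "  facet normal %.9g %.9g %.9g\n    outer loop\n      vertex %.9g %.9g %.9g\n      vertex %.9g %.9g %.9g\n      vertex %.9g %.9g %.9g\n    endloop\n  endfacet",
      nrm[, 1], nrm[, 2], nrm[, 3],
      v1[, 1], v1[, 2], v1[, 3], v2[, 1], v2[, 2], v2[, 3],
      v3[, 1], v3[, 2], v3[, 3])
    writeLines(c(sprintf("solid %s", mesh$name), body,
                 sprintf("endsolid %s", mesh$name)),
               path)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    hdr <- charToRaw(sprintf("%-80s", paste("haa3d binary STL", mesh$name)))[1:80]
    writeBin(hdr, con)
    writeBin(as.integer(nt), con, size = 4L, endian = "little")
    block <- t(cbind(nrm, v1, v2, v3)) # 12 floats per facet
    flo <- writeBin(as.vector(block), raw(), size = 4L, endian = "little")
    flo <- matrix(flo, nrow = 48L)
    rec <- rbind(flo, matrix(as.raw(0L), nrow = 2L, ncol = nt))
    writeBin(as.vector(rec), con)
  }
  invisible(path)
}

#' Watertightness check
#'
#' A mesh is watertight when every undirected edge is shared by exactly two
#' faces.
#'
#' @param mesh a [tri_mesh()].
#' @return logical; attribute `"open_edges"` carries the number of edges not
#'   shared by exactly two faces.
#' @export
is_watertight <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  cnt <- table(key)
  open <- sum(cnt != 2L)
  structure(open == 0L, open_edges = open)
}

#' Read a landmark file
#'
#' JSON object mapping landmark name to `[x, y, z]` (mm), in the same
#' coordinate space as the meshes. Recognized names are
#' `"second_met_head_plantar"` and `"talus_middle_facet_center"`; unknown
#' names are kept with a warning.
#'
#' @param path JSON file path.
#' @return named list of numeric length-3 vectors.
#' @export
read_landmarks <- function(path) {
  if (!file.exists(path)) stop("landmark file not found: ", path)
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (!is.list(raw) || is.null(names(raw))) stop("landmark file must be a JSON object")
  out <- lapply(raw, function(p) {
    p <- as.numeric(p)
    if (length(p) != 3L || !all(is.finite(p)))
      stop("each landmark must be a finite [x, y, z] triple")
    p
  })
  known <- c("second_met_head_plantar", "talus_middle_facet_center")
  unk <- setdiff(names(out), known)
  if (length(unk))
    warning("unrecognized landmark name(s): ", paste(unk, collapse = ", "))
  out
}

#' Write a landmark file
#' @param landmarks named list of numeric length-3 vectors.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(landmarks, path) {
  jsonlite::write_json(lapply(landmarks, as.numeric), path, digits = NA,
                       auto_unbox = FALSE, pretty = TRUE)
  invisible(path)
}
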