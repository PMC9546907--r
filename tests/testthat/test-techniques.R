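# trapezoid prism calcaneus: medial edge tilted `med_deg`, lateral edge
# tilted `lat_deg` (dorsal tip toward medial positive), height 45, medial +y
trapezoid_calc <- function(med_deg = 0, lat_deg = 0, h = 45, w2 = 15) {
  mt <- tan(med_deg * pi / 180)
  lt <- tan(lat_deg * pi / 180)
  poly <- rbind(c(-w2, 0), c(w2, 0), c(w2 + h * mt, h), c(-w2 + h * lt, h))
  prism_mesh(poly, 0, 60)
}

global_frame <- function(side = "right") {
  calc <- box_mesh_t(c(-20, -15, 0), c(60, 15, 45))
  build_foot_frame(calc, c(150, 0, 0), side = side)
}

test_that("technique A recovers the PCA vertical axis and is equivariant", {
  fr <- global_frame()
  tib <- c(0, 0, 1)
  calc <- box_mesh_t(c(0, -15, 0), c(80, 15, 45), "calcaneus")
  r0 <- technique_A(calc, tib, fr)
  expect_s3_class(r0, "haa_result")
  expect_equal(r0$angle_deg, 0, tolerance = 1e-6)

  rot <- apply_transform(calc, valgus_rotation(c(1, 0, 0), c(0, 0, 0), 12))
  r12 <- technique_A(rot, tib, fr)
  expect_equal(r12$angle_deg, 12, tolerance = 0.5)

  # brute-force PCA oracle on a dense uniform sampling of a tilted phantom
  ph <- generate_phantom(phantom_spec(body_valgus_deg = 15, seed = 4))
  frp <- attr(suppressWarnings(measure_phantom(ph)), "frame")
  got <- technique_A(ph$meshes$calcaneus, c(0, 0, 1), frp)
  pts <- sample_surface_uniform(ph$meshes$calcaneus, 4e5, seed = 104)
  ev <- eigen(cov(pts), symmetric = TRUE)
  vert <- ev$vectors[, which.max(abs(t(ev$vectors) %*% c(0, 0, 1)))]
  if (vert[3] < 0) vert <- -vert
  oracle <- signed_haa(c(0, 1), project_frontal(vert, frp))
  expect_lt(abs(got$angle_deg - oracle), 0.2)
})

test_that("techniques B1/B2 are exact trigonometry on the construction", {
  fr <- global_frame()
  tib <- c(0, 0, 1)
  calc <- box_mesh_t(c(0, -15, 0), c(80, 15, 45), "calcaneus")
  calc$vertices <- rbind(calc$vertices, c(25, 0, -2)) # unique plantar apex
  calc$faces <- rbind(calc$faces[-(1:2), ],
                      c(9, 3, 1), c(9, 4, 3), c(9, 2, 4), c(9, 1, 2))

  # talus centroid vertically above the plantar point -> 0 deg
  sphere_at <- function(center)
    apply_transform(box_mesh_t(center - 5, center + 5, "talus"),
                    rigid_transform())
  r0 <- technique_B1(calc, sphere_at(c(25, 0, 48)), tib, fr)
  expect_equal(r0$angle_deg, 0, tolerance = 1e-9)

  r_med <- technique_B1(calc, sphere_at(c(25, 10, 48)), tib, fr)
  expect_equal(r_med$angle_deg, deg(atan(10 / 50)), tolerance = 1e-9)
  expect_equal(r_med$angle_deg, 11.31, tolerance = 1e-2)

  r_lat <- technique_B1(calc, sphere_at(c(25, -10, 48)), tib, fr)
  expect_equal(r_lat$angle_deg, -r_med$angle_deg, tolerance = 1e-9)

  r_b2 <- technique_B2(calc, c(25, 15, 43), tib, fr)
  expect_equal(r_b2$angle_deg, deg(atan(15 / 45)), tolerance = 1e-9)
  expect_equal(r_b2$angle_deg, 18.43, tolerance = 1e-2)
  expect_error(technique_B2(calc, NULL, tib, fr),
               "talus_middle_facet_center")

  # phantom whose facet landmark is 8 mm medial of the talus centroid at the
  # same 50 mm height: B2 - B1 = arctan(18/50) - arctan(10/50)
  ph <- generate_phantom(phantom_spec(talus_offset = c(10, 50),
                                      facet_offset = c(18, 50)))
  a <- phantom_angles(ph)
  expect_equal(a[["B2"]] - a[["B1"]], deg(atan(18 / 50) - atan(10 / 50)),
               tolerance = 1e-6)
  expect_equal(a[["B2"]] - a[["B1"]], 8.489, tolerance = 1e-3)
})

test_that("silhouette contours and technique C match the trapezoid closed forms", {
  fr <- global_frame()
  tib <- c(0, 0, 1)

  # axis-aligned rectangle: both segments vertical at the side edges
  rect <- trapezoid_calc(0, 0)
  ct <- frontal_silhouette_contours(rect, fr)
  expect_equal(ct$medial_dir, c(0, 1), tolerance = 1e-9)
  expect_equal(ct$lateral_dir, c(0, 1), tolerance = 1e-9)
  expect_equal(ct$medial[, 1], c(15, 15), tolerance = 1e-9)
  expect_equal(ct$lateral[, 1], c(-15, -15), tolerance = 1e-9)
  expect_equal(technique_C(rect, tib, fr)$angle_deg, 0, tolerance = 1e-9)

  # parallelogram sheared 10 deg medial: both segments at 10 deg
  shear <- trapezoid_calc(10, 10)
  ct10 <- frontal_silhouette_contours(shear, fr)
  expect_equal(deg(atan2(ct10$medial_dir[1], ct10$medial_dir[2])), 10,
               tolerance = 0.5)
  expect_equal(deg(atan2(ct10$lateral_dir[1], ct10$lateral_dir[2])), 10,
               tolerance = 0.5)
  expect_equal(technique_C(shear, tib, fr)$angle_deg, 10, tolerance = 0.5)

  # trapezoid medial 20 / lateral 0: segments recover both tilts, bisector 10
  trap <- trapezoid_calc(20, 0)
  ctt <- frontal_silhouette_contours(trap, fr)
  expect_equal(deg(atan2(ctt$medial_dir[1], ctt$medial_dir[2])), 20,
               tolerance = 0.5)
  expect_equal(deg(atan2(ctt$lateral_dir[1], ctt$lateral_dir[2])), 0,
               tolerance = 0.5)
  expect_equal(technique_C(trap, tib, fr)$angle_deg, 10, tolerance = 0.5)

  # oracle: direct min/max scan over projected mesh vertices, per half
  pts2 <- cbind(trap$vertices %*% fr$medial_axis,
                trap$vertices %*% fr$dorsal_axis)
  split <- mean(range(pts2[, 2]))
  lo <- pts2[pts2[, 2] <= split, ]; hi <- pts2[pts2[, 2] > split, ]
  med_dir <- hi[which.max(hi[, 1]), ] - lo[which.max(lo[, 1]), ]
  expect_equal(deg(atan2(ctt$medial_dir[1], ctt$medial_dir[2])),
               deg(atan2(med_dir[1], med_dir[2])), tolerance = 0.5)

  # symmetric trapezoid: bisector vertical
  sym <- trapezoid_calc(15, -15)
  expect_equal(technique_C(sym, tib, fr)$angle_deg, 0, tolerance = 1e-6)
})

test_that("posterior_box widths, nesting and degenerate clamping", {
  fr <- global_frame()
  calc <- box_mesh_t(c(0, -15, 0), c(80, 15, 45), "calcaneus")
  s <- surface_quadrature(calc, 1.0)

  b10 <- posterior_box(calc, fr, "fraction", 0.10, samples = s)
  expect_equal(b10$width, 8, tolerance = 1e-9)
  expect_equal(b10$length, 80, tolerance = 1e-9)
  expect_equal(abs(b10$axis[1]), 1, tolerance = 1e-9)
  expect_gt(b10$axis[1], 0) # anterior-positive

  expect_error(posterior_box(calc, fr, "fraction", 0), "fraction")

  # plantar apex 25 mm anterior of the posterior face -> plantar width 25
  apex <- calc
  apex$vertices <- rbind(apex$vertices, c(25, 0, -2))
  apex$faces <- rbind(apex$faces[-(1:2), ],
                      c(9, 3, 1), c(9, 4, 3), c(9, 2, 4), c(9, 1, 2))
  bE <- posterior_box(apex, fr, "plantar", samples = surface_quadrature(apex, 1))
  expect_equal(bE$width, 25, tolerance = 0.05)

  # plantar point at the posterior extreme -> clamp with warning
  back <- calc
  back$vertices <- rbind(back$vertices, c(0, 0, -2))
  back$faces <- rbind(back$faces[-(1:2), ],
                      c(9, 3, 1), c(9, 4, 3), c(9, 2, 4), c(9, 1, 2))
  expect_warning(bB <- posterior_box(back, fr, "plantar",
                                     samples = surface_quadrature(back, 1)),
                 "clamped")
  expect_equal(bB$width, 0.02 * bB$length, tolerance = 1e-6)

  # f = 1 keeps every sample; nesting D10 subset D15 subset D20
  b100 <- posterior_box(calc, fr, "fraction", 1.0, samples = s)
  sc <- as.numeric(s$points %*% b100$axis)
  expect_true(all(sc <= b100$posterior_limit + b100$width + 1e-9))
  k10 <- sc <= b10$posterior_limit + b10$width
  b15 <- posterior_box(calc, fr, "fraction", 0.15, samples = s)
  k15 <- sc <= b15$posterior_limit + b15$width
  b20 <- posterior_box(calc, fr, "fraction", 0.20, samples = s)
  k20 <- sc <= b20$posterior_limit + b20$width
  expect_true(all(k10 <= k15) && all(k15 <= k20))
  # brute-force filter count equals the technique's retained count
  tibax <- c(0, 0, 1)
  rD <- technique_D(calc, tibax, fr, 0.10, samples = s)
  expect_identical(rD$provenance$n_samples_kept, sum(k10))
})

test_that("techniques D and E separate tuberosity from body inclination", {
  # tuberosity tilted +15, body upright: D* and E read the tuberosity,
  # A stays near the body orientation
  ph <- generate_phantom(phantom_spec(tuberosity_valgus_deg = 15))
  a <- phantom_angles(ph)
  for (t in c("D10", "D15", "D20", "E"))
    expect_equal(a[[t]], 15, tolerance = 1)
  expect_lt(abs(a[["A"]]), 5)
  expect_gt(a[["D20"]] - a[["A"]], 9)

  # upright phantom: E ~ 0
  expect_lt(abs(phantom_angles(generate_phantom(phantom_spec()))[["E"]]), 0.5)

  # D at the fraction implied by E's plantar-bounded width equals E
  fr <- attr(suppressWarnings(measure_phantom(ph)), "frame")
  tib <- attr(suppressWarnings(measure_phantom(ph)), "tibia_axis")
  s <- surface_quadrature(ph$meshes$calcaneus, 1.0)
  bE <- suppressWarnings(posterior_box(ph$meshes$calcaneus, fr, "plantar",
                                       samples = s))
  rE <- technique_E(ph$meshes$calcaneus, tib, fr, samples = s)
  rD <- technique_D(ph$meshes$calcaneus, tib, fr, fraction = bE$fraction,
                    samples = s)
  expect_equal(rE$angle_deg, rD$angle_deg, tolerance = 0.1)

  # oracle for the slab axis: eigen-decomposition of a dense uniform sampling
  # clipped by the same box
  pts <- sample_surface_uniform(ph$meshes$calcaneus, 1.2e6, seed = 7)
  b20 <- posterior_box(ph$meshes$calcaneus, fr, "fraction", 0.20, samples = s)
  keep <- as.numeric(pts %*% b20$axis) <= b20$posterior_limit + b20$width
  ev <- eigen(cov(pts[keep, ]), symmetric = TRUE)
  vert <- ev$vectors[, which.max(abs(t(ev$vectors) %*% b20$vertical_axis))]
  if (sum(vert * fr$dorsal_axis) < 0) vert <- -vert
  oracle <- signed_haa(project_frontal(tib, fr), project_frontal(vert, fr))
  r20 <- technique_D(ph$meshes$calcaneus, tib, fr, 0.20, samples = s)
  expect_lt(abs(r20$angle_deg - oracle), 0.3)
})

test_that("compute_all returns fixed-order results and handles missing inputs", {
  ph <- generate_phantom(phantom_spec(body_valgus_deg = 8, seed = 2))
  res <- suppressWarnings(compute_all(ph$meshes, ph$landmarks, side = "right"))
  expect_identical(names(res), c("A", "B1", "B2", "C", "D10", "D15", "D20", "E"))
  expect_length(res, 8L)
  df <- results_to_df(res, "p1", "pre", "right")
  expect_identical(names(df)[4:11], names(res))

  bones2 <- ph$meshes[c("tibia", "calcaneus", "ground", "metatarsal2")]
  expect_warning(expect_warning(
    res6 <- compute_all(bones2, list(), side = "right"),
    "B1 skipped"), "B2 skipped")
  expect_length(res6, 6L)

  expect_error(compute_all(ph$meshes["calcaneus"], ph$landmarks),
               "tibia and calcaneus")
  expect_error(compute_all(ph$meshes[c("tibia", "calcaneus")], list()),
               "second metatarsal head")

  # determinism: identical files from two runs
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  j1 <- withr::local_tempfile(fileext = ".json")
  j2 <- withr::local_tempfile(fileext = ".json")
  res_b <- suppressWarnings(compute_all(ph$meshes, ph$landmarks, side = "right"))
  write_results(res, f1, j1, "p1", "pre", "right")
  write_results(res_b, f2, j2, "p1", "pre", "right")
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(readLines(j1), readLines(j2))
})
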