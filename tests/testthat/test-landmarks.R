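test_that("footprint centers lie on their bone surfaces", {
  k <- default_knee()
  lms <- default_landmarks()
  expect_lt(point_mesh_distance(k$femur, lms$femoral_fp), 0.5)
  expect_lt(point_mesh_distance(k$tibia, lms$tibial_fp), 0.5)
})

test_that("the Blumensaat proxy matches the generator's notch roof", {
  k <- default_knee()
  lms <- default_landmarks()
  d <- lms$blumensaat_dir_2d
  expect_equal(sqrt(sum(d^2)), 1, tolerance = 1e-9)
  expect_gt(d[1], 0)  # oriented posterior -> anterior
  # the generator's roof is a plane of known sagittal slope
  slope <- kneedrill:::NOTCH_ROOF_SLOPE
  expect_equal(atan2(-d[2], d[1]), atan(slope), tolerance = 5 * pi / 180)
  # the apex height matches the analytic roof plane at the apex's AP station
  g <- kneedrill:::femur_geometry(k$params)
  z_pred <- g$z_roof - slope * lms$notch_apex[2]
  expect_lt(abs(lms$notch_apex[3] - z_pred), 1.5)
})

test_that("the proxy direction is insensitive to notch width", {
  base <- knee_params(voxel_pitch = 1.5)
  wide <- knee_params(voxel_pitch = 1.5,
                      notch_width = base$notch_width * 2)
  d1 <- knee_landmarks(generate_knee(base, 5))$blumensaat_dir_2d
  d2 <- knee_landmarks(generate_knee(wide, 5))$blumensaat_dir_2d
  ang <- acos(min(1, sum(d1 * d2))) * 180 / pi
  expect_lt(ang, 5)
})

test_that("quadrant-grid fractions 0 and 1 map exactly to the borders", {
  lms <- default_landmarks()
  g <- lms$grid
  expect_points_equal(grid_point2d(g, 0, 0), g$origin2d, 1e-12)
  expect_points_equal(grid_point2d(g, 1, 1),
                      g$origin2d + g$extent_along * g$e_along +
                        g$extent_perp * g$e_perp, 1e-12)
})

test_that("the femoral footprint sits on the medial-facing wall of the lateral condyle", {
  k <- default_knee()
  lms <- default_landmarks()
  fp <- lms$femoral_fp
  expect_gt(fp[1], 0)  # lateral side of a right knee
  cen <- kneedrill:::face_centroids(k$femur)
  nrm <- kneedrill:::face_normals(k$femur)
  nearest <- which.min(rowSums(sweep(cen, 2, fp)^2))
  expect_lt(nrm[nearest, 1], 0)  # wall faces point medially
})

test_that("the tibial footprint lands at the published plateau fractions", {
  k <- default_knee()
  lms <- default_landmarks()
  pfr <- lms$plateau_frame
  # default 51.5% from the medial border: slightly lateral of midline
  expect_gt(sum((lms$tibial_fp - pfr$origin) * pfr$u), 0)
  # symmetric fractions recover the outline center
  mid <- tibial_footprint_center(k$tibia, pfr, frac_ap = 0.5, frac_ml = 0.5)
  uv <- project_to_plane(rbind(mid), pfr)
  expect_lt(abs(uv[1]), 1)
  expect_lt(point_mesh_distance(k$tibia, mid), 0.5)
})

test_that("landmarks are equivariant under translation of the whole model", {
  k <- default_knee()
  shift <- c(13.5, -7.25, 4)
  k2 <- k
  k2$femur$vertices <- sweep(k$femur$vertices, 2, shift, "+")
  k2$tibia$vertices <- sweep(k$tibia$vertices, 2, shift, "+")
  lms <- default_landmarks()
  lms2 <- knee_landmarks(k2)
  expect_points_equal(lms2$femoral_fp, lms$femoral_fp + shift, 0.5)
  expect_points_equal(lms2$tibial_fp, lms$tibial_fp + shift, 0.5)
  expect_points_equal(lms2$medial_epicondyle, lms$medial_epicondyle + shift, 1e-6)
})

test_that("landmarks of a mirrored left knee mirror the right knee's", {
  p <- knee_params(voxel_pitch = 1.5)
  right <- generate_knee(p, seed = 3)
  left <- generate_knee(knee_params(voxel_pitch = 1.5, side = "left"), seed = 3)
  lr <- knee_landmarks(right)
  ll <- knee_landmarks(canonical_knee(left))
  expect_points_equal(ll$femoral_fp, lr$femoral_fp, 1e-6)
  expect_points_equal(ll$tibial_fp, lr$tibial_fp, 1e-6)
})

test_that("a femur without a notch is rejected", {
  sph <- sphere_mesh(20, 1)
  tea <- ray(c(0, 0, 0), c(1, 0, 0))
  expect_error(notch_reference_line(sph, tea), "no intercondylar notch")
})
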