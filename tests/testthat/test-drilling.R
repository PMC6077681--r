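posed_fixture <- function(flexion = 120) {
  fixture(sprintf("posed_%d", flexion), function()
    flex_knee(default_knee(), default_landmarks(), flexion))
}

mta_fixture <- function(flexion = 120) {
  fixture(sprintf("mta_%d", flexion), function()
    find_mta(posed_fixture(flexion), default_landmarks()$femoral_fp))
}

test_that("the portal line sits 10 mm above the posed plateau, parallel to ML", {
  posed <- posed_fixture(120)
  line <- portal_line(posed)
  pf <- posed$plateau_frame_posed
  for (s in c(-30, 0, 25, 60)) {
    P <- portal_point(line, s)
    expect_equal(sum((P - pf$origin) * pf$w), 10, tolerance = 1e-6)
  }
  dirv <- portal_point(line, 1) - portal_point(line, 0)
  expect_lt(abs(sum(dirv * pf$w)), 1e-9)
})

test_that("portal lines at different flexions are related by the TEA rotation", {
  p100 <- flex_knee(default_knee(), default_landmarks(), 100)
  p130 <- flex_knee(default_knee(), default_landmarks(), 130)
  l100 <- portal_line(p100)
  l130 <- portal_line(p130)
  tea <- default_landmarks()$tea
  dth <- p130$.rot_angle - p100$.rot_angle
  for (s in c(-10, 0, 40)) {
    expect_points_equal(
      rotate_about_axis(portal_point(l100, s), tea$origin, tea$direction, dth),
      portal_point(l130, s), 1e-6)
  }
})

test_that("the transverse angle has the stated datum and monotonicity", {
  posed <- posed_fixture(120)
  pf <- posed$plateau_frame_posed
  F <- default_landmarks()$femoral_fp
  # portal directly anterior of F (in the plateau plane): 0 degrees
  expect_equal(transverse_angle(F + 40 * pf$v, F, pf), 0, tolerance = 1e-9)
  # purely ML drill: 90 degrees
  expect_equal(transverse_angle(F + 25 * pf$u, F, pf), 90, tolerance = 1e-9)

  line <- portal_line(posed)
  s_zero <- -sum((F - line$C) * line$u)
  ss <- seq(s_zero + 1, s_zero + 80, length.out = 50)
  angs <- vapply(ss, function(s) transverse_angle(portal_point(line, s), F, pf),
                 numeric(1))
  expect_true(all(diff(angs) > 0))
})

test_that("the MTA bisection is self-consistent at its tolerance", {
  posed <- posed_fixture(120)
  F <- default_landmarks()$femoral_fp
  mta <- mta_fixture(120)
  expect_true(mta$constraint_active)
  expect_gte(mta$clearance_mm, 0)
  expect_lte(mta$clearance_mm, 0.1)
  # half a degree more transverse: contact
  line <- mta$line
  pf <- posed$plateau_frame_posed
  ang <- function(s) transverse_angle(portal_point(line, s), F, pf)
  s_plus <- uniroot(function(s) ang(s) - (mta$transverse_angle_deg + 0.5),
                    c(mta$s, mta$s + 30), tol = 1e-8)$root
  expect_lt(portal_clearance(posed, F, portal_point(line, s_plus)), 0)
})

test_that("removing the medial condyle deactivates the MTA constraint", {
  k <- default_knee()
  k$femur$face_labels[k$femur$face_labels == "medial_condyle_articular"] <-
    "external_cortex"
  lms <- default_landmarks()
  posed <- flex_knee(k, lms, 120)
  mta <- find_mta(posed, lms$femoral_fp)
  expect_false(mta$constraint_active)
  expect_equal(mta$s, portal_line(posed)$s_range[2] + 20, tolerance = 1e-9)
})

test_that("widening the notch does not decrease the MTA angle", {
  base <- knee_params(voxel_pitch = 1.5)
  wide <- knee_params(voxel_pitch = 1.5, notch_width = base$notch_width + 4)
  get_mta <- function(p) {
    k <- generate_knee(p, seed = 4)
    lms <- knee_landmarks(k)
    find_mta(flex_knee(k, lms, 120), lms$femoral_fp)$transverse_angle_deg
  }
  expect_gte(get_mta(wide), get_mta(base) - 1e-6)
})

test_that("portals at offset angles are found lateral of the MTA portal", {
  posed <- posed_fixture(120)
  F <- default_landmarks()$femoral_fp
  mta <- mta_fixture(120)
  at_mta <- portal_at_angle(posed, F, mta$transverse_angle_deg, mta = mta)
  expect_equal(at_mta$transverse_angle_deg, mta$transverse_angle_deg,
               tolerance = 0.02)
  m10 <- portal_at_angle(posed, F, mta$transverse_angle_deg - 10, mta = mta)
  m20 <- portal_at_angle(posed, F, mta$transverse_angle_deg - 20, mta = mta)
  expect_equal(m10$transverse_angle_deg, mta$transverse_angle_deg - 10,
               tolerance = 0.01)
  expect_equal(m20$transverse_angle_deg, mta$transverse_angle_deg - 20,
               tolerance = 0.01)
  expect_lt(m20$s, m10$s)
  expect_lt(m10$s, mta$s)
  expect_error(portal_at_angle(posed, F, mta$transverse_angle_deg + 5, mta = mta),
               "exceeds")
})

test_that("tunnel length through a sphere matches the chord oracle", {
  sph <- sphere_mesh(20, 1)
  tun <- drill_tunnel(sph, c(0, 0, -20), c(0, 0, -30))
  expect_equal(tun$length_mm, 40, tolerance = 0.5)
  expect_false(tun$short)
  expect_equal(tun$breakage, "none")
  expect_equal(tun$length_mm,
               sqrt(sum((tun$exit_point - c(0, 0, -20))^2)), tolerance = 1e-6)

  # tangential graze: essentially zero length, flagged short
  graze <- drill_tunnel(sph, c(0, 0, -20), c(-10, 0, -20))
  expect_lt(graze$length_mm, 2)
  expect_true(graze$short)
})

test_that("the short-tunnel rule is exactly length < 25 mm", {
  res <- default_results()
  ok <- res[is.na(res$error), ]
  expect_identical(ok$short, ok$length_mm < 25)
})

test_that("breakage classes match the constructed defects and are resolution-stable", {
  fine <- list(n_theta = 144L, t_step = 0.125)
  intact <- drill_tunnel(sphere_mesh(20, 1), c(0, 0, -20), c(0, 0, -30))
  expect_equal(intact$breakage, "none")
  expect_equal(do.call(classify_breakage,
                       c(list(intact, sphere_mesh(20, 1)), fine)), "none")

  ent <- drill_tunnel(sphere_entrance_defect(), c(0, 0, -20), c(0, 0, -30))
  expect_equal(ent$breakage, "entrance")
  expect_equal(do.call(classify_breakage,
                       c(list(ent, sphere_entrance_defect()), fine)), "entrance")

  mid <- drill_tunnel(sphere_slot_defect(), c(0, 0, -20), c(0, 0, -30))
  expect_equal(mid$breakage, "mid_tunnel")
  expect_equal(do.call(classify_breakage,
                       c(list(mid, sphere_slot_defect()), fine)), "mid_tunnel")
})

test_that("entrance and mid-tunnel breakage are never co-reported", {
  res <- default_results()
  ok <- res[is.na(res$error), ]
  expect_true(all(ok$breakage %in% c("none", "entrance", "mid_tunnel")))
})
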