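test_that("the generator is deterministic in (params, seed)", {
  p <- knee_params(voxel_pitch = 2)
  a <- generate_knee(p, seed = 7)
  b <- generate_knee(p, seed = 7)
  expect_identical(a$femur$vertices, b$femur$vertices)
  expect_identical(a$tibia$vertices, b$tibia$vertices)
  c_ <- generate_knee(p, seed = 8)
  expect_false(identical(a$femur$vertices, c_$femur$vertices))
})

test_that("generated knees satisfy the model invariants", {
  k <- default_knee()
  expect_gt(mesh_volume(k$femur), 0)
  expect_gt(mesh_volume(k$tibia), 0)
  for (lab in c("medial_condyle_articular", "lateral_condyle_medial_wall",
                "external_cortex"))
    expect_true(lab %in% k$femur$face_labels)
  expect_true("plateau" %in% k$tibia$face_labels)
  # extension pose: tibia entirely below the femur, no interpenetration
  expect_lt(max(k$tibia$vertices[, 3]), min(k$femur$vertices[, 3]))
})

test_that("the detected epicondylar span matches the prescribed distance", {
  k <- default_knee()
  epi <- epicondylar_axis(k$femur)
  sep <- sqrt(sum((epi$lateral_epicondyle - epi$medial_epicondyle)^2))
  expect_equal(sep, k$params$transepicondylar_distance, tolerance = 2 / 82.1)
})

test_that("a left knee is the mirror image of the right knee", {
  pr <- knee_params(voxel_pitch = 2)
  pl <- knee_params(voxel_pitch = 2, side = "left")
  right <- generate_knee(pr, seed = 3)
  left <- generate_knee(pl, seed = 3)
  mirrored <- left$femur$vertices
  mirrored[, 1] <- -mirrored[, 1]
  expect_lt(max(abs(mirrored - right$femur$vertices)), 1e-6)
  # canonicalization restores the right-knee frame
  canon <- canonical_knee(left)
  expect_true(attr(canon, "mirrored"))
  expect_lt(max(abs(canon$femur$vertices - right$femur$vertices)), 1e-6)
})

test_that("every femur has two condyles separated by an open notch", {
  for (seed in c(2, 13, 77)) {
    k <- generate_knee(knee_params(voxel_pitch = 2), seed = seed)
    g <- kneedrill:::femur_geometry(k$params)
    z0 <- min(k$femur$vertices[, 3]) - 5
    first_entry <- function(x) {
      cr <- cast_ray(k$femur, ray(c(x, 0, z0), c(0, 0, 1)))
      z0 + cr$t[cr$kind == "entering"][1]
    }
    z_mid <- first_entry(0)
    z_med <- first_entry(g$cen_med[1])
    z_lat <- first_entry(g$cen_lat[1])
    expect_gt(z_mid, z_med + 1)  # corridor ray enters bone strictly later
    expect_gt(z_mid, z_lat + 1)
  }
})

test_that("cohort sampling is reproducible and respects the population", {
  a <- sample_cohort(3, seed = 42, pitch = 2)
  b <- sample_cohort(3, seed = 42, pitch = 2)
  for (i in 1:3)
    expect_identical(a[[i]]$femur$vertices, b[[i]]$femur$vertices)
  expect_length(sample_cohort(1, seed = 1, pitch = 2), 1L)

  # CLT bound on the cohort mean of the transepicondylar distance
  coh <- sample_cohort(30, seed = 11, pitch = 4)
  teds <- vapply(coh, function(m) m$params$transepicondylar_distance, numeric(1))
  expect_lt(abs(mean(teds) - 82.1), 3 * 5.7 / sqrt(30))
  expect_true(all(teds >= 60 & teds <= 110))
})
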