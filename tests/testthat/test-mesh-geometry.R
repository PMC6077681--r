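test_that("ray casting reports sorted, alternating crossings with exact cube chords", {
  cube <- unit_cube_mesh()
  cr <- cast_ray(cube, ray(c(0, 0, -5), c(0, 0, 1)))
  expect_equal(nrow(cr), 2L)
  expect_equal(cr$kind, c("entering", "exiting"))
  expect_equal(diff(cr$t), 1.0, tolerance = 1e-12)

  expect_equal(nrow(cast_ray(cube, ray(c(2, 2, -5), c(0, 0, 1)))), 0L)

  # a ray starting inside reports an exiting crossing first
  cr_in <- cast_ray(cube, ray(c(0.1, 0.1, 0), c(1, 0, 0)))
  expect_equal(cr_in$kind[1], "exiting")
  expect_equal(cr_in$t[1], 0.4, tolerance = 1e-12)
})

test_that("chords through a surfaced sphere match the closed form", {
  sph <- sphere_mesh(20, 1)
  cr <- cast_ray(sph, ray(c(0.3, -0.2, -30), c(0, 0, 1)))
  ent <- cr$t[cr$kind == "entering"][1]
  ext <- rev(cr$t[cr$kind == "exiting"])[1]
  expect_equal(ext - ent, 40, tolerance = 0.5)
})

test_that("entering and exiting crossings balance for rays from outside", {
  sph <- sphere_mesh(20, 1)
  set.seed(7)
  for (i in 1:25) {
    o <- c(runif(1, -24, 24), runif(1, -24, 24), -40)
    d <- c(rnorm(2, 0, 0.15), 1)
    cr <- cast_ray(sph, ray(o, d))
    expect_equal(sum(cr$kind == "entering"), sum(cr$kind == "exiting"))
  }
})

test_that("non-watertight meshes are rejected with the open-edge count", {
  cube <- unit_cube_mesh()
  expect_error(surface_mesh(cube$vertices, cube$faces[-1, ]),
               "not watertight.*open")
  bad <- cube$vertices
  bad[1, 1] <- NA
  expect_error(surface_mesh(bad, cube$faces), "finite")
})

test_that("point containment agrees with the analytic sphere indicator", {
  sph <- sphere_mesh(20, 1)
  set.seed(11)
  p <- matrix(runif(3000, -24, 24), ncol = 3)
  r <- sqrt(rowSums(p^2))
  inside <- contains_point(sph, p)
  clear <- abs(r - 20) > 1  # away from the surfacing-pitch band
  expect_true(all(inside[clear] == (r[clear] < 20)))

  cube <- unit_cube_mesh()
  expect_true(contains_point(cube, c(0, 0, 0)))
  expect_false(contains_point(cube, c(4, 4, 4)))
})

test_that("containment is invariant under joint rigid transforms", {
  cube <- unit_cube_mesh()
  set.seed(3)
  p <- matrix(runif(300, -0.8, 0.8), ncol = 3)
  before <- contains_point(cube, p)
  axis_pt <- c(0.2, -0.4, 1)
  axis_dir <- c(1, 2, -1) / sqrt(6)
  rot <- cube
  rot$vertices <- rotate_about_axis(cube$vertices, axis_pt, axis_dir, 37) +
    matrix(rep(c(5, -3, 2), each = nrow(cube$vertices)), ncol = 3)
  p2 <- rotate_about_axis(p, axis_pt, axis_dir, 37) +
    matrix(rep(c(5, -3, 2), each = nrow(p)), ncol = 3)
  expect_identical(contains_point(rot, p2), before)
})

test_that("rotation about an axis is a rigid Rodrigues rotation", {
  expect_points_equal(rotate_about_axis(c(2, 3, 4), c(1, 1, 1), c(0, 0, 1), 0),
                      c(2, 3, 4), 1e-12)
  expect_points_equal(rotate_about_axis(c(1, 0, 0), c(0, 0, 0), c(0, 0, 1), 90),
                      c(0, 1, 0), 1e-12)
  # group property: 36 x 10 degrees = identity
  set.seed(5)
  p <- matrix(rnorm(30), ncol = 3)
  q <- p
  for (i in 1:36) q <- rotate_about_axis(q, c(1, 2, 3), c(1, 1, 0) / sqrt(2), 10)
  expect_lt(max(abs(q - p)), 1e-9)
  # pairwise distances preserved
  r <- rotate_about_axis(p, c(0, 1, 0), c(0, 1, 0), 53)
  expect_lt(max(abs(dist(p) - dist(r))) / max(dist(p)), 1e-9)
  expect_error(rotate_about_axis(p, c(0, 0, 0), c(0, 0, 0), 10), "non-zero")
})

test_that("planar projection uses the frame's (u, v) coordinates", {
  fr <- frame3(c(1, 2, 3), c(0, 1, 0), c(0, 0, 1))  # w = +x
  expect_points_equal(project_to_plane(c(1, 2, 3), fr), c(0, 0), 1e-12)
  p <- c(1, 2, 3) + 3 * fr$u + 4 * fr$v
  expect_points_equal(project_to_plane(p, fr), c(3, 4), 1e-12)
  # round trip: lifted points have zero w-residual and re-project identically
  uv <- matrix(c(1.5, -2, 0.25, 7), ncol = 2)
  lifted <- kneedrill:::lift_from_plane(uv, fr)
  expect_points_equal(project_to_plane(lifted, fr), uv, 1e-12)
  expect_lt(max(abs(sweep(lifted, 2, fr$origin) %*% fr$w)), 1e-12)
})

test_that("meshes survive STL and PLY round trips", {
  cube <- unit_cube_mesh()
  for (fmt in c("stl_bin", "stl_ascii", "ply")) {
    path <- tempfile(fileext = if (fmt == "ply") ".ply" else ".stl")
    write_mesh(cube, path, ascii = fmt == "stl_ascii")
    back <- read_mesh(path)
    expect_equal(mesh_volume(back), 1.0, tolerance = 1e-6)
    expect_equal(nrow(back$vertices), 8L)
    expect_equal(nrow(back$faces), 12L)
    unlink(path)
  }
})
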