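# Shared fixtures, built lazily and cached for the whole test run.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, .fixture_cache)) assign(name, build(), .fixture_cache)
  get(name, .fixture_cache)
}

# exact axis-aligned unit cube centered at the origin (12 outward triangles)
unit_cube_mesh <- function() {
  v <- as.matrix(expand.grid(x = c(-0.5, 0.5), y = c(-0.5, 0.5),
                             z = c(-0.5, 0.5)))
  # faces as vertex indices into the expand.grid order (x fastest)
  quad <- function(a, b, c, d) rbind(c(a, b, c), c(a, c, d))
  f <- rbind(quad(1, 3, 4, 2),  # z = -0.5, normal -z
             quad(5, 6, 8, 7),  # z = +0.5, normal +z
             quad(1, 2, 6, 5),  # y = -0.5
             quad(3, 7, 8, 4),  # y = +0.5
             quad(1, 5, 7, 3),  # x = -0.5
             quad(2, 4, 8, 6))  # x = +0.5
  surface_mesh(v, f)
}

sphere_mesh <- function(radius = 20, pitch = 1) {
  key <- sprintf("sphere_%g_%g", radius, pitch)
  fixture(key, function() {
    pad <- radius + 4 * pitch
    mesh_from_implicit(function(p) sqrt(rowSums(p^2)) - radius,
                       rbind(c(-pad, -pad, -pad), c(pad, pad, pad)),
                       pitch = pitch)
  })
}

# sphere with a wedge removed at the tunnel entrance rim: drilling from
# F = (0,0,-r) upward, wall generators near +x have no bone until t ~ 10 mm
sphere_entrance_defect <- function() {
  fixture("sphere_entrance", function() {
    f <- function(p) {
      sph <- sqrt(rowSums(p^2)) - 20
      box <- pmax(pmax(2 - p[, 1], p[, 1] - 12),
                  abs(p[, 2]) - 12, pmax(-22 - p[, 3], p[, 3] + 10))
      pmax(sph, -box)  # sphere minus box
    }
    mesh_from_implicit(f, rbind(c(-25, -25, -25), c(25, 25, 25)), pitch = 0.5)
  })
}

# sphere with a 3-mm transverse slot crossing the wall at t ~ 15 mm
# (z in [-6.5, -3.5]) on the +x side only
sphere_slot_defect <- function() {
  fixture("sphere_slot", function() {
    f <- function(p) {
      sph <- sqrt(rowSums(p^2)) - 20
      slot <- pmax(2 - p[, 1], abs(p[, 3] + 5) - 1.5)
      pmax(sph, -slot)
    }
    mesh_from_implicit(f, rbind(c(-25, -25, -25), c(25, 25, 25)), pitch = 0.5)
  })
}

default_knee <- function() fixture("knee_default", function()
  generate_knee(knee_params(), seed = 1))

default_landmarks <- function() fixture("landmarks_default", function()
  knee_landmarks(default_knee()))

# the study-condition cohort used by the trend checks (n = 10, seed 42)
default_cohort <- function() fixture("cohort_default", function()
  sample_cohort(10, seed = 42))

default_results <- function() fixture("results_default", function()
  run_grid(default_cohort()))

expect_points_equal <- function(a, b, tol = 1e-9) {
  expect_lt(max(abs(as.numeric(a) - as.numeric(b))), tol)
}
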