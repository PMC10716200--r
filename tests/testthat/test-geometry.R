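test_that("tube mesh has the constructed grid, radius and closed seam", {
  ts <- tube_spec(inner_diameter = 5, length = 60, base_thickness = 0.5,
                  n_axial = 60, n_circ = 32)
  m <- make_tube_mesh(ts)
  expect_equal(nrow(m$quads), 60 * 32)
  r <- sqrt(m$nodes[, 1]^2 + m$nodes[, 2]^2)
  expect_equal(range(r), c(2.75, 2.75))
  # seam closed: each axial station has exactly n_circ distinct nodes and
  # every quad references existing nodes (no duplicated phi = 2*pi column)
  expect_equal(nrow(m$nodes), (60 + 1) * 32)
  expect_true(all(m$quads >= 1 & m$quads <= nrow(m$nodes)))
  # the last column's quads wrap around to phi = 0
  wrap_quads <- m$quads[seq(32, 60 * 32, by = 32), ]
  expect_true(all(m$phi[wrap_quads[, 2]] == 0))

  m15 <- make_tube_mesh(tube_spec(length = 15, n_axial = 15))
  expect_equal(diff(range(m15$nodes[, 3])), 15)
})

test_that("tube_spec rejects bad dimensions naming the field", {
  expect_error(tube_spec(inner_diameter = -5), "inner_diameter")
  expect_error(tube_spec(length = 0), "length")
  expect_error(tube_spec(base_thickness = -1), "base_thickness")
  expect_error(tube_spec(n_circ = 9), "even")
  expect_error(tube_spec(n_circ = 6), "n_circ")
  expect_error(tube_spec(n_axial = 2), "n_axial")
})

test_that("thickness field: constant base, patch minimum, determinism", {
  ts <- tube_spec(5, 60, 0.5, 60, 32)
  th0 <- build_thickness_field(ts)
  expect_true(all(th0 == 0.5))

  # patch centre aligned with an element centre attains min_thickness
  p <- thin_patch_spec(axial_center = 19.5, circ_center = pi / 32,
                       min_thickness = 0.06)
  th <- build_thickness_field(ts, list(p))
  expect_equal(min(th), 0.06)
  expect_equal(th[20, 1], 0.06)   # element centred at z = 19.5, phi = pi/32
  # far from the patch the wall is untouched
  expect_equal(th[50, 16], 0.5)

  # seeded noise is bit-reproducible; different seeds differ
  n1 <- build_thickness_field(ts, noise_amplitude = 0.05, seed = 7L)
  n2 <- build_thickness_field(ts, noise_amplitude = 0.05, seed = 7L)
  n3 <- build_thickness_field(ts, noise_amplitude = 0.05, seed = 8L)
  expect_identical(as.matrix(n1), as.matrix(n2))
  expect_false(identical(as.matrix(n1), as.matrix(n3)))
  expect_true(all(n1 > 0))
})

test_that("thickness field rejects invalid patches", {
  ts <- tube_spec(5, 60, 0.5, 60, 32)
  expect_error(build_thickness_field(
    ts, list(thin_patch_spec(axial_center = 2, axial_halfwidth = 6))),
    "outside")
  expect_error(build_thickness_field(
    ts, list(thin_patch_spec(axial_center = 30, min_thickness = 0.7))),
    "base_thickness")
})

test_that("helix path: turn count, winding radius, layers", {
  ts <- tube_spec(5, 15, 0.5, 15, 32)
  h <- helix_spec(pitch = 2.25, thread_diameter = 0.33)
  hp <- make_helix_path(h, ts)
  r <- sqrt(hp[, "x"]^2 + hp[, "y"]^2)
  expect_equal(range(r), rep(2.5 + 0.5 + 0.33 / 2, 2))
  # turns per layer = span / pitch (~6.67 over 15 mm at pitch 2.25)
  l1 <- hp[hp[, "layer"] == 1, ]
  d_ang <- abs(diff(2 * pi * l1[, "z"] / h$pitch))
  expect_equal(sum(d_ang) / (2 * pi), 15 / 2.25, tolerance = 1e-9)
  # both layers present and opposite slope sense
  expect_setequal(unique(hp[, "layer"]), c(1, 2))

  expect_equal(nrow(make_helix_path(helix_spec(n_layers = 0), ts)), 0)
  expect_error(helix_spec(pitch = -1), "pitch")
  expect_error(helix_spec(pitch = 0.2, thread_diameter = 0.33), "pitch")
})

test_that("helix angle closed form", {
  expect_equal(helix_angle(2.25, 6) * 180 / pi, 6.8, tolerance = 0.01)
})

test_that("helix coverage conserves path length and is near-uniform per row", {
  ts <- tube_spec(5, 60, 0.5, 60, 32)
  mesh <- make_tube_mesh(ts)

  # empty path -> all-zero coverage
  cov0 <- helix_coverage(make_helix_path(helix_spec(n_layers = 0), ts), mesh)
  expect_true(all(cov0 == 0))

  # conservation across pitches and phases (property)
  for (pitch in c(1.5, 2.15, 2.25, 4)) {
    for (phase in c(0, 1.1)) {
      hp <- make_helix_path(helix_spec(pitch = pitch, phase = phase), ts)
      cov <- helix_coverage(hp, mesh)
      expect_lt(abs(sum(cov) - helix_path_length(hp)) / helix_path_length(hp),
                0.001)
    }
  }

  # full double helix: per-row coverage CV < 15%
  cov <- helix_coverage(make_helix_path(helix_spec(), ts), mesh)
  rl <- rowSums(cov)
  expect_lt(stats::sd(rl) / mean(rl), 0.15)
})

test_that("hoop-ring limit concentrates coverage in one row", {
  # a single circular ring at a row centre: sum = circumference
  ts <- tube_spec(5, 60, 0.5, 60, 32)
  mesh <- make_tube_mesh(ts)
  r_w <- 2.5 + 0.5 + 0.33 / 2
  phi <- seq(0, 2 * pi, length.out = 257)
  ring <- cbind(x = r_w * cos(phi), y = r_w * sin(phi),
                z = rep(30.5, 257), layer = rep(1, 257))
  class(ring) <- c("helix_path", "matrix")
  attr(ring, "spec") <- helix_spec()
  cov <- helix_coverage(ring, mesh)
  expect_true(all(cov[-31, ] == 0))
  # polygonal circumference of the sampled ring
  expect_equal(sum(cov), 2 * pi * r_w, tolerance = 1e-3)
})

test_that("mesh area is stable under circumferential refinement", {
  a1 <- helixvessel:::mesh_area(make_tube_mesh(tube_spec(5, 60, 0.5, 60, 32)))
  a2 <- helixvessel:::mesh_area(make_tube_mesh(tube_spec(5, 60, 0.5, 60, 64)))
  expect_lt(abs(a2 - a1) / a1, 0.01)
})

test_that("scaffold model validates coverage conservation and inputs", {
  ts <- tube_spec(5, 60, 0.5, 60, 32)
  mesh <- make_tube_mesh(ts)
  expect_error(scaffold_model(mesh, matrix(0.5, 10, 10)), "grid")
  m <- scaffold_model(mesh, 0.5, helix = helix_spec(),
                      polymer = polymer_params(458, "PVDF"))
  expect_lt(abs(sum(m$coverage) -
                  helix_path_length(make_helix_path(helix_spec(), ts))) /
              sum(m$coverage), 0.001)
  expect_error(scaffold_model(mesh, 0.5, helix = helix_spec()), "polymer")
})
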