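test_that("laplace_reference closed form and thin-wall warning", {
  expect_equal(laplace_reference(0.016, 2.5, 0.5, 1), 0.08)
  expect_equal(laplace_reference(0, 2.5, 0.5, 1), 0)
  expect_equal(laplace_reference(0.016, 2.5, 0.25, 1),
               2 * laplace_reference(0.016, 2.5, 0.5, 1))
  expect_warning(laplace_reference(0.01, 2.5, 1, 1), "thin-wall")
})

test_that("uniform tube pressure solve matches the Laplace oracle within 1%", {
  m <- uniform_tube()
  res <- solve_pressure(m, 0.012)
  expect_true(res$converged)
  oracle <- laplace_reference(0.012, 2.5, 0.5, 1)
  mid <- mean(res$hoop_strain[30, ])
  expect_lt(abs(mid - oracle) / oracle, 0.01)
  # and across the clamp-free central half of the span
  central <- res$hoop_strain[20:40, ]
  expect_lt(max(abs(central - oracle)) / oracle, 0.01)
})

test_that("zero pressure gives zero displacement with no iterations", {
  m <- uniform_tube(n_axial = 20, n_circ = 16)
  res <- solve_pressure(m, 0)
  expect_equal(max(abs(res$U1)), 0)
  expect_equal(res$iterations, 0L)
})

test_that("encastre bands stay fixed; free ends balloon", {
  m <- uniform_tube()
  res <- solve_pressure(m, 0.012)
  z <- res$z_stations
  expect_true(all(res$U1[z <= 5, ] == 0))
  expect_true(all(res$U1[z >= 55, ] == 0))
  free <- solve_pressure(m, 0.012, boundary_condition("free"))
  expect_gt(max(abs(free$U1[1, ])), 0)
})

test_that("full PVDF double helix cuts hoop strain by far more than 10x", {
  m0 <- uniform_tube()
  m1 <- preset_model("pvdf", with_patch = FALSE)
  r0 <- solve_pressure(m0, 0.012)
  r1 <- solve_pressure(m1, 0.012)
  s0 <- mean(r0$hoop_strain[30, ])
  s1 <- mean(r1$hoop_strain[30, ])
  expect_gt(s0 / s1, 10)
  # homogenized stiffness arithmetic: E*A*cos^2(alpha)*n_layers/pitch vs E*t
  A <- pi * (0.33 / 2)^2
  r_w <- 2.5 + 0.5 + 0.33 / 2
  alpha <- helix_angle(2.25, 2 * r_w)
  C_hx <- 458 * A * cos(alpha)^2 * 2 / 2.25
  expect_gt(C_hx, 30)  # ~34 N/mm vs bio E*t = 0.5 N/mm
  # referred to the mid-surface, the smeared stiffness scales by r_w/r_mid
  expect_equal(s0 / s1, (C_hx * r_w / 2.75 + 0.5) / 0.5, tolerance = 0.05)
})

test_that("adding a helix never increases displacement at fixed pressure", {
  m0 <- uniform_tube(n_axial = 30, n_circ = 16)
  ts <- tube_spec(5, 60, 0.5, 30, 16)
  m1 <- scaffold_model(make_tube_mesh(ts), build_thickness_field(ts),
                       helix = helix_spec(pitch = 2.25),
                       polymer = polymer_params(458, "PVDF"))
  r0 <- solve_pressure(m0, 0.016)
  r1 <- solve_pressure(m1, 0.016)
  expect_true(all(r1$U1 <= r0$U1 + 1e-12))
})

test_that("mesh convergence: refining the preset grid moves peak U1 < 2%", {
  m1 <- preset_model("control")
  m2 <- build_scaffold(make_preset("control", n_axial = 120L, n_circ = 64L))
  r1 <- solve_pressure(m1, 0.016)
  r2 <- solve_pressure(m2, 0.016)
  expect_lt(abs(max(r1$U1) - max(r2$U1)) / max(r2$U1), 0.02)
})

test_that("overload pressure flags model validity", {
  m <- uniform_tube(n_axial = 20, n_circ = 16)
  res <- solve_pressure(m, 0.2)   # strain ~ 1: far outside the small-strain regime
  expect_equal(res$validity, "model validity exceeded")
  ok <- solve_pressure(m, 0.012)
  expect_equal(ok$validity, "ok")
})

test_that("longitudinal tension: annular-bar arithmetic and helix neutrality", {
  m <- uniform_tube()
  cur <- solve_longitudinal_tension(m, 6)   # 10% strain
  A <- pi * (3^2 - 2.5^2)
  expect_equal(tail(cur$force, 1), 1 * 0.1 * A, tolerance = 1e-9)
  expect_equal(cur$force[1], 0)

  mp <- preset_model("pvdf", with_patch = FALSE)
  curp <- solve_longitudinal_tension(mp, 6)
  expect_lt(abs(tail(curp$force, 1) - tail(cur$force, 1)) /
              tail(cur$force, 1), 0.05)
  expect_error(solve_longitudinal_tension(m, -1), "negative")
})

test_that("ring initial compliance matches the curved-beam closed form within 2%", {
  # slender elastic ring: R = 10, b x t = 15 x 0.2, E = 1
  EI <- 1 * 15 * 0.2^3 / 12
  k_fe <- helixvessel:::ring_fe_stiffness(R = 10, EA = 1 * 15 * 0.2,
                                          EI = EI, n_elem = 72)
  delta_closed <- 1 * 10^3 / EI * (pi / 4 - 2 / pi)
  expect_lt(abs(1 / k_fe - delta_closed) / delta_closed, 0.02)
})

test_that("transverse ring test: composite stiffening and input checks", {
  mc <- preset_model("control", length = 15, with_patch = FALSE)
  mp <- preset_model("pvdf", length = 15, with_patch = FALSE)
  cc <- solve_transverse_ring(mc, 3)
  cp <- solve_transverse_ring(mp, 3)
  expect_equal(cc$force[1], 0)
  expect_gt(attr(cp, "k_initial") / attr(cc, "k_initial"), 1)
  expect_true(all(diff(cc$force) > 0))
  expect_error(solve_transverse_ring(mc, 3, pin_diameter = 6), "lumen")
  expect_error(solve_transverse_ring(mc, -1), "negative")
})
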