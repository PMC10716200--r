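test_that("compliance arithmetic follows the definition", {
  expect_equal(compliance_pct(5.00, 5.10), 2.0)
  expect_equal(compliance_pct(5, 5), 0)
})

test_that("near-rigid wall gives near-zero compliance", {
  m <- uniform_tube(n_axial = 20, n_circ = 16,
                    bio = damage_plastic_params(E0 = 1e6))
  cr <- compliance_test(m, "normo")
  expect_lt(cr$compliance_pct, 1e-4)
  expect_false(cr$flagged)
})

test_that("linear uniform tube compliance matches the Laplace increment", {
  m <- uniform_tube()
  cr <- compliance_test(m, "normo")
  # same-convention closed form: outer diameter D0 + 2*w with
  # w = p * r_in / (t * E) * r_mid at mid-span
  w_of <- function(p) p * 2.5 / (0.5 * 1) * 2.75
  expected <- compliance_pct(6 + 2 * w_of(0.011), 6 + 2 * w_of(0.016))
  expect_equal(cr$compliance_pct, expected, tolerance = 0.01)
  # the crude strain-based estimate dp*r/(t*E) = 2.5% is matched loosely:
  # referencing the outer (not mid-surface) diameter shifts it down
  expect_equal(cr$compliance_pct, 2.5, tolerance = 0.15)
  expect_gt(cr$d_sys, cr$d_dia)
})

test_that("linear material: the three pressure ranges agree within 5%", {
  m <- uniform_tube()
  cp <- vapply(c("hypo", "normo", "hyper"),
               function(rg) compliance_test(m, rg)$compliance_pct, numeric(1))
  expect_lt((max(cp) - min(cp)) / mean(cp), 0.05)
})

test_that("J-shaped wall law lowers compliance from hypo to hyper", {
  eps <- seq(0.02, 1, length.out = 30)
  pf <- fit_polynomial(data.frame(strain = eps, stress = 0.5 * eps + 8 * eps^3))
  ts <- tube_spec(5, 60, 0.5, 60, 32)
  m <- scaffold_model(make_tube_mesh(ts), build_thickness_field(ts), bio = pf)
  cp <- vapply(c("hypo", "normo", "hyper"),
               function(rg) compliance_test(m, rg)$compliance_pct, numeric(1))
  expect_true(all(diff(cp) < 0))
})

test_that("helix barely moves compliance but multiplies transverse stiffness", {
  m0 <- uniform_tube()
  mp <- preset_model("pvdf", with_patch = FALSE)
  c0 <- compliance_test(m0, "normo")$compliance_pct
  cp <- compliance_test(mp, "normo")$compliance_pct
  # absolute compliance change is small on the physiological percent scale
  expect_lt(c0 - cp, 3)
  expect_gt(c0, cp)
  rc <- tension_test(preset_model("control", length = 15, with_patch = FALSE),
                     "transverse", max_strain = 0.3, n_steps = 150)
  rp <- tension_test(preset_model("pvdf", length = 15, with_patch = FALSE),
                     "transverse", max_strain = 0.3, n_steps = 150)
  expect_gt(stiffness_ratio(rp, rc), 2)
})

test_that("stop criterion: no stop on monotone curves, stop on softening", {
  m <- uniform_tube(n_axial = 20, n_circ = 16)
  cur <- tension_test(m, "longitudinal", max_strain = 0.5)
  expect_true(is.na(attr(cur, "stop_index")))
  expect_equal(nrow(cur), 101)

  # synthetic softening curve: stop at the first sample below 70% of the peak
  eps <- seq(0.01, 1, by = 0.01)
  sig <- c(seq(0.02, 1, length.out = 50), seq(0.99, 0.2, length.out = 50))
  sc <- stress_strain_curve(eps, sig, "longitudinal")
  out <- apply_stop_criterion(sc, 0.30)
  k <- attr(out, "stop_index")
  brute <- which(sig < 0.7 * cummax(sig))[1]   # independent scan
  expect_equal(k, brute)
  expect_equal(nrow(out), k)
  expect_error(tension_test(m, "longitudinal", max_strain = -1), "max_strain")
})

test_that("beyond yield the damage-plastic wall triggers the stop criterion", {
  m <- uniform_tube(n_axial = 20, n_circ = 16)
  cur <- tension_test(m, "longitudinal", max_strain = 0.9)
  # the modulus collapse past the 0.6 yield strain drops the force > 30%
  expect_false(is.na(attr(cur, "stop_index")))
  expect_gt(cur$strain[attr(cur, "stop_index")], 0.6)
})

test_that("reinforced transverse peak stress exceeds the control's", {
  rc <- tension_test(preset_model("control", length = 15, with_patch = FALSE),
                     "transverse", max_strain = 1.0, n_steps = 150)
  rp <- tension_test(preset_model("pvdf", length = 15, with_patch = FALSE),
                     "transverse", max_strain = 1.0, n_steps = 150)
  rl <- tension_test(preset_model("pcl", length = 15, with_patch = FALSE),
                     "transverse", max_strain = 1.0, n_steps = 150)
  expect_gt(max(rp$stress), max(rc$stress))
  expect_gt(max(rl$stress), max(rc$stress))
})

test_that("stiffness ratio identities and window checks", {
  eps <- seq(0.001, 0.1, by = 0.001)
  a <- stress_strain_curve(eps, 2 * eps, "transverse")
  b <- stress_strain_curve(eps, 1 * eps, "transverse")
  expect_equal(stiffness_ratio(a, a), 1)
  expect_equal(stiffness_ratio(a, b), 2)
  short <- stress_strain_curve(eps[1:5], eps[1:5], "transverse")
  expect_error(stiffness_ratio(a, short, strain_window = 0.05), "window")
})

test_that("transverse stiffness ratio orders PVDF above PCL above control", {
  rc <- tension_test(preset_model("control", length = 15, with_patch = FALSE),
                     "transverse", max_strain = 0.3, n_steps = 150)
  rp <- tension_test(preset_model("pvdf", length = 15, with_patch = FALSE),
                     "transverse", max_strain = 0.3, n_steps = 150)
  rl <- tension_test(preset_model("pcl", length = 15, with_patch = FALSE),
                     "transverse", max_strain = 0.3, n_steps = 150)
  r_pvdf <- stiffness_ratio(rp, rc)
  r_pcl <- stiffness_ratio(rl, rc)
  expect_gt(r_pvdf, r_pcl)
  expect_gt(r_pcl, 1)
})
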