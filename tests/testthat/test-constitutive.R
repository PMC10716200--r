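test_that("damage factor endpoints and linear ramp", {
  prm <- damage_plastic_params()
  expect_equal(damage_factor(0, prm), 1)
  expect_equal(damage_factor(0.0055, prm), 0.1)
  expect_equal(damage_factor(0.00275, prm), 0.55)
  # beyond the reference plastic strain the floor holds
  expect_equal(damage_factor(10, prm), 0.1)
})

test_that("damage factor is monotone non-increasing and bounded (property)", {
  prm <- damage_plastic_params()
  set.seed(42)
  pe <- sort(stats::runif(200, 0, 0.02))
  f <- damage_factor(pe, prm)
  expect_true(all(diff(f) <= 0))
  expect_true(all(f >= prm$floor & f <= 1))
})

test_that("stress update below yield is linear elastic and state-preserving", {
  st <- material_state(1)
  up <- stress_update(0.5, st)
  expect_equal(up$sigma, 0.5)
  expect_equal(as.numeric(up$state$PE_acc), 0)
  expect_equal(as.numeric(up$state$f), 1)
  # loading-unloading a virgin point below yield leaves no residual strain:
  # sigma(eps) = E0 * eps passes through the origin
  expect_equal(stress_update(0, up$state)$sigma, 0)
})

test_that("stress update beyond yield accumulates plasticity and damage", {
  st <- material_state(1)
  up <- stress_update(0.65, st)
  expect_equal(as.numeric(up$state$PE_acc), 0.05)
  expect_equal(as.numeric(up$state$f), 0.1)   # 0.05 >> PE_ref
  expect_equal(up$sigma, 0.1 * 1 * 0.6)
  # repeating the same strain changes nothing (monotone, no reverse flow)
  up2 <- stress_update(0.65, up$state)
  expect_equal(up2$state$PE_acc, up$state$PE_acc)
  expect_equal(up2$state$f, up$state$f)
  expect_error(stress_update(-0.1, st), "compression")
})

test_that("repeated cycling never heals and stress at fixed strain never grows", {
  prm <- damage_plastic_params()
  st <- material_state(1)
  eps_seq <- c(0.61, 0.605, 0.62, 0.61, 0.7, 0.65)
  last_pe <- 0; last_f <- 1; sig_at_061 <- Inf
  for (eps in eps_seq) {
    up <- stress_update(eps, st, prm)
    expect_gte(as.numeric(up$state$PE_acc), last_pe)
    expect_lte(as.numeric(up$state$f), last_f)
    last_pe <- as.numeric(up$state$PE_acc)
    last_f <- as.numeric(up$state$f)
    st <- up$state
    s <- stress_update(0.61, st, prm)$sigma
    expect_lte(s, sig_at_061 + 1e-12)
    sig_at_061 <- s
  }
})

test_that("stress update vectorizes over element fields", {
  st <- material_state(2, 3)
  eps <- matrix(c(0.1, 0.65, 0.3, 0.7, 0, 0.6), 2, 3)
  up <- stress_update(eps, st)
  expect_equal(dim(up$state$PE_acc), c(2, 3))
  expect_equal(up$state$PE_acc[2, 2], 0.1)
  expect_equal(up$state$PE_acc[1, 1], 0)
})

test_that("polynomial fit recovers exact coefficients on noiseless data", {
  eps <- seq(0.02, 0.6, length.out = 20)
  fit <- fit_polynomial(data.frame(strain = eps,
                                   stress = 0.5 * eps + 8 * eps^3))
  expect_equal(fit$coefficients[["a1"]], 0.5, tolerance = 1e-6)
  expect_equal(fit$coefficients[["a3"]], 8, tolerance = 1e-6)
  expect_lt(fit$residual, 1e-10)

  lin <- fit_polynomial(data.frame(strain = eps, stress = eps))
  expect_lt(abs(lin$coefficients[["a3"]]), 1e-8)
})

test_that("polynomial fit input validation", {
  eps <- seq(0.1, 0.5, length.out = 10)
  expect_error(fit_polynomial(data.frame(strain = eps[1:3],
                                         stress = eps[1:3])), "5 points")
  expect_error(fit_polynomial(data.frame(strain = rev(eps), stress = eps)),
               "increasing")
  expect_error(fit_polynomial(data.frame(strain = eps, stress = 0 * eps)),
               "degenerate")
})

test_that("poly fit JSON round-trip", {
  eps <- seq(0.02, 0.6, length.out = 20)
  fit <- fit_polynomial(data.frame(strain = eps,
                                   stress = 0.5 * eps + 8 * eps^3))
  f <- withr::local_tempfile(fileext = ".json")
  poly_fit_to_json(fit, f)
  back <- poly_fit_from_json(f)
  expect_equal(back$coefficients, fit$coefficients)
  expect_equal(eval_polynomial(back, 0.3), eval_polynomial(fit, 0.3))
})

test_that("initial modulus matches the origin-constrained slope", {
  eps <- seq(0.0005, 0.05, by = 0.0005)
  lin <- data.frame(strain = eps, stress = 1.0 * eps)
  expect_equal(initial_modulus(lin), 1.0)

  cub <- data.frame(strain = eps, stress = 0.5 * eps + 8 * eps^3)
  # independent oracle: closed-form least-squares slope on the window
  win <- eps[eps <= 0.01]
  expected <- ls_slope_origin(win, 0.5 * win + 8 * win^3)
  expect_equal(initial_modulus(cub), expected)
  expect_equal(expected, 0.5008, tolerance = 1e-3)

  expect_error(initial_modulus(cub, strain_window = 1), "range")
  expect_error(initial_modulus(data.frame(strain = c(0.5, 1),
                                          stress = c(1, 2))), "points")
})
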