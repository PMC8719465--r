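test_that("reduced relaxation obeys its limits and monotonicity", {
  pr <- prony_series(g = 0.99, decay = 0.276)
  expect_equal(reduced_relaxation(0, pr), 1)
  expect_equal(reduced_relaxation(pr$tau, pr), 1 - 0.99 * (1 - exp(-1)),
               tolerance = 1e-14)
  expect_equal(reduced_relaxation(1000 * pr$tau, pr), 1 - 0.99,
               tolerance = 1e-12)
  t <- seq(0, 50, length.out = 200)
  expect_true(all(diff(reduced_relaxation(t, pr)) <= 0))
  pr2 <- prony_series(g = c(0.5, 0.3), tau = c(0.1, 5))
  expect_equal(reduced_relaxation(1e5, pr2), 0.2, tolerance = 1e-10)
  expect_error(reduced_relaxation(-1, pr), ">= 0")
  expect_error(prony_series(g = c(0.6, 0.5), tau = c(1, 2)), "sum")
  expect_error(prony_series(g = 0.5, tau = -1), "> 0")
})

test_that("ramp histories have the stated grids and durations", {
  h <- ramp_history(0.01, 1.0, n_steps = 4, mode = "simple_shear")
  expect_equal(h$time, c(0, 25, 50, 75, 100))
  expect_equal(h$strain, h$time * 0.01)
  expect_equal(max(ramp_history(300, 1.0, 10, "simple_shear")$time), 1 / 300)
  hu <- ramp_history(150, 1.3, 10, "uniaxial_tension")
  expect_equal(max(hu$time), 0.3 / 150)
  expect_equal(hu$strain[1], 1)
  expect_error(ramp_history(-1, 1, 10, "simple_shear"), "rate")
  expect_error(ramp_history(0.01, 1, 10, "uniaxial_tension"), "max_strain")
})

test_that("the elastic limit of both integrators is the Ogden curve", {
  og <- ogden_parameters(1.81, 10.1)
  h <- ramp_history(0.5, 1.0, 200, "simple_shear")
  inst <- instantaneous_shear_stress(h$strain, og)
  expect_equal(qlv_stress_recursive(h, og, prony_series())$stress, inst)
  expect_equal(qlv_stress_quadrature(h, og, prony_series())$stress, inst)
})

test_that("the recursive integrator matches the linear-backbone closed form", {
  # sigma_e = k gamma (alpha = 2), ramp gamma = r t:
  # sigma(t) = k r [t - sum_i g_i (t - tau_i (1 - exp(-t/tau_i)))]
  cases <- list(list(k = 3, r = 0.5, pr = prony_series(0.8, tau = 2)),
                list(k = 10, r = 150, pr = prony_series(0.99, tau = 3.6)),
                list(k = 1, r = 0.01,
                     pr = prony_series(c(0.4, 0.3), tau = c(0.5, 20))))
  for (cs in cases) {
    h <- ramp_history(cs$r, 1.0, 1000, "simple_shear")
    got <- qlv_stress_recursive(h, ogden_parameters(cs$k, 2), cs$pr)$stress
    t <- h$time
    want <- cs$k * cs$r *
      (t - Reduce(`+`, lapply(seq_along(cs$pr$g), function(i)
        cs$pr$g[i] * (t - cs$pr$tau[i] * (1 - exp(-t / cs$pr$tau[i]))))))
    expect_lt(max(abs(got - want)) / max(want), 1e-3)
  }
})

test_that("recursive and quadrature integrators agree", {
  mat <- preset_materials()$cerebellum
  h <- ramp_history(0.01, 1.0, 500, "simple_shear")
  a <- qlv_stress_recursive(h, mat$ogden, mat$prony)$stress
  b <- qlv_stress_quadrature(h, mat$ogden, mat$prony, refinement = 4)$stress
  expect_lt(max(abs(a - b)) / max(abs(a)), 0.005)
})

test_that("quadrature converges to the recursive result at first order or better", {
  mat <- preset_materials()$cerebrum
  dev <- vapply(c(125, 250, 500), function(n) {
    h <- ramp_history(0.01, 1.0, n, "simple_shear")
    a <- qlv_stress_recursive(h, mat$ogden, mat$prony)$stress
    b <- qlv_stress_quadrature(h, mat$ogden, mat$prony, 1)$stress
    max(abs(a - b)) / max(abs(a))
  }, numeric(1))
  expect_lt(dev[2], 0.6 * dev[1])
  expect_lt(dev[3], 0.6 * dev[2])
})

test_that("very fast ramps recover the instantaneous response", {
  mat <- preset_materials()$brainstem
  h <- ramp_history(3e5, 1.0, 500, "simple_shear") # duration << tau
  visc <- qlv_stress_recursive(h, mat$ogden, mat$prony)$stress
  inst <- instantaneous_shear_stress(h$strain, mat$ogden)
  expect_lt(max(abs(visc - inst)) / max(inst), 0.01)
})

test_that("very slow ramps recover the long-term response", {
  og <- ogden_parameters(2, 6)
  pr <- prony_series(0.7, tau = 1e-4) # relaxes long before the ramp ends
  h <- ramp_history(0.01, 1.0, 500, "simple_shear")
  visc <- qlv_stress_recursive(h, og, pr)$stress
  longterm <- (1 - 0.7) * instantaneous_shear_stress(h$strain, og)
  expect_lt(max(abs(visc - longterm)) / max(longterm), 0.01)
})

test_that("the response is causal: truncating the history preserves the past", {
  mat <- preset_materials()$cerebrum
  h <- ramp_history(0.01, 1.0, 400, "simple_shear")
  full <- qlv_stress_recursive(h, mat$ogden, mat$prony)$stress
  cut <- 201L
  h_cut <- loading_history(h$mode, h$time[1:cut], h$strain[1:cut],
                           h$nominal_rate)
  part <- qlv_stress_recursive(h_cut, mat$ogden, mat$prony)$stress
  expect_identical(part, full[1:cut])
})

test_that("uniform-grid and mode preconditions are enforced", {
  og <- ogden_parameters(1, 2)
  h <- loading_history("simple_shear", c(0, 1, 3), c(0, 0.1, 0.3), 0.1)
  expect_error(qlv_stress_recursive(h, og, prony_series(0.5, tau = 1)),
               "uniform")
  expect_error(loading_history("simple_shear", c(0, 2, 1), c(0, 0.2, 0.1),
                               0.1), "increasing")
  expect_error(loading_history("uniaxial_tension", c(0, 1), c(0, 0.1), 0.1),
               "start at 1")
})

test_that("model stress is rate-stiffening and collapses when g = 0", {
  mat <- preset_materials()$cerebellum
  curves <- lapply(c(0.01, 150, 300), function(r)
    rate_response_curve(mat, "simple_shear", r, 1.0, 400))
  s <- vapply(curves, `[[`, numeric(401), "stress")
  idx <- 2:401
  expect_true(all(s[idx, 3] >= s[idx, 2] - 1e-12))
  expect_true(all(s[idx, 2] >= s[idx, 1] - 1e-12))
  # vessel tension: monotone increasing curves
  vas <- preset_materials()$vasculature
  for (r in c(0.01, 150, 300)) {
    cv <- rate_response_curve(vas, "uniaxial_tension", r, 1.3, 400)
    expect_true(all(diff(cv$stress) > 0))
  }
  # g = 0 (no Prony): all rates collapse onto one curve
  el <- material_model("elastic", 1040, ogden = mat$ogden)
  c1 <- rate_response_curve(el, "simple_shear", 0.01, 1.0, 200)
  c2 <- rate_response_curve(el, "simple_shear", 300, 1.0, 200)
  expect_equal(c1$stress, c2$stress)
})
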