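test_that("simple-shear kinematics satisfy lambda - 1/lambda = gamma", {
  expect_equal(shear_kinematics(0)$lambda, c(1, 1, 1))
  # gamma = 3/2 gives lambda = 2 exactly (2 - 1/2 = 3/2)
  expect_equal(shear_kinematics(1.5)$lambda[1], 2)
  # oracle: root-finding on lambda - 1/lambda - gamma
  lam_root <- uniroot(function(l) l - 1 / l - 0.8, c(1, 3),
                      tol = 1e-14)$root
  expect_equal(shear_kinematics(0.8)$lambda[1], lam_root,
               tolerance = 1e-12)
  for (g in c(0.1, 0.5, 1.14, 2)) {
    l <- shear_kinematics(g)$lambda
    expect_lt(abs(l[1] - 1 / l[1] - g), 1e-12)
    expect_equal(prod(l), 1, tolerance = 1e-12)
  }
  expect_error(shear_kinematics(-0.1), "gamma")
})

test_that("strain energy is zero at identity and matches closed forms", {
  og <- ogden_parameters(mu = c(1, 0.5), alpha = c(2, -3))
  expect_identical(strain_energy(principal_stretches(1, 1, 1), og), 0)
  # alpha = 2 single term: W = mu (lambda^2 + lambda^-2 - 2)/2 at lambda 1.5
  og2 <- ogden_parameters(3.7, 2)
  lam <- 1.5
  expect_equal(strain_energy(principal_stretches(lam, 1 / lam, 1), og2),
               3.7 * (lam^2 + lam^-2 - 2) / 2, tolerance = 1e-14)
  # cerebrum parameters at (1.2, 1/1.2, 1): positive finite, equal to the
  # directly evaluated one-term formula
  cer <- preset_materials()$cerebrum$ogden
  w <- strain_energy(principal_stretches(1.2, 1 / 1.2, 1), cer)
  expect_true(is.finite(w) && w > 0)
  expect_equal(w, 2 * 1.81 / 10.1^2 *
                 (1.2^10.1 + 1.2^-10.1 + 1 - 3), tolerance = 1e-14)
  expect_error(principal_stretches(1.2, 1, 1), "incompressibility")
  expect_error(principal_stretches(-1, -1, 1), "positive")
})

test_that("parameter invariants are enforced", {
  expect_error(ogden_parameters(numeric(0), numeric(0)), "non-empty")
  expect_error(ogden_parameters(-1, 2), "mu_i")
  expect_error(ogden_parameters(1, 0.05), "alpha")
  expect_error(instantaneous_uniaxial_stress(0.9, ogden_parameters(1, 2)),
               "tension")
  expect_error(instantaneous_shear_stress(-0.2, ogden_parameters(1, 2)),
               "gamma")
})

test_that("alpha = 2 reduces to the neo-Hookean stress exactly", {
  og <- ogden_parameters(2.5, 2)
  gam <- c(0.01, 0.3, 0.8, 1.4)
  expect_equal(instantaneous_shear_stress(gam, og), 2.5 * gam,
               tolerance = 1e-15)
  lam <- c(1.01, 1.2, 1.5)
  expect_equal(instantaneous_uniaxial_stress(lam, og),
               2.5 * (lam^2 - 1 / lam), tolerance = 1e-15)
  expect_equal(instantaneous_uniaxial_stress(lam, og, "nominal"),
               2.5 * (lam^2 - 1 / lam) / lam, tolerance = 1e-15)
})

test_that("analytic stress equals the numerical derivative of the energy", {
  # shear: sigma_12 = dW/dgamma; uniaxial: sigma_11 = lambda dW/dlambda
  params <- list(ogden_parameters(1.81, 10.1),
                 ogden_parameters(700.4, 12.6),
                 ogden_parameters(c(1, 0.5), c(2, -3)),
                 ogden_parameters(c(0.35, 38.5), c(23.4, -5.3)))
  h <- 1e-6
  w_shear <- function(g, og)
    strain_energy(shear_kinematics(g), og)
  w_uni <- function(l, og)
    strain_energy(principal_stretches(l, 1 / sqrt(l), 1 / sqrt(l)), og)
  for (og in params) {
    for (g in c(0.2, 0.6, 1.0)) {
      num <- (w_shear(g + h, og) - w_shear(g - h, og)) / (2 * h)
      expect_equal(instantaneous_shear_stress(g, og), num,
                   tolerance = 1e-6)
    }
    for (l in c(1.05, 1.2, 1.4)) {
      num <- l * (w_uni(l + h, og) - w_uni(l - h, og)) / (2 * h)
      expect_equal(instantaneous_uniaxial_stress(l, og), num,
                   tolerance = 1e-6)
    }
  }
})

test_that("stress is strictly increasing for positive-exponent terms", {
  for (og in list(ogden_parameters(1.46, 8.0),
                  ogden_parameters(c(1, 2), c(4, 9)))) {
    gam <- seq(0.01, 1.5, length.out = 60)
    expect_true(all(diff(instantaneous_shear_stress(gam, og)) > 0))
    lam <- seq(1.001, 1.5, length.out = 60)
    expect_true(all(diff(instantaneous_uniaxial_stress(lam, og)) > 0))
  }
})

test_that("small-strain shear modulus is the sum of mu and the slope limit", {
  expect_equal(small_strain_shear_modulus(ogden_parameters(1.81, 10.1)),
               1.81)
  expect_equal(small_strain_shear_modulus(
    ogden_parameters(c(1, 0.5), c(2, -3))), 1.5)
  for (og in list(ogden_parameters(1.81, 10.1),
                  ogden_parameters(c(1, 0.5), c(2, -3)))) {
    slope <- instantaneous_shear_stress(1e-8, og) / 1e-8
    expect_equal(slope, small_strain_shear_modulus(og), tolerance = 1e-6)
  }
})
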