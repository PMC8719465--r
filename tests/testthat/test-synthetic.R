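test_that("reference designs and materials carry the study structure", {
  d <- preset_designs()
  expect_equal(d$brain_shear$n, 6L)
  expect_equal(d$brain_shear$rates, c(0.01, 150, 300))
  expect_equal(d$brain_shear$max_strain, 8 / 7)
  expect_equal(d$vessel_tension$n, 12L)
  expect_equal(d$vessel_tension$max_strain, 1.3)
  expect_identical(d$vessel_tension$mode, "uniaxial_tension")
  m <- preset_materials()
  expect_equal(m$cerebrum$ogden$mu, 1.81)
  expect_equal(m$cerebrum$ogden$alpha, 10.1)
  expect_equal(m$cerebrum$prony$g, 0.99)
  expect_equal(1 / m$cerebrum$prony$tau, 0.276)
  expect_null(m$dura$prony)
  expect_null(m$skull$ogden)
  expect_equal(m$skull$elastic_modulus, 2.00)
})

test_that("noise-free generation reproduces the true curve exactly", {
  mat <- preset_materials()$cerebrum
  d <- experiment_design("simple_shear", c(0.01, 300), n = 3,
                         max_strain = 1.0, n_points = 21)
  reps <- generate_replicates(mat, d, noise_model(a = 0, b = 0),
                              n_steps = 200)
  for (j in seq_along(reps$rates))
    for (cv in reps$curves[[j]])
      expect_identical(cv$stress, reps$truth[[j]]$stress)
})

test_that("generation is byte-identical for a fixed seed", {
  mat <- preset_materials()$brainstem
  d <- experiment_design("simple_shear", c(0.01, 150), n = 4,
                         max_strain = 1.0, n_points = 31)
  r1 <- generate_replicates(mat, d, noise_model(a = 0.05, seed = 7),
                            n_steps = 200)
  r2 <- generate_replicates(mat, d, noise_model(a = 0.05, seed = 7),
                            n_steps = 200)
  expect_identical(r1$curves, r2$curves)
  r3 <- generate_replicates(mat, d, noise_model(a = 0.05, seed = 8),
                            n_steps = 200)
  expect_false(identical(r1$curves, r3$curves))
})

test_that("summaries compute mean and SEM pointwise", {
  mk <- function(stress, k)
    stress_strain_curve("simple_shear", 1, c(0, 0.5), stress, replicate = k)
  reps <- structure(list(mode = "simple_shear", rates = 1,
                         curves = list(list(mk(c(0, 1), 1), mk(c(0, 3), 2))),
                         design = NULL),
                    class = "replicate_set")
  s <- summarize_replicates(reps)[[1]]
  expect_equal(s$stress, c(0, 2))
  expect_equal(s$sem, c(0, 1)) # sd = sqrt(2), sem = sqrt(2)/sqrt(2) = 1
  expect_equal(s$n, 2L)
  # identical replicates: SEM zero everywhere
  reps$curves <- list(list(mk(c(0, 2), 1), mk(c(0, 2), 2)))
  expect_equal(summarize_replicates(reps)[[1]]$sem, c(0, 0))
  # n = 1: SEM must be absent, not zero
  reps$curves <- list(list(mk(c(0, 2), 1)))
  expect_null(summarize_replicates(reps)[[1]]$sem)
})

test_that("the empirical SEM follows the declared noise law", {
  mat <- preset_materials()$cerebrum
  d <- experiment_design("simple_shear", 150, n = 6, max_strain = 1.0,
                         n_points = 21)
  sems <- matrix(0, 100, d$n_points)
  truth <- NULL
  for (s in 1:100) {
    reps <- generate_replicates(mat, d, noise_model(a = 0.05, b = 0,
                                                    seed = s),
                                n_steps = 100)
    sems[s, ] <- summarize_replicates(reps)[[1]]$sem
    truth <- reps$truth[[1]]$stress
  }
  want <- 0.05 * abs(truth) / sqrt(6)
  got <- colMeans(sems)
  idx <- which(want > 1e-9) # skip the zero-stress origin
  expect_true(all(abs(got[idx] - want[idx]) / want[idx] < 0.3))
})

test_that("SEM shrinks as one over the square root of n", {
  mat <- preset_materials()$cerebellum
  ns <- c(3, 6, 12, 24)
  mean_sem <- vapply(ns, function(n) {
    d <- experiment_design("simple_shear", 150, n = n, max_strain = 1.0,
                           n_points = 21)
    vals <- vapply(1:20, function(s) {
      reps <- generate_replicates(mat, d,
                                  noise_model(a = 0.05, b = 0, seed = s),
                                  n_steps = 100)
      mean(summarize_replicates(reps)[[1]]$sem[-1])
    }, numeric(1))
    mean(vals)
  }, numeric(1))
  slope <- coef(lm(log(mean_sem) ~ log(ns)))[2]
  expect_lt(abs(slope + 0.5), 0.1)
})

test_that("mean-vs-truth coverage at three SEM matches the t oracle", {
  # with n = 6 Gaussian replicates, (mean - truth)/SEM is t_5 distributed,
  # so the 3-SEM band covers the truth with probability 2*pt(3, 5) - 1
  expected <- 2 * stats::pt(3, df = 5) - 1 # ~0.970
  mat <- preset_materials()$brainstem
  d <- experiment_design("simple_shear", 300, n = 6, max_strain = 1.0,
                         n_points = 21)
  inside <- total <- 0
  for (s in 1:100) {
    reps <- generate_replicates(mat, d, noise_model(a = 0.05, b = 0,
                                                    seed = s),
                                n_steps = 100)
    sm <- summarize_replicates(reps)[[1]]
    truth <- reps$truth[[1]]$stress
    idx <- which(sm$sem > 0)
    inside <- inside + sum(abs(sm$stress[idx] - truth[idx]) <=
                             3 * sm$sem[idx])
    total <- total + length(idx)
  }
  expect_gte(inside / total, 0.95)
  expect_lt(abs(inside / total - expected), 0.02)
})
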