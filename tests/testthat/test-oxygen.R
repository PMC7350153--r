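test_that("forward solver reproduces closed-form limits", {
  # no consumption, equal boundaries: uniform concentration, no flux
  flat <- forward_profile(oxygen_model(Vmax = 0, C_bottom = 1))
  expect_equal(flat$concentration, rep(1, length(flat$depth)), tolerance = 1e-9)

  # zero-order limit: C(z) = C0 - Vmax/(2D) z (L - z), error < 0.1% of C0
  m <- oxygen_model(L = 400, delta_top = 0, C_top_far = 1, C_bottom = 1,
                    Vmax = 0.05, Km = 1e-6)
  p <- forward_profile(m)
  ana <- 1 - m$Vmax / (2 * m$D_tissue) * p$depth * (m$L - p$depth)
  expect_lt(max(abs(p$concentration - ana)), 1e-3)

  # symmetric supply: trough at mid-depth (200 µm for a 400 µm slice)
  expect_lt(abs(p$depth[which.min(p$concentration)] - 200), 5)

  expect_error(forward_profile(m, n_grid = 3), "n_grid")
  expect_error(oxygen_model(L = -1), "L")
  expect_error(oxygen_model(Vmax = -2), "Vmax")
})

test_that("forward solutions obey the maximum principle and deepen monotonically with consumption", {
  set.seed(20)
  for (i in 1:15) {
    m <- oxygen_model(L = stats::runif(1, 200, 500),
                      D_tissue = stats::runif(1, 800, 2500),
                      delta_top = stats::runif(1, 0, 200),
                      C_top_far = 1,
                      C_bottom = stats::runif(1, 0, 1),
                      Vmax = stats::runif(1, 0, 0.3),
                      Km = stats::runif(1, 0.001, 0.05))
    p <- forward_profile(m)
    expect_true(all(p$concentration >= 0))
    expect_lte(max(p$concentration), max(m$C_top_far, m$C_bottom) + 1e-9)
  }

  los <- vapply(c(0.01, 0.03, 0.06, 0.12), function(v)
    lowest_o2(forward_profile(oxygen_model(Vmax = v))), numeric(1))
  expect_true(all(diff(los) < 0))
})

test_that("halving the grid spacing leaves the solution unchanged to 0.01%", {
  m <- oxygen_model(Vmax = 0.05)
  p1 <- forward_profile(m, n_grid = 401L)
  p2 <- forward_profile(m, n_grid = 801L)
  on_common <- p2$concentration[seq(1, 801, by = 2)]
  expect_lt(max(abs(p1$concentration - on_common)) / max(p1$concentration), 1e-4)
})

test_that("lowest_o2 returns the profile minimum in all geometries", {
  expect_equal(lowest_o2(oxygen_profile(0:10, rep(0.7, 11))), 0.7)

  # parabolic zero-order profile: vertex value C0 - Vmax L^2 / (8 D)
  m <- oxygen_model(L = 400, delta_top = 0, C_top_far = 1, C_bottom = 1,
                    Vmax = 0.05, Km = 1e-6)
  expect_equal(lowest_o2(forward_profile(m)),
               1 - 0.05 * 400^2 / (8 * 1500), tolerance = 1e-3)

  # monotone profile (supply from above only): minimum at the deepest point
  mono <- forward_profile(oxygen_model(Vmax = 0, C_bottom = 0.3))
  expect_equal(lowest_o2(mono), mono$concentration[length(mono$depth)])
})

test_that("CMRO2 inversion is exact on noiseless data and robust to fixed-Km misspecification", {
  truth <- oxygen_model(Vmax = 0.05)
  prof <- gen_oxygen_profile(truth, seq(0, 400, by = 5), noise_sd = 0, seed = 1)
  fit <- fit_cmro2(prof, oxygen_model())
  expect_true(fit$converged)
  expect_lt(abs(fit$CMRO2_hat - 0.05) / 0.05, 1e-4)
  expect_lt(fit$residual_rms, 1e-4)
  expect_equal(fit$lowest_O2, lowest_o2(forward_profile(truth)), tolerance = 1e-3)

  # profiles generated with Km perturbed ±50% still yield Vmax within 15%
  for (km_fac in c(0.5, 1.5)) {
    tr <- oxygen_model(Vmax = 0.05, Km = 0.01 * km_fac)
    pr <- gen_oxygen_profile(tr, seq(0, 400, by = 5), noise_sd = 0, seed = 2)
    f <- fit_cmro2(pr, oxygen_model())   # template keeps Km = 0.01
    expect_lt(abs(f$CMRO2_hat - 0.05) / 0.05, 0.15)
  }

  expect_error(fit_cmro2(oxygen_profile(c(0, 100, 200), c(1, 0.5, 0.6)),
                         oxygen_model()), "10 depth")
  expect_error(fit_cmro2(prof, oxygen_model(), free = "Km"), "free")
})

test_that("joint Vmax + C_bottom fitting recovers both parameters", {
  truth <- oxygen_model(Vmax = 0.08, C_bottom = 0.35)
  prof <- gen_oxygen_profile(truth, seq(0, 400, by = 5), noise_sd = 0, seed = 3)
  fit <- fit_cmro2(prof, oxygen_model(), free = c("Vmax", "C_bottom"))
  expect_true(fit$converged)
  expect_lt(abs(fit$CMRO2_hat - 0.08) / 0.08, 1e-3)
  expect_lt(abs(fit$C_bottom_hat - 0.35) / 0.35, 1e-3)
  expect_named(coef(fit), c("Vmax", "C_bottom"))
})

test_that("the model object supports the standard fitted-model verbs", {
  truth <- oxygen_model(Vmax = 0.05)
  prof <- gen_oxygen_profile(truth, seq(0, 400, by = 10), noise_sd = 0.02,
                             seed = 4)
  fit <- fit_cmro2(prof, oxygen_model())
  expect_equal(unname(coef(fit)["Vmax"]), fit$CMRO2_hat)
  expect_length(predict(fit), length(prof$depth))
  expect_equal(predict(fit, depth = c(0, 200)),
               predict(fit)[c(1, 21)], tolerance = 1e-6)
  expect_equal(residuals(fit), prof$concentration - fitted(fit))
  sims <- simulate(fit, nsim = 2, seed = 9)
  expect_length(sims, 2)
  expect_s3_class(sims[[1]], "oxygen_profile")
  expect_output(print(summary(fit)), "multi-start")
})

test_that("CMRO2 contrasts report fold and percent change", {
  expect_equal(cmro2_contrast(2, 2), list(fold_change = 1, percent_change = 0))
  expect_equal(cmro2_contrast(1.09 * 3, 3)$percent_change, 9, tolerance = 1e-9)
  expect_equal(cmro2_contrast(1.5 * 3, 3)$fold_change, 1.5, tolerance = 1e-9)
  expect_error(cmro2_contrast(1, 0), "zero")
})
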