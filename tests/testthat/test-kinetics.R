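test_that("initial velocity: unit conversion, flat trace, curved trace", {
  t <- seq(0, 300, by = 10)
  # slope 0.00622 A/min with NADH epsilon 6220 and 1 cm -> exactly 1 uM/min
  a <- 0.05 + 0.00622 / 60 * t
  est <- estimate_initial_velocity(t, a)
  expect_equal(est$v0, 1, tolerance = 1e-9)
  # flat trace -> zero rate
  est0 <- estimate_initial_velocity(t, rep(0.31, length(t)))
  expect_equal(est0$v0, 0)
  # saturating progress curve with instrument-grade noise: v0 within 5%
  for (s in c(3, 7, 11)) {
    tc <- gen_time_course(v0 = 1, duration_s = 300, dt_s = 2, tau_s = 600,
                          noise_sd = 1e-5, seed = s)
    est2 <- estimate_initial_velocity(tc$time_s, tc$A340)
    expect_lt(abs(est2$v0 - 1) / 1, 0.05)
    # the window retreats well before substrate depletion dominates
    expect_lt(est2$n_points, 60)
  }
  # too few points
  expect_error(estimate_initial_velocity(1:3, c(0, 1, 2)), "time points")
})

test_that("Michaelis-Menten fit: exact recovery, noise, scale equivariance", {
  S <- 5000 / 2^(8:0)
  v <- predict_velocity(S, 0, Vmax = 1, Km = 51)
  f <- fit_michaelis_menten(S, v)
  expect_lt(abs(f$Vmax - 1), 1e-6)
  expect_lt(abs(f$Km - 51) / 51, 1e-6)
  # 3% proportional noise, 3 replicates: Km within 3 SE of truth
  set.seed(7)
  S3 <- rep(S, 3)
  v3 <- predict_velocity(S3, 0, Vmax = 1, Km = 51) * (1 + rnorm(27, 0, 0.03))
  f3 <- fit_michaelis_menten(S3, v3)
  expect_lt(abs(f3$Km - 51), 3 * f3$se[["Km"]])
  # velocities x10 -> Vmax x10, Km unchanged
  f10 <- fit_michaelis_menten(S3, 10 * v3)
  expect_equal(f10$Vmax, 10 * f3$Vmax, tolerance = 1e-8)
  expect_equal(f10$Km, f3$Km, tolerance = 1e-8)
})

test_that("global fit recovers noiseless generating parameters", {
  for (nm in names(kin_truths)) {
    tr <- kin_truths[[nm]]
    d <- gen_kinetics_dataset(tr, noise = list(proportional_sd = 0,
                                               additive_sd = 0), seed = 1)
    f <- fit_inhibition_global(d)
    expect_identical(f$mechanism, tr$mechanism)
    for (p in setdiff(names(tr), "mechanism"))
      expect_lt(abs(f$parameters[[p]] - tr[[p]]) / tr[[p]], 1e-4)
  }
})

test_that("global fit recovers noisy parameters within 3 SE and classifies", {
  # GDP-like mixed truths at the standard design, 2% noise
  f <- fit_inhibition_global(gen_kinetics_dataset(kin_truths$GDP, seed = 101))
  expect_identical(f$mechanism, "mixed")
  for (p in c("Ki", "alpha", "beta"))
    expect_lt(abs(f$parameters[[p]] - kin_truths$GDP[[p]]), 3 * f$se[[p]])
  # GMP-like competitive truths
  fc <- fit_inhibition_global(gen_kinetics_dataset(kin_truths$GMP, seed = 102))
  expect_identical(fc$mechanism, "competitive")
  expect_lt(abs(fc$parameters[["Ki"]] - 600), 3 * fc$se[["Ki"]])
  # inhibitor with no effect -> none
  fn <- fit_inhibition_global(gen_kinetics_dataset(
    list(mechanism = "none", Vmax = 1, Km = 51), seed = 103))
  expect_identical(fn$mechanism, "none")
})

test_that("apparent parameters at I = 0 equal the global (Vmax, Km)", {
  f <- fit_inhibition_global(gen_kinetics_dataset(kin_truths$GDP, seed = 104))
  a0 <- f$apparent[f$apparent$I == 0, ]
  expect_equal(a0$Vmax_app, f$parameters[["Vmax"]], tolerance = 0.05)
  expect_equal(a0$Km_app, f$parameters[["Km"]], tolerance = 0.1)
})

test_that("mechanism selection is deterministic and resolves ties simply", {
  sel <- classify_mechanism(c(none = 100, competitive = 50, mixed = 49))
  expect_identical(sel$mechanism, "competitive")  # within delta of the winner
  expect_true(sel$ambiguous)
  sel2 <- classify_mechanism(c(none = 100, competitive = 60, mixed = 49))
  expect_identical(sel2$mechanism, "mixed")
  expect_false(sel2$ambiguous)
  sel3 <- classify_mechanism(c(none = 50.5, competitive = 50, mixed = 49))
  expect_identical(sel3$mechanism, "none")
})

test_that("parameter recovery: median relative errors beat the reported ones", {
  # over 20 seeded simulations at the standard design and 2% noise, the
  # median relative error of Ki, alpha, beta stays below the relative
  # standard errors reported for the corresponding truth set
  rel_reported <- list(GDP = c(Ki = 40 / 210, alpha = 0.8 / 6.5,
                               beta = 0.005 / 0.033),
                       GTP = c(Ki = 40 / 160, alpha = 0.7 / 4.1,
                               beta = 0.05 / 0.24))
  for (nm in names(rel_reported)) {
    tr <- kin_truths[[nm]]
    errs <- sapply(1:20, function(s) {
      f <- fit_inhibition_global(gen_kinetics_dataset(tr, seed = s))
      sapply(c("Ki", "alpha", "beta"),
             function(p) abs(f$parameters[[p]] - tr[[p]]) / tr[[p]])
    })
    med <- apply(errs, 1, median)
    expect_true(all(med < rel_reported[[nm]]),
                info = paste(nm, paste(round(med, 3), collapse = "/")))
  }
})
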