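test_that("rate laws reproduce their closed-form special values", {
  # Michaelis-Menten half saturation, for every mechanism at I = 0
  expect_equal(predict_velocity(51, 0, Vmax = 1, Km = 51), 0.5)
  expect_equal(predict_velocity(51, 0, Vmax = 1, Km = 51, Ki = 600,
                                mechanism = "competitive"), 0.5)
  expect_equal(predict_velocity(51, 0, Vmax = 1, Km = 51, Ki = 210,
                                alpha = 6.5, beta = 0.033,
                                mechanism = "mixed"), 0.5)
  # competitive at S = Km, I = Ki: Km_app doubles -> Vmax/3
  expect_equal(predict_velocity(51, 600, Vmax = 1, Km = 51, Ki = 600,
                                mechanism = "competitive"), 1 / 3)
  # mixed at the GDP-like truths, value frozen from an independent symbolic
  # evaluation of the rate law (6533/20500)
  expect_equal(predict_velocity(51, 210, Vmax = 1, Km = 51, Ki = 210,
                                alpha = 6.5, beta = 0.033,
                                mechanism = "mixed"),
               0.3186829268292683, tolerance = 1e-12)
})

test_that("invalid parameters are rejected", {
  expect_error(predict_velocity(51, 0, Vmax = -1, Km = 51), "Vmax")
  expect_error(predict_velocity(51, 0, Vmax = 1, Km = Inf), "Km")
  expect_error(predict_velocity(51, 10, Vmax = 1, Km = 51, Ki = 210,
                                alpha = 6.5, beta = -0.1,
                                mechanism = "mixed"), "beta")
  expect_error(predict_velocity(-1, 0, Vmax = 1, Km = 51), ">= 0")
})

test_that("apparent parameters obey their identities and limits", {
  p_comp <- list(mechanism = "competitive", Vmax = 1, Km = 51, Ki = 600)
  p_mix <- list(mechanism = "mixed", Vmax = 1, Km = 51, Ki = 210,
                alpha = 6.5, beta = 0.033)
  # identity at I = 0
  a0 <- apparent_parameters(0, p_mix)
  expect_equal(c(a0$Vmax_app, a0$Km_app), c(1, 51))
  # competitive at I = Ki: Km doubles, Vmax unchanged
  ac <- apparent_parameters(600, p_comp)
  expect_equal(c(ac$Vmax_app, ac$Km_app), c(1, 102))
  # mixed saturating limit: Vmax_app -> beta Vmax, Km_app -> alpha Km
  al <- apparent_parameters(1e6 * 210, p_mix)
  expect_equal(al$Vmax_app, 0.033, tolerance = 1e-3)
  expect_equal(al$Km_app, 6.5 * 51, tolerance = 1e-3)
  # mechanism none passes (Vmax, Km) through unchanged at any I
  an <- apparent_parameters(c(0, 500), list(mechanism = "none", Vmax = 2, Km = 30))
  expect_equal(an$Vmax_app, c(2, 2))
  expect_equal(an$Km_app, c(30, 30))
})

test_that("velocity and apparent parameters are mutually consistent", {
  # v(S, I) == Vmax_app(I) S / (Km_app(I) + S) to machine precision
  set.seed(11)
  for (rep in 1:20) {
    p <- list(mechanism = sample(c("competitive", "mixed"), 1),
              Vmax = runif(1, 0.5, 5), Km = runif(1, 10, 200),
              Ki = runif(1, 50, 1000), alpha = runif(1, 1.1, 10),
              beta = runif(1, 0, 0.9))
    S <- runif(5, 1, 5000); I <- runif(1, 0, 5000)
    v <- predict_velocity(S, I, Vmax = p$Vmax, Km = p$Km, Ki = p$Ki,
                          alpha = p$alpha, beta = p$beta,
                          mechanism = p$mechanism)
    ap <- apparent_parameters(I, p)
    expect_equal(v, ap$Vmax_app * S / (ap$Km_app + S), tolerance = 1e-12)
  }
})

test_that("monotonicity: nondecreasing in S, nonincreasing in I", {
  set.seed(22)
  for (rep in 1:20) {
    p <- list(Vmax = runif(1, 0.5, 5), Km = runif(1, 10, 200),
              Ki = runif(1, 50, 1000), alpha = runif(1, 1.01, 20),
              beta = runif(1, 0, 0.99))
    S <- sort(runif(8, 1, 5000)); I <- sort(runif(8, 0, 5000))
    vS <- predict_velocity(S, I[3], Vmax = p$Vmax, Km = p$Km, Ki = p$Ki,
                           alpha = p$alpha, beta = p$beta, mechanism = "mixed")
    expect_true(all(diff(vS) >= -1e-12))
    vI <- predict_velocity(S[4], I, Vmax = p$Vmax, Km = p$Km, Ki = p$Ki,
                           alpha = p$alpha, beta = p$beta, mechanism = "mixed")
    expect_true(all(diff(vI) <= 1e-12))
  }
})

test_that("mixed-model degenerate limits", {
  S <- c(10, 51, 200, 1000); I <- c(0, 100, 1000, 5000)
  # alpha = 1, beta = 1: inhibitor has no effect
  for (ii in I) {
    expect_equal(predict_velocity(S, ii, Vmax = 1, Km = 51, Ki = 210,
                                  alpha = 1, beta = 1, mechanism = "mixed"),
                 predict_velocity(S, 0, Vmax = 1, Km = 51), tolerance = 1e-12)
  }
  # beta = 0, alpha large: approaches the competitive form
  for (alpha in c(1e3, 1e5, 1e7)) {
    vm <- predict_velocity(S, 300, Vmax = 1, Km = 51, Ki = 210,
                           alpha = alpha, beta = 0, mechanism = "mixed")
    vc <- predict_velocity(S, 300, Vmax = 1, Km = 51, Ki = 210,
                           mechanism = "competitive")
    expect_lt(max(abs(vm - vc) / vc), 3 / alpha)
  }
  # I -> infinity limit: beta Vmax S / (alpha Km + S)
  v_inf <- predict_velocity(S, 1e9 * 210, Vmax = 1, Km = 51, Ki = 210,
                            alpha = 6.5, beta = 0.033, mechanism = "mixed")
  expect_equal(v_inf, 0.033 * S / (6.5 * 51 + S), tolerance = 1e-6)
})
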