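test_that("generators are deterministic in the seed", {
  tr <- kin_truths$GDP
  d1 <- gen_kinetics_dataset(tr, seed = 5)
  d2 <- gen_kinetics_dataset(tr, seed = 5)
  expect_identical(d1, d2)
  expect_false(identical(d1$velocity,
                         gen_kinetics_dataset(tr, seed = 6)$velocity))
  t1 <- gen_itc_titration(itc_truths$apo, seed = 5)
  t2 <- gen_itc_titration(itc_truths$apo, seed = 5)
  expect_identical(t1$heats, t2$heats)
  s1 <- gen_saxs_series(gen_bead_assembly("tetramer"), concentrations = 5,
                        seed = 5)
  s2 <- gen_saxs_series(gen_bead_assembly("tetramer"), concentrations = 5,
                        seed = 5)
  expect_identical(s1[[1]]$I, s2[[1]]$I)
})

test_that("generators do not disturb the global RNG stream", {
  set.seed(99); a <- rnorm(1)
  set.seed(99)
  invisible(gen_kinetics_dataset(kin_truths$GMP, seed = 1))
  invisible(gen_itc_titration(itc_truths$apo, seed = 1))
  b <- rnorm(1)
  expect_identical(a, b)
})

test_that("zero-noise datasets equal the model predictions exactly", {
  tr <- kin_truths$GDP
  d <- gen_kinetics_dataset(tr, noise = list(proportional_sd = 0,
                                             additive_sd = 0), seed = 1)
  v_true <- predict_velocity(d$substrate, d$inhibitor, Vmax = tr$Vmax,
                             Km = tr$Km, Ki = tr$Ki, alpha = tr$alpha,
                             beta = tr$beta, mechanism = "mixed")
  expect_equal(d$velocity, v_true)
  tt <- gen_itc_titration(itc_truths$apo, noise = list(proportional_sd = 0),
                          seed = 1)
  expect_equal(tt$heats,
               single_site_heats(tt$protocol, 1, 1 / 1.7e-6, -26.4))
  ser <- gen_saxs_series(gen_bead_assembly("tetramer"),
                         concentrations = c(2, 8),
                         noise = list(proportional_sd = 0), seed = 1)
  expect_equal(ser[[1]]$I / 2, ser[[2]]$I / 8, tolerance = 1e-12)
})

test_that("empirical noise matches the requested magnitude", {
  # proportional kinetics noise: sd of v/v_true - 1 within 10% of nominal
  tr <- list(mechanism = "none", Vmax = 1, Km = 51)
  d <- gen_kinetics_dataset(tr, noise = list(proportional_sd = 0.02,
                                             additive_sd = 0),
                            design = kinetics_design(replicates = 200),
                            seed = 8)
  v_true <- predict_velocity(d$substrate, 0, Vmax = 1, Km = 51)
  expect_lt(abs(sd(d$velocity / v_true - 1) - 0.02) / 0.02, 0.10)
  # replicate mean converges to the prediction (law of large numbers)
  cell <- d$substrate == max(d$substrate)
  m <- mean(d$velocity[cell]); sem <- sd(d$velocity[cell]) / sqrt(sum(cell))
  expect_lt(abs(m - v_true[cell][1]), 3 * sem)
})

test_that("generated files round-trip bit-exactly through the readers", {
  tmp <- tempfile(fileext = ".csv")
  d <- gen_kinetics_dataset(kin_truths$GMP, seed = 3, inhibitor_id = "GMP")
  write_kinetics_table(d, tmp)
  d2 <- read_kinetics_table(tmp)
  expect_equal(as.data.frame(d2), as.data.frame(d), tolerance = 1e-12)
  expect_identical(attr(d2, "inhibitor_id"), "GMP")

  tmp2 <- tempfile(fileext = ".csv"); tmp2y <- tempfile(fileext = ".yaml")
  tt <- gen_itc_titration(itc_truths$GTP, seed = 3)
  write_itc_table(tt, tmp2, protocol_path = tmp2y)
  tt2 <- read_itc_table(tmp2, tmp2y)
  expect_equal(tt2$heats, tt$heats, tolerance = 1e-12)
  expect_equal(tt2$molar_ratios, tt$molar_ratios, tolerance = 1e-12)

  tmp3 <- tempfile(fileext = ".dat")
  cv <- gen_saxs_series(gen_bead_assembly("tetramer"), concentrations = 5,
                        seed = 3)[[1]]
  write_saxs_dat(cv, tmp3)
  cv2 <- read_saxs_dat(tmp3)
  expect_equal(cv2$I, cv$I, tolerance = 1e-7)
  expect_equal(attr(cv2, "concentration"), 5)
  # identical seed, identical bytes
  tmp4 <- tempfile(fileext = ".dat")
  write_saxs_dat(gen_saxs_series(gen_bead_assembly("tetramer"),
                                 concentrations = 5, seed = 3)[[1]], tmp4)
  expect_identical(readLines(tmp3), readLines(tmp4))
})

test_that("progress-curve generator hits the requested initial slope", {
  tc <- gen_time_course(v0 = 2.5, tau_s = Inf)
  est <- estimate_initial_velocity(tc$time_s, tc$A340)
  expect_equal(est$v0, 2.5, tolerance = 1e-9)
})
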