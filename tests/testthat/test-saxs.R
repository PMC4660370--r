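q400 <- seq(0.005, 0.35, length.out = 400)

test_that("Guinier fit is exact on an ideal Guinier curve", {
  cv <- scattering_curve(q400, 100 * exp(-q400^2 * 45.1^2 / 3))
  gf <- guinier_fit(cv)
  expect_equal(gf$Rg, 45.1, tolerance = 1e-8)
  expect_equal(gf$I0, 100, tolerance = 1e-8)
  expect_lte(gf$qRg_max, 1.3)
  expect_gte(gf$n_points, 8)
})

test_that("Guinier Rg of a sphere is R sqrt(3/5)", {
  cv <- scattering_curve(q400, oracle_sphere_curve(q400, 30))
  gf <- suppressWarnings(guinier_fit(cv))
  expect_lt(abs(gf$Rg - 30 * sqrt(3 / 5)) / (30 * sqrt(3 / 5)), 0.01)
  # with 1% noise, within 3%
  set.seed(5)
  I <- oracle_sphere_curve(q400, 30)
  cvn <- scattering_curve(q400, I * (1 + rnorm(400, 0, 0.01)),
                          sigma = 0.01 * I)
  gfn <- guinier_fit(cvn)
  expect_lt(abs(gfn$Rg - 30 * sqrt(3 / 5)) / (30 * sqrt(3 / 5)), 0.03)
})

test_that("IFT recovers the sphere pair-distance distribution", {
  R <- 40
  cv <- scattering_curve(q400, oracle_sphere_curve(q400, R))
  pr <- ift_pofr(cv, Dmax = 2 * R)
  pth <- oracle_sphere_pofr(pr$r, R)
  s <- sum(pr$p * pth) / sum(pth^2)
  nrmsd <- sqrt(mean((pr$p - s * pth)^2)) / max(s * pth)
  expect_lt(nrmsd, 0.05)
  expect_lt(abs(pr$Rg_pr - R * sqrt(3 / 5)) / (R * sqrt(3 / 5)), 0.02)
  # endpoint constraints hold
  expect_equal(pr$p[1], 0)
  expect_equal(pr$p[length(pr$p)], 0)
  expect_true(all(pr$p >= 0))
})

test_that("IFT is linear in the intensity scale", {
  cv <- scattering_curve(q400, oracle_sphere_curve(q400, 40))
  cv5 <- scattering_curve(q400, 5 * cv$I)
  pr <- ift_pofr(cv, 80, lambda = 1e-4)
  pr5 <- ift_pofr(cv5, 80, lambda = 1e-4)
  expect_equal(pr5$p, 5 * pr$p, tolerance = 1e-3)
  expect_equal(pr5$Rg_pr, pr$Rg_pr, tolerance = 1e-6)
})

test_that("IFT refuses the unregularized system", {
  cv <- scattering_curve(q400, oracle_sphere_curve(q400, 40))
  expect_error(ift_pofr(cv, 80, lambda = 0), "ill-conditioned")
  expect_error(ift_pofr(scattering_curve(q400[1:20], cv$I[1:20]), 80),
               "q range")
})

test_that("Dmax estimation: sphere, dumbbell, scale equivariance", {
  cv <- scattering_curve(q400, oracle_sphere_curve(q400, 40))
  dm <- suppressWarnings(estimate_dmax(cv))
  expect_lt(abs(dm$Dmax - 80) / 80, 0.10)
  # dumbbell: two R = 20 spheres, centers 100 A apart -> Dmax 140
  db <- bead_model(rbind(c(0, 0, 0), c(100, 0, 0)), 20)
  dmd <- suppressWarnings(estimate_dmax(debye_profile(db, q400)))
  expect_lt(abs(dmd$Dmax - 140) / 140, 0.10)
  # doubling all distances doubles the estimate
  db2 <- bead_model(rbind(c(0, 0, 0), c(200, 0, 0)), 40)
  dmd2 <- suppressWarnings(estimate_dmax(debye_profile(db2, q400)))
  expect_equal(dmd2$Dmax / dmd$Dmax, 2, tolerance = 0.1)
})

test_that("Porod volume of a sphere is within 10% of the true volume", {
  cv <- scattering_curve(q400, oracle_sphere_curve(q400, 40))
  po <- porod_volume(cv, guinier = suppressWarnings(guinier_fit(cv)))
  expect_lt(abs(po$Vp - 4 / 3 * pi * 40^3) / (4 / 3 * pi * 40^3), 0.10)
})

test_that("Porod mass conversion reproduces the reference rows", {
  expect_identical(mw_from_porod(807586), 485)
  expect_identical(mw_from_porod(298568), 179)
  expect_identical(mw_from_porod(0), 0)
})

test_that("the analysis chain is invariant to intensity scaling", {
  tet <- gen_bead_assembly("tetramer")
  cv <- debye_profile(tet, q400)
  cvs <- scattering_curve(q400, 7 * cv$I)
  g1 <- guinier_fit(cv); g2 <- guinier_fit(cvs)
  expect_equal(g2$Rg, g1$Rg, tolerance = 1e-9)
  p1 <- porod_volume(cv, g1); p2 <- porod_volume(cvs, g2)
  expect_equal(p2$Vp, p1$Vp, tolerance = 1e-9)
  expect_identical(classify_oligomer(p1$mw_kDa, 57)$state,
                   classify_oligomer(p2$mw_kDa, 57)$state)
})

test_that("profile scaling: identity, known factor, noisy chi2 near 1", {
  tet <- gen_bead_assembly("tetramer")
  th <- debye_profile(tet, q400)
  th$sigma <- rep(1, 400)
  fs <- fit_profile_scale(th, th)
  expect_equal(fs$scale, 1)
  expect_equal(fs$chi2_reduced, 0)
  th5 <- scattering_curve(q400, 5 * th$I)
  expect_equal(fit_profile_scale(th, th5)$scale, 1 / 5, tolerance = 1e-12)
  # seeded noisy synthetic octamer curve against its own model: chi2 ~ 1
  oct <- gen_bead_assembly("octamer")
  ser <- gen_saxs_series(oct, concentrations = 5, seed = 9)
  fso <- fit_profile_scale(ser[[1]], debye_profile(oct, q400))
  expect_gt(fso$chi2_reduced, 0.5)
  expect_lt(fso$chi2_reduced, 2)
})

test_that("oligomer classification thresholds", {
  expect_identical(classify_oligomer(241, 57)$state, "tetramer")
  expect_identical(classify_oligomer(485, 57)$state, "octamer")
  expect_identical(classify_oligomer(8 * 57, 57)$state, "octamer")
  expect_identical(classify_oligomer(350, 57)$state, "other")
  expect_error(classify_oligomer(200, -1), "monomer")
})

test_that("infinite-dilution extrapolation recovers the ideal curve", {
  tet <- gen_bead_assembly("tetramer")
  base <- debye_profile(tet, q400)
  # exact linear concentration dependence -> intercept recovered exactly
  concs <- c(1.25, 2.5, 5, 10, 20)
  series <- lapply(concs, function(cc)
    scattering_curve(q400, cc * base$I * (1 - 0.004 * cc),
                     concentration = cc))
  ext <- extrapolate_infinite_dilution(series)
  expect_equal(ext$I, base$I, tolerance = 1e-9)
  # identical I/c across concentrations -> output equals I/c
  series2 <- lapply(concs, function(cc)
    scattering_curve(q400, cc * base$I, concentration = cc))
  ext2 <- extrapolate_infinite_dilution(series2)
  expect_equal(ext2$I, base$I, tolerance = 1e-9)
  # single concentration: normalized with a warning
  expect_warning(ext1 <- extrapolate_infinite_dilution(series[1]),
                 "single concentration")
  expect_equal(ext1$I, base$I * (1 - 0.004 * 1.25), tolerance = 1e-9)
  # noisy structure-factor series: the chain undoes the attenuation
  ser <- gen_saxs_series(tet, k_sf = 0.004, seed = 21)
  extn <- extrapolate_infinite_dilution(ser)
  gf <- guinier_fit(extn)
  expect_lt(abs(gf$Rg - 45.3) / 45.3, 0.03)
})

test_that("Guinier and p(r) radii agree on synthetic bodies", {
  for (st in c("tetramer", "octamer")) {
    m <- gen_bead_assembly(st)
    cv <- debye_profile(m, q400)
    gf <- guinier_fit(cv)
    dm <- suppressWarnings(estimate_dmax(cv))
    expect_lt(abs(dm$pofr$Rg_pr - gf$Rg) / gf$Rg, 0.03)
  }
})
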