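mono <- terpene_solubility("mono")
binary <- terpene_solubility("binary")

test_that("harmonic mean temperature", {
  expect_equal(harmonic_mean_T(rep(300, 5)), 300)
  expect_equal(harmonic_mean_T(c(200, 600)), 300)
  expect_error(harmonic_mean_T(numeric(0)))
  expect_error(harmonic_mean_T(c(300, -1)))
})

test_that("van't Hoff regression is exact on log-linear data", {
  Tg <- seq(295, 340, length.out = 10)
  Thm <- harmonic_mean_T(Tg)
  x <- exp(-1.5 - 1800 * (1 / Tg - 1 / Thm))
  ds <- solubility_dataset(Tg, x, system = "synthetic")
  r <- vanthoff_regression(ds)
  expect_equal(r$slope, -1800, tolerance = 1e-10)
  expect_equal(r$intercept, -1.5, tolerance = 1e-10)
  # recentring moves only the intercept
  r2 <- vanthoff_regression(ds, Thm = 320)
  expect_equal(r2$slope, r$slope, tolerance = 1e-9)
  expect_error(vanthoff_regression(
    solubility_dataset(c(300, 310), c(0.1, 0.11))), "3 points")
})

test_that("dissolution thermodynamics identities hold", {
  th <- solution_thermodynamics(-1952.4405, -1.9770, 318.8)
  expect_equal(th$dG + 318.8 * th$dS, th$dH, tolerance = 1e-9)
  expect_equal(solution_thermodynamics(0, 0, 300), list(dH = 0, dG = 0, dS = 0))
  w <- enthalpy_entropy_weights(5000, 5000 / 300, 300)
  expect_equal(w$deltaH, 0.5)
  expect_error(enthalpy_entropy_weights(0, 0, 300), "zero")
})

test_that("the full summary reproduces the published monosolvent table", {
  ref <- list(
    "(-)-alpha-pinene" = c(-1.9770, -1952.4405, 5.2401, 16.2326, 34.4791,
                           0.5962, 0.4038),
    "p-cymene" = c(-1.5221, -1088.8702, 4.0412, 9.05287, 15.6937,
                   0.6437, 0.3563),
    "(-)-beta-caryophyllene" = c(-1.9576, -1859.7423, 5.2090, 15.4619,
                                 32.0347, 0.6013, 0.3987),
    "p-cymene + (-)-beta-caryophyllene" = c(-1.6522, -1277.2243, 4.3636,
                                            10.6188, 19.6920, 0.6293, 0.3707))
  for (nm in names(ref)) {
    d <- if (nm %in% names(mono)) mono[[nm]] else binary[[nm]]
    th <- solution_thermo(d)
    got <- c(th$intercept, th$slope, th$dG_kJ, th$dH_kJ, th$dS_J,
             th$deltaH, th$deltaTS)
    expect_equal(got, ref[[nm]], tolerance = 5e-4, label = nm)
  }
})

test_that("dissolution is enthalpy-dominated heat absorption in all systems", {
  for (d in c(mono, binary)) {
    th <- solution_thermo(d)
    expect_gt(th$dH_kJ, 0)
    expect_gt(th$dS_J, 0)
    expect_gt(th$deltaH, th$deltaTS)
    expect_equal(th$deltaH + th$deltaTS, 1, tolerance = 1e-12)
    expect_true(th$Thm >= min(d$T_K) && th$Thm <= max(d$T_K))
  }
})
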