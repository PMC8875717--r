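sol <- dha_properties()

test_that("Apelblat and van't Hoff forward curves behave", {
  expect_equal(apelblat_x(300, 0, 0, 0), 1)
  expect_equal(apelblat_x(312.7, 2.1, -800, 0), vanthoff_x(312.7, 2.1, -800))
  # published parameter set for (-)-alpha-pinene at the lowest temperature
  expect_equal(apelblat_x(299.45, tab4_apelblat_alpha["A"],
                          tab4_apelblat_alpha["B"], tab4_apelblat_alpha["C"]),
               0.09402, tolerance = 2e-4, ignore_attr = TRUE)
  expect_equal(vanthoff_x(300, 0, 0), 1)
  expect_error(apelblat_x(-1, 1, 1, 1), "positive")
})

test_that("lambda-h closed form inverts its defining equation", {
  expect_equal(lambdah_x(443.22, 0.7, 2500, 443.22), 1)
  # lambda = 1 collapses to the ideal/van't Hoff-type form
  expect_equal(lambdah_x(310, 1, 2500, 443.22),
               exp(-2500 * (1 / 310 - 1 / 443.22)), tolerance = 1e-12)
  # substituting x back reproduces lambda*h*(1/T - 1/Tm) to 1e-12
  for (p in list(c(0.63102, 2847.00662), c(0.2, 5000), c(3, 900))) {
    Tv <- c(299.45, 315, 340)
    x <- lambdah_x(Tv, p[1], p[2], 443.22)
    lhs <- log(1 + p[1] * (1 - x) / x)
    expect_equal(lhs, p[1] * p[2] * (1 / Tv - 1 / 443.22), tolerance = 1e-12)
  }
  expect_error(lambdah_x(450, 0.7, 2500, 443.22), "melting")
  expect_error(lambdah_x(310, -1, 2500, 443.22), "lambda")
})

test_that("ideal solubility hits its limits and is monotone", {
  expect_equal(ideal_solubility(443.22, sol), 1)
  expect_equal(ideal_solubility(299.45, sol),
               exp(-(17190 / R_GAS) * (1 / 299.45 - 1 / 443.22)),
               tolerance = 1e-12)
  Tg <- seq(250, 443, by = 1)
  expect_true(all(diff(ideal_solubility(Tg, sol)) > 0))
  expect_error(ideal_solubility(450, sol), "melting")
})

test_that("NRTL activity coefficients match their Gibbs-energy origin", {
  expect_equal(nrtl_gamma(0.3, 310, 0, 0), list(gamma1 = 1, gamma2 = 1))
  # infinite-dilution closed form
  tau12 <- 4616.96557 / (R_GAS * 300); tau21 <- -2402.45933 / (R_GAS * 300)
  expect_equal(log(nrtl_gamma(1e-12, 300, 4616.96557, -2402.45933)$gamma1),
               tau21 + tau12 * exp(-0.3 * tau12), tolerance = 1e-8)
  # gamma1 from the closed form equals the numeric derivative of gE
  gE_RT <- function(x1, Tv, dg12, dg21, a = 0.3) {
    x2 <- 1 - x1
    t12 <- dg12 / (R_GAS * Tv); t21 <- dg21 / (R_GAS * Tv)
    G12 <- exp(-a * t12); G21 <- exp(-a * t21)
    x1 * x2 * (t12 * G12 / (x2 + x1 * G12) + t21 * G21 / (x1 + x2 * G21))
  }
  for (dg in list(c(4616.97, -2402.46), c(-1500, 3000), c(800, 800))) {
    h <- 1e-6; x1 <- 0.35; Tv <- 312
    fp <- (gE_RT(x1 + h, Tv, dg[1], dg[2]) -
           gE_RT(x1 - h, Tv, dg[1], dg[2])) / (2 * h)
    lng1 <- gE_RT(x1, Tv, dg[1], dg[2]) + (1 - x1) * fp
    expect_equal(log(nrtl_gamma(x1, Tv, dg[1], dg[2])$gamma1), lng1,
                 tolerance = 1e-6)
  }
})

test_that("UNIQUAC structural parameters come from group sums", {
  expect_equal(uniquac_rq(c(CH3 = 1), data.frame(group = "CH3", R = 1, Q = 1)),
               list(r = 1, q = 1))
  hexane <- uniquac_rq(c(CH3 = 2, CH2 = 4))
  expect_equal(hexane$r, 4.4998, tolerance = 1e-4)
  expect_equal(hexane$q, 3.856, tolerance = 1e-4)
  doubled <- uniquac_rq(c(CH3 = 4, CH2 = 8))
  expect_equal(doubled$r, 2 * hexane$r)
  expect_equal(doubled$q, 2 * hexane$q)
  expect_error(uniquac_rq(c(XYZ = 1)), "unknown subgroup")
})

test_that("UNIQUAC gamma has the ideal limit and relabeling symmetry", {
  g <- uniquac_gamma(0.4, 310, 0, 0, r = c(3, 3), q = c(2.5, 2.5))
  expect_equal(g$gamma1, 1, tolerance = 1e-12)
  expect_equal(g$gamma2, 1, tolerance = 1e-12)
  a <- uniquac_gamma(0.3, 310, 1500, -700, r = c(5, 3), q = c(4, 2.5))
  b <- uniquac_gamma(0.7, 310, -700, 1500, r = c(3, 5), q = c(2.5, 4))
  expect_equal(a$gamma1, b$gamma2, tolerance = 1e-12)
  expect_equal(a$gamma2, b$gamma1, tolerance = 1e-12)
  expect_error(uniquac_gamma(0.3, 310, 0, 0, r = c(-1, 3), q = c(2, 2)),
               "positive")
})

test_that("both gamma models satisfy Gibbs-Duhem at interior compositions", {
  rqs <- compound_rq("dehydroabietic acid")
  rqv <- compound_rq("(-)-alpha-pinene")
  cases <- list(
    function(x) nrtl_gamma(x, 310, 3000, -1500),
    function(x) nrtl_gamma(x, 299, -2000, 5000),
    function(x) uniquac_gamma(x, 310, 2789.6, -1207.9,
                              c(rqs$r, rqv$r), c(rqs$q, rqv$q)),
    function(x) uniquac_gamma(x, 330, -900, 2500, c(4, 6), c(3, 5)))
  for (gf in cases)
    for (x1 in c(0.15, 0.3, 0.6))
      expect_lt(abs(gibbs_duhem_resid(gf, x1)), 1e-5)
})

test_that("the SLE solver matches a bisection oracle", {
  # trivial gamma: constant activity coefficients scale the ideal curve
  expect_equal(sle_solve_x(function(x, Tv) 1, 310, sol),
               ideal_solubility(310, sol), tolerance = 1e-9)
  expect_equal(sle_solve_x(function(x, Tv) 2, 310, sol),
               ideal_solubility(310, sol) / 2, tolerance = 1e-9)
  set.seed(42)
  for (i in 1:20) {
    dg <- stats::runif(2, -4000, 6000)
    Tv <- stats::runif(1, 298, 335)
    gfun <- function(x, Tv2) nrtl_gamma(x, Tv2, dg[1], dg[2])$gamma1
    x_fp <- sle_solve_x(gfun, Tv, sol)
    x_id <- ideal_solubility(Tv, sol)
    x_bi <- stats::uniroot(function(x) x * gfun(x, Tv) - x_id,
                           c(1e-10, 1 - 1e-9), tol = 1e-13)$root
    expect_equal(x_fp, x_bi, tolerance = 1e-8)
  }
})

test_that("Wilson mixing rules honour their pure-solvent boundaries", {
  expect_equal(wilson_xm(1, 0.2, 0.1, -1.3, -1.8), 0.2, tolerance = 1e-12)
  expect_equal(wilson_xm(0, 0.2, 0.1, -1.3, -1.8), 0.1, tolerance = 1e-12)
  # unit cross parameters with equal pure solubilities are transparent
  expect_equal(wilson_xm(0.5, 0.17, 0.17, 1, 1), 0.17, tolerance = 1e-12)
  expect_error(wilson_xm(0.5, 0.2, 0.1, -1, 2), "singular")
  # van't Hoff variant equals the generic rule fed the same pure curves
  A1 <- 4.14712; B1 <- -1952.44054; A2 <- 1.88763; B2 <- -1088.87019
  Tv <- c(300, 320)
  expect_equal(wilson_vanthoff_xm(0.4, Tv, A1, B1, A2, B2, 0.8, 1.4),
               wilson_xm(0.4, vanthoff_x(Tv, A1, B1), vanthoff_x(Tv, A2, B2),
                         0.8, 1.4), tolerance = 1e-12)
})

test_that("every model's curve rises with temperature on the fitted sets", {
  ap <- terpene_solubility("mono")[["(-)-alpha-pinene"]]
  Tg <- seq(295, 340, by = 0.5)
  for (m in c("apelblat", "lambdah", "vanthoff", "nrtl")) {
    f <- fit_solubility(ap, m)
    expect_true(all(diff(predict(f, Tg)) > 0), label = paste(m, "monotone"))
  }
})
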