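mono <- terpene_solubility("mono")
ap <- mono[["(-)-alpha-pinene"]]

test_that("deviation metrics implement the signed-relative conventions", {
  perfect <- deviation_metrics(c(0.1, 0.2), c(0.1, 0.2))
  expect_equal(perfect$rd, c(0, 0))
  expect_equal(perfect$ard, 0)
  expect_equal(perfect$rmsd, 0)
  one <- deviation_metrics(0.1, 0.09)
  expect_equal(one$rd, 0.1)
  expect_equal(one$ard, 0.1)
  expect_equal(one$rmsd, 0.01)
  # the published calculated column reproduces the published summary metrics
  col <- deviation_metrics(ap$x_exp, tab1_apelblat_col)
  expect_equal(100 * col$ard, 0.297, tolerance = 2e-3)
  expect_equal(1000 * col$rmsd, 0.492, tolerance = 2e-3)
  expect_error(deviation_metrics(c(0.1, 0.2), 0.1), "length")
  expect_error(deviation_metrics(0, 0.1), "positive")
})

test_that("Apelblat refit reproduces the published fit", {
  fit <- fit_solubility(ap, "apelblat")
  expect_s3_class(fit, "sle_fit")
  expect_equal(100 * fit$ard, 0.29696, tolerance = 0.005 / 0.29696)
  expect_equal(1000 * fit$rmsd, 0.49179, tolerance = 0.01 / 0.49179)
  # the calculated-solubility surface is the contract: pointwise 2e-4
  expect_lt(max(abs(fit$x_cal - tab1_apelblat_col)), 2e-4)
  expect_equal(unname(coef(fit)), unname(tab4_apelblat_alpha), tolerance = 1e-4)
  expect_true(fit$converged)
})

test_that("van't Hoff fits agree across objectives and with the table", {
  for (i in seq_len(nrow(tab9_vanthoff))) {
    f <- fit_solubility(mono[[tab9_vanthoff$solvent[i]]], "vanthoff")
    expect_equal(unname(f$params["A"]), tab9_vanthoff$A[i], tolerance = 1e-4)
    expect_equal(unname(f$params["B"]), tab9_vanthoff$B[i], tolerance = 1e-5)
  }
  # x-space and log-space estimates of B agree within one percent
  b_log <- fit_solubility(ap, "vanthoff", objective = "logx")$params["B"]
  b_x <- fit_solubility(ap, "vanthoff", objective = "x")$params["B"]
  expect_lt(abs(b_x - b_log) / abs(b_log), 0.01)
})

test_that("noiseless synthetic data is recovered exactly", {
  truth <- c(lambda = 0.63, h = 2847)
  ds <- simulate_solubility("lambdah", truth, sigma = 0)
  fit <- fit_solubility(ds, "lambdah")
  expect_equal(unname(fit$params), unname(truth), tolerance = 1e-6)
  expect_lt(fit$rss, 1e-20)

  truthv <- c(A = 4.147, B = -1952.4)
  dv <- simulate_solubility("vanthoff", truthv, sigma = 0)
  expect_equal(unname(fit_solubility(dv, "vanthoff")$params), unname(truthv),
               tolerance = 1e-9)
})

test_that("the optimum descends from every start and ignores point order", {
  fit <- fit_solubility(ap, "lambdah")
  expect_true(all(fit$rss <= fit$starts$rss + 1e-12))
  shuf <- ap[sample(nrow(ap)), ]
  ds2 <- solubility_dataset(shuf$T_K, shuf$x_exp, system = "shuffled")
  fit2 <- fit_solubility(ds2, "lambdah")
  expect_equal(fit2$params, fit$params, tolerance = 1e-9)
})

test_that("fit_solubility validates its inputs", {
  tiny <- solubility_dataset(c(300, 310), c(0.1, 0.12))
  expect_error(fit_solubility(tiny, "apelblat"), "more points")
  expect_error(fit_solubility(ap, "wilson"), "binary")
  expect_error(fit_solubility(ap, "nosuch"))
})

test_that("prediction and residual methods are coherent", {
  fit <- fit_solubility(ap, "apelblat")
  expect_equal(predict(fit), fitted(fit))
  expect_equal(predict(fit, ap$T_K), fit$x_cal, tolerance = 1e-12)
  expect_equal(residuals(fit), ap$x_exp - fit$x_cal)
  expect_equal(residuals(fit, "relative"), fit$rd)
  expect_output(print(summary(fit)), "100\\*ARD")
})
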