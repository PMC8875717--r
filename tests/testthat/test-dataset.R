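test_that("mole-fraction bookkeeping is exact", {
  # zero solute, equal-mole symmetry, hand-computed two-component case
  expect_equal(mole_fraction_solubility(c(0, 10), c(300.442, 134.218)), 0)
  expect_equal(mole_fraction_solubility(c(2 * 300.442, 2 * 134.218),
                                        c(300.442, 134.218)), 0.5)
  n1 <- 1 / 300.442; n2 <- 10 / 134.218
  expect_equal(mole_fraction_solubility(c(1, 10), c(300.442, 134.218)),
               n1 / (n1 + n2), tolerance = 1e-12)
  # three components; fractions over all components sum to 1
  m <- c(1.3, 4.2, 5.5); M <- c(300.442, 136.234, 204.351)
  xs <- vapply(1:3, function(i)
    mole_fraction_solubility(m[c(i, setdiff(1:3, i))], M[c(i, setdiff(1:3, i))]),
    0)
  expect_equal(sum(xs), 1, tolerance = 1e-12)
  expect_error(mole_fraction_solubility(c(-1, 5), c(300, 134)), "non-negative")
  expect_error(mole_fraction_solubility(c(1, 5), c(300, 0)), "positive")
  expect_error(mole_fraction_solubility(c(0, 0), c(300, 134)), "positive")
})

test_that("solvent mass fraction covers the unit interval", {
  expect_equal(solvent_mass_fraction(5, 5), 0.5)
  expect_equal(solvent_mass_fraction(1, 0), 1)
  expect_equal(solvent_mass_fraction(3, 7), 0.3)
  expect_error(solvent_mass_fraction(0, 0), "positive")
})

test_that("built-in fixtures match the measured data tables", {
  all_ds <- terpene_solubility("all")
  expect_length(all_ds, 9L)
  expect_equal(sum(vapply(all_ds, nrow, 0L)), 12 * 6 + 9 * 3)

  ap <- all_ds[["(-)-alpha-pinene"]]
  expect_equal(ap$T_K[1], 299.45)
  expect_equal(ap$x_exp[1], 0.09417)
  pc <- all_ds[["p-cymene"]]
  expect_equal(unlist(pc[12, c("T_K", "x_exp")], use.names = FALSE),
               c(336.16, 0.26287))
  apbc <- all_ds[["(-)-alpha-pinene + (-)-beta-caryophyllene"]]
  expect_equal(unlist(apbc[1, c("T_K", "x_exp")], use.names = FALSE),
               c(295.15, 0.08338))
  expect_equal(attr(apbc, "w1"), 0.5)

  # every point satisfies the record invariants; scans carry per-point w1
  for (d in all_ds) {
    expect_true(all(d$T_K > 0))
    expect_true(all(d$x_exp > 0 & d$x_exp < 1))
  }
  expect_true("w1" %in% names(all_ds[["(-)-alpha-pinene + p-cymene (scan)"]]))
})

test_that("read/write round-trip preserves every value", {
  ds <- terpene_solubility("mono")[["p-cymene"]]
  path <- withr::local_tempfile(fileext = ".csv")
  write_solubility(ds, path)
  back <- read_solubility(path)
  expect_equal(back$T_K, ds$T_K)
  expect_equal(back$x_exp, ds$x_exp)
  expect_equal(attr(back, "system"), attr(ds, "system"))

  scan <- terpene_solubility("scan")[[1]]
  write_solubility(scan, path)
  back <- read_solubility(path)
  expect_equal(back$w1, scan$w1)
  expect_equal(back$x_exp, scan$x_exp)
})

test_that("malformed dataset files are rejected with line numbers", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines("system,w1,T_K,x_exp", path)
  expect_error(read_solubility(path), "empty")
  writeLines(c("system,w1,T_K,x_exp", "s,1,300,0.1", "s,1,oops,0.2"), path)
  expect_error(read_solubility(path), "line.*3")
  writeLines(c("system,w1,T_K,x_exp", "s,1,300,0.1", "s,1,300,0.2"), path)
  expect_error(read_solubility(path), "duplicate")
  writeLines(c("system,w1,T_K,x_exp", "s,1,300,1.4"), path)
  expect_error(read_solubility(path), "x_exp")
  writeLines(c("a,b", "1,2"), path)
  expect_error(read_solubility(path), "missing column")
  expect_error(read_solubility(file.path(tempdir(), "nope.csv")), "not found")
})

test_that("dataset constructor enforces its invariants", {
  expect_error(solubility_dataset(c(300, 300), c(0.1, 0.2)), "duplicate")
  expect_error(solubility_dataset(300, 1.2), "strictly in")
  expect_error(solubility_dataset(-5, 0.2), "positive")
  expect_error(solubility_dataset(300, 0.2, solvents = c("a", "b", "c")),
               "one or two")
  expect_error(solubility_dataset(300, 0.2, solvents = "a", w1 = 0.4),
               "monosolvent")
  # canonical ascending-in-T ordering
  d <- solubility_dataset(c(320, 300, 310), c(0.3, 0.1, 0.2))
  expect_equal(d$T_K, c(300, 310, 320))
  expect_equal(d$x_exp, c(0.1, 0.2, 0.3))
})
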