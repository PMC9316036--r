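test_that("rate unit conversion is exact, invertible and guarded", {
  # 6.26 %/min, the hottest NR measurement
  expect_equal(convert_rate(6.26, "fraction_per_s"), 6.26 / 6000)
  expect_equal(convert_rate(6.26, "fraction_per_s"), 1.0433e-3, tolerance = 1e-4)
  expect_equal(convert_rate(6.26, "fraction_per_ms"), 6.26 / 6e6)
  expect_identical(convert_rate(0, "fraction_per_s"), 0)
  expect_identical(convert_rate(0, "fraction_per_ms"), 0)
  expect_equal(convert_rate(6.26, "percent_per_min"), 6.26)
  # round trip via the ms convention
  expect_equal(convert_rate(6.26, "fraction_per_ms") * 6e6, 6.26)
  expect_error(convert_rate(-1, "fraction_per_s"), class = "nadtherm_invalid_measurement")
  expect_error(nadtherm:::.rate_unit_factor("furlongs"), class = "nadtherm_config_error")
})

test_that("arrhenius_rate follows the closed form and its limits", {
  # temperature ratio for the NR activation energy, closed form
  Ea <- 72.41
  expected <- exp((Ea * 1000 / R_GAS) * (1 / 323.15 - 1 / 363.15))
  expect_equal(arrhenius_rate(1, Ea, 363.15) / arrhenius_rate(1, Ea, 323.15), expected)
  expect_equal(expected, 19.5, tolerance = 0.01)
  # Ea = 0: temperature-independent
  expect_equal(arrhenius_rate(3.5, 0, c(280, 310, 400)), rep(3.5, 3))
  # printed NAD parameters evaluated back at 90 C, in %/min, near the measurement
  k_ms <- arrhenius_rate(1.37e11, 123.16, 363.15)
  expect_equal(k_ms * 6e6, 1.60, tolerance = 0.05)
  expect_error(arrhenius_rate(1, 50, -3), class = "nadtherm_domain_error")
})

test_that("rescale_to_base anchors at T0 and gives the expected Q10", {
  k <- rescale_to_base(0.123, 91.0, 310.65)
  expect_identical(k(310.65), 0.123)
  # closed-form Q10 values
  expect_equal(rescale_to_base(1, 57.4)(320.65), 2.00, tolerance = 0.005)
  expect_equal(rescale_to_base(1, 91.0)(320.65), 3.00, tolerance = 0.005)
  expect_error(k(0), class = "nadtherm_domain_error")
})

test_that("rate-scale least squares reproduces the NR series parameters", {
  nr <- dplyr::filter(table1, compound == "NR")
  fit <- fit_arrhenius(nr, unit = "fraction_per_ms")
  expect_equal(fit$Ea_kJ_per_mol, 72.41, tolerance = 0.01)
  # the prefactor lies on a flat exponential ridge: exp(dEa/(R Tbar)) per
  # kJ/mol of Ea, so the band consistent with a 1% Ea agreement is ~30%
  expect_equal(log(fit$A), log(27083.62), tolerance = 0.26)
  expect_gt(fit$A, 0)
  expect_equal(fit$n, 3)
  expect_s3_class(tidy(fit), "tbl_df")
  expect_equal(tidy(fit)$estimate[2], fit$Ea_kJ_per_mol)
})

test_that("fitted Ea is unit invariant and A scales with the unit factor", {
  for (cmp in c("NR", "NMN", "NAD")) {
    d <- dplyr::filter(table1, compound == cmp)
    f_ms <- fit_arrhenius(d, unit = "fraction_per_ms")
    f_pct <- fit_arrhenius(d, unit = "percent_per_min")
    expect_equal(f_ms$Ea_kJ_per_mol, f_pct$Ea_kJ_per_mol, tolerance = 1e-6)
    expect_equal(f_pct$A / f_ms$A, 6e6, tolerance = 1e-4)
  }
})

test_that("two-point series uses the exact closed-form solution", {
  # the NAR pair at 75 and 90 C
  d <- tibble::tibble(compound = "NAR", temperature_K = c(348.15, 363.15),
                      rate_pct_per_min = c(0.12, 0.86))
  fit <- fit_arrhenius(d)
  Ea_exp <- R_GAS * log(0.86 / 0.12) / (1 / 348.15 - 1 / 363.15) / 1000
  expect_equal(fit$Ea_kJ_per_mol, Ea_exp)
  expect_equal(Ea_exp, 138.0, tolerance = 0.005)
  expect_lt(fit$sse, 1e-30)
})

test_that("noise-free synthetic series are recovered to solver precision", {
  truth <- tibble::tibble(compound = "X1", A = 5e8, Ea_kJ_per_mol = 95)
  tab <- gen_rate_table(truth, rel_sd = 0, seed = 1)
  fit <- fit_arrhenius(tab, unit = "fraction_per_ms")
  expect_equal(fit$Ea_kJ_per_mol, 95, tolerance = 1e-6)
  expect_equal(fit$A, 5e8, tolerance = 1e-4)
})

test_that("an all-zero series yields the degenerate no-hydrolysis result", {
  d <- tibble::tibble(compound = "NAAD", temperature_K = c(323.15, 348.15, 363.15),
                      rate_pct_per_min = c(0, 0, 0))
  fit <- fit_arrhenius(d)
  expect_true(fit$degenerate)
  expect_identical(fit$A, 0)
  expect_true(is.na(fit$Ea_kJ_per_mol))
  expect_equal(predict(fit, 363.15), 0)
})

test_that("insufficient data and malformed input are refused", {
  d <- tibble::tibble(temperature_K = c(323.15, 323.15), rate_pct_per_min = c(1, 1.1))
  expect_error(fit_arrhenius(d), class = "nadtherm_insufficient_data")
  expect_error(fit_arrhenius(tibble::tibble(x = 1)), class = "nadtherm_config_error")
  two_cmp <- dplyr::filter(table1, compound %in% c("NR", "NMN"))
  expect_error(fit_arrhenius(two_cmp), class = "nadtherm_config_error")
})

test_that("multistart fit beats a dense brute-force grid on every series", {
  # the stated oracle: no point of an (A, Ea) grid spanning
  # [1e-2, 1e20] x [20, 200] may undercut the returned SSE
  Ea_grid <- seq(20, 200, by = 1)
  logA_grid <- seq(log(1e-2), log(1e20), length.out = 200)
  for (cmp in unique(table1$compound)) {
    d <- dplyr::filter(table1, compound == cmp)
    fit <- fit_arrhenius(d, unit = "fraction_per_ms")
    y <- convert_rate(d$rate_pct_per_min, "fraction_per_ms")
    Tk <- d$temperature_K
    grid_min <- Inf
    for (Ea in Ea_grid) {
      x <- exp(-Ea * 1000 / (R_GAS * Tk))
      sse <- vapply(logA_grid, function(la) sum((y - exp(la) * x)^2), numeric(1))
      grid_min <- min(grid_min, min(sse))
    }
    expect_lte(fit$sse, grid_min * (1 + 1e-9))
  }
})

test_that("predicted rate constants increase with temperature when Ea > 0", {
  for (cmp in unique(table1$compound)) {
    fit <- fit_arrhenius(dplyr::filter(table1, compound == cmp))
    Tk <- seq(280, 380, by = 5)
    expect_true(all(diff(predict(fit, Tk)) > 0), info = cmp)
  }
})

test_that("log-scale and weighted variants differ from the default as documented", {
  nr <- dplyr::filter(table1, compound == "NR")
  f_log <- fit_arrhenius(nr, scale = "log")
  # the log-linear fit is known to give a much lower Ea on this series
  expect_lt(f_log$Ea_kJ_per_mol, 60)
  f_w <- fit_arrhenius(nr, weighting = "inverse_variance")
  expect_false(isTRUE(all.equal(f_w$Ea_kJ_per_mol,
                                fit_arrhenius(nr)$Ea_kJ_per_mol)))
})

test_that("fit_arrhenius_table fits every compound of the bundled table", {
  fits <- fit_arrhenius_table(table1)
  expect_equal(nrow(fits), 5)
  expect_setequal(fits$compound, c("NR", "NMN", "NAD", "NAR", "NAMN"))
  expect_true(all(fits$Ea_kJ_per_mol > 0))
  expect_true(all(fits$A > 0))
})
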