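#' Convert a measured hydrolysis rate to another unit convention
#'
#' Measured non-enzymatic hydrolysis rates are reported as percent substrate
#' lost per minute. For kinetic modelling they are used as first-order rate
#' constants, either per second or per millisecond (fractional loss).
#'
#' @param rate Numeric vector of rates in percent per minute (>= 0).
#' @param unit Target unit: `"percent_per_min"` (identity), `"fraction_per_s"`
#'   (divide by 6000) or `"fraction_per_ms"` (divide by 6e6).
#' @return Numeric vector in the requested unit.
#' @examples
#' convert_rate(6.26, "fraction_per_s") # 1.0433e-3
#' @export
convert_rate <- function(rate, unit = c("percent_per_min", "fraction_per_s", "fraction_per_ms")) {
  unit <- match.arg(unit)
  if (any(!is.finite(rate)) || any(rate < 0)) {
    abort("invalid measurement: rates must be finite and non-negative", class = "nadtherm_invalid_measurement")
  }
  rate / .rate_unit_factor(unit)
}

.rate_unit_factor <- function(unit) {
  switch(unit,
    percent_per_min = 1,
    fraction_per_s = 6000,
    fraction_per_ms = 6e6,
    abort(paste0("unknown rate unit tag: ", unit), class = "nadtherm_config_error")
  )
}

#' Arrhenius rate constant
#'
#' Evaluates k(T) = A exp(-Ea / (R T)) with Ea in kJ/mol and
#' R = 8.314 J/(mol K).
#'
#' @param A Pre-exponential factor (same unit as the returned rate constant).
#' @param Ea_kJ_per_mol Activation energy in kJ/mol.
#' @param temperature_K Absolute temperature(s) in kelvin (> 0).
#' @return Rate constant(s), same unit as `A`.
#' @examples
#' arrhenius_rate(1.37e11, 123.16, 363.15)
#' @export
arrhenius_rate <- function(A, Ea_kJ_per_mol, temperature_K) {
  if (any(temperature_K <= 0)) {
    abort("temperature must be positive kelvin", class = "nadtherm_domain_error")
  }
  A * exp(-Ea_kJ_per_mol * 1000 / (.R_GAS * temperature_K))
}

#' Temperature-scaling of a rate constant anchored at a base temperature
#'
#' Returns a function k(T) = k0 exp(-(Ea/R) (1/T - 1/T0)), i.e. the
#' Arrhenius scaling that equals `k0` exactly at `T0`. This is how every
#' rate constant in the network model is made temperature dependent: its
#' value is specified at the base temperature (37.5 C = 310.65 K) and
#' rescaled by its activation energy.
#'
#' @param k0 Rate constant at the base temperature (> 0 unless zero rate).
#' @param Ea_kJ_per_mol Activation energy in kJ/mol.
#' @param T0_K Base temperature in kelvin (default 310.65).
#' @return A function of temperature (kelvin) returning the scaled constant.
#' @examples
#' k <- rescale_to_base(1, 57.4)
#' k(320.65) # ~ 2, a Q10 of two
#' @export
rescale_to_base <- function(k0, Ea_kJ_per_mol, T0_K = 310.65) {
  if (any(k0 < 0)) abort("k0 must be non-negative", class = "nadtherm_domain_error")
  force(k0); force(Ea_kJ_per_mol); force(T0_K)
  function(temperature_K) {
    if (any(temperature_K <= 0)) {
      abort("temperature must be positive kelvin", class = "nadtherm_domain_error")
    }
    k0 * exp(-(Ea_kJ_per_mol * 1000 / .R_GAS) * (1 / temperature_K - 1 / T0_K))
  }
}

# Profiled sum of squares: for fixed Ea the optimal prefactor is linear
# least squares, so the fit reduces to a 1-d search over Ea.
.arrhenius_profile <- function(Ea, Tk, y, w) {
  x <- exp(-Ea * 1000 / (.R_GAS * Tk))
  A <- sum(w * y * x) / sum(w * x * x)
  list(A = A, sse = sum(w * (y - A * x)^2))
}

#' Fit Arrhenius parameters to a hydrolysis-rate series
#'
#' Fits k = A exp(-Ea/(R T)) to measured rates of one compound by nonlinear
#' least squares on the rate scale (not the log scale), including zero-rate
#' observations. The fit is deterministic: a multistart over activation
#' energies from 20 to 200 kJ/mol (with the prefactor profiled out at each
#' start), a bracketed 1-d refinement, and a final joint Levenberg-Marquardt
#' polish via [minpack.lm::nlsLM()]. The fitted Ea is invariant under a
#' change of rate unit; A scales linearly with it.
#'
#' @param data Data frame with columns `temperature_K` and `rate_pct_per_min`
#'   (optionally `sd_pct_per_min` and `compound`; at most one compound).
#' @param unit Rate unit the fit is performed in (and `A` is reported in);
#'   see [convert_rate()]. Default `"fraction_per_ms"`, the convention in
#'   which reported prefactors for these data are expressed.
#' @param weighting `"none"` (default) or `"inverse_variance"` (weights
#'   1/sd^2; requires `sd_pct_per_min` > 0).
#' @param scale `"rate"` (default) or `"log"` (log-linear regression,
#'   excluding zero rates; provided for comparison, known to give much
#'   lower Ea on sparse series).
#' @return An object of class `arrhenius_fit` with elements `A`,
#'   `Ea_kJ_per_mol`, `unit`, `sse`, `data` (with fitted values and
#'   residuals), `degenerate` (TRUE for an all-zero series, where A = 0 and
#'   Ea is undefined: no detectable hydrolysis). Has [tidy()], [glance()],
#'   [predict()] and [autoplot()] methods.
#' @examples
#' tab <- read_rate_table(nadtherm_example("table1_thermolysis.tsv"))
#' fit <- fit_arrhenius(dplyr::filter(tab, compound == "NR"))
#' glance(fit)
#' @export
fit_arrhenius <- function(data,
                          unit = c("fraction_per_ms", "fraction_per_s", "percent_per_min"),
                          weighting = c("none", "inverse_variance"),
                          scale = c("rate", "log")) {
  unit <- match.arg(unit)
  weighting <- match.arg(weighting)
  scale <- match.arg(scale)
  stopifnot(is.data.frame(data))
  if (!all(c("temperature_K", "rate_pct_per_min") %in% names(data))) {
    abort("data needs columns temperature_K and rate_pct_per_min", class = "nadtherm_config_error")
  }
  compound <- if ("compound" %in% names(data)) unique(data$compound) else NA_character_
  if (length(compound) > 1) {
    abort("fit_arrhenius takes a single compound; use fit_arrhenius_table()", class = "nadtherm_config_error")
  }
  Tk <- data$temperature_K
  if (any(Tk <= 273.15)) abort("temperatures must be kelvin above freezing", class = "nadtherm_domain_error")
  y <- convert_rate(data$rate_pct_per_min, unit)
  n <- length(y)
  if (length(unique(Tk)) < 2) {
    abort("need measurements at >= 2 distinct temperatures", class = "nadtherm_insufficient_data")
  }

  if (all(y == 0)) {
    return(.new_arrhenius_fit(compound, A = 0, Ea = NA_real_, unit, weighting, scale,
      sse = 0, data = data, fitted = rep(0, n), degenerate = TRUE))
  }

  w <- rep(1, n)
  if (weighting == "inverse_variance") {
    if (!"sd_pct_per_min" %in% names(data) || any(data$sd_pct_per_min <= 0)) {
      abort("inverse_variance weighting needs positive sd_pct_per_min", class = "nadtherm_config_error")
    }
    w <- 1 / convert_rate(data$sd_pct_per_min, unit)^2
  }

  if (scale == "log") {
    keep <- y > 0
    if (sum(keep) < 2) abort("log-scale fit needs >= 2 positive rates", class = "nadtherm_insufficient_data")
    fit <- lm(log(y[keep]) ~ I(1 / Tk[keep]), weights = w[keep])
    Ea <- -coef(fit)[[2]] * .R_GAS / 1000
    A <- exp(coef(fit)[[1]])
    fitted <- A * exp(-Ea * 1000 / (.R_GAS * Tk))
    return(.new_arrhenius_fit(compound, A, Ea, unit, weighting, scale,
      sse = sum(w * (y - fitted)^2), data = data, fitted = fitted))
  }

  if (n == 2) {
    # closed form: the two-point fit is exact
    o <- order(Tk)
    T1 <- Tk[o[1]]; T2 <- Tk[o[2]]; k1 <- y[o[1]]; k2 <- y[o[2]]
    if (k1 > 0 && k2 > 0) {
      Ea <- .R_GAS * log(k2 / k1) / (1 / T1 - 1 / T2) / 1000
      A <- k2 / exp(-Ea * 1000 / (.R_GAS * T2))
      fitted <- A * exp(-Ea * 1000 / (.R_GAS * Tk))
      return(.new_arrhenius_fit(compound, A, Ea, unit, weighting, scale,
        sse = sum(w * (y - fitted)^2), data = data, fitted = fitted))
    }
  }

  # multistart on the profiled 1-d surface
  grid <- seq(20, 200, by = 2)
  sse_grid <- vapply(grid, function(e) .arrhenius_profile(e, Tk, y, w)$sse, numeric(1))
  i <- which.min(sse_grid)
  lo <- grid[max(1, i - 1)]; hi <- grid[min(length(grid), i + 1)]
  opt <- optimize(function(e) .arrhenius_profile(e, Tk, y, w)$sse, c(lo, hi), tol = 1e-10)
  Ea <- opt$minimum
  prof <- .arrhenius_profile(Ea, Tk, y, w)
  A <- prof$A; sse <- prof$sse

  # joint polish; keep the profiled solution if LM does not improve
  pol <- tryCatch({
    fit <- minpack.lm::nlsLM(
      y ~ A * exp(-Ea * 1000 / (8.314 * Tk)),
      start = list(A = A, Ea = Ea), weights = w,
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15, ptol = 1e-15)
    )
    list(A = coef(fit)[["A"]], Ea = coef(fit)[["Ea"]])
  }, error = function(e) NULL)
  if (!is.null(pol)) {
    fitted_p <- pol$A * exp(-pol$Ea * 1000 / (.R_GAS * Tk))
    sse_p <- sum(w * (y - fitted_p)^2)
    if (is.finite(sse_p) && sse_p <= sse) {
      A <- pol$A; Ea <- pol$Ea; sse <- sse_p
    }
  }
  fitted <- A * exp(-Ea * 1000 / (.R_GAS * Tk))
  .new_arrhenius_fit(compound, A, Ea, unit, weighting, scale,
    sse = sum(w * (y - fitted)^2), data = data, fitted = fitted)
}

.new_arrhenius_fit <- function(compound, A, Ea, unit, weighting, scale, sse,
                               data, fitted, degenerate = FALSE) {
  aug <- tibble::as_tibble(data)
  aug$.fitted <- fitted
  aug$.resid <- convert_rate(data$rate_pct_per_min, unit) - fitted
  structure(
    list(
      compound = compound, A = A, Ea_kJ_per_mol = Ea, unit = unit,
      gas_constant_R = .R_GAS, weighting = weighting, scale = scale,
      sse = sse, n = nrow(aug), data = aug, degenerate = degenerate
    ),
    class = "arrhenius_fit"
  )
}

#' @export
print.arrhenius_fit <- function(x, ...) {
  cat("Arrhenius fit", if (!is.na(x$compound)) paste0("(", x$compound, ")"), "\n")
  if (x$degenerate) {
    cat("  no detectable hydrolysis (all rates zero): A = 0, Ea undefined\n")
  } else {
    cat(sprintf("  A  = %.6g [%s]\n  Ea = %.4f kJ/mol\n  SSE = %.4g on %d points\n",
                x$A, x$unit, x$Ea_kJ_per_mol, x$sse, x$n))
  }
  invisible(x)
}

#' @method tidy arrhenius_fit
#' @export
tidy.arrhenius_fit <- function(x, ...) {
  tibble(
    term = c("A", "Ea"),
    estimate = c(x$A, x$Ea_kJ_per_mol),
    unit = c(x$unit, "kJ/mol")
  )
}

#' @method glance arrhenius_fit
#' @export
glance.arrhenius_fit <- function(x, ...) {
  tibble(
    compound = x$compound, A = x$A, Ea_kJ_per_mol = x$Ea_kJ_per_mol,
    unit = x$unit, sse = x$sse, n = x$n,
    weighting = x$weighting, scale = x$scale, degenerate = x$degenerate
  )
}

#' @method augment arrhenius_fit
#' @export
augment.arrhenius_fit <- function(x, ...) x$data

#' Predict hydrolysis rate constants from a fitted Arrhenius law
#'
#' @param object An `arrhenius_fit`.
#' @param temperature_K Temperatures (kelvin).
#' @param unit Unit of the returned rates (default: the unit of the fit).
#' @param ... Unused.
#' @return Numeric vector of rate constants.
#' @export
predict.arrhenius_fit <- function(object, temperature_K, unit = object$unit, ...) {
  if (object$degenerate) return(rep(0, length(temperature_K)))
  k <- arrhenius_rate(object$A, object$Ea_kJ_per_mol, temperature_K)
  k * .rate_unit_factor(unit) / .rate_unit_factor(object$unit)
}

#' Fit Arrhenius parameters for every compound in a rate table
#'
#' @param data A rate table as returned by [read_rate_table()].
#' @inheritParams fit_arrhenius
#' @return A tibble with one row per compound: columns as [glance()] of the
#'   per-compound fits.
#' @examples
#' fit_arrhenius_table(read_rate_table(nadtherm_example("table1_thermolysis.tsv")))
#' @export
fit_arrhenius_table <- function(data, unit = "fraction_per_ms",
                                weighting = "none", scale = "rate") {
  split(data, factor(data$compound, levels = unique(data$compound))) %>%
    map(~ glance(fit_arrhenius(.x, unit = unit, weighting = weighting, scale = scale))) %>%
    list_rbind()
}
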