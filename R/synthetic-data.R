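#' Generate a synthetic thermolysis rate table
#'
#' Emulates the design of the in vitro hydrolysis measurements: per
#' compound, true Arrhenius parameters evaluated at a small set of
#' temperatures, multiplicative Gaussian noise with a given relative SD,
#' truncated at zero (undetectable rates print as 0.00). Emitted in the
#' same TSV schema as the bundled measurement fixture, so generated tables
#' flow through [read_rate_table()]/[fit_arrhenius()] unchanged.
#'
#' @param true_params Tibble with columns `compound`, `A`, `Ea_kJ_per_mol`
#'   (A in the unit given by `unit`).
#' @param temperatures_K Measurement temperatures (default: the three used
#'   for the bundled data, 323.15/348.15/363.15 K).
#' @param rel_sd Relative noise SD per observation (default 0.05, the
#'   typical SD/mean of the measured series).
#' @param replicates Replicate tables are concatenated (default 1).
#' @param seed Integer seed.
#' @param unit Unit in which `A` is expressed (default fraction per ms).
#' @return A tibble in the rate-table schema (plus `temperature_K` and
#'   `replicate`).
#' @export
gen_rate_table <- function(true_params,
                           temperatures_K = c(323.15, 348.15, 363.15),
                           rel_sd = 0.05, replicates = 1, seed = 1L,
                           unit = "fraction_per_ms") {
  stopifnot(all(c("compound", "A", "Ea_kJ_per_mol") %in% names(true_params)),
            all(rel_sd >= 0), replicates >= 1)
  withr::with_seed(as.integer(seed), {
    grid <- tidyr::expand_grid(true_params, temperature_K = temperatures_K,
                               replicate = seq_len(replicates))
    k <- arrhenius_rate(grid$A, grid$Ea_kJ_per_mol, grid$temperature_K)
    pct <- k * .rate_unit_factor(unit)  # back to percent per minute
    noisy <- pmax(pct * (1 + rnorm(length(pct), sd = rel_sd)), 0)
    tibble(
      compound = grid$compound,
      temperature_C = grid$temperature_K - 273.15,
      rate_pct_per_min = noisy,
      sd_pct_per_min = pct * rel_sd,
      temperature_K = grid$temperature_K,
      replicate = grid$replicate
    )
  })
}

#' Sample random enzyme profiles
#'
#' Log-uniform abundances within the optimization bounds (PncA and Nampt
#' over [1e-10, 100] nM, the other seven over [0.01, 100] nM), rejection
#' sampled to the total budget. Used for property tests and as random
#' operating points.
#'
#' @param n Number of profiles.
#' @param budget_nM Total abundance cap (default 1000).
#' @param seed Integer seed.
#' @param lower,upper Named bound vectors (defaults: the optimization
#'   bounds).
#' @return A tibble, one row per profile, columns `E_PncA` ... `E_SurE`.
#' @export
gen_enzyme_profiles <- function(n, budget_nM = 1000, seed = 1L,
                                lower = NULL, upper = NULL) {
  stopifnot(n >= 1)
  lower <- lower %||% setNames(ifelse(.ENZYMES %in% .SUBSET_A, 1e-10, 0.01), .ENZYMES)
  upper <- upper %||% setNames(rep(100, length(.ENZYMES)), .ENZYMES)
  ll <- log10(lower[.ENZYMES]); lu <- log10(upper[.ENZYMES])
  withr::with_seed(as.integer(seed), {
    out <- vector("list", n)
    i <- 1
    while (i <= n) {
      E <- 10^runif(length(.ENZYMES), ll, lu)
      if (sum(E) <= budget_nM) {
        out[[i]] <- tibble::as_tibble_row(setNames(as.list(E), paste0("E_", .ENZYMES)))
        i <- i + 1
      }
    }
    list_rbind(out)
  })
}

#' Jitter a model configuration for robustness sweeps
#'
#' Perturbs every enzymatic kcat and Km log-uniformly within a fold range
#' around the base configuration; each jittered config passes schema
#' validation. Used to ask how often qualitative findings (pathway mutual
#' exclusivity, efficiency ordering) survive a different parameterization.
#'
#' @param config Base `nad_config`.
#' @param fold_range Maximum multiplicative perturbation (>= 1; 1 returns
#'   copies of the base).
#' @param n Number of configs.
#' @param seed Integer seed.
#' @return A list of `nad_config` objects.
#' @export
gen_perturbed_configs <- function(config = nad_default_config(), fold_range = 3,
                                  n = 10, seed = 1L) {
  stopifnot(fold_range >= 1, n >= 1)
  config <- validate_model_config(config)
  lf <- log(fold_range)
  withr::with_seed(as.integer(seed), {
    map(seq_len(n), function(i) {
      cfg <- config
      for (id in names(cfg$reactions)) {
        cfg$reactions[[id]]$kcat <- cfg$reactions[[id]]$kcat * exp(runif(1, -lf, lf))
        cfg$reactions[[id]]$Km <- cfg$reactions[[id]]$Km * exp(runif(1, -lf, lf))
      }
      validate_model_config(cfg)
    })
  })
}
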