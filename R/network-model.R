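#' Default model configuration
#'
#' Reads the bundled YAML parameterization of the NAD salvage network:
#' 13 enzyme-catalysed reactions (irreversible Michaelis-Menten in the
#' pyridine substrate, cosubstrates absorbed into kcat) and 5 non-enzymatic
#' glycohydrolysis reactions (first order). See the packaged
#' `default_model.yaml` for units and the rationale of the default values.
#'
#' @param path Optional path to an alternative YAML config.
#' @return A validated config list (class `nad_config`).
#' @export
nad_default_config <- function(path = NULL) {
  path <- path %||% nadtherm_example("default_model.yaml")
  validate_model_config(yaml::read_yaml(path))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Validate a model configuration
#'
#' Checks the schema of a config list: known species and enzymes, positive
#' kinetic constants, ATP costs in {0, 1, 2} (2 only for the NAD synthase
#' step, which cleaves ATP to AMP), and hydrolysis only for the five
#' unstable intermediates (the dinucleotide NAAD shows no detectable
#' hydrolysis and must not have one).
#'
#' @param config A config list (same shape as the bundled YAML).
#' @return The config, classed `nad_config`; errors on violations.
#' @export
validate_model_config <- function(config) {
  req <- c("base_temperature_K", "pyridine_total_mM", "reactions", "hydrolysis")
  miss <- setdiff(req, names(config))
  if (length(miss)) abort(paste0("config missing: ", paste(miss, collapse = ", ")), class = "nadtherm_config_error")
  for (id in names(config$reactions)) {
    r <- config$reactions[[id]]
    if (!r$enzyme %in% .ENZYMES) {
      abort(paste0("reaction ", id, ": unknown enzyme ", r$enzyme), class = "nadtherm_config_error")
    }
    if (!r$substrate %in% .SPECIES || !r$product %in% .SPECIES) {
      abort(paste0("reaction ", id, ": unknown species"), class = "nadtherm_config_error")
    }
    if (r$kcat <= 0 || r$Km <= 0 || r$Ea < 0) {
      abort(paste0("reaction ", id, ": kcat/Km must be > 0, Ea >= 0"), class = "nadtherm_config_error")
    }
    if (!r$atp_cost %in% 0:2 || (r$atp_cost == 2 && r$enzyme != "NadE")) {
      abort(paste0("reaction ", id, ": atp_cost must be 0/1/2, 2 only for NadE"), class = "nadtherm_config_error")
    }
  }
  hyd <- config$hydrolysis$reactions
  hs <- vapply(hyd, function(h) h$substrate, character(1))
  if (!setequal(hs, c("NAD", "NMN", "NR", "NAR", "NAMN"))) {
    abort("hydrolysis must cover exactly NAD, NMN, NR, NAR, NAMN (never NAAD)", class = "nadtherm_config_error")
  }
  structure(config, class = c("nad_config", "list"))
}

#' Build the NAD biosynthesis network model
#'
#' Assembles the 8-species reaction network of bacterial NAD salvage:
#' the four-step PncA/Preiss-Handler route (Nam -> NA -> NAMN -> NAAD ->
#' NAD), the two-step Nampt route (Nam -> NMN -> NAD), the riboside
#' shunts (NadR, SurE, PNP), NAD-consuming enzymes (NCE) closing the
#' cycle, and non-enzymatic glycohydrolysis of the five unstable
#' intermediates. The pyridine moiety is conserved: the all-ones vector is
#' in the left null space of the stoichiometry matrix, so the summed
#' concentration of the eight species stays at `pyridine_total_mM`.
#'
#' Hydrolysis rate constants at the base temperature and their activation
#' energies are, by default, derived by refitting the bundled thermolysis
#' measurements ([fit_arrhenius_table()]); an explicit table can be given
#' in the config instead.
#'
#' @param config A `nad_config` (default: [nad_default_config()]).
#' @param rate_table Thermolysis rate table used when the config requests
#'   fitted hydrolysis parameters (default: the bundled measurements).
#' @return An object of class `nad_model`: reaction tibble, stoichiometry
#'   matrix, conserved total and base temperature.
#' @examples
#' model <- build_default_model()
#' model
#' @export
build_default_model <- function(config = nad_default_config(),
                                rate_table = read_rate_table(nadtherm_example("table1_thermolysis.tsv"))) {
  config <- validate_model_config(config)
  T0 <- config$base_temperature_K

  enz <- imap(config$reactions, function(r, id) {
    tibble(
      id = id, enzyme = r$enzyme, substrate = r$substrate, product = r$product,
      kind = "michaelis_menten", k0 = r$kcat, Km = r$Km, Ea = r$Ea,
      atp_cost = as.integer(r$atp_cost)
    )
  }) %>% list_rbind()

  hyd_cfg <- config$hydrolysis
  if (identical(hyd_cfg$source, "fitted")) {
    fits <- fit_arrhenius_table(rate_table, unit = "fraction_per_s")
    hyd <- imap(hyd_cfg$reactions, function(h, id) {
      f <- fits[fits$compound == h$substrate, ]
      if (nrow(f) != 1) abort(paste0("no thermolysis fit for ", h$substrate), class = "nadtherm_config_error")
      k0 <- if (f$degenerate) 0 else arrhenius_rate(f$A, f$Ea_kJ_per_mol, T0)
      tibble(id = id, enzyme = NA_character_, substrate = h$substrate, product = h$product,
             kind = "first_order", k0 = k0,
             Km = NA_real_, Ea = if (f$degenerate) 0 else f$Ea_kJ_per_mol, atp_cost = 0L)
    }) %>% list_rbind()
  } else {
    hyd <- imap(hyd_cfg$reactions, function(h, id) {
      tibble(id = id, enzyme = NA_character_, substrate = h$substrate, product = h$product,
             kind = "first_order", k0 = h$k_per_s_at_T0, Km = NA_real_, Ea = h$Ea,
             atp_cost = 0L)
    }) %>% list_rbind()
  }

  reactions <- bind_rows(enz, hyd)
  N <- matrix(0, length(.SPECIES), nrow(reactions),
              dimnames = list(.SPECIES, reactions$id))
  for (j in seq_len(nrow(reactions))) {
    N[reactions$substrate[j], j] <- N[reactions$substrate[j], j] - 1
    N[reactions$product[j], j] <- N[reactions$product[j], j] + 1
  }

  structure(
    list(
      species = .SPECIES, enzymes = .ENZYMES, reactions = reactions,
      stoichiometry = N, pyridine_total = config$pyridine_total_mM,
      T0 = T0, config = config
    ),
    class = "nad_model"
  )
}

#' @export
print.nad_model <- function(x, ...) {
  cat("NAD salvage network model\n")
  cat(sprintf("  %d species, %d reactions (%d enzymatic, %d hydrolysis)\n",
              length(x$species), nrow(x$reactions),
              sum(x$reactions$kind == "michaelis_menten"),
              sum(x$reactions$kind == "first_order")))
  cat(sprintf("  pyridine total %.3g mM, base temperature %.2f K\n",
              x$pyridine_total, x$T0))
  invisible(x)
}

# internal: pack the model into flat arrays for the C++ core
.model_arrays <- function(model) {
  r <- model$reactions
  list(
    N = model$stoichiometry,
    sub = match(r$substrate, model$species) - 1L,
    enz = ifelse(is.na(r$enzyme), -1L, match(r$enzyme, model$enzymes) - 1L),
    mm = as.integer(r$kind == "michaelis_menten"),
    k0 = r$k0,
    Km = ifelse(is.na(r$Km), 1, r$Km),
    Ea = r$Ea,
    T0 = model$T0,
    total = model$pyridine_total
  )
}

.check_state <- function(model, state) {
  if (length(state) != length(model$species)) {
    abort("state must have one concentration per species", class = "nadtherm_state_error")
  }
  if (any(!is.finite(state)) || any(state < 0)) {
    abort("concentrations must be finite and non-negative", class = "nadtherm_state_error")
  }
  if (!is.null(names(state))) state <- state[model$species]
  unname(state)
}

.check_profile <- function(E) {
  if (is.null(names(E))) {
    stopifnot(length(E) == length(.ENZYMES))
    names(E) <- .ENZYMES
  }
  if (!all(.ENZYMES %in% names(E))) abort("enzyme profile must name all nine enzymes", class = "nadtherm_config_error")
  E <- E[.ENZYMES]
  if (any(!is.finite(E)) || any(E < 0)) abort("enzyme abundances must be finite and >= 0", class = "nadtherm_config_error")
  E
}

#' Per-reaction fluxes at a given state, profile and temperature
#'
#' Michaelis-Menten reactions: v = kcat(T) E S / (Km + S), with the enzyme
#' abundance converted nM -> mM. Hydrolysis: v = k(T) S. All rate constants
#' are Arrhenius-rescaled from the base temperature ([rescale_to_base()]).
#'
#' @param model A `nad_model`.
#' @param state Named (or species-ordered) concentrations, mM.
#' @param E Named enzyme abundances, nM (nine enzymes).
#' @param temperature_K Temperature, kelvin.
#' @return Named numeric vector of fluxes, mM/s, one per reaction.
#' @export
reaction_rate <- function(model, state, E, temperature_K) {
  state <- .check_state(model, state)
  E <- .check_profile(E)
  if (temperature_K <= 0) abort("temperature must be positive kelvin", class = "nadtherm_domain_error")
  r <- model$reactions
  kT <- r$k0 * exp(-(r$Ea * 1000 / .R_GAS) * (1 / temperature_K - 1 / model$T0))
  S <- state[match(r$substrate, model$species)]
  v <- ifelse(r$kind == "michaelis_menten",
              kT * (E[r$enzyme] * 1e-6) * S / (r$Km + S),
              kT * S)
  setNames(as.numeric(v), r$id)
}

#' Time derivatives of the species concentrations
#'
#' Right-hand side of the ODE system dC/dt = N v(C): stoichiometry times
#' reaction rates. The eight derivatives sum to zero exactly (pyridine
#' moiety conservation).
#'
#' @inheritParams reaction_rate
#' @return Named numeric vector, mM/s per species.
#' @export
ode_rhs <- function(model, state, E, temperature_K) {
  v <- reaction_rate(model, state, E, temperature_K)
  setNames(as.numeric(model$stoichiometry %*% v), model$species)
}

#' Q10 temperature coefficients of the model's reactions
#'
#' The factor by which each rate constant grows over a 10 K rise,
#' k(T + 10)/k(T), from the reaction's activation energy. The default
#' enzymatic parameterization keeps every enzymatic Q10 inside the
#' physiological 2-3 band at the base temperature.
#'
#' @param model A `nad_model`.
#' @param temperature_K Reference temperature (default: the model's base).
#' @return Tibble with columns `id`, `enzyme`, `kind`, `Ea`, `q10`.
#' @export
compute_q10 <- function(model, temperature_K = model$T0) {
  if (temperature_K <= 0) abort("temperature must be positive kelvin", class = "nadtherm_domain_error")
  r <- model$reactions
  q10 <- exp((r$Ea * 1000 / .R_GAS) * (1 / temperature_K - 1 / (temperature_K + 10)))
  tibble(id = r$id, enzyme = r$enzyme, kind = r$kind, Ea = r$Ea, q10 = q10)
}

#' A simple reference enzyme profile
#'
#' Equal abundance for all nine enzymes (default 10 nM each); used as the
#' default operating point for steady-state demonstrations and control
#' analysis. Both routes are active under this profile.
#'
#' @param abundance_nM Abundance given to each enzyme.
#' @return Named numeric vector of nine abundances, nM.
#' @export
default_enzyme_profile <- function(abundance_nM = 10) {
  setNames(rep(abundance_nM, length(.ENZYMES)), .ENZYMES)
}

#' Standard initial condition: all pyridine as free NAD
#'
#' @param model A `nad_model`.
#' @return Named concentrations, mM: NAD at the conserved total, rest 0.
#' @export
default_initial_state <- function(model) {
  s <- setNames(rep(0, length(model$species)), model$species)
  s["NAD"] <- model$pyridine_total
  s
}
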