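#' Concentration control coefficients by metabolic control analysis
#'
#' Scaled control coefficients C^S_p = (p/S) dS/dp of every rate process p
#' (the nine enzyme abundances plus the five hydrolysis rate constants)
#' over every steady-state concentration S. Coefficients are computed by
#' central finite differences in log space, d ln S / d ln p, with each
#' process magnitude perturbed by a factor exp(+/- rel_step). Every
#' coefficient is re-estimated at half the step (Richardson check); a
#' relative discrepancy above 1e-3 flags the entry as unreliable rather
#' than silently reporting it.
#'
#' Because every reaction rate is proportional to exactly one process
#' magnitude, scaling all fourteen processes together only rescales time,
#' so for each species the coefficients sum to zero (summation theorem);
#' this is the natural internal consistency check for the numerics.
#'
#' @param model A `nad_model`.
#' @param E Named enzyme abundances, nM.
#' @param temperature_K Temperature, kelvin.
#' @param rel_step Log-perturbation step (0 < rel_step <= 0.1, default 0.01).
#' @param conc_floor Species below this concentration (mM) get `NA`
#'   coefficients (log-derivative undefined at zero).
#' @return An object of class `nad_mca`: a tibble with columns `process`,
#'   `process_kind`, `species`, `coefficient`, `richardson_rel_diff`,
#'   `flagged`. Has an [autoplot()] method.
#' @examples
#' model <- build_default_model()
#' cc <- control_coefficients(model, default_enzyme_profile(), 310.65)
#' dplyr::filter(cc, process == "PncA", species %in% c("NAD", "Nam"))
#' @export
control_coefficients <- function(model, E, temperature_K, rel_step = 1e-2,
                                 conc_floor = 1e-12) {
  stopifnot(rel_step > 0, rel_step <= 0.1)
  E <- .check_profile(E)
  base <- solve_steady_state(model, E, temperature_K)
  if (!base$converged) abort("base steady state did not converge", class = "nadtherm_not_converged")
  S0 <- base$concentrations
  warm <- pmax(S0, 0)

  hyd_ids <- model$reactions$id[model$reactions$kind == "first_order"]
  processes <- c(model$enzymes, hyd_ids)
  kinds <- c(rep("enzyme", length(model$enzymes)), rep("hydrolysis", length(hyd_ids)))

  solve_scaled <- function(proc, kind, fac) {
    if (kind == "enzyme") {
      E2 <- E
      E2[proc] <- E2[proc] * fac
      m2 <- model
    } else {
      m2 <- model
      j <- match(proc, m2$reactions$id)
      m2$reactions$k0[j] <- m2$reactions$k0[j] * fac
    }
    ss <- solve_steady_state(m2, if (kind == "enzyme") E2 else E, temperature_K, initial = warm)
    if (!ss$converged) return(NULL)
    ss$concentrations
  }

  one_process <- function(proc, kind) {
    # a zero-magnitude process has zero control (scaling zero stays zero)
    mag <- if (kind == "enzyme") E[[proc]] else model$reactions$k0[[match(proc, model$reactions$id)]]
    if (mag == 0) {
      return(tibble(process = proc, process_kind = kind, species = model$species,
                    coefficient = 0, richardson_rel_diff = 0, flagged = FALSE))
    }
    cc_at <- function(d) {
      up <- solve_scaled(proc, kind, exp(d))
      dn <- solve_scaled(proc, kind, exp(-d))
      if (is.null(up) || is.null(dn)) return(NULL)
      lu <- ifelse(up > conc_floor, log(up), NA_real_)
      ld <- ifelse(dn > conc_floor, log(dn), NA_real_)
      (lu - ld) / (2 * d)
    }
    c1 <- cc_at(rel_step)
    c2 <- cc_at(rel_step / 2)
    if (is.null(c1) || is.null(c2)) {
      return(tibble(process = proc, process_kind = kind, species = model$species,
                    coefficient = NA_real_, richardson_rel_diff = NA_real_, flagged = TRUE))
    }
    # Richardson: the half-step estimate is the reported one; discrepancy
    # is relative with an absolute floor so near-zero coefficients are not
    # flagged for noise below that floor
    denom <- pmax(abs(c2), 1e-2)
    rel <- abs(c1 - c2) / denom
    tibble(process = proc, process_kind = kind, species = model$species,
           coefficient = as.numeric(c2),
           richardson_rel_diff = as.numeric(rel),
           flagged = !is.na(rel) & rel > 1e-3)
  }

  out <- map2(processes, kinds, one_process) %>% list_rbind()
  structure(out, class = c("nad_mca", class(tibble())),
            temperature_K = temperature_K, rel_step = rel_step,
            base_concentrations = S0)
}
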