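#' ATP/NAD flux accounting at steady state
#'
#' From a converged steady state, tallies the fluxes of the ATP-consuming
#' reactions and of the NAD-producing reactions:
#'
#' * J_ATP = J_Nampt + J_PncB + 2 J_NadE + J_NadD + J_NadR, where the NadD
#'   and NadR terms sum both substrate branches (each consumes one ATP) and
#'   the NAD synthase flux counts twice (it cleaves ATP to AMP; two
#'   phosphorylations regenerate ATP). The phosphoribosyltransferase steps
#'   (Nampt, PncB) each count one ATP for the autophosphorylation coupled
#'   to their catalytic cycle.
#' * J_NAD = J_NadE + J_NadD(NMN): only the NMN-adenylylation branch of
#'   NadD makes NAD; the NAMN branch makes NAAD (it still costs ATP, so it
#'   appears in J_ATP but not in J_NAD).
#'
#' @param result A converged `steady_state`.
#' @return A one-row tibble: the six named fluxes, `J_ATP`, `J_NAD` and
#'   `ratio` = J_ATP/J_NAD (NA when J_NAD is 0), all mM/s.
#' @examples
#' model <- build_default_model()
#' energy_account(solve_steady_state(model, default_enzyme_profile(), 310.65))
#' @export
energy_account <- function(result) {
  .check_converged(result)
  v <- result$fluxes
  J_NAMPT <- v[["Nampt"]]
  J_PNCB <- v[["PncB"]]
  J_NADE <- v[["NadE"]]
  J_NADD_NMN <- v[["NadD_NMN"]]
  J_NADD_NAMN <- v[["NadD_NAMN"]]
  J_NADR <- v[["NadR_NR"]] + v[["NadR_NAR"]]
  J_ATP <- J_NAMPT + J_PNCB + 2 * J_NADE + J_NADD_NMN + J_NADD_NAMN + J_NADR
  J_NAD <- J_NADE + J_NADD_NMN
  tibble(
    J_NAMPT = J_NAMPT, J_PNCB = J_PNCB, J_NADE = J_NADE,
    J_NADD_NMN = J_NADD_NMN, J_NADD_NAMN = J_NADD_NAMN, J_NADR = J_NADR,
    J_ATP = J_ATP, J_NAD = J_NAD,
    ratio = if (J_NAD > 0) J_ATP / J_NAD else NA_real_
  )
}

.check_converged <- function(result) {
  if (!inherits(result, "steady_state")) abort("expected a steady_state", class = "nadtherm_state_error")
  if (!result$converged) {
    abort("refusing to account fluxes of a non-converged steady state", class = "nadtherm_not_converged")
  }
  invisible(result)
}

#' Total flux of ATP-consuming reactions
#' @inheritParams energy_account
#' @return J_ATP in mM/s.
#' @export
atp_flux <- function(result) energy_account(result)$J_ATP

#' NAD production flux
#' @inheritParams energy_account
#' @return J_NAD in mM/s.
#' @export
nad_flux <- function(result) energy_account(result)$J_NAD

#' ATP cost per NAD produced
#'
#' The energy-efficiency measure J_ATP/J_NAD: how many ATP equivalents the
#' pathway spends per NAD molecule delivered. The stoichiometric floor is
#' 2 for the two-step Nampt route and 4 for the four-step PncA route;
#' futile cycling and hydrolysis losses raise it further.
#'
#' @inheritParams energy_account
#' @return Dimensionless ratio; errors when J_NAD = 0.
#' @export
efficiency <- function(result) {
  acct <- energy_account(result)
  if (!is.finite(acct$ratio)) {
    abort("J_NAD is zero: ATP/NAD ratio undefined", class = "nadtherm_undefined_ratio")
  }
  acct$ratio
}
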