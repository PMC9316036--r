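#' Define an enzyme-allocation optimization problem
#'
#' Sets up one of the three allocation objectives over the nine enzyme
#' abundances E:
#'
#' * `min_ratio`: minimize J_ATP/J_NAD (ATP cost per NAD produced),
#' * `min_atp`: minimize J_ATP,
#' * `max_nad`: maximize the steady-state free-NAD concentration.
#'
#' Constraints: the pathway-selecting pair A = (PncA, Nampt) is bounded in
#' [1e-10, 100] nM, the remaining seven enzymes (subset B) in [0.01, 100]
#' nM, the total enzyme budget is sum(E) <= 1000 nM, and for `min_ratio`
#' and `min_atp` the steady-state NAD concentration must stay in
#' (0.1, 0.3) mM (`max_nad` carries no NAD constraint).
#'
#' @param model A `nad_model`.
#' @param objective One of `"min_ratio"`, `"min_atp"`, `"max_nad"`.
#' @param temperature_K Temperature of the steady states, kelvin.
#' @param generations,population EP schedule (defaults 200 and 20).
#' @param q Tournament size for survivor selection (default 5).
#' @param budget_nM Total abundance budget (default 1000).
#' @param nad_range NAD feasibility interval in mM for the constrained
#'   objectives (default `c(0.1, 0.3)`).
#' @param seed Integer seed making the run reproducible.
#' @param route `"free"` (default) optimizes over both route entry enzymes;
#'   `"pnca"` or `"nampt"` pins the other route's entry enzyme (Nampt or
#'   PncA respectively) at its lower bound, yielding the best allocation
#'   attainable through that route alone. Route-conditioned optima are how
#'   the two pathways' energetics are compared on an equal footing: under
#'   the default kinetics the free optimizer essentially always selects
#'   the cheaper Nampt route, so PncA-type optima are characterized by
#'   conditioning rather than by waiting for rare local-optimum runs.
#' @return An `ep_problem` object for [run_ep()].
#' @export
ep_problem <- function(model, objective = c("min_ratio", "min_atp", "max_nad"),
                       temperature_K = model$T0,
                       generations = 200, population = 20, q = 5,
                       budget_nM = 1000, nad_range = c(0.1, 0.3), seed = 1L,
                       route = c("free", "pnca", "nampt")) {
  objective <- match.arg(objective)
  route <- match.arg(route)
  lower <- setNames(ifelse(.ENZYMES %in% .SUBSET_A, 1e-10, 0.01), .ENZYMES)
  upper <- setNames(rep(100, length(.ENZYMES)), .ENZYMES)
  if (route == "pnca") upper["Nampt"] <- lower[["Nampt"]]
  if (route == "nampt") upper["PncA"] <- lower[["PncA"]]
  structure(
    list(
      model = model, arrays = .model_arrays(model), objective = objective,
      temperature_K = temperature_K, generations = generations,
      population = population, q = q, budget_nM = budget_nM,
      nad_range = if (objective == "max_nad") NULL else nad_range,
      lower = lower, upper = upper, route = route, seed = as.integer(seed),
      initial = unname(default_initial_state(model))
    ),
    class = "ep_problem"
  )
}

# penalty scale: any infeasible point must be worse than any feasible one.
# Feasible objectives are bounded well below this (ratios are O(10),
# fluxes O(1e-3) mM/s, -C_NAD is O(-0.3)).
.EP_INFEAS_OFFSET <- 1e6
.EP_PENALTY_SCALE <- 1e3

#' Evaluate a penalized allocation objective
#'
#' Solves the steady state for the profile, computes the raw objective and
#' adds penalties for constraint violations (enzyme budget, NAD range,
#' solver non-convergence): a fixed infeasibility offset plus a term
#' proportional to the violation, so any feasible point beats any
#' infeasible one and the optimizer is still guided back to feasibility.
#'
#' @param problem An `ep_problem`.
#' @param E Named enzyme abundances, nM (within bounds).
#' @return A list: `value` (penalized), `raw` (unpenalized objective),
#'   `feasible`, `C_NAD`, `account` (energy tibble or NULL).
#' @export
evaluate_objective <- function(problem, E) {
  E <- .check_profile(E)
  res <- .cpp_solve_ss(problem$arrays, E, problem$temperature_K, problem$initial)
  penalty <- 0
  feasible <- TRUE
  if (!isTRUE(res$converged)) {
    penalty <- penalty + .EP_INFEAS_OFFSET + .EP_PENALTY_SCALE
    feasible <- FALSE
  }
  tot <- sum(E)
  if (tot > problem$budget_nM) {
    penalty <- penalty + .EP_INFEAS_OFFSET +
      .EP_PENALTY_SCALE * (tot - problem$budget_nM) / problem$budget_nM
    feasible <- FALSE
  }
  C <- setNames(as.numeric(res$C), problem$model$species)
  C_NAD <- C[["NAD"]]
  if (!is.null(problem$nad_range)) {
    lo <- problem$nad_range[1]; hi <- problem$nad_range[2]
    if (!(C_NAD > lo && C_NAD < hi)) {
      viol <- max(lo - C_NAD, C_NAD - hi, 0)
      penalty <- penalty + .EP_INFEAS_OFFSET + .EP_PENALTY_SCALE * viol / lo
      feasible <- FALSE
    }
  }
  v <- setNames(as.numeric(res$fluxes), problem$model$reactions$id)
  J_NADE <- v[["NadE"]]; J_NADD_NMN <- v[["NadD_NMN"]]
  J_NAD <- J_NADE + J_NADD_NMN
  J_ATP <- v[["Nampt"]] + v[["PncB"]] + 2 * J_NADE + J_NADD_NMN +
    v[["NadD_NAMN"]] + v[["NadR_NR"]] + v[["NadR_NAR"]]
  raw <- switch(problem$objective,
    min_ratio = if (J_NAD > 0) J_ATP / J_NAD else NA_real_,
    min_atp = J_ATP,
    max_nad = -C_NAD
  )
  if (problem$objective == "min_ratio" && !is.finite(raw)) {
    penalty <- penalty + .EP_INFEAS_OFFSET + .EP_PENALTY_SCALE
    feasible <- FALSE
    raw <- NA_real_
  }
  list(
    value = (if (is.finite(raw)) raw else 0) + penalty,
    raw = raw, feasible = feasible, C_NAD = C_NAD,
    J_ATP = J_ATP, J_NAD = J_NAD, concentrations = C, fluxes = v
  )
}

#' Run one evolutionary-programming optimization
#'
#' Classical self-adaptive EP in log10-abundance space (the PncA/Nampt
#' bounds span twelve orders of magnitude, so mutation must be
#' multiplicative): a population of `population` parents each spawns one
#' offspring by Gaussian mutation with per-coordinate lognormally
#' self-adapted step sizes; survivors are chosen by pairwise stochastic
#' tournament (each candidate scores wins against `q` random opponents,
#' the top half by wins survives). The best-ever feasible solution is
#' tracked across all generations and returned. Deterministic given
#' `problem$seed`.
#'
#' @param problem An `ep_problem`.
#' @return An `ep_run` object: `best_profile` (named nM), `best_value`
#'   (raw objective), `feasible`, `classification` (`"pnca_pathway"`,
#'   `"nampt_pathway"` or `"mixed"`, abundance-ratio threshold 1e-2),
#'   steady-state summary at the optimum and the run's seed. Has [tidy()]
#'   and [glance()] methods.
#' @examples
#' \donttest{
#' model <- build_default_model()
#' run <- run_ep(ep_problem(model, "min_ratio", seed = 7))
#' glance(run)
#' }
#' @export
run_ep <- function(problem) {
  stopifnot(inherits(problem, "ep_problem"))
  withr::with_seed(problem$seed, .run_ep_impl(problem))
}

# Generic self-adaptive EP core over box bounds (minimization).
# eval_fn(x) must return list(value = penalized fitness, raw, feasible, ...).
# Used with the allocation objective, and directly testable on surrogate
# objectives.
.ep_core <- function(eval_fn, lb, ub, mu, generations, q, sigma_min = 1e-4) {
  n <- length(lb)
  range <- ub - lb
  tau <- 1 / sqrt(2 * sqrt(n))
  tau_p <- 1 / sqrt(2 * n)
  sigma0 <- range / 6

  X <- matrix(runif(mu * n, rep(lb, each = mu), rep(ub, each = mu)), mu, n)
  S <- matrix(rep(sigma0, each = mu), mu, n)
  evals <- apply(X, 1, eval_fn)
  fit <- vapply(evals, `[[`, numeric(1), "value")

  best <- NULL
  note_best <- function(ev, x) {
    if (isTRUE(ev$feasible) && (is.null(best) || ev$raw < best$raw)) {
      best <<- list(raw = ev$raw, x = x, eval = ev)
    }
  }
  for (i in seq_len(mu)) note_best(evals[[i]], X[i, ])

  history <- numeric(generations)
  for (g in seq_len(generations)) {
    Sp <- S * exp(tau_p * rnorm(mu) + tau * matrix(rnorm(mu * n), mu, n))
    Sp <- pmin(pmax(Sp, sigma_min), matrix(rep(range, each = mu), mu, n))
    Xp <- X + Sp * matrix(rnorm(mu * n), mu, n)
    Xp <- pmin(pmax(Xp, rep(lb, each = mu)), rep(ub, each = mu))
    evals_p <- apply(Xp, 1, eval_fn)
    fit_p <- vapply(evals_p, `[[`, numeric(1), "value")
    for (i in seq_len(mu)) note_best(evals_p[[i]], Xp[i, ])

    allX <- rbind(X, Xp); allS <- rbind(S, Sp)
    allfit <- c(fit, fit_p); alleval <- c(evals, evals_p)
    m2 <- 2 * mu
    wins <- integer(m2)
    for (i in seq_len(m2)) {
      opp <- sample.int(m2, q, replace = TRUE)
      wins[i] <- sum(allfit[i] <= allfit[opp])
    }
    keep <- order(-wins, allfit)[seq_len(mu)]
    X <- allX[keep, , drop = FALSE]
    S <- allS[keep, , drop = FALSE]
    fit <- allfit[keep]
    evals <- alleval[keep]
    history[g] <- min(allfit)
  }
  list(best = best, X = X, S = S, fit = fit, evals = evals, history = history)
}

.run_ep_impl <- function(problem) {
  lb <- log10(problem$lower); ub <- log10(problem$upper)
  eval_x <- function(x) evaluate_objective(problem, setNames(10^x, .ENZYMES))
  core <- .ep_core(eval_x, lb, ub, mu = problem$population,
                   generations = problem$generations, q = problem$q)
  best <- core$best
  history <- core$history
  fit <- core$fit
  X <- core$X
  evals <- core$evals

  if (is.null(best)) {
    # no feasible point found in the whole run
    i <- which.min(fit)
    best_profile <- setNames(10^X[i, ], .ENZYMES)
    return(.new_ep_run(problem, best_profile, NA_real_, evals[[i]], FALSE, history))
  }
  best_profile <- setNames(10^best$x, .ENZYMES)
  .new_ep_run(problem, best_profile, best$raw, best$eval, TRUE, history)
}

.classify_profile <- function(E, threshold = 1e-2) {
  pnca <- E[["PncA"]]; nampt <- E[["Nampt"]]
  if (nampt <= threshold * pnca) "pnca_pathway"
  else if (pnca <= threshold * nampt) "nampt_pathway"
  else "mixed"
}

.new_ep_run <- function(problem, profile, raw, eval, feasible, history) {
  structure(
    list(
      best_profile = profile, best_value = raw, feasible = feasible,
      classification = .classify_profile(profile),
      objective = problem$objective, route = problem$route,
      temperature_K = problem$temperature_K,
      C_NAD = eval$C_NAD, J_ATP = eval$J_ATP, J_NAD = eval$J_NAD,
      ratio = if (is.finite(eval$J_NAD) && eval$J_NAD > 0) eval$J_ATP / eval$J_NAD else NA_real_,
      concentrations = eval$concentrations, fluxes = eval$fluxes,
      seed = problem$seed, history = history,
      n_evals = problem$population * (problem$generations + 1)
    ),
    class = "ep_run"
  )
}

#' @export
print.ep_run <- function(x, ...) {
  cat(sprintf("EP run (%s at %.2f K, seed %d): %s\n", x$objective,
              x$temperature_K, x$seed,
              if (x$feasible) "feasible" else "NO feasible solution"))
  cat(sprintf("  best objective %.6g, class %s, C_NAD %.4f mM\n",
              x$best_value, x$classification, x$C_NAD))
  invisible(x)
}

#' @method tidy ep_run
#' @export
tidy.ep_run <- function(x, ...) {
  tibble(enzyme = names(x$best_profile), abundance_nM = unname(x$best_profile),
         subset = ifelse(names(x$best_profile) %in% .SUBSET_A, "A", "B"))
}

#' @method glance ep_run
#' @export
glance.ep_run <- function(x, ...) {
  tibble(
    objective = x$objective, route = x$route,
    temperature_K = x$temperature_K, seed = x$seed,
    best_value = x$best_value, feasible = x$feasible,
    classification = x$classification, C_NAD = x$C_NAD,
    J_ATP = x$J_ATP, J_NAD = x$J_NAD, ratio = x$ratio,
    E_total = sum(x$best_profile)
  )
}

#' Repeat an optimization and classify the solutions by pathway
#'
#' Runs `n_repeats` independently seeded EP optimizations and classifies
#' each returned profile as PncA-type (Nampt << PncA), Nampt-type
#' (PncA << Nampt) or mixed, with an abundance-ratio threshold of 1e-2.
#' The bimodality of this classification — optima almost never retain both
#' route entry enzymes — is the central qualitative behaviour of the
#' model.
#'
#' @param problem An `ep_problem` (its seed is ignored in favour of
#'   `seeds`).
#' @param n_repeats Number of runs (default 100).
#' @param seeds Integer vector of seeds, one per run (default
#'   `problem$seed + 0:(n_repeats-1)`).
#' @return A list of class `ep_repeats`: `runs` (tibble, one [glance()]
#'   row per run plus the enzyme abundances), `class_counts`,
#'   `enzyme_summary` (per class and enzyme: median and quartiles).
#' @export
repeat_and_classify <- function(problem, n_repeats = 100, seeds = NULL) {
  stopifnot(n_repeats >= 1)
  seeds <- seeds %||% (problem$seed + seq_len(n_repeats) - 1L)
  stopifnot(length(seeds) == n_repeats)
  runs <- map(seeds, function(s) {
    p <- problem
    p$seed <- as.integer(s)
    run <- run_ep(p)
    dplyr::bind_cols(glance(run),
                     tibble::as_tibble_row(setNames(as.list(run$best_profile),
                                                    paste0("E_", names(run$best_profile)))))
  }) %>% list_rbind()
  class_counts <- runs %>% count(.data$classification, name = "n_runs")
  enzyme_summary <- runs %>%
    filter(.data$feasible) %>%
    tidyr::pivot_longer(dplyr::starts_with("E_"), names_to = "enzyme",
                        names_prefix = "E_", values_to = "abundance_nM") %>%
    group_by(.data$classification, .data$enzyme) %>%
    summarise(
      q25 = stats::quantile(.data$abundance_nM, 0.25),
      median = median(.data$abundance_nM),
      q75 = stats::quantile(.data$abundance_nM, 0.75),
      .groups = "drop"
    )
  structure(list(runs = runs, class_counts = class_counts,
                 enzyme_summary = enzyme_summary, objective = problem$objective,
                 temperature_K = problem$temperature_K),
            class = "ep_repeats")
}

#' @export
print.ep_repeats <- function(x, ...) {
  cat(sprintf("EP repeats: %s at %.2f K, %d runs\n", x$objective,
              x$temperature_K, nrow(x$runs)))
  print(x$class_counts)
  invisible(x)
}

#' Repeat the optimization across a temperature grid
#'
#' Reproduces the temperature-sweep study design: at each temperature,
#' `n_repeats` seeded EP runs are performed and summarised per pathway
#' class. The default grid spans the base temperature to the hottest
#' measured hydrolysis point (363.15 K) in six steps.
#'
#' @param problem An `ep_problem` serving as template (its temperature is
#'   replaced by the grid values).
#' @param temperatures Temperature grid, kelvin (all <= 363.15, the upper
#'   end of the thermolysis fits).
#' @param n_repeats Runs per temperature.
#' @return A list of class `nad_sweep`: `runs` (tidy per-run tibble over
#'   all temperatures) and `class_summary` (class-conditional mean J_ATP,
#'   J_NAD and ratio per temperature). Has an [autoplot()] method.
#' @export
temperature_sweep <- function(problem,
                              temperatures = seq(310.65, 363.15, length.out = 6),
                              n_repeats = 20) {
  if (any(temperatures > 363.15 + 1e-9)) {
    abort("temperatures beyond 363.15 K are outside the thermolysis-fit range", class = "nadtherm_domain_error")
  }
  runs <- imap(temperatures, function(Tk, i) {
    p <- problem
    p$temperature_K <- Tk
    # distinct seed block per temperature, derived from the template seed
    reps <- repeat_and_classify(p, n_repeats,
                                seeds = problem$seed + (i - 1L) * n_repeats + seq_len(n_repeats) - 1L)
    reps$runs
  }) %>% list_rbind()
  class_summary <- runs %>%
    filter(.data$feasible) %>%
    group_by(.data$temperature_K, .data$classification) %>%
    summarise(
      n_runs = n(),
      mean_J_ATP = mean(.data$J_ATP), mean_J_NAD = mean(.data$J_NAD),
      mean_ratio = mean(.data$ratio), mean_C_NAD = mean(.data$C_NAD),
      .groups = "drop"
    )
  structure(list(runs = runs, class_summary = class_summary,
                 objective = problem$objective),
            class = "nad_sweep")
}

#' @export
print.nad_sweep <- function(x, ...) {
  cat(sprintf("Temperature sweep (%s): %d runs over %d temperatures\n",
              x$objective, nrow(x$runs), dplyr::n_distinct(x$runs$temperature_K)))
  print(x$class_summary, n = 20)
  invisible(x)
}
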