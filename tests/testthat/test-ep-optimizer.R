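test_that("the EP core locates the minimum of a quadratic bowl", {
  res <- withr::with_seed(42, nadtherm:::.ep_core(
    function(x) {
      v <- sum((x - 0.3)^2)
      list(value = v, raw = v, feasible = TRUE)
    },
    lb = rep(-5, 5), ub = rep(5, 5), mu = 20, generations = 200, q = 5
  ))
  expect_lt(sqrt(sum((res$best$x - 0.3)^2)), 1e-3)
})

test_that("penalties make any infeasible point worse than any feasible one", {
  p <- ep_problem(default_model, "min_ratio", seed = 1)
  E_ok <- default_enzyme_profile(20)
  ev_ok <- evaluate_objective(p, E_ok)
  # inflate past the budget: strictly worse than the same shape scaled down
  E_bad <- default_enzyme_profile(120)  # 9 * 120 = 1080 nM
  ev_bad <- evaluate_objective(p, E_bad)
  expect_false(ev_bad$feasible)
  expect_gt(ev_bad$value, ev_ok$value)
  expect_gt(ev_bad$value, 1e6)  # offset dominates
  # slightly worse violation is penalized more
  ev_worse <- evaluate_objective(p, default_enzyme_profile(130))
  expect_gt(ev_worse$value, ev_bad$value)
})

test_that("the NAD window constrains min_ratio but not max_nad", {
  p <- ep_problem(default_model, "min_ratio", seed = 1)
  # a profile with no NAD synthesis cannot hold NAD in (0.1, 0.3)
  E_dead <- default_enzyme_profile(0.01)
  E_dead[c("PncA", "Nampt")] <- 1e-10
  ev <- evaluate_objective(p, E_dead)
  expect_false(ev$feasible)
  p2 <- ep_problem(default_model, "max_nad", seed = 1)
  expect_null(p2$nad_range)
  ev2 <- evaluate_objective(p2, E_dead)
  expect_true(ev2$feasible)  # only bounds and budget apply
})

test_that("a feasible pure-Nampt profile scores at least the stoichiometric bound", {
  p <- ep_problem(default_model, "min_ratio", seed = 1)
  E <- default_enzyme_profile(20)
  E["PncA"] <- 1e-10
  ev <- evaluate_objective(p, E)
  expect_true(ev$feasible)
  expect_gte(ev$raw, 2)
})

test_that("runs are deterministic given the seed and respect bounds", {
  p <- ep_problem(default_model, "min_ratio", seed = 7, generations = 30)
  r1 <- run_ep(p)
  r2 <- run_ep(p)
  expect_identical(glance(r1), glance(r2))
  expect_identical(r1$best_profile, r2$best_profile)
  expect_true(all(r1$best_profile >= p$lower - 1e-15))
  expect_true(all(r1$best_profile <= p$upper + 1e-15))
  expect_lte(sum(r1$best_profile), 1000)
})

test_that("profile classification uses the declared abundance-ratio threshold", {
  classify <- nadtherm:::.classify_profile
  E <- default_enzyme_profile(1)
  E["PncA"] <- 1; E["Nampt"] <- 0.009
  expect_equal(classify(E), "pnca_pathway")
  E["Nampt"] <- 0.02
  expect_equal(classify(E), "mixed")
  E["PncA"] <- 1e-4; E["Nampt"] <- 50
  expect_equal(classify(E), "nampt_pathway")
})

test_that("repeat_and_classify with one repeat equals the single run", {
  p <- ep_problem(default_model, "min_ratio", seed = 33, generations = 25)
  reps <- repeat_and_classify(p, n_repeats = 1)
  single <- run_ep(p)
  expect_equal(nrow(reps$runs), 1)
  expect_equal(reps$runs$best_value, single$best_value)
  expect_equal(reps$runs$classification, single$classification)
  expect_equal(reps$class_counts$n_runs, 1)
})

test_that("the min-ratio optimum silences one of the two route enzymes", {
  run <- run_ep(ep_problem(default_model, "min_ratio", seed = 5))
  expect_true(run$feasible)
  E <- run$best_profile
  expect_lt(min(E[["PncA"]], E[["Nampt"]]) / max(E[["PncA"]], E[["Nampt"]]), 1e-2)
  # and approaches the two-ATP stoichiometric floor of the cheaper route
  expect_lt(run$best_value, 2.2)
})

test_that("route conditioning pins the excluded enzyme and orders efficiencies", {
  rp <- run_ep(ep_problem(default_model, "min_ratio", seed = 9, route = "pnca"))
  rn <- run_ep(ep_problem(default_model, "min_ratio", seed = 9, route = "nampt"))
  expect_true(rp$feasible && rn$feasible)
  expect_equal(rp$classification, "pnca_pathway")
  expect_equal(rn$classification, "nampt_pathway")
  expect_equal(rp$best_profile[["Nampt"]], 1e-10)
  # the four-step route pays roughly twice per NAD
  expect_gt(rp$ratio, rn$ratio)
  expect_equal(rp$ratio, 4, tolerance = 0.05)
  expect_equal(rn$ratio, 2, tolerance = 0.05)
})

test_that("temperature_sweep refuses temperatures beyond the fitted range", {
  p <- ep_problem(default_model, "min_ratio", seed = 1)
  expect_error(temperature_sweep(p, temperatures = c(310.65, 380)),
               class = "nadtherm_domain_error")
})
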