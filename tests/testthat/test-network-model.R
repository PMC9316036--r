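test_that("the default network has the documented topology", {
  m <- default_model
  expect_equal(length(m$species), 8)
  expect_equal(nrow(m$reactions), 18)
  expect_equal(sum(m$reactions$kind == "michaelis_menten"), 13)
  expect_equal(sum(m$reactions$kind == "first_order"), 5)
  # pyridine conservation: the all-ones vector is in the left null space
  expect_equal(max(abs(colSums(m$stoichiometry))), 0)
  # the NadE step is the only 2-ATP reaction
  expect_equal(m$reactions$id[m$reactions$atp_cost == 2L], "NadE")
  # NAAD is never hydrolysed
  hyd <- m$reactions[m$reactions$kind == "first_order", ]
  expect_false("NAAD" %in% hyd$substrate)
})

test_that("config validation rejects structural violations", {
  cfg <- nad_default_config()
  bad <- cfg; bad$reactions$PncA$enzyme <- "Foo"
  expect_error(validate_model_config(bad), class = "nadtherm_config_error")
  bad <- cfg; bad$reactions$PncA$atp_cost <- 2
  expect_error(validate_model_config(bad), "NadE", class = "nadtherm_config_error")
  bad <- cfg; bad$reactions$NCE$kcat <- -1
  expect_error(validate_model_config(bad), class = "nadtherm_config_error")
  bad <- cfg
  bad$hydrolysis$reactions$hyd_NAAD <- list(substrate = "NAAD", product = "NA")
  expect_error(validate_model_config(bad), "NAAD", class = "nadtherm_config_error")
})

test_that("reaction rates follow the two rate laws and their limits", {
  m <- default_model
  E <- default_enzyme_profile(20)
  zero <- setNames(rep(0, 8), m$species)
  expect_true(all(reaction_rate(m, zero, E, 310.65) == 0))

  # saturation: S >> Km approaches kcat * E (nM -> mM)
  sat <- zero; sat["NAD"] <- 1e4
  v <- reaction_rate(m, sat, E, 310.65)
  expect_equal(v[["NCE"]], 10 * 20e-6, tolerance = 1e-4)

  # hydrolysis flux of NAD at 90 C equals the fitted rate constant times S,
  # and the fit reproduces the measured 1.60 %/min within a few percent
  s <- zero; s["NAD"] <- 0.3
  v90 <- reaction_rate(m, s, E, 363.15)
  expect_equal(v90[["hyd_NAD"]], convert_rate(1.60, "fraction_per_s") * 0.3,
               tolerance = 0.05)
  expect_error(reaction_rate(m, s - 1, E, 310.65), class = "nadtherm_state_error")
})

test_that("the ODE right-hand side conserves the pyridine moiety", {
  m <- default_model
  profs <- gen_enzyme_profiles(10, seed = 11)
  states <- withr::with_seed(12, {
    lapply(1:10, function(i) {
      x <- runif(8); 0.3 * x / sum(x)
    })
  })
  for (i in 1:10) {
    E <- profile_from_row(profs[i, ])
    d <- ode_rhs(m, setNames(states[[i]], m$species), E, runif(1, 300, 363))
    expect_lt(abs(sum(d)), 1e-12 * max(sqrt(sum(d^2)), 1e-300))
  }
})

test_that("single-reaction limiting cases behave as expected", {
  m <- default_model
  E0 <- default_enzyme_profile(0)
  # all enzymes absent, hydrolysis off: frozen system
  cfg0 <- config_no_hydrolysis()
  m0 <- build_default_model(cfg0)
  s <- default_initial_state(m0)
  expect_true(all(ode_rhs(m0, s, E0, 340) == 0))
  expect_true(all(reaction_rate(m0, s, default_enzyme_profile(50), 340)[
    m0$reactions$kind == "first_order"] == 0))

  # only NCE active: NAD falls, Nam rises, at equal magnitude
  En <- E0; En["NCE"] <- 10
  d <- ode_rhs(m0, s, En, 310.65)
  expect_lt(d[["NAD"]], 0)
  expect_gt(d[["Nam"]], 0)
  expect_equal(d[["NAD"]], -d[["Nam"]])
})

test_that("compiled rate/rhs kernels agree with the R reference implementation", {
  m <- default_model
  arr <- nadtherm:::.model_arrays(m)
  profs <- gen_enzyme_profiles(5, seed = 21)
  withr::with_seed(22, {
    for (i in 1:5) {
      E <- profile_from_row(profs[i, ])
      x <- runif(8); s <- setNames(0.3 * x / sum(x), m$species)
      Tk <- runif(1, 300, 363)
      expect_equal(unname(reaction_rate(m, s, E, Tk)),
                   as.numeric(nadtherm:::.cpp_fluxes(arr, E, Tk, unname(s))),
                   tolerance = 1e-12)
      expect_equal(unname(ode_rhs(m, s, E, Tk)),
                   as.numeric(nadtherm:::.cpp_rhs(arr, E, Tk, unname(s))),
                   tolerance = 1e-12)
    }
  })
})

test_that("temperature coefficients: closed form, Ea = 0, and the default band", {
  m <- default_model
  q <- compute_q10(m)
  # every enzymatic reaction of the default config lies in the 2-3 band
  enz <- q[q$kind == "michaelis_menten", ]
  expect_true(all(enz$q10 >= 2 & enz$q10 <= 3))
  # closed-form spot checks via rescale_to_base
  expect_equal(rescale_to_base(1, 57.4, 310.65)(320.65), 2, tolerance = 0.005)
  expect_equal(unname(rescale_to_base(1, 0, 310.65)(320.65)), 1)
  # each reaction's flux at fixed state is non-decreasing in temperature
  E <- default_enzyme_profile()
  s <- setNames(rep(0.3 / 8, 8), m$species)
  v1 <- reaction_rate(m, s, E, 310.65)
  v2 <- reaction_rate(m, s, E, 340)
  expect_true(all(v2 >= v1))
})
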