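# Shared fixtures, built once per test run.

table1 <- read_rate_table(nadtherm_example("table1_thermolysis.tsv"))

default_model <- build_default_model()

# config with hydrolysis switched off entirely (explicit zero rates)
config_no_hydrolysis <- function() {
  cfg <- nad_default_config()
  cfg$hydrolysis$source <- "explicit"
  for (id in names(cfg$hydrolysis$reactions)) {
    cfg$hydrolysis$reactions[[id]]$k_per_s_at_T0 <- 0
    cfg$hydrolysis$reactions[[id]]$Ea <- 0
  }
  cfg
}

# named enzyme vector from a row of gen_enzyme_profiles() output
profile_from_row <- function(row) {
  setNames(as.numeric(row), sub("^E_", "", names(row)))
}

R_GAS <- 8.314
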