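# Memoized fixtures: expensive simulated panels and fits are built once
# per test run and shared across test files.
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures))
    assign(name, builder(), envir = .fixtures)
  get(name, envir = .fixtures)
}

# small panel: cheap enough for MCMC-backed tests
small_sim <- function() fixture("small_sim", function()
  generate_panel(generator_config(seed = 7, n_states = 8,
                                  counties_per_state = 8,
                                  missing_rate = 0)))

small_imp <- function() fixture("small_imp", function()
  fit_imputation_model(small_sim()$deaths,
                       spec = imputation_spec(seed = 7, adapt = 300,
                                              warmup = 300, draws = 800)))

# medium panel for mixed-model structure tests
med_sim <- function() fixture("med_sim", function()
  generate_panel(generator_config(seed = 11, n_states = 25,
                                  counties_per_state = 25)))

med_design <- function() fixture("med_design", function() {
  sim <- med_sim()
  rates <- age_adjust(sim$deaths[sim$deaths$cause_group == "all_cause", ])
  suppressMessages(build_design(sim$panel, rates))
})

med_fit <- function() fixture("med_fit", function()
  suppressWarnings(fit_primary(med_design())))

# full-scale default panel (structure-of-the-study checks)
default_sim <- function() fixture("default_sim", function()
  suppressMessages(generate_panel(generator_config(seed = 42))))

# long-format death table built by hand for standardization unit tests
toy_death_table <- function(counts, person_years,
                            age_groups = as.character(us_standard_population()$age_group),
                            county = "C1", period = 2015,
                            cause = "all_cause") {
  data.frame(county_id = county, period = period, cause_group = cause,
             age_group = age_groups, count = counts,
             person_years = person_years, stringsAsFactors = FALSE)
}
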