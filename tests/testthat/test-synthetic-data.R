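test_that("regeneration with the same seed is identical", {
  cfg <- generator_config(seed = 13, n_states = 5, counties_per_state = 6,
                          missing_rate = 0)
  a <- generate_panel(cfg)
  b <- generate_panel(cfg)
  expect_identical(a, b)
})

test_that("noise-free limit: net gain equals the fixed-effect predictor", {
  cfg <- generator_config(seed = 3, n_states = 5, counties_per_state = 8,
                          sigma_state_intercept = 0, sigma_state_slope = 0,
                          sigma_residual = 0, missing_rate = 0)
  sim <- generate_panel(cfg)
  expect_equal(sim$truth$g, sim$truth$fixed_lp, tolerance = 1e-12)
  # the gain reconstructed from emitted shares equals the predictor for
  # every county whose shares were not clipped
  g_shares <- with(sim$panel, net_republican_gain(R08, R16, D08, D16))
  if (sim$n_clipped == 0)
    expect_equal(g_shares, unname(sim$truth$fixed_lp), tolerance = 1e-9)

  # all-zero coefficients with zero variances: gain = intercept everywhere
  b0 <- cfg$true_coefficients
  b0[] <- 0; b0["intercept"] <- 12
  cfg2 <- generator_config(seed = 3, n_states = 5, counties_per_state = 8,
                           sigma_state_intercept = 0, sigma_state_slope = 0,
                           sigma_residual = 0, missing_rate = 0,
                           true_coefficients = b0)
  sim2 <- generate_panel(cfg2)
  expect_equal(unname(sim2$truth$g), rep(12, nrow(sim2$panel)))
})

test_that("panel satisfies its structural invariants", {
  sim <- small_sim()
  p <- sim$panel
  # shares within [0,100] and party shares sum to <= 100 per election
  for (v in c("R00", "D00", "R08", "D08", "R16", "D16")) {
    expect_true(all(p[[v]] >= 0 & p[[v]] <= 100))
  }
  expect_true(all(p$R08 + p$D08 <= 100 + 1e-9))
  expect_true(all(p$R16 + p$D16 <= 100 + 1e-9))
  # share x total reproduces counts within rounding
  expect_true(all(abs(p$votes_R16 - p$R16 / 100 * p$votes_total_2016) <= 0.5))
  expect_true(all(abs(p$votes_D08 - p$D08 / 100 * p$votes_total_2008) <= 0.5))
  # one state per county
  expect_equal(anyDuplicated(p$county_id), 0L)
  # urban-rural classes are 1..6 and decrease with population
  expect_true(all(p$urban_rural %in% 1:6))
  expect_true(all(p$urban_rural[p$population < 10000] == 6L))

  # all_cause cell counts equal despair + other (and so dominate despair)
  d <- sim$deaths
  key <- paste(d$county_id, d$period, d$age_group)
  ac <- d$count[d$cause_group == "all_cause"]
  oth <- d$count[d$cause_group == "other"]
  dsp_true <- d$count[d$cause_group == "despair"]
  dsp_true[is.na(dsp_true)] <-
    sim$oracle$true_count[match(key[d$cause_group == "despair"][is.na(dsp_true)],
                                paste(sim$oracle$county_id, sim$oracle$period,
                                      sim$oracle$age_group))]
  expect_equal(ac, oth + dsp_true)
})

test_that("oracle holds exactly the suppressed cells, never published ones", {
  sim <- small_sim()
  d <- sim$deaths
  expect_equal(nrow(sim$oracle), sum(d$suppressed))
  expect_true(all(is.na(d$count[d$suppressed])))
  expect_true(all(!is.na(d$count[!d$suppressed])))
  # every oracle value lies inside the censoring interval
  thr <- sim$truth$config$suppression_threshold
  expect_true(all(sim$oracle$true_count >= 1 &
                    sim$oracle$true_count < thr))
})

test_that("suppression of rare-cause cells rises as population falls", {
  # zeros are published, not suppressed, so the monotone relationship is
  # over cells where deaths occurred: the smaller the county, the more
  # likely a nonzero count falls inside the censoring interval.
  sim <- default_sim()
  d <- sim$deaths[sim$deaths$cause_group == "despair", ]
  nonzero <- d$suppressed | (!is.na(d$count) & d$count > 0)
  d <- d[nonzero, ]
  frac <- tapply(d$suppressed, d$county_id, mean)
  pop <- sim$panel$population[match(names(frac), sim$panel$county_id)]
  dec <- cut(rank(pop, ties.method = "first"), 10, labels = FALSE)
  by_dec <- tapply(frac, dec, mean)
  # monotone non-increasing in population decile
  expect_true(all(diff(by_dec) <= 0))
  expect_gt(by_dec[1], by_dec[10])
})

test_that("state intercept dispersion approaches its generating value", {
  cfg <- function(s) generator_config(seed = s, n_states = 200,
                                      counties_per_state = 3,
                                      missing_rate = 0)
  v <- sapply(1:5, function(s) var(generate_panel(cfg(s))$truth$u_state))
  expect_equal(mean(v), 61.87, tolerance = 0.2)
})

test_that("invalid configurations are rejected", {
  expect_error(generator_config(urban_thresholds = c(5, 4, 3, 2, 1)),
               "increasing")
  expect_error(generator_config(rho_intercept_slope = 1.2), "rho")
  expect_error(generator_config(sigma_residual = -1), ">= 0")
  expect_error(generator_config(nonsense_field = 1), "unknown")
})

test_that("simulation bundles round-trip through CSV", {
  sim <- generate_panel(generator_config(seed = 2, n_states = 4,
                                         counties_per_state = 4,
                                         missing_rate = 0))
  dir <- tempfile("simout")
  paths <- write_sim(sim, dir)
  expect_true(all(file.exists(paths)))
  panel2 <- read_panel(paths["panel"])
  expect_equal(panel2$R16, sim$panel$R16, tolerance = 1e-12)
  deaths2 <- read_death_table(paths["deaths"])
  expect_equal(sum(deaths2$suppressed), sum(sim$deaths$suppressed))
  expect_true(all(is.na(deaths2$count[deaths2$suppressed])))
  unlink(dir, recursive = TRUE)
})
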