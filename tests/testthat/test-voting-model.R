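test_that("piecewise population basis is continuous at the knot", {
  sim <- med_sim()
  des <- med_design()
  # hinge is exactly zero at the knot
  d <- des$data
  expect_true(all(d$hinge[d$population <= 50000] == 0))
  expect_true(all(d$hinge[d$population > 50000] > 0))
  # predictor continuous: contributions just below/above the knot agree
  fit <- med_fit()
  bl <- fit$pop_slopes["below_knot"]
  ab <- fit$pop_slopes["above_knot"]
  eps <- 1e-8
  lo <- bl * log10(50000 - eps)
  hi <- bl * log10(50000) + ab * (log10(50000 + eps) - log10(50000))
  expect_equal(unname(lo), unname(bl * log10(50000)), tolerance = 1e-10)
  expect_equal(unname(hi), unname(bl * log10(50000)), tolerance = 1e-10)
  # a 10-fold increase below the knot moves the predictor by exactly the
  # below-knot coefficient (log10 semantics)
  expect_equal(unname(bl * log10(20000) - bl * log10(2000)), unname(bl))
})

test_that("design building applies the complete-case rule", {
  sim <- med_sim()
  rates <- age_adjust(sim$deaths[sim$deaths$cause_group == "all_cause", ])
  n_na <- sum(!complete.cases(
    sim$panel[, grep("_2015$|_2000$", names(sim$panel))]))
  expect_gt(n_na, 0)
  expect_message(des <- build_design(sim$panel, rates), "complete-case")
  expect_equal(des$n_excluded, n_na)
  expect_equal(nrow(des$data), nrow(sim$panel) - n_na)
  bad <- sim$panel; bad$population[1] <- 0
  expect_error(build_design(bad, rates), "population")
})

test_that("table presentation: magnitude per 1% gain is the reciprocal", {
  fit <- med_fit()
  co <- fit$coefficients
  expect_equal(co$magnitude_per_1pct * co$estimate,
               rep(1, nrow(co)), tolerance = 1e-12)
})

test_that("rescaling the death-rate covariate rescales only its slope", {
  des <- med_design()
  fit <- med_fit()
  des2 <- des
  des2$data$d_rate_s <- des2$data$d_rate_s * 2
  fit2 <- suppressWarnings(fit_primary(des2))
  i <- fit$coefficients$term == "d_rate"
  expect_equal(fit2$coefficients$estimate[i],
               fit$coefficients$estimate[i] / 2, tolerance = 1e-3)
  expect_equal(fitted(fit2$fit), fitted(fit$fit), tolerance = 1e-4)
  expect_equal(fit2$r2, fit$r2, tolerance = 1e-5)
})

test_that("equal weights reproduce the unweighted fit", {
  des <- med_design()
  fit <- med_fit()
  # unit weights: identical model, exact agreement
  fit1 <- suppressWarnings(fit_primary(des, weights = rep(1, nrow(des$data))))
  expect_equal(fit1$coefficients$estimate, fit$coefficients$estimate,
               tolerance = 1e-9)
  # any constant weight: same estimates up to optimizer tolerance
  fitw <- suppressWarnings(fit_primary(des, weights = rep(2, nrow(des$data))))
  expect_equal(fitw$coefficients$estimate, fit$coefficients$estimate,
               tolerance = 1e-4)
  expect_equal(fitw$r2, fit$r2, tolerance = 1e-5)
})

test_that("full-rank PCA reproduces the primary fit", {
  des <- med_design()
  fit <- med_fit()
  fitp <- suppressWarnings(fit_pca(des, var_frac = 1))
  expect_equal(fitp$n_components, 8)
  expect_equal(unname(fitted(fitp$fit)), unname(fitted(fit$fit)),
               tolerance = 1e-6)
  i <- which(fit$coefficients$term == "d_rate")
  j <- which(fitp$coefficients$term == "d_rate")
  expect_equal(fitp$coefficients$estimate[j], fit$coefficients$estimate[i],
               tolerance = 1e-6)
})

test_that("R-squared decomposition is ordered and bounded", {
  fit <- med_fit()
  expect_gte(fit$r2["fixed"], 0)
  expect_lte(fit$r2["fixed"], fit$r2["total"])
  expect_lte(fit$r2["total"], 1)
})

test_that("noise-free data give a perfect fit", {
  cfg <- generator_config(seed = 17, n_states = 10, counties_per_state = 15,
                          sigma_state_intercept = 0, sigma_state_slope = 0,
                          sigma_residual = 0, missing_rate = 0)
  sim <- generate_panel(cfg)
  rates <- age_adjust(sim$deaths[sim$deaths$cause_group == "all_cause", ])
  des <- build_design(sim$panel, rates)
  fit <- suppressWarnings(fit_primary(des))
  expect_equal(unname(fit$r2["total"]), 1, tolerance = 1e-6)
})

test_that("zero generating slope variance is recovered as near zero", {
  cfg <- generator_config(seed = 23, n_states = 30, counties_per_state = 40,
                          sigma_state_slope = 0, missing_rate = 0)
  sim <- generate_panel(cfg)
  rates <- age_adjust(sim$deaths[sim$deaths$cause_group == "all_cause", ])
  des <- build_design(sim$panel, rates)
  fit <- suppressWarnings(fit_primary(des))
  # fitted slope SD far below the fixed slope
  expect_lt(sqrt(fit$random$sigma2_slope), 0.5 * 1 / 131)
  i <- fit$coefficients$term == "d_rate"
  expect_lt(abs(fit$coefficients$estimate[i] - 1 / 131),
            3 * fit$coefficients$se[i])
})

test_that("without the random slope the model is the covariate-extended
           random-intercept model", {
  des <- med_design()
  fit_ri <- fit_primary(des, random_slope = FALSE)
  f <- as.formula(paste("g ~",
    paste(c(des$covariates, "d_rate_s", "rural", "l10pop", "hinge"),
          collapse = " + "), "+ (1 | state_id)"))
  ref <- lme4::lmer(f, data = des$data, REML = FALSE)
  got <- fit_ri$coefficients$estimate
  want <- unname(lme4::fixef(ref))
  want[fit_ri$coefficients$term == "d_rate"] <-
    want[fit_ri$coefficients$term == "d_rate"] / 100
  expect_equal(got, want, tolerance = 1e-6)
  expect_equal(fit_ri$random$sigma2_slope, 0)
})

test_that("sensitivity fits agree on the death-rate slope direction", {
  des <- med_design()
  fit <- med_fit()
  sens <- suppressWarnings(sensitivity_suite(des))
  slopes <- c(primary = fit$coefficients$estimate[fit$coefficients$term == "d_rate"],
              sapply(sens, function(f)
                f$coefficients$estimate[f$coefficients$term == "d_rate"]))
  ses <- c(fit$coefficients$se[fit$coefficients$term == "d_rate"],
           sapply(sens, function(f)
             f$coefficients$se[f$coefficients$term == "d_rate"]))
  expect_true(all(sign(slopes) == sign(slopes[1])))
  # estimates overlap within 2 SE of the primary estimate
  expect_true(all(abs(slopes - slopes[1]) <= 2 * (ses + ses[1])))
})

test_that("despair-split secondary model pools across imputations", {
  sim <- small_sim()
  rates <- age_adjust(sim$deaths[sim$deaths$cause_group != "despair", ])
  des <- build_design(sim$panel, rates)
  out <- fit_despair_split(des, small_imp(), sim$deaths)
  expect_true(all(c("d_despair", "d_other") %in% out$pooled$term))
  expect_length(out$per_dataset, small_imp()$M)
  expect_true(all(out$pooled$se > 0))
})
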