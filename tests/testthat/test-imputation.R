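test_that("imputed counts respect the censoring interval in every dataset", {
  sim <- small_sim()
  imp <- small_imp()
  expect_length(imp$datasets, imp$M)
  cen_rows <- is.na(sim$deaths$count[sim$deaths$cause_group == "despair"])
  for (d in imp$datasets) {
    v <- d$count[cen_rows]
    expect_true(all(v >= 1 & v <= 9))
    expect_false(any(is.na(d$count)))
  }
  # observed cells identical across datasets
  obs <- !cen_rows
  base <- imp$datasets[[1]]$count[obs]
  for (d in imp$datasets[-1]) expect_identical(d$count[obs], base)
  # convergence diagnostics are reported and within the bound
  expect_true(all(imp$diagnostics$rhat < imp$spec$rhat_max))
})

test_that("a table with no censored cells returns identical copies", {
  tab <- small_sim()$deaths
  tab <- tab[tab$cause_group == "other", ]
  tab$cause_group <- "despair"  # fully observed stream
  imp <- fit_imputation_model(tab, spec = imputation_spec(M = 4))
  expect_length(imp$datasets, 4)
  expect_identical(imp$datasets[[1]], imp$datasets[[3]])
  expect_null(imp$summaries)
})

test_that("model-based imputation beats the midpoint fill", {
  sim <- small_sim()
  cal <- imputation_calibration(small_imp(), sim$oracle)
  key <- paste(small_imp()$summaries$county_id,
               small_imp()$summaries$period,
               small_imp()$summaries$age_group)
  tru <- sim$oracle$true_count[match(key, paste(sim$oracle$county_id,
                                                sim$oracle$period,
                                                sim$oracle$age_group))]
  mae_mid <- mean(abs(5 - tru))
  expect_lt(cal$mae, mae_mid)
})

test_that("tiny-county imputations shrink toward the state mean rate", {
  # large counties with a well-observed rate, one tiny county with
  # censored cells. The tiny county's imputed rate must sit between the
  # naive interval-midpoint rate (huge at tiny person-years) and the
  # state-level rate. With only two states the group-scale parameter
  # mixes slowly, so the toy uses a longer chain and a looser Rhat bound.
  py_big <- 2e5; py_tiny <- 3000
  rate <- 30 / 1e5
  set.seed(5)
  mk <- function(id, st, py, count, suppressed) {
    data.frame(county_id = id, state_id = st,
               period = rep(c(2000, 2015), each = 1),
               cause_group = "despair", age_group = "all",
               count = count, person_years = py,
               suppressed = suppressed, stringsAsFactors = FALSE)
  }
  big <- do.call(rbind, lapply(1:8, function(i)
    mk(paste0("B", i), if (i <= 4) "S1" else "S2", py_big,
       rpois(2, py_big * rate), FALSE)))
  tiny <- mk("T1", "S1", py_tiny, NA_integer_, TRUE)
  tab <- rbind(big, tiny)
  imp <- fit_imputation_model(tab, spec = imputation_spec(
    seed = 9, adapt = 500, warmup = 1000, draws = 2000, rhat_max = 1.1))
  tiny_rate <- 1e5 * imp$summaries$post_mean / py_tiny
  midpoint_rate <- 1e5 * 5 / py_tiny          # ~167 per 100,000
  state_rate <- 1e5 * mean(big$count / big$person_years)
  expect_true(all(tiny_rate < midpoint_rate))
  expect_true(all(tiny_rate > 0.5 * state_rate))
})

test_that("age-adjust-then-combine equals combine-then-age-adjust", {
  imp <- small_imp()
  std <- us_standard_population()
  # path 1: adjusted rate per completed dataset, then the Rubin mean
  per <- lapply(imp$datasets, function(d) rate_change(age_adjust(d, std)))
  ids <- per[[1]]$county_id
  mat <- sapply(per, function(p) p$delta[match(ids, p$county_id)])
  path1 <- rowMeans(mat)
  # path 2: average the completed counts cell-wise, then adjust once
  avg <- imp$datasets[[1]]
  avg$count <- rowMeans(sapply(imp$datasets, `[[`, "count"))
  p2 <- rate_change(age_adjust(avg, std))
  path2 <- p2$delta[match(ids, p2$county_id)]
  expect_equal(path1, path2, tolerance = 1e-9)
})

test_that("non-convergence is an error, not silent output", {
  sim <- small_sim()
  expect_error(
    fit_imputation_model(sim$deaths,
                         spec = imputation_spec(seed = 1, adapt = 60,
                                                warmup = 0, draws = 60,
                                                rhat_max = 1.0001)),
    "did not converge")
})

test_that("censoring rules and spec validation", {
  r <- censoring_rule()
  expect_equal(r$upper, 9L)
  expect_equal(censoring_rule(threshold = 6, lower = 0)$upper, 5L)
  expect_error(censoring_rule(lower = 2), "0 or 1")
  expect_error(imputation_spec(M = 1), "M must be")
  expect_error(imputation_spec(chains = 1, draws = 3, M = 5), ">= M")
  expect_error(fit_imputation_model(small_sim()$deaths, cause = "nope"),
               "no rows")
})

test_that("midpoint fill is the deterministic baseline", {
  tab <- data.frame(county_id = "a", state_id = "s", period = 2000,
                    cause_group = "despair", age_group = "all",
                    count = c(NA, 12L), person_years = 1000,
                    suppressed = c(TRUE, FALSE))
  out <- midpoint_fill(tab)
  expect_equal(out$count, c(5L, 12L))
})
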