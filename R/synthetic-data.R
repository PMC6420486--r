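#' Configuration for the synthetic county-panel generator
#'
#' Returns the default generator configuration, optionally overridden.
#' Defaults emulate the structure of the US county panel the analysis
#' assumes: ~50 states holding ~3,100 counties with heavy-right-skewed
#' populations, covariate changes between two time points whose means and
#' spreads follow published county tables, a net-Republican-gain outcome
#' driven by a known linear predictor with state random intercepts and
#' state random slopes on the death-rate change, Poisson death counts by
#' age group for an all-cause and a rare-cause ("deaths of despair")
#' stream, and left-censoring of small rare-cause counts.
#'
#' \code{true_coefficients} are in percentage points of net gain per unit
#' of each covariate change (income in $1000s, death rate per 1/100,000);
#' \code{rural} is the rural-vs-urban contrast and \code{log10_pop_below}
#' / \code{log10_pop_above} the piecewise population slopes per 10-fold
#' population increase below/above the 50,000 knot.
#'
#' @param ... named overrides of any default field.
#' @return a list of class \code{generator_config}.
#' @export
generator_config <- function(...) {
  cfg <- list(
    n_states = 50,
    # per-state county counts drawn lognormal (min 3), total ~ 3,100
    counties_per_state = list(meanlog = log(55), sdlog = 0.5),
    seed = 1L,
    population_log10_mean = 4.4,
    population_log10_sd = 0.65,
    # population cutoffs mapping to the 6 ordered urban-rural classes
    # (class 6 = smallest/noncore ... class 1 = large central metro)
    urban_thresholds = c(10000, 50000, 250000, 1e6, 5e6),
    # 2000 baseline levels for the eight covariates
    covariate_baseline_means = c(median_age = 37.5, pct_black = 8.5,
      pct_hispanic = 4.8, pct_asian = 0.7, median_income = 36.1,
      unemployment = 4.4, pct_bachelor = 14.6, pct_insured = 85.5),
    covariate_baseline_sds = c(median_age = 3.6, pct_black = 14.1,
      pct_hispanic = 10.0, pct_asian = 2.6, median_income = 7.5,
      unemployment = 1.6, pct_bachelor = 5.2, pct_insured = 4.8),
    # 2000 -> 2015 changes
    covariate_change_means = c(median_age = 4.0, pct_black = 0.5,
      pct_hispanic = 2.6, pct_asian = 0.5, median_income = 10.4,
      unemployment = 1.2, pct_bachelor = 4.1, pct_insured = 5.4),
    covariate_change_sds = c(median_age = 2.5, pct_black = 1.6,
      pct_hispanic = 2.6, pct_asian = 0.6, median_income = 4.9,
      unemployment = 1.2, pct_bachelor = 2.6, pct_insured = 3.4),
    # points of net gain per unit change; death_rate per 1/100,000
    true_coefficients = c(intercept = 34.6,
      median_age = 1 / 44.51, pct_black = -1 / 3.86,
      pct_hispanic = -1 / 2.35, pct_asian = -1 / 0.72,
      median_income = -1 / 7.504, unemployment = -1 / 3.49,
      pct_bachelor = -1 / 1.99, pct_insured = -1 / 2.56,
      death_rate = 1 / 131, rural = 3.53,
      log10_pop_below = -2.97, log10_pop_above = -7.21),
    sigma_state_intercept = sqrt(61.87),
    sigma_state_slope = 0.003,
    rho_intercept_slope = 0.49,
    sigma_residual = 6.8,
    # all-cause age-adjusted mortality, per 100,000
    baseline_death_rate_mean = 922, baseline_death_rate_sd = 140,
    death_rate_change_mean = -77, death_rate_change_sd = 120,
    death_rate_change_pop_slope = -40,  # extra decline per SD of log10 pop
    # rare-cause stream: lognormal county rates with state/county effects
    despair_rate_params = list(rate_2000 = 22, sigma_state = 0.25,
                               sigma_county = 0.35,
                               log_trend_mean = log(46 / 24),
                               log_trend_sd = 0.20),
    suppression_threshold = 10L,
    # third-party dynamics: other-candidate share and its 2016 rise
    other_share_2008_mean = 1.5, other_share_2008_sd = 0.5,
    other_share_rise_mean = 3.5, other_share_rise_sd = 1.8,
    turnout_mean = 0.42, turnout_sd = 0.05,
    missing_rate = 88 / 3112
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    abort_input("unknown generator_config fields: ",
                paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  validate_generator_config(cfg)
  class(cfg) <- c("generator_config", "list")
  cfg
}

#' Validate a generator configuration
#' @param cfg a \code{generator_config} (or plain list with its fields).
#' @return invisibly TRUE; errors if invalid.
#' @export
validate_generator_config <- function(cfg) {
  stopifnot(cfg$n_states >= 1)
  if (cfg$population_log10_mean <= 0)
    abort_input("population scale must be positive")
  if (any(diff(cfg$urban_thresholds) <= 0))
    abort_input("urban_thresholds must be strictly increasing")
  if (length(cfg$urban_thresholds) != 5)
    abort_input("need 5 urban thresholds for 6 classes")
  if (cfg$sigma_state_intercept < 0 || cfg$sigma_state_slope < 0 ||
      cfg$sigma_residual < 0)
    abort_input("variance parameters must be >= 0")
  if (cfg$sigma_residual == 0 &&
      (cfg$sigma_state_intercept > 0 || cfg$sigma_state_slope > 0)) {
    # allowed: pure random-effect noise
  }
  if (abs(cfg$rho_intercept_slope) > 1)
    abort_input("|rho_intercept_slope| must be <= 1")
  if (cfg$suppression_threshold < 1)
    abort_input("suppression_threshold must be >= 1")
  invisible(TRUE)
}

# internal: map populations to the 6 ordered urban-rural classes
# (1 = most urban, 6 = least)
urban_class <- function(population, thresholds) {
  6L - findInterval(population, thresholds)
}

#' Generate a synthetic county panel and death table
#'
#' Produces a county panel (one row per county: state nesting, population,
#' urban-rural class, covariates at both periods, vote shares and counts
#' for the 2000, 2008 and 2016 elections) together with a long-format
#' death table (county x period x cause group x age group counts with
#' person-years and suppression flags) and an oracle table holding the
#' true values of suppressed cells.
#'
#' The net Republican gain of each county is constructed as
#' \code{intercept + X beta + u_state + (beta_death + v_state) * delta_rate
#' + residual}, where \code{delta_rate} is the county's realized
#' (count-derived) change in age-adjusted all-cause death rate and
#' \code{(u, v)} are bivariate-normal state effects. The gain is then split
#' into party share changes via the third-party share dynamic, so that
#' recomputing the gain from the emitted shares recovers the linear
#' predictor exactly (up to share clipping at \code{[0, 100]}, which is
#' counted in \code{n_clipped}).
#'
#' @param config a \code{generator_config}.
#' @return list of class \code{county_sim}:
#'   \item{panel}{county panel data.frame}
#'   \item{deaths}{death table (suppressed cells have \code{count = NA})}
#'   \item{oracle}{true counts of suppressed cells (kept separate so
#'     imputation tests cannot leak)}
#'   \item{truth}{generating parameters: coefficients, state effects,
#'     per-county linear predictor and realized death-rate change}
#'   \item{n_clipped}{counties where a share had to be clipped}
#' @export
generate_panel <- function(config = generator_config()) {
  validate_generator_config(config)
  cfg <- config
  set.seed(cfg$seed)

  ## --- geography -----------------------------------------------------
  S <- cfg$n_states
  cps <- cfg$counties_per_state
  n_c <- if (is.numeric(cps) && length(cps) == 1) {
    rep(as.integer(cps), S)
  } else {
    pmax(3L, as.integer(round(stats::rlnorm(S, cps$meanlog, cps$sdlog))))
  }
  N <- sum(n_c)
  state_id <- rep(sprintf("S%02d", seq_len(S)), n_c)
  county_id <- sprintf("C%05d", seq_len(N))
  state_idx <- rep(seq_len(S), n_c)

  population <- pmax(100L, as.integer(round(
    10^stats::rnorm(N, cfg$population_log10_mean, cfg$population_log10_sd))))
  ur <- urban_class(population, cfg$urban_thresholds)
  rural <- as.integer(ur >= 5)

  ## --- covariates ----------------------------------------------------
  covs <- names(cfg$covariate_change_means)
  x2000 <- sapply(covs, function(v)
    stats::rnorm(N, cfg$covariate_baseline_means[v],
                 cfg$covariate_baseline_sds[v]))
  # percentage-type covariates live in [0, 100]
  pctv <- grepl("^pct_|^unemployment", covs)
  x2000[, pctv] <- pmin(100, pmax(0, x2000[, pctv]))
  dx <- sapply(covs, function(v)
    stats::rnorm(N, cfg$covariate_change_means[v],
                 cfg$covariate_change_sds[v]))
  x2015 <- x2000 + dx
  x2015[, pctv] <- pmin(100, pmax(0, x2015[, pctv]))
  dx <- x2015 - x2000

  ## --- death counts --------------------------------------------------
  std <- us_standard_population()
  A <- nrow(std)
  # county age structure: standard weights with mild county-level tilt
  tilt <- matrix(stats::rnorm(N * A, 0, 0.10), N, A)
  agew <- sweep(exp(tilt), 2, std$weight, `*`)
  agew <- agew / rowSums(agew)
  py <- agew * population  # person-years per county x age

  zpop <- (log10(population) - cfg$population_log10_mean) /
    cfg$population_log10_sd
  aa2000 <- pmax(200, stats::rnorm(N, cfg$baseline_death_rate_mean,
                                   cfg$baseline_death_rate_sd))
  d_aa <- cfg$death_rate_change_mean +
    cfg$death_rate_change_pop_slope * zpop +
    stats::rnorm(N, 0, cfg$death_rate_change_sd)
  aa2015 <- pmax(150, aa2000 + d_aa)

  dp <- cfg$despair_rate_params
  u_dsp_state <- stats::rnorm(S, 0, dp$sigma_state)
  desp2000 <- dp$rate_2000 *
    exp(u_dsp_state[state_idx] +
          stats::rnorm(N, 0, dp$sigma_county) - dp$sigma_county^2 / 2)
  desp2015 <- desp2000 *
    exp(stats::rnorm(N, dp$log_trend_mean, dp$log_trend_sd))
  desp2000 <- pmin(desp2000, 0.5 * aa2000)
  desp2015 <- pmin(desp2015, 0.5 * aa2015)

  shp_d <- despair_age_shape(std)
  shp_o <- other_age_shape(std)
  draw_counts <- function(overall_rate, shape) {
    # stratum rate = overall * shape_a; age-adjusted rate == overall
    mu <- sweep(py, 2, shape, `*`) * overall_rate / 1e5
    matrix(stats::rpois(N * A, as.vector(mu)), N, A)
  }
  cnt <- list(
    despair_2000 = draw_counts(desp2000, shp_d),
    despair_2015 = draw_counts(desp2015, shp_d),
    other_2000   = draw_counts(pmax(aa2000 - desp2000, 10), shp_o),
    other_2015   = draw_counts(pmax(aa2015 - desp2015, 10), shp_o)
  )

  mk_long <- function(m, period, cause) {
    data.frame(county_id = rep(county_id, A),
               state_id = rep(state_id, A),
               period = period, cause_group = cause,
               age_group = rep(as.character(std$age_group), each = N),
               count = as.vector(m),
               person_years = as.vector(py),
               stringsAsFactors = FALSE)
  }
  deaths <- rbind(
    mk_long(cnt$despair_2000, 2000, "despair"),
    mk_long(cnt$despair_2015, 2015, "despair"),
    mk_long(cnt$other_2000, 2000, "other"),
    mk_long(cnt$other_2015, 2015, "other"),
    mk_long(cnt$despair_2000 + cnt$other_2000, 2000, "all_cause"),
    mk_long(cnt$despair_2015 + cnt$other_2015, 2015, "all_cause")
  )

  # left-censoring of the rare-cause stream: counts in [1, threshold-1]
  thr <- cfg$suppression_threshold
  deaths$suppressed <- deaths$cause_group == "despair" &
    deaths$count >= 1 & deaths$count < thr
  oracle <- deaths[deaths$suppressed,
                   c("county_id", "period", "cause_group", "age_group",
                     "count")]
  names(oracle)[5] <- "true_count"
  deaths$count[deaths$suppressed] <- NA_integer_

  ## --- realized death-rate change (the model covariate) --------------
  all_cause <- deaths[deaths$cause_group == "all_cause", ]
  rates <- age_adjust(all_cause, std)
  rc <- rate_change(rates)
  rc <- rc[match(county_id, rc$county_id), ]
  delta_rate <- rc$delta

  ## --- outcome -------------------------------------------------------
  b <- cfg$true_coefficients
  # bivariate normal (u_s, v_s); parameterization robust to zero scales
  z1 <- stats::rnorm(S); z2 <- stats::rnorm(S)
  rho <- cfg$rho_intercept_slope
  u_s <- cfg$sigma_state_intercept * z1
  v_s <- cfg$sigma_state_slope * (rho * z1 + sqrt(1 - rho^2) * z2)

  l10 <- log10(population)
  hinge <- pmax(0, l10 - log10(50000))
  fixed_lp <- b["intercept"] +
    as.vector(dx %*% b[covs]) +
    b["death_rate"] * delta_rate +
    b["rural"] * rural +
    b["log10_pop_below"] * l10 +
    (b["log10_pop_above"] - b["log10_pop_below"]) * hinge
  g <- fixed_lp + u_s[state_idx] + v_s[state_idx] * delta_rate +
    stats::rnorm(N, 0, cfg$sigma_residual)

  ## --- vote shares ---------------------------------------------------
  other08 <- pmax(0.2, stats::rnorm(N, cfg$other_share_2008_mean,
                                    cfg$other_share_2008_sd))
  R08 <- pmin(92, pmax(5, stats::rnorm(N, 55, 12)))
  D08 <- 100 - R08 - other08
  d_other <- pmax(0.1 - other08,
                  stats::rnorm(N, cfg$other_share_rise_mean,
                               cfg$other_share_rise_sd))
  # g = dR - dD and dR + dD = -d_other jointly determine both changes
  R16 <- R08 + (g - d_other) / 2
  D16 <- D08 - (g + d_other) / 2
  clipped <- R16 < 0 | R16 > 100 | D16 < 0 | D16 > 100
  n_clipped <- sum(clipped)
  if (n_clipped > 0)
    message(n_clipped, " counties had shares clipped to [0, 100]")
  R16 <- pmin(100, pmax(0, R16))
  D16 <- pmin(100, pmax(0, D16))

  # 2000 election baseline (for the alternative-outcome sensitivity)
  other00 <- pmax(0.2, stats::rnorm(N, 2.5, 1.0))
  R00 <- pmin(95, pmax(2, R08 + stats::rnorm(N, 2, 4)))
  D00 <- pmax(0, 100 - R00 - other00)

  turnout <- pmin(0.6, pmax(0.25, stats::rnorm(N, cfg$turnout_mean,
                                               cfg$turnout_sd)))
  total_votes <- round(population * turnout)
  votes <- function(share) as.integer(round(share / 100 * total_votes))

  panel <- data.frame(
    county_id = county_id, state_id = state_id,
    population = population, urban_rural = ur, rural = rural,
    stringsAsFactors = FALSE
  )
  for (v in covs) {
    panel[[paste0(v, "_2000")]] <- x2000[, v]
    panel[[paste0(v, "_2015")]] <- x2015[, v]
  }
  panel$R00 <- R00; panel$D00 <- D00
  panel$R08 <- R08; panel$D08 <- D08
  panel$R16 <- R16; panel$D16 <- D16
  panel$votes_R00 <- votes(R00); panel$votes_D00 <- votes(D00)
  panel$votes_R08 <- votes(R08); panel$votes_D08 <- votes(D08)
  panel$votes_R16 <- votes(R16); panel$votes_D16 <- votes(D16)
  panel$votes_total_2000 <- total_votes
  panel$votes_total_2008 <- total_votes
  panel$votes_total_2016 <- total_votes

  # sprinkle covariate missingness (2015 value of one covariate)
  if (cfg$missing_rate > 0) {
    n_miss <- stats::rbinom(1, N, cfg$missing_rate)
    if (n_miss > 0) {
      idx <- sample.int(N, n_miss)
      which_cov <- sample(covs, n_miss, replace = TRUE)
      for (k in seq_len(n_miss))
        panel[idx[k], paste0(which_cov[k], "_2015")] <- NA_real_
    }
  }

  out <- list(
    panel = panel, deaths = deaths, oracle = oracle,
    truth = list(coefficients = b, covariates = covs,
                 u_state = stats::setNames(u_s, sprintf("S%02d", seq_len(S))),
                 v_state = stats::setNames(v_s, sprintf("S%02d", seq_len(S))),
                 fixed_lp = fixed_lp, g = g, delta_rate = delta_rate,
                 config = cfg),
    n_clipped = n_clipped
  )
  class(out) <- "county_sim"
  out
}

#' @export
print.county_sim <- function(x, ...) {
  cat("Synthetic county panel:", nrow(x$panel), "counties in",
      length(unique(x$panel$state_id)), "states\n")
  cat("  death-table cells:", nrow(x$deaths),
      sprintf("(%d suppressed)\n", sum(x$deaths$suppressed)))
  invisible(x)
}

#' Write a synthetic panel bundle to CSV
#'
#' Writes \code{panel.csv}, \code{deaths.csv}, \code{oracle.csv} (true
#' values of suppressed cells, kept in a separate file) and a
#' \code{config.yaml} echo of the generator settings.
#'
#' @param sim a \code{county_sim} from \code{\link{generate_panel}}.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_sim <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(panel = file.path(dir, "panel.csv"),
             deaths = file.path(dir, "deaths.csv"),
             oracle = file.path(dir, "oracle.csv"),
             config = file.path(dir, "config.yaml"))
  utils::write.csv(sim$panel, paths["panel"], row.names = FALSE)
  utils::write.csv(sim$deaths, paths["deaths"], row.names = FALSE)
  utils::write.csv(sim$oracle, paths["oracle"], row.names = FALSE)
  cfg <- sim$truth$config
  yaml::write_yaml(cfg[setdiff(names(cfg), NULL)], paths["config"])
  invisible(paths)
}

#' Read a county panel CSV
#' @param path path to a panel CSV written by \code{\link{write_sim}}.
#' @return the panel data.frame.
#' @export
read_panel <- function(path) utils::read.csv(path, stringsAsFactors = FALSE)

#' Read a death-table CSV
#' @param path path to a deaths CSV written by \code{\link{write_sim}}.
#' @return the death-table data.frame (suppressed counts are \code{NA}).
#' @export
read_death_table <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  x$suppressed <- as.logical(x$suppressed)
  x
}
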