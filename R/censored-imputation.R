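#' Left-censoring rule for suppressed counts
#'
#' Data providers withhold death counts below a disclosure threshold;
#' statistically such a cell is interval-censored on
#' \code{[lower, threshold - 1]}. The default mirrors the common
#' convention of suppressing counts 1-9 (zeros are published).
#'
#' @param threshold suppression threshold (counts strictly below are
#'   withheld when positive); default 10.
#' @param lower lower bound of the censoring interval, 0 or 1 (default 1).
#' @return list of class \code{censoring_rule} with \code{threshold},
#'   \code{lower}, \code{upper = threshold - 1}.
#' @export
censoring_rule <- function(threshold = 10L, lower = 1L) {
  if (!lower %in% c(0L, 1L)) abort_input("interval lower bound must be 0 or 1")
  if (threshold < lower + 1) abort_input("threshold too small for interval")
  structure(list(threshold = as.integer(threshold), lower = as.integer(lower),
                 upper = as.integer(threshold) - 1L),
            class = "censoring_rule")
}

#' MCMC and model settings for the censored-count imputation model
#'
#' The imputation model is a multilevel left-censored Poisson regression:
#' each county x period x age cell's count is Poisson with log-mean
#' \code{offset + b0 + b_period * [period = later] + u_state + w_county},
#' where the offset is \code{log(person_years x age_shape)} and the state
#' and county intercepts are normal with half-normal priors on their
#' scales. Censored cells contribute the Poisson probability mass over
#' the censoring interval; completed datasets are drawn from the
#' posterior of the latent counts, which is the posterior predictive
#' restricted to the interval.
#'
#' @param chains number of MCMC chains (>= 2 for convergence diagnostics).
#' @param adapt adaptation iterations.
#' @param warmup burn-in iterations per chain.
#' @param draws retained iterations per chain.
#' @param M number of completed datasets (>= 2, default 10).
#' @param seed integer seed; chains get distinct derived RNG seeds.
#' @param prior_sd_fixed SD of the normal priors on \code{b0}, \code{b_period}.
#' @param prior_scale_re scale of the half-normal priors on the
#'   random-effect SDs.
#' @param rhat_max convergence bound on split-chain scale reduction
#'   (default 1.05); exceeding it is an error.
#' @return list of class \code{imputation_spec}.
#' @export
imputation_spec <- function(chains = 2L, adapt = 500L, warmup = 1000L,
                            draws = 1000L, M = 10L, seed = 1L,
                            prior_sd_fixed = 10, prior_scale_re = 1,
                            rhat_max = 1.05) {
  if (M < 2) abort_input("M must be >= 2")
  if (chains * draws < M)
    abort_input("chains x draws must be >= M")
  structure(list(chains = as.integer(chains), adapt = as.integer(adapt),
                 warmup = as.integer(warmup), draws = as.integer(draws),
                 M = as.integer(M), seed = as.integer(seed),
                 prior_sd_fixed = prior_sd_fixed,
                 prior_scale_re = prior_scale_re, rhat_max = rhat_max),
            class = "imputation_spec")
}

# Hierarchically centered parameterization (county effects centered on
# their state's mean, state means on the global intercept): equivalent to
# intercept + independent state/county deviations, but mixes far better
# under the Gibbs/slice samplers JAGS uses for Poisson GLMMs.
imputation_model_string <- "
model {
  for (i in 1:Nobs) {
    yobs[i] ~ dpois(mu_o[i])
    log(mu_o[i]) <- off_o[i] + bp * p_o[i] + w[ct_o[i]]
  }
  for (j in 1:Ncen) {
    cens[j] ~ dinterval(ycen[j], lim)
    ycen[j] ~ dpois(mu_c[j])
    log(mu_c[j]) <- off_c[j] + bp * p_c[j] + w[ct_c[j]]
  }
  b0 ~ dnorm(0, pow(sd_fixed, -2))
  bp ~ dnorm(0, pow(sd_fixed, -2))
  for (s in 1:S) { u[s] ~ dnorm(b0, tau_u) }
  for (c in 1:C) { w[c] ~ dnorm(u[state_of[c]], tau_w) }
  sigma_u ~ dnorm(0, pow(scale_re, -2)) T(0,)
  sigma_w ~ dnorm(0, pow(scale_re, -2)) T(0,)
  tau_u <- pow(sigma_u, -2)
  tau_w <- pow(sigma_w, -2)
}"

#' Fit the multilevel left-censored Bayesian imputation model
#'
#' Imputes suppressed (interval-censored) counts of a rare-cause death
#' stream. See \code{\link{imputation_spec}} for the model. Returns M
#' completed death tables plus per-cell posterior summaries and
#' convergence diagnostics. With no censored cells the result is M
#' identical copies of the input (no MCMC is run).
#'
#' @param table death-table data.frame (columns \code{county_id},
#'   \code{state_id}, \code{period}, \code{cause_group}, \code{age_group},
#'   \code{count}, \code{person_years}, \code{suppressed}); only rows of
#'   \code{cause} are modeled and completed.
#' @param rule a \code{\link{censoring_rule}}.
#' @param spec an \code{\link{imputation_spec}}.
#' @param cause cause group to impute (default \code{"despair"}).
#' @param age_shape optional named vector of relative age-specific rate
#'   multipliers entering the offset; defaults to the package's despair
#'   age shape when the table uses the 11 standard age groups, else 1.
#' @return list of class \code{imputation_set}: \code{datasets} (M
#'   completed tables for \code{cause}), \code{summaries} (per censored
#'   cell: posterior mean, sd, 5th/95th percentiles), \code{diagnostics}
#'   (per-parameter split-chain scale reduction), \code{M}, \code{rule},
#'   \code{spec}.
#' @export
fit_imputation_model <- function(table, rule = censoring_rule(),
                                 spec = imputation_spec(),
                                 cause = "despair", age_shape = NULL) {
  tab <- table[table$cause_group == cause, , drop = FALSE]
  if (!nrow(tab)) abort_input("no rows for cause group '", cause, "'")
  if (is.null(tab$suppressed)) tab$suppressed <- is.na(tab$count)
  cen <- which(tab$suppressed | is.na(tab$count))
  obs <- which(!(tab$suppressed | is.na(tab$count)))

  if (length(cen) == 0L) {
    out <- list(datasets = rep(list(tab), spec$M), summaries = NULL,
                diagnostics = NULL, M = spec$M, rule = rule, spec = spec)
    class(out) <- "imputation_set"
    return(out)
  }
  if (!length(obs)) abort_input("no observed cells to fit the model on")
  if (is.null(tab$state_id))
    abort_input("death table needs a state_id column for the imputation model")

  std_labels <- as.character(us_standard_population()$age_group)
  if (is.null(age_shape)) {
    age_shape <- if (all(as.character(tab$age_group) %in% std_labels))
      stats::setNames(despair_age_shape(), std_labels)
    else stats::setNames(rep(1, length(unique(tab$age_group))),
                         unique(as.character(tab$age_group)))
  }

  st <- factor(tab$state_id)
  ct <- factor(tab$county_id)
  if (any(table(st[obs]) == 0))
    abort_input("every state needs at least one observed cell")
  periods <- sort(unique(tab$period))
  p_late <- as.integer(tab$period == max(periods))
  off <- log(tab$person_years * age_shape[as.character(tab$age_group)])

  data <- list(
    Nobs = length(obs), Ncen = length(cen),
    yobs = as.integer(tab$count[obs]),
    off_o = off[obs], p_o = p_late[obs],
    ct_o = as.integer(ct)[obs],
    cens = rep(1L, length(cen)),
    off_c = off[cen], p_c = p_late[cen],
    ct_c = as.integer(ct)[cen],
    lim = c(rule$lower - 0.5, rule$upper + 0.5),
    S = nlevels(st), C = nlevels(ct),
    state_of = as.integer(st)[match(levels(ct), as.character(ct))],
    sd_fixed = spec$prior_sd_fixed, scale_re = spec$prior_scale_re
  )
  mid <- as.integer(round((rule$lower + rule$upper) / 2))
  inits <- lapply(seq_len(spec$chains), function(ch) {
    list(ycen = rep(mid, length(cen)),
         .RNG.name = "base::Mersenne-Twister",
         .RNG.seed = stage_seed(spec$seed, ch))
  })

  jm <- rjags::jags.model(textConnection(imputation_model_string),
                          data = data, inits = inits,
                          n.chains = spec$chains, n.adapt = spec$adapt,
                          quiet = TRUE)
  if (spec$warmup > 0) stats::update(jm, spec$warmup, progress.bar = "none")
  samp <- rjags::coda.samples(
    jm, variable.names = c("b0", "bp", "sigma_u", "sigma_w", "ycen"),
    n.iter = spec$draws, progress.bar = "none")

  par_cols <- c("b0", "bp", "sigma_u", "sigma_w")
  diag <- data.frame(
    parameter = par_cols,
    rhat = vapply(par_cols, function(p)
      split_rhat(lapply(samp, function(ch) as.numeric(ch[, p]))), 0),
    row.names = NULL)
  if (any(!is.na(diag$rhat) & diag$rhat > spec$rhat_max))
    stop("imputation model did not converge: max Rhat = ",
         round(max(diag$rhat), 3), " (limit ", spec$rhat_max, "); ",
         "increase warmup/draws", call. = FALSE)

  all_draws <- do.call(rbind, lapply(samp, as.matrix))
  ycols <- grep("^ycen", colnames(all_draws))
  ydraws <- all_draws[, ycols, drop = FALSE]
  # ycen[k] columns come back in lexicographic order; restore numeric order
  kidx <- as.integer(gsub("^ycen\\[|\\]$", "", colnames(ydraws)))
  ydraws <- ydraws[, order(kidx), drop = FALSE]

  summaries <- data.frame(
    tab[cen, c("county_id", "state_id", "period", "age_group")],
    post_mean = colMeans(ydraws),
    post_sd = apply(ydraws, 2, stats::sd),
    q05 = apply(ydraws, 2, stats::quantile, probs = 0.05),
    q95 = apply(ydraws, 2, stats::quantile, probs = 0.95),
    row.names = NULL
  )

  pick <- unique(round(seq(1, nrow(ydraws), length.out = spec$M)))
  # guard against duplicate indices when draws are few
  while (length(pick) < spec$M)
    pick <- c(pick, sample.int(nrow(ydraws), spec$M - length(pick)))
  datasets <- lapply(pick[seq_len(spec$M)], function(d) {
    comp <- tab
    comp$count[cen] <- as.integer(ydraws[d, ])
    comp$suppressed <- FALSE
    comp
  })

  out <- list(datasets = datasets, summaries = summaries,
              diagnostics = diag, M = spec$M, rule = rule, spec = spec,
              draws = ydraws)
  class(out) <- "imputation_set"
  out
}

#' Rank-normalized split-chain scale reduction
#'
#' The convergence diagnostic of Vehtari, Gelman, Simpson, Carpenter and
#' Burkner (2021): each chain is split in half, the pooled draws are
#' rank-normalized through the standard-normal quantile function, and the
#' classic potential scale reduction is computed on the transformed
#' sequences. Rank normalization makes the diagnostic reliable for
#' heavy-tailed quantities such as variance-component scales, where the
#' classic statistic over-reads.
#'
#' @param chains list of numeric vectors, one per chain (equal lengths).
#' @return the split-chain R-hat (1 at perfect convergence).
#' @export
split_rhat <- function(chains) {
  stopifnot(length(chains) >= 1)
  n <- length(chains[[1]]) %/% 2
  halves <- unlist(lapply(chains, function(ch)
    list(ch[seq_len(n)], ch[n + seq_len(n)])), recursive = FALSE)
  x <- matrix(unlist(halves), nrow = n)
  if (stats::sd(x) == 0) return(1)
  # rank-normalize over the pooled draws
  z <- matrix(stats::qnorm((rank(x) - 3 / 8) / (length(x) + 1 / 4)),
              nrow = n)
  W <- mean(apply(z, 2, stats::var))
  B <- n * stats::var(colMeans(z))
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Calibration of the imputation posterior against known truth
#'
#' For synthetic data, where the true values of suppressed cells are
#' known, assesses whether the imputation posteriors are calibrated.
#' Reports (a) the raw coverage of the central 90\% posterior interval
#' \code{[q05, q95]} — which for integer-valued posteriors is
#' conservative (at or above the nominal level) because discrete
#' quantiles cannot cut probability mass exactly at 5\% — and (b) the
#' randomized probability integral transform (PIT) coverage, the
#' standard calibration measure for discrete predictive distributions:
#' \code{u = F(t-1) + V (F(t) - F(t-1))} with \code{V ~ U(0,1)} is
#' uniform exactly when the posterior is calibrated, so the fraction of
#' \code{u} in \code{[0.05, 0.95]} should be 90\%.
#'
#' @param imp an \code{imputation_set} with censored cells.
#' @param truth data.frame with \code{county_id}, \code{period},
#'   \code{age_group}, \code{true_count} (the oracle table emitted by
#'   \code{\link{generate_panel}}).
#' @param level central interval mass (default 0.9).
#' @param seed seed for the PIT randomization.
#' @return list: \code{interval_coverage}, \code{pit_coverage},
#'   \code{mae} (posterior-mean absolute error), \code{n_cells}.
#' @export
imputation_calibration <- function(imp, truth, level = 0.9, seed = 1L) {
  if (is.null(imp$summaries)) abort_input("imputation set has no censored cells")
  s <- imp$summaries
  key <- function(d) paste(d$county_id, d$period, d$age_group)
  t_match <- truth$true_count[match(key(s), key(truth))]
  if (anyNA(t_match)) abort_input("truth table does not cover all censored cells")
  alpha <- (1 - level) / 2

  raw <- mean(t_match >= s$q05 & t_match <= s$q95)
  ydraws <- imp$draws
  set.seed(seed)
  V <- stats::runif(length(t_match))
  u <- vapply(seq_along(t_match), function(k) {
    Ft <- mean(ydraws[, k] <= t_match[k])
    Ftm1 <- mean(ydraws[, k] <= t_match[k] - 1)
    Ftm1 + V[k] * (Ft - Ftm1)
  }, 0)
  list(interval_coverage = raw,
       pit_coverage = mean(u >= alpha & u <= 1 - alpha),
       mae = mean(abs(s$post_mean - t_match)),
       n_cells = length(t_match))
}

#' @export
print.imputation_set <- function(x, ...) {
  ncen <- if (is.null(x$summaries)) 0 else nrow(x$summaries)
  cat("Imputation set: M =", x$M, "completed datasets,",
      ncen, "censored cells\n")
  if (!is.null(x$diagnostics))
    cat("  max Rhat:", round(max(x$diagnostics$rhat), 4), "\n")
  invisible(x)
}

#' Deterministic midpoint fill-in for censored cells
#'
#' A naive baseline: every censored cell is set to the midpoint of the
#' censoring interval. Used as the comparator the model-based imputation
#' should beat.
#'
#' @param table death-table data.frame with suppressed cells.
#' @param rule a \code{\link{censoring_rule}}.
#' @return the table with censored counts replaced by the interval
#'   midpoint.
#' @export
midpoint_fill <- function(table, rule = censoring_rule()) {
  cen <- which(table$suppressed | is.na(table$count))
  table$count[cen] <- as.integer(round((rule$lower + rule$upper) / 2))
  table$suppressed <- FALSE
  table
}
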