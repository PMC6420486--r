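# Multivariable random-effects model for net Republican gain.
#
# Internally the death-rate change is rescaled (divided by `rate_scale`)
# before entering lme4, so the random-slope variance is on a scale the
# optimizer handles well; all reported quantities are back-transformed to
# per-1/100,000 units.
rate_scale <- 100

#' Build the design for the voting-change model
#'
#' Assembles, from a county panel and adjusted all-cause rates, the
#' complete-case analysis set: the net-gain outcome, the eight covariate
#' changes (2015 minus 2000), the death-rate change, the rural indicator,
#' and the piecewise log10-population basis with its knot at 50,000. The
#' piecewise basis is the hinge parameterization
#' \code{\{log10(pop), max(0, log10(pop) - log10(knot))\}}, which is
#' continuous at the knot by construction.
#'
#' @param panel county panel (as from \code{\link{generate_panel}}).
#' @param rates \code{adjusted_rates} containing all-cause rates for both
#'   periods.
#' @param knot population knot (default 50,000).
#' @param rural_classes urban-rural classes counted as rural (default
#'   5:6, the non-metro classes).
#' @return list of class \code{vcm_design}: \code{data} (complete-case
#'   model frame), \code{covariates} (names of the change covariates),
#'   \code{knot}, \code{n_excluded}.
#' @export
build_design <- function(panel, rates, knot = 50000, rural_classes = 5:6) {
  if (any(panel$population <= 0)) abort_input("non-positive population")
  covs <- c("median_age", "pct_black", "pct_hispanic", "pct_asian",
            "median_income", "unemployment", "pct_bachelor", "pct_insured")
  d <- data.frame(county_id = panel$county_id, state_id = panel$state_id,
                  population = panel$population, stringsAsFactors = FALSE)
  for (v in covs) {
    a <- panel[[paste0(v, "_2000")]]; b <- panel[[paste0(v, "_2015")]]
    if (is.null(a) || is.null(b))
      abort_input("panel lacks both-period columns for covariate ", v)
    d[[paste0("d_", v)]] <- b - a
  }
  rc <- rate_change(rates[rates$cause_group == "all_cause", ])
  d$d_rate <- rc$delta[match(d$county_id, rc$county_id)]
  d$d_rate_s <- d$d_rate / rate_scale
  d$rural <- as.integer(panel$urban_rural %in% rural_classes)
  d$l10pop <- log10(panel$population)
  d$hinge <- pmax(0, d$l10pop - log10(knot))
  d$g <- net_republican_gain(panel$R08, panel$R16, panel$D08, panel$D16)
  if (!is.null(panel$R00) && !is.null(panel$D00))
    d$g00_16 <- net_republican_gain(panel$R00, panel$R16,
                                    panel$D00, panel$D16)

  vars <- c(paste0("d_", covs), "d_rate", "rural", "l10pop", "g")
  keep <- stats::complete.cases(d[, vars])
  n_excluded <- sum(!keep)
  if (n_excluded > 0)
    message(n_excluded, " counties excluded (missing covariates): ",
            "complete-case analysis")
  out <- list(data = d[keep, , drop = FALSE],
              covariates = paste0("d_", covs),
              knot = knot, n_excluded = n_excluded)
  class(out) <- "vcm_design"
  out
}

vcm_formula <- function(covariates, outcome = "g", random_slope = TRUE) {
  fixed <- paste(c(covariates, "d_rate_s", "rural", "l10pop", "hinge"),
                 collapse = " + ")
  re <- if (random_slope) "(1 + d_rate_s | state_id)" else "(1 | state_id)"
  stats::as.formula(paste(outcome, "~", fixed, "+", re))
}

# internal: shared extraction of a fitted lmer into a model_fit object
summarize_vcm <- function(fit, design, outcome, singular_refit = FALSE) {
  co <- summary(fit)$coefficients
  est <- co[, "Estimate"]; se <- co[, "Std. Error"]
  # back-transform the rescaled death-rate term to per-1/100,000 units
  i <- rownames(co) == "d_rate_s"
  est[i] <- est[i] / rate_scale; se[i] <- se[i] / rate_scale
  rownames(co)[i] <- "d_rate"
  term <- rownames(co)
  z <- est / se
  coefs <- data.frame(
    term = term, estimate = unname(est), se = unname(se),
    z = unname(z), p_value = unname(2 * stats::pnorm(-abs(z))),
    magnitude_per_1pct = unname(ifelse(est != 0, 1 / est, NA_real_)),
    row.names = NULL, stringsAsFactors = FALSE
  )

  vc <- as.data.frame(lme4::VarCorr(fit))
  s2u <- vc$vcov[vc$grp %in% c("state_id", "state_id.1") &
                   vc$var1 == "(Intercept)" & is.na(vc$var2)][1]
  s2v_raw <- vc$vcov[vc$grp %in% c("state_id", "state_id.1") &
                       vc$var1 == "d_rate_s" & is.na(vc$var2)]
  s2v_raw <- if (length(s2v_raw)) s2v_raw[1] else 0
  cov_uv <- vc$vcov[vc$grp == "state_id" & vc$var1 == "(Intercept)" &
                      !is.na(vc$var2) & vc$var2 == "d_rate_s"]
  rho <- if (length(cov_uv) && s2u > 0 && s2v_raw > 0)
    cov_uv / sqrt(s2u * s2v_raw) else NA_real_

  y <- design$data[[outcome]]
  pred_fixed <- stats::predict(fit, re.form = NA)
  pred_total <- stats::predict(fit)
  r2_fixed <- stats::var(pred_fixed) / stats::var(y)
  r2_total <- stats::var(pred_total) / stats::var(y)

  beta_rate <- est[term == "d_rate"]
  re_st <- lme4::ranef(fit)$state_id
  v_s <- if ("d_rate_s" %in% colnames(re_st))
    re_st[, "d_rate_s"] / rate_scale else rep(0, nrow(re_st))
  state_slopes <- data.frame(state_id = rownames(re_st),
                             slope = beta_rate + v_s,
                             stringsAsFactors = FALSE)

  bl <- est[term == "l10pop"]
  pop_slopes <- c(below_knot = unname(bl),
                  above_knot = unname(bl + est[term == "hinge"]))

  out <- list(
    coefficients = coefs,
    random = list(sigma2_intercept = unname(s2u),
                  sigma2_slope = unname(s2v_raw / rate_scale^2),
                  rho = unname(rho),
                  sigma2_residual = stats::sigma(fit)^2),
    r2 = c(fixed = unname(r2_fixed), total = unname(r2_total)),
    r2_convention = "variance of predictions over variance of outcome",
    state_slopes = state_slopes,
    pop_slopes = pop_slopes,
    n = nrow(design$data),
    outcome = outcome,
    singular_refit = singular_refit,
    fit = fit
  )
  class(out) <- "model_fit"
  out
}

#' @export
print.model_fit <- function(x, ...) {
  cat("Multivariable random-effects model (", x$outcome, ", n = ", x$n,
      ")\n", sep = "")
  print(x$coefficients[, c("term", "estimate", "se", "p_value")],
        digits = 3)
  cat(sprintf("  state intercept var %.3f | slope var %.3g | rho %.2f\n",
              x$random$sigma2_intercept, x$random$sigma2_slope,
              x$random$rho))
  cat(sprintf("  R2 fixed %.3f | R2 fixed+random %.3f (%s)\n",
              x$r2["fixed"], x$r2["total"], x$r2_convention))
  invisible(x)
}

#' Fit the primary voting-change model
#'
#' Linear mixed model for the net Republican gain with the covariate
#' changes, rural status and the piecewise log10-population terms as
#' fixed effects, and a state random intercept plus a state random slope
#' on the death-rate change; intercept and slope are bivariate normal
#' with free covariance. Estimation is by maximum likelihood so that the
#' R-squared decomposition and nested model comparisons are coherent.
#'
#' The reported \code{magnitude_per_1pct} column is the table
#' presentation: the change in each covariate associated with one point
#' of net gain, i.e. the reciprocal of the fitted points-per-unit
#' coefficient.
#'
#' @param design a \code{\link{build_design}} result.
#' @param weights optional per-county weights (e.g. population).
#' @param outcome outcome column (default \code{"g"}; use
#'   \code{"g00_16"} for the 2000-baseline sensitivity).
#' @param random_slope include the state random slope (default TRUE).
#' @return a \code{model_fit}: coefficient table, random-effect
#'   (co)variances, R-squared for fixed and fixed+random predictions,
#'   per-state total death-rate slopes, piecewise population slopes.
#' @export
fit_primary <- function(design, weights = NULL, outcome = "g",
                        random_slope = TRUE) {
  d <- design$data
  if (!outcome %in% names(d)) abort_input("no outcome column ", outcome)
  st <- unique(d$state_id)
  if (length(st) < 2) abort_input("need >= 2 states")
  d$.w <- if (is.null(weights)) rep(1, nrow(d)) else weights
  f <- vcm_formula(design$covariates, outcome, random_slope)

  ctrl <- lme4::lmerControl(check.conv.singular = "ignore",
                            calc.derivs = FALSE)
  fit <- suppressMessages(suppressWarnings(
    lme4::lmer(f, data = d, REML = FALSE, weights = .w, control = ctrl)))
  singular_refit <- FALSE
  if (random_slope && lme4::isSingular(fit, tol = 1e-5)) {
    warning("singular random-effects covariance; refitting with ",
            "independent (diagonal) intercept and slope", immediate. = TRUE)
    f2 <- stats::as.formula(paste(
      outcome, "~", paste(c(design$covariates, "d_rate_s", "rural",
                            "l10pop", "hinge"), collapse = " + "),
      "+ (1 + d_rate_s || state_id)"))
    fit <- suppressMessages(suppressWarnings(
      lme4::lmer(f2, data = d, REML = FALSE, weights = .w, control = ctrl)))
    singular_refit <- TRUE
  }
  summarize_vcm(fit, design, outcome, singular_refit)
}

#' The three sensitivity analyses around the primary model
#'
#' (1) the primary model weighted by county population; (2) the
#' demographic/socioeconomic covariate changes replaced by their
#' principal components (death-rate change, rural status and population
#' terms kept as-is); (3) the outcome recomputed against the 2000
#' election baseline.
#'
#' @param design a \code{\link{build_design}} result (must carry
#'   \code{g00_16} for the baseline-2000 fit; the generator emits the
#'   needed 2000 shares).
#' @param pca_var_frac fraction of covariate-change variance the retained
#'   principal components must explain (default 0.9; 1 retains all
#'   components, which reproduces the primary fitted values exactly).
#' @return named list of \code{model_fit}s: \code{weighted}, \code{pca},
#'   \code{baseline2000}. The PCA element also carries
#'   \code{n_components}.
#' @export
sensitivity_suite <- function(design, pca_var_frac = 0.9) {
  out <- list()
  out$weighted <- fit_primary(design, weights = design$data$population)
  out$pca <- fit_pca(design, pca_var_frac)
  if (!"g00_16" %in% names(design$data))
    abort_input("design lacks the 2000-baseline outcome g00_16")
  out$baseline2000 <- fit_primary(design, outcome = "g00_16")
  out
}

#' PCA sensitivity fit
#'
#' Replaces the eight covariate changes by principal components (computed
#' on the standardized changes) retaining at least \code{var_frac} of
#' their variance; the death-rate change and the geography terms stay in
#' the model unchanged.
#'
#' @inheritParams sensitivity_suite
#' @param var_frac variance fraction to retain.
#' @return a \code{model_fit} with an extra \code{n_components} element.
#' @export
fit_pca <- function(design, var_frac = 0.9) {
  d <- design$data
  X <- as.matrix(d[, design$covariates])
  pc <- stats::prcomp(X, center = TRUE, scale. = TRUE)
  cum <- cumsum(pc$sdev^2) / sum(pc$sdev^2)
  k <- which(cum >= var_frac - 1e-12)[1]
  scores <- pc$x[, seq_len(k), drop = FALSE]
  pcn <- paste0("PC", seq_len(k))
  d2 <- d
  d2[pcn] <- scores
  des2 <- design
  des2$data <- d2
  des2$covariates <- pcn
  res <- fit_primary(des2)
  res$n_components <- k
  res
}

#' Secondary model: despair and other-cause rate changes separately
#'
#' Replaces the all-cause death-rate change with two covariates — the
#' change in the "deaths of despair" rate and the change in the
#' all-other-causes rate — fitted once per completed imputation dataset
#' and pooled with Rubin's rules. Random effects are the state intercept
#' (the per-stream random slopes are not identifiable at typical panel
#' sizes).
#'
#' @param design a \code{\link{build_design}} result.
#' @param imp an imputation set for the despair stream.
#' @param deaths the death table (for the observed other-cause stream).
#' @param std standard population for age adjustment.
#' @return list: \code{pooled} (per-term Rubin-combined estimate, se, df,
#'   p), \code{per_dataset} model fits.
#' @export
fit_despair_split <- function(design, imp, deaths,
                              std = us_standard_population()) {
  other <- deaths[deaths$cause_group == "other", ]
  rc_other <- rate_change(age_adjust(other, std))
  fits <- lapply(imp$datasets, function(comp) {
    rc_desp <- rate_change(age_adjust(comp, std))
    d <- design$data
    d$d_despair_s <- rc_desp$delta[match(d$county_id, rc_desp$county_id)] /
      rate_scale
    d$d_other_s <- rc_other$delta[match(d$county_id, rc_other$county_id)] /
      rate_scale
    f <- stats::as.formula(paste(
      "g ~", paste(c(design$covariates, "d_despair_s", "d_other_s",
                     "rural", "l10pop", "hinge"), collapse = " + "),
      "+ (1 | state_id)"))
    suppressMessages(suppressWarnings(
      lme4::lmer(f, data = d, REML = FALSE,
                 control = lme4::lmerControl(check.conv.singular = "ignore"))))
  })
  terms <- rownames(summary(fits[[1]])$coefficients)
  pooled <- do.call(rbind, lapply(terms, function(tm) {
    est <- vapply(fits, function(f) summary(f)$coefficients[tm, "Estimate"], 0)
    w <- vapply(fits, function(f) summary(f)$coefficients[tm, "Std. Error"]^2, 0)
    cb <- rubin_combine(est, w)
    data.frame(term = tm, estimate = cb$estimate, se = cb$se, df = cb$df,
               p_value = rubin_p_value(cb), stringsAsFactors = FALSE)
  }))
  # rescale the two rate terms back to per-1/100,000 units
  i <- pooled$term %in% c("d_despair_s", "d_other_s")
  pooled$estimate[i] <- pooled$estimate[i] / rate_scale
  pooled$se[i] <- pooled$se[i] / rate_scale
  pooled$term <- sub("_s$", "", pooled$term)
  list(pooled = pooled, per_dataset = fits)
}
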