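#' Compare group means with a state random intercept
#'
#' Counties cluster within states, so a naive two-sample test on county
#' values is anti-conservative whenever group membership is correlated
#' with state. This comparison fits \code{value ~ group + (1 | state)} by
#' REML and tests the group fixed effect; reported group means and SDs
#' are the unweighted county summaries (table style), while the
#' difference, statistic and p-value are model-based. The p-value uses
#' the large-sample normal reference for the fixed-effect contrast.
#'
#' @param values numeric county values.
#' @param groups two-level factor (or coercible) of group labels.
#' @param states state identifiers.
#' @param naive also compute the unclustered pooled two-sample test
#'   (default FALSE), returned under \code{naive}.
#' @return list of class \code{comparison_result}: group \code{means} and
#'   \code{sds}, \code{difference} (second level minus first),
#'   \code{statistic}, \code{p_value}, \code{model}, and optionally
#'   \code{naive} (statistic + p-value).
#' @export
compare_groups <- function(values, groups, states, naive = FALSE) {
  groups <- factor(groups)
  if (nlevels(groups) != 2) abort_input("compare_groups needs two groups")
  if (any(table(groups) == 0)) abort_input("each group must be non-empty")
  ok <- stats::complete.cases(values, groups, states)
  values <- values[ok]; groups <- groups[ok]; states <- factor(states[ok])
  if (nlevels(states) < 2) abort_input("need counties from >= 2 states")
  one_state <- tapply(states, groups, function(s) length(unique(s)) == 1)
  if (any(one_state))
    warning("a group lies entirely within one state; ",
            "variance components are weakly identified")

  fit <- suppressMessages(lme4::lmer(
    values ~ groups + (1 | states),
    REML = TRUE,
    control = lme4::lmerControl(check.conv.singular = "ignore")))
  co <- summary(fit)$coefficients
  est <- co[2, "Estimate"]; se <- co[2, "Std. Error"]
  z <- est / se

  out <- list(
    means = tapply(values, groups, mean),
    sds = tapply(values, groups, stats::sd),
    difference = est,
    statistic = z,
    p_value = 2 * stats::pnorm(-abs(z)),
    model = "random-intercept"
  )
  if (naive) {
    # pooled-variance two-sample statistic, normal reference
    n <- table(groups)
    m <- tapply(values, groups, mean)
    v <- tapply(values, groups, stats::var)
    sp2 <- ((n[1] - 1) * v[1] + (n[2] - 1) * v[2]) / (sum(n) - 2)
    tn <- (m[2] - m[1]) / sqrt(sp2 * (1 / n[1] + 1 / n[2]))
    out$naive <- list(statistic = unname(tn),
                      p_value = unname(2 * stats::pnorm(-abs(tn))))
  }
  class(out) <- "comparison_result"
  out
}

#' @export
print.comparison_result <- function(x, ...) {
  cat("Group comparison (", x$model, ")\n", sep = "")
  for (g in names(x$means))
    cat(sprintf("  %s: mean %.2f (SD %.2f)\n", g, x$means[g], x$sds[g]))
  cat(sprintf("  difference %.3f, z = %.2f, p = %.3g\n",
              x$difference, x$statistic, x$p_value))
  invisible(x)
}

#' Did the between-group gap widen across elections?
#'
#' Concatenates the two elections' county values and fits a 3-level
#' random-intercept model (elections within counties within states):
#' \code{value ~ group * election + (1 | state) + (1 | state:county)}.
#' The group-by-election interaction estimates the change in the group
#' gap between elections.
#'
#' @param data data.frame with columns \code{value}, \code{group} (two
#'   levels), \code{election} (two levels), \code{county_id},
#'   \code{state_id}; one row per county and election. Counties present
#'   in only one election are dropped with a message.
#' @return list with \code{interaction} (estimate), \code{se},
#'   \code{statistic}, \code{p_value}, \code{gap_by_election}, and the
#'   fitted model under \code{fit}.
#' @export
election_interaction_model <- function(data) {
  need <- c("value", "group", "election", "county_id", "state_id")
  if (!all(need %in% names(data)))
    abort_input("data must have columns ", paste(need, collapse = ", "))
  tab <- table(data$county_id)
  drop <- names(tab)[tab < 2]
  if (length(drop)) {
    message(length(drop), " counties present in only one election dropped")
    data <- data[!data$county_id %in% drop, ]
  }
  data$group <- factor(data$group)
  data$election <- factor(data$election)
  if (nlevels(data$group) != 2 || nlevels(data$election) != 2)
    abort_input("need exactly two groups and two elections")

  fit <- suppressMessages(lme4::lmer(
    value ~ group * election + (1 | state_id) + (1 | state_id:county_id),
    data = data, REML = TRUE,
    control = lme4::lmerControl(check.conv.singular = "ignore")))
  co <- summary(fit)$coefficients
  irow <- grep(":", rownames(co))
  est <- co[irow, "Estimate"]; se <- co[irow, "Std. Error"]
  gaps <- tapply(data$value, list(data$group, data$election), mean)
  list(interaction = unname(est), se = unname(se),
       statistic = unname(est / se),
       p_value = unname(2 * stats::pnorm(-abs(est / se))),
       gap_by_election = gaps[2, ] - gaps[1, ],
       model = "3-level interaction", fit = fit)
}

#' Rubin-combined group comparison across imputed datasets
#'
#' Runs \code{\link{compare_groups}} once per completed dataset of an
#' imputation set (on a value computed by \code{value_fun} from each
#' completed death table) and pools the group difference with Rubin's
#' rules.
#'
#' @param imp an \code{\link{fit_imputation_model}} result.
#' @param value_fun function(completed_table) returning a data.frame with
#'   \code{county_id} and \code{value}.
#' @param groups,states named by county: vectors aligned with the county
#'   ids returned by \code{value_fun}.
#' @return list: the Rubin-combined \code{difference} (with se, df,
#'   p-value) and the per-dataset results.
#' @export
compare_groups_imputed <- function(imp, value_fun, groups, states) {
  per <- lapply(imp$datasets, function(d) {
    v <- value_fun(d)
    compare_groups(v$value, groups[v$county_id], states[v$county_id])
  })
  comb <- rubin_combine(vapply(per, function(r) r$difference, 0),
                        vapply(per, function(r) (r$difference / r$statistic)^2, 0))
  list(difference = comb, p_value = rubin_p_value(comb), per_dataset = per)
}
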