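#' Directly age-standardized death rates
#'
#' Applies a fixed standard population's age weights to each county's
#' age-specific death rates, per county, period and cause group:
#' \deqn{rate = 100{,}000 \times \sum_a w_a \, \frac{count_a}{py_a}.}
#' Standardization removes differences in age structure between counties
#' so that rates are comparable.
#'
#' Censored cells must be resolved first (run after imputation); all-cause
#' tables are treated as fully observed.
#'
#' @param table a death table: data.frame with columns \code{county_id},
#'   \code{period}, \code{cause_group}, \code{age_group}, \code{count},
#'   \code{person_years} (and optionally \code{suppressed}).
#' @param std a \code{standard_population} (default the US 2000 standard
#'   million in 11 age groups).
#' @return data.frame of class \code{adjusted_rates} with columns
#'   \code{county_id}, \code{period}, \code{cause_group}, \code{rate}
#'   (deaths per 100,000 standard population).
#' @export
age_adjust <- function(table, std = us_standard_population()) {
  validate_standard_population(std)
  need <- c("county_id", "period", "cause_group", "age_group",
            "count", "person_years")
  if (!all(need %in% names(table)))
    abort_input("death table must have columns ", paste(need, collapse = ", "))
  if (anyNA(table$count))
    abort_input("death table contains censored/missing counts; ",
                "impute before age adjustment")
  if (!all(as.character(table$age_group) %in% as.character(std$age_group)))
    abort_input("age groups in table not covered by the standard population")

  bad <- table$person_years <= 0 & table$count > 0
  if (any(bad))
    abort_input("zero person-years with nonzero deaths in ",
                sum(bad), " strata")
  zero_py <- table$person_years <= 0
  if (any(zero_py)) {
    warning(sum(zero_py), " empty strata (no person-years, no deaths) ",
            "contribute 0 to the adjusted rate")
  }

  w <- stats::setNames(std$weight, as.character(std$age_group))
  stratum_rate <- ifelse(zero_py, 0, table$count / table$person_years)
  contrib <- 1e5 * w[as.character(table$age_group)] * stratum_rate

  key <- interaction(table$county_id, table$period, table$cause_group,
                     drop = TRUE, sep = "\r")
  agg <- rowsum(contrib, key)
  ids <- do.call(rbind, strsplit(rownames(agg), "\r", fixed = TRUE))
  out <- data.frame(county_id = ids[, 1],
                    period = type.convert(ids[, 2], as.is = TRUE),
                    cause_group = ids[, 3],
                    rate = as.numeric(agg),
                    stringsAsFactors = FALSE)
  out <- out[order(out$county_id, out$cause_group, out$period), ]
  rownames(out) <- NULL
  class(out) <- c("adjusted_rates", "data.frame")
  out
}

#' Change in adjusted rates between two periods
#'
#' @param rates an \code{adjusted_rates} data.frame covering two periods.
#' @param periods length-2 vector, baseline first (default
#'   \code{c(2000, 2015)}).
#' @return data.frame with \code{county_id}, \code{cause_group},
#'   \code{rate_2000}, \code{rate_2015} (named after the requested
#'   periods), and \code{delta} = later minus baseline.
#' @export
rate_change <- function(rates, periods = c(2000, 2015)) {
  a <- rates[rates$period == periods[1], c("county_id", "cause_group", "rate")]
  b <- rates[rates$period == periods[2], c("county_id", "cause_group", "rate")]
  names(a)[3] <- paste0("rate_", periods[1])
  names(b)[3] <- paste0("rate_", periods[2])
  out <- merge(a, b, by = c("county_id", "cause_group"))
  out$delta <- out[[paste0("rate_", periods[2])]] -
               out[[paste0("rate_", periods[1])]]
  out
}

#' How much higher is one group's rate than another's?
#'
#' \code{100 * (a - b) / b}, i.e. the percent by which \code{a} exceeds
#' \code{b}.
#'
#' @param a,b rates (same units).
#' @param digits decimal places for half-up rounding; \code{NULL} returns
#'   full precision.
#' @return percent difference.
#' @export
pct_higher <- function(a, b, digits = NULL) {
  if (any(b == 0)) abort_input("zero denominator in pct_higher")
  x <- 100 * (a - b) / b
  if (is.null(digits)) x else round_half_up(x, digits)
}

#' Percent decline relative to a baseline rate
#'
#' \code{100 * |delta| / baseline}: the share of the baseline rate lost
#' (or gained) over the interval.
#'
#' @param delta change in rate (later minus baseline).
#' @param baseline baseline rate (must be nonzero).
#' @param digits decimal places for half-up rounding; \code{NULL} for full
#'   precision.
#' @return percent of baseline.
#' @export
decline_pct <- function(delta, baseline, digits = NULL) {
  if (any(baseline == 0)) abort_input("zero baseline in decline_pct")
  x <- 100 * abs(delta) / baseline
  if (is.null(digits)) x else round_half_up(x, digits)
}

#' Ratio of two rate changes
#'
#' Used for "increased k times as much" comparisons between groups.
#'
#' @param delta_a,delta_b rate changes.
#' @param digits decimal places for half-up rounding; \code{NULL} for full
#'   precision.
#' @return \code{delta_a / delta_b}.
#' @export
change_ratio <- function(delta_a, delta_b, digits = NULL) {
  if (any(delta_b == 0)) abort_input("zero denominator in change_ratio")
  x <- delta_a / delta_b
  if (is.null(digits)) x else round_half_up(x, digits)
}

#' Group-level rate contrasts between two county groups
#'
#' Computes, from two collections of adjusted rates, the standard
#' between-group summary: how much higher group A's later-period all-cause
#' rate is than group B's, each group's percent decline since baseline,
#' and the ratio of the groups' changes in the rare-cause ("deaths of
#' despair") stream.
#'
#' @param rates_a,rates_b \code{adjusted_rates} for the two groups.
#' @param periods baseline and comparison period (default 2000, 2015).
#' @return list with elements \code{pct_higher_latest} (all-cause, group A
#'   vs B), \code{decline_pct_a}, \code{decline_pct_b} (all-cause), and
#'   \code{despair_change_ratio} (A's despair delta over B's; \code{NA} if
#'   either group lacks a \code{despair} cause group). Full precision;
#'   round for reporting with the \code{digits} arguments of the
#'   underlying helpers.
#' @export
rate_contrasts <- function(rates_a, rates_b, periods = c(2000, 2015)) {
  grp_mean <- function(r, cause, period) {
    v <- r$rate[r$cause_group == cause & r$period == period]
    if (!length(v)) NA_real_ else mean(v)
  }
  a0 <- grp_mean(rates_a, "all_cause", periods[1])
  a1 <- grp_mean(rates_a, "all_cause", periods[2])
  b0 <- grp_mean(rates_b, "all_cause", periods[1])
  b1 <- grp_mean(rates_b, "all_cause", periods[2])
  da <- grp_mean(rates_a, "despair", periods[2]) -
        grp_mean(rates_a, "despair", periods[1])
  db <- grp_mean(rates_b, "despair", periods[2]) -
        grp_mean(rates_b, "despair", periods[1])
  list(
    pct_higher_latest = pct_higher(a1, b1),
    decline_pct_a = decline_pct(a1 - a0, a0),
    decline_pct_b = decline_pct(b1 - b0, b0),
    despair_change_ratio = if (is.na(da) || is.na(db)) NA_real_
                           else change_ratio(da, db)
  )
}
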