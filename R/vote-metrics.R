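#' Net Republican percentage gain
#'
#' The continuous outcome of the analysis: the signed sum, in percentage
#' points, of the change in the Republican vote share plus the negative of
#' the change in the Democratic vote share between two elections,
#' \deqn{g = (R_{16} - R_{08}) + (D_{08} - D_{16}).}
#' No truncation is applied: a county where both parties lost share to
#' third-party candidates can have a negative g, and a county where the
#' Republican share fell can still have a positive g if the Democratic
#' share fell by more.
#'
#' @param R08,R16,D08,D16 vote shares in percentage points, each in
#'   \code{[0, 100]}. Vectors are recycled by the usual rules.
#' @return numeric vector of net gains in percentage points.
#' @examples
#' net_republican_gain(40, 38, 55, 50)  # +3: R fell, D fell more
#' @export
net_republican_gain <- function(R08, R16, D08, D16) {
  shares <- cbind(R08, R16, D08, D16)
  if (any(!is.finite(shares)) || any(shares < 0) || any(shares > 100))
    abort_input("vote shares must be finite and within [0, 100]")
  (R16 - R08) + (D08 - D16)
}

#' Classify counties by the direction of each party's share change
#'
#' A county is a \code{republican_gain} when the Republican share rose and
#' the Democratic share did not, \code{democratic_gain} for the mirror
#' image, \code{both_gain} when both shares rose (third-party collapse),
#' and \code{both_decline} when neither rose (third-party surge). Exact
#' ties count as "no gain" for that party; a double tie falls into
#' \code{both_decline} with a warning.
#'
#' Marginal counts in the style of published county tallies count a
#' \code{both_gain} county in both parties' gain totals.
#'
#' @param panel a data.frame with columns \code{county_id}, \code{R08},
#'   \code{R16}, \code{D08}, \code{D16} (shares in points). Counties with
#'   any missing share are excluded and reported in \code{n_excluded}.
#' @return a list of class \code{gain_classification}:
#'   \item{labels}{data.frame of \code{county_id}, \code{label}, \code{g}}
#'   \item{counts}{named integer vector over the four exclusive labels}
#'   \item{marginal}{paper-style marginal counts (\code{republican_gain}
#'     and \code{democratic_gain} include \code{both_gain} counties)}
#'   \item{n_excluded}{number of counties dropped for missing shares}
#' @export
classify_counties <- function(panel) {
  need <- c("county_id", "R08", "R16", "D08", "D16")
  if (!all(need %in% names(panel)))
    abort_input("panel must have columns ", paste(need, collapse = ", "))
  ok <- stats::complete.cases(panel[, c("R08", "R16", "D08", "D16")])
  n_excluded <- sum(!ok)
  if (n_excluded > 0)
    message(n_excluded, " counties excluded for missing vote shares")
  p <- panel[ok, , drop = FALSE]

  r_up <- p$R16 > p$R08
  d_up <- p$D16 > p$D08
  label <- ifelse(r_up & d_up, "both_gain",
           ifelse(r_up, "republican_gain",
           ifelse(d_up, "democratic_gain", "both_decline")))
  if (any(p$R16 == p$R08 & p$D16 == p$D08))
    warning("double-tied counties assigned to both_decline")

  lv <- c("republican_gain", "democratic_gain", "both_decline", "both_gain")
  counts <- table(factor(label, levels = lv))
  out <- list(
    labels = data.frame(county_id = p$county_id,
                        label = label,
                        g = net_republican_gain(p$R08, p$R16, p$D08, p$D16),
                        stringsAsFactors = FALSE),
    counts = stats::setNames(as.integer(counts), lv),
    marginal = c(republican_gain = unname(counts["republican_gain"] + counts["both_gain"]),
                 democratic_gain = unname(counts["democratic_gain"] + counts["both_gain"]),
                 both_decline = unname(counts["both_decline"])),
    n_excluded = n_excluded
  )
  class(out) <- "gain_classification"
  out
}

#' @export
print.gain_classification <- function(x, ...) {
  n <- nrow(x$labels)
  cat("County gain classification (", n, " counties",
      if (x$n_excluded) paste0(", ", x$n_excluded, " excluded") else "",
      ")\n", sep = "")
  for (lab in names(x$counts))
    cat(sprintf("  %-16s %5d (%s%%)\n", lab, x$counts[lab],
                format(category_pct(x$counts[lab], n), nsmall = 1)))
  invisible(x)
}

#' Category percentage in table style
#'
#' One decimal place, half-up rounding: \code{category_pct(2607, 3112)} is
#' 83.8.
#'
#' @param count,total non-negative counts.
#' @param digits decimal places (default 1).
#' @return percentage rounded half-up.
#' @export
category_pct <- function(count, total, digits = 1) {
  if (any(total <= 0)) abort_input("total must be positive")
  round_half_up(100 * count / total, digits)
}

#' National vote totals and their change across elections
#'
#' Summarizes party vote totals per election in millions and the change
#' relative to the previous election, in millions and in share points.
#'
#' @param votes data.frame with columns \code{party}, \code{election}
#'   (sortable, e.g. year), \code{votes} (non-negative counts).
#' @return data.frame with one row per party and election: total votes in
#'   millions (\code{millions}, one decimal, half-up), vote share in
#'   percent, and for every election after the first the signed change in
#'   millions (\code{change_millions}) and in share points
#'   (\code{change_share}).
#' @export
vote_totals_delta <- function(votes) {
  need <- c("party", "election", "votes")
  if (!all(need %in% names(votes)))
    abort_input("votes must have columns ", paste(need, collapse = ", "))
  if (any(votes$votes < 0)) abort_input("vote counts must be non-negative")

  agg <- stats::aggregate(votes ~ party + election, data = votes, FUN = sum)
  totals <- stats::aggregate(votes ~ election, data = agg, FUN = sum)
  names(totals)[2] <- "election_total"
  agg <- merge(agg, totals, by = "election")
  agg <- agg[order(agg$party, agg$election), ]
  agg$share <- 100 * agg$votes / agg$election_total

  agg$change_millions <- NA_real_
  agg$change_share <- NA_real_
  for (p in unique(agg$party)) {
    i <- which(agg$party == p)
    if (length(i) > 1) {
      agg$change_millions[i[-1]] <- diff(agg$votes[i]) / 1e6
      agg$change_share[i[-1]] <- diff(agg$share[i])
    }
  }
  data.frame(
    party = agg$party,
    election = agg$election,
    millions = round_half_up(agg$votes / 1e6, 1),
    share = agg$share,
    change_millions = round_half_up(agg$change_millions, 1),
    change_share = agg$change_share,
    stringsAsFactors = FALSE
  )
}
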