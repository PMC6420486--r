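#' Combine estimates across multiply-imputed datasets (Rubin's rules)
#'
#' Pools a scalar estimate computed on each of M completed datasets. The
#' combined point estimate is the mean of the M estimates; the total
#' variance adds the mean within-imputation variance and the
#' between-imputation variance inflated by \code{(1 + 1/M)}:
#' \deqn{T = \bar{W} + (1 + 1/M)\,B,}
#' with small-sample degrees of freedom
#' \eqn{(M-1)\,(1 + \bar{W}/((1+1/M)B))^2}. When the M estimates agree
#' exactly (B = 0) the degrees of freedom are \code{Inf}.
#'
#' @param estimates numeric vector of the M point estimates.
#' @param within_variances numeric vector of the M squared standard
#'   errors.
#' @return list with \code{estimate}, \code{between}, \code{within},
#'   \code{total_variance}, \code{se}, \code{df}, \code{M}.
#' @examples
#' rubin_combine(c(1, 3), c(0, 0))  # estimate 2, total variance 3
#' @export
rubin_combine <- function(estimates, within_variances) {
  M <- length(estimates)
  if (M < 2) abort_input("Rubin's rules need M >= 2 imputations")
  if (length(within_variances) != M)
    abort_input("estimates and within_variances must have equal length")
  if (any(within_variances < 0)) abort_input("negative within-variance")

  qbar <- mean(estimates)
  wbar <- mean(within_variances)
  B <- stats::var(estimates)
  total <- wbar + (1 + 1 / M) * B
  df <- if (B == 0) Inf else (M - 1) * (1 + wbar / ((1 + 1 / M) * B))^2
  list(estimate = qbar, between = B, within = wbar,
       total_variance = total, se = sqrt(total), df = df, M = M)
}

#' Rubin-combined p-value for a pooled estimate
#'
#' Two-sided p-value for the null that the pooled quantity is
#' \code{null_value}, using the t reference with Rubin's degrees of
#' freedom (normal reference when df is infinite).
#'
#' @param combined result of \code{\link{rubin_combine}}.
#' @param null_value null hypothesis value (default 0).
#' @return p-value.
#' @export
rubin_p_value <- function(combined, null_value = 0) {
  t_stat <- (combined$estimate - null_value) / combined$se
  if (is.infinite(combined$df)) 2 * stats::pnorm(-abs(t_stat))
  else 2 * stats::pt(-abs(t_stat), df = combined$df)
}
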