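#' The US 2000 standard million
#'
#' Age weights for direct standardization of death rates, in the 11
#' age-group convention used by CDC WONDER (< 1, 1-4, 5-14, ..., 85+).
#' Weights are proportions of the 2000 US standard million and sum to 1.
#'
#' @return a data.frame with columns \code{age_group} (ordered factor) and
#'   \code{weight} (proportion), class \code{standard_population}.
#' @examples
#' std <- us_standard_population()
#' sum(std$weight)  # 1
#' @export
us_standard_population <- function() {
  labels <- c("<1", "1-4", "5-14", "15-24", "25-34", "35-44",
              "45-54", "55-64", "65-74", "75-84", "85+")
  # 2000 US standard million (SEER/WONDER convention)
  std_million <- c(13818, 55317, 145565, 138646, 135573, 162613,
                   134834, 87247, 66037, 44842, 15508)
  out <- data.frame(
    age_group = factor(labels, levels = labels, ordered = TRUE),
    weight = std_million / 1e6,
    stringsAsFactors = FALSE
  )
  class(out) <- c("standard_population", "data.frame")
  out
}

#' Read a standard population from CSV
#'
#' The CSV must have columns \code{age_group} and \code{weight}; weights are
#' renormalized to sum to 1 if within 1e-6 of 1, otherwise an error is
#' raised.
#'
#' @param path path to the CSV file.
#' @return a \code{standard_population} data.frame.
#' @export
read_standard_population <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("age_group", "weight") %in% names(x)))
    abort_input("standard population CSV needs columns age_group, weight")
  s <- sum(x$weight)
  if (abs(s - 1) > 1e-6)
    abort_input("standard population weights sum to ", s, ", not 1")
  x$weight <- x$weight / s
  x$age_group <- factor(x$age_group, levels = x$age_group, ordered = TRUE)
  class(x) <- c("standard_population", "data.frame")
  x
}

#' Validate a standard population
#' @param std object to validate.
#' @return invisibly TRUE; errors if invalid.
#' @export
validate_standard_population <- function(std) {
  stopifnot(is.data.frame(std), all(c("age_group", "weight") %in% names(std)))
  if (any(std$weight < 0)) abort_input("negative standard-population weight")
  if (abs(sum(std$weight) - 1) > 1e-12)
    abort_input("standard-population weights must sum to 1 within 1e-12")
  invisible(TRUE)
}

# internal: relative age pattern of deaths-of-despair mortality
# (concentrated in working ages), normalized so that
# sum(weight * shape) == 1: a county with overall despair rate R then has
# stratum rates R * shape and age-adjusted rate exactly R.
despair_age_shape <- function(std = us_standard_population()) {
  raw <- c(0.05, 0.05, 0.1, 1.0, 1.8, 2.2, 2.4, 1.6, 0.9, 0.8, 0.9)
  raw / sum(std$weight * raw)
}

# internal: flat shape for "other" causes rising steeply with age
other_age_shape <- function(std = us_standard_population()) {
  raw <- c(1.5, 0.1, 0.05, 0.2, 0.25, 0.5, 1.1, 2.5, 6, 15, 40)
  raw / sum(std$weight * raw)
}
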