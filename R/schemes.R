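# Health-state schemes over the Minimum European Health Module (MEHM) items
# and the age-group scheme used for prevalence estimation.

SRH_LEVELS  <- c("excellent", "very_good", "good", "fair", "poor")
GALI_LEVELS <- c("not_limited", "limited_not_severely", "severely_limited")
CHRONIC_LEVELS <- c("no", "yes")

#' Health-state scheme
#'
#' A scheme maps respondent-level MEHM items to one categorical health
#' state. Four schemes are supported:
#' \describe{
#'   \item{chronic}{longstanding illness, yes/no; full health = "no".}
#'   \item{gali}{Global Activity Limitation Indicator, three levels;
#'     full health = "not_limited".}
#'   \item{srh}{self-rated health on the five-point scale
#'     excellent..poor; full health = "excellent".}
#'   \item{multi}{the joint state over all three items, written
#'     \code{chronic:gali:srh}; full health =
#'     \code{"no:not_limited:excellent"}. The state space is the set of
#'     joint combinations actually observed in the data at estimation
#'     time, not the full cross-product.}
#' }
#' A record missing any item the scheme uses codes to missing and is
#' excluded listwise for that scheme only.
#'
#' @param name one of "chronic", "gali", "srh", "multi".
#' @return An object of class \code{health_scheme} with elements
#'   \code{name}, \code{states} (NULL for "multi" until observed),
#'   \code{full_state} and \code{code}, a function mapping a microdata
#'   data.frame to a character vector of state labels (NA = missing).
#' @examples
#' sc <- health_scheme("srh")
#' sc$full_state
#' @export
health_scheme <- function(name = c("chronic", "gali", "srh", "multi")) {
  name <- match.arg(name)
  sch <- switch(name,
    chronic = list(
      states = CHRONIC_LEVELS, full_state = "no",
      code = function(d) as.character(d$chronic)
    ),
    gali = list(
      states = GALI_LEVELS, full_state = "not_limited",
      code = function(d) as.character(d$gali)
    ),
    srh = list(
      states = SRH_LEVELS, full_state = "excellent",
      code = function(d) ifelse(is.na(d$srh), NA_character_, SRH_LEVELS[d$srh])
    ),
    multi = list(
      states = NULL, full_state = "no:not_limited:excellent",
      code = function(d) {
        s <- ifelse(is.na(d$srh), NA_character_, SRH_LEVELS[d$srh])
        out <- paste(d$chronic, d$gali, s, sep = ":")
        out[is.na(d$chronic) | is.na(d$gali) | is.na(s)] <- NA_character_
        out
      }
    )
  )
  sch$name <- name
  class(sch) <- "health_scheme"
  sch
}

#' @export
print.health_scheme <- function(x, ...) {
  cat("<health_scheme>", x$name, "\n")
  if (!is.null(x$states)) cat("  states:", paste(x$states, collapse = ", "), "\n")
  cat("  full state:", x$full_state, "\n")
  invisible(x)
}

#' Age-group scheme
#'
#' Ordered integer age intervals partitioning ages 15 and above, with an
#' open-ended terminal group. The default matches common health-expectancy
#' practice for EU survey data: 15-29, 30-39, 40-49, five-year groups
#' from 50 to 79, and 80+.
#'
#' @param breaks integer lower bounds of each group; the last group is
#'   open-ended.
#' @return An object of class \code{age_group_scheme} with \code{lower},
#'   \code{upper} (Inf for the last group) and \code{label}.
#' @examples
#' age_groups()$label
#' @export
age_groups <- function(breaks = c(15, 30, 40, 50, 55, 60, 65, 70, 75, 80)) {
  breaks <- as.integer(breaks)
  if (is.unsorted(breaks, strictly = TRUE) || breaks[1] != 15L)
    stop("age group breaks must be strictly increasing and start at 15")
  upper <- c(breaks[-1], Inf)
  label <- ifelse(is.finite(upper),
                  paste0(breaks, "-", upper - 1L),
                  paste0(breaks, "+"))
  structure(list(lower = breaks, upper = upper, label = label),
            class = "age_group_scheme")
}

#' Assign ages to age groups
#'
#' @param age integer vector of ages in years, all >= 15.
#' @param scheme an \code{\link{age_groups}} scheme.
#' @return Character vector of group labels, one per age.
#' @examples
#' assign_age_group(c(17, 52, 101))
#' @export
assign_age_group <- function(age, scheme = age_groups()) {
  if (any(!is.finite(age)) || any(age < 15))
    stop("age must be >= 15 (domain of the age-group scheme)")
  scheme$label[findInterval(age, scheme$lower)]
}
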