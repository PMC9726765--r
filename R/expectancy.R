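# Sullivan-method expectancies: life years lived at each age are split
# over health states by cross-sectional prevalence, then weighted.

.pick_stratum <- function(df, country, sex, what) {
  if (!is.na(country)) df <- df[df$country == country, , drop = FALSE]
  if (!is.na(sex)) df <- df[df$sex == sex, , drop = FALSE]
  if (!nrow(df))
    stop(sprintf("no %s rows for stratum (%s, %s)", what, country, sex))
  if (length(unique(df$country)) > 1L || length(unique(df$sex)) > 1L)
    stop(sprintf("%s covers multiple strata; pass country/sex explicitly", what))
  df
}

# prevalence rows -> matrix [age_group x state] of shares, checked to sum to 1
.prev_matrix <- function(prev) {
  states <- attr(prev, "states") %||% sort(unique(prev$state))
  groups <- unique(prev$age_group)
  m <- matrix(0, length(groups), length(states),
              dimnames = list(groups, states))
  m[cbind(match(prev$age_group, groups), match(prev$state, states))] <- prev$share
  bad <- which(abs(rowSums(m) - 1) > 1e-9)
  if (length(bad))
    stop(sprintf("prevalence shares do not sum to 1 in age group %s",
                 groups[bad[1]]))
  m
}

#' Well-being adjusted health expectancy (Sullivan method)
#'
#' Computes \deqn{WAHE_x = \frac{1}{l_x} \sum_k \sum_{a \ge x}
#' \theta_k\, h_{k,g(a)}\, L_a} where \eqn{L_a} are life-table
#' person-years at single age \eqn{a}, \eqn{h_{k,g(a)}} is the prevalence
#' of state \eqn{k} in the age group containing \eqn{a} (constant within
#' group; the open 80+ group applies to every age at or above 80), and
#' \eqn{\theta_k} is the state's well-being weight with
#' \eqn{\theta_{full} = 1}. With all weights equal to one this is life
#' expectancy; with a 1/0 dichotomy it is health expectancy. Ages are
#' summed in ascending order with compensated summation.
#'
#' @param lt a \code{\link{lifetable}} for the stratum.
#' @param prev a \code{wahe_prevalence} table (see
#'   \code{\link{estimate_prevalence}}); sliced to the life table's
#'   stratum if it covers several.
#' @param weights a weight table with columns \code{country, sex, state,
#'   theta} (e.g. from \code{\link{estimate_weights}}), or a named numeric
#'   vector \code{state -> theta} for a single stratum.
#' @param x anchor age (default 15, the conventional anchor for
#'   comparability with disability-adjusted life expectancy).
#' @param country,sex stratum selectors; default taken from \code{lt}.
#' @return Years, a length-one numeric.
#' @export
compute_hale <- function(lt, prev, weights, x = 15,
                         country = lt$country, sex = lt$sex) {
  stopifnot(inherits(lt, "wahe_lifetable"))
  i <- match(x, lt$age)
  if (is.na(i)) stop(sprintf("domain error: age %s outside the life table", x))
  pv <- .pick_stratum(prev, country, sex, "prevalence")
  m <- .prev_matrix(pv)
  if (is.numeric(weights) && !is.null(names(weights))) {
    th <- weights
  } else {
    wt <- .pick_stratum(weights, country, sex, "weights")
    th <- stats::setNames(wt$theta, wt$state)
  }
  m <- m[, colSums(m) > 0, drop = FALSE]  # zero-share states contribute nothing
  miss <- setdiff(colnames(m), names(th))
  if (length(miss))
    stop(sprintf("state(s) %s present in prevalence but absent from weights",
                 paste(sprintf("'%s'", miss), collapse = ", ")))
  th <- th[colnames(m)]
  if (any(th < 0 | th > 1))
    stop("validation error: weights must lie in [0, 1]")

  ages <- lt$age[lt$age >= x]
  ascheme <- attr(prev, "age_scheme") %||% age_groups()
  g <- assign_age_group(ages, ascheme)
  miss_g <- setdiff(unique(g), rownames(m))
  if (length(miss_g))
    stop(sprintf("prevalence table lacks age group(s) %s needed by the life table",
                 paste(sprintf("'%s'", miss_g), collapse = ", ")))
  qbar <- drop(m %*% th)          # mean weight per age group
  La <- lt$L[lt$age >= x]
  kahan_sum(La * qbar[g]) / lt$l[i]
}

#' Health expectancy (dichotomous Sullivan)
#'
#' \eqn{HE_x = \frac{1}{l_x} \sum_{a \ge x} h_{full,g(a)} L_a}: expected
#' years lived in full health, where full health is the scheme's single
#' designated full state and all decreased-health states count zero.
#'
#' @inheritParams compute_hale
#' @param full_state label of the full-health state; default from the
#'   prevalence table's scheme.
#' @return Years, a length-one numeric.
#' @export
compute_he <- function(lt, prev, full_state = attr(prev, "full_state"),
                       x = 15, country = lt$country, sex = lt$sex) {
  if (is.null(full_state)) stop("full_state must be supplied")
  states <- attr(prev, "states") %||% sort(unique(prev$state))
  th <- stats::setNames(as.numeric(states == full_state), states)
  compute_hale(lt, prev, th, x = x, country = country, sex = sex)
}

#' Compute a table of summary measures of population health
#'
#' For every stratum present in \code{lifetables}, computes LE and, for
#' each supplied scheme, HE and WAHE at the anchor age, returning a tidy
#' table keyed by (country, sex, measure, scheme).
#'
#' @param lifetables named list of \code{\link{lifetable}} objects (as
#'   from \code{\link{read_lifetable}}).
#' @param prevalences named list of \code{wahe_prevalence} tables, one
#'   per scheme (names = scheme names).
#' @param weights named list of weight tables aligned with
#'   \code{prevalences}.
#' @param x anchor age.
#' @return Data.frame of class \code{wahe_smph}: \code{country, sex,
#'   measure, scheme, value_years}; \code{scheme} is NA for LE.
#' @export
compute_smph <- function(lifetables, prevalences, weights, x = 15) {
  if (inherits(lifetables, "wahe_lifetable")) lifetables <- list(lifetables)
  schemes <- names(prevalences)
  stopifnot(identical(sort(schemes), sort(names(weights))))
  rows <- list()
  for (lt in lifetables) {
    rows[[length(rows) + 1L]] <- data.frame(
      country = lt$country, sex = lt$sex, measure = "LE",
      scheme = NA_character_, value_years = life_expectancy(lt, x),
      stringsAsFactors = FALSE)
    for (sc in schemes) {
      pv <- prevalences[[sc]]
      wt <- weights[[sc]]
      rows[[length(rows) + 1L]] <- data.frame(
        country = lt$country, sex = lt$sex,
        measure = c("HE", "WAHE"), scheme = sc,
        value_years = c(compute_he(lt, pv, x = x),
                        compute_hale(lt, pv, wt, x = x)),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("wahe_smph", "data.frame"))
}

#' Summary statistics of SMPH values across countries
#'
#' Per (sex, measure, scheme): mean, standard deviation (n - 1
#' denominator) across countries, and the coefficient of variation
#' \eqn{V = 100 \cdot SD / mean}, reported both unrounded and rounded to
#' the nearest integer percent.
#'
#' @param smph a \code{wahe_smph} table (or any data.frame with columns
#'   \code{country, sex, measure, scheme, value_years}).
#' @return Data.frame with \code{sex, measure, scheme, n_countries,
#'   mean, sd, cv, cv_pct} (\code{cv_pct} = rounded integer percent).
#' @export
summarize_smph <- function(smph) {
  key <- interaction(smph$sex, smph$measure,
                     ifelse(is.na(smph$scheme), "", smph$scheme),
                     drop = TRUE, sep = "\r")
  rows <- lapply(split(seq_len(nrow(smph)), key), function(idx) {
    d <- smph[idx, , drop = FALSE]
    if (length(unique(d$country)) < 2L)
      stop(sprintf("SD undefined: single country for %s/%s",
                   d$measure[1], d$sex[1]))
    m <- mean(d$value_years)
    s <- stats::sd(d$value_years)
    v <- variation_coefficient(m, s)
    data.frame(sex = d$sex[1], measure = d$measure[1], scheme = d$scheme[1],
               n_countries = length(unique(d$country)),
               mean = m, sd = s, cv = v, cv_pct = as.integer(round(v)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
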