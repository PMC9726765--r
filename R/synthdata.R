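# Synthetic EU-SILC-like microdata, Gompertz life tables and two-way
# measure panels with known ground truth, so every stage of the pipeline
# can be verified end to end without external data.

#' Generator configuration
#'
#' Fixes the data-generating process for \code{\link{generate_survey}},
#' \code{\link{generate_lifetable}} and the analytic ground-truth
#' helpers. The latent well-being model mirrors the valuation model
#' exactly: a respondent in state \eqn{k} at age \eqn{a} has latent
#' well-being \eqn{W = \beta^*_k + \gamma^*_1 c + \gamma^*_2 c^2 +
#' \varepsilon}, \eqn{\varepsilon \sim N(0,1)},
#' \eqn{c = (a - 50)/10}, discretized to the 1..10 life-satisfaction
#' scale by the thresholds \eqn{\tau^*}. The state coefficients are tied
#' to the configured true weights through the same standardization the
#' estimator inverts, \eqn{\beta^*_k = -(1 - \theta^*_k)(\tau^*_9 -
#' \tau^*_1)}, so parameter recovery is well-posed.
#'
#' Defaults describe a plausible European adult population: four observed
#' joint MEHM states from full health to severely limited poor health
#' with true weights (1, 0.9, 0.75, 0.5), baseline shares
#' (0.35, 0.35, 0.22, 0.08) at age 50 with worse states becoming more
#' common at older ages, a right-skewed life-satisfaction distribution,
#' and Gompertz adult mortality with remaining life expectancy at 15 of
#' roughly 62 years.
#'
#' @param countries character vector of country codes.
#' @param sexes which sexes to generate.
#' @param n_per_stratum respondents per (country, sex) stratum.
#' @param seed integer seed; identical config + seed gives identical
#'   output.
#' @param age_min,age_max single-year respondent age range (EU-SILC-like:
#'   17 up to an open 80+ tail).
#' @param age_probs optional probability vector over
#'   \code{age_min:age_max}; default declines linearly with age.
#' @param states joint MEHM state labels (\code{chronic:gali:srh}).
#' @param true_thetas true well-being weights per state (full health
#'   first, = 1).
#' @param state_baseline multinomial logits at age 50 (first state is
#'   the reference, 0).
#' @param state_age_slope logit change per decade of age.
#' @param thresholds strictly increasing latent thresholds
#'   \eqn{\tau^*_1 < \dots < \tau^*_9}.
#' @param gamma_age,gamma_age2 latent age effects on the
#'   \eqn{(age-50)/10} scale.
#' @param gompertz named vector \code{c(a=, b=)} of Gompertz mortality
#'   parameters, both > 0.
#' @param omega first age of the life table's open interval.
#' @param weight_model \code{"uniform"} (all survey weights 1) or
#'   \code{"variable"} (lognormal weights).
#' @param missing_rate completely-at-random missingness rate injected
#'   into the health and well-being items.
#' @return A list of class \code{wahe_generator_config}.
#' @export
generator_config <- function(
    countries = "AA",
    sexes = c("male", "female"),
    n_per_stratum = 1000L,
    seed = 1L,
    age_min = 17L, age_max = 90L,
    age_probs = NULL,
    states = c("no:not_limited:excellent",
               "no:not_limited:very_good",
               "yes:limited_not_severely:good",
               "yes:severely_limited:poor"),
    true_thetas = c(1, 0.9, 0.75, 0.5),
    state_baseline = c(0, 0, log(0.22 / 0.35), log(0.08 / 0.35)),
    state_age_slope = c(0, 0.10, 0.35, 0.50),
    thresholds = stats::qnorm(c(0.01, 0.02, 0.04, 0.08, 0.15,
                                0.30, 0.55, 0.80, 0.95)),
    gamma_age = -0.10, gamma_age2 = -0.05,
    gompertz = c(a = 5e-5, b = 0.095),
    omega = 110L,
    weight_model = c("uniform", "variable"),
    missing_rate = 0) {
  weight_model <- match.arg(weight_model)
  k <- length(states)
  stopifnot(length(true_thetas) == k, length(state_baseline) == k,
            length(state_age_slope) == k)
  if (any(diff(thresholds) <= 0))
    stop("thresholds must be strictly increasing")
  if (true_thetas[1] != 1) stop("the first (full-health) state must have theta = 1")
  if (any(true_thetas < 0 | true_thetas > 1)) stop("true thetas must lie in [0, 1]")
  if (any(gompertz <= 0)) stop("Gompertz parameters must be positive")
  if (missing_rate < 0 || missing_rate >= 1) stop("missing_rate must be in [0, 1)")
  ages <- age_min:age_max
  if (is.null(age_probs)) {
    age_probs <- seq(1, 0.35, length.out = length(ages))
  }
  if (length(age_probs) != length(ages)) stop("age_probs length mismatch")
  age_probs <- age_probs / sum(age_probs)
  structure(list(
    countries = countries, sexes = sexes,
    n_per_stratum = as.integer(n_per_stratum), seed = as.integer(seed),
    age_min = as.integer(age_min), age_max = as.integer(age_max),
    age_probs = age_probs, states = states, true_thetas = true_thetas,
    state_baseline = state_baseline, state_age_slope = state_age_slope,
    thresholds = thresholds, gamma_age = gamma_age, gamma_age2 = gamma_age2,
    gompertz = gompertz, omega = as.integer(omega),
    weight_model = weight_model, missing_rate = missing_rate
  ), class = "wahe_generator_config")
}

# true state probabilities at one age (softmax of age-dependent logits)
.state_probs_at_age <- function(cfg, age) {
  lg <- cfg$state_baseline + cfg$state_age_slope * (age - 50) / 10
  e <- exp(lg - max(lg))
  e / sum(e)
}

#' Generate synthetic survey microdata
#'
#' Draws respondents per (country, sex) stratum: age from the configured
#' distribution, joint MEHM health state from the age-dependent
#' multinomial, life satisfaction from the latent-normal model tied to
#' the true well-being weights, and survey weights from the configured
#' weight model; the chronic/GALI/SRH items are the components of the
#' joint state. Optional missingness is injected completely at random.
#'
#' @param cfg a \code{\link{generator_config}}.
#' @return A \code{wahe_survey} data.frame (same layout as
#'   \code{\link{read_microdata}}).
#' @export
generate_survey <- function(cfg) {
  stopifnot(inherits(cfg, "wahe_generator_config"))
  set.seed(cfg$seed)
  ages <- cfg$age_min:cfg$age_max
  beta_star <- beta_from_theta(cfg$true_thetas, cfg$thresholds)
  # per-age state probability matrix (ages x states)
  P <- t(vapply(ages, function(a) .state_probs_at_age(cfg, a),
                numeric(length(cfg$states))))
  parts <- list()
  for (co in cfg$countries) for (sx in cfg$sexes) {
    n <- cfg$n_per_stratum
    age <- sample(ages, n, replace = TRUE, prob = cfg$age_probs)
    ai <- match(age, ages)
    u <- stats::runif(n)
    cum <- t(apply(P, 1, cumsum))
    si <- 1L + rowSums(u > cum[ai, , drop = FALSE])
    ac <- (age - 50) / 10
    W <- beta_star[si] + cfg$gamma_age * ac + cfg$gamma_age2 * ac^2 +
      stats::rnorm(n)
    ls <- 1L + findInterval(W, cfg$thresholds)
    comp <- do.call(rbind, strsplit(cfg$states[si], ":", fixed = TRUE))
    w <- switch(cfg$weight_model,
                uniform = rep(1, n),
                variable = stats::rlnorm(n, meanlog = 0, sdlog = 0.5))
    d <- data.frame(
      person_id = paste(co, sx, seq_len(n), sep = "-"),
      country = co, sex = sx, age = as.integer(age),
      chronic = comp[, 1], gali = comp[, 2],
      srh = match(comp[, 3], SRH_LEVELS),
      life_satisfaction = as.integer(ls),
      cs_weight = w, stringsAsFactors = FALSE
    )
    if (cfg$missing_rate > 0) {
      for (col in c("chronic", "gali", "srh", "life_satisfaction")) {
        hit <- stats::runif(n) < cfg$missing_rate
        d[[col]][hit] <- NA
      }
    }
    parts[[paste(co, sx)]] <- d
  }
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  structure(out, class = c("wahe_survey", "data.frame"))
}

#' Generate a Gompertz period life table
#'
#' Deterministic single-year life table from the Gompertz hazard
#' \eqn{\mu(x) = a e^{bx}}: \eqn{q_x = 1 - \exp(-\frac{a}{b}(e^{b(x+1)} -
#' e^{bx}))}, survivors by recursion from radix 100000 at age 15,
#' \eqn{L_a = l_a - d_a/2} for closed intervals and \eqn{L_\omega =
#' l_\omega / \mu(\omega)} for the open interval.
#'
#' @param cfg a \code{\link{generator_config}} (uses \code{gompertz},
#'   \code{omega}).
#' @param country,sex stratum labels stamped on the table.
#' @return A \code{\link{lifetable}}.
#' @export
generate_lifetable <- function(cfg, country = cfg$countries[1],
                               sex = cfg$sexes[1]) {
  stopifnot(inherits(cfg, "wahe_generator_config"))
  a <- cfg$gompertz[["a"]]; b <- cfg$gompertz[["b"]]
  radix <- 1e5
  omega <- cfg$omega
  ages <- 15:omega
  H <- function(x) a / b * exp(b * x)   # cumulative hazard primitive
  l <- radix * exp(-(H(ages) - H(15)))
  if (l[length(l)] < 1e-12 * radix) {
    keep <- l >= 1e-12 * radix
    omega <- max(ages[keep])
    warning(sprintf("survivorship exhausted; open interval shortened to %d+", omega))
    ages <- 15:omega
    l <- l[keep]
  }
  n <- length(ages)
  d <- c(-diff(l), NA)
  L <- c(l[-n] - d[-n] / 2, l[n] / (a * exp(b * omega)))
  e <- rev(cumsum(rev(L))) / l
  lifetable(ages, l, L, e = e, country = country, sex = sex)
}

#' True age-group prevalence implied by a generator configuration
#'
#' The exact population shares the survey generator converges to: within
#' each age group, the state distribution is the configured per-age
#' multinomial averaged over the respondent age distribution restricted
#' to the group. Ages above the respondent maximum carry the open
#' group's distribution.
#'
#' @param cfg a \code{\link{generator_config}}.
#' @param country,sex stratum labels for the output.
#' @param ages an \code{\link{age_groups}} scheme.
#' @return A \code{wahe_prevalence} table with \code{n_effective = NA}
#'   (population quantities, not estimates).
#' @export
true_group_prevalence <- function(cfg, country = cfg$countries[1],
                                  sex = cfg$sexes[1], ages = age_groups()) {
  stopifnot(inherits(cfg, "wahe_generator_config"))
  avec <- cfg$age_min:cfg$age_max
  grp <- assign_age_group(avec, ages)
  P <- t(vapply(avec, function(a) .state_probs_at_age(cfg, a),
                numeric(length(cfg$states))))
  rows <- list()
  for (g in unique(grp)) {
    sel <- grp == g
    w <- cfg$age_probs[sel] / sum(cfg$age_probs[sel])
    h <- drop(w %*% P[sel, , drop = FALSE])
    rows[[g]] <- data.frame(country = country, sex = sex, age_group = g,
                            state = cfg$states, share = h,
                            n_effective = NA_integer_,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, scheme = "multi", states = cfg$states,
            full_state = cfg$states[1], age_scheme = ages,
            class = c("wahe_prevalence", "data.frame"))
}

#' Analytic WAHE implied by a generator configuration
#'
#' Ground-truth well-being adjusted health expectancy: the Sullivan sum
#' evaluated with the generator's exact life table, exact age-group
#' prevalences and the configured true weights. The pipeline estimate on
#' a large generated sample converges to this value.
#'
#' @param cfg a \code{\link{generator_config}}.
#' @param x anchor age.
#' @return Years.
#' @export
analytic_wahe <- function(cfg, x = 15) {
  lt <- generate_lifetable(cfg)
  prev <- true_group_prevalence(cfg)
  th <- stats::setNames(cfg$true_thetas, cfg$states)
  compute_hale(lt, prev, th, x = x)
}

#' Generate a two-way measure panel with known variance components
#'
#' \eqn{y_{ij} = \mu + r_i + c_j + e_{ij}} with independent normal row,
#' column and error components; the theoretical consistency ICC is
#' \eqn{\sigma^2_r / (\sigma^2_r + \sigma^2_e)} and is recorded in the
#' \code{"theoretical_icc"} attribute.
#'
#' @param n_rows,k_cols matrix dimensions.
#' @param var_rows,var_cols,var_error variance components (>= 0).
#' @param seed integer seed.
#' @param mu grand mean.
#' @return Numeric matrix with dimnames and attribute
#'   \code{theoretical_icc}.
#' @export
generate_measure_panel <- function(n_rows, k_cols, var_rows, var_cols,
                                   var_error, seed = 1L, mu = 50) {
  if (any(c(var_rows, var_cols, var_error) < 0))
    stop("variance components must be non-negative")
  set.seed(seed)
  r <- stats::rnorm(n_rows, 0, sqrt(var_rows))
  cc <- stats::rnorm(k_cols, 0, sqrt(var_cols))
  e <- matrix(stats::rnorm(n_rows * k_cols, 0, sqrt(var_error)), n_rows, k_cols)
  M <- mu + outer(r, rep(1, k_cols)) + outer(rep(1, n_rows), cc) + e
  dimnames(M) <- list(paste0("R", seq_len(n_rows)), paste0("M", seq_len(k_cols)))
  attr(M, "theoretical_icc") <- if (var_rows + var_error > 0)
    var_rows / (var_rows + var_error) else NA_real_
  M
}
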