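# Health-related well-being weights: ordered probit of life satisfaction
# on health-state indicators with age controls, standardized to the [0,1]
# full-health-equivalent (Well-Year) scale by the threshold range.

AGE_CENTER <- 50
AGE_SCALE  <- 10

# age transformed to (age - 50)/10 for optimizer conditioning; squared term
# computed on the transformed scale. Reported gamma coefficients are on
# this transformed scale.
.age_c <- function(age) (age - AGE_CENTER) / AGE_SCALE

# Ordered probit negative log-likelihood and gradient.
# Parameters: beta (p), then tau_1, log(diff(tau)) (J-1 total threshold
# parameters). Reparameterisation guarantees strictly increasing
# thresholds at every optimizer step.
.op_unpack_tau <- function(th) cumsum(c(th[1], exp(th[-1])))

.op_nll <- function(par, y, X, w, J) {
  p <- ncol(X)
  eta <- if (p) drop(X %*% par[seq_len(p)]) else rep(0, length(y))
  tau <- .op_unpack_tau(par[p + seq_len(J - 1)])
  up <- c(tau, Inf)[y]
  lo <- c(-Inf, tau)[y]
  pr <- pnorm(up - eta) - pnorm(lo - eta)
  pr <- pmax(pr, 1e-300)
  -sum(w * log(pr))
}

.op_grad <- function(par, y, X, w, J) {
  p <- ncol(X)
  eta <- if (p) drop(X %*% par[seq_len(p)]) else rep(0, length(y))
  th <- par[p + seq_len(J - 1)]
  tau <- .op_unpack_tau(th)
  up <- c(tau, Inf)[y]
  lo <- c(-Inf, tau)[y]
  pr <- pmax(pnorm(up - eta) - pnorm(lo - eta), 1e-300)
  phi_up <- ifelse(is.finite(up), dnorm(up - eta), 0)
  phi_lo <- ifelse(is.finite(lo), dnorm(lo - eta), 0)
  # d loglik / d eta_i and d loglik / d tau_j accumulated per observation
  dl_deta <- (phi_lo - phi_up) / pr
  g_beta <- if (p) -drop(crossprod(X, w * dl_deta)) else numeric(0)
  dl_dtau <- numeric(J - 1)
  iu <- y                 # upper threshold index (valid when y <= J-1)
  il <- y - 1L            # lower threshold index (valid when y >= 2)
  contrib_up <- w * phi_up / pr
  contrib_lo <- -w * phi_lo / pr
  ok <- iu <= (J - 1L)
  if (any(ok)) {
    rs <- rowsum(contrib_up[ok], iu[ok])
    idx <- as.integer(rownames(rs))
    dl_dtau[idx] <- dl_dtau[idx] + rs[, 1]
  }
  okl <- il >= 1L
  if (any(okl)) {
    rs <- rowsum(contrib_lo[okl], il[okl])
    idx <- as.integer(rownames(rs))
    dl_dtau[idx] <- dl_dtau[idx] + rs[, 1]
  }
  # chain rule through tau = cumsum(c(th1, exp(th_rest)))
  g_th <- numeric(J - 1)
  rev_cum <- rev(cumsum(rev(dl_dtau)))
  g_th[1] <- rev_cum[1]
  if (J > 2) g_th[-1] <- exp(th[-1]) * rev_cum[-1]
  c(g_beta, -g_th)
}

.ordered_probit <- function(y, X, w = NULL, reltol = 1e-12, maxit = 2000L) {
  J <- max(y)
  if (J < 2L) stop("outcome has fewer than 2 observed categories")
  if (is.null(w)) w <- rep(1, length(y))
  p <- ncol(X)
  # deterministic start: all slopes 0, thresholds at the standard-normal
  # quantiles of the (weighted) empirical cumulative outcome distribution
  cum <- unname(cumsum(tapply(w, factor(y, levels = seq_len(J)), sum,
                              default = 0))) / sum(w)
  tau0 <- qnorm(pmin(pmax(cum[-J], 1e-6), 1 - 1e-6))
  tau0 <- cummax(tau0 + seq(0, 1e-6, length.out = J - 1))  # guard exact ties
  th0 <- c(tau0[1], log(pmax(diff(tau0), 1e-6)))
  par0 <- c(rep(0, p), th0)
  fit <- stats::optim(par0, .op_nll, .op_grad, y = y, X = X, w = w, J = J,
                      method = "BFGS",
                      control = list(maxit = maxit, reltol = reltol))
  beta <- fit$par[seq_len(p)]
  tau <- .op_unpack_tau(fit$par[p + seq_len(J - 1)])
  grad <- .op_grad(fit$par, y, X, w, J)
  list(beta = beta, tau = tau, loglik = -fit$value,
       converged = fit$convergence == 0L && all(diff(tau) > 0),
       grad_norm = sqrt(sum(grad^2)), n = length(y))
}

#' Fit the well-being valuation model for one stratum
#'
#' Estimates, by maximum likelihood, the ordered probit
#' \deqn{P(Y \le j \mid x) = \Phi(\tau_j - (\sum_{k \ne full} \beta_k
#' 1[state=k] + \gamma_1 c + \gamma_2 c^2))}
#' where \eqn{Y} is life satisfaction (1..10), the state indicators come
#' from \code{scheme}, and \eqn{c = (age - 50)/10} is centred, rescaled
#' age. Full health is the reference state (\eqn{\beta = 0} by
#' identification). Records missing life satisfaction or the scheme state
#' are excluded listwise. The fit is unweighted by default (survey weights
#' enter prevalence estimation, not the valuation model); set
#' \code{weighted = TRUE} for a survey-weighted pseudo-likelihood.
#'
#' @param data a \code{wahe_survey} data.frame.
#' @param scheme a \code{\link{health_scheme}}.
#' @param country,sex stratum selectors.
#' @param weighted logical; use \code{cs_weight} as pseudo-likelihood
#'   weights.
#' @return An object of class \code{ordered_probit_fit}: \code{betas}
#'   (named by state, reference full state = 0 exactly),
#'   \code{gamma_age}, \code{gamma_age2} (transformed-age scale),
#'   \code{thresholds} (strictly increasing, one fewer than the number of
#'   observed life-satisfaction categories), \code{categories} (observed
#'   outcome values), \code{loglik}, \code{n}, \code{converged},
#'   \code{n_by_state}, \code{stratum}, \code{scheme}, \code{full_state}.
#' @export
fit_wellbeing_model <- function(data, scheme, country, sex,
                                weighted = FALSE) {
  stopifnot(inherits(scheme, "health_scheme"))
  sel <- data$country == country & data$sex == sex
  d <- data[sel, , drop = FALSE]
  state <- scheme$code(d)
  keep <- !is.na(state) & !is.na(d$life_satisfaction)
  d <- d[keep, , drop = FALSE]
  state <- state[keep]
  if (!nrow(d))
    stop(sprintf("no usable records for stratum (%s, %s)", country, sex))
  ls_levels <- sort(unique(d$life_satisfaction))
  if (length(ls_levels) < 2L)
    stop(sprintf("stratum (%s, %s) has fewer than 2 observed well-being categories",
                 country, sex))
  y <- match(d$life_satisfaction, ls_levels)

  full <- scheme$full_state
  obs_states <- scheme$states %||% sort(unique(state))
  obs_states <- intersect(obs_states, unique(state))
  if (!(full %in% obs_states))
    stop(sprintf("full-health state '%s' not observed in stratum (%s, %s)",
                 full, country, sex))
  nonref <- setdiff(obs_states, full)
  sf <- factor(state, levels = c(full, nonref))
  Xs <- if (length(nonref)) stats::model.matrix(~ sf)[, -1, drop = FALSE]
        else matrix(0, nrow(d), 0)
  ac <- .age_c(d$age)
  X <- cbind(Xs, age_c = ac, age_c2 = ac^2)
  w <- if (weighted) d$cs_weight else NULL

  fit <- .ordered_probit(y, X, w)
  if (!fit$converged)
    warning(sprintf("ordered probit did not converge for stratum (%s, %s)",
                    country, sex))
  p <- length(nonref)
  betas <- c(0, fit$beta[seq_len(p)])
  names(betas) <- c(full, nonref)
  n_by_state <- table(factor(state, levels = c(full, nonref)))
  structure(list(
    stratum = c(country = country, sex = sex),
    scheme = scheme$name, full_state = full,
    betas = betas,
    gamma_age = unname(fit$beta[p + 1L]),
    gamma_age2 = unname(fit$beta[p + 2L]),
    thresholds = fit$tau,
    categories = ls_levels,
    loglik = fit$loglik, n = fit$n, converged = fit$converged,
    grad_norm = fit$grad_norm,
    n_by_state = as.integer(n_by_state), state_names = names(n_by_state),
    weighted = weighted
  ), class = "ordered_probit_fit")
}

#' @export
print.ordered_probit_fit <- function(x, ...) {
  cat(sprintf("<ordered_probit_fit> %s / %s, scheme '%s', n = %d, loglik = %.3f%s\n",
              x$stratum["country"], x$stratum["sex"], x$scheme, x$n, x$loglik,
              if (x$converged) "" else " (NOT converged)"))
  print(round(x$betas, 4))
  invisible(x)
}

# The single place the standardization formula lives: a latent-scale
# displacement beta maps to theta = 1 + beta / (tau_max - tau_min).
theta_from_beta <- function(beta, thresholds) {
  rng <- thresholds[length(thresholds)] - thresholds[1]
  if (rng <= 0) stop("threshold range must be positive")
  1 + beta / rng
}
beta_from_theta <- function(theta, thresholds) {
  rng <- thresholds[length(thresholds)] - thresholds[1]
  -(1 - theta) * rng
}

#' Standardize a valuation fit to well-being weights
#'
#' Converts latent-scale state coefficients to well-being weights
#' \eqn{\theta_k = 1 + \beta_k / (\tau_{J-1} - \tau_1)}, the
#' full-threshold-range standardization: a state whose latent displacement
#' spans the whole outcome scale gets weight 0, and full health
#' (reference, \eqn{\beta = 0}) gets weight 1. Weights are clamped to
#' [0, 1]; clamping is recorded in the provenance column.
#'
#' @param fit a converged \code{\link{fit_wellbeing_model}} result.
#' @return Data.frame with columns \code{country, sex, state, theta,
#'   provenance} (\code{estimated} or \code{clamped}), one row per state
#'   including full health (\eqn{\theta = 1}).
#' @export
standardize_weights <- function(fit) {
  stopifnot(inherits(fit, "ordered_probit_fit"))
  if (!isTRUE(fit$converged))
    stop("refusing to standardize a non-converged fit")
  if (any(diff(fit$thresholds) <= 0))
    stop("thresholds are not strictly increasing")
  theta <- theta_from_beta(fit$betas, fit$thresholds)
  clamped <- theta < 0 | theta > 1
  theta <- pmin(pmax(theta, 0), 1)
  data.frame(
    country = unname(fit$stratum["country"]),
    sex = unname(fit$stratum["sex"]),
    state = names(fit$betas),
    theta = unname(theta),
    provenance = ifelse(clamped, "clamped", "estimated"),
    stringsAsFactors = FALSE
  )
}

#' Estimate well-being weights for all strata
#'
#' Fits the valuation model separately per (country, sex) stratum and
#' standardizes to weights. A state observed fewer than \code{min_cell}
#' times in a stratum is considered too sparse for a stratum-specific
#' weight; with \code{pooled_fallback = TRUE} its weight is replaced by
#' the same-sex, all-country pooled estimate and flagged
#' \code{fallback_pooled}.
#'
#' @inheritParams fit_wellbeing_model
#' @param min_cell minimum observations per state dummy for a
#'   stratum-specific weight (default 30).
#' @param pooled_fallback logical; replace sparse-state weights by the
#'   same-sex pooled estimate.
#' @return A data.frame of class \code{wahe_weights} with columns
#'   \code{country, sex, state, theta, provenance}; attribute
#'   \code{scheme}, \code{full_state}, and \code{fits} (the per-stratum
#'   fit objects).
#' @export
estimate_weights <- function(data, scheme, min_cell = 30L,
                             pooled_fallback = TRUE, weighted = FALSE) {
  strata <- unique(data.frame(country = data$country, sex = data$sex,
                              stringsAsFactors = FALSE))
  strata <- strata[order(strata$country, strata$sex), , drop = FALSE]
  fits <- list()
  rows <- list()
  pooled_cache <- list()
  pooled_theta <- function(sex) {
    if (is.null(pooled_cache[[sex]])) {
      pd <- data[data$sex == sex, , drop = FALSE]
      pd$country <- "__pooled__"
      pf <- fit_wellbeing_model(pd, scheme, "__pooled__", sex,
                                weighted = weighted)
      pooled_cache[[sex]] <<- standardize_weights(pf)
    }
    pooled_cache[[sex]]
  }
  for (i in seq_len(nrow(strata))) {
    co <- strata$country[i]; sx <- strata$sex[i]
    fit <- fit_wellbeing_model(data, scheme, co, sx, weighted = weighted)
    fits[[paste(co, sx, sep = ":")]] <- fit
    wt <- standardize_weights(fit)
    sparse <- fit$state_names[fit$n_by_state < min_cell &
                                fit$state_names != fit$full_state]
    if (length(sparse) && pooled_fallback) {
      pw <- pooled_theta(sx)
      for (s in sparse) {
        j <- which(wt$state == s)
        pj <- which(pw$state == s)
        if (length(pj)) {
          wt$theta[j] <- pw$theta[pj]
          wt$provenance[j] <- "fallback_pooled"
        } else {
          warning(sprintf("state '%s' sparse in (%s, %s) and absent from pooled fit",
                          s, co, sx))
        }
      }
    } else if (length(sparse)) {
      warning(sprintf("state(s) %s below min_cell in (%s, %s); kept as estimated",
                      paste(sparse, collapse = ", "), co, sx))
    }
    rows[[i]] <- wt
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, scheme = scheme$name, full_state = scheme$full_state,
            fits = fits, class = c("wahe_weights", "data.frame"))
}

#' Pool well-being weights across strata
#'
#' Unweighted arithmetic mean of stratum weights per state, either by sex
#' or over all strata; the convention for reporting mean weights and for
#' pooled fallback values.
#'
#' @param weights a \code{wahe_weights} data.frame (columns
#'   \code{country, sex, state, theta}).
#' @param level \code{"sex"} (mean per state within sex) or \code{"all"}.
#' @return Data.frame with \code{state}, optionally \code{sex}, and
#'   \code{theta} (mean), \code{n_strata}.
#' @export
pool_weights <- function(weights, level = c("sex", "all")) {
  level <- match.arg(level)
  if (!nrow(weights)) stop("empty weight table")
  if (level == "sex") {
    ag <- stats::aggregate(theta ~ state + sex, data = weights, FUN = mean)
    n <- stats::aggregate(theta ~ state + sex, data = weights, FUN = length)
    ag$n_strata <- n$theta
  } else {
    ag <- stats::aggregate(theta ~ state, data = weights, FUN = mean)
    n <- stats::aggregate(theta ~ state, data = weights, FUN = length)
    ag$n_strata <- n$theta
  }
  ag
}

#' Well-Year semantics of well-being weights
#'
#' A Well-Year is one year of life equivalent in well-being to full
#' health. A state with weight \eqn{\theta} accrues \eqn{\theta} Well-Years
#' per year lived, i.e. loses \eqn{(1 - \theta)} Well-Years per year.
#' Conversely, a state in which \code{elapsed_years} of life are
#' equivalent to \code{equivalent_years} of full health carries weight
#' \eqn{\theta =} \code{equivalent_years / elapsed_years}.
#'
#' @param theta well-being weight in [0, 1].
#' @param years elapsed duration in years.
#' @return \code{well_year_loss}: Well-Years removed over the duration.
#' @examples
#' well_year_loss(0.5, 1)          # half-quality year loses 0.5 Well-Years
#' weight_from_equivalence(0.5, 1) # a year worth six months of full health
#' @export
well_year_loss <- function(theta, years = 1) {
  if (any(theta < 0 | theta > 1)) stop("theta must lie in [0, 1]")
  if (any(years < 0)) stop("years must be non-negative")
  years * (1 - theta)
}

#' @rdname well_year_loss
#' @param equivalent_years full-health duration judged equivalent in
#'   well-being to \code{elapsed_years} lived in the state.
#' @param elapsed_years elapsed duration in years.
#' @return \code{weight_from_equivalence}: the implied weight
#'   \eqn{\theta}.
#' @export
weight_from_equivalence <- function(equivalent_years, elapsed_years = 1) {
  if (any(elapsed_years <= 0)) stop("elapsed duration must be positive")
  if (any(equivalent_years < 0)) stop("equivalent duration must be non-negative")
  theta <- equivalent_years / elapsed_years
  if (any(theta > 1))
    stop("equivalent full-health duration cannot exceed elapsed duration")
  theta
}
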