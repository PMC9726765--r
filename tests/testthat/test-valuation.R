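test_that("fitted log-likelihood matches a naive summation oracle", {
  # 20-record fixture, fixed by hand: two states, varied ages, outcomes 1..5
  d <- make_survey(20,
    age = c(25, 30, 35, 40, 45, 50, 55, 60, 65, 70,
            26, 31, 36, 41, 46, 51, 56, 61, 66, 71),
    chronic = rep(c("no", "yes"), each = 10),
    ls = c(5, 4, 5, 3, 4, 5, 4, 3, 5, 4,
           2, 3, 1, 2, 3, 2, 1, 3, 2, 2))
  fit <- fit_wellbeing_model(d, health_scheme("chronic"), "AA", "male")
  ac <- (d$age - 50) / 10
  eta <- unname(fit$betas[ifelse(d$chronic == "no", "no", "yes")]) +
    fit$gamma_age * ac + fit$gamma_age2 * ac^2
  y <- match(d$life_satisfaction, fit$categories)
  expect_equal(fit$loglik, naive_op_loglik(y, eta, fit$thresholds),
               tolerance = 1e-6)
  expect_equal(unname(fit$betas["no"]), 0)  # reference fixed exactly
  expect_true(all(diff(fit$thresholds) > 0))
  expect_equal(fit$n, 20)
})

test_that("the fit agrees with an independent ordered-probit implementation", {
  skip_if_not_installed("MASS")
  cfg <- generator_config(n_per_stratum = 3000, seed = 31,
                          countries = "AA", sexes = "male")
  d <- generate_survey(cfg)
  sc <- health_scheme("multi")
  fit <- fit_wellbeing_model(d, sc, "AA", "male")
  state <- factor(sc$code(d), levels = fit$state_names)
  ac <- (d$age - 50) / 10
  ref <- MASS::polr(factor(d$life_satisfaction) ~ state + I(ac) + I(ac^2),
                    method = "probit")
  expect_equal(unname(fit$betas[-1]),
               unname(coef(ref)[1:3]), tolerance = 1e-3)
  expect_equal(unname(fit$thresholds), unname(ref$zeta), tolerance = 1e-3)
  expect_equal(fit$loglik, as.numeric(logLik(ref)), tolerance = 1e-6)
})

test_that("standardization maps latent displacements to [0,1] weights", {
  fit <- structure(list(
    stratum = c(country = "AA", sex = "male"), scheme = "srh",
    full_state = "excellent",
    betas = c(excellent = 0, very_good = 0, poor = -3, worse = -5),
    thresholds = c(-1.5, 0, 1.5), converged = TRUE
  ), class = "ordered_probit_fit")
  w <- standardize_weights(fit)
  expect_equal(w$theta[w$state == "excellent"], 1)
  expect_equal(w$theta[w$state == "very_good"], 1)      # beta = 0 -> theta = 1
  expect_equal(w$theta[w$state == "poor"], 0)           # beta = -(range) -> 0
  expect_equal(w$theta[w$state == "worse"], 0)          # clamped
  expect_equal(w$provenance[w$state == "worse"], "clamped")
  fit$converged <- FALSE
  expect_error(standardize_weights(fit), "non-converged")
})

test_that("standardization is invariant to a common latent rescaling", {
  base <- structure(list(
    stratum = c(country = "AA", sex = "male"), scheme = "srh",
    full_state = "a", betas = c(a = 0, b = -0.8, c = -2.1),
    thresholds = seq(-2, 2, length.out = 9), converged = TRUE
  ), class = "ordered_probit_fit")
  w1 <- standardize_weights(base)
  for (cc in c(0.3, 2, 11.7)) {
    scaled <- base
    scaled$betas <- base$betas * cc
    scaled$thresholds <- base$thresholds * cc
    expect_equal(standardize_weights(scaled)$theta, w1$theta,
                 tolerance = 1e-12)
  }
})

test_that("weights pool to unweighted stratum means", {
  wt <- data.frame(
    country = rep(c("A", "B", "C", "D", "E"), each = 2),
    sex = "female",
    state = rep(c("full", "sick"), 5),
    theta = c(1, 0.4, 1, 0.6, 1, 0.55, 1, 0.45, 1, 0.5))
  pooled <- pool_weights(wt, level = "all")
  expect_equal(pooled$theta[pooled$state == "full"], 1)
  expect_equal(pooled$theta[pooled$state == "sick"],
               mean(c(0.4, 0.6, 0.55, 0.45, 0.5)))
  # two-stratum symmetry
  wt2 <- wt[wt$country %in% c("A", "B"), ]
  expect_equal(pool_weights(wt2, "all")$theta[2], 0.5)
})

test_that("sparse states fall back to the pooled same-sex estimate", {
  cfg <- generator_config(n_per_stratum = 1500, seed = 5,
                          countries = c("AA", "BB"), sexes = "male")
  d <- generate_survey(cfg)
  # make the severest state sparse in BB only
  worst <- "yes:severely_limited:poor"
  sc <- health_scheme("multi")
  st <- sc$code(d)
  drop <- which(d$country == "BB" & st == worst)
  keep_few <- head(drop, 10)
  d <- d[-setdiff(drop, keep_few), , drop = FALSE]
  w <- suppressWarnings(estimate_weights(d, sc, min_cell = 30))
  bb <- w[w$country == "BB" & w$state == worst, ]
  expect_equal(bb$provenance, "fallback_pooled")
  aa <- w[w$country == "AA" & w$state == worst, ]
  expect_equal(aa$provenance, "estimated")
})

test_that("weight estimation error shrinks with sample size", {
  sc <- health_scheme("multi")
  err_at <- function(n, seed) {
    cfg <- generator_config(n_per_stratum = n, seed = seed,
                            countries = "AA", sexes = "male")
    w <- standardize_weights(
      fit_wellbeing_model(generate_survey(cfg), sc, "AA", "male"))
    th <- setNames(w$theta, w$state)[cfg$states]
    mean(abs(th - cfg$true_thetas))
  }
  seeds <- c(11, 12, 13)
  small <- mean(vapply(seeds, function(s) err_at(5000, s), numeric(1)))
  large <- mean(vapply(seeds, function(s) err_at(50000, s), numeric(1)))
  expect_lt(large, small)
})

test_that("well-year semantics: losses and equivalence weights", {
  expect_equal(well_year_loss(0.5, 1), 0.5)
  expect_equal(well_year_loss(1, 10), 0)
  expect_equal(weight_from_equivalence(0.5, 1), 0.5)
  expect_equal(weight_from_equivalence(2, 4), 0.5)
  expect_error(weight_from_equivalence(2, 1), "cannot exceed")
  expect_error(well_year_loss(1.2), "\\[0, 1\\]")
})
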