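test_that("hand-computed Sullivan values on the toy table", {
  lt <- toy_lifetable()
  prev <- toy_prevalence(c(full = 0.5, sick = 0.5))
  # WAHE: (1/100) * [1.0*0.5*265 + 0.5*0.5*265] = 1.9875
  expect_equal(compute_hale(lt, prev, c(full = 1, sick = 0.5), x = 15), 1.9875)
  # HE: 265 * 0.5 / 100 = 1.325
  expect_equal(compute_he(lt, prev, full_state = "full", x = 15), 1.325)
})

test_that("identity weights reproduce LE and dichotomy reduces to HE", {
  lt <- toy_lifetable()
  prev <- toy_prevalence(c(full = 0.3, mild = 0.45, severe = 0.25))
  expect_equal(compute_hale(lt, prev, c(full = 1, mild = 1, severe = 1)),
               life_expectancy(lt, 15), tolerance = 1e-12)
  expect_identical(
    compute_hale(lt, prev, c(full = 1, mild = 0, severe = 0)),
    compute_he(lt, prev, full_state = "full"))
  # degenerate prevalences
  p1 <- toy_prevalence(c(full = 1, sick = 0))
  expect_equal(compute_he(lt, p1, "full"), life_expectancy(lt, 15))
  p0 <- toy_prevalence(c(full = 0, sick = 1))
  expect_equal(compute_he(lt, p0, "full"), 0)
})

test_that("missing weights and out-of-range weights are rejected", {
  lt <- toy_lifetable()
  prev <- toy_prevalence(c(full = 0.5, sick = 0.5))
  expect_error(compute_hale(lt, prev, c(full = 1)), "absent from weights")
  expect_error(compute_hale(lt, prev, c(full = 1, sick = 1.4)), "\\[0, 1\\]")
})

test_that("bounds and monotonicity hold over random instances", {
  set.seed(99)
  cfg <- generator_config()
  lt <- generate_lifetable(cfg)
  le <- life_expectancy(lt, 15)
  ag <- age_groups()
  for (rep in 1:200) {
    k <- sample(2:5, 1)
    states <- c("full", paste0("s", seq_len(k - 1)))
    shares <- matrix(rgamma(length(ag$label) * k, 1), length(ag$label))
    shares <- shares / rowSums(shares)
    prev <- structure(data.frame(
      country = "AA", sex = "male",
      age_group = rep(ag$label, k), state = rep(states, each = length(ag$label)),
      share = as.vector(shares), n_effective = 1L, stringsAsFactors = FALSE
    ), states = states, full_state = "full", age_scheme = ag,
    class = c("wahe_prevalence", "data.frame"))
    th <- c(full = 1, setNames(runif(k - 1), states[-1]))
    wv <- compute_hale(lt, prev, th, x = 15)
    he <- compute_he(lt, prev, "full", x = 15)
    expect_lte(he, wv + 1e-9)
    expect_lte(wv, le + 1e-9)
    expect_gte(wv, min(th) * le - 1e-9)
    # raising one weight never lowers WAHE
    j <- sample(states[-1], 1)
    th2 <- th
    th2[j] <- min(1, th[j] + runif(1, 0, 1 - th[j]))
    expect_gte(compute_hale(lt, prev, th2, x = 15), wv - 1e-12)
  }
})

test_that("merging states with equal weights leaves WAHE unchanged", {
  lt <- toy_lifetable()
  prev <- toy_prevalence(c(full = 0.4, a = 0.25, b = 0.15, c = 0.2))
  th <- c(full = 1, a = 0.6, b = 0.6, c = 0.6)
  merged <- toy_prevalence(c(full = 0.4, decreased = 0.6))
  expect_equal(compute_hale(lt, prev, th),
               compute_hale(lt, merged, c(full = 1, decreased = 0.6)),
               tolerance = 1e-12)
})

test_that("Sullivan WAHE matches direct person-year accounting in a stationary population", {
  # stationary population implied by the life table: L_a persons at age a;
  # assign states by the true prevalence and account weighted person-years
  # directly, which is the incidence-free bookkeeping Sullivan shortcuts
  cfg <- generator_config()
  lt <- generate_lifetable(cfg)
  prev <- true_group_prevalence(cfg)
  th <- setNames(cfg$true_thetas, cfg$states)
  ag <- attr(prev, "age_scheme")
  direct <- 0
  for (i in seq_along(lt$age)) {
    g <- assign_age_group(lt$age[i], ag)
    h <- prev$share[prev$age_group == g][match(cfg$states,
                                               prev$state[prev$age_group == g])]
    direct <- direct + lt$L[i] * sum(th * h)
  }
  expect_equal(compute_hale(lt, prev, th, x = 15), direct / lt$l[1],
               tolerance = 1e-9)
})

test_that("cross-country summary statistics and variation coefficients", {
  smph <- data.frame(
    country = rep(c("A", "B", "C"), 2),
    sex = "male",
    measure = rep(c("LE", "WAHE"), each = 3),
    scheme = rep(c(NA, "srh"), each = 3),
    value_years = c(1, 2, 3, 60, 60, 60))
  s <- summarize_smph(smph)
  le <- s[s$measure == "LE", ]
  expect_equal(le$mean, 2)
  expect_equal(le$sd, 1)
  expect_equal(le$cv_pct, 50L)
  wa <- s[s$measure == "WAHE", ]
  expect_equal(wa$sd, 0)
  expect_equal(wa$cv_pct, 0L)
  one <- smph[smph$country == "A", ]
  expect_error(summarize_smph(one), "single country")
})
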