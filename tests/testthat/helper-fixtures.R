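# Shared fixtures, built in code at test time.

# minimal well-formed survey data.frame with canonical columns
make_survey <- function(n = 10, country = "AA", sex = "male",
                        age = 30, chronic = "no", gali = "not_limited",
                        srh = 1L, ls = 8L, w = 1) {
  structure(data.frame(
    person_id = as.character(seq_len(n)),
    country = rep_len(country, n), sex = rep_len(sex, n),
    age = as.integer(rep_len(age, n)),
    chronic = rep_len(chronic, n), gali = rep_len(gali, n),
    srh = as.integer(rep_len(srh, n)),
    life_satisfaction = as.integer(rep_len(ls, n)),
    cs_weight = rep_len(w, n), stringsAsFactors = FALSE
  ), class = c("wahe_survey", "data.frame"))
}

# write a survey data.frame to a temp CSV and return the path
write_survey_csv <- function(d, path = tempfile(fileext = ".csv")) {
  write.csv(d, path, row.names = FALSE)
  path
}

# the 3-age toy life table used in hand-checked expectancy examples
toy_lifetable <- function() {
  lifetable(age = 15:17, l = c(100, 90, 50), L = c(95, 70, 100),
            country = "TT", sex = "male")
}

# single-group age scheme + single-stratum prevalence table for toy cases
toy_prevalence <- function(shares, states = names(shares),
                           country = "TT", sex = "male") {
  ag <- age_groups(15)
  structure(data.frame(
    country = country, sex = sex, age_group = "15+",
    state = states, share = unname(shares), n_effective = 10L,
    stringsAsFactors = FALSE
  ), scheme = "toy", states = states, full_state = states[1],
  age_scheme = ag, class = c("wahe_prevalence", "data.frame"))
}

# naive ordered-probit log-likelihood: direct per-record summation,
# independent of the fitting code's vectorized evaluation
naive_op_loglik <- function(y, eta, tau) {
  tot <- 0
  for (i in seq_along(y)) {
    up <- if (y[i] <= length(tau)) tau[y[i]] else Inf
    lo <- if (y[i] >= 2) tau[y[i] - 1] else -Inf
    tot <- tot + log(pnorm(up - eta[i]) - pnorm(lo - eta[i]))
  }
  tot
}
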