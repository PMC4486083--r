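# Shared oracles and small builders used across the test files.

# 3 Monte-Carlo standard errors for an empirical quantile of a Normal(m, s)
# sample of size n (asymptotic SE of an order statistic).
quantile_mc_tol <- function(s, n, p) {
  z <- stats::qnorm(p)
  3 * s * sqrt(p * (1 - p) / n) / stats::dnorm(z)
}

# mean-parameter net calorie reduction, computed from first principles
analytic_net_kcal <- function(params = ssb_uncertainty_params()) {
  params$consumption_mean * params$energy_density *
    abs(params$elasticity_mean) * params$duty_rate - params$substitution_mean
}

# a single-area population tibble from named group counts
make_area <- function(code, counts, name = code) {
  tab <- ssb_consumption()
  tibble::tibble(
    area_code = code,
    area_name = name,
    gender = tab$gender,
    age_band = tab$age_band,
    count = counts
  )
}

# small deterministic national result for disaggregation tests
toy_national <- function(net_kcal = 6.5) {
  outcomes <- scale_outcomes(net_kcal)
  structure(
    list(duty_rate = 0.20,
         net_kcal = c(mean = net_kcal, p2.5 = net_kcal, p97.5 = net_kcal),
         outcomes = outcomes,
         cost_savings = cost_savings(outcomes)),
    class = "ssb_national"
  )
}
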