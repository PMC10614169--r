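# Varying-slopes trend model: log country-year mean intake regressed on a
# standardized availability covariate, with country intercepts and slopes
# drawn from a pooled bivariate distribution (two-dimensional partial
# pooling; the intercept-slope correlation rho is estimated). Time enters
# only through the covariate; no explicit time term. The bivariate
# distribution is written as intercept marginal x slope conditional,
# which keeps every country's update conjugate-friendly for Gibbs.
model {
  mu_a ~ dnorm(0, 0.25)
  mu_b ~ dnorm(0, 1)
  sigma_a ~ dnorm(0, 1) T(0,)
  sigma_b ~ dnorm(0, pow(slope_sd_scale, -2)) T(0,)
  rho ~ dunif(-1, 1)
  sigma_e ~ dnorm(0, 1) T(0,)

  for (c in 1:C) {
    alpha[c] ~ dnorm(mu_a, pow(sigma_a, -2))
    slope[c] ~ dnorm(mu_b + rho * sigma_b / (sigma_a + 1e-6) * (alpha[c] - mu_a),
                     1 / (pow(sigma_b, 2) * (1 - pow(rho, 2)) + 1e-9))
  }

  # sigma_floor keeps the likelihood proper when a series is fitted
  # exactly (noiseless synthetic data)
  for (i in 1:N) {
    m[i] <- alpha[ctry[i]] + slope[ctry[i]] * x[i]
    y[i] ~ dnorm(m[i], 1 / (pow(sigma_e, 2) + pow(sigma_floor, 2)))
  }
}
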