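# Nested hierarchical intake model.
# Observed survey-stratum means are Normal around the population-weighted
# average of the model means of the fine strata they cover. The variance
# is the survey's pooled relative variance over n (referenced to the
# model mean, which avoids the downward bias of weighting by each cell's
# own estimated SD on skewed intake data), inflated for overdispersed
# (non-representative or coarsely stratified) observations. The model mean is log-additive: a country
# level nested in a region level nested in the global level (hierarchical
# centering keeps each level's update local, which is what a Gibbs
# backend needs), plus an RW1 age curve anchored at the 20-24 reference
# band and additive sex/education/urbanicity/covariate effects; no
# demographic interactions.
model {
  b0 ~ dnorm(0, 0.25)
  beta_cov ~ dnorm(0, pow(prior_sd, -2))
  b_sex ~ dnorm(0, pow(prior_sd, -2))
  b_urb ~ dnorm(0, pow(prior_sd, -2))
  b_edu_m ~ dnorm(0, pow(prior_sd, -2))
  b_edu_h ~ dnorm(0, pow(prior_sd, -2))

  sigma_r ~ dnorm(0, 1) T(0,)
  sigma_c ~ dnorm(0, 1) T(0,)
  sigma_a ~ dnorm(0, 1) T(0,)
  gamma_od ~ dnorm(0, 1) T(0,)

  for (r in 1:R) { r_eff[r] ~ dnorm(b0, pow(sigma_r, -2)) }
  for (c in 1:C) { c_eff[c] ~ dnorm(r_eff[region_of[c]], pow(sigma_c, -2)) }

  # first-order random walk over the 22 ordered age bands, anchored at
  # the 20-24 band (index 7); JAGS resolves the declaration order
  a_age[7] <- 0
  for (k in 8:A) { a_age[k] ~ dnorm(a_age[k - 1], pow(sigma_a, -2)) }
  for (k in 1:6) { a_age[7 - k] ~ dnorm(a_age[8 - k], pow(sigma_a, -2)) }

  # sex/education/urbanicity design columns are centered, so the country
  # level c_eff is (near) orthogonal to the demographic effects, which
  # keeps the Gibbs updates well mixed
  for (s in 1:S) {
    mu_s[s] <- exp(c_eff[ctry_s[s]] + a_age[age_s[s]]
                   + b_sex * male_s[s] + b_edu_m * edu_m_s[s]
                   + b_edu_h * edu_h_s[s]
                   + b_urb * urban_s[s] + beta_cov * z_s[s])
  }

  for (j in 1:J) {
    pred[j] <- inprod(w[j, ], mu_s[idx[j, ]])
    prec_j[j] <- prec_base[j] / exp(gamma_od * infl[j])
    y[j] ~ dnorm(pred[j], prec_j[j])
  }
}
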