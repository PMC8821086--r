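# JAGS model code for the hierarchical TOJ variants.
#
# Shared structure: per DOA condition d, population location mu and spread
# sigma on the latent scale; participant-level latents drawn normally around
# them; cell counts binomial with the model family's psychometric probability.
# Latent scales: log C and log kappa (TVA), PSS in seconds and log logistic
# scale (logistic family). Participant effects are non-centered
# (latent = mu + sigma * z, z ~ N(0,1)): the centered form mixes poorly when
# the spreads are weakly identified (funnel geometry). The kappa >= 1
# constraint is enforced at the population level (truncated location); the
# participant level keeps it as a soft bound through the small spread.
# The deterministic nodes C[i,d] / K[i,d] (or pss[i,d] / S[i,d]) are always
# defined as full participant-by-DOA arrays, also under the fixed_kappa /
# fixed_C constraints, so extraction downstream is uniform.

jags_likelihood_tva <- "
  for (n in 1:Ncell) {
    vp[n] <- K[pid[n], doa[n]] / (1 + K[pid[n], doa[n]]) * C[pid[n], doa[n]]
    vr[n] <- C[pid[n], doa[n]] - vp[n]
    pr[n] <- ifelse(soa[n] < 0,
                    1 - exp(vp[n] * soa[n]) * (1 - vp[n] / (vp[n] + vr[n])),
                    exp(-vr[n] * soa[n]) * vp[n] / (vp[n] + vr[n]))
    p[n] <- max(min(pr[n], 1 - eps), eps)
    y[n] ~ dbin(p[n], N[n])
  }
"

jags_model_string <- function(family, constraint) {
  if (family == "logistic") {
    return(paste0("model {
  for (d in 1:D) {
    muPSS[d] ~ dnorm(pss_loc, pss_prec)
    sdPSS[d] ~ dnorm(0, pss_sd_prec) T(0,)
    muLS[d] ~ dnorm(ls_loc, ls_prec)
    sdLS[d] ~ dnorm(0, sd_prec) T(0,)
  }
  for (i in 1:P) {
    for (d in 1:D) {
      zP[i, d] ~ dnorm(0, 1)
      zS[i, d] ~ dnorm(0, 1)
      pss[i, d] <- muPSS[d] + sdPSS[d] * zP[i, d]
      S[i, d] <- exp(muLS[d] + sdLS[d] * zS[i, d])
    }
  }
  for (n in 1:Ncell) {
    pr[n] <- 1 / (1 + exp((soa[n] - pss[pid[n], doa[n]]) / S[pid[n], doa[n]]))
    p[n] <- max(min(pr[n], 1 - eps), eps)
    y[n] ~ dbin(p[n], N[n])
  }
}"))
  }
  c_block <- if (constraint == "fixed_C") "
  muC ~ dnorm(C_loc, C_prec)
  sdC ~ dnorm(0, sd_prec) T(0,)
  for (i in 1:P) {
    zC[i] ~ dnorm(0, 1)
    for (d in 1:D) { C[i, d] <- exp(muC + sdC * zC[i]) }
  }
" else "
  for (d in 1:D) {
    muC[d] ~ dnorm(C_loc, C_prec)
    sdC[d] ~ dnorm(0, sd_prec) T(0,)
  }
  for (i in 1:P) {
    for (d in 1:D) {
      zC[i, d] ~ dnorm(0, 1)
      C[i, d] <- exp(muC[d] + sdC[d] * zC[i, d])
    }
  }
"
  k_block <- if (constraint == "fixed_kappa") "
  muK ~ dnorm(K_loc, K_prec) T(0,)
  sdK ~ dnorm(0, sd_prec) T(0,)
  for (i in 1:P) {
    zK[i] ~ dnorm(0, 1)
    for (d in 1:D) { K[i, d] <- exp(muK + sdK * zK[i]) }
  }
" else "
  for (d in 1:D) {
    muK[d] ~ dnorm(K_loc, K_prec) T(0,)
    sdK[d] ~ dnorm(0, sd_prec) T(0,)
  }
  for (i in 1:P) {
    for (d in 1:D) {
      zK[i, d] ~ dnorm(0, 1)
      K[i, d] <- exp(muK[d] + sdK[d] * zK[i, d])
    }
  }
"
  paste0("model {", c_block, k_block, jags_likelihood_tva, "}")
}

# Prior hyperparameters in the form JAGS expects (precisions).
jags_prior_data <- function(priors, family) {
  if (family == "tva") {
    list(C_loc = priors$C_location, C_prec = 1 / priors$C_scale^2,
         K_loc = priors$kappa_location, K_prec = 1 / priors$kappa_scale^2,
         sd_prec = 1 / priors$spread_scale^2)
  } else {
    list(pss_loc = priors$pss_location, pss_prec = 1 / priors$pss_scale^2,
         pss_sd_prec = 1 / priors$pss_spread_scale^2,
         ls_loc = priors$logscale_location, ls_prec = 1 / priors$logscale_scale^2,
         sd_prec = 1 / priors$spread_scale^2)
  }
}
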