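# Shared fixtures, built in code.

# Midpoint-of-box PBPK parameter vector for a group.
mid_params <- function(group = "OC") {
  sp <- pbpk_parameter_space(group)
  v <- exp((log(sp$lower) + log(sp$upper)) / 2)
  v[sp$fixed_mask] <- sp$fixed_values[sp$fixed_mask]
  stats::setNames(v, sp$names)
}

# Fast settings for PBPK tests: shorter horizon, looser (but still tight)
# tolerances than the defaults.
fast_settings <- function(group = "OC", ...) {
  pbpk_settings(group, t_end = 4320, rtol = 1e-8, atol = 1e-8, ...)
}

# A small quadratic (log-log nonlinear) forward model used where genuine
# nonlinearity is needed: ln y = A ln p + 0.5 * (Q ln p)^2 elementwise.
quadratic_model <- function(A, Q, b = rep(0, nrow(A))) {
  forward_model(function(params) {
    x <- log(params)
    exp(drop(A %*% x + 0.5 * (Q %*% x)^2 + b))
  }, n_objectives = nrow(A))
}
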